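test_that("landscape generation partitions polygons into GMUs deterministically", {
  spec <- landscape_spec(n_polygons = 1000, n_gmus = 5, seed = 7)
  land <- generate_landscape(spec)
  expect_equal(nrow(land), 1000)
  # every polygon belongs to exactly one GMU; all GMUs populated
  expect_equal(length(unique(land$gmu)), 5)
  expect_false(anyNA(land$gmu))
  expect_equal(sum(tapply(land$area_m2, land$gmu, sum)), sum(land$area_m2))
  # determinism: same spec, same seed, byte-identical
  expect_identical(land, generate_landscape(spec))
  # canopy cover bounded on the percent scale
  expect_true(all(land$canopy_cover >= 0 & land$canopy_cover <= 100))
  expect_true(all(land$area_m2 > 0))
  expect_error(landscape_spec(3, 5), "n_polygons >= n_gmus")
  expect_error(landscape_spec(10, 2, area_mean = -1), "strictly positive")
})

test_that("polygon areas match the target lognormal moments", {
  land <- generate_landscape(landscape_spec(1e4, 5, area_mean = 2980,
                                            area_sd = 5300, seed = 1))
  se <- 5300 / sqrt(1e4)
  expect_lt(abs(mean(land$area_m2) - 2980), 3 * se)
})

test_that("shrub truth follows the logistic-presence gamma-volume model", {
  land <- generate_landscape(landscape_spec(1e4, 4, seed = 2))
  land$z <- rnorm(nrow(land))
  # all-zero coefficients: prevalence ~ 0.5
  tr0 <- species_truth("null", c("(Intercept)" = 0, z = 0),
                       volume_mean = 5e4)
  truth0 <- generate_shrub_truth(land, list(tr0), seed = 3)
  expect_lt(abs(mean(truth0$present) - 0.5), 3 * 0.5 / sqrt(1e4))
  # saturated negative intercept: prevalence ~ 0
  trlo <- species_truth("rare", c("(Intercept)" = -20, z = 0),
                        volume_mean = 5e4)
  expect_equal(mean(generate_shrub_truth(land, list(trlo), seed = 3)$present), 0)
  # mean volume among present polygons within 3 SE of truth
  v <- truth0$volume_cm3_m2[truth0$present]
  se_v <- sd(v) / sqrt(length(v))
  expect_lt(abs(mean(v) - 5e4), 3 * se_v)
  expect_error(generate_shrub_truth(land, list(species_truth(
    "bad", c("(Intercept)" = 0, no_such = 1), 1))), "unknown covariate")
})

test_that("transect designs implement the two-stage field protocol", {
  land <- generate_landscape(landscape_spec(200, 3, seed = 4))
  tr <- species_truth("w", c("(Intercept)" = 1), volume_mean = 4e4)
  truth <- generate_shrub_truth(land, list(tr), seed = 5)
  s1 <- sample_transects(land, truth, 10, design = "stage1", seed = 6)
  expect_true(all(s1$length_m == 180) && all(s1$plot_spacing_m == 60))
  expect_equal(sort(unique(s1$plot_index)), 0:3)
  s2 <- sample_transects(land, truth, 10, design = "stage2", seed = 6)
  expect_true(all(s2$length_m == 90) && all(s2$plot_spacing_m == 30))
  # stage 2 drops the widest diameter
  expect_true(all(is.na(s2$d1_cm)))
  expect_false(all(is.na(s2$d2_cm)))
  # a species absent everywhere appears in no plot
  none <- truth; none$present <- FALSE; none$volume_cm3_m2 <- 0
  s0 <- sample_transects(land, none, 10, seed = 6)
  expect_true(all(is.na(s0$species)))
  expect_error(sample_transects(land, truth, 10, design = "stage3"),
               "arg")
})

test_that("transect densities recover the truth volume in expectation", {
  land <- generate_landscape(landscape_spec(300, 3, seed = 8))
  tr <- species_truth("w", c("(Intercept)" = 4), volume_mean = 6e4,
                      volume_shape = 4)
  truth <- generate_shrub_truth(land, list(tr), seed = 9)
  ts <- sample_transects(land, truth, 300, seed = 10)
  tab <- transect_species_table(ts)
  d <- tab$density_cm3_m2[tab$present]
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - 6e4), 3 * se)
})

test_that("diet generation biases fragments by indigestibility", {
  # arithmetic: p = (2/3, 1/3), DDM = (80, 60) gives equal fragment odds
  p <- c(a = 2 / 3, b = 1 / 3); ddm <- c(a = 80, b = 60)
  smp <- generate_diet_samples(p, ddm, n_samples = 2000,
                               views_per_sample = 60, seed = 12)
  counts <- tapply(smp$views, smp$species, sum)
  q_hat <- counts / sum(counts)
  expect_lt(abs(q_hat[["a"]] - 0.5), 3 * sqrt(0.25 / (2000 * 60)))
  expect_error(generate_diet_samples(c(a = 0.6, b = 0.3), ddm, 5),
               "sum to 1")
  expect_identical(generate_diet_samples(p, ddm, 10, seed = 3),
                   generate_diet_samples(p, ddm, 10, seed = 3))
})

test_that("digestibility correction inverts the fecal generative model", {
  p <- c(w = 0.45, x = 0.30, y = 0.15, z = 0.10)
  ddm <- c(w = 70, x = 55, y = 62, z = 48)
  smp <- generate_diet_samples(p, ddm, n_samples = 500, seed = 13)
  smry <- summarize_diets(smp, ddm_by_species = ddm, total_views = 60)
  est <- smry$species$mean_proportion_all_pct / 100
  names(est) <- smry$species$species
  # componentwise bias within 3 SE over the 500-sample set
  for (s in names(p)) {
    per_sample <- smry$proportions[, s]
    se <- sd(per_sample) / sqrt(length(per_sample))
    expect_lt(abs(est[[s]] - p[[s]]), 3 * se)
  }
})

test_that("harvest generation hits the rubric extremes by scenario", {
  h <- generate_harvest(c(g1 = "declining", g2 = "stable", g3 = "increasing"),
                        seed = 15)
  ti <- trend_index(h)
  expect_lte(ti$total[ti$gmu == "g1"], -3)
  expect_gte(ti$total[ti$gmu == "g3"], 3)
  # stable has no drift: scores 0 in expectation (exact at low noise)
  h0 <- generate_harvest(c(g = "stable"), seed = 16, noise_cv = 0.01)
  expect_equal(trend_index(h0)$total, 0)
  expect_identical(generate_harvest(c(g = "declining"), seed = 2),
                   generate_harvest(c(g = "declining"), seed = 2))
  expect_error(generate_harvest(c(g = "declining"), years = 2010:2015),
               "10 years")
  expect_error(generate_harvest(c(g = "sideways")), "unknown trend")
})

test_that("generated assays land on the species' target quality", {
  tr <- species_truth("sp", c("(Intercept)" = 0), 1e4, ddm_leaf = 58,
                      dp_leaf = 5.2)
  assays <- generate_assays(list(tr))
  prof <- nutrition_profiles(assays)
  expect_equal(prof$DDM_leaf, 58, tolerance = 1e-6)
  expect_equal(prof$DP_leaf, 5.2, tolerance = 1e-6)
})

test_that("past canopy is current canopy minus GMU growth, clipped", {
  land <- generate_landscape(landscape_spec(500, 3, seed = 17))
  growth <- stats::setNames(c(10, 20, 30), sort(unique(land$gmu)))
  past <- generate_past_canopy(land, growth, seed = 18, jitter_sd = 0)
  expect_equal(past$canopy_past_pct,
               pmin(pmax(land$canopy_cover -
                           growth[as.character(land$gmu)], 0), 100),
               ignore_attr = TRUE)
  expect_true(all(past$canopy_past_pct >= 0 & past$canopy_past_pct <= 100))
})
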