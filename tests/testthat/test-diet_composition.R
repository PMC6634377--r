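make_sample_set <- function() {
  # 4 samples, 3 species; species B absent from s3/s4
  rbind(
    data.frame(sample_id = "s1", gmu = "g1", species = c("A", "B", "C"),
               views = c(30, 18, 12)),
    data.frame(sample_id = "s2", gmu = "g1", species = c("A", "B"),
               views = c(40, 20)),
    data.frame(sample_id = "s3", gmu = "g2", species = c("A", "C"),
               views = c(50, 10)),
    data.frame(sample_id = "s4", gmu = "g2", species = "A", views = 60)
  )
}

test_that("fragment proportions normalize view counts and validate the total", {
  expect_equal(fragment_proportions(c(A = 30, B = 18, C = 12), 60),
               c(A = 0.5, B = 0.3, C = 0.2))
  expect_equal(fragment_proportions(c(A = 60), 60), c(A = 1.0))
  expect_error(fragment_proportions(c(A = 30, B = 20), 60), "sum to 50")
  # zero-count species are omitted
  expect_equal(names(fragment_proportions(c(A = 60, B = 0), 60)), "A")
})

test_that("digestibility correction inverts the residue bias and renormalizes", {
  expect_equal(digestibility_correct(c(A = 0.5, B = 0.5), c(A = 80, B = 60)),
               c(A = 2 / 3, B = 1 / 3))
  # equal DDM leaves proportions unchanged (symmetry)
  p <- c(A = 0.2, B = 0.5, C = 0.3)
  expect_equal(digestibility_correct(p, c(A = 70, B = 70, C = 70)), p)
  expect_error(digestibility_correct(c(A = 1), c(A = 100)), "undefined")
  # scale-free: scaling all indigestible fractions cancels out
  p2 <- c(A = 0.4, B = 0.6)
  d1 <- c(A = 80, B = 60)          # residue 0.2, 0.4
  d2 <- c(A = 90, B = 80)          # residue 0.1, 0.2 (halved)
  expect_equal(digestibility_correct(p2, d1), digestibility_correct(p2, d2))
  # corrected proportions always sum to 1
  set.seed(42)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    p <- stats::setNames(prop.table(runif(k)), letters[1:k])
    d <- stats::setNames(runif(k, 30, 90), letters[1:k])
    expect_equal(sum(digestibility_correct(p, d)), 1, tolerance = 1e-12)
  }
})

test_that("diet summary computes occurrence and conditional mean proportions", {
  smry <- summarize_diets(make_sample_set(), total_views = 60)
  sp <- smry$species
  expect_equal(sp$occurrence_pct[sp$species == "A"], 100)
  expect_equal(sp$occurrence_pct[sp$species == "B"], 50)
  expect_equal(sp$occurrence_pct[sp$species == "C"], 50)
  # conditional mean: B present in s1 (0.3) and s2 (1/3)
  expect_equal(sp$mean_proportion_pct[sp$species == "B"],
               100 * mean(c(0.3, 1 / 3)))
  # the published conditional-mean convention: (0.20, 0.28) -> 24%
  two <- rbind(data.frame(sample_id = c("x1", "x1"), species = c("cea", "oth"),
                          views = c(12, 48)),
               data.frame(sample_id = c("x2", "x2"), species = c("cea", "oth"),
                          views = c(16.8, 43.2)),
               data.frame(sample_id = "x3", species = "oth", views = 60))
  s2 <- summarize_diets(two, total_views = 60)
  expect_equal(s2$species$mean_proportion_pct[s2$species$species == "cea"], 24)
  # order invariance
  shuffled <- make_sample_set()[sample(nrow(make_sample_set())), ]
  s3 <- summarize_diets(shuffled, total_views = 60)
  expect_equal(s3$species, smry$species)
  expect_error(summarize_diets(make_sample_set()[0, ]), "empty")
})

test_that("class shares average over all samples", {
  smry <- summarize_diets(make_sample_set(), total_views = 60,
                          species_class = c(A = "shrub", B = "grass", C = "forb"))
  shares <- smry$class_shares
  expect_equal(sum(shares), 100, tolerance = 1e-9)
  expect_equal(unname(shares["grass"]), 100 * mean(c(0.3, 1 / 3, 0, 0)))
})

test_that("minor-species filter retains species at or above the cutoff", {
  df <- data.frame(species = c("a", "b", "c"),
                   gmu_avg_proportion_pct = c(5, 2.9, 3.0))
  expect_equal(filter_minor_species(df), c("a", "c"))
  df_all <- data.frame(species = letters[1:4],
                       gmu_avg_proportion_pct = c(10, 5, 4, 3))
  expect_equal(filter_minor_species(df_all), letters[1:4])
  # 17-species screening table keeps 11
  expect_equal(length(filter_minor_species(example_diet_proportions(),
                                           column = "mean_proportion_pct")), 11)
})

test_that("species accumulation is nondecreasing and reaches total richness", {
  smp <- make_sample_set()
  acc <- species_accumulation(smp, n_permutations = 50, seed = 7)
  expect_true(all(diff(acc$richness) >= 0))
  expect_equal(acc$richness[nrow(acc)], 3)
  # identical samples give a flat curve
  flat <- do.call(rbind, lapply(1:5, function(k)
    data.frame(sample_id = paste0("s", k), species = c("A", "B"),
               views = c(30, 30))))
  acc2 <- species_accumulation(flat, n_permutations = 10, seed = 1)
  expect_true(all(acc2$richness == 2))
})

test_that("accumulation saturates quickly when every species is common", {
  # every species occurs in >= 30% of samples: curve reaches total richness by k = 10
  set.seed(11)
  p <- stats::setNames(rep(1 / 6, 6), paste0("sp", 1:6))
  ddm <- stats::setNames(rep(55, 6), names(p))
  smp <- generate_diet_samples(p, ddm, n_samples = 30, seed = 11)
  acc <- species_accumulation(smp, n_permutations = 100, seed = 2)
  expect_equal(acc$richness[acc$k == 10], 6, tolerance = 0.02)
})

test_that("bootstrap group comparison flags real differences and not null ones", {
  set.seed(3)
  mk <- function(prefix, shrub_views) do.call(rbind, lapply(1:20, function(k) {
    sv <- pmin(pmax(round(shrub_views + rnorm(1, 0, 1)), 1), 59)
    data.frame(sample_id = paste0(prefix, k), species = c("shrubby", "grassy"),
               views = c(sv, 60 - sv))
  }))
  same <- rbind(mk("a", 30), mk("b", 30))
  labels <- stats::setNames(rep(c("g1", "g2"), each = 20),
                            c(paste0("a", 1:20), paste0("b", 1:20)))
  res <- bootstrap_group_difference(same, labels,
                                    species_class = c(shrubby = "shrub",
                                                      grassy = "grass"),
                                    n_boot = 200, seed = 5)
  expect_true(all(res$overlap))
  # disjoint supports: shares ~0.1 vs ~0.9
  diff_set <- rbind(mk("a", 6), mk("b", 54))
  res2 <- bootstrap_group_difference(diff_set, labels,
                                     species_class = c(shrubby = "shrub",
                                                       grassy = "grass"),
                                     n_boot = 200, seed = 5)
  expect_false(any(res2$overlap))
  # fixed seed reproducibility
  res3 <- bootstrap_group_difference(diff_set, labels,
                                     species_class = c(shrubby = "shrub",
                                                       grassy = "grass"),
                                     n_boot = 200, seed = 5)
  expect_identical(res2$ci, res3$ci)
  expect_error(bootstrap_group_difference(same, labels, n_boot = 50), "100")
})
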