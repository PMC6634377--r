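#' Default synthetic covariate definitions
#'
#' The covariate set emulated by the landscape generator: tree canopy cover
#' (percent, beta-shaped), time since fire (derived from simulated fire
#' years), cumulative summer solar radiation and elevation (normal, in
#' standardized units and meters), and a categorical potential natural
#' vegetation (PNV) class.
#'
#' @return list of covariate definitions `(name, dist, params)`.
#' @export
default_covariate_defs <- function() {
  list(
    list(name = "canopy_cover", dist = "beta_pct", params = c(shape1 = 2, shape2 = 1.2)),
    list(name = "solar", dist = "normal", params = c(mean = 0, sd = 1)),
    list(name = "elevation", dist = "normal", params = c(mean = 1100, sd = 300)),
    list(name = "pnv", dist = "categorical",
         params = c(cedar = 0.4, grand_fir = 0.35, subalpine_fir = 0.25))
  )
}

#' Landscape specification for the synthetic generator
#'
#' @param n_polygons,n_gmus counts (`n_polygons >= n_gmus >= 1`).
#' @param area_mean,area_sd target polygon-area moments, m^2 (areas are
#'   drawn lognormal matched to these moments; defaults emulate the
#'   segmentation-scale polygons of the study region).
#' @param covariate_defs see [default_covariate_defs()].
#' @param fire_year_range calendar-year range for simulated fires.
#' @param burn_prob probability a polygon has a recorded fire.
#' @param current_year year at which `time_since_fire` is computed.
#' @param tsf_cap censoring cap (years) for unburned polygons.
#' @param seed RNG seed: the generator is a pure function of (spec, seed).
#' @return list of class `landscape_spec`.
#' @export
landscape_spec <- function(n_polygons, n_gmus, area_mean = 2980,
                           area_sd = 5300,
                           covariate_defs = default_covariate_defs(),
                           fire_year_range = c(1900, 2016), burn_prob = 0.4,
                           current_year = 2016, tsf_cap = 100, seed = 1) {
  if (n_polygons < 1 || n_gmus < 1 || n_polygons < n_gmus)
    stop("need n_polygons >= n_gmus >= 1")
  if (area_mean <= 0 || area_sd <= 0) stop("areas must be strictly positive")
  if (diff(fire_year_range) < 0) stop("bad fire_year_range")
  structure(list(n_polygons = as.integer(n_polygons),
                 n_gmus = as.integer(n_gmus), area_mean = area_mean,
                 area_sd = area_sd, covariate_defs = covariate_defs,
                 fire_year_range = fire_year_range, burn_prob = burn_prob,
                 current_year = current_year, tsf_cap = tsf_cap,
                 seed = as.integer(seed)),
            class = "landscape_spec")
}

#' Generate a synthetic polygon landscape
#'
#' Polygons are abstract records (id, GMU, area, covariate vector) — the
#' downstream analysis never uses geometry.  Areas are lognormal with
#' moments matched to the spec; every polygon belongs to exactly one GMU
#' and every GMU receives at least one polygon.
#'
#' @param spec a [landscape_spec()].
#' @return data.frame: `polygon_id`, `gmu`, `area_m2`, `fire_year` (NA if
#'   unburned), `time_since_fire`, plus one column per covariate.
#' @export
generate_landscape <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  set.seed(spec$seed)
  n <- spec$n_polygons
  sigma2 <- log(1 + (spec$area_sd / spec$area_mean)^2)
  mu <- log(spec$area_mean) - sigma2 / 2
  area <- stats::rlnorm(n, mu, sqrt(sigma2))
  gmu <- c(seq_len(spec$n_gmus),
           sample(spec$n_gmus, n - spec$n_gmus, replace = TRUE))
  gmu <- sprintf("GMU%02d", sample(gmu))  # shuffle so ids are not ordered
  out <- data.frame(polygon_id = sprintf("p%06d", seq_len(n)), gmu = gmu,
                    area_m2 = area)
  for (def in spec$covariate_defs) {
    out[[def$name]] <- switch(def$dist,
      normal = stats::rnorm(n, def$params[["mean"]], def$params[["sd"]]),
      uniform = stats::runif(n, def$params[["min"]], def$params[["max"]]),
      beta_pct = 100 * stats::rbeta(n, def$params[["shape1"]],
                                    def$params[["shape2"]]),
      categorical = sample(names(def$params), n, replace = TRUE,
                           prob = def$params),
      stop("unknown covariate distribution: ", def$dist)
    )
  }
  burned <- stats::runif(n) < spec$burn_prob
  out$fire_year <- ifelse(burned,
                          floor(stats::runif(n, spec$fire_year_range[1],
                                             spec$fire_year_range[2] + 1)), NA)
  out$time_since_fire <- ifelse(is.na(out$fire_year), spec$tsf_cap,
                                pmin(spec$current_year - out$fire_year,
                                     spec$tsf_cap))
  out
}

#' Generative truth for one shrub species
#'
#' @param species species name.
#' @param presence_coefficients named numeric vector of logistic
#'   coefficients on polygon covariates, plus `"(Intercept)"`.
#' @param volume_mean mean shrub volume density among present polygons,
#'   cm^3/m^2 (> 0).
#' @param volume_shape gamma shape of the volume distribution.
#' @param ddm_leaf leaf digestible dry matter, % in (0, 100) — drives both
#'   the diet-generation bias and the assay targets.
#' @param dp_leaf target leaf digestible protein, g/100g.
#' @param browse_prob probability a measured shrub shows browsing.
#' @return list of class `species_truth`.
#' @export
species_truth <- function(species, presence_coefficients, volume_mean,
                          volume_shape = 2, ddm_leaf = 57, dp_leaf = 5.5,
                          browse_prob = 0.3) {
  if (volume_mean <= 0) stop("volume_mean must be > 0")
  if (ddm_leaf <= 0 || ddm_leaf >= 100) stop("ddm_leaf must be in (0, 100)")
  if (is.null(names(presence_coefficients)))
    stop("presence_coefficients must be named")
  if (!"(Intercept)" %in% names(presence_coefficients))
    presence_coefficients <- c("(Intercept)" = 0, presence_coefficients)
  structure(list(species = species,
                 presence_coefficients = presence_coefficients,
                 volume_mean = volume_mean, volume_shape = volume_shape,
                 ddm_leaf = ddm_leaf, dp_leaf = dp_leaf,
                 browse_prob = browse_prob), class = "species_truth")
}

truth_linear_predictor <- function(polygons, coefs) {
  terms <- setdiff(names(coefs), "(Intercept)")
  missing <- setdiff(terms, names(polygons))
  if (length(missing))
    stop("unknown covariate in truth coefficients: ",
         paste(missing, collapse = ", "))
  lp <- rep(coefs[["(Intercept)"]], nrow(polygons))
  for (v in terms) lp <- lp + coefs[[v]] * polygons[[v]]
  lp
}

#' Generate per-polygon shrub presence and volume truth
#'
#' Presence is Bernoulli with logistic probability in the polygon
#' covariates; volume density conditional on presence is gamma with the
#' species' mean and shape.
#'
#' @param polygons a [generate_landscape()] table.
#' @param truths list of [species_truth()] objects.
#' @param seed RNG seed.
#' @return data.frame: `polygon_id`, `species`, `present`, `volume_cm3_m2`
#'   (0 where absent).
#' @export
generate_shrub_truth <- function(polygons, truths, seed = 1) {
  set.seed(seed)
  out <- do.call(rbind, lapply(truths, function(tr) {
    p <- stats::plogis(truth_linear_predictor(polygons, tr$presence_coefficients))
    present <- stats::rbinom(nrow(polygons), 1, p) == 1
    vol <- numeric(nrow(polygons))
    vol[present] <- stats::rgamma(sum(present), shape = tr$volume_shape,
                                  rate = tr$volume_shape / tr$volume_mean)
    data.frame(polygon_id = polygons$polygon_id, species = tr$species,
               present = present, volume_cm3_m2 = vol)
  }))
  rownames(out) <- NULL
  out
}

dims_from_volume <- function(v, noise_cv) {
  # inverse ellipsoid with fixed shape ratios h = 0.8 d2, d1 = 1.2 d2,
  # multiplicative lognormal noise per dimension, unbiased in the product
  d2 <- (6 * v / (pi * 0.8 * 1.2))^(1 / 3)
  sdlog <- sqrt(log(1 + noise_cv^2))
  noise <- function(n) stats::rlnorm(n, -sdlog^2 / 2, sdlog)
  n <- length(v)
  data.frame(height_cm = 0.8 * d2 * noise(n), d1_cm = 1.2 * d2 * noise(n),
             d2_cm = d2 * noise(n))
}

#' Sample vegetation transects from a synthetic landscape
#'
#' Places transects on uniformly sampled polygons and simulates the plot
#' protocol: 4 circular 2-m-radius plots per transect (stage 1: 180-m
#' transects, plots every 60 m; stage 2: 90-m transects, plots every 30 m,
#' widest diameter not recorded).  Where a species is present on the
#' polygon, each plot receives a Poisson number of shrubs whose summed
#' expected volume matches the polygon's truth density; shrub dimensions
#' are derived from volumes with multiplicative lognormal measurement
#' noise.  Dense species-plots (>= 20 shrubs) are recorded as a measured
#' subsample (5-14) with a total count.
#'
#' @param polygons a [generate_landscape()] table.
#' @param truth a [generate_shrub_truth()] table.
#' @param n_transects number of transects (>= 1).
#' @param design `"stage1"` or `"stage2"`.
#' @param seed RNG seed.
#' @param truths optional list of [species_truth()] (for browse
#'   probabilities); default browse probability 0.3.
#' @param mean_shrubs_per_plot expected shrubs per occupied species-plot.
#' @param noise_cv measurement-noise coefficient of variation per
#'   dimension.
#' @return long data.frame of shrub records (empty plots as `species = NA`
#'   rows): `transect_id`, `polygon_id`, `gmu`, `design`, `length_m`,
#'   `plot_spacing_m`, `plot_index`, `species`, `height_cm`, `d1_cm`,
#'   `d2_cm`, `browsed`, `is_subsample`, `shrub_count`.
#' @export
sample_transects <- function(polygons, truth, n_transects,
                             design = c("stage1", "stage2"), seed = 1,
                             truths = NULL, mean_shrubs_per_plot = 2,
                             noise_cv = 0.1) {
  design <- match.arg(design)
  if (n_transects < 1) stop("n_transects must be >= 1")
  set.seed(seed)
  len <- if (design == "stage1") 180 else 90
  spacing <- if (design == "stage1") 60 else 30
  browse_of <- function(s) {
    if (!is.null(truths)) {
      for (tr in truths) if (tr$species == s) return(tr$browse_prob)
    }
    0.3
  }
  poly_idx <- sample(nrow(polygons), n_transects, replace = TRUE)
  pres <- truth[truth$present, ]
  recs <- vector("list", n_transects * 4L)
  ri <- 0L
  for (t in seq_len(n_transects)) {
    pid <- polygons$polygon_id[poly_idx[t]]
    here <- pres[pres$polygon_id == pid, ]
    for (pl in 0:3) {
      base <- data.frame(transect_id = sprintf("t%05d", t), polygon_id = pid,
                         gmu = polygons$gmu[poly_idx[t]], design = design,
                         length_m = len, plot_spacing_m = spacing,
                         plot_index = pl)
      plot_rows <- NULL
      if (nrow(here)) {
        for (j in seq_len(nrow(here))) {
          n_shrubs <- stats::rpois(1, mean_shrubs_per_plot)
          if (n_shrubs == 0) next
          target <- here$volume_cm3_m2[j] * PLOT_AREA_M2 / mean_shrubs_per_plot
          subsampled <- n_shrubs >= 20
          n_measured <- if (subsampled) sample(5:14, 1) else n_shrubs
          vols <- stats::rgamma(n_measured, shape = 2, rate = 2 / target)
          dims <- dims_from_volume(vols, noise_cv)
          if (design == "stage2") dims$d1_cm <- NA_real_
          plot_rows <- rbind(plot_rows, cbind(
            base, species = here$species[j], dims,
            browsed = stats::runif(n_measured) < browse_of(here$species[j]),
            is_subsample = subsampled,
            shrub_count = if (subsampled) n_shrubs else NA_integer_,
            row.names = NULL))
        }
      }
      if (is.null(plot_rows)) {
        plot_rows <- cbind(base, species = NA_character_,
                           height_cm = NA_real_, d1_cm = NA_real_,
                           d2_cm = NA_real_, browsed = NA,
                           is_subsample = FALSE, shrub_count = NA_integer_)
      }
      ri <- ri + 1L
      recs[[ri]] <- plot_rows
    }
  }
  out <- do.call(rbind, recs[seq_len(ri)])
  rownames(out) <- NULL
  out
}

#' Generate fecal diet samples from known diet proportions
#'
#' Fecal fragments are undigested residue, so the fragment probability of
#' species *i* is its ingested proportion times its indigestible fraction,
#' renormalized: `q_i = p_i (1 - DDM_i/100) / sum_j p_j (1 - DDM_j/100)`.
#' View counts per sample are multinomial.  This is the exact inverse of
#' [digestibility_correct()].
#'
#' @param true_proportions named ingested diet proportions, summing to 1.
#' @param ddm_by_species named DDM (%, in (0, 100)) per species.
#' @param n_samples number of fecal samples.
#' @param views_per_sample views per sample (design constant, 60).
#' @param seed RNG seed.
#' @param gmu optional GMU label(s), recycled over samples.
#' @return long data.frame: `sample_id`, `gmu`, `species`, `views`
#'   (zero-count rows omitted).
#' @export
generate_diet_samples <- function(true_proportions, ddm_by_species,
                                  n_samples, views_per_sample = 60, seed = 1,
                                  gmu = "all") {
  if (abs(sum(true_proportions) - 1) > 1e-9)
    stop("true proportions must sum to 1")
  sp <- names(true_proportions)
  if (is.null(sp)) stop("true_proportions must be named")
  ddm <- ddm_by_species[sp]
  if (anyNA(ddm)) stop("DDM missing for some species")
  if (any(ddm <= 0 | ddm >= 100)) stop("DDM must be in (0, 100)")
  q <- true_proportions * (1 - ddm / 100)
  q <- q / sum(q)
  set.seed(seed)
  counts <- stats::rmultinom(n_samples, views_per_sample, q)
  gmu <- rep_len(gmu, n_samples)
  out <- do.call(rbind, lapply(seq_len(n_samples), function(k) {
    nz <- counts[, k] > 0
    data.frame(sample_id = sprintf("s%04d", k), gmu = gmu[k],
               species = sp[nz], views = counts[nz, k])
  }))
  rownames(out) <- NULL
  out
}

#' Generate per-GMU harvest series with injected trends
#'
#' Yearly permits, harvest success and days per harvest with monotone
#' drifts matching the assigned trend plus multiplicative noise.  A
#' `"declining"` GMU loses ~60% of success and permits over the period
#' while days per harvest rise ~60%; `"increasing"` mirrors this (success
#' and permits up ~80%, days down 50%) so that the default rubric scores
#' the extremes at -5/+5; `"stable"` has no drift.
#'
#' @param gmu_trends named character vector mapping GMU ->
#'   `declining`/`stable`/`increasing`.
#' @param years calendar years (>= 10 of them).
#' @param seed RNG seed.
#' @param base list of starting levels: `permits`, `success_pct`,
#'   `days_per_harvest`.
#' @param noise_cv multiplicative noise CV.
#' @return data.frame: `gmu`, `year`, `permits`, `success_pct`,
#'   `days_per_harvest`.
#' @export
generate_harvest <- function(gmu_trends, years = 1984:2016, seed = 1,
                             base = list(permits = 60, success_pct = 40,
                                         days_per_harvest = 8),
                             noise_cv = 0.05) {
  if (length(years) < 10) stop("need at least 10 years")
  bad <- setdiff(gmu_trends, c("declining", "stable", "increasing"))
  if (length(bad)) stop("unknown trend label: ", paste(bad, collapse = ", "))
  set.seed(seed)
  frac <- function(trend, up, down) switch(trend, declining = down,
                                           stable = 0, increasing = up)
  u <- (years - min(years)) / (max(years) - min(years))
  out <- do.call(rbind, lapply(names(gmu_trends), function(g) {
    tr <- gmu_trends[[g]]
    noise <- function(n) exp(stats::rnorm(n, 0, noise_cv))
    permits <- base$permits * (1 + frac(tr, 0.8, -0.6) * u) * noise(length(u))
    success <- base$success_pct * (1 + frac(tr, 0.8, -0.6) * u) * noise(length(u))
    days <- base$days_per_harvest * (1 + frac(tr, -0.5, 0.6) * u) * noise(length(u))
    data.frame(gmu = g, year = years, permits = round(pmax(permits, 0)),
               success_pct = pmin(pmax(success, 0), 100),
               days_per_harvest = pmax(days, 0.1))
  }))
  rownames(out) <- NULL
  out
}

target_assay <- function(de_leaf_target, dp_leaf_target,
                         coeffs = digestion_coefficients(),
                         lignin_ndf = 20, bsa = 0.05) {
  # invert the digestion equations to hit target leaf DE and DP
  ddm_target <- 100 * de_leaf_target / coeffs$ge_leaf
  k <- coeffs$ddm
  slope <- k[["a1"]] * exp(-k[["a2"]] * lignin_ndf) - k[["c"]] * bsa - k[["b1"]]
  ndf <- (ddm_target - k[["b0"]] - 100 * k[["b1"]]) / slope
  cp <- (dp_leaf_target + coeffs$dp[["d0"]] * -1 + coeffs$dp[["d2"]] * bsa) /
    coeffs$dp[["d1"]]
  c(cp_pct = cp, ndf_pct = ndf, lignin_ndf_pct = lignin_ndf, bsa_mg_mg = bsa)
}

#' Generate chemistry assays matching species truth
#'
#' One composited leaf assay (and a lower-quality stem assay) per species,
#' with CP and NDF chosen by inverting the digestion equations so the
#' species lands on its target leaf DE (from `ddm_leaf`) and DP, plus
#' optional normal jitter.
#'
#' @param truths list of [species_truth()] objects.
#' @param coeffs [digestion_coefficients()].
#' @param jitter_sd normal jitter (percentage points) on CP and NDF.
#' @param seed RNG seed.
#' @return assay data.frame as consumed by [nutrition_profiles()].
#' @export
generate_assays <- function(truths, coeffs = digestion_coefficients(),
                            jitter_sd = 0, seed = 1) {
  set.seed(seed)
  out <- do.call(rbind, lapply(truths, function(tr) {
    de_leaf <- coeffs$ge_leaf * tr$ddm_leaf / 100
    leaf <- target_assay(de_leaf, tr$dp_leaf, coeffs)
    stem <- target_assay(de_leaf * 0.65, max(tr$dp_leaf * 0.2, 0.1), coeffs)
    df <- rbind(data.frame(species = tr$species, part = "leaf", t(leaf)),
                data.frame(species = tr$species, part = "stem", t(stem)))
    df$cp_pct <- pmin(pmax(df$cp_pct + stats::rnorm(2, 0, jitter_sd), 0), 100)
    df$ndf_pct <- pmin(pmax(df$ndf_pct + stats::rnorm(2, 0, jitter_sd), 0), 100)
    df
  }))
  rownames(out) <- NULL
  out
}

#' Simulate canopy succession for the past epoch
#'
#' The back-cast consumes a past-canopy table normally derived from
#' reflectance change between satellite scenes; the generator emulates it
#' by removing the canopy growth accrued since the past epoch:
#' `canopy(past) = canopy(current) - growth`, clipped to \[0, 100\], with
#' growth varying by GMU.
#'
#' @param polygons a [generate_landscape()] table.
#' @param growth_by_gmu named vector of canopy growth (percentage points)
#'   per GMU, or a single number.
#' @param seed RNG seed for polygon-level jitter.
#' @param jitter_sd polygon-level growth jitter SD.
#' @return data.frame: `polygon_id`, `canopy_past_pct`.
#' @export
generate_past_canopy <- function(polygons, growth_by_gmu, seed = 1,
                                 jitter_sd = 2) {
  set.seed(seed)
  g <- if (length(growth_by_gmu) == 1 && is.null(names(growth_by_gmu)))
    rep(growth_by_gmu, nrow(polygons))
  else as.numeric(growth_by_gmu[as.character(polygons$gmu)])
  if (anyNA(g)) stop("growth missing for some GMU")
  g <- g + stats::rnorm(nrow(polygons), 0, jitter_sd)
  data.frame(polygon_id = polygons$polygon_id,
             canopy_past_pct = pmin(pmax(polygons$canopy_cover - g, 0), 100))
}
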