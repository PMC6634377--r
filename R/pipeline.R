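#' Default pipeline configuration
#'
#' Every analysis constant is a named configuration key: microhistology
#' views per sample (60), the minor-species exclusion cutoff (3%), plot
#' area (12.56 m^2), quality-class and maintenance thresholds, digestion
#' coefficients, cross-validation settings (K folds, 30 repetitions),
#' trend rubric, GMU exclusion list, and the epoch years (1984, 2016).
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1,
    views_per_sample = 60,
    minor_species_cutoff_pct = 3,
    plot_area_m2 = PLOT_AREA_M2,
    volume_formula = "ellipsoid",
    thresholds = unclass(quality_thresholds()),
    digestion = list(dp = c(d0 = -3.87, d1 = 0.9283, d2 = 11.82),
                     ddm = c(a1 = 0.9231, a2 = 0.0451, b0 = -16.03,
                             b1 = 1.02, c = 0.03),
                     ge_leaf = 19.0, ge_stem = 19.7),
    cv = list(K = 10, reps = 30, nlambda = 50),
    covariates = c("canopy_cover", "time_since_fire", "solar", "elevation"),
    quadratic = "canopy_cover",
    rubric = default_rubric(),
    exclude_gmus = character(),
    epochs = c(past = 1984, current = 2016),
    tsf_cap = 100,
    class_ddm = c(grasses = 60, forbs = 65, conifers = 45)
  )
}

#' Read a pipeline configuration file
#'
#' Reads a YAML configuration, overlays it on [default_config()], and
#' validates it.
#'
#' @param path YAML file path.
#' @return validated configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  validate_config(yaml::read_yaml(path))
}

deep_merge <- function(base, over) {
  for (k in names(over)) {
    if (is.list(base[[k]]) && is.list(over[[k]]))
      base[[k]] <- deep_merge(base[[k]], over[[k]])
    else base[[k]] <- over[[k]]
  }
  base
}

#' Validate a pipeline configuration
#'
#' Fills defaults, checks threshold ordering and units, and — when input
#' tables are supplied — checks cross-references (every species appearing
#' in the diet table must have an assay or a class-level DDM), erroring
#' with the offending species name.
#'
#' @param config partial configuration list (defaults are filled in).
#' @param diet optional diet-views table (`species` column checked).
#' @param assays optional assay table.
#' @return the completed configuration.
#' @export
validate_config <- function(config = list(), diet = NULL, assays = NULL) {
  cfg <- deep_merge(default_config(), config)
  if (is.null(cfg$seed)) stop("seed is mandatory")
  th <- do.call(quality_thresholds, cfg$thresholds)  # re-validates ordering
  cfg$thresholds <- unclass(th)
  do.call(digestion_coefficients, cfg$digestion)
  if (cfg$views_per_sample <= 0) stop("views_per_sample must be positive")
  if (cfg$cv$K < 2) stop("cv K must be >= 2")
  if (!is.null(diet) && !is.null(assays)) {
    known <- c(unique(assays$species), names(cfg$class_ddm))
    missing <- setdiff(unique(diet$species), known)
    if (length(missing))
      stop("species in diet table absent from assays: ",
           paste(missing, collapse = ", "))
  }
  cfg
}

#' Run the full nutritional-landscape pipeline
#'
#' Executes, in order: forage quality profiles from assays; digestibility-
#' corrected diet summary and minor-species filter; transect species table;
#' penalized presence fits per retained species; current- and past-epoch
#' polygon predictions; GMU forage aggregation for both epochs; percent
#' change; harvest trend index; and correlations between the index and
#' forage metrics.  All stage outputs are pure functions of (inputs,
#' config, seed).
#'
#' @param inputs list of input tables: `assays`, `diet` (long view counts),
#'   `transects` (long shrub records with `polygon_id`), `polygons`,
#'   `past_canopy` (polygon_id, canopy_past_pct), `harvest`.
#' @param config configuration list (validated; see [validate_config()]).
#' @param species optional modeled species subset (default: species
#'   retained by the diet filter that appear on transects).
#' @return a list of class `run_report`: `profiles`, `quality_summary`,
#'   `diet`, `retained_species`, `fit_stats` (per-species CV table),
#'   `gmu_current`, `gmu_past`, `change`, `trend`, `correlations`,
#'   `provenance`.
#' @export
run_pipeline <- function(inputs, config = list(), species = NULL) {
  cfg <- validate_config(config, diet = inputs$diet, assays = inputs$assays)
  set.seed(cfg$seed)
  coeffs <- do.call(digestion_coefficients, cfg$digestion)
  th <- do.call(quality_thresholds, cfg$thresholds)

  ## 1. forage quality
  profiles <- nutrition_profiles(inputs$assays, coeffs, th)
  qsum <- summarize_quality(profiles, th)

  ## 2. diet composition
  ddm <- c(stats::setNames(profiles$DDM_leaf, profiles$species), cfg$class_ddm)
  cls_map <- c(stats::setNames(rep("shrub", nrow(profiles)), profiles$species),
               grasses = "grass", forbs = "forb", conifers = "conifer")
  diet <- summarize_diets(inputs$diet, ddm, cls_map, cfg$views_per_sample)
  retained <- filter_minor_species(diet, cfg$minor_species_cutoff_pct)
  retained <- setdiff(retained, names(cfg$class_ddm))

  ## 3. vegetation -> transect modeling table
  tst <- transect_species_table(inputs$transects,
                                volume_formula = cfg$volume_formula)
  if (is.null(species))
    species <- intersect(retained, unique(tst$species))
  if (!length(species)) stop("no retained species observed on transects")
  tr_poly <- unique(inputs$transects[c("transect_id", "polygon_id")])
  tr_cov <- merge(tr_poly, inputs$polygons, by = "polygon_id")

  ## 4. presence + volume models
  fits <- list(); vols <- list(); stats_rows <- list()
  for (s in species) {
    d <- merge(tst[tst$species == s, ], tr_cov, by = "transect_id")
    X <- covariate_matrix(d, cfg$covariates, cfg$quadratic)
    fits[[s]] <- fit_presence_model(X, d$present, K = cfg$cv$K,
                                    reps = cfg$cv$reps,
                                    nlambda = cfg$cv$nlambda,
                                    seed = cfg$seed, species = s)
    pos <- d$density_cm3_m2[d$present]
    vols[[s]] <- fit_volume_model(X[d$present, , drop = FALSE], pos,
                                  K = min(cfg$cv$K, max(2, length(pos) - 1)),
                                  reps = max(2, cfg$cv$reps %/% 3),
                                  nlambda = cfg$cv$nlambda,
                                  seed = cfg$seed, species = s)
    st <- fits[[s]]$stats
    stats_rows[[s]] <- data.frame(
      species = s, auc_mean = st$auc_mean, auc_sd = st$auc_sd,
      kappa_mean = st$kappa_mean, kappa_sd = st$kappa_sd,
      pcc_mean = st$pcc_mean, pcc_sd = st$pcc_sd,
      volume_kind = vols[[s]]$kind, mean_volume = vols[[s]]$mean_volume)
  }
  fit_stats <- do.call(rbind, c(stats_rows, make.row.names = FALSE))

  ## 5. epoch predictions and GMU aggregation
  poly_cur <- backcast_covariates(inputs$polygons, canopy = NULL,
                                  ref_year = cfg$epochs[["current"]],
                                  tsf_cap = cfg$tsf_cap)
  poly_past <- backcast_covariates(inputs$polygons,
                                   canopy = inputs$past_canopy,
                                   ref_year = cfg$epochs[["past"]],
                                   tsf_cap = cfg$tsf_cap)
  occupancy_for <- function(poly) {
    X <- covariate_matrix(poly, cfg$covariates, cfg$quadratic)
    do.call(rbind, lapply(species, function(s) {
      data.frame(polygon_id = poly$polygon_id, species = s,
                 occupied = predict_polygons(fits[[s]], X))
    }))
  }
  gmu_cur <- gmu_forage(occupancy_for(poly_cur), vols, profiles,
                        inputs$polygons, epoch = "current")
  gmu_past <- gmu_forage(occupancy_for(poly_past), vols, profiles,
                         inputs$polygons, epoch = "past")
  change <- percent_change(gmu_cur, gmu_past)

  ## 6. population trend and correlations
  trend <- trend_index(inputs$harvest, cfg$rubric)
  metrics <- list()
  for (col in setdiff(names(gmu_cur$classes), "gmu")) {
    metrics[[paste0("current_", col)]] <-
      stats::setNames(gmu_cur$classes[[col]], gmu_cur$classes$gmu)
    metrics[[paste0("change_", col)]] <-
      stats::setNames(change[[col]], change$gmu)
  }
  correlations <- do.call(rbind, lapply(names(metrics), function(m) {
    res <- try(correlate_index_forage(trend, metrics[[m]],
                                      exclude = cfg$exclude_gmus,
                                      metric_name = m), silent = TRUE)
    if (inherits(res, "try-error"))
      data.frame(metric = m, r = NA_real_, p = NA_real_, n = NA_integer_,
                 excluded = length(cfg$exclude_gmus))
    else res
  }))

  structure(list(profiles = profiles, quality_summary = qsum, diet = diet,
                 retained_species = retained, presence_models = fits,
                 volume_models = vols, fit_stats = fit_stats,
                 gmu_current = gmu_cur, gmu_past = gmu_past, change = change,
                 trend = trend, correlations = correlations,
                 provenance = list(seed = cfg$seed, config = cfg,
                                   package_version =
                                     as.character(utils::packageVersion("forageshed")))),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("Nutritional-landscape run report (seed ", x$provenance$seed, ")\n",
      sep = "")
  cat("- species retained by diet filter:", length(x$retained_species), "\n")
  cat("- presence models fitted:", nrow(x$fit_stats),
      sprintf("(mean CV AUC %.3f)", mean(x$fit_stats$auc_mean)), "\n")
  cat("- GMUs:", nrow(x$gmu_current$classes), "| total forage declined in",
      sum(x$change$total < 0, na.rm = TRUE), "GMU(s)\n")
  r60 <- x$correlations[x$correlations$metric == "change_energy_moderate", ]
  if (nrow(r60) && is.finite(r60$r))
    cat(sprintf("- index vs %% change in moderate-energy forage: r = %.2f (p = %.3f, n = %d)\n",
                r60$r, r60$p, r60$n))
  invisible(x)
}

#' Simulate a complete synthetic study
#'
#' Builds a coherent set of all five study inputs with known truth: a
#' polygon landscape; shrub presence/volume truth for a small forage
#' community whose moderate-energy species are shade-intolerant (negative
#' canopy-cover coefficients); transect samples; chemistry assays matching
#' each species' target quality; fecal diet samples; per-GMU canopy
#' succession since the past epoch; and harvest series whose injected
#' trends are coupled (when `couple = TRUE`) to each GMU's canopy growth —
#' GMUs that lost the most forage get declining harvest signals, so the
#' index-forage correlation has a known positive sign.
#'
#' @param n_polygons,n_gmus,n_transects,n_diet_samples problem sizes.
#' @param seed RNG seed (all sub-generators are seeded from it).
#' @param couple couple harvest trends to canopy growth (TRUE) or assign
#'   them at random (FALSE).
#' @return list with `polygons`, `truth`, `truths`, `transects`, `assays`,
#'   `diet`, `past_canopy`, `harvest`, `growth_by_gmu`, `inputs` (the
#'   subset shaped for [run_pipeline()]).
#' @export
simulate_study <- function(n_polygons = 3000, n_gmus = 12,
                           n_transects = 400, n_diet_samples = 43,
                           seed = 1, couple = TRUE) {
  if (n_gmus < 3) stop("simulate_study needs n_gmus >= 3")
  spec <- landscape_spec(n_polygons, n_gmus, seed = seed)
  polygons <- generate_landscape(spec)
  polygons$canopy_std <- (polygons$canopy_cover - 50) / 25
  truths <- list(
    species_truth("shadeshy moderate A",
                  c("(Intercept)" = 0.3, canopy_std = -1.4),
                  volume_mean = 90000, ddm_leaf = 57, dp_leaf = 5.5),
    species_truth("shadeshy moderate B",
                  c("(Intercept)" = 0.0, canopy_std = -1.1),
                  volume_mean = 60000, ddm_leaf = 56, dp_leaf = 4.8),
    species_truth("shadeshy high",
                  c("(Intercept)" = -0.4, canopy_std = -1.6),
                  volume_mean = 80000, ddm_leaf = 63, dp_leaf = 7.0),
    species_truth("shadetolerant low",
                  c("(Intercept)" = -0.2, canopy_std = 0.8),
                  volume_mean = 20000, ddm_leaf = 52, dp_leaf = 4.0)
  )
  truth <- generate_shrub_truth(polygons, truths, seed = seed + 1)
  transects <- sample_transects(polygons, truth, n_transects,
                                design = "stage1", seed = seed + 2,
                                truths = truths)
  assays <- generate_assays(truths, seed = seed + 3)
  sp <- vapply(truths, `[[`, "", "species")
  p_diet <- stats::setNames(c(0.30, 0.15, 0.10, 0.04, 0.18, 0.08, 0.15),
                            c(sp, "grasses", "forbs", "conifers"))
  ddm_diet <- c(stats::setNames(vapply(truths, `[[`, 0, "ddm_leaf"), sp),
                grasses = 60, forbs = 65, conifers = 45)
  diet <- generate_diet_samples(p_diet, ddm_diet, n_diet_samples,
                                seed = seed + 4,
                                gmu = rep(c("A", "B"),
                                          length.out = n_diet_samples))
  set.seed(seed + 5)
  gmus <- sort(unique(polygons$gmu))
  growth <- stats::setNames(stats::runif(length(gmus), 0, 28), gmus)
  past_canopy <- generate_past_canopy(polygons, growth, seed = seed + 6)
  ord <- order(growth, decreasing = TRUE)  # most canopy growth = most forage lost
  trend_lab <- character(length(gmus))
  third <- ceiling(length(gmus) / 3)
  trend_lab[ord[seq_len(third)]] <- "declining"
  trend_lab[ord[seq(third + 1, 2 * third)]] <- "stable"
  trend_lab[ord[seq(2 * third + 1, length(gmus))]] <- "increasing"
  if (!couple) trend_lab <- sample(trend_lab)
  harvest <- generate_harvest(stats::setNames(trend_lab, gmus),
                              seed = seed + 7)
  list(polygons = polygons, truth = truth, truths = truths,
       transects = transects, assays = assays, diet = diet,
       past_canopy = past_canopy, harvest = harvest,
       growth_by_gmu = growth,
       inputs = list(assays = assays, diet = diet, transects = transects,
                     polygons = polygons, past_canopy = past_canopy,
                     harvest = harvest))
}
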