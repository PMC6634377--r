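#' Fragment proportions from microhistological view counts
#'
#' Each fecal sample is scanned a fixed number of times under magnification
#' (by design, 60 views: 20 views on each of 3 slides) and every view is
#' attributed to a species or forage class.  Raw fragment proportions are
#' view counts over total views; zero-count species are dropped.
#'
#' @param view_counts named non-negative integer vector, one element per
#'   species/class observed.
#' @param total_views number of views per sample (design constant, 60).
#' @return named numeric vector of proportions summing to 1.
#' @export
fragment_proportions <- function(view_counts, total_views = sum(view_counts)) {
  if (is.null(names(view_counts)) || any(!nzchar(names(view_counts))))
    stop("view_counts must be named by species")
  if (any(view_counts < 0)) stop("view counts must be non-negative")
  if (total_views <= 0) stop("total_views must be positive")
  if (sum(view_counts) != total_views)
    stop(sprintf("view counts sum to %d, not total_views = %d",
                 sum(view_counts), total_views))
  p <- view_counts[view_counts > 0] / total_views
  stats::setNames(as.numeric(p), names(view_counts)[view_counts > 0])
}

#' Correct diet proportions for digestibility
#'
#' Fecal fragments are undigested residue, so a highly digestible forage is
#' under-represented in fragment counts.  Inverting the observation process,
#' the ingested proportion of species *i* is proportional to the fragment
#' proportion divided by its indigestible fraction:
#' `p'_i = (p_i / (1 - DDM_i/100)) / sum_j(...)`.
#'
#' @param proportions named fragment proportions (need not sum to 1; they
#'   are renormalized).
#' @param ddm_by_species named vector of digestible dry matter (%, in
#'   (0, 100)) covering every species present.
#' @return named corrected proportions summing to 1.
#' @export
digestibility_correct <- function(proportions, ddm_by_species) {
  sp <- names(proportions)
  if (is.null(sp)) stop("proportions must be named by species")
  missing <- setdiff(sp, names(ddm_by_species))
  if (length(missing))
    stop("no DDM value for species: ", paste(missing, collapse = ", "))
  ddm <- ddm_by_species[sp]
  if (any(ddm >= 100))
    stop("DDM = 100 gives zero indigestible residue; correction undefined")
  if (any(ddm <= 0)) stop("DDM must lie in (0, 100)")
  w <- proportions / (1 - ddm / 100)
  w / sum(w)
}

#' Summarize fecal diet samples
#'
#' Computes, per species: percent occurrence (share of samples in which the
#' species was detected), mean dietary proportion conditional on presence
#' (the convention used for reporting: the average contribution within the
#' diets that contain the species), the unconditional mean over all samples,
#' and the GMU-averaged unconditional mean used by the minor-species filter.
#' Class shares (shrub/grass/forb/conifer) are averaged over all samples.
#'
#' @param samples long data.frame with columns `sample_id`, `species`,
#'   `views`, and optionally `gmu`; zero-count rows may be omitted.
#' @param ddm_by_species named DDM (%) vector; `NULL` skips the
#'   digestibility correction (raw fragment proportions).
#' @param species_class optional named character vector mapping species to
#'   forage classes (`shrub`, `grass`, `forb`, `conifer`); unmapped species
#'   default to `shrub`.
#' @param total_views views per sample (design constant).
#' @return a list of class `diet_summary`: `species` (data.frame with
#'   `species`, `occurrence_pct`, `mean_proportion_pct` (conditional),
#'   `mean_proportion_all_pct`, `gmu_avg_proportion_pct`), `class_shares`
#'   (named mean percentages), `n_samples`, `corrected`.
#' @export
summarize_diets <- function(samples, ddm_by_species = NULL,
                            species_class = NULL, total_views = 60) {
  need <- c("sample_id", "species", "views")
  if (!all(need %in% names(samples)))
    stop("samples must have columns: ", paste(need, collapse = ", "))
  if (nrow(samples) == 0) stop("empty sample set")
  if (!"gmu" %in% names(samples)) samples$gmu <- "all"
  ids <- unique(samples$sample_id)
  all_sp <- sort(unique(samples$species))
  prop <- matrix(0, length(ids), length(all_sp),
                 dimnames = list(as.character(ids), all_sp))
  gmu_of <- character(length(ids))
  for (k in seq_along(ids)) {
    rows <- samples[samples$sample_id == ids[k], ]
    gmu_of[k] <- as.character(rows$gmu[1])
    counts <- c(tapply(rows$views, rows$species, sum))
    p <- fragment_proportions(counts[counts > 0], total_views)
    if (!is.null(ddm_by_species)) p <- digestibility_correct(p, ddm_by_species)
    prop[k, names(p)] <- p
  }
  present <- prop > 0
  occurrence <- 100 * colMeans(present)
  cond_mean <- vapply(all_sp, function(s) {
    i <- present[, s]
    if (any(i)) 100 * mean(prop[i, s]) else 0
  }, numeric(1))
  uncond_mean <- 100 * colMeans(prop)
  by_gmu <- rowsum(prop, gmu_of) / as.vector(table(gmu_of)[sort(unique(gmu_of))])
  gmu_avg <- 100 * colMeans(by_gmu)
  cls <- rep("shrub", length(all_sp))
  names(cls) <- all_sp
  if (!is.null(species_class)) {
    hit <- intersect(all_sp, names(species_class))
    cls[hit] <- species_class[hit]
  }
  class_share <- vapply(c("shrub", "grass", "forb", "conifer"), function(cl) {
    cols <- all_sp[cls == cl]
    if (!length(cols)) 0 else 100 * mean(rowSums(prop[, cols, drop = FALSE]))
  }, numeric(1))
  structure(list(
    species = data.frame(species = all_sp,
                         occurrence_pct = occurrence,
                         mean_proportion_pct = cond_mean,
                         mean_proportion_all_pct = uncond_mean,
                         gmu_avg_proportion_pct = gmu_avg,
                         class = cls, row.names = NULL),
    class_shares = class_share,
    proportions = prop,
    gmu = stats::setNames(gmu_of, rownames(prop)),
    n_samples = length(ids),
    corrected = !is.null(ddm_by_species)
  ), class = "diet_summary")
}

#' @export
print.diet_summary <- function(x, ...) {
  cat("Diet summary over", x$n_samples, "fecal samples",
      if (x$corrected) "(digestibility-corrected)" else "(raw)", "\n")
  df <- x$species
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, 1)
  print(df[order(-df$occurrence_pct), c("species", "occurrence_pct",
                                        "mean_proportion_pct", "class")],
        row.names = FALSE)
  cat("class shares (%):",
      paste(names(x$class_shares), round(x$class_shares, 1), sep = "=",
            collapse = "  "), "\n")
  invisible(x)
}

#' Exclude incidentally consumed minor species
#'
#' Species whose GMU-averaged mean dietary proportion falls below the cutoff
#' (default 3%, boundary inclusive: exactly 3% is retained) are treated as
#' incidental and dropped from downstream analyses.
#'
#' @param summary a `diet_summary` from [summarize_diets()], or a
#'   data.frame with `species` and a proportion column in percent.
#' @param cutoff exclusion cutoff, percent.
#' @param column proportion column used when a data.frame is supplied.
#' @return character vector of retained species.
#' @export
filter_minor_species <- function(summary, cutoff = 3,
                                 column = "gmu_avg_proportion_pct") {
  df <- if (inherits(summary, "diet_summary")) summary$species else summary
  if (!column %in% names(df)) {
    if ("mean_proportion_pct" %in% names(df)) column <- "mean_proportion_pct"
    else stop("no proportion column found")
  }
  df$species[df[[column]] >= cutoff]
}

#' Species accumulation curve over fecal samples
#'
#' Mean number of distinct forage taxa detected in the first *k* samples,
#' averaged over random sample orderings — used to check that the number of
#' fecal samples collected was adequate to detect the primary forage
#' species.
#'
#' @param samples long data.frame as in [summarize_diets()].
#' @param n_permutations random orderings to average over.
#' @param seed RNG seed.
#' @return data.frame with columns `k` and `richness` (nondecreasing).
#' @export
species_accumulation <- function(samples, n_permutations = 100, seed = 1) {
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  ids <- unique(samples$sample_id)
  sp <- sort(unique(samples$species))
  inc <- matrix(0L, length(ids), length(sp),
                dimnames = list(as.character(ids), sp))
  pos <- samples[samples$views > 0, ]
  inc[cbind(match(pos$sample_id, ids), match(pos$species, sp))] <- 1L
  set.seed(seed)
  acc <- vegan::specaccum(inc, method = "random",
                          permutations = max(n_permutations, 2))
  data.frame(k = acc$sites, richness = acc$richness)
}

#' Bootstrap comparison of diet composition between groups
#'
#' Percentile bootstrap 95% confidence intervals for the mean share of each
#' forage class within each group of samples (e.g., two sampling areas),
#' with an overlap flag per class.  Overlapping intervals are read as no
#' significant difference between groups.
#'
#' @param samples long data.frame as in [summarize_diets()].
#' @param group_labels named vector mapping `sample_id` to group.
#' @param ddm_by_species optional DDM vector for correction.
#' @param species_class optional class map (see [summarize_diets()]).
#' @param n_boot bootstrap replicates (>= 100).
#' @param conf confidence level.
#' @param seed RNG seed.
#' @param total_views views per sample.
#' @return list with `ci` (data.frame: class, group, mean, lower, upper)
#'   and `overlap` (named logical per class).
#' @export
bootstrap_group_difference <- function(samples, group_labels,
                                       ddm_by_species = NULL,
                                       species_class = NULL,
                                       n_boot = 1000, conf = 0.95, seed = 1,
                                       total_views = 60) {
  if (n_boot < 100) stop("n_boot must be >= 100")
  smry <- summarize_diets(samples, ddm_by_species, species_class, total_views)
  prop <- smry$proportions
  grp <- group_labels[rownames(prop)]
  if (any(is.na(grp))) stop("every sample_id needs a group label")
  groups <- unique(grp)
  if (length(groups) < 2) stop("need >= 2 groups")
  if (any(table(grp) < 2)) stop("each group needs >= 2 samples")
  cls <- smry$species$class[match(colnames(prop), smry$species$species)]
  class_levels <- unique(cls)
  share <- sapply(class_levels, function(cl)
    rowSums(prop[, cls == cl, drop = FALSE]))
  if (is.null(dim(share))) share <- matrix(share, ncol = length(class_levels),
                                           dimnames = list(NULL, class_levels))
  set.seed(seed)
  alpha <- (1 - conf) / 2
  ci <- do.call(rbind, lapply(groups, function(g) {
    idx <- which(grp == g)
    boots <- replicate(n_boot, {
      colMeans(share[sample(idx, length(idx), replace = TRUE), , drop = FALSE])
    })
    if (is.null(dim(boots))) boots <- matrix(boots, nrow = 1,
                                             dimnames = list(class_levels, NULL))
    data.frame(class = class_levels, group = g,
               mean = colMeans(share[idx, , drop = FALSE]),
               lower = apply(boots, 1, stats::quantile, alpha),
               upper = apply(boots, 1, stats::quantile, 1 - alpha),
               row.names = NULL)
  }))
  overlap <- vapply(class_levels, function(cl) {
    r <- ci[ci$class == cl, ]
    max(r$lower) <= min(r$upper)
  }, logical(1))
  list(ci = ci, overlap = overlap)
}
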