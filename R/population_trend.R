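#' Default trend-scoring rubric
#'
#' Maps the relative change of each harvest metric over the study period to
#' integer component scores.  The relative change statistic is the OLS
#' slope of the yearly series times the period span, divided by the period
#' mean — a scale-free fractional change over the whole period, robust to
#' single-year noise.  Harvest success and permits score in \[-2, 2\]
#' (cutpoints at 10% and 50% relative change); days per harvest scores in
#' \[-1, 1\] with the sign inverted (more days hunted per animal = worse),
#' cutpoint 25%.  Component ranges sum to the index envelope \[-5, 5\].
#' Cutpoints are conventions of this implementation and fully overridable.
#'
#' @return nested list with per-metric `cutpoints`, `max_score`, `invert`.
#' @export
default_rubric <- function() {
  list(
    success = list(cutpoints = c(0.10, 0.50), max_score = 2, invert = FALSE),
    permits = list(cutpoints = c(0.10, 0.50), max_score = 2, invert = FALSE),
    days = list(cutpoints = c(0.25), max_score = 1, invert = TRUE)
  )
}

relative_change <- function(years, values, min_years = 5, max_gap = 2) {
  ok <- is.finite(values)
  if (sum(ok) < min_years)
    stop("need at least ", min_years, " non-missing years")
  # interpolate short gaps only; longer gaps stay missing
  filled <- zoo::na.approx(values, x = years, maxgap = max_gap, na.rm = FALSE)
  keep <- is.finite(filled)
  yr <- years[keep]; v <- filled[keep]
  m <- mean(v)
  if (m == 0) return(0)
  slope <- stats::coef(stats::lm(v ~ yr))[[2]]
  slope * (max(yr) - min(yr)) / m
}

#' Score one harvest metric's trend
#'
#' Computes the relative change of a yearly series and maps it through the
#' rubric cutpoints to an integer score.  For a metric with cutpoints
#' `c(c1, c2)` the score is 0 when `|rel| < c1`, +/-1 when `c1 <= |rel| <
#' c2`, and +/-2 beyond `c2` (one fewer level for single-cutpoint
#' metrics); inverted metrics flip the sign.
#'
#' @param years,values yearly observations (missing years as `NA`).
#' @param metric one of `"success"`, `"permits"`, `"days"`.
#' @param rubric see [default_rubric()].
#' @return integer score.
#' @export
metric_score <- function(years, values, metric = c("success", "permits", "days"),
                         rubric = default_rubric()) {
  metric <- match.arg(metric)
  r <- rubric[[metric]]
  rel <- relative_change(years, values)
  score <- sum(abs(rel) >= r$cutpoints) * sign(rel)
  score <- max(min(score, r$max_score), -r$max_score)
  as.integer(if (r$invert) -score else score)
}

#' Harvest-based population-trend index per GMU
#'
#' Sums the component scores for harvest success, permits offered, and days
#' per harvest into an integer index in \[-5, 5\]; negative values indicate
#' population decline, zero is stable, positive increasing.
#'
#' @param harvest data.frame with columns `gmu`, `year`, `permits`,
#'   `success_pct`, `days_per_harvest`.
#' @param rubric see [default_rubric()].
#' @return data.frame: `gmu`, `s_success`, `s_permits`, `s_days`, `total`,
#'   `label`.
#' @export
trend_index <- function(harvest, rubric = default_rubric()) {
  need <- c("gmu", "year", "permits", "success_pct", "days_per_harvest")
  if (!all(need %in% names(harvest)))
    stop("harvest must have columns: ", paste(need, collapse = ", "))
  out <- do.call(rbind, lapply(split(harvest, harvest$gmu), function(h) {
    h <- h[order(h$year), ]
    s1 <- metric_score(h$year, h$success_pct, "success", rubric)
    s2 <- metric_score(h$year, h$permits, "permits", rubric)
    s3 <- metric_score(h$year, h$days_per_harvest, "days", rubric)
    total <- s1 + s2 + s3
    data.frame(gmu = h$gmu[1], s_success = s1, s_permits = s2, s_days = s3,
               total = total,
               label = if (total < 0) "declining" else if (total > 0)
                 "increasing" else "stable")
  }))
  rownames(out) <- NULL
  if (any(abs(out$total) > 5)) stop("index outside [-5, 5]")
  out
}

#' Correlate the population-trend index with a forage metric across GMUs
#'
#' Pearson correlation (two-sided test) between per-GMU index values and a
#' per-GMU forage quantity or percent-change metric, after excluding GMUs
#' whose forage predictions are dominated by recent disturbance or whose
#' harvest series are truncated.
#'
#' @param indices data.frame with `gmu` and `total` (from [trend_index()]).
#' @param forage data.frame with `gmu` and `value`, or a named vector.
#' @param exclude GMU ids to drop before correlating.
#' @param metric_name label carried in the result.
#' @return data.frame: `metric`, `r`, `p`, `n`, `excluded`.
#' @export
correlate_index_forage <- function(indices, forage, exclude = character(),
                                   metric_name = "forage") {
  if (!is.data.frame(forage))
    forage <- data.frame(gmu = names(forage), value = as.numeric(forage))
  df <- merge(indices[c("gmu", "total")], forage, by = "gmu")
  df <- df[!(as.character(df$gmu) %in% as.character(exclude)), ]
  df <- df[is.finite(df$value), ]
  if (nrow(df) < 3) stop("need at least 3 GMUs after exclusion")
  if (stats::var(df$total) == 0 || stats::var(df$value) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(df$total, df$value, method = "pearson")
  data.frame(metric = metric_name, r = unname(ct$estimate), p = ct$p.value,
             n = nrow(df), excluded = length(exclude))
}
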