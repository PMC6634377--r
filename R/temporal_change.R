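#' Reconstruct polygon covariates for a reference epoch
#'
#' Replaces canopy cover with an epoch-specific estimate (for the past
#' epoch, derived externally from reflectance change between satellite
#' scenes) and recomputes time since fire relative to the epoch year: fires
#' later than the epoch never influence its state, and polygons with no
#' fire on record by the epoch get a censoring cap.  All other covariates
#' are epoch-invariant and copied through.
#'
#' @param polygons data.frame with `polygon_id` and covariate columns
#'   including `canopy_cover`.
#' @param canopy named or `polygon_id`-aligned vector of epoch canopy cover
#'   (%), or a data.frame with `polygon_id` and a canopy column; `NULL`
#'   keeps the current canopy (identity epoch).
#' @param fire_years data.frame with `polygon_id`, `fire_year` (one row per
#'   fire; `NA` or absent id = no recorded fire), or `NULL` to use a
#'   `fire_year` column on `polygons`.
#' @param ref_year epoch year (1984 for the back-cast, 2016 for current).
#' @param tsf_cap censoring cap for time since fire, years.
#' @return data.frame like `polygons` with `canopy_cover`,
#'   `time_since_fire` set for the epoch and an `epoch_year` column.
#' @export
backcast_covariates <- function(polygons, canopy = NULL, fire_years = NULL,
                                ref_year = 1984, tsf_cap = 100) {
  out <- polygons
  if (!is.null(canopy)) {
    if (is.data.frame(canopy)) {
      col <- setdiff(names(canopy), "polygon_id")[1]
      canopy <- stats::setNames(canopy[[col]], canopy$polygon_id)
    }
    if (!is.null(names(canopy))) {
      idx <- match(as.character(out$polygon_id), names(canopy))
      if (anyNA(idx)) stop("missing past canopy for ",
                           sum(is.na(idx)), " polygon(s)")
      canopy <- canopy[idx]
    } else if (length(canopy) != nrow(out)) {
      stop("missing past canopy: length mismatch")
    }
    if (anyNA(canopy)) stop("missing past canopy values")
    out$canopy_cover <- pmin(pmax(as.numeric(canopy), 0), 100)
  }
  if (is.null(fire_years)) {
    fy <- stats::setNames(out$fire_year, out$polygon_id)
  } else {
    fy <- stats::setNames(fire_years$fire_year, fire_years$polygon_id)
  }
  last_fire <- vapply(as.character(out$polygon_id), function(id) {
    f <- fy[names(fy) == id]
    f <- f[!is.na(f) & f <= ref_year]
    if (length(f)) max(f) else NA_real_
  }, numeric(1))
  out$time_since_fire <- ifelse(is.na(last_fire), tsf_cap,
                                pmin(ref_year - last_fire, tsf_cap))
  out$epoch_year <- ref_year
  out
}

#' Percent change in GMU forage between epochs
#'
#' `100 * (current - past) / past` per GMU for every quality class and the
#' total.  Cells with zero past density are undefined and reported as `NA`
#' rather than infinite.
#'
#' @param current,past `gmu_forage_summary` objects ([gmu_forage()]) on the
#'   same GMU set and class definitions.
#' @return data.frame: `gmu` plus one percent-change column per class and
#'   `total`.
#' @export
percent_change <- function(current, past) {
  cur <- current$classes; pst <- past$classes
  if (!identical(sort(cur$gmu), sort(pst$gmu)))
    stop("GMU sets differ between epochs")
  if (!identical(names(cur), names(pst)))
    stop("class definitions differ between epochs")
  pst <- pst[match(cur$gmu, pst$gmu), ]
  out <- data.frame(gmu = cur$gmu)
  for (col in setdiff(names(cur), "gmu")) {
    denom <- pst[[col]]
    out[[col]] <- ifelse(denom == 0, NA_real_,
                         100 * (cur[[col]] - denom) / denom)
  }
  out
}
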