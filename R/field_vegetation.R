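#' Shrub crown volume from field measurements
#'
#' Crown volume from height, widest canopy diameter, and the diameter
#' perpendicular to the widest — the three measurements taken per shrub on
#' vegetation plots.  The default ellipsoid convention is
#' `V = (pi/6) * h * d1 * d2`; a rectangular-box convention is available
#' since only relative volumes matter downstream.
#'
#' @param h height, cm.
#' @param d1 widest canopy diameter, cm.
#' @param d2 perpendicular canopy diameter, cm.
#' @param formula `"ellipsoid"` or `"box"`.
#' @return volume, cm^3 (vectorized).
#' @export
crown_volume <- function(h, d1, d2, formula = c("ellipsoid", "box")) {
  formula <- match.arg(formula)
  if (any(c(h, d1, d2) < 0, na.rm = TRUE)) stop("dimensions must be non-negative")
  v <- h * d1 * d2
  if (formula == "ellipsoid") v <- pi / 6 * v
  v
}

#' Plot area of the circular vegetation plots (m^2), radius 2 m.
#' @export
PLOT_AREA_M2 <- 12.56

#' Shrub volume density on one plot
#'
#' Total crown volume on a circular 2-m-radius plot (12.56 m^2) divided by
#' plot area.  When a species was too dense to measure exhaustively
#' (>= 20 shrubs), a representative subsample (5-14 shrubs) was measured
#' and its mean volume multiplied by the total count; such records carry
#' `is_subsample = TRUE` and a shared `shrub_count`.
#'
#' @param plot data.frame of shrub records for a single plot with columns
#'   `species`, `volume_cm3`, and optionally `is_subsample`, `shrub_count`.
#'   An empty data.frame (or rows with `NA` species marking an empty plot)
#'   gives density 0.
#' @param plot_area_m2 plot area, m^2.
#' @return volume density, cm^3/m^2.
#' @export
plot_volume_density <- function(plot, plot_area_m2 = PLOT_AREA_M2) {
  plot <- plot[!is.na(plot$species), , drop = FALSE]
  if (nrow(plot) == 0) return(0)
  if (is.null(plot$is_subsample)) plot$is_subsample <- FALSE
  total <- 0
  for (s in unique(plot$species)) {
    rec <- plot[plot$species == s, ]
    sub <- rec$is_subsample %in% TRUE
    if (any(sub)) {
      if (!any(is.finite(rec$volume_cm3[sub])))
        stop("subsample mean requested with empty subsample for ", s)
      n <- rec$shrub_count[sub][1]
      if (is.na(n) || n < 1) stop("subsampled records need shrub_count")
      total <- total + mean(rec$volume_cm3[sub]) * n + sum(rec$volume_cm3[!sub])
    } else {
      total <- total + sum(rec$volume_cm3)
    }
  }
  total / plot_area_m2
}

new_calibration_fit <- function(fit, n, label = "pooled") {
  co <- stats::coef(fit)
  list(label = label, intercept = unname(co[1]), slope = unname(co[2]),
       r_squared = summary(fit)$r.squared, n = n)
}

#' Calibrate crown volume against biomass of current annual growth
#'
#' Ordinary least squares of oven-dried current-annual-growth (CAG) mass on
#' crown volume, used to justify crown volume as an index of forage
#' biomass.
#'
#' @param volume crown volumes, cm^3.
#' @param mass CAG dry mass, g.
#' @return a calibration fit: `intercept`, `slope`, `r_squared`, `n`.
#' @export
calibrate_volume_biomass <- function(volume, mass) {
  ok <- is.finite(volume) & is.finite(mass)
  volume <- volume[ok]; mass <- mass[ok]
  if (length(volume) < 3) stop("need at least 3 volume-mass pairs")
  if (stats::var(volume) == 0) stop("zero variance in volume")
  new_calibration_fit(stats::lm(mass ~ volume), length(volume))
}

#' Calibrate the single-diameter shortcut against crown volume
#'
#' Stage-2 sampling recorded only the diameter perpendicular to the widest;
#' this fits, per species, OLS of crown volume on that single diameter and
#' summarizes the R^2 across species.  Species with fewer than 3 records
#' are excluded with a warning.
#'
#' @param measurements data.frame with columns `species`, `d2_cm`,
#'   `volume_cm3`.
#' @return list with `fits` (data.frame: species, intercept, slope,
#'   r_squared, n) and `mean_r2`, `min_r2`, `max_r2`.
#' @export
calibrate_single_diameter <- function(measurements) {
  sp <- split(measurements, measurements$species)
  fits <- list()
  for (s in names(sp)) {
    d <- sp[[s]][is.finite(sp[[s]]$d2_cm) & is.finite(sp[[s]]$volume_cm3), ]
    if (nrow(d) < 3) {
      warning("species ", s, " has n < 3; excluded from calibration")
      next
    }
    f <- new_calibration_fit(stats::lm(volume_cm3 ~ d2_cm, data = d), nrow(d), s)
    fits[[s]] <- data.frame(species = s, intercept = f$intercept,
                            slope = f$slope, r_squared = f$r_squared, n = f$n)
  }
  if (!length(fits)) stop("no species with n >= 3")
  fits <- do.call(rbind, c(fits, make.row.names = FALSE))
  list(fits = fits, mean_r2 = mean(fits$r_squared),
       min_r2 = min(fits$r_squared), max_r2 = max(fits$r_squared))
}

#' Browsing rate for a species
#'
#' Percent of measured shrubs of a species showing ungulate browsing
#' (removal of stems or leaves above 1 m; cannot separate moose from elk or
#' deer).
#'
#' @param measurements data.frame with columns `species` and `browsed`
#'   (logical).
#' @param species species name.
#' @return percent browsed (0-100).
#' @export
browse_rate <- function(measurements, species) {
  b <- measurements$browsed[measurements$species == species]
  b <- b[!is.na(b)]
  if (!length(b)) stop("no measured shrubs of species ", species)
  100 * mean(b)
}

#' Per-transect, per-species presence and volume density
#'
#' The transect (4 plots) is the modeling unit: a species is present on a
#' transect when any plot contains it, and its transect density is the mean
#' of the four per-plot volume densities (plots without the species count
#' as 0).
#'
#' @param transects long data.frame of shrub records with columns
#'   `transect_id`, `plot_index` (0-3), `species`, `volume_cm3` (or
#'   `height_cm`, `d1_cm`, `d2_cm` from which it is computed), and
#'   optionally `is_subsample`, `shrub_count`.  Empty plots appear as rows
#'   with `species = NA`.
#' @param species optional species subset (default: all observed).
#' @param plots_per_transect expected plots per transect (validated).
#' @param volume_formula passed to [crown_volume()] when volumes must be
#'   computed from dimensions.
#' @return data.frame: `transect_id`, `species`, `present` (logical),
#'   `density_cm3_m2`.
#' @export
transect_species_table <- function(transects, species = NULL,
                                   plots_per_transect = 4,
                                   volume_formula = "ellipsoid") {
  if (nrow(transects) == 0) stop("no transects")
  if (!"volume_cm3" %in% names(transects)) {
    transects$volume_cm3 <- crown_volume(transects$height_cm, transects$d1_cm,
                                         transects$d2_cm, volume_formula)
  }
  n_plots <- tapply(transects$plot_index, transects$transect_id,
                    function(p) length(unique(p)))
  bad <- names(n_plots)[n_plots != plots_per_transect]
  if (length(bad))
    stop("transect(s) without exactly ", plots_per_transect, " plots: ",
         paste(utils::head(bad, 5), collapse = ", "))
  if (is.null(species))
    species <- sort(unique(transects$species[!is.na(transects$species)]))
  ids <- unique(transects$transect_id)
  out <- expand.grid(transect_id = ids, species = species,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  dens <- matrix(0, length(ids), length(species),
                 dimnames = list(as.character(ids), species))
  for (id in ids) {
    tr <- transects[transects$transect_id == id, ]
    for (pl in unique(tr$plot_index)) {
      rows <- tr[tr$plot_index == pl, ]
      for (s in intersect(unique(rows$species), species)) {
        dens[as.character(id), s] <- dens[as.character(id), s] +
          plot_volume_density(rows[rows$species %in% s, , drop = FALSE]) /
          plots_per_transect
      }
    }
  }
  out$density_cm3_m2 <- dens[cbind(match(as.character(out$transect_id),
                                         rownames(dens)),
                                   match(out$species, colnames(dens)))]
  out$present <- out$density_cm3_m2 > 0
  out[c("transect_id", "species", "present", "density_cm3_m2")]
}
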