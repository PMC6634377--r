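#' Default digestion coefficients
#'
#' Coefficient sets for the summative browse-digestion equations used to
#' convert forage chemistry into digestible protein (DP), digestible dry
#' matter (DDM), and digestible energy (DE).  The functional forms are
#'
#' \deqn{DP = d_0 + d_1 \cdot CP - d_2 \cdot BSA}
#' \deqn{DDM = (a_1 e^{-a_2 L} - c \cdot BSA) \cdot NDF + (b_0 + b_1 \cdot NDS)}
#' \deqn{DE = GE \cdot DDM / 100}
#'
#' where CP is crude protein (% dry matter), NDF neutral detergent fiber
#' (% dry matter), NDS = 100 - NDF the cell solubles, L lignin + cutin as a
#' percentage of NDF, and BSA the tannin protein-precipitating capacity
#' (mg precipitated per mg forage dry matter).  Gross energy (GE, kJ/g) is a
#' part-specific constant; published means for deciduous browse vary little
#' among species.  All values are data, not code: override any element to
#' transcribe an alternative coefficient set.
#'
#' @param dp numeric length 3, `c(d0, d1, d2)`.
#' @param ddm numeric length 5, `c(a1, a2, b0, b1, c)`.
#' @param ge_leaf,ge_stem gross energy (kJ/g) for leaf and stem material.
#' @return a list of class `digestion_coefficients`.
#' @export
digestion_coefficients <- function(dp = c(d0 = -3.87, d1 = 0.9283, d2 = 11.82),
                                   ddm = c(a1 = 0.9231, a2 = 0.0451,
                                           b0 = -16.03, b1 = 1.02, c = 0.03),
                                   ge_leaf = 19.0, ge_stem = 19.7) {
  dp <- stats::setNames(as.numeric(dp), c("d0", "d1", "d2"))
  ddm <- stats::setNames(as.numeric(ddm), c("a1", "a2", "b0", "b1", "c"))
  stopifnot(ddm[["a1"]] > 0, ddm[["a1"]] <= 1, ddm[["a2"]] > 0,
            dp[["d1"]] > 0, ge_leaf > 0, ge_stem > 0)
  structure(list(dp = dp, ddm = ddm, ge_leaf = ge_leaf, ge_stem = ge_stem),
            class = "digestion_coefficients")
}

#' Forage quality class thresholds
#'
#' Cutpoints (kJ/g for energy, g/100g for protein) separating high, moderate
#' and low quality forage, plus the daily maintenance thresholds: the DE
#' needed to meet summer energetic requirements of a non-lactating,
#' non-pregnant female, and the DP needed to offset metabolic fecal and
#' endogenous urinary nitrogen losses.
#'
#' @param energy_high,energy_moderate DE cutpoints, kJ/g.
#' @param protein_high,protein_moderate DP cutpoints, g/100g.
#' @param de_maintenance,dp_maintenance maintenance thresholds.
#' @return a list of class `quality_thresholds`.
#' @export
quality_thresholds <- function(energy_high = 11.3, energy_moderate = 10.5,
                               protein_high = 6.5, protein_moderate = 4.3,
                               de_maintenance = 10.9, dp_maintenance = 4.3) {
  if (energy_high <= energy_moderate)
    stop("energy_high must exceed energy_moderate")
  if (protein_high <= protein_moderate)
    stop("protein_high must exceed protein_moderate")
  structure(list(energy_high = energy_high, energy_moderate = energy_moderate,
                 protein_high = protein_high, protein_moderate = protein_moderate,
                 de_maintenance = de_maintenance, dp_maintenance = dp_maintenance),
            class = "quality_thresholds")
}

validate_assay <- function(cp, ndf, lignin_ndf, bsa) {
  ok <- is.finite(cp) & is.finite(ndf) & is.finite(lignin_ndf) & is.finite(bsa) &
    cp >= 0 & cp <= 100 & ndf >= 0 & ndf <= 100 &
    lignin_ndf >= 0 & lignin_ndf <= 100 & bsa >= 0
  if (!all(ok)) stop("invalid assay values: CP/NDF/lignin_ndf in [0,100], BSA >= 0")
  invisible(TRUE)
}

#' Digestible protein from forage chemistry
#'
#' `DP = d0 + d1 * CP - d2 * BSA`.  Negative values are legal (a plant whose
#' protein cannot offset tannin binding and metabolic losses) and are
#' returned unclamped.
#'
#' @param cp crude protein, % dry matter.
#' @param bsa tannin protein-precipitating capacity, mg/mg dry matter.
#' @param coeffs a [digestion_coefficients()] object.
#' @return digestible protein, g per 100 g dry matter.
#' @export
digestible_protein <- function(cp, bsa = 0, coeffs = digestion_coefficients()) {
  validate_assay(cp, 0, 0, bsa)
  d <- coeffs$dp
  d[["d0"]] + d[["d1"]] * cp - d[["d2"]] * bsa
}

#' Digestible dry matter from forage chemistry
#'
#' Summative model: potentially digestible fiber declines exponentially in
#' lignification and is further reduced by protein-precipitating tannins;
#' cell solubles digest near-completely above a fixed endogenous loss.
#' Results outside \[0, 100\] are returned as-is with a warning.
#'
#' @param ndf neutral detergent fiber, % dry matter.
#' @param lignin_ndf lignin + cutin, % of NDF.
#' @param bsa tannin protein-precipitating capacity, mg/mg.
#' @inheritParams digestible_protein
#' @return digestible dry matter, % (0-100 scale).
#' @export
digestible_dry_matter <- function(ndf, lignin_ndf = 0, bsa = 0,
                                  coeffs = digestion_coefficients()) {
  validate_assay(0, ndf, lignin_ndf, bsa)
  k <- coeffs$ddm
  nds <- 100 - ndf
  ddm <- (k[["a1"]] * exp(-k[["a2"]] * lignin_ndf) - k[["c"]] * bsa) * ndf +
    (k[["b0"]] + k[["b1"]] * nds)
  out <- ddm < 0 | ddm > 100
  if (any(out))
    warning(sprintf("%d DDM value(s) outside [0, 100]", sum(out)))
  ddm
}

#' Digestible energy from digestible dry matter
#'
#' `DE = GE(part) * DDM / 100`, with gross energy taken as a part-specific
#' constant.  Combined leaf+stem samples (conifers whose leaves are not
#' stripped when browsed) use the leaf GE.
#'
#' @param ddm digestible dry matter, % (0-100).
#' @param part `"leaf"`, `"stem"`, or `"leaf+stem"`.
#' @inheritParams digestible_protein
#' @return digestible energy, kJ/g.
#' @export
digestible_energy <- function(ddm, part = c("leaf", "stem", "leaf+stem"),
                              coeffs = digestion_coefficients()) {
  part <- match.arg(part)
  stopifnot(all(ddm >= 0), all(ddm <= 100))
  ge <- if (part == "stem") coeffs$ge_stem else coeffs$ge_leaf
  ge * ddm / 100
}

#' Classify forage by digestible energy
#'
#' High above `energy_high`, low below `energy_moderate`, moderate between;
#' both boundaries close into the moderate class (a species sitting exactly
#' on the moderate cutpoint is moderate, not low).
#'
#' @param de leaf digestible energy, kJ/g (vectorized).
#' @param thresholds a [quality_thresholds()] object.
#' @return character vector in `c("high", "moderate", "low")`.
#' @export
classify_energy <- function(de, thresholds = quality_thresholds()) {
  stopifnot(all(is.finite(de)))
  ifelse(de > thresholds$energy_high, "high",
         ifelse(de < thresholds$energy_moderate, "low", "moderate"))
}

#' Classify forage by digestible protein
#'
#' High above `protein_high`, low below `protein_moderate`, moderate between
#' (boundaries inclusive into moderate).
#'
#' @param dp leaf digestible protein, g/100g (vectorized).
#' @inheritParams classify_energy
#' @return character vector in `c("high", "moderate", "low")`.
#' @export
classify_protein <- function(dp, thresholds = quality_thresholds()) {
  stopifnot(all(is.finite(dp)))
  ifelse(dp > thresholds$protein_high, "high",
         ifelse(dp < thresholds$protein_moderate, "low", "moderate"))
}

#' Screen leaf quality against maintenance thresholds
#'
#' A species meets the energy requirement when its leaf DE is at or above
#' the maintenance DE; only values strictly below the threshold fail.
#' Likewise for protein against the nitrogen-loss offset.
#'
#' @param de_leaf,dp_leaf leaf digestible energy (kJ/g) and protein (g/100g).
#' @inheritParams classify_energy
#' @return data.frame with logical columns `meets_energy`, `meets_protein`.
#' @export
maintenance_screen <- function(de_leaf, dp_leaf,
                               thresholds = quality_thresholds()) {
  data.frame(meets_energy = de_leaf >= thresholds$de_maintenance,
             meets_protein = dp_leaf >= thresholds$dp_maintenance)
}

#' Build nutrition profiles from chemistry assays
#'
#' Applies the digestion equations to an assay table (one row per species x
#' plant part) and derives per-species DDM, DE and DP for leaves and stems,
#' energy and protein classes (from leaf values), and maintenance screens.
#' Species assayed as combined `leaf+stem` fill the leaf slot (leaf GE) and
#' report no stem values.
#'
#' @param assays data.frame with columns `species`, `part`
#'   (`leaf`/`stem`/`leaf+stem`), `cp_pct`, `ndf_pct`, `lignin_ndf_pct`,
#'   `bsa_mg_mg`.
#' @param coeffs a [digestion_coefficients()] object.
#' @param thresholds a [quality_thresholds()] object.
#' @return data.frame, one row per species: `species`, `DDM_leaf`,
#'   `DDM_stem`, `DE_leaf`, `DE_stem`, `DP_leaf`, `DP_stem`,
#'   `energy_class`, `protein_class`, `meets_energy`, `meets_protein`.
#' @export
nutrition_profiles <- function(assays, coeffs = digestion_coefficients(),
                               thresholds = quality_thresholds()) {
  need <- c("species", "part", "cp_pct", "ndf_pct", "lignin_ndf_pct", "bsa_mg_mg")
  if (!all(need %in% names(assays)))
    stop("assays must have columns: ", paste(need, collapse = ", "))
  if (!all(assays$part %in% c("leaf", "stem", "leaf+stem")))
    stop("part must be leaf, stem, or leaf+stem")
  assays$DDM <- digestible_dry_matter(assays$ndf_pct, assays$lignin_ndf_pct,
                                      assays$bsa_mg_mg, coeffs)
  assays$DP <- digestible_protein(assays$cp_pct, assays$bsa_mg_mg, coeffs)
  assays$DE <- NA_real_
  for (p in unique(assays$part)) {
    i <- assays$part == p
    assays$DE[i] <- digestible_energy(assays$DDM[i], p, coeffs)
  }
  sp <- unique(assays$species)
  pick <- function(col, part) {
    vapply(sp, function(s) {
      i <- assays$species == s & assays$part %in% part
      if (any(i)) assays[[col]][which(i)[1]] else NA_real_
    }, numeric(1))
  }
  out <- data.frame(
    species = sp,
    DDM_leaf = pick("DDM", c("leaf", "leaf+stem")),
    DDM_stem = pick("DDM", "stem"),
    DE_leaf = pick("DE", c("leaf", "leaf+stem")),
    DE_stem = pick("DE", "stem"),
    DP_leaf = pick("DP", c("leaf", "leaf+stem")),
    DP_stem = pick("DP", "stem"),
    row.names = NULL
  )
  out$energy_class <- classify_energy(out$DE_leaf, thresholds)
  out$protein_class <- classify_protein(out$DP_leaf, thresholds)
  scr <- maintenance_screen(out$DE_leaf, out$DP_leaf, thresholds)
  out$meets_energy <- scr$meets_energy
  out$meets_protein <- scr$meets_protein
  out
}

#' Summarize a set of nutrition profiles
#'
#' Per-part mean/min/max of DE and DP (species without stem values are
#' excluded from stem statistics), counts and fractions per energy and
#' protein class, and the fraction of species below each maintenance
#' threshold.
#'
#' @param profiles data.frame as returned by [nutrition_profiles()], or any
#'   data.frame with `DE_leaf`, `DE_stem`, `DP_leaf`, `DP_stem` columns.
#' @inheritParams nutrition_profiles
#' @return a list of class `quality_summary` with elements `stats` (per
#'   part x variable), `energy_classes`, `protein_classes` (named counts),
#'   `frac_below_de_maintenance`, `frac_below_dp_maintenance`, `n`.
#' @export
summarize_quality <- function(profiles, thresholds = quality_thresholds()) {
  if (nrow(profiles) == 0) stop("no profiles to summarize")
  stat_row <- function(x) {
    x <- x[is.finite(x)]
    c(mean = mean(x), min = min(x), max = max(x), n = length(x))
  }
  stats <- rbind(DE_leaf = stat_row(profiles$DE_leaf),
                 DE_stem = stat_row(profiles$DE_stem),
                 DP_leaf = stat_row(profiles$DP_leaf),
                 DP_stem = stat_row(profiles$DP_stem))
  ec <- factor(classify_energy(profiles$DE_leaf, thresholds),
               levels = c("high", "moderate", "low"))
  pc <- factor(classify_protein(profiles$DP_leaf, thresholds),
               levels = c("high", "moderate", "low"))
  structure(list(
    stats = stats,
    energy_classes = table(ec),
    protein_classes = table(pc),
    frac_below_de_maintenance = mean(profiles$DE_leaf < thresholds$de_maintenance),
    frac_below_dp_maintenance = mean(profiles$DP_leaf < thresholds$dp_maintenance),
    n = nrow(profiles)
  ), class = "quality_summary")
}

#' @export
print.quality_summary <- function(x, ...) {
  cat("Forage quality summary (", x$n, " species)\n", sep = "")
  print(round(x$stats, 2))
  cat("energy classes:  ", paste(names(x$energy_classes), as.integer(x$energy_classes),
                                 sep = "=", collapse = "  "), "\n")
  cat("protein classes: ", paste(names(x$protein_classes), as.integer(x$protein_classes),
                                 sep = "=", collapse = "  "), "\n")
  cat(sprintf("below DE maintenance: %.0f%%   below DP maintenance: %.0f%%\n",
              100 * x$frac_below_de_maintenance, 100 * x$frac_below_dp_maintenance))
  invisible(x)
}
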