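#' Published forage-quality table for northern Idaho moose shrubs
#'
#' The twelve forage taxa identified as major components of summer moose
#' diets in northern Idaho, with their percent occurrence in fecal diets,
#' mean dietary proportion (conditional on presence in a diet), percent of
#' sampled shrubs with ungulate browsing, and mean digestible energy (kJ/g)
#' and digestible protein (g/100g) for leaves and stems.  Pacific yew was
#' assayed as combined leaf+stem, so its stem entries are `NA`; the
#' thimbleberry stem DP is negative (protein insufficient to offset
#' metabolic losses) and is preserved as published.
#'
#' The two ceanothus species could not be separated in fecal fragments and
#' share occurrence/proportion values.
#'
#' @return data.frame with columns `species`, `occurrence_pct`,
#'   `mean_proportion_pct`, `browse_pct`, `de_leaf`, `de_stem`, `dp_leaf`,
#'   `dp_stem`.
#' @export
forage_quality_table <- function() {
  data.frame(
    species = c("willow spp.", "mallow ninebark", "bitter cherry",
                "alder-birch spp.", "redstem ceanothus", "evergreen ceanothus",
                "honeysuckle", "redosier dogwood", "common snowberry",
                "huckleberry spp.", "thimbleberry", "pacific yew"),
    occurrence_pct = c(88, 63, 60, 49, 33, 33, 33, 19, 16, 16, 14, 12),
    mean_proportion_pct = c(14, 17, 13, 14, 24, 24, 10, 12, 7, 8, 6, 24),
    browse_pct = c(58, 24, 41, 32, 70, 30, 29, 60, 29, 20, 15, 38),
    de_leaf = c(9.6, 10.5, 10.9, 10.0, 11.6, 11.6, 10.3, 12.1, 10.4, 10.3,
                11.0, 12.9),
    de_stem = c(7.7, 6.0, 6.7, 9.5, 6.4, 8.2, 5.0, 8.5, 5.2, 7.5, 6.8, NA),
    dp_leaf = c(5.44, 1.73, 7.39, 7.37, 7.90, 6.69, 4.21, 5.79, 5.65, 4.02,
                6.37, 2.23),
    dp_stem = c(0.39, 0.29, 0.58, 3.72, 1.08, 1.78, 0.96, 1.35, 0.77, 3.62,
                -0.18, NA)
  )
}

#' Example 17-species diet-proportion table (partly synthetic)
#'
#' A screening table in the shape used for the minor-species filter: one row
#' per forage taxon detected in fecal samples, with GMU-averaged mean
#' dietary proportions.  The eleven major taxa carry the published
#' proportions from [forage_quality_table()] (the two ceanothus species
#' collapse to one indistinguishable taxon).  The six minor taxa fall below
#' the 3% exclusion cutoff; their proportion values are *synthetic*
#' placeholders, because the published screening table is available only as
#' a supplement — only their count and sub-cutoff status matter.
#'
#' @return data.frame with columns `species`, `mean_proportion_pct`,
#'   `synthetic` (logical flag for placeholder rows).
#' @export
example_diet_proportions <- function() {
  major <- data.frame(
    species = c("willow spp.", "mallow ninebark", "bitter cherry",
                "alder-birch spp.", "ceanothus spp.", "honeysuckle",
                "redosier dogwood", "common snowberry", "huckleberry spp.",
                "thimbleberry", "pacific yew"),
    mean_proportion_pct = c(14, 17, 13, 14, 24, 10, 12, 7, 8, 6, 24),
    synthetic = FALSE
  )
  minor <- data.frame(
    species = c("rocky mountain maple", "oceanspray", "rusty menziesia",
                "serviceberry", "wild rose", "elderberry"),
    mean_proportion_pct = c(2.5, 1.8, 1.2, 0.9, 0.7, 0.4),
    synthetic = TRUE
  )
  rbind(major, minor)
}
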