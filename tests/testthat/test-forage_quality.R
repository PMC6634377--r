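test_that("digestible protein follows the summative equation, unclamped", {
  expect_equal(digestible_protein(0, 0), -3.87)
  expect_equal(digestible_protein(10, 0), 5.413)
  # negative DP is legal (protein insufficient to offset tannin + metabolic loss)
  expect_equal(digestible_protein(4.0, 0.01), -0.275)
  # strictly increasing in CP, decreasing in BSA
  cps <- seq(2, 30, by = 2)
  expect_true(all(diff(digestible_protein(cps, 0.1)) > 0))
  bsas <- seq(0, 0.5, by = 0.05)
  expect_true(all(diff(sapply(bsas, function(b) digestible_protein(10, b))) < 0))
})

test_that("digestible dry matter: limits, arithmetic, monotonicity", {
  co <- digestion_coefficients()
  # cell-solubles-only limit: NDF = 0 gives b0 + b1 * 100
  expect_equal(digestible_dry_matter(0, 0, 0), -16.03 + 1.02 * 100)
  expect_equal(digestible_dry_matter(50, 0, 0), 81.125, tolerance = 1e-10)
  # strictly decreasing in lignification and in tannins
  lig <- seq(0, 60, by = 5)
  ddm <- sapply(lig, function(L) digestible_dry_matter(50, L, 0))
  expect_true(all(diff(ddm) < 0))
  bsa <- seq(0, 0.5, by = 0.1)
  ddm_b <- sapply(bsa, function(b) digestible_dry_matter(50, 10, b))
  expect_true(all(diff(ddm_b) < 0))
  expect_warning(digestible_dry_matter(0, 0, 0, digestion_coefficients(
    ddm = c(a1 = 0.9231, a2 = 0.0451, b0 = 10, b1 = 1.02, c = 0.03))),
    "outside")
})

test_that("digestible energy is linear in DDM and zero at DDM = 0", {
  co <- digestion_coefficients(ge_leaf = 20)
  expect_equal(digestible_energy(50, "leaf", co), 10.0)
  expect_equal(digestible_energy(0, "leaf", co), 0)
  expect_equal(digestible_energy(57.4, "leaf", digestion_coefficients(ge_leaf = 19.0)),
               10.906)
  # linearity
  d <- c(10, 20, 40, 80)
  expect_equal(digestible_energy(d, "leaf", co), 20 * d / 100)
  # leaf+stem uses leaf GE
  co2 <- digestion_coefficients(ge_leaf = 19, ge_stem = 25)
  expect_equal(digestible_energy(50, "leaf+stem", co2),
               digestible_energy(50, "leaf", co2))
})

test_that("energy and protein classes partition with boundaries closed into moderate", {
  # species known from the published table
  expect_equal(classify_energy(12.1), "high")       # redosier dogwood
  expect_equal(classify_energy(10.5), "moderate")   # mallow ninebark, on the boundary
  expect_equal(classify_energy(9.6), "low")         # willow
  expect_equal(classify_energy(11.3), "moderate")   # upper boundary closed too
  expect_equal(classify_protein(7.90), "high")      # redstem ceanothus
  expect_equal(classify_protein(4.21), "low")       # honeysuckle
  expect_equal(classify_protein(4.30), "moderate")  # boundary inclusive
  expect_equal(classify_protein(6.5), "moderate")
  # total deterministic partition: exactly one class per value
  vals <- seq(0, 20, by = 0.1)
  cl <- classify_energy(vals)
  expect_true(all(cl %in% c("high", "moderate", "low")))
  expect_equal(length(cl), length(vals))
})

test_that("maintenance screen is inclusive at the threshold", {
  scr <- maintenance_screen(de_leaf = c(9.6, 10.9, 12.9), dp_leaf = c(2.23, 4.3, 7.9))
  expect_equal(scr$meets_energy, c(FALSE, TRUE, TRUE))
  expect_equal(scr$meets_protein, c(FALSE, TRUE, TRUE))
})

test_that("nutrition profiles derive DE from DDM by construction", {
  assays <- data.frame(
    species = c("a", "a", "b"),
    part = c("leaf", "stem", "leaf+stem"),
    cp_pct = c(12, 6, 8), ndf_pct = c(40, 60, 50),
    lignin_ndf_pct = c(15, 30, 20), bsa_mg_mg = c(0.1, 0, 0.05))
  co <- digestion_coefficients()
  prof <- nutrition_profiles(assays, co)
  expect_equal(nrow(prof), 2)
  expect_equal(prof$DE_leaf, co$ge_leaf * prof$DDM_leaf / 100)
  expect_equal(prof$DE_stem[1], co$ge_stem * prof$DDM_stem[1] / 100)
  # combined leaf+stem species reports no stem values
  expect_true(is.na(prof$DE_stem[prof$species == "b"]))
  expect_equal(prof$energy_class, classify_energy(prof$DE_leaf))
})

test_that("quality summary on the published table reproduces its statistics", {
  tab <- forage_quality_table()
  prof <- data.frame(species = tab$species, DE_leaf = tab$de_leaf,
                     DE_stem = tab$de_stem, DP_leaf = tab$dp_leaf,
                     DP_stem = tab$dp_stem)
  qs <- summarize_quality(prof)
  expect_equal(round(qs$stats["DE_leaf", "mean"], 1), 10.9)
  expect_equal(qs$stats["DE_leaf", "max"], 12.9)
  expect_equal(qs$stats["DE_leaf", "min"], 9.6)
  expect_equal(as.integer(qs$energy_classes), c(4, 3, 5))
  expect_equal(as.integer(qs$protein_classes), c(4, 4, 4))
  expect_equal(qs$frac_below_de_maintenance, 0.5)
  expect_equal(qs$frac_below_dp_maintenance, 4 / 12)
  # single profile degenerates to its own value
  one <- summarize_quality(prof[1, ])
  expect_equal(unname(one$stats["DE_leaf", c("mean", "min", "max")]),
               rep(9.6, 3))
  expect_error(summarize_quality(prof[0, ]), "no profiles")
})

test_that("threshold constructors reject bad orderings", {
  expect_error(quality_thresholds(energy_high = 10, energy_moderate = 11),
               "exceed")
  expect_error(quality_thresholds(protein_high = 4, protein_moderate = 5),
               "exceed")
})
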