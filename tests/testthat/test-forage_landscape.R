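# brute-force AUC: fraction of concordant (positive, negative) pairs + half ties
auc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (p in pos) s <- s + sum(p > neg) + 0.5 * sum(p == neg)
  s / (length(pos) * length(neg))
}

test_that("rank-based AUC equals the brute-force pair count, ties included", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # force ties
    expect_equal(auc_mw(scores, labels), auc_brute(scores, labels))
  }
  expect_error(auc_mw(1:3, c(1, 1, 1)), "both classes")
})

test_that("accuracy metrics match direct confusion-table formulas", {
  # confusion TP=40 TN=40 FP=10 FN=10 at threshold 0.5
  labels <- rep(c(1, 0), each = 50)
  scores <- c(rep(0.9, 40), rep(0.1, 10), rep(0.9, 10), rep(0.1, 40))
  m <- evaluate_model(scores, labels, 0.5)
  expect_equal(unname(m["pcc"]), 0.80)
  expect_equal(unname(m["kappa"]), 0.60)
  # perfect ranking and threshold
  p <- evaluate_model(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0), 0.5)
  expect_equal(unname(p), c(1, 1, 1))
  # enumerated confusion tables against the closed-form kappa/pcc
  for (tp in c(5, 20)) for (tn in c(5, 30)) for (fp in c(0, 10)) for (fn in c(3, 8)) {
    labels <- c(rep(1, tp + fn), rep(0, tn + fp))
    scores <- c(rep(0.9, tp), rep(0.1, fn), rep(0.1, tn), rep(0.9, fp))
    m <- evaluate_model(scores, labels, 0.5)
    n <- tp + tn + fp + fn
    po <- (tp + tn) / n
    pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
    expect_equal(unname(m["pcc"]), po)
    expect_equal(unname(m["kappa"]), (po - pe) / (1 - pe))
  }
})

test_that("AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  labels <- rbinom(200, 1, 0.5)
  scores <- rnorm(200) + labels
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auc_mw(scores, labels), ref)
})

test_that("null scores give AUC near 0.5", {
  set.seed(10)
  labels <- rbinom(1e4, 1, 0.5)
  scores <- rnorm(1e4)
  expect_lt(abs(auc_mw(scores, labels) - 0.5), 0.02)
})

test_that("threshold selection minimizes |sens - spec| over all candidates", {
  t0 <- select_threshold(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_gt(t0, 0.35); expect_lte(t0, 0.4)
  m <- evaluate_model(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1), t0)
  expect_equal(unname(m["pcc"]), 0.5)  # sens = spec = 0.5
  # perfectly separated scores: gap midpoint, sens = spec = 1
  t1 <- select_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(t1, 0.5)
  expect_equal(unname(evaluate_model(c(0.1, 0.2, 0.8, 0.9),
                                     c(0, 0, 1, 1), t1)["pcc"]), 1)
  expect_error(select_threshold(rep(0.4, 6), c(0, 0, 0, 1, 1, 1)),
               "all scores equal")
  # exhaustive-enumeration property: no candidate does better
  set.seed(13)
  for (i in 1:15) {
    n <- sample(10:40, 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    scores <- round(runif(n), 2)
    if (length(unique(scores)) < 2) next
    t <- select_threshold(scores, labels)
    gap <- function(tt) {
      pred <- scores >= tt
      abs(mean(pred[labels == 1]) - mean(!pred[labels == 0]))
    }
    cands <- c(0, 1, sort(unique(scores)),
               (sort(unique(scores))[-1] + rev(rev(sort(unique(scores)))[-1])) / 2)
    expect_lte(gap(t), min(sapply(cands, gap)) + 1e-12)
  }
})

test_that("presence model recovers a strong coefficient and its sign", {
  set.seed(31)
  n <- 1000
  x <- cbind(signal = rnorm(n), noise1 = rnorm(n), noise2 = rnorm(n))
  y <- rbinom(n, 1, plogis(3 * x[, "signal"]))
  fit <- fit_presence_model(x, y, K = 5, reps = 3, seed = 2)
  expect_gt(fit$stats$auc_mean, 0.9)
  expect_gt(fit$coefficients[["signal"]], 0)
  expect_true(fit$threshold > 0 && fit$threshold < 1)
  expect_equal(fit$stats$reps, 3)
})

test_that("presence model on pure noise yields chance-level AUC", {
  set.seed(33)
  n <- 1000
  x <- matrix(rnorm(n * 4), n, dimnames = list(NULL, paste0("n", 1:4)))
  y <- rbinom(n, 1, 0.5)
  fit <- fit_presence_model(x, y, K = 5, reps = 3, seed = 4)
  expect_gt(fit$stats$auc_mean, 0.4)
  expect_lt(fit$stats$auc_mean, 0.6)
})

test_that("duplicate covariate columns leave predictions finite and unchanged", {
  set.seed(35)
  n <- 300
  x1 <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "a"))
  y <- rbinom(n, 1, plogis(2 * x1[, 1]))
  f1 <- fit_presence_model(x1, y, K = 5, reps = 2, seed = 1)
  x2 <- cbind(x1, a2 = x1[, 1])
  f2 <- fit_presence_model(x2, y, K = 5, reps = 2, seed = 1)
  expect_true(all(is.finite(f2$coefficients)))
  lp1 <- f1$coefficients[["(Intercept)"]] + f1$coefficients[["a"]] * x1[, 1]
  lp2 <- f2$coefficients[["(Intercept)"]] +
    (f2$coefficients[["a"]] + f2$coefficients[["a2"]]) * x1[, 1]
  expect_equal(cor(lp1, lp2), 1, tolerance = 1e-3)
  expect_error(fit_presence_model(x1, rep(1, n)), "both classes")
  expect_error(fit_presence_model(x1[1:5, , drop = FALSE], c(0, 1, 0, 1, 0),
                                  K = 10), "more observations")
})

test_that("volume model falls back to intercept-only under noise covariates", {
  set.seed(41)
  n <- 250
  x <- matrix(rnorm(n * 5), n, dimnames = list(NULL, paste0("z", 1:5)))
  v <- rgamma(n, shape = 2, rate = 2 / 5e4)
  fit <- fit_volume_model(x, v, K = 5, reps = 3, seed = 6)
  expect_equal(fit$kind, "intercept_only")
  expect_equal(fit$mean_volume, mean(v))
  # a single strong log-linear covariate is retained
  v2 <- rgamma(n, shape = 4, rate = 4 / exp(10 + 1.5 * x[, 1]))
  fit2 <- fit_volume_model(x, v2, K = 5, reps = 3, seed = 6)
  expect_equal(fit2$kind, "covariate")
  expect_gt(fit2$coefficients[["z1"]], 0)
  # constant volumes degenerate to intercept-only at that constant
  fit3 <- fit_volume_model(x, rep(1234, n), K = 5, reps = 2, seed = 1)
  expect_equal(fit3$kind, "intercept_only")
  expect_equal(fit3$mean_volume, 1234)
  expect_error(fit_volume_model(x, c(v[-1], -3)), "positive")
})

test_that("polygon prediction thresholds the logistic response", {
  m <- structure(list(coefficients = c("(Intercept)" = qlogis(0.7)),
                      threshold = 0.5), class = "presence_model")
  polys <- data.frame(polygon_id = 1:5, x = rnorm(5))
  expect_true(all(predict_polygons(m, polys)))
  m$threshold <- 1.0
  expect_false(any(predict_polygons(m, polys)))
  m2 <- structure(list(coefficients = c("(Intercept)" = 0, slope_cov = 2),
                       threshold = 0.5), class = "presence_model")
  expect_error(predict_polygons(m2, polys), "slope_cov")
})

test_that("GMU aggregation follows the occupied-area formula", {
  polys <- data.frame(polygon_id = c("p1", "p2", "p3"),
                      gmu = c("g1", "g1", "g2"),
                      area_m2 = c(2e6, 8e6, 4e6))
  occ <- data.frame(polygon_id = c("p1", "p2", "p3"), species = "w",
                    occupied = c(TRUE, FALSE, TRUE))
  vm <- list(w = list(kind = "intercept_only", mean_volume = 1e5))
  prof <- data.frame(species = "w", energy_class = "high",
                     protein_class = "moderate")
  gf <- gmu_forage(occ, vm, prof, polys)
  # occupied 2e6 of 1e7 m2 at 1e5 cm3/m2 -> 2e4 cm3/m2
  expect_equal(gf$species$density_cm3_m2[gf$species$gmu == "g1"], 2e4)
  expect_equal(gf$species$density_cm3_m2[gf$species$gmu == "g2"], 1e5)
  expect_equal(gf$classes$energy_high, gf$classes$total)
  expect_equal(gf$classes$protein_moderate, gf$classes$total)
  expect_equal(gf$classes$energy_low, c(0, 0))
  # splitting a polygon in two leaves the density invariant
  polys2 <- rbind(polys[-1, ], data.frame(polygon_id = c("p1a", "p1b"),
                                          gmu = "g1", area_m2 = 1e6))
  occ2 <- rbind(occ[-1, ], data.frame(polygon_id = c("p1a", "p1b"),
                                      species = "w", occupied = TRUE))
  gf2 <- gmu_forage(occ2, vm, prof, polys2)
  expect_equal(gf2$classes$total, gf$classes$total)
})
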