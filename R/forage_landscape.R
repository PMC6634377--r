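#' Build a covariate matrix for presence/volume models
#'
#' Numeric covariates pass through; factors/characters are one-hot encoded
#' against a first-level reference; covariates named in `quadratic` also get
#' a squared term (`<name>_sq`) — by default tree canopy cover, whose
#' species-specific shade threshold motivates the quadratic.
#'
#' @param data data.frame holding the covariates.
#' @param covariates character vector of column names.
#' @param quadratic covariate names that also enter squared.
#' @return numeric matrix with one row per row of `data`.
#' @export
covariate_matrix <- function(data, covariates,
                             quadratic = intersect("canopy_cover", covariates)) {
  missing <- setdiff(covariates, names(data))
  if (length(missing))
    stop("missing covariate(s): ", paste(missing, collapse = ", "))
  cols <- list()
  for (v in covariates) {
    x <- data[[v]]
    if (is.numeric(x)) {
      if (anyNA(x)) stop("missing covariate: ", v, " has NA values")
      cols[[v]] <- x
      if (v %in% quadratic) cols[[paste0(v, "_sq")]] <- x^2
    } else {
      x <- factor(x)
      for (lev in levels(x)[-1])
        cols[[paste0(v, "_", make.names(lev))]] <- as.numeric(x == lev)
    }
  }
  do.call(cbind, cols)
}

#' Rank-based AUC (Mann-Whitney concordance)
#' @param scores numeric prediction scores.
#' @param labels 0/1 (or logical) observed presence.
#' @return area under the ROC curve.
#' @export
auc_mw <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Select the probability threshold where specificity equals sensitivity
#'
#' Exact equality rarely exists on finite data, so the threshold minimizing
#' `|sensitivity - specificity|` is chosen among candidate thresholds: the
#' midpoints between adjacent sorted unique scores, plus 0 and 1.  Ties are
#' broken toward the lower threshold.  Predictions at a threshold `t` are
#' positive when `score >= t`.
#'
#' @inheritParams auc_mw
#' @return the selected threshold.
#' @export
select_threshold <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2) stop("both classes must be present")
  u <- sort(unique(scores))
  if (length(u) < 2) stop("all scores equal: no separating threshold")
  cand <- sort(unique(c(0, (u[-1] + u[-length(u)]) / 2, 1)))
  gap <- vapply(cand, function(t) {
    pred <- scores >= t
    sens <- mean(pred[labels == 1])
    spec <- mean(!pred[labels == 0])
    abs(sens - spec)
  }, numeric(1))
  cand[which.min(gap)]  # which.min takes the first (lowest) on ties
}

#' Classification accuracy at a threshold
#'
#' AUC (rank-based), percent correctly classified, and Cohen's kappa with
#' chance agreement from the marginal products.
#'
#' @inheritParams auc_mw
#' @param threshold probability threshold; positive when `score >= t`.
#' @return named numeric vector `c(auc, kappa, pcc)`.
#' @export
evaluate_model <- function(scores, labels, threshold) {
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2) stop("both classes must be present")
  pred <- as.integer(scores >= threshold)
  n <- length(labels)
  tp <- sum(pred == 1 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (pe == 1) 0 else (po - pe) / (1 - pe)
  c(auc = auc_mw(scores, labels), kappa = kappa, pcc = po)
}

make_folds <- function(y, K, stratify = TRUE) {
  n <- length(y)
  fold <- integer(n)
  if (stratify) {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep_len(seq_len(K), length(idx)))
    }
  } else {
    fold <- sample(rep_len(seq_len(K), n))
  }
  fold
}

#' Fit a penalized (lasso) logistic presence model
#'
#' Shrub presence on transects is modeled with L1-regularized logistic
#' regression.  The penalty is chosen by repeated K-fold cross-validation:
#' for each repetition, out-of-fold link scores are pooled and the AUC
#' computed per penalty value; the penalty maximizing the mean AUC across
#' repetitions wins.  The final model is refit on all data at that penalty,
#' and its probability threshold is selected on the training predictions so
#' that specificity equals sensitivity.  Fit statistics (AUC, Cohen's
#' kappa, PCC) are the mean and SD over repetitions of the pooled
#' out-of-fold predictions, each repetition using a threshold selected on
#' its own out-of-fold scores.
#'
#' @param x covariate matrix (see [covariate_matrix()]) or data.frame of
#'   numeric covariates.
#' @param y 0/1 or logical presence, length `nrow(x)`.
#' @param K folds (default 10).
#' @param reps cross-validation repetitions (default 30).
#' @param nlambda penalty-grid size (log-spaced by glmnet from the data's
#'   maximal-penalty bound).
#' @param seed RNG seed.
#' @param species optional species label carried in the result.
#' @return object of class `presence_model`: `coefficients` (named, on the
#'   original covariate scale; zeros = dropped), `penalty`, `threshold`,
#'   `stats` (means/SDs of auc/kappa/pcc, `reps`, `folds`), `covariates`.
#' @export
fit_presence_model <- function(x, y, K = 10, reps = 30, nlambda = 50,
                               seed = 1, species = NULL) {
  x <- as.matrix(x)
  y <- as.integer(as.logical(y))
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (nrow(x) <= K) stop("need more observations than folds")
  if (K < 2) stop("K must be >= 2")
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (ncol(x) < 2) x <- cbind(x, `.pad` = 0)  # glmnet needs >= 2 columns
  set.seed(seed)
  full <- glmnet::glmnet(x, y, family = "binomial", nlambda = nlambda)
  lambda <- full$lambda
  auc_sum <- matrix(NA_real_, reps, length(lambda))
  oof <- array(NA_real_, c(reps, nrow(x), length(lambda)))
  for (r in seq_len(reps)) {
    fold <- make_folds(y, K)
    for (k in seq_len(K)) {
      test <- fold == k
      fit <- glmnet::glmnet(x[!test, , drop = FALSE], y[!test],
                            family = "binomial", lambda = lambda)
      oof[r, test, ] <- stats::predict(fit, x[test, , drop = FALSE],
                                       type = "link")
    }
    auc_sum[r, ] <- apply(oof[r, , , drop = TRUE], 2, auc_mw, labels = y)
  }
  mean_auc <- colMeans(auc_sum)
  best <- which.max(mean_auc)
  lam <- lambda[best]
  per_rep <- t(vapply(seq_len(reps), function(r) {
    sc <- oof[r, , best]
    t0 <- select_threshold(sc, y)
    evaluate_model(sc, y, t0)
  }, c(auc = 0, kappa = 0, pcc = 0)))
  final <- glmnet::glmnet(x, y, family = "binomial", lambda = lambda)
  beta <- stats::coef(final, s = lam)[, 1]
  beta <- beta[names(beta) != ".pad"]
  train_prob <- stats::predict(final, x, s = lam, type = "response")[, 1]
  threshold <- select_threshold(train_prob, y)
  structure(list(
    species = species,
    coefficients = beta,
    penalty = lam,
    threshold = threshold,
    stats = list(auc_mean = mean(per_rep[, "auc"]), auc_sd = stats::sd(per_rep[, "auc"]),
                 kappa_mean = mean(per_rep[, "kappa"]), kappa_sd = stats::sd(per_rep[, "kappa"]),
                 pcc_mean = mean(per_rep[, "pcc"]), pcc_sd = stats::sd(per_rep[, "pcc"]),
                 reps = reps, folds = K),
    covariates = colnames(x)
  ), class = "presence_model")
}

#' @export
print.presence_model <- function(x, ...) {
  cat("Penalized presence model", if (!is.null(x$species)) paste0("[", x$species, "]"),
      "\n  penalty:", signif(x$penalty, 3), " threshold:", round(x$threshold, 3), "\n")
  nz <- x$coefficients[x$coefficients != 0]
  cat("  retained terms:", paste(names(nz), signif(nz, 3), sep = "=", collapse = ", "), "\n")
  s <- x$stats
  cat(sprintf("  CV (%d reps x %d folds): AUC %.3f (%.3f)  kappa %.3f (%.3f)  PCC %.3f (%.3f)\n",
              s$reps, s$folds, s$auc_mean, s$auc_sd, s$kappa_mean, s$kappa_sd,
              s$pcc_mean, s$pcc_sd))
  invisible(x)
}

#' Fit a penalized gamma volume model with intercept-only fallback
#'
#' Shrub volume density (conditional on presence, strictly positive) is
#' modeled with L1-regularized gamma regression (log link), the penalty
#' chosen by repeated K-fold cross-validation on mean squared prediction
#' error under the one-standard-error parsimony rule (the strongest penalty
#' whose CV error is within one SE of the minimum, the `lambda.1se`
#' convention).  When the selected penalty retains no covariate, the
#' model collapses to an intercept-only model predicting the empirical mean
#' of the positive observed volumes — the expected outcome when covariates
#' lack predictive power.
#'
#' @param x covariate matrix or data.frame.
#' @param volumes positive volume densities, cm^3/m^2.
#' @param K folds.
#' @param reps cross-validation repetitions.
#' @param nlambda penalty-grid size.
#' @param seed RNG seed.
#' @param species optional species label.
#' @return object of class `volume_model`: `kind`
#'   (`"covariate"`/`"intercept_only"`), `mean_volume`, `coefficients`,
#'   `penalty`.
#' @export
fit_volume_model <- function(x, volumes, K = 10, reps = 10, nlambda = 50,
                             seed = 1, species = NULL) {
  x <- as.matrix(x)
  if (any(!is.finite(volumes)) || any(volumes <= 0))
    stop("volumes must be positive")
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (ncol(x) < 2) x <- cbind(x, `.pad` = 0)
  set.seed(seed)
  mv <- mean(volumes)
  if (stats::var(volumes) == 0 || nrow(x) <= K) {
    return(structure(list(species = species, kind = "intercept_only",
                          mean_volume = mv, coefficients = NULL, penalty = NA),
                     class = "volume_model"))
  }
  fam <- stats::Gamma(link = "log")
  # IRLS non-convergence at extreme penalties is routine on the gamma path;
  # the cross-validation step discards those penalty values on merit
  full <- try(suppressWarnings(
    glmnet::glmnet(x, volumes, family = fam, nlambda = nlambda)), silent = TRUE)
  if (inherits(full, "try-error") || length(full$lambda) < 2) {
    return(structure(list(species = species, kind = "intercept_only",
                          mean_volume = mv, coefficients = NULL, penalty = NA),
                     class = "volume_model"))
  }
  lambda <- full$lambda
  mse <- matrix(NA_real_, reps * K, length(lambda))
  for (r in seq_len(reps)) {
    fold <- make_folds(rep(1, length(volumes)), K, stratify = FALSE)
    for (k in seq_len(K)) {
      test <- fold == k
      fit <- try(suppressWarnings(
        glmnet::glmnet(x[!test, , drop = FALSE], volumes[!test],
                       family = fam, lambda = lambda)), silent = TRUE)
      if (inherits(fit, "try-error")) next
      pred <- stats::predict(fit, x[test, , drop = FALSE], type = "response")
      mse[(r - 1) * K + k, ] <- colMeans((pred - volumes[test])^2)
    }
  }
  cvm <- colMeans(mse, na.rm = TRUE)
  nfit <- colSums(!is.na(mse))
  cvse <- apply(mse, 2, stats::sd, na.rm = TRUE) / sqrt(pmax(nfit, 1))
  i_min <- which.min(cvm)
  # one-standard-error rule: most parsimonious penalty whose CV error is
  # within one SE of the minimum (lambda is stored in decreasing order)
  best <- min(which(cvm <= cvm[i_min] + cvse[i_min]))
  beta <- stats::coef(full, s = lambda[best])[, 1]
  beta <- beta[names(beta) != ".pad"]
  if (all(beta[-1] == 0)) {
    structure(list(species = species, kind = "intercept_only",
                   mean_volume = mv, coefficients = NULL,
                   penalty = lambda[best]), class = "volume_model")
  } else {
    structure(list(species = species, kind = "covariate",
                   mean_volume = mv, coefficients = beta,
                   penalty = lambda[best]), class = "volume_model")
  }
}

#' @export
print.volume_model <- function(x, ...) {
  cat("Volume model", if (!is.null(x$species)) paste0("[", x$species, "]"),
      "-", x$kind, "\n  mean volume:", format(round(x$mean_volume), big.mark = ","),
      "cm3/m2\n")
  if (x$kind == "covariate") {
    nz <- x$coefficients[x$coefficients != 0]
    cat("  retained terms:", paste(names(nz), signif(nz, 3), sep = "=",
                                   collapse = ", "), "\n")
  }
  invisible(x)
}

#' Predict occupancy over landscape polygons
#'
#' Applies a fitted presence model to the polygon covariates; a polygon is
#' occupied when its predicted presence probability reaches the model's
#' threshold.
#'
#' @param model a `presence_model`.
#' @param polygons data.frame of polygons carrying the model's covariates
#'   (see [covariate_matrix()]), or a precomputed covariate matrix.
#' @param covariates covariate names used to build the matrix when
#'   `polygons` is a data.frame without the model's columns.
#' @return logical vector of occupancy flags, one per polygon.
#' @export
predict_polygons <- function(model, polygons, covariates = NULL) {
  terms <- setdiff(names(model$coefficients), "(Intercept)")
  if (is.matrix(polygons)) {
    X <- polygons
  } else if (all(terms %in% names(polygons))) {
    X <- as.matrix(polygons[terms])
  } else if (!is.null(covariates)) {
    X <- covariate_matrix(polygons, covariates)
  } else {
    stop("missing covariate(s): ",
         paste(setdiff(terms, names(polygons)), collapse = ", "))
  }
  missing <- setdiff(terms, colnames(X))
  if (length(missing))
    stop("missing covariate(s): ", paste(missing, collapse = ", "))
  lp <- model$coefficients[["(Intercept)"]] +
    as.vector(X[, terms, drop = FALSE] %*% model$coefficients[terms])
  stats::plogis(lp) >= model$threshold
}

#' Aggregate predicted forage to game management units
#'
#' Within each GMU, the total area of polygons where a species is predicted
#' to occur is multiplied by the species' mean shrub volume (cm^3/m^2) and
#' divided by the total GMU area, giving an average volume density usable
#' for relative comparisons across space and time.  Species densities are
#' summed into energy and protein quality classes using the nutrition
#' profiles.
#'
#' @param occupancy data.frame with columns `polygon_id`, `species`,
#'   `occupied` (logical) covering every polygon x species.
#' @param volume_models named list of `volume_model` objects per species.
#' @param profiles nutrition profiles ([nutrition_profiles()]) with
#'   `species`, `energy_class`, `protein_class`.
#' @param polygons data.frame with `polygon_id`, `gmu`, `area_m2`.
#' @param epoch label stored on the result (`"current"` or `"past"`).
#' @return object of class `gmu_forage_summary`: `species` (gmu x species
#'   densities, long), `classes` (per-gmu class sums and `total`), `epoch`.
#' @export
gmu_forage <- function(occupancy, volume_models, profiles, polygons,
                       epoch = "current") {
  stopifnot(all(c("polygon_id", "gmu", "area_m2") %in% names(polygons)))
  gmu_area <- tapply(polygons$area_m2, polygons$gmu, sum)
  if (any(gmu_area <= 0)) stop("zero GMU area")
  occ <- merge(occupancy, polygons[c("polygon_id", "gmu", "area_m2")],
               by = "polygon_id")
  species <- sort(unique(occ$species))
  gmus <- sort(unique(as.character(polygons$gmu)))
  rows <- list()
  for (s in species) {
    vm <- volume_models[[s]]
    if (is.null(vm)) stop("no volume model for species ", s)
    d <- occ[occ$species == s & occ$occupied, ]
    occ_area <- tapply(d$area_m2, factor(as.character(d$gmu), levels = gmus), sum)
    occ_area[is.na(occ_area)] <- 0
    rows[[s]] <- data.frame(gmu = gmus, species = s,
                            density_cm3_m2 = as.numeric(occ_area) *
                              vm$mean_volume / as.numeric(gmu_area[gmus]))
  }
  sp_df <- do.call(rbind, c(rows, make.row.names = FALSE))
  ec <- stats::setNames(profiles$energy_class, profiles$species)
  pc <- stats::setNames(profiles$protein_class, profiles$species)
  unknown <- setdiff(species, profiles$species)
  if (length(unknown))
    stop("species without nutrition profile: ", paste(unknown, collapse = ", "))
  cls <- data.frame(gmu = gmus)
  for (lev in c("high", "moderate", "low")) {
    for (axis in c("energy", "protein")) {
      map <- if (axis == "energy") ec else pc
      member <- species[map[species] == lev]
      v <- if (length(member)) {
        tapply(sp_df$density_cm3_m2[sp_df$species %in% member],
               factor(sp_df$gmu[sp_df$species %in% member], levels = gmus), sum)
      } else rep(0, length(gmus))
      v[is.na(v)] <- 0
      cls[[paste(axis, lev, sep = "_")]] <- as.numeric(v)
    }
  }
  total <- tapply(sp_df$density_cm3_m2, factor(sp_df$gmu, levels = gmus), sum)
  cls$total <- as.numeric(total)
  structure(list(species = sp_df, classes = cls, epoch = epoch),
            class = "gmu_forage_summary")
}
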