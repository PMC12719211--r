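#' Fit a PLS1 regression model (NIPALS)
#'
#' Mean-centred NIPALS partial least squares with a single response:
#' at each component, the weight vector is `w = X'y / ||X'y||`, scores
#' `t = X w`, loadings `p = X't / t't` and `q = y't / t't`, after which `X`
#' and `y` are deflated. The equivalent single coefficient vector is
#' `beta = W (P'W)^{-1} q` with intercept `mean(y) - mean(x)' beta`; score-
#' space and beta-form predictions agree to machine precision. `X` is
#' centred but not variance-scaled, the dominant chemometrics convention
#' for reflectance spectra.
#'
#' @param x N x B numeric predictor matrix (spectra).
#' @param y Length-N numeric response (reference chemistry).
#' @param ncomp Number of latent components `k`, `1 <= k <= min(N-1, B)`.
#' @param wavelengths Optional [wavelength_grid()] recorded with the model
#'   (enables grid checks at prediction time).
#' @param target_name Label for the response.
#' @return An object of class `"plsr"` with weights `W`, loadings `P`,
#'   y-loadings `q`, centring vectors, `beta`, `intercept`, `y_range`.
#'   If `X'y` vanishes before `ncomp` components the model stops early with
#'   a warning and records the achieved count.
#' @seealso [plsr_calibrate()] for the full split/CV/evaluation workflow.
#' @export
plsr_fit <- function(x, y, ncomp, wavelengths = NULL, target_name = "y") {
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  b <- ncol(x)
  if (length(y) != n) stopf("x and y lengths disagree")
  if (any(!is.finite(x)) || any(!is.finite(y))) stopf("x and y must be finite")
  kmax <- min(n - 1, b)
  if (!is_count(ncomp) || ncomp > kmax) {
    stopf("ncomp must be an integer in [1, min(N-1, B)] = [1, %d]", kmax)
  }
  x_mean <- colMeans(x)
  y_mean <- mean(y)
  xc <- sweep(x, 2, x_mean)
  if (max(abs(xc)) < 1e-14) stopf("x has zero variance in every column")
  yc <- y - y_mean
  W <- P <- matrix(0, b, ncomp)
  qv <- numeric(ncomp)
  achieved <- 0L
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      if (achieved > 0) {
        warning(sprintf(
          "response orthogonal to X residual at component %d; returning %d component(s)",
          a, achieved))
      }
      break
    }
    w <- w / nw
    tt <- drop(xc %*% w)
    t2 <- sum(tt^2)
    p <- drop(crossprod(xc, tt)) / t2
    qa <- sum(yc * tt) / t2
    xc <- xc - tcrossprod(tt, p)
    yc <- yc - qa * tt
    W[, a] <- w
    P[, a] <- p
    qv[a] <- qa
    achieved <- a
  }
  if (achieved == 0L) stopf("response is orthogonal to x; no components fitted")
  W <- W[, seq_len(achieved), drop = FALSE]
  P <- P[, seq_len(achieved), drop = FALSE]
  qv <- qv[seq_len(achieved)]
  bi <- beta_from_wpq(W, P, qv, x_mean, y_mean, achieved)
  structure(list(
    n_components = achieved,
    x_mean = x_mean, y_mean = y_mean,
    x_weights = W, x_loadings = P, y_loadings = qv,
    beta = bi$beta, intercept = bi$intercept,
    y_range = range(y),
    wavelengths = if (is.null(wavelengths)) NULL else as_grid(wavelengths),
    target_name = target_name,
    n_train = n
  ), class = "plsr")
}

# beta and intercept for the first k components of a fitted basis
beta_from_wpq <- function(W, P, qv, x_mean, y_mean, k) {
  Wk <- W[, seq_len(k), drop = FALSE]
  Pk <- P[, seq_len(k), drop = FALSE]
  R <- Wk %*% solve(crossprod(Pk, Wk))
  beta <- drop(R %*% qv[seq_len(k)])
  list(beta = beta, intercept = y_mean - sum(x_mean * beta))
}

#' Predict from a fitted PLS1 model
#'
#' @param object A `"plsr"` model.
#' @param newdata N x B matrix (or length-B vector) of spectra.
#' @param ncomp Number of components to use (default: all fitted).
#' @param via `"beta"` evaluates `x beta + intercept`; `"scores"` projects
#'   through the latent space. The two routes agree to machine precision
#'   and the scores route exists as an internal consistency check.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.plsr <- function(object, newdata, ncomp = object$n_components,
                         via = c("beta", "scores"), ...) {
  via <- match.arg(via)
  x <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else as.matrix(newdata)
  if (ncol(x) != length(object$x_mean)) {
    stopf("newdata has %d bands; the model expects %d", ncol(x), length(object$x_mean))
  }
  if (!is_count(ncomp) || ncomp > object$n_components) {
    stopf("ncomp must lie in [1, %d]", object$n_components)
  }
  if (via == "beta") {
    bi <- if (ncomp == object$n_components) {
      list(beta = object$beta, intercept = object$intercept)
    } else {
      beta_from_wpq(object$x_weights, object$x_loadings, object$y_loadings,
                    object$x_mean, object$y_mean, ncomp)
    }
    drop(x %*% bi$beta) + bi$intercept
  } else {
    xc <- sweep(x, 2, object$x_mean)
    Wk <- object$x_weights[, seq_len(ncomp), drop = FALSE]
    Pk <- object$x_loadings[, seq_len(ncomp), drop = FALSE]
    R <- Wk %*% solve(crossprod(Pk, Wk))
    scores <- xc %*% R
    drop(scores %*% object$y_loadings[seq_len(ncomp)]) + object$y_mean
  }
}

#' @export
coef.plsr <- function(object, ncomp = object$n_components, ...) {
  bi <- if (ncomp == object$n_components) {
    list(beta = object$beta, intercept = object$intercept)
  } else {
    beta_from_wpq(object$x_weights, object$x_loadings, object$y_loadings,
                  object$x_mean, object$y_mean, ncomp)
  }
  nm <- if (!is.null(object$wavelengths)) {
    sprintf("%gnm", as.numeric(object$wavelengths))
  } else {
    sprintf("b%d", seq_along(bi$beta))
  }
  stats::setNames(c(bi$intercept, bi$beta), c("(Intercept)", nm))
}

#' @export
print.plsr <- function(x, ...) {
  cat(sprintf("<plsr: %d component(s), %d bands, target '%s', fit on %d samples>\n",
              x$n_components, length(x$beta), x$target_name, x$n_train))
  invisible(x)
}

#' Random calibration/prediction split
#'
#' Uniform random partition without replacement; the training set holds
#' `round(train_fraction * N)` samples.
#'
#' @param n Number of samples, or a [spectral_dataset()].
#' @param train_fraction Fraction assigned to the training set, in (0, 1).
#' @param seed RNG seed.
#' @return For scalar `n`, a list of index vectors `train`, `test`; for a
#'   dataset, a list of two datasets.
#' @export
split_dataset <- function(n, train_fraction = 0.75, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stopf("train_fraction must lie in (0, 1)")
  }
  ds <- NULL
  if (inherits(n, "spectral_dataset")) {
    ds <- n
    n <- nrow(ds$x)
  }
  if (n < 8) stopf("at least 8 samples are needed for a split")
  n_train <- round(train_fraction * n)
  if (n_train < 1 || n_train >= n) stopf("split leaves an empty subset")
  train <- with_seed(seed, sort(sample.int(n, n_train)))
  test <- setdiff(seq_len(n), train)
  if (is.null(ds)) {
    list(train = train, test = test)
  } else {
    list(train = ds[train], test = ds[test])
  }
}

#' Random k-fold cross-validation of component count
#'
#' Assigns the training samples to `n_folds` random folds (sizes differing
#' by at most one), fits a model per fold at the maximal feasible component
#' count, pools out-of-fold predictions for each `k <= k_max`, and selects
#' the component count minimising RMSECV. Counts whose RMSECV lies within
#' `tie_tol` (relative) of the minimum are treated as ties and resolved
#' toward the smaller k: differences of a few percent are within
#' cross-validation noise, and the extra components they would admit
#' inflate the coefficient norm, which amplifies per-pixel sensor noise
#' when the model is later applied pixel-wise. `r2_cv` is computed on the
#' pooled out-of-fold predictions at the chosen k.
#'
#' @param x,y Training spectra and response.
#' @param k_max Largest component count to consider; silently feasible
#'   values only (lowered with a warning if a fold cannot support it).
#' @param n_folds Number of folds (`>= 2`).
#' @param seed RNG seed for the fold draw.
#' @param tie_tol Relative RMSECV window treated as a tie (parsimony
#'   margin).
#' @return List: `rmsecv` (curve over k), `chosen_k`, `r2_cv`, `rmsecv_min`,
#'   `folds` (per-sample fold ids), `cv_pred` (pooled out-of-fold
#'   predictions at `chosen_k`).
#' @export
plsr_cv <- function(x, y, k_max = 15, n_folds = 10, seed = 1L,
                    tie_tol = 0.05) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  if (n_folds < 2) stopf("n_folds must be at least 2")
  if (n < n_folds) stopf("fewer samples (%d) than folds (%d)", n, n_folds)
  folds <- with_seed(seed, sample(rep(seq_len(n_folds), length.out = n)))
  min_train <- n - max(tabulate(folds, n_folds))
  feasible <- min(min_train - 1, ncol(x))
  if (k_max > feasible) {
    warning(sprintf("k_max lowered from %d to %d (fold feasibility)", k_max, feasible))
    k_max <- feasible
  }
  pred <- matrix(NA_real_, n, k_max)
  for (f in seq_len(n_folds)) {
    idx <- folds == f
    m <- plsr_fit(x[!idx, , drop = FALSE], y[!idx], ncomp = k_max)
    for (k in seq_len(min(k_max, m$n_components))) {
      pred[idx, k] <- predict(m, x[idx, , drop = FALSE], ncomp = k)
    }
  }
  rmsecv <- sqrt(colMeans((pred - y)^2))
  if (all(is.na(rmsecv))) stopf("cross-validation produced no predictions")
  chosen <- which(rmsecv <= min(rmsecv, na.rm = TRUE) * (1 + tie_tol))[1]
  ss_tot <- sum((y - mean(y))^2)
  r2_cv <- 1 - sum((y - pred[, chosen])^2) / ss_tot
  list(rmsecv = rmsecv, chosen_k = chosen, r2_cv = r2_cv,
       rmsecv_min = rmsecv[chosen], folds = folds, cv_pred = pred[, chosen])
}

#' Goodness-of-fit metrics for predictions
#'
#' `r2 = 1 - SS_res / SS_tot` (penalising bias, not squared correlation),
#' with the total sum of squares about the mean of the evaluated subset,
#' and the root-mean-square error in the units of the response.
#'
#' @param obs,pred Observed and predicted values.
#' @return List with `r2` and `rmse`. With zero variance in `obs`, `r2` is
#'   `NA` with a warning.
#' @export
prediction_metrics <- function(obs, pred) {
  if (length(obs) != length(pred)) stopf("obs and pred lengths differ")
  rmse <- sqrt(mean((obs - pred)^2))
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot <= 0) {
    warning("observed values have zero variance; r2 undefined")
    return(list(r2 = NA_real_, rmse = rmse))
  }
  list(r2 = 1 - sum((obs - pred)^2) / ss_tot, rmse = rmse)
}

#' Ratio of prediction deviation
#'
#' `RPD = sd / rmsep`: the (sample, n-1) standard deviation of the
#' calibration-set reference values divided by the prediction RMSE. Values
#' between 1.5 and 2 distinguish low from high levels; above 2 indicate
#' quantitative capability.
#'
#' @param sd_calibration_reference SD of the calibration reference values.
#' @param rmsep Root-mean-square error of prediction (`> 0`).
#' @return The ratio.
#' @export
rpd <- function(sd_calibration_reference, rmsep) {
  if (!is.finite(rmsep) || rmsep <= 0) stopf("rmsep must be positive")
  sd_calibration_reference / rmsep
}

#' Evaluate a fitted model on a calibration/prediction split
#'
#' @param model A `"plsr"` model fitted on the training subset.
#' @param x_train,y_train Calibration spectra and references.
#' @param x_test,y_test Prediction-set spectra and references.
#' @param cv Optional result of [plsr_cv()] contributing
#'   `r2_cv`/`rmsecv`.
#' @param split_seed Seed recorded with the report.
#' @return A `"model_report"`: `r2_c`, `rmsec`, `r2_cv`, `rmsecv`, `r2_p`,
#'   `rmsep`, `rpd`, `n_components`, sample counts, fold assignments.
#' @export
evaluate_plsr <- function(model, x_train, y_train, x_test, y_test,
                          cv = NULL, split_seed = NA_integer_) {
  stopifnot(inherits(model, "plsr"))
  mc <- prediction_metrics(y_train, predict(model, x_train))
  mp <- prediction_metrics(y_test, predict(model, x_test))
  structure(list(
    target_name = model$target_name,
    r2_c = mc$r2, rmsec = mc$rmse,
    r2_cv = if (is.null(cv)) NA_real_ else cv$r2_cv,
    rmsecv = if (is.null(cv)) NA_real_ else cv$rmsecv_min,
    r2_p = mp$r2, rmsep = mp$rmse,
    rpd = rpd(stats::sd(y_train), mp$rmse),
    n_components = model$n_components,
    n_train = length(y_train), n_test = length(y_test),
    fold_assignments = if (is.null(cv)) NULL else cv$folds,
    split_seed = split_seed,
    model = model
  ), class = "model_report")
}

#' Calibrate, cross-validate, and evaluate a PLS1 model
#'
#' The package's main fitting entry point: draws the random
#' calibration/prediction split, selects the component count by random
#' k-fold cross-validation on the calibration portion only, refits at the
#' chosen count, and evaluates calibration, cross-validation, and
#' prediction performance including the RPD.
#'
#' @param x N x B spectra matrix or a [spectral_dataset()].
#' @param y Length-N response (ignored for a dataset; see `target`).
#' @param target For a dataset: which reference column to model
#'   (`"ppo"` or `"tpc"`).
#' @param wavelengths Optional grid recorded with the model (taken from the
#'   dataset automatically).
#' @param k_max,n_folds,train_fraction Tuning protocol parameters.
#' @param tie_tol Parsimony margin for component selection; see
#'   [plsr_cv()].
#' @param seed Master seed; split and fold draws use derived sub-streams.
#' @param target_name Label recorded with the model.
#' @param ... Passed to methods.
#' @return A `"model_report"` (see [evaluate_plsr()]) whose `model` element
#'   is the final fitted `"plsr"` object; `split` holds the index split.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(40 * 12), 40, 12)
#' y <- 3 * x[, 4] - 2 * x[, 9] + rnorm(40, 0, 0.1)
#' rep <- plsr_calibrate(x, y, k_max = 6, seed = 7)
#' rep$r2_p
#' @export
plsr_calibrate <- function(x, ...) UseMethod("plsr_calibrate")

#' @rdname plsr_calibrate
#' @export
plsr_calibrate.default <- function(x, y, wavelengths = NULL, k_max = 15,
                                   n_folds = 10, train_fraction = 0.75,
                                   seed = 1L, target_name = "y",
                                   tie_tol = 0.05, ...) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  if (n < 8) stopf("at least 8 samples are required to calibrate a model")
  sp <- split_dataset(n, train_fraction, seed = derive_seed(seed, "split"))
  xtr <- x[sp$train, , drop = FALSE]
  ytr <- y[sp$train]
  cv <- plsr_cv(xtr, ytr, k_max = k_max, n_folds = n_folds,
                seed = derive_seed(seed, "folds"), tie_tol = tie_tol)
  model <- plsr_fit(xtr, ytr, ncomp = cv$chosen_k, wavelengths = wavelengths,
                    target_name = target_name)
  rep <- evaluate_plsr(model, xtr, ytr,
                       x[sp$test, , drop = FALSE], y[sp$test],
                       cv = cv, split_seed = seed)
  rep$split <- sp
  rep$rmsecv_curve <- cv$rmsecv
  rep
}

#' @rdname plsr_calibrate
#' @export
plsr_calibrate.spectral_dataset <- function(x, target = c("ppo", "tpc"), ...) {
  target <- match.arg(target, choices = names(x$y))
  plsr_calibrate.default(x$x, x$y[[target]], wavelengths = x$grid,
                         target_name = target, ...)
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("Partial least squares regression report -- target: %s (%d latent components)\n",
              x$target_name, x$n_components))
  tab <- data.frame(
    R2 = c(x$r2_c, x$r2_cv, x$r2_p),
    RMSE = c(x$rmsec, x$rmsecv, x$rmsep),
    row.names = c("Calibration", "Cross-validation", "Prediction"))
  print(round(tab, 4))
  cat(sprintf("RPD %.2f  (n_train %d, n_test %d, seed %s)\n",
              x$rpd, x$n_train, x$n_test, as.character(x$split_seed)))
  invisible(x)
}

#' @export
summary.model_report <- function(object, ...) print(object)

#' Significant wavelengths from beta coefficients
#'
#' Scans `|beta|` for local extrema (bands exceeding both neighbours;
#' endpoints compared to their single neighbour) at least
#' `min_rel_height * max(|beta|)` high, mirroring how influential
#' wavelengths are read off a beta-coefficient plot.
#'
#' @param beta Length-B coefficient vector, or a `"plsr"` model (its
#'   intercept is not part of the scan).
#' @param grid A [wavelength_grid()] of length B (taken from the model if
#'   available).
#' @param min_rel_height Minimum height as a fraction of the largest
#'   `|beta|`.
#' @return Ascending numeric vector of selected wavelengths (nm); empty for
#'   an all-constant beta.
#' @export
significant_wavelengths <- function(beta, grid = NULL, min_rel_height = 0.2) {
  if (inherits(beta, "plsr")) {
    if (is.null(grid)) grid <- beta$wavelengths
    beta <- beta$beta
  }
  if (is.null(grid)) stopf("a wavelength grid is required")
  grid <- as_grid(grid)
  b <- abs(as.numeric(beta))
  if (length(b) != length(grid)) stopf("beta length does not match the grid")
  m <- max(b)
  if (m <= 0) return(numeric(0))
  n <- length(b)
  left <- c(-Inf, b[-n])
  right <- c(b[-1], -Inf)
  is_peak <- b > left & b > right & b >= min_rel_height * m
  sort(as.numeric(grid)[is_peak])
}
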