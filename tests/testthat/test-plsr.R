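test_that("a one-component model recovers a noiseless rank-one signal", {
  withr::with_seed(1, {
    t <- rnorm(30)
    p <- rnorm(12)
    x <- outer(t, p)
    y <- 2 * t + 5
  })
  m <- plsr_fit(x, y, ncomp = 1)
  met <- prediction_metrics(y, predict(m, x))
  expect_equal(met$r2, 1, tolerance = 1e-9)
  expect_lt(met$rmse, 1e-9)
})

test_that("PLSR at full rank matches ordinary least squares", {
  for (i in 1:10) {
    withr::with_seed(100 + i, {
      x <- matrix(rnorm(12 * 5), 12, 5)
      y <- rnorm(12)
    })
    m <- plsr_fit(x, y, ncomp = 5)
    ols <- lm.fit(cbind(1, x), y)
    expect_lt(max(abs(predict(m, x) - ols$fitted.values)), 1e-8)
  }
})

test_that("the first weight vector is the cross-covariance direction", {
  withr::with_seed(3, {
    x <- matrix(rnorm(40 * 20), 40, 20)
    y <- rnorm(40)
  })
  m <- plsr_fit(x, y, ncomp = 3)
  xc <- sweep(x, 2, colMeans(x))
  v1 <- svd(crossprod(y - mean(y), xc))$v[, 1]
  agree <- min(max(abs(m$x_weights[, 1] - v1)), max(abs(m$x_weights[, 1] + v1)))
  expect_lt(agree, 1e-9)
})

test_that("beta-form and score-space predictions coincide for all k", {
  withr::with_seed(4, {
    x <- matrix(rnorm(30 * 25), 30, 25)
    y <- drop(x %*% rnorm(25)) + rnorm(30)
    xnew <- matrix(rnorm(8 * 25), 8, 25)
  })
  for (k in 1:10) {
    m <- plsr_fit(x, y, ncomp = k)
    expect_lt(max(abs(predict(m, xnew, via = "beta") -
                        predict(m, xnew, via = "scores"))), 1e-9)
  }
})

test_that("predictions are equivariant under shifts and scalings of y", {
  withr::with_seed(5, {
    x <- matrix(rnorm(25 * 10), 25, 10)
    y <- drop(x %*% rnorm(10)) + rnorm(25, 0, 0.2)
  })
  m <- plsr_fit(x, y, ncomp = 4)
  m_shift <- plsr_fit(x, y + 7, ncomp = 4)
  expect_equal(predict(m_shift, x), predict(m, x) + 7, tolerance = 1e-9)
  m_scale <- plsr_fit(x, 3 * y, ncomp = 4)
  expect_equal(m_scale$beta, 3 * m$beta, tolerance = 1e-9)
  expect_equal(predict(m_scale, x), 3 * predict(m, x), tolerance = 1e-9)
})

test_that("training RMSE never increases with more components", {
  withr::with_seed(6, {
    x <- matrix(rnorm(30 * 15), 30, 15)
    y <- drop(x %*% rnorm(15)) + rnorm(30)
  })
  rmsec <- sapply(1:10, function(k) {
    prediction_metrics(y, predict(plsr_fit(x, y, ncomp = k), x))$rmse
  })
  expect_true(all(diff(rmsec) <= 1e-10))
})

test_that("the calibration split is uniform, sized, and reproducible", {
  sp <- split_dataset(20, train_fraction = 0.75, seed = 1)
  expect_length(sp$train, 15)
  expect_length(sp$test, 5)
  expect_identical(sp, split_dataset(20, 0.75, seed = 1))
  expect_error(split_dataset(20, train_fraction = 1.2), "\\(0, 1\\)")

  # Monte-Carlo: each of 100 samples lands in the test set in ~25% of seeds
  hits <- matrix(0, 4000, 100)
  for (s in 1:4000) hits[s, split_dataset(100, 0.75, seed = s)$test] <- 1
  freq <- colMeans(hits)
  expect_true(all(freq >= 0.22 & freq <= 0.28))
})

test_that("cross-validation selects parsimonious models and is seeded", {
  withr::with_seed(7, {
    t <- rnorm(40)
    x <- outer(t, rnorm(12))
    y <- 3 * t
  })
  cv <- suppressWarnings(plsr_cv(x, y, k_max = 5, n_folds = 10, seed = 2))
  expect_equal(cv$chosen_k, 1)
  expect_lt(cv$rmsecv[1], 1e-9)

  withr::with_seed(8, {
    x2 <- matrix(rnorm(40 * 10), 40, 10)
    y2 <- drop(x2 %*% rnorm(10)) + rnorm(40, 0, 0.5)
  })
  cv_a <- plsr_cv(x2, y2, k_max = 6, n_folds = 10, seed = 3)
  cv_b <- plsr_cv(x2, y2, k_max = 6, n_folds = 10, seed = 3)
  expect_identical(cv_a$folds, cv_b$folds)
  expect_identical(cv_a$rmsecv, cv_b$rmsecv)

  expect_warning(plsr_cv(x2, y2, k_max = 50, n_folds = 10, seed = 1),
                 "lowered")
})

test_that("cross-validation reports no skill on pure noise", {
  # at any fixed component count the pooled out-of-fold R2 on noise is
  # non-positive; argmin-k selection may add only a small optimism
  r2_fixed_k <- r2_selected <- numeric(20)
  for (s in 1:20) {
    withr::with_seed(6000 + s, {
      x <- matrix(rnorm(40 * 20), 40, 20)
      y <- rnorm(40)
    })
    cv <- plsr_cv(x, y, k_max = 8, n_folds = 10, seed = s)
    r2_selected[s] <- cv$r2_cv
    p5 <- rep(NA_real_, 40)
    for (f in 1:10) {
      idx <- cv$folds == f
      m <- plsr_fit(x[!idx, , drop = FALSE], y[!idx], ncomp = 5)
      p5[idx] <- predict(m, x[idx, , drop = FALSE])
    }
    r2_fixed_k[s] <- 1 - sum((y - p5)^2) / sum((y - mean(y))^2)
  }
  expect_true(all(r2_fixed_k <= 0))
  expect_lt(mean(r2_selected), 0)
  expect_lt(max(r2_selected), 0.15)
})

test_that("prediction metrics match their definitions", {
  m <- prediction_metrics(c(1, 2, 3, 4), c(1, 2, 3, 5))
  expect_equal(m$rmse, 0.5)
  expect_equal(m$r2, 0.8)
  perfect <- prediction_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$rmse, 0)
  const <- prediction_metrics(c(1, 2, 3, 4), rep(2.5, 4))
  expect_equal(const$r2, 0)
  expect_warning(z <- prediction_metrics(rep(2, 4), c(1, 2, 3, 4)),
                 "zero variance")
  expect_true(is.na(z$r2))
})

test_that("RPD is the calibration SD over RMSEP", {
  expect_equal(rpd(1.7, 1.7), 1)
  expect_equal(round(rpd(32.68, 14.59), 2), 2.24)
  expect_equal(round(rpd(33.97, 11.21), 2), 3.03)
  expect_error(rpd(10, 0), "positive")
})

test_that("significant wavelengths are thresholded local extrema of |beta|", {
  g <- wavelength_grid(seq(600, 950, 50))
  beta <- c(0, 1, 0, -2, 0, 0, 0.1, 0)
  expect_equal(significant_wavelengths(beta, g, min_rel_height = 0.4),
               c(650, 750))
  expect_equal(significant_wavelengths(rep(0, 8), g), numeric(0))

  # brute-force oracle on random coefficient vectors
  brute <- function(b, g, thr) {
    ab <- abs(b); m <- max(ab); sel <- c()
    for (i in seq_along(b)) {
      lt <- if (i == 1) TRUE else ab[i] > ab[i - 1]
      rt <- if (i == length(b)) TRUE else ab[i] > ab[i + 1]
      if (lt && rt && ab[i] >= thr * m) sel <- c(sel, g[i])
    }
    sort(as.numeric(sel))
  }
  gg <- hsi_grid()
  for (s in 1:10) {
    b <- withr::with_seed(300 + s, rnorm(length(gg)))
    expect_equal(significant_wavelengths(b, gg, 0.3), brute(b, gg, 0.3))
  }
})

test_that("the full calibration workflow reports coherent metrics", {
  prob <- linear_problem(48, 30, n_signal = 3, noise = 0.3, seed = 9)
  rep <- plsr_calibrate(prob$x, prob$y, k_max = 8, seed = 4)
  expect_s3_class(rep, "model_report")
  expect_equal(rep$n_train, 36)
  expect_equal(rep$n_test, 12)
  expect_gt(rep$r2_p, 0.9)
  expect_gt(rep$rpd, 2)
  expect_true(all(c(rep$rmsec, rep$rmsecv, rep$rmsep) >= 0))
  expect_lte(rep$r2_c, 1)
  # reproducible end to end
  rep2 <- plsr_calibrate(prob$x, prob$y, k_max = 8, seed = 4)
  expect_equal(rep$rmsep, rep2$rmsep)
  expect_identical(rep$split, rep2$split)
  expect_output(print(rep), "Prediction")
})

test_that("early stopping returns the achieved component count", {
  withr::with_seed(10, x <- matrix(rnorm(20 * 6), 20, 6))
  y <- rep(3, 20)  # zero-variance response: X'y = 0 at the first component
  expect_error(plsr_fit(x, y, ncomp = 2), "orthogonal")
  withr::with_seed(11, {
    t <- rnorm(20)
    x1 <- outer(t, rnorm(6))  # rank one: deflation exhausts X after k = 1
  })
  expect_warning(m <- plsr_fit(x1, 2 * t, ncomp = 3), "component")
  expect_equal(m$n_components, 1L)
})
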