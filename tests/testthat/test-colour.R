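test_that("colour-board correction solves the affine least-squares map", {
  patches <- rbind(c(0.1, 0.2, 0.3), c(0.8, 0.1, 0.2),
                   c(0.2, 0.9, 0.4), c(0.3, 0.2, 0.8), c(0.5, 0.5, 0.5))
  id <- fit_colour_correction(patches, patches)
  expect_equal(id$A, diag(3), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(id$offset, rep(0, 3), tolerance = 1e-9)
  expect_equal(id$rmse, 0, tolerance = 1e-12)

  dbl <- fit_colour_correction(patches, 2 * patches)
  expect_equal(dbl$A, 2 * diag(3), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(dbl$offset, rep(0, 3), tolerance = 1e-9)
  expect_equal(apply_colour_correction(dbl, c(0.2, 0.3, 0.4)),
               c(0.4, 0.6, 0.8), tolerance = 1e-9)

  collinear <- rbind(c(0.1, 0.1, 0.1), c(0.2, 0.2, 0.2),
                     c(0.3, 0.3, 0.3), c(0.4, 0.4, 0.4))
  expect_error(fit_colour_correction(collinear, collinear), "rank-deficient")
  expect_error(fit_colour_correction(patches[1:3, ], patches[1:3, ]),
               "at least 4")
})

# independent oracle: the published sRGB -> XYZ (D65) -> CIELAB chain
reference_lab <- function(rgb) {
  lin <- ifelse(rgb <= 0.04045, rgb / 12.92, ((rgb + 0.055) / 1.055)^2.4)
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
  xyz <- drop(M %*% lin) / c(0.95047, 1, 1.08883)
  f <- ifelse(xyz > (6 / 29)^3, xyz^(1 / 3), xyz / (3 * (6 / 29)^2) + 4 / 29)
  c(L = 116 * f[2] - 16, a = 500 * (f[1] - f[2]), b = 200 * (f[2] - f[3]))
}

test_that("sRGB to CIELAB conversion matches the standard matrices", {
  white <- rgb_to_lab(c(1, 1, 1))
  expect_equal(white[1, "L"], 100, tolerance = 1e-6, ignore_attr = TRUE)
  expect_lt(max(abs(white[1, c("a", "b")])), 0.01)
  expect_equal(rgb_to_lab(c(0, 0, 0))[1, "L"], 0, ignore_attr = TRUE)

  grey <- rgb_to_lab(c(0.5, 0.5, 0.5))
  expect_lt(max(abs(grey[1, c("a", "b")])), 0.01)
  expect_lt(abs(grey[1, "L"] - reference_lab(c(0.5, 0.5, 0.5))["L"]), 0.1)

  # full random gamut: conversion chains agree within half a Lab unit
  withr::with_seed(12, cols <- matrix(runif(15), 5, 3))
  ours <- rgb_to_lab(cols)
  ref <- t(apply(cols, 1, reference_lab))
  expect_lt(max(abs(ours - ref)), 0.5)

  expect_error(rgb_to_lab(c(1.2, 0, 0)), "\\[0, 1\\]")
})

test_that("delta E is the CIE76 Euclidean distance and a metric", {
  expect_equal(delta_e(c(50, 2, 2), c(50, 2, 2)), 0)
  expect_equal(delta_e(c(53, 4, 10), c(50, 0, 10)), 5)  # 3-4-5 triangle

  # Table of published colour means: B0 at 24 h vs its 0 h baseline
  tab <- published_colour_means()
  b0_24 <- unlist(tab[tab$blanch_time_min == 0 & tab$storage_h == 24, c("L", "a", "b")])
  b0_0 <- unlist(tab[tab$blanch_time_min == 0 & tab$storage_h == 0, c("L", "a", "b")])
  de <- delta_e(b0_24, b0_0)
  expect_equal(de, sqrt(114.06), tolerance = 1e-12)
  expect_equal(round(de, 2), 10.68)

  trip <- withr::with_seed(13, {
    lapply(1:200, function(i) matrix(rnorm(9, 0, 20), 3, 3))
  })
  for (tr in trip) {
    x <- tr[1, ]; y <- tr[2, ]; z <- tr[3, ]
    expect_gte(delta_e(x, y), 0)
    expect_equal(delta_e(x, y), delta_e(y, x))
    expect_lte(delta_e(x, z), delta_e(x, y) + delta_e(y, z) + 1e-12)
  }
})

test_that("browning summaries difference each replicate against its baseline", {
  rec <- data.frame(
    sample_id = rep(c("r1", "r2"), each = 2),
    blanch_time_min = 0,
    storage_h = rep(c(0, 24), 2),
    L = c(60, 56, 58, 52), a = c(-2, -2, -1, -1), b = c(36, 36, 35, 35))
  out <- browning_summary(rec)
  s24 <- out[out$storage_h == 24, ]
  expect_equal(s24$mean_delta_e, 5)    # replicate dE of 4 and 6
  expect_equal(s24$sd_delta_e, sqrt(2))
  expect_true(is.na(out[out$storage_h == 0, "mean_delta_e"]))

  # unchanged colours: zero difference everywhere
  rec2 <- rec
  rec2[, c("L", "a", "b")] <- rec2[rep(c(1, 1, 3, 3)), c("L", "a", "b")]
  expect_equal(browning_summary(rec2)[2, "mean_delta_e"], 0)

  # a replicate without a baseline is dropped with a warning
  rec3 <- rbind(rec, data.frame(sample_id = "r3", blanch_time_min = 0,
                                storage_h = 24, L = 40, a = 1, b = 30))
  expect_warning(out3 <- browning_summary(rec3), "baseline")
  expect_equal(out3[out3$storage_h == 24, "n"], 2L)
})

test_that("mean per-replicate distance dominates the distance of mean colours", {
  withr::with_seed(14, {
    base <- matrix(rnorm(30, 50, 5), 10, 3)
    after <- base + matrix(rnorm(30, 0, 4), 10, 3)
  })
  per_rep <- mean(delta_e(after, base))
  of_means <- delta_e(colMeans(after), colMeans(base))
  expect_gte(per_rep, of_means - 1e-12)
})
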