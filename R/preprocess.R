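#' Hypercube container
#'
#' An H x W x B reflectance array bound to its [wavelength_grid()], with an
#' optional pixel mask. Reflectance is not clipped to `[0, 1]`: values
#' slightly above 1 legitimately occur near the white-reference level under
#' noise, and clipping would bias band means.
#'
#' @param data Numeric H x W x B array.
#' @param grid A [wavelength_grid()] of length B.
#' @param mask Optional H x W logical matrix.
#' @return An object of class `"hypercube"`.
#' @export
hypercube <- function(data, grid, mask = NULL) {
  grid <- as_grid(grid)
  d <- dim(data)
  if (length(d) != 3) stopf("hypercube data must be an H x W x B array")
  if (d[3] != length(grid)) {
    stopf("cube has %d bands but the grid has %d wavelengths", d[3], length(grid))
  }
  if (any(!is.finite(data))) stopf("hypercube data must be finite")
  if (!is.null(mask)) {
    if (!is.logical(mask) || !all(dim(mask) == d[1:2])) {
      stopf("mask must be an H x W logical matrix")
    }
  }
  structure(list(data = data, grid = grid, mask = mask), class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hypercube: %d x %d pixels, %d bands (%.5g-%.5g nm)>\n",
              d[1], d[2], d[3], min(x$grid), max(x$grid)))
  invisible(x)
}

#' Calibrate raw frames to reflectance
#'
#' Standard two-point radiometric calibration,
#' `R = (raw - dark) / (white - dark)`, removing dark current and -- because
#' the white reference carries the same multiplicative illumination surface
#' as the raw frame -- cancelling uneven illumination. The denominator is
#' floored at `floor` to keep dead pixels finite.
#'
#' @param frames A `"raw_frames"` object (arrays `raw`, `dark`, `white`).
#' @param floor Small positive floor on `white - dark`.
#' @return A [hypercube()] of reflectance.
#' @export
calibrate_reflectance <- function(frames, floor = 1e-6) {
  stopifnot(inherits(frames, "raw_frames"))
  if (floor <= 0) stopf("floor must be positive")
  d <- dim(frames$raw)
  if (!identical(d, dim(frames$dark)) || !identical(d, dim(frames$white))) {
    stopf("raw, dark, and white frame dimensions disagree")
  }
  denom <- frames$white - frames$dark
  frac_bad <- mean(denom <= floor)
  if (frac_bad > 0.01) {
    warning(sprintf(
      "white - dark is at or below the floor at %.1f%% of elements; calibration unreliable there",
      100 * frac_bad))
  }
  refl <- (frames$raw - frames$dark) / pmax(denom, floor)
  hypercube(refl, frames$grid)
}

#' PCA-based region-of-interest segmentation
#'
#' Flattens the cube to pixels x bands, mean-centres, scores pixels on the
#' first principal component, thresholds the PC1 score with Otsu's method,
#' orients the mask so the selected class has the higher mean broadband
#' reflectance (sample brighter than background), and keeps the largest
#' connected component.
#'
#' @param cube A [hypercube()].
#' @param n_components Number of components to compute (PC1 drives the
#'   threshold; must be between 1 and B).
#' @param selection Segmentation rule; only `"otsu_pc1"` is implemented.
#' @return H x W logical foreground mask.
#' @export
pca_roi <- function(cube, n_components = 1, selection = "otsu_pc1") {
  stopifnot(inherits(cube, "hypercube"))
  selection <- match.arg(selection, "otsu_pc1")
  d <- dim(cube$data)
  if (n_components < 1 || n_components > d[3]) {
    stopf("n_components must lie between 1 and the band count (%d)", d[3])
  }
  x <- matrix(cube$data, nrow = d[1] * d[2], ncol = d[3])
  xc <- sweep(x, 2, colMeans(x))
  cv <- crossprod(xc) / (nrow(xc) - 1)
  if (max(abs(cv)) < 1e-12) stopf("no contrast: cube has zero pixel variance")
  e <- eigen(cv, symmetric = TRUE)
  score <- drop(xc %*% e$vectors[, 1])
  if (stats::sd(score) < 1e-12) stopf("no contrast: PC1 score is constant")
  s01 <- (score - min(score)) / (max(score) - min(score))
  thr <- EBImage::otsu(matrix(s01, d[1], d[2]), range = c(0, 1))
  mask <- matrix(s01 > thr, d[1], d[2])
  # orient: masked class must be the brighter (sample vs dark background)
  bright <- rowMeans(x)
  if (mean(bright[mask]) < mean(bright[!mask])) mask <- !mask
  if (!any(mask)) stopf("no contrast: empty foreground mask")
  lab <- EBImage::bwlabel(mask)
  counts <- tabulate(lab[lab > 0])
  mask <- lab == which.max(counts)
  mask
}

#' Mean spectrum over a mask
#'
#' Per-band arithmetic mean over the masked pixels -- the per-sample
#' spectrum used for model calibration.
#'
#' @param cube A [hypercube()].
#' @param mask H x W logical matrix with at least one `TRUE` pixel.
#' @param sample_id Sample identifier.
#' @param metadata Optional list (e.g. `blanch_time_min`, `modality`).
#' @return A `"sample_spectrum"`: `sample_id`, `reflectance` (length B),
#'   `n_pixels`, `metadata`.
#' @export
mean_spectrum <- function(cube, mask, sample_id = "sample", metadata = list()) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$data)
  if (!is.logical(mask) || !all(dim(mask) == d[1:2])) {
    stopf("mask must be an H x W logical matrix")
  }
  n <- sum(mask)
  if (n < 1) stopf("mask selects no pixels")
  x <- matrix(cube$data, nrow = d[1] * d[2], ncol = d[3])
  refl <- colMeans(x[as.vector(mask), , drop = FALSE])
  structure(list(sample_id = sample_id, reflectance = as.numeric(refl),
                 n_pixels = n, metadata = metadata),
            class = "sample_spectrum")
}

#' Standard normal variate transform
#'
#' Centres and scales one spectrum to mean 0 and (sample, n-1) SD 1.
#' Available as an optional scatter correction; the default pipeline fits
#' models on raw reflectance.
#'
#' @param spectrum Numeric vector with positive SD.
#' @return The standardized vector.
#' @export
apply_snv <- function(spectrum) {
  s <- stats::sd(spectrum)
  if (!is.finite(s) || s <= 0) stopf("SNV undefined: spectrum has zero variance")
  (spectrum - mean(spectrum)) / s
}
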