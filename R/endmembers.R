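#' Build a Gaussian-feature endmember spectrum
#'
#' Constructs a reflectance-scale endmember as a flat baseline plus a sum of
#' Gaussian peaks minus a sum of Gaussian valleys, clipped to `[0, 1.5]`.
#' These spectra are the building blocks of the forward simulation: a bulk
#' tissue "matrix" spectrum carrying the modality's characteristic peaks and
#' valleys, and chromophore spectra whose features mark the wavelengths at
#' which PPO activity and total phenolics perturb reflectance.
#'
#' @param grid A [wavelength_grid()].
#' @param peaks,valleys Lists of numeric triples `c(center_nm, width_nm,
#'   amplitude)`; `NULL` for none. Widths are Gaussian sigmas.
#' @param baseline Scalar baseline reflectance.
#' @param name Label for the spectrum.
#' @return An object of class `"endmember_spectrum"` with fields `values`
#'   (length of the grid), `grid`, and `name`.
#' @examples
#' g <- hsi_grid()
#' em <- make_endmember_spectrum(g,
#'   peaks = list(c(705, 15, 0.10), c(800, 25, 0.12)),
#'   valleys = list(c(750, 12, 0.06), c(985, 10, 0.15)),
#'   baseline = 0.45)
#' g[which.max(em$values[g >= 690 & g <= 720])]
#' @export
make_endmember_spectrum <- function(grid, peaks = NULL, valleys = NULL,
                                    baseline = 0, name = "endmember") {
  grid <- as_grid(grid)
  w <- as.numeric(grid)
  check_features <- function(feats, what) {
    if (is.null(feats)) return(NULL)
    if (!is.list(feats)) feats <- list(feats)
    m <- do.call(rbind, lapply(feats, function(f) {
      f <- as.numeric(f)
      if (length(f) != 3) {
        stopf("each %s must be a (center, width, amplitude) triple", what)
      }
      f
    }))
    bad <- m[, 1] < min(w) | m[, 1] > max(w)
    if (any(bad)) {
      stopf("%s centre %.4g nm lies outside the grid range [%.4g, %.4g] nm",
            what, m[which(bad)[1], 1], min(w), max(w))
    }
    if (any(m[, 2] <= 0)) {
      stopf("%s widths must be positive", what)
    }
    m
  }
  pk <- check_features(peaks, "peak")
  vl <- check_features(valleys, "valley")
  gauss_sum <- function(m) {
    if (is.null(m)) return(0)
    v <- numeric(length(w))
    for (i in seq_len(nrow(m))) {
      v <- v + m[i, 3] * exp(-(w - m[i, 1])^2 / (2 * m[i, 2]^2))
    }
    v
  }
  values <- rep(baseline, length(w)) + gauss_sum(pk) - gauss_sum(vl)
  values <- pmin(pmax(values, 0), 1.5)
  structure(list(values = values, grid = grid, name = name),
            class = "endmember_spectrum")
}

#' Endmember presets used by the scene simulator
#'
#' The HSI tissue matrix carries reflectance peaks at 705 and 800 nm and
#' valleys at 750 and 985 nm; the HMI matrix carries sharper peaks at 716 and
#' 812 nm and a pronounced valley near 784 nm, matching the mean-spectrum
#' shapes each modality resolves. The PPO chromophore places unit-height
#' Gaussian features at 705 and 812 nm and the TPC chromophore at 782 and
#' 807 nm, so that wavelength-importance analysis of a fitted model has a
#' known answer to recover.
#'
#' @param which One of `"hsi_matrix"`, `"hmi_matrix"`, `"ppo_chromophore"`,
#'   `"tpc_chromophore"`.
#' @param grid A [wavelength_grid()].
#' @return An `"endmember_spectrum"`.
#' @export
endmember_preset <- function(which = c("hsi_matrix", "hmi_matrix",
                                       "ppo_chromophore", "tpc_chromophore"),
                             grid) {
  which <- match.arg(which)
  switch(which,
    hsi_matrix = make_endmember_spectrum(
      grid,
      peaks = list(c(705, 15, 0.10), c(800, 25, 0.12)),
      valleys = list(c(750, 12, 0.06), c(985, 10, 0.15)),
      baseline = 0.45, name = "hsi_matrix"),
    hmi_matrix = make_endmember_spectrum(
      grid,
      peaks = list(c(716, 12, 0.12), c(812, 16, 0.13)),
      valleys = list(c(784, 10, 0.09)),
      baseline = 0.45, name = "hmi_matrix"),
    ppo_chromophore = make_endmember_spectrum(
      grid,
      peaks = list(c(705, 12, 1.0), c(812, 14, 0.8)),
      baseline = 0, name = "ppo_chromophore"),
    tpc_chromophore = make_endmember_spectrum(
      grid,
      peaks = list(c(782, 14, 1.0), c(807, 12, 0.7)),
      baseline = 0, name = "tpc_chromophore"))
}

#' @export
print.endmember_spectrum <- function(x, ...) {
  cat(sprintf("<endmember_spectrum '%s': %d bands, range [%.3f, %.3f]>\n",
              x$name, length(x$values), min(x$values), max(x$values)))
  invisible(x)
}
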