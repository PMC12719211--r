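#' Spectral dataset
#'
#' N samples x B bands of mean ROI reflectance paired with reference
#' chemistry values -- the input to model calibration.
#'
#' @param x N x B numeric matrix of spectra.
#' @param y Data frame (or named list) of reference values with columns
#'   `ppo` (U/g) and/or `tpc` (mg GAE/100 g), or a single numeric vector.
#' @param grid A [wavelength_grid()] of length B.
#' @param sample_ids Character vector of length N.
#' @param metadata Optional data frame of per-sample covariates
#'   (`blanch_time_min`, `modality`, ...).
#' @return An object of class `"spectral_dataset"`.
#' @export
spectral_dataset <- function(x, y, grid, sample_ids = NULL, metadata = NULL) {
  x <- as.matrix(x)
  grid <- as_grid(grid)
  if (ncol(x) != length(grid)) {
    stopf("spectra have %d bands but the grid has %d", ncol(x), length(grid))
  }
  if (any(!is.finite(x))) stopf("spectra contain missing or non-finite values")
  if (is.numeric(y) && is.null(dim(y))) y <- data.frame(y = y)
  y <- as.data.frame(y)
  if (nrow(y) != nrow(x)) stopf("x and y row counts differ")
  if (any(!is.finite(as.matrix(y)))) stopf("reference values contain missing values")
  if (any(as.matrix(y) < 0)) stopf("reference values must be non-negative")
  if (is.null(sample_ids)) sample_ids <- sprintf("S%03d", seq_len(nrow(x)))
  structure(list(x = x, y = y, grid = grid,
                 sample_ids = as.character(sample_ids),
                 metadata = metadata),
            class = "spectral_dataset")
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf("<spectral_dataset: %d samples x %d bands; targets: %s>\n",
              nrow(x$x), ncol(x$x), paste(names(x$y), collapse = ", ")))
  invisible(x)
}

#' @export
`[.spectral_dataset` <- function(x, i, ...) {
  spectral_dataset(x$x[i, , drop = FALSE], x$y[i, , drop = FALSE], x$grid,
                   x$sample_ids[i],
                   if (!is.null(x$metadata)) x$metadata[i, , drop = FALSE])
}

#' Simulate a calibration dataset of blanched-slice samples
#'
#' Generates `n_samples` scenes cycling through the blanching design (0, 2,
#' 4, 6, 10 min by default), with per-sample lognormal biological variation
#' of the zone concentration baselines, runs each through reflectance
#' calibration, PCA ROI detection and mean-spectrum extraction, and draws
#' noisy bench reference assays. All stochastic stages derive their streams
#' from `seed`.
#'
#' @param n_samples Number of samples.
#' @param mode `"HSI"` or `"HMI"`.
#' @param blanch_times Blanching design, minutes; assigned cyclically.
#' @param assay_cv Relative SD of the reference assays.
#' @param sample_variation SD of the per-sample lognormal factor on the
#'   concentration baselines (biological sample-to-sample variation).
#' @param seed Master RNG seed.
#' @param config Base [scene_config()]; blanch time, seed and per-sample
#'   variation are filled in per sample.
#' @param snv Apply the standard normal variate transform to each extracted
#'   spectrum (default `FALSE`; models are fit on raw reflectance).
#' @param keep_scenes Retain the simulated scenes in the result (memory
#'   heavy; used for map-level analyses).
#' @return A [spectral_dataset()] with `y` columns `ppo`, `tpc`, metadata
#'   `blanch_time_min`/`modality`, plus attributes `truth_bulks` (noise-free
#'   bulk values) and optionally `scenes`.
#' @export
simulate_dataset <- function(n_samples = 60,
                             mode = c("HSI", "HMI"),
                             blanch_times = c(0, 2, 4, 6, 10),
                             assay_cv = 0.05,
                             sample_variation = 0.15,
                             seed = 1L,
                             config = scene_config(mode = mode),
                             snv = FALSE,
                             keep_scenes = FALSE) {
  mode <- match.arg(mode)
  if (n_samples < 1) stopf("n_samples must be positive")
  times <- rep(blanch_times, length.out = n_samples)
  fac <- with_seed(derive_seed(seed, "variation"), {
    list(ppo = exp(stats::rnorm(n_samples, 0, sample_variation)),
         tpc = exp(stats::rnorm(n_samples, 0, sample_variation)))
  })
  b <- length(if (mode == "HSI") hsi_grid() else hmi_grid())
  x <- matrix(NA_real_, n_samples, b)
  y_ppo <- y_tpc <- bulk_ppo <- bulk_tpc <- numeric(n_samples)
  scenes <- if (keep_scenes) vector("list", n_samples) else NULL
  grid <- NULL
  for (i in seq_len(n_samples)) {
    cfg <- config
    cfg$mode <- mode
    cfg$blanch_time_min <- times[i]
    cfg$ppo_profile <- config$ppo_profile * fac$ppo[i]
    cfg$tpc_profile <- config$tpc_profile * fac$tpc[i]
    cfg$seed <- derive_seed(seed, "scene", i)
    sc <- simulate_scene(cfg)
    grid <- sc$grid
    cube <- calibrate_reflectance(sc$frames)
    mask <- pca_roi(cube)
    sp <- mean_spectrum(cube, mask, sprintf("S%03d", i),
                        list(blanch_time_min = times[i], modality = mode))
    x[i, ] <- if (snv) apply_snv(sp$reflectance) else sp$reflectance
    refs <- sample_reference_assays(sc$truth, assay_cv,
                                    derive_seed(seed, "assay", i))
    y_ppo[i] <- refs[["ppo"]]
    y_tpc[i] <- refs[["tpc"]]
    bulk_ppo[i] <- sc$truth$bulk_ppo
    bulk_tpc[i] <- sc$truth$bulk_tpc
    if (keep_scenes) scenes[[i]] <- sc
  }
  ds <- spectral_dataset(
    x, data.frame(ppo = y_ppo, tpc = y_tpc), grid,
    sample_ids = sprintf("S%03d", seq_len(n_samples)),
    metadata = data.frame(blanch_time_min = times, modality = mode,
                          stringsAsFactors = FALSE))
  attr(ds, "truth_bulks") <- data.frame(ppo = bulk_ppo, tpc = bulk_tpc)
  if (keep_scenes) attr(ds, "scenes") <- scenes
  ds
}
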