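#' Scene configuration for the blanched-slice simulator
#'
#' Collects every parameter of the forward model that turns a blanching
#' treatment into raw hyperspectral frames. Defaults define the reference
#' simulation conditions used throughout the package; see the methods
#' vignette for the rationale behind each value.
#'
#' @param mode `"HSI"` (whole-slice macro imaging, disc geometry) or `"HMI"`
#'   (thin-section microscopy, full-frame tissue with a cell-wall ridge
#'   lattice).
#' @param image_height,image_width Frame size in pixels.
#' @param slice_radius_fraction Slice radius as a fraction of
#'   `min(H, W) / 2` (HSI mode only).
#' @param zone_radii Strictly increasing outer radii (fractions of the slice
#'   radius, last `<= 1`) of the concentric tissue zones: pith,
#'   perimedullary zone, vascular ring, cortex.
#' @param blanch_time_min Blanching time in minutes (any value `>= 0`; the
#'   study design uses 0, 2, 4, 6, 10).
#' @param ppo_decay_rate First-order thermal inactivation constant for PPO
#'   (per minute of blanching).
#' @param ppo_profile,tpc_profile Per-zone baseline PPO activity (U/g) and
#'   total phenolic content (mg GAE/100 g), ordered as `zone_radii`. The
#'   perimedullary zone carries the highest levels.
#' @param field_noise_rel Relative amplitude of the smooth spatial
#'   heterogeneity multiplying each concentration field.
#' @param illumination_gradient_amplitude Amplitude `A` of the multiplicative
#'   illumination surface, scaled to range `[1 - A, 1 + A]`.
#' @param dark_current_level Sensor dark current, counts.
#' @param white_level Full-scale counts of the white reference.
#' @param noise_sd Gaussian sensor noise SD, as a fraction of `white_level`.
#' @param background_reflectance Reflectance of the (dark) background board.
#' @param chrom_ppo_scale,chrom_tpc_scale Reflectance perturbation per unit
#'   of concentration multiplying the chromophore endmembers (negative:
#'   higher concentration absorbs more).
#' @param seed Integer RNG seed; mandatory, all stochastic draws derive
#'   sub-streams from it.
#' @return A validated list of class `"scene_config"`.
#' @export
scene_config <- function(mode = c("HSI", "HMI"),
                         image_height = 64,
                         image_width = 64,
                         slice_radius_fraction = 0.9,
                         zone_radii = c(0.35, 0.75, 0.85, 1.0),
                         blanch_time_min = 0,
                         ppo_decay_rate = 0.35,
                         ppo_profile = c(pith = 40, perimedullary = 65,
                                         vascular_ring = 55, cortex = 45),
                         tpc_profile = c(pith = 60, perimedullary = 95,
                                         vascular_ring = 80, cortex = 70),
                         field_noise_rel = 0.08,
                         illumination_gradient_amplitude = 0.15,
                         dark_current_level = 100,
                         white_level = 3000,
                         noise_sd = 0.01,
                         background_reflectance = 0.05,
                         chrom_ppo_scale = -0.002,
                         chrom_tpc_scale = -0.0012,
                         seed = 1L) {
  mode <- match.arg(mode)
  if (!is_count(image_height) || !is_count(image_width)) {
    stopf("image_height and image_width must be positive integers")
  }
  if (!(slice_radius_fraction > 0 && slice_radius_fraction <= 1)) {
    stopf("slice_radius_fraction must lie in (0, 1]")
  }
  if (any(diff(zone_radii) <= 0)) {
    stopf("zone_radii must be strictly increasing")
  }
  if (utils::tail(zone_radii, 1) > 1) {
    stopf("the outermost zone radius must not exceed 1")
  }
  if (length(ppo_profile) != length(zone_radii) ||
      length(tpc_profile) != length(zone_radii)) {
    stopf("ppo_profile and tpc_profile must have one value per zone")
  }
  if (any(ppo_profile < 0) || any(tpc_profile < 0)) {
    stopf("zone concentrations must be non-negative")
  }
  if (ppo_decay_rate < 0) stopf("ppo_decay_rate must be non-negative")
  if (blanch_time_min < 0) stopf("blanch_time_min must be non-negative")
  if (noise_sd < 0) stopf("noise_sd must be non-negative")
  if (field_noise_rel < 0) stopf("field_noise_rel must be non-negative")
  A <- illumination_gradient_amplitude
  if (A < 0 || A >= 1) {
    stopf("illumination_gradient_amplitude must lie in [0, 1)")
  }
  if (dark_current_level < 0) stopf("dark_current_level must be non-negative")
  if (white_level <= 0) stopf("white_level must be positive")
  if (background_reflectance < 0) {
    stopf("background_reflectance must be non-negative")
  }
  if (is.null(seed) || !is.finite(seed)) stopf("a finite integer seed is mandatory")
  structure(list(
    mode = mode,
    image_height = as.integer(image_height),
    image_width = as.integer(image_width),
    slice_radius_fraction = slice_radius_fraction,
    zone_radii = zone_radii,
    blanch_time_min = blanch_time_min,
    ppo_decay_rate = ppo_decay_rate,
    ppo_profile = ppo_profile,
    tpc_profile = tpc_profile,
    field_noise_rel = field_noise_rel,
    illumination_gradient_amplitude = A,
    dark_current_level = dark_current_level,
    white_level = white_level,
    noise_sd = noise_sd,
    background_reflectance = background_reflectance,
    chrom_ppo_scale = chrom_ppo_scale,
    chrom_tpc_scale = chrom_tpc_scale,
    seed = as.integer(seed)
  ), class = "scene_config")
}

zone_names <- function(config) {
  nm <- names(config$ppo_profile)
  if (is.null(nm)) nm <- paste0("zone", seq_along(config$zone_radii))
  nm
}

# Smooth unit-variance random surface: white noise filtered with a separable
# normalized Gaussian kernel (sigma = filter scale), then standardized.
smooth_field <- function(h, w, sigma, seed) {
  kmat <- function(n) {
    d <- outer(seq_len(n), seq_len(n), "-")
    k <- exp(-d^2 / (2 * sigma^2))
    k / rowSums(k)
  }
  with_seed(seed, {
    z <- matrix(stats::rnorm(h * w), h, w)
    f <- kmat(h) %*% z %*% t(kmat(w))
    (f - mean(f)) / stats::sd(f)
  })
}

# Fixed low-order polynomial illumination surface rescaled to exactly
# [1 - A, 1 + A]; analytic, hence checkable.
illumination_surface <- function(h, w, amplitude) {
  if (amplitude == 0) return(matrix(1, h, w))
  u <- matrix(rep((seq_len(w) - (w + 1) / 2) / w, each = h), h, w)
  v <- matrix(rep((seq_len(h) - (h + 1) / 2) / h, times = w), h, w)
  g <- 0.8 * u + 0.5 * v + 0.4 * u^2
  g <- 2 * (g - min(g)) / (max(g) - min(g)) - 1
  1 + amplitude * g
}

# Thin high-reflectance cell-wall ridges for HMI thin sections: a periodic
# lattice with a seed-dependent phase, intensities in [0, 1].
lattice_field <- function(h, w, period = 12, seed = 1L) {
  with_seed(seed, {
    phase <- stats::runif(2, 0, period)
    x <- matrix(rep(seq_len(w), each = h), h, w)
    y <- matrix(rep(seq_len(h), times = w), h, w)
    rx <- pmax(cos(2 * pi * (x + phase[1]) / period), 0)^12
    ry <- pmax(cos(2 * pi * (y + phase[2]) / period), 0)^12
    pmin(rx + ry, 1)
  })
}

#' Lay out the tissue geometry of a simulated sample
#'
#' For HSI mode, places a circular slice in the frame and divides it into
#' concentric annular zones (pith, perimedullary zone, vascular ring,
#' cortex). For HMI mode the full frame is tissue (a 20 x 20 mm thin section
#' has no slice boundary at the microscope's field of view); a cell-wall
#' ridge lattice is attached for rendering and the tissue is labelled as
#' perimedullary-zone material, the region the sections are taken from.
#'
#' @param config A [scene_config()].
#' @return A `"scene_truth"` object with `zone_labels` (integer matrix, 0 =
#'   background) and `foreground_mask` set; concentration fields unset.
#' @export
make_tissue_layout <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  h <- config$image_height
  w <- config$image_width
  if (config$mode == "HSI") {
    cy <- (h + 1) / 2
    cx <- (w + 1) / 2
    r0 <- config$slice_radius_fraction * min(h, w) / 2
    r <- sqrt(outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, "+"))
    fg <- r <= r0
    zl <- matrix(0L, h, w)
    breaks <- c(0, utils::head(config$zone_radii, -1))
    zl[fg] <- findInterval(r[fg] / r0, breaks)
    lattice <- NULL
  } else {
    fg <- matrix(TRUE, h, w)
    zl <- matrix(2L, h, w)  # perimedullary-zone material
    lattice <- lattice_field(h, w, seed = derive_seed(config$seed, "scene"))
  }
  structure(list(
    zone_labels = zl,
    foreground_mask = fg,
    zone_names = zone_names(config),
    ppo_field = NULL,
    tpc_field = NULL,
    bulk_ppo = NA_real_,
    bulk_tpc = NA_real_,
    lattice = lattice,
    mode = config$mode
  ), class = "scene_truth")
}

#' Populate ground-truth concentration fields
#'
#' PPO activity follows first-order thermal inactivation,
#' `zone baseline * exp(-k * t)`, modulated by a smooth multiplicative
#' heterogeneity field; TPC is the per-zone baseline under its own
#' heterogeneity field. Both are clipped at zero and vanish outside the
#' foreground. For a fixed seed the heterogeneity fields do not depend on
#' blanching time, so PPO is pointwise non-increasing in time.
#'
#' @param layout A `"scene_truth"` from [make_tissue_layout()].
#' @param config The same [scene_config()].
#' @return The layout with `ppo_field`, `tpc_field`, `bulk_ppo`, `bulk_tpc`
#'   populated (bulk values are foreground means).
#' @export
assign_concentrations <- function(layout, config) {
  stopifnot(inherits(layout, "scene_truth"), inherits(config, "scene_config"))
  if (is.null(layout$zone_labels)) stopf("layout carries no zone labels")
  if (config$ppo_decay_rate < 0) stopf("ppo_decay_rate must be non-negative")
  h <- nrow(layout$zone_labels)
  w <- ncol(layout$zone_labels)
  fg <- layout$foreground_mask
  zl <- layout$zone_labels
  sigma <- min(h, w) / 8
  g1 <- g2 <- 0
  if (config$field_noise_rel > 0) {
    g1 <- smooth_field(h, w, sigma, derive_seed(config$seed, "fields", 1L))
    g2 <- smooth_field(h, w, sigma, derive_seed(config$seed, "fields", 2L))
  }
  base_p <- base_t <- matrix(0, h, w)
  base_p[fg] <- config$ppo_profile[zl[fg]]
  base_t[fg] <- config$tpc_profile[zl[fg]]
  decay <- exp(-config$ppo_decay_rate * config$blanch_time_min)
  ppo <- pmax(base_p * decay * (1 + config$field_noise_rel * g1), 0)
  tpc <- pmax(base_t * (1 + config$field_noise_rel * g2), 0)
  ppo[!fg] <- 0
  tpc[!fg] <- 0
  layout$ppo_field <- ppo
  layout$tpc_field <- tpc
  layout$bulk_ppo <- mean(ppo[fg])
  layout$bulk_tpc <- mean(tpc[fg])
  layout
}

#' Render raw, dark, and white frame stacks from ground truth
#'
#' Linear-mixing forward model: true reflectance is the tissue matrix
#' spectrum plus concentration-scaled chromophore spectra,
#' `R(x, y, l) = matrix(l) + a_p PPO(x, y) ppo(l) + a_t TPC(x, y) tpc(l)`,
#' with the background at a flat board reflectance and, in HMI mode, a
#' broadband boost on the cell-wall lattice. Raw counts are
#' `dark + illum(x, y) * R * white_level + noise`; the white reference
#' carries the same multiplicative illumination surface (so calibration
#' cancels it) and the dark frame only dark current and noise.
#'
#' @param truth A `"scene_truth"` with concentration fields.
#' @param grid A [wavelength_grid()].
#' @param endmembers Named list with elements `matrix`, `ppo_chromophore`,
#'   `tpc_chromophore`, all on `grid`.
#' @param config The [scene_config()].
#' @return A `"raw_frames"` object: arrays `raw`, `dark`, `white`
#'   (H x W x B) plus the grid.
#' @export
render_frames <- function(truth, grid, endmembers, config) {
  stopifnot(inherits(truth, "scene_truth"), inherits(config, "scene_config"))
  grid <- as_grid(grid)
  need <- c("matrix", "ppo_chromophore", "tpc_chromophore")
  if (!all(need %in% names(endmembers))) {
    stopf("endmembers must contain: %s", paste(need, collapse = ", "))
  }
  for (nm in need) {
    eg <- endmembers[[nm]]$grid
    if (!grids_match(eg, grid, tol = 1e-9)) {
      stopf("endmember '%s' is on a mismatched wavelength grid", nm)
    }
  }
  h <- nrow(truth$foreground_mask)
  w <- ncol(truth$foreground_mask)
  b <- length(grid)
  em_m <- endmembers$matrix$values
  r_true <- array(rep(em_m, each = h * w), dim = c(h, w, b))
  if (!is.null(truth$lattice)) {
    r_true <- r_true + array(truth$lattice * 0.12, dim = c(h, w, b))
  }
  r_true <- r_true +
    outer(truth$ppo_field * config$chrom_ppo_scale,
          endmembers$ppo_chromophore$values) +
    outer(truth$tpc_field * config$chrom_tpc_scale,
          endmembers$tpc_chromophore$values)
  bg <- rep(!truth$foreground_mask, times = b)
  r_true[bg] <- config$background_reflectance
  r_true <- pmax(r_true, 0)

  illum <- array(illumination_surface(h, w, config$illumination_gradient_amplitude),
                 dim = c(h, w, b))
  gain <- config$white_level
  dc <- config$dark_current_level
  nsd <- config$noise_sd * gain
  frames <- with_seed(derive_seed(config$seed, "render"), {
    noise <- function() {
      if (nsd > 0) array(stats::rnorm(h * w * b, 0, nsd), dim = c(h, w, b)) else 0
    }
    list(raw = dc + illum * r_true * gain + noise(),
         white = dc + illum * gain + noise(),
         dark = dc + array(0, dim = c(h, w, b)) + noise())
  })
  structure(list(raw = frames$raw, dark = frames$dark, white = frames$white,
                 grid = grid, true_reflectance = r_true),
            class = "raw_frames")
}

#' Simulate one complete scene
#'
#' Convenience wrapper chaining [make_tissue_layout()],
#' [assign_concentrations()] and [render_frames()] with the modality's
#' default grid and endmember presets.
#'
#' @param config A [scene_config()].
#' @return A list of class `"scene"`: `truth`, `frames`, `grid`,
#'   `endmembers`, `config`.
#' @export
simulate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  grid <- if (config$mode == "HSI") hsi_grid() else hmi_grid()
  endmembers <- list(
    matrix = endmember_preset(
      if (config$mode == "HSI") "hsi_matrix" else "hmi_matrix", grid),
    ppo_chromophore = endmember_preset("ppo_chromophore", grid),
    tpc_chromophore = endmember_preset("tpc_chromophore", grid))
  truth <- assign_concentrations(make_tissue_layout(config), config)
  frames <- render_frames(truth, grid, endmembers, config)
  structure(list(truth = truth, frames = frames, grid = grid,
                 endmembers = endmembers, config = config),
            class = "scene")
}

#' Simulate bench reference assays for a scene
#'
#' Returns the scene's bulk (foreground-mean) PPO activity and TPC with
#' multiplicative Gaussian measurement error of relative SD `assay_cv`,
#' clipped at zero -- the simulated counterpart of destructive enzyme and
#' Folin-Ciocalteu assays.
#'
#' @param truth A `"scene_truth"` with populated fields.
#' @param assay_cv Relative measurement SD (`>= 0`).
#' @param seed RNG seed for the error draws.
#' @return Named numeric vector `c(ppo = ..., tpc = ...)` (U/g,
#'   mg GAE/100 g).
#' @export
sample_reference_assays <- function(truth, assay_cv = 0.05, seed = 1L) {
  stopifnot(inherits(truth, "scene_truth"))
  if (assay_cv < 0) stopf("assay_cv must be non-negative")
  if (!is.finite(truth$bulk_ppo)) stopf("truth has no bulk values; assign concentrations first")
  eps <- with_seed(seed, stats::rnorm(2, 0, assay_cv))
  c(ppo = max(0, truth$bulk_ppo * (1 + eps[1])),
    tpc = max(0, truth$bulk_tpc * (1 + eps[2])))
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf("<scene_truth %s: %dx%d, %d zones, bulk PPO %.3g U/g, bulk TPC %.3g mg/100g>\n",
              x$mode, nrow(x$foreground_mask), ncol(x$foreground_mask),
              length(unique(x$zone_labels[x$foreground_mask])),
              x$bulk_ppo, x$bulk_tpc))
  invisible(x)
}
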