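# Fixture builders shared across the suite. All fixtures are generated in
# code; nothing is read from disk except the published colour-means table.

# fully deterministic scene configuration (no sensor defects by default)
noiseless_cfg <- function(seed = 1, illumination_gradient_amplitude = 0,
                          field_noise_rel = 0, dark_current_level = 0, ...) {
  scene_config(noise_sd = 0,
               illumination_gradient_amplitude = illumination_gradient_amplitude,
               dark_current_level = dark_current_level,
               field_noise_rel = field_noise_rel, seed = seed, ...)
}

# cube with a given per-band spectrum (or scalar) everywhere
flat_cube <- function(h, w, spectrum, grid = hsi_grid()) {
  b <- length(grid)
  if (length(spectrum) == 1) spectrum <- rep(spectrum, b)
  hypercube(array(rep(spectrum, each = h * w), dim = c(h, w, b)), grid)
}

# hand-built raw_frames object (bypasses the simulator)
manual_frames <- function(raw, dark, white, grid) {
  structure(list(raw = raw, dark = dark, white = white, grid = grid),
            class = "raw_frames")
}

# random regression problem with a linear spectral signal
linear_problem <- function(n, b, n_signal = 2, noise = 0, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * b), n, b)
    coefs <- numeric(b)
    coefs[sample(b, n_signal)] <- rnorm(n_signal, 0, 2)
    y <- drop(x %*% coefs) + rnorm(n, 0, noise)
    list(x = x, y = y, coefs = coefs)
  })
}

published_colour_means <- function() {
  read.csv(system.file("extdata", "published_colour_means.csv",
                       package = "blanchspec"))
}
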