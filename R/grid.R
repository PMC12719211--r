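#' Wavelength grid
#'
#' A validated vector of spectral band centres (nm) for the VIS/NIR window
#' used by both imaging modalities. Band centres must be strictly
#' increasing, lie within 600--1000 nm, and number at least 8.
#'
#' @param bands_nm Numeric vector of band centres in nanometres.
#' @return A numeric vector of class `"wavelength_grid"`.
#' @examples
#' g <- wavelength_grid(seq(600, 1000, by = 5))
#' length(g)
#' @export
wavelength_grid <- function(bands_nm) {
  w <- as.numeric(bands_nm)
  if (length(w) < 8) {
    stopf("a wavelength grid needs at least 8 bands, got %d", length(w))
  }
  if (any(!is.finite(w))) {
    stopf("wavelength grid contains non-finite values")
  }
  if (any(diff(w) <= 0)) {
    stopf("wavelengths must be strictly increasing")
  }
  if (any(w < 600 | w > 1000)) {
    stopf("all wavelengths must lie within [600, 1000] nm")
  }
  structure(w, class = "wavelength_grid")
}

#' @rdname wavelength_grid
#' @param step Band spacing in nm.
#' @details `hsi_grid()` is the default macro-imaging grid (600--1000 nm in
#'   5 nm steps, 81 bands); `hmi_grid()` the microscopy grid (4 nm steps,
#'   101 bands, reflecting the finer spectral resolution of the tunable
#'   filter).
#' @export
hsi_grid <- function(step = 5) wavelength_grid(seq(600, 1000, by = step))

#' @rdname wavelength_grid
#' @export
hmi_grid <- function(step = 4) wavelength_grid(seq(600, 1000, by = step))

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("<wavelength_grid: %d bands, %.5g-%.5g nm>\n",
              length(x), min(x), max(x)))
  invisible(x)
}

# grids equal band-for-band within `tol` nm
grids_match <- function(a, b, tol = 0.5) {
  length(a) == length(b) && all(abs(as.numeric(a) - as.numeric(b)) <= tol)
}

as_grid <- function(x) {
  if (inherits(x, "wavelength_grid")) x else wavelength_grid(x)
}
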