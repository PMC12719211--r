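#' Pixel-wise chemical distribution map
#'
#' Applies a fitted PLS1 model to every masked pixel spectrum of a
#' hypercube, turning the calibration model into a spatial map of predicted
#' PPO activity or TPC. Background pixels are encoded as `NA`, never zero.
#'
#' @param cube A [hypercube()] on the model's training grid (band count
#'   equal, centres within 0.5 nm).
#' @param mask H x W logical foreground mask.
#' @param model A `"plsr"` model.
#' @param clip_policy `"train_range"` (default) clips predictions to the
#'   range of the training references -- pixel spectra lie outside the
#'   calibration hull and unclipped extrapolations mislead; `"none"`
#'   leaves the affine predictions untouched.
#' @return A `"distribution_map"`: `values` (H x W, `NA` off-mask), `mask`,
#'   `target_name`, `display_range` (1st--99th percentile of masked
#'   values).
#' @export
predict_map <- function(cube, mask, model,
                        clip_policy = c("train_range", "none")) {
  stopifnot(inherits(cube, "hypercube"), inherits(model, "plsr"))
  clip_policy <- match.arg(clip_policy)
  d <- dim(cube$data)
  if (!is.null(model$wavelengths)) {
    mw <- as.numeric(model$wavelengths)
    cw <- as.numeric(cube$grid)
    if (length(mw) != length(cw)) {
      stopf("grid mismatch: cube has %d bands, model %d", length(cw), length(mw))
    }
    dif <- abs(cw - mw)
    if (any(dif > 0.5)) {
      bad <- which(dif > 0.5)
      stopf("grid mismatch at %d band(s); worst offsets: %s",
            length(bad),
            paste(sprintf("band %d (%.4g vs %.4g nm)",
                          utils::head(bad, 3), cw[utils::head(bad, 3)],
                          mw[utils::head(bad, 3)]), collapse = ", "))
    }
  }
  if (!is.logical(mask) || !all(dim(mask) == d[1:2])) {
    stopf("mask must be an H x W logical matrix")
  }
  x <- matrix(cube$data, nrow = d[1] * d[2], ncol = d[3])
  pred <- drop(x %*% model$beta) + model$intercept
  if (clip_policy == "train_range") {
    pred <- pmin(pmax(pred, model$y_range[1]), model$y_range[2])
  }
  values <- matrix(pred, d[1], d[2])
  values[!mask] <- NA_real_
  dr <- unname(stats::quantile(values[mask], c(0.01, 0.99), na.rm = TRUE))
  structure(list(values = values, mask = mask,
                 target_name = model$target_name,
                 display_range = dr),
            class = "distribution_map")
}

#' @export
print.distribution_map <- function(x, ...) {
  cat(sprintf("<distribution_map '%s': %d x %d, %d masked pixels, display range [%.4g, %.4g]>\n",
              x$target_name, nrow(x$values), ncol(x$values), sum(x$mask),
              x$display_range[1], x$display_range[2]))
  invisible(x)
}

#' Render a distribution map to a PNG file
#'
#' Writes an 8-bit colour image of the map with a vertical colourbar strip
#' on the right; the background is neutral grey. A JSON sidecar
#' (`<path>.json`) annotates the display range, target, and colormap so
#' the image remains interpretable. Re-rendering the same map writes
#' byte-identical output.
#'
#' @param map A `"distribution_map"`.
#' @param out_path Output PNG path.
#' @param colormap_name Palette name understood by
#'   [grDevices::hcl.colors()].
#' @return `out_path`, invisibly.
#' @export
render_map <- function(map, out_path, colormap_name = "viridis") {
  stopifnot(inherits(map, "distribution_map"))
  cols <- grDevices::hcl.colors(256, colormap_name)
  pal <- t(grDevices::col2rgb(cols)) / 255
  lo <- map$display_range[1]
  hi <- map$display_range[2]
  span <- if (hi > lo) hi - lo else 1
  v <- (map$values - lo) / span
  v <- pmin(pmax(v, 0), 1)
  idx <- 1L + as.integer(round(v * 255))
  h <- nrow(map$values)
  w <- ncol(map$values)
  body <- array(0.85, dim = c(h, w, 3))  # neutral background
  ok <- which(!is.na(idx))
  for (ch in 1:3) {
    plane <- body[, , ch]
    plane[ok] <- pal[idx[ok], ch]
    body[, , ch] <- plane
  }
  # colourbar: 2 px gap + 10 px gradient strip, top = display-range maximum
  bar_idx <- as.integer(round(seq(256, 1, length.out = h)))
  canvas <- array(1, dim = c(h, w + 12, 3))
  canvas[, seq_len(w), ] <- body
  for (ch in 1:3) {
    canvas[, (w + 3):(w + 12), ch] <- matrix(pal[bar_idx, ch], h, 10)
  }
  png::writePNG(canvas, out_path)
  jsonlite::write_json(
    list(target = map$target_name,
         display_range = map$display_range,
         colormap = colormap_name,
         n_masked_pixels = sum(map$mask)),
    paste0(out_path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(out_path)
}

#' @export
plot.distribution_map <- function(x, colormap_name = "viridis", ...) {
  cols <- grDevices::hcl.colors(256, colormap_name)
  graphics::image(t(x$values[nrow(x$values):1, ]), col = cols,
                  zlim = x$display_range, axes = FALSE,
                  main = sprintf("%s distribution", x$target_name), ...)
  invisible(x)
}
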