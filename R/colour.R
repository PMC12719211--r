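#' Least-squares colour-board correction
#'
#' Fits the affine map `r = A m + o` from measured to reference patch
#' colours by least squares, the usual way a colour checker board is used
#' to absorb device and illumination deviations before conversion to
#' CIELAB.
#'
#' @param measured_patches,reference_patches Matrices (n x 3, `n >= 4`) of
#'   corresponding RGB triples; the measured patches must not be coplanar
#'   in RGB space.
#' @return A `"colour_correction"`: 3 x 3 matrix `A`, length-3 `offset`,
#'   and the residual `rmse`.
#' @export
fit_colour_correction <- function(measured_patches, reference_patches) {
  m <- as.matrix(measured_patches)
  r <- as.matrix(reference_patches)
  if (ncol(m) != 3 || ncol(r) != 3) stopf("patches must be n x 3 RGB matrices")
  if (nrow(m) != nrow(r)) stopf("patch counts differ")
  if (nrow(m) < 4) stopf("at least 4 patch pairs are required")
  design <- cbind(1, m)
  if (qr(design)$rank < 4) {
    stopf("rank-deficient patch set: measured patches are coplanar in RGB space")
  }
  fit <- stats::lm.fit(design, r)
  cf <- fit$coefficients
  structure(list(A = t(cf[-1, , drop = FALSE]),
                 offset = as.numeric(cf[1, ]),
                 rmse = sqrt(mean(fit$residuals^2))),
            class = "colour_correction")
}

#' Apply a fitted colour correction
#'
#' @param correction A `"colour_correction"`.
#' @param rgb n x 3 matrix or length-3 vector.
#' @return Corrected colours, same shape as the input.
#' @export
apply_colour_correction <- function(correction, rgb) {
  stopifnot(inherits(correction, "colour_correction"))
  x <- if (is.null(dim(rgb))) matrix(rgb, nrow = 1) else as.matrix(rgb)
  out <- x %*% t(correction$A) +
    matrix(correction$offset, nrow(x), 3, byrow = TRUE)
  if (is.null(dim(rgb))) as.numeric(out) else out
}

#' Convert sRGB to CIELAB
#'
#' Standard sRGB inverse-gamma, XYZ (D65), CIELAB chain via
#' [grDevices::convertColor()].
#'
#' @param rgb Length-3 vector or n x 3 matrix, channels in `[0, 1]`.
#' @param whitepoint Reference white; only `"D65"` (the sRGB native white)
#'   is supported.
#' @return n x 3 matrix with columns `L`, `a`, `b` (`L` in `[0, 100]`).
#' @export
rgb_to_lab <- function(rgb, whitepoint = "D65") {
  whitepoint <- match.arg(whitepoint, "D65")
  x <- if (is.null(dim(rgb))) matrix(rgb, nrow = 1) else as.matrix(rgb)
  if (ncol(x) != 3) stopf("rgb must have 3 channels")
  if (any(x < 0 | x > 1)) stopf("rgb channels must lie in [0, 1]")
  lab <- grDevices::convertColor(x, from = "sRGB", to = "Lab")
  colnames(lab) <- c("L", "a", "b")
  lab
}

#' CIE76 colour difference
#'
#' Euclidean distance in CIELAB,
#' `dE = sqrt((L - L0)^2 + (a - a0)^2 + (b - b0)^2)` -- the browning
#' magnitude metric relative to a pre-storage baseline colour.
#'
#' @param lab,lab0 Length-3 `(L, a, b)` vectors or n x 3 matrices (rows
#'   paired).
#' @return Numeric vector of colour differences.
#' @export
delta_e <- function(lab, lab0) {
  a <- if (is.null(dim(lab))) matrix(as.numeric(lab), nrow = 1) else as.matrix(lab)
  b <- if (is.null(dim(lab0))) matrix(as.numeric(lab0), nrow = 1) else as.matrix(lab0)
  if (nrow(b) == 1 && nrow(a) > 1) b <- b[rep(1, nrow(a)), , drop = FALSE]
  if (nrow(a) != nrow(b)) stopf("lab and lab0 row counts differ")
  sqrt(rowSums((a - b)^2))
}

#' Summarise storage browning from per-replicate colour records
#'
#' Computes each replicate's colour difference against its own pre-storage
#' (`storage_h == 0`) baseline, then the group mean and (sample) SD by
#' blanching time and storage time. Baseline rows report the difference as
#' `NA` (tables print it as a dash); replicates lacking a baseline are
#' excluded with a warning. Per-replicate differencing (rather than
#' differencing the group-mean colours) is the only reading under which a
#' mean +/- SD of the colour difference is well defined, and the mean of
#' per-replicate distances is never smaller than the distance of the mean
#' colours.
#'
#' @param records Data frame with columns `sample_id`, `blanch_time_min`,
#'   `storage_h`, `L`, `a`, `b`.
#' @return Data frame: `blanch_time_min`, `storage_h`, `mean_delta_e`,
#'   `sd_delta_e`, `n`.
#' @export
browning_summary <- function(records) {
  req <- c("sample_id", "blanch_time_min", "storage_h", "L", "a", "b")
  if (!all(req %in% names(records))) {
    stopf("records must contain columns: %s", paste(req, collapse = ", "))
  }
  if (any(records$storage_h < 0)) stopf("storage_h must be non-negative")
  base <- records[records$storage_h == 0, ]
  has_base <- records$sample_id %in% base$sample_id
  if (any(!has_base)) {
    warning(sprintf("%d record(s) lack a storage_h = 0 baseline and were excluded",
                    sum(!has_base)))
    records <- records[has_base, ]
  }
  bl <- base[match(records$sample_id, base$sample_id), ]
  de <- delta_e(as.matrix(records[, c("L", "a", "b")]),
                as.matrix(bl[, c("L", "a", "b")]))
  de[records$storage_h == 0] <- NA_real_
  agg <- stats::aggregate(
    de, by = list(blanch_time_min = records$blanch_time_min,
                  storage_h = records$storage_h),
    FUN = function(v) c(mean = mean(v), sd = stats::sd(v), n = length(v)))
  out <- data.frame(blanch_time_min = agg$blanch_time_min,
                    storage_h = agg$storage_h,
                    mean_delta_e = agg$x[, "mean"],
                    sd_delta_e = agg$x[, "sd"],
                    n = as.integer(agg$x[, "n"]))
  out[order(out$blanch_time_min, out$storage_h), , drop = FALSE]
}
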