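# ENVI hypercube interchange: ASCII .hdr + raw little-endian binary cube.
# No pre-installed R package parses ENVI headers, so reader and writer are
# implemented here. Supported: data types 4 (float32) and 5 (float64),
# interleaves BIL, BSQ, BIP, byte order 0.

envi_paths <- function(path) {
  base <- sub("\\.(hdr|dat)$", "", path)
  list(hdr = paste0(base, ".hdr"), dat = paste0(base, ".dat"))
}

#' Write a hypercube to an ENVI file pair
#'
#' Writes `<path>.hdr` (ASCII header including the full-precision
#' wavelength list) and `<path>.dat` (raw binary, little endian).
#'
#' @param cube A [hypercube()].
#' @param path Output base path (a trailing `.hdr`/`.dat` is stripped).
#' @param interleave `"bil"`, `"bsq"`, or `"bip"`.
#' @param data_type ENVI data type code: 4 (float32) or 5 (float64).
#' @return The base path, invisibly.
#' @export
write_envi <- function(cube, path, interleave = c("bil", "bsq", "bip"),
                       data_type = 5) {
  stopifnot(inherits(cube, "hypercube"))
  interleave <- match.arg(interleave)
  if (!data_type %in% c(4, 5)) stopf("unsupported ENVI data type %s", data_type)
  p <- envi_paths(path)
  d <- dim(cube$data)
  perm <- switch(interleave,
                 bil = c(2, 3, 1),   # sample, band, line
                 bsq = c(2, 1, 3),   # sample, line, band
                 bip = c(3, 2, 1))   # band, sample, line
  v <- as.vector(aperm(cube$data, perm))
  hdr <- c(
    "ENVI",
    "description = {blanchspec hypercube}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", data_type),
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    "wavelength units = Nanometers",
    sprintf("wavelength = {%s}",
            paste(format(as.numeric(cube$grid), digits = 17, trim = TRUE),
                  collapse = ", ")))
  writeLines(hdr, p$hdr)
  con <- file(p$dat, "wb")
  on.exit(close(con))
  writeBin(v, con, size = if (data_type == 4) 4L else 8L, endian = "little")
  invisible(sub("\\.(hdr|dat)$", "", path))
}

parse_envi_header <- function(hdr_path) {
  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  fields <- list()
  # key = value, where a {...} value may span lines
  pat <- "(?m)^[ \t]*([a-zA-Z][a-zA-Z0-9 _]*?)[ \t]*=[ \t]*(\\{[^}]*\\}|[^\n]*)"
  ms <- regmatches(txt, gregexpr(pat, txt, perl = TRUE))[[1]]
  for (m in ms) {
    key <- tolower(trimws(sub("=.*", "", m)))
    val <- trimws(sub("^[^=]*=", "", m))
    fields[[key]] <- val
  }
  fields
}

#' Read an ENVI file pair into a hypercube
#'
#' @param path Path to the `.hdr`, the binary file, or their common base.
#' @return A [hypercube()] with the grid taken from the header's mandatory
#'   `wavelength` field.
#' @export
read_envi <- function(path) {
  p <- envi_paths(path)
  if (!file.exists(p$hdr)) stopf("ENVI header not found: %s", p$hdr)
  if (!file.exists(p$dat)) stopf("ENVI data file not found: %s", p$dat)
  f <- parse_envi_header(p$hdr)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  miss <- setdiff(need, names(f))
  if (length(miss)) stopf("ENVI header lacks field(s): %s", paste(miss, collapse = ", "))
  ns <- as.integer(f[["samples"]])
  nl <- as.integer(f[["lines"]])
  nb <- as.integer(f[["bands"]])
  dt <- as.integer(f[["data type"]])
  il <- tolower(f[["interleave"]])
  if (!is.null(f[["byte order"]]) && as.integer(f[["byte order"]]) != 0) {
    stopf("only byte order 0 (little endian) is supported")
  }
  if (!dt %in% c(4L, 5L)) {
    stopf("unsupported ENVI data type %d (only 4 = float32, 5 = float64)", dt)
  }
  if (!il %in% c("bil", "bsq", "bip")) stopf("unsupported interleave '%s'", il)
  if (is.null(f[["wavelength"]])) {
    stopf("ENVI header lacks the mandatory wavelength field")
  }
  wtxt <- gsub("[{}]", "", f[["wavelength"]])
  w <- as.numeric(trimws(strsplit(wtxt, ",")[[1]]))
  if (length(w) != nb) {
    stopf("header declares %d bands but lists %d wavelengths", nb, length(w))
  }
  offset <- as.integer(f[["header offset"]] %||% "0")
  con <- file(p$dat, "rb")
  on.exit(close(con))
  if (offset > 0) readBin(con, "raw", offset)
  n <- ns * nl * nb
  v <- readBin(con, "numeric", n, size = if (dt == 4L) 4L else 8L,
               endian = "little")
  if (length(v) != n) stopf("ENVI data file is truncated")
  data <- switch(il,
    bil = aperm(array(v, dim = c(ns, nb, nl)), c(3, 1, 2)),
    bsq = aperm(array(v, dim = c(ns, nl, nb)), c(2, 1, 3)),
    bip = aperm(array(v, dim = c(nb, ns, nl)), c(3, 2, 1)))
  hypercube(data, wavelength_grid(w))
}

#' Serialize a fitted PLS1 model to JSON
#'
#' A documented plain-text container: matrices are stored row-major with
#' named dimensions, wavelengths at full precision. [read_plsr_json()]
#' restores a model whose predictions agree to double-precision round-off.
#'
#' @param model A `"plsr"` model.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_plsr_json <- function(model, path) {
  stopifnot(inherits(model, "plsr"))
  mat <- function(m) list(dim = dim(m), order = "row-major",
                          values = as.vector(t(m)))
  obj <- list(
    container = "blanchspec-plsr",
    version = 1L,
    target_name = model$target_name,
    n_components = model$n_components,
    n_train = model$n_train,
    wavelengths = if (is.null(model$wavelengths)) NULL else as.numeric(model$wavelengths),
    x_mean = as.numeric(model$x_mean),
    y_mean = model$y_mean,
    x_weights = mat(model$x_weights),
    x_loadings = mat(model$x_loadings),
    y_loadings = as.numeric(model$y_loadings),
    beta = as.numeric(model$beta),
    intercept = model$intercept,
    y_range = as.numeric(model$y_range))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_plsr_json
#' @export
read_plsr_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$container, "blanchspec-plsr")) {
    stopf("%s is not a blanchspec PLSR model container", path)
  }
  unmat <- function(m) matrix(m$values, nrow = m$dim[1], ncol = m$dim[2],
                              byrow = TRUE)
  structure(list(
    n_components = as.integer(obj$n_components),
    x_mean = obj$x_mean, y_mean = obj$y_mean,
    x_weights = unmat(obj$x_weights),
    x_loadings = unmat(obj$x_loadings),
    y_loadings = obj$y_loadings,
    beta = obj$beta, intercept = obj$intercept,
    y_range = obj$y_range,
    wavelengths = if (is.null(obj$wavelengths)) NULL else wavelength_grid(obj$wavelengths),
    target_name = obj$target_name,
    n_train = as.integer(obj$n_train)
  ), class = "plsr")
}
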