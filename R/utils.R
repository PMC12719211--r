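# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. seed = NULL leaves the stream untouched.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# One master seed per run; each stochastic stage draws from its own derived
# sub-stream so that adding a stage never shifts another stage's stream.
# Kept strictly below 2^31 (R integers are 32-bit).
derive_seed <- function(seed, stage, index = 0L) {
  offsets <- c(fields = 11L, render = 23L, assay = 37L, split = 53L,
               folds = 71L, scene = 89L, variation = 97L)
  if (!stage %in% names(offsets)) {
    stop("unknown seed stage: ", stage)
  }
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 48271 + off * 1009 + index * 7919) %% 2147483629) + 1L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x) && x >= 1
}
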