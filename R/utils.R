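#' @importFrom rlang abort warn .data
#' @importFrom stats cor sd var fft rnorm approx pt qt setNames
#' @importFrom tibble tibble as_tibble
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Deterministic 32-bit sub-seed derived from a master seed and an index.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 69621) %% 2147483647)
}

stopifnot_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number.", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be positive.", name))
  if (nonneg && x < 0) abort(sprintf("`%s` must be non-negative.", name))
  invisible(x)
}

# Sample standard deviation of each row of a matrix.
row_sds <- function(m) {
  apply(m, 1L, sd)
}
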