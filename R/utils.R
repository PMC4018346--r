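#' Round half away from zero
#'
#' Fixed-precision rounding with ties going up (0.285 -> 0.29), matching the
#' convention used for reported minor-allele frequencies. Base R's `round()`
#' rounds half to even, which differs on exact ties.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  # the 1e-9 guard absorbs binary representation error in decimal ties
  # (0.285 * 100 is 28.499999999999996 in double precision)
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Derive a reproducible substream seed from a global seed and a stream name
#'
#' The pipeline fans a single global seed out to its stages by name, so that
#' reordering or skipping stages cannot silently change the random numbers a
#' stage sees. The stream name is hashed with a small polynomial hash and
#' folded into the 31-bit positive integer range.
#'
#' @param seed global integer seed.
#' @param stream character stream name (e.g. a stage name).
#' @return a positive integer seed.
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(length(stream) == 1L, is.character(stream))
  h <- 0
  for (k in utf8ToInt(stream)) h <- (h * 131 + k) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 * 7919 + h) %% 2147483629 + 1)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_input <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
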