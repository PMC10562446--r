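# Shared low-level helpers.

#' Quantize a float image to the 16-bit camera scale
#'
#' Rounds to the nearest integer grey value and clips to \[0, 65535\], the
#' range of the instrument's 16-bit camera. Used when committing corrected
#' (floating-point) layers to disk.
#'
#' @param x Numeric matrix (or vector).
#' @return Matrix of the same shape with integer-valued entries in
#'   \[0, 65535\].
#' @export
quantize16 <- function(x) {
  x <- round(x)
  x[x < 0] <- 0
  x[x > 65535] <- 65535
  storage.mode(x) <- "double"
  x
}

# Deterministic sub-seed derivation so that every stage of a run draws from
# an independent, reproducible stream. Kept below 2^31 - 1.
derive_seed <- function(seed, ...) {
  offs <- c(...)
  s <- as.numeric(seed) %% 2147483647
  for (o in offs) {
    s <- (s * 48271 + as.numeric(o) + 1) %% 2147483647
  }
  as.integer(s)
}

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so simulation calls do not perturb user code.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Stop with a consistent message prefix naming the offending argument.
stop_bad <- function(...) stop(..., call. = FALSE)

is_count <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x) &&
  x == floor(x) && x >= 0

# Coefficient of variation in percent, sample (n-1) standard deviation.
cv_percent <- function(x) 100 * stats::sd(x) / mean(x)
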