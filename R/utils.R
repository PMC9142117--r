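# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Commercial rounding: 0.5 rounds to 1, -0.5 rounds to -1. Base `round()`
#' uses banker's rounding, which would make visit totals depend on the parity
#' of the digit before the half.
#'
#' @param x numeric vector.
#' @return numeric vector of rounded values.
#' @keywords internal
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

clamp <- function(x, lo = 0, hi = 100) {
  pmin(pmax(x, lo), hi)
}

invlogit <- function(x) stats::plogis(x)
logit <- function(p) stats::qlogis(p)

#' Quintile group sizes
#'
#' Splits `n` units into five groups as equal as possible, allocating any
#' remainder to the lowest quintiles first (392 -> 79, 79, 78, 78, 78).
#'
#' @param n number of units (>= 5).
#' @return integer vector of length 5, sizes from quintile 1 to 5.
#' @keywords internal
quintile_sizes <- function(n) {
  base <- n %/% 5L
  r <- n %% 5L
  as.integer(base + (seq_len(5L) <= r))
}

# Deterministic sub-seed for a named pseudo-random stream, so that e.g.
# inserting noise records never perturbs the covariate draws. Kept < 2^31.
substream_seed <- function(seed, block) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(block) * 7919L
}

stop_input <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == as.integer(x)
}
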