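# Internal helpers shared across modules.

#' Deterministic integer allocation by floor + largest remainder
#'
#' Splits `n` items across categories with target `fractions` (which must sum
#' to at most 1; any shortfall goes to an implicit remainder category that is
#' dropped). Each category first receives `floor(n * f)`; leftover units go to
#' the categories with the largest fractional remainders, ties resolved in
#' input order.
#'
#' @param n integer total.
#' @param fractions numeric vector of target fractions.
#' @return integer vector, same length as `fractions`, summing to
#'   `round(n * sum(fractions))`.
#' @keywords internal
#' @noRd
alloc_counts <- function(n, fractions) {
  stopifnot(n >= 0, all(fractions >= 0), sum(fractions) <= 1 + 1e-12)
  raw <- n * fractions
  base <- floor(raw)
  total <- floor(n * sum(fractions) + 1e-9)
  short <- total - sum(base)
  if (short > 0) {
    rem <- raw - base
    give <- order(-rem, seq_along(rem))[seq_len(short)]
    base[give] <- base[give] + 1L
  }
  as.integer(base)
}

# Binary split by floor + largest remainder: the flagged category and its
# complement partition n exactly; ties in remainder favour the flagged one.
alloc_binary <- function(n, fraction) {
  alloc_counts(n, c(fraction, 1 - fraction))[1]
}

#' Half-up rounding
#'
#' `round()` in R rounds half to even; report percentages use conventional
#' half-up rounding (0.5 always rounds away from zero).
#' @keywords internal
#' @noRd
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Run `expr` under a local RNG state seeded with `seed`, restoring the caller's
# RNG afterwards. Keeps seeded operations from perturbing global randomness.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Consistent condition classes so callers can distinguish failure modes.
stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("cartatlas_format_error", "error")))
}
stop_integrity <- function(...) {
  stop(errorCondition(paste0(...), class = c("cartatlas_integrity_error", "error")))
}
stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("cartatlas_config_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
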