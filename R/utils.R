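#' Round half away from zero
#'
#' Rounds to `digits` decimals with ties going up (half-up), the convention
#' used for all percentage tables in this package. Base `round()` rounds
#' half to even, which disagrees on e.g. 26.05.
#'
#' @param x numeric vector
#' @param digits decimal places (default 1)
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Derive a module sub-seed from a master seed
#'
#' Each stochastic stage consumes its own stream so that, e.g., adding
#' subjects to the cross-sectional draw does not perturb visit randomness.
#'
#' @param seed master integer seed
#' @param offset small integer identifying the stream
#' @return integer seed below 2^31
#' @export
derive_seed <- function(seed, offset = 0L) {
  as.integer((as.double(seed) * 48271 + offset * 1000003) %% 2147483587)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

assert_prob <- function(x, field) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop_field(field, "probabilities must lie in [0, 1]")
  invisible(x)
}
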