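# Internal helpers shared across modules.

#' Round half-up to the nearest integer
#'
#' Commercial rounding: values exactly halfway between two integers round
#' away from zero (for the non-negative quantities used here, upward).
#' Used for whole-patient demand counts, where base R's banker's rounding
#' would be surprising (e.g. `round(0.5)` is 0).
#'
#' @param x Numeric vector (non-negative in all package uses).
#' @return Integer-valued numeric vector.
#' @examples
#' round_half_up(c(0.5, 1.5, 2.4, 2.5))
#' @export
round_half_up <- function(x) {
  floor(x + 0.5)
}

# stop() with a class so callers/tests can distinguish error kinds
stop_domain <- function(...) {
  stop(errorCondition(paste0(...), class = c("oncocap_domain_error", "error")))
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("oncocap_config_error", "error")))
}

# scalar checks
is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x)
}
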