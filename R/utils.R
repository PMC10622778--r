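#' Round to nearest, halves away from zero
#'
#' Commercial rounding rather than the IEEE banker's rounding used by
#' [base::round()]: 0.5 -> 1, 1.5 -> 2, -0.5 -> -1. Raw values are first
#' snapped to 9 decimals so that quantities that are exact in real
#' arithmetic (e.g. `299 * 0.45 = 134.55`) are not pushed across a rounding
#' boundary by binary floating-point representation.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places to keep (default 0).
#' @return Numeric vector rounded half-away-from-zero.
#' @export
#' @examples
#' round_half_away(c(0.5, 1.5, 2.5, -0.5))
#' round_half_away(8.9666667, digits = 2)
round_half_away <- function(x, digits = 0) {
  s <- 10^digits
  y <- round(abs(x) * s, 9)
  sign(x) * floor(y + 0.5) / s
}

# ceiling with a 9-decimal snap so products such as 20 * 0.1 (binary value
# 2.0000000000000004 in some expressions) do not spuriously bump to 3
ceiling_guarded <- function(x) ceiling(round(x, 9))

rounding_policies <- c("ceiling", "nearest", "none")

apply_rounding <- function(x, rounding = rounding_policies) {
  rounding <- match.arg(rounding)
  switch(rounding,
    ceiling = ceiling_guarded(x),
    nearest = round_half_away(x),
    none    = x
  )
}

abort_schema <- function(message, ...) {
  rlang::abort(message, class = c("mors_schema_error", "mors_error"), ...)
}

abort_validation <- function(message, ...) {
  rlang::abort(message, class = c("mors_validation_error", "mors_error"), ...)
}

abort_domain <- function(message, ...) {
  rlang::abort(message, class = c("mors_domain_error", "mors_error"), ...)
}

abort_unknown_count <- function(message, ...) {
  rlang::abort(message, class = c("mors_unknown_count_error", "mors_error"), ...)
}

check_count_scalar <- function(x, what) {
  if (length(x) != 1 || is.na(x) || !is.numeric(x) || x < 0 || x != trunc(x)) {
    abort_domain(sprintf("`%s` must be a single non-negative integer.", what))
  }
  as.numeric(x)
}
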