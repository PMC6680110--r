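# Internal helpers shared across the package.

#' Round half away from zero
#'
#' Published cost tables use commercial ("half-up") rounding, not the
#' banker's rounding of base [round()]. Used for all reported monetary
#' values (unit costs to the cent, cost lines to 0.01 US$ million).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half away from zero to `digits` decimals.
#' @export
#' @examples
#' round_half_up(2.345, 2)  # 2.35
#' round_half_up(2.5, 0)    # 3
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Classed error so callers/tests can distinguish validation failures from
# programming errors.
nc_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "nutricost_error", "error", "condition")))
}

nc_check <- function(ok, msg, class = "nutricost_invalid_input") {
  if (!isTRUE(ok)) nc_stop(msg, class)
  invisible(TRUE)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

is_fraction <- function(x) {
  is_scalar_number(x) && x >= 0 && x <= 1
}

`%||%` <- function(a, b) if (is.null(a)) b else a
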