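# internal helpers shared across modules

#' Round half away from zero
#'
#' Base [round()] rounds half to even; analytical reports conventionally round
#' half away from zero (2.075 -> 2.08 at two decimals), so reported
#' concentrations, percentages and detection limits use this rule.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_away(2.075, 2) # 2.08
round_half_away <- function(x, digits = 0) {
  stopifnot(is.numeric(x), is.numeric(digits), length(digits) == 1L)
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Convert a concentration in mg/L to a dimensionless mass fraction
#'
#' The Horwitz function takes concentrations as mass fractions. Aqueous food
#' extracts are taken to have unit density, so `x` mg/L is `x` mg/kg and the
#' mass fraction is `x * 1e-6`. Override `density_kg_per_L` for other solvents.
#'
#' @param x Concentration in mg/L.
#' @param density_kg_per_L Matrix density in kg/L (default 1).
#' @return Dimensionless mass fraction.
#' @export
#' @examples
#' mass_fraction(0.2) # 2e-7
mass_fraction <- function(x, density_kg_per_L = 1) {
  stopifnot(is.numeric(x), density_kg_per_L > 0)
  x * 1e-6 / density_kg_per_L
}

# abort with a consistent class so callers can test for invalid input
stop_invalid <- function(msg) {
  abort(msg, class = "sweetval_invalid_input")
}

check_finite_numeric <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop_invalid(sprintf("`%s` must be finite and non-missing.", what))
  }
  invisible(x)
}

# canonical column set of the long-format observation table
long_format_cols <- c(
  "analyte", "matrix", "role", "level_mg_per_L", "replicate", "value",
  "value_unit"
)

check_long_format <- function(data) {
  missing <- setdiff(long_format_cols, names(data))
  if (length(missing) > 0) {
    stop_invalid(sprintf(
      "Input table is missing required column(s): %s.",
      paste(missing, collapse = ", ")
    ))
  }
  invisible(data)
}
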