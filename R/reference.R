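#' Reference steviol-equivalent detection limits for the nine-glycoside panel
#'
#' Reported LOD/LOQ values (mg/kg steviol equivalents, rounded to three
#' decimals) for the panel across beverage, yogurt and snack matrices.
#' Useful as realistic limits for censored-substitution examples and for
#' demonstrating the internal-consistency check that replicate-SD limits
#' satisfy: the unrounded LOQ is exactly (10/3) times the unrounded LOD, so a
#' rounded pair must agree with that ratio within its rounding radius (see
#' [check_limit_ratio()]).
#'
#' @return Tibble: `analyte`, `matrix`, `lod_mg_per_kg`, `loq_mg_per_kg`.
#' @export
reference_detection_limits <- function() {
  readr::read_csv(
    system.file("extdata", "reference_detection_limits.csv",
                package = "sweetval", mustWork = TRUE),
    show_col_types = FALSE, progress = FALSE
  )
}

#' Check a rounded LOD/LOQ pair for 10/3 consistency
#'
#' Replicate-SD detection limits satisfy LOQ = (10/3) LOD before rounding.
#' A reported pair rounded to `digits` decimals is consistent with that
#' identity when some unrounded LOD within the rounding radius of the
#' reported LOD yields an LOQ within the rounding radius of the reported
#' LOQ: `|LOQ - (10/3) LOD| <= (10/3 + 1) * r` with `r = 0.5 * 10^-digits`.
#'
#' @param lod,loq Reported (rounded) limits, same units.
#' @param digits Decimals the pair was rounded to (default 3).
#' @return Logical vector.
#' @export
#' @examples
#' check_limit_ratio(0.060, 0.201) # TRUE
check_limit_ratio <- function(lod, loq, digits = 3) {
  check_finite_numeric(lod, "lod")
  check_finite_numeric(loq, "loq")
  r <- 0.5 * 10^-digits
  abs(loq - (10 / 3) * lod) <= (10 / 3 + 1) * r + 1e-12
}
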