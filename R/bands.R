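#' Acceptance bands for validation criteria
#'
#' The numeric criteria a single-laboratory validation is judged against.
#' Defaults follow the usual guideline values for trace quantitation in food:
#' calibration R-squared above 0.99, per-level calibration %RSD below 15%,
#' repeatability %RSD below 20%, recovery within 70-120%, absolute matrix
#' effect within 80-120%, HorRat below 2 and retention-time RPD below 5%.
#'
#' @param r2_min Minimum coefficient of determination.
#' @param rsd_linearity_max Maximum per-level %RSD of calibration responses.
#' @param rsd_precision_max Maximum repeatability %RSD.
#' @param recovery_range Two-element `c(lower, upper)` percent band.
#' @param me_range Two-element `c(lower, upper)` percent band.
#' @param horrat_max Maximum acceptable HorRat.
#' @param rpd_max Maximum retention-time %RPD.
#' @return An object of class `acceptance_bands` (a named list).
#' @export
#' @examples
#' acceptance_bands()
acceptance_bands <- function(r2_min = 0.99,
                             rsd_linearity_max = 15,
                             rsd_precision_max = 20,
                             recovery_range = c(70, 120),
                             me_range = c(80, 120),
                             horrat_max = 2.0,
                             rpd_max = 5.0) {
  stopifnot(
    r2_min > 0, rsd_linearity_max > 0, rsd_precision_max > 0,
    length(recovery_range) == 2, recovery_range[1] < recovery_range[2],
    length(me_range) == 2, me_range[1] < me_range[2],
    all(recovery_range > 0), all(me_range > 0),
    horrat_max > 0, rpd_max > 0
  )
  structure(
    list(
      r2_min = r2_min,
      rsd_linearity_max = rsd_linearity_max,
      rsd_precision_max = rsd_precision_max,
      recovery_range = recovery_range,
      me_range = me_range,
      horrat_max = horrat_max,
      rpd_max = rpd_max
    ),
    class = "acceptance_bands"
  )
}

#' @export
print.acceptance_bands <- function(x, ...) {
  cat("Acceptance bands:\n")
  cat(sprintf("  R^2            > %.3g\n", x$r2_min))
  cat(sprintf("  linearity %%RSD < %.3g%%\n", x$rsd_linearity_max))
  cat(sprintf("  precision %%RSD < %.3g%%\n", x$rsd_precision_max))
  cat(sprintf("  recovery       %g-%g%%\n", x$recovery_range[1], x$recovery_range[2]))
  cat(sprintf("  matrix effect  %g-%g%%\n", x$me_range[1], x$me_range[2]))
  cat(sprintf("  HorRat         < %.3g\n", x$horrat_max))
  cat(sprintf("  RT %%RPD        < %.3g%%\n", x$rpd_max))
  invisible(x)
}

#' Evaluate values against the acceptance bands
#'
#' Deterministic pass/fail verdicts for a set of computed criterion values.
#' Criteria not supplied are reported as not evaluated (`pass = NA`).
#'
#' @param values Named list or data frame with any of: `r_squared`,
#'   `rsd_linearity`, `rsd_precision`, `recovery`, `matrix_effect`, `horrat`,
#'   `rpd`. Each element may be a vector; the worst case decides the verdict
#'   and is reported as `value`.
#' @param bands An [acceptance_bands()] object.
#' @return A tibble with columns `criterion`, `value` (the offending or worst
#'   value), `pass` (logical, NA when not evaluated).
#' @export
#' @examples
#' evaluate_bands(list(recovery = 65, matrix_effect = 100), acceptance_bands())
evaluate_bands <- function(values, bands = acceptance_bands()) {
  stopifnot(inherits(bands, "acceptance_bands"))
  values <- as.list(values)

  # each rule reports the value furthest out of band (or worst case in band)
  worst_low <- function(x) x[which.min(x)]
  worst_high <- function(x) x[which.max(x)]
  worst_range <- function(x, rng) {
    d <- pmax(rng[1] - x, x - rng[2]) # signed distance out of band
    x[which.max(d)]
  }

  rules <- list(
    r_squared = function(x) {
      v <- worst_low(x)
      list(value = v, pass = v > bands$r2_min)
    },
    rsd_linearity = function(x) {
      v <- worst_high(x)
      list(value = v, pass = v < bands$rsd_linearity_max)
    },
    rsd_precision = function(x) {
      v <- worst_high(x)
      list(value = v, pass = v < bands$rsd_precision_max)
    },
    recovery = function(x) {
      v <- worst_range(x, bands$recovery_range)
      list(value = v, pass = v >= bands$recovery_range[1] & v <= bands$recovery_range[2])
    },
    matrix_effect = function(x) {
      v <- worst_range(x, bands$me_range)
      list(value = v, pass = v >= bands$me_range[1] & v <= bands$me_range[2])
    },
    horrat = function(x) {
      v <- worst_high(x)
      list(value = v, pass = v < bands$horrat_max)
    },
    rpd = function(x) {
      v <- worst_high(x)
      list(value = v, pass = v < bands$rpd_max)
    }
  )

  purrr::map_dfr(names(rules), function(crit) {
    x <- values[[crit]]
    x <- x[is.finite(x)]
    if (is.null(x) || length(x) == 0) {
      return(tibble::tibble(criterion = crit, value = NA_real_, pass = NA))
    }
    res <- rules[[crit]](x)
    tibble::tibble(criterion = crit, value = res$value, pass = res$pass)
  })
}
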