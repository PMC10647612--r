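#' Fit a linear calibration for one analyte in one matrix
#'
#' Ordinary least squares of detector response on concentration over all
#' replicate points (replicates enter as individual points, which preserves
#' the level-wise %RSD information), with an intercept always included.
#' Per-level %RSD of the replicate responses and the coefficient of
#' determination are computed alongside the coefficients; a fit is flagged
#' linear when R-squared exceeds `bands$r2_min` and every level's %RSD is
#' below `bands$rsd_linearity_max`.
#'
#' @param data A data frame with columns `level` (concentration, mg/L) and
#'   `response` (peak area). At least three distinct positive levels.
#' @param analyte,matrix Optional labels carried into the fit.
#' @param weighting `"none"` (default) or `"1/x"` for inverse-concentration
#'   weighted least squares.
#' @param bands An [acceptance_bands()] object for the linearity flags.
#' @return A `calibration_fit` object: list with `slope`, `intercept`,
#'   `r_squared`, `level_rsd` (tibble `level`, `n`, `rsd`), `linear`,
#'   `analyte`, `matrix`, `n`, and the underlying `lm` fit.
#' @seealso [back_calculate()], [fit_calibrations()] for the data-frame-first
#'   variant over many analyte/matrix series.
#' @export
#' @examples
#' d <- data.frame(level = rep(c(0.2, 0.5, 1), each = 3))
#' d$response <- 2000 * d$level + 50
#' fit_calibration(d)
fit_calibration <- function(data, analyte = NA_character_, matrix = NA_character_,
                            weighting = c("none", "1/x"),
                            bands = acceptance_bands()) {
  weighting <- match.arg(weighting)
  if (!all(c("level", "response") %in% names(data))) {
    stop_invalid("`data` must have columns `level` and `response`.")
  }
  level <- data$level
  response <- data$response
  check_finite_numeric(level, "level")
  check_finite_numeric(response, "response")
  if (any(level <= 0)) stop_invalid("Calibration levels must be > 0.")
  if (length(unique(level)) < 3) {
    stop_invalid("At least three distinct calibration levels are required.")
  }

  w <- if (weighting == "1/x") 1 / level else NULL
  fit <- lm(response ~ level, weights = w)
  # R^2 = 1 - SSE/SST (0 for a flat series, where SST = 0)
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((response - mean(response))^2)
  r2 <- if (sst == 0) 0 else 1 - sse / sst

  level_rsd <- tibble::tibble(level = level, response = response) |>
    dplyr::group_by(level) |>
    dplyr::summarise(
      n = dplyr::n(),
      rsd = if (dplyr::n() >= 2 && mean(.data$response) != 0) {
        rsd_percent(.data$response)
      } else {
        NA_real_
      },
      .groups = "drop"
    )

  linear <- r2 > bands$r2_min &&
    all(is.na(level_rsd$rsd) | level_rsd$rsd < bands$rsd_linearity_max)

  structure(
    list(
      analyte = analyte,
      matrix = matrix,
      slope = unname(coef(fit)[["level"]]),
      intercept = unname(coef(fit)[["(Intercept)"]]),
      r_squared = r2,
      level_rsd = level_rsd,
      linear = linear,
      n = length(level),
      weighting = weighting,
      lm = fit
    ),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, ...) {
  lbl <- if (!is.na(x$analyte)) sprintf(" [%s / %s]", x$analyte, x$matrix) else ""
  cat(sprintf("Linear calibration%s\n", lbl))
  cat(sprintf("  y = %.6gx %s %.6g   (n = %d points)\n",
              x$slope, ifelse(x$intercept < 0, "-", "+"), abs(x$intercept), x$n))
  cat(sprintf("  R^2 = %.4f  linear: %s\n", x$r_squared,
              ifelse(x$linear, "yes", "no")))
  invisible(x)
}

#' @export
tidy.calibration_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = unname(suppressWarnings(
      summary(x$lm)$coefficients[, "Std. Error"]
    ))
  )
}

#' @export
glance.calibration_fit <- function(x, ...) {
  tibble::tibble(
    analyte = x$analyte,
    matrix = x$matrix,
    slope = x$slope,
    intercept = x$intercept,
    r_squared = x$r_squared,
    max_level_rsd = suppressWarnings(max(x$level_rsd$rsd, na.rm = TRUE)),
    linear = x$linear,
    n = x$n
  )
}

#' Back-calculate concentrations from detector responses
#'
#' Inverts a fitted calibration line: `(response - intercept) / slope`.
#' Negative results are allowed and returned as-is — they arise from blank
#' noise below the intercept and are handled downstream as censoring
#' candidates.
#'
#' @param fit A `calibration_fit` (or any list with `slope` and `intercept`).
#' @param response Numeric vector of peak areas.
#' @return Concentrations in calibration units (mg/L).
#' @export
#' @examples
#' f <- list(slope = 2, intercept = 1)
#' back_calculate(f, 5) # 2
back_calculate <- function(fit, response) {
  check_finite_numeric(response, "response")
  if (is.null(fit$slope) || !is.finite(fit$slope) || fit$slope == 0) {
    stop_invalid("Calibration slope must be non-zero to back-calculate.")
  }
  (response - fit$intercept) / fit$slope
}

#' Fit calibrations for every analyte/matrix series in a long table
#'
#' Data-frame-first wrapper around [fit_calibration()]: takes the long-format
#' observation table, keeps `role == "calibration"` rows, and fits one line
#' per analyte-by-matrix series.
#'
#' @param data Long-format table (see [read_observations()]): columns
#'   `analyte`, `matrix`, `role`, `level_mg_per_L`, `replicate`, `value`,
#'   `value_unit`.
#' @param bands An [acceptance_bands()] object.
#' @inheritParams fit_calibration
#' @return A tibble with one row per analyte x matrix: `analyte`, `matrix`,
#'   `slope`, `intercept`, `r_squared`, `max_level_rsd`, `linear`, `n`,
#'   `equation` (rendered `"y = ax + b"`), and a `fit` list-column of
#'   `calibration_fit` objects.
#' @export
fit_calibrations <- function(data, bands = acceptance_bands(),
                             weighting = c("none", "1/x")) {
  weighting <- match.arg(weighting)
  check_long_format(data)
  cal <- dplyr::filter(data, .data$role == "calibration")
  if (nrow(cal) == 0) stop_invalid("No rows with role = \"calibration\".")

  cal |>
    dplyr::group_by(.data$analyte, .data$matrix) |>
    dplyr::group_modify(function(df, key) {
      fit <- fit_calibration(
        data.frame(level = df$level_mg_per_L, response = df$value),
        analyte = key$analyte, matrix = key$matrix,
        weighting = weighting, bands = bands
      )
      g <- glance(fit)
      g$analyte <- NULL
      g$matrix <- NULL
      g$equation <- sprintf(
        "y = %.6gx %s %.6g",
        fit$slope, ifelse(fit$intercept < 0, "-", "+"), abs(fit$intercept)
      )
      g$fit <- list(fit)
      g
    }) |>
    dplyr::ungroup()
}

#' @rdname fit_calibrations
#' @param fits A tibble returned by [fit_calibrations()].
#' @param new_data Long-format rows whose `value` column holds peak areas to
#'   quantify against the matching analyte/matrix fit (falling back to the
#'   solvent fit when no matrix-matched fit exists and `fallback_solvent`).
#' @param fallback_solvent Use the solvent calibration when the row's matrix
#'   has no fit of its own (default TRUE).
#' @return For `quantify()`: `new_data` with an added `conc_mg_per_L` column.
#' @export
quantify <- function(fits, new_data, fallback_solvent = TRUE) {
  check_long_format(new_data)
  lookup <- setNames(fits$fit, paste(fits$analyte, fits$matrix, sep = "\r"))
  conc <- purrr::pmap_dbl(
    list(new_data$analyte, new_data$matrix, new_data$value),
    function(a, m, v) {
      fit <- lookup[[paste(a, m, sep = "\r")]]
      if (is.null(fit) && fallback_solvent) {
        fit <- lookup[[paste(a, "solvent", sep = "\r")]]
      }
      if (is.null(fit)) {
        return(NA_real_)
      }
      back_calculate(fit, v)
    }
  )
  dplyr::mutate(new_data, conc_mg_per_L = conc)
}
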