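#' Relative percent difference between two retention times
#'
#' Specificity of a targeted LC-MS/MS method is checked by comparing the
#' retention time of an analyte in a sample against the mean retention time of
#' the corresponding standard. The relative percent difference scales the
#' absolute difference by the mean of the two values,
#' \deqn{\%RPD = 100\,|RT_1 - RT_2| / ((RT_1 + RT_2)/2),}
#' so it is symmetric in its arguments and invariant to a common change of time
#' units. Identification windows conventionally require RPD below 5%.
#'
#' @param rt_a,rt_b Retention times in minutes (vectors recycle).
#' @return Percent RPD in `[0, 200)`.
#' @export
#' @examples
#' rpd_percent(5.0, 4.9) # 2.0202...
rpd_percent <- function(rt_a, rt_b) {
  check_finite_numeric(rt_a, "rt_a")
  check_finite_numeric(rt_b, "rt_b")
  if (any(rt_a <= 0) || any(rt_b <= 0)) {
    stop_invalid("Retention times must be strictly positive.")
  }
  100 * abs(rt_a - rt_b) / ((rt_a + rt_b) / 2)
}

#' Percent relative standard deviation
#'
#' The repeatability measure of replicate determinations:
#' \eqn{\%RSD = 100 \cdot SD / \bar{x}} with the sample standard deviation
#' (n - 1 denominator). Scale-invariant: multiplying every replicate by a
#' positive constant leaves the result unchanged.
#'
#' @param values Numeric vector of at least two replicate measurements.
#' @return Percent RSD.
#' @export
#' @examples
#' rsd_percent(c(1, 2, 3)) # 50
rsd_percent <- function(values) {
  check_finite_numeric(values, "values")
  if (length(values) < 2) {
    stop_invalid("At least two replicate values are required for %RSD.")
  }
  m <- mean(values)
  if (m == 0) stop_invalid("Mean of replicate values is zero; %RSD undefined.")
  100 * sd(values) / m
}

#' Horwitz predicted relative standard deviation
#'
#' The Horwitz function is the empirical inter-laboratory precision expected at
#' a given concentration, \deqn{PRSD = 2^{(1 - 0.5\log_{10} C)},} with `C` the
#' concentration expressed as a dimensionless mass fraction. It is strictly
#' decreasing in `C`: PRSD(1) = 2%, PRSD(0.01) = 4%, PRSD(1e-4) = 8%.
#'
#' @param c_mass_fraction Concentration as a mass fraction in `(0, 1]`
#'   (see [mass_fraction()] to convert mg/L).
#' @return Predicted RSD in percent.
#' @export
#' @examples
#' horwitz_prsd(0.01)           # 4
#' horwitz_prsd(mass_fraction(0.2)) # 20.39 at 0.2 mg/L
horwitz_prsd <- function(c_mass_fraction) {
  check_finite_numeric(c_mass_fraction, "c_mass_fraction")
  if (any(c_mass_fraction <= 0) || any(c_mass_fraction > 1)) {
    stop_invalid("Mass fraction must lie in (0, 1].")
  }
  2^(1 - 0.5 * log10(c_mass_fraction))
}

#' Horwitz ratio (HorRat)
#'
#' Ratio of the observed relative standard deviation to the Horwitz predicted
#' RSD at the same concentration. Single-laboratory values below 2 are
#' conventionally acceptable.
#'
#' @param rsd Observed %RSD (non-negative).
#' @param c_mass_fraction Concentration as a mass fraction in `(0, 1]`.
#' @return Dimensionless ratio.
#' @export
#' @examples
#' horrat(4, 0.01) # 1
horrat <- function(rsd, c_mass_fraction) {
  check_finite_numeric(rsd, "rsd")
  if (any(rsd < 0)) stop_invalid("`rsd` must be non-negative.")
  rsd / horwitz_prsd(c_mass_fraction)
}

#' Spike recovery
#'
#' Accuracy of the method from a spiked blank:
#' \deqn{Recovery\% = 100 (\bar{x}' - \bar{x}) / x_{spike},}
#' where \eqn{\bar{x}'} is the mean measured concentration of the spiked
#' sample, \eqn{\bar{x}} the blank mean and \eqn{x_{spike}} the added
#' concentration, all in the same units.
#'
#' @param spiked_mean Mean measured concentration of the spiked sample.
#' @param spike_level Added concentration (> 0).
#' @param blank_mean Mean of the blank sample (default 0; blanks of
#'   sweetener-free matrices carry no analyte).
#' @return Percent recovery.
#' @export
#' @examples
#' recovery_percent(0.22, 0.2, blank_mean = 0.02) # 100
recovery_percent <- function(spiked_mean, spike_level, blank_mean = 0) {
  check_finite_numeric(spiked_mean, "spiked_mean")
  check_finite_numeric(spike_level, "spike_level")
  check_finite_numeric(blank_mean, "blank_mean")
  if (any(spike_level <= 0)) stop_invalid("`spike_level` must be > 0.")
  100 * (spiked_mean - blank_mean) / spike_level
}

#' Absolute matrix effect
#'
#' Ionization suppression or enhancement from co-eluting matrix components,
#' expressed as the ratio of the analyte signal in a spiked matrix to the
#' signal of the same amount in pure solvent:
#' \deqn{\%ME_A = 100 \cdot A_{matrix} / A_{solvent}.}
#' 100 means no effect; values below 100 indicate suppression, above 100
#' enhancement. Values within 80-120% are conventionally acceptable.
#'
#' @param area_matrix Peak area of the analyte spiked into matrix.
#' @param area_solvent Peak area of the analyte in solvent (> 0).
#' @return Percent absolute matrix effect.
#' @export
#' @examples
#' matrix_effect_percent(80, 100) # 80 (suppression)
matrix_effect_percent <- function(area_matrix, area_solvent) {
  check_finite_numeric(area_matrix, "area_matrix")
  check_finite_numeric(area_solvent, "area_solvent")
  if (any(area_solvent <= 0)) stop_invalid("`area_solvent` must be > 0.")
  100 * area_matrix / area_solvent
}

#' Limits of detection and quantitation from low-level replicates
#'
#' Replicate-SD limits following the Eurachem convention: with `S0` the sample
#' standard deviation of replicate measurements at the lowest spike level and
#' `S0' = S0 / sqrt(n_report)` (where `n_report` is the number of replicate
#' observations averaged when a result is reported),
#' \deqn{LOD = 3 S_0', \qquad LOQ = 10 S_0'.}
#' LOQ/LOD is therefore exactly 10/3 before any rounding, and both limits
#' scale linearly with the replicate SD.
#'
#' Some texts print the reduction of `S0` as a plain division by `n`; set
#' `divisor = "n"` to reproduce that behaviour.
#'
#' @param values Replicate measurements (>= 2) at the lowest concentration,
#'   in the units the limits should carry.
#' @param n_report Number of replicates averaged when reporting a result
#'   (default 1).
#' @param divisor Either `"sqrt_n"` (default, Eurachem) or `"n"`.
#' @return A tibble with one row: `s0`, `s0_prime`, `lod`, `loq`.
#' @export
#' @examples
#' lod_loq(c(0.18, 0.20, 0.22))
lod_loq <- function(values, n_report = 1, divisor = c("sqrt_n", "n")) {
  divisor <- match.arg(divisor)
  check_finite_numeric(values, "values")
  if (length(values) < 2) {
    stop_invalid("At least two replicate values are required for LOD/LOQ.")
  }
  if (!is.numeric(n_report) || length(n_report) != 1L || n_report < 1) {
    stop_invalid("`n_report` must be a single number >= 1.")
  }
  s0 <- sd(values)
  s0p <- if (divisor == "sqrt_n") s0 / sqrt(n_report) else s0 / n_report
  tibble::tibble(s0 = s0, s0_prime = s0p, lod = 3 * s0p, loq = 10 * s0p)
}

#' Substitute left-censored results
#'
#' Results below the limit of detection or quantitation carry an unknown true
#' value; dietary-exposure practice replaces them under three scenarios:
#' lower bound (0), middle bound (half the relevant limit) and upper bound
#' (the limit itself). Detected values pass through unchanged. For any fixed
#' limits the three scenarios are ordered lower <= middle <= upper.
#'
#' @param value Measured concentration (ignored unless `status = "detected"`;
#'   may be `NA` for censored rows).
#' @param status One of `"detected"`, `"below_loq"`, `"below_lod"`
#'   (vectors recycle against `value`).
#' @param lod,loq Limits of detection and quantitation, `lod <= loq`.
#' @param scenario One of `"lower"`, `"middle"`, `"upper"`.
#' @return Numeric vector of substituted concentrations.
#' @export
#' @examples
#' substitute_censored(NA, "below_lod", lod = 0.06, loq = 0.2, scenario = "middle") # 0.03
substitute_censored <- function(value, status, lod, loq,
                                scenario = c("lower", "middle", "upper")) {
  scenario <- match.arg(scenario)
  status <- as.character(status)
  bad <- setdiff(unique(status), c("detected", "below_loq", "below_lod"))
  if (length(bad) > 0) {
    stop_invalid(sprintf("Unknown censoring status: %s.", paste(bad, collapse = ", ")))
  }
  check_finite_numeric(lod, "lod")
  check_finite_numeric(loq, "loq")
  if (any(lod > loq)) stop_invalid("`lod` must not exceed `loq`.")
  n <- max(length(value), length(status))
  value <- rep_len(as.numeric(value), n)
  status <- rep_len(status, n)
  lod <- rep_len(lod, n)
  loq <- rep_len(loq, n)
  frac <- switch(scenario, lower = 0, middle = 0.5, upper = 1)
  out <- value
  out[status == "below_lod"] <- frac * lod[status == "below_lod"]
  out[status == "below_loq"] <- frac * loq[status == "below_loq"]
  if (anyNA(out[status == "detected"])) {
    stop_invalid("Detected results must carry a numeric `value`.")
  }
  out
}

#' Summarise detected concentrations
#'
#' Occurrence-style summary over the samples in which an analyte was detected:
#' mean, sample SD (reported only when n >= 2), minimum, maximum and the
#' detect count. Reported values are rounded half away from zero to
#' `digits` decimals, the convention of concentration tables.
#'
#' @param values Detected concentrations (non-empty numeric vector).
#' @param digits Decimals for the reported values (default 2).
#' @return One-row tibble: `n`, `mean`, `sd` (NA when n < 2), `min`, `max`,
#'   and a rendered `label` like `"2.08 (1.83-2.32)"`.
#' @export
#' @examples
#' summarize_found(c(1.83, 2.32))
summarize_found <- function(values, digits = 2) {
  check_finite_numeric(values, "values")
  if (length(values) < 1) stop_invalid("At least one detected value is required.")
  n <- length(values)
  m <- round_half_away(mean(values), digits)
  s <- if (n >= 2) round_half_away(sd(values), digits) else NA_real_
  lo <- round_half_away(min(values), digits)
  hi <- round_half_away(max(values), digits)
  fmt <- function(x) formatC(x, format = "f", digits = digits)
  label <- if (n >= 2) {
    sprintf("%s ± %s (%s-%s)", fmt(m), fmt(s), fmt(lo), fmt(hi))
  } else {
    sprintf("%s (%s)", fmt(m), fmt(lo))
  }
  tibble::tibble(n = n, mean = m, sd = s, min = lo, max = hi, label = label)
}
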