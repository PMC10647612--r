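# atomic weights (IUPAC 2021, conventional values) sufficient for CHO sugars
.atomic_weights <- c(C = 12.011, H = 1.008, O = 15.999, N = 14.007, S = 32.06)

#' Molecular weight from a molecular formula
#'
#' Parses simple Hill-notation formulas (element symbols with optional counts,
#' e.g. `"C44H70O23"`) and sums conventional atomic weights. Covers C, H, O,
#' N, S — all that glycoside sweeteners need.
#'
#' @param formula Character vector of molecular formulas.
#' @return Molecular weights in g/mol.
#' @export
#' @examples
#' molecular_weight("C20H30O3") # steviol, 318.45
molecular_weight <- function(formula) {
  vapply(formula, function(f) {
    if (is.na(f) || !grepl("^([A-Z][a-z]?[0-9]*)+$", f)) {
      stop_invalid(sprintf("Cannot parse molecular formula '%s'.", f))
    }
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
    parts <- regmatches(f, list(m))[[1]]
    sum(vapply(parts, function(p) {
      el <- gsub("[0-9]", "", p)
      n <- gsub("[^0-9]", "", p)
      n <- if (nzchar(n)) as.numeric(n) else 1
      w <- .atomic_weights[el]
      if (is.na(w)) stop_invalid(sprintf("Unknown element '%s' in '%s'.", el, f))
      unname(w) * n
    }, numeric(1)))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Steviol-equivalent conversion factors
#'
#' Regulatory limits and intake values for steviol glycosides are expressed on
#' the common steviol backbone, so each glycoside concentration is rescaled by
#' a conversion factor CF before aggregation. The default table computes CF as
#' the molecular-weight ratio steviol/glycoside (the JECFA convention) from
#' the formulas in the transition table; e.g. stevioside
#' 318.45 / 804.88 = 0.396. Users with an authoritative CF table can supply
#' their own via `path` (CSV with columns `analyte`, `cf`).
#'
#' @param path Optional CSV path with columns `analyte` and `cf` overriding
#'   the computed defaults.
#' @param transitions Transition table supplying analytes and formulas for
#'   the computed defaults.
#' @return Tibble with columns `analyte`, `cf` (and, for computed defaults,
#'   `formula` and `mw`).
#' @export
#' @examples
#' conversion_factors()
conversion_factors <- function(path = NULL, transitions = srm_transitions()) {
  if (!is.null(path)) {
    tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    if (!all(c("analyte", "cf") %in% names(tab))) {
      stop_invalid("CF table must have columns `analyte` and `cf`.")
    }
    if (any(!is.finite(tab$cf)) || any(tab$cf <= 0)) {
      stop_invalid("Conversion factors must be finite and > 0.")
    }
    return(tibble::as_tibble(tab[, c("analyte", "cf")]))
  }
  mw_steviol <- molecular_weight("C20H30O3")
  mw <- molecular_weight(transitions$formula)
  tibble::tibble(
    analyte = transitions$analyte,
    formula = transitions$formula,
    mw = mw,
    cf = mw_steviol / mw
  )
}

#' Convert a glycoside concentration to steviol equivalents
#'
#' `[SE] = CF x [SG]`: the concentration of an individual steviol glycoside
#' times its conversion factor, in the same concentration units.
#'
#' @param conc Glycoside concentration(s), >= 0.
#' @param cf Conversion factor(s) in (0, 1].
#' @return Steviol-equivalent concentration(s).
#' @export
#' @examples
#' steviol_equivalent(10, 0.5) # 5
steviol_equivalent <- function(conc, cf) {
  check_finite_numeric(conc, "conc")
  check_finite_numeric(cf, "cf")
  if (any(conc < 0)) stop_invalid("`conc` must be non-negative.")
  if (any(cf <= 0)) stop_invalid("Conversion factors must be > 0.")
  conc * cf
}

cf_lookup <- function(analytes, cf_table) {
  idx <- match(analytes, cf_table$analyte)
  if (anyNA(idx)) {
    missing <- unique(analytes[is.na(idx)])
    abort(
      sprintf(
        "No conversion factor for analyte(s): %s.",
        paste(missing, collapse = ", ")
      ),
      class = "sweetval_config_error"
    )
  }
  cf_table$cf[idx]
}

#' Aggregate per-analyte results of one sample into steviol equivalents
#'
#' Substitutes left-censored results under the requested scenario
#' (see [substitute_censored()]), converts each analyte to steviol
#' equivalents, and totals the sample. Totals are ordered
#' lower <= middle <= upper across scenarios for any fixed limits.
#'
#' @param results Data frame with one row per analyte: columns `analyte`,
#'   `status` (`"detected"`, `"below_loq"`, `"below_lod"`), `conc`
#'   (concentration in mg/kg; may be NA for censored rows), `lod`, `loq`
#'   (same units).
#' @param cf_table Conversion-factor table covering every analyte
#'   (see [conversion_factors()]).
#' @param scenario Censoring scenario, `"lower"`, `"middle"` or `"upper"`.
#' @return List with `per_analyte` (tibble: analyte, status, conc_substituted,
#'   cf, se) and `total_se` (numeric scalar).
#' @export
#' @examples
#' res <- data.frame(
#'   analyte = c("Stevioside", "Rebaudioside A"),
#'   status = c("detected", "below_lod"),
#'   conc = c(10, NA), lod = 0.06, loq = 0.2
#' )
#' aggregate_sample(res, scenario = "upper")
aggregate_sample <- function(results, cf_table = conversion_factors(),
                             scenario = c("lower", "middle", "upper")) {
  scenario <- match.arg(scenario)
  needed <- c("analyte", "status", "conc", "lod", "loq")
  if (!all(needed %in% names(results))) {
    stop_invalid(sprintf(
      "`results` must have columns: %s.", paste(needed, collapse = ", ")
    ))
  }
  cf <- cf_lookup(results$analyte, cf_table)
  sub <- substitute_censored(
    results$conc, results$status, results$lod, results$loq, scenario
  )
  se <- steviol_equivalent(pmax(sub, 0), cf)
  per_analyte <- tibble::tibble(
    analyte = results$analyte,
    status = results$status,
    conc_substituted = sub,
    cf = cf,
    se = se
  )
  list(per_analyte = per_analyte, total_se = sum(se), scenario = scenario)
}
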