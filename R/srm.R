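#' Selected-reaction-monitoring transition table
#'
#' The nine steviol glycosides monitored in negative-mode SRM on a triple
#' quadrupole: deprotonated precursor m/z, the quantifier product ion (the
#' most intense transition, used for quantitation), two qualifier product
#' ions (used to confirm identity), collision energies and the reference
#' retention time under the 13-min gradient. Stevioside and rebaudioside B
#' are isobars (precursor 803.458) separated only by retention time
#' (4.895 vs 6.347 min).
#'
#' @param path Optional path to a CSV with the same columns, to monitor a
#'   different panel.
#' @return A tibble with columns `analyte`, `formula`, `reference_rt_min`,
#'   `precursor_mz`, `quantifier_mz`, `quantifier_ce`, `qualifier1_mz`,
#'   `qualifier1_ce`, `qualifier2_mz`, `qualifier2_ce`, `rf_lens`.
#' @export
#' @examples
#' srm_transitions()
srm_transitions <- function(path = NULL) {
  path <- path %||%
    system.file("extdata", "transitions.csv", package = "sweetval", mustWork = TRUE)
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c(
    "analyte", "reference_rt_min", "precursor_mz", "quantifier_mz",
    "qualifier1_mz", "qualifier2_mz"
  )
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop_invalid(sprintf(
      "Transition table is missing column(s): %s.", paste(missing, collapse = ", ")
    ))
  }
  prod <- pmax(tab$quantifier_mz, tab$qualifier1_mz, tab$qualifier2_mz)
  if (any(tab$precursor_mz <= prod) || any(tab$reference_rt_min <= 0)) {
    stop_invalid("Each precursor m/z must exceed its product ions and RTs must be > 0.")
  }
  tab
}

#' Assign SRM peak observations to analytes
#'
#' Matches each observed peak (precursor m/z, product m/z, retention time)
#' against a transition table. A transition is a candidate when both the
#' precursor and the product m/z lie within `mz_tol` of one of its monitored
#' ions and the retention-time relative percent difference against the
#' reference RT is at most `rt_tol_percent` (the identification-window
#' criterion). Ties are broken by smallest RT %RPD, then smallest precursor
#' m/z difference, then analyte name, so the assignment is deterministic and
#' independent of peak order.
#'
#' @param peaks Data frame of peak observations: columns `sample`,
#'   `precursor_mz`, `product_mz`, `rt_min`, `area`.
#' @param transitions A transition table as returned by [srm_transitions()].
#' @param mz_tol m/z tolerance (default 0.5, unit resolution on a triple
#'   quadrupole).
#' @param rt_tol_percent Maximum RT %RPD (default 5).
#' @return `peaks` with added columns `analyte` (NA when unassigned),
#'   `transition` (`"quantifier"`, `"qualifier"`), `rt_rpd`,
#'   `precursor_diff`.
#' @export
match_peaks <- function(peaks, transitions = srm_transitions(),
                        mz_tol = 0.5, rt_tol_percent = 5) {
  if (nrow(transitions) == 0) stop_invalid("Transition table is empty.")
  if (!all(c("precursor_mz", "product_mz", "rt_min") %in% names(peaks))) {
    stop_invalid("`peaks` must have columns precursor_mz, product_mz, rt_min.")
  }
  stopifnot(mz_tol > 0, rt_tol_percent > 0)

  products <- rbind(
    data.frame(i = seq_len(nrow(transitions)), mz = transitions$quantifier_mz,
               role = "quantifier"),
    data.frame(i = seq_len(nrow(transitions)), mz = transitions$qualifier1_mz,
               role = "qualifier"),
    data.frame(i = seq_len(nrow(transitions)), mz = transitions$qualifier2_mz,
               role = "qualifier")
  )

  match_one <- function(prec, prod, rt) {
    prec_diff <- abs(transitions$precursor_mz - prec)
    rt_rpd <- rpd_percent(pmax(rt, .Machine$double.eps), transitions$reference_rt_min)
    cand_rows <- products
    cand_rows$prod_diff <- abs(products$mz - prod)
    cand_rows <- cand_rows[cand_rows$prod_diff <= mz_tol &
                             prec_diff[cand_rows$i] <= mz_tol &
                             rt_rpd[cand_rows$i] <= rt_tol_percent, , drop = FALSE]
    if (nrow(cand_rows) == 0) {
      return(list(analyte = NA_character_, transition = NA_character_,
                  rt_rpd = NA_real_, precursor_diff = NA_real_))
    }
    ord <- order(rt_rpd[cand_rows$i], prec_diff[cand_rows$i],
                 transitions$analyte[cand_rows$i], cand_rows$prod_diff)
    best <- cand_rows[ord[1], ]
    list(
      analyte = transitions$analyte[best$i],
      transition = best$role,
      rt_rpd = rt_rpd[best$i],
      precursor_diff = prec_diff[best$i]
    )
  }

  hits <- purrr::pmap(
    list(peaks$precursor_mz, peaks$product_mz, peaks$rt_min), match_one
  )
  dplyr::mutate(
    tibble::as_tibble(peaks),
    analyte = purrr::map_chr(hits, "analyte"),
    transition = purrr::map_chr(hits, "transition"),
    rt_rpd = purrr::map_dbl(hits, "rt_rpd"),
    precursor_diff = purrr::map_dbl(hits, "precursor_diff")
  )
}

#' Confirm assigned identities per sample
#'
#' An analyte is quantifiable in a sample when its quantifier transition was
#' assigned; it is confirmed when at least one qualifier transition was also
#' observed within tolerance. Quantitation always uses the quantifier peak
#' area (the most intense transition); a quantifier-only hit remains
#' quantifiable but is flagged unconfirmed.
#'
#' @param assigned Output of [match_peaks()] (must contain `sample`, `area`).
#' @return Tibble with one row per sample x assigned analyte: `sample`,
#'   `analyte`, `area` (quantifier area), `n_qualifiers`, `confirmed`,
#'   `rt_rpd` (of the quantifier peak).
#' @export
confirm_identities <- function(assigned) {
  if (!all(c("sample", "analyte", "transition", "area") %in% names(assigned))) {
    stop_invalid("`assigned` must be the output of match_peaks() with a `sample` column.")
  }
  assigned |>
    dplyr::filter(!is.na(.data$analyte)) |>
    dplyr::group_by(.data$sample, .data$analyte) |>
    dplyr::group_modify(function(df, key) {
      q <- df[df$transition == "quantifier", , drop = FALSE]
      best <- if (nrow(q) > 0) which.max(q$area) else integer(0)
      tibble::tibble(
        area = if (nrow(q) > 0) q$area[best] else NA_real_,
        n_qualifiers = sum(df$transition == "qualifier"),
        confirmed = nrow(q) > 0 && any(df$transition == "qualifier"),
        rt_rpd = if (nrow(q) > 0) q$rt_rpd[best] else NA_real_
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$area))
}
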