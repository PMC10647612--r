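#' Read the long-format observation table / an SRM peak list
#'
#' The observation table is the package's exchange format: one row per
#' replicate measurement with columns `analyte`, `matrix`, `role`
#' (`calibration`, `spike`, `blank`, `me_solvent`, `me_matrix`, `sample`),
#' `level_mg_per_L`, `replicate`, `value` and `value_unit` (`area`,
#' `mg_per_L` or `mg_per_kg`). Peak lists carry `sample`, `precursor_mz`,
#' `product_mz`, `rt_min`, `area`.
#'
#' @param path Path to a UTF-8 CSV with a header row.
#' @return A tibble.
#' @export
read_observations <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_long_format(data)
  data
}

#' @rdname read_observations
#' @export
read_peaks <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("sample", "precursor_mz", "product_mz", "rt_min", "area")
  missing <- setdiff(needed, names(data))
  if (length(missing) > 0) {
    stop_invalid(sprintf(
      "Peak list is missing column(s): %s.", paste(missing, collapse = ", ")
    ))
  }
  data
}

#' Absolute matrix effect per analyte, matrix and level
#'
#' Pairs solvent responses (`role = "me_solvent"`) with matrix-spiked
#' responses (`role = "me_matrix"`) by analyte, level and replicate. The
#' level estimate `me_mean` is the ratio of the mean signals,
#' `100 * mean(A_matrix) / mean(A_solvent)` — the signal response of a level
#' is its mean response, and the ratio of means avoids the upward
#' ratio-of-noisy-replicates bias — while `me_sd` is the SD of the
#' per-replicate ratios, describing the replicate scatter the conventional
#' mean-plus-SD table reports.
#'
#' @param data Long-format observation table.
#' @param bands An [acceptance_bands()] object.
#' @return Tibble: `analyte`, `matrix`, `level_mg_per_L`, `n`, `me_mean`,
#'   `me_sd`, `pass`.
#' @export
assess_matrix_effect <- function(data, bands = acceptance_bands()) {
  check_long_format(data)
  solvent <- dplyr::filter(data, .data$role == "me_solvent") |>
    dplyr::select("analyte", "level_mg_per_L", "replicate",
                  area_solvent = "value")
  matrix_ <- dplyr::filter(data, .data$role == "me_matrix") |>
    dplyr::select("analyte", "matrix", "level_mg_per_L", "replicate",
                  area_matrix = "value")
  if (nrow(solvent) == 0 || nrow(matrix_) == 0) {
    stop_invalid("Matrix-effect assessment needs both me_solvent and me_matrix rows.")
  }
  dplyr::inner_join(
    matrix_, solvent,
    by = c("analyte", "level_mg_per_L", "replicate")
  ) |>
    dplyr::mutate(me = matrix_effect_percent(.data$area_matrix, .data$area_solvent)) |>
    dplyr::group_by(.data$analyte, .data$matrix, .data$level_mg_per_L) |>
    dplyr::summarise(
      n = dplyr::n(),
      me_mean = matrix_effect_percent(mean(.data$area_matrix),
                                      mean(.data$area_solvent)),
      me_sd = if (dplyr::n() >= 2) sd(.data$me) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      pass = .data$me_mean >= bands$me_range[1] & .data$me_mean <= bands$me_range[2]
    )
}

#' Precision and accuracy from spiked blanks
#'
#' Quantifies spike and blank responses against the calibration fits
#' (matrix-matched by default, so ionization effects cancel), then per
#' analyte x matrix x spike level computes the replicate mean and SD, %RSD,
#' HorRat (at the found mean concentration converted to a mass fraction by
#' default) and percent recovery, with verdicts against the bands.
#'
#' @param data Long-format observation table with `spike` (and optionally
#'   `blank`) rows holding peak areas or concentrations (`value_unit`).
#' @param fits Calibration fits from [fit_calibrations()] (needed when values
#'   are areas).
#' @param bands An [acceptance_bands()] object.
#' @param calibration `"matrix"` (default) to quantify against the row's own
#'   matrix-matched curve, `"solvent"` to force external calibration.
#' @param horrat_basis `"found"` (default) uses the mean measured
#'   concentration in the Horwitz function; `"added"` uses the spike level.
#' @param density_kg_per_L Density for the mg/L to mass-fraction conversion.
#' @return Tibble: `analyte`, `matrix`, `level_mg_per_L`, `n`, `mean_conc`,
#'   `sd_conc`, `rsd`, `horrat`, `blank_mean`, `recovery`, `rsd_pass`,
#'   `horrat_pass`, `recovery_pass`.
#' @export
assess_precision_accuracy <- function(data, fits = NULL,
                                      bands = acceptance_bands(),
                                      calibration = c("matrix", "solvent"),
                                      horrat_basis = c("found", "added"),
                                      density_kg_per_L = 1) {
  calibration <- match.arg(calibration)
  horrat_basis <- match.arg(horrat_basis)
  check_long_format(data)

  to_conc <- function(rows) {
    if (nrow(rows) == 0) {
      return(dplyr::mutate(rows, conc_mg_per_L = numeric(0)))
    }
    areas <- rows$value_unit == "area"
    if (any(areas)) {
      if (is.null(fits)) {
        stop_invalid("Spike/blank values are areas; calibration `fits` are required.")
      }
      rows_area <- rows[areas, , drop = FALSE]
      if (calibration == "solvent") rows_area$matrix <- "solvent"
      q <- quantify(fits, rows_area, fallback_solvent = TRUE)
      rows$conc_mg_per_L <- NA_real_
      rows$conc_mg_per_L[areas] <- q$conc_mg_per_L
      rows$conc_mg_per_L[!areas] <- rows$value[!areas]
    } else {
      rows$conc_mg_per_L <- rows$value
    }
    rows
  }

  spikes <- to_conc(dplyr::filter(data, .data$role == "spike"))
  if (nrow(spikes) == 0) stop_invalid("No rows with role = \"spike\".")
  sp_matrix <- dplyr::filter(data, .data$role == "spike")$matrix
  spikes$matrix <- sp_matrix # keep the true matrix label under solvent calibration

  blanks <- to_conc(dplyr::filter(data, .data$role == "blank"))
  blank_means <- if (nrow(blanks) > 0) {
    blanks$matrix <- dplyr::filter(data, .data$role == "blank")$matrix
    dplyr::group_by(blanks, .data$analyte, .data$matrix) |>
      dplyr::summarise(blank_mean = mean(.data$conc_mg_per_L), .groups = "drop")
  } else {
    NULL
  }

  out <- spikes |>
    dplyr::group_by(.data$analyte, .data$matrix, .data$level_mg_per_L) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_conc = mean(.data$conc_mg_per_L),
      sd_conc = if (dplyr::n() >= 2) sd(.data$conc_mg_per_L) else NA_real_,
      rsd = if (dplyr::n() >= 2 && mean(.data$conc_mg_per_L) != 0) {
        rsd_percent(.data$conc_mg_per_L)
      } else {
        NA_real_
      },
      .groups = "drop"
    )
  if (is.null(blank_means)) {
    out$blank_mean <- 0
  } else {
    out <- dplyr::left_join(out, blank_means, by = c("analyte", "matrix"))
    out$blank_mean[is.na(out$blank_mean)] <- 0
  }
  horrat_conc <- switch(horrat_basis,
    found = out$mean_conc,
    added = out$level_mg_per_L
  )
  out |>
    dplyr::mutate(
      horrat = ifelse(
        is.na(.data$rsd) | horrat_conc <= 0,
        NA_real_,
        horrat(
          ifelse(is.na(.data$rsd), 0, .data$rsd),
          mass_fraction(pmax(horrat_conc, 1e-12), density_kg_per_L)
        )
      ),
      recovery = recovery_percent(.data$mean_conc, .data$level_mg_per_L,
                                  .data$blank_mean),
      rsd_pass = .data$rsd < bands$rsd_precision_max,
      horrat_pass = .data$horrat < bands$horrat_max,
      recovery_pass = .data$recovery >= bands$recovery_range[1] &
        .data$recovery <= bands$recovery_range[2]
    )
}

#' Limits of detection and quantitation per analyte and matrix
#'
#' Applies the replicate-SD method (see [lod_loq()]) to the back-calculated
#' concentrations at the lowest spike level of each analyte x matrix series,
#' and converts the limits to steviol equivalents (mg/kg at unit density)
#' with the conversion-factor table.
#'
#' @inheritParams assess_precision_accuracy
#' @param cf_table Conversion-factor table (see [conversion_factors()]).
#' @param n_report Replicates averaged when reporting a result (default 1).
#' @param divisor `"sqrt_n"` (default) or `"n"`, see [lod_loq()].
#' @return Tibble: `analyte`, `matrix`, `level_mg_per_L` (the lowest spike
#'   level used), `n`, `s0`, `lod_mg_per_L`, `loq_mg_per_L`,
#'   `lod_se_mg_per_kg`, `loq_se_mg_per_kg`.
#' @export
assess_detection_limits <- function(data, fits = NULL,
                                    cf_table = conversion_factors(),
                                    n_report = 1,
                                    divisor = c("sqrt_n", "n"),
                                    calibration = c("matrix", "solvent")) {
  divisor <- match.arg(divisor)
  calibration <- match.arg(calibration)
  pa <- assess_precision_accuracy(data, fits, calibration = calibration)
  # recompute from the replicate concentrations, not the summary
  check_long_format(data)
  spikes <- dplyr::filter(data, .data$role == "spike")
  conc_of <- function(rows) {
    if (all(rows$value_unit == "area")) {
      m <- rows
      if (calibration == "solvent") m$matrix <- "solvent"
      q <- quantify(fits, m, fallback_solvent = TRUE)
      q$conc_mg_per_L
    } else {
      rows$value
    }
  }
  spikes |>
    dplyr::group_by(.data$analyte, .data$matrix) |>
    dplyr::group_modify(function(df, key) {
      lowest <- min(df$level_mg_per_L)
      reps <- df[df$level_mg_per_L == lowest, , drop = FALSE]
      reps$analyte <- key$analyte
      reps$matrix <- key$matrix
      conc <- conc_of(reps)
      lim <- lod_loq(conc, n_report = n_report, divisor = divisor)
      cf <- cf_lookup(key$analyte, cf_table)
      tibble::tibble(
        level_mg_per_L = lowest,
        n = length(conc),
        s0 = lim$s0,
        lod_mg_per_L = lim$lod,
        loq_mg_per_L = lim$loq,
        lod_se_mg_per_kg = steviol_equivalent(lim$lod, cf),
        loq_se_mg_per_kg = steviol_equivalent(lim$loq, cf)
      )
    }) |>
    dplyr::ungroup()
}

#' Retention-time agreement per analyte
#'
#' Summarises the retention-time relative percent difference of assigned
#' quantifier peaks against the transition-table reference, the specificity
#' check of the identification window.
#'
#' @param peaks A peak list (see [read_peaks()]).
#' @param transitions Transition table.
#' @param bands An [acceptance_bands()] object.
#' @inheritParams match_peaks
#' @return Tibble: `analyte`, `n_peaks`, `rpd_max`, `pass`.
#' @export
assess_retention <- function(peaks, transitions = srm_transitions(),
                             bands = acceptance_bands(),
                             mz_tol = 0.5, rt_tol_percent = 5) {
  assigned <- match_peaks(peaks, transitions, mz_tol, rt_tol_percent)
  assigned |>
    dplyr::filter(!is.na(.data$analyte), .data$transition == "quantifier") |>
    dplyr::group_by(.data$analyte) |>
    dplyr::summarise(
      n_peaks = dplyr::n(),
      rpd_max = max(.data$rt_rpd),
      .groups = "drop"
    ) |>
    dplyr::mutate(pass = .data$rpd_max < bands$rpd_max)
}

#' Run the full validation pipeline
#'
#' Orchestrates calibration fitting, matrix-effect, precision/accuracy,
#' detection-limit and (when a peak list is given) retention assessments over
#' a long-format observation table, and evaluates every criterion against the
#' acceptance bands per analyte x matrix. Stages whose input roles are absent
#' are reported as not evaluated rather than failing.
#'
#' @param data Long-format observation table (see [read_observations()]).
#' @param peaks Optional SRM peak list for the retention/specificity check.
#' @param bands An [acceptance_bands()] object.
#' @param cf_table Conversion-factor table.
#' @param n_report,divisor Passed to [assess_detection_limits()].
#' @param calibration Quantitation calibration, `"matrix"` or `"solvent"`.
#' @param seed Optional seed recorded in the metadata (the pipeline itself is
#'   deterministic).
#' @return A `validation_report`: list with tibbles `calibration`,
#'   `matrix_effect`, `precision_accuracy`, `limits`, `retention` (NULL
#'   without peaks), `verdicts` (analyte x matrix x criterion), and `meta`.
#' @export
run_validation <- function(data, peaks = NULL,
                           bands = acceptance_bands(),
                           cf_table = conversion_factors(),
                           n_report = 1, divisor = "sqrt_n",
                           calibration = c("matrix", "solvent"),
                           seed = NULL) {
  calibration <- match.arg(calibration)
  check_long_format(data)

  has_role <- function(r) any(data$role == r)
  fits <- if (has_role("calibration")) fit_calibrations(data, bands) else NULL
  me <- if (has_role("me_solvent") && has_role("me_matrix")) {
    assess_matrix_effect(data, bands)
  } else {
    NULL
  }
  pa <- if (has_role("spike")) {
    assess_precision_accuracy(data, fits, bands, calibration = calibration)
  } else {
    NULL
  }
  limits <- if (has_role("spike")) {
    assess_detection_limits(data, fits, cf_table, n_report, divisor,
                            calibration = calibration)
  } else {
    NULL
  }
  retention <- if (!is.null(peaks)) {
    assess_retention(peaks, bands = bands,
                     rt_tol_percent = bands$rpd_max)
  } else {
    NULL
  }

  combos <- dplyr::distinct(
    dplyr::filter(data, .data$matrix != "solvent"),
    .data$analyte, .data$matrix
  )
  verdicts <- purrr::pmap_dfr(combos, function(analyte, matrix) {
    vals <- list()
    if (!is.null(fits)) {
      f <- fits[fits$analyte == analyte & fits$matrix == matrix, ]
      if (nrow(f) == 1) {
        vals$r_squared <- f$r_squared
        vals$rsd_linearity <- f$max_level_rsd
      }
    }
    if (!is.null(pa)) {
      p <- pa[pa$analyte == analyte & pa$matrix == matrix, ]
      vals$rsd_precision <- p$rsd
      vals$horrat <- p$horrat
      vals$recovery <- p$recovery
    }
    if (!is.null(me)) {
      m <- me[me$analyte == analyte & me$matrix == matrix, ]
      vals$matrix_effect <- m$me_mean
    }
    if (!is.null(retention)) {
      r <- retention[retention$analyte == analyte, ]
      vals$rpd <- r$rpd_max
    }
    dplyr::mutate(evaluate_bands(vals, bands),
                  analyte = analyte, matrix = matrix, .before = 1)
  })

  structure(
    list(
      calibration = fits,
      matrix_effect = me,
      precision_accuracy = pa,
      limits = limits,
      retention = retention,
      verdicts = verdicts,
      bands = bands,
      meta = list(
        package = "sweetval",
        version = as.character(packageVersion("sweetval")),
        seed = seed,
        calibration_mode = calibration,
        n_report = n_report,
        divisor = divisor,
        input_hash = rlang::hash(data),
        created = format(Sys.time(), tz = "UTC")
      )
    ),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Validation report\n")
  if (!is.null(x$calibration)) {
    cat(sprintf("  calibration: %d series, R^2 %.4f-%.4f\n",
                nrow(x$calibration),
                min(x$calibration$r_squared), max(x$calibration$r_squared)))
  }
  ev <- x$verdicts[!is.na(x$verdicts$pass), ]
  cat(sprintf("  criteria evaluated: %d | passed: %d | failed: %d\n",
              nrow(ev), sum(ev$pass), sum(!ev$pass)))
  if (any(!ev$pass)) {
    bad <- ev[!ev$pass, ]
    for (i in seq_len(nrow(bad))) {
      cat(sprintf("    FAIL %s / %s: %s = %.4g\n", bad$analyte[i],
                  bad$matrix[i], bad$criterion[i], bad$value[i]))
    }
  }
  invisible(x)
}

#' @export
tidy.validation_report <- function(x, ...) {
  x$verdicts
}

#' @export
glance.validation_report <- function(x, ...) {
  ev <- x$verdicts[!is.na(x$verdicts$pass), ]
  tibble::tibble(
    n_analytes = length(unique(x$verdicts$analyte)),
    n_matrices = length(unique(x$verdicts$matrix)),
    n_criteria = nrow(ev),
    n_pass = sum(ev$pass),
    n_fail = sum(!ev$pass),
    all_pass = all(ev$pass),
    r_squared_min = if (!is.null(x$calibration)) {
      min(x$calibration$r_squared[x$calibration$matrix != "solvent"])
    } else {
      NA_real_
    },
    rsd_max = if (!is.null(x$precision_accuracy)) {
      max(x$precision_accuracy$rsd, na.rm = TRUE)
    } else {
      NA_real_
    },
    horrat_max = if (!is.null(x$precision_accuracy)) {
      max(x$precision_accuracy$horrat, na.rm = TRUE)
    } else {
      NA_real_
    }
  )
}

#' Survey quantitation with quality control and censoring
#'
#' Quantifies survey sample triplicates (`role = "sample"`) against the
#' calibration fits, classifies each sample-analyte result against the
#' detection limits, substitutes censored results under the requested
#' scenario, converts to steviol equivalents and summarises per matrix (food
#' group): detected-only mean, SD, min-max and detect count, the shape of an
#' occurrence table, plus per-sample totals and triplicate QC %RSD flagged
#' against the linearity band.
#'
#' @param data Long-format table with `sample` rows (columns as in
#'   [read_observations()] plus a `sample` id column).
#' @param fits Calibration fits from [fit_calibrations()].
#' @param limits Detection limits from [assess_detection_limits()].
#' @param cf_table Conversion-factor table.
#' @param scenario Censoring scenario for totals (default `"lower"`).
#' @param bands An [acceptance_bands()] object (QC %RSD uses
#'   `rsd_linearity_max`).
#' @param calibration `"solvent"` (default, external calibration) or
#'   `"matrix"`.
#' @return List with `per_sample` (sample x analyte results), `summary`
#'   (matrix x analyte occurrence summary with `label` like
#'   `"2.08 ± 0.35 (1.83-2.32)"` or `"ND"`), and `totals` (per-sample
#'   steviol-equivalent totals under the scenario).
#' @export
run_survey <- function(data, fits, limits,
                       cf_table = conversion_factors(),
                       scenario = c("lower", "middle", "upper"),
                       bands = acceptance_bands(),
                       calibration = c("solvent", "matrix")) {
  scenario <- match.arg(scenario)
  calibration <- match.arg(calibration)
  check_long_format(data)
  samples <- dplyr::filter(data, .data$role == "sample")
  if (nrow(samples) == 0) stop_invalid("No rows with role = \"sample\".")
  if (!"sample" %in% names(samples)) {
    stop_invalid("Sample rows need a `sample` id column.")
  }

  q <- samples
  if (calibration == "solvent") q$matrix <- "solvent"
  q <- quantify(fits, q, fallback_solvent = TRUE)
  q$matrix <- samples$matrix

  per_sample <- q |>
    dplyr::group_by(.data$matrix, .data$sample, .data$analyte) |>
    dplyr::summarise(
      n_rep = dplyr::n(),
      conc_mg_per_kg = mean(.data$conc_mg_per_L),
      qc_rsd = if (dplyr::n() >= 2 && mean(.data$conc_mg_per_L) > 0) {
        rsd_percent(.data$conc_mg_per_L)
      } else {
        NA_real_
      },
      .groups = "drop"
    ) |>
    dplyr::left_join(
      dplyr::select(limits, "analyte", "matrix", "lod_mg_per_L", "loq_mg_per_L"),
      by = c("analyte", "matrix")
    ) |>
    dplyr::mutate(
      status = dplyr::case_when(
        .data$conc_mg_per_kg < .data$lod_mg_per_L ~ "below_lod",
        .data$conc_mg_per_kg < .data$loq_mg_per_L ~ "below_loq",
        TRUE ~ "detected"
      ),
      conc_substituted = substitute_censored(
        .data$conc_mg_per_kg, .data$status,
        .data$lod_mg_per_L, .data$loq_mg_per_L, scenario
      ),
      cf = cf_lookup(.data$analyte, cf_table),
      se_mg_per_kg = steviol_equivalent(pmax(.data$conc_substituted, 0), .data$cf),
      qc_pass = is.na(.data$qc_rsd) | .data$qc_rsd < bands$rsd_linearity_max
    )

  summary <- per_sample |>
    dplyr::group_by(.data$matrix, .data$analyte) |>
    dplyr::group_modify(function(df, key) {
      det <- df$se_mg_per_kg[df$status == "detected"]
      if (length(det) == 0) {
        return(tibble::tibble(
          n = 0L, mean = NA_real_, sd = NA_real_, min = NA_real_,
          max = NA_real_, label = "ND",
          qc_rsd_min = suppressWarnings(min(df$qc_rsd, na.rm = TRUE)),
          qc_rsd_max = suppressWarnings(max(df$qc_rsd, na.rm = TRUE))
        ))
      }
      s <- summarize_found(det)
      s$qc_rsd_min <- suppressWarnings(min(df$qc_rsd[df$status == "detected"],
                                           na.rm = TRUE))
      s$qc_rsd_max <- suppressWarnings(max(df$qc_rsd[df$status == "detected"],
                                           na.rm = TRUE))
      s
    }) |>
    dplyr::ungroup()

  totals <- per_sample |>
    dplyr::group_by(.data$matrix, .data$sample) |>
    dplyr::summarise(
      total_se_mg_per_kg = sum(.data$se_mg_per_kg),
      .groups = "drop"
    )

  list(per_sample = per_sample, summary = summary, totals = totals,
       scenario = scenario)
}
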