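#' Write a validation report as JSON
#'
#' Serialises a `validation_report` to JSON keyed
#' `analyte -> matrix -> criterion`, each criterion carrying its computed
#' value and verdict, with the calibration equations, per-level statistics,
#' detection limits (rounded half away from zero to 3 decimals, the reporting
#' convention for limits) and the run metadata.
#'
#' @param report A `validation_report` from [run_validation()].
#' @param path Output path; when `NULL` the JSON string is returned.
#' @return Invisibly the path, or the JSON string when `path` is `NULL`.
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "validation_report"))
  v <- report$verdicts
  by_analyte <- split(v, v$analyte)
  results <- purrr::map(by_analyte, function(va) {
    purrr::map(split(va, va$matrix), function(vm) {
      out <- purrr::map(split(vm, vm$criterion), function(row) {
        list(
          value = if (is.na(row$value)) NULL else unname(row$value),
          pass = if (is.na(row$pass)) "not evaluated" else unname(row$pass)
        )
      })
      a <- vm$analyte[1]
      m <- vm$matrix[1]
      if (!is.null(report$calibration)) {
        f <- report$calibration
        f <- f[f$analyte == a & f$matrix == m, ]
        if (nrow(f) == 1) out$calibration_equation <- f$equation
      }
      if (!is.null(report$limits)) {
        l <- report$limits
        l <- l[l$analyte == a & l$matrix == m, ]
        if (nrow(l) == 1) {
          out$lod_se_mg_per_kg <- round_half_away(l$lod_se_mg_per_kg, 3)
          out$loq_se_mg_per_kg <- round_half_away(l$loq_se_mg_per_kg, 3)
        }
      }
      out
    })
  })
  payload <- list(meta = report$meta, results = results)
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
  if (is.null(path)) {
    return(json)
  }
  writeLines(json, path)
  invisible(path)
}

# minimal pipe-table renderer (two-decimal numbers, the table convention)
md_table <- function(df, digits = 2) {
  fmt <- function(x) {
    if (is.numeric(x)) {
      ifelse(is.na(x), "-", formatC(round_half_away(x, digits),
                                    format = "f", digits = digits))
    } else {
      ifelse(is.na(x), "-", as.character(x))
    }
  }
  cells <- purrr::map(df, fmt)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  rule <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- purrr::pmap_chr(cells, function(...) {
    paste0("| ", paste(c(...), collapse = " | "), " |")
  })
  c(header, rule, body)
}

#' Render a validation report as Markdown tables
#'
#' Writes the calibration, matrix-effect, precision/accuracy and
#' detection-limit summaries as Markdown pipe tables, one section per stage,
#' mirroring the layout of conventional validation reports.
#'
#' @inheritParams report_json
#' @return Invisibly the path, or the Markdown lines when `path` is `NULL`.
#' @export
report_markdown <- function(report, path = NULL) {
  stopifnot(inherits(report, "validation_report"))
  lines <- c(
    "# Validation report",
    "",
    sprintf("Generated by %s %s (input hash %s)%s",
            report$meta$package, report$meta$version,
            report$meta$input_hash,
            if (!is.null(report$meta$seed)) {
              sprintf(", seed %s", report$meta$seed)
            } else {
              ""
            }),
    ""
  )
  add_section <- function(lines, title, df) {
    if (is.null(df)) {
      return(lines)
    }
    c(lines, sprintf("## %s", title), "", md_table(df), "")
  }
  if (!is.null(report$calibration)) {
    cal <- dplyr::select(
      report$calibration, "analyte", "matrix", "equation", "r_squared",
      "max_level_rsd", "linear"
    )
    cal$r_squared <- formatC(round_half_away(cal$r_squared, 4),
                             format = "f", digits = 4)
    lines <- add_section(lines, "Linearity", cal)
  }
  lines <- add_section(lines, "Matrix effect", report$matrix_effect)
  if (!is.null(report$precision_accuracy)) {
    pa <- dplyr::select(
      report$precision_accuracy, "analyte", "matrix", "level_mg_per_L",
      "n", "mean_conc", "rsd", "horrat", "recovery"
    )
    lines <- add_section(lines, "Precision and accuracy", pa)
  }
  if (!is.null(report$limits)) {
    lim <- dplyr::mutate(
      dplyr::select(report$limits, "analyte", "matrix",
                    "lod_se_mg_per_kg", "loq_se_mg_per_kg"),
      dplyr::across(dplyr::ends_with("mg_per_kg"), ~ round_half_away(.x, 3))
    )
    lines <- c(lines, "## Detection limits (steviol equivalents)", "",
               md_table(lim, digits = 3), "")
  }
  lines <- add_section(lines, "Retention time", report$retention)
  lines <- c(lines, "## Verdicts", "", md_table(report$verdicts), "")
  if (is.null(path)) {
    return(lines)
  }
  writeLines(lines, path)
  invisible(path)
}
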