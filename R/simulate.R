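# per-analyte detector truth: solvent-response slopes (area per mg/L) and
# intercepts (area) of plausible triple-quadrupole magnitude for this panel
default_response_truth <- function() {
  tibble::tribble(
    ~analyte,          ~slope, ~intercept,
    "Rebaudioside A",  79846,  3076.40,
    "Rebaudioside B",  23115,  1642.30,
    "Rebaudioside C",  79357,  4082.30,
    "Rebaudioside D",  26518,  1389.70,
    "Rebaudioside F",  76473,  4149.00,
    "Rubusoside",      29488,  1149.00,
    "Dulcoside A",     22672,  2313.80,
    "Stevioside",      48117,  4517.90,
    "Steviolbioside",  32307,  3114.20
  )
}

#' Configuration of the synthetic instrument-data generator
#'
#' Describes a single-laboratory validation design: nine analytes monitored
#' in three food matrices, six-level calibration in triplicate, three spike
#' levels with seven replicates, seven-replicate matrix-effect pairs, and a
#' linear detector with proportional (constant-CV) noise. The generative
#' model is
#' \deqn{A = f_{ME} \cdot (a \cdot c \cdot f_{rec} + b)(1 + \epsilon),
#'   \quad \epsilon \sim N(0, CV),}
#' where the matrix-effect factor \eqn{f_{ME}} multiplies the whole detector
#' signal (ionization suppression/enhancement acts on the signal) and the
#' recovery factor \eqn{f_{rec}} scales the analyte amount reaching the
#' detector (extraction loss acts on the analyte). Solvent responses carry
#' neither factor; matrix-effect spikes are post-extraction additions and
#' carry only \eqn{f_{ME}}; blanks are the same model at zero concentration.
#' Retention times jitter around the transition-table reference by
#' `rt_jitter_sd` minutes.
#'
#' @param seed Integer RNG seed; a fixed seed makes the output byte-identical.
#' @param analytes Character vector (default: the nine-glycoside panel).
#' @param matrices Character vector of sample matrices.
#' @param calibration_levels Calibration concentrations in mg/L.
#' @param spike_levels Spike concentrations in mg/L.
#' @param calibration_replicates Replicate injections per calibration level.
#' @param spike_replicates Replicates per spike level (default 7).
#' @param me_replicates Replicates per matrix-effect level (default 7).
#' @param response_truth Tibble `analyte`, `slope`, `intercept` of true
#'   solvent detector response.
#' @param me_factor Named per-matrix multiplicative matrix-effect factor
#'   (0.85 = 15% suppression).
#' @param recovery_factor Named per-matrix multiplicative recovery factor.
#' @param noise_cv Proportional noise coefficient of variation (default 0.03).
#' @param noise_floor_sd Additive area-noise SD (default 0), for detection-
#'   limit realism near zero signal.
#' @param rt_jitter_sd Retention-time jitter SD in minutes (default 0.01).
#' @param n_samples Survey samples to simulate per matrix (default 0).
#' @param sample_truth Optional tibble `matrix`, `sample`, `analyte`,
#'   `true_mg_per_kg` fixing the survey truth; when `NULL` and
#'   `n_samples > 0` a truth table is drawn from the seed.
#' @return A `sim_config` object (named list).
#' @export
#' @examples
#' sim_config(seed = 1)
sim_config <- function(seed = 1L,
                       analytes = default_response_truth()$analyte,
                       matrices = c("beverage", "yogurt", "snack"),
                       calibration_levels = c(0.2, 0.3, 0.4, 0.5, 0.8, 1.0),
                       spike_levels = c(0.2, 0.5, 1.0),
                       calibration_replicates = 3L,
                       spike_replicates = 7L,
                       me_replicates = 7L,
                       response_truth = default_response_truth(),
                       me_factor = c(beverage = 1.03, yogurt = 0.88, snack = 1.00),
                       recovery_factor = c(beverage = 0.99, yogurt = 0.87, snack = 0.98),
                       noise_cv = 0.03,
                       noise_floor_sd = 0,
                       rt_jitter_sd = 0.01,
                       n_samples = 0L,
                       sample_truth = NULL) {
  cfg_error <- function(msg) abort(msg, class = "sweetval_config_error")
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    cfg_error("`seed` must be a single integer.")
  }
  if (length(analytes) < 1 || length(matrices) < 1) {
    cfg_error("At least one analyte and one matrix are required.")
  }
  if (!all(analytes %in% response_truth$analyte)) {
    cfg_error("`response_truth` must cover every analyte.")
  }
  if (any(calibration_levels <= 0) || any(spike_levels <= 0)) {
    cfg_error("Concentration levels must be > 0.")
  }
  me_factor <- me_factor[matrices]
  recovery_factor <- recovery_factor[matrices]
  if (anyNA(me_factor) || any(me_factor <= 0)) {
    cfg_error("`me_factor` must name every matrix with a positive factor.")
  }
  if (anyNA(recovery_factor) || any(recovery_factor <= 0)) {
    cfg_error("`recovery_factor` must name every matrix with a positive factor.")
  }
  if (noise_cv < 0 || noise_floor_sd < 0 || rt_jitter_sd < 0) {
    cfg_error("Noise parameters must be non-negative.")
  }
  structure(
    list(
      seed = as.integer(seed),
      analytes = analytes,
      matrices = matrices,
      calibration_levels = calibration_levels,
      spike_levels = spike_levels,
      calibration_replicates = as.integer(calibration_replicates),
      spike_replicates = as.integer(spike_replicates),
      me_replicates = as.integer(me_replicates),
      response_truth = response_truth[match(analytes, response_truth$analyte), ],
      me_factor = me_factor,
      recovery_factor = recovery_factor,
      noise_cv = noise_cv,
      noise_floor_sd = noise_floor_sd,
      rt_jitter_sd = rt_jitter_sd,
      n_samples = as.integer(n_samples),
      sample_truth = sample_truth
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic validation design\n")
  cat(sprintf("  seed %d | %d analytes x %d matrices\n",
              x$seed, length(x$analytes), length(x$matrices)))
  cat(sprintf("  calibration %s mg/L x %d | spikes %s mg/L x %d | ME x %d\n",
              paste(x$calibration_levels, collapse = "/"), x$calibration_replicates,
              paste(x$spike_levels, collapse = "/"), x$spike_replicates,
              x$me_replicates))
  cat(sprintf("  noise CV %.3g | RT jitter SD %.3g min\n", x$noise_cv, x$rt_jitter_sd))
  invisible(x)
}

# one draw of the detector model; vectorized over conc
sim_response <- function(conc, slope, intercept, me = 1, rec = 1,
                         noise_cv = 0, noise_floor_sd = 0) {
  mu <- me * (slope * conc * rec + intercept)
  eps <- if (noise_cv > 0) rnorm(length(mu), 0, noise_cv) else 0
  floor_noise <- if (noise_floor_sd > 0) rnorm(length(mu), 0, noise_floor_sd) else 0
  mu * (1 + eps) + floor_noise
}

#' Simulate the long-format validation observation table
#'
#' Draws a complete validation experiment from a [sim_config()]: solvent and
#' matrix-matched calibration series, matrix-effect solvent/matrix pairs,
#' spiked-blank replicates, blanks, and (when `n_samples > 0`) survey sample
#' triplicates. Output is deterministic for a fixed seed.
#'
#' @param config A [sim_config()] object.
#' @return A tibble in the long observation format: `analyte`, `matrix`,
#'   `role` (`calibration`, `spike`, `blank`, `me_solvent`, `me_matrix`,
#'   `sample`), `level_mg_per_L`, `replicate`, `value`, `value_unit`
#'   (all responses are areas), plus `sample` (survey sample id, NA
#'   elsewhere).
#' @export
#' @examples
#' head(simulate_validation_data(sim_config(seed = 7)))
simulate_validation_data <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    rows <- list()
    truth <- config$response_truth

    grid_cal <- tidyr::expand_grid(
      analyte = config$analytes,
      matrix = c("solvent", config$matrices),
      level_mg_per_L = config$calibration_levels,
      replicate = seq_len(config$calibration_replicates)
    )
    grid_me <- tidyr::expand_grid(
      analyte = config$analytes,
      matrix = config$matrices,
      level_mg_per_L = config$spike_levels,
      replicate = seq_len(config$me_replicates)
    )
    grid_spike <- tidyr::expand_grid(
      analyte = config$analytes,
      matrix = config$matrices,
      level_mg_per_L = config$spike_levels,
      replicate = seq_len(config$spike_replicates)
    )
    grid_blank <- tidyr::expand_grid(
      analyte = config$analytes,
      matrix = config$matrices,
      level_mg_per_L = 0,
      replicate = seq_len(config$spike_replicates)
    )

    lookup <- function(grid, what) {
      i <- match(grid$analyte, truth$analyte)
      if (what %in% c("slope", "intercept")) {
        return(truth[[what]][i])
      }
      fac <- config[[what]]
      out <- rep(1, nrow(grid))
      in_matrix <- grid$matrix %in% names(fac)
      out[in_matrix] <- fac[grid$matrix[in_matrix]]
      out
    }

    emit <- function(grid, role, me = TRUE, rec = FALSE) {
      grid$role <- role
      grid$value <- sim_response(
        grid$level_mg_per_L,
        slope = lookup(grid, "slope"),
        intercept = lookup(grid, "intercept"),
        me = if (me) lookup(grid, "me_factor") else 1,
        rec = if (rec) lookup(grid, "recovery_factor") else 1,
        noise_cv = config$noise_cv,
        noise_floor_sd = config$noise_floor_sd
      )
      grid
    }

    rows$calibration <- emit(grid_cal, "calibration")
    rows$me_solvent <- emit(
      dplyr::mutate(grid_me, matrix = "solvent") |> dplyr::distinct(),
      "me_solvent"
    )
    rows$me_matrix <- emit(grid_me, "me_matrix")
    rows$spike <- emit(grid_spike, "spike", rec = TRUE)
    rows$blank <- emit(grid_blank, "blank", rec = TRUE)

    if (config$n_samples > 0 || !is.null(config$sample_truth)) {
      st <- config$sample_truth %||% draw_sample_truth(config)
      grid_sample <- tidyr::expand_grid(st, replicate = 1:3)
      grid_sample$level_mg_per_L <- grid_sample$true_mg_per_kg
      sample_ids <- grid_sample$sample
      grid_sample <- emit(
        grid_sample[, c("analyte", "matrix", "level_mg_per_L", "replicate")],
        "sample", rec = TRUE
      )
      grid_sample$sample <- sample_ids
      rows$sample <- grid_sample
    }

    out <- dplyr::bind_rows(rows)
    if (!"sample" %in% names(out)) out$sample <- NA_character_
    tibble::as_tibble(out) |>
      dplyr::mutate(value_unit = "area") |>
      dplyr::select(
        "analyte", "matrix", "role", "level_mg_per_L", "replicate",
        "value", "value_unit", "sample"
      ) |>
      dplyr::arrange(.data$role, .data$analyte, .data$matrix,
                     .data$level_mg_per_L, .data$replicate)
  })
}

# survey truth: the major glycosides appear often, minor ones rarely;
# levels are log-normal around tens of mg/kg, as in commercial products
draw_sample_truth <- function(config) {
  present_prob <- c(
    "Rebaudioside A" = 1, "Stevioside" = 0.6, "Rebaudioside B" = 0.4
  )
  grid <- tidyr::expand_grid(
    matrix = config$matrices,
    sample = sprintf("S%02d", seq_len(max(config$n_samples, 1L))),
    analyte = config$analytes
  )
  p <- present_prob[grid$analyte]
  p[is.na(p)] <- 0.15
  present <- stats::runif(nrow(grid)) < p
  grid$true_mg_per_kg <- ifelse(
    present, exp(rnorm(nrow(grid), mean = log(20), sd = 1)), 0
  )
  grid[, c("matrix", "sample", "analyte", "true_mg_per_kg")]
}

#' Simulate an SRM peak list
#'
#' One quantifier and one qualifier peak per analyte per sample, with a
#' shared retention-time jitter per chromatographic peak, plus optional decoy
#' peaks at m/z values no transition matches. Exercises the peak-assignment
#' stage.
#'
#' @param config A [sim_config()] (supplies analytes, response truth, noise
#'   and jitter).
#' @param transitions Transition table for the monitored panel.
#' @param n_samples Number of samples (default 3).
#' @param conc_mg_per_L Concentration driving the simulated areas
#'   (default 0.5).
#' @param n_decoys Decoy peaks per sample at unmatched m/z (default 0).
#' @param analytes_present Analytes detected in each sample (default: all in
#'   `config`).
#' @return Tibble: `sample`, `precursor_mz`, `product_mz`, `rt_min`, `area`.
#' @export
simulate_peak_list <- function(config, transitions = srm_transitions(),
                               n_samples = 3, conc_mg_per_L = 0.5,
                               n_decoys = 0,
                               analytes_present = config$analytes) {
  stopifnot(inherits(config, "sim_config"))
  tr <- transitions[transitions$analyte %in% analytes_present, , drop = FALSE]
  withr::with_seed(config$seed + 104729L, { # offset stream from the tables
    out <- purrr::map_dfr(seq_len(n_samples), function(s) {
      i <- match(tr$analyte, config$response_truth$analyte)
      slope <- config$response_truth$slope[i]
      intercept <- config$response_truth$intercept[i]
      slope[is.na(slope)] <- 5e4
      intercept[is.na(intercept)] <- 2e3
      area_q <- sim_response(conc_mg_per_L, slope, intercept,
                             noise_cv = config$noise_cv)
      rt <- tr$reference_rt_min +
        if (config$rt_jitter_sd > 0) rnorm(nrow(tr), 0, config$rt_jitter_sd) else 0
      real <- dplyr::bind_rows(
        tibble::tibble(
          sample = sprintf("S%02d", s),
          precursor_mz = tr$precursor_mz, product_mz = tr$quantifier_mz,
          rt_min = rt, area = area_q
        ),
        tibble::tibble(
          sample = sprintf("S%02d", s),
          precursor_mz = tr$precursor_mz, product_mz = tr$qualifier1_mz,
          rt_min = rt, area = 0.3 * area_q
        )
      )
      if (n_decoys > 0) {
        real <- dplyr::bind_rows(real, tibble::tibble(
          sample = sprintf("S%02d", s),
          precursor_mz = 430 + 17 * seq_len(n_decoys) + 0.111,
          product_mz = 210 + 11 * seq_len(n_decoys) + 0.077,
          rt_min = stats::runif(n_decoys, 1, 12),
          area = stats::runif(n_decoys, 1e3, 1e5)
        ))
      }
      real
    })
    dplyr::arrange(out, .data$sample, .data$precursor_mz, .data$product_mz)
  })
}

#' Write simulated tables to a directory
#'
#' Writes `observations.csv` (long-format validation table) and
#' `peaks.csv` (SRM peak list) as consumed by the rest of the pipeline.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param peaks Also write a peak list (default TRUE).
#' @return Invisibly, the paths written.
#' @export
write_simulated_dataset <- function(config, dir, peaks = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  obs_path <- file.path(dir, "observations.csv")
  readr::write_csv(simulate_validation_data(config), obs_path, progress = FALSE)
  paths <- obs_path
  if (peaks) {
    peak_path <- file.path(dir, "peaks.csv")
    readr::write_csv(simulate_peak_list(config), peak_path, progress = FALSE)
    paths <- c(paths, peak_path)
  }
  invisible(paths)
}
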