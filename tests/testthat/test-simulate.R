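test_that("a fixed seed reproduces the dataset byte for byte", {
  cfg <- sim_config(seed = 123, n_samples = 2)
  d1 <- simulate_validation_data(cfg)
  d2 <- simulate_validation_data(cfg)
  expect_identical(d1, d2)
  p1 <- simulate_peak_list(cfg)
  p2 <- simulate_peak_list(cfg)
  expect_identical(p1, p2)
  # and written CSVs are byte-identical
  f1 <- withr::local_tempdir()
  f2 <- withr::local_tempdir()
  write_simulated_dataset(cfg, f1)
  write_simulated_dataset(cfg, f2)
  expect_identical(
    readLines(file.path(f1, "observations.csv")),
    readLines(file.path(f2, "observations.csv"))
  )
  d3 <- simulate_validation_data(sim_config(seed = 124, n_samples = 2))
  expect_false(identical(d1$value, d3$value))
})

test_that("the design grid matches the configured study layout", {
  cfg <- sim_config(seed = 1)
  d <- simulate_validation_data(cfg)
  counts <- table(d$role)
  expect_equal(unname(counts[["calibration"]]), 9 * 4 * 6 * 3)
  expect_equal(unname(counts[["spike"]]), 9 * 3 * 3 * 7)
  expect_equal(unname(counts[["me_matrix"]]), 9 * 3 * 3 * 7)
  expect_equal(unname(counts[["me_solvent"]]), 9 * 3 * 7)
  expect_equal(unname(counts[["blank"]]), 9 * 3 * 7)
})

test_that("the noiseless limit reproduces the generative identities exactly", {
  d <- simulate_validation_data(noiseless_config())
  fits <- fit_calibrations(d)
  expect_true(all(abs(fits$r_squared - 1) < 1e-12))
  pa <- assess_precision_accuracy(d, fits)
  expect_equal(pa$recovery, rep(100, nrow(pa)), tolerance = 1e-9)
  expect_equal(pa$rsd, rep(0, nrow(pa)), tolerance = 1e-9)
  me <- assess_matrix_effect(d)
  expect_equal(me$me_mean, rep(100, nrow(me)), tolerance = 1e-9)
})

test_that("matrix-effect and recovery factors propagate to the estimators", {
  est <- vapply(1:20, function(s) {
    cfg <- small_config(seed = s, me = 0.8, rec = 0.9)
    d <- simulate_validation_data(cfg)
    fits <- fit_calibrations(d)
    c(
      me = mean(assess_matrix_effect(d)$me_mean),
      rec = mean(assess_precision_accuracy(d, fits)$recovery)
    )
  }, numeric(2))
  expect_equal(mean(est["me", ]), 80, tolerance = 0.02)
  expect_equal(mean(est["rec", ]), 90, tolerance = 0.03)
})

test_that("doubling the noise CV doubles the estimated LOD in expectation", {
  ratio <- vapply(1:40, function(s) {
    lod_at <- function(cv) {
      cfg <- small_config(seed = s, noise_cv = cv)
      d <- simulate_validation_data(cfg)
      fits <- fit_calibrations(d)
      assess_detection_limits(d, fits)$lod_mg_per_L
    }
    lod_at(0.06) / lod_at(0.03)
  }, numeric(1))
  expect_gte(mean(ratio), 1.8)
  expect_lte(mean(ratio), 2.2)
})

test_that("invalid generator configurations are rejected as such", {
  expect_error(sim_config(me_factor = c(beverage = -1)),
               class = "sweetval_config_error")
  expect_error(sim_config(noise_cv = -0.1), class = "sweetval_config_error")
  expect_error(sim_config(analytes = "Unknown compound"),
               class = "sweetval_config_error")
  expect_error(sim_config(calibration_levels = c(0, 0.5)),
               class = "sweetval_config_error")
})

test_that("survey samples are emitted in triplicate with fixed truth", {
  truth <- tibble::tibble(
    matrix = "beverage", sample = c("S01", "S01", "S02"),
    analyte = c("Rebaudioside A", "Stevioside", "Rebaudioside A"),
    true_mg_per_kg = c(50, 10, 0)
  )
  cfg <- sim_config(seed = 5, sample_truth = truth)
  d <- simulate_validation_data(cfg)
  s <- d[d$role == "sample", ]
  expect_equal(nrow(s), 9)
  expect_equal(sort(unique(s$sample)), c("S01", "S02"))
  expect_true(all(table(s$sample, s$analyte) %in% c(0, 3)))
})
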