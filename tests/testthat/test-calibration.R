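make_series <- function(levels = c(0.2, 0.3, 0.4, 0.5, 0.8, 1.0),
                        reps = 3, slope = 2, intercept = 1, noise_cv = 0) {
  d <- expand.grid(level = levels, rep = seq_len(reps))
  mu <- slope * d$level + intercept
  d$response <- mu * (1 + if (noise_cv > 0) rnorm(nrow(d), 0, noise_cv) else 0)
  d[, c("level", "response")]
}

test_that("a noiseless line is recovered exactly with R-squared of one", {
  fit <- fit_calibration(make_series())
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r_squared, 1)
  expect_true(fit$linear)
  expect_equal(fit$level_rsd$rsd, rep(0, 6))
})

test_that("constant responses give zero slope and zero R-squared", {
  d <- make_series(slope = 0, intercept = 5)
  fit <- fit_calibration(d)
  expect_equal(fit$slope, 0)
  expect_equal(fit$r_squared, 0)
  expect_false(fit$linear)
})

test_that("OLS equals the closed-form normal-equation solution", {
  set.seed(11)
  for (i in 1:10) {
    d <- make_series(slope = stats::runif(1, 1e3, 1e5),
                     intercept = stats::runif(1, 0, 5e3),
                     noise_cv = 0.05)
    fit <- fit_calibration(d)
    ora <- oracle_ols(d$level, d$response)
    expect_equal(fit$slope, ora$slope, tolerance = 1e-12)
    expect_equal(fit$intercept, ora$intercept, tolerance = 1e-10)
    expect_equal(fit$r_squared, ora$r_squared, tolerance = 1e-12)
  }
})

test_that("back-calculation inverts the line and round-trips to 1e-9", {
  fit <- list(slope = 2, intercept = 1)
  expect_equal(back_calculate(fit, 5), 2)
  expect_equal(back_calculate(fit, 1), 0)
  set.seed(5)
  f <- fit_calibration(make_series(slope = 79846, intercept = 3076.4,
                                   noise_cv = 0.02))
  for (conc in stats::runif(20, 0.01, 2)) {
    resp <- f$slope * conc + f$intercept
    expect_equal(back_calculate(f, resp), conc, tolerance = 1e-9)
  }
  expect_error(back_calculate(list(slope = 0, intercept = 1), 5),
               class = "sweetval_invalid_input")
})

test_that("negative back-calculated concentrations pass through for censoring", {
  fit <- list(slope = 2, intercept = 10)
  expect_lt(back_calculate(fit, 5), 0)
})

test_that("a noisy series recovers the true slope within 2%", {
  set.seed(101)
  d <- make_series(slope = 79846, intercept = 3076.4, noise_cv = 0.01)
  fit <- fit_calibration(d)
  expect_lt(abs(fit$slope - 79846) / 79846, 0.02)
  expect_gt(fit$r_squared, 0.99)
})

test_that("R-squared degrades as injected noise grows (in expectation)", {
  set.seed(202)
  r2_at <- function(cv) {
    mean(replicate(40, fit_calibration(
      make_series(slope = 5e4, intercept = 2e3, noise_cv = cv)
    )$r_squared))
  }
  expect_gt(r2_at(0.01), r2_at(0.05))
  expect_gt(r2_at(0.05), r2_at(0.15))
})

test_that("degenerate calibration inputs are rejected", {
  expect_error(fit_calibration(data.frame(level = c(1, 1, 1), response = 1:3)),
               class = "sweetval_invalid_input")
  expect_error(fit_calibration(data.frame(level = c(0.5, 1), response = 1:2)),
               class = "sweetval_invalid_input")
  expect_error(fit_calibration(data.frame(level = c(-1, 1, 2), response = 1:3)),
               class = "sweetval_invalid_input")
})

test_that("fit_calibrations fits each analyte-by-matrix series of a long table", {
  d <- simulate_validation_data(noiseless_config())
  fits <- fit_calibrations(d)
  expect_equal(nrow(fits), 9 * 4) # solvent + three matrices
  expect_true(all(abs(fits$r_squared - 1) < 1e-12))
  truth <- sweetval:::default_response_truth()
  reba <- fits[fits$analyte == "Rebaudioside A" & fits$matrix == "solvent", ]
  expect_equal(reba$slope, truth$slope[truth$analyte == "Rebaudioside A"])
  # tidy()/glance() expose coefficients and fit quality
  f1 <- fits$fit[[1]]
  expect_equal(tidy(f1)$estimate, c(f1$intercept, f1$slope))
  expect_equal(glance(f1)$r_squared, f1$r_squared)
})

test_that("quantify back-calculates against the matching matrix fit", {
  d <- simulate_validation_data(noiseless_config())
  fits <- fit_calibrations(d)
  spikes <- d[d$role == "spike", ]
  q <- quantify(fits, spikes)
  expect_equal(q$conc_mg_per_L, spikes$level_mg_per_L, tolerance = 1e-9)
})
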