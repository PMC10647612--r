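test_that("retention-time RPD matches hand arithmetic, is symmetric and scale-free", {
  expect_equal(rpd_percent(5.214, 5.214), 0)
  expect_equal(rpd_percent(5.0, 4.9), 0.1 / 4.95 * 100)
  expect_equal(rpd_percent(4.9, 5.0), rpd_percent(5.0, 4.9))
  # invariant to a common change of time units
  expect_equal(rpd_percent(5.0 * 60, 4.9 * 60), rpd_percent(5.0, 4.9))
  expect_error(rpd_percent(0, 5), class = "sweetval_invalid_input")
  expect_error(rpd_percent(5, -1), class = "sweetval_invalid_input")
})

test_that("%RSD uses the sample SD and is invariant under positive scaling", {
  expect_equal(rsd_percent(c(0.5, 0.5, 0.5)), 0)
  expect_equal(rsd_percent(c(1, 2, 3)), 50) # SD 1, mean 2
  set.seed(42)
  for (i in 1:10) {
    x <- stats::runif(5, 1, 10)
    k <- stats::runif(1, 0.1, 100)
    expect_equal(rsd_percent(k * x), rsd_percent(x))
  }
  expect_error(rsd_percent(1), class = "sweetval_invalid_input")
  expect_error(rsd_percent(c(-1, 1)), class = "sweetval_invalid_input")
})

test_that("Horwitz PRSD has its closed forms and decreases with concentration", {
  expect_equal(horwitz_prsd(1), 2)
  expect_equal(horwitz_prsd(0.01), 4)
  expect_equal(horwitz_prsd(1e-4), 8)
  expect_equal(horwitz_prsd(2e-7), 2^(1 - 0.5 * log10(2e-7)))
  expect_equal(round(horwitz_prsd(mass_fraction(0.2)), 2), 20.39)
  cs <- sort(stats::runif(20, 1e-9, 1))
  expect_true(all(diff(horwitz_prsd(cs)) < 0))
  expect_error(horwitz_prsd(0), class = "sweetval_invalid_input")
  expect_error(horwitz_prsd(1.5), class = "sweetval_invalid_input")
})

test_that("HorRat is observed over predicted RSD", {
  expect_equal(horrat(4, 0.01), 1)
  expect_equal(horrat(0, 0.5), 0)
  expect_equal(round(horrat(8.10, 2e-7), 3), round(8.10 / horwitz_prsd(2e-7), 3))
  expect_error(horrat(-1, 0.01), class = "sweetval_invalid_input")
})

test_that("recovery follows the blank-corrected spike equation", {
  expect_equal(recovery_percent(0.19, 0.2), 95)
  expect_equal(recovery_percent(0.02, 0.2, blank_mean = 0.02), 0)
  expect_equal(recovery_percent(0.22, 0.2, blank_mean = 0.02), 100)
  expect_error(recovery_percent(0.19, 0), class = "sweetval_invalid_input")
})

test_that("absolute matrix effect is the percent signal ratio", {
  expect_equal(matrix_effect_percent(100, 100), 100)
  expect_equal(matrix_effect_percent(80, 100), 80)
  expect_error(matrix_effect_percent(80, 0), class = "sweetval_invalid_input")
  # an enhancement value observed above the 80-120 band must fail it
  verdict <- evaluate_bands(list(matrix_effect = 125.14), acceptance_bands())
  expect_false(verdict$pass[verdict$criterion == "matrix_effect"])
})

test_that("LOD/LOQ derive from the low-level replicate SD with the 10/3 ratio", {
  expect_equal(lod_loq(c(1, 1, 1))$lod, 0)
  lim <- lod_loq(c(0.18, 0.20, 0.22), n_report = 1)
  expect_equal(lim$lod, 3 * sd(c(0.18, 0.20, 0.22)))
  expect_equal(lim$loq / lim$lod, 10 / 3)
  # sqrt(n) reduction and the plain-n variant
  lim4 <- lod_loq(c(0.18, 0.20, 0.22), n_report = 4)
  expect_equal(lim4$lod, lim$lod / 2)
  limn <- lod_loq(c(0.18, 0.20, 0.22), n_report = 4, divisor = "n")
  expect_equal(limn$lod, lim$lod / 4)
  expect_error(lod_loq(0.2), class = "sweetval_invalid_input")
})

test_that("censored substitution maps statuses to 0 / half-limit / limit", {
  expect_equal(substitute_censored(NA, "below_lod", 0.06, 0.2, "lower"), 0)
  expect_equal(substitute_censored(NA, "below_lod", 0.06, 0.2, "middle"), 0.03)
  expect_equal(substitute_censored(NA, "below_lod", 0.06, 0.2, "upper"), 0.06)
  expect_equal(substitute_censored(NA, "below_loq", 0.06, 0.2, "upper"), 0.2)
  expect_equal(substitute_censored(5.3, "detected", 0.06, 0.2, "lower"), 5.3)
  # scenario ordering holds for random limits
  set.seed(7)
  for (i in 1:20) {
    lod <- stats::runif(1, 0, 1)
    loq <- lod * 10 / 3
    st <- sample(c("below_lod", "below_loq"), 1)
    vals <- vapply(
      c("lower", "middle", "upper"),
      function(s) substitute_censored(NA, st, lod, loq, s),
      numeric(1)
    )
    expect_true(all(diff(vals) >= 0))
  }
  expect_error(substitute_censored(NA, "below_lod", 0.3, 0.2, "lower"),
               class = "sweetval_invalid_input")
  expect_error(substitute_censored(NA, "nonsense", 0.06, 0.2, "lower"),
               class = "sweetval_invalid_input")
})

test_that("detected-result summaries reproduce occurrence-table arithmetic", {
  s <- summarize_found(c(1.83, 2.32))
  expect_equal(s$mean, 2.08) # 2.075 rounded half away from zero
  expect_equal(s$min, 1.83)
  expect_equal(s$max, 2.32)
  expect_equal(s$n, 2L)
  s3 <- summarize_found(c(1.64, 15.95))
  expect_equal(s3$mean, 8.80)
  s1 <- summarize_found(4.2)
  expect_true(is.na(s1$sd))
  expect_equal(s1$label, "4.20 (4.20)")
  expect_error(summarize_found(numeric(0)), class = "sweetval_invalid_input")
})

test_that("rounding is half away from zero", {
  expect_equal(round_half_away(2.075, 2), 2.08)
  expect_equal(round_half_away(-2.075, 2), -2.08)
  expect_equal(round_half_away(0.0605, 3), 0.061)
})

test_that("band evaluation returns deterministic verdicts and flags gaps", {
  b <- acceptance_bands()
  v <- evaluate_bands(
    list(matrix_effect = 100, recovery = 65, horrat = 0.48),
    b
  )
  expect_true(v$pass[v$criterion == "matrix_effect"])
  expect_false(v$pass[v$criterion == "recovery"])
  expect_equal(v$value[v$criterion == "recovery"], 65)
  expect_true(v$pass[v$criterion == "horrat"])
  expect_true(is.na(v$pass[v$criterion == "r_squared"])) # not evaluated
  # the worst value decides a multi-level criterion
  v2 <- evaluate_bands(list(recovery = c(95, 119, 71)), b)
  expect_true(v2$pass[v2$criterion == "recovery"])
  v3 <- evaluate_bands(list(recovery = c(95, 121, 71)), b)
  expect_false(v3$pass[v3$criterion == "recovery"])
  expect_equal(v3$value[v3$criterion == "recovery"], 121)
})
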