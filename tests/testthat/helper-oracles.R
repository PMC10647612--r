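# first-principles oracles: explicit-sum recomputations kept deliberately
# independent of the package's implementation paths

oracle_mean <- function(x) {
  s <- 0
  for (v in x) s <- s + v
  s / length(x)
}

oracle_sd <- function(x) {
  m <- oracle_mean(x)
  ss <- 0
  for (v in x) ss <- ss + (v - m)^2
  sqrt(ss / (length(x) - 1))
}

oracle_rsd <- function(x) 100 * oracle_sd(x) / oracle_mean(x)

oracle_rpd <- function(a, b) {
  hi <- max(a, b)
  lo <- min(a, b)
  (hi - lo) / ((hi + lo) / 2) * 100
}

oracle_prsd <- function(c_frac) 2^(1 - 0.5 * (log(c_frac) / log(10)))

oracle_recovery <- function(x, spike, blank = 0) {
  (oracle_mean(x) - blank) / spike * 100
}

oracle_me <- function(a_matrix, a_solvent) a_matrix / a_solvent * 100

oracle_lod_loq <- function(x, n_report = 1) {
  s0p <- oracle_sd(x) / sqrt(n_report)
  c(lod = 3 * s0p, loq = 10 * s0p)
}

# closed-form normal equations for simple OLS with intercept
oracle_ols <- function(x, y) {
  n <- length(x)
  sx <- 0; sy <- 0; sxx <- 0; sxy <- 0
  for (i in seq_len(n)) {
    sx <- sx + x[i]; sy <- sy + y[i]
    sxx <- sxx + x[i]^2; sxy <- sxy + x[i] * y[i]
  }
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  sse <- 0; sst <- 0; ybar <- sy / n
  for (i in seq_len(n)) {
    sse <- sse + (y[i] - intercept - slope * x[i])^2
    sst <- sst + (y[i] - ybar)^2
  }
  list(slope = slope, intercept = intercept, r_squared = 1 - sse / sst)
}

# a reduced one-analyte design for simulation-heavy property tests
small_config <- function(seed, me = 1, rec = 1, noise_cv = 0.03, ...) {
  sim_config(
    seed = seed,
    analytes = "Rebaudioside A",
    matrices = "beverage",
    me_factor = c(beverage = me),
    recovery_factor = c(beverage = rec),
    noise_cv = noise_cv,
    ...
  )
}

noiseless_config <- function(seed = 1, ...) {
  sim_config(
    seed = seed, noise_cv = 0, rt_jitter_sd = 0,
    me_factor = c(beverage = 1, yogurt = 1, snack = 1),
    recovery_factor = c(beverage = 1, yogurt = 1, snack = 1),
    ...
  )
}
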