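tab <- srm_transitions()

peak <- function(prec, prod, rt, sample = "S01", area = 1e4) {
  data.frame(sample = sample, precursor_mz = prec, product_mz = prod,
             rt_min = rt, area = area)
}

test_that("the transition table carries the nine-glycoside panel", {
  expect_equal(nrow(tab), 9)
  expect_true(all(tab$precursor_mz >
                    pmax(tab$quantifier_mz, tab$qualifier1_mz, tab$qualifier2_mz)))
  expect_setequal(
    tab$analyte[tab$precursor_mz == 803.458],
    c("Rebaudioside B", "Stevioside")
  ) # the isobaric pair separated by RT
})

test_that("a quantifier peak at the reference coordinates is assigned", {
  hit <- match_peaks(peak(965.5, 803.45, 4.856), tab)
  expect_equal(hit$analyte, "Rebaudioside A")
  expect_equal(hit$transition, "quantifier")
  expect_equal(hit$rt_rpd, 0)
})

test_that("peaks with no transition within tolerance stay unassigned", {
  hit <- match_peaks(peak(500.0, 300.0, 5.0), tab, mz_tol = 0.5)
  expect_true(is.na(hit$analyte))
})

test_that("isobaric precursors are resolved by retention time", {
  # 803.458 -> 641.x is shared (within 0.5 m/z) between stevioside (RT 4.895)
  # and rebaudioside B (RT 6.347): RT must decide
  hit_b <- match_peaks(peak(803.458, 641.29, 6.30), tab)
  expect_equal(hit_b$analyte, "Rebaudioside B")
  hit_s <- match_peaks(peak(803.458, 641.39, 4.90), tab)
  expect_equal(hit_s$analyte, "Stevioside")
  # at rebaudioside B's RT, stevioside's window (RPD ~26%) cannot capture it
  expect_gt(rpd_percent(6.30, 4.895), 5)
  expect_lt(rpd_percent(6.30, 6.347), 5)
})

test_that("assignment is deterministic and independent of peak order", {
  cfg <- noiseless_config()
  peaks <- simulate_peak_list(cfg, n_samples = 2, n_decoys = 3)
  a1 <- match_peaks(peaks, tab)
  shuffled <- peaks[rev(seq_len(nrow(peaks))), ]
  a2 <- match_peaks(shuffled, tab)
  a2 <- a2[rev(seq_len(nrow(a2))), ]
  expect_equal(a1$analyte, a2$analyte)
  expect_equal(a1$transition, a2$transition)
})

test_that("shrinking tolerances never adds assignments", {
  cfg <- small_config(seed = 9, noise_cv = 0.05, rt_jitter_sd = 0.15)
  cfg$analytes <- tab$analyte
  peaks <- simulate_peak_list(cfg, n_samples = 3, n_decoys = 4)
  n_assigned <- function(mz_tol, rt_tol) {
    sum(!is.na(match_peaks(peaks, tab, mz_tol, rt_tol)$analyte))
  }
  wide <- n_assigned(0.5, 5)
  expect_lte(n_assigned(0.2, 5), wide)
  expect_lte(n_assigned(0.5, 1), wide)
  expect_lte(n_assigned(0.05, 0.2), min(n_assigned(0.2, 5), n_assigned(0.5, 1)))
})

test_that("jitter-free synthetic peaks give full recall and no isobar crossover", {
  cfg <- noiseless_config()
  peaks <- simulate_peak_list(cfg, n_samples = 3)
  assigned <- match_peaks(peaks, tab)
  expect_true(all(!is.na(assigned$analyte)))
  conf <- confirm_identities(assigned)
  expect_equal(nrow(conf), 3 * 9)
  expect_true(all(conf$confirmed))
  # stevioside and rebaudioside B each confirmed independently, never swapped
  iso <- assigned[assigned$precursor_mz == 803.458 & assigned$transition == "quantifier", ]
  expect_equal(
    sort(unique(iso$analyte[abs(iso$rt_min - 4.895) < 0.01])),
    "Stevioside"
  )
  expect_equal(
    sort(unique(iso$analyte[abs(iso$rt_min - 6.347) < 0.01])),
    "Rebaudioside B"
  )
})

test_that("decoy-only peak lists yield zero assignments", {
  cfg <- noiseless_config()
  peaks <- simulate_peak_list(cfg, n_samples = 1, n_decoys = 5,
                              analytes_present = character(0))
  assigned <- match_peaks(peaks, tab)
  expect_true(all(is.na(assigned$analyte)))
  expect_equal(nrow(confirm_identities(assigned)), 0)
})

test_that("a quantifier-only hit stays quantifiable but unconfirmed", {
  p <- peak(965.5, 803.45, 4.856)
  conf <- confirm_identities(match_peaks(p, tab))
  expect_equal(conf$analyte, "Rebaudioside A")
  expect_false(conf$confirmed)
  expect_equal(conf$n_qualifiers, 0L)
  # adding one qualifier peak confirms
  p2 <- rbind(p, peak(965.5, 641.36, 4.856, area = 3e3))
  conf2 <- confirm_identities(match_peaks(p2, tab))
  expect_true(conf2$confirmed)
})

test_that("heavy retention jitter degrades recall below 100%", {
  cfg <- sim_config(seed = 21, rt_jitter_sd = 0.9) # ~3x the 5% RPD window at 5 min
  recalls <- vapply(1:30, function(s) {
    cfg$seed <- s
    peaks <- simulate_peak_list(cfg, n_samples = 1)
    mean(!is.na(match_peaks(peaks, tab)$analyte))
  }, numeric(1))
  expect_lt(mean(recalls), 1)
})

test_that("an empty transition table is rejected", {
  expect_error(match_peaks(peak(965.5, 803.45, 4.856), tab[0, ]),
               class = "sweetval_invalid_input")
})
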