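# Welch band powers, energy ratio / EI, PLHG, engineered feature vector

test_that("a 10 Hz unit sinusoid puts essentially all power in alpha", {
  bp <- welch_band_powers(tone_epoch(10))
  expect_gt(bp$alpha / bp$total_power, 0.99)
  expect_equal(bp$total_power, 0.5, tolerance = 0.01)  # A^2/2 for unit tone
})

test_that("white-noise band powers are proportional to bandwidth", {
  set.seed(11)
  acc <- rep(0, 6)
  n_rep <- 3000
  for (i in seq_len(n_rep)) {
    bp <- welch_band_powers(rnorm(400))
    acc <- acc + unlist(bp[names(eeg_bands())])
  }
  acc <- acc / n_rep
  n_bins <- vapply(eeg_bands(), function(b) diff(b), numeric(1))
  per_bin <- acc / n_bins
  expect_lt(diff(range(per_bin)) / mean(per_bin), 0.05)
})

test_that("zero epoch has zero band powers, and degenerate epochs error downstream", {
  bp <- welch_band_powers(numeric(400))
  expect_true(all(unlist(bp) == 0))
  expect_error(relative_band_powers(bp), "degenerate")
})

test_that("relative and log band powers follow their definitions", {
  bp <- welch_band_powers(tone_epoch(10))
  rel <- relative_band_powers(bp)
  expect_true(all(rel >= 0 & rel <= 1))
  expect_lte(sum(rel), 1)  # bands cover 2-150 Hz of the 1-200 Hz axis
  fake <- structure(list(delta = 100, theta = 1, alpha = 1, beta = 1,
                         low_gamma = 1, high_gamma = 1, total_power = 105),
                    class = "band_power_set")
  expect_equal(log_abs_band_powers(fake)[["log_delta"]], 2)
})

test_that("energy ratio matches the fast/slow band-power formula", {
  rel <- c(rel_delta = 0.3, rel_theta = 0.3, rel_alpha = 0.2, rel_beta = 0.25,
           rel_low_gamma = 0.15, rel_high_gamma = 0.10)
  expect_equal(energy_ratio(rel), 1.0)
  rel5 <- c(rel_delta = 0.2, rel_theta = 0.2, rel_alpha = 0.2, rel_beta = 0.2,
            rel_low_gamma = 0.2, rel_high_gamma = 0.2)
  expect_equal(energy_ratio(rel5), 1.5)
  # gamma-dominated epoch through the full spectral path
  g <- tone_epoch(50, amp = 3) + tone_epoch(10, amp = 0.5)
  expect_gt(energy_ratio(relative_band_powers(welch_band_powers(g))), 1)
  rel0 <- rel; rel0[["rel_theta"]] <- 0; rel0[["rel_alpha"]] <- 0
  expect_error(energy_ratio(rel0), "degenerate")
})

test_that("EI reduces to ER on 1 s epochs and generalizes with onset delay", {
  set.seed(21)
  for (i in 1:10) {
    ep <- rnorm(400) + tone_epoch(sample(5:60, 1))
    er <- energy_ratio(relative_band_powers(welch_band_powers(ep)))
    expect_identical(epileptogenicity_index(er), er)
  }
  expect_equal(epileptogenicity_index(2.0, n_d = 4, n_0 = 0), 2 / 5)
  expect_equal(epileptogenicity_index(0), 0)
})

test_that("PLHG phasor core: locked, random-phase, and bound properties", {
  n <- 400
  a <- rep(2, n)
  expect_equal(plhg_phasor(a, rep(1.3, n), rep(0.1, n)), 2, tolerance = 1e-12)
  set.seed(31)
  mags <- replicate(300, plhg_phasor(rep(1, n), runif(n, 0, 2 * pi), 0))
  # E|mean phasor| = sqrt(pi / (4 n)) ~ 0.044 for n = 400
  expect_equal(mean(mags), sqrt(pi / (4 * n)), tolerance = 0.15)
  env <- abs(rnorm(n))
  expect_lte(plhg_phasor(env, runif(n), runif(n)), max(env))
})

test_that("PLHG detects phase-locked high-gamma bursts on a slow rhythm", {
  t <- (0:399) / 400
  locked <- cos(2 * pi * 6 * t) + 2 * (1 + 0.8 * cos(2 * pi * 6 * t)) * sin(2 * pi * 80 * t)
  v_locked <- plhg(locked)
  expect_equal(v_locked, 2, tolerance = 0.15)   # mean envelope
  unlocked <- cos(2 * pi * 6 * t) + 2 * (1 + 0.8 * cos(2 * pi * 9.5 * t)) * sin(2 * pi * 80 * t)
  expect_gt(v_locked, 3 * plhg(unlocked))
  expect_equal(plhg(numeric(400)), 0)
  # pairs mode is a valid alternative estimator on the same signal
  expect_gt(plhg(locked, mode = "pairs"), plhg(unlocked, mode = "pairs"))
})

test_that("engineered_features returns the stable named 16-vector", {
  set.seed(41)
  ep <- rnorm(400) + tone_epoch(12)
  f <- engineered_features(ep)
  expect_length(f, 16)
  expect_identical(names(f), engineered_feature_names())
  expect_true(all(is.finite(f)))
  expect_identical(names(engineered_features(tone_epoch(30) + rnorm(400, sd = 0.1))),
                   names(f))
})

test_that("gain invariance: relative powers, ER, EI unchanged; log powers shift", {
  set.seed(51)
  ep <- rnorm(400) + tone_epoch(20)
  g <- 7
  f1 <- engineered_features(ep)
  f2 <- engineered_features(g * ep)
  rel <- paste0("rel_", names(eeg_bands()))
  expect_equal(f1[rel], f2[rel], tolerance = 1e-10)
  expect_equal(f1[["ei"]], f2[["ei"]], tolerance = 1e-10)
  logs <- paste0("log_", names(eeg_bands()))
  expect_equal(f2[logs] - f1[logs], setNames(rep(2 * log10(g), 6), logs),
               tolerance = 1e-9)
})

test_that("band powers never exceed the DC-excluded total (Parseval-style)", {
  set.seed(61)
  for (i in 1:5) {
    bp <- welch_band_powers(rnorm(400))
    expect_lte(sum(unlist(bp[names(eeg_bands())])), bp$total_power + 1e-12)
  }
})
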