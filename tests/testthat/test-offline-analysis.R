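test_that("the oracle recovers tone phase and envelope", {
  tone <- gen_pure_sine(5, FS, 30)
  orc <- oracle_phase_envelope(tone$value, FS)
  mid <- tone$time_s > 5 & tone$time_s < 25
  # envelope of a unit tone: the squared band-pass response at 5 Hz
  expect_equal(mean(orc$envelope[mid]), 0.9757, tolerance = 0.02)
  # phase advances 360 f / fs per sample
  d <- diff(orc$phase_deg[mid]) %% 360
  expect_equal(median(d), 360 * 5 / FS, tolerance = 1e-3)
  # analytic-signal property: envelope bounds the band-passed signal
  bp <- offline_bandpass(tone$value, FS)
  expect_true(all(orc$envelope >= abs(bp) - 1e-9))
  # zero signal -> zero envelope; short input rejected
  z <- oracle_phase_envelope(numeric(3000), FS)
  expect_equal(z$envelope, numeric(3000))
  expect_error(oracle_phase_envelope(numeric(100), FS), "10 s")
})

test_that("an amplitude-modulated tone's envelope is recovered", {
  n <- round(30 * FS)
  t <- (0:(n - 1)) / FS
  am <- (1 + 0.5 * sin(2 * pi * 0.2 * t)) * cospi(2 * 5 * t)
  orc <- oracle_phase_envelope(am, FS)
  mid <- t > 5 & t < 25
  truth <- 1 + 0.5 * sin(2 * pi * 0.2 * t)
  expect_lt(max(abs(orc$envelope[mid] - truth[mid]) / truth[mid]), 0.05)
})

test_that("phase error is the wrap-corrected absolute difference", {
  x <- c(10, 180, 350)
  expect_equal(phase_error(x, x), tibble::tibble(mean_deg = 0, sd_deg = 0, n = 3))
  shifted <- wrap_deg(x + 2)
  expect_equal(phase_error(shifted, x)$mean_deg, 2)
  expect_equal(phase_error(shifted, x)$sd_deg, 0)
  expect_equal(phase_error(359, 1)$mean_deg, 2)   # wrap, not 358
  expect_error(phase_error(1:3, 1:4), "equal length")
})

test_that("median instantaneous frequency is reported at 0.1 Hz resolution", {
  tone4 <- gen_pure_sine(4, FS, 20)
  orc4 <- oracle_phase_envelope(tone4$value, FS)
  expect_equal(median_instantaneous_frequency(orc4, FS), 4.0)

  tone543 <- gen_pure_sine(5.43, FS, 20)
  orc543 <- oracle_phase_envelope(tone543$value, FS)
  mid <- which(tone543$time_s > 2 & tone543$time_s < 18)
  expect_equal(median_instantaneous_frequency(orc543, FS, mid), 5.4)

  # linear chirp 4 -> 6 Hz: the median of a linear ramp is its midpoint
  n <- round(30 * FS); t <- (0:(n - 1)) / FS
  chirp <- cospi(2 * (4 * t + (2 / 30) * t^2 / 2))
  orcc <- oracle_phase_envelope(chirp, FS)
  midc <- which(t > 2 & t < 28)
  expect_equal(median_instantaneous_frequency(orcc, FS, midc), 5.0,
               tolerance = 0.1)
  expect_error(median_instantaneous_frequency(orc4, FS, 1:10), "1 s")
})

test_that("trial change is the relative change of median envelope", {
  env <- rep(c(1, 0.5), each = 100)
  expect_equal(trial_change(env, 101:200, 1:100)$change_percent, -50)
  expect_equal(trial_change(env, 1:100, 1:100)$change_percent, 0)
  # 0.61 scaling reproduces a 39% suppression readout
  env2 <- c(rep(2, 100), rep(2 * 0.61, 100))
  expect_equal(trial_change(env2, 101:200, 1:100)$change_percent, -39)
  # absent tremor: zero baseline is undefined, not scored
  ch <- trial_change(c(rep(0, 50), rep(1, 50)), 51:100, 1:50)
  expect_true(ch$undefined)
  expect_error(trial_change(env, integer(0), 1:100), "non-empty")
})

test_that("state profiles flag only medians outside their corrected limits", {
  # note: the median of sign-flipped draws is unchanged by flipping any
  # subset of the values above the median, so the null puts an atom of mass
  # >= 2^(n/2)/2^n at the observed median; a consistent suppression only
  # becomes detectable at the corrected level from n ~ 18 trials
  trials <- tibble::tibble(
    state = c(rep("a", 8), rep("b", 18), rep("c", 10)),
    change_percent = c(rep(0, 8),                   # all-zero: never significant
                       -(30 + 1:18),                # consistent suppression
                       c(-5, 4, 3, -6, 2, -1, 5, -3, 1, -2))  # null-ish
  )
  prof <- profile_significance(trials, n_comparisons = 8, seed = 2)
  expect_false(prof$significant[prof$state == "a"])
  expect_true(prof$significant[prof$state == "b"])
  expect_false(prof$significant[prof$state == "c"])
  expect_true(all(prof$lower <= prof$upper))
  # invariant: significant iff the median falls outside the limits
  expect_equal(prof$significant,
               prof$median_change < prof$lower | prof$median_change > prof$upper)
  # too few trials: untestable
  prof2 <- profile_significance(tibble::tibble(state = "d", change_percent = c(1, 2)))
  expect_true(prof2$untestable)
  expect_identical(profile_significance(trials, n_comparisons = 8, seed = 2),
                   prof)  # seeded
})

test_that("the Bonferroni-corrected profile controls family-wise error", {
  # simulated null: 8 states x 10 trials of symmetric noise, 1000 replicates
  reps <- 1000
  set.seed(99)
  any_sig <- vapply(seq_len(reps), function(r) {
    trials <- tibble::tibble(state = rep(paste0("s", 1:8), each = 10),
                             change_percent = rnorm(80, 0, 10))
    prof <- profile_significance(trials, n_comparisons = 8, ndraws = 10000,
                                 seed = r)
    any(prof$significant)
  }, logical(1))
  fwer <- mean(any_sig)
  mc <- 2 * sqrt(0.05 * 0.95 / reps)
  expect_lte(fwer, 0.05 + mc)
})

test_that("rank-sum envelope comparison matches hand-enumerated ranks", {
  res <- envelope_rank_compare(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 6)          # minimum possible rank sum
  # clearly separated distributions
  set.seed(4)
  a <- rnorm(500); b <- rnorm(500) + 5
  expect_lt(envelope_rank_compare(a, b)$p_value, 1e-10)
  # identical distributions: p is uniform; its median over seeds is ~0.5
  ps <- vapply(1:40, function(s) {
    set.seed(s)
    envelope_rank_compare(rnorm(200), rnorm(200))$p_value
  }, numeric(1))
  expect_gt(median(ps), 0.25)
  expect_lt(median(ps), 0.75)
  expect_error(envelope_rank_compare(numeric(0), 1), "non-empty")
})

test_that("the pre-filter gap shrinks as noise weakens", {
  # the suite's noise scale is a free parameter; sweeping SNR shows the
  # gap is noise-dominated (the causal high-pass phase lead remains)
  gaps <- vapply(c(3, 10), function(snr)
    prefilter_error_gap(prefilter_error_suite(freqs = c(3, 6), seeds = 1:2,
                                              snr = snr, duration_s = 30)),
    numeric(1))
  expect_lt(gaps[2], gaps[1])
  expect_true(all(gaps > 0))
})
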