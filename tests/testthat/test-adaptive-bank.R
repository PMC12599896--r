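test_that("the bank runs 21 streams and zero input keeps everything at rest", {
  bank <- stream_bank(FS)
  out <- bank_step(bank, c(0, 0, 0))
  expect_equal(nrow(out$streams), 21)
  expect_equal(nrow(unique(out$streams[, c("axis", "fc_hz")])), 21)
  expect_equal(out$locked$phi_deg, 0)
  expect_equal(out$locked$axis, "y")
  expect_equal(out$locked$fc_hz, 5)
  for (i in 1:20) out <- bank_step(bank, c(0, 0, 0))
  expect_equal(tremortrack:::mu_axis_values(bank), c(0, 0, 0))
  expect_true(all(tremortrack:::mu_error_values(bank) == 0))
  expect_error(bank_step(bank, c(0, NA, 0)), "finite")
  expect_error(bank_step(bank, c(0, 0)), "length 3")
})

test_that("moving averages equal a naive recomputation", {
  set.seed(7)
  for (W in c(1, 5, 64, 500)) {
    x <- rnorm(1200)
    expect_equal(moving_average(x, W), naive_moving_average(x, W),
                 tolerance = 1e-9)
  }
})

test_that("a y-only tone drives mu_axis and mu_error to the right stream", {
  sc <- tremor_scenario(duration_s = 25, envelope = list(y = 1), freq = 5)
  trk <- track_record(gen_tremor_record(sc))
  sel <- trk$selections
  expect_gt(sel$mu_axis_y[1], 0.5)
  expect_lt(max(sel$mu_axis_x[1], sel$mu_axis_z[1]), 1e-6)
  # among the y streams, the prediction error is smallest at fc = 5
  mu_err <- unlist(sel[1, paste0("mu_error_", 2:8)])
  expect_equal(unname(which.min(mu_err)), 4)  # 5 Hz is the 4th grid point
  expect_equal(sel$axis[1], "y")
  expect_equal(sel$fc_hz[1], 5)
})

test_that("selection happens at exact sample-index multiples of the cadence", {
  sc <- tremor_scenario(duration_s = 70, envelope = list(y = 1), freq = 4)
  trk <- track_record(gen_tremor_record(sc), interval_s = 20)
  k <- round(20 * FS)  # 4161 samples
  expect_equal(trk$selections$time_s, (1:3) * k / FS, tolerance = 1e-12)
  # between instants the locked stream never changes
  lock <- paste(trk$samples$axis, trk$samples$fc_hz)
  changes <- which(lock[-1] != lock[-length(lock)])
  expect_true(all(changes %% k == 0))
  # noiseless 4 Hz tone: fc = 4 at every instant
  expect_true(all(trk$selections$fc_hz == 4))
})

test_that("crossing envelopes switch the selected axis after the crossover", {
  # y starts dominant; x overtakes at t = 30 s with a 2:1 final ratio
  sc <- tremor_scenario(
    duration_s = 61, freq = 5,
    envelope = list(
      y = 0.5,
      x = data.frame(time_s = c(0, 30, 60), value = c(0, 0.5, 1.5))
    )
  )
  trk <- track_record(gen_tremor_record(sc), interval_s = 10)
  sel <- trk$selections
  expect_equal(sel$axis[sel$time_s < 30], rep("y", sum(sel$time_s < 30)))
  # moving averages cross within the 10-s window length after t = 30
  first_x <- sel$time_s[sel$axis == "x"][1]
  expect_lt(first_x - 30, 10 + 10)  # crossover lag below window, next instant
  expect_true(all(sel$axis[sel$time_s >= first_x] == "x"))
})

test_that("exact ties keep the incumbent selection", {
  # identical signals on x and y: mu_axis ties, incumbent y must stay
  tone <- gen_pure_sine(4, FS, 25)$value
  rec <- tremor_record(tone, tone, numeric(length(tone)), fs = FS)
  trk <- track_record(rec, interval_s = 10)
  expect_true(all(trk$selections$axis == "y"))
  # all-zero input: every mu ties at 0; default y / 5 Hz is kept
  zeros <- tremor_record(numeric(5000), numeric(5000), numeric(5000), fs = FS)
  trk0 <- track_record(zeros, interval_s = 10)
  expect_true(all(trk0$selections$axis == "y"))
  expect_true(all(trk0$selections$fc_hz == 5))
})

test_that("select_stream before any samples warns and keeps the default", {
  bank <- stream_bank(FS)
  expect_warning(sel <- select_stream(bank), "before any samples")
  expect_equal(sel$axis, "y")
  expect_equal(sel$fc_hz, 5)
})

test_that("center frequency is recovered at SNR 3 across the grid", {
  # >= 95% of selection instants with constant f_true in the preceding
  # window must pick the true frequency (210 instants here)
  hits <- 0; total <- 0
  for (f in 2:8) {
    for (seed in 1:10) {
      sc <- tremor_scenario(duration_s = 60.2, envelope = list(y = 1), freq = f,
                            noise_kind = "pink", noise_scale = (1 / sqrt(2)) / 3,
                            seed = 1000 * f + seed)
      trk <- track_record(gen_tremor_record(sc))
      hits <- hits + sum(trk$selections$fc_hz == f)
      total <- total + nrow(trk$selections)
    }
  }
  expect_gte(total, 200)
  expect_gte(hits / total, 0.95)
})

test_that("the dominant axis is recovered after a switch at SNR 3", {
  # amplitude ratio 2:1, switch at t = 25 s; instants whose whole preceding
  # window is post-switch must match truth
  hits <- 0; total <- 0
  for (seed in 1:10) {
    sc <- tremor_scenario(
      duration_s = 60.2, freq = 5,
      envelope = list(
        y = data.frame(time_s = c(0, 24.99, 25), value = c(1, 1, 0.5)),
        z = data.frame(time_s = c(0, 24.99, 25), value = c(0.2, 0.2, 1))
      ),
      envelope_method = "constant",
      noise_kind = "pink", noise_scale = (1 / sqrt(2)) / 3, seed = seed
    )
    trk <- track_record(gen_tremor_record(sc))
    sel <- trk$selections
    pre <- sel$time_s <= 25
    post <- sel$time_s >= 35.2   # preceding 10-s window entirely post-switch
    hits <- hits + sum(sel$axis[pre] == "y") + sum(sel$axis[post] == "z")
    total <- total + sum(pre) + sum(post)
  }
  expect_gte(hits / total, 0.95)
})

test_that("the R stepping path replicates the compiled bank exactly", {
  # streaming firmware path (C++) versus an independent batch
  # re-implementation (R): phase must agree on continuous tremor
  sc <- tremor_scenario(duration_s = 25, envelope = list(y = 1, x = 0.4),
                        freq = 5, noise_kind = "pink", noise_scale = 0.2,
                        seed = 8)
  rec <- gen_tremor_record(sc)
  trk <- track_record(rec, interval_s = 10)

  X <- vapply(c("ax_g", "ay_g", "az_g"), function(col)
    filter_apply(make_highpass(FS), rec[[col]]), numeric(nrow(rec)))
  bank <- stream_bank(FS, interval_s = 10)
  k <- round(10 * FS)
  phi <- numeric(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    phi[i] <- bank_step(bank, X[i, ])$locked$phi_deg
    if (i %% k == 0) select_stream(bank)
  }
  err <- phase_error(phi, trk$samples$phi_deg)
  expect_lt(err$mean_deg, 0.5)        # the two-participant replication bound
  expect_lt(err$mean_deg, 1e-9)       # and in fact bit-level agreement
})

test_that("phase estimates degrade when tremor ceases", {
  sc <- tremor_scenario(duration_s = 45, envelope = list(y = 1), freq = 5,
                        cessation = data.frame(start_s = 20, end_s = 32),
                        noise_kind = "pink", noise_scale = 0.1, seed = 3)
  rec <- gen_tremor_record(sc)
  trk <- track_record(rec)
  orc <- oracle_phase_envelope(rec$ay_g, FS)
  err <- circ_dist(trk$samples$phi_deg, orc$phase_deg)
  t <- trk$samples$time_s
  err_on <- mean(err[t > 5 & t < 18])
  err_off <- mean(err[t > 22 & t < 30])
  expect_gt(err_off, err_on)
  expect_lt(err_on, 10)
})
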