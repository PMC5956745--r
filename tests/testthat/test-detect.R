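test_that("baseline noise estimate is robust to sparse events", {
  set.seed(21)
  pure <- sweep_recording(matrix(rnorm(40000, 0, 2)), dt_ms = 0.05)
  est <- estimate_baseline_noise(pure)
  expect_equal(est$sd_pa, 2, tolerance = 0.1)

  flat <- sweep_recording(matrix(rep(-3.5, 1000)), dt_ms = 0.05)
  expect_equal(estimate_baseline_noise(flat)$sd_pa, 0)

  # ~5% of samples contaminated by large events
  qm <- quantal_model(n_p = 40, i_pa = -0.5)
  sim <- simulate_mepsc_recording(qm, sweep_ms = 20000, rate_hz = 8,
                                  noise_sd_pa = 2, seed = 22)
  est2 <- estimate_baseline_noise(sim$recording)
  expect_lt(abs(est2$sd_pa - 2) / 2, 0.15)

  expect_error(estimate_baseline_noise(pure, window_ms = c(0, 0.5)),
               ">= 20 samples")
})

test_that("threshold crossing finds only supra-threshold events", {
  rec <- make_clean_recording(c(200, 600, 1200), c(-10, -3, -10))
  ev <- detect_events(rec, k = 3, noise_sd_pa = 5 / 3)  # threshold 5 pA
  expect_equal(nrow(ev), 2)
  expect_equal(ev$peak_pa, c(-10, -10), tolerance = 0.01)
  expect_equal(ev$onset_ms, c(200, 1200), tolerance = 0.3)
})

test_that("false positives on noise-only recordings are rare", {
  set.seed(23)
  noise <- sweep_recording(matrix(rnorm(1200001, 0, 2)), dt_ms = 0.05)  # 60 s
  ev <- detect_events(noise, k = 3, noise_sd_pa = 2)  # threshold 6 pA
  expect_lt(nrow(ev) / 60, 0.1)
})

test_that("detection recovers >= 95% of well-separated true events", {
  qm <- quantal_model(n_p = 20, i_pa = -0.6)  # 12 pA peak = 4 x threshold
  sim <- simulate_mepsc_recording(qm, n_sweeps = 2, sweep_ms = 30000,
                                  rate_hz = 1, noise_sd_pa = 1, seed = 24)
  ev <- detect_events(sim$recording, k = 3, noise_sd_pa = 1)
  truth <- dplyr::filter(sim$truth, !overlapped)
  hit <- vapply(seq_len(nrow(truth)), function(j) {
    any(ev$sweep == truth$sweep[j] &
          abs(ev$onset_ms - truth$onset_ms[j]) < 1.5)
  }, logical(1))
  expect_gte(mean(hit), 0.95)
})

test_that("detection count is monotonically non-increasing in threshold", {
  # amplitude censoring on a noiseless recording: exact and strict
  rec <- make_clean_recording(c(200, 600, 1000), c(-4, -7, -12),
                              sweep_ms = 1400)
  exact <- vapply(c(3, 5, 9, 15), function(thr) {
    nrow(detect_events(rec, k = thr, noise_sd_pa = 1))
  }, numeric(1))
  expect_equal(exact, c(3, 2, 1, 0))

  # noisy recordings with non-overlapping events (merge window covering
  # the event footprint; overlapping events can merge at low thresholds
  # and split at high ones, which is outside this censoring property)
  qm <- quantal_model()
  for (seed in c(25, 83)) {
    sim <- simulate_mepsc_recording(qm, sweep_ms = 30000, rate_hz = 1,
                                    noise_sd_pa = 1, seed = seed)
    counts <- vapply(c(2.5, 3, 4, 6, 9), function(k) {
      nrow(suppressWarnings(detect_events(sim$recording, k = k,
                                          noise_sd_pa = 1, merge_ms = 5)))
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("a sample shift of the trace shifts detected times exactly", {
  rec <- make_clean_recording(500, -10, sweep_ms = 1500)
  m <- 40
  x <- sweep_matrix(rec)[, 1]
  shifted <- sweep_recording(matrix(c(rep(0, m), head(x, -m))), dt_ms = 0.05)
  e1 <- detect_events(rec, noise_sd_pa = 1)
  e2 <- detect_events(shifted, noise_sd_pa = 1)
  expect_equal(e2$onset_ms - e1$onset_ms, m * 0.05)
  expect_equal(e2$peak_ms - e1$peak_ms, m * 0.05)
})

test_that("screening distinguishes clean events from contaminated decays", {
  # isolated event: both flags true
  rec <- make_clean_recording(500, -10)
  ev <- screen_events(detect_events(rec, noise_sd_pa = 1), rec)
  expect_true(ev$monotonic_rise[1])
  expect_true(ev$clean_decay[1])

  # second event 2 ms later contaminates the first decay (short merge
  # window so the two excursions stay distinct events)
  rec2 <- make_clean_recording(c(500, 502), c(-10, -10))
  ev2 <- screen_events(detect_events(rec2, noise_sd_pa = 5 / 3,
                                     merge_ms = 0.5), rec2)
  expect_equal(nrow(ev2), 2)
  expect_false(ev2$clean_decay[1])

  # noiseless rise of the uncontaminated event is monotonic under the
  # zero-tolerance default
  expect_true(ev2$monotonic_rise[1])
})

test_that("alignment and averaging reproduce the generator mean decay", {
  # single event: the mean is that event
  rec <- make_clean_recording(500, -10)
  ev <- screen_events(detect_events(rec, noise_sd_pa = 1), rec)
  ens1 <- align_and_average(ev, rec, pre_ms = 2, post_ms = 10)
  expect_equal(ens1$mean_pa, ens1$waveforms[1, ])
  expect_equal(max(abs(ens1$sem_pa)), 0)

  # identical noiseless events: SEM is zero everywhere
  rec3 <- make_clean_recording(c(300, 800, 1300), rep(-10, 3))
  ev3 <- screen_events(detect_events(rec3, noise_sd_pa = 1), rec3)
  ens3 <- align_and_average(ev3, rec3, pre_ms = 2, post_ms = 10)
  expect_lt(max(abs(ens3$sem_pa)), 1e-9)

  # stochastic ensemble mean follows i * N_p * exp(-t/tau) after the peak
  qm <- quantal_model()
  ens <- make_ensemble(500, qm, noise_sd = 0, seed = 26)
  pk <- which.max(abs(ens$mean_pa))
  for (mult in c(1, 2, 3)) {
    j <- pk + round(mult * qm$tau_decay_ms / ens$dt_ms)
    expected <- qm$i_pa * qm$n_p * exp(-mult)
    mc_sd <- sqrt(qm$i_pa^2 * qm$n_p * exp(-mult) * (1 - exp(-mult)) / 500)
    expect_lt(abs(ens$mean_pa[j] - expected), 4 * mc_sd)
  }

  expect_error(align_and_average(ev[0, ], rec), "No events")
})
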