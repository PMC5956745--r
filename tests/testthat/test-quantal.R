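test_that("a constructed session with 3 silent sweeps gives failure rate 0.10", {
  # 30 sweeps, stimulus at 20 ms; 27 sweeps respond, 3 are silent
  onsets <- c(rep(list(c(20, 45, 80)), 27), rep(list(numeric(0)), 3))
  amps <- c(rep(list(c(-40, -12, -12)), 27), rep(list(numeric(0)), 3))
  rec <- make_clean_recording(onsets, amps, sweep_ms = 200, n_sweeps = 30,
                              stimulus_times = 20)
  ev <- screen_events(detect_events(rec, noise_sd_pa = 5 / 3), rec)
  qs <- analyze_sr2_session(rec, ev, exclusion_ms = 10)
  g <- glance(qs)
  expect_equal(g$failure_rate, 0.1)
  expect_equal(g$n_sweeps, 30)
  # two asynchronous qEPSCs per responding sweep (45 and 80 ms)
  expect_equal(g$mean_qepsc_count, 2 * 27 / 30)
  expect_equal(g$initial_epsc_pa, -40, tolerance = 0.02 * 40)
  expect_equal(g$initial_epsc_pa_all, -40 * 27 / 30, tolerance = 0.02 * 40)
})

test_that("the exclusion window removes early multiquantal events", {
  onsets <- list(c(20, 22, 26))   # all within 10 ms of the stimulus
  rec <- make_clean_recording(onsets, list(c(-30, -15, -15)),
                              sweep_ms = 150, stimulus_times = 20)
  ev <- screen_events(detect_events(rec, noise_sd_pa = 5 / 3), rec)
  qs <- analyze_sr2_session(rec, ev, exclusion_ms = 10)
  expect_equal(tidy(qs)$n_qepsc, 0)
  expect_false(tidy(qs)$failure)
})

test_that("asynchronous counts from the simulator are recovered within 15%", {
  qm <- quantal_model()
  # rate profile integrating to ~10 events per sweep
  sim <- simulate_sr2_session(qm, n_sweeps = 50, sweep_ms = 500,
                              stim_ms = 50, async_rate_hz = 55.9,
                              async_tau_ms = 200, fail_prob = 0,
                              noise_sd_pa = 1, seed = 61)
  true_mean <- sum(sim$truth$kind == "asynchronous") / 50
  ns <- estimate_baseline_noise(sim$recording)$sd_pa
  ev <- screen_events(detect_events(sim$recording, noise_sd_pa = ns),
                      sim$recording, noise_sd_pa = ns)
  qs <- analyze_sr2_session(sim$recording, ev)
  expect_equal(glance(qs)$mean_qepsc_count, true_mean,
               tolerance = 0.15 * true_mean)
})

test_that("the generator's failure flag is an unbiased Bernoulli draw", {
  qm <- quantal_model()
  q <- 0.2
  fails <- vapply(1:200, function(s) {
    sim <- simulate_sr2_session(qm, n_sweeps = 10, sweep_ms = 40,
                                stim_ms = 5, async_rate_hz = 0,
                                fail_prob = q, noise_sd_pa = 0.2,
                                dt_ms = 0.5, seed = s)
    length(unique(sim$truth$sweep[sim$truth$failure])) / 10
  }, numeric(1))
  se <- sqrt(q * (1 - q) / (200 * 10))
  expect_lt(abs(mean(fails) - q), 2 * se + 1e-9)
})

test_that("minimal-stimulation screening accepts only stable responses", {
  ok <- minimal_stimulation_ok(0.3, latency_ms = rnorm(20, 2, 0.1),
                               amplitude_pa = rnorm(20, -50, 5))
  expect_true(ok$accepted)
  bad_fail <- minimal_stimulation_ok(0.8, rnorm(20, 2, 0.1),
                                     rnorm(20, -50, 5))
  expect_false(bad_fail$accepted)
  bad_lat <- minimal_stimulation_ok(0.3, abs(rnorm(20, 2, 2)) + 0.1,
                                    rnorm(20, -50, 5))
  expect_false(bad_lat$accepted)
})

test_that("train analysis reproduces constructed paired-pulse ratios", {
  stim <- c(20, 30, 40, 50, 60)  # 100 Hz
  amps <- c(-100, -41, -30, -25, -22)
  rec <- make_clean_recording(list(stim), list(amps), sweep_ms = 120,
                              n_sweeps = 6, stimulus_times = stim)
  res <- analyze_train(rec)
  g <- glance(res)
  expect_equal(g$ppr_2_1, 0.41, tolerance = 0.02)
  expect_equal(tidy(res)$normalized[1], 1)

  # identical responses on every pulse: everything normalizes to 1
  flat <- make_clean_recording(list(stim), list(rep(-60, 5)),
                               sweep_ms = 120, n_sweeps = 5,
                               stimulus_times = stim)
  gf <- glance(analyze_train(flat))
  expect_equal(gf$ppr_2_1, 1, tolerance = 0.02)
  expect_equal(tidy(analyze_train(flat))$normalized, rep(1, 5),
               tolerance = 0.02)
})

test_that("depletion-train PPR is recovered from noisy sweeps within 10%", {
  qm <- quantal_model()
  tr <- simulate_train(qm, n_pulses = 5, freq_hz = 100, f = 0.7,
                       tau_rec_ms = 1e9, a1_pa = -100, n_sweeps = 20,
                       noise_sd_pa = 1, seed = 62)
  expect_equal(tr$amplitudes$ppr_true[1], 0.3, tolerance = 1e-6)
  g <- glance(analyze_train(tr$recording))
  expect_equal(g$ppr_2_1, 0.3, tolerance = 0.03)
})

test_that("train analysis requires a known reference condition", {
  stim <- c(20, 30)
  rec <- make_clean_recording(list(stim), list(c(-50, -30)), sweep_ms = 60,
                              n_sweeps = 5, stimulus_times = stim)
  expect_error(analyze_train(list(a = rec), reference = "b"), "absent")
  # normalization across conditions anchors on the reference first pulse
  rec2 <- make_clean_recording(list(stim), list(c(-25, -20)), sweep_ms = 60,
                               n_sweeps = 5, stimulus_times = stim)
  res <- analyze_train(list(high_ca = rec, low_ca = rec2),
                       reference = "high_ca")
  td <- tidy(res)
  expect_equal(td$normalized[td$condition == "low_ca" & td$pulse == 1],
               0.5, tolerance = 0.05)
})

test_that("exact rank-sum p-values match brute-force enumeration", {
  set.seed(63)
  for (nx in 2:6) {
    for (ny in 2:6) {
      x <- runif(nx)
      y <- runif(ny) + 0.2
      got <- wilcoxon_rank_sum(x, y)
      oracle <- brute_force_ranksum(x, y)
      expect_equal(got$statistic, oracle$W)
      expect_equal(got$p_value, oracle$p, tolerance = 1e-12)
    }
  }
})

test_that("rank-sum statistic obeys symmetry and tie conventions", {
  expect_equal(wilcoxon_rank_sum(1:3, 4:6)$statistic, 0)
  expect_equal(wilcoxon_rank_sum(1:3, 4:6)$p_value, 0.1)
  expect_equal(wilcoxon_rank_sum(4:6, 1:3)$statistic, 9)
  expect_equal(wilcoxon_rank_sum(4:6, 1:3)$p_value, 0.1)

  # W(x, y) + W(y, x) = n_x * n_y without ties
  set.seed(64)
  for (rep in 1:10) {
    x <- rnorm(sample(2:8, 1))
    y <- rnorm(sample(2:8, 1))
    expect_equal(wilcoxon_rank_sum(x, y)$statistic +
                   wilcoxon_rank_sum(y, x)$statistic,
                 length(x) * length(y))
  }

  # identical samples: mid-ranks give W = n^2 / 2
  tied <- wilcoxon_rank_sum(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(tied$statistic, 16 / 2)
  expect_equal(tied$method, "normal approximation")
})
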