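test_that("gating simulator reproduces the analytic variance-mean parabola", {
  qm <- quantal_model(n_p = 20, i_pa = -0.69, tau_rise_ms = 0.15,
                      tau_decay_ms = 1.3)
  dt <- 0.05
  set.seed(11)
  wf <- replicate(3000, simulate_quantal_event(qm, dt, 8))
  t <- seq(0, 8, by = dt)
  t_peak <- 5 * qm$tau_rise_ms

  # at the peak all channels are open: current exactly i * N_p, variance 0
  j_pk <- which.min(abs(t - t_peak))
  expect_equal(unique(wf[j_pk, ]), qm$i_pa * qm$n_p)
  expect_equal(var(wf[j_pk, ]), 0)

  # half-decay point: binomial mean and variance of the surviving count
  j_half <- which.min(abs(t - (t_peak + qm$tau_decay_ms * log(2))))
  p <- exp(-(t[j_half] - t_peak) / qm$tau_decay_ms)
  expect_equal(mean(wf[j_half, ]), qm$i_pa * qm$n_p * p, tolerance = 0.03)
  expect_equal(var(wf[j_half, ]), qm$i_pa^2 * qm$n_p * p * (1 - p),
               tolerance = 0.08)
})

test_that("a single channel yields a two-level step of amplitude i", {
  qm <- quantal_model(n_p = 1, i_pa = -0.69, tau_rise_ms = 0,
                      tau_decay_ms = 1.3)
  set.seed(2)
  w <- simulate_quantal_event(qm, 0.05, 10)
  expect_setequal(unique(w), c(qm$i_pa, 0))
  expect_true(all(diff(w == qm$i_pa) <= 0))  # open then closed, no reopening
})

test_that("mEPSC recordings have Poisson counts, correct noise, and seeds", {
  qm <- quantal_model()
  sim <- simulate_mepsc_recording(qm, n_sweeps = 2, sweep_ms = 30000,
                                  rate_hz = 3, noise_sd_pa = 1, seed = 5)
  # 3 Hz x 60 s -> 180 expected; allow 4 Poisson SDs
  expect_lt(abs(nrow(sim$truth) - 180), 4 * sqrt(180))

  null <- simulate_mepsc_recording(qm, n_sweeps = 1, sweep_ms = 5000,
                                   rate_hz = 0, noise_sd_pa = 2, seed = 6)
  expect_equal(nrow(null$truth), 0)
  expect_equal(sd(null$recording$current_pa), 2, tolerance = 0.1)

  again <- simulate_mepsc_recording(qm, n_sweeps = 2, sweep_ms = 30000,
                                    rate_hz = 3, noise_sd_pa = 1, seed = 5)
  expect_identical(sim$recording$current_pa, again$recording$current_pa)
  expect_identical(sim$truth, again$truth)
})

test_that("simulated ramps carry their rectification ground truth", {
  lin <- simulate_iv_ramp(1, 1, noise_sd_pa = 0)
  expect_equal(ri_slope(lin)$ri_slope, 1, tolerance = 1e-10)

  rect <- simulate_iv_ramp(1, 0.3, noise_sd_pa = 0)
  expect_equal(attr(rect, "truth")$ri, 0.3)
  expect_equal(ri_slope(rect)$ri_slope, 0.3, tolerance = 1e-10)

  ris <- vapply(1:10, function(s) {
    ri_slope(simulate_iv_ramp(1, 0.3, noise_sd_pa = 2, seed = s))$ri_slope
  }, numeric(1))
  expect_equal(mean(ris), 0.3, tolerance = 0.05)
})

test_that("Sr2+ sessions reproduce failure and asynchronous-count statistics", {
  qm <- quantal_model()
  # failure flags are Bernoulli(fail_prob): check the mean over many sweeps
  sim <- simulate_sr2_session(qm, n_sweeps = 300, sweep_ms = 40, stim_ms = 5,
                              async_rate_hz = 0, fail_prob = 0.1,
                              noise_sd_pa = 0.5, dt_ms = 0.5, seed = 8)
  n_fail <- length(unique(sim$truth$sweep[sim$truth$failure]))
  expect_lt(abs(n_fail / 300 - 0.1), 2 * sqrt(0.1 * 0.9 / 300))

  # no asynchronous component: only the synchronous event remains
  expect_true(all(sim$truth$kind %in% c("synchronous", "failure")))

  # asynchronous counts match the integral of the decaying rate profile
  sim2 <- simulate_sr2_session(qm, n_sweeps = 100, sweep_ms = 100,
                               stim_ms = 10, async_rate_hz = 50,
                               async_tau_ms = 30, fail_prob = 0,
                               noise_sd_pa = 0.5, dt_ms = 0.5, seed = 9)
  lambda <- 50 * 0.03 * (1 - exp(-90 / 30))
  n_async <- sum(sim2$truth$kind == "asynchronous")
  expect_lt(abs(n_async / 100 - lambda), 4 * sqrt(lambda / 100))
})

test_that("depletion recursion stays in (0, 1] and gives the limit PPR", {
  set.seed(3)
  for (rep in 1:20) {
    f <- runif(1, 0.05, 1)
    tau <- runif(1, 1, 500)
    r <- depletion_states(f, tau, 10, 10)
    expect_true(all(r > 0 & r <= 1))
  }
  # slow recovery: PPR -> 1 - f
  r <- depletion_states(0.59, 1e9, 5, 10)
  expect_equal(r[2] / r[1], 0.41, tolerance = 1e-6)
  # no depletion / instant recovery: PPR = 1
  expect_equal(depletion_states(1e-9, 1e9, 3, 10)[2], 1, tolerance = 1e-6)
  expect_equal(depletion_states(0.8, 1e-9, 3, 10)[2], 1, tolerance = 1e-6)
})

test_that("simulated trains encode amplitudes proportional to f * R_n", {
  qm <- quantal_model()
  tr <- simulate_train(qm, n_pulses = 5, freq_hz = 100, f = 0.59,
                       tau_rec_ms = 1e9, a1_pa = -100, n_sweeps = 3,
                       noise_sd_pa = 0, seed = 1)
  expect_equal(tr$amplitudes$ppr_true[1], 0.41, tolerance = 1e-6)
  expect_equal(tr$amplitudes$amplitude_pa,
               -100 * tr$amplitudes$r_state, tolerance = 1e-12)
})

test_that("terminal generator places Poisson vesicles with seeds and truth", {
  empty <- simulate_terminal(density_per_um2 = 0, seed = 1)
  expect_equal(nrow(empty$vesicles), 0)

  ann <- simulate_terminal(density_per_um2 = 130, seed = 2)
  # 130 per um^2 in 10 um^2 -> ~1300, 4 Poisson SDs
  expect_lt(abs(nrow(ann$vesicles) - 1300), 4 * sqrt(1300))
  expect_true(all(ann$vesicles$diameter_nm > 10))

  again <- simulate_terminal(density_per_um2 = 130, seed = 2)
  expect_identical(ann$vesicles, again$vesicles)

  expect_error(simulate_terminal(terminal = cbind(c(0, 1), c(0, 1))),
               "Degenerate")
})
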