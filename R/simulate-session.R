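#' Simulate a current-voltage ramp with configurable rectification
#'
#' Current is conductance times driving force (reversal 0 mV), with the
#' conductance equal to `g_neg_ns` below -20 mV, `g_pos_ns` above +20 mV,
#' and linearly interpolated between, plus Gaussian noise. The ground-truth
#' rectification index is `g_pos_ns / g_neg_ns`.
#'
#' @param g_neg_ns,g_pos_ns Limb conductances (nS, >= 0).
#' @param v_range Voltage range (mV, length 2), default -90..+60.
#' @param noise_sd_pa Current noise SD (pA).
#' @param n_points Number of ramp samples; the default emulates a ~1.5 s
#'   ramp sampled at 5 kHz.
#' @param seed Optional integer seed.
#' @return An [iv_ramp()] with attribute `truth` = list(ri = g_pos/g_neg).
#' @export
simulate_iv_ramp <- function(g_neg_ns = 1, g_pos_ns = 1,
                             v_range = c(-90, 60), noise_sd_pa = 0,
                             n_points = 7501, seed = NULL) {
  stopifnot(g_neg_ns >= 0, g_pos_ns >= 0, length(v_range) == 2)
  if (!is.null(seed)) set.seed(seed)
  v <- seq(v_range[1], v_range[2], length.out = n_points)
  g <- ifelse(v <= -20, g_neg_ns,
              ifelse(v >= 20, g_pos_ns,
                     g_neg_ns + (g_pos_ns - g_neg_ns) * (v + 20) / 40))
  i <- g * v + rnorm(n_points, 0, noise_sd_pa)  # nS * mV = pA
  ramp <- iv_ramp(v, i, leak_subtracted = TRUE)
  attr(ramp, "truth") <- list(ri = g_pos_ns / g_neg_ns)
  ramp
}

#' Simulate a strontium-substitution quantal release session
#'
#' Each sweep carries one stimulus. On non-failure sweeps a synchronous
#' EPSC of amplitude `sync_amp_pa` occurs at the stimulus, followed by
#' asynchronous stochastic quantal events whose rate decays exponentially
#' (`async_rate_hz * exp(-(t - t_stim)/async_tau_ms)`), emulating
#' Sr2+-desynchronized release. With probability `fail_prob` a sweep is a
#' failure (no synchronous or asynchronous release).
#'
#' @param model A [quantal_model()] for the asynchronous quanta.
#' @param n_sweeps Number of sweeps.
#' @param sweep_ms Sweep duration (ms).
#' @param stim_ms Stimulus time within each sweep (ms).
#' @param sync_amp_pa Peak amplitude of the synchronous EPSC (pA, negative
#'   for inward).
#' @param async_rate_hz Initial asynchronous event rate at the stimulus
#'   (events/s).
#' @param async_tau_ms Decay time constant of the asynchronous rate (ms).
#' @param fail_prob Per-sweep failure probability in [0, 1].
#' @param noise_sd_pa Baseline noise SD (pA).
#' @param dt_ms Sampling interval (ms).
#' @param seed Optional integer seed.
#' @return A list with `recording` (a [sweep_recording()] with stimulus
#'   times) and `truth` (tibble: sweep, time_ms, kind, failure).
#' @export
simulate_sr2_session <- function(model, n_sweeps = 30, sweep_ms = 500,
                                 stim_ms = 50, sync_amp_pa = -50,
                                 async_rate_hz = 25, async_tau_ms = 200,
                                 fail_prob = 0, noise_sd_pa = 1,
                                 dt_ms = 0.05, seed = NULL) {
  stopifnot(inherits(model, "quantal_model"),
            fail_prob >= 0, fail_prob <= 1, stim_ms < sweep_ms)
  if (!is.null(seed)) set.seed(seed)
  n_samp <- floor(sweep_ms / dt_ms) + 1
  t_grid <- seq(0, by = dt_ms, length.out = n_samp)
  ev_dur <- 10 * model$tau_decay_ms
  mat <- matrix(rnorm(n_samp * n_sweeps, 0, noise_sd_pa), nrow = n_samp)
  sync_shape <- sync_amp_pa *
    mean_epsc_shape(t_grid - stim_ms, model$tau_rise_ms, model$tau_decay_ms) *
    (t_grid >= stim_ms)
  truth <- vector("list", n_sweeps)
  for (sw in seq_len(n_sweeps)) {
    failed <- runif(1) < fail_prob
    rows <- tibble::tibble(sweep = sw, time_ms = NA_real_,
                           kind = "failure", failure = TRUE)
    if (!failed) {
      mat[, sw] <- mat[, sw] + sync_shape
      # expected async count is the integral of the rate profile over the sweep
      horizon_ms <- sweep_ms - stim_ms
      lambda <- async_rate_hz * (async_tau_ms / 1000) *
        (1 - exp(-horizon_ms / async_tau_ms))
      n_async <- rpois(1, lambda)
      times <- numeric(0)
      if (n_async > 0) {
        # inverse-CDF sampling of the truncated exponential arrival profile
        u <- runif(n_async)
        times <- stim_ms - async_tau_ms *
          log(1 - u * (1 - exp(-horizon_ms / async_tau_ms)))
        times <- sort(times)
        for (tt in times) {
          idx0 <- round(tt / dt_ms) + 1
          wf <- simulate_quantal_event(model, dt_ms, ev_dur)
          idx <- idx0:min(idx0 + length(wf) - 1, n_samp)
          mat[idx, sw] <- mat[idx, sw] + wf[seq_along(idx)]
        }
      }
      rows <- tibble::tibble(
        sweep = sw,
        time_ms = c(stim_ms, times),
        kind = c("synchronous", rep("asynchronous", length(times))),
        failure = FALSE
      )
    }
    truth[[sw]] <- rows
  }
  rec <- sweep_recording(mat, dt_ms = dt_ms, holding_mv = model$e_rev - 60,
                         stimulus_times = stim_ms,
                         label = "simulated Sr2+ session")
  list(recording = rec, truth = dplyr::bind_rows(truth))
}

#' Vesicle-depletion occupancy states for a stimulus train
#'
#' Release-site occupancy under depression: starting from full occupancy
#' `R[1] = 1`, each pulse releases a fraction `f` of the available
#' resource, which then recovers toward 1 with time constant `tau_rec_ms`
#' over the inter-pulse interval `dt_ms`:
#' `R[n+1] = R[n](1-f) + (1 - R[n](1-f)) (1 - exp(-dt/tau_rec))`.
#' Per-pulse amplitudes are proportional to `f * R[n]`.
#'
#' @param f Release fraction in (0, 1].
#' @param tau_rec_ms Recovery time constant (ms, > 0).
#' @param n_pulses Number of pulses (>= 2).
#' @param dt_ms Inter-pulse interval (ms).
#' @return Numeric vector `R` of length `n_pulses`, all in (0, 1].
#' @export
depletion_states <- function(f, tau_rec_ms, n_pulses, dt_ms) {
  stopifnot(f > 0, f <= 1, tau_rec_ms > 0, n_pulses >= 1, dt_ms > 0)
  r <- numeric(n_pulses)
  r[1] <- 1
  rec_frac <- 1 - exp(-dt_ms / tau_rec_ms)
  for (n in seq_len(n_pulses - 1)) {
    left <- r[n] * (1 - f)
    r[n + 1] <- left + (1 - left) * rec_frac
  }
  r
}

#' Simulate a high-frequency stimulus train with vesicle depletion
#'
#' Evoked amplitudes follow the resource-depletion recursion of
#' [depletion_states()]; each sweep renders the train as scaled mean EPSC
#' shapes plus Gaussian noise. The ground-truth paired-pulse ratio is
#' `R[2]/R[1]`.
#'
#' @param model A [quantal_model()] supplying the EPSC shape.
#' @param n_pulses Number of stimuli (>= 2).
#' @param freq_hz Train frequency (Hz).
#' @param f,tau_rec_ms Depletion parameters; see [depletion_states()].
#' @param a1_pa First-pulse peak amplitude (pA, negative for inward).
#' @param n_sweeps Number of repeated sweeps.
#' @param noise_sd_pa Baseline noise SD (pA).
#' @param dt_ms Sampling interval (ms).
#' @param pre_ms Quiet baseline before the first stimulus (ms).
#' @param post_ms Tail after the last stimulus (ms).
#' @param seed Optional integer seed.
#' @return A list with `amplitudes` (tibble: pulse, r_state, amplitude_pa,
#'   ppr_true) and `recording` (a [sweep_recording()] with stimulus times).
#' @export
simulate_train <- function(model, n_pulses = 5, freq_hz = 100, f = 0.4,
                           tau_rec_ms = 50, a1_pa = -100, n_sweeps = 10,
                           noise_sd_pa = 1, dt_ms = 0.05, pre_ms = 20,
                           post_ms = 50, seed = NULL) {
  stopifnot(inherits(model, "quantal_model"), n_pulses >= 2, freq_hz > 0)
  if (!is.null(seed)) set.seed(seed)
  ipi_ms <- 1000 / freq_hz
  r <- depletion_states(f, tau_rec_ms, n_pulses, ipi_ms)
  amps <- a1_pa * r / r[1]
  stim_times <- pre_ms + (seq_len(n_pulses) - 1) * ipi_ms
  sweep_ms <- pre_ms + (n_pulses - 1) * ipi_ms + post_ms
  n_samp <- floor(sweep_ms / dt_ms) + 1
  t_grid <- seq(0, by = dt_ms, length.out = n_samp)
  clean <- numeric(n_samp)
  for (k in seq_len(n_pulses)) {
    shape <- mean_epsc_shape(t_grid - stim_times[k],
                             model$tau_rise_ms, model$tau_decay_ms) *
      (t_grid >= stim_times[k])
    clean <- clean + amps[k] * shape
  }
  mat <- matrix(rnorm(n_samp * n_sweeps, 0, noise_sd_pa), nrow = n_samp) + clean
  rec <- sweep_recording(mat, dt_ms = dt_ms, holding_mv = -70,
                         stimulus_times = stim_times,
                         label = "simulated evoked train")
  list(
    amplitudes = tibble::tibble(pulse = seq_len(n_pulses), r_state = r,
                                amplitude_pa = amps,
                                ppr_true = r[2] / r[1]),
    recording = rec
  )
}
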