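#' Quantal event model
#'
#' Parameters of the stochastic channel-gating model that generates single
#' quantal currents: all `n_p` channels open at onset (scaled by a smooth
#' rise envelope with time constant `tau_rise_ms`), and each channel closes
#' after an independent exponential lifetime with mean `tau_decay_ms`. The
#' instantaneous current is `i_pa` times the number of channels still open,
#' so the ensemble mean decay is `i_pa * n_p * exp(-t/tau_decay_ms)` and the
#' peak-scaled variance follows the parabola
#' `sigma^2 = i*I - I^2/n_p` (binomial variance of the surviving-channel
#' count).
#'
#' @param n_p Number of channels open at the peak (integer >= 1).
#' @param i_pa Unitary single-channel current at the holding potential (pA;
#'   negative for inward current).
#' @param tau_rise_ms Rise (activation) time constant (ms, >= 0; 0 gives a
#'   step onset).
#' @param tau_decay_ms Mean channel open lifetime (ms, > 0).
#' @param e_rev Reversal potential (mV).
#' @return A list of class `quantal_model`.
#' @export
quantal_model <- function(n_p = 20, i_pa = -0.69, tau_rise_ms = 0.15,
                          tau_decay_ms = 1.3, e_rev = 0) {
  stopifnot(n_p >= 1, n_p == round(n_p), tau_rise_ms >= 0, tau_decay_ms > 0,
            i_pa != 0)
  structure(list(n_p = as.integer(n_p), i_pa = i_pa,
                 tau_rise_ms = tau_rise_ms, tau_decay_ms = tau_decay_ms,
                 e_rev = e_rev),
            class = "quantal_model")
}

rise_envelope <- function(t_ms, tau_rise_ms) {
  if (tau_rise_ms <= 0) as.numeric(t_ms >= 0) else 1 - exp(-t_ms / tau_rise_ms)
}

#' Deterministic mean EPSC shape
#'
#' The noiseless ensemble-mean waveform of [quantal_model()] gating,
#' `(1 - exp(-t/tau_rise)) * exp(-t/tau_decay)`, normalized to unit peak.
#'
#' @param t_ms Times from onset (ms).
#' @param tau_rise_ms,tau_decay_ms Rise and decay time constants (ms).
#' @return Numeric vector, peak value 1.
#' @export
mean_epsc_shape <- function(t_ms, tau_rise_ms, tau_decay_ms) {
  tt <- pmax(t_ms, 0)  # zero before onset
  raw <- rise_envelope(tt, tau_rise_ms) * exp(-tt / tau_decay_ms) *
    (t_ms >= 0)
  if (tau_rise_ms <= 0) return(raw)
  t_peak <- tau_rise_ms * log1p(tau_decay_ms / tau_rise_ms)
  pk <- (1 - exp(-t_peak / tau_rise_ms)) * exp(-t_peak / tau_decay_ms)
  raw / pk
}

#' Simulate one stochastic quantal event
#'
#' Draws one realization of the channel-gating model on a uniform time
#' grid starting at onset. The deterministic rise envelope (normalized
#' `1 - exp(-t/tau_rise)`) reaches 1 at `5 * tau_rise_ms`, where all
#' `n_p` channels are open — so the peak current is exactly
#' `i_pa * n_p` with zero variance. From the peak onward each channel
#' closes after an independent exponential lifetime, giving an ensemble
#' mean decay of `i_pa * n_p * exp(-t'/tau_decay)` and a binomial
#' open-count variance that is exactly the peak-scaled parabola
#' `sigma2 = i*I - I^2/n_p`.
#'
#' @param model A [quantal_model()].
#' @param dt_ms Sampling interval (ms, > 0).
#' @param duration_ms Length of the returned waveform (ms); default
#'   `10 * tau_decay_ms`.
#' @return Numeric vector of current (pA) sampled at `dt_ms` from onset.
#' @export
simulate_quantal_event <- function(model, dt_ms,
                                   duration_ms = 10 * model$tau_decay_ms) {
  stopifnot(inherits(model, "quantal_model"), dt_ms > 0)
  t <- seq(0, duration_ms, by = dt_ms)
  t_peak <- 5 * model$tau_rise_ms
  env <- if (model$tau_rise_ms <= 0) {
    rep(1, length(t))
  } else {
    pmin(rise_envelope(t, model$tau_rise_ms) /
           rise_envelope(t_peak, model$tau_rise_ms), 1)
  }
  lifetimes <- rexp(model$n_p, rate = 1 / model$tau_decay_ms)
  # channels start their exponential closing clocks at the peak
  t_decay <- pmax(t - t_peak, 0)
  n_open <- vapply(t_decay, function(tt) sum(lifetimes > tt), numeric(1))
  n_open[t < t_peak] <- model$n_p
  model$i_pa * env * n_open
}

#' Simulate a miniature EPSC recording
#'
#' Superimposes Poisson-timed stochastic quantal events on Gaussian
#' baseline noise, returning the recording together with a per-event
#' ground-truth table (true onset times, true peak amplitudes, and an
#' overlap flag marking events whose footprints collide).
#'
#' @param model A [quantal_model()].
#' @param n_sweeps Number of sweeps.
#' @param sweep_ms Sweep duration (ms).
#' @param rate_hz Mean event rate (events per second).
#' @param noise_sd_pa Baseline Gaussian noise SD (pA).
#' @param dt_ms Sampling interval (ms).
#' @param holding_mv Holding potential (mV).
#' @param footprint_ms Event footprint used for the overlap flag (ms).
#' @param seed Optional integer seed.
#' @return A list with elements `recording` ([sweep_recording()]) and
#'   `truth` (tibble: sweep, onset_ms, peak_pa, overlapped).
#' @export
simulate_mepsc_recording <- function(model, n_sweeps = 1, sweep_ms = 10000,
                                     rate_hz = 3, noise_sd_pa = 1,
                                     dt_ms = 0.05, holding_mv = -60,
                                     footprint_ms = 10, seed = NULL) {
  stopifnot(inherits(model, "quantal_model"), rate_hz >= 0, noise_sd_pa >= 0)
  if (!is.null(seed)) set.seed(seed)
  n_samp <- floor(sweep_ms / dt_ms) + 1
  ev_dur <- 10 * model$tau_decay_ms
  truth <- vector("list", n_sweeps)
  mat <- matrix(rnorm(n_samp * n_sweeps, 0, noise_sd_pa), nrow = n_samp)
  for (sw in seq_len(n_sweeps)) {
    n_ev <- rpois(1, rate_hz * sweep_ms / 1000)
    if (n_ev == 0) {
      truth[[sw]] <- tibble::tibble(sweep = integer(), onset_ms = numeric(),
                                    peak_pa = numeric(), overlapped = logical())
      next
    }
    onsets <- sort(runif(n_ev, 0, sweep_ms - ev_dur))
    onset_idx <- round(onsets / dt_ms) + 1
    peaks <- numeric(n_ev)
    for (j in seq_len(n_ev)) {
      wf <- simulate_quantal_event(model, dt_ms, ev_dur)
      idx <- onset_idx[j]:min(onset_idx[j] + length(wf) - 1, n_samp)
      mat[idx, sw] <- mat[idx, sw] + wf[seq_along(idx)]
      peaks[j] <- wf[which.max(abs(wf))]
    }
    gaps_ok <- rep(TRUE, n_ev)
    if (n_ev > 1) {
      d_prev <- c(Inf, diff(onsets))
      d_next <- c(diff(onsets), Inf)
      gaps_ok <- d_prev >= footprint_ms & d_next >= footprint_ms
    }
    truth[[sw]] <- tibble::tibble(sweep = sw, onset_ms = onset_idx * dt_ms - dt_ms,
                                  peak_pa = peaks, overlapped = !gaps_ok)
  }
  truth <- dplyr::bind_rows(truth)
  if (nrow(truth) > 0 && mean(truth$overlapped) > 0.5) {
    warn("More than half of simulated events overlap; consider lowering `rate_hz`.")
  }
  rec <- sweep_recording(mat, dt_ms = dt_ms, holding_mv = holding_mv,
                         label = "simulated mEPSC recording")
  list(recording = rec, truth = truth)
}
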