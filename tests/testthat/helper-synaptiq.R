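# Shared fixtures, all generated in code.

# Controlled aligned ensemble straight from the gating simulator: known
# alignment (no detection machinery), optional Gaussian noise.
make_ensemble <- function(n_events, model = quantal_model(), noise_sd = 0,
                          dt = 0.05, pre_ms = 2, decay_ms = 15, seed = 1) {
  set.seed(seed)
  pre <- round(pre_ms / dt)
  nc <- pre + round(decay_ms / dt) + 1
  wf <- matrix(0, n_events, nc)
  for (e in seq_len(n_events)) {
    w <- simulate_quantal_event(model, dt, decay_ms)
    wf[e, (pre + 1):nc] <- w[seq_len(nc - pre)]
  }
  if (noise_sd > 0) wf <- wf + rnorm(length(wf), 0, noise_sd)
  structure(list(
    waveforms = wf,
    time_ms = (seq_len(nc) - pre - 1) * dt,
    align_index = pre + 1L,
    mean_pa = colMeans(wf),
    sem_pa = apply(wf, 2, sd) / sqrt(n_events),
    dt_ms = dt,
    events = tibble::tibble(sweep = seq_len(n_events))
  ), class = "event_ensemble")
}

# Noiseless recording with deterministic EPSC shapes injected at known
# times; amplitudes in pA (signed).
make_clean_recording <- function(onsets_ms, amplitudes_pa, sweep_ms = 2000,
                                 dt = 0.05, tau_rise = 0.15, tau_decay = 1.3,
                                 n_sweeps = 1, noise_sd = 0,
                                 stimulus_times = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- round(sweep_ms / dt) + 1
  t <- seq(0, by = dt, length.out = n)
  mat <- matrix(if (noise_sd > 0) rnorm(n * n_sweeps, 0, noise_sd) else 0,
                nrow = n, ncol = n_sweeps)
  if (!is.list(onsets_ms)) onsets_ms <- list(onsets_ms)
  if (!is.list(amplitudes_pa)) amplitudes_pa <- list(amplitudes_pa)
  if (length(onsets_ms) == 1) onsets_ms <- rep(onsets_ms, n_sweeps)
  if (length(amplitudes_pa) == 1) amplitudes_pa <- rep(amplitudes_pa, n_sweeps)
  for (sw in seq_len(n_sweeps)) {
    for (j in seq_along(onsets_ms[[sw]])) {
      sh <- mean_epsc_shape(t - onsets_ms[[sw]][j], tau_rise, tau_decay) *
        (t >= onsets_ms[[sw]][j])
      mat[, sw] <- mat[, sw] + amplitudes_pa[[sw]][j] * sh
    }
  }
  sweep_recording(mat, dt_ms = dt, holding_mv = -60,
                  stimulus_times = stimulus_times)
}

# Exhaustive-permutation two-sided p for the Mann-Whitney count, used as
# the independent oracle for wilcoxon_rank_sum().
brute_force_ranksum <- function(x, y) {
  nx <- length(x)
  n <- nx + length(y)
  pooled <- c(x, y)
  u_obs <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  combos <- utils::combn(n, nx)
  us <- apply(combos, 2, function(idx) {
    xs <- pooled[idx]
    ys <- pooled[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  })
  p_lo <- mean(us <= u_obs)
  p_hi <- mean(us >= u_obs)
  list(W = u_obs, p = min(1, 2 * min(p_lo, p_hi)))
}
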