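#' Robust baseline noise estimate
#'
#' Location and scale of the event-free baseline: median, and SD from the
#' median absolute deviation scaled to the Gaussian (so sparse synaptic
#' events barely perturb the estimate).
#'
#' @param recording A [sweep_recording()].
#' @param window_ms Optional length-2 time window (ms) restricted to an
#'   event-free / stimulus-free segment; default uses the whole recording.
#' @return One-row tibble: `mean_pa`, `sd_pa`, `n_samples`.
#' @export
estimate_baseline_noise <- function(recording, window_ms = NULL) {
  stopifnot(inherits(recording, "sweep_recording"))
  x <- recording$current_pa
  if (!is.null(window_ms)) {
    stopifnot(length(window_ms) == 2)
    sel <- recording$time_ms >= window_ms[1] & recording$time_ms <= window_ms[2]
    x <- x[sel]
  }
  if (length(x) < 20) abort("Baseline window must contain >= 20 samples.")
  tibble::tibble(mean_pa = median(x),
                 sd_pa = mad(x, constant = 1.4826),
                 n_samples = length(x))
}

boxcar3 <- function(x) {
  n <- length(x)
  if (n < 3) return(x)
  y <- (c(x[1], x[-n]) + x + c(x[-1], x[n])) / 3
  y
}

#' Threshold-crossing event detection
#'
#' Detects inward (negative-going) synaptic events as contiguous
#' excursions of the baseline-subtracted current beyond
#' `-k * noise_sd_pa`. Excursions separated by less than `merge_ms` are
#' merged into one event (refractory merging). The event peak is the
#' signed extremum of the excursion; the onset is the last pre-peak
#' crossing of baseline minus one noise SD, searched backward from the
#' threshold crossing.
#'
#' @param recording A [sweep_recording()].
#' @param k Threshold multiplier (> 0); the threshold is `k * noise_sd_pa`
#'   in pA. Values below 2 trigger a high-false-positive warning.
#' @param noise_sd_pa Baseline noise SD (pA); estimated with
#'   [estimate_baseline_noise()] when NULL.
#' @param merge_ms Refractory merge window (ms). Default 1.
#' @param smooth_ms Boxcar smoothing width applied to the trace before
#'   thresholding (ms); 0 disables. The default 0.3 ms emulates the ~2 kHz
#'   acquisition bandwidth of patch-clamp recordings sampled at 20 kHz;
#'   without band-limiting, white baseline noise crosses a 3-SD threshold
#'   tens of times per second. Peak amplitudes are always read from the
#'   unsmoothed trace.
#' @param baseline_ms Pre-onset window used for the local event baseline
#'   (ms).
#' @return A tibble with one row per event: `sweep`, `onset_ms`,
#'   `peak_ms`, `peak_pa` (baseline-subtracted, signed), `baseline_pa`,
#'   and screening flags (`monotonic_rise`, `clean_decay`,
#'   `post_stimulus_ok`, NA until [screen_events()] runs).
#' @export
detect_events <- function(recording, k = 3, noise_sd_pa = NULL,
                          merge_ms = 1, smooth_ms = 0.3, baseline_ms = 5) {
  stopifnot(inherits(recording, "sweep_recording"), k > 0)
  if (is.null(noise_sd_pa)) {
    noise_sd_pa <- estimate_baseline_noise(recording)$sd_pa
  }
  if (k < 2) {
    warn("Detection threshold below 2 x noise SD: high false-positive regime.")
  }
  dt <- rec_dt(recording)
  thr <- k * noise_sd_pa
  merge_n <- max(1L, round(merge_ms / dt))
  base_n <- max(1L, round(baseline_ms / dt))
  mat <- sweep_matrix(recording)
  out <- vector("list", ncol(mat))
  for (sw in seq_len(ncol(mat))) {
    raw <- mat[, sw]
    b0 <- median(raw)
    x <- raw - b0
    if (smooth_ms > 0) {
      w <- max(1L, round(smooth_ms / dt))
      x <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
      x[is.na(x)] <- 0
    }
    below <- x < -thr
    if (!any(below)) {
      out[[sw]] <- NULL
      next
    }
    r <- rle(below)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    runs <- cbind(starts[r$values], ends[r$values])
    # refractory merging of nearby excursions
    if (nrow(runs) > 1) {
      keep <- list(runs[1, ])
      for (j in 2:nrow(runs)) {
        last <- keep[[length(keep)]]
        if (runs[j, 1] - last[2] <= merge_n) {
          keep[[length(keep)]] <- c(last[1], runs[j, 2])
        } else {
          keep[[length(keep) + 1]] <- runs[j, ]
        }
      }
      runs <- do.call(rbind, keep)
    }
    ev <- apply(runs, 1, function(rg) {
      seg <- rg[1]:rg[2]
      pk <- seg[which.min(x[seg])]
      # onset: last pre-peak sample above -1 SD, searched backward
      on <- rg[1]
      while (on > 1 && x[on - 1] < -noise_sd_pa) on <- on - 1
      b_lo <- max(1, on - base_n)
      local_base <- if (on - 1 >= b_lo) median(raw[b_lo:(on - 1)]) else b0
      c(onset = on, peak = pk, base = local_base, amp = raw[pk] - local_base)
    })
    ev <- t(ev)
    out[[sw]] <- tibble::tibble(
      sweep = sw,
      onset_ms = unname(ev[, "onset"] - 1) * dt,
      peak_ms = unname(ev[, "peak"] - 1) * dt,
      peak_pa = unname(ev[, "amp"]),
      baseline_pa = unname(ev[, "base"])
    )
  }
  ev <- dplyr::bind_rows(out)
  if (nrow(ev) == 0) {
    ev <- tibble::tibble(sweep = integer(), onset_ms = numeric(),
                         peak_ms = numeric(), peak_pa = numeric(),
                         baseline_pa = numeric())
  }
  dplyr::mutate(ev, monotonic_rise = NA, clean_decay = NA,
                post_stimulus_ok = NA)
}

#' Screen detected events for analysis inclusion
#'
#' Sets the three screening flags: `monotonic_rise` is TRUE iff the
#' 3-sample-boxcar-smoothed trace has no slope sign reversal between onset
#' and peak; `clean_decay` is TRUE iff no other event begins within
#' `decay_ms` after the peak (an uncontaminated decay);
#' `post_stimulus_ok` is TRUE iff the peak falls more than `exclusion_ms`
#' after the sweep's stimulus (always TRUE without stimulus times).
#'
#' @param events Event tibble from [detect_events()].
#' @param recording The [sweep_recording()] the events were detected on.
#' @param decay_ms Decay-contamination window after the peak (ms).
#' @param exclusion_ms Post-stimulus exclusion window (ms).
#' @param slope_tol_pa Slope reversals smaller than this (pA per sample)
#'   are ignored in the monotonic-rise check. Default: twice the SD of
#'   the smoothed-slope baseline noise (`2 * sqrt(2)/3 * noise_sd_pa`),
#'   so sub-noise wiggles near the rounded peak do not reject an
#'   otherwise monotonic rise; exactly 0 for a noiseless recording.
#' @param noise_sd_pa Baseline noise SD (pA) used for the default slope
#'   tolerance; estimated from the recording when NULL.
#' @return The event tibble with flags filled in.
#' @export
screen_events <- function(events, recording, decay_ms = 15,
                          exclusion_ms = 10, slope_tol_pa = NULL,
                          noise_sd_pa = NULL) {
  stopifnot(inherits(recording, "sweep_recording"))
  if (nrow(events) == 0) return(events)
  if (is.null(slope_tol_pa)) {
    if (is.null(noise_sd_pa)) {
      noise_sd_pa <- estimate_baseline_noise(recording)$sd_pa
    }
    slope_tol_pa <- 2 * sqrt(2) / 3 * noise_sd_pa
  }
  dt <- rec_dt(recording)
  mat <- sweep_matrix(recording)
  stims <- rec_stims(recording)
  mono <- logical(nrow(events))
  clean <- logical(nrow(events))
  post_ok <- logical(nrow(events))
  for (j in seq_len(nrow(events))) {
    sw <- events$sweep[j]
    on_i <- round(events$onset_ms[j] / dt) + 1
    pk_i <- round(events$peak_ms[j] / dt) + 1
    seg <- boxcar3(mat[on_i:pk_i, sw])
    d <- diff(seg)
    sgn <- sign(events$peak_pa[j])  # inward events rise downward
    mono[j] <- length(d) == 0 || all(sgn * d >= -slope_tol_pa)
    # a later event peaking inside the decay window marks a second
    # threshold crossing contaminating this decay
    later <- events$sweep == sw &
      events$peak_ms > events$peak_ms[j] &
      events$peak_ms <= events$peak_ms[j] + decay_ms
    clean[j] <- !any(later)
    if (is.null(stims) || length(stims[[sw]]) == 0) {
      post_ok[j] <- TRUE
    } else {
      post_ok[j] <- all(events$peak_ms[j] > stims[[sw]] + exclusion_ms |
                        events$peak_ms[j] < stims[[sw]])
    }
  }
  dplyr::mutate(events, monotonic_rise = mono, clean_decay = clean,
                post_stimulus_ok = post_ok)
}

#' Align events on their rising phase and average
#'
#' Each event waveform is aligned at its point of steepest rise (maximum
#' |dI/dt| between onset and peak, on the 3-sample-smoothed trace) and a
#' fixed window around that point is extracted. Events whose window would
#' extend beyond the sweep are dropped. The mean waveform and per-sample
#' SEM are computed column-wise.
#'
#' @param events Event tibble (typically screened and filtered).
#' @param recording The source [sweep_recording()].
#' @param pre_ms,post_ms Window before/after the alignment point (ms).
#' @return An object of class `event_ensemble`: list with the aligned
#'   waveform matrix (events x samples, local-baseline subtracted), time
#'   axis, alignment index, mean, SEM, and the source event rows.
#' @export
align_and_average <- function(events, recording, pre_ms = 5, post_ms = 15) {
  stopifnot(inherits(recording, "sweep_recording"))
  if (nrow(events) == 0) abort("No events to align.")
  dt <- rec_dt(recording)
  mat <- sweep_matrix(recording)
  n_pre <- round(pre_ms / dt)
  n_post <- round(post_ms / dt)
  rows <- vector("list", nrow(events))
  kept <- logical(nrow(events))
  for (j in seq_len(nrow(events))) {
    sw <- events$sweep[j]
    on_i <- round(events$onset_ms[j] / dt) + 1
    pk_i <- round(events$peak_ms[j] / dt) + 1
    seg <- boxcar3(mat[on_i:pk_i, sw])
    al_i <- if (pk_i > on_i) {
      on_i + which.max(abs(diff(seg))) - 1
    } else {
      pk_i
    }
    lo <- al_i - n_pre
    hi <- al_i + n_post
    if (lo < 1 || hi > nrow(mat)) next
    kept[j] <- TRUE
    rows[[j]] <- mat[lo:hi, sw] - events$baseline_pa[j]
  }
  if (!any(kept)) abort("No events fit inside the alignment window.")
  wf <- do.call(rbind, rows[kept])
  mean_wf <- colMeans(wf)
  sem_wf <- if (nrow(wf) > 1) apply(wf, 2, sd) / sqrt(nrow(wf)) else
    rep(0, ncol(wf))
  structure(list(
    waveforms = wf,
    time_ms = seq(-n_pre, n_post) * dt,
    align_index = n_pre + 1L,
    mean_pa = mean_wf,
    sem_pa = sem_wf,
    dt_ms = dt,
    events = events[kept, , drop = FALSE]
  ), class = "event_ensemble")
}

#' @export
print.event_ensemble <- function(x, ...) {
  cat(sprintf("<event_ensemble> %d events x %d samples, dt %.4g ms, peak %.3g pA\n",
              nrow(x$waveforms), ncol(x$waveforms), x$dt_ms,
              x$mean_pa[which.max(abs(x$mean_pa))]))
  invisible(x)
}

#' @describeIn align_and_average Tidy the ensemble mean: one row per sample
#'   with `time_ms`, `mean_pa`, `sem_pa`.
#' @param x An `event_ensemble`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.event_ensemble <- function(x, ...) {
  tibble::tibble(time_ms = x$time_ms, mean_pa = x$mean_pa, sem_pa = x$sem_pa)
}
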