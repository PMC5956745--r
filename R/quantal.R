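#' Analyze a strontium-substitution quantal release session
#'
#' Separates each sweep's response to a single stimulus into the
#' synchronous initial EPSC (events peaking within `exclusion_ms` of the
#' stimulus) and asynchronous quantal EPSCs (events peaking more than
#' `exclusion_ms` after it, excluded earlier to avoid multiquantal
#' contamination). Counting uses every event with a distinct peak;
#' amplitude statistics use only events with a monotonic rise (overlapping
#' decays allowed). A failure is a sweep with no detected response at all
#' after the stimulus. The initial EPSC amplitude is reported both over
#' non-failure sweeps and over all sweeps (failures contributing zero).
#'
#' @param recording A [sweep_recording()] with exactly one stimulus time
#'   per sweep.
#' @param events Event tibble from [detect_events()]; screened with
#'   [screen_events()] first if the flags are still NA.
#' @param exclusion_ms Post-stimulus exclusion window (ms). Default 10.
#' @return An object of class `sr2_summary` with a per-sweep table and
#'   scalar summaries; see [glance.sr2_summary()].
#' @export
analyze_sr2_session <- function(recording, events, exclusion_ms = 10) {
  stopifnot(inherits(recording, "sweep_recording"))
  stims <- rec_stims(recording)
  if (is.null(stims)) abort("Recording has no stimulus times.")
  n_stim <- lengths(stims)
  if (any(n_stim != 1)) abort("Every sweep must have exactly one stimulus.")
  if (nrow(events) > 0 && all(is.na(events$monotonic_rise))) {
    events <- screen_events(events, recording, exclusion_ms = exclusion_ms)
  }
  n_sw <- n_sweeps(recording)
  per_sweep <- purrr::map_dfr(seq_len(n_sw), function(sw) {
    t_stim <- stims[[sw]][1]
    ev <- dplyr::filter(events, .data$sweep == sw, .data$peak_ms >= t_stim)
    async <- dplyr::filter(ev, .data$peak_ms > t_stim + exclusion_ms)
    sync <- dplyr::filter(ev, .data$peak_ms <= t_stim + exclusion_ms)
    init <- if (nrow(sync)) sync$peak_pa[which.max(abs(sync$peak_pa))] else NA_real_
    tibble::tibble(
      sweep = sw, stim_ms = t_stim,
      n_qepsc = nrow(async),
      failure = nrow(ev) == 0,
      initial_pa = init
    )
  })
  amp_events <- dplyr::filter(
    events, .data$monotonic_rise %in% TRUE,
    purrr::map2_lgl(.data$sweep, .data$peak_ms,
                    function(sw, pk) pk > stims[[sw]][1] + exclusion_ms)
  )
  structure(list(
    per_sweep = per_sweep,
    qepsc_amplitudes = amp_events$peak_pa,
    exclusion_ms = exclusion_ms,
    n_sweeps = n_sw
  ), class = "sr2_summary")
}

#' @export
print.sr2_summary <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(paste0(
    "<sr2_summary> %d sweeps: failure rate %.3g, mean qEPSC count %.3g, ",
    "mean qEPSC amplitude %.3g pA\n"),
    g$n_sweeps, g$failure_rate, g$mean_qepsc_count, g$mean_qepsc_pa))
  invisible(x)
}

#' @describeIn analyze_sr2_session Per-sweep table: `sweep`, `stim_ms`,
#'   `n_qepsc`, `failure`, `initial_pa`.
#' @param x An `sr2_summary`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.sr2_summary <- function(x, ...) x$per_sweep

#' One-row summary of an Sr2+ session
#'
#' Columns: `n_sweeps`, `failure_rate`, `mean_qepsc_count` (asynchronous
#' events per sweep, post-exclusion), `mean_qepsc_pa` (mean amplitude of
#' monotonic-rise qEPSCs), `initial_epsc_pa` (mean synchronous amplitude
#' over non-failure sweeps) and `initial_epsc_pa_all` (over all sweeps,
#' failures as 0).
#'
#' @param x An `sr2_summary`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.sr2_summary <- function(x, ...) {
  ps <- x$per_sweep
  init_nonfail <- mean(ps$initial_pa[!ps$failure & !is.na(ps$initial_pa)])
  init_all <- mean(ifelse(ps$failure | is.na(ps$initial_pa), 0, ps$initial_pa))
  tibble::tibble(
    n_sweeps = x$n_sweeps,
    failure_rate = mean(ps$failure),
    mean_qepsc_count = mean(ps$n_qepsc),
    mean_qepsc_pa = if (length(x$qepsc_amplitudes)) {
      mean(x$qepsc_amplitudes)
    } else {
      NA_real_
    },
    initial_epsc_pa = init_nonfail,
    initial_epsc_pa_all = init_all
  )
}

#' Minimal-stimulation acceptance predicate
#'
#' Data-screening check for single-fiber stimulation: an initial failure
#' rate near ~30% during low-frequency stimulation, and invariant EPSC
#' latency and amplitude (low coefficients of variation).
#'
#' @param failure_rate Observed initial failure rate (fraction).
#' @param latency_ms Per-sweep EPSC latencies (ms).
#' @param amplitude_pa Per-sweep EPSC amplitudes (pA).
#' @param fail_range Acceptable failure-rate range. Default c(0.15, 0.45).
#' @param max_latency_cv,max_amplitude_cv Maximum coefficients of
#'   variation for latency and amplitude.
#' @return One-row tibble: `accepted` plus the individual checks.
#' @export
minimal_stimulation_ok <- function(failure_rate, latency_ms, amplitude_pa,
                                   fail_range = c(0.15, 0.45),
                                   max_latency_cv = 0.25,
                                   max_amplitude_cv = 0.5) {
  lat_cv <- sd(latency_ms) / mean(latency_ms)
  amp_cv <- sd(abs(amplitude_pa)) / mean(abs(amplitude_pa))
  ok_fail <- failure_rate >= fail_range[1] && failure_rate <= fail_range[2]
  ok_lat <- is.finite(lat_cv) && lat_cv <= max_latency_cv
  ok_amp <- is.finite(amp_cv) && amp_cv <= max_amplitude_cv
  tibble::tibble(
    accepted = ok_fail && ok_lat && ok_amp,
    failure_rate_ok = ok_fail, latency_ok = ok_lat, amplitude_ok = ok_amp,
    latency_cv = lat_cv, amplitude_cv = amp_cv
  )
}
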