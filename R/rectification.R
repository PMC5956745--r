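#' Slope conductance of an I-V ramp within a voltage window
#'
#' Ordinary least-squares slope of current against voltage restricted to
#' `window` (edges inclusive); pA over mV gives nS.
#'
#' @param ramp An [iv_ramp()].
#' @param window Length-2 voltage window (mV).
#' @return Slope conductance in nS.
#' @export
slope_conductance <- function(ramp, window) {
  stopifnot(inherits(ramp, "iv_ramp"), length(window) == 2)
  window <- sort(window)
  if (window[1] < min(ramp$voltage_mv) || window[2] > max(ramp$voltage_mv)) {
    abort("Window lies outside the ramp's voltage range.")
  }
  sel <- ramp$voltage_mv >= window[1] & ramp$voltage_mv <= window[2]
  if (sum(sel) < 10) abort("Need >= 10 ramp samples inside the window.")
  unname(coef(lm(current_pa ~ voltage_mv, data = ramp[sel, ]))["voltage_mv"])
}

#' Slope-conductance rectification index
#'
#' `RI_slope = G_slope(pos) / G_slope(neg)`, with the slope conductances
#' taken from straight-line fits in the positive (+20..+40 mV) and
#' negative (-40..-20 mV) limbs of the I-V relation. Values well below 1
#' indicate inward rectification (calcium-permeable, GluA2-lacking AMPA
#' receptors under intracellular spermine).
#'
#' @param ramp An [iv_ramp()].
#' @param neg_window,pos_window Voltage windows (mV).
#' @return One-row tibble of class `rectification_result`: `g_neg_ns`,
#'   `g_pos_ns`, `ri_slope`.
#' @export
ri_slope <- function(ramp, neg_window = c(-40, -20), pos_window = c(20, 40)) {
  g_neg <- slope_conductance(ramp, neg_window)
  g_pos <- slope_conductance(ramp, pos_window)
  if (g_neg <= 0) abort("RI undefined: negative-limb conductance <= 0.")
  out <- tibble::tibble(g_neg_ns = g_neg, g_pos_ns = g_pos,
                        ri_slope = g_pos / g_neg)
  class(out) <- c("rectification_result", class(out))
  out
}

#' Count-matched rectification index from mEPSC populations
#'
#' The mean peak conductance of all events detected at the positive
#' potential, divided by the mean peak conductance of an equal number of
#' the largest-magnitude events detected at the negative potential.
#' Largest is judged by amplitude magnitude. Ties at the cutoff magnitude
#' are by default weighted fractionally (all tied events share the
#' marginal count); `ties = "exact_k"` truncates at exactly k events.
#'
#' @param peaks_pos_pa Event peak amplitudes at the positive potential
#'   (pA, signed), or an event tibble with a `peak_pa` column.
#' @param peaks_neg_pa Event peak amplitudes at the negative potential;
#'   must be at least as many as `peaks_pos_pa`.
#' @param v_pos,v_neg Holding potentials (mV).
#' @param e_rev Reversal potential (mV).
#' @param ties Tie handling at the count-match cutoff.
#' @return One-row tibble of class `rectification_result`: `ri_cm`,
#'   `n_events_pos`, `n_events_neg`, mean conductances.
#' @export
ri_count_matched <- function(peaks_pos_pa, peaks_neg_pa, v_pos = 60,
                             v_neg = -60, e_rev = 0,
                             ties = c("fractional", "exact_k")) {
  ties <- match.arg(ties)
  if (is.data.frame(peaks_pos_pa)) peaks_pos_pa <- peaks_pos_pa$peak_pa
  if (is.data.frame(peaks_neg_pa)) peaks_neg_pa <- peaks_neg_pa$peak_pa
  n_pos <- length(peaks_pos_pa)
  n_neg <- length(peaks_neg_pa)
  if (n_pos < 1 || n_neg < 1) abort("Need >= 1 event at each potential.")
  if (n_neg < n_pos) {
    abort("Cannot count-match: fewer negative-potential events than positive.")
  }
  g_pos <- event_conductance(peaks_pos_pa, v_pos, e_rev)
  mags <- abs(peaks_neg_pa)
  g_neg_all <- event_conductance(peaks_neg_pa, v_neg, e_rev)
  ord <- order(mags, decreasing = TRUE)
  k <- n_pos
  if (ties == "exact_k") {
    g_neg_mean <- mean(g_neg_all[ord][seq_len(k)])
  } else {
    cutoff <- mags[ord][k]
    full <- mags > cutoff
    tied <- mags == cutoff
    w_tied <- (k - sum(full)) / sum(tied)
    wts <- full + tied * w_tied
    g_neg_mean <- sum(wts * g_neg_all) / k
  }
  mean_g_pos <- mean(g_pos)
  out <- tibble::tibble(
    ri_cm = mean_g_pos / g_neg_mean,
    mean_g_pos_ns = mean_g_pos, mean_g_neg_ns = g_neg_mean,
    n_events_pos = n_pos, n_events_neg = n_neg
  )
  class(out) <- c("rectification_result", class(out))
  out
}
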