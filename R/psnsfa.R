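#' Peak-scaled non-stationary fluctuation analysis
#'
#' Estimates the weighted-mean single-channel current `i`, the number of
#' channels open at the peak `N_p`, and the background variance from the
#' fluctuation of individual events about their peak-scaled ensemble mean.
#' The ensemble mean waveform is scaled to each event's peak; decay-phase
#' samples (peak onward) are assigned to `n_bins` equal-amplitude bins of
#' the scaled mean; within each bin the squared deviation of the event
#' from the scaled mean is pooled across events; and the binned
#' variance-mean pairs are fitted by least squares to the parabola
#'
#'   `sigma2_PS = i * I - I^2 / N_p + sigma2_B`
#'
#' The chord conductance `gamma = |i| / |V - E_rev|` is reported in pS.
#'
#' Only the decay phase is used: rise-phase latency jitter inflates the
#' variance for reasons unrelated to channel gating. Event peaks are
#' measured on the 3-sample-smoothed waveform near the ensemble peak so
#' that baseline noise perturbs the scaling factors as little as possible.
#'
#' @param ensemble An [align_and_average()] `event_ensemble` of screened
#'   events.
#' @param n_bins Number of equal-amplitude bins (>= 3). Default 30.
#' @param v_mv Holding potential (mV). Default -60.
#' @param e_rev Reversal potential (mV). Default 0.
#' @param min_events Quality floor: refuse the fit below this many events.
#' @param min_bin_n Bins with fewer pooled samples are excluded from the
#'   fit. Default 5.
#' @param weighted Weight bins by pooled sample count (default TRUE);
#'   FALSE gives plain least squares.
#' @param peak_window_ms Half-width of the search window around the
#'   ensemble peak used to measure each event's peak (ms).
#' @return An object of class `psnsfa_fit`: bin table plus `i_pa`, `n_p`,
#'   `sigma2_b`, `sigma2_b_measured`, `gamma_ps`, `n_events`,
#'   `degenerate`.
#' @export
peak_scaled_nsfa <- function(ensemble, n_bins = 30, v_mv = -60, e_rev = 0,
                             min_events = 10, min_bin_n = 5,
                             weighted = TRUE, peak_window_ms = 1) {
  stopifnot(inherits(ensemble, "event_ensemble"), n_bins >= 3)
  if (v_mv == e_rev) abort("Conductance undefined at the reversal potential.")
  wf <- ensemble$waveforms
  n_ev <- nrow(wf)
  if (n_ev < min_events) {
    abort(sprintf(
      "ps-NSFA refused: %d events is below the quality floor of %d.",
      n_ev, min_events), class = "synaptiq_too_few_events")
  }
  m <- ensemble$mean_pa
  sgn <- sign(m[which.max(abs(m))])
  pk <- which.max(sgn * m)  # ensemble peak sample
  if (pk >= length(m) - 3) abort("No decay phase after the ensemble peak.")
  dt <- ensemble$dt_ms
  w <- max(1L, round(peak_window_ms / dt))
  search <- max(1, pk - w):min(ncol(wf), pk + w)
  decay <- pk:ncol(wf)
  frac <- (sgn * m[decay]) / (sgn * m[pk])  # 1 at peak, -> 0
  frac <- pmin(pmax(frac, 0), 1)
  bin_of <- pmin(pmax(ceiling(frac * n_bins), 1L), n_bins)

  # pooled deviation of each event about its peak-scaled mean
  pooled_i <- vector("list", n_ev)
  pooled_d2 <- vector("list", n_ev)
  scale_fac <- numeric(n_ev)
  for (e in seq_len(n_ev)) {
    sm <- boxcar3(wf[e, ])
    pk_e <- sgn * max(sgn * sm[search])
    s_e <- pk_e / m[pk]
    scale_fac[e] <- s_e
    scaled <- s_e * m[decay]
    d <- wf[e, decay] - scaled
    pooled_i[[e]] <- scaled
    pooled_d2[[e]] <- d * d
  }
  bin_idx <- rep(bin_of, times = n_ev)
  all_i <- unlist(pooled_i)
  all_d2 <- unlist(pooled_d2)
  bins <- tibble::tibble(
    bin = factor(bin_idx, levels = seq_len(n_bins))
  ) |>
    dplyr::mutate(i_pa = all_i, d2 = all_d2) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(i_mean_pa = mean(.data$i_pa),
                     var_ps_pa2 = mean(.data$d2),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(bin = as.integer(as.character(.data$bin)),
                  used = .data$n >= min_bin_n)

  fit_df <- dplyr::filter(bins, .data$used)
  if (nrow(fit_df) < 3) abort("Too few occupied bins for the parabolic fit.")
  wts <- if (weighted) fit_df$n else rep(1, nrow(fit_df))
  fit <- lm(var_ps_pa2 ~ i_mean_pa + I(i_mean_pa^2), data = fit_df,
            weights = wts)
  cf <- coef(fit)
  i_pa <- unname(cf["i_mean_pa"])
  curv <- unname(cf["I(i_mean_pa^2)"])
  degenerate <- !is.finite(curv) || curv >= 0
  if (degenerate) {
    warn("Degenerate ps-NSFA fit: non-negative curvature; N_p unbounded.")
    n_p <- Inf
  } else {
    n_p <- -1 / curv
  }
  sigma2_b <- unname(cf["(Intercept)"])

  # measured background variance from the pre-onset baseline region
  n_base <- max(2L, floor((ensemble$align_index - 1) / 2))
  base_block <- wf[, seq_len(n_base), drop = FALSE]
  sigma2_b_measured <- mean(apply(base_block, 2, var))

  gamma_ps <- abs(i_pa / (v_mv - e_rev)) * 1000  # nS -> pS

  structure(list(
    bins = bins, i_pa = i_pa, n_p = n_p, sigma2_b = sigma2_b,
    sigma2_b_measured = sigma2_b_measured, gamma_ps = gamma_ps,
    v_mv = v_mv, e_rev = e_rev, n_events = n_ev, n_bins = n_bins,
    degenerate = degenerate, weighted = weighted,
    scale_factors = scale_fac
  ), class = "psnsfa_fit")
}

#' @export
print.psnsfa_fit <- function(x, ...) {
  cat(sprintf(paste0(
    "<psnsfa_fit> %d events, %d bins: i = %.3g pA, N_p = %.3g, ",
    "sigma2_B = %.3g pA^2, gamma = %.3g pS%s\n"),
    x$n_events, x$n_bins, x$i_pa, x$n_p, x$sigma2_b, x$gamma_ps,
    if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' @describeIn peak_scaled_nsfa Bin table: one row per amplitude bin with
#'   mean current, peak-scaled variance, occupancy, and whether the bin
#'   entered the fit.
#' @param x A `psnsfa_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.psnsfa_fit <- function(x, ...) x$bins

#' @describeIn peak_scaled_nsfa One-row parameter summary.
#' @exportS3Method generics::glance
glance.psnsfa_fit <- function(x, ...) {
  tibble::tibble(i_pa = x$i_pa, n_p = x$n_p, sigma2_b_pa2 = x$sigma2_b,
                 sigma2_b_measured_pa2 = x$sigma2_b_measured,
                 gamma_ps = x$gamma_ps, v_mv = x$v_mv, e_rev = x$e_rev,
                 n_events = x$n_events, degenerate = x$degenerate)
}

#' @describeIn peak_scaled_nsfa Variance-mean plot with the fitted
#'   parabola.
#' @param object A `psnsfa_fit`.
#' @exportS3Method ggplot2::autoplot
autoplot.psnsfa_fit <- function(object, ...) {
  b <- dplyr::filter(object$bins, .data$used)
  grid <- tibble::tibble(
    i_mean_pa = seq(min(b$i_mean_pa), max(b$i_mean_pa), length.out = 200)
  )
  curv <- if (is.finite(object$n_p)) -1 / object$n_p else 0
  grid$var_fit <- object$i_pa * grid$i_mean_pa +
    curv * grid$i_mean_pa^2 + object$sigma2_b
  ggplot2::ggplot(b, ggplot2::aes(x = .data$i_mean_pa, y = .data$var_ps_pa2)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.7) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$var_fit),
                       colour = "firebrick") +
    ggplot2::geom_hline(yintercept = object$sigma2_b, linetype = "dashed") +
    ggplot2::labs(x = "mean current (pA)",
                  y = "peak-scaled variance (pA²)",
                  size = "samples",
                  title = sprintf("ps-NSFA: i = %.2f pA, N_p = %.1f, gamma = %.1f pS",
                                  object$i_pa, object$n_p, object$gamma_ps)) +
    ggplot2::theme_minimal()
}
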