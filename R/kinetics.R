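#' 10-90% rise time of an event waveform
#'
#' Time between the linearly interpolated crossings of 10% and 90% of the
#' baseline-to-peak amplitude on the rising limb. With a noisy
#' (non-monotonic) rise, the last 10% crossing and the first 90% crossing
#' before the peak are used. Invariant to amplitude scaling and baseline
#' offset.
#'
#' @param waveform Numeric vector containing the rise and peak (signed,
#'   e.g. negative-going for inward current).
#' @param dt_ms Sampling interval (ms).
#' @param baseline Baseline level in the same units as `waveform`.
#' @return Rise time in ms.
#' @export
rise_time_10_90 <- function(waveform, dt_ms, baseline = 0) {
  stopifnot(dt_ms > 0)
  rel <- waveform - baseline
  pk <- which.max(abs(rel))
  amp <- rel[pk]
  if (amp == 0) abort("Peak must differ from baseline.")
  frac <- rel[1:pk] / amp  # rises 0 -> 1 regardless of sign
  i90 <- which(frac >= 0.9)[1]
  if (is.na(i90)) abort("No 90% crossing before the peak.")
  if (i90 == 1) return(dt_ms)  # step rise: resolution-limited
  pre10 <- which(frac[1:(i90 - 1)] <= 0.1)
  cross_at <- function(i, level) {
    # linear interpolation between samples i and i+1
    i + (level - frac[i]) / (frac[i + 1] - frac[i])
  }
  t10 <- if (length(pre10) == 0) 1 else cross_at(max(pre10), 0.1)
  t90 <- cross_at(i90 - 1, 0.9)
  (t90 - t10) * dt_ms
}

#' Fit the decay of an event or averaged waveform
#'
#' Nonlinear least-squares fit of `A_f exp(-t/tau_f) + A_s exp(-t/tau_s)`
#' to the post-peak decay, with single- vs double-exponential selection by
#' BIC, and the amplitude-weighted time constant
#' `tau_w = (A_f tau_f + A_s tau_s) / (A_f + A_s)`.
#'
#' The fit window runs from the first sample (the peak) to the first
#' return within one noise SD of baseline, capped at `cap_tau` times the
#' initial single-exponential estimate (so late baseline drift cannot
#' dominate the fit). Initialization uses the first e-fold time with
#' jittered multistarts.
#'
#' @param waveform Decay-phase samples starting at the peak
#'   (baseline-subtracted, signed).
#' @param dt_ms Sampling interval (ms).
#' @param noise_sd_pa Baseline noise SD used to end the fit window (pA);
#'   0 keeps the full (capped) window.
#' @param model "auto" (BIC selection), "single", or "double".
#' @param cap_tau Fit-window cap as a multiple of the initial tau
#'   estimate.
#' @param n_starts Number of jittered multistarts for the biexponential.
#' @return An object of class `decay_fit` with elements `tau_fast`,
#'   `tau_slow`, `frac_fast`, `frac_slow`, `tau_w`, `model`, `rss`,
#'   `n`, `amplitude_pa`.
#' @export
fit_decay <- function(waveform, dt_ms, noise_sd_pa = 0,
                      model = c("auto", "single", "double"),
                      cap_tau = 10, n_starts = 5) {
  model <- match.arg(model)
  stopifnot(dt_ms > 0)
  s <- sign(waveform[1])
  if (s == 0) s <- sign(waveform[which.max(abs(waveform))])
  y_all <- s * waveform  # positive-going decay
  # fit window: peak to return within 1 noise SD, capped at cap_tau * tau0
  end <- length(y_all)
  if (noise_sd_pa > 0) {
    below <- which(y_all < noise_sd_pa)
    if (length(below)) end <- min(end, below[1])
  }
  tau0 <- efold_time(y_all, dt_ms)
  end <- min(end, max(20L, round(cap_tau * tau0 / dt_ms)))
  if (end < 20) abort("Decay fit window must contain >= 20 samples.")
  y <- y_all[1:end]
  t <- (seq_along(y) - 1) * dt_ms
  df <- data.frame(t = t, y = y)

  fit1 <- try(minpack.lm::nlsLM(
    y ~ A * exp(-t / tau), data = df,
    start = list(A = y[1], tau = tau0),
    lower = c(A = 0, tau = dt_ms / 100),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  ), silent = TRUE)
  rss1 <- if (inherits(fit1, "try-error")) Inf else sum(residuals(fit1)^2)

  fit2 <- NULL
  rss2 <- Inf
  if (model != "single") {
    starts <- bi_starts(y[1], tau0, n_starts)
    for (st in starts) {
      f <- try(minpack.lm::nlsLM(
        y ~ Af * exp(-t / tf) + As * exp(-t / ts), data = df,
        start = st,
        lower = c(Af = 0, As = 0, tf = dt_ms / 100, ts = dt_ms / 100),
        control = minpack.lm::nls.lm.control(maxiter = 300)
      ), silent = TRUE)
      if (!inherits(f, "try-error")) {
        r <- sum(residuals(f)^2)
        if (r < rss2) {
          rss2 <- r
          fit2 <- f
        }
      }
    }
  }
  if (is.infinite(rss1) && is.infinite(rss2)) {
    abort("Decay fit failed to converge from any start.")
  }

  scale2 <- sum(y^2)
  use_single <- switch(model,
    single = TRUE,
    double = FALSE,
    auto = {
      if (rss1 <= 1e-18 * scale2) {
        TRUE  # numerically exact single-exponential: adequate by definition
      } else if (is.infinite(rss2)) {
        TRUE
      } else {
        BIC(fit1) <= BIC(fit2)
      }
    }
  )

  if (use_single) {
    cf <- coef(fit1)
    out <- list(tau_fast = unname(cf["tau"]), tau_slow = unname(cf["tau"]),
                frac_fast = 1, frac_slow = 0, tau_w = unname(cf["tau"]),
                model = "single", rss = rss1, n = end,
                amplitude_pa = s * unname(cf["A"]))
  } else {
    cf <- coef(fit2)
    af <- unname(cf["Af"]); as_ <- unname(cf["As"])
    tf <- unname(cf["tf"]); ts_ <- unname(cf["ts"])
    if (tf > ts_) {  # enforce tau_fast <= tau_slow
      tmp <- tf; tf <- ts_; ts_ <- tmp
      tmp <- af; af <- as_; as_ <- tmp
    }
    tot <- af + as_
    out <- list(tau_fast = tf, tau_slow = ts_,
                frac_fast = af / tot, frac_slow = as_ / tot,
                tau_w = (af * tf + as_ * ts_) / tot,
                model = "double", rss = rss2, n = end,
                amplitude_pa = s * tot)
  }
  structure(out, class = "decay_fit")
}

efold_time <- function(y, dt_ms) {
  target <- y[1] / exp(1)
  i <- which(y <= target)[1]
  if (is.na(i) || i == 1) (length(y) / 2) * dt_ms else (i - 1) * dt_ms
}

bi_starts <- function(a0, tau0, n_starts) {
  base <- list(Af = 0.7 * a0, As = 0.3 * a0, tf = tau0, ts = 4 * tau0)
  starts <- list(base)
  if (n_starts > 1) {
    for (j in seq_len(n_starts - 1)) {
      jit <- exp(rnorm(2, 0, 0.4))
      starts[[j + 1]] <- list(Af = 0.7 * a0, As = 0.3 * a0,
                              tf = tau0 * jit[1], ts = 4 * tau0 * jit[2])
    }
  }
  starts
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "<decay_fit> %s: tau_w %.4g ms (tau_f %.4g, tau_s %.4g, frac_f %.3g), rss %.3g\n",
    x$model, x$tau_w, x$tau_fast, x$tau_slow, x$frac_fast, x$rss))
  invisible(x)
}

#' @describeIn fit_decay One row per exponential component.
#' @param x A `decay_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.decay_fit <- function(x, ...) {
  if (x$model == "single") {
    tibble::tibble(component = "fast", tau_ms = x$tau_fast, fraction = 1)
  } else {
    tibble::tibble(component = c("fast", "slow"),
                   tau_ms = c(x$tau_fast, x$tau_slow),
                   fraction = c(x$frac_fast, x$frac_slow))
  }
}

#' @describeIn fit_decay One-row model summary.
#' @exportS3Method generics::glance
glance.decay_fit <- function(x, ...) {
  tibble::tibble(model = x$model, tau_w_ms = x$tau_w, rss = x$rss, n = x$n,
                 amplitude_pa = x$amplitude_pa)
}

#' Peak chord conductance of an event
#'
#' `conductance = peak / (V - E_rev)`, reported positive; pA over mV gives
#' nS directly.
#'
#' @param peak_pa Baseline-subtracted peak amplitude (pA, signed).
#' @param v_mv Holding potential (mV).
#' @param e_rev Reversal potential (mV). Default 0.
#' @return Conductance in nS.
#' @export
event_conductance <- function(peak_pa, v_mv, e_rev = 0) {
  if (any(v_mv == e_rev)) abort("Conductance undefined at the reversal potential.")
  abs(peak_pa / (v_mv - e_rev))
}
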