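#' Analyze evoked EPSC trains and paired-pulse ratios
#'
#' Measures per-pulse amplitudes of minimally evoked EPSC trains, one
#' condition per recording. Each pulse's amplitude is the mean over sweeps
#' of the baseline-subtracted peak in a post-stimulus window, after
#' subtracting the preceding pulse's extrapolated single-exponential
#' decay (so summation during high-frequency trains does not inflate
#' later amplitudes). Amplitudes are normalized to the mean first-pulse
#' amplitude of the reference condition, and the paired-pulse ratio
#' `PPR_2/1` is computed within each condition.
#'
#' @param recordings A named list of [sweep_recording()]s, one per
#'   condition, each with the same number of stimulus times per sweep; or
#'   a single recording (condition "cond1").
#' @param reference Name of the reference condition whose first-pulse
#'   mean anchors the normalization. Default: first condition.
#' @param window_ms Measurement window after each stimulus (ms); default
#'   the inter-pulse interval (capped at 10 ms).
#' @param subtract_decay Subtract the preceding pulse's extrapolated
#'   decay (default TRUE).
#' @return An object of class `train_result`; `tidy()` gives one row per
#'   condition and pulse, `glance()` one row per condition with
#'   `ppr_2_1`.
#' @export
analyze_train <- function(recordings, reference = NULL, window_ms = NULL,
                          subtract_decay = TRUE) {
  if (inherits(recordings, "sweep_recording")) {
    recordings <- list(cond1 = recordings)
  }
  if (is.null(names(recordings)) || any(!nzchar(names(recordings)))) {
    names(recordings) <- paste0("cond", seq_along(recordings))
  }
  reference <- reference %||% names(recordings)[1]
  if (!reference %in% names(recordings)) {
    abort(sprintf("Reference condition '%s' is absent.", reference))
  }
  per_cond <- purrr::imap(recordings, function(rec, cond) {
    measure_train_amplitudes(rec, window_ms = window_ms,
                             subtract_decay = subtract_decay) |>
      dplyr::mutate(condition = cond, .before = 1)
  })
  amps <- dplyr::bind_rows(per_cond)
  ref_a1 <- amps$amplitude_pa[amps$condition == reference & amps$pulse == 1]
  amps <- dplyr::mutate(amps, normalized = .data$amplitude_pa / ref_a1)
  structure(list(amplitudes = amps, reference = reference),
            class = "train_result")
}

measure_train_amplitudes <- function(rec, window_ms = NULL,
                                     subtract_decay = TRUE) {
  stopifnot(inherits(rec, "sweep_recording"))
  stims <- rec_stims(rec)
  if (is.null(stims)) abort("Recording has no stimulus times.")
  n_pulse <- length(stims[[1]])
  if (n_pulse < 1 || any(lengths(stims) != n_pulse)) {
    abort("All sweeps must share the same number of stimulus times.")
  }
  dt <- rec_dt(rec)
  mat <- sweep_matrix(rec)
  n_samp <- nrow(mat)
  peaks <- matrix(NA_real_, ncol(mat), n_pulse)
  for (sw in seq_len(ncol(mat))) {
    st <- stims[[sw]]
    ipi <- if (n_pulse > 1) min(diff(st)) else Inf
    win <- window_ms %||% min(ipi, 10)
    base <- median(mat[seq_len(max(2, round(st[1] / dt))), sw])
    x <- mat[, sw] - base
    for (k in seq_len(n_pulse)) {
      i0 <- round(st[k] / dt) + 1
      i1 <- min(n_samp, round((st[k] + win) / dt) + 1)
      seg <- x[i0:i1]
      corr <- numeric(length(seg))
      if (subtract_decay && k > 1) {
        corr <- extrapolated_decay(x, dt, round(st[k - 1] / dt) + 1, i0, i1)
      }
      seg <- seg - corr
      pk <- which.max(abs(seg))
      peaks[sw, k] <- seg[pk]
    }
  }
  tibble::tibble(
    pulse = seq_len(n_pulse),
    amplitude_pa = colMeans(peaks),
    n_sweeps = ncol(mat)
  )
}

# log-linear single-exponential fit to the tail of the previous response,
# extrapolated over [i0, i1]
extrapolated_decay <- function(x, dt, prev_i0, i0, i1) {
  zero <- numeric(i1 - i0 + 1)
  seg_idx <- prev_i0:(i0 - 1)
  if (length(seg_idx) < 8) return(zero)
  # use the later 60% of the inter-pulse segment, past the previous peak
  tail_idx <- seg_idx[seg_idx >= prev_i0 + ceiling(0.4 * length(seg_idx))]
  y <- x[tail_idx]
  s <- sign(sum(y))
  y <- s * y
  keep <- y > max(y) * 0.02 & y > 0
  if (sum(keep) < 5) return(zero)
  tt <- (tail_idx[keep] - 1) * dt
  fit <- lm(log(y[keep]) ~ tt)
  slope <- coef(fit)[2]
  if (!is.finite(slope) || slope >= 0) return(zero)
  t_out <- (seq(i0, i1) - 1) * dt
  s * exp(coef(fit)[1] + slope * t_out)
}

#' @export
print.train_result <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<train_result> reference '%s'\n", x$reference))
  print(g)
  invisible(x)
}

#' @describeIn analyze_train One row per condition and pulse:
#'   `condition`, `pulse`, `amplitude_pa`, `normalized`, `n_sweeps`.
#' @param x A `train_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.train_result <- function(x, ...) x$amplitudes

#' @describeIn analyze_train One row per condition with first/second
#'   pulse amplitudes and `ppr_2_1`.
#' @exportS3Method generics::glance
glance.train_result <- function(x, ...) {
  x$amplitudes |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      a1_pa = .data$amplitude_pa[.data$pulse == 1],
      a2_pa = if (max(.data$pulse) >= 2) {
        .data$amplitude_pa[.data$pulse == 2]
      } else {
        NA_real_
      },
      ppr_2_1 = .data$a2_pa / .data$a1_pa,
      normalized_a1 = .data$normalized[.data$pulse == 1],
      .groups = "drop"
    ) |>
    dplyr::mutate(reference = x$reference)
}

#' @describeIn analyze_train Normalized amplitude against pulse number,
#'   one line per condition.
#' @param object A `train_result`.
#' @exportS3Method ggplot2::autoplot
autoplot.train_result <- function(object, ...) {
  ggplot2::ggplot(object$amplitudes,
                  ggplot2::aes(x = .data$pulse, y = .data$normalized,
                               colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "pulse", y = "normalized amplitude",
                  colour = "condition") +
    ggplot2::theme_minimal()
}
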