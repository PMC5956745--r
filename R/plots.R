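#' Diagnostic plot of an aligned event ensemble
#'
#' Individual aligned waveforms (thin) with the ensemble mean overlaid.
#'
#' @param object An `event_ensemble` from [align_and_average()].
#' @param max_traces Maximum number of individual traces drawn.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.event_ensemble <- function(object, max_traces = 50, ...) {
  n <- nrow(object$waveforms)
  idx <- if (n > max_traces) {
    round(seq(1, n, length.out = max_traces))
  } else {
    seq_len(n)
  }
  traces <- purrr::map_dfr(idx, function(e) {
    tibble::tibble(event = e, time_ms = object$time_ms,
                   current_pa = object$waveforms[e, ])
  })
  ggplot2::ggplot(traces, ggplot2::aes(x = .data$time_ms,
                                       y = .data$current_pa,
                                       group = .data$event)) +
    ggplot2::geom_line(alpha = 0.15) +
    ggplot2::geom_line(
      data = tibble::tibble(event = 0, time_ms = object$time_ms,
                            current_pa = object$mean_pa),
      colour = "firebrick", linewidth = 0.8) +
    ggplot2::labs(x = "time from alignment (ms)", y = "current (pA)") +
    ggplot2::theme_minimal()
}

#' Diagnostic plot of a terminal annotation
#'
#' Terminal outline, organelles, active zones and vesicle centers.
#'
#' @param object A [terminal_annotation()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.terminal_annotation <- function(object, ...) {
  poly_df <- function(m, id) {
    tibble::tibble(id = id, x = m[, 1], y = m[, 2])
  }
  term <- poly_df(object$terminal, "terminal")
  orgs <- purrr::imap_dfr(object$organelles,
                          function(m, i) poly_df(m, paste0("organelle_", i)))
  azs <- purrr::imap_dfr(object$active_zones,
                         function(m, i) poly_df(m, paste0("az_", i)))
  p <- ggplot2::ggplot() +
    ggplot2::geom_polygon(data = term, ggplot2::aes(.data$x, .data$y),
                          fill = NA, colour = "black") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)") +
    ggplot2::theme_minimal()
  if (nrow(orgs)) {
    p <- p + ggplot2::geom_polygon(
      data = orgs, ggplot2::aes(.data$x, .data$y, group = .data$id),
      fill = "grey80", colour = "grey40")
  }
  if (nrow(object$vesicles)) {
    p <- p + ggplot2::geom_point(
      data = object$vesicles,
      ggplot2::aes(.data$x_nm, .data$y_nm, size = .data$diameter_nm),
      alpha = 0.4, show.legend = FALSE)
  }
  if (nrow(azs)) {
    p <- p + ggplot2::geom_path(
      data = azs, ggplot2::aes(.data$x, .data$y, group = .data$id),
      colour = "firebrick", linewidth = 1.2)
  }
  p
}

#' Variance-mean diagnostic for a simulated quantal ensemble
#'
#' Plots an I-V ramp with its fitted limb slopes.
#'
#' @param object An [iv_ramp()].
#' @param neg_window,pos_window Slope windows (mV).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.iv_ramp <- function(object, neg_window = c(-40, -20),
                             pos_window = c(20, 40), ...) {
  rs <- ri_slope(object, neg_window, pos_window)
  ggplot2::ggplot(tibble::as_tibble(unclass_tbl(object)),
                  ggplot2::aes(.data$voltage_mv, .data$current_pa)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_smooth(
      data = function(d) dplyr::filter(d, .data$voltage_mv >= neg_window[1],
                                       .data$voltage_mv <= neg_window[2]),
      method = "lm", formula = y ~ x, se = FALSE, colour = "steelblue") +
    ggplot2::geom_smooth(
      data = function(d) dplyr::filter(d, .data$voltage_mv >= pos_window[1],
                                       .data$voltage_mv <= pos_window[2]),
      method = "lm", formula = y ~ x, se = FALSE, colour = "steelblue") +
    ggplot2::labs(x = "voltage (mV)", y = "current (pA)",
                  title = sprintf("RI_slope = %.2f", rs$ri_slope)) +
    ggplot2::theme_minimal()
}
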