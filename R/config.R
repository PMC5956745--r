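#' Analysis configuration
#'
#' Bundles every tunable parameter of the measurement chain, with defaults
#' matching the conventions used throughout the package (units: ms, pA, mV,
#' nS/pS, nm, um^2; inward current negative).
#'
#' @param threshold_k Detection threshold as a multiple of the baseline
#'   noise SD (dimensionless). Default 3.
#' @param baseline_ms Length of the pre-event window used for the local
#'   baseline (ms).
#' @param align_pre_ms,align_post_ms Extent of the aligned event window
#'   before and after the alignment point (ms).
#' @param merge_ms Refractory merge window: threshold crossings closer than
#'   this are treated as one event (ms).
#' @param smooth_ms Boxcar smoothing width applied before detection (ms);
#'   0 disables. Default 0.3 ms (~2 kHz bandwidth at 20 kHz sampling).
#' @param nsfa_bins Number of equal-amplitude bins for peak-scaled NSFA
#'   (>= 3). Default 30.
#' @param nsfa_min_events Minimum number of screened events required before
#'   a ps-NSFA fit is attempted. Default 10.
#' @param nsfa_min_bin_n Bins with fewer pooled samples than this are
#'   excluded from the parabolic fit. Default 5.
#' @param nsfa_weighted Weight the parabolic fit by pooled sample count per
#'   bin. Default TRUE.
#' @param e_rev Reversal potential used for conductance conversions (mV).
#' @param ri_neg_window,ri_pos_window Voltage windows (mV, length-2) for the
#'   negative and positive slope conductances of the I-V ramp.
#' @param exclusion_ms Post-stimulus exclusion window for quantal counting
#'   in Sr2+ sessions (ms). Default 10.
#' @param decay_cap_tau Decay-fit window cap, as a multiple of the initial
#'   tau estimate. Default 10.
#' @param grid_square_um2 Area of one grid square for vesicle density
#'   (um^2). Default 0.1.
#' @param proximity_nm Distance from an active zone below which a vesicle
#'   is proximal (nm). Default 100.
#' @param az_unit_nm Active-zone length unit for normalized counts (nm).
#'   Default 50.
#' @param count_match_ties How count-matching resolves ties at the cutoff
#'   magnitude: "fractional" (all tied events, marginal tie weighted
#'   fractionally) or "exact_k" (plain truncation).
#' @param seed Integer seed recorded into pipeline logs.
#'
#' @return A list with class `analysis_config`.
#' @export
analysis_config <- function(threshold_k = 3,
                            baseline_ms = 5,
                            align_pre_ms = 5,
                            align_post_ms = 15,
                            merge_ms = 1,
                            smooth_ms = 0.3,
                            nsfa_bins = 30,
                            nsfa_min_events = 10,
                            nsfa_min_bin_n = 5,
                            nsfa_weighted = TRUE,
                            e_rev = 0,
                            ri_neg_window = c(-40, -20),
                            ri_pos_window = c(20, 40),
                            exclusion_ms = 10,
                            decay_cap_tau = 10,
                            grid_square_um2 = 0.1,
                            proximity_nm = 100,
                            az_unit_nm = 50,
                            count_match_ties = c("fractional", "exact_k"),
                            seed = 1L) {
  count_match_ties <- match.arg(count_match_ties)
  cfg <- list(
    threshold_k = threshold_k, baseline_ms = baseline_ms,
    align_pre_ms = align_pre_ms, align_post_ms = align_post_ms,
    merge_ms = merge_ms, smooth_ms = smooth_ms,
    nsfa_bins = as.integer(nsfa_bins), nsfa_min_events = nsfa_min_events,
    nsfa_min_bin_n = nsfa_min_bin_n, nsfa_weighted = nsfa_weighted,
    e_rev = e_rev, ri_neg_window = ri_neg_window,
    ri_pos_window = ri_pos_window, exclusion_ms = exclusion_ms,
    decay_cap_tau = decay_cap_tau, grid_square_um2 = grid_square_um2,
    proximity_nm = proximity_nm, az_unit_nm = az_unit_nm,
    count_match_ties = count_match_ties, seed = as.integer(seed)
  )
  validate_analysis_config(structure(cfg, class = "analysis_config"))
}

validate_analysis_config <- function(cfg) {
  stopifnot(
    cfg$threshold_k > 0,
    cfg$baseline_ms > 0, cfg$align_pre_ms > 0, cfg$align_post_ms > 0,
    cfg$merge_ms > 0, cfg$smooth_ms >= 0,
    cfg$nsfa_bins >= 3, cfg$nsfa_min_events >= 1,
    cfg$exclusion_ms > 0, cfg$grid_square_um2 > 0,
    cfg$proximity_nm > 0, cfg$az_unit_nm > 0,
    length(cfg$ri_neg_window) == 2, length(cfg$ri_pos_window) == 2
  )
  cfg
}

#' Read or write a flat key-value configuration file
#'
#' The on-disk format is one `key = value` pair per line; vector values are
#' comma-separated. Unknown keys are rejected.
#'
#' @param path File path.
#' @return `read_config()` returns an [analysis_config()]; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) {
    abort(paste0("Malformed config line(s): ", paste(lines[bad], collapse = "; ")))
  }
  keys <- trimws(vapply(kv, `[[`, "", 1))
  vals <- trimws(vapply(kv, `[[`, "", 2))
  defaults <- analysis_config()
  unknown <- setdiff(keys, names(defaults))
  if (length(unknown)) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  parsed <- lapply(seq_along(keys), function(j) {
    template <- defaults[[keys[j]]]
    parts <- trimws(strsplit(vals[j], ",", fixed = TRUE)[[1]])
    if (is.character(template)) {
      parts
    } else if (is.logical(template)) {
      as.logical(parts)
    } else {
      as.numeric(parts)
    }
  })
  args <- setNames(parsed, keys)
  do.call(analysis_config, args)
}

#' @rdname read_config
#' @param cfg An [analysis_config()].
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "analysis_config"))
  fmt <- vapply(names(cfg), function(k) {
    v <- cfg[[k]]
    paste0(k, " = ", paste(format(v, scientific = FALSE, trim = TRUE),
                           collapse = ", "))
  }, "")
  writeLines(fmt, path)
  invisible(path)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  for (k in names(x)) {
    cat(sprintf("  %-18s %s\n", k, paste(format(x[[k]]), collapse = ", ")))
  }
  invisible(x)
}
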