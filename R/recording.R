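#' Multi-sweep current recording
#'
#' A `sweep_recording` is a long-format tibble with columns `sweep`,
#' `time_ms` and `current_pa`, carrying the sampling interval, holding
#' potential, optional per-sweep stimulus times and a free-text label as
#' attributes. Inward currents are negative, in pA; time is in ms.
#'
#' @param current A numeric matrix (samples x sweeps) of membrane current
#'   in pA, or a data frame whose first column is time (ms) and remaining
#'   columns are sweeps.
#' @param dt_ms Sampling interval in ms (ignored when `current` carries a
#'   time column).
#' @param holding_mv Holding potential in mV.
#' @param stimulus_times Optional numeric vector (recycled) or list of
#'   numeric vectors, one per sweep, of stimulus times in ms.
#' @param label Free-text label.
#'
#' @return A tibble of class `sweep_recording`.
#' @export
sweep_recording <- function(current, dt_ms = NULL, holding_mv = -60,
                            stimulus_times = NULL, label = "") {
  if (is.data.frame(current)) {
    tt <- as.numeric(current[[1]])
    dt_ms <- infer_dt(tt)
    current <- as.matrix(current[, -1, drop = FALSE])
    storage.mode(current) <- "double"
  } else {
    current <- as.matrix(current)
    storage.mode(current) <- "double"
    if (is.null(dt_ms)) abort("`dt_ms` is required when `current` is a matrix.")
  }
  if (anyNA(current)) abort("Sweep table is ragged: missing current values.")
  if (!is.numeric(dt_ms) || length(dt_ms) != 1 || dt_ms <= 0) {
    abort("`dt_ms` must be a single positive number.")
  }
  n_samp <- nrow(current)
  n_sw <- ncol(current)
  dur <- (n_samp - 1) * dt_ms
  stim <- normalize_stim_times(stimulus_times, n_sw, dur)
  out <- tibble::tibble(
    sweep = rep(seq_len(n_sw), each = n_samp),
    time_ms = rep(seq(0, by = dt_ms, length.out = n_samp), times = n_sw),
    current_pa = as.vector(current)
  )
  structure(out,
    class = c("sweep_recording", class(out)),
    dt_ms = dt_ms, holding_mv = holding_mv,
    stimulus_times = stim, label = label
  )
}

normalize_stim_times <- function(stimulus_times, n_sweeps, duration_ms) {
  if (is.null(stimulus_times)) return(NULL)
  if (!is.list(stimulus_times)) {
    stimulus_times <- rep(list(as.numeric(stimulus_times)), n_sweeps)
  }
  if (length(stimulus_times) != n_sweeps) {
    abort("`stimulus_times` must have one entry per sweep.")
  }
  ok <- vapply(stimulus_times, function(s) {
    length(s) == 0 || all(s >= 0 & s <= duration_ms)
  }, logical(1))
  if (!all(ok)) abort("Stimulus times must lie within the sweep duration.")
  stimulus_times
}

infer_dt <- function(time_ms, rel_tol = 1e-6) {
  if (length(time_ms) < 2) abort("Need at least two time samples.")
  d <- diff(time_ms)
  dt <- median(d)
  if (dt <= 0 || any(abs(d - dt) > rel_tol * max(dt, 1))) {
    abort("Time column is not a uniform grid.")
  }
  dt
}

#' @export
print.sweep_recording <- function(x, ...) {
  cat(sprintf(
    "<sweep_recording> %d sweeps x %d samples, dt %.4g ms, holding %g mV%s\n",
    n_sweeps(x), n_samples(x), rec_dt(x), rec_holding(x),
    if (nzchar(attr(x, "label"))) paste0(" [", attr(x, "label"), "]") else ""
  ))
  NextMethod()
}

rec_dt <- function(rec) attr(rec, "dt_ms")
rec_holding <- function(rec) attr(rec, "holding_mv")
rec_stims <- function(rec) attr(rec, "stimulus_times")

#' Dimensions of a sweep recording
#'
#' @param rec A [sweep_recording()].
#' @return Number of sweeps / samples per sweep.
#' @export
n_sweeps <- function(rec) length(unique(rec$sweep))

#' @rdname n_sweeps
#' @export
n_samples <- function(rec) sum(rec$sweep == rec$sweep[1])

#' Extract the current matrix (samples x sweeps) from a recording
#'
#' @param rec A [sweep_recording()].
#' @return A numeric matrix, one column per sweep.
#' @export
sweep_matrix <- function(rec) {
  matrix(rec$current_pa, ncol = n_sweeps(rec),
         dimnames = list(NULL, paste0("sweep_", seq_len(n_sweeps(rec)))))
}

#' Read / write delimited sweep tables
#'
#' The on-disk format is a delimited table whose first column is time (ms,
#' uniform grid) and whose remaining columns are one current trace per
#' sweep (pA). A ragged table or a non-uniform time grid is a format error.
#'
#' @param path File path (CSV).
#' @param holding_mv,stimulus_times,label Metadata attached to the result;
#'   see [sweep_recording()].
#' @return `read_sweeps()` returns a [sweep_recording()]; `write_sweeps()`
#'   returns `path` invisibly.
#' @export
read_sweeps <- function(path, holding_mv = -60, stimulus_times = NULL,
                        label = basename(path)) {
  # ragged tables surface as NAs, caught below with a clearer error
  df <- suppressWarnings(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  )
  if (ncol(df) < 2) abort("Sweep table needs a time column and >= 1 sweep.")
  if (anyNA(df)) abort("Sweep table is ragged: missing cells.")
  sweep_recording(as.data.frame(df), holding_mv = holding_mv,
                  stimulus_times = stimulus_times, label = label)
}

#' @rdname read_sweeps
#' @param rec A [sweep_recording()].
#' @export
write_sweeps <- function(rec, path) {
  stopifnot(inherits(rec, "sweep_recording"))
  m <- sweep_matrix(rec)
  df <- tibble::as_tibble(m)
  df <- tibble::add_column(
    df, time_ms = seq(0, by = rec_dt(rec), length.out = nrow(m)),
    .before = 1
  )
  readr::write_csv(df, path)
  invisible(path)
}

#' Current-voltage ramp record
#'
#' An `iv_ramp` is a tibble with columns `voltage_mv` (strictly monotonic)
#' and `current_pa` (leak-subtracted unless stated otherwise).
#'
#' @param voltage_mv Ordered voltage samples (mV).
#' @param current_pa Current samples (pA), same length.
#' @param leak_subtracted Whether the current has been leak-subtracted.
#' @return A tibble of class `iv_ramp`.
#' @export
iv_ramp <- function(voltage_mv, current_pa, leak_subtracted = TRUE) {
  voltage_mv <- as.numeric(voltage_mv)
  current_pa <- as.numeric(current_pa)
  if (length(voltage_mv) != length(current_pa)) {
    abort("`voltage_mv` and `current_pa` must have the same length.")
  }
  d <- diff(voltage_mv)
  if (!(all(d > 0) || all(d < 0))) {
    abort("`voltage_mv` must be strictly monotonic.")
  }
  out <- tibble::tibble(voltage_mv = voltage_mv, current_pa = current_pa)
  structure(out, class = c("iv_ramp", class(out)),
            leak_subtracted = isTRUE(leak_subtracted))
}

#' @rdname iv_ramp
#' @param path File path (CSV with columns voltage_mv, current_pa).
#' @export
read_iv_ramp <- function(path, leak_subtracted = TRUE) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("voltage_mv", "current_pa") %in% names(df))) {
    abort("Ramp table needs columns voltage_mv and current_pa.")
  }
  iv_ramp(df$voltage_mv, df$current_pa, leak_subtracted = leak_subtracted)
}

#' @rdname iv_ramp
#' @param ramp An `iv_ramp`.
#' @export
write_iv_ramp <- function(ramp, path) {
  stopifnot(inherits(ramp, "iv_ramp"))
  readr::write_csv(tibble::as_tibble(unclass_tbl(ramp)), path)
  invisible(path)
}

unclass_tbl <- function(x) {
  class(x) <- setdiff(class(x), c("sweep_recording", "iv_ramp"))
  x
}
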