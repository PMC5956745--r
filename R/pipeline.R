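#' Run one analysis stage end to end
#'
#' Thin plumbing that chains the package's functions for shell-style use:
#' reads the stage's inputs, runs it with the parameters in `config`, and
#' writes tidy CSV result tables plus a structured key-value log
#' (`<stage>_log.txt`) into `out_dir`. All randomness is governed by
#' `config$seed`, so a repeated run with the same seed and config writes
#' byte-identical result tables.
#'
#' Stages and their inputs:
#' \describe{
#'   \item{simulate}{`inputs$model` one of "mepsc", "ramp", "sr2",
#'     "train", "terminal"; writes the simulated data plus a
#'     `truth.csv` sidecar.}
#'   \item{detect}{`inputs$sweeps` (CSV); writes `events.csv`.}
#'   \item{kinetics}{`inputs$sweeps`, `inputs$events`; writes
#'     `kinetics.csv` (ensemble rise time and decay fit).}
#'   \item{nsfa}{`inputs$sweeps`, `inputs$events`; writes
#'     `nsfa_bins.csv` and `nsfa_summary.csv`. With fewer screened
#'     events than the quality floor the fit is refused: a warning is
#'     logged and no summary is written.}
#'   \item{rectify}{`inputs$ramp` (CSV); writes `rectification.csv`.}
#'   \item{quantal}{`inputs$sweeps`, `inputs$events`, `inputs$stim_ms`;
#'     writes `quantal_per_sweep.csv` and `quantal_summary.csv`.}
#'   \item{train}{`inputs$sweeps`, `inputs$stim_ms` (vector); writes
#'     `train.csv`.}
#'   \item{em}{`inputs$annotation` (JSON); writes `vesicle_stats.csv`.}
#' }
#'
#' @param stage Stage name.
#' @param inputs Named list of input file paths / parameters.
#' @param out_dir Output directory (created if absent).
#' @param config An [analysis_config()].
#' @return Invisibly, a character vector of the files written.
#' @export
run_pipeline <- function(stage, inputs = list(), out_dir = ".",
                         config = analysis_config()) {
  stages <- c("simulate", "detect", "kinetics", "nsfa", "rectify",
              "quantal", "train", "em")
  if (!is.character(stage) || length(stage) != 1 || !stage %in% stages) {
    abort(paste0("Unknown stage; must be one of: ",
                 paste(stages, collapse = ", ")), class = "synaptiq_usage")
  }
  stopifnot(inherits(config, "analysis_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  set.seed(config$seed)
  log_lines <- c(paste0("stage = ", stage), paste0("seed = ", config$seed))
  written <- character()
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    readr::write_csv(tibble::as_tibble(df), p)
    written <<- c(written, p)
    log_lines <<- c(log_lines, sprintf("wrote %s (%d rows)", name, nrow(df)))
  }

  if (stage == "simulate") {
    model <- inputs$model %||% "mepsc"
    qm <- quantal_model()
    if (model == "mepsc") {
      sim <- simulate_mepsc_recording(qm, seed = config$seed)
      write_sweeps(sim$recording, file.path(out_dir, "sweeps.csv"))
      written <- c(written, file.path(out_dir, "sweeps.csv"))
      emit(sim$truth, "truth.csv")
    } else if (model == "ramp") {
      ramp <- simulate_iv_ramp(g_neg_ns = 1, g_pos_ns = 1, noise_sd_pa = 2,
                               seed = config$seed)
      write_iv_ramp(ramp, file.path(out_dir, "ramp.csv"))
      written <- c(written, file.path(out_dir, "ramp.csv"))
      emit(tibble::tibble(ri_true = attr(ramp, "truth")$ri), "truth.csv")
    } else if (model == "sr2") {
      sim <- simulate_sr2_session(qm, seed = config$seed)
      write_sweeps(sim$recording, file.path(out_dir, "sweeps.csv"))
      written <- c(written, file.path(out_dir, "sweeps.csv"))
      emit(sim$truth, "truth.csv")
    } else if (model == "train") {
      sim <- simulate_train(qm, seed = config$seed)
      write_sweeps(sim$recording, file.path(out_dir, "sweeps.csv"))
      written <- c(written, file.path(out_dir, "sweeps.csv"))
      emit(sim$amplitudes, "truth.csv")
    } else if (model == "terminal") {
      ann <- simulate_terminal(seed = config$seed)
      write_terminal_annotation(ann, file.path(out_dir, "terminal.json"))
      written <- c(written, file.path(out_dir, "terminal.json"))
      tr <- attr(ann, "truth")
      emit(tibble::as_tibble(tr[c("density_per_um2", "diameter_mean_nm",
                                  "n_total")]), "truth.csv")
    } else {
      abort(paste0("Unknown simulate model: ", model),
            class = "synaptiq_usage")
    }
  } else if (stage == "detect") {
    rec <- read_sweeps(need_input(inputs, "sweeps"))
    noise <- estimate_baseline_noise(rec)
    ev <- detect_events(rec, k = config$threshold_k,
                        noise_sd_pa = noise$sd_pa,
                        merge_ms = config$merge_ms,
                        smooth_ms = config$smooth_ms,
                        baseline_ms = config$baseline_ms)
    ev <- screen_events(ev, rec, decay_ms = config$align_post_ms,
                        exclusion_ms = config$exclusion_ms)
    log_lines <- c(log_lines,
                   sprintf("noise_sd_pa = %.6g", noise$sd_pa),
                   sprintf("n_events = %d", nrow(ev)))
    emit(ev, "events.csv")
  } else if (stage == "kinetics") {
    rec <- read_sweeps(need_input(inputs, "sweeps"))
    ev <- readr::read_csv(need_input(inputs, "events"),
                          show_col_types = FALSE)
    keep <- dplyr::filter(ev, .data$monotonic_rise %in% TRUE,
                          .data$clean_decay %in% TRUE)
    ens <- align_and_average(keep, rec, pre_ms = config$align_pre_ms,
                             post_ms = config$align_post_ms)
    noise <- estimate_baseline_noise(rec)
    pk <- which.max(abs(ens$mean_pa))
    rt <- rise_time_10_90(ens$mean_pa, ens$dt_ms)
    dfit <- fit_decay(ens$mean_pa[pk:length(ens$mean_pa)], ens$dt_ms,
                      noise_sd_pa = noise$sd_pa,
                      cap_tau = config$decay_cap_tau)
    emit(dplyr::bind_cols(tibble::tibble(rise_10_90_ms = rt), glance(dfit),
                          tibble::tibble(n_events = nrow(ens$waveforms))),
         "kinetics.csv")
  } else if (stage == "nsfa") {
    rec <- read_sweeps(need_input(inputs, "sweeps"))
    ev <- readr::read_csv(need_input(inputs, "events"),
                          show_col_types = FALSE)
    keep <- dplyr::filter(ev, .data$monotonic_rise %in% TRUE,
                          .data$clean_decay %in% TRUE)
    fit <- NULL
    if (nrow(keep) >= config$nsfa_min_events) {
      ens <- align_and_average(keep, rec, pre_ms = config$align_pre_ms,
                               post_ms = config$align_post_ms)
      fit <- tryCatch(
        peak_scaled_nsfa(ens, n_bins = config$nsfa_bins,
                         v_mv = rec_holding(rec), e_rev = config$e_rev,
                         min_events = config$nsfa_min_events,
                         min_bin_n = config$nsfa_min_bin_n,
                         weighted = config$nsfa_weighted),
        synaptiq_too_few_events = function(e) NULL)
    }
    if (is.null(fit)) {
      msg <- sprintf(
        "nsfa refused: %d screened events below quality floor %d",
        nrow(keep), config$nsfa_min_events)
      warn(msg)
      log_lines <- c(log_lines, paste0("warning = ", msg))
    } else {
      emit(tidy(fit), "nsfa_bins.csv")
      emit(glance(fit), "nsfa_summary.csv")
    }
  } else if (stage == "rectify") {
    ramp <- read_iv_ramp(need_input(inputs, "ramp"))
    emit(ri_slope(ramp, neg_window = config$ri_neg_window,
                  pos_window = config$ri_pos_window), "rectification.csv")
  } else if (stage == "quantal") {
    rec <- read_sweeps(need_input(inputs, "sweeps"),
                       stimulus_times = need_input(inputs, "stim_ms"))
    ev <- readr::read_csv(need_input(inputs, "events"),
                          show_col_types = FALSE)
    qs <- analyze_sr2_session(rec, ev, exclusion_ms = config$exclusion_ms)
    emit(tidy(qs), "quantal_per_sweep.csv")
    emit(glance(qs), "quantal_summary.csv")
  } else if (stage == "train") {
    rec <- read_sweeps(need_input(inputs, "sweeps"),
                       stimulus_times = need_input(inputs, "stim_ms"))
    tr <- analyze_train(rec)
    emit(dplyr::left_join(tidy(tr),
                          dplyr::select(glance(tr), "condition", "ppr_2_1"),
                          by = "condition"), "train.csv")
  } else if (stage == "em") {
    ann <- read_terminal_annotation(need_input(inputs, "annotation"))
    emit(vesicle_stats(ann, square_area_um2 = config$grid_square_um2,
                       proximity_nm = config$proximity_nm,
                       unit_nm = config$az_unit_nm), "vesicle_stats.csv")
  }

  log_lines <- c(log_lines, config_log_lines(config))
  writeLines(log_lines, file.path(out_dir, paste0(stage, "_log.txt")))
  invisible(written)
}

need_input <- function(inputs, name) {
  v <- inputs[[name]]
  if (is.null(v)) {
    abort(sprintf("Stage input '%s' is required.", name),
          class = "synaptiq_usage")
  }
  v
}

config_log_lines <- function(cfg) {
  vapply(names(cfg), function(k) {
    sprintf("config.%s = %s", k, paste(format(cfg[[k]]), collapse = ","))
  }, "")
}
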