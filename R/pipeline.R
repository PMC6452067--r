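# End-to-end experiment orchestration and study-style reporting.
#
# One master seed fans out to per-stage seeds by fixed offsets (record
# +1, threshold +2, dose +3, PAM +4, satellite tracks +5...), recorded in
# the report so any run can be replayed exactly.

#' Received dose at the response onset
#'
#' The onset SPL is the maximum per-pulse received level up to and
#' including the change-point window; the onset distance is the
#' source-whale range at the change-point.  The onset is censored (an
#' upper bound on the true threshold) when the time resolution of the
#' onset estimate exceeds the pulse interval -- e.g. satellite-tag
#' records, or close exposures without ramp-up where the response starts
#' at the first pulse.
#'
#' @param changepoint_time Change-point time (s), or NA.
#' @param pulse_times Per-pulse times (s).
#' @param pulse_spl Per-pulse received SPL (dB re 1 uPa).
#' @param pulse_range_km Per-pulse source-whale range (km).
#' @param resolution_s Time resolution of the onset estimate (s); e.g.
#'   the MD window step (60 s) for tag records, 3600 s for satellite
#'   records.
#' @param pulse_interval_s Pulse repetition interval (s).
#' @return One-row data frame with `onset_spl`, `onset_distance_km`,
#'   `censored`; `NULL` when there is no change-point.
#' @export
onset_dose <- function(changepoint_time, pulse_times, pulse_spl,
                       pulse_range_km, resolution_s = 60,
                       pulse_interval_s = 20) {
  if (is.na(changepoint_time)) return(NULL)
  upto <- pulse_times <= changepoint_time
  if (!any(upto)) stop("no transmitted pulses before the change-point")
  k <- max(which(upto))
  data.frame(onset_spl = max(pulse_spl[upto]),
             onset_distance_km = pulse_range_km[k],
             censored = resolution_s > pulse_interval_s)
}

#' Run a full synthetic controlled exposure experiment
#'
#' Simulates one focal tag record under the configured treatment, runs
#' the feature extraction and MD change-point analysis, models the
#' per-pulse acoustic dose for the focal whale geometry, and (optionally)
#' simulates and analyses satellite-tagged whales and a PAM mooring
#' scene.  Returns a structured report; with `out_dir` set the report is
#' also written as JSON plus CSV tables.
#'
#' @param config A [sim_config()].
#' @param source_distance_km Source-whale horizontal range at exposure
#'   start; default 0.5 (close) or 17 (distant).
#' @param resample_n Threshold resampling replicates (default 1e4).
#' @param horizon_windows Analysis horizon (number of 1-min windows
#'   scanned for a change-point); default: from exposure start to the
#'   end of the record.
#' @param include_pam,include_sat Run the PAM and satellite-track
#'   stages.
#' @param n_sat Number of satellite-tagged whales.
#' @param out_dir Optional output directory.
#' @return List of class `experiment_report`.
#' @export
run_experiment <- function(config = sim_config(treatment = "close"),
                           source_distance_km = NULL,
                           resample_n = 1e4, horizon_windows = NULL,
                           include_pam = FALSE, include_sat = FALSE,
                           n_sat = 3, out_dir = NULL) {
  t_start <- Sys.time()
  exposed <- config$treatment != "none"
  source_distance_km <- source_distance_km %||%
    switch(config$treatment, close = 0.5, distant = 17, none = NA_real_)

  sched <- if (exposed)
    make_exposure(config$treatment,
                  start_time = config$exposure_start_h * 3600) else NULL

  sim <- make_tag_record(config)
  feats <- tag_features(sim$record)

  exposure_start <- if (exposed) config$exposure_start_h * 3600 else
    config$duration_h * 3600 * 2 / 3
  wins <- window_means(feats, variables = md_variable_set("avoidance"))
  bl <- baseline_summary(wins, baseline_end = exposure_start)
  horizon <- horizon_windows %||%
    max(1L, sum(wins$times > exposure_start))
  thr <- resample_threshold(bl, horizon = horizon, windows = wins,
                            n = resample_n, seed = config$seed + 2L)
  mds <- md_series(wins, bl)
  cp <- detect_changepoint(mds, thr, baseline_end = exposure_start)

  dose <- NULL; onset <- NULL
  if (exposed) {
    range_km <- source_distance_km
    rng_m <- sqrt((range_km * 1000)^2 +
                    (mean(feats$depth, na.rm = TRUE) -
                       sched$source_depth_m)^2)
    spl <- propagate_spl(sched$pulses$source_level, rng_m,
                         f_khz = mean(sched$band_hz) / 1000)
    dose <- data.frame(time = sched$pulses$time, spl = spl,
                       range_km = range_km)
    onset <- onset_dose(cp$changepoint_time, dose$time, dose$spl,
                        dose$range_km, resolution_s = 60,
                        pulse_interval_s = sched$pulse_interval)
    if (!is.null(onset))
      onset$censored <- onset$censored ||
        (sched$ramp_up_min == 0 &&
           cp$changepoint_time <= exposure_start + 15 * 60)
  }

  pam <- NULL
  if (include_pam) {
    cfgp <- config; cfgp$seed <- config$seed + 4L
    n_seg <- cfgp$pam$n_segments
    present <- rep(TRUE, n_seg)
    if (exposed) present[seq(ceiling(n_seg / 2), n_seg)] <- FALSE
    scene <- make_pam_scene(cfgp, present = present, emit = "psd")
    nps <- normalize_psd(scene$psd)
    segs <- segment_level_difference(nps,
                                     segment_s = cfgp$pam$segment_s)
    det <- detect_clicks(segs, 5)
    cap <- click_absent_periods(det$detected,
                                segment_min = cfgp$pam$segment_s / 60)
    pam <- list(segments = det, periods = cap)
  }

  sat <- NULL
  if (include_sat) {
    tracks <- lapply(seq_len(n_sat), function(i) {
      cfgs <- config; cfgs$seed <- config$seed + 5L + i
      make_sat_track(cfgs)
    })
    st <- lapply(tracks, function(tr) {
      flt <- speed_filter(tr$track)
      s <- steps_turns(flt)
      s$ttr <- if (exposed)
        time_to_recovery(s$time, tracks[[1]]$truth$exposure_hour %||%
                           config$hmm_truth$exposure_hour) else 0
      s$splmax <- 135; s$distance_km <- source_distance_km
      s
    })
    fits <- list(none = fit_hmm(st, "none", n_starts = 4))
    if (exposed) fits$recovery <- fit_hmm(st, "recovery", n_starts = 4)
    sat <- list(fits = fits, selection = select_hmm(fits),
                decoded = viterbi(fits[[length(fits)]]))
  }

  report <- structure(list(
    config = config, seed_offsets = c(record = 0, threshold = 2,
                                      dose = 3, pam = 4, sat = 5),
    treatment = config$treatment,
    exposure_start = if (exposed) exposure_start else NA_real_,
    truth_onset = sim$truth$response_onset_time,
    changepoint = cp, threshold = thr, md = mds,
    onset = onset, dose = dose, pam = pam, sat = sat,
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs"))),
    class = "experiment_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write an experiment report to disk
#'
#' @param report An `experiment_report`.
#' @param out_dir Directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(time = report$md$times, md = report$md$md),
                   file.path(out_dir, "md_series.csv"),
                   row.names = FALSE)
  if (!is.null(report$dose))
    utils::write.csv(report$dose, file.path(out_dir, "dose.csv"),
                     row.names = FALSE)
  summary <- list(
    treatment = report$treatment,
    seed = report$config$seed,
    exposure_start_s = report$exposure_start,
    truth_onset_s = report$truth_onset,
    changepoint_s = report$changepoint$changepoint_time,
    threshold = report$changepoint$threshold,
    onset = report$onset,
    elapsed_s = report$elapsed_s)
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(out_dir)
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %s treatment, seed %d\n",
              x$treatment, x$config$seed))
  cat(sprintf("  change-point: %s (threshold %.2f)\n",
              if (is.na(x$changepoint$changepoint_time)) "none" else
                sprintf("%.0f s", x$changepoint$changepoint_time),
              x$changepoint$threshold))
  if (!is.null(x$onset))
    cat(sprintf("  onset SPL %.1f dB re 1 uPa at %.1f km%s\n",
                x$onset$onset_spl, x$onset$onset_distance_km,
                if (x$onset$censored) " (censored: upper bound)" else ""))
  invisible(x)
}
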