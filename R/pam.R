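# Guard-band energy detection of echolocation clicks.
#
# Audio is reduced to framed power spectral densities (Hann window, 50%
# overlap), self-normalized by a noise-floor spectrum (the time average
# of the frames whose mean 5-50 kHz level falls in the lowest 5%), and
# scored per 2.5-min segment as the difference between the echolocation
# band (20-40 kHz) and the guard band (4-8 kHz), each summarised by the
# time average over the loudest 1% of frames.  Clicks are band-limited to
# the echolocation band, so genuine click trains raise the echolocation
# statistic but not the guard statistic, whereas broadband interference
# raises both and cancels in the difference.  Detection thresholds of
# 5 and 8 dB on the level difference are the working points.  Runs of
# consecutive click-absent segments form the click-absence statistic.

#' Framed power spectral density (spectrogram)
#'
#' One-sided PSD per frame with Hann window and density normalization
#' `2 / (fs * sum(w^2))` (DC and Nyquist bins not doubled), so that the
#' PSD integrates to the signal power (Parseval).
#'
#' @param x Audio samples (arbitrary pressure units).
#' @param fs Sample rate (Hz).
#' @param frame Frame length in samples; default 8192 at 144 kHz and
#'   `round(0.0569 * fs)` otherwise (a 56.9 ms frame).
#' @param overlap Fractional frame overlap (default 0.5).
#' @return List of class `psd_spectrogram`: `times` (frame centres, s),
#'   `freq` (Hz), `psd` (bins x frames), `fs`, `frame`.
#' @export
psd_spectrogram <- function(x, fs, frame = NULL, overlap = 0.5) {
  if (is.null(frame))
    frame <- if (fs == 144000) 8192L else as.integer(round(0.0569 * fs))
  if (length(x) < frame) stop("audio shorter than one frame")
  hop <- max(1L, as.integer(round(frame * (1 - overlap))))
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(frame - 1)) / frame)  # periodic Hann
  scale <- 2 / (fs * sum(w^2))
  starts <- seq(1L, length(x) - frame + 1L, by = hop)
  nb <- frame %/% 2L + 1L
  psd <- matrix(0, nb, length(starts))
  chunk <- 256L
  for (c0 in seq(1L, length(starts), by = chunk)) {
    cols <- c0:min(c0 + chunk - 1L, length(starts))
    M <- x[outer(seq_len(frame) - 1L, starts[cols], `+`)] * w
    dim(M) <- c(frame, length(cols))
    X <- stats::mvfft(M)[seq_len(nb), , drop = FALSE]
    P <- scale * (Re(X)^2 + Im(X)^2)
    P[1, ] <- P[1, ] / 2
    if (frame %% 2L == 0L) P[nb, ] <- P[nb, ] / 2
    psd[, cols] <- P
  }
  structure(list(times = (starts - 1 + frame / 2) / fs,
                 freq = seq(0, by = fs / frame, length.out = nb),
                 psd = psd, fs = fs, frame = frame, overlap = overlap),
            class = "psd_spectrogram")
}

#' Normalize a PSD spectrogram by its noise floor
#'
#' The noise-floor spectrum is the time average of the frames whose mean
#' spectral level in the reference band lies in the lowest
#' `quantile` fraction; the output is the per-bin PSD in dB above that
#' floor.  Rare loud transients fall outside the lowest fraction and so
#' do not contaminate the floor.
#'
#' @param ps A `psd_spectrogram`.
#' @param ref_band Reference band (Hz), default 5-50 kHz.
#' @param quantile Fraction of quietest frames used (default 0.05).
#' @param min_frames Below this frame count the floor uses all frames
#'   and the result is flagged.
#' @return List of class `norm_psd`: `times`, `freq`, `db` (bins x
#'   frames, dB re floor), `floor_db`, `flagged`.
#' @export
normalize_psd <- function(ps, ref_band = c(5e3, 50e3), quantile = 0.05,
                          min_frames = 20) {
  sel <- ps$freq >= ref_band[1] & ps$freq <= ref_band[2]
  if (!any(sel)) stop("reference band outside the frequency axis")
  nfr <- ncol(ps$psd)
  frame_level <- colMeans(ps$psd[sel, , drop = FALSE])
  flagged <- nfr < min_frames
  use <- if (flagged) seq_len(nfr) else {
    k <- max(1L, floor(quantile * nfr))
    order(frame_level)[seq_len(k)]
  }
  tiny <- .Machine$double.xmin
  floor_lin <- rowMeans(ps$psd[, use, drop = FALSE])
  dbm <- 10 * log10(pmax(ps$psd, tiny)) -
    10 * log10(pmax(floor_lin, tiny))
  structure(list(times = ps$times, freq = ps$freq, db = dbm,
                 floor_db = 10 * log10(pmax(floor_lin, tiny)),
                 fs = ps$fs, frame = ps$frame,
                 flagged = flagged), class = "norm_psd")
}

band_frame_levels <- function(nps, band) {
  sel <- nps$freq >= band[1] & nps$freq <= band[2]
  if (!any(sel)) stop("band outside the frequency axis")
  10 * log10(colMeans(undb(nps$db[sel, , drop = FALSE])))
}

#' Per-segment echolocation/guard level difference
#'
#' For each band the per-frame band-integrated normalized level is
#' computed; within each segment the statistic is the (linear-domain)
#' time average over the loudest `top_fraction` of frames; the segment
#' score is the echolocation-band statistic minus the guard-band
#' statistic (dB).  The segment grid is anchored at the recording start
#' and a partial trailing segment is dropped.
#'
#' @param nps A `norm_psd`.
#' @param segment_s Segment length (s, default 150 = 2.5 min).
#' @param echo_band,guard_band Bands (Hz).
#' @param top_fraction Fraction of loudest frames averaged (default
#'   0.01).
#' @return Data frame with `segment`, `t_start`, `level_echo`,
#'   `level_guard`, `level_diff` (dB).
#' @export
segment_level_difference <- function(nps, segment_s = 150,
                                     echo_band = c(20e3, 40e3),
                                     guard_band = c(4e3, 8e3),
                                     top_fraction = 0.01) {
  le <- band_frame_levels(nps, echo_band)
  lg <- band_frame_levels(nps, guard_band)
  seg <- floor(nps$times / segment_s)
  # a trailing segment counts as complete when frames cover it to within
  # one analysis frame of its end; shorter partials are dropped
  covered <- max(nps$times) + nps$frame / nps$fs
  n_seg <- floor(covered / segment_s + 1e-9)
  top_mean <- function(v) {
    k <- max(1L, ceiling(top_fraction * length(v)))
    10 * log10(mean(undb(sort(v, decreasing = TRUE)[seq_len(k)])))
  }
  out <- lapply(seq_len(n_seg) - 1L, function(s) {
    i <- seg == s
    if (!any(i)) return(data.frame(segment = s + 1L,
                                   t_start = s * segment_s,
                                   level_echo = NA_real_,
                                   level_guard = NA_real_,
                                   level_diff = NA_real_))
    e <- top_mean(le[i]); g <- top_mean(lg[i])
    data.frame(segment = s + 1L, t_start = s * segment_s,
               level_echo = e, level_guard = g, level_diff = e - g)
  })
  do.call(rbind, out)
}

#' Threshold detection of click-positive segments
#'
#' @param segments Data frame from [segment_level_difference()] (or a
#'   numeric vector of level differences).
#' @param threshold_db Detector threshold (dB); the working points are 5
#'   and 8 dB.
#' @return The input with a logical `detected` column (vector input
#'   returns a logical vector).
#' @export
detect_clicks <- function(segments, threshold_db = 5) {
  if (is.numeric(segments)) return(segments >= threshold_db)
  segments$detected <- segments$level_diff >= threshold_db
  segments
}

#' Precision/recall across a threshold grid
#'
#' @param level_diff Segment scores (dB).
#' @param truth Logical ground-truth click presence per segment.
#' @param thresholds Threshold grid (dB).
#' @return Data frame with `threshold`, `tp`, `fp`, `fn`, `precision`,
#'   `recall`; undefined ratios are NA and flagged via attribute
#'   `flagged`.
#' @export
roc_tune <- function(level_diff, truth,
                     thresholds = seq(0, 12, by = 0.5)) {
  stopifnot(length(level_diff) == length(truth))
  flagged <- !any(truth)
  out <- lapply(thresholds, function(d) {
    det <- level_diff >= d
    tp <- sum(det & truth); fp <- sum(det & !truth)
    fn <- sum(!det & truth)
    data.frame(threshold = d, tp = tp, fp = fp, fn = fn,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
  })
  res <- do.call(rbind, out)
  attr(res, "flagged") <- flagged
  res
}

#' Click-absent periods from a detection series
#'
#' Maximal runs of consecutive non-detected segments.  Runs no longer
#' than `exclude_min` minutes are excluded from the baseline set (such
#' short clicking gaps occur normally during foraging).
#'
#' @param detected Logical vector of per-segment detections (contiguous
#'   series).
#' @param segment_min Segment length in minutes (default 2.5).
#' @param exclude_min Baseline exclusion limit (default 10 min,
#'   inclusive).
#' @return List of class `click_absent_periods`: `periods` (data frame
#'   `start_segment`, `start_min`, `duration_min`, `baseline`),
#'   `baseline_durations_min`.
#' @export
click_absent_periods <- function(detected, segment_min = 2.5,
                                 exclude_min = 10) {
  r <- rle(!detected)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  periods <- data.frame(
    start_segment = starts[keep],
    start_min = (starts[keep] - 1L) * segment_min,
    duration_min = r$lengths[keep] * segment_min)
  periods$baseline <- periods$duration_min > exclude_min
  structure(list(periods = periods,
                 baseline_durations_min =
                   periods$duration_min[periods$baseline],
                 segment_min = segment_min,
                 exclude_min = exclude_min),
            class = "click_absent_periods")
}

#' Last click-absent period starting within a window
#'
#' @param cap A `click_absent_periods`.
#' @param window_min `c(start, end)` in minutes on the segment clock
#'   (e.g. the sonar exposure window).
#' @return One-row data frame, or `NULL` if no period starts inside the
#'   window.
#' @export
last_absent_period_in <- function(cap, window_min) {
  p <- cap$periods
  inw <- p$start_min >= window_min[1] & p$start_min <= window_min[2]
  if (!any(inw)) return(NULL)
  p[max(which(inw)), , drop = FALSE]
}

#' Click-absence outlier test
#'
#' Compares the duration of a click-absent period (the last one starting
#' during sonar exposure) with the empirical distribution of baseline
#' click-absent durations; a response is declared when the duration
#' exceeds the `q`-quantile (type-7) of the baseline durations.
#'
#' @param duration_min Test duration (minutes).
#' @param baseline_durations_min Baseline durations (minutes).
#' @param q Quantile (default 0.95).
#' @return List with `response` (logical), `percentile` (empirical CDF
#'   value of the test duration), `threshold_min`, `n_baseline`,
#'   `low_power` (fewer than 20 baseline periods).
#' @export
absence_outlier_test <- function(duration_min, baseline_durations_min,
                                 q = 0.95) {
  if (length(baseline_durations_min) == 0)
    stop("empty baseline click-absent distribution")
  thr <- stats::quantile(baseline_durations_min, q, type = 7,
                         names = FALSE)
  list(response = duration_min > thr,
       percentile = stats::ecdf(baseline_durations_min)(duration_min),
       threshold_min = thr,
       n_baseline = length(baseline_durations_min),
       low_power = length(baseline_durations_min) < 20)
}
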