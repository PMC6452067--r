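# Synthetic passive-acoustic scenes.
#
# Scenes consist of Gaussian background noise with band-limited click
# transients (Gaussian-windowed tone bursts centred in the 20-40 kHz
# echolocation band) at known times, optional 4-8 kHz tonal interferers
# and optional broadband transients.  The default audio rate of 144 kHz
# makes a 56.9 ms analysis frame exactly 8192 samples.

#' Default PAM scene parameters
#' @return Named list: `fs` (Hz), `segment_s`, `n_segments`,
#'   `click_rate` (clicks per second in click-positive segments),
#'   `click_snr_db` (peak amplitude re noise sd), `click_f0` (Hz),
#'   `click_sd_s` (Gaussian envelope sd), `noise_sd`.
#' @export
pam_defaults <- function() {
  list(fs = 144000, segment_s = 150, n_segments = 12, click_rate = 1.5,
       click_snr_db = 25, click_f0 = 30000, click_sd_s = 8e-5,
       noise_sd = 1)
}

#' Generate a synthetic PAM scene
#'
#' @param config A [sim_config()]; `config$pam` holds the scene
#'   parameters.
#' @param present Logical vector (length `n_segments`): which segments
#'   contain clicking whales.  Default: all, unless `click_rate` is 0.
#' @param interferer_segments Segment indices receiving 4-8 kHz tonal
#'   interferer bursts.
#' @param broadband_segments Segment indices receiving broadband (full
#'   bandwidth) transients, for guard-band-rejection tests.
#' @param emit `"audio"` returns the waveform; `"psd"` reduces each
#'   segment to framed PSDs immediately (memory-friendly for long
#'   scenes) and returns a concatenated `psd_spectrogram`.
#' @param frame Frame length for `emit = "psd"`.
#' @return List `(audio | psd, truth)`; `truth` has `click_times` (s)
#'   and `present`.
#' @export
make_pam_scene <- function(config = sim_config(), present = NULL,
                           interferer_segments = integer(0),
                           broadband_segments = integer(0),
                           emit = c("audio", "psd"), frame = NULL) {
  emit <- match.arg(emit)
  p <- config$pam
  if (p$fs / 2 < 40e3)
    stop("sample rate too low: echolocation band edge above Nyquist")
  nseg <- p$n_segments
  if (is.null(present)) present <- rep(p$click_rate > 0, nseg)
  stopifnot(length(present) == nseg)
  seg_n <- round(p$segment_s * p$fs)
  click_len <- round(8 * p$click_sd_s * p$fs)  # +-4 sd
  tc <- (seq_len(click_len) - click_len / 2) / p$fs
  click_wave <- exp(-tc^2 / (2 * p$click_sd_s^2)) *
    sin(2 * pi * p$click_f0 * tc)
  amp <- p$noise_sd * 10^(p$click_snr_db / 20)
  audio_segs <- vector("list", if (emit == "audio") nseg else 0L)
  psd_segs <- vector("list", if (emit == "psd") nseg else 0L)
  click_times <- numeric(0)
  with_seed(config$seed, {
    for (s in seq_len(nseg)) {
      x <- stats::rnorm(seg_n, 0, p$noise_sd)
      if (present[s] && p$click_rate > 0) {
        nclick <- stats::rpois(1, p$click_rate * p$segment_s)
        t0 <- sort(stats::runif(nclick, 0, p$segment_s - 8 * p$click_sd_s))
        for (tcl in t0) {
          i0 <- round(tcl * p$fs) + 1L
          idx <- i0:(i0 + click_len - 1L)
          x[idx] <- x[idx] + amp * click_wave
        }
        click_times <- c(click_times, (s - 1) * p$segment_s + t0)
      }
      if (s %in% interferer_segments) {
        # 50 ms tonal bursts at 6 kHz, one per second
        bt <- seq(0.5, p$segment_s - 1, by = 1)
        for (b in bt) {
          idx <- round(b * p$fs) + seq_len(round(0.05 * p$fs))
          x[idx] <- x[idx] + amp *
            sin(2 * pi * 6000 * seq_along(idx) / p$fs)
        }
      }
      if (s %in% broadband_segments) {
        # loud white-noise bursts exciting both bands equally
        bt <- seq(0.5, p$segment_s - 1, by = 1)
        for (b in bt) {
          idx <- round(b * p$fs) + seq_len(round(0.01 * p$fs))
          x[idx] <- x[idx] + stats::rnorm(length(idx), 0, 10 * p$noise_sd)
        }
      }
      if (emit == "audio") audio_segs[[s]] <- x
      else psd_segs[[s]] <- psd_spectrogram(x, p$fs, frame = frame)
    }
  })
  truth <- list(click_times = click_times, present = present,
                segment_s = p$segment_s)
  if (emit == "audio")
    return(list(audio = unlist(audio_segs), fs = p$fs, truth = truth))
  # concatenate per-segment spectrograms onto the scene clock
  ps1 <- psd_segs[[1]]
  nfr <- vapply(psd_segs, function(z) ncol(z$psd), 0L)
  psd <- do.call(cbind, lapply(psd_segs, function(z) z$psd))
  times <- unlist(lapply(seq_len(nseg), function(s)
    psd_segs[[s]]$times + (s - 1) * p$segment_s))
  structure(list(times = times, freq = ps1$freq, psd = psd, fs = p$fs,
                 frame = ps1$frame, overlap = ps1$overlap),
            class = "psd_spectrogram") -> ps
  list(psd = ps, truth = truth)
}
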