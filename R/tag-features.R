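# Behavioural time-series variables derived from tag sensor data.
#
# All series are sampled at the tag rate (default 5 Hz).  Window operators
# use centred windows and require full support: samples whose window
# extends beyond the record are NA.  Variables that are only meaningful
# while submerged (speed, ODBA, pitching movement) are masked (NA) at
# depths of 5 m or less.

#' Body orientation from acceleration and magnetic field
#'
#' Pitch is the angle of the longitudinal axis from horizontal (positive
#' nose-up), roll the rotation about the longitudinal axis, and heading
#' the direction of the longitudinal axis in the horizontal plane after
#' tilt correction, clockwise from geographic north in (-pi, pi].
#' Axes: x forward, y right, z down; a level animal reads
#' acceleration (0, 0, -1) g.
#'
#' @param acc n x 3 accelerometer matrix (any consistent unit).
#' @param mag n x 3 magnetometer matrix (any consistent unit).
#' @param declination Magnetic declination (radians) added to the
#'   magnetic heading to obtain geographic heading.
#' @return Data frame with `pitch`, `roll`, `heading` (radians).
#'   Samples with zero-norm acceleration are masked.
#' @export
orientation <- function(acc, mag, declination = 0) {
  acc <- as.matrix(acc); mag <- as.matrix(mag)
  stopifnot(ncol(acc) == 3, ncol(mag) == 3, nrow(acc) == nrow(mag))
  nrm <- sqrt(rowSums(acc^2))
  bad <- !is.finite(nrm) | nrm == 0
  ax <- acc[, 1] / nrm; ay <- acc[, 2] / nrm; az <- acc[, 3] / nrm
  pitch <- atan2(ax, sqrt(ay^2 + az^2))
  roll <- atan2(-ay, -az)
  # de-tilt the magnetic vector: apply Ry(pitch) Rx(roll)
  cr <- cos(roll); sr <- sin(roll); cp <- cos(pitch); sp <- sin(pitch)
  m2 <- cr * mag[, 2] - sr * mag[, 3]
  m3 <- sr * mag[, 2] + cr * mag[, 3]
  h1 <- cp * mag[, 1] + sp * m3
  heading <- wrap_angle(atan2(-m2, h1) + declination)
  pitch[bad] <- NA; roll[bad] <- NA; heading[bad] <- NA
  data.frame(pitch = pitch, roll = roll, heading = heading)
}

#' Depth from pressure with temperature correction
#'
#' `depth = gain * (pressure - offset - tcoef * (temperature - tref))`.
#'
#' @param pressure Raw pressure readings.
#' @param temperature Temperature readings (same length), or `NULL` for
#'   no temperature correction.
#' @param cal List with `offset`, `gain`, `tcoef`, `tref`; if `NULL` the
#'   pressure is returned unchanged with a warning.
#' @return Depth in metres.
#' @export
depth_from_pressure <- function(pressure, temperature = NULL, cal = NULL) {
  if (is.null(cal)) {
    warning("no pressure calibration supplied; returning raw values")
    return(pressure)
  }
  tcorr <- if (is.null(temperature)) 0 else
    (cal$tcoef %||% 0) * (temperature - (cal$tref %||% 0))
  cal$gain * (pressure - cal$offset - tcorr)
}

#' Speed through water from flow-noise level
#'
#' Inverts a monotone level/speed calibration curve by interpolation.
#' Levels outside the calibrated range are clamped to the curve ends and
#' flagged.  Speed is only defined at depths greater than 5 m.
#'
#' @param level Flow-noise band level (dB).
#' @param depth Depth series (m) used for the mask.
#' @param cal Data frame with `speed` and `level`
#'   (default [flow_noise_calibration()]).
#' @param mask_depth_m Mask threshold (default 5 m).
#' @return Numeric speed series (m/s) with attribute `n_clamped`.
#' @export
speed_from_flow_noise <- function(level, depth,
                                  cal = flow_noise_calibration(),
                                  mask_depth_m = 5) {
  stopifnot(all(diff(cal$level) > 0))
  clamped <- sum(level < min(cal$level) | level > max(cal$level),
                 na.rm = TRUE)
  sp <- stats::approx(cal$level, cal$speed, xout = level, rule = 2)$y
  sp[!(depth > mask_depth_m)] <- NA
  attr(sp, "n_clamped") <- clamped
  sp
}

#' Depth-inflection proportion
#'
#' Proportion of zero crossings in the first-difference series of depth,
#' computed in a centred sliding window.
#'
#' @param depth Depth series (m).
#' @param fs Sample rate (Hz).
#' @param window Window length (s, default 30).
#' @return Series in `[0, 1]`, NA at unsupported edges.
#' @export
depth_inflections <- function(depth, fs, window = 30) {
  n <- length(depth)
  k <- round(window * fs)
  if (k > n) stop("record shorter than one window")
  s <- sign(diff(depth))
  # carry the previous sign through flat spots so a plateau is not counted
  if (length(s) && s[1] == 0) s[1] <- 1
  for (rep in which(s == 0)) s[rep] <- s[rep - 1L]  # rare at 5 Hz
  chg <- as.numeric(diff(s) != 0)                    # length n - 2
  # window at sample t covers k samples -> k - 2 difference pairs
  prop <- run_mean(chg, k - 2L)
  # re-centre onto the depth grid: chg[i] sits between samples i and i+2
  c(NA_real_, prop, NA_real_)
}

#' Circular variance in a sliding window
#'
#' One minus the mean resultant length of the angles in a centred window.
#'
#' @param theta Angle series (radians).
#' @param fs Sample rate (Hz).
#' @param window Window length (s, default 60).
#' @return Series in `[0, 1]`; windows that are entirely masked return NA.
#' @export
circular_variance <- function(theta, fs, window = 60) {
  k <- round(window * fs)
  ok <- as.numeric(is.finite(theta))
  cs <- ifelse(is.finite(theta), cos(theta), 0)
  sn <- ifelse(is.finite(theta), sin(theta), 0)
  m <- run_sum(ok, k)
  cv <- 1 - sqrt(run_sum(cs, k)^2 + run_sum(sn, k)^2) / m
  cv[!is.na(m) & m == 0] <- NA
  pmin(pmax(cv, 0), 1)
}

#' Average overall dynamic body acceleration (ODBA)
#'
#' The gravity component is separated with a running mean over the same
#' window; ODBA is the window average of the summed absolute dynamic
#' components of the three axes, masked at depths of 5 m or less.
#'
#' @param acc n x 3 accelerometer matrix.
#' @param depth Depth series (m).
#' @param fs Sample rate (Hz).
#' @param window Averaging window (s, default 5).
#' @param mask_depth_m Mask threshold (default 5 m).
#' @return ODBA series in the units of `acc`.
#' @export
odba <- function(acc, depth, fs, window = 5, mask_depth_m = 5) {
  acc <- as.matrix(acc)
  k <- round(window * fs)
  dyn <- abs(acc - vapply(1:3, function(j) run_mean(acc[, j], k),
                          numeric(nrow(acc))))
  rs <- rowSums(dyn)
  ok <- which(!is.na(rs))
  out <- rep(NA_real_, length(rs))
  if (length(ok))
    out[ok[1]:ok[length(ok)]] <- run_mean(rs[ok[1]:ok[length(ok)]], k)
  out[!(depth > mask_depth_m)] <- NA
  out
}

#' Pitching movement
#'
#' Magnitude of the high-pass-filtered pitch rate (rad/s): cyclic pitching
#' relative to the body axis, with the slow orientation component removed.
#' There is no single field-standard definition of this variable; the
#' high-pass cutoff is configurable and defaults to half the dominant
#' fluking frequency.
#'
#' @param pitch Pitch series (radians).
#' @param depth Depth series (m).
#' @param fs Sample rate (Hz).
#' @param cutoff_hz High-pass cutoff (default 0.175 Hz = 0.5 x 0.35 Hz).
#' @param mask_depth_m Mask threshold (default 5 m).
#' @return Series of |high-pass pitch rate| (rad/s).
#' @export
pitching_movement <- function(pitch, depth, fs, cutoff_hz = 0.175,
                              mask_depth_m = 5) {
  rate <- c(NA, diff(pitch)) * fs
  rate[is.na(rate)] <- 0
  bf <- signal::butter(2, min(0.99, cutoff_hz / (fs / 2)), type = "high")
  out <- abs(signal::filtfilt(bf, rate))
  out[1] <- NA
  out[!(depth > mask_depth_m)] <- NA
  out
}

#' Per-pulse received SPL from tag audio pressure
#'
#' For each pulse the maximum of a 200 ms sliding RMS over the pulse is
#' reported together with the whole-pulse RMS, both as dB re 1 uPa, and
#' their difference (the averaging-time correction for that pulse).
#'
#' @param pressure Calibrated acoustic pressure series (uPa).
#' @param fs Audio sample rate (Hz).
#' @param pulse_times Pulse start times (s, on the recording clock).
#' @param pulse_duration Pulse duration (s).
#' @param window RMS window (s, default 0.2).
#' @return Data frame with `time`, `spl_200ms`, `spl_pulse`,
#'   `correction` (dB).  Pulses outside the recording, or silent pulses,
#'   give NA.
#' @export
received_spl <- function(pressure, fs, pulse_times, pulse_duration,
                         window = 0.2) {
  n <- length(pressure)
  kw <- max(1L, round(window * fs))
  pulse_duration <- rep_len(pulse_duration, length(pulse_times))
  out <- data.frame(time = pulse_times, spl_200ms = NA_real_,
                    spl_pulse = NA_real_, correction = NA_real_)
  for (i in seq_along(pulse_times)) {
    i0 <- round(pulse_times[i] * fs) + 1L
    i1 <- i0 + round(pulse_duration[i] * fs) - 1L
    if (i0 < 1L || i1 > n) next
    seg2 <- pressure[i0:i1]^2
    ms_pulse <- mean(seg2)
    kk <- min(kw, length(seg2))
    ms_win <- max(run_mean(seg2, kk), na.rm = TRUE)
    if (ms_pulse <= 0) next
    out$spl_200ms[i] <- 10 * log10(ms_win)
    out$spl_pulse[i] <- 10 * log10(ms_pulse)
    out$correction[i] <- out$spl_200ms[i] - out$spl_pulse[i]
  }
  out
}

#' Extract the full behavioural feature set from a tag record
#'
#' Convenience wrapper computing every windowed variable used by the
#' change-point and response-intensity analyses.
#'
#' @param record A `tag_record` from [make_tag_record()].
#' @param declination Magnetic declination (radians).
#' @return Data frame of class `feature_series` with `time`, `depth`,
#'   `pitch`, `roll`, `heading`, `speed`, `depth_inflections`,
#'   `circ_var_heading`, `circ_var_pitch`, `odba`, `pitching_movement`.
#' @export
tag_features <- function(record, declination = 0) {
  stopifnot(inherits(record, "tag_record"))
  d <- record$data
  fs <- record$sampling_rate
  ori <- orientation(cbind(d$ax, d$ay, d$az), cbind(d$mx, d$my, d$mz),
                     declination)
  out <- data.frame(
    time = d$time, depth = d$depth,
    pitch = ori$pitch, roll = ori$roll, heading = ori$heading,
    speed = as.numeric(speed_from_flow_noise(d$flow_noise_level, d$depth)),
    depth_inflections = depth_inflections(d$depth, fs),
    circ_var_heading = circular_variance(ori$heading, fs),
    circ_var_pitch = circular_variance(ori$pitch, fs),
    odba = odba(cbind(d$ax, d$ay, d$az), d$depth, fs),
    pitching_movement = pitching_movement(ori$pitch, d$depth, fs))
  class(out) <- c("feature_series", "data.frame")
  attr(out, "sampling_rate") <- fs
  out
}
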