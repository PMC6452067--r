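# Sonar transmission schedules for the two exposure treatments.
#
# The close treatment transmits 1-2 kHz hyperbolic-upsweep pulses of 1 s
# every 20 s for 15 min at constant (full) source level, with no ramp-up.
# The distant treatment transmits a 3.4-3.9 kHz compound tonal (a 500 ms
# linear upsweep from 3350 to 3450 Hz followed by 500 ms tones at 3600 and
# 3900 Hz), 1.5 s every 25 s, with a 20 min ramp-up during which the source
# level rises to its maximum, followed by 15 min at full power.

.protocols <- list(
  close = list(
    band_hz        = c(1000, 2000),
    signal         = "tonal upsweep",
    pulse_duration = 1,
    pulse_interval = 20,
    ramp_up_min    = 0,
    full_power_min = 15,
    source_level   = c(185, 185),   # dB re 1 uPa^2 m^2 (min, max)
    source_depth_m = 8
  ),
  distant = list(
    band_hz        = c(3400, 3900),
    signal         = "compound tonal",
    pulse_duration = 1.5,
    pulse_interval = 25,
    ramp_up_min    = 20,
    full_power_min = 15,
    source_level   = c(154, 214),
    source_depth_m = 17
  )
)

#' Build a sonar transmission schedule
#'
#' Generates the per-pulse transmission schedule for one of the two
#' exposure treatments. During ramp-up (distant treatment only) the source
#' level rises linearly in dB from the minimum to the maximum protocol
#' level; all full-power pulses are transmitted at the maximum level.
#'
#' @param protocol `"close"` or `"distant"`.
#' @param start_time Time of the first pulse (seconds on the experiment
#'   clock; default 0).
#' @param source_level Optional override of the full-power source level
#'   (dB re 1 uPa^2 m^2), e.g. to emulate a reduced-output transmission.
#' @return An object of class `exposure_schedule`: a list with `protocol`,
#'   `band_hz`, `source_depth_m`, `duty_cycle_pct` and a data frame
#'   `pulses` with columns `time`, `duration`, `source_level` and `phase`
#'   (`"ramp-up"` or `"full-power"`).
#' @examples
#' sched <- make_exposure("distant")
#' sched$duty_cycle_pct
#' sum(sched$pulses$phase == "full-power")
#' @export
make_exposure <- function(protocol = c("close", "distant"), start_time = 0,
                          source_level = NULL) {
  protocol <- match.arg(protocol)
  p <- .protocols[[protocol]]
  sl_max <- source_level %||% p$source_level[2]
  sl_min <- if (is.null(source_level)) p$source_level[1] else source_level
  ramp_s <- p$ramp_up_min * 60
  full_s <- p$full_power_min * 60
  t_rel <- seq(0, ramp_s + full_s - p$pulse_interval, by = p$pulse_interval)
  phase <- ifelse(t_rel < ramp_s, "ramp-up", "full-power")
  sl <- ifelse(t_rel < ramp_s,
               sl_min + (sl_max - sl_min) * t_rel / max(ramp_s, 1),
               sl_max)
  structure(list(
    protocol = protocol,
    band_hz = p$band_hz,
    signal = p$signal,
    source_depth_m = p$source_depth_m,
    pulse_duration = p$pulse_duration,
    pulse_interval = p$pulse_interval,
    duty_cycle_pct = duty_cycle(p$pulse_duration, p$pulse_interval),
    ramp_up_min = p$ramp_up_min,
    full_power_min = p$full_power_min,
    pulses = data.frame(time = start_time + t_rel,
                        duration = p$pulse_duration,
                        source_level = sl,
                        phase = phase)
  ), class = "exposure_schedule")
}

#' Transmission duty cycle
#'
#' Percentage of time the source is transmitting.
#'
#' @param pulse_duration Pulse duration (s).
#' @param pulse_interval Pulse repetition interval (s).
#' @return Duty cycle in percent.
#' @examples
#' duty_cycle(1, 20)    # close treatment: 5
#' duty_cycle(1.5, 25)  # distant treatment: 6
#' @export
duty_cycle <- function(pulse_duration, pulse_interval) {
  stopifnot_scalar(pulse_duration, "pulse_duration")
  stopifnot_scalar(pulse_interval, "pulse_interval")
  100 * pulse_duration / pulse_interval
}

#' @export
print.exposure_schedule <- function(x, ...) {
  cat(sprintf("<exposure_schedule> %s treatment: %d pulses (%g s every %g s, duty %.1f%%)\n",
              x$protocol, nrow(x$pulses), x$pulse_duration, x$pulse_interval,
              x$duty_cycle_pct))
  cat(sprintf("  band %g-%g Hz, ramp-up %g min, full power %g min, SL %g-%g dB re 1 uPa^2 m^2\n",
              x$band_hz[1], x$band_hz[2], x$ramp_up_min, x$full_power_min,
              min(x$pulses$source_level), max(x$pulses$source_level)))
  invisible(x)
}
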