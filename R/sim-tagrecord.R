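# Synthetic high-resolution tag records.
#
# The generator is a parametric dive-phase machine, not a mechanistic
# model: a baseline cycle of deep foraging dives (descent, bottom foraging
# with echolocation clicks and buzzes, ascent, surface) alternating with
# shallow-dive bouts, and -- for exposed records -- an avoidance response
# after the configured onset: sustained directed heading with low angular
# variability, elevated swim speed, shallow travel and no foraging sounds.
# Only the statistical contrast between baseline and response behaviour
# matters downstream, so phase parameters are configurable defaults, not
# species-typical assertions.

#' Configuration for the synthetic-data generators
#'
#' @param seed Integer seed; a fixed seed reproduces output bit for bit.
#' @param duration_h Record duration (hours).
#' @param sample_rate Biologging sample rate (Hz).
#' @param treatment `"none"`, `"close"` or `"distant"`.
#' @param exposure_start_h Exposure start (hours into the record).
#' @param response_onset_delay_s Delay from exposure start to response
#'   onset (s).
#' @param avoidance_speed_gain Multiplier on baseline travel speed during
#'   the avoidance response.
#' @param dive Named list of dive-cycle parameters overriding the
#'   defaults (see `sim_dive_defaults()`).
#' @param noise Named list of per-channel noise scales overriding the
#'   defaults: `depth_m`, `accel_g`, `mag_ut`, `flow_db`.
#' @param hmm_truth 3-state movement-process truth for the satellite
#'   track generator; see [hmm_truth_defaults()].
#' @param pam PAM scene parameters; see [pam_defaults()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, duration_h = 6, sample_rate = 5,
                       treatment = c("none", "close", "distant"),
                       exposure_start_h = 4, response_onset_delay_s = 0,
                       avoidance_speed_gain = 1.8,
                       dive = list(), noise = list(),
                       hmm_truth = hmm_truth_defaults(),
                       pam = pam_defaults()) {
  treatment <- match.arg(treatment)
  stopifnot_scalar(duration_h, "duration_h")
  stopifnot_scalar(sample_rate, "sample_rate")
  d <- utils::modifyList(sim_dive_defaults(), dive)
  nz <- utils::modifyList(list(depth_m = 0.3, accel_g = 0.02,
                               mag_ut = 0.5, flow_db = 1.5), noise)
  structure(list(seed = as.integer(seed), duration_h = duration_h,
                 sample_rate = sample_rate, treatment = treatment,
                 exposure_start_h = exposure_start_h,
                 response_onset_delay_s = response_onset_delay_s,
                 avoidance_speed_gain = avoidance_speed_gain,
                 dive = d, noise = nz, hmm_truth = hmm_truth, pam = pam),
            class = "sim_config")
}

#' Default dive-cycle parameters
#' @return Named list of dive-phase parameters (durations s, depths m,
#'   speeds m/s, fluking frequency Hz).
#' @export
sim_dive_defaults <- function() {
  list(deep_depth_m = 800, descent_speed = 1.8, ascent_speed = 1.6,
       bottom_s = 600, surface_s = 180,
       shallow_depth_m = 60, shallow_n = 3, shallow_s = 220,
       shallow_surface_s = 60,
       bottom_speed = 1.2, surface_speed = 0.8, shallow_speed = 1.1,
       fluke_hz = 0.35,
       heading_rw_sd = 0.015, bottom_heading_rw_sd = 0.06,
       response_heading_sd = 0.002, response_depth_m = 40)
}

# Duration (s) of one full baseline dive cycle.
dive_cycle_s <- function(d) {
  deep <- d$deep_depth_m / d$descent_speed + d$bottom_s +
    d$deep_depth_m / d$ascent_speed + d$surface_s
  deep + d$shallow_n * (d$shallow_s + d$shallow_surface_s)
}

# Piecewise phase plan for one baseline cycle: data.frame of
# (phase, duration, depth_target, speed).
baseline_cycle_plan <- function(d) {
  rows <- list(
    c("descent", d$deep_depth_m / d$descent_speed, d$deep_depth_m, d$descent_speed),
    c("bottom", d$bottom_s, d$deep_depth_m, d$bottom_speed),
    c("ascent", d$deep_depth_m / d$ascent_speed, 0, d$ascent_speed),
    c("surface", d$surface_s, 0, d$surface_speed))
  for (i in seq_len(d$shallow_n)) {
    rows <- c(rows, list(
      c("shallow", d$shallow_s, d$shallow_depth_m, d$shallow_speed),
      c("surface", d$shallow_surface_s, 0, d$surface_speed)))
  }
  data.frame(phase = vapply(rows, `[`, "", 1),
             duration = as.numeric(vapply(rows, `[`, "", 2)),
             depth_target = as.numeric(vapply(rows, `[`, "", 3)),
             speed = as.numeric(vapply(rows, `[`, "", 4)))
}

# Forward model: body Euler angles -> accelerometer (g) and magnetometer
# (uT) readings.  Axes: x forward, y right, z down (NED-aligned when the
# animal is level and facing north); heading clockwise from north.
euler_to_sensors <- function(pitch, roll, heading,
                             inclination = 75 * pi / 180, field_ut = 52) {
  rot_t <- function(v1, v2, v3, phi, theta, psi) {
    # apply R^T = Rx(phi)^T Ry(theta)^T Rz(psi)^T to the earth vector
    c1 <- cos(psi); s1 <- sin(psi)
    a1 <- c1 * v1 + s1 * v2; a2 <- -s1 * v1 + c1 * v2; a3 <- v3
    c2 <- cos(theta); s2 <- sin(theta)
    b1 <- c2 * a1 - s2 * a3; b3 <- s2 * a1 + c2 * a3
    c3 <- cos(phi); s3 <- sin(phi)
    cbind(b1, c3 * a2 + s3 * b3, -s3 * a2 + c3 * b3)
  }
  acc <- -rot_t(0, 0, 1, roll, pitch, heading)
  m_n <- field_ut * cos(inclination); m_d <- field_ut * sin(inclination)
  mag <- rot_t(m_n, 0, m_d, roll, pitch, heading)
  list(acc = acc, mag = mag)
}

#' Default flow-noise / speed calibration curve
#'
#' Monotone mapping between speed through water and the band level of
#' low-frequency flow noise, used both by the generator (forward) and by
#' [speed_from_flow_noise()] (inverse).
#' @return Data frame with `speed` (m/s) and `level` (dB).
#' @export
flow_noise_calibration <- function() {
  speed <- seq(0, 5, by = 0.1)
  data.frame(speed = speed, level = 45 + 15 * speed)
}

#' Generate a synthetic tag record
#'
#' @param config A [sim_config()].
#' @return A list `(record, truth)`.  `record` is a list of class
#'   `tag_record` with `sampling_rate`, a data frame `data` (columns
#'   `time` s, `depth` m, `ax, ay, az` g, `mx, my, mz` uT,
#'   `flow_noise_level` dB) and an `annotations` data frame
#'   (`start`, `stop`, `kind` in clicks/buzz).  `truth` records the
#'   response onset time (NA when no response is simulated), per-sample
#'   phase labels and the true speed, heading and depth series.
#' @examples
#' out <- make_tag_record(sim_config(seed = 7, duration_h = 2,
#'                                   exposure_start_h = 1))
#' range(out$record$data$depth)
#' @export
make_tag_record <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  d <- config$dive
  fs <- config$sample_rate
  n <- round(config$duration_h * 3600 * fs)
  cyc <- dive_cycle_s(config$dive)
  if (config$duration_h * 3600 < cyc)
    stop(sprintf("duration (%.2f h) shorter than one dive cycle (%.2f h)",
                 config$duration_h, cyc / 3600))

  onset_s <- if (config$treatment == "none") NA_real_ else
    config$exposure_start_h * 3600 + config$response_onset_delay_s

  with_seed(config$seed, {
    tt <- (seq_len(n) - 1) / fs
    plan <- baseline_cycle_plan(d)
    # Build per-sample phase/speed/target-depth by tiling baseline cycles,
    # truncating the cycle machine at response onset (if any).
    phase <- character(n); speed <- numeric(n); depth <- numeric(n)
    cur_depth <- 0; i <- 1L; prow <- 1L
    n_base <- if (is.na(onset_s)) n else min(n, floor(onset_s * fs) + 1L)
    while (i <= n_base) {
      row <- plan[prow, ]
      k <- max(1L, round(row$duration * fs))
      idx <- i:min(n_base, i + k - 1L)
      phase[idx] <- row$phase
      speed[idx] <- row$speed
      frac <- seq_along(idx) / k
      if (row$phase %in% c("descent", "ascent")) {
        depth[idx] <- cur_depth + (row$depth_target - cur_depth) * frac
      } else if (row$phase == "shallow") {
        # V-shaped shallow dive
        depth[idx] <- row$depth_target * (1 - abs(2 * frac - 1))
      } else {
        depth[idx] <- row$depth_target
      }
      cur_depth <- depth[idx[length(idx)]]
      i <- i + length(idx)
      prow <- prow %% nrow(plan) + 1L
    }
    if (!is.na(onset_s) && n_base < n) {
      idx <- (n_base + 1L):n
      phase[idx] <- "response"
      # sustained flight: clearly above the fastest baseline phase
      speed[idx] <- d$descent_speed * config$avoidance_speed_gain
      # rapid excursion to travel depth, then gentle undulation
      frac <- pmin(1, (tt[idx] - tt[n_base]) / 120)
      depth[idx] <- depth[n_base] +
        (d$response_depth_m - depth[n_base]) * frac +
        6 * sin(2 * pi * (tt[idx] - tt[n_base]) / 300) * (frac == 1)
    }

    # Heading: persistent random walk, more tortuous during bottom
    # foraging, nearly constant during the response.
    hsd <- rep(d$heading_rw_sd, n)
    hsd[phase == "bottom"] <- d$bottom_heading_rw_sd
    hsd[phase == "response"] <- d$response_heading_sd
    heading <- wrap_angle(cumsum(stats::rnorm(n, 0, hsd)))

    # Pitch follows the vertical velocity; small fluking oscillation.
    dz <- c(diff(depth), 0) * fs
    pitch_geo <- -asin(pmax(-0.95, pmin(0.95, dz / pmax(speed, 0.3))))
    fluke_amp <- ifelse(phase %in% c("descent", "response"), 0.10,
                 ifelse(phase == "bottom", 0.06, 0.03))
    pitch <- pitch_geo + fluke_amp * sin(2 * pi * d$fluke_hz * tt)
    roll <- 0.05 * sin(2 * pi * 0.02 * tt) +
      stats::rnorm(n, 0, 0.01)

    sens <- euler_to_sensors(pitch, roll, heading)
    # dynamic (fluking) acceleration along the dorsoventral axis
    dyn <- fluke_amp * 1.5 * sin(2 * pi * d$fluke_hz * tt + pi / 3)
    acc <- sens$acc + cbind(0, 0, dyn) +
      matrix(stats::rnorm(3 * n, 0, config$noise$accel_g), ncol = 3)
    mag <- sens$mag +
      matrix(stats::rnorm(3 * n, 0, config$noise$mag_ut), ncol = 3)

    cal <- flow_noise_calibration()
    flow <- stats::approx(cal$speed, cal$level, xout = speed, rule = 2)$y +
      stats::rnorm(n, 0, config$noise$flow_db)
    depth_obs <- pmax(-1, depth + stats::rnorm(n, 0, config$noise$depth_m))

    # Foraging-sound annotations: clicking through the bottom phase with
    # two buzzes; none after response onset.
    ann <- list()
    r <- rle(phase)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (j in which(r$values == "bottom")) {
      t0 <- tt[starts[j]]; t1 <- tt[ends[j]]
      ann[[length(ann) + 1L]] <-
        data.frame(start = t0 + 5, stop = t1 - 5, kind = "clicks")
      bt <- t0 + (t1 - t0) * c(0.35, 0.7)
      ann[[length(ann) + 1L]] <-
        data.frame(start = bt, stop = bt + 8, kind = "buzz")
    }
    annotations <- if (length(ann)) do.call(rbind, ann) else
      data.frame(start = numeric(), stop = numeric(), kind = character())

    record <- structure(list(
      sampling_rate = fs,
      data = data.frame(time = tt, depth = depth_obs,
                        ax = acc[, 1], ay = acc[, 2], az = acc[, 3],
                        mx = mag[, 1], my = mag[, 2], mz = mag[, 3],
                        flow_noise_level = flow),
      annotations = annotations), class = "tag_record")
    truth <- list(response_onset_time = onset_s,
                  exposure_start = if (config$treatment == "none") NA_real_
                                   else config$exposure_start_h * 3600,
                  phase = phase, speed = speed, heading = heading,
                  depth = depth)
  })
  list(record = record, truth = truth)
}

#' @export
print.tag_record <- function(x, ...) {
  cat(sprintf("<tag_record> %.2f h at %g Hz, %d annotations\n",
              nrow(x$data) / x$sampling_rate / 3600, x$sampling_rate,
              nrow(x$annotations)))
  invisible(x)
}
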