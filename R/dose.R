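# Received-level (acoustic dose) estimation.
#
# The received sound pressure level of each transmitted pulse is modelled
# with geometric spherical spreading plus linear frequency-dependent
# seawater absorption.  This propagation law is a deliberately simple,
# pluggable stand-in: `monte_carlo_dose()` and `mooring_dose()` accept any
# function with the `propagate_spl()` signature, so a full ray-trace
# backend can be substituted without touching the uncertainty machinery,
# which is the substantive part of this module: positional and depth
# uncertainty of the animal are propagated into the received level by
# Monte-Carlo simulation.

#' Seawater absorption coefficient (Thorp)
#'
#' Classical Thorp approximation of the low-frequency volume absorption
#' coefficient in seawater.
#'
#' @param f_khz Frequency in kHz.
#' @return Absorption in dB per km.
#' @examples
#' absorption_db_km(1.5)  # ~0.1 dB/km
#' @export
absorption_db_km <- function(f_khz) {
  f2 <- f_khz^2
  0.11 * f2 / (1 + f2) + 44 * f2 / (4100 + f2) + 2.75e-4 * f2 + 0.003
}

#' Propagate a source level to a received SPL
#'
#' Spherical spreading with linear absorption:
#' `SPL = SL - 20 log10(range / 1 m) - alpha * range_km`.
#' Ranges below the 1 m reference are clamped to 1 m.
#'
#' @param source_level Source level, dB re 1 uPa^2 m^2.
#' @param range_m Source-animal range in metres (vectorised).
#' @param alpha_db_km Absorption coefficient, dB/km; defaults to the Thorp
#'   value at `f_khz`.
#' @param f_khz Band-centre frequency used for the default absorption.
#' @return Received SPL, dB re 1 uPa.
#' @examples
#' propagate_spl(214, 10e3, alpha_db_km = 0)  # 134 dB
#' @export
propagate_spl <- function(source_level, range_m, alpha_db_km = NULL,
                          f_khz = 1.5) {
  if (is.null(alpha_db_km)) alpha_db_km <- absorption_db_km(f_khz)
  r <- pmax(range_m, 1)
  source_level - 20 * log10(r) - alpha_db_km * r / 1000
}

#' Fit surface/diving depth-uncertainty distributions
#'
#' Satellite tags report a coarse regular depth series and a sparser dive
#' summary profile.  Residuals between the coarse depths and a linear
#' interpolation of the summary profile are fitted with two normal
#' distributions by moment matching, split into a surface state and a
#' diving state.
#'
#' @param summary_profile Data frame with `time` (s) and `depth` (m): the
#'   dive summary profile.
#' @param coarse Data frame with `time` and `depth`: the regular (e.g.
#'   2.5 min) depth series.
#' @param surface_depth_m Interpolated depths at or above this value are
#'   treated as the surface state (default 15 m).
#' @param min_n Minimum residuals per state; below it a wide default
#'   standard deviation is returned and flagged.
#' @param default_sd Fallback standard deviation (m).
#' @return A list of class `depth_uncertainty` with elements `surface` and
#'   `diving`, each `(mean, sd, n, defaulted)`.
#' @export
fit_depth_uncertainty <- function(summary_profile, coarse,
                                  surface_depth_m = 15, min_n = 10,
                                  default_sd = 50) {
  interp <- stats::approx(summary_profile$time, summary_profile$depth,
                          xout = coarse$time, rule = 2)$y
  resid <- coarse$depth - interp
  at_surface <- interp <= surface_depth_m
  fit1 <- function(r) {
    if (length(r) < min_n)
      return(list(mean = 0, sd = default_sd, n = length(r), defaulted = TRUE))
    s <- stats::sd(r)
    list(mean = mean(r), sd = s, n = length(r),
         defaulted = FALSE, degenerate = s == 0)
  }
  structure(list(surface = fit1(resid[at_surface]),
                 diving = fit1(resid[!at_surface])),
            class = "depth_uncertainty")
}

# Offset a (lon, lat) position by east/north metres on the sphere.
offset_lonlat <- function(lon, lat, east_m, north_m, r_earth = 6371000) {
  dlat <- north_m / r_earth * 180 / pi
  dlon <- east_m / (r_earth * cos(lat * pi / 180)) * 180 / pi
  cbind(lon = lon + dlon, lat = lat + dlat)
}

slant_range_m <- function(horiz_m, depth_animal, depth_source) {
  sqrt(horiz_m^2 + (depth_animal - depth_source)^2)
}

summarize_dose <- function(spl_draws, pulse_times) {
  # spl_draws: n_draws x n_pulses matrix of received SPLs
  qs <- apply(spl_draws, 2, stats::quantile,
              probs = c(0.05, 0.5, 0.95), type = 7, names = FALSE)
  per_pulse <- data.frame(time = pulse_times,
                          spl_q05 = qs[1, ], spl_median = qs[2, ],
                          spl_q95 = qs[3, ])
  splmax_draws <- apply(spl_draws, 1, max)
  splmax <- stats::quantile(splmax_draws, c(0.05, 0.5, 0.95),
                            type = 7, names = FALSE)
  list(per_pulse = per_pulse,
       splmax = c(q05 = splmax[1], median = splmax[2], q95 = splmax[3]))
}

#' Monte-Carlo received-level estimate for a tracked animal
#'
#' Draws animal positions (isotropic Gaussian around the estimated
#' position) and depths (from a fitted depth-uncertainty state model),
#' computes the 3-D slant range to the source for every pulse and applies
#' the propagation model plus the averaging-time correction.  Per-pulse
#' received levels and the per-exposure maximum (SPLmax) are summarised as
#' the median with a 90% interval.
#'
#' @param schedule An `exposure_schedule` from [make_exposure()].
#' @param source_pos `c(lon, lat)` of the (drifting) source.
#' @param animal_pos `c(lon, lat)` estimated animal position.
#' @param pos_sd_m Isotropic positional uncertainty s.d. (m).
#' @param animal_depth Mean animal depth (m, positive down).
#' @param depth_unc A `depth_uncertainty` object or `NULL` for none.
#' @param diving Logical: use the diving-state (otherwise surface-state)
#'   depth distribution.
#' @param n_draws Number of Monte-Carlo draws (>= 100).
#' @param seed Integer seed.
#' @param correction_db Averaging-time correction added to the modelled
#'   whole-pulse SPL (see [averaging_correction()]).
#' @param propagation Propagation function with the signature of
#'   [propagate_spl()].
#' @param ... Passed to `propagation`.
#' @return A list of class `dose_estimate` with `per_pulse` (data frame)
#'   and `splmax` (named 5/50/95% quantiles), plus the settings used.
#' @export
monte_carlo_dose <- function(schedule, source_pos, animal_pos, pos_sd_m,
                             animal_depth = 0, depth_unc = NULL,
                             diving = TRUE, n_draws = 1000, seed = 1,
                             correction_db = 0,
                             propagation = propagate_spl, ...) {
  if (n_draws < 100) stop("n_draws must be at least 100")
  pulses <- schedule$pulses
  f_khz <- mean(schedule$band_hz) / 1000
  with_seed(seed, {
    pos <- offset_lonlat(animal_pos[1], animal_pos[2],
                         stats::rnorm(n_draws, 0, pos_sd_m),
                         stats::rnorm(n_draws, 0, pos_sd_m))
    z <- rep(animal_depth, n_draws)
    if (!is.null(depth_unc)) {
      st <- if (diving) depth_unc$diving else depth_unc$surface
      z <- pmax(0, z + stats::rnorm(n_draws, st$mean, st$sd))
    }
    horiz <- geosphere::distHaversine(pos, source_pos, r = 6371000)
    rng <- slant_range_m(horiz, z, schedule$source_depth_m)
    loss <- propagation(0, rng, f_khz = f_khz, ...)
    spl_draws <- sweep(matrix(loss, n_draws, nrow(pulses)), 2,
                       pulses$source_level, `+`) + correction_db
    out <- summarize_dose(spl_draws, pulses$time)
  })
  structure(c(out, list(n_draws = n_draws, seed = seed,
                        pos_sd_m = pos_sd_m,
                        correction_db = correction_db)),
            class = "dose_estimate")
}

#' Monte-Carlo received-level estimate near a moored recorder
#'
#' Animals detected on a bottom-moored recorder have unknown positions;
#' simulated animals are placed uniformly (by area) within a detection
#' annulus around the mooring, at depths resampled from pre-exposure
#' satellite-tag depth data.
#'
#' @inheritParams monte_carlo_dose
#' @param mooring_pos `c(lon, lat)` of the mooring.
#' @param detection_range_km `c(min, max)` detection annulus radii (km);
#'   the default 1-4 km reflects the assumed acoustic detection range.
#' @param depth_sample Numeric vector of depths (m) to resample from.
#' @return A `dose_estimate`.
#' @export
mooring_dose <- function(schedule, source_pos, mooring_pos,
                         detection_range_km = c(1, 4), depth_sample = 0,
                         n_draws = 1000, seed = 1, correction_db = 0,
                         propagation = propagate_spl, ...) {
  if (n_draws < 100) stop("n_draws must be at least 100")
  pulses <- schedule$pulses
  f_khz <- mean(schedule$band_hz) / 1000
  r1 <- detection_range_km[1] * 1000
  r2 <- detection_range_km[2] * 1000
  with_seed(seed, {
    u <- stats::runif(n_draws)
    rad <- sqrt(u * (r2^2 - r1^2) + r1^2)   # area-uniform in the annulus
    ang <- stats::runif(n_draws, 0, 2 * pi)
    pos <- offset_lonlat(mooring_pos[1], mooring_pos[2],
                         rad * sin(ang), rad * cos(ang))
    z <- sample(rep_len(depth_sample, max(length(depth_sample), 1)),
                n_draws, replace = TRUE)
    horiz <- geosphere::distHaversine(pos, source_pos, r = 6371000)
    rng <- slant_range_m(horiz, z, schedule$source_depth_m)
    loss <- propagation(0, rng, f_khz = f_khz, ...)
    spl_draws <- sweep(matrix(loss, n_draws, nrow(pulses)), 2,
                       pulses$source_level, `+`) + correction_db
    out <- summarize_dose(spl_draws, pulses$time)
  })
  structure(c(out, list(n_draws = n_draws, seed = seed,
                        detection_range_km = detection_range_km,
                        correction_db = correction_db)),
            class = "dose_estimate")
}

#' Averaging-time correction
#'
#' Modelled levels are whole-pulse RMS levels, whereas measured levels use
#' a 200 ms maximum-RMS window.  The correction is the mean paired
#' difference (200 ms minus whole-pulse), applied additively to modelled
#' levels.
#'
#' @param spl_200ms,spl_whole Paired per-pulse SPLs (dB); `NA` pairs are
#'   dropped.
#' @return List with `correction_db`, `n_pairs` and `flagged` (no usable
#'   pairs: correction 0).
#' @export
averaging_correction <- function(spl_200ms, spl_whole) {
  d <- spl_200ms - spl_whole
  d <- d[is.finite(d)]
  if (length(d) == 0)
    return(list(correction_db = 0, n_pairs = 0L, flagged = TRUE))
  list(correction_db = mean(d), n_pairs = length(d), flagged = FALSE)
}

#' @export
print.dose_estimate <- function(x, ...) {
  cat(sprintf("<dose_estimate> %d pulses, %d draws\n",
              nrow(x$per_pulse), x$n_draws))
  cat(sprintf("  SPLmax median %.1f dB re 1 uPa (90%% CI %.1f-%.1f)\n",
              x$splmax["median"], x$splmax["q05"], x$splmax["q95"]))
  invisible(x)
}
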