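# Feature extraction from tag sensor channels.

test_that("orientation recovers canonical and randomized attitudes", {
  # level, facing north: acceleration (0,0,-g), field north-horizontal
  o <- orientation(matrix(c(0, 0, -1), 1), matrix(c(50, 0, 0), 1))
  expect_equal(unlist(o), c(pitch = 0, roll = 0, heading = 0))

  # pitched up 90 degrees: acceleration along the longitudinal axis
  o2 <- orientation(matrix(c(1, 0, 0), 1), matrix(c(0, 0, -50), 1))
  expect_equal(abs(o2$pitch), pi / 2, tolerance = 1e-12)

  # round trip through the forward model for random attitudes
  set.seed(1)
  n <- 200
  pitch <- runif(n, -1.4, 1.4)
  roll <- runif(n, -1.4, 1.4)
  heading <- runif(n, -pi + 0.01, pi - 0.01)
  sens <- sonarcee:::euler_to_sensors(pitch, roll, heading)
  o3 <- orientation(sens$acc, sens$mag)
  expect_lt(max(abs(o3$pitch - pitch)), 1e-6)
  expect_lt(max(abs(o3$roll - roll)), 1e-6)
  expect_lt(max(abs(sonarcee:::wrap_angle(o3$heading - heading))), 1e-6)

  # zero-norm acceleration sample is masked
  o4 <- orientation(rbind(c(0, 0, -1), c(0, 0, 0)),
                    rbind(c(50, 0, 0), c(50, 0, 0)))
  expect_true(is.na(o4$pitch[2]))
})

test_that("pressure-to-depth calibration removes temperature drift", {
  p <- seq(0, 100, length.out = 50)
  cal <- list(offset = 2, gain = 0.99, tcoef = 0.5, tref = 10)
  expect_equal(depth_from_pressure(p, rep(10, 50), cal),
               0.99 * (p - 2))
  # synthetic temperature drift injected then corrected
  temp <- 10 + seq(0, 4, length.out = 50)
  praw <- (0:49) / 0.99 + 2 + 0.5 * (temp - 10)
  expect_lt(max(abs(depth_from_pressure(praw, temp, cal) - 0:49)), 0.1)
  expect_warning(depth_from_pressure(p, cal = NULL), "calibration")
})

test_that("flow-noise speed inverts the calibration and masks the surface", {
  cal <- flow_noise_calibration()
  mid <- nrow(cal) %/% 2
  sp <- speed_from_flow_noise(cal$level[mid], depth = 100, cal = cal)
  expect_equal(as.numeric(sp), cal$speed[mid])
  # fully masked at or above 5 m
  sp2 <- speed_from_flow_noise(rep(60, 10), depth = rep(4, 10))
  expect_true(all(is.na(sp2)))
  # clamped outside the calibrated range, flagged
  sp3 <- speed_from_flow_noise(c(10, 1e3), depth = c(100, 100))
  expect_equal(attr(sp3, "n_clamped"), 2L)

  # recovery on a synthetic record: errors follow the flow-noise jitter
  out <- make_tag_record(sim_config(seed = 6, duration_h = 2,
                                    exposure_start_h = 1))
  f <- tag_features(out$record)
  ok <- !is.na(f$speed)
  rmse <- sqrt(mean((f$speed[ok] - out$truth$speed[ok])^2))
  expect_lt(rmse, 0.2)   # 1.5 dB noise / (15 dB per m/s) = 0.1 m/s
})

test_that("depth inflections count sign changes of the first difference", {
  fs <- 5
  expect_true(all(depth_inflections(seq(0, 100, by = 0.5), fs)
                  %in% c(0, NA)))
  saw <- rep(c(0, 1), 200)
  di <- depth_inflections(saw, fs, window = 10)
  expect_equal(max(di, na.rm = TRUE), 1)

  # noisy dive profile: direct enumeration oracle in a 30 s window
  set.seed(3)
  prof <- cumsum(rnorm(900)) + 5 * sin((1:900) / 40)
  di2 <- depth_inflections(prof, fs, window = 30)
  k <- 30 * fs; k2 <- k - 2L
  ch <- as.numeric(diff(sign(diff(prof))) != 0)
  lead2 <- ceiling((k2 - 1) / 2)
  for (start in c(1L, 57L, 301L, length(ch) - k2 + 1L)) {
    expect_equal(di2[start + lead2 + 1L],
                 mean(ch[start:(start + k2 - 1L)]), tolerance = 1e-12)
  }
})

test_that("circular variance matches closed forms", {
  fs <- 1
  expect_equal(max(circular_variance(rep(0.7, 100), fs, window = 10),
                   na.rm = TRUE), 0)
  quad <- rep(c(0, pi / 2, pi, 3 * pi / 2), 25)
  cv <- circular_variance(quad, fs, window = 4)
  expect_equal(max(cv, na.rm = TRUE), 1, tolerance = 1e-12)
  two <- rep(c(0, pi / 2), 50)
  cv2 <- circular_variance(two, fs, window = 2)
  expect_equal(stats::median(cv2, na.rm = TRUE), 1 - sqrt(2) / 2,
               tolerance = 1e-12)
})

test_that("ODBA matches the analytic mean of |sin| and masks the surface", {
  fs <- 25; n <- 2000
  depth <- rep(100, n)
  still <- matrix(rep(c(0, 0, -1), each = n), ncol = 3)
  expect_equal(max(odba(still, depth, fs, window = 4), na.rm = TRUE), 0)

  a <- 0.37
  dyn <- a * sin(2 * pi * 0.5 * (0:(n - 1)) / fs)  # 2 s period
  acc <- still; acc[, 1] <- acc[, 1] + dyn
  ob <- odba(acc, depth, fs, window = 4)           # 2 full periods
  expect_equal(stats::median(ob, na.rm = TRUE), 2 * a / pi,
               tolerance = 5e-3)

  depth2 <- depth; depth2[500:600] <- 3
  ob2 <- odba(acc, depth2, fs, window = 4)
  expect_true(all(is.na(ob2[500:600])))
})

test_that("pitching movement is zero for constant pitch and scales with amplitude", {
  fs <- 5; n <- 3000
  depth <- rep(50, n)
  expect_equal(max(pitching_movement(rep(0.3, n), depth, fs),
                   na.rm = TRUE), 0, tolerance = 1e-9)
  tt <- (0:(n - 1)) / fs
  p1 <- 0.05 * sin(2 * pi * 0.35 * tt)
  p2 <- 0.10 * sin(2 * pi * 0.35 * tt)
  m1 <- stats::median(pitching_movement(p1, depth, fs), na.rm = TRUE)
  m2 <- stats::median(pitching_movement(p2, depth, fs), na.rm = TRUE)
  expect_gt(m1, 0)
  expect_equal(m2 / m1, 2, tolerance = 1e-6)
  expect_true(all(is.na(pitching_movement(p1, rep(3, n), fs))))
})

test_that("received SPL reports the 200 ms maximum and whole-pulse RMS", {
  fs <- 4000
  tt <- seq(0, 1 - 1 / fs, by = 1 / fs)
  amp <- 2e6  # uPa
  x <- amp * sin(2 * pi * 400 * tt)
  out <- received_spl(x, fs, pulse_times = 0, pulse_duration = 1)
  expect_equal(out$spl_pulse, 20 * log10(amp / sqrt(2)),
               tolerance = 1e-3)
  expect_equal(out$correction, 0, tolerance = 1e-3)

  # a 200 ms segment 6 dB above the rest; numeric oracle by brute force
  env <- ifelse(tt >= 0.4 & tt < 0.6, 1, 0.5)
  x2 <- amp * env * sin(2 * pi * 400 * tt)
  out2 <- received_spl(x2, fs, 0, 1)
  kw <- round(0.2 * fs)
  ms <- vapply(seq_len(length(x2) - kw + 1L),
               function(s) mean(x2[s:(s + kw - 1L)]^2), 0)
  expect_equal(out2$spl_200ms, 10 * log10(max(ms)), tolerance = 1e-9)
  expect_equal(out2$spl_pulse, 10 * log10(mean(x2^2)), tolerance = 1e-9)
  expect_gt(out2$correction, 0)

  # silence and out-of-record pulses are missing
  out3 <- received_spl(rep(0, fs), fs, c(0, 5), c(0.5, 0.5))
  expect_true(all(is.na(out3$spl_200ms)))
})

test_that("masks propagate into the surface-restricted features", {
  out <- make_tag_record(sim_config(seed = 10, duration_h = 2,
                                    exposure_start_h = 1))
  f <- tag_features(out$record)
  interior <- which(!is.na(f$odba) | !is.na(f$speed))
  shallow <- out$record$data$depth <= 5
  expect_true(all(is.na(f$speed[shallow])))
  expect_true(all(is.na(f$odba[shallow])))
  expect_true(all(is.na(f$pitching_movement[shallow])))
})
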