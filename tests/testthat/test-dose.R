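# Received-level modelling and Monte-Carlo dose estimation.

test_that("spherical spreading with absorption follows the closed form", {
  expect_equal(propagate_spl(214, 1, alpha_db_km = 0), 214)
  expect_equal(propagate_spl(214, 10e3, alpha_db_km = 0), 134)
  expect_equal(propagate_spl(214, 10e3, alpha_db_km = 0.2), 132)
  # clamped below the 1 m reference
  expect_equal(propagate_spl(200, 0.1, alpha_db_km = 0), 200)
  # strictly decreasing in range and in absorption
  r <- seq(100, 20000, by = 100)
  expect_true(all(diff(propagate_spl(214, r, alpha_db_km = 0.1)) < 0))
  expect_true(all(propagate_spl(214, r, alpha_db_km = 0.3) <
                    propagate_spl(214, r, alpha_db_km = 0.1)))
  # Thorp absorption is small at sonar frequencies
  expect_lt(absorption_db_km(1.5), 0.2)
  expect_gt(absorption_db_km(40), absorption_db_km(4))
})

test_that("depth-uncertainty fitting recovers injected residual spread", {
  set.seed(3)
  tt <- seq(0, 7200, by = 60)
  prof <- data.frame(time = tt, depth = 400 + 300 * sin(tt / 900))
  coarse <- data.frame(time = seq(0, 7200, by = 150))
  coarse$depth <- stats::approx(prof$time, prof$depth,
                                coarse$time)$y + rnorm(49, 0, 25)
  du <- fit_depth_uncertainty(prof, coarse, surface_depth_m = 50)
  expect_false(du$diving$defaulted)
  expect_lt(abs(du$diving$sd - 25) / 25, 0.2)

  # zero residuals: degenerate, flagged
  coarse2 <- coarse
  coarse2$depth <- stats::approx(prof$time, prof$depth, coarse2$time)$y
  du2 <- fit_depth_uncertainty(prof, coarse2, surface_depth_m = 50)
  expect_true(du2$diving$degenerate)

  # the surface/diving split follows the interpolated profile exactly
  prof3 <- data.frame(time = c(0, 100, 200, 300), depth = c(0, 0, 500, 500))
  coarse3 <- data.frame(time = c(25, 75, 225, 275), depth = c(1, 2, 480, 520))
  du3 <- fit_depth_uncertainty(prof3, coarse3, surface_depth_m = 15,
                               min_n = 1)
  expect_equal(du3$surface$n, 2L)
  expect_equal(du3$diving$n, 2L)
})

test_that("Monte-Carlo dose collapses to the deterministic SPL without uncertainty", {
  sched <- make_exposure("close", source_level = 214)
  # place the animal 10 km due north of the source, at the source depth
  dlat <- 10000 / (6371000 * pi / 180)
  d0 <- monte_carlo_dose(sched, source_pos = c(-7, 71),
                         animal_pos = c(-7, 71 + dlat), pos_sd_m = 0,
                         animal_depth = sched$source_depth_m,
                         n_draws = 200, seed = 4,
                         propagation = function(sl, r, ...)
                           propagate_spl(sl, r, alpha_db_km = 0))
  expect_equal(unname(d0$splmax["median"]), 134, tolerance = 1e-9)
  expect_equal(unname(d0$splmax["q95"] - d0$splmax["q05"]), 0)
  expect_equal(d0$per_pulse$spl_q05, d0$per_pulse$spl_q95)

  # widening the positional uncertainty widens the 90% interval
  w <- vapply(c(500, 2000, 6000), function(s) {
    d <- monte_carlo_dose(sched, c(-7, 71), c(-7, 71 + dlat),
                          pos_sd_m = s, n_draws = 400, seed = 4)
    unname(d$splmax["q95"] - d$splmax["q05"])
  }, 0)
  expect_true(all(diff(w) > 0))

  # reproducibility and the max property
  d1 <- monte_carlo_dose(sched, c(-7, 71), c(-7, 71 + dlat),
                         pos_sd_m = 1500, n_draws = 300, seed = 9)
  d2 <- monte_carlo_dose(sched, c(-7, 71), c(-7, 71 + dlat),
                         pos_sd_m = 1500, n_draws = 300, seed = 9)
  expect_identical(d1$splmax, d2$splmax)
  expect_gte(d1$splmax["median"], max(d1$per_pulse$spl_median) - 1e-9)
  expect_error(monte_carlo_dose(sched, c(-7, 71), c(-7, 71), 0,
                                n_draws = 10), "n_draws")
})

test_that("mooring dose reduces to the point dose as the annulus collapses", {
  sched <- make_exposure("distant")
  m0 <- mooring_dose(sched, source_pos = c(-7, 71),
                     mooring_pos = c(-7.6, 71.1),
                     detection_range_km = c(0, 0),
                     depth_sample = 17, n_draws = 200, seed = 5)
  pt <- monte_carlo_dose(sched, source_pos = c(-7, 71),
                         animal_pos = c(-7.6, 71.1), pos_sd_m = 0,
                         animal_depth = 17, n_draws = 200, seed = 5)
  expect_equal(unname(m0$splmax["median"]),
               unname(pt$splmax["median"]), tolerance = 1e-6)

  m1 <- mooring_dose(sched, c(-7, 71), c(-7.6, 71.1),
                     detection_range_km = c(1, 4),
                     depth_sample = c(10, 400), n_draws = 400, seed = 5)
  m2 <- mooring_dose(sched, c(-7, 71), c(-7.6, 71.1),
                     detection_range_km = c(1, 8),
                     depth_sample = c(10, 400), n_draws = 400, seed = 5)
  expect_gt(unname(m2$splmax["q95"] - m2$splmax["q05"]),
            unname(m1$splmax["q95"] - m1$splmax["q05"]))
  m3 <- mooring_dose(sched, c(-7, 71), c(-7.6, 71.1),
                     detection_range_km = c(1, 4),
                     depth_sample = c(10, 400), n_draws = 400, seed = 5)
  expect_identical(m1$splmax, m3$splmax)
})

test_that("the averaging-time correction is the mean paired difference", {
  expect_equal(averaging_correction(c(120, 121), c(120, 121))$correction_db, 0)
  ac <- averaging_correction(c(123, 124, NA), c(120, 120, 130))
  expect_equal(ac$correction_db, 3.5)
  expect_equal(ac$n_pairs, 2L)
  none <- averaging_correction(numeric(0), numeric(0))
  expect_true(none$flagged)
  expect_equal(none$correction_db, 0)

  # generator truth: a hot 200 ms segment yields a positive correction
  fs <- 4000; tt <- seq(0, 1 - 1 / fs, by = 1 / fs)
  env <- ifelse(tt >= 0.3 & tt < 0.5, 2, 1)
  x <- 1e6 * env * sin(2 * pi * 500 * tt)
  m <- received_spl(x, fs, 0, 1)
  ac2 <- averaging_correction(m$spl_200ms, m$spl_pulse)
  expect_gt(ac2$correction_db, 0)
})
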