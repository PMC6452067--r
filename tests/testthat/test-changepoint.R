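# Mahalanobis-distance change-point detection.

make_feature_df <- function(x, fs = 1) {
  data.frame(time = (seq_len(nrow(x)) - 1) / fs, a = x[, 1],
             b = if (ncol(x) > 1) x[, 2] else NULL)
}

test_that("window means equal the brute-force per-window mean", {
  set.seed(4)
  n <- 4000
  f <- data.frame(time = 0:(n - 1), a = rnorm(n), b = runif(n))
  f$a[sample(n, 200)] <- NA
  w <- window_means(f, span = 900, step = 60, variables = c("a", "b"))
  oa <- oracle_window_mean(f$a, 1, 900, 60)
  ob <- oracle_window_mean(f$b, 1, 900, 60)
  keep <- w$times %in% (seq_along(oa) - 1) * 60 + 449.5
  expect_equal(w$x[, "a"], oa[seq_len(nrow(w$x))], tolerance = 1e-12)
  expect_equal(w$x[, "b"], ob[seq_len(nrow(w$x))], tolerance = 1e-12)

  # constant features give identical vectors
  fc <- data.frame(time = 0:999, a = rep(2, 1000), b = rep(-1, 1000))
  wc <- window_means(fc, span = 100, step = 10,
                     variables = c("a", "b"))
  expect_true(all(wc$x[, "a"] == 2) && all(wc$x[, "b"] == -1))

  # step function: window means ramp linearly across the step
  fs <- data.frame(time = 0:999, a = rep(c(0, 1), each = 500))
  ws <- window_means(fs, span = 100, step = 1, variables = "a")
  ramp <- ws$x[ws$x[, 1] > 0 & ws$x[, 1] < 1, 1]
  expect_equal(diff(ramp), rep(1 / 100, length(ramp) - 1),
               tolerance = 1e-12)
})

test_that("windows with excessive masking are dropped", {
  f <- data.frame(time = 0:999, a = rnorm(1000))
  f$a[300:520] <- NA
  w <- window_means(f, span = 100, step = 10, variables = "a",
                    max_masked = 0.5)
  expect_gt(length(w$dropped), 0)
  expect_true(all(is.finite(w$x)))
})

test_that("baseline summary matches the textbook sample covariance", {
  x <- cbind(c(1, 2, 4, 7, 11), c(0, 1, 0, 2, 1))
  w <- structure(list(times = 1:5 * 60, x = x, variables = c("v1", "v2")),
                 class = "feature_windows")
  colnames(w$x) <- w$variables
  bs <- baseline_summary(w)
  expect_equal(bs$mean, colMeans(x), ignore_attr = TRUE)
  expect_equal(unname(bs$cov), unname(stats::cov(x)))
  expect_equal(bs$ridge, 0)

  # identical windows: zero covariance, ridge applied and flagged
  wi <- w; wi$x <- matrix(3, 6, 2,
                          dimnames = list(NULL, c("v1", "v2")))
  wi$times <- 1:6 * 60; wi$variables <- c("v1", "v2")
  bi <- baseline_summary(wi)
  expect_gt(bi$ridge, 0)

  # one dimension: plain variance
  w1 <- w; w1$x <- w$x[, 1, drop = FALSE]; w1$variables <- "v1"
  expect_equal(as.numeric(baseline_summary(w1)$cov),
               stats::var(x[, 1]))

  expect_error(baseline_summary(
    structure(list(times = 1:3, x = x[1:3, ],
                   variables = c("v1", "v2")),
              class = "feature_windows")), "baseline windows")
})

test_that("MD series matches closed forms and affine invariance", {
  bs <- structure(list(mean = c(0, 0), cov = diag(c(4, 1)),
                       variables = c("v1", "v2")),
                  class = "baseline_summary")
  w <- structure(list(times = 1:3, variables = c("v1", "v2"),
                      x = rbind(c(0, 0), c(2, 1), c(-2, -1))),
                 class = "feature_windows")
  md <- md_series(w, bs)
  expect_equal(md$md, c(0, sqrt(2), sqrt(2)))

  # 1-D: |w - mu| / sigma
  b1 <- structure(list(mean = 3, cov = matrix(4), variables = "v"),
                  class = "baseline_summary")
  w1 <- structure(list(times = 1, variables = "v",
                       x = matrix(7)), class = "feature_windows")
  expect_equal(md_series(w1, b1)$md, 2)

  # invariance under random invertible linear maps
  set.seed(8)
  X <- matrix(rnorm(300), ncol = 3)
  for (r in 1:5) {
    A <- matrix(rnorm(9), 3); while (abs(det(A)) < 0.1)
      A <- matrix(rnorm(9), 3)
    b <- rnorm(3)
    Y <- X %*% t(A) + matrix(b, nrow(X), 3, byrow = TRUE)
    mk <- function(M) {
      w <- structure(list(times = seq_len(nrow(M)),
                          variables = paste0("v", 1:3), x = M),
                     class = "feature_windows")
      colnames(w$x) <- w$variables
      md_series(w, baseline_summary(w))$md
    }
    expect_equal(mk(X), mk(Y), tolerance = 1e-8)
  }
  expect_error(md_series(w1, bs), "variable sets")
})

test_that("resampling threshold matches the half-normal quantile for horizon 1", {
  # 1-D i.i.d. standard-normal windows, long baseline: the 95% quantile
  # of |z| is 1.96
  w <- simulate_null_windows(n_baseline = 2000, horizon = 1, d = 1,
                             overlap = 1, seed = 2)
  bl <- baseline_summary(restrict_windows(w, 2000 * 60))
  thr <- resample_threshold(bl, horizon = 1, n = 60000, seed = 3,
                            overlap = 1)
  expect_equal(thr$threshold, stats::qnorm(0.975), tolerance = 0.025)

  # fixed seed reproduces the threshold exactly
  thr2 <- resample_threshold(bl, horizon = 1, n = 5000, seed = 9,
                             overlap = 1)
  thr3 <- resample_threshold(bl, horizon = 1, n = 5000, seed = 9,
                             overlap = 1)
  expect_identical(thr2$threshold, thr3$threshold)
})

test_that("q = 1 block resampling over the full baseline gives the baseline max", {
  w <- simulate_null_windows(n_baseline = 120, horizon = 120, d = 3,
                             seed = 5)
  wb <- restrict_windows(w, 120 * 60)
  bl <- baseline_summary(wb)
  thr <- resample_threshold(bl, horizon = 120, windows = wb, n = 2000,
                            q = 1, seed = 1, mode = "block")
  mdb <- md_series(wb, bl)
  expect_equal(thr$threshold, max(mdb$md), tolerance = 1e-12)
})

test_that("change-point detection returns the earliest threshold crossing", {
  md <- structure(list(times = 1:100 * 60,
                       md = rep(1, 100)), class = "md_series")
  expect_true(is.na(detect_changepoint(md, 3, baseline_end = 40 * 60)
                    $changepoint_time))
  md$md[c(70, 80)] <- 5
  cp <- detect_changepoint(md, 3, baseline_end = 40 * 60)
  expect_equal(cp$changepoint_time, 70 * 60)
  # exceedances inside the baseline are not scanned
  md$md[10] <- 99
  expect_equal(detect_changepoint(md, 3, 40 * 60)$changepoint_time,
               70 * 60)
})

test_that("null calibration of the detector is close to 1 - q", {
  cal <- changepoint_null_calibration(n_records = 200, reps = 3000,
                                      seed = 11)
  expect_gt(cal$false_alarm_rate, 0.01)
  expect_lt(cal$false_alarm_rate, 0.10)
})

test_that("an avoidance response is detected at the exposure onset", {
  cfg <- sim_config(seed = 21, duration_h = 6, treatment = "distant",
                    exposure_start_h = 4)
  out <- make_tag_record(cfg)
  f <- tag_features(out$record)
  w <- window_means(f)
  bl <- baseline_summary(w, baseline_end = 4 * 3600)
  thr <- resample_threshold(bl, horizon = sum(w$times > 4 * 3600),
                            n = 3000, seed = 2)
  cp <- detect_changepoint(md_series(w, bl), thr,
                           baseline_end = 4 * 3600)
  expect_false(is.na(cp$changepoint_time))
  # detected within the windowing resolution of the true onset
  expect_lt(abs(cp$changepoint_time - out$truth$response_onset_time),
            15 * 60)
})
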