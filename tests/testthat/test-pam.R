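# Guard-band click detector and click-absence statistic.

small_scene <- function(seed = 4, n_segments = 6, segment_s = 10,
                        present = NULL, snr = 25, ...) {
  cfg <- sim_config(seed = seed, pam = utils::modifyList(pam_defaults(),
    list(segment_s = segment_s, n_segments = n_segments,
         click_snr_db = snr)))
  make_pam_scene(cfg, present = present, ...)
}

test_that("PSD frames satisfy Parseval and degenerate inputs behave", {
  fs <- 144000; n <- 8192 * 4
  k <- 1000
  x <- sin(2 * pi * (k * fs / 8192) * (0:(n - 1)) / fs)
  ps <- psd_spectrogram(x, fs)
  # total power from the one-sided PSD equals the mean square (0.5)
  expect_equal(sum(ps$psd[, 2]) * fs / 8192, mean(x^2),
               tolerance = 1e-6)
  # the peak sits at the driven bin
  expect_equal(which.max(ps$psd[, 2]), k + 1L)

  set.seed(1)
  wn <- rnorm(fs)   # 1 s of white noise
  pw <- psd_spectrogram(wn, fs)
  m <- rowMeans(pw$psd)
  expect_lt(stats::sd(m[-c(1, length(m))]) / mean(m), 0.2)

  expect_true(all(psd_spectrogram(rep(0, 9000), fs)$psd == 0))
  expect_error(psd_spectrogram(rep(0, 100), fs), "shorter")
})

test_that("noise-floor normalization is robust and matches brute force", {
  set.seed(2)
  x <- rnorm(144000)
  ps <- psd_spectrogram(x, 144000)
  nps <- normalize_psd(ps)
  sel <- nps$freq >= 5e3 & nps$freq <= 50e3
  expect_lt(abs(stats::median(nps$db[sel, ])), 1)   # ~0 dB re floor

  # brute-force floor recomputation
  lv <- colMeans(ps$psd[sel, ])
  k <- max(1L, floor(0.05 * ncol(ps$psd)))
  use <- order(lv)[seq_len(k)]
  floor_lin <- rowMeans(ps$psd[, use, drop = FALSE])
  expect_equal(nps$floor_db, 10 * log10(floor_lin), tolerance = 1e-10)

  # rare loud transients do not contaminate the floor
  xt <- x; xt[30000:31000] <- xt[30000:31000] * 50
  pst <- psd_spectrogram(xt, 144000)
  npst <- normalize_psd(pst)
  expect_equal(npst$floor_db, nps$floor_db, tolerance = 0.5)
})

test_that("clicks raise the echolocation band but broadband noise cancels", {
  sc <- small_scene(seed = 5, n_segments = 6,
                    present = c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE),
                    emit = "psd")
  nps <- normalize_psd(sc$psd)
  segs <- segment_level_difference(nps, segment_s = 10)
  expect_gt(min(segs$level_diff[sc$truth$present]), 4)
  expect_lt(max(abs(segs$level_diff[!sc$truth$present])), 2)

  # broadband transients excite both bands: the difference stays small
  sb <- small_scene(seed = 6, n_segments = 4,
                    present = rep(FALSE, 4),
                    broadband_segments = c(2, 4), emit = "psd")
  nb <- normalize_psd(sb$psd)
  segb <- segment_level_difference(nb, segment_s = 10)
  expect_lt(max(abs(segb$level_diff)), 3)
})

test_that("detection thresholds behave monotonically", {
  segs <- data.frame(level_diff = c(6, 2, 9, -1))
  expect_equal(detect_clicks(segs, 5)$detected,
               c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(detect_clicks(segs, 8)$detected,
               c(FALSE, FALSE, TRUE, FALSE))
  # raising the threshold never adds detections
  for (d in seq(0, 12, by = 1.5)) {
    lo <- detect_clicks(segs$level_diff, d)
    hi <- detect_clicks(segs$level_diff, d + 1)
    expect_true(all(lo | !hi))
  }
})

test_that("ROC counts match brute-force confusion matrices", {
  set.seed(9)
  truth <- rep(c(TRUE, FALSE), each = 40)
  score <- ifelse(truth, rnorm(80, 5, 2), rnorm(80, 1, 2))
  roc <- roc_tune(score, truth, thresholds = c(0, 2, 4, 6, 8))
  for (i in seq_len(nrow(roc))) {
    det <- score >= roc$threshold[i]
    expect_equal(roc$tp[i], sum(det & truth))
    expect_equal(roc$fp[i], sum(det & !truth))
    expect_equal(roc$precision[i],
                 sum(det & truth) / max(sum(det), 1e-12),
                 tolerance = 1e-12)
  }
  expect_true(!is.unsorted(-roc$recall))   # recall non-increasing
  roc2 <- roc_tune(rnorm(10, -5), rep(FALSE, 10))
  expect_true(attr(roc2, "flagged"))
})

test_that("click-absent periods are the run-length decomposition", {
  det <- rep(FALSE, 6); det[c(1, 5)] <- TRUE
  cap <- click_absent_periods(det, segment_min = 2.5)
  expect_equal(cap$periods$duration_min, c(7.5, 2.5))
  expect_equal(cap$periods$start_segment, c(2L, 6L))
  # runs of <= 10 min are excluded from the baseline
  expect_equal(cap$baseline_durations_min, numeric(0))

  expect_equal(nrow(click_absent_periods(rep(TRUE, 8))$periods), 0L)

  set.seed(12)
  rnd <- runif(400) < 0.4
  cap2 <- click_absent_periods(rnd)
  r <- rle(!rnd)
  expect_equal(cap2$periods$duration_min, r$lengths[r$values] * 2.5)
  # the run decomposition partitions the segment axis
  expect_equal(sum(r$lengths), 400L)
})

test_that("the absence outlier test uses the stated empirical quantile", {
  base <- rep(c(30, 60, 120, 240), 10)   # minutes
  q95 <- stats::quantile(base, 0.95, type = 7, names = FALSE)
  below <- absence_outlier_test(234, base)
  above <- absence_outlier_test(241, base)
  expect_equal(below$response, 234 > q95)
  expect_true(above$response)
  expect_false(absence_outlier_test(50, base)$response)
  top <- absence_outlier_test(10 * 60, base)
  expect_true(top$response)
  expect_equal(top$percentile, 1)
  expect_true(absence_outlier_test(100, base[1:8])$low_power)
  expect_error(absence_outlier_test(100, numeric(0)), "empty")
})

test_that("level differences are invariant to a constant gain", {
  sc <- small_scene(seed = 13, n_segments = 3,
                    present = c(TRUE, FALSE, TRUE), emit = "audio")
  f <- function(x) {
    ps <- psd_spectrogram(x, sc$fs)
    segment_level_difference(normalize_psd(ps), segment_s = 10)$level_diff
  }
  expect_equal(f(sc$audio), f(3.7 * sc$audio), tolerance = 1e-9)
})

test_that("the last exposure-period absent run is identified", {
  det <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE)
  cap <- click_absent_periods(det)
  hit <- last_absent_period_in(cap, window_min = c(7.5, 12.5))
  expect_equal(hit$start_segment, 5L)
  expect_equal(hit$duration_min, 10)
  expect_null(last_absent_period_in(cap, window_min = c(0, 1)))
})
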