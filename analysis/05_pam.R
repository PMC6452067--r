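#!/usr/bin/env Rscript
# Passive-acoustic analysis: guard-band click detection on a synthetic
# scene, ROC tuning against truth, click-absent periods and the
# exposure-period absence outlier test.  Writes results/pam/.

suppressPackageStartupMessages(library(sonarcee))
out <- "results/pam"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 31, pam = utils::modifyList(pam_defaults(),
  list(segment_s = 15, n_segments = 24, click_snr_db = 24)))
present <- rep(c(TRUE, TRUE, TRUE, FALSE), 6)
scene <- make_pam_scene(cfg, present = present, emit = "psd")
nps <- normalize_psd(scene$psd)
segs <- segment_level_difference(nps, segment_s = 15)
utils::write.csv(segs, file.path(out, "segments.csv"), row.names = FALSE)

roc <- roc_tune(segs$level_diff, present,
                thresholds = seq(0, 12, by = 0.5))
utils::write.csv(roc, file.path(out, "roc.csv"), row.names = FALSE)
cat("working points:\n")
print(roc[roc$threshold %in% c(5, 8), ])

# click-absence statistic on a long detection series with a planted
# exposure-period silence
set.seed(32)
baseline_det <- runif(600) < 0.5
exposure_det <- c(rep(TRUE, 4), rep(FALSE, 40))  # 100 min silence
det <- c(baseline_det, exposure_det)
cap <- click_absent_periods(det)
exp_start_min <- length(baseline_det) * 2.5
last <- last_absent_period_in(cap, c(exp_start_min, exp_start_min + 20))
test <- absence_outlier_test(last$duration_min,
                             cap$baseline_durations_min[
                               cap$periods$start_min[cap$periods$baseline] <
                                 exp_start_min])
cat(sprintf(
  "last exposure-period click-absent run: %.1f min; baseline 95th pct %.1f min; response: %s\n",
  last$duration_min, test$threshold_min, test$response))
writeLines(jsonlite::toJSON(list(
  recall_5db = roc$recall[roc$threshold == 5],
  recall_8db = roc$recall[roc$threshold == 8],
  precision_5db = roc$precision[roc$threshold == 5],
  absence_duration_min = last$duration_min,
  absence_response = test$response,
  absence_percentile = test$percentile),
  auto_unbox = TRUE, digits = NA, pretty = TRUE),
  file.path(out, "summary.json"))
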