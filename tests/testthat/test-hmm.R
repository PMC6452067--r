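# Movement hidden Markov model.

test_that("forward likelihood equals the exhaustive path sum", {
  p2 <- toy_hmm_params(2)
  delta <- sonarcee:::stationary_dist(
    sonarcee:::tpm_from_eta(p2$eta, x = 0, N = 2))
  step <- c(0.4, 2.5, NA, 1.1)
  turn <- c(NA, 0.4, -2.9, 0.1)
  covar <- rep(0, 4)
  nll <- sonarcee:::.hmm_forward_nll(step, turn, covar, 1L,
                                     p2$step_mean, p2$step_sd,
                                     p2$turn_mean, p2$turn_kappa,
                                     p2$eta, numeric(0), delta)
  expect_equal(-nll, enum_loglik(step, turn, covar, p2, delta),
               tolerance = 1e-10)

  # 3 states with a covariate on the transitions out of state 1,
  # two tracks pooled
  p3 <- toy_hmm_params(3)
  delta3 <- sonarcee:::stationary_dist(
    sonarcee:::tpm_from_eta(p3$eta, x = 0, N = 3))
  set.seed(6)
  step3 <- c(rgamma(5, 2, 1), rgamma(3, 2, 1))
  turn3 <- c(NA, runif(4, -pi, pi), NA, runif(2, -pi, pi))
  covar3 <- c(0, 0, 3, 2, 1, 0, 8, 7)
  nll3 <- sonarcee:::.hmm_forward_nll(step3, turn3, covar3, c(1L, 6L),
                                      p3$step_mean, p3$step_sd,
                                      p3$turn_mean, p3$turn_kappa,
                                      p3$eta, p3$coef, delta3)
  direct <- enum_loglik(step3[1:5], turn3[1:5], covar3[1:5], p3,
                        delta3) +
    enum_loglik(step3[6:8], turn3[6:8], covar3[6:8], p3, delta3)
  expect_equal(-nll3, direct, tolerance = 1e-10)
})

test_that("Viterbi equals exhaustive argmax with ties toward lower states", {
  p3 <- toy_hmm_params(3)
  delta3 <- sonarcee:::stationary_dist(
    sonarcee:::tpm_from_eta(p3$eta, x = 0, N = 3))
  set.seed(7)
  for (r in 1:5) {
    step <- rgamma(3, 2, 0.8); turn <- c(NA, runif(2, -pi, pi))
    covar <- c(0, runif(2, 0, 8))
    path <- sonarcee:::.hmm_viterbi_path(step, turn, covar, 1L,
                                         p3$step_mean, p3$step_sd,
                                         p3$turn_mean, p3$turn_kappa,
                                         p3$eta, p3$coef, delta3)
    expect_equal(as.integer(path),
                 enum_viterbi(step, turn, covar, p3, delta3))
  }
  # identical state distributions: ties resolve to state 1 throughout
  pid <- list(step_mean = c(1, 1), step_sd = c(0.5, 0.5),
              turn_mean = c(0, 0), turn_kappa = c(1, 1),
              eta = c(0, 0), coef = numeric(0))
  path <- sonarcee:::.hmm_viterbi_path(c(1, 2, 0.5), c(NA, 0.1, -0.2),
                                       rep(0, 3), 1L, pid$step_mean,
                                       pid$step_sd, pid$turn_mean,
                                       pid$turn_kappa, pid$eta,
                                       numeric(0), c(0.5, 0.5))
  expect_true(all(path == 1L))
})

test_that("steps and turns follow great-circle geometry", {
  tr <- data.frame(time = 0:3, lon = c(0, 0, 0, 0),
                   lat = c(70, 70.01, 70.02, 70.03))
  st <- steps_turns(tr)
  expect_equal(st$step, rep(1.112, 3), tolerance = 1e-3)
  expect_equal(st$turn[-1], rep(0, 2), tolerance = 1e-6)

  # 90-degree left turn: east then north -> +pi/2
  tr2 <- data.frame(time = 0:2, lon = c(0, 0.03, 0.03),
                    lat = c(0, 0, 0.03))
  st2 <- steps_turns(tr2)
  expect_equal(st2$turn[2], pi / 2, tolerance = 1e-3)

  # missing fixes make adjacent intervals missing
  tr3 <- data.frame(time = 0:4, lon = c(0, NA, 0.02, 0.03, 0.04),
                    lat = rep(0, 5))
  st3 <- steps_turns(tr3)
  expect_true(is.na(st3$step[1]) && is.na(st3$step[2]))
  expect_false(is.na(st3$step[3]))
})

test_that("the speed filter removes teleporting fixes and keeps slow tracks", {
  base <- data.frame(time = 0:9, lon = seq(0, 0.09, by = 0.01),
                     lat = rep(60, 10))
  expect_equal(nrow(speed_filter(base)), 10L)
  tp <- base; tp$lon[5] <- 1.5   # ~80 km jump in 1 h
  flt <- speed_filter(tp)
  expect_equal(attr(flt, "removed"), 5L)
  expect_equal(nrow(flt), 9L)
  expect_error(speed_filter(base[1, ]), "at least 2")
})

test_that("time-to-recovery decays linearly from 8 h at exposure", {
  expect_equal(time_to_recovery(10, 10), 8)
  expect_equal(time_to_recovery(14, 10), 4)
  expect_equal(time_to_recovery(c(0, 9.9), 10), c(0, 0))
  expect_equal(time_to_recovery(19, 10), 0)
})

test_that("transition matrices stay row-stochastic at any covariate value", {
  p3 <- toy_hmm_params(3)
  for (x in c(-3, 0, 1.7, 8)) {
    G <- sonarcee:::tpm_from_eta(p3$eta, p3$coef, x, 3)
    expect_equal(rowSums(G), rep(1, 3), tolerance = 1e-12)
    expect_true(all(G > 0))
  }
})

test_that("likelihood is invariant under permutation of states 2 and 3", {
  sim <- simulate_hmm_tracks(2, 60, seed = 14)
  step <- unlist(lapply(sim$tracks, `[[`, "step"))
  turn <- unlist(lapply(sim$tracks, `[[`, "turn"))
  covar <- rep(0, length(step))
  p <- toy_hmm_params(3); p$coef <- numeric(0)
  nll_of <- function(p) {
    delta <- sonarcee:::stationary_dist(
      sonarcee:::tpm_from_eta(p$eta, x = 0, N = 3))
    sonarcee:::.hmm_forward_nll(step, turn, covar, c(1L, 61L),
                                p$step_mean, p$step_sd, p$turn_mean,
                                p$turn_kappa, p$eta, numeric(0), delta)
  }
  q <- p
  sw <- c(1, 3, 2)
  q$step_mean <- p$step_mean[sw]; q$step_sd <- p$step_sd[sw]
  q$turn_mean <- p$turn_mean[sw]; q$turn_kappa <- p$turn_kappa[sw]
  q$eta <- p$eta[c(2, 1, 5, 6, 3, 4)]
  expect_equal(nll_of(p), nll_of(q), tolerance = 1e-10)
})

test_that("fitting a simulated 3-state model recovers its structure", {
  sim <- simulate_hmm_tracks(6, 150, seed = 19)
  fit <- fit_hmm(sim$tracks, "none", n_starts = 3)
  tru <- hmm_truth_defaults()
  expect_true(fit$state1_smallest)
  expect_true(!is.unsorted(fit$params$step_mean[2:3]))
  expect_equal(fit$params$step_mean, tru$step_mean, tolerance = 0.25)
  dec <- viterbi(fit)
  expect_equal(lengths(dec), vapply(sim$tracks, nrow, 0L),
               ignore_attr = TRUE)
  acc <- mean(unlist(dec) == unlist(sim$states))
  expect_gt(acc, 0.8)
})

test_that("model selection picks the simplest model within dAIC 2", {
  fits <- list(a = list(AIC = 100.0, n_par = 10),
               b = list(AIC = 101.5, n_par = 12),
               c = list(AIC = 108, n_par = 14))
  expect_equal(select_hmm(fits)$best, "a")
  fits2 <- list(a = list(AIC = 100, n_par = 14),
                b = list(AIC = 101.5, n_par = 10),
                c = list(AIC = 110, n_par = 8))
  expect_equal(select_hmm(fits2)$best, "b")   # fewest pars within 2
  fits3 <- list(a = list(AIC = 100, n_par = 10),
                b = list(AIC = 105, n_par = 8))
  expect_equal(select_hmm(fits3)$best, "a")   # unique minimum
})

test_that("leave-out sensitivity reports the no-omission fit as the reference", {
  sim <- simulate_hmm_tracks(3, 60, seed = 23)
  res <- leave_out_sensitivity(sim$tracks,
                               covariates = c("none", "recovery"),
                               max_omit = 1, n_starts = 2, maxit = 150)
  expect_equal(res$omitted[1], "")
  expect_true(res$same_as_full[1])
  expect_equal(nrow(res), 4L)   # none omitted + 3 single omissions
  expect_error(leave_out_sensitivity(sim$tracks[1:2]), "at least 3")
})
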