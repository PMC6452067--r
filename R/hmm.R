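# Hidden Markov models of hourly horizontal movement.
#
# Hourly step lengths (gamma) and turn angles (von Mises) are modelled
# with a 3-state HMM: tortuous movement (state 1, shortest steps),
# lower-speed directional movement (state 2) and high-speed directional
# movement (state 3).  All tracks share one set of parameters.  Exposure
# enters through the transitions out of state 1 only, via a
# multinomial-logit term in a time-to-recovery covariate, optionally
# interacted with received SPLmax or source distance.  The likelihood is
# maximised directly (forward algorithm, compiled core) from several
# deterministic starts, and states are decoded with the Viterbi
# algorithm.

#' Default 3-state movement-process truth
#'
#' Used by the synthetic track generators.  Steps in km per hour; turn
#' concentrations dimensionless; transition logits are the off-diagonal
#' multinomial-logit intercepts in row-major order
#' (1->2, 1->3, 2->1, 2->3, 3->1, 3->2), reference = staying.
#' @return Named list.
#' @export
hmm_truth_defaults <- function() {
  list(step_mean = c(0.5, 2, 5), step_sd = c(0.4, 1, 1.5),
       turn_mean = c(0, 0, 0), turn_kappa = c(0.3, 2, 8),
       eta = c(-2.2, -3, -1.5, -2.5, -1.5, -2),
       coef = c(0, 0),
       argos_sd_m = 1000, missing_frac = 0.1, outlier_count = 0,
       n_hours = 96, exposure_hour = 48, start_lonlat = c(-7.3, 71))
}

# von Mises sampler (Best & Fisher rejection algorithm).
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n); filled <- 0L
  while (filled < n) {
    m <- n - filled
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    th <- sign(u3 - 0.5) * acos(pmax(-1, pmin(1, f)))
    nt <- sum(ok)
    if (nt) out[(filled + 1):(filled + nt)] <- th[ok]
    filled <- filled + nt
  }
  wrap_angle(out + mu)
}

tpm_from_eta <- function(eta, coef = c(0, 0), x = 0, N = 3) {
  G <- matrix(0, N, N)
  pos <- 1L
  for (i in seq_len(N)) {
    lin <- numeric(N)
    k <- 1L
    for (j in seq_len(N)) {
      if (j == i) next
      lin[j] <- eta[pos + (k - 1L)]
      if (i == 1L && length(coef)) lin[j] <- lin[j] + coef[k] * x
      k <- k + 1L
    }
    e <- exp(lin); e[i] <- 1
    G[i, ] <- e / sum(e)
    pos <- pos + (N - 1L)
  }
  G
}

stationary_dist <- function(G) {
  N <- nrow(G)
  as.numeric(solve(t(diag(N) - G + 1), rep(1, N)))
}

#' Simulate step/turn series from the 3-state process
#'
#' Direct simulation of pooled hourly step-length / turn-angle tracks
#' with an optional exposure at a given step, driving the transitions out
#' of state 1 through the time-to-recovery covariate (optionally scaled
#' by a per-track SPLmax or distance interaction).
#'
#' @param n_tracks,n_steps Number of tracks and steps per track.
#' @param truth Process truth, see [hmm_truth_defaults()]; `truth$coef`
#'   are the covariate coefficients on 1->2 and 1->3.
#' @param exposure_step Step index of the sonar exposure (`NULL` = no
#'   exposure; covariate identically 0).
#' @param covariate `"recovery"`, `"recovery_spl"` or `"recovery_dist"`:
#'   which covariate the generating coefficients multiply.
#' @param splmax,distance_km Per-track exposure summaries (recycled).
#' @param seed Integer seed.
#' @return List with `tracks` (list of data frames: `step` km, `turn`
#'   rad, `ttr` h, `splmax`, `distance_km`) and `states` (list of true
#'   state vectors).
#' @export
simulate_hmm_tracks <- function(n_tracks = 9, n_steps = 400,
                                truth = hmm_truth_defaults(),
                                exposure_step = NULL,
                                covariate = "recovery",
                                splmax = c(120, 125, 130, 135, 140,
                                           145, 150, 155, 160),
                                distance_km = c(28, 10, 20, 5, 26,
                                                8, 15, 3, 2),
                                seed = 1) {
  splmax <- rep_len(splmax, n_tracks)
  distance_km <- rep_len(distance_km, n_tracks)
  zspl <- as.numeric(scale(splmax))
  zdist <- as.numeric(scale(distance_km))
  if (n_tracks == 1) zspl <- zdist <- 0
  with_seed(seed, {
    tracks <- vector("list", n_tracks)
    states <- vector("list", n_tracks)
    for (w in seq_len(n_tracks)) {
      tt <- seq_len(n_steps)
      ttr <- if (is.null(exposure_step)) rep(0, n_steps) else
        time_to_recovery(tt, exposure_step)
      x <- switch(covariate,
                  recovery = ttr,
                  recovery_spl = ttr * zspl[w],
                  recovery_dist = ttr * zdist[w],
                  stop("unknown covariate"))
      z <- integer(n_steps)
      G0 <- tpm_from_eta(truth$eta, x = 0)
      z[1] <- sample.int(3, 1, prob = stationary_dist(G0))
      for (t in 2:n_steps) {
        G <- tpm_from_eta(truth$eta, truth$coef, x[t])
        z[t] <- sample.int(3, 1, prob = G[z[t - 1], ])
      }
      step <- stats::rgamma(n_steps,
                            shape = (truth$step_mean[z] / truth$step_sd[z])^2,
                            scale = truth$step_sd[z]^2 / truth$step_mean[z])
      turn <- vapply(seq_len(n_steps), function(t)
        rvonmises(1, truth$turn_mean[z[t]], truth$turn_kappa[z[t]]), 0)
      turn[1] <- NA  # undefined at the track start
      tracks[[w]] <- data.frame(step = step, turn = turn, ttr = ttr,
                                splmax = splmax[w],
                                distance_km = distance_km[w])
      states[[w]] <- z
    }
    list(tracks = tracks, states = states)
  })
}

#' Generate a synthetic satellite (Argos-style) track
#'
#' Simulates hourly positions from the 3-state process on the sphere,
#' then degrades them: isotropic Gaussian position noise, a configurable
#' fraction of missing fixes, and optionally planted outlier fixes whose
#' implied speeds exceed the 8 m/s filter threshold.
#'
#' @param config A [sim_config()]; `config$hmm_truth` carries the process
#'   truth and degradation settings, `config$treatment` decides whether
#'   an exposure (at `hmm_truth$exposure_hour`) drives the transitions.
#' @return List `(track, truth)`: `track` is a data frame (`time` h,
#'   `lon`, `lat`, `quality`, `error_sd`) with NA rows for missing fixes;
#'   `truth` holds the state sequence, true positions and outlier
#'   indices.
#' @export
make_sat_track <- function(config = sim_config()) {
  tr <- config$hmm_truth
  if (any(tr$step_mean <= 0)) stop("step-length means must be positive")
  n <- tr$n_hours
  exposure_step <- if (config$treatment == "none") NULL else
    tr$exposure_hour
  sim <- simulate_hmm_tracks(1, n, truth = tr,
                             exposure_step = exposure_step,
                             covariate = "recovery",
                             seed = config$seed)
  st <- sim$tracks[[1]]
  with_seed(config$seed + 1L, {
    bearing <- cumsum(c(stats::runif(1, -pi, pi),
                        ifelse(is.na(st$turn[-1]), 0, st$turn[-1])))
    pos <- matrix(NA_real_, n, 2)
    pos[1, ] <- tr$start_lonlat
    for (t in 2:n) {
      pos[t, ] <- geosphere::destPoint(pos[t - 1, ],
                                       b = bearing[t - 1] * 180 / pi,
                                       d = st$step[t - 1] * 1000,
                                       a = 6371000, f = 0)
    }
    obs <- pos + cbind(
      stats::rnorm(n, 0, tr$argos_sd_m) /
        (111320 * cos(pos[, 2] * pi / 180)),
      stats::rnorm(n, 0, tr$argos_sd_m) / 111320)
    out_idx <- integer(0)
    if (tr$outlier_count > 0) {
      out_idx <- round(seq(n * 0.2, n * 0.8,
                           length.out = tr$outlier_count))
      # displace far enough that the implied speed to both neighbours
      # exceeds 8 m/s even across a few missing fixes (8 m/s ~ 28.8 km/h)
      obs[out_idx, 1] <- obs[out_idx, 1] +
        150000 / (111320 * cos(pos[out_idx, 2] * pi / 180))
    }
    miss <- stats::runif(n) < tr$missing_frac
    miss[pmax(1, pmin(n, c(out_idx - 1L, out_idx, out_idx + 1L)))] <- FALSE
    obs[miss, ] <- NA
    track <- data.frame(time = seq_len(n) - 1, lon = obs[, 1],
                        lat = obs[, 2],
                        quality = ifelse(miss, NA, "1"),
                        error_sd = ifelse(miss, NA, tr$argos_sd_m))
  })
  list(track = track,
       truth = list(states = sim$states[[1]], positions = pos,
                    outliers = out_idx,
                    exposure_hour = exposure_step))
}

#' Speed-filter a track
#'
#' Iteratively removes fixes whose implied great-circle speed to both
#' surviving neighbours exceeds `vmax`, the standard coarse filter for
#' Argos positions.
#'
#' @param track Data frame with `time` (hours), `lon`, `lat`.
#' @param vmax Speed threshold (m/s, default 8).
#' @return The track with offending fixes removed; removed row indices in
#'   attribute `removed`.
#' @export
speed_filter <- function(track, vmax = 8) {
  keep_na <- is.na(track$lon)
  idx <- which(!keep_na)
  if (length(idx) < 2) stop("need at least 2 fixes")
  removed <- integer(0)
  repeat {
    p <- as.matrix(track[idx, c("lon", "lat")])
    tt <- track$time[idx] * 3600
    d <- geosphere::distHaversine(p[-nrow(p), , drop = FALSE],
                                  p[-1, , drop = FALSE], r = 6371000)
    sp <- d / pmax(diff(tt), 1)
    bad_prev <- c(FALSE, sp > vmax)   # speed to previous neighbour
    bad_next <- c(sp > vmax, FALSE)   # speed to next neighbour
    interior <- bad_prev & bad_next
    ends <- (seq_along(idx) == 1 & bad_next) |
            (seq_along(idx) == length(idx) & bad_prev)
    bad <- interior | ends
    if (!any(bad)) break
    # remove the worst offender only, then recompute
    worst <- which.max(pmax(c(0, sp), c(sp, 0)) * bad)
    removed <- c(removed, idx[worst])
    idx <- idx[-worst]
    if (length(idx) < 2) stop("speed filter removed all fixes")
  }
  out <- track[setdiff(seq_len(nrow(track)), removed), , drop = FALSE]
  attr(out, "removed") <- removed
  out
}

#' Hourly steps and turns from regular positions
#'
#' Step lengths are great-circle distances (km) between consecutive
#' hourly positions; turn angles are the change in bearing between
#' successive steps, positive counterclockwise (a 90-degree left turn is
#' +pi/2), in (-pi, pi].  Intervals adjacent to missing positions are
#' missing.
#'
#' @param track Data frame with `time` (h), `lon`, `lat` (NA = missing).
#' @return Data frame with `time` (interval start), `step` (km), `turn`
#'   (rad).
#' @export
steps_turns <- function(track) {
  n <- nrow(track)
  p <- as.matrix(track[, c("lon", "lat")])
  step <- rep(NA_real_, n - 1)
  ok <- stats::complete.cases(p[-n, ]) & stats::complete.cases(p[-1, ])
  step[ok] <- geosphere::distHaversine(p[-n, , drop = FALSE][ok, ,
                                                             drop = FALSE],
                                       p[-1, , drop = FALSE][ok, ,
                                                             drop = FALSE],
                                       r = 6371000) / 1000
  brg <- rep(NA_real_, n - 1)
  brg[ok] <- geosphere::bearing(p[-n, , drop = FALSE][ok, , drop = FALSE],
                                p[-1, , drop = FALSE][ok, , drop = FALSE],
                                a = 6371000, f = 0) * pi / 180
  turn <- c(NA_real_, -wrap_angle(diff(brg)))
  turn[is.na(c(NA, brg[-length(brg)])) | is.na(brg)] <- NA
  data.frame(time = track$time[-n], step = step, turn = turn)
}

#' Time-to-recovery covariate
#'
#' Linear decay from a maximum of `max_h` hours at the exposure time-step
#' to zero `max_h` hours later; zero before exposure.
#'
#' @param times Times (hours).
#' @param exposure_time Exposure time (hours).
#' @param max_h Maximum value (default 8 h).
#' @return Covariate values.
#' @export
time_to_recovery <- function(times, exposure_time, max_h = 8) {
  dt <- times - exposure_time
  ifelse(dt >= 0, pmax(0, max_h - dt), 0)
}

# ---- fitting ----------------------------------------------------------

hmm_pack <- function(p, fix_turn_mean) {
  c(log(p$step_mean), log(p$step_sd),
    if (!fix_turn_mean) p$turn_mean, log(p$turn_kappa), p$eta, p$coef)
}

hmm_unpack <- function(theta, N, has_cov, fix_turn_mean) {
  i <- 0L
  take <- function(k) { v <- theta[i + seq_len(k)]; i <<- i + k; v }
  p <- list(step_mean = exp(take(N)), step_sd = exp(take(N)))
  p$turn_mean <- if (fix_turn_mean) rep(0, N) else
    wrap_angle(take(N))
  p$turn_kappa <- exp(take(N))
  p$eta <- take(N * (N - 1L))
  p$coef <- if (has_cov) take(N - 1L) else numeric(0)
  p
}

hmm_build_covariate <- function(tracks, covariate) {
  if (covariate == "none")
    return(list(x = lapply(tracks, function(tr) rep(0, nrow(tr))),
                scaling = NULL))
  per <- vapply(tracks, function(tr) tr$splmax[1], 0)
  perd <- vapply(tracks, function(tr) tr$distance_km[1], 0)
  if (covariate == "recovery")
    return(list(x = lapply(tracks, function(tr) tr$ttr),
                scaling = NULL))
  vals <- if (covariate == "recovery_spl") per else perd
  mu <- mean(vals); sdv <- stats::sd(vals)
  if (!is.finite(sdv) || sdv == 0) sdv <- 1
  z <- (vals - mu) / sdv
  list(x = lapply(seq_along(tracks),
                  function(w) tracks[[w]]$ttr * z[w]),
       scaling = c(mean = mu, sd = sdv))
}

#' Fit a movement HMM to pooled tracks
#'
#' Direct numerical maximisation of the joint forward log-likelihood over
#' all tracks (shared parameters) from deterministic multi-starts.
#' Missing observations contribute unit likelihood while transitions
#' advance.  After convergence, states are relabelled so that mean step
#' length increases with the state index (states 2 and 3 are
#' exchangeable; the covariate structure pins state 1, and a fit in which
#' state 1 does not have the smallest mean is flagged).
#'
#' @param tracks List of data frames with `step` (km), `turn` (rad) and,
#'   for covariate models, `ttr` plus per-track `splmax` /
#'   `distance_km`.
#' @param covariate `"none"`, `"recovery"`, `"recovery_spl"` or
#'   `"recovery_dist"`; interactions use z-scored per-track SPLmax or
#'   distance (scaling reported in the fit).
#' @param n_states Number of states (default 3).
#' @param n_starts Deterministic multi-starts (default 10).
#' @param fix_turn_mean Fix all von Mises means at 0.
#' @param hessian Compute standard errors.
#' @param maxit Optimiser iteration cap per start.
#' @return List of class `hmm_fit`: `params`, `se`, `logLik`, `AIC`,
#'   `n_par`, `delta`, `covariate`, `scaling`, `state1_smallest`,
#'   `occupancy`, `convergence` and the packed data for decoding.
#' @export
fit_hmm <- function(tracks, covariate = c("none", "recovery",
                                          "recovery_spl",
                                          "recovery_dist"),
                    n_states = 3, n_starts = 10, fix_turn_mean = FALSE,
                    hessian = FALSE, maxit = 300) {
  covariate <- match.arg(covariate)
  N <- n_states
  has_cov <- covariate != "none"
  cov_built <- hmm_build_covariate(tracks, covariate)
  step <- unlist(lapply(tracks, function(tr) tr$step))
  turn <- unlist(lapply(tracks, function(tr) tr$turn))
  covar <- unlist(cov_built$x)
  lens <- vapply(tracks, nrow, 0L)
  track_start <- cumsum(c(1L, lens[-length(lens)]))
  nll <- function(theta) {
    p <- hmm_unpack(theta, N, has_cov, fix_turn_mean)
    if (any(!is.finite(unlist(p)))) return(1e10)
    G0 <- tpm_from_eta(p$eta, x = 0, N = N)
    delta <- tryCatch(stationary_dist(G0), error = function(e) NULL)
    if (is.null(delta) || any(delta < 0)) return(1e10)
    .hmm_forward_nll(step, turn, covar, track_start, p$step_mean,
                     p$step_sd, p$turn_mean, p$turn_kappa, p$eta,
                     if (has_cov) p$coef else numeric(0), delta)
  }
  # deterministic data-driven starts
  qs <- stats::quantile(step[is.finite(step) & step > 0],
                        probs = seq(0.15, 0.9, length.out = N),
                        names = FALSE)
  mean_f <- c(1, 0.7, 1.4, 1, 0.85, 1.2, 1, 0.7, 1.4, 1)
  sd_f <- c(0.8, 0.8, 0.8, 1.2, 0.6, 1, 0.8, 1.2, 0.6, 1)
  kap_b <- c(1, 0.5, 2, 1, 4, 1, 0.5, 2, 1, 4)
  best <- NULL
  for (s in seq_len(n_starts)) {
    j <- (s - 1L) %% 10L + 1L
    p0 <- list(step_mean = qs * mean_f[j], step_sd = qs * sd_f[j],
               turn_mean = rep(0, N),
               turn_kappa = kap_b[j] * seq(0.5, 4, length.out = N),
               eta = rep(-1.5, N * (N - 1L)),
               coef = if (has_cov) rep(0, N - 1L) else numeric(0))
    th0 <- hmm_pack(p0, fix_turn_mean)
    fit <- tryCatch(stats::optim(th0, nll, method = "BFGS",
                                 control = list(maxit = maxit,
                                                reltol = 1e-9)),
                    error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("HMM optimisation failed from all starts")
  p <- hmm_unpack(best$par, N, has_cov, fix_turn_mean)
  # Relabelling.  Without covariates all states are exchangeable: apply
  # the full permutation ordering states by ascending step mean, with
  # the intercepts rebuilt from the permuted transition probabilities.
  # With covariates the structure pins state 1 (its transition row
  # carries the covariate), so only the exchangeable states 2..N are
  # reordered.
  relabel <- function(p, ord) {
    G <- tpm_from_eta(p$eta, x = 0, N = N)[ord, ord]
    p$step_mean <- p$step_mean[ord]; p$step_sd <- p$step_sd[ord]
    p$turn_mean <- p$turn_mean[ord]; p$turn_kappa <- p$turn_kappa[ord]
    p$eta <- unlist(lapply(seq_len(N), function(i)
      log(G[i, -i] / G[i, i])))
    p
  }
  ord_full <- order(p$step_mean)
  if (!has_cov && !identical(ord_full, seq_len(N))) {
    p <- relabel(p, ord_full)
    best$par <- hmm_pack(p, fix_turn_mean)
  } else if (has_cov) {
    ord23 <- c(1L, 1L + order(p$step_mean[-1]))
    if (!identical(ord23, seq_len(N))) {
      cf <- p$coef
      p <- relabel(p, ord23)
      # covariate coefficients live on row 1's off-diagonals: the
      # coefficient for new destination j is the old ord23[j]'s
      p$coef <- cf[ord23[-1] - 1L]
      best$par <- hmm_pack(p, fix_turn_mean)
    }
  }
  se <- NULL
  if (hessian) {
    H <- tryCatch(stats::optimHess(best$par, nll),
                  error = function(e) NULL)
    V <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V) && all(diag(V) > 0)) {
      sd_work <- sqrt(diag(V))
      natural <- c(p$step_mean, p$step_sd,
                   if (!fix_turn_mean) rep(1, N), p$turn_kappa,
                   rep(1, N * (N - 1L)),
                   if (has_cov) rep(1, N - 1L))
      jac <- c(p$step_mean, p$step_sd,
               if (!fix_turn_mean) rep(1, N), p$turn_kappa,
               rep(1, N * (N - 1L)), if (has_cov) rep(1, N - 1L))
      se <- sd_work * abs(jac)
    }
  }
  G0 <- tpm_from_eta(p$eta, x = 0, N = N)
  delta <- stationary_dist(G0)
  n_par <- length(best$par)
  ll <- -best$value
  packed <- list(step = step, turn = turn, covar = covar,
                 track_start = track_start, lens = lens)
  path <- .hmm_viterbi_path(step, turn, covar, track_start, p$step_mean,
                            p$step_sd, p$turn_mean, p$turn_kappa, p$eta,
                            if (has_cov) p$coef else numeric(0), delta)
  occ <- tabulate(path, N) / length(path)
  structure(list(params = p, se = se, logLik = ll,
                 AIC = 2 * n_par - 2 * ll, n_par = n_par, delta = delta,
                 covariate = covariate, scaling = cov_built$scaling,
                 state1_smallest = which.min(p$step_mean) == 1L,
                 occupancy = occ,
                 degenerate_state = any(occ <= 0.01),
                 convergence = best$convergence,
                 fix_turn_mean = fix_turn_mean, n_states = N,
                 packed = packed), class = "hmm_fit")
}

#' Viterbi decoding
#'
#' Jointly most probable state path for every track under a fitted
#' model; ties break toward the lower state index.
#'
#' @param fit An `hmm_fit`.
#' @return List of integer state vectors, one per track.
#' @export
viterbi <- function(fit) {
  p <- fit$params
  path <- .hmm_viterbi_path(fit$packed$step, fit$packed$turn,
                            fit$packed$covar, fit$packed$track_start,
                            p$step_mean, p$step_sd, p$turn_mean,
                            p$turn_kappa, p$eta, p$coef, fit$delta)
  split(path, rep(seq_along(fit$packed$lens), fit$packed$lens))
}

#' Select the best HMM by the parsimony rule
#'
#' The best model is the simplest (fewest parameters) among those within
#' `dAIC_limit` of the minimum AIC.
#'
#' @param fits Named list of `hmm_fit`s (or any objects with `AIC` and
#'   `n_par`).
#' @param dAIC_limit Default 2.
#' @return List with `best` (name), `table` (AIC table with dAIC).
#' @export
select_hmm <- function(fits, dAIC_limit = 2) {
  nm <- names(fits) %||% as.character(seq_along(fits))
  aic <- vapply(fits, function(f) f$AIC, 0)
  npar <- vapply(fits, function(f) f$n_par, 0)
  daic <- aic - min(aic)
  cand <- which(daic < dAIC_limit)
  best <- cand[order(npar[cand], aic[cand])][1]
  tab <- data.frame(model = nm, n_par = npar, AIC = aic, dAIC = daic)
  tab <- tab[order(tab$AIC), ]; rownames(tab) <- NULL
  list(best = nm[best], table = tab)
}

#' Leave-out sensitivity of HMM model selection
#'
#' Refits the candidate covariate models after omitting each combination
#' of one or two tracks and reports whether the selected model changes.
#'
#' @param tracks List of tracks as in [fit_hmm()].
#' @param covariates Candidate covariate models.
#' @param max_omit Largest omission size (default 2).
#' @param ... Passed to [fit_hmm()].
#' @return Data frame with `omitted`, `selected`, `same_as_full`.
#' @export
leave_out_sensitivity <- function(tracks,
                                  covariates = c("none", "recovery",
                                                 "recovery_spl"),
                                  max_omit = 2, ...) {
  if (length(tracks) < 3) stop("need at least 3 tracks")
  run <- function(idx) {
    fits <- lapply(covariates, function(cv)
      fit_hmm(tracks[idx], covariate = cv, ...))
    names(fits) <- covariates
    select_hmm(fits)$best
  }
  full <- run(seq_along(tracks))
  combos <- list(integer(0))
  for (k in seq_len(max_omit))
    combos <- c(combos, utils::combn(length(tracks), k, simplify = FALSE))
  res <- lapply(combos, function(om) {
    sel <- run(setdiff(seq_along(tracks), om))
    data.frame(omitted = paste(om, collapse = ","), selected = sel,
               same_as_full = sel == full)
  })
  do.call(rbind, res)
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat(sprintf("<hmm_fit> %d states, covariate '%s': logLik %.2f, AIC %.2f (%d par)\n",
              x$n_states, x$covariate, x$logLik, x$AIC, x$n_par))
  cat("  step mean (km):", round(x$params$step_mean, 3),
      "| sd:", round(x$params$step_sd, 3), "\n")
  cat("  turn kappa:", round(x$params$turn_kappa, 3),
      "| occupancy:", round(x$occupancy, 3), "\n")
  invisible(x)
}
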