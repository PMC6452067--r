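# Dose-response-intensity model.
#
# The response intensity of whale i in 35-min time-bin k is the expected
# Mahalanobis distance of that bin from the pooled average baseline
# behaviour of all whales, modelled as
#
#   RI_ik = E(MD) = beta0 + beta1 * L_i * exp(beta2 * (tau_i - t_ik)) *
#                   (1 + beta3 * R_i)      for t_ik >= tau_i
#           beta0                          otherwise,
#
# where L_i is the exposure's maximum received SPL minus a 79 dB re 1 uPa
# hearing-threshold offset, R_i the minimum source distance (km) and
# tau_i the exposure bin.  Since tau_i - t_ik <= 0 after exposure, a
# positive beta2 is a decay of the effect with time since exposure.
# Observed MDs are gamma distributed with shape omega and mean RI.  The
# full model and its reduced forms (the SPL term beta1*L replaced by a
# single parameter gamma; no decay; no distance) are compared by AIC.

#' Enumerate the dose-response model family
#'
#' All combinations of `include_level` (SPL-scaled effect `beta1*L`
#' versus a constant effect `gamma`), `include_decay` (`beta2`) and
#' `include_distance` (`beta3`) -- eight models -- plus optionally a pure
#' intercept model with no exposure effect at all.
#'
#' @param intercept_only Add the no-exposure-effect model (default TRUE).
#' @return List of `ri_spec` lists.
#' @export
ri_all_specs <- function(intercept_only = TRUE) {
  specs <- list()
  for (lev in c(TRUE, FALSE)) for (dec in c(TRUE, FALSE))
    for (dis in c(TRUE, FALSE))
      specs[[length(specs) + 1L]] <-
        ri_spec(include_effect = TRUE, include_level = lev,
                include_decay = dec, include_distance = dis)
  if (intercept_only)
    specs[[length(specs) + 1L]] <- ri_spec(include_effect = FALSE)
  specs
}

#' Dose-response model specification
#' @param include_effect Any exposure effect at all? `FALSE` gives the
#'   intercept-only model (parameters `beta0`, `omega`).
#' @param include_level Effect scales with received level (`beta1 * L`);
#'   otherwise a single constant `gamma`.
#' @param include_decay Exponential decay with time since exposure
#'   (`beta2`).
#' @param include_distance Source-distance modulation (`1 + beta3 * R`).
#' @return List of class `ri_spec` with a `label` and parameter count
#'   helper fields.
#' @export
ri_spec <- function(include_effect = TRUE, include_level = TRUE,
                    include_decay = TRUE, include_distance = TRUE) {
  if (!include_effect) include_level <- include_decay <-
      include_distance <- FALSE
  label <- if (!include_effect) "intercept-only" else
    paste0(if (include_level) "level" else "const",
           if (include_decay) "+decay" else "",
           if (include_distance) "+dist" else "")
  structure(list(include_effect = include_effect,
                 include_level = include_level,
                 include_decay = include_decay,
                 include_distance = include_distance,
                 label = label), class = "ri_spec")
}

n_par_ri <- function(spec) {
  2L + spec$include_effect + spec$include_decay + spec$include_distance
}

#' Expected response intensity
#'
#' Evaluates the piecewise mean function for given parameters.
#'
#' @param params Named list/vector: `beta0`, and as applicable `beta1` or
#'   `gamma`, `beta2`, `beta3`.
#' @param spec An `ri_spec`.
#' @param L Received SPLmax minus the 79 dB offset (dB).
#' @param R Minimum source distance (km).
#' @param tau Exposure bin index/time.
#' @param t Bin index/time (vectorised).
#' @return Expected MD for each `t`.
#' @export
ri_predict <- function(params, spec, L, R, tau, t) {
  p <- as.list(params)
  base <- rep(p$beta0, length(t))
  if (!spec$include_effect) return(base)
  eff <- if (spec$include_level) p$beta1 * L else p$gamma
  if (spec$include_decay) eff <- eff * exp(p$beta2 * (tau - t))
  if (spec$include_distance) eff <- eff * (1 + p$beta3 * R)
  ifelse(!is.na(tau) & t >= tau, base + eff, base)
}

# Mean over the data frame: rows of an ri_data set.
ri_mean_rows <- function(params, spec, data) {
  p <- as.list(params)
  mu <- rep(p$beta0, nrow(data))
  if (!spec$include_effect) return(mu)
  on <- !is.na(data$tau) & data$t >= data$tau
  eff <- if (spec$include_level) p$beta1 * data$L[on] else p$gamma
  if (spec$include_decay)
    eff <- eff * exp(p$beta2 * (data$tau[on] - data$t[on]))
  if (spec$include_distance) eff <- eff * (1 + p$beta3 * data$R[on])
  mu[on] <- mu[on] + eff
  mu
}

#' Gamma log-likelihood of a dose-response dataset
#'
#' Sum of log gamma densities with shape `omega` and mean `RI` (scale
#' `RI / omega`).  Non-positive predicted means give `-Inf`.
#'
#' @param params Named parameters including `omega`.
#' @param spec An `ri_spec`.
#' @param data An `ri_data` data frame (see [simulate_ri_data()]).
#' @return Log-likelihood.
#' @export
ri_loglik <- function(params, spec, data) {
  mu <- ri_mean_rows(params, spec, data)
  if (any(!is.finite(mu)) || any(mu <= 0)) return(-Inf)
  om <- params[["omega"]]
  if (!is.finite(om) || om <= 0) return(-Inf)
  ll <- suppressWarnings(sum(stats::dgamma(data$md, shape = om,
                                           scale = mu / om, log = TRUE)))
  if (is.nan(ll)) -Inf else ll
}

# Parameter transforms: positive parameters on log scale; beta3 free.
ri_pack <- function(params, spec) {
  out <- c(lb0 = log(params$beta0), lom = log(params$omega))
  if (spec$include_effect)
    out <- c(out, leff = log(if (spec$include_level) params$beta1
                             else params$gamma))
  if (spec$include_decay) out <- c(out, lb2 = log(params$beta2))
  if (spec$include_distance) out <- c(out, b3 = params$beta3)
  out
}

ri_unpack <- function(theta, spec) {
  p <- list(beta0 = exp(theta[["lb0"]]), omega = exp(theta[["lom"]]))
  if (spec$include_effect) {
    if (spec$include_level) p$beta1 <- exp(theta[["leff"]])
    else p$gamma <- exp(theta[["leff"]])
  }
  if (spec$include_decay) p$beta2 <- exp(theta[["lb2"]])
  if (spec$include_distance) p$beta3 <- theta[["b3"]]
  p
}

#' Fit a dose-response-intensity model by maximum likelihood
#'
#' Positive parameters (`beta0`, `omega`, `beta1`/`gamma`, `beta2`) are
#' optimised on the log scale; `beta3` is unconstrained with positivity
#' of the predicted mean enforced through the likelihood barrier.  A
#' deterministic multi-start grid guards against local optima.  Zero or
#' near-zero MD values are floored at half the smallest positive value
#' (gamma support) and the count reported.
#'
#' @param data An `ri_data` data frame with columns `whale`, `t`, `md`,
#'   `exposed`, `L`, `R`, `tau`.
#' @param spec An `ri_spec`.
#' @param n_starts Number of multi-start points (default 16).
#' @param hessian Compute standard errors from the numerical Hessian.
#' @return List of class `ri_fit` with `params`, `se` (on the natural
#'   scale, delta method), `logLik`, `AIC`, `n_par`, `convergence`,
#'   `n_floored` and the `spec`.
#' @export
fit_ri <- function(data, spec = ri_spec(), n_starts = 16,
                   hessian = TRUE) {
  stopifnot(all(c("md", "t", "tau", "L", "R") %in% names(data)))
  if (spec$include_effect && !any(!is.na(data$tau)))
    stop("no exposed whales in data but spec includes exposure terms")
  n_floored <- sum(data$md <= 0)
  if (n_floored > 0) {
    floor_val <- min(data$md[data$md > 0]) / 2
    data$md[data$md <= 0] <- floor_val
  }
  m0 <- mean(data$md); v0 <- stats::var(data$md)
  om0 <- max(0.1, m0^2 / max(v0, 1e-12))
  Lbar <- mean(data$L[!is.na(data$L)]) %||% 1
  if (!is.finite(Lbar) || Lbar <= 0) Lbar <- 1
  grid <- expand.grid(b0 = m0 * c(0.5, 1.5), om = om0 * c(0.5, 2),
                      eff = m0 * c(0.2, 2), b2 = c(0.05, 0.5))
  grid <- grid[rep(seq_len(nrow(grid)), length.out = max(n_starts, 1)), ]
  nll <- function(theta) {
    ll <- ri_loglik(ri_unpack(theta, spec), spec, data)
    if (!is.finite(ll)) 1e10 else -ll
  }
  best <- NULL
  for (s in seq_len(nrow(grid))) {
    start <- list(beta0 = grid$b0[s], omega = grid$om[s],
                  beta1 = grid$eff[s] / Lbar, gamma = grid$eff[s],
                  beta2 = grid$b2[s], beta3 = 0)
    th0 <- ri_pack(start, spec)
    fit <- tryCatch(
      stats::optim(th0, nll, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all optimisation starts failed")
  params <- ri_unpack(best$par, spec)
  se <- NULL
  if (hessian) {
    H <- tryCatch(stats::optimHess(best$par, nll), error = function(e) NULL)
    if (!is.null(H)) {
      V <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(V) && all(diag(V) > 0)) {
        sd_work <- sqrt(diag(V))
        # delta method: natural = exp(working) except beta3
        scale <- unlist(params)[ri_par_names(spec)]
        scale[names(scale) == "beta3"] <- 1
        se <- stats::setNames(sd_work * abs(scale), ri_par_names(spec))
      }
    }
  }
  ll <- -best$value
  p <- n_par_ri(spec)
  structure(list(params = params, se = se, logLik = ll,
                 AIC = 2 * p - 2 * ll, n_par = p,
                 convergence = best$convergence,
                 n_floored = n_floored, spec = spec),
            class = "ri_fit")
}

ri_par_names <- function(spec) {
  nm <- c("beta0", "omega")
  if (spec$include_effect)
    nm <- c(nm, if (spec$include_level) "beta1" else "gamma")
  if (spec$include_decay) nm <- c(nm, "beta2")
  if (spec$include_distance) nm <- c(nm, "beta3")
  nm
}

#' Fit and compare the dose-response model family by AIC
#'
#' @param data An `ri_data` data frame.
#' @param specs List of `ri_spec` (default [ri_all_specs()]).
#' @param n_starts Multi-start count per fit.
#' @return List of class `ri_comparison` with `table` (sorted data frame
#'   of model, n_par, logLik, AIC, dAIC) and `fits`.
#' @export
compare_ri <- function(data, specs = ri_all_specs(), n_starts = 8) {
  fits <- lapply(specs, function(sp)
    tryCatch(fit_ri(data, sp, n_starts = n_starts, hessian = FALSE),
             error = function(e) NULL))
  ok <- !vapply(fits, is.null, TRUE)
  tab <- data.frame(
    model = vapply(specs[ok], function(s) s$label, ""),
    includes_level = vapply(specs[ok], function(s)
      isTRUE(s$include_level), TRUE),
    n_par = vapply(fits[ok], function(f) f$n_par, 0L),
    logLik = vapply(fits[ok], function(f) f$logLik, 0),
    AIC = vapply(fits[ok], function(f) f$AIC, 0))
  tab <- tab[order(tab$AIC), ]
  tab$dAIC <- tab$AIC - tab$AIC[1]
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits[ok],
                 failed = vapply(specs[!ok], function(s) s$label, "")),
            class = "ri_comparison")
}

#' Simulate a dose-response dataset from the model
#'
#' Generates per-bin MDs for exposed and baseline whales from the gamma
#' observation model with the piecewise mean.  Defaults mirror the study
#' layout: 4 exposed whales (one per experiment, with study-scale SPLmax
#' and minimum source distances) and 10 baseline whales, ~10 bins each.
#'
#' @param truth Named list of true parameters (`beta0`, `omega`, and the
#'   effect parameters used by `spec`).
#' @param spec Generating `ri_spec`.
#' @param n_exposed,n_baseline Whale counts.
#' @param bins_per_whale Bins per whale.
#' @param splmax SPLmax per exposed whale (dB re 1 uPa).
#' @param distance_km Minimum source distance per exposed whale.
#' @param tau_bin Exposure bin index (exposed whales).
#' @param offset_db Hearing-threshold offset subtracted from SPLmax
#'   (default 79).
#' @param seed Integer seed.
#' @return An `ri_data` data frame.
#' @export
simulate_ri_data <- function(truth = list(beta0 = 1, omega = 2,
                                          beta1 = 0.05),
                             spec = ri_spec(include_level = TRUE,
                                            include_decay = FALSE,
                                            include_distance = FALSE),
                             n_exposed = 4, n_baseline = 10,
                             bins_per_whale = 10,
                             splmax = c(126, 145, 155, 160),
                             distance_km = c(28, 0.8, 5.5, 17),
                             tau_bin = 4, offset_db = 79, seed = 1) {
  splmax <- rep_len(splmax, n_exposed)
  distance_km <- rep_len(distance_km, n_exposed)
  rows <- list()
  for (i in seq_len(n_exposed)) {
    rows[[i]] <- data.frame(
      whale = sprintf("exp%02d", i), t = seq_len(bins_per_whale),
      exposed = TRUE, L = splmax[i] - offset_db, R = distance_km[i],
      tau = tau_bin)
  }
  for (i in seq_len(n_baseline)) {
    rows[[n_exposed + i]] <- data.frame(
      whale = sprintf("base%02d", i), t = seq_len(bins_per_whale),
      exposed = FALSE, L = NA_real_, R = NA_real_, tau = NA_real_)
  }
  data <- do.call(rbind, rows)
  with_seed(seed, {
    mu <- ri_mean_rows(truth, spec, data)
    data$md <- stats::rgamma(nrow(data), shape = truth$omega,
                             scale = mu / truth$omega)
  })
  class(data) <- c("ri_data", "data.frame")
  data
}

#' MD time-bins against a pooled baseline
#'
#' Collapses each whale's feature series into non-overlapping bins (35
#' min by default, aligned to the exposure start for exposed whales) and
#' computes each bin's MD from a pooled baseline summary.
#'
#' @param features_list Named list of `feature_series`, one per whale.
#' @param pooled_baseline A `baseline_summary` built from the pooled
#'   baseline bins of all whales.
#' @param bin_span Bin length (s, default 2100 = 35 min).
#' @param align Named numeric vector of exposure start times (s) per
#'   exposed whale; others start at the record start.
#' @param variables Feature columns used.
#' @return Data frame with `whale`, `t` (bin index), `bin_start`, `md`.
#' @export
md_bins <- function(features_list, pooled_baseline, bin_span = 2100,
                    align = NULL,
                    variables = md_variable_set("avoidance")) {
  out <- list()
  for (w in names(features_list)) {
    f <- features_list[[w]]
    t0 <- f$time[1]
    if (!is.null(align) && w %in% names(align)) {
      # shift the grid so a bin boundary falls exactly on exposure start
      t0 <- align[[w]] - bin_span * floor((align[[w]] - f$time[1]) /
                                            bin_span)
    }
    fsub <- f[f$time >= t0, , drop = FALSE]
    wb <- window_means(fsub, span = bin_span, step = bin_span,
                       variables = variables, max_masked = 0.5)
    md <- sqrt(stats::mahalanobis(wb$x, pooled_baseline$mean,
                                  pooled_baseline$cov))
    bin0 <- min(fsub$time)
    out[[w]] <- data.frame(whale = w, t = seq_along(md),
                           bin_start = bin0 +
                             (seq_along(md) - 1) * bin_span,
                           md = md)
  }
  do.call(rbind, out)
}

#' @export
print.ri_fit <- function(x, ...) {
  cat(sprintf("<ri_fit> %s: logLik %.2f, AIC %.2f (%d par)\n",
              x$spec$label, x$logLik, x$AIC, x$n_par))
  print(unlist(x$params))
  invisible(x)
}

#' @export
print.ri_comparison <- function(x, ...) {
  print(x$table)
  invisible(x)
}
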