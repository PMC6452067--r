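# Brute-force oracles shared across tests.  These deliberately use the
# most direct computation available (explicit loops, exhaustive
# enumeration) and stay independent of the package's vectorised /
# compiled code paths.

# Direct per-window mean over centred full-support windows.
oracle_window_mean <- function(x, fs, span_s, step_s) {
  k <- round(span_s * fs)
  stride <- round(step_s * fs)
  starts <- seq(1L, length(x) - k + 1L, by = stride)
  vapply(starts, function(s) mean(x[s:(s + k - 1L)], na.rm = TRUE), 0)
}

ld_gamma_ms <- function(x, m, s)
  stats::dgamma(x, shape = (m / s)^2, scale = s^2 / m, log = TRUE)

ld_vm <- function(x, mu, k)
  k * cos(x - mu) - log(2 * pi) - (log(besselI(k, 0, TRUE)) + k)

obs_logdens <- function(step, turn, j, p) {
  v <- 0
  if (!is.na(step)) v <- v + ld_gamma_ms(step, p$step_mean[j], p$step_sd[j])
  if (!is.na(turn)) v <- v + ld_vm(turn, p$turn_mean[j], p$turn_kappa[j])
  v
}

# Exhaustive path-sum likelihood of one short track.
enum_loglik <- function(step, turn, covar, p, delta) {
  N <- length(p$step_mean)
  Tn <- length(step)
  paths <- as.matrix(expand.grid(rep(list(seq_len(N)), Tn)))
  tot <- 0
  for (r in seq_len(nrow(paths))) {
    z <- paths[r, ]
    pr <- delta[z[1]] * exp(obs_logdens(step[1], turn[1], z[1], p))
    for (t in 2:Tn) {
      G <- sonarcee:::tpm_from_eta(p$eta, p$coef, covar[t], N)
      pr <- pr * G[z[t - 1], z[t]] *
        exp(obs_logdens(step[t], turn[t], z[t], p))
    }
    tot <- tot + pr
  }
  log(tot)
}

# Exhaustive Viterbi (argmax path), ties toward the lexicographically
# smallest state sequence.
enum_viterbi <- function(step, turn, covar, p, delta) {
  N <- length(p$step_mean)
  Tn <- length(step)
  paths <- as.matrix(expand.grid(rep(list(seq_len(N)), Tn)))
  # expand.grid orders first variable fastest: reorder rows so that
  # lexicographic order on (z1, z2, ...) ties resolve to lower states
  ord <- do.call(order, as.data.frame(paths))
  paths <- paths[ord, , drop = FALSE]
  best <- -Inf; arg <- NULL
  for (r in seq_len(nrow(paths))) {
    z <- paths[r, ]
    lp <- log(delta[z[1]]) + obs_logdens(step[1], turn[1], z[1], p)
    for (t in 2:Tn) {
      G <- sonarcee:::tpm_from_eta(p$eta, p$coef, covar[t], N)
      lp <- lp + log(G[z[t - 1], z[t]]) +
        obs_logdens(step[t], turn[t], z[t], p)
    }
    if (lp > best + 1e-12) { best <- lp; arg <- z }
  }
  unname(arg)
}

# Small two-state parameter set used by the enumeration tests.
toy_hmm_params <- function(N = 2) {
  if (N == 2)
    list(step_mean = c(0.6, 3), step_sd = c(0.5, 1.2),
         turn_mean = c(0.3, 0), turn_kappa = c(0.4, 5),
         eta = c(-1.2, -0.7), coef = numeric(0))
  else
    list(step_mean = c(0.5, 2, 5), step_sd = c(0.4, 1, 1.5),
         turn_mean = c(0, 0.2, 0), turn_kappa = c(0.3, 2, 8),
         eta = c(-2.2, -3, -1.5, -2.5, -1.5, -2), coef = c(0.4, 0.9))
}
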