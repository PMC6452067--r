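#include <Rcpp.h>
using namespace Rcpp;

// Hidden Markov model core for hourly step-length / turn-angle series.
//
// States carry gamma step-length and von Mises turn-angle distributions.
// Transition probabilities are multinomial-logit with covariate terms on
// the transitions out of state 1 only (rows 2..N are intercept-only).
// Missing observations contribute unit likelihood; transitions still
// advance.  The forward recursion uses per-step scaling.

// Build the state-dependent log-density matrix (n x N).  Per-state
// normalising constants (gamma shape/scale terms, log I0(kappa)) are
// hoisted out of the observation loop.
static void state_logdens(const NumericVector& step,
                          const NumericVector& turn,
                          const NumericVector& mean,
                          const NumericVector& sd,
                          const NumericVector& tmu,
                          const NumericVector& kappa,
                          NumericMatrix& ld) {
  int n = step.size(), N = mean.size();
  std::vector<double> shape(N), inv_scale(N), g_const(N), vm_const(N);
  for (int j = 0; j < N; ++j) {
    shape[j] = (mean[j] / sd[j]) * (mean[j] / sd[j]);
    double scale = sd[j] * sd[j] / mean[j];
    inv_scale[j] = 1.0 / scale;
    g_const[j] = -shape[j] * std::log(scale) - std::lgamma(shape[j]);
    // log I0(kappa) via the exponentially scaled Bessel function
    double li0 = std::log(Rf_bessel_i(kappa[j], 0.0, 2.0)) + kappa[j];
    vm_const[j] = -std::log(2.0 * M_PI) - li0;
  }
  for (int t = 0; t < n; ++t) {
    bool s_ok = !NumericVector::is_na(step[t]) && step[t] > 0;
    bool a_ok = !NumericVector::is_na(turn[t]);
    double ls = s_ok ? std::log(step[t]) : 0.0;
    for (int j = 0; j < N; ++j) {
      double v = 0.0;
      if (s_ok) v += (shape[j] - 1.0) * ls - step[t] * inv_scale[j] +
                     g_const[j];
      if (a_ok) v += kappa[j] * std::cos(turn[t] - tmu[j]) + vm_const[j];
      ld(t, j) = v;
    }
  }
}

// Transition matrix at one covariate value.  eta: off-diagonal logits,
// row-major (row i: logits for j != i, reference = staying in i);
// coef: covariate coefficients for row 0's off-diagonals.
static void tpm_at(const NumericVector& eta, const NumericVector& coef,
                   double x, int N, std::vector<double>& G) {
  int pos = 0;
  for (int i = 0; i < N; ++i) {
    double denom = 1.0;
    std::vector<double> e(N, 0.0);
    int k = 0;
    for (int j = 0; j < N; ++j) {
      if (j == i) continue;
      double lin = eta[pos + k];
      if (i == 0 && coef.size() > 0) lin += coef[k] * x;
      e[j] = std::exp(lin);
      denom += e[j];
      ++k;
    }
    for (int j = 0; j < N; ++j)
      G[i * N + j] = (j == i) ? 1.0 / denom : e[j] / denom;
    pos += N - 1;
  }
}

// [[Rcpp::export(name = ".hmm_forward_nll")]]
double hmm_forward_nll(NumericVector step, NumericVector turn,
                       NumericVector covar, IntegerVector track_start,
                       NumericVector mean, NumericVector sd,
                       NumericVector tmu, NumericVector kappa,
                       NumericVector eta, NumericVector coef,
                       NumericVector delta) {
  int n = step.size(), N = mean.size();
  NumericMatrix ld(n, N);
  state_logdens(step, turn, mean, sd, tmu, kappa, ld);
  std::vector<double> G(N * N), alpha(N), tmp(N);
  double nll = 0.0;
  int n_tracks = track_start.size();
  for (int tr = 0; tr < n_tracks; ++tr) {
    int t0 = track_start[tr] - 1;
    int t1 = (tr + 1 < n_tracks) ? track_start[tr + 1] - 1 : n;
    // initial step
    double mx = ld(t0, 0);
    for (int j = 1; j < N; ++j) mx = std::max(mx, ld(t0, j));
    double sum = 0.0;
    for (int j = 0; j < N; ++j) {
      alpha[j] = delta[j] * std::exp(ld(t0, j) - mx);
      sum += alpha[j];
    }
    nll -= std::log(sum) + mx;
    for (int j = 0; j < N; ++j) alpha[j] /= sum;
    for (int t = t0 + 1; t < t1; ++t) {
      tpm_at(eta, coef, covar[t], N, G);
      mx = ld(t, 0);
      for (int j = 1; j < N; ++j) mx = std::max(mx, ld(t, j));
      sum = 0.0;
      for (int j = 0; j < N; ++j) {
        double a = 0.0;
        for (int i = 0; i < N; ++i) a += alpha[i] * G[i * N + j];
        tmp[j] = a * std::exp(ld(t, j) - mx);
        sum += tmp[j];
      }
      if (sum <= 0.0 || !std::isfinite(sum)) return 1e10;
      nll -= std::log(sum) + mx;
      for (int j = 0; j < N; ++j) alpha[j] = tmp[j] / sum;
    }
  }
  if (!std::isfinite(nll)) return 1e10;
  return nll;
}

// [[Rcpp::export(name = ".hmm_viterbi_path")]]
IntegerVector hmm_viterbi_path(NumericVector step, NumericVector turn,
                               NumericVector covar,
                               IntegerVector track_start,
                               NumericVector mean, NumericVector sd,
                               NumericVector tmu, NumericVector kappa,
                               NumericVector eta, NumericVector coef,
                               NumericVector delta) {
  int n = step.size(), N = mean.size();
  NumericMatrix ld(n, N);
  state_logdens(step, turn, mean, sd, tmu, kappa, ld);
  IntegerVector path(n);
  std::vector<double> G(N * N);
  NumericMatrix v(n, N);
  IntegerMatrix bp(n, N);
  int n_tracks = track_start.size();
  for (int tr = 0; tr < n_tracks; ++tr) {
    int t0 = track_start[tr] - 1;
    int t1 = (tr + 1 < n_tracks) ? track_start[tr + 1] - 1 : n;
    for (int j = 0; j < N; ++j) v(t0, j) = std::log(delta[j]) + ld(t0, j);
    for (int t = t0 + 1; t < t1; ++t) {
      tpm_at(eta, coef, covar[t], N, G);
      for (int j = 0; j < N; ++j) {
        double best = R_NegInf; int arg = 0;
        for (int i = 0; i < N; ++i) {
          double cand = v(t - 1, i) + std::log(G[i * N + j]);
          if (cand > best + 1e-12) { best = cand; arg = i; }
        }
        v(t, j) = best + ld(t, j);
        bp(t, j) = arg;
      }
    }
    // backtrack (ties toward the lower state index)
    int arg = 0; double best = v(t1 - 1, 0);
    for (int j = 1; j < N; ++j)
      if (v(t1 - 1, j) > best + 1e-12) { best = v(t1 - 1, j); arg = j; }
    path[t1 - 1] = arg + 1;
    for (int t = t1 - 1; t > t0; --t) {
      arg = bp(t, arg);
      path[t - 1] = arg + 1;
    }
  }
  return path;
}
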