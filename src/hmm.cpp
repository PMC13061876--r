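#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward (Rabiner) over concatenated sequences.
// logB: n x K log emission densities; seq_start/seq_len delimit sequences
// (0-based starts). X: n x D observations, used to accumulate the
// Gaussian sufficient statistics so the M-step is a handful of matrix ops.
// Per-time-step max of logB is factored out before exponentiating, so the
// scaling constants stay in range for arbitrary dimension D.
// [[Rcpp::export]]
List hmm_estep_cpp(NumericMatrix logB, NumericVector pi0, NumericMatrix A,
                   IntegerVector seq_start, IntegerVector seq_len,
                   NumericMatrix X) {
  const int K = logB.ncol();
  const int D = X.ncol();
  const int S = seq_start.size();

  double loglik = 0.0;
  NumericVector start_gamma(K);
  NumericMatrix trans_num(K, K);
  NumericVector gamma_sum(K);
  NumericMatrix gx(K, D), gx2(K, D);

  for (int s = 0; s < S; ++s) {
    const int t0 = seq_start[s];
    const int T = seq_len[s];
    NumericMatrix alpha(T, K);
    NumericMatrix b(T, K);
    NumericVector c(T);

    // emissions with per-row max factored out (absorbed into loglik)
    for (int t = 0; t < T; ++t) {
      double m = logB(t0 + t, 0);
      for (int k = 1; k < K; ++k) m = std::max(m, logB(t0 + t, k));
      for (int k = 0; k < K; ++k) b(t, k) = std::exp(logB(t0 + t, k) - m);
      loglik += m;
    }

    // forward
    double csum = 0.0;
    for (int k = 0; k < K; ++k) { alpha(0, k) = pi0[k] * b(0, k); csum += alpha(0, k); }
    if (!(csum > 0.0)) stop("non-finite likelihood at t=1 of sequence %d", s + 1);
    c[0] = csum;
    for (int k = 0; k < K; ++k) alpha(0, k) /= csum;
    for (int t = 1; t < T; ++t) {
      csum = 0.0;
      for (int j = 0; j < K; ++j) {
        double a = 0.0;
        for (int i = 0; i < K; ++i) a += alpha(t - 1, i) * A(i, j);
        a *= b(t, j);
        alpha(t, j) = a;
        csum += a;
      }
      if (!(csum > 0.0)) stop("non-finite likelihood at t=%d of sequence %d", t + 1, s + 1);
      c[t] = csum;
      for (int j = 0; j < K; ++j) alpha(t, j) /= csum;
      loglik += std::log(c[t]);
    }
    loglik += std::log(c[0]);

    // backward, accumulating gamma and xi on the fly
    std::vector<double> beta(K, 1.0), beta_new(K);
    for (int k = 0; k < K; ++k) {
      double g = alpha(T - 1, k);
      gamma_sum[k] += g;
      for (int d = 0; d < D; ++d) {
        const double x = X(t0 + T - 1, d);
        gx(k, d) += g * x;
        gx2(k, d) += g * x * x;
      }
    }
    for (int t = T - 2; t >= 0; --t) {
      const double cinv = 1.0 / c[t + 1];
      for (int i = 0; i < K; ++i) {
        double bsum = 0.0;
        for (int j = 0; j < K; ++j) {
          const double term = A(i, j) * b(t + 1, j) * beta[j];
          trans_num(i, j) += alpha(t, i) * term * cinv;
          bsum += term;
        }
        beta_new[i] = bsum * cinv;
      }
      for (int i = 0; i < K; ++i) {
        beta[i] = beta_new[i];
        const double g = alpha(t, i) * beta[i];
        gamma_sum[i] += g;
        for (int d = 0; d < D; ++d) {
          const double x = X(t0 + t, d);
          gx(i, d) += g * x;
          gx2(i, d) += g * x * x;
        }
        if (t == 0) start_gamma[i] += g;
      }
    }
    if (T == 1)
      for (int k = 0; k < K; ++k) start_gamma[k] += alpha(0, k);
  }

  return List::create(_["loglik"] = loglik, _["start_gamma"] = start_gamma,
                      _["trans_num"] = trans_num, _["gamma_sum"] = gamma_sum,
                      _["gx"] = gx, _["gx2"] = gx2);
}

// Viterbi most-probable path for one sequence, log-space. Returns 1-based labels.
// [[Rcpp::export]]
IntegerVector hmm_viterbi_cpp(NumericMatrix logB, NumericVector log_pi,
                              NumericMatrix logA) {
  const int T = logB.nrow();
  const int K = logB.ncol();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);

  for (int k = 0; k < K; ++k) delta(0, k) = log_pi[k] + logB(0, k);
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < K; ++j) {
      double best = delta(t - 1, 0) + logA(0, j);
      int arg = 0;
      for (int i = 1; i < K; ++i) {
        const double v = delta(t - 1, i) + logA(i, j);
        if (v > best) { best = v; arg = i; }
      }
      delta(t, j) = best + logB(t, j);
      psi(t, j) = arg;
    }
  }

  IntegerVector path(T);
  int arg = 0;
  for (int k = 1; k < K; ++k) if (delta(T - 1, k) > delta(T - 1, arg)) arg = k;
  path[T - 1] = arg + 1;
  for (int t = T - 2; t >= 0; --t) {
    arg = psi(t + 1, arg);
    path[t] = arg + 1;
  }
  return path;
}

// First-order Markov path from pre-drawn uniforms (randomness stays under
// R's RNG so set.seed() governs reproducibility). cumA rows are cumulative
// transition probabilities; cum_init the cumulative initial distribution.
// [[Rcpp::export]]
IntegerVector markov_path_cpp(NumericMatrix cumA, NumericVector cum_init,
                              NumericVector u) {
  const int n = u.size();
  const int K = cumA.ncol();
  IntegerVector path(n);
  int s = 0;
  while (s < K - 1 && u[0] > cum_init[s]) ++s;
  path[0] = s + 1;
  for (int t = 1; t < n; ++t) {
    int j = 0;
    while (j < K - 1 && u[t] > cumA(s, j)) ++j;
    s = j;
    path[t] = s + 1;
  }
  return path;
}

// Direct transition pair counts for a labelled sequence (1-based labels).
// [[Rcpp::export]]
IntegerMatrix transition_counts_cpp(IntegerVector labels, int K) {
  IntegerMatrix counts(K, K);
  const int n = labels.size();
  for (int t = 1; t < n; ++t) counts(labels[t - 1] - 1, labels[t] - 1)++;
  return counts;
}
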