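#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward pass for a two-state (0 = background,
// 1 = archaic) HMM with Poisson emissions scaled per window by an
// exposure factor (callability * mutation-rate scale).  Windows flagged
// missing contribute no emission term (probability 1) but still undergo
// the transition.  Returns the log-likelihood, per-window posteriors and
// summed transition counts for the EM M-step.

static inline double emit_prob(int count, double lambda, double exposure,
                               bool miss) {
  if (miss) return 1.0;
  double lam = lambda * exposure;
  if (lam < 1e-12) lam = 1e-12;
  return R::dpois(count, lam, 0);
}

// [[Rcpp::export]]
List hmm_forward_backward(IntegerVector count, NumericVector exposure,
                          LogicalVector missing, double p_stay_bg,
                          double p_stay_arc, double lambda_bg,
                          double lambda_arc, double pi_arc) {
  int n = count.size();
  if (n == 0) stop("empty window track");
  double A[2][2] = {{p_stay_bg, 1.0 - p_stay_bg},
                    {1.0 - p_stay_arc, p_stay_arc}};
  double lam[2] = {lambda_bg, lambda_arc};
  double pi[2] = {1.0 - pi_arc, pi_arc};

  NumericMatrix alpha(n, 2), beta(n, 2), gamma(n, 2);
  NumericVector scale(n);

  // forward
  for (int s = 0; s < 2; ++s)
    alpha(0, s) = pi[s] * emit_prob(count[0], lam[s], exposure[0], missing[0]);
  scale[0] = alpha(0, 0) + alpha(0, 1);
  if (scale[0] <= 0) scale[0] = 1e-300;
  alpha(0, 0) /= scale[0]; alpha(0, 1) /= scale[0];
  for (int w = 1; w < n; ++w) {
    for (int s = 0; s < 2; ++s) {
      double acc = alpha(w - 1, 0) * A[0][s] + alpha(w - 1, 1) * A[1][s];
      alpha(w, s) = acc * emit_prob(count[w], lam[s], exposure[w], missing[w]);
    }
    scale[w] = alpha(w, 0) + alpha(w, 1);
    if (scale[w] <= 0) scale[w] = 1e-300;
    alpha(w, 0) /= scale[w]; alpha(w, 1) /= scale[w];
  }

  // backward (scaled by the forward scale factors)
  beta(n - 1, 0) = beta(n - 1, 1) = 1.0;
  for (int w = n - 2; w >= 0; --w) {
    double e0 = emit_prob(count[w + 1], lam[0], exposure[w + 1], missing[w + 1]);
    double e1 = emit_prob(count[w + 1], lam[1], exposure[w + 1], missing[w + 1]);
    for (int s = 0; s < 2; ++s)
      beta(w, s) = (A[s][0] * e0 * beta(w + 1, 0) +
                    A[s][1] * e1 * beta(w + 1, 1)) / scale[w + 1];
  }

  double loglik = 0.0;
  for (int w = 0; w < n; ++w) loglik += std::log(scale[w]);

  NumericMatrix xi(2, 2);
  for (int w = 0; w < n; ++w) {
    double g0 = alpha(w, 0) * beta(w, 0);
    double g1 = alpha(w, 1) * beta(w, 1);
    double tot = g0 + g1;
    gamma(w, 0) = g0 / tot; gamma(w, 1) = g1 / tot;
    if (w + 1 < n) {
      double e[2] = {emit_prob(count[w + 1], lam[0], exposure[w + 1], missing[w + 1]),
                     emit_prob(count[w + 1], lam[1], exposure[w + 1], missing[w + 1])};
      double norm = 0.0, x[2][2];
      for (int i = 0; i < 2; ++i)
        for (int j = 0; j < 2; ++j) {
          x[i][j] = alpha(w, i) * A[i][j] * e[j] * beta(w + 1, j);
          norm += x[i][j];
        }
      if (norm > 0)
        for (int i = 0; i < 2; ++i)
          for (int j = 0; j < 2; ++j) xi(i, j) += x[i][j] / norm;
    }
  }

  return List::create(_["loglik"] = loglik, _["gamma"] = gamma,
                      _["xi"] = xi);
}
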