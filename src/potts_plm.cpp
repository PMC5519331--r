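#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Asymmetric pseudo-likelihood objective and gradient for one MSA column.
//
// Parameter layout for focus column r (all indices 1-based on the R side):
//   par[0 .. q-1]                  : fields h_r(a)
//   par[q + (k*q + b)*1 .. ]       : couplings J_{r,j_k}(a, b) stored as
//                                    q x q blocks (a fastest), one block per
//                                    non-focus column j_k in increasing order.
// The negative log-pseudolikelihood is normalized by sum(w); L2 penalties
// lambda_h * ||h||^2 + lambda_J * ||J||^2 are added.
// [[Rcpp::export]]
List plm_obj_grad(NumericVector par, IntegerMatrix X, int r, NumericVector w,
                  double lambda_h, double lambda_J, int q) {
  const int M = X.nrow(), N = X.ncol();
  const int r0 = r - 1;
  const double W = sum(w);
  NumericVector grad(par.size());
  double nll = 0.0;

  std::vector<int> others;
  others.reserve(N - 1);
  for (int j = 0; j < N; ++j) if (j != r0) others.push_back(j);

  std::vector<double> logits(q), p(q);
  for (int m = 0; m < M; ++m) {
    const double wm = w[m] / W;
    for (int a = 0; a < q; ++a) logits[a] = par[a];
    for (size_t k = 0; k < others.size(); ++k) {
      const int b = X(m, others[k]) - 1;            // observed state at column j_k
      const int off = q + (int)(k * q * q) + b * q; // J_{r,j_k}(., b)
      for (int a = 0; a < q; ++a) logits[a] += par[off + a];
    }
    double mx = logits[0];
    for (int a = 1; a < q; ++a) if (logits[a] > mx) mx = logits[a];
    double Z = 0.0;
    for (int a = 0; a < q; ++a) { p[a] = std::exp(logits[a] - mx); Z += p[a]; }
    for (int a = 0; a < q; ++a) p[a] /= Z;

    const int xa = X(m, r0) - 1;
    nll -= wm * (logits[xa] - mx - std::log(Z));

    for (int a = 0; a < q; ++a) grad[a] += wm * p[a];
    grad[xa] -= wm;
    for (size_t k = 0; k < others.size(); ++k) {
      const int b = X(m, others[k]) - 1;
      const int off = q + (int)(k * q * q) + b * q;
      for (int a = 0; a < q; ++a) grad[off + a] += wm * p[a];
      grad[off + xa] -= wm;
    }
  }

  double pen = 0.0;
  for (int a = 0; a < q; ++a) {
    pen += lambda_h * par[a] * par[a];
    grad[a] += 2.0 * lambda_h * par[a];
  }
  for (int t = q; t < par.size(); ++t) {
    pen += lambda_J * par[t] * par[t];
    grad[t] += 2.0 * lambda_J * par[t];
  }

  return List::create(_["value"] = nll + pen, _["grad"] = grad);
}

// Sequence reweighting: w_i = 1 / #{ j : identity(i, j) >= threshold },
// identity computed over all columns (gaps included), self counted.
// [[Rcpp::export]]
NumericVector msa_weights_cpp(IntegerMatrix X, double threshold) {
  const int M = X.nrow(), N = X.ncol();
  std::vector<int> cnt(M, 1); // self
  for (int i = 0; i < M; ++i) {
    for (int j = i + 1; j < M; ++j) {
      int same = 0;
      for (int k = 0; k < N; ++k) if (X(i, k) == X(j, k)) ++same;
      if ((double)same / N >= threshold) { ++cnt[i]; ++cnt[j]; }
    }
  }
  NumericVector w(M);
  for (int i = 0; i < M; ++i) w[i] = 1.0 / cnt[i];
  return w;
}
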