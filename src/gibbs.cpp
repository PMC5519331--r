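#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gibbs sampler for a Potts model with sparse pair couplings.
//
// h: q x N field matrix. pair_i/pair_j: 1-based column indices of coupled
// pairs; Jmats: list of q x q matrices, J[a, b] couples state a at pair_i
// with state b at pair_j. One sweep = one conditional update of every
// column in order. Uses R's RNG so results are controlled by set.seed().
// [[Rcpp::export]]
IntegerMatrix potts_gibbs_cpp(int n_samples, int N, int q, NumericMatrix h,
                              IntegerVector pair_i, IntegerVector pair_j,
                              List Jmats, int burnin, int thin) {
  const int P = pair_i.size();
  IntegerMatrix out(n_samples, N);
  std::vector<int> x(N);
  std::vector<double> logp(q), prob(q);

  // adjacency: for each column, list of (pair index, am-I-the-i-side)
  std::vector<std::vector<std::pair<int, bool> > > adj(N);
  for (int p = 0; p < P; ++p) {
    adj[pair_i[p] - 1].push_back(std::make_pair(p, true));
    adj[pair_j[p] - 1].push_back(std::make_pair(p, false));
  }
  std::vector<NumericMatrix> J;
  for (int p = 0; p < P; ++p) J.push_back(as<NumericMatrix>(Jmats[p]));

  for (int k = 0; k < N; ++k) x[k] = (int)std::floor(unif_rand() * q);

  int kept = 0, sweep = 0;
  while (kept < n_samples) {
    ++sweep;
    for (int k = 0; k < N; ++k) {
      for (int a = 0; a < q; ++a) logp[a] = h(a, k);
      for (size_t t = 0; t < adj[k].size(); ++t) {
        const int p = adj[k][t].first;
        if (adj[k][t].second) {
          const int other = x[pair_j[p] - 1];
          for (int a = 0; a < q; ++a) logp[a] += J[p](a, other);
        } else {
          const int other = x[pair_i[p] - 1];
          for (int a = 0; a < q; ++a) logp[a] += J[p](other, a);
        }
      }
      double mx = logp[0];
      for (int a = 1; a < q; ++a) if (logp[a] > mx) mx = logp[a];
      double Z = 0.0;
      for (int a = 0; a < q; ++a) { prob[a] = std::exp(logp[a] - mx); Z += prob[a]; }
      double u = unif_rand() * Z, acc = 0.0;
      int pick = q - 1;
      for (int a = 0; a < q; ++a) { acc += prob[a]; if (u <= acc) { pick = a; break; } }
      x[k] = pick;
    }
    if (sweep > burnin && ((sweep - burnin) % thin == 0)) {
      for (int k = 0; k < N; ++k) out(kept, k) = x[k] + 1;
      ++kept;
    }
  }
  return out;
}
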