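#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Shrake-Rupley solvent-accessible surface area.
//
// Test points are placed on each expanded sphere (radius + probe) with a
// golden-spiral lattice; a point is accessible if it lies outside every
// neighboring atom's expanded sphere. Per-atom SASA = exposed fraction
// times the expanded-sphere area. O(n^2) neighbor search.
// [[Rcpp::export]]
NumericVector shrake_rupley_cpp(NumericMatrix coords, NumericVector radii,
                                double probe, int n_points) {
  const int n = coords.nrow();
  NumericVector out(n);

  // golden-spiral unit sphere points
  std::vector<double> px(n_points), py(n_points), pz(n_points);
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n_points; ++k) {
    const double z = 1.0 - 2.0 * (k + 0.5) / n_points;
    const double r = std::sqrt(1.0 - z * z);
    const double th = golden * k;
    px[k] = r * std::cos(th); py[k] = r * std::sin(th); pz[k] = z;
  }

  for (int i = 0; i < n; ++i) {
    const double ri = radii[i] + probe;
    std::vector<int> nb;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double rj = radii[j] + probe;
      const double dx = coords(j,0)-coords(i,0), dy = coords(j,1)-coords(i,1),
                   dz = coords(j,2)-coords(i,2);
      if (dx*dx + dy*dy + dz*dz < (ri + rj) * (ri + rj)) nb.push_back(j);
    }
    int exposed = 0;
    for (int k = 0; k < n_points; ++k) {
      const double x = coords(i,0) + ri * px[k];
      const double y = coords(i,1) + ri * py[k];
      const double z = coords(i,2) + ri * pz[k];
      bool free_pt = true;
      for (size_t t = 0; t < nb.size(); ++t) {
        const int j = nb[t];
        const double rj = radii[j] + probe;
        const double dx = x - coords(j,0), dy = y - coords(j,1), dz = z - coords(j,2);
        if (dx*dx + dy*dy + dz*dz < rj * rj) { free_pt = false; break; }
      }
      if (free_pt) ++exposed;
    }
    out[i] = 4.0 * M_PI * ri * ri * exposed / n_points;
  }
  return out;
}
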