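#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double KB_KCAL = 0.0019872041; // kcal/mol/K

// ---- pair potentials -------------------------------------------------------
//
// Model list fields (prepared in R by build_pair_tables()):
//   type: 0 zero; 1 contact + Debye-Hueckel tables; 2 pairwise square well
//   eps, sig, qq : nA x nB tables (type 1)
//   dielectric, debye, cutoff, coulomb
//   core, well, depth : square-well geometry (type 2), depth in kcal/mol
struct PairModel {
  int type;
  NumericMatrix eps, sig, qq;
  double dielectric, debye, cutoff, coulomb;
  double core, well, depth;
};

static PairModel unpack_model(List m) {
  PairModel pm;
  pm.type = as<int>(m["type"]);
  if (pm.type == 1) {
    pm.eps = as<NumericMatrix>(m["eps"]);
    pm.sig = as<NumericMatrix>(m["sig"]);
    pm.qq  = as<NumericMatrix>(m["qq"]);
    pm.dielectric = as<double>(m["dielectric"]);
    pm.debye = as<double>(m["debye"]);
    pm.coulomb = as<double>(m["coulomb"]);
  }
  if (pm.type == 2) {
    pm.core = as<double>(m["core"]);
    pm.well = as<double>(m["well"]);
    pm.depth = as<double>(m["depth"]);
  }
  pm.cutoff = as<double>(m["cutoff"]);
  return pm;
}

static inline double pair_u(const PairModel &pm, int i, int j, double r) {
  if (r > pm.cutoff) return 0.0;
  if (pm.type == 0) return 0.0;
  if (pm.type == 2) {
    if (r < pm.core) return 1e8;
    if (r < pm.well) return -pm.depth;
    return 0.0;
  }
  const double e = pm.eps(i, j), s = pm.sig(i, j);
  double sr2 = (s / r) * (s / r);
  double sr6 = sr2 * sr2 * sr2, sr12 = sr6 * sr6;
  double u;
  if (e < 0.0) {
    // attractive: well of depth |eps| with minimum at r = sigma
    u = -e * (sr12 - 2.0 * sr6);
  } else {
    // repulsive: soft core with barrier +eps at r = sigma, positive tail
    u = (r <= s) ? e * (sr12 - 2.0 * sr6) + 2.0 * e : -e * (sr12 - 2.0 * sr6);
  }
  const double qq = pm.qq(i, j);
  if (qq != 0.0)
    u += pm.coulomb * qq * std::exp(-r / pm.debye) / (pm.dielectric * r);
  return u;
}

// ---- quaternions -----------------------------------------------------------
static inline void quat_rotate(const double *q, const double *v, double *out) {
  // rotate v by unit quaternion q = (w, x, y, z)
  const double w = q[0], x = q[1], y = q[2], z = q[3];
  const double t0 = 2.0 * (y * v[2] - z * v[1]);
  const double t1 = 2.0 * (z * v[0] - x * v[2]);
  const double t2 = 2.0 * (x * v[1] - y * v[0]);
  out[0] = v[0] + w * t0 + (y * t2 - z * t1);
  out[1] = v[1] + w * t1 + (z * t0 - x * t2);
  out[2] = v[2] + w * t2 + (x * t1 - y * t0);
}

static inline void quat_mul(const double *a, const double *b, double *out) {
  out[0] = a[0]*b[0] - a[1]*b[1] - a[2]*b[2] - a[3]*b[3];
  out[1] = a[0]*b[1] + a[1]*b[0] + a[2]*b[3] - a[3]*b[2];
  out[2] = a[0]*b[2] - a[1]*b[3] + a[2]*b[0] + a[3]*b[1];
  out[3] = a[0]*b[3] + a[1]*b[2] - a[2]*b[1] + a[3]*b[0];
}

static inline void quat_normalize(double *q) {
  double n = std::sqrt(q[0]*q[0] + q[1]*q[1] + q[2]*q[2] + q[3]*q[3]);
  for (int k = 0; k < 4; ++k) q[k] /= n;
}

static void random_quat(double *q) {
  for (int k = 0; k < 4; ++k) q[k] = norm_rand();
  quat_normalize(q);
}

// small rotation: random axis, angle uniform in (-step, step)
static void perturb_quat(const double *q, double step, double *out) {
  double ax[3];
  double n = 0.0;
  for (int k = 0; k < 3; ++k) { ax[k] = norm_rand(); n += ax[k]*ax[k]; }
  n = std::sqrt(n);
  const double ang = (unif_rand() * 2.0 - 1.0) * step;
  const double s = std::sin(ang / 2.0) / n;
  double dq[4] = { std::cos(ang / 2.0), ax[0]*s, ax[1]*s, ax[2]*s };
  quat_mul(dq, q, out);
  quat_normalize(out);
}

static inline double min_image(double d, double L) {
  return d - L * std::round(d / L);
}

// total interaction energy of pose (trans, quat) of body B against fixed A,
// minimum-image convention in a cubic box of edge L
static double config_energy(const NumericMatrix &A, const NumericMatrix &Bl,
                            const double *trans, const double *quat, double L,
                            const PairModel &pm) {
  const int nA = A.nrow(), nB = Bl.nrow();
  double U = 0.0;
  for (int j = 0; j < nB; ++j) {
    double v[3] = { Bl(j, 0), Bl(j, 1), Bl(j, 2) }, b[3];
    quat_rotate(quat, v, b);
    for (int k = 0; k < 3; ++k) b[k] += trans[k];
    for (int i = 0; i < nA; ++i) {
      const double dx = min_image(A(i, 0) - b[0], L);
      const double dy = min_image(A(i, 1) - b[1], L);
      const double dz = min_image(A(i, 2) - b[2], L);
      const double r = std::sqrt(dx*dx + dy*dy + dz*dz);
      U += pair_u(pm, i, j, r > 1e-12 ? r : 1e-12);
    }
  }
  return U;
}

// [[Rcpp::export]]
double total_energy_cpp(NumericMatrix A, NumericMatrix Blocal,
                        NumericVector trans, NumericVector quat,
                        double box_edge, List model) {
  PairModel pm = unpack_model(model);
  double t[3] = { trans[0], trans[1], trans[2] };
  double q[4] = { quat[0], quat[1], quat[2], quat[3] };
  return config_energy(A, Blocal, t, q, box_edge, pm);
}

// ---- REMC ------------------------------------------------------------------
// One MC step = one attempted rigid move of body B in every replica.
// Exchange: every exchange_interval steps, n_rep-1 random neighbor-pair
// swap attempts with the standard criterion exp((b_i - b_j)(E_i - E_j)).
// Move sizes adapt toward target_acc during the first adapt_frac*n_steps
// steps, then stay frozen. Uses R's RNG throughout.
// [[Rcpp::export]]
List remc_run_cpp(NumericMatrix A, NumericMatrix Blocal, double box_edge,
                  List model, NumericVector temps, int n_steps,
                  int record_stride, int exchange_interval,
                  double trans_step, double rot_step, double p_jump,
                  double adapt_frac, double target_acc) {
  PairModel pm = unpack_model(model);
  const int R = temps.size();
  const int n_rec = n_steps / record_stride;
  const double L = box_edge;

  std::vector<double> beta(R);
  for (int r = 0; r < R; ++r) beta[r] = 1.0 / (KB_KCAL * temps[r]);

  std::vector<std::array<double,3> > tr(R);
  std::vector<std::array<double,4> > qu(R);
  std::vector<double> E(R), dtr(R, trans_step), drot(R, rot_step);
  std::vector<long> att(R, 0), acc(R, 0), attw(R, 0), accw(R, 0);

  for (int r = 0; r < R; ++r) {
    for (int k = 0; k < 3; ++k) tr[r][k] = unif_rand() * L;
    random_quat(qu[r].data());
    E[r] = config_energy(A, Blocal, tr[r].data(), qu[r].data(), L, pm);
  }

  NumericVector rec_trans(n_rec * R * 3), rec_quat(n_rec * R * 4),
      rec_E(n_rec * R);
  const int adapt_until = (int)(adapt_frac * n_steps);
  const int adapt_window = 200;
  std::vector<long> w_att(R, 0), w_acc(R, 0);

  int rec = 0;
  for (int step = 1; step <= n_steps; ++step) {
    for (int r = 0; r < R; ++r) {
      double nt[3] = { tr[r][0], tr[r][1], tr[r][2] };
      double nq[4] = { qu[r][0], qu[r][1], qu[r][2], qu[r][3] };
      const double u = unif_rand();
      if (u < p_jump) {
        for (int k = 0; k < 3; ++k) nt[k] = unif_rand() * L;
        random_quat(nq);
      } else if (u < p_jump + (1.0 - p_jump) * 0.5) {
        // translation uniform in sphere of radius dtr
        double d[3];
        do {
          for (int k = 0; k < 3; ++k) d[k] = unif_rand() * 2.0 - 1.0;
        } while (d[0]*d[0] + d[1]*d[1] + d[2]*d[2] > 1.0);
        for (int k = 0; k < 3; ++k) {
          nt[k] += d[k] * dtr[r];
          nt[k] -= L * std::floor(nt[k] / L); // wrap into box
        }
      } else {
        perturb_quat(qu[r].data(), drot[r], nq);
      }
      const double En = config_energy(A, Blocal, nt, nq, L, pm);
      ++att[r]; ++w_att[r];
      if (En <= E[r] || unif_rand() < std::exp(-beta[r] * (En - E[r]))) {
        for (int k = 0; k < 3; ++k) tr[r][k] = nt[k];
        for (int k = 0; k < 4; ++k) qu[r][k] = nq[k];
        E[r] = En;
        ++acc[r]; ++w_acc[r];
      }
    }

    if (step <= adapt_until && step % adapt_window == 0) {
      for (int r = 0; r < R; ++r) {
        if (w_att[r] == 0) continue;
        const double a = (double)w_acc[r] / w_att[r];
        const double f = std::exp(1.0 * (a - target_acc));
        dtr[r] = std::min(std::max(dtr[r] * f, 0.01), L / 2.0);
        drot[r] = std::min(std::max(drot[r] * f, 1e-3), M_PI);
        w_att[r] = w_acc[r] = 0;
      }
    }

    if (R > 1 && exchange_interval > 0 && step % exchange_interval == 0) {
      for (int t = 0; t < R - 1; ++t) {
        const int i = (int)std::floor(unif_rand() * (R - 1));
        const int j = i + 1;
        ++attw[i];
        const double d = (beta[i] - beta[j]) * (E[i] - E[j]);
        if (d >= 0.0 || unif_rand() < std::exp(d)) {
          std::swap(tr[i], tr[j]);
          std::swap(qu[i], qu[j]);
          std::swap(E[i], E[j]);
          ++accw[i];
        }
      }
    }

    if (step % record_stride == 0 && rec < n_rec) {
      for (int r = 0; r < R; ++r) {
        for (int k = 0; k < 3; ++k) rec_trans[rec + n_rec * (r + R * k)] = tr[r][k];
        for (int k = 0; k < 4; ++k) rec_quat[rec + n_rec * (r + R * k)] = qu[r][k];
        rec_E[rec + n_rec * r] = E[r];
      }
      ++rec;
    }
  }

  rec_trans.attr("dim") = IntegerVector::create(n_rec, R, 3);
  rec_quat.attr("dim") = IntegerVector::create(n_rec, R, 4);
  rec_E.attr("dim") = IntegerVector::create(n_rec, R);
  NumericVector acc_rate(R), swap_rate(R - 1 > 0 ? R - 1 : 0);
  for (int r = 0; r < R; ++r) acc_rate[r] = att[r] ? (double)acc[r] / att[r] : NA_REAL;
  for (int r = 0; r + 1 < R; ++r) swap_rate[r] = attw[r] ? (double)accw[r] / attw[r] : NA_REAL;
  return List::create(_["trans"] = rec_trans, _["quat"] = rec_quat,
                      _["energy"] = rec_E, _["acceptance"] = acc_rate,
                      _["swap_acceptance"] = swap_rate,
                      _["trans_step"] = NumericVector(dtr.begin(), dtr.end()),
                      _["rot_step"] = NumericVector(drot.begin(), drot.end()));
}

// minimum inter-body bead distance for each pose (minimum image)
// [[Rcpp::export]]
NumericVector pose_min_dist_cpp(NumericMatrix A, NumericMatrix Blocal,
                                NumericMatrix trans, NumericMatrix quat,
                                double box_edge) {
  const int n = trans.nrow(), nA = A.nrow(), nB = Blocal.nrow();
  NumericVector out(n);
  for (int p = 0; p < n; ++p) {
    double t[3] = { trans(p,0), trans(p,1), trans(p,2) };
    double q[4] = { quat(p,0), quat(p,1), quat(p,2), quat(p,3) };
    double best = R_PosInf;
    for (int j = 0; j < nB; ++j) {
      double v[3] = { Blocal(j,0), Blocal(j,1), Blocal(j,2) }, b[3];
      quat_rotate(q, v, b);
      for (int k = 0; k < 3; ++k) b[k] += t[k];
      for (int i = 0; i < nA; ++i) {
        const double dx = min_image(A(i,0) - b[0], box_edge);
        const double dy = min_image(A(i,1) - b[1], box_edge);
        const double dz = min_image(A(i,2) - b[2], box_edge);
        const double r2 = dx*dx + dy*dy + dz*dz;
        if (r2 < best) best = r2;
      }
    }
    out[p] = std::sqrt(best);
  }
  return out;
}

// ligand bead coordinates per pose, COM wrapped to the periodic image
// nearest to ref (typically the receptor COM); rows = poses, 3*nB columns
// [[Rcpp::export]]
NumericMatrix pose_ligand_coords_cpp(NumericMatrix Blocal, NumericMatrix trans,
                                     NumericMatrix quat, double box_edge,
                                     NumericVector ref) {
  const int n = trans.nrow(), nB = Blocal.nrow();
  NumericMatrix out(n, 3 * nB);
  for (int p = 0; p < n; ++p) {
    double t[3] = { trans(p,0), trans(p,1), trans(p,2) };
    double q[4] = { quat(p,0), quat(p,1), quat(p,2), quat(p,3) };
    double shift[3];
    for (int k = 0; k < 3; ++k)
      shift[k] = box_edge * std::round((t[k] - ref[k]) / box_edge);
    for (int j = 0; j < nB; ++j) {
      double v[3] = { Blocal(j,0), Blocal(j,1), Blocal(j,2) }, b[3];
      quat_rotate(q, v, b);
      for (int k = 0; k < 3; ++k) out(p, 3*j + k) = b[k] + t[k] - shift[k];
    }
  }
  return out;
}

// pairwise RMSD between pose ligand-coordinate rows (no superposition:
// the receptor frame is shared)
// [[Rcpp::export]]
NumericMatrix rmsd_matrix_cpp(NumericMatrix coords) {
  const int n = coords.nrow();
  const int nB = coords.ncol() / 3;
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int k = 0; k < 3 * nB; ++k) {
        const double d = coords(i, k) - coords(j, k);
        s += d * d;
      }
      out(i, j) = out(j, i) = std::sqrt(s / nB);
    }
  return out;
}

// per-residue contact counts over poses: a residue is "in contact" in a pose
// if any partner bead lies within cutoff (minimum image)
// [[Rcpp::export]]
List contact_counts_cpp(NumericMatrix A, NumericMatrix Blocal,
                        NumericMatrix trans, NumericMatrix quat,
                        double box_edge, double cutoff) {
  const int n = trans.nrow(), nA = A.nrow(), nB = Blocal.nrow();
  IntegerVector cA(nA), cB(nB);
  const double c2 = cutoff * cutoff;
  std::vector<int> hitA(nA), hitB(nB);
  for (int p = 0; p < n; ++p) {
    std::fill(hitA.begin(), hitA.end(), 0);
    std::fill(hitB.begin(), hitB.end(), 0);
    double t[3] = { trans(p,0), trans(p,1), trans(p,2) };
    double q[4] = { quat(p,0), quat(p,1), quat(p,2), quat(p,3) };
    for (int j = 0; j < nB; ++j) {
      double v[3] = { Blocal(j,0), Blocal(j,1), Blocal(j,2) }, b[3];
      quat_rotate(q, v, b);
      for (int k = 0; k < 3; ++k) b[k] += t[k];
      for (int i = 0; i < nA; ++i) {
        const double dx = min_image(A(i,0) - b[0], box_edge);
        const double dy = min_image(A(i,1) - b[1], box_edge);
        const double dz = min_image(A(i,2) - b[2], box_edge);
        if (dx*dx + dy*dy + dz*dz <= c2) { hitA[i] = 1; hitB[j] = 1; }
      }
    }
    for (int i = 0; i < nA; ++i) cA[i] += hitA[i];
    for (int j = 0; j < nB; ++j) cB[j] += hitB[j];
  }
  return List::create(_["count_A"] = cA, _["count_B"] = cB);
}
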