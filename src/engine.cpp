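// Coarse-grained Metropolis Monte Carlo engine.
//
// The system is a set of beads (4 per residue: N, CA, C and a CB
// pseudo-side-chain) carrying a toy energy: soft-core excluded volume,
// a Gaussian-well native-contact (Go) term on an explicit pair list,
// a helix-propensity bonus on peptide backbone dihedrals, a screened
// Coulomb term, and a quadratic non-optimized-RMSD restraint on receptor
// C-alpha positions. Moves: peptide rigid translation/rotation/teleport,
// peptide pivot (single dihedral), receptor per-residue rigid jiggle.
// All randomness comes from R's RNG so runs are seed-reproducible.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct Par {
  double eps_ev, sigma2, r_core2, e_cap;
  double eps_go, go_w;
  double eps_h, phi_lo, phi_hi, psi_lo, psi_hi;
  double eps_c, lambda, coul_cut2;
  double k_r;
  double s_trans, s_rot, s_pivot, s_rec, s_rec_rot;
  std::vector<double> move_cum; // cumulative move weights (5 moves)
};

struct Sys {
  int n;
  std::vector<double> X; // 3*n, xyz interleaved
  std::vector<int> res, chain;
  std::vector<double> q;
  std::vector<int> restr_slot;        // atom -> restraint index or -1
  std::vector<double> restr_ref;      // 3*m
  std::vector<int> go_i, go_j;
  std::vector<double> go_r0, go_d, go_w;
  std::vector<std::vector<int>> go_of_atom;
  std::vector<int> pep_atoms;         // residue-major N,CA,C,CB
  int pep_nres;
  std::vector<double> phi, psi;       // degrees
  std::vector<std::vector<int>> res_atoms; // per global residue
  double box;
  long overlap_flags;
};

static inline double mimg(double d, double box) {
  if (box > 0) {
    double h = 0.5 * box;
    while (d > h) d -= box;
    while (d < -h) d += box;
  }
  return d;
}

static inline double dist2(const Sys &s, const std::vector<double> &X,
                           int a, int b) {
  double dx = mimg(X[3 * a] - X[3 * b], s.box);
  double dy = mimg(X[3 * a + 1] - X[3 * b + 1], s.box);
  double dz = mimg(X[3 * a + 2] - X[3 * b + 2], s.box);
  return dx * dx + dy * dy + dz * dz;
}

// excluded volume + screened Coulomb for one atom pair (with exclusions)
static inline void pair_energy(const Sys &s, const Par &p,
                               const std::vector<double> &X, int a, int b,
                               double &ev, double &coul, long &flags) {
  if (s.res[a] == s.res[b]) return;
  if (s.chain[a] == s.chain[b] && std::abs(s.res[a] - s.res[b]) == 1) return;
  // component-wise early exit at the pair's own interaction range
  double qq = s.q[a] * s.q[b];
  double cut2 = qq != 0.0 ? p.coul_cut2 : p.sigma2;
  double dx = mimg(X[3 * a] - X[3 * b], s.box);
  double r2 = dx * dx;
  if (r2 >= cut2) return;
  double dy = mimg(X[3 * a + 1] - X[3 * b + 1], s.box);
  r2 += dy * dy;
  if (r2 >= cut2) return;
  double dz = mimg(X[3 * a + 2] - X[3 * b + 2], s.box);
  r2 += dz * dz;
  if (r2 >= cut2) return;
  if (r2 < p.sigma2) {
    if (r2 < p.r_core2) {
      ev += p.e_cap;
      ++flags;
    } else {
      double u = p.sigma2 / r2;
      double u6 = u * u * u;
      ev += p.eps_ev * (u6 * u6 - 1.0);
    }
  }
  if (qq != 0.0) {
    double r = std::sqrt(r2);
    coul += p.eps_c * qq * std::exp(-r / p.lambda) / r;
  }
}

static inline double go_pair_energy(const Sys &s, const Par &p,
                                    const std::vector<double> &X, int k) {
  double w = s.go_w[k] > 0 ? s.go_w[k] : p.go_w;
  double r = std::sqrt(dist2(s, X, s.go_i[k], s.go_j[k]));
  double d = r - s.go_r0[k];
  if (std::fabs(d) > 6.0 * w) return 0.0;
  return -p.eps_go * s.go_d[k] * std::exp(-d * d / (2.0 * w * w));
}

static inline double restraint_one(const Sys &s, const Par &p,
                                   const std::vector<double> &X, int a) {
  int sl = s.restr_slot[a];
  if (sl < 0) return 0.0;
  double dx = X[3 * a] - s.restr_ref[3 * sl];
  double dy = X[3 * a + 1] - s.restr_ref[3 * sl + 1];
  double dz = X[3 * a + 2] - s.restr_ref[3 * sl + 2];
  return p.k_r * (dx * dx + dy * dy + dz * dz);
}

static inline bool helical(const Par &p, double phi, double psi) {
  return phi > p.phi_lo && phi < p.phi_hi && psi > p.psi_lo && psi < p.psi_hi;
}

static double helix_energy_res(const Sys &s, const Par &p, int r) {
  if (r < 1 || r > s.pep_nres - 2) return 0.0;
  return helical(p, s.phi[r], s.psi[r]) ? -p.eps_h : 0.0;
}

struct Ecomp {
  double ev = 0, coul = 0, go = 0, helix = 0, restr = 0;
  double total() const { return ev + coul + go + helix + restr; }
};

static Ecomp full_energy(Sys &s, const Par &p) {
  Ecomp e;
  for (int a = 0; a < s.n; ++a) {
    for (int b = a + 1; b < s.n; ++b)
      pair_energy(s, p, s.X, a, b, e.ev, e.coul, s.overlap_flags);
    e.restr += restraint_one(s, p, s.X, a);
  }
  for (size_t k = 0; k < s.go_i.size(); ++k)
    e.go += go_pair_energy(s, p, s.X, k);
  for (int r = 1; r <= s.pep_nres - 2; ++r)
    e.helix += helix_energy_res(s, p, r);
  return e;
}

static double dihedral_deg(const std::vector<double> &X, int a, int b, int c,
                           int d) {
  double b1[3], b2[3], b3[3];
  for (int k = 0; k < 3; ++k) {
    b1[k] = X[3 * b + k] - X[3 * a + k];
    b2[k] = X[3 * c + k] - X[3 * b + k];
    b3[k] = X[3 * d + k] - X[3 * c + k];
  }
  double n1[3] = {b1[1] * b2[2] - b1[2] * b2[1], b1[2] * b2[0] - b1[0] * b2[2],
                  b1[0] * b2[1] - b1[1] * b2[0]};
  double n2[3] = {b2[1] * b3[2] - b2[2] * b3[1], b2[2] * b3[0] - b2[0] * b3[2],
                  b2[0] * b3[1] - b2[1] * b3[0]};
  double b2n = std::sqrt(b2[0] * b2[0] + b2[1] * b2[1] + b2[2] * b2[2]);
  double m1[3] = {(b2[1] * n1[2] - b2[2] * n1[1]) / b2n,
                  (b2[2] * n1[0] - b2[0] * n1[2]) / b2n,
                  (b2[0] * n1[1] - b2[1] * n1[0]) / b2n};
  double x = n1[0] * n2[0] + n1[1] * n2[1] + n1[2] * n2[2];
  double y = m1[0] * n2[0] + m1[1] * n2[1] + m1[2] * n2[2];
  return std::atan2(y, x) * 180.0 / M_PI;
}

static void rot_matrix(double ux, double uy, double uz, double ang,
                       double R[3][3]) {
  double n = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= n; uy /= n; uz /= n;
  double c = std::cos(ang), s = std::sin(ang), t = 1 - c;
  R[0][0] = c + ux * ux * t; R[0][1] = ux * uy * t - uz * s; R[0][2] = ux * uz * t + uy * s;
  R[1][0] = uy * ux * t + uz * s; R[1][1] = c + uy * uy * t; R[1][2] = uy * uz * t - ux * s;
  R[2][0] = uz * ux * t - uy * s; R[2][1] = uz * uy * t + ux * s; R[2][2] = c + uz * uz * t;
}

static void apply_rot(std::vector<double> &X, const std::vector<int> &atoms,
                      const double R[3][3], const double piv[3]) {
  for (int a : atoms) {
    double v[3] = {X[3 * a] - piv[0], X[3 * a + 1] - piv[1], X[3 * a + 2] - piv[2]};
    for (int k = 0; k < 3; ++k)
      X[3 * a + k] = piv[k] + R[k][0] * v[0] + R[k][1] * v[1] + R[k][2] * v[2];
  }
}

// (dist2 on explicit coordinate array for a Go pair)
static inline double godist2(const Sys &s, const std::vector<double> &X, int k) {
  double dx = mimg(X[3 * s.go_i[k]] - X[3 * s.go_j[k]], s.box);
  double dy = mimg(X[3 * s.go_i[k] + 1] - X[3 * s.go_j[k] + 1], s.box);
  double dz = mimg(X[3 * s.go_i[k] + 2] - X[3 * s.go_j[k] + 2], s.box);
  return dx * dx + dy * dy + dz * dz;
}

static Sys build_sys(List sys) {
  Sys s;
  NumericMatrix coords = sys["coords"];
  s.n = coords.nrow();
  s.X.resize(3 * s.n);
  for (int i = 0; i < s.n; ++i)
    for (int k = 0; k < 3; ++k) s.X[3 * i + k] = coords(i, k);
  s.res = as<std::vector<int>>(sys["res_id"]);
  s.chain = as<std::vector<int>>(sys["chain_id"]);
  s.q = as<std::vector<double>>(sys["charges"]);
  IntegerVector ridx = sys["restraint_atoms"];
  NumericMatrix rref = sys["restraint_ref"];
  s.restr_slot.assign(s.n, -1);
  s.restr_ref.resize(3 * ridx.size());
  for (int i = 0; i < ridx.size(); ++i) {
    s.restr_slot[ridx[i]] = i;
    for (int k = 0; k < 3; ++k) s.restr_ref[3 * i + k] = rref(i, k);
  }
  s.go_i = as<std::vector<int>>(sys["go_i"]);
  s.go_j = as<std::vector<int>>(sys["go_j"]);
  s.go_r0 = as<std::vector<double>>(sys["go_r0"]);
  s.go_d = as<std::vector<double>>(sys["go_depth"]);
  if (s.go_d.size() != s.go_r0.size())
    s.go_d.assign(s.go_r0.size(), 1.0);
  s.go_w = as<std::vector<double>>(sys["go_widths"]);
  if (s.go_w.size() != s.go_r0.size())
    s.go_w.assign(s.go_r0.size(), -1.0); // -1: use the global width
  s.go_of_atom.assign(s.n, {});
  for (size_t k = 0; k < s.go_i.size(); ++k) {
    s.go_of_atom[s.go_i[k]].push_back((int)k);
    s.go_of_atom[s.go_j[k]].push_back((int)k);
  }
  s.pep_atoms = as<std::vector<int>>(sys["pep_atoms"]);
  s.pep_nres = as<int>(sys["pep_nres"]);
  s.phi = as<std::vector<double>>(sys["phi"]);
  s.psi = as<std::vector<double>>(sys["psi"]);
  int nres_tot = 0;
  for (int i = 0; i < s.n; ++i) nres_tot = std::max(nres_tot, s.res[i] + 1);
  s.res_atoms.assign(nres_tot, {});
  for (int i = 0; i < s.n; ++i) s.res_atoms[s.res[i]].push_back(i);
  s.box = as<double>(sys["box_length"]);
  s.overlap_flags = 0;
  return s;
}

static Par build_par(List params, double temperature) {
  Par p;
  double sigma = as<double>(params["sigma_ev"]);
  p.eps_ev = as<double>(params["eps_ev"]);
  p.sigma2 = sigma * sigma;
  double rc = as<double>(params["r_core"]);
  p.r_core2 = rc * rc;
  double u = p.sigma2 / p.r_core2, u6 = u * u * u;
  p.e_cap = p.eps_ev * (u6 * u6 - 1.0);
  p.eps_go = as<double>(params["eps_go"]);
  p.go_w = as<double>(params["go_width"]);
  p.eps_h = as<double>(params["eps_helix"]);
  NumericVector pw = params["phi_window"], sw = params["psi_window"];
  p.phi_lo = pw[0]; p.phi_hi = pw[1]; p.psi_lo = sw[0]; p.psi_hi = sw[1];
  p.eps_c = as<double>(params["eps_coulomb"]);
  p.lambda = as<double>(params["screening_length"]);
  double cc = as<double>(params["coulomb_cutoff"]);
  p.coul_cut2 = cc * cc;
  p.k_r = as<double>(params["k_restraint"]);
  NumericVector ss = params["step_sizes"]; // trans, rot, pivot(deg), rec, rec_rot
  p.s_trans = ss[0]; p.s_rot = ss[1]; p.s_pivot = ss[2];
  p.s_rec = ss[3]; p.s_rec_rot = ss[4];
  NumericVector mw = params["move_weights"];
  double acc = 0;
  p.move_cum.clear();
  for (int i = 0; i < mw.size(); ++i) { acc += mw[i]; p.move_cum.push_back(acc); }
  for (auto &v : p.move_cum) v /= acc;
  (void)temperature;
  return p;
}

// [[Rcpp::export(name = ".mc_run_cpp")]]
List mc_run_cpp(List sys, List params, double temperature, int n_steps,
                int save_interval, int energy_check_interval) {
  Sys s = build_sys(sys);
  Par p = build_par(params, temperature);
  RNGScope scope;

  // receptor bounding sphere: lets rigid/pivot peptide moves skip all
  // receptor interactions when the peptide is far from the receptor
  std::vector<int> rec_atoms, rec_charged, pep_all;
  for (int i = 0; i < s.n; ++i) {
    if (s.chain[i] != 2) {
      rec_atoms.push_back(i);
      if (s.q[i] != 0.0) rec_charged.push_back(i);
    } else {
      pep_all.push_back(i);
    }
  }
  double rec_c[3] = {0, 0, 0}, rec_rad = 0;
  auto update_rec_sphere = [&]() {
    if (rec_atoms.empty()) return;
    for (int k = 0; k < 3; ++k) rec_c[k] = 0;
    for (int a : rec_atoms)
      for (int k = 0; k < 3; ++k) rec_c[k] += s.X[3 * a + k];
    for (int k = 0; k < 3; ++k) rec_c[k] /= rec_atoms.size();
    rec_rad = 0;
    for (int a : rec_atoms) {
      double d2 = 0;
      for (int k = 0; k < 3; ++k) {
        double d = s.X[3 * a + k] - rec_c[k];
        d2 += d * d;
      }
      rec_rad = std::max(rec_rad, std::sqrt(d2));
    }
    rec_rad += 2.0; // cushion for receptor drift between sphere updates
  };
  update_rec_sphere();
  double max_reach = 0;
  for (size_t k = 0; k < s.go_r0.size(); ++k) {
    double w = s.go_w[k] > 0 ? s.go_w[k] : p.go_w;
    max_reach = std::max(max_reach, s.go_r0[k] + 6.0 * w);
  }
  double skip_gap = std::sqrt(std::max(p.coul_cut2, p.sigma2));
  skip_gap = std::max(skip_gap, max_reach);

  Ecomp e = full_energy(s, p);
  s.overlap_flags = 0; // don't count initial-state overlaps per step

  int n_save = n_steps / save_interval;
  NumericVector frames((R_xlen_t)s.n * 3 * n_save);
  NumericMatrix etab(n_save, 6);
  IntegerVector prop(5), acc(5);

  std::vector<char> in_moved(s.n, 0);
  std::vector<double> Xnew;
  int save_ptr = 0;

  for (long step = 1; step <= (long)n_steps; ++step) {
    double u = unif_rand();
    int mv = 0;
    while (mv < (int)p.move_cum.size() - 1 && u > p.move_cum[mv]) ++mv;
    ++prop[mv];

    std::vector<int> moved;
    Xnew = s.X; // proposal workspace (copy; sizes are small)
    double d_phi_new = 0;
    int piv_res = -1;
    bool piv_is_phi = true;
    bool feasible = true;

    if (mv == 0 || mv == 1 || mv == 2) {      // peptide rigid moves
      moved = s.pep_atoms;
      if (mv == 0) {
        double dx = norm_rand() * p.s_trans, dy = norm_rand() * p.s_trans,
               dz = norm_rand() * p.s_trans;
        for (int a : moved) {
          Xnew[3 * a] += dx; Xnew[3 * a + 1] += dy; Xnew[3 * a + 2] += dz;
        }
      } else {
        double c[3] = {0, 0, 0};
        for (int a : moved)
          for (int k = 0; k < 3; ++k) c[k] += s.X[3 * a + k];
        for (int k = 0; k < 3; ++k) c[k] /= moved.size();
        double R[3][3];
        if (mv == 1) {
          rot_matrix(norm_rand(), norm_rand(), norm_rand(),
                     norm_rand() * p.s_rot, R);
          apply_rot(Xnew, moved, R, c);
        } else {                               // teleport: new COM + rotation
          if (s.box <= 0) { feasible = false; }
          else {
            rot_matrix(norm_rand(), norm_rand(), norm_rand(),
                       unif_rand() * 2 * M_PI, R);
            apply_rot(Xnew, moved, R, c);
            double tgt[3] = {unif_rand() * s.box, unif_rand() * s.box,
                             unif_rand() * s.box};
            for (int a : moved)
              for (int k = 0; k < 3; ++k) Xnew[3 * a + k] += tgt[k] - c[k];
          }
        }
      }
    } else if (mv == 3) {                      // pivot
      int nres = s.pep_nres;
      piv_res = (int)(unif_rand() * nres);
      if (piv_res >= nres) piv_res = nres - 1;
      piv_is_phi = unif_rand() < 0.5;
      if ((piv_is_phi && piv_res == 0) || (!piv_is_phi && piv_res == nres - 1)) {
        feasible = false;
      } else {
        int base = 0; // atoms are residue-major within pep_atoms
        int aN = s.pep_atoms[4 * piv_res + 0];
        int aCA = s.pep_atoms[4 * piv_res + 1];
        int aC = s.pep_atoms[4 * piv_res + 2];
        int aCB = s.pep_atoms[4 * piv_res + 3];
        (void)base;
        double ang = norm_rand() * p.s_pivot * M_PI / 180.0;
        double piv_pt[3], ax[3];
        if (piv_is_phi) {
          for (int k = 0; k < 3; ++k) {
            piv_pt[k] = s.X[3 * aN + k];
            ax[k] = s.X[3 * aCA + k] - s.X[3 * aN + k];
          }
          moved.push_back(aC);
          moved.push_back(aCB);
          for (int r = piv_res + 1; r < nres; ++r)
            for (int k = 0; k < 4; ++k) moved.push_back(s.pep_atoms[4 * r + k]);
        } else {
          for (int k = 0; k < 3; ++k) {
            piv_pt[k] = s.X[3 * aCA + k];
            ax[k] = s.X[3 * aC + k] - s.X[3 * aCA + k];
          }
          for (int r = piv_res + 1; r < nres; ++r)
            for (int k = 0; k < 4; ++k) moved.push_back(s.pep_atoms[4 * r + k]);
        }
        double R[3][3];
        rot_matrix(ax[0], ax[1], ax[2], ang, R);
        apply_rot(Xnew, moved, R, piv_pt);
        // recompute the changed dihedral from new coordinates
        if (piv_is_phi) {
          int pC = s.pep_atoms[4 * (piv_res - 1) + 2];
          d_phi_new = dihedral_deg(Xnew, pC, aN, aCA, aC);
        } else {
          int nN = s.pep_atoms[4 * (piv_res + 1) + 0];
          d_phi_new = dihedral_deg(Xnew, aN, aCA, aC, nN);
        }
      }
    } else {                                   // receptor residue jiggle
      std::vector<int> rec_res;
      for (size_t r = 0; r < s.res_atoms.size(); ++r) {
        if (!s.res_atoms[r].empty() && s.chain[s.res_atoms[r][0]] != 2)
          rec_res.push_back((int)r);
      }
      if (rec_res.empty()) feasible = false;
      else {
        int rr = rec_res[(int)(unif_rand() * rec_res.size()) % rec_res.size()];
        moved = s.res_atoms[rr];
        double dx = norm_rand() * p.s_rec, dy = norm_rand() * p.s_rec,
               dz = norm_rand() * p.s_rec;
        for (int a : moved) {
          Xnew[3 * a] += dx; Xnew[3 * a + 1] += dy; Xnew[3 * a + 2] += dz;
        }
        if (unif_rand() < 0.5) {               // small rotation about its CA
          // CA is the second bead (order N, CA, C, CB)
          int aCA = moved.size() >= 2 ? moved[1] : moved[0];
          double piv_pt[3] = {Xnew[3 * aCA], Xnew[3 * aCA + 1], Xnew[3 * aCA + 2]};
          double R[3][3];
          rot_matrix(norm_rand(), norm_rand(), norm_rand(),
                     norm_rand() * p.s_rec_rot, R);
          apply_rot(Xnew, moved, R, piv_pt);
        }
      }
    }

    if (feasible) {
      for (int a : moved) in_moved[a] = 1;
      Ecomp de;
      long fl = 0;
      double ev_o = 0, co_o = 0, ev_n = 0, co_n = 0;
      bool all_far = false;
      if (mv <= 3 && !rec_atoms.empty()) {
        all_far = true;
        double lim = skip_gap + rec_rad;
        double lim2 = lim * lim;
        for (int a : moved) {
          double d2o = 0, d2n = 0;
          for (int k = 0; k < 3; ++k) {
            double dd = mimg(s.X[3 * a + k] - rec_c[k], s.box);
            d2o += dd * dd;
            dd = mimg(Xnew[3 * a + k] - rec_c[k], s.box);
            d2n += dd * dd;
          }
          if (d2o <= lim2 || d2n <= lim2) { all_far = false; break; }
        }
      }
      double ev_lim = std::sqrt(p.sigma2) + rec_rad;
      double ev_lim2 = ev_lim * ev_lim;
      for (int a : moved) {
        // peptide-peptide part (all non-moved peptide atoms)
        for (int b : pep_all) {
          if (in_moved[b] || b == a) continue;
          pair_energy(s, p, s.X, a, b, ev_o, co_o, fl);
          pair_energy(s, p, Xnew, a, b, ev_n, co_n, fl);
        }
        // peptide-receptor part. A moved peptide atom lying outside the
        // receptor sphere plus the excluded-volume range can only touch
        // charged receptor atoms (exact: EV terms are all zero there).
        if (s.chain[a] == 2) {
          if (!all_far && !rec_atoms.empty()) {
            double d2o = 0, d2n = 0;
            for (int k = 0; k < 3; ++k) {
              double dd = mimg(s.X[3 * a + k] - rec_c[k], s.box);
              d2o += dd * dd;
              dd = mimg(Xnew[3 * a + k] - rec_c[k], s.box);
              d2n += dd * dd;
            }
            const std::vector<int> &rlist =
                (d2o > ev_lim2 && d2n > ev_lim2) ? rec_charged : rec_atoms;
            for (int b : rlist) {
              pair_energy(s, p, s.X, a, b, ev_o, co_o, fl);
              pair_energy(s, p, Xnew, a, b, ev_n, co_n, fl);
            }
          }
        } else {
          for (int b : rec_atoms) {
            if (in_moved[b]) continue;
            pair_energy(s, p, s.X, a, b, ev_o, co_o, fl);
            pair_energy(s, p, Xnew, a, b, ev_n, co_n, fl);
          }
        }
        de.restr += restraint_one(s, p, Xnew, a) - restraint_one(s, p, s.X, a);
      }
      de.ev = ev_n - ev_o;
      de.coul = co_n - co_o;
      std::vector<char> done(s.go_i.size(), 0);
      for (int a : moved) {
        if (all_far) break;
        for (int k : s.go_of_atom[a]) {
          if (done[k]) continue;
          done[k] = 1;
          double w = s.go_w[k] > 0 ? s.go_w[k] : p.go_w;
          double ro = std::sqrt(godist2(s, s.X, k));
          double rn = std::sqrt(godist2(s, Xnew, k));
          double dodo = ro - s.go_r0[k], dn = rn - s.go_r0[k];
          double eo = std::fabs(dodo) > 6.0 * w ? 0.0 :
              std::exp(-dodo * dodo / (2 * w * w));
          double en = std::fabs(dn) > 6.0 * w ? 0.0 :
              std::exp(-dn * dn / (2 * w * w));
          de.go += -p.eps_go * s.go_d[k] * (en - eo);
        }
      }
      double old_h = 0, new_h = 0;
      if (piv_res >= 0) {
        old_h = helix_energy_res(s, p, piv_res);
        double keep = piv_is_phi ? s.phi[piv_res] : s.psi[piv_res];
        if (piv_is_phi) s.phi[piv_res] = d_phi_new; else s.psi[piv_res] = d_phi_new;
        new_h = helix_energy_res(s, p, piv_res);
        if (piv_is_phi) s.phi[piv_res] = keep; else s.psi[piv_res] = keep;
        de.helix = new_h - old_h;
      }
      double dE = de.total();
      bool ok = dE <= 0 || unif_rand() < std::exp(-dE / temperature);
      if (ok) {
        for (int a : moved)
          for (int k = 0; k < 3; ++k) s.X[3 * a + k] = Xnew[3 * a + k];
        if (piv_res >= 0) {
          if (piv_is_phi) s.phi[piv_res] = d_phi_new;
          else s.psi[piv_res] = d_phi_new;
        }
        e.ev += de.ev; e.coul += de.coul; e.go += de.go;
        e.helix += de.helix; e.restr += de.restr;
        ++acc[mv];
        // wrap peptide back into the primary box after rigid moves
        if (s.box > 0 && mv <= 2) {
          double c[3] = {0, 0, 0};
          for (int a : s.pep_atoms)
            for (int k = 0; k < 3; ++k) c[k] += s.X[3 * a + k];
          for (int k = 0; k < 3; ++k) c[k] /= s.pep_atoms.size();
          double sh[3];
          bool any = false;
          for (int k = 0; k < 3; ++k) {
            sh[k] = -s.box * std::floor(c[k] / s.box);
            if (sh[k] != 0) any = true;
          }
          if (any)
            for (int a : s.pep_atoms)
              for (int k = 0; k < 3; ++k) s.X[3 * a + k] += sh[k];
        }
      }
      for (int a : moved) in_moved[a] = 0;
    }

    if (energy_check_interval > 0 && step % energy_check_interval == 0) {
      long keep_flags = s.overlap_flags;
      update_rec_sphere();
      Ecomp ref = full_energy(s, p);
      s.overlap_flags = keep_flags;
      if (std::fabs(ref.total() - e.total()) >
          1e-8 * std::max(1.0, std::fabs(ref.total()))) {
        stop("cached energy diverged from recomputed energy");
      }
      e = ref;
    }

    if (step % save_interval == 0 && save_ptr < n_save) {
      for (int i = 0; i < s.n; ++i)
        for (int k = 0; k < 3; ++k)
          frames[(R_xlen_t)save_ptr * s.n * 3 + (R_xlen_t)k * s.n + i] =
              s.X[3 * i + k];
      etab(save_ptr, 0) = e.ev;
      etab(save_ptr, 1) = e.coul;
      etab(save_ptr, 2) = e.go;
      etab(save_ptr, 3) = e.helix;
      etab(save_ptr, 4) = e.restr;
      etab(save_ptr, 5) = e.total();
      ++save_ptr;
    }
  }

  frames.attr("dim") = IntegerVector::create(s.n, 3, n_save);
  NumericMatrix final_coords(s.n, 3);
  for (int i = 0; i < s.n; ++i)
    for (int k = 0; k < 3; ++k) final_coords(i, k) = s.X[3 * i + k];
  colnames(etab) = CharacterVector::create("ev", "coulomb", "go", "helix",
                                           "restraint", "total");
  return List::create(_["frames"] = frames, _["energies"] = etab,
                      _["final_coords"] = final_coords,
                      _["phi"] = s.phi, _["psi"] = s.psi,
                      _["proposed"] = prop, _["accepted"] = acc,
                      _["overlap_flags"] = (double)s.overlap_flags);
}

// [[Rcpp::export(name = ".mc_energy_cpp")]]
List mc_energy_cpp(List sys, List params) {
  Sys s = build_sys(sys);
  Par p = build_par(params, 1.0);
  Ecomp e = full_energy(s, p);
  return List::create(_["ev"] = e.ev, _["coulomb"] = e.coul, _["go"] = e.go,
                      _["helix"] = e.helix, _["restraint"] = e.restr,
                      _["total"] = e.total(),
                      _["overlap_flags"] = (double)s.overlap_flags);
}

// Metropolis chain on a discrete state space with uniform proposals.
// [[Rcpp::export(name = ".metropolis_discrete_cpp")]]
List metropolis_discrete_cpp(NumericVector energies, double temperature,
                             int n_steps, int init, int thin) {
  RNGScope scope;
  int m = energies.size();
  int cur = init;
  std::vector<double> counts(m, 0.0);
  for (int t = 1; t <= n_steps; ++t) {
    int prop = (int)(unif_rand() * m) % m;
    double dE = energies[prop] - energies[cur];
    if (dE <= 0 || unif_rand() < std::exp(-dE / temperature)) cur = prop;
    if (t % thin == 0) counts[cur] += 1.0;
  }
  return List::create(_["counts"] = NumericVector(counts.begin(), counts.end()),
                      _["final_state"] = cur);
}
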