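// CHARMM-form vacuum potential for small molecules: bonds, angles,
// Urey-Bradley, proper dihedrals (periodic), impropers (harmonic),
// Lennard-Jones (Rmin form) + Coulomb over an explicit pair list, and
// harmonic dihedral restraints.  Energies in kcal/mol, lengths in Angstrom,
// angles passed in degrees.  Analytic gradients for all terms.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double DEG = M_PI / 180.0;
static const double COULOMB = 332.0716;  // kcal*Angstrom/(mol*e^2)

struct V3 {
  double x, y, z;
  V3() : x(0), y(0), z(0) {}
  V3(double x_, double y_, double z_) : x(x_), y(y_), z(z_) {}
};
static inline V3 operator-(const V3 &a, const V3 &b) {
  return V3(a.x - b.x, a.y - b.y, a.z - b.z);
}
static inline V3 operator+(const V3 &a, const V3 &b) {
  return V3(a.x + b.x, a.y + b.y, a.z + b.z);
}
static inline V3 operator*(double s, const V3 &a) {
  return V3(s * a.x, s * a.y, s * a.z);
}
static inline double dot(const V3 &a, const V3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline V3 cross(const V3 &a, const V3 &b) {
  return V3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
            a.x * b.y - a.y * b.x);
}
static inline double norm(const V3 &a) { return std::sqrt(dot(a, a)); }

static inline V3 row(const NumericMatrix &m, int i) {
  return V3(m(i, 0), m(i, 1), m(i, 2));
}
static inline void add_row(NumericMatrix &g, int i, const V3 &v) {
  g(i, 0) += v.x; g(i, 1) += v.y; g(i, 2) += v.z;
}

// wrap to (-pi, pi]
static inline double wrap_rad(double x) {
  x -= 2.0 * M_PI * std::floor((x + M_PI) / (2.0 * M_PI));
  if (x <= -M_PI) x += 2.0 * M_PI;   // guard the open boundary
  return x;
}

// dihedral angle (radians) and its gradient wrt the four atoms
static double dihedral_and_grad(const V3 &r1, const V3 &r2, const V3 &r3,
                                const V3 &r4, V3 g[4], bool want_grad) {
  V3 b1 = r2 - r1, b2 = r3 - r2, b3 = r4 - r3;
  V3 m = cross(b1, b2), n = cross(b2, b3);
  double lb2 = norm(b2);
  double x = dot(m, n);
  double y = dot(cross(m, n), b2) / lb2;
  double phi = std::atan2(y, x);
  if (want_grad) {
    double m2 = dot(m, m), n2 = dot(n, n);
    V3 dp1 = (-lb2 / m2) * m;
    V3 dp4 = (lb2 / n2) * n;
    double p = dot(b1, b2) / (lb2 * lb2);
    double q = dot(b3, b2) / (lb2 * lb2);
    V3 dp2 = (-1.0 - p) * dp1 + q * dp4;
    V3 dp3 = (-1.0) * (dp1 + dp2 + dp4);
    g[0] = dp1; g[1] = dp2; g[2] = dp3; g[3] = dp4;
  }
  return phi;
}

// [[Rcpp::export(name = "cpp_dihedral_angles")]]
NumericVector cpp_dihedral_angles(NumericMatrix coords, IntegerMatrix quads) {
  int nq = quads.nrow();
  NumericVector out(nq);
  V3 g[4];
  for (int q = 0; q < nq; ++q) {
    double phi = dihedral_and_grad(row(coords, quads(q, 0) - 1),
                                   row(coords, quads(q, 1) - 1),
                                   row(coords, quads(q, 2) - 1),
                                   row(coords, quads(q, 3) - 1), g, false);
    out[q] = phi / DEG;
  }
  return out;
}

// [[Rcpp::export(name = "cpp_energy")]]
List cpp_energy(NumericMatrix coords,
                IntegerMatrix bonds, NumericVector bond_kb,
                NumericVector bond_b0,
                IntegerMatrix angles, NumericVector ang_k,
                NumericVector ang_th0,
                IntegerMatrix ubs, NumericVector ub_k, NumericVector ub_s0,
                IntegerMatrix dihs, NumericVector dih_k,
                IntegerVector dih_n, NumericVector dih_chi0,
                IntegerMatrix imps, NumericVector imp_k,
                NumericVector imp_chi0,
                IntegerMatrix pairs, NumericVector nb_eps,
                NumericVector nb_rmin, NumericVector nb_qq,
                IntegerMatrix rests, NumericVector rest_k,
                NumericVector rest_target,
                bool want_grad, double r_floor) {
  int n = coords.nrow();
  NumericMatrix grad(n, 3);
  double e_bond = 0, e_angle = 0, e_ub = 0, e_dih = 0, e_imp = 0,
         e_lj = 0, e_el = 0, e_rest = 0;
  bool overlap = false;

  for (int k = 0; k < bonds.nrow(); ++k) {
    int i = bonds(k, 0) - 1, j = bonds(k, 1) - 1;
    V3 d = row(coords, i) - row(coords, j);
    double b = norm(d);
    double db = b - bond_b0[k];
    e_bond += bond_kb[k] * db * db;           // CHARMM: no 1/2 factor
    if (want_grad) {
      V3 f = (2.0 * bond_kb[k] * db / b) * d;
      add_row(grad, i, f);
      add_row(grad, j, (-1.0) * f);
    }
  }

  for (int k = 0; k < angles.nrow(); ++k) {
    int i = angles(k, 0) - 1, j = angles(k, 1) - 1, l = angles(k, 2) - 1;
    V3 u = row(coords, i) - row(coords, j);
    V3 v = row(coords, l) - row(coords, j);
    double lu = norm(u), lv = norm(v);
    double c = dot(u, v) / (lu * lv);
    if (c > 1.0) c = 1.0;
    if (c < -1.0) c = -1.0;
    double th = std::acos(c);
    double dth = th - ang_th0[k] * DEG;
    e_angle += ang_k[k] * dth * dth;
    if (want_grad) {
      double s = std::sqrt(1.0 - c * c);
      if (s < 1e-8) s = 1e-8;
      V3 uh = (1.0 / lu) * u, vh = (1.0 / lv) * v;
      V3 di = (1.0 / (lu * s)) * (c * uh - vh);
      V3 dl = (1.0 / (lv * s)) * (c * vh - uh);
      double coef = 2.0 * ang_k[k] * dth;
      add_row(grad, i, coef * di);
      add_row(grad, l, coef * dl);
      add_row(grad, j, (-coef) * (di + dl));
    }
  }

  for (int k = 0; k < ubs.nrow(); ++k) {
    int i = ubs(k, 0) - 1, j = ubs(k, 1) - 1;
    V3 d = row(coords, i) - row(coords, j);
    double s = norm(d);
    double ds = s - ub_s0[k];
    e_ub += ub_k[k] * ds * ds;
    if (want_grad) {
      V3 f = (2.0 * ub_k[k] * ds / s) * d;
      add_row(grad, i, f);
      add_row(grad, j, (-1.0) * f);
    }
  }

  V3 g[4];
  for (int k = 0; k < dihs.nrow(); ++k) {
    double phi = dihedral_and_grad(row(coords, dihs(k, 0) - 1),
                                   row(coords, dihs(k, 1) - 1),
                                   row(coords, dihs(k, 2) - 1),
                                   row(coords, dihs(k, 3) - 1), g, want_grad);
    double arg = dih_n[k] * phi - dih_chi0[k] * DEG;
    e_dih += dih_k[k] * (1.0 + std::cos(arg));
    if (want_grad) {
      double coef = -dih_k[k] * dih_n[k] * std::sin(arg);
      for (int a = 0; a < 4; ++a) add_row(grad, dihs(k, a) - 1, coef * g[a]);
    }
  }

  for (int k = 0; k < imps.nrow(); ++k) {
    double phi = dihedral_and_grad(row(coords, imps(k, 0) - 1),
                                   row(coords, imps(k, 1) - 1),
                                   row(coords, imps(k, 2) - 1),
                                   row(coords, imps(k, 3) - 1), g, want_grad);
    double dphi = wrap_rad(phi - imp_chi0[k] * DEG);
    e_imp += imp_k[k] * dphi * dphi;
    if (want_grad) {
      double coef = 2.0 * imp_k[k] * dphi;
      for (int a = 0; a < 4; ++a) add_row(grad, imps(k, a) - 1, coef * g[a]);
    }
  }

  for (int k = 0; k < pairs.nrow(); ++k) {
    int i = pairs(k, 0) - 1, j = pairs(k, 1) - 1;
    V3 d = row(coords, i) - row(coords, j);
    double r = norm(d);
    if (r < r_floor) { overlap = true; continue; }
    double sr = nb_rmin[k] / r;
    double sr6 = sr * sr * sr; sr6 *= sr6;
    double sr12 = sr6 * sr6;
    e_lj += nb_eps[k] * (sr12 - 2.0 * sr6);
    e_el += nb_qq[k] / r;
    if (want_grad) {
      double dedr = nb_eps[k] * (-12.0 * sr12 + 12.0 * sr6) / r
                    - nb_qq[k] / (r * r);
      V3 f = (dedr / r) * d;
      add_row(grad, i, f);
      add_row(grad, j, (-1.0) * f);
    }
  }

  for (int k = 0; k < rests.nrow(); ++k) {
    double phi = dihedral_and_grad(row(coords, rests(k, 0) - 1),
                                   row(coords, rests(k, 1) - 1),
                                   row(coords, rests(k, 2) - 1),
                                   row(coords, rests(k, 3) - 1), g, want_grad);
    double dphi = wrap_rad(phi - rest_target[k] * DEG);
    e_rest += rest_k[k] * dphi * dphi;
    if (want_grad) {
      double coef = 2.0 * rest_k[k] * dphi;
      for (int a = 0; a < 4; ++a) add_row(grad, rests(k, a) - 1, coef * g[a]);
    }
  }

  double total = e_bond + e_angle + e_ub + e_dih + e_imp + e_lj + e_el +
                 e_rest;
  List out = List::create(
      _["total"] = total,
      _["breakdown"] = NumericVector::create(
          _["bond"] = e_bond, _["angle"] = e_angle, _["urey_bradley"] = e_ub,
          _["dihedral"] = e_dih, _["improper"] = e_imp, _["lj"] = e_lj,
          _["elec"] = e_el, _["restraint"] = e_rest),
      _["overlap"] = overlap);
  if (want_grad) out["gradient"] = grad;
  return out;
}

// NeRF construction of Cartesian coordinates from internal coordinates.
// build rows: atom, ref1, ref2, ref3 (1-based, 0 = none), bond, angle
// (deg), torsion: fixed value or vars[tvar] + toffset (tvar 1-based,
// 0 = fixed).
// [[Rcpp::export(name = "cpp_build_coords")]]
NumericMatrix cpp_build_coords(int n_atoms, IntegerVector atom,
                               IntegerVector ref1, IntegerVector ref2,
                               IntegerVector ref3, NumericVector bond,
                               NumericVector angle, IntegerVector tvar,
                               NumericVector tfixed, NumericVector toffset,
                               NumericVector vars) {
  NumericMatrix xyz(n_atoms, 3);
  int nb = atom.size();
  for (int r = 0; r < nb; ++r) {
    int ai = atom[r] - 1;
    if (ref1[r] == 0) {
      xyz(ai, 0) = xyz(ai, 1) = xyz(ai, 2) = 0.0;
    } else if (ref2[r] == 0) {
      int a = ref1[r] - 1;
      xyz(ai, 0) = xyz(a, 0) + bond[r];
      xyz(ai, 1) = xyz(a, 1);
      xyz(ai, 2) = xyz(a, 2);
    } else if (ref3[r] == 0) {
      V3 a = row(xyz, ref1[r] - 1), b = row(xyz, ref2[r] - 1);
      V3 u = b - a;
      double lu = norm(u);
      u = (1.0 / lu) * u;
      V3 perp(-u.y, u.x, 0.0);
      double lp = norm(perp);
      perp = (1.0 / lp) * perp;
      double th = angle[r] * DEG;
      V3 d = a + bond[r] * (std::cos(th) * u + std::sin(th) * perp);
      xyz(ai, 0) = d.x; xyz(ai, 1) = d.y; xyz(ai, 2) = d.z;
    } else {
      double tor = (tvar[r] > 0) ? vars[tvar[r] - 1] + toffset[r]
                                 : tfixed[r];
      V3 a = row(xyz, ref1[r] - 1), b = row(xyz, ref2[r] - 1),
         c = row(xyz, ref3[r] - 1);
      double th = angle[r] * DEG;
      double ph = -tor * DEG;
      V3 ab = b - a;
      V3 bhat = (1.0 / norm(ab)) * ab;
      V3 nrm = cross(b - c, bhat);
      V3 nhat = (1.0 / norm(nrm)) * nrm;
      V3 mhat = cross(nhat, bhat);
      V3 d = a + bond[r] * (std::cos(th) * bhat +
                            std::sin(th) * std::cos(ph) * mhat +
                            std::sin(th) * std::sin(ph) * nhat);
      xyz(ai, 0) = d.x; xyz(ai, 1) = d.y; xyz(ai, 2) = d.z;
    }
  }
  return xyz;
}
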