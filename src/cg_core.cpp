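// Core numerics for the coarse-grained model: potential energy and forces,
// BAOAB Langevin dynamics, Debye scattering sums and pair-distance histograms.
// Energies are in units of kBT at 300 K, lengths in Angstrom, bead mass 1,
// time in reduced units.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <cstdint>
#include <random>

using namespace Rcpp;

// --- deterministic RNG (explicit Box-Muller over mt19937_64 so that streams
// --- are bitwise reproducible across standard-library implementations)
struct Rng {
  std::mt19937_64 eng;
  bool have_spare = false;
  double spare = 0.0;
  explicit Rng(uint64_t seed) : eng(seed) {}
  double unif() {
    // 53-bit uniform in (0,1)
    return ((eng() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u, v, s;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s = u * u + v * v;
    } while (s >= 1.0 || s == 0.0);
    double m = std::sqrt(-2.0 * std::log(s) / s);
    spare = v * m; have_spare = true;
    return u * m;
  }
};

struct Topo {
  NumericMatrix bonds;      // i j r0 k
  NumericMatrix angles;     // i j k th0 kth
  NumericMatrix dihedrals;  // i j k l phi0 kphi
  NumericMatrix contacts;   // i j r0 eps
  NumericMatrix hydro;      // i j   (pair list)
  NumericVector charges;    // length N
  std::vector<int64_t> excl; // sorted keys (i-1)*N + (j-1), i<j, excluded from EV
};

struct Pars {
  double kT, ev_eps, ev_sigma, ev_cut, lB, lambdaD, elec_cut;
  double hydro_eps, hydro_r0;
  bool use_contacts, use_ev, use_elec, use_hydro;
  // optional COM-distance restraint
  bool restraint = false;
  std::vector<int> grpA, grpB;
  double res_k = 0.0, res_d0 = 0.0;
};

static Topo unpack_topo(const List& topo, int n) {
  Topo t;
  t.bonds = as<NumericMatrix>(topo["bonds"]);
  t.angles = as<NumericMatrix>(topo["angles"]);
  t.dihedrals = as<NumericMatrix>(topo["dihedrals"]);
  t.contacts = as<NumericMatrix>(topo["contacts"]);
  t.hydro = as<NumericMatrix>(topo["hydro"]);
  t.charges = as<NumericVector>(topo["charges"]);
  NumericVector ex = as<NumericVector>(topo["excl_keys"]);
  t.excl.resize(ex.size());
  for (int i = 0; i < ex.size(); ++i) t.excl[i] = (int64_t) ex[i];
  std::sort(t.excl.begin(), t.excl.end());
  if ((int) t.charges.size() != n) stop("charge vector length mismatch");
  return t;
}

static Pars unpack_pars(const List& p) {
  Pars q;
  q.kT = as<double>(p["kT"]);
  q.ev_eps = as<double>(p["ev_eps"]);
  q.ev_sigma = as<double>(p["ev_sigma"]);
  q.ev_cut = as<double>(p["ev_cut"]);
  q.lB = as<double>(p["lB"]);
  q.lambdaD = as<double>(p["lambdaD"]);
  q.elec_cut = as<double>(p["elec_cut"]);
  q.hydro_eps = as<double>(p["hydro_eps"]);
  q.hydro_r0 = as<double>(p["hydro_r0"]);
  q.use_contacts = as<bool>(p["use_contacts"]);
  q.use_ev = as<bool>(p["use_ev"]);
  q.use_elec = as<bool>(p["use_elec"]);
  q.use_hydro = as<bool>(p["use_hydro"]);
  if (p.containsElementNamed("restraint") && !Rf_isNull(p["restraint"])) {
    List r = as<List>(p["restraint"]);
    q.restraint = true;
    IntegerVector a = as<IntegerVector>(r["group_a"]);
    IntegerVector b = as<IntegerVector>(r["group_b"]);
    for (int i = 0; i < a.size(); ++i) q.grpA.push_back(a[i] - 1);
    for (int i = 0; i < b.size(); ++i) q.grpB.push_back(b[i] - 1);
    q.res_k = as<double>(r["k"]);
    q.res_d0 = as<double>(r["target"]);
  }
  return q;
}

static inline bool excluded(const std::vector<int64_t>& excl, int i, int j, int n) {
  int64_t key = (int64_t) i * n + j;
  return std::binary_search(excl.begin(), excl.end(), key);
}

// energy components and (optionally) forces; coords is n x 3
static NumericVector eval_model(const NumericMatrix& x, const Topo& t, const Pars& p,
                                NumericMatrix* F) {
  const int n = x.nrow();
  double e_bond = 0, e_angle = 0, e_dihedral = 0, e_contact = 0,
         e_ev = 0, e_elec = 0, e_hydro = 0, e_restraint = 0;

  auto addf = [&](int i, double fx, double fy, double fz) {
    if (F) { (*F)(i, 0) += fx; (*F)(i, 1) += fy; (*F)(i, 2) += fz; }
  };

  // bonds: k (r - r0)^2
  for (int b = 0; b < t.bonds.nrow(); ++b) {
    int i = (int) t.bonds(b, 0) - 1, j = (int) t.bonds(b, 1) - 1;
    double r0 = t.bonds(b, 2), k = t.bonds(b, 3);
    double dx = x(i,0)-x(j,0), dy = x(i,1)-x(j,1), dz = x(i,2)-x(j,2);
    double r = std::sqrt(dx*dx + dy*dy + dz*dz);
    if (r <= 0) stop("overlapping bonded beads (r = 0)");
    double dr = r - r0;
    e_bond += k * dr * dr;
    double c = -2.0 * k * dr / r;   // force magnitude / r on i along (i-j)
    addf(i,  c*dx,  c*dy,  c*dz);
    addf(j, -c*dx, -c*dy, -c*dz);
  }

  // angles: k (theta - theta0)^2
  for (int a = 0; a < t.angles.nrow(); ++a) {
    int i = (int) t.angles(a,0) - 1, j = (int) t.angles(a,1) - 1, k = (int) t.angles(a,2) - 1;
    double th0 = t.angles(a,3), kth = t.angles(a,4);
    double r1x = x(i,0)-x(j,0), r1y = x(i,1)-x(j,1), r1z = x(i,2)-x(j,2);
    double r2x = x(k,0)-x(j,0), r2y = x(k,1)-x(j,1), r2z = x(k,2)-x(j,2);
    double n1 = std::sqrt(r1x*r1x + r1y*r1y + r1z*r1z);
    double n2 = std::sqrt(r2x*r2x + r2y*r2y + r2z*r2z);
    if (n1 <= 0 || n2 <= 0) stop("degenerate angle (zero-length arm)");
    double cth = (r1x*r2x + r1y*r2y + r1z*r2z) / (n1 * n2);
    cth = std::max(-1.0, std::min(1.0, cth));
    double th = std::acos(cth);
    double dth = th - th0;
    e_angle += kth * dth * dth;
    if (F) {
      double sth = std::sqrt(std::max(1e-12, 1.0 - cth * cth));
      double coef = -2.0 * kth * dth;            // dV/dtheta * (-1)
      // gradient of theta wrt endpoints
      double gix = (r1x / n1 * cth - r2x / n2) / (n1 * sth);
      double giy = (r1y / n1 * cth - r2y / n2) / (n1 * sth);
      double giz = (r1z / n1 * cth - r2z / n2) / (n1 * sth);
      double gkx = (r2x / n2 * cth - r1x / n1) / (n2 * sth);
      double gky = (r2y / n2 * cth - r1y / n1) / (n2 * sth);
      double gkz = (r2z / n2 * cth - r1z / n1) / (n2 * sth);
      addf(i, coef * gix, coef * giy, coef * giz);
      addf(k, coef * gkx, coef * gky, coef * gkz);
      addf(j, -coef * (gix + gkx), -coef * (giy + gky), -coef * (giz + gkz));
    }
  }

  // dihedrals: k [1 - cos(phi - phi0)] + (k/2) [1 - cos 3(phi - phi0)]
  for (int d = 0; d < t.dihedrals.nrow(); ++d) {
    int i = (int) t.dihedrals(d,0) - 1, j = (int) t.dihedrals(d,1) - 1,
        k = (int) t.dihedrals(d,2) - 1, l = (int) t.dihedrals(d,3) - 1;
    double phi0 = t.dihedrals(d,4), kphi = t.dihedrals(d,5);
    double b1x = x(j,0)-x(i,0), b1y = x(j,1)-x(i,1), b1z = x(j,2)-x(i,2);
    double b2x = x(k,0)-x(j,0), b2y = x(k,1)-x(j,1), b2z = x(k,2)-x(j,2);
    double b3x = x(l,0)-x(k,0), b3y = x(l,1)-x(k,1), b3z = x(l,2)-x(k,2);
    double n1x = b1y*b2z - b1z*b2y, n1y = b1z*b2x - b1x*b2z, n1z = b1x*b2y - b1y*b2x;
    double n2x = b2y*b3z - b2z*b3y, n2y = b2z*b3x - b2x*b3z, n2z = b2x*b3y - b2y*b3x;
    double n1sq = n1x*n1x + n1y*n1y + n1z*n1z;
    double n2sq = n2x*n2x + n2y*n2y + n2z*n2z;
    double b2n = std::sqrt(b2x*b2x + b2y*b2y + b2z*b2z);
    if (b2n <= 0) stop("degenerate dihedral (coincident beads)");
    if (n1sq <= 1e-10 || n2sq <= 1e-10) continue;  // transiently collinear
    double sphi = b2n * (b1x*n2x + b1y*n2y + b1z*n2z);
    double cphi = n1x*n2x + n1y*n2y + n1z*n2z;
    double phi = std::atan2(sphi, cphi);
    double dphi = phi - phi0;
    e_dihedral += kphi * (1.0 - std::cos(dphi)) + 0.5 * kphi * (1.0 - std::cos(3.0 * dphi));
    if (F) {
      double dVdphi = kphi * std::sin(dphi) + 1.5 * kphi * std::sin(3.0 * dphi);
      // standard analytic dihedral derivatives
      double fix =  dVdphi * b2n / n1sq * n1x;
      double fiy =  dVdphi * b2n / n1sq * n1y;
      double fiz =  dVdphi * b2n / n1sq * n1z;
      double flx = -dVdphi * b2n / n2sq * n2x;
      double fly = -dVdphi * b2n / n2sq * n2y;
      double flz = -dVdphi * b2n / n2sq * n2z;
      double b1b2 = b1x*b2x + b1y*b2y + b1z*b2z;
      double b3b2 = b3x*b2x + b3y*b2y + b3z*b2z;
      double tx = (b3b2 * flx - b1b2 * fix) / (b2n * b2n);
      double ty = (b3b2 * fly - b1b2 * fiy) / (b2n * b2n);
      double tz = (b3b2 * flz - b1b2 * fiz) / (b2n * b2n);
      addf(i, fix, fiy, fiz);
      addf(j, -fix + tx, -fiy + ty, -fiz + tz);
      addf(k, -flx - tx, -fly - ty, -flz - tz);
      addf(l, flx, fly, flz);
    }
  }

  // native contacts, 12-10: eps [5 (r0/r)^12 - 6 (r0/r)^10]
  if (p.use_contacts) {
    for (int c = 0; c < t.contacts.nrow(); ++c) {
      int i = (int) t.contacts(c,0) - 1, j = (int) t.contacts(c,1) - 1;
      double r0 = t.contacts(c,2), eps = t.contacts(c,3);
      double dx = x(i,0)-x(j,0), dy = x(i,1)-x(j,1), dz = x(i,2)-x(j,2);
      double r = std::sqrt(dx*dx + dy*dy + dz*dz);
      if (r <= 0) stop("overlapping contact beads (r = 0)");
      double s = r0 / r;
      double s10 = std::pow(s, 10), s12 = s10 * s * s;
      e_contact += eps * (5.0 * s12 - 6.0 * s10);
      double dVdr = eps * (-60.0 * s12 + 60.0 * s10) / r;
      double cc = -dVdr / r;
      addf(i,  cc*dx,  cc*dy,  cc*dz);
      addf(j, -cc*dx, -cc*dy, -cc*dz);
    }
  }

  // excluded volume: eps [(sigma/r)^12 - (sigma/rc)^12] for r < rc,
  // all pairs |i-j| >= 4 not on the exclusion list (1-2/1-3/1-4 pairs are
  // governed by the bonded terms)
  if (p.use_ev) {
    double rc = p.ev_cut, rc2 = rc * rc;
    double shift = std::pow(p.ev_sigma / rc, 12);
    for (int i = 0; i < n; ++i) {
      for (int j = i + 4; j < n; ++j) {
        double dx = x(i,0)-x(j,0), dy = x(i,1)-x(j,1), dz = x(i,2)-x(j,2);
        double r2 = dx*dx + dy*dy + dz*dz;
        if (r2 >= rc2) continue;
        if (excluded(t.excl, i, j, n)) continue;
        if (r2 <= 0) stop("overlapping beads (r = 0)");
        double r = std::sqrt(r2);
        double s12 = std::pow(p.ev_sigma / r, 12);
        e_ev += p.ev_eps * (s12 - shift);
        double dVdr = -12.0 * p.ev_eps * s12 / r;
        double cc = -dVdr / r;
        addf(i,  cc*dx,  cc*dy,  cc*dz);
        addf(j, -cc*dx, -cc*dy, -cc*dz);
      }
    }
  }

  // Debye-Hueckel electrostatics between charged beads, |i-j| >= 3
  if (p.use_elec) {
    std::vector<int> ch;
    for (int i = 0; i < n; ++i) if (t.charges[i] != 0.0) ch.push_back(i);
    double rc = p.elec_cut;
    for (size_t a = 0; a < ch.size(); ++a) {
      for (size_t b = a + 1; b < ch.size(); ++b) {
        int i = ch[a], j = ch[b];
        if (std::abs(i - j) < 3) continue;
        double dx = x(i,0)-x(j,0), dy = x(i,1)-x(j,1), dz = x(i,2)-x(j,2);
        double r = std::sqrt(dx*dx + dy*dy + dz*dz);
        if (r >= rc) continue;
        if (r <= 0) stop("overlapping charged beads (r = 0)");
        double qq = t.charges[i] * t.charges[j];
        double u = p.lB * qq * std::exp(-r / p.lambdaD) / r;
        double u_rc = p.lB * qq * std::exp(-rc / p.lambdaD) / rc;
        e_elec += u - u_rc;
        double dVdr = -u * (1.0 / r + 1.0 / p.lambdaD);
        double cc = -dVdr / r;
        addf(i,  cc*dx,  cc*dy,  cc*dz);
        addf(j, -cc*dx, -cc*dy, -cc*dz);
      }
    }
  }

  // optional short-range hydrophobic well (12-10 at hydro_r0, depth hydro_eps)
  if (p.use_hydro) {
    for (int c = 0; c < t.hydro.nrow(); ++c) {
      int i = (int) t.hydro(c,0) - 1, j = (int) t.hydro(c,1) - 1;
      double dx = x(i,0)-x(j,0), dy = x(i,1)-x(j,1), dz = x(i,2)-x(j,2);
      double r = std::sqrt(dx*dx + dy*dy + dz*dz);
      if (r <= 0) stop("overlapping beads (r = 0)");
      double s = p.hydro_r0 / r;
      double s10 = std::pow(s, 10), s12 = s10 * s * s;
      e_hydro += p.hydro_eps * (5.0 * s12 - 6.0 * s10);
      double dVdr = p.hydro_eps * (-60.0 * s12 + 60.0 * s10) / r;
      double cc = -dVdr / r;
      addf(i,  cc*dx,  cc*dy,  cc*dz);
      addf(j, -cc*dx, -cc*dy, -cc*dz);
    }
  }

  // COM-distance restraint between two bead groups (generator use only)
  if (p.restraint) {
    double ax = 0, ay = 0, az = 0, bx = 0, by = 0, bz = 0;
    int na = p.grpA.size(), nb = p.grpB.size();
    for (int ii : p.grpA) { ax += x(ii,0); ay += x(ii,1); az += x(ii,2); }
    for (int ii : p.grpB) { bx += x(ii,0); by += x(ii,1); bz += x(ii,2); }
    ax /= na; ay /= na; az /= na; bx /= nb; by /= nb; bz /= nb;
    double dx = ax - bx, dy = ay - by, dz = az - bz;
    double d = std::sqrt(dx*dx + dy*dy + dz*dz);
    if (d > 0) {
      double dd = d - p.res_d0;
      e_restraint += p.res_k * dd * dd;
      double coef = -2.0 * p.res_k * dd / d;
      for (int ii : p.grpA) addf(ii,  coef * dx / na,  coef * dy / na,  coef * dz / na);
      for (int ii : p.grpB) addf(ii, -coef * dx / nb, -coef * dy / nb, -coef * dz / nb);
    }
  }

  double total = e_bond + e_angle + e_dihedral + e_contact + e_ev + e_elec +
                 e_hydro + e_restraint;
  return NumericVector::create(
    _["bond"] = e_bond, _["angle"] = e_angle, _["dihedral"] = e_dihedral,
    _["contact"] = e_contact, _["excluded_volume"] = e_ev,
    _["electrostatic"] = e_elec, _["hydrophobic"] = e_hydro,
    _["restraint"] = e_restraint, _["total"] = total);
}

// [[Rcpp::export]]
NumericVector cpp_energy(NumericMatrix coords, List topo, List pars) {
  Topo t = unpack_topo(topo, coords.nrow());
  Pars p = unpack_pars(pars);
  return eval_model(coords, t, p, nullptr);
}

// [[Rcpp::export]]
NumericMatrix cpp_forces(NumericMatrix coords, List topo, List pars) {
  Topo t = unpack_topo(topo, coords.nrow());
  Pars p = unpack_pars(pars);
  NumericMatrix F(coords.nrow(), 3);
  eval_model(coords, t, p, &F);
  return F;
}

// BAOAB Langevin integrator.  Returns frames saved every save_interval steps
// (first frame after save_interval steps), per-frame kinetic energy, and the
// final phase-space point.
// [[Rcpp::export]]
List cpp_langevin(NumericMatrix coords0, List topo, List pars,
                  int n_steps, int save_interval, double dt, double gamma,
                  double seed, bool velocities_init = true) {
  const int n = coords0.nrow();
  Topo t = unpack_topo(topo, n);
  Pars p = unpack_pars(pars);
  Rng rng((uint64_t) seed);

  NumericMatrix x = clone(coords0);
  NumericMatrix v(n, 3), F(n, 3);
  const double kT = p.kT;
  if (velocities_init) {
    double sv = std::sqrt(kT);
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) v(i, d) = sv * rng.norm();
  }

  const int n_frames = (save_interval > 0) ? n_steps / save_interval : 0;
  NumericVector frames(Dimension(n, 3, std::max(n_frames, 0)));
  NumericVector kin(std::max(n_frames, 0));
  IntegerVector fsteps(std::max(n_frames, 0));

  const double c1 = std::exp(-gamma * dt);
  const double c2 = std::sqrt((1.0 - c1 * c1) * kT);

  // initial forces
  std::fill(F.begin(), F.end(), 0.0);
  eval_model(x, t, p, &F);

  int fidx = 0;
  for (int step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) {
        v(i, d) += 0.5 * dt * F(i, d);
        x(i, d) += 0.5 * dt * v(i, d);
      }
    if (gamma > 0) {
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d)
          v(i, d) = c1 * v(i, d) + c2 * rng.norm();
    }
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d)
        x(i, d) += 0.5 * dt * v(i, d);
    std::fill(F.begin(), F.end(), 0.0);
    eval_model(x, t, p, &F);
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d)
        v(i, d) += 0.5 * dt * F(i, d);

    // blow-up guard
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d)
        if (!std::isfinite(x(i, d)) || std::fabs(x(i, d)) > 1e5)
          stop("numerical blow-up at step %d (bead %d)", step, i + 1);

    if (save_interval > 0 && step % save_interval == 0 && fidx < n_frames) {
      double ke = 0;
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d) {
          frames[fidx * n * 3 + d * n + i] = x(i, d);
          ke += 0.5 * v(i, d) * v(i, d);
        }
      kin[fidx] = ke;
      fsteps[fidx] = step;
      ++fidx;
    }
  }

  return List::create(_["frames"] = frames, _["kinetic"] = kin,
                      _["steps"] = fsteps, _["final_coords"] = x,
                      _["final_velocities"] = v);
}

// Debye formula: I(q) = sum_i sum_j f_i f_j sinc(q r_ij)
// [[Rcpp::export]]
NumericVector cpp_debye(NumericMatrix coords, NumericVector f, NumericVector q) {
  const int n = coords.nrow(), m = q.size();
  NumericVector I(m);
  // self terms
  double self = 0;
  for (int i = 0; i < n; ++i) self += f[i] * f[i];
  std::fill(I.begin(), I.end(), self);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = coords(i,0)-coords(j,0), dy = coords(i,1)-coords(j,1),
             dz = coords(i,2)-coords(j,2);
      double r = std::sqrt(dx*dx + dy*dy + dz*dz);
      double ff = 2.0 * f[i] * f[j];
      for (int k = 0; k < m; ++k) {
        double qr = q[k] * r;
        I[k] += ff * (qr < 1e-8 ? 1.0 : std::sin(qr) / qr);
      }
    }
  }
  return I;
}

// weighted pair-distance histogram; returns counts (weights f_i f_j) per bin
// plus the maximum pair distance
// [[Rcpp::export]]
List cpp_pair_hist(NumericMatrix coords, NumericVector f, double bin, int n_bins) {
  const int n = coords.nrow();
  NumericVector h(n_bins);
  double dmax = 0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = coords(i,0)-coords(j,0), dy = coords(i,1)-coords(j,1),
             dz = coords(i,2)-coords(j,2);
      double r = std::sqrt(dx*dx + dy*dy + dz*dz);
      if (r > dmax) dmax = r;
      int b = (int) std::floor(r / bin);
      if (b >= 0 && b < n_bins) h[b] += f[i] * f[j];
    }
  }
  return List::create(_["counts"] = h, _["dmax"] = dmax);
}
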