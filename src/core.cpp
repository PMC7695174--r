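// Structure-based model core: potential evaluation, Langevin (BAOAB)
// integration in reduced units, and the Shadow contact-map construction.
//
// Functional forms:
//   bond        0.5 kb (r - r0)^2
//   angle       0.5 ka/sin^2(th0) (cos th - cos th0)^2   (cosine-harmonic;
//               curvature ka at th0, bounded gradient at collinearity)
//   rigid dih   kd (1 - cos 2 phi)                    minima at 0 and pi
//   flexible    kd [(1 - cos d) + 0.5 (1 - cos 3 d)]  d = phi - phi0
//   contact     eps [ (s/r)^12 - 2 (s/r)^6 ]          minimum -eps at r = s
//   (gaussian)  -eps exp(-(r-s)^2 / 2 w^2) + (sev/r)^12
//   excl. vol.  eev (sev/r)^12, r < rc, non-excluded non-contact pairs
//   restraint   0.5 kr |r - ref|^2
// All energies in reduced units (eps = 1), lengths in nm, kB = 1.

#include <Rcpp.h>
#include <vector>
#include <unordered_set>
#include <cmath>
#include <random>
using namespace Rcpp;

struct Topo {
  int n;
  std::vector<int> bi, bj;            std::vector<double> br0, bk;
  std::vector<int> ai, aj, ak;        std::vector<double> ath0, aka;
  std::vector<int> di, dj, dk, dl;    std::vector<double> dphi0, dkd;
  std::vector<int> dcls;              // 1 rigid, 2 flexible
  std::vector<int> ci, cj;            std::vector<double> csig, ceps;
  int contact_form;                   // 0 LJ 6-12, 1 gaussian
  double gw;                          // gaussian width
  double ev_sigma, ev_eps, ev_cutoff;
  std::unordered_set<long long> excl; // bonded + contact pairs
  std::vector<int> ridx;              std::vector<double> rref, rk;
  double wall_radius, wall_k;         // half-harmonic radial containment
};

static inline long long pkey(int i, int j, int n) {
  if (i > j) std::swap(i, j);
  return (long long)i * n + j;
}

static Topo unpack_topo(const List& tp) {
  Topo T;
  T.n = as<int>(tp["n_atoms"]);
  IntegerMatrix B = tp["bonds"];
  NumericVector br0 = tp["bond_r0"], bk = tp["bond_k"];
  for (int m = 0; m < B.nrow(); ++m) {
    T.bi.push_back(B(m, 0) - 1); T.bj.push_back(B(m, 1) - 1);
    T.br0.push_back(br0[m]); T.bk.push_back(bk[m]);
  }
  IntegerMatrix A = tp["angles"];
  NumericVector th0 = tp["angle_theta0"], ka = tp["angle_k"];
  for (int m = 0; m < A.nrow(); ++m) {
    T.ai.push_back(A(m, 0) - 1); T.aj.push_back(A(m, 1) - 1);
    T.ak.push_back(A(m, 2) - 1);
    T.ath0.push_back(th0[m]); T.aka.push_back(ka[m]);
  }
  IntegerMatrix D = tp["dihedrals"];
  NumericVector p0 = tp["dih_phi0"], kd = tp["dih_k"];
  IntegerVector dc = tp["dih_class"];
  for (int m = 0; m < D.nrow(); ++m) {
    T.di.push_back(D(m, 0) - 1); T.dj.push_back(D(m, 1) - 1);
    T.dk.push_back(D(m, 2) - 1); T.dl.push_back(D(m, 3) - 1);
    T.dphi0.push_back(p0[m]); T.dkd.push_back(kd[m]); T.dcls.push_back(dc[m]);
  }
  IntegerMatrix C = tp["contacts"];
  NumericVector cs = tp["contact_sigma"], ce = tp["contact_eps"];
  for (int m = 0; m < C.nrow(); ++m) {
    T.ci.push_back(C(m, 0) - 1); T.cj.push_back(C(m, 1) - 1);
    T.csig.push_back(cs[m]); T.ceps.push_back(ce[m]);
  }
  T.contact_form = as<int>(tp["contact_form"]);
  T.gw = as<double>(tp["gaussian_width"]);
  T.ev_sigma = as<double>(tp["ev_sigma"]);
  T.ev_eps = as<double>(tp["ev_eps"]);
  T.ev_cutoff = as<double>(tp["ev_cutoff"]);
  IntegerMatrix E = tp["exclusions"];
  for (int m = 0; m < E.nrow(); ++m)
    T.excl.insert(pkey(E(m, 0) - 1, E(m, 1) - 1, T.n));
  for (size_t m = 0; m < T.ci.size(); ++m)
    T.excl.insert(pkey(T.ci[m], T.cj[m], T.n));
  IntegerVector ri = tp["restraint_idx"];
  NumericMatrix rr = tp["restraint_ref"];
  NumericVector rk = tp["restraint_k"];
  for (int m = 0; m < ri.size(); ++m) {
    T.ridx.push_back(ri[m] - 1);
    T.rref.push_back(rr(m, 0)); T.rref.push_back(rr(m, 1));
    T.rref.push_back(rr(m, 2));
    T.rk.push_back(rk.size() == ri.size() ? rk[m] : rk[0]);
  }
  T.wall_radius = as<double>(tp["wall_radius"]);
  T.wall_k = as<double>(tp["wall_k"]);
  return T;
}

// ---------------------------------------------------------------------------
// cell-list neighbour search for the excluded-volume term

struct NList {
  std::vector<int> pi, pj;
  std::vector<double> x0;   // positions at build time
  double skin = 0.2;
  void build(const Topo& T, const std::vector<double>& x) {
    pi.clear(); pj.clear();
    x0 = x;
    const int n = T.n;
    const double rl = T.ev_cutoff + skin;
    double lo[3], hi[3];
    for (int d = 0; d < 3; ++d) { lo[d] = 1e30; hi[d] = -1e30; }
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) {
        lo[d] = std::min(lo[d], x[3 * i + d]);
        hi[d] = std::max(hi[d], x[3 * i + d]);
      }
    int nc[3];
    for (int d = 0; d < 3; ++d) {
      nc[d] = std::max(1, (int)std::floor((hi[d] - lo[d]) / rl));
      if (nc[d] > 64) nc[d] = 64;
    }
    double cw[3];
    for (int d = 0; d < 3; ++d) cw[d] = (hi[d] - lo[d]) / nc[d] + 1e-12;
    auto cell_of = [&](int i, int d) {
      int c = (int)std::floor((x[3 * i + d] - lo[d]) / cw[d]);
      return std::min(std::max(c, 0), nc[d] - 1);
    };
    const int ncell = nc[0] * nc[1] * nc[2];
    std::vector<std::vector<int>> cells(ncell);
    for (int i = 0; i < n; ++i)
      cells[(cell_of(i, 0) * nc[1] + cell_of(i, 1)) * nc[2] + cell_of(i, 2)]
        .push_back(i);
    const double rl2 = rl * rl;
    for (int cx = 0; cx < nc[0]; ++cx)
      for (int cy = 0; cy < nc[1]; ++cy)
        for (int cz = 0; cz < nc[2]; ++cz) {
          const std::vector<int>& a =
            cells[(cx * nc[1] + cy) * nc[2] + cz];
          if (a.empty()) continue;
          for (int dx = -1; dx <= 1; ++dx)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dz = -1; dz <= 1; ++dz) {
                int ex = cx + dx, ey = cy + dy, ez = cz + dz;
                if (ex < 0 || ey < 0 || ez < 0 ||
                    ex >= nc[0] || ey >= nc[1] || ez >= nc[2]) continue;
                int cid = (cx * nc[1] + cy) * nc[2] + cz;
                int eid = (ex * nc[1] + ey) * nc[2] + ez;
                if (eid < cid) continue;
                const std::vector<int>& b = cells[eid];
                for (size_t u = 0; u < a.size(); ++u) {
                  size_t vstart = (eid == cid) ? u + 1 : 0;
                  for (size_t v = vstart; v < b.size(); ++v) {
                    int i = a[u], j = b[v];
                    double d2 = 0;
                    for (int d = 0; d < 3; ++d) {
                      double dd = x[3 * i + d] - x[3 * j + d];
                      d2 += dd * dd;
                    }
                    if (d2 > rl2) continue;
                    if (T.excl.count(pkey(i, j, T.n))) continue;
                    pi.push_back(i); pj.push_back(j);
                  }
                }
              }
        }
  }
  bool stale(const std::vector<double>& x) const {
    double lim = 0.25 * skin * skin;  // (skin/2)^2
    for (size_t i = 0; i < x.size(); i += 3) {
      double d2 = 0;
      for (int d = 0; d < 3; ++d) {
        double dd = x[i + d] - x0[i + d];
        d2 += dd * dd;
      }
      if (d2 > lim) return true;
    }
    return false;
  }
};

// ---------------------------------------------------------------------------
// potential energy and forces

struct EnergyBreakdown {
  double bond = 0, angle = 0, dihedral = 0, contact = 0, ev = 0, restraint = 0;
  double total() const {
    return bond + angle + dihedral + contact + ev + restraint;
  }
};

static EnergyBreakdown eval_ff(const Topo& T, const std::vector<double>& x,
                               std::vector<double>& f, const NList& nl) {
  EnergyBreakdown E;
  std::fill(f.begin(), f.end(), 0.0);
  auto dvec = [&](int i, int j, double* d) {
    for (int c = 0; c < 3; ++c) d[c] = x[3 * j + c] - x[3 * i + c];
  };
  // bonds
  for (size_t m = 0; m < T.bi.size(); ++m) {
    double d[3]; dvec(T.bi[m], T.bj[m], d);
    double r = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    double dr = r - T.br0[m];
    E.bond += 0.5 * T.bk[m] * dr * dr;
    double fac = -T.bk[m] * dr / r;  // force on j along d
    for (int c = 0; c < 3; ++c) {
      f[3 * T.bj[m] + c] += fac * d[c];
      f[3 * T.bi[m] + c] -= fac * d[c];
    }
  }
  // angles (cosine-harmonic): V = 0.5 kc (cos th - cos th0)^2 with
  // kc = ka / max(sin^2 th0, 0.1), so the curvature at th0 is ka for
  // ordinary angles while the force stays smooth through collinearity
  for (size_t m = 0; m < T.ai.size(); ++m) {
    int i = T.ai[m], j = T.aj[m], k = T.ak[m];
    double rij[3], rkj[3];
    for (int c = 0; c < 3; ++c) {
      rij[c] = x[3 * i + c] - x[3 * j + c];
      rkj[c] = x[3 * k + c] - x[3 * j + c];
    }
    double nij = std::sqrt(rij[0]*rij[0] + rij[1]*rij[1] + rij[2]*rij[2]);
    double nkj = std::sqrt(rkj[0]*rkj[0] + rkj[1]*rkj[1] + rkj[2]*rkj[2]);
    double cth = (rij[0]*rkj[0] + rij[1]*rkj[1] + rij[2]*rkj[2]) / (nij * nkj);
    cth = std::min(1.0, std::max(-1.0, cth));
    double c0 = std::cos(T.ath0[m]);
    double s20 = std::max(1.0 - c0 * c0, 0.1);
    double kc = T.aka[m] / s20;
    double dc = cth - c0;
    E.angle += 0.5 * kc * dc * dc;
    double coef = -kc * dc;   // F = -dV/dcos * dcos/dx
    for (int c = 0; c < 3; ++c) {
      double dcdi = (rkj[c] / (nij * nkj)) - cth * rij[c] / (nij * nij);
      double dcdk = (rij[c] / (nij * nkj)) - cth * rkj[c] / (nkj * nkj);
      f[3 * i + c] += coef * dcdi;
      f[3 * k + c] += coef * dcdk;
      f[3 * j + c] -= coef * (dcdi + dcdk);
    }
  }
  // dihedrals
  for (size_t m = 0; m < T.di.size(); ++m) {
    int i = T.di[m], j = T.dj[m], k = T.dk[m], l = T.dl[m];
    double b1[3], b2[3], b3[3];
    for (int c = 0; c < 3; ++c) {
      b1[c] = x[3 * j + c] - x[3 * i + c];
      b2[c] = x[3 * k + c] - x[3 * j + c];
      b3[c] = x[3 * l + c] - x[3 * k + c];
    }
    double mvec[3] = { b1[1]*b2[2]-b1[2]*b2[1], b1[2]*b2[0]-b1[0]*b2[2],
                       b1[0]*b2[1]-b1[1]*b2[0] };
    double nvec[3] = { b2[1]*b3[2]-b2[2]*b3[1], b2[2]*b3[0]-b2[0]*b3[2],
                       b2[0]*b3[1]-b2[1]*b3[0] };
    double b2n = std::sqrt(b2[0]*b2[0] + b2[1]*b2[1] + b2[2]*b2[2]);
    double m2 = mvec[0]*mvec[0] + mvec[1]*mvec[1] + mvec[2]*mvec[2];
    double n2 = nvec[0]*nvec[0] + nvec[1]*nvec[1] + nvec[2]*nvec[2];
    // skip near-collinear triples: |m| = |b1||b2| sin(angle) and the
    // gradient carries 1/|m|^2, so the torque diverges as the backbone
    // straightens; below ~6 degrees from collinear the term is dropped
    if (m2 < 1e-4 || n2 < 1e-4) continue;
    double mdotn = mvec[0]*nvec[0] + mvec[1]*nvec[1] + mvec[2]*nvec[2];
    double cx[3] = { mvec[1]*nvec[2]-mvec[2]*nvec[1],
                     mvec[2]*nvec[0]-mvec[0]*nvec[2],
                     mvec[0]*nvec[1]-mvec[1]*nvec[0] };
    double sphi = (cx[0]*b2[0] + cx[1]*b2[1] + cx[2]*b2[2]) / b2n;
    double phi = std::atan2(sphi, mdotn);
    double dV;
    if (T.dcls[m] == 1) {              // rigid, periodicity 2
      E.dihedral += T.dkd[m] * (1.0 - std::cos(2.0 * phi));
      dV = 2.0 * T.dkd[m] * std::sin(2.0 * phi);
    } else {                           // flexible, SMOG 1+3 form
      double d = phi - T.dphi0[m];
      E.dihedral += T.dkd[m] * ((1.0 - std::cos(d)) +
                                0.5 * (1.0 - std::cos(3.0 * d)));
      dV = T.dkd[m] * (std::sin(d) + 1.5 * std::sin(3.0 * d));
    }
    double fi[3], fl[3];
    for (int c = 0; c < 3; ++c) {
      fi[c] =  dV * b2n / m2 * mvec[c];
      fl[c] = -dV * b2n / n2 * nvec[c];
    }
    double tb = (b1[0]*b2[0] + b1[1]*b2[1] + b1[2]*b2[2]) / (b2n * b2n);
    double ub = (b3[0]*b2[0] + b3[1]*b2[1] + b3[2]*b2[2]) / (b2n * b2n);
    for (int c = 0; c < 3; ++c) {
      double fj = -fi[c] - tb * fi[c] + ub * fl[c];
      double fk = -fl[c] + tb * fi[c] - ub * fl[c];
      f[3 * i + c] += fi[c];
      f[3 * j + c] += fj;
      f[3 * k + c] += fk;
      f[3 * l + c] += fl[c];
    }
  }
  // contacts
  for (size_t m = 0; m < T.ci.size(); ++m) {
    int i = T.ci[m], j = T.cj[m];
    double d[3]; dvec(i, j, d);
    double r2 = d[0]*d[0] + d[1]*d[1] + d[2]*d[2];
    double r = std::sqrt(r2);
    double dV;  // dV/dr
    if (T.contact_form == 0) {
      double sr2 = (T.csig[m] * T.csig[m]) / r2;
      double sr6 = sr2 * sr2 * sr2;
      E.contact += T.ceps[m] * (sr6 * sr6 - 2.0 * sr6);
      dV = -12.0 * T.ceps[m] / r * (sr6 * sr6 - sr6);
    } else {
      double w2 = T.gw * T.gw;
      double dr = r - T.csig[m];
      double g = std::exp(-dr * dr / (2.0 * w2));
      double core = std::pow(T.ev_sigma / r, 12);
      E.contact += -T.ceps[m] * g + core;
      dV = T.ceps[m] * g * dr / w2 - 12.0 * core / r;
    }
    double fac = -dV / r;   // force on j along d
    for (int c = 0; c < 3; ++c) {
      f[3 * j + c] += fac * d[c];
      f[3 * i + c] -= fac * d[c];
    }
  }
  // excluded volume via neighbour list
  const double rc2 = T.ev_cutoff * T.ev_cutoff;
  for (size_t m = 0; m < nl.pi.size(); ++m) {
    int i = nl.pi[m], j = nl.pj[m];
    double d[3]; dvec(i, j, d);
    double r2 = d[0]*d[0] + d[1]*d[1] + d[2]*d[2];
    if (r2 > rc2) continue;
    double s2 = (T.ev_sigma * T.ev_sigma) / r2;
    double s6 = s2 * s2 * s2;
    double e = T.ev_eps * s6 * s6;
    E.ev += e;
    double fac = 12.0 * e / r2;  // -dV/dr / r
    for (int c = 0; c < 3; ++c) {
      f[3 * j + c] += fac * d[c];
      f[3 * i + c] -= fac * d[c];
    }
  }
  // radial containment wall (emulates a sealed shell during restrained
  // tail-generation runs); energy booked under restraint
  if (T.wall_k > 0 && T.wall_radius > 0) {
    for (int i = 0; i < T.n; ++i) {
      double r2 = 0;
      for (int c = 0; c < 3; ++c) r2 += x[3 * i + c] * x[3 * i + c];
      double r = std::sqrt(r2);
      if (r > T.wall_radius) {
        double dr = r - T.wall_radius;
        E.restraint += 0.5 * T.wall_k * dr * dr;
        for (int c = 0; c < 3; ++c)
          f[3 * i + c] -= T.wall_k * dr * x[3 * i + c] / r;
      }
    }
  }
  // restraints
  for (size_t m = 0; m < T.ridx.size(); ++m) {
    int i = T.ridx[m];
    double dx[3];
    double e = 0;
    for (int c = 0; c < 3; ++c) {
      dx[c] = x[3 * i + c] - T.rref[3 * m + c];
      e += dx[c] * dx[c];
    }
    E.restraint += 0.5 * T.rk[m] * e;
    for (int c = 0; c < 3; ++c) f[3 * i + c] -= T.rk[m] * dx[c];
  }
  return E;
}

// [[Rcpp::export(name = ".cg_energy_cpp")]]
List cg_energy_cpp(NumericMatrix pos, List tp) {
  Topo T = unpack_topo(tp);
  if (pos.nrow() != T.n) stop("position matrix does not match topology atom count");
  std::vector<double> x(3 * T.n), f(3 * T.n);
  for (int i = 0; i < T.n; ++i)
    for (int c = 0; c < 3; ++c) x[3 * i + c] = pos(i, c);
  NList nl; nl.build(T, x);
  EnergyBreakdown E = eval_ff(T, x, f, nl);
  NumericMatrix fo(T.n, 3);
  for (int i = 0; i < T.n; ++i)
    for (int c = 0; c < 3; ++c) fo(i, c) = f[3 * i + c];
  return List::create(_["total"] = E.total(), _["bond"] = E.bond,
                      _["angle"] = E.angle, _["dihedral"] = E.dihedral,
                      _["contact"] = E.contact, _["excluded_volume"] = E.ev,
                      _["restraint"] = E.restraint, _["forces"] = fo);
}

// BAOAB Langevin integrator.  friction = 0 reduces to velocity Verlet (NVE).
// [[Rcpp::export(name = ".cg_langevin_cpp")]]
List cg_langevin_cpp(NumericMatrix pos, NumericMatrix vel, List tp,
                     NumericVector mass, double dt, double friction,
                     double temperature, int n_steps, int save_interval,
                     double seed) {
  Topo T = unpack_topo(tp);
  const int n = T.n;
  if (pos.nrow() != n || vel.nrow() != n || mass.size() != n)
    stop("state arrays do not match topology atom count");
  std::vector<double> x(3 * n), v(3 * n), f(3 * n);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) {
      x[3 * i + c] = pos(i, c);
      v[3 * i + c] = vel(i, c);
    }
  std::mt19937_64 gen((uint64_t)seed);
  std::normal_distribution<double> nd(0.0, 1.0);
  const double c1 = std::exp(-friction * dt);
  const double c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1));
  // speed ceiling far beyond the thermal tail (~17 sigma): inert for
  // equilibrium dynamics, but stops the rare r^-12 core runaway in which a
  // colliding pair gains velocity faster than the step can resolve
  const double vmax = 30.0 * std::sqrt(std::max(temperature, 0.1));
  const double vmax2 = vmax * vmax;
  std::vector<double> sig(n);
  for (int i = 0; i < n; ++i) sig[i] = std::sqrt(temperature / mass[i]);

  NList nl; nl.build(T, x);
  EnergyBreakdown E = eval_ff(T, x, f, nl);

  const int n_saves = 1 + (save_interval > 0 ? n_steps / save_interval : 0) +
    ((save_interval > 0 && n_steps % save_interval != 0) ? 1 : 0);
  NumericVector frames((R_xlen_t)n_saves * n * 3);
  NumericVector times(n_saves), epot(n_saves), ekin(n_saves);
  int isave = 0;
  auto save_frame = [&](int step) {
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < 3; ++c)
        frames[(R_xlen_t)isave * n * 3 + (R_xlen_t)i * 3 + c] = x[3 * i + c];
    times[isave] = step * dt;
    epot[isave] = E.total();
    double ke = 0;
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < 3; ++c)
        ke += 0.5 * mass[i] * v[3 * i + c] * v[3 * i + c];
    ekin[isave] = ke;
    ++isave;
  };
  save_frame(0);
  int blow_step = -1;
  for (int s = 1; s <= n_steps; ++s) {
    // B
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < 3; ++c)
        v[3 * i + c] += 0.5 * dt * f[3 * i + c] / mass[i];
    // A
    for (size_t q = 0; q < x.size(); ++q) x[q] += 0.5 * dt * v[q];
    // O
    if (friction > 0) {
      for (int i = 0; i < n; ++i)
        for (int c = 0; c < 3; ++c)
          v[3 * i + c] = c1 * v[3 * i + c] + c2 * sig[i] * nd(gen);
    }
    // A
    for (size_t q = 0; q < x.size(); ++q) x[q] += 0.5 * dt * v[q];
    if (nl.stale(x)) nl.build(T, x);
    E = eval_ff(T, x, f, nl);
    // B
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < 3; ++c)
        v[3 * i + c] += 0.5 * dt * f[3 * i + c] / mass[i];
    for (int i = 0; i < n; ++i) {
      double v2 = 0;
      for (int c = 0; c < 3; ++c) v2 += v[3 * i + c] * v[3 * i + c];
      if (v2 > vmax2) {
        double fscl = vmax / std::sqrt(v2);
        for (int c = 0; c < 3; ++c) v[3 * i + c] *= fscl;
      }
    }
    bool bad = false;
    for (size_t q = 0; q < x.size() && !bad; ++q)
      if (!std::isfinite(x[q]) || std::fabs(x[q]) > 1e6) bad = true;
    if (bad) { blow_step = s; break; }
    if ((save_interval > 0 && s % save_interval == 0) || s == n_steps)
      save_frame(s);
    if (s % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  NumericMatrix xo(n, 3), vo(n, 3);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) {
      xo(i, c) = x[3 * i + c];
      vo(i, c) = v[3 * i + c];
    }
  frames.attr("dim") = IntegerVector::create(3, n, n_saves);
  return List::create(_["frames"] = frames, _["times"] = times,
                      _["epot"] = epot, _["ekin"] = ekin,
                      _["n_saved"] = isave,
                      _["pos"] = xo, _["vel"] = vo,
                      _["blow_step"] = blow_step);
}

// ---------------------------------------------------------------------------
// Shadow contact map.
//
// A pair (i, j) with r_ij <= cutoff is a contact unless some third atom k,
// centred within r_ij of atom i, occludes the line of sight: the segment
// i -> j passes within radius_k of k's centre (radius_k = shadow radius,
// shrunk for atoms directly bonded to i or j).  Intra-chain pairs closer
// than min_sep in sequence, and excluded (bonded) pairs, are removed.

// [[Rcpp::export(name = ".cg_shadow_cpp")]]
List cg_shadow_cpp(NumericMatrix pos, IntegerVector resid, IntegerVector chain,
                   double cutoff, double shadow_radius, double bonded_radius,
                   int min_sep, IntegerMatrix bonds, IntegerMatrix excl) {
  const int n = pos.nrow();
  std::unordered_set<long long> bonded, excluded;
  for (int m = 0; m < bonds.nrow(); ++m)
    bonded.insert(pkey(bonds(m, 0) - 1, bonds(m, 1) - 1, n));
  for (int m = 0; m < excl.nrow(); ++m)
    excluded.insert(pkey(excl(m, 0) - 1, excl(m, 1) - 1, n));
  std::vector<int> oi, oj; std::vector<double> orn;
  const double cut2 = cutoff * cutoff;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d[3] = { pos(j,0)-pos(i,0), pos(j,1)-pos(i,1), pos(j,2)-pos(i,2) };
      double r2 = d[0]*d[0] + d[1]*d[1] + d[2]*d[2];
      if (r2 > cut2) continue;
      if (chain[i] == chain[j] && std::abs(resid[i] - resid[j]) < min_sep)
        continue;
      if (excluded.count(pkey(i, j, n))) continue;
      double rij = std::sqrt(r2);
      bool occluded = false;
      for (int k = 0; k < n && !occluded; ++k) {
        if (k == i || k == j) continue;
        double ki[3] = { pos(k,0)-pos(i,0), pos(k,1)-pos(i,1),
                         pos(k,2)-pos(i,2) };
        double dki2 = ki[0]*ki[0] + ki[1]*ki[1] + ki[2]*ki[2];
        if (dki2 >= r2) continue;  // only atoms within r_ij of i can shadow
        double radk = (bonded.count(pkey(k, i, n)) ||
                       bonded.count(pkey(k, j, n))) ? bonded_radius
                                                    : shadow_radius;
        if (radk <= 0) continue;
        // distance from k to segment i->j
        double t = (ki[0]*d[0] + ki[1]*d[1] + ki[2]*d[2]) / r2;
        t = std::min(1.0, std::max(0.0, t));
        double px = ki[0] - t * d[0], py = ki[1] - t * d[1],
               pz = ki[2] - t * d[2];
        double dseg2 = px * px + py * py + pz * pz;
        if (dseg2 < radk * radk) occluded = true;
      }
      if (!occluded) {
        oi.push_back(i + 1); oj.push_back(j + 1); orn.push_back(rij);
      }
    }
  }
  return List::create(_["i"] = wrap(oi), _["j"] = wrap(oj),
                      _["r_native"] = wrap(orn));
}
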