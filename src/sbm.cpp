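// Calpha structure-based model: energy, analytic forces, Langevin/NVE/umbrella
// integrators. Reduced units throughout: lengths nm, energies epsilon, k_B = 1,
// masses 1. Repulsive (sigma/r)^12 term is shifted to zero at r_cut so the
// integrator's neighbour list introduces no energy jumps.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <unordered_set>
using namespace Rcpp;

static inline double sq(double x) { return x * x; }
static inline double pow12(double x) {  // x^12 by squaring
  double x2 = x * x, x4 = x2 * x2;
  return x4 * x4 * x4;
}

// xoshiro256++ with Box-Muller: fast normal deviates; seeded from R's RNG so
// runs are reproducible given set.seed() (stream is build-dependent)
struct FastNorm {
  uint64_t s[4];
  bool have;
  double cache;
  explicit FastNorm(uint64_t seed) : have(false), cache(0) {
    // splitmix64 expansion
    for (int i = 0; i < 4; ++i) {
      seed += 0x9E3779B97f4A7C15ULL;
      uint64_t z = seed;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() {  // (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double norm() {  // Marsaglia polar method
    if (have) { have = false; return cache; }
    double v1, v2, s2;
    do {
      v1 = 2.0 * unif() - 1.0;
      v2 = 2.0 * unif() - 1.0;
      s2 = v1 * v1 + v2 * v2;
    } while (s2 >= 1.0 || s2 == 0.0);
    double fac = std::sqrt(-2.0 * std::log(s2) / s2);
    cache = v2 * fac;
    have = true;
    return v1 * fac;
  }
};

struct Topo {
  int n;
  std::vector<double> c0s, s0s;   // cos/sin of native dihedral phases
  NumericMatrix bonds;      // i j r0 k        (1-based indices)
  NumericMatrix angles;     // i j k th0 ka
  NumericMatrix dihedrals;  // i j k l phi0 k1 k3
  NumericMatrix contacts;   // i j r0 eps w
  double sigma;             // excluded-volume diameter, nm
  double eps_rep;           // repulsion prefactor, epsilon
  double rcut;              // repulsion cutoff, nm
  double rep_shift;         // (sigma/rcut)^12, subtracted inside cutoff
  std::unordered_set<long long> excl;  // pairs excluded from generic repulsion
  int min_rep_sep;          // |i-j| >= this for generic repulsion

  long long key(int i, int j) const {
    if (i > j) std::swap(i, j);
    return (long long)i * (long long)(n + 1) + j;
  }
};

static Topo make_topo(List tp) {
  Topo t;
  t.n = as<int>(tp["n"]);
  t.bonds = as<NumericMatrix>(tp["bonds"]);
  t.angles = as<NumericMatrix>(tp["angles"]);
  t.dihedrals = as<NumericMatrix>(tp["dihedrals"]);
  t.contacts = as<NumericMatrix>(tp["contacts"]);
  t.sigma = as<double>(tp["sigma"]);
  t.eps_rep = as<double>(tp["eps_rep"]);
  t.rcut = as<double>(tp["rcut"]);
  t.rep_shift = std::pow(t.sigma / t.rcut, 12.0);
  t.min_rep_sep = as<int>(tp["min_rep_sep"]);
  t.c0s.resize(t.dihedrals.nrow());
  t.s0s.resize(t.dihedrals.nrow());
  for (int r = 0; r < t.dihedrals.nrow(); ++r) {
    t.c0s[r] = std::cos(t.dihedrals(r, 4));
    t.s0s[r] = std::sin(t.dihedrals(r, 4));
  }
  IntegerMatrix ex = as<IntegerMatrix>(tp["rep_excl"]);  // 1-based pairs
  for (int r = 0; r < ex.nrow(); ++r) {
    t.excl.insert(t.key(ex(r, 0) - 1, ex(r, 1) - 1));
  }
  return t;
}

// ---- pairwise helpers ------------------------------------------------------

static inline double pair_dist(const std::vector<double>& x, int i, int j,
                               double d[3]) {
  d[0] = x[3 * j] - x[3 * i];
  d[1] = x[3 * j + 1] - x[3 * i + 1];
  d[2] = x[3 * j + 2] - x[3 * i + 2];
  return std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
}

// Gaussian-well native contact (Lammert form):
//   V(r) = eps * [ (1 + (s/r)^12) * (1 - G(r)) - 1 ],  G = exp(-(r-r0)^2/(2w^2))
// Minimum exactly -eps at r = r0; V -> 0 as r -> inf; (s/r)^12 core at small r.
static inline void contact_ev(double r, double r0, double eps, double w,
                              double s, double& V, double& dVdr) {
  double G = std::exp(-sq(r - r0) / (2.0 * w * w));
  double x = pow12(s / r);
  V = eps * ((1.0 + x) * (1.0 - G) - 1.0);
  double dx = -12.0 * x / r;
  double dG = -((r - r0) / (w * w)) * G;
  dVdr = eps * (dx * (1.0 - G) - (1.0 + x) * dG);
}

// ---- full energy/force evaluation -----------------------------------------

struct Breakdown {
  double bond = 0, angle = 0, dihedral = 0, contact = 0, repulsive = 0;
  double total() const { return bond + angle + dihedral + contact + repulsive; }
};

static Breakdown eval_all(const Topo& t, const std::vector<double>& x,
                          std::vector<double>* f,
                          const std::vector<std::pair<int, int> >* replist) {
  Breakdown e;
  int n = t.n;
  double d[3];
  if (f) std::fill(f->begin(), f->end(), 0.0);

  // bonds: (k/2) (r - r0)^2  (GROMACS harmonic convention, as in the
  // simulation package the model constants were calibrated for)
  for (int r = 0; r < t.bonds.nrow(); ++r) {
    int i = (int)t.bonds(r, 0) - 1, j = (int)t.bonds(r, 1) - 1;
    double r0 = t.bonds(r, 2), k = t.bonds(r, 3);
    double rr = pair_dist(x, i, j, d);
    e.bond += 0.5 * k * sq(rr - r0);
    if (f) {
      double dVdr = k * (rr - r0);
      for (int c = 0; c < 3; ++c) {
        double fc = dVdr * d[c] / rr;   // d = x_j - x_i: grad_j += fc
        (*f)[3 * i + c] -= fc;
        (*f)[3 * j + c] += fc;
      }
    }
  }

  // angles: (ka/2) (th - th0)^2
  for (int r = 0; r < t.angles.nrow(); ++r) {
    int i = (int)t.angles(r, 0) - 1, j = (int)t.angles(r, 1) - 1,
        k = (int)t.angles(r, 2) - 1;
    double th0 = t.angles(r, 3), ka = t.angles(r, 4);
    double rij[3], rkj[3];
    for (int c = 0; c < 3; ++c) {
      rij[c] = x[3 * i + c] - x[3 * j + c];
      rkj[c] = x[3 * k + c] - x[3 * j + c];
    }
    double nij = std::sqrt(rij[0] * rij[0] + rij[1] * rij[1] + rij[2] * rij[2]);
    double nkj = std::sqrt(rkj[0] * rkj[0] + rkj[1] * rkj[1] + rkj[2] * rkj[2]);
    double cth = (rij[0] * rkj[0] + rij[1] * rkj[1] + rij[2] * rkj[2]) / (nij * nkj);
    cth = std::max(-1.0, std::min(1.0, cth));
    double th = std::acos(cth);
    e.angle += 0.5 * ka * sq(th - th0);
    if (f) {
      // floor on sin(theta): the angle coordinate is singular at a straight
      // chain; capping the 1/sin factor bounds the force there instead of
      // delivering an unbounded kick when a bend crosses pi
      double sth = std::sqrt(std::max(0.01, 1.0 - cth * cth));
      double dVdth = ka * (th - th0);
      double coef = -dVdth / sth;
      for (int c = 0; c < 3; ++c) {
        double dthdi = (rkj[c] / (nij * nkj) - cth * rij[c] / (nij * nij));
        double dthdk = (rij[c] / (nij * nkj) - cth * rkj[c] / (nkj * nkj));
        (*f)[3 * i + c] += coef * dthdi;
        (*f)[3 * k + c] += coef * dthdk;
        (*f)[3 * j + c] -= coef * (dthdi + dthdk);
      }
    }
  }

  // dihedrals: k1 [1 - cos(phi - phi0)] + k3 [1 - cos 3(phi - phi0)]
  for (int r = 0; r < t.dihedrals.nrow(); ++r) {
    int i = (int)t.dihedrals(r, 0) - 1, j = (int)t.dihedrals(r, 1) - 1,
        k = (int)t.dihedrals(r, 2) - 1, l = (int)t.dihedrals(r, 3) - 1;
    double k1 = t.dihedrals(r, 5), k3 = t.dihedrals(r, 6);
    double b1[3], b2[3], b3[3];
    for (int c = 0; c < 3; ++c) {
      b1[c] = x[3 * j + c] - x[3 * i + c];
      b2[c] = x[3 * k + c] - x[3 * j + c];
      b3[c] = x[3 * l + c] - x[3 * k + c];
    }
    double n1[3] = {b1[1] * b2[2] - b1[2] * b2[1], b1[2] * b2[0] - b1[0] * b2[2],
                    b1[0] * b2[1] - b1[1] * b2[0]};
    double n2[3] = {b2[1] * b3[2] - b2[2] * b3[1], b2[2] * b3[0] - b2[0] * b3[2],
                    b2[0] * b3[1] - b2[1] * b3[0]};
    double nb2 = std::sqrt(b2[0] * b2[0] + b2[1] * b2[1] + b2[2] * b2[2]);
    double m1[3] = {n1[1] * b2[2] - n1[2] * b2[1], n1[2] * b2[0] - n1[0] * b2[2],
                    n1[0] * b2[1] - n1[1] * b2[0]};
    double xx = n1[0] * n2[0] + n1[1] * n2[1] + n1[2] * n2[2];
    double yy = (m1[0] * n2[0] + m1[1] * n2[1] + m1[2] * n2[2]) / nb2;
    // trig-free: cos/sin of phi from the projections, phase shift by phi0
    // via angle-sum identities, 3x angle via triple-angle formulas
    double hyp = std::sqrt(xx * xx + yy * yy);
    double cphi = hyp > 1e-12 ? xx / hyp : 1.0;
    double sphi = hyp > 1e-12 ? yy / hyp : 0.0;
    double c0 = t.c0s[r], s0 = t.s0s[r];
    double cd = cphi * c0 + sphi * s0;          // cos(phi - phi0)
    double sd = sphi * c0 - cphi * s0;          // sin(phi - phi0)
    double c3 = cd * (4.0 * cd * cd - 3.0);     // cos(3 dphi)
    double s3 = sd * (3.0 - 4.0 * sd * sd);     // sin(3 dphi)
    e.dihedral += k1 * (1.0 - cd) + k3 * (1.0 - c3);
    if (f) {
      double dVdphi = k1 * sd + 3.0 * k3 * s3;
      double n1sq = std::max(1e-4, n1[0] * n1[0] + n1[1] * n1[1] + n1[2] * n1[2]);
      double n2sq = std::max(1e-4, n2[0] * n2[0] + n2[1] * n2[1] + n2[2] * n2[2]);
      double fi[3], fl[3];
      for (int c = 0; c < 3; ++c) {
        fi[c] = -dVdphi * nb2 / n1sq * n1[c];
        fl[c] = dVdphi * nb2 / n2sq * n2[c];
      }
      double b1b2 = b1[0] * b2[0] + b1[1] * b2[1] + b1[2] * b2[2];
      double b3b2 = b3[0] * b2[0] + b3[1] * b2[1] + b3[2] * b2[2];
      for (int c = 0; c < 3; ++c) {
        double tj = (b3b2 / (nb2 * nb2)) * fl[c] - (b1b2 / (nb2 * nb2)) * fi[c];
        (*f)[3 * i + c] -= fi[c];
        (*f)[3 * j + c] -= -fi[c] + tj;
        (*f)[3 * k + c] -= -fl[c] - tj;
        (*f)[3 * l + c] -= fl[c];
      }
    }
  }

  // native contacts
  for (int r = 0; r < t.contacts.nrow(); ++r) {
    int i = (int)t.contacts(r, 0) - 1, j = (int)t.contacts(r, 1) - 1;
    double rr = pair_dist(x, i, j, d);
    if (rr < 1e-9) stop("coincident particles in contact pair");
    double V, dVdr;
    contact_ev(rr, t.contacts(r, 2), t.contacts(r, 3), t.contacts(r, 4),
               t.sigma, V, dVdr);
    e.contact += V;
    if (f)
      for (int c = 0; c < 3; ++c) {
        double fc = dVdr * d[c] / rr;
        (*f)[3 * i + c] -= fc;
        (*f)[3 * j + c] += fc;
      }
  }

  // generic excluded volume, shifted at rcut
  double rc2 = t.rcut * t.rcut;
  double s12 = std::pow(t.sigma, 12.0);
  if (replist) {
    for (size_t p = 0; p < replist->size(); ++p) {
      int i = (*replist)[p].first, j = (*replist)[p].second;
      d[0] = x[3 * j] - x[3 * i];
      d[1] = x[3 * j + 1] - x[3 * i + 1];
      d[2] = x[3 * j + 2] - x[3 * i + 2];
      double d2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
      if (d2 >= rc2) continue;
      if (d2 < 1e-18) stop("coincident particles");
      double rr = std::sqrt(d2);
      double x12 = s12 / (d2 * d2 * d2 * d2 * d2 * d2);
      e.repulsive += t.eps_rep *
          (x12 - t.rep_shift + 12.0 * t.rep_shift * (rr - t.rcut) / t.rcut);
      if (f) {
        double dVdr = t.eps_rep *
            (-12.0 * x12 / rr + 12.0 * t.rep_shift / t.rcut);
        for (int c = 0; c < 3; ++c) {
          double fc = dVdr * d[c] / rr;
          (*f)[3 * i + c] -= fc;
          (*f)[3 * j + c] += fc;
        }
      }
    }
  } else {
    for (int i = 0; i < n; ++i)
      for (int j = i + t.min_rep_sep; j < n; ++j) {
        if (t.excl.count(t.key(i, j))) continue;
        d[0] = x[3 * j] - x[3 * i];
        d[1] = x[3 * j + 1] - x[3 * i + 1];
        d[2] = x[3 * j + 2] - x[3 * i + 2];
        double d2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
        if (d2 >= rc2) continue;
        if (d2 < 1e-18) stop("coincident particles");
        double rr = std::sqrt(d2);
        double x12 = s12 / (d2 * d2 * d2 * d2 * d2 * d2);
        e.repulsive += t.eps_rep *
            (x12 - t.rep_shift + 12.0 * t.rep_shift * (rr - t.rcut) / t.rcut);
        if (f) {
          double dVdr = t.eps_rep *
              (-12.0 * x12 / rr + 12.0 * t.rep_shift / t.rcut);
          for (int c = 0; c < 3; ++c) {
            double fc = dVdr * d[c] / rr;
            (*f)[3 * i + c] -= fc;
            (*f)[3 * j + c] += fc;
          }
        }
      }
  }

  // forces are -grad E; accumulate as dV/dx then flip sign once
  if (f)
    for (size_t c = 0; c < f->size(); ++c) (*f)[c] = -(*f)[c];
  return e;
}

// Verlet neighbour list for the repulsive term
static void build_replist(const Topo& t, const std::vector<double>& x,
                          double rlist, std::vector<std::pair<int, int> >& out) {
  out.clear();
  double rl2 = rlist * rlist;
  double d[3];
  for (int i = 0; i < t.n; ++i)
    for (int j = i + t.min_rep_sep; j < t.n; ++j) {
      if (t.excl.count(t.key(i, j))) continue;
      double dx = x[3 * j] - x[3 * i];
      double dy = x[3 * j + 1] - x[3 * i + 1];
      double dz = x[3 * j + 2] - x[3 * i + 2];
      (void)d;
      if (dx * dx + dy * dy + dz * dz < rl2) out.push_back(std::make_pair(i, j));
    }
}

// [[Rcpp::export]]
List cpp_sbm_energy(List topo, NumericMatrix coords) {
  Topo t = make_topo(topo);
  if (coords.nrow() != t.n) stop("coordinate count does not match topology");
  std::vector<double> x(3 * t.n);
  for (int i = 0; i < t.n; ++i)
    for (int c = 0; c < 3; ++c) x[3 * i + c] = coords(i, c);
  Breakdown e = eval_all(t, x, nullptr, nullptr);
  return List::create(_["total"] = e.total(), _["bond"] = e.bond,
                      _["angle"] = e.angle, _["dihedral"] = e.dihedral,
                      _["contact"] = e.contact, _["repulsive"] = e.repulsive);
}

// [[Rcpp::export]]
NumericMatrix cpp_sbm_forces(List topo, NumericMatrix coords) {
  Topo t = make_topo(topo);
  if (coords.nrow() != t.n) stop("coordinate count does not match topology");
  std::vector<double> x(3 * t.n), f(3 * t.n);
  for (int i = 0; i < t.n; ++i)
    for (int c = 0; c < 3; ++c) x[3 * i + c] = coords(i, c);
  eval_all(t, x, &f, nullptr);
  NumericMatrix out(t.n, 3);
  for (int i = 0; i < t.n; ++i)
    for (int c = 0; c < 3; ++c) out(i, c) = f[3 * i + c];
  return out;
}

// ---- smooth (biasable) and sharp Q ----------------------------------------

static double q_sharp(const Topo& t, const std::vector<double>& x, double lambda) {
  int nc = t.contacts.nrow();
  if (nc == 0) return NA_REAL;
  int formed = 0;
  double d[3];
  for (int r = 0; r < nc; ++r) {
    int i = (int)t.contacts(r, 0) - 1, j = (int)t.contacts(r, 1) - 1;
    if (pair_dist(x, i, j, d) < lambda * t.contacts(r, 2)) ++formed;
  }
  return (double)formed / nc;
}

// logistic switch of width 0.1 r0 centred at lambda r0
static double q_smooth(const Topo& t, const std::vector<double>& x, double lambda,
                       std::vector<double>* dq) {
  int nc = t.contacts.nrow();
  double qs = 0.0;
  double d[3];
  if (dq) std::fill(dq->begin(), dq->end(), 0.0);
  for (int r = 0; r < nc; ++r) {
    int i = (int)t.contacts(r, 0) - 1, j = (int)t.contacts(r, 1) - 1;
    double r0 = t.contacts(r, 2), w = 0.1 * r0;
    double rr = pair_dist(x, i, j, d);
    double fq = 1.0 / (1.0 + std::exp((rr - lambda * r0) / w));
    qs += fq;
    if (dq) {
      double dfdr = -fq * (1.0 - fq) / w;
      for (int c = 0; c < 3; ++c) {
        double g = dfdr * d[c] / rr / nc;
        (*dq)[3 * i + c] -= g;
        (*dq)[3 * j + c] += g;
      }
    }
  }
  return qs / nc;
}

// [[Rcpp::export]]
NumericVector cpp_traj_Q(NumericMatrix frames, NumericMatrix contacts,
                         double lambda) {
  // frames: F x 3n (row-per-frame flattened coords); contacts: i j r0
  int F = frames.nrow();
  int nc = contacts.nrow();
  NumericVector out(F);
  for (int fidx = 0; fidx < F; ++fidx) {
    int formed = 0;
    for (int r = 0; r < nc; ++r) {
      int i = (int)contacts(r, 0) - 1, j = (int)contacts(r, 1) - 1;
      double dx = frames(fidx, 3 * j) - frames(fidx, 3 * i);
      double dy = frames(fidx, 3 * j + 1) - frames(fidx, 3 * i + 1);
      double dz = frames(fidx, 3 * j + 2) - frames(fidx, 3 * i + 2);
      if (std::sqrt(dx * dx + dy * dy + dz * dz) < lambda * contacts(r, 2))
        ++formed;
    }
    out[fidx] = (double)formed / nc;
  }
  return out;
}

// ---- integrators -----------------------------------------------------------

// mode: 0 = Langevin (BAOAB), 1 = NVE velocity-Verlet.
// Umbrella bias on smooth Q applied when k_umb > 0.
// [[Rcpp::export]]
List cpp_run_md(List topo, NumericMatrix x0, NumericMatrix v0, double dt,
                double gamma, double temperature, int n_steps, int stride,
                int mode, double q_center, double k_umb, double q_lambda,
                int list_every, double skin) {
  Topo t = make_topo(topo);
  int n = t.n;
  if (x0.nrow() != n) stop("x0 does not match topology");
  std::vector<double> x(3 * n), v(3 * n), f(3 * n), dq(3 * n);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) {
      x[3 * i + c] = x0(i, c);
      v[3 * i + c] = v0(i, c);
    }

  bool bias = k_umb > 0.0;
  std::vector<std::pair<int, int> > replist;
  double rlist = t.rcut + skin;
  build_replist(t, x, rlist, replist);

  int n_frames = n_steps / stride;
  NumericMatrix frames(n_frames, 3 * n);
  NumericVector e_pot(n_frames), e_kin(n_frames), qsharp(n_frames),
      qsm(n_frames), e_bias(n_frames), times(n_frames);

  double c1 = std::exp(-gamma * dt);
  double c2 = std::sqrt(std::max(0.0, (1.0 - c1 * c1) * temperature));

  RNGScope rng;  // one draw from R's RNG seeds the fast stream
  FastNorm fn((uint64_t)(unif_rand() * 9007199254740992.0));

  // initial forces
  Breakdown e = eval_all(t, x, &f, &replist);
  double qs = 0.0, ub = 0.0;
  if (bias) {
    qs = q_smooth(t, x, q_lambda, &dq);
    ub = 0.5 * k_umb * sq(qs - q_center);
    for (int c = 0; c < 3 * n; ++c) f[c] -= k_umb * (qs - q_center) * dq[c];
  }

  int frame = 0;
  for (int step = 1; step <= n_steps; ++step) {
    if (mode == 0) {
      // BAOAB
      for (int c = 0; c < 3 * n; ++c) v[c] += 0.5 * dt * f[c];
      for (int c = 0; c < 3 * n; ++c) x[c] += 0.5 * dt * v[c];
      for (int c = 0; c < 3 * n; ++c) v[c] = c1 * v[c] + c2 * fn.norm();
      for (int c = 0; c < 3 * n; ++c) x[c] += 0.5 * dt * v[c];
    } else {
      // velocity-Verlet
      for (int c = 0; c < 3 * n; ++c) v[c] += 0.5 * dt * f[c];
      for (int c = 0; c < 3 * n; ++c) x[c] += dt * v[c];
    }

    if (step % list_every == 0) build_replist(t, x, rlist, replist);
    e = eval_all(t, x, &f, &replist);
    if (bias) {
      qs = q_smooth(t, x, q_lambda, &dq);
      ub = 0.5 * k_umb * sq(qs - q_center);
      for (int c = 0; c < 3 * n; ++c) f[c] -= k_umb * (qs - q_center) * dq[c];
    }
    for (int c = 0; c < 3 * n; ++c) v[c] += 0.5 * dt * f[c];

    double ek = 0.0;
    for (int c = 0; c < 3 * n; ++c) ek += 0.5 * v[c] * v[c];
    double ep = e.total();
    if (!std::isfinite(ep) || !std::isfinite(ek))
      stop("dynamics diverged at step %d (non-finite energy)", step);

    if (step % stride == 0 && frame < n_frames) {
      for (int c = 0; c < 3 * n; ++c) frames(frame, c) = x[c];
      e_pot[frame] = ep;
      e_kin[frame] = ek;
      qsharp[frame] = q_sharp(t, x, q_lambda);
      qsm[frame] = bias ? qs : q_smooth(t, x, q_lambda, nullptr);
      e_bias[frame] = bias ? ub : 0.0;
      times[frame] = step * dt;
      ++frame;
    }
  }

  NumericMatrix vout(n, 3), xout(n, 3);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) {
      vout(i, c) = v[3 * i + c];
      xout(i, c) = x[3 * i + c];
    }
  return List::create(_["frames"] = frames, _["times"] = times,
                      _["e_pot"] = e_pot, _["e_kin"] = e_kin,
                      _["Q"] = qsharp, _["Q_smooth"] = qsm,
                      _["e_bias"] = e_bias, _["x_final"] = xout,
                      _["v_final"] = vout);
}
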