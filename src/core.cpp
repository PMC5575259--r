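// Coarse-grained chain energetics, overdamped Langevin propagation and
// steepest-descent minimization.  Units: nm, ps, kJ/mol throughout.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Params {
  double sigma, epsilon, lj_cutoff, crossover;
  double bond_k, bond_r0, angle_k, angle_theta0;
  double crosslink_k, crosslink_r0;
  double contact_epsilon, contact_width;
};

Params read_params(const List& p) {
  Params q;
  q.sigma = as<double>(p["sigma"]);
  q.epsilon = as<double>(p["epsilon"]);
  q.lj_cutoff = as<double>(p["lj_cutoff"]);
  q.crossover = as<double>(p["crossover"]);
  q.bond_k = as<double>(p["bond_k"]);
  q.bond_r0 = as<double>(p["bond_r0"]);
  q.angle_k = as<double>(p["angle_k"]);
  q.angle_theta0 = as<double>(p["angle_theta0"]);
  q.crosslink_k = as<double>(p["crosslink_k"]);
  q.crosslink_r0 = as<double>(p["crosslink_r0"]);
  q.contact_epsilon = p.containsElementNamed("contact_epsilon")
                          ? as<double>(p["contact_epsilon"]) : 0.0;
  q.contact_width = p.containsElementNamed("contact_width")
                        ? as<double>(p["contact_width"]) : 0.05;
  return q;
}

// 12-6 Lennard-Jones, plain truncation at the cutoff.  Returns energy and
// writes dV/dr.
inline double lj_e(double r, double sigma, double eps, double cutoff,
                   double* dvdr) {
  if (r >= cutoff) { *dvdr = 0.0; return 0.0; }
  double sr = sigma / r;
  double sr6 = sr * sr * sr; sr6 *= sr6;
  double sr12 = sr6 * sr6;
  *dvdr = 24.0 * eps * (sr6 - 2.0 * sr12) / r;
  return 4.0 * eps * (sr12 - sr6);
}

// Softcore sulfur-sulfur interaction: exactly LJ at and beyond the
// crossover; below it a bounded quadratic core matching LJ in value and
// slope at the crossover, with force -> 0 linearly as r -> 0.
inline double softcore_e(double r, double sigma, double eps, double cutoff,
                         double rc, double* dvdr) {
  if (r >= rc) return lj_e(r, sigma, eps, cutoff, dvdr);
  double d0;
  double v0 = lj_e(rc, sigma, eps, cutoff, &d0);
  double a = d0 / (2.0 * rc);           // a < 0 inside the repulsive wall
  *dvdr = 2.0 * a * r;
  return v0 + a * (r * r - rc * rc);
}

struct EFArgs {
  const double* x;            // n x 3, column-major (x[i], x[i+n], x[i+2n])
  int n;
  const int* is_cys;          // 0/1 per bead
  int ss_i, ss_j;             // 0-based disulfide members, -1 if absent
  const Params* par;
  double force_kj;            // pulling force in kJ/mol/nm
  const double* axis;         // unit 3-vector
  int fixed, pulled;          // 0-based, fixed may be -1
  const char* mask;           // nullptr, or 1 = mobile/included
  const std::vector<std::pair<int,int> >* pairs; // nonbonded list, or nullptr
  const double* contacts;     // m x 3 (i, j, d0), column-major; 1-based i/j
  int n_contacts;
};

inline bool included2(const char* m, int i, int j) {
  return m == nullptr || m[i] || m[j];
}
inline bool included3(const char* m, int i, int j, int k) {
  return m == nullptr || m[i] || m[j] || m[k];
}

// Total energy (terms touching >= 1 masked bead when mask given) and forces.
double energy_forces(const EFArgs& a, double* f) {
  const int n = a.n;
  const double* x = a.x;
  const Params& p = *a.par;
  double e = 0.0;
  if (f) std::fill(f, f + 3 * n, 0.0);

  auto fx = [&](int i) { return x[i]; };
  auto fy = [&](int i) { return x[i + n]; };
  auto fz = [&](int i) { return x[i + 2 * n]; };
  auto addf = [&](int i, double gx, double gy, double gz) {
    if (!f) return;
    f[i] += gx; f[i + n] += gy; f[i + 2 * n] += gz;
  };

  // bonds along the chain
  for (int i = 0; i + 1 < n; ++i) {
    if (!included2(a.mask, i, i + 1)) continue;
    double dx = fx(i + 1) - fx(i), dy = fy(i + 1) - fy(i),
           dz = fz(i + 1) - fz(i);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dr = r - p.bond_r0;
    e += 0.5 * p.bond_k * dr * dr;
    if (f && r > 0) {
      double c = p.bond_k * dr / r;
      addf(i, c * dx, c * dy, c * dz);
      addf(i + 1, -c * dx, -c * dy, -c * dz);
    }
  }

  // harmonic bending at interior beads
  if (p.angle_k > 0) {
    for (int j = 1; j + 1 < n; ++j) {
      int i = j - 1, k = j + 1;
      if (!included3(a.mask, i, j, k)) continue;
      double ax = fx(i) - fx(j), ay = fy(i) - fy(j), az = fz(i) - fz(j);
      double bx = fx(k) - fx(j), by = fy(k) - fy(j), bz = fz(k) - fz(j);
      double na = std::sqrt(ax * ax + ay * ay + az * az);
      double nb = std::sqrt(bx * bx + by * by + bz * bz);
      if (na <= 0 || nb <= 0) continue;
      double ct = (ax * bx + ay * by + az * bz) / (na * nb);
      ct = std::max(-1.0, std::min(1.0, ct));
      double th = std::acos(ct);
      double dth = th - p.angle_theta0;
      e += 0.5 * p.angle_k * dth * dth;
      if (f) {
        double st = std::sqrt(std::max(1e-12, 1.0 - ct * ct));
        double dEdth = p.angle_k * dth;
        // dtheta/dr_i and dtheta/dr_k
        double gix = (ct * ax / na - bx / nb) / (na * st);
        double giy = (ct * ay / na - by / nb) / (na * st);
        double giz = (ct * az / na - bz / nb) / (na * st);
        double gkx = (ct * bx / nb - ax / na) / (nb * st);
        double gky = (ct * by / nb - ay / na) / (nb * st);
        double gkz = (ct * bz / nb - az / na) / (nb * st);
        addf(i, -dEdth * gix, -dEdth * giy, -dEdth * giz);
        addf(k, -dEdth * gkx, -dEdth * gky, -dEdth * gkz);
        addf(j, dEdth * (gix + gkx), dEdth * (giy + gky),
             dEdth * (giz + gkz));
      }
    }
  }

  // nonbonded: 1-2 and 1-3 excluded, crosslinked pair excluded
  auto nb_pair = [&](int i, int j) {
    if ((i == a.ss_i && j == a.ss_j) || (i == a.ss_j && j == a.ss_i)) return;
    if (!included2(a.mask, i, j)) return;
    double dx = fx(j) - fx(i), dy = fy(j) - fy(i), dz = fz(j) - fz(i);
    double r2 = dx * dx + dy * dy + dz * dz;
    double rc2 = p.lj_cutoff * p.lj_cutoff;
    bool ss = a.is_cys[i] && a.is_cys[j];
    if (!ss && r2 >= rc2) return;
    double r = std::sqrt(r2), dvdr;
    double v = ss ? softcore_e(r, p.sigma, p.epsilon, p.lj_cutoff,
                               p.crossover, &dvdr)
                  : lj_e(r, p.sigma, p.epsilon, p.lj_cutoff, &dvdr);
    e += v;
    if (f && r > 0) {
      double c = dvdr / r;
      addf(i, c * dx, c * dy, c * dz);
      addf(j, -c * dx, -c * dy, -c * dz);
    }
  };
  if (a.pairs) {
    for (const auto& pr : *a.pairs) nb_pair(pr.first, pr.second);
  } else {
    for (int i = 0; i < n; ++i)
      for (int j = i + 3; j < n; ++j) nb_pair(i, j);
  }

  // native-contact Gaussian wells (structure-based folded stand-in)
  if (a.contacts && a.n_contacts > 0 && p.contact_epsilon > 0) {
    const int m = a.n_contacts;
    const double w2 = p.contact_width * p.contact_width;
    for (int c = 0; c < m; ++c) {
      int i = (int)a.contacts[c] - 1;
      int j = (int)a.contacts[c + m] - 1;
      double d0 = a.contacts[c + 2 * m];
      if (!included2(a.mask, i, j)) continue;
      double dx = fx(j) - fx(i), dy = fy(j) - fy(i), dz = fz(j) - fz(i);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      double dr = r - d0;
      if (dr > 6.0 * p.contact_width) continue;  // ruptured, negligible tail
      double g = std::exp(-0.5 * dr * dr / w2);
      e += -p.contact_epsilon * g;
      if (f && r > 0) {
        double dvdr = p.contact_epsilon * g * dr / w2;
        double cc = dvdr / r;
        addf(i, cc * dx, cc * dy, cc * dz);
        addf(j, -cc * dx, -cc * dy, -cc * dz);
      }
    }
  }

  // disulfide crosslink restraint
  if (a.ss_i >= 0 && a.ss_j >= 0 && included2(a.mask, a.ss_i, a.ss_j)) {
    int i = a.ss_i, j = a.ss_j;
    double dx = fx(j) - fx(i), dy = fy(j) - fy(i), dz = fz(j) - fz(i);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dr = r - p.crosslink_r0;
    e += 0.5 * p.crosslink_k * dr * dr;
    if (f && r > 0) {
      double c = p.crosslink_k * dr / r;
      addf(i, c * dx, c * dy, c * dz);
      addf(j, -c * dx, -c * dy, -c * dz);
    }
  }

  // constant pulling force on the pulled bead along the axis
  if (a.force_kj != 0.0 && a.pulled >= 0) {
    int pI = a.pulled, fI = a.fixed;
    bool inc = (fI >= 0) ? included2(a.mask, pI, fI)
                         : (a.mask == nullptr || a.mask[pI]);
    if (inc) {
      double proj = fx(pI) * a.axis[0] + fy(pI) * a.axis[1] +
                    fz(pI) * a.axis[2];
      if (fI >= 0)
        proj -= fx(fI) * a.axis[0] + fy(fI) * a.axis[1] + fz(fI) * a.axis[2];
      e -= a.force_kj * proj;
      if (f) {
        addf(pI, a.force_kj * a.axis[0], a.force_kj * a.axis[1],
             a.force_kj * a.axis[2]);
        if (fI >= 0)
          addf(fI, -a.force_kj * a.axis[0], -a.force_kj * a.axis[1],
               -a.force_kj * a.axis[2]);
      }
    }
  }
  return e;
}

// Small fast Gaussian RNG for the integrator noise.  Seeded from R's RNG
// (two uniform draws) so trajectories remain bit-reproducible under
// set.seed(); xoshiro256++ with Box-Muller.
struct NoiseRng {
  uint64_t s[4];
  explicit NoiseRng(uint64_t seed) {
    // splitmix64 expansion of the seed
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97f4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
    have_spare = false;
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // in (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  bool have_spare;
  double spare;
  inline double norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u = unif(), v = unif();
    double r = std::sqrt(-2.0 * std::log(u));
    double a = 2.0 * M_PI * v;
    spare = r * std::sin(a);
    have_spare = true;
    return r * std::cos(a);
  }
};

}  // namespace

// [[Rcpp::export]]
double cpp_lj(double r, double sigma, double epsilon, double cutoff) {
  if (r <= 0) stop("lj: r must be positive");
  double d;
  return lj_e(r, sigma, epsilon, cutoff, &d);
}

// [[Rcpp::export]]
double cpp_softcore(double r, double sigma, double epsilon, double cutoff,
                    double crossover) {
  if (r < 0) stop("softcore_lj: r must be non-negative");
  double d;
  return softcore_e(r, sigma, epsilon, cutoff, crossover, &d);
}

// [[Rcpp::export]]
double cpp_softcore_force(double r, double sigma, double epsilon,
                          double cutoff, double crossover) {
  double d;
  softcore_e(r, sigma, epsilon, cutoff, crossover, &d);
  return -d;
}

static std::vector<char> mask_from(Nullable<LogicalVector> m, int n) {
  std::vector<char> out;
  if (m.isNotNull()) {
    LogicalVector mm(m);
    if ((int)mm.size() != n) stop("mask length mismatch");
    out.resize(n);
    for (int i = 0; i < n; ++i) out[i] = mm[i] == TRUE;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_energy(NumericMatrix coords, IntegerVector is_cys, IntegerVector ss,
                List params, double force_kj, NumericVector axis, int fixed,
                int pulled, Nullable<LogicalVector> mask,
                NumericMatrix contacts) {
  int n = coords.nrow();
  Params p = read_params(params);
  std::vector<char> mk = mask_from(mask, n);
  EFArgs a;
  a.x = coords.begin(); a.n = n; a.is_cys = is_cys.begin();
  a.ss_i = ss.size() == 2 ? ss[0] - 1 : -1;
  a.ss_j = ss.size() == 2 ? ss[1] - 1 : -1;
  a.par = &p; a.force_kj = force_kj; a.axis = axis.begin();
  a.fixed = fixed - 1; a.pulled = pulled - 1;
  a.mask = mk.empty() ? nullptr : mk.data();
  a.pairs = nullptr;
  a.contacts = contacts.nrow() > 0 ? contacts.begin() : nullptr;
  a.n_contacts = contacts.nrow();
  NumericMatrix f(n, 3);
  double e = energy_forces(a, f.begin());
  return List::create(_["energy"] = e, _["forces"] = f);
}

// Steepest descent with frozen environment: only `mobile` beads move; the
// objective is the mobile-subsystem energy (terms touching >= 1 mobile bead).
// [[Rcpp::export]]
List cpp_minimize(NumericMatrix coords, IntegerVector is_cys,
                  IntegerVector ss, List params, double force_kj,
                  NumericVector axis, int fixed, int pulled,
                  LogicalVector mobile, double tol, int max_steps,
                  double init_step, NumericMatrix contacts) {
  int n = coords.nrow();
  Params p = read_params(params);
  std::vector<char> mk(n);
  for (int i = 0; i < n; ++i) mk[i] = mobile[i] == TRUE;
  NumericMatrix x = clone(coords);
  EFArgs a;
  a.x = x.begin(); a.n = n; a.is_cys = is_cys.begin();
  a.ss_i = ss.size() == 2 ? ss[0] - 1 : -1;
  a.ss_j = ss.size() == 2 ? ss[1] - 1 : -1;
  a.par = &p; a.force_kj = force_kj; a.axis = axis.begin();
  a.fixed = fixed - 1; a.pulled = pulled - 1;
  a.mask = mk.data(); a.pairs = nullptr;
  a.contacts = contacts.nrow() > 0 ? contacts.begin() : nullptr;
  a.n_contacts = contacts.nrow();

  std::vector<double> f(3 * n), xtry(3 * n);
  double e = energy_forces(a, f.data());
  double h = init_step;
  int it = 0;
  bool converged = false;
  for (; it < max_steps; ++it) {
    double fmax = 0.0;
    for (int i = 0; i < n; ++i) {
      if (!mk[i]) continue;
      double fn = std::sqrt(f[i] * f[i] + f[i + n] * f[i + n] +
                            f[i + 2 * n] * f[i + 2 * n]);
      if (fn > fmax) fmax = fn;
    }
    if (fmax < tol) { converged = true; break; }
    std::copy(x.begin(), x.end(), xtry.begin());
    for (int i = 0; i < n; ++i) {
      if (!mk[i]) continue;
      xtry[i] += h * f[i] / fmax;
      xtry[i + n] += h * f[i + n] / fmax;
      xtry[i + 2 * n] += h * f[i + 2 * n] / fmax;
    }
    EFArgs at = a; at.x = xtry.data();
    std::vector<double> ftry(3 * n);
    double etry = energy_forces(at, ftry.data());
    if (R_finite(etry) && etry < e) {
      std::copy(xtry.begin(), xtry.end(), x.begin());
      f.swap(ftry);
      e = etry;
      h *= 1.2;
    } else {
      h *= 0.2;
      if (h < 1e-9) break;
    }
  }
  return List::create(_["coords"] = x, _["energy"] = e,
                      _["converged"] = converged, _["steps"] = it);
}

// Overdamped Langevin (Brownian) propagation of one trajectory segment.
// Draws its Gaussian noise from R's RNG so runs are reproducible under
// set.seed().  Optionally checks the thiol-disulfide first-passage distance
// criterion after every integration step and returns at the first hit.
// [[Rcpp::export]]
List cpp_run_segment(NumericMatrix coords, IntegerVector is_cys,
                     IntegerVector ss, IntegerVector free_thiols,
                     List params, List cfg, NumericMatrix contacts) {
  int n = coords.nrow();
  Params p = read_params(params);
  double dt = as<double>(cfg["dt"]);
  double gamma = as<double>(cfg["gamma"]);
  double kT = as<double>(cfg["kT"]);
  int n_steps = as<int>(cfg["n_steps"]);
  int stride = as<int>(cfg["stride"]);
  int fixed = as<int>(cfg["fixed"]);       // 1-based, 0 = none
  int pulled = as<int>(cfg["pulled"]);     // 1-based, 0 = none
  NumericVector axis = cfg["axis"];
  double force_kj = as<double>(cfg["force_kj"]);
  double k_fix = as<double>(cfg["k_fix"]);
  NumericVector fixed_ref = cfg["fixed_ref"];
  double max_step = as<double>(cfg["max_step"]);
  bool detect = as<bool>(cfg["detect"]);
  double d_cutoff = as<double>(cfg["d_cutoff"]);
  double t0 = as<double>(cfg["t0"]);
  double skin = as<double>(cfg["skin"]);

  NumericMatrix x = clone(coords);
  EFArgs a;
  a.x = x.begin(); a.n = n; a.is_cys = is_cys.begin();
  a.ss_i = ss.size() == 2 ? ss[0] - 1 : -1;
  a.ss_j = ss.size() == 2 ? ss[1] - 1 : -1;
  a.par = &p; a.force_kj = force_kj; a.axis = axis.begin();
  a.fixed = fixed - 1; a.pulled = pulled - 1;
  a.mask = nullptr;
  a.contacts = contacts.nrow() > 0 ? contacts.begin() : nullptr;
  a.n_contacts = contacts.nrow();

  // Verlet neighbor list
  std::vector<std::pair<int,int> > pairs;
  std::vector<double> xref(3 * n);
  double rlist = p.lj_cutoff + skin;
  double rlist2 = rlist * rlist;
  auto build_list = [&]() {
    pairs.clear();
    for (int i = 0; i < n; ++i)
      for (int j = i + 3; j < n; ++j) {
        double dx = x[j] - x[i], dy = x[j + n] - x[i + n],
               dz = x[j + 2 * n] - x[i + 2 * n];
        if (dx * dx + dy * dy + dz * dz < rlist2)
          pairs.push_back(std::make_pair(i, j));
      }
    std::copy(x.begin(), x.end(), xref.begin());
  };
  auto list_stale = [&]() {
    double lim = 0.25 * skin * skin;  // (skin/2)^2
    for (int i = 0; i < n; ++i) {
      double dx = x[i] - xref[i], dy = x[i + n] - xref[i + n],
             dz = x[i + 2 * n] - xref[i + 2 * n];
      if (dx * dx + dy * dy + dz * dz > lim) return true;
    }
    return false;
  };
  build_list();
  a.pairs = &pairs;

  int max_frames = stride > 0 ? n_steps / stride : 0;
  std::vector<double> frames;
  frames.reserve((size_t)std::max(0, max_frames) * 3 * n);
  std::vector<double> times;

  std::vector<double> f(3 * n);
  double noise_sd = std::sqrt(2.0 * kT * dt / gamma);
  double inv_gamma_dt = dt / gamma;
  // seed the integrator noise stream from R's RNG state
  uint64_t seed_lo = (uint64_t)(unif_rand() * 4294967296.0);
  uint64_t seed_hi = (uint64_t)(unif_rand() * 4294967296.0);
  NoiseRng rng((seed_hi << 32) ^ seed_lo);

  int status = 0;  // 0 completed, 1 event, 2 diverged
  int ev_attacker = -1, ev_target = -1, ev_leaving = -1, ev_step = -1;
  double ev_d = NA_REAL, ev_angle = NA_REAL, ev_time = NA_REAL;
  int steps_done = 0;

  for (int s = 1; s <= n_steps; ++s) {
    if ((s & 7) == 0 && list_stale()) build_list();
    energy_forces(a, f.data());
    // harmonic restraint holding the fixed bead near its reference
    if (a.fixed >= 0 && k_fix > 0) {
      int i = a.fixed;
      f[i] += -k_fix * (x[i] - fixed_ref[0]);
      f[i + n] += -k_fix * (x[i + n] - fixed_ref[1]);
      f[i + 2 * n] += -k_fix * (x[i + 2 * n] - fixed_ref[2]);
    }
    bool bad = false;
    for (int i = 0; i < n; ++i) {
      double dx = f[i] * inv_gamma_dt + noise_sd * rng.norm();
      double dy = f[i + n] * inv_gamma_dt + noise_sd * rng.norm();
      double dz = f[i + 2 * n] * inv_gamma_dt + noise_sd * rng.norm();
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > max_step * max_step) {
        double sc = max_step / std::sqrt(d2);
        dx *= sc; dy *= sc; dz *= sc;
      }
      x[i] += dx; x[i + n] += dy; x[i + 2 * n] += dz;
      if (!R_finite(x[i]) || !R_finite(x[i + n]) || !R_finite(x[i + 2 * n]))
        bad = true;
    }
    steps_done = s;
    if (bad) { status = 2; ev_step = s; break; }
    if (stride > 0 && s % stride == 0) {
      frames.insert(frames.end(), x.begin(), x.end());
      times.push_back(t0 + s * dt);
    }
    if (detect && a.ss_i >= 0) {
      double best = d_cutoff * d_cutoff;
      int batt = -1, btgt = -1;
      for (int k = 0; k < free_thiols.size(); ++k) {
        int ft = free_thiols[k] - 1;
        int mm[2] = {a.ss_i, a.ss_j};
        for (int m = 0; m < 2; ++m) {
          int t = mm[m];
          double dx = x[ft] - x[t], dy = x[ft + n] - x[t + n],
                 dz = x[ft + 2 * n] - x[t + 2 * n];
          double d2 = dx * dx + dy * dy + dz * dz;
          if (d2 < best) { best = d2; batt = ft; btgt = t; }
        }
      }
      if (batt >= 0) {
        status = 1;
        ev_attacker = batt + 1;
        ev_target = btgt + 1;
        ev_leaving = (btgt == a.ss_i ? a.ss_j : a.ss_i) + 1;
        ev_d = std::sqrt(best);
        ev_step = s;
        ev_time = t0 + s * dt;
        // attack angle: attacker - target - leaving at the attacked sulfur
        int at = batt, tg = btgt, lv = ev_leaving - 1;
        double ux = x[at] - x[tg], uy = x[at + n] - x[tg + n],
               uz = x[at + 2 * n] - x[tg + 2 * n];
        double vx = x[lv] - x[tg], vy = x[lv + n] - x[tg + n],
               vz = x[lv + 2 * n] - x[tg + 2 * n];
        double nu = std::sqrt(ux * ux + uy * uy + uz * uz);
        double nv = std::sqrt(vx * vx + vy * vy + vz * vz);
        if (nu > 0 && nv > 0) {
          double ct = (ux * vx + uy * vy + uz * vz) / (nu * nv);
          ct = std::max(-1.0, std::min(1.0, ct));
          ev_angle = std::acos(ct) * 180.0 / M_PI;
        }
        break;
      }
    }
  }

  int nf = (int)times.size();
  NumericVector fr(frames.begin(), frames.end());
  // frames are stored frame-major: column f of the (3n x nf) matrix is the
  // flattened column-major (x, y, z) coordinate block of frame f
  if (nf > 0) fr.attr("dim") = IntegerVector::create(3 * n, nf);
  List event = R_NilValue;
  if (status == 1)
    event = List::create(_["step"] = ev_step, _["time"] = ev_time,
                         _["attacker"] = ev_attacker,
                         _["target"] = ev_target, _["leaving"] = ev_leaving,
                         _["d_ss"] = ev_d, _["angle"] = ev_angle);
  return List::create(_["frames"] = fr, _["times"] = NumericVector(times.begin(), times.end()),
                      _["coords"] = x, _["status"] = status,
                      _["event"] = event, _["steps_done"] = steps_done);
}
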