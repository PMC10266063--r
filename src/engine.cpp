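// Langevin dynamics core for sticker-spacer bead polymers.
//
// Internal units: length nm, energy kB*T0 (T0 the force-field reference
// temperature), time ns, mass kB*T0 * ns^2 / nm^2.  With the default bead
// mass m = 1 and velocity relaxation time tau_v = 1 ns the friction is
// zeta = m / tau_v = 1 and thermal velocities are sqrt(T/T0) nm/ns.
//
// Interactions:
//   bond  (consecutive beads): U = -K R0^2/2 * log(1 - r^2/R0^2)
//   A-B   attraction:          U = -U0/2 * (1 + cos(pi r / d)),  r < d
//   same-type repulsion (WCA): U = 4 eps [ (d/r)^12 - (d/r)^6 + 1/4 ], r < 2^(1/6) d
// A-B pairs have no excluded volume: bound stickers may overlap in space.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: xoshiro256** seeded by splitmix64, Box-Muller normals.  Fixed
// algorithm so trajectories are bit-reproducible across platforms for a
// given integer seed, independent of R's RNG state.
struct Xoshiro {
  uint64_t s[4];
  bool have_cached;
  double cached;
  explicit Xoshiro(uint64_t seed) : have_cached(false), cached(0.0) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97f4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[1] * 5, 7) * 9;
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double norm() {
    if (have_cached) { have_cached = false; return cached; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 6.283185307179586476925286766559 * u2;
    cached = r * std::sin(a);
    have_cached = true;
    return r * std::cos(a);
  }
};

// Marsaglia-Tsang ziggurat for standard normals (128 layers); much faster
// than Box-Muller for the per-step thermostat noise.
struct Ziggurat {
  uint32_t kn[128];
  double wn[128], fn[128];
  static constexpr double R = 3.442619855899;
  Ziggurat() {
    const double m1 = 2147483648.0;
    double dn = R, tn = R, vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (uint32_t)((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; --i) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (uint32_t)((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }
  inline double sample(Xoshiro &rng) {
    for (;;) {
      uint32_t u = (uint32_t)(rng.next() >> 32);
      int32_t hz = (int32_t)u;
      int iz = hz & 127;
      uint32_t iabs = (hz < 0) ? (uint32_t)(-(int64_t)hz) : (uint32_t)hz;
      if (iabs < kn[iz]) return hz * wn[iz];
      if (iz == 0) {  // tail
        double x, y;
        do {
          x = -std::log(rng.unif()) / R;
          y = -std::log(rng.unif());
        } while (y + y < x * x);
        return (hz > 0) ? R + x : -(R + x);
      }
      double x = hz * wn[iz];
      if (fn[iz] + rng.unif() * (fn[iz - 1] - fn[iz]) <
          std::exp(-0.5 * x * x))
        return x;
    }
  }
};

// ---------------------------------------------------------------------------
struct Params {
  double K, R0, U0, d, eps, dt, tau_v, mass;
  bool exclude_bonded;
};

struct System {
  int n;
  std::vector<double> x, y, z;    // unwrapped positions
  std::vector<double> vx, vy, vz;
  std::vector<int> type;          // 1 = A, 2 = B
  std::vector<int> b1, b2;        // bond index pairs (0-based)
  std::vector<int> partner1, partner2;  // bonded partners per bead (-1 none)
  double box[3];
  double ibox[3];                 // 1 / box
};

// round-to-nearest that the compiler can inline (std::nearbyint must honor
// the FP rounding mode and compiles to a libm call on this toolchain)
static inline double rnear(double x) { return std::floor(x + 0.5); }

static inline double wrap0(double u, double L) {
  double w = u - L * std::floor(u / L);
  if (w >= L) w = 0.0;
  return w;
}

// Force accumulation + potential energy + per-axis pair virial
// W_j = sum over pairs of dr_j * F_ij,j (dr = r_i - r_j, F on bead i).
struct ForceResult {
  std::vector<double> fx, fy, fz;
  double energy;
  double virial[3];
  bool bond_error;      // a bond reached R0
  bool overlap_error;   // same-type pair at zero separation
};

static void accumulate_pair(const System &sys, const Params &p,
                            int i, int j, double u0_scale,
                            ForceResult &res, bool clamp,
                            bool want_energy) {
  double dxv = sys.x[i] - sys.x[j];
  double dyv = sys.y[i] - sys.y[j];
  double dzv = sys.z[i] - sys.z[j];
  dxv -= sys.box[0] * rnear(dxv * sys.ibox[0]);
  dyv -= sys.box[1] * rnear(dyv * sys.ibox[1]);
  dzv -= sys.box[2] * rnear(dzv * sys.ibox[2]);
  double r2 = dxv * dxv + dyv * dyv + dzv * dzv;
  double d2 = p.d * p.d;
  bool same = (sys.type[i] == sys.type[j]);
  double fdivr;  // (-dU/dr)/r so F_i = fdivr * dr

  if (same) {
    double rcut2 = 1.2599210498948732 * d2;  // (2^(1/6) d)^2
    if (r2 >= rcut2) return;
    if (r2 < 1e-24) {
      if (clamp) r2 = 1e-6;
      else { res.overlap_error = true; return; }
    }
    if (clamp && r2 < 0.49 * d2) r2 = 0.49 * d2;  // minimizer only
    double inv_r2 = 1.0 / r2;
    double sr2 = d2 * inv_r2;
    double sr6 = sr2 * sr2 * sr2;
    fdivr = 24.0 * p.eps * (2.0 * sr6 * sr6 - sr6) * inv_r2;
    if (want_energy)
      res.energy += 4.0 * p.eps * (sr6 * sr6 - sr6 + 0.25);
  } else {
    if (r2 >= d2) return;
    double u0 = p.U0 * u0_scale;
    if (u0 == 0.0) return;
    double r = std::sqrt(r2);
    double c = 3.14159265358979323846 / p.d;
    // sin(c r)/r -> c as r -> 0: force vanishes smoothly at overlap
    fdivr = (r > 1e-12) ? -0.5 * u0 * c * std::sin(c * r) / r
                        : -0.5 * u0 * c * c;
    if (want_energy)
      res.energy += -0.5 * u0 * (1.0 + std::cos(c * r));
  }
  double fxp = fdivr * dxv, fyp = fdivr * dyv, fzp = fdivr * dzv;
  res.fx[i] += fxp; res.fy[i] += fyp; res.fz[i] += fzp;
  res.fx[j] -= fxp; res.fy[j] -= fyp; res.fz[j] -= fzp;
  res.virial[0] += dxv * fxp;
  res.virial[1] += dyv * fyp;
  res.virial[2] += dzv * fzp;
}

static void accumulate_bonds(const System &sys, const Params &p,
                             ForceResult &res, bool want_energy) {
  double R02 = p.R0 * p.R0;
  for (size_t k = 0; k < sys.b1.size(); ++k) {
    int i = sys.b1[k], j = sys.b2[k];
    double dxv = sys.x[i] - sys.x[j];
    double dyv = sys.y[i] - sys.y[j];
    double dzv = sys.z[i] - sys.z[j];
    dxv -= sys.box[0] * rnear(dxv * sys.ibox[0]);
    dyv -= sys.box[1] * rnear(dyv * sys.ibox[1]);
    dzv -= sys.box[2] * rnear(dzv * sys.ibox[2]);
    double r2 = dxv * dxv + dyv * dyv + dzv * dzv;
    if (r2 >= R02) { res.bond_error = true; return; }
    if (want_energy)
      res.energy += -0.5 * p.K * R02 * std::log(1.0 - r2 / R02);
    double fdivr = -p.K * R02 / (R02 - r2);  // (-dU/dr)/r
    double fxp = fdivr * dxv, fyp = fdivr * dyv, fzp = fdivr * dzv;
    res.fx[i] += fxp; res.fy[i] += fyp; res.fz[i] += fzp;
    res.fx[j] -= fxp; res.fy[j] -= fyp; res.fz[j] -= fzp;
    res.virial[0] += dxv * fxp;
    res.virial[1] += dyv * fyp;
    res.virial[2] += dzv * fzp;
  }
}

static void compute_forces(const System &sys, const Params &p,
                           double u0_scale, ForceResult &res,
                           bool clamp = false, bool want_energy = true) {
  int n = sys.n;
  res.fx.assign(n, 0.0); res.fy.assign(n, 0.0); res.fz.assign(n, 0.0);
  res.energy = 0.0;
  res.virial[0] = res.virial[1] = res.virial[2] = 0.0;
  res.bond_error = false;
  res.overlap_error = false;

  accumulate_bonds(sys, p, res, want_energy);
  if (res.bond_error) return;

  // nonbonded via cell list (rebuilt every call: cutoffs ~ bead size make it cheap)
  double rcut = 1.1224620483089301 * p.d;
  int nc[3];
  for (int a = 0; a < 3; ++a)
    nc[a] = std::max(1, (int)std::floor(sys.box[a] / rcut));
  bool brute = (nc[0] < 3 || nc[1] < 3 || nc[2] < 3 || n < 32);

  if (brute) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        if (p.exclude_bonded &&
            (sys.partner1[i] == j || sys.partner2[i] == j)) continue;
        accumulate_pair(sys, p, i, j, u0_scale, res, clamp, want_energy);
        if (res.overlap_error) return;
      }
    return;
  }

  int ncell = nc[0] * nc[1] * nc[2];
  std::vector<int> head(ncell, -1), nxt(n, -1), cx_(n), cy_(n), cz_(n);
  for (int i = 0; i < n; ++i) {
    int cx = (int)(wrap0(sys.x[i], sys.box[0]) / sys.box[0] * nc[0]);
    int cy = (int)(wrap0(sys.y[i], sys.box[1]) / sys.box[1] * nc[1]);
    int cz = (int)(wrap0(sys.z[i], sys.box[2]) / sys.box[2] * nc[2]);
    if (cx >= nc[0]) cx = nc[0] - 1;
    if (cy >= nc[1]) cy = nc[1] - 1;
    if (cz >= nc[2]) cz = nc[2] - 1;
    cx_[i] = cx; cy_[i] = cy; cz_[i] = cz;
    int c = (cz * nc[1] + cy) * nc[0] + cx;
    nxt[i] = head[c];
    head[c] = i;
  }
  // atom-centric scan of the 27 neighbour cells, pair counted once (j > i)
  for (int i = 0; i < n; ++i) {
    for (int dz = -1; dz <= 1; ++dz) {
      int oz = cz_[i] + dz;
      oz = (oz < 0) ? oz + nc[2] : (oz >= nc[2] ? oz - nc[2] : oz);
      for (int dy = -1; dy <= 1; ++dy) {
        int oy = cy_[i] + dy;
        oy = (oy < 0) ? oy + nc[1] : (oy >= nc[1] ? oy - nc[1] : oy);
        for (int dx = -1; dx <= 1; ++dx) {
          int ox = cx_[i] + dx;
          ox = (ox < 0) ? ox + nc[0] : (ox >= nc[0] ? ox - nc[0] : ox);
          int c2 = (oz * nc[1] + oy) * nc[0] + ox;
          for (int j = head[c2]; j != -1; j = nxt[j]) {
            if (j <= i) continue;
            if (p.exclude_bonded &&
                (sys.partner1[i] == j || sys.partner2[i] == j)) continue;
            accumulate_pair(sys, p, i, j, u0_scale, res, clamp, want_energy);
            if (res.overlap_error) return;
          }
        }
      }
    }
  }
}

// ---------------------------------------------------------------------------
// Verlet neighbour list with skin: candidate pairs within rcut + skin,
// rebuilt when any bead has moved more than skin/2 since the last build.
struct NeighborList {
  std::vector<int> pi, pj;
  std::vector<double> bx, by, bz;  // positions at build time
  double skin = 0.3;
};

static void build_neighbor_list(const System &sys, const Params &p,
                                NeighborList &nl) {
  int n = sys.n;
  double rlist = 1.1224620483089301 * p.d + nl.skin;
  double rlist2 = rlist * rlist;
  nl.pi.clear();
  nl.pj.clear();
  nl.bx.assign(sys.x.begin(), sys.x.end());
  nl.by.assign(sys.y.begin(), sys.y.end());
  nl.bz.assign(sys.z.begin(), sys.z.end());

  int nc[3];
  for (int a = 0; a < 3; ++a)
    nc[a] = std::max(1, (int)std::floor(sys.box[a] / rlist));
  bool brute = (nc[0] < 3 || nc[1] < 3 || nc[2] < 3 || n < 32);

  auto consider = [&](int i, int j) {
    if (p.exclude_bonded &&
        (sys.partner1[i] == j || sys.partner2[i] == j)) return;
    double dxv = sys.x[i] - sys.x[j];
    double dyv = sys.y[i] - sys.y[j];
    double dzv = sys.z[i] - sys.z[j];
    dxv -= sys.box[0] * rnear(dxv / sys.box[0]);
    dyv -= sys.box[1] * rnear(dyv / sys.box[1]);
    dzv -= sys.box[2] * rnear(dzv / sys.box[2]);
    if (dxv * dxv + dyv * dyv + dzv * dzv < rlist2) {
      nl.pi.push_back(i);
      nl.pj.push_back(j);
    }
  };

  if (brute) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) consider(i, j);
    return;
  }
  int ncell = nc[0] * nc[1] * nc[2];
  std::vector<int> head(ncell, -1), nxt(n, -1), cx_(n), cy_(n), cz_(n);
  for (int i = 0; i < n; ++i) {
    int cx = (int)(wrap0(sys.x[i], sys.box[0]) / sys.box[0] * nc[0]);
    int cy = (int)(wrap0(sys.y[i], sys.box[1]) / sys.box[1] * nc[1]);
    int cz = (int)(wrap0(sys.z[i], sys.box[2]) / sys.box[2] * nc[2]);
    if (cx >= nc[0]) cx = nc[0] - 1;
    if (cy >= nc[1]) cy = nc[1] - 1;
    if (cz >= nc[2]) cz = nc[2] - 1;
    cx_[i] = cx; cy_[i] = cy; cz_[i] = cz;
    int c = (cz * nc[1] + cy) * nc[0] + cx;
    nxt[i] = head[c];
    head[c] = i;
  }
  for (int i = 0; i < n; ++i)
    for (int dz = -1; dz <= 1; ++dz) {
      int oz = cz_[i] + dz;
      oz = (oz < 0) ? oz + nc[2] : (oz >= nc[2] ? oz - nc[2] : oz);
      for (int dy = -1; dy <= 1; ++dy) {
        int oy = cy_[i] + dy;
        oy = (oy < 0) ? oy + nc[1] : (oy >= nc[1] ? oy - nc[1] : oy);
        for (int dx = -1; dx <= 1; ++dx) {
          int ox = cx_[i] + dx;
          ox = (ox < 0) ? ox + nc[0] : (ox >= nc[0] ? ox - nc[0] : ox);
          int c2 = (oz * nc[1] + oy) * nc[0] + ox;
          for (int j = head[c2]; j != -1; j = nxt[j])
            if (j > i) consider(i, j);
        }
      }
    }
}

static bool list_stale(const System &sys, const NeighborList &nl) {
  double lim2 = 0.25 * nl.skin * nl.skin;
  for (int i = 0; i < sys.n; ++i) {
    double dx = sys.x[i] - nl.bx[i];
    double dy = sys.y[i] - nl.by[i];
    double dz = sys.z[i] - nl.bz[i];
    if (dx * dx + dy * dy + dz * dz > lim2) return true;
  }
  return false;
}

static void compute_forces_listed(const System &sys, const Params &p,
                                  double u0_scale, const NeighborList &nl,
                                  ForceResult &res,
                                  bool want_energy = true) {
  int n = sys.n;
  res.fx.assign(n, 0.0); res.fy.assign(n, 0.0); res.fz.assign(n, 0.0);
  res.energy = 0.0;
  res.virial[0] = res.virial[1] = res.virial[2] = 0.0;
  res.bond_error = false;
  res.overlap_error = false;
  accumulate_bonds(sys, p, res, want_energy);
  if (res.bond_error) return;
  size_t np = nl.pi.size();
  for (size_t k = 0; k < np; ++k) {
    accumulate_pair(sys, p, nl.pi[k], nl.pj[k], u0_scale, res, false,
                    want_energy);
    if (res.overlap_error) return;
  }
}

// ---------------------------------------------------------------------------
static System make_system(NumericMatrix pos, NumericMatrix vel,
                          IntegerVector type, IntegerMatrix bonds,
                          NumericVector box) {
  System sys;
  sys.n = pos.nrow();
  sys.x.resize(sys.n); sys.y.resize(sys.n); sys.z.resize(sys.n);
  sys.vx.assign(sys.n, 0.0); sys.vy.assign(sys.n, 0.0); sys.vz.assign(sys.n, 0.0);
  for (int i = 0; i < sys.n; ++i) {
    sys.x[i] = pos(i, 0); sys.y[i] = pos(i, 1); sys.z[i] = pos(i, 2);
  }
  if (vel.nrow() == sys.n)
    for (int i = 0; i < sys.n; ++i) {
      sys.vx[i] = vel(i, 0); sys.vy[i] = vel(i, 1); sys.vz[i] = vel(i, 2);
    }
  sys.type.assign(type.begin(), type.end());
  sys.partner1.assign(sys.n, -1);
  sys.partner2.assign(sys.n, -1);
  for (int k = 0; k < bonds.nrow(); ++k) {
    int i = bonds(k, 0) - 1, j = bonds(k, 1) - 1;  // 1-based from R
    sys.b1.push_back(i); sys.b2.push_back(j);
    if (sys.partner1[i] < 0) sys.partner1[i] = j; else sys.partner2[i] = j;
    if (sys.partner1[j] < 0) sys.partner1[j] = i; else sys.partner2[j] = i;
  }
  sys.box[0] = box[0]; sys.box[1] = box[1]; sys.box[2] = box[2];
  for (int a = 0; a < 3; ++a) sys.ibox[a] = 1.0 / sys.box[a];
  return sys;
}

static Params make_params(List ff, double dt, double tau_v, double mass,
                          bool exclude_bonded) {
  Params p;
  p.K = as<double>(ff["k"]);
  p.R0 = as<double>(ff["r0"]);
  p.U0 = as<double>(ff["u0"]);
  p.d = as<double>(ff["d_bead"]);
  p.eps = as<double>(ff["eps"]);
  p.dt = dt; p.tau_v = tau_v; p.mass = mass;
  p.exclude_bonded = exclude_bonded;
  return p;
}

// [[Rcpp::export]]
List cpp_forces(NumericMatrix pos, IntegerVector type, IntegerMatrix bonds,
                NumericVector box, List ff, double u0_scale,
                bool exclude_bonded) {
  NumericMatrix novel(0, 3);
  System sys = make_system(pos, novel, type, bonds, box);
  Params p = make_params(ff, 0.0, 1.0, 1.0, exclude_bonded);
  ForceResult res;
  compute_forces(sys, p, u0_scale, res);
  if (res.bond_error) stop("bond extension reached R0 (diverging bond)");
  if (res.overlap_error) stop("singular overlap: same-type beads at zero separation");
  NumericMatrix f(sys.n, 3);
  for (int i = 0; i < sys.n; ++i) {
    f(i, 0) = res.fx[i]; f(i, 1) = res.fy[i]; f(i, 2) = res.fz[i];
  }
  return List::create(_["forces"] = f, _["energy"] = res.energy,
                      _["virial"] = NumericVector::create(
                        res.virial[0], res.virial[1], res.virial[2]));
}

// Capped steepest-descent relaxation (for slab initialization).
// [[Rcpp::export]]
NumericMatrix cpp_minimize(NumericMatrix pos, IntegerVector type,
                           IntegerMatrix bonds, NumericVector box, List ff,
                           double u0_scale, bool exclude_bonded,
                           int max_steps, double max_disp) {
  NumericMatrix novel(0, 3);
  System sys = make_system(pos, novel, type, bonds, box);
  Params p = make_params(ff, 0.0, 1.0, 1.0, exclude_bonded);
  ForceResult res;
  for (int step = 0; step < max_steps; ++step) {
    compute_forces(sys, p, u0_scale, res, true);
    double fmax = 0.0;
    for (int i = 0; i < sys.n; ++i) {
      double f2 = res.fx[i] * res.fx[i] + res.fy[i] * res.fy[i] +
                  res.fz[i] * res.fz[i];
      if (f2 > fmax) fmax = f2;
    }
    fmax = std::sqrt(fmax);
    if (fmax < 1e-4) break;
    double scale = max_disp / std::max(fmax, 1e-12);
    if (scale > 0.02) scale = 0.02;
    for (int i = 0; i < sys.n; ++i) {
      sys.x[i] += scale * res.fx[i];
      sys.y[i] += scale * res.fy[i];
      sys.z[i] += scale * res.fz[i];
    }
  }
  NumericMatrix out(sys.n, 3);
  for (int i = 0; i < sys.n; ++i) {
    out(i, 0) = sys.x[i]; out(i, 1) = sys.y[i]; out(i, 2) = sys.z[i];
  }
  return out;
}

// BAOAB Langevin integrator.  temp_rel = T / T0 (thermal energy in kB*T0
// units).  thermostat = false gives velocity-Verlet NVE (used to check
// energy conservation).  wall_half > 0 adds reflective walls on x at
// box_x/2 +- wall_half (slab confinement stage).  u0 ramps linearly from
// u0_begin to u0_end over the run.
// [[Rcpp::export]]
List cpp_run_langevin(NumericMatrix pos, NumericMatrix vel, IntegerVector type,
                      IntegerMatrix bonds, NumericVector box, List ff,
                      double temp_rel, double dt, double tau_v, double mass,
                      double u0_begin, double u0_end, int n_steps,
                      int sample_every, bool save_frames, bool thermostat,
                      bool exclude_bonded, double wall_half, double t_start,
                      int seed) {
  System sys = make_system(pos, vel, type, bonds, box);
  Params p = make_params(ff, dt, tau_v, mass, exclude_bonded);
  Xoshiro rng((uint64_t)seed);

  double V = box[0] * box[1] * box[2];
  double cx = box[0] / 2.0;
  double c1 = thermostat ? std::exp(-dt / tau_v) : 1.0;
  double c2 = thermostat ? std::sqrt((1.0 - c1 * c1) * temp_rel / mass) : 0.0;

  Ziggurat zig;
  NeighborList nl;
  build_neighbor_list(sys, p, nl);
  ForceResult res;
  compute_forces_listed(sys, p, u0_begin, nl, res);
  if (res.bond_error) stop("bond extension reached R0 at start");
  if (res.overlap_error) stop("singular overlap at start");

  int n_samples = (sample_every > 0) ? n_steps / sample_every : 0;
  NumericMatrix pressure(n_samples, 7);
  NumericVector ekin_trace(n_samples), epot_trace(n_samples);
  List frames(save_frames ? n_samples : 0);
  NumericVector frame_times(save_frames ? n_samples : 0);
  int isamp = 0;
  bool aborted = false;
  int abort_step = -1;

  for (int step = 1; step <= n_steps; ++step) {
    double u0s = (n_steps > 1)
      ? u0_begin + (u0_end - u0_begin) * (double)step / (double)n_steps
      : u0_end;
    // B
    double h = 0.5 * dt / mass;
    for (int i = 0; i < sys.n; ++i) {
      sys.vx[i] += h * res.fx[i];
      sys.vy[i] += h * res.fy[i];
      sys.vz[i] += h * res.fz[i];
    }
    // A
    for (int i = 0; i < sys.n; ++i) {
      sys.x[i] += 0.5 * dt * sys.vx[i];
      sys.y[i] += 0.5 * dt * sys.vy[i];
      sys.z[i] += 0.5 * dt * sys.vz[i];
    }
    // O
    if (thermostat)
      for (int i = 0; i < sys.n; ++i) {
        sys.vx[i] = c1 * sys.vx[i] + c2 * zig.sample(rng);
        sys.vy[i] = c1 * sys.vy[i] + c2 * zig.sample(rng);
        sys.vz[i] = c1 * sys.vz[i] + c2 * zig.sample(rng);
      }
    // A
    for (int i = 0; i < sys.n; ++i) {
      sys.x[i] += 0.5 * dt * sys.vx[i];
      sys.y[i] += 0.5 * dt * sys.vy[i];
      sys.z[i] += 0.5 * dt * sys.vz[i];
    }
    if (wall_half > 0.0)
      for (int i = 0; i < sys.n; ++i) {
        double rel = sys.x[i] - cx;
        if (rel > wall_half) {
          sys.x[i] = cx + 2.0 * wall_half - rel;
          sys.vx[i] = -sys.vx[i];
        } else if (rel < -wall_half) {
          sys.x[i] = cx - 2.0 * wall_half - rel;
          sys.vx[i] = -sys.vx[i];
        }
      }
    // B with new forces
    bool sampling = (sample_every > 0 && step % sample_every == 0);
    if (list_stale(sys, nl)) build_neighbor_list(sys, p, nl);
    compute_forces_listed(sys, p, u0s, nl, res, sampling);
    if (res.bond_error || res.overlap_error) {
      aborted = true;
      abort_step = step;
      break;
    }
    for (int i = 0; i < sys.n; ++i) {
      sys.vx[i] += h * res.fx[i];
      sys.vy[i] += h * res.fy[i];
      sys.vz[i] += h * res.fz[i];
    }

    if (sample_every > 0 && step % sample_every == 0 && isamp < n_samples) {
      double k0 = 0.0, k1 = 0.0, k2 = 0.0;
      for (int i = 0; i < sys.n; ++i) {
        k0 += sys.vx[i] * sys.vx[i];
        k1 += sys.vy[i] * sys.vy[i];
        k2 += sys.vz[i] * sys.vz[i];
      }
      double t_now = t_start + step * dt;
      pressure(isamp, 0) = t_now;
      pressure(isamp, 1) = (mass * k0 + res.virial[0]) / V;
      pressure(isamp, 2) = (mass * k1 + res.virial[1]) / V;
      pressure(isamp, 3) = (mass * k2 + res.virial[2]) / V;
      pressure(isamp, 4) = mass * k0 / V;
      pressure(isamp, 5) = mass * k1 / V;
      pressure(isamp, 6) = mass * k2 / V;
      ekin_trace[isamp] = 0.5 * mass * (k0 + k1 + k2);
      epot_trace[isamp] = res.energy;
      if (save_frames) {
        NumericMatrix fr(sys.n, 3);
        for (int i = 0; i < sys.n; ++i) {
          fr(i, 0) = sys.x[i]; fr(i, 1) = sys.y[i]; fr(i, 2) = sys.z[i];
        }
        frames[isamp] = fr;
        frame_times[isamp] = t_now;
      }
      ++isamp;
    }
    if (step % 200000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix pout(sys.n, 3), vout(sys.n, 3);
  for (int i = 0; i < sys.n; ++i) {
    pout(i, 0) = sys.x[i]; pout(i, 1) = sys.y[i]; pout(i, 2) = sys.z[i];
    vout(i, 0) = sys.vx[i]; vout(i, 1) = sys.vy[i]; vout(i, 2) = sys.vz[i];
  }
  return List::create(
    _["positions"] = pout, _["velocities"] = vout,
    _["pressure"] = pressure, _["ekin"] = ekin_trace, _["epot"] = epot_trace,
    _["frames"] = frames, _["frame_times"] = frame_times,
    _["n_sampled"] = isamp, _["aborted"] = aborted,
    _["abort_step"] = abort_step);
}
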