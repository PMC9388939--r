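// Simplified Monte Carlo photon transport engine.
//
// Physics model: collimated point-ish source -> aperture filtering with
// transmission weights and isotropic head leakage -> Woodcock delta-tracking
// through the voxel phantom against an energy-dependent majorant cross
// section -> Klein-Nishina Compton scattering, photoelectric absorption and
// pair production (two back-to-back 511 keV photons) -> per-organ
// track-length kerma estimation (fluence x E x muen/rho scored at every
// Woodcock collision point, real or virtual) with batch statistics.
// Electrons are never transported: dose is the collision kerma, which
// assumes charged-particle equilibrium.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------- RNG -----
// xoshiro256++ seeded through splitmix64: fast, high quality, and fully
// deterministic across runs on one platform for a given 64-bit seed.
struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
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
  inline double u() {                 // uniform in (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double gauss() {             // Box-Muller, no caching (simplicity)
    double a = u(), b = u();
    return std::sqrt(-2.0 * std::log(a)) * std::cos(2.0 * M_PI * b);
  }
  inline void iso_dir(double& dx, double& dy, double& dz) {
    double ct = 2.0 * u() - 1.0;
    double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
    double ph = 2.0 * M_PI * u();
    dx = st * std::cos(ph); dy = st * std::sin(ph); dz = ct;
  }
};

// ------------------------------------------------------------ tables -----
// log-log interpolation on an irregular grid of log-energies.
struct LogTable {
  const double* logE;
  int n;
  inline double interp(const double* logY, double loge) const {
    if (loge <= logE[0]) return logY[0];
    if (loge >= logE[n - 1]) return logY[n - 1];
    int lo = 0, hi = n - 1;
    while (hi - lo > 1) {
      int mid = (lo + hi) / 2;
      if (logE[mid] <= loge) lo = mid; else hi = mid;
    }
    double f = (loge - logE[lo]) / (logE[lo + 1] - logE[lo]);
    return logY[lo] + f * (logY[lo + 1] - logY[lo]);
  }
};

struct Materials {
  LogTable grid;
  int nmat;
  std::vector<const double*> log_mu;    // per material, length grid.n
  std::vector<const double*> log_muen;
  std::vector<double> density, e_per_g, pe_coef;
  const double* log_mumaj;              // majorant linear attenuation

  inline double mu_rho(int m, double loge) const {
    return std::exp(grid.interp(log_mu[m], loge));
  }
  inline double muen_rho(int m, double loge) const {
    return std::exp(grid.interp(log_muen[m], loge));
  }
  inline double mu_majorant(double loge) const {
    return std::exp(grid.interp(log_mumaj, loge));
  }
};

// Klein-Nishina total cross-section per electron (cm^2), E in MeV.
static inline double kn_total(double E) {
  const double re2 = 7.94079e-26;
  double a = E / 0.51099895;
  double t1 = (1.0 + a) / (a * a) *
              (2.0 * (1.0 + a) / (1.0 + 2.0 * a) - std::log1p(2.0 * a) / a);
  double t2 = std::log1p(2.0 * a) / (2.0 * a);
  double t3 = (1.0 + 3.0 * a) / ((1.0 + 2.0 * a) * (1.0 + 2.0 * a));
  return 2.0 * M_PI * re2 * (t1 + t2 - t3);
}

// Sample the Klein-Nishina scattered-energy fraction and polar angle.
static inline void sample_kn(Rng& rng, double E, double& eps, double& cost) {
  double a = E / 0.51099895;
  double eps0 = 1.0 / (1.0 + 2.0 * a);
  double eps0sq = eps0 * eps0;
  double a1 = -std::log(eps0);
  double a2 = 0.5 * (1.0 - eps0sq);
  double t, greject;
  do {
    if (rng.u() * (a1 + a2) < a1)
      eps = std::exp(-a1 * rng.u());
    else
      eps = std::sqrt(eps0sq + (1.0 - eps0sq) * rng.u());
    t = (1.0 - eps) / (a * eps);
    double sint2 = t * (2.0 - t);
    greject = 1.0 - eps * sint2 / (1.0 + eps * eps);
  } while (rng.u() > greject);
  cost = 1.0 - t;
}

// Rotate direction d by polar angle (cost) about itself with azimuth phi.
static inline void rotate_dir(double& dx, double& dy, double& dz,
                              double cost, double phi) {
  double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
  double cphi = std::cos(phi), sphi = std::sin(phi);
  // build orthonormal basis around d
  double ax, ay, az;
  if (std::fabs(dz) < 0.99) { ax = -dy; ay = dx; az = 0.0; }
  else { ax = 0.0; ay = -dz; az = dy; }
  double an = std::sqrt(ax * ax + ay * ay + az * az);
  ax /= an; ay /= an; az /= an;
  double bx = dy * az - dz * ay;
  double by = dz * ax - dx * az;
  double bz = dx * ay - dy * ax;
  double nx = dx * cost + sint * (cphi * ax + sphi * bx);
  double ny = dy * cost + sint * (cphi * ay + sphi * by);
  double nz = dz * cost + sint * (cphi * az + sphi * bz);
  double nn = std::sqrt(nx * nx + ny * ny + nz * nz);
  dx = nx / nn; dy = ny / nn; dz = nz / nn;
}

struct Particle {
  double x, y, z, dx, dy, dz, E, w;
  bool primary;
};

// interaction channel probabilities from the decomposition
// mu_total = Compton(KN) + photoelectric(E^-3 anchor) + pair(remainder).
static inline void channel_probs(const Materials& M, int m, double E,
                                 double loge, double mu_tot,
                                 double& p_c, double& p_pair) {
  double mu_c = M.e_per_g[m] * kn_total(E);
  if (mu_c > mu_tot) mu_c = mu_tot;
  double mu_pe = M.pe_coef[m] / (E * E * E);
  double mu_pair = 0.0;
  if (E > 1.022) {
    mu_pair = mu_tot - mu_c - mu_pe;
    if (mu_pair < 0.0) mu_pair = 0.0;
  }
  p_c = mu_c / mu_tot;
  p_pair = mu_pair / mu_tot;
  (void)loge;
}

// ------------------------------------------------------- source model ----
struct Source {
  int spec_n;                 // number of spectrum bins (1 = monoenergetic)
  const double* spec_E;
  const double* spec_cdf;
  double focal_sigma;         // cm, lateral Gaussian blur of the focal spot
  double area_scale;          // sampled bbox area / full cone area
  double S[3], u[3], v[3], w[3];
  double bbox[4];             // a_lo, a_hi, b_lo, b_hi at isocenter plane
  double jaw[4];              // x_lo, x_hi, y_lo, y_hi
  int n_strips;
  const double* strips;       // n x 4 (y_lo, y_hi, x_lo, x_hi), column-major
  bool has_mlc;
  double t_mlc, t_jaw, leak;

  inline double sample_E(Rng& rng) const {
    if (spec_n == 1) return spec_E[0];
    double uu = rng.u();
    int lo = 0, hi = spec_n - 1;
    while (hi > lo) {
      int mid = (lo + hi) / 2;
      if (spec_cdf[mid] < uu) lo = mid + 1; else hi = mid;
    }
    return spec_E[lo];
  }

  inline double aperture_weight(double a, double b) const {
    if (a < jaw[0] || a > jaw[1] || b < jaw[2] || b > jaw[3]) return t_jaw;
    if (!has_mlc) return 1.0;
    for (int i = 0; i < n_strips; ++i) {
      double ylo = strips[i], yhi = strips[i + n_strips];
      double xlo = strips[i + 2 * n_strips], xhi = strips[i + 3 * n_strips];
      if (b >= ylo && b <= yhi && a >= xlo && a <= xhi) return 1.0;
    }
    return t_mlc;
  }

  inline Particle emit(Rng& rng) const {
    Particle p;
    p.E = sample_E(rng);
    p.primary = true;
    if (leak > 0.0 && rng.u() < leak) {
      p.x = S[0]; p.y = S[1]; p.z = S[2];
      rng.iso_dir(p.dx, p.dy, p.dz);
      p.w = 1.0;
      return p;
    }
    double a = bbox[0] + (bbox[1] - bbox[0]) * rng.u();
    double b = bbox[2] + (bbox[3] - bbox[2]) * rng.u();
    p.w = aperture_weight(a, b) * area_scale;
    double ja = focal_sigma > 0.0 ? focal_sigma * rng.gauss() : 0.0;
    double jb = focal_sigma > 0.0 ? focal_sigma * rng.gauss() : 0.0;
    double sx = S[0] + ja * u[0] + jb * v[0];
    double sy = S[1] + ja * u[1] + jb * v[1];
    double sz = S[2] + ja * u[2] + jb * v[2];
    double px = a * u[0] + b * v[0];
    double py = a * u[1] + b * v[1];
    double pz = a * u[2] + b * v[2];
    double dx = px - sx, dy = py - sy, dz = pz - sz;
    double n = std::sqrt(dx * dx + dy * dy + dz * dz);
    p.x = sx; p.y = sy; p.z = sz;
    p.dx = dx / n; p.dy = dy / n; p.dz = dz / n;
    return p;
  }
};

static Source unpack_source(const List& src) {
  Source s;
  NumericVector E = src["spec_energy"], cdf = src["spec_cdf"];
  s.spec_n = E.size();
  s.spec_E = REAL(E);
  s.spec_cdf = REAL(cdf);
  s.focal_sigma = as<double>(src["focal_sigma"]);
  s.area_scale = as<double>(src["area_scale"]);
  NumericVector S = src["S"], u = src["u"], v = src["v"], w = src["w"],
                bbox = src["bbox"], jaw = src["jaw"];
  for (int i = 0; i < 3; ++i) {
    s.S[i] = S[i]; s.u[i] = u[i]; s.v[i] = v[i]; s.w[i] = w[i];
  }
  for (int i = 0; i < 4; ++i) { s.bbox[i] = bbox[i]; s.jaw[i] = jaw[i]; }
  NumericMatrix strips = src["strips"];
  s.n_strips = strips.nrow();
  s.strips = s.n_strips ? REAL(strips) : nullptr;
  s.has_mlc = as<bool>(src["has_mlc"]);
  s.t_mlc = as<double>(src["t_mlc"]);
  s.t_jaw = as<double>(src["t_jaw"]);
  s.leak = as<double>(src["leak"]);
  return s;
}

static Materials unpack_materials(const List& mats,
                                  std::vector<NumericVector>& keep_mu,
                                  std::vector<NumericVector>& keep_muen) {
  Materials M;
  NumericVector logE = mats["log_energy"];
  M.grid.logE = REAL(logE);
  M.grid.n = logE.size();
  NumericMatrix lmu = mats["log_mu"], lmuen = mats["log_muen"];
  M.nmat = lmu.nrow();
  keep_mu.clear(); keep_muen.clear();
  for (int m = 0; m < M.nmat; ++m) {
    keep_mu.push_back(NumericVector(lmu.row(m)));
    keep_muen.push_back(NumericVector(lmuen.row(m)));
  }
  for (int m = 0; m < M.nmat; ++m) {
    M.log_mu.push_back(REAL(keep_mu[m]));
    M.log_muen.push_back(REAL(keep_muen[m]));
  }
  M.density = as<std::vector<double>>(mats["density"]);
  M.e_per_g = as<std::vector<double>>(mats["e_per_g"]);
  M.pe_coef = as<std::vector<double>>(mats["pe_coef"]);
  NumericVector lmj = mats["log_mumaj"];
  M.log_mumaj = REAL(lmj);
  return M;
}

// ---------------------------------------------------------- transport ----
struct Grid {
  int nx, ny, nz;
  double ox, oy, oz, vx, vy, vz, ex, ey, ez;   // origin, voxel, extent
  const int* mat;
  const int* lab;
  inline bool inside(const Particle& p) const {
    return p.x > ox && p.x < ox + ex && p.y > oy && p.y < oy + ey &&
           p.z > oz && p.z < oz + ez;
  }
  inline int voxel(const Particle& p) const {
    int i = (int)((p.x - ox) / vx);
    int j = (int)((p.y - oy) / vy);
    int k = (int)((p.z - oz) / vz);
    if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) return -1;
    return i + nx * (j + ny * k);
  }
  // advance particle to the box entry point; false if the ray misses
  bool advance_to_entry(Particle& p) const {
    double t0 = 0.0, t1 = 1e30;
    const double pos[3] = {p.x, p.y, p.z};
    const double dir[3] = {p.dx, p.dy, p.dz};
    const double lo[3] = {ox, oy, oz};
    const double hi[3] = {ox + ex, oy + ey, oz + ez};
    for (int i = 0; i < 3; ++i) {
      if (std::fabs(dir[i]) < 1e-14) {
        if (pos[i] <= lo[i] || pos[i] >= hi[i]) return false;
      } else {
        double ta = (lo[i] - pos[i]) / dir[i];
        double tb = (hi[i] - pos[i]) / dir[i];
        if (ta > tb) std::swap(ta, tb);
        if (ta > t0) t0 = ta;
        if (tb < t1) t1 = tb;
      }
    }
    if (t1 <= t0) return false;
    double t = t0 + 1e-9;
    p.x += t * p.dx; p.y += t * p.dy; p.z += t * p.dz;
    return true;
  }
};

struct VrConfig {
  double cutoff, rr_thresh, rr_surv;
  int split_factor;
  bool absorption_only;
};

// Russian roulette; returns false if the particle was killed.
static inline bool roulette(Rng& rng, Particle& p, const VrConfig& vr) {
  if (p.w >= vr.rr_thresh || p.w <= 0.0) return p.w > 0.0;
  if (rng.u() < vr.rr_surv) { p.w /= vr.rr_surv; return true; }
  return false;
}

// Transport one history (the particle plus any secondaries) through the
// grid, scoring the track-length kerma estimator into `tally` (per label).
static void transport_history(Rng& rng, const Grid& G, const Materials& M,
                              const VrConfig& vr, Particle start,
                              double* tally, double* deposited,
                              double* escaped) {
  std::vector<Particle> stack;
  if (!roulette(rng, start, vr)) return;
  if (vr.split_factor > 1) {
    Particle sub = start;
    sub.w = start.w / vr.split_factor;
    for (int i = 0; i < vr.split_factor; ++i) stack.push_back(sub);
  } else {
    stack.push_back(start);
  }
  int guard = 0;
  while (!stack.empty()) {
    Particle p = stack.back();
    stack.pop_back();
    if (!G.inside(p) && !G.advance_to_entry(p)) {
      if (escaped) *escaped += p.w * p.E;
      continue;
    }
    bool alive = true;
    while (alive) {
      if (++guard > 2000000)
        stop("transport guard tripped: runaway history");
      if (!std::isfinite(p.w) || !std::isfinite(p.x) ||
          !std::isfinite(p.E))
        stop("non-finite particle state (simulation bug trap)");
      double loge = std::log(p.E);
      double mumaj = M.mu_majorant(loge);
      double s = -std::log(rng.u()) / mumaj;
      p.x += s * p.dx; p.y += s * p.dy; p.z += s * p.dz;
      int vox = G.voxel(p);
      if (vox < 0) {                       // left the phantom
        if (escaped) *escaped += p.w * p.E;
        break;
      }
      int m = G.mat[vox] - 1;
      if (m < 0) continue;                 // vacuum voxel: virtual collision
      double mu_lin = M.mu_rho(m, loge) * M.density[m];
      int lab = G.lab[vox];
      if (lab > 0 && tally)
        tally[lab - 1] += p.w * p.E * M.muen_rho(m, loge) / mumaj;
      if (rng.u() * mumaj >= mu_lin) continue;   // virtual collision
      if (vr.absorption_only) {
        if (deposited) *deposited += p.w * p.E;
        alive = false;
        break;
      }
      double p_c, p_pair;
      channel_probs(M, m, p.E, loge, M.mu_rho(m, loge), p_c, p_pair);
      double xi = rng.u();
      if (xi < p_c) {                      // Compton scatter
        double eps, cost;
        sample_kn(rng, p.E, eps, cost);
        if (deposited) *deposited += p.w * p.E * (1.0 - eps);
        p.E *= eps;
        rotate_dir(p.dx, p.dy, p.dz, cost, 2.0 * M_PI * rng.u());
        if (p.E < vr.cutoff) {
          if (deposited) *deposited += p.w * p.E;
          alive = false;
        }
        p.primary = false;
      } else if (xi < p_c + p_pair) {      // pair production
        if (deposited) *deposited += p.w * (p.E - 1.022);
        Particle g1 = p;
        g1.E = 0.511; g1.primary = false;
        rng.iso_dir(g1.dx, g1.dy, g1.dz);
        Particle g2 = g1;
        g2.dx = -g1.dx; g2.dy = -g1.dy; g2.dz = -g1.dz;
        if (g1.E >= vr.cutoff) { stack.push_back(g1); stack.push_back(g2); }
        else if (deposited) *deposited += (g1.w + g2.w) * g1.E;
        alive = false;
      } else {                             // photoelectric absorption
        if (deposited) *deposited += p.w * p.E;
        alive = false;
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_run_beam(List grid, List mats, List src, List config) {
  IntegerVector dims = grid["dims"];
  NumericVector vs = grid["voxel_size"], org = grid["origin"];
  IntegerVector mat = grid["material_index"], lab = grid["organ_label"];
  Grid G;
  G.nx = dims[0]; G.ny = dims[1]; G.nz = dims[2];
  G.ox = org[0]; G.oy = org[1]; G.oz = org[2];
  G.vx = vs[0]; G.vy = vs[1]; G.vz = vs[2];
  G.ex = G.nx * G.vx; G.ey = G.ny * G.vy; G.ez = G.nz * G.vz;
  G.mat = INTEGER(mat);
  G.lab = INTEGER(lab);
  int n_labels = as<int>(grid["n_labels"]);

  std::vector<NumericVector> k1, k2;
  Materials M = unpack_materials(mats, k1, k2);
  Source S = unpack_source(src);

  VrConfig vr;
  vr.cutoff = as<double>(config["photon_cutoff"]);
  vr.rr_thresh = as<double>(config["rr_weight_threshold"]);
  vr.rr_surv = as<double>(config["rr_survival"]);
  vr.split_factor = as<int>(config["split_factor"]);
  vr.absorption_only = as<bool>(config["absorption_only"]);
  double n_hist = as<double>(config["n_histories"]);
  int batches = as<int>(config["batches"]);
  uint64_t seed = (uint64_t)as<double>(config["seed"]);

  long hist_per_batch = (long)(n_hist / batches);
  if (hist_per_batch < 1) stop("n_histories < batches");
  NumericMatrix tally(n_labels, batches);
  std::vector<double> acc(n_labels);

  for (int b = 0; b < batches; ++b) {
    Rng rng(seed * 0x100000001b3ULL + 0x9e3779b9ULL * (uint64_t)(b + 1));
    std::fill(acc.begin(), acc.end(), 0.0);
    for (long h = 0; h < hist_per_batch; ++h) {
      Particle p = S.emit(rng);
      transport_history(rng, G, M, vr, p, acc.data(), nullptr, nullptr);
    }
    for (int l = 0; l < n_labels; ++l)
      tally(l, b) = acc[l] / (double)hist_per_batch;
  }
  return List::create(_["tally"] = tally,
                      _["histories_per_batch"] = (double)hist_per_batch);
}

// [[Rcpp::export]]
NumericMatrix cpp_sample_compton(int n, double energy, double seed) {
  Rng rng((uint64_t)seed);
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    double eps, cost;
    sample_kn(rng, energy, eps, cost);
    out(i, 0) = energy * eps;
    out(i, 1) = cost;
  }
  colnames(out) = CharacterVector::create("energy", "cos_theta");
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_sample_source(int n, List src, double seed) {
  Source S = unpack_source(src);
  Rng rng((uint64_t)seed);
  NumericMatrix out(n, 8);
  for (int i = 0; i < n; ++i) {
    Particle p = S.emit(rng);
    out(i, 0) = p.x; out(i, 1) = p.y; out(i, 2) = p.z;
    out(i, 3) = p.dx; out(i, 4) = p.dy; out(i, 5) = p.dz;
    out(i, 6) = p.E; out(i, 7) = p.w;
  }
  colnames(out) = CharacterVector::create("x", "y", "z", "dx", "dy", "dz",
                                          "energy", "weight");
  return out;
}

// Pencil-beam slab experiment on a homogeneous material: direct (analog)
// distance sampling, used for closed-form attenuation, energy bookkeeping
// and variance-reduction unbiasedness checks.  Transmitted weight counts
// never-collided primaries crossing the far face.
// [[Rcpp::export]]
List cpp_pencil_slab(double n_hist, int batches, double energy,
                     double thickness, List mats, int material,
                     NumericVector init_weights, NumericVector init_probs,
                     List config, double seed) {
  std::vector<NumericVector> k1, k2;
  Materials M = unpack_materials(mats, k1, k2);
  int m = material - 1;
  VrConfig vr;
  vr.cutoff = as<double>(config["photon_cutoff"]);
  vr.rr_thresh = as<double>(config["rr_weight_threshold"]);
  vr.rr_surv = as<double>(config["rr_survival"]);
  vr.split_factor = as<int>(config["split_factor"]);
  vr.absorption_only = as<bool>(config["absorption_only"]);
  bool vr_on = as<bool>(config["vr_enabled"]);

  long hist_per_batch = (long)(n_hist / batches);
  NumericVector trans(batches), dep(batches), esc(batches), init(batches);
  int nw = init_weights.size();

  for (int b = 0; b < batches; ++b) {
    Rng rng((uint64_t)seed * 0x100000001b3ULL +
            0x9e3779b9ULL * (uint64_t)(b + 1));
    double tb = 0.0, db = 0.0, eb = 0.0, ib = 0.0;
    for (long h = 0; h < hist_per_batch; ++h) {
      // initial weight from the supplied discrete distribution
      double w0 = init_weights[0];
      if (nw > 1) {
        double uu = rng.u(), c = 0.0;
        for (int i = 0; i < nw; ++i) {
          c += init_probs[i];
          if (uu <= c) { w0 = init_weights[i]; break; }
        }
      }
      ib += w0 * energy;
      std::vector<Particle> stack;
      Particle p0 = {0, 0, 0, 0, 0, 1, energy, w0, true};
      if (vr_on) {
        if (!roulette(rng, p0, vr)) continue;
        if (vr.split_factor > 1) {
          Particle sub = p0;
          sub.w = p0.w / vr.split_factor;
          for (int i = 0; i < vr.split_factor; ++i) stack.push_back(sub);
        } else stack.push_back(p0);
      } else stack.push_back(p0);

      while (!stack.empty()) {
        Particle p = stack.back();
        stack.pop_back();
        bool alive = true;
        while (alive) {
          double loge = std::log(p.E);
          double mu_lin = M.mu_rho(m, loge) * M.density[m];
          double s = -std::log(rng.u()) / mu_lin;
          p.x += s * p.dx; p.y += s * p.dy; p.z += s * p.dz;
          if (p.z < 0.0 || p.z > thickness) {    // left the slab
            if (p.primary && p.z > thickness) tb += p.w;
            eb += p.w * p.E;
            break;
          }
          if (vr.absorption_only) { db += p.w * p.E; alive = false; break; }
          double p_c, p_pair;
          channel_probs(M, m, p.E, loge, M.mu_rho(m, loge), p_c, p_pair);
          double xi = rng.u();
          if (xi < p_c) {
            double eps, cost;
            sample_kn(rng, p.E, eps, cost);
            db += p.w * p.E * (1.0 - eps);
            p.E *= eps;
            rotate_dir(p.dx, p.dy, p.dz, cost, 2.0 * M_PI * rng.u());
            p.primary = false;
            if (p.E < vr.cutoff) { db += p.w * p.E; alive = false; }
          } else if (xi < p_c + p_pair) {
            db += p.w * (p.E - 1.022);
            Particle g1 = p;
            g1.E = 0.511; g1.primary = false;
            rng.iso_dir(g1.dx, g1.dy, g1.dz);
            Particle g2 = g1;
            g2.dx = -g1.dx; g2.dy = -g1.dy; g2.dz = -g1.dz;
            if (g1.E >= vr.cutoff) {
              stack.push_back(g1); stack.push_back(g2);
            } else db += (g1.w + g2.w) * g1.E;
            alive = false;
          } else {
            db += p.w * p.E;
            alive = false;
          }
        }
      }
    }
    trans[b] = tb / hist_per_batch;
    dep[b] = db / hist_per_batch;
    esc[b] = eb / hist_per_batch;
    init[b] = ib / hist_per_batch;
  }
  return List::create(_["transmitted"] = trans, _["deposited"] = dep,
                      _["escaped"] = esc, _["initial"] = init,
                      _["histories_per_batch"] = (double)hist_per_batch);
}
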