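// DPD engine: pairwise forces (conservative, thermostat, bond, electrostatic),
// cell-list neighbour search, modified velocity-Verlet integrator, and RDF
// histogramming. All quantities are in reduced DPD units (conservative cutoff
// r_c = 1, k_B T = 1, particle mass = 1 unless overridden).

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Counter-based pair RNG.
// Keyed by (seed, step, min(i,j), max(i,j)) so the random pair force is
// symmetric in (i,j) and reproducible regardless of traversal order.
// splitmix64 is a well-mixed 64-bit finalizer (Steele et al. 2014).

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97f4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline double pair_uniform(uint64_t seed, uint64_t step,
                                  int i, int j) {
  uint64_t a = (uint64_t)std::min(i, j);
  uint64_t b = (uint64_t)std::max(i, j);
  uint64_t h = splitmix64(seed ^ splitmix64((step << 1) ^
                splitmix64((a << 32) | (b & 0xFFFFFFFFULL))));
  return (double)(h >> 11) * (1.0 / 9007199254740992.0); // [0, 1)
}

// Zero-mean unit-variance symmetric noise: uniform on [-sqrt(3), sqrt(3)].
// Standard in DPD (Groot & Warren): the thermostat only requires the first
// two moments of theta_ij.
static inline double pair_theta(uint64_t seed, uint64_t step, int i, int j) {
  return 3.4641016151377544 * (pair_uniform(seed, step, i, j) - 0.5);
}

// ---------------------------------------------------------------------------
// Minimum-image separation. Non-periodic dimensions use the plain difference.

static inline void min_image(double* d, const double* L, const int* per) {
  for (int k = 0; k < 3; ++k) {
    if (per[k]) d[k] -= L[k] * std::round(d[k] / L[k]);
  }
}

// ---------------------------------------------------------------------------
// Electrostatic pair force, signed magnitude along the unit vector j -> i
// (positive = repulsive). scheme: 1 = C, 2 = CD, 3 = CDS.
// The C-scheme force is truncated to |F| <= cap. CD/CDS use analytic r -> 0
// limits below SMALL_R to avoid catastrophic cancellation in 1/r terms.

static const double SMALL_R = 1e-6;

static inline double elec_pair_force(double r, double zz, int scheme,
                                     double gamma, double lam,
                                     double Rel, double cap) {
  if (zz == 0.0 || r >= Rel) return 0.0;
  if (scheme == 1) { // pure Coulomb, truncated
    if (r < SMALL_R) return (zz > 0 ? cap : -cap);
    double F = gamma * zz / (r * r);
    if (F > cap) F = cap;
    if (F < -cap) F = -cap;
    return F;
  }
  double tD, dtD;
  if (r < SMALL_R) {
    if (scheme == 2) return 0.0;               // F_CD(0) = 0
    return 7.0 * gamma * zz / (4.0 * lam * Rel); // F_CDS(0)
  }
  double u = r / lam;
  double e = std::exp(-2.0 * u);
  tD  = 1.0 - (1.0 + u) * e;
  dtD = (1.0 / lam) * (1.0 + 2.0 * u) * e;
  double tC  = gamma * zz / r;
  double dtC = -gamma * zz / (r * r);
  if (scheme == 2) return -(dtC * tD + tC * dtD);
  double x  = r / Rel;
  double x4 = x * x * x * x;
  double tS  = 1.0 - 1.75 * x + x4 * x * (5.25 - 7.0 * x + 2.5 * x * x);
  double dtS = (1.0 / Rel) * (-1.75 + x4 * (26.25 - 42.0 * x + 17.5 * x * x));
  return -(dtC * tD * tS + tC * dtD * tS + tC * tD * dtS);
}

// ---------------------------------------------------------------------------
// Cell list over an index subset, stored cell-sorted in packed coordinate
// arrays for cache locality; periodic shifts are resolved per neighbour-cell
// offset so the pair kernel needs no per-pair minimum-image rounding.
// Falls back to all-pairs when any dimension has fewer than 3 cells at the
// requested cutoff (the half-stencil would then see the same image twice).

struct CellList {
  bool brute;
  int nc[3];
  std::vector<int> start;          // cell -> [start, end) into order
  std::vector<int> order;          // subset ids, cell-sorted
  std::vector<double> px, py, pz;  // packed positions in `order`
};

static void build_cell_list(CellList& cl, const NumericMatrix& pos,
                            const std::vector<int>& subset,
                            const double* L, const int* per, double cutoff,
                            bool force_brute) {
  cl.brute = force_brute;
  if (!cl.brute) {
    for (int k = 0; k < 3; ++k) {
      cl.nc[k] = (int)std::floor(L[k] / cutoff);
      if (cl.nc[k] < 3) cl.brute = true;
    }
  }
  if (cl.brute) { cl.order = subset; return; }
  int ntot = cl.nc[0] * cl.nc[1] * cl.nc[2];
  size_t m = subset.size();
  std::vector<int> cid(m);
  std::vector<int> cnt(ntot + 1, 0);
  double inv[3];
  for (int k = 0; k < 3; ++k) inv[k] = cl.nc[k] / L[k];
  for (size_t s = 0; s < m; ++s) {
    int i = subset[s], c[3];
    for (int k = 0; k < 3; ++k) {
      int ck = (int)(pos(i, k) * inv[k]);
      if (ck < 0) ck = 0;
      if (ck >= cl.nc[k]) ck = cl.nc[k] - 1;
      c[k] = ck;
    }
    cid[s] = (c[2] * cl.nc[1] + c[1]) * cl.nc[0] + c[0];
    ++cnt[cid[s] + 1];
  }
  for (int c = 0; c < ntot; ++c) cnt[c + 1] += cnt[c];
  cl.start = cnt;
  cl.order.resize(m);
  cl.px.resize(m); cl.py.resize(m); cl.pz.resize(m);
  std::vector<int> cursor(cl.start.begin(), cl.start.end() - 1);
  for (size_t s = 0; s < m; ++s) {
    int slot = cursor[cid[s]]++;
    int i = subset[s];
    cl.order[slot] = i;
    cl.px[slot] = pos(i, 0);
    cl.py[slot] = pos(i, 1);
    cl.pz[slot] = pos(i, 2);
  }
}

// Half stencil: self cell (half loop) + 13 neighbour offsets.
static const int STENCIL[13][3] = {
  {1,0,0},{0,1,0},{0,0,1},{1,1,0},{1,-1,0},{1,0,1},{1,0,-1},
  {0,1,1},{0,1,-1},{1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}
};

// ---------------------------------------------------------------------------
// Force accumulation context

struct ForceCtx {
  double L[3];
  int per[3];
  const double* aij;       // ntype x ntype, column-major
  int ntype;
  double gamma_diss, sigma, inv_sqrt_dt;
  bool thermostat;
  int scheme;              // 0 none, 1 C, 2 CD, 3 CDS
  double el_gamma, el_lam, el_cut, el_cap;
  uint64_t seed, step;
};

// Pair kernels receive original particle ids plus the separation vector
// d = r_i - r_j (already image-resolved) and its squared length.

// Conservative + thermostat kernel for one pair (cutoff 1).
static inline void dpd_pair(const NumericMatrix& vel,
                            const IntegerVector& type, NumericMatrix& F,
                            const ForceCtx& cx, int i, int j,
                            const double* d, double r2) {
  if (r2 >= 1.0 || r2 < 1e-24) return; // exactly coincident pairs: no direction
  double r = std::sqrt(r2);
  double inv_r = 1.0 / r;
  double w = 1.0 - r; // conservative weight and w_R
  double a = cx.aij[type[i] + cx.ntype * type[j]];
  double f = a * w;
  if (cx.thermostat) {
    double rv = (d[0]*(vel(i,0)-vel(j,0)) + d[1]*(vel(i,1)-vel(j,1)) +
                 d[2]*(vel(i,2)-vel(j,2))) * inv_r;
    f += -cx.gamma_diss * w * w * rv;
    f += cx.sigma * w * pair_theta(cx.seed, cx.step, i, j) * cx.inv_sqrt_dt;
  }
  double s = f * inv_r;
  for (int k = 0; k < 3; ++k) {
    double fk = s * d[k];
    F(i,k) += fk;
    F(j,k) -= fk;
  }
}

static inline void elec_pair(const IntegerVector& valence, NumericMatrix& F,
                             const ForceCtx& cx, int i, int j,
                             const double* d, double r2) {
  if (r2 >= cx.el_cut * cx.el_cut || r2 < 1e-24) return;
  double zz = (double)valence[i] * (double)valence[j];
  if (zz == 0.0) return;
  double r = std::sqrt(r2);
  double f = elec_pair_force(r, zz, cx.scheme, cx.el_gamma, cx.el_lam,
                             cx.el_cut, cx.el_cap);
  double s = f / r;
  for (int k = 0; k < 3; ++k) {
    double fk = s * d[k];
    F(i,k) += fk;
    F(j,k) -= fk;
  }
}

template <typename PairFun>
static void loop_pairs(const CellList& cl, const NumericMatrix& pos,
                       const double* L, const int* per, double cut2,
                       PairFun fun) {
  if (cl.brute) {
    int n = (int)cl.order.size();
    for (int a = 0; a < n; ++a) {
      int i = cl.order[a];
      double xi = pos(i,0), yi = pos(i,1), zi = pos(i,2);
      for (int b = a + 1; b < n; ++b) {
        int j = cl.order[b];
        double d[3] = { xi - pos(j,0), yi - pos(j,1), zi - pos(j,2) };
        min_image(d, L, per);
        double r2 = d[0]*d[0] + d[1]*d[1] + d[2]*d[2];
        if (r2 < cut2) fun(i, j, d, r2);
      }
    }
    return;
  }
  const int* nc = cl.nc;
  for (int cz = 0; cz < nc[2]; ++cz)
  for (int cy = 0; cy < nc[1]; ++cy)
  for (int cx = 0; cx < nc[0]; ++cx) {
    int cid = (cz * nc[1] + cy) * nc[0] + cx;
    int a0 = cl.start[cid], a1 = cl.start[cid + 1];
    // within-cell half loop
    for (int a = a0; a < a1; ++a) {
      double xi = cl.px[a], yi = cl.py[a], zi = cl.pz[a];
      for (int b = a + 1; b < a1; ++b) {
        double d[3] = { xi - cl.px[b], yi - cl.py[b], zi - cl.pz[b] };
        double r2 = d[0]*d[0] + d[1]*d[1] + d[2]*d[2];
        if (r2 < cut2) fun(cl.order[a], cl.order[b], d, r2);
      }
    }
    // neighbour cells, with the periodic image shift resolved per offset
    for (int m = 0; m < 13; ++m) {
      int q[3] = { cx + STENCIL[m][0], cy + STENCIL[m][1], cz + STENCIL[m][2] };
      double shift[3] = {0.0, 0.0, 0.0};
      bool ok = true;
      for (int k = 0; k < 3; ++k) {
        if (q[k] < 0) {
          // neighbour's image sits one box length below: d = ri - (rj - L)
          if (!per[k]) { ok = false; break; }
          q[k] += nc[k]; shift[k] = L[k];
        } else if (q[k] >= nc[k]) {
          if (!per[k]) { ok = false; break; }
          q[k] -= nc[k]; shift[k] = -L[k];
        }
      }
      if (!ok) continue;
      int qid = (q[2] * nc[1] + q[1]) * nc[0] + q[0];
      int b0 = cl.start[qid], b1 = cl.start[qid + 1];
      for (int a = a0; a < a1; ++a) {
        double xi = cl.px[a] + shift[0], yi = cl.py[a] + shift[1],
               zi = cl.pz[a] + shift[2];
        for (int b = b0; b < b1; ++b) {
          double d[3] = { xi - cl.px[b], yi - cl.py[b], zi - cl.pz[b] };
          double r2 = d[0]*d[0] + d[1]*d[1] + d[2]*d[2];
          if (r2 < cut2) fun(cl.order[a], cl.order[b], d, r2);
        }
      }
    }
  }
}

// ---------------------------------------------------------------------------
// Full force computation.
// bonds: m x 4 matrix (i, j, k_spring, r0) with 0-based indices.
// wall: soft repulsion a_wall * (1 - dist) within 1 ru of each face of every
// non-periodic dimension.

static void compute_forces_impl(const NumericMatrix& pos,
                                const NumericMatrix& vel,
                                const IntegerVector& type,
                                const IntegerVector& valence,
                                const NumericMatrix& bonds,
                                ForceCtx& cx, double a_wall,
                                bool brute, NumericMatrix& F) {
  int n = pos.nrow();
  std::fill(F.begin(), F.end(), 0.0);

  std::vector<int> all(n);
  for (int i = 0; i < n; ++i) all[i] = i;
  CellList cl;
  build_cell_list(cl, pos, all, cx.L, cx.per, 1.0, brute);
  loop_pairs(cl, pos, cx.L, cx.per, 1.0,
             [&](int i, int j, const double* d, double r2) {
    dpd_pair(vel, type, F, cx, i, j, d, r2);
  });

  if (cx.scheme > 0) {
    std::vector<int> charged;
    for (int i = 0; i < n; ++i) if (valence[i] != 0) charged.push_back(i);
    if (!charged.empty()) {
      CellList ce;
      build_cell_list(ce, pos, charged, cx.L, cx.per, cx.el_cut, brute);
      loop_pairs(ce, pos, cx.L, cx.per, cx.el_cut * cx.el_cut,
                 [&](int i, int j, const double* d, double r2) {
        elec_pair(valence, F, cx, i, j, d, r2);
      });
    }
  }

  for (int b = 0; b < bonds.nrow(); ++b) {
    int i = (int)bonds(b,0), j = (int)bonds(b,1);
    double k = bonds(b,2), r0 = bonds(b,3);
    double d[3] = { pos(i,0)-pos(j,0), pos(i,1)-pos(j,1), pos(i,2)-pos(j,2) };
    min_image(d, cx.L, cx.per);
    double r = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
    if (r < 1e-12) continue;
    double s = -k * (r - r0) / r;
    for (int kk = 0; kk < 3; ++kk) {
      double fk = s * d[kk];
      F(i,kk) += fk;
      F(j,kk) -= fk;
    }
  }

  for (int k = 0; k < 3; ++k) {
    if (cx.per[k]) continue;
    for (int i = 0; i < n; ++i) {
      double x = pos(i,k);
      if (x < 1.0)            F(i,k) += a_wall * (1.0 - x);
      if (cx.L[k] - x < 1.0)  F(i,k) -= a_wall * (1.0 - (cx.L[k] - x));
    }
  }
}

static ForceCtx make_ctx(const NumericVector& box, const LogicalVector& periodic,
                         const NumericMatrix& aij, double gamma_diss,
                         double sigma, double dt, bool thermostat,
                         const List& elec, uint64_t seed, uint64_t step) {
  ForceCtx cx;
  for (int k = 0; k < 3; ++k) { cx.L[k] = box[k]; cx.per[k] = periodic[k] ? 1 : 0; }
  cx.aij = aij.begin();
  cx.ntype = aij.nrow();
  cx.gamma_diss = gamma_diss;
  cx.sigma = sigma;
  cx.inv_sqrt_dt = 1.0 / std::sqrt(dt);
  cx.thermostat = thermostat;
  cx.scheme  = as<int>(elec["scheme_code"]);
  cx.el_gamma = as<double>(elec["gamma"]);
  cx.el_lam   = as<double>(elec["lam"]);
  cx.el_cut   = as<double>(elec["cutoff_el"]);
  cx.el_cap   = as<double>(elec["force_cap"]);
  cx.seed = seed;
  cx.step = step;
  return cx;
}

// [[Rcpp::export]]
NumericMatrix cpp_compute_forces(NumericMatrix pos, NumericMatrix vel,
                                 IntegerVector type, IntegerVector valence,
                                 NumericMatrix bonds, NumericVector box,
                                 LogicalVector periodic, NumericMatrix aij,
                                 double gamma_diss, double sigma, double dt,
                                 bool thermostat, List elec, double a_wall,
                                 double seed, double step, bool brute) {
  ForceCtx cx = make_ctx(box, periodic, aij, gamma_diss, sigma, dt,
                         thermostat, elec, (uint64_t)seed, (uint64_t)step);
  NumericMatrix F(pos.nrow(), 3);
  compute_forces_impl(pos, vel, type, valence, bonds, cx, a_wall, brute, F);
  return F;
}

// [[Rcpp::export]]
double cpp_elec_force_scalar(double r, double zz, int scheme, double gamma,
                             double lam, double cutoff_el, double cap) {
  return elec_pair_force(r, zz, scheme, gamma, lam, cutoff_el, cap);
}

// ---------------------------------------------------------------------------
// Integrator: modified velocity-Verlet (Groot & Warren, lambda = 0.5).
//   v_half = v + (dt/2) f / m
//   r     += dt v_half         (wrap / reflect)
//   f_new  = F(r, v_half)      (dissipative force uses predicted velocity)
//   v      = v_half + (dt/2) f_new / m
// Returns frames (N x 3 x n_frames), diagnostics, final state.

// [[Rcpp::export]]
List cpp_run(NumericMatrix pos0, NumericMatrix vel0, IntegerVector type,
             IntegerVector valence, NumericVector mass, NumericMatrix bonds,
             NumericVector box, LogicalVector periodic, NumericMatrix aij,
             double gamma_diss, double sigma, double dt, bool thermostat,
             List elec, double a_wall, double seed, int step0, int n_steps,
             int emit_every) {
  int n = pos0.nrow();
  NumericMatrix pos = clone(pos0), vel = clone(vel0);
  ForceCtx cx = make_ctx(box, periodic, aij, gamma_diss, sigma, dt,
                         thermostat, elec, (uint64_t)seed, (uint64_t)step0);
  NumericMatrix F(n, 3), Fn(n, 3);
  compute_forces_impl(pos, vel, type, valence, bonds, cx, a_wall, false, F);

  int n_frames = (emit_every > 0) ? n_steps / emit_every : 0;
  NumericVector frames(n_frames > 0 ? (R_xlen_t)n * 3 * n_frames : 0);
  NumericMatrix diag(n_frames, 5); // step, kT, Px, Py, Pz
  int fi = 0;

  double half = 0.5 * dt;
  for (int s = 0; s < n_steps; ++s) {
    uint64_t step_now = (uint64_t)(step0 + s);
    for (int i = 0; i < n; ++i) {
      double im = 1.0 / mass[i];
      for (int k = 0; k < 3; ++k) {
        vel(i,k) += half * F(i,k) * im;   // v_half (= predicted v, lambda 0.5)
        pos(i,k) += dt * vel(i,k);
      }
      for (int k = 0; k < 3; ++k) {
        if (cx.per[k]) {
          pos(i,k) -= cx.L[k] * std::floor(pos(i,k) / cx.L[k]);
        } else { // reflecting boundary
          if (pos(i,k) < 0.0)      { pos(i,k) = -pos(i,k); vel(i,k) = -vel(i,k); }
          if (pos(i,k) > cx.L[k])  { pos(i,k) = 2.0*cx.L[k]-pos(i,k); vel(i,k) = -vel(i,k); }
        }
      }
    }
    cx.step = step_now; // random force of this step
    compute_forces_impl(pos, vel, type, valence, bonds, cx, a_wall, false, Fn);
    for (int i = 0; i < n; ++i) {
      double im = 1.0 / mass[i];
      for (int k = 0; k < 3; ++k) vel(i,k) += half * Fn(i,k) * im;
    }
    std::swap(F, Fn);

    bool finite = true;
    for (int i = 0; i < n && finite; ++i)
      for (int k = 0; k < 3; ++k)
        if (!std::isfinite(pos(i,k))) { finite = false; break; }
    if (!finite)
      stop("integration diverged (non-finite position) at step %d", step0 + s + 1);

    if (emit_every > 0 && (s + 1) % emit_every == 0 && fi < n_frames) {
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k)
          frames[(R_xlen_t)fi * n * 3 + (R_xlen_t)k * n + i] = pos(i,k);
      // diagnostics: kinetic temperature with COM momentum removed, momentum
      double P[3] = {0,0,0}, M = 0;
      for (int i = 0; i < n; ++i) {
        M += mass[i];
        for (int k = 0; k < 3; ++k) P[k] += mass[i] * vel(i,k);
      }
      double ke2 = 0;
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k) {
          double v = vel(i,k) - P[k] / M;
          ke2 += mass[i] * v * v;
        }
      diag(fi,0) = step0 + s + 1;
      diag(fi,1) = (n > 1) ? ke2 / (3.0 * n - 3.0) : 0.0;
      diag(fi,2) = P[0]; diag(fi,3) = P[1]; diag(fi,4) = P[2];
      ++fi;
    }
  }

  if (n_frames > 0) frames.attr("dim") = IntegerVector::create(n, 3, n_frames);
  return List::create(_["positions"] = pos, _["velocities"] = vel,
                      _["frames"] = frames, _["diagnostics"] = diag,
                      _["step"] = step0 + n_steps);
}

// ---------------------------------------------------------------------------
// RDF pair-distance histogram between index sets A and B (1-based from R),
// minimum image, over a frame stack (N x 3 x n_frames). If `same` is true,
// A == B and each unordered pair is counted once.

// [[Rcpp::export]]
NumericVector cpp_rdf_counts(NumericVector frames, IntegerVector dim,
                             IntegerVector idx_a, IntegerVector idx_b,
                             bool same, NumericVector box,
                             LogicalVector periodic,
                             double r_max, double bin_width) {
  int n = dim[0], nf = dim[2];
  int nbin = (int)std::ceil(r_max / bin_width);
  NumericVector counts(nbin);
  double L[3]; int per[3];
  for (int k = 0; k < 3; ++k) { L[k] = box[k]; per[k] = periodic[k] ? 1 : 0; }
  double r2max = r_max * r_max;
  int na = idx_a.size(), nb = idx_b.size();
  for (int f = 0; f < nf; ++f) {
    const double* base = frames.begin() + (R_xlen_t)f * n * 3;
    for (int a = 0; a < na; ++a) {
      int i = idx_a[a] - 1;
      int bstart = same ? a + 1 : 0;
      for (int b = bstart; b < nb; ++b) {
        int j = idx_b[b] - 1;
        if (!same && i == j) continue;
        double d[3];
        for (int k = 0; k < 3; ++k) d[k] = base[k*n + i] - base[k*n + j];
        min_image(d, L, per);
        double r2 = d[0]*d[0] + d[1]*d[1] + d[2]*d[2];
        if (r2 < r2max) {
          int bin = (int)(std::sqrt(r2) / bin_width);
          if (bin < nbin) counts[bin] += 1.0;
        }
      }
    }
  }
  return counts;
}

// All pairs closer than `threshold` (minimum image), excluding an explicit
// 1-based exclusion pair list (deliberately co-located builder pairs).
// Returns a flat vector c(i1, j1, i2, j2, ...), 1-based. Used by builders to
// reject near-coincident random placements.

// [[Rcpp::export]]
IntegerVector cpp_close_pairs(NumericMatrix pos, NumericVector box,
                              LogicalVector periodic, double threshold,
                              IntegerVector excl_i, IntegerVector excl_j) {
  int n = pos.nrow();
  double L[3]; int per[3];
  for (int k = 0; k < 3; ++k) { L[k] = box[k]; per[k] = periodic[k] ? 1 : 0; }
  std::vector<uint64_t> excl;
  for (int e = 0; e < excl_i.size(); ++e) {
    uint64_t a = (uint64_t)std::min(excl_i[e], excl_j[e]);
    uint64_t b = (uint64_t)std::max(excl_i[e], excl_j[e]);
    excl.push_back((a << 32) | b);
  }
  std::sort(excl.begin(), excl.end());
  double t2 = threshold * threshold;
  std::vector<int> out;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double d[3] = { pos(i,0)-pos(j,0), pos(i,1)-pos(j,1), pos(i,2)-pos(j,2) };
      min_image(d, L, per);
      double r2 = d[0]*d[0] + d[1]*d[1] + d[2]*d[2];
      if (r2 < t2) {
        uint64_t key = ((uint64_t)(i + 1) << 32) | (uint64_t)(j + 1);
        if (!std::binary_search(excl.begin(), excl.end(), key)) {
          out.push_back(i + 1);
          out.push_back(j + 1);
        }
      }
    }
  return wrap(out);
}

// Pairwise minimum-image distances for an explicit pair list (1-based), one
// frame. Used by the ion-pair distance trace.

// [[Rcpp::export]]
NumericVector cpp_pair_distances(NumericMatrix pos, IntegerVector pi,
                                 IntegerVector pj, NumericVector box,
                                 LogicalVector periodic) {
  int np = pi.size();
  NumericVector out(np);
  double L[3]; int per[3];
  for (int k = 0; k < 3; ++k) { L[k] = box[k]; per[k] = periodic[k] ? 1 : 0; }
  for (int p = 0; p < np; ++p) {
    int i = pi[p] - 1, j = pj[p] - 1;
    double d[3] = { pos(i,0)-pos(j,0), pos(i,1)-pos(j,1), pos(i,2)-pos(j,2) };
    min_image(d, L, per);
    out[p] = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
  }
  return out;
}
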