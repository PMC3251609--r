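// Streamline propagation core. Positions are world mm; the inverse affine
// maps mm to fractional 0-based voxel indices and the nearest voxel supplies
// the fibre directions (no interpolation, which would average antipodal
// vectors). All randomness comes from R's RNG so results are reproducible
// from set.seed().
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct TrackCtx {
  int nx, ny, nz;
  R_xlen_t nvox;
  const double *inv;    // 4x4 inverse affine, column-major
  const double *dirs;   // nvox * 6
  const int *ndirs;     // nvox
  const double *disp;   // nvox, radians
  const int *brain;     // nvox
  double step;
  int max_steps;
  double curv_cos;      // cos(curvature limit)
};

static inline R_xlen_t voxel_at(const TrackCtx &c, const double *p) {
  const double *m = c.inv;
  double fx = m[0] * p[0] + m[4] * p[1] + m[8] * p[2] + m[12];
  double fy = m[1] * p[0] + m[5] * p[1] + m[9] * p[2] + m[13];
  double fz = m[2] * p[0] + m[6] * p[1] + m[10] * p[2] + m[14];
  int ix = (int)std::lround(fx);
  int iy = (int)std::lround(fy);
  int iz = (int)std::lround(fz);
  if (ix < 0 || ix >= c.nx || iy < 0 || iy >= c.ny || iz < 0 || iz >= c.nz)
    return -1;
  return ix + (R_xlen_t)c.nx * (iy + (R_xlen_t)c.ny * iz);
}

// Draw a propagation direction at voxel v: choose one stored direction
// uniformly, add a Gaussian tangent-plane perturbation with the voxel's
// angular SD, renormalise, and flip the sign to stay within 90 degrees of
// the previous direction (if any). Returns false at isotropic voxels.
static inline bool sample_dir(const TrackCtx &c, R_xlen_t v,
                              const double *prev, bool has_prev,
                              double *out) {
  int k = c.ndirs[v];
  if (k == 0) return false;
  int s = (k == 2 && unif_rand() < 0.5) ? 1 : 0;
  double d0 = c.dirs[v + c.nvox * (3 * s + 0)];
  double d1 = c.dirs[v + c.nvox * (3 * s + 1)];
  double d2 = c.dirs[v + c.nvox * (3 * s + 2)];
  double sdv = c.disp[v];
  if (sdv > 0.0) {
    // orthonormal tangent basis: cross d with its least-aligned axis
    double a0 = std::fabs(d0), a1 = std::fabs(d1), a2 = std::fabs(d2);
    double h0 = 0, h1 = 0, h2 = 0;
    if (a0 <= a1 && a0 <= a2) h0 = 1;
    else if (a1 <= a2) h1 = 1;
    else h2 = 1;
    double t0 = d1 * h2 - d2 * h1;
    double t1 = d2 * h0 - d0 * h2;
    double t2 = d0 * h1 - d1 * h0;
    double tn = std::sqrt(t0 * t0 + t1 * t1 + t2 * t2);
    t0 /= tn; t1 /= tn; t2 /= tn;
    double u0 = d1 * t2 - d2 * t1;
    double u1 = d2 * t0 - d0 * t2;
    double u2 = d0 * t1 - d1 * t0;
    double g1 = norm_rand() * sdv, g2 = norm_rand() * sdv;
    d0 += g1 * t0 + g2 * u0;
    d1 += g1 * t1 + g2 * u1;
    d2 += g1 * t2 + g2 * u2;
    double dn = std::sqrt(d0 * d0 + d1 * d1 + d2 * d2);
    d0 /= dn; d1 /= dn; d2 /= dn;
  }
  if (has_prev) {
    double dp = d0 * prev[0] + d1 * prev[1] + d2 * prev[2];
    if (dp < 0) { d0 = -d0; d1 = -d1; d2 = -d2; }
  }
  out[0] = d0; out[1] = d1; out[2] = d2;
  return true;
}

// Walk one streamline. Records the linear voxel index at every visited
// position (start included) into vis; optionally records positions into pts
// (3 doubles per position). Returns the number of recorded positions, or 0
// when the start voxel is outside the brain.
static int walk(const TrackCtx &c, const double *start, R_xlen_t *vis,
                double *pts) {
  double p[3] = {start[0], start[1], start[2]};
  double prev[3] = {0, 0, 0};
  bool has_prev = false;
  R_xlen_t v = voxel_at(c, p);
  if (v < 0 || !c.brain[v]) return 0;
  int n = 0;
  vis[n] = v;
  if (pts) { pts[3 * n] = p[0]; pts[3 * n + 1] = p[1]; pts[3 * n + 2] = p[2]; }
  ++n;
  for (int s = 0; s < c.max_steps; ++s) {
    double d[3];
    if (!sample_dir(c, v, prev, has_prev, d)) break;
    if (has_prev) {
      double dp = d[0] * prev[0] + d[1] * prev[1] + d[2] * prev[2];
      if (dp < c.curv_cos) break;
    }
    p[0] += c.step * d[0]; p[1] += c.step * d[1]; p[2] += c.step * d[2];
    prev[0] = d[0]; prev[1] = d[1]; prev[2] = d[2];
    has_prev = true;
    v = voxel_at(c, p);
    if (v < 0 || !c.brain[v]) break;
    vis[n] = v;
    if (pts) { pts[3 * n] = p[0]; pts[3 * n + 1] = p[1]; pts[3 * n + 2] = p[2]; }
    ++n;
  }
  return n;
}

static TrackCtx make_ctx(const IntegerVector &dims,
                         const NumericMatrix &inv_affine,
                         const NumericVector &dirs,
                         const IntegerVector &ndirs,
                         const NumericVector &disp,
                         const IntegerVector &brain, double step,
                         int max_steps, double curv_cos) {
  TrackCtx c;
  c.nx = dims[0]; c.ny = dims[1]; c.nz = dims[2];
  c.nvox = (R_xlen_t)c.nx * c.ny * c.nz;
  c.inv = inv_affine.begin();
  c.dirs = dirs.begin();
  c.ndirs = ndirs.begin();
  c.disp = disp.begin();
  c.brain = brain.begin();
  c.step = step;
  c.max_steps = max_steps;
  c.curv_cos = curv_cos;
  return c;
}

// [[Rcpp::export]]
NumericMatrix cpp_propagate(NumericVector start_mm, IntegerVector dims,
                            NumericMatrix inv_affine, NumericVector dirs,
                            IntegerVector ndirs, NumericVector disp,
                            IntegerVector brain, double step, int max_steps,
                            double curv_cos) {
  TrackCtx c = make_ctx(dims, inv_affine, dirs, ndirs, disp, brain, step,
                        max_steps, curv_cos);
  std::vector<R_xlen_t> vis(c.max_steps + 1);
  std::vector<double> pts(3 * (c.max_steps + 1));
  int n = walk(c, start_mm.begin(), vis.data(), pts.data());
  if (n == 0) stop("start position lies outside the brain mask");
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = pts[3 * i];
    out(i, 1) = pts[3 * i + 1];
    out(i, 2) = pts[3 * i + 2];
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_track_mask(NumericMatrix seeds_mm, int n_targets,
                             IntegerVector labels, IntegerVector dims,
                             NumericMatrix inv_affine, NumericVector dirs,
                             IntegerVector ndirs, NumericVector disp,
                             IntegerVector brain, int n_samples, double step,
                             int max_steps, double curv_cos) {
  TrackCtx c = make_ctx(dims, inv_affine, dirs, ndirs, disp, brain, step,
                        max_steps, curv_cos);
  const int *lab = labels.begin();
  int m = seeds_mm.nrow();
  IntegerMatrix counts(m, n_targets);
  std::vector<R_xlen_t> vis(c.max_steps + 1);
  std::vector<char> hit(n_targets);
  for (int si = 0; si < m; ++si) {
    if (si % 64 == 0) checkUserInterrupt();
    double s0[3] = {seeds_mm(si, 0), seeds_mm(si, 1), seeds_mm(si, 2)};
    for (int r = 0; r < n_samples; ++r) {
      std::fill(hit.begin(), hit.end(), 0);
      int n = walk(c, s0, vis.data(), nullptr);
      for (int i = 0; i < n; ++i) {
        int l = lab[vis[i]];
        if (l > 0 && !hit[l - 1]) {
          hit[l - 1] = 1;
          counts(si, l - 1) += 1;
        }
      }
    }
  }
  return counts;
}

// [[Rcpp::export]]
IntegerVector cpp_track_lesion(NumericMatrix seeds_mm, IntegerVector dims,
                               NumericMatrix inv_affine, NumericVector dirs,
                               IntegerVector ndirs, NumericVector disp,
                               IntegerVector brain, int n_samples,
                               double step, int max_steps, double curv_cos) {
  TrackCtx c = make_ctx(dims, inv_affine, dirs, ndirs, disp, brain, step,
                        max_steps, curv_cos);
  IntegerVector out(c.nvox);
  std::vector<R_xlen_t> vis(c.max_steps + 1);
  std::vector<R_xlen_t> stamp(c.nvox, -1);
  R_xlen_t id = 0;
  int m = seeds_mm.nrow();
  for (int si = 0; si < m; ++si) {
    if (si % 64 == 0) checkUserInterrupt();
    double s0[3] = {seeds_mm(si, 0), seeds_mm(si, 1), seeds_mm(si, 2)};
    for (int r = 0; r < n_samples; ++r, ++id) {
      int n = walk(c, s0, vis.data(), nullptr);
      for (int i = 0; i < n; ++i) {
        if (stamp[vis[i]] != id) {
          stamp[vis[i]] = id;
          out[vis[i]] += 1;
        }
      }
    }
  }
  return out;
}
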