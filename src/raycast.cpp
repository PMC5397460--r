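#include <Rcpp.h>
using namespace Rcpp;

double bf_sample3(const double* v, int nx, int ny, int nz,
                  double x, double y, double z);

struct VoxMap {
  // world -> continuous 0-based voxel index (rows of a 4x4 matrix)
  double m[3][4];
  void apply(const double* w, double* out) const {
    for (int r = 0; r < 3; ++r)
      out[r] = m[r][0] * w[0] + m[r][1] * w[1] + m[r][2] * w[2] + m[r][3];
  }
};

static VoxMap makeMap(const NumericMatrix& worldToVox) {
  VoxMap vm;
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 4; ++c) vm.m[r][c] = worldToVox(r, c);
  return vm;
}

// Parametric entry/exit of the ray o + t*d with the voxel box
// [-0.5, n-0.5]^3, computed in voxel space. Returns false on a miss.
static bool boxClip(const double* ov, const double* dv, const int* dim,
                    double& t0, double& t1) {
  t0 = -1e30; t1 = 1e30;
  for (int a = 0; a < 3; ++a) {
    double lo = -0.5, hi = dim[a] - 0.5;
    if (std::fabs(dv[a]) < 1e-12) {
      if (ov[a] < lo || ov[a] > hi) return false;
    } else {
      double ta = (lo - ov[a]) / dv[a], tb = (hi - ov[a]) / dv[a];
      if (ta > tb) std::swap(ta, tb);
      if (ta > t0) t0 = ta;
      if (tb < t1) t1 = tb;
    }
  }
  return t0 <= t1;
}

static inline bool maskAt(const int* m, const int* dim, const double* p) {
  int i = (int)std::lround(p[0]), j = (int)std::lround(p[1]),
      k = (int)std::lround(p[2]);
  if (i < 0 || i >= dim[0] || j < 0 || j >= dim[1] || k < 0 || k >= dim[2])
    return false;
  return m[i + (size_t)dim[0] * (j + (size_t)dim[1] * k)] != 0;
}

// "inside" predicate for surface marching: within the bone mask and not in
// the removed clip half-space n.x > d.
static inline bool insideAt(double t, const double* ow, const double* dw,
                            const double* ov, const double* dv,
                            const int* m, const int* dim,
                            bool hasClip, const double* cn, double cd) {
  if (hasClip) {
    double nd = cn[0] * (ow[0] + t * dw[0]) + cn[1] * (ow[1] + t * dw[1]) +
                cn[2] * (ow[2] + t * dw[2]);
    if (nd > cd) return false;
  }
  double p[3] = {ov[0] + t * dv[0], ov[1] + t * dv[1], ov[2] + t * dv[2]};
  return maskAt(m, dim, p);
}

// First-hit surface search along parallel rays. Rays march from the volume
// entry point in steps of `step` (mm); the first sample inside the clipped
// mask is refined by one bisection between the last outside and first inside
// samples. Returns per-ray hit flag and hit parameter t (mm along dir).
// [[Rcpp::export(name = ".cppFirstHit")]]
List cppFirstHit(LogicalVector mask, IntegerVector dim,
                 NumericMatrix worldToVox, NumericMatrix origins,
                 NumericVector dir, double step,
                 bool hasClip, NumericVector clipN, double clipD) {
  VoxMap vm = makeMap(worldToVox);
  int d3[3] = {dim[0], dim[1], dim[2]};
  const int* m = LOGICAL(mask);
  int n = origins.nrow();
  LogicalVector hit(n);
  NumericVector tout(n);
  double dw[3] = {dir[0], dir[1], dir[2]};
  // direction in voxel space (linear part only)
  double dv[3];
  for (int r = 0; r < 3; ++r)
    dv[r] = vm.m[r][0] * dw[0] + vm.m[r][1] * dw[1] + vm.m[r][2] * dw[2];
  double cn[3] = {0, 0, 0};
  double cd = 0;
  if (hasClip) { cn[0] = clipN[0]; cn[1] = clipN[1]; cn[2] = clipN[2]; cd = clipD; }

  for (int r = 0; r < n; ++r) {
    double ow[3] = {origins(r, 0), origins(r, 1), origins(r, 2)};
    double ov[3];
    vm.apply(ow, ov);
    double t0, t1;
    hit[r] = false;
    tout[r] = NA_REAL;
    if (!boxClip(ov, dv, d3, t0, t1)) continue;
    if (t0 < 0) t0 = 0;
    double tPrev = t0 - step;
    for (double t = t0; t <= t1; t += step) {
      if (insideAt(t, ow, dw, ov, dv, m, d3, hasClip, cn, cd)) {
        // one bisection step between last-outside and first-inside samples
        double tm = 0.5 * (tPrev + t);
        double th;
        if (insideAt(tm, ow, dw, ov, dv, m, d3, hasClip, cn, cd))
          th = 0.5 * (tPrev + tm);
        else
          th = 0.5 * (tm + t);
        hit[r] = true;
        tout[r] = th;
        break;
      }
      tPrev = t;
    }
  }
  return List::create(_["hit"] = hit, _["t"] = tout);
}

// Front-to-back compositing of CT values through a piecewise-linear transfer
// function, restricted to the bone mask (opacity 0 outside it). tfBreaks must
// be strictly increasing; colours/opacities are interpolated linearly and
// clamped at the ends. Opacities are interpreted per sample at the given
// step size. Returns premultiplied accumulated colour and alpha per ray.
// [[Rcpp::export(name = ".cppComposite")]]
List cppComposite(NumericVector vol, LogicalVector mask, IntegerVector dim,
                  NumericMatrix worldToVox, NumericMatrix origins,
                  NumericVector dir, double step,
                  bool hasClip, NumericVector clipN, double clipD,
                  NumericVector tfBreaks, NumericMatrix tfColor,
                  NumericVector tfAlpha) {
  VoxMap vm = makeMap(worldToVox);
  int d3[3] = {dim[0], dim[1], dim[2]};
  const int* m = LOGICAL(mask);
  const double* v = REAL(vol);
  int n = origins.nrow(), nb = tfBreaks.size();
  NumericMatrix col(n, 3);
  NumericVector alpha(n);
  double dw[3] = {dir[0], dir[1], dir[2]};
  double dv[3];
  for (int r = 0; r < 3; ++r)
    dv[r] = vm.m[r][0] * dw[0] + vm.m[r][1] * dw[1] + vm.m[r][2] * dw[2];
  double cn[3] = {0, 0, 0};
  double cd = 0;
  if (hasClip) { cn[0] = clipN[0]; cn[1] = clipN[1]; cn[2] = clipN[2]; cd = clipD; }

  for (int r = 0; r < n; ++r) {
    double ow[3] = {origins(r, 0), origins(r, 1), origins(r, 2)};
    double ov[3];
    vm.apply(ow, ov);
    double t0, t1;
    if (!boxClip(ov, dv, d3, t0, t1)) continue;
    if (t0 < 0) t0 = 0;
    double A = 0, C[3] = {0, 0, 0};
    for (double t = t0; t <= t1 && A < 0.995; t += step) {
      if (!insideAt(t, ow, dw, ov, dv, m, d3, hasClip, cn, cd)) continue;
      double p[3] = {ov[0] + t * dv[0], ov[1] + t * dv[1], ov[2] + t * dv[2]};
      double val = bf_sample3(v, d3[0], d3[1], d3[2], p[0], p[1], p[2]);
      // piecewise-linear transfer function lookup
      double a, c0, c1, c2;
      if (val <= tfBreaks[0]) {
        a = tfAlpha[0]; c0 = tfColor(0, 0); c1 = tfColor(0, 1); c2 = tfColor(0, 2);
      } else if (val >= tfBreaks[nb - 1]) {
        a = tfAlpha[nb - 1];
        c0 = tfColor(nb - 1, 0); c1 = tfColor(nb - 1, 1); c2 = tfColor(nb - 1, 2);
      } else {
        int s = 0;
        while (s < nb - 2 && val > tfBreaks[s + 1]) ++s;
        double f = (val - tfBreaks[s]) / (tfBreaks[s + 1] - tfBreaks[s]);
        a = (1 - f) * tfAlpha[s] + f * tfAlpha[s + 1];
        c0 = (1 - f) * tfColor(s, 0) + f * tfColor(s + 1, 0);
        c1 = (1 - f) * tfColor(s, 1) + f * tfColor(s + 1, 1);
        c2 = (1 - f) * tfColor(s, 2) + f * tfColor(s + 1, 2);
      }
      double w = (1 - A) * a;
      C[0] += w * c0; C[1] += w * c1; C[2] += w * c2;
      A += w;
    }
    col(r, 0) = C[0]; col(r, 1) = C[1]; col(r, 2) = C[2];
    alpha[r] = A;
  }
  return List::create(_["color"] = col, _["alpha"] = alpha);
}
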