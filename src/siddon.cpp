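#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Parametric intersection of a ray with an axis-aligned box.
// Returns false when the ray misses. Directions are unit-norm so the
// parameter t is in mm.
static bool box_clip(const double *lo, const double *hi,
                     const double *o, const double *d,
                     double &t0, double &t1) {
  t0 = -std::numeric_limits<double>::infinity();
  t1 = std::numeric_limits<double>::infinity();
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(d[a]) < 1e-14) {
      if (o[a] < lo[a] || o[a] > hi[a]) return false;
    } else {
      double ta = (lo[a] - o[a]) / d[a];
      double tb = (hi[a] - o[a]) / d[a];
      if (ta > tb) std::swap(ta, tb);
      if (ta > t0) t0 = ta;
      if (tb < t1) t1 = tb;
    }
  }
  return t1 > t0 + 1e-12;
}

struct GridGeom {
  int n[3];
  double sp[3], lo[3], hi[3];
  GridGeom(IntegerVector dims, NumericVector spacing, NumericVector origin) {
    for (int a = 0; a < 3; ++a) {
      n[a] = dims[a];
      sp[a] = spacing[a];
      lo[a] = origin[a];
      hi[a] = origin[a] + n[a] * sp[a];
    }
  }
  inline R_xlen_t idx(int i, int j, int k) const {
    return (R_xlen_t)i + (R_xlen_t)n[0] * ((R_xlen_t)j + (R_xlen_t)n[1] * k);
  }
};

// Walk one ray through the grid, appending (voxel, chord length) pairs.
// Classic Siddon/Amanatides-Woo traversal; coincident plane crossings
// (corner hits) are merged by advancing every axis whose crossing parameter
// ties within 1e-12, and zero-length segments are skipped.
template <typename F>
static void traverse(const GridGeom &g, const double *o, const double *d,
                     F emit) {
  double t0, t1;
  if (!box_clip(g.lo, g.hi, o, d, t0, t1)) return;
  if (t0 < 0 && t1 < 0) return;  // entirely behind the source is still valid
  int iv[3], step[3];
  double tmax[3], tdelta[3];
  const double tie = 1e-12;
  for (int a = 0; a < 3; ++a) {
    double x = o[a] + t0 * d[a];
    int i = (int)std::floor((x - g.lo[a]) / g.sp[a]);
    if (i < 0) i = 0;
    if (i >= g.n[a]) i = g.n[a] - 1;
    iv[a] = i;
    if (d[a] > 1e-14) {
      step[a] = 1;
      tmax[a] = (g.lo[a] + (i + 1) * g.sp[a] - o[a]) / d[a];
      tdelta[a] = g.sp[a] / d[a];
    } else if (d[a] < -1e-14) {
      step[a] = -1;
      tmax[a] = (g.lo[a] + i * g.sp[a] - o[a]) / d[a];
      tdelta[a] = -g.sp[a] / d[a];
    } else {
      step[a] = 0;
      tmax[a] = std::numeric_limits<double>::infinity();
      tdelta[a] = std::numeric_limits<double>::infinity();
    }
  }
  double t = t0;
  while (t < t1 - tie) {
    double tn = std::min(std::min(tmax[0], tmax[1]), tmax[2]);
    if (tn > t1) tn = t1;
    double len = tn - t;
    if (len > tie) emit(iv[0], iv[1], iv[2], len, t);
    bool moved = false;
    for (int a = 0; a < 3; ++a) {
      if (tmax[a] <= tn + tie) {
        iv[a] += step[a];
        tmax[a] += tdelta[a];
        moved = true;
        if (iv[a] < 0 || iv[a] >= g.n[a]) { t = t1; break; }
      }
    }
    t = (t >= t1) ? t1 : tn;
    if (!moved) break;  // numerical safety; cannot normally happen
  }
}

// [[Rcpp::export]]
List cpp_siddon_trace(IntegerVector dims, NumericVector spacing,
                      NumericVector origin, NumericVector o, NumericVector d) {
  GridGeom g(dims, spacing, origin);
  std::vector<int> vi, vj, vk;
  std::vector<double> len, tin;
  traverse(g, REAL(o), REAL(d),
           [&](int i, int j, int k, double L, double t) {
             vi.push_back(i + 1); vj.push_back(j + 1); vk.push_back(k + 1);
             len.push_back(L); tin.push_back(t);
           });
  return List::create(_["i"] = wrap(vi), _["j"] = wrap(vj), _["k"] = wrap(vk),
                      _["length_mm"] = wrap(len), _["t_entry_mm"] = wrap(tin));
}

// [[Rcpp::export]]
NumericVector cpp_siddon_integrate(NumericVector values, IntegerVector dims,
                                   NumericVector spacing, NumericVector origin,
                                   NumericMatrix origins, NumericMatrix dirs) {
  GridGeom g(dims, spacing, origin);
  R_xlen_t nr = origins.nrow();
  NumericVector out(nr);
  const double *val = REAL(values);
  for (R_xlen_t r = 0; r < nr; ++r) {
    double o[3] = {origins(r, 0), origins(r, 1), origins(r, 2)};
    double d[3] = {dirs(r, 0), dirs(r, 1), dirs(r, 2)};
    double acc = 0.0;
    traverse(g, o, d, [&](int i, int j, int k, double L, double) {
      acc += val[g.idx(i, j, k)] * L;
    });
    out[r] = acc;
  }
  return out;
}

// Value of the voxel containing each point; 0 outside the grid box.
// [[Rcpp::export]]
NumericVector cpp_voxel_lookup(NumericVector values, IntegerVector dims,
                               NumericVector spacing, NumericVector origin,
                               NumericMatrix pts) {
  GridGeom g(dims, spacing, origin);
  R_xlen_t np = pts.nrow();
  NumericVector out(np);
  const double *val = REAL(values);
  for (R_xlen_t p = 0; p < np; ++p) {
    int iv[3];
    bool inside = true;
    for (int a = 0; a < 3; ++a) {
      double x = pts(p, a);
      if (x < g.lo[a] || x > g.hi[a]) { inside = false; break; }
      int i = (int)std::floor((x - g.lo[a]) / g.sp[a]);
      if (i == g.n[a]) i = g.n[a] - 1;  // exact upper face
      iv[a] = i;
    }
    out[p] = inside ? val[g.idx(iv[0], iv[1], iv[2])] : 0.0;
  }
  return out;
}

// Trilinear interpolation between voxel centers, border-replicated so that
// points within the outer half-voxel shell still get sensible values;
// 0 outside the grid bounding box.
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector values, IntegerVector dims,
                            NumericVector spacing, NumericVector origin,
                            NumericMatrix pts) {
  GridGeom g(dims, spacing, origin);
  R_xlen_t np = pts.nrow();
  NumericVector out(np);
  const double *val = REAL(values);
  for (R_xlen_t p = 0; p < np; ++p) {
    double w[3];
    int i0[3], i1[3];
    bool inside = true;
    for (int a = 0; a < 3; ++a) {
      double x = pts(p, a);
      if (x < g.lo[a] || x > g.hi[a]) { inside = false; break; }
      double u = (x - g.lo[a]) / g.sp[a] - 0.5;
      int i = (int)std::floor(u);
      double f = u - i;
      if (i < 0) { i = 0; f = 0.0; }
      if (i >= g.n[a] - 1) { i = g.n[a] - 1; f = 0.0; }
      i0[a] = i;
      i1[a] = (i + 1 < g.n[a]) ? i + 1 : i;
      w[a] = f;
    }
    if (!inside) { out[p] = 0.0; continue; }
    double acc = 0.0;
    for (int c = 0; c < 8; ++c) {
      int ia = (c & 1) ? i1[0] : i0[0];
      int ja = (c & 2) ? i1[1] : i0[1];
      int ka = (c & 4) ? i1[2] : i0[2];
      double ww = ((c & 1) ? w[0] : 1 - w[0]) *
                  ((c & 2) ? w[1] : 1 - w[1]) *
                  ((c & 4) ? w[2] : 1 - w[2]);
      acc += ww * val[g.idx(ia, ja, ka)];
    }
    out[p] = acc;
  }
  return out;
}

// Entry/exit parameters of many rays against one box; NA for misses.
// [[Rcpp::export]]
NumericMatrix cpp_box_clip(NumericVector lo, NumericVector hi,
                           NumericMatrix origins, NumericMatrix dirs) {
  R_xlen_t nr = origins.nrow();
  NumericMatrix out(nr, 2);
  for (R_xlen_t r = 0; r < nr; ++r) {
    double o[3] = {origins(r, 0), origins(r, 1), origins(r, 2)};
    double d[3] = {dirs(r, 0), dirs(r, 1), dirs(r, 2)};
    double t0, t1;
    if (box_clip(REAL(lo), REAL(hi), o, d, t0, t1)) {
      out(r, 0) = t0; out(r, 1) = t1;
    } else {
      out(r, 0) = NA_REAL; out(r, 1) = NA_REAL;
    }
  }
  return out;
}
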