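// Low-level geometry kernels: spatially indexed closest-point queries,
// sampled triangle-triangle self-intersection tests, z-column ray-cast
// volume integration, signed-distance-field voxelization of strut/block
// primitives, and marching-tetrahedra surface extraction.
// All coordinates are millimetres; all face indices crossing the R
// boundary are 1-based.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>
#include <unordered_map>
#include <unordered_set>

using namespace Rcpp;

static const double BIG = 1e30;

// ---------------------------------------------------------------------------
// small vector helpers

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline void sub3(const double* a, const double* b, double* out) {
  out[0] = a[0] - b[0]; out[1] = a[1] - b[1]; out[2] = a[2] - b[2];
}
static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double norm3(const double* a) { return std::sqrt(dot3(a, a)); }

// Closest point on triangle abc to p (Ericson, Real-Time Collision Detection)
static void closestPtTriangle(const double* p, const double* a, const double* b,
                              const double* c, double* out) {
  double ab[3], ac[3], ap[3];
  sub3(b, a, ab); sub3(c, a, ac); sub3(p, a, ap);
  double d1 = dot3(ab, ap), d2 = dot3(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) { out[0]=a[0]; out[1]=a[1]; out[2]=a[2]; return; }
  double bp[3]; sub3(p, b, bp);
  double d3 = dot3(ab, bp), d4 = dot3(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) { out[0]=b[0]; out[1]=b[1]; out[2]=b[2]; return; }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + v * ab[k];
    return;
  }
  double cp[3]; sub3(p, c, cp);
  double d5 = dot3(ab, cp), d6 = dot3(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) { out[0]=c[0]; out[1]=c[1]; out[2]=c[2]; return; }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + w * ac[k];
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int k = 0; k < 3; ++k) out[k] = b[k] + w * (c[k] - b[k]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int k = 0; k < 3; ++k) out[k] = a[k] + ab[k] * v + ac[k] * w;
}

// ---------------------------------------------------------------------------
// uniform-grid triangle index

struct MeshIndex {
  std::vector<double> V;   // 3 * nv
  std::vector<int> F;      // 3 * nf (0-based)
  int nv = 0, nf = 0;
  double bmin[3], bmax[3];
  double csz[3];
  int nd[3];
  double mincell = 0.0;
  std::vector<std::vector<int>> cells;
  mutable std::vector<int> stamp;
  mutable int stampCtr = 0;

  int cellIndex(int ix, int iy, int iz) const {
    return (iz * nd[1] + iy) * nd[0] + ix;
  }
};

static MeshIndex* buildIndex(const NumericMatrix& Vm, const IntegerMatrix& Fm) {
  MeshIndex* idx = new MeshIndex();
  idx->nv = Vm.nrow(); idx->nf = Fm.nrow();
  idx->V.resize(3 * idx->nv);
  for (int i = 0; i < idx->nv; ++i)
    for (int k = 0; k < 3; ++k) idx->V[3 * i + k] = Vm(i, k);
  idx->F.resize(3 * idx->nf);
  for (int i = 0; i < idx->nf; ++i)
    for (int k = 0; k < 3; ++k) idx->F[3 * i + k] = Fm(i, k) - 1;

  for (int k = 0; k < 3; ++k) { idx->bmin[k] = BIG; idx->bmax[k] = -BIG; }
  for (int i = 0; i < idx->nv; ++i)
    for (int k = 0; k < 3; ++k) {
      idx->bmin[k] = std::min(idx->bmin[k], idx->V[3 * i + k]);
      idx->bmax[k] = std::max(idx->bmax[k], idx->V[3 * i + k]);
    }
  double ext[3], maxext = 0.0;
  for (int k = 0; k < 3; ++k) {
    ext[k] = std::max(idx->bmax[k] - idx->bmin[k], 1e-9);
    maxext = std::max(maxext, ext[k]);
  }
  // aim for ~2 triangles per occupied cell, bounded grid dims
  double cell = std::cbrt(ext[0] * ext[1] * ext[2] / std::max(idx->nf, 1)) * 1.6;
  if (!(cell > 0.0) || cell < maxext / 160.0) cell = maxext / 160.0;
  for (int k = 0; k < 3; ++k) {
    idx->nd[k] = std::max(1, std::min(160, (int)std::ceil(ext[k] / cell)));
    idx->csz[k] = ext[k] / idx->nd[k];
  }
  idx->mincell = std::min({idx->csz[0], idx->csz[1], idx->csz[2]});
  idx->cells.assign((size_t)idx->nd[0] * idx->nd[1] * idx->nd[2], {});

  for (int f = 0; f < idx->nf; ++f) {
    double lo[3] = {BIG, BIG, BIG}, hi[3] = {-BIG, -BIG, -BIG};
    for (int c = 0; c < 3; ++c) {
      const double* v = &idx->V[3 * idx->F[3 * f + c]];
      for (int k = 0; k < 3; ++k) {
        lo[k] = std::min(lo[k], v[k]);
        hi[k] = std::max(hi[k], v[k]);
      }
    }
    int i0[3], i1[3];
    for (int k = 0; k < 3; ++k) {
      i0[k] = std::max(0, std::min(idx->nd[k] - 1,
              (int)std::floor((lo[k] - idx->bmin[k]) / idx->csz[k])));
      i1[k] = std::max(0, std::min(idx->nd[k] - 1,
              (int)std::floor((hi[k] - idx->bmin[k]) / idx->csz[k])));
    }
    for (int iz = i0[2]; iz <= i1[2]; ++iz)
      for (int iy = i0[1]; iy <= i1[1]; ++iy)
        for (int ix = i0[0]; ix <= i1[0]; ++ix)
          idx->cells[idx->cellIndex(ix, iy, iz)].push_back(f);
  }
  idx->stamp.assign(idx->nf, -1);
  return idx;
}

static void queryIndex(const MeshIndex* idx, const double* p,
                       double* bestPt, double* bestD, int* bestF) {
  int cc[3];
  for (int k = 0; k < 3; ++k) {
    int c = (int)std::floor((p[k] - idx->bmin[k]) / idx->csz[k]);
    cc[k] = std::max(0, std::min(idx->nd[k] - 1, c));
  }
  double best = BIG; int bf = -1; double bp[3] = {0, 0, 0};
  int maxr = std::max({idx->nd[0], idx->nd[1], idx->nd[2]});
  idx->stampCtr++;
  for (int r = 0; r <= maxr; ++r) {
    // cells at Chebyshev ring r hold points at distance >= (r-1) * mincell
    if (bf >= 0 && best <= (double)(r - 1) * idx->mincell) break;
    bool any = false;
    int x0 = cc[0] - r, x1 = cc[0] + r;
    int y0 = cc[1] - r, y1 = cc[1] + r;
    int z0 = cc[2] - r, z1 = cc[2] + r;
    for (int iz = z0; iz <= z1; ++iz) {
      if (iz < 0 || iz >= idx->nd[2]) continue;
      for (int iy = y0; iy <= y1; ++iy) {
        if (iy < 0 || iy >= idx->nd[1]) continue;
        for (int ix = x0; ix <= x1; ++ix) {
          if (ix < 0 || ix >= idx->nd[0]) continue;
          // only the shell of the ring
          if (r > 0 && ix != x0 && ix != x1 && iy != y0 && iy != y1 &&
              iz != z0 && iz != z1)
            continue;
          any = true;
          const std::vector<int>& tris =
              idx->cells[idx->cellIndex(ix, iy, iz)];
          for (int f : tris) {
            if (idx->stamp[f] == idx->stampCtr) continue;
            idx->stamp[f] = idx->stampCtr;
            const double* a = &idx->V[3 * idx->F[3 * f + 0]];
            const double* b = &idx->V[3 * idx->F[3 * f + 1]];
            const double* c = &idx->V[3 * idx->F[3 * f + 2]];
            double q[3];
            closestPtTriangle(p, a, b, c, q);
            double d[3]; sub3(p, q, d);
            double dist = norm3(d);
            if (dist < best) {
              best = dist; bf = f;
              bp[0] = q[0]; bp[1] = q[1]; bp[2] = q[2];
            }
          }
        }
      }
    }
    if (!any && bf >= 0) break;
  }
  bestPt[0] = bp[0]; bestPt[1] = bp[1]; bestPt[2] = bp[2];
  *bestD = best; *bestF = bf;
}

// [[Rcpp::export]]
SEXP cpp_mesh_index(NumericMatrix V, IntegerMatrix F) {
  XPtr<MeshIndex> ptr(buildIndex(V, F), true);
  return ptr;
}

// [[Rcpp::export]]
List cpp_closest_point(SEXP idxptr, NumericMatrix P) {
  XPtr<MeshIndex> idx(idxptr);
  int n = P.nrow();
  NumericMatrix Q(n, 3);
  NumericVector D(n);
  IntegerVector Fi(n);
  for (int i = 0; i < n; ++i) {
    double p[3] = {P(i, 0), P(i, 1), P(i, 2)};
    double q[3], d; int f;
    queryIndex(idx.get(), p, q, &d, &f);
    Q(i, 0) = q[0]; Q(i, 1) = q[1]; Q(i, 2) = q[2];
    D[i] = d; Fi[i] = f + 1;
  }
  return List::create(_["point"] = Q, _["dist"] = D, _["face"] = Fi);
}

// One-shot convenience (builds the index, queries, frees it).
// [[Rcpp::export]]
List cpp_closest_point_mesh(NumericMatrix V, IntegerMatrix F, NumericMatrix P) {
  MeshIndex* idx = buildIndex(V, F);
  int n = P.nrow();
  NumericMatrix Q(n, 3);
  NumericVector D(n);
  IntegerVector Fi(n);
  for (int i = 0; i < n; ++i) {
    double p[3] = {P(i, 0), P(i, 1), P(i, 2)};
    double q[3], d; int f;
    queryIndex(idx, p, q, &d, &f);
    Q(i, 0) = q[0]; Q(i, 1) = q[1]; Q(i, 2) = q[2];
    D[i] = d; Fi[i] = f + 1;
  }
  delete idx;
  return List::create(_["point"] = Q, _["dist"] = D, _["face"] = Fi);
}

// Closest point on a set of segments (boundary polylines are small; brute force)
// [[Rcpp::export]]
List cpp_closest_on_segments(NumericMatrix A, NumericMatrix B, NumericMatrix P) {
  int ns = A.nrow(), n = P.nrow();
  NumericMatrix Q(n, 3);
  NumericVector D(n);
  IntegerVector Si(n);
  for (int i = 0; i < n; ++i) {
    double p[3] = {P(i, 0), P(i, 1), P(i, 2)};
    double best = BIG, bq[3] = {0, 0, 0}; int bs = -1;
    for (int s = 0; s < ns; ++s) {
      double a[3] = {A(s, 0), A(s, 1), A(s, 2)};
      double b[3] = {B(s, 0), B(s, 1), B(s, 2)};
      double ab[3]; sub3(b, a, ab);
      double ap[3]; sub3(p, a, ap);
      double L2 = dot3(ab, ab);
      double t = (L2 > 0.0) ? dot3(ap, ab) / L2 : 0.0;
      t = std::max(0.0, std::min(1.0, t));
      double q[3] = {a[0] + t * ab[0], a[1] + t * ab[1], a[2] + t * ab[2]};
      double d[3]; sub3(p, q, d);
      double dist = norm3(d);
      if (dist < best) { best = dist; bs = s; bq[0]=q[0]; bq[1]=q[1]; bq[2]=q[2]; }
    }
    Q(i, 0) = bq[0]; Q(i, 1) = bq[1]; Q(i, 2) = bq[2];
    D[i] = best; Si[i] = bs + 1;
  }
  return List::create(_["point"] = Q, _["dist"] = D, _["segment"] = Si);
}

// ---------------------------------------------------------------------------
// sampled self-intersection test (Moller 1997 interval method)

static bool computeInterval(double pr0, double pr1, double pr2,
                            double d0, double d1, double d2,
                            double* lo, double* hi) {
  double a = 0, b = 0;
  if (d0 * d1 > 0.0) {
    a = pr2 + (pr0 - pr2) * d2 / (d2 - d0);
    b = pr2 + (pr1 - pr2) * d2 / (d2 - d1);
  } else if (d0 * d2 > 0.0) {
    a = pr1 + (pr0 - pr1) * d1 / (d1 - d0);
    b = pr1 + (pr2 - pr1) * d1 / (d1 - d2);
  } else if (d1 * d2 > 0.0 || d0 != 0.0) {
    a = pr0 + (pr1 - pr0) * d0 / (d0 - d1);
    b = pr0 + (pr2 - pr0) * d0 / (d0 - d2);
  } else if (d1 != 0.0) {
    a = pr1 + (pr0 - pr1) * d1 / (d1 - d0);
    b = pr1 + (pr2 - pr1) * d1 / (d1 - d2);
  } else if (d2 != 0.0) {
    a = pr2 + (pr0 - pr2) * d2 / (d2 - d0);
    b = pr2 + (pr1 - pr2) * d2 / (d2 - d1);
  } else {
    return false;  // coplanar — not handled by the sampled test
  }
  *lo = std::min(a, b); *hi = std::max(a, b);
  return true;
}

static bool triTriIntersect(const double* p0, const double* p1, const double* p2,
                            const double* q0, const double* q1, const double* q2) {
  const double EPS = 1e-10;
  double e1[3], e2[3], n1[3];
  sub3(p1, p0, e1); sub3(p2, p0, e2); cross3(e1, e2, n1);
  double d1c = -dot3(n1, p0);
  double dq0 = dot3(n1, q0) + d1c, dq1 = dot3(n1, q1) + d1c, dq2 = dot3(n1, q2) + d1c;
  if (std::fabs(dq0) < EPS) dq0 = 0; if (std::fabs(dq1) < EPS) dq1 = 0;
  if (std::fabs(dq2) < EPS) dq2 = 0;
  if ((dq0 > 0 && dq1 > 0 && dq2 > 0) || (dq0 < 0 && dq1 < 0 && dq2 < 0)) return false;

  double f1[3], f2[3], n2[3];
  sub3(q1, q0, f1); sub3(q2, q0, f2); cross3(f1, f2, n2);
  double d2c = -dot3(n2, q0);
  double dp0 = dot3(n2, p0) + d2c, dp1 = dot3(n2, p1) + d2c, dp2 = dot3(n2, p2) + d2c;
  if (std::fabs(dp0) < EPS) dp0 = 0; if (std::fabs(dp1) < EPS) dp1 = 0;
  if (std::fabs(dp2) < EPS) dp2 = 0;
  if ((dp0 > 0 && dp1 > 0 && dp2 > 0) || (dp0 < 0 && dp1 < 0 && dp2 < 0)) return false;

  double D[3]; cross3(n1, n2, D);
  int axis = 0;
  double m = std::fabs(D[0]);
  if (std::fabs(D[1]) > m) { m = std::fabs(D[1]); axis = 1; }
  if (std::fabs(D[2]) > m) { axis = 2; }

  double lo1, hi1, lo2, hi2;
  if (!computeInterval(p0[axis], p1[axis], p2[axis], dp0, dp1, dp2, &lo1, &hi1))
    return false;
  if (!computeInterval(q0[axis], q1[axis], q2[axis], dq0, dq1, dq2, &lo2, &hi2))
    return false;
  return std::max(lo1, lo2) < std::min(hi1, hi2) - 1e-12;
}

// Count intersecting non-adjacent triangle pairs, pruned by a uniform grid,
// stopping after max_pairs candidate tests (sampled diagnostic).
// [[Rcpp::export]]
int cpp_self_intersections(NumericMatrix V, IntegerMatrix F, int max_pairs) {
  MeshIndex* idx = buildIndex(V, F);
  std::unordered_set<uint64_t> tested;
  int count = 0;
  long budget = max_pairs;
  size_t ncells = idx->cells.size();
  for (size_t c = 0; c < ncells && budget > 0; ++c) {
    const std::vector<int>& tris = idx->cells[c];
    for (size_t a = 0; a < tris.size() && budget > 0; ++a) {
      for (size_t b = a + 1; b < tris.size() && budget > 0; ++b) {
        int fa = std::min(tris[a], tris[b]), fb = std::max(tris[a], tris[b]);
        uint64_t key = (uint64_t)fa * (uint64_t)idx->nf + (uint64_t)fb;
        if (tested.count(key)) continue;
        tested.insert(key);
        // skip pairs sharing a vertex
        bool share = false;
        for (int i = 0; i < 3 && !share; ++i)
          for (int j = 0; j < 3; ++j)
            if (idx->F[3 * fa + i] == idx->F[3 * fb + j]) { share = true; break; }
        if (share) continue;
        budget--;
        const double* p0 = &idx->V[3 * idx->F[3 * fa + 0]];
        const double* p1 = &idx->V[3 * idx->F[3 * fa + 1]];
        const double* p2 = &idx->V[3 * idx->F[3 * fa + 2]];
        const double* q0 = &idx->V[3 * idx->F[3 * fb + 0]];
        const double* q1 = &idx->V[3 * idx->F[3 * fb + 1]];
        const double* q2 = &idx->V[3 * idx->F[3 * fb + 2]];
        if (triTriIntersect(p0, p1, p2, q0, q1, q2)) count++;
      }
    }
  }
  delete idx;
  return count;
}

// ---------------------------------------------------------------------------
// z-column ray-cast volume (independent of the divergence-theorem path)

static void columnCrossings(const NumericMatrix& V, const IntegerMatrix& F,
                            double x0, double y0, double pitch, int nx, int ny,
                            std::vector<std::vector<double>>& cols) {
  int nf = F.nrow();
  for (int f = 0; f < nf; ++f) {
    double ax = V(F(f, 0) - 1, 0), ay = V(F(f, 0) - 1, 1), az = V(F(f, 0) - 1, 2);
    double bx = V(F(f, 1) - 1, 0), by = V(F(f, 1) - 1, 1), bz = V(F(f, 1) - 1, 2);
    double cx = V(F(f, 2) - 1, 0), cy = V(F(f, 2) - 1, 1), cz = V(F(f, 2) - 1, 2);
    double det = (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
    if (std::fabs(det) < 1e-14) continue;  // edge-on: measure-zero contribution
    double lox = std::min({ax, bx, cx}), hix = std::max({ax, bx, cx});
    double loy = std::min({ay, by, cy}), hiy = std::max({ay, by, cy});
    int i0 = std::max(0, (int)std::ceil((lox - x0) / pitch));
    int i1 = std::min(nx - 1, (int)std::floor((hix - x0) / pitch));
    int j0 = std::max(0, (int)std::ceil((loy - y0) / pitch));
    int j1 = std::min(ny - 1, (int)std::floor((hiy - y0) / pitch));
    for (int j = j0; j <= j1; ++j) {
      double py = y0 + j * pitch;
      for (int i = i0; i <= i1; ++i) {
        double px = x0 + i * pitch;
        double l1 = ((bx - px) * (cy - py) - (by - py) * (cx - px)) / det;
        double l2 = ((cx - px) * (ay - py) - (cy - py) * (ax - px)) / det;
        double l3 = 1.0 - l1 - l2;
        if (l1 < 0.0 || l2 < 0.0 || l3 < 0.0) continue;
        double z = l1 * az + l2 * bz + l3 * cz;
        cols[(size_t)j * nx + i].push_back(z);
      }
    }
  }
}

// [[Rcpp::export]]
double cpp_raycast_volume(NumericMatrix V, IntegerMatrix F, double pitch) {
  double xmin = BIG, xmax = -BIG, ymin = BIG, ymax = -BIG;
  for (int i = 0; i < V.nrow(); ++i) {
    xmin = std::min(xmin, V(i, 0)); xmax = std::max(xmax, V(i, 0));
    ymin = std::min(ymin, V(i, 1)); ymax = std::max(ymax, V(i, 1));
  }
  // irrational fractional offsets keep columns off vertices/edges
  double x0 = xmin + 0.5137931 * pitch, y0 = ymin + 0.7182818 * pitch;
  int nx = std::max(1, (int)std::ceil((xmax - x0) / pitch));
  int ny = std::max(1, (int)std::ceil((ymax - y0) / pitch));
  std::vector<std::vector<double>> cols((size_t)nx * ny);
  columnCrossings(V, F, x0, y0, pitch, nx, ny, cols);
  double vol = 0.0;
  for (auto& zs : cols) {
    if (zs.empty()) continue;
    std::sort(zs.begin(), zs.end());
    if (zs.size() % 2 != 0) continue;  // degenerate column: skip
    for (size_t k = 0; k + 1 < zs.size(); k += 2) vol += zs[k + 1] - zs[k];
  }
  return vol * pitch * pitch;
}

static void toIntervals(std::vector<double>& zs,
                        std::vector<std::pair<double, double>>& iv) {
  if (zs.empty() || zs.size() % 2 != 0) return;
  std::sort(zs.begin(), zs.end());
  for (size_t k = 0; k + 1 < zs.size(); k += 2) iv.push_back({zs[k], zs[k + 1]});
}

// Volume of the union of two closed meshes by column-interval union.
// [[Rcpp::export]]
double cpp_union_volume(NumericMatrix VA, IntegerMatrix FA,
                        NumericMatrix VB, IntegerMatrix FB, double pitch) {
  double xmin = BIG, xmax = -BIG, ymin = BIG, ymax = -BIG;
  for (int i = 0; i < VA.nrow(); ++i) {
    xmin = std::min(xmin, VA(i, 0)); xmax = std::max(xmax, VA(i, 0));
    ymin = std::min(ymin, VA(i, 1)); ymax = std::max(ymax, VA(i, 1));
  }
  for (int i = 0; i < VB.nrow(); ++i) {
    xmin = std::min(xmin, VB(i, 0)); xmax = std::max(xmax, VB(i, 0));
    ymin = std::min(ymin, VB(i, 1)); ymax = std::max(ymax, VB(i, 1));
  }
  double x0 = xmin + 0.5137931 * pitch, y0 = ymin + 0.7182818 * pitch;
  int nx = std::max(1, (int)std::ceil((xmax - x0) / pitch));
  int ny = std::max(1, (int)std::ceil((ymax - y0) / pitch));
  std::vector<std::vector<double>> colsA((size_t)nx * ny), colsB((size_t)nx * ny);
  columnCrossings(VA, FA, x0, y0, pitch, nx, ny, colsA);
  columnCrossings(VB, FB, x0, y0, pitch, nx, ny, colsB);
  double vol = 0.0;
  for (size_t c = 0; c < colsA.size(); ++c) {
    std::vector<std::pair<double, double>> iv;
    toIntervals(colsA[c], iv);
    toIntervals(colsB[c], iv);
    if (iv.empty()) continue;
    std::sort(iv.begin(), iv.end());
    double lo = iv[0].first, hi = iv[0].second;
    for (size_t k = 1; k < iv.size(); ++k) {
      if (iv[k].first > hi) { vol += hi - lo; lo = iv[k].first; hi = iv[k].second; }
      else hi = std::max(hi, iv[k].second);
    }
    vol += hi - lo;
  }
  return vol * pitch * pitch;
}

// Count proper crossings of segment a->b with the mesh (Moller-Trumbore).
// [[Rcpp::export]]
int cpp_segment_crossings(NumericMatrix V, IntegerMatrix F,
                          NumericVector a, NumericVector b) {
  double o[3] = {a[0], a[1], a[2]};
  double d[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  int count = 0;
  for (int f = 0; f < F.nrow(); ++f) {
    const double* v0 = &V(F(f, 0) - 1, 0);
    // NumericMatrix is column-major; copy explicitly
    double p0[3] = {V(F(f, 0) - 1, 0), V(F(f, 0) - 1, 1), V(F(f, 0) - 1, 2)};
    double p1[3] = {V(F(f, 1) - 1, 0), V(F(f, 1) - 1, 1), V(F(f, 1) - 1, 2)};
    double p2[3] = {V(F(f, 2) - 1, 0), V(F(f, 2) - 1, 1), V(F(f, 2) - 1, 2)};
    (void)v0;
    double e1[3], e2[3]; sub3(p1, p0, e1); sub3(p2, p0, e2);
    double pv[3]; cross3(d, e2, pv);
    double det = dot3(e1, pv);
    if (std::fabs(det) < 1e-12) continue;
    double inv = 1.0 / det;
    double tv[3]; sub3(o, p0, tv);
    double u = dot3(tv, pv) * inv;
    if (u < 0.0 || u > 1.0) continue;
    double qv[3]; cross3(tv, e1, qv);
    double w = dot3(d, qv) * inv;
    if (w < 0.0 || u + w > 1.0) continue;
    double t = dot3(e2, qv) * inv;
    if (t > 1e-9 && t < 1.0 - 1e-9) count++;
  }
  return count;
}

// ---------------------------------------------------------------------------
// signed distance fields on a regular grid

static inline size_t gidx(int ix, int iy, int iz, const int* dims) {
  return ((size_t)iz * dims[1] + iy) * dims[0] + ix;
}

static inline double sdSegment(const double* p, const double* a, const double* b,
                               double r) {
  double ab[3]; sub3(b, a, ab);
  double ap[3]; sub3(p, a, ap);
  double L2 = dot3(ab, ab);
  double t = (L2 > 0.0) ? dot3(ap, ab) / L2 : 0.0;
  t = std::max(0.0, std::min(1.0, t));
  double q[3] = {ap[0] - t * ab[0], ap[1] - t * ab[1], ap[2] - t * ab[2]};
  return norm3(q) - r;
}

static inline double sdCylinder(const double* p, const double* a, const double* b,
                                double r) {
  double ab[3]; sub3(b, a, ab);
  double h = norm3(ab);
  double u[3] = {ab[0] / h, ab[1] / h, ab[2] / h};
  double ap[3]; sub3(p, a, ap);
  double y = dot3(ap, u);
  double rad2 = dot3(ap, ap) - y * y;
  double x = std::sqrt(std::max(rad2, 0.0)) - r;
  double z = std::max(-y, y - h);
  double ox = std::max(x, 0.0), oz = std::max(z, 0.0);
  return std::min(std::max(x, z), 0.0) + std::sqrt(ox * ox + oz * oz);
}

// boxes row: center(3), xaxis(3), yaxis(3), zaxis(3), half(3)  — 15 columns
static inline double sdBoxRow(const double* p, const NumericMatrix& B, int row) {
  double rel[3] = {p[0] - B(row, 0), p[1] - B(row, 1), p[2] - B(row, 2)};
  double q[3];
  for (int k = 0; k < 3; ++k) {
    double ax[3] = {B(row, 3 + 3 * k), B(row, 4 + 3 * k), B(row, 5 + 3 * k)};
    q[k] = std::fabs(dot3(rel, ax)) - B(row, 12 + k);
  }
  double o[3] = {std::max(q[0], 0.0), std::max(q[1], 0.0), std::max(q[2], 0.0)};
  double inside = std::min(std::max(q[0], std::max(q[1], q[2])), 0.0);
  return norm3(o) + inside;
}

// Fill f over the primitive's padded grid bbox with min (union) of prim SDF.
template <typename SDF>
static void fillMin(std::vector<double>& f, const double* origin, const int* dims,
                    double pitch, const double* lo, const double* hi, double pad,
                    SDF sdf) {
  int i0[3], i1[3];
  for (int k = 0; k < 3; ++k) {
    i0[k] = std::max(0, (int)std::floor((lo[k] - pad - origin[k]) / pitch));
    i1[k] = std::min(dims[k] - 1, (int)std::ceil((hi[k] + pad - origin[k]) / pitch));
  }
  for (int iz = i0[2]; iz <= i1[2]; ++iz)
    for (int iy = i0[1]; iy <= i1[1]; ++iy)
      for (int ix = i0[0]; ix <= i1[0]; ++ix) {
        double p[3] = {origin[0] + ix * pitch, origin[1] + iy * pitch,
                       origin[2] + iz * pitch};
        size_t g = gidx(ix, iy, iz, dims);
        double d = sdf(p);
        if (d < f[g]) f[g] = d;
      }
}

template <typename SDF>
static void fillSubtract(std::vector<double>& f, const double* origin,
                         const int* dims, double pitch, const double* lo,
                         const double* hi, double pad, SDF sdf) {
  int i0[3], i1[3];
  for (int k = 0; k < 3; ++k) {
    i0[k] = std::max(0, (int)std::floor((lo[k] - pad - origin[k]) / pitch));
    i1[k] = std::min(dims[k] - 1, (int)std::ceil((hi[k] + pad - origin[k]) / pitch));
  }
  for (int iz = i0[2]; iz <= i1[2]; ++iz)
    for (int iy = i0[1]; iy <= i1[1]; ++iy)
      for (int ix = i0[0]; ix <= i1[0]; ++ix) {
        double p[3] = {origin[0] + ix * pitch, origin[1] + iy * pitch,
                       origin[2] + iz * pitch};
        size_t g = gidx(ix, iy, iz, dims);
        double d = -sdf(p);
        if (d > f[g]) f[g] = d;
      }
}

// Signed distance field of union(spheres, capsules, boxes) minus hole
// cylinders, optionally intersected with a half-space (plane = c(n, off):
// keep where n.x + off <= 0). Negative inside.
// [[Rcpp::export]]
NumericVector cpp_sdf_primitives(NumericVector origin, IntegerVector dims,
                                 double pitch, NumericMatrix spheres,
                                 NumericMatrix capsules, NumericMatrix boxes,
                                 NumericMatrix holes, NumericVector plane) {
  int d3[3] = {dims[0], dims[1], dims[2]};
  double org[3] = {origin[0], origin[1], origin[2]};
  std::vector<double> f((size_t)d3[0] * d3[1] * d3[2], BIG);
  double pad = 2.0 * pitch;

  for (int s = 0; s < spheres.nrow(); ++s) {
    double c[3] = {spheres(s, 0), spheres(s, 1), spheres(s, 2)};
    double r = spheres(s, 3);
    double lo[3] = {c[0] - r, c[1] - r, c[2] - r};
    double hi[3] = {c[0] + r, c[1] + r, c[2] + r};
    fillMin(f, org, d3, pitch, lo, hi, pad, [&](const double* p) {
      double d[3]; sub3(p, c, d);
      return norm3(d) - r;
    });
  }
  for (int s = 0; s < capsules.nrow(); ++s) {
    double a[3] = {capsules(s, 0), capsules(s, 1), capsules(s, 2)};
    double b[3] = {capsules(s, 3), capsules(s, 4), capsules(s, 5)};
    double r = capsules(s, 6);
    double lo[3], hi[3];
    for (int k = 0; k < 3; ++k) {
      lo[k] = std::min(a[k], b[k]) - r;
      hi[k] = std::max(a[k], b[k]) + r;
    }
    fillMin(f, org, d3, pitch, lo, hi, pad, [&](const double* p) {
      return sdSegment(p, a, b, r);
    });
  }
  for (int s = 0; s < boxes.nrow(); ++s) {
    double diag = std::sqrt(boxes(s, 12) * boxes(s, 12) +
                            boxes(s, 13) * boxes(s, 13) +
                            boxes(s, 14) * boxes(s, 14));
    double lo[3] = {boxes(s, 0) - diag, boxes(s, 1) - diag, boxes(s, 2) - diag};
    double hi[3] = {boxes(s, 0) + diag, boxes(s, 1) + diag, boxes(s, 2) + diag};
    fillMin(f, org, d3, pitch, lo, hi, pad, [&](const double* p) {
      return sdBoxRow(p, boxes, s);
    });
  }
  for (int s = 0; s < holes.nrow(); ++s) {
    double a[3] = {holes(s, 0), holes(s, 1), holes(s, 2)};
    double b[3] = {holes(s, 3), holes(s, 4), holes(s, 5)};
    double r = holes(s, 6);
    double lo[3], hi[3];
    for (int k = 0; k < 3; ++k) {
      lo[k] = std::min(a[k], b[k]) - r;
      hi[k] = std::max(a[k], b[k]) + r;
    }
    // padded wide so f is raised near the hole wall inside solid material
    fillSubtract(f, org, d3, pitch, lo, hi, 10.0 + 2.0 * pitch,
                 [&](const double* p) { return sdCylinder(p, a, b, r); });
  }
  if (plane.size() == 4) {
    size_t n = f.size();
    for (int iz = 0; iz < d3[2]; ++iz)
      for (int iy = 0; iy < d3[1]; ++iy)
        for (int ix = 0; ix < d3[0]; ++ix) {
          double p[3] = {org[0] + ix * pitch, org[1] + iy * pitch,
                         org[2] + iz * pitch};
          double s = plane[0] * p[0] + plane[1] * p[1] + plane[2] * p[2] + plane[3];
          size_t g = gidx(ix, iy, iz, d3);
          if (s > f[g]) f[g] = s;
        }
    (void)n;
  }
  return NumericVector(f.begin(), f.end());
}

// Signed distance of grid points to a closed mesh; sign from z-column
// parity. Distances are exact in a narrow band around the surface (where
// the extraction interpolates) and chamfer-approximated elsewhere, where
// only the sign and a monotone magnitude matter.
// [[Rcpp::export]]
NumericVector cpp_mesh_sdf_grid(NumericMatrix V, IntegerMatrix F,
                                NumericVector origin, IntegerVector dims,
                                double pitch) {
  int d3[3] = {dims[0], dims[1], dims[2]};
  double org[3] = {origin[0], origin[1], origin[2]};
  int nx = d3[0], ny = d3[1], nz = d3[2];
  size_t npts = (size_t)nx * ny * nz;
  std::vector<std::vector<double>> cols((size_t)nx * ny);
  // columns pass exactly through grid points; callers jitter the origin
  columnCrossings(V, F, org[0], org[1], pitch, nx, ny, cols);

  // chamfer (L1, in cells) distance to the nearest triangle-occupied cell
  const int CBIG = 1 << 28;
  std::vector<int> cd(npts, CBIG);
  for (int fi = 0; fi < F.nrow(); ++fi) {
    double lo[3] = {BIG, BIG, BIG}, hi[3] = {-BIG, -BIG, -BIG};
    for (int c = 0; c < 3; ++c) {
      for (int k = 0; k < 3; ++k) {
        double v = V(F(fi, c) - 1, k);
        lo[k] = std::min(lo[k], v);
        hi[k] = std::max(hi[k], v);
      }
    }
    int i0[3], i1[3];
    for (int k = 0; k < 3; ++k) {
      i0[k] = std::max(0, (int)std::floor((lo[k] - org[k]) / pitch));
      i1[k] = std::min(d3[k] - 1, (int)std::ceil((hi[k] - org[k]) / pitch));
    }
    for (int iz = i0[2]; iz <= i1[2]; ++iz)
      for (int iy = i0[1]; iy <= i1[1]; ++iy)
        for (int ix = i0[0]; ix <= i1[0]; ++ix)
          cd[gidx(ix, iy, iz, d3)] = 0;
  }
  // two-pass 6-neighbour chamfer
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix) {
        size_t g = gidx(ix, iy, iz, d3);
        int d = cd[g];
        if (ix > 0) d = std::min(d, cd[gidx(ix - 1, iy, iz, d3)] + 1);
        if (iy > 0) d = std::min(d, cd[gidx(ix, iy - 1, iz, d3)] + 1);
        if (iz > 0) d = std::min(d, cd[gidx(ix, iy, iz - 1, d3)] + 1);
        cd[g] = d;
      }
  for (int iz = nz - 1; iz >= 0; --iz)
    for (int iy = ny - 1; iy >= 0; --iy)
      for (int ix = nx - 1; ix >= 0; --ix) {
        size_t g = gidx(ix, iy, iz, d3);
        int d = cd[g];
        if (ix + 1 < nx) d = std::min(d, cd[gidx(ix + 1, iy, iz, d3)] + 1);
        if (iy + 1 < ny) d = std::min(d, cd[gidx(ix, iy + 1, iz, d3)] + 1);
        if (iz + 1 < nz) d = std::min(d, cd[gidx(ix, iy, iz + 1, d3)] + 1);
        cd[g] = d;
      }

  MeshIndex* idx = buildIndex(V, F);
  std::vector<double> f(npts);
  for (int iy = 0; iy < ny; ++iy) {
    for (int ix = 0; ix < nx; ++ix) {
      std::vector<double>& zs = cols[(size_t)iy * nx + ix];
      std::sort(zs.begin(), zs.end());
      bool ok = (zs.size() % 2 == 0);
      for (int iz = 0; iz < nz; ++iz) {
        double p[3] = {org[0] + ix * pitch, org[1] + iy * pitch,
                       org[2] + iz * pitch};
        size_t g = gidx(ix, iy, iz, d3);
        double d;
        if (cd[g] <= 2) {
          double q[3]; int bf;
          queryIndex(idx, p, q, &d, &bf);
        } else {
          d = (cd[g] - 1) * pitch;  // conservative far-field magnitude
        }
        bool inside = false;
        if (ok) {
          size_t below = std::lower_bound(zs.begin(), zs.end(), p[2]) - zs.begin();
          inside = (below % 2 == 1);
        }
        f[g] = inside ? -d : d;
      }
    }
  }
  delete idx;
  return NumericVector(f.begin(), f.end());
}

// ---------------------------------------------------------------------------
// Newton refinement of extracted vertices onto the exact primitive SDF
// zero-set (removes the O(pitch^2) inscription bias of the linear
// interpolation). A coarse grid prunes the min-union to nearby primitives;
// every queried point starts within a voxel of its generating primitive.

struct PrimSet {
  const NumericMatrix *sph, *cap, *box, *hol;
  NumericVector plane;
};

static double primSdfCandidates(const double* p, const PrimSet& ps,
                                const std::vector<int>& sphIds,
                                const std::vector<int>& capIds,
                                const std::vector<int>& boxIds) {
  double d = BIG;
  for (int s : sphIds) {
    double c[3] = {(*ps.sph)(s, 0), (*ps.sph)(s, 1), (*ps.sph)(s, 2)};
    double v[3]; sub3(p, c, v);
    d = std::min(d, norm3(v) - (*ps.sph)(s, 3));
  }
  for (int s : capIds) {
    double a[3] = {(*ps.cap)(s, 0), (*ps.cap)(s, 1), (*ps.cap)(s, 2)};
    double b[3] = {(*ps.cap)(s, 3), (*ps.cap)(s, 4), (*ps.cap)(s, 5)};
    d = std::min(d, sdSegment(p, a, b, (*ps.cap)(s, 6)));
  }
  for (int s : boxIds) d = std::min(d, sdBoxRow(p, *ps.box, s));
  for (int s = 0; s < ps.hol->nrow(); ++s) {
    double a[3] = {(*ps.hol)(s, 0), (*ps.hol)(s, 1), (*ps.hol)(s, 2)};
    double b[3] = {(*ps.hol)(s, 3), (*ps.hol)(s, 4), (*ps.hol)(s, 5)};
    d = std::max(d, -sdCylinder(p, a, b, (*ps.hol)(s, 6)));
  }
  if (ps.plane.size() == 4)
    d = std::max(d, ps.plane[0] * p[0] + ps.plane[1] * p[1] +
                    ps.plane[2] * p[2] + ps.plane[3]);
  return d;
}

// [[Rcpp::export]]
NumericMatrix cpp_refine_to_sdf(NumericMatrix V, NumericMatrix spheres,
                                NumericMatrix capsules, NumericMatrix boxes,
                                NumericMatrix holes, NumericVector plane,
                                int iterations) {
  int n = V.nrow();
  NumericMatrix out(n, 3);
  // coarse pruning grid over the primitive bbox
  double lo[3] = {BIG, BIG, BIG}, hi[3] = {-BIG, -BIG, -BIG};
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) {
      lo[k] = std::min(lo[k], V(i, k));
      hi[k] = std::max(hi[k], V(i, k));
    }
  const double cell = 6.0, pad = 5.0;
  int nd[3];
  for (int k = 0; k < 3; ++k)
    nd[k] = std::max(1, (int)std::ceil((hi[k] - lo[k]) / cell) + 1);
  size_t ncell = (size_t)nd[0] * nd[1] * nd[2];
  std::vector<std::vector<int>> sphCells(ncell), capCells(ncell),
      boxCells(ncell);
  auto registerPrim = [&](double* blo, double* bhi, std::vector<std::vector<int>>& cells,
                      int id) {
    int i0[3], i1[3];
    for (int k = 0; k < 3; ++k) {
      i0[k] = std::max(0, (int)std::floor((blo[k] - pad - lo[k]) / cell));
      i1[k] = std::min(nd[k] - 1, (int)std::floor((bhi[k] + pad - lo[k]) / cell));
    }
    for (int iz = i0[2]; iz <= i1[2]; ++iz)
      for (int iy = i0[1]; iy <= i1[1]; ++iy)
        for (int ix = i0[0]; ix <= i1[0]; ++ix)
          cells[((size_t)iz * nd[1] + iy) * nd[0] + ix].push_back(id);
  };
  for (int s = 0; s < spheres.nrow(); ++s) {
    double r = spheres(s, 3);
    double blo[3] = {spheres(s, 0) - r, spheres(s, 1) - r, spheres(s, 2) - r};
    double bhi[3] = {spheres(s, 0) + r, spheres(s, 1) + r, spheres(s, 2) + r};
    registerPrim(blo, bhi, sphCells, s);
  }
  for (int s = 0; s < capsules.nrow(); ++s) {
    double r = capsules(s, 6);
    double blo[3], bhi[3];
    for (int k = 0; k < 3; ++k) {
      blo[k] = std::min(capsules(s, k), capsules(s, 3 + k)) - r;
      bhi[k] = std::max(capsules(s, k), capsules(s, 3 + k)) + r;
    }
    registerPrim(blo, bhi, capCells, s);
  }
  for (int s = 0; s < boxes.nrow(); ++s) {
    double diag = std::sqrt(boxes(s, 12) * boxes(s, 12) +
                            boxes(s, 13) * boxes(s, 13) +
                            boxes(s, 14) * boxes(s, 14));
    double blo[3] = {boxes(s, 0) - diag, boxes(s, 1) - diag, boxes(s, 2) - diag};
    double bhi[3] = {boxes(s, 0) + diag, boxes(s, 1) + diag, boxes(s, 2) + diag};
    registerPrim(blo, bhi, boxCells, s);
  }
  PrimSet ps{&spheres, &capsules, &boxes, &holes, plane};
  const double h = 1e-3;
  for (int i = 0; i < n; ++i) {
    double p[3] = {V(i, 0), V(i, 1), V(i, 2)};
    int cc[3];
    for (int k = 0; k < 3; ++k) {
      int c = (int)std::floor((p[k] - lo[k]) / cell);
      cc[k] = std::max(0, std::min(nd[k] - 1, c));
    }
    size_t g = ((size_t)cc[2] * nd[1] + cc[1]) * nd[0] + cc[0];
    const std::vector<int>& si = sphCells[g];
    const std::vector<int>& ci = capCells[g];
    const std::vector<int>& bi = boxCells[g];
    if (si.empty() && ci.empty() && bi.empty()) {
      out(i, 0) = p[0]; out(i, 1) = p[1]; out(i, 2) = p[2];
      continue;
    }
    for (int it = 0; it < iterations; ++it) {
      double f0 = primSdfCandidates(p, ps, si, ci, bi);
      double grad[3];
      for (int k = 0; k < 3; ++k) {
        double pp[3] = {p[0], p[1], p[2]}, pm[3] = {p[0], p[1], p[2]};
        pp[k] += h; pm[k] -= h;
        grad[k] = (primSdfCandidates(pp, ps, si, ci, bi) -
                   primSdfCandidates(pm, ps, si, ci, bi)) / (2 * h);
      }
      double g2 = dot3(grad, grad);
      if (g2 < 1e-12) break;
      double step = f0 / g2;
      // clamp to half a cell so a bad gradient cannot fling the vertex
      double slen = std::fabs(step) * std::sqrt(g2);
      if (slen > 2.0) step *= 2.0 / slen;
      for (int k = 0; k < 3; ++k) p[k] -= step * grad[k];
    }
    out(i, 0) = p[0]; out(i, 1) = p[1]; out(i, 2) = p[2];
  }
  return out;
}

// ---------------------------------------------------------------------------
// marching tetrahedra (6-tet cube decomposition, edge-keyed welding)

struct MTState {
  std::unordered_map<uint64_t, int> edgeVert;
  std::vector<double> verts;   // x,y,z triples
  std::vector<int> tris;       // 0-based
};

static int mtEdgeVertex(MTState& st, uint64_t gA, uint64_t gB, const double* pA,
                        const double* pB, double vA, double vB) {
  uint64_t a = std::min(gA, gB), b = std::max(gA, gB);
  uint64_t key = a * 2654435761ULL ^ (b + 0x9e3779b97f4a7c15ULL);
  // combine into a unique key: use 64-bit pairing via map of pair
  // (hash collisions impossible if we key on the exact pair; so store pair)
  (void)key;
  uint64_t pairKey = (a << 32) | (b & 0xffffffffULL);
  auto it = st.edgeVert.find(pairKey);
  if (it != st.edgeVert.end()) return it->second;
  double t = vA / (vA - vB);
  double p[3];
  if (gA <= gB) {
    for (int k = 0; k < 3; ++k) p[k] = pA[k] + t * (pB[k] - pA[k]);
  } else {
    // evaluated with swapped operands by the caller ordering; recompute
    for (int k = 0; k < 3; ++k) p[k] = pA[k] + t * (pB[k] - pA[k]);
  }
  int id = (int)(st.verts.size() / 3);
  st.verts.push_back(p[0]); st.verts.push_back(p[1]); st.verts.push_back(p[2]);
  st.edgeVert[pairKey] = id;
  return id;
}

static void emitTri(MTState& st, int a, int b, int c, const double* ref) {
  // orient so the normal points along ref (inside -> outside)
  const double* pa = &st.verts[3 * a];
  const double* pb = &st.verts[3 * b];
  const double* pc = &st.verts[3 * c];
  double e1[3], e2[3], n[3];
  sub3(pb, pa, e1); sub3(pc, pa, e2); cross3(e1, e2, n);
  if (dot3(n, ref) >= 0) {
    st.tris.push_back(a); st.tris.push_back(b); st.tris.push_back(c);
  } else {
    st.tris.push_back(a); st.tris.push_back(c); st.tris.push_back(b);
  }
}

static void doTet(MTState& st, const uint64_t* g, const double (*p)[3],
                  const double* v) {
  int in[4], out[4], ni = 0, no = 0;
  for (int k = 0; k < 4; ++k) {
    if (v[k] < 0) in[ni++] = k; else out[no++] = k;
  }
  if (ni == 0 || ni == 4) return;
  double ref[3] = {0, 0, 0};
  {
    double ci[3] = {0, 0, 0}, co[3] = {0, 0, 0};
    for (int k = 0; k < ni; ++k)
      for (int d = 0; d < 3; ++d) ci[d] += p[in[k]][d] / ni;
    for (int k = 0; k < no; ++k)
      for (int d = 0; d < 3; ++d) co[d] += p[out[k]][d] / no;
    sub3(co, ci, ref);
  }
  if (ni == 1) {
    int A = in[0];
    int e0 = mtEdgeVertex(st, g[A], g[out[0]], p[A], p[out[0]], v[A], v[out[0]]);
    int e1 = mtEdgeVertex(st, g[A], g[out[1]], p[A], p[out[1]], v[A], v[out[1]]);
    int e2 = mtEdgeVertex(st, g[A], g[out[2]], p[A], p[out[2]], v[A], v[out[2]]);
    emitTri(st, e0, e1, e2, ref);
  } else if (ni == 3) {
    int A = out[0];
    int e0 = mtEdgeVertex(st, g[A], g[in[0]], p[A], p[in[0]], v[A], v[in[0]]);
    int e1 = mtEdgeVertex(st, g[A], g[in[1]], p[A], p[in[1]], v[A], v[in[1]]);
    int e2 = mtEdgeVertex(st, g[A], g[in[2]], p[A], p[in[2]], v[A], v[in[2]]);
    emitTri(st, e0, e1, e2, ref);
  } else {  // ni == 2
    int A = in[0], B = in[1], C = out[0], D = out[1];
    int ac = mtEdgeVertex(st, g[A], g[C], p[A], p[C], v[A], v[C]);
    int ad = mtEdgeVertex(st, g[A], g[D], p[A], p[D], v[A], v[D]);
    int bc = mtEdgeVertex(st, g[B], g[C], p[B], p[C], v[B], v[C]);
    int bd = mtEdgeVertex(st, g[B], g[D], p[B], p[D], v[B], v[D]);
    emitTri(st, ac, ad, bd, ref);
    emitTri(st, ac, bd, bc, ref);
  }
}

// [[Rcpp::export]]
List cpp_marching_tetrahedra(NumericVector f, IntegerVector dims,
                             NumericVector origin, double pitch) {
  int d3[3] = {dims[0], dims[1], dims[2]};
  double org[3] = {origin[0], origin[1], origin[2]};
  // tets of the unit cube sharing diagonal 0-6 (consistent across neighbors)
  static const int cubeTets[6][4] = {
    {0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6},
    {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}};
  static const int corner[8][3] = {
    {0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
    {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}};
  MTState st;
  std::vector<double> fv(f.begin(), f.end());
  for (auto& x : fv) if (x == 0.0) x = 1e-12;  // vertex-on-surface nudge

  for (int iz = 0; iz + 1 < d3[2]; ++iz) {
    for (int iy = 0; iy + 1 < d3[1]; ++iy) {
      for (int ix = 0; ix + 1 < d3[0]; ++ix) {
        double cv[8]; uint64_t cg[8]; double cp[8][3];
        bool anyNeg = false, anyPos = false;
        for (int c = 0; c < 8; ++c) {
          int jx = ix + corner[c][0], jy = iy + corner[c][1], jz = iz + corner[c][2];
          size_t g = gidx(jx, jy, jz, d3);
          cv[c] = fv[g];
          cg[c] = (uint64_t)g;
          if (cv[c] < 0) anyNeg = true; else anyPos = true;
          cp[c][0] = org[0] + jx * pitch;
          cp[c][1] = org[1] + jy * pitch;
          cp[c][2] = org[2] + jz * pitch;
        }
        if (!anyNeg || !anyPos) continue;
        for (int t = 0; t < 6; ++t) {
          uint64_t g[4]; double p[4][3]; double v[4];
          for (int k = 0; k < 4; ++k) {
            int c = cubeTets[t][k];
            g[k] = cg[c]; v[k] = cv[c];
            p[k][0] = cp[c][0]; p[k][1] = cp[c][1]; p[k][2] = cp[c][2];
          }
          doTet(st, g, p, v);
        }
      }
    }
  }
  int nvOut = (int)(st.verts.size() / 3);
  int nfOut = (int)(st.tris.size() / 3);
  NumericMatrix Vout(nvOut, 3);
  for (int i = 0; i < nvOut; ++i)
    for (int k = 0; k < 3; ++k) Vout(i, k) = st.verts[3 * i + k];
  IntegerMatrix Fout(nfOut, 3);
  for (int i = 0; i < nfOut; ++i)
    for (int k = 0; k < 3; ++k) Fout(i, k) = st.tris[3 * i + k] + 1;
  return List::create(_["vertices"] = Vout, _["faces"] = Fout);
}
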