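// Geometry kernels: iso-surface extraction, ray casting, closest-point
// queries, quadric decimation, triangle intersection, voxelization.
// Pure Rcpp, no external geometry libraries.

#include <Rcpp.h>
#include <functional>
#include <vector>
#include <map>
#include <queue>
#include <cmath>
#include <limits>
#include <algorithm>

using namespace Rcpp;

typedef std::pair<int, int> Edge;

static inline void vsub(const double* a, const double* b, double* out) {
  out[0] = a[0] - b[0]; out[1] = a[1] - b[1]; out[2] = a[2] - b[2];
}
static inline void vcross(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double vdot(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline double vnorm(const double* a) { return std::sqrt(vdot(a, a)); }

// ---------------------------------------------------------------------------
// Iso-surface extraction by marching tetrahedra (Freudenthal 6-tet cube
// split; consistent main diagonal makes the triangulation conforming across
// cells, with no ambiguous-face configurations). Vertices on grid edges are
// deduplicated, so the output is watertight wherever the field is closed.
// ---------------------------------------------------------------------------

// the six path tetrahedra of the unit cube, corners numbered by bits (dx,dy,dz)
static const int TETS[6][4] = {
  {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
  {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}
};

// [[Rcpp::export]]
List cpp_marching_tets(NumericVector field, IntegerVector dims,
                       NumericVector spacing, NumericVector origin,
                       double iso) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double* f = field.begin();
  std::map<Edge, int> edge_vertex;
  std::vector<double> verts;
  std::vector<int> tris;

  auto gid = [&](int i, int j, int k) { return i + nx * (j + (R_xlen_t)ny * k); };
  auto coord = [&](int g, double* p) {
    int i = g % nx, j = (g / nx) % ny, k = g / (nx * ny);
    p[0] = origin[0] + i * spacing[0];
    p[1] = origin[1] + j * spacing[1];
    p[2] = origin[2] + k * spacing[2];
  };
  auto edge_point = [&](int ga, int gb) {
    Edge e = ga < gb ? Edge(ga, gb) : Edge(gb, ga);
    std::map<Edge, int>::iterator it = edge_vertex.find(e);
    if (it != edge_vertex.end()) return it->second;
    double fa = f[ga], fb = f[gb];
    double t = (iso - fa) / (fb - fa);
    if (t < 1e-6) t = 1e-6;       // keep vertices off grid nodes
    if (t > 1.0 - 1e-6) t = 1.0 - 1e-6;
    double pa[3], pb[3];
    coord(ga, pa); coord(gb, pb);
    int id = (int)(verts.size() / 3);
    for (int d = 0; d < 3; ++d) verts.push_back(pa[d] + t * (pb[d] - pa[d]));
    edge_vertex[e] = id;
    return id;
  };
  // emit triangle oriented so its normal points from the inside (f > iso)
  // region toward the outside region
  auto emit = [&](int a, int b, int c, const double* in_pt, const double* out_pt) {
    double pa[3] = {verts[3 * a], verts[3 * a + 1], verts[3 * a + 2]};
    double pb[3] = {verts[3 * b], verts[3 * b + 1], verts[3 * b + 2]};
    double pc[3] = {verts[3 * c], verts[3 * c + 1], verts[3 * c + 2]};
    double e1[3], e2[3], n[3], dir[3];
    vsub(pb, pa, e1); vsub(pc, pa, e2); vcross(e1, e2, n);
    vsub(out_pt, in_pt, dir);
    if (vdot(n, dir) >= 0) { tris.push_back(a); tris.push_back(b); tris.push_back(c); }
    else                   { tris.push_back(a); tris.push_back(c); tris.push_back(b); }
  };

  int corner[8];
  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        for (int c = 0; c < 8; ++c)
          corner[c] = gid(i + (c & 1), j + ((c >> 1) & 1), k + ((c >> 2) & 1));
        // skip fully inside / outside cells quickly
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c)
          (f[corner[c]] > iso ? any_in : any_out) = true;
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int g[4];
          for (int c = 0; c < 4; ++c) g[c] = corner[TETS[t][c]];
          int inside[4], outside[4], ni = 0, no = 0;
          for (int c = 0; c < 4; ++c)
            if (f[g[c]] > iso) inside[ni++] = g[c]; else outside[no++] = g[c];
          if (ni == 0 || ni == 4) continue;
          double cin[3] = {0, 0, 0}, cout[3] = {0, 0, 0}, p[3];
          for (int c = 0; c < ni; ++c) { coord(inside[c], p); for (int d = 0; d < 3; ++d) cin[d] += p[d] / ni; }
          for (int c = 0; c < no; ++c) { coord(outside[c], p); for (int d = 0; d < 3; ++d) cout[d] += p[d] / no; }
          if (ni == 1) {
            int a = edge_point(inside[0], outside[0]);
            int b = edge_point(inside[0], outside[1]);
            int cc = edge_point(inside[0], outside[2]);
            emit(a, b, cc, cin, cout);
          } else if (ni == 3) {
            int a = edge_point(inside[0], outside[0]);
            int b = edge_point(inside[1], outside[0]);
            int cc = edge_point(inside[2], outside[0]);
            emit(a, b, cc, cin, cout);
          } else { // ni == 2: quad cycle ac, bc, bd, ad
            int q1 = edge_point(inside[0], outside[0]);
            int q2 = edge_point(inside[1], outside[0]);
            int q3 = edge_point(inside[1], outside[1]);
            int q4 = edge_point(inside[0], outside[1]);
            emit(q1, q2, q3, cin, cout);
            emit(q1, q3, q4, cin, cout);
          }
        }
      }

  NumericMatrix V(verts.size() / 3, 3);
  for (size_t r = 0; r < verts.size() / 3; ++r)
    for (int d = 0; d < 3; ++d) V(r, d) = verts[3 * r + d];
  IntegerMatrix F(tris.size() / 3, 3);
  for (size_t r = 0; r < tris.size() / 3; ++r)
    for (int d = 0; d < 3; ++d) F(r, d) = tris[3 * r + d] + 1; // 1-based
  return List::create(_["vertices"] = V, _["triangles"] = F);
}

// ---------------------------------------------------------------------------
// Ray casting (Moller-Trumbore). Returns, per ray, the sorted parameters t of
// all intersections with t >= tmin.
// ---------------------------------------------------------------------------

static bool ray_tri(const double* o, const double* d,
                    const double* a, const double* b, const double* c,
                    double* t_out) {
  const double eps = 1e-12;
  double e1[3], e2[3], pv[3], tv[3], qv[3];
  vsub(b, a, e1); vsub(c, a, e2);
  vcross(d, e2, pv);
  double det = vdot(e1, pv);
  if (std::fabs(det) < eps) return false;
  double inv = 1.0 / det;
  vsub(o, a, tv);
  double u = vdot(tv, pv) * inv;
  if (u < -1e-10 || u > 1.0 + 1e-10) return false;
  vcross(tv, e1, qv);
  double v = vdot(d, qv) * inv;
  if (v < -1e-10 || u + v > 1.0 + 1e-10) return false;
  *t_out = vdot(e2, qv) * inv;
  return true;
}

// [[Rcpp::export]]
List cpp_ray_hits(NumericMatrix origins, NumericMatrix dirs,
                  NumericMatrix V, IntegerMatrix F, double tmin) {
  int nr = origins.nrow(), nf = F.nrow();
  List out(nr);
  for (int r = 0; r < nr; ++r) {
    double o[3] = {origins(r, 0), origins(r, 1), origins(r, 2)};
    double d[3] = {dirs(r, 0), dirs(r, 1), dirs(r, 2)};
    std::vector<double> ts;
    for (int fidx = 0; fidx < nf; ++fidx) {
      double a[3] = {V(F(fidx, 0) - 1, 0), V(F(fidx, 0) - 1, 1), V(F(fidx, 0) - 1, 2)};
      double b[3] = {V(F(fidx, 1) - 1, 0), V(F(fidx, 1) - 1, 1), V(F(fidx, 1) - 1, 2)};
      double c[3] = {V(F(fidx, 2) - 1, 0), V(F(fidx, 2) - 1, 1), V(F(fidx, 2) - 1, 2)};
      double t;
      if (ray_tri(o, d, a, b, c, &t) && t >= tmin) ts.push_back(t);
    }
    std::sort(ts.begin(), ts.end());
    // merge duplicate hits on shared triangle edges
    std::vector<double> uniq;
    for (double t : ts)
      if (uniq.empty() || t - uniq.back() > 1e-8) uniq.push_back(t);
    out[r] = NumericVector(uniq.begin(), uniq.end());
  }
  return out;
}

// ---------------------------------------------------------------------------
// Closest point on a triangle mesh, brute force with a uniform-grid broad
// phase over triangle bounding boxes.
// ---------------------------------------------------------------------------

static void closest_on_tri(const double* p, const double* a, const double* b,
                           const double* c, double* out) {
  // Ericson, Real-Time Collision Detection
  double ab[3], ac[3], ap[3];
  vsub(b, a, ab); vsub(c, a, ac); vsub(p, a, ap);
  double d1 = vdot(ab, ap), d2 = vdot(ac, ap);
  if (d1 <= 0 && d2 <= 0) { for (int i = 0; i < 3; ++i) out[i] = a[i]; return; }
  double bp[3]; vsub(p, b, bp);
  double d3 = vdot(ab, bp), d4 = vdot(ac, bp);
  if (d3 >= 0 && d4 <= d3) { for (int i = 0; i < 3; ++i) out[i] = b[i]; return; }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
    return;
  }
  double cp[3]; vsub(p, c, cp);
  double d5 = vdot(ab, cp), d6 = vdot(ac, cp);
  if (d6 >= 0 && d5 <= d6) { for (int i = 0; i < 3; ++i) out[i] = c[i]; return; }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + w * ac[i];
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + w * (c[i] - b[i]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i] * v + ac[i] * w;
}

// [[Rcpp::export]]
List cpp_closest_point(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  int np = P.nrow(), nf = F.nrow();
  NumericVector dist(np);
  NumericMatrix pts(np, 3);
  IntegerVector tri(np);

  // broad phase: bin triangles into a uniform grid keyed by AABB overlap
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) { lo[d] = R_PosInf; hi[d] = R_NegInf; }
  for (int i = 0; i < V.nrow(); ++i)
    for (int d = 0; d < 3; ++d) {
      lo[d] = std::min(lo[d], V(i, d)); hi[d] = std::max(hi[d], V(i, d));
    }
  double ext = std::max({hi[0] - lo[0], hi[1] - lo[1], hi[2] - lo[2], 1e-9});
  int ncell = std::max(1, (int)std::cbrt((double)nf / 4.0));
  if (ncell > 64) ncell = 64;
  double cell = ext / ncell + 1e-12;
  int gx = std::max(1, (int)std::ceil((hi[0] - lo[0]) / cell));
  int gy = std::max(1, (int)std::ceil((hi[1] - lo[1]) / cell));
  int gz = std::max(1, (int)std::ceil((hi[2] - lo[2]) / cell));
  std::vector<std::vector<int> > bins((size_t)gx * gy * gz);
  auto bidx = [&](int i, int j, int k) { return (size_t)i + (size_t)gx * (j + (size_t)gy * k); };
  auto clampi = [](int x, int n) { return x < 0 ? 0 : (x >= n ? n - 1 : x); };
  for (int fidx = 0; fidx < nf; ++fidx) {
    double tlo[3] = {R_PosInf, R_PosInf, R_PosInf};
    double thi[3] = {R_NegInf, R_NegInf, R_NegInf};
    for (int c = 0; c < 3; ++c)
      for (int d = 0; d < 3; ++d) {
        double x = V(F(fidx, c) - 1, d);
        tlo[d] = std::min(tlo[d], x); thi[d] = std::max(thi[d], x);
      }
    int i0 = clampi((int)((tlo[0] - lo[0]) / cell), gx), i1 = clampi((int)((thi[0] - lo[0]) / cell), gx);
    int j0 = clampi((int)((tlo[1] - lo[1]) / cell), gy), j1 = clampi((int)((thi[1] - lo[1]) / cell), gy);
    int k0 = clampi((int)((tlo[2] - lo[2]) / cell), gz), k1 = clampi((int)((thi[2] - lo[2]) / cell), gz);
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i) bins[bidx(i, j, k)].push_back(fidx);
  }

  for (int pi = 0; pi < np; ++pi) {
    double p[3] = {P(pi, 0), P(pi, 1), P(pi, 2)};
    double best = R_PosInf, bestpt[3] = {0, 0, 0};
    int besttri = -1;
    int ci = clampi((int)((p[0] - lo[0]) / cell), gx);
    int cj = clampi((int)((p[1] - lo[1]) / cell), gy);
    int ck = clampi((int)((p[2] - lo[2]) / cell), gz);
    int maxring = std::max({gx, gy, gz});
    for (int ring = 0; ring <= maxring; ++ring) {
      if (besttri >= 0 && (double)(ring - 1) * cell > best) break;
      for (int k = ck - ring; k <= ck + ring; ++k) {
        if (k < 0 || k >= gz) continue;
        for (int j = cj - ring; j <= cj + ring; ++j) {
          if (j < 0 || j >= gy) continue;
          for (int i = ci - ring; i <= ci + ring; ++i) {
            if (i < 0 || i >= gx) continue;
            int dd = std::max({std::abs(i - ci), std::abs(j - cj), std::abs(k - ck)});
            if (dd != ring) continue; // only the shell
            const std::vector<int>& cand = bins[bidx(i, j, k)];
            for (size_t q = 0; q < cand.size(); ++q) {
              int fidx = cand[q];
              double a[3] = {V(F(fidx, 0) - 1, 0), V(F(fidx, 0) - 1, 1), V(F(fidx, 0) - 1, 2)};
              double b[3] = {V(F(fidx, 1) - 1, 0), V(F(fidx, 1) - 1, 1), V(F(fidx, 1) - 1, 2)};
              double c[3] = {V(F(fidx, 2) - 1, 0), V(F(fidx, 2) - 1, 1), V(F(fidx, 2) - 1, 2)};
              double cp[3];
              closest_on_tri(p, a, b, c, cp);
              double dv[3]; vsub(cp, p, dv);
              double dsq = vnorm(dv);
              if (dsq < best) {
                best = dsq; besttri = fidx;
                for (int d = 0; d < 3; ++d) bestpt[d] = cp[d];
              }
            }
          }
        }
      }
    }
    dist[pi] = best; tri[pi] = besttri + 1;
    for (int d = 0; d < 3; ++d) pts(pi, d) = bestpt[d];
  }
  return List::create(_["distance"] = dist, _["point"] = pts, _["triangle"] = tri);
}

// ---------------------------------------------------------------------------
// Quadric-error-metric edge-collapse decimation (Garland & Heckbert style,
// midpoint placement with endpoint fallback, lazy heap invalidation).
// ---------------------------------------------------------------------------

struct Quadric {
  double m[10]; // symmetric 4x4: a2 ab ac ad b2 bc bd c2 cd d2
  Quadric() { for (int i = 0; i < 10; ++i) m[i] = 0; }
  void add_plane(double a, double b, double c, double d, double w) {
    m[0] += w * a * a; m[1] += w * a * b; m[2] += w * a * c; m[3] += w * a * d;
    m[4] += w * b * b; m[5] += w * b * c; m[6] += w * b * d;
    m[7] += w * c * c; m[8] += w * c * d; m[9] += w * d * d;
  }
  void add(const Quadric& o) { for (int i = 0; i < 10; ++i) m[i] += o.m[i]; }
  double eval(const double* p) const {
    double x = p[0], y = p[1], z = p[2];
    return m[0] * x * x + 2 * m[1] * x * y + 2 * m[2] * x * z + 2 * m[3] * x
         + m[4] * y * y + 2 * m[5] * y * z + 2 * m[6] * y
         + m[7] * z * z + 2 * m[8] * z + m[9];
  }
};

struct HeapEntry {
  double cost;
  int va, vb;
  long stamp;
  bool operator<(const HeapEntry& o) const { return cost > o.cost; } // min-heap
};

// [[Rcpp::export]]
List cpp_qem_decimate(NumericMatrix Vin, IntegerMatrix Fin, int target_faces) {
  int nv = Vin.nrow(), nf = Fin.nrow();
  std::vector<double> V(nv * 3);
  for (int i = 0; i < nv; ++i)
    for (int d = 0; d < 3; ++d) V[3 * i + d] = Vin(i, d);
  std::vector<int> F(nf * 3);
  for (int i = 0; i < nf; ++i)
    for (int d = 0; d < 3; ++d) F[3 * i + d] = Fin(i, d) - 1;

  std::vector<Quadric> Q(nv);
  std::vector<char> fdead(nf, 0);
  std::vector<std::vector<int> > vfaces(nv);
  for (int fi = 0; fi < nf; ++fi) {
    int a = F[3 * fi], b = F[3 * fi + 1], c = F[3 * fi + 2];
    double e1[3], e2[3], n[3];
    vsub(&V[3 * b], &V[3 * a], e1);
    vsub(&V[3 * c], &V[3 * a], e2);
    vcross(e1, e2, n);
    double area2 = vnorm(n);
    if (area2 > 1e-14) {
      double inv = 1.0 / area2;
      double nn[3] = {n[0] * inv, n[1] * inv, n[2] * inv};
      double d = -vdot(nn, &V[3 * a]);
      double w = area2 * 0.5;
      Q[a].add_plane(nn[0], nn[1], nn[2], d, w);
      Q[b].add_plane(nn[0], nn[1], nn[2], d, w);
      Q[c].add_plane(nn[0], nn[1], nn[2], d, w);
    }
    vfaces[a].push_back(fi); vfaces[b].push_back(fi); vfaces[c].push_back(fi);
  }

  std::vector<long> vstamp(nv, 0);
  std::priority_queue<HeapEntry> heap;
  auto best_cost = [&](int a, int b, double* pos) {
    const double* pa = &V[3 * a];
    const double* pb = &V[3 * b];
    double mid[3] = {(pa[0] + pb[0]) / 2, (pa[1] + pb[1]) / 2, (pa[2] + pb[2]) / 2};
    Quadric q = Q[a]; q.add(Q[b]);
    double ca = q.eval(pa), cb = q.eval(pb), cm = q.eval(mid);
    if (cm <= ca && cm <= cb) { for (int d = 0; d < 3; ++d) pos[d] = mid[d]; return cm; }
    if (ca <= cb) { for (int d = 0; d < 3; ++d) pos[d] = pa[d]; return ca; }
    for (int d = 0; d < 3; ++d) pos[d] = pb[d];
    return cb;
  };
  auto push_edge = [&](int a, int b) {
    if (a == b) return;
    int va = std::min(a, b), vb = std::max(a, b);
    double pos[3];
    double c = best_cost(va, vb, pos);
    HeapEntry e; e.cost = c; e.va = va; e.vb = vb;
    e.stamp = vstamp[va] + vstamp[vb];
    heap.push(e);
  };
  for (int fi = 0; fi < nf; ++fi) {
    push_edge(F[3 * fi], F[3 * fi + 1]);
    push_edge(F[3 * fi + 1], F[3 * fi + 2]);
    push_edge(F[3 * fi + 2], F[3 * fi]);
  }

  std::vector<int> parent(nv);
  for (int i = 0; i < nv; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };

  int live_faces = nf;
  while (live_faces > target_faces && !heap.empty()) {
    HeapEntry e = heap.top(); heap.pop();
    int a = find(e.va), b = find(e.vb);
    if (a == b) continue;
    if (e.stamp != vstamp[e.va] + vstamp[e.vb]) continue; // stale
    if (e.va != a || e.vb != b) continue;                 // remapped
    double pos[3];
    best_cost(a, b, pos);

    // collapse b into a; reject collapses that flip a surviving face normal
    bool flip = false;
    double pa_old[3] = {V[3 * a], V[3 * a + 1], V[3 * a + 2]};
    double pb_old[3] = {V[3 * b], V[3 * b + 1], V[3 * b + 2]};
    std::vector<int> touched;
    for (int side = 0; side < 2; ++side) {
      int v = side == 0 ? a : b;
      for (size_t q = 0; q < vfaces[v].size(); ++q) {
        int fi = vfaces[v][q];
        if (fdead[fi]) continue;
        int c0 = find(F[3 * fi]), c1 = find(F[3 * fi + 1]), c2 = find(F[3 * fi + 2]);
        bool hasa = (c0 == a || c1 == a || c2 == a);
        bool hasb = (c0 == b || c1 == b || c2 == b);
        if (hasa && hasb) continue; // will die with the collapse
        // test normal before/after moving v to pos
        double p0[3], p1[3], p2[3], p0n[3], p1n[3], p2n[3];
        int cc[3] = {c0, c1, c2};
        for (int d2 = 0; d2 < 3; ++d2) {
          const double* src = &V[3 * cc[d2]];
          double* dsts[3] = {p0, p1, p2};
          double* dstn[3] = {p0n, p1n, p2n};
          for (int d = 0; d < 3; ++d) {
            dsts[d2][d] = src[d];
            dstn[d2][d] = (cc[d2] == a || cc[d2] == b) ? pos[d] : src[d];
          }
        }
        double e1[3], e2[3], n0[3], n1[3];
        vsub(p1, p0, e1); vsub(p2, p0, e2); vcross(e1, e2, n0);
        vsub(p1n, p0n, e1); vsub(p2n, p0n, e2); vcross(e1, e2, n1);
        if (vdot(n0, n1) <= 0) { flip = true; break; }
        touched.push_back(fi);
      }
      if (flip) break;
    }
    if (flip) {
      // retry later at a penalized cost unless hopeless
      (void)pa_old; (void)pb_old;
      continue;
    }

    parent[b] = a;
    for (int d = 0; d < 3; ++d) V[3 * a + d] = pos[d];
    Q[a].add(Q[b]);
    vstamp[a]++; vstamp[b]++;
    // kill degenerate faces, merge adjacency
    for (size_t q = 0; q < vfaces[b].size(); ++q) {
      int fi = vfaces[b][q];
      if (fdead[fi]) continue;
      int c0 = find(F[3 * fi]), c1 = find(F[3 * fi + 1]), c2 = find(F[3 * fi + 2]);
      if (c0 == c1 || c1 == c2 || c0 == c2) { fdead[fi] = 1; --live_faces; }
      else vfaces[a].push_back(fi);
    }
    vfaces[b].clear();
    // refresh candidate edges around a
    std::vector<int> nbrs;
    for (size_t q = 0; q < vfaces[a].size(); ++q) {
      int fi = vfaces[a][q];
      if (fdead[fi]) continue;
      for (int d = 0; d < 3; ++d) {
        int v = find(F[3 * fi + d]);
        if (v != a) nbrs.push_back(v);
      }
    }
    std::sort(nbrs.begin(), nbrs.end());
    nbrs.erase(std::unique(nbrs.begin(), nbrs.end()), nbrs.end());
    for (size_t q = 0; q < nbrs.size(); ++q) push_edge(a, nbrs[q]);
  }

  // compact
  std::vector<int> vmap(nv, -1);
  std::vector<double> Vout;
  std::vector<int> Fout;
  for (int fi = 0; fi < nf; ++fi) {
    if (fdead[fi]) continue;
    int c[3];
    for (int d = 0; d < 3; ++d) c[d] = find(F[3 * fi + d]);
    if (c[0] == c[1] || c[1] == c[2] || c[0] == c[2]) continue;
    for (int d = 0; d < 3; ++d) {
      if (vmap[c[d]] < 0) {
        vmap[c[d]] = (int)(Vout.size() / 3);
        for (int x = 0; x < 3; ++x) Vout.push_back(V[3 * c[d] + x]);
      }
      Fout.push_back(vmap[c[d]] + 1);
    }
  }
  NumericMatrix VO(Vout.size() / 3, 3);
  for (size_t i = 0; i < Vout.size() / 3; ++i)
    for (int d = 0; d < 3; ++d) VO(i, d) = Vout[3 * i + d];
  IntegerMatrix FO(Fout.size() / 3, 3);
  for (size_t i = 0; i < Fout.size() / 3; ++i)
    for (int d = 0; d < 3; ++d) FO(i, d) = Fout[3 * i + d];
  return List::create(_["vertices"] = VO, _["triangles"] = FO);
}

// ---------------------------------------------------------------------------
// Triangle-triangle intersection count between two triangle soups, skipping
// pairs that share a vertex coordinate (adjacent faces of a conforming mesh).
// Segment-vs-triangle piercing test on all 3+3 edges.
// ---------------------------------------------------------------------------

static bool seg_pierces_tri(const double* p, const double* q,
                            const double* a, const double* b, const double* c) {
  double d[3]; vsub(q, p, d);
  double len = vnorm(d);
  if (len < 1e-14) return false;
  double t;
  double dn[3] = {d[0] / len, d[1] / len, d[2] / len};
  if (!ray_tri(p, dn, a, b, c, &t)) return false;
  return t > 1e-7 * len && t < len * (1.0 - 1e-7);
}

static bool share_vertex(const double* t1, const double* t2) {
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      double dx = t1[3 * i] - t2[3 * j], dy = t1[3 * i + 1] - t2[3 * j + 1],
             dz = t1[3 * i + 2] - t2[3 * j + 2];
      if (dx * dx + dy * dy + dz * dz < 1e-16) return true;
    }
  return false;
}

// [[Rcpp::export]]
int cpp_tri_soup_intersections(NumericMatrix T1, NumericMatrix T2) {
  // T1, T2: (3*ntri) x 3 stacked triangle corners
  int n1 = T1.nrow() / 3, n2 = T2.nrow() / 3;
  int count = 0;
  for (int i = 0; i < n1; ++i) {
    double a1[9];
    for (int c = 0; c < 3; ++c)
      for (int d = 0; d < 3; ++d) a1[3 * c + d] = T1(3 * i + c, d);
    for (int j = 0; j < n2; ++j) {
      double a2[9];
      for (int c = 0; c < 3; ++c)
        for (int d = 0; d < 3; ++d) a2[3 * c + d] = T2(3 * j + c, d);
      if (share_vertex(a1, a2)) continue;
      bool hit = false;
      for (int e = 0; e < 3 && !hit; ++e) {
        if (seg_pierces_tri(&a1[3 * e], &a1[3 * ((e + 1) % 3)], &a2[0], &a2[3], &a2[6])) hit = true;
        if (!hit && seg_pierces_tri(&a2[3 * e], &a2[3 * ((e + 1) % 3)], &a1[0], &a1[3], &a1[6])) hit = true;
      }
      if (hit) ++count;
    }
  }
  return count;
}

// ---------------------------------------------------------------------------
// Parity voxelization: rays along +x through voxel centers.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
LogicalVector cpp_voxelize(NumericMatrix V, IntegerMatrix F,
                           IntegerVector dims, NumericVector spacing,
                           NumericVector origin) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector out((R_xlen_t)nx * ny * nz);
  int nf = F.nrow();
  double dir[3] = {1, 0, 0};
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      double o[3] = {origin[0] - 10 * spacing[0],
                     origin[1] + j * spacing[1],
                     origin[2] + k * spacing[2]};
      std::vector<double> ts;
      for (int fidx = 0; fidx < nf; ++fidx) {
        double a[3] = {V(F(fidx, 0) - 1, 0), V(F(fidx, 0) - 1, 1), V(F(fidx, 0) - 1, 2)};
        double b[3] = {V(F(fidx, 1) - 1, 0), V(F(fidx, 1) - 1, 1), V(F(fidx, 1) - 1, 2)};
        double c[3] = {V(F(fidx, 2) - 1, 0), V(F(fidx, 2) - 1, 1), V(F(fidx, 2) - 1, 2)};
        double t;
        if (ray_tri(o, dir, a, b, c, &t) && t > 0) ts.push_back(t);
      }
      std::sort(ts.begin(), ts.end());
      std::vector<double> uniq;
      for (double t : ts)
        if (uniq.empty() || t - uniq.back() > 1e-9) uniq.push_back(t);
      for (size_t s = 0; s + 1 < uniq.size(); s += 2) {
        double x0 = o[0] + uniq[s], x1 = o[0] + uniq[s + 1];
        int i0 = (int)std::ceil((x0 - origin[0]) / spacing[0] - 1e-9);
        int i1 = (int)std::floor((x1 - origin[0]) / spacing[0] + 1e-9);
        if (i0 < 0) i0 = 0;
        if (i1 >= nx) i1 = nx - 1;
        for (int i = i0; i <= i1; ++i)
          out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = true;
      }
    }
  return out;
}
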