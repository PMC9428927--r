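// Triangle-mesh interpenetration testing for ROM sampling.
//
// Collision between two posed bone meshes is decided by (1) any
// triangle-triangle surface intersection (Moller interval test, accelerated
// by an AABB bounding-volume hierarchy whose result is identical to the
// brute-force all-pairs test) and (2) full containment of one closed mesh
// inside the other, decided by ray-crossing parity of a single vertex.
// Shared-boundary contact without crossing (penetration depth <= tol)
// counts as NON-colliding: interpenetration is the criterion.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

typedef std::array<double, 3> V3;

static inline V3 sub(const V3 &a, const V3 &b) {
  return V3{a[0] - b[0], a[1] - b[1], a[2] - b[2]};
}
static inline V3 add(const V3 &a, const V3 &b) {
  return V3{a[0] + b[0], a[1] + b[1], a[2] + b[2]};
}
static inline V3 cross(const V3 &a, const V3 &b) {
  return V3{a[1] * b[2] - a[2] * b[1],
            a[2] * b[0] - a[0] * b[2],
            a[0] * b[1] - a[1] * b[0]};
}
static inline double dot(const V3 &a, const V3 &b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline double norm(const V3 &a) { return std::sqrt(dot(a, a)); }

// ---------------------------------------------------------------------------
// Moller (1997) triangle-triangle interval overlap test.
// tol > 0 shrinks intervals so that contacts shallower than tol are ignored.
// ---------------------------------------------------------------------------

// 2D coplanar helpers ------------------------------------------------------

static bool edge_edge_test(const double *v0, const double *u0, const double *u1,
                           int i0, int i1, double ax, double ay) {
  double bx = u0[i0] - u1[i0];
  double by = u0[i1] - u1[i1];
  double cx = v0[i0] - u0[i0];
  double cy = v0[i1] - u0[i1];
  double f = ay * bx - ax * by;
  double d = by * cx - bx * cy;
  // strict: endpoint / boundary contact is not a crossing
  if ((f > 0 && d > 0 && d < f) || (f < 0 && d < 0 && d > f)) {
    double e = ax * cy - ay * cx;
    if (f > 0) {
      if (e > 0 && e < f) return true;
    } else {
      if (e < 0 && e > f) return true;
    }
  }
  return false;
}

static bool edge_against_tri_edges(const double *v0, const double *v1,
                                   const double *u0, const double *u1,
                                   const double *u2, int i0, int i1) {
  double ax = v1[i0] - v0[i0];
  double ay = v1[i1] - v0[i1];
  if (edge_edge_test(v0, u0, u1, i0, i1, ax, ay)) return true;
  if (edge_edge_test(v0, u1, u2, i0, i1, ax, ay)) return true;
  if (edge_edge_test(v0, u2, u0, i0, i1, ax, ay)) return true;
  return false;
}

static bool point_in_tri(const double *v0, const double *u0, const double *u1,
                         const double *u2, int i0, int i1) {
  double a, b, c, d0, d1, d2;
  a = u1[i1] - u0[i1];
  b = -(u1[i0] - u0[i0]);
  c = -a * u0[i0] - b * u0[i1];
  d0 = a * v0[i0] + b * v0[i1] + c;
  a = u2[i1] - u1[i1];
  b = -(u2[i0] - u1[i0]);
  c = -a * u1[i0] - b * u1[i1];
  d1 = a * v0[i0] + b * v0[i1] + c;
  a = u0[i1] - u2[i1];
  b = -(u0[i0] - u2[i0]);
  c = -a * u2[i0] - b * u2[i1];
  d2 = a * v0[i0] + b * v0[i1] + c;
  if (d0 * d1 > 0.0 && d0 * d2 > 0.0) return true;
  return false;
}

static bool coplanar_tri_tri(const V3 &n, const double *v0, const double *v1,
                             const double *v2, const double *u0,
                             const double *u1, const double *u2) {
  double ax = std::fabs(n[0]), ay = std::fabs(n[1]), az = std::fabs(n[2]);
  int i0, i1;
  if (ax > ay) {
    if (ax > az) { i0 = 1; i1 = 2; }
    else         { i0 = 0; i1 = 1; }
  } else {
    if (ay > az) { i0 = 0; i1 = 2; }
    else         { i0 = 0; i1 = 1; }
  }
  if (edge_against_tri_edges(v0, v1, u0, u1, u2, i0, i1)) return true;
  if (edge_against_tri_edges(v1, v2, u0, u1, u2, i0, i1)) return true;
  if (edge_against_tri_edges(v2, v0, u0, u1, u2, i0, i1)) return true;
  if (point_in_tri(v0, u0, u1, u2, i0, i1)) return true;
  if (point_in_tri(u0, v0, v1, v2, i0, i1)) return true;
  // area overlap without edge crossings or contained vertices (e.g.
  // coincident triangles): test the strictly interior centroids
  double cv[3], cu[3];
  for (int k = 0; k < 3; ++k) {
    cv[k] = (v0[k] + v1[k] + v2[k]) / 3.0;
    cu[k] = (u0[k] + u1[k] + u2[k]) / 3.0;
  }
  if (point_in_tri(cv, u0, u1, u2, i0, i1)) return true;
  if (point_in_tri(cu, v0, v1, v2, i0, i1)) return true;
  return false;
}

static inline void isect2(double vv0, double vv1, double vv2, double d0,
                          double d1, double d2, double *isect0,
                          double *isect1) {
  double tmp = d0 / (d0 - d1);
  *isect0 = vv0 + (vv1 - vv0) * tmp;
  tmp = d0 / (d0 - d2);
  *isect1 = vv0 + (vv2 - vv0) * tmp;
}

static bool compute_intervals(double vv0, double vv1, double vv2, double d0,
                              double d1, double d2, double d0d1, double d0d2,
                              double *isect0, double *isect1, bool *coplanar) {
  if (d0d1 > 0.0) {
    isect2(vv2, vv0, vv1, d2, d0, d1, isect0, isect1);
  } else if (d0d2 > 0.0) {
    isect2(vv1, vv0, vv2, d1, d0, d2, isect0, isect1);
  } else if (d1 * d2 > 0.0 || d0 != 0.0) {
    isect2(vv0, vv1, vv2, d0, d1, d2, isect0, isect1);
  } else if (d1 != 0.0) {
    isect2(vv1, vv0, vv2, d1, d0, d2, isect0, isect1);
  } else if (d2 != 0.0) {
    isect2(vv2, vv0, vv1, d2, d0, d1, isect0, isect1);
  } else {
    *coplanar = true;
    return false;
  }
  return true;
}

static bool tri_tri_intersect(const double *v0, const double *v1,
                              const double *v2, const double *u0,
                              const double *u1, const double *u2, double tol) {
  V3 V0{v0[0], v0[1], v0[2]}, V1{v1[0], v1[1], v1[2]}, V2{v2[0], v2[1], v2[2]};
  V3 U0{u0[0], u0[1], u0[2]}, U1{u1[0], u1[1], u1[2]}, U2{u2[0], u2[1], u2[2]};

  V3 e1 = sub(V1, V0), e2 = sub(V2, V0);
  V3 n1 = cross(e1, e2);
  double d1 = -dot(n1, V0);
  double du0 = dot(n1, U0) + d1;
  double du1 = dot(n1, U1) + d1;
  double du2 = dot(n1, U2) + d1;

  // snap near-zero plane distances to zero (scaled epsilon)
  double eps1 = 1e-12 * norm(n1) *
                (1.0 + std::max({std::fabs(U0[0]), std::fabs(U0[1]),
                                 std::fabs(U0[2]), std::fabs(V0[0]),
                                 std::fabs(V0[1]), std::fabs(V0[2])}));
  if (std::fabs(du0) < eps1) du0 = 0.0;
  if (std::fabs(du1) < eps1) du1 = 0.0;
  if (std::fabs(du2) < eps1) du2 = 0.0;

  double du0du1 = du0 * du1, du0du2 = du0 * du2;
  if (du0du1 > 0.0 && du0du2 > 0.0) return false; // all on one side

  e1 = sub(U1, U0);
  e2 = sub(U2, U0);
  V3 n2 = cross(e1, e2);
  double d2 = -dot(n2, U0);
  double dv0 = dot(n2, V0) + d2;
  double dv1 = dot(n2, V1) + d2;
  double dv2 = dot(n2, V2) + d2;
  double eps2 = 1e-12 * norm(n2) *
                (1.0 + std::max({std::fabs(U0[0]), std::fabs(U0[1]),
                                 std::fabs(U0[2]), std::fabs(V0[0]),
                                 std::fabs(V0[1]), std::fabs(V0[2])}));
  if (std::fabs(dv0) < eps2) dv0 = 0.0;
  if (std::fabs(dv1) < eps2) dv1 = 0.0;
  if (std::fabs(dv2) < eps2) dv2 = 0.0;

  double dv0dv1 = dv0 * dv1, dv0dv2 = dv0 * dv2;
  if (dv0dv1 > 0.0 && dv0dv2 > 0.0) return false;

  V3 D = cross(n1, n2);
  double maxc = std::fabs(D[0]);
  int index = 0;
  double bb = std::fabs(D[1]), cc = std::fabs(D[2]);
  if (bb > maxc) { maxc = bb; index = 1; }
  if (cc > maxc) { index = 2; }

  double vp0 = V0[index], vp1 = V1[index], vp2 = V2[index];
  double up0 = U0[index], up1 = U1[index], up2 = U2[index];

  bool coplanar = false;
  double i1a, i1b, i2a, i2b;
  if (!compute_intervals(vp0, vp1, vp2, dv0, dv1, dv2, dv0dv1, dv0dv2, &i1a,
                         &i1b, &coplanar)) {
    if (coplanar) return coplanar_tri_tri(n1, v0, v1, v2, u0, u1, u2);
  }
  if (!compute_intervals(up0, up1, up2, du0, du1, du2, du0du1, du0du2, &i2a,
                         &i2b, &coplanar)) {
    if (coplanar) return coplanar_tri_tri(n1, v0, v1, v2, u0, u1, u2);
  }
  if (i1a > i1b) std::swap(i1a, i1b);
  if (i2a > i2b) std::swap(i2a, i2b);
  // strict overlap beyond tol: touching does not count
  if (i1b <= i2a + tol || i2b <= i1a + tol) return false;
  return true;
}

// ---------------------------------------------------------------------------
// Mesh container + AABB BVH
// ---------------------------------------------------------------------------

struct Mesh {
  std::vector<V3> v;
  std::vector<std::array<int, 3> > f;
};

static Mesh as_mesh(const NumericMatrix &V, const IntegerMatrix &F) {
  Mesh m;
  m.v.resize(V.nrow());
  for (int i = 0; i < V.nrow(); ++i)
    m.v[i] = V3{V(i, 0), V(i, 1), V(i, 2)};
  m.f.resize(F.nrow());
  for (int i = 0; i < F.nrow(); ++i)
    m.f[i] = std::array<int, 3>{F(i, 0), F(i, 1), F(i, 2)};
  return m;
}

struct BVHNode {
  V3 bmin, bmax;
  int left = -1, right = -1; // children, -1 for leaf
  int start = 0, count = 0;  // triangle range for leaves
};

struct BVH {
  std::vector<BVHNode> nodes;
  std::vector<int> tri; // permutation of triangle indices
  const Mesh *mesh = nullptr;

  void tri_bounds(int t, V3 &lo, V3 &hi) const {
    const std::array<int, 3> &fc = mesh->f[t];
    for (int k = 0; k < 3; ++k) {
      lo[k] = std::min({mesh->v[fc[0]][k], mesh->v[fc[1]][k], mesh->v[fc[2]][k]});
      hi[k] = std::max({mesh->v[fc[0]][k], mesh->v[fc[1]][k], mesh->v[fc[2]][k]});
    }
  }

  int build_node(int start, int count) {
    BVHNode nd;
    nd.bmin = V3{1e300, 1e300, 1e300};
    nd.bmax = V3{-1e300, -1e300, -1e300};
    for (int i = start; i < start + count; ++i) {
      V3 lo, hi;
      tri_bounds(tri[i], lo, hi);
      for (int k = 0; k < 3; ++k) {
        nd.bmin[k] = std::min(nd.bmin[k], lo[k]);
        nd.bmax[k] = std::max(nd.bmax[k], hi[k]);
      }
    }
    int id = (int)nodes.size();
    nodes.push_back(nd);
    if (count <= 4) {
      nodes[id].start = start;
      nodes[id].count = count;
      return id;
    }
    // split at median of centroids on the longest axis
    int axis = 0;
    double len = nd.bmax[0] - nd.bmin[0];
    for (int k = 1; k < 3; ++k)
      if (nd.bmax[k] - nd.bmin[k] > len) { len = nd.bmax[k] - nd.bmin[k]; axis = k; }
    int mid = start + count / 2;
    std::nth_element(tri.begin() + start, tri.begin() + mid,
                     tri.begin() + start + count,
                     [&](int a, int b) {
                       const std::array<int, 3> &fa = mesh->f[a];
                       const std::array<int, 3> &fb = mesh->f[b];
                       double ca = mesh->v[fa[0]][axis] + mesh->v[fa[1]][axis] +
                                   mesh->v[fa[2]][axis];
                       double cb = mesh->v[fb[0]][axis] + mesh->v[fb[1]][axis] +
                                   mesh->v[fb[2]][axis];
                       return ca < cb;
                     });
    if (mid == start || mid == start + count) mid = start + count / 2;
    int l = build_node(start, mid - start);
    int r = build_node(mid, start + count - mid);
    nodes[id].left = l;
    nodes[id].right = r;
    nodes[id].start = 0;
    nodes[id].count = 0;
    return id;
  }

  void build(const Mesh *m) {
    mesh = m;
    tri.resize(m->f.size());
    for (size_t i = 0; i < tri.size(); ++i) tri[i] = (int)i;
    nodes.clear();
    nodes.reserve(2 * tri.size());
    build_node(0, (int)tri.size());
  }

  // recompute boxes for current vertex positions, keeping topology
  void refit(int id = 0) {
    BVHNode &nd = nodes[id];
    if (nd.left < 0) {
      nd.bmin = V3{1e300, 1e300, 1e300};
      nd.bmax = V3{-1e300, -1e300, -1e300};
      for (int i = nd.start; i < nd.start + nd.count; ++i) {
        V3 lo, hi;
        tri_bounds(tri[i], lo, hi);
        for (int k = 0; k < 3; ++k) {
          nd.bmin[k] = std::min(nd.bmin[k], lo[k]);
          nd.bmax[k] = std::max(nd.bmax[k], hi[k]);
        }
      }
      return;
    }
    refit(nd.left);
    refit(nd.right);
    const BVHNode &l = nodes[nd.left];
    const BVHNode &r = nodes[nd.right];
    for (int k = 0; k < 3; ++k) {
      nd.bmin[k] = std::min(l.bmin[k], r.bmin[k]);
      nd.bmax[k] = std::max(l.bmax[k], r.bmax[k]);
    }
  }
};

static inline bool boxes_overlap(const V3 &amin, const V3 &amax, const V3 &bmin,
                                 const V3 &bmax) {
  for (int k = 0; k < 3; ++k)
    if (amin[k] > bmax[k] || bmin[k] > amax[k]) return false;
  return true;
}

// dual-tree traversal: any intersecting triangle pair?
static bool bvh_pair_intersect(const BVH &A, int na, const BVH &B, int nb,
                               double tol) {
  const BVHNode &a = A.nodes[na];
  const BVHNode &b = B.nodes[nb];
  if (!boxes_overlap(a.bmin, a.bmax, b.bmin, b.bmax)) return false;
  if (a.left < 0 && b.left < 0) {
    for (int i = a.start; i < a.start + a.count; ++i) {
      const std::array<int, 3> &fa = A.mesh->f[A.tri[i]];
      for (int j = b.start; j < b.start + b.count; ++j) {
        const std::array<int, 3> &fb = B.mesh->f[B.tri[j]];
        if (tri_tri_intersect(A.mesh->v[fa[0]].data(), A.mesh->v[fa[1]].data(),
                              A.mesh->v[fa[2]].data(), B.mesh->v[fb[0]].data(),
                              B.mesh->v[fb[1]].data(), B.mesh->v[fb[2]].data(),
                              tol))
          return true;
      }
    }
    return false;
  }
  if (a.left < 0) {
    return bvh_pair_intersect(A, na, B, b.left, tol) ||
           bvh_pair_intersect(A, na, B, b.right, tol);
  }
  if (b.left < 0) {
    return bvh_pair_intersect(A, a.left, B, nb, tol) ||
           bvh_pair_intersect(A, a.right, B, nb, tol);
  }
  return bvh_pair_intersect(A, a.left, B, b.left, tol) ||
         bvh_pair_intersect(A, a.left, B, b.right, tol) ||
         bvh_pair_intersect(A, a.right, B, b.left, tol) ||
         bvh_pair_intersect(A, a.right, B, b.right, tol);
}

// ---------------------------------------------------------------------------
// Point-in-mesh by ray parity (for containment of one closed mesh in another)
// ---------------------------------------------------------------------------

static inline bool ray_box(const V3 &o, const V3 &inv, const V3 &bmin,
                           const V3 &bmax) {
  double tmin = 0.0, tmax = 1e300;
  for (int k = 0; k < 3; ++k) {
    double t1 = (bmin[k] - o[k]) * inv[k];
    double t2 = (bmax[k] - o[k]) * inv[k];
    if (t1 > t2) std::swap(t1, t2);
    tmin = std::max(tmin, t1);
    tmax = std::min(tmax, t2);
    if (tmin > tmax) return false;
  }
  return true;
}

// returns crossing count; sets ok=false when the ray grazes an edge/vertex
static void ray_crossings(const BVH &T, int nid, const V3 &o, const V3 &d,
                          const V3 &inv, int &count, bool &ok) {
  if (!ok) return;
  const BVHNode &nd = T.nodes[nid];
  if (!ray_box(o, inv, nd.bmin, nd.bmax)) return;
  if (nd.left < 0) {
    for (int i = nd.start; i < nd.start + nd.count; ++i) {
      const std::array<int, 3> &fc = T.mesh->f[T.tri[i]];
      const V3 &p0 = T.mesh->v[fc[0]];
      const V3 &p1 = T.mesh->v[fc[1]];
      const V3 &p2 = T.mesh->v[fc[2]];
      V3 e1 = sub(p1, p0), e2 = sub(p2, p0);
      V3 pv = cross(d, e2);
      double det = dot(e1, pv);
      double scale = norm(e1) * norm(e2);
      if (std::fabs(det) < 1e-12 * scale) continue; // parallel
      double invdet = 1.0 / det;
      V3 tv = sub(o, p0);
      double u = dot(tv, pv) * invdet;
      if (u < -1e-10 || u > 1.0 + 1e-10) continue;
      V3 qv = cross(tv, e1);
      double v = dot(d, qv) * invdet;
      if (v < -1e-10 || u + v > 1.0 + 1e-10) continue;
      double t = dot(e2, qv) * invdet;
      if (t <= 1e-12) continue;
      // grazing hit near an edge: ask caller to retry another direction
      if (u < 1e-8 || v < 1e-8 || u + v > 1.0 - 1e-8) { ok = false; return; }
      ++count;
    }
    return;
  }
  ray_crossings(T, nd.left, o, d, inv, count, ok);
  ray_crossings(T, nd.right, o, d, inv, count, ok);
}

static bool point_inside(const BVH &T, const V3 &p) {
  // a few fixed, incommensurate directions; retry on grazing hits
  static const double dirs[5][3] = {{0.5773502691896258, 0.5773502691896258, 0.5773502691896258},
                                    {0.8017837257372732, 0.2672612419124244, 0.5345224838248488},
                                    {0.1690308509457033, 0.8451542547285166, 0.5070925528371099},
                                    {0.9116846116771036, 0.3922322702763681, 0.1230914909793327},
                                    {0.2357022603955158, 0.2357022603955158, 0.9428090415820634}};
  for (int a = 0; a < 5; ++a) {
    V3 d{dirs[a][0], dirs[a][1], dirs[a][2]};
    V3 inv{1.0 / d[0], 1.0 / d[1], 1.0 / d[2]};
    int count = 0;
    bool ok = true;
    ray_crossings(T, 0, p, d, inv, count, ok);
    if (ok) return (count % 2) == 1;
  }
  return false; // every direction grazed: treat as outside
}

// ---------------------------------------------------------------------------
// Exported: single collision test (BVH) and brute-force variant
// ---------------------------------------------------------------------------

static bool meshes_collide(const Mesh &A, BVH &bvhA, const Mesh &B, BVH &bvhB,
                           double tol, bool a_closed, bool b_closed) {
  if (!boxes_overlap(bvhA.nodes[0].bmin, bvhA.nodes[0].bmax,
                     bvhB.nodes[0].bmin, bvhB.nodes[0].bmax))
    return false;
  if (bvh_pair_intersect(bvhA, 0, bvhB, 0, tol)) return true;
  // no surface crossing: check swallowing
  if (a_closed && !B.v.empty() && point_inside(bvhA, B.v[0])) return true;
  if (b_closed && !A.v.empty() && point_inside(bvhB, A.v[0])) return true;
  return false;
}

// [[Rcpp::export]]
bool cpp_check_collision(NumericMatrix VA, IntegerMatrix FA, NumericMatrix VB,
                         IntegerMatrix FB, double tol, bool a_closed,
                         bool b_closed) {
  Mesh A = as_mesh(VA, FA), B = as_mesh(VB, FB);
  BVH bvhA, bvhB;
  bvhA.build(&A);
  bvhB.build(&B);
  return meshes_collide(A, bvhA, B, bvhB, tol, a_closed, b_closed);
}

// [[Rcpp::export]]
bool cpp_collision_brute(NumericMatrix VA, IntegerMatrix FA, NumericMatrix VB,
                         IntegerMatrix FB, double tol) {
  Mesh A = as_mesh(VA, FA), B = as_mesh(VB, FB);
  for (size_t i = 0; i < A.f.size(); ++i)
    for (size_t j = 0; j < B.f.size(); ++j) {
      const std::array<int, 3> &fa = A.f[i];
      const std::array<int, 3> &fb = B.f[j];
      if (tri_tri_intersect(A.v[fa[0]].data(), A.v[fa[1]].data(),
                            A.v[fa[2]].data(), B.v[fb[0]].data(),
                            B.v[fb[1]].data(), B.v[fb[2]].data(), tol))
        return true;
    }
  return false;
}

// [[Rcpp::export]]
LogicalVector cpp_points_in_mesh(NumericMatrix V, IntegerMatrix F,
                                 NumericMatrix P) {
  Mesh M = as_mesh(V, F);
  BVH bvh;
  bvh.build(&M);
  LogicalVector out(P.nrow());
  for (int i = 0; i < P.nrow(); ++i)
    out[i] = point_inside(bvh, V3{P(i, 0), P(i, 1), P(i, 2)});
  return out;
}

// count of intersecting non-adjacent triangle pairs within one mesh
// [[Rcpp::export]]
int cpp_self_intersections(NumericMatrix V, IntegerMatrix F, double tol) {
  Mesh M = as_mesh(V, F);
  int n = (int)M.f.size();
  int count = 0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const std::array<int, 3> &fa = M.f[i];
      const std::array<int, 3> &fb = M.f[j];
      bool share = false;
      for (int a = 0; a < 3 && !share; ++a)
        for (int b = 0; b < 3; ++b)
          if (fa[a] == fb[b]) { share = true; break; }
      if (share) continue;
      if (tri_tri_intersect(M.v[fa[0]].data(), M.v[fa[1]].data(),
                            M.v[fa[2]].data(), M.v[fb[0]].data(),
                            M.v[fb[1]].data(), M.v[fb[2]].data(), tol))
        ++count;
    }
  }
  return count;
}

// ---------------------------------------------------------------------------
// Batch pose classification
// ---------------------------------------------------------------------------

static void rot_xyz(double abad, double fe, double lar, double R[3][3]) {
  // degrees in; composed world rotation R = Rz(lar) %*% Ry(fe) %*% Rx(abad)
  const double k = M_PI / 180.0;
  double cx = std::cos(abad * k), sx = std::sin(abad * k);
  double cy = std::cos(fe * k), sy = std::sin(fe * k);
  double cz = std::cos(lar * k), sz = std::sin(lar * k);
  R[0][0] = cz * cy;
  R[0][1] = cz * sy * sx - sz * cx;
  R[0][2] = cz * sy * cx + sz * sx;
  R[1][0] = sz * cy;
  R[1][1] = sz * sy * sx + cz * cx;
  R[1][2] = sz * sy * cx - cz * sx;
  R[2][0] = -sy;
  R[2][1] = cy * sx;
  R[2][2] = cy * cx;
}

// rigid pose transform x_world = M x + c
struct XForm {
  double M[3][3];
  V3 c;
  inline V3 apply(const V3 &x) const {
    return V3{M[0][0] * x[0] + M[0][1] * x[1] + M[0][2] * x[2] + c[0],
              M[1][0] * x[0] + M[1][1] * x[1] + M[1][2] * x[2] + c[1],
              M[2][0] * x[0] + M[2][1] * x[1] + M[2][2] * x[2] + c[2]};
  }
  inline V3 apply_inv(const V3 &x) const { // M orthonormal
    V3 r = sub(x, c);
    return V3{M[0][0] * r[0] + M[1][0] * r[1] + M[2][0] * r[2],
              M[0][1] * r[0] + M[1][1] * r[1] + M[2][1] * r[2],
              M[0][2] * r[0] + M[1][2] * r[1] + M[2][2] * r[2]};
  }
};

// conservative world-frame AABB of a transformed AABB
static inline void xform_box(const XForm &X, const V3 &bmin, const V3 &bmax,
                             V3 &omin, V3 &omax) {
  V3 ctr{0.5 * (bmin[0] + bmax[0]), 0.5 * (bmin[1] + bmax[1]),
         0.5 * (bmin[2] + bmax[2])};
  V3 hl{0.5 * (bmax[0] - bmin[0]), 0.5 * (bmax[1] - bmin[1]),
        0.5 * (bmax[2] - bmin[2])};
  V3 octr = X.apply(ctr);
  for (int r = 0; r < 3; ++r) {
    double h = std::fabs(X.M[r][0]) * hl[0] + std::fabs(X.M[r][1]) * hl[1] +
               std::fabs(X.M[r][2]) * hl[2];
    omin[r] = octr[r] - h;
    omax[r] = octr[r] + h;
  }
}

// dual traversal with B posed by X (B coordinates -> world); exact triangle
// tests transform B leaf triangles only
static bool bvh_pair_intersect_x(const BVH &A, int na, const BVH &B, int nb,
                                 const XForm &X, double tol) {
  const BVHNode &a = A.nodes[na];
  const BVHNode &b = B.nodes[nb];
  V3 bmin, bmax;
  xform_box(X, b.bmin, b.bmax, bmin, bmax);
  if (!boxes_overlap(a.bmin, a.bmax, bmin, bmax)) return false;
  if (a.left < 0 && b.left < 0) {
    for (int j = b.start; j < b.start + b.count; ++j) {
      const std::array<int, 3> &fb = B.mesh->f[B.tri[j]];
      V3 q0 = X.apply(B.mesh->v[fb[0]]);
      V3 q1 = X.apply(B.mesh->v[fb[1]]);
      V3 q2 = X.apply(B.mesh->v[fb[2]]);
      for (int i = a.start; i < a.start + a.count; ++i) {
        const std::array<int, 3> &fa = A.mesh->f[A.tri[i]];
        if (tri_tri_intersect(A.mesh->v[fa[0]].data(), A.mesh->v[fa[1]].data(),
                              A.mesh->v[fa[2]].data(), q0.data(), q1.data(),
                              q2.data(), tol))
          return true;
      }
    }
    return false;
  }
  if (a.left < 0)
    return bvh_pair_intersect_x(A, na, B, b.left, X, tol) ||
           bvh_pair_intersect_x(A, na, B, b.right, X, tol);
  if (b.left < 0)
    return bvh_pair_intersect_x(A, a.left, B, nb, X, tol) ||
           bvh_pair_intersect_x(A, a.right, B, nb, X, tol);
  return bvh_pair_intersect_x(A, a.left, B, b.left, X, tol) ||
         bvh_pair_intersect_x(A, a.left, B, b.right, X, tol) ||
         bvh_pair_intersect_x(A, a.right, B, b.left, X, tol) ||
         bvh_pair_intersect_x(A, a.right, B, b.right, X, tol);
}

// For each pose (row of `angles`, degrees abad/fe/lar) and each offset (row of
// `offsets`, already in world mm), pose the distal mesh and test collision
// against the fixed proximal mesh. Returns poses x offsets matrix of
// "clear" (no interpenetration) flags. Pivot: acs origin for static regimes;
// origin + offset when pivot_at_offset. With early_exit, remaining offsets of
// a pose are skipped (NA) once one clears: viability is a union over offsets.
// [[Rcpp::export]]
LogicalMatrix cpp_classify_poses(NumericMatrix PV, IntegerMatrix PF,
                                 NumericMatrix DV, IntegerMatrix DF,
                                 NumericMatrix angles, NumericMatrix axes,
                                 NumericVector origin, NumericMatrix offsets,
                                 bool pivot_at_offset, double tol,
                                 bool prox_closed, bool dist_closed,
                                 bool early_exit = false) {
  Mesh P = as_mesh(PV, PF);
  BVH bvhP;
  bvhP.build(&P);
  Mesh D = as_mesh(DV, DF); // neutral distal, never rewritten
  BVH bvhD;
  bvhD.build(&D);

  int npose = angles.nrow();
  int noff = offsets.nrow();
  V3 o{origin[0], origin[1], origin[2]};
  double A[3][3]; // columns are ACS x,y,z in world coordinates
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 3; ++c) A[r][c] = axes(r, c);

  LogicalMatrix clear(npose, noff);

  for (int ip = 0; ip < npose; ++ip) {
    double R[3][3];
    rot_xyz(angles(ip, 0), angles(ip, 1), angles(ip, 2), R);
    XForm X;
    double AR[3][3];
    for (int r = 0; r < 3; ++r)
      for (int c = 0; c < 3; ++c)
        AR[r][c] = A[r][0] * R[0][c] + A[r][1] * R[1][c] + A[r][2] * R[2][c];
    for (int r = 0; r < 3; ++r)
      for (int c = 0; c < 3; ++c)
        X.M[r][c] = AR[r][0] * A[c][0] + AR[r][1] * A[c][1] + AR[r][2] * A[c][2];

    bool found_clear = false;
    for (int io = 0; io < noff; ++io) {
      if (early_exit && found_clear) {
        clear(ip, io) = NA_LOGICAL;
        continue;
      }
      V3 t{offsets(io, 0), offsets(io, 1), offsets(io, 2)};
      // static pivot:  x' = o + M (x + t - o)  =  M x + (o + M(t - o))
      // moving pivot:  x' = o + t + M (x - o)  =  M x + (o + t - M o)
      V3 Mo{X.M[0][0] * o[0] + X.M[0][1] * o[1] + X.M[0][2] * o[2],
            X.M[1][0] * o[0] + X.M[1][1] * o[1] + X.M[1][2] * o[2],
            X.M[2][0] * o[0] + X.M[2][1] * o[1] + X.M[2][2] * o[2]};
      if (pivot_at_offset) {
        X.c = V3{o[0] + t[0] - Mo[0], o[1] + t[1] - Mo[1], o[2] + t[2] - Mo[2]};
      } else {
        V3 Mt{X.M[0][0] * t[0] + X.M[0][1] * t[1] + X.M[0][2] * t[2],
              X.M[1][0] * t[0] + X.M[1][1] * t[1] + X.M[1][2] * t[2],
              X.M[2][0] * t[0] + X.M[2][1] * t[1] + X.M[2][2] * t[2]};
        X.c = V3{o[0] + Mt[0] - Mo[0], o[1] + Mt[1] - Mo[1], o[2] + Mt[2] - Mo[2]};
      }

      bool collide = bvh_pair_intersect_x(bvhP, 0, bvhD, 0, X, tol);
      if (!collide) {
        // containment: boxes must overlap for one mesh to swallow the other
        V3 dmin, dmax;
        xform_box(X, bvhD.nodes[0].bmin, bvhD.nodes[0].bmax, dmin, dmax);
        if (boxes_overlap(bvhP.nodes[0].bmin, bvhP.nodes[0].bmax, dmin, dmax)) {
          if (prox_closed && !D.v.empty() &&
              point_inside(bvhP, X.apply(D.v[0])))
            collide = true;
          if (!collide && dist_closed && !P.v.empty() &&
              point_inside(bvhD, X.apply_inv(P.v[0])))
            collide = true;
        }
      }
      clear(ip, io) = !collide;
      if (!collide) found_clear = true;
    }
    if (ip % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return clear;
}
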