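// 3D Delaunay triangulation (Bowyer-Watson) and alpha-complex volumes.
//
// The alpha complex keeps Delaunay tetrahedra whose circumradius is at most
// alpha; its volume (sum of kept tetrahedra) is the "solid volume of mapped
// degrees" used to summarise a ROM map, and alpha -> Inf recovers the convex
// hull volume. The triangulation uses a single symbolic infinite vertex
// (every hull facet is covered by one "infinite" tetrahedron), so the finite
// tetrahedra tile the convex hull exactly. Input coordinates are rescaled to
// a unit box and given a tiny deterministic jitter so that the cospherical
// degeneracies of grid-sampled pose clouds are decided consistently; the
// jitter perturbs volumes at ~1e-8 relative, far below reported precision.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <map>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

typedef std::array<double, 3> P3;

static inline double det3(double a, double b, double c, double d, double e,
                          double f, double g, double h, double i) {
  return a * (e * i - f * h) - b * (d * i - f * g) + c * (d * h - e * g);
}

static inline double orient3d(const P3 &a, const P3 &b, const P3 &c,
                              const P3 &d) {
  return det3(b[0] - a[0], b[1] - a[1], b[2] - a[2],
              c[0] - a[0], c[1] - a[1], c[2] - a[2],
              d[0] - a[0], d[1] - a[1], d[2] - a[2]);
}

// > 0 when p lies inside the circumsphere of positively-oriented (a,b,c,d)
static double in_sphere(const P3 &a, const P3 &b, const P3 &c, const P3 &d,
                        const P3 &p) {
  double ax = a[0] - p[0], ay = a[1] - p[1], az = a[2] - p[2];
  double bx = b[0] - p[0], by = b[1] - p[1], bz = b[2] - p[2];
  double cx = c[0] - p[0], cy = c[1] - p[1], cz = c[2] - p[2];
  double dx = d[0] - p[0], dy = d[1] - p[1], dz = d[2] - p[2];
  double a2 = ax * ax + ay * ay + az * az;
  double b2 = bx * bx + by * by + bz * bz;
  double c2 = cx * cx + cy * cy + cz * cz;
  double d2 = dx * dx + dy * dy + dz * dz;
  return a2 * det3(bx, by, bz, cx, cy, cz, dx, dy, dz) -
         b2 * det3(ax, ay, az, cx, cy, cz, dx, dy, dz) +
         c2 * det3(ax, ay, az, bx, by, bz, dx, dy, dz) -
         d2 * det3(ax, ay, az, bx, by, bz, cx, cy, cz);
}

// deterministic RNG (splitmix-like) for jitter and insertion order
static inline uint64_t mix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}
static inline double unif01(uint64_t &state) {
  state = mix64(state);
  return (double)(state >> 11) / 9007199254740992.0;
}

static const int INF_V = 0; // symbolic vertex "at infinity"

struct Tet {
  int v[4];
  int nb[4]; // neighbour opposite v[k], -1 if none
  bool alive;
  bool infinite() const {
    return v[0] == INF_V || v[1] == INF_V || v[2] == INF_V || v[3] == INF_V;
  }
  int inf_pos() const {
    for (int k = 0; k < 4; ++k)
      if (v[k] == INF_V) return k;
    return -1;
  }
};

struct Delaunay {
  std::vector<P3> pts; // index 0 is a placeholder for the infinite vertex
  std::vector<Tet> tets;
  P3 Q;                // a point strictly inside the (growing) hull
  int last_alive = 0;
  bool failed = false;

  // conflict ("circumsphere contains p"): infinite tets cover the open
  // half-space beyond their hull facet
  bool in_conflict(const Tet &t, const P3 &p) const {
    int ip = t.inf_pos();
    if (ip < 0)
      return in_sphere(pts[t.v[0]], pts[t.v[1]], pts[t.v[2]], pts[t.v[3]],
                       p) > 0;
    P3 sub[4];
    for (int k = 0; k < 4; ++k) sub[k] = (k == ip) ? p : pts[t.v[k]];
    return orient3d(sub[0], sub[1], sub[2], sub[3]) > 0;
  }

  bool point_in_tet(const Tet &t, const P3 &p) const {
    if (t.infinite()) return false;
    const P3 &a = pts[t.v[0]], &b = pts[t.v[1]], &c = pts[t.v[2]],
             &d = pts[t.v[3]];
    return orient3d(p, b, c, d) >= 0 && orient3d(a, p, c, d) >= 0 &&
           orient3d(a, b, p, d) >= 0 && orient3d(a, b, c, p) >= 0;
  }

  // find a tet in conflict with p (the Bowyer-Watson seed)
  int find_seed(const P3 &p, int hint) {
    int cur = hint;
    int steps = 0;
    int maxsteps = (int)tets.size() + 64;
    while (steps++ < maxsteps) {
      if (cur < 0 || !tets[cur].alive) break;
      const Tet &t = tets[cur];
      if (t.infinite()) {
        if (in_conflict(t, p)) return cur;
        cur = t.nb[t.inf_pos()]; // step inside through the hull facet
        continue;
      }
      const P3 &a = pts[t.v[0]], &b = pts[t.v[1]], &c = pts[t.v[2]],
               &d = pts[t.v[3]];
      double o0 = orient3d(p, b, c, d);
      double o1 = orient3d(a, p, c, d);
      double o2 = orient3d(a, b, p, d);
      double o3 = orient3d(a, b, c, p);
      int worst = -1;
      double wv = 0.0;
      if (o0 < wv) { wv = o0; worst = 0; }
      if (o1 < wv) { wv = o1; worst = 1; }
      if (o2 < wv) { wv = o2; worst = 2; }
      if (o3 < wv) { wv = o3; worst = 3; }
      if (worst < 0) return cur; // p inside this finite tet => in conflict
      cur = t.nb[worst];
    }
    // fallback scans: hull facets first, then everything
    for (int i = (int)tets.size() - 1; i >= 0; --i)
      if (tets[i].alive && tets[i].infinite() && in_conflict(tets[i], p))
        return i;
    for (int i = (int)tets.size() - 1; i >= 0; --i)
      if (tets[i].alive && in_conflict(tets[i], p)) return i;
    return -1;
  }

  // orient a new tet (p, x, y, z), possibly containing INF_V; returns false
  // on degeneracy
  bool orient_new(int pid, int &x, int &y, int &z) {
    const P3 &p = pts[pid];
    if (x != INF_V && y != INF_V && z != INF_V) {
      double o = orient3d(p, pts[x], pts[y], pts[z]);
      if (o == 0.0) return false;
      if (o < 0) std::swap(y, z);
      return true;
    }
    // substitute the interior point Q for INF_V; outside points must then
    // give a positive determinant, so Q must give a negative one
    const P3 *px = (x == INF_V) ? &Q : &pts[x];
    const P3 *py = (y == INF_V) ? &Q : &pts[y];
    const P3 *pz = (z == INF_V) ? &Q : &pts[z];
    double o = orient3d(p, *px, *py, *pz);
    if (o == 0.0) return false;
    if (o > 0) std::swap(y, z);
    return true;
  }

  void insert(int pid) {
    const P3 &p = pts[pid];
    int t0 = find_seed(p, last_alive);
    if (t0 < 0) { failed = true; return; }

    // conflict region by BFS
    std::vector<int> bad;
    std::vector<char> inbad(tets.size(), 0);
    std::vector<int> stack;
    stack.push_back(t0);
    inbad[t0] = 1;
    while (!stack.empty()) {
      int t = stack.back();
      stack.pop_back();
      bad.push_back(t);
      for (int k = 0; k < 4; ++k) {
        int q = tets[t].nb[k];
        if (q < 0 || inbad[q] || !tets[q].alive) continue;
        if (in_conflict(tets[q], p)) {
          inbad[q] = 1;
          stack.push_back(q);
        }
      }
    }

    struct BFace {
      int a, b, c; // oriented so the new tet (p,a,b,c) is positive
      int outside; // neighbour beyond the face (may be -1)
      int from;    // cavity tet that owned the face
    };
    std::vector<BFace> faces;
    for (size_t bi = 0; bi < bad.size(); ++bi) {
      int t = bad[bi];
      for (int k = 0; k < 4; ++k) {
        int q = tets[t].nb[k];
        if (q >= 0 && inbad[q]) continue;
        int f0 = tets[t].v[(k + 1) % 4];
        int f1 = tets[t].v[(k + 2) % 4];
        int f2 = tets[t].v[(k + 3) % 4];
        if (!orient_new(pid, f0, f1, f2)) { failed = true; return; }
        faces.push_back(BFace{f0, f1, f2, q, t});
      }
    }
    for (size_t bi = 0; bi < bad.size(); ++bi) tets[bad[bi]].alive = false;

    // create new tets (p joined to each boundary face) and stitch adjacency
    std::map<std::pair<int, int>, std::pair<int, int> > edge_face;
    std::vector<int> created;
    for (size_t fi = 0; fi < faces.size(); ++fi) {
      const BFace &F = faces[fi];
      Tet nt;
      nt.v[0] = pid; nt.v[1] = F.a; nt.v[2] = F.b; nt.v[3] = F.c;
      nt.nb[0] = F.outside; nt.nb[1] = nt.nb[2] = nt.nb[3] = -1;
      nt.alive = true;
      int id = (int)tets.size();
      tets.push_back(nt);
      created.push_back(id);
      if (F.outside >= 0) {
        Tet &q = tets[F.outside];
        for (int k = 0; k < 4; ++k)
          if (q.nb[k] == F.from) { q.nb[k] = id; break; }
      }
      // internal cavity faces all contain p; keyed by their other two vertices
      int pairs[3][2] = {{F.b, F.c}, {F.a, F.c}, {F.a, F.b}};
      for (int e = 0; e < 3; ++e) {
        std::pair<int, int> key(std::min(pairs[e][0], pairs[e][1]),
                                std::max(pairs[e][0], pairs[e][1]));
        std::map<std::pair<int, int>, std::pair<int, int> >::iterator it =
            edge_face.find(key);
        if (it == edge_face.end()) {
          edge_face[key] = std::make_pair(id, e + 1);
        } else {
          tets[id].nb[e + 1] = it->second.first;
          tets[it->second.first].nb[it->second.second] = id;
          edge_face.erase(it);
        }
      }
    }
    if (!edge_face.empty()) { failed = true; return; }
    if (!created.empty()) last_alive = created.back();
  }

  bool run(const std::vector<P3> &data, double jitter, uint64_t seed) {
    failed = false;
    pts.clear();
    tets.clear();
    size_t n = data.size();
    pts.resize(n + 1);
    pts[0] = P3{0.0, 0.0, 0.0}; // placeholder, never dereferenced for INF_V
    uint64_t st = seed;
    for (size_t i = 0; i < n; ++i) {
      P3 p = data[i];
      for (int k = 0; k < 3; ++k) p[k] += (unif01(st) - 0.5) * jitter;
      pts[i + 1] = p;
    }

    // deterministic shuffled insertion order (point ids 1..n)
    std::vector<int> order(n);
    for (size_t i = 0; i < n; ++i) order[i] = (int)i + 1;
    uint64_t st2 = seed ^ 0xA5A5A5A5ULL;
    for (size_t i = n; i > 1; --i) {
      size_t j = (size_t)(unif01(st2) * i);
      if (j >= i) j = i - 1;
      std::swap(order[i - 1], order[j]);
    }

    // first four points spanning a non-degenerate tet
    const double eps0 = 1e-12;
    size_t i1 = 1;
    while (i1 < n) {
      P3 d = pts[order[i1]];
      const P3 &o = pts[order[0]];
      double dd = (d[0] - o[0]) * (d[0] - o[0]) + (d[1] - o[1]) * (d[1] - o[1]) +
                  (d[2] - o[2]) * (d[2] - o[2]);
      if (dd > eps0 * eps0) break;
      ++i1;
    }
    if (i1 >= n) return false;
    size_t i2 = i1 + 1;
    while (i2 < n) {
      const P3 &a = pts[order[0]], &b = pts[order[i1]], &c = pts[order[i2]];
      P3 u{b[0] - a[0], b[1] - a[1], b[2] - a[2]};
      P3 v{c[0] - a[0], c[1] - a[1], c[2] - a[2]};
      double cx = u[1] * v[2] - u[2] * v[1];
      double cy = u[2] * v[0] - u[0] * v[2];
      double cz = u[0] * v[1] - u[1] * v[0];
      if (cx * cx + cy * cy + cz * cz > eps0 * eps0) break;
      ++i2;
    }
    if (i2 >= n) return false;
    size_t i3 = i2 + 1;
    while (i3 < n) {
      double o = orient3d(pts[order[0]], pts[order[i1]], pts[order[i2]],
                          pts[order[i3]]);
      if (std::fabs(o) > eps0) break;
      ++i3;
    }
    if (i3 >= n) return false;

    int a = order[0], b = order[i1], c = order[i2], d = order[i3];
    if (orient3d(pts[a], pts[b], pts[c], pts[d]) < 0) std::swap(c, d);
    Q = P3{(pts[a][0] + pts[b][0] + pts[c][0] + pts[d][0]) / 4.0,
           (pts[a][1] + pts[b][1] + pts[c][1] + pts[d][1]) / 4.0,
           (pts[a][2] + pts[b][2] + pts[c][2] + pts[d][2]) / 4.0};

    // one finite tet plus four infinite tets over its facets
    int vsets[5][4] = {{a, b, c, d},
                       {INF_V, b, c, d},
                       {INF_V, a, c, d},
                       {INF_V, a, b, d},
                       {INF_V, a, b, c}};
    for (int t = 0; t < 5; ++t) {
      Tet nt;
      for (int k = 0; k < 4; ++k) nt.v[k] = vsets[t][k];
      nt.nb[0] = nt.nb[1] = nt.nb[2] = nt.nb[3] = -1;
      nt.alive = true;
      if (t > 0) {
        // orient the infinite tet: outside points must test positive when
        // substituted for INF_V
        P3 sub[4];
        for (int k = 0; k < 4; ++k)
          sub[k] = (nt.v[k] == INF_V) ? Q : pts[nt.v[k]];
        double o = orient3d(sub[0], sub[1], sub[2], sub[3]);
        if (o == 0.0) return false;
        if (o > 0) std::swap(nt.v[2], nt.v[3]);
      }
      tets.push_back(nt);
    }
    // adjacency by brute-force face matching over the five tets
    for (int t1 = 0; t1 < 5; ++t1)
      for (int k1 = 0; k1 < 4; ++k1) {
        if (tets[t1].nb[k1] >= 0) continue;
        int f1[3], idx = 0;
        for (int k = 0; k < 4; ++k)
          if (k != k1) f1[idx++] = tets[t1].v[k];
        std::sort(f1, f1 + 3);
        for (int t2 = 0; t2 < 5 && tets[t1].nb[k1] < 0; ++t2) {
          if (t2 == t1) continue;
          for (int k2 = 0; k2 < 4; ++k2) {
            int f2[3];
            idx = 0;
            for (int k = 0; k < 4; ++k)
              if (k != k2) f2[idx++] = tets[t2].v[k];
            std::sort(f2, f2 + 3);
            if (f1[0] == f2[0] && f1[1] == f2[1] && f1[2] == f2[2]) {
              tets[t1].nb[k1] = t2;
              tets[t2].nb[k2] = t1;
              break;
            }
          }
        }
      }
    last_alive = 0;

    // insert the remaining points
    for (size_t i = 0; i < n; ++i) {
      if (i == 0 || i == i1 || i == i2 || i == i3) continue;
      insert(order[i]);
      if (failed) return false;
      if (i % 512 == 0) Rcpp::checkUserInterrupt();
    }
    return true;
  }
};

// circumradius^2 of a tetrahedron, +Inf for degenerate slivers
static double circumradius2(const P3 &a, const P3 &b, const P3 &c,
                            const P3 &d) {
  double M[3][3], rhs[3];
  P3 vs[3] = {P3{b[0] - a[0], b[1] - a[1], b[2] - a[2]},
              P3{c[0] - a[0], c[1] - a[1], c[2] - a[2]},
              P3{d[0] - a[0], d[1] - a[1], d[2] - a[2]}};
  for (int r = 0; r < 3; ++r) {
    for (int k = 0; k < 3; ++k) M[r][k] = 2.0 * vs[r][k];
    rhs[r] = vs[r][0] * vs[r][0] + vs[r][1] * vs[r][1] + vs[r][2] * vs[r][2];
  }
  double det = det3(M[0][0], M[0][1], M[0][2], M[1][0], M[1][1], M[1][2],
                    M[2][0], M[2][1], M[2][2]);
  if (std::fabs(det) < 1e-30) return R_PosInf;
  double x = det3(rhs[0], M[0][1], M[0][2], rhs[1], M[1][1], M[1][2], rhs[2],
                  M[2][1], M[2][2]) / det;
  double y = det3(M[0][0], rhs[0], M[0][2], M[1][0], rhs[1], M[1][2], M[2][0],
                  rhs[2], M[2][2]) / det;
  double z = det3(M[0][0], M[0][1], rhs[0], M[1][0], M[1][1], rhs[1], M[2][0],
                  M[2][1], rhs[2]) / det;
  return x * x + y * y + z * z;
}

struct DSU {
  std::vector<int> p;
  DSU(int n) : p(n) { for (int i = 0; i < n; ++i) p[i] = i; }
  int find(int x) { while (p[x] != x) { p[x] = p[p[x]]; x = p[x]; } return x; }
  void unite(int a, int b) { p[find(a)] = find(b); }
};

// Build the Delaunay triangulation and alpha complex of a 3D point cloud.
// Returns the alpha-complex volume, convex-hull (= alpha -> Inf) volume,
// tetrahedron counts and number of connected components. alpha in input
// units; alpha = Inf keeps every tetrahedron.
// [[Rcpp::export]]
List cpp_alpha_complex(NumericMatrix P, double alpha, int seed,
                       bool return_tets = false) {
  int n = P.nrow();
  if (n < 4) stop("need at least 4 points");
  // isotropic rescale to a unit box (preserves shape and radius ratios)
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) {
      lo[k] = std::min(lo[k], P(i, k));
      hi[k] = std::max(hi[k], P(i, k));
    }
  double ext = 0.0;
  for (int k = 0; k < 3; ++k) ext = std::max(ext, hi[k] - lo[k]);
  if (!(ext > 0)) stop("degenerate point cloud (zero extent)");
  double scale = 1.0 / ext;
  std::vector<P3> data(n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k)
      data[i][k] = (P(i, k) - 0.5 * (lo[k] + hi[k])) * scale;

  Delaunay D;
  bool ok = false;
  double jit = 1e-8;
  uint64_t sd = (uint64_t)seed * 2654435761ULL + 1ULL;
  for (int attempt = 0; attempt < 4 && !ok; ++attempt) {
    ok = D.run(data, jit, sd + attempt);
    jit *= 32.0; // retry degenerate inputs with a larger (still tiny) jitter
  }
  if (!ok) stop("Delaunay triangulation failed: points may be (near-)coplanar");

  std::vector<std::array<int, 4> > fin;
  for (size_t t = 0; t < D.tets.size(); ++t) {
    if (!D.tets[t].alive || D.tets[t].infinite()) continue;
    const Tet &tt = D.tets[t];
    fin.push_back(std::array<int, 4>{tt.v[0] - 1, tt.v[1] - 1, tt.v[2] - 1,
                                     tt.v[3] - 1});
  }
  int m = (int)fin.size();
  if (m == 0) stop("all points are coplanar");

  double alpha_s = R_FINITE(alpha) ? alpha * scale : R_PosInf;
  double a2 = R_FINITE(alpha_s) ? alpha_s * alpha_s : R_PosInf;
  double vol_total = 0.0, vol_alpha = 0.0;
  std::vector<char> keep(m, 0);
  for (int t = 0; t < m; ++t) {
    const P3 &a = D.pts[fin[t][0] + 1];
    const P3 &b = D.pts[fin[t][1] + 1];
    const P3 &c = D.pts[fin[t][2] + 1];
    const P3 &d = D.pts[fin[t][3] + 1];
    double vol = std::fabs(orient3d(a, b, c, d)) / 6.0;
    vol_total += vol;
    double r2 = circumradius2(a, b, c, d);
    if (r2 <= a2) {
      keep[t] = 1;
      vol_alpha += vol;
    }
  }

  // connected components of the kept complex (shared-face adjacency)
  DSU dsu(m);
  std::map<std::array<int, 3>, int> face_owner;
  int nkept = 0;
  for (int t = 0; t < m; ++t) {
    if (!keep[t]) continue;
    ++nkept;
    int vv[4] = {fin[t][0], fin[t][1], fin[t][2], fin[t][3]};
    for (int k = 0; k < 4; ++k) {
      std::array<int, 3> f;
      int idx = 0;
      for (int j = 0; j < 4; ++j)
        if (j != k) f[idx++] = vv[j];
      std::sort(f.begin(), f.end());
      std::map<std::array<int, 3>, int>::iterator it = face_owner.find(f);
      if (it == face_owner.end()) face_owner[f] = t;
      else dsu.unite(t, it->second);
    }
  }
  int ncomp = 0;
  for (int t = 0; t < m; ++t)
    if (keep[t] && dsu.find(t) == t) ++ncomp;

  double s3 = scale * scale * scale;
  List out = List::create(
      Named("volume") = vol_alpha / s3,
      Named("hull_volume") = vol_total / s3,
      Named("n_tetrahedra") = m,
      Named("n_kept") = nkept,
      Named("n_components") = ncomp);
  if (return_tets) {
    IntegerMatrix T(m, 4);
    for (int t = 0; t < m; ++t)
      for (int k = 0; k < 4; ++k) T(t, k) = fin[t][k];
    out.push_back(T, "tetrahedra");
  }
  return out;
}
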