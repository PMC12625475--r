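// Mesh hygiene: vertex welding, T-junction stitching, edge/orientation
// audits, connected-component orientation repair, boundary-loop extraction
// and a quickhull 3D convex hull.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <array>
#include <functional>
#include <cmath>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Key3 {
  int64_t a, b, c;
  bool operator==(const Key3 &o) const { return a == o.a && b == o.b && c == o.c; }
};
struct Key3Hash {
  size_t operator()(const Key3 &k) const {
    uint64_t h = 1469598103934665603ull;
    auto mix = [&h](uint64_t x) { h ^= x; h *= 1099511628211ull; };
    mix((uint64_t)k.a); mix((uint64_t)k.b); mix((uint64_t)k.c);
    return (size_t)h;
  }
};

} // namespace

// Merge vertices whose coordinates coincide after rounding to `tol`,
// drop faces whose indices collapse (a safe edge contraction). With
// area2_tol > 0 also drop sliver faces below that squared-doubled-area
// threshold (used on CSG output, where the resulting cracks are stitched;
// never on file input, where dropping would open the surface for good).
// [[Rcpp::export(name = ".cpp_weld")]]
List cpp_weld(NumericMatrix v, IntegerMatrix f, double tol, double area2_tol = 0) {
  int nv = v.nrow(), nf = f.nrow();
  std::unordered_map<Key3, int, Key3Hash> map;
  map.reserve(nv * 2);
  std::vector<int> remap(nv);
  std::vector<double> out;
  out.reserve(nv * 3);
  int nout = 0;
  for (int i = 0; i < nv; ++i) {
    Key3 k{(int64_t)std::llround(v(i, 0) / tol),
           (int64_t)std::llround(v(i, 1) / tol),
           (int64_t)std::llround(v(i, 2) / tol)};
    auto it = map.find(k);
    if (it == map.end()) {
      map.emplace(k, nout);
      remap[i] = nout;
      out.push_back(v(i, 0)); out.push_back(v(i, 1)); out.push_back(v(i, 2));
      ++nout;
    } else remap[i] = it->second;
  }
  std::vector<int> fo;
  fo.reserve(nf * 3);
  for (int i = 0; i < nf; ++i) {
    int a = remap[f(i, 0) - 1], b = remap[f(i, 1) - 1], c = remap[f(i, 2) - 1];
    if (a == b || b == c || a == c) continue;
    if (area2_tol > 0) {
      const double *p0 = &out[3 * a], *p1 = &out[3 * b], *p2 = &out[3 * c];
      double ux = p1[0] - p0[0], uy = p1[1] - p0[1], uz = p1[2] - p0[2];
      double wx = p2[0] - p0[0], wy = p2[1] - p0[1], wz = p2[2] - p0[2];
      double cx = uy * wz - uz * wy, cy = uz * wx - ux * wz, cz = ux * wy - uy * wx;
      if (cx * cx + cy * cy + cz * cz < area2_tol) continue;
    }
    fo.push_back(a + 1); fo.push_back(b + 1); fo.push_back(c + 1);
  }
  NumericMatrix V(nout, 3);
  for (int i = 0; i < nout; ++i)
    for (int k = 0; k < 3; ++k) V(i, k) = out[3 * i + k];
  int nfo = (int)fo.size() / 3;
  IntegerMatrix F(nfo, 3);
  for (int i = 0; i < nfo; ++i)
    for (int k = 0; k < 3; ++k) F(i, k) = fo[3 * i + k];
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// Split triangle edges at vertices that lie on them (within tol) but are not
// endpoints; faces with splits are re-triangulated by a centroid fan so the
// two sides of every former T-junction share identical edges afterwards.
// Only unbalanced (crack) edges are considered: interior manifold edges with
// incidentally collinear vertices are left alone.
// [[Rcpp::export(name = ".cpp_stitch_tjunctions")]]
List cpp_stitch_tjunctions(NumericMatrix v, IntegerMatrix f, double tol) {
  int nv = v.nrow(), nf = f.nrow();
  // directed-edge balance: an edge needs stitching when (a,b) and (b,a)
  // counts differ
  std::unordered_map<uint64_t, int> ebal;
  ebal.reserve((size_t)nf * 3);
  auto dkey = [nv](int a, int b) { return (uint64_t)a * (uint64_t)nv + b; };
  for (int i = 0; i < nf; ++i)
    for (int e = 0; e < 3; ++e) {
      int a = f(i, e) - 1, b = f(i, (e + 1) % 3) - 1;
      if (a < b) { ebal[dkey(a, b)]++; } else { ebal[dkey(b, a)]--; }
    }
  auto unbalanced = [&](int a, int b) {
    auto it = ebal.find(a < b ? dkey(a, b) : dkey(b, a));
    return it != ebal.end() && it->second != 0;
  };
  // spatial hash of vertices
  double cell = 0.0;
  {
    double lo[3] = {R_PosInf, R_PosInf, R_PosInf}, hi[3] = {R_NegInf, R_NegInf, R_NegInf};
    for (int i = 0; i < nv; ++i)
      for (int k = 0; k < 3; ++k) {
        lo[k] = std::min(lo[k], v(i, k));
        hi[k] = std::max(hi[k], v(i, k));
      }
    double diag = std::sqrt((hi[0] - lo[0]) * (hi[0] - lo[0]) +
                            (hi[1] - lo[1]) * (hi[1] - lo[1]) +
                            (hi[2] - lo[2]) * (hi[2] - lo[2]));
    cell = std::max(diag / 128.0, tol * 16.0);
    if (cell <= 0) cell = 1.0;
  }
  std::unordered_map<Key3, std::vector<int>, Key3Hash> grid;
  grid.reserve(nv * 2);
  auto cellOf = [&](double x, double y, double z) {
    return Key3{(int64_t)std::floor(x / cell), (int64_t)std::floor(y / cell),
                (int64_t)std::floor(z / cell)};
  };
  for (int i = 0; i < nv; ++i)
    grid[cellOf(v(i, 0), v(i, 1), v(i, 2))].push_back(i);

  std::vector<double> vx(nv), vy(nv), vz(nv);
  for (int i = 0; i < nv; ++i) { vx[i] = v(i, 0); vy[i] = v(i, 1); vz[i] = v(i, 2); }

  std::vector<double> newv; // appended centroid vertices
  std::vector<int> fo;
  fo.reserve(nf * 3);
  double tol2 = tol * tol;

  std::vector<std::pair<double, int>> splits[3];
  for (int i = 0; i < nf; ++i) {
    int idx[3] = {f(i, 0) - 1, f(i, 1) - 1, f(i, 2) - 1};
    bool any = false;
    for (int e = 0; e < 3; ++e) {
      splits[e].clear();
      int a = idx[e], b = idx[(e + 1) % 3];
      if (!unbalanced(a, b)) continue;
      double ax = vx[a], ay = vy[a], az = vz[a];
      double dx = vx[b] - ax, dy = vy[b] - ay, dz = vz[b] - az;
      double len2 = dx * dx + dy * dy + dz * dz;
      if (len2 <= 0) continue;
      // walk grid cells covered by the segment's bbox (expanded by tol)
      double lo[3] = {std::min(ax, vx[b]) - tol, std::min(ay, vy[b]) - tol, std::min(az, vz[b]) - tol};
      double hi[3] = {std::max(ax, vx[b]) + tol, std::max(ay, vy[b]) + tol, std::max(az, vz[b]) + tol};
      int64_t c0[3], c1[3];
      for (int k = 0; k < 3; ++k) {
        c0[k] = (int64_t)std::floor(lo[k] / cell);
        c1[k] = (int64_t)std::floor(hi[k] / cell);
      }
      for (int64_t cx = c0[0]; cx <= c1[0]; ++cx)
        for (int64_t cy = c0[1]; cy <= c1[1]; ++cy)
          for (int64_t cz = c0[2]; cz <= c1[2]; ++cz) {
            auto it = grid.find(Key3{cx, cy, cz});
            if (it == grid.end()) continue;
            for (int p : it->second) {
              if (p == a || p == b) continue;
              double px = vx[p] - ax, py = vy[p] - ay, pz = vz[p] - az;
              double t = (px * dx + py * dy + pz * dz) / len2;
              if (t <= 1e-9 || t >= 1 - 1e-9) continue;
              double qx = px - t * dx, qy = py - t * dy, qz = pz - t * dz;
              if (qx * qx + qy * qy + qz * qz > tol2) continue;
              splits[e].push_back({t, p});
              any = true;
            }
          }
      std::sort(splits[e].begin(), splits[e].end());
      splits[e].erase(std::unique(splits[e].begin(), splits[e].end(),
                                  [](const std::pair<double, int> &x,
                                     const std::pair<double, int> &y) {
                                    return x.second == y.second;
                                  }),
                      splits[e].end());
    }
    if (!any) {
      fo.push_back(idx[0] + 1); fo.push_back(idx[1] + 1); fo.push_back(idx[2] + 1);
      continue;
    }
    // polygon = corners + on-edge vertices; centroid fan
    std::vector<int> poly;
    for (int e = 0; e < 3; ++e) {
      poly.push_back(idx[e]);
      for (auto &s : splits[e]) poly.push_back(s.second);
    }
    double cxm = 0, cym = 0, czm = 0;
    for (int p : poly) { cxm += vx[p]; cym += vy[p]; czm += vz[p]; }
    double m = (double)poly.size();
    int cidx = nv + (int)newv.size() / 3;
    newv.push_back(cxm / m); newv.push_back(cym / m); newv.push_back(czm / m);
    for (size_t k = 0; k < poly.size(); ++k) {
      int a = poly[k], b = poly[(k + 1) % poly.size()];
      fo.push_back(cidx + 1); fo.push_back(a + 1); fo.push_back(b + 1);
    }
  }

  int nnew = (int)newv.size() / 3;
  NumericMatrix V(nv + nnew, 3);
  for (int i = 0; i < nv; ++i) { V(i, 0) = vx[i]; V(i, 1) = vy[i]; V(i, 2) = vz[i]; }
  for (int i = 0; i < nnew; ++i)
    for (int k = 0; k < 3; ++k) V(nv + i, k) = newv[3 * i + k];
  int nfo = (int)fo.size() / 3;
  IntegerMatrix F(nfo, 3);
  for (int i = 0; i < nfo; ++i)
    for (int k = 0; k < 3; ++k) F(i, k) = fo[3 * i + k];
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// Edge audit. closed: every undirected edge traversed equally often in both
// directions. manifold: every edge shared by exactly two faces.
// [[Rcpp::export(name = ".cpp_edge_status")]]
List cpp_edge_status(int nv, IntegerMatrix f) {
  std::unordered_map<uint64_t, std::pair<int, int>> em; // key a<b -> (fwd, rev)
  em.reserve(f.nrow() * 2);
  for (int i = 0; i < f.nrow(); ++i) {
    for (int e = 0; e < 3; ++e) {
      int a = f(i, e) - 1, b = f(i, (e + 1) % 3) - 1;
      uint64_t key; bool fwd;
      if (a < b) { key = (uint64_t)a * (uint64_t)nv + b; fwd = true; }
      else { key = (uint64_t)b * (uint64_t)nv + a; fwd = false; }
      auto &pr = em[key];
      if (fwd) pr.first++; else pr.second++;
    }
  }
  long nb = 0, nnm = 0, nedges = (long)em.size();
  for (auto &kv : em) {
    int fw = kv.second.first, rv = kv.second.second;
    if (fw != rv) ++nb;
    if (fw + rv != 2) ++nnm;
  }
  return List::create(_["n_edges"] = (double)nedges,
                      _["n_unbalanced"] = (double)nb,
                      _["n_nonmanifold"] = (double)nnm);
}

// Make winding consistent inside each connected component (flood fill over
// manifold edges), then flip whole components whose signed volume is negative.
// [[Rcpp::export(name = ".cpp_orient")]]
List cpp_orient(NumericMatrix v, IntegerMatrix f) {
  int nf = f.nrow(), nv = v.nrow();
  std::unordered_map<uint64_t, std::vector<int>> em;
  em.reserve(nf * 2);
  auto ekey = [nv](int a, int b) {
    return a < b ? (uint64_t)a * (uint64_t)nv + b : (uint64_t)b * (uint64_t)nv + a;
  };
  std::vector<std::array<int, 3>> fc(nf);
  for (int i = 0; i < nf; ++i) {
    fc[i] = {f(i, 0) - 1, f(i, 1) - 1, f(i, 2) - 1};
    for (int e = 0; e < 3; ++e) em[ekey(fc[i][e], fc[i][(e + 1) % 3])].push_back(i);
  }
  std::vector<int> comp(nf, -1);
  std::vector<char> flip(nf, 0);
  int ncomp = 0;
  std::vector<int> stack;
  for (int s = 0; s < nf; ++s) {
    if (comp[s] >= 0) continue;
    comp[s] = ncomp;
    stack.push_back(s);
    while (!stack.empty()) {
      int i = stack.back(); stack.pop_back();
      for (int e = 0; e < 3; ++e) {
        int a = fc[i][e], b = fc[i][(e + 1) % 3];
        if (flip[i]) std::swap(a, b); // effective direction
        auto &lst = em[ekey(a, b)];
        if (lst.size() != 2) continue; // only propagate across manifold edges
        int j = lst[0] == i ? lst[1] : lst[0];
        // does j traverse (a,b) in the same effective direction?
        bool same = false;
        for (int e2 = 0; e2 < 3; ++e2) {
          int a2 = fc[j][e2], b2 = fc[j][(e2 + 1) % 3];
          if (flip[j]) std::swap(a2, b2);
          if (a2 == a && b2 == b) { same = true; break; }
        }
        if (comp[j] < 0) {
          comp[j] = ncomp;
          if (same) flip[j] = 1;
          stack.push_back(j);
        }
        // already-visited disagreement is left alone (non-orientable input)
      }
    }
    ++ncomp;
  }
  // per-component signed volume
  std::vector<double> cvol(ncomp, 0.0);
  for (int i = 0; i < nf; ++i) {
    int a = fc[i][0], b = fc[i][1], c = fc[i][2];
    if (flip[i]) std::swap(b, c);
    double v0[3] = {v(a, 0), v(a, 1), v(a, 2)};
    double v1[3] = {v(b, 0), v(b, 1), v(b, 2)};
    double v2[3] = {v(c, 0), v(c, 1), v(c, 2)};
    cvol[comp[i]] += (v0[0] * (v1[1] * v2[2] - v1[2] * v2[1]) -
                      v0[1] * (v1[0] * v2[2] - v1[2] * v2[0]) +
                      v0[2] * (v1[0] * v2[1] - v1[1] * v2[0])) / 6.0;
  }
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nf; ++i) {
    int a = fc[i][0], b = fc[i][1], c = fc[i][2];
    bool fl = flip[i];
    if (cvol[comp[i]] < 0) fl = !fl;
    if (fl) std::swap(b, c);
    F(i, 0) = a + 1; F(i, 1) = b + 1; F(i, 2) = c + 1;
  }
  return List::create(_["faces"] = F, _["n_components"] = ncomp);
}

// Connected components of the face set through shared vertices (union-find).
// [[Rcpp::export(name = ".cpp_vertex_components")]]
int cpp_vertex_components(int nv, IntegerMatrix f) {
  std::vector<int> parent(nv);
  for (int i = 0; i < nv; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  for (int i = 0; i < f.nrow(); ++i) {
    int a = find(f(i, 0) - 1), b = find(f(i, 1) - 1), c = find(f(i, 2) - 1);
    parent[b] = a;
    parent[find(c)] = find(a);
  }
  std::vector<char> used(nv, 0), seen(nv, 0);
  for (int i = 0; i < f.nrow(); ++i)
    for (int k = 0; k < 3; ++k) used[f(i, k) - 1] = 1;
  int n = 0;
  for (int i = 0; i < nv; ++i)
    if (used[i]) {
      int r = find(i);
      if (!seen[r]) { seen[r] = 1; ++n; }
    }
  return n;
}

// Boundary loops as ordered vertex index cycles (1-based).
// [[Rcpp::export(name = ".cpp_boundary_loops")]]
List cpp_boundary_loops(int nv, IntegerMatrix f) {
  std::unordered_map<uint64_t, int> dir; // directed edge -> count
  dir.reserve(f.nrow() * 3);
  auto dkey = [nv](int a, int b) { return (uint64_t)a * (uint64_t)nv + b; };
  for (int i = 0; i < f.nrow(); ++i)
    for (int e = 0; e < 3; ++e)
      dir[dkey(f(i, e) - 1, f(i, (e + 1) % 3) - 1)]++;
  // boundary directed edges: (a,b) present more often than (b,a)
  std::unordered_map<int, std::vector<int>> nxt;
  for (auto &kv : dir) {
    int a = (int)(kv.first / nv), b = (int)(kv.first % nv);
    auto it = dir.find(dkey(b, a));
    int rev = it == dir.end() ? 0 : it->second;
    int excess = kv.second - rev;
    // a boundary halfedge of an oriented surface is traversed (a,b) with no
    // partner (b,a); the loop continues FROM b, so index by b -> a reversed:
    for (int k = 0; k < excess; ++k) nxt[b].push_back(a);
  }
  List loops;
  while (!nxt.empty()) {
    auto it = nxt.begin();
    int start = it->first;
    std::vector<int> loop;
    int cur = start;
    while (true) {
      auto jt = nxt.find(cur);
      if (jt == nxt.end() || jt->second.empty()) break;
      int prev = jt->second.back();
      jt->second.pop_back();
      if (jt->second.empty()) nxt.erase(jt);
      loop.push_back(cur);
      cur = prev;
      if (cur == start) break;
    }
    if (loop.size() >= 3 && cur == start) {
      std::reverse(loop.begin(), loop.end()); // follow boundary direction a->b
      IntegerVector lv(loop.size());
      for (size_t k = 0; k < loop.size(); ++k) lv[k] = loop[k] + 1;
      loops.push_back(lv);
    }
    if (loops.size() > 10000) break; // hopeless input
  }
  return loops;
}

// ---------------------------------------------------------------------------
// Quickhull 3D. Returns triangle indices (1-based) into the input points,
// outward oriented.
namespace qh {
struct V3 { double x, y, z; };
inline V3 sub(V3 a, V3 b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
inline V3 crs(V3 a, V3 b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline double dt(V3 a, V3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline double nrm(V3 a) { return std::sqrt(dt(a, a)); }

struct Face {
  int a, b, c;
  V3 n; double w;
  std::vector<int> outside;
  bool alive = true;
};
} // namespace qh

// [[Rcpp::export(name = ".cpp_convex_hull")]]
IntegerMatrix cpp_convex_hull(NumericMatrix pts) {
  using namespace qh;
  int n = pts.nrow();
  if (n < 4) stop("convex hull needs at least 4 points");
  std::vector<V3> p(n);
  double diag = 0;
  {
    double lo[3] = {R_PosInf, R_PosInf, R_PosInf}, hi[3] = {R_NegInf, R_NegInf, R_NegInf};
    for (int i = 0; i < n; ++i) {
      p[i] = {pts(i, 0), pts(i, 1), pts(i, 2)};
      lo[0] = std::min(lo[0], p[i].x); hi[0] = std::max(hi[0], p[i].x);
      lo[1] = std::min(lo[1], p[i].y); hi[1] = std::max(hi[1], p[i].y);
      lo[2] = std::min(lo[2], p[i].z); hi[2] = std::max(hi[2], p[i].z);
    }
    diag = std::sqrt((hi[0] - lo[0]) * (hi[0] - lo[0]) + (hi[1] - lo[1]) * (hi[1] - lo[1]) +
                     (hi[2] - lo[2]) * (hi[2] - lo[2]));
  }
  double eps = std::max(1e-12, diag * 1e-10);

  // initial simplex: extreme pair, then farthest from line, then from plane
  int i0 = 0, i1 = 0;
  {
    double best = -1;
    int ext[6] = {0, 0, 0, 0, 0, 0};
    for (int i = 0; i < n; ++i) {
      if (p[i].x < p[ext[0]].x) ext[0] = i;
      if (p[i].x > p[ext[1]].x) ext[1] = i;
      if (p[i].y < p[ext[2]].y) ext[2] = i;
      if (p[i].y > p[ext[3]].y) ext[3] = i;
      if (p[i].z < p[ext[4]].z) ext[4] = i;
      if (p[i].z > p[ext[5]].z) ext[5] = i;
    }
    for (int a = 0; a < 6; ++a)
      for (int b = a + 1; b < 6; ++b) {
        double d = nrm(sub(p[ext[a]], p[ext[b]]));
        if (d > best) { best = d; i0 = ext[a]; i1 = ext[b]; }
      }
    if (best < eps) stop("degenerate point set (all points coincide)");
  }
  int i2 = -1;
  {
    double best = -1;
    V3 d = sub(p[i1], p[i0]);
    double dl = nrm(d);
    for (int i = 0; i < n; ++i) {
      double dist = nrm(crs(d, sub(p[i], p[i0]))) / dl;
      if (dist > best) { best = dist; i2 = i; }
    }
    if (best < eps) stop("degenerate point set (collinear)");
  }
  int i3 = -1;
  V3 n0 = crs(sub(p[i1], p[i0]), sub(p[i2], p[i0]));
  {
    double best = -1, nl = nrm(n0);
    for (int i = 0; i < n; ++i) {
      double dist = std::fabs(dt(n0, sub(p[i], p[i0]))) / nl;
      if (dist > best) { best = dist; i3 = i; }
    }
    if (best < eps) stop("degenerate point set (coplanar)");
  }

  std::vector<Face> faces;
  auto mkface = [&](int a, int b, int c, V3 interior) {
    Face f0;
    f0.a = a; f0.b = b; f0.c = c;
    V3 nn = crs(sub(p[b], p[a]), sub(p[c], p[a]));
    double l = nrm(nn);
    nn = {nn.x / l, nn.y / l, nn.z / l};
    double w = dt(nn, p[a]);
    if (dt(nn, interior) - w > 0) { // interior must be behind
      std::swap(f0.b, f0.c);
      nn = {-nn.x, -nn.y, -nn.z};
      w = -w;
    }
    f0.n = nn; f0.w = w;
    faces.push_back(f0);
    return (int)faces.size() - 1;
  };
  V3 interior{(p[i0].x + p[i1].x + p[i2].x + p[i3].x) / 4,
              (p[i0].y + p[i1].y + p[i2].y + p[i3].y) / 4,
              (p[i0].z + p[i1].z + p[i2].z + p[i3].z) / 4};
  mkface(i0, i1, i2, interior);
  mkface(i0, i1, i3, interior);
  mkface(i0, i2, i3, interior);
  mkface(i1, i2, i3, interior);

  // assign points
  std::vector<int> all(n);
  for (int i = 0; i < n; ++i) all[i] = i;
  auto assign = [&](const std::vector<int> &cand, const std::vector<int> &fidx) {
    for (int i : cand) {
      double best = eps; int bf = -1;
      for (int fi : fidx) {
        if (!faces[fi].alive) continue;
        double d = dt(faces[fi].n, p[i]) - faces[fi].w;
        if (d > best) { best = d; bf = fi; }
      }
      if (bf >= 0) faces[bf].outside.push_back(i);
    }
  };
  assign(all, {0, 1, 2, 3});

  std::vector<int> pending;
  for (int i = 0; i < 4; ++i)
    if (!faces[i].outside.empty()) pending.push_back(i);

  int guard = 0;
  while (!pending.empty() && ++guard < 100000) {
    int fi = pending.back(); pending.pop_back();
    if (!faces[fi].alive || faces[fi].outside.empty()) continue;
    // farthest point
    int far = -1; double best = -1;
    for (int i : faces[fi].outside) {
      double d = dt(faces[fi].n, p[i]) - faces[fi].w;
      if (d > best) { best = d; far = i; }
    }
    // visible set via BFS over current faces (simple scan: face count modest)
    std::vector<int> visible;
    for (size_t k = 0; k < faces.size(); ++k) {
      if (!faces[k].alive) continue;
      if (dt(faces[k].n, p[far]) - faces[k].w > eps) visible.push_back((int)k);
    }
    // horizon edges: edges of visible faces adjacent to a non-visible face
    std::unordered_map<uint64_t, int> ecount;
    auto dkey = [n](int a, int b) { return (uint64_t)a * (uint64_t)n + b; };
    for (int k : visible) {
      int vv[3] = {faces[k].a, faces[k].b, faces[k].c};
      for (int e = 0; e < 3; ++e) ecount[dkey(vv[e], vv[(e + 1) % 3])]++;
    }
    std::vector<std::pair<int, int>> horizon;
    for (auto &kv : ecount) {
      int a = (int)(kv.first / n), b = (int)(kv.first % n);
      if (ecount.find(dkey(b, a)) == ecount.end()) horizon.push_back({a, b});
    }
    // collect orphaned points, retire visible faces
    std::vector<int> orphans;
    for (int k : visible) {
      faces[k].alive = false;
      for (int i : faces[k].outside)
        if (i != far) orphans.push_back(i);
      faces[k].outside.clear();
    }
    // new cone faces
    std::vector<int> newf;
    for (auto &e : horizon) newf.push_back(mkface(e.first, e.second, far, interior));
    assign(orphans, newf);
    for (int k : newf)
      if (!faces[k].outside.empty()) pending.push_back(k);
  }

  int nf = 0;
  for (auto &f0 : faces) if (f0.alive) ++nf;
  IntegerMatrix F(nf, 3);
  int r = 0;
  for (auto &f0 : faces)
    if (f0.alive) {
      F(r, 0) = f0.a + 1; F(r, 1) = f0.b + 1; F(r, 2) = f0.c + 1;
      ++r;
    }
  return F;
}
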