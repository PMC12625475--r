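// Taubin lambda/mu smoothing with a frozen-vertex mask, and point-to-surface
// proximity queries used to build that mask.
#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <unordered_set>
#include <cmath>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

// [[Rcpp::export(name = ".cpp_taubin")]]
NumericMatrix cpp_taubin(NumericMatrix v, IntegerMatrix f, LogicalVector movable,
                         double lambda, double mu, int iterations) {
  int nv = v.nrow(), nf = f.nrow();
  // CSR adjacency over unique undirected edges
  std::vector<std::unordered_set<int>> adj(nv);
  for (int i = 0; i < nf; ++i)
    for (int e = 0; e < 3; ++e) {
      int a = f(i, e) - 1, b = f(i, (e + 1) % 3) - 1;
      adj[a].insert(b);
      adj[b].insert(a);
    }
  std::vector<double> x(nv), y(nv), z(nv), x2(nv), y2(nv), z2(nv);
  for (int i = 0; i < nv; ++i) { x[i] = v(i, 0); y[i] = v(i, 1); z[i] = v(i, 2); }
  auto pass = [&](double fct) {
    for (int i = 0; i < nv; ++i) {
      if (!movable[i] || adj[i].empty()) { x2[i] = x[i]; y2[i] = y[i]; z2[i] = z[i]; continue; }
      double mx = 0, my = 0, mz = 0;
      for (int j : adj[i]) { mx += x[j]; my += y[j]; mz += z[j]; }
      double n = (double)adj[i].size();
      x2[i] = x[i] + fct * (mx / n - x[i]);
      y2[i] = y[i] + fct * (my / n - y[i]);
      z2[i] = z[i] + fct * (mz / n - z[i]);
    }
    x.swap(x2); y.swap(y2); z.swap(z2);
  };
  for (int it = 0; it < iterations; ++it) { pass(lambda); pass(mu); }
  NumericMatrix out(nv, 3);
  for (int i = 0; i < nv; ++i) { out(i, 0) = x[i]; out(i, 1) = y[i]; out(i, 2) = z[i]; }
  return out;
}

namespace {

// squared distance point -> triangle (Ericson, Real-Time Collision Detection)
inline double pointTriDist2(const double p[3], const double a[3],
                            const double b[3], const double c[3]) {
  double ab[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double ac[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double ap[3] = {p[0] - a[0], p[1] - a[1], p[2] - a[2]};
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  auto dist2to = [&](double qx, double qy, double qz) {
    double dx = p[0] - qx, dy = p[1] - qy, dz = p[2] - qz;
    return dx * dx + dy * dy + dz * dz;
  };
  if (d1 <= 0 && d2 <= 0) return dist2to(a[0], a[1], a[2]);
  double bp[3] = {p[0] - b[0], p[1] - b[1], p[2] - b[2]};
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0 && d4 <= d3) return dist2to(b[0], b[1], b[2]);
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double t = d1 / (d1 - d3);
    return dist2to(a[0] + t * ab[0], a[1] + t * ab[1], a[2] + t * ab[2]);
  }
  double cp[3] = {p[0] - c[0], p[1] - c[1], p[2] - c[2]};
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0 && d5 <= d6) return dist2to(c[0], c[1], c[2]);
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double t = d2 / (d2 - d6);
    return dist2to(a[0] + t * ac[0], a[1] + t * ac[1], a[2] + t * ac[2]);
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double t = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return dist2to(b[0] + t * (c[0] - b[0]), b[1] + t * (c[1] - b[1]),
                   b[2] + t * (c[2] - b[2]));
  }
  double denom = 1.0 / (va + vb + vc);
  double vv = vb * denom, ww = vc * denom;
  return dist2to(a[0] + ab[0] * vv + ac[0] * ww, a[1] + ab[1] * vv + ac[1] * ww,
                 a[2] + ab[2] * vv + ac[2] * ww);
}

struct K3 {
  int64_t a, b, c;
  bool operator==(const K3 &o) const { return a == o.a && b == o.b && c == o.c; }
};
struct K3H {
  size_t operator()(const K3 &k) const {
    uint64_t h = 1469598103934665603ull;
    auto mix = [&h](uint64_t x) { h ^= x; h *= 1099511628211ull; };
    mix((uint64_t)k.a); mix((uint64_t)k.b); mix((uint64_t)k.c);
    return (size_t)h;
  }
};

} // namespace

// TRUE for every query point within `dist` of the triangle surface (sv, sf).
// [[Rcpp::export(name = ".cpp_near_surface")]]
LogicalVector cpp_near_surface(NumericMatrix q, NumericMatrix sv, IntegerMatrix sf,
                               double dist) {
  int nq = q.nrow(), nf = sf.nrow();
  double cell = std::max(dist * 2.0, 1e-9);
  // average triangle extent guides the cell size (limits bbox spans)
  double acc = 0;
  for (int t = 0; t < std::min(nf, 200); ++t) {
    int a = sf(t, 0) - 1, b = sf(t, 1) - 1;
    double dx = sv(a, 0) - sv(b, 0), dy = sv(a, 1) - sv(b, 1), dz = sv(a, 2) - sv(b, 2);
    acc += std::sqrt(dx * dx + dy * dy + dz * dz);
  }
  if (nf > 0) cell = std::max(cell, acc / std::min(nf, 200));
  std::unordered_map<K3, std::vector<int>, K3H> grid;
  auto cellIdx = [&](double x) { return (int64_t)std::floor(x / cell); };
  for (int t = 0; t < nf; ++t) {
    int ia = sf(t, 0) - 1, ib = sf(t, 1) - 1, ic = sf(t, 2) - 1;
    double lo[3], hi[3];
    for (int k = 0; k < 3; ++k) {
      lo[k] = std::min({sv(ia, k), sv(ib, k), sv(ic, k)}) - dist;
      hi[k] = std::max({sv(ia, k), sv(ib, k), sv(ic, k)}) + dist;
    }
    for (int64_t x = cellIdx(lo[0]); x <= cellIdx(hi[0]); ++x)
      for (int64_t y = cellIdx(lo[1]); y <= cellIdx(hi[1]); ++y)
        for (int64_t z = cellIdx(lo[2]); z <= cellIdx(hi[2]); ++z)
          grid[K3{x, y, z}].push_back(t);
  }
  LogicalVector out(nq);
  double d2 = dist * dist;
  for (int i = 0; i < nq; ++i) {
    double p[3] = {q(i, 0), q(i, 1), q(i, 2)};
    K3 key{cellIdx(p[0]), cellIdx(p[1]), cellIdx(p[2])};
    auto it = grid.find(key);
    if (it == grid.end()) { out[i] = false; continue; }
    bool hit = false;
    for (int t : it->second) {
      int ia = sf(t, 0) - 1, ib = sf(t, 1) - 1, ic = sf(t, 2) - 1;
      double a[3] = {sv(ia, 0), sv(ia, 1), sv(ia, 2)};
      double b[3] = {sv(ib, 0), sv(ib, 1), sv(ib, 2)};
      double c[3] = {sv(ic, 0), sv(ic, 1), sv(ic, 2)};
      if (pointTriDist2(p, a, b, c) <= d2) { hit = true; break; }
    }
    out[i] = hit;
  }
  return out;
}
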