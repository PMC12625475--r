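// BSP-tree constructive solid geometry on triangle meshes.
// Classic solid-modelling scheme: both operands become BSP trees, each is
// clipped against the other, coplanar faces are routed by normal agreement.
// Planes are kept in Hessian form (unit n, offset w with n.p = w).
#include <Rcpp.h>
#include <vector>
#include <deque>
#include <cmath>
#include <algorithm>
#include <utility>

using namespace Rcpp;

namespace csg {

struct V3 { double x, y, z; };
inline V3 operator+(V3 a, V3 b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
inline V3 operator-(V3 a, V3 b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
inline V3 operator*(V3 a, double s) { return {a.x * s, a.y * s, a.z * s}; }
inline double dot(V3 a, V3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline V3 cross(V3 a, V3 b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline double norm(V3 a) { return std::sqrt(dot(a, a)); }
inline V3 lerp(V3 a, V3 b, double t) { return a + (b - a) * t; }

// Classification tolerance in mm; vertices this close to a splitting plane
// are treated as lying on it.
static const double EPS = 1e-5;

enum { COPL = 0, FRONT = 1, BACK = 2, SPAN = 3 };

struct Poly {
  std::vector<V3> v;
  V3 n; double w;
  bool computePlane() {
    V3 nn{0, 0, 0};  // Newell's method: robust for near-degenerate rings
    const size_t m = v.size();
    for (size_t i = 0; i < m; ++i) {
      const V3 &a = v[i], &b = v[(i + 1) % m];
      nn.x += (a.y - b.y) * (a.z + b.z);
      nn.y += (a.z - b.z) * (a.x + b.x);
      nn.z += (a.x - b.x) * (a.y + b.y);
    }
    double l = norm(nn);
    // near-degenerate polygons have unreliable normals and would poison the
    // BSP with spurious boundary planes; their area is negligible, drop them
    if (l < 1e-7) return false;
    n = nn * (1.0 / l);
    V3 c{0, 0, 0};
    for (const auto &p : v) c = c + p;
    w = dot(n, c * (1.0 / m));
    return true;
  }
  void flip() { std::reverse(v.begin(), v.end()); n = n * (-1.0); w = -w; }
};

static void splitPoly(const V3 &n, double w, const Poly &p,
                      std::vector<Poly> &coF, std::vector<Poly> &coB,
                      std::vector<Poly> &F, std::vector<Poly> &B) {
  const size_t m = p.v.size();
  int ptype = 0;
  std::vector<int> types(m);
  for (size_t i = 0; i < m; ++i) {
    double t = dot(n, p.v[i]) - w;
    int ty = (t < -EPS) ? BACK : (t > EPS) ? FRONT : COPL;
    ptype |= ty;
    types[i] = ty;
  }
  switch (ptype) {
  case COPL: (dot(n, p.n) > 0 ? coF : coB).push_back(p); break;
  case FRONT: F.push_back(p); break;
  case BACK: B.push_back(p); break;
  default: {
    std::vector<V3> fv, bv;
    fv.reserve(m + 2); bv.reserve(m + 2);
    for (size_t i = 0; i < m; ++i) {
      size_t j = (i + 1) % m;
      int ti = types[i], tj = types[j];
      if (ti != BACK) fv.push_back(p.v[i]);
      if (ti != FRONT) bv.push_back(p.v[i]);
      if ((ti | tj) == SPAN) {
        double denom = dot(n, p.v[j] - p.v[i]);
        double t = (w - dot(n, p.v[i])) / denom;
        V3 vv = lerp(p.v[i], p.v[j], t);
        fv.push_back(vv);
        bv.push_back(vv);
      }
    }
    if (fv.size() >= 3) { Poly q; q.v = std::move(fv); q.n = p.n; q.w = p.w; F.push_back(std::move(q)); }
    if (bv.size() >= 3) { Poly q; q.v = std::move(bv); q.n = p.n; q.w = p.w; B.push_back(std::move(q)); }
  }
  }
}

struct Node {
  int front = -1, back = -1;
  bool hasPlane = false;
  V3 n{0, 0, 0}; double w = 0;
  std::vector<Poly> polys;
};

struct BSP {
  std::deque<Node> arena;
  int root;
  BSP() { arena.emplace_back(); root = 0; }
  int newNode() { arena.emplace_back(); return (int)arena.size() - 1; }

  // Splitter heuristic: sample a few candidate polygons, prefer the plane
  // that splits least and balances front/back. Deterministic.
  int pickSplitter(const std::vector<Poly> &ps) const {
    size_t ncand = std::min<size_t>(8, ps.size());
    int bestI = 0; double bestScore = 1e300;
    size_t step = std::max<size_t>(1, ps.size() / 128);
    for (size_t c = 0; c < ncand; ++c) {
      size_t ci = c * ps.size() / ncand;
      const Poly &cand = ps[ci];
      long nf = 0, nb = 0, ns = 0;
      for (size_t k = 0; k < ps.size(); k += step) {
        int pt = 0;
        for (const auto &vv : ps[k].v) {
          double t = dot(cand.n, vv) - cand.w;
          pt |= (t < -EPS) ? BACK : (t > EPS) ? FRONT : COPL;
        }
        if (pt == SPAN) ++ns; else if (pt == FRONT) ++nf; else if (pt == BACK) ++nb;
      }
      double score = 4.0 * ns + std::labs(nf - nb);
      if (score < bestScore) { bestScore = score; bestI = (int)ci; }
    }
    return bestI;
  }

  void build(int at, std::vector<Poly> polys) {
    std::vector<std::pair<int, std::vector<Poly>>> st;
    st.emplace_back(at, std::move(polys));
    while (!st.empty()) {
      int idx = st.back().first;
      std::vector<Poly> ps = std::move(st.back().second);
      st.pop_back();
      if (ps.empty()) continue;
      if (!arena[idx].hasPlane) {
        int bi = pickSplitter(ps);
        arena[idx].hasPlane = true;
        arena[idx].n = ps[bi].n;
        arena[idx].w = ps[bi].w;
      }
      std::vector<Poly> F, B;
      {
        Node &nd = arena[idx];
        for (auto &p : ps) splitPoly(nd.n, nd.w, p, nd.polys, nd.polys, F, B);
      }
      if (!F.empty()) {
        if (arena[idx].front < 0) { int ni = newNode(); arena[idx].front = ni; }
        st.emplace_back(arena[idx].front, std::move(F));
      }
      if (!B.empty()) {
        if (arena[idx].back < 0) { int ni = newNode(); arena[idx].back = ni; }
        st.emplace_back(arena[idx].back, std::move(B));
      }
    }
  }

  void invert() {
    std::vector<int> st{root};
    while (!st.empty()) {
      int i = st.back(); st.pop_back();
      Node &nd = arena[i];
      for (auto &p : nd.polys) p.flip();
      if (nd.hasPlane) { nd.n = nd.n * (-1.0); nd.w = -nd.w; }
      std::swap(nd.front, nd.back);
      if (nd.front >= 0) st.push_back(nd.front);
      if (nd.back >= 0) st.push_back(nd.back);
    }
  }

  std::vector<Poly> clipPolygons(const std::vector<Poly> &in) const {
    std::vector<Poly> out;
    std::vector<std::pair<int, std::vector<Poly>>> st;
    st.emplace_back(root, in);
    while (!st.empty()) {
      int i = st.back().first;
      std::vector<Poly> ps = std::move(st.back().second);
      st.pop_back();
      const Node &nd = arena[i];
      if (!nd.hasPlane) {
        for (auto &p : ps) out.push_back(std::move(p));
        continue;
      }
      std::vector<Poly> F, B;
      for (auto &p : ps) splitPoly(nd.n, nd.w, p, F, B, F, B);
      if (nd.front >= 0) st.emplace_back(nd.front, std::move(F));
      else for (auto &p : F) out.push_back(std::move(p));
      if (nd.back >= 0) st.emplace_back(nd.back, std::move(B));
      // back of a leaf plane: inside the solid -> discarded
    }
    return out;
  }

  void clipTo(const BSP &other) {
    std::vector<int> st{root};
    while (!st.empty()) {
      int i = st.back(); st.pop_back();
      Node &nd = arena[i];
      if (!nd.polys.empty()) nd.polys = other.clipPolygons(nd.polys);
      if (nd.front >= 0) st.push_back(nd.front);
      if (nd.back >= 0) st.push_back(nd.back);
    }
  }

  std::vector<Poly> allPolygons() const {
    std::vector<Poly> out;
    std::vector<int> st{root};
    while (!st.empty()) {
      int i = st.back(); st.pop_back();
      const Node &nd = arena[i];
      out.insert(out.end(), nd.polys.begin(), nd.polys.end());
      if (nd.front >= 0) st.push_back(nd.front);
      if (nd.back >= 0) st.push_back(nd.back);
    }
    return out;
  }
};

static std::vector<Poly> meshToPolys(const NumericMatrix &v, const IntegerMatrix &f) {
  std::vector<Poly> out;
  out.reserve(f.nrow());
  for (int i = 0; i < f.nrow(); ++i) {
    Poly p;
    p.v.resize(3);
    for (int k = 0; k < 3; ++k) {
      int vi = f(i, k) - 1;
      p.v[k] = {v(vi, 0), v(vi, 1), v(vi, 2)};
    }
    if (p.computePlane()) out.push_back(std::move(p));
  }
  return out;
}

} // namespace csg

// [[Rcpp::export(name = ".cpp_csg")]]
List cpp_csg(NumericMatrix va, IntegerMatrix fa,
             NumericMatrix vb, IntegerMatrix fb,
             std::string op) {
  using namespace csg;
  BSP a, b;
  a.build(a.root, meshToPolys(va, fa));
  b.build(b.root, meshToPolys(vb, fb));

  if (op == "union") {
    a.clipTo(b);
    b.clipTo(a);
    b.invert(); b.clipTo(a); b.invert();
    a.build(a.root, b.allPolygons());
  } else if (op == "subtract") {
    a.invert();
    a.clipTo(b);
    b.clipTo(a);
    b.invert(); b.clipTo(a); b.invert();
    a.build(a.root, b.allPolygons());
    a.invert();
  } else if (op == "intersect") {
    a.invert();
    b.clipTo(a);
    b.invert();
    a.clipTo(b);
    b.clipTo(a);
    a.build(a.root, b.allPolygons());
    a.invert();
  } else {
    stop("unknown CSG op");
  }

  std::vector<Poly> polys = a.allPolygons();
  // fan-triangulate; emit a vertex soup (welded on the R side)
  size_t ntri = 0;
  for (const auto &p : polys) ntri += p.v.size() - 2;
  NumericMatrix V((int)(ntri * 3), 3);
  IntegerMatrix F((int)ntri, 3);
  int vi = 0, fi = 0;
  for (const auto &p : polys) {
    for (size_t k = 1; k + 1 < p.v.size(); ++k) {
      const V3 *tri[3] = {&p.v[0], &p.v[k], &p.v[k + 1]};
      for (int j = 0; j < 3; ++j) {
        V(vi + j, 0) = tri[j]->x;
        V(vi + j, 1) = tri[j]->y;
        V(vi + j, 2) = tri[j]->z;
        F(fi, j) = vi + j + 1;
      }
      vi += 3; ++fi;
    }
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}
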