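// Column-parity machinery: vertical rays through a watertight mesh give
// signed crossings; winding along z classifies inside/outside. Used for the
// voxel volume oracle, occupancy grids (CSG fallback), plate-thickness rays
// and voxel surface extraction.
#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Crossing { double z; double s; };

// All vertical-ray crossings for a grid of column centers.
// Columns are offset by a tiny fixed sub-pitch shear to dodge exact
// edge/vertex hits; deterministic.
static std::vector<std::vector<Crossing>>
buildColumns(const NumericMatrix &v, const IntegerMatrix &f,
             double x0, double y0, double pitch, int nx, int ny) {
  std::vector<std::vector<Crossing>> cols((size_t)nx * ny);
  const double jx = pitch * 1.1920929e-3, jy = pitch * 2.3841858e-3;
  for (int t = 0; t < f.nrow(); ++t) {
    int a = f(t, 0) - 1, b = f(t, 1) - 1, c = f(t, 2) - 1;
    double ax = v(a, 0), ay = v(a, 1), az = v(a, 2);
    double bx = v(b, 0), by = v(b, 1), bz = v(b, 2);
    double cx = v(c, 0), cy = v(c, 1), cz = v(c, 2);
    double det = (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
    if (std::fabs(det) < 1e-10) continue; // (near-)vertical: no usable z-crossing
    double s = det > 0 ? 1.0 : -1.0;
    double lox = std::min({ax, bx, cx}), hix = std::max({ax, bx, cx});
    double loy = std::min({ay, by, cy}), hiy = std::max({ay, by, cy});
    int i0 = std::max(0, (int)std::ceil((lox - x0 - jx) / pitch - 0.5));
    int i1 = std::min(nx - 1, (int)std::floor((hix - x0 - jx) / pitch - 0.5));
    int j0 = std::max(0, (int)std::ceil((loy - y0 - jy) / pitch - 0.5));
    int j1 = std::min(ny - 1, (int)std::floor((hiy - y0 - jy) / pitch - 0.5));
    for (int j = j0; j <= j1; ++j) {
      double py = y0 + (j + 0.5) * pitch + jy;
      for (int i = i0; i <= i1; ++i) {
        double px = x0 + (i + 0.5) * pitch + jx;
        double w0 = (bx - px) * (cy - py) - (by - py) * (cx - px);
        double w1 = (cx - px) * (ay - py) - (cy - py) * (ax - px);
        double w2 = (ax - px) * (by - py) - (ay - py) * (bx - px);
        if ((w0 > 0) != (det > 0) || (w1 > 0) != (det > 0) || (w2 > 0) != (det > 0))
          continue;
        double z = (w0 * az + w1 * bz + w2 * cz) / det;
        cols[(size_t)j * nx + i].push_back({z, s});
      }
    }
  }
  return cols;
}

// total length of the inside intervals of one column
static double insideLength(std::vector<Crossing> &cr) {
  if (cr.size() < 2) return 0.0;
  std::sort(cr.begin(), cr.end(), [](const Crossing &a, const Crossing &b) { return a.z < b.z; });
  double len = 0, w = 0;
  for (int i = (int)cr.size() - 1; i > 0; --i) {
    w += cr[i].s;
    if (w > 0.5) len += cr[i].z - cr[i - 1].z;
  }
  return len;
}

} // namespace

// Volume by midpoint quadrature over XY columns with exact z-integration.
// [[Rcpp::export(name = ".cpp_column_volume")]]
double cpp_column_volume(NumericMatrix v, IntegerMatrix f,
                         double x0, double y0, double pitch, int nx, int ny) {
  auto cols = buildColumns(v, f, x0, y0, pitch, nx, ny);
  double vol = 0;
  for (auto &c : cols) vol += insideLength(c);
  return vol * pitch * pitch;
}

// Occupancy grid at voxel centers (winding > 0). Linear index i + nx*(j + ny*k).
// [[Rcpp::export(name = ".cpp_occupancy")]]
LogicalVector cpp_occupancy(NumericMatrix v, IntegerMatrix f,
                            double x0, double y0, double z0,
                            double pitch, int nx, int ny, int nz) {
  auto cols = buildColumns(v, f, x0, y0, pitch, nx, ny);
  LogicalVector occ((R_xlen_t)nx * ny * nz);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      auto &cr = cols[(size_t)j * nx + i];
      if (cr.empty()) continue;
      std::sort(cr.begin(), cr.end(),
                [](const Crossing &a, const Crossing &b) { return a.z < b.z; });
      int m = (int)cr.size();
      std::vector<double> suffix(m + 1, 0.0);
      for (int k = m - 1; k >= 0; --k) suffix[k] = suffix[k + 1] + cr[k].s;
      for (int k = 0; k < nz; ++k) {
        double zc = z0 + (k + 0.5) * pitch;
        int lo = (int)(std::upper_bound(cr.begin(), cr.end(), zc,
                                        [](double z, const Crossing &c) { return z < c.z; }) -
                       cr.begin());
        if (suffix[lo] > 0.5)
          occ[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = true;
      }
    }
  return occ;
}

// Watertight axis-aligned surface of an occupancy grid.
// [[Rcpp::export(name = ".cpp_voxel_surface")]]
List cpp_voxel_surface(LogicalVector occ, int nx, int ny, int nz,
                       double x0, double y0, double z0, double pitch) {
  auto at = [&](int i, int j, int k) -> bool {
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return false;
    return occ[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
  };
  std::unordered_map<int64_t, int> vmap;
  std::vector<double> verts;
  auto corner = [&](int i, int j, int k) -> int {
    int64_t key = (int64_t)i + (int64_t)(nx + 1) * ((int64_t)j + (int64_t)(ny + 1) * k);
    auto it = vmap.find(key);
    if (it != vmap.end()) return it->second;
    int idx = (int)(verts.size() / 3);
    vmap.emplace(key, idx);
    verts.push_back(x0 + i * pitch);
    verts.push_back(y0 + j * pitch);
    verts.push_back(z0 + k * pitch);
    return idx;
  };
  std::vector<int> faces;
  auto quad = [&](int a, int b, int c, int d) {
    faces.push_back(a); faces.push_back(b); faces.push_back(c);
    faces.push_back(a); faces.push_back(c); faces.push_back(d);
  };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (!at(i, j, k)) continue;
        if (!at(i + 1, j, k)) // +x
          quad(corner(i + 1, j, k), corner(i + 1, j + 1, k),
               corner(i + 1, j + 1, k + 1), corner(i + 1, j, k + 1));
        if (!at(i - 1, j, k)) // -x
          quad(corner(i, j, k), corner(i, j, k + 1),
               corner(i, j + 1, k + 1), corner(i, j + 1, k));
        if (!at(i, j + 1, k)) // +y
          quad(corner(i, j + 1, k), corner(i, j + 1, k + 1),
               corner(i + 1, j + 1, k + 1), corner(i + 1, j + 1, k));
        if (!at(i, j - 1, k)) // -y
          quad(corner(i, j, k), corner(i + 1, j, k),
               corner(i + 1, j, k + 1), corner(i, j, k + 1));
        if (!at(i, j, k + 1)) // +z
          quad(corner(i, j, k + 1), corner(i + 1, j, k + 1),
               corner(i + 1, j + 1, k + 1), corner(i, j + 1, k + 1));
        if (!at(i, j, k - 1)) // -z
          quad(corner(i, j, k), corner(i, j + 1, k),
               corner(i + 1, j + 1, k), corner(i + 1, j, k));
      }
  int nv = (int)(verts.size() / 3);
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i)
    for (int k2 = 0; k2 < 3; ++k2) V(i, k2) = verts[3 * i + k2];
  int nf = (int)(faces.size() / 3);
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nf; ++i)
    for (int k2 = 0; k2 < 3; ++k2) F(i, k2) = faces[3 * i + k2] + 1;
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// Point-in-solid test by vertical-ray winding.
// [[Rcpp::export(name = ".cpp_points_inside")]]
LogicalVector cpp_points_inside(NumericMatrix v, IntegerMatrix f, NumericMatrix q) {
  int np = q.nrow();
  LogicalVector out(np);
  for (int i = 0; i < np; ++i) {
    double px = q(i, 0), py = q(i, 1), pz = q(i, 2);
    double w = 0;
    for (int t = 0; t < f.nrow(); ++t) {
      int a = f(t, 0) - 1, b = f(t, 1) - 1, c = f(t, 2) - 1;
      double ax = v(a, 0), ay = v(a, 1), az = v(a, 2);
      double bx = v(b, 0), by = v(b, 1), bz = v(b, 2);
      double cx = v(c, 0), cy = v(c, 1), cz = v(c, 2);
      double det = (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
      if (std::fabs(det) < 1e-10) continue;
      double w0 = (bx - px) * (cy - py) - (by - py) * (cx - px);
      double w1 = (cx - px) * (ay - py) - (cy - py) * (ax - px);
      double w2 = (ax - px) * (by - py) - (ay - py) * (bx - px);
      if ((w0 > 0) != (det > 0) || (w1 > 0) != (det > 0) || (w2 > 0) != (det > 0))
        continue;
      double z = (w0 * az + w1 * bz + w2 * cz) / det;
      if (z > pz) w += det > 0 ? 1.0 : -1.0;
    }
    out[i] = w > 0.5;
  }
  return out;
}

// Inside-length of the vertical ray through each (x, y) query point.
// [[Rcpp::export(name = ".cpp_ray_inside_lengths")]]
NumericVector cpp_ray_inside_lengths(NumericMatrix v, IntegerMatrix f,
                                     NumericVector px, NumericVector py) {
  int np = px.size();
  std::vector<std::vector<Crossing>> cr(np);
  // bin the query points on a uniform grid for triangle -> point lookup
  double lox = R_PosInf, loy = R_PosInf, hix = R_NegInf, hiy = R_NegInf;
  for (int i = 0; i < np; ++i) {
    lox = std::min(lox, px[i]); hix = std::max(hix, px[i]);
    loy = std::min(loy, py[i]); hiy = std::max(hiy, py[i]);
  }
  double cell = std::max({(hix - lox) / 64.0, (hiy - loy) / 64.0, 1e-6});
  std::unordered_map<int64_t, std::vector<int>> bins;
  auto bkey = [&](double x, double y) {
    return (int64_t)std::floor((x - lox) / cell) * 1048576 +
           (int64_t)std::floor((y - loy) / cell);
  };
  for (int i = 0; i < np; ++i) bins[bkey(px[i], py[i])].push_back(i);

  for (int t = 0; t < f.nrow(); ++t) {
    int a = f(t, 0) - 1, b = f(t, 1) - 1, c = f(t, 2) - 1;
    double ax = v(a, 0), ay = v(a, 1), az = v(a, 2);
    double bx = v(b, 0), by = v(b, 1), bz = v(b, 2);
    double cx = v(c, 0), cy = v(c, 1), cz = v(c, 2);
    double det = (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
    if (std::fabs(det) < 1e-10) continue;
    double s = det > 0 ? 1.0 : -1.0;
    double tlox = std::min({ax, bx, cx}), thix = std::max({ax, bx, cx});
    double tloy = std::min({ay, by, cy}), thiy = std::max({ay, by, cy});
    if (thix < lox || tlox > hix || thiy < loy || tloy > hiy) continue;
    int64_t cx0 = (int64_t)std::floor((std::max(tlox, lox) - lox) / cell);
    int64_t cx1 = (int64_t)std::floor((std::min(thix, hix) - lox) / cell);
    int64_t cy0 = (int64_t)std::floor((std::max(tloy, loy) - loy) / cell);
    int64_t cy1 = (int64_t)std::floor((std::min(thiy, hiy) - loy) / cell);
    for (int64_t ci = cx0; ci <= cx1; ++ci)
      for (int64_t cj = cy0; cj <= cy1; ++cj) {
        auto it = bins.find(ci * 1048576 + cj);
        if (it == bins.end()) continue;
        for (int i : it->second) {
          double qx = px[i], qy = py[i];
          double w0 = (bx - qx) * (cy - qy) - (by - qy) * (cx - qx);
          double w1 = (cx - qx) * (ay - qy) - (cy - qy) * (ax - qx);
          double w2 = (ax - qx) * (by - qy) - (ay - qy) * (bx - qx);
          if ((w0 > 0) != (det > 0) || (w1 > 0) != (det > 0) || (w2 > 0) != (det > 0))
            continue;
          double z = (w0 * az + w1 * bz + w2 * cz) / det;
          cr[i].push_back({z, s});
        }
      }
  }
  NumericVector out(np);
  for (int i = 0; i < np; ++i) out[i] = insideLength(cr[i]);
  return out;
}
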