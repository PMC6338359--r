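#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Point-in-mesh by vertical (+z) ray casting with crossing parity.
//
// Triangles are projected to the xy-plane; a query column is assigned to a
// projected triangle by a half-open edge rule (the rasterizer's "top-left"
// convention), so a column passing exactly through a shared projected edge is
// counted in exactly one of the two adjacent triangles and the crossing
// parity stays consistent. Triangles whose projection has (near-)zero area
// lie parallel to the ray and are skipped; they are crossed only on a set of
// columns of measure zero. A crossing that coincides with the query point's
// own z (within tol) marks the point as lying on the surface, which is
// resolved as inside.

struct Tri2 {
  double ax, ay, bx, by, cx, cy;  // CCW projected vertices
  double az, bz, cz;
  double inv_area2;
};

static inline bool edge_counts(double dx, double dy) {
  // half-open rule: rule(d) != rule(-d) for every nonzero d
  return (dy < 0.0) || (dy == 0.0 && dx < 0.0);
}

// collects z-values where the vertical line (px, py) crosses the triangle
static inline bool tri_crossing(const Tri2 &t, double px, double py,
                                double *zout) {
  double e_ab = (t.bx - t.ax) * (py - t.ay) - (t.by - t.ay) * (px - t.ax);
  double e_bc = (t.cx - t.bx) * (py - t.by) - (t.cy - t.by) * (px - t.bx);
  double e_ca = (t.ax - t.cx) * (py - t.cy) - (t.ay - t.cy) * (px - t.cx);
  if (e_ab < 0.0 || (e_ab == 0.0 && !edge_counts(t.bx - t.ax, t.by - t.ay)))
    return false;
  if (e_bc < 0.0 || (e_bc == 0.0 && !edge_counts(t.cx - t.bx, t.cy - t.by)))
    return false;
  if (e_ca < 0.0 || (e_ca == 0.0 && !edge_counts(t.ax - t.cx, t.ay - t.cy)))
    return false;
  // barycentric: weight of vertex a is the edge function opposite to a
  double la = e_bc * t.inv_area2;
  double lb = e_ca * t.inv_area2;
  double lc = e_ab * t.inv_area2;
  *zout = la * t.az + lb * t.bz + lc * t.cz;
  return true;
}

static std::vector<Tri2> project_triangles(const NumericMatrix &V,
                                           const IntegerMatrix &F,
                                           double eps_area) {
  std::vector<Tri2> tris;
  tris.reserve(F.nrow());
  for (int i = 0; i < F.nrow(); ++i) {
    int a = F(i, 0) - 1, b = F(i, 1) - 1, c = F(i, 2) - 1;
    Tri2 t;
    t.ax = V(a, 0); t.ay = V(a, 1); t.az = V(a, 2);
    t.bx = V(b, 0); t.by = V(b, 1); t.bz = V(b, 2);
    t.cx = V(c, 0); t.cy = V(c, 1); t.cz = V(c, 2);
    double area2 = (t.bx - t.ax) * (t.cy - t.ay) -
                   (t.by - t.ay) * (t.cx - t.ax);
    if (std::fabs(area2) <= eps_area) continue;  // parallel to the ray
    if (area2 < 0.0) {  // make projection CCW
      std::swap(t.bx, t.cx); std::swap(t.by, t.cy); std::swap(t.bz, t.cz);
      area2 = -area2;
    }
    t.inv_area2 = 1.0 / area2;
    tris.push_back(t);
  }
  return tris;
}

static double mesh_scale(const NumericMatrix &V) {
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) { lo[d] = R_PosInf; hi[d] = R_NegInf; }
  for (int i = 0; i < V.nrow(); ++i)
    for (int d = 0; d < 3; ++d) {
      if (V(i, d) < lo[d]) lo[d] = V(i, d);
      if (V(i, d) > hi[d]) hi[d] = V(i, d);
    }
  double s = 0.0;
  for (int d = 0; d < 3; ++d) s = std::max(s, hi[d] - lo[d]);
  return s > 0.0 ? s : 1.0;
}

// squared distance from point p to triangle (a, b, c) (Ericson)
static double point_tri_dist2(const double p[3], const double a[3],
                              const double b[3], const double c[3]) {
  double ab[3], ac[3], ap[3];
  for (int d = 0; d < 3; ++d) {
    ab[d] = b[d] - a[d]; ac[d] = c[d] - a[d]; ap[d] = p[d] - a[d];
  }
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  auto dist2_to = [&](double qx, double qy, double qz) {
    double dx = p[0]-qx, dy = p[1]-qy, dz = p[2]-qz;
    return dx*dx + dy*dy + dz*dz;
  };
  if (d1 <= 0.0 && d2 <= 0.0) return dist2_to(a[0], a[1], a[2]);
  double bp[3];
  for (int d = 0; d < 3; ++d) bp[d] = p[d] - b[d];
  double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
  double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
  if (d3 >= 0.0 && d4 <= d3) return dist2_to(b[0], b[1], b[2]);
  double vc = d1*d4 - d3*d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    return dist2_to(a[0] + v*ab[0], a[1] + v*ab[1], a[2] + v*ab[2]);
  }
  double cp[3];
  for (int d = 0; d < 3; ++d) cp[d] = p[d] - c[d];
  double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
  double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
  if (d6 >= 0.0 && d5 <= d6) return dist2_to(c[0], c[1], c[2]);
  double vb = d5*d2 - d1*d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    return dist2_to(a[0] + w*ac[0], a[1] + w*ac[1], a[2] + w*ac[2]);
  }
  double va = d3*d6 - d5*d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return dist2_to(b[0] + w*(c[0]-b[0]), b[1] + w*(c[1]-b[1]),
                    b[2] + w*(c[2]-b[2]));
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return dist2_to(a[0] + ab[0]*v + ac[0]*w, a[1] + ab[1]*v + ac[1]*w,
                  a[2] + ab[2]*v + ac[2]*w);
}

// [[Rcpp::export]]
LogicalVector cpp_points_in_mesh(NumericMatrix V, IntegerMatrix F,
                                 NumericMatrix P) {
  double scale = mesh_scale(V);
  double eps_area = 1e-12 * scale * scale;
  double tol = 1e-9 * scale;
  double tol2 = tol * tol;
  std::vector<Tri2> tris = project_triangles(V, F, eps_area);

  int np = P.nrow();
  LogicalVector inside(np);
  for (int p = 0; p < np; ++p) {
    double pt[3] = {P(p, 0), P(p, 1), P(p, 2)};
    // exact boundary handling: a point on the surface is inside
    bool on_surface = false;
    for (int i = 0; i < F.nrow() && !on_surface; ++i) {
      double a[3], b[3], c[3];
      for (int d = 0; d < 3; ++d) {
        a[d] = V(F(i, 0) - 1, d);
        b[d] = V(F(i, 1) - 1, d);
        c[d] = V(F(i, 2) - 1, d);
      }
      if (pt[0] < std::min(a[0], std::min(b[0], c[0])) - tol ||
          pt[0] > std::max(a[0], std::max(b[0], c[0])) + tol ||
          pt[1] < std::min(a[1], std::min(b[1], c[1])) - tol ||
          pt[1] > std::max(a[1], std::max(b[1], c[1])) + tol ||
          pt[2] < std::min(a[2], std::min(b[2], c[2])) - tol ||
          pt[2] > std::max(a[2], std::max(b[2], c[2])) + tol)
        continue;
      if (point_tri_dist2(pt, a, b, c) <= tol2) on_surface = true;
    }
    if (on_surface) { inside[p] = true; continue; }
    int above = 0;
    double z;
    for (size_t t = 0; t < tris.size(); ++t) {
      if (tri_crossing(tris[t], pt[0], pt[1], &z)) {
        if (std::fabs(z - pt[2]) <= tol) { above = 1; break; }
        if (z > pt[2]) ++above;
      }
    }
    inside[p] = (above % 2 == 1);
  }
  return inside;
}

// Regular-grid containment: grid point (ix, iy, iz) sits at
// origin + spacing * (ix, iy, iz), ix fastest (R array order). One crossing
// list is computed per (ix, iy) column and reused for the whole z range.
// [[Rcpp::export]]
LogicalVector cpp_grid_in_mesh(NumericMatrix V, IntegerMatrix F,
                               NumericVector origin, double spacing,
                               IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  double scale = mesh_scale(V);
  double eps_area = 1e-12 * scale * scale;
  double tol = 1e-9 * scale;
  std::vector<Tri2> tris = project_triangles(V, F, eps_area);

  // bucket triangles per column by projected bounding box
  std::vector<std::vector<int> > buckets((size_t)nx * ny);
  for (size_t t = 0; t < tris.size(); ++t) {
    const Tri2 &tr = tris[t];
    double xmin = std::min(tr.ax, std::min(tr.bx, tr.cx));
    double xmax = std::max(tr.ax, std::max(tr.bx, tr.cx));
    double ymin = std::min(tr.ay, std::min(tr.by, tr.cy));
    double ymax = std::max(tr.ay, std::max(tr.by, tr.cy));
    int i0 = std::max(0, (int)std::ceil((xmin - origin[0]) / spacing - 1e-12));
    int i1 = std::min(nx - 1, (int)std::floor((xmax - origin[0]) / spacing + 1e-12));
    int j0 = std::max(0, (int)std::ceil((ymin - origin[1]) / spacing - 1e-12));
    int j1 = std::min(ny - 1, (int)std::floor((ymax - origin[1]) / spacing + 1e-12));
    for (int j = j0; j <= j1; ++j)
      for (int i = i0; i <= i1; ++i)
        buckets[(size_t)j * nx + i].push_back((int)t);
  }

  LogicalVector inside((R_xlen_t)nx * ny * nz);
  std::vector<double> zs;
  for (int j = 0; j < ny; ++j) {
    double py = origin[1] + spacing * j;
    for (int i = 0; i < nx; ++i) {
      double px = origin[0] + spacing * i;
      const std::vector<int> &cand = buckets[(size_t)j * nx + i];
      zs.clear();
      double z;
      for (size_t c = 0; c < cand.size(); ++c)
        if (tri_crossing(tris[cand[c]], px, py, &z)) zs.push_back(z);
      if (zs.empty()) continue;
      std::sort(zs.begin(), zs.end());
      for (int k = 0; k < nz; ++k) {
        double pz = origin[2] + spacing * k;
        // crossings strictly above pz (outside tol band -> parity;
        // within tol -> on surface -> inside)
        size_t above = zs.end() -
          std::upper_bound(zs.begin(), zs.end(), pz + tol);
        bool on_surface = std::upper_bound(zs.begin(), zs.end(), pz + tol) !=
          std::upper_bound(zs.begin(), zs.end(), pz - tol);
        if (on_surface || (above % 2 == 1))
          inside[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = true;
      }
    }
  }
  return inside;
}
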