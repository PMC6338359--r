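#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Isosurface extraction by marching tetrahedra on the Freudenthal (Kuhn)
// subdivision of each voxel cell into 6 tetrahedra sharing the main diagonal.
// The subdivision is translation-invariant, so shared cell faces carry the
// same diagonal in both neighbouring cells and the extracted surface is
// watertight wherever the foreground does not touch the array boundary
// (callers pad with a zero shell).
//
// Cube corner numbering: bit0 = +x, bit1 = +y, bit2 = +z.
static const int TETS[6][4] = {
  {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
  {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}
};

struct Vec3 { double x, y, z; };

static inline Vec3 vsub(const Vec3 &a, const Vec3 &b) {
  Vec3 r; r.x = a.x - b.x; r.y = a.y - b.y; r.z = a.z - b.z; return r;
}
static inline Vec3 vcross(const Vec3 &a, const Vec3 &b) {
  Vec3 r;
  r.x = a.y * b.z - a.z * b.y;
  r.y = a.z * b.x - a.x * b.z;
  r.z = a.x * b.y - a.y * b.x;
  return r;
}
static inline double vdot(const Vec3 &a, const Vec3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}

// [[Rcpp::export]]
List cpp_marching_tetrahedra(NumericVector field, IntegerVector dims,
                             double iso) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double *f = REAL(field);

  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> fa, fb, fc;

  // global grid-vertex linear id (x fastest, matching R array layout)
  auto gid = [&](int i, int j, int k) -> uint64_t {
    return (uint64_t)i + (uint64_t)nx * ((uint64_t)j + (uint64_t)ny * k);
  };

  // trilinear interpolant of the cell at local coordinates (u, v, w)
  auto trilinear = [](const double cv[8], double u, double v, double w) {
    double f = 0.0;
    for (int c = 0; c < 8; ++c) {
      double wu = (c & 1) ? u : 1.0 - u;
      double wv = (c & 2) ? v : 1.0 - v;
      double ww = (c & 4) ? w : 1.0 - w;
      f += cv[c] * wu * wv * ww;
    }
    return f;
  };

  // Iso-crossing vertex on the tetrahedral edge between cell corners c0/c1.
  // The crossing parameter is found on the cell's trilinear interpolant
  // restricted to the edge (bisection), so vertices lie on the trilinear
  // isosurface; restricted to a shared cell face the interpolant is the
  // bilinear form of the shared corners, and shared-edge vertices are
  // deduplicated by their global edge key, keeping the surface watertight.
  auto edge_point = [&](const double cv[8], const uint64_t cid[8],
                        const Vec3 cpos[8], int c0, int c1) -> int {
    uint64_t id0 = cid[c0], id1 = cid[c1];
    uint64_t lo = id0 < id1 ? id0 : id1;
    uint64_t hi = id0 < id1 ? id1 : id0;
    uint64_t key = lo * (uint64_t)nx * ny * nz + hi;  // nx*ny*nz < 2^31
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double u0 = (c0 & 1), v0 = (c0 & 2) ? 1.0 : 0.0, w0 = (c0 & 4) ? 1.0 : 0.0;
    double u1 = (c1 & 1), v1 = (c1 & 2) ? 1.0 : 0.0, w1 = (c1 & 4) ? 1.0 : 0.0;
    double ta = 0.0, tb = 1.0;  // f(ta) and f(tb) straddle iso
    double fa = cv[c0] - iso;
    for (int it2 = 0; it2 < 50; ++it2) {
      double tm = 0.5 * (ta + tb);
      double fm = trilinear(cv, u0 + tm * (u1 - u0), v0 + tm * (v1 - v0),
                            w0 + tm * (w1 - w0)) - iso;
      if ((fm > 0.0) == (fa > 0.0)) { ta = tm; fa = fm; } else { tb = tm; }
    }
    double t = 0.5 * (ta + tb);
    int idx = (int)vx.size();
    vx.push_back(cpos[c0].x + t * (cpos[c1].x - cpos[c0].x));
    vy.push_back(cpos[c0].y + t * (cpos[c1].y - cpos[c0].y));
    vz.push_back(cpos[c0].z + t * (cpos[c1].z - cpos[c0].z));
    edge_vertex.emplace(key, idx);
    return idx;
  };

  auto add_tri = [&](int a, int b, int c, const Vec3 &outward) {
    Vec3 pa = {vx[a], vy[a], vz[a]};
    Vec3 pb = {vx[b], vy[b], vz[b]};
    Vec3 pc = {vx[c], vy[c], vz[c]};
    Vec3 n = vcross(vsub(pb, pa), vsub(pc, pa));
    if (vdot(n, outward) < 0.0) std::swap(b, c);
    fa.push_back(a); fb.push_back(b); fc.push_back(c);
  };

  Vec3 corner_pos[8];
  double cv[8];
  uint64_t cid[8];

  for (int k = 0; k + 1 < nz; ++k) {
    for (int j = 0; j + 1 < ny; ++j) {
      for (int i = 0; i + 1 < nx; ++i) {
        int n_in = 0;
        for (int c = 0; c < 8; ++c) {
          int ci = i + (c & 1), cj = j + ((c >> 1) & 1), ck = k + ((c >> 2) & 1);
          cid[c] = gid(ci, cj, ck);
          cv[c] = f[cid[c]];
          corner_pos[c].x = ci; corner_pos[c].y = cj; corner_pos[c].z = ck;
          if (cv[c] > iso) ++n_in;
        }
        if (n_in == 0 || n_in == 8) continue;

        for (int t = 0; t < 6; ++t) {
          int in_idx[4], out_idx[4], ni = 0, no = 0;
          for (int c = 0; c < 4; ++c) {
            int v = TETS[t][c];
            if (cv[v] > iso) in_idx[ni++] = v; else out_idx[no++] = v;
          }
          if (ni == 0 || ni == 4) continue;

          // outward reference: from mean of inside corners to mean of outside
          Vec3 cin = {0, 0, 0}, cout = {0, 0, 0};
          for (int c = 0; c < ni; ++c) {
            cin.x += corner_pos[in_idx[c]].x;
            cin.y += corner_pos[in_idx[c]].y;
            cin.z += corner_pos[in_idx[c]].z;
          }
          for (int c = 0; c < no; ++c) {
            cout.x += corner_pos[out_idx[c]].x;
            cout.y += corner_pos[out_idx[c]].y;
            cout.z += corner_pos[out_idx[c]].z;
          }
          Vec3 outward = {cout.x / no - cin.x / ni,
                          cout.y / no - cin.y / ni,
                          cout.z / no - cin.z / ni};

          auto ep = [&](int a, int b) {
            return edge_point(cv, cid, corner_pos, a, b);
          };

          if (ni == 1) {
            int a = in_idx[0];
            add_tri(ep(a, out_idx[0]), ep(a, out_idx[1]), ep(a, out_idx[2]),
                    outward);
          } else if (ni == 3) {
            int a = out_idx[0];
            add_tri(ep(in_idx[0], a), ep(in_idx[1], a), ep(in_idx[2], a),
                    outward);
          } else {  // ni == 2: quad split into two triangles
            int a = in_idx[0], b = in_idx[1];
            int c = out_idx[0], d = out_idx[1];
            int e_ac = ep(a, c), e_ad = ep(a, d);
            int e_bc = ep(b, c), e_bd = ep(b, d);
            add_tri(e_ac, e_ad, e_bd, outward);
            add_tri(e_ac, e_bd, e_bc, outward);
          }
        }
      }
    }
  }

  int nv = (int)vx.size(), nf = (int)fa.size();
  NumericMatrix verts(nv, 3);
  IntegerMatrix faces(nf, 3);
  for (int v = 0; v < nv; ++v) {
    verts(v, 0) = vx[v]; verts(v, 1) = vy[v]; verts(v, 2) = vz[v];
  }
  for (int v = 0; v < nf; ++v) {
    faces(v, 0) = fa[v] + 1; faces(v, 1) = fb[v] + 1; faces(v, 2) = fc[v] + 1;
  }
  return List::create(_["vertices"] = verts, _["faces"] = faces);
}
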