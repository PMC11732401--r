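#include <Rcpp.h>
#include <cmath>
#include <map>
#include <utility>
#include <vector>
using namespace Rcpp;

// Isosurface extraction by marching tetrahedra on a regular grid.
// vals: field sampled at nx*ny*nz nodes (Fortran order: x fastest),
// origin/spacing: grid geometry. Emits a triangle mesh of the level set
// vals == iso, vertices welded on shared grid edges, triangles oriented so
// normals point towards increasing field value.
// Each cube is split into 6 tetrahedra around its main diagonal, which makes
// the surface watertight across cube faces.

struct VKey {
  long long a, b;
  bool operator<(const VKey &o) const {
    return a < o.a || (a == o.a && b < o.b);
  }
};

// [[Rcpp::export]]
List cpp_marching_tets(NumericVector vals, int nx, int ny, int nz,
                       NumericVector origin, double spacing, double iso) {
  if ((long long)nx * ny * nz != (long long)vals.size())
    stop("grid size mismatch");
  auto node = [&](int i, int j, int k) -> long long {
    return (long long)i + (long long)nx * (j + (long long)ny * k);
  };
  // 6 tetrahedra per cube: corners indexed 0..7 as (i+di, j+dj, k+dk),
  // bit 0 = di, bit 1 = dj, bit 2 = dk. All share diagonal 0-7.
  static const int tets[6][4] = {
      {0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
      {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}};
  std::map<VKey, int> vmap;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;

  double cval[8];
  long long cid[8];
  double cpos[8][3];

  auto edge_vertex = [&](int c0, int c1) -> int {
    long long a = cid[c0], b = cid[c1];
    double va = cval[c0], vb = cval[c1];
    const double *pa = cpos[c0], *pb = cpos[c1];
    if (a > b) { std::swap(a, b); std::swap(va, vb); std::swap(pa, pb); }
    VKey key{a, b};
    auto it = vmap.find(key);
    if (it != vmap.end()) return it->second;
    double t = (iso - va) / (vb - va);
    if (t < 0.0) t = 0.0;
    if (t > 1.0) t = 1.0;
    int id = (int)vx.size();
    vx.push_back(pa[0] + t * (pb[0] - pa[0]));
    vy.push_back(pa[1] + t * (pb[1] - pa[1]));
    vz.push_back(pa[2] + t * (pb[2] - pa[2]));
    vmap[key] = id;
    return id;
  };

  auto emit = [&](int e0a, int e0b, int e1a, int e1b, int e2a, int e2b,
                  const double *grad_dir) {
    int i0 = edge_vertex(e0a, e0b);
    int i1 = edge_vertex(e1a, e1b);
    int i2 = edge_vertex(e2a, e2b);
    if (i0 == i1 || i1 == i2 || i0 == i2) return;
    // orient: normal should point along grad_dir (towards higher field)
    double ux = vx[i1] - vx[i0], uy = vy[i1] - vy[i0], uz = vz[i1] - vz[i0];
    double wx = vx[i2] - vx[i0], wy = vy[i2] - vy[i0], wz = vz[i2] - vz[i0];
    double nxv = uy * wz - uz * wy, nyv = uz * wx - ux * wz,
           nzv = ux * wy - uy * wx;
    double d = nxv * grad_dir[0] + nyv * grad_dir[1] + nzv * grad_dir[2];
    if (d >= 0) { tri.push_back(i0); tri.push_back(i1); tri.push_back(i2); }
    else        { tri.push_back(i0); tri.push_back(i2); tri.push_back(i1); }
  };

  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        for (int c = 0; c < 8; ++c) {
          int di = c & 1, dj = (c >> 1) & 1, dk = (c >> 2) & 1;
          cid[c] = node(i + di, j + dj, k + dk);
          cval[c] = vals[cid[c]];
          cpos[c][0] = origin[0] + (i + di) * spacing;
          cpos[c][1] = origin[1] + (j + dj) * spacing;
          cpos[c][2] = origin[2] + (k + dk) * spacing;
        }
        for (int t = 0; t < 6; ++t) {
          const int *T = tets[t];
          bool in[4];
          int nin = 0;
          for (int c = 0; c < 4; ++c) {
            in[c] = cval[T[c]] < iso;
            if (in[c]) ++nin;
          }
          if (nin == 0 || nin == 4) continue;
          // approximate gradient direction: from inside corners to outside
          double g[3] = {0, 0, 0};
          for (int c = 0; c < 4; ++c)
            for (int d = 0; d < 3; ++d)
              g[d] += (in[c] ? -1.0 : 1.0) * cpos[T[c]][d];
          if (nin == 1 || nin == 3) {
            int apex = -1;
            bool apex_in = (nin == 1);
            for (int c = 0; c < 4; ++c)
              if (in[c] == apex_in) apex = c;
            int o[3], no = 0;
            for (int c = 0; c < 4; ++c)
              if (c != apex) o[no++] = c;
            emit(T[apex], T[o[0]], T[apex], T[o[1]], T[apex], T[o[2]], g);
          } else {  // nin == 2: quad -> 2 triangles
            int a[2], b[2], na = 0, nb = 0;
            for (int c = 0; c < 4; ++c)
              (in[c] ? a[na++] : b[nb++]) = c;
            // edge points: (a0,b0), (a0,b1), (a1,b0), (a1,b1)
            emit(T[a[0]], T[b[0]], T[a[0]], T[b[1]], T[a[1]], T[b[1]], g);
            emit(T[a[0]], T[b[0]], T[a[1]], T[b[1]], T[a[1]], T[b[0]], g);
          }
        }
      }
  int nv = (int)vx.size(), nf = (int)tri.size() / 3;
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) { V(i, 0) = vx[i]; V(i, 1) = vy[i]; V(i, 2) = vz[i]; }
  IntegerMatrix F(nf, 3);
  for (int f = 0; f < nf; ++f) {
    F(f, 0) = tri[3 * f];
    F(f, 1) = tri[3 * f + 1];
    F(f, 2) = tri[3 * f + 2];
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}
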