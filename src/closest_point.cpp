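#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <algorithm>
#include <functional>
#include <map>
#include <vector>
using namespace Rcpp;

// Closest point on triangle (a,b,c) to p. Ericson, Real-Time Collision
// Detection, ch. 5.1.5. Writes result into out[3], returns squared distance.
static double closest_pt_triangle(const double *p, const double *a,
                                  const double *b, const double *c,
                                  double *out) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) {
    for (int i = 0; i < 3; ++i) out[i] = a[i];
  } else {
    double bp[3];
    for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
    double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
    double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
    if (d3 >= 0.0 && d4 <= d3) {
      for (int i = 0; i < 3; ++i) out[i] = b[i];
    } else {
      double vc = d1 * d4 - d3 * d2;
      if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
        double v = d1 / (d1 - d3);
        for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
      } else {
        double cp[3];
        for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
        double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
        double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
        if (d6 >= 0.0 && d5 <= d6) {
          for (int i = 0; i < 3; ++i) out[i] = c[i];
        } else {
          double vb = d5 * d2 - d1 * d6;
          if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
            double w = d2 / (d2 - d6);
            for (int i = 0; i < 3; ++i) out[i] = a[i] + w * ac[i];
          } else {
            double va = d3 * d6 - d5 * d4;
            if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
              double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
              for (int i = 0; i < 3; ++i) out[i] = b[i] + w * (c[i] - b[i]);
            } else {
              double denom = 1.0 / (va + vb + vc);
              double v = vb * denom, w = vc * denom;
              for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i] * v + ac[i] * w;
            }
          }
        }
      }
    }
  }
  double dx = p[0] - out[0], dy = p[1] - out[1], dz = p[2] - out[2];
  return dx * dx + dy * dy + dz * dz;
}

// Closest point on a triangle mesh for each query point. Brute force over
// faces with per-face AABB rejection against the current best; initial best
// seeded from the nearest face centroid. V: n x 3, F: m x 3 (0-based),
// Q: q x 3. Returns list(points, dist, face).
// [[Rcpp::export]]
List cpp_mesh_closest(NumericMatrix V, IntegerMatrix F, NumericMatrix Q) {
  int m = F.nrow(), q = Q.nrow();
  if (m == 0) stop("mesh has no faces");
  // face vertex coords and AABBs
  std::vector<double> fa(3 * m), fb(3 * m), fc(3 * m), lo(3 * m), hi(3 * m),
      cen(3 * m);
  for (int f = 0; f < m; ++f) {
    int ia = F(f, 0), ib = F(f, 1), ic = F(f, 2);
    for (int d = 0; d < 3; ++d) {
      double va = V(ia, d), vb = V(ib, d), vc = V(ic, d);
      fa[3 * f + d] = va; fb[3 * f + d] = vb; fc[3 * f + d] = vc;
      double l = std::min(va, std::min(vb, vc));
      double h = std::max(va, std::max(vb, vc));
      lo[3 * f + d] = l; hi[3 * f + d] = h;
      cen[3 * f + d] = (va + vb + vc) / 3.0;
    }
  }
  NumericMatrix P(q, 3);
  NumericVector D(q);
  IntegerVector FI(q);
  double tmp[3];
  for (int i = 0; i < q; ++i) {
    double p[3] = {Q(i, 0), Q(i, 1), Q(i, 2)};
    // seed with nearest centroid
    int seed = 0;
    double best_cen = std::numeric_limits<double>::infinity();
    for (int f = 0; f < m; ++f) {
      double dx = p[0] - cen[3 * f], dy = p[1] - cen[3 * f + 1],
             dz = p[2] - cen[3 * f + 2];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best_cen) { best_cen = d2; seed = f; }
    }
    double best[3];
    double bd2 = closest_pt_triangle(p, &fa[3 * seed], &fb[3 * seed],
                                     &fc[3 * seed], best);
    int bf = seed;
    for (int f = 0; f < m; ++f) {
      if (f == seed) continue;
      // AABB lower bound on squared distance
      double d2 = 0.0;
      for (int d = 0; d < 3; ++d) {
        double v = p[d];
        double e = (v < lo[3 * f + d]) ? lo[3 * f + d] - v
                   : (v > hi[3 * f + d]) ? v - hi[3 * f + d] : 0.0;
        d2 += e * e;
      }
      if (d2 >= bd2) continue;
      double c2 = closest_pt_triangle(p, &fa[3 * f], &fb[3 * f], &fc[3 * f], tmp);
      if (c2 < bd2) {
        bd2 = c2; bf = f;
        best[0] = tmp[0]; best[1] = tmp[1]; best[2] = tmp[2];
      }
    }
    P(i, 0) = best[0]; P(i, 1) = best[1]; P(i, 2) = best[2];
    D[i] = std::sqrt(bd2);
    FI[i] = bf + 1;  // 1-based for R
  }
  return List::create(_["points"] = P, _["dist"] = D, _["face"] = FI);
}

// k nearest neighbours of each query row in X (brute force).
// Returns list(idx: q x k 1-based, dist: q x k).
// [[Rcpp::export]]
List cpp_knn(NumericMatrix X, NumericMatrix Q, int k) {
  int n = X.nrow(), q = Q.nrow();
  if (k < 1 || k > n) stop("k out of range");
  IntegerMatrix idx(q, k);
  NumericMatrix dst(q, k);
  std::vector<std::pair<double, int>> cand(n);
  for (int i = 0; i < q; ++i) {
    double px = Q(i, 0), py = Q(i, 1), pz = Q(i, 2);
    for (int j = 0; j < n; ++j) {
      double dx = X(j, 0) - px, dy = X(j, 1) - py, dz = X(j, 2) - pz;
      cand[j] = std::make_pair(dx * dx + dy * dy + dz * dz, j);
    }
    std::partial_sort(cand.begin(), cand.begin() + k, cand.end());
    for (int j = 0; j < k; ++j) {
      idx(i, j) = cand[j].second + 1;
      dst(i, j) = std::sqrt(cand[j].first);
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dst);
}

// Connected components over mesh vertices via union-find on face edges.
// [[Rcpp::export]]
IntegerVector cpp_vertex_components(IntegerMatrix F, int n_vertices) {
  std::vector<int> parent(n_vertices);
  for (int i = 0; i < n_vertices; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  for (int f = 0; f < F.nrow(); ++f) {
    int a = find(F(f, 0)), b = find(F(f, 1)), c = find(F(f, 2));
    parent[b] = a;
    parent[find(c)] = find(a);
  }
  IntegerVector lab(n_vertices);
  std::map<int, int> relab;
  for (int i = 0; i < n_vertices; ++i) {
    int r = find(i);
    auto it = relab.find(r);
    if (it == relab.end()) { int id = (int)relab.size() + 1; relab[r] = id; lab[i] = id; }
    else lab[i] = it->second;
  }
  return lab;
}
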