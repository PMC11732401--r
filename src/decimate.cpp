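#include <Rcpp.h>
#include <cmath>
#include <queue>
#include <set>
#include <vector>
using namespace Rcpp;

// Quadric-error-metric edge-collapse decimation (Garland & Heckbert).
// Collapses are rejected if they would break the edge link condition
// (manifoldness) or flip any incident face normal. Intended for closed
// manifold meshes; boundary edges (!= 2 incident faces) are never collapsed.

struct Quadric {
  double q[10];  // [q11 q12 q13 q14 q22 q23 q24 q33 q34 q44]
  Quadric() { for (int i = 0; i < 10; ++i) q[i] = 0; }
  void add_plane(double a, double b, double c, double d) {
    q[0] += a * a; q[1] += a * b; q[2] += a * c; q[3] += a * d;
    q[4] += b * b; q[5] += b * c; q[6] += b * d;
    q[7] += c * c; q[8] += c * d; q[9] += d * d;
  }
  void add(const Quadric &o) { for (int i = 0; i < 10; ++i) q[i] += o.q[i]; }
  double eval(const double *v) const {
    double x = v[0], y = v[1], z = v[2];
    return q[0]*x*x + 2*q[1]*x*y + 2*q[2]*x*z + 2*q[3]*x +
           q[4]*y*y + 2*q[5]*y*z + 2*q[6]*y +
           q[7]*z*z + 2*q[8]*z + q[9];
  }
  // optimal position; returns false if the 3x3 system is near-singular
  bool optimal(double *v) const {
    double a11 = q[0], a12 = q[1], a13 = q[2];
    double a22 = q[4], a23 = q[5], a33 = q[7];
    double b1 = -q[3], b2 = -q[6], b3 = -q[8];
    double det = a11 * (a22 * a33 - a23 * a23) - a12 * (a12 * a33 - a23 * a13)
               + a13 * (a12 * a23 - a22 * a13);
    double scale = a11 + a22 + a33;
    if (std::fabs(det) < 1e-10 * scale * scale * scale + 1e-300) return false;
    v[0] = (b1 * (a22 * a33 - a23 * a23) - a12 * (b2 * a33 - a23 * b3)
            + a13 * (b2 * a23 - a22 * b3)) / det;
    v[1] = (a11 * (b2 * a33 - a23 * b3) - b1 * (a12 * a33 - a13 * a23)
            + a13 * (a12 * b3 - b2 * a13)) / det;
    v[2] = (a11 * (a22 * b3 - b2 * a23) - a12 * (a12 * b3 - b2 * a13)
            + b1 * (a12 * a23 - a22 * a13)) / det;
    return true;
  }
};

struct QEntry {
  double cost;
  int a, b, sa, sb;
  bool operator<(const QEntry &o) const { return cost > o.cost; }  // min-heap
};

// [[Rcpp::export]]
List cpp_decimate_qem(NumericMatrix Vin, IntegerMatrix Fin, int target_faces) {
  int nv = Vin.nrow(), nf = Fin.nrow();
  std::vector<double> V(3 * nv);
  for (int i = 0; i < nv; ++i)
    for (int d = 0; d < 3; ++d) V[3 * i + d] = Vin(i, d);
  std::vector<int> F(3 * nf);
  for (int f = 0; f < nf; ++f)
    for (int d = 0; d < 3; ++d) F[3 * f + d] = Fin(f, d);
  std::vector<bool> face_alive(nf, true), vert_alive(nv, true);
  std::vector<std::set<int>> vfaces(nv);
  for (int f = 0; f < nf; ++f)
    for (int d = 0; d < 3; ++d) vfaces[F[3 * f + d]].insert(f);

  auto fnormal = [&](int f, const double *override_pos, int override_v,
                     double *n) -> double {
    const double *p[3];
    double tmp[3][3];
    for (int d = 0; d < 3; ++d) {
      int v = F[3 * f + d];
      if (v == override_v) { p[d] = override_pos; }
      else {
        tmp[d][0] = V[3 * v]; tmp[d][1] = V[3 * v + 1]; tmp[d][2] = V[3 * v + 2];
        p[d] = tmp[d];
      }
    }
    double u[3], w[3];
    for (int d = 0; d < 3; ++d) { u[d] = p[1][d] - p[0][d]; w[d] = p[2][d] - p[0][d]; }
    n[0] = u[1] * w[2] - u[2] * w[1];
    n[1] = u[2] * w[0] - u[0] * w[2];
    n[2] = u[0] * w[1] - u[1] * w[0];
    double len = std::sqrt(n[0]*n[0] + n[1]*n[1] + n[2]*n[2]);
    if (len > 0) { n[0] /= len; n[1] /= len; n[2] /= len; }
    return len;
  };

  std::vector<Quadric> Qv(nv);
  for (int f = 0; f < nf; ++f) {
    double n[3];
    if (fnormal(f, nullptr, -1, n) <= 0) continue;
    int v0 = F[3 * f];
    double d = -(n[0] * V[3*v0] + n[1] * V[3*v0+1] + n[2] * V[3*v0+2]);
    for (int c = 0; c < 3; ++c) Qv[F[3 * f + c]].add_plane(n[0], n[1], n[2], d);
  }

  std::vector<int> stamp(nv, 0);
  std::priority_queue<QEntry> heap;

  auto edge_cost = [&](int a, int b, double *pos) -> double {
    Quadric Q = Qv[a];
    Q.add(Qv[b]);
    double best[3], cbest;
    if (Q.optimal(best)) {
      cbest = Q.eval(best);
    } else {
      double mid[3] = {(V[3*a]+V[3*b])/2, (V[3*a+1]+V[3*b+1])/2, (V[3*a+2]+V[3*b+2])/2};
      const double *cands[3] = {&V[3*a], &V[3*b], mid};
      cbest = Q.eval(cands[0]);
      best[0] = cands[0][0]; best[1] = cands[0][1]; best[2] = cands[0][2];
      for (int c = 1; c < 3; ++c) {
        double e = Q.eval(cands[c]);
        if (e < cbest) { cbest = e; best[0] = cands[c][0]; best[1] = cands[c][1]; best[2] = cands[c][2]; }
      }
    }
    pos[0] = best[0]; pos[1] = best[1]; pos[2] = best[2];
    return cbest;
  };

  auto push_edges_of = [&](int a) {
    std::set<int> nb;
    for (int f : vfaces[a])
      for (int d = 0; d < 3; ++d) {
        int v = F[3 * f + d];
        if (v != a) nb.insert(v);
      }
    double pos[3];
    for (int b : nb) {
      double c = edge_cost(a, b, pos);
      heap.push(QEntry{c, a, b, stamp[a], stamp[b]});
    }
  };
  for (int v = 0; v < nv; ++v)
    if (!vfaces[v].empty()) {
      // push each edge once (a < b)
      std::set<int> nb;
      for (int f : vfaces[v])
        for (int d = 0; d < 3; ++d)
          if (F[3 * f + d] > v) nb.insert(F[3 * f + d]);
      double pos[3];
      for (int b : nb) heap.push(QEntry{edge_cost(v, b, pos), v, b, 0, 0});
    }

  int alive_faces = nf;
  while (alive_faces > target_faces && !heap.empty()) {
    QEntry e = heap.top();
    heap.pop();
    int a = e.a, b = e.b;
    if (!vert_alive[a] || !vert_alive[b]) continue;
    if (stamp[a] != e.sa || stamp[b] != e.sb) continue;
    // shared faces of edge (a,b)
    std::vector<int> shared;
    for (int f : vfaces[a]) if (vfaces[b].count(f)) shared.push_back(f);
    if (shared.size() != 2) continue;  // boundary or non-manifold: skip
    // link condition: common vertex neighbours must be exactly the 2
    // opposite vertices of the shared faces
    std::set<int> na, nbv;
    for (int f : vfaces[a]) for (int d = 0; d < 3; ++d) { int v = F[3*f+d]; if (v != a && v != b) na.insert(v); }
    for (int f : vfaces[b]) for (int d = 0; d < 3; ++d) { int v = F[3*f+d]; if (v != a && v != b) nbv.insert(v); }
    std::vector<int> common;
    for (int v : na) if (nbv.count(v)) common.push_back(v);
    if (common.size() != 2) continue;
    if (alive_faces - 2 < 4) break;  // keep a valid closed mesh
    // candidate position
    double pos[3];
    edge_cost(a, b, pos);
    // normal-flip check over surviving faces incident to a or b
    bool flip = false;
    std::set<int> inc(vfaces[a]);
    inc.insert(vfaces[b].begin(), vfaces[b].end());
    for (int f : inc) {
      if (f == shared[0] || f == shared[1]) continue;
      double n_old[3], n_new[3];
      if (fnormal(f, nullptr, -1, n_old) <= 0) continue;
      // after collapse both a and b sit at pos; faces contain one of them
      int ov = vfaces[a].count(f) ? a : b;
      double area = fnormal(f, pos, ov, n_new);
      if (area < 1e-12 ||
          n_old[0]*n_new[0] + n_old[1]*n_new[1] + n_old[2]*n_new[2] < 0.1) {
        flip = true;
        break;
      }
    }
    if (flip) continue;
    // perform collapse: b merges into a at pos
    V[3*a] = pos[0]; V[3*a+1] = pos[1]; V[3*a+2] = pos[2];
    Qv[a].add(Qv[b]);
    for (int f : shared) {
      if (!face_alive[f]) continue;
      face_alive[f] = false;
      --alive_faces;
      for (int d = 0; d < 3; ++d) vfaces[F[3*f+d]].erase(f);
    }
    std::vector<int> bf(vfaces[b].begin(), vfaces[b].end());
    for (int f : bf) {
      for (int d = 0; d < 3; ++d)
        if (F[3*f+d] == b) F[3*f+d] = a;
      vfaces[b].erase(f);
      vfaces[a].insert(f);
    }
    vert_alive[b] = false;
    ++stamp[a];
    ++stamp[b];
    for (int v : common) ++stamp[v];
    push_edges_of(a);
  }

  // compact
  std::vector<int> remap(nv, -1);
  int nvo = 0;
  for (int v = 0; v < nv; ++v)
    if (vert_alive[v] && !vfaces[v].empty()) remap[v] = nvo++;
  int nfo = 0;
  for (int f = 0; f < nf; ++f) if (face_alive[f]) ++nfo;
  NumericMatrix Vout(nvo, 3);
  for (int v = 0; v < nv; ++v)
    if (remap[v] >= 0)
      for (int d = 0; d < 3; ++d) Vout(remap[v], d) = V[3 * v + d];
  IntegerMatrix Fout(nfo, 3);
  int fo = 0;
  for (int f = 0; f < nf; ++f)
    if (face_alive[f]) {
      for (int d = 0; d < 3; ++d) Fout(fo, d) = remap[F[3 * f + d]];
      ++fo;
    }
  return List::create(_["vertices"] = Vout, _["faces"] = Fout);
}
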