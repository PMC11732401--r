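#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Accumulate the 6x6 Gauss-Newton system for plane-to-plane ICP.
// moved: transformed source points (n x 3); tgt: target points (m x 3);
// src_idx/tgt_idx: 1-based correspondence indices; Ca/Cb: per-point 3x3
// covariances flattened row-major (n x 9, m x 9); R: current 3x3 rotation.
// Residual r_i = moved_i - tgt_j, weight M_i = (Cb_j + R Ca_i R')^{-1},
// Jacobian J_i = [ -[p_i]x | I ].
// [[Rcpp::export]]
List cpp_gicp_accumulate(NumericMatrix moved, NumericMatrix tgt,
                         IntegerVector src_idx, IntegerVector tgt_idx,
                         NumericMatrix Ca, NumericMatrix Cb,
                         NumericMatrix R) {
  double H[36] = {0};
  double g[6] = {0};
  double cost = 0.0;
  int npair = src_idx.size();
  double Rm[9];
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) Rm[3 * a + b] = R(a, b);
  for (int k = 0; k < npair; ++k) {
    int i = src_idx[k] - 1, j = tgt_idx[k] - 1;
    // S = Cb_j + R Ca_i R'
    double A[9], T[9], S[9];
    for (int a = 0; a < 9; ++a) A[a] = Ca(i, a);
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b) {
        double s = 0;
        for (int c = 0; c < 3; ++c) s += Rm[3 * a + c] * A[3 * c + b];
        T[3 * a + b] = s;
      }
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b) {
        double s = 0;
        for (int c = 0; c < 3; ++c) s += T[3 * a + c] * Rm[3 * b + c];
        S[3 * a + b] = Cb(j, 3 * a + b) + s;
      }
    // M = S^{-1} (3x3 inverse via adjugate)
    double det = S[0] * (S[4] * S[8] - S[5] * S[7])
               - S[1] * (S[3] * S[8] - S[5] * S[6])
               + S[2] * (S[3] * S[7] - S[4] * S[6]);
    if (std::fabs(det) < 1e-300) continue;
    double M[9];
    M[0] = (S[4] * S[8] - S[5] * S[7]) / det;
    M[1] = (S[2] * S[7] - S[1] * S[8]) / det;
    M[2] = (S[1] * S[5] - S[2] * S[4]) / det;
    M[3] = (S[5] * S[6] - S[3] * S[8]) / det;
    M[4] = (S[0] * S[8] - S[2] * S[6]) / det;
    M[5] = (S[2] * S[3] - S[0] * S[5]) / det;
    M[6] = (S[3] * S[7] - S[4] * S[6]) / det;
    M[7] = (S[1] * S[6] - S[0] * S[7]) / det;
    M[8] = (S[0] * S[4] - S[1] * S[3]) / det;
    double p[3] = {moved(i, 0), moved(i, 1), moved(i, 2)};
    double r[3] = {p[0] - tgt(j, 0), p[1] - tgt(j, 1), p[2] - tgt(j, 2)};
    // J (3x6): columns 0..2 = -[p]x, columns 3..5 = I
    double J[18] = {0,    p[2], -p[1], 0, 0, 0,
                    -p[2], 0,    p[0], 0, 0, 0,
                    p[1], -p[0], 0,    0, 0, 0};
    J[0 * 6 + 3] = 1; J[1 * 6 + 4] = 1; J[2 * 6 + 5] = 1;
    // MJ = M * J (3x6), then H += J' MJ, g += J' M r
    double MJ[18];
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 6; ++b) {
        double s = 0;
        for (int c = 0; c < 3; ++c) s += M[3 * a + c] * J[6 * c + b];
        MJ[6 * a + b] = s;
      }
    for (int a = 0; a < 6; ++a) {
      for (int b = 0; b < 6; ++b) {
        double s = 0;
        for (int c = 0; c < 3; ++c) s += J[6 * c + a] * MJ[6 * c + b];
        H[6 * a + b] += s;
      }
      double s = 0;
      for (int c = 0; c < 3; ++c)
        s += J[6 * c + a] * (M[3 * c] * r[0] + M[3 * c + 1] * r[1] +
                             M[3 * c + 2] * r[2]);
      g[a] += s;
    }
    cost += r[0] * (M[0] * r[0] + M[1] * r[1] + M[2] * r[2]) +
            r[1] * (M[3] * r[0] + M[4] * r[1] + M[5] * r[2]) +
            r[2] * (M[6] * r[0] + M[7] * r[1] + M[8] * r[2]);
  }
  NumericMatrix Hout(6, 6);
  NumericVector gout(6);
  for (int a = 0; a < 6; ++a) {
    gout[a] = g[a];
    for (int b = 0; b < 6; ++b) Hout(a, b) = H[6 * a + b];
  }
  return List::create(_["H"] = Hout, _["g"] = gout, _["cost"] = cost);
}
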