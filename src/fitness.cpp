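// Forward kinematics of one arm chain and batched CBPSO fitness evaluation.
// Mirrors the R reference implementation in R/rigid_model.R; equality of the
// two paths is asserted in the test suite.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Mat3 { double m[9]; };  // column-major like R

inline Mat3 mult(const Mat3 &a, const Mat3 &b) {
  Mat3 r;
  for (int j = 0; j < 3; ++j)
    for (int i = 0; i < 3; ++i)
      r.m[i + 3 * j] = a.m[i] * b.m[3 * j] + a.m[i + 3] * b.m[1 + 3 * j] +
                       a.m[i + 6] * b.m[2 + 3 * j];
  return r;
}

inline void apply(const Mat3 &a, const double v[3], double out[3]) {
  for (int i = 0; i < 3; ++i)
    out[i] = a.m[i] * v[0] + a.m[i + 3] * v[1] + a.m[i + 6] * v[2];
}

inline Mat3 rotx(double t) {
  double c = std::cos(t), s = std::sin(t);
  Mat3 r = {{1, 0, 0, 0, c, s, 0, -s, c}};
  return r;
}
inline Mat3 roty(double t) {
  double c = std::cos(t), s = std::sin(t);
  Mat3 r = {{c, 0, -s, 0, 1, 0, s, 0, c}};
  return r;
}
inline Mat3 rotz(double t) {
  double c = std::cos(t), s = std::sin(t);
  Mat3 r = {{c, s, 0, -s, c, 0, 0, 0, 1}};
  return r;
}

// markers[5][3]: SHO, ELB, WRI, HAN, TIP in the torso frame.
// angles: sc_fb, sc_ud, sh_x, sh_y, sh_z, elb_x, wr_x, wr_z, hand_x (rad)
void arm_chain(const double *a, const double *L, bool right,
               double markers[5][3]) {
  double s = right ? 1.0 : -1.0;
  Mat3 R_sc = mult(rotz(s * a[1]), roty(s * a[0]));
  double off[3] = {s * L[0], 0, 0};
  apply(R_sc, off, markers[0]);
  Mat3 R_sh = mult(mult(mult(R_sc, rotx(-a[2])), roty(s * a[3])),
                   rotz(s * a[4]));
  double seg[3] = {0, -L[1], 0}, d[3];
  apply(R_sh, seg, d);
  for (int i = 0; i < 3; ++i) markers[1][i] = markers[0][i] + d[i];
  Mat3 R_el = mult(R_sh, rotx(-a[5]));
  seg[1] = -L[2];
  apply(R_el, seg, d);
  for (int i = 0; i < 3; ++i) markers[2][i] = markers[1][i] + d[i];
  Mat3 R_wr = mult(mult(R_el, rotx(-a[6])), rotz(s * a[7]));
  seg[1] = -L[3];
  apply(R_wr, seg, d);
  for (int i = 0; i < 3; ++i) markers[3][i] = markers[2][i] + d[i];
  Mat3 R_ha = mult(R_wr, rotx(-a[8]));
  seg[1] = -L[4];
  apply(R_ha, seg, d);
  for (int i = 0; i < 3; ++i) markers[4][i] = markers[3][i] + d[i];
}

// scapulohumeral rhythm (degrees in, degrees out)
inline double rhythm_fb(double beta) {
  if (beta < 0) return -0.35 * beta;
  if (beta <= 70) return 0.0;
  return -0.22 * beta + 15.4;
}
inline double rhythm_ud(double beta) {
  if (beta < 0) return -0.3 * beta;
  if (beta <= 30) return 0.0;
  return 0.36 * beta - 10.8;
}

}  // namespace

// [[Rcpp::export(name = ".fk_arm_cpp")]]
NumericMatrix fk_arm_cpp(NumericVector angles, NumericVector lengths,
                         bool right) {
  double markers[5][3];
  arm_chain(REAL(angles), REAL(lengths), right, markers);
  NumericMatrix out(5, 3);
  for (int i = 0; i < 5; ++i)
    for (int j = 0; j < 3; ++j) out(i, j) = markers[i][j];
  return out;
}

// X: N x 9 candidate angle vectors; Y: 5 x 3 observed markers (torso frame);
// w: per-marker weights (0 = excluded).  Returns the weighted squared marker
// distance plus the soft scapulohumeral-rhythm prior.
// [[Rcpp::export(name = ".fitness_batch_cpp")]]
NumericVector fitness_batch_cpp(NumericMatrix X, NumericMatrix Y,
                                NumericVector w, NumericVector lengths,
                                bool right, double rhythm_weight) {
  int n = X.nrow();
  NumericVector out(n);
  double markers[5][3];
  const double rad2deg = 57.29577951308232, deg2rad = 1.0 / rad2deg;
  for (int p = 0; p < n; ++p) {
    double a[9];
    for (int k = 0; k < 9; ++k) a[k] = X(p, k);
    arm_chain(a, REAL(lengths), right, markers);
    double f = 0.0;
    for (int j = 0; j < 5; ++j) {
      if (w[j] <= 0) continue;
      double d0 = Y(j, 0) - markers[j][0];
      double d1 = Y(j, 1) - markers[j][1];
      double d2 = Y(j, 2) - markers[j][2];
      f += w[j] * (d0 * d0 + d1 * d1 + d2 * d2);
    }
    if (rhythm_weight > 0) {
      double beta = a[4] * rad2deg;
      double dfb = a[0] - rhythm_fb(beta) * deg2rad;
      double dud = a[1] - rhythm_ud(beta) * deg2rad;
      f += rhythm_weight * (dfb * dfb + dud * dud);
    }
    out[p] = f;
  }
  return out;
}
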