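#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Piecewise-linear interpolation of a periodic waveform with knots V at
// times t (strictly increasing), period T. Times are wrapped into
// [t_1, t_1 + T); between t_M and t_1 + T the segment joins V_M to V_1.

struct Seg { int k1, k2; double a2; }; // value = (1-a2)*V[k1] + a2*V[k2]

static inline Seg locate(double tq, const double* t, int M, double T) {
  double d = tq - t[0];
  double s = d - T * std::floor(d / T);
  if (s < 0) s += T;
  if (s >= T) s -= T;
  double u = t[0] + s;
  Seg sg;
  if (u >= t[M - 1]) {
    double gap = t[0] + T - t[M - 1];
    sg.k1 = M - 1; sg.k2 = 0;
    sg.a2 = gap > 0 ? (u - t[M - 1]) / gap : 0.0;
  } else {
    int j = 0;
    while (j < M - 2 && u >= t[j + 1]) ++j;
    sg.k1 = j; sg.k2 = j + 1;
    sg.a2 = (u - t[j]) / (t[j + 1] - t[j]);
  }
  return sg;
}

// [[Rcpp::export]]
NumericVector cpp_interp_periodic(NumericVector tq, NumericVector V,
                                  NumericVector t, double T) {
  int M = V.size();
  NumericVector out(tq.size());
  for (R_xlen_t i = 0; i < tq.size(); ++i) {
    Seg s = locate(tq[i], t.begin(), M, T);
    out[i] = (1.0 - s.a2) * V[s.k1] + s.a2 * V[s.k2];
  }
  return out;
}

// Weighted sum-of-squares objective:
//   sum_i W_i sum_j ( Vtilde(t_j - r_i / pwv) - v_ij )^2
// vmat is N x M (row i = waveform of cross-section i), r in meters,
// pwv in m/s, t in seconds.
// [[Rcpp::export]]
double cpp_pwv_objective(double pwv, NumericVector V, NumericVector t, double T,
                         NumericMatrix vmat, NumericVector r, NumericVector w) {
  int N = vmat.nrow(), M = vmat.ncol();
  double obj = 0.0;
  for (int i = 0; i < N; ++i) {
    double d = r[i] / pwv;
    double acc = 0.0;
    for (int j = 0; j < M; ++j) {
      Seg s = locate(t[j] - d, t.begin(), M, T);
      double pred = (1.0 - s.a2) * V[s.k1] + s.a2 * V[s.k2];
      double e = pred - vmat(i, j);
      acc += e * e;
    }
    obj += w[i] * acc;
  }
  return obj;
}

// For fixed pwv the objective is quadratic in V: accumulate the normal
// equations (X' W X) V = X' W y over all (i, j) residuals, where each row of
// X has at most two nonzero interpolation weights.
// [[Rcpp::export]]
List cpp_profile_normal_eq(double pwv, NumericVector t, double T,
                           NumericMatrix vmat, NumericVector r, NumericVector w) {
  int N = vmat.nrow(), M = vmat.ncol();
  NumericMatrix A(M, M);
  NumericVector b(M);
  for (int i = 0; i < N; ++i) {
    double d = r[i] / pwv;
    double wi = w[i];
    for (int j = 0; j < M; ++j) {
      Seg s = locate(t[j] - d, t.begin(), M, T);
      double a1 = 1.0 - s.a2, a2 = s.a2;
      double y = vmat(i, j);
      A(s.k1, s.k1) += wi * a1 * a1;
      A(s.k2, s.k2) += wi * a2 * a2;
      A(s.k1, s.k2) += wi * a1 * a2;
      A(s.k2, s.k1) += wi * a1 * a2;
      b[s.k1] += wi * a1 * y;
      b[s.k2] += wi * a2 * y;
    }
  }
  return List::create(_["xtwx"] = A, _["xtwy"] = b);
}
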