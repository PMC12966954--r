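// Per-axis Kalman filter and RTS smoother for the state-space form of the
// continuous-time movement processes.  The state dimension d is 1 (position)
// or 2 (position, velocity); the observation is the position plus white noise
// of variance R.  Several observation series (x axis, y axis, and a constant
// series used for GLS mean profiling) share one set of transition matrices
// and hence one innovation-variance sequence.
//
// Transition matrices Phi and noise covariances Q are computed in R by
// transition() and passed as d*d*n arrays (block i holds the step from time
// i-1 to time i; block 0 is unused).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline void inv2(const double* P, double* Pi, int d) {
  if (d == 1) {
    double v = P[0];
    if (v <= 0) v = 1e-300;
    Pi[0] = 1.0 / v;
    return;
  }
  double a = P[0], b = P[1], c = P[2], e = P[3];
  double det = a * e - b * c;
  double scale = std::fabs(a) + std::fabs(e);
  if (det <= 1e-14 * scale * scale || det <= 0) {
    // near-singular one-step prediction (e.g. exact observations with a tiny
    // time step): regularize before inverting
    double jit = 1e-12 * (scale > 0 ? scale : 1.0);
    a += jit; e += jit;
    det = a * e - b * c;
    if (det <= 0) det = 1e-300;
  }
  Pi[0] = e / det; Pi[1] = -b / det; Pi[2] = -c / det; Pi[3] = a / det;
}

// [[Rcpp::export]]
List kalman_cpp(NumericMatrix Z, LogicalVector obsflag, NumericVector Phis,
                NumericVector Qs, double R, NumericMatrix P0, bool diffuse,
                bool smooth, int d) {
  const int n = Z.nrow(), m = Z.ncol(), dd = d * d;
  NumericMatrix E(n, m);
  NumericVector S(n);
  std::vector<double> xf(n * d * m), Pf(n * dd), xp(n * d * m), Pp(n * dd);

  std::vector<double> x(d * m, 0.0), P(dd);
  for (int i = 0; i < dd; ++i) P[i] = P0[i];
  if (diffuse) {
    if (!obsflag[0]) stop("diffuse initialization requires an observation at the first time");
    for (int j = 0; j < m; ++j) x[0 + d * j] = Z(0, j);
    P[0] = R;
    if (d == 2) { P[1] = 0.0; P[2] = 0.0; }
  }

  std::vector<double> xn(d * m), Pn(dd), K(d);

  for (int i = 0; i < n; ++i) {
    if (i > 0) {
      const double* Phi = &Phis[(size_t)i * dd];
      const double* Q = &Qs[(size_t)i * dd];
      // x <- Phi x ; P <- Phi P Phi' + Q
      for (int j = 0; j < m; ++j) {
        for (int r = 0; r < d; ++r) {
          double s = 0;
          for (int c = 0; c < d; ++c) s += Phi[r + d * c] * x[c + d * j];
          xn[r + d * j] = s;
        }
      }
      // tmp = Phi P
      double tmp[4];
      for (int r = 0; r < d; ++r)
        for (int c = 0; c < d; ++c) {
          double s = 0;
          for (int k = 0; k < d; ++k) s += Phi[r + d * k] * P[k + d * c];
          tmp[r + d * c] = s;
        }
      for (int r = 0; r < d; ++r)
        for (int c = 0; c < d; ++c) {
          double s = Q[r + d * c];
          for (int k = 0; k < d; ++k) s += tmp[r + d * k] * Phi[c + d * k];
          Pn[r + d * c] = s;
        }
      // symmetrize
      if (d == 2) { double o = 0.5 * (Pn[1] + Pn[2]); Pn[1] = o; Pn[2] = o; }
      for (int j = 0; j < d * m; ++j) x[j] = xn[j];
      for (int j = 0; j < dd; ++j) P[j] = Pn[j];
    }
    // store predictions
    for (int j = 0; j < d * m; ++j) xp[(size_t)i * d * m + j] = x[j];
    for (int j = 0; j < dd; ++j) Pp[(size_t)i * dd + j] = P[j];

    double Si = P[0] + R;
    if (Si < 1e-300) Si = 1e-300;
    S[i] = Si;

    if (obsflag[i] && !(diffuse && i == 0)) {
      for (int r = 0; r < d; ++r) K[r] = P[r] / Si;  // P[, position] / S
      for (int j = 0; j < m; ++j) {
        double e = Z(i, j) - x[0 + d * j];
        E(i, j) = e;
        for (int r = 0; r < d; ++r) x[r + d * j] += K[r] * e;
      }
      // P <- P - K * P[position, ]
      double Prow[2];
      for (int c = 0; c < d; ++c) Prow[c] = P[0 + d * c];
      for (int r = 0; r < d; ++r)
        for (int c = 0; c < d; ++c) P[r + d * c] -= K[r] * Prow[c];
      if (d == 2) { double o = 0.5 * (P[1] + P[2]); P[1] = o; P[2] = o; }
      for (int r = 0; r < d; ++r)
        if (P[r + d * r] < 0) P[r + d * r] = 0;
    } else {
      E(i, 0) = NA_REAL;  // row not scored
      if (diffuse && i == 0) {
        for (int j = 1; j < m; ++j) E(i, j) = NA_REAL;
      } else {
        for (int j = 1; j < m; ++j) E(i, j) = NA_REAL;
      }
    }
    for (int j = 0; j < d * m; ++j) xf[(size_t)i * d * m + j] = x[j];
    for (int j = 0; j < dd; ++j) Pf[(size_t)i * dd + j] = P[j];
  }

  List out = List::create(Named("E") = E, Named("S") = S);

  if (smooth) {
    NumericMatrix xs(n, m);
    NumericVector vs(n);
    std::vector<double> xsm(d * m), Psm(dd);
    // init at last time
    for (int j = 0; j < d * m; ++j) xsm[j] = xf[(size_t)(n - 1) * d * m + j];
    for (int j = 0; j < dd; ++j) Psm[j] = Pf[(size_t)(n - 1) * dd + j];
    for (int j = 0; j < m; ++j) xs(n - 1, j) = xsm[0 + d * j];
    vs[n - 1] = Psm[0];
    double Ppi[4], C[4], tmp[4];
    for (int i = n - 2; i >= 0; --i) {
      const double* Phi = &Phis[(size_t)(i + 1) * dd];
      const double* Pfi = &Pf[(size_t)i * dd];
      const double* Ppi1 = &Pp[(size_t)(i + 1) * dd];
      inv2(Ppi1, Ppi, d);
      // C = Pf[i] Phi' inv(Pp[i+1])
      for (int r = 0; r < d; ++r)
        for (int c = 0; c < d; ++c) {
          double s = 0;
          for (int k = 0; k < d; ++k) s += Pfi[r + d * k] * Phi[c + d * k];
          tmp[r + d * c] = s;
        }
      for (int r = 0; r < d; ++r)
        for (int c = 0; c < d; ++c) {
          double s = 0;
          for (int k = 0; k < d; ++k) s += tmp[r + d * k] * Ppi[k + d * c];
          C[r + d * c] = s;
        }
      // x_s = x_f + C (x_s(next) - x_p(next))
      for (int j = 0; j < m; ++j) {
        double dx[2];
        for (int r = 0; r < d; ++r)
          dx[r] = xsm[r + d * j] - xp[(size_t)(i + 1) * d * m + r + d * j];
        for (int r = 0; r < d; ++r) {
          double s = xf[(size_t)i * d * m + r + d * j];
          for (int k = 0; k < d; ++k) s += C[r + d * k] * dx[k];
          xn[r + d * j] = s;
        }
      }
      // P_s = P_f + C (P_s(next) - P_p(next)) C'
      double dP[4], t2[4];
      for (int j = 0; j < dd; ++j) dP[j] = Psm[j] - Ppi1[j];
      for (int r = 0; r < d; ++r)
        for (int c = 0; c < d; ++c) {
          double s = 0;
          for (int k = 0; k < d; ++k) s += C[r + d * k] * dP[k + d * c];
          t2[r + d * c] = s;
        }
      for (int r = 0; r < d; ++r)
        for (int c = 0; c < d; ++c) {
          double s = Pfi[r + d * c];
          for (int k = 0; k < d; ++k) s += t2[r + d * k] * C[c + d * k];
          Pn[r + d * c] = s;
        }
      if (d == 2) { double o = 0.5 * (Pn[1] + Pn[2]); Pn[1] = o; Pn[2] = o; }
      for (int r = 0; r < d; ++r)
        if (Pn[r + d * r] < 0) Pn[r + d * r] = 0;
      for (int j = 0; j < d * m; ++j) xsm[j] = xn[j];
      for (int j = 0; j < dd; ++j) Psm[j] = Pn[j];
      for (int j = 0; j < m; ++j) xs(i, j) = xsm[0 + d * j];
      vs[i] = Psm[0];
    }
    out["xs"] = xs;
    out["vs"] = vs;
  }
  return out;
}
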