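// Fixed-step fourth-order Runge-Kutta integration of the coupled neuronal
// (bilinear/non-linear) and balloon-Windkessel haemodynamic state equations,
// with sparse sampling of the predicted BOLD signal at acquisition times.
//
// State per region: neuronal activity x, vasodilatory signal s, normalized
// flow f, normalized venous volume v, normalized deoxyhaemoglobin q.
//   dx = (A + u B + sum_j x_j D_j) x + C u
//   ds = eps * x - kappa * s - gamma * (f - 1)
//   df = s
//   dv = (f - v^(1/alpha)) / tau
//   dq = (f * (1 - (1-rho)^(1/f)) / rho - v^(1/alpha) * q / v) / tau
//   BOLD = V0 * (k1 (1 - q) + k2 (1 - q/v) + k3 (1 - v)),
//   k1 = 7 rho, k2 = 2, k3 = 2 rho - 0.2.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct DcmSystem {
  int n;
  const double *A;         // n x n, column-major
  const double *B;         // n x n or NULL
  const double *C;         // n (single input)
  const double *D;         // n x n x n (D[, , j] gates by region j) or NULL
  const double *kappa, *gamma_, *tau, *alpha, *rho, *eps;
  bool has_b, has_d;

  // y layout: [x | s | f | v | q], each length n
  inline bool deriv(const double *y, double u, double *dy) const {
    const double *x = y, *s = y + n, *f = y + 2 * n, *v = y + 3 * n,
                 *q = y + 4 * n;
    double *dx = dy, *ds = dy + n, *df = dy + 2 * n, *dv = dy + 3 * n,
           *dq = dy + 4 * n;
    for (int i = 0; i < n; ++i) {
      double acc = C[i] * u;
      for (int j = 0; j < n; ++j) {
        double aij = A[i + j * n];
        if (has_b) aij += u * B[i + j * n];
        if (has_d) {
          for (int k = 0; k < n; ++k) aij += x[k] * D[i + j * n + k * n * n];
        }
        acc += aij * x[j];
      }
      dx[i] = acc;
    }
    for (int i = 0; i < n; ++i) {
      if (!(f[i] > 1e-8 && v[i] > 1e-8 && q[i] > 1e-8)) return false;
      ds[i] = eps[i] * x[i] - kappa[i] * s[i] - gamma_[i] * (f[i] - 1.0);
      df[i] = s[i];
      double fv = std::exp(std::log(v[i]) / alpha[i]);  // v^(1/alpha)
      dv[i] = (f[i] - fv) / tau[i];
      double E = 1.0 - std::exp(std::log1p(-rho[i]) / f[i]);  // 1-(1-rho)^(1/f)
      dq[i] = (f[i] * E / rho[i] - fv * q[i] / v[i]) / tau[i];
    }
    return true;
  }

  inline void bold(const double *y, double V0, double *out) const {
    const double *v = y + 3 * n, *q = y + 4 * n;
    for (int i = 0; i < n; ++i) {
      double k1 = 7.0 * rho[i], k2 = 2.0, k3 = 2.0 * rho[i] - 0.2;
      out[i] = V0 * (k1 * (1.0 - q[i]) + k2 * (1.0 - q[i] / v[i]) +
                     k3 * (1.0 - v[i]));
    }
  }
};

// boxcar input with a monotone cursor (RK4 evaluates t non-decreasingly)
struct Boxcar {
  const double *onset, *dur;
  int nstim, idx;
  Boxcar(const double *o, const double *d, int ns)
      : onset(o), dur(d), nstim(ns), idx(0) {}
  inline double operator()(double t) {
    while (idx < nstim && t >= onset[idx] + dur[idx]) ++idx;
    return (idx < nstim && t >= onset[idx]) ? 1.0 : 0.0;
  }
};

// [[Rcpp::export]]
List integrate_dcm_cpp(NumericMatrix A, Nullable<NumericMatrix> B,
                       NumericVector C, Nullable<NumericVector> D,
                       NumericVector kappa, NumericVector gamma_,
                       NumericVector tau, NumericVector alpha,
                       NumericVector rho, NumericVector eps, double V0,
                       NumericVector stim_onsets, NumericVector stim_durations,
                       double dt, double duration, NumericVector sample_times,
                       bool return_fine) {
  const int n = A.nrow();
  const int nsteps = (int)std::ceil(duration / dt - 1e-9);
  const int nsamp = sample_times.size();

  NumericMatrix Bm;
  NumericVector Dv;
  DcmSystem sys;
  sys.n = n;
  sys.A = REAL(A);
  sys.has_b = B.isNotNull();
  if (sys.has_b) { Bm = B.get(); sys.B = REAL(Bm); } else sys.B = nullptr;
  sys.C = REAL(C);
  sys.has_d = D.isNotNull();
  if (sys.has_d) { Dv = D.get(); sys.D = REAL(Dv); } else sys.D = nullptr;
  sys.kappa = REAL(kappa); sys.gamma_ = REAL(gamma_); sys.tau = REAL(tau);
  sys.alpha = REAL(alpha); sys.rho = REAL(rho); sys.eps = REAL(eps);

  const int dim = 5 * n;
  std::vector<double> y(dim, 0.0), k1(dim), k2(dim), k3(dim), k4(dim),
      tmp(dim), bold_prev(n), bold_cur(n);
  for (int i = 0; i < n; ++i) { y[2 * n + i] = 1.0; y[3 * n + i] = 1.0; y[4 * n + i] = 1.0; }

  NumericMatrix fine;
  NumericVector fine_t;
  if (return_fine) {
    fine = NumericMatrix(n, nsteps + 1);
    fine_t = NumericVector(nsteps + 1);
  }
  NumericMatrix samples(n, nsamp);
  std::fill(samples.begin(), samples.end(), NA_REAL);

  Boxcar u(REAL(stim_onsets), REAL(stim_durations), stim_onsets.size());
  bool diverged = false;

  sys.bold(y.data(), V0, bold_prev.data());
  if (return_fine) {
    for (int i = 0; i < n; ++i) fine(i, 0) = bold_prev[i];
    fine_t[0] = 0.0;
  }
  int si = 0;
  // samples exactly at t = 0
  while (si < nsamp && sample_times[si] <= 0.0) {
    for (int i = 0; i < n; ++i) samples(i, si) = bold_prev[i];
    ++si;
  }

  for (int step = 0; step < nsteps && !diverged; ++step) {
    double t = step * dt;
    double u1 = u(t), u2 = u(t + 0.5 * dt), u4 = u(t + dt);
    bool ok = sys.deriv(y.data(), u1, k1.data());
    if (ok) {
      for (int i = 0; i < dim; ++i) tmp[i] = y[i] + 0.5 * dt * k1[i];
      ok = sys.deriv(tmp.data(), u2, k2.data());
    }
    if (ok) {
      for (int i = 0; i < dim; ++i) tmp[i] = y[i] + 0.5 * dt * k2[i];
      ok = sys.deriv(tmp.data(), u2, k3.data());
    }
    if (ok) {
      for (int i = 0; i < dim; ++i) tmp[i] = y[i] + dt * k3[i];
      ok = sys.deriv(tmp.data(), u4, k4.data());
    }
    if (ok) {
      for (int i = 0; i < dim; ++i) {
        y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
      }
      for (int i = 0; i < n && ok; ++i) {
        ok = std::isfinite(y[i]) && std::fabs(y[i]) < 1e4 &&
             y[2 * n + i] > 1e-8 && y[2 * n + i] < 1e6 &&
             y[3 * n + i] > 1e-8 && y[3 * n + i] < 1e6 &&
             y[4 * n + i] > 1e-8 && y[4 * n + i] < 1e6;
      }
    }
    if (!ok) { diverged = true; break; }

    double t_next = (step + 1) * dt;
    sys.bold(y.data(), V0, bold_cur.data());
    if (return_fine) {
      for (int i = 0; i < n; ++i) fine(i, step + 1) = bold_cur[i];
      fine_t[step + 1] = t_next;
    }
    while (si < nsamp && sample_times[si] <= t_next + 1e-9) {
      double w = (sample_times[si] - t) / dt;
      if (w < 0) w = 0;
      if (w > 1) w = 1;
      for (int i = 0; i < n; ++i) {
        samples(i, si) = (1.0 - w) * bold_prev[i] + w * bold_cur[i];
      }
      ++si;
    }
    std::swap(bold_prev, bold_cur);
  }

  List out = List::create(Named("samples") = samples,
                          Named("diverged") = diverged);
  if (return_fine) {
    out["fine"] = fine;
    out["time"] = fine_t;
  }
  return out;
}
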