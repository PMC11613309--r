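#include <Rcpp.h>
#include <array>
#include <vector>
using namespace Rcpp;

// Predator-prey vector field with forward sensitivity propagation.
//
// State u = (x, y); parameters p = (r, b, m, s). Sensitivities are carried
// w.r.t. the extended vector (r, b, m, s, x0, y0) as a 2 x 6 matrix S with
// S' = A(u) S + B(u), A = df/du, B = df/dp (init-condition columns of B are
// zero; S(0) has identity in the (x0, y0) block).
//
// response: 1 = linear (type I) feeding, 3 = sigmoidal (type III) feeding
// with prey searching time s.

static const int NPAR = 6;

struct LVDeriv {
  double f1, f2;        // dx/dt, dy/dt
  double A[2][2];       // Jacobian wrt state
  double B[2][NPAR];    // Jacobian wrt (r,b,m,s,x0,y0)
};

static inline void lv_rhs(double x, double y, double r, double b, double m,
                          double s, int response, bool sens, LVDeriv &out) {
  if (response == 1) {
    double g = b * x * y;
    out.f1 = r * x - g;
    out.f2 = g - m * y;
    if (sens) {
      out.A[0][0] = r - b * y; out.A[0][1] = -b * x;
      out.A[1][0] = b * y;     out.A[1][1] = b * x - m;
      out.B[0][0] = x;  out.B[0][1] = -x * y; out.B[0][2] = 0.0; out.B[0][3] = 0.0;
      out.B[1][0] = 0.0; out.B[1][1] = x * y; out.B[1][2] = -y;  out.B[1][3] = 0.0;
    }
  } else {
    double x2 = x * x;
    double q = 1.0 + s * x2;
    double g = b * x2 * y / q;
    out.f1 = r * x - g;
    out.f2 = g - m * y;
    if (sens) {
      double q2 = q * q;
      double dg_dx = 2.0 * b * x * y / q2;
      double dg_dy = b * x2 / q;
      double dg_db = x2 * y / q;
      double dg_ds = -b * x2 * x2 * y / q2;
      out.A[0][0] = r - dg_dx; out.A[0][1] = -dg_dy;
      out.A[1][0] = dg_dx;     out.A[1][1] = dg_dy - m;
      out.B[0][0] = x;   out.B[0][1] = -dg_db; out.B[0][2] = 0.0; out.B[0][3] = -dg_ds;
      out.B[1][0] = 0.0; out.B[1][1] = dg_db;  out.B[1][2] = -y;  out.B[1][3] = dg_ds;
    }
    if (sens) {
      for (int i = 0; i < 2; ++i) { out.B[i][4] = 0.0; out.B[i][5] = 0.0; }
    }
    return;
  }
  if (sens) {
    for (int i = 0; i < 2; ++i) { out.B[i][4] = 0.0; out.B[i][5] = 0.0; }
  }
}

// One augmented RHS evaluation: given (u, S) return (du, dS).
static inline void aug_rhs(const double u[2], const double S[2][NPAR],
                           double r, double b, double m, double s,
                           int response, bool sens,
                           double du[2], double dS[2][NPAR]) {
  LVDeriv d;
  lv_rhs(u[0], u[1], r, b, m, s, response, sens, d);
  du[0] = d.f1; du[1] = d.f2;
  if (sens) {
    for (int j = 0; j < NPAR; ++j) {
      dS[0][j] = d.A[0][0] * S[0][j] + d.A[0][1] * S[1][j] + d.B[0][j];
      dS[1][j] = d.A[1][0] * S[0][j] + d.A[1][1] * S[1][j] + d.B[1][j];
    }
  }
}

// [[Rcpp::export]]
List lv_integrate_cpp(double r, double b, double m, double s,
                      double x0, double y0, double horizon, double step,
                      int response, double h_internal, bool sens) {
  if (step <= 0.0) stop("step must be positive");
  int n_out = (int) std::lround(horizon / step);
  if (std::fabs(n_out * step - horizon) > 1e-8 * std::max(1.0, horizon))
    stop("horizon must be a multiple of step");
  int n_sub = std::max(1, (int) std::lround(step / h_internal));
  double h = step / n_sub;

  NumericVector times(n_out + 1), xs(n_out + 1), ys(n_out + 1);
  NumericMatrix Sx, Sy;
  if (sens) { Sx = NumericMatrix(n_out + 1, NPAR); Sy = NumericMatrix(n_out + 1, NPAR); }

  double u[2] = {x0, y0};
  double S[2][NPAR];
  for (int i = 0; i < 2; ++i)
    for (int j = 0; j < NPAR; ++j) S[i][j] = 0.0;
  S[0][4] = 1.0; S[1][5] = 1.0;

  times[0] = 0.0; xs[0] = x0; ys[0] = y0;
  if (sens)
    for (int j = 0; j < NPAR; ++j) { Sx(0, j) = S[0][j]; Sy(0, j) = S[1][j]; }

  double k1u[2], k2u[2], k3u[2], k4u[2];
  double k1S[2][NPAR], k2S[2][NPAR], k3S[2][NPAR], k4S[2][NPAR];
  double ut[2], St[2][NPAR];

  for (int i = 1; i <= n_out; ++i) {
    for (int sub = 0; sub < n_sub; ++sub) {
      aug_rhs(u, S, r, b, m, s, response, sens, k1u, k1S);
      for (int c = 0; c < 2; ++c) ut[c] = u[c] + 0.5 * h * k1u[c];
      if (sens) for (int c = 0; c < 2; ++c) for (int j = 0; j < NPAR; ++j)
        St[c][j] = S[c][j] + 0.5 * h * k1S[c][j];
      aug_rhs(ut, St, r, b, m, s, response, sens, k2u, k2S);
      for (int c = 0; c < 2; ++c) ut[c] = u[c] + 0.5 * h * k2u[c];
      if (sens) for (int c = 0; c < 2; ++c) for (int j = 0; j < NPAR; ++j)
        St[c][j] = S[c][j] + 0.5 * h * k2S[c][j];
      aug_rhs(ut, St, r, b, m, s, response, sens, k3u, k3S);
      for (int c = 0; c < 2; ++c) ut[c] = u[c] + h * k3u[c];
      if (sens) for (int c = 0; c < 2; ++c) for (int j = 0; j < NPAR; ++j)
        St[c][j] = S[c][j] + h * k3S[c][j];
      aug_rhs(ut, St, r, b, m, s, response, sens, k4u, k4S);
      for (int c = 0; c < 2; ++c)
        u[c] += h / 6.0 * (k1u[c] + 2.0 * k2u[c] + 2.0 * k3u[c] + k4u[c]);
      if (sens) for (int c = 0; c < 2; ++c) for (int j = 0; j < NPAR; ++j)
        S[c][j] += h / 6.0 * (k1S[c][j] + 2.0 * k2S[c][j] + 2.0 * k3S[c][j] + k4S[c][j]);
      if (!std::isfinite(u[0]) || !std::isfinite(u[1])) {
        double t_fail = (i - 1) * step + (sub + 1) * h;
        stop("non-finite state at t = %f during integration", t_fail);
      }
    }
    times[i] = i * step; xs[i] = u[0]; ys[i] = u[1];
    if (sens)
      for (int j = 0; j < NPAR; ++j) { Sx(i, j) = S[0][j]; Sy(i, j) = S[1][j]; }
  }

  List out = List::create(_["t"] = times, _["x"] = xs, _["y"] = ys);
  if (sens) { out["Sx"] = Sx; out["Sy"] = Sy; }
  return out;
}

// integrate and return prey density (and optionally its parameter
// sensitivities) at the requested 0-based output indices only
static bool lv_prey_at(double r, double b, double m, double s,
                       double x0, double y0, int n_out, int n_sub, double h,
                       int response, bool sens,
                       const std::vector<int> &idx,
                       std::vector<double> &prey,
                       std::vector<std::array<double, 4>> &grad) {
  double u[2] = {x0, y0};
  double S[2][NPAR];
  for (int i = 0; i < 2; ++i)
    for (int j = 0; j < NPAR; ++j) S[i][j] = 0.0;
  S[0][4] = 1.0; S[1][5] = 1.0;
  size_t next = 0;
  if (next < idx.size() && idx[next] == 0) {
    prey[next] = u[0];
    if (sens) for (int j = 0; j < 4; ++j) grad[next][j] = 0.0;
    ++next;
  }
  double k1u[2], k2u[2], k3u[2], k4u[2];
  double k1S[2][NPAR], k2S[2][NPAR], k3S[2][NPAR], k4S[2][NPAR];
  double ut[2], St[2][NPAR];
  for (int i = 1; i <= n_out && next < idx.size(); ++i) {
    for (int sub = 0; sub < n_sub; ++sub) {
      aug_rhs(u, S, r, b, m, s, response, sens, k1u, k1S);
      for (int c = 0; c < 2; ++c) ut[c] = u[c] + 0.5 * h * k1u[c];
      if (sens) for (int c = 0; c < 2; ++c) for (int j = 0; j < NPAR; ++j)
        St[c][j] = S[c][j] + 0.5 * h * k1S[c][j];
      aug_rhs(ut, St, r, b, m, s, response, sens, k2u, k2S);
      for (int c = 0; c < 2; ++c) ut[c] = u[c] + 0.5 * h * k2u[c];
      if (sens) for (int c = 0; c < 2; ++c) for (int j = 0; j < NPAR; ++j)
        St[c][j] = S[c][j] + 0.5 * h * k2S[c][j];
      aug_rhs(ut, St, r, b, m, s, response, sens, k3u, k3S);
      for (int c = 0; c < 2; ++c) ut[c] = u[c] + h * k3u[c];
      if (sens) for (int c = 0; c < 2; ++c) for (int j = 0; j < NPAR; ++j)
        St[c][j] = S[c][j] + h * k3S[c][j];
      aug_rhs(ut, St, r, b, m, s, response, sens, k4u, k4S);
      for (int c = 0; c < 2; ++c)
        u[c] += h / 6.0 * (k1u[c] + 2.0 * k2u[c] + 2.0 * k3u[c] + k4u[c]);
      if (sens) for (int c = 0; c < 2; ++c) for (int j = 0; j < NPAR; ++j)
        S[c][j] += h / 6.0 * (k1S[c][j] + 2.0 * k2S[c][j] + 2.0 * k3S[c][j] + k4S[c][j]);
      if (!std::isfinite(u[0]) || !std::isfinite(u[1])) return false;
    }
    if (next < idx.size() && idx[next] == i) {
      prey[next] = u[0];
      if (sens) for (int j = 0; j < 4; ++j) grad[next][j] = S[0][j];
      ++next;
    }
  }
  return true;
}

// Calibration loop for the predator-prey model: screen the supplied
// starting points by observation MSE, then plain gradient descent at a
// fixed learning rate with parameter clipping to the bounds.
// starts: n_starts x p matrix; idx: 0-based grid indices of observations.
// [[Rcpp::export]]
List lv_calibrate_cpp(NumericVector y, IntegerVector idx0,
                      NumericMatrix starts, NumericVector lower,
                      NumericVector upper, double x0, double y0,
                      double horizon, double step, int response,
                      double h_internal, int epochs, double lr) {
  int p = starts.ncol();           // 3 (type I) or 4 (type III)
  int n_obs = y.size();
  int n_out = (int) std::lround(horizon / step);
  int n_sub = std::max(1, (int) std::lround(step / h_internal));
  double h = step / n_sub;
  std::vector<int> idx(idx0.begin(), idx0.end());
  std::vector<double> prey(n_obs);
  std::vector<std::array<double, 4>> grad(n_obs);

  auto mse_of = [&](const double *th, bool sens) {
    double s = (p == 4) ? th[3] : 0.0;
    if (!lv_prey_at(th[0], th[1], th[2], s, x0, y0, n_out, n_sub, h,
                    response, sens, idx, prey, grad))
      return R_PosInf;
    double acc = 0.0;
    for (int i = 0; i < n_obs; ++i) {
      double r = prey[i] - y[i];
      acc += r * r;
    }
    return acc / n_obs;
  };

  // screen
  double best = R_PosInf;
  std::vector<double> theta(p);
  for (int i = 0; i < starts.nrow(); ++i) {
    std::vector<double> cand(p);
    for (int j = 0; j < p; ++j) cand[j] = starts(i, j);
    double l = mse_of(cand.data(), false);
    if (l < best) { best = l; theta = cand; }
  }
  std::vector<double> init = theta;

  // plain gradient descent with clipping
  NumericVector loss_curve(epochs);
  for (int e = 0; e < epochs; ++e) {
    double l = mse_of(theta.data(), true);
    loss_curve[e] = l;
    if (!std::isfinite(l)) stop("non-finite loss at step %d", e + 1);
    for (int j = 0; j < p; ++j) {
      double g = 0.0;
      for (int i = 0; i < n_obs; ++i)
        g += 2.0 * (prey[i] - y[i]) * grad[i][j] / n_obs;
      theta[j] -= lr * g;
      if (theta[j] < lower[j]) theta[j] = lower[j];
      if (theta[j] > upper[j]) theta[j] = upper[j];
    }
  }
  return List::create(_["params"] = NumericVector(theta.begin(), theta.end()),
                      _["init"] = NumericVector(init.begin(), init.end()),
                      _["loss_curve"] = loss_curve);
}
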