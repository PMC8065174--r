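#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Piecewise-linear schedule lookup: knot times `kt` (increasing, length k),
// per-neuron knot values `kv` (n x k). Constant extrapolation outside [kt0, ktK].
static inline void sched_eval(const NumericVector& kt, const NumericMatrix& kv,
                              double t, std::vector<double>& out) {
  int n = kv.nrow(), k = kt.size();
  if (k == 1) {
    for (int i = 0; i < n; ++i) out[i] = kv(i, 0);
    return;
  }
  if (t <= kt[0]) {
    for (int i = 0; i < n; ++i) out[i] = kv(i, 0);
    return;
  }
  if (t >= kt[k - 1]) {
    for (int i = 0; i < n; ++i) out[i] = kv(i, k - 1);
    return;
  }
  int hi = 1;
  while (kt[hi] < t) ++hi;
  double f = (t - kt[hi - 1]) / (kt[hi] - kt[hi - 1]);
  for (int i = 0; i < n; ++i)
    out[i] = kv(i, hi - 1) + f * (kv(i, hi) - kv(i, hi - 1));
}

struct CartesianSys {
  const NumericMatrix& J;
  double gamma, gammap, Jvw, Jwv;
  const NumericVector& pt; const NumericMatrix& pv;   // pump P(t) knots
  const NumericVector& bt; const NumericMatrix& bv;   // bias I_ext(t) knots
  bool coupled;
  int n;
  mutable std::vector<double> P, B;

  CartesianSys(const NumericMatrix& J_, double g, double gp, double jvw, double jwv,
               const NumericVector& pt_, const NumericMatrix& pv_,
               const NumericVector& bt_, const NumericMatrix& bv_, bool coupled_)
    : J(J_), gamma(g), gammap(gp), Jvw(jvw), Jwv(jwv),
      pt(pt_), pv(pv_), bt(bt_), bv(bv_), coupled(coupled_), n(pv_.nrow()),
      P(n), B(n) {}

  // state x = (v_1..v_n, w_1..w_n)
  void deriv(double t, const std::vector<double>& x, std::vector<double>& dx) const {
    sched_eval(pt, pv, t, P);
    sched_eval(bt, bv, t, B);
    for (int i = 0; i < n; ++i) {
      double v = x[i], w = x[n + i];
      double cv = 0.0, cw = 0.0;
      if (coupled) {
        for (int j = 0; j < n; ++j) {
          double Jij = J(i, j);
          if (Jij != 0.0) { cv += Jij * x[j]; cw += Jij * x[n + j]; }
        }
      }
      dx[i]     = P[i] * v - v * v * v + Jvw * w + gamma  * cv + B[i];
      dx[n + i] = P[i] * w - w * w * w + Jwv * v + gammap * cw;
    }
  }
};

struct PolarSys {
  // theta-R dynamics, uniform all-to-all coupling Jk, eps_ij = sqrt(Rj/Ri)
  double omega0, Jk, Rfloor;
  const NumericVector& pt; const NumericMatrix& pv;
  int n;
  mutable std::vector<double> P;

  PolarSys(double om, double jk, double rf,
           const NumericVector& pt_, const NumericMatrix& pv_)
    : omega0(om), Jk(jk), Rfloor(rf), pt(pt_), pv(pv_), n(pv_.nrow()), P(n) {}

  // state x = (theta_1..theta_n, R_1..R_n)
  void deriv(double t, const std::vector<double>& x, std::vector<double>& dx) const {
    sched_eval(pt, pv, t, P);
    for (int i = 0; i < n; ++i) {
      double th = x[i];
      double Ri = x[n + i] < Rfloor ? Rfloor : x[n + i];
      double ssin = 0.0, scos = 0.0;
      if (Jk != 0.0) {
        double sq = std::sqrt(Ri);
        for (int j = 0; j < n; ++j) {
          if (j == i) continue;
          double Rj = x[n + j] < Rfloor ? Rfloor : x[n + j];
          double eps = std::sqrt(Rj) / sq;
          double d = th - x[j];
          ssin += eps * std::sin(d);
          scos += eps * std::cos(d);
        }
      }
      dx[i] = omega0 - Jk * ssin + 0.25 * Ri * std::sin(4.0 * th);
      dx[n + i] = 2.0 * P[i] * Ri + 2.0 * Jk * Ri * scos
                - 0.5 * Ri * Ri * (std::cos(4.0 * th) + 3.0);
    }
  }
};

struct KuramotoSys {
  const NumericVector& omega;
  double Jk;
  int n;
  KuramotoSys(const NumericVector& om, double jk) : omega(om), Jk(jk), n(om.size()) {}
  void deriv(double, const std::vector<double>& x, std::vector<double>& dx) const {
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int j = 0; j < n; ++j) s += std::sin(x[i] - x[j]);
      dx[i] = omega[i] - Jk * s;
    }
  }
};

template <class Sys>
static List integrate_fixed(const Sys& sys, std::vector<double> x,
                            double dt, int nsteps, int stride, bool euler,
                            bool floor_second_half, double floorval) {
  int d = x.size();
  int nrec = nsteps / stride + 1;
  NumericVector times(nrec);
  NumericMatrix out(d, nrec);
  std::vector<double> k1(d), k2(d), k3(d), k4(d), tmp(d);

  int half = d / 2;
  auto apply_floor = [&](std::vector<double>& s) {
    if (!floor_second_half) return;
    for (int i = half; i < d; ++i) if (s[i] < floorval) s[i] = floorval;
  };
  apply_floor(x);

  int rec = 0;
  times[rec] = 0.0;
  for (int i = 0; i < d; ++i) out(i, rec) = x[i];
  ++rec;

  double t = 0.0;
  for (int s = 1; s <= nsteps; ++s) {
    if (euler) {
      sys.deriv(t, x, k1);
      for (int i = 0; i < d; ++i) x[i] += dt * k1[i];
    } else {
      sys.deriv(t, x, k1);
      for (int i = 0; i < d; ++i) tmp[i] = x[i] + 0.5 * dt * k1[i];
      sys.deriv(t + 0.5 * dt, tmp, k2);
      for (int i = 0; i < d; ++i) tmp[i] = x[i] + 0.5 * dt * k2[i];
      sys.deriv(t + 0.5 * dt, tmp, k3);
      for (int i = 0; i < d; ++i) tmp[i] = x[i] + dt * k3[i];
      sys.deriv(t + dt, tmp, k4);
      for (int i = 0; i < d; ++i)
        x[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    }
    apply_floor(x);
    t = s * dt;
    if (s % stride == 0) {
      for (int i = 0; i < d; ++i) {
        if (!std::isfinite(x[i]))
          stop("non-finite state at t = %f (step %d); reduce dt or check parameters",
               t, s);
        out(i, rec) = x[i];
      }
      times[rec] = t;
      ++rec;
    }
  }
  return List::create(_["times"] = times, _["state"] = out);
}

// [[Rcpp::export(name = ".sim_cartesian_cpp")]]
List sim_cartesian_cpp(NumericVector v0, NumericVector w0,
                       NumericMatrix J, double gamma, double gammap,
                       double Jvw, double Jwv,
                       NumericVector ptimes, NumericMatrix pvals,
                       NumericVector btimes, NumericMatrix bvals,
                       double dt, int nsteps, int stride, bool euler,
                       bool coupled) {
  int n = v0.size();
  std::vector<double> x(2 * n);
  for (int i = 0; i < n; ++i) { x[i] = v0[i]; x[n + i] = w0[i]; }
  CartesianSys sys(J, gamma, gammap, Jvw, Jwv, ptimes, pvals, btimes, bvals, coupled);
  return integrate_fixed(sys, x, dt, nsteps, stride, euler, false, 0.0);
}

// [[Rcpp::export(name = ".sim_polar_cpp")]]
List sim_polar_cpp(NumericVector theta0, NumericVector R0,
                   double omega0, double Jk,
                   NumericVector ptimes, NumericMatrix pvals,
                   double dt, int nsteps, int stride, bool euler,
                   double Rfloor) {
  int n = theta0.size();
  std::vector<double> x(2 * n);
  for (int i = 0; i < n; ++i) { x[i] = theta0[i]; x[n + i] = R0[i]; }
  PolarSys sys(omega0, Jk, Rfloor, ptimes, pvals);
  return integrate_fixed(sys, x, dt, nsteps, stride, euler, true, Rfloor);
}

// [[Rcpp::export(name = ".sim_kuramoto_cpp")]]
List sim_kuramoto_cpp(NumericVector theta0, NumericVector omegas, double Jk,
                      double dt, int nsteps, int stride, bool euler) {
  KuramotoSys sys(omegas, Jk);
  std::vector<double> x(theta0.begin(), theta0.end());
  // pad state so the generic recorder sees a flat vector; no floor applied
  List res = integrate_fixed(sys, x, dt, nsteps, stride, euler, false, 0.0);
  return res;
}
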