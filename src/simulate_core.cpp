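#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Fixed-step classical Runge-Kutta integrator for the six-stock monocyte /
// LPS / cytokine system with a discrete delay in TNF production, solved by
// the method of steps with a constant pre-history.
//
// State layout:  0 resting, 1 proinflammatory, 2 et, 3 lps, 4 tnf, 5 ccl2
// Parameter layout (canonical order, see R/parameters.R):
//  0 max_activation_rate  1 ac50                 2 hill_n
//  3 immunomodulation_rate 4 lps_removal_rate    5 max_tnf_synthesis_rate
//  6 sc50                 7 hill_m               8 tnf_delay_td
//  9 tnf_degradation_rate 10 ccl2_synth_resting  11 ccl2_synth_inflammatory
// 12 ccl2_synth_et        13 ccl2_degradation_rate
//
// The step h must divide the delay exactly so delayed values fall on stored
// nodes at full steps; half-step stage values use cubic Hermite
// interpolation between nodes (node derivatives are stored alongside).

static inline double hill(double L, double vmax, double c50, double k) {
  if (L <= 0.0) return 0.0;
  double Lk = std::pow(L, k);
  return vmax * Lk / (std::pow(c50, k) + Lk);
}

struct Sys {
  const double *p;
  explicit Sys(const double *prm) : p(prm) {}
  // dy/dt given current state y and the delayed proinflammatory stock
  inline void rhs(const double *y, double pdel, double *dy) const {
    double act = hill(y[3], p[0], p[1], p[2]);   // activation rate, /h
    double syn = hill(y[3], p[5], p[6], p[7]);   // TNF synthesis, pg/h/cell
    double activation = y[0] * act;
    double immunomod  = y[1] * p[3];
    dy[0] = -activation;
    dy[1] = activation - immunomod;
    dy[2] = immunomod;
    dy[3] = -y[3] * p[4];
    dy[4] = pdel * syn - y[4] * p[9];
    dy[5] = y[0] * p[10] + y[1] * p[11] + y[2] * p[12] - y[5] * p[13];
  }
};

// cubic Hermite on [0,1] with node values y0,y1 and scaled slopes m0,m1 (=h*f)
static inline double hermite(double theta, double y0, double y1,
                             double m0, double m1) {
  double t2 = theta * theta, t3 = t2 * theta;
  return (2 * t3 - 3 * t2 + 1) * y0 + (t3 - 2 * t2 + theta) * m0 +
         (-2 * t3 + 3 * t2) * y1 + (t3 - t2) * m1;
}

// [[Rcpp::export(name = ".simulate_core")]]
List simulate_core(NumericVector y0, NumericVector prm, double horizon,
                   double h, NumericVector out_times) {
  if (y0.size() != 6) stop("state vector must have length 6");
  if (prm.size() != 14) stop("parameter vector must have length 14");
  const double *p = REAL(prm);
  const double td = p[8];
  long k = (long)std::llround(td / h);
  if (td > 0 && std::fabs(k * h - td) > 1e-9 * std::max(1.0, td))
    stop("integration step must divide the TNF delay exactly");
  long n = (long)std::ceil(horizon / h - 1e-9);
  if (n < 1) n = 1;

  std::vector<double> Y((n + 1) * 6), F((n + 1) * 6);
  for (int j = 0; j < 6; ++j) Y[j] = y0[j];
  const double P0 = y0[1];
  Sys sys(p);

  // delayed proinflammatory stock at time s (s <= current node time)
  auto histP = [&](double s, long upto) -> double {
    if (s <= 1e-12) return P0;
    double u = s / h;
    long i = (long)std::floor(u + 1e-9);
    double theta = u - i;
    if (i > upto) i = upto;
    if (theta < 1e-9) return Y[i * 6 + 1];
    return hermite(theta, Y[i * 6 + 1], Y[(i + 1) * 6 + 1],
                   h * F[i * 6 + 1], h * F[(i + 1) * 6 + 1]);
  };

  double mins[6];
  for (int j = 0; j < 6; ++j) mins[j] = y0[j];

  double k1[6], k2[6], k3[6], k4[6], yt[6];
  for (long s = 0; s < n; ++s) {
    double t = s * h;
    double *y = &Y[s * 6];
    double *f = &F[s * 6];
    double pd1 = (k == 0) ? y[1] : histP(t - td, s);
    sys.rhs(y, pd1, f);                       // node derivative, stored
    for (int j = 0; j < 6; ++j) k1[j] = f[j];

    for (int j = 0; j < 6; ++j) yt[j] = y[j] + 0.5 * h * k1[j];
    double pd2 = (k == 0) ? yt[1] : histP(t + 0.5 * h - td, s);
    sys.rhs(yt, pd2, k2);

    for (int j = 0; j < 6; ++j) yt[j] = y[j] + 0.5 * h * k2[j];
    double pd3 = (k == 0) ? yt[1] : histP(t + 0.5 * h - td, s);
    sys.rhs(yt, pd3, k3);

    for (int j = 0; j < 6; ++j) yt[j] = y[j] + h * k3[j];
    double pd4 = (k == 0) ? yt[1] : histP(t + h - td, s);
    sys.rhs(yt, pd4, k4);

    double *yn = &Y[(s + 1) * 6];
    for (int j = 0; j < 6; ++j) {
      yn[j] = y[j] + h / 6.0 * (k1[j] + 2 * k2[j] + 2 * k3[j] + k4[j]);
      if (!std::isfinite(yn[j]))
        stop("non-finite state encountered at t = %.4f h", (s + 1) * h);
      if (yn[j] < mins[j]) mins[j] = yn[j];
    }
  }
  {
    // derivative at the final node (needed for output interpolation)
    double *y = &Y[n * 6];
    double pd = (k == 0) ? y[1] : histP(n * h - td, n - 1);
    sys.rhs(y, pd, &F[n * 6]);
  }

  R_xlen_t m = out_times.size();
  NumericMatrix out(m, 8);
  for (R_xlen_t r = 0; r < m; ++r) {
    double t = out_times[r];
    if (t < -1e-9 || t > n * h + 1e-9)
      stop("output time %.4f outside the integrated span", t);
    double u = t / h;
    long i = (long)std::floor(u + 1e-9);
    if (i > n) i = n;
    double theta = u - i;
    out(r, 0) = t;
    if (theta < 1e-9 || i >= n) {
      for (int j = 0; j < 6; ++j) out(r, 1 + j) = Y[i * 6 + j];
    } else {
      for (int j = 0; j < 6; ++j)
        out(r, 1 + j) = hermite(theta, Y[i * 6 + j], Y[(i + 1) * 6 + j],
                                h * F[i * 6 + j], h * F[(i + 1) * 6 + j]);
    }
    out(r, 7) = (k == 0) ? out(r, 2) : histP(t - td, n);
  }

  NumericVector minv(6);
  for (int j = 0; j < 6; ++j) minv[j] = mins[j];
  return List::create(_["states"] = out, _["min_state"] = minv);
}
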