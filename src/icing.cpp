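#include <Rcpp.h>
using namespace Rcpp;

// ICING glucose-insulin-nutrition model core.
//
// State y = (G, I, Q, P1, P2):
//   G  blood glucose            [mmol/L]
//   I  plasma insulin           [mU/L]
//   Q  interstitial insulin     [mU/L]
//   P1 stomach glucose          [mmol]
//   P2 gut glucose              [mmol]
//
// Parameter vector p (fixed order, see icing_params() on the R side):
//   0 p_G    1 alpha_G  2 EGP   3 CNS   4 V_G
//   5 n_I    6 n_C      7 n_K   8 n_L   9 alpha_I
//  10 x_L   11 V_I     12 d1   13 d2   14 P_max  15 u_en
//
// All rates are per minute; integration is fixed-step classical RK4 with
// piecewise-constant inputs held over each step (events are snapped to the
// step grid by the R wrappers, so hour-boundary SI switches and bolus
// administrations are exact).

static inline void icing_deriv(const double *y, const double *p,
                               double si, double enteral_mmol_min,
                               double uex_mU_min, double *dy) {
  const double G = y[0], I = y[1], Q = y[2], P1 = y[3], P2 = y[4];
  const double p_G = p[0], aG = p[1], EGP = p[2], CNS = p[3], VG = p[4];
  const double nI = p[5], nC = p[6], nK = p[7], nL = p[8], aI = p[9];
  const double xL = p[10], VI = p[11], d1 = p[12], d2 = p[13],
               Pmax = p[14], uen = p[15];

  const double P2out = std::min(d2 * P2, Pmax);  // saturable gut emptying
  dy[3] = -d1 * P1 + enteral_mmol_min;
  dy[4] = d1 * P1 - P2out;
  dy[0] = -p_G * G - si * G * Q / (1.0 + aG * Q)
          + (P2out + EGP - CNS) / VG;
  dy[1] = -nK * I - nL * I / (1.0 + aI * I) - nI * (I - Q)
          + (uex_mU_min + (1.0 - xL) * uen) / VI;
  dy[2] = nI * (I - Q) - nC * Q / (1.0 + aG * Q);
}

static inline void rk4_step(double *y, const double *p, double si,
                            double feed, double uex, double h) {
  double k1[5], k2[5], k3[5], k4[5], yt[5];
  icing_deriv(y, p, si, feed, uex, k1);
  for (int j = 0; j < 5; ++j) yt[j] = y[j] + 0.5 * h * k1[j];
  icing_deriv(yt, p, si, feed, uex, k2);
  for (int j = 0; j < 5; ++j) yt[j] = y[j] + 0.5 * h * k2[j];
  icing_deriv(yt, p, si, feed, uex, k3);
  for (int j = 0; j < 5; ++j) yt[j] = y[j] + h * k3[j];
  icing_deriv(yt, p, si, feed, uex, k4);
  for (int j = 0; j < 5; ++j) {
    y[j] += h / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
    if (y[j] < 0.0) y[j] = 0.0;  // compartments are non-negative
  }
}

// piecewise-constant lookup: value of the segment whose start time is the
// largest start <= t (times sorted ascending, first <= t assumed)
static inline double pw_lookup(double t, const NumericVector &tt,
                               const NumericVector &vv) {
  int n = tt.size();
  if (n == 0) return 0.0;
  int i = 0;
  while (i + 1 < n && tt[i + 1] <= t + 1e-9) ++i;
  return vv[i];
}

// [[Rcpp::export]]
NumericMatrix icing_simulate_cpp(NumericVector y0, double t0_h,
                                 double duration_h, double step_min,
                                 NumericVector si_t, NumericVector si_v,
                                 NumericVector ins_t, NumericVector ins_v,
                                 NumericVector feed_t, NumericVector feed_v,
                                 NumericVector bol_t, NumericVector bol_mU,
                                 NumericVector dex_t, NumericVector dex_mmol,
                                 NumericVector p, double out_dt_h) {
  const double h = step_min;                       // minutes
  const long nstep = (long)std::llround(duration_h * 60.0 / h);
  const long out_every = (long)std::llround(out_dt_h * 60.0 / h);
  if (out_every < 1) stop("out_dt_h smaller than the integration step");
  const long nout = nstep / out_every;
  const double VI = p[11];

  double y[5];
  for (int j = 0; j < 5; ++j) y[j] = y0[j];

  // pre-map impulse events to step indices
  std::vector<long> bol_idx(bol_t.size()), dex_idx(dex_t.size());
  for (int i = 0; i < bol_t.size(); ++i)
    bol_idx[i] = (long)std::llround((bol_t[i] - t0_h) * 60.0 / h);
  for (int i = 0; i < dex_t.size(); ++i)
    dex_idx[i] = (long)std::llround((dex_t[i] - t0_h) * 60.0 / h);

  NumericMatrix out(nout + 1, 6);
  auto record = [&](long row, double t_h) {
    out(row, 0) = t_h;
    for (int j = 0; j < 5; ++j) {
      if (!std::isfinite(y[j]))
        stop("non-finite model state at t = %f h", t_h);
      out(row, j + 1) = y[j];
    }
  };

  // impulses scheduled exactly at t0 apply before the first step
  for (size_t i = 0; i < bol_idx.size(); ++i)
    if (bol_idx[i] == 0) y[1] += bol_mU[i] / VI;
  for (size_t i = 0; i < dex_idx.size(); ++i)
    if (dex_idx[i] == 0) y[3] += dex_mmol[i];
  record(0, t0_h);

  long row = 1;
  for (long s = 0; s < nstep; ++s) {
    const double t_h = t0_h + s * h / 60.0;
    for (size_t i = 0; i < bol_idx.size(); ++i)
      if (bol_idx[i] == s && s > 0) y[1] += bol_mU[i] / VI;
    for (size_t i = 0; i < dex_idx.size(); ++i)
      if (dex_idx[i] == s && s > 0) y[3] += dex_mmol[i];

    const double si = pw_lookup(t_h, si_t, si_v);
    const double uex = pw_lookup(t_h, ins_t, ins_v) * 1000.0 / 60.0; // U/h -> mU/min
    const double feed = pw_lookup(t_h, feed_t, feed_v) / 60.0;       // mmol/h -> mmol/min
    rk4_step(y, REAL(p), si, feed, uex, h);

    if ((s + 1) % out_every == 0) record(row++, t0_h + (s + 1) * h / 60.0);
  }
  colnames(out) = CharacterVector::create("time_h", "G", "I", "Q", "P1", "P2");
  return out;
}

// Evaluate hourly BG for a batch of candidate treatments over one interval.
// Each candidate is (insulin U/h given as a bolus of that many U at the top
// of each hour, enteral feed mmol/h); two hour-wise SI paths are integrated
// per candidate. Returns hourly BG at hours 1..L for each path.
// [[Rcpp::export]]
List band_batch_cpp(NumericVector y0, NumericVector p,
                    NumericVector si_path_a, NumericVector si_path_b,
                    NumericVector insulin_U_h, NumericVector feed_mmol_h,
                    double step_min) {
  const int L = si_path_a.size();
  if (si_path_b.size() != L) stop("SI paths differ in length");
  const int nc = insulin_U_h.size();
  if (feed_mmol_h.size() != nc) stop("candidate vectors differ in length");
  const long steps_per_h = (long)std::llround(60.0 / step_min);
  const double h = step_min;
  const double VI = p[11];

  NumericMatrix bg_a(nc, L), bg_b(nc, L);
  for (int c = 0; c < nc; ++c) {
    for (int path = 0; path < 2; ++path) {
      const NumericVector &si = (path == 0) ? si_path_a : si_path_b;
      NumericMatrix &bg = (path == 0) ? bg_a : bg_b;
      double y[5];
      for (int j = 0; j < 5; ++j) y[j] = y0[j];
      const double feed = feed_mmol_h[c] / 60.0;
      for (int hr = 0; hr < L; ++hr) {
        y[1] += insulin_U_h[c] * 1000.0 / VI;   // hourly bolus
        for (long s = 0; s < steps_per_h; ++s)
          rk4_step(y, REAL(p), si[hr], feed, 0.0, h);
        if (!std::isfinite(y[0]))
          stop("non-finite model state in candidate evaluation");
        bg(c, hr) = y[0];
      }
    }
  }
  return List::create(_["bg_a"] = bg_a, _["bg_b"] = bg_b);
}

// Kernel weights of the conditional P(y | x = logx): w_i proportional to
// phi(logx; cx_i, sx_i^2) / px_i, normalised to sum 1.
// [[Rcpp::export]]
NumericVector kde_cond_weights_cpp(double logx, NumericVector cx,
                                   NumericVector sx, NumericVector px) {
  const int n = cx.size();
  NumericVector w(n);
  double mx = R_NegInf;
  for (int i = 0; i < n; ++i) {
    const double z = (logx - cx[i]) / sx[i];
    w[i] = -0.5 * z * z - std::log(sx[i]) - std::log(px[i]);
    if (w[i] > mx) mx = w[i];
  }
  double tot = 0.0;
  for (int i = 0; i < n; ++i) { w[i] = std::exp(w[i] - mx); tot += w[i]; }
  for (int i = 0; i < n; ++i) w[i] /= tot;
  return w;
}

// Conditional CDF of the transition kernel mixture on a grid of log-SI
// values. lo is the lower support bound in log space (-Inf for the full
// line); py are the per-kernel positive-domain normalisers.
// [[Rcpp::export]]
NumericVector kde_cond_cdf_cpp(double logx, NumericVector grid,
                               NumericVector cx, NumericVector cy,
                               NumericVector sx, NumericVector sy,
                               NumericVector px, NumericVector py,
                               double lo) {
  const int n = cx.size(), m = grid.size();
  NumericVector w = kde_cond_weights_cpp(logx, cx, sx, px);
  // prune negligible kernels
  double wmax = 0.0;
  for (int i = 0; i < n; ++i) if (w[i] > wmax) wmax = w[i];
  std::vector<int> keep;
  keep.reserve(n);
  for (int i = 0; i < n; ++i) if (w[i] > wmax * 1e-14) keep.push_back(i);

  NumericVector cdf(m);
  for (size_t k = 0; k < keep.size(); ++k) {
    const int i = keep[k];
    const double plo = std::isfinite(lo)
      ? R::pnorm(lo, cy[i], sy[i], 1, 0) : 0.0;
    const double wi = w[i] / py[i];
    for (int g = 0; g < m; ++g)
      cdf[g] += wi * (R::pnorm(grid[g], cy[i], sy[i], 1, 0) - plo);
  }
  return cdf;
}

// Conditional density P(y = grid | x = logx) in log-SI coordinates.
// [[Rcpp::export]]
NumericVector kde_cond_density_cpp(double logx, NumericVector grid,
                                   NumericVector cx, NumericVector cy,
                                   NumericVector sx, NumericVector sy,
                                   NumericVector px, NumericVector py) {
  const int n = cx.size(), m = grid.size();
  NumericVector w = kde_cond_weights_cpp(logx, cx, sx, px);
  NumericVector dens(m);
  for (int i = 0; i < n; ++i) {
    const double wi = w[i] / py[i];
    if (wi < 1e-300) continue;
    for (int g = 0; g < m; ++g)
      dens[g] += wi * R::dnorm(grid[g], cy[i], sy[i], 0);
  }
  return dens;
}
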