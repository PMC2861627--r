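// Euler-Maruyama integration of the transcription-translation model.
//
// Genes are indexed hb=0, Kr=1, pdm=2, cas=3, x=4.  Each gene i carries an
// mRNA level M_i and a protein level P_i:
//     dM_i = (F_i - dM * M_i) dt + sigma_i dW_i      (noise on mRNA only)
//     dP_i = (M_i - dP * P_i) dt
// The promoter activity is piecewise linear in the summed regulatory input,
//     F_i = g( S_i(t) + sum_j Jt[i][j] * h(P_j) ),   g(u) = max(u, 0),
// with Hill saturation h(P) = P^n / (K^n + P^n).  hb and x have no
// regulators; their default promoters switch off at t_hb and t_x, and their
// noise terms are active only while the promoter is.  Negative excursions
// of M or P are clamped to zero.

#include <Rcpp.h>
using namespace Rcpp;

static inline double hillf(double p, double Kn, double n) {
  if (p <= 0.0) return 0.0;
  double pn = (n == 2.0) ? p * p : std::pow(p, n);
  return pn / (Kn + pn);
}

// Integrate n_trials parameter sets for one network; returns per-trial
// window statistics (onset, offset, nseg) of the thresholded protein levels
// of hb, Kr, pdm, cas -- 12 columns.  clamp_gene: -1 none, else 0..3 with
// clamp_mode 0 = loss (M=P=0), 1 = overexpression (P held at p_oe).
// [[Rcpp::export]]
NumericMatrix sde_window_stats(NumericMatrix Jt, NumericMatrix S,
                               double d_M, double d_P, double K_M,
                               double hill_n, double t_hb, double t_x,
                               double p_th, double dt, double t_total,
                               double sigma, int clamp_gene, int clamp_mode,
                               double p_oe) {
  const int n = Jt.nrow();
  const int nsteps = (int)std::round(t_total / dt);
  const double Kn = std::pow(K_M, hill_n);
  const double sqdt = std::sqrt(dt);
  NumericMatrix out(n, 12);
  std::fill(out.begin(), out.end(), NA_REAL);
  RNGScope scope;

  std::vector<double> M(5), P(5), Fv(5), h(5);
  for (int tr = 0; tr < n; ++tr) {
    for (int g = 0; g < 5; ++g) { M[g] = 0.0; P[g] = 0.0; }
    double onset[4] = {-1, -1, -1, -1}, offset[4] = {-1, -1, -1, -1};
    int nseg[4] = {0, 0, 0, 0};
    bool prev_on[4] = {false, false, false, false};
    if (clamp_gene >= 0 && clamp_mode == 1) P[clamp_gene] = p_oe;

    for (int step = 0; step <= nsteps; ++step) {
      double t = step * dt;
      if (step > 0) {
        for (int g = 0; g < 5; ++g) h[g] = hillf(P[g], Kn, hill_n);
        // promoter activities
        Fv[0] = (t < t_hb) ? S(tr, 0) : 0.0;           // hb
        Fv[4] = (t < t_x) ? S(tr, 4) : 0.0;            // x
        for (int g = 1; g <= 3; ++g) {
          double u = S(tr, g);
          for (int j = 0; j < 5; ++j) u += Jt(tr, (g - 1) * 5 + j) * h[j];
          Fv[g] = (u > 0.0) ? u : 0.0;
        }
        for (int g = 0; g < 5; ++g) {
          if (clamp_gene == g) {
            if (clamp_mode == 0) { M[g] = 0.0; P[g] = 0.0; }
            else { P[g] = p_oe; }
            continue;
          }
          double sig = sigma;
          if (g == 0 && t >= t_hb) sig = 0.0;
          if (g == 4 && t >= t_x) sig = 0.0;
          double dM = (Fv[g] - d_M * M[g]) * dt;
          if (sig > 0.0) dM += sig * sqdt * norm_rand();
          double dPp = (M[g] - d_P * P[g]) * dt;
          M[g] += dM; if (M[g] < 0.0) M[g] = 0.0;
          P[g] += dPp; if (P[g] < 0.0) P[g] = 0.0;
        }
      }
      for (int g = 0; g < 4; ++g) {
        bool on = P[g] > p_th;       // tie (P == p_th) maps to OFF
        if (on) {
          if (!prev_on[g]) nseg[g] += 1;
          if (onset[g] < 0) onset[g] = t;
          offset[g] = t;
        }
        prev_on[g] = on;
      }
    }
    for (int g = 0; g < 4; ++g) {
      out(tr, g * 3 + 0) = onset[g];
      out(tr, g * 3 + 1) = offset[g];
      out(tr, g * 3 + 2) = nseg[g];
    }
  }
  return out;
}

// Full trajectory for a single parameter set (diagnostics / plotting).
// Returns a list with time, M (steps x 5) and P (steps x 5).
// [[Rcpp::export]]
List sde_trajectory(NumericVector Jt, NumericVector S,
                    double d_M, double d_P, double K_M, double hill_n,
                    double t_hb, double t_x, double dt, double t_total,
                    double sigma, int clamp_gene, int clamp_mode,
                    double p_oe) {
  const int nsteps = (int)std::round(t_total / dt);
  const double Kn = std::pow(K_M, hill_n);
  const double sqdt = std::sqrt(dt);
  NumericMatrix Mout(nsteps + 1, 5), Pout(nsteps + 1, 5);
  NumericVector tout(nsteps + 1);
  RNGScope scope;
  std::vector<double> M(5, 0.0), P(5, 0.0), Fv(5), h(5);
  if (clamp_gene >= 0 && clamp_mode == 1) P[clamp_gene] = p_oe;
  for (int step = 0; step <= nsteps; ++step) {
    double t = step * dt;
    if (step > 0) {
      for (int g = 0; g < 5; ++g) h[g] = hillf(P[g], Kn, hill_n);
      Fv[0] = (t < t_hb) ? S[0] : 0.0;
      Fv[4] = (t < t_x) ? S[4] : 0.0;
      for (int g = 1; g <= 3; ++g) {
        double u = S[g];
        for (int j = 0; j < 5; ++j) u += Jt[(g - 1) * 5 + j] * h[j];
        Fv[g] = (u > 0.0) ? u : 0.0;
      }
      for (int g = 0; g < 5; ++g) {
        if (clamp_gene == g) {
          if (clamp_mode == 0) { M[g] = 0.0; P[g] = 0.0; }
          else { P[g] = p_oe; }
          continue;
        }
        double sig = sigma;
        if (g == 0 && t >= t_hb) sig = 0.0;
        if (g == 4 && t >= t_x) sig = 0.0;
        double dM = (Fv[g] - d_M * M[g]) * dt;
        if (sig > 0.0) dM += sig * sqdt * norm_rand();
        double dPp = (M[g] - d_P * P[g]) * dt;
        M[g] += dM; if (M[g] < 0.0) M[g] = 0.0;
        P[g] += dPp; if (P[g] < 0.0) P[g] = 0.0;
      }
    }
    tout[step] = t;
    for (int g = 0; g < 5; ++g) { Mout(step, g) = M[g]; Pout(step, g) = P[g]; }
  }
  if (!(Mout(nsteps, 0) == Mout(nsteps, 0)))
    stop("non-finite state in integration");
  return List::create(_["time"] = tout, _["M"] = Mout, _["P"] = Pout);
}
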