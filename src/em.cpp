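#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama stepper for the pluripotency network.
//
// Parameter vector layout (see pack_params() in R/rhs.R):
//  0 u, 1 s1, 2 s2, 3 s3, 4 s4, 5 s5, 6 s6,
//  7 k1, 8 k2, 9 k3, 10 k4, 11 k5,
// 12 gamma_os, 13 gamma_n, 14 gamma_x,
// 15 d_o, 16 d_s, 17 d_os, 18 d_n, 19 d_x,
// 20 oscillation flag (0/1),
// 21 t_on, 22 t_off, 23 amplitude, 24 k_gate, 25 gamma_gate.
//
// Noise (amplitude sigma, increment sigma*sqrt(dt)*eta) acts on the Nanog
// component only; [N] is clamped at zero after every step (clamp_all also
// clamps [OS] and [X], inert in practice since both integrate their
// deterministic, non-negative-production equations).

static inline double powg(double c, double g) {
  if (g == 1.0) return c;
  if (g == 2.0) return c * c;
  return std::pow(c, g);
}

static inline double hillf(double c, double k, double g) {
  double cg = powg(c, g);
  return cg / (k + cg);
}

// [[Rcpp::export(name = ".em_simulate")]]
NumericMatrix em_simulate(NumericVector y0, double t0, double t_end,
                          double dt, int record_every, NumericVector par,
                          double sigma, bool clamp_all, bool final_only) {
  if (dt <= 0) stop("dt must be > 0");
  long nsteps = (long)std::ceil((t_end - t0) / dt - 1e-9);
  if (nsteps < 1) stop("t_end must exceed t0 by at least dt");
  bool osc = par[20] > 0.5;
  bool has_signal = par[23] > 0.0;
  double os = y0[0], n = y0[1], x = (y0.size() > 2) ? y0[2] : 0.0;

  long nrec = final_only ? 1 : (nsteps / record_every +
                                ((nsteps % record_every) ? 2 : 1));
  NumericMatrix out(nrec, 4);
  long irec = 0;
  if (!final_only) {
    out(0, 0) = t0; out(0, 1) = os; out(0, 2) = n; out(0, 3) = x;
    irec = 1;
  }
  double sq = sigma * std::sqrt(dt);
  double os_ceiling = par[0] * par[1] * par[2] / (par[15] * par[16]);

  for (long i = 0; i < nsteps; ++i) {
    double t = t0 + i * dt;
    double prod_os = par[0] * (par[1] / par[15]) * (par[2] / par[16]) *
                     hillf(os, par[7], par[12]) * hillf(os, par[8], par[12]);
    double d_os_eff = par[17];
    if (has_signal && t >= par[21] && t < par[22]) {
      double y_eff = par[23] * (1.0 - hillf(n, par[24], par[25]));
      d_os_eff *= (1.0 + y_eff);
    }
    double s6x = osc ? par[6] * powg(x, par[14]) : 0.0;
    double ng = powg(n, par[13]);
    double prod_n = par[3] * hillf(os, par[9], par[12]) +
                    par[4] * ng / (par[10] + ng + s6x);
    double dos = prod_os - d_os_eff * os;
    double dn  = prod_n - par[18] * n;
    double dx  = osc ? par[5] * hillf(n, par[11], par[13]) - par[19] * x : 0.0;

    os += dos * dt;
    n  += dn * dt + (sigma > 0.0 ? sq * norm_rand() : 0.0);
    if (osc) x += dx * dt;

    if (n < 0.0) n = 0.0;
    if (clamp_all) {
      if (os < 0.0) os = 0.0;
      if (x < 0.0) x = 0.0;
    }
    if (!R_finite(os) || !R_finite(n) || !R_finite(x) ||
        os > 100.0 * os_ceiling + 1e6)
      stop("state became non-finite at t=%f; reduce the step size dt", t);

    if (!final_only && ((i + 1) % record_every == 0 || i == nsteps - 1)) {
      out(irec, 0) = t0 + (i + 1) * dt;
      out(irec, 1) = os; out(irec, 2) = n; out(irec, 3) = x;
      ++irec;
    }
  }
  if (final_only) {
    out(0, 0) = t0 + nsteps * dt;
    out(0, 1) = os; out(0, 2) = n; out(0, 3) = x;
    ++irec;
  }
  if (irec < nrec) out = out(Range(0, irec - 1), _);
  colnames(out) = CharacterVector::create("t", "os", "n", "x");
  return out;
}

// Snapshot evolution of an ensemble: advances every cell (columns os, n, x)
// by the same time span with independent noise, returning final states only.
// Cells share one RNG stream; statistical independence across cells comes
// from the stream, reproducibility from the R-side set.seed().
// [[Rcpp::export(name = ".em_evolve_ensemble")]]
NumericMatrix em_evolve_ensemble(NumericMatrix states, double t0, double t_end,
                                 double dt, NumericVector par, double sigma,
                                 bool clamp_all) {
  if (dt <= 0) stop("dt must be > 0");
  long nsteps = (long)std::ceil((t_end - t0) / dt - 1e-9);
  bool osc = par[20] > 0.5;
  bool has_signal = par[23] > 0.0;
  int ncell = states.nrow();
  NumericMatrix out = clone(states);
  double sq = sigma * std::sqrt(dt);

  for (long i = 0; i < nsteps; ++i) {
    double t = t0 + i * dt;
    bool sig_on = has_signal && t >= par[21] && t < par[22];
    for (int c = 0; c < ncell; ++c) {
      double os = out(c, 0), n = out(c, 1), x = osc ? out(c, 2) : 0.0;
      double prod_os = par[0] * (par[1] / par[15]) * (par[2] / par[16]) *
                       hillf(os, par[7], par[12]) * hillf(os, par[8], par[12]);
      double d_os_eff = par[17];
      if (sig_on) {
        double y_eff = par[23] * (1.0 - hillf(n, par[24], par[25]));
        d_os_eff *= (1.0 + y_eff);
      }
      double s6x = osc ? par[6] * powg(x, par[14]) : 0.0;
      double ng = powg(n, par[13]);
      double prod_n = par[3] * hillf(os, par[9], par[12]) +
                      par[4] * ng / (par[10] + ng + s6x);
      os += (prod_os - d_os_eff * os) * dt;
      n  += (prod_n - par[18] * n) * dt + (sigma > 0.0 ? sq * norm_rand() : 0.0);
      if (osc) x += (par[5] * hillf(n, par[11], par[13]) - par[19] * x) * dt;
      if (n < 0.0) n = 0.0;
      if (clamp_all) {
        if (os < 0.0) os = 0.0;
        if (x < 0.0) x = 0.0;
      }
      out(c, 0) = os; out(c, 1) = n; out(c, 2) = x;
    }
  }
  colnames(out) = CharacterVector::create("os", "n", "x");
  return out;
}
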