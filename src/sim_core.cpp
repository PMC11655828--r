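#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Freeman sigmoid gain g(u) = C * Q * (1 - exp(-exp(u)/Q)).
static inline double freeman_g(double u, double Q, double C) {
  return C * Q * (1.0 - std::exp(-std::exp(u) / Q));
}

// Euler-Maruyama integration of the delay network
//   du_i/dt = -u_i/tau_i + sum_j w_ij g_j(u_j(t - d_ij)) + I_i(t) + xi(t)
// with a ring buffer of past gain values (depth = max delay in steps + 1)
// and per-step Hebbian updates dw = eta*dt * g_i(t) * g_j(t-d) * (wmax - w)
// on connections flagged plastic.
//
// Connections are triplets (ci -> target, cj -> source, cw, cd delay steps).
// Uses R's RNG (norm_rand), so set.seed() on the R side makes runs
// bit-reproducible.
// [[Rcpp::export]]
List sim_net_cpp(NumericVector u0,
                 NumericMatrix gbuf0,      // (max_d + 1) x n, past gains
                 int gpos0,                // row index (0-based) of most recent g
                 IntegerVector ci, IntegerVector cj,
                 NumericVector cw, IntegerVector cd,
                 LogicalVector cplastic,
                 NumericVector ceta, NumericVector cwmax,
                 NumericVector tau, NumericVector Q, NumericVector C,
                 NumericVector noise_sd, NumericVector tonic,
                 double dt, int n_steps,
                 NumericMatrix stim_wave,  // n_steps x n_stim (may be 0 cols)
                 List stim_targets,        // per stimulus: 0-based unit indices
                 List stim_weights,        // per stimulus: per-target weight
                 bool learning,
                 List probes,              // 0-based unit index vectors
                 int record_every,
                 int record_offset) {      // steps already done since last record
  const int n = u0.size();
  const int ncon = ci.size();
  const int depth = gbuf0.nrow();
  const int nstim = stim_wave.ncol();
  const int nprobe = probes.size();

  NumericVector u = clone(u0);
  NumericMatrix gbuf = clone(gbuf0);
  NumericVector w = clone(cw);
  int gpos = gpos0;

  std::vector<std::vector<int> > ptarg(nstim);
  std::vector<std::vector<double> > pwt(nstim);
  for (int s = 0; s < nstim; ++s) {
    ptarg[s] = as<std::vector<int> >(stim_targets[s]);
    pwt[s]   = as<std::vector<double> >(stim_weights[s]);
  }
  std::vector<std::vector<int> > pidx(nprobe);
  for (int p = 0; p < nprobe; ++p)
    pidx[p] = as<std::vector<int> >(probes[p]);

  int nrec = 0;
  for (int s = 1; s <= n_steps; ++s)
    if ((record_offset + s) % record_every == 0) ++nrec;
  NumericMatrix rec_u(nrec, nprobe), rec_g(nrec, nprobe);
  IntegerVector rec_step(nrec);

  std::vector<double> acc(n), gnow(n);
  RNGScope scope;
  int irec = 0;

  for (int s = 0; s < n_steps; ++s) {
    // gains at current time, pushed into the ring buffer
    for (int i = 0; i < n; ++i) gnow[i] = freeman_g(u[i], Q[i], C[i]);
    gpos = (gpos + 1) % depth;
    for (int i = 0; i < n; ++i) gbuf(gpos, i) = gnow[i];

    // synaptic input from delayed gains
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int k = 0; k < ncon; ++k) {
      int row = gpos - cd[k];
      if (row < 0) row += depth;
      acc[ci[k]] += w[k] * gbuf(row, cj[k]);
    }
    // external / internal stimuli
    for (int st = 0; st < nstim; ++st) {
      double a = stim_wave(s, st);
      if (a == 0.0) continue;
      const std::vector<int>& tg = ptarg[st];
      const std::vector<double>& wt = pwt[st];
      for (size_t q = 0; q < tg.size(); ++q) acc[tg[q]] += a * wt[q];
    }

    // Euler-Maruyama step
    double sqdt = std::sqrt(dt);
    for (int i = 0; i < n; ++i) {
      double du = (-u[i] / tau[i] + acc[i] + tonic[i]) * dt;
      if (noise_sd[i] > 0.0) du += noise_sd[i] * sqdt * norm_rand();
      u[i] += du;
      if (!std::isfinite(u[i]))
        stop("non-finite membrane potential at unit %d, step %d", i + 1, s + 1);
    }

    // Hebbian update: g_i at current time, g_j at t - d (pre-step buffer
    // content, i.e. the same delayed gains that just drove the step)
    if (learning) {
      for (int k = 0; k < ncon; ++k) {
        if (!cplastic[k]) continue;
        int row = gpos - cd[k];
        if (row < 0) row += depth;
        // cap the discrete rate so the continuous-time invariant
        // 0 <= w <= wmax survives any eta * dt
        double rate = ceta[k] * dt * gnow[ci[k]] * gbuf(row, cj[k]);
        if (rate > 1.0) rate = 1.0;
        w[k] += rate * (cwmax[k] - w[k]);
      }
    }

    if ((record_offset + s + 1) % record_every == 0) {
      for (int p = 0; p < nprobe; ++p) {
        double su = 0.0, sg = 0.0;
        const std::vector<int>& ix = pidx[p];
        for (size_t q = 0; q < ix.size(); ++q) {
          su += u[ix[q]];
          sg += freeman_g(u[ix[q]], Q[ix[q]], C[ix[q]]);
        }
        rec_u(irec, p) = su / ix.size();
        rec_g(irec, p) = sg / ix.size();
      }
      rec_step[irec] = record_offset + s + 1;
      ++irec;
    }
  }

  return List::create(_["u"] = u, _["gbuf"] = gbuf, _["gpos"] = gpos,
                      _["w"] = w, _["rec_u"] = rec_u, _["rec_g"] = rec_g,
                      _["rec_step"] = rec_step);
}
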