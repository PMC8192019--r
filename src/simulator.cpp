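// Event-driven per-millisecond simulation of one navigation trial:
// place-cell Poisson input -> spike response action ring -> population-vector
// movement, with sn-Plast updates (immediate ACh depression, eligibility
// trace read out by dopamine at reward). Mirrors the R reference
// implementations of the individual primitives; equivalence is pinned by a
// replay test in the package test suite. Uses R's RNG so set.seed() governs
// every draw.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// weights_in: n_pc x N feedforward weights (masked entries 0); mask: n_pc x N;
// centers: n_pc x 2 place-field centres; well_centers: 2 x 2; baited: 1 or 2;
// directions: N x 2 preferred directions; wlat: N x N lateral weights;
// neuron: chi/tau_m/tau_s/eps0/lambda0/delta_u/theta; plast: eta_ach/eta_da/
// tau_stdp/tau_e/w_min/w_max; times in ms.
// [[Rcpp::export]]
List run_trial_cpp(NumericMatrix weights_in, LogicalMatrix mask,
                   NumericMatrix centers, double sigma, double peak_rate_hz,
                   double arena_radius, NumericMatrix well_centers,
                   double well_radius, int baited, NumericVector start,
                   NumericMatrix directions, NumericMatrix wlat, List neuron,
                   List plast, double tau_gamma, double nu_gamma, double dt,
                   double t_max_ms, bool record = false) {
  const int n_pc = centers.nrow();
  const int N = directions.nrow();
  // row-major working copies: the hot loops sweep action index j for a fixed
  // place cell i, which strides badly through R's column-major storage
  std::vector<double> w((size_t)n_pc * N), wl((size_t)N * N);
  std::vector<char> msk((size_t)n_pc * N);
  for (int i = 0; i < n_pc; ++i)
    for (int j = 0; j < N; ++j) {
      w[(size_t)i * N + j] = weights_in(i, j);
      msk[(size_t)i * N + j] = mask(i, j) ? 1 : 0;
    }
  for (int k = 0; k < N; ++k)
    for (int j = 0; j < N; ++j) wl[(size_t)k * N + j] = wlat(k, j);

  const double chi = neuron["chi"], tau_m = neuron["tau_m"],
               tau_s = neuron["tau_s"], eps0 = neuron["eps0"],
               lambda0 = neuron["lambda0"], delta_u = neuron["delta_u"],
               theta = neuron["theta"];
  const double eta_ach = plast["eta_ach"], eta_da = plast["eta_da"],
               tau_stdp = plast["tau_stdp"], tau_e = plast["tau_e"],
               w_min = plast["w_min"], w_max = plast["w_max"];

  const double peak_ms = peak_rate_hz / 1000.0;     // spikes per ms
  const double lambda0_ms = lambda0 / 1000.0;
  const double dm = std::exp(-dt / tau_m), ds = std::exp(-dt / tau_s);
  const double dg = std::exp(-dt / tau_gamma), dn = std::exp(-dt / nu_gamma);
  const double dstdp = std::exp(-dt / tau_stdp);
  const double c_eps = eps0 / (tau_m - tau_s);
  const double rho_denom = tau_gamma - nu_gamma;
  // place-field support truncated where the rate falls below ~1e-4 of peak
  const double cutoff2 = 9.0 * sigma * sigma;
  // skip the escape draw when the spike probability is below 1e-12
  const double u_skip = theta + delta_u * std::log(1e-12 / (lambda0_ms * dt));
  const double esc_step = std::exp(dt / tau_e);

  const int n_steps = (int)std::round(t_max_ms / dt);

  // action-neuron state
  std::vector<double> am(N, 0.0), as(N, 0.0);       // EPSP accumulators
  std::vector<double> rg(N, 0.0), rn(N, 0.0);       // rate-filter accumulators
  std::vector<double> refr(N, 0.0);                 // refractory accumulator
  std::vector<double> u(N, 0.0), rho(N, 0.0);
  std::vector<char> spiked_now(N, 0);

  // plasticity state; eligibility stored scaled by exp(t/tau_e)
  std::vector<double> pre_trace(n_pc, 0.0), post_trace(N, 0.0);
  std::vector<double> elig((size_t)n_pc * N, 0.0);

  double x0 = start[0], x1 = start[1];
  const double b0 = well_centers(baited - 1, 0), b1 = well_centers(baited - 1, 1);
  const int other = (baited == 1) ? 2 : 1;
  const double o0 = well_centers(other - 1, 0), o1 = well_centers(other - 1, 1);
  const double wr2 = well_radius * well_radius;

  std::vector<int> pre_idx, post_idx;
  pre_idx.reserve(64);
  post_idx.reserve(16);

  int outcome = 0;                                   // 0 timeout, 1 reward, 2 wrong
  double latency = t_max_ms;
  int steps_done = n_steps;

  // well check on the start position: a trial that begins on a well ends at
  // t = 0 (reward still delivers dopamine, on an empty eligibility trace)
  {
    const double db0 = (x0 - b0) * (x0 - b0) + (x1 - b1) * (x1 - b1);
    const double dw0 = (x0 - o0) * (x0 - o0) + (x1 - o1) * (x1 - o1);
    if (db0 <= wr2 || dw0 <= wr2) {
      return List::create(_["outcome"] = (db0 <= wr2) ? 1 : 2,
                          _["latency_ms"] = 0.0, _["steps"] = 0,
                          _["weights"] = clone(weights_in));
    }
  }

  NumericMatrix rec_place, rec_action, rec_traj, rec_rho, rec_u;
  if (record) {
    rec_place = NumericMatrix(n_steps, n_pc);
    rec_action = NumericMatrix(n_steps, N);
    rec_traj = NumericMatrix(n_steps, 2);
    rec_rho = NumericMatrix(n_steps, N);
    rec_u = NumericMatrix(n_steps, N);
  }

  double esc = 1.0;                                  // exp(t / tau_e), lazy

  for (int step = 0; step < n_steps; ++step) {
    const double t = (step + 1) * dt;                // time at end of step, ms
    esc *= esc_step;

    // --- place-cell spikes at current position ---
    pre_idx.clear();
    for (int i = 0; i < n_pc; ++i) {
      const double dx = centers(i, 0) - x0, dy = centers(i, 1) - x1;
      const double d2 = dx * dx + dy * dy;
      if (d2 > cutoff2) continue;
      const double p = peak_ms * dt * std::exp(-d2 / (sigma * sigma));
      if (unif_rand() < p) pre_idx.push_back(i);
    }

    // --- membrane update and action spikes ---
    post_idx.clear();
    for (int j = 0; j < N; ++j) {
      am[j] *= dm;
      as[j] *= ds;
      refr[j] *= dm;                                 // chi * exp(-(t-that)/tau_m)
      u[j] = c_eps * (am[j] - as[j]) + refr[j];
      if (u[j] < u_skip) continue;
      double p = lambda0_ms * std::exp((u[j] - theta) / delta_u) * dt;
      if (p > 1.0) p = 1.0;
      if (unif_rand() < p) {
        post_idx.push_back(j);
        am[j] = 0.0;                                 // own-spike reset
        as[j] = 0.0;
        refr[j] = chi;
      }
    }

    // --- arrivals: feedforward then lateral, skipping same-step spikers ---
    for (int j : post_idx) spiked_now[j] = 1;
    for (int i : pre_idx) {
      for (int j = 0; j < N; ++j) {
        if (spiked_now[j]) continue;
        const double wij = w[(size_t)i * N + j];
        am[j] += wij;
        as[j] += wij;
      }
    }
    for (int k : post_idx) {
      for (int j = 0; j < N; ++j) {
        if (j == k || spiked_now[j]) continue;
        const double wlkj = wl[(size_t)k * N + j];
        am[j] += wlkj;
        as[j] += wlkj;
      }
    }

    // --- rate estimate and action selection ---
    double a0v = 0.0, a1v = 0.0;
    for (int j = 0; j < N; ++j) {
      rg[j] *= dg;
      rn[j] *= dn;
      if (spiked_now[j]) {
        rg[j] += 1.0;
        rn[j] += 1.0;
      }
      rho[j] = (rg[j] - rn[j]) / rho_denom;
      a0v += rho[j] * directions(j, 0);
      a1v += rho[j] * directions(j, 1);
    }
    a0v /= N;
    a1v /= N;

    // --- position update with wall reflection ---
    double nx0 = x0 + a0v, nx1 = x1 + a1v;
    if (nx0 * nx0 + nx1 * nx1 > arena_radius * arena_radius) {
      const double nrm = std::sqrt(x0 * x0 + x1 * x1);
      if (nrm > 1e-12) {
        const double h0 = x0 / nrm, h1 = x1 / nrm;
        const double proj = a0v * h0 + a1v * h1;
        nx0 = x0 + a0v - 2.0 * proj * h0;
        nx1 = x1 + a1v - 2.0 * proj * h1;
      } else {
        nx0 = x0 - a0v;
        nx1 = x1 - a1v;
      }
      const double nn = std::sqrt(nx0 * nx0 + nx1 * nx1);
      if (nn > arena_radius) {
        nx0 *= arena_radius / nn;
        nx1 *= arena_radius / nn;
      }
    }
    x0 = nx0;
    x1 = nx1;

    // --- plasticity step (ACh branch + eligibility accumulation) ---
    for (int i = 0; i < n_pc; ++i) pre_trace[i] *= dstdp;
    for (int j = 0; j < N; ++j) post_trace[j] *= dstdp;
    for (int i : pre_idx) pre_trace[i] += 1.0;
    // post spikes pair with the pre trace (includes simultaneous pres)
    for (int j : post_idx) {
      for (int i = 0; i < n_pc; ++i) {
        const double m = pre_trace[i];
        const size_t ij = (size_t)i * N + j;
        if (m < 1e-12 || msk[ij]) continue;
        elig[ij] += m * esc;
        if (eta_ach > 0.0) {
          double wij = w[ij] - eta_ach * m;
          if (wij < w_min) wij = w_min;
          w[ij] = wij;
        }
      }
    }
    // pre spikes pair with the post trace (strictly earlier posts only)
    for (int i : pre_idx) {
      for (int j = 0; j < N; ++j) {
        const double m = post_trace[j];
        const size_t ij = (size_t)i * N + j;
        if (m < 1e-12 || msk[ij]) continue;
        elig[ij] += m * esc;
        if (eta_ach > 0.0) {
          double wij = w[ij] - eta_ach * m;
          if (wij < w_min) wij = w_min;
          w[ij] = wij;
        }
      }
    }
    for (int j : post_idx) post_trace[j] += 1.0;

    if (record) {
      for (int i : pre_idx) rec_place(step, i) = 1.0;
      for (int j : post_idx) rec_action(step, j) = 1.0;
      rec_traj(step, 0) = x0;
      rec_traj(step, 1) = x1;
      for (int j = 0; j < N; ++j) {
        rec_rho(step, j) = rho[j];
        rec_u(step, j) = u[j];
      }
    }

    for (int j : post_idx) spiked_now[j] = 0;

    // --- well check on the updated position ---
    const double db = (x0 - b0) * (x0 - b0) + (x1 - b1) * (x1 - b1);
    if (db <= wr2) {
      // reward: dopamine reads out the eligibility trace once
      const double descale = 1.0 / esc;
      for (int i = 0; i < n_pc; ++i) {
        for (int j = 0; j < N; ++j) {
          const size_t ij = (size_t)i * N + j;
          const double e = elig[ij];
          if (e <= 0.0 || msk[ij]) continue;
          double wij = w[ij] + eta_da * e * descale;
          if (wij > w_max) wij = w_max;
          if (wij < w_min) wij = w_min;
          w[ij] = wij;
        }
      }
      outcome = 1;
      latency = t;
      steps_done = step + 1;
      break;
    }
    const double dw = (x0 - o0) * (x0 - o0) + (x1 - o1) * (x1 - o1);
    if (dw <= wr2) {
      outcome = 2;
      latency = t;
      steps_done = step + 1;
      break;
    }
  }

  NumericMatrix w_out(n_pc, N);
  for (int i = 0; i < n_pc; ++i)
    for (int j = 0; j < N; ++j) w_out(i, j) = w[(size_t)i * N + j];
  List out = List::create(
      _["outcome"] = outcome, _["latency_ms"] = latency,
      _["steps"] = steps_done, _["weights"] = w_out);
  if (record) {
    out["place_raster"] = rec_place(Range(0, steps_done - 1), _);
    out["action_raster"] = rec_action(Range(0, steps_done - 1), _);
    out["trajectory"] = rec_traj(Range(0, steps_done - 1), _);
    out["rho"] = rec_rho(Range(0, steps_done - 1), _);
    out["u"] = rec_u(Range(0, steps_done - 1), _);
  }
  return out;
}
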