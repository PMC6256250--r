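// Clock-driven co-simulation of LIF neurons, per-neuron energy traces and
// energy-modulated STDP over a fixed wiring diagram.
//
// Conventions (mirrored exactly by the pure-R reference engine used in tests):
//  * all times in seconds; a step covers [t_k, t_k + dt)
//  * spikes emitted in step k are delivered at the start of step k+1
//  * per step: (1) deliver internal spikes queued from the previous step, in
//    emitting-neuron order, each neuron's out-edges in table order; (2) deliver
//    external arrivals; (3) advance energy traces by dt and accumulate the
//    sliding-window integrals; (4) LIF update for every neuron, process
//    emissions (energy impulse, potentiation of plastic afferents, queue
//    deliveries)
//  * arrivals are stamped with the step start time, emissions with the time at
//    the end of the step; depression is applied on arrival at a plastic edge
//    (pairing with the postsynaptic neuron's latest spike), potentiation on
//    emission (pairing each plastic afferent's latest arrival)
//  * the energy ratio alpha used by an update is the postsynaptic neuron's
//    current windowed ratio; alpha is undefined (gate = 1) while no signaling
//    energy has been spent

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Gate {
  double lambda, c;
  bool on;
  // modulation factor for a given alpha (NaN = undefined) and update sign
  double operator()(double alpha, int sgn) const {
    if (!on || !std::isfinite(alpha)) return 1.0;
    return 2.0 / (1.0 + std::exp(lambda * sgn * (alpha - c)));
  }
};

}  // namespace

// [[Rcpp::export(name = ".simulate_cpp")]]
List simulate_cpp(int n_neurons, int n_exc,
                  IntegerVector edge_pre, IntegerVector edge_post,
                  NumericVector edge_weight_in, LogicalVector edge_plastic,
                  NumericVector ext_weight, IntegerVector ext_target,
                  bool ext_plastic, int ext_mode, double ext_rate,
                  NumericVector ext_sched_time, IntegerVector ext_sched_src,
                  NumericVector agg_count, NumericVector agg_mean_w,
                  NumericVector agg_var_w,
                  double dt, double duration, double sample_every,
                  double steady_frac,
                  double tau_m, double v_rest, double v_thr, double v_reset,
                  double t_ref, double efficacy,
                  double e_trans, double e_integ, double tau_trans,
                  double tau_integ, double window, double bin_width,
                  double a_plus, double a_minus, double tau_plus,
                  double tau_minus, bool weight_dependent,
                  double lambda_gain, double set_point_c,
                  bool constraints_enabled, bool plasticity_enabled,
                  int max_spikes) {
  if (dt <= 0) stop("dt must be > 0");
  if (duration < dt) stop("duration must cover at least one step");
  const int n_steps = (int)std::llround(duration / dt);
  const int steps_per_bin = (int)std::llround(bin_width / dt);
  if (steps_per_bin < 1 ||
      std::fabs(steps_per_bin * dt - bin_width) > 1e-9 * bin_width)
    stop("dt must divide the window bin width");
  const int n_bins = (int)std::llround(window / bin_width);
  if (n_bins < 1) stop("window must cover at least one bin");

  const int n_edges = edge_pre.size();
  const int n_ext = ext_weight.size();
  std::vector<double> w(edge_weight_in.begin(), edge_weight_in.end());
  std::vector<double> wx(ext_weight.begin(), ext_weight.end());

  // CSR: out-edges by presynaptic neuron (table order within a neuron)
  std::vector<int> out_ptr(n_neurons + 1, 0), out_idx(n_edges);
  for (int e = 0; e < n_edges; ++e) out_ptr[edge_pre[e]]++;
  for (int j = 0; j < n_neurons; ++j) out_ptr[j + 1] += out_ptr[j];
  {
    // after the prefix pass, out_ptr[p] is the start of 0-based neuron p
    // (counts were tallied into slot `pre`, which is 1-based)
    std::vector<int> fill(n_neurons, 0);
    for (int e = 0; e < n_edges; ++e) {
      int p = edge_pre[e] - 1;
      out_idx[out_ptr[p] + fill[p]] = e;
      fill[p]++;
    }
  }
  // CSR: plastic in-edges by postsynaptic neuron
  std::vector<int> pin_ptr(n_neurons + 1, 0), pin_idx;
  {
    std::vector<int> cnt(n_neurons, 0);
    for (int e = 0; e < n_edges; ++e)
      if (edge_plastic[e]) cnt[edge_post[e] - 1]++;
    for (int j = 0; j < n_neurons; ++j) pin_ptr[j + 1] = pin_ptr[j] + cnt[j];
    pin_idx.assign(pin_ptr[n_neurons], 0);
    std::vector<int> fill(n_neurons, 0);
    for (int e = 0; e < n_edges; ++e)
      if (edge_plastic[e]) {
        int p = edge_post[e] - 1;
        pin_idx[pin_ptr[p] + fill[p]] = e;
        fill[p]++;
      }
  }
  // CSR: external synapses by target neuron (for plastic externals)
  std::vector<int> xin_ptr(n_neurons + 1, 0), xin_idx(n_ext);
  {
    std::vector<int> cnt(n_neurons, 0);
    for (int s = 0; s < n_ext; ++s) cnt[ext_target[s] - 1]++;
    for (int j = 0; j < n_neurons; ++j) xin_ptr[j + 1] = xin_ptr[j] + cnt[j];
    std::vector<int> fill(n_neurons, 0);
    for (int s = 0; s < n_ext; ++s) {
      int p = ext_target[s] - 1;
      xin_idx[xin_ptr[p] + fill[p]] = s;
      fill[p]++;
    }
  }

  // neuron state
  std::vector<double> v(n_neurons, v_rest);
  std::vector<int> refr(n_neurons, 0);
  const int ref_steps = (int)std::llround(t_ref / dt);
  const double leak = std::exp(-dt / tau_m);

  // energy traces: value E and auxiliary G per neuron per energy type
  std::vector<double> Et(n_neurons, 0.0), Gt(n_neurons, 0.0);
  std::vector<double> Ei(n_neurons, 0.0), Gi(n_neurons, 0.0);
  const double dec_t = std::exp(-dt / tau_trans);
  const double dec_i = std::exp(-dt / tau_integ);
  const double cf_t = dt / (tau_trans * tau_trans);
  const double cf_i = dt / (tau_integ * tau_integ);
  // sliding-window integrals: ring of completed bins + running sums
  std::vector<double> ring_t((size_t)n_neurons * n_bins, 0.0);
  std::vector<double> ring_i((size_t)n_neurons * n_bins, 0.0);
  std::vector<double> acc_t(n_neurons, 0.0), acc_i(n_neurons, 0.0);
  std::vector<double> Wt(n_neurons, 0.0), Wi(n_neurons, 0.0);
  int ring_ptr = 0;

  // plasticity pairing state
  std::vector<double> last_post(n_neurons, -1.0);
  std::vector<double> last_pre(n_edges, -1.0);
  std::vector<double> last_pre_x(ext_plastic ? n_ext : 0, -1.0);
  const double tp = tau_plus, tm = tau_minus;
  Gate gate{lambda_gain, set_point_c, constraints_enabled};

  // step-local buffers
  std::vector<double> drive(n_neurons, 0.0);
  std::vector<double> imp_t(n_neurons, 0.0), imp_i(n_neurons, 0.0);
  std::vector<int> fired_prev, fired_now;
  fired_prev.reserve(n_neurons);
  fired_now.reserve(n_neurons);

  // recording
  const int sample_steps = std::max(1, (int)std::llround(sample_every / dt));
  const int n_samples = n_steps / sample_steps + 1;
  NumericVector rec_time(n_samples), rec_wmean(n_samples), rec_wsd(n_samples),
      rec_amean(n_samples), rec_asd(n_samples), rec_rate(n_samples),
      rec_adefined(n_samples);
  int rec_k = 0;
  long long spikes_since_sample = 0;
  const double steady_t = steady_frac * duration;
  std::vector<double> alpha_sum(n_neurons, 0.0);
  std::vector<int> alpha_cnt(n_neurons, 0);
  std::vector<int> spike_count(n_neurons, 0), steady_spikes(n_neurons, 0);
  std::vector<int> sp_neuron;
  std::vector<double> sp_time;
  bool store_spikes = max_spikes > 0;

  const int n_plastic_tot =
      (int)pin_idx.size() + (ext_plastic ? n_ext : 0);

  auto alpha_of = [&](int j) -> double {
    double denom = Wt[j] + Wi[j];
    if (denom <= 0) return NA_REAL;
    return Wt[j] / denom;
  };

  auto record_sample = [&](double t, int step_interval) {
    // mean/sd of plastic weights
    double s = 0, s2 = 0;
    for (size_t k = 0; k < pin_idx.size(); ++k) {
      double x = w[pin_idx[k]];
      s += x;
      s2 += x * x;
    }
    if (ext_plastic)
      for (int k = 0; k < n_ext; ++k) {
        s += wx[k];
        s2 += wx[k] * wx[k];
      }
    rec_time[rec_k] = t;
    if (n_plastic_tot > 0) {
      double m = s / n_plastic_tot;
      rec_wmean[rec_k] = m;
      rec_wsd[rec_k] = n_plastic_tot > 1
          ? std::sqrt(std::max(0.0, (s2 - n_plastic_tot * m * m) /
                                        (n_plastic_tot - 1)))
          : 0.0;
    } else {
      rec_wmean[rec_k] = NA_REAL;
      rec_wsd[rec_k] = NA_REAL;
    }
    double as = 0, as2 = 0;
    int an = 0;
    for (int j = 0; j < n_neurons; ++j) {
      double a = alpha_of(j);
      if (std::isfinite(a)) {
        as += a;
        as2 += a * a;
        an++;
        if (t >= steady_t) {
          alpha_sum[j] += a;
          alpha_cnt[j]++;
        }
      }
    }
    rec_adefined[rec_k] = an;
    rec_amean[rec_k] = an > 0 ? as / an : NA_REAL;
    rec_asd[rec_k] = an > 1
        ? std::sqrt(std::max(0.0, (as2 - an * (as / an) * (as / an)) / (an - 1)))
        : NA_REAL;
    rec_rate[rec_k] = step_interval > 0
        ? (double)spikes_since_sample / n_neurons / (step_interval * dt)
        : NA_REAL;
    spikes_since_sample = 0;
    rec_k++;
  };

  record_sample(0.0, 0);

  R_xlen_t sched_cursor = 0;
  for (int step = 0; step < n_steps; ++step) {
    const double t_now = step * dt;       // stamp for arrivals
    const double t_emit = (step + 1) * dt;  // stamp for emissions

    // (1) internal deliveries from the previous step
    for (int fi : fired_prev) {
      bool pre_exc = fi < n_exc;
      for (int q = out_ptr[fi]; q < out_ptr[fi + 1]; ++q) {
        int e = out_idx[q];
        int j = edge_post[e] - 1;
        double we = w[e];
        drive[j] += (pre_exc ? efficacy : -efficacy) * we;
        imp_t[j] += e_trans * we;
        if (plasticity_enabled && edge_plastic[e]) {
          if (last_post[j] >= 0.0) {
            double dtt = last_post[j] - t_now;  // <= 0
            if (dtt < 0.0) {
              double dw = gate(alpha_of(j), -1) * a_minus * std::exp(dtt / tm);
              if (weight_dependent) dw *= w[e];
              w[e] -= dw;
              if (w[e] < 0.0) w[e] = 0.0;
            }
          }
          last_pre[e] = t_now;
        }
      }
    }
    fired_prev.clear();

    // (2) external arrivals for this step
    if (ext_mode == 1) {
      // on-the-fly Poisson superposition over explicit sources
      int K = (int)R::rpois(n_ext * ext_rate * dt);
      for (int k = 0; k < K; ++k) {
        int s = (int)(unif_rand() * n_ext);
        if (s >= n_ext) s = n_ext - 1;
        int j = ext_target[s] - 1;
        drive[j] += efficacy * wx[s];
        imp_t[j] += e_trans * wx[s];
        if (plasticity_enabled && ext_plastic) {
          if (last_post[j] >= 0.0) {
            double dtt = last_post[j] - t_now;
            if (dtt < 0.0) {
              double dw = gate(alpha_of(j), -1) * a_minus * std::exp(dtt / tm);
              if (weight_dependent) dw *= wx[s];
              wx[s] -= dw;
              if (wx[s] < 0.0) wx[s] = 0.0;
            }
          }
          last_pre_x[s] = t_now;
        }
      }
    } else if (ext_mode == 2) {
      // aggregate compound-Poisson drive per neuron (non-plastic externals)
      for (int j = 0; j < n_neurons; ++j) {
        double lam = agg_count[j] * ext_rate * dt;
        if (lam <= 0) continue;
        int K = (int)R::rpois(lam);
        if (K == 0) continue;
        double S = K * agg_mean_w[j];
        if (agg_var_w[j] > 0) S += std::sqrt(K * agg_var_w[j]) * norm_rand();
        if (S < 0) S = 0;
        drive[j] += efficacy * S;
        imp_t[j] += e_trans * S;
      }
    } else if (ext_mode == 3) {
      // pregenerated schedule: deliver events with time in [t_now, t_now+dt)
      while (sched_cursor < ext_sched_time.size() &&
             ext_sched_time[sched_cursor] < t_now + dt) {
        int s = ext_sched_src[sched_cursor] - 1;
        int j = ext_target[s] - 1;
        drive[j] += efficacy * wx[s];
        imp_t[j] += e_trans * wx[s];
        if (plasticity_enabled && ext_plastic) {
          if (last_post[j] >= 0.0) {
            double dtt = last_post[j] - t_now;
            if (dtt < 0.0) {
              double dw = gate(alpha_of(j), -1) * a_minus * std::exp(dtt / tm);
              if (weight_dependent) dw *= wx[s];
              wx[s] -= dw;
              if (wx[s] < 0.0) wx[s] = 0.0;
            }
          }
          last_pre_x[s] = t_now;
        }
        sched_cursor++;
      }
    }

    // (3) energy trace advance + window bookkeeping
    for (int j = 0; j < n_neurons; ++j) {
      double gt = Gt[j] + imp_t[j];
      Et[j] = dec_t * (Et[j] + gt * cf_t);
      Gt[j] = dec_t * gt;
      double gi = Gi[j] + imp_i[j];
      Ei[j] = dec_i * (Ei[j] + gi * cf_i);
      Gi[j] = dec_i * gi;
      imp_t[j] = 0.0;
      imp_i[j] = 0.0;
      double at = Et[j] * dt, ai = Ei[j] * dt;
      acc_t[j] += at;
      acc_i[j] += ai;
      Wt[j] += at;
      Wi[j] += ai;
    }
    if ((step + 1) % steps_per_bin == 0) {
      for (int j = 0; j < n_neurons; ++j) {
        size_t off = (size_t)j * n_bins + ring_ptr;
        Wt[j] -= ring_t[off];
        Wi[j] -= ring_i[off];
        if (Wt[j] < 0) Wt[j] = 0;
        if (Wi[j] < 0) Wi[j] = 0;
        ring_t[off] = acc_t[j];
        ring_i[off] = acc_i[j];
        acc_t[j] = 0.0;
        acc_i[j] = 0.0;
      }
      ring_ptr = (ring_ptr + 1) % n_bins;
    }

    // (4) LIF update and emissions
    for (int j = 0; j < n_neurons; ++j) {
      if (refr[j] > 0) {
        refr[j]--;
        v[j] = v_reset;
        drive[j] = 0.0;
        continue;
      }
      double vj = v_rest + (v[j] - v_rest) * leak + drive[j];
      drive[j] = 0.0;
      if (vj >= v_thr) {
        v[j] = v_reset;
        refr[j] = ref_steps;
        fired_now.push_back(j);
        imp_i[j] += e_integ;
        spike_count[j]++;
        spikes_since_sample++;
        if (t_emit >= steady_t) steady_spikes[j]++;
        if (store_spikes) {
          if ((int)sp_time.size() < max_spikes) {
            sp_neuron.push_back(j + 1);
            sp_time.push_back(t_emit);
          } else {
            store_spikes = false;
          }
        }
        if (plasticity_enabled) {
          double a = alpha_of(j);
          double fpot = gate(a, +1);
          for (int q = pin_ptr[j]; q < pin_ptr[j + 1]; ++q) {
            int e = pin_idx[q];
            if (last_pre[e] >= 0.0) {
              double dtt = t_emit - last_pre[e];
              if (dtt > 0.0) {
                double dw = fpot * a_plus * std::exp(-dtt / tp);
                if (weight_dependent) dw *= (1.0 - w[e]);
                w[e] += dw;
                if (w[e] > 1.0) w[e] = 1.0;
              }
            }
          }
          if (ext_plastic) {
            for (int q = xin_ptr[j]; q < xin_ptr[j + 1]; ++q) {
              int s = xin_idx[q];
              if (last_pre_x[s] >= 0.0) {
                double dtt = t_emit - last_pre_x[s];
                if (dtt > 0.0) {
                  double dw = fpot * a_plus * std::exp(-dtt / tp);
                  if (weight_dependent) dw *= (1.0 - wx[s]);
                  wx[s] += dw;
                  if (wx[s] > 1.0) wx[s] = 1.0;
                }
              }
            }
          }
        }
        last_post[j] = t_emit;
      } else {
        v[j] = vj;
      }
    }
    std::swap(fired_prev, fired_now);
    fired_now.clear();

    if ((step + 1) % sample_steps == 0) {
      for (int j = 0; j < n_neurons; ++j)
        if (!std::isfinite(v[j]))
          stop("numerical failure (non-finite potential) at step %d", step + 1);
      record_sample(t_emit, sample_steps);
      Rcpp::checkUserInterrupt();
    }
  }

  NumericVector alpha_steady(n_neurons);
  for (int j = 0; j < n_neurons; ++j)
    alpha_steady[j] = alpha_cnt[j] > 0 ? alpha_sum[j] / alpha_cnt[j] : NA_REAL;
  NumericVector alpha_final(n_neurons), wt_final(n_neurons), wi_final(n_neurons);
  for (int j = 0; j < n_neurons; ++j) {
    alpha_final[j] = alpha_of(j);
    wt_final[j] = Wt[j];
    wi_final[j] = Wi[j];
  }

  return List::create(
      _["time"] = rec_time[Range(0, rec_k - 1)],
      _["w_mean"] = rec_wmean[Range(0, rec_k - 1)],
      _["w_sd"] = rec_wsd[Range(0, rec_k - 1)],
      _["alpha_mean"] = rec_amean[Range(0, rec_k - 1)],
      _["alpha_sd"] = rec_asd[Range(0, rec_k - 1)],
      _["alpha_defined"] = rec_adefined[Range(0, rec_k - 1)],
      _["rate"] = rec_rate[Range(0, rec_k - 1)],
      _["weights"] = NumericVector(w.begin(), w.end()),
      _["ext_weights"] = NumericVector(wx.begin(), wx.end()),
      _["spike_neuron"] = IntegerVector(sp_neuron.begin(), sp_neuron.end()),
      _["spike_time"] = NumericVector(sp_time.begin(), sp_time.end()),
      _["spike_count"] = IntegerVector(spike_count.begin(), spike_count.end()),
      _["steady_spike_count"] =
          IntegerVector(steady_spikes.begin(), steady_spikes.end()),
      _["alpha_steady"] = alpha_steady,
      _["alpha_final"] = alpha_final,
      _["w_trans_final"] = wt_final,
      _["w_integ_final"] = wi_final,
      _["spikes_complete"] = store_spikes || max_spikes == 0,
      _["potentials"] = NumericVector(v.begin(), v.end()));
}
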