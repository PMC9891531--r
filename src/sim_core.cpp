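#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Clock-driven (forward Euler) integration of the two-module LIF network.
//
// State per neuron: membrane potential v (dimensionless, threshold 1,
// reset 0 by default), a recurrent synaptic input trace and an external
// drive trace, both decaying with tau_s. Presynaptic spikes are delivered
// through a ring buffer of pending arrivals so that a spike emitted at step
// s first affects the postsynaptic trace at step s + delay_steps (delay 0 is
// promoted to one step: arrivals cannot act within the emitting step).
// Static (intra-module) synapses carry a sign from the presynaptic E/I
// identity; plastic (inter-module E->E) synapses are positive and are
// updated online by the pair-based STDP rule with effective delay xi,
// nearest-neighbour pairing triggered at both pre- and postsynaptic spike
// events, additive updates, hard clipping to [g_min, g_max]. Pairings use
// strictly earlier partner spikes, so exactly coincident somatic spikes
// produce no update (each pair is counted once).
//
// Stimulation pulses are instantaneous kicks of size K added to v of masked
// neurons; module 1 follows the signal-1 pulse steps, module 2 signal 2.
//
// Edge indices arriving from R are 0-based.

// [[Rcpp::export]]
List sim_core(int n,
              IntegerVector module,
              LogicalVector is_ex,
              IntegerVector s_pre, IntegerVector s_post, NumericVector s_w,
              int s_delay_steps,
              IntegerVector p_pre, IntegerVector p_post, NumericVector p_w0,
              int p_delay_steps,
              NumericVector drive_rate_per_step, double w_ext,
              IntegerVector pulse_steps_1, IntegerVector pulse_steps_2,
              LogicalVector stim_mask, double stim_K,
              double dt, int n_steps,
              double tau_m, double tau_s, double v_th, double v_r,
              int ref_steps,
              double a_plus, double a_minus, double tau_plus, double tau_minus,
              double xi, double g_min, double g_max, double current_scale,
              bool plasticity_on,
              int record_every_steps, bool record_weight_snapshots) {
  const int n_static = s_pre.size();
  const int n_plastic = p_pre.size();
  if (s_delay_steps < 0 || p_delay_steps < 0)
    stop("delay steps must be non-negative");
  const int ds = std::max(s_delay_steps, 1);
  const int dp = std::max(p_delay_steps, 1);
  const int D = std::max(ds, dp) + 1;  // ring buffer length

  // adjacency lists
  std::vector<std::vector<int>> out_static(n), out_plastic(n), in_plastic(n);
  for (int e = 0; e < n_static; ++e) out_static[s_pre[e]].push_back(e);
  for (int e = 0; e < n_plastic; ++e) {
    out_plastic[p_pre[e]].push_back(e);
    in_plastic[p_post[e]].push_back(e);
  }
  std::vector<double> pw(p_w0.begin(), p_w0.end());
  std::vector<double> sw_signed(n_static);
  for (int e = 0; e < n_static; ++e)
    sw_signed[e] = is_ex[s_pre[e]] ? s_w[e] : -s_w[e];

  // direction of each plastic edge (module of presynaptic neuron)
  std::vector<char> p_from1(n_plastic);
  int n21 = 0, n12 = 0;
  for (int e = 0; e < n_plastic; ++e) {
    p_from1[e] = (module[p_pre[e]] == 1);
    if (p_from1[e]) ++n21; else ++n12;
  }

  // pulse step lookup
  std::vector<char> pulse1(n_steps, 0), pulse2(n_steps, 0);
  for (int i = 0; i < pulse_steps_1.size(); ++i) {
    int st = pulse_steps_1[i];
    if (st >= 0 && st < n_steps) pulse1[st] = 1;
  }
  for (int i = 0; i < pulse_steps_2.size(); ++i) {
    int st = pulse_steps_2[i];
    if (st >= 0 && st < n_steps) pulse2[st] = 1;
  }

  std::vector<double> v(n, v_r), tr_rec(n, 0.0), tr_ext(n, 0.0);
  std::vector<int> refrac(n, 0);  // steps left in refractory clamp
  std::vector<double> buf((size_t)D * n, 0.0);
  std::vector<double> last_spike(n, -1e18);
  const double decay_s = std::exp(-dt / tau_s);
  const double euler = dt / tau_m;

  std::vector<int> spike_step_rec, spike_neuron_rec;
  std::vector<int> spiking; spiking.reserve(n);

  const int n_rec = n_steps / record_every_steps;
  NumericVector rec_time(n_rec), rec_g21(n_rec), rec_g12(n_rec);
  NumericMatrix snap;
  if (record_weight_snapshots) snap = NumericMatrix(n_rec, n_plastic);
  int rec_i = 0;

  for (int s = 0; s < n_steps; ++s) {
    const int cur = s % D;
    const double t_now = (s + 1) * dt;

    // consume pending arrivals, decay traces, add external Poisson arrivals
    for (int i = 0; i < n; ++i) {
      tr_rec[i] = tr_rec[i] * decay_s + buf[(size_t)cur * n + i];
      buf[(size_t)cur * n + i] = 0.0;
      double arr = drive_rate_per_step[i] > 0
        ? R::rpois(drive_rate_per_step[i]) : 0.0;
      tr_ext[i] = tr_ext[i] * decay_s + arr * w_ext;
      if (refrac[i] > 0) { --refrac[i]; v[i] = v_r; continue; }
      v[i] += euler * (-v[i] + tr_rec[i] + tr_ext[i]);
    }

    // stimulation kicks
    if (pulse1[s] || pulse2[s]) {
      for (int i = 0; i < n; ++i) {
        if (!stim_mask[i] || refrac[i] > 0) continue;
        if ((module[i] == 1 && pulse1[s]) || (module[i] == 2 && pulse2[s]))
          v[i] += stim_K;
      }
    }

    // threshold crossings
    spiking.clear();
    for (int i = 0; i < n; ++i) {
      if (v[i] >= v_th) {
        v[i] = v_r;
        refrac[i] = ref_steps;
        spiking.push_back(i);
      }
    }

    if (!spiking.empty()) {
      for (size_t k = 0; k < spiking.size(); ++k) {
        const int i = spiking[k];
        spike_step_rec.push_back(s);
        spike_neuron_rec.push_back(i);
        // schedule arrivals
        for (size_t q = 0; q < out_static[i].size(); ++q) {
          const int e = out_static[i][q];
          buf[(size_t)((s + ds) % D) * n + s_post[e]] += sw_signed[e] * current_scale;
        }
        for (size_t q = 0; q < out_plastic[i].size(); ++q) {
          const int e = out_plastic[i][q];
          buf[(size_t)((s + dp) % D) * n + p_post[e]] += pw[e] * current_scale;
        }
        // STDP pairing with strictly earlier partner spikes
        if (plasticity_on) {
          for (size_t q = 0; q < out_plastic[i].size(); ++q) {
            const int e = out_plastic[i][q];
            const double tp = last_spike[p_post[e]];
            if (tp > -1e17) {
              const double d = (tp - t_now) + xi;
              if (d > 0)      pw[e] += a_plus * std::exp(-d / tau_plus);
              else if (d < 0) pw[e] -= a_minus * std::exp(d / tau_minus);
              if (pw[e] > g_max) pw[e] = g_max;
              else if (pw[e] < g_min) pw[e] = g_min;
            }
          }
          for (size_t q = 0; q < in_plastic[i].size(); ++q) {
            const int e = in_plastic[i][q];
            const double tp = last_spike[p_pre[e]];
            if (tp > -1e17) {
              const double d = (t_now - tp) + xi;
              if (d > 0)      pw[e] += a_plus * std::exp(-d / tau_plus);
              else if (d < 0) pw[e] -= a_minus * std::exp(d / tau_minus);
              if (pw[e] > g_max) pw[e] = g_max;
              else if (pw[e] < g_min) pw[e] = g_min;
            }
          }
        }
      }
      for (size_t k = 0; k < spiking.size(); ++k)
        last_spike[spiking[k]] = t_now;
    }

    if ((s + 1) % record_every_steps == 0 && rec_i < n_rec) {
      double s21 = 0.0, s12 = 0.0;
      for (int e = 0; e < n_plastic; ++e) {
        if (p_from1[e]) s21 += pw[e]; else s12 += pw[e];
      }
      rec_time[rec_i] = t_now;
      rec_g21[rec_i] = n21 > 0 ? s21 / n21 : NA_REAL;
      rec_g12[rec_i] = n12 > 0 ? s12 / n12 : NA_REAL;
      if (record_weight_snapshots)
        for (int e = 0; e < n_plastic; ++e) snap(rec_i, e) = pw[e];
      ++rec_i;
    }

    if ((s & 1023) == 0) {
      for (int i = 0; i < n; ++i) {
        if (!std::isfinite(v[i]))
          stop("membrane potential diverged (non-finite) at t = %f ms", t_now);
      }
      if ((s & 16383) == 0) Rcpp::checkUserInterrupt();
    }
  }

  List out = List::create(
    Named("spike_step") = wrap(spike_step_rec),
    Named("spike_neuron") = wrap(spike_neuron_rec),
    Named("rec_time") = rec_time,
    Named("rec_g21") = rec_g21,
    Named("rec_g12") = rec_g12,
    Named("plastic_w_final") = wrap(pw),
    Named("n_edges_21") = n21,
    Named("n_edges_12") = n12);
  if (record_weight_snapshots) out["weight_snapshots"] = snap;
  return out;
}
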