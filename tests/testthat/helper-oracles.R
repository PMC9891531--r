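# Independent oracles used across the suite. These are deliberately naive
# (event-by-event, brute-force) implementations kept separate from the
# package's vectorized / compiled code paths.

# Event-level pair-based STDP rule on two perfectly periodic spike trains:
# pre fires at k*T, post at dt_lag + k*T. At every spike event the neuron
# pairs with the partner's most recent strictly-earlier spike and the weight
# changes by A± * sgn(lag + xi) * exp(-|lag + xi| / tau±), lag = t_post - t_pre.
# Returns the accumulated change per period (no bounds).
stdp_event_oracle <- function(dt_lag, T_period, stdp, xi, n_periods = 200) {
  pre <- (0:(n_periods - 1)) * T_period
  post <- dt_lag + pre
  ev <- rbind(data.frame(t = pre, is_pre = TRUE),
              data.frame(t = post, is_pre = FALSE))
  ev <- ev[order(ev$t, ev$is_pre), ]
  total <- 0
  last_pre <- -Inf
  last_post <- -Inf
  apply_rule <- function(lag) {
    d <- lag + xi
    if (d > 0) stdp$a_plus * exp(-d / stdp$tau_plus)
    else if (d < 0) -stdp$a_minus * exp(d / stdp$tau_minus)
    else 0
  }
  for (i in seq_len(nrow(ev))) {
    t <- ev$t[i]
    if (ev$is_pre[i]) {
      if (last_post > -Inf && last_post < t) total <- total + apply_rule(last_post - t)
      last_pre <- t
    } else {
      if (last_pre > -Inf && last_pre < t) total <- total + apply_rule(t - last_pre)
      last_post <- t
    }
  }
  total / n_periods
}

# Direct unrolling of the pulse-onset recurrence, one event at a time.
pulse_oracle <- function(T_pulse, k, T_off, t_start, T_stim) {
  out <- c()
  t <- t_start
  i <- 1
  repeat {
    if (t > t_start + T_stim + 1e-9) break
    out <- c(out, t)
    t <- t + if (i %% k == 0) T_off else T_pulse
    i <- i + 1
  }
  out
}

# A tiny motif network in which both neurons fire only when pulsed: no
# background drive, weights small enough (or scale small enough) that
# synaptic input alone never reaches threshold.
forced_motif <- function(w0 = 0.3, xi_abs = 10, seed = 1) {
  build_network(network_spec(
    module_1 = module_spec(n = 1, frac_ex = 1, p_intra = 0),
    module_2 = module_spec(n = 1, frac_ex = 1, p_intra = 0),
    p_inter = 1, w_inter_mean = w0, w_inter_sd = 0,
    delays_inter = delay_spec(0.5, 0.5 + xi_abs),
    current_scale = 1e-6, seed = seed))
}

# Simulate the forced motif under exact periodic stimulation and return the
# signed weight drift per direction.
forced_motif_drift <- function(delta_t, T_period, xi_abs, w0 = 0.3,
                               n_periods = 40, stdp = stdp_params()) {
  net <- forced_motif(w0 = w0, xi_abs = xi_abs)
  protocol <- stim_protocol(K = 1.5, T_pulse = T_period, delta_t = delta_t,
                            pattern = "continuous", t_start = 50,
                            T_stim = n_periods * T_period)
  res <- simulate_network(net, NULL, protocol,
                          sim_config(t_total = 50 + (n_periods + 2) * T_period,
                                     seed = 1, stdp = stdp))
  pe <- res$plastic_edges
  c(g21 = pe$weight_final[pe$from_module == 1] - pe$weight_initial[pe$from_module == 1],
    g12 = pe$weight_final[pe$from_module == 2] - pe$weight_initial[pe$from_module == 2])
}

# Pooled (both directions) mean plastic coupling from a coupling series.
pooled_coupling <- function(res, window) {
  sel <- res$coupling$time_ms >= window[1] & res$coupling$time_ms <= window[2]
  mean(c(res$coupling$g21[sel], res$coupling$g12[sel]))
}
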