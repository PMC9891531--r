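test_that("a suprathreshold pulse fires a resting neuron within one step", {
  net <- forced_motif()
  p <- stim_protocol(K = 1.5, T_pulse = 1000, k_pulses = 1, T_off = 1000,
                     T_stim = 1, t_start = 100, delta_t = 0.5)
  res <- simulate_network(net, NULL, p, sim_config(t_total = 300, seed = 1))
  sp <- res$spikes
  expect_equal(nrow(sp), 2)
  expect_lt(abs(sp$time_ms[sp$module == 1] - 100), 0.11)
  expect_lt(abs(sp$time_ms[sp$module == 2] - 100.5), 0.11)
  # no input, no spikes
  quiet <- simulate_network(net, NULL, NULL, sim_config(t_total = 200, seed = 1))
  expect_equal(nrow(quiet$spikes), 0)
})

test_that("a presynaptic spike reaches the partner exactly one delay later", {
  # strong coupling, no drive: the pulse-evoked spike of each neuron must
  # ignite the partner only after tau_d + tau_a
  for (tau in list(c(0.5, 10.5), c(0, 0))) {
    net <- build_network(network_spec(
      module_1 = module_spec(n = 1, frac_ex = 1, p_intra = 0),
      module_2 = module_spec(n = 1, frac_ex = 1, p_intra = 0),
      p_inter = 1, w_inter_mean = 1, w_inter_sd = 0,
      delays_inter = delay_spec(tau[1], tau[2]),
      current_scale = 10, seed = 1))
    p <- stim_protocol(K = 1.5, T_pulse = 1000, k_pulses = 1, T_off = 1000,
                       T_stim = 1, t_start = 50, delta_t = 0)
    res <- simulate_network(net, NULL, p,
                            sim_config(t_total = 200, seed = 1,
                                       plasticity = FALSE))
    sp1 <- sort(res$spikes$time_ms[res$spikes$neuron == 1])
    total_delay <- sum(tau)
    expect_equal(sp1[1], 50, tolerance = 1e-9)
    # echo spike: first possible effect is one step after the delay
    expect_gte(sp1[2], 50 + total_delay + 0.1 - 1e-9)
    expect_lt(sp1[2], 50 + total_delay + 5)
  }
})

test_that("plastic weights respect hard bounds at every snapshot", {
  net <- build_network(network_spec(n = 30, seed = 2))
  p <- stim_protocol(T_pulse = 30, delta_t = 5, t_start = 500, T_stim = 1000)
  res <- simulate_network(net, drive_spec(), p,
                          sim_config(t_total = 2000, seed = 3,
                                     record_weight_snapshots = TRUE))
  w <- res$weight_snapshots
  expect_true(all(w >= 0.05 - 1e-12))
  expect_true(all(w <= 1 + 1e-12))
  expect_true(all(res$plastic_edges$weight_final >= 0.05 - 1e-12))
  # saturation at the ceiling: (21, 45) potentiates both directions, so a
  # weight starting at g_max must stay there (up to one trailing pairing)
  drift <- forced_motif_drift(21, 45, xi_abs = 10, w0 = 1, n_periods = 20)
  expect_equal(unname(drift), c(0, 0), tolerance = 0.002)
})

test_that("identical seeds give identical results, different seeds differ", {
  net <- build_network(network_spec(n = 30, seed = 2))
  cfg <- sim_config(t_total = 800, seed = 5)
  a <- simulate_network(net, drive_spec(), NULL, cfg)
  b <- simulate_network(net, drive_spec(), NULL, cfg)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$coupling, b$coupling)
  c <- simulate_network(net, drive_spec(), NULL,
                        sim_config(t_total = 800, seed = 6))
  expect_false(identical(a$spikes, c$spikes))
})

test_that("online STDP updates match direct substitution into the rule", {
  # one forced pre/post pair: lag +10 ms at the synapse gives A+ e^{-1}
  tab <- stdp_params()
  drift <- forced_motif_drift(20, 200, xi_abs = 10, w0 = 0.3, n_periods = 30)
  # per period, direction 1->2: potentiation at delta = 10 plus depression at
  # the complementary lag 190 (negligible); direction 2->1: lag 180, delta =
  # 170 -> negligible potentiation, depression at 30
  per_21 <- tab$a_plus * exp(-10 / tab$tau_plus) -
    tab$a_minus * exp(-190 / tab$tau_minus)
  per_12 <- tab$a_plus * exp(-170 / tab$tau_plus) -
    tab$a_minus * exp(-30 / tab$tau_minus)
  expect_equal(unname(drift["g21"]) / 30, per_21, tolerance = 0.05)
  expect_equal(unname(drift["g12"]) / 30, per_12, tolerance = 0.05)
})

test_that("forced periodic firing drifts with the sign the theory predicts", {
  tab <- stdp_params()
  grid <- expand.grid(frac = c(0.2, 0.5, 0.8), T_period = c(20, 30, 45),
                      xi_abs = c(0, 10))
  n_checked <- 0
  for (i in seq_len(nrow(grid))) {
    T_period <- grid$T_period[i]
    delta_t <- grid$frac[i] * T_period
    xi <- -grid$xi_abs[i]
    th21 <- net_change(delta_t, T_period, tab, xi)
    th12 <- net_change(T_period - delta_t, T_period, tab, xi)
    if (min(abs(th21), abs(th12)) < 2e-4) next # too close to a boundary
    deltas <- ((c(delta_t, T_period - delta_t) + xi) %% T_period)
    if (min(deltas, T_period - deltas) < 1) next # degenerate coincidence
    drift <- forced_motif_drift(delta_t, T_period, grid$xi_abs[i],
                                n_periods = 30)
    expect_equal(sign(unname(drift["g21"])), sign(th21),
                 label = sprintf("g21 at dt=%g T=%g xi=%g", delta_t, T_period, xi))
    expect_equal(sign(unname(drift["g12"])), sign(th12),
                 label = sprintf("g12 at dt=%g T=%g xi=%g", delta_t, T_period, xi))
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 8)
})

test_that("halving the integration step barely changes a deterministic run", {
  run_at <- function(dt) {
    net <- forced_motif(w0 = 0.5)
    p <- stim_protocol(K = 1.5, T_pulse = 30, delta_t = 5,
                       pattern = "continuous", t_start = 50, T_stim = 1200)
    res <- simulate_network(net, NULL, p,
                            sim_config(t_total = 1400, dt = dt, seed = 1))
    utils::tail(res$coupling$g21, 1)
  }
  expect_equal(run_at(0.1), run_at(0.05), tolerance = 0.01)
})

test_that("an isolated module fires irregularly and asynchronously", {
  net <- build_network(network_spec(n = 200, p_inter = 0, seed = 1))
  res <- simulate_network(net, drive_spec(), NULL,
                          sim_config(t_total = 4000, seed = 2,
                                     plasticity = FALSE))
  sp <- res$spikes[res$spikes$module == 1 & res$spikes$time_ms > 1000, ]
  rate <- nrow(sp) / 200 / 3
  expect_gt(rate, 1)
  expect_lt(rate, 30)
  cv <- cv_isi(sp, which(net$module == 1), c(1000, 4000))
  expect_gt(stats::median(cv$cv, na.rm = TRUE), 0.4)
  act <- population_activity(res$spikes, 1, 200, 5, c(1000, 4000))
  expect_lt(pop_fano(act), 0.05)
})

test_that("glance and tidy expose the run summary and the spike record", {
  net <- build_network(network_spec(n = 20, seed = 1))
  res <- simulate_network(net, drive_spec(), NULL,
                          sim_config(t_total = 500, seed = 1))
  g <- glance(res)
  expect_equal(g$n_neurons, 40)
  expect_equal(g$n_spikes, nrow(tidy(res)))
  expect_true(all(diff(tidy(res)$time_ms) >= 0))
  fr <- firing_rate_series(res, bin_ms = 100)
  expect_equal(nrow(fr), 2 * 5)
  expect_true(all(fr$rate_hz >= 0))
})
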