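# Hand-sized spike fixtures built in code
spk <- function(time_ms, neuron, module = 1) {
  tibble::tibble(time_ms = time_ms, neuron = neuron, module = module)
}

test_that("mean coupling equals the direct sum on a tiny fixture", {
  net <- build_network(network_spec(
    module_1 = module_spec(n = 2, frac_ex = 1, p_intra = 0),
    module_2 = module_spec(n = 2, frac_ex = 1, p_intra = 0),
    p_inter = 1, w_inter_mean = 0.5, w_inter_sd = 0, seed = 1))
  # direct sum oracle: edges from module 1 feed neurons 3,4
  from1 <- net$plastic & outer(net$module == 2, net$module == 1)
  expect_equal(mean_coupling(net, "21"),
               sum(net$weights[from1]) / sum(from1))
  expect_equal(mean_coupling(net, "21", normalize = "per_neuron"),
               sum(net$weights[from1]) / 2)
  # all weights at g_max
  net$weights[net$plastic] <- 1
  expect_equal(mean_coupling(net, "21"), 1)
  expect_equal(mean_coupling(net, "12", normalize = "per_neuron"),
               4 * 1 / 2) # edge count * g_max / N
})

test_that("population activity counts spikes per bin as a population fraction", {
  expect_equal(population_activity(spk(numeric(0), integer(0)), 1, 10,
                                   bin_ms = 1, window = c(0, 5))$activity,
               rep(0, 5))
  # every neuron firing once in one bin gives activity 1
  a <- population_activity(spk(rep(2.5, 10), 1:10), 1, 10, bin_ms = 1,
                           window = c(0, 5))
  expect_equal(a$activity, c(0, 0, 1, 0, 0))
  # Poisson expectation: mean activity ~ rate * bin width
  set.seed(1)
  n <- 20; rate <- 0.02 # spikes per ms
  t <- sort(runif(rpois(1, n * rate * 10000), 0, 10000))
  a <- population_activity(spk(t, sample(1:n, length(t), TRUE)), 1, n,
                           bin_ms = 5, window = c(0, 10000))
  expect_equal(mean(a$activity), rate * 5, tolerance = 0.1)
})

test_that("pairwise correlations recover perfect and absent dependence", {
  t1 <- cumsum(rexp(200, 0.02))
  both <- dplyr::bind_rows(spk(t1, 1), spk(t1, 2))
  r <- pairwise_correlations(both, 1, 1:2, window = c(0, max(t1)), bin_ms = 50)
  expect_equal(r$r, 1)
  set.seed(2)
  ind <- purrr::map_dfr(1:8, function(i) spk(sort(runif(400, 0, 20000)), i))
  r2 <- pairwise_correlations(ind, 1, 1:8, window = c(0, 20000), bin_ms = 50)
  expect_equal(nrow(r2), choose(8, 2))
  expect_lt(abs(mean(r2$r)), 0.05)
  # zero-variance neurons are excluded
  r3 <- pairwise_correlations(spk(c(1, 2), c(1, 1)), 1, 1:2,
                              window = c(0, 100))
  expect_equal(nrow(r3), 0)
})

test_that("CV of ISIs separates periodic, Poisson and bursty firing", {
  per <- cv_isi(spk(seq(0, 1000, by = 20), 1))
  expect_equal(per$cv, 0)
  set.seed(3)
  pois <- cv_isi(spk(cumsum(rexp(2000, 0.05)), 1))
  expect_equal(pois$cv, 1, tolerance = 0.1)
  # 10-spike two-state bursty train, hand-computed intervals
  t_burst <- c(0, 2, 4, 6, 8, 100, 102, 104, 106, 108)
  isi <- diff(t_burst)
  expect_equal(cv_isi(spk(t_burst, 1))$cv, sd(isi) / mean(isi))
  # fewer than three spikes is undefined
  expect_true(is.na(cv_isi(spk(c(1, 2), 1))$cv))
})

test_that("population Fano factor ranks synchrony at fixed mean rate", {
  const <- tibble::tibble(time_ms = 0:99, activity = rep(0.2, 100))
  expect_equal(pop_fano(const), 0)
  # synchronized: all spikes in shared volleys; asynchronous: spread out
  n <- 50
  sync <- spk(rep(seq(25, 975, by = 50), each = n), rep(1:n, 20))
  set.seed(4)
  async <- spk(runif(n * 20, 0, 1000), sample(1:n, n * 20, TRUE))
  a_sync <- population_activity(sync, 1, n, 5, c(0, 1000))
  a_async <- population_activity(async, 1, n, 5, c(0, 1000))
  expect_equal(mean(a_sync$activity), mean(a_async$activity), tolerance = 0.01)
  expect_gt(pop_fano(a_sync), 10 * pop_fano(a_async))
  # independent Poisson counts: variance/mean of A = 1/N
  set.seed(5)
  pois <- spk(runif(20000, 0, 20000), sample(1:n, 20000, TRUE))
  a_p <- population_activity(pois, 1, n, 5, c(0, 20000))
  expect_equal(pop_fano(a_p), 1 / n, tolerance = 0.1)
  expect_error(pop_fano(tibble::tibble(activity = rep(0, 10))), "zero mean")
})

test_that("peak frequency finds a 20 Hz modulation and rejects flat series", {
  t <- seq(0, 1999)
  act <- tibble::tibble(time_ms = t,
                        activity = 0.1 + 0.05 * sin(2 * pi * 20 * t / 1000))
  expect_equal(peak_frequency(act), 20, tolerance = 0.05)
  expect_true(is.na(peak_frequency(tibble::tibble(time_ms = t,
                                                  activity = rep(0.3, 2000)))))
  short <- tibble::tibble(time_ms = 0:99, activity = runif(100))
  expect_error(peak_frequency(short, band = c(1, 100)), "too short")
})

test_that("phase lags concentrate at 0 for identical and pi for anti-phase series", {
  t <- seq(0, 1999)
  osc <- function(phase) tibble::tibble(
    time_ms = t, activity = pmax(0, sin(2 * pi * 25 * t / 1000 + phase))^3)
  same <- phase_lags(osc(0), osc(0))
  expect_lt(abs(median(same$dphi)), 0.2)
  anti <- phase_lags(osc(0), osc(pi))
  expect_lt(abs(median(anti$dphi) - pi), 0.2)
  flat <- tibble::tibble(time_ms = t, activity = rep(0.1, 2000))
  expect_error(phase_lags(flat, flat), "peaks")
})

test_that("threshold topology keeps exactly the strong links", {
  net <- build_network(network_spec(n = 40, seed = 6))
  topo_lo <- threshold_topology(net, h = 0.0)
  expect_equal(topo_lo$binary, net$adjacency)
  topo_hi <- threshold_topology(net, h = 1.5)
  expect_equal(sum(topo_hi$binary), 0)
  topo <- threshold_topology(net, h = 0.3)
  expect_equal(unname(topo$binary), unname(net$adjacency & (net$weights >= 0.3)))
  expect_equal(sum(topo$degrees$in_degree), topo$n_plastic_surviving)
  expect_equal(sum(topo$degrees$out_degree), topo$n_plastic_surviving)
})

test_that("metrics_report aggregates the whole suite over a window", {
  net <- build_network(network_spec(n = 30, seed = 2))
  res <- simulate_network(net, drive_spec(), NULL,
                          sim_config(t_total = 2000, seed = 3))
  rep <- metrics_report(res, window = c(500, 2000))
  expect_equal(nrow(rep$summary), 2)
  expect_true(all(rep$summary$pff >= 0, na.rm = TRUE))
  expect_true(all(rep$correlations$r >= -1 & rep$correlations$r <= 1))
  expect_true(all(rep$cv$cv >= 0, na.rm = TRUE))
  expect_equal(rep$window, c(500, 2000))
})
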