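tab2 <- stdp_params() # A+ 0.008, A- 0.005, tau+ 10, tau- 20

test_that("net_change matches direct arithmetic at reference points", {
  # anti-phase firing without delays: both lags 15 on a 30 ms period
  expect_equal(net_change(15, 30, tab2, xi = 0),
               0.008 * exp(-15 / 10) - 0.005 * exp(-15 / 20))
  # zero synaptic lag forces the potentiation exponential to 1
  expect_equal(net_change(10, 30, tab2, xi = -10),
               0.008 - 0.005 * exp(-30 / 20))
  expect_equal(net_change(0, 45, tab2, xi = 0),
               0.008 - 0.005 * exp(-45 / 20))
  # negative synaptic lag wraps into the period: delta = 25 for dt 5, xi -10
  expect_equal(net_change(5, 30, tab2, xi = -10),
               0.008 * exp(-25 / 10) - 0.005 * exp(-5 / 20))
  expect_error(net_change(5, -1, tab2), "positive")
  expect_error(net_change(NaN, 30, tab2), "finite")
})

test_that("classify_pair reproduces the reference regime points", {
  expect_equal(as.character(classify_pair(15, 30, tab2, 0)$label), "decoupled")
  # with a 10 ms effective delay a small 5 ms shift decouples both directions
  cp <- classify_pair(5, 30, tab2, xi_from_abs(10))
  expect_equal(as.character(cp$label), "decoupled")
  expect_lt(cp$dg_21, 0)
  expect_lt(cp$dg_12, 0)
  # spontaneous near-anti-phase firing at (21, 45) potentiates both synapses
  expect_equal(as.character(classify_pair(21, 45, tab2, -10)$label),
               "bidirectional")
  # out-of-range time shifts are flagged, not classified
  expect_equal(as.character(classify_pair(35, 30, tab2, 0)$label),
               "not_applicable")
  expect_equal(as.character(classify_pair(0, 30, tab2, 0)$label),
               "not_applicable")
})

test_that("direction swap is the dt -> T - dt reflection at xi = 0", {
  for (T_period in c(20, 30, 45, 60)) {
    dts <- seq(1, T_period - 1, by = 1)
    a <- classify_pair(dts, T_period, tab2, 0)
    b <- classify_pair(T_period - dts, T_period, tab2, 0)
    expect_equal(as.character(a$label), as.character(b$label))
    expect_equal(a$dg_21, b$dg_12)
  }
})

test_that("classify_pair agrees in sign with the event-level pairing oracle", {
  grid <- expand.grid(T_period = c(20, 30, 45, 60),
                      frac = c(0.15, 0.3, 0.5, 0.7, 0.9),
                      xi = c(0, -5, -10))
  n_checked <- 0
  for (i in seq_len(nrow(grid))) {
    T_period <- grid$T_period[i]
    dt_lag <- grid$frac[i] * T_period
    xi <- grid$xi[i]
    delta <- (dt_lag + xi) %% T_period
    if (min(delta, T_period - delta) < 1) next # degenerate coincidence pairing
    theory <- net_change(dt_lag, T_period, tab2, xi)
    oracle <- stdp_event_oracle(dt_lag, T_period, tab2, xi)
    if (abs(theory) < 1e-5 || abs(oracle) < 1e-5) next # boundary cells
    expect_equal(sign(theory), sign(oracle),
                 label = sprintf("sign at dt=%g T=%g xi=%g", dt_lag, T_period, xi))
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 40)
})

test_that("phase_map flags the infeasible region and is reflection-symmetric", {
  pm <- phase_map(seq(1, 59), seq(10, 60), tab2, xi = 0)
  bad <- pm$delta_t >= pm$T_period
  expect_true(all(pm$label[bad] == "not_applicable"))
  expect_true(all(pm$label[!bad] != "not_applicable"))
  # mirror symmetry about dt = T/2
  ok <- dplyr::filter(pm, label != "not_applicable")
  flipped <- dplyr::mutate(ok, delta_t = T_period - delta_t)
  joined <- dplyr::inner_join(ok, flipped, by = c("delta_t", "T_period"))
  expect_gt(nrow(joined), 1000)
  expect_equal(as.character(joined$label.x), as.character(joined$label.y))
  # the decoupled band straddles dt = T/2
  dec <- dplyr::filter(ok, label == "decoupled")
  mid <- dplyr::summarise(dplyr::group_by(dec, T_period),
                          mid = mean(delta_t) / dplyr::first(T_period))
  expect_true(all(abs(mid$mid - 0.5) < 1e-8))
  expect_error(phase_map(numeric(0), 1:5, tab2), "non-empty")
  expect_error(phase_map(c(2, 1), 1:5, tab2), "increasing")
})

test_that("a nonzero effective delay reshapes the map", {
  dt_axis <- seq(1, 29)
  pm0 <- phase_map(dt_axis, seq(10, 60), tab2, xi = 0)
  pm5 <- phase_map(dt_axis, seq(10, 60), tab2, xi = -5)
  expect_false(identical(as.character(pm0$label), as.character(pm5$label)))
  # with delays, small time shifts become decoupling for some periods
  small <- dplyr::filter(pm5, delta_t <= 5,
                         label == "decoupled")
  expect_gt(nrow(small), 0)
  small0 <- dplyr::filter(pm0, delta_t <= 5,
                          label == "decoupled")
  expect_equal(nrow(small0), 0)
})

test_that("raising the potentiation amplitude never demotes bidirectional cells", {
  dt_axis <- seq(2, 28, by = 2)
  T_axis <- seq(10, 60, by = 5)
  rank <- c(decoupled = 0, unidirectional = 1, bidirectional = 2)
  for (xi in c(0, -10)) {
    lo <- phase_map(dt_axis, T_axis, stdp_params(a_plus = 0.006), xi)
    hi <- phase_map(dt_axis, T_axis, stdp_params(a_plus = 0.010), xi)
    ok <- lo$label != "not_applicable"
    expect_true(all(rank[as.character(hi$label[ok])] >=
                      rank[as.character(lo$label[ok])]))
  }
})

test_that("stdp_ratio_map reproduces the corner regimes", {
  rm <- stdp_ratio_map(c(0.5, 1.6, 2), c(0.5, 1.6, 2),
                       delta_t = 5, T_period = 30, xi = -10)
  lab <- function(a, t) as.character(
    rm$label[rm$a_ratio == a & rm$tau_ratio == t])
  expect_equal(lab(0.5, 0.5), "decoupled")
  expect_equal(lab(2, 2), "bidirectional")
  # the reference stimulation point (Table-2 ratios) decouples
  expect_equal(lab(1.6, 0.5), "decoupled")
  # vanishing potentiation decouples at any time-constant ratio
  rm0 <- stdp_ratio_map(1e-6, c(0.5, 1, 2), delta_t = 5, T_period = 30,
                        xi = -10)
  expect_true(all(rm0$label == "decoupled"))
})

test_that("the depression-dominated predicate follows A tau products", {
  expect_true(is_depression_dominated(stdp_params())) # 0.08 < 0.10
  expect_false(is_depression_dominated(stdp_params(a_plus = 0.011)))
  expect_error(stdp_params(a_plus = -1), "positive")
})
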