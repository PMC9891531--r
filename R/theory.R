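#' Net synaptic change over one firing period
#'
#' Closed-form per-period weight change for a plastic synapse between two
#' neurons firing periodically with period `T`, where the postsynaptic neuron
#' lags the presynaptic one by `dt_lag` at the soma. The pairing perceived at
#' the synapse is shifted by the effective delay `xi = tau_d - tau_a`: the
#' synapse-local lag is `delta = (dt_lag + xi) mod T`, reduced into `[0, T)`.
#' Over one period the synapse experiences one potentiation pairing at lag
#' `delta` and one depression pairing at the complementary lag `T - delta`,
#' giving
#'
#'   `dg = A+ exp(-delta / tau+) - A- exp(-(T - delta) / tau-)`.
#'
#' The reduction into `[0, T)` is what makes the formula valid for negative
#' `dt_lag + xi` (postsynaptic back-propagation arriving before the
#' presynaptic volley), the generic situation for long-range projections.
#'
#' @param dt_lag Somatic spike lag of post relative to pre, ms. Vectorized.
#'   Any real value is accepted; it is reduced modulo `T`.
#' @param T_period Firing period, ms (> 0).
#' @param stdp An [stdp_params()] object.
#' @param xi Signed effective delay `tau_d - tau_a`, ms (use [xi_from_abs()]
#'   to convert a magnitude).
#'
#' @return Numeric vector of signed per-period weight changes (dimensionless).
#' @examples
#' tab <- stdp_params()
#' net_change(15, 30, tab, xi = 0)            # anti-phase firing: depression
#' net_change(c(5, 25), 30, tab, xi = -10)    # both directions at dt = 5 ms
#' @export
net_change <- function(dt_lag, T_period, stdp, xi = 0) {
  stopifnot(inherits(stdp, "stdp_params"))
  if (!is.numeric(T_period) || length(T_period) != 1 || !is.finite(T_period) ||
      T_period <= 0) {
    stop("`T_period` must be a single positive number (ms)", call. = FALSE)
  }
  if (!is.numeric(dt_lag) || any(!is.finite(dt_lag))) {
    stop("`dt_lag` must be finite numeric", call. = FALSE)
  }
  delta <- (dt_lag + xi) %% T_period
  stdp$a_plus * exp(-delta / stdp$tau_plus) -
    stdp$a_minus * exp(-(T_period - delta) / stdp$tau_minus)
}

label_from_signs <- function(dg_fwd, dg_rev) {
  dplyr::case_when(
    dg_fwd < 0 & dg_rev < 0 ~ "decoupled",
    dg_fwd > 0 & dg_rev > 0 ~ "bidirectional",
    .default = "unidirectional"
  )
}

region_levels <- c("decoupled", "unidirectional", "bidirectional", "not_applicable")

#' Classify the connectivity regime of a reciprocal pair
#'
#' For two neurons stimulated periodically with period `T_period` and time
#' shift `delta_t` (neuron 1 leading), the forward synapse (1 -> 2, strength
#' g21) sees a somatic lag of `delta_t` and the reverse synapse (2 -> 1, g12)
#' a lag of `T_period - delta_t`. The signs of the two per-period net changes
#' ([net_change()]) determine the emergent connectivity: both negative gives
#' a decoupled pair, both positive a bidirectionally potentiated pair, mixed
#' signs a unidirectional motif. A change of exactly zero (a measure-zero
#' boundary) is assigned to neither direction: the label follows the non-zero
#' direction if one exists, otherwise "unidirectional" by convention.
#'
#' @param delta_t Stimulation time shift, ms. Vectorized. Must satisfy
#'   `0 < delta_t < T_period`; values outside give `"not_applicable"`.
#' @inheritParams net_change
#' @return A tibble with columns `delta_t`, `T_period`, `dg_21`, `dg_12`,
#'   `label` (factor with levels decoupled, unidirectional, bidirectional,
#'   not_applicable).
#' @examples
#' classify_pair(15, 30, stdp_params(), xi = 0)        # decoupled
#' classify_pair(21, 45, stdp_params(), xi = -10)      # bidirectional
#' @export
classify_pair <- function(delta_t, T_period, stdp, xi = 0) {
  stopifnot(inherits(stdp, "stdp_params"))
  ok <- delta_t > 0 & delta_t < T_period
  dg_21 <- ifelse(ok, net_change(delta_t, T_period, stdp, xi), NA_real_)
  dg_12 <- ifelse(ok, net_change(T_period - delta_t, T_period, stdp, xi), NA_real_)
  label <- ifelse(ok, label_from_signs(dg_21, dg_12), "not_applicable")
  tibble::tibble(
    delta_t = delta_t,
    T_period = T_period,
    dg_21 = dg_21,
    dg_12 = dg_12,
    label = factor(label, levels = region_levels)
  )
}

#' Phase map of emergent pairwise connectivity over (delta_t, T)
#'
#' Evaluates [classify_pair()] on a dense grid of time shifts and firing
#' periods, producing the theoretical phase diagram of emergent two-neuron
#' connectivity. Cells violating `0 < delta_t < T` are flagged
#' `"not_applicable"`.
#'
#' @param dt_axis Strictly increasing grid of time shifts, ms (values > 0;
#'   a leading 0 is tolerated and classified not-applicable).
#' @param T_axis Strictly increasing grid of firing periods, ms (> 0).
#' @inheritParams net_change
#' @return A tibble (class `phase_map`) in long format with one row per grid
#'   cell: `delta_t`, `T_period`, `dg_21`, `dg_12`, `label`. The STDP
#'   parameters and `xi` are attached as attributes.
#' @examples
#' pm <- phase_map(seq(1, 29), seq(10, 60), stdp_params(), xi = 0)
#' dplyr::count(pm, label)
#' @export
phase_map <- function(dt_axis, T_axis, stdp = stdp_params(), xi = 0) {
  check_axis(dt_axis, "dt_axis", min_allowed = 0)
  check_axis(T_axis, "T_axis", min_allowed = .Machine$double.eps)
  grid <- tidyr::expand_grid(T_period = T_axis, delta_t = dt_axis)
  out <- purrr::map_dfr(
    split(grid, grid$T_period),
    function(g) classify_pair(g$delta_t, g$T_period[1], stdp, xi)
  )
  out <- dplyr::arrange(out, .data$T_period, .data$delta_t)
  structure(out, class = c("phase_map", class(out)), stdp = stdp, xi = xi)
}

check_axis <- function(x, name, min_allowed) {
  if (length(x) == 0 || !is.numeric(x)) {
    stop(sprintf("`%s` must be a non-empty numeric vector", name), call. = FALSE)
  }
  if (any(diff(x) <= 0) || any(x < min_allowed)) {
    stop(sprintf("`%s` must be strictly increasing and non-negative", name),
         call. = FALSE)
  }
  invisible(x)
}

#' Map emergent connectivity over STDP amplitude and time-constant ratios
#'
#' Holds the depression parameters and the stimulation point fixed and varies
#' the potentiation/depression amplitude ratio `A+/A-` and time-constant
#' ratio `tau+/tau-`, classifying the emergent pairwise connectivity at each
#' ratio pair. The low/low corner is decoupled (weak, short-window
#' potentiation loses everywhere), the high/high corner bidirectional.
#'
#' @param a_ratio_axis Increasing positive grid of `A+/A-` ratios.
#' @param tau_ratio_axis Increasing positive grid of `tau+/tau-` ratios.
#' @param delta_t,T_period Stimulation point, ms.
#' @param xi Signed effective delay, ms.
#' @param a_minus,tau_minus Fixed depression amplitude and time constant.
#' @return A tibble with `a_ratio`, `tau_ratio`, `dg_21`, `dg_12`, `label`.
#' @examples
#' stdp_ratio_map(c(0.5, 1.6, 2), c(0.5, 1.6, 2), delta_t = 5, T_period = 30,
#'                xi = -10)
#' @export
stdp_ratio_map <- function(a_ratio_axis, tau_ratio_axis, delta_t, T_period,
                           xi = 0, a_minus = 0.005, tau_minus = 20) {
  check_axis(a_ratio_axis, "a_ratio_axis", min_allowed = .Machine$double.eps)
  check_axis(tau_ratio_axis, "tau_ratio_axis", min_allowed = .Machine$double.eps)
  stopifnot(delta_t > 0, delta_t < T_period)
  grid <- tidyr::expand_grid(a_ratio = a_ratio_axis, tau_ratio = tau_ratio_axis)
  purrr::pmap_dfr(grid, function(a_ratio, tau_ratio) {
    stdp <- stdp_params(a_plus = a_ratio * a_minus, a_minus = a_minus,
                        tau_plus = tau_ratio * tau_minus, tau_minus = tau_minus)
    cls <- classify_pair(delta_t, T_period, stdp, xi)
    tibble::tibble(a_ratio = a_ratio, tau_ratio = tau_ratio,
                   dg_21 = cls$dg_21, dg_12 = cls$dg_12, label = cls$label)
  })
}

#' @rdname phase_map
#' @param x A `phase_map`.
#' @export
glance.phase_map <- function(x, ...) {
  applicable <- dplyr::filter(x, .data$label != "not_applicable")
  tibble::tibble(
    n_cells = nrow(x),
    n_applicable = nrow(applicable),
    frac_decoupled = mean(applicable$label == "decoupled"),
    frac_unidirectional = mean(applicable$label == "unidirectional"),
    frac_bidirectional = mean(applicable$label == "bidirectional"),
    xi = attr(x, "xi")
  )
}

#' Plot a connectivity phase map
#'
#' Tile plot of the emergent pairwise connectivity regimes in the
#' (time shift, period) plane, using the conventional colours: decoupled in
#' blue, unidirectional in orange, bidirectional in red.
#'
#' @param object A [phase_map()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phase_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$delta_t, .data$T_period,
                                       fill = .data$label)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(
      decoupled = "#2166ac", unidirectional = "#f4a582",
      bidirectional = "#b2182b", not_applicable = "grey85"
    ), drop = FALSE) +
    ggplot2::labs(x = expression(Delta * t ~ "(ms)"), y = "T (ms)",
                  fill = "regime",
                  title = sprintf("Emergent pairwise connectivity (xi = %g ms)",
                                  attr(object, "xi"))) +
    ggplot2::theme_minimal()
}
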