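#' Membrane and synapse parameters of the LIF neurons
#'
#' Dimensionless leaky integrate-and-fire dynamics: the membrane potential
#' relaxes with time constant `tau_m`, fires on reaching `v_th` and resets to
#' `v_r`; every synaptic arrival is filtered through an exponential trace
#' with time constant `tau_s`.
#'
#' After a spike the potential is clamped at `v_r` for an absolute
#' refractory period `tau_ref`, which bounds single-neuron rates and lets
#' recurrent volleys terminate.
#'
#' @param tau_m Membrane time constant, ms.
#' @param v_th Firing threshold (dimensionless).
#' @param v_r Reset potential (dimensionless).
#' @param tau_s Synaptic trace time constant, ms.
#' @param tau_ref Absolute refractory period, ms (integer multiple of the
#'   integration step).
#' @return A `neuron_params` list.
#' @export
neuron_params <- function(tau_m = 10, v_th = 1, v_r = 0, tau_s = 5,
                          tau_ref = 2) {
  stopifnot(tau_m > 0, tau_s > 0, v_th > v_r, tau_ref >= 0)
  structure(list(tau_m = tau_m, v_th = v_th, v_r = v_r, tau_s = tau_s,
                 tau_ref = tau_ref),
            class = "neuron_params")
}

#' Simulation configuration
#'
#' @param t_total Simulated duration, ms.
#' @param dt Integration step, ms. Must not exceed a tenth of the smallest
#'   membrane/synaptic time constant, and all transmission delays must be
#'   integer multiples of it.
#' @param seed RNG seed for the background drive; `NULL` uses the current
#'   RNG state.
#' @param record_every Interval between weight snapshots, ms.
#' @param record_weight_snapshots Keep the full plastic-weight vector at
#'   every snapshot (memory-heavy; the mean coupling per direction is always
#'   recorded).
#' @param neuron A [neuron_params()].
#' @param stdp An [stdp_params()]; the rule's effective delay xi is taken
#'   from the network's inter-module [delay_spec()].
#' @param plasticity Set `FALSE` to freeze all weights (control runs).
#' @return A `sim_config` list.
#' @export
sim_config <- function(t_total, dt = 0.1, seed = NULL, record_every = 10,
                       record_weight_snapshots = FALSE,
                       neuron = neuron_params(), stdp = stdp_params(),
                       plasticity = TRUE) {
  stopifnot(t_total > 0, dt > 0, inherits(neuron, "neuron_params"),
            inherits(stdp, "stdp_params"))
  if (dt > min(neuron$tau_s, neuron$tau_m) / 10) {
    stop("`dt` must be at most min(tau_s, tau_m)/10 for a stable Euler step",
         call. = FALSE)
  }
  if (record_every < dt) stop("`record_every` must be >= dt", call. = FALSE)
  structure(list(t_total = t_total, dt = dt, seed = seed,
                 record_every = record_every,
                 record_weight_snapshots = record_weight_snapshots,
                 neuron = neuron, stdp = stdp, plasticity = plasticity),
            class = "sim_config")
}

delay_to_steps <- function(tau_ms, dt, what) {
  steps <- tau_ms / dt
  if (abs(steps - round(steps)) > 1e-6) {
    stop(sprintf("%s delay (%g ms) must be an integer multiple of dt (%g ms)",
                 what, tau_ms, dt), call. = FALSE)
  }
  as.integer(round(steps))
}

#' Simulate the plastic two-module network
#'
#' Clock-driven forward-Euler integration of the full network: LIF membrane
#' dynamics, delayed synaptic transmission through exponential traces,
#' aggregate Poisson background drive, instantaneous stimulation kicks, and
#' online pair-based STDP with effective delay on the inter-module
#' excitatory-to-excitatory synapses (additive updates, hard bounds).
#' Deterministic for a fixed `config$seed`.
#'
#' @param connectivity A [build_network()] result.
#' @param drive A [drive_spec()] (`NULL` for no background input).
#' @param protocol A [stim_protocol()] or `NULL` for an unstimulated run.
#' @param config A [sim_config()].
#' @return A `sim_result` with elements
#'   * `spikes`: tibble `time_ms`, `neuron`, `module`, `excitatory`;
#'   * `coupling`: tibble `time_ms`, `g21`, `g12` — the per-edge mean plastic
#'     strength in each direction over time;
#'   * `connectivity_final`: the input connectivity with updated plastic
#'     weights;
#'   * `weight_snapshots` (optional): snapshot-by-edge matrix;
#'   * `protocol`, `drive`, `config`.
#' @examples
#' net <- build_network(network_spec(n = 20, seed = 1))
#' res <- simulate_network(net, drive_spec(), stim_protocol(
#'   t_start = 100, T_stim = 300), sim_config(t_total = 600, seed = 1))
#' res
#' @export
simulate_network <- function(connectivity, drive, protocol, config) {
  stopifnot(inherits(connectivity, "connectivity"), inherits(config, "sim_config"))
  if (!is.null(drive)) stopifnot(inherits(drive, "drive_spec"))
  if (!is.null(protocol)) stopifnot(inherits(protocol, "stim_protocol"))
  spec <- connectivity$spec
  n <- n_neurons(connectivity)
  dt <- config$dt
  n_steps <- as.integer(round(config$t_total / dt))

  edges <- which(connectivity$adjacency, arr.ind = TRUE)
  pl <- connectivity$plastic[edges]
  pre <- edges[, 2L] - 1L
  post <- edges[, 1L] - 1L
  w <- connectivity$weights[edges]

  s_delay <- delay_to_steps(spec$delays_intra$tau, dt, "intra-module")
  p_delay <- delay_to_steps(spec$delays_inter$tau, dt, "inter-module")

  rate_per_step <- if (is.null(drive)) rep(0, n) else {
    ifelse(connectivity$is_excitatory, drive$rate_ex_hz, drive$rate_in_hz) /
      1000 * dt
  }
  w_ext <- if (is.null(drive)) 0 else drive$w_ext

  if (is.null(protocol)) {
    p1 <- p2 <- integer(0)
    mask <- rep(FALSE, n)
    K <- 0
  } else {
    pt <- pulse_times(protocol)
    p1 <- as.integer(round(pt$time_ms[pt$signal == 1] / dt)) - 1L
    p2 <- as.integer(round(pt$time_ms[pt$signal == 2] / dt)) - 1L
    mask <- target_mask(protocol, connectivity)
    K <- protocol$K
  }

  raw <- with_seed(config$seed, sim_core(
    n = n, module = connectivity$module, is_ex = connectivity$is_excitatory,
    s_pre = pre[!pl], s_post = post[!pl], s_w = w[!pl],
    s_delay_steps = s_delay,
    p_pre = pre[pl], p_post = post[pl], p_w0 = w[pl],
    p_delay_steps = p_delay,
    drive_rate_per_step = rate_per_step, w_ext = w_ext,
    pulse_steps_1 = p1, pulse_steps_2 = p2, stim_mask = mask, stim_K = K,
    dt = dt, n_steps = n_steps,
    tau_m = config$neuron$tau_m, tau_s = config$neuron$tau_s,
    v_th = config$neuron$v_th, v_r = config$neuron$v_r,
    ref_steps = delay_to_steps(config$neuron$tau_ref, dt, "refractory"),
    a_plus = config$stdp$a_plus, a_minus = config$stdp$a_minus,
    tau_plus = config$stdp$tau_plus, tau_minus = config$stdp$tau_minus,
    xi = spec$delays_inter$xi, g_min = spec$g_min, g_max = spec$g_max,
    current_scale = spec$current_scale,
    plasticity_on = config$plasticity,
    record_every_steps = as.integer(round(config$record_every / dt)),
    record_weight_snapshots = config$record_weight_snapshots
  ))

  neuron_id <- raw$spike_neuron + 1L
  spikes <- tibble::tibble(
    time_ms = (raw$spike_step + 1L) * dt,
    neuron = neuron_id,
    module = connectivity$module[neuron_id],
    excitatory = connectivity$is_excitatory[neuron_id]
  )
  coupling <- tibble::tibble(time_ms = raw$rec_time,
                             g21 = raw$rec_g21, g12 = raw$rec_g12)
  conn_final <- connectivity
  pl_idx <- edges[pl, , drop = FALSE]
  conn_final$weights[pl_idx] <- raw$plastic_w_final

  out <- list(spikes = spikes, coupling = coupling,
              connectivity_final = conn_final,
              plastic_edges = tibble::tibble(
                pre_id = pre[pl] + 1L, post_id = post[pl] + 1L,
                from_module = connectivity$module[pre[pl] + 1L],
                weight_initial = w[pl], weight_final = raw$plastic_w_final),
              protocol = protocol, drive = drive, config = config)
  if (config$record_weight_snapshots) out$weight_snapshots <- raw$weight_snapshots
  structure(out, class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  g <- utils::tail(x$coupling, 1)
  cat(sprintf(
    "<sim_result> %g ms simulated, %d spikes; final coupling G21 = %.3f, G12 = %.3f\n",
    x$config$t_total, nrow(x$spikes), g$g21, g$g12))
  invisible(x)
}

#' @rdname simulate_network
#' @param x A `sim_result`.
#' @param ... Unused.
#' @export
tidy.sim_result <- function(x, ...) x$spikes

#' @rdname simulate_network
#' @export
glance.sim_result <- function(x, ...) {
  last <- utils::tail(x$coupling, 1)
  dur_s <- x$config$t_total / 1000
  n <- n_neurons(x$connectivity_final)
  tibble::tibble(
    t_total_ms = x$config$t_total,
    n_neurons = n,
    n_spikes = nrow(x$spikes),
    mean_rate_hz = nrow(x$spikes) / n / dur_s,
    g21_initial = x$coupling$g21[1],
    g12_initial = x$coupling$g12[1],
    g21_final = last$g21,
    g12_final = last$g12
  )
}

#' Plot the inter-population mean coupling time course
#'
#' @param object A `sim_result`.
#' @param ... Unused.
#' @return A ggplot object; the stimulation epoch, when present, is shaded.
#' @export
autoplot.sim_result <- function(object, ...) {
  long <- tidyr::pivot_longer(object$coupling, c("g21", "g12"),
                              names_to = "direction", values_to = "G")
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$time_ms / 1000, .data$G,
                                          colour = .data$direction)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "mean inter-population coupling") +
    ggplot2::theme_minimal()
  if (!is.null(object$protocol)) {
    pr <- object$protocol
    p <- p + ggplot2::annotate("rect", xmin = pr$t_start / 1000,
                               xmax = (pr$t_start + pr$T_stim) / 1000,
                               ymin = -Inf, ymax = Inf, alpha = 0.15)
  }
  p
}

#' Mean firing-rate time course per module
#'
#' Bins the spike record and reports the mean single-neuron firing rate of
#' each module (optionally split by E/I class) over time.
#'
#' @param result A `sim_result`.
#' @param bin_ms Bin width, ms.
#' @param by_class Split by excitatory/inhibitory identity.
#' @return A tibble `time_ms`, `module`, (`excitatory`,) `rate_hz`.
#' @export
firing_rate_series <- function(result, bin_ms = 100, by_class = FALSE) {
  stopifnot(inherits(result, "sim_result"))
  conn <- result$connectivity_final
  counts_tbl <- tibble::tibble(module = conn$module,
                               excitatory = conn$is_excitatory)
  sizes <- dplyr::count(counts_tbl, .data$module, .data$excitatory,
                        name = "n_cells")
  if (!by_class) {
    sizes <- dplyr::count(counts_tbl, .data$module, name = "n_cells")
  }
  breaks <- seq(0, result$config$t_total, by = bin_ms)
  sp <- dplyr::mutate(result$spikes,
                      time_ms = breaks[findInterval(.data$time_ms, breaks,
                                                    rightmost.closed = TRUE)])
  keys <- if (by_class) c("time_ms", "module", "excitatory") else c("time_ms", "module")
  grid <- tidyr::expand_grid(time_ms = breaks[-length(breaks)],
                             dplyr::distinct(sizes[setdiff(names(sizes), "n_cells")]))
  sp |>
    dplyr::count(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::right_join(grid, by = keys) |>
    dplyr::left_join(sizes, by = setdiff(keys, "time_ms")) |>
    dplyr::mutate(rate_hz = dplyr::coalesce(.data$n, 0L) / .data$n_cells /
                    (bin_ms / 1000)) |>
    dplyr::select(dplyr::all_of(keys), "rate_hz") |>
    dplyr::arrange(dplyr::across(dplyr::all_of(keys)))
  }
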