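#' Scale presets for the figure-level experiments
#'
#' `"full"` uses the reference problem size (200 neurons per module, 10 s
#' spontaneous epoch, 5 s stimulation, 10 s post-stimulation analysis
#' window). `"reduced"` shrinks the network to 50 neurons per module and the
#' epochs to 2 s / 1 s / 2 s while preserving all proportions (excitatory
#' fraction, connection probabilities, the 4:1 weight ratio), which keeps
#' every headline effect qualitatively intact at a fraction of the cost.
#'
#' @param scale `"reduced"` or `"full"`.
#' @return A list `n`, `pre_ms`, `t_stim_ms`, `post_ms`, `window_ms`.
#' @export
experiment_scale <- function(scale = c("reduced", "full")) {
  scale <- match.arg(scale)
  if (scale == "full") {
    list(scale = scale, n = 200L, pre_ms = 10000, t_stim_ms = 5000,
         post_ms = 10000, window_ms = 10000)
  } else {
    list(scale = scale, n = 50L, pre_ms = 2000, t_stim_ms = 1000,
         post_ms = 2000, window_ms = 2000)
  }
}

experiment_names <- c(
  "motif_decoupling", "network_decoupling", "stdp_sensitivity",
  "burst_vs_continuous", "shifted_vs_unshifted", "ei_targeting",
  "dt_nu_sweep", "isolated_module_check", "topology_report"
)

#' Run one figure-level experiment
#'
#' Each experiment wires together the network builder, the stimulation
#' protocol and the simulator with the parameter set of one headline result,
#' returning the simulation(s) plus before/after metrics. Available names:
#'
#' * `motif_decoupling`: reciprocal two-neuron motif, time-shifted burst
#'   stimulation, both synapses depressed.
#' * `network_decoupling`: the two-module network driven below the coupling
#'   stability threshold by the shifted burst protocol.
#' * `stdp_sensitivity`: the same protocol under alternative STDP parameter
#'   ratios (decoupling vs re-potentiation vs failure).
#' * `burst_vs_continuous`: continuous pulse train reaches low coupling at
#'   least as fast as the burst pattern.
#' * `shifted_vs_unshifted`: the coincident (`delta_t = 0`) control
#'   potentiates where the shifted protocol depresses.
#' * `ei_targeting`: pulses delivered to excitatory or inhibitory cells only.
#' * `dt_nu_sweep`: see [run_sweep()].
#' * `isolated_module_check`: see [isolated_module_check()].
#' * `topology_report`: thresholded binary topology before/after decoupling.
#'
#' @param experiment Experiment name (see above).
#' @param scale `"reduced"` or `"full"` (see [experiment_scale()]).
#' @param seed Integer seed; every stochastic component derives from it.
#' @param out_dir Optional directory; when given, spikes, coupling, the
#'   metrics summary and a JSON manifest sufficient to re-create the run are
#'   written there.
#' @param ... Overrides: `delta_t`, `T_pulse`, `xi_abs`, `stdp`, `drive`,
#'   `drive_motif` (the motif has no in-degree normalization, so its drive
#'   amplitude is calibrated separately),
#'   `pattern`, `target`, `inter_preset`, `dt`, `n`, plus the epoch lengths
#'   `pre_ms`, `t_stim_ms`, `post_ms`, `window_ms`.
#' @return A list of class `experiment_result`: `name`, `runs` (named list
#'   of `sim_result`s or, for sweeps, a tibble), `metrics` (tibble),
#'   `manifest` (named list of all parameters).
#' @examples
#' \donttest{
#' ex <- run_experiment("network_decoupling", scale = "reduced", seed = 1)
#' ex$metrics
#' }
#' @export
run_experiment <- function(experiment, scale = c("reduced", "full"), seed = 1L,
                           out_dir = NULL, ...) {
  name <- match.arg(experiment, experiment_names)
  sc <- experiment_scale(match.arg(scale))
  dots <- list(...)
  for (f in intersect(names(dots), c("n", "pre_ms", "t_stim_ms", "post_ms",
                                     "window_ms"))) {
    sc[[f]] <- dots[[f]]
  }
  pars <- utils::modifyList(list(
    delta_t = 5, T_pulse = 30, xi_abs = 10, stdp = stdp_params(),
    drive = drive_spec(), drive_motif = drive_spec(w_ext = 0.015),
    pattern = "burst", target = "all",
    inter_preset = "strong", dt = 0.1
  ), dots[setdiff(names(dots), c("n", "pre_ms", "t_stim_ms", "post_ms",
                                 "window_ms"))])

  out <- switch(name,
    motif_decoupling = exp_decoupling(sc, pars, seed, motif = TRUE),
    network_decoupling = exp_decoupling(sc, pars, seed, motif = FALSE),
    stdp_sensitivity = exp_stdp_sensitivity(sc, pars, seed),
    burst_vs_continuous = exp_pattern_compare(sc, pars, seed,
      variants = list(burst = "burst", continuous = "continuous")),
    shifted_vs_unshifted = exp_shift_compare(sc, pars, seed),
    ei_targeting = exp_ei_targeting(sc, pars, seed),
    dt_nu_sweep = exp_sweep(sc, pars, seed),
    isolated_module_check = exp_isolated(sc, pars, seed),
    topology_report = exp_topology(sc, pars, seed)
  )
  out$name <- name
  out$manifest <- c(list(name = name, scale = sc, seed = seed),
                    manifest_params(pars))
  class(out) <- "experiment_result"
  if (!is.null(out_dir)) write_experiment(out, out_dir)
  out
}

manifest_params <- function(pars) {
  flat <- pars
  for (nm in names(flat)) {
    if (inherits(flat[[nm]], c("stdp_params", "drive_spec", "delay_spec"))) {
      flat[[nm]] <- unclass(flat[[nm]])
    }
  }
  flat
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %s (%s scale)\n", x$name,
              x$manifest$scale$scale))
  if (!is.null(x$metrics)) print(x$metrics)
  invisible(x)
}

# -- shared machinery ---------------------------------------------------------

experiment_network_spec <- function(sc, pars, seed, motif = FALSE,
                                    p_inter = 0.15) {
  delays_inter <- delay_spec(tau_d = 0.5, tau_a = 0.5 + pars$xi_abs)
  if (motif) {
    network_spec(module_1 = module_spec(n = 1, frac_ex = 1, p_intra = 0),
                 module_2 = module_spec(n = 1, frac_ex = 1, p_intra = 0),
                 p_inter = 1, inter_preset = pars$inter_preset,
                 delays_inter = delays_inter, seed = seed)
  } else {
    network_spec(n = sc$n, p_inter = p_inter,
                 inter_preset = pars$inter_preset,
                 delays_inter = delays_inter, seed = seed)
  }
}

experiment_protocol <- function(sc, pars, delta_t = pars$delta_t,
                                pattern = pars$pattern, target = pars$target) {
  stim_protocol(T_pulse = pars$T_pulse, delta_t = delta_t, pattern = pattern,
                target = target, t_start = sc$pre_ms, T_stim = sc$t_stim_ms)
}

run_protocol_sim <- function(net, sc, pars, protocol, seed,
                             stdp = pars$stdp, drive = pars$drive) {
  t_total <- sc$pre_ms + sc$t_stim_ms + sc$post_ms + pars$T_pulse
  simulate_network(net, drive, protocol,
                   sim_config(t_total = t_total, dt = pars$dt,
                              seed = seed + 1L, stdp = stdp))
}

pre_post_windows <- function(sc, protocol) {
  list(pre = c(max(0, sc$pre_ms - sc$window_ms), sc$pre_ms),
       post = c(sc$pre_ms + sc$t_stim_ms,
                sc$pre_ms + sc$t_stim_ms + sc$window_ms))
}

coupling_before_after <- function(res, windows) {
  avg <- function(w) {
    sel <- res$coupling$time_ms >= w[1] & res$coupling$time_ms <= w[2]
    c(g21 = mean(res$coupling$g21[sel]), g12 = mean(res$coupling$g12[sel]))
  }
  pre <- avg(windows$pre); post <- avg(windows$post)
  tibble::tibble(window = c("pre", "post"),
                 g21 = c(pre["g21"], post["g21"]),
                 g12 = c(pre["g12"], post["g12"]))
}

exp_decoupling <- function(sc, pars, seed, motif) {
  net <- build_network(experiment_network_spec(sc, pars, seed, motif = motif))
  protocol <- experiment_protocol(sc, pars)
  drive <- if (motif) pars$drive_motif else pars$drive
  res <- run_protocol_sim(net, sc, pars, protocol, seed, drive = drive)
  windows <- pre_post_windows(sc, protocol)
  metrics <- dplyr::mutate(coupling_before_after(res, windows), run = "stimulated",
                           .before = 1)
  list(runs = list(stimulated = res), metrics = metrics, windows = windows)
}

exp_stdp_sensitivity <- function(sc, pars, seed) {
  sets <- list(
    decoupling = stdp_params(0.008, 0.005, 10, 20),    # ratios (1.6, 0.5)
    slow_decoupling = stdp_params(0.006, 0.005, 16, 20), # ratios (1.2, 0.8)
    potentiating = stdp_params(0.008, 0.005, 32, 20)   # ratios (1.6, 1.6)
  )
  net <- build_network(experiment_network_spec(sc, pars, seed))
  protocol <- experiment_protocol(sc, pars)
  windows <- pre_post_windows(sc, protocol)
  runs <- purrr::imap(sets, function(stdp, nm) {
    run_protocol_sim(net, sc, pars, protocol, seed, stdp = stdp)
  })
  metrics <- purrr::imap_dfr(runs, function(r, nm) {
    dplyr::mutate(coupling_before_after(r, windows), run = nm, .before = 1)
  })
  list(runs = runs, metrics = metrics, windows = windows)
}

exp_pattern_compare <- function(sc, pars, seed, variants) {
  net <- build_network(experiment_network_spec(sc, pars, seed))
  runs <- purrr::imap(variants, function(pattern, nm) {
    protocol <- experiment_protocol(sc, pars, pattern = pattern)
    run_protocol_sim(net, sc, pars, protocol, seed)
  })
  windows <- pre_post_windows(sc, experiment_protocol(sc, pars))
  metrics <- purrr::imap_dfr(runs, function(r, nm) {
    dplyr::mutate(coupling_before_after(r, windows), run = nm, .before = 1)
  })
  list(runs = runs, metrics = metrics, windows = windows)
}

exp_shift_compare <- function(sc, pars, seed) {
  net <- build_network(experiment_network_spec(sc, pars, seed))
  runs <- list(
    shifted = run_protocol_sim(net, sc, pars,
                               experiment_protocol(sc, pars), seed),
    unshifted = run_protocol_sim(net, sc, pars,
                                 experiment_protocol(sc, pars, delta_t = 0),
                                 seed)
  )
  windows <- pre_post_windows(sc, experiment_protocol(sc, pars))
  metrics <- purrr::imap_dfr(runs, function(r, nm) {
    dplyr::mutate(coupling_before_after(r, windows), run = nm, .before = 1)
  })
  list(runs = runs, metrics = metrics, windows = windows)
}

exp_ei_targeting <- function(sc, pars, seed) {
  net <- build_network(experiment_network_spec(sc, pars, seed))
  runs <- purrr::map(
    rlang::set_names(c("excitatory_only", "inhibitory_only")),
    function(tg) {
      run_protocol_sim(net, sc, pars,
                       experiment_protocol(sc, pars, target = tg), seed)
    })
  windows <- pre_post_windows(sc, experiment_protocol(sc, pars))
  metrics <- purrr::imap_dfr(runs, function(r, nm) {
    dplyr::mutate(coupling_before_after(r, windows), run = nm, .before = 1)
  })
  list(runs = runs, metrics = metrics, windows = windows)
}

exp_sweep <- function(sc, pars, seed) {
  res <- run_sweep(dt_axis = seq(0, 100, by = 20), nu_axis = seq(10, 50, by = 10),
                   scale = sc$scale, seed = seed, xi_abs = pars$xi_abs,
                   stdp = pars$stdp, drive = pars$drive)
  list(runs = res, metrics = res)
}

exp_isolated <- function(sc, pars, seed) {
  series <- isolated_module_check(n = sc$n, seed = seed, drive = pars$drive)
  list(runs = series, metrics = NULL, series = series)
}

exp_topology <- function(sc, pars, seed, h = 0.3) {
  base <- exp_decoupling(sc, pars, seed, motif = FALSE)
  res <- base$runs$stimulated
  net0 <- build_network(experiment_network_spec(sc, pars, seed))
  topo <- list(before = threshold_topology(net0, h),
               after = threshold_topology(res$connectivity_final, h))
  metrics <- tibble::tibble(
    window = c("pre", "post"),
    n_plastic_surviving = c(topo$before$n_plastic_surviving,
                            topo$after$n_plastic_surviving))
  list(runs = base$runs, metrics = metrics, topology = topo)
}

write_experiment <- function(ex, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(ex$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(ex$metrics) && is.data.frame(ex$metrics)) {
    utils::write.csv(ex$metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
  }
  if (is.list(ex$runs) && !is.data.frame(ex$runs)) {
    for (nm in names(ex$runs)) {
      r <- ex$runs[[nm]]
      if (inherits(r, "sim_result")) {
        utils::write.csv(r$spikes, file.path(out_dir, paste0("spikes_", nm, ".csv")),
                         row.names = FALSE)
        utils::write.csv(r$coupling,
                         file.path(out_dir, paste0("coupling_", nm, ".csv")),
                         row.names = FALSE)
      }
    }
  }
  invisible(out_dir)
}

#' Re-create an archived experiment from its manifest
#'
#' @param manifest_path Path to a `manifest.json` written by
#'   [run_experiment()] with `out_dir` set.
#' @return The freshly recomputed `experiment_result`.
#' @export
rerun_from_manifest <- function(manifest_path) {
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  stdp <- do.call(stdp_params, m$stdp[c("a_plus", "a_minus", "tau_plus",
                                        "tau_minus")])
  drive <- do.call(drive_spec, m$drive[c("n_inputs_ex", "n_inputs_in",
                                         "rate_per_input", "w_ext")])
  drive_motif <- do.call(drive_spec, m$drive_motif[c("n_inputs_ex",
                                                     "n_inputs_in",
                                                     "rate_per_input",
                                                     "w_ext")])
  run_experiment(m$name, scale = m$scale$scale, seed = m$seed,
                 delta_t = m$delta_t, T_pulse = m$T_pulse, xi_abs = m$xi_abs,
                 pattern = m$pattern, target = m$target,
                 inter_preset = m$inter_preset, dt = m$dt,
                 stdp = stdp, drive = drive, drive_motif = drive_motif,
                 n = m$scale$n, pre_ms = m$scale$pre_ms,
                 t_stim_ms = m$scale$t_stim_ms, post_ms = m$scale$post_ms,
                 window_ms = m$scale$window_ms)
}

#' Sweep stimulation time shift and frequency
#'
#' Runs one seeded decoupling simulation per (time shift, frequency) grid
#' cell and records the post-offset synchrony (population Fano factor per
#' module) and time-averaged mean coupling per direction. Cells violating
#' `0 < delta_t < T = 1000/nu` are flagged not-applicable and skipped.
#'
#' @param dt_axis Time shifts, ms.
#' @param nu_axis Stimulation frequencies, Hz.
#' @param scale,seed See [run_experiment()].
#' @param xi_abs Effective-delay magnitude, ms.
#' @param stdp,drive Parameter objects.
#' @param n_seeds Seeds averaged per cell.
#' @return A tibble `delta_t`, `nu_hz`, `applicable`, `pff_1`, `pff_2`,
#'   `g_ave_21`, `g_ave_12` (NA where not applicable or where a cell
#'   failed; failures are recorded, not fatal).
#' @export
run_sweep <- function(dt_axis, nu_axis, scale = "reduced", seed = 1L,
                      xi_abs = 10, stdp = stdp_params(), drive = drive_spec(),
                      n_seeds = 1L) {
  sc <- experiment_scale(scale)
  grid <- tidyr::expand_grid(delta_t = dt_axis, nu_hz = nu_axis)
  purrr::pmap_dfr(grid, function(delta_t, nu_hz) {
    T_pulse <- 1000 / nu_hz
    if (!(delta_t > 0 && delta_t < T_pulse)) {
      return(tibble::tibble(delta_t = delta_t, nu_hz = nu_hz,
                            applicable = FALSE, pff_1 = NA_real_,
                            pff_2 = NA_real_, g_ave_21 = NA_real_,
                            g_ave_12 = NA_real_))
    }
    cells <- purrr::map(seq_len(n_seeds), function(k) {
      cell_seed <- seed + 1000L * (k - 1L)
      tryCatch({
        pars <- list(delta_t = delta_t, T_pulse = T_pulse, xi_abs = xi_abs,
                     stdp = stdp, drive = drive, pattern = "burst",
                     target = "all", inter_preset = "strong", dt = 0.1)
        net <- build_network(experiment_network_spec(sc, pars, cell_seed))
        protocol <- experiment_protocol(sc, pars)
        res <- run_protocol_sim(net, sc, pars, protocol, cell_seed)
        w <- pre_post_windows(sc, protocol)$post
        sel <- res$coupling$time_ms >= w[1] & res$coupling$time_ms <= w[2]
        pff <- purrr::map_dbl(1:2, function(m) {
          act <- population_activity(res$spikes, m, sum(net$module == m),
                                     bin_ms = 5, window = w)
          if (mean(act$activity) == 0) NA_real_ else pop_fano(act)
        })
        tibble::tibble(pff_1 = pff[1], pff_2 = pff[2],
                       g_ave_21 = mean(res$coupling$g21[sel]),
                       g_ave_12 = mean(res$coupling$g12[sel]))
      }, error = function(e) {
        tibble::tibble(pff_1 = NA_real_, pff_2 = NA_real_,
                       g_ave_21 = NA_real_, g_ave_12 = NA_real_)
      })
    })
    dplyr::bind_cols(
      tibble::tibble(delta_t = delta_t, nu_hz = nu_hz, applicable = TRUE),
      dplyr::summarise(dplyr::bind_rows(cells),
                       dplyr::across(dplyr::everything(),
                                     ~ mean(.x, na.rm = TRUE))))
  })
}

#' Pulse response of an isolated module
#'
#' Builds a single isolated module (no inter-module projections), lets it
#' settle under background drive, then delivers one subthreshold pulse to
#' the excitatory population and records the excitatory and inhibitory
#' population rates and their ratio around the pulse. In the
#' inhibition-stabilized regime the inhibitory rate rises on the heels of
#' the excitatory transient (balanced amplification) and both return to
#' baseline.
#'
#' @param n Neurons in the module.
#' @param seed Integer seed.
#' @param drive A [drive_spec()].
#' @param pulse_K Kick amplitude delivered to excitatory cells (0 disables
#'   the pulse).
#' @param settle_ms,follow_ms Settling time before and recording time after
#'   the pulse, ms.
#' @param bin_ms Rate bin, ms.
#' @return A tibble `time_ms` (0 at the pulse), `r_ex_hz`, `r_in_hz`,
#'   `ratio`.
#' @export
isolated_module_check <- function(n = 200, seed = 1L, drive = drive_spec(),
                                  pulse_K = 0.5, settle_ms = 1000,
                                  follow_ms = 500, bin_ms = 10) {
  spec <- network_spec(n = n, p_inter = 0, seed = seed)
  net <- build_network(spec)
  protocol <- NULL
  if (pulse_K > 0) {
    protocol <- stim_protocol(K = pulse_K, T_pulse = 2 * (settle_ms + follow_ms),
                              k_pulses = 1, T_off = 2 * (settle_ms + follow_ms),
                              T_stim = 1, t_start = settle_ms, delta_t = 0,
                              pattern = "burst", target = "excitatory_only")
  }
  res <- simulate_network(net, drive, protocol,
                          sim_config(t_total = settle_ms + follow_ms,
                                     seed = seed + 1L, plasticity = FALSE))
  rates <- firing_rate_series(res, bin_ms = bin_ms, by_class = TRUE) |>
    dplyr::filter(.data$module == 1) |>
    tidyr::pivot_wider(names_from = "excitatory", values_from = "rate_hz") |>
    dplyr::rename(r_in_hz = "FALSE", r_ex_hz = "TRUE") |>
    dplyr::mutate(time_ms = .data$time_ms - settle_ms,
                  ratio = .data$r_ex_hz / pmax(.data$r_in_hz, 1e-9)) |>
    dplyr::select("time_ms", "r_ex_hz", "r_in_hz", "ratio")
  rates
}

#' Calibrate the external-drive amplitude
#'
#' Searches the per-arrival amplitude `w_ext` so that an isolated module
#' settles at a target mean excitatory firing rate with irregular,
#' asynchronous activity — the operating point from which strong long-range
#' excitation can still push the coupled network into synchrony. Bisection
#' on short isolated-module simulations.
#'
#' @param target_rate_hz Target mean excitatory rate of the isolated module.
#' @param n,seed,duration_ms Problem size for the calibration runs.
#' @param lower,upper Bracket for `w_ext`.
#' @param iters Bisection iterations.
#' @return A list `w_ext`, `achieved_rate_hz`, `trace` (tibble of the
#'   bisection path).
#' @export
calibrate_drive <- function(target_rate_hz = 3, n = 100, seed = 1L,
                            duration_ms = 2000, lower = 0.015, upper = 0.035,
                            iters = 8) {
  rate_at <- function(w_ext) {
    net <- build_network(network_spec(n = n, p_inter = 0, seed = seed))
    res <- simulate_network(net, drive_spec(w_ext = w_ext), NULL,
                            sim_config(t_total = duration_ms, seed = seed + 1L,
                                       plasticity = FALSE))
    sp <- res$spikes
    sel <- sp$time_ms > duration_ms / 2 & sp$excitatory & sp$module == 1
    sum(sel) / sum(net$module == 1 & net$is_excitatory) /
      (duration_ms / 2000)
  }
  trace <- tibble::tibble(w_ext = numeric(0), rate_hz = numeric(0))
  lo <- lower; hi <- upper
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    r <- rate_at(mid)
    trace <- dplyr::bind_rows(trace, tibble::tibble(w_ext = mid, rate_hz = r))
    if (r > target_rate_hz) hi <- mid else lo <- mid
  }
  best <- trace[which.min(abs(trace$rate_hz - target_rate_hz)), ]
  list(w_ext = best$w_ext, achieved_rate_hz = best$rate_hz, trace = trace)
}
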