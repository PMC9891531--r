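#' Specification of one excitatory-inhibitory module
#'
#' One module is a sparse random (Erdos-Renyi) balanced network of `n`
#' leaky integrate-and-fire neurons, a fraction `frac_ex` of them excitatory.
#' Intra-module synapses are static; inhibitory synapses are on average
#' four-fold stronger than excitatory ones (0.8 vs 0.2 by default), which
#' keeps the module in the locally balanced, inhibition-stabilized regime.
#' Weight magnitudes are drawn from Gaussians and clipped to the global
#' bounds of the network spec.
#'
#' @param n Neurons in the module. `n * frac_ex` must be an integer.
#' @param frac_ex Excitatory fraction (default 0.8, the cortical 4:1 ratio).
#' @param p_intra Connection probability for each ordered intra-module pair.
#' @param w_ex_mean,w_ex_sd Gaussian parameters of excitatory weights.
#' @param w_in_mean,w_in_sd Gaussian parameters of inhibitory weight
#'   magnitudes (the simulator applies the negative sign).
#' @return A `module_spec` list.
#' @examples
#' module_spec(n = 50)
#' @export
module_spec <- function(n = 200, frac_ex = 0.8, p_intra = 0.15,
                        w_ex_mean = 0.2, w_ex_sd = 0.05,
                        w_in_mean = 0.8, w_in_sd = 0.05) {
  n_ex <- n * frac_ex
  if (abs(n_ex - round(n_ex)) > 1e-9) {
    stop("`n * frac_ex` must be an integer number of excitatory neurons",
         call. = FALSE)
  }
  if (p_intra < 0 || p_intra > 1) stop("`p_intra` must lie in [0, 1]", call. = FALSE)
  stopifnot(n >= 1, w_ex_sd >= 0, w_in_sd >= 0, w_ex_mean > 0, w_in_mean > 0)
  structure(list(n = as.integer(n), n_ex = as.integer(round(n_ex)),
                 n_in = as.integer(n - round(n_ex)),
                 frac_ex = frac_ex, p_intra = p_intra,
                 w_ex_mean = w_ex_mean, w_ex_sd = w_ex_sd,
                 w_in_mean = w_in_mean, w_in_sd = w_in_sd),
            class = "module_spec")
}

#' Specification of the two-module network
#'
#' Two identical (by default) modules coupled by plastic inter-module
#' excitatory-to-excitatory synapses with transmission delays. The default
#' inter-module mean weight of 0.8 is the "initially strong" (pathological)
#' preset in which the coupled network synchronizes; `inter_preset = "weak"`
#' selects mean 0.2, matching the distribution from which intra-module
#' excitatory weights are drawn.
#'
#' @param n Neurons per module (forwarded to [module_spec()] for both
#'   modules unless explicit module specs are given).
#' @param module_1,module_2 Optional [module_spec()] overrides.
#' @param p_inter Connection probability for each ordered inter-module
#'   excitatory pair (both directions drawn independently).
#' @param inter_preset `"strong"` (mean 0.8, pathological initial state) or
#'   `"weak"` (mean 0.2).
#' @param w_inter_mean,w_inter_sd Gaussian parameters of inter-module
#'   weights; `w_inter_mean = NULL` takes the preset's mean.
#' @param delays_intra,delays_inter [delay_spec()]s for intra- and
#'   inter-module transmission. Intra-module transmission is instantaneous
#'   by default; inter-module transmission defaults to tau_d = 0.5 ms,
#'   tau_a = 10.5 ms (total 11 ms, effective delay xi = -10 ms).
#' @param g_min,g_max Hard bounds on synaptic strengths.
#' @param current_scale Factor applied to all synaptic currents in the
#'   simulator (weights themselves, and the plasticity acting on them, are
#'   unscaled). The default `NULL` resolves to the reciprocal of the
#'   expected in-degree, `1 / (p_intra * n)` (or `1 / (p_inter * n_ex)`
#'   when there are no intra-module connections, as in the two-neuron
#'   motif, where it equals 1). This in-degree normalization keeps the
#'   summed recurrent input — and hence the dynamical regime — invariant
#'   under rescaling of the module size.
#' @param seed RNG seed used by [build_network()]; `NULL` uses the current
#'   RNG state.
#' @param ... Forwarded to [module_spec()] for both modules.
#' @return A `network_spec` list.
#' @examples
#' network_spec(n = 50, seed = 1)
#' network_spec(inter_preset = "weak")
#' @export
network_spec <- function(n = 200, module_1 = NULL, module_2 = NULL,
                         p_inter = 0.15,
                         inter_preset = c("strong", "weak"),
                         w_inter_mean = NULL, w_inter_sd = 0.05,
                         delays_intra = delay_spec(0, 0),
                         delays_inter = delay_spec(0.5, 10.5),
                         g_min = 0.05, g_max = 1.0, current_scale = NULL,
                         seed = NULL, ...) {
  inter_preset <- match.arg(inter_preset)
  if (is.null(w_inter_mean)) {
    w_inter_mean <- if (inter_preset == "strong") 0.8 else 0.2
  }
  if (is.null(module_1)) module_1 <- module_spec(n = n, ...)
  if (is.null(module_2)) module_2 <- module_spec(n = n, ...)
  stopifnot(inherits(module_1, "module_spec"), inherits(module_2, "module_spec"),
            inherits(delays_intra, "delay_spec"), inherits(delays_inter, "delay_spec"))
  if (p_inter < 0 || p_inter > 1) stop("`p_inter` must lie in [0, 1]", call. = FALSE)
  if (g_min >= g_max) stop("`g_min` must be below `g_max`", call. = FALSE)
  means <- c(module_1$w_ex_mean, module_1$w_in_mean,
             module_2$w_ex_mean, module_2$w_in_mean, w_inter_mean)
  if (any(means < g_min | means > g_max)) {
    stop("configured mean weights must lie within [g_min, g_max]", call. = FALSE)
  }
  if (is.null(current_scale)) {
    current_scale <- if (module_1$p_intra > 0) {
      1 / (module_1$p_intra * module_1$n)
    } else if (p_inter > 0) {
      1 / (p_inter * module_1$n_ex)
    } else 1
  }
  stopifnot(current_scale > 0)
  structure(list(module_1 = module_1, module_2 = module_2, p_inter = p_inter,
                 w_inter_mean = w_inter_mean, w_inter_sd = w_inter_sd,
                 delays_intra = delays_intra, delays_inter = delays_inter,
                 g_min = g_min, g_max = g_max, current_scale = current_scale,
                 seed = seed),
            class = "network_spec")
}

# evaluate `code` under `seed` without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Build the two-module network
#'
#' Draws the adjacency (independent Bernoulli per ordered pair, no
#' self-connections), the Gaussian weight magnitudes (clipped to
#' `[g_min, g_max]`) and the excitatory/inhibitory identities. Inter-module
#' links are drawn only between excitatory neurons, in both directions, and
#' only those synapses are plastic; all intra-module synapses are static.
#' The build is deterministic under a fixed `spec$seed`.
#'
#' @param spec A [network_spec()].
#' @return A `connectivity` object: matrices `adjacency` (post x pre,
#'   logical), `weights` (magnitudes; the simulator applies the inhibitory
#'   sign), `plastic` (logical mask of plastic entries), vectors `module`
#'   and `is_excitatory`, and the originating `spec`.
#' @examples
#' net <- build_network(network_spec(n = 50, seed = 42))
#' net
#' @export
build_network <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  with_seed(spec$seed, {
    m1 <- spec$module_1; m2 <- spec$module_2
    n_tot <- m1$n + m2$n
    module <- rep(1:2, c(m1$n, m2$n))
    # inhibitory neurons first within each module (ids 1..n_in), then excitatory
    is_ex <- c(rep(c(FALSE, TRUE), c(m1$n_in, m1$n_ex)),
               rep(c(FALSE, TRUE), c(m2$n_in, m2$n_ex)))
    adjacency <- matrix(FALSE, n_tot, n_tot)
    weights <- matrix(0, n_tot, n_tot)
    plastic <- matrix(FALSE, n_tot, n_tot)

    draw_block <- function(n_post, n_pre, p) {
      matrix(stats::runif(n_post * n_pre) < p, n_post, n_pre)
    }
    clip <- function(x) pmin(pmax(x, spec$g_min), spec$g_max)

    for (mod in 1:2) {
      ms <- if (mod == 1) m1 else m2
      idx <- which(module == mod)
      a <- draw_block(ms$n, ms$n, ms$p_intra)
      diag(a) <- FALSE
      w <- matrix(0, ms$n, ms$n)
      pre_ex <- is_ex[idx]
      n_edges_ex <- sum(a[, pre_ex])
      n_edges_in <- sum(a[, !pre_ex])
      w[, pre_ex][a[, pre_ex]] <-
        clip(stats::rnorm(n_edges_ex, ms$w_ex_mean, ms$w_ex_sd))
      w[, !pre_ex][a[, !pre_ex]] <-
        clip(stats::rnorm(n_edges_in, ms$w_in_mean, ms$w_in_sd))
      adjacency[idx, idx] <- a
      weights[idx, idx] <- w
    }

    ex1 <- which(module == 1 & is_ex)
    ex2 <- which(module == 2 & is_ex)
    for (dir in list(c(1, 2), c(2, 1))) {
      pre <- if (dir[1] == 1) ex1 else ex2
      post <- if (dir[2] == 1) ex1 else ex2
      a <- draw_block(length(post), length(pre), spec$p_inter)
      w <- matrix(0, length(post), length(pre))
      w[a] <- clip(stats::rnorm(sum(a), spec$w_inter_mean, spec$w_inter_sd))
      adjacency[post, pre] <- a
      weights[post, pre] <- w
      plastic[post, pre] <- a
    }

    structure(list(adjacency = adjacency, weights = weights, plastic = plastic,
                   module = module, is_excitatory = is_ex, spec = spec),
              class = "connectivity")
  })
}

#' @export
print.connectivity <- function(x, ...) {
  cat(sprintf(
    "<connectivity> %d neurons (%d + %d), %d edges (%d plastic inter-module E->E)\n",
    length(x$module), sum(x$module == 1), sum(x$module == 2),
    sum(x$adjacency), sum(x$plastic)))
  invisible(x)
}

#' Number of neurons in a built network
#' @param connectivity A [build_network()] result.
#' @return Integer count over both modules.
#' @export
n_neurons <- function(connectivity) length(connectivity$module)

#' Edge list of a built network
#'
#' @param x A `connectivity` object.
#' @param ... Unused.
#' @return A tibble with one row per synapse: `pre`, `post`, `weight`,
#'   `plastic`, `pre_module`, `post_module`, `pre_excitatory`.
#' @export
tidy.connectivity <- function(x, ...) {
  idx <- which(x$adjacency, arr.ind = TRUE)
  tibble::tibble(
    pre = idx[, 2L],
    post = idx[, 1L],
    weight = x$weights[idx],
    plastic = x$plastic[idx],
    pre_module = x$module[idx[, 2L]],
    post_module = x$module[idx[, 1L]],
    pre_excitatory = x$is_excitatory[idx[, 2L]]
  )
}

#' Summary of drawn weight distributions
#'
#' Groups the drawn synaptic weights into intra-module excitatory,
#' intra-module inhibitory and inter-module classes and reports empirical
#' moments next to the configured Gaussian means, plus the fraction of draws
#' clipped at the bounds. Useful for checking the 4:1 inhibitory/excitatory
#' strength ratio and the clipping rate.
#'
#' @param connectivity A [build_network()] result.
#' @return A tibble with columns `class`, `n`, `mean`, `sd`,
#'   `configured_mean`, `frac_at_gmin`, `frac_at_gmax`.
#' @examples
#' sample_weight_distributions(build_network(network_spec(n = 100, seed = 7)))
#' @export
sample_weight_distributions <- function(connectivity) {
  stopifnot(inherits(connectivity, "connectivity"))
  spec <- connectivity$spec
  edges <- tidy.connectivity(connectivity)
  edges <- dplyr::mutate(edges, class = dplyr::case_when(
    .data$pre_module != .data$post_module ~ "inter_excitatory",
    .data$pre_excitatory ~ "intra_excitatory",
    .default = "intra_inhibitory"
  ))
  cfg <- c(intra_excitatory = spec$module_1$w_ex_mean,
           intra_inhibitory = spec$module_1$w_in_mean,
           inter_excitatory = spec$w_inter_mean)
  edges |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$weight),
      sd = stats::sd(.data$weight),
      frac_at_gmin = mean(.data$weight <= spec$g_min),
      frac_at_gmax = mean(.data$weight >= spec$g_max),
      .groups = "drop"
    ) |>
    dplyr::mutate(configured_mean = unname(cfg[.data$class]), .after = "sd")
}

#' External background drive specification
#'
#' Each neuron receives a large number of independent low-rate Poisson
#' excitatory inputs (8000 trains at 1 spike/s for excitatory cells, 6500
#' for inhibitory cells by default). The superposition is itself Poisson, so
#' the simulator draws one aggregate arrival process per neuron at
#' `n_inputs * rate_per_input` and filters it through the synaptic trace;
#' each arrival contributes `w_ext` to the neuron's external synaptic trace.
#' `w_ext` is not a biophysical observable here: it is calibrated (see
#' [calibrate_drive()]) so that an isolated module fires irregularly at a
#' low rate, with a mean external current `rate * w_ext * tau_s` just below
#' threshold for excitatory cells.
#'
#' @param n_inputs_ex,n_inputs_in Number of independent input trains per
#'   excitatory / inhibitory neuron.
#' @param rate_per_input Mean rate of each train, spikes/s.
#' @param w_ext Amplitude contributed by one arrival (dimensionless).
#' @return A `drive_spec` list with derived aggregate rates
#'   `rate_ex_hz` and `rate_in_hz`.
#' @examples
#' drive_spec()
#' @export
drive_spec <- function(n_inputs_ex = 8000, n_inputs_in = 6500,
                       rate_per_input = 1, w_ext = 0.023) {
  stopifnot(n_inputs_ex >= 0, n_inputs_in >= 0, rate_per_input >= 0, w_ext > 0)
  structure(list(n_inputs_ex = n_inputs_ex, n_inputs_in = n_inputs_in,
                 rate_per_input = rate_per_input, w_ext = w_ext,
                 rate_ex_hz = n_inputs_ex * rate_per_input,
                 rate_in_hz = n_inputs_in * rate_per_input),
            class = "drive_spec")
}

#' @export
print.drive_spec <- function(x, ...) {
  cat(sprintf("<drive_spec> aggregate %g Hz (E) / %g Hz (I), w_ext = %g\n",
              x$rate_ex_hz, x$rate_in_hz, x$w_ext))
  invisible(x)
}

#' Sample the aggregate external arrival process
#'
#' Draws, for each neuron of a built network, the aggregate homogeneous
#' Poisson arrival times of its external background input over a time window.
#' The simulator generates these arrivals internally step by step from the
#' same rates; this generator exposes the process for inspection and for
#' testing the Poisson counting statistics.
#'
#' @param drive A [drive_spec()].
#' @param connectivity A [build_network()] result (supplies E/I identities).
#' @param duration_ms Window length, ms (> 0).
#' @param seed Optional seed.
#' @return A tibble `neuron`, `time_ms`, sorted by neuron then time.
#' @examples
#' net <- build_network(network_spec(n = 10, seed = 1))
#' arr <- make_drive(drive_spec(), net, duration_ms = 100, seed = 1)
#' @export
make_drive <- function(drive, connectivity, duration_ms, seed = NULL) {
  stopifnot(inherits(drive, "drive_spec"), inherits(connectivity, "connectivity"),
            duration_ms > 0)
  with_seed(seed, {
    rate_ms <- ifelse(connectivity$is_excitatory,
                      drive$rate_ex_hz, drive$rate_in_hz) / 1000
    counts <- stats::rpois(length(rate_ms), rate_ms * duration_ms)
    tibble::tibble(
      neuron = rep(seq_along(counts), counts),
      time_ms = stats::runif(sum(counts), 0, duration_ms)
    ) |>
      dplyr::arrange(.data$neuron, .data$time_ms)
  })
}
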