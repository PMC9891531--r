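#' Two-site stimulation protocol
#'
#' Describes the pulse-train protocol delivered to the two modules. Signal 1
#' starts at `t_start`; signal 2 is the same train shifted by `delta_t`.
#' Within a burst, pulses are `T_pulse` apart; after the `k_pulses`-th pulse
#' the next pulse follows after `T_off` (the silent OFF-epoch). The burst
#' ON-epoch is therefore `(k_pulses - 1) * T_pulse`. The continuous pattern
#' is the degenerate case `T_off = T_pulse`: a uniform pulse train at the
#' intra-burst frequency. Pulse generation for each signal stops at that
#' signal's onset plus `T_stim` (half-open window: pulses strictly after the
#' end are dropped).
#'
#' @param K Stimulation intensity: the instantaneous kick added to the
#'   dimensionless membrane potential at each pulse. The default 1.3 is 30%
#'   above threshold, so a pulse reliably elicits a spike in a resting or
#'   near-resting neuron.
#' @param T_pulse Inter-pulse interval within a burst, ms (> 0). The
#'   intra-burst frequency is `1000 / T_pulse` Hz.
#' @param k_pulses Pulses per burst (>= 1).
#' @param T_off OFF-epoch between bursts, ms. `NULL` selects 360 ms for the
#'   burst pattern and `T_pulse` for the continuous pattern.
#' @param T_stim Total stimulation duration per signal, ms.
#' @param t_start Onset of the first pulse of signal 1, ms.
#' @param delta_t Time shift of signal 2 relative to signal 1, ms. Must lie
#'   in `[0, T_pulse)`; 0 is the unshifted (coincident) control.
#' @param pattern `"burst"` or `"continuous"`.
#' @param target Which cells receive the pulses: `"all"`,
#'   `"excitatory_only"` or `"inhibitory_only"`.
#'
#' @return A `stim_protocol` list. `nu_hz` (intra-burst frequency) and
#'   `T_on` are derived fields.
#' @examples
#' stim_protocol()                            # burst pattern defaults
#' stim_protocol(pattern = "continuous")      # T_off collapses to T_pulse
#' @export
stim_protocol <- function(K = 1.3, T_pulse = 30, k_pulses = 5, T_off = NULL,
                          T_stim = 5000, t_start = 10000, delta_t = 5,
                          pattern = c("burst", "continuous"),
                          target = c("all", "excitatory_only", "inhibitory_only")) {
  pattern <- match.arg(pattern)
  target <- match.arg(target)
  if (pattern == "continuous") {
    if (!is.null(T_off) && T_off != T_pulse) {
      stop("continuous pattern requires T_off == T_pulse", call. = FALSE)
    }
    T_off <- T_pulse
    k_pulses <- 1L
  } else if (is.null(T_off)) {
    T_off <- 360
  }
  stopifnot(T_pulse > 0, k_pulses >= 1, T_off >= T_pulse, T_stim > 0,
            t_start >= 0, K > 0)
  if (delta_t < 0 || delta_t >= T_pulse) {
    stop("`delta_t` must lie in [0, T_pulse); 0 is the unshifted control",
         call. = FALSE)
  }
  structure(list(
    K = K, T_pulse = T_pulse, k_pulses = as.integer(k_pulses), T_off = T_off,
    T_on = (k_pulses - 1) * T_pulse, T_stim = T_stim, t_start = t_start,
    delta_t = delta_t, pattern = pattern, target = target,
    nu_hz = 1000 / T_pulse
  ), class = "stim_protocol")
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf(
    paste0("<stim_protocol> %s pattern, K = %g, T = %g ms (%.1f Hz), ",
           "k = %d, T_off = %g ms, T_stim = %g ms, onset %g ms, ",
           "delta_t = %g ms, target = %s\n"),
    x$pattern, x$K, x$T_pulse, x$nu_hz, x$k_pulses, x$T_off, x$T_stim,
    x$t_start, x$delta_t, x$target))
  invisible(x)
}

#' Pulse onset times of a stimulation signal
#'
#' Unrolls the pulse-onset recurrence: each pulse follows the previous one by
#' `T_pulse`, except the last pulse of a burst, after which the next onset
#' follows by `T_off`. Signal 2 is signal 1 shifted by `delta_t`. Pulses
#' strictly after the signal's onset plus `T_stim` are dropped.
#'
#' @param protocol A [stim_protocol()].
#' @param signal Signal index, 1 or 2, or `c(1, 2)` for both.
#' @return A tibble with columns `signal`, `pulse`, `time_ms`.
#' @examples
#' pt <- pulse_times(stim_protocol(t_start = 10000, delta_t = 5))
#' head(pt, 6) # 5 pulses 30 ms apart, then a 360 ms gap
#' @export
pulse_times <- function(protocol, signal = c(1L, 2L)) {
  stopifnot(inherits(protocol, "stim_protocol"))
  signal <- as.integer(signal)
  stopifnot(all(signal %in% 1:2))
  base <- pulse_train(protocol)
  purrr::map_dfr(signal, function(s) {
    shift <- if (s == 2L) protocol$delta_t else 0
    tibble::tibble(signal = s, pulse = seq_along(base), time_ms = base + shift)
  })
}

# one signal's pulse offsets relative to t_start, via the onset recurrence
pulse_train <- function(protocol) {
  times <- numeric(0)
  t <- protocol$t_start
  i <- 1L
  while (t <= protocol$t_start + protocol$T_stim + 1e-9) {
    times <- c(times, t)
    step <- if (i %% protocol$k_pulses == 0L) protocol$T_off else protocol$T_pulse
    t <- t + step
    i <- i + 1L
  }
  times
}

#' Per-neuron stimulation mask
#'
#' Expands a protocol's `target` field into a logical vector over the neurons
#' of a built network: `TRUE` for neurons that receive the pulses of their
#' module's signal (module 1 gets signal 1, module 2 signal 2).
#'
#' @param protocol A [stim_protocol()].
#' @param connectivity A [build_network()] result.
#' @return Logical vector of length `n_neurons(connectivity)`.
#' @examples
#' net <- build_network(network_spec(n = 20, seed = 1))
#' sum(target_mask(stim_protocol(target = "inhibitory_only"), net))
#' @export
target_mask <- function(protocol, connectivity) {
  stopifnot(inherits(protocol, "stim_protocol"),
            inherits(connectivity, "connectivity"))
  switch(protocol$target,
    all = rep(TRUE, length(connectivity$is_excitatory)),
    excitatory_only = connectivity$is_excitatory,
    inhibitory_only = !connectivity$is_excitatory
  )
}
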