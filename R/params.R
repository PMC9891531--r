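#' STDP rule parameters
#'
#' Bundle the four parameters of the pair-based additive STDP rule: the
#' potentiation and depression amplitudes (dimensionless weight change per
#' pairing) and their exponential time constants (ms). Defaults are the
#' cortical profile used throughout the package: a larger potentiation
#' amplitude (`a_plus > a_minus`) with a longer depression window
#' (`tau_plus < tau_minus`), so that uncorrelated firing is
#' depression-dominated (`a_plus * tau_plus < a_minus * tau_minus`).
#'
#' @param a_plus Potentiation amplitude (> 0).
#' @param a_minus Depression amplitude (> 0).
#' @param tau_plus Potentiation time constant in ms (> 0).
#' @param tau_minus Depression time constant in ms (> 0).
#'
#' @return An object of class `stdp_params` (a named list).
#' @examples
#' stdp_params()
#' stdp_params(a_plus = 0.008, tau_plus = 32) # longer potentiation window
#' @export
stdp_params <- function(a_plus = 0.008, a_minus = 0.005,
                        tau_plus = 10, tau_minus = 20) {
  vals <- c(a_plus = a_plus, a_minus = a_minus,
            tau_plus = tau_plus, tau_minus = tau_minus)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all STDP parameters must be finite and strictly positive", call. = FALSE)
  }
  structure(as.list(vals), class = "stdp_params")
}

#' @export
print.stdp_params <- function(x, ...) {
  cat(sprintf(
    "<stdp_params> A+ = %g, A- = %g, tau+ = %g ms, tau- = %g ms (%s)\n",
    x$a_plus, x$a_minus, x$tau_plus, x$tau_minus,
    if (is_depression_dominated(x)) "depression-dominated" else "potentiation-dominated"
  ))
  invisible(x)
}

#' Is an STDP profile depression-dominated?
#'
#' A profile satisfying `a_plus * tau_plus < a_minus * tau_minus` depresses
#' synapses on average under uncorrelated pre/post firing (the integral of the
#' STDP window is negative). This is the condition under which decoupling,
#' once achieved, is self-sustaining: irregular low-rate firing keeps eroding
#' the weights after stimulation offset.
#'
#' @param stdp An [stdp_params()] object.
#' @return `TRUE` if the depression integral dominates.
#' @examples
#' is_depression_dominated(stdp_params()) # 0.008*10 < 0.005*20
#' @export
is_depression_dominated <- function(stdp) {
  stopifnot(inherits(stdp, "stdp_params"))
  stdp$a_plus * stdp$tau_plus < stdp$a_minus * stdp$tau_minus
}

#' Dendritic/axonal delay specification
#'
#' Transmission between two connected neurons involves an axonal delay
#' `tau_a` (presynaptic spike to synapse) and a dendritic back-propagation
#' delay `tau_d` (postsynaptic somatic spike to synapse). Their sum
#' `tau = tau_d + tau_a` is the total transmission delay seen by the
#' postsynaptic current; their difference `xi = tau_d - tau_a` is the
#' effective delay perceived by the plasticity rule at the synapse. For
#' long-range projections `tau_a > tau_d`, so `xi < 0`.
#'
#' @param tau_d Dendritic (back-propagation) delay, ms (>= 0).
#' @param tau_a Axonal delay, ms (>= 0).
#' @return A `delay_spec` list with fields `tau_d`, `tau_a`, `tau`, `xi`.
#' @examples
#' delay_spec(tau_d = 0.5, tau_a = 10.5) # xi = -10, tau = 11
#' @export
delay_spec <- function(tau_d = 0.5, tau_a = 10.5) {
  if (!is.finite(tau_d) || !is.finite(tau_a) || tau_d < 0 || tau_a < 0) {
    stop("delays must be finite and non-negative", call. = FALSE)
  }
  structure(list(tau_d = tau_d, tau_a = tau_a,
                 tau = tau_d + tau_a, xi = tau_d - tau_a),
            class = "delay_spec")
}

#' @export
print.delay_spec <- function(x, ...) {
  cat(sprintf("<delay_spec> tau_d = %g ms, tau_a = %g ms (tau = %g, xi = %g)\n",
              x$tau_d, x$tau_a, x$tau, x$xi))
  invisible(x)
}

#' Signed effective delay from its magnitude
#'
#' Figures in this problem domain are usually parameterized by the magnitude
#' of the effective delay, `|xi|`. Physically, long-range connections have
#' axonal delays exceeding the dendritic back-propagation delay, so the
#' signed effective delay is negative. This helper maps a magnitude to the
#' signed convention used by [net_change()] and the simulator.
#'
#' @param xi_abs Magnitude of the effective delay, ms (>= 0).
#' @return The signed effective delay `-xi_abs`.
#' @examples
#' xi_from_abs(10)
#' @export
xi_from_abs <- function(xi_abs) {
  stopifnot(is.numeric(xi_abs), all(xi_abs >= 0))
  -xi_abs
}
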