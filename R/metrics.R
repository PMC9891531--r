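#' Inter-population mean coupling
#'
#' Mean strength of the plastic inter-module synapses in one direction.
#' `normalize = "per_edge"` (default) averages over the existing plastic
#' synapses, which is the scale on which coupling time courses and the
#' stability threshold (around 0.3) are expressed: it equals the initial
#' weight mean when all weights sit at their configured value.
#' `normalize = "per_neuron"` divides the summed strength by the number of
#' neurons per module instead, which makes the value grow with connection
#' density.
#'
#' @param connectivity A `connectivity` object (e.g. `connectivity_final`
#'   of a [simulate_network()] run).
#' @param direction `"21"` (module 1 -> module 2) or `"12"`.
#' @param normalize `"per_edge"` or `"per_neuron"`.
#' @return A single number (NA if the direction has no plastic edges).
#' @examples
#' net <- build_network(network_spec(n = 20, seed = 1))
#' mean_coupling(net, "21")
#' @export
mean_coupling <- function(connectivity, direction = c("21", "12"),
                          normalize = c("per_edge", "per_neuron")) {
  direction <- match.arg(direction)
  normalize <- match.arg(normalize)
  stopifnot(inherits(connectivity, "connectivity"))
  from <- if (direction == "21") 1L else 2L
  sel <- connectivity$plastic &
    matrix(connectivity$module == from, nrow = nrow(connectivity$plastic),
           ncol = ncol(connectivity$plastic), byrow = TRUE)
  if (!any(sel)) return(NA_real_)
  total <- sum(connectivity$weights[sel])
  if (normalize == "per_edge") total / sum(sel)
  else total / sum(connectivity$module == (3L - from))
}

#' Population activity series
#'
#' Fraction of a module's neurons firing per time bin: the binned spike
#' count divided by the module size.
#'
#' @param spikes A spike tibble with columns `time_ms`, `neuron`, `module`
#'   (e.g. `tidy()` of a `sim_result`).
#' @param module Module label to select.
#' @param n_neurons Neurons in that module (needed because silent neurons
#'   leave no trace in the spike record).
#' @param bin_ms Bin width, ms.
#' @param window Length-2 numeric window `c(from, to)` in ms; defaults to
#'   the full span of the record.
#' @return A tibble `time_ms` (bin start), `activity`.
#' @export
population_activity <- function(spikes, module, n_neurons, bin_ms = 1,
                                window = NULL) {
  stopifnot(bin_ms > 0, n_neurons >= 1)
  if (is.null(window)) window <- c(0, max(spikes$time_ms, 0))
  stopifnot(length(window) == 2, window[2] > window[1])
  breaks <- seq(window[1], window[2], by = bin_ms)
  if (length(breaks) < 2) stop("window shorter than one bin", call. = FALSE)
  sel <- spikes$time_ms >= window[1] & spikes$time_ms < breaks[length(breaks)] &
    spikes$module == module
  counts <- tabulate(findInterval(spikes$time_ms[sel], breaks),
                     nbins = length(breaks) - 1)
  tibble::tibble(time_ms = breaks[-length(breaks)],
                 activity = counts / n_neurons)
}

#' Pairwise spike-count correlations within a module
#'
#' Pearson correlation of binned spike counts for neuron pairs of one
#' module over an analysis window. Neurons with zero count variance in the
#' window are excluded. All pairs are used up to `max_pairs`; beyond that a
#' seeded random subsample of pairs is taken.
#'
#' @inheritParams population_activity
#' @param neuron_ids Integer ids of the module's neurons (silent ones
#'   included).
#' @param bin_ms Bin width for counting, ms (default 50).
#' @param max_pairs Pair-subsampling threshold.
#' @param seed Seed for pair subsampling.
#' @return A tibble `i`, `j`, `r`.
#' @export
pairwise_correlations <- function(spikes, module, neuron_ids, window,
                                  bin_ms = 50, max_pairs = 20000, seed = 1) {
  stopifnot(length(window) == 2, window[2] > window[1])
  breaks <- seq(window[1], window[2], by = bin_ms)
  n_bins <- length(breaks) - 1
  if (n_bins < 2) stop("window must span at least two bins", call. = FALSE)
  sel <- spikes$module == module & spikes$time_ms >= window[1] &
    spikes$time_ms < breaks[length(breaks)]
  sp <- spikes[sel, ]
  counts <- matrix(0L, n_bins, length(neuron_ids),
                   dimnames = list(NULL, neuron_ids))
  tab <- table(factor(findInterval(sp$time_ms, breaks), levels = seq_len(n_bins)),
               factor(sp$neuron, levels = neuron_ids))
  counts[] <- as.integer(tab)
  keep <- apply(counts, 2, stats::var) > 0
  if (sum(keep) < 2) {
    return(tibble::tibble(i = integer(0), j = integer(0), r = numeric(0)))
  }
  counts <- counts[, keep, drop = FALSE]
  ids <- neuron_ids[keep]
  pairs <- utils::combn(seq_along(ids), 2)
  if (ncol(pairs) > max_pairs) {
    pairs <- pairs[, with_seed(seed, sample.int(ncol(pairs), max_pairs)),
                   drop = FALSE]
  }
  cm <- stats::cor(counts)
  tibble::tibble(i = ids[pairs[1, ]], j = ids[pairs[2, ]],
                 r = cm[cbind(pairs[1, ], pairs[2, ])])
}

#' Coefficient of variation of inter-spike intervals
#'
#' `sd(ISI) / mean(ISI)` per neuron over an analysis window; 0 for a
#' perfectly periodic train, near 1 for Poisson firing. Neurons with fewer
#' than three spikes in the window (fewer than two intervals) get `NA`.
#'
#' @inheritParams population_activity
#' @param neuron_ids Neurons to evaluate; defaults to all neurons present
#'   in the record.
#' @return A tibble `neuron`, `n_spikes`, `cv`.
#' @export
cv_isi <- function(spikes, neuron_ids = NULL, window = NULL) {
  if (is.null(window)) window <- c(0, max(spikes$time_ms, 0) + 1e-9)
  sp <- spikes[spikes$time_ms >= window[1] & spikes$time_ms < window[2], ]
  if (is.null(neuron_ids)) neuron_ids <- sort(unique(sp$neuron))
  sp |>
    dplyr::filter(.data$neuron %in% neuron_ids) |>
    dplyr::group_by(neuron = factor(.data$neuron, levels = neuron_ids)) |>
    dplyr::summarise(n_spikes = dplyr::n(), cv = {
      isi <- diff(sort(.data$time_ms))
      if (length(isi) < 2) NA_real_ else stats::sd(isi) / mean(isi)
    }, .groups = "drop") |>
    tidyr::complete(neuron, fill = list(n_spikes = 0L, cv = NA_real_)) |>
    dplyr::mutate(neuron = as.integer(as.character(.data$neuron)))
}

#' Population Fano factor
#'
#' Variance over mean of a population-activity series: the normalized
#' amplitude of population-activity fluctuations. It grows when neurons fire
#' in synchrony (all bins empty or crowded) and is small in asynchronous
#' states with the same mean rate.
#'
#' @param activity A [population_activity()] tibble (or any tibble with an
#'   `activity` column).
#' @return A single number; errors if the mean activity is zero.
#' @export
pop_fano <- function(activity) {
  a <- activity$activity
  m <- mean(a)
  if (m == 0) stop("zero mean activity: population Fano factor undefined",
                   call. = FALSE)
  stats::var(a) / m
}

#' Dominant frequency of a population-activity series
#'
#' Peak of the magnitude spectrum of the mean-subtracted activity within a
#' frequency band (1-100 Hz by default). Returns `NA` when the spectrum is
#' flat (zero variance).
#'
#' @param activity A [population_activity()] tibble; bins must be regular.
#' @param band Length-2 frequency band in Hz.
#' @return Peak frequency in Hz, or `NA`.
#' @export
peak_frequency <- function(activity, band = c(1, 100)) {
  a <- activity$activity - mean(activity$activity)
  if (stats::var(activity$activity) == 0) return(NA_real_)
  dt_s <- diff(activity$time_ms[1:2]) / 1000
  n <- length(a)
  if (n * dt_s < 1 / band[1]) {
    stop("window too short to resolve the requested band", call. = FALSE)
  }
  spec <- Mod(stats::fft(a))[seq_len(floor(n / 2))]
  freq <- (seq_len(floor(n / 2)) - 1) / (n * dt_s)
  in_band <- freq >= band[1] & freq <= band[2]
  freq[in_band][which.max(spec[in_band])]
}

#' Smoothed activity helper: centred moving average
#' @noRd
smooth_activity <- function(activity, k = 5) {
  a <- activity$activity
  if (k > 1) {
    a <- stats::filter(a, rep(1 / k, k), sides = 2)
    a[is.na(a)] <- activity$activity[is.na(a)]
  }
  dplyr::mutate(activity, activity = as.numeric(a))
}

#' Phase lags between the synchronous discharges of two modules
#'
#' Detects the discharge peaks of each module's (smoothed) population
#' activity and maps, for every peak of module 1, the lag to the nearest
#' following peak of module 2 onto the circle using the measured oscillation
#' period. A concentration near 0 indicates in-phase, near pi anti-phase
#' collective firing.
#'
#' @param activity_1,activity_2 [population_activity()] tibbles on the same
#'   bins.
#' @param min_height Peak threshold as a multiple of the series' mean +
#'   standard deviation.
#' @param smooth_bins Moving-average width (bins) applied before peak
#'   picking.
#' @return A tibble `t_peak_ms`, `lag_ms`, `dphi` (radians in `[0, 2*pi)`).
#'   Errors if either series has no detectable peaks.
#' @export
phase_lags <- function(activity_1, activity_2, min_height = 1,
                       smooth_bins = 5) {
  a1 <- smooth_activity(activity_1, smooth_bins)
  a2 <- smooth_activity(activity_2, smooth_bins)
  find <- function(a) {
    thr <- mean(a$activity) + min_height * stats::sd(a$activity)
    pk <- pracma::findpeaks(a$activity, minpeakheight = thr,
                            minpeakdistance = max(2, smooth_bins))
    if (is.null(pk)) return(numeric(0))
    sort(a$time_ms[pk[, 2]])
  }
  p1 <- find(a1); p2 <- find(a2)
  if (length(p1) < 2 || length(p2) < 1) {
    stop("no detectable discharge peaks in the window", call. = FALSE)
  }
  period <- stats::median(diff(p1))
  lags <- purrr::map_dbl(p1, function(t0) {
    nxt <- p2[p2 >= t0]
    if (length(nxt) == 0) return(NA_real_)
    nxt[1] - t0
  })
  out <- tibble::tibble(t_peak_ms = p1, lag_ms = lags,
                        dphi = (2 * pi * lags / period) %% (2 * pi))
  dplyr::filter(out, !is.na(.data$lag_ms))
}

#' Threshold the weight matrix into a binary topology
#'
#' Binary connectivity obtained by keeping synapses with strength at least
#' `h`, together with the in/out-degree distributions of the plastic
#' (inter-module) subgraph. After a successful decoupling run with threshold
#' 0.3 most long-range links are eliminated.
#'
#' @param connectivity A `connectivity` object.
#' @param h Strength threshold.
#' @return A list of class `topology_summary`: `h`, `binary` (logical
#'   matrix over all neurons), `degrees` (tibble `neuron`, `module`,
#'   `in_degree`, `out_degree` over surviving plastic edges), and
#'   `n_plastic_surviving`.
#' @export
threshold_topology <- function(connectivity, h) {
  stopifnot(inherits(connectivity, "connectivity"), is.numeric(h))
  binary <- connectivity$adjacency & (connectivity$weights >= h)
  pl <- binary & connectivity$plastic
  degrees <- tibble::tibble(
    neuron = seq_along(connectivity$module),
    module = connectivity$module,
    in_degree = rowSums(pl),
    out_degree = colSums(pl)
  )
  structure(list(h = h, binary = binary, degrees = degrees,
                 n_plastic_surviving = sum(pl)),
            class = "topology_summary")
}

#' @export
print.topology_summary <- function(x, ...) {
  cat(sprintf("<topology_summary> h = %g: %d edges survive (%d plastic)\n",
              x$h, sum(x$binary), x$n_plastic_surviving))
  invisible(x)
}

#' Full metrics report for a simulation window
#'
#' Computes the whole analysis suite over a window of a simulation: the mean
#' coupling per direction, and per module the population Fano factor,
#' spike-count correlation distribution, ISI irregularity distribution and
#' spectral peak. Bin widths follow common practice for cortical network
#' analyses: 1 ms activity bins for spectra and phases, 5 ms for the Fano
#' factor, 50 ms for spike-count correlations; all are configurable.
#'
#' @param result A [simulate_network()] result.
#' @param window Length-2 analysis window, ms.
#' @param activity_bin_ms,fano_bin_ms,corr_bin_ms Bin widths, ms.
#' @return A `metrics_report` list with a `summary` tibble (one row per
#'   module) plus the underlying `correlations` and `cv` tibbles and the
#'   window/bins used.
#' @export
metrics_report <- function(result, window,
                           activity_bin_ms = 1, fano_bin_ms = 5,
                           corr_bin_ms = 50) {
  stopifnot(inherits(result, "sim_result"), length(window) == 2)
  conn <- result$connectivity_final
  sp <- result$spikes
  per_module <- purrr::map_dfr(1:2, function(m) {
    ids <- which(conn$module == m)
    act_f <- population_activity(sp, m, length(ids), fano_bin_ms, window)
    act_s <- population_activity(sp, m, length(ids), activity_bin_ms, window)
    rate <- sum(sp$module == m & sp$time_ms >= window[1] &
                  sp$time_ms < window[2]) / length(ids) /
      diff(window) * 1000
    tibble::tibble(
      module = m,
      mean_rate_hz = rate,
      pff = if (mean(act_f$activity) > 0) pop_fano(act_f) else NA_real_,
      peak_freq_hz = tryCatch(peak_frequency(act_s), error = function(e) NA_real_)
    )
  })
  corr <- purrr::map_dfr(1:2, function(m) {
    ids <- which(conn$module == m)
    dplyr::mutate(
      pairwise_correlations(sp, m, ids, window, bin_ms = corr_bin_ms),
      module = m, .before = 1)
  })
  cv <- purrr::map_dfr(1:2, function(m) {
    ids <- which(conn$module == m)
    dplyr::mutate(cv_isi(sp[sp$module == m, ], ids, window), module = m,
                  .before = 1)
  })
  structure(list(
    summary = dplyr::mutate(per_module,
                            g21 = mean_coupling(conn, "21"),
                            g12 = mean_coupling(conn, "12")),
    correlations = corr, cv = cv, window = window,
    bins = c(activity = activity_bin_ms, fano = fano_bin_ms,
             corr = corr_bin_ms)
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> window %g-%g ms\n", x$window[1], x$window[2]))
  print(x$summary)
  invisible(x)
}
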