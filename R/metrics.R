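#' Detect action potentials in a membrane-voltage trace
#'
#' Upward threshold crossings are grouped into spikes: contiguous
#' above-threshold runs whose separation is shorter than `min_separation`
#' are merged (refractory grouping), and each spike is timed at the local
#' maximum of its group.
#'
#' @param time sample times, ms, uniformly spaced.
#' @param v membrane potential, mV, same length.
#' @param threshold detection threshold, mV. The default 0 mV sits well
#'   above rest and well below the spike peak.
#' @param min_separation minimum peak separation, ms (> 0).
#' @return an object of class `spike_train`: list with `spike_times`,
#'   `peak_values`, `threshold`, `min_separation`.
#' @examples
#' tr <- synthetic_trace(spike_times = c(20, 60), t_end = 100)
#' detect_spikes(tr$time, tr$v)$spike_times
#' @export
detect_spikes <- function(time, v, threshold = 0, min_separation = 2) {
  if (length(time) != length(v) || length(time) < 2)
    stop("time and v must be equal-length vectors (length >= 2)")
  dts <- diff(time)
  if (max(dts) - min(dts) > 1e-6 * mean(dts))
    stop("trace must be uniformly sampled")
  if (min_separation <= 0) stop("min_separation must be positive")
  above <- v >= threshold
  if (!any(above)) {
    return(structure(list(spike_times = numeric(0), peak_values = numeric(0),
                          threshold = threshold,
                          min_separation = min_separation),
                     class = "spike_train"))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  # merge runs whose gap to the previous run is below min_separation
  groups <- list(runs[1, ])
  if (nrow(runs) > 1) {
    for (k in 2:nrow(runs)) {
      prev <- groups[[length(groups)]]
      if (time[runs[k, 1]] - time[prev[2]] < min_separation)
        groups[[length(groups)]] <- c(prev[1], runs[k, 2])
      else
        groups[[length(groups) + 1L]] <- runs[k, ]
    }
  }
  st <- pv <- numeric(length(groups))
  for (k in seq_along(groups)) {
    g <- groups[[k]]
    idx <- g[1]:g[2]
    pk <- idx[which.max(v[idx])]
    st[k] <- time[pk]; pv[k] <- v[pk]
  }
  structure(list(spike_times = st, peak_values = pv, threshold = threshold,
                 min_separation = min_separation),
            class = "spike_train")
}

#' @exportS3Method base::print
print.spike_train <- function(x, ...) {
  cat(sprintf("spike train: %d spikes (threshold %g mV)\n",
              length(x$spike_times), x$threshold))
  if (length(x$spike_times))
    cat("  times (ms):", paste(signif(x$spike_times, 5), collapse = ", "),
        "\n")
  invisible(x)
}

#' Firing rate over a window
#'
#' Spike count inside `[window[1], window[2])` divided by the window
#' duration, in Hz.
#'
#' @param train a `spike_train` from [detect_spikes()].
#' @param window two times, ms, `window[2] > window[1]`.
#' @return firing rate, Hz.
#' @export
firing_rate <- function(train, window) {
  stopifnot(inherits(train, "spike_train"), length(window) == 2)
  if (window[2] <= window[1]) stop("window must have positive duration")
  n <- sum(train$spike_times >= window[1] & train$spike_times < window[2])
  n / (window[2] - window[1]) * 1000
}

#' Full width at half maximum of each detected spike
#'
#' For each spike, the width of the interval where the trace stays at or
#' above `baseline + (peak - baseline)/2`, with the two half-crossings
#' located by linear interpolation. Spikes whose half-level crossing runs
#' into the trace edge are excluded with a warning.
#'
#' @param time,v the trace (ms, mV).
#' @param train a `spike_train` from [detect_spikes()] on the same trace.
#' @param baseline reference level, mV (typically the resting potential of
#'   the same run).
#' @return numeric vector of widths, ms, aligned with
#'   `train$spike_times`; a spike whose half-level crossing runs into the
#'   trace edge is excluded as `NA`.
#' @export
fwhm <- function(time, v, train, baseline) {
  stopifnot(inherits(train, "spike_train"))
  out <- rep(NA_real_, length(train$spike_times))
  for (k in seq_along(train$spike_times)) {
    pk <- which.min(abs(time - train$spike_times[k]))
    half <- baseline + (v[pk] - baseline) / 2
    i <- pk
    while (i > 1 && v[i] >= half) i <- i - 1
    j <- pk
    nn <- length(v)
    while (j < nn && v[j] >= half) j <- j + 1
    if (v[i] >= half || v[j] >= half) {
      warning(sprintf("spike at %g ms truncated at trace edge; excluded",
                      train$spike_times[k]))
      next
    }
    t_left <- time[i] + (half - v[i]) / (v[i + 1] - v[i]) *
      (time[i + 1] - time[i])
    t_right <- time[j - 1] + (half - v[j - 1]) / (v[j] - v[j - 1]) *
      (time[j] - time[j - 1])
    out[k] <- t_right - t_left
  }
  out
}

#' Inter-spike delays
#'
#' Successive differences of the spike times; empty for fewer than two
#' spikes.
#'
#' @param train a `spike_train`.
#' @return numeric vector, ms.
#' @export
interspike_delays <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  diff(train$spike_times)
}

#' Resting-baseline shift over a spike-free window
#'
#' Time-average of the trace over the window minus `reference`. Errors if
#' the window contains detected spikes.
#'
#' @param time,v the trace (ms, mV).
#' @param reference reference potential, mV.
#' @param window two times, ms.
#' @param threshold,min_separation passed to the spike check.
#' @return mean shift, mV.
#' @export
baseline_shift <- function(time, v, reference, window,
                           threshold = 0, min_separation = 2) {
  sel <- time >= window[1] & time <= window[2]
  if (sum(sel) < 2) stop("window contains fewer than 2 samples")
  tr <- detect_spikes(time[sel], v[sel], threshold, min_separation)
  if (length(tr$spike_times))
    stop("window contains spikes; baseline shift is undefined there")
  mean(v[sel]) - reference
}

#' Summary metrics of one simulated trace
#'
#' Convenience wrapper: detects spikes on one recorded compartment and
#' assembles the quantities the sweeps tabulate.
#'
#' @param res a `sim_result`.
#' @param compartment which compartment to analyse (default: middle).
#' @param rate_window window for [firing_rate()], ms; default the full run.
#' @param baseline reference potential, mV; default the first sample.
#' @param threshold,min_separation detector settings.
#' @return list with `n_spikes`, `firing_rate` (Hz), `fwhm_ms` (vector),
#'   `delays_ms` (vector), `peaks_mV` (vector), `spike_times`, `baseline`.
#' @export
ap_metrics <- function(res, compartment = NULL, rate_window = NULL,
                       baseline = NULL, threshold = 0, min_separation = 2) {
  stopifnot(inherits(res, "sim_result"))
  if (is.null(compartment))
    compartment <- max(1L, ncol(res$V_trace) %/% 2L)
  v <- res$V_trace[, compartment]
  tt <- res$times
  if (is.null(rate_window)) rate_window <- c(0, max(tt))
  if (is.null(baseline)) baseline <- v[1]
  train <- detect_spikes(tt, v, threshold, min_separation)
  wid <- suppressWarnings(fwhm(tt, v, train, baseline))
  inw <- train$spike_times >= rate_window[1] &
    train$spike_times < rate_window[2]
  list(n_spikes = length(train$spike_times),
       n_spikes_window = sum(inw),
       firing_rate = firing_rate(train, rate_window),
       fwhm_ms = wid,
       fwhm_window = wid[inw],
       delays_ms = interspike_delays(train),
       delays_window = diff(train$spike_times[inw]),
       peaks_mV = train$peak_values,
       peaks_window = train$peak_values[inw],
       spike_times = train$spike_times,
       baseline = baseline)
}
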