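#' Construct a fluorescence trace
#'
#' @param values numeric vector, detector a.u.
#' @param time time axis in seconds (same length as `values`).
#' @param stimulus a [stimulus_protocol()].
#' @return Object of class `fluor_trace`.
#' @export
fluor_trace <- function(values, time, stimulus = stimulus_protocol()) {
  if (length(values) != length(time)) stop("fluor_trace: values/time length mismatch")
  if (any(!is.finite(values))) stop("fluor_trace: values must be finite")
  structure(list(values = as.numeric(values), time = as.numeric(time),
                 stimulus = stimulus), class = "fluor_trace")
}

#' Average a line scan over its spatial dimension
#'
#' The mean fluorescence across the scanned line at each time point is the
#' raw calcium transient.
#'
#' @param rec a `linescan` recording.
#' @return A `fluor_trace` of per-sample means (length = samples).
#' @export
spatial_average <- function(rec) {
  stopifnot(inherits(rec, "linescan"))
  if (nrow(rec$intensity) < 1 || ncol(rec$intensity) < 1)
    stop("spatial_average: empty intensity matrix")
  n <- ncol(rec$intensity)
  fluor_trace(colMeans(rec$intensity),
              time = (seq_len(n) - 1) * rec$sampling_interval,
              stimulus = rec$stimulus)
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies a Butterworth low-pass forward and backward (zero phase, DC gain
#' one). The trace is extended by odd reflection at both ends before
#' filtering so that start-up transients die out outside the data.
#'
#' @param trace a `fluor_trace`.
#' @param cutoff cutoff frequency, Hz. Must lie below the Nyquist
#'   frequency. Transients carry little content above ~1 Hz; the 10 Hz
#'   default removes shot noise while leaving the rise untouched.
#' @param order filter order (default 4).
#' @return Filtered `fluor_trace` of the same length.
#' @export
lowpass_filter <- function(trace, cutoff = 10, order = 4) {
  stopifnot(inherits(trace, "fluor_trace"))
  n <- length(trace$values)
  dt <- if (n > 1) trace$time[2] - trace$time[1] else stop("lowpass_filter: trace too short")
  nyquist <- 1 / (2 * dt)
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff >= nyquist)
    stop("lowpass_filter: cutoff must lie in (0, Nyquist)")
  if (order < 1) stop("lowpass_filter: order must be >= 1")
  bf <- signal::butter(order, cutoff / nyquist, type = "low")
  pad <- min(n - 1L, max(200L, ceiling(5 / (cutoff * dt))))
  x <- trace$values
  # filter the deviation from the endpoint-to-endpoint trend: the trend is
  # far below the cutoff and bypassing it makes the DC gain exactly one
  trend <- x[1] + (x[n] - x[1]) * (seq_len(n) - 1) / (n - 1)
  r <- x - trend
  left <- 2 * r[1] - r[(pad + 1):2]
  right <- 2 * r[n] - r[(n - 1):(n - pad)]
  rf <- signal::filtfilt(bf, c(left, r, right))
  trace$values <- trend + rf[(pad + 1):(pad + n)]
  trace
}

#' Iterative moving-average smoothing
#'
#' Repeated centred moving average with reflected edges. Each pass is a
#' convolution with a length-`window` boxcar, so total variation never
#' increases.
#'
#' @param trace a `fluor_trace`.
#' @param window odd window length in samples (>= 3). The default 15
#'   samples spans ~21 ms at the standard sampling rate.
#' @param iterations number of passes (>= 1).
#' @return Smoothed `fluor_trace` of the same length.
#' @export
iterative_smooth <- function(trace, window = 15, iterations = 3) {
  stopifnot(inherits(trace, "fluor_trace"))
  if (window < 3 || window %% 2 == 0) stop("iterative_smooth: window must be odd and >= 3")
  if (iterations < 1) stop("iterative_smooth: iterations must be >= 1")
  h <- (window - 1L) %/% 2L
  x <- trace$values
  n <- length(x)
  if (n <= h + 1) stop("iterative_smooth: trace shorter than half window")
  kern <- rep(1 / window, window)
  for (i in seq_len(iterations)) {
    xp <- c(x[(h + 1):2], x, x[(n - 1):(n - h)])  # reflected edges
    sm <- stats::filter(xp, kern, sides = 2)
    x <- as.numeric(sm[(h + 1):(h + n)])
  }
  trace$values <- x
  trace
}

#' Average repeated sweeps
#'
#' Pointwise mean of repeated recordings of the same cell. All traces must
#' have identical length and stimulus metadata.
#'
#' @param traces list of `fluor_trace` objects (>= 1).
#' @return A `fluor_trace`.
#' @export
average_repeats <- function(traces) {
  if (!is.list(traces) || length(traces) < 1 ||
      !all(vapply(traces, inherits, logical(1), "fluor_trace")))
    stop("average_repeats: need a non-empty list of fluor_trace objects")
  n <- length(traces[[1]]$values)
  if (!all(vapply(traces, function(t) length(t$values) == n, logical(1))))
    stop("average_repeats: traces have mismatched lengths")
  ref <- traces[[1]]$stimulus
  same <- vapply(traces, function(t) isTRUE(all.equal(t$stimulus, ref)), logical(1))
  if (!all(same)) stop("average_repeats: traces have mismatched stimulus metadata")
  out <- traces[[1]]
  out$values <- Reduce(`+`, lapply(traces, `[[`, "values")) / length(traces)
  out
}

#' Convert a fluorescence trace to percent dF/F
#'
#' The baseline F0 is the mean over a pre-stimulus window (default
#' 0.5-4.5 s of the 5-s pre-stimulus period, avoiding the sweep edges);
#' values become `100 * (F - F0) / F0`. This baseline is distinct from the
#' resting-fluorescence metric, which uses only the first 100 ms
#' (see [resting_fluorescence()]).
#'
#' @param trace a `fluor_trace`.
#' @param baseline_window numeric length-2, seconds. Must end at or before
#'   stimulus onset and contain at least 10 samples.
#' @return Object of class `dff_trace`: list with `values` (percent dF/F),
#'   `f0`, `time`, `stimulus`.
#' @export
compute_dff <- function(trace, baseline_window = c(0.5, 4.5)) {
  stopifnot(inherits(trace, "fluor_trace"))
  if (length(baseline_window) != 2 || diff(baseline_window) <= 0)
    stop("compute_dff: invalid baseline window")
  if (baseline_window[2] > trace$stimulus$onset_time)
    stop("compute_dff: baseline window overlaps the stimulus")
  in_win <- trace$time >= baseline_window[1] & trace$time <= baseline_window[2]
  if (sum(in_win) < 10) stop("compute_dff: baseline window contains fewer than 10 samples")
  f0 <- mean(trace$values[in_win])
  if (f0 <= 0) stop("compute_dff: baseline fluorescence F0 must be positive")
  structure(list(values = 100 * (trace$values - f0) / f0, f0 = f0,
                 time = trace$time, stimulus = trace$stimulus),
            class = "dff_trace")
}
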