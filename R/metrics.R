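#' Resting fluorescence of a cell
#'
#' Mean raw pixel intensity over the first `window` seconds of the sweep
#' (default 100 ms), before any dF/F conversion. Reported in detector a.u.
#'
#' @param trace a `fluor_trace` of raw (unnormalised) fluorescence.
#' @param window averaging window from sweep start, seconds.
#' @return Numeric scalar, a.u.
#' @export
resting_fluorescence <- function(trace, window = 0.1) {
  stopifnot(inherits(trace, "fluor_trace"))
  if (max(trace$time) < window) stop("resting_fluorescence: trace shorter than window")
  mean(trace$values[trace$time < window])
}

#' Locate the peak of a dF/F transient
#'
#' The peak is the maximal dF/F at or after stimulus onset; ties are broken
#' toward the earliest time (relevant for plateau-shaped transients after
#' long trains).
#'
#' @param dff a `dff_trace`.
#' @return List with `peak` (percent dF/F) and `t_peak` (seconds).
#' @export
detect_peak <- function(dff) {
  stopifnot(inherits(dff, "dff_trace"))
  sel <- which(dff$time >= dff$stimulus$onset_time)
  if (!length(sel)) stop("detect_peak: no samples at or after stimulus onset")
  i <- sel[which.max(dff$values[sel])]
  list(peak = dff$values[i], t_peak = dff$time[i])
}

#' Rise time of a transient
#'
#' Interval between stimulus onset and the transient peak.
#'
#' @param t_peak peak time, seconds.
#' @param protocol the [stimulus_protocol()].
#' @return RT in seconds.
#' @export
rise_time <- function(t_peak, protocol) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  if (t_peak < protocol$onset_time) stop("rise_time: t_peak precedes stimulus onset")
  t_peak - protocol$onset_time
}

#' Polynomial fit of the rising phase
#'
#' Least-squares polynomial over [onset, t_peak]; the slope is the maximum
#' of the fitted first derivative on that window. Degree 3 captures the
#' sigmoid rise without ringing.
#'
#' @param dff a `dff_trace`.
#' @param onset,t_peak window bounds, seconds.
#' @param degree polynomial degree.
#' @return List of class `rise_fit`: `coefficients` (increasing powers),
#'   `slope` (percent dF/F per second), `r_squared`.
#' @export
fit_rise <- function(dff, onset = dff$stimulus$onset_time, t_peak, degree = 3) {
  stopifnot(inherits(dff, "dff_trace"))
  sel <- dff$time >= onset & dff$time <= t_peak
  if (sum(sel) < degree + 2)
    stop("fit_rise: fewer than degree + 2 samples in the rise window")
  t <- dff$time[sel] - onset
  y <- dff$values[sel]
  fit <- lm(y ~ poly(t, degree, raw = TRUE))
  cf <- unname(coef(fit))
  cf[is.na(cf)] <- 0
  tt <- seq(0, max(t), length.out = 200)
  deriv <- rep(0, length(tt))
  for (k in seq_len(degree)) deriv <- deriv + k * cf[k + 1] * tt^(k - 1)
  ssr <- sum(fit$residuals^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) max(0, min(1, 1 - ssr / sst)) else 1
  structure(list(coefficients = cf, slope = max(deriv), r_squared = r2),
            class = "rise_fit")
}

#' Bi-exponential fit of the decay phase
#'
#' Fits `a1 exp(-(t - t_peak)/tau1) + a2 exp(-(t - t_peak)/tau2) + offset`
#' by bounded Levenberg-Marquardt least squares (amplitudes >= 0, time
#' constants within `tau_bounds`), from several deterministic starting
#' points, keeping the best-residual fit. The decay window is decimated to
#' at most `max_points` samples for speed.
#'
#' @param dff a `dff_trace`.
#' @param t_peak peak time, seconds.
#' @param tau_bounds length-2 bounds on both time constants, seconds.
#' @param n_starts number of starting points (>= 1; at most the size of the
#'   built-in deterministic start grid).
#' @param max_points maximum samples used in the fit.
#' @return Object of class `decay_fit`: `a1`, `a2`, `tau1`, `tau2`
#'   (with `tau1 <= tau2`), `offset`, `r_squared`, `converged`,
#'   `non_decaying`.
#' @export
fit_decay <- function(dff, t_peak, tau_bounds = c(0.05, 60), n_starts = 5,
                      max_points = 2000) {
  stopifnot(inherits(dff, "dff_trace"))
  sel <- which(dff$time >= t_peak)
  if (length(sel) < 20) stop("fit_decay: fewer than 20 samples after t_peak")
  t <- dff$time[sel] - t_peak
  y <- dff$values[sel]
  # fit the active decay, not the recovered baseline: once the trace has
  # fallen below 2% of its peak-time value the remaining samples carry no
  # shape information and only bias the components toward the flat tail
  if (y[1] > 0) {
    below <- which(y < 0.02 * y[1])
    below <- below[below > 20]
    if (length(below)) {
      cut <- min(length(y), ceiling(below[1] * 1.25))
      t <- t[seq_len(cut)]
      y <- y[seq_len(cut)]
    }
  }
  if (length(t) > max_points) {
    keep <- unique(round(seq(1, length(t), length.out = max_points)))
    t <- t[keep]; y <- y[keep]
  }
  m <- length(y)
  head_m <- mean(y[seq_len(max(3, m %/% 10))])
  tail_m <- mean(y[seq(m - max(3, m %/% 10) + 1, m)])
  non_decaying <- tail_m >= head_m
  amp <- max(head_m - tail_m, 1e-6)
  starts <- list(c(1, 5), c(0.5, 2), c(2, 10), c(0.3, 20), c(1, 1.5),
                 c(3, 30), c(0.1, 1))
  starts <- starts[seq_len(min(n_starts, length(starts)))]
  lower <- c(a1 = 0, a2 = 0, tau1 = tau_bounds[1], tau2 = tau_bounds[1],
             offset = -Inf)
  upper <- c(a1 = Inf, a2 = Inf, tau1 = tau_bounds[2], tau2 = tau_bounds[2],
             offset = Inf)
  best <- NULL
  best_rss <- Inf
  for (s in starts) {
    st <- list(a1 = amp / 2, a2 = amp / 2,
               tau1 = min(max(s[1], tau_bounds[1]), tau_bounds[2]),
               tau2 = min(max(s[2], tau_bounds[1]), tau_bounds[2]),
               offset = tail_m)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ a1 * exp(-t / tau1) + a2 * exp(-t / tau2) + offset,
        start = st, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (rss < best_rss) { best_rss <- rss; best <- fit }
    }
  }
  if (is.null(best)) {
    return(structure(list(a1 = NA_real_, a2 = NA_real_, tau1 = NA_real_,
                          tau2 = NA_real_, offset = NA_real_,
                          r_squared = NA_real_, converged = FALSE,
                          non_decaying = non_decaying),
                     class = "decay_fit"))
  }
  cf <- as.list(coef(best))
  if (cf$tau1 > cf$tau2) {  # order components: tau1 fast, tau2 slow
    cf[c("a1", "a2", "tau1", "tau2")] <- cf[c("a2", "a1", "tau2", "tau1")]
  }
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) max(0, min(1, 1 - best_rss / sst)) else 1
  structure(list(a1 = cf$a1, a2 = cf$a2, tau1 = cf$tau1, tau2 = cf$tau2,
                 offset = cf$offset, r_squared = r2, converged = TRUE,
                 non_decaying = non_decaying),
            class = "decay_fit")
}

.decay_curve <- function(fit, t) {
  fit$a1 * exp(-t / fit$tau1) + fit$a2 * exp(-t / fit$tau2)
}

# smallest t (seconds after the peak) at which the offset-free fitted decay
# reaches `frac` of its peak-time value; NA if not reached within `horizon`
.decay_crossing <- function(fit, frac, horizon) {
  g0 <- fit$a1 + fit$a2
  if (!is.finite(g0) || g0 <= 0) return(NA_real_)
  target <- frac * g0
  f <- function(t) .decay_curve(fit, t) - target
  if (f(horizon) > 0) return(NA_real_)  # has not reached the level yet
  uniroot(f, c(0, horizon), tol = 1e-6)$root
}

#' Decay constant DT1
#'
#' Time for the fitted decay (offset removed) to fall to exp(-1) of its
#' value at the peak, i.e. to lose ~63% of the peak amplitude. Computed by
#' root-finding on the fitted curve, so it is exact (DT1 = tau) for a
#' mono-exponential decay and well defined for bi-exponentials.
#'
#' @param fit a `decay_fit`.
#' @param horizon maximum time after the peak within the sweep, seconds;
#'   if the curve has not decayed 63% by then, DT1 is censored (`NA` with
#'   attribute `censored`).
#' @return DT1 in seconds, or `NA` (censored).
#' @export
compute_dt1 <- function(fit, horizon = Inf) {
  stopifnot(inherits(fit, "decay_fit"))
  if (!isTRUE(fit$converged)) return(structure(NA_real_, censored = FALSE))
  h <- if (is.finite(horizon)) horizon else 10 * max(fit$tau1, fit$tau2)
  out <- .decay_crossing(fit, exp(-1), h)
  structure(out, censored = is.na(out))
}

#' Residual recovery time DT2
#'
#' The 90% recovery time T90 is when the fitted decay reaches 10% of its
#' peak-time amplitude above baseline; DT2 = T90 - DT1 is the additional
#' time needed to recover after DT1. Positive for any monotone decay.
#'
#' @param fit a `decay_fit`.
#' @param dt1 DT1 in seconds (from [compute_dt1()]).
#' @param horizon maximum time after the peak within the sweep, seconds.
#' @return DT2 in seconds, or `NA` with attribute `censored` if the
#'   transient has not recovered 90% within the sweep.
#' @export
compute_dt2 <- function(fit, dt1, horizon = Inf) {
  stopifnot(inherits(fit, "decay_fit"))
  if (!isTRUE(fit$converged) || is.na(dt1)) return(structure(NA_real_, censored = FALSE))
  h <- if (is.finite(horizon)) horizon else 20 * max(fit$tau1, fit$tau2)
  t90 <- .decay_crossing(fit, 0.1, h)
  structure(if (is.na(t90)) NA_real_ else t90 - dt1, censored = is.na(t90))
}

#' Extract transient parameters for one cell
#'
#' Runs the full chain on the repeated sweeps of a cell: spatial average of
#' each repeat, repeat averaging, zero-phase low-pass filtering, iterative
#' smoothing, dF/F conversion, then peak/rise/decay quantification.
#' Resting fluorescence is measured on the raw averaged trace. Cells whose
#' peak does not exceed the responder threshold are flagged
#' `responder = FALSE` and their rise/decay parameters are `NA`.
#'
#' @param recordings list of `linescan` repeats of one cell.
#' @param config a [run_config()] (or the default).
#' @return One-row data.frame: labels, `resting_f_au`, `peak_pct`, `rt_s`,
#'   `slope_pct_per_s`, `dt1_s`, `dt2_s`, `responder`, `f0_au`,
#'   `prestim_sd_pct`, `fit_r2_rise`, `fit_r2_decay`, `dt1_censored`,
#'   `dt2_censored`.
#' @export
extract_parameters <- function(recordings, config = default_config()) {
  if (inherits(recordings, "linescan")) recordings <- list(recordings)
  stopifnot(length(recordings) >= 1,
            all(vapply(recordings, inherits, logical(1), "linescan")))
  pp <- config$preprocessing
  ft <- config$fitting
  raw <- average_repeats(lapply(recordings, spatial_average))
  resting <- resting_fluorescence(raw, ft$resting_window_s)
  den <- iterative_smooth(
    lowpass_filter(raw, cutoff = pp$filter_cutoff_hz, order = pp$filter_order),
    window = pp$smooth_window, iterations = pp$smooth_iterations)
  dff <- compute_dff(den, baseline_window = unlist(pp$baseline_window_s))
  prestim <- dff$values[dff$time >= pp$baseline_window_s[[1]] &
                          dff$time <= pp$baseline_window_s[[2]]]
  pk <- detect_peak(dff)
  labels <- recordings[[1]]$labels
  row <- data.frame(
    cell_id = labels$cell %||% NA_character_,
    animal = labels$animal %||% NA_character_,
    litter = labels$litter %||% NA_character_,
    sex = labels$sex %||% NA_character_,
    condition = labels$condition %||% NA_character_,
    resting_f_au = resting,
    peak_pct = pk$peak,
    rt_s = NA_real_, slope_pct_per_s = NA_real_,
    dt1_s = NA_real_, dt2_s = NA_real_,
    responder = pk$peak > ft$responder_threshold_pct,
    f0_au = dff$f0,
    prestim_sd_pct = sd(prestim),
    fit_r2_rise = NA_real_, fit_r2_decay = NA_real_,
    dt1_censored = FALSE, dt2_censored = FALSE,
    stringsAsFactors = FALSE)
  if (!row$responder) return(row)
  row$rt_s <- rise_time(pk$t_peak, dff$stimulus)
  rise <- tryCatch(fit_rise(dff, t_peak = pk$t_peak, degree = ft$rise_degree),
                   error = function(e) NULL)
  if (!is.null(rise)) {
    row$slope_pct_per_s <- rise$slope
    row$fit_r2_rise <- rise$r_squared
  }
  horizon <- max(dff$time) - pk$t_peak
  dec <- tryCatch(
    fit_decay(dff, pk$t_peak, tau_bounds = unlist(ft$tau_bounds_s),
              n_starts = ft$n_starts, max_points = ft$decay_max_points),
    error = function(e) NULL)
  if (!is.null(dec) && isTRUE(dec$converged) && !dec$non_decaying) {
    dt1 <- compute_dt1(dec, horizon)
    dt2 <- compute_dt2(dec, as.numeric(dt1), horizon)
    row$dt1_s <- as.numeric(dt1)
    row$dt2_s <- as.numeric(dt2)
    row$dt1_censored <- isTRUE(attr(dt1, "censored"))
    row$dt2_censored <- isTRUE(attr(dt2, "censored"))
    row$fit_r2_decay <- dec$r_squared
  }
  row
}
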