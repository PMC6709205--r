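#' Simple linear regression between two transient parameters
#'
#' Ordinary least squares of `y` on `x` with the usual t test on the slope
#' (two-sided, `n - 2` degrees of freedom).
#'
#' @param x,y numeric vectors of equal length (pairs with missing values
#'   are dropped).
#' @return data.frame with `r_squared`, `beta`, `t_stat`, `df`, `p_value`,
#'   `n`.
#' @export
ols_regression <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("ols_regression: need at least 3 complete pairs")
  if (sd(x) == 0) stop("ols_regression: x is constant")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  beta <- unname(coef(fit)[2])
  tstat <- unname(sm$coefficients[2, "t value"])
  data.frame(r_squared = unname(sm$r.squared), beta = beta, t_stat = tstat,
             df = n - 2L, p_value = 2 * pt(abs(tstat), n - 2, lower.tail = FALSE),
             n = n)
}

#' Freedman-Diaconis histogram bins
#'
#' Bin width `2 * IQR * n^(-1/3)` with linear-interpolation (type 7)
#' quantiles; the number of bins is the range divided by the width, rounded
#' up. Falls back to the square-root rule (with a warning) when the IQR is
#' zero.
#'
#' @param x numeric vector (n >= 2; non-finite values dropped).
#' @return List with `bin_width`, `n_bins`, `rule` ("fd" or "sqrt").
#' @export
fd_bins <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2) stop("fd_bins: need at least 2 finite values")
  iqr <- unname(diff(quantile(x, c(0.25, 0.75), type = 7)))
  rng <- diff(range(x))
  if (iqr == 0) {
    warning("fd_bins: IQR is zero; falling back to the square-root rule")
    n_bins <- max(1L, ceiling(sqrt(n)))
    width <- if (rng > 0) rng / n_bins else 1
    return(list(bin_width = width, n_bins = n_bins, rule = "sqrt"))
  }
  width <- 2 * iqr * n^(-1 / 3)
  n_bins <- max(1L, ceiling(rng / width))
  list(bin_width = width, n_bins = n_bins, rule = "fd")
}

#' Holm step-down multiple-comparison procedure
#'
#' Orders the p-values and rejects `p_(i)` while
#' `p_(i) <= alpha / (m - i + 1)`, stopping at the first failure. The
#' single-step Bonferroni family threshold `alpha / m` is reported
#' alongside (some analyses quote that fixed threshold; the two agree on
#' the smallest p-value).
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @param alpha family-wise error rate.
#' @return List with `decisions` (data.frame: `p_value`, `threshold`,
#'   `reject`, in input order), `bonferroni_threshold`, `alpha`.
#' @export
holm_stepdown <- function(p_values, alpha = 0.05) {
  m <- length(p_values)
  if (m == 0)
    return(list(decisions = data.frame(p_value = numeric(0),
                                       threshold = numeric(0),
                                       reject = logical(0)),
                bonferroni_threshold = numeric(0), alpha = alpha))
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("holm_stepdown: p-values must lie in [0, 1]")
  ord <- order(p_values)
  thresh_sorted <- alpha / (m - seq_len(m) + 1)
  ok <- p_values[ord] <= thresh_sorted
  reject_sorted <- cumprod(ok) == 1  # stop at the first failure
  reject <- logical(m); reject[ord] <- reject_sorted
  threshold <- numeric(m); threshold[ord] <- thresh_sorted
  list(decisions = data.frame(p_value = p_values, threshold = threshold,
                              reject = reject),
       bonferroni_threshold = alpha / m, alpha = alpha)
}

#' Paired t test with mean percent change
#'
#' t test on pairwise differences (df = n - 1, two sided), plus the mean
#' across cells of the per-cell percent change `100 (after - before) /
#' before`, the effect-size summary used for drug effects.
#'
#' @param before,after numeric vectors of equal length, matched by cell
#'   (pairs with missing values are dropped).
#' @return List with `t`, `df`, `p_value`, `mean_pct_change`, `n`.
#' @export
paired_t <- function(before, after) {
  if (length(before) != length(after)) stop("paired_t: mismatched pairing")
  keep <- is.finite(before) & is.finite(after)
  before <- before[keep]; after <- after[keep]
  n <- length(before)
  if (n < 2) stop("paired_t: need at least 2 complete pairs")
  d <- after - before
  pct <- mean(100 * d / before)
  if (sd(d) == 0) {
    if (all(d == 0)) return(list(t = 0, df = n - 1L, p_value = 1,
                                 mean_pct_change = pct, n = n))
    warning("paired_t: zero-variance differences; t is infinite")
    return(list(t = sign(mean(d)) * Inf, df = n - 1L, p_value = 0,
                mean_pct_change = pct, n = n))
  }
  tt <- t.test(after, before, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_pct_change = pct, n = n)
}

#' Summary table of population transient parameters
#'
#' Peak amplitude is summarised as median [IQR] (its distribution is
#' right-skewed); resting fluorescence, RT, DT1 and DT2 as mean +/- SD.
#' Summaries are per group (default: condition); groups with no data are
#' omitted with a warning.
#'
#' @param table data.frame of per-cell parameters as produced by
#'   [extract_parameters()].
#' @param group_by grouping column name(s).
#' @return data.frame: `group`, `parameter`, `n`, `center`, `spread_lo`,
#'   `spread_hi`, `summary_type`.
#' @export
summarize_population <- function(table, group_by = "condition") {
  stopifnot(is.data.frame(table), nrow(table) >= 1)
  pars <- c(resting_f_au = "mean_sd", peak_pct = "median_iqr",
            rt_s = "mean_sd", dt1_s = "mean_sd", dt2_s = "mean_sd")
  grp <- interaction(table[group_by], drop = FALSE)
  out <- list()
  for (g in levels(grp)) {
    sub <- table[grp == g, , drop = FALSE]
    if (nrow(sub) == 0) {
      warning("summarize_population: empty group '", g, "' omitted")
      next
    }
    for (pn in names(pars)) {
      v <- sub[[pn]]
      v <- v[is.finite(v)]
      if (!length(v)) next
      if (pars[[pn]] == "median_iqr") {
        q <- quantile(v, c(0.25, 0.5, 0.75), type = 7)
        out[[length(out) + 1L]] <- data.frame(
          group = g, parameter = pn, n = length(v), center = unname(q[2]),
          spread_lo = unname(q[1]), spread_hi = unname(q[3]),
          summary_type = "median_iqr")
      } else {
        s <- if (length(v) > 1) sd(v) else 0
        out[[length(out) + 1L]] <- data.frame(
          group = g, parameter = pn, n = length(v), center = mean(v),
          spread_lo = mean(v) - s, spread_hi = mean(v) + s,
          summary_type = "mean_sd")
      }
    }
  }
  do.call(rbind, out)
}

#' Natural-log transformed peak column for mixed-model export
#'
#' Adds `log_peak_pct = log(peak_pct)` (NA for non-positive peaks) to a
#' parameter table; peak amplitudes are log-transformed before mixed-model
#' analyses to meet normality assumptions. The mixed models themselves are
#' fitted outside this package.
#'
#' @param table per-cell parameter data.frame.
#' @return The table with a `log_peak_pct` column appended.
#' @export
add_log_peak <- function(table) {
  stopifnot(is.data.frame(table))
  lp <- rep(NA_real_, nrow(table))
  ok <- is.finite(table$peak_pct) & table$peak_pct > 0
  lp[ok] <- log(table$peak_pct[ok])
  table$log_peak_pct <- lp
  table
}
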