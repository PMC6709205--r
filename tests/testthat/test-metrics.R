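test_that("resting fluorescence is the mean of the first 100 ms", {
  dt <- 1 / 700  # 0.1 s spans exactly 70 samples
  t <- (seq_len(2000) - 1) * dt
  st <- stimulus_protocol(onset_time = 2)
  expect_equal(resting_fluorescence(fluor_trace(rep(438, 2000), t, st)), 438)

  v <- rep(410, 2000)
  v[seq(1, 2000, 2)] <- 400; v[seq(2, 2000, 2)] <- 420
  expect_equal(resting_fluorescence(fluor_trace(v, t, st)), 410)

  set.seed(6)
  r <- runif(2000, 300, 500)
  expected <- mean(r[seq_len(sum(t < 0.1))])
  expect_equal(resting_fluorescence(fluor_trace(r, t, st)), expected)

  expect_error(resting_fluorescence(fluor_trace(r[1:10], t[1:10], st)), "shorter")
})

test_that("peak detection finds the post-onset maximum, earliest on ties", {
  dt <- 28.16 / 20000
  tri <- make_decay_dff(function(tt) pmax(0, 50 * (1 - tt / 3)), t_peak = 6.2,
                        peak = 50)
  pk <- detect_peak(tri)
  expect_equal(pk$peak, 50, tolerance = 1e-3)
  expect_equal(pk$t_peak, 6.2, tolerance = 2 * dt)

  flat <- make_decay_dff(function(tt) rep(0, length(tt)), peak = 0)
  expect_equal(detect_peak(flat)$peak, 0)

  # plateau: two equal maxima; the earlier wins
  v <- rep(0, 1000)
  v[300] <- 10; v[600] <- 10
  d <- structure(list(values = v, f0 = 400, time = (seq_len(1000) - 1) * dt,
                      stimulus = stimulus_protocol(onset_time = 0)),
                 class = "dff_trace")
  expect_equal(detect_peak(d)$t_peak, 299 * dt)
})

test_that("rise time is peak time minus onset", {
  st <- stimulus_protocol(onset_time = 5)
  expect_equal(rise_time(6.22, st), 1.22)
  expect_equal(rise_time(5, st), 0)
  expect_error(rise_time(4.9, st), "precedes")
})

test_that("rise fitting recovers slope of simple and simulated rises", {
  dt <- 28.16 / 20000
  ramp <- make_decay_dff(function(tt) 120 * exp(-tt / 2), t_peak = 6.2, peak = 120)
  fit <- fit_rise(ramp, t_peak = 6.2, degree = 1)
  expect_equal(fit$slope, 100, tolerance = 1e-6)  # 120% over 1.2 s
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  expect_error(fit_rise(ramp, onset = 6.19, t_peak = 6.1945, degree = 3), "samples")

  # smooth noiseless transient with a cubic (smoothstep) rise: fitted slope
  # within 5% of the maximum finite-difference derivative
  dt <- 28.16 / 20000
  time <- seq(0, 28.16 - dt, by = dt)
  v <- numeric(length(time))
  ris <- time >= 5 & time < 6.2
  ss <- (time[ris] - 5) / 1.2
  v[ris] <- 60 * (3 * ss^2 - 2 * ss^3)
  v[time >= 6.2] <- 60 * exp(-(time[time >= 6.2] - 6.2) / 2.5)
  d <- structure(list(values = v, f0 = 438, time = time,
                      stimulus = stimulus_protocol(onset_time = 5)),
                 class = "dff_trace")
  pk <- detect_peak(d)
  ft <- fit_rise(d, t_peak = pk$t_peak, degree = 3)
  sel <- d$time >= 5 & d$time <= pk$t_peak
  fd <- max(diff(d$values[sel]) / diff(d$time[sel]))
  expect_lt(abs(ft$slope - fd) / fd, 0.05)
})

test_that("bi-exponential decay fitting recovers known generating curves", {
  # mono-exponential: one component recovers tau within 2%, the other is tiny
  mono <- make_decay_dff(function(tt) 60 * exp(-tt / 2), peak = 60)
  f1 <- fit_decay(mono, t_peak = 6.2)
  expect_true(f1$converged)
  dom <- if (f1$a1 >= f1$a2) c(f1$a1, f1$tau1, f1$a2) else c(f1$a2, f1$tau2, f1$a1)
  expect_lt(abs(dom[2] - 2) / 2, 0.02)
  expect_lt(dom[3], 0.01 * 60)

  # two-component decay, noiseless: both taus within 5%
  bi <- make_decay_dff(function(tt) 30 * exp(-tt / 1) + 30 * exp(-tt / 5), peak = 60)
  f2 <- fit_decay(bi, t_peak = 6.2)
  expect_true(f2$converged)
  expect_lt(abs(f2$tau1 - 1) / 1, 0.05)
  expect_lt(abs(f2$tau2 - 5) / 5, 0.05)
  # residual essentially zero (relative to peak^2)
  t <- seq(0, 20, by = 0.01)
  resid <- max(abs(f2$a1 * exp(-t / f2$tau1) + f2$a2 * exp(-t / f2$tau2) +
                     f2$offset - (30 * exp(-t / 1) + 30 * exp(-t / 5))))
  expect_lt(resid^2, 1e-6 * 60^2)

  rising <- make_decay_dff(function(tt) 10 + 5 * tt / max(tt), peak = 10)
  f3 <- fit_decay(rising, t_peak = 6.2)
  expect_true(f3$non_decaying)
})

test_that("DT1 and DT2 match closed forms and a bisection oracle", {
  mkfit <- function(a1, tau1, a2, tau2) {
    structure(list(a1 = a1, a2 = a2, tau1 = tau1, tau2 = tau2, offset = 0,
                   r_squared = 1, converged = TRUE, non_decaying = FALSE),
              class = "decay_fit")
  }
  expect_equal(as.numeric(compute_dt1(mkfit(60, 2, 0, 10))), 2, tolerance = 1e-3)
  expect_equal(as.numeric(compute_dt1(mkfit(55, 2.62, 0, 10))), 2.62, tolerance = 1e-3)

  # bi-exponential: root of 0.5 e^-t + 0.5 e^-t/5 = e^-1 by bisection
  bis <- function(frac) {
    g <- function(t) 0.5 * exp(-t) + 0.5 * exp(-t / 5) - frac
    lo <- 0; hi <- 60
    for (i in 1:60) { mid <- (lo + hi) / 2; if (g(mid) > 0) lo <- mid else hi <- mid }
    (lo + hi) / 2
  }
  fit <- mkfit(30, 1, 30, 5)
  dt1 <- as.numeric(compute_dt1(fit))
  expect_equal(dt1, bis(exp(-1)), tolerance = 1e-4)

  # mono-exponential DT2 = tau (ln 10 - 1)
  d1 <- as.numeric(compute_dt1(mkfit(60, 2, 0, 10)))
  d2 <- as.numeric(compute_dt2(mkfit(60, 2, 0, 10), d1))
  expect_equal(d1 + d2, 2 * log(10), tolerance = 1e-3)
  expect_gt(d2, 0)

  expect_equal(as.numeric(compute_dt2(fit, dt1)), bis(0.1) - dt1, tolerance = 1e-4)

  # censoring: level not reached within the sweep horizon
  slow <- mkfit(60, 50, 0, 50)
  d <- compute_dt1(slow, horizon = 20)
  expect_true(is.na(d))
  expect_true(attr(d, "censored"))
})

test_that("extraction recovers ground truth and honours the responder rule", {
  p <- sim_cell_params(noise_sd = 0)
  ca <- simulate_calcium(p, default_protocol())
  f <- fluorescence_ideal(ca, p)
  rec <- linescan(matrix(f, nrow = 1), sampling_interval = ca$dt,
                  stimulus = default_protocol())
  row <- extract_parameters(list(rec))
  base_idx <- ca$time >= 0.5 & ca$time <= 4.5
  dff_true <- 100 * (f - mean(f[base_idx])) / mean(f[base_idx])
  pk_true <- max(dff_true)
  tpk_true <- ca$time[which.max(dff_true)]
  expect_lt(abs(row$peak_pct - pk_true) / pk_true, 0.05)
  expect_lt(abs(row$rt_s - (tpk_true - 5)) / (tpk_true - 5), 0.05)
  g <- function(tt) approx(ca$time, dff_true, xout = tt)$y
  t63 <- uniroot(function(tt) g(tt) - exp(-1) * pk_true,
                 c(tpk_true, 28))$root - tpk_true
  expect_lt(abs(row$dt1_s - t63) / t63, 0.05)

  # flat recording: non-responder without decay parameters
  flat <- linescan(matrix(400, nrow = 2, ncol = 20000),
                   sampling_interval = 28.16 / 20000,
                   stimulus = default_protocol())
  frow <- extract_parameters(list(flat))
  expect_false(frow$responder)
  expect_true(is.na(frow$dt1_s))

  # three identical repeats equal single-repeat extraction
  r1 <- extract_parameters(list(rec))
  r3 <- extract_parameters(list(rec, rec, rec))
  expect_equal(r1$peak_pct, r3$peak_pct)
  expect_equal(r1$dt1_s, r3$dt1_s)
})

test_that("time rescaling and amplitude scaling act as expected on the metrics", {
  # time rescale by s multiplies RT/DT1/DT2 by s, leaves peak unchanged
  base_fun <- function(tt) 60 * exp(-tt / 2)
  d1 <- make_decay_dff(base_fun, t_peak = 6.2)
  s <- 1.5
  d2 <- make_decay_dff(function(tt) 60 * exp(-tt / (2 * s)), t_peak = 5 + 1.2 * s)
  r1 <- list(pk = detect_peak(d1)); r2 <- list(pk = detect_peak(d2))
  expect_equal(r2$pk$peak, r1$pk$peak, tolerance = 1e-3)
  rt1 <- rise_time(r1$pk$t_peak, d1$stimulus)
  rt2 <- rise_time(r2$pk$t_peak, d2$stimulus)
  expect_equal(rt2 / rt1, s, tolerance = 0.01)
  f1 <- fit_decay(d1, r1$pk$t_peak); f2 <- fit_decay(d2, r2$pk$t_peak)
  dt1a <- as.numeric(compute_dt1(f1)); dt1b <- as.numeric(compute_dt1(f2))
  expect_equal(dt1b / dt1a, s, tolerance = 0.01)

  # amplitude scaling leaves RT/DT1 unchanged, scales peak and slope
  a <- 2.5
  d3 <- make_decay_dff(function(tt) a * 60 * exp(-tt / 2), t_peak = 6.2,
                       peak = a * 60)
  pk3 <- detect_peak(d3)
  expect_equal(pk3$peak / r1$pk$peak, a, tolerance = 1e-6)
  f3 <- fit_decay(d3, pk3$t_peak)
  expect_equal(as.numeric(compute_dt1(f3)), dt1a, tolerance = 0.01)
  sl1 <- fit_rise(d1, t_peak = r1$pk$t_peak, degree = 3)$slope
  sl3 <- fit_rise(d3, t_peak = pk3$t_peak, degree = 3)$slope
  expect_equal(sl3 / sl1, a, tolerance = 0.01)
})
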