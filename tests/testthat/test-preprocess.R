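make_rec <- function(mat, dt = 1 / 700) {
  linescan(mat, sampling_interval = dt, stimulus = stimulus_protocol(onset_time = 0.5))
}

test_that("spatial averaging equals per-sample column means", {
  rec <- make_rec(matrix(7, nrow = 4, ncol = 50))
  expect_equal(spatial_average(rec)$values, rep(7, 50))

  rec2 <- make_rec(matrix(c(0, 10), nrow = 2, ncol = 1))
  expect_equal(spatial_average(rec2)$values, 5)

  set.seed(1)
  m <- matrix(runif(76 * 1000, 0, 4095), nrow = 76)
  tr <- spatial_average(make_rec(m))
  brute <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    s <- 0
    for (i in seq_len(nrow(m))) s <- s + m[i, j]
    brute[j] <- s / nrow(m)
  }
  expect_equal(tr$values, brute)
})

test_that("zero-phase Butterworth has unit DC gain and bounded stop-band leakage", {
  dt <- 1 / 710
  n <- 4000
  t <- (seq_len(n) - 1) * dt
  const <- fluor_trace(rep(100, n), t, stimulus_protocol(onset_time = 3))
  expect_lt(max(abs(lowpass_filter(const, 10, 4)$values - 100)), 1e-9)

  # sinusoid at 10x cutoff: output amplitude below the squared single-pass
  # analytic Butterworth magnitude at that frequency
  f_sin <- 100; cutoff <- 10
  sine <- fluor_trace(sin(2 * pi * f_sin * t), t, stimulus_protocol(onset_time = 3))
  out <- lowpass_filter(sine, cutoff, 4)
  core <- out$values[500:(n - 500)]
  gain_bound <- butter_gain2(f_sin, cutoff, 4)  # |H|^2 of one pass
  # the analytic bound sits near the double-precision noise floor of the
  # forward-backward recursion; allow that floor on top of it
  expect_lt(max(abs(core)), gain_bound + 1e-7)

  # slow Gaussian bump: zero phase means the peak does not move
  bump <- exp(-((t - 3)^2) / (2 * 1^2))
  tb <- fluor_trace(bump, t, stimulus_protocol(onset_time = 5))
  out2 <- lowpass_filter(tb, cutoff, 4)
  expect_lte(abs(which.max(out2$values) - which.max(bump)), 1)

  expect_error(lowpass_filter(const, cutoff = 400, order = 4), "Nyquist")
})

test_that("iterative smoothing is a repeated boxcar convolution", {
  t <- seq(0, 1, length.out = 201)
  const <- fluor_trace(rep(3.5, 201), t, stimulus_protocol(onset_time = 0.99))
  expect_equal(iterative_smooth(const, 15, 3)$values, rep(3.5, 201))

  imp <- rep(0, 201); imp[101] <- 1
  sm <- iterative_smooth(fluor_trace(imp, t, stimulus_protocol(onset_time = 0.99)), 3, 1)
  expect_equal(sm$values[101], 1 / 3)
  expect_equal(sm$values[100], 1 / 3)

  # two passes equal an explicit double convolution with reflected edges
  set.seed(2)
  x <- rnorm(120)
  w <- 5; h <- 2
  brute_pass <- function(v) {
    vp <- c(v[(h + 1):2], v, v[(length(v) - 1):(length(v) - h)])
    out <- numeric(length(v))
    for (i in seq_along(v)) out[i] <- mean(vp[i:(i + w - 1)])
    out
  }
  tr <- fluor_trace(x, seq(0, 1, length.out = 120), stimulus_protocol(onset_time = 0.99))
  expect_equal(iterative_smooth(tr, w, 2)$values, brute_pass(brute_pass(x)),
               tolerance = 1e-12)

  # total variation never increases
  tv <- function(v) sum(abs(diff(v)))
  prev <- x
  for (it in 1:3) {
    cur <- iterative_smooth(tr, 15, it)$values
    expect_lte(tv(cur), tv(prev) + 1e-12)
    prev <- cur
  }

  expect_error(iterative_smooth(tr, 4, 1), "odd")
  expect_error(iterative_smooth(tr, 1, 1), "odd|window")
})

test_that("repeat averaging is the pointwise mean with matching metadata", {
  t <- seq(0, 1, length.out = 50)
  st <- stimulus_protocol(onset_time = 0.9)
  f <- function(v) fluor_trace(v, t, st)
  x <- sin(t * 6)
  expect_equal(average_repeats(list(f(x), f(x), f(x)))$values, x)
  expect_equal(average_repeats(list(f(x), f(-x)))$values, rep(0, 50))

  set.seed(3)
  a <- rnorm(50); b <- rnorm(50); cc <- rnorm(50)
  brute <- numeric(50)
  for (i in 1:50) brute[i] <- (a[i] + b[i] + cc[i]) / 3
  expect_equal(average_repeats(list(f(a), f(b), f(cc)))$values, brute)

  short <- fluor_trace(x[1:40], t[1:40], st)
  expect_error(average_repeats(list(f(x), short)), "length")
  other <- fluor_trace(x, t, stimulus_protocol(onset_time = 0.8))
  expect_error(average_repeats(list(f(x), other)), "stimulus")
})

test_that("dF/F conversion uses the pre-stimulus baseline", {
  dt <- 1 / 710
  t <- (seq_len(7000) - 1) * dt
  st <- stimulus_protocol(onset_time = 5)
  expect_equal(compute_dff(fluor_trace(rep(100, 7000), t, st))$values, rep(0, 7000))

  v <- rep(100, 7000); v[6000] <- 160
  d <- compute_dff(fluor_trace(v, t, st))
  expect_equal(d$f0, 100)
  expect_equal(d$values[6000], 60)

  expect_error(compute_dff(fluor_trace(rep(0, 7000), t, st)), "positive")
  expect_error(compute_dff(fluor_trace(v, t, st), baseline_window = c(1, 6)),
               "overlaps")
})

test_that("spatial and repeat averaging commute, and dF/F is scale free", {
  set.seed(4)
  st <- stimulus_protocol(onset_time = 0.05)
  recs <- lapply(1:3, function(i)
    linescan(matrix(runif(8 * 60, 100, 200), nrow = 8), sampling_interval = 1 / 700,
             stimulus = st))
  via_traces <- average_repeats(lapply(recs, spatial_average))
  pooled <- Reduce(`+`, lapply(recs, `[[`, "intensity")) / 3
  via_matrix <- spatial_average(linescan(pooled, sampling_interval = 1 / 700,
                                         stimulus = st))
  expect_equal(via_traces$values, via_matrix$values)

  dt <- 1 / 710
  t <- (seq_len(7000) - 1) * dt
  v <- 100 + 50 * exp(-((t - 6)^2))
  tr <- fluor_trace(v, t, stimulus_protocol(onset_time = 5))
  d1 <- compute_dff(tr)
  tr2 <- tr; tr2$values <- tr$values * 3.7
  d2 <- compute_dff(tr2)
  expect_equal(d1$values, d2$values, tolerance = 1e-12)

  # filtering preserves the mean of a long stationary segment within 0.1%
  set.seed(5)
  noise <- fluor_trace(100 + rnorm(8000), (seq_len(8000) - 1) * dt,
                       stimulus_protocol(onset_time = 11))
  filt <- lowpass_filter(noise, 10, 4)
  seg <- 1000:7000
  expect_lt(abs(mean(filt$values[seg]) - mean(noise$values[seg])) /
              mean(noise$values[seg]), 0.001)
})
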