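test_that("calcium stays at rest without pulses and follows the one-pulse closed form", {
  p <- sim_cell_params()
  none <- simulate_calcium(p, stimulus_protocol(train_duration = 0), duration = 5)
  expect_equal(max(abs(none$values - p$baseline_ca)), 0)

  one <- simulate_calcium(p, stimulus_protocol(onset_time = 1, pulse_frequency = 1,
                                               train_duration = 1), duration = 8)
  k <- p$k_serca + p$k_pmca
  t0 <- one$time[which.max(one$values)]
  after <- one$time >= t0
  expected <- p$baseline_ca + p$influx_per_ap * exp(-k * (one$time[after] - t0))
  expect_lt(max(abs(one$values[after] - expected)), 1e-8)
  expect_true(all(one$values >= p$baseline_ca - 1e-12))
})

test_that("RK4 integration matches a 100x-finer explicit-Euler oracle within 0.5%", {
  p <- sim_cell_params()
  proto <- stimulus_protocol(onset_time = 2)
  dur <- 10
  dt <- acquisition_defaults()$sampling_interval
  ca <- simulate_calcium(p, proto, duration = dur, dt = dt)
  f <- fluorescence_ideal(ca, p)
  orc <- euler_oracle(p, proto, dur, dt, refine = 100)
  expect_lt(rel_sup_err(ca$values, orc$calcium), 0.005)
  expect_lt(rel_sup_err(f, orc$fluor), 0.005)
})

test_that("simulate_calcium validates its inputs", {
  p <- sim_cell_params()
  expect_error(simulate_calcium(p, stimulus_protocol(), dt = 0), "dt")
  expect_error(simulate_calcium(p, stimulus_protocol(onset_time = 50), duration = 10),
               "beyond sweep")
})

test_that("constant calcium yields the equilibrium-binding fluorescence", {
  p <- sim_cell_params(noise_sd = 0)
  ca <- simulate_calcium(p, stimulus_protocol(train_duration = 0), duration = 5)
  f <- fluorescence_ideal(ca, p)
  act <- p$indicator_kon * p$baseline_ca^p$hill_n
  b_eq <- p$indicator_total * act / (act + p$indicator_koff)
  expect_equal(f, rep(p$f_rest + p$f_gain * b_eq, length(f)), tolerance = 1e-10)

  rec <- simulate_fluorescence(ca, p, pixels = 3, seed = 1)
  expect_equal(dim(rec$intensity), c(3L, length(f)))
  expect_equal(unname(rec$intensity[1, ]), unname(rec$intensity[2, ]))
})

test_that("fast binding approaches the Hill equilibrium closed form", {
  # kon large: bound fraction tracks c^n / (c^n + Kd) closely after settling
  p <- sim_cell_params(indicator_kon = 400, indicator_koff = 100, noise_sd = 0)
  proto <- stimulus_protocol(onset_time = 1)
  ca <- simulate_calcium(p, proto, duration = 8)
  f <- fluorescence_ideal(ca, p)
  cn <- ca$values^p$hill_n
  kd <- p$indicator_koff / p$indicator_kon
  f_eq <- p$f_rest + p$f_gain * p$indicator_total * cn / (cn + kd)
  settled <- ca$time > 2  # after the train; c varies on seconds scale
  expect_lt(max(abs(f[settled] - f_eq[settled])) / max(f_eq), 0.01)
})

test_that("noiseless peak fluorescence is monotone in pulse count and bath calcium", {
  p <- sim_cell_params(noise_sd = 0)
  peak_for <- function(n_pulses, bath = 1) {
    pp <- p; pp$bath_ca_factor <- bath
    proto <- stimulus_protocol(onset_time = 2, pulse_frequency = 50,
                               train_duration = n_pulses / 50)
    max(fluorescence_ideal(simulate_calcium(pp, proto, duration = 15), pp))
  }
  peaks <- vapply(c(1, 5, 10, 25, 50, 100), peak_for, 0)
  expect_true(all(diff(peaks) >= 0))
  peaks_ca <- vapply(c(0.1, 0.5, 1, 2), function(b) peak_for(25, b), 0)
  expect_true(all(diff(peaks_ca) >= 0))
})

test_that("identical seeds give identical recordings, different seeds differ", {
  p <- sim_cell_params()
  ca <- simulate_calcium(p, stimulus_protocol(onset_time = 1), duration = 3)
  a <- simulate_fluorescence(ca, p, pixels = 6, seed = 11)
  b <- simulate_fluorescence(ca, p, pixels = 6, seed = 11)
  d <- simulate_fluorescence(ca, p, pixels = 6, seed = 12)
  expect_identical(a$intensity, b$intensity)
  expect_false(identical(a$intensity, d$intensity))
})

test_that("population generation is deterministic and matches its spec", {
  expect_equal(nrow(draw_population_params(population_spec(0, 5))), 0)

  spec <- population_spec(4, 3, seed = 5)
  t1 <- draw_population_params(spec)
  t2 <- draw_population_params(spec)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 12)
  expect_equal(length(unique(t1$animal)), 4)

  # empirical mean of log influx within 3 standard errors of the location
  spec_big <- population_spec(20, 10, seed = 8)
  tab <- draw_population_params(spec_big)
  d <- spec_big$distributions$influx_per_ap
  se <- d$sdlog / sqrt(nrow(tab))
  expect_lt(abs(mean(log(tab$influx_per_ap)) - d$meanlog), 3 * se)

  pop <- generate_population(population_spec(2, 2, seed = 3), pixels = 4)
  expect_length(pop$cells, 4)
  expect_length(pop$cells[[1]]$recordings, 3)
  pop2 <- generate_population(population_spec(2, 2, seed = 3), pixels = 4)
  expect_identical(pop$cells[[4]]$recordings[[3]]$intensity,
                   pop2$cells[[4]]$recordings[[3]]$intensity)
})

test_that("a default population lands in the tuned bands and stays unimodal", {
  res <- run_pipeline(out_dir = file.path(tempdir(), "pop_prop"),
                      n_animals = 10, cells_per_animal = 10,
                      seed = 7, pixels = 8)
  use <- res$parameters[res$parameters$responder & !res$parameters$excluded, ]
  expect_gt(nrow(use), 80)
  # medians near the tuned targets (wide bands: these are sampling medians)
  expect_gt(median(use$peak_pct), 30)
  expect_lt(median(use$peak_pct), 95)
  expect_gt(mean(use$rt_s), 1.0)
  expect_lt(mean(use$rt_s), 1.7)
  expect_gt(mean(use$dt1_s, na.rm = TRUE), 2.1)
  expect_lt(mean(use$dt1_s, na.rm = TRUE), 3.3)
  expect_gt(mean(use$resting_f_au), 395)
  expect_lt(mean(use$resting_f_au), 485)
  # every parameter distribution unimodal; decay independent of size
  expect_true(all(res$stats$dip_tests$p_value > 0.05))
  r <- res$stats$regressions
  expect_lt(r$r_squared[r$x == "peak_pct" & r$y == "dt1_s"], 0.3)
})
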