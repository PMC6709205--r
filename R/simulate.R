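#' Default acquisition geometry of the line-scan system
#'
#' 20,000 line scans over 28.16 s (sampling interval ~1.408 ms, >700 Hz),
#' 76 pixels spanning 9.3 um.
#'
#' @return list with `n_samples`, `duration`, `sampling_interval`, `pixels`,
#'   `pixel_pitch_um`.
#' @export
acquisition_defaults <- function() {
  list(n_samples = 20000L, duration = 28.16,
       sampling_interval = 28.16 / 20000, pixels = 76L, pixel_pitch_um = 9.3)
}

#' Simulate intracellular free calcium for one sweep
#'
#' Integrates the single-compartment clearance model with fixed-step RK4 at
#' the sampling interval; each action potential adds
#' `influx_per_ap * bath_ca_factor` instantaneously at the nearest sample.
#' The initial condition is the resting steady state (equal to
#' `baseline_ca` at nominal pump rates).
#'
#' @param params a [sim_cell_params()] object.
#' @param protocol a [stimulus_protocol()].
#' @param duration sweep length, seconds. Must cover the pulse train.
#' @param dt sampling interval, seconds. Must be positive.
#' @return An object of class `calcium_trace`: list with `time`, `values`
#'   (free calcium), `params`, `protocol`, `dt`.
#' @export
simulate_calcium <- function(params, protocol,
                             duration = acquisition_defaults()$duration,
                             dt = acquisition_defaults()$sampling_interval) {
  stopifnot(inherits(params, "sim_cell_params"),
            inherits(protocol, "stimulus_protocol"))
  if (!is.numeric(dt) || dt <= 0) stop("simulate_calcium: dt must be > 0")
  pulses <- build_pulse_train(protocol)
  if (length(pulses) && max(pulses) > duration)
    stop("simulate_calcium: pulse train extends beyond sweep duration")
  n <- as.integer(round(duration / dt))
  pulse_idx <- if (length(pulses)) as.integer(round(pulses / dt)) + 1L else integer(0)
  k_tot <- params$k_serca + params$k_pmca
  c_init <- (params$k_serca * params$baseline_ca + params$leak) / k_tot
  pars <- c(k_serca = params$k_serca, k_pmca = params$k_pmca,
            baseline_ca = params$baseline_ca, leak = params$leak,
            indicator_kon = params$indicator_kon,
            indicator_koff = params$indicator_koff,
            indicator_total = params$indicator_total, hill_n = params$hill_n)
  out <- .sim_rk4_cpp(n, dt, pars, pulse_idx,
                      params$influx_per_ap * params$bath_ca_factor,
                      c_init, 0)
  structure(list(time = (seq_len(n) - 1) * dt, values = out[, 1],
                 params = params, protocol = protocol, dt = dt),
            class = "calcium_trace")
}

#' Simulate a line-scan recording from a calcium time course
#'
#' Integrates the indicator binding ODE
#' `db/dt = kon c^hill (Btot - b) - koff b` along the calcium trace
#' (fixed-step RK4, calcium linearly interpolated at half steps), starting
#' from binding equilibrium at the initial calcium level. Noiseless
#' fluorescence is `f_rest + f_gain * b`; each pixel row receives
#' independent Gaussian noise and is clipped to the 12-bit detector range
#' [0, 4095] and quantised to integer counts.
#'
#' @param calcium a `calcium_trace` from [simulate_calcium()].
#' @param params a [sim_cell_params()]; defaults to the parameters stored
#'   in `calcium`.
#' @param pixels number of pixels along the scanned line.
#' @param seed integer seed for the pixel noise; identical seeds give
#'   identical recordings.
#' @param labels optional named list of annotation labels (cell, animal,
#'   litter, sex, condition, repeat).
#' @return An object of class `linescan`; see [linescan()].
#' @export
simulate_fluorescence <- function(calcium, params = calcium$params,
                                  pixels = acquisition_defaults()$pixels,
                                  seed = NULL, labels = list()) {
  stopifnot(inherits(calcium, "calcium_trace"))
  if (!is.numeric(pixels) || pixels < 1) stop("simulate_fluorescence: pixels must be >= 1")
  pixels <- as.integer(pixels)
  f <- fluorescence_ideal(calcium, params)
  n <- length(f)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  noise <- if (params$noise_sd > 0) {
    matrix(rnorm(pixels * n, 0, params$noise_sd), nrow = pixels)
  } else matrix(0, nrow = pixels, ncol = n)
  intensity <- round(pmax(pmin(sweep(noise, 2, f, `+`), 4095), 0))
  linescan(intensity, sampling_interval = calcium$dt,
           pixel_pitch_um = acquisition_defaults()$pixel_pitch_um,
           stimulus = calcium$protocol, labels = labels)
}

#' Noiseless fluorescence time course for a calcium trace
#'
#' @param calcium a `calcium_trace`.
#' @param params a [sim_cell_params()].
#' @return Numeric vector of noiseless fluorescence, a.u.
#' @export
fluorescence_ideal <- function(calcium, params = calcium$params) {
  stopifnot(inherits(calcium, "calcium_trace"))
  c0 <- calcium$values[1]
  act0 <- params$indicator_kon * c0^params$hill_n
  b0 <- params$indicator_total * act0 / (act0 + params$indicator_koff)
  pars <- c(indicator_kon = params$indicator_kon,
            indicator_koff = params$indicator_koff,
            indicator_total = params$indicator_total, hill_n = params$hill_n)
  b <- .sim_b_cpp(calcium$values, calcium$dt, pars, b0)
  params$f_rest + params$f_gain * b
}

#' Construct a line-scan recording object
#'
#' @param intensity numeric matrix, pixels x samples, detector a.u. in
#'   [0, 4095].
#' @param sampling_interval seconds per line.
#' @param pixel_pitch_um spatial extent per pixel count reference (default
#'   9.3 um over 76 pixels).
#' @param stimulus a [stimulus_protocol()].
#' @param labels named list of annotations.
#' @return An object of class `linescan`.
#' @export
linescan <- function(intensity, sampling_interval, pixel_pitch_um = 9.3,
                     stimulus = stimulus_protocol(), labels = list()) {
  if (!is.matrix(intensity) || nrow(intensity) < 1 || ncol(intensity) < 1)
    stop("linescan: intensity must be a pixels x samples matrix")
  if (!is.numeric(sampling_interval) || sampling_interval <= 0)
    stop("linescan: sampling_interval must be > 0")
  structure(list(intensity = intensity, sampling_interval = sampling_interval,
                 pixel_pitch_um = pixel_pitch_um, stimulus = stimulus,
                 labels = labels),
            class = "linescan")
}

#' @export
print.linescan <- function(x, ...) {
  cat(sprintf("line scan: %d px x %d samples (%.2f s at %.1f Hz)\n",
              nrow(x$intensity), ncol(x$intensity),
              ncol(x$intensity) * x$sampling_interval, 1 / x$sampling_interval))
  invisible(x)
}

#' Simulate the repeated sweeps recorded for one cell
#'
#' Runs the standard sweep for the given (condition-adjusted) parameters
#' and returns `n_repeats` recordings with independent pixel noise.
#'
#' @param params a [sim_cell_params()].
#' @param protocol a [stimulus_protocol()].
#' @param n_repeats number of repeated sweeps (optical recordings are
#'   repeated three times per cell and averaged).
#' @param seed integer; repeat seeds are derived deterministically.
#' @param pixels pixels per line.
#' @param labels named list of annotations.
#' @return List of `linescan` objects.
#' @export
simulate_cell_recordings <- function(params, protocol = stimulus_protocol(),
                                     n_repeats = 3L, seed = 1L,
                                     pixels = acquisition_defaults()$pixels,
                                     labels = list()) {
  ca <- simulate_calcium(params, protocol)
  lapply(seq_len(n_repeats), function(r) {
    lab <- labels
    lab$repeat_id <- r
    simulate_fluorescence(ca, params, pixels = pixels,
                          seed = (seed + 7919L * (r - 1L)) %% .Machine$integer.max,
                          labels = lab)
  })
}

#' Specification of a simulated population
#'
#' Describes how many animals and cells to draw and the across-cell
#' distributions of the generative parameters. Calcium influx per action
#' potential is log-normal across cells, producing the strong rightward
#' skew seen in peak-amplitude distributions; rates and fluorescence
#' parameters are (truncated) normal. Animals are grouped into litters of
#' two and alternate male/female.
#'
#' @param n_animals number of animals.
#' @param cells_per_animal cells recorded per animal.
#' @param seed master seed; the population is fully reproducible from it.
#' @param distributions named list overriding entries of the default
#'   parameter distributions (each entry: `list(dist, ...)` with
#'   `dist = "lognormal"` (meanlog, sdlog), `"normal"` (mean, sd, min) or
#'   `"fixed"` (value)).
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_animals = 20L, cells_per_animal = 10L,
                            seed = 1L, distributions = list()) {
  if (n_animals < 0 || cells_per_animal < 0) stop("population_spec: counts must be >= 0")
  defaults <- .default_param_distributions()
  dist <- modifyList(defaults, distributions)
  bad <- vapply(dist, function(d) {
    (!is.null(d$sd) && d$sd < 0) || (!is.null(d$sdlog) && d$sdlog < 0)
  }, logical(1))
  if (any(bad)) stop("population_spec: distribution scales must be >= 0")
  structure(list(n_animals = as.integer(n_animals),
                 cells_per_animal = as.integer(cells_per_animal),
                 seed = as.integer(seed), distributions = dist),
            class = "population_spec")
}

.default_param_distributions <- function() {
  cfg <- default_config()$population$distributions
  cfg
}

.draw_one <- function(d) {
  switch(d$dist,
         fixed = d$value,
         normal = max(d$min %||% 0, rnorm(1, d$mean, d$sd)),
         lognormal = stats::rlnorm(1, d$meanlog, d$sdlog),
         stop("unknown distribution: ", d$dist))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Draw the ground-truth parameter table of a population
#'
#' Deterministic given the spec seed. Litters are consecutive animal pairs
#' and sex alternates within litters.
#'
#' @param spec a [population_spec()].
#' @return data.frame with one row per cell: `cell_id`, `animal`, `litter`,
#'   `sex`, `noise_seed` and one column per generative parameter.
#' @export
draw_population_params <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  n_cells <- spec$n_animals * spec$cells_per_animal
  if (n_cells == 0L) {
    return(data.frame(cell_id = character(0), animal = character(0),
                      litter = character(0), sex = character(0),
                      noise_seed = integer(0)))
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(spec$seed)
  rows <- vector("list", n_cells)
  i <- 0L
  for (a in seq_len(spec$n_animals)) {
    for (cc in seq_len(spec$cells_per_animal)) {
      i <- i + 1L
      draws <- lapply(spec$distributions, .draw_one)
      rows[[i]] <- data.frame(
        cell_id = sprintf("a%02d_c%02d", a, cc),
        animal = sprintf("animal%02d", a),
        litter = sprintf("litter%02d", (a + 1L) %/% 2L),
        sex = if (a %% 2L == 1L) "M" else "F",
        noise_seed = 0L,
        as.data.frame(draws))
    }
  }
  out <- do.call(rbind, rows)
  out$noise_seed <- sample.int(.Machine$integer.max - 1L, n_cells)
  out
}

.params_from_row <- function(row) {
  sim_cell_params(
    baseline_ca = row$baseline_ca, influx_per_ap = row$influx_per_ap,
    k_serca = row$k_serca, k_pmca = row$k_pmca,
    indicator_kon = row$indicator_kon, indicator_koff = row$indicator_koff,
    indicator_total = row$indicator_total, hill_n = row$hill_n,
    f_rest = row$f_rest, f_gain = row$f_gain, noise_sd = row$noise_sd,
    bath_ca_factor = row$bath_ca_factor)
}

#' Generate a labelled synthetic population with recordings
#'
#' Draws ground-truth parameters for every cell and simulates the standard
#' sweep three times per cell with independent pixel noise. Deterministic
#' given the spec seed. Note that recordings are large (a full-resolution
#' sweep is 76 x 20000 doubles); for population-scale runs prefer the
#' streaming pipeline in [run_pipeline()], which generates and processes
#' one cell at a time from the same parameter table.
#'
#' @param spec a [population_spec()].
#' @param condition condition label applied to every cell (see
#'   [apply_condition()]).
#' @param protocol the stimulus protocol.
#' @param pixels pixels per line (reduce for faster, lighter populations).
#' @param n_repeats sweeps per cell.
#' @return List with `params` (ground-truth data.frame) and `cells`, a list
#'   of per-cell lists (`cell_id`, labels, `params`, `recordings`).
#' @export
generate_population <- function(spec, condition = "baseline",
                                protocol = stimulus_protocol(),
                                pixels = acquisition_defaults()$pixels,
                                n_repeats = 3L) {
  tab <- draw_population_params(spec)
  cells <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    p <- apply_condition(.params_from_row(row), condition)
    labels <- list(cell = row$cell_id, animal = row$animal,
                   litter = row$litter, sex = row$sex, condition = condition)
    recs <- simulate_cell_recordings(p, protocol, n_repeats = n_repeats,
                                     seed = row$noise_seed, pixels = pixels,
                                     labels = labels)
    list(cell_id = row$cell_id, animal = row$animal, litter = row$litter,
         sex = row$sex, condition = condition, params = p, recordings = recs)
  })
  list(params = tab, cells = cells)
}
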