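#' Write a line-scan recording to disk
#'
#' Stores the intensity matrix as a 16-bit grayscale TIFF and the
#' acquisition/stimulus metadata in a JSON sidecar with the same base name
#' (`<base>.tif` + `<base>.json`). The round trip is lossless for integer
#' intensities in the detector range.
#'
#' @param rec a `linescan`.
#' @param path output path; a `.tif` extension is added/replaced as needed.
#' @return Invisibly, the two file paths written.
#' @export
write_linescan <- function(rec, path) {
  stopifnot(inherits(rec, "linescan"))
  base <- sub("\\.(tif|tiff)$", "", path)
  tif <- paste0(base, ".tif")
  json <- paste0(base, ".json")
  mat <- round(rec$intensity)
  if (any(mat < 0 | mat > 65535)) stop("write_linescan: intensities outside uint16 range")
  tiff::writeTIFF(mat / 65535, tif, bits.per.sample = 16L, compression = "none")
  meta <- list(sampling_interval_s = rec$sampling_interval,
               pixel_pitch_um = rec$pixel_pitch_um,
               stimulus = unclass(rec$stimulus),
               labels = rec$labels)
  jsonlite::write_json(meta, json, auto_unbox = TRUE, digits = NA)
  invisible(c(tif = tif, json = json))
}

#' Read a line-scan recording from disk
#'
#' Counterpart of [write_linescan()]; reads `<base>.tif` and
#' `<base>.json`. Missing required metadata fields raise an error naming
#' the field.
#'
#' @param path path to the `.tif` (or the common base name).
#' @return A `linescan`.
#' @export
read_linescan <- function(path) {
  base <- sub("\\.(tif|tiff)$", "", path)
  tif <- paste0(base, ".tif")
  json <- paste0(base, ".json")
  if (!file.exists(tif)) stop("read_linescan: missing TIFF file: ", tif)
  if (!file.exists(json)) stop("read_linescan: missing JSON sidecar: ", json)
  mat <- round(tiff::readTIFF(tif, as.is = FALSE) * 65535)
  meta <- jsonlite::read_json(json, simplifyVector = TRUE)
  for (field in c("sampling_interval_s", "stimulus")) {
    if (is.null(meta[[field]]))
      stop("read_linescan: metadata missing required field '", field, "'")
  }
  st <- meta$stimulus
  for (field in c("onset_time", "pulse_frequency", "train_duration")) {
    if (is.null(st[[field]]))
      stop("read_linescan: stimulus metadata missing required field '", field, "'")
  }
  protocol <- stimulus_protocol(onset_time = st$onset_time,
                                pulse_frequency = st$pulse_frequency,
                                train_duration = st$train_duration,
                                pulse_width_ms = st$pulse_width_ms %||% 0.1)
  linescan(mat, sampling_interval = meta$sampling_interval_s,
           pixel_pitch_um = meta$pixel_pitch_um %||% 9.3,
           stimulus = protocol,
           labels = as.list(meta$labels))
}

# deterministic CSV writer (fixed number formatting, no timestamps)
.write_table <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  for (cn in names(df)[num]) {
    df[[cn]] <- vapply(df[[cn]], function(v) {
      if (!is.finite(v)) return(if (is.na(v)) "NA" else as.character(v))
      sprintf("%.10g", v)
    }, character(1))
  }
  write.csv(df, path, row.names = FALSE, quote = TRUE)
}

#' Run the simulation-to-statistics pipeline
#'
#' Simulates a labelled population under a condition, extracts the
#' transient parameters of every cell (streaming: one cell's recordings
#' are generated, quantified and discarded before the next, keeping memory
#' flat), applies the damaged-cell exclusion rule, and writes the
#' parameter table, summary statistics, the inter-parameter regression
#' battery with Holm correction, dip tests of unimodality, and a run
#' manifest. Deterministic given the seeds: identical configurations and
#' seeds produce byte-identical CSVs.
#'
#' The exclusion rule is a reproducible proxy for the visual rejection of
#' overly bright or unstable cells: cells whose resting fluorescence or
#' pre-stimulus dF/F standard deviation exceed configurable population
#' quantiles are flagged and excluded from the statistics (with the reason
#' logged).
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param n_animals,cells_per_animal population size (defaults from
#'   config).
#' @param seed master seed for the population.
#' @param condition condition label applied to all cells.
#' @param pixels pixels per line; the default full resolution can be
#'   lowered for faster runs.
#' @param dump_traces if TRUE, writes the averaged raw trace of each cell
#'   as `traces/<cell>.csv` (time_s, value).
#' @return Invisibly, a list with the output `paths`, the `parameters`
#'   table (including excluded cells, flagged), and the `stats` tables.
#' @export
run_pipeline <- function(config = run_config(), out_dir,
                         n_animals = NULL, cells_per_animal = NULL,
                         seed = 1L, condition = "baseline",
                         pixels = NULL, dump_traces = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pop <- config$population
  spec <- population_spec(
    n_animals = n_animals %||% pop$n_animals,
    cells_per_animal = cells_per_animal %||% pop$cells_per_animal,
    seed = seed,
    distributions = pop$distributions)
  tab <- draw_population_params(spec)
  protocol <- default_protocol()
  px <- pixels %||% config$acquisition$pixels
  if (dump_traces) dir.create(file.path(out_dir, "traces"), showWarnings = FALSE)
  rows <- vector("list", nrow(tab))
  failures <- list()
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    p <- apply_condition(.params_from_row(row), condition,
                         tg_block_fraction = config$conditions$tg_block_fraction,
                         ph_block_fraction = config$conditions$ph_block_fraction,
                         ca_factors = unlist(config$conditions$ca_factors))
    labels <- list(cell = row$cell_id, animal = row$animal,
                   litter = row$litter, sex = row$sex, condition = condition)
    res <- tryCatch({
      recs <- simulate_cell_recordings(p, protocol, seed = row$noise_seed,
                                       pixels = px, labels = labels)
      if (dump_traces) {
        tr <- average_repeats(lapply(recs, spatial_average))
        .write_table(data.frame(time_s = tr$time, value = tr$values),
                     file.path(out_dir, "traces", paste0(row$cell_id, ".csv")))
      }
      extract_parameters(recs, config)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <- data.frame(
        cell_id = row$cell_id, reason = conditionMessage(res))
      next
    }
    rows[[i]] <- res
  }
  params <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  excl <- config$exclusion
  if (is.null(params)) {
    warning("run_pipeline: no cells produced any output")
    params <- data.frame()
  } else {
    q_rest <- quantile(params$resting_f_au, excl$resting_quantile, type = 7)
    q_sd <- quantile(params$prestim_sd_pct, excl$prestim_sd_quantile, type = 7)
    params$excluded <- params$resting_f_au > q_rest | params$prestim_sd_pct > q_sd
    params$exclusion_reason <- ifelse(
      params$resting_f_au > q_rest, "resting fluorescence above population quantile",
      ifelse(params$prestim_sd_pct > q_sd, "pre-stimulus variability above population quantile", ""))
    params <- add_log_peak(params)
  }
  paths <- list(parameters = file.path(out_dir, "parameters.csv"))
  .write_table(params, paths$parameters)
  if (length(failures)) {
    paths$failures <- file.path(out_dir, "excluded.csv")
    .write_table(do.call(rbind, failures), paths$failures)
  }

  stats <- NULL
  usable <- if (nrow(params) > 0)
    params[!params$excluded & params$responder, , drop = FALSE] else params
  if (nrow(usable) >= 4) {
    stats <- population_statistics(usable, alpha = config$stats$alpha,
                                   dip_n_boot = config$stats$dip_n_boot,
                                   dip_seed = seed)
    paths$summary <- file.path(out_dir, "summary.csv")
    paths$regressions <- file.path(out_dir, "regressions.csv")
    paths$dip_tests <- file.path(out_dir, "dip_tests.csv")
    .write_table(stats$summary, paths$summary)
    .write_table(stats$regressions, paths$regressions)
    .write_table(stats$dip_tests, paths$dip_tests)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("catrace")),
    seed = seed, condition = condition, pixels = px,
    n_animals = spec$n_animals, cells_per_animal = spec$cells_per_animal,
    n_cells_quantified = nrow(params),
    n_cells_failed = length(failures),
    n_cells_excluded = if (nrow(params) > 0) sum(params$excluded) else 0L,
    config_hash = .config_hash(unclass(config)),
    config = unclass(config))
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(paths = paths, parameters = params, stats = stats))
}

#' Population statistics battery
#'
#' The statistics applied to a per-cell parameter table: all pairwise
#' simple regressions among resting fluorescence, peak, slope, RT, DT1 and
#' DT2 (with Holm step-down correction and the Bonferroni family
#' threshold), dip tests of unimodality for the five headline parameters,
#' Freedman-Diaconis bin widths for their histograms, and the grouped
#' summary table.
#'
#' @param table per-cell parameter data.frame (responders).
#' @param alpha family-wise error rate for the corrections.
#' @param dip_n_boot Monte-Carlo replicates for dip p-values.
#' @param dip_seed seed for the dip null simulations.
#' @return List with `regressions`, `dip_tests`, `summary` data.frames.
#' @export
population_statistics <- function(table, alpha = 0.05, dip_n_boot = 1000,
                                  dip_seed = 1) {
  vars <- c("resting_f_au", "peak_pct", "slope_pct_per_s", "rt_s", "dt1_s", "dt2_s")
  vars <- vars[vars %in% names(table)]
  pairs <- utils::combn(vars, 2)
  regs <- lapply(seq_len(ncol(pairs)), function(j) {
    vx <- pairs[1, j]; vy <- pairs[2, j]
    r <- tryCatch(ols_regression(table[[vx]], table[[vy]]),
                  error = function(e) NULL)
    if (is.null(r)) return(NULL)
    cbind(data.frame(x = vx, y = vy), r)
  })
  regs <- do.call(rbind, regs[!vapply(regs, is.null, logical(1))])
  hs <- holm_stepdown(regs$p_value, alpha = alpha)
  regs$holm_threshold <- hs$decisions$threshold
  regs$holm_reject <- hs$decisions$reject
  regs$bonferroni_threshold <- hs$bonferroni_threshold

  dip_vars <- c("resting_f_au", "peak_pct", "rt_s", "dt1_s", "dt2_s")
  dips <- lapply(dip_vars, function(v) {
    x <- table[[v]]
    x <- x[is.finite(x)]
    if (length(x) < 4) return(NULL)
    null <- dip_null_distribution(length(x), dip_n_boot, seed = dip_seed)
    d <- dip_statistic(x)
    fb <- fd_bins(x)
    data.frame(parameter = v, n = length(x), dip = d,
               p_value = mean(null >= d),
               fd_bin_width = fb$bin_width, fd_n_bins = fb$n_bins)
  })
  dips <- do.call(rbind, dips[!vapply(dips, is.null, logical(1))])

  list(regressions = regs, dip_tests = dips,
       summary = summarize_population(table))
}
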