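.catrace_env <- new.env(parent = emptyenv())

#' Default run configuration
#'
#' Reads the packaged YAML configuration (acquisition geometry, standard
#' stimulus, simulator defaults, population distributions, preprocessing
#' and fitting parameters). The result is cached per session.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  if (is.null(.catrace_env$config)) {
    path <- system.file("extdata", "default_config.yaml", package = "catrace")
    if (path == "") {  # not installed (e.g. pkgload); fall back to source tree
      path <- file.path("inst", "extdata", "default_config.yaml")
    }
    .catrace_env$config <- yaml::read_yaml(path)
  }
  .catrace_env$config
}

#' Build a run configuration with overrides
#'
#' Starts from [default_config()] and applies nested overrides.
#'
#' @param ... named overrides, each a (possibly nested) list merged into the
#'   corresponding section, e.g. `preprocessing = list(filter_cutoff_hz = 15)`.
#' @return Nested named list with class `run_config`.
#' @export
run_config <- function(...) {
  over <- list(...)
  cfg <- default_config()
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == ""))
      stop("run_config: overrides must be named")
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("run_config: unknown section(s): ", paste(bad, collapse = ", "))
    cfg <- modifyList(cfg, over)
  }
  structure(cfg, class = c("run_config", "list"))
}

#' Default simulated-cell parameters from the packaged configuration
#'
#' @param overrides named list of parameter overrides.
#' @return A [sim_cell_params()] object.
#' @export
default_cell_params <- function(overrides = list()) {
  cfg <- default_config()$cell
  do.call(sim_cell_params, modifyList(cfg, overrides))
}

#' Standard stimulus protocol from the packaged configuration
#'
#' @return A [stimulus_protocol()].
#' @export
default_protocol <- function() {
  p <- default_config()$protocol
  stimulus_protocol(onset_time = p$onset_time_s,
                    pulse_frequency = p$pulse_frequency_hz,
                    train_duration = p$train_duration_s,
                    pulse_width_ms = p$pulse_width_ms)
}

# FNV-1a hash of a deparse()d object; used to stamp output manifests
.config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b %% 256))
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}
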