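#' Define an electrical stimulation protocol
#'
#' A pulse train delivered to the nerve, described by its onset within the
#' sweep, pulse frequency and train duration. The number of action
#' potentials is derived as `floor(pulse_frequency * train_duration)`, with
#' a minimum of one pulse whenever the train has positive duration (a 1 Hz
#' train of 1 s delivers a single pulse at onset). The default protocol is
#' the standard sweep: a 0.5-s train at 50 Hz starting 5 s into the
#' recording, evoking 25 action potentials.
#'
#' @param onset_time time of the first pulse, seconds from sweep start.
#' @param pulse_frequency pulse rate, Hz. Must be positive.
#' @param train_duration duration of the train, seconds. May be zero (no
#'   stimulus).
#' @param pulse_width_ms electrical pulse width in milliseconds. Metadata
#'   only; pulses are treated as instantaneous by the simulator.
#' @return An object of class `stimulus_protocol`.
#' @examples
#' p <- stimulus_protocol()
#' p$n_pulses  # 25
#' @export
stimulus_protocol <- function(onset_time = 5, pulse_frequency = 50,
                              train_duration = 0.5, pulse_width_ms = 0.1) {
  if (!is.numeric(onset_time) || onset_time < 0)
    stop("invalid protocol: onset_time must be >= 0")
  if (!is.numeric(pulse_frequency) || pulse_frequency <= 0)
    stop("invalid protocol: pulse_frequency must be > 0")
  if (!is.numeric(train_duration) || train_duration < 0)
    stop("invalid protocol: train_duration must be >= 0")
  n_pulses <- if (train_duration > 0) {
    max(1L, as.integer(floor(pulse_frequency * train_duration)))
  } else 0L
  structure(
    list(onset_time = onset_time,
         pulse_frequency = pulse_frequency,
         train_duration = train_duration,
         pulse_width_ms = pulse_width_ms,
         n_pulses = n_pulses),
    class = "stimulus_protocol")
}

#' Pulse times of a stimulation protocol
#'
#' Expands a protocol into the vector of pulse times
#' `onset_time + k / pulse_frequency`, `k = 0, ..., n_pulses - 1`.
#'
#' @param protocol a [stimulus_protocol()].
#' @return Numeric vector of pulse times in seconds (length `n_pulses`;
#'   empty for a zero-duration train).
#' @examples
#' length(build_pulse_train(stimulus_protocol()))  # 25
#' @export
build_pulse_train <- function(protocol) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  if (protocol$n_pulses == 0L) return(numeric(0))
  protocol$onset_time + (seq_len(protocol$n_pulses) - 1) / protocol$pulse_frequency
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf("stimulus: %g Hz x %g s (%d pulses) from t = %g s\n",
              x$pulse_frequency, x$train_duration, x$n_pulses, x$onset_time))
  invisible(x)
}
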