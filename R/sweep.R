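#' Construct a recorded sweep
#'
#' A sweep is one recorded trace (current in voltage clamp, membrane voltage
#' in current clamp) together with its sampling rate and stimulus markers.
#' Sample `i` covers time `(i - 1) / sampling_rate_hz * 1000` ms from sweep
#' start; all stimulus markers are in ms from sweep start.
#'
#' @param samples Numeric vector of samples (pA in voltage clamp, mV in
#'   current clamp).
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param mode `"voltage_clamp"` (evoked currents, downward) or
#'   `"current_clamp"` (evoked potentials, upward).
#' @param led_onset_ms LED stimulus onset, ms from sweep start. Must leave at
#'   least 40 ms of pre-stimulus baseline.
#' @param led_duration_ms LED pulse duration in ms.
#' @param holding Holding potential in mV (-85 for EPSC recordings, about
#'   -70 adjusted membrane for EPSP recordings).
#' @param pharmacology One of `"none"`, `"TTX"`, `"TTX_4AP"`.
#' @return An object of class `sweep`.
#' @export
new_sweep <- function(samples, sampling_rate_hz, mode = c("voltage_clamp", "current_clamp"),
                      led_onset_ms, led_duration_ms = 2,
                      holding = if (match.arg(mode) == "voltage_clamp") -85 else -70,
                      pharmacology = c("none", "TTX", "TTX_4AP")) {
  mode <- match.arg(mode)
  pharmacology <- match.arg(pharmacology)
  if (!is.numeric(samples) || length(samples) == 0L) {
    stop("`samples` must be a non-empty numeric vector", call. = FALSE)
  }
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0) {
    stop("`sampling_rate_hz` must be positive", call. = FALSE)
  }
  if (led_onset_ms < 40) {
    stop("`led_onset_ms` must be >= 40 ms so the baseline window fits", call. = FALSE)
  }
  structure(
    list(
      samples = as.numeric(samples),
      sampling_rate_hz = as.numeric(sampling_rate_hz),
      mode = mode,
      led_onset_ms = as.numeric(led_onset_ms),
      led_duration_ms = as.numeric(led_duration_ms),
      holding = as.numeric(holding),
      pharmacology = pharmacology
    ),
    class = "sweep"
  )
}

#' @export
print.sweep <- function(x, ...) {
  cat(sprintf(
    "<sweep> %s, %d samples @ %g kHz (%.1f ms), LED %g ms for %g ms, %s\n",
    x$mode, length(x$samples), x$sampling_rate_hz / 1000,
    length(x$samples) / x$sampling_rate_hz * 1000,
    x$led_onset_ms, x$led_duration_ms, x$pharmacology
  ))
  invisible(x)
}

# time of sample i (1-based) in ms from sweep start
sweep_times_ms <- function(sweep) {
  (seq_along(sweep$samples) - 1) / sweep$sampling_rate_hz * 1000
}

sweep_duration_ms <- function(sweep) {
  length(sweep$samples) / sweep$sampling_rate_hz * 1000
}
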