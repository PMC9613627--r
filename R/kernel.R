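#' Difference-of-exponentials synaptic kernel
#'
#' Normalized double-exponential waveform
#' \eqn{k (e^{-t/\tau_d} - e^{-t/\tau_r})} with the scale factor \eqn{k}
#' chosen so the peak equals 1. This is the standard phenomenological shape
#' for a postsynaptic current: fast rise (\eqn{\tau_r}), slow decay
#' (\eqn{\tau_d}).
#'
#' @param t_ms Time since event onset in ms; values `< 0` return 0.
#' @param rise_tau_ms,decay_tau_ms Rise and decay time constants in ms;
#'   must satisfy `0 < rise_tau_ms < decay_tau_ms`.
#' @return Kernel values, unit peak.
#' @export
psc_kernel <- function(t_ms, rise_tau_ms, decay_tau_ms) {
  stopifnot(rise_tau_ms > 0, decay_tau_ms > rise_tau_ms)
  tp <- psc_kernel_peak_time(rise_tau_ms, decay_tau_ms)
  peak <- exp(-tp / decay_tau_ms) - exp(-tp / rise_tau_ms)
  out <- ifelse(t_ms < 0, 0,
                (exp(-t_ms / decay_tau_ms) - exp(-t_ms / rise_tau_ms)) / peak)
  out
}

#' Analytic peak time of the difference-of-exponentials kernel
#'
#' @inheritParams psc_kernel
#' @return Time to peak from event onset, ms.
#' @export
psc_kernel_peak_time <- function(rise_tau_ms, decay_tau_ms) {
  rise_tau_ms * decay_tau_ms / (decay_tau_ms - rise_tau_ms) *
    log(decay_tau_ms / rise_tau_ms)
}
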