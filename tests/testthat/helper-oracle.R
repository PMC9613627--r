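# Independent dense-grid oracle for evoked-event metrics.
#
# Evaluates the analytic difference-of-exponentials event on a 1 MHz grid
# and measures amplitude, 20-80% extrapolated latency, and kinetics by
# brute-force scans over that grid. Shares no code with the package's
# interpolation-based measurement path.
oracle_event_metrics <- function(amplitude, latency_ms, rise_tau_ms, decay_tau_ms,
                                 grid_hz = 1e6, window_ms = 35) {
  dt <- 1000 / grid_hz
  t <- seq(0, window_ms, by = dt) # ms after LED onset
  tt <- t - latency_ms
  raw <- ifelse(tt < 0, 0, exp(-tt / decay_tau_ms) - exp(-tt / rise_tau_ms))
  tp <- rise_tau_ms * decay_tau_ms / (decay_tau_ms - rise_tau_ms) *
    log(decay_tau_ms / rise_tau_ms)
  peak_val <- exp(-tp / decay_tau_ms) - exp(-tp / rise_tau_ms)
  d <- amplitude * raw / peak_val
  peak_i <- which.max(d)
  amp <- d[peak_i]
  peak_t <- t[peak_i]
  t20 <- t[which(d >= 0.2 * amp)[1]]
  t80 <- t[which(d >= 0.8 * amp)[1]]
  lat <- t20 - (t80 - t20) / 3
  after <- which(t > peak_t)
  dec_i <- after[which(d[after] <= amp / exp(1))[1]]
  list(amplitude = amp, peak_time_ms = peak_t, latency_ms = lat,
       rise_time_ms = t80 - t20, time_to_peak_ms = peak_t - lat,
       decay_time_ms = t[dec_i] - peak_t)
}

# small, fast generator config used across tests
test_config <- function(...) {
  generator_config(sweep_duration_ms = 120, ...)
}

# a hand-built linear-rise sweep: baseline until onset + 3 ms, linear rise
# to a plateau of -`amp` reached at onset + 13 ms (voltage clamp)
linear_rise_sweep <- function(amp = 100, fs = 20000, onset = 50) {
  t <- (0:(0.12 * fs) - 0) / fs * 1000
  x <- rep(0, length(t))
  ris <- t >= onset + 3 & t <= onset + 13
  x[ris] <- -amp * (t[ris] - onset - 3) / 10
  x[t > onset + 13] <- -amp
  new_sweep(x, fs, "voltage_clamp", led_onset_ms = onset)
}
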