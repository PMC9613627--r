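#' Baseline statistics of a sweep
#'
#' Mean and standard deviation of the trace over the 40 ms immediately
#' preceding the LED stimulus onset (window `[onset - 40, onset)`,
#' half-open on the right).
#'
#' @param sweep A [new_sweep()] object.
#' @param window_ms Baseline window length in ms (default 40).
#' @return List with `baseline_mean` and `baseline_sd`.
#' @export
compute_baseline <- function(sweep, window_ms = 40) {
  t <- sweep_times_ms(sweep)
  idx <- which(t >= sweep$led_onset_ms - window_ms & t < sweep$led_onset_ms)
  if (length(idx) == 0L || t[idx[1]] > sweep$led_onset_ms - window_ms + 1 / sweep$sampling_rate_hz * 1000) {
    stop("insufficient pre-stimulus samples for a ", window_ms,
         " ms baseline window", call. = FALSE)
  }
  x <- sweep$samples[idx]
  list(baseline_mean = mean(x), baseline_sd = stats::sd(x))
}

# Baseline-subtracted deflection, with evoked polarity mapped to positive:
# downward (negative) in voltage clamp, upward in current clamp.
deflection_trace <- function(sweep, baseline_mean) {
  sgn <- if (sweep$mode == "voltage_clamp") -1 else 1
  sgn * (sweep$samples - baseline_mean)
}

#' Evoked-response amplitude
#'
#' The response peak is the extremum of the trace within 35 ms after LED
#' onset (window `(onset, onset + 35]`), relative to the baseline mean;
#' polarity is fixed by recording mode (downward currents in voltage clamp,
#' upward potentials in current clamp). The amplitude is reported as a
#' magnitude. Ties between equal extrema go to the earliest time.
#'
#' @param sweep A [new_sweep()] object.
#' @param baseline Optional precomputed [compute_baseline()] result.
#' @param window_ms Response window length after LED onset (default 35).
#' @return List with `amplitude`, `peak_time_ms` (relative to LED onset),
#'   `baseline_mean`, `baseline_sd`.
#' @export
measure_amplitude <- function(sweep, baseline = NULL, window_ms = 35) {
  if (is.null(baseline)) baseline <- compute_baseline(sweep)
  t <- sweep_times_ms(sweep)
  if (sweep$led_onset_ms + window_ms > sweep_duration_ms(sweep)) {
    stop("response window extends past end of sweep", call. = FALSE)
  }
  idx <- which(t > sweep$led_onset_ms & t <= sweep$led_onset_ms + window_ms)
  d <- deflection_trace(sweep, baseline$baseline_mean)[idx]
  peak_i <- which.max(d) # which.max returns the first maximum: earliest tie wins
  list(
    amplitude = max(d[peak_i], 0),
    peak_time_ms = t[idx[peak_i]] - sweep$led_onset_ms,
    baseline_mean = baseline$baseline_mean,
    baseline_sd = baseline$baseline_sd
  )
}

# time (ms, sweep clock) of the last rising crossing of `level` at or
# before the peak, i.e. the crossing on the rise contiguous with the peak;
# sub-sample position by linear interpolation against the preceding sample.
# For a monotone rise this is the unique (first) crossing.
rising_crossing_time <- function(d_full, t_full, idx, level) {
  prev <- c(if (idx[1] > 1L) d_full[idx[1] - 1L] else -Inf,
            d_full[idx[-length(idx)]])
  rising <- which(d_full[idx] >= level & prev < level)
  if (length(rising) == 0L) return(NA_real_)
  j <- idx[rising[length(rising)]]
  if (j == 1L || d_full[j - 1] >= level) return(t_full[j])
  t0 <- t_full[j - 1]; t1 <- t_full[j]
  d0 <- d_full[j - 1]; d1 <- d_full[j]
  t0 + (level - d0) / (d1 - d0) * (t1 - t0)
}

#' Evoked-response latency by 20-80% extrapolation
#'
#' Finds the times where the baseline-subtracted response crosses 20% and
#' 80% of its peak on the rising phase contiguous with the peak (the last
#' upward crossing of each level at or before the peak — for a clean
#' monosynaptic event this is the unique crossing), then returns the time
#' at which the straight line through those two points crosses the
#' baseline. Sub-sample crossing times are obtained by linear
#' interpolation, which removes the sampling-rate dependence of the
#' estimate. Anchoring the crossings to the rise into the peak rather than
#' to the earliest level exceedance keeps baseline noise wiggles from
#' defining a spuriously short latency on weak or absent events.
#'
#' @param sweep A [new_sweep()] object.
#' @param event A [measure_amplitude()] result with `amplitude > 0`.
#' @return List with `latency_ms` (relative to LED onset; `NA` when the
#'   crossings cannot be found), `t20_ms`, `t80_ms`.
#' @export
estimate_latency <- function(sweep, event) {
  if (event$amplitude <= 0) {
    return(list(latency_ms = NA_real_, t20_ms = NA_real_, t80_ms = NA_real_))
  }
  t <- sweep_times_ms(sweep)
  d <- deflection_trace(sweep, event$baseline_mean)
  peak_abs <- sweep$led_onset_ms + event$peak_time_ms
  idx <- which(t > sweep$led_onset_ms & t <= peak_abs)
  t20 <- rising_crossing_time(d, t, idx, 0.2 * event$amplitude)
  t80 <- rising_crossing_time(d, t, idx, 0.8 * event$amplitude)
  if (is.na(t20) || is.na(t80) || t20 >= t80) {
    return(list(latency_ms = NA_real_, t20_ms = NA_real_, t80_ms = NA_real_))
  }
  # line through (t20, 0.2A), (t80, 0.8A) hits 0 at t20 - (t80 - t20)/3
  lat <- (t20 - (t80 - t20) / 3) - sweep$led_onset_ms
  list(latency_ms = lat,
       t20_ms = t20 - sweep$led_onset_ms,
       t80_ms = t80 - sweep$led_onset_ms)
}

#' Responsiveness classification
#'
#' A cell is responsive to the light stimulus when both criteria hold: the
#' response latency is strictly less than the cutoff (7 ms default; 4 ms is
#' the stricter alternative) and the response amplitude exceeds 3 times the
#' standard deviation of the baseline activity. An undefined latency is
#' non-responsive.
#'
#' @param event An event list carrying `latency_ms`, `amplitude`,
#'   `baseline_sd` (see [measure_event()]).
#' @param cutoff_ms Latency cutoff in ms, 7 or 4.
#' @param sd_factor Amplitude criterion multiplier (default 3).
#' @return Logical flag.
#' @export
classify_responsive <- function(event, cutoff_ms = 7, sd_factor = 3) {
  if (is.na(event$latency_ms)) return(FALSE)
  (event$latency_ms < cutoff_ms) && (event$amplitude > sd_factor * event$baseline_sd)
}

#' Response kinetics
#'
#' Rise time (20-80%), time to peak (peak time minus latency), and decay
#' time (time from the peak to the first fall to `1/e` of the peak,
#' interpolated between samples).
#'
#' @param sweep A [new_sweep()] object.
#' @param event A measured event with positive amplitude and defined latency
#'   (see [measure_event()]).
#' @return List with `rise_time_ms`, `time_to_peak_ms`, `decay_time_ms`
#'   (`NA` with `decay_truncated = TRUE` when the trace ends before the
#'   `1/e` crossing).
#' @export
measure_kinetics <- function(sweep, event) {
  if (event$amplitude <= 0 || is.na(event$latency_ms)) {
    stop("kinetics require a measured event with positive amplitude and defined latency",
         call. = FALSE)
  }
  t <- sweep_times_ms(sweep)
  d <- deflection_trace(sweep, event$baseline_mean)
  peak_abs <- sweep$led_onset_ms + event$peak_time_ms
  level <- event$amplitude / exp(1)
  after <- which(t > peak_abs)
  below <- after[d[after] <= level]
  if (length(below) == 0L) {
    decay <- NA_real_; truncated <- TRUE
  } else {
    j <- below[1]
    t0 <- t[j - 1]; t1 <- t[j]; d0 <- d[j - 1]; d1 <- d[j]
    tc <- if (d0 <= level) t0 else t0 + (level - d0) / (d1 - d0) * (t1 - t0)
    decay <- tc - peak_abs; truncated <- FALSE
  }
  list(
    rise_time_ms = event$t80_ms - event$t20_ms,
    time_to_peak_ms = event$peak_time_ms - event$latency_ms,
    decay_time_ms = decay,
    decay_truncated = truncated
  )
}

#' Full single-sweep event measurement
#'
#' Convenience wrapper chaining [compute_baseline()], [measure_amplitude()],
#' [estimate_latency()] and [classify_responsive()].
#'
#' @inheritParams classify_responsive
#' @param sweep A [new_sweep()] object.
#' @return An object of class `psc_event`: a list with `baseline_mean`,
#'   `baseline_sd`, `amplitude`, `peak_time_ms`, `latency_ms`, `t20_ms`,
#'   `t80_ms`, `responsive`, `latency_cutoff_used_ms`.
#' @export
measure_event <- function(sweep, cutoff_ms = 7) {
  amp <- measure_amplitude(sweep)
  lat <- estimate_latency(sweep, amp)
  ev <- c(amp, lat)
  ev$responsive <- classify_responsive(ev, cutoff_ms)
  ev$latency_cutoff_used_ms <- cutoff_ms
  class(ev) <- "psc_event"
  ev
}

#' EPSP amplitude for spiking cells
#'
#' When the cell fires in response to the light stimulus, the EPSP amplitude
#' is the difference between the baseline membrane potential and the spike
#' threshold potential rather than the (clipped) peak. The threshold is the
#' first sample before the action-potential peak where the depolarization
#' rate reaches `dvdt_threshold` (20 mV/ms by convention).
#'
#' @param sweep A current-clamp [new_sweep()] object.
#' @param dvdt_threshold Threshold-detection slope, mV/ms.
#' @param spike_peak_mv Minimum membrane potential for a deflection to count
#'   as an action-potential peak (default -10 mV).
#' @param window_ms Response window after LED onset (default 35).
#' @return List with `applicable` (FALSE when no spike lies in the window —
#'   use [measure_amplitude()] instead), `amplitude` (mV),
#'   `threshold_mv`, `baseline_mean`, `baseline_sd`.
#' @export
epsp_amplitude_spiking <- function(sweep, dvdt_threshold = 20,
                                   spike_peak_mv = -10, window_ms = 35) {
  if (sweep$mode != "current_clamp") {
    stop("spiking EPSP amplitude applies to current-clamp sweeps", call. = FALSE)
  }
  bl <- compute_baseline(sweep)
  t <- sweep_times_ms(sweep)
  v <- sweep$samples
  idx <- which(t > sweep$led_onset_ms & t <= sweep$led_onset_ms + window_ms)
  cand <- idx[v[idx] >= spike_peak_mv]
  if (length(cand) == 0L) {
    return(list(applicable = FALSE, amplitude = NA_real_, threshold_mv = NA_real_,
                baseline_mean = bl$baseline_mean, baseline_sd = bl$baseline_sd))
  }
  peak_i <- cand[which.max(v[cand])]
  dvdt <- c(0, diff(v)) * sweep$sampling_rate_hz / 1000 # mV/ms at each sample
  pre <- which(seq_along(v) <= peak_i & t > sweep$led_onset_ms & dvdt >= dvdt_threshold)
  if (length(pre) == 0L) {
    return(list(applicable = FALSE, amplitude = NA_real_, threshold_mv = NA_real_,
                baseline_mean = bl$baseline_mean, baseline_sd = bl$baseline_sd))
  }
  # threshold = membrane potential where dV/dt first reaches the criterion
  thr_i <- pre[1]
  threshold_mv <- v[thr_i - 1]
  list(applicable = TRUE,
       amplitude = threshold_mv - bl$baseline_mean,
       threshold_mv = threshold_mv,
       baseline_mean = bl$baseline_mean, baseline_sd = bl$baseline_sd)
}

#' Monosynaptic classification via TTX / 4-AP
#'
#' An evoked event is classified as monosynaptic when the control response
#' is responsive, the response is abolished by TTX, and it is recovered by
#' adding 4-AP. Recovery uses the same amplitude criterion as
#' responsiveness (amplitude above 3 times the condition's own baseline SD);
#' no latency requirement is imposed on the recovered event since 4-AP
#' recovered events are slower.
#'
#' @param control,ttx,ttx_4ap [measure_event()] results from the same cell
#'   under no drug, TTX, and TTX + 4-AP.
#' @param sd_factor Amplitude criterion multiplier (default 3).
#' @return `"monosynaptic"`, `"not_recovered"`, or `"not_applicable"`.
#' @export
classify_monosynaptic <- function(control, ttx, ttx_4ap, sd_factor = 3) {
  if (!isTRUE(control$responsive)) return("not_applicable")
  abolished <- ttx$amplitude <= sd_factor * ttx$baseline_sd
  recovered <- ttx_4ap$amplitude > sd_factor * ttx_4ap$baseline_sd
  if (abolished && recovered) "monosynaptic" else "not_recovered"
}

#' Per-cell events table
#'
#' Measures every cell's sweep in a synthetic (or schema-compatible) slice
#' dataset and returns the tidy events table consumed by the connectivity
#' stage.
#'
#' @param dataset A [gen_slice_dataset()] result (cells with rendered
#'   sweeps).
#' @param cutoff_ms Latency cutoff passed to [classify_responsive()].
#' @return Tibble with one row per cell: `cell_id`, `slice_id`, `area`,
#'   `layer`, `cell_class`, `measure`, `amplitude`, `latency_ms`,
#'   `baseline_sd`, `responsive`, `cutoff`.
#' @export
events_table <- function(dataset, cutoff_ms = 7) {
  cells <- dataset$cells
  evs <- purrr::map(cells$sweep, measure_event, cutoff_ms = cutoff_ms)
  tibble::tibble(
    cell_id = cells$cell_id,
    slice_id = cells$slice_id,
    area = cells$area,
    layer = cells$layer,
    cell_class = cells$cell_class,
    measure = ifelse(purrr::map_chr(cells$sweep, "mode") == "voltage_clamp",
                     "EPSC", "EPSP"),
    amplitude = purrr::map_dbl(evs, "amplitude"),
    latency_ms = purrr::map_dbl(evs, "latency_ms"),
    baseline_sd = purrr::map_dbl(evs, "baseline_sd"),
    responsive = purrr::map_lgl(evs, "responsive"),
    cutoff = cutoff_ms
  )
}
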