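#' Spike detection by thresholding
#'
#' Upward threshold crossings of a current-clamp voltage trace, one spike
#' per crossing with a refractory lockout so that noisy double-crossings
#' within the lockout count once.
#'
#' @param sweep A current-clamp [new_sweep()] object.
#' @param threshold_mv Detection threshold in mV (default 0).
#' @param lockout_ms Refractory lockout after each detected crossing
#'   (default 1 ms).
#' @return Numeric vector of spike times in ms from sweep start.
#' @export
detect_spikes <- function(sweep, threshold_mv = 0, lockout_ms = 1) {
  if (sweep$mode != "current_clamp") {
    stop("spike detection applies to current-clamp sweeps", call. = FALSE)
  }
  v <- sweep$samples
  t <- sweep_times_ms(sweep)
  up <- which(v[-1] >= threshold_mv & v[-length(v)] < threshold_mv) + 1L
  if (length(up) == 0L) return(numeric(0))
  keep <- numeric(0)
  last <- -Inf
  for (i in up) {
    if (t[i] - last >= lockout_ms) {
      keep <- c(keep, t[i])
      last <- t[i]
    }
  }
  keep
}

#' Peristimulus time histogram
#'
#' Trial-mean firing rate aligned to the LED onset: spikes are binned at
#' `bin_ms` resolution, converted to Hz, and smoothed with a boxcar kernel
#' of `kernel_ms` width. Edge bins use the partial kernel renormalized to
#' the number of contributing bins, so a flat rate stays flat at the edges.
#'
#' @param trials Trial tibble with list-column `spike_times` and
#'   `led_onset_ms` (see [gen_sharpening_trials()]).
#' @param condition Optional condition filter (`"led_on"`/`"led_off"`).
#' @param t_range Alignment window in ms relative to LED onset.
#' @param bin_ms Bin width (default 1 ms).
#' @param kernel_ms Boxcar kernel width (default 4 ms).
#' @return Tibble with `time_ms` (bin centers, relative to LED onset) and
#'   `rate_hz`.
#' @export
compute_psth <- function(trials, condition = NULL, t_range = c(-50, 100),
                         bin_ms = 1, kernel_ms = 4) {
  if (!is.null(condition)) trials <- trials[trials$condition == condition, ]
  if (nrow(trials) == 0L) stop("no trials to average", call. = FALSE)
  breaks <- seq(t_range[1], t_range[2], by = bin_ms)
  aligned <- unlist(purrr::map2(trials$spike_times, trials$led_onset_ms, `-`))
  nb <- length(breaks) - 1L
  inside <- aligned[aligned >= t_range[1] & aligned < t_range[2]]
  counts <- tabulate(findInterval(inside, breaks), nbins = nb)
  rate <- counts / nrow(trials) / (bin_ms / 1000)
  k <- max(1L, round(kernel_ms / bin_ms))
  kern <- rep(1, k)
  smoothed <- stats::filter(rate, kern / k, sides = 2)
  # renormalize edge bins where the kernel hangs over the ends
  weight <- stats::filter(rep(1, length(rate)), kern / k, sides = 2)
  smoothed <- as.numeric(smoothed / weight)
  na_idx <- which(is.na(smoothed))
  if (length(na_idx)) {
    # stats::filter leaves NAs at the extreme edges for even kernels; fill
    # by renormalized partial sums
    for (i in na_idx) {
      lo <- max(1L, i - k %/% 2); hi <- min(length(rate), i + (k - 1L) %/% 2)
      smoothed[i] <- mean(rate[lo:hi])
    }
  }
  tibble::tibble(time_ms = breaks[-length(breaks)] + bin_ms / 2,
                 rate_hz = smoothed)
}

#' Initial firing-rate comparison between LED-on and LED-off trials
#'
#' Per cell, the spike count inside the 10 ms window after the LED onset
#' (or the matching nominal time in LED-off trials) divided by trial count
#' and window length, then a two-sided Wilcoxon signed-rank test across
#' cells pairing the two conditions.
#'
#' @param trials Paired trial tibble (see [gen_sharpening_trials()]).
#' @param window_ms Rate window after LED onset (default 10).
#' @return List with `per_cell` (tibble `cell_id`, `rate_on_hz`,
#'   `rate_off_hz`) and `test` (comparison tibble).
#' @export
sharpening_rates <- function(trials, window_ms = 10) {
  if (!all(c("led_on", "led_off") %in% trials$condition)) {
    stop("need paired led_on and led_off trials", call. = FALSE)
  }
  per_cell <- trials |>
    dplyr::mutate(n_window = purrr::map2_dbl(
      .data$spike_times, .data$led_onset_ms,
      function(s, on) sum(s >= on & s < on + window_ms)
    )) |>
    dplyr::group_by(.data$cell_id, .data$condition) |>
    dplyr::summarise(rate_hz = sum(.data$n_window) / dplyr::n() / (window_ms / 1000),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "rate_hz") |>
    dplyr::rename(rate_on_hz = "led_on", rate_off_hz = "led_off")
  test <- paired_signed_rank(per_cell$rate_on_hz, per_cell$rate_off_hz,
                             "rate on vs off")
  list(per_cell = per_cell, test = test)
}

#' First-spike delay after the LED-on period
#'
#' Per trial, the time of the first spike at or after LED offset
#' (`onset + duration`, closed left boundary) minus the LED onset; per
#' cell, the mean over trials that contain such a spike. Trials without a
#' qualifying spike are excluded and counted. A two-sided Wilcoxon
#' signed-rank test compares the per-cell on/off delays.
#'
#' @param trials Paired trial tibble.
#' @return List with `per_cell` (tibble `cell_id`, `delay_on_ms`,
#'   `delay_off_ms`, `n_missing_on`, `n_missing_off`) and `test`.
#' @export
first_spike_delay <- function(trials) {
  delays <- trials |>
    dplyr::mutate(delay = purrr::pmap_dbl(
      list(.data$spike_times, .data$led_onset_ms, .data$led_duration_ms),
      function(s, on, dur) {
        q <- s[s >= on + dur]
        if (length(q) == 0) NA_real_ else q[1] - on
      }
    )) |>
    dplyr::group_by(.data$cell_id, .data$condition) |>
    dplyr::summarise(mean_delay = mean(.data$delay, na.rm = TRUE),
                     n_missing = sum(is.na(.data$delay)), .groups = "drop")
  per_cell <- delays |>
    tidyr::pivot_wider(names_from = "condition",
                       values_from = c("mean_delay", "n_missing")) |>
    dplyr::rename(delay_on_ms = "mean_delay_led_on",
                  delay_off_ms = "mean_delay_led_off",
                  n_missing_on = "n_missing_led_on",
                  n_missing_off = "n_missing_led_off")
  none <- !is.finite(per_cell$delay_on_ms) | !is.finite(per_cell$delay_off_ms)
  if (any(none)) {
    message(sum(none), " cell(s) had no qualifying spikes in a condition; excluded")
  }
  ok <- per_cell[!none, ]
  test <- paired_signed_rank(ok$delay_on_ms, ok$delay_off_ms,
                             "first-spike delay on vs off")
  list(per_cell = per_cell, test = test)
}

paired_signed_rank <- function(x, y, label) {
  if (length(x) == 0 || all(x == y)) {
    return(comparison_result("wilcoxon_signed_rank", label, 0, 1))
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))
  comparison_result("wilcoxon_signed_rank", label,
                    unname(wt$statistic), unname(wt$p.value))
}

#' Second- and third-spike probability curves
#'
#' Per cell and feedback delay \eqn{\Delta t}: the fraction of trials with
#' at least 2 (and at least 3) spikes inside the response window after the
#' feed-forward onset. Group means over cells carry seeded nonparametric
#' bootstrap 68% confidence intervals (resampling cells with replacement,
#' percentile 16-84), and each \eqn{\Delta t} is compared with the
#' feed-forward-only condition by a paired two-sided Wilcoxon signed-rank
#' test across cells.
#'
#' @param trials Bursting trial tibble (see [gen_bursting_trials()]).
#' @param window_ms Response window after feed-forward onset (default 50).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Bootstrap seed.
#' @return List with `per_cell` (tibble `cell_id`, `dt_ms`, `condition`,
#'   `p2`, `p3`, `n_trials`), `curve` (per `dt_ms`: `p2_mean`, `p3_mean`
#'   and 68% CIs), and `tests` (vs feed-forward-only).
#' @export
burst_spike_probabilities <- function(trials, window_ms = 50, n_boot = 1000,
                                      seed = 1L) {
  per_cell <- trials |>
    dplyr::mutate(n_spk = purrr::map2_dbl(
      .data$spike_times, .data$ff_onset_ms,
      function(s, on) sum(s >= on & s < on + window_ms)
    )) |>
    dplyr::group_by(.data$cell_id, .data$condition, .data$dt_ms) |>
    dplyr::summarise(p2 = mean(.data$n_spk >= 2), p3 = mean(.data$n_spk >= 3),
                     n_trials = dplyr::n(), .groups = "drop")
  ff_fb <- dplyr::filter(per_cell, .data$condition == "ff_fb")
  curve <- ff_fb |>
    dplyr::group_by(.data$dt_ms) |>
    dplyr::group_modify(function(df, key) {
      ci2 <- bootstrap_mean_ci(df$p2, n_boot, derive_seed(seed, round(key$dt_ms * 7 + 1000)))
      ci3 <- bootstrap_mean_ci(df$p3, n_boot, derive_seed(seed, round(key$dt_ms * 7 + 2000)))
      tibble::tibble(p2_mean = mean(df$p2), p2_lo = ci2[1], p2_hi = ci2[2],
                     p3_mean = mean(df$p3), p3_lo = ci3[1], p3_hi = ci3[2],
                     n_cells = nrow(df))
    }) |>
    dplyr::ungroup()
  ff_only <- per_cell |>
    dplyr::filter(.data$condition == "ff_only") |>
    dplyr::select("cell_id", ff_p2 = "p2", ff_p3 = "p3")
  tests <- ff_fb |>
    dplyr::inner_join(ff_only, by = "cell_id") |>
    dplyr::group_by(.data$dt_ms) |>
    dplyr::group_modify(function(df, key) {
      dplyr::bind_rows(
        paired_signed_rank(df$p2, df$ff_p2, sprintf("p2 dt=%g vs ff_only", key$dt_ms)),
        paired_signed_rank(df$p3, df$ff_p3, sprintf("p3 dt=%g vs ff_only", key$dt_ms))
      )
    }) |>
    dplyr::ungroup()
  list(per_cell = per_cell, curve = curve, tests = tests)
}

# percentile bootstrap CI of the mean, resampling units with replacement
bootstrap_mean_ci <- function(x, n_boot = 1000, seed = 1L,
                              probs = c(0.16, 0.84)) {
  if (length(x) == 0) return(c(NA_real_, NA_real_))
  with_local_seed(seed, {
    means <- vapply(seq_len(n_boot), function(i) {
      mean(x[sample.int(length(x), replace = TRUE)])
    }, numeric(1))
    unname(stats::quantile(means, probs))
  })
}

#' Second-spike timing statistics
#'
#' For each cell with at least one second spike across trials, the sample
#' mean and sample standard deviation (n - 1 denominator) of the
#' second-spike time relative to the feedback onset. A single qualifying
#' trial leaves the SD missing (flagged via `n_qualifying`). Cross-group
#' two-sided rank-sum tests compare both the means and the SDs.
#'
#' @param trials Bursting trial tibble with a `group` column (e.g. the
#'   pathway) or a single implicit group.
#' @param window_ms Response window after feed-forward onset.
#' @return List with `per_cell` (tibble `group`, `cell_id`,
#'   `mean_delay_ms`, `sd_delay_ms`, `n_qualifying`) and `tests`
#'   (rank-sum on means and on SDs; empty with one group).
#' @export
second_spike_timing <- function(trials, window_ms = 50) {
  if (!"group" %in% names(trials)) trials$group <- "all"
  per_trial <- trials |>
    dplyr::filter(.data$condition == "ff_fb") |>
    dplyr::mutate(second_delay = purrr::pmap_dbl(
      list(.data$spike_times, .data$ff_onset_ms, .data$fb_onset_ms),
      function(s, ff, fb) {
        resp <- s[s >= ff & s < ff + window_ms]
        if (length(resp) >= 2) resp[2] - fb else NA_real_
      }
    ))
  per_cell <- per_trial |>
    dplyr::group_by(.data$group, .data$cell_id) |>
    dplyr::summarise(
      n_qualifying = sum(!is.na(.data$second_delay)),
      mean_delay_ms = mean(.data$second_delay, na.rm = TRUE),
      sd_delay_ms = stats::sd(.data$second_delay[!is.na(.data$second_delay)]),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_qualifying >= 1)
  groups <- unique(per_cell$group)
  tests <- if (length(groups) == 2) {
    a <- per_cell[per_cell$group == groups[1], ]
    b <- per_cell[per_cell$group == groups[2], ]
    dplyr::bind_rows(
      rank_sum_result(a$mean_delay_ms, b$mean_delay_ms,
                      paste("mean delay:", groups[1], "vs", groups[2])),
      rank_sum_result(a$sd_delay_ms[!is.na(a$sd_delay_ms)],
                      b$sd_delay_ms[!is.na(b$sd_delay_ms)],
                      paste("sd delay:", groups[1], "vs", groups[2]))
    )
  } else {
    comparison_result("rank_sum", character(), numeric(), numeric())[0, ]
  }
  list(per_cell = per_cell, tests = tests)
}

rank_sum_result <- function(x, y, label) {
  if (length(x) == 0 || length(y) == 0) {
    return(comparison_result("rank_sum", label, NA_real_, NA_real_))
  }
  if (length(unique(c(x, y))) == 1L) {
    # fully tied samples carry no ordering information
    return(comparison_result("rank_sum", label, length(x) * length(y) / 2, 1))
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y))
  p <- unname(wt$p.value)
  comparison_result("rank_sum", label, unname(wt$statistic),
                    if (is.finite(p)) p else 1)
}

#' Cumulative distribution of second-spike delays
#'
#' Pooled empirical CDF of the second-spike time relative to the feedback
#' onset, per group.
#'
#' @inheritParams second_spike_timing
#' @return Tibble with `group`, `delay_ms` (sorted), `cum_prob`.
#' @export
cumulative_timing_distribution <- function(trials, window_ms = 50) {
  if (!"group" %in% names(trials)) trials$group <- "all"
  delays <- trials |>
    dplyr::filter(.data$condition == "ff_fb") |>
    dplyr::mutate(second_delay = purrr::pmap_dbl(
      list(.data$spike_times, .data$ff_onset_ms, .data$fb_onset_ms),
      function(s, ff, fb) {
        resp <- s[s >= ff & s < ff + window_ms]
        if (length(resp) >= 2) resp[2] - fb else NA_real_
      }
    )) |>
    dplyr::filter(!is.na(.data$second_delay))
  delays |>
    dplyr::group_by(.data$group) |>
    dplyr::arrange(.data$second_delay, .by_group = TRUE) |>
    dplyr::mutate(delay_ms = .data$second_delay,
                  cum_prob = dplyr::row_number() / dplyr::n()) |>
    dplyr::ungroup() |>
    dplyr::select("group", "delay_ms", "cum_prob")
}

#' Intrinsic burstiness and minimal bursting current
#'
#' A burst is a run of two or more spikes whose interspike intervals are
#' all at or below `burst_isi_ms`. Per step, the in-burst firing rate
#' (spikes in bursts over total burst duration) and out-of-burst rate
#' (remaining spikes over remaining step duration) give the score
#' \eqn{(f_{in} - f_{out}) / (f_{in} + f_{out})}; the burstiness of the
#' cell is the median score over the first (at most) 5 current steps, in
#' ascending current order, that elicited a burst. The minimal bursting
#' current is the lowest step current with at least one burst. No bursting
#' step gives burstiness 0 and a missing minimal current.
#'
#' @param step_responses [gen_step_protocol()] result (columns
#'   `current_pA`, `spike_times`).
#' @param step_duration_ms Step length in ms (default 700).
#' @param burst_isi_ms Interspike-interval threshold defining a burst
#'   (default 10).
#' @param pad_ms Optional padding added to each side of a burst's
#'   first-to-last spike span when computing its duration (default 0).
#' @param max_steps Number of bursting steps entering the median (default
#'   5).
#' @return List with `burstiness` (in `[-1, 1]`), `min_burst_current_pA`
#'   (`NA` when no step bursts) and `per_step` (tibble `current_pA`,
#'   `has_burst`, `score`).
#' @export
intrinsic_burstiness <- function(step_responses, step_duration_ms = 700,
                                 burst_isi_ms = 10, pad_ms = 0,
                                 max_steps = 5) {
  per_step <- purrr::map2_dfr(
    step_responses$current_pA, step_responses$spike_times,
    function(I, s) {
      b <- burst_score(s, step_duration_ms, burst_isi_ms, pad_ms)
      tibble::tibble(current_pA = I, has_burst = b$has_burst, score = b$score)
    }
  )
  bursting <- per_step[per_step$has_burst, ]
  bursting <- bursting[order(bursting$current_pA), ]
  if (nrow(bursting) == 0L) {
    return(list(burstiness = 0, min_burst_current_pA = NA_real_,
                per_step = per_step))
  }
  use <- utils::head(bursting, max_steps)
  list(burstiness = stats::median(use$score),
       min_burst_current_pA = min(bursting$current_pA),
       per_step = per_step)
}

burst_score <- function(spikes, step_duration_ms, burst_isi_ms, pad_ms) {
  if (length(spikes) < 2) return(list(has_burst = FALSE, score = NA_real_))
  isi <- diff(spikes)
  in_burst_interval <- isi <= burst_isi_ms
  if (!any(in_burst_interval)) return(list(has_burst = FALSE, score = NA_real_))
  # group consecutive burst intervals into runs
  runs <- rle(in_burst_interval)
  idx_end <- cumsum(runs$lengths)
  idx_start <- idx_end - runs$lengths + 1L
  burst_spikes <- 0L
  burst_dur_ms <- 0
  in_burst <- rep(FALSE, length(spikes))
  for (r in seq_along(runs$values)) {
    if (!runs$values[r]) next
    first <- idx_start[r]            # first interval index of the run
    last <- idx_end[r] + 1L          # last spike index of the run
    in_burst[first:last] <- TRUE
    burst_spikes <- burst_spikes + (last - first + 1L)
    burst_dur_ms <- burst_dur_ms + (spikes[last] - spikes[first]) + 2 * pad_ms
  }
  out_spikes <- sum(!in_burst)
  out_dur_ms <- max(step_duration_ms - burst_dur_ms, .Machine$double.eps)
  f_in <- burst_spikes / (burst_dur_ms / 1000)
  f_out <- out_spikes / (out_dur_ms / 1000)
  list(has_burst = TRUE, score = (f_in - f_out) / (f_in + f_out))
}
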