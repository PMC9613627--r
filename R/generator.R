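#' Synthetic-recording generator configuration
#'
#' Holds every constant the synthetic modules share: sampling, PSC kinetics
#' and noise, latency distribution, the per-(area, layer, class) amplitude
#' table emulating the connectivity structure of the recordings, spike
#' threshold, sharpening-trial parameters, bursting-trial parameters, and
#' the somatic step protocol. Protocol constants default to the study
#' conditions: 2 ms LED pulses, 300 ms sustained steps with a 20 ms LED
#' delivered at a random time 100-200 ms after step onset, feedback delays
#' \eqn{\Delta t \in \{-10,-6,-3,0,3,6,10\}} ms, and a 700 ms step protocol
#' from -200 pA to 600 pA in 20 pA increments.
#'
#' @param sampling_rate_hz Sampling rate (default 20 kHz).
#' @param noise_sd Baseline noise SD (pA in voltage clamp, mV in current
#'   clamp scaled by `epsp_noise_sd`).
#' @param noise_tau_ms Correlation time constant of the recording noise
#'   (default 1 ms). Whole-cell recordings are low-pass filtered, so the
#'   noise is modelled as a stationary AR(1) process with this time
#'   constant rather than white samples.
#' @param rise_tau_ms,decay_tau_ms PSC kernel time constants.
#' @param latency_mean_ms,latency_sd_ms Evoked-event latency distribution.
#' @param class_amplitude_table Tibble with columns `area`, `layer`,
#'   `cell_class`, `mean_amplitude`, `dispersion` (lognormal sdlog). Default
#'   [default_amplitude_table()].
#' @param spike_threshold_mv Somatic spike threshold for current-clamp
#'   sweeps (default -40 mV; resting membrane is adjusted to -70 mV).
#' @param epsp_noise_sd Current-clamp noise SD in mV.
#' @param sharpening Named list: `baseline_rate_hz`, `led_spike_prob`,
#'   `led_spike_delay_ms`, `led_spike_jitter_ms`, `suppression_ms`,
#'   `isi_shape` (gamma shape of the renewal interspike intervals; larger is
#'   more regular), `step_duration_ms`, `led_duration_ms`,
#'   `led_onset_range_ms`.
#' @param bursting Tibble with columns `dt_ms`, `p2`, `p3` giving the
#'   second-/third-spike probabilities per feedback delay, plus attributes
#'   set through `bursting_ff_only` and `second_spike_delay`. Default
#'   [default_bursting_params()] for the somatosensory pathway.
#' @param bursting_ff_only Named vector `c(p2 = , p3 = )` for
#'   feed-forward-only trials.
#' @param second_spike_delay Named vector `c(mean_ms = , sd_ms = )` of the
#'   second-spike time relative to feedback onset.
#' @param step_protocol Named list `duration_ms`, `start_pA`, `stop_pA`,
#'   `step_pA`.
#' @param led_onset_ms,led_duration_ms,sweep_duration_ms Evoked-sweep
#'   stimulus layout.
#' @param seed Integer seed; identical configuration and seed give
#'   byte-identical datasets.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(sampling_rate_hz = 20000,
                             noise_sd = 2,
                             noise_tau_ms = 1,
                             rise_tau_ms = 0.5,
                             decay_tau_ms = 5,
                             latency_mean_ms = 3,
                             latency_sd_ms = 0.5,
                             class_amplitude_table = default_amplitude_table(),
                             spike_threshold_mv = -40,
                             epsp_noise_sd = 0.3,
                             sharpening = list(
                               baseline_rate_hz = 20,
                               led_spike_prob = 0.9,
                               led_spike_delay_ms = 3,
                               led_spike_jitter_ms = 1,
                               suppression_ms = 40,
                               isi_shape = 10,
                               step_duration_ms = 300,
                               led_duration_ms = 20,
                               led_onset_range_ms = c(100, 200)
                             ),
                             bursting = default_bursting_params("vS1"),
                             bursting_ff_only = c(p2 = 0.15, p3 = 0.09),
                             second_spike_delay = c(mean_ms = 16, sd_ms = 8),
                             step_protocol = list(duration_ms = 700,
                                                  start_pA = -200,
                                                  stop_pA = 600,
                                                  step_pA = 20),
                             led_onset_ms = 50,
                             led_duration_ms = 2,
                             sweep_duration_ms = 150,
                             seed = 1L) {
  cfg <- structure(
    list(
      sampling_rate_hz = sampling_rate_hz,
      noise_sd = noise_sd,
      noise_tau_ms = noise_tau_ms,
      rise_tau_ms = rise_tau_ms,
      decay_tau_ms = decay_tau_ms,
      latency_mean_ms = latency_mean_ms,
      latency_sd_ms = latency_sd_ms,
      class_amplitude_table = class_amplitude_table,
      spike_threshold_mv = spike_threshold_mv,
      epsp_noise_sd = epsp_noise_sd,
      sharpening = sharpening,
      bursting = bursting,
      bursting_ff_only = bursting_ff_only,
      second_spike_delay = second_spike_delay,
      step_protocol = step_protocol,
      led_onset_ms = led_onset_ms,
      led_duration_ms = led_duration_ms,
      sweep_duration_ms = sweep_duration_ms,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  if (cfg$sampling_rate_hz <= 0) stop("sampling_rate_hz must be positive", call. = FALSE)
  if (cfg$rise_tau_ms <= 0 || cfg$decay_tau_ms <= cfg$rise_tau_ms) {
    stop("PSC taus must satisfy 0 < rise_tau_ms < decay_tau_ms", call. = FALSE)
  }
  probs <- c(cfg$sharpening$led_spike_prob, cfg$bursting$p2, cfg$bursting$p3,
             cfg$bursting_ff_only)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]", call. = FALSE)
  if (any(cfg$bursting$p3 > cfg$bursting$p2)) {
    stop("p3 > p2 at some dt: a third spike requires a second", call. = FALSE)
  }
  if (cfg$bursting_ff_only[["p3"]] > cfg$bursting_ff_only[["p2"]]) {
    stop("feed-forward-only p3 exceeds p2", call. = FALSE)
  }
  cfg
}

#' Default per-class amplitude table
#'
#' Mean evoked EPSC amplitudes (pA) and lognormal dispersions per (area,
#' layer, class), encoding the qualitative connectivity structure of the
#' recordings: L1 interneurons above the L2/3 pyramidal reference in both
#' areas, SOM+ above VIP+ in V1 but VIP+ above SOM+ in vS1, L2/3 above L5
#' in V1 with the opposite in vS1 (SOM+ excepted), and weak vS1 L4 input.
#'
#' @param dispersion Common lognormal sdlog for cell-to-cell variability.
#' @return Tibble with columns `area`, `layer`, `cell_class`,
#'   `mean_amplitude`, `dispersion`.
#' @export
default_amplitude_table <- function(dispersion = 0.4) {
  tab <- tibble::tribble(
    ~area, ~layer, ~cell_class, ~mean_amplitude,
    "V1",  "L1",   "L1_interneuron", 280,
    "V1",  "L2/3", "Pyr", 150,
    "V1",  "L2/3", "PV",  260,
    "V1",  "L2/3", "SOM", 230,
    "V1",  "L2/3", "VIP",  60,
    "V1",  "L4",   "Pyr",  70,
    "V1",  "L4",   "PV",  110,
    "V1",  "L4",   "SOM",  90,
    "V1",  "L5",   "Pyr",  90,
    "V1",  "L5",   "PV",  150,
    "V1",  "L5",   "SOM", 110,
    "vS1", "L1",   "L1_interneuron", 215,
    "vS1", "L2/3", "Pyr", 100,
    "vS1", "L2/3", "PV",  120,
    "vS1", "L2/3", "SOM",  45,
    "vS1", "L2/3", "VIP", 140,
    "vS1", "L4",   "Pyr",  10,
    "vS1", "L4",   "PV",   70,
    "vS1", "L4",   "SOM",   5,
    "vS1", "L5",   "Pyr", 170,
    "vS1", "L5",   "PV",  200,
    "vS1", "L5",   "SOM",  70
  )
  tab$dispersion <- dispersion
  tab
}

#' Default bursting probability profiles
#'
#' Second-/third-spike probabilities as a function of the feedback delay
#' \eqn{\Delta t}, per pathway. The visual pathway shows a reliable,
#' temporally precise single extra spike (peak p2 about 0.53-0.54 at
#' \eqn{\Delta t} 3-6 ms, p3 = 0 everywhere), the somatosensory pathway
#' shows burst facilitation (p2 about 0.6 and p3 about 0.26 for
#' \eqn{\Delta t} 0-6 ms).
#'
#' @param pathway `"V1"` (LM feedback) or `"vS1"` (vM1 feedback).
#' @return Tibble with `dt_ms`, `p2`, `p3`.
#' @export
default_bursting_params <- function(pathway = c("vS1", "V1")) {
  pathway <- match.arg(pathway)
  dt <- c(-10, -6, -3, 0, 3, 6, 10)
  if (pathway == "V1") {
    tibble::tibble(
      dt_ms = dt,
      p2 = c(0.20, 0.22, 0.30, 0.45, 0.53, 0.54, 0.35),
      p3 = 0
    )
  } else {
    tibble::tibble(
      dt_ms = dt,
      p2 = c(0.18, 0.25, 0.40, 0.60, 0.60, 0.55, 0.30),
      p3 = c(0.05, 0.08, 0.15, 0.26, 0.26, 0.22, 0.10)
    )
  }
}

# derive a per-unit 32-bit seed from the dataset seed: reproducible
# sub-streams per cell/trial without consuming the global stream
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 104729) %% 2147483647)
}

# stationary AR(1) recording noise: rho = exp(-dt/tau), unit marginal
# variance, scaled to `sd`. Mirrors the low-pass filtered noise of a
# whole-cell amplifier rather than sample-wise white noise.
recording_noise <- function(n, sd, tau_ms, sampling_rate_hz) {
  if (sd <= 0) return(numeric(n))
  rho <- exp(-(1000 / sampling_rate_hz) / tau_ms)
  e <- stats::rnorm(n, 0, sqrt(1 - rho^2))
  x <- stats::filter(e, rho, method = "recursive", init = stats::rnorm(1))
  sd * as.numeric(x)
}

#' Generate one evoked-PSC voltage-clamp sweep
#'
#' Baseline noise plus a difference-of-exponentials event starting at LED
#' onset + latency, rendered as a downward (negative) deflection at -85 mV
#' holding; the noiseless peak magnitude equals `amplitude`.
#'
#' @param cfg A [generator_config()].
#' @param amplitude Event peak magnitude in pA (`>= 0`; 0 means no event).
#' @param latency Event onset latency after LED onset, ms.
#' @param seed Integer seed for the sweep's noise.
#' @return A [new_sweep()] object.
#' @export
gen_psc_sweep <- function(cfg, amplitude, latency, seed = cfg$seed) {
  stopifnot(amplitude >= 0, latency >= 0)
  n <- round(cfg$sweep_duration_ms / 1000 * cfg$sampling_rate_hz)
  t <- (seq_len(n) - 1) / cfg$sampling_rate_hz * 1000
  x <- -amplitude * psc_kernel(t - cfg$led_onset_ms - latency,
                               cfg$rise_tau_ms, cfg$decay_tau_ms)
  if (cfg$noise_sd > 0) {
    x <- x + with_local_seed(seed, recording_noise(n, cfg$noise_sd,
                                                   cfg$noise_tau_ms,
                                                   cfg$sampling_rate_hz))
  }
  new_sweep(x, cfg$sampling_rate_hz, "voltage_clamp",
            led_onset_ms = cfg$led_onset_ms,
            led_duration_ms = cfg$led_duration_ms, holding = -85)
}

#' Generate one evoked-EPSP current-clamp sweep
#'
#' Resting membrane at -70 mV with an upward difference-of-exponentials
#' depolarization; if the noiseless depolarization would cross the
#' configured spike threshold, a stereotyped action potential (fast rise to
#' +30 mV, fast repolarization) is superimposed at the threshold crossing.
#'
#' @inheritParams gen_psc_sweep
#' @param amplitude Depolarization peak in mV above rest.
#' @return A [new_sweep()] object (`current_clamp`).
#' @export
gen_epsp_sweep <- function(cfg, amplitude, latency, seed = cfg$seed) {
  stopifnot(amplitude >= 0, latency >= 0)
  rest <- -70
  n <- round(cfg$sweep_duration_ms / 1000 * cfg$sampling_rate_hz)
  t <- (seq_len(n) - 1) / cfg$sampling_rate_hz * 1000
  depol <- amplitude * psc_kernel(t - cfg$led_onset_ms - latency,
                                  cfg$rise_tau_ms, cfg$decay_tau_ms)
  v <- rest + depol
  if (rest + amplitude >= cfg$spike_threshold_mv && amplitude > 0) {
    cross <- which(v >= cfg$spike_threshold_mv)
    if (length(cross) > 0) {
      # stereotyped AP: 0.5 ms rise to +30 mV, 1 ms fall to -75, recover
      i0 <- cross[1]
      ap_t <- t - t[i0]
      up <- ap_t >= 0 & ap_t < 0.5
      down <- ap_t >= 0.5 & ap_t < 1.5
      after <- ap_t >= 1.5
      v[up] <- cfg$spike_threshold_mv +
        (30 - cfg$spike_threshold_mv) * ap_t[up] / 0.5
      v[down] <- 30 - (30 - (-75)) * (ap_t[down] - 0.5) / 1
      v[after] <- -75 + (rest - (-75)) * (1 - exp(-(ap_t[after] - 1.5) / 10))
    }
  }
  if (cfg$epsp_noise_sd > 0) {
    v <- v + with_local_seed(seed, recording_noise(n, cfg$epsp_noise_sd,
                                                   cfg$noise_tau_ms,
                                                   cfg$sampling_rate_hz))
  }
  new_sweep(v, cfg$sampling_rate_hz, "current_clamp",
            led_onset_ms = cfg$led_onset_ms,
            led_duration_ms = cfg$led_duration_ms, holding = rest)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# run `expr` under a local seeded RNG stream, restoring the caller's stream
with_local_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  expr
}

#' Generate a slice-grouped connectivity dataset
#'
#' Draws cells from the per-class amplitude table, assigns them to slices
#' (each slice holds at least one L2/3 pyramidal reference cell of its
#' area), applies a per-slice multiplicative gain emulating virus-titer
#' variability, and renders one evoked sweep per cell. True amplitudes and
#' latencies are stored as ground truth.
#'
#' @param cfg A [generator_config()].
#' @param design Tibble with columns `area`, `layer`, `cell_class`,
#'   `n_cells`; defaults to `n_per_group` cells of every row of
#'   `cfg$class_amplitude_table`.
#' @param n_per_group Cells per (area, layer, class) group when `design` is
#'   not given.
#' @param cells_per_slice Target number of cells on one slice.
#' @param slice_gain_sd Lognormal sdlog of the per-slice gain.
#' @param mode `"voltage_clamp"` renders EPSC sweeps, `"current_clamp"`
#'   renders EPSP sweeps (amplitudes are then interpreted in mV via
#'   `epsp_scale`).
#' @param epsp_scale mV of depolarization per 10 pA of synaptic current
#'   when rendering current-clamp sweeps.
#' @param render_sweeps Set `FALSE` to skip waveform rendering (cells table
#'   and ground truth only).
#' @return An object of class `slice_dataset`: list with `cells` (tibble,
#'   one row per cell, list-column `sweep`), `ground_truth` (tibble),
#'   `slice_gains` (tibble), `config`, `seed`.
#' @export
gen_slice_dataset <- function(cfg, design = NULL, n_per_group = 12,
                              cells_per_slice = 4, slice_gain_sd = 0.3,
                              mode = c("voltage_clamp", "current_clamp"),
                              epsp_scale = 0.1, render_sweeps = TRUE) {
  mode <- match.arg(mode)
  tab <- cfg$class_amplitude_table
  if (is.null(design)) {
    design <- dplyr::mutate(tab[, c("area", "layer", "cell_class")],
                            n_cells = n_per_group)
  }
  missing <- dplyr::anti_join(design, tab, by = c("area", "layer", "cell_class"))
  if (nrow(missing) > 0) {
    stop("class_amplitude_table does not cover every requested group",
         call. = FALSE)
  }
  design <- design[design$n_cells > 0, , drop = FALSE]
  if (nrow(design) == 0L) {
    empty <- tibble::tibble(cell_id = character(), slice_id = character(),
                            area = character(), layer = character(),
                            cell_class = character(), mode = character(),
                            true_amplitude = double(), true_latency = double(),
                            sweep = list())
    return(structure(list(cells = empty, ground_truth = empty[, 1:8],
                          slice_gains = tibble::tibble(slice_id = character(),
                                                       gain = double()),
                          config = cfg, seed = cfg$seed),
                     class = "slice_dataset"))
  }
  with_local_seed(cfg$seed, {
    cells <- design |>
      dplyr::left_join(tab, by = c("area", "layer", "cell_class")) |>
      tidyr::uncount(.data$n_cells)
    # slices are per-area; reference cells (L2/3 Pyr) are dealt round-robin
    # first so every slice owns at least one
    cells <- cells |>
      dplyr::group_by(area) |>
      dplyr::group_modify(function(df, key) {
        is_ref <- df$layer == "L2/3" & df$cell_class == "Pyr"
        n_ref <- sum(is_ref)
        if (n_ref == 0L) {
          stop("every area needs at least one L2/3 pyramidal reference cell",
               call. = FALSE)
        }
        n_slices <- max(1L, min(n_ref, ceiling(nrow(df) / cells_per_slice)))
        slice_of <- integer(nrow(df))
        slice_of[is_ref] <- rep_len(seq_len(n_slices), n_ref)
        slice_of[!is_ref] <- rep_len(seq_len(n_slices), sum(!is_ref))
        df$slice_id <- sprintf("%s_slice%02d", key$area, slice_of)
        df
      }) |>
      dplyr::ungroup()
    gains <- cells |>
      dplyr::distinct(slice_id) |>
      dplyr::mutate(gain = stats::rlnorm(dplyr::n(), 0, slice_gain_sd))
    cells <- cells |>
      dplyr::left_join(gains, by = "slice_id") |>
      dplyr::mutate(
        cell_id = sprintf("%s_c%03d", slice_id, dplyr::row_number()),
        true_amplitude = mean_amplitude * gain *
          stats::rlnorm(dplyr::n(), -dispersion^2 / 2, dispersion),
        true_latency = pmax(0.5, stats::rnorm(dplyr::n(), cfg$latency_mean_ms,
                                              cfg$latency_sd_ms)),
        mode = mode
      )
    if (mode == "current_clamp") {
      cells$true_amplitude <- cells$true_amplitude * epsp_scale
    }
    if (render_sweeps) {
      gen_one <- if (mode == "voltage_clamp") gen_psc_sweep else gen_epsp_sweep
      cells$sweep <- purrr::pmap(
        list(cells$true_amplitude, cells$true_latency, seq_len(nrow(cells))),
        function(a, l, i) gen_one(cfg, a, l, seed = derive_seed(cfg$seed, i))
      )
    } else {
      cells$sweep <- vector("list", nrow(cells))
    }
    cells <- cells[, c("cell_id", "slice_id", "area", "layer", "cell_class",
                       "mode", "true_amplitude", "true_latency", "sweep")]
    structure(
      list(cells = cells,
           ground_truth = cells[, c("cell_id", "slice_id", "area", "layer",
                                    "cell_class", "mode", "true_amplitude",
                                    "true_latency")],
           slice_gains = gains,
           config = cfg,
           seed = cfg$seed),
      class = "slice_dataset"
    )
  })
}

# one equilibrium renewal spike train over [0, duration_ms) at `rate_hz`
# with gamma-distributed interspike intervals (shape `shape`; mean
# 1000/rate ms). The first spike is drawn from the equilibrium
# forward-recurrence distribution (a uniform fraction of a length-biased
# interval, gamma with shape + 1), so the spike count in any window is
# exactly rate * window in expectation.
renewal_train <- function(rate_hz, duration_ms, shape) {
  if (rate_hz <= 0) return(numeric(0))
  mean_isi <- 1000 / rate_hz
  n_max <- ceiling(duration_ms / mean_isi * 3) + 10
  isis <- stats::rgamma(n_max, shape = shape, scale = mean_isi / shape)
  first <- stats::rgamma(1, shape = shape + 1, scale = mean_isi / shape) *
    stats::runif(1)
  t <- cumsum(c(first, isis))
  t[t < duration_ms]
}

#' Generate a current-clamp cohort of one cell class
#'
#' Renders `n_cells` evoked-EPSP sweeps for a single (area, layer, class)
#' group, with depolarization amplitudes drawn uniformly from
#' `amp_range_mv`. With the default range the cohort is strictly
#' subthreshold (every depolarization stays below the configured spike
#' threshold), which is the construction used to check that the
#' spiking-classification stage never flags cells that cannot fire.
#'
#' @param cfg A [generator_config()].
#' @param n_cells Number of cells.
#' @param area,layer,cell_class Group labels.
#' @param amp_range_mv Uniform amplitude range in mV of depolarization.
#' @param cells_per_slice Cells per synthetic slice id.
#' @return Tibble with `cell_id`, `slice_id`, `area`, `layer`,
#'   `cell_class`, `mode`, `true_amplitude`, `true_latency`, `sweep`.
#' @export
gen_epsp_cohort <- function(cfg, n_cells = 48, area = "vS1", layer = "L2/3",
                            cell_class = "SOM", amp_range_mv = c(2, 25),
                            cells_per_slice = 4) {
  with_local_seed(cfg$seed, {
    amps <- stats::runif(n_cells, amp_range_mv[1], amp_range_mv[2])
    lats <- pmax(0.5, stats::rnorm(n_cells, cfg$latency_mean_ms, cfg$latency_sd_ms))
    slice <- sprintf("%s_slice%02d", area,
                     rep(seq_len(ceiling(n_cells / cells_per_slice)),
                         each = cells_per_slice)[seq_len(n_cells)])
    sweeps <- purrr::pmap(list(amps, lats, seq_len(n_cells)), function(a, l, i) {
      gen_epsp_sweep(cfg, a, l, seed = derive_seed(cfg$seed, 20000L + i))
    })
    tibble::tibble(
      cell_id = sprintf("%s_c%03d", slice, seq_len(n_cells)),
      slice_id = slice, area = area, layer = layer, cell_class = cell_class,
      mode = "current_clamp", true_amplitude = amps, true_latency = lats,
      sweep = sweeps
    )
  })
}

#' Generate paired LED-on / LED-off sharpening trials
#'
#' Emulates sustained-step experiments: on every trial the cell fires a
#' renewal train at the configured baseline rate for the 300 ms step. In
#' LED-on trials a 20 ms LED arrives at a random time 100-200 ms after step
#' onset; with probability `led_spike_prob` it forces one spike within
#' 10 ms of LED onset, and baseline spikes are suppressed from LED onset
#' until `suppression_ms` after LED offset. Each LED-on trial is paired
#' with an LED-off trial carrying the same nominal LED time.
#'
#' @param cfg A [generator_config()].
#' @param n_cells Number of cells.
#' @param n_trials Trials per cell, even (half on, half off, paired).
#' @return Tibble of trials with columns `cell_id`, `trial`, `condition`
#'   (`led_on`/`led_off`), `led_onset_ms`, `led_duration_ms`,
#'   `spike_times` (list-column), plus a `ground_truth` attribute with each
#'   trial's forced-spike indicator and time.
#' @export
gen_sharpening_trials <- function(cfg, n_cells = 20, n_trials = 10) {
  if (n_trials %% 2 != 0) stop("n_trials must be even (paired on/off)", call. = FALSE)
  sp <- cfg$sharpening
  with_local_seed(cfg$seed, {
    rows <- list()
    truth <- list()
    k <- 0L
    for (ci in seq_len(n_cells)) {
      set.seed(derive_seed(cfg$seed, ci))
      for (pair in seq_len(n_trials / 2)) {
        onset <- stats::runif(1, sp$led_onset_range_ms[1], sp$led_onset_range_ms[2])
        base_off <- renewal_train(sp$baseline_rate_hz, sp$step_duration_ms, sp$isi_shape)
        base_on <- renewal_train(sp$baseline_rate_hz, sp$step_duration_ms, sp$isi_shape)
        # suppression_ms = 0 disables the mechanism entirely (null
        # configuration); otherwise baseline spikes are removed from LED
        # onset until suppression_ms after LED offset
        if (sp$suppression_ms > 0 || sp$led_spike_prob > 0) {
          sup_end <- onset + sp$led_duration_ms + sp$suppression_ms
          on_spikes <- base_on[base_on < onset | base_on >= sup_end]
        } else {
          on_spikes <- base_on
        }
        forced <- stats::runif(1) < sp$led_spike_prob
        forced_t <- NA_real_
        if (forced) {
          forced_t <- onset + min(9.9, max(0, sp$led_spike_delay_ms +
                                              stats::rnorm(1, 0, sp$led_spike_jitter_ms)))
          on_spikes <- sort(c(on_spikes, forced_t))
        }
        for (cond in c("led_on", "led_off")) {
          k <- k + 1L
          rows[[k]] <- tibble::tibble(
            cell_id = sprintf("cell%03d", ci),
            trial = pair,
            condition = cond,
            led_onset_ms = onset,
            led_duration_ms = sp$led_duration_ms,
            spike_times = list(if (cond == "led_on") on_spikes else sort(base_off))
          )
        }
        truth[[length(truth) + 1L]] <- tibble::tibble(
          cell_id = sprintf("cell%03d", ci), trial = pair,
          forced_spike = forced, forced_time_ms = forced_t
        )
      }
    }
    out <- dplyr::bind_rows(rows)
    attr(out, "ground_truth") <- dplyr::bind_rows(truth)
    out
  })
}

#' Generate feed-forward / feedback bursting trials
#'
#' Every trial carries a feed-forward spike at the somatic pulse time. On
#' combined trials the feedback pulse arrives at \eqn{\Delta t} relative to
#' feed-forward onset; a second spike occurs with probability
#' \eqn{p_2(\Delta t)} at feedback onset plus a delay drawn from the
#' configured second-spike-delay distribution, and a third spike with
#' conditional probability \eqn{p_3/p_2} given the second.
#' Feed-forward-only control trials use `cfg$bursting_ff_only`.
#'
#' @param cfg A [generator_config()].
#' @param n_cells Number of cells.
#' @param trials_per_dt Trials per \eqn{\Delta t} (and for the
#'   feed-forward-only condition); the recordings used 6-10.
#' @param ff_onset_ms Feed-forward pulse time within the sweep.
#' @return Tibble of trials: `cell_id`, `condition` (`ff_fb`/`ff_only`),
#'   `dt_ms` (`NA` for `ff_only`), `trial`, `ff_onset_ms`, `fb_onset_ms`,
#'   `spike_times` (list-column); `ground_truth` attribute has per-trial
#'   true second/third-spike indicators and times.
#' @export
gen_bursting_trials <- function(cfg, n_cells = 15, trials_per_dt = 8,
                                ff_onset_ms = 100) {
  validate_generator_config(cfg)
  burst <- cfg$bursting
  dd <- cfg$second_spike_delay
  conds <- dplyr::bind_rows(
    tibble::tibble(condition = "ff_fb", dt_ms = burst$dt_ms,
                   p2 = burst$p2, p3 = burst$p3),
    tibble::tibble(condition = "ff_only", dt_ms = NA_real_,
                   p2 = cfg$bursting_ff_only[["p2"]],
                   p3 = cfg$bursting_ff_only[["p3"]])
  )
  with_local_seed(cfg$seed, {
    rows <- list(); truth <- list(); k <- 0L
    for (ci in seq_len(n_cells)) {
      set.seed(derive_seed(cfg$seed, 10000L + ci))
      for (r in seq_len(nrow(conds))) {
        cc <- conds[r, ]
        fb_onset <- if (cc$condition == "ff_fb") ff_onset_ms + cc$dt_ms else NA_real_
        anchor <- if (is.na(fb_onset)) ff_onset_ms else fb_onset
        for (tr in seq_len(trials_per_dt)) {
          spikes <- ff_onset_ms
          second <- stats::runif(1) < cc$p2
          second_t <- NA_real_; third <- FALSE; third_t <- NA_real_
          if (second) {
            second_t <- max(anchor + stats::rnorm(1, dd[["mean_ms"]], dd[["sd_ms"]]),
                            ff_onset_ms + 2)
            spikes <- c(spikes, second_t)
            third <- stats::runif(1) < (cc$p3 / max(cc$p2, .Machine$double.eps))
            if (third) {
              third_t <- second_t + stats::rgamma(1, shape = 4, scale = 1)
              spikes <- c(spikes, third_t)
            }
          }
          k <- k + 1L
          rows[[k]] <- tibble::tibble(
            cell_id = sprintf("cell%03d", ci),
            condition = cc$condition, dt_ms = cc$dt_ms, trial = tr,
            ff_onset_ms = ff_onset_ms, fb_onset_ms = fb_onset,
            spike_times = list(sort(spikes))
          )
          truth[[k]] <- tibble::tibble(
            cell_id = sprintf("cell%03d", ci),
            condition = cc$condition, dt_ms = cc$dt_ms, trial = tr,
            second_spike = second, second_time_ms = second_t,
            third_spike = third, third_time_ms = third_t
          )
        }
      }
    }
    out <- dplyr::bind_rows(rows)
    attr(out, "ground_truth") <- dplyr::bind_rows(truth)
    out
  })
}

#' Generate somatic step-protocol responses
#'
#' Emulates the 700 ms step protocol (-200 pA to 600 pA in 20 pA steps).
#' Non-bursty cells fire evenly spaced spikes above rheobase, at a rate
#' growing with current. Bursty cells additionally emit an initial spike
#' cluster (interspike intervals below the burst threshold) followed by
#' sparse spikes, for every step at or above `burst_current_pA`.
#'
#' @param cfg A [generator_config()].
#' @param bursty Logical: intrinsically bursty cell?
#' @param rheobase_pA Minimal current that elicits any spikes.
#' @param burst_current_pA Minimal current that elicits a burst (bursty
#'   cells only).
#' @param burst_isi_ms Interspike interval inside the generated cluster.
#' @param seed Integer seed (timing jitter).
#' @return Tibble with `current_pA` and `spike_times` (list-column, ms from
#'   step onset), class `step_responses`.
#' @export
gen_step_protocol <- function(cfg, bursty = TRUE, rheobase_pA = 100,
                              burst_current_pA = 200, burst_isi_ms = 4,
                              seed = cfg$seed) {
  sp <- cfg$step_protocol
  currents <- seq(sp$start_pA, sp$stop_pA, by = sp$step_pA)
  with_local_seed(seed, {
    resp <- purrr::map(currents, function(I) {
      if (I < rheobase_pA) return(numeric(0))
      rate <- 2 + (I - rheobase_pA) / 40 # Hz, grows with current
      n_reg <- max(1, round(rate * sp$duration_ms / 1000))
      regular <- seq(15, sp$duration_ms - 10, length.out = n_reg) +
        stats::rnorm(n_reg, 0, 0.5)
      if (bursty && I >= burst_current_pA) {
        cluster <- 10 + burst_isi_ms * (0:2) + stats::rnorm(3, 0, 0.1)
        sparse <- regular[regular > max(cluster) + 30]
        sort(c(cluster, sparse))
      } else {
        sort(regular)
      }
    })
    structure(tibble::tibble(current_pA = currents, spike_times = resp),
              class = c("step_responses", class(tibble::tibble())))
  })
}
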