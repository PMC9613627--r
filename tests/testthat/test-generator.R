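test_that("the PSC kernel peaks at 1 at its analytic peak time", {
  for (taus in list(c(0.5, 5), c(1, 8), c(0.3, 3))) {
    tp <- psc_kernel_peak_time(taus[1], taus[2])
    t <- seq(0, 40, by = 1e-3)
    k <- psc_kernel(t, taus[1], taus[2])
    expect_equal(max(k), 1, tolerance = 1e-6)
    expect_equal(t[which.max(k)], tp, tolerance = 1e-2)
  }
})

test_that("identical config and seed give byte-identical sweeps and datasets", {
  cfg <- test_config(seed = 42)
  s1 <- gen_psc_sweep(cfg, 100, 3, seed = 7)
  s2 <- gen_psc_sweep(cfg, 100, 3, seed = 7)
  expect_identical(s1$samples, s2$samples)

  d1 <- gen_slice_dataset(cfg, n_per_group = 2)
  d2 <- gen_slice_dataset(cfg, n_per_group = 2)
  expect_identical(d1$cells$true_amplitude, d2$cells$true_amplitude)
  expect_identical(d1$cells$sweep[[5]]$samples, d2$cells$sweep[[5]]$samples)

  t1 <- gen_sharpening_trials(cfg, 3, 4)
  t2 <- gen_sharpening_trials(cfg, 3, 4)
  expect_identical(t1$spike_times, t2$spike_times)

  b1 <- gen_bursting_trials(cfg, 3, 4)
  b2 <- gen_bursting_trials(cfg, 3, 4)
  expect_identical(b1$spike_times, b2$spike_times)
})

test_that("generator calls do not disturb the caller's RNG stream", {
  cfg <- test_config(seed = 5)
  set.seed(123)
  a <- stats::runif(1)
  set.seed(123)
  invisible(gen_slice_dataset(cfg, n_per_group = 2, render_sweeps = FALSE))
  b <- stats::runif(1)
  expect_identical(a, b)
})

test_that("noiseless synthetic events recover configured amplitude and latency", {
  cfg <- test_config(noise_sd = 0)
  ev <- measure_event(gen_psc_sweep(cfg, 100, 3))
  expect_equal(ev$amplitude, 100, tolerance = 0.01) # within 1 pA
  expect_equal(ev$latency_ms, 3, tolerance = 0.1)   # within 0.3 ms

  # zero amplitude with noise: no event is detected as responsive
  cfgn <- test_config(noise_sd = 2, seed = 3)
  ev0 <- measure_event(gen_psc_sweep(cfgn, 0, 0, seed = 9))
  expect_false(ev0$responsive)
})

test_that("slice gains cancel after normalization when class means are equal", {
  tab <- default_amplitude_table(dispersion = 0)
  tab$mean_amplitude <- 100
  cfg <- test_config(noise_sd = 0, latency_sd_ms = 0,
                     class_amplitude_table = tab, seed = 8)
  ds <- gen_slice_dataset(cfg, n_per_group = 3, slice_gain_sd = 0.5,
                          render_sweeps = FALSE)
  ev <- ds$ground_truth
  ev$amplitude <- ev$true_amplitude
  norm <- normalize_to_reference(ev)
  expect_true(all(abs(norm$log2_ratio) < 1e-10))
})

test_that("configured class orderings show up in ground-truth medians", {
  cfg <- test_config(seed = 13)
  ds <- gen_slice_dataset(cfg, n_per_group = 12, render_sweeps = FALSE)
  ev <- ds$ground_truth
  ev$amplitude <- ev$true_amplitude
  norm <- normalize_to_reference(ev)
  med <- function(a, cl) {
    stats::median(norm$log2_ratio[norm$area == a & norm$cell_class == cl])
  }
  expect_gt(med("V1", "SOM"), med("V1", "VIP"))
  expect_gt(med("vS1", "VIP"), med("vS1", "SOM"))
})

test_that("a zero-cell request yields an empty dataset without error", {
  cfg <- test_config()
  design <- default_amplitude_table()[0, c("area", "layer", "cell_class")]
  design$n_cells <- integer(0)
  ds <- gen_slice_dataset(cfg, design = design)
  expect_equal(nrow(ds$cells), 0)
})

test_that("a design outside the amplitude table is rejected", {
  cfg <- test_config()
  design <- tibble::tibble(area = "V1", layer = "L6", cell_class = "Pyr",
                           n_cells = 2)
  expect_error(gen_slice_dataset(cfg, design = design), "cover")
})

test_that("generated amplitudes match the configured mean within 3 standard errors", {
  tab <- tibble::tibble(area = c("V1", "V1"), layer = c("L2/3", "L2/3"),
                        cell_class = c("Pyr", "SOM"),
                        mean_amplitude = c(150, 230), dispersion = 0.4)
  cfg <- test_config(class_amplitude_table = tab, seed = 17)
  design <- dplyr::mutate(tab[, 1:3], n_cells = 600)
  ds <- gen_slice_dataset(cfg, design = design, slice_gain_sd = 0,
                          render_sweeps = FALSE)
  for (cl in c("Pyr", "SOM")) {
    x <- ds$ground_truth$true_amplitude[ds$ground_truth$cell_class == cl]
    mu <- tab$mean_amplitude[tab$cell_class == cl]
    se <- stats::sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - mu), 3 * se + 0.02 * mu)
  }
})

test_that("sharpening trials honor their null and forced-spike configurations", {
  # forced spike with probability 1 and zero jitter lands exactly at
  # onset + fixed delay
  cfg <- test_config(seed = 19)
  cfg$sharpening$led_spike_prob <- 1
  cfg$sharpening$led_spike_jitter_ms <- 0
  tr <- gen_sharpening_trials(cfg, 4, 6)
  on <- tr[tr$condition == "led_on", ]
  hit <- purrr::map2_lgl(on$spike_times, on$led_onset_ms, function(s, o) {
    any(abs(s - (o + cfg$sharpening$led_spike_delay_ms)) < 1e-9)
  })
  expect_true(all(hit))

  # null configuration: on and off rates in the LED window are compatible
  cfg0 <- test_config(seed = 23)
  cfg0$sharpening$led_spike_prob <- 0
  cfg0$sharpening$suppression_ms <- 0
  tr0 <- gen_sharpening_trials(cfg0, 20, 10)
  r0 <- sharpening_rates(tr0)
  expect_gt(r0$test$p_raw, 0.01)
})

test_that("bursting trials enforce p3 <= p2 and reproduce trivial settings", {
  cfg <- test_config()
  bad <- cfg
  bad$bursting$p3 <- bad$bursting$p2 + 0.1
  expect_error(gen_bursting_trials(bad, 2, 2), "p3")

  # p2 = 1, zero delay spread: second spike exactly at FB onset + mean delay
  cfg2 <- test_config(seed = 29)
  cfg2$bursting$p2 <- rep(1, 7)
  cfg2$bursting$p3 <- rep(0, 7)
  cfg2$second_spike_delay <- c(mean_ms = 4, sd_ms = 0)
  tr <- gen_bursting_trials(cfg2, 3, 4)
  fb <- tr[tr$condition == "ff_fb", ]
  ok <- purrr::map2_lgl(fb$spike_times, fb$fb_onset_ms, function(s, fbt) {
    length(s) >= 2 && abs(s[2] - max(fbt + 4, s[1] + 2)) < 1e-9
  })
  expect_true(all(ok))
  st <- second_spike_timing(tr[!is.na(tr$dt_ms) & tr$dt_ms %in% c(3, 6, 10), ])
  expect_true(all(st$per_cell$sd_delay_ms < 1e-9, na.rm = TRUE))

  # p3 = 0 everywhere: the measured third-spike probability is 0
  bp <- burst_spike_probabilities(tr, seed = 1)
  expect_true(all(bp$curve$p3_mean == 0))
})

test_that("binomial sampling recovers a configured second-spike probability", {
  cfg <- test_config(seed = 37)
  cfg$bursting$p2 <- rep(0.6, 7)
  cfg$bursting$p3 <- rep(0, 7)
  tr <- gen_bursting_trials(cfg, 25, 10)
  bp <- burst_spike_probabilities(tr, seed = 2)
  p2_at_3 <- bp$curve$p2_mean[bp$curve$dt_ms == 3]
  se <- sqrt(0.6 * 0.4 / (25 * 10))
  expect_lt(abs(p2_at_3 - 0.6), 4 * se)
})

test_that("step-protocol responses encode burstiness by construction", {
  cfg <- test_config(seed = 41)
  bursty <- gen_step_protocol(cfg, bursty = TRUE, burst_current_pA = 200)
  ib <- intrinsic_burstiness(bursty)
  expect_equal(ib$min_burst_current_pA, 200)
  expect_gt(ib$burstiness, 0.5)

  regular <- gen_step_protocol(cfg, bursty = FALSE)
  ib0 <- intrinsic_burstiness(regular)
  expect_equal(ib0$burstiness, 0)
  expect_true(is.na(ib0$min_burst_current_pA))
})
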