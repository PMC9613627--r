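#!/usr/bin/env Rscript
# Stage 5: L5 intrinsically-bursty spike/burst analysis.
#
# Second/third-spike probability curves over the feedback delay for both
# pathway profiles (bootstrap 68% CIs over cells), second-spike timing
# statistics with the cross-pathway rank-sum comparison, the pooled
# cumulative timing distributions, and the intrinsic-burstiness metrics
# from the step protocol.

suppressMessages({library(cracmr); library(dplyr)})

seed <- 20260928L
out <- "results"
dir.create(out, showWarnings = FALSE)

make_trials <- function(pw) {
  cfg <- generator_config(
    seed = seed + match(pw, c("V1", "vS1")),
    bursting = default_bursting_params(pw),
    second_spike_delay = if (pw == "V1") c(mean_ms = 4.4, sd_ms = 0.49)
                         else c(mean_ms = 16, sd_ms = 8),
    bursting_ff_only = if (pw == "V1") c(p2 = 0.20, p3 = 0)
                       else c(p2 = 0.15, p3 = 0.09)
  )
  n_cells <- if (pw == "V1") 11 else 15
  tr <- gen_bursting_trials(cfg, n_cells = n_cells, trials_per_dt = 8)
  tr$group <- pw
  tr$cell_id <- paste(pw, tr$cell_id, sep = "_")
  tr
}

trials <- bind_rows(make_trials("V1"), make_trials("vS1"))

curves <- trials |>
  group_by(group) |>
  group_modify(~ burst_spike_probabilities(.x, seed = seed)$curve) |>
  ungroup()
readr::write_csv(curves, file.path(out, "burst_probability_curves.csv"))
for (pw in c("V1", "vS1")) {
  cc <- curves[curves$group == pw, ]
  message(sprintf("%s: peak p2 %.2f at dt %g ms; max p3 %.2f",
                  pw, max(cc$p2_mean), cc$dt_ms[which.max(cc$p2_mean)],
                  max(cc$p3_mean)))
}

# timing where feedback follows feed-forward (dt >= 0)
timing_trials <- trials[!is.na(trials$dt_ms) & trials$dt_ms >= 0, ]
timing <- second_spike_timing(timing_trials)
readr::write_csv(timing$per_cell, file.path(out, "second_spike_timing.csv"))
readr::write_csv(timing$tests, file.path(out, "timing_tests.csv"))
for (pw in c("V1", "vS1")) {
  pc <- timing$per_cell[timing$per_cell$group == pw, ]
  message(sprintf("%s second-spike delay: mean %.1f ms, SD %.2f ms (n = %d cells)",
                  pw, mean(pc$mean_delay_ms), mean(pc$sd_delay_ms, na.rm = TRUE),
                  nrow(pc)))
}
message(sprintf("rank-sum on per-cell means/SDs: p = %.2g / %.2g",
                timing$tests$p_raw[1], timing$tests$p_raw[2]))

cdf <- cumulative_timing_distribution(timing_trials)
readr::write_csv(cdf, file.path(out, "second_spike_cdf.csv"))

# intrinsic burstiness from the step protocol, both areas
ib <- bind_rows(lapply(c("V1", "vS1"), function(pw) {
  cfg <- generator_config(seed = seed + 10 + match(pw, c("V1", "vS1")))
  cells <- lapply(1:8, function(i) {
    steps <- gen_step_protocol(cfg, bursty = TRUE, seed = cfg$seed + i)
    r <- intrinsic_burstiness(steps)
    tibble::tibble(area = pw, cell = i, burstiness = r$burstiness,
                   min_burst_current_pA = r$min_burst_current_pA)
  })
  bind_rows(cells)
}))
readr::write_csv(ib, file.path(out, "intrinsic_burstiness.csv"))
message(sprintf("intrinsic burstiness: V1 median %.2f, vS1 median %.2f (rank-sum p = %.2g)",
                stats::median(ib$burstiness[ib$area == "V1"]),
                stats::median(ib$burstiness[ib$area == "vS1"]),
                suppressWarnings(stats::wilcox.test(
                  ib$burstiness[ib$area == "V1"],
                  ib$burstiness[ib$area == "vS1"])$p.value)))
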