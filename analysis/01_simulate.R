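#!/usr/bin/env Rscript
# Stage 1: generate the synthetic recording campaign.
#
# Produces a slice-grouped connectivity dataset (EPSC sweeps for every
# (area, layer, class) group, with per-slice gain variability and stored
# ground truth), paired LED-on/off sharpening trials, feed-forward /
# feedback bursting trials for both pathway profiles, and step-protocol
# responses for bursty and regular cells.

suppressMessages(library(cracmr))

seed <- 20260928L
out <- "results"
dir.create(file.path(out, "data"), recursive = TRUE, showWarnings = FALSE)

cfg <- generator_config(seed = seed)
ds <- gen_slice_dataset(cfg, n_per_group = 12)
save_dataset(ds, file.path(out, "data", "slice_dataset"))
message(sprintf("slice dataset: %d cells on %d slices",
                nrow(ds$cells), nrow(ds$slice_gains)))

sharp <- gen_sharpening_trials(cfg, n_cells = 20, n_trials = 10)
saveRDS_path <- file.path(out, "data", "sharpening_trials.csv")
readr::write_csv(
  dplyr::mutate(sharp, spike_times = purrr::map_chr(
    spike_times, ~ paste(round(.x, 4), collapse = ";"))),
  saveRDS_path
)
message(sprintf("sharpening: %d trials over %d cells", nrow(sharp), 20))

for (pw in c("V1", "vS1")) {
  cfg_pw <- generator_config(
    seed = seed + match(pw, c("V1", "vS1")),
    bursting = default_bursting_params(pw),
    second_spike_delay = if (pw == "V1") c(mean_ms = 4.4, sd_ms = 0.49)
                         else c(mean_ms = 16, sd_ms = 8),
    bursting_ff_only = if (pw == "V1") c(p2 = 0.20, p3 = 0)
                       else c(p2 = 0.15, p3 = 0.09)
  )
  n_cells <- if (pw == "V1") 11 else 15
  bt <- gen_bursting_trials(cfg_pw, n_cells = n_cells, trials_per_dt = 8)
  readr::write_csv(
    dplyr::mutate(bt, spike_times = purrr::map_chr(
      spike_times, ~ paste(round(.x, 4), collapse = ";"))),
    file.path(out, "data", sprintf("bursting_trials_%s.csv", pw))
  )
  message(sprintf("bursting (%s): %d trials over %d cells", pw, nrow(bt), n_cells))
}

message("done: inputs written under results/data/")
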