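#' Default pipeline configuration
#'
#' A single configuration list drives every stage: the generator
#' sub-configuration, the latency cutoff (7 ms default, 4 ms alternate),
#' slice inclusion threshold, problem sizes, and seeds. Unknown keys in a
#' user-supplied configuration are rejected.
#'
#' @param seed Master seed; stage seeds derive from it.
#' @param latency_cutoff_ms 7 (default) or 4.
#' @param min_mean_epsc_pA Slice inclusion threshold for the spiking stage.
#' @param n_per_group Cells per (area, layer, class) group in the simulated
#'   slice dataset.
#' @param n_sharpening_cells,n_sharpening_trials Sharpening-stage sizes.
#' @param n_bursting_cells,trials_per_dt Bursting-stage sizes.
#' @param generator Optional [generator_config()] override.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, latency_cutoff_ms = 7,
                            min_mean_epsc_pA = 50, n_per_group = 12,
                            n_sharpening_cells = 15, n_sharpening_trials = 10,
                            n_bursting_cells = 12, trials_per_dt = 8,
                            generator = NULL) {
  if (!latency_cutoff_ms %in% c(7, 4)) {
    stop("latency_cutoff_ms must be 7 or 4", call. = FALSE)
  }
  if (is.null(generator)) generator <- generator_config(seed = seed)
  structure(
    list(seed = as.integer(seed), latency_cutoff_ms = latency_cutoff_ms,
         min_mean_epsc_pA = min_mean_epsc_pA, n_per_group = n_per_group,
         n_sharpening_cells = n_sharpening_cells,
         n_sharpening_trials = n_sharpening_trials,
         n_bursting_cells = n_bursting_cells, trials_per_dt = trials_per_dt,
         generator = generator),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields of [pipeline_config()] may be overridden from a YAML file;
#' unknown keys are rejected with their names.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- setdiff(names(formals(pipeline_config)), "generator")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, raw)
}

#' Save / load a slice dataset
#'
#' Datasets serialize to a directory of plain-text files: `cells.csv` (one
#' row per cell; waveforms are regenerated deterministically from the
#' stored seed rather than stored), `ground_truth.json`, and
#' `manifest.json` (schema version and seed). `load_dataset()` validates
#' the schema and re-renders the sweeps.
#'
#' @param dataset A [gen_slice_dataset()] result.
#' @param dir Output directory (created if missing).
#' @return `save_dataset()` returns `dir` invisibly; `load_dataset()`
#'   returns a `slice_dataset`.
#' @export
save_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(dplyr::select(dataset$cells, -"sweep"),
                   file.path(dir, "cells.csv"))
  jsonlite::write_json(dataset$ground_truth, file.path(dir, "ground_truth.json"),
                       dataframe = "rows", digits = NA)
  jsonlite::write_json(
    list(schema_version = "1.0", seed = dataset$seed,
         n_cells = nrow(dataset$cells)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE
  )
  invisible(dir)
}

#' @rdname save_dataset
#' @param cfg Generator configuration used to re-render sweeps (must match
#'   the one that generated the dataset).
#' @param schema_version Expected schema version.
#' @export
load_dataset <- function(dir, cfg, schema_version = "1.0") {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path)) stop("no manifest.json in ", dir, call. = FALSE)
  man <- jsonlite::read_json(man_path)
  if (!identical(man$schema_version, schema_version)) {
    stop("dataset schema version ", man$schema_version,
         " does not match expected ", schema_version,
         "; migrate the dataset first", call. = FALSE)
  }
  cells <- readr::read_csv(file.path(dir, "cells.csv"),
                           show_col_types = FALSE)
  required <- c("cell_id", "slice_id", "area", "layer", "cell_class", "mode",
                "true_amplitude", "true_latency")
  missing <- setdiff(required, names(cells))
  if (length(missing) > 0) {
    stop("cells.csv is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(cells) != man$n_cells) {
    stop("cells.csv has ", nrow(cells), " rows but manifest records ",
         man$n_cells, " (truncated file?)", call. = FALSE)
  }
  gt <- tibble::as_tibble(jsonlite::fromJSON(file.path(dir, "ground_truth.json")))
  gen_one <- function(mode) if (mode == "voltage_clamp") gen_psc_sweep else gen_epsp_sweep
  cells$sweep <- purrr::pmap(
    list(cells$true_amplitude, cells$true_latency, seq_len(nrow(cells)),
         cells$mode),
    function(a, l, i, m) gen_one(m)(cfg, a, l, seed = derive_seed(cfg$seed, i))
  )
  structure(list(cells = cells, ground_truth = gt,
                 slice_gains = NULL, config = cfg,
                 seed = as.integer(man$seed)),
            class = "slice_dataset")
}

#' Run the full analysis pipeline
#'
#' Executes simulate, events, connectivity statistics, spike dynamics, and
#' report stages end to end, writing tidy CSV tables and a JSON summary
#' under `out_dir`. The run is deterministic given the configuration seed;
#' a run manifest (seed, package version, per-stage row counts) is written
#' alongside the results.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = "results") {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- config$generator
  t0 <- Sys.time()
  log_stage <- function(name, ...) {
    message(sprintf("[%s] %s (%.1fs elapsed)", name, paste0(...),
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }

  # simulate
  ds <- gen_slice_dataset(cfg, n_per_group = config$n_per_group)
  sharp <- gen_sharpening_trials(cfg, config$n_sharpening_cells,
                                 config$n_sharpening_trials)
  burst_trials <- gen_bursting_trials(cfg, config$n_bursting_cells,
                                      config$trials_per_dt)
  steps <- gen_step_protocol(cfg, bursty = TRUE)
  log_stage("simulate", nrow(ds$cells), " cells, ", nrow(sharp), " sharpening trials, ",
            nrow(burst_trials), " bursting trials")

  # events
  events <- events_table(ds, cutoff_ms = config$latency_cutoff_ms)
  readr::write_csv(events, file.path(out_dir, "events.csv"))
  log_stage("events", nrow(events), " events measured")

  # connectivity statistics
  norm <- normalize_to_reference(events)
  fractions <- responsive_fraction_table(events)
  class_groups <- split(norm$log2_ratio,
                        paste(norm$area, norm$layer, norm$cell_class))
  kw <- lapply(split(norm, norm$area), function(df) {
    kruskal_wallis(split(df$log2_ratio,
                         paste(df$layer, df$cell_class)))
  })
  comparisons <- dplyr::bind_rows(kw, .id = "area")
  readr::write_csv(norm |> dplyr::select(-"baseline_sd"),
                   file.path(out_dir, "normalized_responses.csv"))
  readr::write_csv(fractions, file.path(out_dir, "responsive_fractions.csv"))
  readr::write_csv(comparisons, file.path(out_dir, "comparisons.csv"))
  log_stage("stats", nrow(norm), " normalized responses")

  # spike dynamics
  rates <- sharpening_rates(sharp)
  delays <- first_spike_delay(sharp)
  bursts <- burst_spike_probabilities(burst_trials, seed = config$seed)
  burstiness <- intrinsic_burstiness(steps,
                                     step_duration_ms = cfg$step_protocol$duration_ms)
  readr::write_csv(rates$per_cell, file.path(out_dir, "sharpening_rates.csv"))
  readr::write_csv(delays$per_cell, file.path(out_dir, "first_spike_delays.csv"))
  readr::write_csv(bursts$curve, file.path(out_dir, "burst_probability_curve.csv"))
  log_stage("dynamics", nrow(bursts$curve), " burst-curve points")

  manifest <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("cracmr")),
    latency_cutoff_ms = config$latency_cutoff_ms,
    rows = list(events = nrow(events), normalized = nrow(norm),
                fractions = nrow(fractions),
                sharpening_cells = nrow(rates$per_cell),
                burst_curve = nrow(bursts$curve)),
    burstiness = burstiness$burstiness,
    min_burst_current_pA = burstiness$min_burst_current_pA
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  write_report(list(fractions = fractions, comparisons = comparisons,
                    burst_curve = bursts$curve,
                    sharpening_test = rates$test,
                    delay_test = delays$test), out_dir)
  log_stage("report", "written to ", out_dir)
  invisible(manifest)
}

#' Write a report summary
#'
#' Serializes whatever stage results are present into a JSON summary
#' (tables are written by the stages themselves as CSV). Empty input
#' produces an empty-but-valid skeleton.
#'
#' @param results Named list of stage results (tibbles or scalars).
#' @param out_dir Output directory.
#' @return Path of the summary file, invisibly.
#' @export
write_report <- function(results, out_dir = "results") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(results, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
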