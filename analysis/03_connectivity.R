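#!/usr/bin/env Rscript
# Stage 3: slice-normalized connectivity comparison.
#
# Normalizes amplitudes to the within-slice L2/3 pyramidal reference,
# runs per-area Kruskal-Wallis tests over (layer, class) groups with
# Conover-Iman post hoc pairs, sign-flip permutation tests of every class
# against the reference, and cross-pathway rank-sum comparisons with
# Benjamini-Hochberg adjustment.

suppressMessages({library(cracmr); library(dplyr)})

out <- "results"
ev <- readr::read_csv(file.path(out, "events_cutoff7.csv"), show_col_types = FALSE)

norm <- normalize_to_reference(ev)
readr::write_csv(select(norm, -any_of("baseline_sd")),
                 file.path(out, "normalized_responses.csv"))

medians <- norm |>
  group_by(area, layer, cell_class) |>
  summarise(median_log2 = stats::median(log2_ratio), n = n(), .groups = "drop")
readr::write_csv(medians, file.path(out, "normalized_medians.csv"))
l1 <- medians[medians$cell_class == "L1_interneuron", ]
message(sprintf("L1 interneuron median log2 ratios: V1 %.2f, vS1 %.2f",
                l1$median_log2[l1$area == "V1"], l1$median_log2[l1$area == "vS1"]))

# per-area omnibus + post hoc
comp <- list()
for (a in unique(norm$area)) {
  sub <- norm[norm$area == a, ]
  groups <- split(sub$log2_ratio, paste(sub$layer, sub$cell_class))
  kw <- kruskal_wallis(groups)
  message(sprintf("%s Kruskal-Wallis over %d groups: H = %.1f, p = %.2g",
                  a, length(groups), kw$statistic, kw$p_raw))
  comp[[paste0("kw_", a)]] <- kw
  comp[[paste0("conover_", a)]] <- conover_posthoc(groups)
  # each non-reference class against the L2/3 pyramidal reference
  nonref <- sub[!(sub$layer == "L2/3" & sub$cell_class == "Pyr"), ]
  perm <- nonref |>
    group_by(layer, cell_class) |>
    group_modify(~ permutation_signed_test(.x$log2_ratio)) |>
    ungroup()
  comp[[paste0("signflip_", a)]] <- perm
}

# matched types across pathways, BH-adjusted
types <- norm |> distinct(layer, cell_class)
fam <- list()
for (i in seq_len(nrow(types))) {
  v1 <- norm$log2_ratio[norm$area == "V1" & norm$layer == types$layer[i] &
                          norm$cell_class == types$cell_class[i]]
  vs1 <- norm$log2_ratio[norm$area == "vS1" & norm$layer == types$layer[i] &
                           norm$cell_class == types$cell_class[i]]
  if (length(v1) > 0 && length(vs1) > 0) {
    fam[[paste(types$layer[i], types$cell_class[i])]] <- list(v1, vs1)
  }
}
cross <- cross_pathway_comparison(fam)
comp$cross_pathway <- cross
message(sprintf("cross-pathway: %d comparisons, %d significant after BH at 0.05",
                nrow(cross), sum(cross$p_adjusted < 0.05)))

readr::write_csv(bind_rows(comp, .id = "family"), file.path(out, "comparisons.csv"))
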