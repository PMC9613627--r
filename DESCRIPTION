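Package: cracmr
Title: Analysis of Optogenetic Cortico-Cortical Circuit-Mapping Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for quantifying cell-type-specific connectivity and
    dynamics from channelrhodopsin-assisted circuit-mapping (CRACM-style)
    whole-cell recordings. Extracts evoked postsynaptic current/potential
    metrics (baseline, amplitude, 20-80% extrapolated latency, kinetics),
    classifies cell responsiveness and monosynaptic origin (TTX/4-AP),
    normalizes amplitudes within slices to L2/3 pyramidal references and runs
    the nonparametric comparison battery (Kruskal-Wallis, Conover-Iman post
    hoc, permutation sign-flip, rank-sum with Benjamini-Hochberg), analyses
    temporal sharpening of spike trains under sustained current steps (PSTH,
    initial-rate and first-spike-delay comparisons), and quantifies burst
    facilitation of L5 intrinsically-bursty neurons (second/third-spike
    probability curves with bootstrap confidence intervals, spike-timing
    statistics, intrinsic burstiness). Includes a seeded synthetic-data
    generator emulating the recordings so every stage is testable without
    raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
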