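---
title: "Methods: quantifying cell-type-specific feedback connectivity and dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying cell-type-specific feedback connectivity and dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cracmr)
```

## The problem

Optogenetic circuit mapping asks which cell types a long-range projection
actually contacts. Axon terminals of a source area (e.g. a higher-order
visual or motor area) are made light-sensitive with channelrhodopsin;
brief blue-light pulses then evoke postsynaptic currents (EPSCs, voltage
clamp at −85 mV) or potentials (EPSPs, current clamp near −70 mV) in
neurons of the target area, recorded one cell at a time in acute slices.
The analysis questions are: which cells respond, and how strongly relative
to a common within-slice reference; whether responses are monosynaptic;
how feedback reshapes spiking under sustained somatic drive; and whether
feedback paired with a brief somatic pulse facilitates bursting in layer-5
intrinsically bursty (IB) cells.

`cracmr` implements this full analysis chain plus a synthetic-recording
generator with stored ground truth, so that every stage can be exercised
and validated without any raw recordings.

## Evoked-event measurement

For a sweep with LED onset $t_0$:

* **Baseline**: mean and SD over $[t_0 - 40, t_0)$ ms.
* **Amplitude**: magnitude of the extremum of the baseline-subtracted
  trace over $(t_0, t_0 + 35]$ ms, downward in voltage clamp and upward in
  current clamp; ties go to the earliest sample.
* **Latency**: the trace crosses 20% and 80% of the peak on the rising
  phase contiguous with the peak; the line through $(t_{20}, 0.2A)$ and
  $(t_{80}, 0.8A)$ is extrapolated back to baseline, giving
  $t_{20} - (t_{80} - t_{20})/3$ relative to LED onset. Crossing times are
  interpolated between samples, which removes the sampling-rate dependence
  of the estimate.
* **Kinetics**: rise time $t_{80} - t_{20}$, time to peak
  (peak time − latency), and decay time to $1/e$ of the peak
  (interpolated; flagged if the sweep ends first).
* **Responsiveness**: latency $< 7$ ms (strict; 4 ms as the stricter
  alternative) *and* amplitude $> 3\times$ baseline SD. An undefined
  latency is non-responsive.
* **Spiking EPSPs**: when the cell fires within the response window, the
  EPSP amplitude is baseline-to-threshold, with the threshold potential
  detected as the first sample before the action-potential peak where
  $dV/dt \ge 20$ mV/ms (a standard convention for a detector the
  criteria leave open).
* **Monosynaptic origin**: control responsive, abolished under TTX,
  recovered under TTX + 4-AP. Recovery reuses the amplitude criterion
  against the recovered condition's own baseline SD, without a latency
  requirement — 4-AP-recovered events are slower by construction.

### Why the crossings anchor to the rise into the peak

A natural reading of "the two points of time when the current was 20% and
80% of the peak" is the *first* crossing of each level after stimulus
onset. On clean events both readings coincide. On weak or absent events
they do not: with any realistic (Gaussian, low-pass-filtered) recording
noise, the trace crosses $0.2 \times$ peak within the first few
milliseconds almost surely, so the first-crossing rule assigns short
latencies to pure noise and the responsiveness criterion then passes
roughly a third of pure-noise sweeps. Anchoring both crossings to the last
upward crossing at or before the peak — the standard 20–80% rise-time
convention — measures the rise of the event itself and brings the
pure-noise responsive rate down to about 7% (reported by the test suite).
That residual is irreducible: the amplitude criterion compares the 35 ms
extremum (typically ≈2.5 SD for stationary Gaussian noise) against a
3 SD threshold estimated from a 40 ms baseline, a scale-free contest that
noise occasionally wins. At the evoked amplitudes the recordings report
(tens to hundreds of pA against ~2 pA noise) the false-positive floor is
inconsequential.

## Slice normalization and the statistical battery

Evoked amplitudes are not comparable across slices and animals because
virus expression varies. Every slice therefore carries at least one L2/3
pyramidal reference cell, and each cell's amplitude is reported as
$\log_2(\text{amplitude} / \overline{\text{ref}})$ with
$\overline{\text{ref}}$ the mean reference amplitude on that slice. This
makes the analysis invariant to any per-slice multiplicative gain, which
the test suite checks directly.

The comparison battery mirrors the study design:

* **Kruskal–Wallis** (tie-corrected, via `stats::kruskal.test`) per area
  over (layer, class) groups.
* **Conover–Iman post hoc** pairwise comparisons on the pooled ranks,
  $t = (\bar R_i - \bar R_j) \big/ \sqrt{S^2 \tfrac{N-1-H}{N-k}
  (\tfrac1{n_i} + \tfrac1{n_j})}$ with $N - k$ degrees of freedom,
  reported raw (no within-pathway adjustment, matching the design).
  Implemented in the package since no installed library provides it; the
  tests pin it to hand-applied values of the published formula.
* **Permutation sign-flip test** for each class against the reference:
  the statistic is the mean log2 ratio and the two-sided p-value is the
  fraction of the $2^n$ sign assignments at least as extreme, exhaustive
  for $n \le 20$ and a seeded Monte-Carlo sample above that. The study
  names this test without defining it; symmetry about zero (equality with
  the reference) is the natural null.
* **Cross-pathway rank-sum** tests per matched cell type with
  Benjamini–Hochberg adjustment across the family. Fully tied samples
  (e.g. the reference class against itself, all zeros) are reported with
  p = 1 rather than a degenerate statistic.

Normalized-response comparisons include responsive and non-responsive
cells alike (exclusion is exposed as a choice to the caller, not a
default), since the criteria define responsiveness for counting, not a
gate on amplitudes.

The spiking analysis only admits slices whose mean reference EPSC is at
least 50 pA — the boundary is treated as inclusive since the threshold is
described as a minimum — and counts spiking cells over all cells recorded
in current-clamp mode per group.

## Spike-train analyses

**Temporal sharpening.** Trials pair a 300 ms somatic step with a 20 ms
LED at a random onset 100–200 ms into the step, interleaved with LED-off
trials carrying the same nominal LED time. PSTHs use 1 ms bins smoothed
with a 4 ms boxcar (the description "box-car filter of 4 ms time bins" is
ambiguous between bin width and kernel width; 1 ms bins with a 4 ms
kernel is the finer-grained reading and both are configurable), with edge
bins renormalized to the partial kernel so a flat rate stays flat. The
excitatory effect is the firing rate within 10 ms of LED onset (on vs
off, paired Wilcoxon signed-rank across cells); the inhibitory effect is
the delay of the first spike at or after LED offset (closed left
boundary) relative to LED onset.

**Bursting.** Trials carry a feed-forward spike at the 2 ms somatic pulse
and optionally a feedback pulse at
$\Delta t \in \{-10,-6,-3,0,3,6,10\}$ ms. Second/third spikes are counted
in a $[FF, FF + 50)$ ms window — the recordings eliminate subsequent
spiking within at least 20 ms but fix no counting window; 50 ms covers
the slow pathway's delays (mean 16, SD 8 ms) with margin and is
configurable. Per cell and $\Delta t$ the per-trial fractions give
$p_2, p_3$; group means carry seeded bootstrap 68% CIs (resample cells
with replacement, $B = 1000$, percentile 16–84), and each $\Delta t$ is
compared with the feed-forward-only condition by paired signed-rank.
Group means weight cells equally regardless of trial count. Second-spike
timing (relative to feedback onset) is summarized per cell by the sample
mean and $n-1$ SD over qualifying trials — cells without any second spike
are excluded, a single qualifying trial leaves the SD missing — and
compared across pathways by rank-sum on the means and on the SDs.

**Intrinsic burstiness.** From the 700 ms step protocol (−200 to 600 pA
in 20 pA steps), a burst is a run of ≥2 spikes with interspike intervals
at or below 10 ms (configurable; the upstream toolkit the metric follows
does not publish its parameters). Per step,
$f_{in}$ = spikes-in-bursts over total burst duration (first-to-last
spike span; an optional pad is exposed but defaults to 0, matching the
metric's worked arithmetic) and $f_{out}$ = remaining spikes over the
remaining step time; the score is $(f_{in} - f_{out})/(f_{in} + f_{out})
\in [-1, 1]$. The cell's burstiness is the median score over the first
(at most) five bursting steps in ascending current order; the minimal
bursting current is the lowest step current with a burst. No bursting
step gives burstiness 0 and a missing minimal current.

## The synthetic-recording generator

The generator emulates exactly the statistical structure the analyses
assume, with every draw under a master seed (sub-seeds per cell/trial for
reproducible generation) and ground truth stored alongside.

* **Evoked events** are difference-of-exponentials kernels
  $A k (e^{-t/\tau_d} - e^{-t/\tau_r})$ with $k$ normalizing the peak to
  $A$ ($\tau_r = 0.5$, $\tau_d = 5$ ms by default), onset latency
  $\mathcal N(3, 0.5^2)$ ms, rendered downward at −85 mV holding.
  Recording noise is a stationary AR(1) process with 1 ms correlation
  time and 2 pA SD — whole-cell recordings are low-pass filtered, so
  sample-wise white noise at 20 kHz would be unrealistic.
* **The class-amplitude table** encodes the connectivity structure the
  comparisons should recover: L1 interneurons above the L2/3 pyramidal
  reference in both areas, SOM+ over VIP+ in V1 and the reverse in vS1,
  L2/3 over L5 in V1 and the reverse in vS1 (SOM+ excepted), and very
  weak vS1 L4 input. Per-slice lognormal gains emulate virus-titer
  variability; the normalization must and does cancel them.
* **Sharpening trials** are point processes, not membrane simulations,
  since every downstream statistic consumes spike times only: a gamma
  renewal train (shape 10, 20 Hz) with the equilibrium
  forward-recurrence start, so the expected count in any window is
  unbiased; on LED-on trials a forced spike within 10 ms of LED onset
  (probability 0.9 by default) and removal of baseline spikes from LED
  onset until 40 ms past LED offset. Setting both the forced-spike
  probability and the suppression to zero disables the mechanism
  entirely, making the null configuration exactly null. Ten paired
  trials per cell is a free choice (the recordings do not report trial
  counts for this protocol).
* **Bursting trials** draw an independent second spike with probability
  $p_2(\Delta t)$ at feedback onset plus a configured delay
  (fast/precise for the visual pathway, slow/jittered for the
  somatosensory pathway, per the two profile presets), and a third with
  conditional probability $p_3/p_2$; configurations with
  $p_3 > p_2$ are rejected. Eight trials per $\Delta t$ sits inside the
  recorded 6–10.
* **Step responses** place an initial spike cluster above a configurable
  bursting current plus sparse regular spikes (bursty cells), or evenly
  spaced spikes only (regular cells), so the burstiness metrics have
  known targets.

What the generator does *not* emulate: biophysical membrane dynamics,
electrode artifacts, series-resistance effects, non-stationary drift, or
correlations between cells recorded simultaneously. Passing tests
therefore validate the measurement and statistical machinery under the
stated stochastic structure, not robustness to every pathology of real
recordings.

## Numerical and design choices

* Windows are half-open — $[t_0 - 40, t_0)$ for baseline,
  $(t_0, t_0 + 35]$ for the response — matching "prior to" and "within
  35 ms after"; sub-sample crossings by linear interpolation; ties on
  equal extrema go to the earliest time.
* The slice-inclusion boundary (50 pA) is inclusive.
* Bootstrap and Monte-Carlo procedures take explicit seeds and are
  byte-reproducible; identical configuration and seed reproduce every
  dataset and CSV output exactly.
* Degenerate inputs are defined, not errors: all-identical groups give
  H = 0 and p = 1; all-zero sign-flip input gives p = 1; empty groups
  report missing fractions; a cell with one qualifying trial reports a
  mean but no SD.
* Problem sizes in the shipped analyses (12 cells per group, 20
  sharpening cells × 10 trials, 11–15 bursting cells × 8 trials per
  $\Delta t$) match the scale of the recorded cohorts, which is also the
  scale at which the parameter-recovery tests demonstrate that the
  statistics resolve the configured effects.

## Known limitations

* The pure-noise responsive rate (~7%) exceeds a "few percent" for the
  reasons above; it is a property of the published criteria under
  Gaussian noise, reported rather than hidden.
* Conover–Iman p-values are reported raw within pathways by design;
  users running many post hoc pairs should consider their own
  multiplicity control.
* The EPSP spike-threshold detector (20 mV/ms) is a convention; real
  threshold estimates vary by a few mV across detectors.
* Second-spike timing under negative $\Delta t$ (feedback before
  feed-forward) is clamped by the feed-forward refractory period in the
  generator, so timing statistics are characterized for
  $\Delta t \ge 0$, where the recordings' delay statistics live.
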