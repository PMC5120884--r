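---
title: "wormstate: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{wormstate: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormstate)
```

# The problem

A single neuromodulatory neuron can bias an animal's behavioral state
without being required for the state itself. Quantifying that claim for a
*C. elegans* neuron takes four kinds of evidence, each with its own data
and analysis:

1. **Spontaneous locomotion**: does losing the neuron change how much time
   animals spend crawling forward, how often they re-initiate bouts, how
   long bouts last, and how fast they move?
2. **Calcium imaging in moving animals**: does the neuron's activity track
   transitions between backward and forward crawling, and does the rate of
   the velocity change predict the rate of the calcium change?
3. **Optogenetic stimulation**: does activating the neuron lengthen forward
   runs and raise run velocity during stimulation epochs?
4. **Sorted-cell transcriptomics**: which transcripts does the neuron
   express, inferred subtractively by comparing marker-positive FACS
   fractions between a wild type and a mutant that congenitally lacks the
   neuron?

`wormstate` implements the quantitative side of all four, plus a
synthetic-data module that generates each input kind with known ground
truth, so the whole pipeline is testable without any recordings.

# Locomotion: bouts and motility metrics

**Input.** Per-frame head, tail and centroid coordinates (µm,
stage-corrected), typically 10 frames/s, with head/tail identity fixed at
the start of the recording.

**Signed velocity.** `body_axis_velocity()` projects the per-frame
centroid displacement on the unit tail→head axis and multiplies by the
frame rate. The projection makes the sign (forward vs backward) intrinsic
to the animal and the reading invariant to stage rotation and translation;
frames with a degenerate axis (head = tail, a tracking failure) are marked
untracked and excluded from all denominators.

**Segmentation.** Frames with `|v|` at or below a pause threshold (default
20 µm/s — well below crawling speeds of 100–200 µm/s yet above coordinate
jitter) are pauses; otherwise the sign gives forward/reversal. A candidate
bout must last more than 3 frames or at least 300 ms (the two coincide at
10 frames/s); shorter excursions are absorbed — into the flanking state
when both sides agree, else into pause, else into the longer neighbour —
so single-frame jitter never counts as a re-initiation. Bout intervals are
half-open `[start, end)` on 0-based frames and exactly tile the tracked
frames; bouts truncated by the recording edge are kept.

**Metrics.** `bout_metrics()` reports per state: fraction of tracked time
(summing to 1), initiations per minute, mean bout duration and mean
per-bout signed velocity — the four quantities a genotype comparison
needs.

**Curvature kymograms.** With a midline (≥3 ordered points per frame),
`curvature_kymogram()` returns the signed angle between successive midline
tangents as a (body position × time) matrix; propagating bends appear as
diagonal stripes whose slope is the wave speed.

# Calcium: ratiometric ΔF/F and transition analysis

**Ratio and ΔF/F.** `ratiometric_dff()` computes GCaMP/RFP per frame; a
motion artifact that multiplies both channels cancels exactly. ΔF/F is
`(ratio − baseline)/baseline`; the default baseline is the 10th percentile
of the ratio over the recording — robust to activity transients, which
occupy the upper tail — and a fixed value or reference-window mean can be
supplied instead.

**Transitions.** `detect_transitions()` emits one event per adjacent
reversal/forward bout pair. A crawling worm passes through zero velocity
when it switches direction, so sub-second pauses between the two
directional bouts (≤ 1 s by default) do not break adjacency; the anchor is
the midpoint of that crossing gap. Because a slow indicator needs seconds
to respond, rate analyses restrict events to sustained flanking bouts
(`min_from_s = 2`, `min_to_s = 5` in the package's own analyses): a
destination bout shorter than the indicator's rise time cannot express the
response whose slope is being measured.

**Rates and slopes.** For a reversal→forward event, the velocity trough is
the minimum during the reversal bout and the peak the maximum during the
forward bout; the acceleration rate is `(v_peak − v_trough) / n_frames`
with `n_frames` the trough-to-peak frame count. Forward→reversal events
use the mirrored formula `(v_trough − v_peak) / n_frames`. The calcium
rise/decay is the least-squares slope of ΔF/F over the same trough-to-peak
interval — the paired quantities share a support by construction.
`rate_correlation()` then reports the Pearson correlation (two-sided p)
between velocity rate and calcium slope across events, and
`event_aligned_average()` gives the mean ± SEM trace around anchors.

# Optogenetics: runs, turns and epochs

**Heading and turns.** `compute_heading()` box-smooths the centroid
(default 0.5 s, damping pixel jitter at 30 frames/s) and takes the
direction of per-frame displacement; frames with sub-threshold
displacement have no defined heading. A frame is a turn frame when the
circular heading difference across the ends of a centered 1-s window
exceeds 60°; contiguous flags merge into turns. A centered window was
chosen over a trailing one so a turn is flagged at the frames where the
reorientation actually happens; both the threshold and window are
configurable (`opto_config()`).

**Runs and epochs.** Runs are maximal turn-free intervals, each with
duration, path length and mean speed; runs and turns tile the recording.
Stimulation alternates OFF/ON with a 3-min half-period by default; a run
belongs to the epoch containing its start (runs spanning a boundary are
not split — attributing them to their starting epoch preserves run
integrity, and both duration and path length are reported because "run
length" can mean either).

**Phasic velocity.** For each OFF→ON switch flanked by the required
seconds of continuous forward movement (10 s by default; 4 s is the
choice for slow mutants, configurable rather than hard-coded per
genotype), `phasic_velocity_change()` averages speed over the pre- and
post-windows and compares the per-switch pairs with a two-sided Wilcoxon
matched-pairs signed-rank test. Unsmoothed centroid speed is appropriate
here: smoothing across the switch leaks ON frames into the pre-window and
biases the step estimate toward zero.

# Enrichment: the subtractive pipeline

**Design.** Two genotypes (wild type, mutant missing the target cell),
each with a marker-positive FACS fraction ("GFP+") and an unsorted
"AllCells" reference from the same animals, ≥3 replicates per group.
Within each genotype, transcripts enriched in GFP+ over AllCells are
called by: FDR-adjusted p < 0.05 (strict) **and** mean-GFP+/mean-AllCells
ratio > 1. The ratio criterion is the plain mean ratio; a reading based on
quotients of log2-transformed means exists as a config mode
(`ratio_mode = "log2"`), but the plain ratio is the one consistent with
reported fold changes, so it is the default. Subtracting the mutant's
enriched set from the wild type's then nominates transcripts of the
missing cell: `shared` genes are enriched in both, `wt_only` genes are the
candidates, and the symmetric difference is the "preferentially enriched"
set.

**Normalization.** `size_factors()` implements median-of-ratios: sample
j's factor is the median over genes of count/geometric-mean, using genes
with nonzero counts in every sample. It agrees with the standard
implementation used by count-based differential-expression tools (checked
against `DESeq2::estimateSizeFactorsForMatrix` in the test suite).

**Testing.** `nb_test()` models normalized counts as negative binomial
(`var = µ + α µ²`). The per-gene dispersion is a pooled method-of-moments
estimate shrunk 80% toward the median dispersion of expressed genes:
moment estimates from 3–4 replicates are extremely noisy, and sharing
information across genes is what makes small-sample count testing
workable. The Wald statistic on the log-ratio of group means (delta
method, 0.5 pseudocount) is referred to a t distribution with
`n1 + n2 − 2 + 25` degrees of freedom; the 25 prior degrees of freedom
reflect the information borrowed by the shrinkage, in the spirit of
empirical-Bayes moderated statistics. This combination was chosen so the
null rejection rate sits at the nominal level on simulated null designs of
the study's size while retaining power for a few-fold planted effect; the
test suite verifies both, plus agreement with an exact permutation oracle
(whose resolution at 4 vs 3 replicates is limited to 1/35 — the reason the
oracle comparison is phrased in ranks and medians rather than a uniform
per-gene bound). `bh_fdr()` is the Benjamini-Hochberg step-up (via
`p.adjust`), verified against its brute-force definition.

**Validation.** `validate_markers()` checks that known positive markers of
the sorted cell types come out enriched and that non-target-tissue
negatives do not.

# Statistics

`compare_groups()` uses the two-sided Mann-Whitney U for two groups and
Kruskal-Wallis with Dunn's multiple-comparison post-hoc (pairwise z tests
on pooled mean ranks with tie correction; Bonferroni-family adjustment by
default) for more. `paired_test()` is the Wilcoxon matched-pairs
signed-rank test; with ≤12 nonzero differences the p value is exact by
enumeration of all sign assignments of the (average-)ranked absolute
differences — which stays exact under ties, where the textbook exact
algorithm is unavailable — and larger samples use the normal approximation
with tie correction. All tests are two-sided.

# The synthetic-data module

The generators define the study conditions under which the pipeline is
validated; every parameter is config-exposed and none is hard-coded as
truth downstream.

**Locomotion** (`simulate_trajectory()`): a three-state semi-Markov
process — exponential dwell times (explicit dwell distributions match
bout-level statistics better than a per-frame Markov chain), an embedded
transition chain with no self-transitions, per-state target speeds. The
wild-type-like default preset (dwell means 30/1.5/1.5 s for F/R/P, speeds
150/100/0 µm/s) has an analytic forward time fraction of about 0.95
(`stationary_state_fractions()`). The signed velocity follows the state
target with first-order dynamics — acceleration time constant 2 s, braking
0.3 s — because real crawling speed builds over seconds within a bout
while braking at a reversal is fast; this matters downstream: with
white-noise speeds, the velocity trough and peak of a transition would sit
at noise-determined positions and the trough-to-peak slope window would
routinely land inside the indicator's post-transition dip. The heading
diffuses by Gaussian circular increments (15°/√s); reversals keep the
heading and negate the along-axis displacement, as worms back up along
their body axis. Gaussian speed noise (20 µm/s in motion, 4 µm/s in
pauses) models measurement and physiological jitter.

**Calcium** (`simulate_calcium_session()`): activity `a(t)` is a
first-order low-pass filter (τ = 3 s) of the forward-state indicator
delayed by a 1-s onset lag — indicators respond within about a second,
while the filter makes the signal *peak* only 8–10 s after a transition,
the empirically relevant regime. GCaMP = `F0(1 + α a(t)) m(t)` + noise and
RFP = `R0 m(t)` + noise share the multiplicative artifact `m(t)`
(sinusoidal by default), so the noiseless ratio is exactly artifact-free.
Sessions for transition analysis use dwell means 15/6/2 s — recordings
suitable for transition analysis come from animals that reverse often and
substantially — and 15-minute durations so a session yields enough events
for a within-session correlation.

**Optogenetics** (`simulate_opto_session()`): alternating runs
(exponential durations) and brief >90° reorientations (~0.5 s), an
OFF-first epoch square wave, a run-duration multiplier applied to runs
starting in ON epochs and a speed multiplier applied per ON frame. Ground
truth records every run with its sampled duration and epoch.

**Counts** (`simulate_counts()`): 20 cell-type profiles; AllCells mixes
all of them uniformly, GFP+ mixes 5, and the mutant drops the target type
from both mixtures. Non-planted genes (gamma base levels, mean 100) are
identical across types, so their GFP+ and AllCells mixture means coincide
and they are genuinely null for enrichment — which is what makes empirical
FDR measurable. Planted genes (50 by default) are expressed only in the
target type at 5× a gamma base level whose scale (mean 400) reflects that
cell-type-specific transcripts worth validating are robustly quantifiable.
Counts are negative binomial (dispersion 0.1) around mixture means times
log-normal library size factors; 4 GFP+ vs 3 AllCells replicates per
genotype.

**What the generators do not emulate.** No posture dynamics beyond the
midline abstraction, no omega-turns or head-tail collisions, no
photobleaching or focus drift in the fluorescence channels, no
batch/bleed-through structure in the counts, and cell-type profiles vary
only at planted genes. Passing tests therefore demonstrate that the
analysis recovers known structure under realistic noise — not that every
artifact of real recordings is handled.

# Numerical choices and degenerate inputs

- Bout intervals half-open, 0-based; fractions sum to 1 within 1e−9.
- Heading differences are circular in (−180°, 180°]; the turn window is
  centered, with the odd frame going to the trailing side.
- All-zero samples, single-observation groups, zero-variance correlations
  and all-zero gene rows are flagged or rejected with named errors rather
  than propagating NaN.
- Enrichment with a zero AllCells mean reports an infinite fold change and
  falls back to the q criterion alone.
- Every generator is bit-reproducible given a seed.

# Problem sizes used by the test suite

The suite validates properties at sizes chosen to make sampling error
small relative to the assertion margins: 10 three-minute animals for
fraction/dwell recovery, 100 random traces for the turn-detection oracle,
200 fifteen-minute sessions for correlation-sign recovery, 12 half-hour
stimulation sessions for the phasic effect, 2000 null genes for test
calibration, 1000 random vectors for the BH oracle, and 2000-replicate
null resampling for the type-I error of the nonparametric tests.

# Known limitations

- The NB test is a moderated Wald test, not a full GLM with per-gene
  dispersion estimation; it is calibrated for the two-group sorted-cell
  design, not for arbitrary multi-factor designs.
- Segmentation slightly over-assigns forward time (~1–3%) because ramp
  frames at bout boundaries carry the sign of the incoming state; the
  bias is visible against ground truth and shared by any threshold-based
  segmentation of dynamically ramping velocity.
- Dunn's post-hoc uses the large-sample z approximation; exact small-n
  post-hoc enumeration is not provided.
- Pooled (not per-animal) event correlation is the default; per-animal
  aggregation can be done by calling `rate_correlation()` on per-animal
  event tables.
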