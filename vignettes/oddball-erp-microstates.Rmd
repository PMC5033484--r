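---
title: "Methods: oddball ERP simulation, topographic statistics and microstates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: oddball ERP simulation, topographic statistics and microstates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erpstates)
```

This vignette documents the models, the tunable parameters, the numerical
choices and the known limitations of the package — the information a
maintainer or reviewer needs to judge what a passing test suite does and does
not establish.

## 1. The design and the sequencer

A block presents `n_standards_per_block` standards in runs of 3, 4 or 5,
each run followed by exactly one deviant (non-target or target), so no two
deviants are ever adjacent. The run-length multiset is solved exactly: among
all non-negative count vectors whose lengths sum to the standards total with
one run per deviant, the most balanced one (minimal spread) is chosen, and
for the study-scale block (640 standards, 160 deviants) this is 53/54/53 —
reproducing the printed totals deterministically. The design does not state
whether the three run lengths are balanced; balancing is this package's
choice because it is the only deterministic reading that reproduces the
totals for every seed. Across the four blocks, each (category, colour)
stimulus cell serves once as standard, once as non-target and once as target,
via a fixed rotation table.

The sequencer also surfaces one bookkeeping inconsistency in the emulated
design description: with 640 standards + 80 non-targets sharing a response
button out of 800 trials, the shared response covers 90% of trials, not the
87.5% quoted in the source narrative. The simulator reproduces the design
counts; the percentage is left as quoted elsewhere.

## 2. The signal generator

Each planted component is a fixed scalp topography (zero channel mean, unit
GFP — average-reference-consistent by construction) times a Gaussian time
course. Defaults:

| parameter | P1 | N1 | why |
|---|---|---|---|
| latency mean (ms) | 116.5 | 164.5 | midpoints of the reported 114–119 / 159–170 ranges |
| latency sd between subjects (ms) | 2 | 3 | spans the reported ranges at ±2 sd |
| Gaussian width (ms) | 22 | 26 | FWHM ≈ 50–60 ms, typical early-component width |
| base amplitude (µV) | 5 | 5 | typical posterior P1/N170 magnitudes |

Condition effects are multiplicative, configured as a wildcard table; the
defaults mirror the emulated study's observed structure (standards largest
P1, faces > butterflies at P1, blue > green for non-target P1, targets >
non-targets at N1, no N1 category effect). Components may optionally be
restricted to a condition subset (`condition =` in `component_spec()`),
which is how topographic (shape) effects are planted.

Noise is temporally white at the continuous-recording level and spatially
smoothed by a Gaussian channel-distance kernel (width 0.6 on the unit
sphere), normalized to unit marginal variance so `noise_sd` (default 8 µV)
is the per-channel trial-level sd. Between-subject amplitude scaling is
log-normal (`subject_sd = 0.15`), keeping scalings positive. Blinks are
Poisson events (12/min) with a 200 µV Gaussian transient on the EOG channel,
propagated to the scalp by a fixed front-to-back coefficient gradient
(~0.4 frontal to ~0.05 occipital). A fixed per-subject propagation vector
makes the regression-based correction exactly identifiable, which the
parameter-recovery tests exploit.

The montage is an idealized spherical layout generated from each label's
sagittal row and lateral index. It is geometrically sensible (front–back
gradients, correct neighbourhoods for the occipital analysis sites) but is
*not* a digitized standard cap; only relative geometry is ever used.

`simulate_condition_evokeds()` is a shortcut generator for statistical
property studies: it emits the subject × condition averages directly, with
noise scaled by `1/sqrt(n_trials)` and temporally band-limited at 30 Hz to
match what the full chain produces after filtering and averaging. Statistical
conclusions drawn from it (calibration, power, dissociation rates) carry over
to the full chain only insofar as preprocessing is unbiased — which the
preprocessing tests check separately.

What the generator does **not** emulate: non-stationary and 1/f noise, alpha
oscillations, channel drift or bad channels, saccades and muscle artifacts,
latency jitter within subject, overlapping responses from the rapid stream
(the evoked responses of adjacent trials do overlap in the continuous
simulation, but no deconvolution is attempted), and any real image-level
confounds. Passing tests therefore demonstrate correctness of the
*statistics*, not robustness to everything real EEG contains.

## 3. Preprocessing

* **Filter**: the emulated chain quotes a 30 Hz zero-phase low-pass with a
  48 dB/octave slope. This is realized as a 4th-order digital Butterworth
  run forward and backward: 24 dB/oct per pass, 48 dB/oct combined, zero
  phase, unit DC gain. (An 8th-order filter run twice would give 96 dB/oct
  combined — steeper than quoted — and is numerically less robust in
  transfer-function form at this normalized cutoff.) Odd-symmetric
  reflection padding of 12 cutoff periods suppresses the start-up transient;
  the realization is recorded in the recording's provenance metadata. The
  acquisition-side 0.01–200 Hz on-line filter is not re-implemented: the
  simulation is already band-limited.
* **Ocular correction**: blink maxima are detected on the EOG by a robust
  z-threshold (default 3) with a 400 ms refractory separation; segments of
  ±200 ms around each maximum enter a per-channel regression of scalp on
  EOG after the stimulus-locked average has been subtracted (so evoked
  activity does not bias the coefficients) and each pooled segment is
  demeaned. The fitted coefficient times the full EOG trace is subtracted
  everywhere. With no blinks, or an EOG variance of ~0 over the segments,
  the transform is the identity (with a warning in the latter case).
* **Epochs**: half-open windows `[−100, 500)` ms — 600 samples at 1 kHz —
  with baseline `[−100, 0)` ms. The source states the epoch but not the
  baseline; the full pre-stimulus interval is the field convention. Trials
  too close to the recording edge are dropped with reason `edge`.
* **Rejection**: any epoch exceeding ±75 µV on any scalp channel is
  flagged; the EOG channel is excluded from the screen (it legitimately
  carries hundreds of µV). Rejection runs *after* ocular correction — the
  source does not state the order; correcting first retains blink-afflicted
  trials whose neural content is recoverable, and the choice is
  configurable by reordering the calls.
* **Averaging and reference**: arithmetic mean over kept, correct trials
  per condition; evokeds are re-referenced to the common average (channel
  mean exactly zero per timepoint), which leaves GFP invariant and commutes
  with averaging — both verified as properties.

## 4. Component statistics

Peaks are found on the ROI-mean waveform (mean over the component's
electrode set): the *first* local extremum of the required polarity whose
sign matches, searching 80–160 ms for P1 and 130–210 ms for N170 — windows
that enclose the reported latency ranges with margin. Whether the original
marking was per electrode or on a pooled waveform is ambiguous; ROI-mean is
the default because a single latency per condition is what the 40 ms
mean-amplitude rule needs. A window without a qualifying extremum yields a
flagged missing result, never a silent window edge. With noisy
subject-level averages the first-peak rule has a small early bias (an early
noise ripple can qualify); on grand averages, where the rule is actually
applied, the bias is negligible, and amplitude conclusions rest on the 40 ms
mean around the peak rather than the peak sample.

The repeated-measures ANOVA computes every main effect and interaction of a
fully crossed within-subject design from orthonormal contrast projections of
the subject × cell matrix. Greenhouse–Geisser epsilon uses the projected
covariance (`tr(S)^2 / (q tr(S S))`), is exactly 1 for two-level effects,
and scales both degrees of freedom for the corrected p. Partial eta squared
satisfies `F df1 / (F df1 + df2)` identically. Electrode sets enter as
Location × Site (P1: occipital vs parieto-occipital × 3 sites) and
Hemisphere × Site (N170: left vs right × 4 sites) factors. A degenerate
design in which the dependent variable is constant across conditions reports
F = 0 rather than 0/0. Post-hoc comparisons, where needed, are paired
t-tests with Holm correction — the source names no procedure.

## 5. TANOVA

The observed statistic at each timepoint is the global dissimilarity between
the two conditions' GFP-normalized group-mean maps — GFP-normalization makes
the test shape-only, which is what "configuration divergence" means; a raw
(unnormalized) variant is available via the `dissimilarity()` building
blocks but is not the default. The null swaps each subject's condition
assignment. With `method = "auto"` the test enumerates all `2^n` relabelings
exhaustively whenever `2^n ≤ n_perm` (an exact test whose smallest
attainable p is `2^-n`, the identity relabeling counting itself) and
otherwise samples `n_perm` relabelings with add-one smoothing,
`p = (count + 1)/(n_perm + 1)`, keeping p within `[1/(n_perm+1), 1]`. The
same relabeling set is applied at every timepoint, which preserves the
temporal coherence of the p-series that window extraction relies on.
Significant windows are maximal runs of `p < alpha` lasting at least
`min_duration` (default 10 ms — the temporal criterion behind the published
windows is not stated, so this is an explicit, configurable choice).

## 6. Microstates

Segmentation is polarity-sensitive AAHC — the ERP convention, where a
P1-positive and an N1-negative map are genuinely different states — with
polarity-insensitive mode (first principal orientation templates, absolute
correlations) available for completeness. Starting from singleton clusters
(optionally GFP peaks), the cluster contributing least explained variance
(`sum (x_t . a_k)^2` over members) is dissolved and its members reassigned
to the best-correlated survivor; templates are member means renormalized to
unit GFP. Models are recorded for every K in `k_range`, and the
cross-validation criterion `sigma^2 ((C-1)/(C-1-K))^2` picks K
(undefined at `K ≥ C−1`, by construction of the predictive variance). The
source reports two P1-range and two N1-range maps but not the total K nor
the range searched; `k_range = 2:8` is the default and is always reported,
never assumed.

Back-fitting labels each timepoint with the best-correlated template (signed
correlation in polarity-sensitive mode; ties to the lowest index; zero-GFP
timepoints unassigned) and accumulates per-map GFP-weighted squared
correlation, normalized by the window's total squared GFP. Maps are named by
the median latency of their assigned training frames relative to the P1 and
N1 ranges (defaults 80–120 and 140–180 ms, the topographic windows of the
emulated analysis; the pipeline driver widens them to 80–140/140–200 ms
because the default wide components produce transition maps near 130 ms).

Whether back-fitting was originally restricted to component windows or run
over the whole epoch is not stated. The dissociation analysis restricts each
range's back-fit to its own window. This is not cosmetic: with a whole-epoch
denominator, the explained-variance fractions of the P1-range maps
mechanically decrease whenever N1-range activity grows, so an attention
effect at N1 would masquerade as an (inverted) attention effect on the
P1-range maps. Windowed normalization removes that coupling.

Explained variance indexes map *shape*; amplitude effects that leave shape
unchanged appear instead in the GFP statistics (`mean_gfp` per map, or
window-mean GFP), which is why the analysis driver reports both — mirroring
the emulated study's parallel ANOVAs on explained variance and GFP.

## 7. The dissociation study

The headline property — a category effect only in the P1 range and an
attention effect only in the N1 range — is planted with
`dissociation_recipe()`: faces and butterflies evoke topographically
distinct P1 maps of equal amplitude; targets evoke a distinct, larger N1 map
than non-targets. The recipe uses narrower time courses (FWHM ≈ 30 ms,
still within the realistic range for these components) than the default
generator. That narrowing is what makes the property's premise literally
true: with 50–60 ms wide components, the N1's rising flank reaches into the
P1 window, so an "N1-only" amplitude effect is in fact physically present in
the P1 window and any sufficiently powered test will (correctly) find it.
The dissociation criterion is evaluated over simulated datasets of 10
subjects at the default noise level, via the windowed back-fit ANOVAs: a
range shows an effect when the corresponding main effect or its interaction
with Map is significant at α = 0.05.

## 8. Problem sizes and numerical choices

The analysis scripts run 12 subjects at 250 Hz with 160 + 20 + 20 trials per
block; the statistical test suites use 5–19 subjects, 16–64 channels and
100–200 permutation datasets. These sizes are the package's choice of a
desk-scale study that keeps every Monte-Carlo band meaningful (e.g. 20 000
pooled null timepoints for the TANOVA calibration) while remaining quick to
re-run. Tolerances: oracle equivalences are asserted at 1e-8 (ANOVA) and
1e-10 (summation identities); average-reference zero means at 1e-9 µV;
exact-test p-values at 1e-12. Seeds propagate from a single master seed via
`sample.int` streams, so every artifact regenerates byte-identically
(provenance timestamps aside).

## 9. Known limitations

* The montage is idealized; no import of digitized electrode positions.
* EDF/BrainVision import is not provided — no reader for those formats is
  available in the package's dependency footprint, and the synthetic module
  plus the plain-text containers cover the package's analysis scope.
* The Gratton-style correction assumes a single blink source with linear,
  stationary propagation; it does not handle saccades or multiple ocular
  sources.
* The first-peak rule is noise-sensitive at the single-subject level (see
  §4); latency inferences should rest on grand averages.
* AAHC is deterministic but greedy; no smoothing/minimum-segment-duration
  constraint is applied by default (configurable upstream of back-fitting).
* The type-I calibration of the TANOVA is demonstrated for exchangeable
  subject-level noise; real spatially/temporally structured artifacts can
  still inflate point-wise rejections, which is why window duration (not
  single timepoints) carries the inferential weight.
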