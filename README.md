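# erpstates

Simulation and topographic analysis of visual oddball ERP experiments:
planted P1/N1 component structure, the full preprocessing chain, classical
repeated-measures component statistics, reference-free topographic statistics
(GFP, DISS, randomization TANOVA), and functional microstate segmentation
with cross-validation model selection and per-subject back-fitting.

## The scientific problem

In a visual oddball stream, rare deviant stimuli differ from frequent
standards either in colour only (non-targets, to be ignored) or in colour and
category (targets, requiring a response switch). With faces and butterflies
as the two categories and each stimulus cell rotating through every role
across blocks, the design separates *category* effects (face vs butterfly)
from *attention* effects (target vs non-target) on the early visual ERP
components: the medial-occipital P1 (~115 ms) and the lateral
occipito-temporal N1/N170 (~165 ms). The substantive question is whether
these effects occupy distinct scalp topographies — a category effect confined
to the P1 range and an attention effect confined to the N1 range — which is a
statement about map *shape*, not amplitude, and therefore needs
reference-free statistics.

Because no EEG recordings are deposited for this kind of study, the package
ships a first-class synthetic-data module: an exact sequencer for the oddball
design (640 standards per block in runs of 3/4/5, interleaved with 80 + 80
deviants), a continuous 64-channel + EOG signal generator with planted
component topographies, condition effect multipliers, blink artifacts and
spatially correlated noise, and a behavioural model (Bernoulli accuracy,
shifted log-normal RT) centred on the reported condition means. Every
downstream stage is testable against the generator's ground truth.

## The statistics at its core

* **GFP** (global field power) of an average-referenced map `u`:
  `GFP(u) = sqrt(mean(u_i^2))` — reference-free signal strength.
* **DISS** (global dissimilarity) between maps `u`, `v`:
  `DISS = sqrt(mean((u/GFP_u - v/GFP_v)^2))`, with
  `DISS^2 = 2(1 - r_spatial)`; 0 for proportional maps, 2 for polarity
  reversal.
* **TANOVA**: at each timepoint, observed DISS between the two conditions'
  GFP-normalized group means; the null distribution swaps each subject's
  condition assignment (exhaustive over the `2^n` relabelings when feasible,
  otherwise sampled with add-one smoothing `p = (c + 1)/(n_perm + 1)`).
* **Microstates**: atomize-and-agglomerate hierarchical clustering (AAHC) of
  the grand-average map series; the worst cluster (least global explained
  variance) is dissolved and its members reassigned by spatial correlation.
  Model order is chosen by the cross-validation criterion
  `sigma^2 * ((C-1)/(C-1-K))^2` over channels `C`; templates are back-fitted
  to individual ERPs by maximal spatial correlation, yielding per-map
  GFP-weighted explained variance.
* **rmANOVA**: classical fully-within repeated-measures F tests from
  orthonormal contrast projections, with Greenhouse–Geisser epsilon
  `tr(S)^2/(q * sum(S^2))`, corrected p-values, and partial eta squared
  `F*df1/(F*df1 + df2)`.

## Worked example

```r
library(erpstates)

design <- design_config()           # 640 standards + 80/80 deviants per block
sim <- sim_config(n_subjects = 6, sampling_rate = 250, noise_sd = 8)
study <- simulate_condition_evokeds(design, sim, n_trials = 60, seed = 42)

meas <- measure_components(study$evokeds, list(p1_component()), study$conditions)
rm_anova(meas, dv = "mean_amplitude", subject = "subject",
         within = c("role", "category", "colour"))
#>   effect        df_num df_den       F      p_gg partial_eta_sq
#> 1 role               1      5  55.0   0.000703          0.917
#> 2 category           1      5 188.    0.0000369         0.974
#> 3 role:category      1      5   0.490 0.515             0.0892
```

The planted effects surface exactly where they were planted: the category
multiplier on P1 gives a large Category main effect, the non-target > target
P1 modulation a Deviant (role) effect, and no interaction. The paired TANOVA
on deviant faces vs butterflies localizes the topographic difference to the
P1–N1 transition:

```r
dev <- study$conditions
faces <- lapply(study$evokeds, function(e)
  rereference_average(grand_average(e[dev$condition_id[dev$category == "face"]])))
butterflies <- lapply(study$evokeds, function(e)
  rereference_average(grand_average(e[dev$condition_id[dev$category == "butterfly"]])))
tanova(faces, butterflies, n_perm = 1000, seed = 1)
#> <tanova_result: 150 timepoints, exact test (64 relabelings), alpha=0.05>
#>   significant: [116, 160) ms
```

## The analysis workflow

The numbered scripts under `analysis/` run the full study at a reduced scale
(12 subjects, 250 Hz, 160 + 20 + 20 trials per block; see
`analysis/config.R`) and write their tables under `results/`:

1. `01_simulate.R` — design arithmetic, trial sequences, behaviour, montage.
2. `02_preprocess.R` — 30 Hz zero-phase low-pass, EOG blink regression,
   epoching with baseline, ±75 µV rejection, per-condition averages with
   common-average reference.
3. `03_components.R` — P1/N170 peaks, 40 ms mean amplitudes, the five-factor
   deviant ANOVAs, planned contrasts, behavioural ANOVAs.
4. `04_tanova.R` — point-wise randomization TANOVA of deviant faces vs
   butterflies with significant-window extraction.
5. `05_microstates.R` — AAHC segmentation of the deviant grand averages,
   CV-based model selection, map naming by latency range, back-fit
   explained-variance ANOVAs, and window-mean GFP ANOVAs.

Run them in order from the repository root, e.g.
`Rscript analysis/01_simulate.R`.

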