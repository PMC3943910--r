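---
title: "Methods: breath VOC biomarker discovery with breathmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: breath VOC biomarker discovery with breathmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breathmark)
```

## The measurement and the statistical problem

A point-of-care breath test couples a gas chromatograph to a surface
acoustic wave (SAW) detector. The detector responds only to the mass of
eluting volatile organic compounds (VOCs), producing a dense trace of
detector response versus retention time (about 3013 scans per minute); it
carries no chemical-structure information. Each test collects two traces
per subject: alveolar breath and ambient room air. Because inspired room
air contributes VOCs to breath, the informative quantity is the **alveolar
gradient** — abundance in breath minus abundance in room air — computed
here per fixed-width segment of the scan axis. Positive gradients suggest
endogenous production; negative gradients suggest net uptake or clearance.

With thousands of candidate segments and modest cohorts, the central risk
is selecting spurious biomarkers. The pipeline therefore calibrates
selection against a Monte-Carlo permutation null rather than trusting raw
ranking.

## Pipeline

1. **Segmentation and gradients.** Chromatograms are tiled into half-open
   segments `[start, end)` of `width_scans` scans (0-based scan
   coordinates; the last segment may be short). Within a segment, breath
   and air responses are aggregated (`sum` by default, `mean` optional) and
   subtracted. No baseline correction or peak picking is applied — the
   method operates on raw segmented signal differences.
2. **Candidate ranking.** Each segment's gradients are compared between the
   disease and control groups by the C-statistic (ROC AUC, Mann-Whitney
   pair counting with half-credit for ties). Ranking uses the *folded* AUC
   `max(AUC, 1 - AUC)`, because both elevated and depressed gradients are
   candidate biomarkers; the direction is retained for classification.
3. **Permutation null.** Subjects are randomly reassigned between the two
   groups (preserving group sizes) `n_reps = 40` times; each permutation
   rescores every segment. One permutation scores all segments, so the
   resulting "random" curve is internally coherent.
4. **Rank-abundance selection.** On an accuracy grid over `[0.5, 1]`
   (step 0.005), the "correct" curve counts segments whose folded AUC
   reaches each level under the true labels; the "random" curve is the mean
   count across permutations. The selection threshold is the smallest grid
   accuracy at which the random curve declines below one expected segment;
   all segments at or above it are selected, and the vertical distance
   between curves there is the excess (beyond-chance) biomarker count. If
   the random curve never falls below 1, the selection is empty with a
   warning.
5. **Adjacent-signal merging.** A single compound spreads over adjacent
   detector scans, so runs of selected segments separated by at most
   `max_gap = 1` unselected segment merge into one biomarker peak,
   represented by the segment with the highest folded AUC (earliest on
   ties).
6. **Weighted digital analysis (WDA).** The classifier sums, over merged
   biomarkers, `weight * digital`, where `digital` is 1 when the subject's
   gradient lies on the disease side of a marker-specific cutoff. The
   literature cites WDA without formulas, so this package fixes a
   documented reconstruction: the cutoff maximises the Youden index
   (sensitivity + specificity − 1) of the single marker over midpoints of
   the sorted training gradients; the disease side follows the sign of
   `AUC − 0.5` (ties count as disease-higher); the weight is the marker's
   Gini coefficient `2·foldedAUC − 1`, hence in `[0, 1]`. A divergent
   weight definition would be a one-line change in `fit_rule()`.
7. **Validation.** The resubstitution ROC scores the training data; the
   operating point maximises sensitivity + specificity. Leave-one-out (LOO)
   cross-validation removes one subject at a time and re-derives the
   *entire* algorithm — permutation null, selection, merging, and WDA
   fitting — on the remainder before scoring the held-out subject; all
   out-of-sample scores pool into one ROC.
8. **Screening projection.** A validated (sensitivity, specificity) pair is
   projected onto a screened population at a given prevalence: expected
   TP/FP/FN/TN counts, PPV/NPV before and after testing, and enrichment
   factors (post-test over pre-test value).

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `width_scans` | 30 | scans | not fixed by the instrument method; ~0.6 s at 3013 scans/min, so a typical peak spans 1–3 segments |
| `aggregate` | `sum` | — | area-like abundance; `mean` available, recorded in all metadata |
| `n_reps` | 40 | permutations | the Monte-Carlo protocol of the instrument method |
| `grid_step` | 0.005 | folded AUC | fine enough that threshold discretisation moves selection by < 1 grid cell on the test fixtures |
| `max_gap` | 1 | segments | "closely adjacent" signals merge; no number is fixed by the method |
| `seed` | — | — | all randomness (permutations, folds) derives deterministically from it |

## Numerical and tie-breaking conventions

- The C-statistic is computed from midranks, which reproduces brute-force
  pair counting (wins + ties/2) exactly in floating point; the trapezoidal
  ROC AUC agrees with it to one ulp.
- Curve thresholding uses a `1e-9` guard so a folded AUC algebraically equal
  to a grid value is never lost to float rounding.
- Ties: folded-AUC ranking breaks toward the lower segment index; the
  AUC = 0.5 direction is disease-higher; cutoff ties resolve to the smallest
  cutoff; operating-point ties resolve to higher sensitivity, then lower
  threshold; a gradient exactly at a WDA cutoff counts as disease-like, and
  a score exactly at the decision threshold is positive.
- Degenerate inputs fail loudly: mismatched breath/air scan counts, unknown
  labels, single-class cohorts, out-of-ladder retention times. Two
  deliberate soft spots: an empty selection is a warning (tiny cohorts with
  many segments genuinely cannot beat the below-one rule), and an empty LOO
  fold scores its held-out subject 0 with a warning so one pathological fold
  cannot crash a cross-validation.
- Screening counts are rounded half-up to whole people *before* predictive
  values are computed, matching published screening projections;
  `exact = TRUE` disables this. Enrichment factors divide full-precision
  post-test values by pre-test values — rounding the post-test percentage
  first would visibly change the third decimal.
- LOO fold seeds are hashed from `(master seed, subject id)`, so fold
  results do not depend on subject order.

## The synthetic cohort generator

Real GC-SAW breath chromatograms from the motivating clinical setting are
not publicly deposited, so the package ships a generator
([`sim_config()`]/[`generate_cohort()`]) that emulates exactly the
structure the analysis assumes, with every stated default chosen once:

- Gaussian peaks (sigma 12 scans) at cohort-shared positions on a flat
  baseline (level 10) with white detector noise (SD 1, detector units);
  3013 scans per trace (one minute of elution).
- Log-normal peak amplitudes: cohort-level medians around 50 detector units
  (between-peak log-SD 0.5), between-subject log-SD 0.25. Abundances are
  positive and right-skewed; the disease effect shifts informative peaks'
  log-amplitudes by `effect_size × 0.25` (direction fixed per peak), so no
  effect size can produce negative abundances.
- Room air shares the peak positions at `air_fraction = 0.4` of each
  subject's amplitudes, with independent noise — so subtracting air removes
  a genuinely shared ambient background, which is the rationale for the
  alveolar gradient.
- A single cohort seed drives everything; per-subject streams derive from
  `(seed, subject id)`.

What the generator does **not** emulate: chromatographic tailing and
co-elution, retention-time drift between days, heteroscedastic detector
response, and instrument-specific baseline behaviour. A green test on
synthetic cohorts therefore establishes that the *statistical machinery*
behaves as claimed (type-I control of the selection rule, recovery of
planted effects, absence of optimism leaks in LOO) — not that the breath
test's published clinical accuracies are reproduced, which would require
the original chromatograms.

## Design choices that were genuinely open

- **Segment width** is unstated in the source method; it is configurable
  with a documented default (30 scans) rather than hidden.
- **Disjoint segments**: the phrase "a time series of alveolar gradients"
  supports non-overlapping tiling; overlap is not implemented.
- **Shared permutations**: whether the 40 random assignments were shared
  across segments or redrawn per segment is unstated; they are shared here
  so the random curve is a coherent function of one label permutation. An
  alternative per-segment z-score test (correct AUC versus permutation
  spread) is noted but not the primary rule; the curve-based below-one rule
  is the operationally described procedure.
- **"Repeated leave-one-out bootstrap"** is implemented as exhaustive LOO
  with full per-fold re-derivation — the operational description of the
  procedure — with Monte-Carlo spread available by repeating over master
  seeds.
- **WDA formulas** are a reconstruction (see above) and flagged as such.

## Worked example

```{r example, eval = FALSE}
coh <- generate_cohort(sim_config(seed = 11))
report <- run_pipeline(coh$records, pipeline_config(seed = 11))
print(report)
project_screening(0.818, 0.700, prevalence = 0.00395, population = 1e6)
```

## Known limitations

- The WDA weighting is a documented reconstruction of a method cited
  without formulas; published clinical discriminant values need not be
  reproduced exactly even given the original data.
- The below-one selection rule controls the *expected* false-biomarker
  count near one; it is not an FDR procedure.
- No peak deconvolution or chemical identification: biomarkers are
  chromatographic segments. The Kovats index utility
  ([`kovats_index()`]) supports relating segment retention times to
  n-alkane standards, nothing more.
- Proprietary instrument file formats are out of scope; chromatograms are
  read from plain two-column CSV.
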