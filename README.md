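# breathmark

Biomarker discovery and classification for point-of-care breath
volatolomics with GC-SAW detection (a gas chromatograph coupled to a
surface acoustic wave detector).

Breath tests of this kind collect, for each subject, one chromatogram of
exhaled alveolar breath and one of ambient room air. The detector responds
to the mass of eluting volatile organic compounds (VOCs) at ~3013 scans per
minute but carries no chemical-structure information, so analysis operates
on the raw signal: chromatograms are tiled into fixed-width segments and
each segment's **alveolar gradient** — detector response in breath minus
the corresponding response in room air — becomes one candidate biomarker.
The statistical challenge is that a modest cohort faces thousands of
candidate segments, so naive ranking finds "biomarkers" in pure noise.

`breathmark` implements the full pipeline:

- **Discovery.** Each segment is scored by its C-statistic
  $C = \Pr(X_\text{disease} > X_\text{control}) + \tfrac12 \Pr(\text{tie})$
  (the ROC AUC), folded as $\max(C, 1-C)$ so that both elevated and
  depressed gradients count. A Monte-Carlo null — 40 random reassignments of
  diagnosis, each rescoring every segment — yields "correct" vs "random"
  rank-abundance curves: the number of candidates exceeding each accuracy
  level under true vs permuted labels. Where the random curve declines
  below one expected segment, everything above that accuracy is selected,
  and runs of adjacent selected segments (signals of a single compound
  spread over neighbouring detector scans) merge into biomarker peaks.
- **Classification.** A weighted digital analysis (WDA) classifier sums,
  over biomarkers, $w_i \cdot d_i$ with $d_i \in \{0,1\}$ indicating the
  disease side of a Youden-optimal cutoff and $w_i = 2\,\mathrm{AUC}_i - 1$.
- **Validation.** Exhaustive leave-one-out cross-validation re-derives the
  entire algorithm (null, selection, merging, WDA) per fold; pooled
  out-of-sample scores give the honest ROC, and the operating point
  maximises sensitivity + specificity.
- **Screening projection.** Expected TP/FP/FN/TN counts, PPV/NPV and
  enrichment factors ($\text{post-test}/\text{pre-test}$ value) for a
  screened population at a given prevalence.
- **Synthetic cohorts.** A seeded generator plants informative Gaussian
  peaks over a shared room-air background so every stage is testable
  without instrument data (no real chromatograms ship with the package).

See the methods vignette (`vignettes/breathmark-methods.Rmd`) for the
model, conventions and design decisions — including that the WDA weighting
is a documented reconstruction of a method cited without formulas.

## Worked example

```r
library(breathmark)

# a synthetic cohort: 40/40 subjects, 5 informative of 30 VOC peaks
coh    <- generate_cohort(sim_config(seed = 11))
report <- run_pipeline(coh$records, pipeline_config(seed = 11))
print(report)
#> <analysis_report> 80 subjects (40 disease / 40 control), 101 segments
#>   discovery: threshold 0.67, 14 selected segment(s), 5 merged peak(s), excess 13.12
#>   resubstitution: AUC 0.996; sens 1.000 / spec 0.925
#>   leave-one-out:  AUC 0.990; sens 1.000 / spec 0.925
```

The discovery stage found that at folded AUC 0.67 the permutation null
expects fewer than one surviving segment; 14 segments survive under the
true labels (an excess of ~13 beyond chance) and merge into 5 biomarker
peaks — matching the 5 planted informative peaks. The leave-one-out AUC
(0.990) sits just below the resubstitution AUC (0.996), the expected mild
optimism of in-sample scoring.

Projecting a test with 81.8% sensitivity and 70.0% specificity onto one
million screened women at a prevalence of 3.95 cancers per 1000:

```r
project_screening(0.818, 0.700, prevalence = 0.00395, population = 1e6)
#> Screening 1,000,000 people, prevalence 0.395%, sensitivity 81.8%, specificity 70.0%
#>                  disease+        disease-
#>   test positive  TP = 3,231      FP = 298,815
#>   test negative  FN = 719        TN = 697,235
#>   PPV pre/post: 0.395% / 1.070%  (enrichment 2.708)
#>   NPV pre/post: 99.605% / 99.897%  (enrichment 1.003)
```

A positive breath test enriches the screened population ~2.7-fold for
disease risk; a negative test leaves a 99.897% probability of being
disease-free.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the pipeline end-to-end from scratch: it generates a synthetic
cohort under the package's stated simulation world, runs discovery, WDA
fitting and leave-one-out validation, chains the validated operating point
into a population screening projection, and writes the results JSON to
`--out`. All randomness derives from `--seed`.
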