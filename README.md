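# cometbag

Alzheimer's disease (AD) typically presents with greater medial temporal
lobe (MTL) atrophy than cortical atrophy, but a substantial minority of
patients — often younger at onset — show the reverse, cortical-predominant
pattern. `cometbag` implements an analysis pipeline for testing whether
*biological* age, estimated from blood DNA methylation with epigenetic
clocks, modulates where a patient falls on this cortical-to-MTL spectrum
beyond chronological age alone.

The pipeline covers, as reusable, tested R functions:

- **Cohort classification** — amyloid status from the nearest PET or CSF
  measure within 2 years of baseline MRI (florbetapir SUVR ≥ 1.1,
  PiB SUVR ≥ 1.47, CSF Aβ-42 < 980 pg/mL; PET preferred over CSF), and
  assignment to an amyloid-negative cognitively unimpaired (CU) reference
  cohort vs an amyloid-positive symptomatic (MCI/dementia) cohort.
- **Biological age gap (BAG)** — linear epigenetic clocks applied to
  methylation beta values; per-clock BAG as the residual of regressing
  clock-predicted age on chronological age; averaging across clocks;
  stratification into accelerated / neutral / decelerated groups at
  ±0.5 SD.
- **Harmonization** — reference-fitted parametric empirical-Bayes ComBat:
  scanner-field-strength batch effects are estimated on the CU reference
  and removed from all subjects at the ROI level, preserving age, sex and
  diagnosis effects.
- **CoMeT** — the Cortico-Medial Temporal index. Cortical (18 bilateral
  DKT thickness ROIs) and MTL (entorhinal/parahippocampal thickness,
  hippocampal/amygdalar volume) composites are converted to w-scores
  against the CU reference (age + sex for thickness, age + ICV for
  volume), and

  ```
  CoMeT = w_cortical − w_MTL
  ```

  Lower CoMeT = relatively greater cortical involvement (less typical
  presentation); higher CoMeT = relatively greater MTL involvement.
- **Statistics** — Pearson correlation, Wilcoxon rank-sum (exact
  enumeration for small tie-free samples, tie-corrected normal
  approximation otherwise) with rank-biserial effect sizes, chi-squared
  association, and cohort descriptives.
- **Synthetic cohort generator** — a first-class module emitting an
  ADNI-like cohort with planted, recorded ground truth: covariate-driven
  ROI measures with two-scanner batch effects, diagnosis-dependent
  atrophy, a latent per-participant BAG coupled to the cortical-minus-MTL
  atrophy contrast at a configurable correlation, and methylation betas
  constructed so that each clock predicts chronological age + latent
  BAG + noise. Real cohort data are access-controlled; every stage is
  testable against this generator's truth record.

## Worked example

Run the whole pipeline on a synthetic cohort at the published cohort
scale (329 CU / 378 MCI / 304 dementia), either from R:

```r
library(cometbag)
cfg <- pipeline_config(synthetic = synthetic_config(seed = 7), seed = 7)
res <- run_pipeline(cfg, outdir = "comet_run")
```

or from the shell with the bundled front-end:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "comet-bioage", package = "cometbag"))') \
  run-all --seed 7 --outdir comet_run
```

`comet_run/summary.txt` then reads (abridged):

```
pearson_comet_bag                [symptomatic]  n=682, r=0.136, p=0.0003651
wilcoxon_comet_decel_vs_accel    [symptomatic]  n=(210,216), W=40087, rank-biserial=-0.209, p=0.0001863
pearson_comet_bag                [CU]  n=329, r=0.007, p=0.8967

CU mean w-scores: cortical -1.414e-14, MTL 3.866e-16, CoMeT -1.463e-14
```

Reading these numbers: in the symptomatic cohort CoMeT correlates
positively with BAG (biologically *older* patients sit toward the
MTL-predominant, typical end), the decelerated group has lower CoMeT
than the accelerated group (negative rank-biserial under the fixed
group order decelerated-vs-accelerated), the CU cohort shows no such
association, and the CU composite w-scores average zero by construction
of the reference regression. The default generator plants a latent
BAG–atrophy-contrast coupling of 0.15, so the recovered r ≈ 0.14 is the
planted signal, not noise.

The same run directory contains every intermediate table
(`cohort_labels.csv`, `bag.csv`, `roi_harmonized.csv`, `comet.csv`,
`analysis.csv`, `descriptives.csv`) and a provenance manifest with
parameters, seeds and file hashes; an identical config + seed reproduces
the directory byte for byte.

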