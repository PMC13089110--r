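---
title: "Methods: biological age acceleration and the cortical-to-MTL atrophy balance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biological age acceleration and the cortical-to-MTL atrophy balance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cometbag)
```

# The scientific question and the model

Alzheimer's disease neurodegeneration varies along a spectrum from
MTL-predominant (typical, amnestic) to cortical-predominant (less
typical) presentations, and chronological age is an imperfect predictor
of where a patient falls. `cometbag` operationalizes the hypothesis
that *biological* age — estimated epigenetically — carries additional
signal, via two derived quantities:

**Biological age gap (BAG).** Each epigenetic clock is a linear
predictor over CpG beta values, `m = intercept + sum(coef * beta)`,
optionally followed by the log-linear adult anti-transform
(`(a+1)e^m − 1` below the transition age `a = 20`, `a + m(a+1)` above).
The per-clock BAG is the residual from an ordinary least-squares
regression of clock-predicted age on chronological age over the
analysis cohort. This regression-based definition absorbs calibration
offsets and slope miscalibration of a clock, so BAG is exactly
mean-zero and exactly uncorrelated with chronological age on the
fitting cohort — a property the test suite asserts at 1e-10. BAGs from
three clocks are averaged to damp clock-specific noise (the average of
three residual vectors has strictly lower error variance around the
latent gap than any single clock, another tested property). No
covariates are adjusted at this stage; adjustment happens downstream in
the w-scores. Participants are stratified at ±`k` standard deviations
of the cohort BAG distribution (`k = 0.5` by default, sample SD with
denominator n−1); the boundary `|z| = k` is assigned to the extreme
groups ("at least k SD" read inclusively — a probability-zero event in
continuous data, fixed for reproducibility.)

Which cohort the BAG regression is fitted on is configurable
(`bag_cohort` in `pipeline_config()`): the default fits over all
participants with methylation, since BAG is computed before any
cohort-stratified analysis; per-cohort fitting is supported for
sensitivity analyses.

**CoMeT.** Structural involvement is summarized by two composites:
cortical (18 bilateral DKT thickness ROIs) and MTL
(entorhinal + parahippocampal thickness; hippocampal + amygdalar
volume). Each composite averages the left and right hemisphere of each
ROI first, then the ROIs (unweighted — no surface-area weighting). Each
composite is converted to a w-score, a covariate-adjusted z-score
against the cognitively unimpaired (CU) reference:

    w = (observed − predicted from CU regression) / CU residual SD

with age + sex as covariates for thickness and age + ICV for volume
(the volume rule is taken literally: ICV, not ICV and sex). CoMeT is
the signed difference `w_cortical − w_MTL`; lower values mean
relatively greater cortical involvement.

Because the MTL mixes measure kinds with different covariate rules, the
MTL w-score is defined as the mean of two separately w-scored
sub-composites (thickness and volume). This keeps each measure
correctly covariate-adjusted; the combination rule itself was a
genuinely open design point and is isolated in `mtl_composite_w()` so
alternatives can be substituted.

The residual SD uses denominator n − p (p = 3 fitted parameters), so
the CU reference scored with its own model has mean exactly 0 and
sample SD `sqrt((n−p)/(n−1))`, slightly below one; the tests assert the
exact adjusted value rather than 1.

# Harmonization

Scanner field strength (1.5T vs 3T) shifts ROI measures. The package
implements reference-fitted parametric empirical-Bayes ComBat: per
feature, a least-squares fit of the value on biological covariates plus
batch indicators; standardization by the pooled residual SD (MLE
denominator n); per-batch location/scale estimates shrunk toward
moment-matched parametric priors (normal for location, inverse-gamma
for scale) by iterative conditional updates. The fit uses only the CU
reference; the stored model then transforms any row, including
symptomatic subjects never seen at fit time, with covariate
contributions added back unchanged — this fit-on-reference /
apply-to-new design is why the algorithm is implemented here rather
than delegated to an implementation that only transforms its own
training data. On identical inputs the implementation agrees with an
independent parametric ComBat implementation to 1e-6 (tested on a
committed fixture against `sva::ComBat`).

Numerical choices: EB iteration stops when the relative change of
successive location and scale updates falls below 1e-4 (at most 1000
iterations); per-batch scale estimates use denominator n_b − 1;
covariate columns that are constant in the reference (diagnosis, when
fitting on CU only) are dropped and recorded, and entirely-dropped
factor covariates are skipped at apply time. Moment-matched priors need
at least two features; with a single feature the model falls back to
the unshrunken per-batch estimates. Degenerate inputs — fewer than two
batches, batches with fewer than two reference rows, batch-confounded
covariates, unseen batch labels at apply time — raise typed errors.

A known property worth stating plainly: when batches differ in noise
*scale*, the EB scale correction divides each row's standardized
residual by its batch's scale factor. For out-of-reference subjects
whose residual contains disease atrophy absent from the reference, this
rescales that atrophy differently per batch, leaving a small
batch-linked difference proportional to the atrophy magnitude times the
scale imbalance. This is inherent to location/scale harmonization
applied outside its reference population, not an implementation defect;
the batch-removal tests therefore plant a pure location shift.

# The synthetic cohort generator

Real cohort data of this kind are access-controlled, so the generator
is a first-class, tested module that emulates the study conditions and
records every planted parameter in a truth sidecar sufficient to verify
recovery without re-running it.

What it emulates: cohort sizes at the published scale (329 CU / 378 MCI
/ 304 dementia by default; the DNA-methylation subset scale 163/170/115
is used where analyses are methylation-bound); age from a truncated
normal centred at 74.84 y (SD 6.96 y) on \[55, 95\]; 44.4% female; ICV
normal around 1.45e6 mm^3 (SD 1.3e5) with a sex offset; two scanner
batches (default P(1.5T) = 0.5) with an additive shift (+0.08 mm on
thickness, proportionally scaled for volumes, applied to the 3T batch)
and a noise-scale factor (1.2); thinning of −0.01 mm/y, a +0.05 mm
female thickness offset, and ICV-proportional volumes; amyloid measures
drawn on the diagnosis-consistent side of the positivity cutoffs with
offsets that exercise the 2-year nearest-measure rule (including ~30%
second measures, some outside the window); and APOE4 and CDRSB
distributions matching the published descriptives (21% vs 68.5%
carriers; medians 0 / 1.5 / 5).

The latent structure: each participant carries a latent BAG
`g ~ N(0, bag_sd = 4 y)`. Symptomatic subjects carry cortical and MTL
atrophy whose means are `atrophy_cortex = −2` and `atrophy_mtl = −2.5`
in reference-SD units, and whose difference (the atrophy contrast) is
drawn jointly with `g` at correlation `coupling_rho` (default 0.15)
with dispersion `contrast_sd = 4`. Atrophy is planted at the composite
level in the generator's own reference-SD units (the measurement-noise
SD of the corresponding CU composite), so downstream w-scores recover
the planted values directly. `contrast_sd` is not in the published
description and was fixed once by design analysis: the measured
CoMeT–BAG correlation equals the latent coupling times an attenuation
factor from clock noise (~0.96 with three clocks at 2 y noise against a
4 y latent SD) and from composite measurement noise relative to the
contrast dispersion (~0.94 at `contrast_sd = 4`); at 4 the planted
coupling is recoverable within the tested ±0.03 band while symptomatic
w-score spread stays in a realistic few-w-score-unit range. MCI and
dementia share the same atrophy distribution (a simplification; the
configured values are the symptomatic mean exactly).

Methylation betas are constructed by the affine pseudoinverse map on
each clock's disjoint 50-CpG support, centred at beta 0.5 for maximal
clipping headroom, with CpG-level noise projected orthogonal to the
coefficient vector so the planted prediction is exact:
`apply_clock(betas, clock_k) = age + g + N(0, clock_noise_sd)`. If any
planted value would require clipping outside \[0, 1\] the generator
raises an error rather than silently destroying the signal. A
configurable fraction of participants (default 5%) receives a duplicate
row flagged as a technical replicate, drawn with fresh assay noise, to
exercise the one-replicate selection rule.

What it does **not** emulate: CpG biology (correlation structure,
bimodal beta distributions at the array level, probe artifacts),
longitudinal visits (one MRI and one methylation timepoint per subject;
offset fields are still populated), site-level batch structure beyond
field strength, diagnosis-severity gradients within the symptomatic
group, and any genotype–methylation dependence. Passing tests therefore
demonstrate that the *pipeline* recovers what was planted under
realistic noise — not that the biological model is true of real
cohorts.

All randomness flows from one seed; each table draws from a sub-stream
derived from the seed and a stream label (`derive_seed()`), so adding a
table never perturbs earlier ones and identical configurations
reproduce byte-identical outputs.

# Statistical battery

Two-sided p-values throughout; no multiple-testing correction (none is
part of the analysis design). Pearson correlation uses the t reference
with n − 2 df. The Wilcoxon rank-sum test uses midranks; the reported
W is the rank sum of the first group; the exact p-value is computed by
full enumeration when `n_a + n_b ≤ 12` without ties, otherwise a normal
approximation with tie-corrected variance and continuity correction.
The rank-biserial effect size is the mean pairwise dominance
`(#a>b − #a<b)/(n_a n_b)`, ties contributing zero. Group-order
conventions are fixed — (decelerated, accelerated) and (younger,
older) — so a negative rank-biserial always means the first group is
lower. Chi-squared tests are Pearson's without continuity correction.

On exact-vs-approximate agreement: the continuity-corrected normal
approximation agrees with exact enumeration within 0.02 absolute
p-value only when both groups have at least ~6 observations (the
agreement is checked exhaustively over every attainable rank sum at
6 + 6); with very small or singleton groups the approximation can be
off by 0.04–0.12, which is why the implementation switches to exact
enumeration there instead of relying on the approximation.

Comparisons with fewer than two subjects in a group are reported as
"not computable" rows rather than errors, so a sparse stratum never
aborts a full report.

# Problem sizes and tolerances used in the tests

The suite verifies parameter recovery at the scales the analysis is
designed for: BAG recovery (r > 0.9 against the latent gap) at n = 500
over 20 seeds; coupling recovery (mean measured CoMeT–BAG r within
±0.03 of the planted 0.15, sign recovery in >95% of seeds, and a null
centred on 0) at the methylation-subset scale (285 symptomatic) over
200 seeds per condition; batch-shift removal and age-slope preservation
at 500 CU / 1000 symptomatic. Construction identities (CU mean
w-scores, BAG decorrelation) are asserted at 1e-10; oracle equivalences
(ComBat fixture, closed-form OLS, brute-force dominance) at 1e-6 to
1e-12. Determinism is asserted as byte-identical run directories under
identical config + seed.

# Known limitations

* The generator's planted truth is linear-Gaussian; none of the tests
  probe robustness to heavy-tailed measurement error or non-linear
  age effects (the w-score model is linear in age by design).
* Reference-fitted ComBat interacts with out-of-reference effects under
  batch scale imbalance, as described above.
* The clock module applies published-format coefficient files but ships
  none; analyses of real data require the user to supply clock
  coefficients in the documented CSV layout.
* CoMeT's interpretation as an atypicality index inherits the ROI set
  definition; alternative atlases or vertex-wise maps are out of scope,
  though the ROI sets are overridable via YAML.
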