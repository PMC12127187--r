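---
title: "Methods: simulating and evaluating synergistic ophthalmic screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and evaluating synergistic ophthalmic screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synopht)
```

# The evaluation problem

Screening programmes increasingly pair an automated grader with an early
career clinician: the automated tool estimates the vertical cup-to-disc
ratio (CDR) from fundus photographs and flags retinal disease, the
clinician examines the patient in person, and a *synergistic* referral
rule calls a patient positive when **either** assessor is positive. This
package provides everything needed to evaluate such a set-up end to end —
with a simulator standing in for patient data, exact tools for working
with published summary panels, and the dual-threshold ROC analysis that a
logical-OR combination of two continuous scores requires.

The design target throughout is a tertiary-care evaluation in which
three expert annotators define a per-eye ground-truth CDR (their mean),
a patient is a *glaucoma suspect* when the maximum CDR across eyes is at
least 0.6 or the inter-eye difference exceeds 0.2, the AI operating rule
thresholds the patient-level maximum estimated CDR at 0.55, and retinal
findings are grouped into risk-of-vision-loss tiers (none / mild /
medium / high).

# The cohort simulator

`simulate_cohort()` draws, for each patient:

* **True CDR per eye** from a truncated bivariate normal:
  mean 0.45, SD 0.12, truncated to [0.10, 0.95], inter-eye correlation
  0.85. The location and scale are chosen so that the 0.55/0.6 decision
  thresholds sit in the upper tail and the ground-truth suspect rule
  fires for a minority of patients (about one in five), matching the
  class balance such screening cohorts exhibit. The paired truncation is
  sampled by joint rejection (the truncation mass at the defaults is
  about 0.2%, so the loop terminates almost immediately).
* **Expert annotations** as truth plus independent per-annotator noise.
  The three noise SDs (0.0783, 0.1347, 0.0230) are not free knobs: they
  are the unique solution of the one-factor model
  $r_{ij} = \lambda_i \lambda_j$, $\lambda_i =
  \sigma_T / \sqrt{\sigma_T^2 + \sigma_i^2}$, inverted analytically from
  the three target pairwise expert correlations (0.553, 0.820, 0.650).
  The middle annotator is deliberately the noisy one.
* **AI estimates** as truth plus a constant bias of −0.04 and noise with
  SD 0.0212, calibrated in closed form so that the mean absolute error
  against the expert-mean ground truth is 0.056 (using the folded-normal
  mean of the difference distribution).
* **Resident estimates** with a proportional bias:
  $\mathrm{res} = 0.5 + 1.2\,(T - 0.5) - 0.0301 + \varepsilon$,
  $\sigma_\varepsilon = 0.1112$. The slope above 1 reproduces
  underestimation of small CDRs and overestimation of large ones with a
  single parameter; the intercept makes the total bias against ground
  truth −0.04 and the noise SD makes the MAE 0.105.
* **Gradability** from a single patient-level uniform with nested
  thresholds, so that AI-gradable ⊆ expert-gradable ⊆ resident-assessed
  with marginal rates 61.6% / 78.6% / 95.4%. Nesting reflects the
  observed ordering of these rates; an independent-draws mode is
  available (`nested_gradability = FALSE`). Estimates are missing
  exactly where the flag is `FALSE`.
* **Disease tier** from the prevalence vector (239, 75, 40, 41)/395 and
  binary disease calls per rater drawn at per-tier operating points.
  The default operating points are the exact cell fractions of the
  reconstructed retinal panel (see below): e.g. AI sensitivity 46/75
  (mild), 32/40 (medium), 41/41 (high), specificity 229/239. Calls are
  conditionally independent between raters given the tier, because the
  published panel does not identify their joint distribution; the
  OR-combination's sensitivity in simulated cohorts is therefore a
  property (it must dominate both components), not a value target.
* **Age, symptoms and cataract status** for the media-opacity
  comparison: truncated-normal age (59.1 ± 15.7, bounded to [18, 95]),
  independent symptom Bernoullis, and a cataract probability that rises
  with age and with failed image quality.

Each field group consumes its own RNG substream spawned from the master
seed, so cohorts are bit-identical under a fixed `(config, seed)` and
adding a new field group cannot perturb existing draws.

## What the simulator does and does not claim

A calibration caveat worth stating plainly: under the shared-truth
additive-noise model, the published error and correlation anchors are
not jointly attainable. With the expert-mean noise SD fixed at 0.0525 by
the expert calibration, an AI estimator with MAE 0.056 *necessarily*
correlates with the ground truth at about 0.90 — the published 0.728
would require either a much larger AI error or a much narrower true-CDR
distribution than the suspect-prevalence structure allows. The defaults
are calibrated to the error/bias anchors (MAE and −0.04 bias), and
`implied_agreement()` exposes the closed-form model-implied bias, MAE
and correlation for any configuration; parameter-recovery tests compare
empirical cohorts against those implied values. Real data exhibit
heteroscedastic, truth-correlated errors that this simulator does not
model — so passing recovery tests demonstrates internal consistency of
the pipeline, not fidelity to any particular patient population.

The simulator likewise does not model dependence between disease status
and gradability (real ungradable images are enriched for retinal
detachment, vitreous haemorrhage and cataract), beyond the
`ungradable_extra_sd` knob used by the quality ablation; and it draws
exactly two eyes per patient.

# CDR geometry from segmentation masks

`compute_cdr()` reduces a binary disc/cup mask pair to a vertical
cup-to-disc ratio the way a segmentation-based pipeline does after its
U-Nets: take the **largest 4-connected component** of each mask, measure
the **vertical extent** (max row − min row + 1, robust to interior holes
from imperfect masks), intersect the cup with the disc first (anatomical
containment — segmentation spill can otherwise produce CDR > 1), and
divide. ROI extraction (`extract_roi()`) uses 0-based half-open boxes;
`rescale_to_frame()` maps measurements from a resized ROI back to
original-frame pixels with half-up rounding. These conventions (extent
vs row count, padding, rounding) are module decisions — the measurement
itself is only specified as "the ratio of the heights" — and they are
fixed and documented so they are testable.

`synthesize_mask_pair()` rasterizes concentric axis-aligned ellipses
through pixel centers, so a disc with vertical semi-axis $b$ spans
exactly $2b + 1$ rows and the round-trip error of the target CDR is
bounded by $2/(2b+1)$ — the bound the geometry tests assert across the
full grid of targets.

# Decision rules

* `glaucoma_suspect()`: max available CDR ≥ threshold (inclusive), or —
  both eyes present and the clause enabled — inter-eye difference
  strictly greater than 0.2. One available eye decides alone; none means
  undetermined. Note the full rule is *not* monotone per eye: raising
  the lower eye can dissolve the asymmetry clause. Only the
  threshold-only rule (used for AI and resident predictions, applied to
  the patient-level maximum CDR) is monotone per eye.
* `synergy_or()`: OR with undetermined-handling — one determinate input
  decides; both undetermined stays undetermined and is excluded from
  metrics.
* `risk_tier()` / `retinal_disease_positive()`: a configurable
  finding-to-tier map (the shipped `default_risk_map()` is a package
  choice and should be reviewed against local grading guidelines);
  tessellated fundus maps to `none` and never counts as disease.
* `media_opacity()`: a configurable set of conjunction rules; the
  default set contains exactly one rule — age ≥ 60, blurry vision, and
  no gradable image.
* `optimize_threshold_f1()`: scans unique score values, ties broken
  toward the largest threshold (the highest-specificity operating point
  among F1 maximizers).

# Metrics, reconstruction and bootstrap

`metric_set()` reports accuracy, sensitivity, specificity, PPV and F1,
with zero-denominator metrics as `NA` rather than 0. Published panels
print these to one decimal in percent; all matching against printed
values uses **half-up** rounding, which is what reproduces the published
agreement percentage and kappa.

`reconstruct_counts()` is the bridge between printed panels and exact
tests: when several classifiers share one truth, the printed rounded
metrics over-determine the integer confusion cells, and exhaustive
search over the positive count `P` recovers them exactly — asserting
uniqueness rather than assuming it, and returning the ambiguity set when
the inputs under-determine the cells. For the shipped glaucoma panel
(n = 245), sensitivities/specificities alone identify `P = 46` and all
twelve remaining printed values follow from the reconstructed cells; for
the retinal panel (n = 395), the resident's printed PPV and F1 serve as
tie-breakers and identify `P = 156`.

Bootstrap inference is percentile-based with patient-level resampling
for classification metrics (eye-level data feed the CDR error analyses
instead), defaulting to 2,000 resamples. The paired two-sided p-value
resamples patients jointly and counts tie mass on both sides,
`p = 2 min(frac(Δ* ≤ 0), frac(Δ* ≥ 0))` clipped to `(1/n_boot, 1]`.
The published analysis names only "the bootstrap estimation method", so
interval type (percentile vs BCa), `n_boot` and the p-value construction
are package decisions; published CI endpoints are consequently treated
as illustrative, never as test targets. A 300-replication null
simulation (two raters with an identical error process, n = 500)
verifies the empirical type-I error at α = 0.05 falls in [0.02, 0.09].

# The OR-synergy ROC envelope

For two continuous scores combined by OR, every pair of cutoffs
$(\tau_a, \tau_b)$ over the observed unique values (plus $+\infty$)
yields an achievable (FPR, TPR) point; a missing score never contributes
a positive, and patients missing both scores are excluded. The
**frontier** is the Pareto-dominant upper-left subset of that cloud —
achievable operating points, not a convex hull — with each point
annotated by one achieving threshold pair. Equivalence with exhaustive
threshold-pair enumeration is asserted on hundreds of random small
instances.

AUC is the trapezoid over the frontier closed at (0, 0) and (1, 1). Two
consequences are worth knowing. First, the envelope AUC always
dominates both single-score AUCs (setting one threshold to $+\infty$
recovers each component). Second, because the Pareto set drops dominated
staircase corners, its trapezoid can slightly exceed the single-score
Mann–Whitney AUC even when the partner score is uninformative; the
collapse identities (absent or duplicated partner) are therefore exact
on the frontier *points*, while AUC satisfies dominance.

`operating_point()` extracts the clinically named points: highest
sensitivity at a specificity floor, highest specificity at a sensitivity
floor, or the F1-optimal point at a given prevalence.

# The study pipeline

`run_study()` assembles the full report. Analysis subsets follow the
evaluation design — glaucoma metrics on patients with CDR from all
raters, eye-level agreement on eyes graded by all raters, retinal
metrics on patients with a disease call from both raters — and every
exclusion is logged so subset sizes plus exclusions sum to the cohort
size. `quality_ablation()` contrasts the AI with and without its image
quality gate, splitting the ungated analysis by gate status; in
simulated cohorts with degraded ungated estimates, specificity without
gating falls below specificity with gating in essentially every seed, a
directional property the tests check by sign count.

For resident glaucoma calls the pipeline defaults to the plain CDR
cutoff at 0.6 on the patient maximum (`resident_use_asymmetry = FALSE`),
because the simulator generates resident CDR measurements rather than
free-text referral decisions; the asymmetry-clause mode is a switch.
Whether the AI threshold applies per eye or to the patient maximum is
likewise resolved toward the patient maximum, which is also the ROC
score.

# Problem sizes and numerical choices

The shipped tests use cohorts of a few hundred patients for pipeline
properties, 10,000 patients (≈12,000 fully graded eyes) for parameter
recovery, 500 random instances for the envelope/oracle equivalence, 300
replications for bootstrap level, and 200 bootstrap resamples inside
simulation loops (2,000 for one-off intervals) — sizes at which the
Monte-Carlo tolerances quoted above are comfortable margins rather than
knife edges. Other fixed numerical choices: 1.96 (not a t quantile) for
limits of agreement; relative error denominated by the ground-truth CDR
(the rater-mean alternative is available); half-up rounding to one
decimal wherever printed percentages are matched; probability
validation at tolerance 1e-9 for prevalence sums.

# Known limitations

* The simulator's error model is homoscedastic given the rater; it
  reproduces summary anchors, not full empirical distributions.
* The published correlation anchors for AI (0.728) and residents
  (0.538) against ground truth are unattainable jointly with the error
  anchors under this model (see above); `implied_agreement()` is the
  contract the simulator does satisfy.
* The finding-to-tier map is a reviewed default, not a clinical
  standard.
* No regression-based (proportional-bias-adjusted) limits of agreement;
  no AND- or weighted-score fusion; no learned segmentation or image
  enhancement — masks enter the geometry module as given.
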