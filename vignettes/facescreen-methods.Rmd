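---
title: "Simulated face-image screening studies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated face-image screening studies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

facescreen simulates and evaluates a matched case-control facial-image
classification study end to end: a synthetic cohort with a parametric
disease effect on facial geometry, video-like yaw sweeps, simulated
expert raters, pair-cohesive nested cross-validation with a
hyperparameter search, two-phase classifier training, Youden-threshold
discretization with three-view majority voting, and bootstrap comparison
of machine ensembles against the expert panel. This vignette documents
the models behind each stage, the tunable parameters and their defaults,
the numerical choices, and what the simulation can and cannot say about
real data.

## The cohort model

`generate_cohort()` draws case and control profiles for a study of (by
default) 155 cases and 153 controls recruited at 7 sites, 143 of the
controls individually matched to a case on sex, site and age within
5 years. Matching is implemented *generatively*: the matched control of
a pair is derived from its case's attributes, with the age jittered
uniformly inside the tolerance. This guarantees a feasible matching for
any configuration, instead of searching for one post hoc and possibly
failing. Unmatched cases (12 at defaults) and unmatched controls (10)
are drawn from the same marginal distributions, so the two groups remain
indistinguishable in expectation, mirroring a design in which a minority
of participants could not be pair-matched but group-level balance was
preserved.

Ages follow a triangular distribution on 23-86 years peaking at 58; the
triangular shape reproduces the intended cohort median without claiming
knowledge of the true age distribution. Disease-status flags mark 79% of
cases as biochemically controlled, with newly diagnosed cases drawn from
the uncontrolled subset (12% marginally).

## The facial-morphology model and its closed-form oracle

Each participant carries a latent morphology vector over the four
features classically altered by chronic growth-hormone excess: face
width, mandible size, nose size, lip thickness. For participant $i$,

$$ m_i = \mathrm{base} + \delta \cdot \mathrm{mult}^{[\mathrm{male}_i]}
  \cdot [\mathrm{case}_i] + \varepsilon_i, \qquad
  \varepsilon_i \sim N(0, \sigma_b^2 I_4), $$

and every rendered frame adds independent jitter
$N(0, \sigma_w^2 I_4)$ for pose and expression variation. Defaults:
$\delta = 0.11$ on every feature, multiplier $1.3$ (facial changes are
more pronounced in men), $\sigma_b = 0.15$, $\sigma_w = 0.05$. Because
both groups are Gaussian with a mean shift, the Bayes AUC of the latent
vectors has the closed form $\Phi(d/\sqrt 2)$ with
$d = \lVert\delta\rVert\,\mathrm{mult}^{[\mathrm{male}]}/\sigma_b$.
`latent_separability()` reports it, `face_params_for_auc()` inverts it,
and the test suite uses it as an independent oracle for everything the
trained classifiers should recover. At the defaults the per-sex latent
AUCs are about 0.85 (women) and 0.91 (men), chosen so that the overall
separability sits near the head-line discrimination level of published
face-classification studies of this disorder (AUC around 0.89).

`render_participant_video()` renders a deterministic grayscale face for
each of `n_frames` yaw angles sweeping $-90^\circ \ldots +90^\circ$
uniformly: a head ellipse whose width scales with the width feature and
foreshortens as the head turns, a jaw region, a nose blob that
translates with yaw, a lip band, and a fixed mid-gray clothing band at
the image base. Three rendering choices matter and were made
deliberately:

* **Dark face on a white background.** The emulated recordings are lit
  against a white backdrop. This also makes the test-set mask dilation
  (below) a near-no-op over background pixels, so training and test
  images stay distributionally comparable — with a dark background the
  dilated white mask introduced a train/test covariate shift large
  enough to break threshold transfer.
* **Soft shape edges** (logistic edge profile, width 0.07 in normalized
  coordinates): pixel intensities respond continuously and monotonically
  to the latent features, so the geometric signal is recoverable by the
  desk-scale classifiers.
* **Balanced feature salience.** The shape sizes and intensities were
  calibrated so that a trained linear readout weights the four latent
  features roughly equally. The closed-form oracle assumes the optimal
  isotropic direction; a renderer in which, say, lips occupy three
  pixels would silently cap every classifier well below the oracle, and
  the recovery tests would measure the renderer, not the pipeline.

Renderings are 64x64 grayscale by default: large enough to carry the
geometry, small enough that the full 1100-model protocol runs on a desk.

## Frame selection and clothing masking

`build_image_sets()` extracts the two image sets used throughout: 20
training images at uniformly spaced yaw targets over the full sweep
(endpoints included — the neutral reading of "20 angles from -90 to
+90") and 3 test images at 0, 45 and 90 degrees. For each target the
nearest-yaw frame is chosen, ties to the earlier frame. Clothing is
masked to pure white in all images, emulating the removal of
clothing-related confounding (many real controls were health-care
workers in uniform); for test images the mask is first dilated by 2
pixels (box structuring element), emulating the manual adjustment that
guaranteed no clothing survived in the images shown to experts and used
for final evaluation. The dilation radius is configurable since the
original step was manual and unparameterized.

## Expert-rater simulation

Each of 12 simulated raters classifies every participant once, in an
individual random order, with 50 random participants shown twice. An
annotation is positive with the rater's sensitivity (cases) or one minus
specificity (controls); the repeat presentation flips the first answer
with probability 0.07; with probability 0.01 the rater "recognizes" the
participant and the annotation is flagged excluded (the source protocol
excluded such judgements; no rate was reported, so a small configurable
default is used). Default operating points are fixed vectors with median
sensitivity 0.62 and median specificity 0.87, the published medians of
the real panel; the flip probability 0.07 yields an expected intrarater
Cohen's kappa of 0.85 at those operating points
(`expected_intrarater_kappa()` gives the analytic value under the flip
model), matching the published median reliability.

Raters are conditionally independent given the truth. This is the one
substantive divergence from real panels, where raters correlate strongly
on hard faces. It has a measurable consequence: the discretized
majority ensemble of 12 *independent* raters at sensitivity 0.66 has an
expected bootstrap-mean sensitivity of
$\sum_k \binom{12}{k}0.66^k 0.34^{12-k}\,P(\mathrm{Bin}(12,k/12)\ge 6)
= 0.848$, not 0.66 — aggregation boosts an independent panel far more
than it boosts a correlated one. Simulated ensemble-level operating
points are therefore *not* comparable to published ensemble values even
when the individual operating points are calibrated to match; only
rater-level medians and reliability are.

## Split planning

All partitions operate on *units*: a matched pair is one unit and
co-travels everywhere (splitting a pair across folds would leak the
matching structure), unmatched participants are singleton units, and
sampling is participant-atomic so no image of one participant can reach
two sides of any split. Units are stratified into pair / case-singleton
/ control-singleton classes and dealt round-robin with shuffled order
and fold rotation, keeping each stratum balanced across folds to within
one unit.

The nested design per outer fold (10 folds): the held-out fold is the
test set; the remaining modeling units get one 80/10/10
hyperparameter-search split (largest-remainder rounding within each
stratum, re-randomized per outer fold) and one 10-fold inner plan in
which each inner fold serves once as the development set. The
accounting is design-forced: per architecture, 10 outer folds times (20
search trials + 10 inner folds) = 300 trainings, 200 for the
10-trial face-pretrained architecture, 1100 over the default roster, of
which 100 per architecture contribute predictions, giving every
participant exactly 10 predictions per architecture.

## Backbones and the two-phase trainer

The protocol is backbone-pluggable. The built-in stand-ins keep the full
design runnable on one CPU: three "imagenet-style" variants are fixed
random linear projections of the pixel vector (distinct weights per
name, 32 features), the "face-pretrained-style" variant is the same with
48 features, and `linear_probe` is 8x8 average pooling. Real pretrained
networks can be supplied through the `extractor` hook of
`backbone_spec()`; reproducing their weights or accuracies is explicitly
out of scope.

`train_model()` fits a logistic prediction head by minibatch gradient
descent under the two-phase schedule: phase 1 trains the head alone with
the backbone frozen; phase 2 trains the whole network (for frozen
backbones the head continues alone — the linear-probe reading). Updates
use Adam with decoupled weight decay (default $10^{-3}$): with adaptive
steps the entire searched learning-rate range $[10^{-4}, 10^{-1}]$
trains usefully within desk-scale epoch budgets, which plain SGD does
not. Development-set ROC AUC is evaluated after every epoch (one full
pass of the training set); the checkpoint with the best development AUC
is the model kept. Early stopping (patience 5) halts training once five
epochs pass without improvement, and is enabled by default only for the
face-pretrained-style architecture, mirroring its role as the expensive
model in the emulated design.

Numerical choices: features are centred per feature but scaled by a
*single global* standard deviation — per-feature scaling amplifies
near-constant features (the fixed clothing band) by orders of magnitude
and destroys train/test transfer; the SD floor is $10^{-3}$; AUC ties in
checkpoint selection keep the earlier epoch (improvement must exceed
$10^{-12}$); single-class development sets are rejected because AUC is
undefined.

The search (`run_hpo()`) draws the learning rate log-uniformly from
$[10^{-4}, 10^{-1}]$, the batch size from {16, 32, 64} and the phase-1
epoch count from 1-5, trains each trial on the search-training part with
the search-development part for checkpoint selection, scores it by image
AUC on the search-test part, and returns the first-reached best trial.

## Prediction and evaluation

Per final model, the Youden threshold (maximizing $J = Se + Sp - 1$) is
computed on that model's inner development set — the only development
set a final model has. Candidate cutpoints are the midpoints between
consecutive distinct scores plus infinite sentinels, a finite complete
search; ties prefer the smallest threshold; a score at the threshold is
positive. The three test-view scores are discretized at the model's
threshold and majority-voted into the model's participant-level
prediction. Architecture ensembles pool member predictions by
concatenation (30 predictions for the three-member ensemble, 40 with
the face-pretrained model added), because the downstream statistics
operate on discretized predictions; score averaging is a non-goal.

`bootstrap_ensemble_metrics()` implements the study's bootstrap: per
run, each participant's prediction set (12 raters or 10 models or a
pooled ensemble) is resampled with replacement at its own size, the mean
is that participant's ensemble score, binary metrics discretize at 0.5
or more, and ROC AUC uses the mean scores; 10,000 runs give per-metric
means and percentile 95% intervals. Resampling predictions within
participants estimates predictor-ensemble variability, not cohort
sampling variability; a participant-level resampling mode is available
behind `resample = "participants"` for the latter. Precision is
undefined (`NA`) in a run without predicted positives and F1 is then 0
by convention; such runs essentially never occur at study scale.
Subgroup analyses repeat the bootstrap within sex, three equal-count age
groups (ties to the lower group; preset bounds accepted), and
biochemical-control strata, where sensitivity comes from the patient
subset and specificity always uses all controls, since controls carry no
disease status. `agreement_table()` decomposes, per class, which
predictors classified each participant correctly, the Venn-style view of
expert-model complementarity.

## Problem sizes and runtime

The defaults were chosen so every full-design computation runs on a
single CPU: 64x64 grayscale frames, 21-frame sweeps, 32-64 dimensional
features, 2+12 epoch schedules. At these sizes the complete 1100-model
protocol takes minutes, and the latent-AUC recovery experiment (one
architecture, 300 trainings) runs three replicate cohorts in a few
minutes. The replicate averaging exists because the *realized* latent
AUC of one 308-participant cohort has a sampling SD of about 0.026
around its calibrated value; three replicates measure recovery of the
calibrated value with proportionally less noise.

## What passing tests do and do not show

The generator produces exactly the structure the pipeline assumes:
Gaussian latent effects rendered into deterministic geometry, honest
pair matching, independent raters with known operating points. Passing
recovery tests therefore shows that the *pipeline* — splits, training,
thresholds, voting, bootstrap — measures without bias and without
leakage what the generator put in. It does not show that any backbone
would detect real disease from real photographs: photorealism,
demographic covariate structure, rater correlation, and
treatment-induced change over time are all outside the generator by
design. Where a published quantity is design-forced (model counts,
predictions per participant) or arithmetic (balanced accuracy and F1
from an operating point), the package reproduces it exactly; where it
depends on real images or real rater correlation, the package computes
the analogous quantity on synthetic data and documents the divergence
(see the rater-independence note above).

## Known limitations

* Rater independence (discussed above) inflates ensemble-level metrics
  relative to correlated real panels.
* The fold stratification balances case/control classes only; sex and
  site are balanced in expectation through pair cohesion but not
  enforced per fold.
* The stand-in backbones are linear; they recover the generator's
  geometry but say nothing about the feature hierarchies of real
  networks.
* The within-participant bootstrap understates cohort-level sampling
  uncertainty; its intervals describe the predictor ensemble, and the
  participant-level mode should be used for population claims.
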