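# facescreen

Simulated face-image screening studies with nested cross-validation and
expert benchmarks.

## The problem

Facial changes — a wider face, an enlarged mandible and nose, thicker
lips — are a hallmark of acromegaly and often the key to its diagnosis,
which is nevertheless delayed by years in typical series.
Machine-learning classification of face photographs is a promising
prescreening route, and the credible study designs in this area share a
demanding protocol: a matched case-control cohort, multi-angle images
per participant, pair-cohesive nested cross-validation with a
hyperparameter search, per-model Youden-threshold discretization with
multi-view majority voting, and a bootstrap comparison of model
ensembles against a panel of expert clinicians.

The images behind such studies are sensitive personal data and are not
shared. facescreen makes the *protocol* itself a tested, reusable
artifact: it generates a fully synthetic study — cohort, video-like yaw
sweeps with a parametric disease effect on facial geometry, and
simulated expert raters — and runs the complete analysis pipeline on it,
so every stage is verifiable against closed-form oracles with no
downloads and no GPUs. User-supplied images, yaw annotations, clothing
masks and rater tables can replace any generated stage through the same
CSV/PNG interfaces.

## The models at the core

**Latent morphology.** Participant $i$ carries
$m_i = \mathrm{base} + \delta\,\mathrm{mult}^{[\mathrm{male}]}[\mathrm{case}] + \varepsilon_i$
with $\varepsilon_i \sim N(0, \sigma_b^2 I_4)$ over (width, jaw, nose,
lip), rendered deterministically into grayscale frames across yaw
$-90^\circ..+90^\circ$. The Bayes separability is the closed form
$\mathrm{AUC} = \Phi(d/\sqrt2)$, $d = \lVert\delta\rVert\,
\mathrm{mult}^{[\mathrm{male}]}/\sigma_b$ — the oracle every recovery
test is checked against.

**The protocol.** Outer 10-fold cross-validation, stratified and
pair-cohesive; per fold an 80/10/10 hyperparameter-search split and an
inner 10-fold train/development plan; two-phase training (head only,
then the whole network) with per-epoch development ROC AUC checkpointing
and optional patience-5 early stopping; per-model Youden thresholds
($\max\, Se + Sp - 1$) on the model's development set; majority vote
over the 3 test views (0°, 45°, 90°); per-participant prediction sets
(10 models per architecture, or 12 raters) resampled 10,000 times, with
means discretized at ≥ 0.5 for binary metrics and used raw for ROC AUC.

## Worked example

A complete small study — generate, preprocess, plan, search, train,
predict, evaluate — in a few seconds:

```r
library(facescreen)

cfg <- smoke_run_config(seed = 3)     # 44 participants, 2x2 folds, 1 architecture
res <- run_pipeline(cfg, outdir = "smoke_out")

readr::read_csv("smoke_out/metrics.csv")
#>   predictor    sensitivity     specificity     balanced_accuracy precision       f1              roc_auc
#> 1 linear_probe 0.86(0.77-0.91) 0.58(0.55-0.64) 0.72(0.68-0.77)   0.67(0.64-0.71) 0.75(0.71-0.80) 0.73(0.68-0.77)
#> 2 experts      0.76(0.64-0.91) 0.93(0.86-0.95) 0.85(0.77-0.93)   0.92(0.84-0.95) 0.83(0.72-0.93) 0.94(0.90-0.98)
```

Each cell is the bootstrap mean with its percentile 95% interval. On
this deliberately tiny cohort the single trained architecture reaches a
held-out ROC AUC of about 0.73 (about 20 training participants per
model leave plenty of estimation noise — at full study scale the same
architecture reaches the mid-0.80s), while the simulated 12-expert
panel shows the familiar clinician profile of high specificity (0.93)
and lower sensitivity (0.76). `smoke_out/` also contains the cohort table, the
rater annotations with intrarater-kappa table, the fold plan as JSON,
one row per trained model, per-image scores, per-model predictions, the
expert-model agreement decomposition and an md5 manifest — rerunning
with the same seed reproduces identical file hashes.

The pieces compose directly at study scale:

```r
cohort <- generate_cohort(cohort_config(), seed = 1)   # 155 cases / 153 controls / 143 pairs
study  <- run_study(cohort, seed = 1)                  # 1100 trainings, 4 architectures
bm <- bootstrap_ensemble_metrics(
  build_ensemble(study$predictions,
                 c("imagenet_style_a", "imagenet_style_b", "imagenet_style_c"),
                 "imagenet_ensemble"),
  cohort_truth(cohort), B = 10000, seed = 1)
tidy(bm)        # metric / mean / lower / upper
autoplot(bm)
```

Fitted objects follow broom conventions: `tidy()` on a trained model
gives its per-epoch development-AUC trajectory, `glance()` its selected
checkpoint; `tidy()` on a bootstrap result gives the metric table.

## Package layout

| Stage | Functions |
|---|---|
| Synthetic cohort | `cohort_config()`, `generate_cohort()`, `face_params()`, `render_participant_video()`, `draw_latents()`, `latent_separability()` |
| Expert simulation | `rater_params()`, `simulate_expert_raters()` |
| Frame pipeline | `angle_spec()`, `select_frames()`, `apply_clothing_mask()`, `build_image_sets()`, `write_frames()` |
| Fold planning | `plan_outer_folds()`, `plan_hpo_split()`, `plan_inner_folds()`, `plan_nested()`, `count_trainings()` |
| Training | `backbone_spec()`, `training_config()`, `train_model()`, `hpo_config()`, `run_hpo()`, `run_nested_training()`, `run_study()` |
| Prediction | `youden_threshold()`, `discretize()`, `majority_vote()`, `collect_predictions()`, `build_ensemble()` |
| Expert analysis | `ensemble_experts()`, `intrarater_kappa()`, `expected_intrarater_kappa()` |
| Metrics | `confusion_metrics()`, `metrics_from_rates()`, `roc_auc()`, `bootstrap_ensemble_metrics()`, `subgroup_metrics()`, `agreement_table()` |
| Orchestration | `run_config()`, `validate_config()`, `run_pipeline()`, `write_run_config()` |

The methods vignette (`vignettes/facescreen-methods.Rmd`) documents the
generative models, defaults, numerical choices and limitations.
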