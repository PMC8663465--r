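# facescreen

Markerless screening for hypomimia — the "masked face" of Parkinson
disease — from short 2D grayscale face videos (a poker face followed by a
smile), for researchers building or validating classical computer-vision
screening pipelines.

## What it computes

The pipeline runs entirely on 68-point facial landmarks (iBUG-68 scheme)
and the normalized face image:

1. **Normalization.** Each frame is mapped into a canonical 256 × 256
   frame by a closed-form similarity transform that places the two eye
   centers (means of points 36–41 and 42–47) exactly at (89.6, 102.4) and
   (166.4, 102.4).
2. **Geometric features.** The characteristic triangle of the mouth —
   corners p48, p54 against the lip centers p51, p57 — yields the corner
   angles θ_left, θ_right. The main features are the apex-minus-neutral
   changes Δθ (a smile shrinks the corner angle; hypomimia shrinks the
   change), with the overall mouth-axis deviation, per-side corner
   elevations, and their asymmetry |dev_L − dev_R| as auxiliary features.
   Neutral and apex frames are selected by the mouth-width /
   inter-ocular-distance ratio.
3. **Texture features.** HOG (9 unsigned bins, 8-px cells, 2 × 2 blocks,
   L2-Hys) and uniform LBP (P = 8, R = 1, per-cell L1-normalized
   histograms) over eye and mouth regions of the normalized face.
4. **Classification.** SVM (RBF), KNN (k = 5) and random forest (100
   trees) on geometric, texture and combined feature sets, with a
   stratified train/test split and leakage-safe standardization.
5. **Evaluation.** ROC/AUC (trapezoid = tie-aware pairwise concordance),
   the Youden index J = max(TPR − FPR) with its optimal threshold,
   confusion-matrix metrics at that threshold, patient-group Pearson
   correlations with clinical covariates (Fisher-z 95% CIs), and a
   noncentral-F repeated-measures ANOVA sample-size calculator
   (λ = f²·N·m/(1+(m−1)ρ)).

No patient videos ship with the package. A synthetic cohort generator
(`generate_cohort()`) draws two groups with controllable effects on smile
amplitude, mouth asymmetry and facial texture, renders line-art frames with
analytic ground-truth landmarks, and samples clinical covariates — so every
stage is testable end to end.

## Worked example

```r
library(facescreen)

cfg <- cohort_config(n_patient = 12, n_control = 12, effect_angle = 1.5,
                     effect_texture = 0.5, rng_seed = 42)
report <- run_pipeline(cfg, n_train = 14)
print(report)
#> <report bundle>
#>   algorithm feature_set  auc youden_j threshold accuracy precision recall f_measure
#> 1       svm   geometric 0.96      0.8    0.5203      0.9    0.8333    1.0    0.9091
#> 2       knn   geometric 0.94      0.8    0.5000      0.9    1.0000    0.8    0.8889
#> 3        rf   geometric 0.86      0.6    0.4500      0.8    0.8000    0.8    0.8000
#> 4       svm     texture 1.00      1.0    0.4955      1.0    1.0000    1.0    1.0000
#> 5       knn     texture 1.00      1.0    0.4000      1.0    1.0000    1.0    1.0000
#> 6        rf     texture 1.00      1.0    0.4300      1.0    1.0000    1.0    1.0000
#> 7       svm    combined 1.00      1.0    0.4956      1.0    1.0000    1.0    1.0000
#> 8       knn    combined 1.00      1.0    0.4000      1.0    1.0000    1.0    1.0000
#> 9        rf    combined 1.00      1.0    0.4950      1.0    1.0000    1.0    1.0000
```

The cohort has a 1.5-SD hypomimia effect on the smile corner-angle change
and a 50% texture-contrast reduction in patients, so geometric features
discriminate well (AUC 0.86–0.96 on the 10-subject test set) and texture
features separate the groups completely at these effect sizes; the
`threshold` column is each model's Youden-optimal score cut, and the
confusion-matrix columns are evaluated at that cut. `report$correlations`
holds the patient-group covariate correlation table (no correlations are
expected — covariates are independent of facial traits by default), and
`report$roc_points` the nine ROC curves.

The design sample-size calculation behind a study of this shape:

```r
rm_anova_sample_size(f_effect = 0.4, alpha = 0.05, power = 0.95,
                     k_groups = 2, m_measurements = 120, rho = 0.5)
#> [1] 44
```

i.e. 22 participants per group suffice for a large between-group effect
measured 120 times per subject at intra-subject correlation 0.5.

A thin command-line wrapper with `synth`, `extract`, `train`, `evaluate`,
`correlate`, `power` and `run` subcommands is installed at
`inst/scripts/facescreen.R`.

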