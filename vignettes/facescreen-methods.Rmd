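---
title: "Quantifying hypomimia from 2D face video: methods and design notes"
author: "facescreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hypomimia from 2D face video: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facescreen)
```

## The screening problem

Facial-muscle rigidity in Parkinson disease reduces the amplitude and
coordination of facial expression — the "masked face", or hypomimia. A short
2D video in which a participant holds a poker face and then smiles contains
two complementary kinds of evidence:

* **geometry** — how much the mouth shape changes between the neutral frame
  and the smile apex, and how symmetrically the two corners move;
* **texture** — how much fine detail (wrinkling, folds around the eyes and
  mouth) the expressive regions of the face carry.

`facescreen` implements the full classical pipeline: 68-point landmark
normalization, mouth-angle geometric features, HOG/LBP texture descriptors
over eye and mouth regions, SVM/KNN/random-forest classification with a
stratified split, and ROC/Youden evaluation, together with the clinical
side-statistics (covariate correlation tables with Fisher-z intervals and a
repeated-measures ANOVA power calculator). Because no public video cohort
with this protocol exists, the package ships a synthetic cohort generator
with analytic ground-truth landmarks; every stage is exercised and tested
against it.

## Landmark normalization

Landmarks use the iBUG-68 scheme in 0-based, y-down pixel coordinates.
Normalization maps each frame into a canonical 256 x 256 frame by a
4-degree-of-freedom **similarity** transform (rotation, uniform scale,
translation), not a full 6-DOF affine: shear would distort the very mouth
angles the pipeline measures, and alignment ("face correction") is exactly
what a similarity achieves. The default anchor correspondence is the two eye
centers (means of points 36–41 and 42–47) mapped to (89.6, 102.4) and
(166.4, 102.4) — eyes at 35%/65% of the width and 40% of the height,
inter-ocular distance 76.8 px. Two-point alignment has a closed form (one
complex division), so the anchors are hit to machine precision; a
least-squares similarity over all 68 points against a template is available
behind `method = "procrustes"` for noisy landmark sources. Images are
resampled by inverse-mapping bilinear interpolation with out-of-frame
pixels set to 0.

Consequences that the tests verify: all geometric angle features are
invariant (≤ 0.1°) to arbitrary rotation/scale/translation of the raw
input, and transform round-trips are exact to 1e-6 px.

## Geometric mouth features

The characteristic triangle of the mouth uses outer-lip landmarks only: the
corners p48/p54 as vertices, with the upper- and lower-lip centers p51/p57
as the opposing edge. Features (all in degrees):

* `theta_left`, `theta_right` — the corner angles, via the arccos of the
  normalized dot product. A smile widens the mouth, so the corner angle
  *shrinks*; the apex-minus-neutral differences `d_theta_left/right` are the
  main features (negative for a normal smile, near zero under hypomimia).
* `delta_overall` — signed angle of the corner-to-corner axis against the
  horizontal (`atan2`, y-down: positive = image-right corner lower).
* `dev_left`, `dev_right` — per-side corner elevation above the mouth
  center (midpoint of p51/p57); `asym_apex = |dev_left − dev_right|` is the
  auxiliary asymmetry feature.

Key frames are chosen by the **mouth-width ratio** (corner distance over
inter-ocular distance) rather than by the angles themselves, so frame
selection is decoupled from the feature being measured: the neutral frame
is the minimizer within the first 40% of the sequence (the protocol places
the poker face first), the apex the global maximizer, ties toward the
earlier frame. Degenerate all-constant sequences fall back to
(first, last) with a warning flag. Frame indices are 1-based in the R API.

Differences are apex-minus-neutral subtractions, not ratios: angle
differences stay in interpretable degree units and behave linearly near
zero amplitude.

## Texture features

Eye (points 36–47) and mouth (48–67) ROIs are cut from the normalized face
with fractional margins (25%/20%), resampled to 128 x 32 and 64 x 32, and
described by:

* **HOG** — centered finite-difference gradients; 9 unsigned orientation
  bins over [0°, 180°) with magnitude-weighted votes linearly interpolated
  between the two nearest bin centers (centers at i·20°, wrapping at 180°);
  8-px cells, 2 x 2-cell blocks sliding by one cell, L2-Hys normalization
  with clip 0.2. The 64 x 32 mouth ROI yields 7·3 blocks · 4 cells · 9 bins
  = 756 values. HOG is exactly invariant to global additive intensity
  shifts.
* **uniform LBP** — P = 8 neighbors at radius R = 1, bilinear sampling,
  `neighbor >= center` sets the bit (ties set the bit, which pins the code
  of perfectly flat regions); codes with ≤ 2 circular transitions map to 58
  uniform bins plus one catch-all, histogrammed over 8 x 4 (mouth) and
  16 x 4 (eyes) cell grids, each cell L1-normalized. Pixels without a full
  circular neighborhood (a border margin of `ceiling(R)`) are skipped.

One numerical caveat worth stating precisely: with interpolated neighbor
sampling, LBP is exactly invariant to *increasing affine* intensity
transforms (interpolation commutes with them) but only approximately
invariant to general monotone transforms, because a nonlinear map does not
commute with the weighted means that interpolation produces; near-tie
diagonal comparisons can flip. The non-interpolated integer-neighbor
variant would be exactly monotone-invariant but is not what this package
implements. Texture is computed on the apex frame only (configurable): the
apex maximally stretches the perioral and periocular skin, which is where
the group difference in fine detail expresses itself.

The paper trail for these descriptors ends at their names — no
hyperparameters are published for this protocol — so the defaults above are
the field-standard ones and all are exposed (`hog_params()`,
`lbp_params()`, `roi_spec()`) for sensitivity analyses.

## Classification

One feature row per subject (never per frame — per-frame rows would leak
subject identity across the split). The split is stratified random with
largest-remainder allocation, default 80 training / 60 test subjects for a
140-subject cohort. Standardization (z-scoring) is fitted on training rows
only and applied to all rows; zero-variance columns are set to 0. Combined
features are the column concatenation [geometric | texture] standardized
the same way.

Defaults, all overridable: SVM with RBF kernel, cost 1, bandwidth
`1/(p · mean feature variance)` (the "scale" rule), decision values
oriented on the training set and squashed to [0, 1] by the logistic
function; KNN with k = 5, Euclidean distance, score = neighbor-vote
fraction; random forest with 100 trees and `floor(sqrt(p))` candidate
features per split, score = tree-vote fraction, seeded for determinism.

## Evaluation and clinical statistics

`roc_auc()` sweeps every distinct score as a threshold; the AUC is the
trapezoidal integral, which equals the pairwise concordance probability
with ties counted 0.5 (verified exactly against a brute-force pair count).
The Youden index J = max(TPR − FPR) picks the operating threshold; among
maximizers the highest-TPR one wins, and the reported cut is the midpoint
between the two adjacent distinct scores straddling it. Hard labels for
accuracy/precision/recall/F are taken at that threshold.

Covariate correlations are computed within the patient group only, as a
clinical correlation table (variable, n, p, r, Fisher-z 95% CI), with raw
p-values — the analysis is descriptive, and multiplicity correction would
change its meaning. Constant covariates produce flagged `NA` rows, not
errors.

The power calculator follows the G*Power convention for a between-groups
factor in a repeated-measures design: noncentrality
λ = f²·N·m/(1 + (m − 1)ρ), df₁ = k − 1, df₂ = N − k, power from the
noncentral F distribution; `rm_anova_sample_size()` returns the smallest
balanced N reaching the target. With f = 0.4, α = .05, power .95, k = 2,
m = 120, ρ = 0.5 it returns N = 44 (22 per group); with m = 1 the classic
two-group answer N = 84. Other conventions exist (e.g. multiplying into
the error term instead); the one implemented is stated here because the
choice changes N.

## The synthetic cohort generator

The generator emulates the screening study design: two groups, one
poker-face-to-smile sequence per subject, subject-level latent traits,
clinical covariates. Per subject:

* `smile_angle_gain` ~ N(12°, 3°) truncated at 0, with patients shifted
  down by `effect_angle` SD — the hypomimia effect;
* `asymmetry` ~ N(0, 1.5°·(1 + effect_asym)) for patients;
* `texture_contrast` ~ U(0.8, 1) multiplied by (1 − `effect_texture`) for
  patients;
* neutral corner angle ~ N(55°, 3°), mouth width ~ N(58, 2) px,
  inter-ocular distance 100 px on a 256-px canvas — values that put all
  angles in a numerically comfortable mid-range;
* expression phase over the default 11 frames is the half-sine
  `sin(π·(j−1)/(n−1))`: neutral first frame, apex in the middle, relaxed
  end, mirroring the instruction order. 11 frames is deliberate
  down-sampling of a 10–15 s clip: the pipeline uses two key frames, so
  dense temporal sampling adds cost without information.

The landmark model is analytic and mirror-symmetric by construction: the
mouth widens by 30% at apex, the corner angle shrinks linearly from the
neutral angle by the gain (lip height is solved by root-finding so the
mean corner angle hits its target exactly), corners elevate by 6°·phase
with ±asymmetry/2 split between sides. Ground truth is therefore
recoverable: measured corner-angle change regresses on the latent gain
with slope 1.00 across a cohort, the tests' parameter-recovery anchor.

Frames are rendered as parametric line-art — head ellipse, contour strokes
through the landmarks, sinusoidal wrinkle bands near the eye corners and
around the mouth with amplitude proportional to `texture_contrast`, plus
Gaussian pixel noise (SD 2) — rather than photorealistic faces. The
pipeline consumes gradient and micro-pattern statistics, not identity, so
line art suffices to carry a controllable group texture effect and keeps
generation dependency-free. Because texture features need only the apex
frame and geometry only the landmarks, `generate_cohort()` renders just
the key frames by default (`render = "all"` and `"none"` are available).

Covariates (age, onset, duration, LEDD, UPDRS, H-Y, MMSE, NMSS, PDQ-39,
HAM-A, RBD, QUIP, freezing of gait) are drawn from plausible scale ranges
independently of the facial traits — matching the observed clinical
pattern that facial-feature model outputs do not correlate with symptom
scales — unless `covariate_link = TRUE`, which ties UPDRS to the smile
deficit with correlation −0.6 for power studies of the correlation
analysis.

### What the generator does and does not emulate

It emulates: group effects on smile amplitude, asymmetry dispersion and
texture detail; per-subject anatomical variation; detector-free
ground-truth landmarks; covariates independent of facial severity. It does
not emulate: landmark-detector error (the detection interface is pluggable
precisely so a real detector can be wrapped), head pose change within a
sequence, facial tremor, illumination variation, or photorealistic
appearance. Passing tests therefore demonstrate that the pipeline is
correct and sensitive under controlled conditions — not that any given
accuracy transfers to clinical video.

A consequence of the generator's simplicity worth knowing: at the texture
effect sizes used in the recovery tests (`effect_texture = 0.5`), patient
and control contrast distributions do not overlap at all, so texture-based
classifiers reach AUC 1.0 and the combined features can only tie, not
strictly beat, the texture modality. The fusion property tested is
"combined at least matches the best single modality, and strictly beats
geometry".

## Numerical choices and degenerate inputs

* Angles via `acos` of a clamped dot product, signed angles via `atan2`;
  coincident landmark points raise a `fs_degenerate_geometry` error rather
  than NaN.
* Two-point alignment is exact; coincident eye centers are an error.
* Ties: key-frame selection breaks toward the earlier frame; the Youden
  maximizer with the highest TPR wins; LBP comparison ties set the bit.
* All randomness flows from one root seed through a documented
  linear-congruential derivation (`subject i`, `frame j`, stage tags), so
  cohorts, splits, forests and reports are bit-reproducible and report
  files from equal configurations are byte-identical.
* Simulation sizes in the test suite (10 replicate cohorts for effect
  recovery, 10 for null calibration, 20 for correlation calibration, 200
  random instances for the ROC oracles, 1000 for the angle oracles) were
  chosen to make the binomial acceptance bounds meaningful while keeping
  the default suite comfortably runnable on one CPU.
* Replicate-based calibration checks use binomial 95% bounds around the
  nominal rate rather than hard "all runs inside" rules: a ±2·SE band is
  exceeded by ~5% of healthy runs by construction, and the bounds make the
  tests reject miscalibration rather than ordinary sampling noise.

## Limitations

The pipeline measures mouth geometry only (no brow/blink geometry), uses
one apex frame for texture, and assumes a single face per frame. The
landmark normalization assumes in-plane similarity; out-of-plane pose is
not corrected. The synthetic validation bounds what the tests can claim
about clinical data, as discussed above. DeLong confidence intervals for
AUC and probability calibration of classifier scores are out of scope.
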