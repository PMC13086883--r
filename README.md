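# radgrade

Deep-learning risk stratification of intermediate-grade breast tumours
from dynamic contrast-enhanced (DCE) MRI.

## The problem

The Nottingham Histologic Grade (NHG) drives treatment decisions in breast
cancer, but the intermediate grade (NHG2) — about half of all cases — is a
biologically heterogeneous group whose members behave anywhere from
NHG1-like (indolent) to NHG3-like (aggressive). `radgrade` implements an
imaging-based sub-stratification of that group: a convolutional neural
network is trained to separate NHG1 from NHG3 tumours on routine 4-phase
DCE MRI, and the trained classifier is then applied to NHG2 tumours,
splitting them into **DRG2−** (NHG1-like) and **DRG2+** (NHG3-like)
subgroups whose recurrence-free survival (RFS) can be compared and whose
label can be tested for independent prognostic value.

Because the package is exercised entirely on synthetic data, it ships a
first-class phantom-cohort generator: 4-phase DCE tumour phantoms whose
enhancement kinetics, size and morphology are monotone in a latent
aggressiveness score *a* ∈ [0, 1], together with clinical covariates and
censored exponential survival times whose log-hazard is linear in *a* and
in T stage ≥ 2, nodal invasion and triple-negative subtype. The latent
score gives every downstream claim a recoverable ground truth.

## The method

- **Preprocessing** — per patient, joint min–max normalisation across the
  pre-contrast and three post-contrast phases; a 3 × 14 × 64 × 64
  (phase × slice × row × col) crop centred on the tumour centroid; for
  training, the *k* slices nearest the central slice with ~2k/7 of them
  horizontally and ~2k/7 vertically flipped (at k = 14: 4 + 4 flipped,
  6 unchanged); for evaluation, one deterministic central slice.
- **Network** — six blocks of (3 × 3 conv, pad 1) → ReLU → (2 × 2 max
  pool), widths 16 → 512, reaching a 512-feature 1 × 1 map, then
  512 → 256 → 1 with a sigmoid output. Training minimises class-weighted
  binary cross-entropy with Adam. The CNN kernels (im2col + GEMM forward,
  full backpropagation, Grad-CAM) are implemented in RcppArmadillo.
- **Operating point** — the threshold maximising Youden's
  J = sensitivity + specificity − 1 over the training-set patient scores;
  `score ≥ threshold` ⇒ DRG2+.
- **Survival** — Kaplan–Meier curves and log-rank tests per arm; two Cox
  proportional-hazards models on the stratified grade-2 patients (base:
  age, T ≥ 2, N ≥ 1, molecular subtype; full: + DRG2 label; Efron ties);
  Harrell's C-index from all comparable pairs; a paired bootstrap (1000
  resamples, both models refitted per resample) for the C-index difference
  with a percentile CI and a sign-fraction two-sided p-value.
- **Explanation** — Grad-CAM maps at any conv block:
  ReLU(Σ_c α_c A_c) with α_c the spatial mean of ∂logit/∂A_c, bilinearly
  upsampled and max-normalised.

## Worked example

```r
library(radgrade)

res <- run_pipeline(run_config(
  n_grade1 = 150, n_grade2 = 400, n_grade3 = 150,
  slices_per_patient = 8, profile = "test",
  bootstrap = 1000, seed = 1))
```

The run logs each stage; with seed 1 it prints (about 5–6 minutes on one
CPU):

```
split: 240 train / 60 test patients
train: 1920 slices, 15 epochs (profile test)
AUC train 1.000 [1.000-1.000], test 0.998 [0.990-1.000]
Youden threshold 0.3596 (J = 1.000)
strata: 183 DRG2- / 217 DRG2+ of 400
Cox C-index 0.671 -> 0.696 (delta 0.0224, p = 0.004);
  DRG2+ adjusted HR 2.09 [1.55-2.82]
```

Reading the output: the network separates the extreme grades essentially
perfectly on held-out patients (test AUC 0.998); the Youden cutoff applied
to 400 synthetic grade-2 tumours calls 217 of them NHG3-like; and the
DRG2+ label carries a two-fold adjusted hazard for recurrence
(HR 2.09, 95% CI 1.55–2.82) independent of age, stage, nodal status and
subtype, raising the Cox model's concordance from 0.671 to 0.696
(paired-bootstrap p = 0.004). On synthetic cohorts the label is
*expected* to work — the latent aggressiveness that shapes the images also
drives the hazard — so these numbers validate the machinery, not the
clinical claim.

Useful entry points: `simulate_cohort()`, `train_cnn()`,
`score_patients()`, `youden_threshold()`, `classify_grade2()`,
`compare_groups()`, `run_rfs_analysis()`, `grad_cam()`,
`sweep_slices()`; results have `tidy()`/`glance()` methods and
`autoplot()`/`plot_km()` figures.

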