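---
title: "Weakly supervised PET/CT prognosis: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly supervised PET/CT prognosis: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Deep prognostic models for rare cancers such as extranodal NK/T cell
lymphoma face a structural data problem: event-time supervision requires
years of follow-up, so most of an imaging archive is unusable for
supervised training. This package implements a weakly supervised strategy
for that setting. Patients with at least two years of progression-free
survival (PFS) follow-up form the labeled cohort; patients with short or
missing follow-up form an unlabeled pool that would otherwise be
discarded. The pipeline has four steps:

1. train a 3D residual convolutional network on the labeled training
   patients (relapse within follow-up vs. not);
2. extract the 128 features of the global average-pooling layer for
   labeled and unlabeled patients;
3. fit a linear positive-negative-unlabeled (PNU) classifier on those
   features and let it assign *implicit labels* to the unlabeled pool;
4. retrain the network from a fresh initialization on the union of truly
   and implicitly labeled patients.

The prognostic score is the **prediction similarity index (PSI)**, the
ratio of the network's positive to negative predicted probability. With a
two-class softmax head the probabilities sum to one, so PSI > 1 is
equivalent to a positive probability above one half; a PSI of exactly 1
(equal probabilities) is assigned to the low group under the strict
inequality. An epsilon guard (1e-12 on the denominator) keeps PSI finite
when the negative probability underflows to zero.

## PNU risk estimation

Let $\ell$ be a margin loss (logistic by default, $\ell(0)=\ln 2$) and
$\pi_p$ the positive class prior. The supervised risk is

$$R_{PN}(g) = \pi_p\,\mathbb{E}_p[\ell(g)] + (1-\pi_p)\,\mathbb{E}_n[\ell(-g)].$$

Because the unlabeled marginal is the prior-weighted mixture of the class
marginals, the negative-class term can be estimated *without negative
labels*:

$$R_{PU}(g) = \pi_p\,\mathbb{E}_p[\ell(g)] +
  \big[\mathbb{E}_u[\ell(-g)] - \pi_p\,\mathbb{E}_p[\ell(-g)]\big],$$

and symmetrically $R_{NU}$. The combined objective interpolates with a
weight $\gamma \in [-1, 1]$: $(1-\gamma)R_{PN} + \gamma R_{PU}$ for
$\gamma \ge 0$ and $(1+\gamma)R_{PN} - \gamma R_{NU}$ for $\gamma < 0$;
the endpoints reproduce the three risks exactly (this identity is tested
bitwise). The bracketed implicit terms are unbiased but can go negative
in small samples; the default non-negative correction clamps them at
zero (toggleable, because unbiasedness itself is checked by a
Monte-Carlo test against a numerically integrated population risk).

Choices that the published formulation leaves open, and what this package
does:

* **Prior** $\pi_p$: the relapse prevalence among labeled training
  patients. Estimating the prior from unlabeled data is out of scope.
* **$\gamma$ selection**: no selection rule is prescribed anywhere, so
  the package cross-validates the PN risk on the labeled samples over the
  grid $\{-0.5, -0.25, 0, 0.25, 0.5, 0.75, 1\}$ (5 folds by default).
* **Optimizer**: deterministic full-batch gradient descent on a
  standardized feature scale, step 0.1 halved whenever the penalized risk
  increases, convergence at relative change below 1e-8, cap 2000
  iterations. Determinism matters more here than speed: fits are
  bit-reproducible and invariant to sample duplication.
* **"Maximized prediction probability"** is ambiguous between risk
  minimization and probability maximization; the package implements risk
  minimization, the canonical reading for PNU classification.
* Implicit labels are hard (sign of the score, ties negative) with a
  confidence $1/(1+e^{-|s|})$; one labeling round only, no iterative
  self-training.

## The network

No deep-learning framework with 3D convolutions is part of this package's
dependency stack, so the network is implemented natively: im2col-based
3x3x3 convolutions (BLAS matrix products), 2x2x2 max pooling, residual
blocks with identity or projection shortcuts, global average pooling and
a two-way softmax head, with exact reverse-mode gradients (verified
against numeric differentiation).

The topology is an 18-layer-style residual network moved to 3D with stage
widths (16, 32, 64, 128) rather than the canonical (64, ..., 512) - the
last width must be 128 so that average pooling emits exactly 128
features, which is the externally fixed quantity. Two input channels
carry the PET (z-scored SUV) and CT (min-max scaled) ROI; a PET-only
switch exists. Batch normalization is deliberately omitted: with cohorts
of tens of patients, batch statistics are noisy and break bitwise
reproducibility; instead the residual-branch closing convolutions are
down-scaled at initialization, which keeps deep signal propagation stable
at this depth. The softmax head starts at zero, so an untrained network
predicts 0.5/0.5 - a useful symmetry anchor for tests.

Training hyperparameters (Adam, learning rate 1e-3, batch 8, cap 60
epochs, early stopping on a stratified 15% validation split with patience
10, inverse-class-frequency loss weights, augmentation off by default)
are package defaults, not claims about the original study, which reports
none of them. With a fixed seed and single-threaded BLAS, full training
runs are bit-reproducible; the experiment harness relies on this.

Step 4 *retrains from scratch* with the same seed family rather than
fine-tuning the baseline (a `finetune` flag provides the alternative).
Retraining makes the zero-weight degeneracy exact: with unlabeled weight
0 the retrained network is bit-identical to the fully supervised (CDL)
run, which doubles as a strong pipeline integrity test.

## The synthetic cohort

No public data exist for this disease setting (the motivating cohort is
single-center and private), so the simulator is a first-class module that
reproduces the *statistical structure* the method assumes, not PET
physics:

* 84 labeled patients (64 train / 20 test, relapse ratio preserved up to
  integer rounding) followed 24-60 months, plus 83 unlabeled patients
  with 1-24 months of follow-up, allocated 39/29/15 across three scanner
  profiles with voxel sizes 5.47 mm isotropic, 2.7 x 2.7 x 2.79 mm and
  1.6 x 1.6 x 1.5 mm; each profile also sets a Gaussian point-spread
  FWHM (6 / 4 / 3 mm) and an additive SUV noise level (0.15 / 0.10 /
  0.08). Labeled patients are acquired on the first profile.
* One axis-aligned ellipsoidal lesion per patient, with log-normal mean
  SUV, semi-axes and multiplicative texture-field variance; the latent
  relapse class shifts these distributions by `effect_size` (default 1.5
  log-scale SDs for uptake, half that for size and texture). Effect size
  0 makes the classes indistinguishable; separability is monotone in the
  effect size by construction, and both properties are tested on the
  sampled parameters directly.
* PFS is exponential with class hazards 0.08 and 0.005 events/month, so
  about 85% of relapse-prone and 11% of non-relapse patients have an
  observed event by 24 months - a realistic separation for an aggressive
  lymphoma. The supervised label is the *observed* event indicator, so
  label noise relative to the latent class exists by design.
* Clinical covariates (age, gender, LDH, ECOG, EBV-DNA,
  beta2-microglobulin, Ann Arbor stage, B symptoms) are class-correlated
  draws (uniform / binomial / log-normal by type) with a configurable
  association strength, so multivariate Cox analysis has signal.
* The relapse prevalence within the labeled splits is not published;
  the default 0.3 is configurable and nothing downstream depends on it.
* The unlabeled pool's prevalence defaults to the labeled prevalence
  (the PNU prior assumption) and can be set separately to study prior
  misspecification.

What the simulator does **not** emulate: reconstruction algorithms,
sinograms, attenuation, multi-lesion disease, irregular lesion shapes,
and inter-scanner biases beyond resolution/noise/voxel geometry. Passing
tests therefore demonstrate that the pipeline's machinery behaves as
specified under its own assumptions - not clinical performance on real
PET/CT.

## Preprocessing and PET metrics

ROIs are physical cubes (default 96 mm - large enough to cover simulated
lesions at all three voxel geometries) centred on the mask centroid and
trilinearly resampled to 32^3 voxels (16^3 in the fast test and
acceptance configurations). Voxel indices are 0-based, crop windows are
half-open, and out-of-grid samples take the per-channel background value
(0 after normalization). PET normalization uses the training cohort's
in-ROI mean/SD, frozen and reused at test time so no test-set statistics
leak into preprocessing.

SUVmax, SUVmean, MTV and TLG follow the fixed-fraction convention: the
MTV segmentation keeps mask voxels at or above 41% of SUVmax (a common
harmonization choice; the convention used in the motivating study is
unpublished, so the fraction is a parameter, not a claim), SUVmean is
averaged over that segmentation, and TLG = SUVmean x MTV. MTV is
non-increasing in the threshold fraction and all metrics are invariant
to voxel permutation - both tested.

## Survival evaluation

Kaplan-Meier estimation, the log-rank test and Cox proportional-hazards
fits (Efron tie handling, Wald intervals) are delegated to the standard
survival machinery behind this package's interfaces, and each is tested
against hand or brute-force oracles (product-limit hand examples,
hypergeometric log-rank tables, dense partial-likelihood grid searches,
CI coverage simulations). The time-dependent ROC/AUC uses the
cumulative-cases / dynamic-controls definition with IPCW weights from the
Kaplan-Meier estimate of the censoring distribution, implemented in the
package; with no censoring it reduces exactly to Mann-Whitney pair
counting, which is how it is tested. The default horizon is 24 months,
the cohort's defining follow-up window. Univariate screening
dichotomizes continuous variables at their median (published cutoff
tables for this setting mix medians with unexplained values, so the
median rule is applied uniformly) and applies no multiplicity
correction, matching the evaluation protocol it reproduces; the 0.05
significance threshold is used throughout.

## Problem sizes and numerical choices

The weakly-supervised-vs-supervised comparison (`wsdl_experiment()`)
uses the full cohort structure (84 labeled / 83 unlabeled) at 32^3 ROI
resolution with 8 training epochs per run and 10 seeds; one seed costs
roughly a minute on a single CPU core. Eight epochs is a deliberate
desk-scale operating point chosen from pilot training curves: both arms
are equally undertrained, so the comparison isolates the value of the
additional implicitly labeled data rather than optimizer budgets. Module
tests use 16^3 inputs and miniature cohorts; the acceptance script runs
a three-seed comparison at 16^3. Tolerances: bitwise identity where the
algebra is exact (risk endpoints, reproducibility), 1e-10 to 1e-12 for
hand oracles, 1e-4 for optimizer-vs-grid-search agreement, and
3-standard-error bands for Monte-Carlo checks.

## Known limitations

* The synthetic generator's realism is structural, not physical;
  absolute AUC values on it do not transfer to patients.
* The PNU stage is linear on deep features; nonlinear PNU heads are out
  of scope.
* Single index lesion per patient; multi-lesion aggregation is an
  extension point.
* Exact bit reproducibility assumes single-threaded BLAS; with threaded
  BLAS, results can differ at floating-point rounding level.
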