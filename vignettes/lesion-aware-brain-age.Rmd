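---
title: "Lesion-aware brain age and the prediction of glioma-related epilepsy"
author: "lesionBAI authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lesion-aware brain age and the prediction of glioma-related epilepsy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionBAI)
```

## The problem

Brain-age models regress chronological age on structural T1-weighted MRI and
interpret the residual — the brain-age gap — as a marker of accelerated or
decelerated aging. They assume globally intact anatomy, which a glioma
violates: the tumor and its peritumoral edema dominate any naive feature
extraction. `lesionBAI` implements a lesion-aware variant of the approach
for neuro-oncology: the network sees only non-tumorous tissue, its raw
output is bias-corrected, and the residual is normalized into a bounded,
age-comparable index that feeds a downstream classifier for glioma-related
epilepsy (GRE).

The package is a complete, desk-scale implementation: every stage runs on
synthetic 3D phantoms shipped with the package, so the full pipeline is
testable without any clinical or consortium data.

## The model

**Brain Age Network (BAN).** A 3D convolutional regressor in the VGG style:
isotropic 3×3×3 kernels, residual units with short-circuit connections, and
downsampling done exclusively by stride-2 convolutions (no pooling layers).
Before any feature extraction, voxels under the manually delineated lesion
mask (tumor core plus edema) are excluded — set to the background fill value
after z-score normalization, which itself uses only non-background,
non-lesion voxels. Because both normalization and exclusion ignore the mask
interior, predictions are *exactly* invariant to arbitrary intensity changes
inside the lesion; the test suite asserts bit-identical outputs under random
rewrites.

The irregular non-tumor region is mapped to a fixed-size input for the
regression head by **ROI-Align pooling**: the tight bounding box of the
remaining foreground is laid over the final feature map, divided into a
fixed output grid, and each cell averages trilinear-interpolated samples
(2 per axis by default, 1 sample meaning the cell center). The operator is
linear in the feature map and is materialized as a sparse matrix, so its
gradient is a transpose product.

**Training protocol.** Bin-weighted L1 loss — subjects are grouped into
10-year age bins and weighted inversely to bin occupancy, normalized to
mean 1, which equalizes each bin's total contribution — optimized with Adam
(learning rate 0.001, weight decay 1e-6, beta1 0.9, beta2 0.999). The
learning rate halves when the training loss plateaus for 5 consecutive
epochs; training stops early after 20 epochs without validation-MAE
improvement, restoring the best weights. Subjects are split 70/10/20
(train/validation/test) by stratified largest-remainder rounding, and
5-fold cross-validation on the training subset is available for
hyperparameter selection (`crossValidateBan()`).

One numerical choice deserves note: the network regresses the
*standardized* age (center and scale frozen from the training split,
stored with the model, un-scaled at prediction). With ages spanning decades
a scalar L1 target makes the regression head traverse a distance of many
tens of units, which Adam at the protocol learning rate covers only after
hundreds of epochs; standardizing the target makes all optimization
distances O(1) without touching the protocol constants. Reported losses and
MAEs are always in years.

**Bias correction and the Brain Age Index.** Raw predictions regress toward
the training mean, making the raw gap age-dependent. On a healthy reference
cohort the package fits ordinary least squares of predicted on
chronological age Ω (slope α, intercept β) and freezes the cohort MAE, then
corrects every prediction as

> corrected = predicted + [Ω − (αΩ + β)] + MAE

On a noiseless linear cohort this removes the age trend exactly:
corrected − Ω is the constant MAE term for every subject (an exact test).
The MAE offset shifts all corrected ages upward by a constant; whether a
signed or cohort-centered term was intended is ambiguous, so the formula is
implemented as stated with an `includeMae = FALSE` flag for the purely
linear correction. The normalized index

> BAI = (corrected − Ω) / (corrected + Ω)

is strictly inside (−1, 1) for positive inputs, increasing in corrected
age, decreasing in Ω, and invariant to rescaling both by a common positive
factor.

**GRE prediction.** Radiomic features are extracted from the lesion region
(the package implements a compact, fully specified 19-feature set:
11 first-order statistics including a 32-bin histogram entropy, 4 shape
features, and 4 gray-level co-occurrence features at distance 1 averaged
over the 13 unique 3D directions after 32-level quantization; any
externally computed feature CSV is accepted equally). Selection proceeds
as: Mann-Whitney filter at raw p < 0.05 (no multiplicity correction at this
stage), Spearman pruning of clusters with |ρ| > 0.9 (strict; the
representative is the member with the smallest filter p, ties broken
lexicographically), greedy iterative redundancy reduction (drop the feature
with the highest mean absolute correlation while any pair exceeds a
secondary 0.8 threshold — "redundancy reduction preserving descriptive
power" names a goal, not a rule, so this greedy reading is our documented
interpretation), and finally
L1-penalized logistic regression with the penalty chosen at the minimum
mean 10-fold cross-validated deviance (the minimum-criteria rule, not the
1-SE rule). Nonzero-coefficient features form the radiomic signature; the
score is their standardized linear combination with the standardization
frozen at selection time.

Two gradient-boosted classifiers — radiomic and clinical (chronological
age, tumor grade, BAI, and by default sex) — are tuned by random search
over the grid {learning rate 0.01/0.05/0.1; leaves 31/63/127; depth
5/7/10/−1; min data in leaf 20/50; L1 and L2 0/0.1/0.01; feature fraction
0.8/0.9/1.0}, maximizing mean AUC over a seed-fixed stratified 5-fold
split shared between both models. Their out-of-fold probabilities — each
subject scored by the model that never saw it — are stacked by a logistic
regression; the stacking fit never sees in-fold probabilities, and the
`FusionModel` records the fold map and OOF streams so tests can assert the
hygiene. The operating threshold is Youden's J on the training OOF fusion
probabilities, frozen before test evaluation. AUC intervals use a seeded
stratified bootstrap (2000 resamples, percentile).

The boosting backend is xgboost run as a leaf-wise gradient-boosted tree
learner; the search-space fields map onto `max_leaves` (loss-guided
growth), `min_child_weight` (via the 1/4 hessian bound of the logistic
loss), `alpha`/`lambda` and `colsample_bytree`. The contract is any GBDT
learner honoring those fields.

## The phantom generator

`generateCohort()` builds cohorts whose structure encodes age in two ways a
small network can recover and a closed form can verify: a central
ventricle-like sphere whose radius grows linearly with *effective age*
(Ω plus the planted aging shift; 0.06 voxels/year by default, plus a small
subject-level jitter so the summary stays non-degenerate when the signal
strength is set to 0), and a bright cortical band whose thickness shrinks
linearly with effective age. Both survive per-volume z-scoring, which a
global intensity drift would not. Noise is additive homoscedastic Gaussian
— the simplest model supporting power reasoning.

Glioma subjects receive an off-center ellipsoidal core with an edema shell
produced by binary dilation (2 voxels by default); the mask is the union.
Placement retries keep the lesion's overlap with the ventricular region
under a configurable fraction (5%), with a final carve-out guaranteeing the
invariant, so lesion exclusion can never erase the age signal.

The label model resolves a circularity in the design: the configuration
states per-group aging shifts *and* a logistic label model on grade and the
aging perturbation. The generator draws a latent perturbation z ~ N(0, 1)
per glioma subject, assigns epilepsy ~ Bernoulli(plogis(−0.6 − 0.4·highGrade
− 0.5·z)), and sets the true shift to the group mean (15 years-equivalent
non-epileptic, 10 epileptic) plus 2·z. Group mean shifts then match the
configured values, the label depends on grade and the perturbation with the
correct sign (larger perturbation → less likely epileptic), and the
control < epileptic < non-epileptic ordering of accelerated aging is known
by construction. Defaults mirror the study conditions the framework
targets: ages uniform on 20–85, 30% glioma prevalence, 70% high grade,
≈30% GRE among gliomas, and shifts placed so that mean BAI at Ω ≈ 50 lands
near 0.10 (epileptic) and 0.13 (non-epileptic) against ≈0.02 for controls.
Epileptic lesions are additionally given higher internal texture variance,
so the radiomic stream carries a genuine (deliberately strong) label
signal.

What the phantoms do *not* emulate: MRI physics, bias fields, registration
error, multi-site effects, and clinical effect sizes. Phantom effects are
larger and cleaner than clinical reality — the fusion classifier typically
separates phantom GRE perfectly, where the clinical problem is much harder — so passing tests demonstrate correctness of the machinery,
not clinical performance. Reproducing cohort-level values (MAE 3.35/15.84
years, AUC 0.79/0.85) requires the original multicenter and consortium
images and is explicitly out of scope.

## Problem sizes and numerical choices

Desk-scale defaults keep every stage tractable on one CPU: 32³ phantoms at
2 mm isotropic spacing, a 2-stage network with 4/8 channels for tests and
pipeline defaults (the `BanConfig` default is 3 stages, 16/32/64,
configurable upward), ≈340 subjects and ≤ 25 epochs for the end-to-end
recovery runs, batch size 8. Convolutions are evaluated by im2col gathers
plus BLAS products with hand-derived gradients (verified against numerical
differentiation); single-threaded BLAS gives bit reproducibility under
fixed seeds. Degenerate inputs are handled explicitly: constant included
regions reject normalization, a mask covering all foreground raises an
"empty ROI" error, constant feature columns are dropped with a warning
before correlation graphing, exact zeros define image background, masks
binarize at 0.5, and two empty masks have Dice 1 by definition.

Other interpretation decisions, made once and kept: the printed weight
decay of "1 × 10^6" is read as a slip for 1e-6 (the former would zero the
network); the mask-QC ICC(2,1) is computed on per-subject lesion volumes
from two raters, the only unit that supports a two-way single-measure ICC
directly; the healthy cohort both trains the network and fits the bias
correction (the framework's "brain age equals chronological age in healthy
subjects" premise), with joint training available via the splits argument;
the Mann-Whitney test uses the exact U tail for tie-free samples with
n ≤ 12 and a tie- and continuity-corrected normal approximation otherwise.

## Limitations

The network is intentionally small; at clinical resolution (~91³ at 2 mm)
training would need a compiled or GPU backend. The radiomic set is compact
rather than exhaustive (no wavelet/filtered-image features). The iterative
redundancy-reduction rule is one defensible reading of an underspecified
procedure. The fusion stage assumes two probability streams; extending to
more modalities is mechanical but not implemented.

## A short tour

```{r tour, eval = FALSE}
coh <- generateCohort(PhantomConfig(nSubjects = 120, seed = 1))
subj <- subjectTable(coh)
controls <- which(subj$grade == "none")
sp <- lapply(splitDataset(subj[controls, ], seed = 2),
             function(i) controls[i])
fit <- trainBan(cohortVolumes(coh), cohortMasks(coh), subj$age, sp,
                BanConfig(convChannels = c(4L, 8L), maxEpochs = 15L))
bc <- fitBiasCorrection(fit@biasFitInputs$predicted, fit@biasFitInputs$age)
pred <- predictAges(fit, cohortVolumes(coh), cohortMasks(coh))
tab <- agePredictionTable(subj$id, pred, subj$age, bc)
head(tab)
```

The full pipeline, including feature selection and fusion, is one call:

```{r pipeline, eval = FALSE}
manifest <- runPipeline(outDir = "run", seed = 1, verbose = TRUE)
```
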