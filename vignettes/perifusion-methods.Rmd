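---
title: "Methods: dual-loss image features, multimodal fusion, and their evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-loss image features, multimodal fusion, and their evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Severe periodontitis is visible on a panoramic dental radiograph as alveolar
bone loss, and it co-occurs with a range of systemic diseases (anemia,
neurological disorders, cardiovascular disease among the best documented).
`perifusion` implements a two-phase multimodal classifier that asks how much
of a patient's systemic disease-chapter membership can be predicted from oral
data alone: a radiograph plus eight routine demographic/clinical features
(age, gender, income, tooth count, periodontal stage, and three bone-loss
measures).

Real paired dental-medical cohorts are essentially never public, so the
package ships a synthetic-cohort generator with the same statistical
skeleton, which makes every downstream stage testable end to end and gives
closed-form oracles for what each modality can achieve at best.

## Phase 1: the dual-loss autoencoder

Images $x^{(i)} \in [0,1]^{H \times W}$ are encoded by $Q_\phi$ to a latent
vector $z$, decoded back by $P_\theta$, and simultaneously classified by a
small dense head $D_\psi$ against the binary severity grouping (generalized
Stage III / Stage IV periodontitis vs everything milder). Training minimizes

$$L = \underbrace{\tfrac1N \sum_i \lVert x^{(i)} - P_\theta(Q_\phi(x^{(i)}))
\rVert^2}_{\text{reconstruction (MSE)}} \; + \; w_{ce}
\underbrace{\tfrac1N \sum_i -\big[y_i \log D_\psi(z_i) + (1-y_i)\log(1 -
D_\psi(z_i))\big]}_{\text{classification (cross-entropy)}}$$

with $w_{ce} = 1$ by default, i.e. the plain sum of the two losses. The MSE
gradient flows through decoder and encoder, the cross-entropy gradient
through head and encoder; both update the shared encoder jointly per batch.
The point of the second loss is that reconstruction alone has no reason to
prioritize a small, disease-relevant region; the classification term pulls
severity-discriminative structure into the latent code without any
pixel-level annotation. Setting `loss_weight_ce = 0` gives the
reconstruction-only ablation used to test exactly this claim.

Architecture: three stride-2 3×3 convolution blocks (8, 16, 32 channels,
ReLU) and a dense map to the latent; the decoder mirrors them with 2×
nearest-neighbour upsampling, ending in a sigmoid; the head is three dense
layers with Leaky-ReLU (slope 0.01, a conventional choice — the slope is not
prescribed anywhere) and a sigmoid output. The networks are implemented
directly in R (im2col convolutions over BLAS matrix products, Adam
optimizer, all finite-difference-checked in the test suite); at desk scale
(32×32 to 64×64 inputs) this trains in seconds to a minute on one CPU core.
We deliberately omit the bidirectional ConvLSTM skip stage of the BCDU-Net
family that inspired the reconstruction path: at these resolutions the
dual-loss mechanism, not the skip dialect, is what carries the method.

Training recipe (defaults): Adam, batch 32, 10 epochs at learning rate 1e-4
followed by 10 refinement epochs at 1e-5. The full latent vector feeds the
head (no pooling). `latent_dim` defaults to 128; 8192 is available to mirror
the full-resolution feature count and only matters at radiograph resolution.
All initialization, shuffling and dropout run off a single seed, so training
is bit-reproducible on one machine.

## Phase 2: the three-branch fusion classifier

The frozen latent features (no fine-tuning through the encoder — the
pipeline is strictly two-phase) and the eight tabular features enter
separate branches: $N_1$ compresses the image features to 32 units, $N_2$
lifts the tabular features to 32 units, so neither modality dominates the
concatenation; the joint trunk $N_3$ (dense 64 → 32 with dropout 0.5
between dense layers, each unit $u_i = \mathrm{ReLU}(\sum_p W_{ip} X_p +
b)$) emits the chapter probability. One independent binary classifier is
trained per disease chapter (learning rate 1e-4, batch 50, 300 epochs,
Adam). The branch widths and dropout rate are not published for the original
model; equal widths and 0.5 are our defaults, both configurable. Both
feature blocks are z-scored with training-set statistics before entering the
model — the raw scales (income vs stage code) differ by orders of magnitude
and would otherwise dominate early training.

Unimodal variants simply drop one branch; the trunk then consumes the
surviving 32 units. Classification uses a 0.5 threshold for hard labels
unless configured otherwise.

Class balance: a chapter's training set is downsampled (majority class
reduced to the minority count, minority always kept intact) only when the
majority exceeds **double** the minority — our reading of "extremely
unbalanced"; milder imbalance is left untouched. Balancing happens after the
70/30 split and inside each CV training fold, never on test data; the order
is not prescribed by the source description, and doing it this way prevents
test-set leakage.

## Evaluation harness

* **Splits.** Stratified 70/30 train/test, then stratified ten-fold CV on
  the training portion (fold sizes differ by at most one; positives fill
  folds round-robin and negatives continue the cycle).
* **AUC.** Mann–Whitney statistic with half credit for ties. The ROC curve
  enumerates all distinct thresholds.
* **Confidence intervals.** DeLong structural-components variance with a
  normal approximation, clipped to [0, 1] — chosen (the source does not say
  how its CIs were computed) so that single-AUC intervals and the paired
  test share one variance machinery. A degenerate variance (perfect
  separation at small n) is widened by a continuity rule and flagged.
* **Paired comparison.** DeLong's two-sided test on the placement-value
  covariances; verified in the tests against `pROC` to 1e-10 and against a
  paired bootstrap, and calibrated under a 2000-replicate null (rejection
  rate 0.05 ± 0.01 at α = 0.05).
* **Threshold metrics.** Accuracy, sensitivity, specificity, precision, F1
  (harmonic mean identity enforced on every report), and row-normalized
  confusion matrices. The "± spread" on test metrics is the standard
  deviation across `n_refits` refits with fresh balancing/initialization
  seeds, which is our explicit operationalization of reported spreads whose
  definition is otherwise unstated.

No multiple-testing correction is applied across chapters, matching the
original analysis.

## Interpretability

* **Grad-CAM** against the last encoder convolution with the severity logit
  as class score: channel weights are spatially averaged gradients, the map
  is the ReLU of the weighted activation sum, bilinearly upsampled and
  min–max normalized. The target layer is configurable; the classification
  path is the one worth visualizing because it is what the dual loss adds.
* **Localization score**: the fraction of heat mass inside the planted
  lesion mask. Its chance baseline is the mask's area fraction (a uniform
  map scores exactly that), so "the saliency found the lesion" becomes the
  quantitative statement `mean score > area fraction` over test images.
* **PCA projection** of the latent space to 2-D (deterministic up to our
  sign convention: each component's largest loading is positive), with the
  mean silhouette width by severity as the quantitative surrogate for "the
  classes form two clusters".

## The synthetic cohort

Each subject carries a latent risk $s \sim N(0,1)$ decomposed into
independent parts $s = s_{img} + s_{tab} + s_{res}$ with variances
$w_{img}$, $w_{tab}$, $1 - w_{img} - w_{tab}$. Severity is $s$ above the
quantile giving an expected severe fraction of 45.8% (544/1188, the split of
the source cohort). The image is a schematic tooth-row texture with a bright
alveolar-crest band; severe subjects get the central band section eroded by
`lesion_effect`, graded by $s_{img}$, plus Gaussian pixel noise — anatomical
realism is out of scope, but the property that the disease signal is
*spatially localized* (what Grad-CAM must find) is preserved, and the
planted mask marks exactly the pixels whose expected intensity differs
between labels. The seven continuous clinical features load linearly on the
standardized tabular component $z_{tab}$ only (gender is an independent
Bernoulli(0.61), the cohort's female share). Loading the features on
$s_{tab}$ rather than on total $s$ keeps the two modalities' information
disjoint, which is what makes unimodal and fused Bayes performance
analytically known — the design goal that motivated the decomposition.
Chapter labels are conditionally independent given risk and follow
$\mathrm{logit}(p_c) = \alpha_c + \beta_{img} s_{img} + \beta_{tab} s_{tab}$
with $\alpha_c$ solved numerically so the marginal prevalence matches its
target (logistic-normal mean). Nothing is known about real chapter
co-occurrence structure beyond prevalence, so none is modelled.

Missing values are injected only into the three bone-level columns
(mirroring the real cohort, where the alveolar bone level was occasionally
unmeasurable), and mean imputation fills them.

Default conditions: n = 400, 32×32 images, `lesion_effect` 0.5, signal
weights 0.35/0.35, pixel noise sd 0.05, β = 2 per modality, 14 chapters at
plausible adult prevalences. Two named regimes are used in the acceptance
experiments: the *dual-signal* regime (weights 0.5/0.5, strong lesion, low
noise) where both modalities are informative and fusion must beat each
alone, and the *low-contrast* regime (`lesion_effect` 0.25, noise sd 0.15)
where the lesion is a small share of image variance, giving the
classification loss room to demonstrate its benefit over reconstruction-only
training. What passing these tests does **not** show: robustness to
anatomical variability, acquisition artifacts, site effects, or label noise
of real radiographs and EHR codes — the generator has none of those.

## Numerical choices and degenerate inputs

* Cross-entropy probabilities are clipped at 1e-7 before the log.
* AUC requires both classes; single-class folds are skipped with a warning.
* Precision (and F1) with an empty predicted-positive set is reported `NA`.
* An all-zero Grad-CAM map (no positive gradient) warns and scores `NA`.
* PCA on zero-variance latents and imputation of an all-missing column are
  errors, not silent results.
* Images round-trip through 8-bit PNG; tabular values are generated at
  record precision (fixed decimals) so CSV round trips are exact.
* The problem sizes used by the test-suite experiments (n = 400 cohorts,
  five seeds, 32×32 images, latent 128) were chosen so the full suite and
  the acceptance script each complete comfortably on a single CPU core
  while keeping the Monte-Carlo bands meaningful.

## Known limitations

DICOM input is not supported (no reader in the dependency set); convert to
grayscale PNG first. The encoder is a plain convolutional stack, not the
full BCDU-Net. Probabilities are not calibrated, chapters are modelled
independently, and the synthetic cohort's closed-form convenience is also
its main departure from reality: real modalities share information, so real
fusion gains will be smaller than the generator's.
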