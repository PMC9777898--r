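# perifusion

Predicting systemic disease-chapter membership from oral health data, by
fusing panoramic-radiograph image features with routine clinical records.

Severe periodontitis shows up on a panoramic radiograph as alveolar bone
loss and is epidemiologically linked to systemic conditions — anemia,
neurological disorders, cardiovascular disease among others. `perifusion`
implements a two-phase multimodal pipeline for this prediction problem,
together with the synthetic benchmark, evaluation harness and
interpretability tooling needed to study it without access to a private
hospital cohort:

1. **Phase 1 — dual-loss autoencoder.** An encoder/decoder network is
   trained on the images with the sum of two losses,
   `L = MSE(x, x̂) + w·CE(y, D(z))`: reconstruction plus classification of
   the latent code `z` against binary periodontal severity (generalized
   Stage III / Stage IV vs milder). The classification term pulls
   disease-related structure into the latent space without any pixel
   annotation; `w = 0` gives the reconstruction-only ablation that tests
   that claim. The latent vector is the image feature set.
2. **Phase 2 — three-branch fusion classifier.** Per disease chapter, a
   binary network takes the (frozen) latent features through branch `N1`
   and the eight clinical features (age, gender, income, tooth count,
   periodontal stage, three bone-loss measures) through branch `N2`, each
   to 32 units so neither modality dominates, concatenates them into trunk
   `N3` (dense + ReLU, dropout between layers), and emits the chapter
   probability. Image-only and tabular-only variants drop a branch.

The evaluation harness provides stratified 70/30 splits, ten-fold
cross-validation, Mann–Whitney AUC with DeLong confidence intervals,
DeLong's paired AUC comparison test, downsampling-based class balancing,
threshold metrics (accuracy, sensitivity, specificity, precision, F1) with
refit spreads, and normalized confusion matrices. Interpretability tools
compute Grad-CAM saliency over the encoder's classification path — scored
quantitatively against the generator's planted lesion masks — and 2-D PCA
projections of the latent space with severity silhouettes.

All networks are implemented directly in R (im2col convolutions over BLAS
matrix products, Adam), finite-difference-verified in the test suite, and
sized so everything runs in minutes on one CPU core.

## Worked example

```r
library(perifusion)

# a 400-subject synthetic cohort in which both modalities carry signal
spec <- cohort_spec(n_subjects = 400, image_signal_weight = 0.5,
                    tabular_signal_weight = 0.5, seed = 1)
cohort <- generate_cohort(spec)
cohort
#> Synthetic cohort: 400 subjects, 32x32 images, 14 chapters; severe fraction 0.453

# phase 1: dual-loss autoencoder on the training subjects
config <- run_config(seed = 1, cohort = spec)
p1 <- run_phase1(cohort, config)
tail(p1$ae$history, 1)[, c("epoch", "mse", "ce", "total")]
#>    epoch        mse         ce    total
#> 21    20 0.08225726 0.08335677 0.165614

# phase 2: fused + unimodal chapter models, DeLong comparisons
config$chapters <- "ch_IX"   # circulatory-system chapter
p2 <- run_phase2(p1, cohort, config, run_cv = FALSE)
p2$ch_IX$fused
#> Chapter ch_IX [fused]: test AUC 0.824 +/- 0.018
#>   acc 0.77 sens 0.73 spec 0.80 prec 0.71 F1 0.72
p2$ch_IX$delong$fused_vs_tabular
#> DeLong paired test: AUC 0.8367 vs 0.7494, z = 2.062, p = 0.03916
```

The fused test AUC exceeds both unimodal models, and the paired DeLong test
quantifies the gain over the weaker modality on the shared test subjects.
The per-epoch history shows both loss components falling during phase 1;
`linear_probe_auc()`, `pca_project()`/`silhouette_by_label()` and
`grad_cam()`/`localization_score()` then measure how much severity signal
the latent space carries and where in the image the model found it.

A command-line front end with `simulate` / `phase1` / `phase2` / `demo`
subcommands lives at `inst/cli/perifusion.R`:

```sh
Rscript inst/cli/perifusion.R demo --seed 1 --out demo_out
```

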