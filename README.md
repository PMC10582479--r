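# mggan

Adversarial translation of hematoxylin–eosin (HE) stained histopathology
images into immunohistochemistry-like (IHC) images, in pure R.

Obtaining IHC sections — the standard readout for diagnostic markers such as
HER2 in breast cancer — is expensive; HE sections are cheap and routine.
Paired image-to-image translation offers a computational substitute: learn
the HE→IHC mapping from registered image pairs. This package implements a
multi-generator conditional GAN for that task, together with everything
needed to exercise it at desk scale: a procedural generator of paired
stain-like images stratified by HER2-style expression grade (0, 1+, 2+, 3+),
full-reference quality metrics, ablation and weight-sweep harnesses, and a
command-line interface. Because no deep-learning framework is required, the
package ships its own reverse-mode automatic-differentiation and
convolution engine, validated against finite-difference gradients.

## The model

**Generator.** Two U-shaped encoder–decoder networks (stride-2 encoders,
nearest-neighbour-upsampling decoders, skip connections, residual
bottleneck) operate at different spatial scales: the fine branch sees the
input at native resolution; the coarse branch sees it average-pooled by a
factor *s* (default 2) and its output is upsampled back. The branch feature
maps are concatenated and projected by a learned 1×1 convolution to RGB,
with a sigmoid mapping the translated image ŷ = G(x) into (0, 1).

**Discriminator.** The candidate image (paired channel-wise with its source
in conditional mode) is partitioned into a 4×4 grid of 16 independent
patches; one shared convolutional encoder ends in a sigmoid probability per
patch, and the discriminator's output is the mean patch probability —
emphasising local, high-frequency realism.

**Objective.** With D(x,·) the patch-averaged conditional discriminator:

    L_final = L_cGAN(G, D) + λ₁ · L_L1(G) + λ₂ · L_cross(G)

where `L_L1 = E‖y − G(x)‖₁` (mean absolute error),
`L_cross = −E[ y·log G(x) + (1−y)·log(1−G(x)) ]` is a pixel-wise
cross-entropy consistency regulariser, and the adversarial term is either
the log form (BCE discriminator, non-saturating generator) or the
least-squares form. Defaults λ₁ = 100, λ₂ = 10; λ₂ = 0 recovers the
classic conditional-GAN-plus-L1 objective. Training uses Adam
(β₁ = 0.5, β₂ = 0.999, learning rate 1e-4 for both networks) with
alternating one-discriminator/one-generator updates per pair.

**Metrics.** MSE, PSNR = 10·log₁₀(MAX²/MSE) in dB, and SSIM
(whole-image moments by default, Gaussian sliding window optional) on the
normalised [0, 1] intensity scale.

## Worked example

Generate a paired synthetic dataset, fit the translator at desk scale, and
evaluate it against the untranslated copy baseline:

```r
library(mggan)

params <- stain_scene_params(canvas_size = 32, n_nuclei = 6,
                             nucleus_radius_range = c(2, 4),
                             noise_sd = 0.02, seed = 1)
generate_dataset(80, rep(0.25, 4), params, "toy_ds", "paired_dirs")
split <- split_dataset(load_dataset("toy_ds"), 0.2, seed = 1)

mean(sapply(split$test, function(p) psnr(p$target, p$source)))
#> copy-baseline PSNR: 15.53 dB

fit <- mggan(
  split,
  train_config(epochs = 10, lr = 2e-3, seed = 1,
               weights = loss_weights(lambda1 = 100, lambda2 = 10)),
  multigen_spec(fine = unet_spec(depth = 2, base_channels = 8),
                coarse = unet_spec(depth = 2, base_channels = 8)),
  patch_grid_spec(grid = c(4, 4), encoder_depth = 2, base_channels = 8))
fit
#> Multi-generator adversarial stain translator
#>   trained 10 epochs on 64 pairs (32x32 px), gan_mode=log, lambda1=100, lambda2=10
#>   final step losses: total 8.6259 (adv 0.7192, l1 0.03784, cross 0.4123), d 1.3497
#>   test (16 pairs): PSNR 21.19 dB / SSIM 0.8008 / MSE 1.121e-02
```

The fitted translator reaches 21.2 dB test PSNR against the 15.5 dB copy
baseline: it has learned the stain mapping (background and nuclear
recolouring plus the average membrane-ring staining) rather than merely
reproducing its input. `predict(fit, image_or_pairs)` translates new
images; `discriminate(fit$discriminator, source, candidate)` exposes the
16 patch probabilities and their mean:

```r
discriminate(fit$discriminator, split$test[[1]]$source,
             predict(fit, split$test[[1]]))
#> <patch_scores> 4x4 grid, aggregate 0.4894
```

An aggregate near 0.5 means the discriminator can no longer tell the
translation from a real IHC image. `run_ablation()` compares the GGAN /
DGAN / MGGAN\* / MGGAN variants and `sweep_lambdas()` grids (λ₁, λ₂), both
on shared seeds.

## Command line

```sh
Rscript inst/cli/mggan.R simulate --n 80 --size 32 --seed 1 --out toy_ds
Rscript inst/cli/mggan.R train --data toy_ds --out run1 --epochs 10 --lr 0.002
Rscript inst/cli/mggan.R translate --model run1/model.rds --in toy_ds/A --out run1/pred --panels
Rscript inst/cli/mggan.R evaluate --ref toy_ds/B --cand run1/pred --out run1/eval.csv
```

Every command writes a `run_manifest.json` (resolved configuration,
package version, seed, timestamp) sufficient to reproduce it. Exit codes:
0 success, 64 usage, 65 validation, 74 I/O.

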