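#' Weights of the composite generator objective
#'
#' The final objective is `adv + lambda1 * L1 + lambda2 * cross`, balancing
#' the conditional adversarial term, the L1 reconstruction term and the
#' pixel-wise cross-entropy consistency term. The defaults (lambda1 = 100,
#' lambda2 = 10) are the values selected by cross-validated sweeps over
#' lambda1 in [80, 120] and lambda2 in [0.1, 100]. Setting `lambda2 = 0`
#' drops the consistency regulariser (the MGGAN* ablation).
#'
#' @param lambda1 Nonnegative L1 weight.
#' @param lambda2 Nonnegative cross-entropy weight.
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(lambda1 = 100, lambda2 = 10) {
  if (lambda1 < 0 || lambda2 < 0)
    stop_usage("loss weights must be nonnegative")
  structure(list(lambda1 = lambda1, lambda2 = lambda2),
            class = "loss_weights")
}

#' Generator adversarial loss
#'
#' `log` mode is the non-saturating form `-mean(log(score_fake))` (the
#' generator climbs the discriminator's probability of real); `lsgan` mode
#' is the least-squares form `0.5 * mean((score_fake - 1)^2)`.
#'
#' @param scores_fake `patch_scores` (or numeric vector) of the
#'   discriminator's probabilities on translated images.
#' @param mode `"log"` or `"lsgan"`.
#' @param eps Clamping constant applied before logs.
#' @return Scalar loss; tends to 0 as the generator fools the discriminator.
#' @export
generator_adversarial_loss <- function(scores_fake, mode = c("log", "lsgan"),
                                       eps = 1e-7) {
  mode <- match.arg(mode)
  sf <- scores_vector(scores_fake)
  if (length(sf) == 0) stop_validation("scores must be nonempty")
  if (mode == "log") -mean(log(clamp01(sf, eps)))
  else 0.5 * mean((sf - 1)^2)
}

#' L1 reconstruction loss
#'
#' Mean absolute difference over all pixels and channels between the target
#' image and the translated image.
#'
#' @param target,synthetic Arrays of identical shape.
#' @return Scalar loss >= 0.
#' @export
l1_loss <- function(target, synthetic) {
  check_same_shape(target, synthetic, "target and synthetic")
  mean(abs(target - synthetic))
}

#' Cross-entropy consistency loss
#'
#' Pixel-wise binary cross-entropy between a reference image `r` in [0, 1]
#' and the synthetic image `s` in (0, 1):
#' `-mean(r * log(s) + (1 - r) * log(1 - s))`, averaged over all pixels and
#' channels. Used as a regulariser that pulls the translated image towards
#' consistency with the real image; by default the training loop uses the
#' target stain image as the reference.
#'
#' @param reference Array in [0, 1].
#' @param synthetic Array of the same shape, strictly inside (0, 1) (the
#'   generator's sigmoid output guarantees this); values are clamped to
#'   `[eps, 1 - eps]` before logs.
#' @param eps Clamping constant.
#' @return Scalar loss >= 0.
#' @export
cross_entropy_consistency <- function(reference, synthetic, eps = 1e-7) {
  check_same_shape(reference, synthetic, "reference and synthetic")
  if (min(reference) < 0 || max(reference) > 1)
    stop_validation("reference must be in [0, 1]")
  s <- clamp01(synthetic, eps)
  -mean(reference * log(s) + (1 - reference) * log(1 - s))
}

#' Total generator objective
#'
#' Combines the adversarial, L1 and cross-entropy terms into
#' `total = adv + lambda1 * l1 + lambda2 * cross`. With `lambda2 = 0` this
#' reduces to the classic conditional-GAN-plus-L1 objective; with both
#' weights 0 it is the pure adversarial loss.
#'
#' @param scores_fake Discriminator scores on the translated image.
#' @param target Target stain image.
#' @param synthetic Translated image.
#' @param weights A [loss_weights()] object.
#' @param mode Adversarial mode, `"log"` or `"lsgan"`.
#' @param reference Reference image for the consistency term; defaults to
#'   `target` (set to the source image for the strict-letter variant).
#' @return A `loss_breakdown`: list with `adv`, `l1`, `cross`, `total`.
#' @export
total_generator_loss <- function(scores_fake, target, synthetic,
                                 weights = loss_weights(),
                                 mode = c("log", "lsgan"),
                                 reference = target) {
  mode <- match.arg(mode)
  if (!inherits(weights, "loss_weights")) {
    if (is.numeric(weights) && length(weights) == 2)
      weights <- loss_weights(weights[1], weights[2])
    else stop_usage("weights must be a loss_weights object")
  }
  adv <- generator_adversarial_loss(scores_fake, mode)
  l1 <- l1_loss(target, synthetic)
  cross <- cross_entropy_consistency(reference, synthetic)
  loss_breakdown(adv, l1, cross, weights)
}

loss_breakdown <- function(adv, l1, cross, weights) {
  structure(list(adv = adv, l1 = l1, cross = cross,
                 total = adv + weights$lambda1 * l1 + weights$lambda2 * cross,
                 weights = weights),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf(
    "<loss_breakdown> total %.4f = adv %.4f + %g * l1 %.5f + %g * cross %.4f\n",
    x$total, x$adv, x$weights$lambda1, x$l1, x$weights$lambda2, x$cross))
  invisible(x)
}
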