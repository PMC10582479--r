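# Every loss is checked against an independent scalar-loop oracle on random
# 4x4x3 images, plus its closed-form values.

loop_l1 <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + abs(a[i] - b[i])
  s / length(a)
}

loop_bce <- function(r, s) {
  acc <- 0
  for (i in seq_along(r))
    acc <- acc - (r[i] * log(s[i]) + (1 - r[i]) * log(1 - s[i]))
  acc / length(r)
}

test_that("generator adversarial loss has the stated closed forms", {
  half <- patch_scores(matrix(0.5, 4, 4))
  expect_equal(generator_adversarial_loss(half, "log"), log(2),
               tolerance = 1e-12)
  expect_equal(generator_adversarial_loss(half, "lsgan"), 0.125,
               tolerance = 1e-12)
  fooled <- rep(1 - 1e-12, 16)
  expect_lt(generator_adversarial_loss(fooled, "log"), 1e-5)
  expect_lt(generator_adversarial_loss(fooled, "lsgan"), 1e-10)
  expect_error(generator_adversarial_loss(numeric(0)),
               class = "mggan_validation_error")
})

test_that("L1 loss equals the element-wise loop oracle", {
  expect_identical(l1_loss(rand_image(4, 4, 1), rand_image(4, 4, 1)), 0)
  expect_equal(l1_loss(array(0.2, c(4, 4, 3)), array(0.5, c(4, 4, 3))), 0.3,
               tolerance = 1e-12)
  a <- rand_image(4, 4, seed = 11)
  b <- rand_image(4, 4, seed = 12)
  expect_equal(l1_loss(a, b), loop_l1(a, b), tolerance = 1e-7)
  expect_error(l1_loss(a, rand_image(5, 5)),
               class = "mggan_validation_error")
})

test_that("cross-entropy consistency equals the per-pixel loop oracle", {
  half <- array(0.5, c(4, 4, 3))
  expect_equal(cross_entropy_consistency(half, half), log(2),
               tolerance = 1e-12)
  ones <- array(1, c(4, 4, 3))
  expect_lt(cross_entropy_consistency(ones, array(1 - 1e-7, c(4, 4, 3))),
            1e-5)
  r <- rand_image(4, 4, seed = 13)
  s <- rand_image(4, 4, seed = 14, lo = 0.05, hi = 0.95)
  expect_equal(cross_entropy_consistency(r, s), loop_bce(r, s),
               tolerance = 1e-6)
  expect_gte(cross_entropy_consistency(r, s), 0)
})

test_that("total objective is the documented weighted sum", {
  scores <- patch_scores(matrix(runif(16, 0.2, 0.8), 4, 4))
  y <- rand_image(4, 4, seed = 15)
  yhat <- rand_image(4, 4, seed = 16, lo = 0.05, hi = 0.95)
  # with both weights zero the objective reduces to the adversarial term
  lb0 <- total_generator_loss(scores, y, yhat, loss_weights(0, 0))
  expect_equal(lb0$total, lb0$adv, tolerance = 1e-12)
  # dropping the cross term reproduces the cGAN + lambda*L1 objective
  lb_star <- total_generator_loss(scores, y, yhat, loss_weights(100, 0))
  expect_equal(lb_star$total, lb_star$adv + 100 * lb_star$l1,
               tolerance = 1e-12)
  # full objective on the default weights
  lb <- total_generator_loss(scores, y, yhat, loss_weights(100, 10))
  expect_equal(lb$total, lb$adv + 100 * lb$l1 + 10 * lb$cross,
               tolerance = 1e-10)
  expect_equal(lb$adv, generator_adversarial_loss(scores, "log"))
  expect_equal(lb$l1, l1_loss(y, yhat))
  expect_equal(lb$cross, cross_entropy_consistency(y, yhat))
  expect_error(total_generator_loss(scores, y, yhat, loss_weights(-1, 0)),
               class = "mggan_usage_error")
})

test_that("worked arithmetic: adv 0.5 + 100*0.01 + 10*0.02 = 1.7", {
  lb <- mggan:::loss_breakdown(0.5, 0.01, 0.02, loss_weights(100, 10))
  expect_equal(lb$total, 1.7, tolerance = 1e-12)
})

test_that("total is affine in the weights with slopes (l1, cross)", {
  scores <- patch_scores(matrix(runif(16, 0.2, 0.8), 4, 4))
  y <- rand_image(4, 4, seed = 17)
  yhat <- rand_image(4, 4, seed = 18, lo = 0.05, hi = 0.95)
  tot <- function(l1w, l2w)
    total_generator_loss(scores, y, yhat, loss_weights(l1w, l2w))$total
  base <- total_generator_loss(scores, y, yhat, loss_weights(50, 5))
  expect_equal((tot(51, 5) - tot(49, 5)) / 2, base$l1, tolerance = 1e-9)
  expect_equal((tot(50, 6) - tot(50, 4)) / 2, base$cross, tolerance = 1e-9)
})

test_that("training-graph loss nodes agree with the exported losses", {
  y <- rand_image(4, 4, seed = 19)
  yhat <- rand_image(4, 4, seed = 20, lo = 0.05, hi = 0.95)
  sc <- runif(16, 0.1, 0.9)
  node <- mggan:::ad_const
  expect_equal(mggan:::op_l1_to(y, node(yhat))$value, l1_loss(y, yhat),
               tolerance = 1e-12)
  expect_equal(mggan:::op_bce_to(y, node(yhat))$value,
               cross_entropy_consistency(y, yhat), tolerance = 1e-12)
  expect_equal(mggan:::op_negmeanlog(node(sc))$value,
               generator_adversarial_loss(sc, "log"), tolerance = 1e-12)
  expect_equal(mggan:::op_half_mean_sq(node(sc), 1)$value,
               generator_adversarial_loss(sc, "lsgan"), tolerance = 1e-12)
})
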