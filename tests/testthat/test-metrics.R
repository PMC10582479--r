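loop_mse <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + (a[i] - b[i])^2
  s / length(a)
}

test_that("mse equals the double-loop oracle and its closed forms", {
  a <- rand_image(6, 6, seed = 1)
  expect_identical(mse(a, a), 0)
  expect_equal(mse(array(0.3, c(4, 4, 3)), array(0.34, c(4, 4, 3))), 1.6e-3,
               tolerance = 1e-12)
  b <- rand_image(6, 6, seed = 2)
  expect_equal(mse(a, b), loop_mse(a, b), tolerance = 1e-10)
  expect_equal(mse(a, b), mse(b, a))
  expect_error(mse(a, rand_image(5, 5)), class = "mggan_validation_error")
})

test_that("psnr matches its closed form", {
  mk <- function(m) {
    ref <- array(0.5, c(10, 10, 3))
    list(ref = ref, cand = ref + sqrt(m))
  }
  p <- mk(0.01)
  expect_equal(psnr(p$ref, p$cand), 20, tolerance = 1e-9)
  # mse = max^2 gives 0 dB
  expect_equal(psnr(array(0, c(4, 4, 3)), array(1, c(4, 4, 3))), 0,
               tolerance = 1e-12)
  expect_equal(psnr(mk(1.59e-3)$ref, mk(1.59e-3)$cand),
               10 * log10(1 / 1.59e-3), tolerance = 1e-6)
  a <- rand_image(4, 4, seed = 3)
  expect_identical(psnr(a, a), Inf)
  # 8-bit convention
  expect_equal(psnr(array(0, c(2, 2, 3)), array(10 / 255, c(2, 2, 3)),
                    max_value = 1),
               20 * log10(255 / 10), tolerance = 1e-9)
})

test_that("ssim of an image with itself is exactly 1", {
  img <- rand_image(16, 16, seed = 4)
  expect_identical(ssim(img, img), 1)
  cst <- array(0.37, c(8, 8, 3))
  expect_identical(ssim(cst, cst), 1)   # degenerate moments, stabilisers rescue
})

test_that("global ssim matches a from-scratch moment computation", {
  cfg <- ssim_config()
  x <- rand_image(8, 8, seed = 5)
  y <- rand_image(8, 8, seed = 6)
  oracle <- mean(vapply(1:3, function(ch) {
    xi <- as.vector(x[, , ch]); yi <- as.vector(y[, , ch])
    n <- length(xi)
    mx <- sum(xi) / n; my <- sum(yi) / n
    vx <- 0; vy <- 0; cxy <- 0
    for (i in seq_len(n)) {
      vx <- vx + (xi[i] - mx)^2
      vy <- vy + (yi[i] - my)^2
      cxy <- cxy + (xi[i] - mx) * (yi[i] - my)
    }
    vx <- vx / n; vy <- vy / n; cxy <- cxy / n
    (2 * mx * my + cfg$c1) * (2 * cxy + cfg$c2) /
      ((mx^2 + my^2 + cfg$c1) * (vx + vy + cfg$c2))
  }, numeric(1)))
  expect_equal(ssim(x, y), oracle, tolerance = 1e-8)
  expect_equal(ssim(x, y), ssim(y, x))
  # bounded above by 1, equality only at identity
  expect_lt(ssim(x, y), 1 - 1e-12)
})

test_that("sliding-window ssim behaves like a local similarity", {
  x <- rand_image(24, 24, seed = 7)
  cfg <- ssim_config(window = "sliding")
  expect_equal(ssim(x, x, cfg), 1, tolerance = 1e-12)
  y <- pmin(pmax(x + array(rnorm(length(x), sd = 0.1), dim(x)), 0), 1)
  s <- ssim(x, y, cfg)
  expect_lt(s, 1)
  expect_gte(s, -1)
})

test_that("psnr decreases monotonically with noise level in expectation", {
  ref <- rand_image(16, 16, seed = 8, lo = 0.2, hi = 0.8)
  sds <- c(0.02, 0.05, 0.1, 0.2)
  set.seed(99)
  mean_psnr <- vapply(sds, function(s) {
    mean(replicate(10, {
      noisy <- pmin(pmax(ref + array(rnorm(length(ref), sd = s), dim(ref)),
                         0), 1)
      psnr(ref, noisy)
    }))
  }, numeric(1))
  expect_true(all(diff(mean_psnr) < 0))
})

test_that("evaluate_dataset aggregates per-image metrics consistently", {
  pairs <- toy_pairs(4, seed = 2, canvas = 16)
  # candidates equal to the references: perfect scores, PSNR excluded
  rep0 <- evaluate_dataset(pairs, candidates = lapply(pairs, `[[`, "target"))
  expect_equal(rep0$aggregate$ssim, 1)
  expect_equal(rep0$aggregate$mse, 0)
  expect_equal(rep0$n_psnr_excluded, 4)
  expect_true(is.na(rep0$aggregate$psnr_db))
  # aggregate PSNR is the arithmetic mean of per-image dB values
  ref <- array(0.5, c(8, 8, 3))
  mk_pair <- function(id) image_pair(ref, ref, id = id)
  cands <- list(ref + sqrt(0.1), ref + sqrt(0.01))   # 10 dB and 20 dB
  rep1 <- evaluate_dataset(list(mk_pair("a"), mk_pair("b")),
                           candidates = cands)
  expect_equal(rep1$aggregate$psnr_db, 15, tolerance = 1e-9)
  # self-consistency: aggregates recomputable from the per-image table
  expect_equal(rep1$aggregate$mse, mean(rep1$per_image$mse))
  expect_equal(rep1$aggregate$ssim, mean(rep1$per_image$ssim))
  expect_error(evaluate_dataset(list()), class = "mggan_validation_error")
  expect_error(evaluate_dataset(pairs, candidates = cands),
               class = "mggan_validation_error")
  # CSV report: one row per image plus the summary row
  f <- tempfile(fileext = ".csv")
  write_metric_report(rep1, f)
  df <- read.csv(f)
  expect_equal(nrow(df), 3)
  expect_equal(df$psnr_db[df$id == "summary"], 15, tolerance = 1e-9)
})
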