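# Training runs here are deliberately tiny (few pairs, 16-32 px, 1-3
# epochs): they exercise bookkeeping, determinism and resume semantics, not
# translation quality (which the learning test covers).

toy_config <- function(epochs, seed = 1, ...) {
  train_config(epochs = epochs, lr = 2e-3, seed = seed,
               weights = loss_weights(100, 10), ...)
}

test_that("train_config validates and carries the reference defaults", {
  cfg <- train_config()
  expect_equal(cfg$epochs, 200)
  expect_equal(cfg$lr, 1e-4)
  expect_equal(cfg$beta1, 0.5)
  expect_equal(cfg$beta2, 0.999)
  expect_equal(cfg$weights$lambda1, 100)
  expect_equal(cfg$weights$lambda2, 10)
  expect_error(train_config(epochs = 0), class = "mggan_usage_error")
  expect_error(train_config(lr = -1), class = "mggan_usage_error")
  expect_error(train_config(beta1 = 1), class = "mggan_usage_error")
})

test_that("one epoch over four pairs at batch size one runs four steps", {
  pairs <- toy_pairs(4, seed = 3)
  fit <- mggan(pairs, toy_config(1), tiny_gen_spec(), tiny_disc_spec())
  expect_equal(nrow(fit$history), 4)
  expect_equal(unique(fit$history$epoch), 1)
  expect_true(all(is.finite(fit$history$total)))
  expect_true(all(is.finite(fit$history$d_loss)))
  expect_true(all(is.finite(fit$history$l1)))
  expect_null(fit$test_report)
})

test_that("a train step updates both networks and reports finite losses", {
  pairs <- toy_pairs(2, seed = 4)
  tr <- mggan_trainer(tiny_gen_spec(), tiny_disc_spec(), 32, toy_config(1))
  g_before <- mggan:::params_snapshot(tr$gen$params)
  d_before <- mggan:::params_snapshot(tr$disc$params)
  res <- train_step(tr, pairs[1])
  expect_s3_class(res$g_loss, "loss_breakdown")
  expect_true(is.finite(res$g_loss$l1))
  expect_true(is.finite(res$d_loss))
  expect_false(identical(mggan:::params_snapshot(tr$gen$params), g_before))
  expect_false(identical(mggan:::params_snapshot(tr$disc$params), d_before))
  # Adam time step advanced once per network
  expect_equal(tr$opt$adam_g$t, 1L)
  expect_equal(tr$opt$adam_d$t, 1L)
})

test_that("identical seed, config and data give identical runs", {
  pairs <- toy_pairs(6, seed = 5)
  f1 <- mggan(pairs, toy_config(2, seed = 11), tiny_gen_spec(),
              tiny_disc_spec())
  f2 <- mggan(pairs, toy_config(2, seed = 11), tiny_gen_spec(),
              tiny_disc_spec())
  expect_identical(f1$history, f2$history)
  expect_identical(coef(f1), coef(f2))
  f3 <- mggan(pairs, toy_config(2, seed = 12), tiny_gen_spec(),
              tiny_disc_spec())
  expect_false(identical(f1$history, f3$history))
})

test_that("resuming from a checkpoint reproduces the uninterrupted run", {
  pairs <- toy_pairs(4, seed = 6)
  out1 <- file.path(tempdir(), "run_full")
  out2 <- file.path(tempdir(), "run_resumed")
  unlink(c(out1, out2), recursive = TRUE)
  cfg <- toy_config(3, seed = 21, checkpoint_every = 1)
  full <- mggan(pairs, cfg, tiny_gen_spec(), tiny_disc_spec(),
                out_dir = out1)
  resumed <- mggan(pairs, cfg, tiny_gen_spec(), tiny_disc_spec(),
                   out_dir = out2,
                   resume = file.path(out1, "ckpt_epoch2.rds"))
  expect_identical(full$history, resumed$history)
  expect_identical(coef(full), coef(resumed))
  ck <- load_checkpoint(file.path(out1, "model.rds"))
  expect_equal(ck$epoch, 3)
  expect_identical(mggan:::params_snapshot(ck$trainer$gen$params),
                   coef(full)$generator)
  expect_error(load_checkpoint(file.path(out1, "nope.rds")),
               class = "mggan_io_error")
})

test_that("generator loss trends downward within the first epoch", {
  pairs <- toy_pairs(16, seed = 7)
  fit <- mggan(pairs, toy_config(1, seed = 31), tiny_gen_spec(),
               tiny_disc_spec())
  h <- fit$history
  first_q <- mean(h$total[1:4])
  last_q <- mean(h$total[13:16])
  expect_lt(last_q, first_q)
  expect_true(all(is.finite(h$d_loss)))
})

test_that("fitted-model methods expose the standard interface", {
  pairs <- toy_pairs(6, seed = 8)
  split <- split_dataset(pairs, 1 / 3, seed = 1)
  fit <- mggan(split, toy_config(1, seed = 41), tiny_gen_spec(),
               tiny_disc_spec())
  expect_s3_class(fit$test_report, "metric_report")
  expect_output(print(fit), "stain translator")
  expect_output(print(summary(fit)), "generator")
  y <- predict(fit, pairs[[1]])
  expect_identical(dim(y), dim(pairs[[1]]$source))
  ys <- predict(fit, pairs[1:2])
  expect_length(ys, 2)
  cf <- coef(fit)
  expect_named(cf, c("generator", "discriminator"))
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("ablation variants differ only in their documented fields", {
  base <- toy_config(1, seed = 51)
  vg <- variant_config("GGAN", base)
  vd <- variant_config("DGAN", base)
  vs <- variant_config("MGGAN_star", base)
  vm <- variant_config("MGGAN", base)
  expect_null(vg$gen_spec$coarse)
  expect_setequal(vg$changed, c("lambda2", "coarse_branch"))
  expect_equal(vd$config$weights$lambda2, 0)
  expect_equal(vs$changed, "lambda2")
  # DGAN and MGGAN_star are the same configuration under different labels
  expect_identical(vd$config, vs$config)
  expect_identical(vd$gen_spec, vs$gen_spec)
  # MGGAN differs from MGGAN_star only in lambda2
  cfg_star <- vs$config; cfg_star$weights <- vm$config$weights
  expect_identical(cfg_star, vm$config)
  expect_length(vm$changed, 0)
  expect_error(variant_config("Pix2pix", base), class = "mggan_usage_error")
})

test_that("single-variant ablation and 1x1 sweep reduce to a direct fit", {
  pairs <- toy_pairs(6, seed = 9, canvas = 16)
  split <- split_dataset(pairs, 1 / 3, seed = 2)
  gs <- multigen_spec(unet_spec(2, 4), unet_spec(1, 4), 2)
  dsp <- patch_grid_spec(c(4, 4), 1, 4)
  cfg <- toy_config(1, seed = 61)
  ab <- run_ablation(split, cfg, "MGGAN", gs, dsp)
  expect_equal(nrow(ab$summary), 1)
  direct <- mggan(split, cfg, gs, dsp)
  expect_equal(ab$summary$psnr_db, direct$test_report$aggregate$psnr_db)
  sw <- sweep_lambdas(split, cfg, 100, 10, gs, dsp)
  expect_equal(nrow(sw$grid), 1)
  expect_equal(sw$grid$psnr_db, direct$test_report$aggregate$psnr_db)
  # grid bookkeeping: 2x2 grid gives 4 cells, and the reference operating
  # point (100, 10) sits inside the default grids
  sw2 <- sweep_lambdas(split, cfg, c(80, 100), c(0, 10), gs, dsp)
  expect_equal(nrow(sw2$grid), 4)
  expect_true(100 %in% eval(formals(sweep_lambdas)$lambda1_values))
  expect_true(10 %in% eval(formals(sweep_lambdas)$lambda2_values))
  expect_error(sweep_lambdas(split, cfg, numeric(0), 1, gs, dsp),
               class = "mggan_usage_error")
})
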