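#' Training configuration
#'
#' Optimiser and schedule settings for adversarial training. The defaults
#' are the reference settings: Adam with beta1 = 0.5, beta2 = 0.999,
#' learning rate 1e-4 for both networks, 200 epochs, pair-wise (batch size
#' 1) updates, and the composite objective with lambda1 = 100, lambda2 = 10.
#'
#' @param epochs Number of passes over the training pairs (>= 1).
#' @param lr Learning rate for both generator and discriminator.
#' @param beta1,beta2 Adam moment decays.
#' @param batch_size Pairs per update step.
#' @param seed Master seed: parameter initialisation and epoch shuffling are
#'   all derived from it.
#' @param gan_mode `"log"` (BCE discriminator, non-saturating generator) or
#'   `"lsgan"` (least-squares both sides).
#' @param weights A [loss_weights()] object.
#' @param checkpoint_every Checkpoint interval in epochs (`NULL` = only the
#'   final model is written).
#' @param ce_reference Reference image of the cross-entropy consistency
#'   term: `"target"` (default) or `"source"`.
#' @param lr_decay Linearly decay the learning rate to 0 over the run
#'   (off by default; the reference schedule is a fixed rate).
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 200, lr = 1e-4, beta1 = 0.5,
                         beta2 = 0.999, batch_size = 1, seed = 1,
                         gan_mode = c("log", "lsgan"),
                         weights = loss_weights(), checkpoint_every = NULL,
                         ce_reference = c("target", "source"),
                         lr_decay = FALSE) {
  gan_mode <- match.arg(gan_mode)
  ce_reference <- match.arg(ce_reference)
  if (epochs < 1) stop_usage("epochs must be >= 1")
  if (lr <= 0) stop_usage("lr must be positive")
  if (beta1 < 0 || beta1 >= 1 || beta2 < 0 || beta2 >= 1)
    stop_usage("beta1 and beta2 must be in [0, 1)")
  if (batch_size < 1) stop_usage("batch_size must be >= 1")
  if (!inherits(weights, "loss_weights"))
    stop_usage("weights must be a loss_weights object")
  structure(list(epochs = as.integer(epochs), lr = lr, beta1 = beta1,
                 beta2 = beta2, batch_size = as.integer(batch_size),
                 seed = as.integer(seed), gan_mode = gan_mode,
                 weights = weights,
                 checkpoint_every = if (is.null(checkpoint_every)) NULL
                                    else as.integer(checkpoint_every),
                 ce_reference = ce_reference, lr_decay = isTRUE(lr_decay)),
            class = "train_config")
}

#' Assemble a trainer
#'
#' Builds the generator and discriminator (parameter initialisation derived
#' deterministically from `config$seed`) together with their Adam states.
#'
#' @param gen_spec A [multigen_spec()].
#' @param disc_spec A [patch_grid_spec()].
#' @param image_size Side of the training images.
#' @param config A [train_config()].
#' @return An object of class `mggan_trainer`.
#' @export
mggan_trainer <- function(gen_spec = multigen_spec(),
                          disc_spec = patch_grid_spec(),
                          image_size = 64, config = train_config()) {
  gen <- build_generator(gen_spec, image_size, derive_seed(config$seed, 1L))
  disc <- build_discriminator(disc_spec, image_size,
                              derive_seed(config$seed, 2L))
  # optimiser state lives in an environment so train_step can update it
  # in place (parameter values already do, being ad_param environments)
  opt <- new.env(parent = emptyenv())
  opt$adam_g <- adam_init(gen$params)
  opt$adam_d <- adam_init(disc$params)
  structure(list(gen = gen, disc = disc, config = config, opt = opt),
            class = "mggan_trainer")
}

d_loss_node <- function(sr, sf, mode) {
  if (mode == "log")
    op_wsum(list(op_negmeanlog(sr), op_negmeanlog1m(sf)), c(1, 1))
  else
    op_wsum(list(op_half_mean_sq(sr, 1), op_half_mean_sq(sf, 0)), c(1, 1))
}

g_adv_node <- function(sf, mode) {
  if (mode == "log") op_negmeanlog(sf) else op_half_mean_sq(sf, 1)
}

#' One adversarial training step
#'
#' Performs one discriminator update (real pair against the detached
#' translated image) followed by one generator update with the composite
#' objective, averaging gradients over the batch. Models are updated in
#' place; the component losses are returned.
#'
#' @param trainer An [mggan_trainer()].
#' @param pair_batch List of [image_pair()] objects.
#' @param lr Optional learning-rate override for this step.
#' @return List with `g_loss` (a `loss_breakdown`) and `d_loss` (scalar).
#' @export
train_step <- function(trainer, pair_batch, lr = NULL) {
  if (!inherits(trainer, "mggan_trainer"))
    stop_usage("trainer must be an mggan_trainer")
  if (inherits(pair_batch, "image_pair")) pair_batch <- list(pair_batch)
  cfg <- trainer$config
  if (is.null(lr)) lr <- cfg$lr
  k <- length(pair_batch)
  all_params <- c(trainer$gen$params, trainer$disc$params)

  xs <- lapply(pair_batch, function(p) ad_const(p$source))
  yhat <- lapply(seq_len(k), function(i) gen_forward(trainer$gen, xs[[i]]))

  # --- discriminator update (fake detached from the generator graph) ---
  ad_zero_grad(all_params)
  d_terms <- lapply(seq_len(k), function(i) {
    sr <- disc_forward(trainer$disc, xs[[i]],
                       ad_const(pair_batch[[i]]$target))
    sf <- disc_forward(trainer$disc, xs[[i]], ad_const(yhat[[i]]$value))
    d_loss_node(sr, sf, cfg$gan_mode)
  })
  d_total <- op_wsum(d_terms, rep(1 / k, k))
  if (!is.finite(d_total$value))
    stop_validation("non-finite discriminator loss (", d_total$value, ")")
  ad_backward(d_total)
  trainer$opt$adam_d <- adam_step(trainer$disc$params, trainer$opt$adam_d,
                                  lr, cfg$beta1, cfg$beta2)

  # --- generator update ---
  ad_zero_grad(all_params)
  g_terms <- lapply(seq_len(k), function(i) {
    sf <- disc_forward(trainer$disc, xs[[i]], yhat[[i]])
    adv <- g_adv_node(sf, cfg$gan_mode)
    l1 <- op_l1_to(pair_batch[[i]]$target, yhat[[i]])
    ref <- if (cfg$ce_reference == "target") pair_batch[[i]]$target
           else pair_batch[[i]]$source
    cross <- op_bce_to(ref, yhat[[i]])
    list(adv = adv, l1 = l1, cross = cross)
  })
  w <- cfg$weights
  parts <- unlist(lapply(g_terms, function(t) list(t$adv, t$l1, t$cross)),
                  recursive = FALSE)
  coefs <- rep(c(1, w$lambda1, w$lambda2) / k, k)
  g_total <- op_wsum(parts, coefs)
  if (!is.finite(g_total$value))
    stop_validation("non-finite generator loss (", g_total$value, ")")
  ad_backward(g_total)
  trainer$opt$adam_g <- adam_step(trainer$gen$params, trainer$opt$adam_g,
                                  lr, cfg$beta1, cfg$beta2)
  ad_zero_grad(all_params)

  mean_of <- function(f) mean(vapply(g_terms, function(t) f(t)$value,
                                     numeric(1)))
  list(g_loss = loss_breakdown(mean_of(function(t) t$adv),
                               mean_of(function(t) t$l1),
                               mean_of(function(t) t$cross), w),
       d_loss = d_total$value)
}

save_checkpoint <- function(trainer, path, epoch, history) {
  ck <- list(format = "mggan_checkpoint", version = 1L,
             gen_spec = trainer$gen$spec, disc_spec = trainer$disc$spec,
             config = trainer$config, image_size = trainer$gen$image_size,
             gen_params = params_snapshot(trainer$gen$params),
             disc_params = params_snapshot(trainer$disc$params),
             adam_g = trainer$opt$adam_g, adam_d = trainer$opt$adam_d,
             epoch = epoch, history = history,
             rng = get(".Random.seed", envir = globalenv()))
  saveRDS(ck, path)
  invisible(path)
}

#' Load a training checkpoint
#'
#' Restores the generator, discriminator and optimiser states saved by
#' [mggan()]. The returned trainer can be passed back to [mggan()] via its
#' `resume` argument (by path) or used directly for translation.
#'
#' @param path Path to a checkpoint `.rds` written during training.
#' @return List with `trainer`, `epoch`, `history`.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop_io("checkpoint not found: ", path)
  ck <- readRDS(path)
  if (!identical(ck$format, "mggan_checkpoint"))
    stop_validation("not an mggan checkpoint: ", path)
  if (ck$version > 1L)
    stop_validation("checkpoint version ", ck$version, " is newer than ",
                    "this package supports")
  trainer <- mggan_trainer(ck$gen_spec, ck$disc_spec, ck$image_size,
                           ck$config)
  params_restore(trainer$gen$params, ck$gen_params)
  params_restore(trainer$disc$params, ck$disc_params)
  trainer$opt$adam_g <- ck$adam_g
  trainer$opt$adam_d <- ck$adam_d
  list(trainer = trainer, epoch = ck$epoch, history = ck$history,
       rng = ck$rng)
}

resolve_training_data <- function(data) {
  if (is.character(data)) data <- load_dataset(data)
  if (inherits(data, "dataset_split"))
    return(list(train = data$train, test = data$test))
  if (inherits(data, "image_pair")) data <- list(data)
  list(train = data, test = list())
}

#' Fit the stain-translation model
#'
#' Trains the multi-generator and patch discriminator by alternating
#' adversarial updates (one discriminator step, then one generator step per
#' batch). Fully deterministic given the configuration seed: identical
#' seed, configuration and data reproduce identical loss histories, and
#' resuming from a checkpoint continues the run bit-for-bit.
#'
#' @param data A `dataset_split`, a list of [image_pair()] objects (then no
#'   test evaluation is run), or a dataset directory.
#' @param config A [train_config()].
#' @param gen_spec A [multigen_spec()].
#' @param disc_spec A [patch_grid_spec()].
#' @param out_dir Optional directory for checkpoints
#'   (`ckpt_epoch<N>.rds`) and the final model (`model.rds`).
#' @param resume Optional path to a checkpoint to continue from; training
#'   runs on to `config$epochs`.
#' @param verbose Print one line per epoch.
#' @return An object of class `mggan` with components `generator`,
#'   `discriminator`, `config`, `history` (one row per step), and
#'   `test_report` (a `metric_report`, or `NULL` without a test split).
#' @seealso [predict.mggan()], [run_ablation()], [sweep_lambdas()]
#' @export
mggan <- function(data, config = train_config(),
                  gen_spec = multigen_spec(), disc_spec = patch_grid_spec(),
                  out_dir = NULL, resume = NULL, verbose = FALSE) {
  ds <- resolve_training_data(data)
  if (length(ds$train) == 0) stop_usage("empty training set")
  image_size <- dim(ds$train[[1]]$source)[1L]
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  has_old_rng <- exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE)
  if (has_old_rng) old_rng <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old_rng)
    assign(".Random.seed", old_rng, envir = globalenv()))

  if (is.null(resume)) {
    trainer <- mggan_trainer(gen_spec, disc_spec, image_size, config)
    start_epoch <- 0L
    history <- NULL
    set.seed(derive_seed(config$seed, 3L))
  } else {
    ck <- load_checkpoint(resume)
    trainer <- ck$trainer
    config <- trainer$config
    start_epoch <- ck$epoch
    history <- ck$history
    assign(".Random.seed", ck$rng, envir = globalenv())
  }

  n <- length(ds$train)
  step <- if (is.null(history)) 0L else max(history$step)
  hist_rows <- list()
  for (epoch in seq_len(config$epochs)) {
    if (epoch <= start_epoch) next
    lr <- if (config$lr_decay)
      config$lr * (1 - (epoch - 1) / config$epochs) else config$lr
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    for (b in batches) {
      step <- step + 1L
      res <- train_step(trainer, ds$train[b], lr = lr)
      hist_rows[[length(hist_rows) + 1L]] <- data.frame(
        step = step, epoch = epoch, adv = res$g_loss$adv,
        l1 = res$g_loss$l1, cross = res$g_loss$cross,
        total = res$g_loss$total, d_loss = res$d_loss)
    }
    if (verbose) {
      last <- hist_rows[[length(hist_rows)]]
      message(sprintf("epoch %d/%d  total %.4f  d %.4f", epoch,
                      config$epochs, last$total, last$d_loss))
    }
    if (!is.null(out_dir) && !is.null(config$checkpoint_every) &&
        epoch %% config$checkpoint_every == 0L) {
      h <- rbind(history, do.call(rbind, hist_rows))
      save_checkpoint(trainer, file.path(out_dir,
                      sprintf("ckpt_epoch%d.rds", epoch)), epoch, h)
    }
  }
  history <- rbind(history, do.call(rbind, hist_rows))

  test_report <- if (length(ds$test) > 0)
    evaluate_dataset(ds$test, model = trainer$gen) else NULL

  if (!is.null(out_dir))
    save_checkpoint(trainer, file.path(out_dir, "model.rds"),
                    config$epochs, history)

  structure(list(generator = trainer$gen, discriminator = trainer$disc,
                 trainer = trainer, config = config,
                 gen_spec = trainer$gen$spec, disc_spec = trainer$disc$spec,
                 history = history, test_report = test_report,
                 n_train = n, n_test = length(ds$test)),
            class = "mggan")
}

#' @export
print.mggan <- function(x, ...) {
  cat(sprintf("Multi-generator adversarial stain translator\n"))
  cat(sprintf("  trained %d epochs on %d pairs (%dx%d px), gan_mode=%s, ",
              x$config$epochs, x$n_train, x$generator$image_size,
              x$generator$image_size, x$config$gan_mode))
  cat(sprintf("lambda1=%g, lambda2=%g\n", x$config$weights$lambda1,
              x$config$weights$lambda2))
  last <- x$history[nrow(x$history), ]
  cat(sprintf("  final step losses: total %.4f (adv %.4f, l1 %.5f, cross %.4f), d %.4f\n",
              last$total, last$adv, last$l1, last$cross, last$d_loss))
  if (!is.null(x$test_report))
    cat(sprintf("  test (%d pairs): PSNR %.2f dB / SSIM %.4f / MSE %.3e\n",
                x$n_test, x$test_report$aggregate$psnr_db,
                x$test_report$aggregate$ssim, x$test_report$aggregate$mse))
  invisible(x)
}

#' @export
summary.mggan <- function(object, ...) {
  n_g <- sum(vapply(object$generator$params,
                    function(p) length(p$value), numeric(1)))
  n_d <- sum(vapply(object$discriminator$params,
                    function(p) length(p$value), numeric(1)))
  out <- list(config = object$config, n_params_generator = n_g,
              n_params_discriminator = n_d,
              n_steps = nrow(object$history),
              first_epoch_total = mean(object$history$total[
                object$history$epoch == min(object$history$epoch)]),
              last_epoch_total = mean(object$history$total[
                object$history$epoch == max(object$history$epoch)]),
              test_report = object$test_report)
  class(out) <- "summary.mggan"
  out
}

#' @export
print.summary.mggan <- function(x, ...) {
  cat(sprintf("mggan fit: %d steps, %s generator / %s discriminator parameters\n",
              x$n_steps, format(x$n_params_generator, big.mark = ","),
              format(x$n_params_discriminator, big.mark = ",")))
  cat(sprintf("  mean generator total loss: %.4f (first epoch) -> %.4f (last epoch)\n",
              x$first_epoch_total, x$last_epoch_total))
  if (!is.null(x$test_report)) print(x$test_report)
  invisible(x)
}

#' Translate images with a fitted model
#'
#' @param object A fitted [mggan()] object.
#' @param newdata An image array, an [image_pair()] (its source is used), or
#'   a list of either.
#' @param ... Unused.
#' @return Translated image(s) in (0, 1), matching the input structure.
#' @export
predict.mggan <- function(object, newdata, ...) {
  take_source <- function(x) if (inherits(x, "image_pair")) x$source else x
  if (is.list(newdata) && !is_image(newdata) &&
      !inherits(newdata, "image_pair"))
    lapply(newdata, function(p) translate(object$generator, take_source(p)))
  else
    translate(object$generator, take_source(newdata))
}

#' Plot training loss trajectories
#'
#' Per-step generator total loss and discriminator loss on a log scale.
#'
#' @param x A fitted [mggan()] object.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.mggan <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$step, cbind(h$total, h$d_loss), type = "l",
                    lty = 1, col = c("firebrick", "steelblue"),
                    xlab = "step", ylab = "loss", log = "y", ...)
  graphics::legend("topright", c("generator total", "discriminator"),
                   lty = 1, col = c("firebrick", "steelblue"), bty = "n")
  invisible(x)
}

#' @export
coef.mggan <- function(object, ...) {
  list(generator = params_snapshot(object$generator$params),
       discriminator = params_snapshot(object$discriminator$params))
}
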