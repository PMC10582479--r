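#' Configuration of an ablation variant
#'
#' Maps an ablation label onto a (config, generator spec) pair derived from
#' the base settings:
#' \describe{
#'   \item{GGAN}{single generator (fine branch only) + patch discriminator,
#'     no cross-entropy term (lambda2 = 0).}
#'   \item{DGAN}{multi-generator + patch discriminator, lambda2 = 0.}
#'   \item{MGGAN_star}{the full structure with the cross-entropy term
#'     abandoned (lambda2 = 0); identical configuration to DGAN, kept as a
#'     separate label.}
#'   \item{MGGAN}{the full model.}
#' }
#'
#' @param variant One of `"GGAN"`, `"DGAN"`, `"MGGAN_star"`, `"MGGAN"`.
#' @param base_config A [train_config()].
#' @param gen_spec A [multigen_spec()] for the full model.
#' @return List with `label`, `config`, `gen_spec` and `changed` (the fields
#'   altered relative to the base).
#' @export
variant_config <- function(variant, base_config = train_config(),
                           gen_spec = multigen_spec()) {
  if (!variant %in% c("GGAN", "DGAN", "MGGAN_star", "MGGAN"))
    stop_usage("unknown ablation variant: ", variant)
  cfg <- base_config
  gs <- gen_spec
  changed <- character()
  if (variant %in% c("GGAN", "DGAN", "MGGAN_star")) {
    cfg$weights <- loss_weights(cfg$weights$lambda1, 0)
    changed <- c(changed, "lambda2")
  }
  if (variant == "GGAN") {
    gs["coarse"] <- list(NULL)   # keep the field present, set to NULL
    changed <- c(changed, "coarse_branch")
  }
  list(label = variant, config = cfg, gen_spec = gs, changed = changed)
}

#' Run the ablation harness
#'
#' Trains and evaluates the requested model variants on a shared
#' train/test split with shared seeds, so the only differences between runs
#' are the documented configuration fields of each variant.
#'
#' @param data A `dataset_split` (a test split is required for the reports).
#' @param base_config A [train_config()] shared by all variants.
#' @param variants Subset of `c("GGAN", "DGAN", "MGGAN_star", "MGGAN")`.
#' @param gen_spec,disc_spec Architecture of the full model.
#' @param verbose Print progress.
#' @return An `mggan_ablation`: `summary` data frame (variant, psnr_db,
#'   ssim, mse) plus the per-variant `reports` and `models`.
#' @export
run_ablation <- function(data, base_config = train_config(),
                         variants = c("GGAN", "DGAN", "MGGAN_star", "MGGAN"),
                         gen_spec = multigen_spec(),
                         disc_spec = patch_grid_spec(), verbose = FALSE) {
  if (length(variants) == 0) stop_usage("no variants requested")
  runs <- lapply(variants, function(v) {
    vc <- variant_config(v, base_config, gen_spec)
    if (verbose) message("ablation variant: ", v)
    fit <- mggan(data, vc$config, vc$gen_spec, disc_spec, verbose = FALSE)
    list(label = v, fit = fit, report = fit$test_report)
  })
  summary <- do.call(rbind, lapply(runs, function(r) {
    ag <- r$report$aggregate
    data.frame(variant = r$label, psnr_db = ag$psnr_db, ssim = ag$ssim,
               mse = ag$mse)
  }))
  structure(list(summary = summary,
                 reports = stats::setNames(lapply(runs, `[[`, "report"),
                                           variants),
                 models = stats::setNames(lapply(runs, `[[`, "fit"),
                                          variants)),
            class = "mggan_ablation")
}

#' @export
print.mggan_ablation <- function(x, ...) {
  cat("Ablation results (toy scale):\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Sweep the objective weights
#'
#' Trains one model per (lambda1, lambda2) grid cell with shared seeds and
#' reports test metrics per cell. The default grids cover the reference
#' exploration ranges lambda1 in [80, 120] and lambda2 in [0.1, 100],
#' including the selected operating point (100, 10).
#'
#' @param data A `dataset_split`.
#' @param config Base [train_config()]; its weights are overridden cell by
#'   cell.
#' @param lambda1_values,lambda2_values Nonnegative weight grids.
#' @param gen_spec,disc_spec Model architecture.
#' @param out_csv Optional path for the grid as CSV.
#' @param verbose Print progress.
#' @return An `mggan_sweep`: `grid` data frame (lambda1, lambda2, psnr_db,
#'   ssim, mse) and the per-cell `reports`.
#' @export
sweep_lambdas <- function(data, config = train_config(),
                          lambda1_values = c(80, 90, 100, 110, 120),
                          lambda2_values = c(0.1, 1, 10, 100),
                          gen_spec = multigen_spec(),
                          disc_spec = patch_grid_spec(),
                          out_csv = NULL, verbose = FALSE) {
  if (length(lambda1_values) == 0 || length(lambda2_values) == 0)
    stop_usage("lambda grids must be nonempty")
  if (any(lambda1_values < 0) || any(lambda2_values < 0))
    stop_usage("lambda values must be nonnegative")
  cells <- expand.grid(lambda1 = lambda1_values, lambda2 = lambda2_values,
                       KEEP.OUT.ATTRS = FALSE)
  reports <- vector("list", nrow(cells))
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cfg <- config
    cfg$weights <- loss_weights(cells$lambda1[i], cells$lambda2[i])
    if (verbose)
      message(sprintf("sweep cell lambda1=%g lambda2=%g",
                      cells$lambda1[i], cells$lambda2[i]))
    fit <- mggan(data, cfg, gen_spec, disc_spec)
    reports[[i]] <- fit$test_report
    ag <- fit$test_report$aggregate
    rows[[i]] <- data.frame(lambda1 = cells$lambda1[i],
                            lambda2 = cells$lambda2[i],
                            psnr_db = ag$psnr_db, ssim = ag$ssim,
                            mse = ag$mse)
  }
  grid <- do.call(rbind, rows)
  if (!is.null(out_csv)) utils::write.csv(grid, out_csv, row.names = FALSE)
  structure(list(grid = grid, reports = reports), class = "mggan_sweep")
}

#' @export
print.mggan_sweep <- function(x, ...) {
  cat("Objective-weight sweep (toy scale):\n")
  print(x$grid, row.names = FALSE)
  invisible(x)
}
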