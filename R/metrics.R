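#' SSIM configuration
#'
#' Stabiliser constants `c1 = (k1 * L)^2` and `c2 = (k2 * L)^2` with the
#' universal defaults k1 = 0.01, k2 = 0.03, and the dynamic range L (1.0 on
#' the package's normalised intensity scale). `window = "global"` computes
#' one SSIM value from whole-image moments; `window = "sliding"` averages an
#' 11 x 11 Gaussian-weighted (sd 1.5) local SSIM map, the convention of most
#' reference implementations.
#'
#' @param k1,k2 Stabiliser factors.
#' @param L Dynamic range of the intensities.
#' @param window `"global"` or `"sliding"`.
#' @param window_size,window_sd Sliding-window size (odd) and Gaussian sd.
#' @return An object of class `ssim_config`.
#' @export
ssim_config <- function(k1 = 0.01, k2 = 0.03, L = 1.0,
                        window = c("global", "sliding"),
                        window_size = 11, window_sd = 1.5) {
  window <- match.arg(window)
  if (L <= 0) stop_usage("L must be positive")
  if (k1 <= 0 || k2 <= 0) stop_usage("k1 and k2 must be positive")
  structure(list(k1 = k1, k2 = k2, L = L, c1 = (k1 * L)^2, c2 = (k2 * L)^2,
                 window = window, window_size = as.integer(window_size),
                 window_sd = window_sd),
            class = "ssim_config")
}

#' Mean squared error between two images
#'
#' Mean of squared differences over all pixels and channels.
#'
#' @param reference,candidate Arrays of identical shape.
#' @return Scalar >= 0.
#' @export
mse <- function(reference, candidate) {
  check_same_shape(reference, candidate, "reference and candidate")
  mean((reference - candidate)^2)
}

#' Peak signal-to-noise ratio in decibels
#'
#' `10 * log10(max_value^2 / MSE)`. Identical images (MSE = 0) give `Inf`;
#' dataset aggregation excludes such values with a logged count, since the
#' ratio is undefined there.
#'
#' @param reference,candidate Arrays of identical shape.
#' @param max_value Peak intensity (1.0 on the normalised scale; use 255 for
#'   8-bit integer data).
#' @return PSNR in dB (possibly `Inf`).
#' @export
psnr <- function(reference, candidate, max_value = 1.0) {
  m <- mse(reference, candidate)
  if (m == 0) return(Inf)
  10 * log10(max_value^2 / m)
}

gaussian_kernel <- function(size, sd) {
  half <- (size - 1) / 2
  g <- exp(-(seq(-half, half)^2) / (2 * sd^2))
  k <- outer(g, g)
  k / sum(k)
}

# Windowed moments of one channel via im2col gather + kernel weights.
channel_ssim_sliding <- function(x, y, cfg) {
  size <- cfg$window_size
  kern <- as.vector(gaussian_kernel(size, cfg$window_sd))
  d <- dim(x)
  map <- im2col_map(d[1L], d[2L], 1L, size, 1L)
  cx <- matrix(x[map$idx], nrow = nrow(map$idx))
  cy <- matrix(y[map$idx], nrow = nrow(map$idx))
  mux <- cx %*% kern
  muy <- cy %*% kern
  sx <- (cx * cx) %*% kern - mux^2
  sy <- (cy * cy) %*% kern - muy^2
  sxy <- (cx * cy) %*% kern - mux * muy
  num <- (2 * mux * muy + cfg$c1) * (2 * sxy + cfg$c2)
  den <- (mux^2 + muy^2 + cfg$c1) * (sx + sy + cfg$c2)
  mean(num / den)
}

channel_ssim_global <- function(x, y, cfg) {
  mux <- mean(x); muy <- mean(y)
  sx <- mean((x - mux)^2)
  sy <- mean((y - muy)^2)
  sxy <- mean((x - mux) * (y - muy))
  ((2 * mux * muy + cfg$c1) * (2 * sxy + cfg$c2)) /
    ((mux^2 + muy^2 + cfg$c1) * (sx + sy + cfg$c2))
}

#' Structural similarity index
#'
#' In global mode (the default) one SSIM value is computed from whole-image
#' means, variances and covariance per channel, then averaged over channels;
#' identical images give exactly 1. Sliding mode averages a Gaussian-windowed
#' local SSIM map instead.
#'
#' @param reference,candidate Arrays of identical shape with values in
#'   `[0, L]`.
#' @param config An [ssim_config()].
#' @return Scalar in (-1, 1]; 1 iff the images are identical (global mode).
#' @export
ssim <- function(reference, candidate, config = ssim_config()) {
  check_same_shape(reference, candidate, "reference and candidate")
  f <- if (config$window == "global") channel_ssim_global
       else channel_ssim_sliding
  if (is.matrix(reference)) return(f(reference, candidate, config))
  vals <- vapply(seq_len(dim(reference)[3L]), function(ch)
    f(reference[, , ch], candidate[, , ch], config), numeric(1))
  mean(vals)
}

#' Evaluate translated images against references
#'
#' Computes per-image MSE, PSNR and SSIM plus their dataset means. Supply
#' either `candidates` (a list of translated images aligned with `pairs`) or
#' `model` (a generator used to translate every pair's source). References
#' are the pairs' target images. Images with infinite PSNR (exact matches)
#' are excluded from the PSNR mean; the report records how many.
#'
#' @param pairs List of [image_pair()] objects.
#' @param candidates Optional list of candidate images, same length/order.
#' @param model Optional [build_generator()] model used when `candidates` is
#'   missing.
#' @param config An [ssim_config()].
#' @return A `metric_report`: `per_image` data frame (id, mse, psnr_db,
#'   ssim), `aggregate` list of means, `n_images`, `n_psnr_excluded`.
#' @export
evaluate_dataset <- function(pairs, candidates = NULL, model = NULL,
                             config = ssim_config()) {
  if (length(pairs) == 0) stop_validation("empty evaluation set")
  if (is.null(candidates)) {
    if (is.null(model))
      stop_usage("supply either candidates or a generator model")
    candidates <- lapply(pairs, function(p) translate(model, p$source))
  }
  if (length(candidates) != length(pairs))
    stop_validation("candidates and pairs must have equal length")
  rows <- lapply(seq_along(pairs), function(i) {
    ref <- pairs[[i]]$target
    cand <- candidates[[i]]
    data.frame(id = pairs[[i]]$id, mse = mse(ref, cand),
               psnr_db = psnr(ref, cand), ssim = ssim(ref, cand, config))
  })
  per_image <- do.call(rbind, rows)
  metric_report(per_image)
}

metric_report <- function(per_image) {
  finite_psnr <- per_image$psnr_db[is.finite(per_image$psnr_db)]
  structure(list(
    per_image = per_image,
    aggregate = list(
      mse = mean(per_image$mse),
      psnr_db = if (length(finite_psnr)) mean(finite_psnr) else NA_real_,
      ssim = mean(per_image$ssim)
    ),
    n_images = nrow(per_image),
    n_psnr_excluded = sum(!is.finite(per_image$psnr_db))
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> %d images: PSNR %.2f dB / SSIM %.4f / MSE %.3e\n",
              x$n_images, x$aggregate$psnr_db, x$aggregate$ssim,
              x$aggregate$mse))
  if (x$n_psnr_excluded > 0)
    cat(sprintf("  (%d exact matches excluded from the PSNR mean)\n",
                x$n_psnr_excluded))
  invisible(x)
}

#' Write a metric report as CSV
#'
#' One row per image plus a `summary` row holding the aggregates.
#'
#' @param report A `metric_report`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_metric_report <- function(report, path) {
  df <- report$per_image
  df <- rbind(df, data.frame(id = "summary", mse = report$aggregate$mse,
                             psnr_db = report$aggregate$psnr_db,
                             ssim = report$aggregate$ssim))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
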