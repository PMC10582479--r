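#' Patch-grid discriminator specification
#'
#' The discriminator partitions the candidate image into a `grid` of
#' non-overlapping patches (default 4 x 4, i.e. 16 independent patches),
#' scores every patch with one shared convolutional encoder ending in a
#' sigmoid, and reports the arithmetic mean of the patch probabilities as
#' its aggregate output. In conditional mode (the default, matching the
#' conditional adversarial objective) the aligned source patch is
#' concatenated channel-wise to the candidate patch before encoding.
#'
#' @param grid Integer (rows, cols) of the patch partition.
#' @param encoder_depth Number of stride-2 encoder stages; the patch side
#'   must be divisible by `2^encoder_depth`.
#' @param base_channels Encoder channel count at the first stage.
#' @param conditional Score (source, candidate) pairs rather than the
#'   candidate alone.
#' @return An object of class `patch_grid_spec`.
#' @export
patch_grid_spec <- function(grid = c(4, 4), encoder_depth = 2,
                            base_channels = 32, conditional = TRUE) {
  if (length(grid) != 2 || any(grid < 1))
    stop_usage("grid must be two positive integers (rows, cols)")
  if (encoder_depth < 1) stop_usage("encoder_depth must be >= 1")
  structure(list(grid = as.integer(grid),
                 encoder_depth = as.integer(encoder_depth),
                 base_channels = as.integer(base_channels),
                 conditional = isTRUE(conditional)),
            class = "patch_grid_spec")
}

#' Build the patch discriminator
#'
#' @param spec A [patch_grid_spec()].
#' @param image_size Side of the images to be scored; must be divisible by
#'   the grid, and the resulting patch side by `2^encoder_depth`.
#' @param seed Integer seed for parameter initialisation.
#' @return An object of class `mggan_discriminator`.
#' @export
build_discriminator <- function(spec = patch_grid_spec(), image_size = 64,
                                seed = 1) {
  if (!inherits(spec, "patch_grid_spec"))
    stop_usage("spec must be a patch_grid_spec")
  image_size <- as.integer(image_size)
  if (image_size %% spec$grid[1] != 0L || image_size %% spec$grid[2] != 0L)
    stop_usage("image_size ", image_size, " not divisible by the patch grid")
  ph <- image_size %/% spec$grid[1]
  pw <- image_size %/% spec$grid[2]
  if (ph %% 2^spec$encoder_depth != 0L || pw %% 2^spec$encoder_depth != 0L)
    stop_usage("patch size ", ph, "x", pw, " not divisible by 2^encoder_depth")
  in_ch <- if (spec$conditional) 6L else 3L
  ch <- pmin(spec$base_channels * 2^(0:(spec$encoder_depth - 1)),
             spec$base_channels * 8L)
  layers <- with_seed(seed, {
    ls <- list()
    prev <- in_ch
    for (l in seq_len(spec$encoder_depth)) {
      ls[[paste0("enc", l)]] <- conv_layer_params(4L, prev, ch[l])
      prev <- ch[l]
    }
    ls$head <- conv_layer_params(1L, prev, 1L)
    ls
  })
  structure(list(spec = spec, image_size = image_size,
                 patch_size = c(ph, pw), seed = seed, layers = layers,
                 params = flatten_layer_params(layers)),
            class = "mggan_discriminator")
}

#' @export
print.mggan_discriminator <- function(x, ...) {
  cat(sprintf(
    "<mggan_discriminator> %dx%d patch grid (%d patches of %dx%d), %s\n",
    x$spec$grid[1], x$spec$grid[2], prod(x$spec$grid),
    x$patch_size[1], x$patch_size[2],
    if (x$spec$conditional) "conditional" else "unconditional"))
  invisible(x)
}

#' Partition an image into grid patches
#'
#' Splits the image into `rows * cols` non-overlapping tiles that cover it
#' exactly, returned in raster order (left to right, then top to bottom).
#'
#' @param image H x W x 3 array.
#' @param grid Integer (rows, cols); H and W must be divisible by them.
#' @return List of patch arrays in raster order.
#' @export
extract_patches <- function(image, grid = c(4, 4)) {
  check_image(image, "image", range01 = FALSE)
  d <- dim(image)
  grid <- as.integer(grid)
  if (d[1L] %% grid[1] != 0L || d[2L] %% grid[2] != 0L)
    stop_usage("image ", d[1L], "x", d[2L], " not divisible by grid ",
               grid[1], "x", grid[2])
  ph <- d[1L] %/% grid[1]
  pw <- d[2L] %/% grid[2]
  out <- vector("list", grid[1] * grid[2])
  for (r in seq_len(grid[1]))
    for (cc in seq_len(grid[2]))
      out[[(r - 1L) * grid[2] + cc]] <-
        image[(r - 1L) * ph + seq_len(ph), (cc - 1L) * pw + seq_len(pw), ,
              drop = FALSE]
  out
}

# Shared patch encoder on an ad node; returns a scalar probability node.
patch_encoder_forward <- function(disc, patch) {
  h <- patch
  for (l in seq_len(disc$spec$encoder_depth)) {
    lay <- disc$layers[[paste0("enc", l)]]
    h <- op_conv2d(h, lay$w, lay$b, 2L, 1L)
    if (l > 1L) h <- op_instance_norm(h)
    h <- op_lrelu(h)
  }
  h <- op_conv2d(h, disc$layers$head$w, disc$layers$head$b, 1L, 0L)
  op_sigmoid(op_mean(h))
}

#' Score one patch
#'
#' Runs the shared encoder on a single patch (with its aligned source patch
#' in conditional mode) and returns the sigmoid probability that the patch
#' is real.
#'
#' @param disc An [build_discriminator()] model.
#' @param patch Candidate patch array (patch_size x patch_size x 3).
#' @param source_patch Aligned source patch, required in conditional mode.
#' @return Scalar probability strictly in (0, 1).
#' @export
score_patch <- function(disc, patch, source_patch = NULL) {
  if (!inherits(disc, "mggan_discriminator"))
    stop_usage("disc must be an mggan_discriminator")
  d <- dim(patch)
  if (is.null(d) || d[1L] != disc$patch_size[1] ||
      d[2L] != disc$patch_size[2] || d[3L] != 3L)
    stop_validation("patch must be ", disc$patch_size[1], "x",
                    disc$patch_size[2], "x3")
  if (disc$spec$conditional) {
    if (is.null(source_patch))
      stop_usage("conditional discriminator needs source_patch")
    check_same_shape(patch, source_patch, "candidate and source patches")
    patch <- array(c(source_patch, patch), c(d[1L], d[2L], 6L))
  }
  patch_encoder_forward(disc, ad_const(patch))$value
}

# Full discriminator forward on ad nodes; returns the vector node of patch
# probabilities in raster order.
disc_forward <- function(disc, source, candidate) {
  grid <- disc$spec$grid
  ph <- disc$patch_size[1]
  pw <- disc$patch_size[2]
  inp <- if (disc$spec$conditional) op_concat_c(source, candidate)
         else candidate
  scores <- vector("list", grid[1] * grid[2])
  for (r in seq_len(grid[1]))
    for (cc in seq_len(grid[2])) {
      patch <- op_crop(inp, (r - 1L) * ph + seq_len(ph),
                       (cc - 1L) * pw + seq_len(pw))
      scores[[(r - 1L) * grid[2] + cc]] <- patch_encoder_forward(disc, patch)
    }
  op_stack(scores)
}

#' Score a candidate image patch-wise
#'
#' Partitions the candidate (and, in conditional mode, the source) into the
#' discriminator's patch grid, scores each patch with the shared encoder,
#' and aggregates by the arithmetic mean.
#'
#' @param disc An [build_discriminator()] model.
#' @param source Source image (conditioning input).
#' @param candidate Candidate (real or translated) image, same shape.
#' @return A `patch_scores` object: `per_patch` (rows x cols matrix of
#'   probabilities) and `aggregate` (their mean).
#' @export
discriminate <- function(disc, source, candidate) {
  check_image(source, "source", range01 = FALSE)
  check_image(candidate, "candidate", range01 = FALSE)
  check_same_shape(source, candidate, "source and candidate")
  if (dim(candidate)[1L] != disc$image_size)
    stop_validation("images are ", dim(candidate)[1L], " px but the ",
                    "discriminator was built for ", disc$image_size, " px")
  sc <- disc_forward(disc, ad_const(source), ad_const(candidate))$value
  patch_scores(matrix(sc, nrow = disc$spec$grid[1],
                      ncol = disc$spec$grid[2], byrow = TRUE))
}

#' Construct a patch-score object
#'
#' @param per_patch Matrix of per-patch probabilities in (0, 1).
#' @return A `patch_scores` object with `aggregate` equal to the mean.
#' @export
patch_scores <- function(per_patch) {
  per_patch <- as.matrix(per_patch)
  if (any(per_patch <= 0) || any(per_patch >= 1))
    stop_validation("patch scores must be strictly in (0, 1)")
  structure(list(per_patch = per_patch, aggregate = mean(per_patch)),
            class = "patch_scores")
}

#' @export
print.patch_scores <- function(x, ...) {
  cat(sprintf("<patch_scores> %dx%d grid, aggregate %.4f\n",
              nrow(x$per_patch), ncol(x$per_patch), x$aggregate))
  invisible(x)
}

scores_vector <- function(scores) {
  if (inherits(scores, "patch_scores")) as.vector(t(scores$per_patch))
  else as.numeric(scores)
}

#' Discriminator loss
#'
#' Binary cross-entropy (`bce`, the default training loss) or least-squares
#' (`lsgan`) loss over the patch probabilities of a real and a translated
#' candidate. Probabilities are clamped to `[eps, 1 - eps]` before logs.
#'
#' BCE: `-mean(log(score_real)) - mean(log(1 - score_fake))`.
#' LSGAN: `0.5 * mean((score_real - 1)^2) + 0.5 * mean(score_fake^2)`.
#'
#' @param scores_real,scores_fake `patch_scores` objects (or numeric score
#'   vectors) for the real pair and the translated candidate.
#' @param mode `"bce"` or `"lsgan"`.
#' @param eps Clamping constant.
#' @return Scalar loss.
#' @export
discriminator_loss <- function(scores_real, scores_fake,
                               mode = c("bce", "lsgan"), eps = 1e-7) {
  mode <- match.arg(mode)
  sr <- scores_vector(scores_real)
  sf <- scores_vector(scores_fake)
  if (length(sr) == 0 || length(sf) == 0)
    stop_validation("scores must be nonempty")
  if (mode == "bce") {
    -mean(log(clamp01(sr, eps))) - mean(log(1 - clamp01(sf, eps)))
  } else {
    0.5 * mean((sr - 1)^2) + 0.5 * mean(sf^2)
  }
}
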