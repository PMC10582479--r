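#' U-shaped branch specification
#'
#' One encoder-decoder branch of the multi-generator: `depth` stride-2
#' down-sampling stages, a mirrored nearest-neighbour-upsampling decoder with
#' skip connections concatenating encoder features at matching resolutions,
#' and optionally a residual block at the bottleneck.
#'
#' @param depth Number of down/up-sampling levels (>= 1).
#' @param base_channels Channel count at full resolution; doubles per level
#'   (capped at 8x).
#' @param use_residual_blocks Add a residual block at the bottleneck.
#' @param norm_mode `"instance"`, `"batch"` or `"none"`. Normalisation is
#'   computed per image, so with the package's pair-wise training batch mode
#'   coincides with instance mode.
#' @return An object of class `unet_spec`.
#' @export
unet_spec <- function(depth = 3, base_channels = 32,
                      use_residual_blocks = TRUE, norm_mode = "instance") {
  if (depth < 1) stop_usage("depth must be >= 1")
  if (base_channels < 1) stop_usage("base_channels must be >= 1")
  if (!norm_mode %in% c("instance", "batch", "none"))
    stop_usage("norm_mode must be instance, batch or none")
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 use_residual_blocks = isTRUE(use_residual_blocks),
                 norm_mode = norm_mode),
            class = "unet_spec")
}

#' Multi-generator specification
#'
#' The generator is two U-shaped branches at different spatial scales: the
#' fine branch consumes the input at native resolution, the coarse branch
#' consumes it downsampled by `coarse_scale_factor` (average pooling) and its
#' output feature map is upsampled back before fusion. The branch feature
#' maps are concatenated channel-wise and projected by a learned 1x1
#' convolution to 3 channels, followed by a sigmoid that maps the translated
#' image into the open interval (0, 1). Setting `coarse = NULL` gives the
#' single-generator (GGAN) variant.
#'
#' @param fine [unet_spec()] for the full-resolution branch.
#' @param coarse [unet_spec()] for the downscaled branch, or `NULL`.
#' @param coarse_scale_factor Integer >= 2 downsampling factor for the coarse
#'   branch input.
#' @param fusion Fusion mode; only `"concat_project"` is defined.
#' @return An object of class `multigen_spec`.
#' @export
multigen_spec <- function(fine = unet_spec(), coarse = unet_spec(),
                          coarse_scale_factor = 2,
                          fusion = "concat_project") {
  if (!inherits(fine, "unet_spec")) stop_usage("fine must be a unet_spec")
  if (!is.null(coarse) && !inherits(coarse, "unet_spec"))
    stop_usage("coarse must be a unet_spec or NULL")
  if (!is.null(coarse) && coarse_scale_factor < 2)
    stop_usage("coarse_scale_factor must be >= 2")
  if (fusion != "concat_project")
    stop_usage("unknown fusion mode: ", fusion)
  structure(list(fine = fine, coarse = coarse,
                 coarse_scale_factor = as.integer(coarse_scale_factor),
                 fusion = fusion),
            class = "multigen_spec")
}

unet_channels <- function(spec) {
  pmin(spec$base_channels * 2^(0:spec$depth), spec$base_channels * 8L)
}

# Parameters of one U-shaped branch, as a flat named list of ad_param nodes.
unet_params <- function(spec, prefix) {
  ch <- unet_channels(spec)
  p <- list()
  p[[paste0(prefix, ".stem")]] <- conv_layer_params(3L, 3L, ch[1])
  for (l in seq_len(spec$depth))
    p[[paste0(prefix, ".down", l)]] <- conv_layer_params(4L, ch[l], ch[l + 1])
  if (spec$use_residual_blocks) {
    cd <- ch[spec$depth + 1]
    p[[paste0(prefix, ".res1")]] <- conv_layer_params(3L, cd, cd)
    p[[paste0(prefix, ".res2")]] <- conv_layer_params(3L, cd, cd)
  }
  for (l in rev(seq_len(spec$depth)))
    p[[paste0(prefix, ".up", l)]] <-
      conv_layer_params(3L, ch[l + 1] + ch[l], ch[l])
  p[[paste0(prefix, ".feat")]] <-
    conv_layer_params(3L, ch[1], spec$base_channels)
  p
}

conv_block <- function(x, layer, spec, stride = 1L, pad = 1L,
                       act = op_lrelu) {
  h <- op_conv2d(x, layer$w, layer$b, stride, pad)
  h <- op_norm(h, spec$norm_mode)
  act(h)
}

# Forward pass of one branch; returns a full-resolution feature-map node.
unet_forward <- function(params, prefix, spec, x, ablate_skips = FALSE) {
  h <- conv_block(x, params[[paste0(prefix, ".stem")]], spec)
  skips <- vector("list", spec$depth)
  for (l in seq_len(spec$depth)) {
    skips[[l]] <- h
    h <- conv_block(h, params[[paste0(prefix, ".down", l)]], spec,
                    stride = 2L, pad = 1L)
  }
  if (spec$use_residual_blocks) {
    r <- conv_block(h, params[[paste0(prefix, ".res1")]], spec)
    r2 <- params[[paste0(prefix, ".res2")]]
    r <- op_norm(op_conv2d(r, r2$w, r2$b, 1L, 1L), spec$norm_mode)
    h <- op_lrelu(op_add(h, r))
  }
  for (l in rev(seq_len(spec$depth))) {
    h <- op_upsample_nearest(h, 2L)
    sk <- skips[[l]]
    if (ablate_skips) sk <- ad_const(array(0, dim(sk$value)))
    h <- op_concat_c(h, sk)
    h <- conv_block(h, params[[paste0(prefix, ".up", l)]], spec)
  }
  feat <- params[[paste0(prefix, ".feat")]]
  op_conv2d(h, feat$w, feat$b, 1L, 1L)
}

flatten_layer_params <- function(layers) {
  out <- list()
  for (nm in names(layers)) {
    out[[paste0(nm, ".w")]] <- layers[[nm]]$w
    out[[paste0(nm, ".b")]] <- layers[[nm]]$b
  }
  out
}

#' Build the multi-generator
#'
#' Instantiates all branch and fusion parameters with He-style Gaussian
#' initialisation, deterministic under `seed`.
#'
#' @param spec A [multigen_spec()].
#' @param image_size Side length of the (square) images the generator will
#'   translate. Must be divisible by `2^depth` of the fine branch and by
#'   `coarse_scale_factor * 2^depth` of the coarse branch.
#' @param seed Integer seed for parameter initialisation.
#' @return An object of class `mggan_generator`.
#' @export
build_generator <- function(spec = multigen_spec(), image_size = 64,
                            seed = 1) {
  if (!inherits(spec, "multigen_spec"))
    stop_usage("spec must be a multigen_spec")
  image_size <- as.integer(image_size)
  if (image_size %% 2^spec$fine$depth != 0L)
    stop_usage("image_size ", image_size, " not divisible by 2^depth = ",
               2^spec$fine$depth, " of the fine branch")
  if (!is.null(spec$coarse)) {
    need <- spec$coarse_scale_factor * 2^spec$coarse$depth
    if (image_size %% need != 0L)
      stop_usage("image_size ", image_size,
                 " not divisible by coarse_scale_factor * 2^depth = ", need)
  }
  layers <- with_seed(seed, {
    ls <- unet_params(spec$fine, "fine")
    fuse_in <- spec$fine$base_channels
    if (!is.null(spec$coarse)) {
      ls <- c(ls, unet_params(spec$coarse, "coarse"))
      fuse_in <- fuse_in + spec$coarse$base_channels
    }
    ls$fuse <- conv_layer_params(1L, fuse_in, 3L)
    ls
  })
  structure(list(spec = spec, image_size = image_size, seed = seed,
                 layers = layers, params = flatten_layer_params(layers)),
            class = "mggan_generator")
}

#' @export
print.mggan_generator <- function(x, ...) {
  n_par <- sum(vapply(x$params, function(p) length(p$value), numeric(1)))
  cat(sprintf(
    "<mggan_generator> %s, %dx%d px, %s parameters\n",
    if (is.null(x$spec$coarse)) "single branch"
    else sprintf("dual branch (coarse 1/%d scale)", x$spec$coarse_scale_factor),
    x$image_size, x$image_size, format(n_par, big.mark = ",")))
  invisible(x)
}

# Full generator forward pass on an ad node; returns the translated-image
# node with values in (0, 1).
gen_forward <- function(model, x, ablate_skips = FALSE) {
  spec <- model$spec
  feat <- unet_forward(model$layers, "fine", spec$fine, x, ablate_skips)
  if (!is.null(spec$coarse)) {
    s <- spec$coarse_scale_factor
    xc <- op_avgpool(x, s)
    cf <- unet_forward(model$layers, "coarse", spec$coarse, xc, ablate_skips)
    feat <- op_concat_c(feat, op_upsample_nearest(cf, s))
  }
  op_sigmoid(op_conv2d(feat, model$layers$fuse$w, model$layers$fuse$b,
                       1L, 0L))
}

#' Translate source images
#'
#' Runs the generator in inference mode. The output has the same shape as
#' the input with all values strictly inside (0, 1) (sigmoid output
#' activation). Deterministic: repeated calls give identical results.
#'
#' @param model An [build_generator()] model.
#' @param source One H x W x 3 array in [0, 1], or a list of such arrays
#'   (each translated independently).
#' @param ablate_skips Zero the encoder skip features at the decoder
#'   (diagnostic; quantifies the contribution of the skip connections).
#' @return Translated image(s), matching the input structure.
#' @export
translate <- function(model, source, ablate_skips = FALSE) {
  if (!inherits(model, "mggan_generator"))
    stop_usage("model must be an mggan_generator")
  if (is.list(source) && !is_image(source))
    return(lapply(source, function(s) translate(model, s, ablate_skips)))
  check_image(source, "source")
  d <- dim(source)
  if (d[1L] != model$image_size || d[2L] != model$image_size)
    stop_validation("source is ", d[1L], "x", d[2L],
                    " but the generator was built for ",
                    model$image_size, "x", model$image_size)
  gen_forward(model, ad_const(source), ablate_skips)$value
}

#' Fuse the two branch feature maps into an image
#'
#' Channel-wise concatenation of the fine and coarse feature maps followed by
#' a learned 1x1 projection to 3 channels and the sigmoid output activation.
#' The coarse map must already be upsampled to the fine resolution.
#'
#' @param fine_out,coarse_out H x W x C feature arrays (same H, W);
#'   `coarse_out` may be `NULL` for the single-branch variant.
#' @param projection Either an `mggan_generator` (its fusion layer is used)
#'   or a list with elements `w` (1 x 1 x (C1+C2) x 3 array) and `b`
#'   (length-3 numeric).
#' @return H x W x 3 image with values in (0, 1).
#' @export
fuse_branches <- function(fine_out, coarse_out, projection) {
  if (inherits(projection, "mggan_generator"))
    projection <- list(w = projection$layers$fuse$w$value,
                       b = projection$layers$fuse$b$value)
  x <- if (is.null(coarse_out)) fine_out else {
    check_same_shape(fine_out[, , 1, drop = FALSE],
                     coarse_out[, , 1, drop = FALSE],
                     "fine and coarse feature maps")
    array(c(fine_out, coarse_out),
          c(dim(fine_out)[1:2], dim(fine_out)[3] + dim(coarse_out)[3]))
  }
  fw <- conv2d_forward(x, projection$w, projection$b, 1L, 0L)
  array(stats::plogis(fw$y), dim(fw$y))
}
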