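# Shared fixtures: all inputs are generated in code at test time.

rand_image <- function(h = 4, w = 4, seed = 1, lo = 0.05, hi = 0.95) {
  set.seed(seed)
  array(runif(h * w * 3, lo, hi), c(h, w, 3))
}

# Desk-scale architecture used by the training tests: narrow dual-branch
# generator and patch discriminator for 32 px images.
tiny_gen_spec <- function(single = FALSE) {
  multigen_spec(fine = unet_spec(depth = 2, base_channels = 8),
                coarse = if (single) NULL
                         else unet_spec(depth = 2, base_channels = 8),
                coarse_scale_factor = 2)
}

tiny_disc_spec <- function() {
  patch_grid_spec(grid = c(4, 4), encoder_depth = 2, base_channels = 8)
}

# In-memory toy dataset of paired 32 px stain scenes, uniform grade mix.
toy_pairs <- function(n, seed = 1, canvas = 32, noise_sd = 0.02) {
  base <- stain_scene_params(canvas_size = canvas, n_nuclei = 6,
                             nucleus_radius_range = c(2, 4),
                             noise_sd = noise_sd, seed = seed)
  grades <- rep(0:3, length.out = n)
  lapply(seq_len(n), function(i) {
    p <- base
    p$grade <- grades[i]
    p$seed <- seed + 31L * i
    pair <- render_pair(sample_layout(p), p)
    pair$id <- sprintf("toy_%03d", i)
    pair
  })
}

# Central-difference numerical gradient of a scalar function.
num_grad <- function(fn, x, eps = 1e-6) {
  g <- array(0, dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- x[i] + eps
    xm[i] <- x[i] - eps
    g[i] <- (fn(xp) - fn(xm)) / (2 * eps)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a
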