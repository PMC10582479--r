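#' Parameters for a synthetic stain scene
#'
#' Describes one procedurally generated tissue-like scene: elliptical nuclei
#' scattered on a uniform background. The paired renderers
#' ([render_source()] and [render_target()]) share the geometry, so the
#' source->target mapping is a known deterministic transform plus bounded
#' Gaussian noise. The `grade` parameter emulates the four HER2
#' immunohistochemistry expression categories (0, 1+, 2+, 3+): in the target
#' rendering a membrane ring around each nucleus is stained DAB-brown with
#' intensity increasing in grade, mirroring how pathologists grade membrane
#' staining completeness and intensity.
#'
#' @param canvas_size Side of the square canvas in pixels (>= 16 and
#'   divisible by 4, the default discriminator patch grid).
#' @param n_nuclei Number of elliptical nuclei (>= 0).
#' @param nucleus_radius_range Length-2 numeric, min and max semi-axis in
#'   pixels.
#' @param grade Integer expression grade in \{0, 1, 2, 3\}.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise on the
#'   [0, 1] intensity scale; must satisfy 0 <= noise_sd < 0.5.
#' @param seed Integer seed; the whole scene (layout and noise) is a pure
#'   function of the parameters including this seed.
#' @return An object of class `stain_scene_params`.
#' @seealso [sample_layout()], [render_source()], [render_target()],
#'   [generate_dataset()]
#' @export
#' @examples
#' p <- stain_scene_params(canvas_size = 32, n_nuclei = 5, grade = 3, seed = 1)
#' pair <- render_pair(sample_layout(p), p)
#' dim(pair$source)
stain_scene_params <- function(canvas_size = 64, n_nuclei = 12,
                               nucleus_radius_range = c(3, 7), grade = 2,
                               noise_sd = 0.02, seed = 1) {
  if (!is.numeric(canvas_size) || canvas_size < 16 || canvas_size %% 4 != 0)
    stop_usage("canvas_size must be >= 16 and divisible by 4")
  if (!is.numeric(n_nuclei) || n_nuclei < 0)
    stop_usage("n_nuclei must be a nonnegative count")
  if (length(nucleus_radius_range) != 2 || any(nucleus_radius_range <= 0) ||
      nucleus_radius_range[1] > nucleus_radius_range[2])
    stop_usage("nucleus_radius_range must be positive (min, max)")
  if (!grade %in% 0:3)
    stop_usage("grade must be one of 0, 1, 2, 3")
  if (!is.numeric(noise_sd) || noise_sd < 0 || noise_sd >= 0.5)
    stop_usage("noise_sd must satisfy 0 <= noise_sd < 0.5")
  structure(list(canvas_size = as.integer(canvas_size),
                 n_nuclei = as.integer(n_nuclei),
                 nucleus_radius_range = as.numeric(nucleus_radius_range),
                 grade = as.integer(grade),
                 noise_sd = as.numeric(noise_sd),
                 seed = as.integer(seed)),
            class = "stain_scene_params")
}

#' Fixed colour anchors of the synthetic stain renderer
#'
#' RGB triplets (on [0, 1]) for the hematoxylin-eosin source rendering (pale
#' eosin background, dark hematoxylin nuclei) and the immunohistochemistry
#' target rendering (pale background, counterstained nuclei, DAB-brown
#' membrane stain). These are configuration constants, not learned, so the
#' ground-truth source->target mapping stays known for oracle checks.
#'
#' @return Named list of RGB vectors.
#' @export
stain_colors <- function() {
  list(
    he_background  = c(0.91, 0.79, 0.86),
    he_nucleus     = c(0.27, 0.20, 0.50),
    ihc_background = c(0.93, 0.90, 0.87),
    ihc_nucleus    = c(0.50, 0.53, 0.69),
    dab            = c(0.40, 0.22, 0.08)
  )
}

# Relative ring outer radius: membrane band spans normalised radius (1, 1.35].
.ring_outer <- 1.35

#' Sample a nucleus layout
#'
#' Draws `n_nuclei` rotated ellipses uniformly over the canvas (centres kept
#' one maximal radius away from the border so every nucleus lies within the
#' canvas). Deterministic given `params$seed`; the caller's RNG state is left
#' untouched.
#'
#' @param params A [stain_scene_params()] object.
#' @return A `scene_layout`: data frame with columns `center_x`, `center_y`,
#'   `radius_x`, `radius_y`, `angle` (pixel units, angle in radians).
#' @export
sample_layout <- function(params) {
  if (!inherits(params, "stain_scene_params"))
    stop_usage("params must be a stain_scene_params object")
  n <- params$n_nuclei
  size <- params$canvas_size
  rmax <- params$nucleus_radius_range[2]
  margin <- min(rmax, size / 2 - 1)
  layout <- with_seed(params$seed, {
    data.frame(
      center_x = stats::runif(n, margin, size - margin),
      center_y = stats::runif(n, margin, size - margin),
      radius_x = stats::runif(n, params$nucleus_radius_range[1], rmax),
      radius_y = stats::runif(n, params$nucleus_radius_range[1], rmax),
      angle    = stats::runif(n, 0, pi)
    )
  })
  class(layout) <- c("scene_layout", "data.frame")
  layout
}

# Normalised elliptical radius field: for every pixel, the minimum over
# nuclei of the rotated-ellipse radial coordinate (1 on the nucleus border).
radius_field <- function(layout, canvas_size) {
  px <- rep(seq_len(canvas_size) - 0.5, each = canvas_size)   # column coord x
  py <- rep.int(seq_len(canvas_size) - 0.5, canvas_size)      # row coord y
  r <- rep(Inf, canvas_size * canvas_size)
  for (i in seq_len(nrow(layout))) {
    dx <- px - layout$center_x[i]
    dy <- py - layout$center_y[i]
    ca <- cos(layout$angle[i]); sa <- sin(layout$angle[i])
    u <- (dx * ca + dy * sa) / layout$radius_x[i]
    v <- (-dx * sa + dy * ca) / layout$radius_y[i]
    r <- pmin(r, sqrt(u * u + v * v))
  }
  matrix(r, canvas_size, canvas_size)
}

#' Nucleus mask of a layout
#'
#' @param layout A `scene_layout`.
#' @param canvas_size Canvas side in pixels.
#' @return Logical matrix, `TRUE` inside any nucleus.
#' @export
nucleus_mask <- function(layout, canvas_size) {
  radius_field(layout, canvas_size) <= 1
}

paint <- function(size, background) {
  img <- array(0, c(size, size, 3))
  for (ch in 1:3) img[, , ch] <- background[ch]
  img
}

apply_mask_color <- function(img, mask, color) {
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[mask] <- color[ch]
    img[, , ch] <- plane
  }
  img
}

add_noise <- function(img, sd, seed) {
  if (sd == 0) return(img)
  noisy <- with_seed(seed, img + stats::rnorm(length(img), sd = sd))
  array(pmin(pmax(noisy, 0), 1), dim(img))
}

#' Render the source (HE-like) image of a scene
#'
#' Pale eosin-pink background with dark hematoxylin-purple nuclei, plus
#' additive Gaussian noise (sd `params$noise_sd`) clipped to [0, 1]. The HE
#' appearance carries no information about the expression grade, as in real
#' tissue.
#'
#' @param layout A `scene_layout` from [sample_layout()].
#' @param params The matching [stain_scene_params()].
#' @return H x W x 3 array with values in [0, 1].
#' @export
render_source <- function(layout, params) {
  cols <- stain_colors()
  img <- paint(params$canvas_size, cols$he_background)
  img <- apply_mask_color(img, nucleus_mask(layout, params$canvas_size),
                          cols$he_nucleus)
  add_noise(img, params$noise_sd, derive_seed(params$seed, 1L))
}

#' Render the target (IHC-like) image of a scene
#'
#' Same geometry as [render_source()]: pale background, counterstained
#' nuclei, and a membrane ring around each nucleus stained DAB-brown with
#' intensity increasing linearly in `params$grade` (grade 0: unstained;
#' grade 3: maximal). Uses an independent noise stream from the source so the
#' pair shares geometry but not noise.
#'
#' @inheritParams render_source
#' @return H x W x 3 array with values in [0, 1].
#' @export
render_target <- function(layout, params) {
  cols <- stain_colors()
  size <- params$canvas_size
  img <- paint(size, cols$ihc_background)
  r <- radius_field(layout, size)
  strength <- params$grade / 3
  ring <- r > 1 & r <= .ring_outer
  ring_color <- (1 - strength) * cols$ihc_background + strength * cols$dab
  img <- apply_mask_color(img, ring, ring_color)
  img <- apply_mask_color(img, r <= 1, cols$ihc_nucleus)
  add_noise(img, params$noise_sd, derive_seed(params$seed, 2L))
}

#' Render a registered source/target pair
#'
#' @inheritParams render_source
#' @return An [image_pair()] with the scene grade attached.
#' @export
render_pair <- function(layout, params) {
  image_pair(render_source(layout, params), render_target(layout, params),
             id = paste0("scene_", params$seed), grade = params$grade)
}

# Largest-remainder apportionment of n into proportions p (ties to the
# earlier category), so exact when n * p is integral.
apportion <- function(n, p) {
  raw <- n * p
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

#' Generate a paired stain-translation dataset on disk
#'
#' Writes `n_pairs` registered source/target pairs in one of two layouts:
#' `paired_dirs` (`out_dir/A/<name>.png` and `out_dir/B/<name>.png`) or
#' `side_by_side` (one PNG per pair, source on the left half). A
#' `manifest.csv` (columns `name`, `grade`, `seed`, `dialect`) makes the
#' dataset fully reproducible from the base seed.
#'
#' @param n_pairs Number of pairs (>= 1).
#' @param grade_mix Length-4 proportions over grades 0..3; must sum to 1.
#'   Counts use largest-remainder rounding, so exact when divisible.
#' @param base_params [stain_scene_params()] supplying canvas size, nucleus
#'   statistics, noise level and the base seed.
#' @param out_dir Output directory (created if needed).
#' @param dialect `"paired_dirs"` or `"side_by_side"`.
#' @return Invisibly, the manifest data frame (with a `path`/`path_source`,
#'   `path_target` column depending on dialect).
#' @export
generate_dataset <- function(n_pairs, grade_mix = rep(0.25, 4),
                             base_params = stain_scene_params(),
                             out_dir,
                             dialect = c("paired_dirs", "side_by_side")) {
  dialect <- match.arg(dialect)
  if (!is.numeric(n_pairs) || n_pairs < 1)
    stop_usage("n_pairs must be >= 1")
  n_pairs <- as.integer(n_pairs)
  if (length(grade_mix) != 4 || any(grade_mix < 0) ||
      abs(sum(grade_mix) - 1) > 1e-8)
    stop_usage("grade_mix must be 4 nonnegative proportions summing to 1")
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    stop_io("cannot create output directory: ", out_dir)

  counts <- apportion(n_pairs, grade_mix)
  grades <- rep(0:3, counts)
  grades <- with_seed(derive_seed(base_params$seed, 17L),
                      sample(grades, length(grades)))

  if (dialect == "paired_dirs") {
    dir.create(file.path(out_dir, "A"), showWarnings = FALSE)
    dir.create(file.path(out_dir, "B"), showWarnings = FALSE)
  }

  rows <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    seed_i <- derive_seed(base_params$seed, 1000L + i)
    p <- base_params
    p$grade <- grades[i]
    p$seed <- seed_i
    pair <- render_pair(sample_layout(p), p)
    name <- sprintf("pair_%04d", i)
    if (dialect == "paired_dirs") {
      pa <- file.path(out_dir, "A", paste0(name, ".png"))
      pb <- file.path(out_dir, "B", paste0(name, ".png"))
      save_image(pair$source, pa)
      save_image(pair$target, pb)
      rows[[i]] <- data.frame(name = name, grade = grades[i], seed = seed_i,
                              dialect = dialect,
                              path_source = file.path("A", basename(pa)),
                              path_target = file.path("B", basename(pb)))
    } else {
      pp <- file.path(out_dir, paste0(name, ".png"))
      img <- array(0, c(p$canvas_size, 2L * p$canvas_size, 3L))
      img[, seq_len(p$canvas_size), ] <- pair$source
      img[, p$canvas_size + seq_len(p$canvas_size), ] <- pair$target
      save_image(img, pp)
      rows[[i]] <- data.frame(name = name, grade = grades[i], seed = seed_i,
                              dialect = dialect, path = basename(pp))
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
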