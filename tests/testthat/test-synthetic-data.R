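test_that("layout sampling is deterministic under the seed", {
  p <- stain_scene_params(n_nuclei = 10, seed = 7)
  expect_identical(sample_layout(p), sample_layout(p))
  p8 <- stain_scene_params(n_nuclei = 10, seed = 8)
  expect_false(isTRUE(all.equal(sample_layout(p), sample_layout(p8))))
  p0 <- stain_scene_params(n_nuclei = 0, seed = 7)
  expect_equal(nrow(sample_layout(p0)), 0)
  lay <- sample_layout(p)
  expect_true(all(lay$center_x > 0 & lay$center_x < p$canvas_size))
  expect_true(all(lay$center_y > 0 & lay$center_y < p$canvas_size))
  expect_true(all(lay$radius_x > 0 & lay$radius_y > 0))
})

test_that("parameter validation rejects out-of-range scenes", {
  expect_error(stain_scene_params(canvas_size = 8), class = "mggan_usage_error")
  expect_error(stain_scene_params(grade = 4), class = "mggan_usage_error")
  expect_error(stain_scene_params(noise_sd = 0.5), class = "mggan_usage_error")
  expect_error(stain_scene_params(n_nuclei = -1), class = "mggan_usage_error")
})

test_that("noiseless source rendering hits the colour anchors exactly", {
  cols <- stain_colors()
  p <- stain_scene_params(n_nuclei = 0, noise_sd = 0, seed = 1)
  img <- render_source(sample_layout(p), p)
  for (ch in 1:3)
    expect_true(all(img[, , ch] == cols$he_background[ch]))

  # one nucleus centred on the canvas: the central pixel is pure nucleus
  p1 <- stain_scene_params(canvas_size = 32, n_nuclei = 1,
                           nucleus_radius_range = c(5, 6), noise_sd = 0,
                           seed = 3)
  lay <- sample_layout(p1)
  lay$center_x <- 16; lay$center_y <- 16
  img1 <- render_source(lay, p1)
  expect_equal(as.vector(img1[16, 16, ]), cols$he_nucleus)
})

test_that("additive noise has the configured standard deviation", {
  # one large nucleus gives >1e4 interior pixels far from the clip bounds
  p <- stain_scene_params(canvas_size = 128, n_nuclei = 1,
                          nucleus_radius_range = c(60, 62), noise_sd = 0.05,
                          seed = 11)
  lay <- sample_layout(p)
  lay$center_x <- 64; lay$center_y <- 64
  p0 <- p; p0$noise_sd <- 0
  noisy <- render_source(lay, p)
  clean <- render_source(lay, p0)
  mask <- array(rep(nucleus_mask(lay, 128), 3), dim(noisy))
  expect_gt(sum(mask), 3e4)
  dev_sd <- sd((noisy - clean)[mask])
  expect_lt(abs(dev_sd - 0.05) / 0.05, 0.2)
})

test_that("membrane staining is absent at grade 0 and increases with grade", {
  base <- stain_scene_params(canvas_size = 64, n_nuclei = 8, noise_sd = 0,
                             seed = 5)
  lay <- sample_layout(base)
  cols <- stain_colors()
  renders <- lapply(0:3, function(g) {
    p <- base; p$grade <- g
    render_target(lay, p)
  })
  # grade 0: every pixel outside nuclei is pure background
  nuc <- array(rep(nucleus_mask(lay, 64), 3), dim(renders[[1]]))
  bg <- array(rep(cols$ihc_background, each = 64 * 64), dim(renders[[1]]))
  expect_true(all(renders[[1]][!nuc] == bg[!nuc]))
  # ring darkness (1 - mean intensity on the ring) strictly increases
  r <- mggan:::radius_field(lay, 64)
  ring <- array(rep(r > 1 & r <= mggan:::.ring_outer, 3), dim(renders[[1]]))
  darkness <- vapply(renders, function(im) 1 - mean(im[ring]), numeric(1))
  expect_true(all(diff(darkness) > 0))
  expect_gt(darkness[4], darkness[2])   # grade 3 > grade 1
  # geometry is shared: identical nucleus masks across all grades
  for (g in 2:4)
    expect_identical(renders[[1]][!ring & !nuc], renders[[g]][!ring & !nuc])
  pair <- render_pair(lay, base)
  expect_identical(dim(pair$source), dim(pair$target))
})

test_that("generate_dataset writes exact grade counts and is reproducible", {
  base <- stain_scene_params(canvas_size = 16, n_nuclei = 3,
                             nucleus_radius_range = c(2, 3), seed = 9)
  d1 <- file.path(tempdir(), "gen_a")
  d2 <- file.path(tempdir(), "gen_b")
  unlink(c(d1, d2), recursive = TRUE)
  m1 <- generate_dataset(8, rep(0.25, 4), base, d1, "paired_dirs")
  m2 <- generate_dataset(8, rep(0.25, 4), base, d2, "paired_dirs")
  expect_equal(as.vector(table(m1$grade)), rep(2L, 4))
  # byte-identical outputs under the same base seed
  f1 <- list.files(d1, recursive = TRUE, full.names = TRUE)
  f2 <- list.files(d2, recursive = TRUE, full.names = TRUE)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  # skewed mix: exact counts when divisible
  d3 <- file.path(tempdir(), "gen_c")
  unlink(d3, recursive = TRUE)
  m3 <- generate_dataset(100, c(0.5, 0.5, 0, 0), base, d3, "paired_dirs")
  expect_equal(sum(m3$grade == 0), 50)
  expect_equal(sum(m3$grade == 1), 50)
  pairs <- load_dataset(d3)
  expect_length(pairs, 100)
})

test_that("side_by_side dialect round-trips through load_dataset", {
  base <- stain_scene_params(canvas_size = 16, n_nuclei = 2,
                             nucleus_radius_range = c(2, 3), noise_sd = 0,
                             seed = 4)
  d <- file.path(tempdir(), "gen_sbs")
  unlink(d, recursive = TRUE)
  generate_dataset(3, rep(0.25, 4), base, d, "side_by_side")
  pairs <- load_dataset(d)
  expect_length(pairs, 3)
  expect_identical(dim(pairs[[1]]$source), c(16L, 16L, 3L))
  # same scenes written as paired_dirs agree up to 8-bit quantisation
  d2 <- file.path(tempdir(), "gen_sbs2")
  unlink(d2, recursive = TRUE)
  generate_dataset(3, rep(0.25, 4), base, d2, "paired_dirs")
  pairs2 <- load_dataset(d2)
  expect_lt(max(abs(pairs[[1]]$source - pairs2[[1]]$source)), 1e-12)
})
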