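#' A registered source/target image pair
#'
#' Container for one aligned (source stain, target stain) RGB pair. All
#' intensities live on the normalised [0, 1] scale; this is the convention
#' used throughout the package (so the cross-entropy consistency loss has
#' arguments in (0, 1) and the PSNR peak value is 1).
#'
#' @param source,target H x W x 3 arrays in [0, 1] with identical dimensions.
#' @param id Identifier string.
#' @param grade Optional integer expression grade.
#' @return An object of class `image_pair`.
#' @export
image_pair <- function(source, target, id = "pair", grade = NULL) {
  check_image(source, "source")
  check_image(target, "target")
  check_same_shape(source, target, "source and target")
  structure(list(source = source, target = target, id = as.character(id),
                 grade = grade),
            class = "image_pair")
}

#' @export
print.image_pair <- function(x, ...) {
  d <- dim(x$source)
  cat(sprintf("<image_pair '%s'> %dx%d px%s\n", x$id, d[1], d[2],
              if (!is.null(x$grade)) sprintf(", grade %d", x$grade) else ""))
  invisible(x)
}

read_image <- function(path) {
  if (!file.exists(path)) stop_io("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop_validation("unsupported image format: .", ext)
  )
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3L] == 4L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Load a registered image pair from disk
#'
#' Supports two dataset dialects: `paired_dirs`, where source and target live
#' in separate files, and `side_by_side`, where one composite image carries
#' the source on the left half and the target on the right. 8- and 16-bit
#' PNG/TIFF are normalised to [0, 1] by their bit-depth maximum (the codecs
#' do this natively).
#'
#' @param path_or_paths For `paired_dirs`, character vector of two paths
#'   (source, target); for `side_by_side`, one path.
#' @param dialect `"paired_dirs"` or `"side_by_side"`.
#' @param id Identifier; defaults to the (first) file name.
#' @param grade Optional grade annotation.
#' @return An [image_pair()].
#' @export
load_pair <- function(path_or_paths,
                      dialect = c("paired_dirs", "side_by_side"),
                      id = NULL, grade = NULL) {
  dialect <- match.arg(dialect)
  if (is.null(id))
    id <- tools::file_path_sans_ext(basename(path_or_paths[1]))
  if (dialect == "paired_dirs") {
    if (length(path_or_paths) != 2)
      stop_usage("paired_dirs dialect needs two paths (source, target)")
    src <- read_image(path_or_paths[1])
    tgt <- read_image(path_or_paths[2])
    if (!identical(dim(src), dim(tgt)))
      stop_validation("source and target shapes differ for pair '", id, "'")
  } else {
    img <- read_image(path_or_paths[1])
    w <- dim(img)[2L]
    if (w %% 2L != 0L)
      stop_validation("side_by_side image must have even width, got ", w)
    src <- img[, seq_len(w %/% 2L), , drop = FALSE]
    tgt <- img[, w %/% 2L + seq_len(w %/% 2L), , drop = FALSE]
  }
  image_pair(src, tgt, id = id, grade = grade)
}

#' Save an image losslessly
#'
#' Quantises by `round(v * (2^bits - 1))` and writes PNG (8-bit) or TIFF
#' (8- or 16-bit, chosen by file extension). Values must already be in
#' [0, 1]; out-of-range input is an error so that clipping is always an
#' explicit caller decision.
#'
#' @param image H x W x 3 array in [0, 1].
#' @param path Output path ending in .png, .tif or .tiff.
#' @param bit_depth 8 or 16 (16 requires TIFF).
#' @return Invisibly, `path`.
#' @export
save_image <- function(image, path, bit_depth = 8) {
  check_image(image, "image")
  if (!bit_depth %in% c(8, 16)) stop_usage("bit_depth must be 8 or 16")
  maxv <- 2^bit_depth - 1
  q <- round(image * maxv) / maxv
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (bit_depth != 8)
      stop_usage("PNG output is 8-bit; use a .tiff path for 16-bit")
    png::writePNG(q, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(q, path, bits.per.sample = bit_depth)
  } else {
    stop_validation("unsupported output format: .", ext)
  }
  invisible(path)
}

#' Split pairs into train and test sets
#'
#' Deterministic seeded shuffle; the test set holds `round(n * test_fraction)`
#' pairs and the split is disjoint and exhaustive.
#'
#' @param pairs List of [image_pair()] objects (ids must be unique).
#' @param test_fraction Fraction in (0, 1).
#' @param seed Integer seed for the shuffle.
#' @return A `dataset_split`: list with elements `train` and `test`.
#' @export
split_dataset <- function(pairs, test_fraction, seed = 1) {
  n <- length(pairs)
  if (n < 2) stop_usage("need at least 2 pairs to split")
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1)
    stop_usage("test_fraction must be in (0, 1)")
  ids <- vapply(pairs, function(p) p$id, character(1))
  if (anyDuplicated(ids))
    stop_validation("pair ids must be unique")
  n_test <- round(n * test_fraction)
  n_test <- max(1L, min(n - 1L, as.integer(n_test)))
  perm <- with_seed(seed, sample.int(n))
  structure(list(test = pairs[perm[seq_len(n_test)]],
                 train = pairs[perm[-seq_len(n_test)]]),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> %d train / %d test pairs\n",
              length(x$train), length(x$test)))
  invisible(x)
}

#' Load a generated dataset from its manifest
#'
#' Reads the `manifest.csv` written by [generate_dataset()] and loads every
#' pair in manifest order.
#'
#' @param dir Dataset directory containing `manifest.csv`.
#' @return List of [image_pair()] objects with grades attached.
#' @export
load_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop_io("no manifest.csv in ", dir)
  manifest <- utils::read.csv(mf, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    if (identical(row$dialect, "side_by_side")) {
      load_pair(file.path(dir, basename(row$path)), "side_by_side",
                id = row$name, grade = row$grade)
    } else {
      load_pair(c(file.path(dir, "A", paste0(row$name, ".png")),
                  file.path(dir, "B", paste0(row$name, ".png"))),
                "paired_dirs", id = row$name, grade = row$grade)
    }
  })
}
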