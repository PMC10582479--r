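# Shared validation helpers and error conditions.
#
# Error classes map onto the CLI exit-code contract:
#   mggan_usage_error      -> bad arguments / parameters (exit 64)
#   mggan_io_error         -> missing or unwritable files (exit 74)
#   mggan_validation_error -> malformed data (exit 65)

stop_usage <- function(...) {
  stop(errorCondition(paste0(...), class = c("mggan_usage_error", "mggan_error")))
}

stop_io <- function(...) {
  stop(errorCondition(paste0(...), class = c("mggan_io_error", "mggan_error")))
}

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("mggan_validation_error", "mggan_error")))
}

# Run expr under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic derived seeds, kept inside the 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) %% 2147483647 + as.double(k) * 7919) %% 2147483647)
}

is_image <- function(x) {
  is.numeric(x) && length(dim(x)) == 3L && dim(x)[3L] == 3L
}

check_image <- function(x, name = "image", range01 = TRUE) {
  if (!is_image(x))
    stop_validation(name, " must be an H x W x 3 numeric array")
  if (range01 && (min(x) < 0 || max(x) > 1))
    stop_validation(name, " must have values in [0, 1]")
  invisible(x)
}

check_same_shape <- function(a, b, what = "images") {
  if (!identical(dim(a), dim(b)))
    stop_validation(what, " must have identical dimensions (",
                    paste(dim(a), collapse = "x"), " vs ",
                    paste(dim(b), collapse = "x"), ")")
  invisible(NULL)
}

fmt_num <- function(x, digits = 4) formatC(x, digits = digits, format = "fg")
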