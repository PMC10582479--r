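# 2-D convolution via im2col + BLAS matrix multiply.
#
# Images are (H, W, C) arrays, column-major. im2col gathers, for every output
# pixel, the k*k*Cin receptive-field values into one row of a matrix; the
# convolution is then a single matrix product with the (k*k*Cin, Cout) weight
# matrix. Gather/scatter index maps depend only on the geometry and are
# cached per (padded size, channels, kernel, stride).

.conv_cache <- new.env(parent = emptyenv())

im2col_map <- function(hp, wp, cin, k, stride) {
  key <- paste(hp, wp, cin, k, stride, sep = "x")
  hit <- .conv_cache[[key]]
  if (!is.null(hit)) return(hit)
  oh <- (hp - k) %/% stride + 1L
  ow <- (wp - k) %/% stride + 1L
  oi <- rep.int(seq_len(oh), ow)
  oj <- rep(seq_len(ow), each = oh)
  base <- (oi - 1L) * stride + (oj - 1L) * stride * hp          # 0-based corners
  ki <- rep.int(seq_len(k), k * cin)
  kj <- rep.int(rep(seq_len(k), each = k), cin)
  kc <- rep(seq_len(cin), each = k * k)
  off <- (ki - 1L) + (kj - 1L) * hp + (kc - 1L) * hp * wp
  idx <- outer(base, off, "+") + 1L
  storage.mode(idx) <- "integer"
  idxvec <- as.vector(idx)
  map <- list(idx = idx, idxvec = idxvec, groups = sort(unique(idxvec)),
              oh = oh, ow = ow)
  assign(key, map, envir = .conv_cache)
  map
}

pad_hw <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1L] + 2L * p, d[2L] + 2L * p, d[3L]))
  out[p + seq_len(d[1L]), p + seq_len(d[2L]), ] <- x
  out
}

unpad_hw <- function(x, p, d) {
  if (p == 0L) return(x)
  x[p + seq_len(d[1L]), p + seq_len(d[2L]), , drop = FALSE]
}

conv2d_forward <- function(x, w, b, stride = 1L, pad = 0L) {
  dx <- dim(x)
  dw <- dim(w)
  stopifnot(dx[3L] == dw[3L])
  xp <- pad_hw(x, pad)
  dp <- dim(xp)
  map <- im2col_map(dp[1L], dp[2L], dp[3L], dw[1L], stride)
  cols <- matrix(xp[map$idx], nrow = nrow(map$idx))
  wm <- matrix(w, nrow = dw[1L] * dw[2L] * dw[3L])
  y <- cols %*% wm
  y <- y + rep(b, each = nrow(y))
  list(y = array(y, c(map$oh, map$ow, dw[4L])), cols = cols, map = map)
}

conv2d_backward <- function(gy, cols, map, x_dim, w, stride, pad,
                            need_dx = TRUE) {
  dw <- dim(w)
  gym <- matrix(gy, nrow = nrow(cols))
  dwm <- crossprod(cols, gym)
  db <- colSums(gym)
  dx <- NULL
  if (need_dx) {
    wm <- matrix(w, nrow = dw[1L] * dw[2L] * dw[3L])
    dcols <- tcrossprod(gym, wm)
    acc <- rowsum.default(as.vector(dcols), map$idxvec)
    hp <- x_dim[1L] + 2L * pad
    wp <- x_dim[2L] + 2L * pad
    dxp <- numeric(hp * wp * x_dim[3L])
    dxp[map$groups] <- acc
    dx <- unpad_hw(array(dxp, c(hp, wp, x_dim[3L])), pad, x_dim)
  }
  list(dw = array(dwm, dw), db = db, dx = dx)
}

# Autodiff convolution node. w, b are parameter nodes; x may be a node or a
# plain array.
op_conv2d <- function(x, w, b, stride = 1L, pad = 1L) {
  x <- as_ad(x)
  fw <- conv2d_forward(x$value, w$value, b$value, stride, pad)
  x_dim <- dim(x$value)
  ad_node(fw$y, list(x, w, b), function(g, n) {
    bk <- conv2d_backward(g, fw$cols, fw$map, x_dim, w$value, stride, pad,
                          need_dx = x$requires_grad)
    list(bk$dx, bk$dw, bk$db)
  })
}

# He-style initial weights for a (k, k, cin, cout) kernel.
init_conv_w <- function(k, cin, cout, gain = 1) {
  sd <- gain * sqrt(2 / (k * k * cin))
  array(stats::rnorm(k * k * cin * cout, sd = sd), c(k, k, cin, cout))
}

conv_layer_params <- function(k, cin, cout, gain = 1) {
  list(w = ad_param(init_conv_w(k, cin, cout, gain)),
       b = ad_param(numeric(cout)))
}
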