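# Reverse-mode automatic differentiation on dense numeric arrays.
#
# A computation is a DAG of nodes; each node holds its forward value, its
# parent nodes and a backward closure that maps the node's upstream gradient
# to gradients for each parent. Gradients only flow through nodes reachable
# from a parameter (requires_grad propagation), so constant inputs cost
# nothing on the backward pass.

.ad <- new.env(parent = emptyenv())
.ad$gen <- 0L

ad_node <- function(value, parents = list(), backfn = NULL) {
  n <- new.env(parent = emptyenv())
  n$vgen <- 0L
  n$value <- value
  n$parents <- parents
  n$backfn <- backfn
  n$grad <- NULL
  n$is_param <- FALSE
  n$requires_grad <- any(vapply(parents, function(p) p$requires_grad, logical(1)))
  class(n) <- "ad_node"
  n
}

#' @keywords internal
ad_const <- function(value) ad_node(value)

ad_param <- function(value) {
  n <- ad_node(value)
  n$is_param <- TRUE
  n$requires_grad <- TRUE
  n
}

ad_value <- function(x) if (inherits(x, "ad_node")) x$value else x

as_ad <- function(x) if (inherits(x, "ad_node")) x else ad_const(x)

# Accumulate gradient g into node n.
ad_accum <- function(n, g) {
  if (is.null(g)) return(invisible(NULL))
  n$grad <- if (is.null(n$grad)) g else n$grad + g
  invisible(NULL)
}

# Backpropagate from a scalar root. Fills $grad on every node that requires
# a gradient; returns invisibly the topological order used.
ad_backward <- function(root) {
  stopifnot(inherits(root, "ad_node"), length(root$value) == 1L)
  topo <- vector("list", 256L)
  k <- 0L
  # visitation is marked by a per-call generation stamp on the nodes; this
  # avoids interning one symbol per node, which would grow R's symbol table
  gen <- .ad$gen + 1L
  .ad$gen <- gen
  visit <- function(n) {
    if (n$vgen == gen || !n$requires_grad) return(invisible(NULL))
    n$vgen <- gen
    for (p in n$parents) visit(p)
    k <<- k + 1L
    if (k > length(topo)) length(topo) <<- 2L * k
    topo[[k]] <<- n
    invisible(NULL)
  }
  visit(root)
  root$grad <- 1
  for (i in rev(seq_len(k))) {
    n <- topo[[i]]
    if (is.null(n$backfn) || is.null(n$grad)) next
    gs <- n$backfn(n$grad, n)
    for (j in seq_along(n$parents)) {
      p <- n$parents[[j]]
      if (p$requires_grad) ad_accum(p, gs[[j]])
    }
  }
  invisible(topo[seq_len(k)])
}

ad_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---- elementwise ops --------------------------------------------------------

op_add <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  ad_node(a$value + b$value, list(a, b), function(g, n) list(g, g))
}

op_lrelu <- function(x, alpha = 0.2) {
  v <- x$value
  y <- pmax(v, 0) + alpha * pmin(v, 0)
  dim(y) <- dim(v)
  ad_node(y, list(x), function(g, n) {
    d <- ifelse(v > 0, 1, alpha)
    list(g * d)
  })
}

op_relu <- function(x) {
  v <- x$value
  y <- pmax(v, 0)
  dim(y) <- dim(v)
  ad_node(y, list(x), function(g, n) list(g * (v > 0)))
}

op_sigmoid <- function(x) {
  y <- stats::plogis(x$value)
  dim(y) <- dim(x$value)
  ad_node(y, list(x), function(g, n) list(g * y * (1 - y)))
}

# Instance normalisation: zero mean / unit variance per channel over the
# spatial grid (population variance). No learned affine terms; the following
# convolution supplies scale and shift.
op_instance_norm <- function(x, eps = 1e-5) {
  v <- x$value
  d <- dim(v)
  np <- d[1L] * d[2L]
  xm <- matrix(v, np, d[3L])
  mu <- colMeans(xm)
  xc <- xm - rep(mu, each = np)
  inv <- 1 / sqrt(colMeans(xc * xc) + eps)
  xhat <- xc * rep(inv, each = np)
  y <- array(xhat, d)
  ad_node(y, list(x), function(g, n) {
    gm <- matrix(g, np, d[3L])
    gmean <- colMeans(gm)
    gxmean <- colMeans(gm * xhat)
    dx <- (gm - rep(gmean, each = np) - xhat * rep(gxmean, each = np)) *
      rep(inv, each = np)
    list(array(dx, d))
  })
}

op_norm <- function(x, mode) {
  switch(mode,
    none = x,
    instance = op_instance_norm(x),
    batch = op_instance_norm(x),
    stop("unknown norm_mode: ", mode)
  )
}

# Channel-wise concatenation of (H, W, Ca) and (H, W, Cb).
op_concat_c <- function(a, b) {
  da <- dim(a$value); db <- dim(b$value)
  stopifnot(da[1L] == db[1L], da[2L] == db[2L])
  y <- array(c(a$value, b$value), c(da[1L], da[2L], da[3L] + db[3L]))
  na <- length(a$value)
  ad_node(y, list(a, b), function(g, n) {
    gv <- as.vector(g)
    list(array(gv[seq_len(na)], da), array(gv[-seq_len(na)], db))
  })
}

# Extract the sub-image rows ri, cols rj (contiguous ranges).
op_crop <- function(x, ri, rj) {
  d <- dim(x$value)
  y <- x$value[ri, rj, , drop = FALSE]
  ad_node(y, list(x), function(g, n) {
    dx <- array(0, d)
    dx[ri, rj, ] <- g
    list(dx)
  })
}

op_mean <- function(x) {
  v <- x$value
  ad_node(mean(v), list(x), function(g, n) {
    gv <- rep(g / length(v), length(v))
    dim(gv) <- dim(v)
    list(gv)
  })
}

# Collect scalar nodes into one vector node.
op_stack <- function(nodes) {
  vals <- vapply(nodes, function(n) n$value, numeric(1))
  ad_node(vals, nodes, function(g, n) as.list(g))
}

# Weighted sum of scalar nodes: sum_i w[i] * nodes[[i]].
op_wsum <- function(nodes, w) {
  vals <- vapply(nodes, function(n) n$value, numeric(1))
  ad_node(sum(w * vals), nodes, function(g, n) as.list(g * w))
}

# ---- resampling -------------------------------------------------------------

# Nearest-neighbour upsampling by integer factor f.
op_upsample_nearest <- function(x, f) {
  d <- dim(x$value)
  ri <- rep(seq_len(d[1L]), each = f)
  rj <- rep(seq_len(d[2L]), each = f)
  y <- x$value[ri, rj, , drop = FALSE]
  ad_node(y, list(x), function(g, n) {
    # each source pixel receives the sum over its f x f block
    gp <- array(g, c(f, d[1L], f * d[2L] * d[3L]))
    s1 <- array(colSums(gp), c(d[1L], f, d[2L] * d[3L]))
    s2 <- colSums(aperm(s1, c(2L, 1L, 3L)))
    list(array(s2, d))
  })
}

# Average pooling by integer factor f (used to build the coarse-branch input).
op_avgpool <- function(x, f) {
  d <- dim(x$value)
  stopifnot(d[1L] %% f == 0L, d[2L] %% f == 0L)
  h <- d[1L] %/% f; w <- d[2L] %/% f
  gp <- array(x$value, c(f, h, f * w * d[3L]))
  s1 <- array(colSums(gp), c(h, f, w * d[3L]))
  s2 <- colSums(aperm(s1, c(2L, 1L, 3L)))
  y <- array(s2 / (f * f), c(h, w, d[3L]))
  ad_node(y, list(x), function(g, n) {
    ri <- rep(seq_len(h), each = f)
    rj <- rep(seq_len(w), each = f)
    list(g[ri, rj, , drop = FALSE] / (f * f))
  })
}

# ---- loss ops ---------------------------------------------------------------

clamp01 <- function(x, eps = 1e-7) pmin(pmax(x, eps), 1 - eps)

# Mean absolute deviation between node x and constant array ref.
op_l1_to <- function(ref, x) {
  v <- x$value
  stopifnot(length(v) == length(ref))
  ad_node(mean(abs(v - ref)), list(x), function(g, n) {
    list(array(g * sign(v - ref) / length(v), dim(v)))
  })
}

# Pixel-wise binary cross-entropy of node x against constant reference ref.
op_bce_to <- function(ref, x, eps = 1e-7) {
  v <- x$value
  s <- clamp01(v, eps)
  val <- -mean(ref * log(s) + (1 - ref) * log(1 - s))
  ad_node(val, list(x), function(g, n) {
    d <- (-ref / s + (1 - ref) / (1 - s)) / length(v)
    d[v <= eps | v >= 1 - eps] <- 0
    list(array(g * d, dim(v)))
  })
}

op_negmeanlog <- function(x, eps = 1e-7) {
  v <- x$value
  s <- clamp01(v, eps)
  ad_node(-mean(log(s)), list(x), function(g, n) {
    d <- -1 / (s * length(v))
    d[v <= eps | v >= 1 - eps] <- 0
    list(g * d)
  })
}

op_negmeanlog1m <- function(x, eps = 1e-7) {
  v <- x$value
  s <- clamp01(v, eps)
  ad_node(-mean(log(1 - s)), list(x), function(g, n) {
    d <- 1 / ((1 - s) * length(v))
    d[v <= eps | v >= 1 - eps] <- 0
    list(g * d)
  })
}

# 0.5 * mean((x - a)^2) for scalar target a (least-squares GAN terms).
op_half_mean_sq <- function(x, a = 0) {
  v <- x$value
  ad_node(0.5 * mean((v - a)^2), list(x), function(g, n) {
    list(g * (v - a) / length(v))
  })
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) array(0, dim(p$value) %||% length(p$value))),
    v = lapply(params, function(p) array(0, dim(p$value) %||% length(p$value))),
    t = 0L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One Adam update in place on the parameter nodes; gradients are read from
# p$grad and cleared by the caller.
adam_step <- function(params, state, lr, beta1 = 0.5, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in seq_along(params)) {
    p <- params[[k]]
    g <- p$grad
    if (is.null(g)) next
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g * g
    mhat <- state$m[[k]] / bc1
    vhat <- state$v[[k]] / bc2
    p$value <- p$value - lr * mhat / (sqrt(vhat) + eps)
  }
  state
}

# Extract plain-array copies of parameter values (checkpointing).
params_snapshot <- function(params) lapply(params, function(p) p$value)

params_restore <- function(params, snapshot) {
  stopifnot(length(params) == length(snapshot))
  for (k in seq_along(params)) params[[k]]$value <- snapshot[[k]]
  invisible(NULL)
}
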