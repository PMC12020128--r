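# Minimal tape-based reverse-mode automatic differentiation on dense numeric
# arrays. Every differentiable component in the package (augmenter generator,
# consistency classifier, backbones, gate fusion, task heads, losses) is built
# from the primitives below. Nodes are environments; ids increase at creation,
# and every parent is created before its child, so reverse-id order is a valid
# topological order for backpropagation.

.ag <- new.env(parent = emptyenv())
.ag$id <- 0L

new_ag_node <- function(value, parents = list(), backfn = NULL) {
  .ag$id <- .ag$id + 1L
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$parents <- parents
  node$backfn <- backfn
  node$id <- .ag$id
  class(node) <- "ag_node"
  node
}

is_ag_node <- function(x) inherits(x, "ag_node")

#' Numeric value of an autodiff node (or passthrough for plain numerics)
#' @param x an `ag_node` or numeric array
#' @return the underlying numeric value
#' @export
ag_value <- function(x) if (is_ag_node(x)) x$value else x

#' Create a leaf (parameter) node
#' @param value numeric array holding the parameter values
#' @return an `ag_node` leaf whose gradient is populated by [ag_backward()]
#' @export
ag_leaf <- function(value) new_ag_node(value)

as_node <- function(x) if (is_ag_node(x)) x else new_ag_node(x)

accumulate_grad <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
}

#' Reverse-mode sweep from a scalar node
#'
#' Accumulates gradients into every reachable node's `$grad` field.
#' @param node scalar-valued `ag_node` (the objective)
#' @export
ag_backward <- function(node) {
  stopifnot(is_ag_node(node), length(node$value) == 1L)
  # collect reachable subgraph
  seen <- new.env(parent = emptyenv())
  stack <- list(node)
  nodes <- list()
  while (length(stack)) {
    cur <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(cur$id)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    nodes[[length(nodes) + 1L]] <- cur
    for (p in cur$parents) stack[[length(stack) + 1L]] <- p
  }
  ord <- order(vapply(nodes, function(n) n$id, integer(1)), decreasing = TRUE)
  for (n in nodes) n$grad <- NULL
  node$grad <- 1
  for (i in ord) {
    cur <- nodes[[i]]
    if (is.null(cur$grad) || is.null(cur$backfn)) next
    gs <- cur$backfn(cur$grad)
    for (j in seq_along(cur$parents)) {
      if (!is.null(gs[[j]])) accumulate_grad(cur$parents[[j]], gs[[j]])
    }
  }
  invisible(node)
}

shape_of <- function(x) if (is.null(dim(x))) length(x) else dim(x)

# ---- elementwise arithmetic ------------------------------------------------

#' @rdname ag_ops
#' @param a,b nodes or numerics (scalar or same shape)
#' @export
ag_add <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  va <- a$value; vb <- b$value
  new_ag_node(va + vb, list(a, b), function(g) {
    list(if (length(va) == 1L && length(g) > 1L) sum(g) else g,
         if (length(vb) == 1L && length(g) > 1L) sum(g) else g)
  })
}

#' @rdname ag_ops
#' @export
ag_sub <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  va <- a$value; vb <- b$value
  new_ag_node(va - vb, list(a, b), function(g) {
    list(if (length(va) == 1L && length(g) > 1L) sum(g) else g,
         if (length(vb) == 1L && length(g) > 1L) -sum(g) else -g)
  })
}

#' @rdname ag_ops
#' @export
ag_mul <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  va <- a$value; vb <- b$value
  new_ag_node(va * vb, list(a, b), function(g) {
    ga <- g * vb; gb <- g * va
    list(if (length(va) == 1L && length(ga) > 1L) sum(ga) else ga,
         if (length(vb) == 1L && length(gb) > 1L) sum(gb) else gb)
  })
}

#' @rdname ag_ops
#' @export
ag_div <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  va <- a$value; vb <- b$value
  new_ag_node(va / vb, list(a, b), function(g) {
    ga <- g / vb; gb <- -g * va / vb^2
    list(if (length(va) == 1L && length(ga) > 1L) sum(ga) else ga,
         if (length(vb) == 1L && length(gb) > 1L) sum(gb) else gb)
  })
}

#' @rdname ag_ops
#' @export
ag_neg <- function(a) {
  a <- as_node(a)
  new_ag_node(-a$value, list(a), function(g) list(-g))
}

# ---- activations -----------------------------------------------------------

#' Autodiff primitives
#'
#' Elementwise, linear-algebra and image primitives of the reverse-mode
#' engine. All accept `ag_node`s or plain numerics and return `ag_node`s.
#' @name ag_ops
#' @param x node or numeric array
#' @return an `ag_node`
NULL

#' @rdname ag_ops
#' @export
ag_sigmoid <- function(x) {
  x <- as_node(x)
  s <- 1 / (1 + exp(-x$value))
  new_ag_node(s, list(x), function(g) list(g * s * (1 - s)))
}

#' @rdname ag_ops
#' @export
ag_tanh <- function(x) {
  x <- as_node(x)
  t <- tanh(x$value)
  new_ag_node(t, list(x), function(g) list(g * (1 - t^2)))
}

#' @rdname ag_ops
#' @export
ag_relu <- function(x) {
  x <- as_node(x)
  v <- x$value
  new_ag_node(pmax(v, 0), list(x), function(g) list(g * (v > 0)))
}

#' @rdname ag_ops
#' @export
ag_gelu <- function(x) {
  x <- as_node(x)
  v <- x$value
  ph <- stats::pnorm(v)
  out <- v * ph
  if (!is.null(dim(v))) dim(out) <- dim(v)
  new_ag_node(out, list(x), function(g) list(g * (ph + v * stats::dnorm(v))))
}

#' @rdname ag_ops
#' @export
ag_log <- function(x) {
  x <- as_node(x)
  v <- x$value
  new_ag_node(log(v), list(x), function(g) list(g / v))
}

#' @rdname ag_ops
#' @export
ag_exp <- function(x) {
  x <- as_node(x)
  e <- exp(x$value)
  new_ag_node(e, list(x), function(g) list(g * e))
}

# Clamp with straight-through gradient inside [lo, hi]; zero where the input
# fell strictly outside (saturation).
#' @rdname ag_ops
#' @param lo,hi clamp bounds
#' @export
ag_clamp <- function(x, lo, hi) {
  x <- as_node(x)
  v <- x$value
  inside <- (v >= lo) & (v <= hi)
  out <- pmin(pmax(v, lo), hi)
  if (!is.null(dim(v))) dim(out) <- dim(v)
  new_ag_node(out, list(x), function(g) list(g * inside))
}

#' @rdname ag_ops
#' @export
ag_pmax <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  va <- a$value; vb <- b$value
  awins <- va >= vb
  out <- pmax(va, vb)
  if (!is.null(dim(va))) dim(out) <- dim(va)
  new_ag_node(out, list(a, b), function(g) {
    ga <- g * awins; gb <- g * !awins
    list(if (length(va) == 1L && length(ga) > 1L) sum(ga) else ga,
         if (length(vb) == 1L && length(gb) > 1L) sum(gb) else gb)
  })
}

#' @rdname ag_ops
#' @export
ag_pmin <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  va <- a$value; vb <- b$value
  awins <- va <= vb
  out <- pmin(va, vb)
  if (!is.null(dim(va))) dim(out) <- dim(va)
  new_ag_node(out, list(a, b), function(g) {
    ga <- g * awins; gb <- g * !awins
    list(if (length(va) == 1L && length(ga) > 1L) sum(ga) else ga,
         if (length(vb) == 1L && length(gb) > 1L) sum(gb) else gb)
  })
}

# ---- reductions and indexing ----------------------------------------------

#' @rdname ag_ops
#' @export
ag_sum <- function(x) {
  x <- as_node(x)
  v <- x$value
  new_ag_node(sum(v), list(x), function(g) {
    out <- rep(g, length(v))
    if (!is.null(dim(v))) dim(out) <- dim(v)
    list(out)
  })
}

#' @rdname ag_ops
#' @export
ag_mean <- function(x) {
  x <- as_node(x)
  v <- x$value
  n <- length(v)
  new_ag_node(mean(v), list(x), function(g) {
    out <- rep(g / n, n)
    if (!is.null(dim(v))) dim(out) <- dim(v)
    list(out)
  })
}

# Select elements by flat index; gradient scatters back.
#' @rdname ag_ops
#' @param idx integer vector of flat indices
#' @export
ag_index <- function(x, idx) {
  x <- as_node(x)
  v <- x$value
  new_ag_node(as.numeric(v[idx]), list(x), function(g) {
    out <- numeric(length(v))
    if (anyDuplicated(idx)) {
      for (k in seq_along(idx)) out[idx[k]] <- out[idx[k]] + g[k]
    } else {
      out[idx] <- g
    }
    if (!is.null(dim(v))) dim(out) <- dim(v)
    list(out)
  })
}

# ---- linear algebra --------------------------------------------------------

#' @rdname ag_ops
#' @param A,B matrices (nodes or numeric)
#' @export
ag_matmul <- function(A, B) {
  A <- as_node(A); B <- as_node(B)
  va <- A$value; vb <- B$value
  new_ag_node(va %*% vb, list(A, B), function(g) {
    list(g %*% t(vb), t(va) %*% g)
  })
}

# W x + b for a source channel-descriptor vector x (length Cin) -> length Cout
#' @rdname ag_ops
#' @param W weight matrix node, `b` bias vector node
#' @export
ag_affine <- function(x, W, b) {
  x <- as_node(x); W <- as_node(W); b <- as_node(b)
  vx <- x$value; vW <- W$value
  new_ag_node(as.numeric(vW %*% vx) + b$value, list(x, W, b), function(g) {
    list(as.numeric(t(vW) %*% g), outer(g, vx), g)
  })
}

# ---- image ops (H x W x C arrays) ------------------------------------------

# cached flat-index plans for the im2col 3x3 convolution, keyed by H_W_C
conv_plan <- function(H, W, C) {
  key <- paste(H, W, C, sep = "_")
  plan <- .ag$conv_plans[[key]]
  if (!is.null(plan)) return(plan)
  PH <- H + 2L; PW <- W + 2L
  rows_out <- rep(seq_len(H), W)
  cols_out <- rep(seq_len(W), each = H)
  chan_off <- (seq_len(C) - 1L) * PH * PW
  # gather indices: (pixel) x (9 offsets x C channels), offset-major
  idx <- matrix(0L, H * W, 9L * C)
  k <- 0L
  for (di in 0:2) for (dj in 0:2) {
    k <- k + 1L
    base <- (rows_out + di) + (cols_out + dj - 1L) * PH
    for (c in seq_len(C)) idx[, (k - 1L) * C + c] <- base + chan_off[c]
  }
  inner <- as.integer(outer((rows_out + 1L) + cols_out * PH, chan_off, "+"))
  plan <- list(idx = idx, inner = inner, npad = PH * PW * C)
  if (is.null(.ag$conv_plans)) .ag$conv_plans <- list()
  .ag$conv_plans[[key]] <- plan
  plan
}

# 3x3 "same" convolution via im2col. W is a (9*Cin) x Cout matrix whose rows
# are ordered offset-major: (di,dj) scanning dj in -1:1 within di in -1:1,
# channels contiguous within each offset.
#' @rdname ag_ops
#' @param b bias vector (length Cout)
#' @export
ag_conv3x3 <- function(x, W, b) {
  x <- as_node(x); W <- as_node(W); b <- as_node(b)
  v <- x$value
  d <- dim(v); H <- d[1]; Wd <- d[2]; C <- d[3]
  vW <- W$value
  Cout <- ncol(vW)
  plan <- conv_plan(H, Wd, C)
  pv <- numeric(plan$npad)
  pv[plan$inner] <- v
  cols <- pv[plan$idx]
  dim(cols) <- c(H * Wd, 9L * C)
  ym <- cols %*% vW
  ym <- ym + rep(b$value, each = H * Wd)
  dim(ym) <- c(H, Wd, Cout)
  new_ag_node(ym, list(x, W, b), function(g) {
    gm <- g
    dim(gm) <- c(H * Wd, Cout)
    dW <- crossprod(cols, gm)
    db <- colSums(gm)
    dcols <- gm %*% t(vW)
    dpad <- numeric(plan$npad)
    for (k in 1:9) {
      sel <- ((k - 1L) * C + 1L):(k * C)
      tk <- plan$idx[, sel]
      dpad[tk] <- dpad[tk] + dcols[, sel]
    }
    dx <- dpad[plan$inner]
    dim(dx) <- d
    list(dx, dW, db)
  })
}

# 1x1 channel-mixing convolution: W is Cin x Cout.
#' @rdname ag_ops
#' @export
ag_conv1x1 <- function(x, W, b) {
  x <- as_node(x); W <- as_node(W); b <- as_node(b)
  v <- x$value
  d <- dim(v); H <- d[1]; Wd <- d[2]; C <- d[3]
  vW <- W$value
  Cout <- ncol(vW)
  xm <- matrix(v, H * Wd, C)
  ym <- sweep(xm %*% vW, 2L, b$value, "+")
  new_ag_node(array(ym, c(H, Wd, Cout)), list(x, W, b), function(g) {
    gm <- matrix(g, H * Wd, Cout)
    list(array(gm %*% t(vW), c(H, Wd, C)), crossprod(xm, gm), colSums(gm))
  })
}

# cached flat indices of the four 2x2-block corners, keyed by input shape
pool_plan <- function(H, W, C) {
  key <- paste("p", H, W, C, sep = "_")
  plan <- .ag$conv_plans[[key]]
  if (!is.null(plan)) return(plan)
  h <- H %/% 2L; w <- W %/% 2L
  ro <- rep(seq_len(h), w)          # output row
  co <- rep(seq_len(w), each = h)   # output col
  chan <- rep((seq_len(C) - 1L) * H * W, each = h * w)
  base <- function(di, dj) {
    rep((2L * ro - 1L + di) + (2L * co - 2L + dj) * H, C) + chan
  }
  plan <- list(i11 = base(0L, 0L), i21 = base(1L, 0L),
               i12 = base(0L, 1L), i22 = base(1L, 1L),
               out_dim = c(h, w, C))
  if (is.null(.ag$conv_plans)) .ag$conv_plans <- list()
  .ag$conv_plans[[key]] <- plan
  plan
}

#' @rdname ag_ops
#' @export
ag_avgpool2 <- function(x) {
  x <- as_node(x)
  v <- x$value
  d <- dim(v); H <- d[1]; W <- d[2]; C <- d[3]
  stopifnot(H %% 2L == 0L, W %% 2L == 0L)
  plan <- pool_plan(H, W, C)
  out <- (v[plan$i11] + v[plan$i21] + v[plan$i12] + v[plan$i22]) / 4
  dim(out) <- plan$out_dim
  new_ag_node(out, list(x), function(g) {
    dx <- numeric(length(v))
    q <- g / 4
    dx[plan$i11] <- q; dx[plan$i21] <- q
    dx[plan$i12] <- q; dx[plan$i22] <- q
    dim(dx) <- d
    list(dx)
  })
}

#' @rdname ag_ops
#' @export
ag_upsample2 <- function(x) {
  x <- as_node(x)
  v <- x$value
  d <- dim(v); H <- d[1]; W <- d[2]; C <- d[3]
  plan <- pool_plan(2L * H, 2L * W, C)  # corners of the OUTPUT grid
  out <- numeric(4L * H * W * C)
  vv <- as.numeric(v)
  out[plan$i11] <- vv; out[plan$i21] <- vv
  out[plan$i12] <- vv; out[plan$i22] <- vv
  dim(out) <- c(2L * H, 2L * W, C)
  new_ag_node(out, list(x), function(g) {
    dx <- g[plan$i11] + g[plan$i21] + g[plan$i12] + g[plan$i22]
    dim(dx) <- d
    list(dx)
  })
}

# global average pool: H x W x C -> length-C descriptor
#' @rdname ag_ops
#' @export
ag_gap <- function(x) {
  x <- as_node(x)
  v <- x$value
  d <- dim(v); n <- d[1] * d[2]
  out <- colMeans(matrix(v, n, d[3]))
  new_ag_node(out, list(x), function(g) {
    list(array(rep(g, each = n) / n, d))
  })
}

# multiply channel c of x by s[c]
#' @rdname ag_ops
#' @param s per-channel scale vector (length C)
#' @export
ag_chan_scale <- function(x, s) {
  x <- as_node(x); s <- as_node(s)
  v <- x$value; vs <- s$value
  d <- dim(v); n <- d[1] * d[2]
  sb <- array(rep(vs, each = n), d)
  new_ag_node(v * sb, list(x, s), function(g) {
    list(g * sb, colSums(matrix(g * v, n, d[3])))
  })
}

# append constant (non-trainable) channels, e.g. coordinate grids
#' @rdname ag_ops
#' @param const_chans H x W x Ck numeric array appended after x's channels
#' @export
ag_append_chan <- function(x, const_chans) {
  x <- as_node(x)
  v <- x$value
  d <- dim(v)
  dc <- dim(const_chans)
  stopifnot(all(dc[1:2] == d[1:2]))
  out <- array(c(v, const_chans), c(d[1], d[2], d[3] + dc[3]))
  new_ag_node(out, list(x), function(g) {
    list(g[, , seq_len(d[3]), drop = FALSE])
  })
}

# channel subset (keeps 3-d shape)
#' @rdname ag_ops
#' @param channels integer vector of channel indices to keep
#' @export
ag_slice_chan <- function(x, channels) {
  x <- as_node(x)
  v <- x$value
  d <- dim(v)
  new_ag_node(v[, , channels, drop = FALSE], list(x), function(g) {
    dx <- array(0, d)
    dx[, , channels] <- g
    list(dx)
  })
}

# ---- parameter-tree helpers ------------------------------------------------

# wrap a nested list of numeric arrays into leaves (same structure)
ag_wrap <- function(params) {
  if (is.null(params)) return(NULL)
  if (is.list(params)) lapply(params, ag_wrap) else ag_leaf(params)
}

# extract gradients from a wrapped tree (zeros where no gradient flowed)
ag_grads <- function(wrapped) {
  if (is.null(wrapped)) return(NULL)
  if (is.list(wrapped)) return(lapply(wrapped, ag_grads))
  g <- wrapped$grad
  if (is.null(g)) {
    g <- wrapped$value * 0
  } else if (!is.null(dim(wrapped$value))) {
    dim(g) <- dim(wrapped$value)
  }
  g
}

# theta <- theta - lr * grad, elementwise over a nested list
sgd_step <- function(params, grads, lr) {
  if (is.null(params)) return(NULL)
  if (is.list(params)) {
    return(mapply(sgd_step, params, grads, MoreArgs = list(lr = lr),
                  SIMPLIFY = FALSE))
  }
  params - lr * grads
}

# zero tree with the same structure as params
tree_zero <- function(params) {
  if (is.null(params)) return(NULL)
  if (is.list(params)) return(lapply(params, tree_zero))
  params * 0
}

# sum of squared entries over a tree
tree_sq_norm <- function(x) {
  if (is.null(x)) return(0)
  if (is.list(x)) return(sum(vapply(x, tree_sq_norm, numeric(1))))
  sum(x^2)
}

# scale every array in the tree
tree_scale <- function(x, s) {
  if (is.null(x)) return(NULL)
  if (is.list(x)) return(lapply(x, tree_scale, s = s))
  x * s
}

# heavy-ball momentum: v' = mu v + g ; p' = p - lr v'
momentum_step <- function(params, grads, vel, lr, mu) {
  if (is.null(params)) return(list(params = NULL, vel = NULL))
  if (is.list(params)) {
    out <- mapply(momentum_step, params, grads, vel,
                  MoreArgs = list(lr = lr, mu = mu), SIMPLIFY = FALSE)
    return(list(params = lapply(out, `[[`, "params"),
                vel = lapply(out, `[[`, "vel")))
  }
  v <- mu * vel + grads
  list(params = params - lr * v, vel = v)
}

# TRUE if every array in the tree is finite
params_finite <- function(params) {
  if (is.list(params)) return(all(vapply(params, params_finite, logical(1))))
  all(is.finite(params))
}
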