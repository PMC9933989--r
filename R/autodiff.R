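# Minimal reverse-mode automatic differentiation over dense arrays.
#
# A tape records nodes in forward order; each node holds its value, a list of
# parent nodes and a backward closure returning the gradient contribution for
# each parent. Parameters are leaf nodes tagged with their name so gradients
# can be collected after the backward sweep. This is deliberately small: only
# the operations the network family needs are implemented, each delegating the
# heavy lifting to the compiled kernels in src/.

new_tape <- function() {
  tape <- new.env(parent = emptyenv())
  tape$nodes <- vector("list", 256L)
  tape$n <- 0L
  tape
}

tp_node <- function(tape, value, parents = list(), backward = NULL,
                    param_name = NULL) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$parents <- parents
  node$backward <- backward
  node$param_name <- param_name
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- node
  tape$n <- n
  node
}

tp_const <- function(tape, value) tp_node(tape, value)

tp_param <- function(tape, params, name) {
  tp_node(tape, params[[name]], param_name = name)
}

acc_grad <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

# Backward sweep from a scalar loss node; returns named list of parameter
# gradients (arrays shaped like the parameters).
tp_backward <- function(tape, loss) {
  loss$grad <- 1
  grads <- list()
  for (i in seq.int(tape$n, 1L)) {
    node <- tape$nodes[[i]]
    if (is.null(node$grad)) next
    if (!is.null(node$param_name)) {
      nm <- node$param_name
      if (is.null(grads[[nm]])) grads[[nm]] <- node$grad
      else grads[[nm]] <- grads[[nm]] + node$grad
    }
    if (!is.null(node$backward)) {
      gs <- node$backward(node)
      for (j in seq_along(node$parents)) {
        if (!is.null(gs[[j]])) acc_grad(node$parents[[j]], gs[[j]])
      }
    }
  }
  grads
}

# ---- elementwise ops ------------------------------------------------------

op_relu <- function(tape, x) {
  v <- x$value
  v[v < 0] <- 0
  tp_node(tape, v, list(x), function(node) {
    g <- node$grad
    g[x$value <= 0] <- 0
    list(g)
  })
}

op_sigmoid <- function(tape, x) {
  v <- 1 / (1 + exp(-x$value))
  tp_node(tape, v, list(x), function(node) list(node$grad * v * (1 - v)))
}

op_tanh <- function(tape, x) {
  v <- tanh(x$value)
  tp_node(tape, v, list(x), function(node) list(node$grad * (1 - v * v)))
}

op_add <- function(tape, a, b) {
  tp_node(tape, a$value + b$value, list(a, b),
          function(node) list(node$grad, node$grad))
}

op_mul <- function(tape, a, b) {
  tp_node(tape, a$value * b$value, list(a, b),
          function(node) list(node$grad * b$value, node$grad * a$value))
}

# ---- convolutional ops (H x W x C arrays) ---------------------------------

# w node holds the R array (kh, kw, cin, cout); reshaped to K x cout for the
# kernel (column-major flattening keeps row order (ky, kx, cin)).
# `cache_cols` keeps the forward im2col matrix for the backward pass (used
# while training); inference forwards skip it to keep memory flat.
op_conv2d <- function(tape, x, w, b, kh = 3L, kw = 3L, cache_cols = FALSE) {
  dw <- dim(w$value)
  cin <- dw[3]
  wm <- matrix(w$value, nrow = prod(dw[1:3]), ncol = dw[4])
  if (cache_cols) {
    fw <- conv2d_fwd_train_cpp(x$value, wm, b$value, kh, kw)
    return(tp_node(tape, fw$y, list(x, w, b), function(node) {
      gs <- conv2d_bwd_cols_cpp(fw$cols, wm, node$grad, cin, kh, kw)
      list(gs$dx, array(gs$dw, dim = dw), as.numeric(gs$db))
    }))
  }
  v <- conv2d_fwd_cpp(x$value, wm, b$value, kh, kw)
  tp_node(tape, v, list(x, w, b), function(node) {
    gs <- conv2d_bwd_cpp(x$value, wm, node$grad, kh, kw)
    list(gs$dx, array(gs$dw, dim = dw), as.numeric(gs$db))
  })
}

# 1x1 convolution for channel-last arrays of any rank: a plain matrix product
# on the channel dimension. w: cin x cout matrix, b: length cout.
op_conv1x1 <- function(tape, x, w, b) {
  d <- dim(x$value)
  cin <- d[length(d)]
  n <- prod(d) / cin
  xm <- matrix(x$value, nrow = n, ncol = cin)
  ym <- xm %*% w$value
  ym <- sweep(ym, 2L, b$value, "+")
  cout <- ncol(w$value)
  v <- array(ym, dim = c(d[-length(d)], cout))
  tp_node(tape, v, list(x, w, b), function(node) {
    gm <- matrix(node$grad, nrow = n, ncol = cout)
    list(array(gm %*% t(w$value), dim = d), t(xm) %*% gm, colSums(gm))
  })
}

op_maxpool2 <- function(tape, x) {
  fw <- maxpool2_fwd_cpp(x$value)
  H <- dim(x$value)[1]; W <- dim(x$value)[2]
  tp_node(tape, fw$y, list(x), function(node) {
    list(maxpool2_bwd_cpp(node$grad, fw$idx, H, W))
  })
}

op_tconv2 <- function(tape, x, w, b) {
  dw <- dim(w$value)                 # (2, 2, cin, cout)
  wm <- matrix(w$value, nrow = prod(dw[1:3]), ncol = dw[4])
  v <- tconv2_fwd_cpp(x$value, wm, b$value)
  tp_node(tape, v, list(x, w, b), function(node) {
    gs <- tconv2_bwd_cpp(x$value, wm, node$grad)
    list(gs$dx, array(gs$dw, dim = dw), as.numeric(gs$db))
  })
}

op_concat_c <- function(tape, a, b) {
  da <- dim(a$value); db_ <- dim(b$value)
  nd <- length(da)
  v <- array(c(a$value, b$value), dim = c(da[-nd], da[nd] + db_[nd]))
  tp_node(tape, v, list(a, b), function(node) {
    g <- node$grad
    ia <- seq_len(prod(da))
    list(array(g[ia], dim = da), array(g[-ia], dim = db_))
  })
}

# Channel slice [from..to] on the last dimension.
op_slice_c <- function(tape, x, from, to) {
  d <- dim(x$value)
  nd <- length(d)
  n <- prod(d[-nd])
  idx <- as.vector(outer(seq_len(n), (seq.int(from, to) - 1L) * n, "+"))
  v <- array(x$value[idx], dim = c(d[-nd], to - from + 1L))
  tp_node(tape, v, list(x), function(node) {
    g <- array(0, dim = d)
    g[idx] <- node$grad
    list(g)
  })
}

# Instance normalization: per-channel statistics over all non-channel dims.
op_instnorm <- function(tape, x, gamma, beta, eps = 1e-5) {
  d <- dim(x$value)
  nd <- length(d)
  C <- d[nd]
  n <- prod(d) / C
  xm <- matrix(x$value, nrow = n, ncol = C)
  mu <- colMeans(xm)
  xc <- sweep(xm, 2L, mu)
  vr <- colMeans(xc * xc)
  istd <- 1 / sqrt(vr + eps)
  xhat <- sweep(xc, 2L, istd, "*")
  ym <- sweep(sweep(xhat, 2L, gamma$value, "*"), 2L, beta$value, "+")
  tp_node(tape, array(ym, dim = d), list(x, gamma, beta), function(node) {
    gm <- matrix(node$grad, nrow = n, ncol = C)
    dgamma <- colSums(gm * xhat)
    dbeta <- colSums(gm)
    gh <- sweep(gm, 2L, gamma$value, "*")
    dx <- sweep(gh, 2L, colMeans(gh)) -
      sweep(xhat, 2L, colMeans(gh * xhat), "*")
    dx <- sweep(dx, 2L, istd, "*")
    list(array(dx, dim = d), dgamma, dbeta)
  })
}

# ---- dense head (latent-space point regression) ---------------------------

op_gap <- function(tape, x) {
  d <- dim(x$value)
  nd <- length(d)
  C <- d[nd]
  n <- prod(d) / C
  v <- colMeans(matrix(x$value, nrow = n, ncol = C))
  tp_node(tape, v, list(x), function(node) {
    list(array(rep(node$grad / n, each = n), dim = d))
  })
}

op_dense <- function(tape, x, w, b) {
  v <- as.numeric(x$value %*% w$value + b$value)
  tp_node(tape, v, list(x, w, b), function(node) {
    g <- node$grad
    list(as.numeric(w$value %*% g), outer(x$value, g), g)
  })
}

# ---- temporal plumbing ----------------------------------------------------

# Slice frame t (1-based) from an (H, W, T, C) node -> (H, W, C).
op_slice_frame <- function(tape, x, t) {
  d <- dim(x$value)
  v <- array(x$value[, , t, , drop = FALSE], dim = d[c(1, 2, 4)])
  tp_node(tape, v, list(x), function(node) {
    g <- array(0, dim = d)
    g[, , t, ] <- node$grad
    list(g)
  })
}

# Stack a list of (H, W, C) nodes into (H, W, T, C).
op_stack_frames <- function(tape, xs) {
  d <- dim(xs[[1]]$value)
  T_ <- length(xs)
  v <- array(0, dim = c(d[1], d[2], T_, d[3]))
  for (t in seq_len(T_)) v[, , t, ] <- xs[[t]]$value
  tp_node(tape, v, xs, function(node) {
    lapply(seq_len(T_), function(t) {
      array(node$grad[, , t, , drop = FALSE], dim = d)
    })
  })
}

op_conv3d <- function(tape, x, w, b) {
  dw <- dim(w$value)                 # (3, 3, 3, cin, cout)
  wm <- matrix(w$value, nrow = prod(dw[1:4]), ncol = dw[5])
  d <- dim(x$value)
  v <- conv3d_fwd_cpp(x$value, wm, b$value, d[1], d[2], d[3], d[4])
  tp_node(tape, v, list(x, w, b), function(node) {
    gs <- conv3d_bwd_cpp(x$value, wm, node$grad, d[1], d[2], d[3], d[4], dw[5])
    list(gs$dx, array(gs$dw, dim = dw), as.numeric(gs$db))
  })
}

# Spatial 2x2 max-pool of an (H, W, T, C) node, frames pooled independently;
# implemented by folding (T, C) into the slice dimension of the 2D kernel.
op_maxpool2_s <- function(tape, x) {
  d <- dim(x$value)
  x3 <- array(x$value, dim = c(d[1], d[2], d[3] * d[4]))
  fw <- maxpool2_fwd_cpp(x3)
  v <- array(fw$y, dim = c(d[1] / 2, d[2] / 2, d[3], d[4]))
  tp_node(tape, v, list(x), function(node) {
    g3 <- array(node$grad, dim = c(d[1] / 2, d[2] / 2, d[3] * d[4]))
    list(array(maxpool2_bwd_cpp(g3, fw$idx, d[1], d[2]), dim = d))
  })
}

# Spatial transposed convolution applied per frame with shared weights.
op_tconv2_s <- function(tape, x, w, b) {
  dw <- dim(w$value)
  wm <- matrix(w$value, nrow = prod(dw[1:3]), ncol = dw[4])
  d <- dim(x$value)
  T_ <- d[3]
  v <- array(0, dim = c(2 * d[1], 2 * d[2], T_, dw[4]))
  for (t in seq_len(T_)) {
    v[, , t, ] <- tconv2_fwd_cpp(array(x$value[, , t, , drop = FALSE],
                                       dim = d[c(1, 2, 4)]), wm, b$value)
  }
  tp_node(tape, v, list(x, w, b), function(node) {
    dx <- array(0, dim = d)
    dwa <- 0; dba <- 0
    for (t in seq_len(T_)) {
      gs <- tconv2_bwd_cpp(array(x$value[, , t, , drop = FALSE],
                                 dim = d[c(1, 2, 4)]), wm,
                           array(node$grad[, , t, , drop = FALSE],
                                 dim = c(2 * d[1], 2 * d[2], dw[4])))
      dx[, , t, ] <- gs$dx
      dwa <- dwa + gs$dw
      dba <- dba + as.numeric(gs$db)
    }
    list(dx, array(dwa, dim = dw), dba)
  })
}

# ---- losses ---------------------------------------------------------------

# Soft Dice loss 1 - (2*sum(p*t) + eps) / (sum(p) + sum(t) + eps); the target
# is a constant array.
op_dice_loss <- function(tape, pred, target, eps = 1) {
  p <- pred$value
  num <- 2 * sum(p * target) + eps
  den <- sum(p) + sum(target) + eps
  v <- 1 - num / den
  tp_node(tape, v, list(pred), function(node) {
    list(node$grad * (-(2 * target * den - num) / den^2))
  })
}

op_mse_loss <- function(tape, pred, target) {
  n <- length(target)
  diff <- pred$value - target
  tp_node(tape, sum(diff * diff) / n, list(pred), function(node) {
    list(node$grad * 2 * diff / n)
  })
}

# Weighted sum of scalar loss nodes.
op_wsum <- function(tape, nodes, weights) {
  v <- 0
  for (i in seq_along(nodes)) v <- v + weights[i] * nodes[[i]]$value
  tp_node(tape, v, nodes, function(node) {
    lapply(seq_along(nodes), function(i) node$grad * weights[i])
  })
}
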