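# Minimal reverse-mode automatic differentiation over rank-4 feature
# tensors stored channel-first as (C, H, W, N) arrays. Each tape node is an
# environment holding its value, its parent nodes and a backward closure
# that scatters the node's accumulated gradient into its parents. The tape
# is rebuilt on every forward pass; parameters are persistent nodes whose
# gradients are reset between optimizer steps.
#
# The op set is exactly what the detector needs: convolution (via compiled
# im2col + BLAS gemm), batch normalization, SiLU/ReLU/sigmoid, elementwise
# add, channel- and pixel-broadcast multiply (for the attention weights),
# channel concatenation, max/average pooling, global and cross-channel
# pooling, and nearest-neighbor 2x upsampling.

.ad_counter <- new.env(parent = emptyenv())
.ad_counter$i <- 0L

ad_node <- function(value, parents = list(), backfn = NULL) {
  e <- new.env(parent = emptyenv())
  .ad_counter$i <- .ad_counter$i + 1L
  e$id <- .ad_counter$i
  e$value <- value
  e$parents <- parents
  e$backfn <- backfn
  e$grad <- NULL
  class(e) <- "ad_node"
  e
}

#' Create a trainable parameter node
#' @param value numeric array/matrix/vector of initial values.
#' @return an `ad_node` flagged as a parameter.
#' @export
ad_param <- function(value) {
  e <- ad_node(value)
  e$is_param <- TRUE
  e
}

ad_const <- function(value) ad_node(value)

ad_accum <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

# Topological sort (iterative DFS), then reverse sweep.
ad_backward <- function(root, seed_grad) {
  root$grad <- seed_grad
  order <- vector("list", 4096L)
  no <- 0L
  visited <- new.env(parent = emptyenv())
  stack <- list(list(node = root, expanded = FALSE))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (top$expanded) {
      no <- no + 1L
      if (no > length(order)) order <- c(order, vector("list", length(order)))
      order[[no]] <- top$node
    } else {
      key <- as.character(top$node$id)
      if (!is.null(visited[[key]])) next
      visited[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = top$node, expanded = TRUE)
      for (p in top$node$parents)
        stack[[length(stack) + 1L]] <- list(node = p, expanded = FALSE)
    }
  }
  for (i in rev(seq_len(no))) {
    nd <- order[[i]]
    if (!is.null(nd$backfn) && !is.null(nd$grad)) nd$backfn(nd)
  }
  invisible(NULL)
}

# Promote a (C,H,W) array to (C,H,W,1).
as_chwn <- function(x) {
  d <- dim(x)
  if (length(d) == 3) dim(x) <- c(d, 1L)
  x
}

## ---- convolution -----------------------------------------------------

# x: node (Cin,H,W,N); Wp: param (Cout, Cin*k*k); bp: param vector or NULL.
op_conv <- function(x, Wp, bp = NULL, k = 1L, stride = 1L, pad = 0L) {
  d <- dim(x$value)
  C <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
  Cout <- nrow(Wp$value)
  Ho <- (H + 2 * pad - k) %/% stride + 1L
  Wo <- (W + 2 * pad - k) %/% stride + 1L
  yv <- array(0, c(Cout, Ho, Wo, N))
  fast1x1 <- (k == 1L && stride == 1L && pad == 0L)
  if (fast1x1) {
    ym <- Wp$value %*% matrix(x$value, nrow = C)
    if (!is.null(bp)) ym <- ym + bp$value
    yv <- array(ym, c(Cout, Ho, Wo, N))
  } else {
    cols <- im2col_batch_cpp(x$value, C, H, W, N, k, stride, pad)
    ym <- Wp$value %*% cols
    if (!is.null(bp)) ym <- ym + bp$value
    yv <- array(ym, c(Cout, Ho, Wo, N))
  }
  parents <- c(list(x, Wp), if (!is.null(bp)) list(bp))
  ad_node(yv, parents, function(node) {
    dym <- matrix(node$grad, nrow = Cout)
    if (fast1x1) {
      dW <- tcrossprod(dym, matrix(x$value, nrow = C))
      dx <- array(crossprod(Wp$value, dym), dim(x$value))
    } else {
      dW <- tcrossprod(dym, cols)
      dcols <- crossprod(Wp$value, dym)
      dx <- array(col2im_batch_cpp(dcols, C, H, W, N, k, stride, pad),
                  dim(x$value))
    }
    ad_accum(x, dx)
    ad_accum(Wp, dW)
    if (!is.null(bp)) ad_accum(bp, rowSums(dym))
  })
}

## ---- batch normalization ---------------------------------------------

# state: environment with running mean/var vectors (length C).
op_bn <- function(x, gamma, beta, state, training = TRUE,
                  momentum = 0.1, eps = 1e-5) {
  d <- dim(x$value)
  C <- d[1]
  xm <- matrix(x$value, nrow = C)
  if (training) {
    m <- rowMeans(xm)
    v <- rowMeans(xm * xm) - m * m
    v <- pmax(v, 0)
    state$mean <- (1 - momentum) * state$mean + momentum * m
    state$var <- (1 - momentum) * state$var + momentum * v
  } else {
    m <- state$mean
    v <- state$var
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- (xm - m) * invstd
  ym <- gamma$value * xhat + beta$value
  yv <- array(ym, d)
  ad_node(yv, list(x, gamma, beta), function(node) {
    dym <- matrix(node$grad, nrow = C)
    dgamma <- rowSums(dym * xhat)
    dbeta <- rowSums(dym)
    dxhat <- dym * gamma$value
    if (training) {
      M <- ncol(xm)
      dxm <- (invstd / M) *
        (M * dxhat - rowSums(dxhat) - xhat * rowSums(dxhat * xhat))
    } else {
      dxm <- dxhat * invstd
    }
    ad_accum(x, array(dxm, d))
    ad_accum(gamma, dgamma)
    ad_accum(beta, dbeta)
  })
}

## ---- activations ------------------------------------------------------

op_relu <- function(x) {
  yv <- pmax(x$value, 0)
  ad_node(yv, list(x), function(node) {
    ad_accum(x, node$grad * (x$value > 0))
  })
}

op_silu <- function(x) {
  s <- 1 / (1 + exp(-x$value))
  yv <- x$value * s
  ad_node(yv, list(x), function(node) {
    ad_accum(x, node$grad * (s * (1 + x$value * (1 - s))))
  })
}

op_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$value))
  ad_node(s, list(x), function(node) {
    ad_accum(x, node$grad * s * (1 - s))
  })
}

## ---- arithmetic and broadcasting --------------------------------------

op_add <- function(a, b) {
  ad_node(a$value + b$value, list(a, b), function(node) {
    ad_accum(a, node$grad)
    ad_accum(b, node$grad)
  })
}

# x: (C,H,W,N); w: (C,1,1,N) per-channel attention weights.
op_cmul <- function(x, w) {
  d <- dim(x$value)
  C <- d[1]; HW <- d[2] * d[3]; N <- d[4]
  yv <- array(0, d)
  for (n in seq_len(N))
    yv[, , , n] <- matrix(x$value[, , , n], C) * w$value[, 1, 1, n]
  ad_node(yv, list(x, w), function(node) {
    dx <- array(0, d)
    dw <- array(0, dim(w$value))
    for (n in seq_len(N)) {
      dyn <- matrix(node$grad[, , , n], C)
      dx[, , , n] <- dyn * w$value[, 1, 1, n]
      dw[, 1, 1, n] <- rowSums(dyn * matrix(x$value[, , , n], C))
    }
    ad_accum(x, dx)
    ad_accum(w, dw)
  })
}

# x: (C,H,W,N); w: (1,H,W,N) per-pixel attention weights.
op_smul <- function(x, w) {
  d <- dim(x$value)
  C <- d[1]; HW <- d[2] * d[3]; N <- d[4]
  yv <- array(0, d)
  for (n in seq_len(N)) {
    ws <- as.vector(w$value[1, , , n])
    yv[, , , n] <- matrix(x$value[, , , n], C) * rep(ws, each = C)
  }
  ad_node(yv, list(x, w), function(node) {
    dx <- array(0, d)
    dw <- array(0, dim(w$value))
    for (n in seq_len(N)) {
      ws <- as.vector(w$value[1, , , n])
      dyn <- matrix(node$grad[, , , n], C)
      dx[, , , n] <- dyn * rep(ws, each = C)
      dw[1, , , n] <- colSums(dyn * matrix(x$value[, , , n], C))
    }
    ad_accum(x, dx)
    ad_accum(w, dw)
  })
}

op_concat_c <- function(nodes) {
  ds <- lapply(nodes, function(n) dim(n$value))
  Cs <- vapply(ds, `[`, integer(1), 1)
  d1 <- ds[[1]]
  yv <- array(0, c(sum(Cs), d1[2], d1[3], d1[4]))
  off <- 0L
  for (i in seq_along(nodes)) {
    yv[off + seq_len(Cs[i]), , , ] <- nodes[[i]]$value
    off <- off + Cs[i]
  }
  ad_node(yv, nodes, function(node) {
    off <- 0L
    for (i in seq_along(nodes)) {
      ad_accum(nodes[[i]], node$grad[off + seq_len(Cs[i]), , , , drop = FALSE])
      off <- off + Cs[i]
    }
  })
}

## ---- pooling -----------------------------------------------------------

op_maxpool <- function(x, k, stride = 1L, pad = 0L) {
  d <- dim(x$value)
  C <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
  Ho <- (H + 2 * pad - k) %/% stride + 1L
  Wo <- (W + 2 * pad - k) %/% stride + 1L
  r <- maxpool_fwd_batch_cpp(x$value, C, H, W, N, k, stride, pad)
  yv <- array(r$y, c(C, Ho, Wo, N))
  ad_node(yv, list(x), function(node) {
    dx <- array(scatter_add_cpp(r$idx, as.vector(node$grad),
                                C * H * W * N), d)
    ad_accum(x, dx)
  })
}

# Non-overlapping s x s average pooling (stride matching for the attention
# paths inside a strided Conv-AT block).
op_avgpool_s <- function(x, s) {
  if (s == 1L) return(x)
  d <- dim(x$value)
  C <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
  Ho <- H %/% s; Wo <- W %/% s
  yv <- array(0, c(C, Ho, Wo, N))
  for (i in seq_len(s)) for (j in seq_len(s))
    yv <- yv + x$value[, seq(i, by = s, length.out = Ho),
                       seq(j, by = s, length.out = Wo), , drop = FALSE]
  yv <- yv / (s * s)
  ad_node(yv, list(x), function(node) {
    dx <- array(0, d)
    g <- node$grad / (s * s)
    for (i in seq_len(s)) for (j in seq_len(s))
      dx[, seq(i, by = s, length.out = Ho),
         seq(j, by = s, length.out = Wo), ] <- g
    ad_accum(x, dx)
  })
}

op_gap <- function(x) {
  d <- dim(x$value)
  C <- d[1]; HW <- d[2] * d[3]; N <- d[4]
  yv <- array(0, c(C, 1, 1, N))
  for (n in seq_len(N)) yv[, 1, 1, n] <- rowMeans(matrix(x$value[, , , n], C))
  ad_node(yv, list(x), function(node) {
    dx <- array(0, d)
    for (n in seq_len(N))
      dx[, , , n] <- matrix(node$grad[, 1, 1, n] / HW, C, HW)
    ad_accum(x, dx)
  })
}

op_gmp <- function(x) {
  d <- dim(x$value)
  C <- d[1]; HW <- d[2] * d[3]; N <- d[4]
  yv <- array(0, c(C, 1, 1, N))
  js <- matrix(0L, C, N)
  for (n in seq_len(N)) {
    m <- matrix(x$value[, , , n], C)
    j <- max.col(m, ties.method = "first")
    js[, n] <- j
    yv[, 1, 1, n] <- m[cbind(seq_len(C), j)]
  }
  ad_node(yv, list(x), function(node) {
    dx <- array(0, d)
    for (n in seq_len(N)) {
      m <- matrix(0, C, HW)
      m[cbind(seq_len(C), js[, n])] <- node$grad[, 1, 1, n]
      dx[, , , n] <- m
    }
    ad_accum(x, dx)
  })
}

# Mean / max across channels -> (1,H,W,N) maps (spatial attention inputs).
op_cmean <- function(x) {
  d <- dim(x$value)
  C <- d[1]; HW <- d[2] * d[3]; N <- d[4]
  yv <- array(0, c(1, d[2], d[3], N))
  for (n in seq_len(N)) yv[1, , , n] <- colMeans(matrix(x$value[, , , n], C))
  ad_node(yv, list(x), function(node) {
    dx <- array(0, d)
    for (n in seq_len(N))
      dx[, , , n] <- rep(as.vector(node$grad[1, , , n]) / C, each = C)
    ad_accum(x, dx)
  })
}

op_cmax <- function(x) {
  d <- dim(x$value)
  C <- d[1]; HW <- d[2] * d[3]; N <- d[4]
  yv <- array(0, c(1, d[2], d[3], N))
  js <- matrix(0L, HW, N)
  for (n in seq_len(N)) {
    m <- matrix(x$value[, , , n], C)
    j <- max.col(t(m), ties.method = "first")
    js[, n] <- j
    yv[1, , , n] <- m[cbind(j, seq_len(HW))]
  }
  ad_node(yv, list(x), function(node) {
    dx <- array(0, d)
    for (n in seq_len(N)) {
      m <- matrix(0, C, HW)
      m[cbind(js[, n], seq_len(HW))] <- as.vector(node$grad[1, , , n])
      dx[, , , n] <- m
    }
    ad_accum(x, dx)
  })
}

op_upsample2 <- function(x) {
  d <- dim(x$value)
  H <- d[2]; W <- d[3]
  yv <- x$value[, rep(seq_len(H), each = 2), rep(seq_len(W), each = 2), ,
                drop = FALSE]
  ad_node(yv, list(x), function(node) {
    g <- node$grad
    dx <- array(0, d)
    for (i in 1:2) for (j in 1:2)
      dx <- dx + g[, seq(i, by = 2, length.out = H),
                   seq(j, by = 2, length.out = W), , drop = FALSE]
    ad_accum(x, dx)
  })
}
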