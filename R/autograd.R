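#' @title Reverse-mode differentiation engine
#' @name autograd
#' @description
#' A small define-by-run tape for the tensors this package needs: C x H x W
#' feature volumes, H x W images, channel-descriptor vectors and scalar
#' losses. Each operation records a closure that propagates the adjoint to
#' its parents; [ag_backward()] walks the tape in reverse. Convolutions are
#' lowered to im2col + BLAS matrix products, which is what makes CPU training
#' of the fusion GAN practical in base R.
#'
#' Layer parameters live in environments (see `conv_layer()`), outside the
#' tape; their gradients accumulate across a mini-batch and are consumed by
#' the Adam optimizer.
#' @keywords internal
NULL

.ag <- new.env(parent = emptyenv())
.ag$tape <- NULL
.ag$k <- 0L
.ag$on <- FALSE

ag_tape_reset <- function(record = TRUE) {
  .ag$tape <- if (record) vector("list", 256L) else NULL
  .ag$k <- 0L
  .ag$on <- record
  invisible(NULL)
}

ag_node <- function(value, parents = list(), backward = NULL) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n$parents <- parents
  n$backward <- backward
  if (.ag$on && !is.null(backward)) {
    k <- .ag$k + 1L
    if (k > length(.ag$tape)) .ag$tape <- c(.ag$tape, vector("list", k))
    .ag$tape[[k]] <- n
    .ag$k <- k
  }
  n
}

ag_const <- function(value) ag_node(value)

acc_grad <- function(n, g) {
  n$grad <- if (is.null(n$grad)) g else n$grad + g
  invisible(NULL)
}

# Run reverse sweep from a scalar node; `seed` scales the loss adjoint
# (1/batch_size averages gradients over a batch of per-sample graphs).
ag_backward <- function(loss, seed = 1) {
  if (!.ag$on) stop("ag_backward: tape is not recording", call. = FALSE)
  acc_grad(loss, seed)
  for (k in rev(seq_len(.ag$k))) {
    n <- .ag$tape[[k]]
    if (!is.null(n$grad) && !is.null(n$backward)) n$backward(n$grad)
  }
  invisible(NULL)
}

## ---- convolution lowering -------------------------------------------------

# x: array (C, H, W). Returns (C*k*k) x (Ho*Wo) patch matrix plus geometry.
im2col <- function(x, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]
  if (pad > 0L) {
    xp <- array(0, c(C, H + 2L * pad, W + 2L * pad))
    xp[, pad + seq_len(H), pad + seq_len(W)] <- x
  } else xp <- x
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  cols <- matrix(0, C * k * k, Ho * Wo)
  r <- 0L
  for (b in seq_len(k)) for (a in seq_len(k)) {
    rows <- a + stride * (seq_len(Ho) - 1L)
    cls <- b + stride * (seq_len(Wo) - 1L)
    cols[r + seq_len(C), ] <- matrix(xp[, rows, cls, drop = FALSE], C)
    r <- r + C
  }
  list(cols = cols, Ho = Ho, Wo = Wo)
}

col2im <- function(dcols, C, H, W, k, stride, pad, Ho, Wo) {
  dxp <- array(0, c(C, H + 2L * pad, W + 2L * pad))
  r <- 0L
  for (b in seq_len(k)) for (a in seq_len(k)) {
    rows <- a + stride * (seq_len(Ho) - 1L)
    cls <- b + stride * (seq_len(Wo) - 1L)
    dxp[, rows, cls] <- dxp[, rows, cls, drop = FALSE] +
      array(dcols[r + seq_len(C), , drop = FALSE], c(C, Ho, Wo))
    r <- r + C
  }
  if (pad > 0L) {
    dxp[, pad + seq_len(H), pad + seq_len(W), drop = FALSE]
  } else dxp
}

## ---- layers ----------------------------------------------------------------

# Kaiming fan-in initialization; weights stored flattened (c_out x c_in*k*k).
conv_layer <- function(c_in, c_out, k = 3L, stride = 1L,
                       pad = (k - 1L) %/% 2L) {
  l <- new.env(parent = emptyenv())
  fan_in <- c_in * k * k
  l$W <- matrix(stats::rnorm(c_out * fan_in, sd = sqrt(2 / fan_in)),
                c_out, fan_in)
  l$b <- numeric(c_out)
  l$k <- as.integer(k); l$stride <- as.integer(stride)
  l$pad <- as.integer(pad)
  l$c_in <- as.integer(c_in); l$c_out <- as.integer(c_out)
  l$wscale <- 1
  l$gW <- NULL; l$gb <- NULL
  class(l) <- "fg_layer"
  l
}

fc_layer <- function(n_in, n_out) {
  l <- new.env(parent = emptyenv())
  l$W <- matrix(stats::rnorm(n_out * n_in, sd = sqrt(2 / n_in)), n_out, n_in)
  l$b <- numeric(n_out)
  l$wscale <- 1
  l$gW <- NULL; l$gb <- NULL
  class(l) <- "fg_layer"
  l
}

layer_acc <- function(l, gW, gb) {
  l$gW <- if (is.null(l$gW)) gW else l$gW + gW
  l$gb <- if (is.null(l$gb)) gb else l$gb + gb
  invisible(NULL)
}

zero_grads <- function(layers) {
  for (l in layers) { l$gW <- NULL; l$gb <- NULL }
  invisible(NULL)
}

n_layer_params <- function(layers) {
  sum(vapply(layers, function(l) length(l$W) + length(l$b), numeric(1)))
}

## ---- ops -------------------------------------------------------------------

ag_conv <- function(xn, l) {
  Weff <- if (l$wscale == 1) l$W else l$W * l$wscale
  out <- cpp_conv_fwd(xn$value, Weff, l$b, l$k, l$stride, l$pad)
  if (!.ag$on) return(ag_node(out))
  ag_node(out, parents = list(xn), backward = function(g) {
    r <- cpp_conv_bwd(xn$value, Weff, g, l$k, l$stride, l$pad)
    layer_acc(l, r$dW * l$wscale, as.vector(r$db))
    acc_grad(xn, r$dx)
  })
}

# Pure-R reference of the conv lowering (same patch ordering as the C++
# kernels); retained as the independent oracle for the compiled path.
r_conv_fwd <- function(x, W, b, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  ic <- im2col(x, k, stride, pad)
  array(W %*% ic$cols + b, c(nrow(W), ic$Ho, ic$Wo))
}

ag_fc <- function(vn, l) {
  Weff <- if (l$wscale == 1) l$W else l$W * l$wscale
  v <- vn$value
  y <- drop(Weff %*% v) + l$b
  if (!.ag$on) return(ag_node(y))
  ag_node(y, parents = list(vn), backward = function(g) {
    layer_acc(l, outer(g, v) * l$wscale, g)
    acc_grad(vn, drop(crossprod(Weff, g)))
  })
}

ag_elu <- function(xn) {
  v <- cpp_elu_fwd(xn$value)
  if (!.ag$on) return(ag_node(v))
  ag_node(v, parents = list(xn), backward = function(g) {
    acc_grad(xn, cpp_elu_bwd(v, g))
  })
}

ag_sigmoid <- function(xn) {
  s <- 1 / (1 + exp(-xn$value))
  if (!.ag$on) return(ag_node(s))
  ag_node(s, parents = list(xn), backward = function(g) {
    acc_grad(xn, g * s * (1 - s))
  })
}

ag_add <- function(an, bn) {
  v <- an$value + bn$value
  if (!.ag$on) return(ag_node(v))
  ag_node(v, parents = list(an, bn), backward = function(g) {
    acc_grad(an, g); acc_grad(bn, g)
  })
}

ag_sub <- function(an, bn) {
  v <- an$value - bn$value
  if (!.ag$on) return(ag_node(v))
  ag_node(v, parents = list(an, bn), backward = function(g) {
    acc_grad(an, g); acc_grad(bn, -g)
  })
}

# Subgradient 0 at exact zeros.
ag_abs <- function(xn) {
  s <- sign(xn$value)
  if (!.ag$on) return(ag_node(abs(xn$value)))
  ag_node(abs(xn$value), parents = list(xn), backward = function(g) {
    acc_grad(xn, g * s)
  })
}

# x: (C,H,W) scaled per channel by vector g of length C.
ag_scale_channels <- function(xn, gn) {
  x <- xn$value
  v <- x * gn$value          # length-C vector recycles along dim 1
  if (!.ag$on) return(ag_node(v))
  C <- dim(x)[1]
  ag_node(v, parents = list(xn, gn), backward = function(g) {
    acc_grad(xn, g * gn$value)
    acc_grad(gn, rowSums(matrix(g * x, C)))
  })
}

# x: (C,H,W) scaled per pixel by H x W matrix s.
ag_scale_spatial <- function(xn, sn) {
  x <- xn$value
  d <- dim(x); C <- d[1]
  S <- array(rep(as.vector(sn$value), each = C), d)
  v <- x * S
  if (!.ag$on) return(ag_node(v))
  ag_node(v, parents = list(xn, sn), backward = function(g) {
    acc_grad(xn, g * S)
    acc_grad(sn, matrix(colSums(matrix(g * x, C)), d[2], d[3]))
  })
}

ag_concat <- function(an, bn) {
  a <- an$value; b <- bn$value
  da <- dim(a); db <- dim(b)
  v <- array(0, c(da[1] + db[1], da[2], da[3]))
  v[seq_len(da[1]), , ] <- a
  v[da[1] + seq_len(db[1]), , ] <- b
  if (!.ag$on) return(ag_node(v))
  ag_node(v, parents = list(an, bn), backward = function(g) {
    acc_grad(an, g[seq_len(da[1]), , , drop = FALSE])
    acc_grad(bn, g[da[1] + seq_len(db[1]), , , drop = FALSE])
  })
}

# Stack two H x W maps into a (2,H,W) volume (spatial-attention input).
ag_stack2 <- function(an, bn) {
  d <- dim(an$value)
  v <- array(0, c(2L, d[1], d[2]))
  v[1L, , ] <- an$value
  v[2L, , ] <- bn$value
  if (!.ag$on) return(ag_node(v))
  ag_node(v, parents = list(an, bn), backward = function(g) {
    acc_grad(an, matrix(g[1L, , ], d[1], d[2]))
    acc_grad(bn, matrix(g[2L, , ], d[1], d[2]))
  })
}

# Global average pool (C,H,W) -> length-C vector.
ag_gap <- function(xn) {
  d <- dim(xn$value)
  v <- rowMeans(matrix(xn$value, d[1]))
  if (!.ag$on) return(ag_node(v))
  ag_node(v, parents = list(xn), backward = function(g) {
    acc_grad(xn, array(g, d) / (d[2] * d[3]))
  })
}

# Global max pool (C,H,W) -> length-C vector; first max wins on ties.
ag_gmp <- function(xn) {
  d <- dim(xn$value)
  mx <- matrix(xn$value, d[1])
  j <- max.col(mx, ties.method = "first")
  v <- mx[cbind(seq_len(d[1]), j)]
  if (!.ag$on) return(ag_node(v))
  ag_node(v, parents = list(xn), backward = function(g) {
    dmx <- matrix(0, d[1], d[2] * d[3])
    dmx[cbind(seq_len(d[1]), j)] <- g
    acc_grad(xn, array(dmx, d))
  })
}

# Channelwise mean over C: (C,H,W) -> H x W.
ag_chan_mean <- function(xn) {
  d <- dim(xn$value)
  v <- matrix(colMeans(matrix(xn$value, d[1])), d[2], d[3])
  if (!.ag$on) return(ag_node(v))
  ag_node(v, parents = list(xn), backward = function(g) {
    acc_grad(xn, array(rep(as.vector(g), each = d[1]), d) / d[1])
  })
}

# Channelwise max over C: (C,H,W) -> H x W; first max wins on ties.
ag_chan_max <- function(xn) {
  d <- dim(xn$value)
  mx <- matrix(xn$value, d[1])
  idx <- max.col(t(mx), ties.method = "first")
  np <- d[2] * d[3]
  v <- matrix(mx[cbind(idx, seq_len(np))], d[2], d[3])
  if (!.ag$on) return(ag_node(v))
  ag_node(v, parents = list(xn), backward = function(g) {
    dmx <- matrix(0, d[1], np)
    dmx[cbind(idx, seq_len(np))] <- as.vector(g)
    acc_grad(xn, array(dmx, d))
  })
}

# (1,H,W) volume -> H x W matrix.
ag_drop_channel <- function(xn) {
  d <- dim(xn$value)
  v <- matrix(xn$value[1L, , ], d[2], d[3])
  if (!.ag$on) return(ag_node(v))
  ag_node(v, parents = list(xn), backward = function(g) {
    acc_grad(xn, array(g, d))
  })
}

# H x W matrix -> (1,H,W) volume.
ag_add_channel <- function(xn) {
  d <- dim(xn$value)
  v <- array(xn$value, c(1L, d[1], d[2]))
  if (!.ag$on) return(ag_node(v))
  ag_node(v, parents = list(xn), backward = function(g) {
    acc_grad(xn, matrix(g[1L, , ], d[1], d[2]))
  })
}

# Same-size Laplacian (edge-mirror padding) as a differentiable op on an
# H x W matrix node. The adjoint folds the mirrored border contributions
# back onto the edge pixels.
ag_laplacian <- function(xn, kern) {
  v <- conv2_same(xn$value, kern)
  if (!.ag$on) return(ag_node(v))
  H <- nrow(xn$value); W <- ncol(xn$value)
  ag_node(v, parents = list(xn), backward = function(g) {
    dxp <- matrix(0, H + 2L, W + 2L)
    for (a in 1:3) for (b in 1:3) {
      w <- kern[a, b]
      if (w != 0)
        dxp[(a - 1L) + seq_len(H), (b - 1L) + seq_len(W)] <-
          dxp[(a - 1L) + seq_len(H), (b - 1L) + seq_len(W)] + w * g
    }
    dx <- dxp[1L + seq_len(H), 1L + seq_len(W)]
    dx[1L, ] <- dx[1L, ] + dxp[1L, 1L + seq_len(W)]
    dx[H, ] <- dx[H, ] + dxp[H + 2L, 1L + seq_len(W)]
    dx[, 1L] <- dx[, 1L] + dxp[1L + seq_len(H), 1L]
    dx[, W] <- dx[, W] + dxp[1L + seq_len(H), W + 2L]
    dx[1L, 1L] <- dx[1L, 1L] + dxp[1L, 1L]
    dx[1L, W] <- dx[1L, W] + dxp[1L, W + 2L]
    dx[H, 1L] <- dx[H, 1L] + dxp[H + 2L, 1L]
    dx[H, W] <- dx[H, W] + dxp[H + 2L, W + 2L]
    acc_grad(xn, dx)
  })
}

# mean(w * (x - t)^2) over all elements; t, w fixed arrays.
ag_wmse <- function(xn, target, w) {
  r <- xn$value - target
  n <- length(r)
  v <- sum(w * r * r) / n
  if (!.ag$on) return(ag_node(v))
  ag_node(v, parents = list(xn), backward = function(g) {
    acc_grad(xn, (2 * g / n) * w * r)
  })
}

# (s - c)^2 for a scalar node.
ag_sq_err <- function(sn, c) {
  r <- as.numeric(sn$value) - c
  if (!.ag$on) return(ag_node(r * r))
  ag_node(r * r, parents = list(sn), backward = function(g) {
    acc_grad(sn, 2 * g * r)
  })
}

ag_axpy <- function(an, bn, wa = 1, wb = 1) {
  v <- wa * an$value + wb * bn$value
  if (!.ag$on) return(ag_node(v))
  ag_node(v, parents = list(an, bn), backward = function(g) {
    acc_grad(an, wa * g); acc_grad(bn, wb * g)
  })
}

## ---- Adam ------------------------------------------------------------------

adam_new <- function(layers, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  opt <- new.env(parent = emptyenv())
  opt$layers <- layers
  opt$lr <- lr; opt$beta1 <- beta1; opt$beta2 <- beta2; opt$eps <- eps
  opt$t <- 0L
  for (l in layers) {
    l$mW <- l$W * 0; l$vW <- l$W * 0
    l$mb <- l$b * 0; l$vb <- l$b * 0
  }
  opt
}

adam_step <- function(opt) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  c1 <- 1 - b1^opt$t; c2 <- 1 - b2^opt$t
  for (l in opt$layers) {
    if (is.null(l$gW)) next
    l$mW <- b1 * l$mW + (1 - b1) * l$gW
    l$vW <- b2 * l$vW + (1 - b2) * l$gW^2
    l$W <- l$W - opt$lr * (l$mW / c1) / (sqrt(l$vW / c2) + opt$eps)
    l$mb <- b1 * l$mb + (1 - b1) * l$gb
    l$vb <- b2 * l$vb + (1 - b2) * l$gb^2
    l$b <- l$b - opt$lr * (l$mb / c1) / (sqrt(l$vb / c2) + opt$eps)
  }
  invisible(NULL)
}
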