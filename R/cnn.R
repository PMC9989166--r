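# Minimal convolutional network engine: 3x3 same-padding convolutions via
# im2col + BLAS matmul, ReLU, 2x2 max/average pooling, global average
# pooling, a sigmoid unit, weighted binary cross-entropy, and Adam. Kept
# deliberately small: it exists to train the frame-level attack classifier,
# not to be a general framework.
#
# Internal data layout is H x W x B x C (batch before channels): the im2col
# row order (h, w, b) then falls straight out of R's column-major flattening,
# so no array permutations are needed anywhere in the training loop.

# --- im2col / col2im (3x3 kernel, zero padding 1) ---------------------------

# Column order is offset-major: the block for kernel offset k holds the C
# input channels, column index = (k - 1) * C + c. The weight matrix rows
# follow the same order.
im2col3 <- function(X) {
  d <- dim(X); H <- d[1]; W <- d[2]; B <- d[3]; C <- d[4]
  Xp <- array(0, c(H + 2L, W + 2L, B, C))
  Xp[2L:(H + 1L), 2L:(W + 1L), , ] <- X
  M <- matrix(0, H * W * B, 9L * C)
  k <- 0L
  for (dj in 0:2) for (di in 0:2) {
    M[, k * C + seq_len(C)] <- Xp[di + seq_len(H), dj + seq_len(W), , ]
    k <- k + 1L
  }
  M
}

col2im3 <- function(dM, H, W, B, C) {
  Gp <- array(0, c(H + 2L, W + 2L, B, C))
  k <- 0L
  for (dj in 0:2) for (di in 0:2) {
    Gp[di + seq_len(H), dj + seq_len(W), , ] <-
      Gp[di + seq_len(H), dj + seq_len(W), , , drop = FALSE] +
      array(dM[, k * C + seq_len(C)], c(H, W, B, C))
    k <- k + 1L
  }
  Gp[2L:(H + 1L), 2L:(W + 1L), , , drop = FALSE]
}

conv3_forward <- function(X, Wm, b) {
  d <- dim(X)
  M <- im2col3(X)
  Z <- M %*% Wm
  Z <- sweep(Z, 2L, b, `+`)
  list(out = array(Z, c(d[1], d[2], d[3], ncol(Wm))), M = M, in_dim = d)
}

conv3_backward <- function(cache, Wm, dY, need_dx = TRUE) {
  d <- cache$in_dim
  dZ <- matrix(dY, d[1] * d[2] * d[3], length(dY) / (d[1] * d[2] * d[3]))
  dW <- crossprod(cache$M, dZ)
  db <- colSums(dZ)
  dX <- if (need_dx) col2im3(tcrossprod(dZ, Wm), d[1], d[2], d[3], d[4])
        else NULL
  list(dX = dX, dW = dW, db = db)
}

# --- pooling (on the two leading spatial dimensions) ------------------------

pool2_slices <- function(X) {
  d <- dim(X)
  i1 <- seq(1L, d[1], 2L); i2 <- i1 + 1L
  j1 <- seq(1L, d[2], 2L); j2 <- j1 + 1L
  list(s11 = X[i1, j1, , , drop = FALSE], s21 = X[i2, j1, , , drop = FALSE],
       s12 = X[i1, j2, , , drop = FALSE], s22 = X[i2, j2, , , drop = FALSE])
}

maxpool2_forward <- function(X) {
  s <- pool2_slices(X)
  out <- pmax(s$s11, s$s21, s$s12, s$s22)
  list(out = out, slices = s, in_dim = dim(X))
}

# reuses the cached forward output instead of recomputing the max
maxpool2_backward <- function(cache, dY) {
  s <- cache$slices; M <- cache$out
  m11 <- s$s11 == M
  m21 <- (s$s21 == M) & !m11
  m12 <- (s$s12 == M) & !m11 & !m21
  m22 <- (s$s22 == M) & !m11 & !m21 & !m12
  d <- cache$in_dim
  dX <- array(0, d)
  i1 <- seq(1L, d[1], 2L); i2 <- i1 + 1L
  j1 <- seq(1L, d[2], 2L); j2 <- j1 + 1L
  dX[i1, j1, , ] <- dY * m11
  dX[i2, j1, , ] <- dY * m21
  dX[i1, j2, , ] <- dY * m12
  dX[i2, j2, , ] <- dY * m22
  dX
}

avgpool2_forward <- function(X) {
  s <- pool2_slices(X)
  list(out = (s$s11 + s$s21 + s$s12 + s$s22) / 4, in_dim = dim(X))
}

# Downsample a stack by repeated 2x2 average pooling (the network's fixed
# input reduction, applied once per video rather than once per batch).
pool_stack <- function(X, factor = 1L) {
  if (factor > 1L)
    for (k in seq_len(round(log2(factor)))) X <- avgpool2_forward(X)$out
  X
}

# --- network ----------------------------------------------------------------

cnn_init <- function(in_channels, filters = c(8L, 16L, 32L), seed = NULL) {
  with_seed(seed, {
    cin <- in_channels
    convs <- lapply(filters, function(f) {
      fan_in <- 9 * cin
      W <- matrix(stats::rnorm(fan_in * f, 0, sqrt(2 / fan_in)), fan_in, f)
      layer <- list(W = W, b = numeric(f))
      cin <<- f
      layer
    })
    list(filters = filters,
         convs = convs,
         dense = list(w = stats::rnorm(cin, 0, sqrt(1 / cin)), b = 0))
  })
}

# Forward pass: per conv block conv -> ReLU -> maxpool, then global average
# pooling and a sigmoid unit. X is H x W x B x C at input resolution.
cnn_forward <- function(net, X, keep_cache = FALSE) {
  caches <- list()
  for (i in seq_along(net$convs)) {
    cf <- conv3_forward(X, net$convs[[i]]$W, net$convs[[i]]$b)
    A <- cf$out
    relu_mask <- A > 0
    A <- A * relu_mask
    mp <- maxpool2_forward(A)
    X <- mp$out
    if (keep_cache)
      caches[[length(caches) + 1L]] <- list(c = cf, relu = relu_mask, mp = mp)
  }
  d <- dim(X)
  Fm <- matrix(colMeans(matrix(X, d[1] * d[2], d[3] * d[4])), d[3], d[4])
  z <- as.numeric(Fm %*% net$dense$w) + net$dense$b
  p <- stats::plogis(z)
  list(p = p, z = z, Fm = Fm, gap_dim = d, caches = caches)
}

# Backward pass from per-sample logit gradients; returns gradients shaped
# like the network parameters.
cnn_backward <- function(net, fwd, dz) {
  gF <- outer(dz, net$dense$w)                     # B x C
  gw <- as.numeric(crossprod(fwd$Fm, dz))
  gb <- sum(dz)
  d <- fwd$gap_dim
  dX <- array(rep(gF, each = d[1] * d[2]) / (d[1] * d[2]), d)
  grads <- vector("list", length(net$convs))
  for (ci in rev(seq_along(fwd$caches))) {
    cache <- fwd$caches[[ci]]
    dA <- maxpool2_backward(cache$mp, dX)
    dA <- dA * cache$relu
    bk <- conv3_backward(cache$c, net$convs[[ci]]$W, dA, need_dx = ci > 1L)
    grads[[ci]] <- list(dW = bk$dW, db = bk$db)
    dX <- bk$dX
  }
  list(convs = grads, dense = list(dw = gw, db = gb))
}

# Weighted binary cross-entropy on logits; returns loss and dL/dz.
bce_loss <- function(z, y, w) {
  p <- stats::plogis(z)
  eps <- 1e-12
  loss <- -sum(w * (y * log(p + eps) + (1 - y) * log(1 - p + eps))) / sum(w)
  dz <- w * (p - y) / sum(w)
  list(loss = loss, dz = dz)
}

flatten_params <- function(net) {
  c(unlist(lapply(net$convs, function(l) c(l$W, l$b))),
    net$dense$w, net$dense$b)
}

flatten_grads <- function(net, gr) {
  c(unlist(lapply(gr$convs, function(l) c(l$dW, l$db))),
    gr$dense$dw, gr$dense$db)
}

unflatten_params <- function(net, theta) {
  pos <- 1L
  for (i in seq_along(net$convs)) {
    nw <- length(net$convs[[i]]$W)
    net$convs[[i]]$W[] <- theta[pos:(pos + nw - 1L)]; pos <- pos + nw
    nb <- length(net$convs[[i]]$b)
    net$convs[[i]]$b <- theta[pos:(pos + nb - 1L)]; pos <- pos + nb
  }
  nw <- length(net$dense$w)
  net$dense$w <- theta[pos:(pos + nw - 1L)]; pos <- pos + nw
  net$dense$b <- theta[pos]
  net
}

# Adam on (X, y) minibatches. X: H x W x B x C at network input resolution,
# y: 0/1, pos_weight applied to positive samples in the loss.
cnn_train <- function(net, X, y, epochs = 15L,
                      batch_size = 32L, lr = 1e-3, pos_weight = 1,
                      seed = NULL) {
  theta <- flatten_params(net)
  m <- numeric(length(theta)); v <- numeric(length(theta))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; step <- 0L
  n <- length(y)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      idx <- sample.int(n)
      for (b0 in seq(1L, n, batch_size)) {
        ids <- idx[b0:min(b0 + batch_size - 1L, n)]
        Xb <- X[, , ids, , drop = FALSE]
        yb <- y[ids]
        wb <- ifelse(yb == 1, pos_weight, 1)
        fwd <- cnn_forward(net, Xb, keep_cache = TRUE)
        l <- bce_loss(fwd$z, yb, wb)
        gr <- cnn_backward(net, fwd, l$dz)
        g <- flatten_grads(net, gr)
        step <- step + 1L
        m <- beta1 * m + (1 - beta1) * g
        v <- beta2 * v + (1 - beta2) * g^2
        mh <- m / (1 - beta1^step)
        vh <- v / (1 - beta2^step)
        theta <- theta - lr * mh / (sqrt(vh) + eps)
        net <- unflatten_params(net, theta)
      }
    }
  })
  net
}

cnn_predict <- function(net, X, chunk = 256L) {
  B <- dim(X)[3]
  p <- numeric(B)
  for (b0 in seq(1L, B, chunk)) {
    ids <- b0:min(b0 + chunk - 1L, B)
    p[ids] <- cnn_forward(net, X[, , ids, , drop = FALSE])$p
  }
  p
}
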