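# Minimal convolutional network engine.
#
# Tensors are numeric arrays of dimension (H, W, C, B) (column-major, H
# fastest). Convolutions are evaluated as im2col patch-matrix products so the
# heavy lifting happens inside BLAS dgemm; the backward scatter (col2im) is a
# cached sparse-matrix product. Everything is deterministic: no dropout, no
# atomics, single code path.

.geom_cache <- new.env(parent = emptyenv())

# Geometry for a convolution over a padded plane.
# pad: c(top, bottom, left, right).
conv_geom <- function(H, W, C, k, stride, pad) {
  key <- paste(H, W, C, k, stride, paste(pad, collapse = "."), sep = "_")
  g <- .geom_cache[[key]]
  if (!is.null(g)) return(g)
  Hp <- H + pad[1] + pad[2]
  Wp <- W + pad[3] + pad[4]
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  assert_that((Hp - k) %% stride == 0 && (Wp - k) %% stride == 0,
              "convolution geometry does not tile the padded input")
  r0 <- (seq_len(Ho) - 1L) * stride          # 0-based top row of each patch
  c0 <- (seq_len(Wo) - 1L) * stride
  pos_r <- rep(r0, times = Wo)               # output positions, H fastest
  pos_c <- rep(c0, each = Ho)
  dr <- rep(0:(k - 1L), times = k)           # kernel offsets, row fastest
  dc <- rep(0:(k - 1L), each = k)
  # (HoWo x k^2) linear indices into one padded channel plane
  idx1 <- outer(pos_c, dc, "+") * Hp + outer(pos_r, dr, "+") + 1L
  storage.mode(idx1) <- "integer"
  plane <- Hp * Wp
  idxC <- matrix(0L, nrow(idx1), k * k * C)
  for (ci in seq_len(C)) {
    idxC[, ((ci - 1L) * k * k + 1L):(ci * k * k)] <- idx1 + (ci - 1L) * plane
  }
  scatter <- Matrix::sparseMatrix(
    i = as.vector(idxC), j = seq_along(idxC), x = 1,
    dims = c(plane * C, length(idxC)))
  g <- list(H = H, W = W, C = C, k = k, stride = stride, pad = pad,
            Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo, idxC = idxC, scatter = scatter)
  .geom_cache[[key]] <- g
  g
}

pad_tensor <- function(X, pad) {
  if (all(pad == 0)) return(X)
  d <- dim(X)
  Xp <- array(0, c(d[1] + pad[1] + pad[2], d[2] + pad[3] + pad[4], d[3], d[4]))
  Xp[pad[1] + seq_len(d[1]), pad[3] + seq_len(d[2]), , ] <- X
  Xp
}

# Same-padding for kernel k (asymmetric when k is even), stride 1.
same_pad <- function(k) {
  lo <- (k - 1L) %/% 2L
  hi <- k - 1L - lo
  c(lo, hi, lo, hi)
}

#' @noRd
conv_fw <- function(X, Wm, bias, k, stride, pad) {
  d <- dim(X)
  g <- conv_geom(d[1], d[2], d[3], k, stride, pad)
  B <- d[4]
  Xp <- pad_tensor(X, pad)
  npos <- g$Ho * g$Wo
  Xpm <- matrix(Xp, ncol = B)
  P <- matrix(0, npos * B, ncol(g$idxC))
  for (bi in seq_len(B)) {
    P[(bi - 1L) * npos + seq_len(npos), ] <- Xpm[, bi][g$idxC]
  }
  Y <- P %*% Wm
  Y <- sweep(Y, 2L, bias, "+")
  Cout <- ncol(Wm)
  out <- array(0, c(g$Ho, g$Wo, Cout, B))
  for (bi in seq_len(B)) {
    out[, , , bi] <- Y[(bi - 1L) * npos + seq_len(npos), ]
  }
  list(out = out, cache = list(P = P, g = g, B = B, Cout = Cout))
}

#' @noRd
conv_bw <- function(dY, cache, Wm) {
  g <- cache$g; B <- cache$B; Cout <- cache$Cout
  npos <- g$Ho * g$Wo
  dYm <- matrix(0, npos * B, Cout)
  for (bi in seq_len(B)) {
    dYm[(bi - 1L) * npos + seq_len(npos), ] <- matrix(dY[, , , bi], npos, Cout)
  }
  dW <- crossprod(cache$P, dYm)
  db <- colSums(dYm)
  dP <- dYm %*% t(Wm)
  dX <- array(0, c(g$H, g$W, g$C, B))
  ri <- g$pad[1] + seq_len(g$H)
  ci <- g$pad[3] + seq_len(g$W)
  for (bi in seq_len(B)) {
    v <- as.numeric(g$scatter %*% as.vector(dP[(bi - 1L) * npos + seq_len(npos), ]))
    dXp <- array(v, c(g$Hp, g$Wp, g$C))
    dX[, , , bi] <- dXp[ri, ci, , drop = FALSE]
  }
  list(dX = dX, dW = dW, db = db)
}

maxpool_fw <- function(X) {
  d <- dim(X)
  assert_that(d[1] %% 2 == 0 && d[2] %% 2 == 0, "max pooling needs even H and W")
  ro <- seq(1L, d[1], 2L); re <- seq(2L, d[1], 2L)
  co <- seq(1L, d[2], 2L); ce <- seq(2L, d[2], 2L)
  x11 <- X[ro, co, , , drop = FALSE]; x21 <- X[re, co, , , drop = FALSE]
  x12 <- X[ro, ce, , , drop = FALSE]; x22 <- X[re, ce, , , drop = FALSE]
  m <- pmax(x11, x21, x12, x22)
  w1 <- m == x11
  w2 <- (m == x21) & !w1
  w3 <- (m == x12) & !(w1 | w2)
  w4 <- !(w1 | w2 | w3)
  list(out = m, cache = list(w = list(w1, w2, w3, w4), d = d))
}

maxpool_bw <- function(dY, cache) {
  d <- cache$d
  ro <- seq(1L, d[1], 2L); re <- seq(2L, d[1], 2L)
  co <- seq(1L, d[2], 2L); ce <- seq(2L, d[2], 2L)
  dX <- array(0, d)
  dX[ro, co, , ] <- dY * cache$w[[1]]
  dX[re, co, , ] <- dY * cache$w[[2]]
  dX[ro, ce, , ] <- dY * cache$w[[3]]
  dX[re, ce, , ] <- dY * cache$w[[4]]
  dX
}

upsample_fw <- function(X) {
  d <- dim(X)
  X[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , , drop = FALSE]
}

upsample_bw <- function(dY) {
  d <- dim(dY)
  ro <- seq(1L, d[1], 2L); re <- seq(2L, d[1], 2L)
  co <- seq(1L, d[2], 2L); ce <- seq(2L, d[2], 2L)
  dY[ro, co, , , drop = FALSE] + dY[re, co, , , drop = FALSE] +
    dY[ro, ce, , , drop = FALSE] + dY[re, ce, , , drop = FALSE]
}

instnorm_fw <- function(X, gamma, beta, eps = 1e-5) {
  d <- dim(X)
  n <- d[1] * d[2]
  Xm <- matrix(X, n, d[3] * d[4])
  mu <- colMeans(Xm)
  xc <- Xm - rep(mu, each = n)
  v <- colMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * rep(inv, each = n)
  gcol <- rep(gamma, times = d[4])
  bcol <- rep(beta, times = d[4])
  y <- xhat * rep(gcol, each = n) + rep(bcol, each = n)
  list(out = array(y, d),
       cache = list(xhat = xhat, inv = inv, gcol = gcol, d = d, n = n))
}

instnorm_bw <- function(dY, cache) {
  d <- cache$d; n <- cache$n
  C <- d[3]; B <- d[4]
  dYm <- matrix(dY, n, C * B)
  dg_col <- colSums(dYm * cache$xhat)
  db_col <- colSums(dYm)
  dgamma <- rowSums(matrix(dg_col, C, B))
  dbeta <- rowSums(matrix(db_col, C, B))
  dxhat <- dYm * rep(cache$gcol, each = n)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dx <- (dxhat - rep(s1 / n, each = n) - cache$xhat * rep(s2 / n, each = n)) *
    rep(cache$inv, each = n)
  list(dX = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

relu_fw <- function(X) list(out = pmax(X, 0), cache = X > 0)
relu_bw <- function(dY, cache) dY * cache

sigmoid_fw <- function(X) {
  y <- 1 / (1 + exp(-X))
  list(out = y, cache = y)
}
sigmoid_bw <- function(dY, cache) dY * cache * (1 - cache)

# Scaled tanh mapping network outputs onto the [0, 255] pixel range.
scaled_tanh_fw <- function(X) {
  t <- tanh(X)
  list(out = 127.5 * (t + 1), cache = t)
}
scaled_tanh_bw <- function(dY, cache) dY * 127.5 * (1 - cache * cache)

# ---- parameters --------------------------------------------------------------

# He-normal initialized convolution parameters. Weights are stored as the
# (k^2 * Cin) x Cout matrix the im2col product consumes; row order is kernel
# offsets (row fastest) within input-channel blocks, matching conv_geom.
init_conv <- function(k, cin, cout) {
  W <- matrix(rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
              k * k * cin, cout)
  list(W = W, b = numeric(cout))
}

init_norm <- function(C) list(gamma = rep(1, C), beta = numeric(C))

n_params_list <- function(params) {
  sum(vapply(params, function(p) {
    if (is.list(p)) n_params_list(p) else length(p)
  }, numeric(1)))
}

# ---- Adam --------------------------------------------------------------------

adam_init <- function(params) {
  zero_like <- function(p) {
    if (is.list(p)) lapply(p, zero_like) else array(0, dim = dim(p) %||% length(p))
  }
  list(m = lapply(params, zero_like), v = lapply(params, zero_like), t = 0L)
}

# Applies one Adam update in place (functionally): params and grads are
# parallel nested lists of numeric arrays. betas default to the study's
# optimizer settings (0.9, 0.99).
adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.99, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- list(p = p, m = m, v = v)
      for (nm in names(p)) {
        r <- upd(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out$p[[nm]] <- r$p; out$m[[nm]] <- r$m; out$v[[nm]] <- r$v
      }
      return(out)
    }
    if (is.null(g)) return(list(p = p, m = m, v = v))
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(p = p, m = m, v = v)
  }
  out <- list(params = params, state = state)
  for (nm in names(params)) {
    r <- upd(params[[nm]], grads[[nm]], state$m[[nm]], state$v[[nm]])
    out$params[[nm]] <- r$p
    out$state$m[[nm]] <- r$m
    out$state$v[[nm]] <- r$v
  }
  out$state$t <- state$t
  out
}

# Sum two parallel grad lists (NULL-tolerant).
grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) {
    for (nm in names(a)) a[[nm]] <- grads_add(a[[nm]], b[[nm]])
    return(a)
  }
  a + b
}

# Stack a list of H x W x C images into an (H, W, C, B) batch tensor.
stack_batch <- function(imgs) {
  d <- dim(imgs[[1]])
  out <- array(0, c(d, length(imgs)))
  for (i in seq_along(imgs)) out[, , , i] <- imgs[[i]]
  out
}
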