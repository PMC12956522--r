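# Low-level numeric primitives shared by the forward and backward passes:
# 3x3 convolution as nine shifted matrix products, 2x2 max pooling with argmax
# bookkeeping, batch normalization, and the arctangent surrogate.

# arctangent pseudo-derivative of the spike indicator, slope s:
# g(u) = s / (1 + (pi * s * u)^2), u = v_pre - v_th
surrogate_deriv <- function(u, slope) {
  slope / (1 + (pi * slope * u)^2)
}

# smooth relaxation of the Heaviside spike whose derivative is exactly
# surrogate_deriv(); used only for finite-difference gradient verification
surrogate_spike <- function(u, slope) {
  0.5 + atan(pi * slope * u) / pi
}

# shift a [B, C, H, W] array by (di, dj) in the spatial plane, zero padding
shift2d <- function(x, di, dj) {
  d <- dim(x)
  out <- array(0, d)
  ri <- seq_len(d[3])
  rj <- seq_len(d[4])
  si <- ri + di
  sj <- rj + dj
  ok_i <- si >= 1 & si <= d[3]
  ok_j <- sj >= 1 & sj <= d[4]
  out[, , ri[ok_i], rj[ok_j]] <- x[, , si[ok_i], sj[ok_j], drop = FALSE]
  out
}

# 3x3 same-padding convolution; W is [O, C, 3, 3], x is [B, C, H, W]
conv3_forward <- function(x, W, b) {
  d <- dim(x)
  B <- d[1]; C <- d[2]; H <- d[3]; Wd <- d[4]
  O <- dim(W)[1]
  zm <- matrix(0, O, B * H * Wd)
  for (di in -1:1) {
    for (dj in -1:1) {
      Wk <- matrix(W[, , di + 2, dj + 2], O, C)
      S <- shift2d(x, di, dj)
      Sm <- matrix(aperm(S, c(2, 1, 3, 4)), C, B * H * Wd)
      zm <- zm + Wk %*% Sm
    }
  }
  z <- aperm(array(zm, c(O, B, H, Wd)), c(2, 1, 3, 4))
  for (o in seq_len(O)) z[, o, , ] <- z[, o, , ] + b[o]
  z
}

# backward of conv3_forward: returns gradients wrt x, W, b
conv3_backward <- function(x, W, dz) {
  d <- dim(x)
  B <- d[1]; C <- d[2]; H <- d[3]; Wd <- d[4]
  O <- dim(W)[1]
  dzm <- matrix(aperm(dz, c(2, 1, 3, 4)), O, B * H * Wd)
  dW <- array(0, dim(W))
  dx <- array(0, d)
  for (di in -1:1) {
    for (dj in -1:1) {
      Wk <- matrix(W[, , di + 2, dj + 2], O, C)
      S <- shift2d(x, di, dj)
      Sm <- matrix(aperm(S, c(2, 1, 3, 4)), C, B * H * Wd)
      dW[, , di + 2, dj + 2] <- dzm %*% t(Sm)
      dSm <- t(Wk) %*% dzm
      dS <- aperm(array(dSm, c(C, B, H, Wd)), c(2, 1, 3, 4))
      dx <- dx + shift2d(dS, -di, -dj)
    }
  }
  db <- apply(dz, 2, sum)
  list(dx = dx, dW = dW, db = db)
}

# 2x2 stride-2 max pooling with first-max tie-break; returns pooled values and
# the winning quadrant index (1..4) for gradient routing
pool2_forward <- function(x) {
  d <- dim(x)
  io <- seq(1, d[3], 2)
  jo <- seq(1, d[4], 2)
  q <- list(
    x[, , io, jo, drop = FALSE], x[, , io + 1, jo, drop = FALSE],
    x[, , io, jo + 1, drop = FALSE], x[, , io + 1, jo + 1, drop = FALSE]
  )
  out <- q[[1]]
  arg <- array(1L, dim(out))
  for (k in 2:4) {
    better <- q[[k]] > out
    out[better] <- q[[k]][better]
    arg[better] <- k
  }
  list(out = out, arg = arg)
}

pool2_backward <- function(dout, arg, in_dim) {
  dx <- array(0, in_dim)
  io <- seq(1, in_dim[3], 2)
  jo <- seq(1, in_dim[4], 2)
  sel <- list(
    function(m) list(io, jo), function(m) list(io + 1, jo),
    function(m) list(io, jo + 1), function(m) list(io + 1, jo + 1)
  )
  for (k in 1:4) {
    ij <- sel[[k]](NULL)
    mask <- (arg == k) * dout
    cur <- dx[, , ij[[1]], ij[[2]], drop = FALSE]
    dx[, , ij[[1]], ij[[2]]] <- cur + mask
  }
  dx
}

# batch normalization over rows of a [n x features] matrix
bn_forward <- function(z, bn, train_mode) {
  if (train_mode) {
    n <- nrow(z)
    mu <- colMeans(z)
    va <- colMeans(z^2) - mu^2
    invstd <- 1 / sqrt(va + bn$eps)
    xhat <- sweep(sweep(z, 2, mu), 2, invstd, `*`)
    y <- sweep(sweep(xhat, 2, bn$gamma, `*`), 2, bn$beta, `+`)
    list(y = y, xhat = xhat, invstd = invstd, mean = mu, var = va)
  } else {
    invstd <- 1 / sqrt(bn$rvar + bn$eps)
    xhat <- sweep(sweep(z, 2, bn$rmean), 2, invstd, `*`)
    y <- sweep(sweep(xhat, 2, bn$gamma, `*`), 2, bn$beta, `+`)
    list(y = y, xhat = xhat, invstd = invstd)
  }
}

bn_backward <- function(dy, cache, bn) {
  n <- nrow(dy)
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2, bn$gamma, `*`)
  t1 <- colSums(dxhat)
  t2 <- colSums(dxhat * cache$xhat)
  dz <- sweep(
    n * dxhat - rep(1, n) %o% t1 - cache$xhat * (rep(1, n) %o% t2),
    2, cache$invstd / n, `*`
  )
  list(dz = dz, dgamma = dgamma, dbeta = dbeta)
}

# reshape helpers between [B, C, H, W] conv activations and the [(B*H*W) x C]
# matrix layout batch norm operates on
conv_to_bnmat <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(1, 3, 4, 2)), d[1] * d[3] * d[4], d[2])
}

bnmat_to_conv <- function(m, d) {
  aperm(array(m, c(d[1], d[3], d[4], d[2])), c(1, 4, 2, 3))
}
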