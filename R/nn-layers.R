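# Differentiable primitives used by the encoder. Every *_fwd returns the
# output plus the cache its matching *_bwd needs; backward passes are written
# against the same conventions throughout:
#   - feature matrices are (B*Tp) x D with batch-major row blocks
#     (row (i-1)*Tp + t holds frame t of sample i);
#   - channel matrices are C x (B*T) with batch-major column blocks.

glorot <- function(n_in, n_out, gain = 1) {
  lim <- gain * sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

# GELU, tanh approximation (cheap and standard at this scale).
GELU_C0 <- sqrt(2 / pi)

gelu_fwd <- function(x) {
  t <- tanh(GELU_C0 * (x + 0.044715 * x^3))
  0.5 * x * (1 + t)
}

gelu_bwd <- function(dy, x) {
  x2 <- x * x
  t <- tanh(GELU_C0 * (x + 0.044715 * x * x2))
  dy * (0.5 * (1 + t) +
          0.5 * x * (1 - t * t) * GELU_C0 * (1 + 3 * 0.044715 * x2))
}

# Caching variants for large activations: forward keeps the tanh factor so
# backward skips re-evaluating it.
gelu_fwd_c <- function(x) {
  t <- tanh(GELU_C0 * (x + 0.044715 * x^3))
  list(Y = 0.5 * x * (1 + t), t = t)
}

gelu_bwd_c <- function(dy, x, t) {
  dy * (0.5 * (1 + t) +
          0.5 * x * (1 - t * t) * GELU_C0 * (1 + 3 * 0.044715 * x * x))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

lin_fwd <- function(X, W, b) {
  Y <- X %*% W
  Y + rep(b, each = nrow(Y))
}

lin_bwd <- function(dY, X, W) {
  list(dW = crossprod(X, dY), db = colSums(dY), dX = tcrossprod(dY, W))
}

# --- shifted views (circular-free, zero padded) -------------------------------

# Column index map for reading a C x (B*T) matrix at temporal offset `off`
# inside each length-T block; out-of-range positions point at the sentinel
# column n+1 (a zero column appended by the caller).
.shift_cache <- new.env(parent = emptyenv())

shift_idx <- function(B, T_len, off) {
  key <- paste(B, T_len, off, sep = "_")
  hit <- .shift_cache[[key]]
  if (!is.null(hit)) return(hit)
  t_src <- seq_len(T_len) + off
  bad <- t_src < 1L | t_src > T_len
  base <- rep((seq_len(B) - 1L) * T_len, each = T_len)
  idx <- base + rep(t_src, times = B)
  idx[rep(bad, times = B)] <- B * T_len + 1L
  .shift_cache[[key]] <- idx
  idx
}

pad_zero_col <- function(X) cbind(X, 0)
pad_zero_row <- function(X) rbind(X, 0)

# Shifted views of a C x n channel matrix at each tap of a (k, d) kernel;
# shared between the channel-mixing and depthwise convolutions of a branch.
conv_shifts <- function(X, k, d, B, T_len) {
  Xp <- pad_zero_col(X)
  offs <- (seq_len(k) - (k + 1L) / 2L) * d
  lapply(offs, function(o) Xp[, shift_idx(B, T_len, o), drop = FALSE])
}

# --- full (channel-mixing) dilated temporal convolution -----------------------
# X: C x n (n = B*T, batch-major blocks). W: K x (C*k) flat over taps.
conv_full_fwd <- function(X, W, b, k, d, B, T_len, shifted = NULL) {
  if (is.null(shifted)) shifted <- conv_shifts(X, k, d, B, T_len)
  C <- nrow(X)
  K <- nrow(W)
  Y <- matrix(b, K, B * T_len)
  for (j in seq_len(k))
    Y <- Y + W[, (j - 1L) * C + seq_len(C), drop = FALSE] %*% shifted[[j]]
  list(Y = Y, shifted = shifted, C = C)
}

# Gradient w.r.t. a shifted read is a scatter-add; because the index map is a
# per-block shift, the scatter equals a gather at the opposite offset.
conv_full_bwd <- function(dY, cache, W, k, d, B, T_len) {
  C <- cache$C
  n <- B * T_len
  dW <- matrix(0, nrow(W), ncol(W))
  dX <- matrix(0, C, n)
  offs <- (seq_len(k) - (k + 1L) / 2L) * d
  for (j in seq_len(k)) {
    cols <- (j - 1L) * C + seq_len(C)
    dW[, cols] <- tcrossprod(dY, cache$shifted[[j]])
    blkp <- pad_zero_col(crossprod(W[, cols, drop = FALSE], dY))
    dX <- dX + blkp[, shift_idx(B, T_len, -offs[j]), drop = FALSE]
  }
  list(dW = dW, db = rowSums(dY), dX = dX)
}

# --- depthwise (channel-preserving) temporal convolution ----------------------
# X: C x n. w: C x m x k array, bias: C x m. Output: list of m matrices C x n
# stacked into an array C x n x m.
conv_dw_fwd <- function(X, w, bias, k, d, B, T_len, shifted = NULL) {
  C <- nrow(X); n <- ncol(X); m <- dim(w)[2]
  if (is.null(shifted)) shifted <- conv_shifts(X, k, d, B, T_len)
  Y <- array(0, c(C, n, m))
  for (q in seq_len(m)) {
    acc <- matrix(bias[, q], C, n)
    for (j in seq_len(k)) acc <- acc + shifted[[j]] * w[, q, j]
    Y[, , q] <- acc
  }
  list(Y = Y, shifted = shifted)
}

conv_dw_bwd <- function(dY, cache, w, k, d, B, T_len) {
  C <- dim(dY)[1]; n <- dim(dY)[2]; m <- dim(w)[2]
  dw <- array(0, dim(w)); dbias <- matrix(0, C, m)
  dX <- matrix(0, C, n)
  offs <- (seq_len(k) - (k + 1L) / 2L) * d
  inv_idx <- lapply(offs, function(o) shift_idx(B, T_len, -o))
  for (q in seq_len(m)) {
    dq <- dY[, , q]
    dbias[, q] <- rowSums(dq)
    dqp <- pad_zero_col(dq)
    for (j in seq_len(k)) {
      dw[, q, j] <- rowSums(cache$shifted[[j]] * dq)
      dX <- dX + dqp[, inv_idx[[j]], drop = FALSE] * w[, q, j]
    }
  }
  list(dw = dw, dbias = dbias, dX = dX)
}

# --- normalization ------------------------------------------------------------

# LayerNorm over columns of an n x D matrix (one row = one token).
ln_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  Xc <- X - mu
  v <- rowMeans(Xc * Xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- Xc * inv
  n <- nrow(X)
  Y <- xhat * rep(g, each = n) + rep(b, each = n)
  list(Y = Y, xhat = xhat, inv = inv)
}

ln_bwd <- function(dY, cache, g) {
  xhat <- cache$xhat; inv <- cache$inv
  dxhat <- dY * rep(g, each = nrow(dY))
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dX <- (dxhat - m1 - xhat * m2) * inv
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}

# BatchNorm over rows of a D x n matrix (one row = one feature, stats over the
# n = B*T samples). Running statistics are updated in training mode.
bn_fwd <- function(X, g, b, rmean, rvar, training, momentum = 0.1, eps = 1e-5) {
  if (training) {
    mu <- rowMeans(X)
    Xc <- X - mu
    v <- rowMeans(Xc * Xc)
    rmean <- (1 - momentum) * rmean + momentum * mu
    n <- ncol(X)
    rvar <- (1 - momentum) * rvar + momentum * v * n / max(1, n - 1)
  } else {
    mu <- rmean; v <- rvar
    Xc <- X - mu
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- Xc * inv
  list(Y = xhat * g + b, xhat = xhat, inv = inv, rmean = rmean, rvar = rvar,
       training = training)
}

bn_bwd <- function(dY, cache, g) {
  xhat <- cache$xhat; inv <- cache$inv
  dg <- rowSums(dY * xhat)
  db <- rowSums(dY)
  dxhat <- dY * g
  if (cache$training) {
    m1 <- rowMeans(dxhat)
    m2 <- rowMeans(dxhat * xhat)
    dX <- (dxhat - m1 - xhat * m2) * inv
  } else {
    dX <- dxhat * inv
  }
  list(dX = dX, dg = dg, db = db)
}

# --- dropout ------------------------------------------------------------------

drop_fwd <- function(X, p, training) {
  if (!training || p <= 0) return(list(Y = X, mask = NULL))
  mask <- (stats::runif(length(X)) >= p) / (1 - p)
  dim(mask) <- dim(X)
  list(Y = X * mask, mask = mask)
}

drop_bwd <- function(dY, cache) if (is.null(cache$mask)) dY else dY * cache$mask

# --- multi-head self-attention ------------------------------------------------
# X: (B*Tp) x D, batch-major blocks. Returns attention output before the
# residual add. Weight rows sum to one by construction of the row softmax.
mhsa_fwd <- function(X, p, pre, B, Tp, h) {
  D <- ncol(X)
  dk <- D %/% h
  Q <- lin_fwd(X, p[[paste0(pre, ".Wq")]], p[[paste0(pre, ".bq")]])
  K <- lin_fwd(X, p[[paste0(pre, ".Wk")]], p[[paste0(pre, ".bk")]])
  V <- lin_fwd(X, p[[paste0(pre, ".Wv")]], p[[paste0(pre, ".bv")]])
  O <- matrix(0, nrow(X), D)
  Ps <- vector("list", B * h)
  sc <- 1 / sqrt(dk)
  seq_tp <- seq_len(Tp)
  for (i in seq_len(B)) {
    rows <- (i - 1L) * Tp + seq_tp
    Qb <- Q[rows, , drop = FALSE]
    Kb <- K[rows, , drop = FALSE]
    Vb <- V[rows, , drop = FALSE]
    Ob <- matrix(0, Tp, D)
    for (hd in seq_len(h)) {
      cols <- (hd - 1L) * dk + seq_len(dk)
      S <- tcrossprod(Qb[, cols, drop = FALSE], Kb[, cols, drop = FALSE]) * sc
      S <- S - S[cbind(seq_tp, max.col(S, "first"))]
      P <- exp(S)
      P <- P / rowSums(P)
      Ob[, cols] <- P %*% Vb[, cols, drop = FALSE]
      Ps[[(i - 1L) * h + hd]] <- P
    }
    O[rows, ] <- Ob
  }
  Y <- lin_fwd(O, p[[paste0(pre, ".Wo")]], p[[paste0(pre, ".bo")]])
  list(Y = Y, Q = Q, K = K, V = V, O = O, Ps = Ps, X = X)
}

mhsa_bwd <- function(dY, cache, p, pre, B, Tp, h) {
  D <- ncol(cache$X)
  dk <- D %/% h
  sc <- 1 / sqrt(dk)
  g <- list()
  lo <- lin_bwd(dY, cache$O, p[[paste0(pre, ".Wo")]])
  g[[paste0(pre, ".Wo")]] <- lo$dW; g[[paste0(pre, ".bo")]] <- lo$db
  dO <- lo$dX
  dQ <- matrix(0, nrow(dY), D); dK <- dQ; dV <- dQ
  for (i in seq_len(B)) {
    rows <- (i - 1L) * Tp + seq_len(Tp)
    dOb <- dO[rows, , drop = FALSE]
    Vb <- cache$V[rows, , drop = FALSE]
    Kb <- cache$K[rows, , drop = FALSE]
    Qb <- cache$Q[rows, , drop = FALSE]
    dQb <- matrix(0, Tp, D); dKb <- dQb; dVb <- dQb
    for (hd in seq_len(h)) {
      cols <- (hd - 1L) * dk + seq_len(dk)
      P <- cache$Ps[[(i - 1L) * h + hd]]
      dOh <- dOb[, cols, drop = FALSE]
      dP <- tcrossprod(dOh, Vb[, cols, drop = FALSE])
      dVb[, cols] <- crossprod(P, dOh)
      dS <- P * (dP - rowSums(dP * P))
      dQb[, cols] <- dS %*% Kb[, cols, drop = FALSE] * sc
      dKb[, cols] <- crossprod(dS, Qb[, cols, drop = FALSE]) * sc
    }
    dQ[rows, ] <- dQb; dK[rows, ] <- dKb; dV[rows, ] <- dVb
  }
  lq <- lin_bwd(dQ, cache$X, p[[paste0(pre, ".Wq")]])
  lk <- lin_bwd(dK, cache$X, p[[paste0(pre, ".Wk")]])
  lv <- lin_bwd(dV, cache$X, p[[paste0(pre, ".Wv")]])
  g[[paste0(pre, ".Wq")]] <- lq$dW; g[[paste0(pre, ".bq")]] <- lq$db
  g[[paste0(pre, ".Wk")]] <- lk$dW; g[[paste0(pre, ".bk")]] <- lk$db
  g[[paste0(pre, ".Wv")]] <- lv$dW; g[[paste0(pre, ".bv")]] <- lv$db
  list(grads = g, dX = lq$dX + lk$dX + lv$dX)
}

# Sinusoidal positional encoding, Tp x D (fixed, not learned).
positional_encoding <- function(Tp, D) {
  pos <- seq_len(Tp) - 1L
  i <- seq_len(D) - 1L
  angle <- outer(pos, 10000^(-(i %/% 2L) * 2 / D))
  pe <- matrix(0, Tp, D)
  even <- which(i %% 2L == 0L)
  odd <- which(i %% 2L == 1L)
  pe[, even] <- sin(angle[, even, drop = FALSE])
  pe[, odd] <- cos(angle[, odd, drop = FALSE])
  pe
}

# Depthwise convolution along the frame axis of an n x D feature matrix
# (kernel k, dilation 1), used inside the temporal encoder layers.
feat_dw_fwd <- function(X, w, bias, k, B, Tp) {
  n <- nrow(X); D <- ncol(X)
  Xp <- pad_zero_row(X)
  offs <- seq_len(k) - (k + 1L) / 2L
  shifted <- lapply(offs, function(o) Xp[shift_idx(B, Tp, o), , drop = FALSE])
  Y <- matrix(rep(bias, each = n), n, D)
  for (j in seq_len(k)) Y <- Y + shifted[[j]] * rep(w[, j], each = n)
  list(Y = Y, shifted = shifted)
}

feat_dw_bwd <- function(dY, cache, w, k, B, Tp) {
  D <- ncol(dY)
  dw <- matrix(0, D, k)
  offs <- seq_len(k) - (k + 1L) / 2L
  dYp <- pad_zero_row(dY)
  dX <- matrix(0, nrow(dY), D)
  n <- nrow(dY)
  for (j in seq_len(k)) {
    dw[, j] <- colSums(cache$shifted[[j]] * dY)
    dX <- dX + dYp[shift_idx(B, Tp, -offs[j]), , drop = FALSE] * rep(w[, j], each = n)
  }
  list(dw = dw, dbias = colSums(dY), dX = dX)
}

# Mean pooling of adjacent frame pairs along batch-major column blocks of a
# K x (B*T) matrix; returns K x (B*T/2).
pool2_fwd <- function(X, B, T_len) {
  n <- ncol(X)
  odd <- seq(1L, n, by = 2L)
  (X[, odd, drop = FALSE] + X[, odd + 1L, drop = FALSE]) / 2
}

pool2_bwd <- function(dY) {
  K <- nrow(dY); n2 <- ncol(dY)
  dX <- matrix(0, K, 2L * n2)
  dX[, seq(1L, 2L * n2, by = 2L)] <- dY / 2
  dX[, seq(2L, 2L * n2, by = 2L)] <- dY / 2
  dX
}
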