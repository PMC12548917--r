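# Layer primitives with explicit forward/backward passes.
#
# Conventions used throughout:
#  * Batched feature maps are matrices with depth (feature) channels as
#    columns and rows ordered time-fastest within trial: row index
#    r = t + (n - 1) * T. Functions that need the time structure take the
#    extents T (time) and N (trials) alongside.
#  * forward functions return list(out = ..., cache = ...); the matching
#    backward takes (cache, dout) and returns the input gradient plus one
#    gradient per parameter.
#  * All convolutions are bias-free (the batch-norm shift plays that role).

# ---- temporal convolution, one shared filter bank over many series --------

# x: (T, S) matrix of S independent series; W: (k, F) filter bank.
# 'same' padding: (k-1)%/%2 zeros before, the rest after.
conv_time_shared_fwd <- function(x, W) {
  T <- nrow(x); S <- ncol(x); k <- nrow(W)
  pl <- (k - 1L) %/% 2L
  xp <- matrix(0, T + k - 1L, S)
  xp[pl + seq_len(T), ] <- x
  xcol <- matrix(0, T * S, k)
  for (j in seq_len(k)) xcol[, j] <- xp[j:(j + T - 1L), ]
  list(out = xcol %*% W, # (T*S, F), rows t-fastest within series
       cache = list(xcol = xcol, T = T, S = S, k = k, pl = pl, W = W))
}

conv_time_shared_bwd <- function(cache, dout) {
  dW <- crossprod(cache$xcol, dout)
  dxcol <- dout %*% t(cache$W)
  T <- cache$T; S <- cache$S; k <- cache$k
  dxp <- matrix(0, T + k - 1L, S)
  for (j in seq_len(k))
    dxp[j:(j + T - 1L), ] <- dxp[j:(j + T - 1L), ] + matrix(dxcol[, j], T, S)
  list(dx = dxp[cache$pl + seq_len(T), , drop = FALSE], dW = dW)
}

# ---- depthwise spatial convolution (collapses the channel axis) -----------

# z: array (T, C, N, F1); W: array (C, D, F1). Output (T*N, F1*D) with the
# D depth-multiplier maps of filter f in columns (f-1)*D + 1:D.
dw_spatial_fwd <- function(z, W) {
  d <- dim(z); T <- d[1]; C <- d[2]; N <- d[3]; F1 <- d[4]
  D <- dim(W)[2]
  out <- matrix(0, T * N, F1 * D)
  for (f in seq_len(F1)) {
    xf <- matrix(aperm(array(z[, , , f], c(T, C, N)), c(1, 3, 2)), T * N, C)
    out[, (f - 1L) * D + seq_len(D)] <- xf %*% W[, , f]
  }
  list(out = out, cache = list(z = z, W = W))
}

dw_spatial_bwd <- function(cache, dout) {
  z <- cache$z; W <- cache$W
  d <- dim(z); T <- d[1]; C <- d[2]; N <- d[3]; F1 <- d[4]
  D <- dim(W)[2]
  dW <- array(0, dim(W))
  dz <- array(0, dim(z))
  for (f in seq_len(F1)) {
    xf <- matrix(aperm(array(z[, , , f], c(T, C, N)), c(1, 3, 2)), T * N, C)
    df <- dout[, (f - 1L) * D + seq_len(D), drop = FALSE]
    dW[, , f] <- crossprod(xf, df)
    dxf <- df %*% t(W[, , f])                      # (T*N, C)
    dz[, , , f] <- aperm(array(dxf, c(T, N, C)), c(1, 3, 2))
  }
  list(dz = dz, dW = dW)
}

# ---- per-depth temporal convolution (depthwise, 'same' padding) -----------

# m: (T*N, dep); W: (k, dep), one k-tap filter per depth channel.
# The (T*N, dep) matrix reinterprets as (T, N*dep) without copying order.
dwconv_time_fwd <- function(m, T, N, W) {
  dep <- ncol(m)
  xm <- m
  dim(xm) <- c(T, N * dep)
  y <- cpp_dwconv_fwd(xm, W, N)
  dim(y) <- c(T * N, dep)
  list(out = y, cache = list(xm = xm, T = T, N = N, dep = dep, W = W))
}

dwconv_time_bwd <- function(cache, dout) {
  dym <- dout
  dim(dym) <- c(cache$T, cache$N * cache$dep)
  res <- cpp_dwconv_bwd(cache$xm, cache$W, dym, cache$N)
  dx <- res$dx
  dim(dx) <- c(cache$T * cache$N, cache$dep)
  list(dx = dx, dW = res$dw)
}

# ---- batch normalization ---------------------------------------------------

bn_init <- function(dep) {
  list(gamma = rep(1, dep), beta = rep(0, dep),
       run_mean = rep(0, dep), run_var = rep(1, dep))
}

# m: (rows, dep); stats per column. momentum/eps are the usual framework
# defaults (0.1 / 1e-5); biased variance in-batch, unbiased in the running
# estimate.
bn_fwd <- function(m, p, training, momentum = 0.1, eps = 1e-5) {
  if (training) {
    mu <- colMeans(m)
    v <- colMeans(m * m) - mu * mu
    v[v < 0] <- 0
    nr <- nrow(m)
    p$run_mean <- (1 - momentum) * p$run_mean + momentum * mu
    p$run_var <- (1 - momentum) * p$run_var +
      momentum * v * nr / max(nr - 1L, 1L)
  } else {
    mu <- p$run_mean
    v <- p$run_var
  }
  inv_sd <- 1 / sqrt(v + eps)
  ap <- cpp_bn_apply(m, mu, inv_sd, p$gamma, p$beta)
  list(out = ap$out, state = p,
       cache = list(xhat = ap$xhat, inv_sd = inv_sd, gamma = p$gamma,
                    training = training))
}

bn_bwd <- function(cache, dout) {
  res <- cpp_bn_bwd(cache$xhat, dout, cache$gamma, cache$inv_sd,
                    cache$training)
  list(dx = res$dx, dgamma = res$dgamma, dbeta = res$dbeta)
}

# ---- layer normalization (per row over the embedding) ----------------------

ln_init <- function(dep) list(gamma = rep(1, dep), beta = rep(0, dep))

ln_fwd <- function(m, p, eps = 1e-5) {
  mu <- rowMeans(m)
  xc <- m - mu
  v <- rowMeans(xc * xc)
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- xc * inv_sd
  out <- add_cols(scale_cols(xhat, p$gamma), p$beta)
  list(out = out, cache = list(xhat = xhat, inv_sd = inv_sd, gamma = p$gamma))
}

ln_bwd <- function(cache, dout) {
  xhat <- cache$xhat
  dgamma <- colSums(dout * xhat)
  dbeta <- colSums(dout)
  dxhat <- scale_cols(dout, cache$gamma)
  dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) *
    cache$inv_sd
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- ELU / dropout / pooling ----------------------------------------------

elu_fwd <- function(m) {
  out <- elu(m)
  list(out = out, cache = out)
}

elu_bwd <- function(cache, dout) cpp_elu_grad(cache, dout)

dropout_fwd <- function(m, p, training) {
  if (!training || p <= 0) return(list(out = m, cache = NULL))
  mask <- (matrix(stats::runif(length(m)), nrow(m)) >= p) / (1 - p)
  list(out = m * mask, cache = mask)
}

dropout_bwd <- function(cache, dout) {
  if (is.null(cache)) dout else dout * cache
}

# m: (T*N, dep); non-overlapping average pooling of width w along time,
# trailing remainder dropped (floor division).
avgpool_time_fwd <- function(m, T, N, w) {
  dep <- ncol(m)
  Tp <- T %/% w
  a <- array(m, c(T, N, dep))[seq_len(Tp * w), , , drop = FALSE]
  pooled <- colMeans(matrix(a, w, Tp * N * dep))
  list(out = matrix(pooled, Tp * N, dep),
       cache = list(T = T, N = N, w = w, Tp = Tp, dep = dep))
}

avgpool_time_bwd <- function(cache, dout) {
  T <- cache$T; N <- cache$N; w <- cache$w; Tp <- cache$Tp; dep <- cache$dep
  g <- array(dout, c(Tp, N, dep))
  dx <- array(0, c(T, N, dep))
  expanded <- array(rep(as.vector(g) / w, each = w), c(w, Tp, N, dep))
  dx[seq_len(Tp * w), , ] <- array(expanded, c(Tp * w, N, dep))
  matrix(dx, T * N, dep)
}

# ---- multi-head scaled dot-product self-attention ---------------------------

# Projection matrices are stored with all heads side by side:
# Wq, Wk, Wv, Wo are (F2, F2); head h owns columns (h-1)*dh + 1:dh of
# Wq/Wk/Wv and the matching rows of Wo.
attn_init <- function(F2, heads, seed_dummy = NULL) {
  lim <- sqrt(6 / (F2 + F2))
  ru <- function() matrix(stats::runif(F2 * F2, -lim, lim), F2, F2)
  list(Wq = ru(), Wk = ru(), Wv = ru(), Wo = ru(), heads = heads,
       d_h = F2 %/% heads)
}

# m: (n_seq*N, F2), rows time-fastest within trial.
attn_fwd <- function(m, p, n_seq, N, attn_dropout = 0, training = FALSE) {
  F2 <- ncol(m)
  heads <- p$heads; dh <- p$d_h
  if (n_seq < 1L) stop_config("attention input sequence is empty")
  Q <- m %*% p$Wq; K <- m %*% p$Wk; V <- m %*% p$Wv
  Z <- matrix(0, nrow(m), F2)
  probs <- vector("list", heads * N)
  masks <- vector("list", heads * N)
  scl <- 1 / sqrt(dh)
  for (h in seq_len(heads)) {
    cols <- (h - 1L) * dh + seq_len(dh)
    for (n in seq_len(N)) {
      rows <- (n - 1L) * n_seq + seq_len(n_seq)
      S <- (Q[rows, cols, drop = FALSE] %*%
              t(K[rows, cols, drop = FALSE])) * scl
      P <- softmax_rows(S)
      idx <- (h - 1L) * N + n
      probs[[idx]] <- P
      if (training && attn_dropout > 0) {
        mk <- (matrix(stats::runif(length(P)), nrow(P)) >= attn_dropout) /
          (1 - attn_dropout)
        masks[[idx]] <- mk
        P <- P * mk
      }
      Z[rows, cols] <- P %*% V[rows, cols, drop = FALSE]
    }
  }
  out <- Z %*% p$Wo
  list(out = out,
       cache = list(m = m, Q = Q, K = K, V = V, Z = Z, probs = probs,
                    masks = masks, n_seq = n_seq, N = N, heads = heads,
                    dh = dh, p = p, training = training,
                    attn_dropout = attn_dropout))
}

attn_bwd <- function(cache, dout) {
  p <- cache$p; n_seq <- cache$n_seq; N <- cache$N
  heads <- cache$heads; dh <- cache$dh
  dWo <- crossprod(cache$Z, dout)
  dZ <- dout %*% t(p$Wo)
  dQ <- matrix(0, nrow(cache$m), ncol(cache$m))
  dK <- dQ; dV <- dQ
  scl <- 1 / sqrt(dh)
  for (h in seq_len(heads)) {
    cols <- (h - 1L) * dh + seq_len(dh)
    for (n in seq_len(N)) {
      rows <- (n - 1L) * n_seq + seq_len(n_seq)
      idx <- (h - 1L) * N + n
      P <- cache$probs[[idx]]
      Pd <- if (is.null(cache$masks[[idx]])) P else P * cache$masks[[idx]]
      Vh <- cache$V[rows, cols, drop = FALSE]
      dZh <- dZ[rows, cols, drop = FALSE]
      dPd <- dZh %*% t(Vh)
      dV[rows, cols] <- crossprod(Pd, dZh)
      dP <- if (is.null(cache$masks[[idx]])) dPd else dPd * cache$masks[[idx]]
      dS <- P * (dP - rowSums(dP * P))             # softmax backward
      dQ[rows, cols] <- (dS %*% cache$K[rows, cols, drop = FALSE]) * scl
      dK[rows, cols] <- (crossprod(dS, cache$Q[rows, cols, drop = FALSE])) * scl
    }
  }
  dWq <- crossprod(cache$m, dQ)
  dWk <- crossprod(cache$m, dK)
  dWv <- crossprod(cache$m, dV)
  dm <- dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
  list(dx = dm, dWq = dWq, dWk = dWk, dWv = dWv, dWo = dWo)
}

# ---- dilated causal convolution --------------------------------------------

# m: (Tn*NB, din); W: (k*din, dout) with tap j owning rows
# (j-1)*din + 1:din; tap k is the current time step, tap j looks back
# (k-j)*dil steps. Left-only (causal) zero padding.
causal_conv_fwd <- function(m, Tn, NB, W, k, dil) {
  din <- ncol(m)
  a <- array(m, c(Tn, NB, din))
  xcol <- matrix(0, Tn * NB, k * din)
  for (j in seq_len(k)) {
    s <- (k - j) * dil
    as_ <- array(0, c(Tn, NB, din))
    if (s < Tn) as_[(s + 1L):Tn, , ] <- a[seq_len(Tn - s), , , drop = FALSE]
    xcol[, (j - 1L) * din + seq_len(din)] <- matrix(as_, Tn * NB, din)
  }
  list(out = xcol %*% W,
       cache = list(xcol = xcol, Tn = Tn, NB = NB, din = din, k = k,
                    dil = dil, W = W))
}

causal_conv_bwd <- function(cache, dout) {
  dW <- crossprod(cache$xcol, dout)
  dxcol <- dout %*% t(cache$W)
  Tn <- cache$Tn; NB <- cache$NB; din <- cache$din
  k <- cache$k; dil <- cache$dil
  dm <- array(0, c(Tn, NB, din))
  for (j in seq_len(k)) {
    s <- (k - j) * dil
    if (s < Tn) {
      block <- array(dxcol[, (j - 1L) * din + seq_len(din), drop = FALSE],
                     c(Tn, NB, din))
      dm[seq_len(Tn - s), , ] <- dm[seq_len(Tn - s), , , drop = FALSE] +
        block[(s + 1L):Tn, , , drop = FALSE]
    }
  }
  list(dx = matrix(dm, Tn * NB, din), dW = dW)
}

# ---- fully connected --------------------------------------------------------

linear_fwd <- function(x, W, b) {
  list(out = add_cols(x %*% W, b), cache = list(x = x, W = W))
}

linear_bwd <- function(cache, dout) {
  list(dx = dout %*% t(cache$W), dW = crossprod(cache$x, dout),
       db = colSums(dout))
}

# Glorot-uniform initialization
glorot <- function(nr, nc, fan_in = nr, fan_out = nc) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}
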