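# The decoder network: parameter initialization, the full forward pass with
# caches and stage-shape recording, the matching backward pass, and the
# exported per-module operations.

#' Initialize a decoder model
#'
#' Allocates all learnable parameters (Glorot-uniform weights, unit/zero
#' batch-norm affine terms, zero fully-connected biases) for the given
#' architecture configuration. Ablation switches in the configuration decide
#' which blocks get parameters at all.
#'
#' @param cfg a \code{\link{model_config}}.
#' @param seed integer seed for the weight initialization.
#' @return An object of class \code{"mifuse_model"}: list with \code{cfg} and
#'   the parameter tree \code{params}.
#' @export
init_model <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "model_config"))
  F1 <- cfg$F1; F2 <- cfg$F2; C <- cfg$C; Nc <- cfg$Nc
  t2 <- post_pool_len(cfg)
  ab <- cfg$ablate
  params <- with_seed(mix_seed(seed, 101L), {
    p <- list(
      Wt = glorot(cfg$temporal_kernel, F1),
      bn1 = bn_init(F1),
      Ws = array(stats::runif(C * cfg$D * F1, -sqrt(6 / (C + cfg$D)),
                              sqrt(6 / (C + cfg$D))), c(C, cfg$D, F1)),
      bn2 = bn_init(F2),
      bn3 = bn_init(F2))
    if (!("msc" %in% ab)) {
      branch_filters <- c(F2 %/% 4L, F2 %/% 4L, F2 %/% 2L)
      p$msc <- lapply(seq_len(3L), function(b) {
        k <- cfg$msc_kernels[b]; Fb <- branch_filters[b]
        list(Wd = glorot(k, F2, fan_in = k, fan_out = k),
             Wp = glorot(F2, Fb),
             bn = bn_init(Fb))
      })
    }
    tcn_on <- !("tcn" %in% ab)
    msa_on <- !("msa" %in% ab)
    if (tcn_on && msa_on) {
      p$ln <- ln_init(F2)
      p$attn <- attn_init(F2, cfg$heads)
    }
    if (tcn_on) {
      din1 <- if ("feature_fusion" %in% ab) F2 else 2L * F2
      dout <- 2L * F2
      p$tcn <- lapply(seq_len(cfg$L), function(i) {
        din <- if (i == 1L) din1 else dout
        blk <- list(W1 = glorot(cfg$Kt * din, dout, fan_in = cfg$Kt * din),
                    bnA = bn_init(dout),
                    W2 = glorot(cfg$Kt * dout, dout, fan_in = cfg$Kt * dout),
                    bnB = bn_init(dout))
        if (din != dout) blk$Wr <- glorot(din, dout)
        blk
      })
      p$fc2 <- list(W = glorot(cfg$n_windows * dout, Nc), b = rep(0, Nc))
    }
    if (!("decision_fusion" %in% ab) || !tcn_on)
      p$fc1 <- list(W = glorot(F2 * t2, Nc), b = rep(0, Nc))
    if (cfg$fusion == "concat" && tcn_on && !("decision_fusion" %in% ab))
      p$fuse <- list(W = glorot(2L * Nc, Nc), b = rep(0, Nc))
    p
  })
  structure(list(cfg = cfg, params = params), class = "mifuse_model")
}

post_pool1_len <- function(cfg) cfg$T %/% cfg$pool_width
post_pool_len <- function(cfg) (cfg$T %/% cfg$pool_width) %/% cfg$pool_width

#' @export
print.mifuse_model <- function(x, ...) {
  cat(sprintf("<mifuse_model> %d learnable parameters\n", count_parameters(x)))
  print(x$cfg)
  invisible(x)
}

# Coerce epochs / (C,T) matrix / (N,C,T) array to the internal (T, C, N)
# layout.
as_input_array <- function(x, cfg) {
  if (inherits(x, "eeg_epochs")) x <- x$data
  if (is.matrix(x)) x <- array(x, c(1L, nrow(x), ncol(x)))
  d <- dim(x)
  if (length(d) != 3L || d[2] != cfg$C || d[3] != cfg$T)
    stop_config("input shape (%s) does not match config (C=%d, T=%d)",
                paste(d, collapse = ","), cfg$C, cfg$T)
  aperm(x, c(3, 2, 1)) # (T, C, N)
}

# ---- full forward pass -------------------------------------------------------

# Returns probabilities plus (when keep_cache) everything needed for the
# backward pass, and a stage-shape table for contract inspection.
net_fwd <- function(model, x, training = FALSE, keep_cache = training) {
  cfg <- model$cfg; p <- model$params
  xa <- as_input_array(x, cfg)
  T <- cfg$T; C <- cfg$C; N <- dim(xa)[3]
  F1 <- cfg$F1; F2 <- cfg$F2; w <- cfg$pool_width
  ab <- cfg$ablate
  tcn_on <- !("tcn" %in% ab); msa_on <- !("msa" %in% ab)
  ff_on <- !("feature_fusion" %in% ab); df_on <- !("decision_fusion" %in% ab)
  cache <- list(); stages <- list()
  st <- function(name, extent) stages[[length(stages) + 1L]] <<-
      list(stage = name, extent = extent)

  ## --- spatiotemporal convolution block
  tc <- conv_time_shared_fwd(matrix(xa, T, C * N), p$Wt)  # (T*C*N, F1)
  st("temporal_conv", c(F1, C, T))
  b1 <- bn_fwd(tc$out, p$bn1, training)
  model$params$bn1 <- b1$state
  st("bn1", c(F1, C, T))
  z1 <- array(b1$out, c(T, C, N, F1))
  sp <- dw_spatial_fwd(z1, p$Ws)                          # (T*N, F2)
  st("spatial_conv", c(F2, 1, T))
  b2 <- bn_fwd(sp$out, p$bn2, training)
  model$params$bn2 <- b2$state
  e2 <- elu_fwd(b2$out)
  st("bn2_elu", c(F2, 1, T))
  T1 <- T %/% w
  p1 <- avgpool_time_fwd(e2$out, T, N, w)
  st("pool1", c(F2, 1, T1))
  d1 <- dropout_fwd(p1$out, cfg$conv_dropout, training)
  st("drop1", c(F2, 1, T1))
  sc_out <- d1$out                                         # (T1*N, F2)

  ## --- multi-branch separable convolution block
  if (!("msc" %in% ab)) {
    br <- vector("list", 3L)
    outs <- vector("list", 3L)
    for (b in seq_len(3L)) {
      dw <- dwconv_time_fwd(sc_out, T1, N, p$msc[[b]]$Wd)
      pw <- list(out = dw$out %*% p$msc[[b]]$Wp, x = dw$out)
      bnb <- bn_fwd(pw$out, p$msc[[b]]$bn, training)
      model$params$msc[[b]]$bn <- bnb$state
      eb <- elu_fwd(bnb$out)
      br[[b]] <- list(dw = dw, pw = pw, bn = bnb, elu = eb)
      outs[[b]] <- eb$out
    }
    mcat <- do.call(cbind, outs)                           # (T1*N, F2)
  } else {
    br <- NULL
    mcat <- sc_out
  }
  st("msc_branches", c(F2, 1, T1))
  b3 <- bn_fwd(mcat, p$bn3, training)
  model$params$bn3 <- b3$state
  e3 <- elu_fwd(b3$out)
  st("bn3_elu", c(F2, 1, T1))
  T2 <- T1 %/% w
  p2 <- avgpool_time_fwd(e3$out, T1, N, w)
  st("pool2", c(F2, 1, T2))
  d2 <- dropout_fwd(p2$out, cfg$conv_dropout, training)
  st("drop2", c(F2, 1, T2))
  msc_out <- d2$out                                        # (T2*N, F2)

  ## --- classifier branch A: flatten + FC1
  logits1 <- NULL; fc1 <- NULL; fc1_in <- NULL
  if (!is.null(p$fc1)) {
    arr <- array(msc_out, c(T2, N, F2))
    fc1_in <- t(matrix(aperm(arr, c(1, 3, 2)), T2 * F2, N)) # (N, F2*T2)
    st("flatten1", F2 * T2)
    fc1 <- linear_fwd(fc1_in, p$fc1$W, p$fc1$b)
    logits1 <- fc1$out
    st("fc1", cfg$Nc)
  }

  ## --- branch B: attention, feature fusion, windowed TCN, FC2
  logits2 <- NULL; ln <- NULL; at <- NULL; ea <- NULL; fc2 <- NULL
  fused <- NULL; tcnc <- NULL; fc2_in <- NULL; msa_out <- NULL
  if (tcn_on) {
    if (msa_on) {
      ln <- ln_fwd(msc_out, p$ln)
      st("layer_norm", c(F2, T2))
      at <- attn_fwd(ln$out, p$attn, T2, N, cfg$attn_dropout, training)
      ea <- elu_fwd(at$out)
      msa_out <- if (cfg$msa_residual) msc_out + ea$out else ea$out
      st("msa", c(F2, T2))
    } else {
      msa_out <- msc_out
    }
    fused <- if (ff_on) cbind(msc_out, msa_out) else msa_out
    st("feature_fusion", c(ncol(fused), T2))
    tcnc <- windowed_tcn_fwd(fused, T2, N, cfg, p$tcn, training)
    fc2_in <- tcnc$out                                     # (N, n_windows*2F2)
    st("tcn_windows", ncol(fc2_in))
    fc2 <- linear_fwd(fc2_in, p$fc2$W, p$fc2$b)
    logits2 <- fc2$out
    st("fc2", cfg$Nc)
  }

  ## --- decision fusion
  if (tcn_on && df_on && !is.null(logits1)) {
    if (cfg$fusion == "sum") {
      logits <- logits1 + logits2
      fuse <- NULL
    } else {
      fuse <- linear_fwd(cbind(logits1, logits2), p$fuse$W, p$fuse$b)
      logits <- fuse$out
    }
  } else if (tcn_on && !df_on) {
    logits <- logits2; fuse <- NULL
  } else {
    logits <- logits1; fuse <- NULL
  }
  st("decision_fusion", cfg$Nc)
  probs <- softmax_rows(logits)
  st("softmax", cfg$Nc)

  if (keep_cache)
    cache <- list(tc = tc, b1 = b1, z1dim = dim(z1), sp = sp, b2 = b2,
                  e2 = e2, p1 = p1, d1 = d1, br = br, b3 = b3, e3 = e3,
                  p2 = p2, d2 = d2, fc1 = fc1, ln = ln, at = at, ea = ea,
                  fc2 = fc2, fuse = fuse, tcnc = tcnc, msc_out = msc_out,
                  sc_out = sc_out, T1 = T1, T2 = T2, N = N)
  list(probs = probs, logits = logits, logits1 = logits1, logits2 = logits2,
       fc1_in = fc1_in, fc2_in = fc2_in, stages = stages, cache = cache,
       bn_updated = model$params)
}

# Shared-weight TCN over n_windows overlapping windows of the fused sequence.
# fused: (T2*N, dep). Windows are stacked into the batch dimension
# (window-fastest within trial), run through the TCN once, and the last time
# step of every window is concatenated per trial.
windowed_tcn_fwd <- function(fused, T2, N, cfg, tcn_params, training) {
  dep <- ncol(fused)
  nw <- cfg$n_windows
  lw <- T2 - nw + 1L
  if (lw < 1L) stop_config("sequence length %d shorter than n_windows = %d", T2, nw)
  a <- array(fused, c(T2, N, dep))
  wins <- array(0, c(lw, nw, N, dep))
  for (wdx in seq_len(nw))
    wins[, wdx, , ] <- a[wdx:(wdx + lw - 1L), , , drop = FALSE]
  m <- matrix(wins, lw * nw * N, dep)
  run <- tcn_stack_fwd(m, lw, nw * N, cfg, tcn_params, training)
  dout <- 2L * cfg$F2
  last <- run$out[(seq_len(nw * N) - 1L) * lw + lw, , drop = FALSE] # t = lw rows
  arr2 <- array(last, c(nw, N, dout))
  # per trial, window blocks in order: out[n, (w-1)*dout + j] = arr2[w, n, j]
  out <- matrix(aperm(arr2, c(2, 3, 1)), N, nw * dout)
  list(out = out, cache = list(run = run, T2 = T2, N = N, dep = dep,
                               nw = nw, lw = lw, dout = dout))
}

windowed_tcn_bwd <- function(cache, dout_mat, cfg, tcn_params) {
  nw <- cache$nw; N <- cache$N; lw <- cache$lw; dout <- cache$dout
  darr2 <- aperm(array(dout_mat, c(N, dout, nw)), c(3, 1, 2))
  dlast <- matrix(darr2, nw * N, dout)
  dm_run <- matrix(0, lw * nw * N, dout)
  dm_run[(seq_len(nw * N) - 1L) * lw + lw, ] <- dlast
  back <- tcn_stack_bwd(cache$run, dm_run, cfg, tcn_params)
  dm <- back$dx                                            # (lw*nw*N, dep)
  dwins <- array(dm, c(lw, nw, N, cache$dep))
  dfused <- array(0, c(cache$T2, N, cache$dep))
  for (wdx in seq_len(nw))
    dfused[wdx:(wdx + lw - 1L), , ] <-
      array(dfused[wdx:(wdx + lw - 1L), , ], c(lw, N, cache$dep)) +
      array(dwins[, wdx, , ], c(lw, N, cache$dep))
  list(dx = matrix(dfused, cache$T2 * N, cache$dep), dtcn = back$dtcn)
}

# L residual blocks of two dilated causal convolutions each.
tcn_stack_fwd <- function(m, Tn, NB, cfg, tcn_params, training) {
  blocks <- vector("list", cfg$L)
  acts <- vector("list", cfg$L)
  x <- m
  for (i in seq_len(cfg$L)) {
    bp <- tcn_params[[i]]
    dil <- 2L^(i - 1L)
    c1 <- causal_conv_fwd(x, Tn, NB, bp$W1, cfg$Kt, dil)
    bA <- bn_fwd(c1$out, bp$bnA, training)
    eA <- elu_fwd(bA$out)
    dA <- dropout_fwd(eA$out, cfg$tcn_dropout, training)
    c2 <- causal_conv_fwd(dA$out, Tn, NB, bp$W2, cfg$Kt, dil)
    bB <- bn_fwd(c2$out, bp$bnB, training)
    eB <- elu_fwd(bB$out)
    dB <- dropout_fwd(eB$out, cfg$tcn_dropout, training)
    res <- if (!is.null(bp$Wr)) x %*% bp$Wr else x
    out <- dB$out + res
    blocks[[i]] <- list(x = x, c1 = c1, bA = bA, eA = eA, dA = dA,
                        c2 = c2, bB = bB, eB = eB, dB = dB, dil = dil)
    acts[[i]] <- out
    x <- out
  }
  list(out = x, blocks = blocks, acts = acts, Tn = Tn, NB = NB)
}

tcn_stack_bwd <- function(run, dout, cfg, tcn_params) {
  dtcn <- vector("list", cfg$L)
  dx <- dout
  for (i in rev(seq_len(cfg$L))) {
    bl <- run$blocks[[i]]
    bp <- tcn_params[[i]]
    d_res <- dx
    d_branch <- dropout_bwd(bl$dB$cache, dx)
    d_branch <- elu_bwd(bl$eB$cache, d_branch)
    bB <- bn_bwd(bl$bB$cache, d_branch)
    c2 <- causal_conv_bwd(bl$c2$cache, bB$dx)
    dA <- dropout_bwd(bl$dA$cache, c2$dx)
    dA <- elu_bwd(bl$eA$cache, dA)
    bA <- bn_bwd(bl$bA$cache, dA)
    c1 <- causal_conv_bwd(bl$c1$cache, bA$dx)
    g <- list(W1 = c1$dW,
              bnA = list(gamma = bA$dgamma, beta = bA$dbeta),
              W2 = c2$dW,
              bnB = list(gamma = bB$dgamma, beta = bB$dbeta))
    if (!is.null(bp$Wr)) {
      g$Wr <- crossprod(bl$x, d_res)
      dx <- c1$dx + d_res %*% t(bp$Wr)
    } else {
      dx <- c1$dx + d_res
    }
    dtcn[[i]] <- g
  }
  list(dx = dx, dtcn = dtcn)
}

# ---- full backward pass ------------------------------------------------------

net_bwd <- function(model, fwd, dlogits) {
  cfg <- model$cfg; p <- model$params; ch <- fwd$cache
  if (is.null(ch) || length(ch) == 0L)
    stop("forward pass was run without keep_cache")
  N <- ch$N; T1 <- ch$T1; T2 <- ch$T2
  F2 <- cfg$F2; T <- cfg$T; C <- cfg$C; w <- cfg$pool_width
  ab <- cfg$ablate
  tcn_on <- !("tcn" %in% ab); msa_on <- !("msa" %in% ab)
  ff_on <- !("feature_fusion" %in% ab); df_on <- !("decision_fusion" %in% ab)
  g <- list()

  # decision fusion -> branch logits
  d1l <- NULL; d2l <- NULL
  if (tcn_on && df_on && !is.null(ch$fc1)) {
    if (cfg$fusion == "sum") {
      d1l <- dlogits; d2l <- dlogits
    } else {
      fb <- linear_bwd(ch$fuse$cache, dlogits)
      g$fuse <- list(W = fb$dW, b = fb$db)
      d1l <- fb$dx[, seq_len(cfg$Nc), drop = FALSE]
      d2l <- fb$dx[, cfg$Nc + seq_len(cfg$Nc), drop = FALSE]
    }
  } else if (tcn_on && !df_on) {
    d2l <- dlogits
  } else {
    d1l <- dlogits
  }

  d_msc_out <- matrix(0, T2 * N, F2)

  # branch A: FC1 <- flatten
  if (!is.null(d1l)) {
    fb1 <- linear_bwd(ch$fc1$cache, d1l)
    g$fc1 <- list(W = fb1$dW, b = fb1$db)
    darr <- array(t(fb1$dx), c(T2, F2, N))                 # invert flatten
    d_msc_out <- d_msc_out + matrix(aperm(darr, c(1, 3, 2)), T2 * N, F2)
  }

  # branch B
  if (tcn_on && !is.null(d2l)) {
    fb2 <- linear_bwd(ch$fc2$cache, d2l)
    g$fc2 <- list(W = fb2$dW, b = fb2$db)
    wt <- windowed_tcn_bwd(ch$tcnc$cache, fb2$dx, cfg, p$tcn)
    g$tcn <- wt$dtcn
    if (ff_on) {
      d_msc_out <- d_msc_out + wt$dx[, seq_len(F2), drop = FALSE]
      d_msa <- wt$dx[, F2 + seq_len(F2), drop = FALSE]
    } else {
      d_msa <- wt$dx
    }
    if (msa_on) {
      if (cfg$msa_residual) d_msc_out <- d_msc_out + d_msa
      d_ea <- elu_bwd(ch$ea$cache, d_msa)
      ab_ <- attn_bwd(ch$at$cache, d_ea)
      g$attn <- list(Wq = ab_$dWq, Wk = ab_$dWk, Wv = ab_$dWv, Wo = ab_$dWo)
      lb <- ln_bwd(ch$ln$cache, ab_$dx)
      g$ln <- list(gamma = lb$dgamma, beta = lb$dbeta)
      d_msc_out <- d_msc_out + lb$dx
    } else {
      d_msc_out <- d_msc_out + d_msa
    }
  }

  # MSC block backward: drop2 <- pool2 <- elu <- bn3 <- concat <- branches
  dd2 <- dropout_bwd(ch$d2$cache, d_msc_out)
  dp2 <- avgpool_time_bwd(ch$p2$cache, dd2)
  de3 <- elu_bwd(ch$e3$cache, dp2)
  b3 <- bn_bwd(ch$b3$cache, de3)
  g$bn3 <- list(gamma = b3$dgamma, beta = b3$dbeta)
  d_sc_out <- matrix(0, T1 * N, F2)
  if (!("msc" %in% ab)) {
    branch_filters <- c(F2 %/% 4L, F2 %/% 4L, F2 %/% 2L)
    off <- 0L
    g$msc <- vector("list", 3L)
    for (b in seq_len(3L)) {
      Fb <- branch_filters[b]
      dob <- b3$dx[, off + seq_len(Fb), drop = FALSE]
      off <- off + Fb
      bl <- ch$br[[b]]
      deb <- elu_bwd(bl$elu$cache, dob)
      bnb <- bn_bwd(bl$bn$cache, deb)
      dWp <- crossprod(bl$pw$x, bnb$dx)
      d_dw <- bnb$dx %*% t(p$msc[[b]]$Wp)
      dw <- dwconv_time_bwd(bl$dw$cache, d_dw)
      g$msc[[b]] <- list(Wd = dw$dW, Wp = dWp,
                         bn = list(gamma = bnb$dgamma, beta = bnb$dbeta))
      d_sc_out <- d_sc_out + dw$dx
    }
  } else {
    d_sc_out <- b3$dx
  }

  # SC block backward
  dd1 <- dropout_bwd(ch$d1$cache, d_sc_out)
  dp1 <- avgpool_time_bwd(ch$p1$cache, dd1)
  de2 <- elu_bwd(ch$e2$cache, dp1)
  b2 <- bn_bwd(ch$b2$cache, de2)
  g$bn2 <- list(gamma = b2$dgamma, beta = b2$dbeta)
  spb <- dw_spatial_bwd(ch$sp$cache, b2$dx)
  g$Ws <- spb$dW
  b1 <- bn_bwd(ch$b1$cache, matrix(spb$dz, prod(dim(spb$dz)[1:3]), cfg$F1))
  g$bn1 <- list(gamma = b1$dgamma, beta = b1$dbeta)
  tcb <- conv_time_shared_bwd(ch$tc$cache, b1$dx)
  g$Wt <- tcb$dW
  g
}

# ---- exported module operations ---------------------------------------------

#' Spatiotemporal convolution module forward pass
#'
#' Temporal convolution (shared filter bank, 'same' padding, no bias), batch
#' norm, depthwise spatial convolution collapsing the channel axis, batch
#' norm, ELU, average pooling and dropout.
#'
#' @param x a \code{C x T} matrix (one epoch) or \code{N x C x T} array.
#' @param model a \code{\link{init_model}} result (its \code{cfg} fixes all
#'   extents).
#' @param training apply dropout and batch statistics as in training.
#' @return A feature map: list with \code{values} (array \code{F2 x 1 x T\%/\%8}
#'   for a single epoch, else \code{N x F2 x 1 x T\%/\%8}) and \code{axes}.
#' @export
sc_forward <- function(x, model, training = FALSE) {
  cfg <- model$cfg
  single <- is.matrix(x)
  fwd <- net_fwd(model, x, training = training, keep_cache = TRUE)
  out <- fwd$cache$d1$out # (T1*N, F2)
  feature_map(out, fwd$cache$T1, fwd$cache$N, cfg$F2, single)
}

#' Multi-branch separable convolution module forward pass
#'
#' Three parallel depthwise-separable branches (kernels 8/16/32, filter
#' counts F2/4, F2/4, F2/2), depth concatenation, batch norm, ELU, average
#' pooling and dropout. Input and output depth both equal \code{F2}.
#'
#' @param fm feature map from \code{\link{sc_forward}}, or a plain
#'   \code{(T1*N) x F2} matrix (then give \code{T1}, \code{N}).
#' @param model the model.
#' @param training training mode flag.
#' @param T1,N extents when \code{fm} is a plain matrix.
#' @return A feature map of depth \code{F2} and time extent
#'   \code{T1 \%/\% pool_width}.
#' @export
msc_forward <- function(fm, model, training = FALSE, T1 = NULL, N = NULL) {
  cfg <- model$cfg; p <- model$params
  m <- as_fm_matrix(fm, cfg$F2)
  T1 <- T1 %||% attr(m, "T"); N <- N %||% attr(m, "N")
  if (ncol(m) != cfg$F2)
    stop_config("MSC input depth %d != F2 = %d", ncol(m), cfg$F2)
  if (!("msc" %in% cfg$ablate)) {
    outs <- lapply(seq_len(3L), function(b) {
      dw <- dwconv_time_fwd(m, T1, N, p$msc[[b]]$Wd)
      bnb <- bn_fwd(dw$out %*% p$msc[[b]]$Wp, p$msc[[b]]$bn, training)
      elu(bnb$out)
    })
    m <- do.call(cbind, outs)
  }
  b3 <- bn_fwd(m, p$bn3, training)
  e3 <- elu(b3$out)
  T2 <- T1 %/% cfg$pool_width
  pl <- avgpool_time_fwd(e3, T1, N, cfg$pool_width)
  dr <- dropout_fwd(pl$out, cfg$conv_dropout, training)
  feature_map(dr$out, T2, N, cfg$F2, single = (N == 1L))
}

#' Multi-head self-attention forward pass
#'
#' Layer-normalizes the input sequence, computes per-head queries/keys/values
#' by linear maps, scaled dot-product attention with optional dropout,
#' concatenates the heads, projects with the output matrix and applies ELU.
#' Sequence length and embedding width are unchanged.
#'
#' @param y an \code{n x F2} matrix (one sequence) or \code{(n*N) x F2}
#'   matrix with \code{N} stacked sequences.
#' @param model the model (must hold attention parameters).
#' @param n_seq sequence length (defaults to \code{nrow(y)} for one
#'   sequence).
#' @param training apply attention dropout.
#' @param layer_norm apply the input layer normalization (part of the
#'   network's attention block).
#' @return Matrix of the same shape as \code{y}; attribute
#'   \code{"attention"} holds the per-head post-softmax attention matrices
#'   (before dropout).
#' @export
msa_forward <- function(y, model, n_seq = nrow(y), training = FALSE,
                        layer_norm = TRUE) {
  cfg <- model$cfg; p <- model$params
  if (is.null(p$attn)) stop_config("model has no attention parameters (ablated?)")
  if (nrow(y) == 0L) stop_config("attention input sequence is empty")
  N <- nrow(y) %/% n_seq
  m <- if (layer_norm) ln_fwd(y, p$ln)$out else y
  at <- attn_fwd(m, p$attn, n_seq, N, cfg$attn_dropout, training)
  out <- elu(at$out)
  if (cfg$msa_residual) out <- y + out
  attr(out, "attention") <- at$cache$probs
  out
}

#' Temporal convolutional network forward pass (single sequence)
#'
#' Runs one sequence through the stack of dilated causal residual blocks and
#' returns the final time step's feature vector. The receptive field
#' \code{1 + 2(Kt-1)(2^L - 1)} must exceed the sequence length.
#'
#' @param seq_x an \code{n x depth} matrix, depth matching the TCN input
#'   (2*F2, or F2 when feature fusion is ablated).
#' @param model the model.
#' @param training training mode flag.
#' @param return_activations also return every block's full output sequence
#'   (used for causality checks).
#' @return The last-step feature vector (length \code{2*F2}); with
#'   \code{return_activations = TRUE}, a list \code{(out, activations)}.
#' @export
tcn_forward <- function(seq_x, model, training = FALSE,
                        return_activations = FALSE) {
  cfg <- model$cfg
  if (is.null(model$params$tcn)) stop_config("model has no TCN parameters (ablated?)")
  n <- nrow(seq_x)
  rfs <- receptive_field_size(cfg$Kt, cfg$L)
  if (rfs <= n)
    stop_config(paste0("receptive field size %d (= 1 + 2(Kt-1)(2^L - 1)) must be ",
                       "larger than the input sequence length %d"), rfs, n)
  run <- tcn_stack_fwd(seq_x, n, 1L, cfg, model$params$tcn, training)
  out <- run$out[n, ]
  if (return_activations) list(out = out, activations = run$acts) else out
}

#' Feature fusion: depth concatenation of multi-scale and attention features
#'
#' @param msc_out feature map or \code{(n*N) x F2} matrix of multi-scale
#'   convolution features.
#' @param msa_out matrix of attention features with the same time extent.
#' @return The fused \code{(n*N) x 2*F2} matrix, MSC features first.
#' @export
feature_fusion <- function(msc_out, msa_out) {
  a <- as_fm_matrix(msc_out)
  b <- as_fm_matrix(msa_out)
  if (nrow(a) != nrow(b))
    stop_config("time-extent mismatch in feature fusion: %d vs %d rows",
                nrow(a), nrow(b))
  cbind(unclass(a), unclass(b))
}

#' Windowed shared-weight TCN over a fused sequence
#'
#' Slices \code{n_windows} overlapping windows out of the fused sequence,
#' runs each through the same TCN, and concatenates the windows' last-step
#' vectors into one feature vector of length \code{n_windows * 2 * F2}.
#'
#' @param fused an \code{n x depth} matrix (one trial's fused sequence).
#' @param model the model.
#' @param training training mode flag.
#' @return Numeric vector of length \code{n_windows * 2 * F2}.
#' @export
windowed_tcn <- function(fused, model, training = FALSE) {
  cfg <- model$cfg
  n <- nrow(fused)
  if (n < cfg$n_windows)
    stop_config("sequence length %d shorter than n_windows = %d", n, cfg$n_windows)
  res <- windowed_tcn_fwd(fused, n, 1L, cfg, model$params$tcn, training)
  drop(res$out)
}

#' Decision fusion of the two branch classifiers
#'
#' Adds the multi-scale branch's logits and the TCN branch's logits
#' element-wise and applies the softmax, yielding the final class
#' probabilities.
#'
#' @param logits_msc numeric vector (or \code{N x Nc} matrix) of MSC-branch
#'   logits.
#' @param logits_tcn logits of the TCN branch, same shape.
#' @return Probability vector/matrix summing to 1 per trial.
#' @export
decision_fusion <- function(logits_msc, logits_tcn) {
  single <- is.null(dim(logits_msc))
  a <- rbind(logits_msc); b <- rbind(logits_tcn)
  if (!all(dim(a) == dim(b)))
    stop_config("logit length mismatch in decision fusion")
  out <- softmax_rows(a + b)
  if (single) drop(out) else out
}

# feature-map helpers -----------------------------------------------------

feature_map <- function(m, Tn, N, depth, single) {
  values <- if (single) {
    aperm(array(m, c(Tn, 1L, depth)), c(3, 2, 1))          # (depth, 1, time)
  } else {
    aperm(array(m, c(Tn, N, depth)), c(2, 3, 1))           # (N, depth, time) -> add spatial
  }
  if (!single) {
    d <- dim(values)
    values <- array(values, c(d[1], d[2], 1L, d[3]))
  }
  structure(list(values = values,
                 axes = list(depth = depth, spatial = 1L, time = Tn),
                 matrix = m, T = Tn, N = N),
            class = "feature_map")
}

as_fm_matrix <- function(x, expected_depth = NULL) {
  if (inherits(x, "feature_map")) {
    m <- x$matrix
    attr(m, "T") <- x$T; attr(m, "N") <- x$N
    return(m)
  }
  if (is.array(x) && length(dim(x)) == 3L) {
    # (depth, 1, time) single feature map
    d <- dim(x)
    m <- t(matrix(x[, 1L, ], d[1], d[3]))                  # (time, depth)
    attr(m, "T") <- d[3]; attr(m, "N") <- 1L
    return(m)
  }
  m <- as.matrix(x)
  attr(m, "T") <- attr(x, "T") %||% nrow(m)
  attr(m, "N") <- attr(x, "N") %||% 1L
  m
}

#' @export
print.feature_map <- function(x, ...) {
  cat(sprintf("<feature_map> depth %d x spatial %d x time %d (%d trial(s))\n",
              x$axes$depth, x$axes$spatial, x$axes$time, x$N))
  invisible(x)
}

# ---- whole-network conveniences ----------------------------------------------

#' Full decoder forward pass
#'
#' @param model a \code{\link{init_model}} result.
#' @param x epochs (\code{eeg_epochs}), an \code{N x C x T} array, or a
#'   single \code{C x T} matrix. Inputs are expected to be normalized
#'   already.
#' @param training training mode (dropout active, batch statistics from the
#'   batch).
#' @return List with \code{probs} (\code{N x Nc}, rows summing to 1),
#'   \code{logits}, per-branch logits, and \code{stages} (the shape trace).
#' @export
model_forward <- function(model, x, training = FALSE) {
  fwd <- net_fwd(model, x, training = training, keep_cache = FALSE)
  fwd[c("probs", "logits", "logits1", "logits2", "stages")]
}

#' Count learnable parameters
#'
#' @param model a model or a \code{\link{model_config}} (then a throwaway
#'   model is initialized to count).
#' @return Integer number of learnable scalars (batch-norm running statistics
#'   excluded).
#' @export
count_parameters <- function(model) {
  if (inherits(model, "model_config")) model <- init_model(model, seed = 1L)
  sum(unlist(lapply(trainable_leaves(model$params), function(l) length(l$value))))
}

# Recursively enumerate trainable leaves as list(path, value).
trainable_leaves <- function(tree, path = character(0)) {
  skip <- c("run_mean", "run_var", "heads", "d_h")
  out <- list()
  for (nm in names(tree) %||% as.character(seq_along(tree))) {
    item <- if (is.null(names(tree))) tree[[as.integer(nm)]] else tree[[nm]]
    if (is.list(item)) {
      out <- c(out, trainable_leaves(item, c(path, nm)))
    } else if (is.numeric(item) && !(nm %in% skip)) {
      out[[length(out) + 1L]] <- list(path = c(path, nm), value = item)
    }
  }
  out
}

#' Per-stage shape trace of the architecture
#'
#' Runs a single dummy epoch through the network and records every stage's
#' output extent, for comparison against the architecture contract (the
#' published layer table): temporal/spatial convolutions at
#' \code{(F1,C,T)}/\code{(F2,1,T)}, pooled maps at \code{T\%/\%8} and
#' \code{T\%/\%64}, attention at \code{(F2, T\%/\%64)}, fused depth
#' \code{2*F2}, TCN output \code{n_windows*2*F2}, classifier extents
#' \code{Nc}.
#'
#' @param cfg a \code{\link{model_config}} (or a model).
#' @param seed initialization seed for the dummy weights.
#' @return \code{data.frame} with columns \code{stage} and \code{extent}
#'   (comma-separated extents); attribute \code{"rfs"} carries the TCN
#'   receptive field size and \code{"tcn_input_len"} the fused sequence
#'   length entering the TCN.
#' @export
shape_trace <- function(cfg, seed = 1L) {
  model <- if (inherits(cfg, "mifuse_model")) cfg else init_model(cfg, seed)
  cfg <- model$cfg
  x <- matrix(0, cfg$C, cfg$T)
  x[] <- stats::rnorm(length(x))
  fwd <- net_fwd(model, x, training = FALSE, keep_cache = FALSE)
  df <- data.frame(
    stage = vapply(fwd$stages, `[[`, character(1), "stage"),
    extent = vapply(fwd$stages, function(s)
      paste(s$extent, collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  attr(df, "rfs") <- receptive_field_size(cfg$Kt, cfg$L)
  attr(df, "tcn_input_len") <- post_pool_len(cfg)
  df
}
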