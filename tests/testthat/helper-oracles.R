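# Shared fixtures and independent brute-force oracles used across test files.

# Small architecture for fast structural tests (all dropout off so forward
# passes are deterministic in training mode too).
tiny_cfg <- function(...) {
  model_config(C = 3, T = 192, Nc = 3, F1 = 4, D = 2, heads = 2,
               conv_dropout = 0, attn_dropout = 0, tcn_dropout = 0, ...)
}

# Desk-scale synthetic study conditions: 4 channels, 64 Hz, 4 s epochs,
# 4 classes on single-channel mu/beta signatures.
desk_spec <- function(trials_per_class = 24, modulation_depth = 0.8,
                      noise_sd = 0.3, seed = 5, ...) {
  synthetic_spec("mi4", n_channels = 4, fs = 64, epoch_duration = 4,
                 trials_per_class = trials_per_class,
                 modulation_depth = modulation_depth, noise_sd = noise_sd,
                 seed = seed, ...)
}

desk_cfg <- function(...) model_config(C = 4, T = 256, Nc = 4, F1 = 8, ...)

# Train one model on one synthetic subject with a train/val/test split;
# returns test accuracy, history, the fitted model and the test set.
desk_run <- function(ablate = "none", subject = 1, seed = subject,
                     spec = desk_spec(), max_epochs = 150, patience = 150,
                     batch_size = 16) {
  ep <- generate_epochs(spec, subject)
  n <- length(ep$labels)
  sp <- mifuse:::stratified_holdout(ep$labels, seq_len(n), 0.25, seed = seed)
  te <- epochs_subset(ep, sp$val)
  sp2 <- mifuse:::stratified_holdout(ep$labels, sp$train, 0.2, seed = seed + 97)
  tr <- epochs_subset(ep, sp2$train)
  va <- epochs_subset(ep, sp2$val)
  st <- zscore_fit(tr)
  tr <- zscore_apply(tr, st); va <- zscore_apply(va, st)
  te <- zscore_apply(te, st)
  cfg <- desk_cfg(ablate = if (identical(ablate, "none")) character(0) else ablate)
  fit <- train_model(init_model(cfg, seed), tr, va,
                     train_config(max_epochs = max_epochs, patience = patience,
                                  batch_size = batch_size, seed = seed))
  ev <- evaluate_model(fit$model, te)
  list(test_accuracy = ev$accuracy, history = fit$history, model = fit$model,
       test = te, norm_stats = st)
}

# One moderately trained model cached for the whole test run (embeddings,
# spectra and prediction tests share it).
.fit_cache <- new.env(parent = emptyenv())
get_trained_fit <- function() {
  if (is.null(.fit_cache$fit)) {
    spec <- desk_spec(trials_per_class = 18)
    ep <- generate_epochs(spec, 1)
    .fit_cache$epochs <- ep
    .fit_cache$spec <- spec
    .fit_cache$fit <- mifuse(ep, config = desk_cfg(),
                             control = train_config(max_epochs = 60,
                                                    patience = 60,
                                                    batch_size = 16, seed = 3))
  }
  list(fit = .fit_cache$fit, epochs = .fit_cache$epochs, spec = .fit_cache$spec)
}

# ---- independent oracles ----------------------------------------------------

# Naive layer normalization (population variance, eps 1e-5), per row.
naive_layernorm <- function(y, gamma, beta, eps = 1e-5) {
  t(apply(y, 1L, function(r) {
    (r - mean(r)) / sqrt(mean((r - mean(r))^2) + eps) * gamma + beta
  }))
}

# Brute-force multi-head attention: layer norm, per-head linear maps,
# scaled dot-product softmax attention, concat, output projection, ELU.
# Everything in explicit loops, no shared code with the implementation.
naive_msa <- function(y, Wq, Wk, Wv, Wo, heads, ln_gamma, ln_beta) {
  F2 <- ncol(y)
  dh <- F2 / heads
  x <- naive_layernorm(y, ln_gamma, ln_beta)
  n <- nrow(x)
  Z <- matrix(0, n, F2)
  for (h in seq_len(heads)) {
    cols <- (h - 1) * dh + seq_len(dh)
    Q <- x %*% Wq[, cols, drop = FALSE]
    K <- x %*% Wk[, cols, drop = FALSE]
    V <- x %*% Wv[, cols, drop = FALSE]
    for (i in seq_len(n)) {
      s <- numeric(n)
      for (j in seq_len(n)) s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(dh)
      p <- exp(s - max(s)); p <- p / sum(p)
      for (j in seq_len(n)) Z[i, cols] <- Z[i, cols] + p[j] * V[j, ]
    }
  }
  out <- Z %*% Wo
  ifelse(out > 0, out, exp(out) - 1)
}

# Brute-force single dilated-causal residual block in evaluation mode
# (batch-norm with running stats mean 0 / var 1, no dropout).
naive_tcn_block <- function(x, W1, W2, Kt, dil, eps = 1e-5) {
  n <- nrow(x); din <- ncol(x); dout <- ncol(W1)
  conv <- function(inp, W) {
    dcin <- ncol(inp)
    out <- matrix(0, n, ncol(W))
    for (t in seq_len(n)) {
      for (j in seq_len(Kt)) {
        src <- t - (Kt - j) * dil
        if (src >= 1) {
          taps <- W[(j - 1) * dcin + seq_len(dcin), , drop = FALSE]
          out[t, ] <- out[t, ] + as.numeric(inp[src, , drop = FALSE] %*% taps)
        }
      }
    }
    out
  }
  act <- function(m) {
    m <- m / sqrt(1 + eps) # eval-mode batch norm, running stats (0, 1)
    ifelse(m > 0, m, exp(m) - 1)
  }
  branch <- act(conv(act(conv(x, W1)), W2))
  x + branch
}

# Expected stage extents of the architecture contract for a configuration.
contract_extents <- function(cfg) {
  mifuse:::expected_extents(cfg)
}
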