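# Architecture contracts: stage shapes, module semantics, causality,
# receptive field arithmetic.

test_that("configuration invariants are enforced", {
  expect_error(model_config(C = 22, T = 1000, Nc = 4, F1 = 3, D = 2),
               "divisible by 4")
  expect_error(model_config(C = 22, T = 1000, Nc = 4, F1 = 6, D = 2,
                            heads = 8), "divisible by heads")
  expect_error(model_config(C = 22, T = 100, Nc = 4), "n_windows")
  expect_error(model_config(C = 22, T = 1000, Nc = 4, ablate = "bogus"),
               "unknown ablation")
  # mff expands to both fusion switches
  cfg <- model_config(C = 22, T = 1000, Nc = 4, ablate = "mff")
  expect_setequal(cfg$ablate, c("feature_fusion", "decision_fusion"))
})

test_that("receptive field size follows the dilated-causal formula", {
  expect_identical(receptive_field_size(4, 2), 19L)
  expect_identical(receptive_field_size(1, 5), 1L)
  expect_identical(receptive_field_size(3, 3), 29L)
  expect_error(receptive_field_size(0, 1), ">= 1")
})

test_that("stage extents follow the contract for several geometries", {
  for (geo in list(c(C = 22, T = 1000, F1 = 32),
                   c(C = 3, T = 1000, F1 = 32),
                   c(C = 4, T = 256, F1 = 8))) {
    cfg <- model_config(C = geo["C"], T = geo["T"], Nc = 4, F1 = geo["F1"])
    tr <- shape_trace(cfg, seed = 1)
    want <- contract_extents(cfg)
    for (i in seq_len(nrow(tr)))
      expect_identical(tr$extent[i], paste(want[[tr$stage[i]]], collapse = ","),
                       info = paste(tr$stage[i], "at C =", geo["C"]))
  }
})

test_that("the spatial convolution collapses channels regardless of channel count", {
  for (C in c(3, 22)) {
    cfg <- model_config(C = C, T = 1000, Nc = 4)
    fm <- sc_forward(matrix(rnorm(C * 1000), C, 1000), init_model(cfg, 1))
    expect_equal(unlist(fm$axes), c(depth = 64, spatial = 1, time = 125))
  }
})

test_that("convolutions carry no bias: zero input gives zero pre-norm activations", {
  co <- mifuse:::conv_time_shared_fwd(matrix(0, 64, 3),
                                      matrix(rnorm(16 * 4), 16, 4))
  expect_true(all(co$out == 0))
  dw <- mifuse:::dwconv_time_fwd(matrix(0, 32, 8), 16, 2,
                                 matrix(rnorm(8 * 8), 8, 8))
  expect_true(all(dw$out == 0))
})

test_that("the separable branches keep depth F2 and single-branch depth matches its filter count", {
  cfg <- tiny_cfg()
  model <- init_model(cfg, 2)
  x <- matrix(rnorm(cfg$C * cfg$T), cfg$C, cfg$T)
  sc <- sc_forward(x, model)
  msc <- msc_forward(sc, model)
  expect_equal(msc$axes$depth, cfg$F2)
  expect_equal(msc$axes$time, cfg$T %/% 64)
  # branch filter counts F2/4 + F2/4 + F2/2 == F2
  fcounts <- vapply(model$params$msc, function(b) ncol(b$Wp), integer(1))
  expect_equal(fcounts, c(cfg$F2 %/% 4L, cfg$F2 %/% 4L, cfg$F2 %/% 2L))
  expect_equal(sum(fcounts), cfg$F2)
})

test_that("attention preserves shape, normalizes rows, and handles n = 1", {
  cfg <- model_config(C = 22, T = 1000, Nc = 4)
  model <- init_model(cfg, 3)
  y <- matrix(rnorm(15 * 64), 15, 64)
  out <- msa_forward(y, model)
  expect_equal(dim(out), c(15, 64))
  for (P in attr(out, "attention"))
    expect_true(all(abs(rowSums(P) - 1) < 1e-6))

  one <- msa_forward(matrix(rnorm(64), 1, 64), model)
  expect_equal(dim(one), c(1, 64))
  expect_equal(attr(one, "attention")[[1]], matrix(1, 1, 1))
  expect_error(msa_forward(y[0, , drop = FALSE], model), "empty")
})

test_that("attention matches the brute-force scaled dot-product oracle", {
  cfg <- model_config(C = 22, T = 1000, Nc = 4, heads = 1, attn_dropout = 0)
  model <- init_model(cfg, 4)
  # hand-set small integer projection weights, single head
  F2 <- cfg$F2
  set.seed(8)
  model$params$attn$Wq <- matrix(sample(-2:2, F2 * F2, TRUE) / 4, F2, F2)
  model$params$attn$Wk <- matrix(sample(-2:2, F2 * F2, TRUE) / 4, F2, F2)
  model$params$attn$Wv <- matrix(sample(-2:2, F2 * F2, TRUE) / 4, F2, F2)
  model$params$attn$Wo <- matrix(sample(-2:2, F2 * F2, TRUE) / 4, F2, F2)
  y <- matrix(rnorm(2 * F2), 2, F2)
  got <- msa_forward(y, model)
  want <- naive_msa(y, model$params$attn$Wq, model$params$attn$Wk,
                    model$params$attn$Wv, model$params$attn$Wo, heads = 1,
                    model$params$ln$gamma, model$params$ln$beta)
  expect_equal(unclass(got), want, ignore_attr = TRUE, tolerance = 1e-12)

  # multi-head agrees too
  cfg8 <- model_config(C = 22, T = 1000, Nc = 4, heads = 8, attn_dropout = 0)
  m8 <- init_model(cfg8, 5)
  y8 <- matrix(rnorm(3 * 64), 3, 64)
  got8 <- msa_forward(y8, m8)
  want8 <- naive_msa(y8, m8$params$attn$Wq, m8$params$attn$Wk,
                     m8$params$attn$Wv, m8$params$attn$Wo, heads = 8,
                     m8$params$ln$gamma, m8$params$ln$beta)
  expect_equal(unclass(got8), want8, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("a TCN residual block matches its brute-force oracle and the RFS precondition holds", {
  cfg <- tiny_cfg(L = 1L, Kt = 4L) # RFS = 7
  model <- init_model(cfg, 6)
  dep <- 2L * cfg$F2
  set.seed(61)
  x <- matrix(rnorm(3 * dep), 3, dep)
  res <- tcn_forward(x, model, return_activations = TRUE)
  want <- naive_tcn_block(x, model$params$tcn[[1]]$W1,
                          model$params$tcn[[1]]$W2, Kt = 4, dil = 1)
  expect_equal(res$activations[[1]], want, tolerance = 1e-10)
  expect_equal(res$out, want[3, ], tolerance = 1e-10)

  # sequences at least as long as the receptive field are rejected
  long <- matrix(rnorm(7 * dep), 7, dep)
  expect_error(tcn_forward(long, model), "receptive field")
})

test_that("TCN activations are causal in every layer", {
  cfg <- model_config(C = 22, T = 1000, Nc = 4, tcn_dropout = 0)
  model <- init_model(cfg, 7)
  dep <- 2L * cfg$F2
  set.seed(31)
  x <- matrix(rnorm(13 * dep), 13, dep)
  base <- tcn_forward(x, model, return_activations = TRUE)$activations
  for (t in 1:13) {
    xp <- x
    xp[t, ] <- xp[t, ] + rnorm(dep)
    pert <- tcn_forward(xp, model, return_activations = TRUE)$activations
    for (l in seq_along(base)) {
      if (t > 1)
        expect_equal(pert[[l]][1:(t - 1), ], base[[l]][1:(t - 1), ],
                     info = sprintf("layer %d, perturbed t = %d", l, t))
      expect_false(isTRUE(all.equal(pert[[l]][t:13, ], base[[l]][t:13, ])))
    }
  }
})

test_that("zeroed TCN branch weights make each block an identity map", {
  cfg <- tiny_cfg(Kt = 3L, L = 1L) # RFS = 5
  model <- init_model(cfg, 8)
  model$params$tcn[[1]]$W1[] <- 0
  model$params$tcn[[1]]$W2[] <- 0
  dep <- 2L * cfg$F2
  x <- matrix(abs(rnorm(3 * dep)), 3, dep)
  expect_equal(tcn_forward(x, model), x[3, ], tolerance = 1e-12)
})

test_that("feature fusion concatenates depths and splits back exactly", {
  a <- matrix(rnorm(15 * 64), 15, 64)
  b <- matrix(rnorm(15 * 64), 15, 64)
  fused <- feature_fusion(a, b)
  expect_equal(dim(fused), c(15, 128))
  expect_equal(fused[, 1:64], a)
  expect_equal(fused[, 65:128], b)
  # zero attention features leave the first half untouched
  z <- feature_fusion(a, b * 0)
  expect_equal(z[, 1:64], a)
  expect_true(all(z[, 65:128] == 0))
  expect_error(feature_fusion(a, b[1:10, ]), "mismatch")
})

test_that("the windowed TCN emits n_windows * 2 * F2 features from shared weights", {
  cfg <- model_config(C = 22, T = 1000, Nc = 4, tcn_dropout = 0)
  model <- init_model(cfg, 9)
  fused <- matrix(rnorm(15 * 128), 15, 128)
  v <- windowed_tcn(fused, model)
  expect_length(v, 3 * 128)
  # each window's output equals a direct single-sequence TCN run
  for (w in 1:3) {
    win <- fused[w:(w + 12), ]
    expect_equal(v[(w - 1) * 128 + 1:128], unname(tcn_forward(win, model)),
                 tolerance = 1e-10)
  }
  # single window configuration
  cfg1 <- model_config(C = 22, T = 1000, Nc = 4, n_windows = 1L,
                       tcn_dropout = 0)
  m1 <- init_model(cfg1, 9)
  expect_length(windowed_tcn(fused, m1), 128)
})

test_that("decision fusion sums logits before the softmax", {
  expect_equal(decision_fusion(rep(0, 4), rep(0, 4)), rep(0.25, 4))
  l <- c(1.2, -0.3, 0.4, 0)
  expect_equal(decision_fusion(l, rep(0, 4)), drop(exp(l) / sum(exp(l))))
  p <- decision_fusion(c(1, 0), c(1, 0))
  expect_equal(p, c(exp(2), 1) / (exp(2) + 1), tolerance = 1e-4)
  expect_equal(round(p, 4), c(0.8808, 0.1192))
  expect_error(decision_fusion(rep(0, 4), rep(0, 3)), "mismatch")
})

test_that("the full forward pass emits a probability simplex point and is deterministic in eval mode", {
  cfg <- tiny_cfg()
  model <- init_model(cfg, 10)
  x <- array(rnorm(5 * cfg$C * cfg$T), c(5, cfg$C, cfg$T))
  out <- model_forward(model, x)
  expect_equal(dim(out$probs), c(5, 3))
  expect_true(all(out$probs > 0))
  expect_true(all(abs(rowSums(out$probs) - 1) < 1e-6))
  out2 <- model_forward(model, x)
  expect_identical(out$probs, out2$probs)
})

test_that("parameter counts are stable, monotone in F1, and independent of window count", {
  cfg <- model_config(C = 22, T = 1000, Nc = 4)
  expect_identical(count_parameters(cfg), count_parameters(cfg))
  big <- model_config(C = 22, T = 1000, Nc = 4, F1 = 64)
  expect_gt(count_parameters(big), count_parameters(cfg))
  w1 <- model_config(C = 22, T = 1000, Nc = 4, n_windows = 1L)
  cp_w1 <- count_parameters(w1)
  cp_w3 <- count_parameters(cfg)
  # shared TCN weights: the only difference is the FC2 input width
  expect_equal(cp_w3 - cp_w1, (3 - 1) * 2 * 64 * 4)
})

test_that("ablation switches change the graph as specified", {
  x <- array(rnorm(2 * 3 * 192), c(2, 3, 192))
  for (ab in c("msc", "msa", "tcn", "feature_fusion", "decision_fusion",
               "mff")) {
    cfg <- tiny_cfg(ablate = ab)
    out <- model_forward(init_model(cfg, 11), x)
    expect_true(all(abs(rowSums(out$probs) - 1) < 1e-6), info = ab)
  }
  # dropped TCN branch leaves only the multi-scale classifier logits
  out_tcn <- model_forward(init_model(tiny_cfg(ablate = "tcn"), 11), x)
  expect_null(out_tcn$logits2)
  expect_equal(out_tcn$logits, out_tcn$logits1)
  # dropped decision fusion scores with the TCN branch only
  out_df <- model_forward(init_model(tiny_cfg(ablate = "decision_fusion"), 11), x)
  expect_null(out_df$logits1)
  expect_equal(out_df$logits, out_df$logits2)
})
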