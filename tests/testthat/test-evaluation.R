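# Metrics, statistical comparison, interpretability exports.

test_that("confusion matrices tally trials exactly", {
  expect_equal(as.matrix(confusion_matrix(c(0, 1), c(0, 1), 2)),
               diag(2), ignore_attr = TRUE)
  expect_equal(as.matrix(confusion_matrix(c(0, 0, 1, 1), c(1, 1, 0, 0), 2)),
               matrix(c(0, 2, 2, 0), 2), ignore_attr = TRUE)
  set.seed(20)
  y <- sample(0:3, 200, TRUE)
  p <- sample(0:3, 200, TRUE)
  cm <- confusion_matrix(y, p, 4)
  expect_equal(sum(cm), 200)
  expect_equal(unname(rowSums(cm)), unname(as.vector(table(factor(y, 0:3)))))
  expect_equal(unname(colSums(cm)), unname(as.vector(table(factor(p, 0:3)))))
  expect_error(confusion_matrix(c(0, 5), c(0, 1), 2), "0, 2")
})

test_that("accuracy is the trace over the total", {
  expect_equal(accuracy(matrix(c(10, 0, 0, 10), 2)), 1.0)
  expect_equal(accuracy(matrix(c(0, 10, 10, 0), 2)), 0.0)
  expect_equal(accuracy(matrix(c(40, 20, 10, 30), 2)), 0.70)
  expect_error(accuracy(matrix(0, 2, 2)), "empty")
})

test_that("Cohen's kappa follows the marginal-agreement formula", {
  expect_equal(cohen_kappa(diag(5) * 7), 1.0)
  cm <- matrix(c(40, 20, 10, 30), 2) # p_a 0.7, p_e 0.5
  expect_equal(cohen_kappa(cm), 0.4, tolerance = 1e-12)
  # invariant under simultaneous row/column permutation
  set.seed(3)
  m <- matrix(rpois(16, 10), 4)
  perm <- sample(4)
  expect_equal(cohen_kappa(m), cohen_kappa(m[perm, perm]), tolerance = 1e-12)
  expect_error(cohen_kappa(matrix(c(5, 0, 0, 0), 2)), "p_e")
})

test_that("kappa of marginal-independent predictions converges to zero", {
  set.seed(77)
  n <- 1e5
  y <- sample(0:3, n, TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
  p <- sample(0:3, n, TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
  expect_lt(abs(cohen_kappa(confusion_matrix(y, p, 4))), 0.01)
})

test_that("kappa agrees with an independent implementation on random matrices", {
  set.seed(13)
  for (i in 1:50) {
    nc <- sample(2:5, 1)
    cm <- matrix(rpois(nc * nc, sample(3:20, 1)), nc)
    diag(cm) <- diag(cm) + sample(0:30, 1) # keep p_e away from 1
    expect_equal(cohen_kappa(cm), e1071::classAgreement(cm)$kappa,
                 tolerance = 1e-10)
  }
})

test_that("the paired Wilcoxon comparison behaves at its boundary cases", {
  a <- c(0.9, 0.85, 0.88, 0.92, 0.87, 0.91, 0.86, 0.9, 0.89)
  b <- a - seq(0.01, 0.09, by = 0.01) # distinct positive paired differences
  res <- wilcoxon_compare(a, b)
  expect_lt(res$p_value, 0.05)
  expect_equal(res$p_value, 2 / 512, tolerance = 1e-10) # exact n = 9 one-sided x 2
  # symmetry of the two-sided test
  expect_equal(wilcoxon_compare(b, a)$p_value, res$p_value)
  # identical inputs degenerate to p = 1 with a warning
  expect_warning(eq <- wilcoxon_compare(a, a), "degenerate")
  expect_equal(eq$p_value, 1)
  expect_error(wilcoxon_compare(a[1:3], b[1:3]), ">= 5")
})

test_that("embeddings are deterministic, finite, and class-separated after training", {
  ctx <- get_trained_fit()
  ep <- zscore_apply(ctx$epochs, ctx$fit$norm_stats)
  emb <- export_embeddings(ctx$fit$model, ep)
  expect_equal(nrow(emb$embeddings), length(ep$labels))
  expect_true(all(is.finite(emb$embeddings)))
  # duplicated trial -> identical rows
  dup <- epochs_subset(ep, c(1, 1))
  e2 <- export_embeddings(ctx$fit$model, dup)
  expect_equal(e2$embeddings[1, ], e2$embeddings[2, ])
  # mean within-class distance below mean between-class distance
  D <- as.matrix(dist(emb$embeddings))
  same <- outer(emb$labels, emb$labels, "==") & upper.tri(D)
  diff <- outer(emb$labels, emb$labels, "!=") & upper.tri(D)
  expect_lt(mean(D[same]), mean(D[diff]))
})

test_that("kernel spectra expose the three branch resolutions", {
  cfg <- desk_cfg()
  model <- init_model(cfg, 5)
  sp <- kernel_spectra(model, fs = 64)
  expect_setequal(unique(sp$branch), 1:3)
  res <- vapply(1:3, function(b) {
    f <- sort(unique(sp$frequency[sp$branch == b]))
    f[2] - f[1]
  }, numeric(1))
  # kernel lengths 8/16/32 -> frequency resolutions in ratio 4:2:1
  expect_equal(res / res[3], c(4, 2, 1))

  # a pure sinusoid kernel peaks at its own bin
  k <- nrow(model$params$msc[[3]]$Wd)
  model$params$msc[[3]]$Wd[, 1] <- sin(2 * pi * 5 * (0:(k - 1)) / k)
  sp2 <- kernel_spectra(model, fs = 64)
  b3 <- sp2[sp2$branch == 3 & sp2$kernel == 1, ]
  expect_equal(which.max(b3$magnitude), 5 + 1)

  # two tones closer than the short branch's resolution: the long branch
  # resolves two peaks, the short branch merges them into one
  two_tone <- function(len) {
    t <- 0:(len - 1)
    sin(2 * pi * 3 * t / 32) + sin(2 * pi * 5 * t / 32)
  }
  model$params$msc[[3]]$Wd[, 2] <- two_tone(32)
  model$params$msc[[1]]$Wd[, 2] <- two_tone(8)
  sp3 <- kernel_spectra(model, fs = 64)
  count_peaks <- function(mag) {
    sum(diff(sign(diff(c(-Inf, mag, -Inf)))) == -2)
  }
  long <- sp3[sp3$branch == 3 & sp3$kernel == 2, "magnitude"]
  short <- sp3[sp3$branch == 1 & sp3$kernel == 2, "magnitude"]
  expect_gte(count_peaks(long), 2)
  expect_equal(count_peaks(short), 1)
})
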