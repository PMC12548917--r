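# Loss, optimization, early stopping, determinism, constraint projection.

tiny_train_set <- function(n = 12, seed = 1) {
  set.seed(seed)
  cfg <- tiny_cfg()
  data <- array(rnorm(n * cfg$C * cfg$T), c(n, cfg$C, cfg$T))
  labels <- rep(0:2, length.out = n)
  # plant a large class-dependent offset so the task is memorizable
  for (i in seq_len(n)) data[i, 1, ] <- data[i, 1, ] + 3 * labels[i]
  list(cfg = cfg, epochs = eeg_epochs(data, labels, fs = 64))
}

test_that("cross-entropy matches closed-form evaluations", {
  expect_equal(cross_entropy_loss(matrix(0, 3, 4), c(0, 1, 3)), log(4),
               tolerance = 1e-12)
  # saturated one-hot logits drive the loss to zero
  big <- matrix(0, 2, 3); big[cbind(1:2, 1:2)] <- 1e6
  expect_lt(cross_entropy_loss(big, c(0, 1)), 1e-9)
  # M = 2, Nc = 2, logits [[1,0],[0,1]], labels (0, 1)
  expect_equal(cross_entropy_loss(rbind(c(1, 0), c(0, 1)), c(0, 1)),
               -log(exp(1) / (exp(1) + 1)), tolerance = 1e-12)
  expect_equal(round(cross_entropy_loss(rbind(c(1, 0), c(0, 1)), c(0, 1)), 4),
               0.3133)
  expect_error(cross_entropy_loss(matrix(0, 2, 3), c(0, 5)), "label")
})

test_that("the loss gradient is the softmax minus the one-hot target", {
  logits <- matrix(rnorm(8), 2, 4)
  y <- c(2L, 0L)
  g <- mifuse:::cross_entropy_grad(logits, y)
  eps <- 1e-6
  for (i in 1:2) for (j in 1:4) {
    lp <- logits; lp[i, j] <- lp[i, j] + eps
    lm <- logits; lm[i, j] <- lm[i, j] - eps
    fd <- (cross_entropy_loss(lp, y) - cross_entropy_loss(lm, y)) / (2 * eps)
    expect_equal(g[i, j], fd, tolerance = 1e-6)
  }
})

test_that("a single repeated batch is memorized to near-zero loss", {
  ts <- tiny_train_set()
  fit <- train_model(init_model(ts$cfg, 1), ts$epochs, ts$epochs,
                     train_config(max_epochs = 400, patience = 400,
                                  batch_size = 12, seed = 1))
  expect_lt(min(fit$history$step_loss), 0.01)
})

test_that("early stopping halts exactly patience evaluations after the best one", {
  # a loss sequence that improves, then plateaus at its optimum
  losses <- c(1.0, 0.6, 0.3, 0.30005, 0.2999, 0.31, 0.32, 0.33, 0.3, 0.35)
  st <- NULL
  stopped_at <- NA_integer_
  for (i in seq_along(losses)) {
    st <- mifuse:::early_stop_update(st, losses[i], patience = 4,
                                     min_delta = 1e-4)
    if (st$stop) { stopped_at <- i; break }
  }
  # improvements smaller than min_delta (evals 4, 5) do not reset patience
  expect_equal(st$best_eval, 3L)
  expect_equal(stopped_at, 7L) # exactly patience = 4 evaluations after 3
  expect_equal(st$best_loss, 0.3)

  # the integration path: training that plateaus stops patience epochs
  # after its best validation epoch
  ts <- tiny_train_set()
  fit <- train_model(init_model(ts$cfg, 1), ts$epochs, ts$epochs,
                     train_config(max_epochs = 400, patience = 8,
                                  batch_size = 12, seed = 1))
  h <- fit$history
  if (h$stopped_epoch < 400)
    expect_equal(h$stopped_epoch - h$best_epoch, 8L)
  expect_equal(h$val_loss[h$best_epoch], min(h$val_loss))
})

test_that("training with a fixed seed is bit-reproducible", {
  ts <- tiny_train_set()
  tc <- train_config(max_epochs = 4, patience = 10, batch_size = 6, seed = 7)
  a <- train_model(init_model(ts$cfg, 2), ts$epochs, ts$epochs, tc)
  b <- train_model(init_model(ts$cfg, 2), ts$epochs, ts$epochs, tc)
  expect_identical(a$history$step_loss, b$history$step_loss)
  expect_identical(a$history$val_loss, b$history$val_loss)
  expect_identical(a$model$params, b$model$params)
})

test_that("early stopping returns the weights of the best validation epoch", {
  ts <- tiny_train_set()
  fit <- train_model(init_model(ts$cfg, 3), ts$epochs, ts$epochs,
                     train_config(max_epochs = 15, patience = 15,
                                  batch_size = 6, seed = 2))
  h <- fit$history
  expect_equal(h$val_loss[h$best_epoch], min(h$val_loss), tolerance = 1e-12)
  # re-evaluating the returned model reproduces the best recorded loss
  ev <- evaluate_model(fit$model, ts$epochs)
  expect_equal(ev$loss, h$val_loss[h$best_epoch], tolerance = 1e-10)
})

test_that("max-norm constraints hold after every optimization stage", {
  ts <- tiny_train_set()
  fit <- train_model(init_model(ts$cfg, 4), ts$epochs, ts$epochs,
                     train_config(max_epochs = 5, patience = 10,
                                  batch_size = 6, seed = 3))
  p <- fit$model$params
  cfg <- ts$cfg
  expect_lte(max(sqrt(colSums(p$fc1$W^2))), cfg$fc_max_norm + 1e-8)
  expect_lte(max(sqrt(colSums(p$fc2$W^2))), cfg$fc_max_norm + 1e-8)
  for (blk in p$tcn)
    for (wn in c("W1", "W2"))
      expect_lte(max(sqrt(colSums(blk[[wn]]^2))), cfg$tcn_max_norm + 1e-8)
  for (wn in c("Wq", "Wk", "Wv", "Wo"))
    expect_lte(max(sqrt(colSums(p$attn[[wn]]^2))), cfg$msa_max_norm + 1e-8)
})

test_that("degenerate training inputs raise informative errors", {
  ts <- tiny_train_set()
  empty <- epochs_subset(ts$epochs, integer(0))
  expect_error(train_model(init_model(ts$cfg, 1), empty, ts$epochs,
                           train_config(max_epochs = 1)), "insufficient")
  expect_error(train_config(learning_rate = -1))
  expect_error(train_config(patience = 0))
})
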