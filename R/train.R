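#' Training configuration
#'
#' Optimizer and early-stopping hyperparameters: Adam with learning rate
#' 0.001, beta1 = 0.9, beta2 = 0.99 and weight decay 0.001; training halts
#' once the validation loss has not improved by more than \code{min_delta}
#' for \code{patience} consecutive per-epoch evaluations, and the weights
#' from the best validation point are returned.
#'
#' @param learning_rate Adam step size.
#' @param beta1,beta2 Adam moment decay rates.
#' @param weight_decay L2 penalty added to every gradient.
#' @param batch_size mini-batch size M.
#' @param max_epochs hard cap on training epochs.
#' @param patience early-stopping patience, in validation evaluations (one
#'   per epoch).
#' @param min_delta smallest absolute validation-loss decrease that counts as
#'   an improvement.
#' @param seed seed controlling initialization, shuffling and dropout.
#' @param deterministic if \code{TRUE} (default) the whole run is a pure
#'   function of the seed.
#' @return An object of class \code{"train_config"}.
#' @export
train_config <- function(learning_rate = 0.001, beta1 = 0.9, beta2 = 0.99,
                         weight_decay = 0.001, batch_size = 64L,
                         max_epochs = 500L, patience = 300L,
                         min_delta = 1e-4, seed = 1L, deterministic = TRUE) {
  stopifnot(learning_rate > 0, beta1 >= 0, beta1 < 1, beta2 >= 0, beta2 < 1,
            patience >= 1)
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), min_delta = min_delta,
                 seed = as.integer(seed),
                 deterministic = isTRUE(deterministic)),
            class = "train_config")
}

#' Cross-entropy loss on logits
#'
#' Mean over the batch of \code{-log softmax(x)[label]}: the standard
#' multiclass cross-entropy applied to the fused pre-softmax logits.
#'
#' @param logits \code{M x Nc} matrix of pre-softmax scores.
#' @param labels integer vector of true classes in \code{[0, Nc)}.
#' @return Scalar loss.
#' @export
#' @examples
#' cross_entropy_loss(matrix(0, 2, 4), c(0, 3)) # log(4)
cross_entropy_loss <- function(logits, labels) {
  logits <- rbind(logits)
  labels <- as.integer(labels)
  if (any(labels < 0L) || any(labels >= ncol(logits)))
    stop_config("label out of range [0, %d)", ncol(logits))
  mx <- apply(logits, 1L, max)
  lse <- mx + log(rowSums(exp(logits - mx)))
  true_logit <- logits[cbind(seq_len(nrow(logits)), labels + 1L)]
  mean(lse - true_logit)
}

# gradient of mean cross-entropy w.r.t. logits
cross_entropy_grad <- function(logits, labels) {
  P <- softmax_rows(logits)
  M <- nrow(P)
  P[cbind(seq_len(M), as.integer(labels) + 1L)] <-
    P[cbind(seq_len(M), as.integer(labels) + 1L)] - 1
  P / M
}

# ---- parameter-tree utilities ------------------------------------------------

# Paths mix character names and (for unnamed lists) numeric-string indices.
path_key <- function(tree, nm) {
  if (is.null(names(tree)) && grepl("^[0-9]+$", nm)) as.integer(nm) else nm
}

tree_get <- function(tree, path) {
  for (nm in path) tree <- tree[[path_key(tree, nm)]]
  tree
}

tree_set <- function(tree, path, value) {
  key <- path_key(tree, path[1L])
  if (length(path) == 1L) tree[[key]] <- value
  else tree[[key]] <- tree_set(tree[[key]], path[-1L], value)
  tree
}

adam_init <- function(params) {
  leaves <- trainable_leaves(params)
  list(t = 0L,
       paths = lapply(leaves, `[[`, "path"),
       m = lapply(leaves, function(l) l$value * 0),
       v = lapply(leaves, function(l) l$value * 0))
}

adam_step <- function(params, grads, state, tcfg, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - tcfg$beta1^state$t
  bc2 <- 1 - tcfg$beta2^state$t
  for (i in seq_along(state$paths)) {
    path <- state$paths[[i]]
    w <- tree_get(params, path)
    g <- tree_get(grads, path)
    if (is.null(g)) next
    g <- g + tcfg$weight_decay * w
    state$m[[i]] <- tcfg$beta1 * state$m[[i]] + (1 - tcfg$beta1) * g
    state$v[[i]] <- tcfg$beta2 * state$v[[i]] + (1 - tcfg$beta2) * g * g
    w <- w - tcfg$learning_rate * (state$m[[i]] / bc1) /
      (sqrt(state$v[[i]] / bc2) + eps)
    params <- tree_set(params, path, w)
  }
  list(params = params, state = state)
}

# Re-project weights onto their max-norm balls (per incoming-weight vector,
# i.e. per column): fully-connected layers and the decision-fusion map at
# fc_max_norm, every TCN kernel at tcn_max_norm, attention projections at
# msa_max_norm.
clamp_cols <- function(W, max_norm) {
  nrm <- sqrt(colSums(W^2))
  s <- pmin(1, max_norm / pmax(nrm, 1e-12))
  scale_cols(W, s)
}

project_max_norms <- function(params, cfg) {
  for (nm in c("fc1", "fc2", "fuse"))
    if (!is.null(params[[nm]]))
      params[[nm]]$W <- clamp_cols(params[[nm]]$W, cfg$fc_max_norm)
  if (!is.null(params$tcn))
    for (i in seq_along(params$tcn)) {
      for (wn in c("W1", "W2", "Wr"))
        if (!is.null(params$tcn[[i]][[wn]]))
          params$tcn[[i]][[wn]] <- clamp_cols(params$tcn[[i]][[wn]],
                                              cfg$tcn_max_norm)
    }
  if (!is.null(params$attn))
    for (wn in c("Wq", "Wk", "Wv", "Wo"))
      params$attn[[wn]] <- clamp_cols(params$attn[[wn]], cfg$msa_max_norm)
  params
}

# Early-stopping bookkeeping: a new loss counts as an improvement only if it
# undercuts the best loss by more than min_delta; `stop` turns true after
# `patience` consecutive evaluations without one.
early_stop_update <- function(state, loss, patience, min_delta) {
  if (is.null(state))
    state <- list(best_loss = Inf, best_eval = 0L, since = 0L,
                  eval = 0L, stop = FALSE)
  state$eval <- state$eval + 1L
  if (loss < state$best_loss - min_delta) {
    state$best_loss <- loss
    state$best_eval <- state$eval
    state$since <- 0L
  } else {
    state$since <- state$since + 1L
    if (state$since >= patience) state$stop <- TRUE
  }
  state
}

# ---- training loop -----------------------------------------------------------

#' Train a decoder with Adam and early stopping
#'
#' Mini-batch Adam with weight decay on the cross-entropy of the fused
#' logits; max-norm constraints are re-projected after every step. The
#' validation set is evaluated once per epoch; training stops after
#' \code{patience} evaluations without a loss improvement greater than
#' \code{min_delta}, and the weights from the best validation epoch are
#' returned. With a fixed seed the run is bit-reproducible.
#'
#' @param model an initialized \code{\link{init_model}}; its weights are the
#'   starting point.
#' @param train,val normalized \code{eeg_epochs} (normalize both with
#'   statistics fitted on \code{train} only).
#' @param tcfg a \code{\link{train_config}}.
#' @param verbose print per-epoch progress.
#' @return List with \code{model} (weights from the best validation epoch)
#'   and \code{history}: per-step training loss, per-epoch validation
#'   loss/accuracy, \code{best_epoch}, \code{stopped_epoch}.
#' @export
train_model <- function(model, train, val, tcfg = train_config(),
                        verbose = FALSE) {
  stopifnot(inherits(model, "mifuse_model"), inherits(tcfg, "train_config"))
  if (length(train$labels) == 0L || length(val$labels) == 0L)
    stop_config("insufficient data: empty training or validation set")
  cfg <- model$cfg
  n <- length(train$labels)
  opt <- adam_init(model$params)
  best_params <- model$params
  es <- NULL
  hist <- list(step_loss = numeric(0), val_loss = numeric(0),
               val_acc = numeric(0))
  stopped <- tcfg$max_epochs
  has_old_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old_seed) old_seed <- get(".Random.seed", envir = globalenv())
  set.seed(mix_seed(tcfg$seed, 1009L))
  on.exit(if (has_old_seed) assign(".Random.seed", old_seed, envir = globalenv()))
  for (epoch in seq_len(tcfg$max_epochs)) {
    ord <- sample.int(n)
    nb <- ceiling(n / tcfg$batch_size)
    for (b in seq_len(nb)) {
      idx <- ord[((b - 1L) * tcfg$batch_size + 1L):min(b * tcfg$batch_size, n)]
      xb <- train$data[idx, , , drop = FALSE]
      yb <- train$labels[idx]
      fwd <- net_fwd(model, xb, training = TRUE, keep_cache = TRUE)
      model$params <- fwd$bn_updated
      loss <- cross_entropy_loss(fwd$logits, yb)
      if (!is.finite(loss))
        stop_config("training diverged (non-finite loss) at step %d",
                    length(hist$step_loss) + 1L)
      hist$step_loss <- c(hist$step_loss, loss)
      grads <- net_bwd(model, fwd, cross_entropy_grad(fwd$logits, yb))
      upd <- adam_step(model$params, grads, opt, tcfg)
      opt <- upd$state
      model$params <- project_max_norms(upd$params, cfg)
    }
    ev <- evaluate_model(model, val)
    hist$val_loss <- c(hist$val_loss, ev$loss)
    hist$val_acc <- c(hist$val_acc, ev$accuracy)
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f  acc %.3f",
                      epoch, loss, ev$loss, ev$accuracy))
    es <- early_stop_update(es, ev$loss, tcfg$patience, tcfg$min_delta)
    if (es$best_eval == epoch) best_params <- model$params
    if (es$stop) {
      stopped <- epoch
      break
    }
  }
  model$params <- best_params
  hist$best_epoch <- es$best_eval
  hist$stopped_epoch <- stopped
  list(model = model, history = hist)
}

#' Score a model on an epoch set
#'
#' Evaluation-mode forward pass (no dropout, running batch-norm statistics).
#'
#' @param model a trained model.
#' @param epochs normalized \code{eeg_epochs}.
#' @return List with \code{loss}, \code{accuracy}, \code{predicted} (0-based
#'   class per trial) and \code{probs}.
#' @export
evaluate_model <- function(model, epochs) {
  fwd <- net_fwd(model, epochs$data, training = FALSE, keep_cache = FALSE)
  pred <- max.col(fwd$probs) - 1L
  list(loss = cross_entropy_loss(fwd$logits, epochs$labels),
       accuracy = mean(pred == epochs$labels),
       predicted = pred, probs = fwd$probs)
}
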