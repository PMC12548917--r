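#' Fit a multi-scale fusion decoder to labelled EEG epochs
#'
#' The main entry point of the package: takes an epoched, labelled EEG set,
#' carves out a stratified validation subset, fits per-channel Z-score
#' normalization on the training part only, trains the hybrid
#' convolution/attention/TCN network with Adam and early stopping, and
#' returns a fitted-model object with the usual methods
#' (\code{print}, \code{summary}, \code{coef}, \code{predict}, \code{plot}).
#'
#' @param epochs an \code{\link{eeg_epochs}} set.
#' @param config a \code{\link{model_config}}; defaults to the standard
#'   architecture sized to the data.
#' @param control a \code{\link{train_config}}.
#' @param val_fraction fraction of trials (stratified) held out for early
#'   stopping.
#' @param seed seed for the split, initialization and training; overrides
#'   \code{control$seed}.
#' @param verbose print training progress.
#' @return An object of class \code{"mifuse"}.
#' @export
#' @examples
#' \donttest{
#' spec <- synthetic_spec("mi4", n_channels = 8, fs = 128,
#'                        epoch_duration = 2, trials_per_class = 12,
#'                        modulation_depth = 0.8, noise_sd = 0.3)
#' ep <- generate_epochs(spec, 1)
#' fit <- mifuse(ep, config = model_config(8, 256, 4, F1 = 8),
#'               control = train_config(max_epochs = 30, patience = 10,
#'                                      batch_size = 16))
#' predict(fit, ep)[1:5]
#' }
mifuse <- function(epochs, config = NULL, control = train_config(),
                   val_fraction = 0.2, seed = control$seed, verbose = FALSE) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  d <- dim(epochs$data)
  if (is.null(config))
    config <- model_config(C = d[2], T = d[3], Nc = epochs$n_classes)
  control$seed <- as.integer(seed)
  sp <- stratified_holdout(epochs$labels, seq_len(d[1]),
                           fraction = val_fraction, seed = seed)
  tr <- epochs_subset(epochs, sp$train)
  va <- epochs_subset(epochs, sp$val)
  stats <- zscore_fit(tr)
  fit <- train_model(init_model(config, seed = seed),
                     zscore_apply(tr, stats), zscore_apply(va, stats),
                     control, verbose = verbose)
  structure(list(model = fit$model, config = config, control = control,
                 norm_stats = stats, history = fit$history,
                 n_train = length(sp$train), n_val = length(sp$val),
                 seed = as.integer(seed), call = match.call()),
            class = "mifuse")
}

#' @export
print.mifuse <- function(x, ...) {
  h <- x$history
  cat("Multi-scale fusion EEG decoder\n")
  cat(sprintf("  %d channels x %d samples -> %d classes; %d parameters\n",
              x$config$C, x$config$T, x$config$Nc, count_parameters(x$model)))
  cat(sprintf("  trained %d epoch(s) on %d trials (best epoch %d, val acc %.3f)\n",
              h$stopped_epoch, x$n_train, h$best_epoch,
              h$val_acc[max(h$best_epoch, 1)]))
  invisible(x)
}

#' @export
summary.mifuse <- function(object, ...) {
  h <- object$history
  out <- list(config = object$config,
              n_parameters = count_parameters(object$model),
              n_train = object$n_train, n_val = object$n_val,
              best_epoch = h$best_epoch, stopped_epoch = h$stopped_epoch,
              best_val_loss = if (h$best_epoch > 0) h$val_loss[h$best_epoch] else NA,
              best_val_accuracy = if (h$best_epoch > 0) h$val_acc[h$best_epoch] else NA)
  class(out) <- "summary.mifuse"
  out
}

#' @export
print.summary.mifuse <- function(x, ...) {
  print(x$config)
  cat(sprintf("  parameters: %d\n  train/val trials: %d/%d\n", x$n_parameters,
              x$n_train, x$n_val))
  cat(sprintf("  best epoch %d of %d: val loss %.4f, val accuracy %.3f\n",
              x$best_epoch, x$stopped_epoch, x$best_val_loss,
              x$best_val_accuracy))
  invisible(x)
}

#' @export
coef.mifuse <- function(object, ...) object$model$params

#' Predict classes or probabilities for new epochs
#'
#' Applies the stored normalization statistics (fitted on the training data)
#' and runs an evaluation-mode forward pass.
#'
#' @param object a fitted \code{"mifuse"}.
#' @param newdata an \code{eeg_epochs} set with matching geometry.
#' @param type \code{"class"} (0-based labels) or \code{"prob"}.
#' @param ... unused.
#' @return Integer vector or \code{N x Nc} probability matrix.
#' @export
predict.mifuse <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  stopifnot(inherits(newdata, "eeg_epochs"))
  x <- zscore_apply(newdata, object$norm_stats)
  fwd <- net_fwd(object$model, x$data, training = FALSE, keep_cache = FALSE)
  if (type == "prob") fwd$probs else max.col(fwd$probs) - 1L
}

#' Plot training history
#'
#' Training loss per step and validation loss/accuracy per epoch, with the
#' best-validation epoch marked.
#'
#' @param x a fitted \code{"mifuse"}.
#' @param ... passed to \code{plot}.
#' @export
plot.mifuse <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(h$step_loss, type = "l", xlab = "step", ylab = "training loss", ...)
  plot(h$val_loss, type = "l", xlab = "epoch", ylab = "validation loss", ...)
  graphics::abline(v = h$best_epoch, lty = 2)
  invisible(x)
}
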