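# Experiment drivers: within-subject k-fold, cross-subject LOSO, ablation.

# Train/evaluate one fold: fits normalization on the training indices only,
# carves a stratified validation subset out of them for early stopping, and
# scores the held-out test indices.
run_fold <- function(epochs, train_idx, test_idx, mcfg, tcfg, seed) {
  sp <- stratified_holdout(epochs$labels, train_idx, fraction = 0.2,
                           seed = seed)
  tr <- epochs_subset(epochs, sp$train)
  va <- epochs_subset(epochs, sp$val)
  te <- epochs_subset(epochs, test_idx)
  stats <- zscore_fit(tr)
  tr <- zscore_apply(tr, stats); va <- zscore_apply(va, stats)
  te <- zscore_apply(te, stats)
  model <- init_model(mcfg, seed = seed)
  tcfg$seed <- seed
  fit <- train_model(model, tr, va, tcfg)
  if (length(test_idx) > 0L) {
    ev <- evaluate_model(fit$model, te)
    cm <- confusion_matrix(te$labels, ev$predicted, mcfg$Nc)
  } else {
    ev <- list(accuracy = NA_real_)
    cm <- NULL
  }
  list(accuracy = ev$accuracy, cm = cm, history = fit$history,
       model = fit$model, norm_stats = stats,
       indices = list(train = sp$train, val = sp$val, test = test_idx))
}

#' Within-subject k-fold evaluation protocol
#'
#' For every subject: stratified k folds, one model trained per fold (with a
#' validation subset carved from the fold's training part for early
#' stopping), tested on the held-out part. Per-subject accuracy is the
#' unweighted mean over folds.
#'
#' @param cohort a list of \code{eeg_epochs}, one per subject.
#' @param mcfg a \code{\link{model_config}}.
#' @param tcfg a \code{\link{train_config}}.
#' @param k folds per subject (default 5).
#' @param seed protocol seed; per-fold seeds derive from it.
#' @return An \code{"eval_report"}: per-subject accuracies, mean, sd, pooled
#'   and subject-averaged Cohen's kappa, per-subject confusion matrices.
#' @export
run_within_subject <- function(cohort, mcfg, tcfg, k = 5L, seed = 1L) {
  if (inherits(cohort, "eeg_epochs")) cohort <- list(cohort)
  acc <- numeric(length(cohort))
  cms <- vector("list", length(cohort))
  ids <- vapply(cohort, `[[`, character(1), "subject_id")
  for (s in seq_along(cohort)) {
    ep <- cohort[[s]]
    plan <- make_within_subject_folds(ep, k = k, seed = mix_seed(seed, s))
    fold_acc <- numeric(k)
    cm <- matrix(0L, mcfg$Nc, mcfg$Nc)
    for (f in seq_len(k)) {
      res <- run_fold(ep, plan$folds[[f]]$train, plan$folds[[f]]$test,
                      mcfg, tcfg, seed = mix_seed(seed, s, f))
      fold_acc[f] <- res$accuracy
      cm <- cm + res$cm
    }
    acc[s] <- mean(fold_acc)
    cms[[s]] <- structure(cm, class = c("confusion_matrix", "matrix"))
  }
  eval_report("within_subject", ids, acc, cms, seed)
}

#' Cross-subject leave-one-subject-out protocol
#'
#' One model per held-out subject, trained on the pooled remaining subjects
#' (a stratified 20% of the pooled trials serves as validation for early
#' stopping) and tested on every trial of the held-out subject.
#'
#' @inheritParams run_within_subject
#' @return An \code{"eval_report"} with one row per held-out subject.
#' @export
run_cross_subject <- function(cohort, mcfg, tcfg, seed = 1L) {
  plan <- make_loso_folds(cohort)
  ids <- vapply(cohort, `[[`, character(1), "subject_id")
  acc <- numeric(length(cohort))
  cms <- vector("list", length(cohort))
  for (f in seq_along(plan$folds)) {
    fold <- plan$folds[[f]]
    pooled <- epochs_bind(cohort[fold$train])
    res <- run_fold(pooled, seq_along(pooled$labels), integer(0), mcfg, tcfg,
                    seed = mix_seed(seed, 5000L, f))
    te <- zscore_apply(cohort[[fold$test]], res$norm_stats)
    ev <- evaluate_model(res$model, te)
    acc[f] <- ev$accuracy
    cms[[f]] <- confusion_matrix(te$labels, ev$predicted, mcfg$Nc)
  }
  eval_report("loso", ids, acc, cms, seed)
}

#' Ablation experiment
#'
#' Re-runs the within-subject protocol with one architecture block bypassed:
#' \code{"msc"} (branches replaced by identity), \code{"msa"} (multi-scale
#' features fed to the fusion twice), \code{"tcn"} (TCN branch dropped),
#' \code{"feature_fusion"} (TCN sees attention output only),
#' \code{"decision_fusion"} (TCN logits only), or \code{"mff"} (both fusions
#' off). \code{"none"} reproduces the unablated protocol.
#'
#' @inheritParams run_within_subject
#' @param removed_block which block to remove.
#' @return An \code{"eval_report"} tagged with the removed block.
#' @export
run_ablation <- function(cohort, mcfg, tcfg, removed_block = "none",
                         k = 5L, seed = 1L) {
  removed_block <- match.arg(removed_block,
                             c("none", "msc", "msa", "tcn", "feature_fusion",
                               "decision_fusion", "mff"))
  acfg <- mcfg
  if (removed_block != "none") {
    acfg$ablate <- normalize_ablate(union(mcfg$ablate, removed_block))
    validate_model_config(acfg)
  }
  rep <- run_within_subject(cohort, acfg, tcfg, k = k, seed = seed)
  rep$removed_block <- removed_block
  rep
}

# ---- report container --------------------------------------------------------

eval_report <- function(protocol, subject_ids, accuracies, cms, seed) {
  pooled <- Reduce(`+`, lapply(cms, as.matrix))
  structure(list(
    protocol = protocol,
    subjects = data.frame(subject = subject_ids, accuracy = accuracies,
                          stringsAsFactors = FALSE),
    mean_accuracy = mean(accuracies),
    sd_accuracy = stats::sd(accuracies),
    kappa_pooled = cohen_kappa(pooled),
    kappa_by_subject = vapply(cms, function(c) {
      k <- try(cohen_kappa(c), silent = TRUE)
      if (inherits(k, "try-error")) NA_real_ else k
    }, numeric(1)),
    confusion = cms, pooled_confusion = pooled, seed = seed),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> protocol: %s%s, seed %d\n", x$protocol,
              if (!is.null(x$removed_block) && x$removed_block != "none")
                paste0(" (removed: ", x$removed_block, ")") else "", x$seed))
  wide <- sprintf("%.4f", x$subjects$accuracy)
  names(wide) <- x$subjects$subject
  print(wide, quote = FALSE)
  cat(sprintf("  Avg %.4f  Std %.4f  K-score (pooled) %.4f  K-score (mean) %.4f\n",
              x$mean_accuracy, x$sd_accuracy, x$kappa_pooled,
              mean(x$kappa_by_subject, na.rm = TRUE)))
  invisible(x)
}

#' Write an evaluation report as CSV + JSON
#'
#' Emits \code{<prefix>.csv} (per-subject rows plus an Avg/K-score/Std
#' summary row), \code{<prefix>.json} (full report), and one confusion
#' matrix CSV per subject.
#'
#' @param report an \code{"eval_report"}.
#' @param prefix output path prefix.
#' @return The prefix, invisibly.
#' @export
write_report <- function(report, prefix) {
  df <- report$subjects
  df$kappa <- report$kappa_by_subject
  summary_row <- data.frame(subject = "Avg", accuracy = report$mean_accuracy,
                            kappa = report$kappa_pooled)
  utils::write.csv(rbind(df, summary_row), paste0(prefix, ".csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(protocol = report$protocol,
         removed_block = report$removed_block %||% "none",
         subjects = df, mean_accuracy = report$mean_accuracy,
         sd_accuracy = report$sd_accuracy,
         kappa_pooled = report$kappa_pooled, seed = report$seed),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  for (i in seq_along(report$confusion))
    utils::write.csv(as.matrix(report$confusion[[i]]),
                     sprintf("%s_cm_%s.csv", prefix, report$subjects$subject[i]))
  invisible(prefix)
}
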