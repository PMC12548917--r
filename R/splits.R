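#' Stratified k-fold split plan for within-subject evaluation
#'
#' Shuffles trials deterministically (given \code{seed}), then deals each
#' class's trials round-robin over \code{k} folds so that every fold's label
#' histogram deviates from the global proportions by at most one trial per
#' class. Each fold's held-out part doubles as the validation set for early
#' stopping when no separate validation split is carved out.
#'
#' @param epochs an \code{eeg_epochs} object.
#' @param k number of folds (>= 2).
#' @param seed integer seed controlling the shuffle.
#' @return An object of class \code{"split_plan"}: list with \code{scheme =
#'   "within_subject_kfold"} and \code{folds}, a list of \code{k} lists each
#'   holding integer vectors \code{train} and \code{test} (1-based trial
#'   indices).
#' @export
make_within_subject_folds <- function(epochs, k = 5L, seed = 1L) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  k <- as.integer(k)
  if (k < 2L) stop_config("k must be >= 2")
  n <- length(epochs$labels)
  counts <- table(epochs$labels)
  if (any(counts < k))
    stop_config("insufficient data: class %s has %d trials but k = %d",
                names(counts)[which.min(counts)], min(counts), k)
  fold_of <- integer(n)
  with_seed(mix_seed(seed, 7L), {
    classes <- sort(unique(epochs$labels))
    for (ci in seq_along(classes)) {
      idx <- sample(which(epochs$labels == classes[ci]))
      # rotate the starting fold per class so fold sizes stay balanced
      fold_of[idx] <- (seq_along(idx) - 2L + ci) %% k + 1L
    }
  })
  folds <- lapply(seq_len(k), function(f)
    list(train = which(fold_of != f), test = which(fold_of == f)))
  plan <- structure(list(scheme = "within_subject_kfold", folds = folds,
                         n = n, seed = seed), class = "split_plan")
  validate_split_plan(plan)
  plan
}

#' Leave-one-subject-out split plan
#'
#' One fold per subject: that subject's trials are the test set, everyone
#' else's are the training pool.
#'
#' @param cohort a list of \code{eeg_epochs}, one per subject.
#' @return A \code{"split_plan"} with \code{scheme = "loso"}; each fold holds
#'   \code{train}/\code{test} subject positions (indices into \code{cohort})
#'   and the held-out \code{subject_id}.
#' @export
make_loso_folds <- function(cohort) {
  if (length(cohort) < 2L) stop_config("LOSO needs at least 2 subjects")
  ids <- vapply(cohort, `[[`, character(1), "subject_id")
  if (anyDuplicated(ids))
    stop_config("duplicate subject_id in cohort: %s", ids[duplicated(ids)][1])
  folds <- lapply(seq_along(cohort), function(i)
    list(train = setdiff(seq_along(cohort), i), test = i,
         subject_id = ids[i]))
  structure(list(scheme = "loso", folds = folds, n = length(cohort)),
            class = "split_plan")
}

# Disjointness / exhaustiveness assertions shared by both schemes.
validate_split_plan <- function(plan) {
  test_union <- sort(unlist(lapply(plan$folds, `[[`, "test")))
  if (any(duplicated(test_union)) || !identical(test_union, seq_len(plan$n)))
    stop_config("split plan is not an exhaustive disjoint partition")
  for (f in plan$folds)
    if (length(intersect(f$train, f$test)) > 0L)
      stop_config("split plan has overlapping train/test indices")
  invisible(plan)
}

#' @export
print.split_plan <- function(x, ...) {
  sizes <- vapply(x$folds, function(f) length(f$test), integer(1))
  cat(sprintf("<split_plan> %s: %d folds, test sizes {%s}\n",
              x$scheme, length(x$folds), paste(sizes, collapse = ",")))
  invisible(x)
}

# Carve a stratified validation subset out of a training index vector
# (used for early stopping inside LOSO training pools).
stratified_holdout <- function(labels, idx, fraction = 0.2, seed = 1L) {
  val <- integer(0)
  with_seed(mix_seed(seed, 13L), {
    for (cls in unique(labels[idx])) {
      pool <- idx[labels[idx] == cls]
      n_val <- max(1L, floor(length(pool) * fraction))
      val <- c(val, sample(pool, n_val))
    }
  })
  list(train = setdiff(idx, val), val = sort(val))
}
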