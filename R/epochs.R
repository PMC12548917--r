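#' Labelled EEG epoch set
#'
#' Container for epoched multichannel EEG: a numeric array of dimension
#' \code{n_trials x channels x samples} plus integer class labels and
#' recording metadata. This is the exchange object every other function in
#' the package consumes and produces.
#'
#' @param data numeric array, \code{n_trials x C x T}. All values must be
#'   finite.
#' @param labels integer vector of per-trial class labels in
#'   \code{[0, n_classes)}.
#' @param fs sampling frequency in Hz.
#' @param channel_names character vector of length \code{C}; defaults to
#'   \code{"ch1"...}.
#' @param subject_id identifier of the recorded subject.
#' @param n_classes number of classes; defaults to \code{max(labels) + 1}.
#'
#' @return An object of class \code{"eeg_epochs"}: a list with elements
#'   \code{data}, \code{labels}, \code{fs}, \code{channel_names},
#'   \code{subject_id}, \code{n_classes}.
#' @export
#' @examples
#' x <- eeg_epochs(array(rnorm(2 * 3 * 64), c(2, 3, 64)),
#'                 labels = c(0, 1), fs = 250)
#' print(x)
eeg_epochs <- function(data, labels, fs, channel_names = NULL,
                       subject_id = "S01", n_classes = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_config("`data` must be a 3-d array (n_trials x channels x samples)")
  storage.mode(data) <- "double"
  if (any(!is.finite(data)))
    stop_config("`data` contains non-finite values (NaN/Inf)")
  n_trials <- dim(data)[1L]
  C <- dim(data)[2L]
  T <- dim(data)[3L]
  if (C < 1L) stop_config("need at least one channel")
  if (T < 64L)
    stop_config("epochs must have >= 64 samples (two pooling stages of width 8), got %d", T)
  labels <- as.integer(labels)
  if (length(labels) != n_trials)
    stop_config("length(labels) == %d but data has %d trials",
                length(labels), n_trials)
  if (any(labels < 0L)) stop_config("labels must be >= 0")
  if (is.null(n_classes)) n_classes <- max(labels) + 1L
  n_classes <- as.integer(n_classes)
  if (any(labels >= n_classes))
    stop_config("label %d out of range for %d classes",
                max(labels), n_classes)
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(C))
  if (length(channel_names) != C)
    stop_config("channel_names must have length %d", C)
  structure(
    list(data = data, labels = labels, fs = as.numeric(fs),
         channel_names = as.character(channel_names),
         subject_id = as.character(subject_id), n_classes = n_classes),
    class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> subject %s: %d trials x %d channels x %d samples @ %g Hz\n",
              x$subject_id, d[1], d[2], d[3], x$fs))
  tab <- table(factor(x$labels, levels = 0:(x$n_classes - 1L)))
  cat("  labels:", paste(sprintf("%s:%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' Subset an epoch set by trial index
#'
#' @param x an \code{eeg_epochs} object.
#' @param idx integer vector of trial indices (1-based).
#' @return An \code{eeg_epochs} with only the selected trials.
#' @export
epochs_subset <- function(x, idx) {
  eeg_epochs(x$data[idx, , , drop = FALSE], x$labels[idx], x$fs,
             x$channel_names, x$subject_id, x$n_classes)
}

#' Concatenate epoch sets along the trial axis
#'
#' Used to pool subjects for cross-subject training. All sets must agree on
#' channel count, sample count, sampling rate and class count.
#'
#' @param sets a list of \code{eeg_epochs}.
#' @param subject_id identifier for the pooled set.
#' @return A pooled \code{eeg_epochs}; an attribute \code{"trial_subject"}
#'   records the originating subject of every trial.
#' @export
epochs_bind <- function(sets, subject_id = "pooled") {
  stopifnot(length(sets) >= 1L)
  dims <- vapply(sets, function(s) dim(s$data)[2:3], numeric(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop_config("cannot pool epoch sets with differing channel/sample counts")
  if (length(unique(vapply(sets, `[[`, numeric(1), "fs"))) != 1L)
    stop_config("cannot pool epoch sets with differing sampling rates")
  data <- do.call(abind3, lapply(sets, `[[`, "data"))
  labels <- unlist(lapply(sets, `[[`, "labels"))
  out <- eeg_epochs(data, labels, sets[[1]]$fs, sets[[1]]$channel_names,
                    subject_id, max(vapply(sets, `[[`, integer(1), "n_classes")))
  attr(out, "trial_subject") <-
    unlist(lapply(sets, function(s) rep(s$subject_id, length(s$labels))))
  out
}

# rbind for 3-d arrays along the first (trial) axis
abind3 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  n <- sum(vapply(xs, function(x) dim(x)[1L], integer(1)))
  out <- array(0, c(n, d[2], d[3]))
  at <- 0L
  for (x in xs) {
    k <- dim(x)[1L]
    out[at + seq_len(k), , ] <- x
    at <- at + k
  }
  out
}
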