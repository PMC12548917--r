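#' Write an epoch set to a single-file fixture container
#'
#' Serializes the epoch array, labels and metadata losslessly into one file
#' (R native serialization, version 3). Companion of
#' \code{\link{read_fixture}}.
#'
#' @param epochs an \code{eeg_epochs} object.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_fixture <- function(epochs, path) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  obj <- list(format = "mifuse-epochs", version = 1L,
              data = epochs$data, labels = epochs$labels, fs = epochs$fs,
              channel_names = epochs$channel_names,
              subject_id = epochs$subject_id, n_classes = epochs$n_classes)
  saveRDS(obj, path, version = 3)
  invisible(path)
}

#' Read an epoch set from a fixture container
#'
#' @param path file written by \code{\link{write_fixture}}.
#' @return The reconstructed, validated \code{eeg_epochs}.
#' @export
read_fixture <- function(path) {
  if (!file.exists(path)) stop_config("fixture file not found: %s", path)
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "mifuse-epochs"))
    stop_config("not an epoch fixture container: %s", path)
  for (field in c("data", "labels", "fs", "channel_names", "subject_id",
                  "n_classes"))
    if (is.null(obj[[field]]))
      stop_config("fixture is missing required field `%s`", field)
  if (any(obj$labels >= obj$n_classes))
    stop_config("fixture labels exceed declared n_classes = %d", obj$n_classes)
  eeg_epochs(obj$data, obj$labels, obj$fs, obj$channel_names,
             obj$subject_id, obj$n_classes)
}

#' Load cue-locked epochs from a GDF recording (optional)
#'
#' Thin wrapper over the MNE biosignal reader (invoked through the system
#' \code{python}); cuts fixed-length epochs from cue onset, keeping EEG
#' channels only. Requires a Python installation with \code{mne} on the
#' \code{PATH}; everything else in the package works without it, and all
#' tests use fixtures instead.
#'
#' @param path a GDF file.
#' @param event_codes integer vector of cue annotation codes, mapped in order
#'   to classes \code{0, 1, ...}.
#' @param epoch_window length of the epoch cut from each cue, in seconds.
#' @param python python executable to use.
#' @return An \code{eeg_epochs}. Trials whose window overruns the recording
#'   end are skipped with a warning reporting the count.
#' @export
load_gdf_epochs <- function(path, event_codes = c(769L, 770L, 771L, 772L),
                            epoch_window = 4.0, python = "python") {
  if (!file.exists(path)) stop_config("cannot read GDF file: %s", path)
  if (Sys.which(python) == "")
    stop_config("GDF support needs a python executable with mne installed")
  tmp <- tempfile("gdf2flat")
  script <- system.file("python", "gdf_to_flat.py", package = "mifuse")
  if (script == "") stop_config("converter script missing from installation")
  status <- system2(python, c(script, shQuote(path), shQuote(tmp),
                              paste(event_codes, collapse = ","),
                              format(epoch_window)),
                    stdout = TRUE, stderr = TRUE)
  code <- attr(status, "status") %||% 0L
  if (code != 0L)
    stop_config("GDF conversion failed:\n%s", paste(status, collapse = "\n"))
  hdr <- jsonlite::fromJSON(paste0(tmp, ".json"))
  n <- hdr$n_trials; C <- hdr$n_channels; T <- hdr$n_samples
  raw <- readBin(paste0(tmp, ".f32"), what = "numeric", size = 4L,
                 n = n * C * T, endian = "little")
  unlink(paste0(tmp, c(".json", ".f32")))
  if (hdr$n_skipped > 0)
    warning(sprintf("%d trial(s) skipped: epoch window exceeded recording end",
                    hdr$n_skipped))
  # python writes trials x channels x samples, C-order (samples fastest)
  arr <- aperm(array(raw, c(T, C, n)), c(3, 2, 1))
  eeg_epochs(arr, hdr$labels, hdr$fs, hdr$channel_names, hdr$subject_id,
             length(event_codes))
}
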