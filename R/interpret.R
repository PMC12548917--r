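#' Export penultimate-layer embeddings
#'
#' Returns, per trial, the concatenated inputs of the two branch classifiers
#' (the flattened multi-scale features feeding FC1 and the windowed TCN
#' vector feeding FC2) — the representation just before decision fusion.
#' Deterministic in evaluation mode; intended for external 2-D embedding
#' (e.g. t-SNE) of class structure.
#'
#' @param model a trained model.
#' @param epochs normalized \code{eeg_epochs}.
#' @return List with \code{embeddings} (\code{n_trials x p} matrix) and
#'   \code{labels}.
#' @export
export_embeddings <- function(model, epochs) {
  fwd <- net_fwd(model, epochs$data, training = FALSE, keep_cache = FALSE)
  emb <- cbind(fwd$fc1_in, fwd$fc2_in)
  if (is.null(emb))
    stop_config("model exposes no penultimate features (both branches ablated?)")
  list(embeddings = emb, labels = epochs$labels)
}

#' Frequency response of the multi-branch convolution kernels
#'
#' Discrete Fourier transform magnitude of every first-layer depthwise kernel
#' of the three separable branches, evaluated at the post-pooling sampling
#' rate \code{fs / pool_width}. Kernels of length 8/16/32 span 4x/2x/1x
#' coarser frequency grids, which is what lets the longer branches resolve
#' narrower bands.
#'
#' @param model a model (trained or freshly initialized).
#' @param fs the recording sampling rate in Hz (the kernels act on the
#'   once-pooled sequence, so their rate is \code{fs / pool_width}).
#' @return Long-format \code{data.frame(branch, kernel, frequency, magnitude)}
#'   with one row per kernel and non-negative frequency bin.
#' @export
kernel_spectra <- function(model, fs = 250) {
  p <- model$params
  if (is.null(p$msc)) stop_config("model has no multi-branch kernels (ablated?)")
  fs_pool <- fs / model$cfg$pool_width
  out <- list()
  for (b in seq_along(p$msc)) {
    W <- p$msc[[b]]$Wd                       # (k, depth)
    k <- nrow(W)
    nbin <- k %/% 2L + 1L
    freqs <- (seq_len(nbin) - 1L) * fs_pool / k
    for (j in seq_len(ncol(W))) {
      mag <- Mod(stats::fft(W[, j]))[seq_len(nbin)]
      out[[length(out) + 1L]] <- data.frame(
        branch = b, kernel = j, frequency = freqs, magnitude = mag)
    }
  }
  do.call(rbind, out)
}
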