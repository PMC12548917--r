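#' Fit per-channel Z-score normalization statistics
#'
#' Computes, for every channel, the mean and variance over all training
#' trials and time points. The returned statistics are meant to be applied
#' unchanged to validation and test data so that no information leaks from
#' held-out trials into the normalization.
#'
#' @param train an \code{eeg_epochs} training set.
#' @return An object of class \code{"norm_stats"}: list with numeric vectors
#'   \code{mean} and \code{variance} (one entry per channel, population
#'   variance) and the channel count.
#' @export
#' @examples
#' x <- eeg_epochs(array(rnorm(4 * 2 * 64), c(4, 2, 64)), rep(0:1, 2), 250)
#' s <- zscore_fit(x)
#' y <- zscore_apply(x, s)
zscore_fit <- function(train) {
  stopifnot(inherits(train, "eeg_epochs"))
  d <- dim(train$data)
  if (d[1L] == 0L) stop_config("cannot fit normalization on an empty set")
  m <- numeric(d[2L]); v <- numeric(d[2L])
  for (c in seq_len(d[2L])) {
    xc <- train$data[, c, ]
    m[c] <- mean(xc)
    v[c] <- mean((xc - m[c])^2)
    if (v[c] <= 0)
      stop_config("degenerate channel %d (\"%s\"): zero variance in training data",
                  c, train$channel_names[c])
  }
  structure(list(mean = m, variance = v, n_channels = d[2L]),
            class = "norm_stats")
}

#' Apply Z-score normalization statistics
#'
#' Standardizes each channel with statistics fitted by \code{\link{zscore_fit}}.
#' The default divides by the standard deviation (conventional Z-scoring);
#' \code{denominator = "variance"} divides by the variance instead, for
#' comparison with formulations that write the denominator as \eqn{\delta^2}.
#'
#' @param x an \code{eeg_epochs} object.
#' @param stats a \code{"norm_stats"} object from \code{\link{zscore_fit}}.
#' @param denominator \code{"sd"} (default) or \code{"variance"}.
#' @return The normalized \code{eeg_epochs}, same shape.
#' @export
zscore_apply <- function(x, stats, denominator = c("sd", "variance")) {
  stopifnot(inherits(x, "eeg_epochs"), inherits(stats, "norm_stats"))
  denominator <- match.arg(denominator)
  d <- dim(x$data)
  if (d[2L] != stats$n_channels)
    stop_config("channel-count mismatch: data has %d channels, stats %d",
                d[2L], stats$n_channels)
  den <- if (denominator == "sd") sqrt(stats$variance) else stats$variance
  out <- x$data
  for (c in seq_len(d[2L]))
    out[, c, ] <- (out[, c, ] - stats$mean[c]) / den[c]
  x$data <- out
  x
}

#' @export
print.norm_stats <- function(x, ...) {
  cat(sprintf("<norm_stats> %d channels; mean range [%.3g, %.3g], sd range [%.3g, %.3g]\n",
              x$n_channels, min(x$mean), max(x$mean),
              min(sqrt(x$variance)), max(sqrt(x$variance))))
  invisible(x)
}
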