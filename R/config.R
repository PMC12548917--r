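#' Network architecture configuration
#'
#' Collects every architecture hyperparameter of the decoder in one validated
#' object: the spatiotemporal convolution (temporal filter count \code{F1},
#' depth multiplier \code{D}, temporal kernel width, pooling width), the
#' multi-branch separable convolution kernel sizes, the attention head count
#' and dropout, the temporal convolutional network (kernel size \code{Kt},
#' residual block count \code{L}), the number of sliding TCN windows, and the
#' max-norm constraints applied during optimization. \code{F2 = D * F1} is
#' derived.
#'
#' @param C number of EEG channels.
#' @param T number of samples per epoch.
#' @param Nc number of classes.
#' @param F1 temporal filter count (default 32).
#' @param D depth multiplier (default 2); \code{F2 = D * F1} must be
#'   divisible by 4 (branch filter counts) and by \code{heads}.
#' @param temporal_kernel temporal convolution width in samples (default 16;
#'   32 matches an alternative reading of the architecture description).
#' @param pool_width average-pooling width, applied twice (default 8).
#' @param msc_kernels kernel widths of the three separable branches.
#' @param heads attention head count (default 8).
#' @param attn_dropout dropout rate inside attention (default 0.3).
#' @param conv_dropout dropout rate after the pooling stages (default 0.5).
#' @param Kt TCN kernel size (default 4).
#' @param L TCN residual block count (default 2).
#' @param tcn_dropout dropout inside TCN blocks (default 0.5).
#' @param n_windows number of overlapping sliding windows fed to the shared
#'   TCN (default 3, giving a fused vector of length \code{3 * 2 * F2}).
#' @param fc_max_norm max norm of each fully-connected unit's incoming
#'   weights (default 0.25).
#' @param tcn_max_norm max norm of each TCN filter (default 0.5).
#' @param msa_max_norm max norm of attention projection columns (default
#'   0.25).
#' @param msa_residual add a residual connection around the attention block
#'   (default \code{FALSE}).
#' @param fusion \code{"sum"} (default): decision fusion adds the two branch
#'   logit vectors before the softmax; \code{"concat"}: concatenates them and
#'   applies a learned linear map to \code{Nc}.
#' @param ablate character vector of blocks to bypass: any of \code{"msc"},
#'   \code{"msa"}, \code{"tcn"}, \code{"feature_fusion"},
#'   \code{"decision_fusion"}, \code{"mff"} (= both fusions).
#' @return An object of class \code{"model_config"}.
#' @export
#' @examples
#' cfg <- model_config(C = 22, T = 1000, Nc = 4)
#' cfg$F2
#' receptive_field_size(cfg$Kt, cfg$L)
model_config <- function(C, T, Nc, F1 = 32L, D = 2L, temporal_kernel = 16L,
                         pool_width = 8L, msc_kernels = c(8L, 16L, 32L),
                         heads = 8L, attn_dropout = 0.3, conv_dropout = 0.5,
                         Kt = 4L, L = 2L, tcn_dropout = 0.5, n_windows = 3L,
                         fc_max_norm = 0.25, tcn_max_norm = 0.5,
                         msa_max_norm = 0.25, msa_residual = FALSE,
                         fusion = c("sum", "concat"), ablate = character(0)) {
  fusion <- match.arg(fusion)
  F2 <- as.integer(D) * as.integer(F1)
  cfg <- structure(list(
    C = as.integer(C), T = as.integer(T), Nc = as.integer(Nc),
    F1 = as.integer(F1), D = as.integer(D), F2 = F2,
    temporal_kernel = as.integer(temporal_kernel),
    pool_width = as.integer(pool_width),
    msc_kernels = as.integer(msc_kernels), heads = as.integer(heads),
    attn_dropout = attn_dropout, conv_dropout = conv_dropout,
    Kt = as.integer(Kt), L = as.integer(L), tcn_dropout = tcn_dropout,
    n_windows = as.integer(n_windows), fc_max_norm = fc_max_norm,
    tcn_max_norm = tcn_max_norm, msa_max_norm = msa_max_norm,
    msa_residual = isTRUE(msa_residual), fusion = fusion,
    ablate = normalize_ablate(ablate)), class = "model_config")
  validate_model_config(cfg)
  cfg
}

normalize_ablate <- function(ablate) {
  known <- c("msc", "msa", "tcn", "feature_fusion", "decision_fusion", "mff")
  ablate <- setdiff(unique(as.character(ablate)), "none")
  bad <- setdiff(ablate, known)
  if (length(bad) > 0L)
    stop_config("unknown ablation switch \"%s\" (known: %s)",
                bad[1], paste(known, collapse = ", "))
  if ("mff" %in% ablate)
    ablate <- unique(c(setdiff(ablate, "mff"), "feature_fusion", "decision_fusion"))
  ablate
}

validate_model_config <- function(cfg) {
  if (cfg$Nc < 2L) stop_config("Nc must be >= 2")
  if (cfg$F2 != cfg$D * cfg$F1) stop_config("F2 must equal D * F1")
  if (cfg$F2 %% 4L != 0L)
    stop_config("F2 = %d must be divisible by 4 (branch filter counts F2/4, F2/4, F2/2)",
                cfg$F2)
  if (cfg$F2 %% cfg$heads != 0L)
    stop_config("F2 = %d must be divisible by heads = %d", cfg$F2, cfg$heads)
  t2 <- (cfg$T %/% cfg$pool_width) %/% cfg$pool_width
  if (t2 < cfg$n_windows)
    stop_config("T = %d leaves only %d post-pooling steps; need >= n_windows = %d",
                cfg$T, t2, cfg$n_windows)
  win_len <- t2 - cfg$n_windows + 1L
  rfs <- receptive_field_size(cfg$Kt, cfg$L)
  if (rfs <= win_len)
    stop_config(paste0("receptive field size %d (= 1 + 2(Kt-1)(2^L - 1)) must ",
                       "exceed the TCN window length %d"), rfs, win_len)
  invisible(cfg)
}

#' Receptive field size of the dilated causal TCN
#'
#' For a stack of \code{L} residual blocks, each holding two dilated causal
#' convolutions of kernel size \code{Kt} with dilation doubling per block,
#' the receptive field is \code{1 + 2 * (Kt - 1) * (2^L - 1)} time steps.
#' It must exceed the input sequence length for the final element of the TCN
#' output to see the whole sequence.
#'
#' @param Kt kernel size (>= 1).
#' @param L residual block count (>= 1).
#' @return Integer receptive field size in time steps.
#' @export
#' @examples
#' receptive_field_size(4, 2) # 19
receptive_field_size <- function(Kt, L) {
  if (Kt < 1 || L < 1) stop_config("Kt and L must be >= 1")
  as.integer(1 + 2 * (Kt - 1) * (2^L - 1))
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("<model_config> C=%d T=%d Nc=%d | F1=%d D=%d F2=%d | kernels t=%d msc=(%s) | heads=%d | TCN Kt=%d L=%d windows=%d\n",
              x$C, x$T, x$Nc, x$F1, x$D, x$F2, x$temporal_kernel,
              paste(x$msc_kernels, collapse = ","), x$heads, x$Kt, x$L,
              x$n_windows))
  if (length(x$ablate) > 0L)
    cat("  ablated:", paste(x$ablate, collapse = ", "), "\n")
  invisible(x)
}
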