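# Internal helpers: deterministic seed derivation and small numeric utilities.

# 32-bit mixing of integer counters into a seed in [1, 2^31 - 2].
# Gives each (subject, trial) its own reproducible stream independent of
# generation order. FNV-style multiply/xor carried out in double precision,
# reduced mod 2^31 - 1 (all intermediates stay below 2^53, so exact).
mix_seed <- function(...) {
  counters <- c(...)
  m <- 2147483647 # 2^31 - 1
  h <- 216613626
  for (v in counters) {
    v <- as.numeric(v) %% m
    h <- (h * 31 + v + 1) %% m
    h <- (h * 2654435761) %% m
  }
  as.integer(h %% (m - 1) + 1)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Multiply column j of M by s[j] / add s[j] to column j (compiled kernels).
scale_cols <- function(M, s) cpp_scale_cols(M, s)

add_cols <- function(M, s) cpp_add_cols(M, s)

# Row-wise softmax with max-shift for stability.
softmax_rows <- function(M) cpp_softmax_rows(M)

elu <- function(x) cpp_elu(x)

# Derivative of ELU expressed through its output (exp(x) = y + 1 for x <= 0).
elu_grad_from_output <- function(y) {
  out <- y
  pos <- y > 0
  out[pos] <- 1
  out[!pos] <- y[!pos] + 1
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(sprintf(...), call. = FALSE)
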