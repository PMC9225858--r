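# Shared internal helpers: seeded evaluation, reflection padding, rotation.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so library code never perturbs user
# simulations.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic per-slice seed derived from a base seed and an index; kept
# within the 32-bit signed integer range.
derive_seed <- function(seed, index) {
  m <- 2147483587
  as.integer((((as.numeric(seed) %% m) * 48271) %% m + as.numeric(index) * 20011) %% m)
}

# Map an out-of-range 1-based index into 1..n by symmetric (half-sample)
# reflection: ..., 2, 1 | 1, 2, ..., n | n, n-1, ...
reflect_index <- function(idx, n) {
  if (n == 1L) return(rep(1L, length(idx)))
  period <- 2L * n
  idx <- ((idx - 1L) %% period + period) %% period  # 0 .. 2n-1
  ifelse(idx < n, idx + 1L, period - idx)
}

# Pad a matrix by symmetric reflection on all sides.
reflect_pad <- function(m, pad) {
  if (pad == 0L) return(m)
  ri <- reflect_index(seq(1L - pad, nrow(m) + pad), nrow(m))
  ci <- reflect_index(seq(1L - pad, ncol(m) + pad), ncol(m))
  m[ri, ci, drop = FALSE]
}

# Rotate a matrix 90 degrees counter-clockwise; k applications give k*90.
rot90 <- function(m, k = 1L) {
  k <- ((k %% 4L) + 4L) %% 4L
  for (i in seq_len(k)) m <- t(m)[ncol(m):1L, , drop = FALSE]
  m
}

is_binary <- function(x) all(x %in% c(0, 1))

`%||%` <- function(a, b) if (is.null(a)) b else a
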