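# Internal numerical helpers shared across modules.

# Cholesky with jitter escalation: start at 1e-10 on the diagonal and multiply
# by 10 up to 1e-6 before giving up. Matrices built from trees or Matern
# kernels are PSD in exact arithmetic but can lose that numerically.
chol_safe <- function(M, max_jitter = 1e-6) {
  jitter <- 0
  repeat {
    L <- tryCatch(chol(M + diag(jitter, nrow(M))), error = function(e) NULL)
    if (!is.null(L)) return(L)
    jitter <- if (jitter == 0) 1e-10 else jitter * 10
    if (jitter > max_jitter) {
      abort("matrix is not positive definite even after jitter up to 1e-6")
    }
  }
}

# Solve M x = b via an upper-triangular Cholesky factor R (M = R'R).
chol_solve <- function(R, b) {
  backsolve(R, backsolve(R, b, transpose = TRUE))
}

# Deterministic sub-seed derivation so independent random streams can be
# spawned from one user-facing seed without sharing state. Kept below 2^31.
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  bytes <- utf8ToInt(key)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483629
  as.integer(h + 1)
}

check_binary <- function(x, arg = "trait") {
  if (anyNA(x)) abort(sprintf("%s contains NA values", arg))
  if (!all(x %in% c(0, 1))) abort(sprintf("%s must contain only 0/1 values", arg))
  invisible(x)
}

# Exact-count thresholding of a continuous liability vector: the top k values
# (ties broken by rank order, which is measure-zero for continuous draws)
# become 1 so the realised prevalence is exactly k / n.
threshold_at_count <- function(liability, k) {
  n <- length(liability)
  out <- numeric(n)
  if (k > 0) out[order(liability, decreasing = TRUE)[seq_len(k)]] <- 1
  out
}
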