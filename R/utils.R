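`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  expr
}

# Derive a stream of child seeds from one master seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_input <- function(...) stop(..., call. = FALSE)

symmetrize <- function(M) (M + t(M)) / 2

is_symmetric_tol <- function(M, tol = 1e-10) {
  is.matrix(M) && nrow(M) == ncol(M) && max(abs(M - t(M))) <= tol * max(1, max(abs(M)))
}

# Largest eigenvalue of crossprod(X) by power iteration (avoids a p x p eigen).
spectral_norm_sq <- function(X, iter = 50L, tol = 1e-8) {
  p <- ncol(X)
  if (p == 0L) return(0)
  v <- rep(1 / sqrt(p), p)
  lam <- 0
  for (k in seq_len(iter)) {
    w <- crossprod(X, X %*% v)
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(0)
    v_new <- as.numeric(w / nw)
    if (abs(nw - lam) <= tol * max(1, nw)) {
      lam <- nw
      break
    }
    lam <- nw
    v <- v_new
  }
  lam
}
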