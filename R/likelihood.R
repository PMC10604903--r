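# Simultaneous diagonalization of (Cg, Ce): find A with A Ce A' = I and
# A Cg A' = diag(d).  Then V_i = s_i Cg + Ce has inverse A' diag(1/(1+s_i d)) A
# and log-determinant sum(log1p(s_i d)) + log|Ce|.  All likelihood code runs
# through this transform; nothing ever forms an nq x nq matrix.
.trait_transform <- function(Cg, Ce, jitter_warn = TRUE) {
  q <- nrow(Ce)
  Lc <- tryCatch(t(chol(Ce)), error = function(e) NULL)
  if (is.null(Lc)) {
    if (jitter_warn)
      warning("residual covariance not positive definite; adding 1e-8 jitter")
    Lc <- t(chol(Ce + (1e-8 + 1e-8 * mean(diag(Ce))) * diag(q)))
  }
  Linv <- forwardsolve(Lc, diag(q))
  M <- symmetrize(Linv %*% Cg %*% t(Linv))
  ed <- eigen(M, symmetric = TRUE)
  A <- t(ed$vectors) %*% Linv
  list(A = A, Ainv = solve(A), d = pmax(ed$values, 0),
       logdet_ce = 2 * sum(log(diag(Lc))))
}

# Per-block weights w_ij = 1/(1 + s_i d_j), an n x q matrix.
.block_weights <- function(s, d) 1 / (1 + outer(s, d))

#' Rotate data into the kinship eigenbasis
#'
#' Forms `Ytil = U'Y` and `Xtil = U'[1, X]` (a trait-shared intercept
#' column is always prepended to the fixed design). After rotation the
#' rows of `Ytil` are independent `q`-variate normals with covariance
#' `V_i = s_i Cg + Ce`.
#'
#' @param eig a `kinship_eigen` from [eigendecompose_kinship()].
#' @param traits a [trait_matrix()] (or numeric matrix).
#' @param genotypes a [genotype_matrix()] (or numeric matrix).
#' @param intercept prepend an intercept column (default `TRUE`).
#' @return a `rotated_dataset`: list with `Ytil`, `Xtil`, eigenvalues `s`,
#'   and label bookkeeping.
#' @export
rotate <- function(eig, traits, genotypes, intercept = TRUE) {
  Y <- as.matrix(unclass(traits))
  X <- as.matrix(unclass(genotypes))
  n <- nrow(Y)
  if (nrow(X) != n || nrow(eig$U) != n)
    stop_input("dimension mismatch between traits (", n, "), genotypes (",
               nrow(X), ") and kinship (", nrow(eig$U), ")")
  if (intercept) X <- cbind(`(Intercept)` = 1, X)
  Ut <- t(eig$U)
  structure(list(Ytil = Ut %*% Y, Xtil = Ut %*% X, s = eig$s,
                 intercept = intercept,
                 trait_names = colnames(Y), effect_names = colnames(X)),
            class = "rotated_dataset")
}

# Shared internals: residual-based pieces of the block likelihood.
.resid_rot <- function(rot, B) {
  B <- as.matrix(B)
  if (nrow(B) != ncol(rot$Xtil) || ncol(B) != ncol(rot$Ytil))
    stop_input("effect matrix must be ", ncol(rot$Xtil), " x ", ncol(rot$Ytil))
  rot$Ytil - rot$Xtil %*% B
}

.nll_from_resid <- function(R, s, tt) {
  n <- nrow(R); q <- ncol(R)
  W <- .block_weights(s, tt$d)
  Rt <- R %*% t(tt$A)
  0.5 * (n * q * log(2 * pi) + sum(log1p(outer(s, tt$d))) +
           n * tt$logdet_ce + sum(Rt^2 * W))
}

#' Negative log-likelihood of the multi-trait mixed model
#'
#' Evaluates `-log L` of `vec(Y) ~ N(vec(XB), Cg (x) K + Ce (x) I)` in the
#' kinship eigenbasis, as a sum over `n` independent `q`-dimensional
#' Gaussian blocks with covariance `V_i = s_i Cg + Ce`. Identical (to
#' numerical precision) to the dense `nq`-dimensional Gaussian likelihood.
#'
#' @param rot a `rotated_dataset` from [rotate()].
#' @param B effect matrix (`ncol(Xtil) x q`, intercept row first when the
#'   rotation carries an intercept).
#' @param cov a [covariance_pair()].
#' @return scalar negative log-likelihood (nats).
#' @export
negative_log_likelihood <- function(rot, B, cov) {
  tt <- .trait_transform(cov$Cg, cov$Ce)
  if (any(!is.finite(tt$d)))
    stop_input("singular within-block covariance")
  .nll_from_resid(.resid_rot(rot, B), rot$s, tt)
}

#' Gradient of the negative log-likelihood in the effects
#'
#' Returns `d(-LL)/dB = -Xtil' (R V^{-1})` where row `i` of `(R V^{-1})`
#' is `r_i V_i^{-1}` and `R = Ytil - Xtil B`.
#'
#' @inheritParams negative_log_likelihood
#' @return matrix of the same shape as `B`.
#' @export
gradient_wrt_effects <- function(rot, B, cov) {
  tt <- .trait_transform(cov$Cg, cov$Ce)
  R <- .resid_rot(rot, B)
  W <- .block_weights(rot$s, tt$d)
  Rt <- R %*% t(tt$A)
  -crossprod(rot$Xtil, (Rt * W) %*% tt$A)
}

#' Gradients of the negative log-likelihood in the covariances
#'
#' `d(-LL)/dCg = 1/2 sum_i s_i (V_i^{-1} - V_i^{-1} r_i' r_i V_i^{-1})`,
#' and the same with `s_i` replaced by 1 for `Ce`; both symmetrized.
#'
#' @inheritParams negative_log_likelihood
#' @return list with `q x q` components `Cg` and `Ce`.
#' @export
gradient_wrt_covariances <- function(rot, B, cov) {
  tt <- .trait_transform(cov$Cg, cov$Ce)
  R <- .resid_rot(rot, B)
  s <- rot$s
  W <- .block_weights(s, tt$d)
  Rt <- R %*% t(tt$A)
  Rw <- Rt * W
  Gg <- 0.5 * t(tt$A) %*% (diag(colSums(W * s), ncol(W)) - crossprod(Rw, Rw * s)) %*% tt$A
  Ge <- 0.5 * t(tt$A) %*% (diag(colSums(W), ncol(W)) - crossprod(Rw)) %*% tt$A
  list(Cg = symmetrize(Gg), Ce = symmetrize(Ge))
}

#' Exact generalized least squares for a subset of fixed effects
#'
#' Solves the GLS problem for the selected design columns (the intercept
#' column is always included and listed first), all other effects held at
#' zero, under block covariance `V_i = s_i Cg + Ce`. Also returns the
#' sampling covariance of `vec(B_hat)` (columns of `B_hat` stacked).
#'
#' @param rot a `rotated_dataset` (built with `intercept = TRUE`).
#' @param cov a [covariance_pair()].
#' @param columns indices of `Xtil` columns to estimate, or marker names;
#'   defaults to all columns. The intercept column is added if absent.
#' @return list with `effects` (`k x q`) and `vcov` (`kq x kq`).
#' @export
gls_effects <- function(rot, cov, columns = NULL) {
  Xt <- rot$Xtil
  q <- ncol(rot$Ytil)
  if (is.null(columns)) columns <- seq_len(ncol(Xt))
  if (is.character(columns)) columns <- match(columns, rot$effect_names)
  if (rot$intercept) columns <- union(1L, columns)
  k <- length(columns)
  if (k >= nrow(Xt))
    stop_input("more coefficients than observations in GLS")
  Xs <- Xt[, columns, drop = FALSE]
  tt <- .trait_transform(cov$Cg, cov$Ce)
  W <- .block_weights(rot$s, tt$d)
  Ys <- rot$Ytil %*% t(tt$A)
  Bstar <- matrix(0, k, q)
  Cblocks <- vector("list", q)
  for (j in seq_len(q)) {
    w <- W[, j]
    XtWX <- crossprod(Xs, Xs * w)
    cn <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(cn) || any(diag(cn) < sqrt(.Machine$double.eps) * max(diag(cn))))
      stop_input("rank-deficient design in GLS (selected columns are collinear)")
    Bstar[, j] <- backsolve(cn, backsolve(cn, crossprod(Xs, w * Ys[, j]),
                                          transpose = TRUE))
    Cblocks[[j]] <- chol2inv(cn)
  }
  Bhat <- Bstar %*% t(tt$Ainv)
  # Cov(vec(Bhat)) = (Ainv (x) I_k) blockdiag(Cblocks) (Ainv' (x) I_k)
  V <- matrix(0, k * q, k * q)
  for (j in seq_len(q)) for (l in seq_len(q)) {
    blk <- matrix(0, k, k)
    for (m in seq_len(q))
      blk <- blk + tt$Ainv[j, m] * tt$Ainv[l, m] * Cblocks[[m]]
    V[((j - 1) * k + 1):(j * k), ((l - 1) * k + 1):(l * k)] <- blk
  }
  rownames(Bhat) <- rot$effect_names[columns]
  colnames(Bhat) <- rot$trait_names
  list(effects = Bhat, vcov = V, columns = columns)
}
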