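#' VanRaden genomic relationship matrix
#'
#' Computes `K = W W' / (2 * sum_j p_j (1 - p_j))` where `W = X - 2p` is
#' the allele-frequency-centred genotype matrix and `p_j` the per-marker
#' alternative-allele frequency estimated from the data. Negative
#' eigenvalues from rounding are clamped to zero so the result is positive
#' semi-definite.
#'
#' @param genotypes a raw-coded [genotype_matrix()].
#' @return a [kinship_matrix()].
#' @export
compute_vanraden_kinship <- function(genotypes) {
  if (geno_coding(genotypes) != "raw012")
    stop_input("VanRaden kinship needs raw 0/1/2 genotypes")
  X <- unclass(genotypes)
  p <- attr(genotypes, "allele_freqs") %||% (colMeans(X) / 2)
  mono <- p <= 0 | p >= 1
  if (any(mono))
    stop_input("monomorphic marker(s) with zero denominator term: ",
               paste(utils::head(colnames(X)[mono], 5), collapse = ", "))
  W <- sweep(X, 2, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  K <- tcrossprod(W) / denom
  K <- symmetrize(K)
  ev <- eigen(K, symmetric = TRUE)
  if (min(ev$values) < -1e-6)
    warning("kinship eigenvalue ", format(min(ev$values)),
            " clamped to zero (beyond numerical noise)")
  if (min(ev$values) < 0) {
    lam <- pmax(ev$values, 0)
    K <- symmetrize(ev$vectors %*% (lam * t(ev$vectors)))
    dimnames(K) <- list(rownames(X), rownames(X))
  }
  kinship_matrix(K, individual_ids = rownames(X))
}

#' Standardize genotype columns
#'
#' Centres each marker to mean zero and scales to unit population standard
#' deviation (`sqrt(mean((x - mean)^2))`), so a common L1 weight acts
#' uniformly across markers in penalized fits. Original allele frequencies
#' are retained. Double standardization is refused.
#'
#' @param genotypes a raw-coded [genotype_matrix()].
#' @return a standardized [genotype_matrix()].
#' @export
standardize_genotypes <- function(genotypes) {
  if (geno_coding(genotypes) != "raw012")
    stop_input("genotypes are already standardized")
  X <- unclass(genotypes)
  mu <- colMeans(X)
  sdev <- sqrt(colMeans(sweep(X, 2, mu)^2))
  zero <- sdev <= 0
  if (any(zero))
    stop_input("zero-variance marker(s): ",
               paste(utils::head(colnames(X)[zero], 5), collapse = ", "))
  Z <- sweep(sweep(X, 2, mu), 2, sdev, "/")
  genotype_matrix(Z, coding = "standardized",
                  allele_freqs = attr(genotypes, "allele_freqs"))
}

#' Eigendecomposition of the kinship matrix
#'
#' The workhorse of efficient multi-trait mixed-model computation: in the
#' eigenbasis of `K` the `nq x nq` covariance `Cg (x) K + Ce (x) I`
#' block-diagonalizes into `n` blocks `s_i Cg + Ce`. Eigenvalues are
#' clamped at zero and returned in descending order; each eigenvector's
#' largest-magnitude entry is made positive so the decomposition is
#' deterministic.
#'
#' @param kinship a [kinship_matrix()] (or symmetric matrix).
#' @return a `kinship_eigen`: list with orthonormal `U` (n x n) and
#'   nonnegative eigenvalues `s` (descending).
#' @export
eigendecompose_kinship <- function(kinship) {
  K <- as.matrix(unclass(kinship))
  if (!is_symmetric_tol(K, 1e-8))
    stop_input("kinship matrix is not symmetric within 1e-8")
  if (all(K[upper.tri(K)] == 0) && all(K[lower.tri(K)] == 0)) {
    # already diagonal: use the (permuted) standard basis
    ord <- order(diag(K), decreasing = TRUE)
    return(structure(list(U = diag(nrow(K))[, ord, drop = FALSE],
                          s = pmax(diag(K)[ord], 0)),
                     class = "kinship_eigen"))
  }
  ev <- eigen(symmetrize(K), symmetric = TRUE)
  U <- ev$vectors
  # deterministic sign: largest-|entry| of each eigenvector positive
  for (j in seq_len(ncol(U))) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  structure(list(U = U, s = pmax(ev$values, 0)), class = "kinship_eigen")
}

# Guard against a stale precomputed eigendecomposition (e.g. computed before
# individuals were reordered): verify U diag(s) U' acts like K on one fixed
# probe vector.  O(n^2), negligible next to any use of the decomposition.
.check_eig <- function(eig, kinship) {
  K <- as.matrix(unclass(kinship))
  n <- nrow(K)
  if (nrow(eig$U) != n)
    stop_input("kinship eigendecomposition has the wrong dimension")
  v <- sin(seq_len(n))
  r1 <- K %*% v
  r2 <- eig$U %*% (eig$s * crossprod(eig$U, v))
  if (max(abs(r1 - r2)) > 1e-6 * max(1, max(abs(r1))))
    stop_input("supplied kinship eigendecomposition does not match the ",
               "kinship matrix (stale, or individuals were reordered?)")
  invisible(TRUE)
}
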