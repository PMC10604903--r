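#' Penalty specification
#'
#' The regularizer is
#' `R(B) = lambda * sum_ij |B_ij| + gamma * sum_(j,j') c_jj' ||B_:j - B_:j'||_2`,
#' an entrywise L1 term for marker selection plus a convex-clustering term
#' that shrinks whole trait effect profiles toward one another. The edge
#' set defaults to the complete graph over traits with unit weights; edge
#' weights `c_jj'` may encode prior knowledge of which traits share
#' architecture.
#'
#' @param lambda nonnegative L1 weight.
#' @param gamma nonnegative clustering weight.
#' @param q number of traits (needed to build the default complete graph
#'   when `gamma > 0`).
#' @param edges two-column integer matrix of unordered trait pairs, or
#'   `"complete"`.
#' @param weights nonnegative per-edge weights (recycled).
#' @return a `penalty_spec`.
#' @export
penalty_spec <- function(lambda = 0, gamma = 0, q = NULL, edges = "complete",
                         weights = 1) {
  if (lambda < 0 || gamma < 0) stop_input("lambda and gamma must be nonnegative")
  if (identical(edges, "complete")) {
    if (gamma > 0) {
      if (is.null(q)) stop_input("q is needed to build the complete trait graph")
      edges <- t(utils::combn(q, 2L))
    } else {
      edges <- matrix(integer(0), 0, 2)
    }
  } else {
    edges <- matrix(as.integer(edges), ncol = 2)
    if (nrow(edges) && any(edges[, 1] == edges[, 2]))
      stop_input("self-edges are not allowed in the trait graph")
    if (!is.null(q) && nrow(edges) && max(edges) > q)
      stop_input("edge references a trait index beyond q")
  }
  weights <- rep_len(weights, nrow(edges))
  if (any(weights < 0)) stop_input("edge weights must be nonnegative")
  structure(list(lambda = lambda, gamma = gamma, edges = edges,
                 weights = weights), class = "penalty_spec")
}

#' Evaluate the penalty
#'
#' @param B effect matrix (penalized rows only; callers exclude any
#'   intercept row before calling).
#' @param spec a [penalty_spec()].
#' @return scalar penalty value.
#' @export
penalty_value <- function(B, spec) {
  B <- as.matrix(B)
  val <- spec$lambda * sum(abs(B))
  if (spec$gamma > 0 && nrow(spec$edges)) {
    dn <- sqrt(colSums((B[, spec$edges[, 1], drop = FALSE] -
                          B[, spec$edges[, 2], drop = FALSE])^2))
    val <- val + spec$gamma * sum(spec$weights * dn)
  }
  val
}

#' Entrywise soft thresholding
#'
#' Proximal operator of the L1 penalty:
#' `sign(z) * max(|z| - threshold, 0)`. Rows listed in `exempt` are passed
#' through unchanged (used for the unpenalized intercept row).
#'
#' @param Z numeric matrix.
#' @param threshold nonnegative scalar.
#' @param exempt integer row indices exempt from thresholding.
#' @return matrix of the same shape.
#' @export
prox_l1 <- function(Z, threshold, exempt = integer(0)) {
  if (threshold < 0) stop_input("threshold must be nonnegative")
  out <- sign(Z) * pmax(abs(Z) - threshold, 0)
  if (length(exempt)) out[exempt, ] <- Z[exempt, , drop = FALSE]
  out
}

# Block soft threshold of a vector: shrink its Euclidean norm by k.
.block_soft <- function(v, k) {
  nv <- sqrt(sum(v^2))
  if (nv <= k) v * 0 else v * (1 - k / nv)
}

#' Proximal operator of the combined penalty
#'
#' Computes `argmin_B 1/2 ||B - Z||_F^2 + step * R(B)` for the combined
#' L1 + trait-clustering penalty by ADMM: the quadratic couples the trait
#' graph through a small `q x q` Laplacian system (solved in its
#' eigenbasis), while the L1 copy and each edge-difference copy have
#' closed-form (block) soft-threshold updates. With `gamma = 0` this
#' reduces exactly to [prox_l1()].
#'
#' @param Z numeric matrix (penalized rows only).
#' @param spec a [penalty_spec()].
#' @param step positive proximal step size.
#' @param tol stopping tolerance on the scaled primal/dual residuals.
#' @param max_iter ADMM iteration cap; non-convergence is flagged via the
#'   `converged` attribute and a warning, never silently.
#' @param rho ADMM penalty parameter.
#' @param warm optional warm start (the `state` attribute of a previous
#'   call on a nearby input), used by iterative callers; the solution is
#'   unchanged, only the iteration count drops.
#' @return matrix of the same shape as `Z`, with attributes `residual`,
#'   `iterations`, `converged` and `state`.
#' @export
prox_combined <- function(Z, spec, step, tol = 1e-6, max_iter = 200L, rho = 1,
                          warm = NULL) {
  if (step <= 0) stop_input("step must be positive")
  Z <- as.matrix(Z)
  if (spec$gamma == 0 || nrow(spec$edges) == 0L) {
    out <- prox_l1(Z, step * spec$lambda)
    attributes(out) <- c(attributes(out),
                         list(residual = 0, iterations = 0L, converged = TRUE))
    return(out)
  }
  p <- nrow(Z); q <- ncol(Z)
  E <- nrow(spec$edges)
  # signed incidence matrix of the trait graph: edge_diff(B) = B %*% Inc
  Inc <- matrix(0, q, E)
  Inc[cbind(spec$edges[, 1], seq_len(E))] <- 1
  Inc[cbind(spec$edges[, 2], seq_len(E))] <- -1
  L <- tcrossprod(Inc)  # graph Laplacian
  eL <- eigen((1 + rho) * diag(q) + rho * L, symmetric = TRUE)
  Qm <- eL$vectors; dinv <- 1 / eL$values
  if (is.null(warm)) {
    M <- Z; UM <- matrix(0, p, q)
    D <- Z %*% Inc; UD <- matrix(0, p, E)
  } else {
    M <- warm$M; UM <- warm$UM; D <- warm$D; UD <- warm$UD
  }
  tl <- step * spec$lambda / rho
  tg <- step * spec$gamma * spec$weights / rho
  scale <- 1 + sqrt(sum(Z^2))
  res <- Inf; it <- 0L
  for (it in seq_len(max_iter)) {
    # B-update: B ((1+rho) I + rho L) = Z + rho (M - UM) + rho (D - UD) Inc'
    RHS <- Z + rho * (M - UM) + tcrossprod(rho * (D - UD), Inc)
    B <- ((RHS %*% Qm) * rep(dinv, each = p)) %*% t(Qm)
    M_old <- M; D_old <- D
    M <- prox_l1(B + UM, tl)
    BE <- B %*% Inc
    V <- BE + UD
    nv <- sqrt(colSums(V^2))
    D <- V * rep(pmax(1 - tg / pmax(nv, .Machine$double.xmin), 0), each = p)
    UM <- UM + B - M
    UD <- UD + BE - D
    r_prim <- sqrt(sum((B - M)^2) + sum((BE - D)^2))
    # dual residual: rho * change in (M, D) mapped back through the operator
    r_dual <- rho * sqrt(sum(((M - M_old) + tcrossprod(D - D_old, Inc))^2))
    res <- max(r_prim, r_dual)
    if (res <= tol * scale) break
  }
  converged <- res <= tol * scale
  if (!converged)
    warning("prox_combined: ADMM reached max_iter with residual ",
            format(res), " (tol ", format(tol * scale), ")")
  structure(M, residual = res, iterations = it, converged = converged,
            state = list(M = M, UM = UM, D = D, UD = UD))
}
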