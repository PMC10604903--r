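# Independent oracles used across the test suite.  Everything here builds
# the dense nq-dimensional objects explicitly (Kronecker products, full
# covariance solves); the package itself never does.

dense_nll_oracle <- function(Y, X, B, Cg, Ce, K) {
  n <- nrow(Y); q <- ncol(Y)
  Sigma <- kronecker(Cg, K) + kronecker(Ce, diag(n))
  r <- as.vector(Y - X %*% B)
  ch <- chol(Sigma)
  0.5 * (n * q * log(2 * pi) + 2 * sum(log(diag(ch))) +
           sum(backsolve(ch, r, transpose = TRUE)^2))
}

dense_grad_oracle <- function(Y, X, B, Cg, Ce, K) {
  n <- nrow(Y); q <- ncol(Y); p <- ncol(X)
  Sigma <- kronecker(Cg, K) + kronecker(Ce, diag(n))
  r <- as.vector(Y - X %*% B)
  matrix(-t(kronecker(diag(q), X)) %*% solve(Sigma, r), p, q)
}

dense_gls_oracle <- function(Y, Xs, Cg, Ce, K) {
  n <- nrow(Y); q <- ncol(Y)
  Sigma <- kronecker(Cg, K) + kronecker(Ce, diag(n))
  D <- kronecker(diag(q), Xs)
  Si <- solve(Sigma)
  V <- solve(t(D) %*% Si %*% D)
  list(effects = matrix(V %*% t(D) %*% Si %*% as.vector(Y), ncol(Xs), q),
       vcov = V)
}

dense_gebv_oracle <- function(resid_train, Cg, Ce, Ktt, Kts) {
  ntr <- nrow(resid_train); q <- ncol(resid_train)
  Stt <- kronecker(Cg, Ktt) + kronecker(Ce, diag(ntr))
  Sts <- kronecker(Cg, Kts)
  matrix(Sts %*% solve(Stt, as.vector(resid_train)), nrow(Kts), q)
}

# Brute-force BH step-up straight from its definition.
bh_brute <- function(p, fdr) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= i * fdr / m) k <- i
  rej <- logical(m)
  if (k > 0) rej[o[seq_len(k)]] <- TRUE
  rej
}

# Univariate mixed-model ML on the dense covariance, via Nelder-Mead on
# log-variances (independent of the package's Cholesky/L-BFGS path).
uni_ml_oracle <- function(y, K) {
  n <- length(y)
  o <- rep(1, n)
  nll <- function(par) {
    Sigma <- par[1] * K + par[2] * diag(n)
    ch <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    w1 <- backsolve(ch, o, transpose = TRUE)
    wy <- backsolve(ch, y, transpose = TRUE)
    mu <- sum(w1 * wy) / sum(w1^2)
    r <- backsolve(ch, y - mu * o, transpose = TRUE)
    0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(r^2))
  }
  v0 <- stats::var(y)
  res <- stats::optim(log(c(v0 / 2, v0 / 2)), function(lp) nll(exp(lp)),
                      method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  list(sigma_g2 = exp(res$par[1]), sigma_e2 = exp(res$par[2]),
       nll = res$value)
}

# Dual certificate for the combined-penalty proximal problem
#   min 1/2 ||B - Z||^2 + t*lambda ||B||_1 + t*gamma sum_e c_e ||B e_e||.
# Projected gradient ascent on the concave dual g(S) = <S,Z> - ||S||^2/2
# over the product of the L-infinity ball and per-edge L2 balls; the dual
# optimum equals the primal optimum (strong duality, both finite).
prox_dual_oracle <- function(Z, spec, step, iters = 20000L) {
  p <- nrow(Z); q <- ncol(Z)
  edges <- spec$edges; E <- nrow(edges)
  tl <- step * spec$lambda
  tg <- step * spec$gamma * spec$weights
  alpha <- matrix(0, p, q)
  beta <- matrix(0, p, max(E, 1L))
  stepd <- 1 / (1 + 2 * q)
  assemble <- function(alpha, beta) {
    S <- alpha
    for (e in seq_len(E)) {
      S[, edges[e, 1]] <- S[, edges[e, 1]] + beta[, e]
      S[, edges[e, 2]] <- S[, edges[e, 2]] - beta[, e]
    }
    S
  }
  for (it in seq_len(iters)) {
    S <- assemble(alpha, beta)
    Gr <- Z - S
    alpha <- pmin(pmax(alpha + stepd * Gr, -tl), tl)
    for (e in seq_len(E)) {
      b <- beta[, e] + stepd * (Gr[, edges[e, 1]] - Gr[, edges[e, 2]])
      nb <- sqrt(sum(b^2))
      if (nb > tg[e]) b <- b * tg[e] / nb
      beta[, e] <- b
    }
  }
  S <- assemble(alpha, beta)
  sum(S * Z) - 0.5 * sum(S^2)
}

# Random small model instance with labelled containers.
random_instance <- function(n, q, p, seed, pd_boost = 0.2) {
  withr_seed <- function(expr) regmtlmm:::with_seed(seed, expr)
  withr_seed({
    A <- matrix(rnorm(n * n), n)
    K <- crossprod(A) / n
    X <- matrix(rnorm(n * p), n, p)
    Y <- matrix(rnorm(n * q), n, q)
    ids <- paste0("i", seq_len(n))
    dimnames(K) <- list(ids, ids)
    rownames(X) <- rownames(Y) <- ids
    colnames(X) <- paste0("m", seq_len(p))
    colnames(Y) <- paste0("t", seq_len(q))
    Lg <- matrix(rnorm(q * q), q)
    Le <- matrix(rnorm(q * q), q)
    list(Y = Y, X = X, K = K,
         B = matrix(rnorm(p * q), p, q),
         Cg = crossprod(Lg) / q,
         Ce = crossprod(Le) / q + pd_boost * diag(q))
  })
}

# Small simulated dataset with structure, aligned and standardized.
simulated_dataset <- function(n = 80, p = 100, q = 3, scenario = 1,
                              qtn = 10, seed = 1, fst = 0.15,
                              groups = NULL) {
  G <- generate_structured_genotypes(n, p, n_subpops = 2, fst = fst,
                                     seed = seed)
  Gs <- standardize_genotypes(G)
  K <- compute_vanraden_kinship(G)
  sc <- scenario_spec(scenario, q = q, p = p, qtn_per_trait = qtn,
                      groups = groups)
  truth <- generate_effect_matrix(sc, seed = seed + 1)
  cov <- default_trait_covariances(q, groups = sc$groups, B = truth$B_true,
                                   K = K)
  Y <- simulate_phenotypes(Gs, K, truth, cov, seed = seed + 2)
  list(data = align(Y, Gs, K), truth = truth, cov = cov, spec = sc)
}
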