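test_that("null variance components match a univariate ML oracle (q = 1)", {
  sim <- simulated_dataset(n = 60, p = 40, q = 1, qtn = 5, seed = 13)
  d <- sim$data
  vc <- fit_variance_components_null(d)
  orc <- uni_ml_oracle(as.numeric(unclass(d$traits)),
                       unclass(d$kinship))
  expect_equal(vc$Cg[1, 1], orc$sigma_g2, tolerance = 1e-4)
  expect_equal(vc$Ce[1, 1], orc$sigma_e2, tolerance = 1e-4)
})

test_that("identity kinship triggers the identifiability fallback", {
  set.seed(14)
  Y <- trait_matrix(matrix(rnorm(60), 30, 2,
                           dimnames = list(paste0("i", 1:30), c("a", "b"))))
  G <- genotype_matrix(matrix(sample(0:2, 150, TRUE), 30, 5,
                              dimnames = list(paste0("i", 1:30),
                                              paste0("m", 1:5))))
  K <- kinship_matrix(diag(30), individual_ids = paste0("i", 1:30))
  d <- align(Y, G, K)
  expect_warning(vc <- fit_variance_components_null(d), "identifiable")
  expect_equal(max(abs(vc$Cg)), 0)
  # Ce then absorbs the full trait covariance (ML, about the sample cov)
  expect_lt(max(abs(vc$Ce - cov(unclass(Y)) * 29 / 30)), 0.15)
})

test_that("degenerate phenotypes are refused", {
  Y <- trait_matrix(matrix(1, 10, 2, dimnames = list(paste0("i", 1:10),
                                                     c("a", "b"))))
  G <- genotype_matrix(matrix(rep(c(0, 1, 2), length.out = 40), 10, 4,
                              dimnames = list(paste0("i", 1:10),
                                              paste0("m", 1:4))))
  K <- kinship_matrix(diag(10) + 0.1, individual_ids = paste0("i", 1:10))
  expect_error(fit_variance_components_null(align(Y, G, K)), "zero variance")
})

test_that("objective trace is monotone and heavy L1 zeroes all markers", {
  sim <- simulated_dataset(n = 50, p = 30, q = 3, qtn = 5, seed = 15)
  d <- sim$data
  lmax <- lambda_max(d)
  fit <- fit_regularized_mtlmm(d, penalty_spec(0.2 * lmax, 0, q = 3),
                               fit_options(outer_max = 10))
  expect_true(all(diff(fit$objective_trace) <= 1e-10))
  fit0 <- fit_regularized_mtlmm(d, penalty_spec(10 * lmax, 0, q = 3),
                                fit_options(outer_max = 6))
  expect_equal(max(abs(fit0$B_hat[-1, ])), 0)
  expect_gt(max(abs(fit0$B_hat[1, ])), 0)  # intercept is unpenalized
})

test_that("unpenalized fit (p < n) matches an alternating dense GLS/ML oracle", {
  sim <- simulated_dataset(n = 30, p = 3, q = 2, qtn = 2, seed = 16)
  d <- sim$data
  fit <- fit_regularized_mtlmm(d, penalty_spec(0, 0, q = 2),
                               fit_options(outer_max = 60, outer_tol = 1e-10))
  Y <- unclass(d$traits); X <- unclass(d$genotypes); K <- unclass(d$kinship)
  Xf <- cbind(1, X)
  # oracle: exact dense GLS for B, Nelder-Mead on dense -LL for (Cg, Ce)
  Cg <- cov(Y) / 2; Ce <- cov(Y) / 2
  idx <- which(lower.tri(diag(2), diag = TRUE))
  for (it in 1:30) {
    B <- dense_gls_oracle(Y, Xf, Cg, Ce, K)$effects
    par0 <- c(t(chol(Cg + 1e-10 * diag(2)))[idx], t(chol(Ce))[idx])
    obj <- function(th) {
      Lg <- matrix(0, 2, 2); Le <- matrix(0, 2, 2)
      Lg[idx] <- th[1:3]; Le[idx] <- th[4:6]
      dense_nll_oracle(Y, Xf, B, tcrossprod(Lg),
                       tcrossprod(Le) + 1e-8 * diag(2), K)
    }
    res <- optim(par0, obj, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))
    Lg <- matrix(0, 2, 2); Le <- matrix(0, 2, 2)
    Lg[idx] <- res$par[1:3]; Le[idx] <- res$par[4:6]
    Cg <- tcrossprod(Lg); Ce <- tcrossprod(Le) + 1e-8 * diag(2)
  }
  B_orc <- dense_gls_oracle(Y, Xf, Cg, Ce, K)$effects
  expect_lt(max(abs(unname(fit$B_hat) - B_orc)), 1e-5)
  obj_pkg <- tail(fit$objective_trace, 1)
  obj_orc <- dense_nll_oracle(Y, Xf, B_orc, Cg, Ce, K)
  expect_equal(obj_pkg, obj_orc, tolerance = 1e-8)
})

test_that("mtLM with one trait and L1 penalty matches a lasso solver", {
  skip_if_not_installed("glmnet")
  sim <- simulated_dataset(n = 60, p = 30, q = 1, qtn = 5, seed = 17)
  d <- sim$data
  lam <- 0.15 * lambda_max(d, model = "mtLM")
  fit <- fit_regularized_mtlmm(d, penalty_spec(lam, 0, q = 1),
                               fit_options(outer_max = 40, outer_tol = 1e-10,
                                           fista_max = 2000,
                                           fista_tol = 1e-12),
                               model = "mtLM")
  sig2 <- fit$cov_hat$Ce[1, 1]
  gl <- glmnet::glmnet(unclass(d$genotypes), as.numeric(unclass(d$traits)),
                       lambda = lam * sig2 / nrow(d$traits),
                       standardize = FALSE, thresh = 1e-14)
  b_gl <- as.numeric(coef(gl))
  expect_lt(max(abs(as.numeric(fit$B_hat) - b_gl)), 1e-5)
})

test_that("freezing Cg at zero collapses the mixed model to the linear model", {
  sim <- simulated_dataset(n = 40, p = 20, q = 2, qtn = 4, seed = 18)
  d <- sim$data
  spec <- penalty_spec(0.3 * lambda_max(d, model = "mtLM"), 0, q = 2)
  opts <- fit_options(outer_max = 15, outer_tol = 1e-9)
  f1 <- fit_regularized_mtlmm(d, spec, opts, model = "mtLMM",
                              init = list(freeze_cg = TRUE))
  f2 <- fit_regularized_mtlmm(d, spec, opts, model = "mtLM")
  expect_lt(max(abs(f1$B_hat - f2$B_hat)), 1e-6)
  expect_equal(tail(f1$objective_trace, 1), tail(f2$objective_trace, 1),
               tolerance = 1e-8)
})

test_that("nonzero count is non-increasing along a lambda path", {
  sim <- simulated_dataset(n = 50, p = 40, q = 2, qtn = 5, seed = 19)
  d <- sim$data
  lmax <- lambda_max(d)
  eig <- eigendecompose_kinship(d$kinship)
  warm <- NULL
  counts <- integer(0)
  for (r in c(1, 0.5, 0.25, 0.1, 0.05)) {
    fit <- fit_regularized_mtlmm(d, penalty_spec(r * lmax, 0, q = 2),
                                 fit_options(outer_max = 12), eig = eig,
                                 init = warm)
    warm <- list(B = fit$B_hat, Cg = fit$cov_hat$Cg, Ce = fit$cov_hat$Ce)
    counts <- c(counts, sum(detected_support(fit$B_hat)))
  }
  expect_true(all(diff(rev(counts)) <= 0))
  expect_equal(counts[1], 0L)  # at lambda_max nothing enters
})

test_that("trait permutation permutes the solution (label equivariance)", {
  sim <- simulated_dataset(n = 40, p = 15, q = 3, qtn = 4, seed = 20)
  d <- sim$data
  perm <- c(3, 1, 2)
  dp <- structure(list(traits = trait_matrix(unclass(d$traits)[, perm]),
                       genotypes = d$genotypes, kinship = d$kinship),
                  class = "aligned_dataset")
  spec <- penalty_spec(0.3 * lambda_max(d), 0, q = 3)
  opts <- fit_options(outer_max = 10, outer_tol = 1e-9)
  f <- fit_regularized_mtlmm(d, spec, opts)
  fp <- fit_regularized_mtlmm(dp, spec, opts)
  # agreement is limited by the finite optimizer tolerances, not exact
  expect_lt(max(abs(unname(fp$B_hat) - unname(f$B_hat[, perm]))), 1e-4)
})

test_that("regularization selection returns planted optimum and breaks ties", {
  sim <- simulated_dataset(n = 60, p = 30, q = 2, qtn = 4, seed = 21)
  d <- sim$data
  g1 <- penalty_spec(0.5, 0, q = 2)
  expect_identical(select_regularization(d, list(g1), seed = 2)$best, g1)

  # planted optimum: under the fixed-effects-only model, prediction must
  # come from B, so the permissive lambda beats the all-zero fit
  lmax <- lambda_max(d, model = "mtLM")
  grid <- list(penalty_spec(2 * lmax, 0, q = 2),
               penalty_spec(0.05 * lmax, 0, q = 2))
  sel <- select_regularization(d, grid, opts = fit_options(outer_max = 8),
                               seed = 3, model = "mtLM")
  expect_equal(sel$best$lambda, 0.05 * lmax)
  expect_true(is.data.frame(sel$table) && nrow(sel$table) == 2)

  # identical scores (duplicate specs): larger lambda wins
  grid2 <- list(penalty_spec(0.2, 0, q = 2), penalty_spec(0.4, 0, q = 2),
                penalty_spec(0.4, 0, q = 2))
  sel2 <- select_regularization(d, grid2, opts = fit_options(outer_max = 6),
                                seed = 4)
  expect_equal(sel2$best$lambda, 0.4)
})

test_that("a stale kinship eigendecomposition is rejected", {
  sim <- simulated_dataset(n = 20, p = 10, q = 2, qtn = 2, seed = 22)
  d <- sim$data
  K <- unclass(d$kinship)
  eig_stale <- eigendecompose_kinship(K[nrow(K):1, ncol(K):1])
  expect_error(fit_variance_components_null(d, eig = eig_stale),
               "does not match")
  expect_error(scan_multi_trait(d, eig = eig_stale), "does not match")
  ok <- eigendecompose_kinship(d$kinship)
  expect_silent(vc <- fit_variance_components_null(d, eig = ok))
})
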