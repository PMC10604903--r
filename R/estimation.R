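#' Optimizer options
#'
#' Controls for the alternating proximal-gradient fit: an accelerated
#' proximal-gradient (FISTA) pass over the effect matrix, then a
#' quasi-Newton pass over Cholesky-parameterized covariances, repeated
#' until the penalized objective stabilizes.
#'
#' @param outer_max,outer_tol outer alternation cap and relative-change
#'   stopping tolerance on the penalized objective.
#' @param fista_max,fista_tol inner proximal-gradient cap and tolerance.
#' @param backtrack step-shrink factor in (0,1) for the line search.
#' @param cov_maxit L-BFGS iteration cap per covariance step.
#' @param prox_max_iter ADMM iteration cap per proximal subproblem (only
#'   relevant when the clustering weight is positive).
#' @param seed seed for any data splits made by callers (the optimizer
#'   itself is deterministic).
#' @return a `fit_options` list.
#' @export
fit_options <- function(outer_max = 50L, outer_tol = 1e-6,
                        fista_max = 500L, fista_tol = 1e-7,
                        backtrack = 0.5, cov_maxit = 60L,
                        prox_max_iter = 200L, seed = 1L) {
  stopifnot(outer_max >= 1, fista_max >= 1, outer_tol > 0, fista_tol > 0,
            backtrack > 0, backtrack < 1, prox_max_iter >= 1)
  structure(list(outer_max = as.integer(outer_max), outer_tol = outer_tol,
                 fista_max = as.integer(fista_max), fista_tol = fista_tol,
                 backtrack = backtrack, cov_maxit = as.integer(cov_maxit),
                 prox_max_iter = as.integer(prox_max_iter),
                 seed = as.integer(seed)),
            class = "fit_options")
}

.ltri <- function(q) which(lower.tri(diag(q), diag = TRUE))

.safe_chol_lower <- function(C) {
  out <- tryCatch(t(chol(C)), error = function(e) NULL)
  if (!is.null(out)) return(out)
  ridge <- 1e-8 * (1 + mean(diag(C)))
  repeat {
    out <- tryCatch(t(chol(C + ridge * diag(nrow(C)))), error = function(e) NULL)
    if (!is.null(out)) return(out)
    ridge <- ridge * 10
  }
}

# One covariance step: minimize the block NLL of residual R over
# (Cg, Ce) = (Lg Lg', Le Le' + eps I), holding effects fixed.
.cov_step <- function(R, s, Cg, Ce, fix_cg = FALSE, maxit = 60L) {
  q <- ncol(R); n <- nrow(R)
  idx <- .ltri(q)
  eps_pd <- 1e-8
  Lg0 <- .safe_chol_lower(Cg + 1e-10 * diag(q))
  Le0 <- .safe_chol_lower(Ce)
  unpack <- function(th) {
    Lg <- matrix(0, q, q); Le <- matrix(0, q, q)
    if (fix_cg) {
      Le[idx] <- th
    } else {
      Lg[idx] <- th[seq_along(idx)]
      Le[idx] <- th[-seq_along(idx)]
    }
    list(Cg = if (fix_cg) Cg else tcrossprod(Lg),
         Ce = tcrossprod(Le) + eps_pd * diag(q), Lg = Lg, Le = Le)
  }
  fn <- function(th) {
    cc <- unpack(th)
    tt <- .trait_transform(cc$Cg, cc$Ce, jitter_warn = FALSE)
    .nll_from_resid(R, s, tt)
  }
  gr <- function(th) {
    cc <- unpack(th)
    tt <- .trait_transform(cc$Cg, cc$Ce, jitter_warn = FALSE)
    W <- .block_weights(s, tt$d)
    Rt <- R %*% t(tt$A)
    Rw <- Rt * W
    Ge <- 0.5 * t(tt$A) %*% (diag(colSums(W), q) - crossprod(Rw)) %*% tt$A
    Ge <- symmetrize(Ge)
    dLe <- (2 * Ge %*% cc$Le)[idx]
    if (fix_cg) return(dLe)
    Gg <- 0.5 * t(tt$A) %*% (diag(colSums(W * s), q) - crossprod(Rw, Rw * s)) %*% tt$A
    Gg <- symmetrize(Gg)
    c((2 * Gg %*% cc$Lg)[idx], dLe)
  }
  th0 <- if (fix_cg) Le0[idx] else c(Lg0[idx], Le0[idx])
  f0 <- fn(th0)
  res <- tryCatch(
    stats::optim(th0, fn, gr, method = "L-BFGS-B",
                 control = list(maxit = maxit, factr = 1e7)),
    error = function(e) NULL)
  if (is.null(res) || !is.finite(res$value) || res$value > f0) {
    cc <- unpack(th0); cc$nll <- f0
  } else {
    cc <- unpack(res$par); cc$nll <- res$value
  }
  cc[c("Cg", "Ce", "nll")]
}

# GLS fit of the intercept row only (all other effects fixed at zero
# contribution through `offset`, an n x q matrix already subtracted).
.intercept_gls <- function(Ytil, otil, tt, W) {
  q <- ncol(Ytil)
  Ys <- Ytil %*% t(tt$A)
  bstar <- vapply(seq_len(q), function(j)
    sum(W[, j] * otil * Ys[, j]) / sum(W[, j] * otil^2), numeric(1))
  matrix(bstar, 1) %*% t(tt$Ainv)
}

#' Null-model variance components
#'
#' Maximum-likelihood estimates of `(Cg, Ce)` under the intercept-only
#' model `vec(Y) ~ N(vec(1 mu'), Cg (x) K + Ce (x) I)`, by alternating an
#' exact GLS intercept with quasi-Newton covariance steps in the kinship
#' eigenbasis. Initialization is `Cg = Ce = cov(Y)/2`.
#'
#' When the kinship eigenvalues are all equal (e.g. `K = I`) only the sum
#' `Cg + Ce` is identified; a warning is issued and `Cg` is forced to zero.
#'
#' @param data an [align()]ed dataset.
#' @param eig optional precomputed [eigendecompose_kinship()] result.
#' @param max_outer,tol alternation cap and relative NLL tolerance.
#' @return a [covariance_pair()] with attributes `intercept` (1 x q) and
#'   `nll`.
#' @export
fit_variance_components_null <- function(data, eig = NULL, max_outer = 100L,
                                         tol = 1e-8) {
  Y <- as.matrix(unclass(data$traits))
  n <- nrow(Y); q <- ncol(Y)
  if (n <= q) stop_input("need more individuals than traits for the null fit")
  if (all(apply(Y, 2, stats::var) <= 0))
    stop_input("phenotypes have zero variance; null model is degenerate")
  if (!is.null(eig)) .check_eig(eig, data$kinship)
  eig <- eig %||% eigendecompose_kinship(data$kinship)
  s <- eig$s
  fix_cg <- FALSE
  if (stats::sd(s) < 1e-10) {
    warning("kinship eigenvalues are constant: Cg and Ce are not separately ",
            "identifiable; forcing Cg = 0")
    fix_cg <- TRUE
  }
  Ut <- t(eig$U)
  Ytil <- Ut %*% Y
  otil <- as.numeric(Ut %*% rep(1, n))
  S <- stats::cov(Y)
  Cg <- if (fix_cg) matrix(0, q, q) else S / 2
  Ce <- if (fix_cg) S else S / 2
  nll_prev <- Inf; mu <- matrix(0, 1, q)
  for (iter in seq_len(max_outer)) {
    tt <- .trait_transform(Cg, Ce, jitter_warn = FALSE)
    W <- .block_weights(s, tt$d)
    mu <- .intercept_gls(Ytil, otil, tt, W)
    R <- Ytil - otil %*% mu
    st <- .cov_step(R, s, Cg, Ce, fix_cg = fix_cg, maxit = 60L)
    Cg <- st$Cg; Ce <- st$Ce
    if (is.finite(nll_prev) &&
        abs(nll_prev - st$nll) <= tol * max(1, abs(st$nll))) {
      nll_prev <- st$nll
      break
    }
    nll_prev <- st$nll
  }
  out <- covariance_pair(Cg, Ce)
  colnames(out$Cg) <- rownames(out$Cg) <- colnames(Y)
  colnames(out$Ce) <- rownames(out$Ce) <- colnames(Y)
  attr(out, "intercept") <- mu
  attr(out, "nll") <- nll_prev
  out
}

# Initial FISTA step size 1/L with L = lam_max(X'X) * max_i lam_max(V_i^{-1});
# lam_min(Ce + s Cg) is concave in s, so its minimum over [min s, max s]
# is attained at an endpoint.
.fista_step0 <- function(Xtil, s, Cg, Ce) {
  lx <- spectral_norm_sq(Xtil)
  lmin <- function(si) min(eigen(Ce + si * Cg, symmetric = TRUE,
                                 only.values = TRUE)$values)
  vmin <- min(lmin(min(s)), lmin(max(s)))
  1 / (lx / max(vmin, 1e-12))
}

# Accelerated proximal-gradient (FISTA) pass over B with backtracking and
# best-iterate tracking (the returned iterate never has a worse penalized
# objective than the starting point).
.fista_bstep <- function(Ytil, Xtil, s, tt, spec, B0, opts, step0) {
  pen_rows <- seq.int(2L, nrow(B0))
  W <- .block_weights(s, tt$d)
  tA <- t(tt$A)
  const <- 0.5 * (nrow(Ytil) * ncol(Ytil) * log(2 * pi) +
                    sum(log1p(outer(s, tt$d))) + nrow(Ytil) * tt$logdet_ce)
  fval <- function(B) {
    Rt <- (Ytil - Xtil %*% B) %*% tA
    const + 0.5 * sum(Rt^2 * W)
  }
  fgrad <- function(B) {
    Rt <- (Ytil - Xtil %*% B) %*% tA
    list(f = const + 0.5 * sum(Rt^2 * W),
         g = -crossprod(Xtil, (Rt * W) %*% tt$A))
  }
  gpen <- function(B) penalty_value(B[pen_rows, , drop = FALSE], spec)
  prox_state <- NULL
  prox_unconverged <- FALSE
  prox_step <- function(G, t) {
    out <- G
    pc <- withCallingHandlers(
      prox_combined(G[pen_rows, , drop = FALSE], spec, t,
                    max_iter = opts$prox_max_iter %||% 200L,
                    warm = prox_state),
      warning = function(w) {
        if (grepl("prox_combined", conditionMessage(w))) {
          prox_unconverged <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
    prox_state <<- attr(pc, "state")
    out[pen_rows, ] <- pc
    out
  }
  B <- B0
  Bx <- B0; By <- B0; tk <- 1
  t <- step0
  Fbest <- fval(B0) + gpen(B0); Bbest <- B0
  Fprev <- Fbest
  for (it in seq_len(opts$fista_max)) {
    fg <- fgrad(By)
    repeat {
      cand <- prox_step(By - t * fg$g, t)
      dd <- cand - By
      fc <- fval(cand)
      if (fc <= fg$f + sum(fg$g * dd) + sum(dd^2) / (2 * t) + 1e-12) break
      t <- t * opts$backtrack
      if (t < step0 * 1e-12) break
    }
    Fc <- fc + gpen(cand)
    if (Fc < Fbest) {
      Fbest <- Fc
      Bbest <- cand
    }
    tk_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    By <- cand + ((tk - 1) / tk_new) * (cand - Bx)
    Bx <- cand; tk <- tk_new
    # windowed stop: progress right after a warm start can be slow before
    # the momentum builds up, so compare against the value 10 iterations ago
    if (it %% 10L == 0L) {
      if (Fprev - Fc <= 10 * opts$fista_tol * max(1, abs(Fc))) break
      Fprev <- Fc
    }
  }
  if (prox_unconverged)
    warning("some inner proximal subproblems hit their iteration cap; ",
            "the returned solution is still objective-decreasing")
  list(B = Bbest, obj = Fbest)
}

#' Fit a regularized multi-trait (mixed) linear model
#'
#' Minimizes the penalized negative log-likelihood
#' `-LL(B, Cg, Ce) + R(B)` with the L1 + trait-clustering penalty of
#' [penalty_spec()], alternating (a) an accelerated proximal-gradient
#' (FISTA) pass over the effect matrix `B` in the kinship eigenbasis with
#' (b) a quasi-Newton step over Cholesky-parameterized covariances. The
#' trait-wise intercept is part of the design and never penalized. With
#' `model = "mtLM"` the genetic term is dropped (`Cg` frozen at zero),
#' giving the regularized multi-trait linear model.
#'
#' The number of markers may exceed the number of individuals. Every
#' accepted outer iteration leaves the penalized objective no larger than
#' before (the `objective_trace` is non-increasing).
#'
#' @param data an [align()]ed dataset (markers typically standardized, see
#'   [standardize_genotypes()]).
#' @param spec a [penalty_spec()].
#' @param opts a [fit_options()].
#' @param model `"mtLMM"` (kinship random effect) or `"mtLM"` (none).
#' @param eig optional precomputed kinship eigendecomposition.
#' @param init optional warm start: list with any of `B`, `Cg`, `Ce`.
#' @return a `fit_result`: list with `B_hat` (`(p+1) x q`, intercept row
#'   first), `cov_hat` ([covariance_pair()]), `objective_trace`,
#'   `converged`, `spec`, `n_outer`, `model`.
#' @export
fit_regularized_mtlmm <- function(data, spec, opts = fit_options(),
                                  model = c("mtLMM", "mtLM"), eig = NULL,
                                  init = NULL) {
  model <- match.arg(model)
  Y <- as.matrix(unclass(data$traits))
  X <- as.matrix(unclass(data$genotypes))
  n <- nrow(Y); q <- ncol(Y); p <- ncol(X)
  if (model == "mtLMM") {
    if (!is.null(eig)) .check_eig(eig, data$kinship)
    eig <- eig %||% eigendecompose_kinship(data$kinship)
    Ut <- t(eig$U)
    s <- eig$s
    Ytil <- Ut %*% Y
    Xtil <- Ut %*% cbind(1, X)
  } else {
    s <- rep(0, n)
    Ytil <- Y
    Xtil <- cbind(1, X)
  }
  freeze_cg <- model == "mtLM" || isTRUE(init$freeze_cg)
  S <- stats::cov(Y)
  Cg <- init$Cg %||% (if (freeze_cg) matrix(0, q, q) else S / 2)
  Ce <- init$Ce %||% (if (freeze_cg) S else S / 2)
  B <- init$B %||% matrix(0, p + 1, q)
  # put the intercept at its GLS optimum so B = 0 is a fixed point for
  # large lambda
  tt <- .trait_transform(Cg, Ce, jitter_warn = FALSE)
  if (is.null(init$B))
    B[1, ] <- .intercept_gls(Ytil, Xtil[, 1], tt,
                             .block_weights(s, tt$d))
  trace <- numeric(0)
  obj_prev <- Inf
  converged <- FALSE
  n_outer <- 0L
  for (outer in seq_len(opts$outer_max)) {
    n_outer <- outer
    tt <- .trait_transform(Cg, Ce, jitter_warn = FALSE)
    step0 <- .fista_step0(Xtil, s, Cg, Ce)
    bs <- .fista_bstep(Ytil, Xtil, s, tt, spec, B, opts, step0)
    B <- bs$B
    R <- Ytil - Xtil %*% B
    st <- .cov_step(R, s, Cg, Ce, fix_cg = freeze_cg, maxit = opts$cov_maxit)
    gB <- penalty_value(B[-1, , drop = FALSE], spec)
    obj_new <- st$nll + gB
    if (obj_new <= bs$obj + 1e-12) {
      Cg <- st$Cg; Ce <- st$Ce
    } else {
      obj_new <- bs$obj
    }
    if (is.finite(obj_prev) && obj_new > obj_prev + 1e-8)
      stop_input("penalized objective increased during optimization (trace: ",
                 paste(format(c(trace, obj_new)), collapse = ", "), ")")
    trace <- c(trace, obj_new)
    if (is.finite(obj_prev) &&
        abs(obj_prev - obj_new) <= opts$outer_tol * max(1, abs(obj_new))) {
      converged <- TRUE
      obj_prev <- obj_new
      break
    }
    obj_prev <- obj_new
  }
  rownames(B) <- c("(Intercept)", colnames(X))
  colnames(B) <- colnames(Y)
  cov_hat <- covariance_pair(Cg, Ce)
  structure(list(B_hat = B, cov_hat = cov_hat, objective_trace = trace,
                 converged = converged, spec = spec, n_outer = n_outer,
                 model = model, individual_ids = rownames(Y),
                 trait_names = colnames(Y)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  nz <- sum(abs(x$B_hat[-1, , drop = FALSE]) > 1e-8)
  cat("fit_result (", x$model, "): lambda=", x$spec$lambda,
      " gamma=", x$spec$gamma, "; ", nz, " nonzero effects; ",
      x$n_outer, " outer iterations, ",
      if (x$converged) "converged" else "NOT converged", "\n", sep = "")
  invisible(x)
}

#' Smallest L1 weight that zeroes all marker effects
#'
#' Computes `max |d(-LL)/dB|` over marker rows at the intercept-only
#' solution under the initial covariances (`Cg = Ce = cov(Y)/2`, or
#' `Ce = cov(Y)` for `model = "mtLM"`): any `lambda` at or above this
#' leaves the L1 fit at `B = 0`.
#'
#' @inheritParams fit_regularized_mtlmm
#' @return scalar.
#' @export
lambda_max <- function(data, model = c("mtLMM", "mtLM"), eig = NULL) {
  model <- match.arg(model)
  Y <- as.matrix(unclass(data$traits))
  X <- as.matrix(unclass(data$genotypes))
  n <- nrow(Y); q <- ncol(Y)
  if (model == "mtLMM") {
    if (!is.null(eig)) .check_eig(eig, data$kinship)
    eig <- eig %||% eigendecompose_kinship(data$kinship)
    Ut <- t(eig$U)
    s <- eig$s
    Ytil <- Ut %*% Y; Xtil <- Ut %*% cbind(1, X)
  } else {
    s <- rep(0, n); Ytil <- Y; Xtil <- cbind(1, X)
  }
  S <- stats::cov(Y)
  Cg <- if (model == "mtLM") matrix(0, q, q) else S / 2
  Ce <- if (model == "mtLM") S else S / 2
  tt <- .trait_transform(Cg, Ce, jitter_warn = FALSE)
  W <- .block_weights(s, tt$d)
  mu <- .intercept_gls(Ytil, Xtil[, 1], tt, W)
  Rt <- (Ytil - Xtil[, 1] %*% mu) %*% t(tt$A)
  G <- -crossprod(Xtil[, -1, drop = FALSE], (Rt * W) %*% tt$A)
  max(abs(G))
}

#' Default regularization grid
#'
#' Ten `lambda` values log-spaced from [lambda_max()] down to
#' `0.01 * lambda_max`; when `clustering = TRUE`, each is crossed with
#' `gamma = 0` plus a five-point log-spaced grid on the same scale.
#'
#' @inheritParams fit_regularized_mtlmm
#' @param clustering include the trait-clustering term.
#' @param n_lambda,n_gamma grid sizes.
#' @param lambda_min_ratio smallest lambda as a fraction of `lambda_max`.
#' @return list of [penalty_spec()]s, strongest regularization first.
#' @export
default_penalty_grid <- function(data, clustering = FALSE, n_lambda = 10L,
                                 n_gamma = 5L, lambda_min_ratio = 0.01,
                                 model = c("mtLMM", "mtLM"), eig = NULL) {
  model <- match.arg(model)
  lmax <- lambda_max(data, model = model, eig = eig)
  q <- ncol(data$traits)
  lams <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                  length.out = n_lambda))
  gams <- if (clustering)
    c(0, exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                 length.out = n_gamma))) else 0
  grid <- list()
  for (g in sort(gams, decreasing = TRUE))
    for (l in lams)
      grid <- c(grid, list(penalty_spec(lambda = l, gamma = g, q = q)))
  grid
}

#' Hyperparameter selection on an inner holdout
#'
#' Splits the training individuals once into an inner training set and a
#' holdout (default 20%), fits every penalty specification on the inner
#' set, predicts holdout GEBVs, and returns the specification with the
#' largest mean per-trait Pearson correlation. Ties (and all-missing
#' scores, e.g. under a null fit with constant predictions) are broken
#' toward stronger regularization: larger `lambda`, then larger `gamma`.
#' Callers refit the winner on the full training set.
#'
#' @param train an [align()]ed training dataset.
#' @param grid nonempty list of [penalty_spec()]s.
#' @param opts a [fit_options()].
#' @param holdout_fraction fraction of training individuals held out.
#' @param seed seed for the single inner split.
#' @param model `"mtLMM"` or `"mtLM"`.
#' @param dfmax saturation cap: a fit whose support exceeds `dfmax`
#'   (marker, trait) cells is scored as missing and the grid walk stops
#'   (such fits are uninformative about support and expensive).
#' @param one_se apply the one-standard-error parsimony rule: choose the
#'   strongest regularization whose score is within one standard error
#'   (over traits) of the best score.
#' @return list with `best` (a [penalty_spec()]) and `table`
#'   (per-spec holdout scores).
#' @export
select_regularization <- function(train, grid, opts = fit_options(),
                                  holdout_fraction = 0.2, seed = 1L,
                                  model = c("mtLMM", "mtLM"),
                                  dfmax = Inf, one_se = FALSE) {
  model <- match.arg(model)
  if (!length(grid)) stop_input("empty regularization grid")
  if (holdout_fraction <= 0 || holdout_fraction >= 1)
    stop_input("holdout_fraction must be in (0, 1)")
  n <- nrow(train$traits); q <- ncol(train$traits)
  n_hold <- max(3L, round(holdout_fraction * n))
  if (n - n_hold < q + 2L) stop_input("training split too small")
  hold <- with_seed(seed, sort(sample.int(n, n_hold)))
  inner <- setdiff(seq_len(n), hold)
  inner_data <- subset_dataset(train, inner)
  eig_inner <- eigendecompose_kinship(inner_data$kinship)
  scores <- rep(NA_real_, length(grid))
  ses <- rep(NA_real_, length(grid))
  warm <- NULL
  ok <- logical(length(grid))
  for (i in seq_along(grid)) {
    fit <- tryCatch(
      fit_regularized_mtlmm(inner_data, grid[[i]], opts, model = model,
                            eig = eig_inner, init = warm),
      error = function(e) NULL)
    if (is.null(fit)) next
    ok[i] <- TRUE
    # warm-start the effects only: re-estimated covariances can sit near
    # the PSD boundary, where they would throttle the next fit's step size
    warm <- list(B = fit$B_hat)
    if (sum(detected_support(fit$B_hat)) > dfmax) break  # saturated
    pred <- predict_gebv(fit, train, inner, hold)
    acc <- pearson_accuracy(unclass(train$traits)[hold, , drop = FALSE], pred)
    if (!all(is.na(acc))) {
      scores[i] <- mean(acc, na.rm = TRUE)
      ses[i] <- stats::sd(acc, na.rm = TRUE) / sqrt(sum(!is.na(acc)))
    }
  }
  if (!any(ok)) stop_input("all fits failed during regularization selection")
  lam <- vapply(grid, function(g) g$lambda, numeric(1))
  gam <- vapply(grid, function(g) g$gamma, numeric(1))
  key <- ifelse(is.na(scores), -Inf, scores)
  top <- order(key, lam, gam, decreasing = TRUE)[1]
  best <- top
  if (one_se && is.finite(key[top])) {
    cutoff <- key[top] - max(ses[top], 0, na.rm = TRUE)
    eligible <- which(key >= cutoff)
    best <- eligible[order(lam[eligible], gam[eligible],
                           decreasing = TRUE)[1]]
  }
  list(best = grid[[best]],
       table = data.frame(lambda = lam, gamma = gam, score = scores,
                          se = ses))
}
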