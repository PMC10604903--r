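#' Genomic estimated breeding values for a test set
#'
#' Predicts test-set phenotypes from a fitted model as
#' `Y_test = X_test B_hat + G_test`, where `G_test` is the conditional
#' mean of the genetic effect given the training residuals:
#' `vec(G_test) = (Cg (x) K_ts) (Cg (x) K_tt + Ce (x) I)^{-1}
#' vec(Y_train - X_train B_hat)`. The solve is performed in the
#' eigenbasis of `K_tt`; the dense Kronecker matrix is never formed. For
#' `model = "mtLM"` fits (or `Cg = 0`) the genetic term is zero.
#'
#' @param fit a `fit_result` trained on `data_full[train_idx]`.
#' @param data_full the full [align()]ed dataset (kinship must cover
#'   training and test individuals).
#' @param train_idx,test_idx disjoint individual indices.
#' @return numeric `length(test_idx) x q` prediction matrix.
#' @export
predict_gebv <- function(fit, data_full, train_idx, test_idx) {
  if (length(intersect(train_idx, test_idx)))
    stop_input("train and test indices overlap")
  X <- as.matrix(unclass(data_full$genotypes))
  Y <- as.matrix(unclass(data_full$traits))
  B <- fit$B_hat
  pred <- cbind(1, X[test_idx, , drop = FALSE]) %*% B
  Cg <- fit$cov_hat$Cg
  if (fit$model == "mtLM" || all(Cg == 0)) return(pred)
  K <- as.matrix(unclass(data_full$kinship))
  Ktt <- symmetrize(K[train_idx, train_idx, drop = FALSE])
  Kts <- K[test_idx, train_idx, drop = FALSE]
  ev <- eigen(Ktt, symmetric = TRUE)
  s <- pmax(ev$values, 0)
  resid <- Y[train_idx, , drop = FALSE] -
    cbind(1, X[train_idx, , drop = FALSE]) %*% B
  tt <- .trait_transform(Cg, fit$cov_hat$Ce, jitter_warn = FALSE)
  W <- .block_weights(s, tt$d)
  Rt <- (crossprod(ev$vectors, resid)) %*% t(tt$A)
  Z <- ev$vectors %*% ((Rt * W) %*% tt$A)
  pred + Kts %*% Z %*% Cg
}

#' Per-trait Pearson prediction accuracy
#'
#' @param observed,predicted numeric `n_test x q` matrices.
#' @return numeric vector of per-trait correlations; `NA` where either
#'   column is constant.
#' @export
pearson_accuracy <- function(observed, predicted) {
  observed <- as.matrix(observed); predicted <- as.matrix(predicted)
  if (!identical(dim(observed), dim(predicted)))
    stop_input("observed and predicted must have identical shapes")
  if (nrow(observed) < 3L) stop_input("need at least 3 test individuals")
  vapply(seq_len(ncol(observed)), function(j) {
    if (stats::sd(observed[, j]) == 0 || stats::sd(predicted[, j]) == 0)
      return(NA_real_)
    stats::cor(observed[, j], predicted[, j])
  }, numeric(1))
}

# Univariate profile ML in an eigenbasis: y ~ N(o * mu, sig2 * (h*s + 1-h)).
.uni_profile_ml <- function(yt, ot, s) {
  n <- length(yt)
  nll_h <- function(h) {
    v <- h * s + (1 - h)
    mu <- sum(ot * yt / v) / sum(ot^2 / v)
    r <- yt - ot * mu
    sig2 <- mean(r^2 / v)
    0.5 * (n * log(2 * pi) + n * log(sig2) + sum(log(v)) + n)
  }
  opt <- stats::optimize(nll_h, c(0, 1 - 1e-8), tol = 1e-10)
  h <- opt$minimum
  # prefer the boundary when it is as good (flat likelihood near h = 0)
  if (nll_h(0) <= opt$objective + 1e-10) h <- 0
  v <- h * s + (1 - h)
  mu <- sum(ot * yt / v) / sum(ot^2 / v)
  sig2 <- mean((yt - ot * mu)^2 / v)
  list(h = h, sigma_g2 = h * sig2, sigma_e2 = (1 - h) * sig2, mu = mu,
       nll = nll_h(h))
}

#' Univariate RR-BLUP baseline
#'
#' Fits, separately per trait, the ridge-regression BLUP of marker
#' effects: `u_hat = X' (X X' + (sigma_e^2 / sigma_u^2) I)^{-1}
#' (y - 1 mu_hat)` with the variance ratio from univariate maximum
#' likelihood on the marker-derived relationship `X X'`, then predicts
#' `X_test u_hat + mu_hat`.
#'
#' @param data an [align()]ed dataset (kinship unused).
#' @param train_idx,test_idx disjoint individual indices.
#' @return `length(test_idx) x q` prediction matrix.
#' @export
rrblup_baseline <- function(data, train_idx, test_idx) {
  if (length(intersect(train_idx, test_idx)))
    stop_input("train and test indices overlap")
  X <- as.matrix(unclass(data$genotypes))
  Y <- as.matrix(unclass(data$traits))
  Xtr <- X[train_idx, , drop = FALSE]
  Xte <- X[test_idx, , drop = FALSE]
  Km <- tcrossprod(Xtr)
  ev <- eigen(symmetrize(Km), symmetric = TRUE)
  s <- pmax(ev$values, 0)
  ot <- as.numeric(crossprod(ev$vectors, rep(1, nrow(Xtr))))
  pred <- matrix(0, length(test_idx), ncol(Y),
                 dimnames = list(rownames(Y)[test_idx], colnames(Y)))
  for (j in seq_len(ncol(Y))) {
    yt <- as.numeric(crossprod(ev$vectors, Y[train_idx, j]))
    ml <- .uni_profile_ml(yt, ot, s)
    if (ml$sigma_g2 <= 0) {
      pred[, j] <- ml$mu
      next
    }
    ratio <- ml$sigma_e2 / ml$sigma_g2
    rt <- yt - ot * ml$mu
    sol <- ev$vectors %*% (rt / (s + ratio))
    u <- crossprod(Xtr, sol)
    pred[, j] <- Xte %*% u + ml$mu
  }
  pred
}

#' Cross-validated genomic prediction accuracy
#'
#' The evaluation protocol for genomic selection: `n_splits` independent
#' seeded train/test splits (default 80/20, with all traits masked in the
#' test set). For the regularized methods, regularization parameters are
#' chosen per split on an inner 20% holdout of the training data
#' ([select_regularization()]), the model is refitted on the full
#' training set, test GEBVs are predicted and scored by per-trait Pearson
#' correlation.
#'
#' @param data an [align()]ed dataset.
#' @param method one of `"mtLMM-L1"`, `"mtLM-L1"`, `"mtLMM-clust"`,
#'   `"mtLM-clust"`, `"rrblup-uni"`.
#' @param n_splits number of random splits.
#' @param test_fraction fraction of individuals per test set.
#' @param grid optional list of [penalty_spec()]s (a compact
#'   lambda-path default is built per split otherwise).
#' @param opts a [fit_options()].
#' @param seed master seed; identical seeds give identical results.
#' @param holdout_fraction inner holdout fraction for parameter selection.
#' @return a `cv_result`: list with `per_split` (`n_splits x q`
#'   correlations), `mean`, `sd`, `split_seeds`.
#' @export
cross_validate <- function(data, method = c("mtLMM-L1", "mtLM-L1",
                                            "mtLMM-clust", "mtLM-clust",
                                            "rrblup-uni"),
                           n_splits = 50L, test_fraction = 0.2, grid = NULL,
                           opts = fit_options(), seed = 1L,
                           holdout_fraction = 0.2) {
  method <- match.arg(method)
  if (test_fraction <= 0 || test_fraction >= 1)
    stop_input("test_fraction must be in (0, 1)")
  n <- nrow(data$traits); q <- ncol(data$traits)
  Y <- as.matrix(unclass(data$traits))
  n_test <- max(3L, round(test_fraction * n))
  if (n - n_test < q + 2L)
    stop_input("split leaves fewer than q + 2 training individuals")
  seeds <- derive_seeds(seed, n_splits)
  per_split <- matrix(NA_real_, n_splits, q,
                      dimnames = list(NULL, colnames(Y)))
  for (b in seq_len(n_splits)) {
    test <- with_seed(seeds[b], sort(sample.int(n, n_test)))
    train <- setdiff(seq_len(n), test)
    if (method == "rrblup-uni") {
      pred <- rrblup_baseline(data, train, test)
    } else {
      model <- if (startsWith(method, "mtLMM")) "mtLMM" else "mtLM"
      clustering <- endsWith(method, "clust")
      train_data <- subset_dataset(data, train)
      eig_tr <- eigendecompose_kinship(train_data$kinship)
      g <- grid %||% .compact_grid(train_data, model, clustering, eig = eig_tr)
      sel <- select_regularization(train_data, g, opts = opts,
                                   holdout_fraction = holdout_fraction,
                                   seed = seeds[b], model = model)
      fit <- fit_regularized_mtlmm(train_data, sel$best, opts, model = model,
                                   eig = eig_tr)
      pred <- predict_gebv(fit, data, train, test)
    }
    per_split[b, ] <- pearson_accuracy(Y[test, , drop = FALSE], pred)
  }
  structure(list(per_split = per_split,
                 mean = colMeans(per_split, na.rm = TRUE),
                 sd = apply(per_split, 2, stats::sd, na.rm = TRUE),
                 split_seeds = seeds, method = method),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("cv_result (", x$method, "), ", nrow(x$per_split), " splits\n", sep = "")
  print(round(rbind(mean = x$mean, sd = x$sd), 3))
  invisible(x)
}
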