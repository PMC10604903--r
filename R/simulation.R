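#' Simulation scenario for QTN effect architecture
#'
#' Four effect structures for the fixed QTN effect matrix `B`:
#' 1. *random* - each trait gets its own random support, effects iid
#'    standard normal;
#' 2. *clustered* - traits are partitioned into groups (by default two
#'    groups of three plus one group of the remaining `q - 6`; empty
#'    groups are dropped) that share a common QTN support, with entries
#'    `mu + eps`, `mu ~ Uniform[-1, 1]` (shared within the group per QTN
#'    by default) and `eps ~ N(0, 0.25)` trait-specific;
#' 3. *mixed* - the sum of a random draw (20 QTNs/trait) and a clustered
#'    draw (80 QTNs/group);
#' 4. *null* - no fixed effects.
#'
#' @param scenario integer 1-4.
#' @param q,p numbers of traits and markers.
#' @param qtn_per_trait QTNs per trait (scenarios 1-2; default 100).
#' @param mixed_split QTN counts `(random, clustered)` for scenario 3.
#' @param groups optional list of trait-index vectors partitioning
#'   `1:q` (scenarios 2-3).
#' @param eps_sd standard deviation of the trait-specific effect noise.
#' @param mu_shared share the Uniform base effect within a group per QTN
#'   (`TRUE`, default) or draw it per (marker, trait) entry.
#' @return a `scenario_spec`.
#' @export
scenario_spec <- function(scenario, q, p, qtn_per_trait = 100L,
                          mixed_split = c(20L, 80L), groups = NULL,
                          eps_sd = 0.5, mu_shared = TRUE) {
  scenario <- as.integer(scenario)
  if (!scenario %in% 1:4) stop_input("scenario must be 1, 2, 3 or 4")
  if (scenario %in% c(2L, 3L)) {
    if (is.null(groups)) {
      if (q < 6L) stop_input("clustered scenarios need q >= 6 (or explicit groups)")
      groups <- list(1:3, 4:6)
      if (q > 6L) groups <- c(groups, list(7:q))
    }
    ug <- sort(unlist(groups))
    if (!identical(ug, seq_len(q)))
      stop_input("groups must partition 1..q")
  }
  need <- if (scenario == 3L) sum(mixed_split) else qtn_per_trait
  if (scenario != 4L && need > p)
    stop_input("QTN count (", need, ") exceeds the number of markers (", p, ")")
  structure(list(scenario = scenario, q = as.integer(q), p = as.integer(p),
                 qtn_per_trait = as.integer(qtn_per_trait),
                 mixed_split = as.integer(mixed_split), groups = groups,
                 eps_sd = eps_sd, mu_shared = isTRUE(mu_shared)),
            class = "scenario_spec")
}

.draw_random_effects <- function(p, q, qtn) {
  B <- matrix(0, p, q)
  for (j in seq_len(q)) {
    rows <- sample.int(p, qtn)
    B[rows, j] <- stats::rnorm(qtn)
  }
  B
}

.draw_clustered_effects <- function(p, q, qtn, groups, eps_sd, mu_shared) {
  B <- matrix(0, p, q)
  for (g in groups) {
    rows <- sample.int(p, qtn)
    if (mu_shared) {
      mu <- stats::runif(qtn, -1, 1)
      for (j in g) B[rows, j] <- mu + stats::rnorm(qtn, sd = eps_sd)
    } else {
      for (j in g) B[rows, j] <- stats::runif(qtn, -1, 1) +
          stats::rnorm(qtn, sd = eps_sd)
    }
  }
  B
}

#' Draw a ground-truth QTN effect matrix
#'
#' @param spec a [scenario_spec()].
#' @param seed RNG seed; identical seeds reproduce the draw bit for bit.
#' @return a `ground_truth`: list with `B_true` (`p x q`), logical
#'   `support` (`B_true != 0`) and the generating [scenario_spec()].
#' @export
generate_effect_matrix <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "scenario_spec"))
  B <- with_seed(seed, switch(as.character(spec$scenario),
    "1" = .draw_random_effects(spec$p, spec$q, spec$qtn_per_trait),
    "2" = .draw_clustered_effects(spec$p, spec$q, spec$qtn_per_trait,
                                  spec$groups, spec$eps_sd, spec$mu_shared),
    "3" = .draw_random_effects(spec$p, spec$q, spec$mixed_split[1]) +
      .draw_clustered_effects(spec$p, spec$q, spec$mixed_split[2],
                              spec$groups, spec$eps_sd, spec$mu_shared),
    "4" = matrix(0, spec$p, spec$q)))
  structure(list(B_true = B, support = B != 0, spec = spec),
            class = "ground_truth")
}

#' Sample from a matrix-variate normal distribution
#'
#' Draws `G = L_row Z L_col'` with `Z` iid standard normal, so that
#' `vec(G)` has covariance `col_cov (x) row_cov`. Positive semi-definite
#' covariances are factored through their (clamped) eigendecompositions.
#'
#' @param row_cov `n x n` PSD row covariance.
#' @param col_cov `q x q` PSD column covariance.
#' @param seed optional RNG seed.
#' @return `n x q` numeric matrix.
#' @export
sample_matrix_normal <- function(row_cov, col_cov, seed = NULL) {
  psd_factor <- function(C) {
    C <- as.matrix(C)
    if (!is_symmetric_tol(C, 1e-8)) stop_input("covariance must be symmetric")
    ev <- eigen(symmetrize(C), symmetric = TRUE)
    if (min(ev$values) < -1e-8 * max(1, abs(ev$values[1])))
      stop_input("covariance is not positive semi-definite")
    ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  }
  Lr <- psd_factor(row_cov)
  Lc <- psd_factor(col_cov)
  n <- nrow(Lr); q <- nrow(Lc)
  draw <- function() Lr %*% matrix(stats::rnorm(n * q), n, q) %*% t(Lc)
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Simulate phenotypes from the multi-trait mixed model
#'
#' `Y = X B_true + G + E` with `G ~ N(0, Cg, K)` and `E ~ N(0, Ce, I)`
#' (matrix-variate normals with column covariances `Cg`, `Ce`).
#'
#' @param genotypes `n x p` [genotype_matrix()] (the scale of `B_true`
#'   refers to this coding).
#' @param kinship `n x n` [kinship_matrix()].
#' @param truth a `ground_truth` from [generate_effect_matrix()].
#' @param cov a [covariance_pair()].
#' @param seed RNG seed.
#' @return a [trait_matrix()].
#' @export
simulate_phenotypes <- function(genotypes, kinship, truth, cov, seed = 1L) {
  X <- as.matrix(unclass(genotypes))
  K <- as.matrix(unclass(kinship))
  B <- truth$B_true
  if (ncol(X) != nrow(B) || nrow(X) != nrow(K))
    stop_input("shape mismatch between genotypes, kinship and effects")
  n <- nrow(X); q <- ncol(B)
  Y <- with_seed(seed, {
    G <- sample_matrix_normal(K, cov$Cg)
    E <- sample_matrix_normal(diag(n), cov$Ce)
    X %*% B + G + E
  })
  rownames(Y) <- rownames(X)
  colnames(Y) <- paste0("trait", seq_len(q))
  trait_matrix(Y)
}

#' Synthetic structured genotypes (Balding-Nichols model)
#'
#' Individuals are split evenly into subpopulations. Each marker gets an
#' ancestral frequency uniform on `maf_range`; subpopulation frequencies
#' are Beta-distributed around it with parameter
#' `Fst` (`Beta(p(1-Fst)/Fst, (1-p)(1-Fst)/Fst)`), and genotypes are
#' `Binomial(2, freq)` draws. This induces the population structure a
#' mixed model must correct for. Monomorphic columns are resampled.
#'
#' @param n,p numbers of individuals and markers.
#' @param n_subpops number of subpopulations.
#' @param fst differentiation parameter in `[0, 1)`; 0 means no structure.
#' @param maf_range ancestral minor-allele frequency range, inside (0, 0.5].
#' @param seed RNG seed.
#' @return a raw-coded [genotype_matrix()] with a `subpop` attribute.
#' @export
generate_structured_genotypes <- function(n, p, n_subpops = 2L, fst = 0.1,
                                          maf_range = c(0.05, 0.5),
                                          seed = 1L) {
  if (fst < 0 || fst >= 1) stop_input("fst must be in [0, 1)")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop_input("maf_range must be inside (0, 0.5]")
  pop <- rep(seq_len(n_subpops), length.out = n)
  X <- with_seed(seed, {
    draw_col <- function() {
      anc <- stats::runif(1, maf_range[1], maf_range[2])
      f <- if (fst == 0) rep(anc, n_subpops)
      else stats::rbeta(n_subpops, anc * (1 - fst) / fst,
                        (1 - anc) * (1 - fst) / fst)
      stats::rbinom(n, 2, f[pop])
    }
    M <- matrix(0, n, p)
    for (j in seq_len(p)) {
      x <- draw_col()
      tries <- 0L
      while (length(unique(x)) < 2L && tries < 50L) {
        x <- draw_col()
        tries <- tries + 1L
      }
      M[, j] <- x
    }
    M
  })
  rownames(X) <- paste0("ind", seq_len(n))
  colnames(X) <- paste0("m", seq_len(p))
  out <- genotype_matrix(X, coding = "raw012")
  attr(out, "subpop") <- pop
  out
}

#' Default trait covariances for synthetic phenotypes
#'
#' Genetic covariance with unit variances and correlation `within_cor`
#' inside each trait group (zero between groups); diagonal residual
#' covariance. When a ground-truth effect matrix on standardized markers
#' is supplied, both are rescaled so the total genetic-plus-residual
#' variance matches the total fixed-effect signal variance (heritability
#' of the QTN signal about one half).
#'
#' @param q number of traits.
#' @param groups optional list of trait groups (defaults to one group).
#' @param B optional `p x q` true effect matrix (standardized-marker scale).
#' @param K optional kinship (its mean diagonal scales the genetic part).
#' @param within_cor within-group genetic correlation.
#' @return a [covariance_pair()].
#' @export
default_trait_covariances <- function(q, groups = NULL, B = NULL, K = NULL,
                                      within_cor = 0.5) {
  Cg <- diag(q)
  if (!is.null(groups))
    for (g in groups) Cg[g, g] <- within_cor + (1 - within_cor) * diag(length(g))
  Ce <- diag(q)
  if (!is.null(B) && any(B != 0)) {
    signal <- sum(B^2)  # Var(XB) trace for standardized, uncorrelated markers
    kbar <- if (is.null(K)) 1 else mean(diag(as.matrix(unclass(K))))
    noise <- kbar * sum(diag(Cg)) + sum(diag(Ce))
    sc <- signal / noise
    Cg <- Cg * sc
    Ce <- Ce * sc
  }
  covariance_pair(Cg, Ce)
}

#' Score a detected support against the truth
#'
#' True/false positives and negatives are counted over (marker, trait)
#' cells. Conventions: precision is 1 when nothing is detected; F1 is 0
#' when there are no true positives but some error exists, and 1 when
#' estimated and truth agree exactly. The false positive rate divides by
#' the number of truly-null cells.
#'
#' @param estimated,truth logical matrices of identical shape.
#' @return a `detection_metrics` list: `precision`, `recall`, `f1`,
#'   `fpr`, and the raw counts.
#' @export
evaluate_detection <- function(estimated, truth) {
  estimated <- as.matrix(estimated); truth <- as.matrix(truth)
  if (!identical(dim(estimated), dim(truth)))
    stop_input("estimated and truth supports differ in shape")
  tp <- sum(estimated & truth)
  fp <- sum(estimated & !truth)
  fn <- sum(!estimated & truth)
  n_null <- sum(!truth)
  precision <- if (tp + fp == 0) 1 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 1 else tp / (tp + fn)
  f1 <- if (tp == 0) {
    if (fp == 0 && fn == 0) 1 else 0
  } else 2 * precision * recall / (precision + recall)
  fpr <- if (n_null == 0) 0 else fp / n_null
  structure(list(precision = precision, recall = recall, f1 = f1, fpr = fpr,
                 tp = tp, fp = fp, fn = fn, n_null = n_null),
            class = "detection_metrics")
}

#' Detection benchmark over simulated phenotype replicates
#'
#' For each scenario and replicate: draw a ground-truth effect matrix,
#' simulate phenotypes from the multi-trait mixed model on the supplied
#' genotypes/kinship, run each detection method, and score it against the
#' truth. Single-marker methods detect via BH-significant tests; the
#' regularized methods via nonzero coefficients (with regularization
#' chosen per replicate on an inner holdout). The multi-trait
#' single-marker scan detects at marker level and is scored against the
#' marker-level truth (a marker is causal if it affects any trait);
#' trait-resolved methods are scored over (marker, trait) cells.
#'
#' @param genotypes,kinship the genotype and kinship matrices to simulate
#'   on (markers typically standardized).
#' @param scenarios a [scenario_spec()] or list of them.
#' @param methods subset of the six detector names (see
#'   [stability_counts()]).
#' @param cov optional [covariance_pair()]; by default rebuilt per
#'   replicate from the drawn effects via [default_trait_covariances()].
#' @param n_replicates trait replicates per scenario.
#' @param fdr BH level for the single-marker methods.
#' @param seed master seed.
#' @param grid,opts passed to the regularized detectors.
#' @return list with `summary` (mean and sd of precision/recall/F1/FPR
#'   per scenario and method) and `replicates` (per-replicate table).
#' @export
run_scenario_benchmark <- function(genotypes, kinship, scenarios,
                                   methods = .method_names, cov = NULL,
                                   n_replicates = 50L, fdr = 0.05, seed = 1L,
                                   grid = NULL, opts = fit_options()) {
  if (inherits(scenarios, "scenario_spec")) scenarios <- list(scenarios)
  methods <- match.arg(methods, .method_names, several.ok = TRUE)
  K <- kinship
  rows <- list()
  for (sc in scenarios) {
    seeds <- derive_seeds(seed + sc$scenario, n_replicates)
    for (r in seq_len(n_replicates)) {
      truth <- generate_effect_matrix(sc, seed = seeds[r])
      cov_r <- cov %||% default_trait_covariances(
        sc$q, groups = sc$groups, B = truth$B_true, K = K)
      Y <- simulate_phenotypes(genotypes, K, truth, cov_r, seed = seeds[r] + 1L)
      data <- structure(list(traits = Y, genotypes = genotypes, kinship = K),
                        class = "aligned_dataset")
      truth_marker <- matrix(apply(truth$support, 1, any), ncol = 1)
      for (m in methods) {
        det <- .detect_support(data, m, fdr = fdr, grid = grid, opts = opts,
                               select_seed = seeds[r])
        tr <- if (ncol(det) == 1L) truth_marker else truth$support
        met <- evaluate_detection(det, tr)
        rows[[length(rows) + 1L]] <- data.frame(
          scenario = sc$scenario, method = m, replicate = r,
          precision = met$precision, recall = met$recall,
          f1 = met$f1, fpr = met$fpr)
      }
    }
  }
  reps <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(reps, list(reps$scenario, reps$method),
                                     drop = TRUE), function(d)
    data.frame(scenario = d$scenario[1], method = d$method[1],
               precision = mean(d$precision), recall = mean(d$recall),
               f1 = mean(d$f1), f1_sd = stats::sd(d$f1),
               fpr = mean(d$fpr), fpr_sd = stats::sd(d$fpr))))
  rownames(agg) <- NULL
  list(summary = agg, replicates = reps)
}
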