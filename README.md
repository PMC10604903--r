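# regmtlmm

Regularized multi-trait linear mixed models for genome-wide association
studies (GWAS) and genomic selection (GS) in structured populations.

## The problem

Diversity panels — the workhorse design of plant quantitative genetics —
mix subpopulation structure with uneven familial relatedness. Any model
that ignores this confounding mistakes ancestry for biology. The standard
correction is the linear mixed model with a genomic relationship (kinship)
random effect, but its common forms test one marker and one trait at a
time. `regmtlmm` fits the *joint* model for `q` traits and all `p`
markers at once:

    Y = X B + G + E,    G ~ N(0, C_g ⊗ K),    E ~ N(0, C_e ⊗ I)

with a penalized likelihood

    min  −log L(B, C_g, C_e) + λ Σ|B_ij| + γ Σ_(j,j') c_jj' ‖B_:j − B_:j'‖₂

The L1 term selects markers in the `p ≫ n` regime; the convex-clustering
term couples traits that share genetic architecture. Estimation uses
accelerated proximal gradient steps in the kinship eigenbasis (no
`nq × nq` matrix is ever formed) alternating with quasi-Newton updates of
the Cholesky-parameterized trait covariances.

The package also provides the classical single-marker single-trait and
multi-trait scans with Benjamini–Hochberg FDR control, GEBV prediction
with cross-validation and an RR-BLUP baseline, and a fully seeded
synthetic-data module (Balding–Nichols structured genotypes, matrix-variate
phenotypes, four QTN architectures) for detection benchmarking.

## Worked example

```r
library(regmtlmm)

# synthetic diversity panel: 2 subpopulations, Fst 0.15
G  <- generate_structured_genotypes(120, 100, n_subpops = 2, fst = 0.15,
                                    seed = 33)
Gs <- standardize_genotypes(G)
K  <- compute_vanraden_kinship(G)

# one strong marker effect on trait 1
X <- unclass(Gs)
set.seed(1)
Y <- matrix(rnorm(120 * 3), 120, 3)
Y[, 1] <- Y[, 1] + 1.2 * X[, 7]
rownames(Y) <- rownames(X); colnames(Y) <- paste0("t", 1:3)
d <- align(trait_matrix(Y), Gs, K)

# multi-trait single-marker scan
sm <- scan_multi_trait(d, fdr = 0.05)
which.min(sm$pvalue)   # 7
min(sm$pvalue)         # 1.04e-13
sum(sm$rejected)       # 1

# joint regularized fit
lmax <- lambda_max(d)
fit  <- fit_regularized_mtlmm(d, penalty_spec(0.4 * lmax, 0, q = 3))
fit   # fit_result (mtLMM): lambda=24.5 gamma=0; 9 nonzero effects; converged
b <- fit$B_hat[-1, 1]
names(which.max(abs(b)))   # "m7", coefficient 1.0 (next largest: 0.04)
```

The scan pinpoints marker 7 with a `χ²₃` p-value of `1.04e-13` (the only
BH rejection at FDR 5%); the penalized joint fit puts a coefficient of
`1.0` on the same marker in trait 1's column — close to the simulated
effect of 1.2 after shrinkage — with every other selected coefficient
more than twenty times smaller.

For prediction, `cross_validate(d, "mtLMM-L1", n_splits = 50, seed = 1)`
runs seeded 80/20 splits with per-split holdout selection of `λ` (and `γ`)
and reports per-trait Pearson accuracies; `rrblup_baseline()` gives the
standard univariate comparator.

A thin command-line wrapper with `kinship`, `fit`, `gwas`, `cv` and
`simulate` subcommands lives at `inst/cli/regmtlmm.R`.

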