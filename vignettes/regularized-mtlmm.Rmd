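---
title: "Regularized multi-trait linear mixed models: model, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regularized multi-trait linear mixed models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regmtlmm)
```

## The model

`regmtlmm` models $q$ traits measured on $n$ individuals jointly with $p$
genome-wide markers:

$$Y = XB + G + E, \qquad
G \sim N_{n\times q}(0,\, C_g,\, K), \qquad
E \sim N_{n\times q}(0,\, C_e,\, I_n),$$

where $Y$ is $n \times q$, $X$ is the $n \times p$ marker matrix (plus an
unpenalized trait-wise intercept), $B$ is the $p \times q$ matrix of fixed
marker effects, $K$ is the genomic relationship (kinship) matrix, and
$C_g$, $C_e$ are $q \times q$ genetic and residual trait covariances.
Equivalently $\mathrm{vec}(Y) \sim N_{nq}(\mathrm{vec}(XB),\,
C_g \otimes K + C_e \otimes I_n)$.

The random term $G$ is what distinguishes this from a multi-trait linear
model (mtLM): in diversity panels, individuals cluster into subpopulations
and differ in familial relatedness, and without $G$ the strongest
associations tend to be artifacts of that structure. The package fits both
variants (`model = "mtLMM"` / `"mtLM"`) so the effect of the correction
can be measured.

Because all $p$ markers enter the fixed design at once ($p \gg n$ is the
norm), the fit is penalized:

$$\min_{B, C_g, C_e}\; -\!\log L(B, C_g, C_e) \;+\;
\lambda \sum_{ij} |B_{ij}| \;+\;
\gamma \sum_{(j,j') \in E} c_{jj'}\, \lVert B_{:j} - B_{:j'} \rVert_2 .$$

The L1 term performs marker selection. The second, convex-clustering term
shrinks whole trait *effect profiles* toward one another and is the tool
for trait groups that share genetic architecture (pleiotropy, strongly
correlated traits). The trait graph defaults to the complete graph with
unit weights; `penalty_spec()` accepts prior edge weights $c_{jj'}$. The
norm in the clustering term is Euclidean, consistent with the convex
clustering literature.

## Likelihood evaluation

Nothing in the package ever forms the $nq \times nq$ covariance. With the
eigendecomposition $K = U\,\mathrm{diag}(s)\,U'$, rotating $Y$ and $X$ by
$U'$ makes the rows independent $q$-variate normals with covariance
$V_i = s_i C_g + C_e$. A simultaneous diagonalization of $(C_g, C_e)$
(solve $A C_e A' = I$, $A C_g A' = \mathrm{diag}(d)$) then reduces every
block inverse to elementwise weights $1/(1 + s_i d_j)$, so one likelihood
or gradient evaluation costs $O(npq + nq^2 + q^3)$. The dense Kronecker
construction exists only in the test suite, as an independent oracle; the
two agree to $10^{-8}$ relative on randomized instances.

## Estimation

`fit_regularized_mtlmm()` alternates:

* **B-step** — accelerated proximal gradient (FISTA) with backtracking
  from an initial step $1/\hat L$,
  $\hat L = \lambda_{\max}(\tilde X'\tilde X)\cdot\max_i
  \lambda_{\max}(V_i^{-1})$ (the smallest block eigenvalue is evaluated
  only at the extreme kinship eigenvalues — it is concave in $s$). The
  inner stop compares objective progress over ten-iteration windows, which
  is robust to the slow early progress typical of warm starts. The
  returned iterate is the best one seen, so a B-step never increases the
  objective.
* **Covariance step** — L-BFGS on Cholesky factors $C_g = L_g L_g'$,
  $C_e = L_e L_e' + 10^{-8} I$ with analytic gradients, holding $B$ fixed.
  A step that fails to improve the objective is discarded.

The outer loop stops when the relative change of the penalized objective
falls below `outer_tol`; the recorded `objective_trace` is non-increasing
by construction, and the test suite enforces this on every fit it runs.

The proximal operator of the combined penalty has no closed form; it is
solved by ADMM, splitting off the L1 copy (soft threshold) and one copy
per trait-graph edge (block soft threshold). The quadratic tie involves
only a $q \times q$ graph Laplacian, solved in its eigenbasis. With
$\gamma = 0$ the operator short-circuits to exact soft thresholding. The
ADMM state can be warm-started between consecutive FISTA iterations,
which cuts the inner iteration count sharply without changing the
solution; accuracy is certified in the tests against a projected-ascent
dual bound (duality gap below $10^{-5}$).

Defaults (`fit_options()`): `outer_max = 50`, `outer_tol = 1e-6`,
`fista_max = 500`, `fista_tol = 1e-7`, backtracking factor `0.5`; ADMM
uses $\rho = 1$, 200 iterations, tolerance $10^{-6}$. Initialization is
$B = 0$ with the intercept at its GLS optimum and
$C_g = C_e = \tfrac12\,\widehat{\mathrm{cov}}(Y)$ — a symmetric,
scale-aware start. The optimizer is deterministic; seeds only ever govern
data splits and simulation draws.

Two numerical notes learned the hard way. First, ML covariance estimates
can land on the PSD boundary ($\lambda_{\min}(\hat C_e) \to 0$), which is
statistically legitimate but makes $1/\hat L$ collapse; warm starts along
a regularization path therefore carry only $B$ and re-initialize the
covariances. Second, the intercept is placed at its GLS optimum before
the first B-step so that $B = 0$ is an exact fixed point whenever
$\lambda \ge \lambda_{\max}$ (`lambda_max()` computes that threshold at
the initial covariances).

### Hyperparameters

`default_penalty_grid()` spaces ten $\lambda$ values logarithmically over
$[\,0.01\lambda_{\max},\, \lambda_{\max}]$, crossed with $\gamma = 0$ plus
a five-point grid on the same scale when clustering is on.
`select_regularization()` implements holdout selection: a single 20%
holdout of the training individuals, scored by mean per-trait Pearson
correlation of the holdout GEBVs, ties broken toward stronger
regularization. This is the protocol used inside the cross-validation
loop, where prediction is the target quantity.

The detection benchmark uses the same holdout-selection protocol, with
three safeguards that matter when the target is the *support* rather than
the prediction. The compact default grid starts at $\lambda_{\max}$
itself, so the empty model — which for the mixed variants still predicts
through the genomic-BLUP channel — competes in the holdout scoring and
wins on data without marker signal. A saturation cap (`dfmax`) discards
fits whose support exceeds a fraction of `n × q`, since such fits carry
no selection information and dominate runtime. And `γ` is tied to
`λ` by a fixed factor of one half, playing the role of a mixing parameter
as in sparse-group penalties. An optional one-standard-error parsimony
rule (`one_se`) is available but not used by default: prediction through
the genetic random effect is strong enough in these panels that the rule
tends to collapse every regularized fit to the empty model. Information
criteria (BIC/EBIC) were rejected for the same regime-specific reason in
reverse — under weak per-QTN signal the likelihood gain of a true QTN
sits below their complexity charge, so they return the empty model
outright.

## GWAS scans and detection

`scan_single_trait()` / `scan_multi_trait()` are the classical
single-marker baselines: variance components are estimated once under the
intercept-only null model (`fit_variance_components_null()`) and reused
for every marker — the faster of the two conventions in the single-marker
literature — then each marker gets an exact GLS estimate and a Wald
$\chi^2_1$ (per trait) or $\chi^2_q$ (joint) test, with Benjamini-Hochberg
control applied across the markers of a scan. In the decorrelated trait
basis the $q$-df Wald statistic is computed as a sum of independent 1-df
pieces, which makes the scan a handful of vectorized passes over the
marker matrix.

Regularized methods declare a (marker, trait) pair detected when
$|\hat B_{ij}| > 10^{-8}$ on the standardized-marker scale
(`detected_support()`). The multi-trait single-marker scan detects at
marker level (one p-value per marker); stability summaries
(`stability_counts()`) therefore report per-trait frequencies plus the
per-marker maximum across traits, and the simulation benchmark scores
that method against the marker-level truth (a marker is causal if it
affects any trait).

When kinship eigenvalues are all equal ($K \propto I$), $C_g$ and $C_e$
are not separately identifiable — only their sum enters any $V_i$ — so
the null fit warns and pins $C_g = 0$.

## Genomic prediction

GEBVs for unphenotyped individuals combine the fixed part with the
conditional mean of the genetic effect given the training residuals:
$\hat G_{\text{test}} = (C_g \otimes K_{ts})\,
(C_g \otimes K_{tt} + C_e \otimes I)^{-1}\,
\mathrm{vec}(Y_{\text{tr}} - X_{\text{tr}}\hat B)$, evaluated in the
$K_{tt}$ eigenbasis. Whether the genetic BLUP term belongs in the GEBV at
all is a genuine modelling choice; it is included here because the fitted
$\hat C_g$, $\hat C_e$ exist precisely to be used, and the mtLM variant
($\hat G = 0$) provides the contrast. `cross_validate()` runs the
evaluation protocol — independent seeded 80/20 splits with all traits
masked in the test set, per-split hyperparameter selection on an inner
20% holdout, refit on the full training set, per-trait Pearson accuracy —
and `rrblup_baseline()` supplies the standard univariate ridge-regression
BLUP comparator (variance ratio from univariate ML on the marker-derived
relationship $XX'$).

## The synthetic-data generator

Because the real diversity-panel data live in an external repository, the
package carries a generator that emulates their shape:

* `generate_structured_genotypes()` — Balding-Nichols subpopulation
  structure: ancestral frequencies uniform on `maf_range`, subpopulation
  frequencies Beta-distributed with differentiation parameter $F_{st}$,
  genotypes Binomial(2, freq). This produces the confounding (kinship
  block structure) that the mixed model exists to correct; it does *not*
  reproduce linkage-disequilibrium decay, so detection here is free of
  the "hit in LD with the causal site" ambiguity of real panels.
* `generate_effect_matrix()` — the four QTN architectures: trait-specific
  random supports (iid standard normal effects); group-clustered supports
  (traits partitioned into two groups of three plus the remainder, QTN
  base effect $\mu \sim U[-1,1]$ shared within a group, trait-specific
  noise $N(0, 0.25)$); their superposition (20 + 80 QTNs); and the global
  null. The shared-$\mu$ reading makes group members have *similar*
  effects, which is the regime where trait clustering can help at all; a
  per-entry $\mu$ is available behind `mu_shared = FALSE`.
* `default_trait_covariances()` — unit-variance $C_g$ with within-group
  correlation 0.5, diagonal $C_e$, both rescaled so the total
  genetic-plus-residual variance equals the total fixed-QTN signal
  variance (QTN-signal heritability about one half).

Under that calibration each individual QTN explains a small slice of a
trait's variance (with 20 QTNs per group, roughly 2.5%), which is the
deliberately hard regime: passing the benchmark tests shows the methods
rank sensibly under weak polygenic-like signal, not that any of them
recovers such supports cleanly. A second caveat: the synthetic kinship is
built from the *same* few hundred markers that carry the QTNs, so the
random effect can partially absorb fixed QTN signal; real panels, with
orders of magnitude more markers, dilute this effect.

## Problem sizes used by the checks

The test suite and the acceptance script run entirely on generated data
at desk scale: dense-oracle comparisons at $n \le 14$, $q \le 4$;
calibration with 50 null replicates at $n = 120$, $p = 150$, $q = 3$;
covariance recovery at $n = 400$, $q = 2$ over 20 seeds; and the scenario
benchmark at $n = 200$, $p = 500$, $q = 6$ with 20 trait replicates
(clustered scenario with 20 QTNs per group, and the null scenario for
false-positive rates). These sizes are the package's own reproducibility
choices; the full-size experiments of the original studies additionally
require the external maize/sorghum panels.

## Known limitations

* No P-values for regularized estimates: inference after selection is an
  open problem and deliberately out of scope; the scans provide the
  calibrated-test route.
* The fitted objective is penalized ML, not REML; variance components
  from the null model carry the usual downward ML bias at small $n$.
* The clustering penalty helps only when trait groups truly share
  effect profiles; under trait-specific architectures it can only cost
  accuracy (its weight should then be selected to zero or near zero).
* SCAD-type nonconvex penalties, Bayesian comparators, multi-kernel and
  GxE extensions are not implemented.
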