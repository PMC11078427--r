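---
title: "Comparing polygenic score performance with correlation contrasts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing polygenic score performance with correlation contrasts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corcompare)
```

## The problem and the model

For a given quantitative trait there are usually many candidate polygenic
scores (PGS), built from different discovery GWAS, optimization methods and
LD reference panels, and their predictive performance differs across
populations. A natural performance scale is the Pearson correlation between
a score and the outcome: for standardized outcome and score, the
least-squares slope equals the correlation $r_{xy}$ and its square equals
the model $R^2$, so correlation-based comparisons generally agree with
$R^2$-based ones for pairwise questions while extending to joint,
multi-score, multi-population hypotheses.

With $P$ scores and $K$ independent population samples, let
$\rho_{i,j}$ be the population correlation of score $i$ with the outcome in
population $j$, and stack the sample estimates population-major (score
index fastest):

$$u = (r_{1,1},\dots,r_{P,1},\; r_{1,2},\dots,r_{P,K}).$$

For large $n$, $u - \mu \sim N(0, \Sigma_\infty(u))$, where the covariance
of two sample correlations sharing the outcome within one population is

$$\operatorname{var}(r_i) = \frac{(1-r_i^2)^2}{n},\qquad
\operatorname{cov}(r_i, r_j) = \frac{\phi_{ij}(1 - r_i^2 - r_j^2)
  - \tfrac12 r_i r_j (1 - r_i^2 - r_j^2 - \phi_{ij}^2)}{n},$$

with $\phi_{ij}$ the correlation between the two scores. Population
correlations entering these formulas are replaced by their sample plug-in
estimates, the standard practice for this family of statistics. In the
parametric mode the $K$ samples are independent, so $\Sigma_\infty(u)$ is
block-diagonal with exact zeros between populations.

Any linear hypothesis $H_0: A\mu = \mu_0$ with an $m$-row, full-row-rank
contrast matrix $A$ is tested with the quadratic form

$$S = (Au - \mu_0)'\,(A \Sigma_\infty(u) A')^{-1}\,(Au - \mu_0)
  \;\sim\; \chi^2_{m},$$

and three built-in contrasts cover the ANOVA-like questions:

* **within** ($m = P-1$): do the scores have equal mean correlation with
  the outcome, averaged over populations? Rows carry $+1/K$ for score 1 and
  $-1/K$ for each other score, in every population.
* **between** ($m = K-1$): is the mean score-outcome correlation equal
  across populations? Rows carry $\pm 1/P$.
* **interaction** ($m = (P-1)(K-1)$): is the pattern of score differences
  the same in every population? Double-difference rows with entries in
  $\{+1,-1,0\}$.

Score 1 and population 1 anchor the built-in contrasts. This choice is
cosmetic: $S$ is invariant to replacing $A$ with $MA$ for any invertible
$M$, which the test suite checks numerically, but it fixes the sign and
meaning of the reported contrast estimates $Au$.

```{r example}
set.seed(7)
mats <- build_setting_matrices("III", tau = 0.4, phi = 0.5, delta = 0.1)
df <- rbind(
  local({s <- simulate_population(mats$A, 1500, "A")
         data.frame(pop = "A", y = s$y, s$X)}),
  local({s <- simulate_population(mats$B, 1500, "B")
         data.frame(pop = "B", y = s$y, s$X)}))
fit <- corcompare(y ~ PGS1 + PGS2 + PGS3 | pop, data = df)
fit
```

## Preprocessing

`corcompare()` mirrors standard PGS evaluation practice:

* **Complete-case filtering** over the used columns (outcome, group,
  scores, covariates). No imputation is attempted.
* **Inverse-rank normalization** (`int = TRUE`) maps the outcome through
  `qnorm((rank - c) / (n - 2c + 1))` with the Blom offset $c = 3/8$ and
  average ranks for ties. The offset is configurable in
  `inverse_rank_normalize()`; any choice gives the same correlations up to
  the (tiny) difference in the normal scores, and rank-based transforms are
  invariant under increasing transformations of the raw outcome. The
  transform is applied once to the pooled outcome, before grouping.
* **Covariate residualization** (`covariates = ...`): outcome *and* every
  score are replaced by their least-squares residuals on an intercept plus
  the covariates, *within each population*, before correlating. With
  genetic principal components as covariates this guards the correlations
  against confounding by population structure — and is the reason these
  tests are recommended for quantitative outcomes only, since a binary
  outcome cannot be residualized this way with a linear model.
* **Standardization** is available (`standardize()`) but never required:
  Pearson correlations are invariant to affine rescaling. Sample standard
  deviations use the $n-1$ denominator throughout.

A correlation at or below zero is flagged (never altered): a PGS should
correlate positively with its intended outcome, and a negative value
usually means the effect alleles were flipped when the score was computed.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `method` | `"parametric"` | Covariance of $u$: asymptotic formulas, or bootstrap (`"bootstrap"`/`"permutation"`) |
| `level` | 0.95 | Confidence level for per-correlation and pairwise intervals |
| `n_boot` | 1000 | Bootstrap replicates for $\hat\Sigma(u)$ |
| `n_perm` | 1000 | Permutations for the permutation p-value |
| `offset` | 3/8 | Rank offset of the inverse-normal transform |

The asymptotic mode is accurate for population samples of roughly 500
individuals or more; below that the package emits an advisory warning and
the nonparametric mode is preferable. All correlations live on the unit
scale, so parameters like `tau`, `phi`, `delta` below are unitless.

## Nonparametric mode

The bootstrap covariance resamples individuals with replacement
independently within each population, recomputes $u$ per replicate, and
takes the replicate covariance (denominator $n_{boot}-1$). Cross-population
blocks are *estimated* rather than forced to zero, dropping the
independence assumption of the parametric mode. A replicate that produces a
constant column is redrawn (at most 100 times).

Permutation p-values need an exchangeability argument, and the scheme is an
explicit modelling choice of this package, flagged in the output:

* **between**: under the null the joint distribution of (outcome, scores)
  is the same in every population, so individuals are pooled and population
  labels reassigned at random (sizes preserved);
* **within / interaction**: under the null the score columns are
  exchangeable given a common inter-score correlation, so the $P$ score
  labels are shuffled independently for each individual.

The observed statistic uses the bootstrap covariance; permuted statistics
recompute $u$ only, holding that covariance fixed. The p-value uses the
add-one rule $p = (1 + \#\{S_{perm} \ge S_{obs}\})/(1 + n_{perm})$, so it
is never exactly zero. Per-population RNG streams are derived
deterministically from the plan's seed, making results independent of
population ordering and bit-reproducible.

## Numerical choices

* $\Sigma$ is symmetrized as $(\Sigma + \Sigma')/2$; eigenvalues below
  $-10^{-10}\lambda_{max}$ raise an error, smaller negative ripples are
  tolerated and handled at inversion time.
* If $A\Sigma A'$ is numerically singular (reciprocal condition number
  below $10^{-12}$ — e.g. nearly collinear scores), the test falls back to
  the Moore–Penrose pseudo-inverse with degrees of freedom equal to the
  numerical rank, and warns.
* A contrast supplied with linearly dependent rows is rank-reduced with a
  warning; $\mu_0$ defaults to zero for all built-ins.
* Degenerate pairwise differences (zero estimated variance) return a
  zero-width interval with a warning rather than failing.

## What the simulation engine emulates

`run_experiment()` reproduces the classic two-population, three-score
study design. Outcome and scores are jointly multivariate normal with unit
variances; within each population all scores share the inter-score
correlation $\phi$, and the outcome row encodes the design: setting I
perturbs the last score's outcome correlation from $\tau$ to $\tau+\delta$
in *both* populations (a within alternative), setting II raises *all*
scores in population B (a between alternative), setting III perturbs the
last score in population B only (an interaction alternative). $\delta = 0$
is the global null in every setting. Parameter combinations whose
correlation matrix is not positive semi-definite are refused by
`build_setting_matrices()` and reported as skipped by the CLI grid runner,
never silently adjusted.

Each replicate draws the two samples, runs the three tests and records
rejections at each requested level (defaults 0.025 and 0.05); replicate $r$
uses a deterministic child seed of the configuration seed, so experiments
can be split or reordered without changing results. The problem sizes used
by the package's own validation suite follow the study design directly:
1000 replicates of $n = 1000$ per population for the type-I-error and
power checks, 200{,}000 Monte-Carlo datasets for the covariance oracle,
and 2000 bootstrap replicates at $n = 5000$ for the
parametric/nonparametric agreement check; smaller draws are used where a
property (determinism, monotonicity trends) does not need full precision.

Because the generator is multivariate normal, passing these checks says
nothing about heavy tails, skewness, nonlinear score-outcome
relationships, or outcome measurement artifacts in real cohorts — the
inverse-rank normalization exists precisely because real phenotypes are
not normal. The generator also draws populations independently, so it
cannot probe violations of the parametric independence assumption (the
bootstrap covariance exists for that), and it makes all scores
exchangeable up to the single perturbed one.

## Known limitations

* Correlation comparisons, not nested-model or $R^2$-decomposition
  comparisons; no multiple-testing correction is applied by the engine
  (raw p-values are reported, as is conventional here).
* Quantitative outcomes only; binary/disease outcomes cannot be
  residualized for covariates with a linear model and are deliberately
  unsupported.
* Unequal population sizes are handled, but the precision of each
  population's correlations scales with its own $n$; interpret pairwise
  intervals with that in mind.
* The asymptotic covariance ignores $O(1/n^2)$ terms; at $n < 500$ use the
  nonparametric mode.
```
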