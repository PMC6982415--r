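---
title: "Residual-permutation tests for the mediated indirect effect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residual-permutation tests for the mediated indirect effect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medperm)
```

## The model and the inferential problem

Single-mediator analysis posits two linear regressions for an exposure
$X$, mediator $M$, outcome $Y$ and covariates $C$:

$$E[Y \mid X, C, M] = \gamma_0 + \gamma_1 X + \gamma_2 C + \gamma_3 M,$$
$$E[M \mid X, C] = \alpha_0 + \alpha_1 X + \alpha_2 C,$$

and quantifies the mediated ("indirect") effect as the product
$\alpha_1\gamma_3$.  Two features make small-sample inference on
$\widehat{\alpha_1\gamma_3}$ awkward.  First, the product of two
approximately normal coefficient estimates is not itself normal, so
normal-theory (Sobel-type) intervals misbehave at small $n$; this
package deliberately computes no standard errors and does all inference
by resampling.  Second, the null hypothesis $\alpha_1\gamma_3 = 0$ is
*composite*: it holds when $\alpha_1 = 0$, when $\gamma_3 = 0$, or both,
and these three configurations give the test statistic different
sampling behaviour.

Covariate adjustment rules out the naive permutation schemes.  Permuting
raw $Y$ breaks not only the association under test but also the $Y$–$C$
association, turning the procedure into a global test of all
coefficients; permuting raw $X$ likewise destroys $X$–$C$ structure.
The package therefore permutes *model residuals*, which are exchangeable
(approximately) under the respective null model while the covariate
structure stays intact.  Raw-data permutation is intentionally not
offered.

## The three permutation procedures

All three tests share one mechanical core.  A base model pair supplies
fitted values and residuals $(\hat Y, e_Y)$ and $(\hat M, e_M)$; each
permutation draws rearranged residual vectors $e_Y^*, e_M^*$, forms the
reconstructed responses $Y^* = \hat Y + e_Y^*$ and $M^* = \hat M +
e_M^*$, and refits the two full models with $Y^*$ and $M^*$ as the
responses.  Following the Freedman–Lane and ter Braak conventions, the
design matrices are never modified: $Y^*$ is regressed on the original
$(X, C, M)$ and $M^*$ on the original $(X, C)$.  (The alternative of
also substituting $M^*$ as a predictor in the outcome refit makes the
full-model procedure's draws null-centred, which would leave its
interval-based decision with essentially no power; the fixed-design
convention is both the classical one and the one that reproduces the
published operating characteristics.)  Because only responses change,
each refitted coefficient is an inner product with a fixed projection
vector — the Frisch–Waugh representation of a single coefficient — so a
permutation run is a pair of matrix products rather than $2 n_{perm}$
QR decompositions.  A test in the suite verifies the identity against
explicit refits at tolerance $10^{-10}$.

**IERM** (indirect effect under reduced models) takes residuals from the
*reduced* fits $Y \sim X + C$ and $M \sim C$, which exclude the
coefficients under test, and compares the observed
$(\hat\alpha_1\hat\gamma_3)_{orig}$ with the permutation distribution of
$\hat\alpha_1^*\hat\gamma_3^*$.  The two-sided p-value is the proportion
of draws with magnitude at least that of the observed product.  Note the
permutation operates under $\alpha_1 = \gamma_3 = 0$ jointly; when
exactly one coefficient is truly zero the observed product (one real
signal times noise) is stochastically larger than the doubly-null draws,
and the test grossly over-rejects.  This is the known miscalibration of
a product statistic calibrated under the wrong member of the composite
null; IERM is included as a subject of study and a cautionary baseline,
not a recommendation.

**PSRM** (permutation supremum test under reduced models) shares the
same permutation stream but records $\hat\alpha_1^*$, $\hat\gamma_3^*$
and their product, producing three two-sided p-values for the observed
$\hat\alpha_1$, $\hat\gamma_3$ and $\hat\alpha_1\hat\gamma_3$.  The null
is rejected only when all three are at or below $\alpha$; the operative
p-value is their maximum.  Requiring each component to be individually
significant is what respects the composite null, and it makes PSRM
conservative where IERM inflates.  The three statistics per permutation
come from the *same* draw — a single permutation loop — not from three
independent runs.

**IEFM** (indirect effect under full models) is the standard comparator:
residuals and fitted values come from the *full* models.  Because the
full-model fitted values retain the estimated signal, the permutation
distribution of $\hat\alpha_1^*\hat\gamma_3^*$ centres near the observed
estimate and acts as a confidence distribution; its $\omega/2$ and
$1-\omega/2$ percentiles are confidence bounds and the null is rejected
when 0 lies outside.  No p-value exists for this procedure — the
decision is interval-based.

Two details of the shared machinery are worth recording:

* *Independent versus joint permutations.*  The procedure descriptions
  permute $e_Y$ and $e_M$ but do not say whether the same rearrangement
  is applied to both vectors.  Independent draws break all associations
  under the null and are the default (`perm_scheme = "independent"`);
  a shared permutation is available as `"joint"`.  Empirically the two
  choices give indistinguishable rejection rates on the simulation grid
  (differences within one Monte-Carlo standard error), so the
  distinction is cosmetic at the scales studied here.
* *Tie handling.*  The p-value convention is the plain proportion
  $b/n_{perm}$ of draws with "equal or greater" magnitude (a smoothed
  $(b+1)/(n_{perm}+1)$ variant is available via `smoothed = TRUE`).
  Magnitude equality is judged to a relative tolerance of $10^{-9}$:
  draws that equal the observed statistic in exact arithmetic (the
  identity permutation is the canonical case) can differ by a few ulps
  when computed along a different floating-point route, and a strict
  `>=` would resolve such ties arbitrarily.  The tolerance is orders of
  magnitude below any statistically meaningful difference between
  draws.
* *Exact enumeration.*  With `exact = TRUE` the tests enumerate all
  permutations ($n \le 6$, where $6! = 720$); under the independent
  scheme the null set is the full cross product of outcome and mediator
  permutations.  An independently coded nested-loop enumeration, with
  OLS solved by the normal equations and permutations from a different
  generator, reproduces the exact p-values bit for bit in the test
  suite.

## Bootstrap comparators

Three case-resampling bootstrap tests are provided for comparison, all
sharing one stream of draws: rows of $(X, C, M, Y)$ are resampled with
replacement, both full models refit, and $\hat\alpha_1^*\hat\gamma_3^*$
recorded.  The percentile (PB) interval takes the $\alpha/2$ and
$1-\alpha/2$ empirical percentiles; the bias-corrected (BCB) interval
shifts the percentile levels by the median-bias constant
$z_0 = \Phi^{-1}(\#\{\theta^* < \hat\theta\}/n_{boot})$ (strict
inequality; ties with the observed value count below with weight 0);
the accelerated (BCAB) interval additionally uses the jackknife
acceleration $a = \sum(\bar\theta - \theta_{-i})^3 / (6[\sum(\bar\theta
- \theta_{-i})^2]^{3/2})$.  All intervals use the same
nearest-order-statistic quantile (index $\lceil q \cdot n \rceil$, no
interpolation) as the permutation module, so every decision is an exact
function of the draws.  The bootstrap count defaults to 10,000 to
parallel the permutation default; the comparison literature does not
fix a count.

## The synthetic-data generator

Simulated datasets are multivariate normal by construction: a condition
is a $4 \times 4$ correlation matrix over $(X, C, M, Y)$, and a dataset
of size $n$ is $Z L^{\top}$ where $L$ is the lower-triangular Cholesky
factor and $Z$ is $n \times 4$ standard normal.  Means are 0 and
variances 1 throughout — the correlation structure *is* the condition,
and the implied regression coefficients follow from population normal
equations on submatrices (`implied_coefficients()`), e.g. $\alpha_1$
solves the $2\times 2$ system for regressing $M$ on $(X, C)$.  These
implied values are exact linear algebra, not simulation, and the test
suite checks them against the published condition tables to the printed
precision.

The generator emulates exactly what the simulation design studied:
continuous jointly normal variables, homoscedastic errors, a single
covariate, linear relationships.  Passing tests therefore say nothing
about non-normal marginals, heteroscedastic or heavy-tailed errors,
discrete exposures, exposure–mediator interaction, or multiple
mediators — all out of scope.

The condition catalogue (`condition_catalogue()`) enumerates three
covariate scenarios — (a) $C$ a covariate of $Y$ only, (b) $C$ a
confounder of $X$–$Y$, (c) $C$ a confounder of $M$–$Y$ — each at weak
(0.15) and strong (0.6) correlation strength, crossed with hypothesis
configurations: both path correlations zero (`null1`), $\rho_{XM} = 0$
with $\rho_{MY} \in \{0.15, 0.3, 0.6\}$ (`null2`, which makes
$\alpha_1 = 0$ exactly under every scenario pattern), and the
$3 \times 3$ alternative grid.  Grid points whose matrices fail positive
definiteness (smallest eigenvalue $\le 10^{-10}$) are dropped — the same
filter the original design applied; scenario c loses three
strong-confounder alternatives this way.  Two design choices were
genuinely open:

* For scenario b, no `null3` ($\alpha_1 \ne 0, \gamma_3 = 0$) rows
  exist: with $\rho_{XY}, \rho_{CY}$ pinned at the scenario strength, no
  grid value of $\rho_{MY}$ makes the partial coefficient $\gamma_3$
  zero, and the published scenario-b null table indeed contains none.
  The catalogue returns an empty null3 list for scenario b.
* For scenarios a and c, `null3` rows are built by *solving* for the
  $\rho_{MY}$ that makes the implied $\gamma_3$ exactly zero given the
  other five correlations ($\rho_{MY} = \rho_{XM}\rho_{XY}$ in scenario
  a, where $C$ is uncorrelated with $X$ and $M$).  This preserves the
  defining property of a null condition — $\alpha_1\gamma_3 = 0$ exactly
  — at the cost of using off-grid correlation values; a mirrored on-grid
  choice ($\rho_{MY} = 0$) would *not* be a null of the indirect effect
  in the presence of confounding, since a zero marginal $M$–$Y$
  correlation does not imply a zero partial $\gamma_3$.

## The simulation harness

`run_study()` estimates a rejection rate by replicated simulation: each
replicate derives a child seed from a stable polynomial hash of
(master seed, replicate index, condition id, method), generates a
dataset, runs the test, and records the decision.  Child seeding makes
every replicate recomputable in isolation and the study invariant to
execution order; the suite tests both properties.  Failed replicates
(e.g. a bootstrap whose draws all fall on one side of the estimate, so
$z_0$ is undefined) are excluded and counted, never redrawn, so a rate
is always a ratio of observed decisions.  `compare_methods()` runs
several methods against the same generated datasets, with bootstrap
variants sharing one set of resampling draws, mirroring how side-by-side
method comparisons were designed.

Monte-Carlo calibration is flagged with Wald bounds: a level-$\alpha$
test run on $R$ replicates should produce a rate within $\alpha \pm
1.96\sqrt{\alpha(1-\alpha)/R}$ — $(0.036, 0.064)$ at $\alpha = 0.05$,
$R = 1000$, to three decimals.  Following the convention of the
published tables, the `exceeds_wald` flag marks only rates *above* the
upper bound (computed unrounded): a conservative test below the lower
bound is not a size violation.

### Problem sizes used in the checks

The published studies used 1,000 replicates with 10,000 permutations per
replicate.  The package's acceptance script reruns the headline cells at
1,000 replicates with 2,000 resamples per replicate, and the stochastic
test-suite checks use 500 replicates; both compare to the published
rates within three binomial standard errors at the replicate count used.
These sizes were chosen once as a desk-verifiable scale: with 2,000
permutations the discreteness of the p-value grid (1/2000) is negligible
relative to binomial noise at $R \le 1000$, so the replicate count, not
the permutation count, dominates the comparison error.

## Numerical choices

* OLS is solved by QR decomposition, never the normal equations; rank
  is checked on the singular values with relative tolerance $10^{-8}$,
  and a deficient design reports the offending column by name
  (exposure–mediator collinearity is the practically relevant case).
* Quantiles of resampling draws are nearest order statistics,
  $\lceil q n \rceil$, with a $10^{-9}$ deduction before the ceiling so
  that a level that is an integer multiple of $1/n$ in exact arithmetic
  (e.g. recovered through a $\Phi/\Phi^{-1}$ round trip in the BC
  construction with $z_0 = 0$) does not spill into the next order
  statistic.
* An observed indirect effect of exactly 0 has p-value 1 by the tie
  convention; no special-casing.
* Permutations are drawn by R's `sample.int` (Fisher–Yates); one seeded
  stream per test invocation, set from the `seed` argument when given.

## Known limitations

IERM is intentionally miscalibrated under the one-sided members of the
composite null; it should not be used for inference.  PSRM is
conservative when both coefficients are zero (rejection far below
nominal), the price of supremum-based protection.  The IEFM interval has
no accompanying p-value, so its evidence cannot be graded continuously.
All operating characteristics were verified under the multivariate
normal generator above; behaviour under model misspecification is
unstudied here.  Exact enumeration is limited to $n \le 6$, where the
cross-product null set is still enumerable; beyond that the tests are
approximate with Monte-Carlo error $O(n_{perm}^{-1/2})$.
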