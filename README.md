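# medperm

Resampling tests for the mediated indirect effect in studies with small
sample sizes, with covariate adjustment done right.

## The problem

Mediation analysis decomposes the effect of an exposure *X* on an
outcome *Y* into a direct path and an indirect path through a mediator
*M*, using two linear models:

```
E[Y | X, C, M] = γ0 + γ1·X + γ2·C + γ3·M
E[M | X, C]    = α0 + α1·X + α2·C
```

The indirect effect is the product **α₁·γ₃**.  Its estimate is not
normally distributed, so small-sample inference leans on resampling —
but once covariates *C* are adjusted for (mediation assumes no
unmeasured confounding, so they must be), permuting raw data is wrong:
it destroys the covariate associations along with the one under test.
The remedy is to permute *model residuals*.

`medperm` implements, for analysts running adjusted mediation models at
small *n*:

* **PSRM** — the permutation supremum test under reduced models (the
  recommended test).  Residuals from the null-model fits (`Y ~ X + C`,
  `M ~ C`) are permuted, added back to the null-model fitted values, and
  the full models refit per permutation with the designs fixed
  (Freedman–Lane).  α₁, γ₃ and α₁·γ₃ are each tested two-sidedly, the
  null is rejected only if **all three** are significant, and the
  reported p-value is the maximum.  This respects the composite null
  α₁·γ₃ = 0 (true when either coefficient is zero) and holds the type I
  error at or below nominal across confounding scenarios.
* **IERM** — the same permutation stream aimed directly at α₁·γ₃ with a
  single p-value.  Calibrated under α₁ = γ₃ = 0 jointly, it grossly
  over-rejects when exactly one coefficient is zero; it is included as a
  cautionary baseline, not a recommendation.
* **IEFM** — the standard comparator, permuting *full*-model residuals
  (ter Braak style) and inverting the draws into a percentile confidence
  interval; rejection means 0 falls outside.
* **PB / BCB / BCAB** — percentile, bias-corrected and
  bias-corrected-accelerated case-resampling bootstrap tests, the usual
  alternatives in this literature.

Plus a full simulation bench: a Cholesky-based multivariate-normal
generator over 4×4 correlation structures, the catalogue of
covariate/confounder conditions with their implied population
coefficients, and a seeded, order-invariant harness for type I error /
power studies with Wald-bound flagging.

## Worked example

```r
library(medperm)

# a mediated chain with one confounder, n = 30
cond <- correlation_condition(rho_xc = 0.15, rho_xm = 0.6, rho_cm = 0,
                              rho_xy = 0.15, rho_cy = 0.15, rho_my = 0.6,
                              scenario = "b", strength = "weak",
                              hypothesis = "alternative")
implied_coefficients(cond)[c("alpha1", "gamma3")]
#> $alpha1
#> [1] 0.6138107
#> $gamma3
#> [1] 0.8259109

d <- generate_mediation_data(cond, n = 30, seed = 7)
psrm_test(d, n_perm = 10000, seed = 1)
#> PSRM test of the indirect effect
#>   indirect effect estimate:  0.40354  (alpha1 =  0.5449, gamma3 =  0.7405)
#>   p-value: 0.0006  [indirect 0, alpha1 0.0006, gamma3 0.0001; supremum rule]
#>   reject H0 at level 0.05: yes   (10000 resamples)
```

The estimate is α̂₁·γ̂₃; the three bracketed p-values test the product
and each path coefficient against the reduced-model permutation
distribution, and the headline p-value is their supremum — here all
three paths are unambiguous, so mediation is declared.  Against real
data, build the same object from a file:

```r
d <- read_mediation_data("study.csv", x = "treatment", m = "anxiety",
                         y = "attitude", c = c("age", "income"))
```

or from the shell via the bundled CLI:

```sh
inst/cli/medperm test --file study.csv --x treatment --m anxiety \
    --y attitude --c age,income --method psrm --nperm 10000 --seed 1
inst/cli/medperm simulate --scenario b --strength strong \
    --hypothesis null2 --method psrm,iefm --n 30 --reps 1000 --out rates.csv
inst/cli/medperm coefficients --rho_xm 0.6 --rho_my 0.15 --rho_xc 0.6 \
    --rho_xy 0.6 --rho_cy 0.6
```

A rejection-rate study in code:

```r
est <- run_study(cond, "psrm", n = 30, n_replicates = 1000,
                 inner_count = 10000, master_seed = 1)
```

Every replicate derives its own child seed, so any single cell of a
results table can be recomputed in isolation.

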