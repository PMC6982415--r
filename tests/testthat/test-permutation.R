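test_that("two-sided permutation p-value follows the magnitude convention", {
  expect_equal(two_sided_perm_pvalue(0, rnorm(7)), 1)        # zero statistic
  expect_equal(two_sided_perm_pvalue(10, c(1, -2, 3)), 0)    # beyond all draws
  expect_equal(two_sided_perm_pvalue(2, c(1, -2, 3, 0.5)), 0.5)
  # ties count as exceedances; smoothed variant shifts by 1/(n+1)
  expect_equal(two_sided_perm_pvalue(2, c(2, -2, 1, 0)), 0.5)
  expect_equal(two_sided_perm_pvalue(2, c(1, -2, 3, 0.5), smoothed = TRUE),
               3 / 5)
  expect_error(two_sided_perm_pvalue(1, numeric(0)), "nonempty")
})

test_that("fast permuted refits equal explicit full-model refits", {
  d <- make_chain_data(23, seed = 21)
  f <- fit_mediation(d, with_reduced = TRUE)
  set.seed(99)
  idx <- medperm:::perm_index_matrices(23, 25, "independent", FALSE)
  draws <- medperm:::perm_draws(
    d, yhat = f$outcome_reduced$fitted, ey = f$outcome_reduced$residuals,
    mhat = f$mediator_reduced$fitted, em = f$mediator_reduced$residuals,
    n_perm = 25, perm_indices = idx)
  for (j in c(1L, 7L, 25L)) {
    ystar <- f$outcome_reduced$fitted +
      f$outcome_reduced$residuals[idx$idx_y[, j]]
    mstar <- f$mediator_reduced$fitted +
      f$mediator_reduced$residuals[idx$idx_m[, j]]
    # explicit refits with permuted responses on the original designs
    refit_y <- fit_linear(ystar, cbind(X = d$x, d$c, M = d$m))
    refit_m <- fit_linear(mstar, cbind(X = d$x, d$c))
    expect_equal(draws$alpha1[j], refit_m$coefficients[["X"]],
                 tolerance = 1e-10)
    expect_equal(draws$gamma3[j], refit_y$coefficients[["M"]],
                 tolerance = 1e-10)
  }
})

test_that("identity permutations reproduce the observed statistics", {
  d <- make_chain_data(18, seed = 31)
  f <- fit_mediation(d, with_reduced = TRUE)
  ident <- matrix(rep(1:18, 10), 18)
  draws <- medperm:::perm_draws(
    d, yhat = f$outcome_reduced$fitted, ey = f$outcome_reduced$residuals,
    mhat = f$mediator_reduced$fitted, em = f$mediator_reduced$residuals,
    n_perm = 10, perm_indices = list(idx_y = ident, idx_m = ident))
  expect_equal(draws$alpha1, rep(f$alpha1, 10), tolerance = 1e-10)
  expect_equal(draws$gamma3, rep(f$gamma3, 10), tolerance = 1e-10)
  expect_equal(two_sided_perm_pvalue(f$indirect, draws$indirect), 1)
  expect_equal(two_sided_perm_pvalue(f$alpha1, draws$alpha1), 1)
})

test_that("exact enumeration matches the brute-force oracle", {
  set.seed(17)
  x <- rnorm(5); cc <- rnorm(5)
  m <- 0.6 * x + rnorm(5)
  y <- 0.7 * m + 0.2 * cc + rnorm(5)
  d <- mediation_data(x, m, y, cc)
  oracle <- brute_force_ierm(x, m, y, cc)
  res <- ierm_test(d, alpha = 0.05, exact = TRUE)
  expect_equal(res$n_perm_used, ncol(medperm:::all_permutations(5))^2)
  expect_identical(res$p_value, oracle$p)
  # the two null distributions agree as multisets
  f <- fit_mediation(d, with_reduced = TRUE)
  draws <- medperm:::perm_draws(
    d, yhat = f$outcome_reduced$fitted, ey = f$outcome_reduced$residuals,
    mhat = f$mediator_reduced$fitted, em = f$mediator_reduced$residuals,
    n_perm = 1, scheme = "independent", exact = TRUE)
  expect_equal(sort(draws$indirect), sort(oracle$draws), tolerance = 1e-9)
})

test_that("exact enumeration is refused beyond the factorial cap", {
  d <- make_chain_data(8, seed = 2)
  expect_error(ierm_test(d, exact = TRUE), "n <= 6")
})

test_that("permutation tests are seed-deterministic", {
  d <- make_chain_data(30, seed = 41)
  for (fn in list(ierm_test, psrm_test)) {
    r1 <- fn(d, n_perm = 300, seed = 123)
    r2 <- fn(d, n_perm = 300, seed = 123)
    expect_identical(r1$p_value, r2$p_value)
  }
  i1 <- iefm_test(d, n_perm = 300, seed = 123)
  i2 <- iefm_test(d, n_perm = 300, seed = 123)
  expect_identical(c(i1$ci_lower, i1$ci_upper), c(i2$ci_lower, i2$ci_upper))
  # different seeds move the p-value only by Monte-Carlo noise
  r3 <- ierm_test(d, n_perm = 300, seed = 456)
  r1 <- ierm_test(d, n_perm = 300, seed = 123)
  expect_lt(abs(r3$p_value - r1$p_value), 0.15)
})

test_that("PSRM p-value is the supremum of its components", {
  for (s in 1:10) {
    d <- make_chain_data(20, noise = 2, seed = 100 + s)
    r <- psrm_test(d, n_perm = 200, seed = s)
    expect_identical(r$p_value, max(r$p_indirect, r$p_alpha1, r$p_gamma3))
    expect_gte(r$p_value, r$p_indirect)
    expect_identical(r$reject, r$p_value <= r$alpha)
  }
})

test_that("PSRM never rejects when IERM on the same draws retains", {
  # same seed => same permutation stream => p_indirect identical
  d <- make_chain_data(25, noise = 1.5, seed = 77)
  ri <- ierm_test(d, n_perm = 400, seed = 5)
  rp <- psrm_test(d, n_perm = 400, seed = 5)
  expect_identical(rp$p_indirect, ri$p_value)
  expect_true(!rp$reject || ri$reject)
})

test_that("overwhelming mediated signal is detected", {
  set.seed(55)
  x <- rnorm(30)
  m <- x + 0.3 * rnorm(30)
  y <- m + 0.3 * rnorm(30)
  d <- mediation_data(x, m, y)
  r <- ierm_test(d, n_perm = 500, seed = 1)
  expect_equal(r$p_value, 0)
  expect_true(r$reject)
  expect_true(psrm_test(d, n_perm = 500, seed = 1)$reject)
  expect_true(iefm_test(d, n_perm = 500, seed = 1)$reject)
})

test_that("widening the IEFM level never rescinds a rejection", {
  d <- make_chain_data(30, noise = 0.4, seed = 61)
  levels <- c(0.02, 0.05, 0.1, 0.2, 0.5)
  rejects <- vapply(levels, function(a)
    iefm_test(d, n_perm = 400, alpha = a, seed = 9)$reject, logical(1))
  expect_true(all(diff(rejects) >= 0))  # monotone in alpha
})

test_that("joint permutation scheme applies one shared permutation", {
  d <- make_chain_data(15, seed = 71)
  set.seed(4)
  idx <- medperm:::perm_index_matrices(15, 20, "joint", FALSE)
  expect_identical(idx$idx_y, idx$idx_m)
  set.seed(4)
  idx2 <- medperm:::perm_index_matrices(15, 20, "independent", FALSE)
  expect_false(identical(idx2$idx_y, idx2$idx_m))
  # both schemes give valid tests on null data
  r <- psrm_test(d, n_perm = 200, seed = 8, perm_scheme = "joint")
  expect_true(r$p_value >= 0 && r$p_value <= 1)
})

test_that("composite-null conservatism: PSRM at or below IEFM", {
  # alpha1 = 0, gamma3 != 0: the hard null configuration
  cond <- cond_b(xm = 0, my = 0.6, s = 0.6, hypothesis = "null2")
  reps <- 150
  psrm <- run_study(cond, "psrm", n = 30, n_replicates = reps,
                    inner_count = 400, master_seed = 3)
  iefm <- run_study(cond, "iefm", n = 30, n_replicates = reps,
                    inner_count = 400, master_seed = 3)
  se2 <- 2 * sqrt(0.09 * 0.91 / reps)
  expect_lte(psrm$rate, iefm$rate + se2)
})

test_that("a strong X-Y confounder uncorrelated with M leaves PSRM at level", {
  cond <- cond_b(xm = 0, my = 0, s = 0.6, hypothesis = "null1")
  est <- run_study(cond, "psrm", n = 30, n_replicates = 150,
                   inner_count = 400, master_seed = 13)
  expect_lte(est$rate, 0.05 + 2 * sqrt(0.05 * 0.95 / 150))
})
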