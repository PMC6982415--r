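test_that("implied coefficients reproduce every printed scenario-b pair", {
  # (rho_xm, rho_my, strength) -> printed (alpha1, gamma3), 3-4 decimals
  rows <- rbind(
    # null rows: alpha1 = 0 and gamma3 equals rho_my exactly
    c(0.00, 0.00, 0.15, 0,      0),
    c(0.00, 0.15, 0.15, 0,      0.15),
    c(0.00, 0.30, 0.15, 0,      0.3),
    c(0.00, 0.60, 0.15, 0,      0.6),
    c(0.00, 0.00, 0.60, 0,      0),
    c(0.00, 0.15, 0.60, 0,      0.15),
    c(0.00, 0.30, 0.60, 0,      0.3),
    c(0.00, 0.60, 0.60, 0,      0.6),
    # alternative rows, weak confounder
    c(0.15, 0.15, 0.15, 0.1535, 0.1335),
    c(0.15, 0.30, 0.15, 0.1535, 0.2870),
    c(0.15, 0.60, 0.15, 0.1535, 0.5941),
    c(0.30, 0.15, 0.15, 0.3069, 0.1221),
    c(0.30, 0.30, 0.15, 0.3069, 0.2873),
    c(0.30, 0.60, 0.15, 0.3069, 0.6177),
    c(0.60, 0.15, 0.15, 0.6138, 0.1136),
    c(0.60, 0.30, 0.15, 0.6138, 0.3510),
    c(0.60, 0.60, 0.15, 0.6138, 0.8259),
    # alternative rows, strong confounder
    c(0.15, 0.15, 0.60, 0.2344, 0.0972),
    c(0.15, 0.30, 0.60, 0.2344, 0.2526),
    c(0.15, 0.60, 0.60, 0.2344, 0.5636),
    c(0.30, 0.15, 0.60, 0.4688, 0.0436),
    c(0.30, 0.30, 0.60, 0.4688, 0.2182),
    c(0.30, 0.60, 0.60, 0.4688, 0.5673),
    c(0.60, 0.15, 0.60, 0.9375, -0.1710),
    c(0.60, 0.30, 0.60, 0.9375, 0.1714),
    c(0.60, 0.60, 0.60, 0.9375, 0.8571))
  for (i in seq_len(nrow(rows))) {
    ic <- implied_coefficients(cond_b(rows[i, 1], rows[i, 2], rows[i, 3]))
    # agreement to the printed precision (absolute half-ulp of the print)
    expect_lt(abs(ic$alpha1 - rows[i, 4]), 5e-4,
              label = sprintf("alpha1 row %d deviation", i))
    expect_lt(abs(ic$gamma3 - rows[i, 5]), 5e-4,
              label = sprintf("gamma3 row %d deviation", i))
  }
  # independence: identity correlation matrix implies all-zero coefficients
  ic0 <- implied_coefficients(correlation_condition())
  expect_identical(unname(unlist(ic0)), rep(0, 5))
})

test_that("the generator reproduces its target correlation structure", {
  # independent variables stay independent
  d0 <- generate_mediation_data(correlation_condition(), 1e5, seed = 1)
  V <- cbind(d0$x, d0$c[, 1], d0$m, d0$y)
  off <- cor(V)[upper.tri(diag(4))]
  expect_lt(max(abs(off)), 0.01)

  # the weak-confounder example structure, large n
  cond <- cond_b(xm = 0.15, my = 0.15, s = 0.15)
  d <- generate_mediation_data(cond, 1e6, seed = 2)
  S <- cor(cbind(X = d$x, C = d$c[, 1], M = d$m, Y = d$y))
  expect_lt(max(abs(S - cond$rho)), 0.005)

  # marginals are standard normal
  expect_lt(abs(mean(d$m)), 0.005)
  expect_lt(abs(sd(d$y) - 1), 0.005)
})

test_that("generation is seed-deterministic and guards sample size", {
  cond <- cond_b(0.3, 0.3, 0.15)
  d1 <- generate_mediation_data(cond, 50, seed = 9)
  d2 <- generate_mediation_data(cond, 50, seed = 9)
  expect_identical(d1$y, d2$y)
  expect_error(generate_mediation_data(cond, 4), "at least 5")
})

test_that("non-positive-definite structures are rejected with diagnostics", {
  expect_error(correlation_condition(rho_xm = 1),
               "not positive definite.*eigenvalue")
  expect_error(correlation_condition(rho_xm = 0.9, rho_my = 0.9,
                                     rho_xy = -0.5),
               "not positive definite")
  expect_error(correlation_condition(rho_xc = 1.2), "within")
})

test_that("parameter recovery: sample fits converge to implied coefficients", {
  cond <- cond_b(xm = 0.6, my = 0.15, s = 0.6)   # includes a negative gamma3
  ic <- implied_coefficients(cond)
  d <- generate_mediation_data(cond, 2e5, seed = 3)
  f <- fit_mediation(d)
  expect_lt(abs(f$alpha1 - ic$alpha1), 0.01)
  expect_lt(abs(f$gamma3 - ic$gamma3), 0.01)
  expect_equal(sign(f$gamma3), -1)
})

test_that("the scenario-b catalogue matches the published condition counts", {
  nulls <- condition_catalogue("b", hypothesis = c("null1", "null2", "null3"))
  expect_length(nulls, 8)          # 2 strengths x (1 null1 + 3 null2)
  alts <- condition_catalogue("b", hypothesis = "alternative")
  expect_length(alts, 18)          # 2 strengths x 3 x 3 grid
  # condition 8 of the null table: strong confounder, gamma3 = 0.6
  ic8 <- implied_coefficients(nulls[[8]])
  expect_equal(ic8$alpha1, 0)
  expect_equal(ic8$gamma3, 0.6)
})

test_that("catalogued conditions are positive definite and nulls are exact", {
  cat_all <- condition_catalogue()
  expect_gt(length(cat_all), 50)
  for (cd in cat_all) {
    ev <- eigen(cd$rho, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 1e-10)
    ic <- implied_coefficients(cd)
    if (cd$hypothesis != "alternative")
      expect_lt(abs(ic$alpha1 * ic$gamma3), 1e-12)
  }
  # the positive-definite filter bites: scenario c loses strong-confounder
  # alternatives relative to the full 18-point grid
  expect_lt(length(condition_catalogue("c", hypothesis = "alternative")), 18)
})

test_that("conditions round-trip through a YAML mapping", {
  tf <- tempfile(fileext = ".yaml")
  writeLines(c("rho_xc: 0.6", "rho_xy: 0.6", "rho_cy: 0.6",
               "rho_my: 0.6", "scenario: b", "strength: strong",
               "hypothesis: null2"), tf)
  cond <- read_condition(tf)
  expect_equal(cond$rho["M", "Y"], 0.6)
  expect_equal(cond$rho["X", "M"], 0)
  expect_identical(cond$scenario, "b")
  ic <- implied_coefficients(cond)
  expect_equal(ic$alpha1, 0)
  unlink(tf)
})
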