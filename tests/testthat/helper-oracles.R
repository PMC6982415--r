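# Independent reference implementations used as oracles.  Everything here
# deliberately avoids the package's computational routes: OLS is solved by
# the normal equations, permutations come from e1071, and procedures are
# written as plain nested loops.

# OLS coefficients via the normal equations (design includes intercept)
ols_coef <- function(D, y) solve(crossprod(D), crossprod(D, y))

# Brute-force exhaustive reduced-model permutation test of the indirect
# effect: enumerates every pair of (outcome, mediator) permutations.
brute_force_ierm <- function(x, m, y, cc) {
  n <- length(x)
  XC  <- cbind(1, x, cc)
  XCM <- cbind(XC, m)
  C1  <- cbind(1, cc)
  b_y <- ols_coef(XCM, y)
  b_m <- ols_coef(XC, m)
  orig <- b_m[2L] * b_y[nrow(b_y)]
  # reduced models
  b_yr <- ols_coef(XC, y);  yhat <- drop(XC %*% b_yr);  ey <- y - yhat
  b_mr <- ols_coef(C1, m);  mhat <- drop(C1 %*% b_mr);  em <- m - mhat
  P <- e1071::permutations(n)
  draws <- numeric(nrow(P)^2)
  k <- 0L
  for (i in seq_len(nrow(P))) {
    ystar <- yhat + ey[P[i, ]]
    for (j in seq_len(nrow(P))) {
      mstar <- mhat + em[P[j, ]]
      # Freedman-Lane refits: permuted responses, original designs
      cy <- ols_coef(XCM, ystar)
      cm <- ols_coef(XC, mstar)
      k <- k + 1L
      draws[k] <- cm[2L] * cy[nrow(cy)]
    }
  }
  list(orig = orig, draws = draws,
       p = mean(abs(draws) >= abs(orig) * (1 - 1e-9)))
}

# chain-structured data: x -> m -> y with noise
make_chain_data <- function(n, noise = 0.5, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  cc <- rnorm(n)
  m <- 0.8 * x + noise * rnorm(n)
  y <- 0.8 * m + 0.3 * cc + noise * rnorm(n)
  mediation_data(x, m, y, cc)
}

# the scenario-b conditions used across tests (Tables 1-3 layout)
cond_b <- function(xm, my, s, hypothesis = NULL) {
  correlation_condition(rho_xc = s, rho_xm = xm, rho_cm = 0,
                        rho_xy = s, rho_cy = s, rho_my = my,
                        scenario = "b",
                        strength = if (s == 0.15) "weak" else "strong",
                        hypothesis = hypothesis)
}

binom_3se <- function(p, n) 3 * sqrt(p * (1 - p) / n)
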