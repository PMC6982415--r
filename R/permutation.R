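#' Two-sided permutation p-value
#'
#' The p-value is the proportion of null draws whose magnitude equals or
#' exceeds the magnitude of the observed statistic.  Ties count as
#' exceedances, so an observed value of exactly 0 yields p = 1.  By this
#' convention the p-value is always an integer multiple of
#' `1/length(null_draws)` and may be exactly 0.  Set `smoothed = TRUE`
#' for the (b + 1)/(n + 1) variant, which is guaranteed valid (never 0)
#' at the price of departing from the plain proportion.
#'
#' Equality of magnitudes is judged to a relative tolerance of 1e-9:
#' draws produced by refitting permuted data can differ from the observed
#' statistic by a few ulps even when they are equal in exact arithmetic
#' (the identity permutation is the canonical case), and a strict
#' floating-point `>=` would resolve such ties arbitrarily.
#'
#' @param observed observed statistic (scalar).
#' @param null_draws numeric vector of statistics computed on permuted
#'   data.
#' @param smoothed use the (b + 1)/(n + 1) convention?
#' @return p-value in `[0, 1]`.
#' @examples
#' two_sided_perm_pvalue(2, c(1, -2, 3, 0.5))  # 0.5
#' @export
two_sided_perm_pvalue <- function(observed, null_draws, smoothed = FALSE) {
  if (length(null_draws) == 0L) stop("null_draws must be nonempty")
  b <- sum(abs(null_draws) >= abs(observed) * (1 - 1e-9))
  n <- length(null_draws)
  if (smoothed) (b + 1) / (n + 1) else b / n
}

## all permutations of 1:n, one per column (recursive; n is tiny here)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n, n * ncol(sub))
  k <- 0L
  for (i in seq_len(n)) {          # value placed in the first position
    rest <- setdiff(seq_len(n), i)
    for (j in seq_len(ncol(sub))) {
      k <- k + 1L
      out[, k] <- c(i, rest[sub[, j]])
    }
  }
  out
}

MAX_EXACT_FACTORIAL <- 720L  # n <= 6: joint cross-product stays enumerable

## Draw index matrices (n x B) for permuting the outcome and mediator
## residual vectors.  Under the independent scheme each vector gets its
## own permutation; under the joint scheme both share one.
perm_index_matrices <- function(n, n_perm, scheme, exact) {
  if (exact) {
    K <- factorial(n)
    if (K > MAX_EXACT_FACTORIAL)
      stop("exact enumeration supported only for n <= 6 (n! <= ",
           MAX_EXACT_FACTORIAL, ")")
    P <- all_permutations(n)
    if (scheme == "independent") {
      # full cross product of (outcome perm, mediator perm)
      idx_y <- P[, rep(seq_len(K), each = K), drop = FALSE]
      idx_m <- P[, rep(seq_len(K), times = K), drop = FALSE]
    } else {
      idx_y <- idx_m <- P
    }
  } else {
    idx_y <- vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
    idx_m <- if (scheme == "independent")
      vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
    else idx_y
  }
  list(idx_y = idx_y, idx_m = idx_m)
}

## Core engine shared by the three permutation tests.
##
## Given base fitted values and residuals (from either the reduced or the
## full models), reconstructs the responses Y* = Yhat + eY*,
## M* = Mhat + eM* for every permutation and refits the two full models
## with the permuted responses.  Following the residual-permutation
## convention of Freedman-Lane and ter Braak, the design matrices stay
## fixed: Y* is regressed on the original (1, X, C, M) and M* on the
## original (1, X, C).  The refitted coefficients of interest are then
## inner products with two fixed projection vectors,
##   alpha1* = <x residualized on (1, C),    M*> / ||x residualized on (1, C)||^2
##   gamma3* = <m residualized on (1, X, C), Y*> / ||m residualized on (1, X, C)||^2
## (the Frisch-Waugh form of a single coefficient), which equal the
## coefficients from explicit refits (checked in the test suite to
## 1e-10) at a fraction of the cost.
perm_draws <- function(data, yhat, ey, mhat, em, n_perm,
                       scheme = c("independent", "joint"),
                       exact = FALSE, perm_indices = NULL) {
  scheme <- match.arg(scheme)
  n <- length(data$x)
  x_perp <- qr.resid(qr(cbind(1, data$c)), data$x)
  w_alpha <- x_perp / sum(x_perp^2)
  m_perp <- qr.resid(qr(cbind(1, data$x, data$c)), data$m)
  w_gamma <- m_perp / sum(m_perp^2)

  if (is.null(perm_indices))
    perm_indices <- perm_index_matrices(n, n_perm, scheme, exact)
  idx_y <- perm_indices$idx_y
  idx_m <- perm_indices$idx_m
  B <- ncol(idx_y)

  Ystar <- yhat + matrix(ey[idx_y], n, B)
  Mstar <- mhat + matrix(em[idx_m], n, B)
  alpha1 <- drop(crossprod(Mstar, w_alpha))
  gamma3 <- drop(crossprod(Ystar, w_gamma))
  list(alpha1 = alpha1, gamma3 = gamma3, indirect = alpha1 * gamma3,
       n_perm_used = B)
}

perm_result <- function(method, fit, alpha, n_perm_used, seed,
                        p_value = NA_real_, p_indirect = NA_real_,
                        p_alpha1 = NA_real_, p_gamma3 = NA_real_,
                        ci_lower = NA_real_, ci_upper = NA_real_,
                        reject) {
  structure(list(method = method,
                 estimate = fit$indirect,
                 alpha1 = fit$alpha1,
                 gamma3 = fit$gamma3,
                 p_value = p_value,
                 p_indirect = p_indirect,
                 p_alpha1 = p_alpha1,
                 p_gamma3 = p_gamma3,
                 ci_lower = ci_lower,
                 ci_upper = ci_upper,
                 alpha = alpha,
                 reject = reject,
                 n_perm_used = n_perm_used,
                 seed = seed),
            class = "medperm_test")
}

#' @export
print.medperm_test <- function(x, ...) {
  cat(sprintf("%s test of the indirect effect\n", x$method))
  cat(sprintf("  indirect effect estimate: % .5f  (alpha1 = % .4f, gamma3 = % .4f)\n",
              x$estimate, x$alpha1, x$gamma3))
  if (!is.na(x$p_value))
    cat(sprintf("  p-value: %.4g", x$p_value))
  if (!is.na(x$p_alpha1))
    cat(sprintf("  [indirect %.4g, alpha1 %.4g, gamma3 %.4g; supremum rule]",
                x$p_indirect, x$p_alpha1, x$p_gamma3))
  if (!is.na(x$ci_lower))
    cat(sprintf("  %g%% CI: [%.5f, %.5f]", 100 * (1 - x$alpha),
                x$ci_lower, x$ci_upper))
  cat(sprintf("\n  reject H0 at level %.3g: %s   (%d resamples)\n",
              x$alpha, if (x$reject) "yes" else "no", x$n_perm_used))
  invisible(x)
}

#' Flatten a test result to a one-row data frame
#'
#' @param x a `medperm_test` object.
#' @param row.names,optional,... passed on conventions of
#'   [as.data.frame()]; unused.
#' @return One-row data frame with method, estimate, p-values, bounds,
#'   decision and resample count -- convenient for CSV export.
#' @export
as.data.frame.medperm_test <- function(x, row.names = NULL,
                                       optional = FALSE, ...) {
  data.frame(method = x$method, estimate = x$estimate,
             alpha1 = x$alpha1, gamma3 = x$gamma3,
             p_value = x$p_value, p_indirect = x$p_indirect,
             p_alpha1 = x$p_alpha1, p_gamma3 = x$p_gamma3,
             ci_lower = x$ci_lower, ci_upper = x$ci_upper,
             alpha = x$alpha, reject = x$reject,
             n_resamples = x$n_perm_used,
             seed = if (is.null(x$seed)) NA_integer_ else x$seed,
             stringsAsFactors = FALSE)
}

check_perm_cfg <- function(n_perm, alpha) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
}

#' Permutation test of the indirect effect under reduced models (IERM)
#'
#' Freedman--Lane residual permutation aimed directly at the indirect
#' effect.  The procedure: (1) fit the full models and record the observed
#' \eqn{(\hat\alpha_1\hat\gamma_3)_{orig}}; (2) fit the reduced models
#' `y ~ x + c` and `m ~ c`, whose residuals carry no signal for the
#' coefficients under test; (3) permute the two reduced-model residual
#' vectors, add them back to the reduced-model fitted values to form
#' `Y*` and `M*`, refit the full models with `Y*` and `M*` as the
#' responses (the design matrices stay fixed, as in Freedman--Lane), and
#' record \eqn{\hat\alpha_1^*\hat\gamma_3^*}; (4) the two-sided p-value
#' is the proportion of permuted products at least as large in magnitude
#' as the observed one.
#'
#' Because both residual vectors are permuted, the null distribution is
#' generated under \eqn{\alpha_1 = \gamma_3 = 0} jointly -- not under the
#' composite null \eqn{\alpha_1\gamma_3 = 0}.  When exactly one
#' coefficient is zero this test is anticonservative, which is why
#' [psrm_test()] is the recommended procedure; IERM is provided for
#' completeness and for study of that miscalibration.
#'
#' @param data a [mediation_data()] object.
#' @param n_perm number of permutations (ignored when `exact = TRUE`).
#' @param alpha significance level in (0, 1).
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @param exact enumerate all permutations (requires `n <= 6`); under the
#'   independent scheme the null set is the full cross product of outcome
#'   and mediator permutations.
#' @param perm_scheme permute the two residual vectors with independent
#'   permutations (default) or with one shared (`"joint"`) permutation.
#'   The independent scheme breaks all associations under the null.
#' @param smoothed use the (b + 1)/(n + 1) p-value convention; see
#'   [two_sided_perm_pvalue()].
#' @return A `medperm_test` object (see [as.data.frame.medperm_test()]).
#' @seealso [psrm_test()], [iefm_test()]
#' @examples
#' d <- mediation_data(x = rnorm(20), m = rnorm(20), y = rnorm(20))
#' ierm_test(d, n_perm = 200, seed = 1)
#' @export
ierm_test <- function(data, n_perm = 10000, alpha = 0.05, seed = NULL,
                      exact = FALSE,
                      perm_scheme = c("independent", "joint"),
                      smoothed = FALSE) {
  perm_scheme <- match.arg(perm_scheme)
  check_perm_cfg(n_perm, alpha)
  if (!is.null(seed)) set.seed(seed)
  fit <- fit_mediation(data, with_reduced = TRUE)
  draws <- perm_draws(data,
                      yhat = fit$outcome_reduced$fitted,
                      ey   = fit$outcome_reduced$residuals,
                      mhat = fit$mediator_reduced$fitted,
                      em   = fit$mediator_reduced$residuals,
                      n_perm = n_perm, scheme = perm_scheme, exact = exact)
  p <- two_sided_perm_pvalue(fit$indirect, draws$indirect, smoothed)
  perm_result("IERM", fit, alpha, draws$n_perm_used, seed,
              p_value = p, reject = p <= alpha)
}

#' Permutation supremum test under reduced models (PSRM)
#'
#' The recommended test.  It shares the IERM permutation stream (reduced
#' model residuals, Freedman--Lane reconstruction, full-model refits) but
#' evaluates the composite null hypothesis \eqn{\alpha_1\gamma_3 = 0}
#' properly: each permutation contributes \eqn{\hat\alpha_1^*},
#' \eqn{\hat\gamma_3^*} and their product, yielding three two-sided
#' p-values for the observed \eqn{\hat\alpha_1}, \eqn{\hat\gamma_3} and
#' \eqn{\hat\alpha_1\hat\gamma_3}.  Mediation is declared only when all
#' three are significant; the operative p-value is the supremum (maximum)
#' of the three.  Both component significances are required because the
#' null holds whenever either coefficient is zero.
#'
#' @inheritParams ierm_test
#' @return A `medperm_test` object; `p_value` holds the supremum,
#'   `p_indirect`, `p_alpha1` and `p_gamma3` the component p-values.
#' @seealso [ierm_test()], [iefm_test()]
#' @export
psrm_test <- function(data, n_perm = 10000, alpha = 0.05, seed = NULL,
                      exact = FALSE,
                      perm_scheme = c("independent", "joint"),
                      smoothed = FALSE) {
  perm_scheme <- match.arg(perm_scheme)
  check_perm_cfg(n_perm, alpha)
  if (!is.null(seed)) set.seed(seed)
  fit <- fit_mediation(data, with_reduced = TRUE)
  draws <- perm_draws(data,
                      yhat = fit$outcome_reduced$fitted,
                      ey   = fit$outcome_reduced$residuals,
                      mhat = fit$mediator_reduced$fitted,
                      em   = fit$mediator_reduced$residuals,
                      n_perm = n_perm, scheme = perm_scheme, exact = exact)
  p_ie <- two_sided_perm_pvalue(fit$indirect, draws$indirect, smoothed)
  p_a  <- two_sided_perm_pvalue(fit$alpha1,   draws$alpha1,   smoothed)
  p_g  <- two_sided_perm_pvalue(fit$gamma3,   draws$gamma3,   smoothed)
  p_sup <- max(p_ie, p_a, p_g)
  perm_result("PSRM", fit, alpha, draws$n_perm_used, seed,
              p_value = p_sup, p_indirect = p_ie,
              p_alpha1 = p_a, p_gamma3 = p_g,
              reject = p_sup <= alpha)
}

#' Permutation test of the indirect effect under full models (IEFM)
#'
#' The standard comparison method (ter Braak style): residuals are taken
#' from the *full* models, permuted, added back to the full-model fitted
#' values, and the full models refit per permutation with the
#' reconstructed responses (designs fixed).  Because the full-model
#' fitted values retain the estimated signal, the permutation
#' distribution of \eqn{\hat\alpha_1^*\hat\gamma_3^*} centres near the
#' observed estimate and serves as a confidence distribution: its
#' \eqn{\omega/2} and \eqn{1 - \omega/2} empirical percentiles
#' (nearest-order-statistic definition, index `ceiling(q * n_perm)`)
#' are the confidence bounds, and the null is rejected when 0 falls
#' outside them.  No p-value is produced; the decision is
#' interval-based.
#'
#' @inheritParams ierm_test
#' @return A `medperm_test` object with `ci_lower`/`ci_upper` populated
#'   and `p_value` absent (`NA`).
#' @seealso [psrm_test()]
#' @export
iefm_test <- function(data, n_perm = 10000, alpha = 0.05, seed = NULL,
                      exact = FALSE,
                      perm_scheme = c("independent", "joint")) {
  perm_scheme <- match.arg(perm_scheme)
  check_perm_cfg(n_perm, alpha)
  if (!is.null(seed)) set.seed(seed)
  fit <- fit_mediation(data, with_reduced = FALSE)
  draws <- perm_draws(data,
                      yhat = fit$outcome_full$fitted,
                      ey   = fit$outcome_full$residuals,
                      mhat = fit$mediator_full$fitted,
                      em   = fit$mediator_full$residuals,
                      n_perm = n_perm, scheme = perm_scheme, exact = exact)
  ci <- order_stat_quantile(draws$indirect, c(alpha / 2, 1 - alpha / 2))
  reject <- ci[1L] > 0 || ci[2L] < 0
  perm_result("IEFM", fit, alpha, draws$n_perm_used, seed,
              ci_lower = ci[1L], ci_upper = ci[2L], reject = reject)
}

## Nearest-order-statistic (inverse empirical CDF) quantile: the
## ceiling(q * n)-th order statistic, no interpolation.  Shared by the
## permutation and bootstrap interval constructions so decisions are
## exact functions of the draws.  The small deduction before ceiling()
## keeps q * n that is an integer in exact arithmetic (e.g. q recovered
## from a normal CDF/quantile round trip) from spilling into the next
## order statistic.
order_stat_quantile <- function(draws, probs) {
  s <- sort(draws)
  idx <- pmin(pmax(ceiling(probs * length(s) - 1e-9), 1L), length(s))
  s[idx]
}
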