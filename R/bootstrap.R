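#' Case-resampling bootstrap draws of the indirect effect
#'
#' Resamples whole rows of `(x, m, y, c)` with replacement, refits the two
#' full mediation models on each resample, and records
#' \eqn{\hat\alpha_1^*\hat\gamma_3^*}.  Rank-deficient resamples (possible
#' in principle with discrete data) are redrawn, up to `100 * n_boot`
#' attempts in total.
#'
#' @param data a [mediation_data()] object.
#' @param n_boot number of bootstrap resamples.
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return Numeric vector of `n_boot` indirect-effect draws.
#' @export
bootstrap_indirect_draws <- function(data, n_boot = 10000, seed = NULL) {
  if (n_boot < 1L) stop("n_boot must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n <- length(data$x)
  XC  <- cbind(1, data$x, data$c)
  XCM <- cbind(XC, data$m)
  y <- data$y; m <- data$m
  p_med <- ncol(XC); p_out <- ncol(XCM)
  draws <- numeric(n_boot)
  attempts <- 0L; max_attempts <- 100L * n_boot
  b <- 1L
  while (b <= n_boot) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("bootstrap redraw cap exceeded: data produce rank-deficient ",
           "resamples too often")
    idx <- sample.int(n, replace = TRUE)
    fm <- .lm.fit(XC[idx, , drop = FALSE], m[idx])
    fy <- .lm.fit(XCM[idx, , drop = FALSE], y[idx])
    if (fm$rank < p_med || fy$rank < p_out) next
    draws[b] <- fm$coefficients[2L] * fy$coefficients[p_out]
    b <- b + 1L
  }
  draws
}

#' Percentile bootstrap interval
#'
#' The \eqn{\alpha/2} and \eqn{1 - \alpha/2} empirical percentiles of the
#' bootstrap draws, using the nearest-order-statistic quantile definition
#' shared with the permutation tests.
#'
#' @param draws bootstrap draws of the statistic.
#' @param alpha significance level; the interval has nominal coverage
#'   `1 - alpha`.
#' @return Length-2 numeric vector `c(lower, upper)`.
#' @export
pb_interval <- function(draws, alpha = 0.05) {
  if (length(draws) == 0L) stop("draws must be nonempty")
  stats::setNames(order_stat_quantile(draws, c(alpha / 2, 1 - alpha / 2)),
                  c("lower", "upper"))
}

#' Bias-corrected bootstrap interval
#'
#' Efron's bias-corrected percentile interval.  The median-bias constant
#' is \eqn{z_0 = \Phi^{-1}(\#\{draws < observed\}/n_{boot})} (strict
#' inequality; draws tied with the observed value count below with weight
#' `0`), and the percentile levels are shifted to
#' \eqn{\Phi(2 z_0 + z_{\alpha/2})} and \eqn{\Phi(2 z_0 + z_{1-\alpha/2})}.
#' With half the draws below the observed value, \eqn{z_0 = 0} and the
#' interval coincides with [pb_interval()].
#'
#' @inheritParams pb_interval
#' @param observed the statistic computed on the original data.
#' @return Length-2 numeric vector `c(lower, upper)`.
#' @export
bc_interval <- function(draws, observed, alpha = 0.05) {
  if (length(draws) == 0L) stop("draws must be nonempty")
  frac_below <- mean(draws < observed)
  if (frac_below <= 0 || frac_below >= 1)
    stop("all bootstrap draws fall on one side of the observed value; ",
         "z0 is undefined (increase n_boot)")
  z0 <- qnorm(frac_below)
  lv <- pnorm(2 * z0 + qnorm(c(alpha / 2, 1 - alpha / 2)))
  stats::setNames(order_stat_quantile(draws, lv), c("lower", "upper"))
}

#' Bias-corrected accelerated (BCa) bootstrap interval
#'
#' Extends [bc_interval()] with a jackknife acceleration constant.  With
#' leave-one-out indirect-effect estimates \eqn{\hat\theta_{-i}} and their
#' mean \eqn{\bar\theta},
#' \deqn{a = \frac{\sum_i (\bar\theta - \hat\theta_{-i})^3}
#'                {6 [\sum_i (\bar\theta - \hat\theta_{-i})^2]^{3/2}}}
#' and the percentile levels become
#' \eqn{\Phi(z_0 + (z_0 + z_q) / (1 - a (z_0 + z_q)))} for
#' \eqn{q \in \{\alpha/2, 1 - \alpha/2\}}.  With `a = 0` the interval
#' reduces to the bias-corrected one.
#'
#' @inheritParams bc_interval
#' @param data the original [mediation_data()] (needed for the jackknife);
#'   requires `n >= ncol(c) + 5` so every leave-one-out fit is identified.
#' @return Length-2 numeric vector `c(lower, upper)`.
#' @export
bca_interval <- function(draws, observed, data, alpha = 0.05) {
  if (length(draws) == 0L) stop("draws must be nonempty")
  n <- length(data$x)
  if (n < ncol(data$c) + 5L)
    stop("jackknife needs n >= p + 5")
  frac_below <- mean(draws < observed)
  if (frac_below <= 0 || frac_below >= 1)
    stop("all bootstrap draws fall on one side of the observed value; ",
         "z0 is undefined (increase n_boot)")
  z0 <- qnorm(frac_below)
  theta <- jackknife_indirect(data)
  dev <- mean(theta) - theta
  ssq <- sum(dev^2)
  if (ssq <= 0)
    stop("zero jackknife variance; acceleration constant undefined")
  a <- sum(dev^3) / (6 * ssq^1.5)
  zq <- qnorm(c(alpha / 2, 1 - alpha / 2))
  lv <- pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
  stats::setNames(order_stat_quantile(draws, lv), c("lower", "upper"))
}

## leave-one-out indirect-effect estimates
jackknife_indirect <- function(data) {
  n <- length(data$x)
  XC  <- cbind(1, data$x, data$c)
  XCM <- cbind(XC, data$m)
  p_out <- ncol(XCM)
  vapply(seq_len(n), function(i) {
    fm <- .lm.fit(XC[-i, , drop = FALSE], data$m[-i])
    fy <- .lm.fit(XCM[-i, , drop = FALSE], data$y[-i])
    fm$coefficients[2L] * fy$coefficients[p_out]
  }, numeric(1L))
}

#' Bootstrap tests of the indirect effect
#'
#' Runs the case-resampling bootstrap and applies one of the three
#' interval constructions: percentile (`"pb"`), bias-corrected (`"bcb"`)
#' or bias-corrected accelerated (`"bcab"`).  The null hypothesis of no
#' indirect effect is rejected when 0 lies outside the interval.
#'
#' @param data a [mediation_data()] object.
#' @param method interval construction.
#' @param n_boot number of bootstrap resamples.
#' @param alpha significance level.
#' @param seed optional integer seed.
#' @return A `medperm_test` object with `ci_lower`/`ci_upper` populated;
#'   `n_perm_used` holds the bootstrap count.
#' @examples
#' d <- mediation_data(x = rnorm(30), m = rnorm(30), y = rnorm(30))
#' bootstrap_test(d, "pb", n_boot = 500, seed = 1)
#' @export
bootstrap_test <- function(data, method = c("pb", "bcb", "bcab"),
                           n_boot = 10000, alpha = 0.05, seed = NULL) {
  method <- match.arg(method)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  fit <- fit_mediation(data)
  draws <- bootstrap_indirect_draws(data, n_boot)
  ci <- switch(method,
               pb   = pb_interval(draws, alpha),
               bcb  = bc_interval(draws, fit$indirect, alpha),
               bcab = bca_interval(draws, fit$indirect, data, alpha))
  perm_result(toupper(method), fit, alpha,
              length(draws), seed,
              ci_lower = ci[[1L]], ci_upper = ci[[2L]],
              reject = ci[[1L]] > 0 || ci[[2L]] < 0)
}
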