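#' Least-squares fit with explicit rank checking
#'
#' Fits `response ~ predictors` with an intercept by QR decomposition.
#' Rank deficiency is detected from the singular values of the design
#' matrix (relative tolerance 1e-8) and reported with the name of the
#' offending column, so that accidental collinearity between the exposure
#' and mediator surfaces as a clear error rather than silent `NA`
#' coefficients.
#'
#' @param response numeric vector.
#' @param predictors numeric matrix of predictor columns (no intercept
#'   column; one is prepended).  May have zero columns.
#' @return An object of class `linear_fit`: list with `coefficients`
#'   (intercept first, then predictors in column order), `fitted` and
#'   `residuals`.
#' @export
fit_linear <- function(response, predictors) {
  y <- as.numeric(response)
  X <- as.matrix(predictors)
  storage.mode(X) <- "double"
  if (nrow(X) != length(y))
    stop("response and predictors have different numbers of rows")
  if (is.null(colnames(X)) && ncol(X) > 0L)
    colnames(X) <- paste0("V", seq_len(ncol(X)))
  D <- cbind(`(Intercept)` = 1, X)
  sv <- svd(D, nu = 0L, nv = 0L)$d
  if (sv[length(sv)] <= 1e-8 * sv[1L]) {
    # locate the first column linearly dependent on its predecessors
    qrD <- qr(D, tol = 1e-8)
    bad <- colnames(D)[qrD$pivot[-seq_len(qrD$rank)]]
    stop("collinear predictor column(s): ", paste(bad, collapse = ", "))
  }
  qrD <- qr(D)
  beta <- qr.coef(qrD, y)
  fitted <- drop(D %*% beta)
  structure(list(coefficients = beta,
                 fitted = fitted,
                 residuals = y - fitted),
            class = "linear_fit")
}

#' Fit the full (and optionally reduced) mediation regressions
#'
#' Fits the outcome model `y ~ x + c + m` and the mediator model
#' `m ~ x + c`.  When `with_reduced = TRUE` the two null models used by
#' the reduced-model permutation tests are fitted as well: `y ~ x + c`
#' (outcome without the mediator) and `m ~ c` (mediator without the
#' exposure).
#'
#' Coefficient order is fixed as (intercept, x, covariates, m) for the
#' outcome model and (intercept, x, covariates) for the mediator model,
#' so `alpha1` is always the second coefficient of the mediator fit and
#' `gamma3` the last coefficient of the outcome fit.
#'
#' @param data a [mediation_data()] object.
#' @param with_reduced also fit the reduced models?
#' @return An object of class `fitted_mediation`: list with elements
#'   `outcome_full`, `mediator_full`, `outcome_reduced`,
#'   `mediator_reduced` (the last two `NULL` unless requested), `alpha1`,
#'   `gamma3` and `indirect` (`alpha1 * gamma3`).
#' @export
fit_mediation <- function(data, with_reduced = FALSE) {
  stopifnot(inherits(data, "mediation_data"))
  XC  <- cbind(X = data$x, data$c)
  XCM <- cbind(XC, M = data$m)
  outcome_full  <- fit_linear(data$y, XCM)
  mediator_full <- fit_linear(data$m, XC)
  alpha1 <- unname(mediator_full$coefficients["X"])
  gamma3 <- unname(outcome_full$coefficients["M"])
  outcome_reduced <- mediator_reduced <- NULL
  if (with_reduced) {
    outcome_reduced  <- fit_linear(data$y, XC)
    mediator_reduced <- fit_linear(data$m, data$c)
  }
  structure(list(outcome_full = outcome_full,
                 mediator_full = mediator_full,
                 outcome_reduced = outcome_reduced,
                 mediator_reduced = mediator_reduced,
                 alpha1 = alpha1,
                 gamma3 = gamma3,
                 indirect = alpha1 * gamma3),
            class = "fitted_mediation")
}

#' Indirect effect from a fitted mediation model
#'
#' Returns the product-of-coefficients estimate
#' \eqn{\hat\alpha_1 \hat\gamma_3}: the exposure coefficient of the
#' mediator model times the mediator coefficient of the outcome model.
#'
#' @param fit a [fit_mediation()] result.
#' @return Numeric scalar.
#' @export
indirect_effect <- function(fit) {
  stopifnot(inherits(fit, "fitted_mediation"))
  fit$alpha1 * fit$gamma3
}

#' @export
print.fitted_mediation <- function(x, ...) {
  cat("Mediation model fit\n")
  cat(sprintf("  alpha1 (X -> M):   % .5f\n", x$alpha1))
  cat(sprintf("  gamma3 (M -> Y):   % .5f\n", x$gamma3))
  cat(sprintf("  indirect effect:   % .5f\n", x$indirect))
  if (!is.null(x$outcome_reduced)) cat("  (reduced models fitted)\n")
  invisible(x)
}
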