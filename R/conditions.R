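VAR_ORDER <- c("X", "C", "M", "Y")
PD_TOL <- 1e-10

#' Define a simulation condition from six pairwise correlations
#'
#' A condition is a 4x4 correlation matrix over the variables
#' `(X, C, M, Y)` -- exposure, covariate, mediator, outcome -- plus
#' optional labels for the covariate scenario, confounding strength and
#' hypothesis configuration.  The matrix must be positive definite
#' (smallest eigenvalue greater than 1e-10); data are generated from it
#' by [generate_mediation_data()] and its implied population regression
#' coefficients recovered by [implied_coefficients()].
#'
#' @param rho_xc,rho_xm,rho_cm,rho_xy,rho_cy,rho_my pairwise correlations
#'   in `[-1, 1]`.
#' @param scenario optional label: `"a"` (C a covariate of Y only),
#'   `"b"` (C confounds X--Y), `"c"` (C confounds M--Y).
#' @param strength optional label `"weak"` or `"strong"`.
#' @param hypothesis optional label: `"null1"` (\eqn{\alpha_1 = 0,
#'   \gamma_3 = 0}), `"null2"` (\eqn{\alpha_1 = 0, \gamma_3 \ne 0}),
#'   `"null3"` (\eqn{\alpha_1 \ne 0, \gamma_3 = 0}) or `"alternative"`.
#' @return An object of class `correlation_condition`: list with the
#'   4x4 matrix `rho`, the labels, and a short `id` string.
#' @examples
#' correlation_condition(rho_xc = 0.15, rho_xy = 0.15, rho_cy = 0.15,
#'                       rho_xm = 0.15, rho_my = 0.15)
#' @export
correlation_condition <- function(rho_xc = 0, rho_xm = 0, rho_cm = 0,
                                  rho_xy = 0, rho_cy = 0, rho_my = 0,
                                  scenario = NULL, strength = NULL,
                                  hypothesis = NULL) {
  r <- c(xc = rho_xc, xm = rho_xm, cm = rho_cm,
         xy = rho_xy, cy = rho_cy, my = rho_my)
  if (any(!is.finite(r)) || any(abs(r) > 1))
    stop("correlations must be finite and within [-1, 1]")
  R <- diag(4)
  dimnames(R) <- list(VAR_ORDER, VAR_ORDER)
  R["X", "C"] <- R["C", "X"] <- rho_xc
  R["X", "M"] <- R["M", "X"] <- rho_xm
  R["C", "M"] <- R["M", "C"] <- rho_cm
  R["X", "Y"] <- R["Y", "X"] <- rho_xy
  R["C", "Y"] <- R["Y", "C"] <- rho_cy
  R["M", "Y"] <- R["Y", "M"] <- rho_my
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= PD_TOL)
    stop(sprintf(
      "correlation matrix is not positive definite (smallest eigenvalue %.3g)",
      min(ev)))
  structure(list(rho = R,
                 scenario = scenario, strength = strength,
                 hypothesis = hypothesis,
                 id = paste(c(scenario, strength, hypothesis,
                              sprintf("%g", r)), collapse = "_")),
            class = "correlation_condition")
}

#' @export
print.correlation_condition <- function(x, ...) {
  lbl <- paste(Filter(Negate(is.null),
                      list(x$scenario, x$strength, x$hypothesis)),
               collapse = "/")
  cat("Correlation condition", if (nzchar(lbl)) paste0(" [", lbl, "]"), "\n")
  print(round(x$rho, 4))
  ic <- implied_coefficients(x)
  cat(sprintf("implied alpha1 = %.4f, gamma3 = %.4f, indirect = %.4f\n",
              ic$alpha1, ic$gamma3, ic$alpha1 * ic$gamma3))
  invisible(x)
}

#' Generate multivariate-normal mediation data from a condition
#'
#' Draws an `n x 4` matrix `Z` of independent standard normals and
#' returns `Z %*% t(L)`, where `L` is the lower-triangular Cholesky
#' factor of the condition's correlation matrix, so the columns
#' `(X, C, M, Y)` have zero mean, unit variance and the prescribed
#' correlations.
#'
#' @param condition a [correlation_condition()].
#' @param n sample size (`n >= 5`).
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return A [mediation_data()] object with one covariate column `C`.
#' @export
generate_mediation_data <- function(condition, n, seed = NULL) {
  stopifnot(inherits(condition, "correlation_condition"))
  if (n < 5L) stop("n must be at least 5")
  if (!is.null(seed)) set.seed(seed)
  L <- t(chol(condition$rho))   # lower triangular
  Z <- matrix(rnorm(n * 4L), n, 4L)
  D <- Z %*% t(L)
  colnames(D) <- VAR_ORDER
  mediation_data(x = D[, "X"], m = D[, "M"], y = D[, "Y"],
                 c = D[, "C", drop = FALSE])
}

#' Population regression coefficients implied by a correlation structure
#'
#' With all variables standardized, the population coefficients of the
#' two mediation regressions follow from the normal equations on
#' submatrices of the correlation matrix: regressing M on (X, C) solves a
#' 2x2 system for `(alpha1, alpha2)`, and regressing Y on (X, C, M)
#' solves a 3x3 system for `(gamma1, gamma2, gamma3)`.  These are the
#' coefficient values a simulated dataset estimates as `n` grows.
#'
#' @param condition a [correlation_condition()].
#' @return List with `alpha1`, `alpha2`, `gamma1`, `gamma2`, `gamma3`.
#' @examples
#' cond <- correlation_condition(rho_xc = 0.15, rho_xm = 0.15,
#'                               rho_xy = 0.15, rho_cy = 0.15,
#'                               rho_my = 0.15)
#' implied_coefficients(cond)  # alpha1 = 0.1535, gamma3 = 0.1335
#' @export
implied_coefficients <- function(condition) {
  stopifnot(inherits(condition, "correlation_condition"))
  R <- condition$rho
  a <- solve(R[c("X", "C"), c("X", "C")], R[c("X", "C"), "M"])
  g <- solve(R[c("X", "C", "M"), c("X", "C", "M")], R[c("X", "C", "M"), "Y"])
  list(alpha1 = unname(a["X"]), alpha2 = unname(a["C"]),
       gamma1 = unname(g["X"]), gamma2 = unname(g["C"]),
       gamma3 = unname(g["M"]))
}

## correlation rho_MY that makes the population gamma3 exactly zero,
## given the other five correlations: gamma3 = 0 iff rho_MY equals the
## projection of Y's correlations with (X, C) through M's.
solve_rho_my_for_null_gamma3 <- function(rho_xc, rho_xm, rho_cm,
                                         rho_xy, rho_cy) {
  R2 <- matrix(c(1, rho_xc, rho_xc, 1), 2L)
  drop(c(rho_xm, rho_cm) %*% solve(R2, c(rho_xy, rho_cy)))
}

scenario_base <- function(scenario, s) {
  switch(scenario,
         a = list(xc = 0, cm = 0, cy = s, xy = s),
         b = list(xc = s, cm = 0, cy = s, xy = s),
         c = list(xc = 0, cm = s, cy = s, xy = s),
         stop("unknown scenario: ", scenario))
}

make_cond <- function(base, xm, my, scenario, strength, hypothesis) {
  tryCatch(
    correlation_condition(rho_xc = base$xc, rho_xm = xm, rho_cm = base$cm,
                          rho_xy = base$xy, rho_cy = base$cy, rho_my = my,
                          scenario = scenario, strength = strength,
                          hypothesis = hypothesis),
    error = function(e) NULL)   # non-positive-definite grids are dropped
}

#' Enumerate the simulation condition catalogue
#'
#' Builds the grid of correlation conditions used in the type I error and
#' power studies.  For each covariate scenario and confounding strength
#' `s` (0.15 weak, 0.6 strong), the scenario pattern pins four of the six
#' correlations:
#' \itemize{
#'   \item scenario `a`: `rho_xc = rho_cm = 0`, `rho_cy = rho_xy = s`;
#'   \item scenario `b`: `rho_cm = 0`, `rho_xc = rho_cy = rho_xy = s`;
#'   \item scenario `c`: `rho_xc = 0`, `rho_cm = rho_cy = rho_xy = s`.
#' }
#' The hypothesis then sets the two path correlations:
#' \itemize{
#'   \item `null1`: `rho_xm = rho_my = 0` (both coefficients zero);
#'   \item `null2`: `rho_xm = 0`, `rho_my` in `{0.15, 0.3, 0.6}`
#'     (\eqn{\alpha_1 = 0} exactly under every scenario pattern);
#'   \item `null3`: `rho_xm` in `{0.15, 0.3, 0.6}` with `rho_my` solved
#'     so the implied \eqn{\gamma_3} is exactly zero.  Under scenario `b`
#'     no grid value of `rho_my` achieves \eqn{\gamma_3 = 0}, so its
#'     null3 list is empty (matching the eight null conditions reported
#'     for that scenario).
#'   \item `alternative`: `rho_xm`, `rho_my` over
#'     `{0.15, 0.3, 0.6}^2`.
#' }
#' Conditions whose matrices fail positive definiteness are dropped; this
#' is the same filter the simulation design itself applies.
#'
#' @param scenario character vector from `c("a", "b", "c")`.
#' @param strength character vector from `c("weak", "strong")`.
#' @param hypothesis character vector from
#'   `c("null1", "null2", "null3", "alternative")`.
#' @param sample_size optional sample size attached to each condition as
#'   attribute `"n"` (metadata only).
#' @return List of [correlation_condition()] objects.
#' @examples
#' length(condition_catalogue("b", hypothesis = c("null1", "null2")))  # 8
#' length(condition_catalogue("b", hypothesis = "alternative"))       # 18
#' @export
condition_catalogue <- function(scenario = c("a", "b", "c"),
                                strength = c("weak", "strong"),
                                hypothesis = c("null1", "null2",
                                               "null3", "alternative"),
                                sample_size = NULL) {
  scenario <- match.arg(scenario, several.ok = TRUE)
  strength <- match.arg(strength, several.ok = TRUE)
  hypothesis <- match.arg(hypothesis, several.ok = TRUE)
  grid_vals <- c(0.15, 0.3, 0.6)
  out <- list()
  for (sc in scenario) for (st in strength) {
    s <- if (st == "weak") 0.15 else 0.6
    base <- scenario_base(sc, s)
    for (hy in hypothesis) {
      conds <- switch(hy,
        null1 = list(make_cond(base, 0, 0, sc, st, hy)),
        null2 = lapply(grid_vals, function(my)
          make_cond(base, 0, my, sc, st, hy)),
        null3 = if (sc == "b") list() else lapply(grid_vals, function(xm) {
          my <- solve_rho_my_for_null_gamma3(base$xc, xm, base$cm,
                                             base$xy, base$cy)
          if (abs(my) >= 1) NULL else make_cond(base, xm, my, sc, st, hy)
        }),
        alternative = {
          g <- expand.grid(xm = grid_vals, my = grid_vals)
          lapply(seq_len(nrow(g)), function(i)
            make_cond(base, g$xm[i], g$my[i], sc, st, hy))
        })
      out <- c(out, Filter(Negate(is.null), conds))
    }
  }
  if (!is.null(sample_size))
    out <- lapply(out, function(cd) { attr(cd, "n") <- sample_size; cd })
  out
}

#' Read a condition from a YAML or JSON-style mapping
#'
#' The file maps the six correlations (keys `rho_xc`, `rho_xm`, `rho_cm`,
#' `rho_xy`, `rho_cy`, `rho_my`; omitted keys default to 0) and the
#' optional labels `scenario`, `strength`, `hypothesis`.
#'
#' @param path path to a YAML file (JSON is a subset of YAML).
#' @return A [correlation_condition()].
#' @export
read_condition <- function(path) {
  mapping <- yaml::read_yaml(path)
  get0n <- function(k) if (is.null(mapping[[k]])) 0 else as.numeric(mapping[[k]])
  correlation_condition(rho_xc = get0n("rho_xc"), rho_xm = get0n("rho_xm"),
                        rho_cm = get0n("rho_cm"), rho_xy = get0n("rho_xy"),
                        rho_cy = get0n("rho_cy"), rho_my = get0n("rho_my"),
                        scenario = mapping$scenario, strength = mapping$strength,
                        hypothesis = mapping$hypothesis)
}
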