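#' Wald bounds for a Monte-Carlo rejection proportion
#'
#' A simulated rejection rate based on `n_replicates` binary decisions
#' has (approximate) 95% Wald interval
#' `nominal +/- 1.96 * sqrt(nominal * (1 - nominal) / n_replicates)`
#' under a correctly calibrated test.  Rates above the upper bound flag a
#' test whose size exceeds the nominal level beyond sampling variation;
#' at `nominal = 0.05` and 1,000 replicates the bounds are
#' (0.036, 0.064) to three decimals.
#'
#' @param nominal nominal level in (0, 1).
#' @param n_replicates number of Monte-Carlo replicates.
#' @return Length-2 numeric vector `c(lower, upper)` (unrounded).
#' @examples
#' round(wald_bounds(0.05, 1000), 3)
#' @export
wald_bounds <- function(nominal, n_replicates) {
  if (!(nominal > 0 && nominal < 1)) stop("nominal must be in (0, 1)")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  half <- qnorm(0.975) * sqrt(nominal * (1 - nominal) / n_replicates)
  stats::setNames(nominal + c(-half, half), c("lower", "upper"))
}

## Deterministic 31-bit child seed from a master seed and replicate
## identity.  A simple polynomial string hash mod 2^31 - 1: stable across
## platforms and sessions, and independent of replicate execution order,
## so any single replicate can be recomputed in isolation.
child_seed <- function(master_seed, replicate, condition_id, method) {
  key <- paste(master_seed, replicate, condition_id, method, sep = "|")
  h <- as.numeric(master_seed) %% 2147483647
  for (byte in utf8ToInt(key)) h <- (h * 31 + byte) %% 2147483647
  as.integer(max(h, 1))
}

run_one_test <- function(method, dat, inner_count, nominal, perm_scheme) {
  if (is.function(method)) return(method(dat, alpha = nominal))
  switch(method,
         ierm = ierm_test(dat, n_perm = inner_count, alpha = nominal,
                          perm_scheme = perm_scheme),
         psrm = psrm_test(dat, n_perm = inner_count, alpha = nominal,
                          perm_scheme = perm_scheme),
         iefm = iefm_test(dat, n_perm = inner_count, alpha = nominal,
                          perm_scheme = perm_scheme),
         pb   = ,
         bcb  = ,
         bcab = bootstrap_test(dat, method, n_boot = inner_count,
                               alpha = nominal),
         stop("unknown method: ", method))
}

method_label <- function(method) {
  if (is.function(method)) "custom" else toupper(method)
}

new_rate_estimate <- function(condition, method, n, decisions, n_excluded,
                              inner_count, nominal, master_seed) {
  n_rep <- length(decisions)
  rate <- if (n_rep) sum(decisions) / n_rep else NA_real_
  wb <- wald_bounds(nominal, max(n_rep, 1L))
  structure(list(condition = condition,
                 method = method_label(method),
                 sample_size = n,
                 n_replicates = n_rep,
                 n_inner = inner_count,
                 rejections = sum(decisions),
                 rate = rate,
                 nominal = nominal,
                 master_seed = master_seed,
                 n_excluded = n_excluded,
                 exceeds_wald = isTRUE(rate > wb[["upper"]])),
            class = "rejection_rate_estimate")
}

#' @export
print.rejection_rate_estimate <- function(x, ...) {
  cat(sprintf(
    "%s: rejection rate %.3f (%d/%d replicates, n = %d, %d resamples)%s\n",
    x$method, x$rate, x$rejections, x$n_replicates, x$sample_size,
    x$n_inner, if (x$exceeds_wald) "  [exceeds Wald bound]" else ""))
  if (x$n_excluded > 0)
    cat(sprintf("  %d replicate(s) excluded due to errors\n", x$n_excluded))
  invisible(x)
}

#' Estimate the rejection rate of a test under one simulation condition
#'
#' Runs `n_replicates` independent replicates: each derives a child seed
#' from the master seed (so replicates can be recomputed individually and
#' in any order), generates a dataset of size `n` from the condition's
#' correlation structure, runs the requested test at level `nominal`,
#' and records the binary decision.  Under a null condition the rate
#' estimates type I error; under an alternative it estimates power.
#' Replicates that fail (e.g. a degenerate bootstrap) are excluded and
#' counted rather than redrawn, so the rate remains a ratio of observed
#' decisions.
#'
#' @param condition a [correlation_condition()].
#' @param method one of `"ierm"`, `"psrm"`, `"iefm"`, `"pb"`, `"bcb"`,
#'   `"bcab"`, or a function `f(data, alpha)` returning a list with a
#'   logical element `reject` (useful for calibration checks).
#' @param n sample size per replicate.
#' @param n_replicates number of Monte-Carlo replicates.
#' @param inner_count permutations (or bootstrap resamples) per replicate.
#' @param nominal significance level of the inner test.
#' @param master_seed integer master seed.
#' @param perm_scheme passed to the permutation tests.
#' @return A `rejection_rate_estimate` object: condition, method label,
#'   counts, `rate`, exclusion count, master seed, and `exceeds_wald`
#'   (rate above the upper Wald bound for `nominal` at the replicate
#'   count used).
#' @examples
#' cond <- correlation_condition(rho_xc = 0.15, rho_xy = 0.15,
#'                               rho_cy = 0.15)
#' run_study(cond, "psrm", n = 30, n_replicates = 10, inner_count = 99,
#'           master_seed = 1)
#' @export
run_study <- function(condition, method, n, n_replicates = 1000,
                      inner_count = 10000, nominal = 0.05,
                      master_seed = 1,
                      perm_scheme = c("independent", "joint")) {
  stopifnot(inherits(condition, "correlation_condition"))
  perm_scheme <- match.arg(perm_scheme)
  if (n_replicates < 1L || inner_count < 1L)
    stop("n_replicates and inner_count must be >= 1")
  decisions <- logical(0)
  n_excluded <- 0L
  mlab <- method_label(method)
  for (r in seq_len(n_replicates)) {
    set.seed(child_seed(master_seed, r, condition$id, mlab))
    dat <- generate_mediation_data(condition, n)
    res <- tryCatch(
      run_one_test(method, dat, inner_count, nominal, perm_scheme),
      error = function(e) NULL)
    if (is.null(res)) n_excluded <- n_excluded + 1L
    else decisions <- c(decisions, isTRUE(res$reject))
  }
  if (n_excluded > 0)
    message(n_excluded, " replicate(s) excluded due to errors")
  new_rate_estimate(condition, method, n, decisions, n_excluded,
                    inner_count, nominal, master_seed)
}

#' Side-by-side rejection rates of several methods on one condition
#'
#' Like [run_study()] for a vector of methods, but each replicate
#' generates one dataset shared by all methods, and the bootstrap methods
#' additionally share one set of case-resampling draws (they differ only
#' in the interval construction).  This is the configuration used when
#' comparing permutation and bootstrap tests under identical conditions.
#'
#' @inheritParams run_study
#' @param methods character vector of method labels (see [run_study()]).
#' @return Named list of `rejection_rate_estimate` objects, one per
#'   method.
#' @export
compare_methods <- function(condition, methods, n, n_replicates = 1000,
                            inner_count = 10000, nominal = 0.05,
                            master_seed = 1,
                            perm_scheme = c("independent", "joint")) {
  stopifnot(inherits(condition, "correlation_condition"))
  perm_scheme <- match.arg(perm_scheme)
  boot_methods <- intersect(methods, c("pb", "bcb", "bcab"))
  other_methods <- setdiff(methods, boot_methods)
  decisions <- lapply(methods, function(m) logical(0))
  names(decisions) <- methods
  excluded <- integer(length(methods))
  names(excluded) <- methods
  for (r in seq_len(n_replicates)) {
    set.seed(child_seed(master_seed, r, condition$id, "shared"))
    dat <- generate_mediation_data(condition, n)
    for (m in other_methods) {
      res <- tryCatch(
        run_one_test(m, dat, inner_count, nominal, perm_scheme),
        error = function(e) NULL)
      if (is.null(res)) excluded[m] <- excluded[m] + 1L
      else decisions[[m]] <- c(decisions[[m]], isTRUE(res$reject))
    }
    if (length(boot_methods)) {
      fit <- fit_mediation(dat)
      draws <- tryCatch(bootstrap_indirect_draws(dat, inner_count),
                        error = function(e) NULL)
      for (m in boot_methods) {
        ci <- if (is.null(draws)) NULL else tryCatch(
          switch(m,
                 pb   = pb_interval(draws, nominal),
                 bcb  = bc_interval(draws, fit$indirect, nominal),
                 bcab = bca_interval(draws, fit$indirect, dat, nominal)),
          error = function(e) NULL)
        if (is.null(ci)) excluded[m] <- excluded[m] + 1L
        else decisions[[m]] <- c(decisions[[m]],
                                 ci[[1L]] > 0 || ci[[2L]] < 0)
      }
    }
  }
  out <- lapply(methods, function(m)
    new_rate_estimate(condition, m, n, decisions[[m]], excluded[[m]],
                      inner_count, nominal, master_seed))
  names(out) <- vapply(methods, method_label, character(1))
  out
}

#' Arrange rejection-rate estimates as a results table
#'
#' Produces one row per condition and sample size, in input order, with
#' the six correlations, the implied population coefficients `alpha1`
#' and `gamma3`, and one rate column per method plus a companion
#' `<method>_exceeds` flag for rates above the upper Wald bound.
#'
#' @param estimates list of `rejection_rate_estimate` objects sharing a
#'   nominal level and replicate count.
#' @return A data frame (empty for an empty input list).
#' @export
tabulate_estimates <- function(estimates) {
  if (length(estimates) == 0L) return(data.frame())
  stopifnot(all(vapply(estimates, inherits, logical(1),
                       "rejection_rate_estimate")))
  noms <- unique(vapply(estimates, function(e) e$nominal, numeric(1)))
  if (length(noms) > 1L)
    stop("estimates mix nominal levels: ", paste(noms, collapse = ", "))
  reps <- unique(vapply(estimates, function(e) e$n_replicates, numeric(1)))
  if (length(reps) > 1L)
    stop("estimates mix replicate counts: ", paste(reps, collapse = ", "))
  key <- vapply(estimates, function(e)
    paste(e$condition$id, e$sample_size), character(1))
  methods <- unique(vapply(estimates, function(e) e$method, character(1)))
  rows <- lapply(unique(key), function(k) {
    grp <- estimates[key == k]
    e1 <- grp[[1L]]
    R <- e1$condition$rho
    ic <- implied_coefficients(e1$condition)
    row <- data.frame(scenario = e1$condition$scenario %||% NA_character_,
                      strength = e1$condition$strength %||% NA_character_,
                      hypothesis = e1$condition$hypothesis %||% NA_character_,
                      n = e1$sample_size,
                      rho_xc = R["X", "C"], rho_xm = R["X", "M"],
                      rho_cm = R["C", "M"], rho_xy = R["X", "Y"],
                      rho_cy = R["C", "Y"], rho_my = R["M", "Y"],
                      alpha1 = ic$alpha1, gamma3 = ic$gamma3,
                      stringsAsFactors = FALSE)
    for (m in methods) {
      hit <- Filter(function(e) e$method == m, grp)
      row[[m]] <- if (length(hit)) hit[[1L]]$rate else NA_real_
      row[[paste0(m, "_exceeds")]] <-
        if (length(hit)) hit[[1L]]$exceeds_wald else NA
    }
    row
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarize Wald-bound exceedances per method
#'
#' Counts, over a set of rejection-rate estimates, how many conditions
#' each method's rate exceeded the upper Wald bound, together with the
#' percentage of conditions affected.
#'
#' @param estimates list of `rejection_rate_estimate` objects.
#' @return Data frame with columns `method`, `n_conditions`, `n_exceeds`,
#'   `pct_exceeds`.
#' @export
exceedance_summary <- function(estimates) {
  methods <- unique(vapply(estimates, function(e) e$method, character(1)))
  do.call(rbind, lapply(methods, function(m) {
    grp <- Filter(function(e) e$method == m, estimates)
    k <- sum(vapply(grp, function(e) e$exceeds_wald, logical(1)))
    data.frame(method = m, n_conditions = length(grp), n_exceeds = k,
               pct_exceeds = 100 * k / length(grp),
               stringsAsFactors = FALSE)
  }))
}
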