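#' Bundle exposure, mediator, outcome and covariates for mediation analysis
#'
#' Every test in the package consumes a `mediation_data` object: aligned
#' numeric vectors for the exposure `x`, mediator `m` and outcome `y`, plus
#' an optional covariate matrix `c` with one column per adjustment variable.
#'
#' The constructor enforces the assumptions the resampling tests rely on:
#' equal lengths, no missing values, nonzero variance in every column, and
#' enough rows to leave residual degrees of freedom in the full outcome
#' model (`n >= ncol(c) + 4`).
#'
#' @param x numeric exposure vector.
#' @param m numeric mediator vector.
#' @param y numeric outcome vector.
#' @param c optional covariate matrix or data frame (`n` rows); a bare
#'   vector is treated as a single column.  `NULL` means no covariates.
#' @return An object of class `mediation_data`: a list with elements `x`,
#'   `m`, `y` and `c` (an `n x p` matrix, `p >= 0`).
#' @examples
#' d <- mediation_data(x = rnorm(30), m = rnorm(30), y = rnorm(30),
#'                     c = rnorm(30))
#' fit_mediation(d)
#' @export
mediation_data <- function(x, m, y, c = NULL) {
  x <- as.numeric(x); m <- as.numeric(m); y <- as.numeric(y)
  if (is.null(c)) {
    cmat <- matrix(numeric(0), nrow = length(x), ncol = 0)
  } else {
    cmat <- as.matrix(c)
    storage.mode(cmat) <- "double"
    if (is.null(colnames(cmat)))
      colnames(cmat) <- paste0("C", seq_len(ncol(cmat)))
  }
  n <- length(x)
  if (length(m) != n || length(y) != n || nrow(cmat) != n)
    stop("x, m, y and c must have the same number of observations")
  p <- ncol(cmat)
  if (n < p + 4L)
    stop(sprintf(
      "need at least %d observations to fit the full outcome model with %d covariate(s); got %d",
      p + 4L, p, n))
  vals <- cbind(x = x, m = m, y = y, cmat)
  if (anyNA(vals)) stop("missing values are not allowed in mediation data")
  vr <- apply(vals, 2L, var)
  if (any(vr <= 0))
    stop("zero-variance column(s): ",
         paste(colnames(vals)[vr <= 0], collapse = ", "))
  structure(list(x = x, m = m, y = y, c = cmat),
            class = "mediation_data")
}

#' @export
print.mediation_data <- function(x, ...) {
  cat(sprintf("Mediation data: n = %d, covariates = %d%s\n",
              length(x$x), ncol(x$c),
              if (ncol(x$c)) paste0(" (", paste(colnames(x$c), collapse = ", "), ")")
              else ""))
  invisible(x)
}

#' Read mediation data from a delimited text file
#'
#' Reads a CSV or TSV file with a header row and maps named columns to the
#' exposure, mediator, outcome and covariate roles.
#'
#' @param path file path.  Files ending in `.tsv` or `.txt` are read as
#'   tab-separated; everything else as comma-separated.
#' @param x,m,y column names for exposure, mediator and outcome.
#' @param c character vector of covariate column names (may be empty).
#' @inherit mediation_data return
#' @export
read_mediation_data <- function(path, x, m, y, c = character()) {
  tab <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE))
    read.delim(path, check.names = FALSE)
  else
    read.csv(path, check.names = FALSE)
  need <- c(x, m, y, c)
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("column(s) not found in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  cmat <- if (length(c)) as.matrix(tab[c]) else NULL
  mediation_data(tab[[x]], tab[[m]], tab[[y]], cmat)
}
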