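#' Moment matrix with sample size
#'
#' A `corr_matrix` bundles a symmetric correlation (or covariance) matrix with
#' the sample size `n` that produced it. It is the sufficient statistic that
#' every model fit in this package consumes: maximum-likelihood
#' covariance-structure estimation needs only the moment matrix and `n`,
#' never the raw records.
#'
#' @param mat symmetric numeric matrix with row/column names.
#' @param n sample size behind the matrix.
#' @param type `"correlation"` (unit diagonal enforced) or `"covariance"`.
#' @param p_values optional matching matrix of two-sided p-values.
#' @return an object of class `corr_matrix`.
#' @export
corr_matrix <- function(mat, n, type = c("correlation", "covariance"),
                        p_values = NULL) {
  type <- match.arg(type)
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) stop("moment matrix must be square")
  if (is.null(rownames(mat)) && is.null(colnames(mat)))
    stop("moment matrix needs variable names")
  if (is.null(rownames(mat))) rownames(mat) <- colnames(mat)
  if (is.null(colnames(mat))) colnames(mat) <- rownames(mat)
  if (!identical(rownames(mat), colnames(mat)))
    stop("row and column names differ")
  if (anyDuplicated(rownames(mat))) stop("duplicate variable names")
  if (any(!is.finite(mat))) stop("non-finite entries in moment matrix")
  if (max(abs(mat - t(mat))) > 1e-12)
    stop("matrix not symmetric (tolerance 1e-12)")
  mat <- (mat + t(mat)) / 2
  if (type == "correlation") {
    if (max(abs(diag(mat) - 1)) > 1e-12)
      stop("correlation matrix must have unit diagonal")
    diag(mat) <- 1
    if (max(abs(mat)) > 1 + 1e-12) stop("correlations must lie in [-1, 1]")
  }
  n <- as.integer(n)
  if (is.na(n) || n < 1) stop("n must be a positive integer")
  if (!is.null(p_values)) {
    p_values <- as.matrix(p_values)
    stopifnot(identical(dim(p_values), dim(mat)))
    dimnames(p_values) <- dimnames(mat)
  }
  structure(list(mat = mat, n = n, type = type, p_values = p_values),
            class = "corr_matrix")
}

#' @export
as.matrix.corr_matrix <- function(x, ...) x$mat

#' @export
dim.corr_matrix <- function(x) dim(x$mat)

#' @export
print.corr_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("<%s matrix: %d variables, n = %d>\n", x$type, ncol(x$mat), x$n))
  print(round(x$mat, digits))
  invisible(x)
}

#' Restrict a moment matrix to a subset of variables
#'
#' @param m a [corr_matrix()].
#' @param vars variable names to keep, in the requested order.
#' @return a `corr_matrix` over `vars`.
#' @export
subset_corr <- function(m, vars) {
  stopifnot(inherits(m, "corr_matrix"))
  missing <- setdiff(vars, rownames(m$mat))
  if (length(missing))
    stop("variables not in matrix: ", paste(missing, collapse = ", "))
  corr_matrix(m$mat[vars, vars, drop = FALSE], m$n, m$type,
              if (!is.null(m$p_values)) m$p_values[vars, vars, drop = FALSE])
}

#' Read / write square moment matrices as CSV
#'
#' The on-disk layout is a square CSV with variable names in the header and
#' first column, as exchanged between spreadsheet tools.
#'
#' @param path file path.
#' @param n sample size to attach (not stored in the CSV).
#' @param type `"correlation"` or `"covariance"`.
#' @return `read_corr_matrix()` returns a [corr_matrix()];
#'   `write_corr_matrix()` returns `path` invisibly.
#' @export
read_corr_matrix <- function(path, n, type = "correlation") {
  df <- utils::read.csv(path, check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  storage.mode(mat) <- "double"
  corr_matrix(mat, n, type)
}

#' @rdname read_corr_matrix
#' @param m a [corr_matrix()] to write.
#' @export
write_corr_matrix <- function(m, path) {
  stopifnot(inherits(m, "corr_matrix"))
  df <- data.frame(variable = rownames(m$mat), m$mat, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Project a correlation matrix to the nearest positive semi-definite matrix
#'
#' Printed correlation tables are rounded and can be indefinite. Eigenvalues
#' below `floor` are clipped to `floor` and the matrix is rescaled back to a
#' unit diagonal. An input that is already PSD (all eigenvalues >= `floor`)
#' is returned unchanged.
#'
#' @param m a [corr_matrix()] in correlation mode.
#' @param floor smallest admissible eigenvalue (default `1e-6`).
#' @return a `corr_matrix`; attribute `"max_delta"` records the largest
#'   absolute entry change (0 when the input was already PSD), attribute
#'   `"min_eigenvalue"` the smallest eigenvalue of the input.
#' @export
nearest_psd <- function(m, floor = 1e-6) {
  stopifnot(inherits(m, "corr_matrix"))
  e <- eigen(m$mat, symmetric = TRUE)
  out <- m
  if (min(e$values) >= floor) {
    attr(out, "max_delta") <- 0
  } else {
    # alternate eigenvalue clipping with unit-diagonal rescaling until both
    # constraints hold (rescaling alone can push an eigenvalue back below)
    fixed <- m$mat
    for (it in 1:100) {
      ed <- eigen(fixed, symmetric = TRUE)
      if (min(ed$values) >= floor * (1 - 1e-9) &&
          max(abs(diag(fixed) - 1)) < 1e-12) break
      vals <- pmax(ed$values, floor)
      fixed <- ed$vectors %*% (vals * t(ed$vectors))
      d <- sqrt(diag(fixed))
      fixed <- fixed / (d %o% d)
      fixed <- (fixed + t(fixed)) / 2
      diag(fixed) <- 1
    }
    dimnames(fixed) <- dimnames(m$mat)
    out <- corr_matrix(fixed, m$n, m$type, m$p_values)
    attr(out, "max_delta") <- max(abs(fixed - m$mat))
  }
  attr(out, "min_eigenvalue") <- min(e$values)
  out
}

## internal: stop early if a moment matrix is not positive definite
check_pd <- function(mat, what = "moment matrix") {
  ev <- eigen(mat, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop(what, " is not positive definite (min eigenvalue ",
         format(min(ev), digits = 3),
         "); consider nearest_psd()", call. = FALSE)
  invisible(TRUE)
}
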