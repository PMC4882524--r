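#' Simulate trait tables from a path model
#'
#' Draws Gaussian shocks for all exogenous variances and disturbances
#' (respecting declared residual covariances such as the correlated
#' soil-nutrient residuals), propagates them through `(I - A)^-1`, discards
#' latent columns, and optionally rescales the observed columns to target
#' means and SDs. Reproducible under a fixed seed.
#'
#' @param spec a [model_spec()].
#' @param params named vector of free-parameter values keyed by RAM slot
#'   label (see `build_ram(spec)$slots$label`); a standardized population
#'   system uses standardized coefficients with shock variances
#'   `1 - R^2`.
#' @param n number of records.
#' @param seed integer seed.
#' @param means,sds optional named vectors of target means / SDs for
#'   rescaling observed columns (off by default; correlations are
#'   scale-free).
#' @return a [trait_table()] with `n` rows and one column per observed
#'   variable.
#' @export
simulate_model <- function(spec, params, n, seed = 26845,
                           means = NULL, sds = NULL) {
  stopifnot(inherits(spec, "model_spec"), n >= length(spec$observed) + 1)
  ram <- build_ram(spec)
  if (is.null(names(params)) || !all(ram$slots$label %in% names(params)))
    stop("params must be named by RAM slot label")
  m <- ram_matrices(ram, as.numeric(params[ram$slots$label]))
  ev <- eigen(m$S, symmetric = TRUE)
  if (min(ev$values) < -1e-10) stop("shock covariance is not PSD")
  half <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  shocks <- matrix(stats::rnorm(n * ram$k), n, ram$k) %*% half
  B <- solve(diag(ram$k) - m$A)
  x <- shocks %*% t(B)
  colnames(x) <- ram$vars
  x <- x[, spec$observed, drop = FALSE]
  if (!is.null(sds))
    for (v in intersect(colnames(x), names(sds)))
      x[, v] <- x[, v] / stats::sd(x[, v]) * sds[[v]]
  if (!is.null(means))
    for (v in intersect(colnames(x), names(means)))
      x[, v] <- x[, v] - mean(x[, v]) + means[[v]]
  trait_table(as.data.frame(x))
}

#' Population parameter vector of a fitted model
#'
#' Convenience for recovery experiments: returns the fitted raw or
#' standardized estimates keyed by slot label, directly usable as
#' `params` in [simulate_model()].
#'
#' @param fit a [fit_ml()] result.
#' @param standardized use the standardized solution (default).
#' @return named numeric vector.
#' @export
fitted_params <- function(fit, standardized = TRUE) {
  stopifnot(inherits(fit, "sem_fit"))
  if (standardized) {
    if (is.null(fit$std)) fit <- standardize(fit)
    stats::setNames(fit$std$table$estimate, fit$std$table$label)
  } else fit$estimates
}

#' Sample with an exact in-sample correlation matrix
#'
#' Draws an n-by-p Gaussian matrix, centers it, whitens it with its own
#' sample factor, and recolors with the Cholesky factor of the target, so
#' the sample correlation matrix of the output equals the target to
#' numerical precision (columns have mean 0 and variance 1 in-sample).
#' Bridges raw-data operations and a printed correlation table: any
#' moment-based fit on the output equals the fit on the target matrix.
#'
#' @param target a positive-definite [corr_matrix()].
#' @param n rows to generate; must exceed the number of variables.
#' @param seed integer seed.
#' @return a [trait_table()].
#' @export
exact_moment_sample <- function(target, n = NULL, seed = 26845) {
  stopifnot(inherits(target, "corr_matrix"))
  if (is.null(n)) n <- target$n
  p <- ncol(target$mat)
  if (n <= p) stop("need n > p to whiten the sample")
  check_pd(target$mat, "target matrix")
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  x <- matrix(stats::rnorm(n * p), n, p)
  x <- scale(x, center = TRUE, scale = FALSE)
  s <- stats::cov(x)
  y <- x %*% solve(chol(s)) %*% chol(target$mat)
  colnames(y) <- colnames(target$mat)
  trait_table(as.data.frame(y))
}
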