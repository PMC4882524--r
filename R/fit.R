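#' Maximum-likelihood discrepancy between a sample and an implied matrix
#'
#' `F = ln det(Sigma) - ln det(S) + tr(S Sigma^-1) - p`. Nonnegative, zero
#' exactly when the two matrices coincide. `(n-1) * F` at the minimum is the
#' model chi-square.
#'
#' @param S sample moment matrix (a [corr_matrix()] or plain symmetric
#'   matrix), positive definite.
#' @param sigma implied covariance matrix with the same variable ordering.
#' @return the scalar discrepancy.
#' @export
ml_discrepancy <- function(S, sigma) {
  if (inherits(S, "corr_matrix")) S <- S$mat
  stopifnot(identical(dim(S), dim(sigma)))
  p <- ncol(S)
  check_pd(S, "sample matrix")
  cS <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(cS))
    stop("implied matrix is not positive definite; consider nearest_psd()",
         call. = FALSE)
  ld_sigma <- 2 * sum(log(diag(cS)))
  ld_s <- c(determinant(S, logarithm = TRUE)$modulus)
  ld_sigma - ld_s + sum(diag(S %*% chol2inv(cS))) - p
}

## ---- internal objective / analytic gradient on the transformed scale ----
## variances are log-transformed; everything else is raw.

ml_objective <- function(ram, S_samp) {
  p <- ram$p; k <- ram$k
  is_var <- ram$slots$kind == "variance"
  ld_s <- c(determinant(S_samp, logarithm = TRUE)$modulus)

  to_raw <- function(theta) {
    out <- theta
    out[is_var] <- exp(theta[is_var])
    out
  }
  from_raw <- function(params) {
    out <- params
    out[is_var] <- log(pmax(params[is_var], 1e-12))
    out
  }
  fn <- function(theta) {
    m <- ram_matrices(ram, to_raw(theta))
    B <- tryCatch(solve(diag(k) - m$A), error = function(e) NULL)
    if (is.null(B)) return(1e10)
    sig <- (B %*% m$S %*% t(B))[1:p, 1:p, drop = FALSE]
    cS <- tryCatch(chol(sig), error = function(e) NULL)
    if (is.null(cS)) return(1e10)
    val <- 2 * sum(log(diag(cS))) - ld_s + sum(diag(S_samp %*% chol2inv(cS))) - p
    if (!is.finite(val)) 1e10 else val
  }
  gr <- function(theta) {
    raw <- to_raw(theta)
    m <- ram_matrices(ram, raw)
    B <- solve(diag(k) - m$A)
    FB <- B[1:p, , drop = FALSE]
    sig <- FB %*% m$S %*% t(FB)
    si <- tryCatch(chol2inv(chol(sig)), error = function(e) NULL)
    if (is.null(si)) return(rep(0, length(theta)))
    W <- si - si %*% S_samp %*% si          # dF/dSigma (symmetric part)
    BSBt <- B %*% m$S %*% t(B)
    sl <- ram$slots
    g <- numeric(nrow(sl))
    for (i in seq_len(nrow(sl))) {
      r <- sl$row[i]; cc <- sl$col[i]
      if (sl$matrix[i] == "A") {
        D <- B[1:p, r] %o% BSBt[cc, 1:p]
        g[i] <- sum(W * (D + t(D)))
      } else if (r == cc) {
        g[i] <- sum(W * (FB[, r] %o% FB[, r])) * raw[i]  # chain rule, log scale
      } else {
        D <- FB[, r] %o% FB[, cc]
        g[i] <- sum(W * (D + t(D)))
      }
    }
    g
  }
  list(fn = fn, gr = gr, to_raw = to_raw, from_raw = from_raw, is_var = is_var)
}

#' Fit a structural equation model by maximum likelihood
#'
#' Minimizes the ML discrepancy between the model-implied covariance and the
#' supplied moment matrix over the free parameters, with variance parameters
#' kept positive through a log transform (bounded below at 1e-6). The
#' optimizer is a quasi-Newton method with an analytic gradient; `restarts`
#' seeded perturbed starts are tried and the best objective kept. A fit is
#' declared converged when the gradient norm falls below 1e-6.
#'
#' A correlation matrix is treated as a covariance matrix (the standard
#' reproducible route when only a printed correlation table is available);
#' standard errors on such input are approximate.
#'
#' @param spec a [model_spec()].
#' @param moments a [corr_matrix()] with `n` greater than the number of
#'   observed variables.
#' @param restarts number of optimizer starts (first is unperturbed).
#' @param seed integer seed controlling the start perturbations.
#' @param se compute standard errors (see [standard_errors()]).
#' @param indices compute fit indices (see [fit_indices()]).
#' @param start optional named vector of raw-scale start values (matched by
#'   slot label); used to warm-start refits during the backward search.
#' @return an object of class `sem_fit`: estimates (raw and standardized),
#'   `F_min`, `chisq`, `df`, `p_value`, fit indices, per-variable R-squared,
#'   standard errors, and optimizer diagnostics.
#' @export
fit_ml <- function(spec, moments, restarts = 5, seed = 26845,
                   se = TRUE, indices = TRUE, start = NULL) {
  stopifnot(inherits(spec, "model_spec"), inherits(moments, "corr_matrix"))
  miss <- setdiff(spec$observed, rownames(moments$mat))
  if (length(miss))
    stop("moment matrix lacks variable(s): ", paste(miss, collapse = ", "))
  moments <- subset_corr(moments, spec$observed)
  S_samp <- moments$mat
  n <- moments$n
  p <- length(spec$observed)
  if (n <= p) stop("need n > number of observed variables")
  check_pd(S_samp, "moment matrix")
  df <- count_df(spec)

  ram <- build_ram(spec)
  obj <- ml_objective(ram, S_samp)
  raw0 <- ram_start(ram, S_samp)
  if (!is.null(start)) {
    hit <- intersect(names(start), names(raw0))
    raw0[hit] <- start[hit]
    raw0[obj$is_var] <- pmax(raw0[obj$is_var], 1e-4)
  }
  theta0 <- obj$from_raw(raw0)
  lower <- ifelse(obj$is_var, log(1e-6), -Inf)

  best <- NULL; tried <- 0L
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  for (r in seq_len(restarts)) {
    set.seed(seed + r - 1L)
    th <- if (r == 1) theta0 else theta0 + stats::rnorm(length(theta0), 0, 0.2)
    o <- tryCatch(
      stats::nlminb(th, obj$fn, gradient = obj$gr, lower = lower,
                    control = list(iter.max = 2000, eval.max = 4000,
                                   rel.tol = 1e-14, abs.tol = 1e-8)),
      error = function(e) NULL)
    if (is.null(o) || !is.finite(o$objective)) next
    tried <- tried + 1L
    if (is.null(best) || o$objective < best$objective) best <- o
  }
  if (is.null(best)) stop("optimization failed in every restart")

  proj_norm <- function(par) {
    g <- obj$gr(par)
    at <- obj$is_var & par <= log(1e-6) + 1e-8
    g[at & g > 0] <- 0
    sqrt(sum(g^2))
  }
  if (proj_norm(best$par) >= 1e-6) {    # polish flat tails to the tolerance
    o <- tryCatch(
      stats::optim(best$par, obj$fn, obj$gr, method = "L-BFGS-B",
                   lower = lower, control = list(maxit = 5000, factr = 1)),
      error = function(e) NULL)
    if (!is.null(o) && o$value <= best$objective + 1e-12)
      best <- list(par = o$par, objective = o$value,
                   iterations = best$iterations)
  }

  g <- obj$gr(best$par)
  at_bound <- obj$is_var & best$par <= log(1e-6) + 1e-8
  g[at_bound & g > 0] <- 0          # KKT: bound-active gradients may be positive
  grad_norm <- sqrt(sum(g^2))
  converged <- is.finite(best$objective) && grad_norm < 1e-6
  est <- obj$to_raw(best$par)
  names(est) <- ram$slots$label
  heywood <- any(obj$is_var & est <= 1e-6 * (1 + 1e-8))
  if (heywood)
    warning("Heywood case: variance estimate at its lower bound", call. = FALSE)

  Fmin <- best$objective
  chisq <- (n - 1) * Fmin
  fit <- structure(list(
    spec = spec, ram = ram, moments = moments, n = n,
    estimates = est, F_min = Fmin,
    chisq = chisq, df = df,
    p_value = if (df > 0) stats::pchisq(chisq, df, lower.tail = FALSE) else NA_real_,
    converged = converged, grad_norm = grad_norm,
    iterations = best$iterations, restarts_used = tried,
    heywood = heywood,
    implied = implied_covariance(ram, est)
  ), class = "sem_fit")

  fit <- standardize(fit)
  if (indices && converged) fit <- fit_indices(fit)
  if (se && converged) fit <- standard_errors(fit)
  if (!converged)
    warning("fit did not converge (gradient norm ", format(grad_norm),
            "); indices suppressed", call. = FALSE)
  fit
}

#' Independence-baseline fit
#'
#' The baseline model frees every variance and fixes all covariances at
#' zero; its ML solution is closed-form (`Sigma = diag(S)`), giving
#' `F_b = sum(log diag(S)) - log det(S)` — for a correlation matrix R simply
#' `-log det(R)` — with `df_b = p(p-1)/2`. Needed by the comparative fit
#' index.
#'
#' @param moments a [corr_matrix()].
#' @return list with `F_min`, `chisq`, `df`, `n`.
#' @export
baseline_fit <- function(moments) {
  stopifnot(inherits(moments, "corr_matrix"))
  S <- moments$mat
  check_pd(S)
  p <- ncol(S)
  Fb <- sum(log(diag(S))) - c(determinant(S, logarithm = TRUE)$modulus)
  structure(list(F_min = Fb, chisq = (moments$n - 1) * Fb,
                 df = p * (p - 1) / 2, n = moments$n),
            class = "sem_baseline")
}

#' Fit indices for a converged model
#'
#' Augments a fit with: RMSEA `sqrt(max(chisq - df, 0) / (df (n-1)))`;
#' GFI `1 - tr[(Sigma^-1 S - I)^2] / tr[(Sigma^-1 S)^2]`;
#' AGFI `1 - p(p+1)/(2 df) (1 - GFI)`; CFI
#' `1 - max(chisq - df, 0) / max(chisq_b - df_b, chisq - df, 0)`; and
#' AIC `chisq + 2 t`. RMSEA and AGFI are undefined (NA) at df = 0.
#'
#' @param fit a converged [fit_ml()] result.
#' @param baseline optional [baseline_fit()] on the same moments (computed
#'   if omitted).
#' @return `fit` with an `indices` list added.
#' @export
fit_indices <- function(fit, baseline = NULL) {
  stopifnot(inherits(fit, "sem_fit"))
  if (!fit$converged) stop("fit indices require a converged fit")
  if (is.null(baseline)) baseline <- baseline_fit(fit$moments)
  p <- fit$ram$p; df <- fit$df; n <- fit$n
  chisq <- fit$chisq
  S <- fit$moments$mat
  sig_inv_S <- chol2inv(chol(fit$implied)) %*% S
  gfi <- 1 - sum(diag((sig_inv_S - diag(p)) %*% (sig_inv_S - diag(p)))) /
    sum(diag(sig_inv_S %*% sig_inv_S))
  rmsea <- if (df > 0) sqrt(max(chisq - df, 0) / (df * (n - 1))) else NA_real_
  agfi <- if (df > 0) 1 - (p * (p + 1) / (2 * df)) * (1 - gfi) else NA_real_
  denom <- max(baseline$chisq - baseline$df, chisq - df, 0)
  cfi <- if (denom > 0) 1 - max(chisq - df, 0) / denom else 1
  fit$indices <- list(chisq = chisq, df = df, p_value = fit$p_value,
                      rmsea = rmsea, gfi = gfi, agfi = agfi, cfi = cfi,
                      aic = chisq + 2 * nrow(fit$ram$slots),
                      baseline_chisq = baseline$chisq,
                      baseline_df = baseline$df)
  fit
}

#' Standard errors via the numerically differentiated Hessian
#'
#' Parameter covariance is `(2 / (n-1)) H^-1`, with `H` the central-difference
#' Hessian (step 1e-5) of the ML discrepancy at the optimum on the
#' transformed (log-variance) scale; variance-parameter SEs are mapped back
#' by the delta method. z is estimate/SE with a two-sided normal p-value.
#'
#' @param fit a converged [fit_ml()] result.
#' @return `fit` with columns `se`, `z`, `p` added to `fit$parameters`.
#' @export
standard_errors <- function(fit) {
  stopifnot(inherits(fit, "sem_fit"))
  if (!fit$converged) stop("standard errors require a converged fit")
  ram <- fit$ram
  obj <- ml_objective(ram, fit$moments$mat)
  theta <- obj$from_raw(fit$estimates)
  t_len <- length(theta)
  h <- 1e-5
  H <- matrix(NA_real_, t_len, t_len)
  f0 <- obj$fn(theta)
  step <- function(i, s) { th <- theta; th[i] <- th[i] + s; th }
  for (i in seq_len(t_len)) {
    H[i, i] <- (obj$fn(step(i, h)) - 2 * f0 + obj$fn(step(i, -h))) / h^2
    if (i > 1) for (j in seq_len(i - 1)) {
      thpp <- step(i, h); thpp[j] <- thpp[j] + h
      thpm <- step(i, h); thpm[j] <- thpm[j] - h
      thmp <- step(i, -h); thmp[j] <- thmp[j] + h
      thmm <- step(i, -h); thmm[j] <- thmm[j] - h
      H[i, j] <- H[j, i] <-
        (obj$fn(thpp) - obj$fn(thpm) - obj$fn(thmp) + obj$fn(thmm)) / (4 * h^2)
    }
  }
  est <- fit$estimates
  ## variance parameters at their lower bound behave as fixed: exclude them
  ## from the information matrix (their own SE is undefined at the boundary)
  free <- !(obj$is_var & est <= 1e-6 * (1 + 1e-6))
  se_t <- rep(NA_real_, t_len)
  vc <- tryCatch((2 / (fit$n - 1)) * solve(H[free, free, drop = FALSE]),
                 error = function(e) NULL)
  if (is.null(vc) || any(!is.finite(diag(vc))) || any(diag(vc) < 0)) {
    message("Hessian singular or indefinite; standard errors unavailable")
  } else {
    se_t[free] <- sqrt(diag(vc))
  }
  se_raw <- ifelse(obj$is_var, est * se_t, se_t)   # delta method off log scale
  z <- est / se_raw
  fit$parameters <- data.frame(label = ram$slots$label, kind = ram$slots$kind,
                               estimate = unname(est), se = unname(se_raw),
                               z = unname(z),
                               p = unname(2 * stats::pnorm(-abs(z))),
                               stringsAsFactors = FALSE)
  fit
}

#' @export
print.sem_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<sem_fit: %d observed, %d free parameters, %s>\n",
              x$ram$p, nrow(x$ram$slots),
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  chisq = %.3f on df = %d (p = %s), F_ml = %.6f\n",
              x$chisq, x$df,
              if (is.na(x$p_value)) "NA" else sprintf("%.3f", x$p_value),
              x$F_min))
  if (!is.null(x$indices))
    cat(sprintf("  RMSEA = %.3f  AGFI = %.3f  CFI = %.3f  AIC = %.2f\n",
                x$indices$rmsea, x$indices$agfi, x$indices$cfi, x$indices$aic))
  if (!is.null(x$std)) {
    cat("  standardized solution:\n")
    tab <- x$std$table
    tab$estimate <- round(tab$estimate, digits)
    print(tab, row.names = FALSE)
  }
  invisible(x)
}
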