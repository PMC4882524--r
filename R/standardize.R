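#' Standardized solution
#'
#' Rescales every coefficient by implied-SD ratios so all variables
#' (including latents) have unit variance: a path or loading `j -> i`
#' becomes `a_ij * sd(j) / sd(i)`; (co)variances become correlations.
#' Each latent's sign is then normalized so that its first indicator's
#' standardized loading is positive (the latent "points the same way" as
#' its anchor indicator); sign flips leave all fitted moments unchanged.
#'
#' @param fit a [fit_ml()] result.
#' @return `fit` with a `std` element: standardized `A` and `S` over the
#'   full (observed + latent) system, implied SDs, flipped latents, and a
#'   tidy coefficient table.
#' @export
standardize <- function(fit) {
  stopifnot(inherits(fit, "sem_fit"))
  ram <- fit$ram
  m <- ram_matrices(ram, fit$estimates)
  B <- solve(diag(ram$k) - m$A)
  full <- B %*% m$S %*% t(B)
  sdv <- sqrt(diag(full))
  if (any(sdv <= 0)) stop("zero implied variance; cannot standardize")
  Astar <- m$A * outer(1 / sdv, sdv)
  Sstar <- m$S * outer(1 / sdv, 1 / sdv)
  dimnames(Astar) <- dimnames(Sstar) <- list(ram$vars, ram$vars)

  flipped <- character()
  for (l in names(ram$spec$latents)) {
    first <- ram$spec$latents[[l]][1]
    if (Astar[first, l] < 0) {
      Astar[, l] <- -Astar[, l]; Astar[l, ] <- -Astar[l, ]
      Sstar[, l] <- -Sstar[, l]; Sstar[l, ] <- -Sstar[l, ]
      flipped <- c(flipped, l)
    }
  }

  sl <- ram$slots
  std_est <- numeric(nrow(sl))
  for (i in seq_len(nrow(sl))) {
    if (sl$matrix[i] == "A") std_est[i] <- Astar[sl$row[i], sl$col[i]]
    else std_est[i] <- Sstar[sl$row[i], sl$col[i]]
  }
  tab <- data.frame(label = sl$label, kind = sl$kind, estimate = std_est,
                    stringsAsFactors = FALSE)
  fit$std <- list(A = Astar, S = Sstar, sd = sdv, flipped = flipped,
                  table = tab)
  fit
}

#' Explained variance per endogenous variable
#'
#' In the standardized metric each variable has unit variance, so
#' `R^2(v) = 1 - standardized disturbance variance of v` for every variable
#' with at least one incoming path or loading.
#'
#' @param fit a standardized [fit_ml()] result.
#' @return named numeric vector of R-squared values.
#' @export
r_squared <- function(fit) {
  stopifnot(inherits(fit, "sem_fit"))
  if (is.null(fit$std)) fit <- standardize(fit)
  A <- fit$std$A
  endo <- rownames(A)[rowSums(A != 0) > 0]
  out <- 1 - diag(fit$std$S)[endo]
  names(out) <- endo
  out
}
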