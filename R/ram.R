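#' Reticular (RAM) matrix form of a path model
#'
#' Translates a [model_spec()] into the standard reticular form: an
#' asymmetric coefficient matrix `A` (paths and loadings, column = source,
#' row = target), a symmetric matrix `S` (variances on the diagonal, free
#' covariances off it), and an observed-row filter. The implied covariance
#' over the observed variables is `F (I-A)^{-1} S (I-A)^{-T} F'`. Each free
#' parameter owns exactly one slot (plus its mirror in `S`); the first
#' loading of every latent is fixed to 1.
#'
#' @param spec a [model_spec()].
#' @return an object of class `ram_system` with elements `vars` (observed
#'   then latent), `p`, `k`, `slots` (one row per free parameter: label,
#'   matrix, row, col, kind), and `fixed` (fixed unit loadings).
#' @export
build_ram <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  vars <- c(spec$observed, spec$lat_names)
  k <- length(vars); p <- length(spec$observed)
  idx <- stats::setNames(seq_len(k), vars)

  lab <- character(); mtx <- character(); row <- integer(); col <- integer()
  kind <- character()
  add <- function(l, m, r, c, kd) {
    lab <<- c(lab, l); mtx <<- c(mtx, m); row <<- c(row, r); col <<- c(col, c)
    kind <<- c(kind, kd)
  }
  if (nrow(spec$paths))
    for (i in seq_len(nrow(spec$paths)))
      add(paste0(spec$paths$from[i], "->", spec$paths$to[i]), "A",
          idx[[spec$paths$to[i]]], idx[[spec$paths$from[i]]], "path")
  fixed <- list()
  for (l in names(spec$latents)) {
    inds <- spec$latents[[l]]
    fixed[[length(fixed) + 1]] <- c(idx[[inds[1]]], idx[[l]])
    for (ind in inds[-1])
      add(paste0("load(", ind, ")"), "A", idx[[ind]], idx[[l]], "loading")
  }
  if (nrow(spec$covs))
    for (i in seq_len(nrow(spec$covs)))
      add(paste0(spec$covs$a[i], "~~", spec$covs$b[i]), "S",
          idx[[spec$covs$a[i]]], idx[[spec$covs$b[i]]], "cov")
  for (v in vars)
    add(paste0("var(", v, ")"), "S", idx[[v]], idx[[v]], "variance")

  slots <- data.frame(label = lab, matrix = mtx, row = row, col = col,
                      kind = kind, stringsAsFactors = FALSE)
  stopifnot(nrow(slots) == n_free(spec))
  structure(list(spec = spec, vars = vars, observed = spec$observed,
                 p = p, k = k, slots = slots, fixed = fixed),
            class = "ram_system")
}

#' @export
print.ram_system <- function(x, ...) {
  cat(sprintf("<ram_system: %d observed + %d latent, %d free parameters>\n",
              x$p, x$k - x$p, nrow(x$slots)))
  invisible(x)
}

## internal: materialize A and S at a parameter vector (raw scale)
ram_matrices <- function(ram, params) {
  stopifnot(length(params) == nrow(ram$slots))
  k <- ram$k
  A <- matrix(0, k, k, dimnames = list(ram$vars, ram$vars))
  S <- matrix(0, k, k, dimnames = list(ram$vars, ram$vars))
  sl <- ram$slots
  for (i in seq_len(nrow(sl))) {
    if (sl$matrix[i] == "A") A[sl$row[i], sl$col[i]] <- params[i]
    else {
      S[sl$row[i], sl$col[i]] <- params[i]
      S[sl$col[i], sl$row[i]] <- params[i]
    }
  }
  for (f in ram$fixed) A[f[1], f[2]] <- 1
  list(A = A, S = S)
}

#' Model-implied covariance matrix
#'
#' @param ram a [build_ram()] system.
#' @param params numeric vector of free-parameter values, in slot order
#'   (see `ram$slots$label`); a named vector is matched by label.
#' @return symmetric implied covariance matrix over the observed variables.
#' @export
implied_covariance <- function(ram, params) {
  stopifnot(inherits(ram, "ram_system"))
  if (!is.null(names(params)) && all(ram$slots$label %in% names(params)))
    params <- params[ram$slots$label]
  m <- ram_matrices(ram, as.numeric(params))
  B <- solve(diag(ram$k) - m$A)
  full <- B %*% m$S %*% t(B)
  sig <- full[seq_len(ram$p), seq_len(ram$p), drop = FALSE]
  sig <- (sig + t(sig)) / 2
  dimnames(sig) <- list(ram$observed, ram$observed)
  sig
}

## internal: default start values (paths 0, loadings 1, variances half the
## sample variance of the mapped variable -- 0.5 on correlation input)
ram_start <- function(ram, S_samp) {
  sl <- ram$slots
  start <- numeric(nrow(sl))
  svar <- stats::setNames(rep(1, ram$k), ram$vars)
  svar[colnames(S_samp)] <- diag(S_samp)
  for (l in names(ram$spec$latents))  # latent scale follows its first indicator
    svar[l] <- svar[ram$spec$latents[[l]][1]]
  for (i in seq_len(nrow(sl))) {
    start[i] <- switch(sl$kind[i],
                       path = 0, cov = 0, loading = 1,
                       variance = 0.5 * svar[ram$vars[sl$row[i]]])
  }
  names(start) <- sl$label
  start
}
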