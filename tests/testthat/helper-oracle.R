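# Independent ML oracle for recursive observed-variable path models.
#
# For a DAG with independent disturbances the Gaussian likelihood factorizes
# over equations, so the ML solution is closed-form: each child's
# coefficients are the regression of the child on its parents computed from
# the sample moment matrix, and the residual variance is the corresponding
# regression residual variance. The implied covariance matrix is then built
# recursively in topological order (path-tracing rules), with no RAM matrix
# inverse, so this route shares no code with the package's optimizer.

oracle_fit_dag <- function(spec, moments) {
  S <- if (inherits(moments, "corr_matrix")) moments$mat else moments
  ord <- foliarsem:::topo_order(spec)
  parents <- function(v) spec$paths$from[spec$paths$to == v]

  coefs <- list(); resid <- numeric(0)
  for (v in ord) {
    pa <- parents(v)
    if (length(pa)) {
      b <- solve(S[pa, pa, drop = FALSE], S[pa, v])
      coefs[[v]] <- stats::setNames(as.numeric(b), pa)
      resid[v] <- S[v, v] - sum(b * S[pa, v])
    } else {
      coefs[[v]] <- numeric(0)
      resid[v] <- S[v, v]
    }
  }

  # implied moments by recursion in topological order:
  # cov(v, earlier u) = sum_pa b_pa cov(pa, u); var(v) = b' Cov(pa) b + resid
  imp <- matrix(0, length(ord), length(ord), dimnames = list(ord, ord))
  for (i in seq_along(ord)) {
    v <- ord[i]; pa <- parents(v)
    if (i > 1) for (j in seq_len(i - 1)) {
      u <- ord[j]
      imp[v, u] <- imp[u, v] <- if (length(pa))
        sum(coefs[[v]] * imp[pa, u]) else 0
    }
    imp[v, v] <- resid[v] + if (length(pa))
      drop(coefs[[v]] %*% imp[pa, pa, drop = FALSE] %*% coefs[[v]]) else 0
  }

  sdv <- sqrt(diag(imp))
  std <- list()
  for (v in ord) for (u in names(coefs[[v]]))
    std[[paste0(u, "->", v)]] <-
      as.numeric(coefs[[v]][u] * sdv[u] / sdv[v])
  endo <- ord[vapply(ord, function(v) length(parents(v)) > 0, logical(1))]
  list(coefs = coefs, resid = resid, implied = imp, std = unlist(std),
       r_squared = vapply(endo, function(v) 1 - resid[v] / imp[v, v],
                          numeric(1)))
}
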