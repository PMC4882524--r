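#' Orthogonal-shock variance partitioning
#'
#' In the standardized system every variable is a linear combination of
#' independent source shocks (exogenous variables and disturbances):
#' `x = (I - A*)^-1 e`, `Var(e) = S*`. The variance of a response `v` —
#' exactly 1 — therefore splits additively over groups of shocks: the
#' contribution of group `G` is the quadratic form of `v`'s row of
#' `(I - A*)^-1` with `S*` restricted to `G`'s rows and columns.
#' Covariances *within* a group (e.g. correlated soil-nutrient residuals)
#' stay inside that group's share; covariances *across* groups would break
#' additivity and are rejected. The response's own disturbance is excluded
#' from every group share, so the group shares sum to `100 * R^2`.
#'
#' @param fit a standardized, converged [fit_ml()] result.
#' @param groups named list: group label -> character vector of variables
#'   whose shock (exogenous variance or disturbance) the group owns. `NULL`
#'   puts every shock in its own group.
#' @param response a single endogenous variable name.
#' @return `partition_r2()`: one-row data frame of percentages plus
#'   `total`; `partition_all()`: class `varpart_table`, one row per
#'   endogenous structural variable (latents included, indicators not).
#' @export
partition_r2 <- function(fit, groups = NULL, response) {
  stopifnot(inherits(fit, "sem_fit"))
  if (is.null(fit$std)) fit <- standardize(fit)
  A <- fit$std$A; S <- fit$std$S
  vars <- rownames(A)
  if (!response %in% vars) stop("unknown response: ", response)
  if (all(A[response, ] == 0)) stop("'", response, "' is exogenous")
  if (is.null(groups)) {
    src <- setdiff(structural_vars(fit), response)
    groups <- stats::setNames(as.list(src), src)
  }
  B <- solve(diag(length(vars)) - A)
  dimnames(B) <- dimnames(A)
  rowv <- B[response, ]

  ## shocks that actually feed the response (its own excluded)
  feeders <- vars[abs(rowv) > 1e-12 & diag(S) > 0]
  feeders <- setdiff(feeders, response)
  covered <- unlist(groups, use.names = FALSE)
  orphans <- setdiff(feeders, covered)
  if (length(orphans))
    stop("groups do not cover source shock(s): ",
         paste(orphans, collapse = ", "))
  ## cross-group shock covariances break exact additivity
  gl <- lapply(groups, function(g) setdiff(intersect(g, vars), response))
  for (i in seq_along(gl)) for (j in seq_along(gl)) {
    if (i < j && length(gl[[i]]) && length(gl[[j]]) &&
        max(abs(S[gl[[i]], gl[[j]], drop = FALSE])) > 1e-12)
      stop("shock covariance across groups '", names(gl)[i], "' and '",
           names(gl)[j], "'; decomposition would not be additive")
  }
  shares <- vapply(gl, function(g) {
    if (!length(g)) return(0)
    100 * drop(rowv[g] %*% S[g, g, drop = FALSE] %*% rowv[g])
  }, numeric(1))
  out <- as.data.frame(as.list(shares), check.names = FALSE)
  out <- cbind(data.frame(response = response, stringsAsFactors = FALSE), out)
  out$total <- sum(shares)
  out
}

#' @rdname partition_r2
#' @export
partition_all <- function(fit, groups = NULL) {
  stopifnot(inherits(fit, "sem_fit"))
  if (is.null(fit$std)) fit <- standardize(fit)
  A <- fit$std$A
  resp <- intersect(structural_vars(fit), rownames(A)[rowSums(A != 0) > 0])
  rows <- lapply(resp, function(v) partition_r2(fit, groups, v))
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(response = character(), total = numeric())
  rownames(out) <- NULL
  class(out) <- c("varpart_table", "data.frame")
  out
}

## internal: structural variables = everything except pure indicators
structural_vars <- function(fit) {
  setdiff(fit$ram$vars, unlist(fit$spec$latents, use.names = FALSE))
}

#' Write a variance-partition table to CSV or JSON
#'
#' @param x a [partition_all()] table.
#' @param path output file; format by extension (`.csv` or `.json`).
#' @param digits decimals for the CSV (percent convention; default 1).
#' @export
write_varpart <- function(x, path, digits = 1) {
  df <- as.data.frame(x)
  if (grepl("\\.json$", path))
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  else {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], round, digits)
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
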