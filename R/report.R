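#' Serialize a fit to JSON
#'
#' Writes estimates, standardized estimates, fit indices, per-variable
#' R-squared, and (when available) standard errors.
#'
#' @param fit a [fit_ml()] result.
#' @param path output file.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "sem_fit"))
  if (is.null(fit$std)) fit <- standardize(fit)
  out <- list(
    model = model_text(fit$spec),
    n = fit$n,
    converged = fit$converged,
    estimates = as.list(fit$estimates),
    standardized = stats::setNames(as.list(fit$std$table$estimate),
                                   fit$std$table$label),
    chisq = fit$chisq, df = fit$df, p_value = fit$p_value,
    indices = fit$indices,
    r_squared = as.list(r_squared(fit)),
    parameters = fit$parameters)
  jsonlite::write_json(out, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' Human-readable fit report
#'
#' A fixed-format text block mirroring the usual fit-index table layout
#' (3 decimals for coefficients, 3 for indices), suitable for diffing
#' across runs.
#'
#' @param fit a [fit_ml()] result with indices.
#' @return character vector of report lines.
#' @export
fit_report <- function(fit) {
  stopifnot(inherits(fit, "sem_fit"))
  if (is.null(fit$std)) fit <- standardize(fit)
  lines <- c(
    sprintf("n = %d, free parameters = %d", fit$n, nrow(fit$ram$slots)),
    sprintf("chisq = %.3f  df = %d  p = %s", fit$chisq, fit$df,
            if (is.na(fit$p_value)) "NA" else sprintf("%.3f", fit$p_value)))
  if (!is.null(fit$indices))
    lines <- c(lines, sprintf("RMSEA = %.3f  AGFI = %.3f  CFI = %.3f  AIC = %.3f",
                              fit$indices$rmsea, fit$indices$agfi,
                              fit$indices$cfi, fit$indices$aic))
  lines <- c(lines, "standardized solution:")
  tab <- fit$std$table
  lines <- c(lines, sprintf("  %-18s %8.3f", tab$label, tab$estimate))
  r2 <- r_squared(fit)
  lines <- c(lines, "R-squared:",
             sprintf("  %-18s %8.3f", names(r2), r2))
  lines
}
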