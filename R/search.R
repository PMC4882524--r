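#' AIC comparison of two fitted models
#'
#' AIC here follows the `chisq + 2t` convention. Two fits are directly
#' comparable only when they model the same observed variables; otherwise
#' the difference is still reported but flagged.
#'
#' @param a,b [fit_ml()] results with computed indices.
#' @return list: `better` (`"a"`, `"b"` or `"tie"`), `delta`
#'   (`AIC(a) - AIC(b)`), `comparable`.
#' @export
compare_aic <- function(a, b) {
  stopifnot(inherits(a, "sem_fit"), inherits(b, "sem_fit"))
  if (is.null(a$indices) || is.null(b$indices))
    stop("both fits need indices (fit_indices)")
  comparable <- setequal(a$spec$observed, b$spec$observed)
  if (!comparable)
    warning("AIC compared across different observed-variable sets",
            call. = FALSE)
  delta <- a$indices$aic - b$indices$aic
  list(better = if (delta < 0) "a" else if (delta > 0) "b" else "tie",
       delta = delta, comparable = comparable)
}

#' Backward AIC-guided model simplification
#'
#' Starting from a prior model, repeatedly fits every candidate obtained by
#' dropping one structural path or one free covariance (loadings are never
#' dropped), accepts the drop with the lowest AIC provided it is below the
#' current AIC, and stops when no drop improves AIC. Ties break
#' lexicographically by edge label. After each accepted drop, housekeeping
#' removes structural observed variables that have become explanatorily
#' inert: variables with no incident edge at all, and non-outcome variables
#' left without any directed route to an outcome (their remaining incident
#' edges are deleted and the moment matrix shrinks; such steps are flagged
#' as not AIC-comparable). Candidate fits that fail to converge are skipped
#' with a warning.
#'
#' After the AIC pass, structural paths and covariances whose two-sided
#' p-value exceeds `alpha` are eliminated one at a time (largest p first,
#' refitting in between), mirroring the usual reporting convention that a
#' published path diagram carries only significant arrows; set
#' `alpha = NULL` to keep the pure-AIC endpoint.
#'
#' @param prior a [model_spec()] identified on `moments`.
#' @param moments a [corr_matrix()] covering the prior's observed variables.
#' @param outcome character vector of outcome variables; default: the
#'   structural sinks of the prior (endogenous, no outgoing path).
#' @param alpha significance level for the post-AIC elimination stage
#'   (default `NULL`: pure-AIC endpoint, the recommended default since
#'   inflated boundary-case standard errors can cascade; set e.g. 0.05 to
#'   mirror published-diagram pruning).
#' @param restarts optimizer restarts per candidate fit (warm-started from
#'   the current solution).
#' @param seed integer seed (fit restarts are seeded from it).
#' @param verbose print accepted actions as the search runs.
#' @return an object of class `search_trace`: `steps` (data frame of
#'   action, chisq, df, AIC, comparability), `final` ([model_spec()]),
#'   `final_fit`, `removed` (variables dropped from the model).
#' @export
stepwise_prune <- function(prior, moments, outcome = NULL, restarts = 2,
                           seed = 26845, alpha = NULL, verbose = FALSE) {
  stopifnot(inherits(prior, "model_spec"), inherits(moments, "corr_matrix"))
  if (is.null(outcome)) {
    endo <- unique(prior$paths$to)
    outcome <- setdiff(endo, prior$paths$from)
    outcome <- setdiff(outcome, names(prior$latents))
  }
  if (!length(outcome)) stop("cannot determine outcome variable(s)")

  fit_quiet <- function(spec, start = NULL)
    tryCatch(
      suppressWarnings(fit_ml(spec, moments, restarts = restarts,
                              seed = seed, se = FALSE, indices = TRUE,
                              start = start)),
      error = function(e) NULL)

  cur_spec <- prior
  cur_fit <- fit_quiet(cur_spec)
  if (is.null(cur_fit) || !cur_fit$converged)
    stop("prior model does not converge on these moments")
  if (cur_fit$df < 0) stop("prior model is under-identified")

  steps <- data.frame(action = "start", label = NA_character_,
                      chisq = cur_fit$chisq, df = cur_fit$df,
                      aic = cur_fit$indices$aic,
                      n_observed = length(cur_spec$observed),
                      aic_comparable = TRUE, stringsAsFactors = FALSE)
  removed <- character()

  record <- function(action, label, fit, comparable) {
    steps <<- rbind(steps, data.frame(
      action = action, label = label, chisq = fit$chisq, df = fit$df,
      aic = fit$indices$aic, n_observed = length(fit$spec$observed),
      aic_comparable = comparable, stringsAsFactors = FALSE))
    if (verbose) message(action, " ", label, "  (AIC ",
                         round(fit$indices$aic, 2), ")")
  }

  housekeeping <- function(spec, fit) {
    repeat {
      changed <- FALSE
      incident <- c(spec$paths$from, spec$paths$to, spec$covs$a, spec$covs$b)
      droppable <- setdiff(struct_observed(spec), outcome)
      alive <- reaches(spec, intersect(outcome, spec$structural))
      for (v in droppable) {
        inert <- !(v %in% incident) || !(v %in% alive)
        if (inert) {
          spec <- spec_remove_variable(spec, v)
          newfit <- fit_quiet(spec, start = fit$estimates)
          if (is.null(newfit) || !newfit$converged) {
            warning("refit after removing '", v, "' failed; variable kept",
                    call. = FALSE)
            next
          }
          fit <- newfit
          removed <<- c(removed, v)
          record("remove variable", v, fit, comparable = FALSE)
          changed <- TRUE
          break
        }
      }
      if (!changed) break
    }
    list(spec = spec, fit = fit)
  }

  hk <- housekeeping(cur_spec, cur_fit)
  cur_spec <- hk$spec; cur_fit <- hk$fit

  repeat {
    cands <- list()
    if (nrow(cur_spec$paths))
      for (i in seq_len(nrow(cur_spec$paths)))
        cands[[length(cands) + 1]] <- list(
          kind = "drop path",
          label = paste0(cur_spec$paths$from[i], "->", cur_spec$paths$to[i]),
          spec = spec_drop_path(cur_spec, cur_spec$paths$from[i],
                                cur_spec$paths$to[i]))
    if (nrow(cur_spec$covs))
      for (i in seq_len(nrow(cur_spec$covs)))
        cands[[length(cands) + 1]] <- list(
          kind = "drop covariance",
          label = paste0(cur_spec$covs$a[i], "~~", cur_spec$covs$b[i]),
          spec = spec_drop_cov(cur_spec, cur_spec$covs$a[i],
                               cur_spec$covs$b[i]))
    if (!length(cands)) break
    cands <- cands[order(vapply(cands, `[[`, character(1), "label"))]

    aics <- rep(NA_real_, length(cands))
    fits <- vector("list", length(cands))
    for (i in seq_along(cands)) {
      f <- fit_quiet(cands[[i]]$spec, start = cur_fit$estimates)
      if (is.null(f) || !f$converged) {
        warning("candidate '", cands[[i]]$label,
                "' did not converge; skipped", call. = FALSE)
        next
      }
      fits[[i]] <- f
      aics[i] <- f$indices$aic
    }
    if (all(is.na(aics))) break
    best <- which.min(aics)   # first index wins ties (lexicographic order)
    if (aics[best] >= cur_fit$indices$aic) break
    cur_spec <- cands[[best]]$spec
    cur_fit <- fits[[best]]
    record(cands[[best]]$kind, cands[[best]]$label, cur_fit, TRUE)
    hk <- housekeeping(cur_spec, cur_fit)
    cur_spec <- hk$spec; cur_fit <- hk$fit
  }

  ## significance-elimination stage: published diagrams carry only
  ## significant arrows, which backward AIC alone does not guarantee
  ## (AIC retains any edge with delta-chisq >= 2, i.e. p up to ~0.16)
  if (!is.null(alpha)) {
    repeat {
      sf <- tryCatch(suppressWarnings(standard_errors(cur_fit)),
                     error = function(e) NULL)
      if (is.null(sf) || is.null(sf$parameters)) break
      par <- sf$parameters
      cand <- par[par$kind %in% c("path", "cov") & !is.na(par$p) &
                    par$p > alpha, , drop = FALSE]
      if (!nrow(cand)) break
      worst <- cand$label[which.max(cand$p)]
      new_spec <- if (grepl("->", worst, fixed = TRUE)) {
        ends <- strsplit(worst, "->", fixed = TRUE)[[1]]
        spec_drop_path(cur_spec, ends[1], ends[2])
      } else {
        ends <- strsplit(worst, "~~", fixed = TRUE)[[1]]
        spec_drop_cov(cur_spec, ends[1], ends[2])
      }
      new_fit <- fit_quiet(new_spec, start = cur_fit$estimates)
      if (is.null(new_fit) || !new_fit$converged) {
        warning("refit after eliminating '", worst, "' failed; kept",
                call. = FALSE)
        break
      }
      cur_spec <- new_spec; cur_fit <- new_fit
      record("drop insignificant", worst, cur_fit, TRUE)
      hk <- housekeeping(cur_spec, cur_fit)
      cur_spec <- hk$spec; cur_fit <- hk$fit
    }
  }

  structure(list(steps = steps, final = cur_spec, final_fit = cur_fit,
                 removed = removed, outcome = outcome),
            class = "search_trace")
}

#' @export
print.search_trace <- function(x, ...) {
  cat(sprintf("<search_trace: %d steps, removed: %s>\n",
              nrow(x$steps) - 1,
              if (length(x$removed)) paste(x$removed, collapse = ", ")
              else "none"))
  print(x$steps, row.names = FALSE)
  invisible(x)
}

#' Serialize a search trace to JSON
#'
#' @param trace a [stepwise_prune()] result.
#' @param path output file.
#' @export
write_search_trace <- function(trace, path) {
  jsonlite::write_json(
    list(steps = trace$steps, removed = trace$removed,
         outcome = trace$outcome, final_model = model_text(trace$final)),
    path, dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
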