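#' Declarative path-model specification
#'
#' A `model_spec` describes a recursive (acyclic) structural equation model:
#' directed paths among structural variables, latent variables measured by
#' ordered indicator lists (the first indicator's loading is fixed to 1 to
#' set the latent's scale), and free residual covariances. Free parameters
#' are implied, never listed: one coefficient per path, one loading per
#' non-first indicator, one (co)variance per declared pair, and one variance
#' per variable (an exogenous variance or a disturbance variance).
#'
#' @param paths two-column matrix/data.frame (or list of length-2 vectors)
#'   of directed edges `from -> to` among structural variables.
#' @param latents named list: latent name -> ordered character vector of
#'   indicator names (at least 2).
#' @param covs optional two-column structure of unordered free-covariance
#'   pairs (exogenous covariances or residual covariances).
#' @param observed optional extra observed variable names to keep in the
#'   model even when no edge touches them (they are then modelled as
#'   uncorrelated with everything, with a free variance) — used by the
#'   backward search to compare models on a fixed variable set.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(paths = NULL, latents = list(), covs = NULL,
                       observed = NULL) {
  as_edges <- function(x, what) {
    if (is.null(x) || (is.list(x) && !is.data.frame(x) && !length(x)))
      return(data.frame(from = character(), to = character(),
                        stringsAsFactors = FALSE))
    if (is.list(x) && !is.data.frame(x))
      x <- do.call(rbind, lapply(x, function(e) as.character(e)))
    x <- as.data.frame(x, stringsAsFactors = FALSE)
    if (ncol(x) != 2) stop(what, " must have two columns")
    names(x) <- c("from", "to")
    x$from <- as.character(x$from); x$to <- as.character(x$to)
    x
  }
  paths <- as_edges(paths, "paths")
  covs <- as_edges(covs, "covs"); names(covs) <- c("a", "b")

  if (length(latents)) {
    if (is.null(names(latents)) || any(names(latents) == ""))
      stop("latents must be a named list")
    for (l in names(latents)) {
      latents[[l]] <- as.character(latents[[l]])
      if (length(latents[[l]]) < 2)
        stop("latent '", l, "' needs at least 2 indicators")
      if (anyDuplicated(latents[[l]]))
        stop("duplicate indicators for latent '", l, "'")
    }
  }
  lat_names <- names(latents)
  indicators <- unlist(latents, use.names = FALSE)
  if (anyDuplicated(indicators))
    stop("an indicator may load on only one latent here")
  if (length(intersect(indicators, lat_names)))
    stop("a latent cannot be an indicator")

  if (any(paths$from == paths$to)) stop("self-loop path")
  if (anyDuplicated(paste(paths$from, paths$to))) stop("duplicate path")
  if (nrow(covs)) {
    if (any(covs$a == covs$b)) stop("covariance pair must be distinct")
    key <- apply(covs[, c("a", "b")], 1, function(z) paste(sort(z), collapse = "~"))
    if (anyDuplicated(key)) stop("duplicate covariance pair")
  }
  bad <- intersect(indicators, c(paths$from, paths$to, covs$a, covs$b))
  if (length(bad))
    stop("indicator(s) used as structural variable: ",
         paste(bad, collapse = ", "))

  structural <- unique(c(paths$from, paths$to, covs$a, covs$b, lat_names))
  extra <- setdiff(as.character(observed %||% character()),
                   c(structural, indicators))
  structural <- c(structural, extra)
  observed <- c(setdiff(structural, lat_names), indicators)
  if (!length(observed)) stop("model has no observed variables")

  rownames(paths) <- NULL
  rownames(covs) <- NULL
  spec <- structure(list(paths = paths, latents = latents, covs = covs,
                         observed = observed, lat_names = lat_names,
                         structural = structural),
                    class = "model_spec")
  topo_order(spec)  # errors on a cycle
  spec
}

## topological order of the structural variables; errors on a cycle
topo_order <- function(spec) {
  nodes <- spec$structural
  if (!length(nodes)) return(character())
  edges <- spec$paths
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  for (t in edges$to) indeg[t] <- indeg[t] + 1L
  queue <- nodes[indeg == 0]
  out <- character()
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    out <- c(out, v)
    kids <- edges$to[edges$from == v]
    for (k in kids) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(out) != length(nodes))
    stop("cycle detected among: ",
         paste(setdiff(nodes, out), collapse = ", "), call. = FALSE)
  out
}

#' Parse the line-oriented model grammar
#'
#' Three directive forms, one per line; `#` starts a comment:
#' \preformatted{
#' latent LMT1: SLA LS
#' path MAP -> TSK
#' cov TSK ~~ TSP
#' }
#' A latent must be declared before it is used in a `path` or `cov` line.
#' Every non-blank line must parse; offending lines are reported with their
#' line number.
#'
#' @param text character scalar (or vector of lines) in the grammar above.
#' @return a [model_spec()].
#' @export
parse_model_spec <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n"))
  lines <- sub("#.*$", "", lines)
  paths <- list(); covs <- list(); latents <- list()
  seen_latent_use <- character()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") next
    if (grepl("^latent\\s+", ln)) {
      m <- regmatches(ln, regexec("^latent\\s+(\\S+)\\s*:\\s*(.+)$", ln))[[1]]
      if (length(m) != 3)
        stop("line ", i, ": cannot parse latent declaration: '", ln, "'")
      nm <- m[2]
      if (nm %in% names(latents)) stop("line ", i, ": latent '", nm, "' redeclared")
      if (nm %in% seen_latent_use)
        stop("line ", i, ": latent '", nm, "' used before declaration")
      latents[[nm]] <- strsplit(trimws(m[3]), "\\s+")[[1]]
    } else if (grepl("^path\\s+", ln)) {
      m <- regmatches(ln, regexec("^path\\s+(\\S+)\\s*->\\s*(\\S+)$", ln))[[1]]
      if (length(m) != 3)
        stop("line ", i, ": cannot parse path: '", ln, "'")
      paths[[length(paths) + 1]] <- c(m[2], m[3])
      seen_latent_use <- c(seen_latent_use, m[2], m[3])
    } else if (grepl("^cov\\s+", ln)) {
      m <- regmatches(ln, regexec("^cov\\s+(\\S+)\\s*~~\\s*(\\S+)$", ln))[[1]]
      if (length(m) != 3)
        stop("line ", i, ": cannot parse covariance: '", ln, "'")
      covs[[length(covs) + 1]] <- c(m[2], m[3])
      seen_latent_use <- c(seen_latent_use, m[2], m[3])
    } else {
      stop("line ", i, ": unrecognized directive: '", ln, "'")
    }
  }
  tryCatch(model_spec(paths, latents, covs),
           error = function(e) stop("model text invalid: ", conditionMessage(e),
                                    call. = FALSE))
}

#' @rdname parse_model_spec
#' @param path file containing model text.
#' @export
read_model_spec <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  parse_model_spec(readLines(path, warn = FALSE))
}

#' Serialize a model back to the text grammar
#'
#' @param spec a [model_spec()].
#' @return a character scalar that [parse_model_spec()] accepts.
#' @export
model_text <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  out <- character()
  for (l in names(spec$latents))
    out <- c(out, paste0("latent ", l, ": ",
                         paste(spec$latents[[l]], collapse = " ")))
  if (nrow(spec$paths))
    out <- c(out, paste0("path ", spec$paths$from, " -> ", spec$paths$to))
  if (nrow(spec$covs))
    out <- c(out, paste0("cov ", spec$covs$a, " ~~ ", spec$covs$b))
  paste(out, collapse = "\n")
}

#' Count free parameters and model degrees of freedom
#'
#' Free parameters t = paths + non-first loadings + free covariances +
#' one variance per variable (observed and latent). With p observed
#' variables, df = p(p+1)/2 - t.
#'
#' @param spec a [model_spec()].
#' @return `n_free()` the integer t; `count_df()` the integer df (with a
#'   warning when negative, i.e. under-identified by counting).
#' @export
n_free <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  k <- length(spec$observed) + length(spec$lat_names)
  nload <- sum(vapply(spec$latents, length, integer(1)) - 1L)
  nrow(spec$paths) + nload + nrow(spec$covs) + k
}

#' @rdname n_free
#' @export
count_df <- function(spec) {
  p <- length(spec$observed)
  df <- p * (p + 1) / 2 - n_free(spec)
  if (df < 0)
    warning("model is under-identified by parameter counting (df = ",
            df, ")", call. = FALSE)
  as.integer(df)
}

#' Validate a model specification, with identification warnings
#'
#' Re-runs the structural checks and warns (rather than errors) about
#' latents with exactly two indicators, which are identified only through
#' their structural neighbours.
#'
#' @param spec a [model_spec()].
#' @return `spec`, invisibly.
#' @export
validate_model_spec <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  topo_order(spec)
  two <- names(spec$latents)[vapply(spec$latents, length, integer(1)) == 2]
  if (length(two))
    warning("latent(s) with exactly 2 indicators (identified only via ",
            "structural neighbours): ", paste(two, collapse = ", "),
            call. = FALSE)
  invisible(spec)
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec: %d observed, %d latent, %d paths, %d free cov, df = %d>\n",
              length(x$observed), length(x$lat_names), nrow(x$paths),
              nrow(x$covs), suppressWarnings(count_df(x))))
  cat(model_text(x), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- internal editing helpers used by the backward search ----
## keep_vars = TRUE preserves the observed-variable set so that AIC stays
## comparable across candidate drops.

struct_observed <- function(spec) setdiff(spec$structural, spec$lat_names)

spec_drop_path <- function(spec, from, to, keep_vars = TRUE) {
  keep <- !(spec$paths$from == from & spec$paths$to == to)
  model_spec(spec$paths[keep, , drop = FALSE], spec$latents,
             if (nrow(spec$covs)) spec$covs else NULL,
             observed = if (keep_vars) struct_observed(spec))
}

spec_drop_cov <- function(spec, a, b, keep_vars = TRUE) {
  keep <- !((spec$covs$a == a & spec$covs$b == b) |
              (spec$covs$a == b & spec$covs$b == a))
  model_spec(spec$paths, spec$latents,
             if (any(keep)) spec$covs[keep, , drop = FALSE] else NULL,
             observed = if (keep_vars) struct_observed(spec))
}

spec_remove_variable <- function(spec, v) {
  if (v %in% names(spec$latents) || v %in% unlist(spec$latents))
    stop("only structural observed variables can be removed")
  keep_p <- spec$paths$from != v & spec$paths$to != v
  keep_c <- spec$covs$a != v & spec$covs$b != v
  model_spec(spec$paths[keep_p, , drop = FALSE], spec$latents,
             if (any(keep_c)) spec$covs[keep_c, , drop = FALSE] else NULL,
             observed = setdiff(struct_observed(spec), v))
}

## variables with a directed route into `targets` (targets included)
reaches <- function(spec, targets) {
  out <- targets
  repeat {
    more <- unique(spec$paths$from[spec$paths$to %in% out])
    more <- setdiff(more, out)
    if (!length(more)) break
    out <- c(out, more)
  }
  out
}
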