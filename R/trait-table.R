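#' Individual-level trait / environment tables
#'
#' A `trait_table` is a plain data frame of finite numeric measurements, one
#' row per individual (here: one sampled tree) and one named column per
#' variable (climate, topsoil chemistry, leaf morphology, leaf nitrogen).
#' Validation is strict: missing or non-numeric cells are rejected rather
#' than imputed, because the analyses downstream assume complete data.
#'
#' @param df data frame of numeric columns.
#' @return the validated data frame with class `trait_table` prepended.
#' @export
trait_table <- function(df) {
  df <- as.data.frame(df)
  if (ncol(df) == 0 || nrow(df) == 0) stop("empty trait table")
  if (anyDuplicated(names(df)))
    stop("duplicate column names: ",
         paste(unique(names(df)[duplicated(names(df))]), collapse = ", "))
  for (j in seq_along(df)) {
    col <- df[[j]]
    if (!is.numeric(col))
      stop("column '", names(df)[j], "' is not numeric")
    bad <- which(!is.finite(col))
    if (length(bad))
      stop("missing or non-finite value at row ", bad[1],
           ", column '", names(df)[j], "'")
  }
  if (nrow(df) < 3) stop("need at least 3 records")
  class(df) <- c("trait_table", "data.frame")
  df
}

#' Read a delimited trait table
#'
#' Expects a header row and a fully numeric body; any blank, missing, or
#' non-numeric cell aborts with its row and column location.
#'
#' @param path file path.
#' @param delimiter field separator (default `","`; use `"\t"` for TSV).
#' @return a [trait_table()].
#' @export
read_trait_table <- function(path, delimiter = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = delimiter,
                           colClasses = "character", check.names = FALSE,
                           strip.white = TRUE)
  if (nrow(raw) == 0) stop("empty file: ", path)
  out <- raw
  for (j in seq_along(raw)) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(v) | raw[[j]] == "")
    if (length(bad))
      stop("non-numeric or missing cell at row ", bad[1],
           ", column '", names(raw)[j], "' in ", path)
    out[[j]] <- v
  }
  trait_table(out)
}

#' @rdname read_trait_table
#' @param data a [trait_table()] to write.
#' @export
write_trait_table <- function(data, path, delimiter = ",") {
  utils::write.table(data, path, sep = delimiter, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Descriptive statistics per variable
#'
#' Computes, for each column, the arithmetic mean, the standard error of the
#' mean (s / sqrt(n), with s the n-1 sample standard deviation), the minimum,
#' the maximum, and the coefficient of variation CV = 100 * s / mean (in
#' percent). A zero-variance column gets SE = CV = 0; a zero-mean column has
#' an undefined CV, reported as `NA` and flagged.
#'
#' @param data a [trait_table()].
#' @return data frame with columns `variable`, `mean`, `se`, `min`, `max`,
#'   `cv`; rows in column order.
#' @export
summarize_traits <- function(data) {
  stopifnot(inherits(data, "trait_table") || is.data.frame(data))
  if (nrow(data) < 2) stop("need at least 2 records to summarize")
  rows <- lapply(names(data), function(v) {
    x <- data[[v]]
    s <- stats::sd(x)
    m <- mean(x)
    cv <- if (s == 0) 0 else if (m == 0) NA_real_ else 100 * s / m
    data.frame(variable = v, mean = m, se = s / sqrt(length(x)),
               min = min(x), max = max(x), cv = cv)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pearson correlation matrix with two-sided significance
#'
#' Correlations are the usual sample Pearson coefficients; p-values come from
#' t = r * sqrt(n - 2) / sqrt(1 - r^2) on n - 2 degrees of freedom,
#' two-sided. The diagonal is exactly 1 with p = 0.
#'
#' @param data a [trait_table()] with at least 3 rows and no constant column.
#' @return a [corr_matrix()] carrying the p-value matrix and `n = nrow(data)`.
#' @export
pearson_matrix <- function(data) {
  stopifnot(is.data.frame(data))
  if (nrow(data) < 3) stop("need n >= 3 for correlations")
  sds <- vapply(data, stats::sd, numeric(1))
  if (any(sds == 0))
    stop("zero variance in variable(s): ",
         paste(names(data)[sds == 0], collapse = ", "))
  x <- as.matrix(data)
  n <- nrow(x)
  r <- stats::cor(x)
  r[r > 1] <- 1; r[r < -1] <- -1
  tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  diag(r) <- 1
  diag(p) <- 0
  corr_matrix(r, n, "correlation", p_values = p)
}

#' Export summary statistics as JSON
#'
#' @param stats data frame from [summarize_traits()].
#' @param path output file.
#' @export
write_summary_json <- function(stats, path) {
  jsonlite::write_json(stats, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
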