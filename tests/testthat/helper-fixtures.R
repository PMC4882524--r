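# shared fixtures: paper-model fits are reused across test files

.fit_cache <- new.env(parent = emptyenv())

cached_fit <- function(name) {
  if (!exists(name, .fit_cache)) {
    m2 <- table2_fixture()
    mods <- paper_models()
    assign(name, fit_ml(mods[[name]], m2), .fit_cache)
  }
  get(name, .fit_cache)
}

# random correlation matrix (positive definite, unit diagonal)
random_corr <- function(p, seed) {
  set.seed(seed)
  x <- matrix(rnorm(3 * p * p), 3 * p, p)
  s <- crossprod(x) / (3 * p)
  d <- sqrt(diag(s))
  r <- s / (d %o% d)
  dimnames(r) <- list(paste0("V", seq_len(p)), paste0("V", seq_len(p)))
  corr_matrix(r, n = 500)
}

# random observed-variable DAG over p variables (edge i -> j for i < j)
random_dag_spec <- function(p, seed, edge_prob = 0.5) {
  set.seed(seed)
  edges <- list()
  vars <- paste0("V", seq_len(p))
  for (i in seq_len(p - 1)) for (j in seq(i + 1, p))
    if (runif(1) < edge_prob)
      edges[[length(edges) + 1]] <- c(vars[i], vars[j])
  if (!length(edges)) edges[[1]] <- c(vars[1], vars[2])
  model_spec(paths = edges, observed = vars)
}
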