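test_that("simulation is reproducible and honours the null model", {
  chain <- parse_model_spec("path X -> M\npath M -> Z")
  pars <- c("X->M" = 0.7, "M->Z" = 0.5, "var(X)" = 1,
            "var(M)" = 0.51, "var(Z)" = 0.75)
  a <- simulate_model(chain, pars, n = 50, seed = 3)
  b <- simulate_model(chain, pars, n = 50, seed = 3)
  expect_identical(a, b)
  c <- simulate_model(chain, pars, n = 50, seed = 4)
  expect_false(identical(a, c))

  # edgeless model: correlations vanish at CLT rate
  null3 <- model_spec(observed = c("A", "B", "C"))
  pars0 <- c("var(A)" = 1, "var(B)" = 1, "var(C)" = 1)
  n <- 2e5
  sim <- simulate_model(null3, pars0, n = n, seed = 8)
  r <- pearson_matrix(sim)$mat
  diag(r) <- 0
  expect_lt(max(abs(r)), 3 / sqrt(n))
})

test_that("simulated correlations converge to the model-implied matrix", {
  mods <- paper_models()
  fit <- cached_fit("nmass_final")
  truth <- fitted_params(fit)
  n <- 2e5
  sim <- simulate_model(mods$nmass_final, truth, n = n, seed = 21)
  r <- pearson_matrix(sim)$mat
  implied <- implied_covariance(build_ram(mods$nmass_final),
                                truth[build_ram(mods$nmass_final)$slots$label])
  implied_corr <- stats::cov2cor(implied)
  expect_lt(abs(r["SLA", "Nmass"] - implied_corr["SLA", "Nmass"]), 0.01)
  expect_lt(max(abs(r - implied_corr[rownames(r), colnames(r)])), 0.015)
})

test_that("rescaling reproduces requested means and SDs", {
  single <- parse_model_spec("path X -> Y")
  pars <- c("X->Y" = 0.5, "var(X)" = 1, "var(Y)" = 0.75)
  sim <- simulate_model(single, pars, n = 200, seed = 5,
                        means = c(X = 10, Y = -2), sds = c(X = 3, Y = 0.5))
  expect_equal(mean(sim$X), 10, tolerance = 1e-10)
  expect_equal(sd(sim$Y), 0.5, tolerance = 1e-10)
})

test_that("moment sufficiency: raw-table fits equal matrix fits", {
  mods <- paper_models()
  m2 <- table2_fixture()
  raw <- exact_moment_sample(m2, n = 90, seed = 6)
  f_raw <- fit_ml(mods$narea_final, pearson_matrix(raw), se = FALSE)
  f_mat <- fit_ml(mods$narea_final, m2, se = FALSE)
  expect_equal(f_raw$F_min, f_mat$F_min, tolerance = 1e-8)
  expect_equal(f_raw$estimates, f_mat$estimates, tolerance = 1e-6)
})

test_that("end-to-end recovery at study scale: bias and SE calibration", {
  # fits use sample covariance input, where the Wishart SE theory applies
  # (correlation-input SEs are documented as approximate)
  mods <- paper_models()
  fit0 <- cached_fit("narea_final")
  truth <- fitted_params(fit0)
  ram <- build_ram(mods$narea_final)
  lab <- ram$slots$label[ram$slots$kind %in% c("path", "loading")]
  pop <- implied_covariance(ram, truth[ram$slots$label])
  se_rep <- {
    fse <- fit_ml(mods$narea_final, corr_matrix(pop, n = 90,
                                                type = "covariance"))
    fse$parameters$se[match(lab, fse$parameters$label)]
  }
  nrep <- 120
  raw <- std <- matrix(NA_real_, nrep, length(lab),
                       dimnames = list(NULL, lab))
  for (i in seq_len(nrep)) {
    sim <- simulate_model(mods$narea_final, truth, n = 90, seed = 4000 + i)
    cv <- cov(as.matrix(sim))
    f <- tryCatch(suppressWarnings(
      fit_ml(mods$narea_final, corr_matrix(cv, n = 90, type = "covariance"),
             restarts = 1, se = FALSE, indices = FALSE)),
      error = function(e) NULL)
    if (is.null(f) || !f$converged) next
    std[i, ] <- setNames(f$std$table$estimate, f$std$table$label)[lab]
    raw[i, ] <- f$estimates[lab]
  }
  expect_gt(mean(!is.na(raw[, 1])), 0.95)
  expect_lt(max(abs(colMeans(std, na.rm = TRUE) - truth[lab])), 0.02)
  ratio <- apply(raw, 2, sd, na.rm = TRUE) / se_rep
  expect_true(all(ratio > 0.75 & ratio < 1.25))
})
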