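test_that("implied covariance follows the path algebra", {
  # no paths, unit variances: identity
  empty <- model_spec(observed = c("X", "Y"))
  ram0 <- build_ram(empty)
  expect_equal(implied_covariance(ram0, c("var(X)" = 1, "var(Y)" = 1)),
               diag(2), ignore_attr = TRUE)

  # single path with disturbance 1 - b^2 gives a correlation matrix
  b <- 0.6
  single <- parse_model_spec("path X -> Y")
  ram1 <- build_ram(single)
  sig <- implied_covariance(ram1, c("X->Y" = b, "var(X)" = 1,
                                    "var(Y)" = 1 - b^2))
  expect_equal(sig, matrix(c(1, b, b, 1), 2), ignore_attr = TRUE)

  # chain: cov(X, Z) = b1 b2, checked against a large simulation
  chain <- parse_model_spec("path X -> M\npath M -> Z")
  ramc <- build_ram(chain)
  pars <- c("X->M" = 0.7, "M->Z" = 0.5, "var(X)" = 1,
            "var(M)" = 1 - 0.49, "var(Z)" = 1 - 0.25)
  sigc <- implied_covariance(ramc, pars)
  expect_equal(sigc["X", "Z"], 0.35, tolerance = 1e-12)
  n <- 2e5
  sim <- simulate_model(chain, pars, n = n, seed = 99)
  mc <- cov(sim$X, sim$Z)
  expect_lt(abs(mc - 0.35), 3 * sqrt((1 + 0.35^2) / n))
})

test_that("ML discrepancy is a proper divergence", {
  S <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(ml_discrepancy(S, S), 0, tolerance = 1e-12)
  expect_equal(ml_discrepancy(S, diag(2)), -log(0.75), tolerance = 1e-10)

  for (seed in 1:10) {
    a <- random_corr(4, seed)$mat
    b <- random_corr(4, seed + 100)$mat
    expect_gt(ml_discrepancy(a, b), 0)
    # invariant under simultaneous reordering
    ix <- sample(4)
    expect_equal(ml_discrepancy(a[ix, ix], b[ix, ix]),
                 ml_discrepancy(a, b), tolerance = 1e-12)
  }
  expect_error(ml_discrepancy(matrix(c(1, 2, 2, 1), 2), diag(2)),
               "not positive definite")
})

test_that("fitting moments generated by the model recovers the truth", {
  mods <- paper_models()
  fit0 <- cached_fit("nmass_final")
  sigma <- implied_covariance(fit0$ram, fit0$estimates)
  mom <- corr_matrix(sigma, n = 90, type = "covariance")
  refit <- fit_ml(mods$nmass_final, mom, se = FALSE)
  expect_true(refit$converged)
  expect_lt(refit$F_min, 1e-10)
  expect_lt(max(abs(refit$estimates - fit0$estimates[names(refit$estimates)])),
            1e-4)
})

test_that("a saturated model fits any PD matrix exactly with df 0", {
  sat <- parse_model_spec("path X -> Y\npath X -> Z\npath Y -> Z")
  expect_equal(count_df(sat), 0L)
  m <- random_corr(3, seed = 5)
  dimnames(m$mat) <- list(c("X", "Y", "Z"), c("X", "Y", "Z"))
  f <- fit_ml(sat, m, se = FALSE)
  expect_lt(f$chisq, 1e-8)
  expect_true(is.na(f$p_value))
})

test_that("standardized solution equals implied correlations and is scale-free", {
  single <- parse_model_spec("path X -> Y")
  r <- 0.43
  mom <- corr_matrix(matrix(c(1, r, r, 1), 2,
                            dimnames = list(c("X", "Y"), c("X", "Y"))),
                     n = 50)
  f <- fit_ml(single, mom, se = FALSE)
  expect_equal(f$std$table$estimate[f$std$table$label == "X->Y"], r,
               tolerance = 1e-8)
  expect_equal(unname(r_squared(f)["Y"]), r^2, tolerance = 1e-8)

  # pre-scaling the input covariance by a positive diagonal leaves the
  # standardized solution unchanged
  mods <- paper_models()
  m2 <- table2_fixture()
  sub <- subset_corr(m2, mods$narea_final$observed)
  d <- c(2.5, 0.4, 7, 1.3, 0.2, 30)
  scaled <- corr_matrix(diag(d) %*% sub$mat %*% diag(d) |>
                          `dimnames<-`(dimnames(sub$mat)),
                        n = 90, type = "covariance")
  f1 <- fit_ml(mods$narea_final, sub, se = FALSE)
  f2 <- fit_ml(mods$narea_final, scaled, se = FALSE)
  expect_equal(f2$std$table$estimate, f1$std$table$estimate, tolerance = 1e-6)
  expect_equal(f2$chisq, f1$chisq, tolerance = 1e-6)
})

test_that("baseline fit has the closed form and dominates nested models", {
  idm <- corr_matrix(diag(3) |> `dimnames<-`(list(c("a", "b", "c"),
                                              c("a", "b", "c"))), n = 30)
  expect_equal(baseline_fit(idm)$chisq, 0)

  r5 <- corr_matrix(matrix(c(1, .5, .5, 1), 2,
                           dimnames = list(c("a", "b"), c("a", "b"))), n = 40)
  expect_equal(baseline_fit(r5)$F_min, -log(0.75), tolerance = 1e-12)
  expect_equal(baseline_fit(r5)$df, 1)

  f <- cached_fit("narea_final")
  expect_gte(baseline_fit(f$moments)$chisq, f$chisq)
})

test_that("fit indices respect their definitional bounds", {
  # exact-fit moments: chisq ~ 0 below df, so RMSEA = 0 and CFI = 1
  mods <- paper_models()
  fit0 <- cached_fit("nmass_final")
  sigma <- implied_covariance(fit0$ram, fit0$estimates)
  f <- fit_ml(mods$nmass_final,
              corr_matrix(sigma, n = 90, type = "covariance"), se = FALSE)
  expect_equal(f$indices$rmsea, 0)
  expect_equal(f$indices$cfi, 1)
  expect_equal(f$indices$aic, f$chisq + 2 * 14, tolerance = 1e-12)

  for (nm in c("nmass_final", "narea_final")) {
    ff <- cached_fit(nm)
    expect_lte(ff$indices$agfi, ff$indices$gfi)
    expect_lte(ff$indices$gfi, 1)
    expect_true(ff$indices$cfi >= 0 && ff$indices$cfi <= 1)
  }

  # df = 0: RMSEA and AGFI undefined
  sat <- parse_model_spec("path X -> Y")
  m <- corr_matrix(matrix(c(1, .3, .3, 1), 2,
                          dimnames = list(c("X", "Y"), c("X", "Y"))), n = 30)
  fs <- fit_ml(sat, m, se = FALSE)
  expect_true(is.na(fs$indices$rmsea))
  expect_true(is.na(fs$indices$agfi))
})

test_that("standard errors scale as 1/sqrt(n-1) and match Monte-Carlo spread", {
  mods <- paper_models()
  m2 <- table2_fixture()
  sub <- subset_corr(m2, mods$nmass_final$observed)
  f90 <- fit_ml(mods$nmass_final, sub)
  sub2 <- corr_matrix(sub$mat, n = 179, p_values = NULL)
  f179 <- fit_ml(mods$nmass_final, sub2)
  ratio <- f90$parameters$se / f179$parameters$se
  expect_equal(ratio, rep(sqrt(178 / 89), length(ratio)), tolerance = 1e-3)

  # single-path model: SD of estimates across replicates vs reported SE
  single <- parse_model_spec("path X -> Y")
  pars <- c("X->Y" = 0.5, "var(X)" = 1, "var(Y)" = 0.75)
  nrep <- 150; nobs <- 400
  est <- se_rep <- numeric(nrep)
  for (i in seq_len(nrep)) {
    sim <- simulate_model(single, pars, n = nobs, seed = 1000 + i)
    f <- fit_ml(single, pearson_matrix(sim), restarts = 1,
                se = (i == 1), indices = FALSE)
    est[i] <- f$estimates["X->Y"]
    if (i == 1) se_rep[1] <- f$parameters$se[f$parameters$label == "X->Y"]
  }
  expect_lt(abs(sd(est) - se_rep[1]) / se_rep[1], 0.15)
})

test_that("standardized estimates agree with the closed-form DAG oracle", {
  for (seed in 1:20) {
    p <- 3 + (seed %% 4)
    spec <- random_dag_spec(p, seed = seed)
    mom <- random_corr(p, seed = 300 + seed)
    f <- fit_ml(spec, mom, restarts = 2, se = FALSE, indices = FALSE)
    expect_true(f$converged)
    orc <- oracle_fit_dag(spec, mom)
    std <- setNames(f$std$table$estimate, f$std$table$label)
    expect_lt(max(abs(std[names(orc$std)] - orc$std)), 1e-3)
    r2 <- r_squared(f)
    expect_lt(max(abs(r2[names(orc$r_squared)] - orc$r_squared)), 1e-3)
    # the oracle's implied matrix achieves the same discrepancy
    vs <- rownames(f$implied)
    expect_equal(ml_discrepancy(subset_corr(mom, vs), orc$implied[vs, vs]),
                 f$F_min, tolerance = 1e-8)
  }
})

test_that("parameters are recovered from data simulated at n = 5000", {
  mods <- paper_models()
  truth <- fitted_params(cached_fit("nmass_final"))
  sim <- simulate_model(mods$nmass_final, truth, n = 5000, seed = 4242)
  f <- fit_ml(mods$nmass_final, pearson_matrix(sim), se = FALSE)
  std <- setNames(f$std$table$estimate, f$std$table$label)
  lab <- f$ram$slots$label[f$ram$slots$kind %in% c("path", "loading")]
  expect_lt(max(abs(std[lab] - truth[lab])), 0.03)
})
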