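test_that("trait tables round-trip through CSV and reject bad cells", {
  df <- data.frame(a = c(1, 2, 3), b = c(4.5, 5.5, 6.5))
  tt <- trait_table(df)
  expect_s3_class(tt, "trait_table")
  expect_identical(dim(tt), c(3L, 2L))

  path <- withr::local_tempfile(fileext = ".csv")
  write_trait_table(tt, path)
  back <- read_trait_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tt), tolerance = 1e-12)

  # simulated data at realistic scale survives a write/read cycle exactly
  mods <- paper_models()
  t1 <- table1_fixture()
  sim <- simulate_model(mods$nmass_final,
                        fitted_params(cached_fit("nmass_final")),
                        n = 30, seed = 7,
                        means = setNames(t1$mean, t1$variable),
                        sds = setNames(t1$sd, t1$variable))
  write_trait_table(sim, path)
  expect_equal(as.data.frame(read_trait_table(path)), as.data.frame(sim),
               tolerance = 1e-12)

  writeLines(c("a,b", "1,2", ",3"), path)
  expect_error(read_trait_table(path), "row 2.*column 'a'")
  writeLines(c("a,b", "1,x"), path)
  expect_error(read_trait_table(path), "row 1.*column 'b'")
  writeLines("a,b", path)
  expect_error(read_trait_table(path))
  expect_error(trait_table(data.frame(a = 1:3, a = 4:6, check.names = FALSE)),
               "duplicate")
})

test_that("summary statistics match hand computations and ignore row order", {
  tt <- trait_table(data.frame(x = c(1, 2, 3), k = c(5, 5, 5), z = c(-1, 0, 1)))
  s <- summarize_traits(tt)
  x <- s[s$variable == "x", ]
  expect_equal(x$mean, 2)
  expect_equal(x$se, 1 / sqrt(3), tolerance = 1e-12)
  expect_equal(x$cv, 50)
  k <- s[s$variable == "k", ]
  expect_equal(c(k$se, k$cv), c(0, 0))
  expect_true(is.na(s[s$variable == "z", "cv"]))   # zero mean: CV undefined

  shuffled <- trait_table(tt[c(3, 1, 2), ])
  expect_equal(summarize_traits(shuffled), s)

  jpath <- withr::local_tempfile(fileext = ".json")
  write_summary_json(s, jpath)
  js <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  expect_equal(js$mean, s$mean, tolerance = 1e-12)
  expect_equal(js$cv, s$cv, tolerance = 1e-12)
})

test_that("summary statistics recover generator targets on rescaled data", {
  t1 <- table1_fixture()
  mods <- paper_models()
  sim <- simulate_model(mods$narea_final,
                        fitted_params(cached_fit("narea_final")),
                        n = 90, seed = 11,
                        means = setNames(t1$mean, t1$variable),
                        sds = setNames(t1$sd, t1$variable))
  s <- summarize_traits(sim)
  for (v in names(sim)) {
    tgt <- t1[t1$variable == v, ]
    expect_equal(s[s$variable == v, "mean"], tgt$mean, tolerance = 1e-8)
  }
  expect_true("LDW" %in% attr(t1, "flagged"))  # printed min equals its mean
})

test_that("pearson matrix matches hand values with valid p-values", {
  tt <- trait_table(data.frame(x = c(1, 2, 3, 4), y = c(1, 3, 2, 4)))
  cm <- pearson_matrix(tt)
  expect_equal(cm$mat["x", "y"], 0.8, tolerance = 1e-12)
  expect_equal(diag(cm$mat), c(x = 1, y = 1))
  expect_equal(diag(cm$p_values), c(x = 0, y = 0))
  expect_equal(cm$n, 4L)

  tt2 <- trait_table(data.frame(x = c(1, 2, 3, 5), mx = -c(1, 2, 3, 5),
                                z = rnorm(4)))
  cm2 <- pearson_matrix(tt2)
  expect_equal(cm2$mat["x", "mx"], -1, tolerance = 1e-12)
  expect_lt(cm2$p_values["x", "mx"], 1e-10)
  expect_true(max(abs(cm2$mat - t(cm2$mat))) < 1e-15)

  expect_error(pearson_matrix(trait_table(data.frame(a = 1:4, c = rep(2, 4)))),
               "zero variance.*c")
})

test_that("nearest_psd clips eigenvalues, keeps unit diagonal, is idempotent", {
  idm <- diag(3); dimnames(idm) <- list(letters[1:3], letters[1:3])
  id <- corr_matrix(idm, n = 10)
  fixed <- nearest_psd(id)
  expect_equal(fixed$mat, id$mat)
  expect_equal(attr(fixed, "max_delta"), 0)

  near1 <- corr_matrix(matrix(c(1, 0.999999, 0.999999, 1), 2,
                              dimnames = list(c("a", "b"), c("a", "b"))),
                       n = 10)
  expect_equal(attr(nearest_psd(near1), "max_delta"), 0)

  # indefinite: equicorrelation below the -1/(p-1) PSD boundary
  bad <- matrix(-0.52, 3, 3); diag(bad) <- 1
  dimnames(bad) <- list(letters[1:3], letters[1:3])
  expect_lt(min(eigen(bad, only.values = TRUE)$values), -0.01)
  m <- corr_matrix(bad, n = 20)
  rep <- nearest_psd(m)
  expect_gte(min(eigen(rep$mat, only.values = TRUE)$values), 1e-6 - 1e-12)
  expect_equal(diag(rep$mat), c(a = 1, b = 1, c = 1))
  expect_gt(attr(rep, "max_delta"), 0)
  again <- nearest_psd(rep)
  expect_equal(again$mat, rep$mat, tolerance = 1e-9)
})

test_that("exact-moment samples reproduce their target correlations", {
  tgt <- random_corr(4, seed = 42)
  y <- exact_moment_sample(tgt, n = 20, seed = 1)
  expect_equal(pearson_matrix(y)$mat, tgt$mat, tolerance = 1e-10)

  idt <- corr_matrix(diag(3) |> `dimnames<-`(list(c("a", "b", "c"),
                                              c("a", "b", "c"))), n = 20)
  y0 <- exact_moment_sample(idt, n = 20, seed = 2)
  off <- pearson_matrix(y0)$mat; diag(off) <- 0
  expect_lt(max(abs(off)), 1e-10)

  expect_error(exact_moment_sample(tgt, n = 3), "n > p")
})
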