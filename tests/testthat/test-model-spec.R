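test_that("model grammar parses, validates and round-trips", {
  s <- parse_model_spec("path X -> Y")
  expect_equal(sort(s$observed), c("X", "Y"))
  expect_equal(nrow(s$paths), 1L)
  expect_length(s$lat_names, 0)

  txt <- "
    # morphology factor with two indicators
    latent L: A B
    path X -> L
    path L -> Y
    cov X ~~ Y
  "
  s2 <- parse_model_spec(txt)
  expect_equal(s2$latents$L, c("A", "B"))
  expect_equal(nrow(s2$covs), 1L)
  expect_equal(parse_model_spec(model_text(s2)), s2)

  expect_error(parse_model_spec("path X -> Y\npath Y -> X"), "cycle")
  expect_error(parse_model_spec("latent L: A"), "2 indicators")
  expect_error(parse_model_spec("path X -> L\nlatent L: A B"),
               "line 2.*used before declaration")
  expect_error(parse_model_spec("pathway X Y"), "line 1")
  expect_error(parse_model_spec("path X -> Y\npath X -> Y"), "duplicate")
  expect_warning(validate_model_spec(parse_model_spec("latent L: A B\npath X -> L")),
                 "2 indicators")
})

test_that("free-parameter and df counting follow the p(p+1)/2 - t rule", {
  single <- parse_model_spec("path X -> Y")
  expect_equal(n_free(single), 3L)          # 1 path + 2 variances
  expect_equal(count_df(single), 0L)        # saturated 2-variable model

  mods <- paper_models()
  expect_equal(n_free(mods$nmass_final), 14L)
  expect_equal(count_df(mods$nmass_final), 7L)
  expect_equal(n_free(mods$narea_final), 15L)
  expect_equal(count_df(mods$narea_final), 6L)

  over <- model_spec(paths = list(c("X", "Y")),
                     covs = list(c("X", "Y")))    # more slots than moments
  expect_warning(count_df(over), "under-identified")
})

test_that("paper model fixtures have the published topology", {
  mods <- paper_models()
  expect_named(mods, c("nmass_final", "narea_final", "prior_nmass",
                       "prior_narea"))
  expect_equal(sort(mods$nmass_final$observed),
               sort(c("Nmass", "SLA", "LS", "TSK", "TSP", "MAP")))
  expect_equal(mods$nmass_final$latents$LMT1, c("SLA", "LS"))
  expect_equal(mods$narea_final$latents$LMT2, c("SLA", "LDW"))
  # the prior contains the climate/soil variables the final models dropped
  for (pr in mods[c("prior_nmass", "prior_narea")]) {
    expect_true(all(c("MAT", "TSN") %in% pr$observed))
    expect_equal(pr$latents$LMT, c("SLA", "LS", "LDW"))
  }
  expect_false(any(c("MAT", "TSN") %in% mods$nmass_final$observed))
  expect_false(any(c("MAT", "TSN") %in% mods$narea_final$observed))

  # the installed model-text files parse to the same objects
  dir <- system.file("extdata", "models", package = "foliarsem")
  for (nm in names(mods))
    expect_equal(read_model_spec(file.path(dir, paste0(nm, ".txt"))),
                 mods[[nm]], label = nm)
})

test_that("RAM construction maps every free parameter to one slot", {
  mods <- paper_models()
  ram <- build_ram(mods$nmass_final)
  expect_equal(nrow(ram$slots), 14L)
  expect_equal(ram$vars, c(mods$nmass_final$observed, "LMT1"))
  # slot-wise reconstruction reproduces the spec's edges
  paths <- ram$slots[ram$slots$kind == "path", ]
  rebuilt <- data.frame(from = ram$vars[paths$col], to = ram$vars[paths$row],
                        stringsAsFactors = FALSE)
  expect_equal(rebuilt[order(rebuilt$from, rebuilt$to), ],
               mods$nmass_final$paths[order(mods$nmass_final$paths$from,
                                            mods$nmass_final$paths$to), ],
               ignore_attr = TRUE)
  # one fixed unit loading per latent (first indicator)
  expect_length(ram$fixed, 1L)

  # dropping any one path raises df by exactly one
  pr <- mods$prior_nmass
  df0 <- count_df(pr)
  for (i in seq_len(nrow(pr$paths))) {
    reduced <- foliarsem:::spec_drop_path(pr, pr$paths$from[i], pr$paths$to[i])
    expect_equal(count_df(reduced), df0 + 1L)
  }
})

test_that("every accepted model admits a topological order", {
  for (seed in 1:10) {
    s <- random_dag_spec(sample(3:7, 1), seed = seed)
    ord <- foliarsem:::topo_order(s)
    pos <- setNames(seq_along(ord), ord)
    if (nrow(s$paths))
      expect_true(all(pos[s$paths$from] < pos[s$paths$to]))
  }
})
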