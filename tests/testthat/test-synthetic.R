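test_that("generation is deterministic in (config, seed)", {
  cfg <- synth_config(n_cases = 500, seed = 101, quarters = "2022Q4")
  s1 <- generate_synthetic(cfg)
  s2 <- generate_synthetic(cfg)
  expect_bundle_equal(s1$bundles[[1]], s2$bundles[[1]])
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_faers_quarter(s1$bundles[[1]], d1)
  p2 <- write_faers_quarter(s2$bundles[[1]], d2)
  for (nm in names(p1)) {
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]))
  }
  s3 <- generate_synthetic(synth_config(n_cases = 500, seed = 102,
                                        quarters = "2022Q4"))
  expect_false(identical(s1$bundles[[1]]$demo, s3$bundles[[1]]$demo))
})

test_that("duplicate rate zero yields exactly n_cases after dedup", {
  syn <- generate_synthetic(synth_config(n_cases = 400, duplicate_rate = 0,
                                         seed = 8, quarters = "2022Q4"))
  expect_equal(syn$truth$n_versions, 400)
  store <- build_case_store(syn$bundles)
  expect_equal(nrow(store$cases), 400)
})

test_that("duplicate versions are earlier-dated copies of their case", {
  syn <- generate_synthetic(synth_config(n_cases = 800, duplicate_rate = 0.3,
                                         seed = 15))
  demo <- do.call(rbind, lapply(syn$bundles, function(b) b$demo))
  dup_cases <- names(which(table(demo$caseid) == 2))
  expect_gt(length(dup_cases), 100)
  for (cid in dup_cases[1:25]) {
    v <- demo[demo$caseid == cid, , drop = FALSE]
    v <- v[order(as.numeric(v$primaryid)), , drop = FALSE]
    expect_lt(as.numeric(v$fda_dt[1]), as.numeric(v$fda_dt[2]))
  }
  store <- build_case_store(syn$bundles)
  expect_equal(nrow(store$cases), 800)
  # survivors are always the later (higher-primaryid) versions
  expect_true(all(grepl("2$", store$cases$primaryid)))
})

test_that("marginal cohort sizes and event rates are calibrated", {
  cfg <- synth_config(n_cases = 10000, seed = 55, quarters = "2022Q4",
                      planted_associations = list())
  syn <- generate_synthetic(cfg)
  n <- cfg$n_cases
  counts <- table(syn$truth$cohort$cohort)
  probs <- vapply(cfg$drug_exposure, function(e) e$p %||% NA_real_, 0)
  probs[is.na(probs)] <- 1 - sum(probs, na.rm = TRUE)
  for (lab in names(probs)) {
    p <- probs[[lab]]
    expect_lt(abs(counts[[lab]] / n - p), 3 * sqrt(p * (1 - p) / n),
              label = lab)
  }
  for (pt in names(cfg$background_event_rates)) {
    p <- cfg$background_event_rates[[pt]]
    expect_lt(abs(syn$truth$event_counts[[pt]] / n - p),
              3 * sqrt(p * (1 - p) / n), label = pt)
  }
})

test_that("an unachievable planted odds ratio is rejected at config time", {
  expect_error(
    synth_config(background_event_rates = c("Nausea" = 1),
                 planted_associations = list(
                   list(cohort = "ICI", pt = "Nausea", or = 5))),
    "unachievable")
  expect_error(
    synth_config(planted_associations = list(
      list(cohort = "ICI", pt = "Unrated term", or = 2))),
    "no background rate")
})

test_that("the realized planted odds ratio tracks its target", {
  ors <- vapply(1:5, function(i) {
    syn <- generate_synthetic(synth_config(n_cases = 50000, seed = 600 + i,
                                           quarters = "2022Q4"))
    syn$truth$planted[[1]]$sample_or
  }, 0)
  expect_true(all(ors > 13 & ors < 30))
  expect_lt(abs(mean(ors) - 20), 4)
})

test_that("the small fixture matches its hand-enumerated expectations", {
  fx <- fixture_small()
  ex <- fx$expected
  expect_equal(nrow(fx$bundle$demo), ex$n_versions)
  store <- classify_regimens(build_case_store(fx$bundle))
  expect_equal(nrow(store$cases), ex$n_cases)
  expect_equal(store$cases$primaryid[store$cases$caseid == "1001"],
               ex$survivor_1001)
  expect_equal(store$cases$primaryid[store$cases$caseid == "1002"],
               ex$survivor_1002)
  counts <- table(store$cases$regimen)
  expect_equal(as.integer(counts[names(ex$regimen)]),
               unname(ex$regimen))
  s <- summarize_cases(store, event_terms("HRAE"))
  expect_equal(s$n_cases, ex$hrae_cases)
  expect_equal(fatal_fraction(store), ex$fatal_hrae)
  expect_equal(s$age$median, ex$age$median)
  expect_equal(unname(s$age$iqr), ex$age$iqr)
  expect_equal(s$age$n, ex$age$n)
  # the 2x2 for autoimmune hepatitis, report unit, against the rest
  sc <- scan_signals(store, event_terms("hit", terms = "Autoimmune hepatitis"),
                     strategies = "ICI", unit = "reports")
  e <- ex$autoimmune_2x2_reports
  expect_equal(sc$n_observed, unname(e["a"]))
  expect_equal(sc$n_expected,
               unname(e["n_drug"] * (e["a"] + e["c"]) / e["n_total"]))
})
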