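test_that("category counts and percentages follow the case total", {
  store <- make_tiny_store(list(
    list(drugs = list(c("PS", "NIVOLUMAB")), sex = "M",
         reactions = "Autoimmune hepatitis"),
    list(drugs = list(c("PS", "NIVOLUMAB")), sex = "M",
         reactions = "Autoimmune hepatitis"),
    list(drugs = list(c("PS", "NIVOLUMAB")), sex = "F",
         reactions = "Immune-mediated hepatitis"),
    list(drugs = list(c("PS", "NIVOLUMAB")), sex = "",
         reactions = "Hepatitis fulminant"),
    list(drugs = list(c("PS", "ASPIRIN")), sex = "F",
         reactions = "Nausea")))     # unmatched case, excluded
  s <- summarize_cases(store, event_terms("HRAE"))
  expect_equal(s$n_cases, 4)
  expect_equal(s$sex$n, c(2, 1, 1))
  expect_equal(s$sex$pct, c(50.0, 25.0, 25.0))
})

test_that("age summaries use linear interpolation and ignore missing ages", {
  cases <- lapply(c("1", "2", "3", ""), function(a) {
    list(drugs = list(c("PS", "NIVOLUMAB")), age = a,
         age_cod = if (nzchar(a)) "YR" else "",
         reactions = "Autoimmune hepatitis")
  })
  s <- summarize_cases(make_tiny_store(cases), event_terms("HRAE"))
  expect_equal(s$age$median, 2)
  expect_equal(unname(s$age$iqr), c(1.5, 2.5))
  expect_equal(s$age$n, 3)
  # dropping the missing-age case does not change the summary
  s3 <- summarize_cases(make_tiny_store(cases[1:3]), event_terms("HRAE"))
  expect_equal(s3$age[c("median", "iqr")], s$age[c("median", "iqr")])
})

test_that("single-valued variables account for every case", {
  syn <- generate_synthetic(synth_config(n_cases = 4000, seed = 19,
                                         quarters = "2022Q4"))
  store <- classify_regimens(build_case_store(syn$bundles))
  s <- summarize_cases(store, event_terms("HEPATITIS_SCAN"))
  for (nm in c("region", "reporter", "sex", "regimen", "years")) {
    expect_equal(sum(s[[nm]]$n), s$n_cases, label = nm)
    expect_lt(abs(sum(s[[nm]]$pct) - 100), 0.2)
  }
})

test_that("summary is invariant to case order", {
  syn <- generate_synthetic(synth_config(n_cases = 3000, seed = 29,
                                         quarters = "2022Q4"))
  store <- classify_regimens(build_case_store(syn$bundles))
  s1 <- summarize_cases(store)
  set.seed(1)
  store2 <- store
  perm <- sample(nrow(store2$cases))
  store2$cases <- store2$cases[perm, , drop = FALSE]
  s2 <- summarize_cases(store2)
  expect_equal(s2[c("n_cases", "sex", "region", "regimen", "outcomes")],
               s1[c("n_cases", "sex", "region", "regimen", "outcomes")])
})

test_that("planted demographic and outcome rates are recovered", {
  cfg <- synth_config(
    n_cases = 5000, seed = 37, quarters = "2022Q4",
    background_event_rates = c("Autoimmune hepatitis" = 0.05,
                               "Nausea" = 0.05),
    planted_associations = list(),
    event_outcome_rates = list("Autoimmune hepatitis" = c(DE = 0.25)))
  syn <- generate_synthetic(cfg)
  store <- classify_regimens(build_case_store(syn$bundles))
  s <- summarize_cases(store, event_terms("HRAE"))
  n <- s$n_cases
  expect_gt(n, 150)
  # sex proportions within 3 binomial standard errors of the planted values
  for (cat in c("Male", "Female")) {
    p <- c(Male = 0.55, Female = 0.36)[[cat]]
    obs <- s$sex$n[s$sex$category == cat] / n
    expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / n))
  }
  # fatal fraction within 3 standard errors of the planted 0.25
  ff <- fatal_fraction(store, event_terms("HRAE"))
  expect_lt(abs(ff - 0.25), 3 * sqrt(0.25 * 0.75 / n))
})

test_that("empty case sets summarize to zeros, not errors", {
  store <- make_tiny_store(list(
    list(drugs = list(c("PS", "NIVOLUMAB")), reactions = "Nausea")))
  s <- summarize_cases(store, event_terms("HRAE"))
  expect_equal(s$n_cases, 0)
  expect_equal(sum(s$sex$n), 0)
  expect_true(is.na(s$age$median))
  expect_true(is.nan(fatal_fraction(store, event_terms("HRAE"))))
})

test_that("multi-outcome cases count once per outcome category", {
  store <- make_tiny_store(list(
    list(drugs = list(c("PS", "NIVOLUMAB")),
         reactions = "Autoimmune hepatitis", outcomes = c("DE", "HO", "OT")),
    list(drugs = list(c("PS", "NIVOLUMAB")),
         reactions = "Autoimmune hepatitis")))
  s <- summarize_cases(store, event_terms("HRAE"))
  o <- setNames(s$outcomes$n, s$outcomes$category)
  expect_equal(unname(o[c("Death", "Hospitalization", "Others", "Missing")]),
               c(1, 1, 1, 1))
  # outcome mentions may exceed the case total
  expect_gt(sum(o), s$n_cases)
  expect_equal(fatal_fraction(store, event_terms("HRAE")), 0.5)
})
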