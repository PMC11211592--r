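test_that("derive_table reconstructs 2x2 cells from marginal counts", {
  tab <- derive_table(634, 353949, 4566, 49568379, "external-comparator")
  expect_equal(c(tab$a, tab$b, tab$c, tab$d),
               c(634, 353315, 4566, 49209864))
  expect_equal(derive_table(546, 353949, 350, 49568379)$d, 49214080)
  tab0 <- derive_table(0, 100, 0, 1000)
  expect_equal(c(tab0$a, tab0$b, tab0$c, tab0$d), c(0, 100, 0, 900))
  h2h <- derive_table(336, 268517, 8, 22903, "head-to-head")
  expect_equal(c(h2h$a, h2h$b, h2h$c, h2h$d), c(336, 268181, 8, 22895))
  expect_error(derive_table(50, 40, 10, 1000), "inconsistent counts")
})

test_that("ror reproduces the published autoimmune-hepatitis signal", {
  tab <- derive_table(634, 353949, 4566, 49568379)
  r <- ror(tab)
  expect_equal(round_half_up(r$estimate), 19.34)
  expect_equal(round_half_up(r$lower), 17.80)
  expect_equal(round_half_up(r$upper), 21.02)
})

test_that("ror has the analytic values on simple tables", {
  sym <- list(a = 10, b = 10, c = 10, d = 10)
  expect_equal(ror(sym)$estimate, 1)
  expect_equal(ror(list(a = 5, b = 5, c = 1, d = 10))$estimate, 10)
  # a = 0 without correction: zero estimate, undefined bounds
  r0 <- ror(list(a = 0, b = 10, c = 5, d = 100))
  expect_equal(r0$estimate, 0)
  expect_false(r0$defined)
  # Haldane correction makes the same table estimable
  rh <- ror(list(a = 0, b = 10, c = 5, d = 100), correction = "haldane")
  expect_true(rh$defined)
  expect_equal(rh$estimate, (0.5 * 100.5) / (10.5 * 5.5))
  expect_error(ror(list(a = 0, b = 0, c = 0, d = 0)), "all-zero")
})

test_that("ror matches cross-product oracle, is symmetric, nests estimate", {
  set.seed(31)
  for (i in 1:50) {
    cells <- sample(1:400, 4, replace = TRUE)
    tab <- list(a = cells[1], b = cells[2], c = cells[3], d = cells[4])
    swap <- list(a = cells[3], b = cells[4], c = cells[1], d = cells[2])
    r <- ror(tab)
    # independent oracle: ratio of reporting odds computed directly
    odds_exposed <- cells[1] / cells[2]
    odds_comparator <- cells[3] / cells[4]
    expect_equal(r$estimate, odds_exposed / odds_comparator)
    expect_lt(abs(r$estimate * ror(swap)$estimate - 1), 1e-9)
    expect_true(r$lower <= r$estimate && r$estimate <= r$upper)
  }
  # interval width shrinks monotonically as all cells scale up
  widths <- vapply(c(1, 2, 5, 10), function(k) {
    r <- ror(list(a = 8 * k, b = 90 * k, c = 40 * k, d = 900 * k))
    log(r$upper) - log(r$lower)
  }, 0)
  expect_true(all(diff(widths) < 0))
})

test_that("information component matches its expectation formula", {
  out <- ic(634, 353949, 5200, 49568379)
  expect_equal(round_half_up(out$n_expected), 37.13)
  # forced equality gives IC 0 under both methods
  expect_equal(ic(37, 37 * 100, 100, 10000, method = "plain")$ic, 0)
  sh <- ic(37, 37 * 100, 100, 10000, method = "shrunk")
  expect_equal(sh$ic, 0)
  expect_lt(sh$ic025, 0)
  expect_gt(sh$ic975, 0)
  # no observations: shrinkage keeps the value defined and negative
  z <- ic(0, 100, 10, 10000, method = "shrunk")
  expect_equal(z$ic, log2(0.5 / (0.1 + 0.5)))
  expect_lt(z$ic, 0)
  expect_error(ic(1, 1, 1, 0), "positive")
})

test_that("plain IC sign agrees with observed minus expected", {
  set.seed(17)
  for (i in 1:40) {
    n_total <- sample(5000:50000, 1)
    n_drug <- sample(100:2000, 1)
    n_event <- sample(50:1000, 1)
    n_obs <- sample(1:min(n_drug, n_event), 1)
    out <- ic(n_obs, n_drug, n_event, n_total, method = "plain")
    expect_equal(sign(out$ic), sign(n_obs - out$n_expected))
  }
})

test_that("relative risk is the incidence ratio", {
  expect_equal(round_half_up(relative_risk(6.5, 3.8)), 1.71)
  expect_equal(relative_risk(4.2, 4.2), 1)
  expect_equal(relative_risk(0, 5), 0)
  expect_error(relative_risk(1, 0), "positive")
})

test_that("the joint signal criterion requires cases, ROR05 and IC025", {
  crit <- signal_criteria()
  expect_true(evaluate_signal(
    list(n_observed = 634, ror05 = 17.80, ic025 = 2.43), crit))
  expect_false(evaluate_signal(
    list(n_observed = 9, ror05 = 5.0, ic025 = 1.0), crit))
  # elevated ROR alone is not a signal: published hepatitis-acute row
  expect_false(evaluate_signal(
    list(n_observed = 85, ror05 = 1.83, ic025 = -0.50), crit))
  expect_true(evaluate_signal(
    list(n_observed = 10, ror05 = 1.5, ic025 = 0.5), crit))
  stricter <- signal_criteria(min_cases = 11)
  expect_false(evaluate_signal(
    list(n_observed = 10, ror05 = 1.5, ic025 = 0.5), stricter))
})

test_that("scans flag planted cells and tolerate empty cohorts", {
  syn <- generate_synthetic(synth_config(n_cases = 20000, seed = 3,
                                         quarters = "2022Q4"))
  store <- classify_regimens(build_case_store(syn$bundles))
  sc <- scan_signals(store, event_terms("HEPATITIS_SCAN"),
                     strategies = "ICI")
  expect_equal(sc$term[sc$signal], "Immune-mediated hepatitis")
  expect_true(all(diff(sc$n_observed) <= 0))
  # terms absent from the store give zero-count rows, not errors
  empty <- scan_signals(store, event_terms("absent", terms = "No such PT"),
                        strategies = c("ICI", "DUAL_ICI"))
  expect_equal(empty$n_observed, c(0, 0))
  expect_false(any(empty$signal))
})

test_that("two disjoint planted associations are both recovered, no others", {
  cfg <- synth_config(
    n_cases = 30000, seed = 13, quarters = "2022Q4",
    planted_associations = list(
      list(cohort = "DUAL_ICI", pt = "Autoimmune hepatitis", or = 25),
      list(cohort = "ANTI_CTLA4_MONO", pt = "Hepatitis fulminant", or = 40)))
  syn <- generate_synthetic(cfg)
  store <- classify_regimens(build_case_store(syn$bundles))
  sc <- scan_signals(store, event_terms("HEPATITIS_SCAN"),
                     strategies = c("DUAL_ICI", "ANTI_CTLA4_MONO"))
  flagged <- sc[sc$signal, c("term", "strategy")]
  expect_equal(nrow(flagged), 2)
  expect_true(any(flagged$term == "Autoimmune hepatitis" &
                    flagged$strategy == "DUAL_ICI"))
  expect_true(any(flagged$term == "Hepatitis fulminant" &
                    flagged$strategy == "ANTI_CTLA4_MONO"))
})

test_that("head-to-head contrasts compare cohorts directly", {
  syn <- generate_synthetic(synth_config(n_cases = 20000, seed = 23,
                                         quarters = "2022Q4"))
  store <- classify_regimens(build_case_store(syn$bundles))
  ct <- contrast_cohorts(store, event_terms("HRAE"), "DUAL_ICI", "MONO",
                         unit = "reports")
  expect_equal(ct$n_a + ct$n_b,
               sum(store$cases$regimen %in%
                     c("DUAL_ICI", "ANTI_PD1_MONO", "ANTI_PDL1_MONO",
                       "ANTI_CTLA4_MONO")))
  manual <- (ct$a / (ct$n_a - ct$a)) / (ct$c / (ct$n_b - ct$c))
  expect_equal(ct$ror, manual)
})
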