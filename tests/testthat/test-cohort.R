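test_that("drug normalization resolves brands, ingredients and combinations", {
  expect_equal(normalize_drug("OPDIVO"),
               data.frame(agent = "nivolumab", class = "ANTI_PD1",
                          stringsAsFactors = FALSE))
  expect_equal(nrow(normalize_drug("ASPIRIN")), 0)
  # prod_ai takes precedence over the verbatim name
  expect_equal(normalize_drug("UNKNOWN BRAND", "PEMBROLIZUMAB")$agent,
               "pembrolizumab")
  combo <- normalize_drug("NIVOLUMAB AND IPILIMUMAB")
  expect_setequal(combo$agent, c("nivolumab", "ipilimumab"))
  expect_setequal(combo$class, c("ANTI_PD1", "ANTI_CTLA4"))
  # case and whitespace insensitive
  expect_equal(normalize_drug("  keytruda ")$agent, "pembrolizumab")
  expect_equal(normalize_drug("IPILIMUMAB; NIVOLUMAB")$agent,
               c("ipilimumab", "nivolumab"))
})

test_that("the dictionary covers all eight agents and accepts extensions", {
  dict <- ici_dictionary()
  agents <- unique(dict$agent[dict$class %in%
                                c("ANTI_PD1", "ANTI_PDL1", "ANTI_CTLA4")])
  expect_setequal(agents, c("nivolumab", "pembrolizumab", "cemiplimab",
                            "atezolizumab", "avelumab", "durvalumab",
                            "ipilimumab", "tremelimumab"))
  ext <- ici_dictionary(extra = data.frame(
    synonym = "MYCHEMO", agent = "mychemo", class = "CHEMO"))
  expect_equal(normalize_drug("mychemo", dictionary = ext)$class, "CHEMO")
})

test_that("regimen classification follows the PS-role rules", {
  store <- make_tiny_store(list(
    list(drugs = list(c("PS", "NIVOLUMAB"))),
    list(drugs = list(c("PS", "NIVOLUMAB"), c("PS", "IPILIMUMAB"))),
    list(drugs = list(c("PS", "PEMBROLIZUMAB"), c("C", "CARBOPLATIN"))),
    list(drugs = list(c("PS", "ASPIRIN"))),
    list(drugs = list(c("PS", "DURVALUMAB"))),
    list(drugs = list(c("PS", "YERVOY"))),
    # ICI in a non-PS role does not create exposure
    list(drugs = list(c("C", "NIVOLUMAB"), c("PS", "ASPIRIN"))),
    # combination string on a single PS row is dual therapy
    list(drugs = list(c("PS", "NIVOLUMAB AND IPILIMUMAB"))),
    # duplicate listings of one agent collapse to monotherapy
    list(drugs = list(c("PS", "NIVOLUMAB"), c("PS", "OPDIVO")))))
  expect_equal(as.character(store$cases$regimen),
               c("ANTI_PD1_MONO", "DUAL_ICI", "ICI_PLUS_CHEMO", "NON_ICI",
                 "ANTI_PDL1_MONO", "ANTI_CTLA4_MONO", "NON_ICI", "DUAL_ICI",
                 "ANTI_PD1_MONO"))
})

test_that("regimen labels partition the store and ignore drug-row order", {
  syn <- generate_synthetic(synth_config(n_cases = 2000, seed = 5,
                                         quarters = "2022Q4"))
  store <- build_case_store(syn$bundles)
  labeled <- classify_regimens(store)
  expect_false(any(is.na(labeled$cases$regimen)))
  counts <- table(labeled$cases$regimen)
  expect_equal(sum(counts), nrow(labeled$cases))
  mono_dual_chemo <- sum(counts[c("ANTI_PD1_MONO", "ANTI_PDL1_MONO",
                                  "ANTI_CTLA4_MONO", "DUAL_ICI",
                                  "ICI_PLUS_CHEMO")])
  expect_equal(mono_dual_chemo, sum(counts) - counts[["NON_ICI"]])
  set.seed(99)
  store2 <- store
  store2$drug <- store2$drug[sample(nrow(store2$drug)), , drop = FALSE]
  labeled2 <- classify_regimens(store2)
  expect_equal(as.character(labeled2$cases$regimen),
               as.character(labeled$cases$regimen))
})

test_that("event term sets behave as documented", {
  scan <- event_terms("HEPATITIS_SCAN")
  hrae <- event_terms("HRAE")
  expect_length(scan$terms, 35)
  expect_length(hrae$terms, 3)
  # designated terms are a subset of the scanned terms
  expect_true(all(hrae$terms %in% scan$terms))
  expect_equal(select_events(c("Autoimmune hepatitis", "Nausea"), hrae),
               "Autoimmune hepatitis")
  expect_length(select_events("AUTOIMMUNE HEPATITIS", hrae), 1)
  expect_length(select_events("Hepatitis C", hrae), 0)
  expect_equal(select_events("Hepatitis C", scan), "Hepatitis C")
  custom <- event_terms("mine", terms = c("Rash", "Pruritus"))
  expect_equal(select_events("rash", custom), "Rash")
})

test_that("indication organs and reporter regions map as documented", {
  expect_equal(map_indication_to_organ("Malignant melanoma"), "Skin")
  expect_equal(map_indication_to_organ("Non-small cell lung cancer"), "Lung")
  expect_equal(map_indication_to_organ("Renal cell carcinoma"), "Kidney")
  expect_equal(map_indication_to_organ("Hepatocellular carcinoma"), "Liver")
  expect_equal(map_indication_to_organ("Product used for unknown indication"),
               "Unspecified")
  expect_equal(map_indication_to_organ(NA), "Unspecified")
  expect_equal(map_indication_to_organ("Something exotic"), "Others")
  expect_equal(map_country_to_region(c("US", "JP", "DE", "AU", "ZA", "BR")),
               c("Americas", "Asia", "Europe", "Oceania", "Africa",
                 "Americas"))
  expect_equal(map_country_to_region(c("", "XXQ")), c("Missing", "Missing"))
})
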