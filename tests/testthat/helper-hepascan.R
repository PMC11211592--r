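# Shared fixtures: tiny in-code stores for cohort/dedup tests.

# Build a one-quarter store from terse row specs:
#   drugs = list(c(role, drugname), ...) per case; reactions = character()
make_tiny_store <- function(cases) {
  demo <- NULL; drug <- NULL; reac <- NULL; outc <- NULL
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    pid <- paste0(100 + i, "1")
    demo <- rbind(demo, data.frame(
      primaryid = pid, caseid = as.character(100 + i),
      fda_dt = cs$fda_dt %||% "20220315", age = cs$age %||% "",
      age_cod = cs$age_cod %||% "", sex = cs$sex %||% "M",
      reporter_country = cs$country %||% "US", occp_cod = "MD",
      stringsAsFactors = FALSE))
    for (j in seq_along(cs$drugs)) {
      d <- cs$drugs[[j]]
      drug <- rbind(drug, data.frame(
        primaryid = pid, drug_seq = as.character(j), role_cod = d[1],
        drugname = d[2], prod_ai = if (length(d) > 2) d[3] else "",
        stringsAsFactors = FALSE))
    }
    for (pt in cs$reactions %||% "Nausea") {
      reac <- rbind(reac, data.frame(primaryid = pid, pt = pt,
                                     stringsAsFactors = FALSE))
    }
    for (oc in cs$outcomes %||% character(0)) {
      outc <- rbind(outc, data.frame(primaryid = pid, outc_cod = oc,
                                     stringsAsFactors = FALSE))
    }
  }
  bundle <- hepascan::faers_bundle(demo = demo, drug = drug, reac = reac,
                                   outc = outc, quarter = "2022Q1")
  hepascan::classify_regimens(hepascan::build_case_store(bundle))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

bundle_tables <- c("demo", "drug", "reac", "outc", "indi", "ther")

expect_bundle_equal <- function(b1, b2) {
  for (nm in bundle_tables) {
    expect_identical(b1[[nm]], b2[[nm]], label = paste("table", nm))
  }
}
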