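# Clinical characterization of event-matched cases: region, reporter type,
# year band, sex, age, regimen, outcomes, and indication organ, with counts
# and percentages over the case total (missing categories included in the
# denominator).

HCP_CODES <- c("MD", "PH", "OT", "HP")
NON_HCP_CODES <- c("CN", "LW")

year_band <- function(fda_dt) {
  yr <- suppressWarnings(as.integer(substr(blank_to_na(as.character(fda_dt)),
                                           1, 4)))
  ifelse(is.na(yr), "other",
  ifelse(yr >= 2021, "2021-2023Q1",
  ifelse(yr >= 2016, "2016-2020",
  ifelse(yr >= 2011, "2011-2015", "other"))))
}

count_pct <- function(x, levels, n_total) {
  x <- factor(x, levels = levels)
  n <- as.integer(table(x))
  data.frame(category = levels, n = n,
             pct = if (n_total > 0) round_half_up(100 * n / n_total, 1) else 0,
             stringsAsFactors = FALSE)
}

# Cases (surviving primaryids) whose reactions match the term set.
matching_case_ids <- function(store, terms) {
  rec <- event_records(store)
  unique(rec$primaryid[rec$pt %in% norm_label(terms$terms)])
}

#' Summarize clinical characteristics of event-matched cases
#'
#' Restricts a deduplicated, regimen-labeled store to the cases reporting
#' any term of `terms` and tabulates: reporting region, reporter type
#' (healthcare vs non-healthcare professional), reporting-year band
#' (2011-2015, 2016-2020, 2021-2023Q1, other), sex, age (median and IQR by
#' linear interpolation over non-missing parsed ages; never imputed),
#' treatment regimen, outcomes (a case can carry several outcome codes, so
#' outcome counts may exceed the case total), and indication organ.
#' Percentages use the full case count (missing included) as denominator,
#' at 1 decimal place, half-up.
#'
#' @param store regimen-labeled `faers_store`.
#' @param terms an [event_terms()] set (default the three designated
#'   hepatitis adverse events).
#' @param dictionary drug dictionary, used to pick the indication of the
#'   primary-suspect checkpoint-inhibitor drug.
#' @return object of class `case_summary`.
#' @export
summarize_cases <- function(store, terms = event_terms("HRAE"),
                            dictionary = ici_dictionary()) {
  stopifnot(inherits(store, "faers_store"))
  ids <- matching_case_ids(store, terms)
  cases <- store$cases[store$cases$primaryid %in% ids, , drop = FALSE]
  n <- nrow(cases)

  region <- count_pct(map_country_to_region(cases$reporter_country),
                      c("Americas", "Europe", "Asia", "Oceania", "Africa",
                        "Missing"), n)
  occ <- norm_label(cases$occp_cod)
  reporter <- count_pct(
    ifelse(occ %in% HCP_CODES, "Healthcare professional",
    ifelse(occ %in% NON_HCP_CODES, "Non-healthcare professional", "Missing")),
    c("Healthcare professional", "Non-healthcare professional", "Missing"), n)
  years <- count_pct(year_band(cases$fda_dt),
                     c("2011-2015", "2016-2020", "2021-2023Q1", "other"), n)
  sex <- count_pct(
    ifelse(norm_label(cases$sex) == "M", "Male",
    ifelse(norm_label(cases$sex) == "F", "Female", "Missing")),
    c("Male", "Female", "Missing"), n)
  ages <- parse_age(cases$age, cases$age_cod)
  ages <- ages[!is.na(ages)]
  age <- list(
    median = if (length(ages)) unname(stats::median(ages)) else NA_real_,
    iqr = if (length(ages)) unname(stats::quantile(ages, c(0.25, 0.75),
                                                   type = 7)) else
      c(NA_real_, NA_real_),
    n = length(ages))
  regimen <- count_pct(as.character(cases$regimen), REGIMEN_LEVELS, n)

  # outcomes: any code per case; CA/RI/OT pool into "Others"; a case with no
  # outcome row counts as Missing
  outc <- store$outc[store$outc$primaryid %in% cases$primaryid, , drop = FALSE]
  oc <- norm_label(outc$outc_cod)
  per_case <- function(codes) {
    length(unique(outc$primaryid[oc %in% codes]))
  }
  o_n <- c(per_case("DE"), per_case("LT"), per_case("HO"), per_case("DS"),
           per_case(c("CA", "RI", "OT")),
           sum(!(cases$primaryid %in% outc$primaryid)))
  outcomes <- data.frame(
    category = c("Death", "Life-threatening", "Hospitalization", "Disability",
                 "Others", "Missing"),
    n = o_n,
    pct = if (n > 0) round_half_up(100 * o_n / n, 1) else 0,
    stringsAsFactors = FALSE)

  # indication of the first primary-suspect ICI drug (fallback: first listed
  # indication of the report)
  indis <- store$indi[store$indi$primaryid %in% cases$primaryid, , drop = FALSE]
  first_indi <- indis[!duplicated(indis$primaryid), , drop = FALSE]
  ind_pt <- first_indi$indi_pt[match(cases$primaryid, first_indi$primaryid)]
  organ_levels <- c(names(ORGAN_RULES)[-1], "Unspecified", "Others")
  organs <- map_indication_to_organ(ind_pt)
  indication <- count_pct(organs, unique(c(organ_levels, organs)), n)

  structure(list(n_cases = n, region = region, reporter = reporter,
                 years = years, sex = sex, age = age, regimen = regimen,
                 outcomes = outcomes, indication = indication,
                 event_set = terms$name),
            class = "case_summary")
}

#' @export
print.case_summary <- function(x, ...) {
  cat(sprintf("Case summary for event set '%s': %d cases\n", x$event_set,
              x$n_cases))
  cat(sprintf("Age, years: median %s (IQR %s-%s); n = %d non-missing\n",
              format(x$age$median), format(x$age$iqr[1]),
              format(x$age$iqr[2]), x$age$n))
  for (nm in c("sex", "region", "reporter", "years", "regimen", "outcomes",
               "indication")) {
    tab <- x[[nm]]
    tab <- tab[tab$n > 0 | nm %in% c("sex", "reporter"), , drop = FALSE]
    cat("--", nm, "\n")
    for (i in seq_len(nrow(tab))) {
      cat(sprintf("   %-28s %6d (%.1f%%)\n", tab$category[i], tab$n[i],
                  tab$pct[i]))
    }
  }
  invisible(x)
}

#' Fraction of event-matched cases with a fatal outcome
#'
#' @param store regimen-labeled `faers_store`.
#' @param terms an [event_terms()] set.
#' @return proportion of matched cases carrying outcome code `DE` (`NaN`
#'   when no case matches).
#' @export
fatal_fraction <- function(store, terms = event_terms("HRAE")) {
  ids <- matching_case_ids(store, terms)
  if (!length(ids)) return(NaN)
  oc <- store$outc
  fatal <- unique(oc$primaryid[norm_label(oc$outc_cod) == "DE"])
  mean(ids %in% fatal)
}
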