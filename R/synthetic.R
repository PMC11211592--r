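# Synthetic spontaneous-report generator: emits FAERS-format quarter
# bundles with known ground truth (cohort assignment, duplicate versions,
# background event rates, plantable drug-event odds ratios, demographics,
# outcomes) so every pipeline stage is testable without downloading
# anything. Generation is a pure function of (config, seed).

default_drug_exposure <- function() {
  list(
    ANTI_PD1_MONO = list(p = 0.13, drugs = c("NIVOLUMAB", "OPDIVO",
                                             "PEMBROLIZUMAB", "KEYTRUDA",
                                             "CEMIPLIMAB", "LIBTAYO")),
    ANTI_PDL1_MONO = list(p = 0.05, drugs = c("ATEZOLIZUMAB", "TECENTRIQ",
                                              "AVELUMAB", "DURVALUMAB",
                                              "IMFINZI")),
    ANTI_CTLA4_MONO = list(p = 0.03, drugs = c("IPILIMUMAB", "YERVOY",
                                               "TREMELIMUMAB")),
    DUAL_ICI = list(p = 0.05, drugs = c("NIVOLUMAB", "OPDIVO",
                                        "PEMBROLIZUMAB"),
                    partner = c("IPILIMUMAB", "YERVOY")),
    ICI_PLUS_CHEMO = list(p = 0.04, drugs = c("PEMBROLIZUMAB", "KEYTRUDA",
                                              "NIVOLUMAB"),
                          chemo = c("CARBOPLATIN", "CISPLATIN", "PACLITAXEL",
                                    "PEMETREXED")),
    NON_ICI = list(drugs = c("ASPIRIN", "METFORMIN", "ATORVASTATIN",
                             "LISINOPRIL", "OMEPRAZOLE", "IBUPROFEN"))
  )
}

default_demographics <- function() {
  list(sex = c(M = 0.55, F = 0.36, missing = 0.09),
       age_mean = 63, age_sd = 12, age_missing = 0.30,
       country = c(US = 0.34, JP = 0.08, FR = 0.08, DE = 0.07, GB = 0.06,
                   IT = 0.05, CA = 0.04, ES = 0.04, CN = 0.03, AU = 0.03,
                   BR = 0.03, KR = 0.03, ZA = 0.01, missing = 0.11),
       occupation = c(MD = 0.40, PH = 0.15, OT = 0.10, HP = 0.05, CN = 0.18,
                      LW = 0.02, missing = 0.10))
}

default_indications <- function() {
  list(
    ici = c("Malignant melanoma" = 0.33, "Non-small cell lung cancer" = 0.25,
            "Renal cell carcinoma" = 0.12, "Hepatocellular carcinoma" = 0.06,
            "Gastric cancer" = 0.05,
            "Squamous cell carcinoma of head and neck" = 0.05,
            "Urothelial carcinoma" = 0.05,
            "Product used for unknown indication" = 0.09),
    other = c("Hypertension" = 0.30, "Pain" = 0.25, "Diabetes mellitus" = 0.20,
              "Gastrooesophageal reflux disease" = 0.15,
              "Product used for unknown indication" = 0.10))
}

#' Synthetic report-store configuration
#'
#' Full generative specification for fixture quarters. Defaults describe an
#' ICI-enriched desk-scale database: 30% of cases exposed to a checkpoint
#' inhibitor across the five regimen cohorts, hepatitis preferred terms at
#' background reporting rates around 1 per 1,000 cases, and one planted
#' association (immune-mediated hepatitis at odds ratio 20 against its
#' 0.001 background in the ICI-exposed cohort). For a planted
#' `(cohort, pt, or)` the event probability in the cohort satisfies
#' `p1/(1-p1) = or * p0/(1-p0)` with `p0` the background rate, so the
#' report-level exposure-by-event odds ratio equals `or` by construction.
#'
#' @param n_cases number of distinct cases.
#' @param duplicate_rate probability a case receives an extra, earlier
#'   version (content-identical apart from `primaryid`/`fda_dt`).
#' @param quarters quarter labels the reports are spread over (uniformly).
#' @param drug_exposure named list of cohort entries: `p` (probability;
#'   omitted for the remainder cohort), `drugs` (PS-role spellings, one
#'   sampled per case), optional `partner` (second PS drug, for dual
#'   therapy) and `chemo` (concomitant-role partner).
#' @param background_event_rates named vector, preferred term -> baseline
#'   per-report probability; events are independent Bernoulli draws per PT,
#'   so one report may carry several PTs.
#' @param planted_associations list of `list(cohort=, pt=, or=)`; `cohort`
#'   may be a regimen label or `"ICI"` for any ICI-exposed case.
#' @param demographics list with `sex`, `country`, `occupation` probability
#'   vectors (`missing` as a category) and `age_mean`, `age_sd`,
#'   `age_missing`.
#' @param outcome_rates named vector, outcome code -> per-case probability.
#' @param event_outcome_rates optional list, preferred term -> named vector
#'   overriding `outcome_rates` for cases carrying that term.
#' @param seed integer RNG seed; identical config + seed gives identical
#'   output.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_cases = 200000,
                         duplicate_rate = 0.05,
                         quarters = c("2022Q2", "2022Q3", "2022Q4", "2023Q1"),
                         drug_exposure = default_drug_exposure(),
                         background_event_rates = c(
                           "Immune-mediated hepatitis" = 0.001,
                           "Autoimmune hepatitis" = 0.001,
                           "Hepatitis fulminant" = 0.0005,
                           "Hepatitis acute" = 0.001,
                           "Nausea" = 0.03,
                           "Fatigue" = 0.025),
                         planted_associations = list(
                           list(cohort = "ICI",
                                pt = "Immune-mediated hepatitis", or = 20)),
                         demographics = default_demographics(),
                         outcome_rates = c(DE = 0.05, LT = 0.03, HO = 0.25,
                                           DS = 0.01, OT = 0.45),
                         event_outcome_rates = list(),
                         seed = 20230401) {
  probs <- vapply(drug_exposure, function(e) e$p %||% NA_real_, 0)
  named <- probs[!is.na(probs)]
  stopifnot(n_cases >= 1, duplicate_rate >= 0, duplicate_rate <= 1,
            all(named >= 0), sum(named) <= 1,
            all(background_event_rates >= 0),
            all(background_event_rates <= 1),
            all(outcome_rates >= 0), all(outcome_rates <= 1))
  for (assoc in planted_associations) {
    stopifnot(!is.null(assoc$cohort), !is.null(assoc$pt), assoc$or > 0)
    p0 <- unname(background_event_rates[assoc$pt])
    if (is.na(p0)) {
      stop("planted association PT has no background rate: ", assoc$pt)
    }
    odds1 <- assoc$or * p0 / (1 - p0)
    p1 <- odds1 / (1 + odds1)
    if (!is.finite(p1) || p1 >= 1) {
      stop("odds ratio unachievable at this background rate: ", assoc$pt)
    }
  }
  structure(list(n_cases = n_cases, duplicate_rate = duplicate_rate,
                 quarters = quarters, drug_exposure = drug_exposure,
                 background_event_rates = background_event_rates,
                 planted_associations = planted_associations,
                 demographics = demographics, outcome_rates = outcome_rates,
                 event_outcome_rates = event_outcome_rates, seed = seed),
            class = "synth_config")
}

quarter_start <- function(quarter) {
  y <- as.integer(substr(quarter, 1, 4))
  q <- as.integer(substr(quarter, 6, 6))
  as.Date(sprintf("%d-%02d-01", y, (q - 1) * 3 + 1))
}

sample_cat <- function(n, probs, missing_as = "") {
  labs <- names(probs)
  labs[labs == "missing"] <- missing_as
  sample(labs, n, replace = TRUE, prob = probs)
}

#' Generate a synthetic FAERS-format store
#'
#' Draws a case-level database from a [synth_config()]: one cohort label
#' per case, a PS-role drug spelling (plus partner/chemotherapy rows where
#' the cohort requires them), independent Bernoulli event draws per
#' preferred term with planted odds ratios applied in their cohorts,
#' demographics, outcomes, and duplicate earlier versions at the configured
#' rate, split into per-quarter [faers_bundle()]s.
#'
#' @param config a [synth_config()].
#' @return object of class `synthetic_faers`: list with `bundles` (named
#'   list of [faers_bundle()]) and `truth` (per-case cohort labels, planted
#'   parameters with realized counts and the realized sample odds ratio).
#' @export
generate_synthetic <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_cases
  exposure <- config$drug_exposure
  probs <- vapply(exposure, function(e) e$p %||% NA_real_, 0)
  if (any(is.na(probs))) {
    probs[is.na(probs)] <- (1 - sum(probs, na.rm = TRUE)) / sum(is.na(probs))
  }
  cohort <- sample(names(exposure), n, replace = TRUE, prob = probs)
  is_ici <- cohort != "NON_ICI"

  caseid <- as.character(seq_len(n) + 10000000L)
  primaryid <- paste0(caseid, "2")

  qi <- sample(seq_along(config$quarters), n, replace = TRUE)
  day <- sample(1:89, n, replace = TRUE)
  date_main <- quarter_start(config$quarters[qi]) + day
  fda_dt <- format(date_main, "%Y%m%d")

  dg <- config$demographics
  sex <- sample_cat(n, dg$sex)
  age_years <- pmin(pmax(round(stats::rnorm(n, dg$age_mean, dg$age_sd)), 18), 95)
  age <- as.character(age_years)
  age_cod <- rep("YR", n)
  in_months <- stats::runif(n) < 0.05
  age[in_months] <- as.character(age_years[in_months] * 12)
  age_cod[in_months] <- "MON"
  miss_age <- stats::runif(n) < dg$age_missing
  age[miss_age] <- ""
  age_cod[miss_age] <- ""
  country <- sample_cat(n, dg$country)
  occp <- sample_cat(n, dg$occupation)

  # event draws: per-PT Bernoulli with planted odds ratios in their cohorts
  pts <- names(config$background_event_rates)
  event <- matrix(FALSE, n, length(pts), dimnames = list(NULL, pts))
  for (j in seq_along(pts)) {
    p <- rep(config$background_event_rates[[j]], n)
    for (assoc in config$planted_associations) {
      if (assoc$pt != pts[j]) next
      in_cohort <- if (assoc$cohort == "ICI") is_ici else cohort == assoc$cohort
      p0 <- config$background_event_rates[[j]]
      odds1 <- assoc$or * p0 / (1 - p0)
      p[in_cohort] <- odds1 / (1 + odds1)
    }
    event[, j] <- stats::runif(n) < p
  }
  no_event <- rowSums(event) == 0

  reac <- data.frame(
    primaryid = c(rep(primaryid, ncol(event))[as.vector(event)],
                  primaryid[no_event]),
    pt = c(rep(pts, each = n)[as.vector(event)],
           rep("Drug ineffective", sum(no_event))),
    stringsAsFactors = FALSE)

  # drug and indication rows
  ind <- default_indications()
  indication <- ifelse(is_ici, sample_cat(n, ind$ici), sample_cat(n, ind$other))
  drug_rows <- list()
  indi_rows <- list()
  for (lab in names(exposure)) {
    idx <- which(cohort == lab)
    if (!length(idx)) next
    e <- exposure[[lab]]
    drug_rows[[lab]] <- data.frame(
      primaryid = primaryid[idx], drug_seq = "1", role_cod = "PS",
      drugname = sample(e$drugs, length(idx), replace = TRUE),
      prod_ai = "", stringsAsFactors = FALSE)
    seq_next <- 2L
    if (!is.null(e$partner)) {
      drug_rows[[paste0(lab, ".partner")]] <- data.frame(
        primaryid = primaryid[idx], drug_seq = as.character(seq_next),
        role_cod = "PS",
        drugname = sample(e$partner, length(idx), replace = TRUE),
        prod_ai = "", stringsAsFactors = FALSE)
      seq_next <- seq_next + 1L
    }
    if (!is.null(e$chemo)) {
      drug_rows[[paste0(lab, ".chemo")]] <- data.frame(
        primaryid = primaryid[idx], drug_seq = as.character(seq_next),
        role_cod = "C",
        drugname = sample(e$chemo, length(idx), replace = TRUE),
        prod_ai = "", stringsAsFactors = FALSE)
    }
    indi_rows[[lab]] <- data.frame(
      primaryid = primaryid[idx], indi_drug_seq = "1",
      indi_pt = indication[idx], stringsAsFactors = FALSE)
  }
  drug <- do.call(rbind, drug_rows)
  indi <- do.call(rbind, indi_rows)

  # outcomes, optionally event-dependent
  outc_rows <- list()
  for (code in names(config$outcome_rates)) {
    p <- rep(config$outcome_rates[[code]], n)
    for (pt in names(config$event_outcome_rates)) {
      ov <- config$event_outcome_rates[[pt]]
      if (!code %in% names(ov) || !pt %in% pts) next
      p[event[, pt]] <- ov[[code]]
    }
    hit <- stats::runif(n) < p
    outc_rows[[code]] <- data.frame(primaryid = primaryid[hit],
                                    outc_cod = code, stringsAsFactors = FALSE)
  }
  outc <- do.call(rbind, outc_rows) %||%
    data.frame(primaryid = character(0), outc_cod = character(0))

  ther <- data.frame(primaryid = primaryid, dsg_drug_seq = "1",
                     stringsAsFactors = FALSE)

  demo <- data.frame(primaryid = primaryid, caseid = caseid, fda_dt = fda_dt,
                     age = age, age_cod = age_cod, sex = sex,
                     reporter_country = country, occp_cod = occp,
                     stringsAsFactors = FALSE)

  # duplicate earlier versions: same caseid, lower primaryid, strictly
  # earlier fda_dt, possibly landing in an earlier quarter file
  dup <- which(stats::runif(n) < config$duplicate_rate)
  dup_qi <- integer(0)
  if (length(dup)) {
    dup_qi <- vapply(qi[dup], function(k) sample.int(k, 1), 0L)
    same_q <- dup_qi == qi[dup]
    dup_day <- integer(length(dup))
    # same-quarter duplicates draw a day strictly before the main version's
    dup_day[same_q] <- vapply(day[dup][same_q],
                              function(d) sample.int(d, 1) - 1L, 0L)
    dup_day[!same_q] <- sample(1:89, sum(!same_q), replace = TRUE)
    dup_date <- quarter_start(config$quarters[dup_qi]) + dup_day
    dup_demo <- demo[dup, , drop = FALSE]
    dup_demo$primaryid <- paste0(caseid[dup], "1")
    dup_demo$fda_dt <- format(dup_date, "%Y%m%d")
    clone <- function(tab) {
      sel <- tab[tab$primaryid %in% primaryid[dup], , drop = FALSE]
      sel$primaryid <- sub("2$", "1", sel$primaryid)
      sel
    }
    demo <- rbind(demo, dup_demo)
    drug <- rbind(drug, clone(drug))
    reac <- rbind(reac, clone(reac))
    outc <- rbind(outc, clone(outc))
    indi <- rbind(indi, clone(indi))
    ther <- rbind(ther, clone(ther))
  }

  version_quarter <- config$quarters[c(qi, dup_qi)]
  names(version_quarter) <- demo$primaryid
  bundles <- list()
  for (q in config$quarters) {
    pids <- demo$primaryid[version_quarter == q]
    sel <- function(tab) {
      out <- tab[tab$primaryid %in% pids, , drop = FALSE]
      out[order_ids(out$primaryid), , drop = FALSE]
    }
    bundles[[q]] <- faers_bundle(
      demo = sel(demo), drug = sel(drug), reac = sel(reac), outc = sel(outc),
      indi = sel(indi), ther = sel(ther), quarter = q)
  }

  planted <- lapply(config$planted_associations, function(assoc) {
    in_cohort <- if (assoc$cohort == "ICI") is_ici else cohort == assoc$cohort
    has_pt <- event[, assoc$pt]
    a <- sum(in_cohort & has_pt); b <- sum(in_cohort & !has_pt)
    c_ <- sum(!in_cohort & has_pt); d <- sum(!in_cohort & !has_pt)
    c(assoc, list(a = a, b = b, c = c_, d = d,
                  sample_or = (a * d) / (b * c_)))
  })
  structure(list(
    bundles = bundles,
    truth = list(cohort = data.frame(caseid = caseid, primaryid = primaryid,
                                     cohort = cohort,
                                     stringsAsFactors = FALSE),
                 planted = planted,
                 n_cases = n, n_versions = nrow(demo),
                 event_counts = colSums(event))),
    class = "synthetic_faers")
}

#' @export
print.synthetic_faers <- function(x, ...) {
  cat(sprintf("Synthetic FAERS store: %d cases, %d versions, %d quarters\n",
              x$truth$n_cases, x$truth$n_versions, length(x$bundles)))
  for (p in x$truth$planted) {
    cat(sprintf("  planted %s x '%s': target OR %.3g, realized %.3g (a=%d)\n",
                p$cohort, p$pt, p$or, p$sample_or, p$a))
  }
  invisible(x)
}

#' Hand-readable fixture bundle with enumerated expected outputs
#'
#' A deterministic 50-case, 52-version bundle covering every pipeline
#' stage: duplicate versions resolved by date and by primaryid, all five
#' regimen categories (including a combination drug string and brand-name
#' spellings), hepatitis events with known 2x2 cells, multi-outcome
#' reports, and ages in mixed units. The `expected` element enumerates the
#' stage-by-stage truth used by the tests.
#'
#' @return list with `bundle` (a [faers_bundle()]) and `expected` (named
#'   list of hand-computed outputs).
#' @export
fixture_small <- function() {
  demo <- NULL; drug <- NULL; reac <- NULL; outc <- NULL; indi <- NULL
  add <- function(df, ...) rbind(df, data.frame(..., stringsAsFactors = FALSE))
  caseids <- as.character(1001:1050)
  pid <- function(cid, v = "2") paste0(cid, v)
  sexes <- ifelse(as.integer(caseids) %% 10 == 0, "",
                  ifelse(as.integer(caseids) %% 2 == 1, "M", "F"))
  countries <- rep(c("US", "JP", "FR", "DE", ""), 10)
  days <- sprintf("202210%02d", (seq_along(caseids) %% 28) + 1)
  for (i in seq_along(caseids)) {
    cid <- caseids[i]
    n_i <- as.integer(cid)
    age <- ""; age_cod <- ""
    if (cid == "1001") { age <- "60"; age_cod <- "YR" }
    if (cid == "1002") { age <- "63"; age_cod <- "YR" }
    if (cid == "1003") { age <- "66"; age_cod <- "YR" }
    if (cid == "1004") { age <- "756"; age_cod <- "MON" }
    demo <- add(demo, primaryid = pid(cid), caseid = cid, fda_dt = days[i],
                age = age, age_cod = age_cod, sex = sexes[i],
                reporter_country = countries[i],
                occp_cod = if (n_i %% 3 == 0) "CN" else "MD")
    if (n_i <= 1020) {                               # anti-PD-1 monotherapy
      drugname <- if (n_i %% 2 == 1) "NIVOLUMAB" else "OPDIVO"
      drug <- add(drug, primaryid = pid(cid), drug_seq = "1",
                  role_cod = "PS", drugname = drugname, prod_ai = "")
      reac <- add(reac, primaryid = pid(cid),
                  pt = if (n_i <= 1005) "Autoimmune hepatitis" else "Nausea")
      indi <- add(indi, primaryid = pid(cid), indi_drug_seq = "1",
                  indi_pt = "Malignant melanoma")
    } else if (n_i <= 1030) {                        # dual ICI therapy
      if (n_i == 1030) {
        drug <- add(drug, primaryid = pid(cid), drug_seq = "1",
                    role_cod = "PS",
                    drugname = "NIVOLUMAB AND IPILIMUMAB", prod_ai = "")
      } else {
        drug <- add(drug, primaryid = pid(cid), drug_seq = "1",
                    role_cod = "PS", drugname = "NIVOLUMAB", prod_ai = "")
        drug <- add(drug, primaryid = pid(cid), drug_seq = "2",
                    role_cod = "PS", drugname = "IPILIMUMAB", prod_ai = "")
      }
      reac <- add(reac, primaryid = pid(cid),
                  pt = if (n_i <= 1024) "Immune-mediated hepatitis" else
                    "Fatigue")
      indi <- add(indi, primaryid = pid(cid), indi_drug_seq = "1",
                  indi_pt = "Renal cell carcinoma")
    } else if (n_i <= 1035) {                        # anti-CTLA-4 monotherapy
      drug <- add(drug, primaryid = pid(cid), drug_seq = "1",
                  role_cod = "PS", drugname = "YERVOY", prod_ai = "IPILIMUMAB")
      reac <- add(reac, primaryid = pid(cid),
                  pt = if (n_i == 1031) "Hepatitis fulminant" else "Rash")
      indi <- add(indi, primaryid = pid(cid), indi_drug_seq = "1",
                  indi_pt = "Malignant melanoma")
    } else if (n_i <= 1040) {                        # ICI plus chemotherapy
      drug <- add(drug, primaryid = pid(cid), drug_seq = "1",
                  role_cod = "PS", drugname = "KEYTRUDA", prod_ai = "")
      drug <- add(drug, primaryid = pid(cid), drug_seq = "2",
                  role_cod = "C", drugname = "CARBOPLATIN", prod_ai = "")
      reac <- add(reac, primaryid = pid(cid),
                  pt = if (n_i == 1036) "Immune-mediated hepatitis" else
                    "Nausea")
      indi <- add(indi, primaryid = pid(cid), indi_drug_seq = "1",
                  indi_pt = "Non-small cell lung cancer")
    } else {                                         # non-ICI background
      drug <- add(drug, primaryid = pid(cid), drug_seq = "1",
                  role_cod = "PS", drugname = "ASPIRIN", prod_ai = "")
      reac <- add(reac, primaryid = pid(cid),
                  pt = if (n_i == 1041) "Autoimmune hepatitis" else "Headache")
      indi <- add(indi, primaryid = pid(cid), indi_drug_seq = "1",
                  indi_pt = "Hypertension")
    }
  }
  # duplicate versions: case 1001 has an older-dated version (date rule);
  # case 1002 has a same-date lower-primaryid version (primaryid rule)
  demo <- add(demo, primaryid = "10011", caseid = "1001",
              fda_dt = "20220815", age = "60", age_cod = "YR", sex = "M",
              reporter_country = "US", occp_cod = "MD")
  demo <- add(demo, primaryid = "10021", caseid = "1002",
              fda_dt = days[2], age = "63", age_cod = "YR", sex = "F",
              reporter_country = "JP", occp_cod = "MD")
  drug <- add(drug, primaryid = "10011", drug_seq = "1", role_cod = "PS",
              drugname = "NIVOLUMAB", prod_ai = "")
  drug <- add(drug, primaryid = "10021", drug_seq = "1", role_cod = "PS",
              drugname = "OPDIVO", prod_ai = "")
  reac <- add(reac, primaryid = "10011", pt = "Autoimmune hepatitis")
  reac <- add(reac, primaryid = "10021", pt = "Autoimmune hepatitis")
  outc <- data.frame(
    primaryid = c(pid("1001"), pid("1002"), pid("1003"), pid("1021"),
                  pid("1021"), pid("1031")),
    outc_cod = c("DE", "DE", "HO", "DE", "HO", "DE"),
    stringsAsFactors = FALSE)
  bundle <- faers_bundle(demo = demo, drug = drug, reac = reac, outc = outc,
                         indi = indi, quarter = "2022Q4")
  expected <- list(
    n_versions = 52,
    n_cases = 50,
    survivor_1001 = "10012",  # newer FDA receipt date wins
    survivor_1002 = "10022",  # same date: higher primaryid wins
    regimen = c(ANTI_PD1_MONO = 20, ANTI_PDL1_MONO = 0, ANTI_CTLA4_MONO = 5,
                DUAL_ICI = 10, ICI_PLUS_CHEMO = 5, NON_ICI = 10),
    hrae_cases = 12,           # 5 + 4 + 1 + 1 ICI-exposed, 1 background
    fatal_hrae = 4 / 12,       # 1001, 1002, 1021, 1031 carry DE
    autoimmune_2x2_reports = c(a = 5, n_drug = 40, c = 1, n_total = 50),
    age = list(median = 63, iqr = c(62.25, 63.75), n = 4))
  list(bundle = bundle, expected = expected)
}
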