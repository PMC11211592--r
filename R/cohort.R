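# Exposure cohorts and event sets: drug-name normalization to immune
# checkpoint inhibitor (ICI) agents and classes, treatment-regimen
# classification over primary-suspect drugs, hepatitis event-term sets, and
# the indication-organ and country-region maps used by the descriptives.

ICI_CLASSES <- c("ANTI_PD1", "ANTI_PDL1", "ANTI_CTLA4")
REGIMEN_LEVELS <- c("ANTI_PD1_MONO", "ANTI_PDL1_MONO", "ANTI_CTLA4_MONO",
                    "DUAL_ICI", "ICI_PLUS_CHEMO", "NON_ICI")

# Eight marketed checkpoint inhibitors with generic and brand synonyms.
ICI_AGENTS <- list(
  nivolumab     = list(class = "ANTI_PD1",   synonyms = c("NIVOLUMAB", "OPDIVO")),
  pembrolizumab = list(class = "ANTI_PD1",   synonyms = c("PEMBROLIZUMAB", "KEYTRUDA", "LAMBROLIZUMAB")),
  cemiplimab    = list(class = "ANTI_PD1",   synonyms = c("CEMIPLIMAB", "CEMIPLIMAB-RWLC", "LIBTAYO")),
  atezolizumab  = list(class = "ANTI_PDL1",  synonyms = c("ATEZOLIZUMAB", "TECENTRIQ")),
  avelumab      = list(class = "ANTI_PDL1",  synonyms = c("AVELUMAB", "BAVENCIO")),
  durvalumab    = list(class = "ANTI_PDL1",  synonyms = c("DURVALUMAB", "IMFINZI")),
  ipilimumab    = list(class = "ANTI_CTLA4", synonyms = c("IPILIMUMAB", "YERVOY")),
  tremelimumab  = list(class = "ANTI_CTLA4", synonyms = c("TREMELIMUMAB", "TREMELIMUMAB-ACTL", "IMJUDO"))
)

# Curated cytotoxic chemotherapy synonyms (platinums, taxanes,
# antimetabolites, anthracyclines, topoisomerase inhibitors, vinca
# alkaloids); extensible via the `extra` argument of ici_dictionary().
CHEMO_SYNONYMS <- list(
  carboplatin      = c("CARBOPLATIN", "PARAPLATIN"),
  cisplatin        = c("CISPLATIN", "PLATINOL"),
  oxaliplatin      = c("OXALIPLATIN", "ELOXATIN"),
  paclitaxel       = c("PACLITAXEL", "TAXOL", "NAB-PACLITAXEL", "ABRAXANE"),
  docetaxel        = c("DOCETAXEL", "TAXOTERE"),
  gemcitabine      = c("GEMCITABINE", "GEMZAR"),
  pemetrexed       = c("PEMETREXED", "ALIMTA"),
  fluorouracil     = c("FLUOROURACIL", "5-FLUOROURACIL", "5-FU"),
  capecitabine     = c("CAPECITABINE", "XELODA"),
  cyclophosphamide = c("CYCLOPHOSPHAMIDE", "CYTOXAN"),
  doxorubicin      = c("DOXORUBICIN", "ADRIAMYCIN"),
  epirubicin       = c("EPIRUBICIN", "ELLENCE"),
  etoposide        = c("ETOPOSIDE", "VEPESID"),
  irinotecan       = c("IRINOTECAN", "CAMPTOSAR"),
  vinorelbine      = c("VINORELBINE", "NAVELBINE")
)

#' Drug synonym dictionary
#'
#' Builds the synonym-to-agent lookup used for cohort construction: every
#' normalized synonym string maps to an agent name and a class, one of
#' `ANTI_PD1`, `ANTI_PDL1`, `ANTI_CTLA4` (the eight checkpoint inhibitors,
#' with generic and brand names), `CHEMO` (a curated cytotoxic list), or a
#' user-supplied class.
#'
#' @param extra optional data frame with columns `synonym`, `agent`, `class`
#'   appended to the shipped dictionary (user extension point).
#' @return data frame with columns `synonym` (normalized), `agent`, `class`.
#' @export
ici_dictionary <- function(extra = NULL) {
  rows <- lapply(names(ICI_AGENTS), function(agent) {
    data.frame(synonym = ICI_AGENTS[[agent]]$synonyms, agent = agent,
               class = ICI_AGENTS[[agent]]$class, stringsAsFactors = FALSE)
  })
  chemo <- lapply(names(CHEMO_SYNONYMS), function(agent) {
    data.frame(synonym = CHEMO_SYNONYMS[[agent]], agent = agent,
               class = "CHEMO", stringsAsFactors = FALSE)
  })
  dict <- do.call(rbind, c(rows, chemo))
  if (!is.null(extra)) {
    stopifnot(all(c("synonym", "agent", "class") %in% names(extra)))
    dict <- rbind(dict, extra[, c("synonym", "agent", "class")])
  }
  dict$synonym <- norm_label(dict$synonym)
  dict[!duplicated(dict$synonym), , drop = FALSE]
}

# Split a verbatim drug string into candidate components: the whole string
# first, then ";", "+", "," and the word "AND"/"WITH" as separators, then a
# parenthetical-stripped variant of each.
drug_components <- function(x) {
  x <- norm_label(x)
  if (is.na(x) || x == "") return(character(0))
  parts <- unlist(strsplit(x, "[;+,]|\\bAND\\b|\\bWITH\\b"))
  parts <- c(parts, gsub("\\s*\\([^)]*\\)", "", parts))
  unique(c(x, trimws(parts[trimws(parts) != ""])))
}

#' Normalize one drug mention to agents and classes
#'
#' Matches the active-ingredient string first, then the verbatim drug name;
#' each is matched case-insensitively after trimming, first as a whole and
#' then component-wise on `;`/`+`/`AND`-separated parts, so combination
#' strings like `"NIVOLUMAB AND IPILIMUMAB"` yield both agents. Matching is
#' exact after normalization — the dictionary, not fuzzy matching, is the
#' recall lever.
#'
#' @param drugname verbatim drug name string.
#' @param prod_ai active-ingredient string or `NA`.
#' @param dictionary a dictionary from [ici_dictionary()].
#' @return data frame with columns `agent`, `class` (zero rows if nothing
#'   matches).
#' @export
normalize_drug <- function(drugname, prod_ai = NA, dictionary = ici_dictionary()) {
  for (field in c(prod_ai, drugname)) {
    comps <- drug_components(field)
    if (!length(comps)) next
    hit <- dictionary[match(comps, dictionary$synonym, nomatch = 0L), ,
                      drop = FALSE]
    if (nrow(hit)) {
      hit <- hit[!duplicated(hit$agent), c("agent", "class"), drop = FALSE]
      rownames(hit) <- NULL
      return(hit)
    }
  }
  data.frame(agent = character(0), class = character(0),
             stringsAsFactors = FALSE)
}

# Vectorized matcher over a drug entry table: returns one row per
# (drug row, matched agent), caching on unique spelling pairs.
match_drug_table <- function(drug, dictionary) {
  if (!nrow(drug)) {
    return(data.frame(primaryid = character(0), role_cod = character(0),
                      agent = character(0), class = character(0),
                      stringsAsFactors = FALSE))
  }
  prod_ai <- if ("prod_ai" %in% names(drug)) drug$prod_ai else ""
  key <- paste(norm_label(drug$drugname), norm_label(prod_ai), sep = "\r")
  uk <- unique(key)
  idx <- match(key, uk)
  lut <- lapply(strsplit(uk, "\r", fixed = TRUE), function(p) {
    normalize_drug(p[1], if (length(p) > 1) p[2] else NA, dictionary)
  })
  counts <- vapply(lut, nrow, 0L)[idx]
  rows <- rep(seq_len(nrow(drug)), counts)
  hits <- do.call(rbind, lut[idx[counts > 0]])
  if (is.null(hits)) {
    hits <- data.frame(agent = character(0), class = character(0),
                       stringsAsFactors = FALSE)
  }
  data.frame(primaryid = drug$primaryid[rows],
             role_cod = toupper(trimws(drug$role_cod[rows])),
             agent = hits$agent, class = hits$class,
             stringsAsFactors = FALSE)
}

#' Classify treatment regimens
#'
#' Assigns exactly one treatment-strategy label per case. ICI exposure is
#' assessed over primary-suspect (PS) drug entries only; chemotherapy
#' co-exposure may sit in any role, since partners are typically coded
#' SS/C. Labels: `DUAL_ICI` iff at least one anti-PD-1/PD-L1 agent and one
#' anti-CTLA-4 agent are PS; otherwise `ICI_PLUS_CHEMO` iff any PS ICI plus
#' any chemotherapy-class drug; otherwise class monotherapy; `NON_ICI` iff
#' no PS-role ICI. Duplicate listings of one agent, and same-class double
#' listings, collapse to the class monotherapy label.
#'
#' @param store a `faers_store` from [build_case_store()].
#' @param dictionary dictionary from [ici_dictionary()].
#' @return `store` with a `regimen` factor column added to `store$cases`
#'   (levels [REGIMEN_LEVELS]).
#' @export
classify_regimens <- function(store, dictionary = ici_dictionary()) {
  stopifnot(inherits(store, "faers_store"))
  matches <- match_drug_table(store$drug, dictionary)
  ps <- matches[matches$role_cod == "PS" & matches$class %in% ICI_CLASSES, ,
                drop = FALSE]
  pid <- store$cases$primaryid
  has <- function(df, cls) pid %in% df$primaryid[df$class %in% cls]
  pd <- has(ps, c("ANTI_PD1", "ANTI_PDL1"))
  pd1 <- has(ps, "ANTI_PD1")
  ctla <- has(ps, "ANTI_CTLA4")
  chemo <- pid %in% matches$primaryid[matches$class == "CHEMO"]
  ici <- pd | ctla
  label <- rep("NON_ICI", length(pid))
  label[ici] <- ifelse(pd[ici] & ctla[ici], "DUAL_ICI",
                ifelse(chemo[ici], "ICI_PLUS_CHEMO",
                ifelse(ctla[ici], "ANTI_CTLA4_MONO",
                ifelse(pd1[ici], "ANTI_PD1_MONO", "ANTI_PDL1_MONO"))))
  store$cases$regimen <- factor(label, levels = REGIMEN_LEVELS)
  agent_map <- ps[!duplicated(ps[c("primaryid", "agent")]), , drop = FALSE]
  store$ici_agents <- agent_map[, c("primaryid", "agent", "class")]
  store
}

# The 35 hepatitis preferred terms of the scan set.
HEPATITIS_SCAN_PTS <- c(
  "Autoimmune hepatitis", "Immune-mediated hepatitis", "Hepatitis acute",
  "Hepatitis fulminant", "Hepatitis cholestatic", "Hepatitis toxic",
  "Hepatitis C", "Hepatitis B reactivation", "Hepatitis B", "Hepatitis E",
  "Ischaemic hepatitis", "Hepatitis viral", "Acute hepatitis B",
  "Cytomegalovirus hepatitis", "Chronic hepatitis", "Steatohepatitis",
  "Non-alcoholic steatohepatitis", "Hepatitis A", "Hepatitis B DNA increased",
  "Chronic hepatitis B", "Hepatitis C virus test positive",
  "Hepatitis A antibody positive", "Hepatitis B core antibody positive",
  "Hepatitis D", "Chronic hepatitis C", "Hepatitis alcoholic",
  "Hepatitis B surface antibody positive", "Hepatitis E virus test positive",
  "Hepatitis G", "Hepatitis B virus test positive",
  "Hepatitis B antigen positive", "Hepatitis B E antibody positive",
  "Hepatitis chronic persistent", "Radiation hepatitis",
  "Hepatitis virus-associated nephropathy")

# The three designated ICI-related hepatitis adverse events.
HRAE_PTS <- c("Autoimmune hepatitis", "Immune-mediated hepatitis",
              "Hepatitis fulminant")

#' Built-in event term sets
#'
#' MedDRA preferred-term sets used throughout the pipeline, matched
#' case-insensitively: `"HEPATITIS_SCAN"` (35 hepatitis PTs scanned for
#' disproportionality), `"HRAE"` (the three designated ICI-related
#' hepatitis adverse events: autoimmune hepatitis, immune-mediated
#' hepatitis, hepatitis fulminant), and `"HEPATOBILIARY"` (a configurable
#' reference superset, defaulting to the scan set, used as a within-organ
#' comparator).
#'
#' @param name set name, or a character vector of PTs to wrap as a custom
#'   set.
#' @param terms optional character vector overriding the terms (used to
#'   configure `HEPATOBILIARY`).
#' @return an object of class `event_terms` (name plus term vector).
#' @export
event_terms <- function(name = c("HRAE", "HEPATITIS_SCAN", "HEPATOBILIARY"),
                        terms = NULL) {
  if (length(name) == 1 && !name %in% c("HRAE", "HEPATITIS_SCAN",
                                        "HEPATOBILIARY") && is.null(terms)) {
    stop("unknown built-in event set: ", name)
  }
  name <- if (is.null(terms)) match.arg(name) else as.character(name[1])
  if (is.null(terms)) {
    terms <- switch(name, HRAE = HRAE_PTS, HEPATITIS_SCAN = HEPATITIS_SCAN_PTS,
                    HEPATOBILIARY = HEPATITIS_SCAN_PTS)
  }
  terms <- as.character(terms)
  stopifnot(length(terms) > 0)
  structure(list(name = name, terms = terms), class = "event_terms")
}

#' @export
print.event_terms <- function(x, ...) {
  cat(sprintf("Event term set '%s': %d preferred terms\n", x$name,
              length(x$terms)))
  invisible(x)
}

#' Select matching event terms for a report
#'
#' Case-insensitive intersection of a report's reaction preferred terms with
#' a term set; returns the term set's canonical spellings of the matches.
#'
#' @param reaction_pts character vector of the report's reaction PTs.
#' @param terms an [event_terms()] set.
#' @return character vector of matched canonical PT spellings.
#' @export
select_events <- function(reaction_pts, terms) {
  stopifnot(inherits(terms, "event_terms"))
  terms$terms[norm_label(terms$terms) %in% norm_label(reaction_pts)]
}

# Keyword rules mapping an indication preferred term to an organ category.
# First matching rule wins; unmatched terms fall into "Others".
ORGAN_RULES <- list(
  Unspecified     = "PRODUCT USED FOR UNKNOWN INDICATION|UNKNOWN INDICATION",
  `Head and neck` = "HEAD AND NECK|NASOPHARY|OROPHARY|HYPOPHARY|LARYN|TONGUE|TONSIL",
  Skin            = "MELANOMA|SKIN|BASAL CELL|MERKEL",
  Pleura          = "MESOTHELIOMA|PLEURA",
  Lung            = "LUNG|BRONCH",
  Kidney          = "RENAL|KIDNEY|NEPHRO",
  Cholecyst       = "GALL ?BLADDER|CHOLECYST|BILIARY|BILE DUCT|CHOLANGIO",
  Liver           = "HEPATOCELL|HEPATIC|LIVER",
  Bladder         = "BLADDER|UROTHELIAL",
  Stomach         = "GASTRIC|STOMACH|GASTRO-?OESOPHAGEAL|GASTRO-?ESOPHAGEAL",
  Breast          = "BREAST",
  Prostate        = "PROSTAT",
  Uterus          = "UTER|ENDOMETRI|CERVI",
  Esophagus       = "OESOPHAG|ESOPHAG",
  Lymphoid        = "LYMPHOMA|HODGKIN",
  Ovary           = "OVAR",
  Pancreas        = "PANCREA",
  Brain           = "GLIO|BRAIN|ASTROCYT|NEUROBLAST",
  Colon           = "COLON|COLORECT|RECTAL|RECTUM",
  Hematologic     = "LEUKAEMIA|LEUKEMIA|MYELOMA|MYELODYSPLAST",
  Thymoma         = "THYMOMA|THYMIC"
)

#' Map an indication preferred term to an organ category
#'
#' Keyword rules assign each treatment-indication PT to one organ category
#' (Skin, Lung, Kidney, ...); unmatched terms map to `"Others"`, and absent
#' or explicitly unknown indications to `"Unspecified"`.
#'
#' @param indication_pt character vector of indication PTs (`NA` allowed).
#' @return character vector of organ labels.
#' @export
map_indication_to_organ <- function(indication_pt) {
  x <- norm_label(indication_pt)
  out <- rep("Others", length(x))
  out[is.na(x) | x == ""] <- "Unspecified"
  todo <- out == "Others"
  for (organ in names(ORGAN_RULES)) {
    hit <- todo & grepl(ORGAN_RULES[[organ]], x)
    out[hit] <- organ
    todo <- todo & !hit
  }
  out
}

# Static ISO-3166 alpha-2 -> continent table (plus a few spelled-out names
# common in older report files). Unlisted or blank codes map to "Missing".
COUNTRY_REGION <- local({
  reg <- list(
    Americas = c("US", "CA", "MX", "BR", "AR", "CL", "CO", "PE", "VE", "EC",
                 "BO", "PY", "UY", "GY", "SR", "GF", "CR", "PA", "GT", "HN",
                 "SV", "NI", "BZ", "CU", "DO", "HT", "JM", "TT", "BB", "BS",
                 "PR", "GL", "AW", "CW", "GD", "LC", "VC", "AG", "DM", "KN"),
    Europe = c("GB", "DE", "FR", "IT", "ES", "PT", "NL", "BE", "LU", "CH",
               "AT", "IE", "DK", "SE", "NO", "FI", "IS", "PL", "CZ", "SK",
               "HU", "RO", "BG", "GR", "HR", "SI", "RS", "BA", "ME", "MK",
               "AL", "EE", "LV", "LT", "UA", "BY", "MD", "RU", "MT", "CY",
               "LI", "MC", "SM", "AD", "VA", "XK", "GI", "FO", "JE", "GG",
               "IM"),
    Asia = c("JP", "CN", "KR", "KP", "TW", "HK", "MO", "IN", "PK", "BD",
             "LK", "NP", "BT", "MV", "TH", "VN", "MY", "SG", "ID", "PH",
             "MM", "KH", "LA", "BN", "TL", "MN", "KZ", "KG", "TJ", "TM",
             "UZ", "AF", "IR", "IQ", "SY", "LB", "JO", "IL", "PS", "SA",
             "AE", "QA", "KW", "BH", "OM", "YE", "TR", "GE", "AM", "AZ"),
    Oceania = c("AU", "NZ", "PG", "FJ", "SB", "VU", "NC", "PF", "WS", "TO",
                "TV", "KI", "NR", "PW", "FM", "MH", "GU", "MP", "CK"),
    Africa = c("ZA", "EG", "NG", "KE", "MA", "TN", "DZ", "LY", "GH", "ET",
               "TZ", "UG", "SN", "CI", "CM", "ZW", "ZM", "MW", "MZ", "AO",
               "NA", "BW", "RW", "BI", "SD", "SS", "SO", "DJ", "ER", "GA",
               "CG", "CD", "CF", "TD", "NE", "ML", "BF", "BJ", "TG", "GN",
               "GW", "GM", "SL", "LR", "MR", "MG", "MU", "SC", "KM", "CV",
               "ST", "GQ", "LS", "SZ"))
  names_map <- c("UNITED STATES" = "Americas", "USA" = "Americas",
                 "CANADA" = "Americas", "BRAZIL" = "Americas",
                 "UNITED KINGDOM" = "Europe", "GERMANY" = "Europe",
                 "FRANCE" = "Europe", "ITALY" = "Europe", "SPAIN" = "Europe",
                 "JAPAN" = "Asia", "CHINA" = "Asia", "INDIA" = "Asia",
                 "KOREA, REPUBLIC OF" = "Asia", "AUSTRALIA" = "Oceania",
                 "NEW ZEALAND" = "Oceania", "SOUTH AFRICA" = "Africa")
  tab <- unlist(lapply(names(reg), function(r) setNames(rep(r, length(reg[[r]])),
                                                        reg[[r]])))
  c(tab, names_map)
})

#' Map a reporter country to a continental region
#'
#' ISO-3166 alpha-2 codes (and a few spelled-out country names seen in
#' legacy files) map to one of Americas, Europe, Asia, Oceania, Africa via a
#' packaged static table; unknown or absent values map to `"Missing"`.
#'
#' @param country character vector of country codes or names.
#' @return character vector of region labels.
#' @export
map_country_to_region <- function(country) {
  x <- norm_label(country)
  out <- unname(COUNTRY_REGION[x])
  out[is.na(out)] <- "Missing"
  out
}
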