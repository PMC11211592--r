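# Reading and writing FAERS-style quarterly ASCII bundles.
#
# The supported dialect is the modern quarterly-data-extract layout:
# "$"-delimited text tables with a mandatory header row, one file per table
# (DEMO, DRUG, REAC, OUTC, INDI, THER), named by prefix plus a quarter suffix
# such as DEMO23Q1.txt. The pre-2012Q3 legacy layout is not implemented; the
# `dialect` argument records the extension point.

TABLE_NAMES <- c("demo", "drug", "reac", "outc", "indi", "ther")

# Canonical (modeled) columns per table; anything else in a source file is
# carried through untouched so no information is dropped on round-trip.
CANONICAL_COLS <- list(
  demo = c("primaryid", "caseid", "fda_dt", "age", "age_cod", "sex",
           "reporter_country", "occp_cod"),
  drug = c("primaryid", "drug_seq", "role_cod", "drugname", "prod_ai"),
  reac = c("primaryid", "pt"),
  outc = c("primaryid", "outc_cod"),
  indi = c("primaryid", "indi_drug_seq", "indi_pt"),
  ther = c("primaryid", "dsg_drug_seq")
)

OUTCOME_CODES <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")
DRUG_ROLES <- c("PS", "SS", "C", "I")

empty_table <- function(name) {
  cols <- CANONICAL_COLS[[name]]
  df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                      stringsAsFactors = FALSE)
  df
}

empty_rejects <- function() {
  data.frame(table = character(0), primaryid = character(0),
             reason = character(0), stringsAsFactors = FALSE)
}

#' Construct a FAERS quarter bundle
#'
#' A `faers_bundle` is the in-memory image of one quarterly file set: a
#' demographics table (`demo`, one row per report *version*) plus the linked
#' entry tables (`drug`, `reac`, `outc`, `indi`, `ther`), all keyed by
#' `primaryid`, together with a quarantine table of rejected rows. Missing
#' values are represented as empty strings, matching the file dialect, so
#' that write/read round-trips are field-identical.
#'
#' @param demo,drug,reac,outc,indi,ther data frames with at least the
#'   canonical columns of each table (character-valued).
#' @param quarter quarter label such as `"2023Q1"`, or `NA`.
#' @param rejected quarantine data frame (`table`, `primaryid`, `reason`).
#' @return an object of class `faers_bundle`.
#' @export
faers_bundle <- function(demo = empty_table("demo"), drug = empty_table("drug"),
                         reac = empty_table("reac"), outc = empty_table("outc"),
                         indi = empty_table("indi"), ther = empty_table("ther"),
                         quarter = NA_character_, rejected = empty_rejects()) {
  tabs <- list(demo = demo, drug = drug, reac = reac, outc = outc,
               indi = indi, ther = ther)
  for (nm in TABLE_NAMES) {
    tab <- as.data.frame(tabs[[nm]], stringsAsFactors = FALSE)
    missing_cols <- setdiff(CANONICAL_COLS[[nm]], names(tab))
    for (mc in missing_cols) tab[[mc]] <- character(nrow(tab))
    for (cc in names(tab)) tab[[cc]] <- na_to_blank(tab[[cc]])
    rownames(tab) <- NULL
    tabs[[nm]] <- tab
  }
  if (anyDuplicated(tabs$demo$primaryid)) {
    stop("duplicated primaryid in DEMO table of one bundle")
  }
  known <- c("", tabs$demo$primaryid)
  for (nm in setdiff(TABLE_NAMES, "demo")) {
    orphan <- !(tabs[[nm]]$primaryid %in% known)
    if (any(orphan)) {
      stop(sprintf("%s entries reference primaryids absent from DEMO: %s",
                   toupper(nm),
                   paste(utils::head(unique(tabs[[nm]]$primaryid[orphan]), 3),
                         collapse = ", ")))
    }
  }
  structure(c(tabs, list(quarter = as.character(quarter), rejected = rejected)),
            class = "faers_bundle")
}

#' @export
print.faers_bundle <- function(x, ...) {
  cat("FAERS quarter bundle", if (!is.na(x$quarter)) sprintf("[%s]", x$quarter),
      "\n")
  for (nm in TABLE_NAMES) {
    cat(sprintf("  %-5s %6d rows\n", toupper(nm), nrow(x[[nm]])))
  }
  if (nrow(x$rejected)) cat(sprintf("  rejected: %d rows\n", nrow(x$rejected)))
  invisible(x)
}

quarter_suffix <- function(quarter) {
  if (is.na(quarter)) return("")
  m <- regmatches(quarter, regexec("^([0-9]{4})Q([1-4])$", quarter))[[1]]
  if (length(m) == 3) paste0(substr(m[2], 3, 4), "Q", m[3]) else ""
}

quarter_from_filename <- function(path) {
  m <- regmatches(basename(path),
                  regexec("([0-9]{2})Q([1-4])", basename(path)))[[1]]
  if (length(m) == 3) paste0("20", m[2], "Q", m[3]) else NA_character_
}

read_delim_table <- function(path) {
  dt <- data.table::fread(path, sep = "$", header = TRUE, quote = "",
                          colClasses = "character", encoding = "Latin-1",
                          fill = TRUE, data.table = FALSE,
                          blank.lines.skip = FALSE)
  names(dt) <- tolower(trimws(names(dt)))
  if (anyDuplicated(names(dt))) {
    stop(sprintf("duplicated header column %s in %s",
                 names(dt)[duplicated(names(dt))][1], basename(path)),
         call. = FALSE)
  }
  dt
}

#' Read one FAERS-style quarter
#'
#' Locates the `$`-delimited tables in `path` by filename prefix
#' (DEMO/DRUG/REAC/OUTC/INDI/THER, case-insensitive) and assembles a
#' [faers_bundle()]. DEMO rows whose mandatory keys fail validation
#' (blank `primaryid`/`caseid`, malformed `fda_dt`) are quarantined into the
#' bundle's `rejected` table with a reason, never silently dropped, so parsed
#' plus rejected rows always equal the source row count. Unknown columns are
#' preserved verbatim.
#'
#' @param path directory containing the quarter's files, or a character
#'   vector of file paths.
#' @param dialect file dialect; only `"qde"` (the modern `$`-delimited
#'   quarterly extract) is implemented.
#' @return a [faers_bundle()].
#' @export
read_faers_quarter <- function(path, dialect = "qde") {
  dialect <- match.arg(dialect, "qde")
  files <- if (length(path) == 1 && dir.exists(path)) {
    list.files(path, full.names = TRUE)
  } else {
    path
  }
  pick <- function(prefix) {
    hit <- files[grepl(paste0("^", prefix), basename(files),
                       ignore.case = TRUE)]
    if (length(hit) > 1) {
      stop(sprintf("multiple %s files found in quarter: %s", toupper(prefix),
                   paste(basename(hit), collapse = ", ")))
    }
    if (length(hit)) hit else NULL
  }
  demo_file <- pick("demo")
  if (is.null(demo_file)) stop("no DEMO file found in ", paste(path, collapse = ", "))
  raw <- read_delim_table(demo_file)
  for (key in c("primaryid", "caseid")) {
    if (!key %in% names(raw)) {
      stop(sprintf("missing mandatory column '%s' in %s", key,
                   basename(demo_file)), call. = FALSE)
    }
  }
  rejected <- empty_rejects()
  fd <- raw$fda_dt %||% rep("", nrow(raw))
  bad_key <- trimws(raw$primaryid) == "" | trimws(raw$caseid) == ""
  bad_dt <- !bad_key & trimws(fd) != "" & !valid_fda_dt(fd)
  if (any(bad_key)) {
    rejected <- rbind(rejected, data.frame(
      table = "demo", primaryid = raw$primaryid[bad_key],
      reason = "blank primaryid or caseid", stringsAsFactors = FALSE))
  }
  if (any(bad_dt)) {
    rejected <- rbind(rejected, data.frame(
      table = "demo", primaryid = raw$primaryid[bad_dt],
      reason = sprintf("malformed fda_dt '%s'", fd[bad_dt]),
      stringsAsFactors = FALSE))
  }
  demo <- raw[!(bad_key | bad_dt), , drop = FALSE]

  others <- list()
  for (nm in setdiff(TABLE_NAMES, "demo")) {
    f <- pick(nm)
    if (is.null(f)) {
      others[[nm]] <- empty_table(nm)
      next
    }
    tab <- read_delim_table(f)
    if (!"primaryid" %in% names(tab)) {
      stop(sprintf("missing mandatory column 'primaryid' in %s", basename(f)),
           call. = FALSE)
    }
    keep <- tab$primaryid %in% demo$primaryid
    if (any(!keep)) {
      rejected <- rbind(rejected, data.frame(
        table = nm, primaryid = tab$primaryid[!keep],
        reason = "primaryid not in DEMO", stringsAsFactors = FALSE))
    }
    others[[nm]] <- tab[keep, , drop = FALSE]
  }
  faers_bundle(demo = demo, drug = others$drug, reac = others$reac,
               outc = others$outc, indi = others$indi, ther = others$ther,
               quarter = quarter_from_filename(demo_file), rejected = rejected)
}

#' Write one FAERS-style quarter
#'
#' Emits the six `$`-delimited tables of a bundle into `dir`, one file per
#' table with a header row, named `DEMO<yy>Q<q>.txt` etc. Output is
#' byte-stable for a fixed bundle.
#'
#' @param bundle a [faers_bundle()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named character vector of file paths written.
#' @export
write_faers_quarter <- function(bundle, dir) {
  stopifnot(inherits(bundle, "faers_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  suffix <- quarter_suffix(bundle$quarter)
  paths <- character(0)
  for (nm in TABLE_NAMES) {
    path <- file.path(dir, paste0(toupper(nm), suffix, ".txt"))
    data.table::fwrite(bundle[[nm]], path, sep = "$", quote = FALSE, na = "")
    paths[nm] <- path
  }
  invisible(paths)
}

# Hours per year and related conversion constants (Julian year of 365.25 d).
AGE_UNIT_DIVISOR <- c(YR = 1, DEC = 0.1, MON = 12, WK = 52.1775,
                      DY = 365.25, HR = 8766)

#' Convert a FAERS age field to years
#'
#' FAERS stores patient age as a value plus a unit code (`YR` years, `DEC`
#' decades, `MON` months, `WK` weeks, `DY` days, `HR` hours). This converts
#' any value to years; it is total: non-numeric or absent values, and unknown
#' unit codes (after a warning), yield `NA` rather than an error.
#'
#' @param age_value character or numeric vector of age values.
#' @param age_code character vector of unit codes, recycled.
#' @return numeric vector of ages in years (`NA` where unparseable).
#' @examples
#' parse_age("63", "YR")   # 63
#' parse_age("756", "MON") # 63
#' @export
parse_age <- function(age_value, age_code) {
  n <- max(length(age_value), length(age_code))
  value <- suppressWarnings(as.numeric(rep_len(blank_to_na(age_value), n)))
  code <- norm_label(rep_len(as.character(age_code), n))
  code[is.na(code) | code == ""] <- "YR"
  unknown <- !(code %in% names(AGE_UNIT_DIVISOR))
  if (any(unknown & !is.na(value))) {
    warning("unknown age unit code(s): ",
            paste(unique(code[unknown & !is.na(value)]), collapse = ", "))
  }
  div <- unname(AGE_UNIT_DIVISOR[code])
  out <- value / div
  out[unknown] <- NA_real_
  out[!is.na(out) & out < 0] <- NA_real_
  as.numeric(out)
}
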