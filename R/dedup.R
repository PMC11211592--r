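# Case deduplication: collapse the submitted versions of each case to its
# current version using the FDA-recommended rule — for identical CASEID keep
# the most recent FDA_DT; on FDA_DT ties keep the higher PRIMARYID.

fda_dt_key <- function(fda_dt) {
  key <- suppressWarnings(as.numeric(blank_to_na(as.character(fda_dt))))
  # an undated version should never beat a dated one
  key[is.na(key)] <- 0
  key
}

#' Deduplicate report versions
#'
#' Given a demographics table with one row per report version (possibly
#' pooled across several quarters), keeps exactly one surviving version per
#' distinct `caseid`: the version maximizing `(fda_dt, primaryid)`
#' lexicographically. Missing `fda_dt` sorts lowest. Identifiers that are
#' fully numeric strings are compared by numeric value, others
#' lexicographically. Output rows are sorted by `caseid` so the result is
#' deterministic and independent of input order.
#'
#' @param demo data frame with columns `primaryid`, `caseid`, `fda_dt`.
#' @return the surviving subset of `demo` rows, one per caseid, sorted by
#'   caseid.
#' @export
deduplicate_reports <- function(demo) {
  stopifnot(all(c("primaryid", "caseid", "fda_dt") %in% names(demo)))
  if (nrow(demo) == 0) return(demo)
  o <- order_ids(demo$caseid, fda_dt_key(demo$fda_dt), demo$primaryid)
  sorted <- demo[o, , drop = FALSE]
  survivors <- sorted[!duplicated(sorted$caseid, fromLast = TRUE), ,
                      drop = FALSE]
  survivors <- survivors[order_ids(survivors$caseid), , drop = FALSE]
  rownames(survivors) <- NULL
  survivors
}

#' Build a deduplicated case store from quarter bundles
#'
#' Pools one or more [faers_bundle()]s, deduplicates the pooled report
#' versions globally (versions of one case may arrive in different
#' quarters), and restricts every entry table to the surviving primaryids.
#' Entry rows of non-surviving versions are discarded wholesale: FAERS
#' versions are full replacements, never deltas. A funnel log records the
#' version-to-case collapse and any rows quarantined at parse time, so every
#' count is auditable.
#'
#' @param bundles a [faers_bundle()] or a list of them.
#' @return an object of class `faers_store` with elements `cases` (one row
#'   per case), entry tables `drug`, `reac`, `outc`, `indi`, `ther`,
#'   `rejected`, and `funnel` (stage, n_in, n_out, reason).
#' @export
build_case_store <- function(bundles) {
  if (inherits(bundles, "faers_bundle")) bundles <- list(bundles)
  stopifnot(length(bundles) > 0,
            all(vapply(bundles, inherits, TRUE, "faers_bundle")))
  pool <- function(nm) {
    tabs <- lapply(bundles, function(b) {
      tab <- b[[nm]]
      if (nm == "demo" && nrow(tab) && !"quarter" %in% names(tab)) {
        tab$quarter <- rep(na_to_blank(b$quarter), nrow(tab))
      }
      tab
    })
    # tolerate heterogeneous pass-through columns across quarters
    cols <- unique(unlist(lapply(tabs, names)))
    tabs <- lapply(tabs, function(tab) {
      for (mc in setdiff(cols, names(tab))) tab[[mc]] <- character(nrow(tab))
      tab[, cols, drop = FALSE]
    })
    out <- do.call(rbind, tabs)
    rownames(out) <- NULL
    out
  }
  demo <- pool("demo")
  if (anyDuplicated(demo$primaryid)) {
    stop("duplicated primaryid across pooled bundles")
  }
  cases <- deduplicate_reports(demo)
  keep <- cases$primaryid
  out <- list(cases = cases)
  for (nm in setdiff(TABLE_NAMES, "demo")) {
    tab <- pool(nm)
    out[[nm]] <- tab[tab$primaryid %in% keep, , drop = FALSE]
    rownames(out[[nm]]) <- NULL
  }
  rejected <- do.call(rbind, lapply(bundles, function(b) b$rejected))
  out$rejected <- rejected %||% empty_rejects()
  out$funnel <- data.frame(
    stage = c("parse_demo", "deduplicate"),
    n_in = c(nrow(demo) + sum(out$rejected$table == "demo"), nrow(demo)),
    n_out = c(nrow(demo), nrow(cases)),
    reason = c("rejected malformed rows", "non-current case versions"),
    stringsAsFactors = FALSE)
  structure(out, class = "faers_store")
}

#' @export
print.faers_store <- function(x, ...) {
  cat(sprintf("FAERS case store: %d cases (from %d versions)\n",
              nrow(x$cases), x$funnel$n_in[x$funnel$stage == "deduplicate"]))
  cat(sprintf("  drug rows %d | reaction rows %d | outcome rows %d\n",
              nrow(x$drug), nrow(x$reac), nrow(x$outc)))
  if ("regimen" %in% names(x$cases)) {
    tab <- table(x$cases$regimen)
    cat("  regimens:", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n")
  }
  invisible(x)
}

# Append a filtering stage to a store's funnel log.
funnel_append <- function(funnel, stage, n_in, n_out, reason) {
  rbind(funnel, data.frame(stage = stage, n_in = n_in, n_out = n_out,
                           reason = reason, stringsAsFactors = FALSE))
}
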