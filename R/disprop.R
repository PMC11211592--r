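# Disproportionality statistics: 2x2 table construction under two
# comparator conventions, the reporting odds ratio (ROR) with its Wald 95%
# interval, the information component (IC) with a shrinkage credibility
# interval, relative risk, the joint signal criterion, and the
# event-by-strategy scan.

#' Build a 2x2 contingency table
#'
#' Two comparator conventions are supported. `"external-comparator"`
#' reconstructs the table from marginal counts as published signal tables
#' print them: `a` = exposed reports with the event, `b` = remaining exposed
#' reports (`n_drug - a`), `c` = events among the *non-exposed* remainder of
#' the database, `d = n_total - n_drug - c`. `"head-to-head"` compares two
#' cohorts directly: `a` of `n_drug` in cohort A versus `c` of `n_total`
#' (here: cohort B's total) in cohort B.
#'
#' @param n_observed events in the exposed cohort (`a`).
#' @param n_drug exposed cohort total (`a + b`).
#' @param n_event_comparator events in the comparator (`c`).
#' @param n_total full database total (external convention) or comparator
#'   cohort total (head-to-head).
#' @param convention `"external-comparator"` or `"head-to-head"`.
#' @return object of class `contingency_2x2` with fields `a`, `b`, `c`, `d`.
#' @export
derive_table <- function(n_observed, n_drug, n_event_comparator, n_total,
                         convention = c("external-comparator", "head-to-head")) {
  convention <- match.arg(convention)
  a <- n_observed
  b <- n_drug - n_observed
  c_ <- n_event_comparator
  d <- if (convention == "external-comparator") {
    n_total - n_drug - n_event_comparator
  } else {
    n_total - n_event_comparator
  }
  cells <- c(a = a, b = b, c = c_, d = d)
  if (any(!is.finite(cells)) || any(cells < 0)) {
    stop(sprintf(paste0("inconsistent counts: derived cells (a=%s, b=%s, ",
                        "c=%s, d=%s) from n_observed=%s, n_drug=%s, ",
                        "n_event_comparator=%s, n_total=%s"),
                 a, b, c_, d, n_observed, n_drug, n_event_comparator,
                 n_total))
  }
  structure(list(a = a, b = b, c = c_, d = d, convention = convention),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(c("exposed", "comparator"),
                              c("event", "no event")))
  cat(sprintf("2x2 contingency table (%s)\n", x$convention))
  print(m)
  invisible(x)
}

#' Reporting odds ratio with Wald 95% interval
#'
#' `ROR = (a d)/(b c)` with bounds
#' `exp(log ROR -/+ 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. With
#' `correction = "haldane"`, 0.5 is first added to every cell (opt-in, never
#' silent). Without correction, `a = 0` yields estimate 0 with undefined
#' (`NA`) bounds; an all-zero table is an error.
#'
#' @param table a `contingency_2x2`, or anything coercible via
#'   `list(a=,b=,c=,d=)`.
#' @param correction `"none"` or `"haldane"`.
#' @param conf_level confidence level of the Wald interval.
#' @return list with `estimate`, `lower`, `upper`, `defined` (logical).
#' @export
ror <- function(table, correction = c("none", "haldane"), conf_level = 0.95) {
  correction <- match.arg(correction)
  a <- table$a; b <- table$b; c_ <- table$c; d <- table$d
  if (all(c(a, b, c_, d) == 0)) stop("all-zero 2x2 table: ROR undefined")
  if (correction == "haldane") {
    a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (a == 0) {
    return(list(estimate = 0, lower = NA_real_, upper = NA_real_,
                defined = FALSE))
  }
  if (b * c_ == 0 || d == 0) {
    return(list(estimate = if (b * c_ == 0) Inf else (a * d) / (b * c_),
                lower = NA_real_, upper = NA_real_, defined = FALSE))
  }
  est <- (a * d) / (b * c_)
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  list(estimate = est, lower = exp(log(est) - z * se),
       upper = exp(log(est) + z * se), defined = TRUE)
}

#' Information component with credibility bounds
#'
#' `n_expected = n_drug * n_event / n_total` is the co-reporting count
#' expected under independence. The `"plain"` IC is
#' `log2(n_observed / n_expected)`; the default `"shrunk"` method applies
#' the standard 0.5 shrinkage, `log2((n_observed + 0.5)/(n_expected +
#' 0.5))`, with the published percentile approximations for the 95%
#' credibility bounds:
#' `ic025 = ic - 3.3 (n+0.5)^(-1/2) - 2 (n+0.5)^(-3/2)` and
#' `ic975 = ic + 2.4 (n+0.5)^(-1/2) - 0.5 (n+0.5)^(-3/2)`.
#'
#' @param n_observed observed co-reporting count.
#' @param n_drug exposed total.
#' @param n_event database-wide event total (inclusive of the exposed
#'   cohort).
#' @param n_total database total; must be positive.
#' @param method `"shrunk"` (default) or `"plain"`.
#' @return list with `n_expected`, `ic`, `ic025`, `ic975`, `defined`.
#' @export
ic <- function(n_observed, n_drug, n_event, n_total,
               method = c("shrunk", "plain")) {
  method <- match.arg(method)
  if (n_total <= 0) stop("n_total must be positive")
  stopifnot(n_drug <= n_total, n_event <= n_total, n_observed <= n_drug)
  n_expected <- n_drug * n_event / n_total
  if (method == "plain") {
    defined <- n_observed > 0 && n_expected > 0
    val <- if (defined) log2(n_observed / n_expected) else NA_real_
    return(list(n_expected = n_expected, ic = val, ic025 = NA_real_,
                ic975 = NA_real_, defined = defined))
  }
  ns <- n_observed + 0.5
  val <- log2(ns / (n_expected + 0.5))
  list(n_expected = n_expected,
       ic = val,
       ic025 = val - 3.3 * ns^(-0.5) - 2 * ns^(-1.5),
       ic975 = val + 2.4 * ns^(-0.5) - 0.5 * ns^(-1.5),
       defined = TRUE)
}

#' Relative risk of two incidence percentages
#'
#' @param p_exposed incidence in the exposed group (any consistent unit,
#'   e.g. percent).
#' @param p_comparator incidence in the comparator group; must be positive.
#' @return the ratio `p_exposed / p_comparator`.
#' @export
relative_risk <- function(p_exposed, p_comparator) {
  if (any(p_comparator <= 0)) stop("comparator incidence must be positive")
  p_exposed / p_comparator
}

#' Signal criteria
#'
#' The joint three-part criterion for designating a drug-event pair a
#' disproportionality signal: at least `min_cases` observed cases, lower
#' Wald bound of the ROR above `ror05_gt`, and lower credibility bound of
#' the IC above `ic025_gt`.
#'
#' @param min_cases minimum observed case count (inclusive), default 10.
#' @param ror05_gt strict lower threshold on ROR05, default 1.
#' @param ic025_gt strict lower threshold on IC025, default 0.
#' @return object of class `signal_criteria`.
#' @export
signal_criteria <- function(min_cases = 10, ror05_gt = 1, ic025_gt = 0) {
  stopifnot(min_cases >= 1)
  structure(list(min_cases = min_cases, ror05_gt = ror05_gt,
                 ic025_gt = ic025_gt), class = "signal_criteria")
}

#' Evaluate the joint signal criterion
#'
#' @param result list/row with `n_observed`, `ror05`, `ic025`.
#' @param criteria a [signal_criteria()].
#' @return logical (vectorized over the fields).
#' @export
evaluate_signal <- function(result, criteria = signal_criteria()) {
  stopifnot(inherits(criteria, "signal_criteria"))
  n <- result$n_observed
  r <- result$ror05
  i <- result$ic025
  ok <- n >= criteria$min_cases &
    !is.na(r) & r > criteria$ror05_gt &
    !is.na(i) & i > criteria$ic025_gt
  ok & !is.na(ok)
}

#' One disproportionality result row
#'
#' Combines the 2x2-derived ROR (Wald interval) and IC (shrinkage
#' credibility interval) for one drug(-set) by event(-set) pair, with the
#' signal flag. The ROR comparator excludes the exposed cohort (the `c` cell
#' is non-exposed events), while the IC expectation uses the inclusive
#' database event total `n_event = a + c`, matching how published signal
#' tables are reconstructable from their printed counts.
#'
#' @param n_observed exposed events (`a`).
#' @param n_drug exposed total.
#' @param n_event_comparator non-exposed events (`c`).
#' @param n_total database total.
#' @param criteria a [signal_criteria()].
#' @param ic_method `"shrunk"` or `"plain"`.
#' @param correction passed to [ror()].
#' @return one-row data frame of class `disprop_result`.
#' @export
disprop <- function(n_observed, n_drug, n_event_comparator, n_total,
                    criteria = signal_criteria(),
                    ic_method = "shrunk", correction = "none") {
  tab <- derive_table(n_observed, n_drug, n_event_comparator, n_total,
                      "external-comparator")
  r <- ror(tab, correction = correction)
  i <- ic(n_observed, n_drug, n_observed + n_event_comparator, n_total,
          method = ic_method)
  row <- data.frame(
    n_observed = n_observed, n_expected = i$n_expected,
    ror = r$estimate, ror05 = r$lower, ror95 = r$upper,
    ic = i$ic, ic025 = i$ic025, ic975 = i$ic975,
    stringsAsFactors = FALSE)
  row$signal <- evaluate_signal(row, criteria)
  class(row) <- c("disprop_result", "data.frame")
  row
}

#' @export
print.disprop_result <- function(x, digits = 2, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, TRUE)
  y[num] <- lapply(y[num], round_half_up, digits = digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

# Distinct (report, normalized PT) event records of a store, with strategy
# labels attached.
event_records <- function(store) {
  reac <- store$reac
  rec <- data.frame(primaryid = reac$primaryid, pt = norm_label(reac$pt),
                    stringsAsFactors = FALSE)
  rec <- rec[!is.na(rec$pt) & rec$pt != "", , drop = FALSE]
  rec[!duplicated(rec[c("primaryid", "pt")]), , drop = FALSE]
}

# Case sets per strategy label. "ICI" pools every ICI-exposed regimen;
# "MONO" pools the three monotherapy classes; regimen levels select
# themselves.
strategy_primaryids <- function(store, strategy) {
  reg <- as.character(store$cases$regimen)
  pick <- switch(strategy,
    ICI = reg != "NON_ICI",
    MONO = reg %in% c("ANTI_PD1_MONO", "ANTI_PDL1_MONO", "ANTI_CTLA4_MONO"),
    ANTI_PD1_PDL1_MONO = reg %in% c("ANTI_PD1_MONO", "ANTI_PDL1_MONO"),
    reg == strategy)
  store$cases$primaryid[pick]
}

#' Scan event terms across treatment strategies
#'
#' Computes one disproportionality row per (event term, strategy) pair,
#' comparing each strategy cohort against the remainder of the store
#' (external-comparator convention). The counting unit is configurable:
#' `"events"` counts distinct report-PT records (denominators are event
#' records), `"reports"` counts case reports (denominators are case
#' counts). Empty cells yield rows with `n_observed = 0` and undefined
#' flags, never an error. Rows are sorted by descending `n_observed`.
#'
#' @param store a regimen-labeled `faers_store` (see [classify_regimens()]).
#' @param terms an [event_terms()] set (or list of sets).
#' @param strategies character vector of strategy labels: any regimen level,
#'   `"ICI"` (all ICI-exposed), `"MONO"`, or `"ANTI_PD1_PDL1_MONO"`.
#' @param criteria a [signal_criteria()].
#' @param unit `"events"` or `"reports"`.
#' @param composite if `TRUE`, each term set contributes a single pooled row
#'   (any term counts) instead of one row per term.
#' @param ic_method passed to [ic()].
#' @return data frame of class `disprop_scan`.
#' @export
scan_signals <- function(store, terms = event_terms("HEPATITIS_SCAN"),
                         strategies = c("ICI", "DUAL_ICI", "MONO"),
                         criteria = signal_criteria(),
                         unit = c("events", "reports"),
                         composite = FALSE, ic_method = "shrunk") {
  stopifnot(inherits(store, "faers_store"),
            "regimen" %in% names(store$cases))
  unit <- match.arg(unit)
  if (inherits(terms, "event_terms")) terms <- list(terms)
  rec <- event_records(store)
  n_total <- if (unit == "events") nrow(rec) else nrow(store$cases)
  rows <- list()
  for (strategy in strategies) {
    pids <- strategy_primaryids(store, strategy)
    exposed <- rec$primaryid %in% pids
    n_drug <- if (unit == "events") sum(exposed) else length(pids)
    for (ts in terms) {
      groups <- if (composite) {
        setNames(list(norm_label(ts$terms)), ts$name)
      } else {
        setNames(as.list(norm_label(ts$terms)), ts$terms)
      }
      for (gname in names(groups)) {
        is_term <- rec$pt %in% groups[[gname]]
        # a report matching several terms of a composite set counts once
        a <- length(unique(rec$primaryid[is_term & exposed]))
        c_ <- length(unique(rec$primaryid[is_term & !exposed]))
        row <- disprop(a, n_drug, c_, n_total, criteria = criteria,
                       ic_method = ic_method)
        rows[[length(rows) + 1]] <- cbind(
          data.frame(event_set = ts$name, term = gname, strategy = strategy,
                     stringsAsFactors = FALSE),
          as.data.frame(row))
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_observed, out$term, out$strategy), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unit") <- unit
  attr(out, "criteria") <- criteria
  class(out) <- c("disprop_scan", "data.frame")
  out
}

#' @export
print.disprop_scan <- function(x, digits = 2, max_rows = 20, ...) {
  cat(sprintf("Disproportionality scan (%d rows, unit = %s)\n", nrow(x),
              attr(x, "unit") %||% "?"))
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, TRUE)
  y[num] <- lapply(y[num], round_half_up, digits = digits)
  print.data.frame(utils::head(y, max_rows), row.names = FALSE)
  if (nrow(y) > max_rows) cat(sprintf("  ... %d more rows\n", nrow(y) - max_rows))
  invisible(x)
}

#' @export
summary.disprop_scan <- function(object, ...) {
  sig <- object[object$signal, , drop = FALSE]
  cat(sprintf("%d (term, strategy) cells scanned; %d flagged as signals\n",
              nrow(object), nrow(sig)))
  if (nrow(sig)) {
    print.data.frame(
      data.frame(term = sig$term, strategy = sig$strategy,
                 n = sig$n_observed, ror = round_half_up(sig$ror),
                 ror05 = round_half_up(sig$ror05),
                 ic025 = round_half_up(sig$ic025)),
      row.names = FALSE)
  }
  invisible(sig)
}

#' Head-to-head cohort contrast
#'
#' Compares event reporting between two strategy cohorts directly (subgroup
#' contrasts such as dual therapy versus monotherapy): only the ROR is
#' reported, since the information component is not defined for
#' drug-versus-drug comparisons.
#'
#' @param store regimen-labeled `faers_store`.
#' @param terms an [event_terms()] set, counted as a composite.
#' @param strategy_a,strategy_b strategy labels as in [scan_signals()].
#' @param unit `"events"` or `"reports"`.
#' @param correction passed to [ror()].
#' @return one-row data frame with counts, totals and ROR interval.
#' @export
contrast_cohorts <- function(store, terms, strategy_a, strategy_b,
                             unit = c("events", "reports"),
                             correction = "none") {
  unit <- match.arg(unit)
  rec <- event_records(store)
  tset <- norm_label(terms$terms)
  count <- function(strategy) {
    pids <- strategy_primaryids(store, strategy)
    inside <- rec$primaryid %in% pids
    n <- if (unit == "events") sum(inside) else length(pids)
    a <- length(unique(rec$primaryid[inside & rec$pt %in% tset]))
    c(a = a, n = n)
  }
  ka <- count(strategy_a); kb <- count(strategy_b)
  tab <- derive_table(ka["a"], ka["n"], kb["a"], kb["n"], "head-to-head")
  r <- ror(tab, correction = correction)
  data.frame(event_set = terms$name, strategy_a = strategy_a,
             strategy_b = strategy_b,
             a = unname(ka["a"]), n_a = unname(ka["n"]),
             c = unname(kb["a"]), n_b = unname(kb["n"]),
             ror = r$estimate, ror05 = r$lower, ror95 = r$upper,
             stringsAsFactors = FALSE)
}
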