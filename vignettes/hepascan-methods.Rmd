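---
title: "Methods: disproportionality analysis of hepatitis events under checkpoint inhibition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality analysis of hepatitis events under checkpoint inhibition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepascan)
```

## The problem and the data model

Spontaneous reporting systems such as FAERS collect voluntary reports of
suspected drug–adverse-event pairs. They have no denominator population and
severe reporting biases, so the quantity of interest is not incidence but
*disproportionality*: whether a drug–event pair is reported more often than
its reporting frequency under independence within the database would
predict. `hepascan` applies this to hepatitis preferred terms (PTs, the
MedDRA level at which FAERS codes events) among reports naming an immune
checkpoint inhibitor (ICI) as a primary-suspect drug.

A quarterly file set is read into a `faers_bundle`: one demographics row
per report *version* plus drug, reaction, outcome, indication and therapy
entry tables keyed by `primaryid`. The supported dialect is the modern
`$`-delimited quarterly extract with a header row; the pre-2012Q3 legacy
layout is left as an extension point behind the `dialect` argument, since a
single uniform reader is assumed across the study window. Files are read as
Latin-1 so ingestion never fails on free-text bytes. Rows with unusable
mandatory keys (blank `primaryid`/`caseid`, malformed `fda_dt`) are
quarantined with a reason, never dropped: parsed plus rejected rows equal
source rows per table, which keeps the case funnel auditable end to end.

## Deduplication

FAERS distributes every revision of a case. The pipeline keeps, per
`caseid`, the version maximizing `(fda_dt, primaryid)` lexicographically —
most recent FDA receipt date first, higher `primaryid` on date ties. Two
degenerate inputs are resolved by documented choice rather than error: a
missing `fda_dt` sorts lowest (a dated version always beats an undated
one), and identifiers that are fully numeric strings are compared by value,
others lexicographically, so "higher primaryid" is always well defined.
Versions of one case may arrive in different quarters, so deduplication
runs over the pooled store, and the entry tables of losing versions are
discarded wholesale: FAERS versions are full replacements, never deltas.

## Cohorts and event sets

Drug mentions are normalized against a synonym dictionary covering the
eight marketed checkpoint inhibitors (generic and brand names) plus a
curated cytotoxic-chemotherapy list; both are user-extensible. Matching is
exact after normalization (uppercase, trim, collapse whitespace), tried on
the active-ingredient field first, then the verbatim name, whole string
first and then on `;`/`+`/`AND`-separated components so combination
strings resolve to all their agents. No fuzzy matching is performed —
determinism is preferred over recall, with the dictionary as the recall
lever.

Regimen classification uses primary-suspect (PS) entries for ICI exposure,
because that role restriction defines the exposed cohort; chemotherapy
partners may sit in any role, since co-administered cytotoxics are
typically coded secondary-suspect or concomitant and the
ICI-plus-chemotherapy category would otherwise be unreachable. Exactly one
label per case: `DUAL_ICI` (PS anti-PD-1/PD-L1 *and* PS anti-CTLA-4),
else `ICI_PLUS_CHEMO`, else a class monotherapy, else `NON_ICI`. Two cells
the published category scheme leaves undefined are resolved by choice:
duplicate or same-class double listings collapse to the class monotherapy,
and a PD-1 plus PD-L1 double listing (no CTLA-4) is labeled by the PD-1
class, PD-1 first.

Three built-in PT sets drive the analysis: the 35-term hepatitis scan set,
the three designated hepatitis-related adverse events (autoimmune
hepatitis, immune-mediated hepatitis, hepatitis fulminant — always a
subset of the scan set), and a configurable hepatobiliary reference set.
PT strings are opaque labels matched case-insensitively; no MedDRA
hierarchy or SMQ traversal is attempted.

## Disproportionality statistics

For cells $a,b,c,d$, the reporting odds ratio is $\mathrm{ROR} = ad/bc$
with Wald bounds
$\exp(\ln \mathrm{ROR} \mp z_{0.975}\sqrt{1/a+1/b+1/c+1/d})$. The
information component uses $N_\mathrm{expected} = N_\mathrm{drug}
N_\mathrm{event} / N_\mathrm{total}$ and, by default, the shrinkage form
$\mathrm{IC} = \log_2 \frac{N_\mathrm{observed} + 0.5}{N_\mathrm{expected}
+ 0.5}$ with credibility bounds
$\mathrm{IC025} = \mathrm{IC} - 3.3(N+0.5)^{-1/2} - 2(N+0.5)^{-3/2}$ and
$\mathrm{IC975} = \mathrm{IC} + 2.4(N+0.5)^{-1/2} - 0.5(N+0.5)^{-3/2}$
(the standard percentile approximation from the Bayesian
confidence-propagation tradition). A pair is a signal when
$N_\mathrm{observed} \ge 10$, $\mathrm{ROR05} > 1$ and
$\mathrm{IC025} > 0$ jointly; the case minimum is inclusive ("no fewer
than ten") and configurable.

Conventions that needed deciding:

- **Comparator.** Reconstructing published signal tables from their
  printed counts shows the ROR comparator excludes the exposed cohort
  (`c` is non-exposed events) while the IC expectation uses the inclusive
  database event total ($N_\mathrm{event} = a + c$). Both conventions are
  implemented and named; these are the defaults.
- **Counting unit.** Disproportionality denominators are event records
  (distinct report × PT pairs) by default, descriptives are report-level;
  `unit = "reports"` switches the scan. With rare events the two units
  give nearly identical RORs.
- **Zero cells.** The Haldane 0.5 correction is opt-in; `a = 0` without
  correction reports estimate 0 with undefined bounds, flagged.
- **IC025 caveat.** Published IC025 values for this analysis are *not*
  reproducible from the printed counts under either the plain or the
  shrinkage formula (all give materially higher values). The exact
  upstream computation is unknown; the package therefore validates the IC
  by its properties — sign agreement with observed minus expected, zero at
  forced equality, and near-nominal interval behaviour under independence
  simulations — and never against the printed IC025 numbers. Similarly,
  several published head-to-head interval bounds are not log-symmetric
  about their estimates and are inconsistent with the Wald formula that
  reproduces the point estimates; only point estimates are compared for
  those contrasts, and one printed subgroup estimate (fulminant, dual
  versus monotherapy) differs in the second decimal from its own printed
  counts, which `worked_examples()` displays rather than hides.
- **Multiple testing.** None is applied beyond the joint IC/ROR
  criterion, matching standard signal-detection practice; a Bonferroni
  option on the scan exists for users via `signal_criteria()` thresholds.
- **Rounding.** Report output rounds half away from zero at 2 decimals
  (1 for percentages), the convention of published tables;
  `round_half_up()` is exported because R's `round()` is half-even.

## Descriptive characterization

`summarize_cases()` restricts the deduplicated, regimen-labeled store to
cases reporting the event set and tabulates region, reporter type,
year band (2011–2015, 2016–2020, 2021–2023Q1, with anything earlier or
undated in `other`), sex, age, regimen, outcomes and indication organ.
Percentages use the full case count including missing as denominator. Ages
are converted to years from any FAERS unit code; the median and IQR use
linear interpolation between order statistics (quantile type 7, the
convention that yields fractional quartiles on integer ages) over
non-missing values only — missing ages are omitted, never imputed. Outcome
codes are counted once per case per category, and a case may carry
several, so outcome counts may exceed the case total. The indication organ
comes from keyword rules over the first listed indication of the report's
PS drug; country-to-region uses a packaged static ISO-3166 table.

## The synthetic generator

`generate_synthetic()` emulates the structure the analysis assumes: cohort
assignment by configured exposure probabilities with realistic spelling
variation (brands, combination partners), per-PT independent Bernoulli
event draws (a report may carry several PTs, exercising the
events-versus-reports distinction), demographics, event-dependent outcome
rates, and duplicate earlier versions that differ only in
`primaryid`/`fda_dt`. For a planted association the cohort's event
probability satisfies $p_1/(1-p_1) = \mathrm{OR} \cdot p_0/(1-p_0)$, so
the report-level exposure-by-event odds ratio equals the target by
construction; a saturating background rate makes the target unachievable
and is rejected at configuration time. Generation is a pure function of
(config, seed).

Defaults are a deliberately ICI-enriched desk-scale database: 30% ICI
exposure across five regimen cohorts (a real spontaneous-report database
is far more dilute; the enrichment gives stable cell counts at fixture
sizes without changing any estimator property), hepatitis background
rates around $10^{-3}$ per report, a 5% duplicate rate, and one planted
association — immune-mediated hepatitis at odds ratio 20 against its
$10^{-3}$ background in the ICI cohort — as the reference recovery
condition. The default `n_cases` is 200,000, the full recovery condition;
the test suite runs 200 replicates at 20,000 cases each (and smaller sizes
for structural checks), sizes chosen so the planted cell still carries
~100+ events while the whole suite stays interactive.

What the generator does *not* emulate — narrative free text, misspelled
drug names beyond the dictionary, temporal reporting trends, correlated
events, reporter-dependent differential reporting — bounds what passing
tests show: they validate the pipeline's correctness and calibration on
structurally faithful data, not robustness to real-world FAERS noise, and
no synthetic result transfers to clinical risk estimates.

## Known limitations

Disproportionality measures reporting, not risk: no causal or incidence
interpretation is supported, which is also why the package reports the
pooled-trial relative risk only as a worked example. Raw-database-scale
figures (total report counts, the real hepatitis case series and its
Table-level breakdowns) require the actual database download and are out
of scope; the descriptive module is validated against planted synthetic
distributions instead. The legacy pre-2012Q3 file dialect, FAERS XML, and
MedDRA hierarchy files are not implemented.
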