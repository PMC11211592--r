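# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize a label string for matching
#'
#' Uppercases, trims, and collapses internal whitespace. All string matching
#' in the package (drug synonyms, MedDRA preferred terms) is exact after this
#' normalization; no fuzzy matching is performed.
#'
#' @param x character vector.
#' @return normalized character vector (`NA` preserved).
#' @keywords internal
norm_label <- function(x) {
  x <- toupper(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

#' Round half away from zero
#'
#' Fixed-precision rounding with ties going away from zero (the convention of
#' most published pharmacovigilance tables), as opposed to [round()]'s
#' round-half-even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Canonical form of an identifier for ordering: fully numeric strings are
# stripped of leading zeros and compared by value (via nchar-then-lex order);
# anything else is compared lexicographically after uppercasing.
canonical_id <- function(x) {
  x <- as.character(x)
  num <- !is.na(x) & grepl("^[0-9]+$", x)
  x[num] <- sub("^0+(?=[0-9])", "", x[num], perl = TRUE)
  x[!num] <- toupper(trimws(x[!num]))
  x
}

# Order permutation over identifier strings consistent with numeric order on
# fully numeric ids.
order_ids <- function(...) {
  keys <- list(...)
  cols <- list()
  for (k in keys) {
    if (is.character(k)) {
      cc <- canonical_id(k)
      cols <- c(cols, list(nchar(cc), cc))
    } else {
      cols <- c(cols, list(k))
    }
  }
  do.call(order, cols)
}

# Validate an 8-digit YYYYMMDD integer-valued date string; returns TRUE/FALSE.
valid_fda_dt <- function(x) {
  x <- as.character(x)
  ok <- !is.na(x) & grepl("^[0-9]{8}$", x)
  mm <- suppressWarnings(as.integer(substr(x, 5, 6)))
  ok & !is.na(mm) & mm >= 1L & mm <= 12L
}

# Empty-string missing convention used throughout the file dialect.
blank_to_na <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & trimws(x) == ""] <- NA_character_
  x
}
na_to_blank <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  x
}
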