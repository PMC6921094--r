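# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as opposed to the IEEE round-half-even
#' used by [base::round()]. Coverage percentages and rate statistics are
#' reported with half-up rounding so that e.g. 95.78\% prints as 96\%.
#'
#' @param x numeric vector.
#' @param digits number of decimal places to keep.
#' @return `x` rounded half-up to `digits` decimals.
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Lowercase + trim, the normalization applied to status labels and actions.
norm_lower <- function(x) tolower(trimws(x))

# Uppercase + trim, the normalization applied to HGNC-style gene symbols.
norm_gene <- function(x) toupper(trimws(x))

# Map "" and literal "NULL" to NA: missing-value placeholders are normalized
# to absent at parse time so downstream null-removal rules are testable.
na_if_null <- function(x) {
  x[!is.na(x) & (x == "" | x == "NULL")] <- NA_character_
  x
}

# Strict ISO-8601 date parsing; unparseable values become NA.
parse_iso_date <- function(x) {
  out <- as.Date(rep(NA_character_, length(x)))
  ok <- !is.na(x) & grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  out[ok] <- as.Date(x[ok], format = "%Y-%m-%d")
  out
}

# Escape the five XML special characters in text content.
xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  gsub("'", "&apos;", x, fixed = TRUE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
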