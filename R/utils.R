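# Shared low-level helpers: missing-value sentinels, strict numeric parsing,
# name/value normalization, and classed conditions.

# Sentinels treated as missing in biomedical CSV dialects (case-insensitive).
.missing_sentinels <- c("", "na", "nan", "null")

#' Test cells for missingness
#'
#' A cell is missing when it is \code{NA} or one of the sentinel strings
#' \code{""}, \code{"NA"}, \code{"NaN"}, \code{"null"} (case-insensitive).
#'
#' @param x Character vector of cell values.
#' @return Logical vector, \code{TRUE} where the cell is missing.
#' @export
isMissingCell <- function(x) {
  is.na(x) | tolower(trimws(x)) %in% .missing_sentinels
}

# Strict numeric parser: integers, decimals, scientific notation. Thousands
# separators and anything else yield NA. Vectorized.
parseNumericStrict <- function(x) {
  x <- trimws(x)
  ok <- grepl("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$", x)
  out <- rep(NA_real_, length(x))
  out[ok] <- as.numeric(x[ok])
  out[!is.finite(out)] <- NA_real_
  out
}

# Normalization used by review rules R1/R2: case-fold, strip everything that
# is not alphanumeric (this also collapses whitespace/underscores).
normalizeLabel <- function(x) {
  gsub("[^a-z0-9]+", "", tolower(x))
}

# Tokenize an attribute name on snake/camel/space boundaries, case-folded.
tokenizeName <- function(x) {
  x <- gsub("([a-z0-9])([A-Z])", "\\1 \\2", x)
  toks <- strsplit(tolower(x), "[^a-z0-9]+")[[1]]
  toks[nzchar(toks)]
}

# Classed conditions ---------------------------------------------------------

harmonizrError <- function(class, message, call = NULL) {
  structure(
    class = c(class, "harmonizr_error", "error", "condition"),
    list(message = message, call = call)
  )
}

stopHarmonizr <- function(class, message) {
  stop(harmonizrError(class, message))
}

warnHarmonizr <- function(class, message) {
  warning(structure(
    class = c(class, "harmonizr_warning", "warning", "condition"),
    list(message = message, call = NULL)
  ))
}

# Deterministic ordering helper: order by score descending, ties broken
# lexicographically by name (C locale via method = "radix").
orderByScoreThenName <- function(score, name) {
  order(-score, name, method = "radix")
}
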