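# String similarity primitives shared by the schema and value matchers.
# All routines case-fold their inputs; all return values in [0, 1].

# Levenshtein distance matrix via utils::adist (edit costs all 1).
levenshteinDistance <- function(a, b) {
  utils::adist(a, b)
}

# Normalized Levenshtein distance: d / max(nchar); two empty strings -> 0.
normalizedLevenshtein <- function(a, b) {
  d <- utils::adist(tolower(a), tolower(b))
  denom <- outer(nchar(a), nchar(b), pmax)
  out <- ifelse(denom == 0, 0, d / denom)
  dim(out) <- dim(d)
  out
}

levenshteinSimilarity <- function(a, b) {
  1 - normalizedLevenshtein(a, b)
}

# Jaro similarity of two strings (scalar).
jaroSimilarity <- function(a, b) {
  s <- strsplit(a, "")[[1]]
  t <- strsplit(b, "")[[1]]
  ls <- length(s); lt <- length(t)
  if (ls == 0 && lt == 0) return(1)
  if (ls == 0 || lt == 0) return(0)
  window <- max(0L, floor(max(ls, lt) / 2) - 1L)
  s_matched <- logical(ls); t_matched <- logical(lt)
  m <- 0L
  for (i in seq_len(ls)) {
    lo <- max(1L, i - window); hi <- min(lt, i + window)
    if (lo > hi) next
    for (j in lo:hi) {
      if (!t_matched[j] && s[i] == t[j]) {
        s_matched[i] <- TRUE; t_matched[j] <- TRUE; m <- m + 1L
        break
      }
    }
  }
  if (m == 0L) return(0)
  # transpositions: matched characters out of order
  si <- s[s_matched]; tj <- t[t_matched]
  transp <- sum(si != tj) / 2
  (m / ls + m / lt + (m - transp) / m) / 3
}

# Jaro-Winkler: Jaro boosted by common-prefix length (<= 4), p = 0.1.
jaroWinklerSimilarity <- function(a, b) {
  a <- tolower(a); b <- tolower(b)
  jaro <- jaroSimilarity(a, b)
  maxp <- min(4L, nchar(a), nchar(b))
  prefix <- 0L
  while (prefix < maxp &&
         substr(a, prefix + 1L, prefix + 1L) == substr(b, prefix + 1L, prefix + 1L)) {
    prefix <- prefix + 1L
  }
  jaro + prefix * 0.1 * (1 - jaro)
}

# Character 3-grams of a case-folded string padded with "#" at both ends.
characterTrigrams <- function(x) {
  x <- paste0("#", tolower(x), "#")
  n <- nchar(x)
  if (n < 3) return(x)
  substring(x, seq_len(n - 2L), seq(3L, n))
}

# Cosine similarity between trigram count vectors of two strings.
trigramCosine <- function(a, b) {
  ga <- table(characterTrigrams(a))
  gb <- table(characterTrigrams(b))
  common <- intersect(names(ga), names(gb))
  if (length(common) == 0) return(0)
  num <- sum(as.numeric(ga[common]) * as.numeric(gb[common]))
  num / (sqrt(sum(as.numeric(ga)^2)) * sqrt(sum(as.numeric(gb)^2)))
}

# Jaccard similarity of the token sets of two attribute names.
tokenSetJaccard <- function(a, b) {
  ta <- unique(tokenizeName(a))
  tb <- unique(tokenizeName(b))
  if (length(ta) == 0 && length(tb) == 0) return(1)
  u <- length(union(ta, tb))
  if (u == 0) return(0)
  length(intersect(ta, tb)) / u
}

#' Composite name similarity
#'
#' Mean of four string similarity components: normalized Levenshtein
#' similarity, Jaro-Winkler, token-set Jaccard (after snake/camel/space
#' tokenization and case folding), and character 3-gram cosine. Symmetric,
#' in \eqn{[0, 1]}, and equal to 1 for identical names.
#'
#' @param a,b Attribute names.
#' @return Similarity in \eqn{[0, 1]}.
#' @examples
#' compositeNameScore("gender", "gender")
#' compositeNameScore("Tumor_Focality", "tumor_focality")
#' @export
compositeNameScore <- function(a, b) {
  mean(c(
    levenshteinSimilarity(a, b)[1, 1],
    jaroWinklerSimilarity(a, b),
    tokenSetJaccard(a, b),
    trigramCosine(a, b)
  ))
}
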