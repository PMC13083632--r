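# Independent oracle implementations used to check the package's primitives.
# These deliberately re-derive each quantity from its textbook definition and
# never call the code paths they verify.

# Textbook dynamic-programming Levenshtein distance.
oracleLevenshtein <- function(a, b) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  d <- matrix(0, length(a) + 1, length(b) + 1)
  d[, 1] <- 0:length(a)
  d[1, ] <- 0:length(b)
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1, d[i + 1, j] + 1,
                             d[i, j] + (a[i] != b[j]))
    }
  }
  d[length(a) + 1, length(b) + 1]
}

# Brute-force maximum-weight assignment over all row permutations (square
# matrices up to ~6x6). Returns the maximum achievable total score for a
# rectangular matrix after zero padding.
oracleAssignmentCost <- function(scores) {
  nr <- nrow(scores); nc <- ncol(scores)
  n <- max(nr, nc)
  padded <- matrix(0, n, n)
  padded[seq_len(nr), seq_len(nc)] <- scores
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  best <- -Inf
  for (p in perms(seq_len(n))) {
    tot <- sum(padded[cbind(seq_len(n), p)])
    if (tot > best) best <- tot
  }
  best
}

# Closed-form 1-D EMD between two equal-size empirical samples after pooled
# min-max scaling: mean absolute difference of the matched order statistics.
oracleEmdEqualN <- function(x, y) {
  stopifnot(length(x) == length(y))
  lo <- min(x, y); hi <- max(x, y)
  if (hi == lo) return(0)
  x <- (x - lo) / (hi - lo); y <- (y - lo) / (hi - lo)
  mean(abs(sort(x) - sort(y)))
}

# Independent TF-IDF / cosine over padded character 3-grams, following the
# smoothed-IDF formula ln((1+N)/(1+df)) + 1 directly.
oracleTfidfCosine <- function(a, b, docs) {
  gramsOf <- function(s) {
    s <- paste0("#", tolower(s), "#")
    vapply(seq_len(nchar(s) - 2), function(i) substr(s, i, i + 2), character(1))
  }
  allGrams <- lapply(docs, gramsOf)
  vocab <- unique(unlist(allGrams))
  N <- length(docs)
  df <- vapply(vocab, function(g) sum(vapply(allGrams, function(gs) g %in% gs, logical(1))),
               numeric(1))
  idf <- log((1 + N) / (1 + df)) + 1
  vec <- function(s) {
    gs <- gramsOf(s)
    v <- vapply(vocab, function(g) sum(gs == g), numeric(1)) * idf
    v / sqrt(sum(v^2))
  }
  sum(vec(a) * vec(b))
}

# Independent re-implementation of the signed feature-hashing encoder.
oracleHashVector <- function(text, dimension) {
  s <- paste0("#", tolower(text), "#")
  grams <- vapply(seq_len(nchar(s) - 2), function(i) substr(s, i, i + 2), character(1))
  v <- numeric(dimension)
  for (g in grams) {
    bytes <- utf8ToInt(g)
    h <- 5381
    for (b in bytes) h <- (h * 131 + b) %% 2147483647
    h2 <- 2166136261
    for (b in bytes) h2 <- (h2 * 137 + b) %% 2147483629
    j <- (h %% dimension) + 1
    v[j] <- v[j] + if (h2 %% 2 == 0) 1 else -1
  }
  v / sqrt(sum(v^2))
}

# Exhaustive optimal one-to-one fuzzy pairing (maximum number of pairs under
# the distance threshold), for cross-checking the greedy pairing.
oracleMaxFuzzyPairs <- function(a, b, theta) {
  d <- utils::adist(tolower(a), tolower(b)) / outer(nchar(a), nchar(b), pmax)
  ok <- d <= theta
  best <- 0
  recurse <- function(i, usedB, count) {
    if (count + (length(a) - i + 1) <= best) return()
    if (i > length(a)) {
      best <<- max(best, count)
      return()
    }
    recurse(i + 1, usedB, count)  # skip a[i]
    for (j in seq_along(b)) {
      if (!usedB[j] && ok[i, j]) {
        usedB[j] <- TRUE
        recurse(i + 1, usedB, count + 1)
        usedB[j] <- FALSE
      }
    }
  }
  recurse(1, logical(length(b)), 0)
  best
}

# Label normalization as the review rules define it (case fold, strip
# non-alphanumerics), restated independently.
normalizeLabelOracle <- function(x) gsub("[^a-z0-9]+", "", tolower(x))

# Small RCC-flavored source table used across worked-example tests.
rccSourceTable <- function() {
  harmonTable(data.frame(
    Gender = c("Female", "Male", "Female", "Male"),
    Race = c("White", "Asian", "White", "Other"),
    BMI = c("22.1", "30.4", "27.9", "24.3"),
    Tumor_Focality = c("Unifocal", "Multifocal", "Unifocal", "Unifocal"),
    Age = c("61", "47", "55", "68"),
    check.names = FALSE
  ), "rcc")
}

# Assay-metadata source table mirroring the repository-submission use case.
geoSourceTable <- function() {
  harmonTable(data.frame(
    `Assay Type` = c("RNA-Seq", "RNA-Seq", "RNA-Seq"),
    Organism = c("Homo Sapiens", "Homo Sapiens", "Homo Sapiens"),
    check.names = FALSE
  ), "geo")
}
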