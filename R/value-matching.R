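# Value matchers: align the values of matched attribute pairs to the target's
# permissible values, plus numeric-transform inference for unit conversions.
# All text similarity is computed after case folding, so matches that differ
# only in capitalization always score 1.0 without any model call.

.valueMethods <- c("tfidf", "edit_distance", "embedding", "llm")

#' Edit-distance similarity between two strings
#'
#' Default scorer: \eqn{1 - \mathrm{lev}(s, t) / \max(|s|, |t|)} after case
#' folding; two empty strings score 1. A custom scorer may be supplied; it
#' must be symmetric with range \eqn{[0, 1]} (violations raise a
#' \code{ScorerContractError}).
#'
#' @param s,t Strings.
#' @param scorer Optional \code{function(s, t) -> similarity}.
#' @return Similarity in \eqn{[0, 1]}.
#' @examples
#' valueEditDistance("kitten", "sitting")  # 1 - 3/7
#' @export
valueEditDistance <- function(s, t, scorer = NULL) {
  if (is.null(scorer)) {
    return(levenshteinSimilarity(s, t)[1, 1])
  }
  out <- scorer(s, t)
  if (!is.numeric(out) || length(out) != 1 || is.na(out) || out < 0 || out > 1) {
    stopHarmonizr("ScorerContractError",
                  "custom scorer must return a single similarity in [0, 1]")
  }
  out
}

#' TF-IDF character 3-gram similarity matrix
#'
#' Case-folded, boundary-padded (\code{"#"}) character 3-grams; TF-IDF
#' weights fitted over the union vocabulary of sources and targets with
#' smoothed IDF \eqn{\ln((1+N)/(1+df)) + 1}; cosine similarity of the
#' L2-normalized vectors. Exact case-insensitive string equality forces a
#' similarity of 1.
#'
#' @param sources,targets Character vectors (at least one target).
#' @return Numeric matrix, rows = sources, columns = targets.
#' @examples
#' valueTfidf(c("CNV_LOW", "CNV_HIGH"), c("CNV_L", "CNV_H"))
#' @export
valueTfidf <- function(sources, targets) {
  if (length(targets) < 1) {
    stopHarmonizr("MissingValuesError", "tfidf needs at least one target value")
  }
  docs <- c(sources, targets)
  grams <- lapply(docs, characterTrigrams)
  vocab <- sort(unique(unlist(grams)))
  N <- length(docs)
  tf <- matrix(0, N, length(vocab), dimnames = list(NULL, vocab))
  for (i in seq_len(N)) {
    tab <- table(grams[[i]])
    tf[i, names(tab)] <- as.numeric(tab)
  }
  idf <- log((1 + N) / (1 + colSums(tf > 0))) + 1
  w <- sweep(tf, 2, idf, `*`)
  nrm <- sqrt(rowSums(w^2))
  nrm[nrm == 0] <- 1
  w <- w / nrm
  ns <- length(sources)
  sim <- w[seq_len(ns), , drop = FALSE] %*% t(w[ns + seq_along(targets), , drop = FALSE])
  eq <- outer(tolower(sources), tolower(targets), `==`)
  sim[eq] <- 1
  dimnames(sim) <- list(sources, targets)
  pmin(pmax(sim, 0), 1)
}

#' Embedding cosine similarity matrix between value lists
#'
#' Cosine similarity of encoder vectors, mapped from \eqn{[-1, 1]} to
#' \eqn{[0, 1]} via \eqn{(x + 1)/2}.
#'
#' @param sources,targets Character vectors.
#' @param encoder A \linkS4class{TextEncoder} (default: hash encoder).
#' @return Numeric matrix, rows = sources, columns = targets.
#' @export
valueEmbedding <- function(sources, targets, encoder = hashEncoder()) {
  es <- encodeText(encoder, sources)
  et <- encodeText(encoder, targets)
  sim <- (es %*% t(et) + 1) / 2
  dimnames(sim) <- list(sources, targets)
  pmin(pmax(sim, 0), 1)
}

# Similarity matrix dispatch shared with the schema-level value reranker.
valueSimilarityMatrix <- function(sources, targets, method = "tfidf", methodArgs = list()) {
  switch(method,
    tfidf = valueTfidf(sources, targets),
    edit_distance = {
      scorer <- methodArgs$scorer
      m <- if (is.null(scorer)) {
        levenshteinSimilarity(sources, targets)
      } else {
        outer(seq_along(sources), seq_along(targets),
              Vectorize(function(i, j) valueEditDistance(sources[i], targets[j], scorer)))
      }
      eq <- outer(tolower(sources), tolower(targets), `==`)
      m[eq] <- 1
      dimnames(m) <- list(sources, targets)
      m
    },
    embedding = valueEmbedding(sources, targets,
                               if (is.null(methodArgs$encoder)) hashEncoder() else methodArgs$encoder),
    stopHarmonizr("UnknownMethodError",
                  sprintf("unknown value-matching method '%s' (available: %s)",
                          method, paste(.valueMethods, collapse = ", ")))
  )
}

# Chat-adapter value selection: one call per source value; abstentions yield
# unmatched values; out-of-set answers are rejected and the next-best
# (tfidf) candidate is used instead.
.valueLlmMatrixless <- function(svals, tvals, adapter, tau) {
  tf <- valueTfidf(svals, tvals)
  rows <- lapply(seq_along(svals), function(i) {
    res <- selectCandidate(adapter, data.frame(name = tvals, stringsAsFactors = FALSE),
                           svals[i])
    if (!is.null(res) && !res$choice %in% tvals) {
      j <- orderByScoreThenName(tf[i, ], tvals)[1]
      res <- list(choice = tvals[j], confidence = unname(tf[i, j]))
    }
    if (is.null(res) || res$confidence < tau) {
      data.frame(source_value = svals[i], target_value = NA_character_,
                 similarity = NA_real_, stringsAsFactors = FALSE)
    } else {
      data.frame(source_value = svals[i], target_value = res$choice,
                 similarity = res$confidence, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

.resolvePairs <- function(source, schema, pairs) {
  stopifnot(is.data.frame(pairs),
            all(c("source_attribute", "target_attribute") %in% colnames(pairs)))
  missingSrc <- setdiff(pairs$source_attribute, columnNames(source))
  if (length(missingSrc) > 0) {
    stopHarmonizr("UnknownAttributeError",
                  sprintf("source attributes not in table: %s", paste(missingSrc, collapse = ", ")))
  }
  missingTgt <- setdiff(pairs$target_attribute, schema@attributes)
  if (length(missingTgt) > 0) {
    stopHarmonizr("UnknownAttributeError",
                  sprintf("target attributes not in schema: %s", paste(missingTgt, collapse = ", ")))
  }
  pairs
}

#' Match source values against target permissible values
#'
#' For each attribute pair, aligns the distinct source values with the target
#' attribute's permissible values. Each source value receives its top-1
#' candidate when the similarity reaches \code{tau}, and is reported as
#' unmatched (target \code{NA}) otherwise, so matched and unmatched rows
#' together cover all distinct source values.
#'
#' @param source A \linkS4class{HarmonTable}.
#' @param target Target table/schema/standard (as in
#'   \code{\link{matchSchema}}).
#' @param pairs data.frame of attribute matches with columns
#'   \code{source_attribute}, \code{target_attribute} (e.g. the output of
#'   \code{\link{matchSchema}}).
#' @param method One of \code{tfidf}, \code{edit_distance}, \code{embedding},
#'   \code{llm}.
#' @param methodArgs Named list (e.g. \code{scorer}, \code{encoder},
#'   \code{adapter}).
#' @param tau Minimum similarity for a top-1 value match (default 0.3).
#' @return data.frame with columns \code{source_attribute},
#'   \code{target_attribute}, \code{source_value}, \code{target_value},
#'   \code{similarity}.
#' @examples
#' src <- harmonTable(data.frame(CNV_class = c("CNV_LOW", "CNV_HIGH")), "src")
#' tgt <- harmonTable(data.frame(CNV_status = c("CNV_L", "CNV_H")), "tgt")
#' pairs <- data.frame(source_attribute = "CNV_class", target_attribute = "CNV_status")
#' matchValues(src, tgt, pairs, method = "tfidf")
#' @export
matchValues <- function(source, target, pairs, method = "tfidf",
                        methodArgs = list(), tau = 0.3) {
  ranked <- rankValueMatches(source, target, pairs, method = method,
                             methodArgs = methodArgs, topK = 1L, tau = tau)
  out <- ranked[, c("source_attribute", "target_attribute", "source_value",
                    "target_value", "similarity")]
  rownames(out) <- NULL
  attr(out, "method") <- method
  out
}

#' Rank candidate value matches
#'
#' Per source value, up to \code{topK} candidate target values in descending
#' similarity. With \code{topK = 1} this reduces to \code{\link{matchValues}}
#' (sub-threshold top-1 candidates are reported as unmatched).
#'
#' @inheritParams matchValues
#' @param topK Candidates per source value.
#' @return data.frame with columns \code{source_attribute},
#'   \code{target_attribute}, \code{source_value}, \code{target_value},
#'   \code{similarity}, \code{rank}.
#' @export
rankValueMatches <- function(source, target, pairs, method = "tfidf",
                             methodArgs = list(), topK = 10L, tau = 0.3) {
  stopifnot(is(source, "HarmonTable"))
  if (!method %in% .valueMethods) {
    stopHarmonizr("UnknownMethodError",
                  sprintf("unknown value-matching method '%s' (available: %s)",
                          method, paste(.valueMethods, collapse = ", ")))
  }
  schema <- resolveTargetSchema(target)
  pairs <- .resolvePairs(source, schema, pairs)
  if (!is.null(methodArgs$tau)) tau <- methodArgs$tau

  out <- list()
  for (r in seq_len(nrow(pairs))) {
    sa <- pairs$source_attribute[r]
    ta <- pairs$target_attribute[r]
    svals <- distinctValues(source, sa)
    tvals <- permissibleValues(schema, ta)
    if (length(tvals) == 0) {
      stopHarmonizr("MissingValuesError",
                    sprintf("target attribute '%s' has no permissible values", ta))
    }
    if (length(svals) == 0) next
    if (method == "llm") {
      adapter <- if (is.null(methodArgs$adapter)) mockChatAdapter() else methodArgs$adapter
      res <- tryCatch(.valueLlmMatrixless(svals, tvals, adapter, tau), error = function(e) e)
      if (inherits(res, "error")) {
        warnHarmonizr("AdapterFallbackWarning",
                      sprintf("adapter failed (%s); falling back to tfidf",
                              conditionMessage(res)))
        sim <- valueTfidf(svals, tvals)
        res <- NULL
      }
      if (!is.null(res)) {
        res$source_attribute <- sa
        res$target_attribute <- ta
        res$rank <- 1L
        out[[length(out) + 1L]] <- res[, c("source_attribute", "target_attribute",
                                           "source_value", "target_value",
                                           "similarity", "rank")]
        next
      }
    } else {
      sim <- valueSimilarityMatrix(svals, tvals, method = method, methodArgs = methodArgs)
    }
    k <- min(topK, length(tvals))
    rows <- lapply(seq_along(svals), function(i) {
      ord <- orderByScoreThenName(sim[i, ], tvals)[seq_len(k)]
      d <- data.frame(source_attribute = sa, target_attribute = ta,
                      source_value = svals[i], target_value = tvals[ord],
                      similarity = unname(sim[i, ord]), rank = seq_len(k),
                      stringsAsFactors = FALSE)
      if (topK == 1L && d$similarity[1] < tau) {
        d$target_value <- NA_character_
        d$similarity <- NA_real_
      }
      d
    })
    out[[length(out) + 1L]] <- do.call(rbind, rows)
  }
  res <- if (length(out) == 0) {
    data.frame(source_attribute = character(0), target_attribute = character(0),
               source_value = character(0), target_value = character(0),
               similarity = numeric(0), rank = integer(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, out)
  }
  rownames(res) <- NULL
  attr(res, "method") <- method
  res
}

# Numeric-transform inference --------------------------------------------------

#' Construct a NumericTransform
#'
#' @param scale Multiplicative factor (non-zero).
#' @param offset Additive offset.
#' @param rounding One of \code{"none"}, \code{"floor"}, \code{"nearest"}.
#' @param provenance Free-text provenance tag.
#' @return A \linkS4class{NumericTransform}.
#' @export
numericTransform <- function(scale = 1, offset = 0, rounding = "none",
                             provenance = "user") {
  new("NumericTransform", scale = as.numeric(scale), offset = as.numeric(offset),
      rounding = rounding, provenance = provenance)
}

#' Apply a NumericTransform to numeric values
#'
#' @param transform A \linkS4class{NumericTransform}.
#' @param x Numeric vector.
#' @return Transformed numeric vector.
#' @examples
#' applyNumericTransform(numericTransform(365.25, rounding = "floor"), 25)  # 9131
#' @export
applyNumericTransform <- function(transform, x) {
  out <- x * transform@scale + transform@offset
  switch(transform@rounding,
         none = out,
         floor = floor(out),
         nearest = round(out))
}

#' Algebraic inverse of a NumericTransform (ignoring rounding)
#'
#' @param transform A \linkS4class{NumericTransform}.
#' @return The inverse \linkS4class{NumericTransform} (rounding
#'   \code{"none"}).
#' @export
invertNumericTransform <- function(transform) {
  numericTransform(scale = 1 / transform@scale,
                   offset = -transform@offset / transform@scale,
                   rounding = "none", provenance = "inverse")
}

# Unit vocabulary for hint-based inference.
.normalizeUnit <- function(u) {
  if (is.null(u) || length(u) == 0 || !nzchar(u)) return(NA_character_)
  u <- tolower(trimws(u))
  if (u %in% c("year", "years", "yr", "yrs")) return("years")
  if (u %in% c("month", "months", "mo", "mos")) return("months")
  if (u %in% c("day", "days")) return("days")
  if (u %in% c("kilogram", "kilograms", "kg")) return("kg")
  if (u %in% c("gram", "grams", "g")) return("g")
  u
}

.unitConversionTable <- list(
  "years->days" = list(scale = 365.25, rounding = "floor"),
  "years->months" = list(scale = 12, rounding = "floor"),
  "days->years" = list(scale = 1 / 365.25, rounding = "none"),
  "months->years" = list(scale = 1 / 12, rounding = "none"),
  "kg->g" = list(scale = 1000, rounding = "none"),
  "g->kg" = list(scale = 1 / 1000, rounding = "none")
)

# Scales an adapter may propose, as text tokens.
.candidateScales <- c("12", "365.25", "1/12", "1/365.25", "1000", "1/1000", "1")

#' Infer a numeric transform for a matched numeric attribute pair
#'
#' Deterministic path: when the source and target units are known (target
#' unit from the attribute metadata), the conversion is looked up in a fixed
#' table (years to days uses 365.25 days/year with floor rounding; years to
#' months uses 12). Equal units yield the identity. Without a unit hint, an
#' optional adapter may propose one of the candidate scales \{12, 365.25,
#' 1/12, 1/365.25, 1000, 1/1000, 1\}; otherwise the identity transform is
#' returned with provenance \code{"no-evidence"}.
#'
#' @param cells Character or numeric vector: the source column's cells
#'   (must be numeric-kinded with at least 3 non-missing values).
#' @param targetMetadata Metadata map of the target attribute (its
#'   \code{unit} key is the target unit hint).
#' @param sourceUnit Optional unit of the source column (e.g. from user
#'   input or fixture ground truth).
#' @param adapter Optional \linkS4class{ChatAdapter}.
#' @return A \linkS4class{NumericTransform}.
#' @examples
#' inferNumericTransform(c(25, 61, 47), list(unit = "days"), sourceUnit = "years")
#' @export
inferNumericTransform <- function(cells, targetMetadata = list(),
                                  sourceUnit = NULL, adapter = NULL) {
  cells <- as.character(cells)
  obs <- cells[!isMissingCell(cells)]
  if (inferColumnKind(cells) != "numeric" || length(obs) < 3) {
    stopHarmonizr("NotNumericError",
                  "source column must be numeric with at least 3 non-missing values")
  }
  su <- .normalizeUnit(sourceUnit)
  tu <- .normalizeUnit(targetMetadata$unit)
  if (!is.na(su) && !is.na(tu)) {
    if (su == tu) {
      return(numericTransform(1, 0, "none", provenance = "unit-hint"))
    }
    key <- paste0(su, "->", tu)
    conv <- .unitConversionTable[[key]]
    if (!is.null(conv)) {
      return(numericTransform(conv$scale, 0, conv$rounding, provenance = "unit-hint"))
    }
  }
  if (!is.null(adapter)) {
    query <- paste("convert", if (is.na(su)) "" else su, "to",
                   if (is.na(tu)) "" else tu,
                   paste(utils::head(obs, 5), collapse = " "))
    res <- tryCatch(
      selectCandidate(adapter, data.frame(name = .candidateScales,
                                          stringsAsFactors = FALSE), query),
      error = function(e) NULL)
    if (!is.null(res) && res$choice %in% .candidateScales) {
      scale <- eval(parse(text = res$choice))
      if (scale != 0) {
        return(numericTransform(scale, 0, if (scale > 1) "floor" else "none",
                                provenance = "adapter"))
      }
    }
  }
  numericTransform(1, 0, "none", provenance = "no-evidence")
}
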