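# Schema matchers behind one dispatch contract. Every matcher returns, per
# source attribute, a ranking of target attributes with similarities in
# [0, 1]; match ties are always broken lexicographically by target attribute
# name so results are reproducible. All matchers operate on distinct-value
# sets or value distributions and are therefore invariant to the row order
# of the source table.

.schemaMethods <- c("composite_name", "similarity_flooding", "distribution_based",
                    "jaccard_distance", "magneto_zs_bp", "magneto_zs_llm",
                    "two_phase", "max_val_sim", "llm")

# Coerce the target argument (HarmonTable, TargetSchema, StandardModel, or a
# registered standard name) into a TargetSchema.
resolveTargetSchema <- function(target) {
  if (is.character(target) && length(target) == 1) target <- loadStandard(target)
  schema <- asTargetSchema(target)
  if (length(schema@attributes) == 0) {
    stopHarmonizr("EmptySchemaError", "target schema has no attributes")
  }
  schema
}

# Build a ranked-match data.frame from a sources x targets similarity matrix.
.rankingFromMatrix <- function(mat, topK) {
  src <- rownames(mat)
  tgt <- colnames(mat)
  k <- min(topK, length(tgt))
  rows <- lapply(seq_along(src), function(i) {
    ord <- orderByScoreThenName(mat[i, ], tgt)[seq_len(k)]
    data.frame(source_attribute = src[i], target_attribute = tgt[ord],
               similarity = unname(mat[i, ord]), rank = seq_len(k),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Distinct source values and their observed counts, per column.
.sourceValueProfile <- function(source) {
  cols <- columnNames(source)
  stats::setNames(lapply(cols, function(cn) {
    vals <- distinctValues(source, cn)
    cells <- columnCells(source, cn)
    obs <- cells[!isMissingCell(cells)]
    list(values = vals,
         counts = as.numeric(table(factor(obs, levels = vals))),
         kind = columnKind(source, cn))
  }), cols)
}

# Target attribute profiles: permissible values, weights (observed counts for
# table-origin schemas, uniform for standards), declared/inferred kind.
.targetValueProfile <- function(schema) {
  stats::setNames(lapply(schema@attributes, function(a) {
    vals <- schema@permissibleValues[[a]]
    cnt <- schema@valueCounts[[a]]
    if (length(cnt) != length(vals)) cnt <- rep(1, length(vals))
    list(values = vals, counts = cnt, kind = targetAttributeKind(schema, a))
  }), schema@attributes)
}

# --- composite name matcher (simplified composite of string/set metrics) ----

.matchCompositeName <- function(source, schema, topK, args) {
  src <- columnNames(source)
  tgt <- schema@attributes
  mat <- outer(seq_along(src), seq_along(tgt),
               Vectorize(function(i, j) compositeNameScore(src[i], tgt[j])))
  dimnames(mat) <- list(src, tgt)
  .rankingFromMatrix(mat, topK)
}

# --- similarity flooding ----------------------------------------------------

.matchSimilarityFlooding <- function(source, schema, topK, args) {
  eps <- if (is.null(args$eps)) 1e-4 else args$eps
  maxIter <- if (is.null(args$max_iter)) 100L else as.integer(args$max_iter)
  srcKinds <- vapply(columnNames(source), function(cn) columnKind(source, cn), character(1))
  tgtKinds <- vapply(schema@attributes, function(a) targetAttributeKind(schema, a), character(1))
  mat <- floodSimilarity(columnNames(source), srcKinds,
                         schema@attributes, tgtKinds,
                         eps = eps, maxIter = maxIter)
  .rankingFromMatrix(mat, topK)
}

# --- distribution-based matcher ---------------------------------------------

# 1-D Earth mover's distance between weighted empirical distributions after
# min-max scaling over the pooled range; equals the integral of |delta CDF|.
emdSimilarity <- function(x, wx, y, wy) {
  lo <- min(x, y); hi <- max(x, y)
  if (hi > lo) {
    x <- (x - lo) / (hi - lo)
    y <- (y - lo) / (hi - lo)
  } else {
    # all mass at one point in both distributions
    return(1)
  }
  wx <- wx / sum(wx); wy <- wy / sum(wy)
  breaks <- sort(unique(c(0, x, y, 1)))
  Fx <- vapply(breaks, function(b) sum(wx[x <= b]), numeric(1))
  Fy <- vapply(breaks, function(b) sum(wy[y <= b]), numeric(1))
  n <- length(breaks)
  emd <- sum(abs(Fx[-n] - Fy[-n]) * diff(breaks))
  1 - emd
}

# Total-variation similarity between categorical frequency vectors over the
# union of exact values.
tvSimilarity <- function(vx, wx, vy, wy) {
  u <- union(vx, vy)
  px <- stats::setNames(rep(0, length(u)), u)
  py <- px
  px[vx] <- wx / sum(wx)
  py[vy] <- wy / sum(wy)
  1 - 0.5 * sum(abs(px - py))
}

.matchDistributionBased <- function(source, schema, topK, args) {
  sp <- .sourceValueProfile(source)
  tp <- .targetValueProfile(schema)
  thin <- c(
    names(sp)[vapply(sp, function(p) sum(p$counts) < 2, logical(1))],
    names(tp)[vapply(tp, function(p) sum(p$counts) < 2, logical(1))]
  )
  if (length(thin) > 0) {
    warnHarmonizr("InsufficientDataWarning",
                  sprintf("columns with <2 non-missing values scored 0: %s",
                          paste(unique(thin), collapse = ", ")))
  }
  mat <- matrix(0, length(sp), length(tp), dimnames = list(names(sp), names(tp)))
  for (i in names(sp)) {
    for (j in names(tp)) {
      a <- sp[[i]]; b <- tp[[j]]
      if (sum(a$counts) < 2 || sum(b$counts) < 2) next
      if (a$kind == "numeric" && b$kind == "numeric") {
        x <- parseNumericStrict(a$values); y <- parseNumericStrict(b$values)
        ok <- !is.na(x); oky <- !is.na(y)
        if (!any(ok) || !any(oky)) next
        mat[i, j] <- emdSimilarity(x[ok], a$counts[ok], y[oky], b$counts[oky])
      } else if (a$kind == "text" && b$kind == "text") {
        mat[i, j] <- tvSimilarity(a$values, a$counts, b$values, b$counts)
      }  # kind-mismatched pairs keep score 0
    }
  }
  .rankingFromMatrix(pmin(pmax(mat, 0), 1), topK)
}

# --- fuzzy Jaccard with Levenshtein pairing ---------------------------------

# Greedy one-to-one pairing of two distinct-value sets in ascending
# normalized Levenshtein distance, keeping only pairs with distance <= theta.
# Ties broken by (distance, source value, target value).
greedyFuzzyPairs <- function(a, b, theta) {
  if (length(a) == 0 || length(b) == 0) {
    return(data.frame(source = character(0), target = character(0),
                      distance = numeric(0), stringsAsFactors = FALSE))
  }
  d <- normalizedLevenshtein(a, b)
  cand <- which(d <= theta, arr.ind = TRUE)
  if (nrow(cand) == 0) {
    return(data.frame(source = character(0), target = character(0),
                      distance = numeric(0), stringsAsFactors = FALSE))
  }
  dist <- d[cand]
  ord <- order(dist, a[cand[, 1]], b[cand[, 2]], method = "radix")
  usedA <- logical(length(a)); usedB <- logical(length(b))
  keep <- integer(0)
  for (k in ord) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!usedA[i] && !usedB[j]) {
      usedA[i] <- TRUE; usedB[j] <- TRUE
      keep <- c(keep, k)
    }
  }
  data.frame(source = a[cand[keep, 1]], target = b[cand[keep, 2]],
             distance = dist[keep], stringsAsFactors = FALSE)
}

#' Fuzzy Jaccard similarity of two value sets
#'
#' Builds a fuzzy intersection by greedy one-to-one pairing of distinct
#' values in ascending normalized Levenshtein distance (only pairs with
#' distance \eqn{\le \theta}); the similarity is
#' \eqn{|I| / (|U_s| + |U_t| - |I|)}. At \eqn{\theta = 0} this equals the
#' exact Jaccard similarity (up to case folding), and it is monotone
#' non-decreasing in \eqn{\theta}.
#'
#' @param a,b Character vectors of distinct values.
#' @param theta Normalized Levenshtein distance threshold (default 0.2).
#' @return Similarity in \eqn{[0, 1]}.
#' @examples
#' jaccardLevenshteinSimilarity(c("CNV_LOW", "CNV_HIGH"), c("CNV_L", "CNV_H"), theta = 0.5)
#' @export
jaccardLevenshteinSimilarity <- function(a, b, theta = 0.2) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0 && length(b) == 0) return(1)
  pairs <- greedyFuzzyPairs(a, b, theta)
  i <- nrow(pairs)
  i / (length(a) + length(b) - i)
}

.matchJaccardLevenshtein <- function(source, schema, topK, args) {
  theta <- if (is.null(args$theta)) 0.2 else args$theta
  sp <- .sourceValueProfile(source)
  tp <- .targetValueProfile(schema)
  mat <- matrix(0, length(sp), length(tp), dimnames = list(names(sp), names(tp)))
  for (i in names(sp)) {
    for (j in names(tp)) {
      mat[i, j] <- jaccardLevenshteinSimilarity(sp[[i]]$values, tp[[j]]$values, theta)
    }
  }
  .rankingFromMatrix(mat, topK)
}

# --- magneto: embedding retrieval + bipartite reranking ----------------------

#' Serialize and embed a column for candidate retrieval
#'
#' The column is serialized as \code{"name: <name>. values: v1, ..., v15"}
#' (the first 15 distinct values in sorted order, so the embedding is
#' invariant to the table's row order) and encoded into a unit vector.
#'
#' @param name Column/attribute name.
#' @param values Distinct values of the column.
#' @param encoder A \linkS4class{TextEncoder}.
#' @return Unit-norm numeric vector.
#' @export
embedColumn <- function(name, values, encoder) {
  text <- serializeColumn(name, values)
  as.numeric(encodeText(encoder, text))
}

serializeColumn <- function(name, values) {
  # deterministic value order so embeddings are invariant to row order
  vals <- utils::head(sort(unique(values), method = "radix"), 15L)
  paste0("name: ", name, ". values:",
         if (length(vals) > 0) paste0(" ", paste(vals, collapse = ", ")) else "")
}

.cosineMatrix <- function(source, schema, encoder) {
  sp <- .sourceValueProfile(source)
  tp <- .targetValueProfile(schema)
  stexts <- vapply(names(sp), function(n) serializeColumn(n, sp[[n]]$values), character(1))
  ttexts <- vapply(names(tp), function(n) serializeColumn(n, tp[[n]]$values), character(1))
  es <- encodeText(encoder, stexts)
  et <- encodeText(encoder, ttexts)
  mat <- es %*% t(et)
  dimnames(mat) <- list(names(sp), names(tp))
  pmin(pmax(mat, 0), 1)
}

.matchMagnetoZs <- function(source, schema, topK, args, reranker = c("bp", "llm")) {
  reranker <- match.arg(reranker)
  encoder <- if (is.null(args$encoder)) hashEncoder() else args$encoder
  cos <- .cosineMatrix(source, schema, encoder)
  src <- rownames(cos); tgt <- colnames(cos)
  ck <- min(if (is.null(args$candidate_k)) max(topK, 10L) else args$candidate_k, length(tgt))

  # candidate retrieval: top-ck by cosine per source attribute
  candSets <- lapply(src, function(s) tgt[orderByScoreThenName(cos[s, ], tgt)[seq_len(ck)]])
  names(candSets) <- src
  union_cand <- sort(unique(unlist(candSets)))

  winners <- character(length(src))
  names(winners) <- src
  if (reranker == "bp") {
    restricted <- matrix(0, length(src), length(union_cand),
                         dimnames = list(src, union_cand))
    for (s in src) restricted[s, candSets[[s]]] <- cos[s, candSets[[s]]]
    assigned <- bipartiteRerank(restricted)
    for (i in seq_along(src)) winners[i] <- union_cand[assigned[i]]
  } else {
    sp <- .sourceValueProfile(source)
    tp <- .targetValueProfile(schema)
    adapter <- if (is.null(args$adapter)) mockChatAdapter() else args$adapter
    for (s in src) {
      cands <- data.frame(
        name = candSets[[s]],
        context = vapply(candSets[[s]], function(a) {
          paste(attributeMetadata(schema, a)$description,
                paste(utils::head(tp[[a]]$values, 5L), collapse = " "))
        }, character(1)),
        stringsAsFactors = FALSE
      )
      query <- paste(s, paste(utils::head(sp[[s]]$values, 5L), collapse = " "))
      res <- tryCatch(selectCandidate(adapter, cands, query), error = function(e) e)
      if (inherits(res, "error")) {
        warnHarmonizr("AdapterFallbackWarning",
                      sprintf("adapter failed (%s); using bipartite reranking",
                              conditionMessage(res)))
        return(.matchMagnetoZs(source, schema, topK, args, reranker = "bp"))
      }
      winners[s] <- if (is.null(res) || !res$choice %in% candSets[[s]]) {
        candSets[[s]][1]  # abstention / out-of-set answer: keep cosine winner
      } else {
        res$choice
      }
    }
  }

  # ranked output: assignment winner first (reported with the max candidate
  # cosine so the ranked similarities stay non-increasing), remaining targets
  # by cosine
  k <- min(topK, length(tgt))
  rows <- lapply(src, function(s) {
    ord <- tgt[orderByScoreThenName(cos[s, ], tgt)]
    ordered <- c(winners[s], setdiff(ord, winners[s]))[seq_len(k)]
    sims <- unname(cos[s, ordered])
    sims[1] <- max(cos[s, ])
    data.frame(source_attribute = s, target_attribute = ordered,
               similarity = sims, rank = seq_len(k), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# --- two-phase and value-informed reranking ---------------------------------

.matchTwoPhase <- function(source, schema, topK, args) {
  phase1 <- if (is.null(args$phase1)) "composite_name" else args$phase1
  phase2 <- if (is.null(args$phase2)) "jaccard_distance" else args$phase2
  pruneK <- if (is.null(args$prune_k)) topK else as.integer(args$prune_k)
  r1 <- .dispatchSchemaMethod(phase1, source, schema, pruneK, args)
  if (pruneK == 1L) return(r1[r1$rank == 1L, , drop = FALSE])
  r2full <- .dispatchSchemaMethod(phase2, source, schema, length(schema@attributes), args)
  key2 <- paste0(r2full$source_attribute, "\r", r2full$target_attribute)
  s2 <- stats::setNames(r2full$similarity, key2)
  rows <- lapply(split(r1, r1$source_attribute), function(d) {
    sc2 <- unname(s2[paste0(d$source_attribute, "\r", d$target_attribute)])
    sc2[is.na(sc2)] <- 0
    ord <- order(-sc2, -d$similarity, d$target_attribute, method = "radix")
    k <- min(topK, nrow(d))
    data.frame(source_attribute = d$source_attribute[ord[seq_len(k)]],
               target_attribute = d$target_attribute[ord[seq_len(k)]],
               similarity = sc2[ord[seq_len(k)]], rank = seq_len(k),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[unique(r1$source_attribute)])
  rownames(out) <- NULL
  out
}

.matchMaxValSim <- function(source, schema, topK, args) {
  phase1 <- if (is.null(args$phase1)) "magneto_zs_bp" else args$phase1
  valueMethod <- if (is.null(args$value_method)) "tfidf" else args$value_method
  pruneK <- if (is.null(args$prune_k)) max(topK, 10L) else as.integer(args$prune_k)
  r1 <- .dispatchSchemaMethod(phase1, source, schema, pruneK, args)
  sp <- .sourceValueProfile(source)
  tp <- .targetValueProfile(schema)
  rows <- lapply(split(r1, r1$source_attribute), function(d) {
    s <- d$source_attribute[1]
    svals <- sp[[s]]$values
    vscore <- vapply(seq_len(nrow(d)), function(r) {
      tvals <- tp[[d$target_attribute[r]]]$values
      if (length(tvals) == 0 || length(svals) == 0) {
        return(0.5 * d$similarity[r])  # no enumerable values: damp phase-1 score
      }
      sim <- valueSimilarityMatrix(svals, tvals, method = valueMethod, methodArgs = args)
      mean(apply(sim, 1, max))
    }, numeric(1))
    ord <- order(-vscore, -d$similarity, d$target_attribute, method = "radix")
    k <- min(topK, nrow(d))
    data.frame(source_attribute = s,
               target_attribute = d$target_attribute[ord[seq_len(k)]],
               similarity = vscore[ord[seq_len(k)]], rank = seq_len(k),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[unique(r1$source_attribute)])
  rownames(out) <- NULL
  out
}

# --- chat-model matcher -------------------------------------------------------

.matchLlm <- function(source, schema, topK, args) {
  adapter <- if (is.null(args$adapter)) mockChatAdapter() else args$adapter
  sp <- .sourceValueProfile(source)
  tp <- .targetValueProfile(schema)
  tgt <- schema@attributes
  k <- min(topK, length(tgt))
  fallback <- function(msg) {
    warnHarmonizr("AdapterFallbackWarning",
                  sprintf("adapter failed (%s); falling back to composite_name", msg))
    .matchCompositeName(source, schema, topK, args)
  }
  rows <- list()
  for (s in columnNames(source)) {
    cands <- data.frame(
      name = tgt,
      context = vapply(tgt, function(a) {
        paste(attributeMetadata(schema, a)$description,
              paste(utils::head(tp[[a]]$values, 5L), collapse = " "))
      }, character(1)),
      stringsAsFactors = FALSE
    )
    query <- paste(s, paste(utils::head(sp[[s]]$values, 5L), collapse = " "))
    comp <- vapply(tgt, function(a) compositeNameScore(s, a), numeric(1))
    res <- tryCatch(selectCandidate(adapter, cands, query), error = function(e) e)
    if (inherits(res, "error")) return(fallback(conditionMessage(res)))
    if (!is.null(res) && !res$choice %in% tgt) res <- NULL  # out-of-set: rejected
    if (is.null(res)) {
      ord <- orderByScoreThenName(comp, tgt)[seq_len(k)]
      rows[[s]] <- data.frame(source_attribute = s, target_attribute = tgt[ord],
                              similarity = unname(comp[ord]), rank = seq_len(k),
                              stringsAsFactors = FALSE)
    } else {
      rest <- setdiff(tgt, res$choice)
      restSim <- pmin(comp[rest], res$confidence)
      ord <- orderByScoreThenName(restSim, rest)
      ordered <- c(res$choice, rest[ord])[seq_len(k)]
      sims <- c(res$confidence, unname(restSim[ord]))[seq_len(k)]
      rows[[s]] <- data.frame(source_attribute = s, target_attribute = ordered,
                              similarity = sims, rank = seq_len(k),
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# --- dispatch ----------------------------------------------------------------

.dispatchSchemaMethod <- function(method, source, schema, topK, args) {
  switch(method,
    composite_name = .matchCompositeName(source, schema, topK, args),
    similarity_flooding = .matchSimilarityFlooding(source, schema, topK, args),
    distribution_based = .matchDistributionBased(source, schema, topK, args),
    jaccard_distance = .matchJaccardLevenshtein(source, schema, topK, args),
    magneto_zs_bp = .matchMagnetoZs(source, schema, topK, args, reranker = "bp"),
    magneto_zs_llm = .matchMagnetoZs(source, schema, topK, args, reranker = "llm"),
    two_phase = .matchTwoPhase(source, schema, topK, args),
    max_val_sim = .matchMaxValSim(source, schema, topK, args),
    llm = .matchLlm(source, schema, topK, args),
    stopHarmonizr("UnknownMethodError",
                  sprintf("unknown schema-matching method '%s' (available: %s)",
                          method, paste(.schemaMethods, collapse = ", ")))
  )
}

#' Rank candidate schema matches
#'
#' For each source attribute, returns up to \code{topK} candidate target
#' attributes in descending similarity (lexicographic tie-break by target
#' attribute name).
#'
#' @param source A \linkS4class{HarmonTable}.
#' @param target A \linkS4class{HarmonTable}, \linkS4class{TargetSchema},
#'   \linkS4class{StandardModel}, or the name of a registered standard.
#' @param method One of \code{composite_name}, \code{similarity_flooding},
#'   \code{distribution_based}, \code{jaccard_distance},
#'   \code{magneto_zs_bp}, \code{magneto_zs_llm}, \code{two_phase},
#'   \code{max_val_sim}, \code{llm}.
#' @param topK Maximum candidates per source attribute (default 10).
#' @param methodArgs Named list of method arguments (e.g. \code{theta},
#'   \code{eps}, \code{max_iter}, \code{encoder}, \code{adapter},
#'   \code{phase1}, \code{phase2}, \code{value_method}, \code{prune_k},
#'   \code{candidate_k}).
#' @return data.frame with columns \code{source_attribute},
#'   \code{target_attribute}, \code{similarity}, \code{rank}.
#' @examples
#' src <- harmonTable(data.frame(Gender = c("Female", "Male")), "src")
#' rankSchemaMatches(src, "toy_cdm", method = "composite_name", topK = 3)
#' @export
rankSchemaMatches <- function(source, target, method = "magneto_zs_bp",
                              topK = 10L, methodArgs = list()) {
  stopifnot(is(source, "HarmonTable"))
  if (topK < 1) stopHarmonizr("UnknownMethodError", "topK must be >= 1")
  if (!method %in% .schemaMethods) {
    stopHarmonizr("UnknownMethodError",
                  sprintf("unknown schema-matching method '%s' (available: %s)",
                          method, paste(.schemaMethods, collapse = ", ")))
  }
  schema <- resolveTargetSchema(target)
  out <- .dispatchSchemaMethod(method, source, schema, as.integer(topK), methodArgs)
  out$similarity <- pmin(pmax(out$similarity, 0), 1)
  attr(out, "method") <- method
  out
}

#' Match a source table's schema against a target
#'
#' Returns exactly one match (the top-1 candidate) per source attribute.
#'
#' @inheritParams rankSchemaMatches
#' @return data.frame with columns \code{source_attribute},
#'   \code{target_attribute}, \code{similarity}; one row per source column.
#' @examples
#' src <- harmonTable(data.frame(Gender = c("Female", "Male")), "src")
#' matchSchema(src, "toy_cdm", method = "composite_name")
#' @export
matchSchema <- function(source, target, method = "magneto_zs_bp",
                        methodArgs = list()) {
  ranked <- rankSchemaMatches(source, target, method = method, topK = 1L,
                              methodArgs = methodArgs)
  out <- ranked[ranked$rank == 1L, c("source_attribute", "target_attribute", "similarity")]
  rownames(out) <- NULL
  attr(out, "method") <- method
  out
}
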