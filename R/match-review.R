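# Deterministic triage of schema and value matches into accept /
# needs_review / reject, each with the rule that fired and a templated
# explanation naming the evidence. An optional chat adapter may refine
# needs_review outcomes only: the offline rule core can never be overturned
# on its accept or reject decisions.

# Fraction of the smaller value set covered by the fuzzy intersection
# (greedy one-to-one Levenshtein pairing at threshold theta).
fuzzyValueOverlap <- function(a, b, theta = 0.2) {
  a <- unique(tolower(a)); b <- unique(tolower(b))
  if (length(a) == 0 || length(b) == 0) return(0)
  nrow(greedyFuzzyPairs(a, b, theta)) / min(length(a), length(b))
}

.reviewLabels <- c("accept", "needs_review", "reject")

#' Evaluate schema matches with the deterministic rule core
#'
#' Rules are applied in order; the first hit wins:
#' \describe{
#'   \item{R1}{normalized-name equality and (no enumerable values on either
#'     side, or case-insensitive value-set equality) — accept}
#'   \item{R2}{value sets equal after case/punctuation normalization — accept}
#'   \item{R3}{similarity >= 0.9 and fuzzy value overlap >= 0.5 — accept}
#'   \item{R4}{similarity < 0.4, or zero value overlap and zero name-token
#'     overlap — reject}
#'   \item{R5}{otherwise — needs_review}
#' }
#' An adapter, when present, may only refine R5 (needs_review) outcomes.
#'
#' @param source A \linkS4class{HarmonTable}.
#' @param target Target table/schema/standard.
#' @param matches data.frame with \code{source_attribute},
#'   \code{target_attribute} and optionally \code{similarity}.
#' @param adapter Optional \linkS4class{ChatAdapter}.
#' @return data.frame with columns \code{source_attribute},
#'   \code{target_attribute}, \code{similarity}, \code{label},
#'   \code{rule_id}, \code{explanation}.
#' @export
evaluateSchemaMatches <- function(source, target, matches, adapter = NULL) {
  schema <- resolveTargetSchema(target)
  matches <- .resolvePairs(source, schema, matches)
  rows <- lapply(seq_len(nrow(matches)), function(r) {
    sa <- matches$source_attribute[r]
    ta <- matches$target_attribute[r]
    sim <- if ("similarity" %in% colnames(matches)) matches$similarity[r] else NA_real_
    svals <- distinctValues(source, sa)
    tvals <- permissibleValues(schema, ta)
    nameEq <- normalizeLabel(sa) == normalizeLabel(ta)
    valueSetEqCI <- length(svals) > 0 && length(tvals) > 0 &&
      setequal(tolower(svals), tolower(tvals))
    valueSetEqNorm <- length(svals) > 0 && length(tvals) > 0 &&
      setequal(normalizeLabel(svals), normalizeLabel(tvals))
    overlap <- fuzzyValueOverlap(svals, tvals)
    tokOverlap <- length(intersect(tokenizeName(sa), tokenizeName(ta)))

    if (nameEq && (length(svals) == 0 || length(tvals) == 0 || valueSetEqCI)) {
      label <- "accept"; rule <- "R1"
      expl <- sprintf("names '%s' and '%s' are identical after normalization%s",
                      sa, ta,
                      if (valueSetEqCI) " and their value sets agree (case-insensitive)" else "")
    } else if (valueSetEqNorm) {
      label <- "accept"; rule <- "R2"
      expl <- sprintf("the value sets of '%s' and '%s' are identical after case and punctuation normalization (e.g. '%s' ~ '%s')",
                      sa, ta, svals[1], tvals[1])
    } else if (!is.na(sim) && sim >= 0.9 && overlap >= 0.5) {
      label <- "accept"; rule <- "R3"
      expl <- sprintf("similarity %.3f >= 0.9 and %.0f%% of values have close counterparts",
                      sim, 100 * overlap)
    } else if ((!is.na(sim) && sim < 0.4) || (overlap == 0 && tokOverlap == 0)) {
      label <- "reject"; rule <- "R4"
      expl <- if (!is.na(sim) && sim < 0.4) {
        sprintf("similarity %.3f < 0.4", sim)
      } else {
        sprintf("'%s' and '%s' share no name tokens and none of their values are close",
                sa, ta)
      }
    } else {
      label <- "needs_review"; rule <- "R5"
      expl <- sprintf("inconclusive evidence for '%s' -> '%s' (similarity %s, value overlap %.0f%%); human review recommended",
                      sa, ta, if (is.na(sim)) "unknown" else sprintf("%.3f", sim),
                      100 * overlap)
    }
    if (label == "needs_review" && !is.null(adapter)) {
      res <- tryCatch(
        selectCandidate(adapter,
                        data.frame(name = .reviewLabels, stringsAsFactors = FALSE),
                        paste(sa, ta, paste(utils::head(svals, 5), collapse = " "))),
        error = function(e) NULL)
      if (!is.null(res) && res$choice %in% .reviewLabels) {
        label <- res$choice
        rule <- "R5-adapter"
        expl <- sprintf("escalated to adapter, which chose '%s' (confidence %.2f)",
                        label, res$confidence)
      }
    }
    data.frame(source_attribute = sa, target_attribute = ta, similarity = sim,
               label = label, rule_id = rule, explanation = expl,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Evaluate value matches with the deterministic rule core
#'
#' Per matched value: a proposed target outside the permissible set is
#' rejected (\code{out-of-domain}); equality after normalization accepts;
#' similarity >= 0.8 accepts; similarity < 0.4 rejects; anything in between
#' needs review.
#'
#' @param valueMatches data.frame from \code{\link{matchValues}} (unmatched
#'   rows are skipped).
#' @param target Target table/schema/standard providing the permissible
#'   values.
#' @return data.frame with columns \code{source_attribute},
#'   \code{target_attribute}, \code{source_value}, \code{target_value},
#'   \code{similarity}, \code{label}, \code{rule_id}, \code{explanation}.
#' @export
evaluateValueMatches <- function(valueMatches, target) {
  schema <- resolveTargetSchema(target)
  vm <- valueMatches[!is.na(valueMatches$target_value), , drop = FALSE]
  rows <- lapply(seq_len(nrow(vm)), function(r) {
    sv <- vm$source_value[r]; tv <- vm$target_value[r]
    sim <- vm$similarity[r]
    pv <- permissibleValues(schema, vm$target_attribute[r])
    if (length(pv) > 0 && !tv %in% pv) {
      label <- "reject"; rule <- "out-of-domain"
      expl <- sprintf("'%s' is not a permissible value of '%s'", tv,
                      vm$target_attribute[r])
    } else if (normalizeLabel(sv) == normalizeLabel(tv)) {
      label <- "accept"; rule <- "V1"
      expl <- sprintf("'%s' and '%s' are identical after normalization", sv, tv)
    } else if (!is.na(sim) && sim >= 0.8) {
      label <- "accept"; rule <- "V2"
      expl <- sprintf("similarity %.3f >= 0.8 between '%s' and '%s'", sim, sv, tv)
    } else if (!is.na(sim) && sim < 0.4) {
      label <- "reject"; rule <- "V3"
      expl <- sprintf("similarity %.3f < 0.4 between '%s' and '%s'", sim, sv, tv)
    } else {
      label <- "needs_review"; rule <- "V4"
      expl <- sprintf("'%s' -> '%s' has intermediate similarity %s; human review recommended",
                      sv, tv, if (is.na(sim)) "unknown" else sprintf("%.3f", sim))
    }
    data.frame(source_attribute = vm$source_attribute[r],
               target_attribute = vm$target_attribute[r],
               source_value = sv, target_value = tv, similarity = sim,
               label = label, rule_id = rule, explanation = expl,
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0) {
    return(data.frame(source_attribute = character(0), target_attribute = character(0),
                      source_value = character(0), target_value = character(0),
                      similarity = numeric(0), label = character(0),
                      rule_id = character(0), explanation = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
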