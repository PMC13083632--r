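# Deterministic offline model backends. The hash encoder and the mock chat
# adapter are the defaults everywhere; pretrained encoders or hosted models
# are drop-in replacements behind the same contracts (configuration, not
# code).

# Stable polynomial string hashes over UTF-8 bytes. Doubles are exact below
# 2^53, so the modular arithmetic is platform-independent. Version-pinned:
# changing these constants changes every stored vector.
.hashBucket <- function(s, modulo) {
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  h %% modulo
}

.hashSign <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) h <- (h * 137 + b) %% 2147483629
  if (h %% 2 == 0) 1 else -1
}

#' Create a signed feature-hashing text encoder
#'
#' Character 3-gram counts (case-folded, \code{"#"}-padded) are hashed into
#' \code{dimension} buckets with a sign drawn from a second hash (signed
#' hashing reduces collision bias); the resulting vector is L2-normalized.
#' Seedless and stable across runs and platforms.
#'
#' @param dimension Number of hash buckets (>= 16; default 512).
#' @return A \linkS4class{HashTextEncoder}.
#' @examples
#' enc <- hashEncoder()
#' v <- encodeText(enc, c("gender", "Gender"))
#' all.equal(v[1, ], v[2, ])  # case folding
#' @export
hashEncoder <- function(dimension = 512L) {
  new("HashTextEncoder", name = "hash", dimension = as.integer(dimension))
}

#' @describeIn hashEncoder Encode texts; one unit-norm row per text.
#' @param encoder A \linkS4class{HashTextEncoder}.
#' @param texts Character vector.
#' @export
setMethod("encodeText", "HashTextEncoder", function(encoder, texts) {
  d <- encoder@dimension
  out <- matrix(0, nrow = length(texts), ncol = d)
  for (i in seq_along(texts)) {
    grams <- characterTrigrams(texts[i])
    v <- numeric(d)
    for (g in grams) {
      j <- .hashBucket(g, d) + 1L
      v[j] <- v[j] + .hashSign(g)
    }
    nrm <- sqrt(sum(v^2))
    if (nrm > 0) v <- v / nrm
    out[i, ] <- v
  }
  rownames(out) <- names(texts)
  out
})

#' Create the deterministic mock chat adapter
#'
#' Selects the candidate whose name and context share the largest fraction
#' of query tokens; confidence is that overlap fraction; abstains when no
#' candidate overlaps. Token-overlap ties are resolved by the character
#' 3-gram cosine between the query and the candidate name, and remaining
#' ties go to the lexicographically smallest candidate name.
#'
#' @return A \linkS4class{MockChatAdapter}.
#' @export
mockChatAdapter <- function() {
  new("MockChatAdapter", name = "mock", modelId = "token-overlap")
}

#' @describeIn mockChatAdapter Candidate selection by token overlap.
#' @param adapter A \linkS4class{MockChatAdapter}.
#' @param candidates data.frame with columns \code{name} and optionally
#'   \code{context}.
#' @param query Character context.
#' @export
setMethod("selectCandidate", "MockChatAdapter", function(adapter, candidates, query) {
  stopifnot(nrow(candidates) >= 1)
  qtok <- unique(unlist(lapply(query, tokenizeName)))
  if (length(qtok) == 0) return(NULL)
  ov <- vapply(seq_len(nrow(candidates)), function(i) {
    ctok <- unique(c(tokenizeName(candidates$name[i]),
                     if (!is.null(candidates$context)) tokenizeName(candidates$context[i])))
    length(intersect(qtok, ctok)) / length(qtok)
  }, numeric(1))
  if (max(ov) == 0) return(NULL)
  tri <- vapply(candidates$name, function(nm) trigramCosine(query, nm), numeric(1))
  ord <- order(-ov, -tri, candidates$name, method = "radix")
  list(choice = candidates$name[ord[1]], confidence = ov[ord[1]])
})
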