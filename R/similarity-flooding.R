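# Similarity flooding over flat table schemas. Each schema becomes a small
# directed graph (schema node -> column nodes, labeled "column"; column node
# -> kind node, labeled "kind"). The pairwise-connectivity graph pairs up
# same-labeled edges of the two graphs; similarity is propagated along it
# until the iterates stabilize, then normalized by the maximum ("basic"
# fixpoint formula).

.schemaGraph <- function(names, kinds) {
  # edges: from, to, label
  data.frame(
    from = c(rep("#schema#", length(names)), names),
    to = c(names, paste0("kind:", kinds)),
    label = c(rep("column", length(names)), rep("kind", length(names))),
    stringsAsFactors = FALSE
  )
}

# Core fixpoint. Returns the sigma matrix over (source column, target column)
# pairs. eps = Inf performs zero iterations (initial map).
floodSimilarity <- function(sourceNames, sourceKinds, targetNames, targetKinds,
                            eps = 1e-4, maxIter = 100L) {
  gs <- .schemaGraph(sourceNames, sourceKinds)
  gt <- .schemaGraph(targetNames, targetKinds)

  # pairwise-connectivity graph: pair same-labeled edges
  pcgFrom <- character(0); pcgTo <- character(0); pcgLabel <- character(0)
  for (i in seq_len(nrow(gs))) {
    same <- which(gt$label == gs$label[i])
    for (j in same) {
      pcgFrom <- c(pcgFrom, paste0(gs$from[i], "\r", gt$from[j]))
      pcgTo <- c(pcgTo, paste0(gs$to[i], "\r", gt$to[j]))
      pcgLabel <- c(pcgLabel, gs$label[i])
    }
  }
  nodes <- unique(c(pcgFrom, pcgTo))
  idx <- stats::setNames(seq_along(nodes), nodes)

  # propagation matrix: forward and backward edges, coefficient 1/out-degree
  # per (node, label, direction)
  n <- length(nodes)
  P <- matrix(0, n, n)  # P[p, q]: weight of edge q -> p
  addEdges <- function(from, to, label) {
    key <- paste0(from, "\r\r", label)
    deg <- table(key)
    w <- 1 / as.numeric(deg[key])
    for (k in seq_along(from)) {
      P[idx[[to[k]]], idx[[from[k]]]] <<- P[idx[[to[k]]], idx[[from[k]]]] + w[k]
    }
  }
  addEdges(pcgFrom, pcgTo, pcgLabel)           # forward
  addEdges(pcgTo, pcgFrom, paste0("b:", pcgLabel))  # backward

  # initial similarity
  sigma <- numeric(n)
  for (k in seq_len(n)) {
    parts <- strsplit(nodes[k], "\r", fixed = TRUE)[[1]]
    a <- parts[1]; b <- parts[2]
    sigma[k] <- if (a == "#schema#" || b == "#schema#") {
      if (a == b) 1 else 0
    } else if (startsWith(a, "kind:") || startsWith(b, "kind:")) {
      if (a == b) 1 else 0
    } else {
      compositeNameScore(a, b)
    }
  }
  if (max(sigma) > 0) sigma <- sigma / max(sigma)

  converged <- is.infinite(eps)
  if (!is.infinite(eps)) {
    for (iter in seq_len(maxIter)) {
      nxt <- sigma + as.vector(P %*% sigma)
      m <- max(nxt)
      if (m > 0) nxt <- nxt / m
      delta <- max(abs(nxt - sigma))
      sigma <- nxt
      if (delta < eps) {
        converged <- TRUE
        break
      }
    }
    if (!converged) {
      warnHarmonizr("NonConvergenceWarning",
                    sprintf("similarity flooding did not converge in %d iterations", maxIter))
    }
  }

  out <- matrix(0, length(sourceNames), length(targetNames),
                dimnames = list(sourceNames, targetNames))
  for (i in seq_along(sourceNames)) {
    for (j in seq_along(targetNames)) {
      key <- paste0(sourceNames[i], "\r", targetNames[j])
      if (key %in% nodes) out[i, j] <- sigma[idx[[key]]]
    }
  }
  pmin(pmax(out, 0), 1)
}
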