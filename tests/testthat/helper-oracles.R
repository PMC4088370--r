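# Independent oracles and fixture builders. These deliberately share no code
# with the package: distances come from a Floyd-Warshall dynamic programme,
# hypergeometric tail probabilities from explicit enumeration of draws.

# all-pairs shortest-path matrix by Floyd-Warshall; Inf = unreachable
fwDistances <- function(net) {
  nodes <- netNodes(net)
  n <- length(nodes)
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(D) <- 0
  e <- netEdges(net)
  if (nrow(e)) {
    i <- match(e[, 1], nodes); j <- match(e[, 2], nodes)
    D[cbind(i, j)] <- 1; D[cbind(j, i)] <- 1
  }
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], `+`))
  D
}

# oracle eccentricity of every node, over its own component
fwEccentricities <- function(D) {
  apply(D, 1, function(row) max(row[is.finite(row)]))
}

# oracle centre set + radius over the largest component (ties to the
# component with the lexicographically smallest node, as in the package)
fwCentre <- function(D) {
  comp <- fwComponents(D)
  sizes <- table(comp)
  biggest <- names(sizes)[sizes == max(sizes)]
  pick <- min(vapply(biggest, function(b) min(which(comp == b)), integer(1)))
  inLcc <- comp == comp[pick]
  ecc <- fwEccentricities(D)[inLcc]
  list(centres = sort(names(ecc)[ecc == min(ecc)]),
       radius = as.integer(min(ecc)),
       diameter = as.integer(max(ecc)))
}

fwComponents <- function(D) {
  n <- nrow(D)
  comp <- integer(n)
  k <- 0L
  for (v in seq_len(n)) if (comp[v] == 0L) {
    k <- k + 1L
    comp[is.finite(D[v, ])] <- k
  }
  comp
}

# Erdos-Renyi style random simple graph over letter-number node IDs
randomNetwork <- function(n, p, ensureEdge = TRUE) {
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < p
  if (ensureEdge && !any(keep)) keep[sample(nrow(pairs), 1)] <- TRUE
  PINetwork(pairs[keep, , drop = FALSE], nodes = nodes, quiet = TRUE)
}

# exact upper-tail hypergeometric P(X >= q) by enumerating all C(N, n) draws
bruteHypergeom <- function(N, K, n, q) {
  draws <- combn(N, n)
  hits <- colSums(draws <= K)  # successes are items 1..K
  mean(hits >= q)
}

writeTempLines <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
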