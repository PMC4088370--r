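# Metric-space model of a PIN: hop-count shortest paths, eccentricity,
# topological centre, zone partition, per-zone graph metrics.
#
# The graph metric is unweighted hop count; all distances are breadth-first.
# Eccentricity and the centre are computed over the largest connected
# component only, because "zones around the centre" can only cover nodes
# with a finite distance to it; smaller components are reported as
# unreachable.

# adjacency as a list of integer neighbour indices, one entry per node
.adjacency <- function(net) {
  n <- length(net@nodes)
  e <- net@edges
  if (!nrow(e)) {
    return(split(integer(0), factor(integer(0), levels = seq_len(n))))
  }
  i <- match(e[, 1L], net@nodes)
  j <- match(e[, 2L], net@nodes)
  split(c(j, i), factor(c(i, j), levels = seq_len(n)))
}

# breadth-first distances from (possibly several) source indices;
# NA for unreachable nodes
.bfs <- function(adj, src) {
  n <- length(adj)
  dist <- rep(NA_integer_, n)
  dist[src] <- 0L
  frontier <- src
  d <- 0L
  while (length(frontier)) {
    nb <- unique(unlist(adj[frontier], use.names = FALSE))
    nb <- nb[is.na(dist[nb])]
    if (!length(nb)) break
    d <- d + 1L
    dist[nb] <- d
    frontier <- nb
  }
  dist
}

# connected component label per node
.components <- function(adj) {
  n <- length(adj)
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (v in seq_len(n)) {
    if (is.na(comp[v])) {
      k <- k + 1L
      comp[!is.na(.bfs(adj, v))] <- k
    }
  }
  comp
}

# indices of the largest connected component; ties broken towards the
# component containing the lexicographically smallest node ID (determinism)
.largestComponent <- function(net, adj) {
  comp <- .components(adj)
  sizes <- tabulate(comp)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    firstNode <- vapply(best, function(k) min(which(comp == k)), integer(1))
    best <- best[which.min(firstNode)]  # nodes are sorted, so index order = lexicographic
  }
  which(comp == best)
}

#' Breadth-first shortest-path distances from one protein
#'
#' Hop-count distances from \code{source} to every reachable node: the
#' smallest number of interactions that must be traversed. Unreachable nodes
#' are absent from the result.
#'
#' @param net a [PINetwork-class].
#' @param source a node ID present in the network.
#' @return named integer vector of distances; \code{result[source] == 0}.
#' @export
#' @examples
#' net <- readEdgeListString("A\tB\nB\tC\nC\tD\nD\tE")
#' shortestPathLengths(net, "C")
shortestPathLengths <- function(net, source) {
  idx <- match(source, net@nodes)
  if (length(source) != 1L || is.na(idx))
    stop("unknown source node: ", paste(source, collapse = ", "))
  d <- .bfs(.adjacency(net), idx)
  names(d) <- net@nodes
  d[!is.na(d)]
}

#' Eccentricity of a node
#'
#' The maximum shortest-path distance from \code{node} to any node in its
#' connected component. An isolated node has eccentricity 0.
#'
#' @inheritParams shortestPathLengths
#' @param node a node ID present in the network.
#' @return integer eccentricity.
#' @export
eccentricity <- function(net, node) {
  idx <- match(node, net@nodes)
  if (length(node) != 1L || is.na(idx))
    stop("unknown node: ", paste(node, collapse = ", "))
  d <- .bfs(.adjacency(net), idx)
  max(d, 0L, na.rm = TRUE)
}

#' Find the topological centre of a network
#'
#' The centre is the set of proteins minimising eccentricity over the
#' largest connected component, i.e. those with the smallest maximal
#' distance to other proteins. The centre is defined purely metrically and
#' is not assumed to be the highest-degree node. All tied minimisers are
#' returned; the minimum eccentricity is the network radius.
#'
#' @inheritParams shortestPathLengths
#' @return list with elements \code{centres} (character, sorted),
#'   \code{radius} (integer) and \code{eccentricities} (named integer vector
#'   over the largest component).
#' @export
#' @examples
#' net <- readEdgeListString("A\tB\nB\tC\nC\tD\nD\tE")
#' findCentre(net)$centres  # "C"
findCentre <- function(net) {
  if (!length(net@nodes)) stop("cannot find the centre of an empty network")
  adj <- .adjacency(net)
  lcc <- .largestComponent(net, adj)
  ecc <- vapply(lcc, function(v) {
    d <- .bfs(adj, v)
    max(d, 0L, na.rm = TRUE)
  }, integer(1))
  names(ecc) <- net@nodes[lcc]
  r <- min(ecc)
  list(centres = sort(names(ecc)[ecc == r]),
       radius = as.integer(r),
       eccentricities = ecc)
}

#' Partition proteins into zones by distance from the centre
#'
#' Zone k is the set of nodes at shortest-path distance exactly k from the
#' nearest centre (minimum over the centre set when the centre is tied).
#' Zone 1 proteins interact directly with the centre; zone 2 proteins
#' interact with at least one zone 1 protein but not the centre, and so on.
#' Nodes with no path to any centre are reported as unreachable, not zoned.
#'
#' @inheritParams shortestPathLengths
#' @param centres optional character vector of centre node IDs; when
#'   omitted, [findCentre()] is used.
#' @return a [ZoneDecomposition-class].
#' @export
#' @examples
#' net <- readEdgeListString("A\tB\nB\tC\nC\tD\nD\tE")
#' zonePartition(net)
zonePartition <- function(net, centres = NULL) {
  if (!length(net@nodes)) stop("cannot decompose an empty network")
  adj <- .adjacency(net)
  fc <- NULL
  if (is.null(centres)) {
    fc <- findCentre(net)
    centres <- fc$centres
  }
  idx <- match(centres, net@nodes)
  if (!length(idx) || anyNA(idx))
    stop("centre node(s) not in the network: ",
         paste(centres[is.na(idx)], collapse = ", "))
  d <- .bfs(adj, idx)
  reach <- !is.na(d)
  zoneOf <- setNames(d[reach], net@nodes[reach])
  unreachable <- net@nodes[!reach]
  radius <- max(zoneOf)

  # diameter of the centre's component
  if (!is.null(fc)) {
    diam <- max(fc$eccentricities)
  } else {
    ridx <- which(reach)
    diam <- max(vapply(ridx, function(v) {
      dv <- .bfs(adj, v)
      max(dv, 0L, na.rm = TRUE)
    }, integer(1)))
  }

  # zone-adjacency invariant: every zone-k node (k >= 1) has a neighbour at
  # zone k-1 -- automatic for BFS layers, asserted defensively
  if (any(zoneOf >= 1L)) {
    nidx <- match(names(zoneOf), net@nodes)
    bad <- vapply(seq_along(zoneOf), function(i) {
      k <- zoneOf[i]
      if (k == 0L) return(FALSE)
      !any(d[adj[[nidx[i]]]] == k - 1L, na.rm = TRUE)
    }, logical(1))
    if (any(bad))
      stop("internal error: zone-adjacency invariant violated for ",
           paste(names(zoneOf)[bad], collapse = ", "))
  }

  new("ZoneDecomposition",
      centres = sort(centres),
      zoneOf = zoneOf,
      radius = as.integer(radius),
      diameter = as.integer(diam),
      unreachable = unreachable)
}

#' Network diameter
#'
#' Maximum eccentricity over the largest connected component.
#'
#' @inheritParams shortestPathLengths
#' @return integer diameter.
#' @export
networkDiameter <- function(net) {
  if (!length(net@nodes)) stop("cannot compute the diameter of an empty network")
  adj <- .adjacency(net)
  lcc <- .largestComponent(net, adj)
  max(vapply(lcc, function(v) {
    d <- .bfs(adj, v)
    max(d, 0L, na.rm = TRUE)
  }, integer(1)))
}

#' Per-zone graph metrics
#'
#' One row per non-empty zone index >= 1: node count, average degree (one
#' decimal, rounded half away from zero), minimum and maximum degree, and
#' the number of quills (degree-1 nodes). Degrees are degrees in the FULL
#' network, not in the zone-induced subgraph. The centre (zone 0) is
#' reported separately via \code{includeCentre = TRUE}, matching the
#' convention that centre proteins are named rather than counted in zones.
#'
#' @inheritParams shortestPathLengths
#' @param decomposition a [ZoneDecomposition-class] computed on \code{net}.
#' @param includeCentre also emit the zone 0 row.
#' @return data.frame with columns \code{zone}, \code{nodes},
#'   \code{aveDegree}, \code{minDegree}, \code{maxDegree}, \code{quills}.
#' @export
zoneMetrics <- function(net, decomposition, includeCentre = FALSE) {
  stopifnot(is(decomposition, "ZoneDecomposition"))
  z <- zoneOf(decomposition)
  if (!all(names(z) %in% net@nodes))
    stop("decomposition refers to nodes absent from the network")
  deg <- nodeDegree(net)[names(z)]
  lo <- if (includeCentre) 0L else 1L
  ks <- sort(unique(z[z >= lo]))
  if (!length(ks))
    return(data.frame(zone = integer(0), nodes = integer(0),
                      aveDegree = numeric(0), minDegree = integer(0),
                      maxDegree = integer(0), quills = integer(0)))
  rows <- lapply(ks, function(k) {
    dk <- deg[z == k]
    data.frame(zone = as.integer(k),
               nodes = length(dk),
               aveDegree = roundHalfAway(mean(dk), 1L),
               minDegree = as.integer(min(dk)),
               maxDegree = as.integer(max(dk)),
               quills = sum(dk == 1L))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Write a zone metrics table as TSV
#'
#' Mirrors the row/column layout of a per-zone graph metrics table (zone
#' index, nodes, average/min/max degree, quills), preceded by comment lines
#' recording the centre ID(s), radius and diameter.
#'
#' @param metrics data.frame from [zoneMetrics()].
#' @param decomposition the [ZoneDecomposition-class] the metrics came from.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeZoneMetrics <- function(metrics, decomposition, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# centre: ", paste(centres(decomposition), collapse = ",")),
    paste0("# radius: ", radiusOf(decomposition)),
    paste0("# diameter: ", diameterOf(decomposition))), con)
  utils::write.table(metrics, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
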