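#' @import methods
NULL

# ---------------------------------------------------------------------------
# PINetwork: a simple undirected graph over string node IDs
# ---------------------------------------------------------------------------

#' PINetwork: an undirected protein interaction network
#'
#' A simple (no self-loops, no multi-edges) undirected graph whose nodes are
#' gene-symbol strings. Edges are stored canonically: each row of the edge
#' matrix satisfies \code{edge[1] < edge[2]} and rows are unique and sorted,
#' so two networks with the same interactions are identical objects.
#'
#' @slot nodes character vector of unique node IDs (sorted).
#' @slot edges two-column character matrix of canonical unordered pairs.
#'
#' @seealso [PINetwork()] the constructor, [readEdgeList()], [mergeNetworks()]
#' @name PINetwork-class
#' @aliases PINetwork-class
#' @exportClass PINetwork
setClass("PINetwork",
  slots = c(nodes = "character", edges = "matrix"),
  prototype = prototype(
    nodes = character(0),
    edges = matrix(character(0), ncol = 2,
                   dimnames = list(NULL, c("from", "to")))
  )
)

setValidity("PINetwork", function(object) {
  e <- object@edges
  msgs <- character(0)
  if (!is.character(e) || ncol(e) != 2L)
    return("edges must be a two-column character matrix")
  if (anyDuplicated(object@nodes))
    msgs <- c(msgs, "node IDs must be unique")
  if (nrow(e)) {
    if (any(e[, 1L] == e[, 2L]))
      msgs <- c(msgs, "self-loops are not allowed")
    if (any(e[, 1L] > e[, 2L]))
      msgs <- c(msgs, "edges must be canonically ordered (from < to)")
    if (anyDuplicated(paste(e[, 1L], e[, 2L], sep = "\r")))
      msgs <- c(msgs, "duplicate edges are not allowed")
    if (!all(c(e) %in% object@nodes))
      msgs <- c(msgs, "every edge endpoint must be a known node")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a PINetwork
#'
#' Canonicalises the input: self-loops are dropped and duplicate edges
#' (including reversed duplicates, \code{A-B} vs \code{B-A}) are collapsed,
#' each with a logged count. Node IDs are exact strings; no case folding or
#' alias resolution is performed, because any symbol normalisation would
#' silently change zone counts.
#'
#' @param edges two-column character matrix or data.frame of interactions
#'   (may be empty).
#' @param nodes optional additional node IDs (e.g. isolated nodes).
#' @param quiet suppress cleaning messages.
#' @return a [PINetwork-class] object.
#' @export
#' @examples
#' net <- PINetwork(cbind(c("A", "B", "C"), c("B", "C", "A")))
#' numNodes(net); numEdges(net)
PINetwork <- function(edges = NULL, nodes = NULL, quiet = FALSE) {
  if (is.null(edges)) {
    e <- matrix(character(0), ncol = 2)
  } else {
    e <- as.matrix(edges)
    if (length(e) == 0L) e <- matrix(character(0), ncol = 2)
    if (ncol(e) != 2L) stop("'edges' must have exactly two columns")
    storage.mode(e) <- "character"
  }
  nSelf <- 0L; nDup <- 0L
  if (nrow(e)) {
    self <- e[, 1L] == e[, 2L]
    nSelf <- sum(self)
    e <- e[!self, , drop = FALSE]
    if (nrow(e)) {
      e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
      key <- paste(e[, 1L], e[, 2L], sep = "\r")
      dup <- duplicated(key)
      nDup <- sum(dup)
      e <- e[!dup, , drop = FALSE]
      e <- e[order(e[, 1L], e[, 2L]), , drop = FALSE]
    }
  }
  if (!quiet && nSelf > 0L) .logmsg("dropped ", nSelf, " self-loop(s)")
  if (!quiet && nDup > 0L)  .logmsg("collapsed ", nDup, " duplicate edge(s)")
  allNodes <- sort(unique(c(as.character(nodes), c(e))))
  dimnames(e) <- list(NULL, c("from", "to"))
  new("PINetwork", nodes = allNodes, edges = e)
}

# ---------------------------------------------------------------------------
# ZoneDecomposition
# ---------------------------------------------------------------------------

#' ZoneDecomposition: nodes classified by distance from the network centre
#'
#' The result of [zonePartition()]. Zone 0 is the centre set itself; zone k
#' contains the nodes at shortest-path distance exactly k from the nearest
#' centre. Nodes with no path to any centre are listed in \code{unreachable}
#' and carry no zone index.
#'
#' @slot centres character vector of centre node IDs (all eccentricity
#'   minimisers when computed by [findCentre()]).
#' @slot zoneOf named integer vector: distance from the nearest centre for
#'   every reachable node (centres included at 0).
#' @slot radius integer, the centre's eccentricity (= max zone index).
#' @slot diameter integer, max eccentricity over the centre's component.
#' @slot unreachable character vector of nodes outside the centre's
#'   component.
#'
#' @name ZoneDecomposition-class
#' @aliases ZoneDecomposition-class
#' @exportClass ZoneDecomposition
setClass("ZoneDecomposition",
  slots = c(centres = "character", zoneOf = "integer",
            radius = "integer", diameter = "integer",
            unreachable = "character"),
  prototype = prototype(centres = character(0),
                        zoneOf = setNames(integer(0), character(0)),
                        radius = 0L, diameter = 0L,
                        unreachable = character(0))
)

setValidity("ZoneDecomposition", function(object) {
  z <- object@zoneOf
  msgs <- character(0)
  if (length(z) && is.null(names(z)))
    return("zoneOf must be a named integer vector")
  if (length(object@centres)) {
    if (!all(object@centres %in% names(z)))
      msgs <- c(msgs, "every centre must appear in zoneOf")
    else if (any(z[object@centres] != 0L))
      msgs <- c(msgs, "centres must be at zone 0")
  }
  if (length(z)) {
    if (any(z < 0L)) msgs <- c(msgs, "zone indices must be non-negative")
    if (max(z) != object@radius)
      msgs <- c(msgs, "radius must equal the maximum zone index")
  }
  if (length(z) > length(object@centres)) {
    if (object@diameter < object@radius)
      msgs <- c(msgs, "must have radius <= diameter")
    # the triangle-inequality upper bound d(u,v) <= d(u,c) + d(c,v) needs a
    # common centre c, so it only constrains single-centre decompositions
    if (length(object@centres) == 1L &&
        object@diameter > 2L * object@radius)
      msgs <- c(msgs, "single-centre decompositions must have diameter <= 2*radius")
  }
  if (any(object@unreachable %in% names(z)))
    msgs <- c(msgs, "unreachable nodes cannot carry a zone index")
  if (length(msgs)) msgs else TRUE
})

# ---------------------------------------------------------------------------
# AnnotationSet / ConsistentGeneSet
# ---------------------------------------------------------------------------

#' AnnotationSet: a named set of gene IDs
#'
#' A gene list such as "essential genes" or "approved drug targets".
#' Members may include IDs absent from a given network; those are ignored
#' (and counted) when the set is mapped onto zones.
#'
#' @slot name set name.
#' @slot members unique gene IDs.
#' @name AnnotationSet-class
#' @aliases AnnotationSet-class
#' @exportClass AnnotationSet
setClass("AnnotationSet",
  slots = c(name = "character", members = "character"),
  prototype = prototype(name = NA_character_, members = character(0))
)

setValidity("AnnotationSet", function(object) {
  if (length(object@name) != 1L) return("name must be a single string")
  if (anyDuplicated(object@members)) return("members must be unique")
  TRUE
})

#' @rdname AnnotationSet-class
#' @param name set name (single string).
#' @param members character vector of gene IDs; duplicates are collapsed.
#' @return an \code{AnnotationSet}.
#' @export
#' @examples
#' AnnotationSet("essential", c("TP53", "MYC", "TP53"))
AnnotationSet <- function(name, members = character(0)) {
  new("AnnotationSet", name = as.character(name),
      members = unique(as.character(members)))
}

#' ConsistentGeneSet: genes expressed in at least a threshold fraction of
#' samples
#'
#' An [AnnotationSet-class] produced by [filterConsistentGenes()], carrying
#' the presence-fraction threshold that defined it (the consistent-expression
#' filter, default 0.99).
#'
#' @slot threshold presence fraction in (0, 1].
#' @name ConsistentGeneSet-class
#' @aliases ConsistentGeneSet-class
#' @exportClass ConsistentGeneSet
setClass("ConsistentGeneSet",
  contains = "AnnotationSet",
  slots = c(threshold = "numeric"),
  prototype = prototype(threshold = 0.99)
)

setValidity("ConsistentGeneSet", function(object) {
  if (length(object@threshold) != 1L ||
      object@threshold <= 0 || object@threshold > 1)
    return("threshold must be a single value in (0, 1]")
  TRUE
})

# ---------------------------------------------------------------------------
# PresenceMatrix
# ---------------------------------------------------------------------------

#' PresenceMatrix: binary gene-by-sample expression calls
#'
#' Gene Expression Barcode style absence/presence calls: a 0/1 matrix with
#' unique gene IDs as row names and sample IDs as column names.
#'
#' @slot calls integer matrix of 0/1 calls, dimnames = (genes, samples).
#' @name PresenceMatrix-class
#' @aliases PresenceMatrix-class
#' @exportClass PresenceMatrix
setClass("PresenceMatrix", slots = c(calls = "matrix"))

setValidity("PresenceMatrix", function(object) {
  m <- object@calls
  if (!is.numeric(m)) return("calls must be numeric 0/1")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("calls must have gene row names and sample column names")
  if (anyDuplicated(rownames(m))) return("gene IDs must be unique")
  if (length(m) && !all(m %in% c(0L, 1L)))
    return("calls must contain only 0 and 1")
  TRUE
})

#' @rdname PresenceMatrix-class
#' @param calls 0/1 matrix with gene row names and sample column names.
#' @return a \code{PresenceMatrix}.
#' @export
PresenceMatrix <- function(calls) {
  storage.mode(calls) <- "integer"
  new("PresenceMatrix", calls = calls)
}

# ---------------------------------------------------------------------------
# ProportionTestResult
# ---------------------------------------------------------------------------

#' ProportionTestResult: a pooled two-proportion z-test
#'
#' Result of [twoProportionZ()]. The pooled standard error uses
#' \eqn{\hat p = (x_1 + x_2)/(n_1 + n_2)} and
#' \eqn{z = (p_1 - p_2)/\sqrt{\hat p (1-\hat p)(1/n_1 + 1/n_2)}}.
#'
#' @slot count1,n1,count2,n2 the two counts and sample sizes.
#' @slot p1,p2,pooled the sample proportions and pooled proportion.
#' @slot z the standardised test statistic (sign matches p1 - p2).
#' @slot pValue the p-value under the standard normal.
#' @slot alpha significance level (default 0.01).
#' @slot significant \code{pValue < alpha}.
#' @slot alternative "two.sided", "greater" or "less".
#' @slot label optional label (e.g. "zone1 vs zone2").
#' @name ProportionTestResult-class
#' @aliases ProportionTestResult-class
#' @exportClass ProportionTestResult
setClass("ProportionTestResult",
  slots = c(count1 = "numeric", n1 = "numeric",
            count2 = "numeric", n2 = "numeric",
            p1 = "numeric", p2 = "numeric", pooled = "numeric",
            z = "numeric", pValue = "numeric", alpha = "numeric",
            significant = "logical", alternative = "character",
            label = "character"),
  prototype = prototype(alpha = 0.01, alternative = "two.sided",
                        label = NA_character_)
)

setValidity("ProportionTestResult", function(object) {
  msgs <- character(0)
  if (object@count1 > object@n1 || object@count2 > object@n2)
    msgs <- c(msgs, "counts cannot exceed sample sizes")
  if (object@pValue < 0 || object@pValue > 1)
    msgs <- c(msgs, "pValue must lie in [0, 1]")
  if (!object@alternative %in% c("two.sided", "greater", "less"))
    msgs <- c(msgs, "unknown alternative")
  if (length(msgs)) msgs else TRUE
})

# ---------------------------------------------------------------------------
# Synthetic-data parameter and truth containers
# ---------------------------------------------------------------------------

#' CorePeripheryParams: parameters of the planted core-periphery generator
#'
#' Describes a single-centre network built as concentric shells: zone 1
#' nodes all touch the centre (so the centre degree equals
#' \code{zoneSizes[1]}), each zone-k node is guaranteed at least one edge
#' into zone k-1, edge densities decay outward, and outer zones are
#' dominated by degree-1 "quills". See [generateCorePeriphery()].
#'
#' @slot zoneSizes integer vector, nodes per zone (zone 1 outward).
#' @slot pIntra within-zone edge probability, one per zone.
#' @slot pAdjacent adjacent-zone edge probability, one per zone pair
#'   (k, k+1).
#' @slot quills number of planted degree-1 nodes per zone (each attached to
#'   one node of the previous shell and nothing else).
#' @slot chains number of reserved centre-to-rim paths whose interior nodes
#'   carry no other edges; with >= 2 such chains the planted centre is
#'   provably the unique eccentricity minimiser.
#' @slot nNoise number of uniformly random extra edges (long-range
#'   shortcuts); 0 for exact zone recovery.
#' @slot seed integer seed fixing all randomness.
#' @name CorePeripheryParams-class
#' @aliases CorePeripheryParams-class
#' @exportClass CorePeripheryParams
setClass("CorePeripheryParams",
  slots = c(zoneSizes = "integer", pIntra = "numeric",
            pAdjacent = "numeric", quills = "integer",
            chains = "integer", nNoise = "integer", seed = "integer")
)

setValidity("CorePeripheryParams", function(object) {
  K <- length(object@zoneSizes)
  msgs <- character(0)
  if (K == 0L) msgs <- c(msgs, "zoneSizes must be non-empty")
  if (any(object@zoneSizes < 1L))
    msgs <- c(msgs, "every zone must have at least one node (no empty zone before a non-empty one)")
  if (length(object@pIntra) != K)
    msgs <- c(msgs, "pIntra must have one probability per zone")
  if (length(object@pAdjacent) != max(K - 1L, 0L))
    msgs <- c(msgs, "pAdjacent must have one probability per adjacent zone pair")
  if (any(c(object@pIntra, object@pAdjacent) < 0) ||
      any(c(object@pIntra, object@pAdjacent) > 1))
    msgs <- c(msgs, "probabilities must lie in [0, 1]")
  if (length(object@quills) != K)
    msgs <- c(msgs, "quills must have one count per zone")
  else {
    if (any(object@quills < 0L) || any(object@quills + object@chains > object@zoneSizes))
      msgs <- c(msgs, "quills + chains cannot exceed the zone size")
    if (K > 1L) {
      pool <- object@zoneSizes - object@quills - object@chains
      if (any(pool[-K] < 1L))
        msgs <- c(msgs, "every non-terminal zone needs at least one regular (non-quill, non-chain) node to parent the next shell")
    }
  }
  if (object@nNoise < 0L) msgs <- c(msgs, "nNoise must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' @rdname CorePeripheryParams-class
#' @param zoneSizes,pIntra,pAdjacent,quills,chains,nNoise,seed see slots.
#' @return a \code{CorePeripheryParams} object.
#' @export
corePeripheryParams <- function(zoneSizes, pIntra = rep(0, length(zoneSizes)),
                                pAdjacent = rep(0, max(length(zoneSizes) - 1L, 0L)),
                                quills = rep(0L, length(zoneSizes)),
                                chains = 0L, nNoise = 0L, seed = 1L) {
  new("CorePeripheryParams",
      zoneSizes = as.integer(zoneSizes), pIntra = as.numeric(pIntra),
      pAdjacent = as.numeric(pAdjacent), quills = as.integer(quills),
      chains = as.integer(chains), nNoise = as.integer(nNoise),
      seed = as.integer(seed))
}

#' PlantedTruth: ground truth emitted with a synthetic network
#'
#' Records the planted centre, the planted node-to-zone map, and the
#' per-zone metrics table (computed from the emitted network's actual
#' degrees, so it is consistent with the network by construction).
#'
#' @slot centre the planted centre node ID.
#' @slot zoneOf named integer vector of planted zone indices (centre at 0).
#' @slot metrics data.frame with columns zone, nodes, aveDegree, minDegree,
#'   maxDegree, quills.
#' @name PlantedTruth-class
#' @aliases PlantedTruth-class
#' @exportClass PlantedTruth
setClass("PlantedTruth",
  slots = c(centre = "character", zoneOf = "integer", metrics = "data.frame")
)
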