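# Planted core-periphery generator: single-centre networks built as
# concentric shells with decaying edge density and quill-dominated outer
# zones, plus zone-biased annotation sets and Bernoulli presence matrices.
# Every generator is bit-reproducible given its seed.

# node naming: centre "C0", zone-k members "z<k>_<i>"
.zoneNodeNames <- function(zoneSizes) {
  lapply(seq_along(zoneSizes), function(k)
    sprintf("z%d_%03d", k, seq_len(zoneSizes[k])))
}

#' Generate a core-periphery network with planted zone structure
#'
#' Builds a single-centre network shell by shell. Every zone 1 node is wired
#' to the centre (so the centre degree is \code{zoneSizes[1]}); every
#' regular zone-k node receives one guaranteed edge to a regular zone-(k-1)
#' node plus Bernoulli extra edges within its zone (\code{pIntra}) and to
#' the previous zone (\code{pAdjacent}); planted quills receive exactly one
#' edge to the previous shell. With \code{nNoise = 0} all edges connect
#' equal or adjacent shells, so the planted zone index is exactly the
#' distance from the centre. Noise edges are uniformly random extra pairs
#' and can only shorten distances, never lengthen them.
#'
#' \code{chains} reserved nodes per zone form centre-to-rim paths whose
#' interior nodes carry no other edges. With at least two such chains the
#' planted centre is the unique eccentricity minimiser: the centre reaches
#' everything within the radius K, while any other node needs K + 1 steps
#' to the tip of a chain it does not sit on (chain interiors are reachable
#' only through the centre).
#'
#' @param params a [CorePeripheryParams-class].
#' @return list with elements \code{network} ([PINetwork-class]) and
#'   \code{truth} ([PlantedTruth-class]).
#' @export
#' @examples
#' out <- generateCorePeriphery(corePeripheryParams(zoneSizes = 5, seed = 7))
#' out$network  # a star: 5 quills around the centre
generateCorePeriphery <- function(params) {
  stopifnot(is(params, "CorePeripheryParams"))
  validObject(params)
  set.seed(params@seed)
  K <- length(params@zoneSizes)
  zoneNames <- .zoneNodeNames(params@zoneSizes)
  centre <- "C0"

  # role assignment within each zone: chains first, then quills, then regular
  chains <- params@chains
  chainNodes <- lapply(seq_len(K), function(k)
    if (chains > 0L) zoneNames[[k]][seq_len(chains)] else character(0))
  quillNodes <- lapply(seq_len(K), function(k) {
    q <- params@quills[k]
    if (q > 0L) zoneNames[[k]][chains + seq_len(q)] else character(0)
  })
  regularNodes <- lapply(seq_len(K), function(k)
    setdiff(zoneNames[[k]], c(chainNodes[[k]], quillNodes[[k]])))

  from <- character(0); to <- character(0)
  addEdges <- function(a, b) {
    from <<- c(from, a); to <<- c(to, b)
  }

  # zone 1: everyone touches the centre
  addEdges(rep(centre, params@zoneSizes[1L]), zoneNames[[1L]])
  # chains: straight paths outward, no other edges on their interiors
  if (chains > 0L && K > 1L) {
    for (cix in seq_len(chains)) {
      for (k in 2:K)
        addEdges(chainNodes[[k - 1L]][cix], chainNodes[[k]][cix])
    }
  }
  for (k in seq_len(K)) {
    reg <- regularNodes[[k]]
    if (k > 1L) {
      pool <- regularNodes[[k - 1L]]
      # guaranteed parent in the previous shell (planted distance is exact)
      if (length(reg))
        addEdges(sample(pool, length(reg), replace = TRUE), reg)
      if (length(quillNodes[[k]]))
        addEdges(sample(pool, length(quillNodes[[k]]), replace = TRUE),
                 quillNodes[[k]])
      # extra adjacent-shell edges
      pAdj <- params@pAdjacent[k - 1L]
      if (pAdj > 0 && length(reg) && length(pool)) {
        hit <- which(matrix(stats::runif(length(reg) * length(pool)),
                            length(reg)) < pAdj, arr.ind = TRUE)
        if (nrow(hit)) addEdges(reg[hit[, 1L]], pool[hit[, 2L]])
      }
    }
    # intra-shell edges among regular nodes
    pIn <- params@pIntra[k]
    if (pIn > 0 && length(reg) > 1L) {
      prs <- utils::combn(reg, 2L)
      keep <- stats::runif(ncol(prs)) < pIn
      if (any(keep)) addEdges(prs[1L, keep], prs[2L, keep])
    }
  }
  # long-range noise shortcuts (only ever shrink distances)
  if (params@nNoise > 0L) {
    allNodes <- c(centre, unlist(zoneNames))
    a <- sample(allNodes, params@nNoise, replace = TRUE)
    b <- sample(allNodes, params@nNoise, replace = TRUE)
    ok <- a != b
    addEdges(a[ok], b[ok])
  }

  net <- PINetwork(cbind(from, to), quiet = TRUE)
  zoneOf <- setNames(
    as.integer(c(0L, rep(seq_len(K), params@zoneSizes))),
    c(centre, unlist(zoneNames)))
  deg <- nodeDegree(net)[names(zoneOf)]
  metrics <- do.call(rbind, lapply(seq_len(K), function(k) {
    dk <- deg[zoneOf == k]
    data.frame(zone = k, nodes = length(dk),
               aveDegree = roundHalfAway(mean(dk), 1L),
               minDegree = as.integer(min(dk)),
               maxDegree = as.integer(max(dk)),
               quills = sum(dk == 1L))
  }))
  truth <- new("PlantedTruth", centre = centre, zoneOf = zoneOf,
               metrics = metrics)
  list(network = net, truth = truth)
}

#' A scaled preset emulating the shape of a large human functional PIN
#'
#' Five shells around a single centre, sizes proportional to the zone sizes
#' observed in large human PINs scaled down to ~460 nodes so the whole
#' pipeline runs in seconds: a small dense first shell, bulky middle shells,
#' thin quill-dominated outer shells, and edge probabilities decaying
#' outward. Two reserved centre-to-rim chains make the planted centre the
#' unique eccentricity minimiser (see [generateCorePeriphery()]).
#'
#' @param seed integer seed.
#' @param noise if \code{TRUE}, adds 30 uniformly random long-range edges;
#'   planted zone indices are then upper bounds on the true distances rather
#'   than exact.
#' @return a [CorePeripheryParams-class].
#' @export
hfpinLikeParams <- function(seed = 1L, noise = FALSE) {
  corePeripheryParams(
    zoneSizes = c(19L, 230L, 173L, 29L, 5L),
    pIntra    = c(0.50, 0.060, 0.010, 0.010, 0),
    pAdjacent = c(0.25, 0.040, 0.015, 0.020),
    quills    = c(0L, 9L, 33L, 15L, 3L),
    chains    = 2L,
    nNoise    = if (noise) 30L else 0L,
    seed      = seed)
}

#' Generate an annotation set with zone-dependent prevalence
#'
#' Each node is included independently with the prevalence of its planted
#' zone, emulating annotation classes (essential genes, drug targets) whose
#' prevalence decreases monotonically away from the centre. Zones beyond
#' the supplied prevalence vector, and the centre (zone 0), have
#' prevalence 0 unless given explicitly via a named vector.
#'
#' @param truth a [PlantedTruth-class].
#' @param prevalence numeric vector of inclusion probabilities; unnamed
#'   vectors apply to zones 1, 2, ... in order, named vectors are indexed
#'   by zone ("0", "1", ...).
#' @param seed integer seed.
#' @param name set name.
#' @return an [AnnotationSet-class].
#' @export
generateZoneBiasedAnnotation <- function(truth, prevalence, seed = 1L,
                                         name = "planted") {
  stopifnot(is(truth, "PlantedTruth"))
  if (any(prevalence < 0) || any(prevalence > 1))
    stop("prevalences must lie in [0, 1]")
  if (is.null(names(prevalence)))
    names(prevalence) <- as.character(seq_along(prevalence))
  z <- plantedZones(truth)
  p <- prevalence[as.character(z)]
  p[is.na(p)] <- 0
  set.seed(seed)
  AnnotationSet(name, names(z)[stats::runif(length(z)) < p])
}

#' Generate a Bernoulli presence/absence call matrix
#'
#' Independent 0/1 calls per gene and sample, with a per-gene presence
#' probability; emulates barcode-style absence/presence call downloads.
#'
#' @param genes character vector of gene IDs.
#' @param samples number of samples (>= 1).
#' @param presenceProb presence probability, recycled over genes, or a named
#'   vector indexed by gene ID.
#' @param seed integer seed.
#' @param samplePrefix sample ID prefix.
#' @return a [PresenceMatrix-class].
#' @export
generatePresenceMatrix <- function(genes, samples, presenceProb = 0.5,
                                   seed = 1L, samplePrefix = "s") {
  if (samples < 1L) stop("need at least one sample")
  if (!is.null(names(presenceProb))) {
    p <- presenceProb[genes]
    p[is.na(p)] <- 0
  } else {
    p <- rep_len(presenceProb, length(genes))
  }
  set.seed(seed)
  calls <- matrix(
    as.integer(stats::runif(length(genes) * samples) < rep(p, samples)),
    nrow = length(genes),
    dimnames = list(genes, sprintf("%s%03d", samplePrefix, seq_len(samples))))
  PresenceMatrix(calls)
}

#' Read generator parameters from a YAML file
#'
#' Keys: \code{zone_sizes}, \code{p_intra}, \code{p_adjacent},
#' \code{quills}, \code{chains}, \code{n_noise}, \code{seed}; or
#' \code{preset: hfpin-like} with optional \code{noise} and \code{seed}.
#'
#' @param path YAML file path.
#' @return a [CorePeripheryParams-class].
#' @export
readCorePeripheryParams <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$preset)) {
    if (cfg$preset != "hfpin-like") stop("unknown preset: ", cfg$preset)
    return(hfpinLikeParams(seed = cfg$seed %||% 1L,
                           noise = isTRUE(cfg$noise)))
  }
  corePeripheryParams(
    zoneSizes = cfg$zone_sizes,
    pIntra = cfg$p_intra %||% rep(0, length(cfg$zone_sizes)),
    pAdjacent = cfg$p_adjacent %||% rep(0, max(length(cfg$zone_sizes) - 1L, 0L)),
    quills = cfg$quills %||% rep(0L, length(cfg$zone_sizes)),
    chains = cfg$chains %||% 0L,
    nNoise = cfg$n_noise %||% 0L,
    seed = cfg$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
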