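# Mapping annotation sets onto zones: the count/percentage distribution
# tables at the heart of the analysis (the "N (x%)" cells), the
# consistent-expression filter, and multi-set summaries with an average row.

#' Distribution of an annotation set across zones
#'
#' For each zone the exact set intersection count, the zone size, and the
#' percentage \code{100 * count / size} rounded half away from zero to one
#' decimal. Members mapping to the centre appear in a separate zone 0 row,
#' not in zone 1. Members absent from the network are counted as unmapped
#' and logged; members in the network but outside the centre's component
#' (unreachable) are likewise reported via an attribute.
#'
#' @param decomposition a [ZoneDecomposition-class].
#' @param annotation an [AnnotationSet-class] (or any object with
#'   \code{members()}).
#' @return data.frame with columns \code{zone}, \code{count}, \code{size},
#'   \code{percent}, one row per zone index 0..radius, with attributes
#'   \code{annotation} (set name), \code{unmapped} (member IDs not in the
#'   network) and \code{unreachableMembers} (members outside the centre's
#'   component).
#' @export
#' @examples
#' net <- readEdgeListString("C\tA\nC\tB\nA\tB\nB\tD")
#' dec <- zonePartition(net)
#' zoneDistribution(dec, AnnotationSet("ess", c("A", "D", "X")))
zoneDistribution <- function(decomposition, annotation) {
  stopifnot(is(decomposition, "ZoneDecomposition"))
  mem <- members(annotation)
  z <- zoneOf(decomposition)
  if (!length(z)) stop("empty decomposition")
  if (!length(mem))
    warning("annotation set '", setName(annotation),
            "' is empty; report is all zeros")
  unmapped <- setdiff(mem, c(names(z), unreachableNodes(decomposition)))
  if (length(unmapped))
    .logmsg(length(unmapped), " member(s) of '", setName(annotation),
            "' not in the network")
  unreach <- intersect(mem, unreachableNodes(decomposition))
  ks <- 0:max(z)
  size <- vapply(ks, function(k) sum(z == k), integer(1))
  count <- vapply(ks, function(k) sum(names(z)[z == k] %in% mem), integer(1))
  out <- data.frame(zone = ks, count = count, size = size,
                    percent = zonePercent(count, size))
  attr(out, "annotation") <- setName(annotation)
  attr(out, "unmapped") <- unmapped
  attr(out, "unreachableMembers") <- unreach
  out
}

#' Consistent-expression filter
#'
#' Keeps the genes called present in at least \code{threshold} of the
#' samples (count of 1-calls / number of samples >= threshold), the
#' "expressed in at least 99\% of samples of a cancer of interest" rule.
#' Gene expression is used as a proxy for protein expression: gene IDs map
#' to network nodes by identity.
#'
#' @param matrix a [PresenceMatrix-class].
#' @param threshold presence fraction in (0, 1], default 0.99.
#' @param label source label (e.g. the cancer type); becomes the set name.
#' @return a [ConsistentGeneSet-class].
#' @export
#' @examples
#' pm <- PresenceMatrix(matrix(c(1L, 1L, 1L, 0L), 2, 2,
#'                      dimnames = list(c("g1", "g2"), c("s1", "s2"))))
#' members(filterConsistentGenes(pm, 0.99, "demo"))
filterConsistentGenes <- function(matrix, threshold = 0.99, label = "consistent") {
  stopifnot(is(matrix, "PresenceMatrix"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1)
    stop("threshold must be a single fraction in (0, 1]")
  calls <- presenceCalls(matrix)
  if (ncol(calls) == 0L) stop("presence matrix has zero samples")
  frac <- rowMeans(calls)
  keep <- frac >= threshold - 1e-12  # counts are integral; guard float noise only
  new("ConsistentGeneSet", name = as.character(label),
      members = rownames(calls)[keep], threshold = threshold)
}

#' Zone distributions for several annotation sets, with an average row
#'
#' Computes [zoneDistribution()] per set and a summary percentage matrix
#' (sets x zones) whose final \code{Average} row is the unweighted
#' arithmetic mean of the per-set percentages per zone, rounded half away
#' from zero to one decimal.
#'
#' @param decomposition a [ZoneDecomposition-class].
#' @param annotations non-empty list of [AnnotationSet-class] objects.
#' @return list with \code{reports} (named list of per-set data.frames) and
#'   \code{summary} (data.frame: \code{annotation}, \code{n} = total mapped
#'   members over zones, then one \code{percent.zone<k>} column per zone,
#'   plus the Average row).
#' @export
multiSetDistribution <- function(decomposition, annotations) {
  if (!length(annotations)) stop("need at least one annotation set")
  reports <- lapply(annotations, function(a) zoneDistribution(decomposition, a))
  names(reports) <- vapply(annotations, setName, character(1))
  ks <- reports[[1L]]$zone
  pct <- matrix(unlist(lapply(reports, function(r) {
    p <- r$percent
    p[is.na(p)] <- 0
    p
  })), nrow = length(reports), byrow = TRUE)
  avg <- roundHalfAway(colMeans(pct), 1L)
  summary <- data.frame(
    annotation = c(names(reports), "Average"),
    n = c(vapply(reports, function(r) sum(r$count), integer(1)), NA_integer_),
    rbind(pct, avg))
  colnames(summary)[-(1:2)] <- paste0("percent.zone", ks)
  rownames(summary) <- NULL
  list(reports = reports, summary = summary)
}

#' Write a zone distribution report as TSV
#'
#' @param report data.frame from [zoneDistribution()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeZoneDistribution <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# annotation: ", attr(report, "annotation")),
    paste0("# unmapped_members: ", length(attr(report, "unmapped")))), con)
  utils::write.table(report, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
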