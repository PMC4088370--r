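# Generics and accessors. Slots are never touched directly by user code.

#' @rdname PINetwork-class
#' @param x,object a \code{PINetwork}.
#' @export
setGeneric("netNodes", function(x) standardGeneric("netNodes"))
#' @rdname PINetwork-class
#' @export
setGeneric("netEdges", function(x) standardGeneric("netEdges"))
#' @rdname PINetwork-class
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))
#' @rdname PINetwork-class
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))
#' @rdname PINetwork-class
#' @export
setGeneric("nodeDegree", function(x) standardGeneric("nodeDegree"))

#' @rdname PINetwork-class
setMethod("netNodes", "PINetwork", function(x) x@nodes)
#' @rdname PINetwork-class
setMethod("netEdges", "PINetwork", function(x) x@edges)
#' @rdname PINetwork-class
setMethod("numNodes", "PINetwork", function(x) length(x@nodes))
#' @rdname PINetwork-class
setMethod("numEdges", "PINetwork", function(x) nrow(x@edges))

#' @rdname PINetwork-class
setMethod("nodeDegree", "PINetwork", function(x) {
  deg <- integer(length(x@nodes))
  names(deg) <- x@nodes
  if (nrow(x@edges)) {
    tab <- table(c(x@edges[, 1L], x@edges[, 2L]))
    deg[names(tab)] <- as.integer(tab)
  }
  deg
})

setMethod("show", "PINetwork", function(object) {
  cat("PINetwork with", length(object@nodes), "nodes and",
      nrow(object@edges), "edges\n")
  if (length(object@nodes)) {
    head <- utils::head(object@nodes, 5L)
    cat("  nodes:", paste(head, collapse = ", "),
        if (length(object@nodes) > 5L) "..." else "", "\n")
  }
})

#' @rdname ZoneDecomposition-class
#' @param x,object a \code{ZoneDecomposition}.
#' @export
setGeneric("centres", function(x) standardGeneric("centres"))
#' @rdname ZoneDecomposition-class
#' @export
setGeneric("zoneOf", function(x) standardGeneric("zoneOf"))
#' @rdname ZoneDecomposition-class
#' @export
setGeneric("radiusOf", function(x) standardGeneric("radiusOf"))
#' @rdname ZoneDecomposition-class
#' @export
setGeneric("diameterOf", function(x) standardGeneric("diameterOf"))
#' @rdname ZoneDecomposition-class
#' @export
setGeneric("unreachableNodes", function(x) standardGeneric("unreachableNodes"))
#' @rdname ZoneDecomposition-class
#' @export
setGeneric("zoneSizes", function(x) standardGeneric("zoneSizes"))

#' @rdname ZoneDecomposition-class
setMethod("centres", "ZoneDecomposition", function(x) x@centres)
#' @rdname ZoneDecomposition-class
setMethod("zoneOf", "ZoneDecomposition", function(x) x@zoneOf)
#' @rdname ZoneDecomposition-class
setMethod("radiusOf", "ZoneDecomposition", function(x) x@radius)
#' @rdname ZoneDecomposition-class
setMethod("diameterOf", "ZoneDecomposition", function(x) x@diameter)
#' @rdname ZoneDecomposition-class
setMethod("unreachableNodes", "ZoneDecomposition", function(x) x@unreachable)

#' @rdname ZoneDecomposition-class
#' @details \code{zoneSizes()} returns a named integer vector of node counts
#'   per zone index (zone 0 = the centre set).
setMethod("zoneSizes", "ZoneDecomposition", function(x) {
  if (!length(x@zoneOf)) return(setNames(integer(0), character(0)))
  tab <- table(x@zoneOf)
  setNames(as.integer(tab), names(tab))
})

setMethod("show", "ZoneDecomposition", function(object) {
  cat("ZoneDecomposition\n")
  cat("  centre(s):", paste(object@centres, collapse = ", "), "\n")
  cat("  radius:", object@radius, " diameter:", object@diameter, "\n")
  zs <- zoneSizes(object)
  if (length(zs))
    cat("  zone sizes:",
        paste(sprintf("%s:%d", names(zs), zs), collapse = "  "), "\n")
  if (length(object@unreachable))
    cat("  unreachable nodes:", length(object@unreachable), "\n")
})

#' @rdname AnnotationSet-class
#' @param x,object an \code{AnnotationSet}.
#' @export
setGeneric("setName", function(x) standardGeneric("setName"))
#' @rdname AnnotationSet-class
#' @export
setGeneric("members", function(x) standardGeneric("members"))

#' @rdname AnnotationSet-class
setMethod("setName", "AnnotationSet", function(x) x@name)
#' @rdname AnnotationSet-class
setMethod("members", "AnnotationSet", function(x) x@members)

setMethod("show", "AnnotationSet", function(object) {
  cat("AnnotationSet '", object@name, "': ",
      length(object@members), " members\n", sep = "")
})

#' @rdname ConsistentGeneSet-class
#' @param x,object a \code{ConsistentGeneSet}.
#' @export
setGeneric("callThreshold", function(x) standardGeneric("callThreshold"))
#' @rdname ConsistentGeneSet-class
setMethod("callThreshold", "ConsistentGeneSet", function(x) x@threshold)

setMethod("show", "ConsistentGeneSet", function(object) {
  cat("ConsistentGeneSet '", object@name, "': ", length(object@members),
      " genes present in >= ", 100 * object@threshold,
      "% of samples\n", sep = "")
})

#' @rdname PresenceMatrix-class
#' @param x,object a \code{PresenceMatrix}.
#' @export
setGeneric("presenceCalls", function(x) standardGeneric("presenceCalls"))
#' @rdname PresenceMatrix-class
#' @export
setGeneric("geneIDs", function(x) standardGeneric("geneIDs"))
#' @rdname PresenceMatrix-class
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' @rdname PresenceMatrix-class
setMethod("presenceCalls", "PresenceMatrix", function(x) x@calls)
#' @rdname PresenceMatrix-class
setMethod("geneIDs", "PresenceMatrix", function(x) rownames(x@calls))
#' @rdname PresenceMatrix-class
setMethod("sampleIDs", "PresenceMatrix", function(x) colnames(x@calls))

setMethod("show", "PresenceMatrix", function(object) {
  cat("PresenceMatrix:", nrow(object@calls), "genes x",
      ncol(object@calls), "samples\n")
})

#' @rdname ProportionTestResult-class
#' @param x,object a \code{ProportionTestResult}.
#' @export
setGeneric("zStatistic", function(x) standardGeneric("zStatistic"))
#' @rdname ProportionTestResult-class
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' @rdname ProportionTestResult-class
#' @export
setGeneric("isSignificant", function(x) standardGeneric("isSignificant"))

#' @rdname ProportionTestResult-class
setMethod("zStatistic", "ProportionTestResult", function(x) x@z)
#' @rdname ProportionTestResult-class
setMethod("pValue", "ProportionTestResult", function(x) x@pValue)
#' @rdname ProportionTestResult-class
setMethod("isSignificant", "ProportionTestResult", function(x) x@significant)

setMethod("show", "ProportionTestResult", function(object) {
  lab <- if (!is.na(object@label)) paste0(" [", object@label, "]") else ""
  cat(sprintf(
    "Two-proportion z-test%s (%s)\n  p1 = %d/%d = %.4f   p2 = %d/%d = %.4f\n  z = %.4f   p = %.4g   %s at alpha = %g\n",
    lab, object@alternative,
    object@count1, object@n1, object@p1,
    object@count2, object@n2, object@p2,
    object@z, object@pValue,
    if (object@significant) "SIGNIFICANT" else "not significant",
    object@alpha))
})

#' @rdname PlantedTruth-class
#' @param x,object a \code{PlantedTruth}.
#' @export
setGeneric("plantedCentre", function(x) standardGeneric("plantedCentre"))
#' @rdname PlantedTruth-class
#' @export
setGeneric("plantedZones", function(x) standardGeneric("plantedZones"))
#' @rdname PlantedTruth-class
#' @export
setGeneric("plantedMetrics", function(x) standardGeneric("plantedMetrics"))

#' @rdname PlantedTruth-class
setMethod("plantedCentre", "PlantedTruth", function(x) x@centre)
#' @rdname PlantedTruth-class
setMethod("plantedZones", "PlantedTruth", function(x) x@zoneOf)
#' @rdname PlantedTruth-class
setMethod("plantedMetrics", "PlantedTruth", function(x) x@metrics)

setMethod("show", "PlantedTruth", function(object) {
  cat("PlantedTruth: centre", object@centre, "with",
      max(object@zoneOf), "zones over", length(object@zoneOf), "nodes\n")
})
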