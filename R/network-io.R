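# Readers and writers for the plain-text formats the pipeline consumes:
# 2-column TSV and SIF edge lists, GMT gene sets, presence/absence call
# matrices, zone assignment tables and KEGG Mapper colour files.
# All writers sort by node ID so output is deterministic.

#' Read an undirected network from an edge list
#'
#' Supports two formats. \code{"tsv"}: two (or more) whitespace/tab-separated
#' fields per line, the first two being the interacting node IDs.
#' \code{"sif"}: \code{node relation node [node ...]}; one edge is created
#' from the first node to every node from the third field on, and the
#' relation type is ignored (all edges are one undirected interaction
#' class). Lines starting with \code{#} and blank lines are skipped.
#' Self-loops and duplicate/reversed edges are dropped with a logged count.
#' An empty file yields a valid empty network.
#'
#' @param path file path.
#' @param format \code{"tsv"} (default) or \code{"sif"}.
#' @return a [PINetwork-class].
#' @export
readEdgeList <- function(path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  readEdgeListString(paste(lines, collapse = "\n"), format = format)
}

#' @rdname readEdgeList
#' @param text edge list as a single string (convenience for examples and
#'   tests; identical parsing to [readEdgeList()]).
#' @export
readEdgeListString <- function(text, format = c("tsv", "sif")) {
  format <- match.arg(format)
  lines <- if (nzchar(text)) strsplit(text, "\n", fixed = TRUE)[[1]] else character(0)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  need <- if (format == "tsv") 2L else 3L
  from <- character(0); to <- character(0)
  for (ln in keep) {
    f <- strsplit(trimws(lines[ln]), "[ \t]+")[[1]]
    if (length(f) < need)
      stop(sprintf("parse error at line %d: expected at least %d fields, found %d",
                   ln, need, length(f)))
    if (format == "tsv") {
      from <- c(from, f[1L]); to <- c(to, f[2L])
    } else {
      tgt <- f[3:length(f)]
      from <- c(from, rep(f[1L], length(tgt))); to <- c(to, tgt)
    }
  }
  PINetwork(cbind(from, to))
}

#' Write a network as an edge list
#'
#' Inverse of [readEdgeList()] for networks without isolated nodes (an edge
#' list cannot represent a node with no interactions). Edges are written in
#' canonical sorted order.
#'
#' @param net a [PINetwork-class].
#' @param path output file path.
#' @param format \code{"tsv"} or \code{"sif"} (relation type \code{"pp"}).
#' @return the path, invisibly.
#' @export
writeEdgeList <- function(net, path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  e <- netEdges(net)
  iso <- setdiff(netNodes(net), c(e))
  if (length(iso))
    warning(length(iso), " isolated node(s) cannot be represented in an edge list")
  lines <- if (format == "tsv") paste(e[, 1L], e[, 2L], sep = "\t")
           else paste(e[, 1L], "pp", e[, 2L], sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read annotation sets from a GMT file
#'
#' One set per non-empty line: \code{name<TAB>description<TAB>member...}.
#' Duplicate members within a line are collapsed; a set with no members is
#' retained empty with a warning; a duplicated set name is an error.
#'
#' @param path GMT file path.
#' @return named list of [AnnotationSet-class] objects.
#' @export
readAnnotationSets <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    name <- f[1L]
    if (name %in% names(out))
      stop("duplicate annotation set name: ", name)
    mem <- if (length(f) >= 3L) unique(f[3:length(f)]) else character(0)
    mem <- mem[nzchar(mem)]
    if (!length(mem))
      warning("annotation set '", name, "' has no members; retained empty")
    out[[name]] <- AnnotationSet(name, mem)
  }
  out
}

#' Write annotation sets to a GMT file
#'
#' @param sets list of [AnnotationSet-class] objects.
#' @param path output path.
#' @param description description field (recycled).
#' @return the path, invisibly.
#' @export
writeAnnotationSets <- function(sets, path, description = "na") {
  lines <- vapply(sets, function(s)
    paste(c(setName(s), description, sort(members(s))), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-by-sample presence/absence call matrix
#'
#' TSV layout: header row of sample IDs (an optional leading corner label is
#' tolerated), then one row per gene: gene ID followed by 0/1 calls, one per
#' sample. Non-binary cells and duplicated gene IDs are errors that name the
#' offending coordinates.
#'
#' @param path TSV file path.
#' @return a [PresenceMatrix-class].
#' @export
readPresenceMatrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop("presence matrix needs a header row and at least one gene row")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  nData <- length(fields[[2L]])  # gene ID + one call per sample
  samples <- if (length(header) == nData) header[-1L] else header
  if (length(samples) != nData - 1L)
    stop("header declares ", length(samples), " samples but data rows have ",
         nData - 1L, " call columns")
  if (length(samples) == 0L) stop("presence matrix has zero samples")
  genes <- character(length(fields) - 1L)
  calls <- matrix(NA_integer_, nrow = length(fields) - 1L,
                  ncol = length(samples))
  for (i in 2:length(fields)) {
    f <- fields[[i]]
    if (length(f) != nData)
      stop("row ", i, " has ", length(f), " fields, expected ", nData)
    genes[i - 1L] <- f[1L]
    vals <- f[-1L]
    bad <- which(!vals %in% c("0", "1"))
    if (length(bad))
      stop(sprintf("non-binary call '%s' at gene '%s' (row %d), sample '%s' (column %d)",
                   vals[bad[1L]], f[1L], i, samples[bad[1L]], bad[1L]))
    calls[i - 1L, ] <- as.integer(vals)
  }
  dupes <- genes[duplicated(genes)]
  if (length(dupes))
    stop("duplicated gene ID(s): ", paste(unique(dupes), collapse = ", "))
  dimnames(calls) <- list(genes, samples)
  PresenceMatrix(calls)
}

#' Merge two networks non-redundantly
#'
#' Node set = union of node sets; edge set = union of canonicalised
#' unordered pairs. Commutative and idempotent. Node identity is exact
#' string match on gene symbols; no alias resolution is attempted.
#'
#' @param a,b [PINetwork-class] objects.
#' @return the combined [PINetwork-class].
#' @export
#' @examples
#' g <- readEdgeListString("A\tB")
#' h <- readEdgeListString("C\tD")
#' numEdges(mergeNetworks(g, h))  # 2
mergeNetworks <- function(a, b) {
  stopifnot(is(a, "PINetwork"), is(b, "PINetwork"))
  PINetwork(rbind(netEdges(a), netEdges(b)),
            nodes = c(netNodes(a), netNodes(b)), quiet = TRUE)
}

#' Default KEGG Mapper zone colour scheme
#'
#' Zone 1: red, zone 2: orange, zone 3: yellow, zone 4: green.
#'
#' @return named character vector mapping zone index to colour name.
#' @export
keggDefaultColours <- function() {
  c("1" = "red", "2" = "orange", "3" = "yellow", "4" = "green")
}

#' Export a zone-to-colour file for KEGG Mapper
#'
#' Writes the two-column \code{geneID<TAB>colour} file accepted by the KEGG
#' "Color objects in pathway maps" form, one line per mapped node, sorted by
#' gene ID. Nodes whose zone index has no colour in the scheme are an error
#' unless \code{skipMissing = TRUE}, in which case they are skipped with a
#' logged count (the centre, zone 0, is skipped under the default scheme).
#'
#' @param zones a [ZoneDecomposition-class] or a named integer node-to-zone
#'   map.
#' @param path output file path.
#' @param colourScheme named character vector, zone index to colour name.
#' @param skipMissing skip (rather than error on) nodes whose zone has no
#'   colour.
#' @return the path, invisibly.
#' @export
exportKeggMapper <- function(zones, path, colourScheme = keggDefaultColours(),
                             skipMissing = FALSE) {
  z <- if (is(zones, "ZoneDecomposition")) zoneOf(zones) else zones
  if (!length(names(z)) && length(z))
    stop("'zones' must be named by node ID")
  col <- colourScheme[as.character(z)]
  miss <- is.na(col)
  if (any(miss)) {
    if (!skipMissing)
      stop("no colour for zone(s) ",
           paste(sort(unique(z[miss])), collapse = ", "),
           "; set skipMissing = TRUE to drop them")
    .logmsg("skipped ", sum(miss), " node(s) with uncoloured zone index")
  }
  nodes <- names(z)[!miss]
  col <- col[!miss]
  ord <- order(nodes)
  writeLines(paste(nodes[ord], col[ord], sep = "\t"), path)
  invisible(path)
}

#' Write zone assignments as TSV
#'
#' Two columns, \code{node<TAB>zone}, sorted by node ID, with the centre
#' node(s) at zone 0. Round-trips losslessly with [readZoneAssignments()].
#' Unreachable nodes carry no zone and are not written.
#'
#' @param decomposition a [ZoneDecomposition-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeZoneAssignments <- function(decomposition, path) {
  z <- zoneOf(decomposition)
  ord <- order(names(z))
  writeLines(c("node\tzone",
               if (length(z)) paste(names(z)[ord], z[ord], sep = "\t")),
             path)
  invisible(path)
}

#' Read zone assignments written by [writeZoneAssignments()]
#'
#' @param path TSV path with header \code{node<TAB>zone}.
#' @return named integer vector, node to zone index.
#' @export
readZoneAssignments <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, colClasses = c("character", "integer"))
  setNames(df$zone, df$node)
}
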