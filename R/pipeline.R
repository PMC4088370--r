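# End-to-end orchestration: a validated configuration object, the full
# analysis (load -> merge -> decompose -> metrics -> distributions -> tests
# -> enrichment -> exports) and a run manifest sufficient to re-run the
# bundle. All outputs are deterministic: files are sorted, a single seed
# drives any synthetic steps, and no timestamps are written.

#' Analysis configuration
#'
#' Validates an analysis configuration: referenced files must exist,
#' \code{alpha} must lie in (0, 1) and \code{threshold} in (0, 1].
#'
#' @param network path to the network edge list.
#' @param format edge list format, "tsv" or "sif".
#' @param network2 optional second network, merged non-redundantly into the
#'   first.
#' @param annotations optional GMT file of annotation sets.
#' @param pathways optional GMT file of pathway sets for enrichment.
#' @param presence optional named character vector of presence-matrix paths
#'   (names are the source labels, e.g. cancer types).
#' @param threshold consistent-expression threshold, default 0.99.
#' @param alpha significance level, default 0.01.
#' @param outDir output directory (created if missing).
#' @param seed integer seed for any synthetic steps.
#' @param pairs "all" or "adjacent" zone pairs for the z-tests.
#' @param bonferroniPairs Bonferroni-correct the pairwise z-tests.
#' @param keggColours zone-to-colour map for the KEGG Mapper export.
#' @return a validated configuration (list with class
#'   \code{"AnalysisConfig"}).
#' @export
analysisConfig <- function(network, format = "tsv", network2 = NULL,
                           annotations = NULL, pathways = NULL,
                           presence = NULL, threshold = 0.99, alpha = 0.01,
                           outDir = "pinzones_out", seed = 1L,
                           pairs = "all", bonferroniPairs = FALSE,
                           keggColours = keggDefaultColours()) {
  mustExist <- c(network = network, network2 = network2,
                 annotations = annotations, pathways = pathways, presence)
  missing <- mustExist[!file.exists(mustExist)]
  if (length(missing))
    stop("config validation: missing input file(s): ",
         paste(missing, collapse = ", "))
  if (!(alpha > 0 && alpha < 1)) stop("config validation: alpha must lie in (0, 1)")
  if (!(threshold > 0 && threshold <= 1))
    stop("config validation: threshold must lie in (0, 1]")
  if (!format %in% c("tsv", "sif"))
    stop("config validation: unknown format: ", format)
  if (!is.null(presence) && is.null(names(presence)))
    stop("config validation: presence matrices must be labelled (named paths)")
  structure(list(network = network, format = format, network2 = network2,
                 annotations = annotations, pathways = pathways,
                 presence = presence, threshold = threshold, alpha = alpha,
                 outDir = outDir, seed = as.integer(seed), pairs = pairs,
                 bonferroniPairs = bonferroniPairs,
                 keggColours = keggColours),
            class = "AnalysisConfig")
}

#' Read an analysis configuration from YAML
#'
#' Keys mirror the arguments of [analysisConfig()] in snake_case:
#' \code{network}, \code{format}, \code{network2}, \code{annotations},
#' \code{pathways}, \code{presence} (mapping label -> path),
#' \code{threshold}, \code{alpha}, \code{out_dir}, \code{seed},
#' \code{pairs}, \code{bonferroni_pairs}.
#'
#' @param path YAML file path.
#' @return a validated \code{AnalysisConfig}.
#' @export
readAnalysisConfig <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- yaml::read_yaml(path)
  presence <- NULL
  if (!is.null(cfg$presence)) presence <- unlist(cfg$presence)
  analysisConfig(
    network = cfg$network,
    format = cfg$format %||% "tsv",
    network2 = cfg$network2,
    annotations = cfg$annotations,
    pathways = cfg$pathways,
    presence = presence,
    threshold = cfg$threshold %||% 0.99,
    alpha = cfg$alpha %||% 0.01,
    outDir = cfg$out_dir %||% "pinzones_out",
    seed = cfg$seed %||% 1L,
    pairs = cfg$pairs %||% "all",
    bonferroniPairs = isTRUE(cfg$bonferroni_pairs))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

#' Run the full zone analysis
#'
#' Executes the whole pipeline and writes, deterministically, into
#' \code{config$outDir}: \code{zone_assignments.tsv},
#' \code{zone_metrics.tsv}, one \code{distribution_<set>.tsv} per annotation
#' set plus \code{distribution_summary.tsv}, \code{pairwise_tests.tsv},
#' \code{enrichment.tsv} (when pathways are supplied),
#' \code{consistent_expression_summary.tsv} (when presence matrices are
#' supplied), \code{kegg_mapper.tsv}, and \code{manifest.yaml} recording
#' inputs (with MD5 checksums), package version, seed and parameters. Any
#' stage failure aborts with a stage-named error.
#'
#' @param config an \code{AnalysisConfig} from [analysisConfig()] or
#'   [readAnalysisConfig()].
#' @return the manifest (list), invisibly.
#' @export
runFullAnalysis <- function(config) {
  stopifnot(inherits(config, "AnalysisConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  out <- function(f) {
    outputs <<- c(outputs, f)
    file.path(config$outDir, f)
  }

  net <- .stage("load", {
    n <- readEdgeList(config$network, config$format)
    if (!is.null(config$network2))
      n <- mergeNetworks(n, readEdgeList(config$network2, config$format))
    n
  })

  dec <- .stage("decompose", zonePartition(net))
  .stage("decompose", writeZoneAssignments(dec, out("zone_assignments.tsv")))

  met <- .stage("metrics", zoneMetrics(net, dec))
  .stage("metrics", writeZoneMetrics(met, dec, out("zone_metrics.tsv")))

  annSets <- NULL
  if (!is.null(config$annotations)) {
    annSets <- .stage("distribute", readAnnotationSets(config$annotations))
    msd <- .stage("distribute", multiSetDistribution(dec, annSets))
    for (nm in names(msd$reports))
      .stage("distribute", writeZoneDistribution(
        msd$reports[[nm]],
        out(paste0("distribution_", gsub("[^A-Za-z0-9_.-]", "_", nm), ".tsv"))))
    .stage("distribute", utils::write.table(
      msd$summary, out("distribution_summary.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE))

    tests <- .stage("test", {
      do.call(rbind, lapply(names(msd$reports), function(nm) {
        tt <- pairwiseZoneTests(msd$reports[[nm]], alpha = config$alpha,
                                pairs = config$pairs,
                                bonferroni = config$bonferroniPairs)
        cbind(annotation = nm, tt)
      }))
    })
    .stage("test", utils::write.table(
      tests, out("pairwise_tests.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE))
  }

  if (!is.null(config$pathways)) {
    enr <- .stage("enrich", {
      pws <- readAnnotationSets(config$pathways)
      z <- zoneOf(dec)
      universe <- netNodes(net)
      do.call(rbind, lapply(sort(unique(z[z >= 1L])), function(k) {
        cbind(zone = k,
              hypergeomEnrichment(names(z)[z == k], pws, universe,
                                  alpha = config$alpha))
      }))
    })
    .stage("enrich", utils::write.table(
      enr, out("enrichment.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE))
  }

  if (!is.null(config$presence)) {
    cons <- .stage("filter-expression", {
      lapply(names(config$presence), function(lab)
        filterConsistentGenes(readPresenceMatrix(config$presence[[lab]]),
                              config$threshold, lab))
    })
    msd2 <- .stage("filter-expression", multiSetDistribution(dec, cons))
    .stage("filter-expression", utils::write.table(
      msd2$summary, out("consistent_expression_summary.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE))
  }

  .stage("export", exportKeggMapper(dec, out("kegg_mapper.tsv"),
                                    colourScheme = config$keggColours,
                                    skipMissing = TRUE))

  manifest <- .stage("manifest", {
    inputs <- c(network = config$network, network2 = config$network2,
                annotations = config$annotations, pathways = config$pathways,
                config$presence)
    m <- list(
      package = "PINzones",
      version = as.character(utils::packageVersion("PINzones")),
      seed = config$seed,
      parameters = list(format = config$format,
                        threshold = config$threshold, alpha = config$alpha,
                        pairs = config$pairs,
                        bonferroni_pairs = config$bonferroniPairs),
      inputs = lapply(seq_along(inputs), function(i) list(
        role = names(inputs)[i], path = unname(inputs[i]),
        md5 = unname(tools::md5sum(inputs[i])))),
      config = list(network = config$network, format = config$format,
                    network2 = config$network2,
                    annotations = config$annotations,
                    pathways = config$pathways,
                    presence = as.list(config$presence),
                    threshold = config$threshold, alpha = config$alpha,
                    out_dir = config$outDir, seed = config$seed,
                    pairs = config$pairs,
                    bonferroni_pairs = config$bonferroniPairs),
      outputs = sort(outputs))
    yaml::write_yaml(m, file.path(config$outDir, "manifest.yaml"))
    m
  })
  invisible(manifest)
}

#' Re-run an analysis from its manifest
#'
#' The manifest written by [runFullAnalysis()] embeds the full
#' configuration; re-executing it reproduces the bundle.
#'
#' @param manifestPath path to a \code{manifest.yaml}.
#' @param outDir optional new output directory (defaults to the one in the
#'   manifest).
#' @return the new manifest, invisibly.
#' @export
runFromManifest <- function(manifestPath, outDir = NULL) {
  m <- yaml::read_yaml(manifestPath)
  cfg <- m$config
  presence <- if (length(cfg$presence)) unlist(cfg$presence) else NULL
  config <- analysisConfig(
    network = cfg$network, format = cfg$format, network2 = cfg$network2,
    annotations = cfg$annotations, pathways = cfg$pathways,
    presence = presence, threshold = cfg$threshold, alpha = cfg$alpha,
    outDir = outDir %||% cfg$out_dir, seed = cfg$seed, pairs = cfg$pairs,
    bonferroniPairs = isTRUE(cfg$bonferroni_pairs))
  runFullAnalysis(config)
}
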