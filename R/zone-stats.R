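# Statistical machinery: the pooled two-proportion z-test used for
# between-zone comparisons, pairwise zone tests, Fisher's exact test as a
# cross-check, and hypergeometric over-representation with Bonferroni
# correction (the in-package replacement for an external enrichment
# service).

#' Pooled two-proportion z-test
#'
#' Tests H0: p1 = p2 with the standard pooled statistic
#' \deqn{z = (p_1 - p_2) / \sqrt{\hat p (1 - \hat p)(1/n_1 + 1/n_2)},}
#' where \eqn{\hat p = (x_1 + x_2)/(n_1 + n_2)}, and a normal p-value
#' (two-sided by default; a one-sided mode is available since the
#' between-zone claims are directional). No continuity correction is
#' applied; use [fisherExactCheck()] as an exact cross-check.
#'
#' When the pooled proportion is 0 or 1 the variance is zero; both sample
#' proportions are then necessarily equal and the test degenerates to
#' z = 0, p = 1 (never significant).
#'
#' @param count1,n1 successes and size of sample 1.
#' @param count2,n2 successes and size of sample 2.
#' @param alpha significance level, default 0.01.
#' @param alternative "two.sided" (default), "greater" or "less".
#' @param label optional label attached to the result.
#' @return a [ProportionTestResult-class].
#' @export
#' @examples
#' twoProportionZ(161, 374, 1002, 4610)  # z ~ 9.37, p << 0.01
twoProportionZ <- function(count1, n1, count2, n2, alpha = 0.01,
                           alternative = c("two.sided", "greater", "less"),
                           label = NA_character_) {
  alternative <- match.arg(alternative)
  if (n1 <= 0 || n2 <= 0) stop("sample sizes must be positive")
  if (count1 < 0 || count2 < 0 || count1 > n1 || count2 > n2)
    stop("counts must lie in [0, n]")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  p1 <- count1 / n1
  p2 <- count2 / n2
  pooled <- (count1 + count2) / (n1 + n2)
  if (pooled == 0 || pooled == 1) {
    # zero pooled variance forces p1 == p2; define z = 0 rather than 0/0
    stopifnot(p1 == p2)
    z <- 0
    pv <- 1
  } else {
    se <- sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
    z <- (p1 - p2) / se
    pv <- switch(alternative,
      two.sided = 2 * stats::pnorm(-abs(z)),
      greater   = stats::pnorm(z, lower.tail = FALSE),
      less      = stats::pnorm(z))
  }
  new("ProportionTestResult",
      count1 = count1, n1 = n1, count2 = count2, n2 = n2,
      p1 = p1, p2 = p2, pooled = pooled, z = z, pValue = pv,
      alpha = alpha, significant = pv < alpha,
      alternative = alternative, label = as.character(label))
}

#' Fisher's exact test on the same 2x2 layout
#'
#' Exact cross-check for [twoProportionZ()]: the two-sided Fisher test on
#' the table \code{rbind(c(count1, n1 - count1), c(count2, n2 - count2))}.
#' Provided as a cross-check, not the default test.
#'
#' @inheritParams twoProportionZ
#' @return the two-sided Fisher p-value.
#' @export
fisherExactCheck <- function(count1, n1, count2, n2) {
  stats::fisher.test(matrix(c(count1, n1 - count1, count2, n2 - count2),
                            nrow = 2, byrow = TRUE))$p.value
}

#' Pairwise two-proportion z-tests between zones
#'
#' Runs [twoProportionZ()] on every unordered pair of zones (index >= 1)
#' from a zone distribution report, flagging adjacent pairs (consecutive
#' zone indices). Zones of size 0 are skipped with a warning. By default
#' each pair is tested at \code{alpha} without multiplicity correction
#' (matching per-pair significance reporting); \code{bonferroni = TRUE}
#' multiplies p-values by the number of pairs (capped at 1).
#'
#' @param report data.frame from [zoneDistribution()] (columns \code{zone},
#'   \code{count}, \code{size}).
#' @param alpha significance level, default 0.01.
#' @param pairs "all" (default) or "adjacent" (only consecutive zones).
#' @param bonferroni correct across pairs.
#' @param alternative passed to [twoProportionZ()].
#' @return data.frame with columns \code{zoneA}, \code{zoneB},
#'   \code{count1}, \code{n1}, \code{count2}, \code{n2}, \code{z},
#'   \code{pValue}, \code{significant}, \code{adjacent}.
#' @export
pairwiseZoneTests <- function(report, alpha = 0.01,
                              pairs = c("all", "adjacent"),
                              bonferroni = FALSE,
                              alternative = "two.sided") {
  pairs <- match.arg(pairs)
  r <- report[report$zone >= 1L, , drop = FALSE]
  empty <- r$size == 0L
  if (any(empty)) {
    warning("skipping zero-size zone(s): ",
            paste(r$zone[empty], collapse = ", "))
    r <- r[!empty, , drop = FALSE]
  }
  if (nrow(r) < 2L) stop("need at least two zones with positive size")
  idx <- utils::combn(nrow(r), 2L)
  rows <- lapply(seq_len(ncol(idx)), function(j) {
    a <- idx[1L, j]; b <- idx[2L, j]
    res <- twoProportionZ(r$count[a], r$size[a], r$count[b], r$size[b],
                          alpha = alpha, alternative = alternative,
                          label = sprintf("zone%d vs zone%d",
                                          r$zone[a], r$zone[b]))
    data.frame(zoneA = r$zone[a], zoneB = r$zone[b],
               count1 = r$count[a], n1 = r$size[a],
               count2 = r$count[b], n2 = r$size[b],
               z = res@z, pValue = res@pValue,
               adjacent = r$zone[b] - r$zone[a] == 1L)
  })
  out <- do.call(rbind, rows)
  if (pairs == "adjacent") out <- out[out$adjacent, , drop = FALSE]
  if (bonferroni) out$pValue <- pmin(1, out$pValue * nrow(out))
  out$significant <- out$pValue < alpha
  rownames(out) <- NULL
  out[, c("zoneA", "zoneB", "count1", "n1", "count2", "n2",
          "z", "pValue", "significant", "adjacent")]
}

#' Hypergeometric over-representation of pathways in a zone
#'
#' For each pathway, the upper-tail hypergeometric probability of drawing at
#' least the observed overlap: population = universe, successes = pathway
#' members in the universe, draws = the zone's proteins. Bonferroni
#' correction multiplies the raw p by the number of pathways tested (capped
#' at 1). The universe defaults to the network analysed -- it is the
#' sampling frame the zones were drawn from -- rather than the whole genome.
#'
#' @param zoneMembers character vector, the zone's node IDs.
#' @param pathways list of [AnnotationSet-class] objects (or named list of
#'   character vectors).
#' @param universe character vector of all node IDs in the sampling frame.
#' @param alpha corrected-p significance cutoff, default 0.01.
#' @return data.frame sorted by corrected then raw p: \code{pathway},
#'   \code{overlap}, \code{zoneSize}, \code{pathwaySize},
#'   \code{universeSize}, \code{p}, \code{pBonferroni},
#'   \code{proportion} (overlap / zone size), \code{significant}.
#' @export
hypergeomEnrichment <- function(zoneMembers, pathways, universe, alpha = 0.01) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  zm <- unique(zoneMembers)
  outside <- setdiff(zm, universe)
  if (length(outside)) {
    warning(length(outside), " zone member(s) outside the universe dropped")
    zm <- intersect(zm, universe)
  }
  N <- length(universe)
  n <- length(zm)
  m <- length(pathways)
  getMembers <- function(p) if (is(p, "AnnotationSet")) members(p) else p
  getName <- function(p, i) {
    if (is(p, "AnnotationSet")) setName(p)
    else if (!is.null(names(pathways))) names(pathways)[i]
    else paste0("pathway", i)
  }
  rows <- lapply(seq_along(pathways), function(i) {
    pw <- intersect(getMembers(pathways[[i]]), universe)
    K <- length(pw)
    q <- length(intersect(zm, pw))
    # P(X >= q); q = 0 gives 1 by construction
    p <- stats::phyper(q - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = getName(pathways[[i]], i),
               overlap = q, zoneSize = n, pathwaySize = K,
               universeSize = N, p = p,
               pBonferroni = min(1, p * m),
               proportion = if (n > 0) q / n else NA_real_)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$pBonferroni < alpha
  out <- out[order(out$pBonferroni, out$p, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-zone proportions of a pathway's proteins
#'
#' The fraction of each zone's nodes that belong to the pathway -- the same
#' arithmetic as [zoneDistribution()], reported per pathway (the
#' "proportion of proteins involved in each enriched pathway" table cells).
#'
#' @param decomposition a [ZoneDecomposition-class].
#' @param pathway an [AnnotationSet-class].
#' @return data.frame as returned by [zoneDistribution()].
#' @export
pathwayZoneProportions <- function(decomposition, pathway) {
  zoneDistribution(decomposition, pathway)
}
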