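# The pooled two-proportion z-test, pairwise zone comparisons, and
# hypergeometric over-representation, with exact oracles.

test_that("identical proportions give z = 0, p = 1", {
  r <- twoProportionZ(50, 100, 50, 100)
  expect_equal(zStatistic(r), 0)
  expect_equal(pValue(r), 1)
  expect_false(isSignificant(r))
})

test_that("degenerate all-zero and all-one tables are defined, not errors", {
  r0 <- twoProportionZ(0, 10, 0, 10)
  expect_equal(zStatistic(r0), 0)
  expect_false(isSignificant(r0))
  r1 <- twoProportionZ(10, 10, 5, 5)
  expect_equal(zStatistic(r1), 0)
  expect_equal(pValue(r1), 1)
})

test_that("hand-evaluated pooled formula on the zone1/zone2 essential counts", {
  # p1 = 161/374, p2 = 1002/4610, pooled = 1163/4984:
  # z = (p1 - p2) / sqrt(pooled (1 - pooled) (1/374 + 1/4610)) = 9.3721
  r <- twoProportionZ(161, 374, 1002, 4610)
  expect_equal(zStatistic(r), 9.3721, tolerance = 1e-4)
  expect_lt(pValue(r), 0.01)
  expect_true(isSignificant(r))
  # exact cross-check: Fisher agrees on significance
  expect_lt(fisherExactCheck(161, 374, 1002, 4610), 0.01)
})

test_that("the z-test is antisymmetric under swapping the samples", {
  set.seed(31)
  for (i in 1:25) {
    n1 <- sample(5:80, 1); n2 <- sample(5:80, 1)
    c1 <- sample(0:n1, 1); c2 <- sample(0:n2, 1)
    a <- twoProportionZ(c1, n1, c2, n2)
    b <- twoProportionZ(c2, n2, c1, n1)
    expect_equal(zStatistic(a), -zStatistic(b))
    expect_equal(pValue(a), pValue(b))
    expect_equal(sign(zStatistic(a)), sign(a@p1 - a@p2))
  }
})

test_that("one-sided alternatives integrate the correct tail", {
  r <- twoProportionZ(30, 50, 10, 50, alternative = "greater")
  expect_equal(pValue(r), pnorm(zStatistic(r), lower.tail = FALSE))
  r2 <- twoProportionZ(10, 50, 30, 50, alternative = "less")
  expect_equal(pValue(r2), pnorm(zStatistic(r2)))
})

test_that("invalid inputs are rejected", {
  expect_error(twoProportionZ(5, 0, 1, 10), "positive")
  expect_error(twoProportionZ(11, 10, 1, 10), "counts")
  expect_error(twoProportionZ(1, 10, 1, 10, alpha = 1.5), "alpha")
})

test_that("pairwise tests cover all pairs, flag adjacency, skip empty zones", {
  rep <- data.frame(zone = 0:3, count = c(0L, 30L, 30L, 0L),
                    size = c(1L, 60L, 120L, 0L))
  expect_warning(tt <- pairwiseZoneTests(rep), "zero-size")
  expect_equal(nrow(tt), 1L)  # only zones 1 and 2 remain
  expect_true(tt$adjacent)
  expect_true(tt$significant)  # 0.5 vs 0.25

  # identical proportions everywhere -> nothing significant
  rep2 <- data.frame(zone = 1:3, count = c(10L, 20L, 40L),
                     size = c(50L, 100L, 200L))
  tt2 <- pairwiseZoneTests(rep2)
  expect_equal(nrow(tt2), 3L)
  expect_false(any(tt2$significant))
  expect_equal(sum(tt2$adjacent), 2L)

  expect_error(pairwiseZoneTests(data.frame(zone = 1L, count = 1L,
                                            size = 10L)), "at least two")
})

test_that("zone1-5 essential counts: which adjacent pairs are significant is
           frozen against the Fisher oracle", {
  # printed counts/sizes; the z-test and Fisher agree pair by pair:
  # (1,2) and (2,3) significant at 0.01, (3,4) and (4,5) not
  rep <- data.frame(zone = 1:5,
                    count = c(161L, 1002L, 392L, 55L, 10L),
                    size = c(374L, 4610L, 3464L, 578L, 104L))
  tt <- pairwiseZoneTests(rep, alpha = 0.01, pairs = "adjacent")
  expect_equal(tt$significant, c(TRUE, TRUE, FALSE, FALSE))
  fisher <- mapply(fisherExactCheck, tt$count1, tt$n1, tt$count2, tt$n2)
  expect_equal(fisher < 0.01, tt$significant)
})

test_that("bonferroni over pairs is monotone and capped at 1", {
  rep <- data.frame(zone = 1:4, count = c(5L, 6L, 5L, 6L),
                    size = c(20L, 20L, 20L, 20L))
  raw <- pairwiseZoneTests(rep)
  adj <- pairwiseZoneTests(rep, bonferroni = TRUE)
  expect_true(all(adj$pValue >= raw$pValue))
  expect_true(all(adj$pValue <= 1))
  expect_equal(adj$pValue, pmin(1, raw$pValue * nrow(raw)))
})

test_that("hypergeometric p matches the closed-form single-term example", {
  # universe 20, pathway 5, zone 10, overlap 5:
  # P(X >= 5) = C(5,5) C(15,5) / C(20,10) = 3003/184756
  res <- hypergeomEnrichment(paste0("z", 1:10),
                             list(AnnotationSet("pw", paste0("z", 1:5))),
                             universe = paste0("z", 1:20))
  expect_equal(res$p, 3003 / 184756, tolerance = 1e-12)
  expect_equal(res$overlap, 5L)
})

test_that("hypergeometric upper tail equals brute-force draw enumeration", {
  set.seed(57)
  for (rep in 1:30) {
    N <- sample(6:15, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    universe <- sprintf("u%02d", 1:N)
    pw <- AnnotationSet("pw", universe[1:K])
    zone <- sample(universe, n)
    res <- hypergeomEnrichment(zone, list(pw), universe)
    q <- res$overlap
    expect_equal(res$p, bruteHypergeom(N, K, n, q), tolerance = 1e-10)
  }
})

test_that("saturated and empty overlaps give p = 1", {
  universe <- paste0("g", 1:12)
  zone <- universe[1:6]
  res <- hypergeomEnrichment(zone, list(AnnotationSet("all", universe)),
                             universe)
  expect_equal(res$p, 1)
  res0 <- hypergeomEnrichment(zone,
            list(AnnotationSet("none", paste0("g", 7:12))), universe)
  expect_equal(res0$overlap, 0L)  # disjoint by construction
  expect_equal(res0$p, 1)
  expect_error(hypergeomEnrichment(zone, list(), character(0)), "universe")
})

test_that("bonferroni correction scales with the number of pathways tested", {
  universe <- paste0("g", 1:30)
  zone <- universe[1:10]
  pw <- AnnotationSet("pw", universe[1:8])
  one <- hypergeomEnrichment(zone, list(pw), universe)
  dummy <- lapply(1:4, function(i) AnnotationSet(paste0("d", i),
                                                 universe[25:30]))
  five <- hypergeomEnrichment(zone, c(list(pw), dummy), universe)
  row <- five[five$pathway == "pw", ]
  expect_equal(row$pBonferroni, min(1, one$p * 5))
  expect_true(all(five$pBonferroni <= 1))
  # results sorted by corrected p
  expect_equal(five$pBonferroni, sort(five$pBonferroni))
})

test_that("pathway zone proportions recover planted prevalences", {
  sim <- generateCorePeriphery(hfpinLikeParams(seed = 8))
  truth <- sim$truth
  prev <- c(0.4, 0.2, 0.1)
  ann <- generateZoneBiasedAnnotation(truth, prev, seed = 80, name = "pw")
  dec <- zonePartition(sim$network, centres = plantedCentre(truth))
  rep <- suppressWarnings(pathwayZoneProportions(dec, ann))
  for (k in 1:3) {
    row <- rep[rep$zone == k, ]
    se <- sqrt(prev[k] * (1 - prev[k]) / row$size)
    expect_lte(abs(row$count / row$size - prev[k]), 3 * se)
  }
  # pathway covering exactly zone 1 is 100% there, 0% elsewhere
  z <- zoneOf(dec)
  pw1 <- AnnotationSet("z1", names(z)[z == 1L])
  rep1 <- pathwayZoneProportions(dec, pw1)
  expect_equal(rep1$percent[rep1$zone == 1L], 100)
  expect_true(all(rep1$percent[rep1$zone > 1L] == 0))
})
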