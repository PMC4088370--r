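# Annotation-to-zone distribution tables, the consistent-expression filter,
# and multi-set summaries.

# small fixed decomposition used throughout: star-with-tail
#   centre H; zone 1 = {A, B, C}; zone 2 = {D}
fixtureDec <- function() {
  net <- readEdgeListString("H\tA\nH\tB\nH\tC\nC\tD")
  zonePartition(net, centres = "H")
}

test_that("zone distribution counts exact intersections with percentages", {
  dec <- fixtureDec()
  rep <- suppressMessages(
    zoneDistribution(dec, AnnotationSet("s", c("A", "B", "D", "X"))))
  expect_equal(rep$zone, c(0L, 1L, 2L))
  expect_equal(rep$count, c(0L, 2L, 1L))
  expect_equal(rep$size, c(1L, 3L, 1L))
  expect_equal(rep$percent, c(0, 66.7, 100))
  expect_equal(attr(rep, "unmapped"), "X")
  # consistency: counts + unmapped + unreachable members = |members|
  expect_equal(sum(rep$count) + length(attr(rep, "unmapped")) +
                 length(attr(rep, "unreachableMembers")), 4L)
})

test_that("saturating and disjoint annotations hit 100% and 0%", {
  dec <- fixtureDec()
  all <- AnnotationSet("all", names(zoneOf(dec)))
  rep <- zoneDistribution(dec, all)
  expect_true(all(rep$percent == 100))

  far <- AnnotationSet("far", c("Q1", "Q2"))
  rep <- suppressMessages(suppressWarnings(zoneDistribution(dec, far)))
  expect_true(all(rep$count == 0L))
  expect_length(attr(rep, "unmapped"), 2L)

  expect_warning(suppressMessages(
    zoneDistribution(dec, AnnotationSet("none"))), "empty")
})

test_that("members at the centre land in the zone 0 row, not zone 1", {
  dec <- fixtureDec()
  rep <- zoneDistribution(dec, AnnotationSet("c", "H"))
  expect_equal(rep$count[rep$zone == 0L], 1L)
  expect_equal(rep$count[rep$zone == 1L], 0L)
})

test_that("percentages are invariant to node relabelling", {
  net <- readEdgeListString("H\tA\nH\tB\nA\tC")
  dec <- zonePartition(net, centres = "H")
  rep1 <- zoneDistribution(dec, AnnotationSet("s", c("A", "C")))
  relab <- c(H = "n4", A = "n3", B = "n2", C = "n1")
  e <- netEdges(net)
  net2 <- PINetwork(cbind(relab[e[, 1]], relab[e[, 2]]))
  dec2 <- zonePartition(net2, centres = "n4")
  rep2 <- zoneDistribution(dec2, AnnotationSet("s", c("n3", "n1")))
  expect_equal(rep1$percent, rep2$percent)
  expect_equal(rep1$count, rep2$count)
})

test_that("consistent-expression filter applies >= at the boundary", {
  calls <- matrix(0L, 3, 100,
                  dimnames = list(c("g99", "g98", "g100"),
                                  sprintf("s%03d", 1:100)))
  calls["g99", 1:99] <- 1L
  calls["g98", 1:98] <- 1L
  calls["g100", ] <- 1L
  pm <- PresenceMatrix(calls)
  kept <- members(filterConsistentGenes(pm, 0.99, "t"))
  expect_true("g99" %in% kept)    # 99/100 >= 0.99
  expect_false("g98" %in% kept)   # 98/100 < 0.99
  expect_true("g100" %in% kept)

  allOnes <- PresenceMatrix(matrix(1L, 2, 3,
                            dimnames = list(c("a", "b"), c("x", "y", "z"))))
  expect_setequal(members(filterConsistentGenes(allOnes, 0.99, "t")),
                  c("a", "b"))
})

test_that("filter is monotone in the threshold", {
  set.seed(9)
  pm <- generatePresenceMatrix(sprintf("g%02d", 1:40), 50,
                               presenceProb = runif(40), seed = 4)
  prev <- members(filterConsistentGenes(pm, 0.05, "t"))
  for (th in c(0.2, 0.5, 0.8, 0.95, 1)) {
    cur <- members(filterConsistentGenes(pm, th, "t"))
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("filter records its threshold and label", {
  pm <- PresenceMatrix(matrix(1L, 1, 2, dimnames = list("g", c("a", "b"))))
  gs <- filterConsistentGenes(pm, 0.75, "breast")
  expect_s4_class(gs, "ConsistentGeneSet")
  expect_equal(callThreshold(gs), 0.75)
  expect_equal(setName(gs), "breast")
})

test_that("multi-set summary averages percentages unweighted", {
  dec <- fixtureDec()
  # zone 1 percentages: set1 -> 1/3 = 33.3, set2 -> 3/3 = 100
  s1 <- AnnotationSet("one", "A")
  s2 <- AnnotationSet("two", c("A", "B", "C"))
  msd <- multiSetDistribution(dec, list(s1, s2))
  sm <- msd$summary
  avg <- sm[sm$annotation == "Average", ]
  expect_equal(avg$percent.zone1, roundHalfAway((33.3 + 100) / 2, 1))

  # single set: average row equals the set's row
  msd1 <- multiSetDistribution(dec, list(s2))
  expect_equal(unlist(msd1$summary[2, -(1:2)]),
               unlist(msd1$summary[1, -(1:2)]))

  # two sets with zone percentages 2.0 and 4.0 average to 3.0
  expect_equal(roundHalfAway(mean(c(2.0, 4.0)), 1), 3.0)
})

test_that("random annotation prevalence is recovered near global prevalence", {
  # permuting membership uniformly keeps the expected per-zone proportion
  # equal to the global prevalence; Monte-Carlo at 3 standard errors
  sim <- generateCorePeriphery(hfpinLikeParams(seed = 2))
  dec <- zonePartition(sim$network, centres = plantedCentre(sim$truth))
  nodes <- names(zoneOf(dec))
  p <- 0.3
  set.seed(123)
  rep <- zoneDistribution(dec, AnnotationSet("rand",
           sample(nodes, round(p * length(nodes)))))
  big <- rep$size >= 100  # only zones large enough for the normal bound
  se <- sqrt(p * (1 - p) / rep$size[big])
  expect_true(all(abs(rep$count[big] / rep$size[big] - p) <= 3 * se))
})
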