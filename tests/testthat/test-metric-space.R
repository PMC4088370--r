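# Distances, eccentricity, centre, zones and per-zone metrics, checked on
# hand-solvable graphs and against the Floyd-Warshall oracle.

pathNet <- readEdgeListString("A\tB\nB\tC\nC\tD\nD\tE")

test_that("BFS distances match the hand solution on a path", {
  d <- shortestPathLengths(pathNet, "C")
  expect_equal(d[order(names(d))], c(A = 2L, B = 1L, C = 0L, D = 1L, E = 2L))
  expect_error(shortestPathLengths(pathNet, "Z"), "unknown source")
})

test_that("disconnected nodes are absent from the distance map", {
  net <- PINetwork(cbind("A", "B"), nodes = "F")
  d <- shortestPathLengths(net, "A")
  expect_false("F" %in% names(d))
  expect_equal(unname(d[c("A", "B")]), c(0L, 1L))
})

test_that("eccentricity on path and star graphs", {
  expect_equal(eccentricity(pathNet, "C"), 2L)
  expect_equal(eccentricity(pathNet, "A"), 4L)
  star <- readEdgeListString("H\tL1\nH\tL2\nH\tL3\nH\tL4\nH\tL5")
  expect_equal(eccentricity(star, "H"), 1L)
  expect_equal(eccentricity(star, "L3"), 2L)
  iso <- PINetwork(nodes = "A")
  expect_equal(eccentricity(iso, "A"), 0L)
})

test_that("centre of a path is its midpoint; 4-cycle is fully tied", {
  fc <- findCentre(pathNet)
  expect_equal(fc$centres, "C")
  expect_equal(fc$radius, 2L)

  cyc <- readEdgeListString("A\tB\nB\tC\nC\tD\nD\tA")
  fc <- findCentre(cyc)
  expect_setequal(fc$centres, c("A", "B", "C", "D"))
  expect_equal(fc$radius, 2L)

  expect_error(findCentre(PINetwork()), "empty")
})

test_that("the centre is the eccentricity minimiser, not the max-degree hub", {
  # lollipop: hub H has degree 5 but sits at the end of a long handle;
  # the metric centre is M, halfway along the handle
  net <- readEdgeListString(paste(
    "H\tL1", "H\tL2", "H\tL3", "H\tL4",
    "H\tM1", "M1\tM", "M\tM2", "M2\tT1", "T1\tT2",
    sep = "\n"))
  deg <- nodeDegree(net)
  expect_equal(names(which.max(deg)), "H")
  expect_equal(findCentre(net)$centres, "M")
})

test_that("zone partition layers a star and a path as expected", {
  star <- readEdgeListString("H\tL1\nH\tL2\nH\tL3")
  dec <- zonePartition(star)
  expect_equal(centres(dec), "H")
  expect_equal(unname(zoneSizes(dec)), c(1L, 3L))

  dec <- zonePartition(pathNet, centres = "C")
  z <- zoneOf(dec)
  expect_setequal(names(z)[z == 1L], c("B", "D"))
  expect_setequal(names(z)[z == 2L], c("A", "E"))
  expect_equal(radiusOf(dec), 2L)
  expect_error(zonePartition(pathNet, centres = "Z"), "not in the network")
})

test_that("multi-centre zones take the minimum distance over centres", {
  # path A-B-C-D-E with centres {A, E}: hand-derived min-over-centres BFS
  dec <- zonePartition(pathNet, centres = c("A", "E"))
  z <- zoneOf(dec)
  expect_equal(unname(z[c("A", "E")]), c(0L, 0L))
  expect_setequal(names(z)[z == 1L], c("B", "D"))
  expect_equal(names(z)[z == 2L], "C")
  expect_equal(radiusOf(dec), 2L)
})

test_that("unreachable nodes are listed, not zoned", {
  net <- PINetwork(rbind(c("A", "B"), c("X", "Y")))
  dec <- zonePartition(net, centres = "A")
  expect_setequal(unreachableNodes(dec), c("X", "Y"))
  expect_false(any(c("X", "Y") %in% names(zoneOf(dec))))
})

test_that("zone metrics use full-network degrees and count quills", {
  star <- readEdgeListString("H\tL1\nH\tL2\nH\tL3\nH\tL4\nH\tL5")
  m <- zoneMetrics(star, zonePartition(star))
  expect_equal(m$zone, 1L)
  expect_equal(m$nodes, 5L)
  expect_equal(m$aveDegree, 1)
  expect_equal(m$quills, 5L)

  m <- zoneMetrics(pathNet, zonePartition(pathNet, centres = "C"))
  expect_equal(m$zone, c(1L, 2L))
  expect_equal(m$nodes, c(2L, 2L))
  expect_equal(m$aveDegree, c(2.0, 1.0))
  expect_equal(m$quills, c(0L, 2L))

  mc <- zoneMetrics(pathNet, zonePartition(pathNet, centres = "C"),
                    includeCentre = TRUE)
  expect_equal(mc$zone[1], 0L)
  expect_equal(mc$nodes[1], 1L)
})

test_that("diameter of path and complete graphs", {
  expect_equal(networkDiameter(pathNet), 4L)
  k4 <- readEdgeListString("A\tB\nA\tC\nA\tD\nB\tC\nB\tD\nC\tD")
  expect_equal(networkDiameter(k4), 1L)
})

test_that("distances, eccentricities, centres and diameter match the
           Floyd-Warshall oracle on random graphs", {
  set.seed(20240901)
  for (rep in 1:60) {
    n <- sample(4:15, 1)
    net <- randomNetwork(n, runif(1, 0.15, 0.6))
    D <- fwDistances(net)
    # distances from a random source
    src <- sample(netNodes(net), 1)
    d <- shortestPathLengths(net, src)
    srcRow <- D[src, ]
    oracle <- srcRow[is.finite(srcRow)]  # vector subset keeps names at length 1
    expect_setequal(names(d), names(oracle))
    nm <- sort(names(d))
    expect_equal(unname(d[nm]), as.integer(oracle[nm]))
    # eccentricity of a random node
    v <- sample(netNodes(net), 1)
    expect_equal(eccentricity(net, v),
                 as.integer(max(D[v, is.finite(D[v, ])])))
    # centre set, radius, diameter
    fc <- findCentre(net)
    oc <- fwCentre(D)
    expect_equal(fc$centres, oc$centres)
    expect_equal(fc$radius, oc$radius)
    expect_equal(networkDiameter(net), oc$diameter)
  }
})

test_that("decomposition invariants hold on random graphs", {
  set.seed(77)
  for (rep in 1:40) {
    net <- randomNetwork(sample(5:15, 1), runif(1, 0.1, 0.5))
    dec <- zonePartition(net)
    z <- zoneOf(dec)
    # partition: zones + unreachable = node set, disjoint
    expect_setequal(c(names(z), unreachableNodes(dec)), netNodes(net))
    expect_equal(anyDuplicated(c(names(z), unreachableNodes(dec))), 0L)
    # centres at zone 0, radius = max zone, bounds
    expect_true(all(z[centres(dec)] == 0L))
    expect_equal(max(z), radiusOf(dec))
    expect_gte(diameterOf(dec), radiusOf(dec))
    # the 2*radius bound needs a single common centre in the triangle
    # inequality; tied centres only guarantee radius <= diameter
    if (length(centres(dec)) == 1L)
      expect_lte(diameterOf(dec), 2L * radiusOf(dec))
    # zone adjacency: every zone-k node has a neighbour at k-1
    e <- netEdges(net)
    for (v in names(z)[z >= 1L]) {
      nb <- c(e[e[, 1] == v, 2], e[e[, 2] == v, 1])
      expect_true(any(z[intersect(nb, names(z))] == z[v] - 1L))
    }
  }
})

test_that("zone metrics TSV export carries centre, radius and diameter", {
  dec <- zonePartition(pathNet)
  f <- tempfile()
  writeZoneMetrics(zoneMetrics(pathNet, dec), dec, f)
  lines <- readLines(f)
  expect_equal(lines[1], "# centre: C")
  expect_equal(lines[2], "# radius: 2")
  expect_equal(lines[3], "# diameter: 4")
  tab <- read.delim(f, comment.char = "#")
  expect_equal(tab$zone, c(1L, 2L))
})

test_that("distances and diameter also agree with igraph", {
  # second, independent implementation (igraph's BFS) alongside the
  # Floyd-Warshall oracle
  set.seed(501)
  for (rep in 1:10) {
    net <- randomNetwork(sample(6:14, 1), runif(1, 0.2, 0.5))
    e <- netEdges(net)
    ig <- igraph::graph_from_data_frame(as.data.frame(e), directed = FALSE,
                                        vertices = netNodes(net))
    src <- sample(netNodes(net), 1)
    d <- shortestPathLengths(net, src)
    igd <- igraph::distances(ig, v = src)[1, ]
    igd <- igd[is.finite(igd)]
    nm <- sort(names(d))
    expect_setequal(names(d), names(igd))
    expect_equal(unname(d[nm]), as.integer(igd[nm]))
    comp <- igraph::components(ig)
    lcc <- names(comp$membership)[comp$membership ==
                                    which.max(comp$csize)]
    expect_equal(networkDiameter(net),
                 as.integer(igraph::diameter(
                   igraph::induced_subgraph(ig, lcc), unconnected = FALSE)))
  }
})
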