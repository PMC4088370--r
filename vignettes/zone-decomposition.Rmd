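---
title: "Zone decomposition of protein interaction networks as metric spaces"
author: "PINzones"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zone decomposition of protein interaction networks as metric spaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PINzones)
```

## The model

A protein interaction network is treated as a simple undirected graph over
gene-symbol node IDs and, through the hop-count shortest-path distance
$d(u, v)$, as a finite metric space. Three quantities organise the analysis:

* **eccentricity** $\mathrm{ecc}(v) = \max_u d(v, u)$ over $v$'s connected
  component;
* the **topological centre**, the set of nodes minimising eccentricity, with
  the minimum value being the **radius**; the maximum eccentricity is the
  **diameter**;
* **zones**: zone $k$ is the set of nodes at distance exactly $k$ from the
  nearest centre. Zone 1 interacts directly with the centre; every zone-$k$
  node ($k \ge 1$) has, by construction of breadth-first layers, at least one
  neighbour in zone $k-1$.

The centre is a purely metric notion. It deliberately is *not* the
highest-degree hub: `findCentre()` returns the eccentricity minimisers, and
the test suite includes a graph whose max-degree node is not the centre. In
the human networks that motivated this design the centre is a single protein
(a MAP kinase in each case), but the method does not assume uniqueness: all
tied minimisers are returned, and zones then use the minimum distance over
the centre set.

### Assumptions and degenerate inputs

* Graphs are simple: self-loops are dropped and duplicate or reversed edges
  collapsed at construction time, each with a logged count. The degree-1
  "quill" statistic presupposes this.
* Eccentricity, centre and diameter are computed on the **largest connected
  component**; nodes of smaller components are reported as `unreachable` and
  carry no zone index. "Zones around the centre" can only cover nodes at a
  finite distance from it, and the analysis set is the giant component.
  Component-size ties are broken toward the component containing the
  lexicographically smallest node ID, for determinism.
* Node identity is exact string match. No case folding, alias resolution or
  ID mapping is attempted, because any silent symbol normalisation would
  change zone counts. Merging two networks (`mergeNetworks()`) is the plain
  union of node and canonicalised edge sets: commutative and idempotent.
* With a **single** centre $c$ the triangle inequality gives
  $\mathrm{radius} \le \mathrm{diameter} \le 2\,\mathrm{radius}$, and the
  class validity enforces it. With tied centres only the lower bound holds:
  the covering radius $\max_v \min_{c} d(c, v)$ (the maximum zone index) can
  be smaller than half the diameter — a 4-cycle has covering radius 1 and
  diameter 2 under its four tied centres. Validity therefore applies the
  upper bound to single-centre decompositions only.
* An empty network is an error for `findCentre()`/`zonePartition()`; an
  empty file is a *valid* empty network for the readers.

## Zone tables and rounding

`zoneMetrics()` reports, per zone, the node count, average/minimum/maximum
degree and the quill count, with degrees always taken in the **full**
network, not the zone-induced subgraph. The centre (zone 0) is reported
separately from the zone table — centre proteins are named, not counted in
zones. `zoneDistribution()` reports, per zone, the exact intersection count
with an annotation set, the zone size, and the percentage
$100\,\mathrm{count}/\mathrm{size}$.

All printed percentages use **one decimal, rounding half away from zero**
(`roundHalfAway()`), because published zone tables of this kind mix rounding
conventions from cell to cell (some cells truncate, some round); fixing one
convention and documenting it beats reproducing an inconsistency. Percentage
assertions in the test suite are restricted to cells where the printed value
agrees with this convention. Multi-set summaries add an `Average` row: the
unweighted arithmetic mean of the per-set percentages per zone (absent sets
contribute 0), again to one decimal.

Annotation members absent from the network are counted and logged, never
silently dropped; members falling on the centre go to a zone 0 row rather
than zone 1; members in the network but outside the centre's component are
reported via an attribute.

## Statistics

**Two-proportion z-test.** Between-zone differences in annotation
proportions are tested with the standard pooled statistic
$z = (p_1 - p_2)/\sqrt{\hat p(1-\hat p)(1/n_1 + 1/n_2)}$ with
$\hat p = (x_1+x_2)/(n_1+n_2)$ and a two-sided normal p-value at
$\alpha = 0.01$ by default. Design choices:

* no continuity correction — `fisherExactCheck()` wraps Fisher's exact test
  as the exact cross-check instead;
* a one-sided mode is available by flag, since the scientific claims are
  directional (central zones have *higher* proportions);
* when the pooled proportion is 0 or 1 the variance vanishes, but then the
  two sample proportions are necessarily equal, so the test is defined as
  $z = 0$, $p = 1$;
* pairwise tests across zones are reported per pair without multiplicity
  correction by default (matching per-pair significance reporting);
  `bonferroni = TRUE` corrects across the pairs tested. Both "all pairs" and
  "adjacent pairs only" modes exist because which pairs were historically
  tested is not recorded.

An exhaustive sweep over every $2\times2$ table with both sample sizes up to
50 (1,755,625 tables) freezes the disagreement set between the z-test and
two-sided Fisher at $\alpha = 0.01$: 50,196 tables (2.9%), of which 50,124
are z-significant but not Fisher-significant — the familiar
anti-conservatism of the normal approximation in small samples — and 72 the
reverse. On the printed essential-gene counts for zones 1–5, the adjacent
pairs (1,2) and (2,3) are significant at 0.01 while (3,4) and (4,5) are not,
and Fisher agrees on all four calls; blanket "all between-zone differences
are significant" claims should therefore be read per pair.

**Over-representation.** Pathway enrichment per zone is the upper-tail
hypergeometric probability $P(X \ge \text{overlap})$ with population =
universe, successes = pathway ∩ universe, draws = the zone's nodes, with
Bonferroni correction over the pathways tested (cutoff 0.01 by default).
The universe defaults to the network's node set, not the genome: the network
is the sampling frame the zones partition. Raw p-values are validated
against brute-force enumeration of all $\binom{N}{n}$ draws for universes up
to 15.

**Consistent-expression filter.** `filterConsistentGenes()` keeps genes
whose presence fraction is $\ge$ the threshold (default 0.99, i.e. "present
in at least 99% of samples"); the boundary is inclusive, so 99/100 samples
passes at 0.99. The comparison adds a $10^{-12}$ float guard only — counts
are integral. Gene expression stands proxy for protein expression: gene IDs
map to nodes by identity.

## The synthetic generator and what it does (not) show

`generateCorePeriphery()` plants a known decomposition instead of hoping one
emerges: a single centre; shells of given sizes with every zone-1 node wired
to the centre (the centre degree is therefore exactly `zoneSizes[1]` — any
centre-adjacent node *is* zone 1, so a separate centre-degree knob would be
inconsistent); a guaranteed parent edge from every shell node into the
previous shell; Bernoulli intra-shell (`pIntra`) and adjacent-shell
(`pAdjacent`) extras with outward-decaying defaults; and planted quills
(degree-1 nodes) dominating the outer shells.

Two structural guarantees make the ground truth exact rather than
probabilistic:

1. **Zone exactness.** With `nNoise = 0` every edge joins equal or adjacent
   shells and every node has a parent edge, so the planted zone index equals
   the true distance from the centre. With noise edges, shortcuts can only
   *shorten* distances, so the computed zone index is $\le$ the planted one
   for every node — both asserted in the tests.
2. **Centre uniqueness.** Two reserved centre-to-rim *chains* — paths whose
   interior nodes carry no other edges — force every non-centre node $u$ to
   need $K + 1$ steps to reach the tip of a chain it does not sit on
   (chain interiors are reachable only through the centre), while the centre
   reaches everything within the radius $K$. The planted centre is thus the
   unique eccentricity minimiser by construction, deterministically, for any
   seed.

The shipped preset (`hfpinLikeParams()`) uses five shells of sizes
19/230/173/29/5 (~460 nodes, the observed shape of large human PINs scaled
down by ~20× so the full pipeline and test suite run in seconds),
`pIntra = (0.50, 0.06, 0.01, 0.01, 0)`, `pAdjacent = (0.25, 0.04, 0.015,
0.02)` and quill counts (0, 9, 33, 15, 3) scaled from the same source shape.
This reproduces the qualitative signature — average degree ≈ 66 in zone 1
collapsing to 1 in zone 5, outer zones mostly quills, >90% of nodes within
distance 3 of the centre. The noise variant adds 30 uniform random edges.

`generateZoneBiasedAnnotation()` includes each node independently with its
zone's prevalence (zones beyond the supplied vector get 0), emulating
annotation classes whose prevalence decays outward;
`generatePresenceMatrix()` draws i.i.d. Bernoulli calls. All generators are
bit-reproducible given their seed.

**What passing these tests shows — and does not.** The synthetic networks
validate the *algorithms*: distances, centre, zones, tables and tests behave
exactly as specified on graphs with known structure. They do not certify
anything about real interactomes: real PINs have heavy-tailed degree
distributions, correlated annotations, false-positive and missing edges, and
no guarantee of a unique centre. Recovery of a planted annotation prevalence
is a calibration check of the mapping machinery, not evidence that any
biological class is so distributed. Calibration is asserted on the
seed-averaged recovered prevalence (20 seeds, tolerance 3 binomial standard
errors per zone); individual seeds exceed a per-draw 3-SE band at the
expected binomial rate (~0.3% of draws), which is noise, not
miscalibration.

## Pipeline determinism and problem sizes

`runFullAnalysis()` writes a fixed set of sorted, timestamp-free TSVs plus a
`manifest.yaml` (inputs with MD5 checksums, package version, seed,
parameters, full configuration). Identical configuration and seed give a
byte-identical analysis bundle, and the manifest alone suffices to re-run
(`runFromManifest()`). A single top-level seed drives any synthetic steps;
derived sub-seeds keep stages independent of one another.

Default problem sizes were chosen so the whole suite stays fast while still
exercising every code path at meaningful scale: the ~460-node preset for
end-to-end runs, 200 random graphs of ≤ 15 nodes for the Floyd–Warshall
oracle sweep, universes ≤ 15 for exact hypergeometric enumeration, and
sample sizes ≤ 50 for the exhaustive z-vs-Fisher sweep. Larger networks are
handled by the same code (all-pairs BFS is $O(VE)$; the ~10⁴-node scale of
real human PINs is minutes, not hours), but they are inputs the user
supplies — the package does not download or bundle any interactome.

## Known limitations

* Hop-count distances only: no edge weights, confidences or directions.
* Edge-list formats cannot represent isolated nodes; `writeEdgeList()` warns
  when it must drop them.
* The centre computation is exact (all-pairs BFS), not approximated; for
  networks far beyond 10⁵ nodes a sampling or pruning strategy would be
  needed.
* Zone tables for multi-centre decompositions use the covering radius (max
  zone index), which is smaller than the graph radius reported by
  `findCentre()` whenever centres are tied and far apart; the single-centre
  case — the one observed in practice — has no such gap.
* The enrichment machinery tests user-supplied gene sets; it bundles no
  pathway database and does not attempt to reproduce any specific web
  service's p-values.
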