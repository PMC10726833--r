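---
title: "Methods: PPI network crosstalk analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PPI network crosstalk analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppicrosstalk)
```

This vignette documents the models, conventions and design choices behind
`ppicrosstalk`, in the spirit of a methods section: what each stage assumes,
which parameters matter, and what the synthetic-data experiments do and do
not demonstrate about real data.

## Interaction filtering

Raw interaction evidence arrives as publication-annotated records with a
confidence score. Two scoring dialects coexist in practice: probability-like
scores in $[0,1]$ (BioGRID physical evidence, STRING combined scores rescaled
from 0–1000), and unbounded scores above 1 produced by some quantitative
assays. The filter treats these as disjoint strata keyed by publication:

* **Physical-only.** Only records typed `physical` pass; genetic records and
  records whose type is unrecognized are dropped and counted. Keeping
  unknown types silently would bias downstream networks toward whichever
  source formats its types unexpectedly.
* **Confidence cutoff** (probability-like publications): keep
  `score >= 0.85`. "Below the threshold is removed" makes the cutoff
  inclusive, so a score of exactly 0.85 survives.
* **Overflow rule** (publications containing any score $> 1$): keep records
  scoring *strictly* above $1.5 \times$ the publication's mean score. The
  strict inequality implies a single-record publication above 1 is always
  dropped (its mean equals its own score) — intentional, since a lone
  unbounded score carries no within-publication context to judge it by.

The overflow rule is a one-shot selection, not an idempotent filter:
re-applying it to its own output re-computes the mean over the survivors and
would discard more records. The pipeline therefore applies it exactly once,
in the order physical → overflow → confidence → merge. Because the two score
rules act on disjoint publication strata, exchanging their order does not
change the result (tested). The per-publication mean is computed *after* the
physical-only filter, i.e. over the records the score rules can actually act
on.

Merging canonicalizes pairs: orientations collapse (`A–B` = `B–A`),
self-interactions are removed by default (every downstream statistic —
density, clustering, MCODE density scores — assumes a simple graph), the
maximum score and the union of source labels are retained. Gene symbols are
uppercased and whitespace-trimmed; no alias resolution is attempted, so
symbol variants from different sources remain distinct nodes.

## Network construction

Networks are built by inducing the filtered pair set on a seed gene list;
optionally the seed set is first expanded by its first neighbors (the
two-step construction: expand, then induce on the expanded set). Seeds with
no retained interaction are excluded from the node set by default — which is
why a network can have fewer nodes than seed proteins — with a flag to keep
them as isolates. Nodes carry `role` (seed/neighbor) and `origin` tags;
merging two networks unions nodes and edges and tags nodes present in both
origins as `both`, so the provenance of a combined network remains
queryable. `overlap_summary()` computes exclusive node/edge counts for every
non-empty subset of networks (Venn-diagram algebra).

## Topological conventions

All statistics follow the Cytoscape NetworkAnalyzer conventions, which
matters because published tables are only reproducible under the same
treatment of disconnected graphs:

* geodesics are computed within each connected component; unreachable pairs
  never enter a mean or a maximum;
* closeness centrality is $1/\mathrm{asp}(v)$, the reciprocal of the node's
  mean geodesic distance to reachable nodes — so closeness and asp are
  mutually redundant and the identity $C(v)\cdot \mathrm{asp}(v)=1$ is an
  internal consistency check;
* radiality is $(\Delta + 1 - \mathrm{asp}(v))/\Delta$ with $\Delta$ the
  *component* diameter. Evaluated at published values (asp 4.564 and 6.507
  in a diameter-18 component) this convention reproduces the printed
  3-decimal radialities (0.802, 0.694), which is how the choice of component
  versus global diameter was settled;
* the network clustering coefficient averages the node values over **all**
  nodes, counting degree-$<2$ nodes as 0 (the NetworkAnalyzer default; a
  different convention that averages over degree-$\ge 2$ nodes only would
  inflate sparse networks);
* heterogeneity is the coefficient of variation of the degree distribution
  with population (not sample) variance; it is 0 for regular graphs;
* hub tables sort by degree with lexicographic tie-break, for
  reproducibility.

Reported tables round to 3 decimals; full precision is kept internally.

## MCODE

The molecular-complex detection algorithm is implemented from scratch:

1. **Weighting.** For each vertex $v$, take the subgraph induced by its
   closed neighborhood, find its highest $k$-core, and set
   $w(v) = k \times \text{density(core)}$, using simple-graph density
   $2E/(n(n-1))$. Core numbers use standard iterative pruning.
2. **Seeding and expansion.** Seeds are processed in decreasing weight
   (ties by name) among unassigned vertices. Expansion is breadth-first from
   the seed, admitting unassigned neighbors with
   $w(u) \ge w(\text{seed}) \times (1 - \text{cutoff})$ up to `max_depth`;
   a vertex rejected for a cluster is not revisited for that cluster.
3. **Post-processing.** Haircut removes singly-connected members; clusters
   whose induced subgraph lacks a $k$-core of order `k_core` are discarded.
   Fluff is exposed in the parameter object but not implemented.

Cluster score is $\text{density} \times \text{size}$, so an $n$-clique
scores $n$. Edge counts are reported on the deduplicated simple graph:
published MCODE exports sometimes count multi-edges (a 5-node cluster listed
with 23 edges exceeds the simple maximum of 10) while their scores still
reconcile with simple density — this package keeps both columns consistent
with the simple graph. Parameter defaults are node score cutoff 0.2, K-core
2, max depth 100, haircut on, fluff off. Tie-breaks (weight, then name) make
the output deterministic.

## GO enrichment

Over-representation uses the exact hypergeometric upper tail, accumulated in
log space via `lchoose` so genome-scale tails ($N \approx 2\times 10^4$,
$p < 10^{-15}$) do not underflow. The correction is Bonferroni with $m$
equal to the number of distinct terms annotated to at least one query gene
(reported as an attribute for transparency); the background $N$ defaults to
the number of annotated genes in the annotation file and can be overridden,
since different curation snapshots use different universes. Query genes
absent from the universe stay in the denominator $n$ — a 24-gene cluster is
reported as "$k$ of 24" even if some members are unannotated — but cannot
contribute to $k$. Annotations can be closed under `is_a` ancestors
(true-path rule) before testing; the OBO reader extracts `is_a` edges only
and rejects cyclic ontologies.

## Linear-path decomposition

Path length is counted in **proteins, endpoints included** (a 6-protein
path has 5 edges); a flag exposes edge-count semantics. The network is
traversed as undirected — physical interactions carry no direction, and the
source/sink roles impose the only orientation. Enumeration is depth-first
with two guards: a precomputed breadth-first distance-to-sink prunes any
branch whose remaining edge budget cannot reach the sink, and a `max_paths`
cap aborts loudly rather than silently truncating. Neighbors are visited in
lexicographic order, making the output ordering deterministic. Participation
percentages are computed over the pooled path list; the bottleneck ranking
averages participation across the requested lengths (default 5–8,
bracketing typical characteristic path lengths of such networks) and
excludes the endpoints, which trivially sit on every path.

Worst cases remain exponential: on dense graphs with generous length
budgets the guard exists precisely because pruning cannot help. Desk-scale
queries (lengths 5–8 on networks of order $10^3$ nodes) are feasible.

## Synthetic data and what it shows

The generators emulate the statistical structure the pipeline assumes:

* **Interactions**: publications of 8 records each, 25% using the overflow
  dialect (scores uniform on $[1.1, 10]$), the rest probability-like
  (uniform on $[0.5, 1]$, straddling the 0.85 cutoff); 80/15/5%
  physical/genetic/unknown types and occasional self-interactions. Keep/drop
  ground truth is computed at generation time directly from the declared
  rules.
* **Networks**: a preferential-attachment background (default 60 nodes,
  2 edges per new node), chosen because real PPI networks are scale-free
  with heavy-tailed degree distributions; planted modules are realized at
  their requested internal density (default one 6-clique) and wired to the
  background by exactly 2 bridge edges — enough to connect, too few to
  dilute the module density. The module-recovery experiments use a 20-node
  background, the hardest small setting in which background 2-cores could
  plausibly compete with the planted clique.
* **Annotations**: each planted term annotates $k$ genes inside its module
  and $K-k$ outside (default $K=8$, $k=5$ on the default module), plus
  uniform background terms and a universe-wide root term that fixes
  $N$ to the full node count.
* **Path testbeds**: layered graphs, complete bipartite between consecutive
  layers, single source and sink; the simple-path count at node-length equal
  to the layer count is exactly the product of interior layer widths.

Determinism is per-operation: each generator derives its own RNG stream
from (master seed, operation name), so adding a generator never perturbs the
output of another.

These experiments demonstrate algorithmic correctness (against planted
truth and independent oracles), not biological fidelity. Real interaction
data have correlated noise, study bias toward well-studied proteins,
incomplete annotation and inconsistent identifiers — none of which the
generators model. Passing the planted-recovery suites says the
implementation finds what is there under the stated conditions; it does not
certify recovery rates on any particular database snapshot.

## Numerical and testing choices

* The hypergeometric tail is validated two ways: exhaustively against
  enumeration of all $\binom{N}{n}$ draws for every parameterization with
  $N \le 12$, and against `stats::phyper` at genome scale. The
  implementation itself never calls `phyper`, keeping the cross-check
  independent.
* Topology is validated against a Floyd–Warshall triple-loop oracle on 200
  random graphs of up to 12 nodes; path enumeration against an unpruned
  all-sequence recursion on graphs of up to 10 nodes. These sizes make the
  oracles exact and exhaustive while the full suite stays fast.
* Recovery experiments use 50 seeded syntheses for module detection and 100
  for enrichment — large enough to expose a systematically broken rate,
  small enough to run in seconds.
* Degenerate inputs follow a "report missing, never fake a zero" rule:
  singleton components have undefined mean distances (`NA`), edgeless
  graphs undefined diameters, empty path lists produce empty tables with
  total 0.

## Known limitations

* No identifier mapping: symbol variants across sources remain distinct
  nodes.
* MCODE's fluff option is a stub; the haircut is a single pruning pass.
* The Bonferroni family is the only correction offered; with the published
  universe sizes any dominating correction yields the same accept/reject
  decisions at the printed precision, but FDR-style corrections are out of
  scope.
* Exhaustive path enumeration is exponential in the worst case; the
  `max_paths` guard turns pathological queries into loud errors, not
  answers.
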