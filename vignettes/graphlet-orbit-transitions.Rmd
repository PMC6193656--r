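---
title: "Comparing temporal networks by graphlet-orbit transitions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing temporal networks by graphlet-orbit transitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gotnet)
```

## The model

A temporal network is an ordered sequence of snapshots $S_1, \dots, S_s$
over a shared node universe, with *active-edge* semantics: an edge exists
only in the snapshots where it is listed. Static subgraph methods summarize
such data by collapsing it — either into one aggregate graph or into
per-snapshot summaries — and thereby lose the identity of *which* group of
nodes changed and *how*.

The fingerprint computed here keeps that identity. Within a connected
induced $k$-node subgraph (a *graphlet*), each node occupies an
*automorphism orbit*: the equivalence class of positions under the
graphlet's self-isomorphisms. The orbit is the node's role — center versus
leaf of a star, a 4-cycle position, a clique member. For a node set whose
induced subgraph is connected in two consecutive snapshots, each of its $k$
nodes performs one *orbit transition* from its role at $t$ to its role at
$t+1$. Accumulating these over all node sets and all consecutive snapshot
pairs yields the transition matrix

$$T_{x,y}(N) = \#\{\text{(node, snapshot pair) with role } x \text{ at } t
\text{ and } y \text{ at } t+1\},$$

an $|O| \times |O|$ summary of how roles persist and change. Node sets
connected in only one of the two snapshots contribute nothing: when a group
disconnects it stops being a group. Transitions are orbit-to-orbit, not
graphlet-restricted — a star center may become a clique member.

Two networks are compared by row-normalizing their matrices
($ntr_{i,j} = t_{i,j} / \sum_k t_{i,k}$, all-zero rows kept at zero) and
averaging cellwise agreement:

$$OTA(N_1, N_2) = \frac{1}{|O|^2} \sum_{i,j}
\bigl(1 - |ntr^{N_1}_{i,j} - ntr^{N_2}_{i,j}|\bigr) \in [0, 1].$$

Row normalization (rather than a global one) gives rare source orbits the
same weight as common ones; rare roles often separate networks better. For
comparisons *within* a set, `nota()` rescales the pairwise OTA values so
the most similar pair sits at 1 and the most dissimilar at 0.

```{r}
cat3 <- build_catalog(3)
tri_to_path <- temporal_network(
  list(snapshot(rbind(c(1, 2), c(2, 3), c(1, 3)), 3),
       snapshot(rbind(c(1, 2), c(2, 3)), 3)),
  nodes = c("a", "b", "c"))
got_matrix(tri_to_path, cat3)
```

The triangle's one orbit (O3) feeds the chain center (O1) once — node `b` —
and the chain periphery (O2) twice, as the orbit definitions force.

## Catalogs and orbit numbering

`build_catalog(k, directed)` enumerates every labeled graph on $k$ nodes
($2^{\binom{k}{2}}$ undirected, $2^{k(k-1)}$ directed), keeps the connected
ones, groups them into isomorphism classes by an exhaustive-permutation
canonical code (minimum adjacency bit string over all $k!$ relabelings), and
partitions each class's positions into orbits via its automorphisms. No
external canonical-labeling tool is involved; at $k \le 6$ determinism and
verifiability matter more than speed, and the whole $k = 6$ catalog builds
in about a second. The resulting totals — 3, 11, 58, 407 orbits for
undirected $k = 3..6$; 30 and 697 for directed $k = 3, 4$ — are asserted in
the test suite. Directed catalogs stop at $k = 4$: beyond that the
transition space ($|O|^2$) is impractically large.

Orbit ids must be deterministic because they index transition matrices.
Graphlets are ordered by (edge count, canonical code) and orbits within a
graphlet by smallest canonical position. The 4-node undirected catalog is
additionally pinned to the conventional numbering — star (center $O_1$,
leaf $O_2$), path, cycle ($O_5$), paw, diamond, clique ($O_{11}$) — with
higher-degree orbits first within a graphlet; the full mapping is emitted
by `export_catalog_json()`. Only those four names are fixed by convention;
the remaining ids follow the deterministic sort.

Each catalog also carries a lookup table from *any* labeled $k$-node
adjacency code to the global orbit id of each position. The census
therefore never canonicalizes during enumeration: classifying an occurrence
is one table access.

## Census

`enumerate_connected()` lists every connected induced $k$-subgraph exactly
once, using ESU-style recursive extension over exclusive neighborhoods
(implemented in C++). Per-node orbit counts (`orbit_frequency_matrix()`,
rows are graphlet degree vectors), graphlet frequencies, graphlet degree
distributions (`gdd_from_fr()`) and the degree distribution (`ndd()`)
derive from the same enumeration. Disconnected subgraphs are excluded by
construction — counting them would require scanning all $\binom{n}{k}$
subsets.

Matching between consecutive snapshots keys occurrences by their sorted
node tuple and holds at most two snapshots' occurrence indexes in memory.
Nodes that leave the network simply never match.

## Static baselines

Two classic static methods are included for comparison, both evaluated on
the aggregate network (the union of all snapshot edge sets):

* **GDD-agreement** (`gda()`): graphlet degree distributions are padded to
  a common multiplicity range, normalized by total area, and agree per
  orbit as $1 - \tfrac{1}{\sqrt 2}\lVert nG_j - nH_j \rVert_2$, averaged
  over orbits. No $1/p$ weighting is applied — normalization is by total
  area only, which departs from some of the older agreement literature and
  is documented here deliberately.
* **Motif fingerprints** (`motif_fingerprint()`): graphlet frequencies are
  scored against an ensemble of degree-preserving randomizations (double
  edge swaps; 100 replicates by default, 10 × |E| attempted swaps each) as
  $\delta = (f - f_0)/(f + f_0)$, normalized to unit length. $\delta$ is
  defined as 0 when $f = f_0 = 0$, avoiding NaNs for graphlets that never
  occur; no small-$\varepsilon$ correction is added.

## Synthetic models

`table1_models()` defines six evolving-model variants used as ground truth
in the grouping experiment: Erdős–Rényi and Barabási–Albert wiring with
edge-deletion probability $P(e^-) \in \{0, 0.5\}$, and Watts–Strogatz rings
with rewiring $\beta \in \{0, 0.2\}$. Defaults are 5 snapshots, 250 initial
nodes, 10% node growth per snapshot (floor rounding, new ids appended) and
density $E/N^2 = 0.01$, enforced exactly per snapshot by rounding for the
Erdős and Barabási families: each transition keeps surviving edges and tops
up — uniformly, or preferentially with weight degree + 1 so isolated
newcomers can attach — to $\mathrm{round}(0.01\,N^2)$ edges.

The Strogatz family instead maintains a persistent circular ordering of
nodes (new nodes spliced in uniformly at random) and rebuilds the ring
edges from that ordering each snapshot, wiring every node to its nearest
ring neighbors at the even degree closest to $2 \times 0.01 \times N$
(halves rounded up; degree 6 at $N = 250$), then rewires each edge
independently with probability $\beta$. Rebuilding from the persistent
ordering — rather than splicing edges incrementally — keeps every
$\beta = 0$ snapshot an exact ring lattice (uniform even degree, clustering
$3(d-2)/(4(d-1))$), which the tests assert; the cost is that a rewired edge
lives for one snapshot only. Consequently the exact edge-count law
$E = \mathrm{round}(0.01\,N^2)$ applies to the Erdős and Barabási families,
while rings satisfy their own degree law ($E = Nd/2$; density 0.012 at
$N = 250$) — the two constraints are mutually exclusive for a ring.

What the generators emulate: stable density, gradual node arrival, model-
characteristic wiring, and (optionally) heavy edge turnover. What they do
not emulate: bursty arrival, community structure, weighted or bipartite
interactions, and the size heterogeneity of real network collections — so
passing grouping tests shows the methods separate *wiring mechanisms*, not
that they classify arbitrary real-world categories.

## The grouping experiment

`run_grouping_experiment()` reproduces the synthetic evaluation protocol:
generate a replicated suite (replicate seeds derived from one master seed),
represent each network by method-specific features — motif scores (SM),
aggregate orbit frequencies (SG), concatenated per-snapshot orbit
frequencies (STG), or the flattened transition-count matrix (GoT) — reduce
by PCA keeping 99% of variance (centering only; features within a method
share a scale), min-max-normalize pairwise Euclidean distances, and sweep a
grouping threshold from 0 to 1 in steps of 0.001. Precision is the fraction
of grouped pairs sharing a model label (defined as 1 before anything is
grouped, so curves start at recall 0, precision 1), recall the fraction of
same-label pairs grouped, and $AUPR = \sum_k \Pr(k)\,\Delta Rec(k)$.

The unit of comparison is the **network**: one feature row per network.
A node-level representation (rows of `orbit_frequency_matrix()` or
`node_transition_vectors()`) is available for custom pipelines, but since
all six models share the node-growth schedule, averaging node vectors is a
constant rescaling of the network-level totals and changes nothing in the
distance geometry.

The test suite runs this experiment at a reduced scale (6 models × 5
replicates, 100 initial nodes, 5 snapshots, five master seeds) chosen so
the whole protocol replays in seconds per repetition. Two findings from
those runs are worth stating plainly. Transition features consistently
outrank the concatenated per-snapshot frequencies (STG) — temporal
*linkage* carries signal that per-snapshot summaries miss. But aggregate
orbit frequencies (SG) attain the highest AUPR at network level: summing a
network's orbit frequencies into a single row is a strong model signature
under these generators, especially with edge turnover, where the aggregate
accumulates several snapshots' worth of wiring. Accounts of transition
methods that report large advantages over static graphlets rest on
node-level comparison protocols whose remaining details (per-pair feature
joins, the similarity transform) are not fully recoverable; at network
level, with these models and sizes, the static aggregate baseline is
genuinely hard to beat, and the package reports that honestly rather than
tuning the protocol until the expected ordering appears.

## Numerical choices and degenerate inputs

* Snapshot indices are 0-based and contiguous; missing intermediate indices
  yield empty snapshots. Input edges are undirected (`b a` equals `a b`),
  duplicates collapse, self-loops drop with a warning.
* Characteristic path length is computed on the largest connected
  component; snapshots with fewer than two nodes there report 0.
* All-zero rows of a transition matrix stay all-zero under normalization;
  `ota()` of two never-occupied rows contributes full agreement.
* `nota()` on a set whose pairwise agreements are all equal returns 1
  everywhere with a warning, as does `distance_matrix()` on identical rows
  (all-zero, with a warning).
* Discretization bounds are closed on the right: rare $[0, 1/3]$, common
  $(1/3, 2/3]$, frequent $(2/3, 1]$.
* PCA on a constant feature matrix returns a single zero component;
  `precision_recall()` refuses single-class label sets (recall would be
  undefined).
* Replicate seeds are drawn from one master seed via `sample.int()`, so any
  integer master seed below $2^{31}$ reproduces a suite exactly.

## Limitations

Census cost grows exponentially in $k$ and with density; $k = 4$ is the
practical default (121 transition cells), $k = 5$ feasible on sparse
networks (3364 cells), and directed transitions at $k = 4$ (485k cells) are
gated behind the R API on purpose. The transition matcher requires exact
node-set persistence: data where identities churn completely between
snapshots produce near-empty matrices, and the metric degrades to
comparing zeros. Snapshot boundaries are taken as given; the method does
not choose the time resolution, although results depend on it.
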