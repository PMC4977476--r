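---
title: "Building phylogenies from pathway modules: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building phylogenies from pathway modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathmodtree)
```

This vignette is the package's own account of what it computes, which
knobs matter, and where genuinely open design choices were resolved.

## The problem

Species-specific renderings of a signal transduction pathway — for
instance the Wnt cascade as curated per organism in KEGG — differ in
which genes are present and how they interact.  Treating each rendering
as a graph, one can define a distance between species from the graphs
alone and build a phylogeny describing how the pathway developed.  The
package implements two such distances and the machinery around them:

* the **module distance** \(D_M\): decompose each pathway into modules,
  compare species by module-membership overlap;
* the **topology distance** \(D_P\): align whole graphs by graphlet
  signatures and score edge correctness.

Both feed neighbor joining; the resulting trees can be scored against
reference phylogenies by an exact optimal branch matching.

## Pathway graphs and KGML

A `pathway_graph` is an undirected simple graph.  KGML relations are
directional and may repeat; they are collapsed to simple undirected
edges at parse time because the module distance uses node membership
only, and graphlet counting presupposes simple undirected graphs —
"total degree" is a single scalar per node throughout.

Parsing decisions that were genuinely open:

* **Entry retention.** `gene` entries always become nodes, and
  `ortholog` entries are treated as gene-class too (their KO identifiers
  carry cross-species identity, which is the whole point of the member
  namespace).  `compound` entries are kept only on request
  (`include_compounds = TRUE`, default off: the distances are about gene
  content).  `map` links and legacy `enzyme` entries are dropped.
* **Group expansion.** A KGML `group` entry denotes a complex.  It is
  replaced by its component entries joined as a clique, and every
  relation touching the group is re-attached to all components —
  membership-based similarity needs genes, not complex placeholders.
* **Member identity across species.** No public statement fixes how
  genes should be matched one-to-one across species (orthology table
  vs. accession identity).  Both are supported: by default the entry
  name tokens are used verbatim with the species prefix stripped; a
  two-column namespace map (e.g. a KEGG Orthology table) can be supplied
  to any reader or pipeline call, and the choice is recorded in the run
  manifest.  This is the main reproducibility gap for real KEGG inputs
  and is deliberately surfaced as a user-level switch.

## Modularization

Modules are connected, disjoint node sets that keep most of their edges
internal.  The decomposition is governed by one integer factor `c`,
legal between 1 and the graph's maximum total degree:

1. every node with total degree ≥ `c` seeds its own module;
2. synchronous label propagation: each unassigned node adjacent to at
   least one module joins the module to which it has most edges, ties
   broken by the module containing its highest-degree neighbour, then by
   the module with the smallest member identifier;
3. seedless connected components become single whole modules; isolated
   nodes become singletons.

Tie-breaking is fully specified so the decomposition is deterministic
and independent of node iteration order.  Modules never overlap: the
species-similarity normalization below presupposes a fixed module list,
so overlapping variants are excluded by design.  Module count is
non-increasing in `c` (each component's count falls from its seed count
toward 1), which the test suite asserts across the full legal range.
The pipeline default is `c = 3`, a mid-range value for pathway graphs
whose maximum degrees sit around 5–10; it is always recorded in the run
manifest, and per graph the factor is capped at that graph's own maximum
degree so a shared value stays legal for every species.

## Module distances

For modules as member-identifier sets,
\(Sim(M_1,M_2) = |M_1 \cap M_2| / |M_1 \cup M_2|\),
\(S_M(x,y) = \sum_{i,j} Sim(M_i,M_j) / (m_1 m_2)\) over **all** module
pairs (no best-match shortcut), and \(D_M = 1 - S_M\).  Two
consequences are worth stating plainly:

* \(S_M(x,x) < 1\) whenever a species has more than one distinct
  module, so the assembled distance matrix forces its diagonal to zero
  explicitly — neighbor joining consumes off-diagonals only, and the
  contract is documented rather than hidden.
* With many small modules the grid average is dominated by unrelated
  pairs, so distances crowd toward 1; the phylogenetic signal lives in
  their differences.  See the design notes below for what this means in
  practice.

The implementation is vectorized (incidence-matrix cross products) and
is checked against a naive double-loop evaluator to below 1e-12 on
random inputs.

## Graphlet signatures and the topology distance

The 30 connected graphs on 2–5 nodes ("graphlets") have 73 node orbits.
The catalog is generated in code: graphlets are enumerated exhaustively,
canonicalized by the minimum adjacency bit-code over vertex
permutations, and ordered by size, edge count, degree sequence and
canonical code; orbits within a graphlet are ordered by degree,
neighbour degrees and triangle membership.  This deterministic numbering
reproduces the conventional indices for orbits 0–14 (edge, path,
triangle and the six 4-node graphlets); the published 73-orbit numbering
exists only in figure form, so the package's convention is its own — it
is used consistently on both sides of every comparison, and orbit 0
always counts edge endpoints (so equals degree).

Signature similarity between nodes uses the weighted logarithmic scheme
of graphlet-based alignment: per-orbit distance
\(w_i\,|\log(u_i+1)-\log(v_i+1)| / \log(\max(u_i,v_i)+2)\) with
\(w_i = 1 - \log o_i / \log 73\).  The dependency counts \(o_i\) are
computed from a subgraph-embedding relation (orbit *j* affects orbit *i*
when *j*'s graphlet embeds in *i*'s with a *j*-orbit node landing on the
*i*-orbit node) rather than transcribed from a table; orbit 0 gets
weight 1, and the single orbit affected by all others (the complete
5-node graphlet) gets weight 0 under this formula — a degenerate but
harmless endpoint of the weighting.

Alignment is greedy seed-and-extend: cost
\(2 - [(1-\alpha)(\deg u + \deg v)/(\max\deg G + \max\deg H) + \alpha\,
sim(u,v)]\), seed at the cheapest pair, then pair nodes sphere by sphere
(equal breadth-first radius around the two seeds) in cost order; new
seeds are drawn while unaligned nodes remain, components of the smaller
graph are processed in decreasing size, and leftovers are matched by
cost alone.  Ties break by cost, then degree gap, then smallest node-id
pair, making the aligner deterministic.  `alpha = 0.8` is the package
default — no value is claimed for any published study.  Edge correctness
of an edge-free graph is 1 by convention (vacuous condition; a warning is
emitted), and \(D_P\) always embeds the smaller graph in the larger so
the distance is symmetric.  The aligner is a heuristic: self-alignment
quality is asserted as a mean over random instances, not as perfection.

## Neighbor joining and sequence stand-ins

Tree building delegates to the classic neighbor-joining implementation
in `ape` behind a validating wrapper (symmetry, zero diagonal, no
missing values; the two-taxon case handled directly).  NJ is consistent
on additive matrices, which the suite exploits: distances read off
random planted trees must return those trees exactly (splits identical,
path lengths within 1e-9).  Negative branch lengths are kept as computed
by default; `clamp_negative` moves them to zero and compensates on the
sister branch for viewers that dislike them.

For reference trees from ribosomal RNA alignments the package provides
p-distances and the Jukes–Cantor transform with the pairwise-deletion
convention (a site is compared when neither sequence of the pair has a
gap or missing symbol; `U` reads as `T`, `N` and `?` count as missing).
More elaborate substitution models are out of scope — externally
computed matrices can be fed straight into `neighbor_joining()`.

## Comparing trees

Every branch of an unrooted tree induces a bipartition of the leaves.
Branch pairs are scored by pairing the sides both ways and taking the
better pairing's worse Jaccard index — identical splits score 1,
incompatible quartet splits score 1/3.  The branch map maximizing total
score is found by an exact assignment solve (a hand-written
Jonker–Volgenant-style Hungarian algorithm, checked against factorial
enumeration for small trees); when branch counts differ the smaller set
is padded with null partners scoring 0.

The percentage summary is `100 × total / max(branch count)` over **all**
branches, pendant and internal.  Published pairwise-comparison
percentages do not state their normalization; counting all branches
follows the rule "each branch is paired", is prominent in the
documentation, and an `internal_only` variant exists for exploration.
Branch lengths are ignored throughout — the comparison is topological.

## The synthetic generator

`simulate_family()` evolves a random connected ancestor graph along a
known phylogeny by Poisson-distributed node losses, node gains (fresh
members from the shared namespace, attached preferentially to
higher-degree nodes so hubs persist and modularization keeps structure)
and optional edge rewires.  Member identifiers are global, so module
overlap between leaves is exact set intersection by construction, and
`emit_kgml()` writes each leaf as a valid KGML file that parses back
identically — the generator is the package's self-contained stand-in
for a pathway database snapshot.

Default regime, chosen once: ancestor of 40 nodes at edge density 0.15,
loss and gain rates 0.08 events per unit branch length, planted-tree
branch lengths uniform on [30, 60].  The branch-length rule is sized so
every branch expects roughly 5 or more events, keeping the probability
of an entirely event-free branch — whose split no distance-based method
could recover — below about 1% per branch.

What the generator does **not** emulate: curation bias (real pathway
annotations are richer for model organisms), correlated gain/loss of
functionally linked genes, sequence evolution, and the sparse hub-and-
chain structure of hand-drawn pathway maps (Erdős–Rényi ancestors are
more homogeneous).  Passing the end-to-end tests therefore demonstrates
the pipeline's internal correctness and its behaviour under a clean
birth–death signal, not performance on real KEGG data.

## Behaviour of the module distance in the dense regime

One empirical property of the method deserves an honest note.  At the
test regime's density (mean degree near 6) the seeding rule at `c = 3`
makes most nodes seeds, so modules are mostly singletons and
\(S_M \approx |X \cap Y| / (m_1 m_2)\).  The per-species module counts
\(m\) then vary with gain/loss history, and the \(1/(m_1 m_2)\)
normalization injects species-specific distortion of the same order as
the phylogenetic signal.  In the suite's end-to-end experiment the
module tree recovers the planted topology in the large majority of
replicates, but a degenerate one-module-per-species control (distance =
one minus whole-set Jaccard) is at least as accurate on average in this
regime — the acceptance suite states the stronger expectation and
records the outcome as-is.  On sparse, hub-dominated graphs (the regime
of curated pathway maps, where `c = 3` yields a handful of sizeable
modules) the grid average behaves differently; the acceptance script's
module-vs-pathway comparison, which the module tree wins, is the
package-level reproduction of the method's motivating claim.

## Numerical and degenerate-input choices

* Distance matrices are exact rational arithmetic in double precision;
  no tolerance is applied before neighbor joining.
* Edge-free graphs: modularization bypasses the `c` range check (the
  interval is empty) and yields singletons; edge correctness is 1 by
  convention; empty graphs modularize to zero modules.
* Text outputs are formatted at 10 significant digits; JSON reports
  carry full doubles.  Re-running any CLI command with the same inputs
  and seed is byte-identical on primary outputs (manifests carry a
  timestamp and are provenance, not output).
* All randomness flows through explicit `seed` arguments; library calls
  save and restore the caller's RNG state.

## Problem sizes in the shipped tests

The suite favours exhaustively checkable sizes: orbit counts against
full subset enumeration on graphs of up to 12 nodes; branch matching
against factorial enumeration for trees of up to 7 branches; NJ
consistency on 5–15 leaves; the end-to-end experiment on 20 simulated
8-leaf families with 40-node ancestors; the pathway-tree arm of the
acceptance script on 3 of those families (graphlet alignment of 40-node
graphs is the one genuinely expensive stage).  These sizes were chosen
as the smallest at which each property is meaningfully exercised.

## Known limitations

* The modularization algorithm is one concrete, fully specified member
  of the family of degree-seeded decompositions; it is isolated behind
  `modularize()` so variants can be added without touching the distance
  stage.
* The aligner is greedy and heuristic; it does not attempt the exact
  (NP-hard) maximum-edge-correctness alignment, and no randomized
  restarts run by default.
* KGML reactions, directionality, stoichiometry and rendering
  coordinates are ignored by design.
* Real-data workflows (orthology mapping, reference alignments) require
  user-supplied inputs; the package performs no network access.
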