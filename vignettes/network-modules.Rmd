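---
title: "Signed signaling networks and differentially regulated modules: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signed signaling networks and differentially regulated modules: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(signalmods)
```

# The model

`signalmods` works with one carrier object throughout: a **signed directed
graph** whose nodes are annotated pathway entities and whose edges encode
controlling interactions — activation (+1) or inhibition (−1). Binding and
conversion semantics are deliberately out of scope: the graphs describe who
regulates whom, not how complexes assemble. An edge is identified by the
full `(source, target, sign)` triple, so a pair of genes may legitimately
be connected by both an activating and an inhibiting edge (databases often
report both, e.g. context-dependent regulation); only *identical* triples
are treated as duplicates. Self-loops are dropped on construction: the
downstream algorithms (Steiner trees, modularity) assume loop-free graphs,
and an autoregulatory loop carries no information for either.

## From annotated pathways to gene networks

Database pathway graphs mix proteins with small molecules, nucleic acids
and nested pathways, and annotate nodes with heterogeneous identifiers.
The transformation to a gene-level network proceeds in four steps, each an
exported function so intermediate states are inspectable:

1. **Identifier mapping** (`map_identifiers()`): each node's reference
   identifiers (e.g. UniProt or Entrez) are converted to HGNC symbols.
   Nodes with no mappable reference keep an empty symbol list and are
   labelled by their display name — the instance-name fallback — rather
   than discarded, because curated complexes ("beta-catenin destruction
   complex") are biologically meaningful nodes.
2. **Connectivity-preserving filtering** (`filter_nonmappable_nodes()`):
   entities that cannot carry expression values (small molecules, DNA,
   RNA, nested pathways, and nodes with neither symbol nor name) are
   removed, and for every directed path `u → r₁ → … → r_k → w` whose
   interior is entirely removable, a direct edge `u → w` is added. The
   sign of the new edge is the **product** of the constituent signs: the
   source material is silent on sign composition, and the product is the
   standard convention for signed path effects (inhibiting an inhibitor
   activates). The computation uses signed reachability through the
   removable subgraph iterated to fixpoint, not sequential node deletion,
   so the result is independent of removal order, and parallel removable
   paths of opposite net sign yield both edges. Self-loops created by
   rewiring are dropped.
3. **Splitting** (`split_multi_symbol_nodes()`): a node annotated with k
   symbols becomes k single-symbol nodes, each inheriting every incident
   edge. Edges between two multi-symbol nodes therefore expand to the full
   cross product — the conservative reading of "this family node interacts
   with that family node".
4. **Merging** (`merge_same_symbol_nodes()`): nodes sharing a symbol are
   merged, edge endpoints relabelled, duplicates collapsed. After this
   step node ids *are* gene symbols (or display-name labels).

Group assignment (canonical / non-canonical / inhibition / regulation /
discarded) is an explicit input table, not an algorithm: the original
stratification was expert curation, and re-deriving it from keywords is
not reproducible (keyword selection is provided, but only as a coarse
pre-filter). Bundle pathways holding several signaling branches as
disconnected components can be split per weakly connected component
(`split_record_by_components()`); weak connectivity is used because
direction-blind membership is what "a branch of the diagram" means
operationally. Per-group merging is plain set union of SIF triples,
keeping only nodes with at least one interaction — therefore idempotent,
commutative and associative, which the tests check by permutation.

## Network characterization

* **Degree** counts all incident edges, parallel signed edges separately —
  a node regulated both positively and negatively by the same partner is
  genuinely busier than one with a single edge.
* **Betweenness** is computed on the directed, unweighted simple
  projection (parallel edges collapsed) with fractional credit among tied
  shortest paths. Whether the original analysis treated the graphs as
  directed is not documented; we follow the default of the igraph
  implementation it used, and record this as an assumption. The tests pin
  the semantics to a brute-force all-pairs enumeration oracle on small
  random graphs.
* **Key nodes** are the intersection of the top-k lists (default k = 15)
  of both centralities, ties at rank k included — so the candidate lists
  can exceed k, and a graph with fewer than k nodes trivially returns all
  nodes (with a message).
* **Communities** come from Clauset–Newman–Moore greedy modularity
  maximization (`igraph::cluster_fast_greedy`) on the undirected,
  unweighted, loop-free projection, cut at the maximal-modularity step of
  the merge path (first maximum when tied, i.e. the finer partition). We
  deliberately use the cited implementation rather than re-implementing
  CNM with a lexicographic tie-break: the algorithm is deterministic for a
  given node ordering, which our fixed construction order provides, and
  the tests verify the returned modularity against a direct recomputation
  and — on an 8-node planted example — against exhaustive maximization
  over all partitions.

## Enrichment

The **universe** for over-representation is all measured genes (all rows
of the summarized differential table); the tested gene set is intersected
with the universe first. The Fisher test is the one-sided hypergeometric
upper tail — enrichment only, matching how the original analysis read its
results; sidedness is not configurable for the Fisher test but the
Wilcoxon alternative is exposed. The Wilcoxon test ranks the entire table
(default: by p-value, ascending) and compares in-set ranks to all other
ranks, one-sided ("in-set genes rank higher"); it uses exact p-values for
universes up to 50 genes without ties and the tie-corrected normal
approximation otherwise. Probe-level tables are summarized by keeping each
gene's smallest-p probe (ties: larger |log fold-change|, then probe id),
and multiple testing uses Bonferroni — the family-wise procedure of the
source analyses; an FDR hook would be a one-line change but is not part
of the tested surface.

## Steiner modules

DEGs are mapped to network nodes and become **terminals**; the Steiner
tree introduces the minimal connecting nodes. Choices:

* The heuristic runs on the **undirected, unweighted (hop metric)**
  projection. Signaling direction is restored afterwards: the module is
  the full signed directed subgraph induced on the tree's node set, not
  the tree itself. An undirected heuristic is what the original tooling
  provided, and hop weights are the only defensible choice when no edge
  confidences exist.
* **Kou–Markowsky–Berman**: metric closure over terminals → MST (Kruskal,
  edges ordered by weight, then endpoints) → expansion of closure edges
  into shortest paths (deterministic backward reconstruction choosing the
  lexicographically smallest predecessor) → BFS spanning tree from the
  smallest terminal → iterative pruning of non-terminal leaves. The
  result is a tree (|E| = |V|−1), contains all terminals, and is within
  twice the optimum — verified against exhaustive Steiner search on all
  small random instances in the tests. The tie-breaks make the output
  reproducible, but they are *a* deterministic choice, not the unique
  lexicographically-minimal tree; Steiner node identities should be read
  as one valid connecting set, while terminal counts are
  heuristic-independent.
* Terminals are restricted to the **largest connected component** of the
  undirected projection (the heuristic needs a connected host); DEGs
  outside the network or that component are reported as dropped, never
  silently lost, and mapping zero terminals is an error.
* For export and plotting, fold-changes are clamped to ±`cap` (defaults:
  3 for microarray-derived, 4 for RNA-Seq-derived modules — the
  conventional saturation of diverging color scales); the raw value is
  always preserved in its own column.

## Validation

The earlier (microarray) module is the **reference**; overlap fractions
are reference-relative: node overlap |V_ref ∩ V_val| / |V_ref|, edge
overlap over ordered (source, target) pairs. Signs are ignored by default
because module comparison asks "is the same wiring present", not "with
the same annotation"; `use_sign = TRUE` switches to strict triple
identity. Fold-change correlation is Pearson's r over genes present in
both modules and both differential tables (the supplementary-style DEG
tables list only significant genes, so in practice this means genes
significant in both datasets), with the t-transform p-value and Fisher-z
95% CI. Steiner concordance classifies each reference Steiner node as
confirmed-as-Steiner, confirmed-as-DEG, or unconfirmed in the validation
module; the three counts partition the reference Steiner set by
construction, which the tests assert.

# The synthetic-data generator

The generator exists so that every stage has realistic, fully
reproducible inputs:

* `simulate_pathway_collection()` draws pathways of 8–18 nodes from a
  shared gene universe (so pathways overlap, as real collections do), on a
  random recursive tree backbone plus ~0.6·m extra edges (weakly
  connected, mildly redundant), with 25% inhibiting edges, a `p_nongene`
  fraction of non-gene entities (default 0.2) and a `p_multisymbol`
  fraction of two-symbol gene nodes (default 0.1). These rates reflect
  what parsed pathway graphs look like after controlling-interaction
  extraction: mostly proteins, a minority of metabolites/nucleic acids,
  occasional unresolved families.
* `simulate_expression()` is a log-scale Gaussian model: gene-specific
  baselines in [6, 10] (log₂-intensity range), independent noise with
  `sigma = 0.5`, and planted genes shifted by `effect` in the second
  group. `effect` may be a signed vector recycled over the planted genes,
  which is how heterogeneous up/down regulation is planted. The
  differential table is computed by pooled-variance two-sample t-tests
  with Bonferroni adjustment — pooled, not Welch, because the noise model
  is homoskedastic by construction (at n = 5 per group the Welch
  degrees-of-freedom penalty costs real power against a correct
  equal-variance model). This plain pipeline is a stand-in for
  platform-specific differential models; the package consumes
  differential tables agnostically, so nothing downstream depends on how
  the table was made.
* `plant_connected_terminals()` samples a breadth-first neighbourhood of
  a random start node in the largest component — a mutually reachable
  "active region", the configuration a Steiner module is meant to
  recover.

What the generator does **not** emulate: count-based RNA-Seq noise
(negative binomial), probe-level microarray structure, correlated
expression along network edges, batch effects, and the scale of real
curated collections (hundreds of nodes per network). Passing tests
therefore demonstrate algorithmic correctness and pipeline integrity
under a faithful small-scale model, not robustness to platform-specific
noise.

# Study sizes and reproducibility

The test suite and the acceptance script run the pipeline at deliberately
modest sizes chosen to exercise every code path while keeping each
end-to-end replicate around a third of a second: collections of 12–20
pathways over 120–200 genes (per-group networks of ~20–60 nodes),
10 planted genes with signed effects up to |4| on `sigma = 0.5` noise and
6 samples per group, and a measured universe of network genes plus 100–150
background genes. At the reference design stated for the power check
(effect 3, sigma 0.5, n = 5), per-gene Bonferroni-adjusted power is ≈0.99,
and the end-to-end recovery check uses effect 4 with n = 6 so that every
planted gene is recovered in all 20 replicates rather than ~99% of them.
Oracle-based property tests (brute-force betweenness, exhaustive Steiner
optimum, exhaustive modularity, hypergeometric and rank-sum enumeration,
transitive-closure rewiring) run on graphs of ≤ 12 nodes where exhaustive
computation is exact.

All randomness flows through explicit integer seeds; generators save and
restore the global RNG state, so library calls never perturb a user's
stream. Two runs with the same seeds produce byte-identical output files,
which the orchestration tests assert.

# Known limitations

* The gene networks inherit every omission of their source pathway
  collections; no edges are inferred, so genuinely interacting genes
  absent from the curated graphs can never appear in a module.
* Sign composition across removed entities assumes multiplicativity;
  saturation or dominance effects in real cascades are not modelled.
* The Steiner heuristic guarantees a 2-approximation, not optimality, and
  its Steiner-node identities depend on documented but arbitrary
  tie-breaks.
* Betweenness and community detection ignore edge signs; a
  signed-modularity treatment would be a meaningful extension but has no
  counterpart in the validated surface.
* Fisher/Wilcoxon enrichment treats genes as exchangeable; gene-length or
  expression-level biases of real platforms are out of scope.
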