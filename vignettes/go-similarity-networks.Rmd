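---
title: "Protein similarity networks from GO graph embeddings: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Protein similarity networks from GO graph embeddings: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gosimnet)
```

## The problem

The Gene Ontology (GO) describes gene products with a controlled vocabulary
of terms in three namespaces (biological process, cellular component,
molecular function), connected by typed relations (`is_a`, `part_of`, ...)
into a directed acyclic graph. Proteins are annotated by sets of GO terms,
so two proteins can be compared through the terms that annotate them.
Classical information-content (IC) measures compare two terms only through
the annotation frequency of their most informative common ancestor and
ignore where the terms sit in the graph. `gosimnet` instead treats the
ontology as a graph, learns a vector for every node with standard graph
embeddings, and scores protein pairs in vector space. Two variants are
supported:

* **GO + DTW** — term vectors are learned from the undirected GO graph
  (term–term edges only); a protein becomes the sequence of its annotated
  terms' vectors, and two proteins are compared by dynamic time warping
  (DTW) between their vector sequences.
* **GOA + cosine** — protein nodes are added to the graph, one edge per
  (protein, annotating term) pair, forming the GO-annotation (GOA) graph;
  protein vectors are learned directly and pairs scored by cosine
  similarity.

Scored pairs are screened into a similarity network (threshold or rank
band) and the network's internal consistency is measured with a
link-prediction protocol.

## Graph construction

`parse_obo()` reads the `[Term]` stanzas of an OBO flat file; obsolete
terms are dropped together with any relation touching them, and `alt_id`
accessions are remembered so annotations citing them map to the canonical
id. `parse_gaf()` reads GAF 2.x, keys annotations by the column-2
accession, drops (and counts) terms absent from the ontology, and collapses
duplicate pairs. Evidence codes are kept unless an include/exclude list is
given.

`build_go_graph()` flattens every relation to a single undirected,
unweighted edge regardless of type and direction, and merges the three
namespaces by default; both choices are configurable (`relation_types`,
`namespaces`). Direction and type matter for reasoning over the ontology,
but the embedding methods used here operate on undirected neighbourhood
structure, and keeping every relation preserves the most connectivity.
Annotations are *not* propagated to ancestor terms before building the GOA
graph: a protein is linked only to its directly annotated terms, so the
random walks themselves discover ancestors. (IC computation, by contrast,
always uses the descendant closure — that is its definition.)

## Embeddings

Four methods share one interface, `embed_graph()`:

* **DeepWalk / node2vec** — truncated random walks feed a skip-gram model
  with negative sampling. The second-order walk is biased by the return
  parameter `p` and in–out parameter `q`: stepping from `curr` with
  previous node `t`, neighbour `x` has unnormalized weight `1/p` if
  `x = t`, `1` if `x` is adjacent to `t`, `1/q` otherwise. `p = q = 1`
  reproduces the uniform walk exactly, and DeepWalk is implemented as that
  special case — one code path, two method tags.
* **LINE** — edge-sampling optimization of first-order proximity (the
  log-sigmoid inner product of edge endpoints, with negative sampling)
  and/or second-order proximity (separate context vectors); the default
  `"concatenated"` trains each order at half the dimension and binds them.
* **SDNE** — an adjacency-row autoencoder (one hidden layer, sigmoid
  activations, Adam) whose bottleneck is the embedding; nonzero adjacency
  entries are up-weighted by `beta` in the reconstruction loss, and an
  `alpha`-weighted Laplacian term pulls the bottleneck codes of adjacent
  nodes together.

Defaults are `dim = 128`, `walk_length = 80`, `walks_per_node = 10`,
`window = 10`, `epochs = 5`, `p = q = 1`, 5 negative samples — the standard
values of the embedding literature; SDNE uses hidden width `min(256, n)`,
`alpha = 1e-5`, `beta = 5`. For graphs of a few hundred nodes (the scale of
the bundled fixtures) smaller dimensions work equally well; the test suite
uses `dim = 16` on 60-node graphs.

The skip-gram and LINE inner loops are compiled (Rcpp) and use an internal
xorshift generator, so a fixed seed gives bitwise-identical embeddings on
the same machine, single-threaded. All stochastic stages fan a run-level
seed out deterministically per stage, so e.g. the walk stage and the
training stage draw from independent streams. A subtlety worth recording:
stage functions force their arguments *before* seeding, because an argument
expression that itself consumes randomness (for example an inline generator
call) would otherwise clobber the stage seed. LINE's negative sampler skips
draws equal to either endpoint of the sampled edge; on very small graphs
self-negatives otherwise dominate and collapse the vectors.

Isolated nodes get r length-1 walks, hence a vector trained only from
negative updates (effectively near its random initialization); they are
listed in the `isolated` attribute of the result.

## IC baselines

`compute_ic_table()` computes, for each term g, the fraction `p(g)` of
annotated proteins carrying g *or any descendant*, and
`ic(g) = -log p(g)` (natural log; a term annotating nothing gets `p = 0`,
`ic = Inf`, and pairs involving it are treated as undefined rather than
infinitely similar). Two term measures are provided, both driven by the
most informative common ancestor (MICA) `g_c`:

* Jiang–Conrath: `2 ic(g_c) - ic(g1) - ic(g2)`, a non-positive quantity
  that is 0 exactly when both terms carry their MICA's information.
* Relevance: the Lin ratio `2 ic(g_c) / (ic(g1) + ic(g2))` modulated by the
  rarity `1 - p(g_c)` of the ancestor. Both multiplicative and additive
  compositions of these two factors appear in print; the package defaults
  to Schlicker's original multiplicative form, which keeps the score in
  `[0, 1)` and vanishes when the MICA is the root, with the additive
  variant behind `composition = "additive"`. No rescaling of the
  Jiang–Conrath score to a positive range is applied before averaging.

Protein pairs are scored by best-match averaging (`bma()`): each term's
best match in the other protein's set, averaged within each direction and
then across the two directions, each sum divided by the size of the set it
runs over. Undefined term pairs (no common ancestor, infinite IC,
cross-namespace) are skipped from their max; a pair is undefined only when
every term pair is.

## DTW over term-vector sequences

DTW needs sequences, but GO annotation sets are unordered; the package
orders each protein's term vectors by the lexicographic order of the term
ids. This is a convention, not biology — its virtue is that shared terms
appear in the same relative order in both sequences, so they can align
diagonally, and the choice is deterministic. The cumulative grid uses the
recurrence in which a vertical or horizontal step adds the local distance
once and a diagonal step adds it twice; the first row and column are
cumulative sums from cell (1,1), and `D(m, n)` is the reported distance.
The local metric defaults to Euclidean distance with `1 - cosine` as an
option. The diagonal weight of 2 compensates for the diagonal covering two
grid steps at once, so degenerate all-diagonal alignments are not
automatically favoured.

Screening rules need similarities on a common scale, so the raw distance is
mapped to `s = 1 / (1 + D(m, n) / (m + n))`: strictly decreasing in the
length-normalized distance, equal to 1 only at distance 0. The `m + n`
normalization counteracts the upward bias of longer annotation lists (more
cells on any warping path), letting one threshold apply across proteins
with different annotation counts.

`screen_network()` implements both screening rules: `tau` keeps pairs
scoring strictly above the threshold; a rank band keeps the top, middle
(centred at the median rank) or last `band_frac` of all *defined* pairs,
with ties broken by score descending then protein-id pair ascending, so
band membership is reproducible. Undefined pairs never enter the ranking
denominator. `coincidence_degree()` compares two edge sets as
`|intersection| / max(|A|, |B|)` — normalizing by the larger set makes the
measure symmetric and conservative.

## Link prediction protocol

`split_edges()` removes 20% of the network's edges outright (`E_r`,
excluded from scoring entirely — they are neither probes nor candidate
non-edges), then splits the remainder into a training graph `E_p` and
probes `E_t` (20% of the survivors by default; the split fractions and the
probe share are parameters). Candidate pairs are the probes plus every
non-edge of the original network (exhaustive up to 2,000 nodes, a uniform
sample of 10 × |E_t| non-edges beyond). Three structural indexes score
candidates on the training graph: common neighbours (CN), Jaccard (JC) and
resource allocation (RA, reciprocal-degree-weighted common neighbours).

AUC is computed exactly from ranks (the Mann–Whitney probability that a
random probe outscores a random non-edge, ties counting 1/2), not by
sampling. Precision at depth L is `m / L` with `m` the probes among the top
L; recall is `m / M` with `M` the number of probe edges, so recall reaches
1 when all probes are retrieved — the variant that normalizes by all
surviving edges is available via `recall_denominator`. AUCPR is the
trapezoidal area under the (recall, precision) curve.

One structural fact discovered while validating: on a planted-partition
graph, within-community *non-edges* have exactly the same common-neighbour
distribution as held-out within-community edges, so with exhaustive
candidates the AUC of any common-neighbour index tops out well below 1
(≈ 0.74 at n = 200, p_in = 0.3, p_out = 0.02) no matter how strong the
communities are. Screened similarity networks do not share this ceiling:
their probes concentrate in dense high-similarity cores while their
candidate non-edges span the whole protein set.

## The synthetic fixture generator

`fixture_spec()` bundles the generator defaults, which are the package's
standard study conditions: a 200-term, 5-layer, single-root ontology
(every non-root term draws 1–2 parents from the layer above, so the DAG is
acyclic by construction); 100 proteins in 2 communities; 3–8 annotations
per protein; a planted-partition PPI reference with `p_in = 0.3`,
`p_out = 0.02`.

Communities are anchored to disjoint *module-sized* blocks of leaf terms —
`block_size = ceiling(1.5 * max k) = 12` by default — and a protein draws a
Binomial(k, 0.9) share of its annotations from its own block, the rest
uniformly from the remaining leaves. The small shared pool is the point:
proteins of one functional module reuse the same specific terms heavily,
which is what makes functionally similar real proteins look similar to
every method in this package (annotation overlap for the IC baselines,
shared graph neighbourhoods for the embeddings). Anchoring to leaves rather
than internal terms lets both kinds of signal coexist. With
community-sized pools instead (say, half of all ~100 leaves per block),
within-community pairs would share only ~0.5 terms on average — a fixture
too weak to exercise the downstream screening and link-prediction stages,
which is precisely the signal guarantee this module exists to provide.

What the generator does *not* emulate: realistic GO topology (term-degree
distributions, namespace sizes), annotation depth (it annotates leaves
only), evidence-code structure, or PPI degree distributions. Passing tests
on these fixtures therefore demonstrate that the pipeline recovers planted
annotation structure end to end — not that any particular biological
conclusion transfers to a specific GO release; for real data the same code
paths run unchanged on downloaded OBO/GAF/PPI files.

## Numerical choices and degenerate inputs

* Ties in the MICA (equal IC among common ancestors) break to the
  lexicographically smallest id; ties in rank screening break by score then
  pair id; both make results order-independent.
* Zero vectors make cosine similarity undefined (`NA`), and such pairs are
  excluded and reported, not silently scored 0.
* `dtw_distance` on empty sets or mismatched dimensions errors; a
  one-element pair reduces to the local metric.
* An all-tied score list yields AUC 0.5 by the rank formula without special
  casing.
* SDNE training aborts with a diagnostic on non-finite loss; `epochs = 0`
  returns the (seed-reproducible) random initialization.
* Problem sizes in the test suite: 60-node graphs for embedding unit
  checks, the 200-term / 100-protein fixture for the end-to-end checks,
  5 link-prediction repeats per configuration — chosen so the suite
  documents the method at the scale a laptop reruns comfortably.

## Known limitations

* DTW over lexicographically ordered sets is a convention; any fixed
  ordering changes the exact distances (though identical sets always score
  1, and shared-term alignment is preserved).
* The GOA variant treats term and protein nodes identically during
  embedding; no node-type weighting is attempted.
* No Sakoe–Chiba banding or other DTW speedups: all-pairs scoring is
  O(n² · m · n̄ · d) and intended for up to ~10⁴ proteins.
* Resnik similarity, Wang's graph-based measure, OWL parsing, and
  identifier-mapping services are out of scope; a static two-column mapping
  file is the supported way to align PPI accessions.
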