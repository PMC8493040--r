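# gosimnet

Protein functional similarity networks from Gene Ontology (GO) graph
embeddings, with information-content baselines and a link-prediction
evaluation protocol.

## What it does, and for whom

Proteins are annotated by GO terms, and the terms themselves form a
directed acyclic graph. Classical semantic-similarity measures compare two
proteins only through the annotation frequency of their terms' common
ancestors and discard the graph structure around the terms. `gosimnet` is
for computational biologists who want to score protein pairs through that
structure instead:

1. **Embed** every node of the undirected GO graph (term–term edges) or the
   combined GOA graph (term–term plus protein–term annotation edges) with
   one of four standard graph embeddings — DeepWalk, node2vec, LINE, SDNE.
   DeepWalk/node2vec walks follow the biased second-order rule: from
   current node *v* with previous node *t*, neighbour *x* has unnormalized
   weight 1/p if *x* = *t*, 1 if *x* ~ *t*, and 1/q otherwise; walks feed a
   skip-gram model with negative sampling.
2. **Score** each protein pair: either dynamic time warping between the two
   proteins' sequences of term vectors, with the recurrence
   `D(i,j) = min( D(i-1,j) + d, D(i,j-1) + d, D(i-1,j-1) + 2d )`
   mapped to a similarity `s = 1 / (1 + D(m,n)/(m+n))`, or the cosine
   `ω_m·ω_n / (‖ω_m‖‖ω_n‖)` of protein vectors learned from the GOA graph.
   IC baselines (Jiang–Conrath `2·IC(g_c) − IC(g₁) − IC(g₂)` and the
   relevance measure `[2·IC(g_c)/(IC(g₁)+IC(g₂))]·(1 − p(g_c))`, combined
   over term sets by best-match averaging) are built in for comparison.
3. **Screen** the scored pairs into a similarity network (threshold τ or a
   top/middle/last rank band) and **evaluate** it: hold out edges, score
   probe and non-edge candidates with common-neighbours, Jaccard or
   resource-allocation indexes on the training graph, and report exact
   rank-based AUC plus precision/recall (`m/L`, `m/M`) and AUCPR.

A synthetic fixture generator (layered DAG ontology, community-structured
annotations, planted-partition PPI reference) makes the whole pipeline
testable offline; the same code paths run unchanged on real `go.obo`,
GAF 2.x and PPI edge-list files.

## Worked example

```r
library(gosimnet)

spec <- fixture_spec(n_terms = 60, n_layers = 4, n_proteins = 30, seed = 7)
ont <- gen_ontology(spec)           # layered single-root DAG
ann <- gen_annotations(spec, ont)   # 2 communities of proteins
go  <- build_go_graph(ont)          # undirected, unweighted term graph

emb <- embed_graph(go, "node2vec", dim = 32, seed = 7)
sim <- similarity_matrix(names(ann$annotations), "go_dtw", emb, ann)
head(sim$pairs, 3)
#>   protein_a protein_b     score
#> 1    SP0001    SP0002 0.3313271
#> 2    SP0001    SP0003 0.3684676
#> 3    SP0001    SP0004 0.3342806

net <- screen_network(sim, band = "top", band_frac = 0.10)
net
#> <similarity_network> 25 nodes, 44 edges (go_dtw, top 10%)

run_link_prediction(net, "ra", repeats = 5, seed = 7)
#> <linkpred_result> index=ra: AUC 0.6881 (sd 0.0965), AUCPR 0.1594 (sd 0.1377), 5 repeats

ppi <- gen_ppi(spec, attr(ann, "communities"))
coincidence_degree(net, ppi)
#> [1] 0.2531646
```

Reading the numbers: each `score` is the normalized DTW similarity of two
proteins' term-vector sequences (1 = identical annotation sets). The top
10% of the 435 scored pairs forms a 44-edge network; held-out edges of that
network are recovered by the resource-allocation index clearly above chance
(AUC 0.69 on this deliberately small demo; at the package's default scale
of 100 proteins the top-5% network reaches AUC ≈ 0.8), and a quarter of the
network's edges coincide with the planted protein-interaction reference.
At full scale the package reproduces the expected qualitative ordering
AUC(top 5%) > AUC(middle 5%) > AUC(last 5%).

A command-line front-end with subcommands `fixtures`, `embed`, `icsim`,
`protsim`, `screen`, `coincide`, `linkpred` and `run` is installed at
`inst/cli/gosimnet.R`:

```sh
Rscript inst/cli/gosimnet.R fixtures --preset small --seed 7 --outdir fx
Rscript inst/cli/gosimnet.R run --obo fx/ontology.obo --gaf fx/annotations.gaf \
    --ppi fx/ppi.tsv --mode go_dtw --method node2vec --seed 7 --outdir run1
```

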