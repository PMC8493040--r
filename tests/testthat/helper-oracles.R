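# Independent oracles and tiny fixture builders shared across tests.

# Brute-force DTW: enumerate every admissible warping path from (1,1) to
# (m,n) with steps (+1,0), (0,+1), (+1,+1); vertical/horizontal steps add
# the local cost once, diagonal steps add it twice; cell (1,1) contributes
# its cost once.
brute_dtw <- function(dl) {
  m <- nrow(dl)
  n <- ncol(dl)
  best <- Inf
  rec <- function(i, j, cost) {
    if (i == m && j == n) {
      best <<- min(best, cost)
      return(invisible())
    }
    if (i < m) rec(i + 1, j, cost + dl[i + 1, j])
    if (j < n) rec(i, j + 1, cost + dl[i, j + 1])
    if (i < m && j < n) rec(i + 1, j + 1, cost + 2 * dl[i + 1, j + 1])
  }
  rec(1, 1, dl[1, 1])
  best
}

euclid_local <- function(vm, vn) {
  outer(seq_len(nrow(vm)), seq_len(nrow(vn)),
        Vectorize(function(i, j) sqrt(sum((vm[i, ] - vn[j, ])^2))))
}

# Brute-force annotation frequencies: explicit descendant enumeration by
# repeated child expansion over the relation table, then counting proteins
# annotated anywhere in the closure.
brute_ic_p <- function(ontology, annotations) {
  rel <- ontology$relations
  terms <- ontology$terms$id[!ontology$terms$obsolete]
  N <- length(annotations$annotations)
  p <- vapply(terms, function(t) {
    d <- t
    repeat {
      add <- setdiff(rel$child[rel$parent %in% d], d)
      if (length(add) == 0L) break
      d <- c(d, add)
    }
    hits <- vapply(annotations$annotations,
                   function(g) any(g %in% d), logical(1))
    sum(hits) / N
  }, numeric(1))
  stats::setNames(p, terms)
}

# Chain ontology C is_a B is_a A (single namespace).
chain_ontology <- function() {
  ontology_graph(
    terms = data.frame(id = c("GO:0000001", "GO:0000002", "GO:0000003"),
                       name = c("A", "B", "C"),
                       namespace = "biological_process", obsolete = FALSE),
    relations = data.frame(child = c("GO:0000002", "GO:0000003"),
                           parent = c("GO:0000001", "GO:0000002"),
                           type = "is_a")
  )
}

# Chain plus annotations giving p(A) = 1, p(B) = 0.5, p(C) = 0.25.
chain_quarter_annotations <- function() {
  annotation_set(list(P1 = "GO:0000003", P2 = "GO:0000002",
                      P3 = "GO:0000001", P4 = "GO:0000001"))
}

# Two 10-cliques as one graph, nodes n1..n20 (communities 1 and 2).
two_cliques <- function() {
  g <- igraph::disjoint_union(igraph::make_full_graph(10),
                              igraph::make_full_graph(10))
  igraph::V(g)$name <- sprintf("n%02d", 1:20)
  g
}

# Mean within- and between-group cosine similarity of an embedding.
cosine_separation <- function(emb, groups) {
  M <- unclass(emb)[names(groups), , drop = FALSE]
  nrm <- sqrt(rowSums(M^2))
  keep <- nrm > 0
  M <- M[keep, , drop = FALSE] / nrm[keep]
  groups <- groups[keep]
  S <- tcrossprod(M)
  ut <- upper.tri(S)
  same <- outer(groups, groups, "==")
  c(within = mean(S[ut & same]), between = mean(S[ut & !same]))
}

# Planted 2-community graph on 60 nodes from the fixture generator.
planted_graph <- function(seed, n = 60L, p_in = 0.3, p_out = 0.02) {
  comm <- stats::setNames(rep(1:2, length.out = n), sprintf("v%03d", seq_len(n)))
  spec <- fixture_spec(n_proteins = n, p_in = p_in, p_out = p_out,
                       seed = seed)
  edges <- gen_ppi(spec, comm)
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = names(comm)))
  list(graph = g, communities = comm, edges = edges)
}

# Minimal OBO text used by parser tests.
write_tiny_obo <- function(path, extra = character(0)) {
  writeLines(c(
    "format-version: 1.2",
    "",
    "[Term]",
    "id: GO:0000001",
    "name: alpha",
    "namespace: molecular_function",
    "",
    "[Term]",
    "id: GO:0000002",
    "name: beta",
    "namespace: molecular_function",
    "is_a: GO:0000001 ! alpha",
    "",
    "[Term]",
    "id: GO:0000003",
    "name: gamma",
    "namespace: biological_process",
    "is_a: GO:0000001 ! alpha",
    extra
  ), path)
  path
}

gaf_row <- function(protein, term, evidence = "IEA") {
  paste("UniProtKB", protein, protein, "", term, "GO_REF:0", evidence, "",
        "P", "", "", "protein", "taxon:1", "20200101", "UniProt", "", "",
        sep = "\t")
}
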