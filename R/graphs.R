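# Undirected GO / GOA graph construction.

GO_NAMESPACES <- c("biological_process", "cellular_component",
                   "molecular_function")

#' Flatten an ontology into an undirected, unweighted GO graph
#'
#' Every typed directed relation (`is_a`, `part_of`, ...) becomes a single
#' undirected edge, regardless of type and direction; duplicate edges
#' collapse. The three namespaces are merged by default.
#'
#' @param ontology an [ontology_graph()].
#' @param namespaces namespaces to keep (subset of the three GO namespaces).
#'   Terms with no recorded namespace are kept only when all three are
#'   selected.
#' @param relation_types `"all"` or a character vector of relation types to
#'   retain before flattening.
#' @return An [igraph::graph] with vertex attributes `name` and
#'   `kind = "term"`.
#' @export
build_go_graph <- function(ontology, namespaces = GO_NAMESPACES,
                           relation_types = "all") {
  if (length(namespaces) == 0L) stop("empty namespace selection")
  namespaces <- match.arg(namespaces, GO_NAMESPACES, several.ok = TRUE)
  terms <- live_terms(ontology)
  if (nrow(terms) == 0L) stop("ontology has no live terms")
  keep <- terms$namespace %in% namespaces |
    (is.na(terms$namespace) & length(namespaces) == 3L)
  terms <- terms[keep, , drop = FALSE]
  if (nrow(terms) == 0L) stop("no terms in namespaces: ",
                              paste(namespaces, collapse = ", "))
  rel <- ontology$relations
  if (!identical(relation_types, "all")) {
    rel <- rel[rel$type %in% relation_types, , drop = FALSE]
  }
  rel <- rel[rel$child %in% terms$id & rel$parent %in% terms$id, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    rel[, c("child", "parent")],
    directed = FALSE,
    vertices = data.frame(name = terms$id, stringsAsFactors = FALSE)
  )
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  igraph::V(g)$kind <- "term"
  g
}

#' Build the combined GOA graph
#'
#' Combines the flattened term-term relations with one undirected edge per
#' (protein, annotating term) pair into a single heterogeneous graph.
#' Protein and term identifier spaces must be disjoint.
#'
#' @inheritParams build_go_graph
#' @param annotations an [annotation_set()] consistent with `ontology`.
#' @return An [igraph::graph] with vertex attribute `kind` in
#'   `{"term", "protein"}`.
#' @export
build_goa_graph <- function(ontology, annotations, namespaces = GO_NAMESPACES,
                            relation_types = "all") {
  go <- build_go_graph(ontology, namespaces, relation_types)
  terms <- igraph::V(go)$name
  prot <- names(annotations$annotations)
  clash <- intersect(prot, live_terms(ontology)$id)
  if (length(clash)) {
    stop("protein ids collide with GO accessions: ",
         paste(head(clash, 5), collapse = ", "))
  }
  ann_term <- unlist(annotations$annotations, use.names = FALSE)
  ann_prot <- rep(prot, lengths(annotations$annotations))
  keep <- ann_term %in% terms
  g <- igraph::add_vertices(go, length(prot), name = prot, kind = "protein")
  if (any(keep)) {
    g <- igraph::add_edges(g, rbind(ann_prot[keep], ann_term[keep]))
  }
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Write a graph as a two-column edge-list TSV
#'
#' @param graph an igraph object or two-column edge data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_tsv <- function(graph, path) {
  if (inherits(graph, "igraph")) {
    e <- igraph::as_edgelist(graph)
  } else {
    e <- as.matrix(graph[, 1:2])
  }
  utils::write.table(e, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a two-column edge-list TSV into an undirected graph
#'
#' @param path input path.
#' @return An undirected simplified [igraph::graph].
#' @export
read_edge_tsv <- function(path) {
  e <- utils::read.table(path, sep = "\t", header = FALSE,
                         colClasses = "character")
  g <- igraph::graph_from_data_frame(e[, 1:2], directed = FALSE)
  igraph::simplify(g)
}
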