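# Synthetic desk-scale fixtures: layered DAG ontologies, community-
# structured annotation sets, and planted-partition PPI networks. These
# generate the same file formats the real pipeline reads, so every stage is
# testable without external downloads.

#' Specification of a synthetic fixture
#'
#' Defaults describe the standard study conditions used throughout the test
#' suite: a 200-term, 5-layer ontology; 100 proteins in 2 communities, each
#' drawing 3-8 leaf-term annotations with 90% of draws from its community's
#' leaf block; and a planted-partition PPI network with within/between edge
#' probabilities 0.3 / 0.02.
#'
#' @param n_terms,n_layers ontology size and depth (`n_layers >= 2`).
#' @param n_proteins,n_communities protein count and community count.
#' @param k_range integer range (min, max) of annotations per protein.
#' @param within_rate probability an annotation is drawn from the protein's
#'   own community leaf block rather than uniformly from the remaining
#'   leaves.
#' @param block_size leaf terms per community anchor block; the default
#'   `ceiling(1.5 * max(k_range))` keeps the pool module-sized, mimicking
#'   the heavy term reuse within a functional module or complex.
#' @param p_in,p_out PPI edge probabilities within / between communities.
#' @param seed integer seed; all generators are deterministic under it.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_terms = 200L, n_layers = 5L, n_proteins = 100L,
                         n_communities = 2L, k_range = c(3L, 8L),
                         within_rate = 0.9, block_size = NULL,
                         p_in = 0.3, p_out = 0.02, seed = 1L) {
  block_size <- as.integer(block_size %||% ceiling(1.5 * max(k_range)))
  stopifnot(n_layers >= 2L, n_terms >= n_layers,
            within_rate >= 0, within_rate <= 1,
            p_in >= 0, p_in <= 1, p_out >= 0, p_out <= 1,
            length(k_range) == 2L, k_range[1] >= 1L,
            k_range[2] >= k_range[1], block_size >= k_range[2])
  structure(list(n_terms = as.integer(n_terms), n_layers = as.integer(n_layers),
                 n_proteins = as.integer(n_proteins),
                 n_communities = as.integer(n_communities),
                 k_range = as.integer(k_range), within_rate = within_rate,
                 block_size = block_size,
                 p_in = p_in, p_out = p_out, seed = as.integer(seed)),
            class = "fixture_spec")
}

# Layer sizes: single root, then geometric growth renormalized to n_terms.
fixture_layer_sizes <- function(n_terms, n_layers) {
  if (n_layers == 1L) return(n_terms)
  w <- 2^(seq_len(n_layers - 1L))
  rest <- n_terms - 1L
  sizes <- pmax(1L, floor(rest * w / sum(w)))
  # distribute the remainder to the deepest layers
  while (sum(sizes) < rest) {
    sizes[n_layers - 1L] <- sizes[n_layers - 1L] + 1L
  }
  while (sum(sizes) > rest) {
    i <- which(sizes > 1L)
    sizes[i[1]] <- sizes[i[1]] - 1L
  }
  c(1L, sizes)
}

#' Generate a layered DAG ontology
#'
#' Single root; every non-root term receives 1-2 `is_a` parents drawn
#' uniformly from the layer above, so the result is acyclic by
#' construction. One namespace per generated ontology.
#'
#' @param spec a [fixture_spec()].
#' @param namespace namespace assigned to every term.
#' @return An [ontology_graph()].
#' @export
gen_ontology <- function(spec, namespace = "biological_process") {
  set.seed(fan_seed(spec$seed, "ontology"))
  sizes <- fixture_layer_sizes(spec$n_terms, spec$n_layers)
  ids <- sprintf("GO:%07d", seq_len(spec$n_terms))
  layer <- rep(seq_along(sizes), sizes)
  child <- character(0)
  parent <- character(0)
  for (l in 2:length(sizes)) {
    above <- ids[layer == l - 1L]
    for (t in ids[layer == l]) {
      n_par <- sample(1:2, 1L)
      n_par <- min(n_par, length(above))
      parents <- above[sample.int(length(above), n_par)]
      child <- c(child, rep(t, n_par))
      parent <- c(parent, parents)
    }
  }
  og <- ontology_graph(
    terms = data.frame(id = ids, name = paste("synthetic term", seq_along(ids)),
                       namespace = namespace, obsolete = FALSE,
                       stringsAsFactors = FALSE),
    relations = data.frame(child = child, parent = parent, type = "is_a",
                           stringsAsFactors = FALSE)
  )
  attr(og, "layer") <- stats::setNames(layer, ids)
  og
}

fixture_leaves <- function(ontology) {
  ids <- live_terms(ontology)$id
  sort(setdiff(ids, unique(ontology$relations$parent)))
}

#' Generate a community-structured annotation set
#'
#' Proteins are assigned round-robin to communities; each community is
#' anchored to a disjoint, module-sized block of leaf terms (`block_size`
#' terms). A protein draws k annotations (k uniform in `k_range`): a
#' Binomial(k, `within_rate`) number from its own block and the rest
#' uniformly from the leaves outside the block. The small shared pool means
#' proteins of one community reuse the same specific terms heavily, so
#' annotation overlap is much higher within communities than between — the
#' signal every downstream stage is asked to recover.
#'
#' @param spec a [fixture_spec()].
#' @param ontology the ontology from [gen_ontology()].
#' @return An [annotation_set()] with attribute `communities` (named integer
#'   vector protein -> community).
#' @export
gen_annotations <- function(spec, ontology) {
  leaves <- fixture_leaves(ontology)  # force before seeding
  set.seed(fan_seed(spec$seed, "annotations"))
  C <- spec$n_communities
  block_size <- spec$block_size
  if (block_size < spec$k_range[2]) {
    stop("leaf block smaller than the maximum annotations per protein")
  }
  if (block_size * C > length(leaves)) {
    stop("ontology has too few leaves for the requested community blocks")
  }
  blocks <- split(leaves[seq_len(block_size * C)],
                  rep(seq_len(C), each = block_size))
  prot <- sprintf("SP%04d", seq_len(spec$n_proteins))
  comm <- rep(seq_len(C), length.out = spec$n_proteins)
  ann <- vector("list", spec$n_proteins)
  names(ann) <- prot
  for (i in seq_len(spec$n_proteins)) {
    k <- sample(spec$k_range[1]:spec$k_range[2], 1L)
    n_within <- stats::rbinom(1L, k, spec$within_rate)
    block <- blocks[[comm[i]]]
    outside <- setdiff(leaves, block)
    n_out <- min(k - n_within, length(outside))
    n_within <- k - n_out
    terms <- c(block[sample.int(length(block), n_within)],
               if (n_out > 0L) outside[sample.int(length(outside), n_out)])
    ann[[i]] <- terms
  }
  out <- annotation_set(ann)
  attr(out, "communities") <- stats::setNames(comm, prot)
  out
}

#' Generate a planted-partition PPI network
#'
#' Independent edges: probability `p_in` within a community, `p_out`
#' between. Serves as the reference interaction network for coincidence and
#' link-prediction experiments.
#'
#' @param spec a [fixture_spec()].
#' @param communities named vector protein -> community (e.g. the
#'   `communities` attribute of [gen_annotations()]).
#' @return A canonical two-column edge data frame with attribute
#'   `communities`.
#' @export
gen_ppi <- function(spec, communities) {
  prot <- names(communities)  # force before seeding
  if (spec$p_out >= spec$p_in) {
    warning("p_out >= p_in: the planted partition carries no signal")
  }
  set.seed(fan_seed(spec$seed, "ppi"))
  n <- length(prot)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  same <- communities[idx[, 1]] == communities[idx[, 2]]
  pr <- ifelse(same, spec$p_in, spec$p_out)
  hit <- stats::runif(length(pr)) < pr
  edges <- canonical_edges(data.frame(a = prot[idx[hit, 1]],
                                      b = prot[idx[hit, 2]],
                                      stringsAsFactors = FALSE))
  attr(edges, "communities") <- communities
  edges
}

#' Write a complete fixture to disk
#'
#' Emits the OBO ontology, the GAF annotation file and the PPI edge-list
#' TSV that the pipeline front-end reads.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if missing).
#' @return Named list of the three file paths, invisibly.
#' @export
write_fixtures <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ont <- gen_ontology(spec)
  ann <- gen_annotations(spec, ont)
  ppi <- gen_ppi(spec, attr(ann, "communities"))
  paths <- list(obo = file.path(dir, "ontology.obo"),
                gaf = file.path(dir, "annotations.gaf"),
                ppi = file.path(dir, "ppi.tsv"))
  write_obo(ont, paths$obo)
  write_gaf(ann, paths$gaf)
  write_edge_tsv(ppi, paths$ppi)
  invisible(paths)
}
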