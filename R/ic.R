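# Information-content term similarity: IC table, MICA, Jiang-Conrath and
# relevance (Rel) similarities, and best-match-average protein similarity.

# Directed child -> parent igraph over the ontology relations.
directed_relation_graph <- function(ontology, relation_types = "all") {
  rel <- ontology$relations
  if (!identical(relation_types, "all")) {
    rel <- rel[rel$type %in% relation_types, , drop = FALSE]
  }
  terms <- live_terms(ontology)
  igraph::graph_from_data_frame(
    rel[, c("child", "parent")], directed = TRUE,
    vertices = data.frame(name = terms$id, stringsAsFactors = FALSE))
}

#' Compute the information-content table of an annotated ontology
#'
#' For each term g, `p(g)` is the fraction of the N annotated proteins that
#' are annotated by g or any of its descendants, and `ic(g) = -log p(g)`
#' (natural log). Terms that annotate nothing (directly or via descendants)
#' get `p = 0` and `ic = Inf`.
#'
#' @param ontology an [ontology_graph()]; its directed relations must be
#'   acyclic.
#' @param annotations an [annotation_set()].
#' @param relation_types relation types used for the descendant closure
#'   (default all, matching the undirected flattening).
#' @return An `ic_table`: data frame with columns `term`, `p`, `ic` and
#'   attributes `N` (number of annotated proteins) and `ancestors` (named
#'   list of ancestor-or-self id vectors, reused by [mica()]).
#' @export
compute_ic_table <- function(ontology, annotations, relation_types = "all") {
  g <- directed_relation_graph(ontology, relation_types)
  if (!igraph::is_dag(g)) stop("directed relations contain a cycle")
  terms <- igraph::V(g)$name
  N <- length(annotations$annotations)

  # proteins directly on each term
  prot <- rep(names(annotations$annotations),
              lengths(annotations$annotations))
  term <- unlist(annotations$annotations, use.names = FALSE)
  keep <- term %in% terms
  by_term <- split(prot[keep], term[keep])

  # ancestors-or-self of every term (edges run child -> parent, so ancestors
  # are reachable "out"); a term's protein count then propagates to each of
  # its ancestors, i.e. the descendant-closed count.
  anc <- lapply(igraph::ego(g, order = igraph::vcount(g), mode = "out"),
                function(v) v$name)
  names(anc) <- terms

  counts <- new.env(parent = emptyenv())
  for (t in terms) assign(t, character(0), envir = counts)
  for (t in names(by_term)) {
    for (a in anc[[t]]) {
      assign(a, c(get(a, envir = counts), by_term[[t]]), envir = counts)
    }
  }
  p <- vapply(terms,
              function(t) length(unique(get(t, envir = counts))) / N,
              numeric(1))
  ic <- ifelse(p > 0, -log(p), Inf)
  out <- data.frame(term = terms, p = unname(p), ic = unname(ic),
                    stringsAsFactors = FALSE)
  attr(out, "N") <- N
  attr(out, "ancestors") <- anc
  ns <- live_terms(ontology)
  attr(out, "namespace") <- stats::setNames(ns$namespace, ns$id)
  class(out) <- c("ic_table", "data.frame")
  out
}

ic_of <- function(ic_table, g) {
  i <- match(g, ic_table$term)
  if (is.na(i)) NA_real_ else ic_table$ic[i]
}

p_of <- function(ic_table, g) {
  i <- match(g, ic_table$term)
  if (is.na(i)) NA_real_ else ic_table$p[i]
}

#' Most informative common ancestor of two terms
#'
#' A term counts as its own ancestor. Cross-namespace pairs, and pairs
#' without any common ancestor, have no MICA and return `NA`.
#'
#' @param g1,g2 term ids.
#' @param ic_table an `ic_table` from [compute_ic_table()].
#' @return The id of the common ancestor with maximal IC (ties broken by
#'   lexicographically smallest id), or `NA_character_`.
#' @export
mica <- function(g1, g2, ic_table) {
  ns <- attr(ic_table, "namespace")
  if (!is.null(ns) && g1 %in% names(ns) && g2 %in% names(ns)) {
    if (!is.na(ns[[g1]]) && !is.na(ns[[g2]]) && ns[[g1]] != ns[[g2]]) {
      return(NA_character_)
    }
  }
  anc <- attr(ic_table, "ancestors")
  if (is.null(anc[[g1]]) || is.null(anc[[g2]])) return(NA_character_)
  common <- intersect(anc[[g1]], anc[[g2]])
  if (length(common) == 0L) return(NA_character_)
  ics <- ic_table$ic[match(common, ic_table$term)]
  best <- common[ics == max(ics)]
  sort(best)[1]
}

#' Jiang-Conrath term similarity
#'
#' `2 ic(g_c) - ic(g1) - ic(g2)` with `g_c` the MICA; always `<= 0`, with 0
#' exactly when both terms carry the IC of their MICA. Pairs with an
#' undefined MICA or infinite IC are undefined (`NA`).
#'
#' @inheritParams mica
#' @return A non-positive real, or `NA_real_` when undefined.
#' @export
sim_jc <- function(g1, g2, ic_table) {
  gc <- mica(g1, g2, ic_table)
  if (is.na(gc)) return(NA_real_)
  ics <- c(ic_of(ic_table, g1), ic_of(ic_table, g2), ic_of(ic_table, gc))
  if (any(is.na(ics)) || any(!is.finite(ics))) return(NA_real_)
  2 * ics[3] - ics[1] - ics[2]
}

#' Relevance (Rel) term similarity
#'
#' The Lin ratio `2 ic(g_c) / (ic(g1) + ic(g2))` modulated by the rarity of
#' the MICA. The default multiplicative composition
#' `lin * (1 - p(g_c))` (Schlicker's relevance measure) keeps values in
#' `[0, 1)`; an additive variant `lin + (1 - p(g_c))` is available.
#'
#' @inheritParams mica
#' @param composition `"multiplicative"` (default) or `"additive"`.
#' @return Similarity value (`[0, 1)` for the multiplicative form), 0 when
#'   both terms are roots with zero IC, `NA_real_` when undefined.
#' @export
sim_rel <- function(g1, g2, ic_table,
                    composition = c("multiplicative", "additive")) {
  composition <- match.arg(composition)
  gc <- mica(g1, g2, ic_table)
  if (is.na(gc)) return(NA_real_)
  ic1 <- ic_of(ic_table, g1)
  ic2 <- ic_of(ic_table, g2)
  icc <- ic_of(ic_table, gc)
  pc <- p_of(ic_table, gc)
  if (any(is.na(c(ic1, ic2, icc, pc))) || !all(is.finite(c(ic1, ic2, icc)))) {
    return(NA_real_)
  }
  if (ic1 + ic2 == 0) return(0)
  lin <- 2 * icc / (ic1 + ic2)
  if (composition == "multiplicative") lin * (1 - pc) else lin + (1 - pc)
}

#' Best-match-average similarity between two annotated proteins
#'
#' Averages, over both directions, each term's best match in the other
#' protein's term set:
#' `1/2 [ mean_g max_g' sim(g, g') + mean_g' max_g sim(g, g') ]`.
#' Undefined term pairs are skipped from their max; terms with no defined
#' partner drop out of their mean. Symmetric by construction.
#'
#' @param pm,pn protein ids.
#' @param annotations an [annotation_set()].
#' @param termsim function `(g1, g2) -> numeric` (e.g. a closure over
#'   [sim_jc()] or [sim_rel()]), returning `NA` for undefined pairs.
#' @return The BMA similarity, or `NA_real_` when every term pair is
#'   undefined.
#' @export
bma <- function(pm, pn, annotations, termsim) {
  gm <- annotations$annotations[[pm]]
  gn <- annotations$annotations[[pn]]
  if (is.null(gm) || is.null(gn)) stop("both proteins must be annotated")
  S <- matrix(NA_real_, length(gm), length(gn))
  for (i in seq_along(gm)) {
    for (j in seq_along(gn)) {
      S[i, j] <- termsim(gm[i], gn[j])
    }
  }
  row_max <- apply(S, 1, function(x) if (all(is.na(x))) NA_real_ else
    max(x, na.rm = TRUE))
  col_max <- apply(S, 2, function(x) if (all(is.na(x))) NA_real_ else
    max(x, na.rm = TRUE))
  if (all(is.na(row_max)) && all(is.na(col_max))) return(NA_real_)
  (mean(row_max, na.rm = TRUE) + mean(col_max, na.rm = TRUE)) / 2
}

#' Write an IC table as TSV
#'
#' @param ic_table an `ic_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ic_table <- function(ic_table, path) {
  utils::write.table(as.data.frame(ic_table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
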