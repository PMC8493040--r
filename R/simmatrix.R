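# All-pairs protein similarity tables, network screening, and the
# coincidence degree between edge sets.

#' Score all protein pairs
#'
#' Two modes mirror the two pipeline variants: `go_dtw` turns each protein's
#' annotated GO terms (in lexicographic term-id order) into its sequence of
#' term vectors and scores pairs by the normalized DTW similarity;
#' `goa_cosine` scores pairs by the cosine of the protein vectors learned
#' from the GOA graph. Pairs that cannot be scored (no embedded annotated
#' term; zero vector) are recorded separately, not silently dropped.
#'
#' @param proteins character vector of protein ids.
#' @param mode `"go_dtw"` or `"goa_cosine"`.
#' @param embeddings an `embedding_map` of term vectors (`go_dtw`) or
#'   protein vectors (`goa_cosine`).
#' @param annotations an [annotation_set()]; required for `go_dtw`.
#' @param metric local DTW metric, see [dtw_distance()].
#' @return A `protein_similarity` object: list with `pairs` (data frame
#'   `protein_a`, `protein_b`, `score`; `a < b` lexicographically, sorted),
#'   `undefined` (same shape plus `reason`), `mode`, `metric`.
#' @export
similarity_matrix <- function(proteins, mode = c("go_dtw", "goa_cosine"),
                              embeddings, annotations = NULL,
                              metric = c("euclidean", "cosine")) {
  mode <- match.arg(mode)
  metric <- match.arg(metric)
  proteins <- sort(unique(as.character(proteins)))
  if (length(proteins) < 2L) stop("need at least two proteins")

  if (mode == "go_dtw") {
    if (is.null(annotations)) stop("go_dtw mode needs annotations")
    vsets <- vector("list", length(proteins))
    names(vsets) <- proteins
    for (p in proteins) {
      terms <- annotations$annotations[[p]]
      terms <- terms[terms %in% rownames(embeddings)]
      if (length(terms) > 0L) {
        vsets[[p]] <- unclass(embeddings)[sort(terms), , drop = FALSE]
      }
    }
  } else {
    vecs <- vector("list", length(proteins))
    names(vecs) <- proteins
    ok <- proteins %in% rownames(embeddings)
    for (p in proteins[ok]) vecs[[p]] <- unclass(embeddings)[p, ]
  }

  n <- length(proteins)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  a <- proteins[idx[, 1]]
  b <- proteins[idx[, 2]]
  score <- rep(NA_real_, length(a))
  reason <- rep(NA_character_, length(a))

  for (k in seq_along(a)) {
    if (mode == "go_dtw") {
      va <- vsets[[a[k]]]
      vb <- vsets[[b[k]]]
      if (is.null(va) || is.null(vb)) {
        reason[k] <- "no embedded annotated term"
        next
      }
      score[k] <- normalized_dtw_similarity(va, vb, metric)
    } else {
      wa <- vecs[[a[k]]]
      wb <- vecs[[b[k]]]
      if (is.null(wa) || is.null(wb)) {
        reason[k] <- "no protein vector"
        next
      }
      s <- cosine_similarity(wa, wb)
      if (is.na(s)) {
        reason[k] <- "zero vector"
        next
      }
      score[k] <- s
    }
  }

  def <- !is.na(score)
  pairs <- data.frame(protein_a = a[def], protein_b = b[def],
                      score = score[def], stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$protein_a, pairs$protein_b), , drop = FALSE]
  rownames(pairs) <- NULL
  undefined <- data.frame(protein_a = a[!def], protein_b = b[!def],
                          reason = reason[!def], stringsAsFactors = FALSE)
  structure(list(pairs = pairs, undefined = undefined, mode = mode,
                 metric = metric, proteins = proteins),
            class = "protein_similarity")
}

#' @export
print.protein_similarity <- function(x, ...) {
  cat(sprintf("<protein_similarity> %s: %d proteins, %d scored pairs, %d undefined\n",
              x$mode, length(x$proteins), nrow(x$pairs), nrow(x$undefined)))
  invisible(x)
}

#' Turn a protein_similarity into a full symmetric matrix
#'
#' Unit diagonal; undefined pairs are `NA`.
#'
#' @param x a `protein_similarity`.
#' @param ... unused.
#' @return A symmetric numeric matrix.
#' @export
as.matrix.protein_similarity <- function(x, ...) {
  p <- x$proteins
  M <- matrix(NA_real_, length(p), length(p), dimnames = list(p, p))
  diag(M) <- 1
  ia <- match(x$pairs$protein_a, p)
  ib <- match(x$pairs$protein_b, p)
  M[cbind(ia, ib)] <- x$pairs$score
  M[cbind(ib, ia)] <- x$pairs$score
  M
}

#' Screen a score table into a similarity network
#'
#' Two screening rules: `tau` keeps pairs with score strictly above the
#' threshold; `band` ranks all defined pairs by score (descending, ties
#' broken by protein-id pair) and keeps a 100*`band_frac`% band — `"top"`
#' the first ranks, `"last"` the final ranks, `"middle"` the band centred
#' at the median rank. Undefined pairs never enter the ranking.
#'
#' @param scores a `protein_similarity` (or its `pairs` data frame).
#' @param tau similarity threshold; mutually exclusive with `band`.
#' @param band `"top"`, `"middle"` or `"last"`.
#' @param band_frac width of the band as a fraction of the scored pairs.
#' @return A `similarity_network`: list with `edges` (data frame
#'   `protein_a`, `protein_b`, `score`), `nodes`, `rule`.
#' @export
screen_network <- function(scores, tau = NULL, band = NULL,
                           band_frac = 0.05) {
  pairs <- if (inherits(scores, "protein_similarity")) scores$pairs else scores
  if (nrow(pairs) == 0L) stop("no scored pairs to screen")
  if (is.null(tau) == is.null(band)) {
    stop("give exactly one of tau= or band=")
  }
  if (!is.null(tau)) {
    keep <- pairs[pairs$score > tau, , drop = FALSE]
    rule <- sprintf("tau>%g", tau)
  } else {
    band <- match.arg(band, c("top", "middle", "last"))
    o <- order(-pairs$score, pairs$protein_a, pairs$protein_b)
    pairs <- pairs[o, , drop = FALSE]
    n <- nrow(pairs)
    k <- round(band_frac * n)
    if (k < 1L || k > n) stop("band wider than available pairs")
    ranks <- switch(band,
      top = seq_len(k),
      last = seq.int(n - k + 1L, n),
      middle = seq_len(k) + floor((n - k) / 2)
    )
    keep <- pairs[ranks, , drop = FALSE]
    rule <- sprintf("%s %g%%", band, 100 * band_frac)
  }
  rownames(keep) <- NULL
  mode <- if (inherits(scores, "protein_similarity")) scores$mode else "scores"
  structure(
    list(edges = keep, nodes = sort(unique(c(keep$protein_a, keep$protein_b))),
         rule = rule, mode = mode),
    class = "similarity_network"
  )
}

#' @export
print.similarity_network <- function(x, ...) {
  cat(sprintf("<similarity_network> %d nodes, %d edges (%s, %s)\n",
              length(x$nodes), nrow(x$edges), x$mode, x$rule))
  invisible(x)
}

#' Convert a similarity network to an igraph
#'
#' @param network a `similarity_network`.
#' @return A weighted undirected [igraph::graph].
#' @export
network_graph <- function(network) {
  g <- igraph::graph_from_data_frame(network$edges[, 1:2], directed = FALSE)
  igraph::E(g)$weight <- network$edges$score
  g
}

#' Coincidence degree between two edge sets
#'
#' The shared fraction `|Ea` \eqn{\cap} `Eb| / max(|Ea|, |Eb|)`: the
#' intersection normalized by the larger set, hence symmetric and in
#' `[0, 1]`.
#'
#' @param ea,eb edge sets: two-column data frames/matrices of node pairs, or
#'   `similarity_network` objects.
#' @return The coincidence degree.
#' @export
coincidence_degree <- function(ea, eb) {
  get_edges <- function(x) {
    if (inherits(x, "similarity_network")) x <- x$edges
    if (inherits(x, "igraph")) x <- igraph::as_edgelist(x)
    canonical_edges(x)
  }
  ea <- get_edges(ea)
  eb <- get_edges(eb)
  if (nrow(ea) == 0L || nrow(eb) == 0L) stop("empty edge set")
  ka <- pair_key(ea$a, ea$b)
  kb <- pair_key(eb$a, eb$b)
  length(intersect(ka, kb)) / max(length(ka), length(kb))
}
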