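# Link-prediction evaluation: edge splitting, CN/JC/RA structural indexes,
# exact rank-based AUC, precision-recall curves, repeated experiments.

#' Split a network's edges for a link-prediction experiment
#'
#' Removes a fraction `remove_frac` of the edges (E_r, discarded from all
#' scoring), then divides the remainder E_s into a training set E_p and a
#' probe set E_t with `probe_frac` of E_s as probes. Uniform sampling
#' without replacement; deterministic under `seed`.
#'
#' @param network a `similarity_network`, igraph, or two-column edge frame
#'   with at least 10 edges.
#' @param remove_frac fraction of edges removed outright.
#' @param probe_frac fraction of the surviving edges used as probes.
#' @param seed integer seed.
#' @return An `edge_split`: list with canonical edge frames `e_r`, `e_p`,
#'   `e_t`, the node set, and the seed.
#' @export
split_edges <- function(network, remove_frac = 0.2, probe_frac = 0.2,
                        seed = 1L) {
  if (inherits(network, "similarity_network")) {
    edges <- network$edges[, 1:2]
    nodes <- network$nodes
  } else if (inherits(network, "igraph")) {
    edges <- as.data.frame(igraph::as_edgelist(network),
                           stringsAsFactors = FALSE)
    nodes <- igraph::V(network)$name
  } else {
    edges <- network[, 1:2]
    nodes <- sort(unique(c(as.character(edges[[1]]),
                           as.character(edges[[2]]))))
  }
  edges <- canonical_edges(edges)
  m <- nrow(edges)
  if (m < 10L) stop("need at least 10 edges to split")
  if (remove_frac <= 0 || remove_frac >= 1 || probe_frac <= 0 ||
      probe_frac >= 1) {
    stop("remove_frac and probe_frac must lie in (0, 1)")
  }
  set.seed(fan_seed(seed, "split"))
  n_r <- round(remove_frac * m)
  i_r <- sample.int(m, n_r)
  rest <- setdiff(seq_len(m), i_r)
  n_t <- round(probe_frac * length(rest))
  i_t <- rest[sample.int(length(rest), n_t)]
  i_p <- setdiff(rest, i_t)
  if (length(i_p) == 0L || length(i_t) == 0L || n_r == 0L) {
    stop("degenerate split: one partition is empty")
  }
  structure(
    list(e_r = edges[i_r, , drop = FALSE], e_p = edges[i_p, , drop = FALSE],
         e_t = edges[i_t, , drop = FALSE], nodes = nodes,
         seed = as.integer(seed)),
    class = "edge_split"
  )
}

training_graph <- function(split) {
  g <- igraph::graph_from_data_frame(
    split$e_p, directed = FALSE,
    vertices = data.frame(name = split$nodes, stringsAsFactors = FALSE))
  igraph::simplify(g)
}

nbr_set <- function(graph, v) igraph::neighbors(graph, v)$name

#' Common-neighbours index
#'
#' `|Gamma(x) n Gamma(y)|` on the training graph — the (x, y) entry of the
#' squared adjacency matrix.
#'
#' @param graph training [igraph::graph].
#' @param x,y distinct node ids.
#' @return Non-negative integer count.
#' @export
cn_index <- function(graph, x, y) {
  stopifnot(x != y)
  length(intersect(nbr_set(graph, x), nbr_set(graph, y)))
}

#' Jaccard index
#'
#' `|Gamma(x) n Gamma(y)| / |Gamma(x) u Gamma(y)|`; 0 by convention when
#' both nodes are isolated.
#'
#' @inheritParams cn_index
#' @return Value in `[0, 1]`.
#' @export
jc_index <- function(graph, x, y) {
  stopifnot(x != y)
  gx <- nbr_set(graph, x)
  gy <- nbr_set(graph, y)
  u <- union(gx, gy)
  if (length(u) == 0L) return(0)
  length(intersect(gx, gy)) / length(u)
}

#' Resource-allocation index
#'
#' Sum of reciprocal training-graph degrees over the common neighbours:
#' high-degree shared neighbours contribute less.
#'
#' @inheritParams cn_index
#' @return Non-negative real.
#' @export
ra_index <- function(graph, x, y) {
  stopifnot(x != y)
  z <- intersect(nbr_set(graph, x), nbr_set(graph, y))
  if (length(z) == 0L) return(0)
  sum(1 / igraph::degree(graph, z))
}

# Vectorized scoring of many pairs via sparse adjacency algebra.
score_pairs <- function(graph, pairs, index = c("cn", "jc", "ra")) {
  index <- match.arg(index)
  A <- igraph::as_adjacency_matrix(graph, sparse = TRUE)
  nodes <- rownames(A)
  ia <- match(pairs[[1]], nodes)
  ib <- match(pairs[[2]], nodes)
  if (anyNA(ia) || anyNA(ib)) stop("pair references an unknown node")
  deg <- Matrix::rowSums(A)
  S <- switch(index,
    cn = A %*% A,
    jc = A %*% A,
    ra = A %*% Matrix::Diagonal(x = ifelse(deg > 0, 1 / deg, 0)) %*% A
  )
  cn <- as.numeric(S[cbind(ia, ib)])
  if (index == "jc") {
    un <- unname(deg[ia] + deg[ib]) - cn
    cn <- ifelse(un > 0, cn / un, 0)
  }
  cn
}

#' Exact link-prediction AUC
#'
#' Rank-based (Mann-Whitney) probability that a uniformly chosen probe pair
#' outscores a uniformly chosen non-edge pair, ties counting 1/2 — computed
#' exactly from ranks, no sampling.
#'
#' @param scored data frame with columns `score` and logical `probe`.
#' @return AUC in `[0, 1]` (0.5 when all scores tie).
#' @export
auc_score <- function(scored) {
  n1 <- sum(scored$probe)
  n0 <- sum(!scored$probe)
  if (n1 == 0L || n0 == 0L) stop("need at least one probe and one non-edge")
  r <- rank(scored$score)
  (sum(r[scored$probe]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Precision-recall curve over ranked candidate pairs
#'
#' Candidates are sorted by score descending (ties broken by pair id); at
#' each cutoff L the precision is `m / L` and the recall `m / M`, with `m`
#' the probes among the top L and `M` the number of probe edges (so recall
#' reaches 1; the variant normalizing by all surviving edges
#' `|E| - |E_r|` is available). AUCPR is the trapezoidal area under
#' (recall, precision).
#'
#' @param scored data frame with columns `pair` (id used for tie-breaks),
#'   `score`, `probe`.
#' @param recall_denominator `"probes"` (M = number of probes) or
#'   `"removed_complement"` (M supplied via `m_total`).
#' @param m_total denominator override used by `"removed_complement"`.
#' @return List with vectors `precision`, `recall`, scalar `aucpr`, and
#'   `precision_at`/`recall_at` for L in 10, 50, 100 (where available).
#' @export
pr_curve <- function(scored, recall_denominator = c("probes",
                                                    "removed_complement"),
                     m_total = NULL) {
  recall_denominator <- match.arg(recall_denominator)
  M <- if (recall_denominator == "probes") sum(scored$probe) else m_total
  if (is.null(M) || M == 0L) stop("recall denominator M is zero or missing")
  o <- order(-scored$score, scored$pair)
  hit <- cumsum(scored$probe[o])
  L <- seq_along(hit)
  precision <- hit / L
  recall <- hit / M
  aucpr <- sum(diff(c(0, recall)) * (precision + c(precision[1], head(precision, -1))) / 2)
  at <- c(10L, 50L, 100L)
  at <- at[at <= length(L)]
  list(precision = precision, recall = recall, aucpr = aucpr,
       precision_at = stats::setNames(precision[at], at),
       recall_at = stats::setNames(recall[at], at))
}

# Candidate pairs for one split: probes (E_t) plus non-edges of the full
# network (E excluded entirely, so removed edges are never scored).
candidate_pairs <- function(split, max_exhaustive_nodes = 2000L,
                            nonedge_factor = 10L) {
  nodes <- split$nodes
  all_edges <- rbind(split$e_r, split$e_p, split$e_t)
  edge_keys <- pair_key(all_edges$a, all_edges$b)
  n <- length(nodes)
  if (n <= max_exhaustive_nodes) {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    a <- nodes[idx[, 1]]
    b <- nodes[idx[, 2]]
    keys <- pair_key(a, b)
    keep <- !(keys %in% edge_keys)
    non <- data.frame(a = pmin(a, b)[keep], b = pmax(a, b)[keep],
                      stringsAsFactors = FALSE)
  } else {
    want <- nonedge_factor * nrow(split$e_t)
    got <- character(0)
    non_a <- character(0)
    non_b <- character(0)
    while (length(got) < want) {
      a <- nodes[sample.int(n, want, replace = TRUE)]
      b <- nodes[sample.int(n, want, replace = TRUE)]
      ok <- a != b
      a <- a[ok]; b <- b[ok]
      keys <- pair_key(a, b)
      new <- !(keys %in% edge_keys) & !(keys %in% got)
      new <- new & !duplicated(keys)
      got <- c(got, keys[new])
      non_a <- c(non_a, pmin(a, b)[new])
      non_b <- c(non_b, pmax(a, b)[new])
    }
    non <- data.frame(a = non_a[seq_len(want)], b = non_b[seq_len(want)],
                      stringsAsFactors = FALSE)
  }
  probes <- split$e_t
  data.frame(
    a = c(probes$a, non$a),
    b = c(probes$b, non$b),
    probe = rep(c(TRUE, FALSE), c(nrow(probes), nrow(non))),
    stringsAsFactors = FALSE
  )
}

#' Run a repeated link-prediction experiment
#'
#' For each repeat: split the edges, score every candidate pair (probes plus
#' non-edges; exhaustive for networks up to `max_exhaustive_nodes` nodes,
#' otherwise a uniform non-edge sample) with the chosen structural index on
#' the training graph, and compute AUC and the precision-recall summary.
#'
#' @param network a `similarity_network`, igraph, or edge frame.
#' @param index `"cn"`, `"jc"` or `"ra"`.
#' @param remove_frac,probe_frac see [split_edges()].
#' @param repeats number of independent splits.
#' @param seed run-level seed (fanned out per repeat).
#' @param max_exhaustive_nodes exhaustive non-edge enumeration limit.
#' @return A `linkpred_result`: list with `per_repeat` (data frame of auc /
#'   aucpr), their means and standard deviations, and the last repeat's
#'   precision/recall vectors.
#' @export
run_link_prediction <- function(network, index = c("ra", "cn", "jc"),
                                remove_frac = 0.2, probe_frac = 0.2,
                                repeats = 5L, seed = 1L,
                                max_exhaustive_nodes = 2000L) {
  index <- match.arg(index)
  aucs <- numeric(repeats)
  aucprs <- numeric(repeats)
  last <- NULL
  for (r in seq_len(repeats)) {
    split <- split_edges(network, remove_frac, probe_frac,
                         seed = fan_seed(seed, "repeat", r))
    set.seed(fan_seed(seed, "candidates", r))
    cand <- candidate_pairs(split, max_exhaustive_nodes)
    g <- training_graph(split)
    sc <- data.frame(
      pair = pair_key(cand$a, cand$b),
      score = score_pairs(g, cand[, c("a", "b")], index),
      probe = cand$probe,
      stringsAsFactors = FALSE
    )
    aucs[r] <- auc_score(sc)
    last <- pr_curve(sc)
    aucprs[r] <- last$aucpr
  }
  structure(
    list(index = index,
         per_repeat = data.frame(repeat_ = seq_len(repeats), auc = aucs,
                                 aucpr = aucprs),
         auc_mean = mean(aucs), auc_sd = stats::sd(aucs),
         aucpr_mean = mean(aucprs), aucpr_sd = stats::sd(aucprs),
         precision = last$precision, recall = last$recall,
         precision_at = last$precision_at, recall_at = last$recall_at),
    class = "linkpred_result"
  )
}

#' @export
print.linkpred_result <- function(x, ...) {
  cat(sprintf(
    "<linkpred_result> index=%s: AUC %.4f (sd %.4f), AUCPR %.4f (sd %.4f), %d repeats\n",
    x$index, x$auc_mean, x$auc_sd, x$aucpr_mean, x$aucpr_sd,
    nrow(x$per_repeat)))
  invisible(x)
}
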