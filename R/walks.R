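# Biased random walks (node2vec) and walk corpora.

#' Random-walk parameters
#'
#' `p` (return) and `q` (in-out) bias the second-order walk of node2vec;
#' `p = q = 1` reproduces the uniform first-order walk of DeepWalk exactly.
#'
#' @param p return parameter, > 0.
#' @param q in-out parameter, > 0.
#' @param walk_length maximum walk length L.
#' @param walks_per_node walks started from each node, r.
#' @param seed integer seed.
#' @return A `walk_params` list.
#' @export
walk_params <- function(p = 1, q = 1, walk_length = 80, walks_per_node = 10,
                        seed = 1L) {
  stopifnot(p > 0, q > 0, walk_length >= 1, walks_per_node >= 1)
  structure(list(p = p, q = q, walk_length = as.integer(walk_length),
                 walks_per_node = as.integer(walks_per_node),
                 seed = as.integer(seed)),
            class = "walk_params")
}

#' Second-order transition distribution of the biased walk
#'
#' Given the previous node `t` and the current node, the unnormalized weight
#' of stepping to neighbour `x` is `1/p` if `x = t`, `1` if `x` is adjacent
#' to `t`, and `1/q` otherwise; the returned probabilities are normalized to
#' sum to one. Without a previous node (first step) the distribution is
#' uniform over the neighbours.
#'
#' @param graph undirected [igraph::graph].
#' @param curr current node id.
#' @param prev previous node id, or `NULL` for the first step.
#' @param params a [walk_params()].
#' @return Named numeric vector of probabilities over the neighbours of
#'   `curr` (empty if `curr` has none).
#' @export
node2vec_transition <- function(graph, curr, prev = NULL, params = walk_params()) {
  nbrs <- igraph::neighbors(graph, curr)$name
  if (length(nbrs) == 0L) return(stats::setNames(numeric(0), character(0)))
  if (is.null(prev)) {
    w <- rep(1, length(nbrs))
  } else {
    prev_nbrs <- igraph::neighbors(graph, prev)$name
    w <- ifelse(nbrs == prev, 1 / params$p,
                ifelse(nbrs %in% prev_nbrs, 1, 1 / params$q))
  }
  stats::setNames(w / sum(w), nbrs)
}

#' Generate a corpus of (biased) random walks
#'
#' Starts `walks_per_node` walks from every node (node order reshuffled each
#' epoch), stepping by the node2vec second-order rule. Walks stop early only
#' at nodes without neighbours. Deterministic under the seed in `params`.
#'
#' @inheritParams node2vec_transition
#' @return A `walk_corpus`: list with `walks` (list of integer node-index
#'   vectors), `nodes` (node names indexed by those integers), and the
#'   parameters.
#' @export
generate_walks <- function(graph, params = walk_params()) {
  n <- igraph::vcount(graph)
  if (n == 0L) stop("empty graph")
  nodes <- igraph::V(graph)$name
  adj <- lapply(igraph::adjacent_vertices(graph, igraph::V(graph)),
                as.integer)
  uniform <- params$p == 1 && params$q == 1
  L <- params$walk_length

  set.seed(fan_seed(params$seed, "walks"))
  walks <- vector("list", n * params$walks_per_node)
  w_i <- 0L
  for (epoch in seq_len(params$walks_per_node)) {
    for (start in sample.int(n)) {
      walk <- integer(L)
      walk[1L] <- start
      len <- 1L
      while (len < L) {
        cur <- walk[len]
        nb <- adj[[cur]]
        if (length(nb) == 0L) break
        if (uniform || len == 1L) {
          nxt <- nb[sample.int(length(nb), 1L)]
        } else {
          prev <- walk[len - 1L]
          w <- ifelse(nb == prev, 1 / params$p,
                      ifelse(nb %in% adj[[prev]], 1, 1 / params$q))
          nxt <- nb[sample.int(length(nb), 1L, prob = w)]
        }
        len <- len + 1L
        walk[len] <- nxt
      }
      w_i <- w_i + 1L
      walks[[w_i]] <- walk[seq_len(len)]
    }
  }
  structure(list(walks = walks, nodes = nodes, params = params),
            class = "walk_corpus")
}

#' @export
print.walk_corpus <- function(x, ...) {
  cat(sprintf("<walk_corpus> %d walks over %d nodes (L = %d, r = %d)\n",
              length(x$walks), length(x$nodes), x$params$walk_length,
              x$params$walks_per_node))
  invisible(x)
}
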