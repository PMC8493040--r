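# Embedding front-ends: skip-gram over walks, LINE, and the common
# embed_graph() dispatcher.

new_embedding_map <- function(mat, nodes, method) {
  rownames(mat) <- nodes
  structure(mat, method = method, class = c("embedding_map", "matrix", "array"))
}

#' @export
print.embedding_map <- function(x, ...) {
  cat(sprintf("<embedding_map> %d nodes x %d dims (method: %s)\n",
              nrow(x), ncol(x), attr(x, "method")))
  invisible(x)
}

#' Train skip-gram (negative sampling) embeddings from a walk corpus
#'
#' Word2vec-style skip-gram with negative sampling over windowed
#' co-occurrences in the walks. Deterministic for a fixed corpus and seed.
#'
#' @param corpus a `walk_corpus` from [generate_walks()].
#' @param dim embedding dimension d.
#' @param window context window size.
#' @param epochs training passes over the corpus.
#' @param negative negative samples per positive pair.
#' @param alpha initial learning rate (linearly decayed).
#' @param seed integer seed.
#' @param method tag stored on the result (`deepwalk` or `node2vec`).
#' @return An `embedding_map`: numeric matrix, one row per node.
#' @export
train_skipgram <- function(corpus, dim = 128L, window = 10L, epochs = 5L,
                           negative = 5L, alpha = 0.025, seed = 1L,
                           method = "deepwalk") {
  if (dim <= 0L) stop("dim must be positive")
  if (window <= 0L) stop("window must be positive")
  if (length(corpus$walks) == 0L) stop("empty walk corpus")
  mat <- sgns_train_cpp(corpus$walks, length(corpus$nodes), as.integer(dim),
                        as.integer(window), as.integer(epochs),
                        as.integer(negative), alpha,
                        fan_seed(seed, "skipgram"))
  new_embedding_map(mat, corpus$nodes, method)
}

#' LINE embeddings by edge sampling
#'
#' First-order proximity maximizes the log-sigmoid inner product over
#' observed edges with negative sampling; second-order uses separate context
#' vectors; `"concatenated"` trains both at half the dimension and binds the
#' halves.
#'
#' @param graph undirected [igraph::graph] with at least one edge.
#' @param dim embedding dimension.
#' @param order `"first"`, `"second"`, or `"concatenated"`.
#' @param epochs scales the number of edge samples
#'   (`epochs * max(10^4, 200 |E|)`).
#' @param negative negative samples per edge sample.
#' @param alpha initial learning rate.
#' @param seed integer seed.
#' @return An `embedding_map`.
#' @export
line_embed <- function(graph, dim = 128L, order = c("concatenated", "first",
                                                    "second"),
                       epochs = 5L, negative = 5L, alpha = 0.025, seed = 1L) {
  order <- match.arg(order)
  if (igraph::ecount(graph) < 1L) stop("LINE needs a graph with >= 1 edge")
  if (order == "concatenated" && dim %% 2L != 0L) {
    stop("dim must be even for order = 'concatenated'")
  }
  nodes <- igraph::V(graph)$name
  edges <- igraph::as_edgelist(graph, names = FALSE)
  storage.mode(edges) <- "integer"
  n_samples <- epochs * max(1e4, 200 * nrow(edges))
  one <- function(ord, d, off) {
    line_train_cpp(edges, length(nodes), as.integer(d), ord, n_samples,
                   as.integer(negative), alpha,
                   fan_seed(seed, "line", off))
  }
  mat <- switch(order,
    first = one(1L, dim, 1L),
    second = one(2L, dim, 2L),
    concatenated = cbind(one(1L, dim %/% 2L, 1L), one(2L, dim %/% 2L, 2L))
  )
  new_embedding_map(mat, nodes, "line")
}

#' Embed a graph with one of the four supported methods
#'
#' Dispatcher covering DeepWalk (uniform walks + skip-gram), node2vec
#' (p/q-biased walks + skip-gram), LINE and SDNE. DeepWalk and node2vec
#' share one code path; DeepWalk fixes `p = q = 1`.
#'
#' @param graph undirected [igraph::graph].
#' @param method one of `"deepwalk"`, `"node2vec"`, `"line"`, `"sdne"`.
#' @param dim embedding dimension.
#' @param seed integer seed.
#' @param p,q node2vec bias parameters (ignored elsewhere).
#' @param walk_length,walks_per_node,window,epochs walk/training controls.
#' @param ... further arguments passed to [line_embed()] or [sdne_embed()].
#' @return An `embedding_map`.
#' @export
embed_graph <- function(graph, method = c("node2vec", "deepwalk", "line",
                                          "sdne"),
                        dim = 128L, seed = 1L, p = 1, q = 1,
                        walk_length = 80L, walks_per_node = 10L,
                        window = 10L, epochs = 5L, ...) {
  method <- match.arg(method)
  if (method %in% c("deepwalk", "node2vec")) {
    if (method == "deepwalk") {
      p <- 1
      q <- 1
    }
    wp <- walk_params(p = p, q = q, walk_length = walk_length,
                      walks_per_node = walks_per_node, seed = seed)
    corpus <- generate_walks(graph, wp)
    emb <- train_skipgram(corpus, dim = dim, window = window, epochs = epochs,
                          seed = seed, method = method, ...)
  } else if (method == "line") {
    emb <- line_embed(graph, dim = dim, epochs = epochs, seed = seed, ...)
  } else {
    emb <- sdne_embed(graph, dim = dim, epochs = max(epochs * 60L, 100L),
                      seed = seed, ...)
  }
  iso <- igraph::V(graph)$name[igraph::degree(graph) == 0L]
  attr(emb, "isolated") <- iso
  emb
}

#' Write an embedding map as TSV
#'
#' One row per node: node id then the d coordinates. With
#' `word2vec_header = TRUE` a leading "n d" line is written (the word2vec
#' text format).
#'
#' @param embeddings an `embedding_map`.
#' @param path output path.
#' @param word2vec_header write the "n d" header line?
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(embeddings, path, word2vec_header = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  if (word2vec_header) {
    writeLines(paste(nrow(embeddings), ncol(embeddings)), con)
  }
  utils::write.table(
    data.frame(node = rownames(embeddings), unclass(embeddings)[, ,
                                                                drop = FALSE]),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an embedding map written by [write_embeddings()]
#'
#' @param path input path.
#' @param method method tag to attach.
#' @return An `embedding_map`.
#' @export
read_embeddings <- function(path, method = "unknown") {
  first <- readLines(path, n = 1L)
  skip <- if (grepl("^\\d+[ \t]\\d+$", first)) 1L else 0L
  df <- utils::read.table(path, sep = "\t", header = FALSE, skip = skip,
                          stringsAsFactors = FALSE)
  df[[1]] <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  new_embedding_map(mat, df[[1]], method)
}
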