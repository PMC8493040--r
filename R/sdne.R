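# SDNE: adjacency autoencoder with a Laplacian first-order penalty.
#
# The encoder compresses each node's adjacency row S_i through one hidden
# layer to a d-dimensional bottleneck; the decoder reconstructs S_i. Nonzero
# adjacency entries are up-weighted by beta in the reconstruction loss, and
# the bottleneck is pulled together along observed edges by an
# alpha-weighted Laplacian term. Trained full-batch with Adam.

sigm <- function(x) 1 / (1 + exp(-x))

#' SDNE embeddings
#'
#' @param graph undirected [igraph::graph].
#' @param dim bottleneck (embedding) dimension, `< vcount(graph)`.
#' @param hidden hidden-layer width; default `min(256, n)`.
#' @param alpha weight of the first-order (Laplacian) term.
#' @param beta up-weight applied to nonzero adjacency entries in the
#'   reconstruction loss (zero entries keep weight 1).
#' @param epochs full-batch gradient steps; `epochs = 0` returns the random
#'   initialization (still reproducible under the seed).
#' @param lr Adam learning rate.
#' @param l2 weight decay on the layer matrices.
#' @param seed integer seed.
#' @return An `embedding_map` with attribute `loss` (the per-epoch total
#'   loss trace).
#' @export
sdne_embed <- function(graph, dim = 128L, hidden = NULL, alpha = 1e-5,
                       beta = 5, epochs = 300L, lr = 0.01, l2 = 1e-4,
                       seed = 1L) {
  n <- igraph::vcount(graph)
  if (n == 0L) stop("empty graph")
  if (dim >= n) stop("SDNE requires dim < number of nodes")
  hidden <- hidden %||% min(256L, n)
  nodes <- igraph::V(graph)$name
  S <- as.matrix(igraph::as_adjacency_matrix(graph, sparse = TRUE))
  storage.mode(S) <- "double"
  B <- 1 + (beta - 1) * (S > 0)
  L <- diag(igraph::degree(graph)) - S  # unnormalized Laplacian

  set.seed(fan_seed(seed, "sdne"))
  init <- function(a, b) matrix(stats::rnorm(a * b, sd = sqrt(2 / (a + b))),
                                a, b)
  params <- list(W1 = init(n, hidden), b1 = rep(0, hidden),
                 W2 = init(hidden, dim), b2 = rep(0, dim),
                 W3 = init(dim, hidden), b3 = rep(0, hidden),
                 W4 = init(hidden, n), b4 = rep(0, n))
  mom <- lapply(params, function(p) p * 0)
  vel <- lapply(params, function(p) p * 0)
  b1a <- 0.9; b2a <- 0.999; epsa <- 1e-8

  forward <- function(pm) {
    H1 <- sigm(sweep(S %*% pm$W1, 2, pm$b1, "+"))
    Y <- sigm(sweep(H1 %*% pm$W2, 2, pm$b2, "+"))
    H2 <- sigm(sweep(Y %*% pm$W3, 2, pm$b3, "+"))
    Xh <- sigm(sweep(H2 %*% pm$W4, 2, pm$b4, "+"))
    list(H1 = H1, Y = Y, H2 = H2, Xh = Xh)
  }

  loss_trace <- numeric(0)
  for (ep in seq_len(epochs)) {
    fw <- forward(params)
    R <- (fw$Xh - S) * B
    l_rec <- sum(R^2)
    l_first <- alpha * sum(diag(crossprod(fw$Y, L %*% fw$Y)))
    loss_trace <- c(loss_trace, l_rec + l_first)
    if (!is.finite(l_rec + l_first)) {
      stop("SDNE training diverged (non-finite loss at epoch ", ep, ")")
    }

    dXh <- 2 * R * B * fw$Xh * (1 - fw$Xh)
    dW4 <- crossprod(fw$H2, dXh) + l2 * params$W4
    db4 <- colSums(dXh)
    dH2 <- tcrossprod(dXh, params$W4) * fw$H2 * (1 - fw$H2)
    dW3 <- crossprod(fw$Y, dH2) + l2 * params$W3
    db3 <- colSums(dH2)
    dY <- tcrossprod(dH2, params$W3) + 2 * alpha * (L %*% fw$Y)
    dY <- dY * fw$Y * (1 - fw$Y)
    dW2 <- crossprod(fw$H1, dY) + l2 * params$W2
    db2 <- colSums(dY)
    dH1 <- tcrossprod(dY, params$W2) * fw$H1 * (1 - fw$H1)
    dW1 <- crossprod(S, dH1) + l2 * params$W1
    db1 <- colSums(dH1)

    grads <- list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
                  W3 = dW3, b3 = db3, W4 = dW4, b4 = db4)
    for (nm in names(params)) {
      mom[[nm]] <- b1a * mom[[nm]] + (1 - b1a) * grads[[nm]]
      vel[[nm]] <- b2a * vel[[nm]] + (1 - b2a) * grads[[nm]]^2
      mhat <- mom[[nm]] / (1 - b1a^ep)
      vhat <- vel[[nm]] / (1 - b2a^ep)
      params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + epsa)
    }
  }

  Y <- forward(params)$Y
  emb <- new_embedding_map(Y, nodes, "sdne")
  attr(emb, "loss") <- loss_trace
  emb
}
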