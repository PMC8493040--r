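test_that("node2vec transition follows the 1/p, 1, 1/q rule and normalizes", {
  path <- igraph::make_graph(~ a - b, b - c)
  # prev = a, curr = b, p = 2, q = 4: weights {a: 1/2, c: 1/4}
  pr <- node2vec_transition(path, "b", "a", walk_params(p = 2, q = 4))
  expect_equal(pr[["a"]], 2 / 3)
  expect_equal(pr[["c"]], 1 / 3)

  tri <- igraph::make_graph(~ a - b, b - c, a - c, c - d)
  # prev = a, curr = c, p = 1, q = 2: weights {a: 1, b: 1, d: 1/2}
  pr2 <- node2vec_transition(tri, "c", "a", walk_params(p = 1, q = 2))
  expect_equal(pr2[["d"]], 0.2)
  expect_equal(sum(pr2), 1)

  # p = q = 1 reduces to the uniform DeepWalk step
  pr3 <- node2vec_transition(tri, "c", "a", walk_params())
  expect_equal(unname(pr3), rep(1 / 3, 3))

  # first step (no prev) is uniform; isolated node has empty distribution
  expect_equal(unname(node2vec_transition(path, "b", NULL, walk_params())),
               c(0.5, 0.5))
  iso <- igraph::make_graph(~ a - b) + igraph::vertex("z")
  expect_length(node2vec_transition(iso, "z", NULL, walk_params()), 0)
})

test_that("generate_walks respects adjacency, length, count and seed", {
  g <- igraph::make_graph(~ a - b, b - c, c - d) + igraph::vertex("z")
  wp <- walk_params(walk_length = 5, walks_per_node = 3, seed = 7)
  corp <- generate_walks(g, wp)
  expect_length(corp$walks, 3 * igraph::vcount(g))
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  for (w in corp$walks) {
    expect_lte(length(w), 5)
    if (length(w) > 1) {
      steps <- cbind(w[-length(w)], w[-1])
      expect_true(all(A[steps] == 1))
    }
  }
  # isolated node: r walks of length 1
  zi <- match("z", corp$nodes)
  zwalks <- Filter(function(w) w[1] == zi, corp$walks)
  expect_length(zwalks, 3)
  expect_true(all(lengths(zwalks) == 1))
  # determinism
  corp2 <- generate_walks(g, wp)
  expect_identical(corp$walks, corp2$walks)
})

test_that("first-step transition frequencies match the uniform law", {
  g <- igraph::make_graph(~ a - b, a - c, a - d, a - e)
  corp <- generate_walks(g, walk_params(walk_length = 2,
                                        walks_per_node = 3000, seed = 5))
  firsts <- vapply(Filter(function(w) w[1] == match("a", corp$nodes),
                          corp$walks),
                   function(w) w[2], integer(1))
  freq <- tabulate(firsts, nbins = length(corp$nodes))[-match("a", corp$nodes)]
  # 3000 walks from a over 4 neighbours; 3 binomial SEs ~ 0.024
  expect_true(all(abs(freq / 3000 - 0.25) < 0.025))
})

test_that("skip-gram embeddings separate two cliques and are reproducible", {
  g <- two_cliques()
  groups <- stats::setNames(rep(1:2, each = 10), igraph::V(g)$name)
  corp <- generate_walks(g, walk_params(walk_length = 20, walks_per_node = 5,
                                        seed = 2))
  emb <- train_skipgram(corp, dim = 16, window = 5, epochs = 3, seed = 2)
  expect_equal(dim(unclass(emb)), c(20L, 16L))
  sep <- cosine_separation(emb, groups)
  expect_gt(sep["within"], sep["between"])

  emb2 <- train_skipgram(corp, dim = 16, window = 5, epochs = 3, seed = 2)
  expect_identical(unclass(emb), unclass(emb2))
  expect_error(train_skipgram(corp, dim = 0), "positive")
  expect_error(train_skipgram(corp, dim = 4, window = 0), "positive")
})

test_that("a single-node corpus still yields a finite vector", {
  g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertex("solo")
  corp <- generate_walks(g, walk_params(walks_per_node = 2, seed = 1))
  emb <- train_skipgram(corp, dim = 8, window = 2, epochs = 1, seed = 1)
  expect_true(all(is.finite(unclass(emb)["solo", ])))
})

test_that("LINE first order pulls edge endpoints together", {
  g <- igraph::make_graph(~ a - b)
  emb <- line_embed(g, dim = 8, order = "first", epochs = 5, seed = 3)
  expect_gt(sum(unclass(emb)["a", ] * unclass(emb)["b", ]), 0)
  expect_error(line_embed(g, dim = 7, order = "concatenated"), "even")
  emb2 <- line_embed(g, dim = 8, order = "first", epochs = 5, seed = 3)
  expect_identical(unclass(emb), unclass(emb2))
})

test_that("LINE separates two cliques", {
  g <- two_cliques()
  groups <- stats::setNames(rep(1:2, each = 10), igraph::V(g)$name)
  emb <- line_embed(g, dim = 16, epochs = 3, seed = 4)
  sep <- cosine_separation(emb, groups)
  expect_gt(sep["within"], sep["between"])
})

test_that("SDNE trains, reduces its loss, separates cliques, reproduces", {
  g <- two_cliques()
  groups <- stats::setNames(rep(1:2, each = 10), igraph::V(g)$name)
  emb <- sdne_embed(g, dim = 4, epochs = 80, seed = 5)
  tr <- attr(emb, "loss")
  expect_lt(tr[length(tr)], tr[1])
  sep <- cosine_separation(emb, groups)
  expect_gt(sep["within"], sep["between"])

  # epochs = 0: random but reproducible initialization
  e0a <- sdne_embed(g, dim = 4, epochs = 0, seed = 9)
  e0b <- sdne_embed(g, dim = 4, epochs = 0, seed = 9)
  expect_identical(unclass(e0a), unclass(e0b))
  expect_true(all(is.finite(unclass(e0a))))
  expect_error(sdne_embed(g, dim = 30), "dim <")
})

test_that("embed_graph dispatches DeepWalk as node2vec with p = q = 1", {
  g <- two_cliques()
  dw <- embed_graph(g, "deepwalk", dim = 8, walk_length = 10,
                    walks_per_node = 2, window = 3, epochs = 1, seed = 6)
  nv <- embed_graph(g, "node2vec", dim = 8, p = 1, q = 1, walk_length = 10,
                    walks_per_node = 2, window = 3, epochs = 1, seed = 6)
  expect_equal(unclass(dw), unclass(nv), ignore_attr = TRUE)
  expect_identical(attr(dw, "method"), "deepwalk")
})

test_that("embeddings round-trip through the TSV formats", {
  g <- two_cliques()
  emb <- embed_graph(g, "deepwalk", dim = 4, walk_length = 5,
                     walks_per_node = 1, window = 2, epochs = 1, seed = 8)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_embeddings(emb, f)
  back <- read_embeddings(f, method = "deepwalk")
  expect_equal(unclass(back), unclass(emb), tolerance = 1e-8,
               ignore_attr = TRUE)
  f2 <- withr::local_tempfile(fileext = ".txt")
  write_embeddings(emb, f2, word2vec_header = TRUE)
  expect_equal(readLines(f2, n = 1), "20 4")
})
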