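test_that("DTW handles the degenerate and hand-computed grids", {
  v <- matrix(rnorm(6), 2, 3)
  expect_equal(dtw_distance(v, v), 0)
  a <- matrix(rnorm(3), 1)
  b <- matrix(rnorm(3), 1)
  expect_equal(dtw_distance(a, b), sqrt(sum((a - b)^2)))

  # 1-D sets {0, 1} vs {0, 2} under absolute difference:
  # local grid rows (0,2),(1,1); cumulative rows (0,2),(1,2); distance 2
  al <- dtw_alignment(matrix(c(0, 1), ncol = 1), matrix(c(0, 2), ncol = 1))
  expect_equal(al$D, matrix(c(0, 1, 2, 2), 2, 2))
  expect_equal(al$distance, 2)
  expect_equal(al$path[1, ], c(i = 1, j = 1))
  expect_equal(al$path[nrow(al$path), ], c(i = 2, j = 2))
  steps <- diff(al$path)
  expect_true(all(steps %in% 0:1) && all(rowSums(steps) >= 1))

  expect_error(dtw_distance(matrix(1, 1, 2), matrix(1, 1, 3)), "dimension")
  expect_error(dtw_distance(matrix(numeric(0), 0, 2), matrix(1, 1, 2)),
               "empty")
})

test_that("DTW equals the brute-force path enumeration and is symmetric", {
  set.seed(42)
  for (i in 1:30) {
    m <- sample(1:4, 1)
    n <- sample(1:4, 1)
    d <- sample(1:3, 1)
    vm <- matrix(rnorm(m * d), m, d)
    vn <- matrix(rnorm(n * d), n, d)
    dl <- euclid_local(vm, vn)
    expect_equal(dtw_distance(vm, vn), brute_dtw(dl), tolerance = 1e-9)
    expect_equal(dtw_distance(vm, vn), dtw_distance(vn, vm))
    expect_gte(dtw_distance(vm, vn), 0)
  }
})

test_that("normalized DTW similarity maps distance into (0, 1]", {
  v <- matrix(rnorm(8), 2, 4)
  expect_equal(normalized_dtw_similarity(v, v), 1)
  # the hand case: D = 2, m + n = 4 -> 1 / (1 + 0.5) = 2/3
  expect_equal(normalized_dtw_similarity(matrix(c(0, 1), ncol = 1),
                                         matrix(c(0, 2), ncol = 1)), 2 / 3)
  # monotone: larger raw DTW means strictly smaller similarity
  s1 <- normalized_dtw_similarity(matrix(c(0, 1), ncol = 1),
                                  matrix(c(0, 2), ncol = 1))
  s2 <- normalized_dtw_similarity(matrix(c(0, 1), ncol = 1),
                                  matrix(c(0, 5), ncol = 1))
  expect_gt(s1, s2)
})

test_that("cosine similarity covers identity, orthogonality, zero vectors", {
  w <- rnorm(5)
  expect_equal(cosine_similarity(w, w), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 0), c(1, 1)), 1 / sqrt(2))
  expect_true(is.na(cosine_similarity(c(0, 0), c(1, 1))))
})

make_term_embedding <- function(terms, d = 4, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(length(terms) * d), length(terms), d)
  rownames(m) <- terms
  structure(m, method = "test", class = c("embedding_map", "matrix", "array"))
}

test_that("similarity_matrix scores all pairs and records undefined ones", {
  terms <- sprintf("GO:%07d", 1:6)
  emb <- make_term_embedding(terms[1:5])  # GO:...6 left unembedded
  ann <- annotation_set(list(
    P1 = terms[1:2], P2 = terms[2:3], P3 = terms[c(1, 4)], P4 = terms[6]))
  sim <- similarity_matrix(c("P1", "P2", "P3", "P4"), "go_dtw", emb, ann)
  expect_equal(nrow(sim$pairs), choose(3, 2))
  expect_equal(nrow(sim$undefined), 3)
  expect_true(all(sim$undefined$protein_a == "P4" |
                    sim$undefined$protein_b == "P4"))
  M <- as.matrix(sim)
  expect_equal(diag(M), stats::setNames(rep(1, 4), sort(c("P1", "P2", "P3",
                                                          "P4"))))
  expect_equal(M["P1", "P2"], M["P2", "P1"])

  # invariant to the input ordering of proteins
  sim2 <- similarity_matrix(c("P3", "P1", "P4", "P2"), "go_dtw", emb, ann)
  expect_equal(sim2$pairs, sim$pairs)

  # identical singleton annotation sets give similarity exactly 1
  ann_same <- annotation_set(list(A = terms[1], B = terms[1], C = terms[1]))
  sim3 <- similarity_matrix(c("A", "B", "C"), "go_dtw", emb, ann_same)
  expect_equal(sim3$pairs$score, rep(1, 3))
})

test_that("goa_cosine mode scores protein vectors", {
  emb <- make_term_embedding(c("P1", "P2", "P3"))
  sim <- similarity_matrix(c("P1", "P2", "P3"), "goa_cosine", emb)
  expect_equal(nrow(sim$pairs), 3)
  expect_true(all(sim$pairs$score >= -1 & sim$pairs$score <= 1))
})

test_that("screening rules keep the right pairs", {
  pairs <- data.frame(protein_a = c("A", "A", "B"),
                      protein_b = c("B", "C", "C"),
                      score = c(0.9, 0.5, 0.3))
  net <- screen_network(pairs, tau = 0.4)
  expect_equal(nrow(net$edges), 2)

  set.seed(3)
  big <- data.frame(protein_a = sprintf("P%03d", 1:100),
                    protein_b = sprintf("Q%03d", 1:100),
                    score = runif(100))
  top <- screen_network(big, band = "top")
  expect_equal(nrow(top$edges), 5)
  expect_equal(top$edges$score, sort(big$score, decreasing = TRUE)[1:5])
  last <- screen_network(big, band = "last")
  mid <- screen_network(big, band = "middle")
  key <- function(n) paste(n$edges$protein_a, n$edges$protein_b)
  expect_length(intersect(key(top), key(last)), 0)
  expect_length(intersect(key(top), key(mid)), 0)
  expect_error(screen_network(big), "exactly one")
  expect_error(screen_network(big, band = "top", band_frac = 0.001),
               "band wider")
})

test_that("coincidence degree normalizes by the larger edge set", {
  ea <- data.frame(a = c("x", "y"), b = c("y", "z"))
  expect_equal(coincidence_degree(ea, ea), 1)
  eb <- data.frame(a = "p", b = "q")
  expect_equal(coincidence_degree(ea, eb), 0)
  # |Ea| = 10, |Eb| = 4, overlap 2 -> 2/10
  ea10 <- data.frame(a = sprintf("a%02d", 1:10), b = sprintf("b%02d", 1:10))
  eb4 <- data.frame(a = c(ea10$a[1:2], "u", "v"),
                    b = c(ea10$b[1:2], "w", "x"))
  expect_equal(coincidence_degree(ea10, eb4), 0.2)
  expect_equal(coincidence_degree(eb4, ea10), 0.2)
  expect_error(coincidence_degree(ea[0, ], eb), "empty")
})
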