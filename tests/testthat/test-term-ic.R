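test_that("annotation frequency counts a term's descendant closure", {
  # corpus of 50 proteins, 10 annotated by g or its offspring -> p(g) = 0.2
  ont <- ontology_graph(
    terms = data.frame(
      id = c("GO:0000001", "GO:0000002", "GO:0000003", "GO:0000004",
             "GO:0000005"),
      name = c("root", "g", "g child 1", "g child 2", "other"),
      namespace = "biological_process", obsolete = FALSE),
    relations = data.frame(
      child = c("GO:0000002", "GO:0000003", "GO:0000004", "GO:0000005"),
      parent = c("GO:0000001", "GO:0000002", "GO:0000002", "GO:0000001"),
      type = "is_a")
  )
  ann <- c(
    lapply(1:4, function(i) "GO:0000002"),
    lapply(1:3, function(i) "GO:0000003"),
    lapply(1:3, function(i) "GO:0000004"),
    lapply(1:40, function(i) "GO:0000005")
  )
  names(ann) <- sprintf("P%02d", seq_along(ann))
  ict <- compute_ic_table(ont, annotation_set(ann))
  expect_equal(ict$p[ict$term == "GO:0000002"], 0.2)
  expect_equal(ict$ic[ict$term == "GO:0000002"], -log(0.2))
  # root covers every protein
  expect_equal(ict$p[ict$term == "GO:0000001"], 1)
  expect_equal(ict$ic[ict$term == "GO:0000001"], 0)
})

test_that("a single leaf annotation propagates p = 1 up a chain", {
  ont <- chain_ontology()
  ict <- compute_ic_table(ont, annotation_set(list(P1 = "GO:0000003")))
  expect_equal(ict$p, rep(1, 3))
})

test_that("cycles in the directed relations are fatal", {
  ont <- ontology_graph(
    terms = data.frame(id = c("GO:0000001", "GO:0000002"), name = c("A", "B"),
                       namespace = "biological_process", obsolete = FALSE),
    relations = data.frame(child = c("GO:0000001", "GO:0000002"),
                           parent = c("GO:0000002", "GO:0000001"),
                           type = "is_a")
  )
  expect_error(compute_ic_table(ont, annotation_set(list(P1 = "GO:0000001"))),
               "cycle")
})

test_that("IC table matches the brute-force descendant-count oracle", {
  for (seed in 1:4) {
    spec <- fixture_spec(n_terms = sample(20:50, 1), n_layers = 4,
                         n_proteins = 20, k_range = c(2, 4), seed = seed)
    set.seed(seed)
    ont <- gen_ontology(spec)
    ann <- gen_annotations(spec, ont)
    ict <- compute_ic_table(ont, ann)
    oracle <- brute_ic_p(ont, ann)
    expect_equal(stats::setNames(ict$p, ict$term), oracle[ict$term])
    # monotonicity: p never decreases from child to parent
    rel <- ont$relations
    expect_true(all(oracle[rel$child] <= oracle[rel$parent] + 1e-12))
  }
})

test_that("mica picks the most informative common ancestor", {
  ont <- chain_ontology()
  ict <- compute_ic_table(ont, chain_quarter_annotations())
  expect_equal(mica("GO:0000003", "GO:0000003", ict), "GO:0000003")
  expect_equal(mica("GO:0000003", "GO:0000002", ict), "GO:0000002")

  # siblings meet only at the root
  ont2 <- ontology_graph(
    terms = data.frame(id = c("GO:0000001", "GO:0000002", "GO:0000003"),
                       name = c("A", "B", "C"),
                       namespace = "biological_process", obsolete = FALSE),
    relations = data.frame(child = c("GO:0000002", "GO:0000003"),
                           parent = "GO:0000001", type = "is_a")
  )
  ict2 <- compute_ic_table(
    ont2, annotation_set(list(P1 = "GO:0000002", P2 = "GO:0000003")))
  expect_equal(mica("GO:0000002", "GO:0000003", ict2), "GO:0000001")
})

test_that("Jiang-Conrath similarity has its closed forms and sign", {
  ont <- chain_ontology()
  ict <- compute_ic_table(ont, chain_quarter_annotations())
  # p(A) = 1, p(B) = 1/2, p(C) = 1/4
  expect_equal(sim_jc("GO:0000003", "GO:0000003", ict), 0)
  expect_equal(sim_jc("GO:0000003", "GO:0000002", ict), -log(2))
  # siblings with equal ic k under a zero-ic root -> -2k
  ont2 <- ontology_graph(
    terms = data.frame(id = c("GO:0000001", "GO:0000002", "GO:0000003"),
                       name = c("A", "B", "C"),
                       namespace = "biological_process", obsolete = FALSE),
    relations = data.frame(child = c("GO:0000002", "GO:0000003"),
                           parent = "GO:0000001", type = "is_a")
  )
  ict2 <- compute_ic_table(
    ont2, annotation_set(list(P1 = "GO:0000002", P2 = "GO:0000003")))
  k <- -log(0.5)
  expect_equal(sim_jc("GO:0000002", "GO:0000003", ict2), -2 * k)
  expect_lte(sim_jc("GO:0000002", "GO:0000003", ict2), 0)
})

test_that("relevance similarity composes the Lin ratio with MICA rarity", {
  ont <- chain_ontology()
  ict <- compute_ic_table(ont, chain_quarter_annotations())
  # identical terms: lin = 1, so sim = 1 - p(g)
  ontg <- ontology_graph(
    terms = data.frame(id = c("GO:0000001", "GO:0000002"),
                       name = c("root", "g"),
                       namespace = "biological_process", obsolete = FALSE),
    relations = data.frame(child = "GO:0000002", parent = "GO:0000001",
                           type = "is_a")
  )
  ann <- c(lapply(1:1, function(i) "GO:0000002"),
           lapply(1:4, function(i) "GO:0000001"))
  names(ann) <- sprintf("P%d", 1:5)
  ictg <- compute_ic_table(ontg, annotation_set(ann))
  expect_equal(p_of <- ictg$p[ictg$term == "GO:0000002"], 0.2)
  expect_equal(sim_rel("GO:0000002", "GO:0000002", ictg), 0.8)

  # chain p = (1, 1/2, 1/4): sim_rel(C, B) = (2 log2 / 3 log2) * 1/2 = 1/3
  expect_equal(sim_rel("GO:0000003", "GO:0000002", ict), 1 / 3)
  # MICA at the root (p = 1) kills the multiplicative form
  ict2 <- compute_ic_table(
    ont, annotation_set(list(P1 = "GO:0000003", P2 = "GO:0000002",
                             P3 = "GO:0000001")))
  expect_equal(sim_rel("GO:0000001", "GO:0000001", ict2), 0)
  # additive variant exceeds the multiplicative one off the root
  expect_gt(sim_rel("GO:0000003", "GO:0000002", ict, composition = "additive"),
            sim_rel("GO:0000003", "GO:0000002", ict))
})

test_that("best-match average evaluates and symmetrizes Eq-style examples", {
  ann <- annotation_set(list(Pm = "GO:0000010", Pn = c("GO:0000011",
                                                       "GO:0000012"),
                             Pq = "GO:0000010"))
  sim_tab <- function(g1, g2) {
    key <- paste(sort(c(g1, g2)), collapse = "|")
    switch(key,
           "GO:0000010|GO:0000011" = 0.9,
           "GO:0000010|GO:0000012" = 0.1,
           "GO:0000010|GO:0000010" = 0.6,
           NA_real_)
  }
  # 1/2 * (0.9 + (0.9 + 0.1) / 2) = 0.7
  expect_equal(bma("Pm", "Pn", ann, sim_tab), 0.7)
  expect_equal(bma("Pn", "Pm", ann, sim_tab), bma("Pm", "Pn", ann, sim_tab))
  # singleton sets reduce to the single term-pair similarity
  expect_equal(bma("Pm", "Pq", ann, sim_tab), 0.6)
  # all pairs undefined -> undefined
  expect_true(is.na(bma("Pm", "Pn", ann, function(a, b) NA_real_)))
})

test_that("rel similarity stays in [0, 1) and jc non-positive on fixtures", {
  spec <- fixture_spec(n_terms = 40, n_layers = 4, n_proteins = 25,
                       k_range = c(2, 4), seed = 13)
  ont <- gen_ontology(spec)
  ann <- gen_annotations(spec, ont)
  ict <- compute_ic_table(ont, ann)
  set.seed(13)
  terms <- sample(ict$term[is.finite(ict$ic)], 10)
  for (i in 1:9) {
    r <- sim_rel(terms[i], terms[i + 1], ict)
    j <- sim_jc(terms[i], terms[i + 1], ict)
    if (!is.na(r)) expect_true(r >= 0 && r < 1)
    if (!is.na(j)) expect_lte(j, 0)
  }
})
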