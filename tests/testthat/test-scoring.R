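test_that("BDeu log score matches closed-form and degenerate cases", {
  d0 <- forward_sample(cancer_fixture(0.9)$network, 0)
  expect_identical(bdeu_log_score(cancer_true(), d0), 0)

  # single binary variable, records {0, 1}, ess = 1:
  # Gamma(1)/Gamma(3) * (Gamma(1.5)/Gamma(0.5))^2 = 1/8
  d1 <- as_bn_dataset(data.frame(x = c("0", "1")))
  expect_equal(bdeu_log_score(empty_graph(1, "x"), d1), log(1 / 8), tolerance = 1e-12)

  two_cycle <- structure(
    list(adjacency = matrix(c(0L, 1L, 1L, 0L), 2, 2), variables = c("a", "b")),
    class = "bn_graph"
  )
  d2 <- as_bn_dataset(data.frame(a = c("0", "1"), b = c("0", "1")))
  expect_error(bdeu_log_score(two_cycle, d2), "acyclic")
})

test_that("BDeu agrees with a literal transcription on random problems", {
  for (s in 1:25) {
    pr <- random_problem(p = 3 + s %% 2, n = 50 + 10 * s, seed = s, max_arity = 3)
    g <- random_dag(n_variables(pr$data), s %% 4, seed = s + 50)
    expect_equal(
      bdeu_log_score(g, pr$data),
      bdeu_oracle(g, pr$data),
      tolerance = 1e-9
    )
    expect_lte(bdeu_log_score(g, pr$data), 0)
  }
})

test_that("BDeu is score-equivalent across three-node equivalence classes", {
  pr <- random_problem(p = 3, n = 150, seed = 7, max_arity = 3)
  dags <- lapply(penbayes:::enumerate_dags(3), bn_graph)
  expect_length(dags, 25)
  scores <- vapply(dags, bdeu_log_score, numeric(1), d = pr$data)
  keys <- vapply(dags, function(g) {
    s <- skeleton_and_vstructures(g)
    paste(c(t(s$skeleton), t(s$v_structures)), collapse = "-")
  }, character(1))
  for (k in unique(keys)) {
    cls <- scores[keys == k]
    expect_lt(max(cls) - min(cls), 1e-6)
  }
  expect_gt(length(unique(keys)), 1)
})

test_that("the score decomposes into independent family terms", {
  pr <- random_problem(p = 4, n = 120, seed = 3)
  d <- pr$data
  # changing node 2's parent set changes the score by the same amount
  # whatever the rest of the graph looks like
  base1 <- graph_from_edges(4, rbind(c(1, 2)))
  alt1 <- graph_from_edges(4, rbind(c(1, 2), c(3, 2)))
  base2 <- graph_from_edges(4, rbind(c(1, 2), c(1, 4), c(3, 4)))
  alt2 <- graph_from_edges(4, rbind(c(1, 2), c(3, 2), c(1, 4), c(3, 4)))
  delta1 <- bdeu_log_score(alt1, d) - bdeu_log_score(base1, d)
  delta2 <- bdeu_log_score(alt2, d) - bdeu_log_score(base2, d)
  expect_equal(delta1, delta2, tolerance = 1e-9)
})

test_that("edge strength normalises the score magnitude per record and edge", {
  d <- forward_sample(cancer_fixture(0.9)$network, 400, seed = 2)
  g <- cancer_true()
  es <- edge_strength(g, d)
  expect_equal(es, abs(bdeu_log_score(g, d)) / (400 * 5), tolerance = 1e-12)
  expect_gt(es, 0)
  expect_identical(edge_strength(empty_graph(5, cancer_vars), d), Inf)
  d0 <- forward_sample(cancer_fixture(0.9)$network, 0)
  expect_error(edge_strength(g, d0), "at least one record")
})

test_that("structure weights normalise quality and exclude edgeless graphs", {
  d <- forward_sample(cancer_fixture(0.9)$network, 500, seed = 3)
  g <- cancer_true()
  expect_equal(structure_weights(list(g), d), 1)
  # identical structures share the edge strength: equal thirds
  expect_equal(structure_weights(list(g, g, g), d), rep(1 / 3, 3))
  w <- structure_weights(list(cancer_b1(), cancer_b2(), cancer_b3()), d)
  expect_equal(sum(w), 1, tolerance = 1e-9)
  expect_true(all(w > 0))
  # lower edge strength (better structure) must carry more weight
  es <- vapply(
    list(cancer_b1(), cancer_b2(), cancer_b3()),
    edge_strength, numeric(1), d = d
  )
  expect_identical(order(w), order(-es))

  expect_warning(
    w2 <- structure_weights(list(g, empty_graph(5, cancer_vars)), d),
    "edgeless"
  )
  expect_equal(w2, c(1, 0))
  expect_error(
    suppressWarnings(structure_weights(list(empty_graph(5, cancer_vars)), d)),
    "edgeless"
  )
})

test_that("weighted adjacency scales the 0/1 matrix elementwise", {
  b1 <- cancer_b1()
  expect_identical(weighted_adjacency(b1, 0), matrix(0, 5, 5, dimnames = dimnames(b1$adjacency)) * 1)
  expect_identical(weighted_adjacency(b1, 1), b1$adjacency * 1)
  wa <- weighted_adjacency(b1, 0.31)
  expect_equal(wa[2, 1], 0.31)
  expect_equal(wa[3, 1], 0.31)
  expect_equal(wa[4, 2], 0.31)
  expect_equal(wa[5, 3], 0.31)
  expect_equal(sum(wa), 4 * 0.31)
})
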