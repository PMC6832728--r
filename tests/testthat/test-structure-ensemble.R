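test_that("the weighted adjacency sum reproduces the worked five-node merge", {
  graphs <- list(cancer_b1(), cancer_b2(), cancer_b3())
  w <- c(0.31, 0.34, 0.35)
  fw <- final_weighted_adjacency(graphs, w)
  m <- fw$matrix
  expect_equal(m[2, 1], 1.00, tolerance = 1e-9) # Smoking -> Bronchitis
  expect_equal(m[3, 1], 1.00, tolerance = 1e-9) # Smoking -> LungCancer
  expect_equal(m[4, 2], 0.66, tolerance = 1e-9) # Bronchitis -> Dyspnea
  expect_equal(m[4, 3], 0.69, tolerance = 1e-9) # LungCancer -> Dyspnea
  expect_equal(m[5, 3], 0.65, tolerance = 1e-9) # LungCancer -> Xray
  expect_identical(sum(m > 0), 5L)

  single <- final_weighted_adjacency(list(cancer_b1()), 1)
  expect_equal(single$matrix, cancer_b1()$adjacency * 1, ignore_attr = TRUE)

  e1 <- graph_from_edges(4, rbind(c(1, 2)))
  e2 <- graph_from_edges(4, rbind(c(3, 4)))
  two <- final_weighted_adjacency(list(e1, e2), c(0.5, 0.5))
  expect_equal(sort(two$matrix[two$matrix > 0]), c(0.5, 0.5))

  expect_error(final_weighted_adjacency(list(e1), c(0.5, 0.5)), "same length")
  expect_error(final_weighted_adjacency(list(e1, e2), c(0.5, 0.4)), "sum to one")
})

test_that("threshold voting with fixed weights merges the worked example exactly", {
  graphs <- list(cancer_b1(), cancer_b2(), cancer_b3())
  merged <- structure_ensemble(graphs,
    data = NULL, t_factor = 2,
    weights = c(0.31, 0.34, 0.35)
  )
  expect_equal(attr(merged, "fwam")$gamma, 0.62, tolerance = 1e-12)
  expect_identical(merged$adjacency, cancer_true()$adjacency)
})

test_that("unanimity keeps a structure and conflicting directions cancel", {
  d <- forward_sample(cancer_fixture(0.9)$network, 1000, seed = 41)
  g <- cancer_true()
  merged <- structure_ensemble(list(g, g, g), d, t_factor = 2)
  expect_identical(merged$adjacency, g$adjacency)

  ab <- graph_from_edges(2, rbind(c(1, 2)), c("a", "b"))
  ba <- graph_from_edges(2, rbind(c(2, 1)), c("a", "b"))
  out <- structure_ensemble(list(ab, ba),
    data = NULL, t_factor = 2,
    weights = c(0.5, 0.5)
  )
  expect_identical(n_edges(out), 0L) # each entry 0.5, gamma = 1.0
})

test_that("equal-weight voting follows strict majority arithmetic", {
  # an edge present in 6 of 10 equally weighted structures survives a
  # half-count threshold; present in 4 of 10 it does not
  e <- graph_from_edges(3, rbind(c(1, 2)), c("a", "b", "c"))
  o <- empty_graph(3, c("a", "b", "c"))
  w <- rep(0.1, 10)
  six <- structure_ensemble(c(rep(list(e), 6), rep(list(o), 4)),
    data = NULL, t_factor = 5, weights = w
  )
  expect_identical(n_edges(six), 1L)
  four <- structure_ensemble(c(rep(list(e), 4), rep(list(o), 6)),
    data = NULL, t_factor = 5, weights = w
  )
  expect_identical(n_edges(four), 0L)
})

test_that("voting output is an acyclic subset of the input edges, order-free", {
  for (s in 1:8) {
    graphs <- lapply(1:4, function(k) random_dag(5, 4 + (s + k) %% 4, seed = 10 * s + k))
    d <- random_problem(p = 5, n = 300, seed = s + 60)$data
    merged <- suppressWarnings(structure_ensemble(graphs, d, t_factor = 1.5))
    expect_true(is_acyclic(merged))
    union_adj <- Reduce(`+`, lapply(graphs, function(g) g$adjacency)) > 0
    expect_true(all(merged$adjacency <= union_adj))

    perm <- rev(seq_along(graphs))
    merged2 <- suppressWarnings(structure_ensemble(graphs[perm], d, t_factor = 1.5))
    expect_identical(merged$adjacency, merged2$adjacency)
  }
})

test_that("tidy views of the voting matrix expose weights and threshold", {
  graphs <- list(cancer_b1(), cancer_b2(), cancer_b3())
  merged <- structure_ensemble(graphs,
    data = NULL, t_factor = 2,
    weights = c(0.31, 0.34, 0.35)
  )
  td <- tidy(attr(merged, "fwam"))
  expect_identical(nrow(td), 5L)
  expect_true(all(td$passes))
  expect_s3_class(autoplot(attr(merged, "fwam")), "ggplot")
})
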