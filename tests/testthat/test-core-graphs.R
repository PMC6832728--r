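test_that("acyclicity detection handles empty, cyclic and merged graphs", {
  expect_true(is_acyclic(empty_graph(5)))
  two_cycle <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_false(is_acyclic(two_cycle))
  expect_true(is_acyclic(cancer_true()))
  expect_error(is_acyclic(matrix(0, 2, 3)), "malformed")
  expect_error(is_acyclic(matrix(c(0, 2, 0, 0), 2, 2)), "malformed")
})

test_that("acyclicity agrees with igraph on random directed graphs", {
  skip_if_not_installed("igraph")
  set.seed(5)
  for (i in 1:30) {
    p <- sample(3:7, 1)
    a <- matrix(rbinom(p * p, 1, 0.3), p, p)
    diag(a) <- 0L
    ig <- igraph::graph_from_adjacency_matrix(t(a), mode = "directed")
    expect_identical(is_acyclic(a), igraph::is_dag(ig))
  }
})

test_that("markov blankets cover parents, children and spouses", {
  expect_identical(markov_blanket(empty_graph(4), 2), integer(0))
  collider <- graph_from_edges(3, rbind(c(1, 3), c(2, 3))) # A -> C <- B
  expect_identical(markov_blanket(collider, 1), c(2L, 3L))
  # LungCancer: parent Smoking, children Dyspnea and Xray, spouse Bronchitis
  expect_identical(markov_blanket(cancer_true(), 3), c(1L, 2L, 4L, 5L))
  expect_length(markov_blanket(cancer_true(), 3), 4)
  expect_error(markov_blanket(empty_graph(3), 4), "out of range")
})

test_that("blanket membership is symmetric on random DAGs", {
  for (s in 1:10) {
    g <- random_dag(6, 8, seed = s)
    for (i in 1:6) {
      for (j in markov_blanket(g, i)) {
        expect_true(i %in% markov_blanket(g, j))
      }
    }
  }
})

test_that("average blanket size matches hand-derived values", {
  expect_identical(ambs(empty_graph(7)), 0)
  chain2 <- graph_from_edges(2, rbind(c(1, 2)))
  expect_identical(ambs(chain2), 1)
  # blanket sizes 2 + 3 + 4 + 2 + 1 over five nodes
  expect_identical(ambs(cancer_true()), 12 / 5)
})

test_that("average blanket size is invariant across a Markov-equivalence class", {
  set.seed(11)
  for (p in 3:4) {
    dags <- penbayes:::enumerate_dags(p)
    graphs <- lapply(dags, bn_graph)
    keys <- vapply(graphs, function(g) {
      s <- skeleton_and_vstructures(g)
      paste(c(t(s$skeleton), t(s$v_structures)), collapse = "-")
    }, character(1))
    for (k in unique(keys)) {
      vals <- vapply(graphs[keys == k], ambs, numeric(1))
      expect_lt(max(vals) - min(vals), 1e-12)
    }
  }
})

test_that("structural Hamming distance counts adds, deletes and reversals once", {
  g <- cancer_true()
  expect_identical(shd(g, g), 0L)
  expect_identical(shd(cancer_b1(), g), 1L) # one missing edge
  expect_identical(shd(empty_graph(5, cancer_vars), g), 5L)
  reversed <- graph_from_edges(2, rbind(c(2, 1)))
  forward <- graph_from_edges(2, rbind(c(1, 2)))
  expect_identical(shd(forward, reversed), 1L)
  expect_error(shd(empty_graph(3), empty_graph(4)), "node set")
})

test_that("shd is a metric on random DAG triples", {
  for (s in 1:15) {
    g1 <- random_dag(5, (s %% 8) + 1, seed = s)
    g2 <- random_dag(5, ((s + 3) %% 9) + 1, seed = s + 100)
    g3 <- random_dag(5, ((s + 5) %% 7) + 1, seed = s + 200)
    expect_identical(shd(g1, g1), 0L)
    expect_identical(shd(g1, g2), shd(g2, g1))
    expect_lte(shd(g1, g3), shd(g1, g2) + shd(g2, g3))
  }
})

test_that("skeleton and v-structure extraction identifies colliders", {
  chain <- graph_from_edges(3, rbind(c(1, 2), c(2, 3)))
  s <- skeleton_and_vstructures(chain)
  expect_identical(unname(s$skeleton), rbind(c(1L, 2L), c(2L, 3L)))
  expect_identical(nrow(s$v_structures), 0L)

  collider <- graph_from_edges(3, rbind(c(1, 3), c(2, 3)))
  s <- skeleton_and_vstructures(collider)
  expect_identical(unname(s$v_structures), rbind(c(1L, 3L, 2L)))

  # Bronchitis -> Dyspnea <- LungCancer is the network's only collider
  s <- skeleton_and_vstructures(cancer_true())
  expect_identical(unname(s$v_structures), rbind(c(2L, 4L, 3L)))
})

test_that("adjacency TSV round-trips and rejects corrupt cells", {
  path <- withr::local_tempfile(fileext = ".tsv")
  g <- cancer_true()
  write_graph_tsv(g, path)
  back <- read_graph_tsv(path)
  expect_identical(back$adjacency, g$adjacency)
  expect_identical(back$variables, g$variables)

  e <- empty_graph(3, c("a", "b", "c"))
  write_graph_tsv(e, path)
  expect_identical(read_graph_tsv(path)$adjacency, e$adjacency)

  lines <- readLines(path)
  lines[3] <- sub("0", "2", lines[3])
  writeLines(lines, path)
  expect_error(read_graph_tsv(path), "non-binary")
})
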