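test_that("the five-node ground truth has the documented shape", {
  gt <- cancer_fixture(0.9)
  expect_identical(gt$true_edge_count, 5L)
  expect_identical(gt$true_ambs, 2.4)
  expect_identical(gt$network$variables, cancer_vars)
  for (cpt in gt$network$cpts) {
    expect_true(all(abs(rowSums(cpt) - 1) < 1e-12))
    # every row's favoured state carries the configured probability
    expect_true(all(apply(cpt, 1, max) %in% c(0.5, 0.9)))
  }
  expect_error(cancer_fixture(0.4))
})

test_that("near-deterministic tables make every base learner find the skeleton", {
  gt <- cancer_fixture(0.99)
  d <- forward_sample(gt$network, 20000, seed = 71)
  for (learn in list(hill_climb, tabu_search, mmhc)) {
    expect_same_skeleton(learn(d), gt$network$graph)
  }
})

test_that("random DAG generation honours edge counts, seeds and acyclicity", {
  expect_identical(n_edges(random_dag(6, 0, seed = 1)), 0L)
  dense <- random_dag(5, 10, seed = 2)
  expect_identical(n_edges(dense), 10L)
  expect_true(is_acyclic(dense))
  expect_identical(random_dag(7, 9, seed = 3)$adjacency, random_dag(7, 9, seed = 3)$adjacency)
  expect_error(random_dag(4, 7, seed = 1), "too many edges")
})

test_that("random tables respect the Dirichlet concentration regimes", {
  g <- random_dag(4, 4, seed = 4)
  sharp <- random_cpts(g, rep(2, 4), concentration = 0.01, seed = 5)
  maxima <- unlist(lapply(sharp$cpts, function(m) apply(m, 1, max)))
  expect_gt(mean(maxima > 0.95), 0.8)

  flat <- random_cpts(g, rep(3, 4), concentration = 1e6, seed = 6)
  expect_true(all(abs(unlist(flat$cpts) - 1 / 3) < 0.01))

  expect_identical(
    random_cpts(g, rep(2, 4), 1, seed = 7)$cpts,
    random_cpts(g, rep(2, 4), 1, seed = 7)$cpts
  )
})

test_that("forward sampling matches the generating tables", {
  gt <- cancer_fixture(0.9)
  d0 <- forward_sample(gt$network, 0)
  expect_identical(n_records(d0), 0L)
  expect_identical(d0$variables, cancer_vars)

  # forced one-hot rows reproduce a single configuration
  g <- graph_from_edges(2, rbind(c(1, 2)), c("a", "b"))
  forced <- bn_network(g, list(matrix(c(0, 1), 1, 2), rbind(c(1, 0), c(0, 1))))
  df <- forward_sample(forced, 50, seed = 72)
  expect_true(all(df$x[, 1] == 2L))
  expect_true(all(df$x[, 2] == 2L))

  d <- forward_sample(gt$network, 100000, seed = 73)
  s_yes <- d$x[, 1] == 2L
  expect_lt(abs(mean(d$x[s_yes, 2] == 2L) - 0.9), 0.01)
  expect_lt(abs(mean(s_yes) - 0.5), 0.01)
  expect_identical(
    forward_sample(gt$network, 100, seed = 74)$x,
    forward_sample(gt$network, 100, seed = 74)$x
  )
})

test_that("sampled root marginals pass goodness of fit across seeds", {
  gt <- cancer_fixture(0.9)
  passes <- 0L
  for (s in 1:40) {
    d <- forward_sample(gt$network, 2000, seed = 800 + s)
    counts <- tabulate(d$x[, 1], nbins = 2)
    p <- stats::chisq.test(counts, p = c(0.5, 0.5))$p.value
    if (p > 0.01) passes <- passes + 1L
  }
  expect_gte(passes, 35L)
})

test_that("structure degradation removes and rewires edges acyclically", {
  g <- cancer_true()
  expect_identical(degrade_structure(g, 0)$adjacency, g$adjacency)
  for (s in 1:30) {
    deg <- degrade_structure(g, 1, seed = s)
    kept <- sum(deg$adjacency & g$adjacency)
    expect_lte(kept, 2L) # at least three of the five originals are gone
    expect_true(is_acyclic(deg))
    half <- degrade_structure(g, 0.5, seed = s)
    expect_true(is_acyclic(half))
    expect_lte(sum(half$adjacency & g$adjacency), 2L) # ceil(2.5) = 3 removed
  }
})

test_that("networks round-trip through the interchange format and JSON", {
  gt <- cancer_fixture(0.85)
  bif <- withr::local_tempfile(fileext = ".bif")
  write_bif(gt$network, bif, name = "cancer")
  back <- read_bif(bif)
  expect_identical(back$variables, gt$network$variables)
  expect_identical(back$graph$adjacency, gt$network$graph$adjacency)
  expect_equal(back$cpts, gt$network$cpts, tolerance = 1e-12, ignore_attr = TRUE)

  g <- random_dag(4, 5, seed = 8)
  bn <- random_cpts(g, c(2, 3, 2, 3), concentration = 1, seed = 9)
  write_bif(bn, bif)
  b2 <- read_bif(bif)
  expect_equal(b2$cpts, bn$cpts, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(b2$graph$adjacency, bn$graph$adjacency)

  js <- withr::local_tempfile(fileext = ".json")
  write_bn_json(bn, js)
  b3 <- read_bn_json(js)
  expect_identical(b3$graph$adjacency, bn$graph$adjacency)
  expect_equal(b3$cpts, bn$cpts, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(b3$levels, bn$levels)
})
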