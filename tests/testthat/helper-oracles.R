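# Shared fixtures and independent oracles.

cancer_vars <- c("Smoking", "Bronchitis", "LungCancer", "Dyspnea", "Xray")

# The three partial candidate structures of the five-node diagnosis example:
# each misses one of the five true edges.
cancer_b1 <- function() {
  graph_from_edges(5, rbind(c(1, 2), c(1, 3), c(2, 4), c(3, 5)), cancer_vars)
}
cancer_b2 <- function() {
  graph_from_edges(5, rbind(c(1, 2), c(1, 3), c(3, 4), c(3, 5)), cancer_vars)
}
cancer_b3 <- function() {
  graph_from_edges(5, rbind(c(1, 2), c(1, 3), c(2, 4), c(3, 4)), cancer_vars)
}
cancer_true <- function() cancer_fixture(0.9)$network$graph

# Literal transcription of the BDeu joint probability: explicit loops over
# parent configurations and child states, counts taken by direct record
# comparison. Independent of the package's tabulation/caching path.
bdeu_oracle <- function(g, d, ess = 1) {
  x <- d$x
  total <- 0
  for (i in seq_len(n_nodes(g))) {
    pa <- which(g$adjacency[i, ] == 1L)
    ri <- d$arities[i]
    if (length(pa) == 0) {
      configs <- matrix(integer(0), nrow = 1, ncol = 0)
    } else {
      configs <- as.matrix(expand.grid(lapply(d$arities[pa], seq_len)))
    }
    qi <- nrow(configs)
    npij <- ess / qi
    npijk <- ess / (ri * qi)
    for (j in seq_len(qi)) {
      in_config <- rep(TRUE, nrow(x))
      for (s in seq_along(pa)) {
        in_config <- in_config & (x[, pa[s]] == configs[j, s])
      }
      nijk <- vapply(seq_len(ri), function(k) sum(in_config & x[, i] == k), numeric(1))
      nij <- sum(nijk)
      total <- total + lgamma(npij) - lgamma(npij + nij) +
        sum(lgamma(npijk + nijk) - lgamma(npijk))
    }
  }
  total
}

# A random discrete dataset with known generating DAG.
random_problem <- function(p, n, seed, concentration = 1, max_arity = 2) {
  m <- seed %% (p * (p - 1) / 2 + 1) # deterministic edge count per seed
  g <- random_dag(p, m, seed = seed)
  arities <- if (max_arity > 2) {
    2 + (seq_len(p) + seed) %% (max_arity - 1)
  } else {
    rep(2L, p)
  }
  bn <- random_cpts(g, arities, concentration = concentration, seed = seed + 1)
  list(graph = g, network = bn, data = forward_sample(bn, n, seed = seed + 2))
}

skeleton_matrix <- function(g) unname((g$adjacency + t(g$adjacency)) > 0)

expect_same_skeleton <- function(g1, g2) {
  expect_identical(skeleton_matrix(g1), skeleton_matrix(g2))
}

# Pre-registered problem scheme for the search-oracle studies: random DAG
# with a noisy-OR parameterisation (identifiable, DAG-faithful dependencies;
# see the methods vignette) and well-separated seeds.
oracle_problem <- function(t, n) {
  base <- 10000 + t * 13
  g <- random_dag(3, t %% 4, seed = base)
  bn <- noisy_or_network(g, seed = base + 5000000)
  list(graph = g, network = bn, data = forward_sample(bn, n, seed = base + 9000000))
}
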