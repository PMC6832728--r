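#' Bayesian networks: structure plus conditional probability tables
#'
#' A `bn_network` couples a DAG with one conditional probability table (CPT)
#' per node. Node `i`'s CPT is a `q_i x r_i` matrix: one row per joint
#' configuration of its parents (first listed parent varying fastest, parents
#' in ascending index order), one column per state, rows summing to one.
#' Networks are used for forward simulation and as ground truth in
#' evaluation; learning itself only ever sees sampled data.
#'
#' @param graph A `bn_graph` DAG.
#' @param cpts List of CPT matrices, one per node.
#' @param levels Optional list of state labels per node (defaults to
#'   `s1..sr`).
#' @return An object of class `bn_network`.
#' @export
bn_network <- function(graph, cpts, levels = NULL) {
  stopifnot(inherits(graph, "bn_graph"), is_acyclic(graph))
  p <- n_nodes(graph)
  if (length(cpts) != p) stop("one CPT per node is required", call. = FALSE)
  arities <- vapply(cpts, ncol, integer(1))
  if (is.null(levels)) {
    levels <- lapply(arities, function(r) paste0("s", seq_len(r)))
  }
  for (i in seq_len(p)) {
    q <- prod(arities[parents_of(graph, i)])
    if (nrow(cpts[[i]]) != q) {
      stop(sprintf(
        "CPT for node %d must have %d rows (one per parent configuration)",
        i, q
      ), call. = FALSE)
    }
    if (any(abs(rowSums(cpts[[i]]) - 1) > 1e-9)) {
      stop(sprintf("CPT rows for node %d must sum to 1", i), call. = FALSE)
    }
  }
  structure(
    list(
      graph = graph, cpts = cpts, arities = as.integer(arities),
      levels = levels, variables = graph$variables
    ),
    class = "bn_network"
  )
}

#' @export
print.bn_network <- function(x, ...) {
  cat(sprintf(
    "<bn_network> %d nodes, %d edges, arities: %s\n",
    n_nodes(x$graph), n_edges(x$graph), paste(x$arities, collapse = ", ")
  ))
  invisible(x)
}

with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Five-node respiratory-diagnosis ground truth
#'
#' The classic five-node diagnostic network: Smoking influences Bronchitis
#' and LungCancer; Dyspnea is caused by Bronchitis and LungCancer; Xray
#' reflects LungCancer. All variables are binary (`no`/`yes`). The
#' structure is the classic textbook network; the CPTs are synthetic,
#' built by one documented rule so that derived numbers are reproducible: the root is uniform, each
#' child's favoured state has probability `cpt_strength` given its parents
#' (Bronchitis/LungCancer mirror Smoking, Xray mirrors LungCancer), and
#' Dyspnea is a noisy OR of its two parents.
#'
#' @param cpt_strength Probability in `(0.5, 1)` of each child's most likely
#'   state given its parents; higher values give cleaner, more identifiable
#'   data.
#' @return A list of class `bn_ground_truth` with fields `network`, `name`,
#'   `true_ambs` and `true_edge_count`.
#' @examples
#' gt <- cancer_fixture(0.9)
#' gt$true_ambs # 2.4
#' @export
cancer_fixture <- function(cpt_strength = 0.9) {
  stopifnot(cpt_strength > 0.5, cpt_strength < 1)
  s <- cpt_strength
  vars <- c("Smoking", "Bronchitis", "LungCancer", "Dyspnea", "Xray")
  g <- graph_from_edges(
    5,
    rbind(c(1, 2), c(1, 3), c(2, 4), c(3, 4), c(3, 5)), # (parent, child)
    vars
  )
  lv <- rep(list(c("no", "yes")), 5)
  mirror <- matrix(c(s, 1 - s, 1 - s, s), 2, 2, byrow = TRUE) # rows: parent no/yes
  noisy_or <- rbind(
    c(s, 1 - s), # B = no, L = no -> Dyspnea mostly no
    c(1 - s, s), # B = yes, L = no
    c(1 - s, s), # B = no, L = yes
    c(1 - s, s) # both
  )
  cpts <- list(
    Smoking = matrix(c(0.5, 0.5), 1, 2),
    Bronchitis = mirror,
    LungCancer = mirror,
    Dyspnea = noisy_or,
    Xray = mirror
  )
  net <- bn_network(g, cpts, levels = lv)
  structure(
    list(
      network = net, name = "cancer",
      true_ambs = ambs(g), true_edge_count = n_edges(g)
    ),
    class = "bn_ground_truth"
  )
}

#' Random DAG
#'
#' A DAG drawn as a uniform random topological order plus `m` forward edges
#' sampled without replacement. Deterministic per seed.
#'
#' @param p Node count.
#' @param m Edge count, at most `p * (p - 1) / 2`.
#' @param seed Integer seed (or `NULL` to use the current RNG state).
#' @return A `bn_graph` DAG.
#' @export
random_dag <- function(p, m, seed = NULL) {
  if (m > p * (p - 1) / 2) {
    stop("too many edges for an acyclic graph", call. = FALSE)
  }
  with_seed(seed, {
    ord <- sample.int(p)
    pairs <- utils::combn(p, 2) # positions in the order: col 1 before col 2
    pick <- if (m > 0) sample.int(ncol(pairs), m) else integer(0)
    a <- matrix(0L, p, p)
    for (k in pick) {
      parent <- ord[pairs[1, k]]
      child <- ord[pairs[2, k]]
      a[child, parent] <- 1L
    }
    bn_graph(a)
  })
}

#' Random conditional probability tables for a DAG
#'
#' Each CPT row is drawn from a symmetric Dirichlet with the given
#' concentration: small values (e.g. 0.01) give near-deterministic rows,
#' large values near-uniform rows. Deterministic per seed.
#'
#' @param g A `bn_graph` DAG.
#' @param arities Integer vector of node arities.
#' @param concentration Positive Dirichlet concentration parameter.
#' @param seed Integer seed (or `NULL`).
#' @return A `bn_network`.
#' @export
random_cpts <- function(g, arities, concentration = 1, seed = NULL) {
  stopifnot(concentration > 0)
  p <- n_nodes(g)
  arities <- as.integer(arities)
  with_seed(seed, {
    cpts <- lapply(seq_len(p), function(i) {
      q <- prod(arities[parents_of(g, i)])
      r <- arities[i]
      raw <- matrix(stats::rgamma(q * r, shape = concentration), q, r)
      zero <- rowSums(raw) == 0 # numerically degenerate draws at tiny shape
      raw[zero, 1] <- 1
      raw / rowSums(raw)
    })
    bn_network(g, cpts)
  })
}

#' Forward (ancestral) sampling from a network
#'
#' Samples `n` iid records from the joint distribution by drawing each node
#' in topological order given its sampled parents. Deterministic per seed.
#'
#' @param bn A `bn_network`.
#' @param n Number of records (`>= 0`).
#' @param seed Integer seed (or `NULL`).
#' @return A `bn_dataset` with the network's variables, arities and state
#'   labels.
#' @export
forward_sample <- function(bn, n, seed = NULL) {
  stopifnot(inherits(bn, "bn_network"), n >= 0)
  p <- n_nodes(bn$graph)
  x <- matrix(1L, nrow = n, ncol = p)
  with_seed(seed, {
    if (n > 0) {
      for (i in topological_order(bn$graph)) {
        pa <- parents_of(bn$graph, i)
        r <- bn$arities[i]
        cpt <- bn$cpts[[i]]
        j <- rep.int(1L, n)
        q <- 1L
        for (pp in pa) {
          j <- j + (x[, pp] - 1L) * q
          q <- q * bn$arities[pp]
        }
        cm <- t(apply(cpt, 1, cumsum))
        u <- stats::runif(n)
        if (r == 1) {
          x[, i] <- 1L
        } else {
          x[, i] <- 1L + as.integer(rowSums(u > cm[j, -r, drop = FALSE]))
        }
      }
    }
    new_bn_dataset(x, bn$variables, bn$arities, bn$levels)
  })
}

#' Randomly degrade a structure
#'
#' Removes `ceiling(fraction * M)` randomly chosen edges and rewires half of
#' the removed ones (rounded down) to random positions that keep the graph
#' acyclic. Emulates a constituent learner that performs poorly, for
#' robustness studies. Deterministic per seed; the output is always a DAG.
#'
#' @param g A `bn_graph` DAG.
#' @param fraction Fraction of edges to remove, in `[0, 1]`.
#' @param seed Integer seed (or `NULL`).
#' @return A `bn_graph` DAG.
#' @export
degrade_structure <- function(g, fraction, seed = NULL) {
  stopifnot(fraction >= 0, fraction <= 1)
  m <- n_edges(g)
  if (m == 0 || fraction == 0) {
    return(g)
  }
  with_seed(seed, {
    a <- g$adjacency
    edges <- which(a == 1L, arr.ind = TRUE)
    n_rm <- ceiling(fraction * m)
    rm_idx <- sample.int(nrow(edges), n_rm)
    a[edges[rm_idx, , drop = FALSE]] <- 0L
    n_add <- n_rm %/% 2L
    p <- nrow(a)
    added <- 0L
    orig <- g$adjacency
    # never rewire onto a removed (or reversed) original position
    free <- which(a == 0L & t(a) == 0L & orig == 0L & t(orig) == 0L & diag(p) == 0)
    free <- sample(free)
    for (pos in free) {
      if (added >= n_add) break
      a[pos] <- 1L
      if (is_acyclic(a)) added <- added + 1L else a[pos] <- 0L
    }
    bn_graph(a, g$variables)
  })
}

#' Noisy-OR parameterisation of a DAG
#'
#' Binary-variable tables in the classic noisy-OR family: each root is a
#' fair coin, and a child is activated by each active parent independently
#' with a per-parent strength drawn uniformly from `strength_range`, on top
#' of a background leak. Every edge induces a monotone, marginally
#' detectable dependence, so sampled data are faithful to the graph at
#' moderate sample sizes -- the regime score-based greedy search is meant
#' for, and the generator used by the search-oracle studies.
#'
#' @param g A `bn_graph` DAG.
#' @param strength_range Lower and upper bound of the per-parent activation
#'   probability.
#' @param leak Probability of spontaneous activation.
#' @param seed Integer seed (or `NULL`).
#' @return A `bn_network` with all-binary variables.
#' @export
noisy_or_network <- function(g, strength_range = c(0.5, 0.9), leak = 0.1,
                             seed = NULL) {
  p <- n_nodes(g)
  with_seed(seed, {
    cpts <- lapply(seq_len(p), function(i) {
      pa <- parents_of(g, i)
      if (length(pa) == 0) {
        return(matrix(0.5, 1, 2))
      }
      s <- stats::runif(length(pa), strength_range[1], strength_range[2])
      combos <- config_states(rep(2L, length(pa)))
      p_yes <- vapply(seq_len(nrow(combos)), function(r) {
        active <- combos[r, ] == 2L
        1 - (1 - leak) * prod(1 - s[active])
      }, numeric(1))
      cbind(1 - p_yes, p_yes)
    })
    bn_network(g, cpts)
  })
}
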