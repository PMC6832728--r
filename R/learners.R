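#' Search configuration for the base learners
#'
#' @param ess Equivalent sample size for BDeu scoring (positive).
#' @param max_iterations Maximum number of accepted moves in a search.
#' @param tabu_length Length of the tabu list (recent undo-moves barred).
#' @param alpha Significance level for conditional-independence tests in the
#'   skeleton phase of [mmhc()].
#' @param max_parents Cap on parent-set size (default unbounded; a guard for
#'   pathological data, not needed for networks of moderate width).
#' @param max_sepset Largest conditioning-set size tried by [mmpc()].
#' @return A list of class `search_config`.
#' @export
search_config <- function(ess = 1, max_iterations = 200L, tabu_length = 10L,
                          alpha = 0.05, max_parents = Inf, max_sepset = 3L) {
  stopifnot(
    ess > 0, max_iterations >= 1, tabu_length >= 1,
    alpha > 0, alpha < 1, max_sepset >= 0
  )
  structure(
    list(
      ess = ess, max_iterations = as.integer(max_iterations),
      tabu_length = as.integer(tabu_length), alpha = alpha,
      max_parents = max_parents, max_sepset = as.integer(max_sepset)
    ),
    class = "search_config"
  )
}

# Transitive closure of the edge relation; reach[u, v] is TRUE iff there is
# a directed path u -> ... -> v. adjacency is row = child, so the edge
# relation is t(adjacency).
reachability <- function(adj) {
  e <- t(adj) > 0
  reach <- e
  repeat {
    nxt <- reach | (reach %*% e > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  reach
}

# Does a directed path u -> ... -> v exist in `adj`, ignoring the direct
# edge u -> v? Used to admit edge reversals.
path_avoiding_edge <- function(adj, u, v) {
  adj2 <- adj
  adj2[v, u] <- 0L
  stack <- u
  seen <- logical(nrow(adj))
  while (length(stack) > 0) {
    cur <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (seen[cur]) next
    seen[cur] <- TRUE
    ch <- which(adj2[, cur] == 1L)
    if (v %in% ch) {
      return(TRUE)
    }
    stack <- c(stack, ch)
  }
  FALSE
}

# Shared deterministic score-based search over {add, delete, reverse}.
# Moves are accepted greedily; with `tabu = TRUE`, the memory holds recently
# visited structures and, at a local optimum, the best move leading to an
# unvisited structure is accepted; the best structure visited is returned.
# Tie-break among near-equal deltas: add < delete < reverse, then
# lexicographic (parent, child) -- tied score-equivalent additions orient
# along the column order (see the methods vignette).
score_search <- function(d, cfg, whitelist = NULL, tabu = FALSE) {
  p <- n_variables(d)
  adj <- matrix(0L, p, p)
  pa <- rep(list(integer(0)), p)
  fs <- vapply(
    seq_len(p), function(i) family_bdeu(d, i, integer(0), cfg$ess),
    numeric(1)
  )
  tol <- 1e-8
  cur_score <- sum(fs)
  best_score <- cur_score
  best_adj <- adj
  visited <- character(0)
  visited_cap <- 10L * cfg$tabu_length
  stall <- 0L
  stall_limit <- max(10L, 2L * cfg$tabu_length)
  iter <- 0L

  apply_move <- function(a, type, i, j) {
    if (type == 1L) {
      a[i, j] <- 1L
    } else if (type == 2L) {
      a[i, j] <- 0L
    } else {
      a[i, j] <- 0L
      a[j, i] <- 1L
    }
    a
  }
  if (tabu) visited <- paste(adj, collapse = "")

  while (iter < cfg$max_iterations) {
    reach <- reachability(adj)
    types <- integer(0)
    cis <- integer(0)
    pjs <- integer(0)
    deltas <- numeric(0)
    for (i in seq_len(p)) {
      for (j in seq_len(p)) {
        if (i == j) next
        if (adj[i, j] == 0L && adj[j, i] == 0L) {
          if (!is.null(whitelist) && !whitelist[i, j]) next
          if (length(pa[[i]]) >= cfg$max_parents) next
          if (reach[i, j]) next # i already reaches j: adding j -> i cycles
          delta <- family_bdeu(d, i, sort(c(pa[[i]], j)), cfg$ess) - fs[i]
          types <- c(types, 1L)
          cis <- c(cis, i)
          pjs <- c(pjs, j)
          deltas <- c(deltas, delta)
        } else if (adj[i, j] == 1L) {
          # delete j -> i
          delta <- family_bdeu(d, i, setdiff(pa[[i]], j), cfg$ess) - fs[i]
          types <- c(types, 2L)
          cis <- c(cis, i)
          pjs <- c(pjs, j)
          deltas <- c(deltas, delta)
          # reverse j -> i to i -> j
          if (length(pa[[j]]) < cfg$max_parents &&
            !path_avoiding_edge(adj, j, i)) {
            delta <- (family_bdeu(d, i, setdiff(pa[[i]], j), cfg$ess) - fs[i]) +
              (family_bdeu(d, j, sort(c(pa[[j]], i)), cfg$ess) - fs[j])
            types <- c(types, 3L)
            cis <- c(cis, i)
            pjs <- c(pjs, j)
            deltas <- c(deltas, delta)
          }
        }
      }
    }
    if (length(deltas) == 0) break
    k <- NA_integer_
    if (!tabu) {
      grp <- which(deltas >= max(deltas) - tol)
      grp <- grp[order(types[grp], pjs[grp], cis[grp])]
      k <- grp[[1]]
      if (deltas[k] <= tol) break
    } else {
      # best move whose resulting structure has not been visited recently
      for (cand in order(-deltas, types, pjs, cis)) {
        key <- paste(
          apply_move(adj, types[cand], cis[cand], pjs[cand]),
          collapse = ""
        )
        if (!(key %in% visited)) {
          k <- cand
          break
        }
      }
      if (is.na(k)) break
      if (deltas[k] <= tol) {
        stall <- stall + 1L
        if (stall > stall_limit) break
      }
    }
    i <- cis[k]
    j <- pjs[k]
    adj <- apply_move(adj, types[k], i, j)
    if (types[k] == 1L) {
      pa[[i]] <- sort(c(pa[[i]], j))
      fs[i] <- family_bdeu(d, i, pa[[i]], cfg$ess)
    } else if (types[k] == 2L) {
      pa[[i]] <- setdiff(pa[[i]], j)
      fs[i] <- family_bdeu(d, i, pa[[i]], cfg$ess)
    } else {
      pa[[i]] <- setdiff(pa[[i]], j)
      pa[[j]] <- sort(c(pa[[j]], i))
      fs[i] <- family_bdeu(d, i, pa[[i]], cfg$ess)
      fs[j] <- family_bdeu(d, j, pa[[j]], cfg$ess)
    }
    cur_score <- sum(fs)
    if (tabu) {
      visited <- c(visited, paste(adj, collapse = ""))
      if (length(visited) > visited_cap) {
        visited <- visited[seq.int(length(visited) - visited_cap + 1L, length(visited))]
      }
    }
    if (cur_score > best_score + tol) {
      best_score <- cur_score
      best_adj <- adj
      stall <- 0L
    }
    iter <- iter + 1L
  }
  structure(
    list(adjacency = if (tabu) best_adj else adj, score = if (tabu) best_score else cur_score),
    class = "search_state"
  )
}

#' Hill-climbing structure learner
#'
#' Greedy BDeu search from the empty graph over the operators add, delete and
#' reverse edge, accepting the single best improving move per step and
#' stopping at a local optimum. Deterministic: ties among near-equal moves
#' are broken add < delete < reverse, then by (parent, child) index, so a
#' tied single-edge addition (the two orientations of a first edge between
#' a pair are always score-equivalent) is oriented along the column order.
#'
#' @param data A data frame or `bn_dataset` of discrete variables.
#' @param cfg A [search_config()].
#' @return A `bn_graph` DAG, with the BDeu score in attribute `"score"`.
#' @export
hill_climb <- function(data, cfg = search_config()) {
  d <- as_bn_dataset(data)
  if (n_records(d) < 1) stop("empty dataset", call. = FALSE)
  st <- score_search(d, cfg, tabu = FALSE)
  out <- bn_graph(st$adjacency, d$variables)
  attr(out, "score") <- st$score
  out
}

#' Tabu-search structure learner
#'
#' Hill climbing with a tabu memory of recently visited structures (up to
#' ten times `tabu_length`): at a local optimum the best -- possibly
#' non-improving -- move whose resulting structure is not in the memory is
#' accepted, and the search stops after a run of non-improving moves. The
#' best-scoring DAG visited is returned, so its score is never below
#' [hill_climb()]'s on the same input.
#'
#' @inheritParams hill_climb
#' @return A `bn_graph` DAG, with the BDeu score in attribute `"score"`.
#' @export
tabu_search <- function(data, cfg = search_config()) {
  d <- as_bn_dataset(data)
  if (n_records(d) < 1) stop("empty dataset", call. = FALSE)
  st <- score_search(d, cfg, tabu = TRUE)
  out <- bn_graph(st$adjacency, d$variables)
  attr(out, "score") <- st$score
  out
}

# All DAG adjacency matrices over p nodes (row = child). Bitmask enumeration
# with an acyclicity filter for p <= 4; for p = 5 that space (2^20) is too
# large, so DAGs are generated as topological order + forward edge subset and
# de-duplicated, which yields each DAG at least once.
enumerate_dags <- function(p) {
  stopifnot(p >= 1, p <= 5)
  if (p == 1) {
    return(list(matrix(0L, 1, 1)))
  }
  if (p <= 4) {
    off <- which(diag(p) == 0)
    n_bits <- length(off)
    out <- list()
    for (mask in 0:(2^n_bits - 1)) {
      bits <- as.integer(intToBits(mask)[seq_len(n_bits)])
      a <- matrix(0L, p, p)
      a[off] <- bits
      if (is_acyclic(a)) out[[length(out) + 1L]] <- a
    }
    return(out)
  }
  perms <- function(v) {
    if (length(v) == 1) {
      return(list(v))
    }
    do.call(c, lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(rest) c(v[i], rest))
    }))
  }
  pairs <- utils::combn(p, 2)
  npair <- ncol(pairs)
  seen <- new.env(parent = emptyenv())
  out <- list()
  for (ord in perms(seq_len(p))) {
    pos <- order(ord)
    for (mask in 0:(2^npair - 1)) {
      bits <- as.integer(intToBits(mask)[seq_len(npair)])
      a <- matrix(0L, p, p)
      for (k in which(bits == 1L)) {
        u <- pairs[1, k]
        v <- pairs[2, k]
        if (pos[u] < pos[v]) a[v, u] <- 1L else a[u, v] <- 1L
      }
      key <- paste(a, collapse = "")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        out[[length(out) + 1L]] <- a
      }
    }
  }
  out
}

#' Exhaustive structure search (test oracle)
#'
#' Enumerates every DAG over at most five nodes and returns the BDeu-maximal
#' one. Ties are broken towards fewer edges, then the lexicographically
#' smallest adjacency matrix. Intended as an oracle for the heuristic
#' learners on tiny problems, not as a practical learner.
#'
#' @inheritParams hill_climb
#' @return A `bn_graph`, with attributes `"score"` and `"n_dags"` (number of
#'   DAGs enumerated).
#' @export
exhaustive_search <- function(data, cfg = search_config()) {
  d <- as_bn_dataset(data)
  p <- n_variables(d)
  if (p > 5) {
    stop("exhaustive search is limited to 5 variables", call. = FALSE)
  }
  dags <- enumerate_dags(p)
  scores <- vapply(dags, function(a) {
    s <- 0
    for (i in seq_len(p)) s <- s + family_bdeu(d, i, which(a[i, ] == 1L), cfg$ess)
    s
  }, numeric(1))
  tol <- 1e-9
  top <- which(scores >= max(scores) - tol)
  edges <- vapply(dags[top], sum, numeric(1))
  top <- top[edges == min(edges)]
  if (length(top) > 1) {
    keys <- vapply(dags[top], function(a) paste(t(a), collapse = ""), character(1))
    top <- top[order(keys)]
  }
  best <- top[[1]]
  out <- bn_graph(dags[[best]], d$variables)
  attr(out, "score") <- scores[best]
  attr(out, "n_dags") <- length(dags)
  out
}
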