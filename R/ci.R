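#' G-squared conditional independence test
#'
#' Likelihood-ratio test of `x` independent of `y` given the variables in
#' `z`, on a discrete dataset. Within each stratum of the conditioning
#' variables, `G2 = 2 * sum(observed * log(observed / expected))` over the
#' `x` by `y` contingency table; the statistic is summed over strata and
#' referred to a chi-square distribution. Strata with a zero margin
#' contribute nothing and reduce the degrees of freedom (per-stratum df are
#' computed from non-empty margins).
#'
#' @param data A data frame or `bn_dataset`.
#' @param x,y Column indices of the two tested variables.
#' @param z Integer vector of conditioning-variable indices (possibly empty).
#' @return A one-row tibble with columns `statistic`, `df` and `p_value`.
#' @export
g2_test <- function(data, x, y, z = integer(0)) {
  d <- as_bn_dataset(data)
  res <- g2_core(d, x, y, z)
  tibble::tibble(
    statistic = res[[1]], df = as.integer(res[[2]]), p_value = res[[3]]
  )
}

# plain-vector work horse (statistic, df, p), cached per dataset: the
# max-min forward phase re-tests the same triples many times
g2_core <- function(d, x, y, z) {
  z <- sort(z)
  key <- paste0("g2|", x, "|", y, "|", paste(z, collapse = ","))
  hit <- d$cache[[key]]
  if (!is.null(hit)) {
    return(hit)
  }
  n <- nrow(d$x)
  if (n == 0) stop("empty dataset", call. = FALSE)
  rx <- d$arities[x]
  ry <- d$arities[y]
  s <- rep.int(1L, n)
  q <- 1L
  for (p in z) {
    s <- s + (d$x[, p] - 1L) * q
    q <- q * d$arities[p]
  }
  cell <- d$x[, x] + rx * (d$x[, y] - 1L) + rx * ry * (s - 1L)
  counts <- array(tabulate(cell, nbins = rx * ry * q), dim = c(rx, ry, q))
  stat <- 0
  df <- 0L
  for (k in seq_len(q)) {
    tab <- counts[, , k]
    ns <- sum(tab)
    if (ns == 0) next
    rm <- rowSums(tab)
    cm <- colSums(tab)
    exp_tab <- outer(rm, cm) / ns
    nz <- tab > 0
    stat <- stat + 2 * sum(tab[nz] * log(tab[nz] / exp_tab[nz]))
    df <- df + max(sum(rm > 0) - 1L, 0L) * max(sum(cm > 0) - 1L, 0L)
  }
  p_value <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  out <- c(stat, df, p_value)
  d$cache[[key]] <- out
  out
}

# Minimum association of y with x over all conditioning subsets of cpc
# (up to max_sepset). Returns the minimising statistic and the largest
# p-value encountered (y is droppable as soon as any subset renders it
# independent at level alpha).
min_association <- function(d, x, y, cpc, max_sepset) {
  best_stat <- Inf
  worst_p <- 0
  sizes <- 0:min(length(cpc), max_sepset)
  for (k in sizes) {
    subsets <- if (k == 0) {
      list(integer(0))
    } else if (length(cpc) == k) {
      list(cpc) # combn would misread a scalar first argument
    } else {
      utils::combn(cpc, k, simplify = FALSE)
    }
    for (s in subsets) {
      res <- g2_core(d, x, y, s)
      if (res[[1]] < best_stat) best_stat <- res[[1]]
      if (res[[3]] > worst_p) worst_p <- res[[3]]
    }
  }
  list(statistic = best_stat, p_value = worst_p)
}

#' Max-min parents-and-children skeleton discovery
#'
#' For each node, grows a candidate parents-and-children set with the
#' max-min heuristic: at each step the variable with the maximal minimum
#' association (G-squared statistic minimised over conditioning subsets of
#' the current set) is added, and variables rendered independent at level
#' `alpha` by any subset are excluded. A backward pass re-tests members, and
#' an edge is kept only when each endpoint recovers the other (AND rule).
#'
#' @inheritParams hill_climb
#' @return A symmetric logical `P x P` matrix; entry `[i, j]` is `TRUE` when
#'   the undirected edge i -- j is in the estimated skeleton.
#' @export
mmpc <- function(data, cfg = search_config()) {
  d <- as_bn_dataset(data)
  if (n_records(d) < 1) stop("empty dataset", call. = FALSE)
  p <- n_variables(d)
  cpc_of <- vector("list", p)
  for (x in seq_len(p)) {
    cpc <- integer(0)
    excluded <- logical(p)
    excluded[x] <- TRUE
    repeat {
      cand <- which(!excluded & !(seq_len(p) %in% cpc))
      if (length(cand) == 0) break
      stats_min <- numeric(length(cand))
      indep <- logical(length(cand))
      for (k in seq_along(cand)) {
        res <- min_association(d, x, cand[k], cpc, cfg$max_sepset)
        stats_min[k] <- res$statistic
        indep[k] <- res$p_value > cfg$alpha
      }
      excluded[cand[indep]] <- TRUE
      open <- which(!indep)
      if (length(open) == 0) break
      pick <- open[order(-stats_min[open], cand[open])][1]
      cpc <- sort(c(cpc, cand[pick]))
    }
    # backward pass: drop members separated by a subset of the others
    repeat {
      dropped <- FALSE
      for (y in cpc) {
        res <- min_association(d, x, y, setdiff(cpc, y), cfg$max_sepset)
        if (res$p_value > cfg$alpha) {
          cpc <- setdiff(cpc, y)
          dropped <- TRUE
          break
        }
      }
      if (!dropped) break
    }
    cpc_of[[x]] <- cpc
  }
  skel <- matrix(FALSE, p, p)
  for (x in seq_len(p)) {
    for (y in cpc_of[[x]]) {
      if (x %in% cpc_of[[y]]) {
        skel[x, y] <- TRUE
        skel[y, x] <- TRUE
      }
    }
  }
  dimnames(skel) <- list(d$variables, d$variables)
  skel
}

#' Max-min hill-climbing structure learner
#'
#' Hybrid learner: [mmpc()] estimates an undirected skeleton by
#' conditional-independence testing, then a BDeu hill climb orients it --
#' edge additions are restricted to skeleton pairs while deletions and
#' reversals remain unrestricted, so the result's skeleton is a subset of
#' the tested one.
#'
#' @inheritParams hill_climb
#' @return A `bn_graph` DAG, with the BDeu score in attribute `"score"`.
#' @export
mmhc <- function(data, cfg = search_config()) {
  d <- as_bn_dataset(data)
  if (n_records(d) < 1) stop("empty dataset", call. = FALSE)
  skel <- mmpc(d, cfg)
  st <- score_search(d, cfg, whitelist = skel, tabu = FALSE)
  out <- bn_graph(st$adjacency, d$variables)
  attr(out, "score") <- st$score
  out
}
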