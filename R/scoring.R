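#' BDeu log score of a structure
#'
#' Natural log of the Bayesian Dirichlet equivalent uniform (BDeu) marginal
#' likelihood of the data given the DAG, with the uniform structure prior
#' dropped (constant under comparison). The Dirichlet hyperparameters are the
#' standard BDeu choice `ess / (r_i * q_i)` per cell, where `r_i` is the
#' child's arity and `q_i` the number of joint parent configurations. The
#' score decomposes into per-family terms and is equal across all DAGs in the
#' same Markov-equivalence class.
#'
#' @param g A `bn_graph` DAG over the dataset's variables.
#' @param d A `bn_dataset` (or data frame).
#' @param ess Equivalent sample size, a positive real. Default 1.
#' @return The log score (`<= 0` for `N >= 1`; `0` for an empty dataset).
#' @export
bdeu_log_score <- function(g, d, ess = 1) {
  d <- as_bn_dataset(d)
  stopifnot(inherits(g, "bn_graph"), ess > 0)
  if (n_nodes(g) != n_variables(d)) {
    stop("graph and dataset disagree on the variable set", call. = FALSE)
  }
  if (!is_acyclic(g)) {
    stop("BDeu is only defined for acyclic structures", call. = FALSE)
  }
  if (n_records(d) == 0) {
    return(0)
  }
  total <- 0
  for (i in seq_len(n_nodes(g))) {
    total <- total + family_bdeu(d, i, parents_of(g, i), ess)
  }
  total
}

# One family's BDeu term, cached per dataset (learners re-score the same
# families many times within a slice).
family_bdeu <- function(d, child, parents, ess) {
  key <- paste(child, paste(parents, collapse = ","), ess, sep = "|")
  hit <- d$cache[[key]]
  if (!is.null(hit)) {
    return(hit)
  }
  x <- d$x
  n <- nrow(x)
  ri <- d$arities[child]
  j <- rep.int(1L, n)
  q <- 1L
  for (p in parents) {
    j <- j + (x[, p] - 1L) * q
    q <- q * d$arities[p]
  }
  cell <- (j - 1L) * ri + x[, child]
  counts <- matrix(tabulate(cell, nbins = q * ri), nrow = ri)
  nij <- colSums(counts)
  aijk <- ess / (ri * q)
  aij <- ess / q
  # configurations with nij = 0 contribute exactly 0
  score <- sum(lgamma(aij) - lgamma(aij + nij)) +
    sum(lgamma(aijk + counts) - lgamma(aijk))
  d$cache[[key]] <- score
  score
}

#' Edge strength of a structure
#'
#' The magnitude of the BDeu log score normalised by record count and edge
#' count, `|log BDeu| / (N * M)`. It measures the average per-edge cost of the
#' structure on the data: a lower value means higher per-edge structural
#' quality. An edgeless structure has no per-edge quantity and returns `Inf`;
#' such structures carry no votes in an ensemble.
#'
#' @inheritParams bdeu_log_score
#' @return A positive real, or `Inf` when the graph has no edges.
#' @export
edge_strength <- function(g, d, ess = 1) {
  d <- as_bn_dataset(d)
  n <- n_records(d)
  if (n < 1) {
    stop("edge strength needs at least one record", call. = FALSE)
  }
  m <- n_edges(g)
  if (m == 0) {
    return(Inf)
  }
  abs(bdeu_log_score(g, d, ess)) / (n * m)
}

#' Ensemble weights of a set of structures
#'
#' Normalised quality weights: each structure's weight is the reciprocal of
#' its edge strength divided by the sum of reciprocals over all structures,
#' so weights sum to one and a structure with a lower (better) edge strength
#' carries a larger vote. Edgeless structures (infinite edge strength) are
#' excluded with a warning and get weight zero; the rest are renormalised.
#' See the methods vignette for why the weight must point in the quality
#' direction for threshold voting keyed to `min(weight)` to behave as a
#' majority rule.
#'
#' @param structures A list of `bn_graph`s over the dataset's variables.
#' @param d A `bn_dataset` (or data frame).
#' @param ess Equivalent sample size.
#' @return Numeric vector of weights, one per structure, summing to one over
#'   the included structures; excluded structures get exactly zero.
#' @export
structure_weights <- function(structures, d, ess = 1) {
  if (length(structures) < 1) {
    stop("at least one structure is required", call. = FALSE)
  }
  d <- as_bn_dataset(d)
  es <- vapply(structures, edge_strength, numeric(1), d = d, ess = ess)
  ok <- is.finite(es)
  if (!any(ok)) {
    stop("all structures are edgeless; no weights can be assigned", call. = FALSE)
  }
  if (!all(ok)) {
    warning(sprintf(
      "%d edgeless structure(s) excluded from weighting", sum(!ok)
    ), call. = FALSE)
  }
  w <- numeric(length(es))
  w[ok] <- (1 / es[ok]) / sum(1 / es[ok])
  w
}

#' Weighted adjacency matrix of a structure
#'
#' Elementwise product of a structure's 0/1 adjacency matrix and its ensemble
#' weight.
#'
#' @param g A `bn_graph`.
#' @param w Weight in `[0, 1]`.
#' @return A `P x P` numeric matrix.
#' @export
weighted_adjacency <- function(g, w) {
  stopifnot(inherits(g, "bn_graph"), w >= 0, w <= 1)
  g$adjacency * w
}
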