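#' Final weighted adjacency matrix
#'
#' The elementwise sum of each structure's adjacency matrix scaled by its
#' ensemble weight. When the weights sum to one every entry lies in
#' `[0, 1]` and entry `[i, j]` is the total weight of the structures voting
#' for the edge `j -> i`.
#'
#' @param graphs A list of `bn_graph`s over the same variables.
#' @param weights Numeric weights, one per graph, summing to one (within
#'   1e-6) over the graphs.
#' @return An object of class `fwam`: list with `matrix`, `weights`,
#'   `gamma` (unset, `NA`), `t_factor` (unset) and `variables`.
#' @export
final_weighted_adjacency <- function(graphs, weights) {
  if (length(graphs) != length(weights)) {
    stop("graphs and weights must have the same length", call. = FALSE)
  }
  if (length(graphs) == 0) stop("no structures given", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-6) {
    stop("weights must sum to one", call. = FALSE)
  }
  p <- n_nodes(graphs[[1]])
  m <- matrix(0, p, p)
  for (k in seq_along(graphs)) {
    if (n_nodes(graphs[[k]]) != p) {
      stop("all structures must share the node set", call. = FALSE)
    }
    m <- m + weighted_adjacency(graphs[[k]], weights[[k]])
  }
  vars <- graphs[[1]]$variables
  dimnames(m) <- list(vars, vars)
  structure(
    list(
      matrix = m, weights = weights, gamma = NA_real_,
      t_factor = NA_real_, variables = vars
    ),
    class = "fwam"
  )
}

#' @export
print.fwam <- function(x, ...) {
  cat(sprintf(
    "<fwam> %d nodes, %d voted entries, gamma = %s\n",
    nrow(x$matrix), sum(x$matrix > 0),
    if (is.na(x$gamma)) "unset" else format(x$gamma)
  ))
  print(round(x$matrix, 3))
  invisible(x)
}

#' Tidy a weighted adjacency matrix
#'
#' @param x An `fwam`.
#' @param ... Unused.
#' @return A tibble of the nonzero entries: `from`, `to`, `weight`, and
#'   whether the entry clears the voting threshold (`NA` when unset).
#' @method tidy fwam
#' @export
tidy.fwam <- function(x, ...) {
  idx <- which(x$matrix > 0, arr.ind = TRUE)
  out <- tibble::tibble(
    from = x$variables[idx[, 2]],
    to = x$variables[idx[, 1]],
    weight = x$matrix[idx],
    passes = if (is.na(x$gamma)) NA else x$matrix[idx] > x$gamma
  )
  dplyr::arrange(out, dplyr::desc(.data$weight), .data$to, .data$from)
}

#' Heat-map view of a weighted adjacency matrix
#'
#' @param object An `fwam`.
#' @param ... Unused.
#' @return A ggplot object: voted edge weights by (child, parent) cell, with
#'   the threshold reflected in the fill legend title when set.
#' @method autoplot fwam
#' @export
autoplot.fwam <- function(object, ...) {
  df <- tidyr_like_expand(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$parent, y = .data$child, fill = .data$weight)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::scale_fill_gradient(
      low = "white", high = "steelblue",
      name = if (is.na(object$gamma)) {
        "vote weight"
      } else {
        sprintf("vote weight\n(gamma = %.2f)", object$gamma)
      }
    ) +
    ggplot2::scale_y_discrete(limits = rev(object$variables)) +
    ggplot2::labs(x = "parent", y = "child") +
    ggplot2::theme_minimal()
}

tidyr_like_expand <- function(object) {
  p <- length(object$variables)
  tibble::tibble(
    child = factor(rep(object$variables, p), levels = object$variables),
    parent = factor(rep(object$variables, each = p), levels = object$variables),
    weight = as.vector(object$matrix)
  )
}

#' Weighted-vote merge of candidate structures
#'
#' The core ensemble step, reused at every layer of the pipeline. Structure
#' weights are computed on the supplied dataset (edge strength normalised
#' over the candidates) unless fixed `weights` are given; the weighted
#' adjacency matrices are summed; and the voting threshold is
#' `gamma = t_factor * min(weight)` over the participating (edged)
#' structures. Entries strictly above `gamma` are considered in descending
#' vote order (ties: ascending child then parent index) and each edge is
#' added unless it would create a directed cycle, so stronger consensus
#' edges win cycle conflicts and the result is always a DAG.
#'
#' @param graphs A non-empty list of `bn_graph`s over the data's variables.
#' @param data A data frame or `bn_dataset` used to weight the candidates.
#' @param t_factor Positive threshold factor `T`; an edge must be carried by
#'   more than `T` structures' worth of minimal weight to survive.
#' @param ess Equivalent sample size for the weighting score.
#' @param weights Optional fixed weights (summing to one), bypassing the
#'   data-driven weighting; used when weights are supplied upstream.
#' @return The merged `bn_graph` DAG, with the `fwam` (including `gamma`) in
#'   attribute `"fwam"` and the weights in attribute `"weights"`.
#' @export
structure_ensemble <- function(graphs, data, t_factor, ess = 1, weights = NULL) {
  if (length(graphs) == 0) stop("no structures to merge", call. = FALSE)
  stopifnot(t_factor > 0)
  if (is.null(weights)) {
    weights <- structure_weights(graphs, data, ess = ess)
  }
  fw <- final_weighted_adjacency(graphs, weights)
  participating <- weights > 0
  gamma <- t_factor * min(weights[participating])
  fw$gamma <- gamma
  fw$t_factor <- t_factor
  p <- nrow(fw$matrix)
  cand <- which(fw$matrix > gamma, arr.ind = TRUE)
  merged <- matrix(0L, p, p)
  if (nrow(cand) > 0) {
    vals <- fw$matrix[cand]
    ord <- order(-vals, cand[, 1], cand[, 2])
    for (k in ord) {
      i <- cand[k, 1]
      j <- cand[k, 2]
      merged[i, j] <- 1L
      if (!is_acyclic(merged)) merged[i, j] <- 0L
    }
  }
  out <- bn_graph(merged, graphs[[1]]$variables)
  attr(out, "fwam") <- fw
  attr(out, "weights") <- weights
  out
}
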