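#' Directed graphs over a fixed variable order
#'
#' Structures are held as a `P x P` binary adjacency matrix with the
#' **row = child** convention: `adjacency[i, j] == 1` means there is a
#' directed edge `j -> i`. All learners and the ensemble produce and consume
#' this representation; every serialisation states the convention.
#'
#' @param adjacency A square 0/1 matrix (row = child, column = parent).
#' @param variables Optional character vector of node names; defaults to the
#'   matrix dimnames or `V1..VP`.
#' @return An object of class `bn_graph`.
#' @examples
#' g <- bn_graph(matrix(c(0, 1, 0, 0), 2, 2), c("a", "b")) # edge a -> b
#' n_edges(g)
#' @export
bn_graph <- function(adjacency, variables = NULL) {
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency)) {
    stop("adjacency matrix must be square", call. = FALSE)
  }
  if (!all(adjacency %in% c(0, 1))) {
    stop("adjacency entries must be 0 or 1", call. = FALSE)
  }
  if (any(diag(adjacency) != 0)) {
    stop("self-loops are not allowed", call. = FALSE)
  }
  if (is.null(variables)) {
    variables <- rownames(adjacency)
    if (is.null(variables)) variables <- paste0("V", seq_len(nrow(adjacency)))
  }
  if (length(variables) != nrow(adjacency)) {
    stop("variables must name every node", call. = FALSE)
  }
  storage.mode(adjacency) <- "integer"
  dimnames(adjacency) <- list(variables, variables)
  structure(list(adjacency = adjacency, variables = variables),
    class = "bn_graph"
  )
}

#' @rdname bn_graph
#' @param p Node count.
#' @export
empty_graph <- function(p, variables = NULL) {
  bn_graph(matrix(0L, p, p), variables)
}

#' Build a graph from an edge list
#'
#' @param p Node count.
#' @param edges Two-column matrix or data frame of `(parent, child)` index
#'   pairs (or a zero-row object for the empty graph).
#' @param variables Optional node names.
#' @return A `bn_graph`.
#' @export
graph_from_edges <- function(p, edges, variables = NULL) {
  a <- matrix(0L, p, p)
  edges <- as.matrix(edges)
  if (nrow(edges) > 0) a[cbind(edges[, 2], edges[, 1])] <- 1L
  bn_graph(a, variables)
}

#' @rdname bn_graph
#' @param g A `bn_graph`.
#' @export
n_edges <- function(g) sum(g$adjacency)

#' @rdname bn_graph
#' @export
n_nodes <- function(g) nrow(g$adjacency)

parents_of <- function(g, node) which(g$adjacency[node, ] == 1L)
children_of <- function(g, node) which(g$adjacency[, node] == 1L)

#' @export
print.bn_graph <- function(x, ...) {
  cat(sprintf(
    "<bn_graph> %d nodes, %d edges (row = child convention)\n",
    n_nodes(x), n_edges(x)
  ))
  ed <- which(x$adjacency == 1L, arr.ind = TRUE)
  if (nrow(ed) > 0) {
    lab <- paste0(
      x$variables[ed[, 2]], " -> ", x$variables[ed[, 1]]
    )
    cat(" ", paste(sort(lab), collapse = "\n  "), "\n", sep = "")
  }
  invisible(x)
}

#' Tidy a directed graph into an edge tibble
#'
#' @param x A `bn_graph`.
#' @param ... Unused.
#' @return A tibble with columns `from`, `to` (variable names) and the
#'   corresponding indices `from_index`, `to_index`.
#' @method tidy bn_graph
#' @export
tidy.bn_graph <- function(x, ...) {
  ed <- which(x$adjacency == 1L, arr.ind = TRUE)
  out <- tibble::tibble(
    from = x$variables[ed[, 2]],
    to = x$variables[ed[, 1]],
    from_index = as.integer(ed[, 2]),
    to_index = as.integer(ed[, 1])
  )
  dplyr::arrange(out, .data$from_index, .data$to_index)
}

#' Test a directed graph for acyclicity
#'
#' Kahn's elimination: repeatedly delete nodes whose in-row is empty; the
#' graph is acyclic iff every node can be deleted.
#'
#' @param g A `bn_graph` (or bare adjacency matrix).
#' @return `TRUE` iff the graph has no directed cycle.
#' @export
is_acyclic <- function(g) {
  a <- if (inherits(g, "bn_graph")) g$adjacency else as.matrix(g)
  if (nrow(a) != ncol(a) || !all(a %in% c(0L, 1L))) {
    stop("malformed adjacency matrix", call. = FALSE)
  }
  alive <- rep(TRUE, nrow(a))
  repeat {
    indeg <- rowSums(a[, alive, drop = FALSE])
    free <- alive & indeg == 0
    if (!any(free)) break
    alive[free] <- FALSE
    if (!any(alive)) {
      return(TRUE)
    }
  }
  !any(alive)
}

#' Topological order of a DAG
#'
#' @param g A `bn_graph` assumed acyclic.
#' @return Integer vector: node indices, parents before children.
#' @export
topological_order <- function(g) {
  a <- g$adjacency
  alive <- rep(TRUE, nrow(a))
  order <- integer(0)
  while (any(alive)) {
    indeg <- rowSums(a[, alive, drop = FALSE])
    free <- which(alive & indeg == 0)
    if (length(free) == 0) stop("graph has a cycle", call. = FALSE)
    order <- c(order, free)
    alive[free] <- FALSE
  }
  order
}

#' Markov blanket of a node
#'
#' Parents, children and the children's other parents (spouses) of a node;
#' the node itself is excluded. Together these shield the node from the rest
#' of the network.
#'
#' @param g A `bn_graph` (DAG).
#' @param node Node index in `1..P`.
#' @return Sorted integer vector of blanket member indices.
#' @export
markov_blanket <- function(g, node) {
  p <- n_nodes(g)
  if (!is.numeric(node) || length(node) != 1 || node < 1 || node > p) {
    stop("node index out of range", call. = FALSE)
  }
  ch <- children_of(g, node)
  spouses <- unlist(lapply(ch, function(c) parents_of(g, c)), use.names = FALSE)
  mb <- union(union(parents_of(g, node), ch), spouses)
  sort(setdiff(mb, node))
}

#' Average Markov blanket size
#'
#' The mean, over all `P` nodes, of the Markov blanket size. A complexity
#' statistic of a structure, invariant across the Markov-equivalence class
#' (the skeleton and the non-adjacent co-parent pairs determine it).
#'
#' @param g A `bn_graph` (DAG).
#' @return Mean blanket size, in `[0, P - 1]`.
#' @export
ambs <- function(g) {
  p <- n_nodes(g)
  sizes <- vapply(seq_len(p), function(i) length(markov_blanket(g, i)), numeric(1))
  sum(sizes) / p
}

#' Structural Hamming distance
#'
#' Number of edge operations (add a missing edge, delete an extra edge,
#' reverse a wrongly oriented edge) needed to turn one DAG into another; a
#' reversed edge counts one. Symmetric in its arguments.
#'
#' @param g1,g2 `bn_graph`s over the same variables, in the same order.
#' @return Non-negative integer.
#' @export
shd <- function(g1, g2) {
  if (n_nodes(g1) != n_nodes(g2) || !identical(g1$variables, g2$variables)) {
    stop("graphs must share the same node set and order", call. = FALSE)
  }
  a <- g1$adjacency
  b <- g2$adjacency
  p <- nrow(a)
  d <- 0L
  for (i in seq_len(p - 1)) {
    for (j in seq(i + 1L, p)) {
      e1 <- c(a[i, j], a[j, i]) # j->i, i->j in g1
      e2 <- c(b[i, j], b[j, i])
      if (!identical(e1, e2)) d <- d + 1L
    }
  }
  d
}

#' Skeleton and v-structures of a DAG
#'
#' The undirected skeleton plus all collider triples `x -> z <- y` with `x`
#' and `y` non-adjacent. Skeleton and v-structures together identify the
#' Markov-equivalence class, so equivalence-aware tests compare these.
#'
#' @param g A `bn_graph` (DAG).
#' @return A list with `skeleton` (two-column matrix of node index pairs,
#'   `i < j`) and `v_structures` (three-column matrix of `(x, z, y)` triples,
#'   `x < y`).
#' @export
skeleton_and_vstructures <- function(g) {
  a <- g$adjacency
  und <- (a + t(a)) > 0
  idx <- which(und & upper.tri(und), arr.ind = TRUE)
  skeleton <- cbind(i = idx[, 1], j = idx[, 2])
  vs <- NULL
  for (z in seq_len(nrow(a))) {
    pa <- parents_of(g, z)
    if (length(pa) >= 2) {
      for (cmb in utils::combn(pa, 2, simplify = FALSE)) {
        x <- min(cmb)
        y <- max(cmb)
        if (!und[x, y]) vs <- rbind(vs, c(x, z, y))
      }
    }
  }
  if (is.null(vs)) vs <- matrix(integer(0), ncol = 3)
  colnames(vs) <- c("x", "z", "y")
  list(skeleton = skeleton, v_structures = vs[order(vs[, 1], vs[, 2], vs[, 3]), , drop = FALSE])
}

#' Are two DAGs Markov equivalent?
#'
#' @param g1,g2 `bn_graph`s over the same variables.
#' @return `TRUE` iff skeletons and v-structure sets coincide.
#' @export
markov_equivalent <- function(g1, g2) {
  s1 <- skeleton_and_vstructures(g1)
  s2 <- skeleton_and_vstructures(g2)
  identical(unname(s1$skeleton), unname(s2$skeleton)) &&
    identical(unname(s1$v_structures), unname(s2$v_structures))
}

#' Write / read an adjacency matrix as TSV
#'
#' The file carries a comment line stating the row = child convention, a
#' header row of variable names, then the 0/1 matrix. Round-trips losslessly.
#'
#' @param g A `bn_graph`.
#' @param path Output path.
#' @return `path` invisibly (writer); a `bn_graph` (reader).
#' @export
write_graph_tsv <- function(g, path) {
  stopifnot(inherits(g, "bn_graph"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# adjacency: entry [i,j] = 1 means edge j -> i (row = child)", con)
  writeLines(paste(g$variables, collapse = "\t"), con)
  utils::write.table(g$adjacency,
    file = con, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' @rdname write_graph_tsv
#' @export
read_graph_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  vars <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  p <- length(vars)
  if (length(lines) != p + 1L) {
    stop(sprintf("expected %d matrix rows in %s", p, path), call. = FALSE)
  }
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  if (any(lengths(rows) != p)) {
    stop(sprintf("matrix dimension mismatch in %s", path), call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(unlist(rows)))
  if (anyNA(vals) || !all(vals %in% c(0, 1))) {
    stop(sprintf("non-binary adjacency cell in %s", path), call. = FALSE)
  }
  bn_graph(matrix(vals, nrow = p, byrow = TRUE), vars)
}
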