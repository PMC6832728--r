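#' Read and write networks in the Bayesian Interchange Format
#'
#' A plain-text serialisation of a `bn_network`: one `variable` block per
#' node listing its discrete states, and one `probability` block per node
#' giving either a root `table` line or one line per joint parent
#' configuration (parent states in declaration order, the first listed
#' parent varying fastest across lines). The reader supports the subset the
#' writer emits plus the common published benchmark layout.
#'
#' @param bn A `bn_network`.
#' @param path File path.
#' @param name Network name written into the header.
#' @return `path` invisibly (writer); a `bn_network` (reader).
#' @export
write_bif <- function(bn, path, name = "network") {
  stopifnot(inherits(bn, "bn_network"))
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("network %s {", name)
  w("}")
  p <- n_nodes(bn$graph)
  for (i in seq_len(p)) {
    w("variable %s {", bn$variables[i])
    w(
      "  type discrete [ %d ] { %s };", bn$arities[i],
      paste(bn$levels[[i]], collapse = ", ")
    )
    w("}")
  }
  for (i in seq_len(p)) {
    pa <- parents_of(bn$graph, i)
    cpt <- bn$cpts[[i]]
    if (length(pa) == 0) {
      w("probability ( %s ) {", bn$variables[i])
      w("  table %s;", paste(format(cpt[1, ], digits = 15), collapse = ", "))
    } else {
      w(
        "probability ( %s | %s ) {", bn$variables[i],
        paste(bn$variables[pa], collapse = ", ")
      )
      q <- nrow(cpt)
      combos <- config_states(bn$arities[pa])
      for (row in seq_len(q)) {
        labels <- vapply(
          seq_along(pa),
          function(s) bn$levels[[pa[s]]][combos[row, s]], character(1)
        )
        w(
          "  (%s) %s;", paste(labels, collapse = ", "),
          paste(format(cpt[row, ], digits = 15), collapse = ", ")
        )
      }
    }
    w("}")
  }
  invisible(path)
}

# All joint configurations of the given arities, first column fastest;
# row r matches parent-configuration index r used by the scorer and sampler.
config_states <- function(arities) {
  if (length(arities) == 0) {
    return(matrix(integer(0), nrow = 1, ncol = 0))
  }
  as.matrix(expand.grid(lapply(arities, seq_len)))
}

#' @rdname write_bif
#' @export
read_bif <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  vars <- character(0)
  levels <- list()
  i <- 1L
  n_lines <- length(lines)
  while (i <= n_lines) {
    ln <- lines[i]
    if (grepl("^variable\\s", ln)) {
      nm <- sub("^variable[[:space:]]+([^[:space:]{]+).*$", "\\1", ln)
      repeat {
        i <- i + 1L
        if (i > n_lines) stop("unterminated variable block", call. = FALSE)
        if (grepl("^type\\s", lines[i])) {
          states <- sub("^.*\\{\\s*(.*?)\\s*\\}.*$", "\\1", lines[i])
          vars <- c(vars, nm)
          levels[[nm]] <- trimws(strsplit(states, ",")[[1]])
        }
        if (grepl("\\}\\s*$", lines[i]) && !grepl("^type", lines[i])) break
      }
    }
    i <- i + 1L
  }
  p <- length(vars)
  if (p == 0) stop("no variable blocks found", call. = FALSE)
  arities <- vapply(levels, length, integer(1))
  adj <- matrix(0L, p, p)
  cpts <- rep(list(NULL), p)
  i <- 1L
  while (i <= n_lines) {
    ln <- lines[i]
    if (grepl("^probability\\s*\\(", ln)) {
      head <- sub("^probability\\s*\\(([^)]*)\\).*$", "\\1", ln)
      parts <- strsplit(head, "|", fixed = TRUE)[[1]]
      child <- match(trimws(parts[1]), vars)
      pa <- if (length(parts) > 1) {
        match(trimws(strsplit(parts[2], ",")[[1]]), vars)
      } else {
        integer(0)
      }
      if (anyNA(c(child, pa))) {
        stop("probability block names unknown variable", call. = FALSE)
      }
      adj[child, pa] <- 1L
      r <- arities[child]
      q <- prod(arities[pa])
      cpt <- matrix(NA_real_, max(q, 1L), r)
      repeat {
        i <- i + 1L
        if (i > n_lines) stop("unterminated probability block", call. = FALSE)
        row_ln <- lines[i]
        if (grepl("^\\}", row_ln)) break
        if (grepl("^table", row_ln)) {
          vals <- as.numeric(trimws(strsplit(
            sub(";\\s*$", "", sub("^table", "", row_ln)), ","
          )[[1]]))
          cpt[1, ] <- vals
        } else if (grepl("^\\(", row_ln)) {
          cfg <- sub("^\\(([^)]*)\\).*$", "\\1", row_ln)
          states <- trimws(strsplit(cfg, ",")[[1]])
          idx <- vapply(
            seq_along(pa),
            function(s) match(states[s], levels[[pa[s]]]), integer(1)
          )
          # row index under the package convention: parents in ascending
          # index order, first parent fastest
          o <- order(pa)
          row <- 1L
          mult <- 1L
          for (s in o) {
            row <- row + (idx[s] - 1L) * mult
            mult <- mult * arities[pa[s]]
          }
          vals <- as.numeric(trimws(strsplit(
            sub(";\\s*$", "", sub("^\\([^)]*\\)", "", row_ln)), ","
          )[[1]]))
          cpt[row, ] <- vals
        }
      }
      if (anyNA(cpt)) stop("incomplete probability table", call. = FALSE)
      cpts[[child]] <- cpt
    }
    i <- i + 1L
  }
  g <- bn_graph(adj, vars)
  bn_network(g, cpts, levels = unname(levels))
}

#' JSON mirror of a network
#'
#' A lossless JSON representation of a `bn_network` (variables, state
#' labels, adjacency with the row = child convention, and per-node CPT rows).
#'
#' @param bn A `bn_network`.
#' @param path File path.
#' @return `path` invisibly (writer); a `bn_network` (reader).
#' @export
write_bn_json <- function(bn, path) {
  stopifnot(inherits(bn, "bn_network"))
  obj <- list(
    variables = bn$variables,
    levels = bn$levels,
    adjacency = bn$graph$adjacency,
    cpts = lapply(bn$cpts, function(m) unname(apply(m, 1, c, simplify = FALSE)))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bn_json
#' @export
read_bn_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- length(obj$variables)
  g <- bn_graph(obj$adjacency, obj$variables)
  levels <- obj$levels
  if (is.matrix(levels)) { # equal arities simplify to a row-major matrix
    levels <- lapply(seq_len(p), function(i) levels[i, ])
  }
  cpts <- lapply(seq_len(p), function(i) {
    m <- obj$cpts[[i]]
    if (is.list(m)) m <- do.call(rbind, m)
    if (!is.matrix(m)) m <- matrix(m, nrow = 1)
    matrix(as.numeric(m), nrow = nrow(m))
  })
  bn_network(g, cpts, levels = levels)
}
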