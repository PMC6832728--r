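#' Discrete categorical datasets
#'
#' A `bn_dataset` is the unit of data consumed by every structure learner in
#' the package: `N` complete records over `P` categorical variables with known
#' arities. Internally each column is stored as an integer code in `1..r_i`;
#' the original labels are kept so files round-trip losslessly. Variable order
#' is fixed and shared with every graph learned over the same variables.
#'
#' @param data A data frame (or tibble) of categorical columns. Factors keep
#'   their level order; other columns are coded by first appearance.
#' @param arities Optional integer vector of arities, one per column. Needed
#'   when a subset of the data may not exhibit every level (e.g. slices);
#'   defaults to the number of distinct observed values, with a minimum of 2.
#' @return An object of class `bn_dataset` with fields `x` (integer matrix,
#'   codes `1..r`), `variables`, `arities` and `levels`.
#' @examples
#' d <- as_bn_dataset(data.frame(a = c("y", "n", "y"), b = c("0", "1", "1")))
#' n_records(d)
#' @export
as_bn_dataset <- function(data, arities = NULL) {
  if (inherits(data, "bn_dataset")) {
    return(data)
  }
  stopifnot(is.data.frame(data))
  if (ncol(data) < 1L) {
    stop("a dataset needs at least one variable", call. = FALSE)
  }
  vars <- names(data)
  cols <- vector("list", ncol(data))
  levs <- vector("list", ncol(data))
  for (i in seq_along(data)) {
    col <- data[[i]]
    if (anyNA(col)) {
      stop(sprintf("variable '%s' contains missing values", vars[i]), call. = FALSE)
    }
    if (is.factor(col)) {
      levs[[i]] <- levels(col)
      cols[[i]] <- as.integer(col)
    } else {
      u <- unique(as.character(col))
      levs[[i]] <- u
      cols[[i]] <- match(as.character(col), u)
    }
  }
  r <- if (is.null(arities)) {
    pmax(2L, vapply(levs, length, integer(1)))
  } else {
    as.integer(arities)
  }
  if (length(r) != length(vars) || any(r < 2L)) {
    stop("arities must give one integer >= 2 per variable", call. = FALSE)
  }
  obs <- vapply(levs, length, integer(1))
  if (any(obs > r)) {
    stop("observed levels exceed the declared arity", call. = FALSE)
  }
  x <- matrix(unlist(cols, use.names = FALSE), ncol = length(vars))
  storage.mode(x) <- "integer"
  new_bn_dataset(x, vars, r, levs)
}

new_bn_dataset <- function(x, variables, arities, levels) {
  structure(
    list(
      x = x,
      variables = variables,
      arities = as.integer(arities),
      levels = levels,
      cache = new.env(parent = emptyenv())
    ),
    class = "bn_dataset"
  )
}

#' @rdname as_bn_dataset
#' @param d A `bn_dataset`.
#' @export
n_records <- function(d) nrow(d$x)

#' @rdname as_bn_dataset
#' @export
n_variables <- function(d) ncol(d$x)

#' Take a row subset of a dataset
#'
#' Keeps variable order, arities and level maps so that slices of a large
#' dataset remain scoreable even when a slice misses rare levels. Used by the
#' slicing layers of the pipeline, which read contiguous blocks.
#'
#' @param d A `bn_dataset`.
#' @param rows Integer row indices.
#' @return A `bn_dataset` with the selected records (own score cache).
#' @export
dataset_slice <- function(d, rows) {
  stopifnot(inherits(d, "bn_dataset"))
  new_bn_dataset(d$x[rows, , drop = FALSE], d$variables, d$arities, d$levels)
}

#' @export
print.bn_dataset <- function(x, ...) {
  cat(sprintf(
    "<bn_dataset> %d records x %d variables (arities: %s)\n",
    nrow(x$x), ncol(x$x), paste(x$arities, collapse = ", ")
  ))
  invisible(x)
}

#' Convert a dataset back to a tibble of labels
#'
#' @param x A `bn_dataset`.
#' @param ... Unused.
#' @return A tibble with the original categorical labels.
#' @method as_tibble bn_dataset
#' @export
as_tibble.bn_dataset <- function(x, ...) {
  out <- lapply(seq_len(ncol(x$x)), function(i) x$levels[[i]][x$x[, i]])
  names(out) <- x$variables
  tibble::as_tibble(out)
}

#' Read a categorical dataset from CSV
#'
#' The file must have a header row and no missing cells. Levels are mapped to
#' integer codes by first appearance per column and the mapping is retained,
#' so a file written by [write_dataset_csv()] reads back identically.
#'
#' @param path Path to a CSV file.
#' @param sep Field separator (default comma).
#' @param arities Optional arity vector, as in [as_bn_dataset()].
#' @return A `bn_dataset`.
#' @export
read_dataset_csv <- function(path, sep = ",", arities = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) {
    stop(sprintf("empty file: %s", path), call. = FALSE)
  }
  parts <- strsplit(lines, sep, fixed = TRUE)
  header <- parts[[1]]
  p <- length(header)
  widths <- lengths(parts[-1])
  if (any(widths != p)) {
    bad <- which(widths != p)[1] + 1L
    stop(sprintf("ragged row at line %d of %s", bad, path), call. = FALSE)
  }
  body <- parts[-1]
  cells <- unlist(body, use.names = FALSE)
  if (any(cells == "" | cells == "NA")) {
    idx <- which(matrix(cells == "" | cells == "NA", ncol = p, byrow = TRUE),
      arr.ind = TRUE
    )[1, 1]
    stop(sprintf("missing value at line %d of %s", idx + 1L, path), call. = FALSE)
  }
  df <- as.data.frame(
    matrix(cells, ncol = p, byrow = TRUE),
    stringsAsFactors = FALSE
  )
  names(df) <- header
  as_bn_dataset(df, arities = arities)
}

#' Write a categorical dataset to CSV
#'
#' @param d A `bn_dataset` or data frame.
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(d, path, sep = ",") {
  d <- as_bn_dataset(d)
  df <- as.data.frame(as_tibble.bn_dataset(d))
  utils::write.table(df,
    file = path, sep = sep, quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}
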