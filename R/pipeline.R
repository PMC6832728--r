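#' Partition a dataset across local learners
#'
#' Contiguous row blocks of `floor(N / k)` records, with the remainder
#' appended to the last block; order is preserved and no record is lost or
#' duplicated.
#'
#' @param data A data frame or `bn_dataset`.
#' @param k Number of partitions (local learners), `1 <= k <= N`.
#' @return A list of `k` `bn_dataset`s.
#' @export
partition_global <- function(data, k) {
  d <- as_bn_dataset(data)
  n <- n_records(d)
  if (k < 1 || k > n) {
    stop("k must be between 1 and the number of records", call. = FALSE)
  }
  base <- n %/% k
  starts <- (seq_len(k) - 1L) * base + 1L
  ends <- starts + base - 1L
  ends[k] <- n
  lapply(seq_len(k), function(i) dataset_slice(d, seq.int(starts[i], ends[i])))
}

#' Number of data slices per local learner
#'
#' `floor(N / (k * als))`, clamped below at one (with a warning when even a
#' single full-size slice does not fit).
#'
#' @param n Total record count.
#' @param k Number of local learners.
#' @param als Appropriate learning size (records per slice).
#' @return A positive integer.
#' @export
num_data_slices <- function(n, k, als) {
  stopifnot(n > 0, k > 0, als > 0)
  nd <- n %/% (k * als)
  if (nd < 1) {
    warning("dataset smaller than one full slice per learner; using one undersized slice",
      call. = FALSE
    )
    nd <- 1L
  }
  as.integer(nd)
}

default_learners <- function() {
  list(mmhc = mmhc, hc = hill_climb, tabu = tabu_search)
}

#' First ensemble layer: learn one structure from a data slice
#'
#' Runs the constituent algorithms (by default max-min hill climbing, hill
#' climbing and tabu search) on one slice and merges their structures by
#' weighted voting with threshold factor 2, i.e. simple majority of three.
#' A failing algorithm is dropped with a warning; if fewer than two remain,
#' the single surviving structure (best edge strength) is returned. When
#' every learned structure is edgeless the merge is the empty graph.
#'
#' @param slice A data frame or `bn_dataset`.
#' @param search A [search_config()] shared by the constituent algorithms.
#' @param ess Equivalent sample size for the vote weighting.
#' @param learners Named list of functions `(data, cfg) -> bn_graph`;
#'   override to swap or wrap constituent algorithms.
#' @param t_factor Voting threshold factor (default 2).
#' @return The merged `bn_graph`.
#' @export
data_slice_learner <- function(slice, search = search_config(), ess = search$ess,
                               learners = default_learners(), t_factor = 2) {
  d <- as_bn_dataset(slice)
  if (n_records(d) < 1) stop("empty data slice", call. = FALSE)
  graphs <- list()
  for (nm in names(learners)) {
    g <- tryCatch(learners[[nm]](d, search), error = function(e) {
      warning(sprintf("constituent learner '%s' failed: %s", nm, conditionMessage(e)),
        call. = FALSE
      )
      NULL
    })
    if (!is.null(g)) graphs[[nm]] <- g
  }
  if (length(graphs) == 0) {
    stop("all constituent learners failed", call. = FALSE)
  }
  if (length(graphs) < 2) {
    warning("fewer than two constituent structures; returning the survivor",
      call. = FALSE
    )
    return(graphs[[1]])
  }
  es <- vapply(graphs, edge_strength, numeric(1), d = d, ess = ess)
  if (all(!is.finite(es))) {
    return(empty_graph(n_variables(d), d$variables))
  }
  suppressWarnings(structure_ensemble(unname(graphs), d, t_factor = t_factor, ess = ess))
}

#' Second ensemble layer: merge the structures of one learner's slices
#'
#' Learns one structure per slice with [data_slice_learner()], tracks the
#' slice whose merged structure has the best (lowest) edge strength, and
#' merges all slice structures by weighted voting on that best slice with
#' threshold factor `n_slices / 2` -- an edge must appear in more than half
#' of the slice structures (by weight) to survive.
#'
#' @param slices List of `bn_dataset`s (the learner's data slices).
#' @param search,ess,learners As in [data_slice_learner()].
#' @return A list of class `local_result`: `local_graph`, `best_slice_id`,
#'   `best_slice_es`, `slice_graphs` (count) and `best_slice` (the dataset,
#'   carried forward for the global merge).
#' @export
local_learner <- function(slices, search = search_config(), ess = search$ess,
                          learners = default_learners()) {
  nd <- length(slices)
  stopifnot(nd >= 1)
  graphs <- vector("list", nd)
  es <- numeric(nd)
  for (k in seq_len(nd)) {
    graphs[[k]] <- data_slice_learner(slices[[k]],
      search = search, ess = ess,
      learners = learners
    )
    es[k] <- edge_strength(graphs[[k]], slices[[k]], ess)
  }
  best <- which.min(es)
  merged <- if (all(!is.finite(es))) {
    empty_graph(n_variables(slices[[1]]), slices[[1]]$variables)
  } else {
    suppressWarnings(
      structure_ensemble(graphs, slices[[best]], t_factor = nd / 2, ess = ess)
    )
  }
  structure(
    list(
      local_graph = merged, best_slice_id = best, best_slice_es = es[best],
      slice_graphs = nd, best_slice = slices[[best]]
    ),
    class = "local_result"
  )
}

#' Third ensemble layer: merge the local structures into the final DAG
#'
#' Selects the slice with the best (lowest) edge strength across all local
#' results as the representative dataset, and merges the local structures by
#' weighted voting on it with threshold factor `2 * k / 3` -- an edge must
#' appear in more than two thirds of the local structures to survive.
#'
#' @param locals List of `local_result`s.
#' @param ess Equivalent sample size for the vote weighting.
#' @return The final `bn_graph`.
#' @export
global_ensemble <- function(locals, ess = 1) {
  k <- length(locals)
  stopifnot(k >= 1)
  graphs <- lapply(locals, `[[`, "local_graph")
  best <- which.min(vapply(locals, `[[`, numeric(1), "best_slice_es"))
  ds_bg <- locals[[best]]$best_slice
  if (all(vapply(graphs, n_edges, numeric(1)) == 0)) {
    return(empty_graph(n_nodes(graphs[[1]]), graphs[[1]]$variables))
  }
  suppressWarnings(
    structure_ensemble(graphs, ds_bg, t_factor = 2 * k / 3, ess = ess)
  )
}

#' Three-layer ensemble structure learning
#'
#' The full pipeline: (1) the dataset is split into `k` contiguous
#' partitions, one per local learner, and the appropriate learning size is
#' estimated once on the first partition by greedy doubling; (2) each
#' partition is cut into slices of that size and each local learner merges
#' its per-slice three-algorithm ensembles by majority voting; (3) the local
#' structures are merged into the final DAG by a two-thirds vote. Local
#' learners are independent, so they may run in parallel worker processes;
#' the result is a pure function of the data and configuration, identical
#' for any worker count.
#'
#' @param data A data frame or `bn_dataset` of discrete variables.
#' @param k Number of local learners (data partitions).
#' @param workers Parallel worker processes for the local-learning phase.
#' @param ess Equivalent sample size used by every scoring step.
#' @param als A precomputed [als_config()] (or an `als_result` / integer
#'   slice size to skip the estimation phase).
#' @param search A [search_config()] shared by the base learners.
#' @param learners Named list of constituent algorithms, as in
#'   [data_slice_learner()].
#' @param seed Optional integer; recorded in the report and set before
#'   learning (the pipeline itself is deterministic).
#' @return An object of class `penbayes_fit`: `graph` (the final DAG) and
#'   `report` (ALS estimate, slices per learner, per-learner summaries,
#'   work counts, per-phase timings, configuration echo).
#' @examples
#' \donttest{
#' gt <- cancer_fixture(0.9)
#' d <- forward_sample(gt$network, 40000, seed = 1)
#' fit <- run_penbayes(d, k = 2)
#' shd(fit$graph, gt$network$graph)
#' }
#' @export
run_penbayes <- function(data, k = 4, workers = 1L, ess = 1,
                         als = als_config(ess = ess),
                         search = search_config(ess = ess),
                         learners = default_learners(), seed = NULL) {
  d <- as_bn_dataset(data)
  n <- n_records(d)
  t0 <- proc.time()[["elapsed"]]
  parts <- partition_global(d, k)
  if (!is.null(seed)) set.seed(seed)

  if (inherits(als, "als_config")) {
    min_n <- als$initial_multiplier * n_variables(d) * k
    if (n < min_n) {
      stop(sprintf(
        "dataset too small: %d records, but k = %d learners need at least %d",
        n, k, min_n
      ), call. = FALSE)
    }
    als_res <- calculate_als(parts[[1]],
      cfg = als,
      learner = function(s) {
        data_slice_learner(s, search = search, ess = ess, learners = learners)
      }
    )
  } else if (inherits(als, "als_result")) {
    als_res <- als
  } else {
    als_res <- structure(
      list(
        als = as.integer(als), ambs_trace = numeric(0), es_trace = numeric(0),
        slice_sizes = integer(0), steps = 0L, final_ambs = NA_real_,
        final_es = NA_real_, truncated = FALSE
      ),
      class = "als_result"
    )
  }
  nd <- num_data_slices(n, k, als_res$als)
  t1 <- proc.time()[["elapsed"]]

  slice_rows <- function(part) {
    np <- n_records(part)
    size <- min(als_res$als, np)
    starts <- (seq_len(nd) - 1L) * size + 1L
    ends <- pmin(starts + size - 1L, np)
    ends[nd] <- np # remainder rows join the last slice
    lapply(seq_len(nd), function(s) dataset_slice(part, seq.int(starts[s], ends[s])))
  }
  run_local <- function(part) {
    local_learner(slice_rows(part), search = search, ess = ess, learners = learners)
  }
  locals <- if (workers > 1L) {
    parallel::mclapply(parts, run_local, mc.cores = workers)
  } else {
    lapply(parts, run_local)
  }
  t2 <- proc.time()[["elapsed"]]
  final <- global_ensemble(locals, ess = ess)
  t3 <- proc.time()[["elapsed"]]

  local_summary <- tibble::tibble(
    learner = seq_len(k),
    n_records = vapply(parts, n_records, integer(1)),
    best_slice_id = vapply(locals, `[[`, integer(1), "best_slice_id"),
    best_slice_es = vapply(locals, `[[`, numeric(1), "best_slice_es"),
    n_edges = vapply(locals, function(l) n_edges(l$local_graph), numeric(1))
  )
  report <- list(
    n = n, p = n_variables(d), k = k, als = als_res, nd = nd,
    slice_learner_calls = k * nd, local_merges = k, global_merges = 1L,
    local_summary = local_summary,
    global_weights = attr(final, "weights"),
    timings = c(
      preprocess = t1 - t0, local = t2 - t1, global = t3 - t2,
      total = t3 - t0
    ),
    config = list(ess = ess, workers = workers, seed = seed)
  )
  structure(list(graph = final, report = report), class = "penbayes_fit")
}

#' @rdname run_penbayes
#' @export
penbayes <- run_penbayes

#' @export
print.penbayes_fit <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "<penbayes_fit> %d records, %d variables | k = %d, ALS = %d, %d slice(s)/learner\n",
    r$n, r$p, r$k, r$als$als, r$nd
  ))
  cat(sprintf(
    "final structure: %d edges (%.1fs total)\n",
    n_edges(x$graph), r$timings[["total"]]
  ))
  invisible(x)
}

#' Tidy and summarise a fitted structure
#'
#' `tidy()` returns the final edge list; `glance()` a one-row summary of the
#' run (sizes, ALS, slices, work counts, timing).
#'
#' @param x A `penbayes_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy penbayes_fit
#' @export
tidy.penbayes_fit <- function(x, ...) {
  tidy.bn_graph(x$graph)
}

#' @rdname tidy.penbayes_fit
#' @method glance penbayes_fit
#' @export
glance.penbayes_fit <- function(x, ...) {
  r <- x$report
  tibble::tibble(
    n = r$n, p = r$p, k = r$k, als = r$als$als, als_steps = r$als$steps,
    final_ambs = r$als$final_ambs, nd = r$nd,
    slice_learner_calls = r$slice_learner_calls,
    n_edges = n_edges(x$graph), seconds = unname(r$timings[["total"]])
  )
}

#' Voting heat map of the final merge
#'
#' @param object A `penbayes_fit`.
#' @param ... Unused.
#' @return A ggplot: the global-layer weighted adjacency matrix with its
#'   voting threshold.
#' @method autoplot penbayes_fit
#' @export
autoplot.penbayes_fit <- function(object, ...) {
  fw <- attr(object$graph, "fwam")
  if (is.null(fw)) stop("fit carries no voting matrix", call. = FALSE)
  autoplot.fwam(fw)
}
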