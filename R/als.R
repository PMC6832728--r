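#' Configuration for the appropriate-learning-size estimator
#'
#' @param eps1 Relative convergence tolerance for the average Markov blanket
#'   size (default 0.05).
#' @param eps2 Relative convergence tolerance for edge strength (default
#'   0.05).
#' @param mstep Maximum number of doubling steps (default 20).
#' @param initial_multiplier Records per attribute in the first slice
#'   (default 50); the starting slice is `initial_multiplier * P` rows.
#' @param ess Equivalent sample size for scoring.
#' @return A list of class `als_config`.
#' @export
als_config <- function(eps1 = 0.05, eps2 = 0.05, mstep = 20L,
                       initial_multiplier = 50L, ess = 1) {
  stopifnot(eps1 > 0, eps2 > 0, mstep >= 0, initial_multiplier >= 1, ess > 0)
  structure(
    list(
      eps1 = eps1, eps2 = eps2, mstep = as.integer(mstep),
      initial_multiplier = as.integer(initial_multiplier), ess = ess
    ),
    class = "als_config"
  )
}

resolve_learner <- function(learner, search, ess) {
  if (is.function(learner)) {
    return(learner)
  }
  learner <- match.arg(learner, c("ensemble", "hc", "tabu", "mmhc"))
  switch(learner,
    ensemble = function(s) data_slice_learner(s, search = search, ess = ess),
    hc = function(s) hill_climb(s, search),
    tabu = function(s) tabu_search(s, search),
    mmhc = function(s) mmhc(s, search)
  )
}

#' Appropriate learning size by greedy doubling
#'
#' Estimates the smallest data-slice size on which learned-structure
#' statistics stabilise, by learning on a leading slice and doubling its
#' size until both the average Markov blanket size and the edge strength of
#' the learned structure change by less than a relative tolerance between
#' consecutive doublings (or the step budget / dataset is exhausted).
#' Slices are leading-prefix reads, so the data are assumed iid in row
#' order. The sentinel initial "best" values (AMBS 1, edge strength -1)
#' guarantee the first convergence check fails, so at least one doubling is
#' performed whenever `mstep >= 1`.
#'
#' @param data A data frame or `bn_dataset`.
#' @param cfg An [als_config()].
#' @param learner `"ensemble"` (the default: the three-algorithm data-slice
#'   learner), `"hc"`, `"tabu"`, `"mmhc"`, or any function mapping a
#'   `bn_dataset` to a `bn_graph`.
#' @param search A [search_config()] for the built-in learners.
#' @return An object of class `als_result`: `als` (the selected record
#'   count), `ambs_trace` and `es_trace` (one value per evaluated slice),
#'   `slice_sizes`, `steps`, `final_ambs` and `truncated` (`TRUE` when the
#'   dataset ran out before convergence, in which case the best size seen is
#'   returned).
#' @export
calculate_als <- function(data, cfg = als_config(), learner = "ensemble",
                          search = search_config(ess = cfg$ess)) {
  d <- as_bn_dataset(data)
  learn <- resolve_learner(learner, search, cfg$ess)
  p <- n_variables(d)
  n <- n_records(d)
  slice_size <- cfg$initial_multiplier * p
  if (n < slice_size) {
    stop(sprintf(
      "dataset has %d records but the initial slice needs %d", n, slice_size
    ), call. = FALSE)
  }
  slice <- dataset_slice(d, seq_len(slice_size))
  g <- learn(slice)
  current_ambs <- ambs(g)
  current_es <- edge_strength(g, slice, cfg$ess)
  best_ambs <- 1
  best_es <- -1
  step <- 0L
  truncated <- FALSE
  ambs_trace <- current_ambs
  es_trace <- current_es
  sizes <- slice_size
  while (step < cfg$mstep &&
    (abs(current_ambs - best_ambs) > best_ambs * cfg$eps1 ||
      abs(current_es - best_es) > best_es * cfg$eps2)) {
    if (slice_size * 2L > n) {
      truncated <- TRUE
      break
    }
    slice_size <- slice_size * 2L
    best_ambs <- current_ambs
    best_es <- current_es
    slice <- dataset_slice(d, seq_len(slice_size))
    g <- learn(slice)
    current_ambs <- ambs(g)
    current_es <- edge_strength(g, slice, cfg$ess)
    step <- step + 1L
    ambs_trace <- c(ambs_trace, current_ambs)
    es_trace <- c(es_trace, current_es)
    sizes <- c(sizes, slice_size)
  }
  structure(
    list(
      als = slice_size, ambs_trace = ambs_trace, es_trace = es_trace,
      slice_sizes = sizes, steps = step, final_ambs = current_ambs,
      final_es = current_es, truncated = truncated
    ),
    class = "als_result"
  )
}

#' @export
print.als_result <- function(x, ...) {
  cat(sprintf(
    "<als_result> als = %d after %d doubling(s); final AMBS %.3f, ES %.4f%s\n",
    x$als, x$steps, x$final_ambs, x$final_es,
    if (x$truncated) " (truncated: dataset exhausted)" else ""
  ))
  invisible(x)
}

#' Tidy the convergence trace of an ALS estimate
#'
#' @param x An `als_result`.
#' @param ... Unused.
#' @return A tibble with one row per evaluated slice: `step`, `slice_size`,
#'   `ambs`, `edge_strength`.
#' @method tidy als_result
#' @export
tidy.als_result <- function(x, ...) {
  tibble::tibble(
    step = seq_along(x$slice_sizes) - 1L,
    slice_size = x$slice_sizes,
    ambs = x$ambs_trace,
    edge_strength = x$es_trace
  )
}

#' @method glance als_result
#' @export
glance.als_result <- function(x, ...) {
  tibble::tibble(
    als = x$als, steps = x$steps, final_ambs = x$final_ambs,
    final_es = x$final_es, truncated = x$truncated
  )
}

#' Convergence plot of an ALS estimate
#'
#' @param object An `als_result`.
#' @param ... Unused.
#' @return A ggplot of AMBS and edge strength against slice size (log2
#'   x-axis), one panel per statistic.
#' @method autoplot als_result
#' @export
autoplot.als_result <- function(object, ...) {
  tr <- tidy.als_result(object)
  df <- tibble::tibble(
    slice_size = rep(tr$slice_size, 2),
    value = c(tr$ambs, tr$edge_strength),
    statistic = rep(c("AMBS", "edge strength"), each = nrow(tr))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$slice_size, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(trans = "log2") +
    ggplot2::facet_wrap(~ .data$statistic, scales = "free_y") +
    ggplot2::labs(
      x = "slice size (records)", y = NULL,
      title = sprintf("Doubling convergence (ALS = %d)", object$als)
    ) +
    ggplot2::theme_minimal()
}
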