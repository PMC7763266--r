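#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a causal graph into an edge list
#'
#' @param x A [causal_graph()].
#' @param ... Unused.
#' @return A tibble with one row per directed edge: `cause`, `effect`, and
#'   `row_score` (the minimised message length of the effect's parent
#'   selection, `NA` for ground-truth graphs).
#' @method tidy causal_graph
#' @export
tidy.causal_graph <- function(x, ...) {
  adj <- x$adjacency
  idx <- which(adj, arr.ind = TRUE)
  tibble::tibble(
    cause = colnames(adj)[idx[, "col"]],
    effect = rownames(adj)[idx[, "row"]],
    row_score = if (is.null(x$scores)) NA_real_ else x$scores[idx[, "row"]]
  )
}

#' One-row summary of a causal graph
#'
#' @param x A [causal_graph()].
#' @param ... Unused.
#' @return A tibble with node count, edge count, density over the
#'   `p*(p-1)` ordered pairs (self-loops counted separately), and the total
#'   message length over targets when available.
#' @method glance causal_graph
#' @export
glance.causal_graph <- function(x, ...) {
  p <- nrow(x$adjacency)
  off <- x$adjacency; diag(off) <- FALSE
  tibble::tibble(
    p = p,
    n_edges = sum(x$adjacency),
    n_self_loops = sum(diag(x$adjacency)),
    density = sum(off) / (p * (p - 1)),
    total_score = if (is.null(x$scores)) NA_real_ else
      sum(x$scores, na.rm = TRUE),
    n_failed = length(x$failed %||% integer(0))
  )
}

#' Tidy a per-target selection into one row per candidate series
#'
#' @param x An `hggm_selection` from [select_parents_exhaustive()] or
#'   [select_parents_ga()].
#' @param ... Unused.
#' @return A tibble with `series`, `selected`, plus the target and score.
#' @method tidy hggm_selection
#' @export
tidy.hggm_selection <- function(x, ...) {
  tibble::tibble(
    target = x$target_name,
    series_index = seq_along(x$Q),
    selected = x$Q
  )
}

#' One-row summary of a per-target selection
#'
#' @param x An `hggm_selection`.
#' @param ... Unused.
#' @return A tibble with the score, lambda, cardinality and search effort.
#' @method glance hggm_selection
#' @export
glance.hggm_selection <- function(x, ...) {
  tibble::tibble(
    target = x$target_name,
    method = x$method,
    k = sum(x$Q),
    score = x$score,
    lambda = x$lambda,
    phi = x$phi %||% NA_real_,
    n_evaluated = x$n_evaluated,
    n_unique = x$n_unique
  )
}

#' Plot a causal graph as an adjacency heat map
#'
#' @param object A [causal_graph()].
#' @param ... Unused.
#' @return A ggplot: causes on the x axis, effects on the y axis, filled
#'   cells for directed edges.
#' @method autoplot causal_graph
#' @export
autoplot.causal_graph <- function(object, ...) {
  df <- tidyr::expand_grid(
    effect = rownames(object$adjacency),
    cause = colnames(object$adjacency)
  )
  df$edge <- as.vector(t(object$adjacency))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cause, y = .data$effect,
                                   fill = .data$edge)) +
    ggplot2::geom_tile(colour = "grey70") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "white",
                                          `TRUE` = "grey20"),
                               guide = "none") +
    ggplot2::scale_y_discrete(limits = rev(rownames(object$adjacency))) +
    ggplot2::labs(x = "cause", y = "effect") +
    ggplot2::theme_minimal()
}

#' Plot a benchmark report: mean F-measure against series length
#'
#' @param object An `hggm_benchmark` from [run_benchmark()].
#' @param ... Unused.
#' @return A ggplot of mean F per cell and method, faceted by graph
#'   density and lag.
#' @method autoplot hggm_benchmark
#' @export
autoplot.hggm_benchmark <- function(object, ...) {
  sm <- summary(object)
  sm$config <- paste0("p=", sm$p, ", ", sm$n_edges, " edges, d=", sm$d)
  ggplot2::ggplot(sm, ggplot2::aes(x = .data$n, y = .data$mean_f,
                                   colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~config) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "series length n", y = "mean F-measure",
                  colour = "method") +
    ggplot2::theme_minimal()
}
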