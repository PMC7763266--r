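#' Genetic-algorithm settings
#'
#' @param m Even population size (default 20).
#' @param ng Number of generations (default 10).
#' @return A list of class `ga_control`.
#' @export
ga_control <- function(m = 20L, ng = 10L) {
  m <- as.integer(m); ng <- as.integer(ng)
  stopifnot(m >= 2L, m %% 2L == 0L, ng >= 1L)
  structure(list(m = m, ng = ng), class = "ga_control")
}

# bitstring key and deterministic secondary order for tie-breaking
q_key <- function(Q) paste(as.integer(Q), collapse = "")
q_value <- function(Q) sum(as.integer(Q) * 2^(seq_along(Q) - 1))

# memoised per-target scorer over candidate indicator vectors; the gamma
# dispersion (kappa) is estimated once per target from the marginal fit
make_scorer <- function(panel, target, lag, control) {
  full <- build_lag_design(panel, lag, target)
  family <- hggm_family(full$family)
  phi_fixed <- if (family$name == "gamma") 1 / gamma_shape_ml(full$y) else NULL
  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  score <- function(Q) {
    key <- q_key(Q)
    if (!is.null(cache[[key]])) return(cache[[key]])
    res <- hmml(full, Q, control = control, phi = phi_fixed)
    n_eval <<- n_eval + 1L
    cache[[key]] <- res
    res
  }
  list(score = score, full = full,
       n_unique = function() length(ls(cache)),
       n_eval = function() n_eval,
       cached = function() {
    keys <- ls(cache)
    list(keys = keys,
         totals = vapply(keys, function(k) cache[[k]]$total, numeric(1)))
  })
}

# parsimony tie-break over a set of evaluated candidates:
# among all candidates whose score is within `tol` of the minimum, keep the
# ones with the fewest selected series; among those, the "last in the list"
# when the list is sorted ascending by (score, bitstring value)
select_best_candidate <- function(Qs, scores, tol = 1e-9) {
  stopifnot(length(Qs) == length(scores), length(Qs) > 0)
  finite <- is.finite(scores)
  if (!any(finite)) {
    # every candidate rejected: fall back to the sparsest candidate offered
    ones <- vapply(Qs, sum, numeric(1))
    return(which.min(ones))
  }
  smin <- min(scores[finite])
  cand <- which(finite & scores <= smin + tol)
  ones <- vapply(Qs[cand], sum, numeric(1))
  cand <- cand[ones == min(ones)]
  if (length(cand) == 1L) return(cand)
  ord <- order(scores[cand], vapply(Qs[cand], q_value, numeric(1)))
  cand[ord[length(ord)]]
}

new_selection <- function(Q, res, target, target_name, method, scorer,
                          extra = list()) {
  structure(
    c(list(Q = as.logical(Q), score = res$total, lambda = res$lambda,
           mml = res$score, phi = res$phi, target = target,
           target_name = target_name, method = method,
           n_evaluated = scorer$n_eval(), n_unique = scorer$n_unique()),
      extra),
    class = "hggm_selection"
  )
}

#' @export
print.hggm_selection <- function(x, ...) {
  cat("<hggm_selection> target '", x$target_name, "' (", x$method, "): {",
      paste(which(x$Q), collapse = ", "), "} score ", format(x$score),
      " nats\n", sep = "")
  invisible(x)
}

#' Exhaustive minimum-message-length parent selection for one target
#'
#' Evaluates the lambda-minimised message length of all `2^p` candidate
#' parent sets of one target series and returns the minimiser under the
#' parsimony tie-break: among candidates whose score ties the minimum
#' (within `tie_tol`), the one with the fewest selected series wins, and
#' among those the last in the list sorted ascending by score (with the
#' bitstring value as deterministic secondary key).
#'
#' @param panel A [ts_panel()].
#' @param target Target series index or name.
#' @param lag Positive integer lag.
#' @param control An [hggm_control()].
#' @param max_p Enumeration guard: refuse panels with more than this many
#'   series (use [select_parents_ga()] beyond it).
#' @return An `hggm_selection` with the winning indicator `Q`, its score,
#'   and a tibble `all_scores` of every candidate evaluated.
#' @export
select_parents_exhaustive <- function(panel, target, lag,
                                      control = hggm_control(),
                                      max_p = 20L) {
  stopifnot(inherits(panel, "ts_panel"))
  p <- ncol(panel$values)
  if (p > max_p) {
    stop("exhaustive enumeration over 2^", p, " subsets refused ",
         "(max_p = ", max_p, "); use select_parents_ga()", call. = FALSE)
  }
  scorer <- make_scorer(panel, target, lag, control)
  codes <- 0:(2^p - 1)
  Qs <- lapply(codes, function(code) as.logical(bitwAnd(
    bitwShiftR(code, 0:(p - 1)), 1L)))
  results <- lapply(Qs, scorer$score)
  totals <- vapply(results, `[[`, numeric(1), "total")
  best <- select_best_candidate(Qs, totals, tol = control$tie_tol)
  all_scores <- tibble::tibble(
    Q = vapply(Qs, q_key, character(1)),
    k = vapply(Qs, sum, numeric(1)),
    score = totals,
    lambda = vapply(results, function(r) r$lambda %||% NA_real_, numeric(1))
  )
  new_selection(Qs[[best]], results[[best]], scorer$full$target,
                scorer$full$target_name, "exhaustive", scorer,
                extra = list(all_scores = all_scores))
}

#' Genetic-algorithm minimum-message-length parent selection for one target
#'
#' Minimises the per-target message length over candidate parent sets with
#' a small elitist genetic algorithm. Each generation: (1) the population of
#' `m` indicator bitstrings is scored; (2) the best `m/2` form the elite;
#' (3) consecutive elite pairs are crossed over at a uniformly random cut,
#' giving `m/2` children; (4) one uniformly chosen elite parent is mutated
#' at a uniformly random bit; (5) the next population is the elite plus the
#' best children (the mutant competes as a child) until size `m`. Scores are
#' memoised by bitstring, and the returned candidate is the best bitstring
#' ever evaluated, under the same parsimony tie-break as the exhaustive
#' search. Elitism makes the best-ever score non-increasing across
#' generations.
#'
#' @param panel A [ts_panel()].
#' @param target Target series index or name.
#' @param lag Positive integer lag.
#' @param ga A [ga_control()].
#' @param control An [hggm_control()].
#' @param seed Integer seed for the GA's random draws (population,
#'   crossover cuts, mutation). The RNG state of the session is restored
#'   on exit.
#' @return An `hggm_selection`; `history` traces the best-ever score per
#'   generation.
#' @export
select_parents_ga <- function(panel, target, lag, ga = ga_control(),
                              control = hggm_control(), seed = NULL) {
  stopifnot(inherits(panel, "ts_panel"), inherits(ga, "ga_control"))
  p <- ncol(panel$values)
  scorer <- make_scorer(panel, target, lag, control)

  runner <- function() {
    pop <- lapply(seq_len(ga$m), function(i) stats::runif(p) < 0.5)
    history <- numeric(ga$ng)
    for (g in seq_len(ga$ng)) {
      res <- lapply(pop, scorer$score)
      totals <- vapply(res, `[[`, numeric(1), "total")
      ord <- order(totals, vapply(pop, q_value, numeric(1)))
      elite <- pop[ord[seq_len(ga$m %/% 2L)]]

      children <- list()
      pairs <- seq(1L, length(elite) - 1L, by = 2L)
      for (a in pairs) {
        pa <- elite[[a]]; pb <- elite[[a + 1L]]
        cut <- if (p > 1L) sample.int(p - 1L, 1L) else 1L
        children[[length(children) + 1L]] <- c(pa[seq_len(cut)],
                                               pb[-seq_len(cut)])
        children[[length(children) + 1L]] <- c(pb[seq_len(cut)],
                                               pa[-seq_len(cut)])
      }
      mutant <- elite[[sample.int(length(elite), 1L)]]
      pos <- sample.int(p, 1L)
      mutant[pos] <- !mutant[pos]
      children[[length(children) + 1L]] <- mutant

      cres <- lapply(children, scorer$score)
      ctot <- vapply(cres, `[[`, numeric(1), "total")
      cord <- order(ctot, vapply(children, q_value, numeric(1)))
      need <- ga$m - length(elite)
      pop <- c(elite, children[cord[seq_len(need)]])

      cached <- scorer$cached()
      history[g] <- min(cached$totals)
    }
    history
  }
  history <- if (is.null(seed)) runner() else with_seed_restore(seed, runner)

  cached <- scorer$cached()
  Qs <- lapply(cached$keys, function(k) {
    as.logical(as.integer(strsplit(k, "")[[1]]))
  })
  best <- select_best_candidate(Qs, cached$totals, tol = control$tie_tol)
  res <- scorer$score(Qs[[best]])
  new_selection(Qs[[best]], res, scorer$full$target,
                scorer$full$target_name, "genetic", scorer,
                extra = list(history = history))
}

# run `fn` under a temporary RNG seed, restoring the caller's RNG state
with_seed_restore <- function(seed, fn) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Infer the full Granger-causal graph of a panel
#'
#' Runs the per-target parent search independently for each of the `p`
#' series and assembles the results into a directed causal graph: row `i`
#' of the adjacency matrix is the selected indicator vector of target `i`
#' (entry `(i, j) = 1` means series `j` Granger-causes series `i`;
#' self-loops are allowed). Per-target GA seeds are derived as
#' `seed + target index`, so rows are independent and reproducible. A
#' failing per-target search leaves its row empty and is recorded in
#' `failed`.
#'
#' @param panel A [ts_panel()].
#' @param lag Positive integer lag.
#' @param method `"exhaustive"` (all `2^p` subsets; small `p` only) or
#'   `"genetic"`.
#' @param ga A [ga_control()] (genetic method only).
#' @param control An [hggm_control()].
#' @param seed Master seed for the genetic method.
#' @return An object of class `causal_graph` with the logical `adjacency`
#'   matrix, per-target scores and the list of per-target selections.
#' @examples
#' \donttest{
#' g <- random_causal_graph(4, 6, seed = 1)
#' pan <- simulate_hggm_panel(g, rep("gaussian", 4), n = 150, lag = 2,
#'                            strength = 0.9, seed = 2)
#' fit <- infer_graph(pan, lag = 2, method = "exhaustive")
#' tidy(fit)
#' }
#' @export
infer_graph <- function(panel, lag, method = c("exhaustive", "genetic"),
                        ga = ga_control(), control = hggm_control(),
                        seed = NULL) {
  stopifnot(inherits(panel, "ts_panel"))
  method <- match.arg(method)
  p <- ncol(panel$values)
  if (p < 2L) stop("graph inference needs at least two series", call. = FALSE)

  selections <- vector("list", p)
  adjacency <- matrix(FALSE, p, p, dimnames = list(panel$names, panel$names))
  scores <- rep(NA_real_, p)
  failed <- integer(0)
  for (i in seq_len(p)) {
    sel <- tryCatch(
      if (method == "exhaustive") {
        select_parents_exhaustive(panel, i, lag, control = control)
      } else {
        select_parents_ga(panel, i, lag, ga = ga, control = control,
                          seed = if (is.null(seed)) NULL else seed + i)
      },
      error = function(e) e
    )
    if (inherits(sel, "error")) {
      warning("target ", panel$names[[i]], " failed: ",
              conditionMessage(sel), call. = FALSE)
      failed <- c(failed, i)
      next
    }
    selections[[i]] <- sel
    adjacency[i, ] <- sel$Q
    scores[i] <- sel$score
  }
  causal_graph(adjacency, scores = scores, selections = selections,
               method = method, lag = lag, failed = failed)
}

#' Construct a causal graph object
#'
#' Thin container for a directed graph over the panel's series: a `p x p`
#' logical adjacency matrix where entry `(i, j)` says that series `j` is a
#' (Granger-)cause of series `i`. Used both for ground-truth graphs from the
#' synthetic generator and for inferred graphs, which additionally carry
#' per-target scores.
#'
#' @param adjacency Logical (or 0/1) square matrix.
#' @param scores Optional per-target (row) score vector.
#' @param selections,method,lag,failed Optional inference metadata.
#' @return An object of class `causal_graph`.
#' @export
causal_graph <- function(adjacency, scores = NULL, selections = NULL,
                         method = NULL, lag = NULL, failed = integer(0)) {
  adjacency <- as.matrix(adjacency)
  stopifnot(nrow(adjacency) == ncol(adjacency))
  mode(adjacency) <- "logical"
  if (is.null(dimnames(adjacency))) {
    nms <- paste0("x", seq_len(nrow(adjacency)))
    dimnames(adjacency) <- list(nms, nms)
  }
  structure(
    list(adjacency = adjacency, scores = scores, selections = selections,
         method = method, lag = lag, failed = failed),
    class = "causal_graph"
  )
}

#' @export
print.causal_graph <- function(x, ...) {
  p <- nrow(x$adjacency)
  cat("<causal_graph> ", p, " series, ", sum(x$adjacency), " directed edges",
      if (!is.null(x$method)) paste0(" (", x$method, ", lag ", x$lag, ")"),
      "\n", sep = "")
  invisible(x)
}
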