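#' Draw a uniformly random directed causal graph
#'
#' Samples `n_edges` distinct directed edges (no self-loops) uniformly among
#' the `p * (p - 1)` ordered pairs and returns the corresponding adjacency
#' matrix (row = effect, column = cause).
#'
#' @param p Number of series / nodes.
#' @param n_edges Number of directed edges, `0 <= n_edges <= p*(p-1)`.
#' @param seed Optional integer seed (session RNG state restored).
#' @return A [causal_graph()].
#' @export
random_causal_graph <- function(p, n_edges, seed = NULL) {
  p <- as.integer(p); n_edges <- as.integer(n_edges)
  if (n_edges < 0L || n_edges > p * (p - 1L)) {
    stop("`n_edges` must lie in [0, p*(p-1)] = [0, ", p * (p - 1L), "]",
         call. = FALSE)
  }
  draw <- function() {
    off_diag <- which(diag(p) == 0) # column-major indices of the p(p-1) slots
    picked <- sample(off_diag, n_edges)
    adj <- matrix(FALSE, p, p)
    adj[picked] <- TRUE
    adj
  }
  adj <- if (is.null(seed)) draw() else with_seed_restore(seed, draw)
  causal_graph(adj)
}

# baseline (no-parent) distribution parameters per family: mean and sd used
# both for sampling and for the standardizing squash of regressor values
family_baseline <- function(family) {
  switch(family,
    gaussian = list(mean = 0, sd = 1),
    binomial = list(mean = 0.5, sd = 0.5),
    poisson = list(mean = 1, sd = 1),
    gamma = list(mean = 2, sd = sqrt(2), shape = 2),  # shape 2, scale 1
    inverse_gaussian = list(mean = 1, sd = 1, shape = 1)
  )
}

# inverse-Gaussian sampler (Michael, Schucany & Haas transformation)
rinvgauss <- function(n, mean = 1, shape = 1) {
  nu <- stats::rnorm(n)
  y <- nu^2
  x <- mean + mean^2 * y / (2 * shape) -
    mean / (2 * shape) * sqrt(4 * mean * shape * y + mean^2 * y^2)
  u <- stats::runif(n)
  ifelse(u <= mean / (mean + x), x, mean^2 / x)
}

# draw one observation per series given the aggregate causal signal eta on
# the scale of the family's own linear predictor: identity (gaussian), logit
# (binomial), log (poisson), reciprocal (gamma, eta >= 0) and positive
# identity (inverse-Gaussian, eta >= 0); the baseline (eta = 0) reproduces
# the family_baseline() distribution
draw_family <- function(family, eta) {
  b <- family_baseline(family)
  switch(family,
    gaussian = stats::rnorm(length(eta), mean = eta, sd = 1),
    binomial = stats::rbinom(length(eta), 1L, stats::plogis(eta)),
    poisson = stats::rpois(length(eta), lambda = exp(eta)),
    gamma = {
      mu <- 1 / (1 / b$mean + eta) # reciprocal link, eta >= 0
      stats::rgamma(length(eta), shape = b$shape, scale = mu / b$shape)
    },
    inverse_gaussian = {
      mu <- b$mean + eta # identity link, eta >= 0
      rinvgauss(length(eta), mean = mu, shape = b$shape)
    }
  )
}

# transform of a parent's lagged values feeding the linear predictor of a
# target of family `target_family`. Contributions are kept *proportional*
# to the parent's values (scaled by the baseline sd, never centred or
# curved) wherever the link's domain permits, because only a proportional
# signal is exactly representable by the intercept-free GLM the criterion
# fits -- a transform with g(0) != 0 or a centring constant injects
# structure a through-the-origin regression cannot absorb. Clips act only
# as stability / domain guards:
# * real-line predictors (gaussian, binomial logit targets): u = x / sd,
#   clipped at +/- 6 so feedback loops cannot diverge; exact on the bulk
#   of the range;
# * log predictor (poisson target): centred tanh of the standardized
#   source -- exp(eta) must stay bounded and the counts informative, which
#   rules out a proportional form (its unavoidable mean offset collapses
#   the Poisson mean); the offset of the centred tanh vanishes for
#   symmetric sources and stays small otherwise;
# * positive predictors (gamma reciprocal, inverse-Gaussian identity):
#   the positive part of u, capped at 6 -- exact for positive-valued
#   sources, and the predictor stays nonnegative for any source.
signal_transform <- function(x, source_family, baseline, target_family) {
  u <- x / baseline$sd
  switch(target_family,
    gaussian = pmin(pmax(u, -6), 6),
    binomial = pmin(pmax(u, -6), 6),
    poisson = tanh(u - baseline$mean / baseline$sd),
    pmin(pmax(u, 0), 6) # gamma / inverse_gaussian
  )
}

#' Simulate a mixed-family panel from a causal graph
#'
#' Generates each series forward in time under its family's GLM, with the
#' causal mechanism expressed on the scale of the fitted model's linear
#' predictor — the same regression-through-the-origin GLM class the
#' inference fits. The aggregate causal signal into series `i` at time `t`
#' is `eta_i(t) = sum over parents j, lags l of sign_ji * strength *
#' g(x_j[t - l])`: every lag of a causal connection carries the same
#' coefficient magnitude `strength`, and `g` transforms the parent's values
#' as the target's link requires (see below). A series with parents then
#' follows the intercept-free model exactly — its mean is the link-inverse
#' of the aggregate signal alone: `mu = eta` (gaussian), `plogis(eta)`
#' (binomial), `exp(eta)` (poisson), `mu = 1/eta` (gamma, reciprocal link)
#' and `mu = eta` (inverse-Gaussian), the last two floored at a small
#' positive predictor (0.05) as a domain guard.
#'
#' The transform `g` keeps contributions proportional to the parent's
#' sd-scaled values wherever the link's domain permits, because only a
#' proportional signal is exactly representable by the no-intercept GLM the
#' criterion fits: gaussian and binomial targets receive the values clipped
#' at `+/- 6` (the clip prevents divergence of feedback loops, whose edge
#' signs are additionally randomized; the logit absorbs any real signal);
#' poisson targets receive a centred tanh — `exp(eta)` must stay bounded
#' and the counts informative, which a proportional signal's mean offset
#' would destroy; gamma and inverse-Gaussian targets receive the positive
#' part capped at 6 with positive signs — exact for positive-valued
#' parents, and the reciprocal link is self-damping (large parent values
#' shrink the mean, small ones grow it).
#'
#' Series without parents are baseline noise; the first `d` values of every
#' series are baseline draws. Baselines: gaussian N(0,1); binomial
#' Bernoulli(0.5); poisson mean 1; gamma shape 2, scale 1;
#' inverse-Gaussian mean 1, shape 1.
#'
#' @param graph A [causal_graph()] (row = effect, column = cause).
#' @param families Character vector of `p` family labels.
#' @param n Series length.
#' @param lag Lag `d` of the causal mechanism.
#' @param strength Per-lag coefficient magnitude of a causal connection,
#'   in `(0, 1]`.
#' @param seed Optional integer seed (session RNG state restored).
#' @return A [ts_panel()].
#' @export
simulate_hggm_panel <- function(graph, families, n, lag, strength,
                                seed = NULL) {
  stopifnot(inherits(graph, "causal_graph"))
  p <- nrow(graph$adjacency)
  families <- match_families(families, colnames(graph$adjacency))
  d <- as.integer(lag)
  stopifnot(d >= 1L, n > d, strength > 0, strength <= 1)
  baselines <- lapply(families, family_baseline)
  parents <- lapply(seq_len(p), function(i) which(graph$adjacency[i, ]))

  gen <- function() {
    # edge signs: random for the real-line and log predictors (stability
    # of feedback loops), fixed positive for the positive-domain predictors
    signs <- matrix(sample(c(-1, 1), p * p, replace = TRUE), p, p)
    for (i in seq_len(p)) {
      if (families[[i]] %in% c("gamma", "inverse_gaussian")) signs[i, ] <- 1
    }
    values <- matrix(0, n, p)
    for (i in seq_len(p)) {
      values[seq_len(d), i] <- draw_family(families[[i]], rep(0, d))
    }
    for (t in (d + 1L):n) {
      draws <- numeric(p)
      for (i in seq_len(p)) {
        if (length(parents[[i]]) == 0L) {
          draws[i] <- draw_family(families[[i]], 0)
          next
        }
        eta <- 0
        for (j in parents[[i]]) {
          s <- signal_transform(values[(t - d):(t - 1L), j], families[[j]],
                                baselines[[j]], families[[i]])
          eta <- eta + signs[i, j] * strength * sum(s)
        }
        # caused series follow the intercept-free model exactly: the mean is
        # the link-inverse of the aggregate signal alone (floored at a small
        # positive predictor for the positive-domain links)
        draws[i] <- switch(families[[i]],
          gamma = {
            bl <- baselines[[i]]
            mu <- 1 / max(eta, 0.05)
            stats::rgamma(1L, shape = bl$shape, scale = mu / bl$shape)
          },
          inverse_gaussian = {
            rinvgauss(1L, mean = max(eta, 0.05),
                      shape = baselines[[i]]$shape)
          },
          draw_family(families[[i]], eta)
        )
      }
      values[t, ] <- draws
    }
    colnames(values) <- names(families)
    values
  }
  values <- if (is.null(seed)) gen() else with_seed_restore(seed, gen)
  ts_panel(values, families)
}

#' F-measure between two directed graphs
#'
#' Precision/recall harmonic mean over directed edges, each ordered pair
#' counted once. Conventions: a prediction with no edges against a
#' non-empty truth scores 0; two empty graphs score 1.
#'
#' @param predicted,truth [causal_graph()]s over the same `p` nodes.
#' @return F-measure in `[0, 1]`.
#' @examples
#' a <- causal_graph(matrix(c(0,1,0,0), 2, 2))
#' f_measure(a, a)
#' @export
f_measure <- function(predicted, truth) {
  ap <- predicted$adjacency; at <- truth$adjacency
  stopifnot(all(dim(ap) == dim(at)))
  np <- sum(ap); nt <- sum(at)
  if (np == 0 && nt == 0) return(1)
  if (np == 0 || nt == 0) return(0)
  tp <- sum(ap & at)
  precision <- tp / np
  recall <- tp / nt
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

# baseline predictors the benchmark reports next to the MML searches
baseline_graph <- function(kind, p) {
  switch(kind,
    empty = causal_graph(matrix(FALSE, p, p)),
    random = causal_graph(matrix(stats::runif(p * p) < 0.5, p, p) &
                            diag(p) == 0)
  )
}

#' Benchmark MML Granger inference on random causal graphs
#'
#' For each grid cell, draws `replicates` random graphs, simulates a panel
#' from each with [simulate_hggm_panel()], runs the requested inference
#' methods plus two reference predictors (`empty`: no edges; `random`: each
#' ordered pair included with probability 1/2), and scores every inferred
#' graph against the truth with [f_measure()].
#'
#' @param grid A data frame with one row per experimental cell and columns
#'   `p`, `n_edges`, `strength`, `n`, `d`, and `families` (a list-column of
#'   family-label vectors, or a single comma-separated string per row).
#' @param methods Character subset of `c("exhaustive", "genetic")`.
#' @param replicates Random graph draws per cell.
#' @param ga A [ga_control()].
#' @param control An [hggm_control()].
#' @param seed Master seed; every replicate derives its own sub-seed, so
#'   the full report is reproducible.
#' @param shuffle_families Randomly reassign the family labels to nodes in
#'   every replicate (the mix is kept, the assignment varies).
#' @param baselines Include the reference predictors.
#' @return A tibble of class `hggm_benchmark`: one row per
#'   (cell, replicate, method) with the achieved F-measure. Summarise with
#'   [summary.hggm_benchmark()] or plot with `autoplot()`.
#' @export
run_benchmark <- function(grid, methods = c("exhaustive", "genetic"),
                          replicates = 10L, ga = ga_control(),
                          control = hggm_control(), seed = 1L,
                          shuffle_families = TRUE, baselines = TRUE) {
  grid <- tibble::as_tibble(grid)
  stopifnot(all(c("p", "n_edges", "strength", "n", "d") %in% names(grid)),
            "families" %in% names(grid))
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- list()
  for (cell in seq_len(nrow(grid))) {
    g <- grid[cell, ]
    fams <- g$families[[1]]
    if (length(fams) == 1L && grepl(",", fams)) {
      fams <- trimws(strsplit(fams, ",")[[1]])
    }
    if (length(fams) != g$p) stop("cell ", cell, ": need ", g$p,
                                  " family labels", call. = FALSE)
    for (r in seq_len(replicates)) {
      rep_seed <- (seed + 7919L * cell + r) %% .Machine$integer.max
      truth <- random_causal_graph(g$p, g$n_edges, seed = rep_seed)
      fams_r <- if (shuffle_families) {
        with_seed_restore(rep_seed + 1L, function() sample(fams))
      } else fams
      panel <- simulate_hggm_panel(truth, fams_r, n = g$n, lag = g$d,
                                   strength = g$strength,
                                   seed = rep_seed + 2L)
      fits <- list()
      for (mth in methods) {
        fit <- tryCatch(
          infer_graph(panel, lag = g$d, method = mth, ga = ga,
                      control = control, seed = rep_seed + 3L),
          error = function(e) e
        )
        fits[[mth]] <- fit
      }
      if (baselines) {
        fits$empty <- baseline_graph("empty", g$p)
        fits$random <- with_seed_restore(rep_seed + 4L, function() {
          baseline_graph("random", g$p)
        })
      }
      for (mth in names(fits)) {
        ok <- !inherits(fits[[mth]], "error")
        rows[[length(rows) + 1L]] <- tibble::tibble(
          cell = cell, p = g$p, n_edges = g$n_edges,
          strength = g$strength, n = g$n, d = g$d,
          replicate = r, method = mth,
          f = if (ok) f_measure(fits[[mth]], truth) else NA_real_,
          failed = !ok
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("hggm_benchmark", class(out))
  out
}

#' Summarise a benchmark report to one row per cell and method
#'
#' @param object An `hggm_benchmark` tibble from [run_benchmark()].
#' @param ... Unused.
#' @return Tibble with the mean F-measure, its spread, and the number of
#'   failed replicates per (cell, method).
#' @export
summary.hggm_benchmark <- function(object, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(object),
                    .data$cell, .data$p, .data$n_edges, .data$strength,
                    .data$n, .data$d, .data$method),
    mean_f = mean(.data$f, na.rm = TRUE),
    sd_f = stats::sd(.data$f, na.rm = TRUE),
    n_failed = sum(.data$failed),
    n_rep = dplyr::n(),
    .groups = "drop"
  )
}
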