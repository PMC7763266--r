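#' Structure code of a candidate parent set
#'
#' Message-length cost (in nats) of stating which `k` of the `p` candidate
#' series are selected: `log C(p, k) + log(p + 1)` — first encode the
#' cardinality uniformly over `0..p`, then the subset uniformly among the
#' `C(p, k)` subsets of that size.
#'
#' @param p Number of candidate series.
#' @param k Number of selected series, `0 <= k <= p`.
#' @return Code length in nats.
#' @examples
#' structure_code(5, 0) # log 6
#' structure_code(5, 2) # log 10 + log 6
#' @export
structure_code <- function(p, k) {
  stopifnot(k >= 0, k <= p)
  lchoose(p, k) + log(p + 1)
}

#' Control settings for the MML criterion and lambda search
#'
#' @param lambda_lower,lambda_upper Bounds of the search interval `H` for the
#'   ridge hyperparameter `lambda` (defaults `[0.1, 1000]`).
#' @param grid_points Number of log-spaced points of the coarse pre-scan
#'   used to initialise the simplex search.
#' @param reltol Convergence tolerance of the Nelder-Mead search on
#'   `log(lambda)`.
#' @param k_convention How the parameter count `k` in the
#'   `(k/2) log(2 pi lambda)` and constant terms of the code is taken:
#'   `"series"` counts the selected series (as printed in the criterion),
#'   `"coefficients"` counts all `d * k` regression coefficients.
#' @param robust Use the sandwich (squared-residual) binomial weights.
#' @param poisson_phi_tol Band around dispersion 1 inside which plain
#'   poisson weights are used.
#' @param irls_tol,irls_maxit IRLS convergence settings.
#' @param tie_tol Score-equality tolerance (nats) for the parsimony
#'   tie-break of the subset searches.
#' @return A list of class `hggm_control`.
#' @export
hggm_control <- function(lambda_lower = 0.1, lambda_upper = 1000,
                         grid_points = 13L, reltol = 1e-8,
                         k_convention = c("series", "coefficients"),
                         robust = FALSE, poisson_phi_tol = 0.1,
                         irls_tol = 1e-8, irls_maxit = 100L,
                         tie_tol = 1e-9) {
  stopifnot(lambda_lower > 0, lambda_upper > lambda_lower)
  structure(
    list(lambda_lower = lambda_lower, lambda_upper = lambda_upper,
         grid_points = as.integer(grid_points), reltol = reltol,
         k_convention = match.arg(k_convention),
         robust = isTRUE(robust), poisson_phi_tol = poisson_phi_tol,
         irls_tol = irls_tol, irls_maxit = as.integer(irls_maxit),
         tie_tol = tie_tol),
    class = "hggm_control"
  )
}

mml_k <- function(design, control) {
  k <- length(design$selected)
  if (control$k_convention == "coefficients") k <- k * design$d
  k
}

#' MML87 message length of one candidate at a fixed lambda
#'
#' Assembles the six-term message length of a candidate parent set for one
#' target series: negative log-likelihood, half log-determinant of the
#' ridge-corrected Fisher information `X' W X + lambda I`, the prior terms
#' `(k/2) log(2 pi lambda) + (lambda / 2 phi) * ||beta||^2`, the constant
#' terms `(1/2) log(n - d) - ((k+1)/2) log(2 pi) + (1/2) log((k+1) pi)`, and
#' the structure code of the subset. `total` is the exact sum of the parts.
#' All lengths are in nats.
#'
#' For the empty candidate (`k = 0`) the Fisher, prior and lambda terms
#' vanish and the likelihood is evaluated at the family's null mean.
#' A likelihood sentinel of `-Inf` (domain failure) yields `total = Inf`,
#' i.e. the candidate is rejected.
#'
#' @param design A `lag_design` restricted to the candidate (see
#'   [subset_design()]).
#' @param fit An `hggm_fit` for that design.
#' @param family An [hggm_family()] for the target.
#' @param lambda Positive ridge hyperparameter.
#' @param phi Dispersion estimate for the target.
#' @param control An [hggm_control()].
#' @return An object of class `mml_score`: list of the named parts and
#'   `total`.
#' @export
mml_code <- function(design, fit, family, lambda, phi,
                     control = hggm_control()) {
  stopifnot(inherits(design, "lag_design"), lambda > 0, phi > 0)
  m <- length(design$y)
  k <- mml_k(design, control)
  str_code <- structure_code(design$p, length(design$selected))

  if (ncol(design$X) == 0L) {
    L <- null_log_likelihood(family, design$y, phi)
    parts <- list(
      neg_log_lik = -L,
      fisher_logdet = 0,
      prior_terms = 0,
      constant_terms = 0.5 * log(m) - 0.5 * log(2 * pi) + 0.5 * log(pi),
      structure_code = str_code,
      lambda = lambda
    )
    parts$total <- parts$neg_log_lik + parts$fisher_logdet +
      parts$prior_terms + parts$constant_terms + parts$structure_code
    return(structure(parts, class = "mml_score"))
  }

  L <- glm_log_likelihood(family, design$y, fit$eta, phi)
  w <- glm_weights(family, design$y, fit$eta, phi,
                   robust = control$robust,
                   poisson_phi_tol = control$poisson_phi_tol)
  if (!is.finite(L) || is.null(w)) {
    parts <- list(neg_log_lik = Inf, fisher_logdet = NA_real_,
                  prior_terms = NA_real_, constant_terms = NA_real_,
                  structure_code = str_code, lambda = lambda, total = Inf)
    return(structure(parts, class = "mml_score"))
  }
  A <- crossprod(design$X * sqrt(w)) + diag(lambda, ncol(design$X))
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) {
    parts <- list(neg_log_lik = -L, fisher_logdet = Inf,
                  prior_terms = NA_real_, constant_terms = NA_real_,
                  structure_code = str_code, lambda = lambda, total = Inf)
    return(structure(parts, class = "mml_score"))
  }
  fisher_logdet <- sum(log(diag(ch))) # = 1/2 log det(A)
  prior_terms <- k / 2 * log(2 * pi * lambda) +
    lambda / (2 * phi) * sum(fit$beta^2)
  constant_terms <- 0.5 * log(m) - (k + 1) / 2 * log(2 * pi) +
    0.5 * log((k + 1) * pi)
  parts <- list(
    neg_log_lik = -L,
    fisher_logdet = fisher_logdet,
    prior_terms = prior_terms,
    constant_terms = constant_terms,
    structure_code = str_code,
    lambda = lambda
  )
  parts$total <- parts$neg_log_lik + parts$fisher_logdet +
    parts$prior_terms + parts$constant_terms + parts$structure_code
  structure(parts, class = "mml_score")
}

#' @export
print.mml_score <- function(x, ...) {
  cat("<mml_score> total = ", format(x$total), " nats (lambda = ",
      format(x$lambda), ")\n", sep = "")
  invisible(x)
}

#' Lambda-minimised message length of a candidate parent set
#'
#' Computes the HMML score of one candidate: the initial maximum-likelihood
#' coefficients and the dispersion are estimated once for the candidate, the
#' weight matrix and likelihood are held fixed, and the message length is
#' minimised over the ridge hyperparameter `lambda` in `H` (default
#' `[0.1, 1000]`) by a coarse log-spaced grid scan followed by Nelder-Mead
#' on `log(lambda)` clamped to `H`. The structure code of the subset is part
#' of the returned total.
#'
#' Because the likelihood and Fisher weights are fixed during the lambda
#' search, the log-determinant is evaluated through a single symmetric
#' eigendecomposition of `X' W X`, so each lambda evaluation costs only the
#' sum `1/2 * sum(log(e_j + lambda))`.
#'
#' @param design_full Full `lag_design` over all `p` series for the target.
#' @param Q Logical candidate-indicator vector of length `p`.
#' @param control An [hggm_control()].
#' @param phi Optional fixed dispersion (e.g. the once-per-target gamma
#'   `kappa`); estimated from the candidate fit when `NULL`.
#' @return List with elements `total`, `lambda`, `score` (the `mml_score`
#'   at the optimum), `fit` and `phi`.
#' @export
hmml <- function(design_full, Q, control = hggm_control(), phi = NULL) {
  stopifnot(inherits(design_full, "lag_design"))
  family <- hggm_family(design_full$family)
  design <- subset_design(design_full, Q)
  y <- design$y
  m <- length(y)

  if (ncol(design$X) == 0L) {
    if (is.null(phi)) {
      nullfit <- structure(list(beta = numeric(0),
                                mu = rep(null_mean(family, y), m)),
                           class = "hggm_fit")
      phi <- estimate_dispersion(family, y, nullfit)
    }
    sc <- mml_code(design, NULL, family, control$lambda_lower, phi, control)
    return(list(total = sc$total, lambda = sc$lambda, score = sc,
                fit = NULL, phi = phi))
  }

  fit <- fit_glm_irls(design$X, y, family,
                      tol = control$irls_tol, maxit = control$irls_maxit)
  if (is.null(phi)) phi <- estimate_dispersion(family, y, fit)

  L <- glm_log_likelihood(family, y, fit$eta, phi)
  w <- glm_weights(family, y, fit$eta, phi, robust = control$robust,
                   poisson_phi_tol = control$poisson_phi_tol)
  if (!is.finite(L) || is.null(w)) {
    sc <- mml_code(design, fit, family, control$lambda_lower, phi, control)
    return(list(total = Inf, lambda = NA_real_, score = sc,
                fit = fit, phi = phi))
  }

  ev <- eigen(crossprod(design$X * sqrt(w)), symmetric = TRUE,
              only.values = TRUE)$values
  ev <- pmax(ev, 0) # X'WX is PSD; clip tiny negative round-off
  k <- mml_k(design, control)
  bb <- sum(fit$beta^2)
  const <- -L + 0.5 * log(m) - (k + 1) / 2 * log(2 * pi) +
    0.5 * log((k + 1) * pi) + structure_code(design$p, length(design$selected))

  obj <- function(loglam) {
    loglam <- min(max(loglam, log(control$lambda_lower)),
                  log(control$lambda_upper))
    lam <- exp(loglam)
    0.5 * sum(log(ev + lam)) + k / 2 * log(2 * pi * lam) +
      lam / (2 * phi) * bb + const
  }

  grid <- exp(seq(log(control$lambda_lower), log(control$lambda_upper),
                  length.out = control$grid_points))
  gvals <- vapply(log(grid), obj, numeric(1))
  start <- log(grid[which.min(gvals)])
  opt <- suppressWarnings(
    stats::optim(start, obj, method = "Nelder-Mead",
                 control = list(reltol = control$reltol, maxit = 200L))
  )
  loglam <- min(max(opt$par, log(control$lambda_lower)),
                log(control$lambda_upper))
  best <- if (opt$value <= min(gvals)) exp(loglam) else grid[which.min(gvals)]

  sc <- mml_code(design, fit, family, best, phi, control)
  list(total = sc$total, lambda = best, score = sc, fit = fit, phi = phi)
}
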