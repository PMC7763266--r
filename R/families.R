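#' Exponential-family specification for heterogeneous Granger regression
#'
#' Returns the family object used to fit and score one target series. Each
#' family fixes the link between the linear predictor `eta = X beta` and the
#' conditional mean, the log-likelihood (with all constant terms), the
#' diagonal weight matrix entering the Fisher-information block of the MML
#' code, and the dispersion convention:
#'
#' * `gaussian` — identity link, dispersion `phi = sigma^2` (mean squared
#'   residual), unit weights.
#' * `binomial` — logit link, `phi = 1`, weights `exp(eta)/(1+exp(eta))^2`.
#' * `poisson` — log link, Pearson dispersion, weights `exp(eta)` when the
#'   dispersion is close to 1 and the squared residual `(y - exp(eta))^2`
#'   otherwise.
#' * `gamma` — reciprocal mean `mu = 1/eta` (the linear predictor must stay
#'   strictly positive), dispersion `kappa` = 1/shape from a marginal
#'   maximum-likelihood gamma fit of the target, weights `mu^2`.
#' * `inverse_gaussian` — identity mean `mu = eta` (again positive),
#'   dispersion `xi` = mean of `(y - mu)^2 / (mu^2 y)`, weights `1/mu`.
#'
#' For the gamma and inverse-Gaussian families a candidate whose fitted
#' linear predictor leaves the positive domain receives a `-Inf`
#' log-likelihood sentinel, which the subset search treats as "reject this
#' candidate".
#'
#' @param name Family label.
#' @return An object of class `hggm_family`.
#' @export
hggm_family <- function(name = c("gaussian", "binomial", "poisson",
                                 "gamma", "inverse_gaussian")) {
  name <- match.arg(name)
  base <- switch(name,
    gaussian = stats::gaussian(),
    binomial = stats::binomial(),
    poisson = stats::poisson(),
    gamma = stats::Gamma(link = "inverse"),
    inverse_gaussian = stats::inverse.gaussian(link = "identity")
  )
  structure(list(name = name, base = base), class = "hggm_family")
}

#' @export
print.hggm_family <- function(x, ...) {
  cat("<hggm_family> ", x$name, " (link: ", x$base$link, ")\n", sep = "")
  invisible(x)
}

family_mean <- function(family, eta) {
  switch(family$name,
    gaussian = eta,
    binomial = stats::plogis(eta),
    poisson = exp(eta),
    gamma = 1 / eta,
    inverse_gaussian = eta
  )
}

# linear-predictor domain: gamma (mu = 1/eta) and inverse-Gaussian (mu = eta)
# require eta > 0 everywhere
eta_in_domain <- function(family, eta) {
  if (family$name %in% c("gamma", "inverse_gaussian")) {
    all(is.finite(eta)) && all(eta > 0)
  } else {
    all(is.finite(eta))
  }
}

# mean used by the empty (k = 0) candidate: the zero-linear-predictor mean
# where that lies in the family's domain, otherwise the sample mean
null_mean <- function(family, y) {
  switch(family$name,
    gaussian = 0,
    binomial = 0.5,
    poisson = 1,
    gamma = mean(y),
    inverse_gaussian = mean(y)
  )
}

#' Exact GLM log-likelihood of a target series
#'
#' Evaluates the full log-likelihood (all constants included: normalising
#' terms, log-factorials, log-Gamma) of the target observations under the
#' family's density at linear predictor `eta = X beta` and dispersion `phi`.
#' Returns `-Inf` when the linear predictor leaves the family's mean domain
#' (gamma and inverse-Gaussian require a strictly positive predictor).
#'
#' @param family An [hggm_family()].
#' @param y Response vector (observations `d+1 ... n` of the target).
#' @param eta Linear predictor vector, same length as `y`.
#' @param phi Dispersion (`sigma^2`, `1`, Pearson `phi`, `kappa` or `xi`).
#' @return The scalar log-likelihood in nats.
#' @export
glm_log_likelihood <- function(family, y, eta, phi = 1) {
  stopifnot(inherits(family, "hggm_family"))
  if (length(eta) == 1L) eta <- rep(eta, length(y))
  stopifnot(length(eta) == length(y), phi > 0)
  if (!eta_in_domain(family, eta)) return(-Inf)
  m <- length(y)
  switch(family$name,
    gaussian = {
      -m / 2 * log(2 * pi * phi) - sum((y - eta)^2) / (2 * phi)
    },
    binomial = {
      # y*eta - log(1 + exp(eta)), computed stably
      sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
    },
    poisson = {
      sum(y * eta - exp(eta) - lgamma(y + 1))
    },
    gamma = {
      # shape a = 1/kappa, scale kappa * mu, mu = 1/eta
      a <- 1 / phi
      mu <- 1 / eta
      sum((a - 1) * log(y) - y / (phi * mu) - a * log(phi * mu) - lgamma(a))
    },
    inverse_gaussian = {
      mu <- eta
      sum(-0.5 * log(2 * pi * phi * y^3) - (y - mu)^2 / (2 * phi * mu^2 * y))
    }
  )
}

# log-likelihood at the null (k = 0) mean, used by the empty candidate set
null_log_likelihood <- function(family, y, phi) {
  mu0 <- null_mean(family, y)
  eta0 <- switch(family$name,
    gaussian = mu0,
    binomial = stats::qlogis(mu0),
    poisson = log(mu0),
    gamma = 1 / mu0,
    inverse_gaussian = mu0
  )
  glm_log_likelihood(family, y, rep(eta0, length(y)), phi)
}

#' Diagonal GLM weight matrix
#'
#' Returns the diagonal of the weight matrix `W` entering the
#' Fisher-information block `X' W X` of the MML code, evaluated at the fitted
#' linear predictor. The non-robust forms are: unit weights (gaussian),
#' `exp(eta)/(1+exp(eta))^2` (binomial), `exp(eta)` (poisson), `mu^2 = 1/eta^2`
#' (gamma) and `1/mu = 1/eta` (inverse-Gaussian). The robust / overdispersed
#' variants replace the binomial and poisson entries with squared residuals;
#' for the poisson family the robust form is selected automatically when the
#' estimated dispersion is far from 1 (see `control` in [hggm_control()]).
#'
#' @param family An [hggm_family()].
#' @param y Response vector.
#' @param eta Linear predictor vector.
#' @param phi Dispersion estimate (drives the poisson switch).
#' @param robust Force the robust (sandwich) variant for the binomial family.
#' @param poisson_phi_tol Half-width of the band around `phi = 1` inside
#'   which the plain poisson weights are used.
#' @return Numeric vector of diagonal weights, or `NULL` when the linear
#'   predictor leaves the family's domain (sentinel propagation).
#' @export
glm_weights <- function(family, y, eta, phi = 1, robust = FALSE,
                        poisson_phi_tol = 0.1) {
  stopifnot(inherits(family, "hggm_family"))
  if (!eta_in_domain(family, eta)) return(NULL)
  switch(family$name,
    gaussian = rep(1, length(eta)),
    binomial = {
      if (robust) {
        (y - stats::plogis(eta))^2
      } else {
        e <- exp(-abs(eta))
        e / (1 + e)^2 # = exp(eta)/(1+exp(eta))^2, symmetric in the sign
      }
    },
    poisson = {
      if (abs(phi - 1) > poisson_phi_tol) {
        (y - exp(eta))^2
      } else {
        exp(eta)
      }
    },
    gamma = 1 / eta^2,
    inverse_gaussian = 1 / eta
  )
}

#' Fit an intercept-free GLM by iteratively reweighted least squares
#'
#' Maximum-likelihood initial estimates of the regression coefficients for
#' one candidate design, obtained with `stats::glm.fit` (IRLS) under the
#' family's link and no intercept. Degenerate designs (aliased columns,
#' separation, domain failures of the gamma / inverse-Gaussian links) fall
#' back to a ridge-jittered linearised solve and are flagged as
#' non-converged; the subset search still scores such candidates, and the
#' likelihood sentinel rejects them when the fitted predictor is invalid.
#'
#' @param X Design matrix (no intercept column; may have zero columns).
#' @param y Response vector.
#' @param family An [hggm_family()].
#' @param tol IRLS convergence tolerance (relative deviance change).
#' @param maxit Maximum IRLS iterations.
#' @return An object of class `hggm_fit`: list with `beta`, `eta`, `mu`,
#'   `converged`, `iterations`.
#' @export
fit_glm_irls <- function(X, y, family, tol = 1e-8, maxit = 100L) {
  stopifnot(inherits(family, "hggm_family"))
  if (is.null(dim(X))) X <- matrix(X, ncol = 1L)
  if (ncol(X) == 0L) {
    return(structure(
      list(beta = numeric(0), eta = rep(0, length(y)),
           mu = rep(null_mean(family, y), length(y)),
           converged = TRUE, iterations = 0L),
      class = "hggm_fit"
    ))
  }
  res <- tryCatch(
    suppressWarnings(
      stats::glm.fit(X, y, family = family$base, intercept = FALSE,
                     control = stats::glm.control(epsilon = tol, maxit = maxit))
    ),
    error = function(e) NULL
  )
  if (!is.null(res) && all(is.finite(res$coefficients) | is.na(res$coefficients))) {
    beta <- res$coefficients
    beta[is.na(beta)] <- 0 # aliased columns carry no signal
    eta <- drop(X %*% beta)
    mu <- family_mean(family, eta)
    converged <- isTRUE(res$converged) && !anyNA(res$coefficients)
    # separation: the deviance plateaus while the fitted probabilities pin
    # to the boundary -- flag the fit, selection proceeds with the iterate
    if (family$name == "binomial" && any(mu < 1e-10 | mu > 1 - 1e-10)) {
      converged <- FALSE
    }
    return(structure(
      list(beta = unname(beta), eta = eta, mu = mu,
           converged = converged, iterations = res$iter),
      class = "hggm_fit"
    ))
  }
  # ridge-jittered linearised fallback: regress the link-transformed
  # (domain-adjusted) response on X with a small ridge
  mustart <- switch(family$name,
    gaussian = y,
    binomial = (y + 0.5) / 2,
    poisson = y + 0.1,
    gamma = pmax(y, min(y[y > 0], 1e-3)),
    inverse_gaussian = pmax(y, min(y[y > 0], 1e-3))
  )
  z <- switch(family$name,
    gaussian = mustart,
    binomial = stats::qlogis(mustart),
    poisson = log(mustart),
    gamma = 1 / mustart,
    inverse_gaussian = mustart
  )
  A <- crossprod(X) + diag(1e-6, ncol(X))
  beta <- drop(solve(A, crossprod(X, z)))
  eta <- drop(X %*% beta)
  structure(
    list(beta = unname(beta), eta = eta, mu = family_mean(family, eta),
         converged = FALSE, iterations = maxit),
    class = "hggm_fit"
  )
}

#' @export
print.hggm_fit <- function(x, ...) {
  cat("<hggm_fit> ", length(x$beta), " coefficients, ",
      if (x$converged) "converged" else "NOT converged",
      " (", x$iterations, " iterations)\n", sep = "")
  invisible(x)
}

#' Estimate the dispersion parameter of a fitted target
#'
#' Family conventions: mean squared residual for gaussian (`phi = sigma^2`),
#' fixed `1` for binomial, Pearson chi-square over residual degrees of
#' freedom for poisson, `kappa = 1/shape` from a marginal maximum-likelihood
#' gamma fit of the target series for gamma (estimated once per target, not
#' per candidate), and the mean of `(y - mu)^2 / (mu^2 y)` for
#' inverse-Gaussian. Non-positive estimates are floored at a small epsilon.
#'
#' @param family An [hggm_family()].
#' @param y Response vector.
#' @param fit An `hggm_fit` for the candidate design (ignored by the
#'   binomial and gamma rules).
#' @param eps Positive floor.
#' @return Positive scalar dispersion estimate.
#' @export
estimate_dispersion <- function(family, y, fit = NULL, eps = 1e-8) {
  stopifnot(inherits(family, "hggm_family"))
  phi <- switch(family$name,
    gaussian = mean((y - fit$mu)^2),
    binomial = 1,
    poisson = {
      k <- length(fit$beta)
      df <- max(length(y) - k, 1L)
      sum((y - fit$mu)^2 / pmax(fit$mu, eps)) / df
    },
    gamma = 1 / gamma_shape_ml(y),
    inverse_gaussian = {
      mu <- fit$mu
      if (!all(is.finite(mu)) || any(mu <= 0)) return(eps)
      mean((y - mu)^2 / (mu^2 * y))
    }
  )
  if (!is.finite(phi) || phi <= eps) phi <- eps
  phi
}

# marginal ML gamma shape (gamfit analogue), via MASS::fitdistr with a
# moment-based fallback for degenerate samples
gamma_shape_ml <- function(y) {
  stopifnot(all(y > 0))
  est <- tryCatch(
    suppressWarnings(MASS::fitdistr(y, "gamma"))$estimate[["shape"]],
    error = function(e) NA_real_
  )
  if (!is.finite(est) || est <= 0) {
    est <- mean(y)^2 / max(stats::var(y), 1e-12)
  }
  est
}
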