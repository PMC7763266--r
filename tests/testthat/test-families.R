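# independent pointwise log-density oracle: log of the per-observation
# density evaluated with stats::d* functions (hand-coded for the
# inverse-Gaussian, which base R does not ship)
oracle_loglik <- function(family, y, eta, phi) {
  dens <- switch(family,
    gaussian = stats::dnorm(y, mean = eta, sd = sqrt(phi)),
    binomial = stats::dbinom(y, 1, stats::plogis(eta)),
    poisson = stats::dpois(y, exp(eta)),
    gamma = stats::dgamma(y, shape = 1 / phi, scale = phi / eta),
    inverse_gaussian = {
      mu <- eta
      (2 * pi * phi * y^3)^(-1 / 2) * exp(-(y - mu)^2 / (2 * phi * mu^2 * y))
    }
  )
  sum(log(dens))
}

random_eta <- function(family, m) {
  switch(family,
    gamma = runif(m, 0.2, 2),
    inverse_gaussian = runif(m, 0.3, 3),
    runif(m, -1.5, 1.5)
  )
}

random_response <- function(family, m) {
  switch(family,
    gaussian = rnorm(m),
    binomial = rbinom(m, 1, 0.5),
    poisson = rpois(m, 1.5),
    gamma = rgamma(m, shape = 2, scale = 1),
    inverse_gaussian = mmlgranger:::rinvgauss(m, 1, 1)
  )
}

test_that("log-likelihood equals the pointwise density-product oracle", {
  withr::with_seed(42, {
    for (family in all_families) {
      fam <- hggm_family(family)
      for (rep in 1:20) {
        m <- sample(10:40, 1)
        y <- random_response(family, m)
        eta <- random_eta(family, m)
        phi <- if (family == "binomial") 1 else runif(1, 0.4, 2)
        expect_equal(glm_log_likelihood(fam, y, eta, phi),
                     oracle_loglik(family, y, eta, phi),
                     tolerance = 1e-10)
      }
    }
  })
})

test_that("hand-evaluated likelihood identities hold", {
  # standard normal at zero, two observations
  gau <- hggm_family("gaussian")
  expect_equal(glm_log_likelihood(gau, c(0, 0), c(0, 0), 1), -log(2 * pi))
  # poisson with zero linear predictor: sum(y*0 - 1 - log(y!))
  poi <- hggm_family("poisson")
  expect_equal(glm_log_likelihood(poi, c(1, 2), c(0, 0), 1), -2 - log(2))
})

test_that("domain violations yield the -Inf sentinel", {
  gam <- hggm_family("gamma")
  expect_identical(glm_log_likelihood(gam, c(1, 2), c(0.5, -0.1), 0.5), -Inf)
  ig <- hggm_family("inverse_gaussian")
  expect_identical(glm_log_likelihood(ig, c(1, 2), c(0.5, 0), 1), -Inf)
  expect_null(glm_weights(gam, c(1, 2), c(0.5, -0.1)))
})

test_that("weight matrices match their printed diagonal forms", {
  m <- 7
  withr::with_seed(9, {
    eta <- rnorm(m)
    y <- rnorm(m)
    expect_equal(glm_weights(hggm_family("gaussian"), y, eta), rep(1, m))

    bin <- hggm_family("binomial")
    expect_equal(glm_weights(bin, y, eta),
                 exp(eta) / (1 + exp(eta))^2)
    expect_equal(glm_weights(bin, rep(0, m), rep(0, m))[1], 0.25)

    poi <- hggm_family("poisson")
    expect_equal(glm_weights(poi, y, eta, phi = 1), exp(eta))
    # overdispersed switch: squared residuals, zero at an exact fit
    yy <- exp(eta)
    expect_equal(glm_weights(poi, yy, eta, phi = 2), rep(0, m))

    eta_pos <- runif(m, 0.2, 2)
    expect_equal(glm_weights(hggm_family("gamma"), y, eta_pos), 1 / eta_pos^2)
    expect_equal(glm_weights(hggm_family("inverse_gaussian"), y, eta_pos),
                 1 / eta_pos)
  })
})

test_that("gaussian IRLS equals ordinary least squares", {
  pan <- white_noise_panel(p = 2, n = 100, seed = 11)
  des <- build_lag_design(pan, lag = 2, target = 1)
  fit <- fit_glm_irls(des$X, des$y, hggm_family("gaussian"))
  ols <- stats::lm.fit(des$X, des$y)
  expect_equal(fit$beta, unname(ols$coefficients), tolerance = 1e-10)
  expect_true(fit$converged)
})

test_that("poisson IRLS recovers a planted coefficient", {
  withr::with_seed(21, {
    x <- runif(500, 0.5, 1.5)
    b <- 0.8
    y <- rpois(500, exp(b * x))
    fit <- fit_glm_irls(matrix(x, ncol = 1), y, hggm_family("poisson"))
    expect_true(fit$converged)
    expect_equal(fit$beta, b, tolerance = 0.1)
  })
})

test_that("separable binomial data yield a flagged but finite fit", {
  x <- c(-2, -1.5, -1, 1, 1.5, 2)
  y <- c(0, 0, 0, 1, 1, 1)
  fit <- fit_glm_irls(matrix(x, ncol = 1), y, hggm_family("binomial"))
  expect_false(fit$converged)
  expect_true(all(is.finite(fit$beta)))
})

test_that("the IRLS fixed point satisfies the score equations", {
  for (family in c("gaussian", "binomial", "poisson", "gamma")) {
    pan <- random_family_panel(family, n = 120, p = 2, seed = 31)
    des <- build_lag_design(pan, lag = 2, target = 1)
    fam <- hggm_family(family)
    fit <- fit_glm_irls(des$X, des$y, fam)
    if (!fit$converged) next
    # score: X' (y - mu) * dmu/deta / V(mu) = 0 at the MLE
    base <- fam$base
    mu <- fit$mu
    score <- crossprod(des$X, (des$y - mu) * base$mu.eta(fit$eta) /
                                base$variance(mu))
    expect_lt(max(abs(score)) / length(des$y), 1e-4)
  }
})

test_that("the fitted coefficients locally maximise the likelihood", {
  withr::with_seed(17, {
    for (family in c("gaussian", "poisson", "gamma")) {
      pan <- random_family_panel(family, n = 150, p = 2, seed = 17)
      des <- build_lag_design(pan, lag = 1, target = 1)
      fam <- hggm_family(family)
      fit <- fit_glm_irls(des$X, des$y, fam)
      if (!fit$converged) next
      phi <- estimate_dispersion(fam, des$y, fit)
      L0 <- glm_log_likelihood(fam, des$y, fit$eta, phi)
      for (k in 1:12) {
        delta <- rnorm(length(fit$beta))
        delta <- delta / sqrt(sum(delta^2)) * runif(1, 0.01, 0.1)
        eta1 <- drop(des$X %*% (fit$beta + delta))
        L1 <- glm_log_likelihood(fam, des$y, eta1, phi)
        expect_lte(L1, L0 + 1e-8)
      }
    }
  })
})

test_that("dispersion estimates follow the family conventions", {
  fam_b <- hggm_family("binomial")
  expect_identical(estimate_dispersion(fam_b, c(0, 1, 1)), 1)

  # perfect gaussian fit is floored at a small positive value
  fam_g <- hggm_family("gaussian")
  fit0 <- structure(list(beta = 1, mu = c(1, 2, 3)), class = "hggm_fit")
  expect_gt(estimate_dispersion(fam_g, c(1, 2, 3), fit0), 0)
  expect_lt(estimate_dispersion(fam_g, c(1, 2, 3), fit0), 1e-6)

  # poisson Pearson dispersion near 1 for equidispersed data
  withr::with_seed(5, {
    x <- runif(1000, 0.5, 1.5)
    y <- rpois(1000, exp(0.5 * x))
    fam_p <- hggm_family("poisson")
    fit <- fit_glm_irls(matrix(x, ncol = 1), y, fam_p)
    phi <- estimate_dispersion(fam_p, y, fit)
    expect_gt(phi, 0.8)
    expect_lt(phi, 1.2)
  })

  # gamma dispersion is 1/shape of a marginal ML fit
  withr::with_seed(6, {
    y <- rgamma(2000, shape = 2, scale = 1)
    fam <- hggm_family("gamma")
    phi <- estimate_dispersion(fam, y)
    expect_equal(phi, 0.5, tolerance = 0.1)
  })
})
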