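test_that("structure code evaluates the subset-coding formula", {
  expect_equal(structure_code(5, 0), log(6))
  expect_equal(structure_code(5, 2), log(10) + log(6))
  # binomial-coefficient symmetry
  for (p in 2:8) for (k in 0:p) {
    expect_equal(structure_code(p, k), structure_code(p, p - k))
  }
})

test_that("empty-candidate code reduces to its closed form", {
  pan <- white_noise_panel(p = 3, n = 60, seed = 2)
  full <- build_lag_design(pan, lag = 2, target = 1)
  res <- hmml(full, rep(FALSE, 3))
  m <- length(full$y)
  fam <- hggm_family("gaussian")
  phi <- mean(full$y^2) # residuals about the gaussian null mean 0
  L0 <- glm_log_likelihood(fam, full$y, rep(0, m), phi)
  expect_equal(res$total,
               -L0 + 0.5 * log(m) - 0.5 * log(2 * pi) + 0.5 * log(pi) +
                 structure_code(3, 0),
               tolerance = 1e-10)
  expect_equal(res$score$fisher_logdet, 0)
  expect_equal(res$score$prior_terms, 0)
})

test_that("gaussian Fisher log-determinant matches the spectral identity", {
  pan <- white_noise_panel(p = 3, n = 80, seed = 8)
  full <- build_lag_design(pan, lag = 2, target = 2)
  des <- subset_design(full, c(TRUE, TRUE, FALSE))
  fam <- hggm_family("gaussian")
  fit <- fit_glm_irls(des$X, des$y, fam)
  phi <- estimate_dispersion(fam, des$y, fit)
  for (lambda in c(0.1, 1, 37.5, 1000)) {
    sc <- mml_code(des, fit, fam, lambda, phi)
    s <- svd(des$X, nu = 0, nv = 0)$d
    expect_equal(sc$fisher_logdet, sum(log(s^2 + lambda)) / 2,
                 tolerance = 1e-10)
  }
})

test_that("the six printed terms sum to the toy-fit total", {
  des <- toy_design() # 5 response points, lag 1, p = 2
  sub <- subset_design(des, c(TRUE, FALSE))
  fam <- hggm_family("gaussian")
  fit <- fit_glm_irls(sub$X, sub$y, fam)
  phi <- estimate_dispersion(fam, sub$y, fit)
  lambda <- 2.5
  sc <- mml_code(sub, fit, fam, lambda, phi)

  m <- length(sub$y)
  k <- 1
  # hand-assembled terms
  L <- sum(dnorm(sub$y, drop(sub$X %*% fit$beta), sqrt(phi), log = TRUE))
  fisher <- 0.5 * log(det(crossprod(sub$X) + lambda * diag(ncol(sub$X))))
  prior <- k / 2 * log(2 * pi * lambda) + lambda / (2 * phi) * sum(fit$beta^2)
  const <- 0.5 * log(m) - (k + 1) / 2 * log(2 * pi) + 0.5 * log((k + 1) * pi)
  struct <- log(choose(2, 1)) + log(3)
  expect_equal(sc$total, -L + fisher + prior + const + struct,
               tolerance = 1e-10)
  # decomposition bookkeeping: total is exactly the sum of its parts
  expect_identical(sc$total,
                   sc$neg_log_lik + sc$fisher_logdet + sc$prior_terms +
                     sc$constant_terms + sc$structure_code)
})

test_that("every lambda term is nondecreasing in lambda", {
  des <- toy_design()
  sub <- subset_design(des, c(TRUE, TRUE))
  fam <- hggm_family("gaussian")
  fit <- fit_glm_irls(sub$X, sub$y, fam)
  phi <- estimate_dispersion(fam, sub$y, fit)
  lams <- c(0.1, 1, 10, 100, 1000)
  tot <- vapply(lams, function(l) mml_code(sub, fit, fam, l, phi)$total,
                numeric(1))
  fis <- vapply(lams, function(l) mml_code(sub, fit, fam, l, phi)$fisher_logdet,
                numeric(1))
  expect_true(all(diff(fis) >= 0))
  # hence the lambda minimum over H is attained no later than both endpoints
  res <- hmml(des, c(TRUE, TRUE))
  expect_lte(res$total, min(tot))
})

test_that("hmml is invariant to the order of series in the candidate", {
  withr::with_seed(13, {
    m <- matrix(rnorm(240), 80, 3)
    colnames(m) <- c("a", "b", "c")
    pan1 <- ts_panel(m, rep("gaussian", 3))
    pan2 <- ts_panel(m[, c(2, 1, 3)], rep("gaussian", 3))
    f1 <- build_lag_design(pan1, 2, "c")
    f2 <- build_lag_design(pan2, 2, "c")
    r1 <- hmml(f1, c(TRUE, TRUE, FALSE))
    r2 <- hmml(f2, c(TRUE, TRUE, FALSE))
    expect_equal(r1$total, r2$total, tolerance = 1e-8)
  })
})

test_that("a strong planted signal beats the empty candidate", {
  pan <- planted_panel(p = 3, n = 300, d = 2, b = 0.9, seed = 4)
  full <- build_lag_design(pan, 2, 2)
  truth <- c(TRUE, FALSE, FALSE)
  expect_lt(hmml(full, truth)$total, hmml(full, rep(FALSE, 3))$total)
})

test_that("irrelevant pure-noise parents increase the expected code length", {
  # Monte-Carlo over independent replicates: adding noise series to the
  # already-correct (empty) candidate lengthens the message on average
  deltas <- vapply(1:50, function(r) {
    pan <- white_noise_panel(p = 3, n = 100, seed = 100 + r)
    full <- build_lag_design(pan, 2, 1)
    hmml(full, c(FALSE, TRUE, TRUE))$total - hmml(full, rep(FALSE, 3))$total
  }, numeric(1))
  expect_gt(mean(deltas), 0)
})

test_that("likelihood sentinel propagates to an infinite total", {
  # a gamma target with a negative-predictor fit must reject the candidate
  des <- toy_design()
  sub <- subset_design(des, c(TRUE, FALSE))
  fam <- hggm_family("gamma")
  fake_fit <- structure(list(beta = -1, eta = -sub$X[, 1],
                             mu = -1 / sub$X[, 1]), class = "hggm_fit")
  sc <- mml_code(sub, fake_fit, fam, 1, 0.5)
  expect_identical(sc$total, Inf)
})
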