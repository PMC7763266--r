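# Small in-code fixtures shared across the suite.

# p gaussian white-noise series, no causal structure
white_noise_panel <- function(p = 3, n = 100, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n * p), n, p)
    colnames(m) <- paste0("x", seq_len(p))
    ts_panel(m, rep("gaussian", p))
  })
}

# gaussian panel with a single planted edge cause -> effect, equal per-lag
# coefficients b on the cause's standardized values
planted_panel <- function(p = 3, n = 300, d = 2, b = 0.9, cause = 1,
                          effect = 2, seed = 1) {
  adj <- matrix(FALSE, p, p)
  adj[effect, cause] <- TRUE
  simulate_hggm_panel(causal_graph(adj), rep("gaussian", p), n = n, lag = d,
                      strength = b, seed = seed)
}

# a tiny deterministic design for hand-checked criterion arithmetic
toy_design <- function() {
  pan <- ts_panel(
    cbind(a = c(0.3, -0.1, 0.4, 0.2, -0.3, 0.25),
          b = c(0.1, 0.2, -0.2, 0.15, 0.05, -0.1)),
    c("gaussian", "gaussian")
  )
  build_lag_design(pan, lag = 1, target = "a")
}

random_family_panel <- function(family, n = 60, p = 2, seed = 1) {
  withr::with_seed(seed, {
    m <- switch(family,
      gaussian = matrix(rnorm(n * p), n, p),
      binomial = matrix(rbinom(n * p, 1, 0.5), n, p),
      poisson = matrix(rpois(n * p, 1.5), n, p),
      gamma = matrix(rgamma(n * p, shape = 2, scale = 1), n, p),
      inverse_gaussian = matrix(mmlgranger:::rinvgauss(n * p, 1, 1), n, p)
    )
    colnames(m) <- paste0("x", seq_len(p))
    ts_panel(m, rep(family, p))
  })
}

all_families <- c("gaussian", "binomial", "poisson", "gamma",
                  "inverse_gaussian")
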