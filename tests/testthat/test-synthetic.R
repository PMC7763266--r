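test_that("random graphs carry exactly the requested edges", {
  g0 <- random_causal_graph(5, 0, seed = 1)
  expect_equal(sum(g0$adjacency), 0)
  gfull <- random_causal_graph(5, 20, seed = 1)
  expect_equal(sum(gfull$adjacency), 20)
  expect_true(all(!diag(gfull$adjacency))) # complete digraph, no self-loops
  expect_error(random_causal_graph(5, 21), "n_edges")
  g8 <- random_causal_graph(5, 8, seed = 2)
  expect_equal(sum(g8$adjacency), 8)
  expect_true(all(!diag(g8$adjacency)))
})

test_that("edge sampling is uniform over admissible ordered pairs", {
  p <- 5; ne <- 8; draws <- 10000
  counts <- matrix(0, p, p)
  withr::with_seed(99, {
    for (i in seq_len(draws)) {
      counts <- counts + random_causal_graph(p, ne)$adjacency
    }
  })
  freq <- counts[!diag(p)] / draws
  expect_true(all(abs(freq - ne / (p * (p - 1))) < 0.02))
  expect_true(all(diag(counts) == 0))
})

test_that("simulation is reproducible and respects declared domains", {
  g <- random_causal_graph(5, 8, seed = 3)
  fams <- c("gamma", "gaussian", "poisson", "binomial", "inverse_gaussian")
  a <- simulate_hggm_panel(g, fams, n = 200, lag = 2, strength = 0.6,
                           seed = 11)
  b <- simulate_hggm_panel(g, fams, n = 200, lag = 2, strength = 0.6,
                           seed = 11)
  expect_identical(a$values, b$values)
  # ts_panel() would have errored on any domain violation; spot-check anyway
  expect_true(all(a$values[, 1] > 0))
  expect_true(all(a$values[, 4] %in% c(0, 1)))
})

test_that("parentless series reproduce their baseline distributions", {
  g <- causal_graph(matrix(FALSE, 5, 5))
  fams <- c("gaussian", "poisson", "gamma", "binomial", "inverse_gaussian")
  pan <- simulate_hggm_panel(g, fams, n = 2000, lag = 2, strength = 0.5,
                             seed = 21)
  v <- pan$values
  expect_equal(mean(v[, 1]), 0, tolerance = 0.1)       # N(0, 1)
  expect_equal(stats::var(v[, 1]), 1, tolerance = 0.15)
  expect_equal(mean(v[, 2]), 1, tolerance = 0.1)       # poisson mean 1
  expect_equal(mean(v[, 3]), 2, tolerance = 0.15)      # gamma shape 2 scale 1
  expect_equal(stats::var(v[, 3]), 2, tolerance = 0.35)
  expect_equal(mean(v[, 4]), 0.5, tolerance = 0.05)    # Bernoulli(1/2)
  expect_equal(mean(v[, 5]), 1, tolerance = 0.1)       # IG mean 1
})

test_that("a planted edge leaves a detectable lagged cross-correlation", {
  pan <- planted_panel(p = 2, n = 500, d = 2, b = 0.9, cause = 1,
                       effect = 2, seed = 33)
  x <- pan$values[, 1]; y <- pan$values[, 2]
  obs <- abs(stats::cor(x[1:498], y[3:500]))
  # permutation null for the same statistic
  null <- withr::with_seed(34, {
    vapply(1:200, function(i) {
      xs <- sample(x)
      abs(stats::cor(xs[1:498], y[3:500]))
    }, numeric(1))
  })
  expect_gt(obs, stats::quantile(null, 0.99))
})

test_that("F-measure follows its precision/recall definition", {
  g <- function(edges, p = 3) {
    adj <- matrix(FALSE, p, p)
    for (e in edges) adj[e[2], e[1]] <- TRUE # cause -> effect
    causal_graph(adj)
  }
  truth <- g(list(c(1, 2), c(2, 3)))
  expect_equal(f_measure(truth, truth), 1)
  pred <- g(list(c(1, 2), c(3, 1)))
  expect_equal(f_measure(pred, truth), 0.5) # P = R = 1/2
  expect_equal(f_measure(g(list(c(3, 2))), truth), 0)
  expect_equal(f_measure(g(list()), truth), 0)
  expect_equal(f_measure(g(list()), g(list())), 1)
  # invariance under a simultaneous node relabeling
  perm <- c(2, 3, 1)
  pg <- function(x) causal_graph(x$adjacency[perm, perm])
  expect_equal(f_measure(pg(pred), pg(truth)), f_measure(pred, truth))
})

test_that("benchmark reports are deterministic and internally consistent", {
  grid <- tibble::tibble(p = 3, n_edges = 2, strength = 0.9, n = 120, d = 2,
                         families = list(rep("gaussian", 3)))
  bm1 <- run_benchmark(grid, methods = "exhaustive", replicates = 3,
                       seed = 5)
  bm2 <- run_benchmark(grid, methods = "exhaustive", replicates = 3,
                       seed = 5)
  expect_identical(as.data.frame(bm1), as.data.frame(bm2))
  sm <- summary(bm1)
  for (mth in unique(bm1$method)) {
    expect_equal(sm$mean_f[sm$method == mth],
                 mean(bm1$f[bm1$method == mth]))
  }
  expect_true(all(bm1$f >= 0 & bm1$f <= 1))
  expect_true(all(c("exhaustive", "empty", "random") %in% bm1$method))
  # a single replicate reports itself as the mean
  bm3 <- run_benchmark(grid, methods = "exhaustive", replicates = 1,
                       seed = 6, baselines = FALSE)
  expect_equal(summary(bm3)$mean_f, bm3$f)
})
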