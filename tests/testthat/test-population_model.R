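test_that("bottleneck sampling is binomial with the right edge cases", {
  p <- experiment_params()
  b0 <- bottleneck_distribution(0, p)
  expect_equal(b0$probabilities[1], 1)
  expect_equal(sum(b0$probabilities), 1)
  b1 <- bottleneck_distribution(1, p)
  expect_equal(b1$probabilities[p$bottleneck_size + 1], 1)
  b2 <- bottleneck_distribution(0.5, experiment_params(bottleneck_size = 2))
  expect_equal(b2$probabilities, c(0.25, 0.5, 0.25))
  expect_error(bottleneck_distribution(1.2, p), "f0")
  expect_error(bottleneck_distribution(-0.1, p), "f0")
})

test_that("growth from monomorphic founders is degenerate", {
  for (method in c("dp", "asymptotic")) {
    p <- experiment_params(bottleneck_size = 20, divisions = 4, grid_size = 64)
    g0 <- growth_distribution(0, p, s = 0.7, method = method)
    expect_equal(g0$probabilities[1], 1)
    gB <- growth_distribution(20, p, s = 0.2, method = method)
    expect_equal(gB$probabilities[64], 1)
  }
  expect_error(growth_distribution(5, experiment_params(), s = 1.5), "s must")
  expect_error(growth_distribution(300, experiment_params()), "founders")
})

test_that("neutral growth keeps the martingale mean and Beta moments", {
  ## full scale: branching-process kernel vs Beta(i, B - i)
  p <- experiment_params()
  gd <- growth_distribution(10, p, s = 0)
  m <- sum(gd$grid * gd$probabilities)
  v <- sum(gd$grid^2 * gd$probabilities) - m^2
  expect_equal(m, 10 / 200, tolerance = 1e-3)
  beta_var <- 10 * 190 / (200^2 * 201)
  expect_lt(abs(v - beta_var) / beta_var, 0.05)

  ## small scale: exact DP; finite-population variance is Beta variance
  ## shrunk by (1 - B/N)
  ps <- experiment_params(bottleneck_size = 20, divisions = 4, grid_size = 256)
  gs <- growth_distribution(5, ps, s = 0, method = "dp")
  ms <- sum(gs$grid * gs$probabilities)
  vs <- sum(gs$grid^2 * gs$probabilities) - ms^2
  expect_equal(ms, 0.25, tolerance = 2e-3)
  vexp <- (5 * 15 / (20^2 * 21)) * (1 - 20 / 320)
  expect_lt(abs(vs - vexp) / vexp, 0.05)
})

test_that("distributions conserve probability across parameters", {
  for (cfg in list(list(B = 20, d = 4, j = 3, s = 0.5),
                   list(B = 200, d = 15, j = 1, s = -0.5),
                   list(B = 200, d = 15, j = 150, s = 0.9),
                   list(B = 50, d = 5, j = 25, s = -1))) {
    p <- experiment_params(bottleneck_size = cfg$B, divisions = cfg$d,
                           grid_size = 128)
    gd <- growth_distribution(cfg$j, p, s = cfg$s)
    expect_equal(sum(gd$probabilities), 1, tolerance = 1e-10)
    expect_true(all(gd$probabilities >= 0))
  }
})

test_that("mean final frequency is non-decreasing in s", {
  p <- experiment_params(grid_size = 256)
  means <- vapply(c(-0.6, -0.2, 0, 0.2, 0.6), function(s) {
    gd <- growth_distribution(10, p, s = s)
    sum(gd$grid * gd$probabilities)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("analytic growth kernels match the event-exact simulator", {
  ## exact DP regime
  p1 <- experiment_params(bottleneck_size = 20, divisions = 4, grid_size = 64)
  f1 <- simulate_growth(3, p1, s = 0.3, replicates = 5e4, seed = 101,
                        method = "exact")
  expect_lt(tv_against_sample(growth_distribution(3, p1, s = 0.3), f1), 0.02)

  ## branching-process regime (N = 1600 forced asymptotic)
  p2 <- experiment_params(bottleneck_size = 50, divisions = 5, grid_size = 64)
  f2 <- simulate_growth(25, p2, s = -0.3, replicates = 5e4, seed = 102,
                        method = "exact")
  expect_lt(tv_against_sample(
    growth_distribution(25, p2, s = -0.3, method = "asymptotic"), f2), 0.02)
})

test_that("the asymptotic sampler agrees with event-exact simulation", {
  p <- experiment_params(bottleneck_size = 200, divisions = 6, grid_size = 64)
  fe <- simulate_growth(5, p, s = 0.4, replicates = 2e4, seed = 7, method = "exact")
  fa <- simulate_growth(5, p, s = 0.4, replicates = 2e4, seed = 8,
                        method = "asymptotic")
  se <- sqrt(var(fe) / 2e4 + var(fa) / 2e4)
  expect_lt(abs(mean(fe) - mean(fa)), 4 * se)
  expect_lt(abs(sd(fe) - sd(fa)) / sd(fe), 0.05)
})

test_that("simulate_growth is seeded, deterministic and respects edge cases", {
  p <- experiment_params(bottleneck_size = 20, divisions = 4)
  expect_identical(simulate_growth(5, p, 0.2, 100, seed = 42),
                   simulate_growth(5, p, 0.2, 100, seed = 42))
  expect_false(identical(simulate_growth(5, p, 0.2, 100, seed = 42),
                         simulate_growth(5, p, 0.2, 100, seed = 43)))
  expect_true(all(simulate_growth(0, p, 0.9, 50, seed = 1) == 0))
  expect_true(all(simulate_growth(20, p, 0.3, 50, seed = 1) == 1))

  ## symmetry: half mutant founders stay at mean 1/2 under neutrality
  p6 <- experiment_params(bottleneck_size = 200, divisions = 6)
  f <- simulate_growth(100, p6, s = 0, replicates = 1e4, seed = 5)
  expect_lt(abs(mean(f) - 0.5), 3 * sd(f) / sqrt(1e4))
})

test_that("a single positively selected founder expands far beyond 1/B", {
  ## regression fixture: one founder at s = 0.5 under default geometry
  p <- experiment_params()
  f <- simulate_growth(1, p, s = 0.5, replicates = 2e4, seed = 9,
                       method = "asymptotic")
  expect_gt(mean(f), 0.2)   # neutral expectation would be 1/200 = 0.005
})
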