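test_that("allele frequencies and Bonferroni thresholds compute exactly", {
  expect_equal(round(allele_frequency_percent(156, 282), 2), 55.32)
  expect_equal(round(allele_frequency_percent(42, 3122), 2), 1.35)
  expect_equal(allele_frequency_percent(0, 725), 0)
  expect_error(allele_frequency_percent(10, 0), "total")
  expect_error(allele_frequency_percent(800, 725), "alt")

  expect_equal(signif(bonferroni_alpha(2.9e5), 2), 1.7e-7)
  expect_equal(bonferroni_alpha(1), 0.05)
  expect_equal(bonferroni_alpha(100), 5e-4)
})

test_that("the read error model mixes frequency and miscalls linearly", {
  p0 <- experiment_params(seq_error = 0)
  expect_equal(observed_read_prob(0, p0), 0)
  expect_equal(observed_read_prob(1, p0), 1)
  p3 <- experiment_params(seq_error = 3e-3)
  expect_equal(observed_read_prob(0, p3), 1e-3)
  ## diploid mode halves the read-level fraction
  pd <- experiment_params(seq_error = 0, diploid = TRUE)
  expect_equal(observed_read_prob(1, pd), 0.5)
})

test_that("the early-frequency posterior concentrates correctly", {
  p <- experiment_params()
  ## large zero-count depth pins the posterior near zero
  post0 <- early_frequency_posterior(0, 50000, p)
  expect_lt(sum(post0$grid * post0$probabilities), 1e-3)
  ## symmetric counts put the mode at the bin nearest 1/2
  ph <- experiment_params(seq_error = 0)
  posth <- early_frequency_posterior(300, 600, ph)
  expect_equal(posth$grid[which.max(posth$probabilities)], 0.5,
               tolerance = 1.5 / ph$grid_size)
  ## printed-table counts: mean in the brute-force window
  postb <- early_frequency_posterior(42, 3122, p)
  mb <- sum(postb$grid * postb$probabilities)
  expect_gt(mb, 0.010); expect_lt(mb, 0.017)
})

test_that("drift p-values behave as one-sided tail probabilities", {
  p <- experiment_params()
  ## a late count of zero cannot be exceeded: p = 1 in the gain direction
  d0 <- drift_pvalue(site_observation("z", 0, 725, 0, 282), p)
  expect_equal(d0$p_value, 1)
  expect_equal(d0$direction, "gain")
  ## unchanged frequency at matched depths is unremarkable
  dn <- drift_pvalue(site_observation("n", 50, 1000, 50, 1000), p)
  expect_gt(dn$p_value, 0.05)
  ## monotone in the late count within the gain regime
  ps <- vapply(c(60, 90, 130, 200), function(y)
    drift_pvalue(site_observation("m", 50, 1000, y, 1000), p)$p_value,
    numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_true(all(ps >= 0 & ps <= 1))
  ## significance flag is p < alpha
  expect_false(dn$significant)
  expect_identical(dn$alpha, bonferroni_alpha(2.9e5))
})

test_that("drift p-values match a full Monte Carlo of the null chain", {
  ## small geometries where every division event can be simulated
  set.seed(314)
  configs <- list(
    list(B = 20, d = 4, k = 5, n = 200, y = 12, nl = 250),
    list(B = 20, d = 3, k = 10, n = 150, y = 4, nl = 120),
    list(B = 12, d = 4, k = 3, n = 100, y = 9, nl = 180),
    list(B = 20, d = 4, k = 20, n = 400, y = 12, nl = 300),
    list(B = 16, d = 2, k = 8, n = 160, y = 14, nl = 200))
  for (i in seq_along(configs)) {
    cf <- configs[[i]]
    p <- experiment_params(bottleneck_size = cf$B, divisions = cf$d,
                           grid_size = 256)
    obs <- site_observation("mc", cf$k, cf$n, cf$y, cf$nl)
    p_chain <- drift_pvalue(obs, p)$p_value
    R <- 1e5
    p_mc <- mc_null_pvalue(obs, p, replicates = R, seed = 1000 + i)
    se <- sqrt(max(p_mc * (1 - p_mc), 1e-6) / R)
    expect_lt(abs(p_chain - p_mc), 3 * se + 2e-3)
  }
})

test_that("the selection likelihood orders hypotheses sensibly", {
  p <- experiment_params()
  obs_null <- site_observation("n", 50, 1000, 50, 1000)
  expect_gt(selection_likelihood(obs_null, 0, p),
            selection_likelihood(obs_null, 0.9, p))
  obs_sel <- site_observation("chr9:21974774:A", 0, 725, 156, 282)
  expect_gt(selection_likelihood(obs_sel, 0.5, p),
            selection_likelihood(obs_sel, 0, p))
  expect_true(is.finite(selection_likelihood(obs_sel, -1, p)))
})

test_that("the s = 0 likelihood equals the null chain's late-count pmf", {
  ## reconstruct P(late_alt | early counts, s = 0) from the public pieces
  p <- experiment_params(bottleneck_size = 20, divisions = 4, grid_size = 512)
  obs <- site_observation("c", 30, 300, 45, 350)
  post <- early_frequency_posterior(obs$early_alt, obs$early_total, p)
  B <- p$bottleneck_size
  pj <- numeric(B + 1)
  for (k in seq_along(post$grid))
    pj <- pj + post$probabilities[k] * dbinom(0:B, B, post$grid[k])
  pmf_y <- 0
  for (j in 0:B) {
    if (pj[j + 1] < 1e-14) next
    gd <- growth_distribution(j, p, s = 0)
    q <- observed_read_prob(gd$grid, p)
    pmf_y <- pmf_y + pj[j + 1] *
      sum(gd$probabilities * dbinom(obs$late_alt, obs$late_total, q))
  }
  expect_equal(selection_likelihood(obs, 0, p), log(pmf_y), tolerance = 0.02)
})

test_that("selection estimation recovers null and respects its invariants", {
  p <- experiment_params()
  est0 <- estimate_selection(site_observation("n", 50, 1000, 50, 1000), p)
  expect_equal(est0$s_hat, 0)
  expect_lte(est0$ci_low, est0$s_hat)
  expect_gte(est0$ci_high, est0$s_hat)
  expect_equal(max(est0$profile$loglik),
               est0$profile$loglik[est0$profile$s == est0$s_hat])
  ## the profile is a proper grid over [-1, 1]
  expect_equal(range(est0$profile$s), c(-1, 1))
  expect_equal(nrow(est0$profile), 41)
})
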