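test_that("expected variant sites follow the host/dope genotype rules", {
  host <- data.frame(site_id = c("s1", "s2", "s3", "s4"),
                     allele1 = c("A", "A", "C", "G"),
                     allele2 = c("A", "T", "C", "G"),
                     stringsAsFactors = FALSE)
  dope <- data.frame(site_id = host$site_id,
                     allele1 = c("A", "A", "C", "T"),
                     allele2 = c("G", "A", "C", "T"),
                     stringsAsFactors = FALSE)
  spec <- mixture_spec(host, dope, dope_fraction = 0.004, depth = 2000)
  ev <- expected_variant_sites(spec)
  ## s1: host hom A, dope het A/G -> expected at fraction * 1/2
  expect_equal(ev$expected_freq[ev$site_id == "s1"], 0.002)
  ## s2: host het -> excluded entirely
  expect_false("s2" %in% ev$site_id)
  ## s3: identical genotypes -> nothing expected
  expect_false("s3" %in% ev$site_id)
  ## s4: dope hom-alt -> 2 copies at fraction * 1
  expect_equal(ev$expected_freq[ev$site_id == "s4"], 0.004)

  ## identical tables everywhere -> empty expectation
  spec_same <- mixture_spec(host, host, dope_fraction = 0.004)
  expect_equal(nrow(expected_variant_sites(spec_same)), 0L)
})

test_that("sensitivity and specificity reduce to their set definitions", {
  m <- sensitivity_specificity(c("a", "b"), c("a", "b"), c("a", "b", "c", "d"))
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  m0 <- sensitivity_specificity(character(0), c("a"), c("a", "b"))
  expect_equal(m0$sensitivity, 0)
  expect_equal(m0$specificity, 1)
  expect_warning(
    mNA <- sensitivity_specificity(c("a"), character(0), c("a", "b")),
    "undefined")
  expect_true(is.na(mNA$sensitivity))
  expect_error(sensitivity_specificity("a", "z", c("a", "b")), "subset")
})

test_that("synthetic mixtures at the doped fractions reach benchmark sensitivity", {
  gt <- make_genotype_tables(n_sites = 3000, n_diff = 400, seed = 61)
  spec <- mixture_spec(gt$host, gt$dope, dope_fraction = 0.004, depth = 2000)
  metrics <- lapply(1:20, function(s) evaluate_mixture(spec, seed = 7000 + s))
  sens <- vapply(metrics, `[[`, numeric(1), "sensitivity")
  specf <- vapply(metrics, `[[`, numeric(1), "specificity")
  expect_gte(median(sens), 0.74)
  expect_gte(median(specf), 0.87)
})

test_that("sensitivity is monotone in dope fraction and depth", {
  gt <- make_genotype_tables(n_sites = 2000, n_diff = 300, seed = 62)
  grid <- expand.grid(fraction = c(0.002, 0.004), depth = c(1000, 2000))
  sens <- vapply(seq_len(nrow(grid)), function(i) {
    spec <- mixture_spec(gt$host, gt$dope, dope_fraction = grid$fraction[i],
                         depth = grid$depth[i])
    median(vapply(1:5, function(s)
      evaluate_mixture(spec, seed = 100 + s)$sensitivity, numeric(1)))
  }, numeric(1))
  ## increasing fraction at fixed depth
  expect_lt(sens[1], sens[2]); expect_lt(sens[3], sens[4])
  ## increasing depth at fixed fraction
  expect_lt(sens[1], sens[3]); expect_lt(sens[2], sens[4])
})

test_that("a zero dope fraction yields a host-only library", {
  gt <- make_genotype_tables(n_sites = 500, n_diff = 100, seed = 63)
  spec <- mixture_spec(gt$host, gt$dope, dope_fraction = 0, depth = 500,
                       params = experiment_params(seq_error = 0))
  pu <- simulate_doped_library(spec, seed = 1)
  counts <- as.matrix(pu[c("A", "C", "G", "T")])
  host_idx <- cbind(seq_len(nrow(pu)), match(gt$host$allele1, c("A", "C", "G", "T")))
  expect_true(all(counts[host_idx] == rowSums(counts)))
})
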