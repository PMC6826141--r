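test_that("the Poisson-binomial call matches closed forms and enumeration", {
  expect_equal(poisson_binomial_call(0, rep(30, 100)), 1)
  ## three Q10 reads, one alternate: 1 - (1 - 0.1/3)^3
  expect_equal(poisson_binomial_call(1, rep(10, 3)), 1 - (1 - 0.1 / 3)^3,
               tolerance = 1e-12)
  ## mixed qualities against full enumeration over read outcomes
  set.seed(20)
  for (rep in 1:5) {
    quals <- sample(c(10, 20, 30, 40), 9, replace = TRUE)
    k <- sample(1:4, 1)
    expect_equal(poisson_binomial_call(k, quals),
                 enum_poisbin_tail(k, 10^(-quals / 10) / 3))
  }
  ## 8 alternate reads in 30 Q30 reads is far beyond error expectation
  expect_lt(poisson_binomial_call(8, rep(30, 30)), 0.01)
  expect_error(poisson_binomial_call(1, numeric(0)), "empty")
  expect_error(poisson_binomial_call(5, rep(30, 3)), "exceed")
})

test_that("screen_pair keeps single-passage calls and respects its gates", {
  n <- 60
  early <- make_pileup(1:n, "A", depth = 500)
  late <- make_pileup(1:n, "A", depth = 500)
  ## site 10: strong alternate in late only -> SM-V detected in late
  late[10, "T"] <- 12; late[10, "A"] <- 488
  ## site 20: same alternate called in both passages -> shared, not SM-V
  early[20, "G"] <- 15; early[20, "A"] <- 485
  late[20, "G"] <- 15; late[20, "A"] <- 485
  ## site 30: below min_alt_count in late -> no call
  late[30, "C"] <- 2; late[30, "A"] <- 498
  ## site 40: a germline-like variant present in both passages -> shared
  early[40, "T"] <- 150; early[40, "A"] <- 350
  late[40, "T"] <- 350; late[40, "A"] <- 150
  ## site 45: late-only T call, but the early passage carries another
  ## allele imbalance, so the host genotype is not homozygous reference
  early[45, "G"] <- 100; early[45, "A"] <- 400
  late[45, "T"] <- 12; late[45, "A"] <- 488

  res <- screen_pair(early, late)
  expect_s3_class(res, "screen_result")
  expect_equal(res$smv$site_id, "chrT:10:T")
  expect_equal(res$smv$passage_detected, "late")
  expect_equal(res$smv$late_alt, 12L)
  expect_setequal(res$shared$site_id, c("chrT:20:G", "chrT:40:T"))

  ## swapping the passages swaps the detected label, same site set
  swapped <- screen_pair(late, early)
  expect_equal(swapped$smv$site_id, res$smv$site_id)
  expect_equal(swapped$smv$passage_detected, "early")

  ## raising min_alt_count above the signal removes the call
  res_hi <- screen_pair(early, late, screen_thresholds(min_alt_count = 20))
  expect_equal(nrow(res_hi$smv), 0L)

  expect_error(screen_pair(early, late[1:10, ]), "same sites")
})

test_that("per-read qualities feed the call through the exact DP", {
  pu_e <- make_pileup(1:3, "A", depth = 40)
  pu_l <- make_pileup(1:3, "A", depth = 40)
  qcols <- function(pu, i, ref_n, ref_q, alt, alt_n, alt_q) {
    for (b in c("A", "C", "G", "T")) pu[[paste0("qual_", b)]] <- ""
    pu$qual_A <- paste(rep(ref_q, ref_n), collapse = ",")
    pu[[paste0("qual_", alt)]][i] <- paste(rep(alt_q, alt_n), collapse = ",")
    pu
  }
  pu_l[2, "T"] <- 3L; pu_l[2, "A"] <- 37L
  pu_e <- qcols(pu_e, 2, 40, 35, "T", 0, 35)
  pu_lq <- qcols(pu_l, 2, 37, 35, "T", 3, 35)
  res <- screen_pair(pu_e, pu_lq)
  expect_equal(res$smv$site_id, "chrT:2:T")
  ## the same three alternate reads at phred 0 (error prob 1/3 each) are
  ## consistent with sequencing error, so no call is made
  pu_l0 <- qcols(pu_l, 2, 37, 35, "T", 3, 0)
  res2 <- screen_pair(pu_e, pu_l0, screen_thresholds())
  expect_equal(nrow(res2$smv), 0L)
})

test_that("shared-site outliers are flagged by the 3-SD rule", {
  ## all equal differences: none exceed mean + 3 SD
  flat <- data.frame(early_freq = rep(0.3, 10), late_freq = rep(0.32, 10))
  expect_equal(nrow(shared_site_outliers(flat)), 0L)
  ## one large change among 99 small ones
  set.seed(4)
  bg <- data.frame(early_freq = runif(99, 0.49, 0.51))
  bg$late_freq <- bg$early_freq + rnorm(99, 0, 0.001)
  hit <- data.frame(early_freq = 0.0135, late_freq = 0.2143)
  out <- shared_site_outliers(rbind(bg, hit))
  expect_equal(nrow(out), 1L)
  expect_equal(out$early_freq, 0.0135)
  expect_warning(shared_site_outliers(flat[1, ]), "fewer than 2")
})

test_that("the neighborhood filter drops clusters and merges dinucleotides", {
  iso <- data.frame(site_id = "c:100:T", chrom = "c", pos = 100L,
                    ref = "C", alt = "T", class = "transition",
                    stringsAsFactors = FALSE)
  expect_equal(nrow(neighborhood_filter(iso)), 1L)
  ## three candidates within 10 bp are all removed at max_neighbors = 1
  clus <- data.frame(site_id = paste0("c:", c(100, 105, 108), ":T"),
                     chrom = "c", pos = c(100L, 105L, 108L),
                     ref = "C", alt = "T", class = "transition",
                     stringsAsFactors = FALSE)
  expect_equal(nrow(neighborhood_filter(clus)), 0L)
  ## adjacent CC>TT pair merges into one kept dinucleotide event
  din <- data.frame(site_id = paste0("c:", c(200, 201), ":T"),
                    chrom = "c", pos = c(200L, 201L),
                    ref = "C", alt = "T", class = "transition",
                    stringsAsFactors = FALSE)
  out <- neighborhood_filter(din)
  expect_equal(nrow(out), 1L)
  expect_equal(out$ref, "CC")
  expect_equal(out$alt, "TT")
  expect_equal(out$class, "dinucleotide")
})

test_that("substitutions classify into transitions, transversions, dinucleotides", {
  expect_equal(classify_substitution("C", "T"), "transition")
  expect_equal(classify_substitution("A", "G"), "transition")
  expect_equal(classify_substitution("C", "A"), "transversion")
  expect_equal(classify_substitution("G", "T"), "transversion")
  expect_equal(classify_substitution("CC", "TT"), "dinucleotide")
  expect_error(classify_substitution("C", "C"), "differ")
  expect_error(classify_substitution("N", "T"), "non-ACGT")
})
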