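# Shared fixtures and independent oracles for the test suite. Everything
# is built in code; no data files.

table3_sites <- function() {
  data.frame(
    site_id = c("chr9:21974774:A", "chr5:60169670:T", "chr13:32914714:T"),
    early_alt = c(0L, 0L, 42L),
    early_total = c(725L, 2168L, 3122L),
    late_alt = c(156L, 122L, 642L),
    late_total = c(282L, 705L, 2996L),
    stringsAsFactors = FALSE
  )
}

## Total variation distance between a frequency_distribution and a sample
## of frequencies, binned to the distribution's grid.
tv_against_sample <- function(fd, sample_freqs) {
  G <- length(fd$grid)
  emp <- tabulate(pmax(1L, ceiling(sample_freqs * G)), G) / length(sample_freqs)
  0.5 * sum(abs(emp - fd$probabilities))
}

## Brute-force Poisson-binomial tail P(X >= k) by enumeration over all
## 2^n read outcomes (oracle for the DP; n must be small).
enum_poisbin_tail <- function(k, err_probs) {
  n <- length(err_probs)
  stopifnot(n <= 14)
  outcomes <- expand.grid(rep(list(c(0, 1)), n))
  prob <- apply(outcomes, 1, function(x)
    prod(ifelse(x == 1, err_probs, 1 - err_probs)))
  sum(prob[rowSums(outcomes) >= k])
}

## Small pileup over a handful of sites with constant Q30 reads.
make_pileup <- function(pos, ref, depth, alt_allele = NULL, alt_count = 0L,
                        chrom = "chrT") {
  n <- length(pos)
  ref <- rep_len(ref, n)
  depth <- rep_len(depth, n)
  alt_count <- rep_len(alt_count, n)
  pu <- data.frame(chrom = chrom, pos = as.integer(pos), ref = ref,
                   A = 0L, C = 0L, G = 0L, T = 0L, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    pu[i, ref[i]] <- depth[i] - alt_count[i]
    if (!is.null(alt_allele) && alt_count[i] > 0)
      pu[i, alt_allele[i]] <- alt_count[i]
  }
  attr(pu, "default_qual") <- 30
  pu
}

## Full Monte Carlo of the drift-null chain (independent of the grid
## machinery): continuous posterior draw of the early frequency by
## inverse-CDF of the truncated Beta in read-probability space, binomial
## bottleneck, event-exact growth, binomial late reads.
mc_null_pvalue <- function(obs, params, replicates, seed) {
  cf <- clonedrift:::read_prob_coef(params)
  B <- params$bottleneck_size
  N <- final_population_size(params)
  k <- obs$early_alt; n <- obs$early_total
  y <- obs$late_alt; nl <- obs$late_total
  withr::with_seed(seed, {
    lo <- pbeta(cf$c0, k + 1, n - k + 1)
    hi <- pbeta(cf$c0 + cf$c1, k + 1, n - k + 1)
    q <- qbeta(runif(replicates, lo, hi), k + 1, n - k + 1)
    f <- pmin(1, pmax(0, (q - cf$c0) / cf$c1))
    j <- rbinom(replicates, B, f)
    fl <- numeric(replicates)
    for (jv in unique(j)) {
      idx <- which(j == jv)
      fl[idx] <- if (jv == 0) 0
      else if (jv == B) 1
      else clonedrift:::urn_growth_sim_cpp(jv, B, N, 0, length(idx))
    }
    ylate <- rbinom(replicates, nl, cf$c0 + cf$c1 * fl)
    gain <- (y / nl) >= (k / n)
    if (gain) mean(ylate >= y) else mean(ylate <= y)
  })
}

## Host/dope genotype tables with a controlled number of differing sites
## (half heterozygous, half homozygous in the doped-in sample).
make_genotype_tables <- function(n_sites, n_diff, seed) {
  withr::with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    host <- data.frame(site_id = sprintf("s%05d", seq_len(n_sites)),
                       allele1 = sample(bases, n_sites, replace = TRUE),
                       stringsAsFactors = FALSE)
    host$allele2 <- host$allele1
    dope <- host
    diff_idx <- sample(n_sites, n_diff)
    hom_idx <- diff_idx[seq_len(floor(n_diff / 2))]
    for (i in diff_idx) {
      a <- sample(setdiff(bases, host$allele1[i]), 1)
      dope$allele2[i] <- a
      if (i %in% hom_idx) dope$allele1[i] <- a
    }
    list(host = host, dope = dope, diff_idx = sort(diff_idx))
  })
}
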