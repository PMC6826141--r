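## ---------------------------------------------------------------------------
## Site observations
## ---------------------------------------------------------------------------

#' A single site's paired-passage allele counts
#'
#' The unit of inference: alternate and total read counts at one genomic
#' site in the early (pre-expansion) and late (post-expansion) passage.
#'
#' @param site_id Site identifier, conventionally `"chrom:pos:alt"` with a
#'   1-based position.
#' @param early_alt,early_total Alternate and total read counts, early passage.
#' @param late_alt,late_total Alternate and total read counts, late passage.
#' @return An object of class `site_observation`.
#' @examples
#' site_observation("chr9:21974774:A", 0, 725, 156, 282)
#' @export
site_observation <- function(site_id, early_alt, early_total, late_alt, late_total) {
  obs <- list(site_id = as.character(site_id),
              early_alt = as.integer(early_alt),
              early_total = as.integer(early_total),
              late_alt = as.integer(late_alt),
              late_total = as.integer(late_total))
  validate_site_observation(obs)
  structure(obs, class = "site_observation")
}

validate_site_observation <- function(obs) {
  for (p in c("early", "late")) {
    alt <- obs[[paste0(p, "_alt")]]
    total <- obs[[paste0(p, "_total")]]
    if (is.na(alt) || is.na(total))
      stop(sprintf("%s passage counts must be integers", p))
    if (total < 1L)
      stop(sprintf("%s_total must be >= 1", p))
    if (alt < 0L || alt > total)
      stop(sprintf("%s_alt must lie in 0..%s_total (got %d/%d)", p, p, alt, total))
  }
  invisible(obs)
}

as_site_observation <- function(x) {
  if (inherits(x, "site_observation")) return(x)
  site_observation(if (!is.null(x$site_id)) x$site_id else "site",
                   x$early_alt, x$early_total, x$late_alt, x$late_total)
}

#' @export
print.site_observation <- function(x, ...) {
  cat(sprintf("%s: early %d/%d (%.2f%%) -> late %d/%d (%.2f%%)\n",
              x$site_id, x$early_alt, x$early_total,
              allele_frequency_percent(x$early_alt, x$early_total),
              x$late_alt, x$late_total,
              allele_frequency_percent(x$late_alt, x$late_total)))
  invisible(x)
}

#' Variant allele frequency in percent
#'
#' @param alt,total Alternate and total read counts (vectorized).
#' @return `100 * alt / total`. Rounding is left to display.
#' @examples
#' allele_frequency_percent(156, 282)  # 55.32
#' @export
allele_frequency_percent <- function(alt, total) {
  if (any(total < 1)) stop("total must be >= 1")
  if (any(alt < 0 | alt > total)) stop("alt must lie in 0..total")
  100 * alt / total
}

#' Bonferroni-corrected significance threshold
#'
#' Family-wise error control over the sequenced target: the threshold is
#' the family-wise rate divided by the number of tested positions
#' (the target-region size in base pairs, 2.9e5 by default).
#'
#' @param n_sites Number of tests (>= 1).
#' @param fwer Family-wise error rate (default 0.05).
#' @return `fwer / n_sites`.
#' @examples
#' bonferroni_alpha(2.9e5)  # 1.7e-7
#' @export
bonferroni_alpha <- function(n_sites, fwer = 0.05) {
  if (!is.numeric(n_sites) || any(n_sites < 1)) stop("n_sites must be >= 1")
  if (!is.numeric(fwer) || any(fwer <= 0 | fwer >= 1)) stop("fwer must lie in (0, 1)")
  fwer / n_sites
}

## ---------------------------------------------------------------------------
## Read error model
## ---------------------------------------------------------------------------

#' Probability that an aligned read shows the alternate allele
#'
#' Combines the true frequency with the sequencing-error terms: a true
#' alternate base is read correctly with probability \eqn{1 - \epsilon};
#' a true reference base is miscalled as this particular alternate with
#' probability \eqn{\epsilon / 3} (miscalls distribute uniformly over the
#' three other bases). In diploid mode the read-level fraction is half the
#' cell fraction.
#'
#' @param f True mutant frequency in `[0, 1]` (vectorized).
#' @param params An [experiment_params()] object.
#' @return Per-read alternate-allele probability.
#' @examples
#' observed_read_prob(0, experiment_params(seq_error = 3e-3))  # 1e-3
#' @export
observed_read_prob <- function(f, params = experiment_params()) {
  stopifnot(inherits(params, "experiment_params"))
  if (any(f < 0 | f > 1)) stop("f must lie in [0, 1]")
  eps <- params$seq_error
  fr <- if (params$diploid) f / 2 else f
  fr * (1 - eps) + (1 - fr) * eps / 3
}

## Linear map f -> q: q = c0 + c1 * f
read_prob_coef <- function(params) {
  eps <- params$seq_error
  c1 <- (1 - 4 * eps / 3) * (if (params$diploid) 0.5 else 1)
  list(c0 = eps / 3, c1 = c1)
}

## ---------------------------------------------------------------------------
## Early-frequency posterior
## ---------------------------------------------------------------------------

## Posterior masses over nf uniform bins spanning the high-likelihood
## region of the true early frequency, under a uniform prior and the
## binomial read likelihood through the error model. Because q is linear
## in f, each bin's integrated likelihood is an incomplete-beta difference
## (exact under the flat prior).
fine_early_posterior <- function(k, n, params, nf = 2048L) {
  cf <- read_prob_coef(params)
  qlo <- qbeta(1e-15, k + 1, n - k + 1)
  qhi <- qbeta(1 - 1e-15, k + 1, n - k + 1)
  flo <- max(0, (qlo - cf$c0) / cf$c1)
  fhi <- min(1, (qhi - cf$c0) / cf$c1)
  if (!(fhi > flo)) { flo <- 0; fhi <- 1 }
  edges <- seq(flo, fhi, length.out = nf + 1L)
  q_edges <- cf$c0 + cf$c1 * edges
  mass <- pbeta(q_edges[-1L], k + 1, n - k + 1) -
    pbeta(q_edges[-(nf + 1L)], k + 1, n - k + 1)
  if (sum(mass) <= 0) {
    ## far-tail fallback: relative likelihood at bin midpoints in log space
    mids0 <- (edges[-1L] + edges[-(nf + 1L)]) / 2
    ll <- dbinom(k, n, cf$c0 + cf$c1 * mids0, log = TRUE)
    mass <- exp(ll - max(ll))
  }
  mids <- (edges[-1L] + edges[-(nf + 1L)]) / 2
  list(mids = mids, mass = mass / sum(mass), flo = flo, fhi = fhi)
}

#' Posterior distribution of the true early-passage frequency
#'
#' Conditions on the early passage's alternate read count under a uniform
#' grid prior on the true frequency and the binomial read likelihood with
#' sequencing error ([observed_read_prob()]). This is the conditioning
#' step of the drift-null chain; it handles observed zero counts without
#' forcing the true frequency to zero.
#'
#' @param early_alt,early_total Early-passage read counts.
#' @param params An [experiment_params()] object.
#' @return A [frequency_distribution()] on the standard grid.
#' @examples
#' post <- early_frequency_posterior(42, 3122)
#' sum(post$grid * post$probabilities)  # ~ 0.0135
#' @export
early_frequency_posterior <- function(early_alt, early_total,
                                      params = experiment_params()) {
  stopifnot(inherits(params, "experiment_params"))
  early_alt <- as.integer(early_alt); early_total <- as.integer(early_total)
  if (early_total < 1L || early_alt < 0L || early_alt > early_total)
    stop("counts must satisfy 0 <= early_alt <= early_total, early_total >= 1")
  G <- params$grid_size
  cf <- read_prob_coef(params)
  q_edges <- cf$c0 + cf$c1 * grid_edges(G)
  mass <- pbeta(q_edges[-1L], early_alt + 1, early_total - early_alt + 1) -
    pbeta(q_edges[-(G + 1L)], early_alt + 1, early_total - early_alt + 1)
  if (sum(mass) <= 0) {
    ll <- dbinom(early_alt, early_total,
                 cf$c0 + cf$c1 * grid_centers(G), log = TRUE)
    mass <- exp(ll - max(ll))
  }
  frequency_distribution(grid_centers(G), mass / sum(mass))
}

## ---------------------------------------------------------------------------
## The inference chain: early reads -> founders -> growth -> late reads
## ---------------------------------------------------------------------------

## Founder-count distribution given the early read counts, marginalized
## over the fine-grid posterior on the true early frequency. Support is
## trimmed to founder counts with non-negligible probability.
site_founder_distribution <- function(obs, params) {
  B <- params$bottleneck_size
  post <- fine_early_posterior(obs$early_alt, obs$early_total, params)
  jmin <- qbinom(1e-13, B, post$flo)
  jmax <- min(B, qbinom(1 - 1e-13, B, post$fhi) + 2L)
  js <- jmin:jmax
  M <- outer(post$mids, js, function(f, j) dbinom(j, B, f))
  Pj <- colSums(post$mass * M)
  keep <- Pj > max(Pj) * 1e-16
  list(js = js[keep], Pj = Pj[keep] / sum(Pj[keep]))
}

## The inference chain works on an internal support for the late
## frequency: the exact count support (m/N for m = 1..N) when the final
## population is small enough for the exact dynamic program, otherwise
## the grid-bin centers of the branching-process kernel. Frequency
## exactly zero (no mutant founders) is carried as a separate atom.
chain_support <- function(params) {
  N <- final_population_size(params)
  if (N <= 4096) list(type = "count", freq = seq_len(N) / N, N = as.integer(N))
  else list(type = "bin", freq = grid_centers(params$grid_size), N = N)
}

growth_kernel_vec <- function(j, s, params, support) {
  if (support$type == "bin") return(growth_kernel_probs(j, s, params))
  key <- sprintf("cnt|%d|%d|%d|%.10g", params$bottleneck_size,
                 params$divisions, j, s)
  hit <- .kernel_cache[[key]]
  if (!is.null(hit)) return(hit)
  ## drop the count-0 entry: mutant counts never decrease, so j >= 1
  ## founders place no mass at zero
  v <- growth_pmf_dp(j, params$bottleneck_size, support$N, s)[-1L]
  .kernel_cache[[key]] <- v
  v
}

## Mix growth kernels over founder counts on the chain support.
mix_growth <- function(founder, s, params, support) {
  p_zero <- 0
  vec <- numeric(length(support$freq))
  for (idx in seq_along(founder$js)) {
    j <- founder$js[idx]
    w <- founder$Pj[idx]
    if (j == 0L) p_zero <- p_zero + w
    else vec <- vec + w * growth_kernel_vec(j, s, params, support)
  }
  list(p_zero = p_zero, vec = vec)
}

## P(late_alt = y | support point). On the exact count support this is a
## plain binomial pmf; on bins the pmf is integrated over the read
## probability within the bin (incomplete-beta identity), falling back to
## the bin-center pmf where the integral underflows.
late_support_pmf <- function(y, n, params, support) {
  cf <- read_prob_coef(params)
  if (support$type == "count")
    return(dbinom(y, n, cf$c0 + cf$c1 * support$freq))
  G <- params$grid_size
  q_edges <- cf$c0 + cf$c1 * grid_edges(G)
  dq <- diff(q_edges)
  d <- pbeta(q_edges[-1L], y + 1, n - y + 1) - pbeta(q_edges[-(G + 1L)], y + 1, n - y + 1)
  pmf <- d / ((n + 1) * dq)
  zero <- pmf <= 0
  if (any(zero)) {
    qc <- cf$c0 + cf$c1 * support$freq
    pmf[zero] <- dbinom(y, n, qc[zero])
  }
  pmf
}

## ---------------------------------------------------------------------------
## Drift-null test
## ---------------------------------------------------------------------------

#' Drift-null p-value for an observed early-to-late frequency change
#'
#' Tests whether the change in a site's variant allele frequency between
#' passages is explicable by the bottleneck and neutral stochastic growth
#' alone. The null chain conditions on the early read count
#' ([early_frequency_posterior()]), draws the founder mutant count
#' binomially at the bottleneck, grows the population without selection
#' ([growth_distribution()] with `s = 0`), and samples the late reads
#' binomially through the error model. The p-value is the probability of
#' a late count at least as extreme as observed, one-sided in the
#' direction of the observed frequency change; extreme tails are
#' accumulated in log space.
#'
#' @param obs A [site_observation()] (or a list/1-row data frame with the
#'   same fields).
#' @param params An [experiment_params()] object.
#' @param alpha Significance threshold; defaults to
#'   `bonferroni_alpha(target_bp, fwer)`.
#' @param target_bp Bonferroni denominator, the sequenced target size in
#'   base pairs (default 2.9e5).
#' @param fwer Family-wise error rate (default 0.05).
#' @return An object of class `drift_test`: `p_value`, `log10_p`, `alpha`,
#'   `significant`, `direction` (`"gain"` or `"loss"`).
#' @examples
#' \donttest{
#' drift_pvalue(site_observation("chr9:21974774:A", 0, 725, 156, 282))
#' }
#' @export
drift_pvalue <- function(obs, params = experiment_params(), alpha = NULL,
                         target_bp = 2.9e5, fwer = 0.05) {
  stopifnot(inherits(params, "experiment_params"))
  obs <- as_site_observation(obs)
  if (is.null(alpha)) alpha <- bonferroni_alpha(target_bp, fwer)
  y <- obs$late_alt
  n <- obs$late_total
  gain <- (y / n) >= (obs$early_alt / obs$early_total)

  support <- chain_support(params)
  founder <- site_founder_distribution(obs, params)
  mx <- mix_growth(founder, 0, params, support)
  cf <- read_prob_coef(params)
  qc <- cf$c0 + cf$c1 * support$freq

  log_terms <- c(
    if (mx$p_zero > 0)
      log(mx$p_zero) + pbinom(if (gain) y - 1 else y, n, cf$c0,
                              lower.tail = !gain, log.p = TRUE),
    {
      pos <- mx$vec > 0
      log(mx$vec[pos]) + pbinom(if (gain) y - 1 else y, n, qc[pos],
                                lower.tail = !gain, log.p = TRUE)
    }
  )
  log_p <- min(logsumexp(log_terms), 0)
  structure(list(site_id = obs$site_id,
                 p_value = exp(log_p),
                 log10_p = log_p / log(10),
                 alpha = alpha,
                 significant = exp(log_p) < alpha,
                 direction = if (gain) "gain" else "loss"),
            class = "drift_test")
}

#' @export
print.drift_test <- function(x, ...) {
  cat(sprintf("Drift-null test for %s: p = %.3e (log10 p = %.2f), %s\n",
              x$site_id, x$p_value, x$log10_p, x$direction))
  cat(sprintf("  %s at Bonferroni alpha = %.3g\n",
              if (x$significant) "SIGNIFICANT" else "not significant", x$alpha))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Selection-coefficient likelihood and MLE
## ---------------------------------------------------------------------------

site_loglik_given_chain <- function(founder, binpmf, zeropmf, s, params, support) {
  mx <- mix_growth(founder, s, params, support)
  L <- mx$p_zero * zeropmf + sum(mx$vec * binpmf)
  log(max(L, 1e-300))
}

#' Log-likelihood of a selection coefficient at one site
#'
#' Evaluates \eqn{\log P(\mathrm{late\_alt} \mid \mathrm{late\_total},
#' \mathrm{early\ counts}, s)} under the same chain as [drift_pvalue()],
#' with growth under selection `s` (mutant cells divide with relative
#' weight `1 + s`). Probabilities are floored at 1e-300 so the result is
#' always finite.
#'
#' @param obs A [site_observation()].
#' @param s Selection coefficient in `[-1, 1]`.
#' @param params An [experiment_params()] object.
#' @return The log-likelihood (a single finite number).
#' @export
selection_likelihood <- function(obs, s, params = experiment_params()) {
  stopifnot(inherits(params, "experiment_params"))
  obs <- as_site_observation(obs)
  if (!is.numeric(s) || length(s) != 1L || is.na(s) || s < -1 || s > 1)
    stop("selection coefficient s must lie in [-1, 1]")
  support <- chain_support(params)
  founder <- site_founder_distribution(obs, params)
  binpmf <- late_support_pmf(obs$late_alt, obs$late_total, params, support)
  cf <- read_prob_coef(params)
  zeropmf <- dbinom(obs$late_alt, obs$late_total, cf$c0)
  site_loglik_given_chain(founder, binpmf, zeropmf, s, params, support)
}

#' Maximum-likelihood selection coefficient with likelihood-ratio CI
#'
#' Grid search for the selection coefficient over `s` in `[-1, 1]`
#' maximizing [selection_likelihood()], with a 95% confidence interval
#' from the log-likelihood ratio test (chi-square with 1 degree of
#' freedom: all grid values with `2 * (logL(s_hat) - logL(s)) <= 3.84`).
#' Ties at the maximum resolve to the smallest `|s|`.
#'
#' @param obs A [site_observation()].
#' @param params An [experiment_params()] object.
#' @param grid_step Spacing of the `s` grid (default 0.05).
#' @param conf_level Confidence level of the likelihood-ratio interval
#'   (default 0.95).
#' @return An object of class `selection_estimate`: `s_hat`, `ci_low`,
#'   `ci_high`, and the `profile` data frame of `(s, loglik)` pairs.
#' @examples
#' \donttest{
#' estimate_selection(site_observation("chr9:21974774:A", 0, 725, 156, 282))
#' }
#' @export
estimate_selection <- function(obs, params = experiment_params(),
                               grid_step = 0.05, conf_level = 0.95) {
  stopifnot(inherits(params, "experiment_params"))
  obs <- as_site_observation(obs)
  if (!is.numeric(grid_step) || grid_step <= 0 || grid_step > 1)
    stop("grid_step must lie in (0, 1]")
  ## round grid values to exact decimals so reported estimates and CI
  ## bounds compare cleanly against literals like 0.4
  s_grid <- round(seq(-1, 1, by = grid_step), 10)
  support <- chain_support(params)
  founder <- site_founder_distribution(obs, params)
  binpmf <- late_support_pmf(obs$late_alt, obs$late_total, params, support)
  cf <- read_prob_coef(params)
  zeropmf <- dbinom(obs$late_alt, obs$late_total, cf$c0)
  loglik <- vapply(s_grid, function(s)
    site_loglik_given_chain(founder, binpmf, zeropmf, s, params, support), numeric(1))
  floor_log <- log(1e-300)
  if (all(loglik <= floor_log + 1e-9))
    stop("likelihood underflow: profile is flat at the numeric floor")
  max_ll <- max(loglik)
  maximizers <- s_grid[loglik >= max_ll - 1e-9]
  s_hat <- maximizers[order(abs(maximizers))][1]
  crit <- stats::qchisq(conf_level, df = 1)
  in_ci <- 2 * (max_ll - loglik) <= crit + 1e-9
  structure(list(site_id = obs$site_id,
                 s_hat = s_hat,
                 ci_low = min(s_grid[in_ci]),
                 ci_high = max(s_grid[in_ci]),
                 conf_level = conf_level,
                 profile = data.frame(s = s_grid, loglik = loglik)),
            class = "selection_estimate")
}

#' @export
print.selection_estimate <- function(x, ...) {
  cat(sprintf("Selection estimate for %s: s_hat = %.2f, %d%% CI [%.2f, %.2f]\n",
              x$site_id, x$s_hat, round(100 * x$conf_level),
              x$ci_low, x$ci_high))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Batch interface over site tables
## ---------------------------------------------------------------------------

#' Drift tests and selection estimates for a table of sites
#'
#' Runs [drift_pvalue()] on every row of a site table and, by default,
#' [estimate_selection()] on the sites that are significant at the
#' Bonferroni-corrected threshold (mirroring the study design, where the
#' selection coefficient is only interpreted for sites inconsistent with
#' drift).
#'
#' @param sites Data frame with columns `site_id`, `early_alt`,
#'   `early_total`, `late_alt`, `late_total` (see [read_site_table()]).
#' @param params An [experiment_params()] object.
#' @param target_bp Bonferroni denominator (default 2.9e5).
#' @param fwer Family-wise error rate (default 0.05).
#' @param s_step Selection-grid spacing (default 0.05).
#' @param estimate `"significant"` (default), `"all"`, or `"none"`.
#' @return The input data frame with columns `p_value`, `alpha`,
#'   `significant`, `direction`, `s_hat`, `ci_low`, `ci_high` appended.
#' @export
analyze_sites <- function(sites, params = experiment_params(),
                          target_bp = 2.9e5, fwer = 0.05, s_step = 0.05,
                          estimate = c("significant", "all", "none")) {
  estimate <- match.arg(estimate)
  alpha <- bonferroni_alpha(target_bp, fwer)
  out <- sites
  out$p_value <- NA_real_
  out$alpha <- alpha
  out$significant <- NA
  out$direction <- NA_character_
  out$s_hat <- NA_real_
  out$ci_low <- NA_real_
  out$ci_high <- NA_real_
  for (i in seq_len(nrow(sites))) {
    obs <- as_site_observation(as.list(sites[i, ]))
    dt <- drift_pvalue(obs, params, alpha = alpha)
    out$p_value[i] <- dt$p_value
    out$significant[i] <- dt$significant
    out$direction[i] <- dt$direction
    if (estimate == "all" || (estimate == "significant" && dt$significant)) {
      est <- estimate_selection(obs, params, grid_step = s_step)
      out$s_hat[i] <- est$s_hat
      out$ci_low[i] <- est$ci_low
      out$ci_high[i] <- est$ci_high
    }
  }
  out
}
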