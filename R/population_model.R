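#' @useDynLib clonedrift, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats dbinom pbinom qbinom rbinom pbeta qbeta pgamma qgamma
#'   rgamma rlnorm runif sd median quantile setNames
#' @importFrom utils head read.delim write.table packageVersion modifyList
NULL

## ---------------------------------------------------------------------------
## Distribution containers
## ---------------------------------------------------------------------------

#' Construct a frequency distribution on the standard grid
#'
#' A discrete probability distribution over allele-frequency bins. Bin
#' centers are strictly increasing in \eqn{[0, 1]}; the first bin also
#' carries any mass at frequency exactly 0 (the "zero bin").
#'
#' @param grid Numeric vector of strictly increasing bin centers in `[0,1]`.
#' @param probabilities Matching vector of non-negative probabilities
#'   summing to 1 (within 1e-10; renormalized exactly).
#' @return An object of class `frequency_distribution`.
#' @export
frequency_distribution <- function(grid, probabilities) {
  if (length(grid) != length(probabilities))
    stop("grid and probabilities must have equal length")
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  if (any(grid < 0 | grid > 1)) stop("grid centers must lie in [0, 1]")
  if (any(probabilities < -1e-12)) stop("probabilities must be non-negative")
  probabilities <- pmax(probabilities, 0)
  s <- sum(probabilities)
  if (abs(s - 1) > 1e-10)
    stop(sprintf("probabilities sum to %.12f, not 1", s))
  structure(list(grid = as.numeric(grid),
                 probabilities = probabilities / s),
            class = "frequency_distribution")
}

#' @export
print.frequency_distribution <- function(x, ...) {
  m <- sum(x$grid * x$probabilities)
  v <- sum(x$grid^2 * x$probabilities) - m^2
  cat(sprintf("Frequency distribution on %d bins: mean %.4g, sd %.4g\n",
              length(x$grid), m, sqrt(max(v, 0))))
  invisible(x)
}

#' Distribution of founder mutant-cell counts after the bottleneck
#'
#' Binomial sampling of `bottleneck_size` founder cells from a population
#' with mutant-lineage frequency `f0`: the first transition of the
#' two-stage Markov chain (bottleneck, then growth).
#'
#' @param f0 Mutant-lineage frequency in `[0, 1]` before the bottleneck.
#' @param params An [experiment_params()] object.
#' @return An object of class `founder_distribution`: a list with
#'   `counts` (0..B) and `probabilities`.
#' @examples
#' bd <- bottleneck_distribution(0.05, experiment_params())
#' sum(bd$counts * bd$probabilities)  # ~ 200 * 0.05 = 10
#' @export
bottleneck_distribution <- function(f0, params = experiment_params()) {
  stopifnot(inherits(params, "experiment_params"))
  if (!is.numeric(f0) || length(f0) != 1L || is.na(f0) || f0 < 0 || f0 > 1)
    stop("f0 must be a single frequency in [0, 1]")
  B <- params$bottleneck_size
  structure(list(counts = 0:B, probabilities = dbinom(0:B, B, f0)),
            class = "founder_distribution")
}

#' @export
print.founder_distribution <- function(x, ...) {
  cat(sprintf("Founder distribution over 0..%d mutant cells: mean %.4g\n",
              max(x$counts), sum(x$counts * x$probabilities)))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Growth: exact division-event DP for small populations
## ---------------------------------------------------------------------------

## Exact pmf of the mutant count after the population grows from B to N
## cells by single division events (divider chosen with weight (1+s) for
## mutant, 1 for wild type). Returns a vector over counts 0..N.
growth_pmf_dp <- function(founders, B, N, s) {
  a <- 1 + s
  p <- numeric(N + 1L)
  p[founders + 1L] <- 1
  if (founders == 0L || founders == B) return(p)
  for (n in B:(N - 1L)) {
    m <- 0:n
    w <- a * m
    pm <- w / (w + (n - m))
    cur <- p[1:(n + 1L)]
    p[1:(n + 2L)] <- c(cur * (1 - pm), 0) + c(0, cur * pm)
  }
  p
}

## Map a pmf over counts 0..N to grid-bin probabilities (bin k is
## ((k-1)/G, k/G]; frequency 0 falls in bin 1).
count_pmf_to_bins <- function(pmf, N, grid_size) {
  freq <- (0:N) / N
  bin <- pmax(1L, ceiling(freq * grid_size))
  probs <- numeric(grid_size)
  agg <- rowsum(pmf, group = bin)
  probs[as.integer(rownames(agg))] <- agg[, 1]
  probs
}

## ---------------------------------------------------------------------------
## Growth: Yule branching-process (Gamma race) kernel for large populations
## ---------------------------------------------------------------------------

## The i founder mutant lineages and B-i wild-type lineages grow as
## independent Yule processes with split rates (1+s) and 1. Their scaled
## sizes converge to W_m ~ Gamma(i) and W_w ~ Gamma(B-i); at the time the
## total reaches N the mutant fraction x satisfies
##   W_m v^(1+s) = x N,  W_w v = (1-x) N.
## Eliminating v gives P(F <= x) = E_b[ pgamma(thr(x, b), shape = i) ] with
## thr = x (1-x)^{-a} N^{1-a} b^a, b = W_w. The expectation over b is an
## equal-probability-weight quadrature on Gamma(B-i) quantiles.
race_nodes <- 256L

growth_cdf_race <- function(x, founders, B, N, s) {
  a <- 1 + s
  w <- B - founders
  b <- qgamma((seq_len(race_nodes) - 0.5) / race_nodes, shape = w)
  logx <- log(x)
  log1mx <- log1p(-x)
  ## thr matrix: edges x (rows) by nodes b (cols), built in log space
  lt <- outer(logx - a * log1mx + (1 - a) * log(N), a * log(b), `+`)
  cdf <- rowMeans(pgamma(exp(lt), shape = founders))
  cdf[x <= 0] <- 0
  cdf[x >= 1] <- 1
  cdf
}

growth_probs_race <- function(founders, B, N, s, grid_size) {
  edges <- grid_edges(grid_size)
  cdf <- growth_cdf_race(edges, founders, B, N, s)
  probs <- pmax(diff(cdf), 0)
  probs / sum(probs)
}

## Internal dispatcher producing grid-bin probabilities for one founder
## count, with memoization (the drift test and the selection profile reuse
## the same kernels across sites).
.kernel_cache <- new.env(parent = emptyenv())

growth_kernel_probs <- function(founders, s, params, method = "auto") {
  B <- params$bottleneck_size
  N <- final_population_size(params)
  G <- params$grid_size
  key <- sprintf("%d|%d|%d|%d|%.10g|%s", B, params$divisions, G, founders, s, method)
  hit <- .kernel_cache[[key]]
  if (!is.null(hit)) return(hit)
  probs <-
    if (founders == 0L) {
      c(1, numeric(G - 1L))
    } else if (founders == B) {
      c(numeric(G - 1L), 1)
    } else if (s == -1) {
      ## mutants never divide: frequency is exactly founders / N
      p <- numeric(G)
      p[max(1L, ceiling(founders / N * G))] <- 1
      p
    } else if (method == "dp" || (method == "auto" && N <= 4096)) {
      count_pmf_to_bins(growth_pmf_dp(founders, B, as.integer(N), s), as.integer(N), G)
    } else {
      growth_probs_race(founders, B, N, s, G)
    }
  .kernel_cache[[key]] <- probs
  probs
}

#' Distribution of the mutant frequency after stochastic growth
#'
#' Grows a population of `founders` mutant and `B - founders` wild-type
#' cells to the final size \eqn{B \cdot 2^d} by fitness-proportional
#' division events (mutant cells divide with relative weight `1 + s`), and
#' returns the distribution of the final mutant frequency on the standard
#' grid. Under neutrality (`s = 0`) this distribution converges to
#' Beta(founders, B - founders) and its mean is exactly `founders / B`
#' (the drift martingale).
#'
#' Small final populations (\eqn{B \cdot 2^d \le 4096}) are computed by an
#' exact dynamic program over division events; larger ones use the Yule
#' branching-process limit of the same division process (founder lineages
#' grow as independent Yule processes with rates `1+s` and 1). The
#' event-level Monte Carlo simulator [simulate_growth()] is the reference
#' for both regimes.
#'
#' @param founders Integer mutant founder count in `0..B`.
#' @param params An [experiment_params()] object.
#' @param s Selection coefficient in `[-1, 1]`.
#' @param method `"auto"` (default: exact DP for final size <= 4096, else
#'   branching-process kernel), `"dp"`, or `"asymptotic"`.
#' @return A [frequency_distribution()].
#' @examples
#' gd <- growth_distribution(10, experiment_params(), s = 0)
#' sum(gd$grid * gd$probabilities)  # ~ 10 / 200
#' @export
growth_distribution <- function(founders, params = experiment_params(), s = 0,
                                method = c("auto", "dp", "asymptotic")) {
  stopifnot(inherits(params, "experiment_params"))
  method <- match.arg(method)
  founders <- as.integer(founders)
  B <- params$bottleneck_size
  if (is.na(founders) || founders < 0L || founders > B)
    stop("founders must lie in 0..bottleneck_size")
  if (!is.numeric(s) || length(s) != 1L || is.na(s) || s < -1 || s > 1)
    stop("selection coefficient s must lie in [-1, 1]")
  if (method == "dp" && final_population_size(params) > 2^22)
    stop("final population too large for the exact dynamic program")
  probs <- growth_kernel_probs(founders, s, params, method = method)
  frequency_distribution(grid_centers(params$grid_size), probs)
}

## ---------------------------------------------------------------------------
## Monte Carlo simulation of growth
## ---------------------------------------------------------------------------

## Sample final frequencies from the Gamma-race representation (the
## N -> infinity limit of the division process; accurate to O(1/sqrt(N))).
sample_growth_race <- function(founders, B, N, s, replicates) {
  i <- founders
  w <- B - i
  a <- 1 + s
  if (i == 0L) return(rep(0, replicates))
  if (i == B) return(rep(1, replicates))
  if (a == 0) return(rep(i / N, replicates))
  Wm <- rgamma(replicates, shape = i)
  Ww <- rgamma(replicates, shape = w)
  ## solve Wm e^{a t} + Ww e^{t} = N for t by bisection (h is increasing)
  lo <- pmin(log(N / 2 / Wm) / a, log(N / 2 / Ww))
  hi <- pmin(log(N / Wm) / a, log(N / Ww))
  for (it in 1:80) {
    mid <- (lo + hi) / 2
    h <- Wm * exp(a * mid) + Ww * exp(mid) - N
    above <- h > 0
    hi[above] <- mid[above]
    lo[!above] <- mid[!above]
  }
  t <- (lo + hi) / 2
  pmin(1, pmax(0, Wm * exp(a * t) / N))
}

#' Simulate stochastic growth from the bottleneck
#'
#' Monte Carlo simulation of the division process behind
#' [growth_distribution()]: starting from `founders` mutant cells among
#' `bottleneck_size` founders, one cell divides per event (mutants with
#' relative weight `1 + s`) until the population reaches
#' \eqn{B \cdot 2^d} cells.
#'
#' @param founders Integer mutant founder count in `0..B`.
#' @param params An [experiment_params()] object.
#' @param s Selection coefficient in `[-1, 1]`.
#' @param replicates Number of independent replicates (>= 1).
#' @param seed Integer seed; identical seeds give identical output.
#' @param method `"exact"` runs every division event (compiled); this is
#'   the reference implementation but its cost is proportional to
#'   `replicates * B * 2^divisions`. `"asymptotic"` samples from the Yule
#'   branching-process limit of the same process (error of order
#'   \eqn{1/\sqrt{N}} in the final frequency), which is how full
#'   experimental scales (\eqn{N \approx 6.5} million cells) are handled.
#'   `"auto"` picks `"exact"` whenever the event count is affordable.
#' @return Numeric vector of final mutant frequencies, one per replicate.
#' @examples
#' f <- simulate_growth(10, experiment_params(divisions = 4), s = 0,
#'                      replicates = 1000, seed = 1)
#' mean(f)  # ~ 0.05
#' @export
simulate_growth <- function(founders, params = experiment_params(), s = 0,
                            replicates, seed,
                            method = c("auto", "exact", "asymptotic")) {
  stopifnot(inherits(params, "experiment_params"))
  method <- match.arg(method)
  founders <- as.integer(founders)
  B <- params$bottleneck_size
  if (is.na(founders) || founders < 0L || founders > B)
    stop("founders must lie in 0..bottleneck_size")
  if (!is.numeric(s) || length(s) != 1L || is.na(s) || s < -1 || s > 1)
    stop("selection coefficient s must lie in [-1, 1]")
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L) stop("replicates must be >= 1")
  N <- final_population_size(params)
  if (method == "auto")
    method <- if ((N - B) * replicates <= 2e9) "exact" else "asymptotic"
  with_local_seed(seed, {
    if (method == "exact")
      urn_growth_sim_cpp(founders, B, N, s, replicates)
    else
      sample_growth_race(founders, B, N, s, replicates)
  })
}
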