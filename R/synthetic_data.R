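## ---------------------------------------------------------------------------
## Synthetic paired-passage experiments with known ground truth
## ---------------------------------------------------------------------------

#' Configuration of a synthetic paired-passage experiment
#'
#' Describes a complete in-silico version of the targeted-sequencing
#' experiment: a target region of `n_sites` positions sequenced in an
#' early and a late passage, with a configurable set of true somatic
#' variants that pass through the bottleneck and grow under their own
#' selection coefficients.
#'
#' @param n_sites Number of target positions (default 2.9e5, the target
#'   region size in bp).
#' @param variants `NULL`, or a data frame with columns `pos` (1-based,
#'   unique), `early_freq` (true pre-bottleneck frequency in `[0,1]`) and
#'   `s` (selection coefficient in `[-1,1]`); an optional `alt` column
#'   fixes the variant base.
#' @param mean_depth Mean read depth per site and passage (default 1656).
#' @param depth_sdlog Log-scale standard deviation of the per-site
#'   log-normal depth distribution (default 0.25; 0 gives constant depth).
#' @param params An [experiment_params()] object (bottleneck, divisions,
#'   error rate).
#' @param phred_quality Constant phred quality attached to emitted reads
#'   (default 30, matching the quality floor of the screen).
#' @param seed Integer seed; the whole experiment is a deterministic
#'   function of the configuration.
#' @return A list of class `truth_config`.
#' @export
truth_config <- function(n_sites = 290000L, variants = NULL,
                         mean_depth = 1656, depth_sdlog = 0.25,
                         params = experiment_params(), phred_quality = 30,
                         seed = 1L) {
  stopifnot(inherits(params, "experiment_params"))
  n_sites <- as.integer(n_sites)
  if (is.na(n_sites) || n_sites < 1L) stop("n_sites must be >= 1")
  if (mean_depth < 1) stop("mean_depth must be >= 1")
  if (depth_sdlog < 0) stop("depth_sdlog must be >= 0")
  if (!is.null(variants)) {
    need <- c("pos", "early_freq", "s")
    if (!all(need %in% names(variants)))
      stop("variants must have columns pos, early_freq, s")
    if (anyDuplicated(variants$pos)) stop("variant positions must be unique")
    if (any(variants$pos < 1 | variants$pos > n_sites))
      stop("variant positions must lie in 1..n_sites")
    if (any(variants$early_freq < 0 | variants$early_freq > 1))
      stop("early_freq must lie in [0, 1]")
    if (any(variants$s < -1 | variants$s > 1)) stop("s must lie in [-1, 1]")
  }
  structure(list(n_sites = n_sites, variants = variants,
                 mean_depth = mean_depth, depth_sdlog = depth_sdlog,
                 params = params, phred_quality = phred_quality,
                 seed = as.integer(seed)),
            class = "truth_config")
}

## Sequential conditional binomials so per-site allele counts sum exactly
## to the depth. `probs` is an n x 4 matrix of per-allele read
## probabilities (rows sum to 1).
rmultinom_rows <- function(depth, probs) {
  n <- length(depth)
  counts <- matrix(0L, n, 4L, dimnames = list(NULL, BASES))
  remaining <- depth
  remaining_p <- rep(1, n)
  for (j in 1:3) {
    pj <- ifelse(remaining_p > 0, pmin(1, probs[, j] / remaining_p), 0)
    counts[, j] <- rbinom(n, remaining, pj)
    remaining <- remaining - counts[, j]
    remaining_p <- remaining_p - probs[, j]
  }
  counts[, 4L] <- remaining
  counts
}

## Draw one final frequency for each variant given founder counts, using
## the event-exact simulator when the final population is small and the
## Yule branching-process sampler at full scale. Runs under the caller's
## RNG state (no re-seeding) so the experiment stays deterministic.
draw_growth <- function(founders, s, params) {
  B <- params$bottleneck_size
  N <- final_population_size(params)
  vapply(seq_along(founders), function(i) {
    if (founders[i] == 0L) return(0)
    if (founders[i] == B) return(1)
    if (N <= 65536) urn_growth_sim_cpp(founders[i], B, N, s[i], 1L)
    else sample_growth_race(founders[i], B, N, s[i], 1L)
  }, numeric(1))
}

#' Simulate a complete paired-passage experiment
#'
#' Forward-simulates the whole study design for one sample: every variant
#' site's true early frequency passes through the binomial 200-cell
#' bottleneck, grows under its selection coefficient to the final
#' population, and both passages are sequenced with per-site log-normal
#' depth and the uniform miscall error model; non-variant sites emit
#' error-only reads. The output feeds the screen and the drift/selection
#' inference directly, with a truth table for evaluation.
#'
#' @param config A [truth_config()] object.
#' @return A list of class `synthetic_experiment` with elements
#'   `sites` (a site table for the variant sites, see [read_site_table()]),
#'   `early_pileup` and `late_pileup` (pileup data frames over all sites),
#'   and `truth` (`site_id`, `true_s`, `true_early_freq`, `founders`,
#'   `true_late_freq`).
#' @examples
#' cfg <- truth_config(n_sites = 1000, mean_depth = 200, seed = 7,
#'                     params = experiment_params(divisions = 13))
#' ex <- simulate_experiment(cfg)
#' colSums(ex$early_pileup[c("A", "C", "G", "T")])
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "truth_config"))
  params <- config$params
  n <- config$n_sites
  with_local_seed(config$seed, {
    chrom <- "sim1"
    ref <- sample(BASES, n, replace = TRUE)
    v <- config$variants
    alt <- rep(NA_character_, n)
    f_early <- numeric(n)
    s_true <- numeric(n)
    is_var <- logical(n)
    founders <- integer(n)
    f_late <- numeric(n)
    if (!is.null(v) && nrow(v) > 0) {
      pos_v <- as.integer(v$pos)
      is_var[pos_v] <- TRUE
      f_early[pos_v] <- v$early_freq
      s_true[pos_v] <- v$s
      alt_v <- if ("alt" %in% names(v)) as.character(v$alt) else rep(NA_character_, nrow(v))
      for (k in seq_along(pos_v)) {
        if (is.na(alt_v[k]) || alt_v[k] == ref[pos_v[k]])
          alt_v[k] <- sample(setdiff(BASES, ref[pos_v[k]]), 1L)
      }
      alt[pos_v] <- alt_v
      founders[pos_v] <- rbinom(nrow(v), params$bottleneck_size, v$early_freq)
      f_late[pos_v] <- draw_growth(founders[pos_v], s_true[pos_v], params)
    }

    emit_passage <- function(freq) {
      depth <- if (config$depth_sdlog > 0)
        pmax(1L, as.integer(round(rlnorm(n,
          meanlog = log(config$mean_depth) - config$depth_sdlog^2 / 2,
          sdlog = config$depth_sdlog))))
      else rep(as.integer(round(config$mean_depth)), n)
      ## true composition is fr alternate, (1 - fr) reference; reads keep
      ## their base with probability 1 - eps and miscall uniformly over
      ## the other three bases, so each row of probs sums to exactly 1
      eps <- params$seq_error
      fr <- if (params$diploid) freq / 2 else freq
      probs <- matrix(eps / 3, n, 4L, dimnames = list(NULL, BASES))
      ref_idx <- cbind(seq_len(n), match(ref, BASES))
      probs[ref_idx] <- (1 - fr) * (1 - eps) + fr * eps / 3
      has_alt <- !is.na(alt)
      if (any(has_alt)) {
        alt_idx <- cbind(which(has_alt), match(alt[has_alt], BASES))
        probs[alt_idx] <- fr[has_alt] * (1 - eps) + (1 - fr[has_alt]) * eps / 3
      }
      counts <- rmultinom_rows(depth, probs)
      pu <- data.frame(chrom = chrom, pos = seq_len(n), ref = ref,
                       A = counts[, "A"], C = counts[, "C"],
                       G = counts[, "G"], T = counts[, "T"],
                       stringsAsFactors = FALSE)
      attr(pu, "default_qual") <- config$phred_quality
      pu
    }

    early <- emit_passage(f_early)
    late <- emit_passage(f_late)

    idx <- which(is_var)
    site_id <- if (length(idx) == 0L) character(0)
    else paste(chrom, idx, alt[idx], sep = ":")
    alt_count <- function(pu, i) vapply(seq_along(i), function(k)
      pu[[alt[i[k]]]][i[k]], numeric(1))
    sites <- data.frame(site_id = site_id,
                        early_alt = as.integer(alt_count(early, idx)),
                        early_total = as.integer(pileup_depth(early)[idx]),
                        late_alt = as.integer(alt_count(late, idx)),
                        late_total = as.integer(pileup_depth(late)[idx]),
                        stringsAsFactors = FALSE)
    truth <- data.frame(site_id = site_id,
                        true_s = s_true[idx],
                        true_early_freq = f_early[idx],
                        founders = founders[idx],
                        true_late_freq = f_late[idx],
                        stringsAsFactors = FALSE)
    structure(list(sites = sites, early_pileup = early, late_pileup = late,
                   truth = truth, config = config),
              class = "synthetic_experiment")
  })
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat(sprintf("Synthetic paired-passage experiment: %d sites, %d true variant(s), mean depth %.0f\n",
              x$config$n_sites, nrow(x$truth), x$config$mean_depth))
  invisible(x)
}

#' Simulate a doped (mosaic control) sequencing library
#'
#' Emulates the detection-limit experiment: DNA from a host individual is
#' mixed with a small fraction of DNA from a second (doped-in) individual
#' and sequenced. At each site the allele mixture is the
#' genotype-weighted average of the two individuals, read through the
#' uniform miscall error model.
#'
#' @param spec A [mixture_spec()] object.
#' @param seed Integer seed; output is deterministic given the spec.
#' @return A pileup data frame over the spec's site universe (reference
#'   set to the host's first allele).
#' @export
simulate_doped_library <- function(spec, seed) {
  stopifnot(inherits(spec, "mixture_spec"))
  with_local_seed(seed, {
    host <- spec$host; dope <- spec$dope
    n <- nrow(host)
    eps <- spec$params$seq_error
    phi <- spec$dope_fraction
    geno_frac <- function(g) {
      m <- matrix(0, n, 4L, dimnames = list(NULL, BASES))
      m[cbind(seq_len(n), match(g$allele1, BASES))] <-
        m[cbind(seq_len(n), match(g$allele1, BASES))] + 0.5
      m[cbind(seq_len(n), match(g$allele2, BASES))] <-
        m[cbind(seq_len(n), match(g$allele2, BASES))] + 0.5
      m
    }
    truef <- (1 - phi) * geno_frac(host) + phi * geno_frac(dope)
    ## observed per-allele read probability through the error model
    obs <- truef * (1 - eps) + (1 - truef) * eps / 3
    obs <- obs / rowSums(obs)
    depth <- if (spec$depth_sdlog > 0)
      pmax(1L, as.integer(round(rlnorm(n,
        meanlog = log(spec$depth) - spec$depth_sdlog^2 / 2,
        sdlog = spec$depth_sdlog))))
    else rep(as.integer(round(spec$depth)), n)
    counts <- rmultinom_rows(depth, obs)
    pu <- data.frame(chrom = host$chrom %||% "mix1",
                     pos = host$pos %||% seq_len(n),
                     ref = host$allele1,
                     A = counts[, "A"], C = counts[, "C"],
                     G = counts[, "G"], T = counts[, "T"],
                     site_id = host$site_id,
                     stringsAsFactors = FALSE)
    attr(pu, "default_qual") <- 30
    pu
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
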