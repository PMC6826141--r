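## ---------------------------------------------------------------------------
## Detection limit: sensitivity/specificity on doped DNA mixtures
## ---------------------------------------------------------------------------

#' Specification of a doped (mosaic control) DNA mixture
#'
#' Describes a mixture of host DNA with a small fraction of DNA from a
#' second individual, used to measure the variant screen's limit of
#' detection: sites where the doped-in genotype differs from a homozygous
#' host genotype carry variant alleles at frequency
#' `dope_fraction * copies / 2`.
#'
#' @param host,dope Genotype tables: data frames with columns `site_id`,
#'   `allele1`, `allele2` (A/C/G/T) over the same site universe, in the
#'   same order. Optional `chrom`/`pos` columns are carried through.
#' @param dope_fraction Proportion of input DNA from the doped-in
#'   individual, in `[0, 0.5)` (the experimental libraries used 0.002 and
#'   0.004; 0 gives a pure host library).
#' @param depth Mean sequencing depth (default 2000).
#' @param depth_sdlog Log-normal depth dispersion (default 0, constant).
#' @param params An [experiment_params()] object (supplies the error rate).
#' @return A list of class `mixture_spec`.
#' @export
mixture_spec <- function(host, dope, dope_fraction, depth = 2000,
                         depth_sdlog = 0, params = experiment_params()) {
  for (g in list(host, dope)) {
    if (!all(c("site_id", "allele1", "allele2") %in% names(g)))
      stop("genotype tables need columns site_id, allele1, allele2")
    if (!all(c(g$allele1, g$allele2) %in% BASES))
      stop("genotype alleles must be A/C/G/T")
  }
  if (nrow(host) != nrow(dope) || !all(host$site_id == dope$site_id))
    stop("host and dope genotype tables must share the same site universe")
  if (!is.numeric(dope_fraction) || dope_fraction < 0 || dope_fraction >= 0.5)
    stop("dope_fraction must lie in [0, 0.5)")
  if (depth < 1) stop("depth must be >= 1")
  structure(list(host = host, dope = dope,
                 dope_fraction = dope_fraction,
                 depth = depth, depth_sdlog = depth_sdlog, params = params),
            class = "mixture_spec")
}

#' Sites where the doped-in DNA is expected to produce variant alleles
#'
#' Only sites with a homozygous host genotype are considered; at those, a
#' doped-in allele differing from the host allele is expected at read
#' frequency `dope_fraction * copies / 2` (copies = 1 for a heterozygous,
#' 2 for a homozygous doped-in genotype).
#'
#' @param spec A [mixture_spec()] object.
#' @return Data frame with `site_id`, `alt`, `copies`, `expected_freq`
#'   (one row per expected site/allele).
#' @export
expected_variant_sites <- function(spec) {
  stopifnot(inherits(spec, "mixture_spec"))
  host <- spec$host; dope <- spec$dope
  hom <- host$allele1 == host$allele2
  out <- list()
  for (i in which(hom)) {
    h <- host$allele1[i]
    da <- c(dope$allele1[i], dope$allele2[i])
    diff_alleles <- unique(da[da != h])
    for (a in diff_alleles) {
      copies <- sum(da == a)
      out[[length(out) + 1L]] <- data.frame(
        site_id = host$site_id[i], alt = a, copies = copies,
        expected_freq = spec$dope_fraction * copies / 2,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(site_id = character(0), alt = character(0),
                      copies = integer(0), expected_freq = numeric(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Call variant sites in a doped library
#'
#' Detection rule of the mixture evaluation: at sites with a homozygous
#' host genotype, a non-host allele carrying at least `min_alt` reads is
#' called. (This mirrors the pileup-based detection used for the control
#' libraries; the minimum-count threshold suppresses error-driven calls,
#' which carry very few reads.)
#'
#' @param pileup Pileup data frame from [simulate_doped_library()] (must
#'   carry a `site_id` column).
#' @param host Host genotype table (`site_id`, `allele1`, `allele2`).
#' @param min_alt Minimum alternate read count (default 3).
#' @return Character vector of called `site_id`s.
#' @export
call_mixture_variants <- function(pileup, host, min_alt = 3L) {
  if (!"site_id" %in% names(pileup)) stop("pileup must carry site_id")
  m <- match(pileup$site_id, host$site_id)
  if (anyNA(m)) stop("pileup sites missing from host genotype table")
  hom <- host$allele1[m] == host$allele2[m]
  called <- character(0)
  for (b in BASES) {
    idx <- hom & host$allele1[m] != b & pileup[[b]] >= min_alt
    called <- c(called, pileup$site_id[idx])
  }
  sort(unique(called))
}

#' Sensitivity and specificity of variant detection
#'
#' Sensitivity is the proportion of expected variant sites that were
#' called (true-positive rate); specificity is the proportion of eligible
#' sites with no expected variant that were not called (true-negative
#' rate).
#'
#' @param called Character vector of called site ids.
#' @param expected Character vector of site ids where a variant allele is
#'   expected; must be a subset of `eligible`.
#' @param eligible Character vector of all evaluated site ids (the
#'   denominator universe, e.g. all host-homozygous sites).
#' @return A list with `sensitivity`, `specificity`, `n_expected`,
#'   `n_eligible`. Sensitivity is `NA` (with a warning) when no variant
#'   site is expected.
#' @examples
#' sensitivity_specificity(c("s1", "s2"), c("s1", "s2"), c("s1", "s2", "s3"))
#' @export
sensitivity_specificity <- function(called, expected, eligible) {
  called <- unique(as.character(called))
  expected <- unique(as.character(expected))
  eligible <- unique(as.character(eligible))
  if (!all(expected %in% eligible))
    stop("expected sites must be a subset of eligible sites")
  sens <- if (length(expected) == 0L) {
    warning("no expected variant sites; sensitivity undefined")
    NA_real_
  } else length(intersect(called, expected)) / length(expected)
  negatives <- setdiff(eligible, expected)
  spec <- if (length(negatives) == 0L) NA_real_
  else length(setdiff(negatives, called)) / length(negatives)
  list(sensitivity = sens, specificity = spec,
       n_expected = length(expected), n_eligible = length(eligible))
}

#' Simulate and evaluate one doped-mixture library
#'
#' Convenience wrapper: simulates the mixture library
#' ([simulate_doped_library()]), calls variants
#' ([call_mixture_variants()]), and scores them against the expected
#' sites ([sensitivity_specificity()]) with the host-homozygous sites as
#' the eligible universe.
#'
#' @param spec A [mixture_spec()] object.
#' @param seed Integer seed.
#' @param min_alt Minimum alternate read count for a call (default 3).
#' @return As [sensitivity_specificity()], plus `called`.
#' @export
evaluate_mixture <- function(spec, seed, min_alt = 3L) {
  stopifnot(inherits(spec, "mixture_spec"))
  pu <- simulate_doped_library(spec, seed)
  called <- call_mixture_variants(pu, spec$host, min_alt = min_alt)
  expected <- unique(expected_variant_sites(spec)$site_id)
  eligible <- spec$host$site_id[spec$host$allele1 == spec$host$allele2]
  res <- sensitivity_specificity(called, expected, eligible)
  res$called <- called
  res
}
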