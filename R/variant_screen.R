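## ---------------------------------------------------------------------------
## Somatic-variant screen on paired-passage pileups
## ---------------------------------------------------------------------------
##
## Pileups are data frames with columns chrom, pos (1-based), ref, and
## per-allele read counts A, C, G, T. Optional columns qual_A..qual_T hold
## comma-separated phred base qualities per read; when absent, all reads
## are assumed to carry the constant default quality (the screen operates
## downstream of MQ>=30 / BQ>=30 filtering, so Q30 is the default floor).

BASES <- c("A", "C", "G", "T")

phred_to_error <- function(q) 10^(-q / 10)

#' Quality-aware variant-call p-value at one site
#'
#' Tests whether `alt_count` alternate reads at a site exceed what
#' sequencing error alone would produce. Under the error-only null each
#' read independently shows this particular alternate allele with
#' probability \eqn{10^{-Q/10}/3} (its phred error probability, spread
#' uniformly over the three non-source bases), so the alternate count is
#' Poisson-binomial across the site's reads. The p-value is
#' \eqn{P(X \ge \mathrm{alt\_count})}, computed by exact dynamic-programming
#' convolution (a closed-form binomial when all qualities are equal).
#'
#' @param alt_count Observed reads supporting the alternate allele.
#' @param qualities Phred base qualities of all reads covering the site
#'   (alternate and reference); must be non-empty.
#' @return The p-value (1 when `alt_count` is 0).
#' @examples
#' poisson_binomial_call(1, rep(10, 3))  # 1 - (1 - 0.1/3)^3
#' @export
poisson_binomial_call <- function(alt_count, qualities) {
  if (length(qualities) == 0L) stop("qualities must be non-empty (empty pileup)")
  if (any(qualities < 0 | qualities > 60)) stop("phred qualities must lie in [0, 60]")
  alt_count <- as.integer(alt_count)
  n <- length(qualities)
  if (alt_count > n) stop("alt_count cannot exceed the number of reads")
  if (alt_count <= 0L) return(1)
  e <- phred_to_error(qualities) / 3
  if (length(unique(qualities)) == 1L)
    return(pbinom(alt_count - 1L, n, e[1], lower.tail = FALSE))
  ## DP over P(X <= alt_count - 1): state vector of length alt_count
  v <- c(1, numeric(alt_count - 1L))
  for (ei in e)
    v <- v * (1 - ei) + c(0, head(v, -1L)) * ei
  max(0, min(1, 1 - sum(v)))
}

#' Thresholds controlling the somatic-variant screen
#'
#' @param p_threshold Significance cutoff for the per-allele call
#'   (default 0.01), applied to the multiplicity-corrected p-value.
#' @param min_alt_count Minimum alternate reads for a call (default 3;
#'   validation data show error-driven false positives carry <= 2 reads).
#' @param hom_ref_frac Minimum early-passage reference-allele read
#'   fraction for a site to count as homozygous reference (default 0.98),
#'   the pileup-level surrogate for a diploid genotype call.
#' @param correction Multiple-testing correction applied to the raw
#'   Poisson-binomial p-value before comparing with `p_threshold`, in the
#'   style of the dynamic Bonferroni correction low-frequency callers
#'   apply: `"positions"` (default) multiplies by the number of screened
#'   positions, `"tests"` by the number of (site, allele) tests that
#'   reached `min_alt_count` in that passage, `"none"` uses the raw
#'   p-value.
#' @param default_qual Phred quality assumed for reads when the pileup
#'   carries no per-read qualities (default 30).
#' @return A list of class `screen_thresholds`.
#' @export
screen_thresholds <- function(p_threshold = 0.01, min_alt_count = 3L,
                              hom_ref_frac = 0.98,
                              correction = c("positions", "tests", "none"),
                              default_qual = 30) {
  correction <- match.arg(correction)
  stopifnot(p_threshold > 0, p_threshold < 1, min_alt_count >= 1,
            hom_ref_frac > 0.5, hom_ref_frac <= 1,
            default_qual >= 0, default_qual <= 60)
  structure(list(p_threshold = p_threshold,
                 min_alt_count = as.integer(min_alt_count),
                 hom_ref_frac = hom_ref_frac,
                 correction = correction,
                 default_qual = default_qual),
            class = "screen_thresholds")
}

validate_pileup <- function(pu, label = "pileup") {
  need <- c("chrom", "pos", "ref", BASES)
  miss <- setdiff(need, names(pu))
  if (length(miss) > 0)
    stop(sprintf("%s is missing columns: %s", label, paste(miss, collapse = ", ")))
  if (!all(pu$ref %in% BASES)) stop(sprintf("%s has non-ACGT ref alleles", label))
  counts <- as.matrix(pu[BASES])
  if (any(counts < 0)) stop(sprintf("%s has negative counts", label))
  invisible(pu)
}

pileup_depth <- function(pu) pu$A + pu$C + pu$G + pu$T

site_qualities <- function(pu, row, default_qual) {
  qcols <- paste0("qual_", BASES)
  if (!all(qcols %in% names(pu))) return(NULL)
  qs <- unlist(lapply(qcols, function(cn) {
    x <- pu[[cn]][row]
    if (is.na(x) || !nzchar(x)) numeric(0)
    else as.numeric(strsplit(as.character(x), ",", fixed = TRUE)[[1]])
  }))
  if (length(qs) == 0L) NULL else qs
}

## All (site, allele) tests for one passage: alternate alleles carrying at
## least min_alt_count reads, with raw and multiplicity-corrected p-values.
passage_tests <- function(pu, thresholds) {
  depth <- pileup_depth(pu)
  rows <- integer(0); alleles <- character(0); counts <- integer(0)
  for (b in BASES) {
    idx <- which(pu$ref != b & pu[[b]] >= thresholds$min_alt_count & depth > 0)
    rows <- c(rows, idx)
    alleles <- c(alleles, rep(b, length(idx)))
    counts <- c(counts, pu[[b]][idx])
  }
  n_tests <- length(rows)
  if (n_tests == 0L)
    return(data.frame(row = integer(0), allele = character(0),
                      count = integer(0), depth = integer(0),
                      p_raw = numeric(0), p_adj = numeric(0),
                      called = logical(0)))
  has_quals <- all(paste0("qual_", BASES) %in% names(pu))
  p_raw <- if (has_quals) {
    vapply(seq_len(n_tests), function(k) {
      qs <- site_qualities(pu, rows[k], thresholds$default_qual)
      if (is.null(qs)) qs <- rep(thresholds$default_qual, depth[rows[k]])
      poisson_binomial_call(counts[k], qs)
    }, numeric(1))
  } else {
    e <- phred_to_error(thresholds$default_qual) / 3
    pbinom(counts - 1L, depth[rows], e, lower.tail = FALSE)
  }
  factor <- switch(thresholds$correction,
                   positions = nrow(pu),
                   tests = n_tests,
                   none = 1)
  p_adj <- pmin(1, p_raw * factor)
  data.frame(row = rows, allele = alleles, count = counts,
             depth = depth[rows], p_raw = p_raw, p_adj = p_adj,
             called = p_adj < thresholds$p_threshold,
             stringsAsFactors = FALSE)
}

#' Screen a pair of passages for somatic mutations with frequency change
#'
#' Applies the two-step discovery rule to paired early/late pileups over
#' the same target region: (a) call variant alleles in each passage with
#' the quality-aware error test ([poisson_binomial_call()], corrected for
#' the number of tests performed) at `p_threshold`; (b) retain sites whose
#' variant allele is called in exactly one passage. Sites called in both
#' passages are returned separately for the shared-site outlier check
#' ([shared_site_outliers()]). An SM-V is only eligible if the passage
#' without the call looks homozygous reference (reference-allele read
#' fraction >= `hom_ref_frac`), the pileup-level surrogate for a
#' homozygous host genotype; shared sites are not gated, since the
#' outlier rule evaluates them on frequency change alone.
#'
#' @param early,late Pileup data frames over the same site universe
#'   (`chrom`, `pos`, `ref`, counts `A`,`C`,`G`,`T`, optional
#'   `qual_A`..`qual_T`).
#' @param thresholds A [screen_thresholds()] object.
#' @return A list of class `screen_result` with `smv` (candidate somatic
#'   mutations called in exactly one passage) and `shared` (variant
#'   alleles called in both passages, with per-passage frequencies).
#' @export
screen_pair <- function(early, late, thresholds = screen_thresholds()) {
  stopifnot(inherits(thresholds, "screen_thresholds"))
  validate_pileup(early, "early pileup")
  validate_pileup(late, "late pileup")
  if (nrow(early) != nrow(late) ||
      !all(early$chrom == late$chrom) || !all(early$pos == late$pos) ||
      !all(early$ref == late$ref))
    stop("early and late pileups must cover the same sites in the same order")

  te <- passage_tests(early, thresholds)
  tl <- passage_tests(late, thresholds)
  key_e <- paste(te$row, te$allele)[te$called]
  key_l <- paste(tl$row, tl$allele)[tl$called]

  depth_e <- pileup_depth(early)
  depth_l <- pileup_depth(late)
  ridx <- cbind(seq_len(nrow(early)), match(early$ref, BASES))
  ## host-genotype gate: the passage NOT carrying the call must look
  ## homozygous reference (a germline variant would show in both), so the
  ## screen stays symmetric under passage swapping
  hom_e <- depth_e > 0 &
    as.matrix(early[BASES])[ridx] / pmax(depth_e, 1) >= thresholds$hom_ref_frac
  hom_l <- depth_l > 0 &
    as.matrix(late[BASES])[ridx] / pmax(depth_l, 1) >= thresholds$hom_ref_frac

  build <- function(keys, passage) {
    if (length(keys) == 0L) return(empty_smv())
    parts <- strsplit(keys, " ", fixed = TRUE)
    row <- as.integer(vapply(parts, `[`, "", 1L))
    allele <- vapply(parts, `[`, "", 2L)
    keep <- switch(passage,
                   early = hom_l[row],
                   late = hom_e[row],
                   both = rep(TRUE, length(row)))
    row <- row[keep]; allele <- allele[keep]
    if (length(row) == 0L) return(empty_smv())
    ea <- vapply(seq_along(row), function(k) early[[allele[k]]][row[k]], numeric(1))
    la <- vapply(seq_along(row), function(k) late[[allele[k]]][row[k]], numeric(1))
    pe <- pl <- rep(NA_real_, length(row))
    mt <- match(paste(row, allele), paste(te$row, te$allele))
    pe[!is.na(mt)] <- te$p_adj[mt[!is.na(mt)]]
    mt <- match(paste(row, allele), paste(tl$row, tl$allele))
    pl[!is.na(mt)] <- tl$p_adj[mt[!is.na(mt)]]
    data.frame(site_id = paste(early$chrom[row], early$pos[row], allele, sep = ":"),
               chrom = early$chrom[row], pos = early$pos[row],
               ref = early$ref[row], alt = allele,
               passage_detected = passage,
               early_alt = as.integer(ea), early_total = as.integer(depth_e[row]),
               late_alt = as.integer(la), late_total = as.integer(depth_l[row]),
               p_early = pe, p_late = pl,
               stringsAsFactors = FALSE)
  }

  only_e <- setdiff(key_e, key_l)
  only_l <- setdiff(key_l, key_e)
  both <- intersect(key_e, key_l)
  smv <- rbind(build(only_e, "early"), build(only_l, "late"))
  shared <- build(both, "both")
  if (nrow(smv) > 0) {
    smv$class <- classify_substitution(smv$ref, smv$alt)
    smv <- smv[order(smv$chrom, smv$pos, smv$alt), , drop = FALSE]
    rownames(smv) <- NULL
  }
  if (nrow(shared) > 0) {
    shared$early_freq <- shared$early_alt / shared$early_total
    shared$late_freq <- shared$late_alt / shared$late_total
  } else {
    shared$early_freq <- numeric(0)
    shared$late_freq <- numeric(0)
  }
  structure(list(smv = smv, shared = shared, thresholds = thresholds),
            class = "screen_result")
}

empty_smv <- function() {
  data.frame(site_id = character(0), chrom = character(0), pos = integer(0),
             ref = character(0), alt = character(0),
             passage_detected = character(0),
             early_alt = integer(0), early_total = integer(0),
             late_alt = integer(0), late_total = integer(0),
             p_early = numeric(0), p_late = numeric(0),
             stringsAsFactors = FALSE)
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("Somatic-variant screen: %d candidate SM-V(s), %d shared variant(s)\n",
              nrow(x$smv), nrow(x$shared)))
  if (nrow(x$smv) > 0) print(x$smv[c("site_id", "passage_detected",
                                     "early_alt", "early_total",
                                     "late_alt", "late_total")])
  invisible(x)
}

#' Outlier frequency changes among variants shared by both passages
#'
#' Variant alleles called in both passages are mostly germline or stable
#' mosaic variants; a site whose between-passage frequency difference is
#' an extreme outlier (|difference| above the mean + 3 standard
#' deviations over all shared sites) is recovered as a candidate under
#' selection despite being present in both passages.
#'
#' @param shared Data frame of shared variants with columns `early_freq`
#'   and `late_freq` (as produced in `screen_pair()$shared`).
#' @return The flagged subset (with `passage_detected = "both"`); empty
#'   with a warning when fewer than 2 shared sites are available.
#' @export
shared_site_outliers <- function(shared) {
  if (!all(c("early_freq", "late_freq") %in% names(shared)))
    stop("shared table must have early_freq and late_freq columns")
  if (nrow(shared) < 2L) {
    warning("fewer than 2 shared variant sites; outlier screen skipped")
    return(shared[0, , drop = FALSE])
  }
  delta <- abs(shared$late_freq - shared$early_freq)
  cut <- mean(delta) + 3 * sd(delta)
  out <- shared[delta > cut, , drop = FALSE]
  if (nrow(out) > 0 && "passage_detected" %in% names(out))
    out$passage_detected <- "both"
  rownames(out) <- NULL
  out
}

#' Filter candidates with an excess of neighbors within a window
#'
#' Clustered candidate mutations are a hallmark of alignment artifacts.
#' Adjacent-position candidate pairs are first merged into single
#' dinucleotide events (e.g. CC>TT, the UV-damage signature), then any
#' candidate with more than `max_neighbors` other candidates within
#' `window_bp` on the same chromosome is removed.
#'
#' @param candidates SM-V data frame (sorted by position within
#'   chromosome) with columns `chrom`, `pos`, `ref`, `alt`.
#' @param window_bp Neighborhood half-width in bp (default 50).
#' @param max_neighbors Maximum allowed co-candidates in the window
#'   (default 1).
#' @return The filtered data frame; merged dinucleotide events carry
#'   two-base `ref`/`alt` and `class = "dinucleotide"`.
#' @export
neighborhood_filter <- function(candidates, window_bp = 50, max_neighbors = 1) {
  if (nrow(candidates) == 0L) return(candidates)
  cand <- candidates[order(candidates$chrom, candidates$pos), , drop = FALSE]
  ## merge adjacent-position pairs into dinucleotide events
  drop <- logical(nrow(cand))
  for (i in seq_len(nrow(cand) - 1L)) {
    if (drop[i]) next
    j <- i + 1L
    if (cand$chrom[j] == cand$chrom[i] && cand$pos[j] == cand$pos[i] + 1L &&
        nchar(cand$ref[i]) == 1L && nchar(cand$ref[j]) == 1L) {
      cand$ref[i] <- paste0(cand$ref[i], cand$ref[j])
      cand$alt[i] <- paste0(cand$alt[i], cand$alt[j])
      cand$site_id[i] <- paste(cand$chrom[i], cand$pos[i], cand$alt[i], sep = ":")
      if ("class" %in% names(cand)) cand$class[i] <- "dinucleotide"
      drop[j] <- TRUE
    }
  }
  cand <- cand[!drop, , drop = FALSE]
  n_neighbors <- vapply(seq_len(nrow(cand)), function(i) {
    sum(cand$chrom == cand$chrom[i] & abs(cand$pos - cand$pos[i]) <= window_bp) - 1L
  }, integer(1))
  out <- cand[n_neighbors <= max_neighbors, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a substitution as transition, transversion or dinucleotide
#'
#' Transitions exchange bases within a chemical class (A<->G, C<->T);
#' transversions cross classes. Two-base events (tandem dinucleotide
#' substitutions such as CC>TT, characteristic of UV damage) are labeled
#' `"dinucleotide"`.
#'
#' @param ref,alt Reference and alternate base(s); vectorized.
#' @return Character vector of `"transition"`, `"transversion"` or
#'   `"dinucleotide"`.
#' @examples
#' classify_substitution(c("C", "C", "CC"), c("T", "A", "TT"))
#' @export
classify_substitution <- function(ref, alt) {
  if (length(ref) != length(alt)) stop("ref and alt must have equal length")
  ok_single <- function(x) x %in% BASES
  ok_di <- function(x) nchar(x) == 2L &
    ok_single(substr(x, 1, 1)) & ok_single(substr(x, 2, 2))
  out <- character(length(ref))
  for (i in seq_along(ref)) {
    r <- toupper(ref[i]); a <- toupper(alt[i])
    if (r == a) stop("ref and alt must differ")
    if (ok_single(r) && ok_single(a)) {
      purines <- c("A", "G")
      out[i] <- if ((r %in% purines) == (a %in% purines)) "transition" else "transversion"
    } else if (ok_di(r) && ok_di(a)) {
      out[i] <- "dinucleotide"
    } else {
      stop(sprintf("non-ACGT substitution: %s>%s", r, a))
    }
  }
  out
}
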