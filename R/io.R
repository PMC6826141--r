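## ---------------------------------------------------------------------------
## TSV dialects, configuration files, result writers
## ---------------------------------------------------------------------------

SITE_TABLE_COLS <- c("site_id", "early_alt", "early_total", "late_alt", "late_total")

#' Read a site table of paired-passage allele counts
#'
#' The site-table dialect is a TSV with header columns `site_id`,
#' `early_alt`, `early_total`, `late_alt`, `late_total` (counts mirror a
#' published table's "minor allele count / total count" columns for the
#' initial and final population samples). Every row is validated;
#' errors name the offending row and field.
#'
#' @param path Path to the TSV file.
#' @return A data frame of validated observations (row order preserved).
#' @export
read_site_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("site table not found: %s", path))
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = "character")
  miss <- setdiff(SITE_TABLE_COLS, names(df))
  if (length(miss) > 0)
    stop(sprintf("site table is missing column(s): %s", paste(miss, collapse = ", ")))
  df <- df[SITE_TABLE_COLS]
  for (cn in SITE_TABLE_COLS[-1]) {
    val <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(val) | val != floor(val) | val < 0)
    if (length(bad) > 0)
      stop(sprintf("row %d: field %s is not a non-negative integer (%s)",
                   bad[1], cn, df[[cn]][bad[1]]))
    df[[cn]] <- as.integer(val)
  }
  for (i in seq_len(nrow(df))) {
    res <- tryCatch(validate_site_observation(as.list(df[i, ])),
                    error = function(e) e)
    if (inherits(res, "error"))
      stop(sprintf("row %d: %s", i, conditionMessage(res)))
  }
  df
}

#' Write a site table
#'
#' @param sites Data frame with the site-table columns.
#' @param path Output TSV path.
#' @export
write_site_table <- function(sites, path) {
  miss <- setdiff(SITE_TABLE_COLS, names(sites))
  if (length(miss) > 0)
    stop(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  write.table(sites[SITE_TABLE_COLS], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write analysis results with a reproducibility sidecar
#'
#' Writes the results of [analyze_sites()] as a TSV with a fixed column
#' order and p-values in scientific notation with 3 significant digits,
#' plus a YAML sidecar (`<path>.meta.yaml`) recording the parameters,
#' seed and package version so the file can be regenerated exactly from
#' its inputs.
#'
#' @param results Data frame from [analyze_sites()].
#' @param path Output TSV path.
#' @param params The [experiment_params()] used (recorded in the sidecar).
#' @param seed Seed used for any stochastic step (recorded in the sidecar).
#' @param sidecar Write the metadata sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, params = experiment_params(),
                          seed = NA_integer_, sidecar = TRUE) {
  if (is.null(results)) stop("results must be non-null")
  out <- results
  cols <- intersect(c(SITE_TABLE_COLS, "p_value", "alpha", "significant",
                      "direction", "s_hat", "ci_low", "ci_high"),
                    names(out))
  out <- out[cols]
  for (cn in intersect(c("p_value", "alpha"), cols))
    out[[cn]] <- sprintf("%.2e", out[[cn]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (sidecar) {
    meta <- list(
      tool = "clonedrift",
      version = as.character(packageVersion("clonedrift")),
      seed = if (is.na(seed)) NULL else as.integer(seed),
      params = list(bottleneck_size = params$bottleneck_size,
                    divisions = params$divisions,
                    seq_error = params$seq_error,
                    grid_size = params$grid_size,
                    diploid = params$diploid))
    yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  }
  invisible(path)
}

#' Write and read the pileup TSV dialect
#'
#' Columns: `chrom`, `pos`, `ref`, per-allele counts `A`,`C`,`G`,`T`, and
#' comma-separated per-read phred qualities `qual_A`..`qual_T`. When a
#' pileup has no per-read qualities, constant qualities (the pileup's
#' `default_qual` attribute) are expanded on write.
#'
#' @param pileup Pileup data frame.
#' @param path TSV path.
#' @return `path` (write) or the pileup data frame (read).
#' @export
write_pileup_tsv <- function(pileup, path) {
  validate_pileup(pileup)
  out <- pileup[c("chrom", "pos", "ref", BASES)]
  qcols <- paste0("qual_", BASES)
  if (all(qcols %in% names(pileup))) {
    out[qcols] <- pileup[qcols]
  } else {
    q <- attr(pileup, "default_qual") %||% 30
    for (b in BASES)
      out[[paste0("qual_", b)]] <- vapply(pileup[[b]], function(k)
        paste(rep(q, k), collapse = ","), character(1))
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pileup_tsv
#' @export
read_pileup_tsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("pileup not found: %s", path))
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = "character")
  validate_pileup(within(df, {
    A <- as.integer(A); C <- as.integer(C); G <- as.integer(G); T <- as.integer(T)
  }))
  df$pos <- as.integer(df$pos)
  for (b in BASES) df[[b]] <- as.integer(df[[b]])
  df
}

#' Serialize a frequency distribution to TSV
#'
#' @param dist A [frequency_distribution()].
#' @param path Output path (columns `bin_center`, `probability`).
#' @export
write_frequency_distribution <- function(dist, path) {
  stopifnot(inherits(dist, "frequency_distribution"))
  write.table(data.frame(bin_center = dist$grid, probability = dist$probabilities),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write run configuration files
#'
#' Run configurations are YAML key-value files shared by all subcommands;
#' unknown keys are rejected so typos fail fast. A commented template
#' ships in `system.file("extdata", "config_template.yaml", package =
#' "clonedrift")`.
#'
#' @param path YAML file path.
#' @return A list with `params` (an [experiment_params()]) and the
#'   remaining settings.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config not found: %s", path))
  raw <- yaml::read_yaml(path)
  known <- c("bottleneck_size", "divisions", "seq_error", "grid_size",
             "diploid", "target_bp", "fwer", "s_step", "p_threshold",
             "min_alt_count", "hom_ref_frac", "mean_depth", "depth_sdlog",
             "n_sites", "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0)
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  defaults <- list(target_bp = 2.9e5, fwer = 0.05, s_step = 0.05,
                   p_threshold = 0.01, min_alt_count = 3L, hom_ref_frac = 0.98,
                   mean_depth = 1656, depth_sdlog = 0.25, n_sites = 290000L,
                   seed = 1L)
  cfg <- modifyList(defaults, raw)
  cfg$params <- experiment_params(
    bottleneck_size = raw$bottleneck_size %||% 200L,
    divisions = raw$divisions %||% 15L,
    seq_error = raw$seq_error %||% 1e-3,
    grid_size = raw$grid_size %||% 512L,
    diploid = raw$diploid %||% FALSE)
  cfg
}

#' @rdname read_run_config
#' @param config A list of settings (as returned by [read_run_config()]).
#' @export
write_run_config <- function(config, path) {
  cfg <- config
  if (!is.null(cfg$params)) {
    p <- cfg$params
    cfg$params <- NULL
    cfg <- cfg[setdiff(names(cfg), c("bottleneck_size", "divisions",
                                     "seq_error", "grid_size", "diploid"))]
    cfg <- c(list(bottleneck_size = p$bottleneck_size, divisions = p$divisions,
                  seq_error = p$seq_error, grid_size = p$grid_size,
                  diploid = p$diploid), cfg)
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Export SM-V calls as a minimal VCF
#'
#' Writes an 8-column VCFv4.2 body with `AF_EARLY` and `AF_LATE` INFO
#' fields (allele frequencies per passage) and the detecting passage.
#'
#' @param smv SM-V data frame from [screen_pair()].
#' @param path Output `.vcf` path.
#' @export
write_smv_vcf <- function(smv, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=clonedrift",
    "##INFO=<ID=AF_EARLY,Number=A,Type=Float,Description=\"Variant allele frequency, early passage\">",
    "##INFO=<ID=AF_LATE,Number=A,Type=Float,Description=\"Variant allele frequency, late passage\">",
    "##INFO=<ID=PASSAGE,Number=1,Type=String,Description=\"Passage in which the variant was detected\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(smv) > 0) {
    info <- sprintf("AF_EARLY=%.6g;AF_LATE=%.6g;PASSAGE=%s",
                    smv$early_alt / smv$early_total,
                    smv$late_alt / smv$late_total,
                    smv$passage_detected)
    writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s",
                       smv$chrom, smv$pos, smv$site_id, smv$ref, smv$alt, info),
               con)
  }
  invisible(path)
}
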