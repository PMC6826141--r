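#' Experiment parameters for the bottleneck-and-growth model
#'
#' Bundles the quantities that define the in vitro expansion experiment:
#' the bottleneck size \eqn{B} (cells plated per well), the number of
#' population doublings \eqn{d} during expansion, the per-base sequencing
#' error rate \eqn{\epsilon}, and the resolution of the frequency grid used
#' by the numeric kernels. The final population size is \eqn{B \cdot 2^d}.
#'
#' @param bottleneck_size Integer, number of founder cells sampled at the
#'   bottleneck (default 200, the experimental plating density).
#' @param divisions Integer, population doublings during expansion
#'   (default 15, the midpoint of the experimental 13--17 range).
#' @param seq_error Per-base probability that a sequenced base is miscalled
#'   (default 1e-3, consistent with the Q30 base-quality floor applied to
#'   all read counts). Miscalls are assumed to distribute uniformly over
#'   the three non-source bases.
#' @param grid_size Number of uniform frequency bins on \eqn{[0, 1]} used
#'   by the analytic kernels (default 512).
#' @param diploid Logical; if `TRUE`, the modeled frequency is interpreted
#'   as the fraction of heterozygous cells, so the expected read-level
#'   allele fraction is half the cell fraction. Off by default: allele
#'   frequencies are modeled directly, since observed late frequencies can
#'   exceed the 50% ceiling of a strictly heterozygous-cell model.
#'
#' @return An object of class `experiment_params`.
#' @examples
#' p <- experiment_params()
#' final_population_size(p)
#' @export
experiment_params <- function(bottleneck_size = 200L,
                              divisions = 15L,
                              seq_error = 1e-3,
                              grid_size = 512L,
                              diploid = FALSE) {
  bottleneck_size <- as.integer(bottleneck_size)
  divisions <- as.integer(divisions)
  grid_size <- as.integer(grid_size)
  if (is.na(bottleneck_size) || bottleneck_size < 1L)
    stop("bottleneck_size must be an integer >= 1")
  if (is.na(divisions) || divisions < 1L || divisions > 30L)
    stop("divisions must be an integer in [1, 30]")
  if (!is.numeric(seq_error) || seq_error < 0 || seq_error >= 0.5)
    stop("seq_error must lie in [0, 0.5)")
  if (is.na(grid_size) || grid_size < 64L)
    stop("grid_size must be an integer >= 64")
  structure(
    list(bottleneck_size = bottleneck_size,
         divisions = divisions,
         seq_error = seq_error,
         grid_size = grid_size,
         diploid = isTRUE(diploid)),
    class = "experiment_params"
  )
}

#' @export
print.experiment_params <- function(x, ...) {
  cat("Experiment parameters (bottleneck-and-growth model)\n")
  cat(sprintf("  bottleneck size (B): %d cells\n", x$bottleneck_size))
  cat(sprintf("  divisions (d):       %d (final population %s cells)\n",
              x$divisions, format(final_population_size(x), big.mark = ",")))
  cat(sprintf("  seq error (eps):     %g per base\n", x$seq_error))
  cat(sprintf("  frequency grid:      %d bins\n", x$grid_size))
  if (x$diploid) cat("  ploidy mode:         diploid (read fraction = cell fraction / 2)\n")
  invisible(x)
}

#' Final population size implied by the parameters
#'
#' @param params An [experiment_params()] object.
#' @return `bottleneck_size * 2^divisions` as a double (can exceed
#'   `.Machine$integer.max` for large `divisions`).
#' @export
final_population_size <- function(params) {
  stopifnot(inherits(params, "experiment_params"))
  params$bottleneck_size * 2^params$divisions
}

## Frequency grid helpers: grid_size uniform bins on [0, 1]; bin k covers
## ((k-1)/G, k/G] with bin 1 also holding frequency 0 (the "zero bin").
grid_edges <- function(grid_size) seq(0, 1, length.out = grid_size + 1L)
grid_centers <- function(grid_size) (seq_len(grid_size) - 0.5) / grid_size

## Numerically stable log(sum(exp(x))); -Inf entries are ignored.
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == Inf]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`,
## restoring the caller's .Random.seed afterwards (no global RNG leakage).
with_local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
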