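#' Simulation configuration
#'
#' Bundles every user-facing parameter of a spike-in run and validates the
#' bounds once, up front.
#'
#' @param vaf_low,vaf_high Bounds of the variant allele fraction. In random
#'   selection mode each accepted position is assigned a VAF drawn uniformly
#'   from `[vaf_low, vaf_high]`; in user-specified mode the bounds are only
#'   used to validate the per-position VAFs. Fractions in `(0, 1]`.
#' @param n_snv Number of SNVs to simulate (random mode only; must be `NULL`
#'   in user-specified mode).
#' @param target_coverage Optional target depth. When set, only candidate
#'   positions whose filtered depth lies inside
#'   `[target * (1 - coverage_tolerance), target * (1 + coverage_tolerance)]`
#'   (closed range) are accepted.
#' @param coverage_tolerance Fractional half-width of the coverage window
#'   (default 0.10, i.e. 100x +/- 10).
#' @param min_mq Minimum read mapping quality; aligned segments below this
#'   contribute nothing to pileups and are never mutated (default 20).
#' @param min_bq Minimum base quality at the candidate position, applied the
#'   same way (default 20).
#' @param min_separation Minimum number of intervening bases between two
#'   accepted positions: positions `p1`, `p2` are compatible iff
#'   `abs(p1 - p2) >= min_separation + 1` (default 1, i.e. at least one base
#'   between them).
#' @param seed Integer seed; the whole pipeline consumes a single RNG stream
#'   seeded once, so identical inputs + seed reproduce the run exactly.
#' @param down_sample_coverage Optional average coverage to down-sample the
#'   input BAM to before variant selection.
#' @param include_duplicates Count (and allow mutation of) duplicate-flagged
#'   reads (default `TRUE`).
#' @param verbose Include per-criterion rejection counters in the log.
#'
#' @return An object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(vaf_low = 0.01,
                              vaf_high = 0.10,
                              n_snv = NULL,
                              target_coverage = NULL,
                              coverage_tolerance = 0.10,
                              min_mq = 20L,
                              min_bq = 20L,
                              min_separation = 1L,
                              seed = 1L,
                              down_sample_coverage = NULL,
                              include_duplicates = TRUE,
                              verbose = FALSE) {
  if (!is.numeric(vaf_low) || !is.numeric(vaf_high) ||
      vaf_low <= 0 || vaf_high > 1 || vaf_low > vaf_high) {
    stop("VAF bounds must satisfy 0 < vaf_low <= vaf_high <= 1")
  }
  if (!is.null(n_snv)) {
    n_snv <- as.integer(n_snv)
    if (is.na(n_snv) || n_snv < 1L) stop("n_snv must be a positive integer")
  }
  if (!is.null(target_coverage)) {
    if (target_coverage <= 0) stop("target_coverage must be positive")
  }
  if (coverage_tolerance < 0) stop("coverage_tolerance must be >= 0")
  if (min_mq < 0 || min_bq < 0) stop("quality thresholds must be >= 0")
  min_separation <- as.integer(min_separation)
  if (is.na(min_separation) || min_separation < 0L) {
    stop("min_separation must be a non-negative integer")
  }
  if (!is.null(down_sample_coverage) && down_sample_coverage <= 0) {
    stop("down_sample_coverage must be positive")
  }
  structure(
    list(
      vaf_low = vaf_low,
      vaf_high = vaf_high,
      n_snv = n_snv,
      target_coverage = target_coverage,
      coverage_tolerance = coverage_tolerance,
      min_mq = as.integer(min_mq),
      min_bq = as.integer(min_bq),
      min_separation = min_separation,
      seed = as.integer(seed),
      down_sample_coverage = down_sample_coverage,
      include_duplicates = isTRUE(include_duplicates),
      verbose = isTRUE(verbose)
    ),
    class = "simulation_config"
  )
}

# Closed coverage acceptance range, or NULL when no target is set.
coverage_range <- function(config) {
  if (is.null(config$target_coverage)) {
    return(NULL)
  }
  c(config$target_coverage * (1 - config$coverage_tolerance),
    config$target_coverage * (1 + config$coverage_tolerance))
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Spike-in simulation configuration\n")
  cat(sprintf("  VAF range: [%.4f, %.4f]\n", x$vaf_low, x$vaf_high))
  if (!is.null(x$n_snv)) cat(sprintf("  SNVs requested: %d\n", x$n_snv))
  if (!is.null(x$target_coverage)) {
    rng <- coverage_range(x)
    cat(sprintf("  target coverage: %g (accepted range [%g, %g])\n",
                x$target_coverage, rng[1], rng[2]))
  }
  cat(sprintf("  min MQ %d, min BQ %d, min separation %d, seed %d\n",
              x$min_mq, x$min_bq, x$min_separation, x$seed))
  invisible(x)
}
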