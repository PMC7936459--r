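# Stage 1: choose and validate the positions to mutate.
#
# Candidate positions come either from random draws over the BED footprint
# (uniform over bases, hence regions weighted by length) or from an explicit
# user list. Every candidate is screened against four criteria before it
# becomes a simulation target: it must be mono-allelic at the configured
# MQ/BQ thresholds, lie inside the target coverage window when one is set,
# be far enough from every previously accepted position, and require at
# least one read to be mutated after rounding. User-specified candidates are
# additionally rejected when the requested allele equals the observed
# genotype or the record names a contig absent from the BAM header.

#' Draw variant allele fractions
#'
#' Uniform draws from `[vaf_low, vaf_high]` on the current RNG stream.
#'
#' @param vaf_low,vaf_high VAF bounds, `0 < vaf_low <= vaf_high <= 1`.
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
assign_vaf <- function(vaf_low, vaf_high, n = 1L) {
  if (vaf_low > vaf_high) stop("vaf_low must be <= vaf_high")
  if (vaf_low <= 0 || vaf_high > 1) stop("VAF bounds must lie in (0, 1]")
  stats::runif(n, vaf_low, vaf_high)
}

#' Draw variant alleles
#'
#' Uniform choice among the three bases different from the observed
#' genotype.
#'
#' @param observed_genotype A single base, one of A/C/G/T.
#' @param n Number of draws.
#' @return Character vector of bases, never equal to `observed_genotype`.
#' @export
assign_variant_allele <- function(observed_genotype, n = 1L) {
  if (!observed_genotype %in% .BASES) {
    stop("observed genotype must be a single A/C/G/T base (mono-allelic ",
         "positions only)")
  }
  sample(setdiff(.BASES, observed_genotype), n, replace = TRUE)
}

#' Number of reads to mutate for a VAF at a coverage
#'
#' The product of the assigned VAF and the filtered coverage, rounded half
#' up to the nearest whole number. Positions where this rounds to zero are
#' rejected during selection.
#'
#' @param vaf Variant allele fraction.
#' @param coverage Filtered depth at the position.
#' @return Integer count.
#' @export
reads_to_mutate <- function(vaf, coverage) {
  if (any(coverage < 0)) stop("coverage must be >= 0")
  round_half_up(vaf * coverage)
}

# Fresh per-criterion rejection tally (log accounting).
new_rejection_tally <- function() {
  list(checked = 0L, accepted = 0L,
       existing_variant = 0L, coverage_range = 0L, separation = 0L,
       allele_equals_genotype = 0L, zero_reads = 0L, exceeds_depth = 0L,
       unknown_chrom = 0L)
}

.REJECTION_REASONS <- c("existing_variant", "coverage_range", "separation",
                        "allele_equals_genotype", "zero_reads",
                        "exceeds_depth", "unknown_chrom")

.tally_add <- function(tally, outcome) {
  tally$checked <- tally$checked + 1L
  tally[[outcome]] <- tally[[outcome]] + 1L
  tally
}

#' Screen one candidate position
#'
#' Applies the selection criteria to a pileup summary and either accepts the
#' position (returning a fully specified simulation target) or rejects it
#' with a reason. Criteria are checked in order: existing variant, coverage
#' range, minimum separation, allele-equals-genotype (user mode), zero reads
#' to mutate.
#'
#' @param pileup A [pileup_counts()] summary computed at the config
#'   thresholds.
#' @param config A [simulation_config()].
#' @param vaf The VAF assigned (random mode) or requested (user mode) for
#'   this position.
#' @param accepted_pos Integer vector of already-accepted 0-based positions
#'   on the same chromosome.
#' @param requested_allele Requested variant allele (user mode), or `NULL`
#'   to draw one uniformly among the three non-genotype bases.
#' @return A list with `accepted` (logical), `reason` (`NA` or one of
#'   `existing_variant`, `coverage_range`, `separation`,
#'   `allele_equals_genotype`, `zero_reads`, `exceeds_depth`), and `target`
#'   (a one-row data.frame when accepted).
#' @export
check_position <- function(pileup, config, vaf, accepted_pos = integer(0),
                           requested_allele = NULL) {
  reject <- function(reason) list(accepted = FALSE, reason = reason,
                                  target = NULL)
  n_alleles <- sum(pileup$allele_counts > 0L)
  if (n_alleles >= 2L) {
    return(reject("existing_variant"))
  }
  rng <- coverage_range(config)
  if (!is.null(rng) && (pileup$depth < rng[1] || pileup$depth > rng[2])) {
    return(reject("coverage_range"))
  }
  if (length(accepted_pos) > 0L &&
      any(abs(accepted_pos - pileup$pos) < config$min_separation + 1L)) {
    return(reject("separation"))
  }
  if (!is.null(requested_allele) && !is.na(pileup$observed_genotype) &&
      toupper(requested_allele) == pileup$observed_genotype) {
    return(reject("allele_equals_genotype"))
  }
  n_reads <- reads_to_mutate(vaf, pileup$depth)
  if (n_reads == 0L) {
    return(reject("zero_reads"))
  }
  if (n_reads > pileup$depth) {
    return(reject("exceeds_depth"))
  }
  allele <- if (is.null(requested_allele)) {
    assign_variant_allele(pileup$observed_genotype)
  } else {
    toupper(requested_allele)
  }
  target <- data.frame(
    chrom = pileup$chrom,
    pos = pileup$pos,
    assigned_vaf = vaf,
    requested_vaf = if (is.null(requested_allele)) NA_real_ else vaf,
    variant_allele = allele,
    observed_genotype = pileup$observed_genotype,
    coverage = pileup$depth,
    n_reads = n_reads,
    fwd_count = pileup$fwd_count,
    rev_count = pileup$rev_count,
    stringsAsFactors = FALSE
  )
  list(accepted = TRUE, reason = NA_character_, target = target)
}

.empty_targets <- function() {
  data.frame(chrom = character(0), pos = integer(0),
             assigned_vaf = numeric(0), requested_vaf = numeric(0),
             variant_allele = character(0), observed_genotype = character(0),
             coverage = integer(0), n_reads = integer(0),
             fwd_count = integer(0), rev_count = integer(0),
             stringsAsFactors = FALSE)
}

#' Random variant selection over a BED footprint
#'
#' Draws candidate positions uniformly, without replacement, over every base
#' of the region union (so regions are weighted by length), assigns each a
#' uniform VAF, and screens it with [check_position()] until `config$n_snv`
#' targets are accepted or the footprint is exhausted. Exhaustion returns
#' the partial target list with a warning; the per-criterion tally explains
#' every rejection.
#'
#' @param bam Indexed BAM path.
#' @param regions Regions in 0-based half-open coordinates (data.frame or
#'   `GRanges`).
#' @param config A [simulation_config()] with `n_snv` set.
#' @return A list with `targets` (data.frame, one row per accepted position)
#'   and `tally` (per-criterion rejection counts; `checked == accepted +
#'   sum(rejections)`).
#' @export
select_random_targets <- function(bam, regions, config) {
  if (is.null(config$n_snv)) {
    stop("random variant selection requires n_snv in the configuration")
  }
  gr <- GenomicRanges::reduce(.regions_to_granges(regions))
  chroms <- as.character(GenomicRanges::seqnames(gr))
  starts0 <- GenomicRanges::start(gr) - 1L
  widths <- GenomicRanges::width(gr)
  pos_chrom <- rep(chroms, widths)
  pos0 <- unlist(lapply(seq_along(widths), function(i) {
    starts0[i] + seq_len(widths[i]) - 1L
  }))
  n_total <- length(pos0)
  order <- sample.int(n_total)
  idx <- region_pileup(bam, gr, min_mq = config$min_mq,
                       min_bq = config$min_bq,
                       include_duplicates = config$include_duplicates)

  tally <- new_rejection_tally()
  targets <- list()
  accepted_pos <- list() # chrom -> integer vector
  for (i in order) {
    if (length(targets) >= config$n_snv) break
    chrom <- pos_chrom[i]
    vaf <- assign_vaf(config$vaf_low, config$vaf_high)
    pu <- .pileup_from_index(idx, chrom, pos0[i])
    res <- check_position(pu, config, vaf,
                          accepted_pos = accepted_pos[[chrom]] %||% integer(0))
    if (res$accepted) {
      tally <- .tally_add(tally, "accepted")
      targets[[length(targets) + 1L]] <- res$target
      accepted_pos[[chrom]] <- c(accepted_pos[[chrom]], pu$pos)
    } else {
      tally <- .tally_add(tally, res$reason)
    }
  }
  targets <- if (length(targets) > 0L) {
    do.call(rbind, targets)
  } else {
    .empty_targets()
  }
  if (nrow(targets) < config$n_snv) {
    warning(sprintf(
      paste0("candidate space exhausted: %d of %d requested SNVs accepted ",
             "after checking all %d footprint positions"),
      nrow(targets), config$n_snv, n_total))
  }
  list(targets = targets, tally = tally)
}

#' User-specified variant selection
#'
#' Screens each user record, in file order, with its requested VAF and
#' allele. Records naming a contig absent from the BAM header are rejected
#' under `unknown_chrom`.
#'
#' @param bam Indexed BAM path.
#' @param user_records Parsed user-dialect records (see [parse_bed()]):
#'   `chrom`, `start`, `end`, `vaf`, `allele`.
#' @param config A [simulation_config()].
#' @return As [select_random_targets()].
#' @export
select_user_targets <- function(bam, user_records, config) {
  header_chroms <- names(.bam_targets(bam))
  known <- user_records[user_records$chrom %in% header_chroms, ,
                        drop = FALSE]
  idx <- if (nrow(known) > 0L) {
    region_pileup(bam,
                  data.frame(chrom = known$chrom, start = known$start,
                             end = known$end),
                  min_mq = config$min_mq, min_bq = config$min_bq,
                  include_duplicates = config$include_duplicates)
  } else {
    new.env(parent = emptyenv())
  }
  tally <- new_rejection_tally()
  targets <- list()
  accepted_pos <- list()
  for (i in seq_len(nrow(user_records))) {
    rec <- user_records[i, ]
    if (!rec$chrom %in% header_chroms) {
      tally <- .tally_add(tally, "unknown_chrom")
      next
    }
    pu <- .pileup_from_index(idx, rec$chrom, rec$start)
    res <- check_position(pu, config, rec$vaf,
                          accepted_pos = accepted_pos[[rec$chrom]] %||%
                            integer(0),
                          requested_allele = rec$allele)
    if (res$accepted) {
      tally <- .tally_add(tally, "accepted")
      targets[[length(targets) + 1L]] <- res$target
      accepted_pos[[rec$chrom]] <- c(accepted_pos[[rec$chrom]], pu$pos)
    } else {
      tally <- .tally_add(tally, res$reason)
    }
  }
  targets <- if (length(targets) > 0L) {
    do.call(rbind, targets)
  } else {
    .empty_targets()
  }
  list(targets = targets, tally = tally)
}
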