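# Stage 2: per target, pick criteria-passing reads honouring the original
# strand distribution and the single-use read ledger, then write all
# mutations into a new BAM in one pass.

#' Mutation ledger
#'
#' A set of read identities (`qname` + mate ordinal) already selected for
#' mutation. A read enters the ledger at most once across the whole run, so
#' no aligned segment is ever mutated at more than one offset.
#'
#' @return An empty ledger.
#' @export
new_mutation_ledger <- function() {
  structure(new.env(parent = emptyenv()), class = "mutation_ledger")
}

#' @rdname new_mutation_ledger
#' @param ledger A mutation ledger.
#' @param keys Character vector of read identity keys.
#' @export
ledger_add <- function(ledger, keys) {
  for (k in keys) assign(k, TRUE, envir = ledger)
  invisible(ledger)
}

#' @rdname new_mutation_ledger
#' @export
ledger_has <- function(ledger, keys) {
  vapply(keys, function(k) exists(k, envir = ledger, inherits = FALSE),
         logical(1), USE.NAMES = FALSE)
}

#' @rdname new_mutation_ledger
#' @export
ledger_size <- function(ledger) {
  length(ls(envir = ledger))
}

#' Split a mutation count across strands
#'
#' Allocates `n_mutate` reads between the forward and reverse strands in
#' proportion to the position's original strand counts: `n_fwd =
#' round_half_up(n_mutate * fwd_count / (fwd_count + rev_count))`, the rest
#' reverse. Quotas are capped at the available count per strand with the
#' remainder rebalanced to the other strand; when the total available is
#' below `n_mutate` the returned quota covers what exists and `shortage` is
#' set.
#'
#' @param n_mutate Reads to mutate (>= 1).
#' @param fwd_count,rev_count Strand counts of criteria-passing reads at the
#'   position.
#' @return A list with `n_fwd`, `n_rev`, `shortage`.
#' @export
allocate_strand_quota <- function(n_mutate, fwd_count, rev_count) {
  if (n_mutate < 1L) stop("n_mutate must be >= 1")
  total <- fwd_count + rev_count
  if (total < n_mutate) {
    return(list(n_fwd = as.integer(fwd_count), n_rev = as.integer(rev_count),
                shortage = TRUE))
  }
  n_fwd <- round_half_up(n_mutate * fwd_count / total)
  n_rev <- n_mutate - n_fwd
  if (n_fwd > fwd_count) { # defensive; cannot occur when total >= n_mutate
    n_rev <- n_rev + (n_fwd - fwd_count)
    n_fwd <- fwd_count
  }
  if (n_rev > rev_count) {
    n_fwd <- n_fwd + (n_rev - rev_count)
    n_rev <- rev_count
  }
  list(n_fwd = as.integer(n_fwd), n_rev = as.integer(n_rev),
       shortage = FALSE)
}

#' Select reads to mutate at one target
#'
#' Eligible reads are properly paired, mapped, primary, pass the MQ/BQ
#' thresholds, carry the observed genotype base at the target position (the
#' variant is never stacked on a sequencing-error base), are not under a
#' deletion or soft clip there, and are absent from the ledger. Within each
#' strand the choice is a seeded uniform draw (a shuffle, not positional
#' order). Selected identities enter the ledger immediately. If one strand
#' cannot fill its quota the deficit is rebalanced to the other strand; any
#' remaining deficit is reported as a shortage.
#'
#' @param bam Indexed BAM path.
#' @param target One-row target data.frame from the selection stage.
#' @param quota A quota from [allocate_strand_quota()].
#' @param ledger A [new_mutation_ledger()].
#' @param config A [simulation_config()].
#' @return A list with `reads` (data.frame `qname`, `mate`, `strand`,
#'   `offset`), `n_required`, `n_selected`, `shortage`.
#' @export
select_reads <- function(bam, target, quota, ledger, config) {
  df <- site_reads(bam, target$chrom, target$pos,
                   min_mq = config$min_mq, min_bq = config$min_bq,
                   include_duplicates = config$include_duplicates)
  paired <- bitwAnd(df$flag, .FLAG$PAIRED + .FLAG$PROPER) ==
    .FLAG$PAIRED + .FLAG$PROPER
  keys <- .read_key(df$qname, df$mate)
  eligible <- df[paired &
                   df$base == target$observed_genotype &
                   !ledger_has(ledger, keys), , drop = FALSE]
  n_required <- quota$n_fwd + quota$n_rev

  pick <- function(pool, k) {
    if (nrow(pool) == 0L || k <= 0L) {
      return(pool[integer(0), , drop = FALSE])
    }
    pool[sample.int(nrow(pool))[seq_len(min(k, nrow(pool)))], ,
         drop = FALSE]
  }
  pool_f <- eligible[eligible$strand == "+", , drop = FALSE]
  pool_r <- eligible[eligible$strand == "-", , drop = FALSE]
  sel_f <- pick(pool_f, quota$n_fwd)
  sel_r <- pick(pool_r, quota$n_rev)
  deficit <- n_required - nrow(sel_f) - nrow(sel_r)
  if (deficit > 0L) {
    left_f <- pool_f[!rownames(pool_f) %in% rownames(sel_f), , drop = FALSE]
    extra_f <- pick(left_f, deficit)
    sel_f <- rbind(sel_f, extra_f)
    deficit <- deficit - nrow(extra_f)
  }
  if (deficit > 0L) {
    left_r <- pool_r[!rownames(pool_r) %in% rownames(sel_r), , drop = FALSE]
    extra_r <- pick(left_r, deficit)
    sel_r <- rbind(sel_r, extra_r)
    deficit <- deficit - nrow(extra_r)
  }
  sel <- rbind(sel_f, sel_r)
  ledger_add(ledger, .read_key(sel$qname, sel$mate))
  list(
    reads = sel[, c("qname", "mate", "strand", "offset"), drop = FALSE],
    n_required = as.integer(n_required),
    n_selected = nrow(sel),
    shortage = nrow(sel) < n_required
  )
}

#' Run the variant simulation stage
#'
#' For every target: allocate the strand quota from the position's original
#' strand counts, select reads under the single-use ledger, and record the
#' per-read mutation (identity, offset, variant allele). All mutations are
#' then written in one [write_mutated_bam()] call. A target where fewer
#' reads than required could be mutated is recorded as a shortage, not an
#' error.
#'
#' @param bam Input BAM path.
#' @param targets Target data.frame from the selection stage.
#' @param config A [simulation_config()].
#' @param dest Output BAM path.
#' @return A list with `bam` (output path), `records` (per-target
#'   data.frame: `chrom`, `pos`, `n_required`, `n_mutated`, `n_fwd_mutated`,
#'   `n_rev_mutated`, `shortage`), `mutations` (per-read data.frame), and
#'   the `ledger`.
#' @export
run_simulation <- function(bam, targets, config,
                           dest = tempfile(fileext = ".bam")) {
  ledger <- new_mutation_ledger()
  records <- vector("list", nrow(targets))
  mutations <- vector("list", nrow(targets))
  for (i in seq_len(nrow(targets))) {
    tg <- targets[i, ]
    quota <- allocate_strand_quota(tg$n_reads, tg$fwd_count, tg$rev_count)
    sel <- select_reads(bam, tg, quota, ledger, config)
    records[[i]] <- data.frame(
      chrom = tg$chrom, pos = tg$pos,
      n_required = tg$n_reads,
      n_mutated = sel$n_selected,
      n_fwd_mutated = sum(sel$reads$strand == "+"),
      n_rev_mutated = sum(sel$reads$strand == "-"),
      shortage = sel$shortage || quota$shortage,
      stringsAsFactors = FALSE
    )
    if (nrow(sel$reads) > 0L) {
      mutations[[i]] <- data.frame(
        qname = sel$reads$qname,
        mate = sel$reads$mate,
        offset = sel$reads$offset,
        alt = tg$variant_allele,
        chrom = tg$chrom,
        pos = tg$pos,
        strand = sel$reads$strand,
        stringsAsFactors = FALSE
      )
    }
  }
  records <- if (nrow(targets) > 0L) {
    do.call(rbind, records)
  } else {
    data.frame(chrom = character(0), pos = integer(0),
               n_required = integer(0), n_mutated = integer(0),
               n_fwd_mutated = integer(0), n_rev_mutated = integer(0),
               shortage = logical(0), stringsAsFactors = FALSE)
  }
  mutations <- do.call(rbind, mutations[!vapply(mutations, is.null,
                                                logical(1))])
  if (is.null(mutations)) {
    mutations <- data.frame(qname = character(0), mate = integer(0),
                            offset = integer(0), alt = character(0),
                            chrom = character(0), pos = integer(0),
                            strand = character(0), stringsAsFactors = FALSE)
  }
  out <- write_mutated_bam(bam, mutations, dest)
  list(bam = out, records = records, mutations = mutations, ledger = ledger)
}
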