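# Read-level BAM access: filtered per-position read tables and allele
# counts, average coverage over regions, fragment-level down-sampling, and
# writing a mutated copy of a BAM.
#
# All positions in this package are 0-based; the 1-based SAM convention is
# confined to this file and to the CIGAR walk.

#' Criteria-passing reads overlapping one position
#'
#' Returns one row per primary aligned segment that carries a counted base at
#' `pos`: mapped, not secondary, not supplementary, mapping quality `>=
#' min_mq`, base quality at the position `>= min_bq`, and an A/C/G/T base
#' aligned at the position (segments with a deletion or reference skip there
#' contribute nothing). Overlapping mates of one fragment are two independent
#' segments and both appear.
#'
#' @param bam Path to a coordinate-sorted, indexed BAM file.
#' @param chrom Reference sequence name (must exist in the BAM header).
#' @param pos 0-based position.
#' @param min_mq,min_bq Inclusive quality thresholds.
#' @param include_duplicates Keep duplicate-flagged segments (default `TRUE`).
#'
#' @return A data.frame with columns `qname`, `mate` (1/2, or 0 when
#'   unpaired), `flag`, `strand` (`"+"`/`"-"`), `mapq`, `base`, `bq`,
#'   `offset` (0-based offset of the position within SEQ as stored).
#' @export
site_reads <- function(bam, chrom, pos, min_mq = 0L, min_bq = 0L,
                       include_duplicates = TRUE) {
  .check_chrom(bam, chrom)
  empty <- data.frame(
    qname = character(0), mate = integer(0), flag = integer(0),
    strand = character(0), mapq = integer(0), base = character(0),
    bq = integer(0), offset = integer(0), stringsAsFactors = FALSE
  )
  if (pos < 0) {
    return(empty)
  }
  which <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, pos + 1L))
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE,
    isDuplicate = if (include_duplicates) NA else FALSE
  )
  param <- Rsamtools::ScanBamParam(
    which = which, flag = flag,
    what = c("qname", "flag", "mapq", "pos", "cigar", "seq", "qual")
  )
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  n <- length(res$qname)
  if (n == 0L) {
    return(empty)
  }
  # fast path for plain match CIGARs; full walk otherwise
  simple <- grepl("^[0-9]+M$", res$cigar)
  offs <- integer(n)
  offs[simple] <- pos + 1L - res$pos[simple]
  len <- as.integer(sub("M$", "", res$cigar[simple]))
  offs[simple][offs[simple] < 0L | offs[simple] >= len] <- NA_integer_
  if (any(!simple)) {
    offs[!simple] <- query_offsets_at(res$cigar[!simple], res$pos[!simple],
                                      pos + 1L)
  }
  keep <- !is.na(offs)
  if (!any(keep)) {
    return(empty)
  }
  seqs <- as.character(res$seq)[keep]
  quals <- as.character(res$qual)[keep]
  offs <- offs[keep]
  base <- substr(seqs, offs + 1L, offs + 1L)
  bq <- utf8ToInt(paste(substr(quals, offs + 1L, offs + 1L),
                        collapse = "")) - 33L
  out <- data.frame(
    qname = res$qname[keep],
    mate = .mate_ordinal(res$flag[keep]),
    flag = res$flag[keep],
    strand = ifelse(.is_reverse(res$flag[keep]), "-", "+"),
    mapq = res$mapq[keep],
    base = toupper(base),
    bq = bq,
    offset = offs,
    stringsAsFactors = FALSE
  )
  out <- out[out$mapq >= min_mq & out$bq >= min_bq & out$base %in% .BASES, ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filtered pileup allele counts at one position
#'
#' Depth, per-base allele counts and forward/reverse strand counts at a
#' single position after mapping- and base-quality filtering, plus the
#' observed genotype (the single base seen when the position is
#' mono-allelic, `"MULTI"` when two or more alleles pass the filters, `NA`
#' at depth 0).
#'
#' @inheritParams site_reads
#' @return An object of class `pileup_summary`: a list with `chrom`, `pos`
#'   (0-based), `depth`, `allele_counts` (named integer vector over
#'   A/C/G/T), `fwd_count`, `rev_count`, `observed_genotype`.
#' @export
pileup_counts <- function(bam, chrom, pos, min_mq = 20L, min_bq = 20L,
                          include_duplicates = TRUE) {
  df <- site_reads(bam, chrom, pos, min_mq = min_mq, min_bq = min_bq,
                   include_duplicates = include_duplicates)
  counts <- vapply(.BASES, function(b) sum(df$base == b), integer(1))
  depth <- sum(counts)
  seen <- names(counts)[counts > 0L]
  genotype <- if (depth == 0L) {
    NA_character_
  } else if (length(seen) == 1L) {
    seen
  } else {
    "MULTI"
  }
  structure(
    list(
      chrom = chrom,
      pos = as.integer(pos),
      depth = as.integer(depth),
      allele_counts = counts,
      fwd_count = sum(df$strand == "+"),
      rev_count = sum(df$strand == "-"),
      observed_genotype = genotype
    ),
    class = "pileup_summary"
  )
}

#' @export
print.pileup_summary <- function(x, ...) {
  cat(sprintf("%s:%d depth %d (%s) fwd/rev %d/%d genotype %s\n",
              x$chrom, x$pos, x$depth,
              paste(sprintf("%s=%d", names(x$allele_counts),
                            x$allele_counts), collapse = " "),
              x$fwd_count, x$rev_count, x$observed_genotype))
  invisible(x)
}

#' Average filtered coverage over regions
#'
#' Mean quality-filtered depth over every base in the union of `regions`;
#' bases covered by no read count as depth 0. Only A/C/G/T bases passing the
#' MQ/BQ thresholds contribute, matching [pileup_counts()].
#'
#' @param bam Indexed BAM path.
#' @param regions A `GRanges`, or a data.frame with `chrom`/`start`/`end`
#'   columns in 0-based half-open (BED) coordinates.
#' @inheritParams site_reads
#' @return A single numeric value.
#' @export
average_coverage <- function(bam, regions, min_mq = 20L, min_bq = 20L,
                             include_duplicates = TRUE) {
  gr <- .regions_to_granges(regions)
  if (length(gr) == 0L) {
    stop("regions must be non-empty")
  }
  gr <- GenomicRanges::reduce(gr)
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE,
    isDuplicate = if (include_duplicates) NA else FALSE
  )
  pp <- Rsamtools::PileupParam(
    max_depth = 1000000L,
    min_base_quality = as.integer(min_bq),
    min_mapq = as.integer(min_mq),
    min_nucleotide_depth = 1L,
    distinguish_strands = FALSE,
    distinguish_nucleotides = TRUE,
    include_deletions = FALSE,
    include_insertions = FALSE
  )
  p <- Rsamtools::pileup(
    bam,
    scanBamParam = Rsamtools::ScanBamParam(which = gr, flag = flag),
    pileupParam = pp
  )
  p <- p[p$nucleotide %in% .BASES, , drop = FALSE]
  sum(p$count) / sum(GenomicRanges::width(gr))
}

# Batched filtered pileup over many positions in one htslib pass. Returns a
# lookup environment keyed by "chrom#pos0" holding, per position, the same
# quantities as pileup_counts(); positions absent from the table have depth
# 0. Semantically identical to per-position pileup_counts() (asserted by the
# test suite), but orders of magnitude faster when screening thousands of
# candidate positions.
region_pileup <- function(bam, regions, min_mq = 20L, min_bq = 20L,
                          include_duplicates = TRUE) {
  gr <- GenomicRanges::reduce(.regions_to_granges(regions))
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE,
    isDuplicate = if (include_duplicates) NA else FALSE
  )
  pp <- Rsamtools::PileupParam(
    max_depth = 1000000L,
    min_base_quality = as.integer(min_bq),
    min_mapq = as.integer(min_mq),
    min_nucleotide_depth = 1L,
    distinguish_strands = TRUE,
    distinguish_nucleotides = TRUE,
    include_deletions = FALSE,
    include_insertions = FALSE
  )
  p <- Rsamtools::pileup(
    bam,
    scanBamParam = Rsamtools::ScanBamParam(which = gr, flag = flag),
    pileupParam = pp
  )
  p <- p[p$nucleotide %in% .BASES, , drop = FALSE]
  idx <- new.env(parent = emptyenv())
  if (nrow(p) > 0L) {
    key <- paste0(as.character(p$seqnames), "#", p$pos - 1L)
    nuc <- as.character(p$nucleotide)
    fwd <- p$strand == "+"
    for (grp in split(seq_len(nrow(p)), key)) {
      counts <- vapply(.BASES, function(b)
        sum(p$count[grp][nuc[grp] == b]), integer(1))
      assign(key[grp[1]], list(
        counts = counts,
        fwd = sum(p$count[grp][fwd[grp]]),
        rev = sum(p$count[grp][!fwd[grp]])
      ), envir = idx)
    }
  }
  idx
}

# Assemble a pileup_summary from a region_pileup() lookup.
.pileup_from_index <- function(idx, chrom, pos) {
  key <- paste0(chrom, "#", pos)
  entry <- if (exists(key, envir = idx, inherits = FALSE)) {
    get(key, envir = idx, inherits = FALSE)
  } else {
    list(counts = stats::setNames(integer(4), .BASES), fwd = 0L, rev = 0L)
  }
  depth <- sum(entry$counts)
  seen <- names(entry$counts)[entry$counts > 0L]
  structure(
    list(chrom = chrom, pos = as.integer(pos), depth = as.integer(depth),
         allele_counts = entry$counts,
         fwd_count = as.integer(entry$fwd),
         rev_count = as.integer(entry$rev),
         observed_genotype = if (depth == 0L) NA_character_
                             else if (length(seen) == 1L) seen
                             else "MULTI"),
    class = "pileup_summary"
  )
}

#' Down-sample a BAM to a target average coverage
#'
#' Estimates the current average coverage over `regions`, then retains each
#' read fragment (both mates together, keyed on the query name) independently
#' with probability `p = target_coverage / current`. When `p >= 1` the input
#' is copied unchanged and a warning is raised. The output is
#' coordinate-sorted and indexed.
#'
#' @inheritParams average_coverage
#' @param target_coverage Desired average coverage (> 0).
#' @param seed Integer seed for the retention draws.
#' @param dest Output BAM path (ending in `.bam`).
#' @return The output BAM path, invisibly gaining a `.bai` index alongside.
#' @export
downsample_bam <- function(bam, regions, target_coverage,
                           min_mq = 20L, min_bq = 20L, seed = 1L,
                           dest = tempfile(fileext = ".bam")) {
  if (target_coverage <= 0) stop("target_coverage must be positive")
  current <- average_coverage(bam, regions, min_mq = min_mq, min_bq = min_bq)
  if (current <= 0) stop("current average coverage over regions is zero")
  p <- target_coverage / current
  if (p >= 1) {
    warning(sprintf(
      "target coverage %.1f >= current coverage %.1f; copying input unchanged",
      target_coverage, current))
    file.copy(bam, dest, overwrite = TRUE)
    Rsamtools::indexBam(dest)
    return(dest)
  }
  sam <- Rsamtools::asSam(bam, tempfile())
  on.exit(unlink(c(sam)), add = TRUE)
  lines <- readLines(sam)
  is_hdr <- startsWith(lines, "@")
  recs <- lines[!is_hdr]
  qn <- sub("\t.*$", "", recs)
  uq <- unique(qn)
  keep_q <- with_seed(seed, uq[stats::runif(length(uq)) < p])
  out_sam <- tempfile(fileext = ".sam")
  on.exit(unlink(out_sam), add = TRUE)
  writeLines(c(lines[is_hdr], recs[qn %in% keep_q]), out_sam)
  .sam_to_bam(out_sam, dest)
}

#' Write a mutated copy of a BAM
#'
#' Replaces one base of SEQ in each targeted primary aligned segment, leaving
#' every other field (POS, CIGAR, MAPQ, FLAG, mate information, the base
#' quality string, tags) and every untouched read byte-identical. Reads are
#' not realigned. The output is coordinate-sorted and indexed.
#'
#' @param bam Input BAM path.
#' @param mutations A data.frame with one row per segment to mutate:
#'   `qname`, `mate` (1/2, or 0 for unpaired), `offset` (0-based offset into
#'   SEQ as stored), `alt` (replacement base). Each (`qname`, `mate`)
#'   identity may appear at most once (single-use read contract).
#' @param dest Output BAM path.
#' @return `dest`, with a `.bai` index alongside.
#' @export
write_mutated_bam <- function(bam, mutations,
                              dest = tempfile(fileext = ".bam")) {
  stopifnot(is.data.frame(mutations),
            all(c("qname", "mate", "offset", "alt") %in% names(mutations)) ||
              nrow(mutations) == 0L)
  if (nrow(mutations) > 0L) {
    keys <- .read_key(mutations$qname, mutations$mate)
    if (anyDuplicated(keys)) {
      stop("duplicate read identities in mutation set: ",
           paste(unique(keys[duplicated(keys)]), collapse = ", "))
    }
    if (!all(toupper(mutations$alt) %in% .BASES)) {
      stop("variant alleles must be A, C, G or T")
    }
  } else {
    keys <- character(0)
  }
  sam <- Rsamtools::asSam(bam, tempfile())
  on.exit(unlink(sam), add = TRUE)
  lines <- readLines(sam)
  is_hdr <- startsWith(lines, "@")
  rec_idx <- which(!is_hdr)
  if (nrow(mutations) > 0L && length(rec_idx) > 0L) {
    fields <- strsplit(lines[rec_idx], "\t", fixed = TRUE)
    qnames <- vapply(fields, `[[`, character(1), 1L)
    flags <- as.integer(vapply(fields, `[[`, character(1), 2L))
    primary <- bitwAnd(flags, .FLAG$SECONDARY + .FLAG$SUPPLEMENTARY) == 0L
    rec_keys <- .read_key(qnames, .mate_ordinal(flags))
    hit <- match(rec_keys, keys)
    hit[!primary] <- NA_integer_
    applied <- logical(nrow(mutations))
    for (j in which(!is.na(hit))) {
      m <- hit[j]
      fl <- fields[[j]]
      seq <- fl[[10]]
      off <- mutations$offset[m]
      if (off < 0L || off >= nchar(seq)) {
        stop(sprintf("offset %d outside read %s (length %d)",
                     off, rec_keys[j], nchar(seq)))
      }
      substr(seq, off + 1L, off + 1L) <- toupper(mutations$alt[m])
      fl[[10]] <- seq
      lines[rec_idx[j]] <- paste(fl, collapse = "\t")
      applied[m] <- TRUE
    }
    if (!all(applied)) {
      stop("mutation target reads not found as primary alignments: ",
           paste(keys[!applied], collapse = ", "))
    }
  }
  out_sam <- tempfile(fileext = ".sam")
  on.exit(unlink(out_sam), add = TRUE)
  writeLines(lines, out_sam)
  .sam_to_bam(out_sam, dest)
}

# SAM text -> sorted, indexed BAM at `dest` (a path ending in .bam).
.sam_to_bam <- function(sam, dest) {
  stem <- sub("\\.bam$", "", dest)
  out <- Rsamtools::asBam(sam, stem, overwrite = TRUE,
                          indexDestination = TRUE)
  out
}
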