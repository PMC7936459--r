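# Deterministic synthetic paired-end fixture generator.
#
# The generator exists so that every expected pileup is exactly computable:
# reads are error-free copies of a seeded pseudo-random reference, tiled so
# that every interior position of a focal zone has exactly `depth` covering
# segments with an exactly controlled forward-strand fraction. First mates
# tile the focal zone; their mates are placed in a disjoint downstream zone
# so that focal-zone pileups are never contaminated by mate overlap.
# Sequencing-error realism is deliberately out of scope: the point of
# spiking variants into an existing BAM is to inherit realism from real
# data, and the fixture's job is to make truth exactly checkable.

#' Fixture specification
#'
#' @param contig Contig name.
#' @param focal_width Width (bp) of the focal zone tiled by first mates; the
#'   generated BED covers its interior `[read_length, focal_width -
#'   read_length)`.
#' @param read_length Read length (bp).
#' @param depth Exact fold-coverage at interior focal positions. Must divide
#'   evenly into the tiling (`read_length` and `depth` are reconciled via
#'   their gcd), and be a multiple of 10 unless `strand_fraction_fwd` is 0,
#'   0.5 or 1.
#' @param strand_fraction_fwd Fraction of focal-zone segments on the forward
#'   strand, exact at every interior position; a multiple of 0.1.
#' @param base_quality Constant Phred base quality of ordinary reads.
#' @param mapping_quality Constant mapping quality of ordinary reads.
#' @param planted_variants Optional data.frame (`pos`, `alt`, `fraction`)
#'   of pre-existing variants: at 0-based focal position `pos`, a fraction
#'   of covering first mates carry `alt` instead of the reference base.
#' @param low_quality_fraction Fraction of focal segments downgraded to
#'   `low_mq`/`low_bq` (to exercise the quality filters).
#' @param low_mq,low_bq Qualities of the downgraded subset.
#' @param duplicate_fraction Fraction of fragments duplicated with the SAM
#'   duplicate flag set.
#' @param seed Integer seed; the fixture is byte-reproducible under it.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(contig = "sim1",
                         focal_width = 2000L,
                         read_length = 100L,
                         depth = 100L,
                         strand_fraction_fwd = 0.5,
                         base_quality = 30L,
                         mapping_quality = 60L,
                         planted_variants = NULL,
                         low_quality_fraction = 0,
                         low_mq = 5L,
                         low_bq = 10L,
                         duplicate_fraction = 0,
                         seed = 1L) {
  focal_width <- as.integer(focal_width)
  read_length <- as.integer(read_length)
  depth <- as.integer(depth)
  if (depth < 1L) stop("depth must be >= 1")
  if (focal_width < 3L * read_length) {
    stop("focal_width must be at least 3 * read_length")
  }
  f10 <- strand_fraction_fwd * 10
  if (abs(f10 - round(f10)) > 1e-9) {
    stop("strand_fraction_fwd must be a multiple of 0.1")
  }
  if (!strand_fraction_fwd %in% c(0, 0.5, 1) && depth %% 10L != 0L) {
    stop("depth must be a multiple of 10 for this strand_fraction_fwd")
  }
  g <- .gcd(depth, read_length)
  step <- read_length %/% g
  per_start <- depth %/% g
  if (!is.null(planted_variants)) {
    stopifnot(is.data.frame(planted_variants),
              all(c("pos", "alt", "fraction") %in% names(planted_variants)))
    interior <- c(read_length, focal_width - read_length)
    if (any(planted_variants$pos < interior[1] |
            planted_variants$pos >= interior[2])) {
      stop("planted variant positions must lie in the focal interior")
    }
  }
  structure(
    list(
      contig = contig, focal_width = focal_width,
      read_length = read_length, depth = depth,
      step = step, per_start = per_start,
      strand_fraction_fwd = strand_fraction_fwd,
      base_quality = as.integer(base_quality),
      mapping_quality = as.integer(mapping_quality),
      planted_variants = planted_variants,
      low_quality_fraction = low_quality_fraction,
      low_mq = as.integer(low_mq), low_bq = as.integer(low_bq),
      duplicate_fraction = duplicate_fraction,
      seed = as.integer(seed)
    ),
    class = "fixture_spec"
  )
}

.gcd <- function(a, b) if (b == 0L) a else .gcd(b, a %% b)

#' Generate a reference FASTA, sorted+indexed BAM, and BED fixture
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @param name Basename for the three files.
#' @return A list with `fasta`, `bam`, `bed` paths, the `spec`, the contig
#'   `length`, and `interior` (0-based half-open focal interval with exact
#'   depth and strand fraction, also the extent of the BED).
#' @export
generate_fixture <- function(spec, dir = tempfile("fixture"),
                             name = "fixture") {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  L <- spec$read_length
  W <- spec$focal_width
  moff <- W + 2L * L # distance between mate starts; mate zones disjoint
  contig_len <- moff + W + 2L * L

  with_seed(spec$seed, {
    ref <- sample(.BASES, contig_len, replace = TRUE)

    starts <- seq(0L, W - spec$step, by = spec$step)
    frag_start <- rep(starts, each = spec$per_start)
    nfrag <- length(frag_start)
    idx <- seq_len(nfrag) - 1L

    nfwd10 <- as.integer(round(10 * spec$strand_fraction_fwd))
    fwd1 <- (idx %% 10L) < nfwd10

    seq1 <- vapply(frag_start,
                   function(s) paste(ref[(s + 1L):(s + L)], collapse = ""),
                   character(1))
    start2 <- frag_start + moff
    seq2 <- vapply(start2,
                   function(s) paste(ref[(s + 1L):(s + L)], collapse = ""),
                   character(1))

    # pre-existing variants: first round(fraction * depth) covering first
    # mates (by fragment index) carry the alternate base
    if (!is.null(spec$planted_variants)) {
      for (k in seq_len(nrow(spec$planted_variants))) {
        pv <- spec$planted_variants[k, ]
        covering <- which(frag_start > pv$pos - L & frag_start <= pv$pos)
        n_mut <- round_half_up(pv$fraction * length(covering))
        for (i in utils::head(covering, n_mut)) {
          off <- pv$pos - frag_start[i]
          substr(seq1[i], off + 1L, off + 1L) <- toupper(pv$alt)
        }
      }
    }

    mapq <- rep(spec$mapping_quality, nfrag)
    bq_char <- intToUtf8(33L + spec$base_quality)
    qual1 <- rep(strrep(bq_char, L), nfrag)
    if (spec$low_quality_fraction > 0) {
      nlow <- round_half_up(spec$low_quality_fraction * nfrag)
      low <- sample.int(nfrag, nlow)
      mapq[low] <- spec$low_mq
      qual1[low] <- strrep(intToUtf8(33L + spec$low_bq), L)
    }

    qname <- sprintf("f%06d", idx)
    flag1 <- 1L + 2L + 64L +
      ifelse(fwd1, 0L, 16L) + ifelse(fwd1, 32L, 0L)
    flag2 <- 1L + 2L + 128L +
      ifelse(fwd1, 16L, 0L) + ifelse(fwd1, 0L, 32L)
    tlen <- moff + L

    rec1 <- paste(qname, flag1, spec$contig, frag_start + 1L, mapq,
                  paste0(L, "M"), "=", start2 + 1L, tlen, seq1, qual1,
                  sep = "\t")
    rec2 <- paste(qname, flag2, spec$contig, start2 + 1L, mapq,
                  paste0(L, "M"), "=", frag_start + 1L, -tlen, seq2, qual1,
                  sep = "\t")
    recs <- c(rec1, rec2)

    if (spec$duplicate_fraction > 0) {
      ndup <- round_half_up(spec$duplicate_fraction * nfrag)
      dup <- sample.int(nfrag, ndup)
      drec1 <- paste(paste0("dup_", qname[dup]), flag1[dup] + 1024L,
                     spec$contig, frag_start[dup] + 1L, mapq[dup],
                     paste0(L, "M"), "=", start2[dup] + 1L, tlen,
                     seq1[dup], qual1[dup], sep = "\t")
      drec2 <- paste(paste0("dup_", qname[dup]), flag2[dup] + 1024L,
                     spec$contig, start2[dup] + 1L, mapq[dup],
                     paste0(L, "M"), "=", frag_start[dup] + 1L, -tlen,
                     seq2[dup], qual1[dup], sep = "\t")
      recs <- c(recs, drec1, drec2)
    }

    fasta <- file.path(dir, paste0(name, ".fa"))
    refset <- Biostrings::DNAStringSet(paste(ref, collapse = ""))
    names(refset) <- spec$contig
    Biostrings::writeXStringSet(refset, fasta)

    sam <- file.path(dir, paste0(name, ".sam"))
    writeLines(c(
      "@HD\tVN:1.6\tSO:coordinate",
      sprintf("@SQ\tSN:%s\tLN:%d", spec$contig, contig_len),
      recs
    ), sam)
    bam <- .sam_to_bam(sam, file.path(dir, paste0(name, ".bam")))
    unlink(sam)

    interior <- c(L, W - L)
    bed <- file.path(dir, paste0(name, ".bed"))
    writeLines(sprintf("%s\t%d\t%d", spec$contig, interior[1], interior[2]),
               bed)

    list(fasta = fasta, bam = bam, bed = bed, spec = spec,
         length = contig_len, interior = interior, contig = spec$contig)
  })
}
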