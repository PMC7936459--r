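# Independent oracles and small SAM builders used across the suite.
#
# naive_site() re-derives per-position read tables by a whole-file scan with
# plain offset arithmetic (it refuses non-trivial CIGARs), so it shares no
# code with the package's indexed query + CIGAR walk.

suppressPackageStartupMessages({
  library(Rsamtools)
  library(GenomicRanges)
  library(IRanges)
})

# Brute-force per-read scan at a 0-based position. Only valid for alignments
# whose CIGAR is a single match run ("<n>M"), which all generated fixtures
# guarantee.
naive_site <- function(bam, chrom, pos, min_mq = 20, min_bq = 20,
                       include_duplicates = TRUE) {
  sb <- scanBam(bam, param = ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "mapq", "seq", "qual")
  ))[[1]]
  stopifnot(all(grepl("^[0-9]+M$", sb$cigar)))
  len <- as.integer(sub("M$", "", sb$cigar))
  drop_flags <- 4L + 256L + 2048L + if (include_duplicates) 0L else 1024L
  keep <- as.character(sb$rname) == chrom &
    bitwAnd(sb$flag, drop_flags) == 0L &
    sb$pos <= pos + 1L & pos + 1L <= sb$pos + len - 1L
  idx <- which(keep)
  off1 <- pos + 1L - sb$pos[idx] + 1L # 1-based offset within the read
  base <- toupper(substr(as.character(sb$seq[idx]), off1, off1))
  bq <- vapply(substr(as.character(sb$qual[idx]), off1, off1),
               function(ch) utf8ToInt(ch) - 33L, integer(1),
               USE.NAMES = FALSE)
  ok <- sb$mapq[idx] >= min_mq & bq >= min_bq & base %in% c("A", "C", "G", "T")
  data.frame(
    qname = sb$qname[idx][ok],
    flag = sb$flag[idx][ok],
    strand = ifelse(bitwAnd(sb$flag[idx][ok], 16L) > 0L, "-", "+"),
    base = base[ok],
    stringsAsFactors = FALSE
  )
}

naive_counts <- function(bam, chrom, pos, min_mq = 20, min_bq = 20,
                         include_duplicates = TRUE) {
  df <- naive_site(bam, chrom, pos, min_mq, min_bq, include_duplicates)
  counts <- vapply(c(A = "A", C = "C", G = "G", T = "T"),
                   function(b) sum(df$base == b), integer(1))
  list(depth = nrow(df), counts = counts,
       fwd = sum(df$strand == "+"), rev = sum(df$strand == "-"))
}

# Write an ad-hoc SAM (single contig) and return a sorted+indexed BAM path.
make_bam <- function(records, contig = "ref1", len = 1000L,
                     dir = tempfile("tinybam")) {
  dir.create(dir, showWarnings = FALSE)
  sam <- file.path(dir, "t.sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", contig, len),
    records
  ), sam)
  asBam(sam, file.path(dir, "t"), overwrite = TRUE, indexDestination = TRUE)
}

# One SAM record; pos is 1-based, seq/qual strings, proper pair by default.
sam_rec <- function(qname, pos, seq, qual, flag = 99L, mapq = 60L,
                    cigar = paste0(nchar(seq), "M"), contig = "ref1",
                    mpos = pos + 200L) {
  paste(qname, flag, contig, pos, mapq, cigar, "=", mpos, 300L, seq, qual,
        sep = "\t")
}

# All alignment records of a BAM as one data.frame (for record diffing).
read_records <- function(bam) {
  sb <- scanBam(bam, param = ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "mapq", "seq", "qual")
  ))[[1]]
  df <- data.frame(
    qname = sb$qname, flag = sb$flag, rname = as.character(sb$rname),
    pos = sb$pos, cigar = sb$cigar, mapq = sb$mapq,
    seq = as.character(sb$seq), qual = as.character(sb$qual),
    stringsAsFactors = FALSE
  )
  df[order(df$qname, df$flag), ]
}

# Phred quality character for an integer score.
qchar <- function(q) intToUtf8(33L + q)

# Requested alleles differing from the fixture genotype at given positions.
non_genotype_alleles <- function(bam, chrom, positions) {
  vapply(positions, function(p) {
    g <- pileup_counts(bam, chrom, p)$observed_genotype
    setdiff(c("A", "C", "G", "T"), g)[1]
  }, character(1))
}

write_user_bed <- function(path, chrom, positions, vafs, alleles) {
  writeLines(sprintf("%s\t%d\t%d\t%.4f\t%s", chrom, positions,
                     positions + 1L, vafs, alleles), path)
  path
}
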