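# Shared low-level helpers: SAM flag bits, rounding, seeded evaluation,
# region coercion.

# SAM flag bits (SAM spec section 1.4)
.FLAG <- list(
  PAIRED = 1L, PROPER = 2L, UNMAP = 4L, MUNMAP = 8L,
  REVERSE = 16L, MREVERSE = 32L, READ1 = 64L, READ2 = 128L,
  SECONDARY = 256L, QCFAIL = 512L, DUP = 1024L, SUPPLEMENTARY = 2048L
)

.BASES <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Computes the integer number of reads to mutate and the per-strand quota:
#' values with fractional part exactly 0.5 round up, so the zero-read
#' boundary sits cleanly at `vaf * coverage < 0.5`.
#'
#' @param x numeric vector (non-negative in all internal uses).
#' @return integer vector.
#' @export
round_half_up <- function(x) {
  as.integer(floor(x + 0.5))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Coerce regions to a GRanges. Accepts a GRanges directly, or a data.frame
# with columns chrom/start/end in 0-based half-open (BED) coordinates, which
# is converted to the 1-based closed convention GRanges uses.
.regions_to_granges <- function(regions) {
  if (methods::is(regions, "GRanges")) {
    return(regions)
  }
  if (is.data.frame(regions)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(regions)))
    return(GenomicRanges::GRanges(
      seqnames = regions$chrom,
      ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end)
    ))
  }
  stop("regions must be a GRanges or a data.frame with chrom/start/end")
}

# Mate ordinal from a SAM flag: 1 = first of pair, 2 = second, 0 = unpaired.
.mate_ordinal <- function(flag) {
  ifelse(bitwAnd(flag, .FLAG$READ1) > 0L, 1L,
         ifelse(bitwAnd(flag, .FLAG$READ2) > 0L, 2L, 0L))
}

.is_reverse <- function(flag) bitwAnd(flag, .FLAG$REVERSE) > 0L

# Key uniquely identifying one primary aligned segment.
.read_key <- function(qname, mate) paste0(qname, "#", mate)

.header_cache <- new.env(parent = emptyenv())

# Header target lengths, cached per (path, mtime) to avoid re-reading the
# header on every per-position query.
.bam_targets <- function(bam) {
  key <- paste0(normalizePath(bam), "#", file.mtime(bam))
  if (!exists(key, envir = .header_cache, inherits = FALSE)) {
    assign(key, Rsamtools::scanBamHeader(bam)[[1]]$targets,
           envir = .header_cache)
  }
  get(key, envir = .header_cache, inherits = FALSE)
}

.check_chrom <- function(bam, chrom) {
  targets <- .bam_targets(bam)
  if (!chrom %in% names(targets)) {
    stop(sprintf("sequence '%s' is not present in the BAM header of %s",
                 chrom, bam))
  }
  invisible(targets[[chrom]])
}
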