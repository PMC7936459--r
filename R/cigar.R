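# CIGAR arithmetic: locate the query offset of a reference position within
# one aligned segment. Only the query coordinate is needed (mutations are
# written into SEQ as stored, i.e. in alignment orientation), so a simple
# two-cursor walk over the CIGAR operations suffices.

# 0-based offset into SEQ of the base aligned to 1-based reference position
# `target1`, or NA when the position falls in a deletion/reference skip or
# outside the aligned span (e.g. under a soft clip).
query_offset_at <- function(cigar, aln_start1, target1) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  ref <- aln_start1
  q <- 1L # 1-based index of the next unconsumed query base
  for (op in ops) {
    n <- as.integer(substr(op, 1L, nchar(op) - 1L))
    type <- substr(op, nchar(op), nchar(op))
    if (type %in% c("M", "=", "X")) {
      if (target1 >= ref && target1 < ref + n) {
        return(q + (target1 - ref) - 1L)
      }
      ref <- ref + n
      q <- q + n
    } else if (type %in% c("I", "S")) {
      q <- q + n
    } else if (type %in% c("D", "N")) {
      if (target1 >= ref && target1 < ref + n) {
        return(NA_integer_)
      }
      ref <- ref + n
    }
    # H and P consume neither sequence nor reference
  }
  NA_integer_
}

# Vectorised over reads (one shared target position).
query_offsets_at <- function(cigars, starts1, target1) {
  mapply(query_offset_at, cigars, starts1,
         MoreArgs = list(target1 = target1),
         USE.NAMES = FALSE)
}
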