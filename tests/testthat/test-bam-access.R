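# Filtered pileup counting, average coverage, down-sampling, and mutated-BAM
# writing, each checked against brute-force oracles.

test_that("pileup counts apply MQ/BQ filters exactly as a naive scan", {
  a20 <- strrep("A", 20)
  q30 <- strrep(qchar(30), 20)
  q10 <- strrep(qchar(10), 20)
  # 10 clean reads, thresholds (20, 20) -> depth 10 {A:10}
  bam <- make_bam(vapply(1:10, function(i)
    sam_rec(sprintf("r%02d", i), 101, a20, q30), character(1)))
  pu <- pileup_counts(bam, "ref1", 105, min_mq = 20, min_bq = 20)
  expect_identical(pu$depth, 10L)
  expect_identical(unname(pu$allele_counts),
                   unname(naive_counts(bam, "ref1", 105)$counts))
  expect_identical(pu$allele_counts[["A"]], 10L)
  expect_identical(pu$observed_genotype, "A")
  expect_identical(pu$depth, pu$fwd_count + pu$rev_count)

  # 8 clean reads + 2 reads at BQ 10, threshold 20 -> depth 8
  bam2 <- make_bam(c(
    vapply(1:8, function(i) sam_rec(sprintf("a%d", i), 101, a20, q30),
           character(1)),
    sam_rec("lowq1", 101, a20, q10), sam_rec("lowq2", 101, a20, q10)
  ))
  expect_identical(pileup_counts(bam2, "ref1", 105)$depth, 8L)
  expect_identical(pileup_counts(bam2, "ref1", 105, min_bq = 10)$depth, 10L)
})

test_that("positions without reads give empty summaries; unknown contigs error", {
  bam <- make_bam(sam_rec("r1", 101, strrep("A", 20), strrep(qchar(30), 20)))
  pu <- pileup_counts(bam, "ref1", 500)
  expect_identical(pu$depth, 0L)
  expect_true(all(pu$allele_counts == 0L))
  expect_true(is.na(pu$observed_genotype))
  # beyond the contig end: empty, not an error
  expect_identical(pileup_counts(bam, "ref1", 10000)$depth, 0L)
  expect_error(pileup_counts(bam, "nope", 10), "not present in the BAM header")
})

test_that("pileup equals the naive oracle across randomized fixtures", {
  for (seed in 1:4) {
    frac <- c(0, 0.3, 0.5, 1)[seed]
    spec <- fixture_spec(focal_width = 400, depth = 50,
                         strand_fraction_fwd = frac,
                         low_quality_fraction = 0.15,
                         duplicate_fraction = 0.1, seed = 100 + seed)
    fx <- generate_fixture(spec)
    positions <- c(120L, 200L, 277L)
    for (p in positions) {
      pu <- pileup_counts(fx$bam, fx$contig, p)
      oracle <- naive_counts(fx$bam, fx$contig, p)
      expect_identical(pu$depth, oracle$depth)
      expect_identical(unname(pu$allele_counts), unname(oracle$counts))
      expect_identical(pu$fwd_count, oracle$fwd)
      expect_identical(pu$rev_count, oracle$rev)
      expect_identical(pu$depth, sum(pu$allele_counts))
      expect_identical(pu$depth, pu$fwd_count + pu$rev_count)
    }
  }
})

test_that("the batched region pileup agrees with per-position counts everywhere", {
  spec <- fixture_spec(focal_width = 400, depth = 50,
                       strand_fraction_fwd = 0.3,
                       low_quality_fraction = 0.2, duplicate_fraction = 0.1,
                       planted_variants = data.frame(pos = 180, alt = "A",
                                                     fraction = 0.3),
                       seed = 107)
  fx <- generate_fixture(spec)
  bed <- data.frame(chrom = fx$contig, start = 150L, end = 250L)
  idx <- snvspike:::region_pileup(fx$bam, bed)
  for (p in seq(150L, 249L)) {
    batched <- snvspike:::.pileup_from_index(idx, fx$contig, p)
    single <- pileup_counts(fx$bam, fx$contig, p)
    expect_identical(unname(batched$allele_counts),
                     unname(single$allele_counts))
    expect_identical(batched$fwd_count, single$fwd_count)
    expect_identical(batched$rev_count, single$rev_count)
    expect_identical(batched$observed_genotype, single$observed_genotype)
  }
  # a position with no reads resolves to an empty summary
  empty <- snvspike:::.pileup_from_index(idx, fx$contig, 5000L)
  expect_identical(empty$depth, 0L)
})

test_that("average coverage is the mean filtered depth over the region union", {
  fx <- generate_fixture(fixture_spec(focal_width = 600, depth = 50, seed = 9))
  expect_equal(average_coverage(
    fx$bam, data.frame(chrom = fx$contig, start = 150, end = 350)), 50)
  # a region with no reads
  gap <- data.frame(chrom = fx$contig, start = fx$length - 50,
                    end = fx$length)
  expect_equal(average_coverage(fx$bam, gap), 0)
  # two equal-length regions at depths 40 and 60 average to 50
  a20 <- strrep("A", 100)
  q <- strrep(qchar(30), 100)
  bam <- make_bam(c(
    vapply(1:40, function(i) sam_rec(sprintf("x%02d", i), 101, a20, q),
           character(1)),
    vapply(1:60, function(i) sam_rec(sprintf("y%02d", i), 301, a20, q),
           character(1))
  ))
  two <- data.frame(chrom = "ref1", start = c(100, 300), end = c(200, 400))
  expect_equal(average_coverage(bam, two), 50)
  expect_error(average_coverage(bam, data.frame(chrom = character(0),
                                                start = integer(0),
                                                end = integer(0))),
               "non-empty")
})

test_that("down-sampling hits the target coverage and keeps mates together", {
  fx <- generate_fixture(fixture_spec(focal_width = 800, depth = 100,
                                      seed = 31))
  bed <- data.frame(chrom = fx$contig, start = fx$interior[1],
                    end = fx$interior[2])
  ds <- downsample_bam(fx$bam, bed, 50, seed = 7)
  cov <- average_coverage(ds, bed)
  # fragment retention is binomial(p = 0.5); generous 3-sigma style bound
  expect_lt(abs(cov - 50), 10)
  recs <- read_records(ds)
  expect_true(all(table(recs$qname) == 2L)) # never orphan a mate
  # determinism under the seed
  ds2 <- downsample_bam(fx$bam, bed, 50, seed = 7)
  expect_identical(read_records(ds), read_records(ds2))
  ds3 <- downsample_bam(fx$bam, bed, 50, seed = 8)
  expect_false(identical(sort(unique(read_records(ds)$qname)),
                         sort(unique(read_records(ds3)$qname))))
})

test_that("down-sampling to >= current coverage copies the input with a warning", {
  fx <- generate_fixture(fixture_spec(focal_width = 400, depth = 20,
                                      seed = 33))
  bed <- data.frame(chrom = fx$contig, start = fx$interior[1],
                    end = fx$interior[2])
  expect_warning(ds <- downsample_bam(fx$bam, bed, 100, seed = 1),
                 "copying input unchanged")
  expect_identical(read_records(ds), read_records(fx$bam))
})

test_that("mutated BAMs change exactly one base and nothing else", {
  fx <- generate_fixture(fixture_spec(focal_width = 400, depth = 100,
                                      seed = 41))
  before <- read_records(fx$bam)

  # empty mutation map: record-identical output
  out0 <- write_mutated_bam(fx$bam, data.frame())
  expect_identical(read_records(out0), before)

  # one read, offset 5: sequence differs at exactly index 5
  mut1 <- data.frame(qname = "f000010", mate = 1L, offset = 5L, alt = "N")
  expect_error(write_mutated_bam(fx$bam, mut1), "A, C, G or T")
  row <- before[before$qname == "f000010" & bitwAnd(before$flag, 64L) > 0L, ]
  old_base <- substr(row$seq, 6, 6)
  alt <- setdiff(c("A", "C", "G", "T"), old_base)[1]
  mut1$alt <- alt
  out1 <- write_mutated_bam(fx$bam, mut1)
  after <- read_records(out1)
  expect_identical(after[, c("qname", "flag", "rname", "pos", "cigar",
                             "mapq", "qual")],
                   before[, c("qname", "flag", "rname", "pos", "cigar",
                              "mapq", "qual")])
  changed <- which(after$seq != before$seq)
  expect_length(changed, 1L)
  diff_at <- which(strsplit(after$seq[changed], "")[[1]] !=
                     strsplit(before$seq[changed], "")[[1]])
  expect_identical(diff_at, 6L)

  # mutate 5 of 100 reads at one position: pileup recount sees 5 variants
  site <- naive_site(fx$bam, fx$contig, 200, min_mq = 20, min_bq = 20)
  g <- names(sort(table(site$base), decreasing = TRUE))[1]
  pick <- head(site[site$base == g, ], 5)
  alt <- setdiff(c("A", "C", "G", "T"), g)[1]
  mut5 <- data.frame(qname = pick$qname,
                     mate = ifelse(bitwAnd(pick$flag, 64L) > 0L, 1L, 2L),
                     offset = 200L - (before$pos[match(pick$qname,
                                                       before$qname)] - 1L),
                     alt = alt)
  out5 <- write_mutated_bam(fx$bam, mut5)
  pu <- pileup_counts(out5, fx$contig, 200)
  expect_identical(pu$allele_counts[[alt]], 5L)
  expect_identical(pu$depth, 100L)
  oracle <- naive_counts(out5, fx$contig, 200)
  expect_identical(unname(pu$allele_counts), unname(oracle$counts))
})

test_that("mutation targets that cannot be applied are hard errors", {
  fx <- generate_fixture(fixture_spec(focal_width = 400, depth = 20,
                                      seed = 43))
  expect_error(write_mutated_bam(
    fx$bam, data.frame(qname = "ghost", mate = 1L, offset = 0L, alt = "A")),
    "ghost")
  expect_error(write_mutated_bam(
    fx$bam, data.frame(qname = "f000001", mate = 1L, offset = 500L,
                       alt = "A")),
    "outside read")
  expect_error(write_mutated_bam(
    fx$bam, data.frame(qname = c("f000001", "f000001"), mate = c(1L, 1L),
                       offset = c(1L, 2L), alt = c("A", "C"))),
    "duplicate read identities")
})
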