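# Stage 1: VAF/allele assignment, read-count rounding, the four rejection
# criteria, and both selection modes.

test_that("assigned VAFs are uniform over the requested range and seeded", {
  expect_equal(assign_vaf(0.05, 0.05, 10), rep(0.05, 10))
  set.seed(1)
  draws <- assign_vaf(0.01, 0.10, 1e4)
  expect_true(all(draws >= 0.01 & draws <= 0.10))
  # mean of U(0.01, 0.10): 0.055, sd of the mean = 0.09/sqrt(12)/100
  expect_lt(abs(mean(draws) - 0.055), 3 * 0.09 / sqrt(12) / 100)
  set.seed(7)
  a <- assign_vaf(0.01, 0.10, 100)
  set.seed(7)
  expect_identical(assign_vaf(0.01, 0.10, 100), a)
  expect_error(assign_vaf(0.2, 0.1), "vaf_low")
})

test_that("variant alleles exclude the genotype and are uniform over the rest", {
  set.seed(11)
  draws <- assign_variant_allele("A", 3e4)
  expect_false(any(draws == "A"))
  freq <- table(draws) / length(draws)
  expect_true(all(abs(freq - 1 / 3) < 3 * sqrt((1 / 3) * (2 / 3) / 3e4)))
  set.seed(3)
  a <- assign_variant_allele("G", 50)
  set.seed(3)
  expect_identical(assign_variant_allele("G", 50), a)
  expect_error(assign_variant_allele("MULTI"), "mono-allelic")
})

test_that("reads to mutate rounds half up on the VAF-coverage product", {
  expect_identical(reads_to_mutate(0.05, 100), 5L)
  expect_identical(reads_to_mutate(0.004, 100), 0L) # rejected downstream
  expect_identical(reads_to_mutate(0.015, 100), 2L) # 1.5 rounds up
  expect_identical(reads_to_mutate(0.005, 100), 1L)
  expect_identical(reads_to_mutate(0.5, 0), 0L)
})

test_that("candidate screening rejects under each criterion in turn", {
  mk_pu <- function(counts, fwd = NULL) {
    depth <- sum(counts)
    seen <- names(counts)[counts > 0]
    structure(list(chrom = "chr1", pos = 500L, depth = as.integer(depth),
                   allele_counts = counts,
                   fwd_count = fwd %||% depth, rev_count = depth - (fwd %||% depth),
                   observed_genotype = if (depth == 0) NA_character_
                                       else if (length(seen) == 1) seen
                                       else "MULTI"),
              class = "pileup_summary")
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  cfg <- simulation_config(target_coverage = 100, coverage_tolerance = 0.10)

  # an existing variant disqualifies before anything else
  res <- check_position(mk_pu(c(A = 98L, C = 0L, G = 0L, T = 2L)), cfg, 0.05)
  expect_identical(res$reason, "existing_variant")
  # depth 85 misses the [90, 110] window
  res <- check_position(mk_pu(c(A = 85L, C = 0L, G = 0L, T = 0L)), cfg, 0.05)
  expect_identical(res$reason, "coverage_range")
  # a neighbour at distance 1 violates min_separation = 1 (needs >= 2)
  res <- check_position(mk_pu(c(A = 100L, C = 0L, G = 0L, T = 0L)), cfg,
                        0.05, accepted_pos = 501L)
  expect_identical(res$reason, "separation")
  res <- check_position(mk_pu(c(A = 100L, C = 0L, G = 0L, T = 0L)), cfg,
                        0.05, accepted_pos = 502L)
  expect_true(res$accepted)
  # requested allele equal to the genotype (user mode)
  res <- check_position(mk_pu(c(A = 100L, C = 0L, G = 0L, T = 0L)), cfg,
                        0.05, requested_allele = "A")
  expect_identical(res$reason, "allele_equals_genotype")
  # zero reads after rounding
  res <- check_position(mk_pu(c(A = 100L, C = 0L, G = 0L, T = 0L)), cfg,
                        0.004)
  expect_identical(res$reason, "zero_reads")
  # clean accept: n_reads = 5, allele differs from genotype
  res <- check_position(mk_pu(c(A = 100L, C = 0L, G = 0L, T = 0L)), cfg, 0.05)
  expect_true(res$accepted)
  expect_identical(res$target$n_reads, 5L)
  expect_true(res$target$variant_allele %in% c("C", "G", "T"))
  expect_identical(res$target$observed_genotype, "A")
})

fx <- generate_fixture(fixture_spec(focal_width = 1200, depth = 100,
                                    seed = 61))
bed <- data.frame(chrom = fx$contig, start = fx$interior[1],
                  end = fx$interior[2])

test_that("random selection accepts the requested number on a clean fixture", {
  cfg <- simulation_config(n_snv = 10, vaf_low = 0.05, vaf_high = 0.10,
                           seed = 1)
  set.seed(cfg$seed)
  sel <- select_random_targets(fx$bam, bed, cfg)
  expect_identical(nrow(sel$targets), 10L)
  expect_identical(sel$tally$accepted, 10L)
  t <- sel$tally
  expect_identical(t$checked,
                   t$accepted + t$existing_variant + t$coverage_range +
                     t$separation + t$zero_reads + t$allele_equals_genotype +
                     t$exceeds_depth + t$unknown_chrom)
  # every accepted target is mono-allelic with n_reads >= 1 and in range
  expect_true(all(sel$targets$n_reads >= 1L))
  expect_true(all(sel$targets$observed_genotype %in% c("A", "C", "G", "T")))
  expect_true(all(sel$targets$variant_allele !=
                    sel$targets$observed_genotype))
  # pairwise separation on each chromosome
  pos <- sort(sel$targets$pos)
  expect_true(all(diff(pos) >= cfg$min_separation + 1L))
  # seeded determinism
  set.seed(cfg$seed)
  sel2 <- select_random_targets(fx$bam, bed, cfg)
  expect_identical(sel$targets, sel2$targets)
})

test_that("exhausting the candidate space returns a partial list and full tally", {
  # a footprint of 30 positions cannot host 25 SNVs at min_separation 9
  narrow <- data.frame(chrom = fx$contig, start = 200L, end = 230L)
  cfg <- simulation_config(n_snv = 25, vaf_low = 0.1, vaf_high = 0.1,
                           min_separation = 9L, seed = 5)
  set.seed(cfg$seed)
  expect_warning(sel <- select_random_targets(fx$bam, narrow, cfg),
                 "exhausted")
  expect_lt(nrow(sel$targets), 25L)
  expect_identical(sel$tally$checked, 30L)
  expect_identical(sel$tally$checked,
                   sel$tally$accepted + sel$tally$separation)
  pos <- sort(sel$targets$pos)
  expect_true(all(diff(pos) >= 10L))
})

test_that("user-specified selection honours requested VAF/allele and rejects mismatches", {
  pos <- seq(150L, 906L, by = 4L)[1:190]
  alleles <- non_genotype_alleles(fx$bam, fx$contig, pos)
  genos <- vapply(pos, function(p)
    pileup_counts(fx$bam, fx$contig, p)$observed_genotype, character(1))
  recs <- data.frame(chrom = fx$contig, start = pos, end = pos + 1L,
                     vaf = 0.05, allele = alleles)
  cfg <- simulation_config(seed = 3)
  sel <- select_user_targets(fx$bam, recs, cfg)
  expect_identical(nrow(sel$targets), 190L)
  expect_identical(sel$targets$assigned_vaf, rep(0.05, 190))
  expect_identical(sel$targets$variant_allele, alleles)

  # allele == genotype and unknown chromosomes are distinct rejections
  bad <- data.frame(chrom = c(fx$contig, "chrZ"),
                    start = c(pos[10], 10L), end = c(pos[10] + 1L, 11L),
                    vaf = 0.05, allele = c(genos[10], "A"))
  sel2 <- select_user_targets(fx$bam, bad, cfg)
  expect_identical(nrow(sel2$targets), 0L)
  expect_identical(sel2$tally$allele_equals_genotype, 1L)
  expect_identical(sel2$tally$unknown_chrom, 1L)
  expect_identical(sel2$tally$checked, 2L)
})
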