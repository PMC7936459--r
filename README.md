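# snvspike

Somatic single-nucleotide variant (SNV) spike-in simulation in existing BAM
alignments.

## The problem

Somatic and mosaic SNVs occur in only a fraction of a sample's cells, so they
appear in sequencing data at sub-heterozygous variant allele fractions
(VAF = variant reads / depth). Benchmarking the callers that hunt for them
requires truth sets that do not exist for real data. `snvspike` builds such
truth sets by *mutating the reads of a real BAM file in place*: at each
selected position it rewrites `round(VAF × coverage)` criteria-passing reads
to carry a chosen variant allele. Because the reads themselves are reused,
the instrument- and experiment-specific error profile, the base and mapping
qualities, and the local strand distribution of the data are all preserved —
unlike read-resimulation approaches that must model errors synthetically.

The simulation runs in three stages:

1. **Variant selection** — candidate positions come from a BED file, either
   random draws over 3-column ranges or explicit 5-column rows
   (`chrom start end VAF allele`, auto-detected). Each candidate is screened
   with MQ/BQ-filtered pileup counts and rejected if it already carries a
   variant, falls outside the target coverage window, sits too close to an
   accepted position, or needs zero reads after rounding.
2. **Variant simulation** — for each accepted position, reads are drawn per
   strand in proportion to the position's original forward/reverse counts
   (`n_fwd = round(n × fwd/(fwd+rev))`), restricted to properly paired,
   primary, quality-passing reads that carry the observed genotype base. A
   read is mutated at most once across the whole run. Mutated reads keep
   their position, CIGAR, FLAG, mapping quality and base-quality string —
   they are not realigned.
3. **Variant evaluation** — alleles are recounted from the output BAM; a
   target fails when its achieved VAF misses the contract by more than the
   rounding granularity `0.5/coverage`. Outputs: the mutated BAM + index, a
   ground-truth BED of achieved VAFs, and a log with yield and rejection
   accounting.

A deterministic paired-end fixture generator (`generate_fixture()`) with
exactly computable coverage, strand fractions and planted variants provides
the test surface, and `downsample_bam()` reduces a BAM to a target average
coverage fragment-by-fragment.

## Worked example

```r
library(snvspike)

# a clean 100x fixture: reference FASTA, sorted+indexed BAM, BED
fx <- generate_fixture(fixture_spec(focal_width = 1200, depth = 100,
                                    seed = 11))

cfg <- simulation_config(n_snv = 5, vaf_low = 0.05, vaf_high = 0.20,
                         target_coverage = 100, seed = 9)
res <- spike_variants(fx$bam, fx$bed, "out/run", cfg)
res$report
#> spike-in simulation report: 5 defined, 5 selected, 5 succeeded, 0 failed (yield 100.0%)
#> reads required 59, mutated 59
```

Five positions were accepted, 59 reads were rewritten (the sum of
`round(VAF × 100)` over the five assigned VAFs), and the recounted VAFs all
landed inside the requested range, so the yield — successes over the number
of SNVs defined for simulation — is 100%. `out/run_simulated_snvs.bed` now
holds the truth set (position, achieved VAF, coverage, variant allele),
`out/run_simulation_log.txt` the full accounting, and `out/run.bam` the
mutated alignments for the caller under test.

The same pipeline is scriptable from a shell:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/snvspike.R", package="snvspike"))') \
  --input-bam in.bam --input-bed targets.bed --output-prefix out/run \
  --number-snv 1000 --vaf-low 0.01 --vaf-high 0.10 \
  --target-coverage 100 --coverage-tolerance 0.10 --down-sample 100 \
  --random-seed 1 --verbose
```

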