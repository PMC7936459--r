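---
title: "Methods: somatic SNV spike-in simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: somatic SNV spike-in simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snvspike)
```

## The model

`snvspike` simulates somatic single-nucleotide variants by editing reads of
an existing coordinate-sorted BAM file. At a position with filtered depth
$d$ and an assigned variant allele fraction $v$, the simulator rewrites

$$n = \mathrm{round}_{1/2\uparrow}(v \cdot d)$$

reads to carry the variant allele (half-up rounding, so the rejection
boundary for "zero reads after rounding" sits cleanly at $v d < 0.5$). The
achieved VAF recounted from the output is $n / d$, so the only intrinsic
error source is that integer rounding, bounded by $0.5/d$. Everything else
about the data — base qualities, mapping qualities, error bases, duplicate
structure, local strand balance — is inherited from the input reads, which
is the point of spiking into real alignments rather than simulating reads.

Three assumptions matter:

* **Pileup counting unit.** Every aligned segment counts independently,
  including overlapping mates of one fragment. This matches how
  depth-of-coverage tools count and keeps the VAF arithmetic exact; callers
  that collapse mate overlaps will see slightly different denominators, and
  both mates of an overlapping pair may independently be selected for
  mutation (segment-level, not fragment-level, consistency).
* **Mutated reads carry the genotype base.** Only reads whose base at the
  target position equals the observed genotype are eligible, so the variant
  is never stacked on a sequencing-error base and the mutated-read count
  equals the recounted variant-allele count exactly.
* **No realignment.** A mutated read differs from its original at exactly
  one base; position, CIGAR, FLAG, MAPQ, mate fields and the base-quality
  string are byte-identical. `validate_remapping()` quantifies the residual
  risk (reads that would map elsewhere after mutation) with an external
  aligner; it is diagnostic only.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `vaf_low`, `vaf_high` | 0.01, 0.10 | VAF bounds; random mode draws uniformly from $[v_\ell, v_h]$, user mode validates against them |
| `n_snv` | — | number of SNVs to simulate (random mode) |
| `target_coverage`, `coverage_tolerance` | unset, 0.10 | accept only positions with depth in $[t(1-\tau), t(1+\tau)]$ (closed) |
| `min_mq`, `min_bq` | 20, 20 | inclusive quality thresholds applied to every pileup and to read eligibility |
| `min_separation` | 1 | accepted positions must have $\lvert p_1 - p_2\rvert \ge s + 1$, i.e. at least $s$ intervening bases |
| `seed` | 1 | single RNG stream for the whole run; fixed default so default runs reproduce |
| `down_sample_coverage` | unset | down-sample the input to this average coverage before selection |
| `include_duplicates` | `TRUE` | duplicate-flagged reads count in pileups and may be mutated |

Duplicates are included by default because marked duplicates still appear in
most pileup-based depth definitions; a flag excludes them for callers that
filter duplicates.

## Selection

Candidates are screened in a fixed order — existing variant (any second
allele with one or more filtered counts disqualifies, the strictest
reading), coverage window, minimum separation, requested-allele-equals-
genotype (user mode), zero reads after rounding — and each rejection
increments exactly one counter, so `checked == accepted + sum(rejections)`
holds on every run. Zero-depth positions fall under the coverage criterion
when a target coverage is set and under zero-reads otherwise. A
`reads-to-mutate exceeds depth` counter exists for completeness but cannot
fire while VAFs are capped at 1.

Random mode draws positions uniformly over the BED footprint *without
replacement* (regions implicitly weighted by length), guaranteeing
termination: when the footprint is exhausted before `n_snv` acceptances the
partial target list is returned with a warning. Whether the draw should be
with or without replacement, and whether region choice should be
length-weighted, were open design points; without-replacement plus
length-weighting gives uniform coverage of the footprint and a clean
exhaustion bound.

Selection screens candidates against one batched, quality-filtered pileup
pass over the whole footprint (`Rsamtools::pileup`); the test suite asserts
position-by-position equality between that batch and the per-position
`pileup_counts()` used everywhere else, and both against a brute-force
per-read scan.

## Simulation

The per-position strand quota is
$n_{fwd} = \mathrm{round}_{1/2\uparrow}(n \cdot f/(f+r))$, $n_{rev} = n -
n_{fwd}$, capped at each strand's availability with the remainder rebalanced
(when $f + r \ge n$ the cap provably never binds). Within a strand, reads
are chosen by a seeded shuffle rather than positional order, to avoid
5'-bias artifacts. A single-use ledger over (query name, mate ordinal)
guarantees no read is mutated twice across the run — the mechanism behind
the saturation of mutation yield as requests grow. When one strand's
eligible pool is too small the deficit moves to the other strand first;
achieving the VAF outranks strand fidelity, which is a modeling goal.

## Evaluation and the failure bound

Alleles are recounted from the output BAM with the same filters. A target is
*failed* when its achieved VAF misses the contract by more than the rounding
granularity: outside $[v_\ell - 0.5/d,\; v_h + 0.5/d]$ in random mode, or
$\lvert \hat v - v \rvert > 0.5/d$ against the requested VAF in user mode
(the user-mode bound is this package's choice; only the random-mode range
definition is standard). The widening by $0.5/d$ is deliberate: a strict
range comparison would label a target failed when rounding alone pushes
$n/d$ marginally past a bound even though every required read was mutated,
which contradicts the intended meaning of failure — a shortage of
criteria-passing reads. Failed targets with residual mutant reads are listed
in the log with their residual VAF; the truth BED contains only successes,
because it is the benchmarking ground truth.

The mutation yield is $N_{success}/N_{simulate}$, where $N_{simulate}$ is
the number of variants *defined* for simulation (the request in random mode,
the row count in user mode). Selection exhaustion therefore depresses yield
just as read shortage does.

## The fixture generator

`generate_fixture()` emulates a uniform short-read experiment in which every
expected number is exactly computable: error-free reads tile a focal zone so
each interior position has exactly `depth` covering segments; mates live in
a disjoint downstream zone so focal pileups are never contaminated; the
forward-strand fraction is realised by a periodic pattern (period 10), exact
at every interior position (hence `depth` must be a multiple of 10 for
fractions other than 0, 0.5, 1); planted variants, a low-quality read
subset, and duplicate-flagged copies exercise the rejection criteria and
filters. The reference is a seeded random base string, so unique enough for
re-mapping validation to reach 1.0 on clean runs.

What the fixture does **not** emulate — sequencing errors, indels, soft
clips, coverage waviness, GC bias, fragment-length variation — bounds what
green tests prove: they certify the simulator's arithmetic and bookkeeping
(VAF accuracy, strand fidelity, single-use accounting, field preservation),
not robustness to messy real data. On real BAMs the same code paths run, but
coverage heterogeneity and error bases shrink the eligible read pools, which
surfaces as coverage-window rejections and (at high request densities)
failed mutations — exactly the diagnostics the log reports. CIGAR handling
beyond pure matches is covered separately by construction (clipped, inserted
and deleted alignments are tested against an independent htslib pileup).

## Numerical and degenerate-input choices

* Half-up rounding everywhere a count is derived from a fraction.
* All internal coordinates 0-based; BED is 0-based half-open; the 1-based
  SAM convention is confined to the I/O layer.
* Coverage windows are closed intervals; quality thresholds are inclusive
  ($\ge$).
* Empty runs are defined: zero requested variants yield an `N/A` yield, a
  header-only truth BED, and a well-formed log.
* Down-sampling retains fragments (both mates or neither) with probability
  $p = t/\bar c$ via a seeded draw per unique query name; $p \ge 1$ copies
  the input unchanged with a warning.
* Positions beyond the contig end give empty pileups; unknown contigs are
  contract errors (random mode) or counted rejections (user records).

## Test problem sizes

The suite and the acceptance script run on fixtures of 0.4–3.2 kb focal
zones at 20–200× (thousands of reads, hundreds of targets), chosen so every
expected value is hand- or oracle-computable and the full suite completes in
about a minute. The yield-saturation curve uses a 3,000-position footprint
supporting ~30 disjoint read pools (`min_separation` = read length − 1):
requests at 0.1× and 0.5× capacity succeed completely — a packing bound
($\ge \lceil W/(2L-1) \rceil = 16$ accepted positions) guarantees the 0.5×
run deterministically — while requests at 1× and 2× capacity exhaust the
candidate space near the random-sequential-packing density (~0.75 of
capacity) and the yield falls accordingly. This reproduces, at desk scale
and deterministically, the same limitation that causes yield decay on real
data: once a read can be used only once, availability shrinks as the request
grows.

## Limitations

* SNVs only; no indels, SVs, or CNVs, and no CRAM.
* Segment-level mutation of overlapping mates can place a variant on one
  mate but not the other; callers that collapse overlaps see half-weight
  evidence there.
* Not recommended for long-read data: a single long read overlaps many
  candidate positions, so the single-use rule exhausts pools quickly.
* The lowest simulable VAF and the VAF resolution are set by the input
  coverage ($1/d$ steps).
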