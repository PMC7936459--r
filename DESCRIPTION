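Package: snvspike
Title: Somatic SNV Spike-In Simulation in Existing BAM Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates somatic single-nucleotide variants by mutating reads
    of an existing coordinate-sorted BAM file at user-controlled positions,
    variant allele fractions, and depths, preserving the original sequencing
    error environment, base and mapping qualities, and the per-position
    strand distribution. The simulation runs in three stages (variant
    selection, variant simulation, variant evaluation) and emits a mutated
    BAM with index, a ground-truth BED of the simulated variants, and a log
    of selection, mutation and yield diagnostics for benchmarking somatic
    variant callers. Includes a deterministic paired-end fixture generator
    and a coverage down-sampler.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rsamtools,
    GenomicRanges,
    IRanges,
    Biostrings,
    jsonlite,
    methods,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
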