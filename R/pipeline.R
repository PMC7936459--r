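# Single-call driver wiring configuration -> optional down-sampling ->
# selection -> simulation -> evaluation -> outputs.

#' Run the full spike-in pipeline
#'
#' Executes the three simulation stages against a BAM/BED pair and writes
#' the four standard outputs: `<prefix>.bam` (+ `.bai`),
#' `<prefix>_simulation_log.txt` and `<prefix>_simulated_snvs.bed`, plus a
#' `<prefix>_manifest.json` run manifest (resolved configuration, input
#' checksums, seed, package version) written before stage 1 so a run can be
#' reproduced exactly. The selection mode is auto-detected from the BED
#' dialect. Failed mutations are reported, never fatal.
#'
#' @param bam Coordinate-sorted input BAM; indexed (an index is created if
#'   missing).
#' @param bed Input BED: 3-column ranges (random mode) or 5-column single
#'   positions with VAF and allele (user-specified mode).
#' @param output_prefix Path prefix for the outputs.
#' @param config A [simulation_config()]; `n_snv` is required in random
#'   mode and rejected in user-specified mode.
#' @return Invisibly, a list with `report`, `truth`, `targets`, `records`,
#'   `mutations`, `tally`, and `paths`.
#' @export
spike_variants <- function(bam, bed, output_prefix, config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!file.exists(bam)) stop("input BAM not found: ", bam)
  if (!file.exists(paste0(bam, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam))) {
    message("input BAM has no index; indexing")
    Rsamtools::indexBam(bam)
  }
  parsed <- parse_bed(bed)
  if (parsed$mode == "user_specified" && !is.null(config$n_snv)) {
    stop("n_snv cannot be combined with a user-specified (5-column) BED; ",
         "the number of variants is the number of BED rows")
  }
  if (parsed$mode == "random" && is.null(config$n_snv)) {
    stop("a 3-column BED requires n_snv in the configuration")
  }

  dir.create(dirname(output_prefix), recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    bam = paste0(output_prefix, ".bam"),
    log = paste0(output_prefix, "_simulation_log.txt"),
    truth_bed = paste0(output_prefix, "_simulated_snvs.bed"),
    manifest = paste0(output_prefix, "_manifest.json")
  )
  manifest <- list(
    tool = "snvspike",
    version = as.character(utils::packageVersion("snvspike")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = unclass(config),
    inputs = list(
      bam = list(path = normalizePath(bam),
                 md5 = unname(tools::md5sum(bam))),
      bed = list(path = normalizePath(bed),
                 md5 = unname(tools::md5sum(bed)))
    ),
    selection_mode = parsed$mode,
    outputs = paths
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")

  work_bam <- bam
  if (!is.null(config$down_sample_coverage)) {
    ds_path <- paste0(output_prefix, "_downsampled.bam")
    regions <- if (parsed$mode == "random") {
      parsed$records
    } else {
      data.frame(chrom = parsed$records$chrom,
                 start = parsed$records$start,
                 end = parsed$records$end)
    }
    work_bam <- downsample_bam(bam, regions, config$down_sample_coverage,
                               min_mq = config$min_mq,
                               min_bq = config$min_bq,
                               seed = config$seed, dest = ds_path)
    paths$downsampled_bam <- work_bam
  }

  set.seed(config$seed)
  sel <- if (parsed$mode == "random") {
    select_random_targets(work_bam, parsed$records, config)
  } else {
    select_user_targets(work_bam, parsed$records, config)
  }
  sim <- run_simulation(work_bam, sel$targets, config, dest = paths$bam)
  n_requested <- if (parsed$mode == "random") {
    config$n_snv
  } else {
    nrow(parsed$records)
  }
  ev <- evaluate_simulation(sim$bam, sel$targets, sim$records, config,
                            tally = sel$tally, n_requested = n_requested)

  chrom_order <- names(Rsamtools::scanBamHeader(work_bam)[[1]]$targets)
  write_truth_bed(ev$truth, paths$truth_bed, chrom_order = chrom_order)
  write_log(ev$report, paths$log, verbose = config$verbose)

  invisible(list(report = ev$report, truth = ev$truth,
                 targets = sel$targets, records = sim$records,
                 mutations = sim$mutations, tally = sel$tally,
                 paths = paths))
}
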