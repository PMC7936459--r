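# BED parsing (two dialects) and the simulation outputs: the truth-set BED
# and the human-readable log.
#
# Coordinates are 0-based half-open on disk (standard BED) and 0-based
# inside the package.

#' Parse an input BED file and detect the selection mode
#'
#' Two dialects are supported. Plain 3-column rows (`chrom start end`)
#' describe ranges for random variant selection. Rows with at least five
#' columns where column 4 is a VAF in `(0, 1]` and column 5 a single A/C/G/T
#' base describe user-specified single positions (`end == start + 1`); extra
#' trailing columns are ignored with a warning. The mode is `user_specified`
#' iff every data row matches the user dialect; files mixing dialects are
#' rejected. Lines starting with `#`, `track` or `browser` and blank lines
#' are skipped.
#'
#' @param path Path to a tab-delimited BED file.
#' @return A list with `mode` (`"random"` or `"user_specified"`) and
#'   `records` (a data.frame with `chrom`, `start`, `end`, plus `vaf` and
#'   `allele` in user mode).
#' @export
parse_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*$", lines) & !startsWith(lines, "#") &
    !startsWith(lines, "track") & !startsWith(lines, "browser")
  lineno <- which(keep)
  rows <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (length(rows) == 0L) stop("BED file contains no data rows: ", path)

  perr <- function(i, ...) {
    stop(sprintf("%s: line %d: %s", path, lineno[i], paste0(...)))
  }
  parse_int <- function(x) suppressWarnings(as.integer(x))
  parse_num <- function(x) suppressWarnings(as.numeric(x))

  nf <- lengths(rows)
  if (any(nf < 3L)) {
    perr(which(nf < 3L)[1], "fewer than 3 tab-separated columns")
  }
  looks_user <- vapply(rows, function(f) {
    length(f) >= 5L && !is.na(parse_num(f[4])) &&
      toupper(f[5]) %in% .BASES
  }, logical(1))

  if (any(looks_user) && !all(looks_user)) {
    stop(sprintf(
      "%s: mixed BED dialects (line %d has VAF/allele columns, line %d %s)",
      path, lineno[which(looks_user)[1]], lineno[which(!looks_user)[1]],
      "does not"))
  }
  mode <- if (all(looks_user)) "user_specified" else "random"

  chrom <- vapply(rows, `[[`, character(1), 1L)
  start <- parse_int(vapply(rows, `[[`, character(1), 2L))
  end <- parse_int(vapply(rows, `[[`, character(1), 3L))
  for (i in seq_along(rows)) {
    if (chrom[i] == "") perr(i, "empty chromosome name")
    if (is.na(start[i]) || is.na(end[i])) perr(i, "non-integer coordinates")
    if (start[i] < 0L) perr(i, "negative start coordinate")
    if (start[i] >= end[i]) {
      perr(i, sprintf("start (%d) must be < end (%d)", start[i], end[i]))
    }
  }

  if (mode == "user_specified") {
    vaf <- parse_num(vapply(rows, `[[`, character(1), 4L))
    allele <- toupper(vapply(rows, `[[`, character(1), 5L))
    for (i in seq_along(rows)) {
      if (end[i] != start[i] + 1L) {
        perr(i, "user-specified rows must describe a single position ",
             "(end == start + 1)")
      }
      if (is.na(vaf[i]) || vaf[i] <= 0 || vaf[i] > 1) {
        perr(i, sprintf("VAF %s outside (0, 1]", rows[[i]][4]))
      }
    }
    if (any(nf > 5L)) {
      warning(sprintf("%s: ignoring extra trailing columns (first at line %d)",
                      path, lineno[which(nf > 5L)[1]]))
    }
    records <- data.frame(chrom = chrom, start = start, end = end,
                          vaf = vaf, allele = allele,
                          stringsAsFactors = FALSE)
  } else {
    records <- data.frame(chrom = chrom, start = start, end = end,
                          stringsAsFactors = FALSE)
  }
  list(mode = mode, records = records)
}

#' Write the simulation truth-set BED
#'
#' One row per successfully simulated variant: chrom, start, end (0-based
#' half-open single position), the achieved VAF recounted from the output
#' BAM (4 decimal places), the recounted coverage, and the variant allele.
#' Rows are ordered by chromosome (following `chrom_order` when given, e.g.
#' the BAM header order) and position. Failed mutations are reported in the
#' log, not here, so the truth set contains only within-contract variants.
#'
#' @param truth Data.frame with columns `chrom`, `pos` (0-based), `vaf`,
#'   `coverage`, `allele`.
#' @param path Output path.
#' @param chrom_order Optional character vector fixing the chromosome order.
#' @return `path`, invisibly.
#' @export
write_truth_bed <- function(truth, path, chrom_order = NULL) {
  header <- "#chrom\tstart\tend\tVAF\tcoverage\tvariant_allele"
  if (nrow(truth) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  chrom_order <- chrom_order %||% unique(truth$chrom)
  ord <- order(match(truth$chrom, chrom_order), truth$pos)
  truth <- truth[ord, , drop = FALSE]
  rows <- sprintf("%s\t%d\t%d\t%.4f\t%d\t%s",
                  truth$chrom, truth$pos, truth$pos + 1L,
                  truth$vaf, truth$coverage, truth$allele)
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Write the human-readable simulation log
#'
#' Reports every headline metric of the run under stable section headers:
#' positions checked and selected, reads required and mutated, the number of
#' variants defined for simulation, successes, failed mutations, the
#' mutation yield, mean coverage of selected positions, and the achieved VAF
#' and variant allele distributions. With `verbose`, per-criterion rejection
#' counters from the selection stage are included.
#'
#' @param report A `simulation_report` from [evaluate_simulation()].
#' @param path Output path.
#' @param verbose Include the rejection accounting.
#' @return `path`, invisibly.
#' @export
write_log <- function(report, path, verbose = FALSE) {
  t <- report$rejection_tally
  fmt_pct <- function(x) {
    if (is.na(x)) "N/A" else sprintf("%.1f%%", 100 * x)
  }
  lines <- c(
    "somatic SNV spike-in simulation log",
    "===================================",
    "",
    "## Variant selection",
    sprintf("positions checked: %d", t$checked),
    sprintf("positions selected for simulation: %d", t$accepted),
    sprintf("mean coverage of selected positions: %s",
            ifelse(is.na(report$mean_target_coverage), "N/A",
                   sprintf("%.2f", report$mean_target_coverage)))
  )
  if (verbose) {
    lines <- c(lines,
      "rejections by criterion:",
      sprintf("  existing variant: %d", t$existing_variant),
      sprintf("  coverage range: %d", t$coverage_range),
      sprintf("  minimum separation: %d", t$separation),
      sprintf("  zero reads to mutate: %d", t$zero_reads),
      sprintf("  allele equals genotype: %d", t$allele_equals_genotype),
      sprintf("  reads to mutate exceeds depth: %d", t$exceeds_depth),
      sprintf("  chromosome not in BAM header: %d", t$unknown_chrom)
    )
  }
  lines <- c(lines,
    "",
    "## Variant simulation",
    sprintf("reads required: %d", report$reads_required),
    sprintf("reads mutated: %d", report$reads_mutated),
    "",
    "## Variant evaluation",
    sprintf("variants defined for simulation (N_simulate): %d",
            report$n_simulate),
    sprintf("successfully simulated variants (N_success): %d",
            report$n_success),
    sprintf("failed mutations: %d", report$n_failed),
    sprintf("mutation yield: %s", fmt_pct(report$mutation_yield))
  )
  if (report$n_failed > 0L) {
    res <- report$per_target[!report$per_target$success, , drop = FALSE]
    lines <- c(lines, "failed positions (residual VAF):",
               sprintf("  %s:%d achieved %.4f of %.4f (%d of %d reads)",
                       res$chrom, res$pos, res$achieved_vaf,
                       res$assigned_vaf, res$n_mutated, res$n_required))
  }
  lines <- c(lines, "", "achieved VAF distribution:")
  if (nrow(report$per_target) > 0L) {
    qs <- stats::quantile(report$per_target$achieved_vaf,
                          c(0, 0.25, 0.5, 0.75, 1))
    lines <- c(lines,
               sprintf("  min %.4f / q25 %.4f / median %.4f / q75 %.4f / max %.4f",
                       qs[1], qs[2], qs[3], qs[4], qs[5]))
  } else {
    lines <- c(lines, "  (no simulated variants)")
  }
  ad <- report$allele_distribution
  lines <- c(lines, "variant allele distribution:",
             sprintf("  %s", paste(sprintf("%s=%d", names(ad), ad),
                                   collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}
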