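## End-to-end orchestration: sequencing pipeline (demultiplex -> trim ->
## assign -> pileup -> call), LR dosage pipeline, CGH pipeline and the
## validation comparison. Each run can persist its outputs plus a
## machine-readable manifest under a run directory.

.write_manifest <- function(out_dir, stage, inputs, params) {
  man <- list(stage = stage,
              package_version = as.character(utils::packageVersion("panelseq")),
              inputs = inputs,
              input_md5 = as.list(tools::md5sum(unlist(inputs[file.exists(
                unlist(inputs))]))),
              params = params,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Run the sequencing pipeline on a pooled batch
#'
#' Demultiplexes by barcode, trims primers and sub-Q30 tails, assigns reads
#' to genes with pseudogene discard, builds the pileup restricted to panel
#' regions plus flanks, and calls variants and coverage failures. When
#' `out_dir` is given, writes `calls.vcf`, `coverage_flags.tsv`,
#' `run_log.json` (read-conservation counters, per-sample mean depth,
#' thresholds) and a manifest.
#'
#' @param fastq1,fastq2 pooled FASTQ paths (`fastq2` optional).
#' @param sheet a [SampleSheet-class].
#' @param panel a [PanelDefinition-class].
#' @param refs a [ReferenceSet-class].
#' @param out_dir optional run directory (created).
#' @param q_threshold trimming Phred threshold (default 30).
#' @param min_depth coverage-failure threshold (default 50).
#' @return list: calls (VRanges), coverage_flags, pileup, counters,
#'   mean_depth (named per sample), paths (if written).
#' @export
runSeqPipeline <- function(fastq1, fastq2 = NULL, sheet, panel, refs,
                           out_dir = NULL, q_threshold = 30L,
                           min_depth = 50L) {
  for (f in c(fastq1, fastq2)) if (!file.exists(f))
    stop("input file not found: ", f)
  dmx <- demultiplexReads(fastq1, fastq2, sheet)
  if (!nrow(dmx$reads))
    warning("no reads routed to any sample; emitting header-only VCF")
  am <- panelAmplicons(panel)
  primers <- unique(c(mcols(am)$forward_primer, mcols(am)$reverse_primer))
  trimmed <- trimReads(dmx$reads, primers, q_threshold = q_threshold)
  asg <- assignReads(trimmed, refs)
  pile <- buildPileup(asg, panel)
  res <- callVariants(pile, panel, refs, min_depth = min_depth)
  counters <- c(input = dmx$total, routed = nrow(dmx$reads),
                unassigned = dmx$unassigned, pileupCounters(pile))
  pc <- pileupCalls(pile)
  mean_depth <- if (nrow(pc)) {
    dt <- data.table::as.data.table(pc)
    d <- dt[, list(depth = sum(count)), by = c("sample_id", "contig", "pos")]
    md <- d[, list(mean_depth = mean(depth)), by = "sample_id"]
    setNames(md$mean_depth, md$sample_id)
  } else numeric(0)
  out <- list(calls = res$calls, coverage_flags = res$coverage_flags,
              pileup = pile, counters = counters, mean_depth = mean_depth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    vcf <- file.path(out_dir, "calls.vcf")
    writeVariantCalls(res$calls, vcf, references = refs)
    write.table(res$coverage_flags, file.path(out_dir, "coverage_flags.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(counters = as.list(counters),
                              mean_depth = as.list(mean_depth),
                              q_threshold = q_threshold,
                              min_depth = min_depth),
                         file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    .write_manifest(out_dir, "seq", list(fastq1 = fastq1, fastq2 = fastq2),
                    list(q_threshold = q_threshold, min_depth = min_depth))
    out$paths <- list(vcf = vcf)
  }
  out
}

#' Run the large-rearrangement dosage pipeline on a batch count matrix
#'
#' Applies the full normalization chain (sample mean -> batch median ->
#' region summary -> copy-number dosage), calls deletion/duplication events,
#' and flags single-allele (dropout) amplicons. Failed samples are reported
#' as "No Result".
#'
#' @param counts an [AmpliconCounts-class] (or a count-matrix TSV path).
#' @param panel a [PanelDefinition-class].
#' @param out_dir optional run directory.
#' @param del_threshold,dup_threshold dosage cutoffs (1.5 / 2.5).
#' @param z_threshold,dropout_target,dropout_tolerance dropout criteria.
#' @return list: dosage ([RegionDosage-class]), lr_calls, dropout_flags,
#'   scatter, failed ("No Result" samples), masked amplicons.
#' @export
runLrPipeline <- function(counts, panel, out_dir = NULL, del_threshold = 1.5,
                          dup_threshold = 2.5, z_threshold = 4,
                          dropout_target = 0.5, dropout_tolerance = 0.15) {
  if (is.character(counts)) counts <- readCountMatrix(counts)
  ns <- normalizeSampleCounts(counts)
  nb <- normalizeBatchRatios(ns)
  sm <- summarizeRegionRatios(nb, panel)
  dos <- regionDosage(sm, panel)
  lr <- callLargeRearrangements(dos, del_threshold, dup_threshold)
  drp <- flagAlleleDropout(nb, panel, lr_calls = lr,
                           z_threshold = z_threshold,
                           target = dropout_target,
                           tolerance = dropout_tolerance)
  sc <- dosageScatterData(dos)
  out <- list(dosage = dos, lr_calls = lr, dropout_flags = drp, scatter = sc,
              failed = ns$failed, masked = nb$masked)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeDosageTable(dos, file.path(out_dir, "dosage.tsv"))
    write.table(lr, file.path(out_dir, "lr_calls.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(drp, file.path(out_dir, "dropout_flags.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(sc, file.path(out_dir, "scatter.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (length(ns$failed))
      writeLines(paste(ns$failed, "No Result", sep = "\t"),
                 file.path(out_dir, "no_result.tsv"))
    .write_manifest(out_dir, "lr", list(),
                    list(del_threshold = del_threshold,
                         dup_threshold = dup_threshold,
                         z_threshold = z_threshold))
  }
  out
}

#' Run the CGH pipeline on a probe intensity table
#'
#' Computes raw log2 ratios, applies the four-stage normalization stack and
#' calls regions on the log2 scale.
#'
#' @param probes probe table (data.frame or TSV path).
#' @param panel a [PanelDefinition-class].
#' @param historic optional [historicProbeStats()] output.
#' @param out_dir optional run directory.
#' @param del_threshold,dup_threshold,min_probes calling parameters.
#' @return list: normalized, calls, untestable.
#' @export
runCghPipeline <- function(probes, panel, historic = NULL, out_dir = NULL,
                           del_threshold = -0.5, dup_threshold = 0.4,
                           min_probes = 3L) {
  if (is.character(probes)) probes <- readProbeTable(probes)
  nr <- normalizeCgh(probes, historic = historic)
  calls <- callCghRegions(nr, panel, del_threshold, dup_threshold, min_probes)
  out <- list(normalized = nr, calls = calls,
              untestable = attr(calls, "untestable"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(nr, file.path(out_dir, "normalized_probes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(calls, file.path(out_dir, "cgh_calls.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    .write_manifest(out_dir, "cgh", list(),
                    list(del_threshold = del_threshold,
                         dup_threshold = dup_threshold,
                         min_probes = min_probes))
  }
  out
}

#' Run the validation comparison between two call sets
#'
#' @param test,truth call sets: VCF paths, VRanges or data.frames.
#' @param panel a [PanelDefinition-class].
#' @param bases_per_sample,n_samples denominators (see [compareCallsets()]).
#' @param confidence level for the exact bounds (default 0.95).
#' @param out_dir optional run directory.
#' @return list: table ([ConcordanceTable-class]), sensitivity,
#'   specificity, sensitivity_bound, specificity_bound, summary.
#' @export
runValidation <- function(test, truth, panel, bases_per_sample = NULL,
                          n_samples = NULL, confidence = 0.95,
                          out_dir = NULL) {
  if (is.character(test)) test <- readVariantCalls(test)
  if (is.character(truth)) truth <- readVariantCalls(truth)
  tab <- compareCallsets(test, truth, panel,
                         bases_per_sample = bases_per_sample,
                         n_samples = n_samples)
  sens <- sensitivity(tab)
  spec <- specificity(tab)
  sb <- exactLowerBound(tab@tp, tab@tp + tab@fn, confidence)
  pb <- exactLowerBound(tab@tn, tab@tn + tab@fp, confidence)
  summ <- concordanceSummary(tab, confidence)
  out <- list(table = tab, sensitivity = sens, specificity = spec,
              sensitivity_bound = sb, specificity_bound = pb,
              summary = summ)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(summ, file.path(out_dir, "concordance_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(discordantSites(tab),
                file.path(out_dir, "discordant_sites.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    .write_manifest(out_dir, "validate", list(), list(confidence = confidence))
  }
  out
}
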