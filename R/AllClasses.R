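#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- queryHits subjectHits
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges findOverlaps seqnames start end width mcols mcols<-
#' @importFrom Biostrings DNAStringSet reverseComplement writeXStringSet readDNAStringSet
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom stats median qbeta quantile rbinom rnbinom rnorm rpois runif sd lowess approx setNames
#' @importFrom utils read.delim write.table
#' @importClassesFrom S4Vectors Hits DataFrame
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom SummarizedExperiment SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment rowRanges
NULL

.datatable.aware <- TRUE

setClassUnion("df_or_NULL", c("data.frame", "NULL"))

#' Panel definition: regions of interest and the amplicons that tile them
#'
#' A `PanelDefinition` holds the regions a germline panel reports against
#' (typically coding exons plus short intronic flanks) and the PCR amplicons
#' that tile them. Regions and amplicons are stored as [GenomicRanges::GRanges]
#' on gene-named contigs; the amplicon/region overlap index is precomputed at
#' construction and kept in sync by the validity method.
#'
#' Region metadata columns: `gene_name`, `region_label`, `upstream_flank`
#' (<= 20 bases), `downstream_flank` (<= 10 bases), `tested_by_lr`. Amplicon
#' ranges span the insert (primers excluded); metadata columns: `amplicon_id`,
#' `forward_primer`, `reverse_primer`, `multiplex_group`.
#'
#' @slot regions GRanges of panel regions.
#' @slot amplicons GRanges of amplicon inserts.
#' @slot overlaps Hits from `findOverlaps(amplicons, regions)`.
#'
#' @seealso [loadPanel()], [panelRegions()], [panelAmplicons()]
#' @export
setClass("PanelDefinition",
  representation(regions = "GRanges", amplicons = "GRanges", overlaps = "Hits"))

.validPanelDefinition <- function(object) {
  msg <- character()
  rg <- object@regions
  am <- object@amplicons
  need_r <- c("gene_name", "region_label", "upstream_flank", "downstream_flank",
              "tested_by_lr")
  if (!all(need_r %in% names(mcols(rg))))
    msg <- c(msg, "regions must carry gene_name, region_label, upstream_flank, downstream_flank, tested_by_lr")
  else {
    if (any(mcols(rg)$upstream_flank > 20))
      msg <- c(msg, "upstream_flank exceeds the 20-base maximum")
    if (any(mcols(rg)$downstream_flank > 10))
      msg <- c(msg, "downstream_flank exceeds the 10-base maximum")
    lbl <- paste(mcols(rg)$gene_name, mcols(rg)$region_label)
    if (anyDuplicated(lbl))
      msg <- c(msg, "region_label must be unique within each gene")
  }
  need_a <- c("amplicon_id", "forward_primer", "reverse_primer", "multiplex_group")
  if (!all(need_a %in% names(mcols(am))))
    msg <- c(msg, "amplicons must carry amplicon_id, forward_primer, reverse_primer, multiplex_group")
  else {
    if (any(!nzchar(mcols(am)$forward_primer)) || any(!nzchar(mcols(am)$reverse_primer)))
      msg <- c(msg, "amplicon primers must be non-empty")
    if (anyDuplicated(mcols(am)$amplicon_id))
      msg <- c(msg, "amplicon_id must be unique")
  }
  if (length(msg)) msg else TRUE
}
setValidity("PanelDefinition", .validPanelDefinition)

#' Reference sequences for panel genes and their homologous pseudogenes
#'
#' Gene and pseudogene sequences are kept in separate [Biostrings::DNAStringSet]
#' maps with disjoint identifiers; `homologyPairs` links each gene with the
#' pseudogene(s) it must be disambiguated from during read assignment.
#'
#' @slot genes DNAStringSet of functional gene references.
#' @slot pseudogenes DNAStringSet of pseudogene references.
#' @slot homologyPairs data.frame with columns `gene`, `pseudogene`.
#' @export
setClass("ReferenceSet",
  representation(genes = "DNAStringSet", pseudogenes = "DNAStringSet",
                 homologyPairs = "data.frame"))

.validReferenceSet <- function(object) {
  msg <- character()
  gn <- names(object@genes); pn <- names(object@pseudogenes)
  if (is.null(gn) || anyDuplicated(gn)) msg <- c(msg, "gene ids must be unique")
  if (length(pn) && anyDuplicated(pn)) msg <- c(msg, "pseudogene ids must be unique")
  if (length(intersect(gn, pn)))
    msg <- c(msg, "gene and pseudogene identifiers must be disjoint")
  hp <- object@homologyPairs
  if (!all(c("gene", "pseudogene") %in% names(hp)))
    msg <- c(msg, "homologyPairs needs columns gene, pseudogene")
  else if (nrow(hp)) {
    if (!all(hp$gene %in% gn)) msg <- c(msg, "homology pair references unknown gene id")
    if (!all(hp$pseudogene %in% pn)) msg <- c(msg, "homology pair references unknown pseudogene id")
  }
  if (length(msg)) msg else TRUE
}
setValidity("ReferenceSet", .validReferenceSet)

#' Sample sheet mapping 6-nt barcodes to samples within a batch
#'
#' @slot entries data.frame with columns `sample_id`, `barcode`, `batch_id`.
#'   Barcodes are exactly 6 nucleotides and unique within a batch.
#' @export
setClass("SampleSheet", representation(entries = "data.frame"))

.validSampleSheet <- function(object) {
  e <- object@entries
  msg <- character()
  if (!all(c("sample_id", "barcode", "batch_id") %in% names(e)))
    return("entries needs columns sample_id, barcode, batch_id")
  if (any(nchar(e$barcode) != 6L))
    msg <- c(msg, "barcodes must be exactly 6 nucleotides")
  if (any(grepl("[^ACGT]", e$barcode)))
    msg <- c(msg, "barcodes must be A/C/G/T only")
  dup <- unlist(lapply(split(e$barcode, e$batch_id), function(b) anyDuplicated(b) > 0L))
  if (any(dup)) msg <- c(msg, "barcodes must be unique within a batch")
  if (length(msg)) msg else TRUE
}
setValidity("SampleSheet", .validSampleSheet)

#' Simulation configuration for synthetic panel batches
#'
#' Defaults emulate the production assay: 96-sample batches, mean depth
#' around 1000x, 2x150 paired-end reads, amplicons multiplexed in groups of
#' five, and pseudogene homologs at 95-98 percent identity. Event injection is
#' driven by three specs: `variant_spec` (SNVs/indels with zygosity),
#' `lr_spec` (whole-region heterozygous deletions/duplications, copy change
#' -1 or +1) and `dropout_spec` (single-allele amplification of one amplicon).
#'
#' @slot seed integer seed controlling every random draw.
#' @slot n_samples samples per batch (default 96).
#' @slot mean_depth target mean read depth per base (default 1000).
#' @slot read_length read length in bases, paired (default 150).
#' @slot base_error_rate per-base substitution error probability.
#' @slot n_genes number of genes in the simulated panel.
#' @slot regions_per_gene exon-like regions per gene.
#' @slot region_length bases per region.
#' @slot amplicons_per_region tiling amplicons per region (default 5).
#' @slot pseudogene_identity sequence identity of pseudogene homologs, in
#'   `[0.90, 0.99]`.
#' @slot pseudogene_fraction fraction of genes given a pseudogene homolog.
#' @slot contamination_rate fraction of a gene's reads drawn from its
#'   pseudogene (crosstalk the assignment step must discard).
#' @slot variant_spec data.frame: sample_id, gene, position (1-based within
#'   the gene), ref, alt, zygosity.
#' @slot lr_spec data.frame: sample_id, gene, region_labels (comma-joined
#'   span), copy_change (-1 or +1).
#' @slot dropout_spec data.frame: sample_id, amplicon_id.
#' @slot amplicon_count_noise_cv coefficient of variation of per-amplicon
#'   counts (0 gives the exact noise-free mode used by identity tests).
#' @slot sub_q30_fraction fraction of reads with a degraded 3' quality tail.
#' @slot probes_per_region CGH probes per region (default 27).
#' @export
setClass("SimulationConfig",
  representation(seed = "integer", n_samples = "integer", mean_depth = "numeric",
    read_length = "integer", base_error_rate = "numeric", n_genes = "integer",
    regions_per_gene = "integer", region_length = "integer",
    amplicons_per_region = "integer", pseudogene_identity = "numeric",
    pseudogene_fraction = "numeric", contamination_rate = "numeric",
    variant_spec = "data.frame", lr_spec = "data.frame",
    dropout_spec = "data.frame", amplicon_count_noise_cv = "numeric",
    sub_q30_fraction = "numeric", probes_per_region = "integer"))

.validSimulationConfig <- function(object) {
  msg <- character()
  pr <- c(base_error_rate = object@base_error_rate,
          pseudogene_fraction = object@pseudogene_fraction,
          contamination_rate = object@contamination_rate,
          sub_q30_fraction = object@sub_q30_fraction)
  bad <- pr < 0 | pr > 1
  if (any(bad)) msg <- c(msg, paste(names(pr)[bad], "must lie in [0,1]"))
  if (object@pseudogene_identity >= 1)
    msg <- c(msg, "pseudogene_identity must be < 1 (an identical pseudogene is indistinguishable)")
  if (object@pseudogene_identity < 0.5)
    msg <- c(msg, "pseudogene_identity unrealistically low")
  if (object@n_genes < 1L) msg <- c(msg, "n_genes must be >= 1")
  if (length(msg)) msg else TRUE
}
setValidity("SimulationConfig", .validSimulationConfig)

#' Ground truth accompanying a simulated batch
#'
#' @slot variants data.frame of expected variant calls (sample_id, contig,
#'   pos, ref, alt, zygosity).
#' @slot dosages data.frame of expected region copy numbers (sample_id, gene,
#'   region_label, copies; wild type 2).
#' @slot dropouts data.frame of expected allele-dropout flags (sample_id,
#'   amplicon_id).
#' @export
setClass("TruthSet",
  representation(variants = "data.frame", dosages = "data.frame",
                 dropouts = "data.frame"))

#' Samples-by-amplicons read-count matrix
#'
#' Thin [SummarizedExperiment::SummarizedExperiment] container: rows are
#' amplicons (with their insert ranges when known), columns are the samples of
#' one batch, and the single `"counts"` assay holds non-negative trimmed,
#' mapped read counts.
#' @export
setClass("AmpliconCounts", contains = "SummarizedExperiment")

.validAmpliconCounts <- function(object) {
  cts <- assay(object, "counts")
  if (any(cts < 0)) return("counts must be non-negative")
  TRUE
}
setValidity("AmpliconCounts", .validAmpliconCounts)

#' Region copy-number dosage for every sample in a batch
#'
#' Rows are panel regions, columns samples; the `"dosage"` assay is on the
#' copy-number scale (wild type = 2). Row metadata records `n_amplicons` (how
#' many amplicons back each region) and `dispersion`, the batch standard
#' deviation of the region summary used to judge outliers. Failed samples and
#' untestable regions are `NA` ("No Result").
#' @export
setClass("RegionDosage", contains = "RangedSummarizedExperiment")

#' Per-position allele pileup for assigned reads
#'
#' @slot calls data.frame with one row per (sample_id, contig, pos, allele)
#'   carrying `count`, `fwd` and `rev` read support. SNV alleles are single
#'   bases; indel alleles are keyed by their left-normalized `ref>alt`
#'   representation anchored one base 5' of the event.
#' @slot counters named integer vector of bookkeeping counters (reads in,
#'   assigned, discarded as pseudogene, unmapped, outside panel).
#' @export
setClass("Pileup",
  representation(calls = "data.frame", counters = "integer"))

#' Concordance accounting between a test and a truth call set
#'
#' Base-complete accounting over `n_samples` x `bases_per_sample` positions:
#' TP + FN + FP + TN equals the total bases compared. Zygosity-discordant
#' sites are counted as one FN plus one FP and itemized in `discordant`.
#'
#' @slot tp,fn,fp,tn numeric counts.
#' @slot bases_per_sample bases analyzed per sample.
#' @slot n_samples number of samples compared.
#' @slot discordant data.frame itemizing FN/FP/zygosity-mismatch sites.
#' @export
setClass("ConcordanceTable",
  representation(tp = "numeric", fn = "numeric", fp = "numeric", tn = "numeric",
    bases_per_sample = "numeric", n_samples = "numeric",
    discordant = "data.frame"))

.validConcordanceTable <- function(object) {
  v <- c(object@tp, object@fn, object@fp, object@tn)
  if (any(v < 0)) return("counts must be non-negative")
  TRUE
}
setValidity("ConcordanceTable", .validConcordanceTable)

#' Exact one-sided binomial confidence bound
#'
#' @slot point_estimate observed proportion.
#' @slot lower_bound exact (Clopper-Pearson) one-sided lower confidence limit.
#' @slot confidence confidence level (default 0.95).
#' @slot method always `"exact one-sided"`.
#' @export
setClass("ConfidenceBound",
  representation(point_estimate = "numeric", lower_bound = "numeric",
                 confidence = "numeric", method = "character"))

.validConfidenceBound <- function(object) {
  if (object@lower_bound > object@point_estimate + 1e-12)
    return("lower_bound must not exceed point_estimate")
  if (object@lower_bound < 0 || object@point_estimate > 1)
    return("bounds must lie in [0,1]")
  TRUE
}
setValidity("ConfidenceBound", .validConfidenceBound)
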