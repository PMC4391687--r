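## Constructors, accessors and show methods for the core classes.

#' Construct a PanelDefinition
#'
#' @param regions GRanges of panel regions with metadata columns `gene_name`,
#'   `region_label`, `upstream_flank`, `downstream_flank`, `tested_by_lr`.
#' @param amplicons GRanges of amplicon inserts with metadata columns
#'   `amplicon_id`, `forward_primer`, `reverse_primer`, `multiplex_group`.
#' @return A [PanelDefinition-class] with the amplicon/region overlap index
#'   built (half-open interval intersection on the same contig).
#' @export
PanelDefinition <- function(regions, amplicons) {
  ov <- findOverlaps(amplicons, regions)
  new("PanelDefinition", regions = regions, amplicons = amplicons, overlaps = ov)
}

#' @describeIn PanelDefinition regions of interest as GRanges.
#' @param x,object a PanelDefinition.
#' @export
panelRegions <- function(x) x@regions

#' @describeIn PanelDefinition amplicon inserts as GRanges.
#' @export
panelAmplicons <- function(x) x@amplicons

#' @describeIn PanelDefinition Hits index linking amplicons to the regions
#'   they overlap.
#' @export
ampliconOverlaps <- function(x) x@overlaps

setMethod("show", "PanelDefinition", function(object) {
  cat("PanelDefinition:", length(object@regions), "regions,",
      length(object@amplicons), "amplicons on",
      length(unique(as.character(seqnames(object@regions)))), "contigs\n")
  cat("  genes:", paste(unique(mcols(object@regions)$gene_name), collapse = ", "), "\n")
})

#' Construct a ReferenceSet
#'
#' @param genes named DNAStringSet (or named character) of gene references.
#' @param pseudogenes named DNAStringSet of pseudogene references; may be
#'   empty.
#' @param homologyPairs data.frame with columns `gene`, `pseudogene`.
#' @export
ReferenceSet <- function(genes, pseudogenes = DNAStringSet(),
                         homologyPairs = data.frame(gene = character(),
                                                    pseudogene = character())) {
  new("ReferenceSet", genes = DNAStringSet(genes),
      pseudogenes = DNAStringSet(pseudogenes),
      homologyPairs = homologyPairs)
}

#' @describeIn ReferenceSet gene sequences.
#' @param x,object a ReferenceSet.
#' @export
refGenes <- function(x) x@genes

#' @describeIn ReferenceSet pseudogene sequences.
#' @export
refPseudogenes <- function(x) x@pseudogenes

#' @describeIn ReferenceSet gene/pseudogene homology pairing.
#' @export
homologyPairs <- function(x) x@homologyPairs

setMethod("show", "ReferenceSet", function(object) {
  cat("ReferenceSet:", length(object@genes), "genes,",
      length(object@pseudogenes), "pseudogenes,",
      nrow(object@homologyPairs), "homology pairs\n")
})

#' Construct a SampleSheet
#'
#' @param sample_id,barcode,batch_id vectors, or pass a data.frame carrying
#'   those columns as `sample_id`.
#' @export
SampleSheet <- function(sample_id, barcode = NULL, batch_id = "batch1") {
  if (is.data.frame(sample_id)) e <- sample_id
  else e <- data.frame(sample_id = as.character(sample_id),
                       barcode = toupper(as.character(barcode)),
                       batch_id = as.character(batch_id))
  new("SampleSheet", entries = e)
}

#' @describeIn SampleSheet the (sample_id, barcode, batch_id) table.
#' @param x,object a SampleSheet.
#' @export
sheetEntries <- function(x) x@entries

setMethod("show", "SampleSheet", function(object) {
  cat("SampleSheet:", nrow(object@entries), "samples in",
      length(unique(object@entries$batch_id)), "batch(es)\n")
})

#' Construct a SimulationConfig
#'
#' All arguments have assay-realistic defaults (96-sample batch, mean depth
#' 1000, 2x150 paired reads, 5 amplicons per region, pseudogene identity
#' 0.97); see [SimulationConfig-class] for their meaning.
#'
#' @param seed integer seed.
#' @param n_samples,mean_depth,read_length,base_error_rate,n_genes numbers.
#' @param regions_per_gene,region_length,amplicons_per_region numbers.
#' @param pseudogene_identity,pseudogene_fraction,contamination_rate numbers.
#' @param variant_spec,lr_spec,dropout_spec event data.frames (see class doc).
#' @param amplicon_count_noise_cv,sub_q30_fraction,probes_per_region numbers.
#' @export
SimulationConfig <- function(seed = 1L, n_samples = 96L, mean_depth = 1000,
    read_length = 150L, base_error_rate = 0.001, n_genes = 4L,
    regions_per_gene = 5L, region_length = 120L, amplicons_per_region = 5L,
    pseudogene_identity = 0.97, pseudogene_fraction = 0.5,
    contamination_rate = 0.05,
    variant_spec = .empty_variant_spec(), lr_spec = .empty_lr_spec(),
    dropout_spec = .empty_dropout_spec(), amplicon_count_noise_cv = 0.08,
    sub_q30_fraction = 0.1, probes_per_region = 27L) {
  new("SimulationConfig", seed = as.integer(seed),
      n_samples = as.integer(n_samples), mean_depth = mean_depth,
      read_length = as.integer(read_length), base_error_rate = base_error_rate,
      n_genes = as.integer(n_genes), regions_per_gene = as.integer(regions_per_gene),
      region_length = as.integer(region_length),
      amplicons_per_region = as.integer(amplicons_per_region),
      pseudogene_identity = pseudogene_identity,
      pseudogene_fraction = pseudogene_fraction,
      contamination_rate = contamination_rate,
      variant_spec = variant_spec, lr_spec = lr_spec,
      dropout_spec = dropout_spec,
      amplicon_count_noise_cv = amplicon_count_noise_cv,
      sub_q30_fraction = sub_q30_fraction,
      probes_per_region = as.integer(probes_per_region))
}

.empty_variant_spec <- function()
  data.frame(sample_id = character(), gene = character(), position = integer(),
             ref = character(), alt = character(), zygosity = character())
.empty_lr_spec <- function()
  data.frame(sample_id = character(), gene = character(),
             region_labels = character(), copy_change = integer())
.empty_dropout_spec <- function()
  data.frame(sample_id = character(), amplicon_id = character())

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig: seed", object@seed, "|", object@n_samples, "samples |",
      object@n_genes, "genes x", object@regions_per_gene, "regions | depth",
      object@mean_depth, "\n")
  cat("  events:", nrow(object@variant_spec), "variants,",
      nrow(object@lr_spec), "LRs,", nrow(object@dropout_spec), "dropouts\n")
})

#' Construct a TruthSet
#' @param variants,dosages,dropouts ground-truth data.frames.
#' @export
TruthSet <- function(variants = .empty_truth_variants(),
                     dosages = data.frame(), dropouts = .empty_dropout_spec()) {
  new("TruthSet", variants = variants, dosages = dosages, dropouts = dropouts)
}
.empty_truth_variants <- function()
  data.frame(sample_id = character(), contig = character(), pos = integer(),
             ref = character(), alt = character(), zygosity = character())

#' @describeIn TruthSet expected variant calls.
#' @param x,object a TruthSet.
#' @export
truthVariants <- function(x) x@variants

#' @describeIn TruthSet expected region copy numbers.
#' @export
truthDosages <- function(x) x@dosages

#' @describeIn TruthSet expected allele-dropout flags.
#' @export
truthDropouts <- function(x) x@dropouts

setMethod("show", "TruthSet", function(object) {
  cat("TruthSet:", nrow(object@variants), "variants,",
      sum(object@dosages$copies != 2), "non-diploid region dosages,",
      nrow(object@dropouts), "dropouts\n")
})

#' Construct an AmpliconCounts matrix
#'
#' @param counts integer matrix, amplicons in rows, samples in columns;
#'   dimnames give amplicon and sample identifiers.
#' @param rowRanges optional GRanges of amplicon inserts (same order as rows).
#' @export
AmpliconCounts <- function(counts, rowRanges = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have amplicon rownames and sample colnames")
  if (is.null(rowRanges))
    se <- SummarizedExperiment(assays = list(counts = counts))
  else
    se <- SummarizedExperiment(assays = list(counts = counts), rowRanges = rowRanges)
  new("AmpliconCounts", se)
}

#' @describeIn Pileup the per-position allele count table.
#' @param x,object a Pileup.
#' @export
pileupCalls <- function(x) x@calls

#' @describeIn Pileup read-conservation counters accumulated during
#'   processing.
#' @export
pileupCounters <- function(x) x@counters

setMethod("show", "Pileup", function(object) {
  cat("Pileup:", nrow(object@calls), "allele records,",
      length(unique(object@calls$sample_id)), "samples\n")
  cat("  counters:", paste(names(object@counters), object@counters,
                           collapse = ", "), "\n")
})

#' Construct a ConcordanceTable
#' @param tp,fn,fp,tn counts.
#' @param bases_per_sample,n_samples denominator bookkeeping.
#' @param discordant itemized discordant sites.
#' @export
ConcordanceTable <- function(tp, fn, fp, tn, bases_per_sample = NA_real_,
                             n_samples = NA_real_,
                             discordant = data.frame()) {
  new("ConcordanceTable", tp = as.numeric(tp), fn = as.numeric(fn),
      fp = as.numeric(fp), tn = as.numeric(tn),
      bases_per_sample = as.numeric(bases_per_sample),
      n_samples = as.numeric(n_samples), discordant = discordant)
}

#' @describeIn ConcordanceTable counts as a named vector (tp, fn, fp, tn).
#' @param x,object a ConcordanceTable.
#' @export
concordanceCounts <- function(x)
  c(tp = x@tp, fn = x@fn, fp = x@fp, tn = x@tn)

#' @describeIn ConcordanceTable itemized discordant sites.
#' @export
discordantSites <- function(x) x@discordant

setMethod("show", "ConcordanceTable", function(object) {
  cat("ConcordanceTable over", object@n_samples, "samples x",
      format(object@bases_per_sample, big.mark = ","), "bases\n")
  cat(sprintf("  TP %s  FN %s  FP %s  TN %s\n",
              format(object@tp, big.mark = ","), object@fn, object@fp,
              format(object@tn, big.mark = ",")))
})

#' @describeIn ConfidenceBound numeric lower limit.
#' @param x,object a ConfidenceBound.
#' @export
lowerBound <- function(x) x@lower_bound

#' @describeIn ConfidenceBound observed proportion.
#' @export
pointEstimate <- function(x) x@point_estimate

setMethod("show", "ConfidenceBound", function(object) {
  cat(sprintf("ConfidenceBound: estimate %.6f, exact one-sided lower %g%% bound %.6f (> %s%%)\n",
              object@point_estimate, object@confidence * 100,
              object@lower_bound, formatPercentTruncated(object@lower_bound)))
})
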