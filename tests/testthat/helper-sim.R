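## Shared fixtures and small utilities, built in code at test time.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
  library(S4Vectors)
  library(SummarizedExperiment)
})

## memoized small simulated panel used across files
.fixture_env <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    cfg <- SimulationConfig(seed = 42, n_samples = 4, n_genes = 3,
                            regions_per_gene = 3)
    .fixture_env$sim <- c(simulatePanel(cfg), list(cfg = cfg))
  }
  .fixture_env$sim
}

## VRanges call set -> plain data.frame keyed like a TruthSet
calls_df <- function(calls) {
  if (!length(calls))
    return(data.frame(sample_id = character(), contig = character(),
                      pos = integer(), ref = character(), alt = character(),
                      zygosity = character(), status = character()))
  data.frame(
    sample_id = as.character(VariantAnnotation::sampleNames(calls)),
    contig = as.character(seqnames(calls)), pos = start(calls),
    ref = VariantAnnotation::ref(calls), alt = VariantAnnotation::alt(calls),
    zygosity = calls$zygosity, status = calls$status)
}

call_key <- function(df) paste(df$sample_id, df$contig, df$pos, df$ref,
                               df$alt, df$zygosity)

## hand-built two-gene reference set with a pseudogene sharing a segment
toy_refs <- function() {
  set.seed(7)
  base <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  gene_a <- base
  ## pseudogene: identical in [1,200], divergent at 10 sites in [201,400]
  x <- strsplit(base, "")[[1]]
  div <- seq(210, 390, by = 20)
  x[div] <- vapply(x[div], function(b)
    setdiff(c("A", "C", "G", "T"), b)[1], "")
  ps_a <- paste(x, collapse = "")
  gene_b <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  ReferenceSet(
    genes = DNAStringSet(c(GENE_A = gene_a, GENE_B = gene_b)),
    pseudogenes = DNAStringSet(c(PSEUDO_A = ps_a)),
    homologyPairs = data.frame(gene = "GENE_A", pseudogene = "PSEUDO_A"))
}

phred_string <- function(q, n) strrep(rawToChar(as.raw(q + 33L)), n)

## one wide region so arbitrary positions are inside the panel
.flat_panel <- function(width = 90000L) {
  rg <- GRanges("PANEL", IRanges(1, width))
  mcols(rg) <- DataFrame(gene_name = "PANEL", region_label = "all",
                         upstream_flank = 0L, downstream_flank = 0L,
                         tested_by_lr = FALSE)
  am <- GRanges("PANEL", IRanges(1, width))
  mcols(am) <- DataFrame(amplicon_id = "A1", forward_primer = "ACGT",
                         reverse_primer = "ACGT", multiplex_group = "m1")
  PanelDefinition(rg, am)
}
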