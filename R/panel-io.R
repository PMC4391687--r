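## Readers and writers for the formats the pipeline touches: the BED-like
## panel manifest, FASTA references with a homology pairing table, sample
## sheets, count/dosage/probe TSVs and VCF output.
##
## Manifest dialect: tab-separated with a header, one line per record.
## Columns: record_type (region|amplicon), contig, start, end (0-based
## half-open), gene_name, region_label, upstream_flank, downstream_flank,
## tested_by_lr, amplicon_id, forward_primer, reverse_primer,
## multiplex_group. Fields not applicable to a record type hold ".".
## In memory everything is GRanges (1-based closed); the converters are exact.

.manifest_cols <- c("record_type", "contig", "start", "end", "gene_name",
  "region_label", "upstream_flank", "downstream_flank", "tested_by_lr",
  "amplicon_id", "forward_primer", "reverse_primer", "multiplex_group")

#' Load a panel manifest
#'
#' Reads the tab-separated panel manifest (regions of interest and amplicon
#' definitions, 0-based half-open coordinates on disk) and returns a
#' validated [PanelDefinition-class] with the amplicon/region overlap index
#' built.
#'
#' @param manifest_path path to the manifest TSV.
#' @return A [PanelDefinition-class].
#' @examples
#' pan <- simulatePanel(SimulationConfig(seed = 1, n_genes = 2))$panel
#' tf <- tempfile(fileext = ".tsv")
#' writePanelManifest(pan, tf)
#' identical(panelRegions(loadPanel(tf)), panelRegions(pan))
#' @export
loadPanel <- function(manifest_path) {
  tab <- tryCatch(
    read.delim(manifest_path, colClasses = "character", check.names = FALSE),
    error = function(e) stop("cannot parse manifest: ", conditionMessage(e)))
  if (!all(.manifest_cols %in% names(tab)))
    stop("manifest header must contain: ", paste(.manifest_cols, collapse = ", "))
  n <- nrow(tab)
  line_no <- seq_len(n) + 1L  # header is line 1
  num <- function(x, what, i) {
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("manifest line %d: malformed %s '%s'",
                   line_no[i][bad[1]], what, x[bad[1]]))
    v
  }
  is_reg <- tab$record_type == "region"
  is_amp <- tab$record_type == "amplicon"
  bad <- which(!(is_reg | is_amp))
  if (length(bad))
    stop(sprintf("manifest line %d: unknown record_type '%s'",
                 line_no[bad[1]], tab$record_type[bad[1]]))
  start0 <- num(tab$start, "start", seq_len(n))
  end0 <- num(tab$end, "end", seq_len(n))

  r <- which(is_reg)
  if (!length(r)) stop("manifest defines no regions")
  uf <- num(tab$upstream_flank[r], "upstream_flank", r)
  df <- num(tab$downstream_flank[r], "downstream_flank", r)
  if (any(uf > 20))
    stop(sprintf("manifest line %d: upstream_flank %g exceeds the 20-base maximum",
                 line_no[r][which(uf > 20)[1]], max(uf)))
  if (any(df > 10))
    stop(sprintf("manifest line %d: downstream_flank %g exceeds the 10-base maximum",
                 line_no[r][which(df > 10)[1]], max(df)))
  if (any(start0[r] >= end0[r]))
    stop(sprintf("manifest line %d: region start must be < end",
                 line_no[r][which(start0[r] >= end0[r])[1]]))
  regions <- GRanges(tab$contig[r], IRanges(start0[r] + 1L, end0[r]))
  mcols(regions) <- DataFrame(gene_name = tab$gene_name[r],
    region_label = tab$region_label[r], upstream_flank = as.integer(uf),
    downstream_flank = as.integer(df),
    tested_by_lr = tab$tested_by_lr[r] %in% c("TRUE", "true", "1"))

  a <- which(is_amp)
  if (any(start0[a] >= end0[a]))
    stop(sprintf("manifest line %d: amplicon insert_start must be < insert_end",
                 line_no[a][which(start0[a] >= end0[a])[1]]))
  amplicons <- GRanges(tab$contig[a], IRanges(start0[a] + 1L, end0[a]))
  mcols(amplicons) <- DataFrame(amplicon_id = tab$amplicon_id[a],
    forward_primer = toupper(tab$forward_primer[a]),
    reverse_primer = toupper(tab$reverse_primer[a]),
    multiplex_group = tab$multiplex_group[a])
  PanelDefinition(regions, amplicons)
}

#' Write a panel manifest
#'
#' Inverse of [loadPanel()]; coordinates are converted back to 0-based
#' half-open. `loadPanel(writePanelManifest(x, f))` reproduces `x`.
#'
#' @param panel a [PanelDefinition-class].
#' @param out_path output TSV path.
#' @return `out_path`, invisibly.
#' @export
writePanelManifest <- function(panel, out_path) {
  rg <- panelRegions(panel); am <- panelAmplicons(panel)
  dot <- function(n) rep(".", n)
  rtab <- data.frame(record_type = "region",
    contig = as.character(seqnames(rg)), start = start(rg) - 1L, end = end(rg),
    gene_name = mcols(rg)$gene_name, region_label = mcols(rg)$region_label,
    upstream_flank = mcols(rg)$upstream_flank,
    downstream_flank = mcols(rg)$downstream_flank,
    tested_by_lr = mcols(rg)$tested_by_lr,
    amplicon_id = dot(length(rg)), forward_primer = dot(length(rg)),
    reverse_primer = dot(length(rg)), multiplex_group = dot(length(rg)))
  atab <- data.frame(record_type = "amplicon",
    contig = as.character(seqnames(am)), start = start(am) - 1L, end = end(am),
    gene_name = dot(length(am)), region_label = dot(length(am)),
    upstream_flank = dot(length(am)), downstream_flank = dot(length(am)),
    tested_by_lr = dot(length(am)),
    amplicon_id = mcols(am)$amplicon_id,
    forward_primer = mcols(am)$forward_primer,
    reverse_primer = mcols(am)$reverse_primer,
    multiplex_group = mcols(am)$multiplex_group)
  write.table(rbind(rtab, atab), out_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(out_path)
}

#' Load gene and pseudogene references
#'
#' Reads a FASTA of reference sequences and a two-column homology table
#' (`gene<TAB>pseudogene`, no header required if the header is absent, a
#' header line `gene  pseudogene` is also accepted) pairing each gene with
#' its homologous pseudogene. Ids appearing in the pseudogene column are
#' placed in the pseudogene map; all other records are genes. Sequences are
#' uppercased.
#'
#' @param fasta_path FASTA of all reference sequences.
#' @param homology_path TSV of gene/pseudogene pairs; may list zero pairs, in
#'   which case pseudogene filtering is a no-op.
#' @return A [ReferenceSet-class].
#' @export
loadReferences <- function(fasta_path, homology_path) {
  seqs <- readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate FASTA id: ", names(seqs)[duplicated(names(seqs))][1])
  seqs <- DNAStringSet(toupper(seqs))
  hl <- readLines(homology_path)
  hl <- hl[nzchar(trimws(hl))]
  hl <- hl[!(seq_along(hl) == 1L & grepl("^gene\\b", hl))]
  if (length(hl)) {
    parts <- strsplit(hl, "\t")
    if (any(lengths(parts) != 2L)) stop("homology file must have 2 tab-separated columns")
    hp <- data.frame(gene = vapply(parts, `[`, "", 1L),
                     pseudogene = vapply(parts, `[`, "", 2L))
  } else {
    hp <- data.frame(gene = character(), pseudogene = character())
  }
  unknown <- setdiff(c(hp$gene, hp$pseudogene), names(seqs))
  if (length(unknown))
    stop("homology pair references unknown id: ", unknown[1])
  is_ps <- names(seqs) %in% hp$pseudogene
  ReferenceSet(genes = seqs[!is_ps], pseudogenes = seqs[is_ps],
               homologyPairs = hp)
}

#' Write references to FASTA plus homology table
#' @param refs a [ReferenceSet-class].
#' @param fasta_path,homology_path output paths.
#' @export
writeReferences <- function(refs, fasta_path, homology_path) {
  writeXStringSet(c(refGenes(refs), refPseudogenes(refs)), fasta_path)
  hp <- homologyPairs(refs)
  writeLines(c("gene\tpseudogene", paste(hp$gene, hp$pseudogene, sep = "\t")),
             homology_path)
  invisible(fasta_path)
}

#' Load a sample sheet TSV
#'
#' Expected columns: `sample_id`, `barcode` (6 nt), `batch_id`.
#' @param path TSV path.
#' @export
loadSampleSheet <- function(path) {
  SampleSheet(read.delim(path, colClasses = "character"))
}

#' Write a sample sheet TSV
#' @param sheet a [SampleSheet-class].
#' @param path output path.
#' @export
writeSampleSheet <- function(sheet, path) {
  write.table(sheetEntries(sheet), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

## ---- VCF ----

#' Left-normalize an indel against its reference sequence
#'
#' Applies the standard VCF parsimony/left-alignment convention: shared
#' trailing bases are trimmed (extending to the left through repeat tracts),
#' then shared leading bases beyond the anchor are trimmed. SNVs pass
#' through unchanged.
#'
#' @param refseq the contig sequence (character or DNAString).
#' @param pos 1-based position of the first `ref` base.
#' @param ref,alt allele strings as observed.
#' @return list(pos, ref, alt) in left-normalized form.
#' @export
leftNormalize <- function(refseq, pos, ref, alt) {
  refseq <- as.character(refseq)
  repeat {
    lr <- nchar(ref); la <- nchar(alt)
    if (lr > 0 && la > 0 && substr(ref, lr, lr) == substr(alt, la, la) &&
        (lr > 1 || la > 1)) {
      ref <- substr(ref, 1L, lr - 1L)
      alt <- substr(alt, 1L, la - 1L)
      if (nchar(ref) == 0L || nchar(alt) == 0L) {
        if (pos == 1L) { # cannot extend left; re-anchor on the right instead
          nxt <- substr(refseq, pos + nchar(ref), pos + nchar(ref))
          ref <- paste0(ref, nxt); alt <- paste0(alt, nxt)
          break
        }
        pos <- pos - 1L
        b <- substr(refseq, pos, pos)
        ref <- paste0(b, ref); alt <- paste0(b, alt)
      }
    } else break
  }
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref)); alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Write variant calls to VCF
#'
#' Calls are sorted, indels are left-normalized against the supplied
#' references, the REF allele is checked against the reference sequence, and
#' zygosity is encoded in GT (`0/1` heterozygous, `1/1` homozygous). Calls in
#' the intermediate-frequency bands carry the per-genotype filter tag
#' `confirm` (Sanger follow-up); passing calls carry `PASS`.
#'
#' @param calls a [VariantAnnotation::VRanges] as produced by
#'   [callVariants()], with metadata columns `zygosity`, `status`,
#'   `non_wt_frequency`, `forward_depth`, `reverse_depth`.
#' @param out_path output `.vcf` path.
#' @param references optional [ReferenceSet-class] for REF validation and
#'   left-normalization.
#' @return `out_path`, invisibly.
#' @export
writeVariantCalls <- function(calls, out_path, references = NULL) {
  if (length(calls)) {
    if (!is.null(references)) {
      seqs <- c(refGenes(references), refPseudogenes(references))
      for (i in seq_along(calls)) {
        ctg <- as.character(seqnames(calls)[i])
        if (!ctg %in% names(seqs)) next
        rs <- as.character(seqs[[ctg]])
        ln <- leftNormalize(rs, start(calls)[i], VariantAnnotation::ref(calls)[i],
                            VariantAnnotation::alt(calls)[i])
        obs <- substr(rs, ln$pos, ln$pos + nchar(ln$ref) - 1L)
        if (obs != ln$ref)
          stop(sprintf("REF allele %s does not match reference %s at %s:%d",
                       ln$ref, obs, ctg, ln$pos))
        VariantAnnotation::ref(calls)[i] <- ln$ref
        VariantAnnotation::alt(calls)[i] <- ln$alt
        IRanges::ranges(calls)[i] <- IRanges(ln$pos, width = nchar(ln$ref))
      }
    }
    calls <- calls[order(as.character(seqnames(calls)), start(calls),
                         as.character(VariantAnnotation::sampleNames(calls)))]
    calls$GT <- ifelse(calls$zygosity == "heterozygous", "0/1", "1/1")
    flt <- matrix(calls$status != "flagged_for_confirmation", ncol = 1,
                  dimnames = list(NULL, "confirm"))
    VariantAnnotation::softFilterMatrix(calls) <- flt
  }
  if (!length(calls)) {
    writeLines(c("##fileformat=VCFv4.2",
                 paste0("##fileDate=", format(Sys.Date(), "%Y%m%d")),
                 "##FILTER=<ID=confirm,Description=\"Intermediate frequency; Sanger follow-up\">",
                 "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                 paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", sep = "\t")), out_path)
    return(invisible(out_path))
  }
  VariantAnnotation::writeVcf(calls, out_path)
  invisible(out_path)
}

#' Read variant calls back from a VCF written by [writeVariantCalls()]
#'
#' @param vcf_path path to the VCF.
#' @return A [VariantAnnotation::VRanges] with `zygosity` and `status`
#'   metadata columns reconstructed from GT and the `confirm` filter tag.
#' @export
readVariantCalls <- function(vcf_path) {
  vcf <- VariantAnnotation::readVcf(vcf_path)
  if (!nrow(vcf)) return(VariantAnnotation::VRanges())
  vr <- as(vcf, "VRanges")
  ## the expansion materializes every (range, sample) pair; keep only the
  ## samples actually genotyped at each site
  gt <- as.character(vr$GT)
  vr <- vr[!is.na(gt) & gt != "." & gt != "./."]
  if (length(vr)) {
    sf <- VariantAnnotation::softFilterMatrix(vr)
    flagged <- if ("confirm" %in% colnames(sf)) !sf[, "confirm"]
               else rep(FALSE, length(vr))
    flagged[is.na(flagged)] <- FALSE
    vr$zygosity <- ifelse(as.character(vr$GT) == "1/1", "homozygous",
                          "heterozygous")
    vr$status <- ifelse(flagged, "flagged_for_confirmation", "called")
  }
  vr
}

## ---- dosage / count / probe tables ----

#' Write a region dosage table
#'
#' One row per (sample, region) with dosage on the copy-number scale; failed
#' samples / untestable regions are written as the explicit null marker `NA`
#' ("No Result"). Values round-trip through [readDosageTable()] exactly as
#' written (full precision via `format(..., digits = 15)`).
#'
#' @param dosages a [RegionDosage-class].
#' @param out_path output TSV path.
#' @export
writeDosageTable <- function(dosages, out_path) {
  d <- assay(dosages, "dosage")
  rd <- rowData(dosages)
  tab <- data.frame(
    sample_id = rep(colnames(d), each = nrow(d)),
    gene = rep(rd$gene_name, ncol(d)),
    region_label = rep(rd$region_label, ncol(d)),
    dosage = as.vector(d),
    n_amplicons = rep(rd$n_amplicons, ncol(d)),
    dispersion = rep(rd$dispersion, ncol(d)))
  tab$dosage <- ifelse(is.na(tab$dosage), "NA", format(tab$dosage, digits = 15))
  write.table(tab, out_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_path)
}

#' Read a dosage table written by [writeDosageTable()]
#' @param path TSV path.
#' @return data.frame with sample_id, gene, region_label, dosage,
#'   n_amplicons, dispersion.
#' @export
readDosageTable <- function(path) {
  tab <- read.delim(path, colClasses = c(dosage = "character"))
  tab$dosage <- suppressWarnings(as.numeric(tab$dosage))
  tab
}

#' Write a samples-by-amplicons count matrix as TSV
#' @param counts an [AmpliconCounts-class] or plain matrix (amplicons x
#'   samples).
#' @param out_path output TSV path.
#' @export
writeCountMatrix <- function(counts, out_path) {
  m <- if (is(counts, "AmpliconCounts")) assay(counts, "counts") else counts
  tab <- data.frame(amplicon_id = rownames(m), m, check.names = FALSE)
  write.table(tab, out_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_path)
}

#' Read a count matrix TSV into an AmpliconCounts object
#' @param path TSV path (first column `amplicon_id`, one column per sample).
#' @export
readCountMatrix <- function(path) {
  tab <- read.delim(path, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  AmpliconCounts(m)
}

#' Write a CGH probe intensity table as TSV
#' @param probes data.frame with probe_id, contig, position, gene_name,
#'   region_label, gc_fraction, sample_signal, reference_signal.
#' @param out_path output TSV path.
#' @export
writeProbeTable <- function(probes, out_path) {
  write.table(probes, out_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_path)
}

#' Read a CGH probe intensity table
#' @param path TSV path.
#' @export
readProbeTable <- function(path) read.delim(path)

#' Gene and transcript metadata of the production hereditary-cancer panel
#'
#' Static metadata only: the gene symbols, reference transcripts and
#' syndrome associations of the 25-gene panel this toolkit was built
#' around (CDKN2A appears as its two transcripts P16/P14ARF, MUTYH as two
#' alternative transcripts). All computation in the package is generic
#' over [PanelDefinition-class]; nothing reads this table.
#'
#' @return data.frame with columns gene, transcript, syndrome_association.
#' @export
panelGeneTable <- function() {
  read.delim(system.file("extdata", "panel_genes.tsv", package = "panelseq"))
}

#' Truncate a proportion to a printed percentage
#'
#' Validation bounds are reported in the conservative "greater than" style:
#' the proportion is truncated (not rounded) to two decimal places on the
#' percent scale, so 0.999236 prints as "99.92".
#' @param p proportion in `[0,1]`.
#' @param digits decimal places kept (default 2).
#' @return character scalar.
#' @export
formatPercentTruncated <- function(p, digits = 2) {
  f <- 10^digits
  sprintf(paste0("%.", digits, "f"), floor(p * 100 * f) / f)
}
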