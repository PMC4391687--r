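test_that("panel manifests round-trip and the overlap index matches brute force", {
  sim <- small_sim()
  tf <- withr::local_tempfile(fileext = ".tsv")
  writePanelManifest(sim$panel, tf)
  back <- loadPanel(tf)
  expect_equal(as.data.frame(panelRegions(back)),
               as.data.frame(panelRegions(sim$panel)))
  expect_equal(as.data.frame(panelAmplicons(back)),
               as.data.frame(panelAmplicons(sim$panel)))

  ## overlap index == brute-force half-open interval intersection
  rg <- panelRegions(back); am <- panelAmplicons(back)
  ov <- ampliconOverlaps(back)
  got <- sort(paste(queryHits(ov), subjectHits(ov)))
  want <- character()
  for (a in seq_along(am)) for (r in seq_along(rg)) {
    if (as.character(seqnames(am))[a] == as.character(seqnames(rg))[r] &&
        start(am)[a] <= end(rg)[r] && end(am)[a] >= start(rg)[r])
      want <- c(want, paste(a, r))
  }
  expect_equal(got, sort(want))
  ## every region base covered by >= 1 amplicon
  for (r in seq_along(rg)) {
    ai <- queryHits(ov)[subjectHits(ov) == r]
    cov <- vapply(seq(start(rg)[r], end(rg)[r]), function(p)
      sum(start(am)[ai] <= p & end(am)[ai] >= p), 0)
    expect_true(all(cov >= 1))
  }
})

test_that("malformed manifests are rejected with informative errors", {
  sim <- small_sim()
  tf <- withr::local_tempfile(fileext = ".tsv")
  writePanelManifest(sim$panel, tf)
  tab <- read.delim(tf, colClasses = "character")

  bad <- tab; bad$upstream_flank[1] <- "25"
  f1 <- withr::local_tempfile(fileext = ".tsv")
  write.table(bad, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(loadPanel(f1), "20-base maximum")

  bad <- tab
  amp_row <- which(bad$record_type == "amplicon")[1]
  bad$end[amp_row] <- bad$start[amp_row]   # empty half-open interval
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(bad, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(loadPanel(f2), "insert_start must be < insert_end")

  bad <- tab; bad$start[2] <- "oops"
  f3 <- withr::local_tempfile(fileext = ".tsv")
  write.table(bad, f3, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(loadPanel(f3), "line 3")   # header is line 1
})

test_that("reference FASTA + homology table load, validate and round-trip", {
  refs <- toy_refs()
  fa <- withr::local_tempfile(fileext = ".fasta")
  ho <- withr::local_tempfile(fileext = ".tsv")
  writeReferences(refs, fa, ho)
  back <- loadReferences(fa, ho)
  expect_equal(names(refGenes(back)), c("GENE_A", "GENE_B"))
  expect_equal(names(refPseudogenes(back)), "PSEUDO_A")
  expect_equal(nrow(homologyPairs(back)), 1L)
  expect_equal(as.character(refGenes(back)[["GENE_A"]]),
               as.character(refGenes(refs)[["GENE_A"]]))

  ## empty homology file -> no pairs, filtering becomes a no-op
  writeLines(character(), ho)
  nops <- loadReferences(fa, ho)
  expect_equal(nrow(homologyPairs(nops)), 0L)
  expect_equal(length(refPseudogenes(nops)), 0L)

  ## duplicate FASTA id
  writeLines(c(">DUP", "ACGT", ">DUP", "ACGT"), fa)
  expect_error(loadReferences(fa, ho), "duplicate FASTA id")

  ## pair referencing unknown id
  writeReferences(refs, fa, ho)
  writeLines(c("gene\tpseudogene", "GENE_A\tNOPE"), ho)
  expect_error(loadReferences(fa, ho), "unknown id")
})

test_that("the shipped panel metadata lists all genes with transcripts", {
  tab <- panelGeneTable()
  expect_gte(nrow(tab), 25L)
  expect_true(all(c("BRCA1", "BRCA2", "PMS2", "CHEK2", "EPCAM") %in% tab$gene))
  expect_true(all(grepl("^NM_", tab$transcript)))
})

test_that("indel left-normalization follows the VCF parsimony convention", {
  ##            123456789012
  refseq <-    "GGACCCCTTAGT"
  ## deletion inside the C-run, observed as (5, CCC, C), left-aligns to the
  ## run start
  expect_equal(leftNormalize(refseq, 5, "CCC", "C"),
               list(pos = 3L, ref = "ACC", alt = "A"))
  ## insertion inside the run likewise
  expect_equal(leftNormalize(refseq, 5, "C", "CC"),
               list(pos = 3L, ref = "A", alt = "AC"))
  ## SNVs pass through
  expect_equal(leftNormalize(refseq, 4, "C", "T"),
               list(pos = 4L, ref = "C", alt = "T"))
  ## already-parsimonious indel is unchanged
  expect_equal(leftNormalize(refseq, 8, "TTA", "T"),
               list(pos = 8L, ref = "TTA", alt = "T"))
})

test_that("variant calls round-trip through VCF with zygosity and filter tags", {
  refs <- ReferenceSet(genes = DNAStringSet(
    c(G1 = "ACGTACGTAAGGTTCCAAGGTTACGT")))
  vr <- VariantAnnotation::VRanges(
    seqnames = "G1", ranges = IRanges(c(5, 10, 15), width = c(1, 3, 1)),
    ref = c("A", "AGG", "C"), alt = c("G", "A", "CTT"),
    sampleNames = c("S1", "S1", "S2"), totalDepth = c(100L, 80L, 120L))
  vr$zygosity <- c("heterozygous", "heterozygous", "homozygous")
  vr$status <- c("called", "flagged_for_confirmation", "called")
  vr$non_wt_frequency <- c(0.5, 0.2, 0.97)
  f <- withr::local_tempfile(fileext = ".vcf")
  writeVariantCalls(vr, f, references = refs)

  txt <- readLines(f)
  body <- txt[!startsWith(txt, "#")]
  expect_length(body, 3L)
  expect_true(any(grepl("0/1", body)) && any(grepl("1/1", body)))
  expect_true(any(grepl("confirm", body)))

  back <- readVariantCalls(f)
  expect_length(back, 3L)
  got <- calls_df(back)
  want <- calls_df(vr)
  got <- got[order(got$sample_id, got$pos), ]
  want <- want[order(want$sample_id, want$pos), ]
  expect_equal(call_key(got), call_key(want))
  expect_equal(sort(got$status), sort(want$status))

  ## empty call set -> header-only VCF
  fe <- withr::local_tempfile(fileext = ".vcf")
  writeVariantCalls(VariantAnnotation::VRanges(), fe)
  expect_true(all(startsWith(readLines(fe), "#")))
  expect_length(readVariantCalls(fe), 0L)

  ## REF allele must match the reference sequence
  bad <- vr[1]
  VariantAnnotation::ref(bad) <- "T"
  expect_error(writeVariantCalls(bad, f, references = refs),
               "does not match")
})

test_that("dosage tables round-trip with explicit No Result markers", {
  sim <- small_sim()
  cfg <- SimulationConfig(seed = 9, n_samples = 10, n_genes = 3,
                          regions_per_gene = 3, amplicon_count_noise_cv = 0.05)
  cm <- simulateCountMatrix(cfg, sim$panel)
  m <- assay(cm$counts, "counts")
  m[, "S03"] <- 0L  # failed sample
  res <- runLrPipeline(AmpliconCounts(m), sim$panel)
  expect_equal(res$failed, "S03")
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeDosageTable(res$dosage, tf)
  back <- readDosageTable(tf)
  expect_equal(nrow(back), nrow(res$dosage) * ncol(res$dosage))
  expect_true(all(is.na(back$dosage[back$sample_id == "S03"])))
  d <- assay(res$dosage, "dosage")
  got <- back$dosage[back$sample_id == "S01"]
  expect_equal(got, unname(d[, "S01"]), tolerance = 1e-9)

  ## count matrices round-trip exactly
  cf <- withr::local_tempfile(fileext = ".tsv")
  writeCountMatrix(cm$counts, cf)
  cback <- readCountMatrix(cf)
  expect_equal(assay(cback, "counts"), assay(cm$counts, "counts"))
})
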