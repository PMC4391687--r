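test_that("demultiplexing routes by exact barcode and conserves reads", {
  sheet <- SampleSheet(sample_id = c("S1", "S2"),
                       barcode = c("ACGTAC", "TTGGCC"))
  f1 <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", paste0("ACGTAC", strrep("A", 30)), "+", phred_string(37, 36),
               "@r2", paste0("TTGGCC", strrep("C", 30)), "+", phred_string(37, 36),
               "@r3", paste0("ACGTAA", strrep("G", 30)), "+", phred_string(37, 36)),
             f1)  # r3: one mismatch from ACGTAC -> unassigned
  dmx <- demultiplexReads(f1, sheet = sheet)
  expect_equal(dmx$total, 3L)
  expect_equal(dmx$unassigned, 1L)
  expect_equal(nrow(dmx$reads) + dmx$unassigned, dmx$total)
  expect_equal(dmx$reads$sample_id, c("S1", "S2"))
  ## barcode stripped
  expect_equal(dmx$reads$seq[1], strrep("A", 30))
  expect_equal(nchar(dmx$reads$qual[1]), 30L)

  ## empty input -> empty map with zero counts
  fe <- withr::local_tempfile(fileext = ".fastq")
  writeLines(character(), fe)
  de <- demultiplexReads(fe, sheet = sheet)
  expect_equal(de$total, 0L)
  expect_equal(nrow(de$reads), 0L)

  ## duplicate barcodes within a batch rejected at sheet construction
  expect_error(SampleSheet(sample_id = c("A", "B"),
                           barcode = c("ACGTAC", "ACGTAC")),
               "unique within a batch")
  expect_error(SampleSheet(sample_id = "A", barcode = "ACGT"), "exactly 6")
})

test_that("trimming removes primers and sub-Q30 tails, never interior bases", {
  primer <- "ACGTACGTACGTACGTAC"
  body <- strrep("GATC", 20)  # 80 bases

  ## all Q40: unchanged apart from the primer
  r <- trimReads(paste0(primer, body), primers = primer,
                 quals = phred_string(40, 98))
  expect_true(r$primer_removed)
  expect_equal(r$seq, body)
  expect_equal(r$bases_trimmed, 18L)

  ## last 10 bases Q2: exactly those removed
  q <- paste0(phred_string(40, 70), phred_string(2, 10))
  r <- trimReads(body, primers = primer, quals = q)
  expect_false(r$primer_removed)
  expect_equal(nchar(r$seq), 70L)
  expect_equal(r$seq, substr(body, 1, 70))
  expect_equal(r$bases_trimmed, 10L)

  ## sawtooth tail with isolated good bases is still removed by the
  ## sliding-mean guard
  q <- paste0(phred_string(40, 70), "+5+5+5+5+5")  # Q10,Q20 alternating
  r <- trimReads(body, primers = primer, quals = q)
  expect_equal(nchar(r$seq), 70L)

  ## read equal to its primer -> empty read, primer removed
  r <- trimReads(primer, primers = primer, quals = phred_string(40, 18))
  expect_true(r$primer_removed)
  expect_equal(nchar(r$seq), 0L)

  ## primer with one mismatch still recognized
  p2 <- paste0("T", substr(primer, 2, 18))
  r <- trimReads(paste0(p2, body), primers = primer,
                 quals = phred_string(40, 98))
  expect_true(r$primer_removed)
  expect_equal(r$seq, body)

  ## interior order untouched: trimmed read is always a prefix
  set.seed(1)
  rs <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  qs <- rawToChar(as.raw(sample(c(2, 20, 40), 60, TRUE) + 33))
  r <- trimReads(rs, primers = primer, quals = qs)
  expect_equal(r$seq, substr(rs, 1, nchar(r$seq)))
})

test_that("pseudogene discard rule: ties and better pseudogene scores discard", {
  refs <- toy_refs()
  ga <- as.character(refGenes(refs)[["GENE_A"]])
  pa <- as.character(refPseudogenes(refs)[["PSEUDO_A"]])

  ## read from the shared identical segment [1,200]: tie -> discard
  shared <- substr(ga, 30, 149)
  ## read overlapping divergent sites, matching the gene exactly -> assigned
  gene_only <- substr(ga, 230, 349)
  ## read matching the pseudogene exactly over divergent sites -> discard
  ps_only <- substr(pa, 230, 349)
  ## garbage read -> unmapped
  garbage <- strrep("ACCGGTTA", 15)

  asg <- assignReads(c(shared, gene_only, ps_only, garbage), refs)$assignments
  expect_equal(asg$status, c("discarded_pseudogene", "assigned",
                             "discarded_pseudogene", "unmapped"))
  expect_equal(asg$gene_score[1], asg$pseudogene_score[1])  # exact tie
  expect_gt(asg$gene_score[2], asg$pseudogene_score[2])
  expect_gt(asg$pseudogene_score[3], asg$gene_score[3])
  expect_equal(asg$best_gene[2], "GENE_A")

  ## reverse-complement reads assign identically
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(c(shared, gene_only))))
  asg_rc <- assignReads(rc, refs)$assignments
  expect_equal(asg_rc$status, c("discarded_pseudogene", "assigned"))
  expect_equal(asg_rc$strand[2], "-")

  ## read with 3 mismatches against the gene still assigned; score drops by
  ## 5 per mismatch under +2/-3 scoring
  mm <- gene_only
  substr(mm, 10, 10) <- "N"  # will mismatch everything
  asg_mm <- assignReads(chartr("N", setdiff(c("A","C","G","T"),
    substr(gene_only, 10, 10))[1], mm), refs)$assignments
  expect_equal(asg_mm$status, "assigned")
  expect_equal(asg_mm$gene_score, 2 * 120 - 5)
})

test_that("contaminant pseudogene reads spanning a divergent site never enter the gene pileup", {
  refs <- toy_refs()
  pa <- as.character(refPseudogenes(refs)[["PSEUDO_A"]])
  div <- seq(210, 390, by = 20)
  set.seed(11)
  starts <- sample(150:280, 40, TRUE)
  reads <- substring(pa, starts, starts + 119)
  spans_div <- vapply(starts, function(s) any(div >= s & div <= s + 119), TRUE)
  asg <- assignReads(reads, refs)$assignments
  expect_true(all(asg$status[spans_div] == "discarded_pseudogene"))
})

test_that("pileup counts agree with a brute-force recount and track orientation", {
  refs <- ReferenceSet(genes = DNAStringSet(c(
    G1 = paste0(strrep("ACGT", 20), strrep("TGCA", 20)))))
  rg <- GRanges("G1", IRanges(1, 160))
  mcols(rg) <- DataFrame(gene_name = "G1", region_label = "exon 1",
                         upstream_flank = 0L, downstream_flank = 0L,
                         tested_by_lr = TRUE)
  am <- GRanges("G1", IRanges(1, 80))
  mcols(am) <- DataFrame(amplicon_id = "A1", forward_primer = "ACGT",
                         reverse_primer = "ACGT", multiplex_group = "m1")
  panel <- PanelDefinition(rg, am)
  g1 <- as.character(refGenes(refs)[["G1"]])

  ## 100 reads of the reference over [21,100]; 40 of them carry T at 50
  ref_read <- substr(g1, 21, 100)
  alt_read <- ref_read
  substr(alt_read, 30, 30) <- "T"   # position 50 on the reference
  stopifnot(substr(g1, 50, 50) != "T")
  df <- data.frame(read_id = sprintf("r%03d", 1:100), mate = 1L,
                   sample_id = "S1",
                   seq = c(rep(ref_read, 60), rep(alt_read, 40)),
                   qual = phred_string(40, 80))
  asg <- assignReads(df, refs)
  pile <- buildPileup(asg, panel)
  pc <- pileupCalls(pile)
  at50 <- pc[pc$pos == 50, ]
  expect_equal(sum(at50$count), 100L)
  expect_equal(at50$count[at50$allele == "T"], 40L)
  ## non-wild-type frequency 0.40 surfaces in the caller
  calls <- callVariants(pile, panel, refs, min_depth = 10)$calls
  expect_equal(calls$non_wt_frequency[start(calls) == 50], 0.40)

  ## brute force: depth at any position <= reads overlapping it
  depth <- tapply(pc$count, pc$pos, sum)
  overl <- vapply(as.integer(names(depth)), function(p)
    sum(p >= 21 & p <= 100) * 100, 0)
  expect_true(all(depth <= overl))
  ## conservation counters
  expect_equal(unname(pileupCounters(pile)["assigned"]), 100L)
  expect_equal(sum(pileupCounters(pile)[c("assigned",
    "discarded_pseudogene", "unmapped")]), 100L)
})

test_that("read conservation holds through the full pipeline counters", {
  sim <- small_sim()
  rd <- simulateReads(sim$cfg, sim$panel, sim$refs)
  res <- runSeqPipeline(rd$fastq1, rd$fastq2, rd$sheet, sim$panel, sim$refs,
                        min_depth = 10)
  ct <- res$counters
  expect_equal(unname(ct["routed"] + ct["unassigned"]), unname(ct["input"]))
  expect_equal(unname(ct["assigned"] + ct["discarded_pseudogene"] +
                      ct["unmapped"]), unname(ct["routed"]))
})
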