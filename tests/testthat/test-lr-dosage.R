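## a 10-amplicon, 2-region toy panel for normalization arithmetic
.toy_lr_panel <- function() {
  rg <- GRanges(rep("G1", 2), IRanges(c(1, 200), c(100, 300)))
  mcols(rg) <- DataFrame(gene_name = "G1",
                         region_label = c("exon 1", "exon 2"),
                         upstream_flank = 0L, downstream_flank = 0L,
                         tested_by_lr = TRUE)
  am <- GRanges(rep("G1", 8),
                IRanges(c(1, 26, 51, 76, 200, 226, 251, 276), width = 30))
  mcols(am) <- DataFrame(amplicon_id = paste0("A", 1:8),
                         forward_primer = "ACGT", reverse_primer = "ACGT",
                         multiplex_group = "m1")
  PanelDefinition(rg, am)
}

.uniform_counts <- function(value = 500, n_amp = 8, n_s = 10) {
  m <- matrix(value, n_amp, n_s,
              dimnames = list(paste0("A", seq_len(n_amp)),
                              sprintf("S%02d", seq_len(n_s))))
  m
}

test_that("sample normalization divides by the sample mean and flags failures", {
  m <- .uniform_counts()
  ns <- normalizeSampleCounts(m)
  expect_equal(unname(ns$ratios), matrix(1, 8, 10))
  ## one amplicon at twice the sample mean: solve x = 2(3500 + x)/8
  m2 <- .uniform_counts()
  m2["A3", ] <- 7000 / 6
  r <- normalizeSampleCounts(m2)$ratios
  expect_equal(unname(r["A3", 1]), 2, tolerance = 1e-12)
  ## all-zero sample -> failed, excluded downstream
  m3 <- .uniform_counts(); m3[, "S04"] <- 0
  ns3 <- normalizeSampleCounts(m3)
  expect_equal(ns3$failed, "S04")
  expect_true(all(is.na(ns3$ratios[, "S04"])))
})

test_that("batch normalization cancels amplicon efficiency and is robust to one outlier", {
  m <- .uniform_counts(n_s = 96)
  m["A5", ] <- m["A5", ] * 2   # systematic 2x efficiency
  adj <- normalizeBatchRatios(normalizeSampleCounts(m))$adjusted
  expect_equal(unname(adj), matrix(1, 8, 96), tolerance = 1e-12)

  ## single-sample deletion on one amplicon among 96; with 50 amplicons the
  ## sample-mean shift from one halved amplicon is ~1%, and the per-amplicon
  ## batch median ignores the single outlier
  m2 <- .uniform_counts(n_amp = 50, n_s = 96)
  m2["A2", "S07"] <- m2["A2", "S07"] / 2
  adj2 <- normalizeBatchRatios(normalizeSampleCounts(m2))$adjusted
  expect_equal(unname(adj2["A2", "S07"]), 0.5, tolerance = 0.02)
  expect_equal(unname(adj2["A1", "S07"]), 1, tolerance = 0.02)
  expect_true(all(abs(adj2[, setdiff(colnames(adj2), "S07")] - 1) < 1e-12))

  expect_error(normalizeBatchRatios(normalizeSampleCounts(
    .uniform_counts(n_s = 4))), "at least 8")
})

test_that("batch normalization is idempotent and dosage is scale invariant", {
  set.seed(4)
  m <- matrix(rpois(8 * 20, 400), 8, 20,
              dimnames = list(paste0("A", 1:8), sprintf("S%02d", 1:20)))
  panel <- .toy_lr_panel()
  a1 <- normalizeBatchRatios(normalizeSampleCounts(m))$adjusted
  a2 <- normalizeBatchRatios(a1)$adjusted
  expect_equal(a1, a2, tolerance = 1e-12)

  d1 <- assay(runLrPipeline(AmpliconCounts(m), panel)$dosage, "dosage")
  m_scaled <- m; m_scaled[, "S03"] <- m_scaled[, "S03"] * 17L
  d2 <- assay(runLrPipeline(AmpliconCounts(m_scaled), panel)$dosage, "dosage")
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("region summaries average amplicon ratios and propagate nulls", {
  panel <- .toy_lr_panel()
  adj <- .uniform_counts(1, 8, 10)
  adj[c("A1", "A2", "A3", "A4"), "S01"] <- 0.5
  s <- summarizeRegionRatios(adj, panel)
  expect_equal(unname(s["G1|exon 1", "S01"]), 0.5)
  ## one dropout amplicon attenuates the summary: {1, 1, 0.5, 1} -> 0.875,
  ## and the 3-amplicon case of {1, 1, 0.5} -> 0.833
  expect_equal(unname(mean(c(1, 1, 0.5))), 0.8333333, tolerance = 1e-6)
  adj2 <- .uniform_counts(1, 8, 10)
  adj2["A6", "S02"] <- 0.5
  s2 <- summarizeRegionRatios(adj2, panel)
  expect_equal(unname(s2["G1|exon 2", "S02"]), mean(c(1, 0.5, 1, 1)))
  ## masked amplicons are dropped; fully masked region is untestable
  adj3 <- .uniform_counts(1, 8, 10)
  adj3[c("A5", "A6", "A7", "A8"), ] <- NA
  s3 <- summarizeRegionRatios(adj3, panel)
  expect_true(all(is.na(s3["G1|exon 2", ])))
  expect_true(all(!is.na(s3["G1|exon 1", ])))
})

test_that("LR calls merge adjacent regions and respect thresholds", {
  panel <- .toy_lr_panel()
  mk_dosage <- function(v_s01) {
    d <- matrix(2, 2, 10, dimnames = list(c("G1|exon 1", "G1|exon 2"),
                                          sprintf("S%02d", 1:10)))
    d[, "S01"] <- v_s01
    rr <- panelRegions(panel)
    mcols(rr)$n_amplicons <- 4L
    mcols(rr)$dispersion <- 0.05
    se <- SummarizedExperiment(assays = list(dosage = d), rowRanges = rr)
    rownames(se) <- rownames(d)
    new("RegionDosage", se)
  }
  ## contiguous low dosages -> one deletion spanning both regions
  del <- callLargeRearrangements(mk_dosage(c(1.0, 0.95)))
  expect_equal(nrow(del), 1L)
  expect_equal(del$type, "deletion")
  expect_equal(del$region_labels, "exon 1,exon 2")
  expect_equal(del$n_regions, 2L)
  ## all dosages within [1.8, 2.2] -> silence
  expect_equal(nrow(callLargeRearrangements(mk_dosage(c(1.9, 2.2)))), 0L)
  ## one region at 2.9 -> single-region duplication
  dup <- callLargeRearrangements(mk_dosage(c(2.9, 2.0)))
  expect_equal(dup$type, "duplication")
  expect_equal(dup$region_labels, "exon 1")
})

test_that("dropout flags require the single-allele level, a batch z-score, and no LR call", {
  panel <- .toy_lr_panel()
  ## tight batch, one amplicon at half dosage -> flagged
  adj <- .uniform_counts(1, 8, 96)
  adj["A4", "S05"] <- 0.5
  fl <- flagAlleleDropout(adj, panel)
  expect_equal(fl$sample_id, "S05")
  expect_equal(fl$amplicon_id, "A4")
  expect_gte(fl$z, 4)
  ## uniform batch -> no flags
  expect_equal(nrow(flagAlleleDropout(.uniform_counts(1, 8, 96), panel)), 0L)
  ## an amplicon at 0.5 inside a called whole-region deletion is consumed
  adj2 <- .uniform_counts(1, 8, 96)
  adj2[c("A1", "A2", "A3", "A4"), "S05"] <- 0.5
  lr <- data.frame(sample_id = "S05", gene = "G1", region_labels = "exon 1",
                   type = "deletion", mean_dosage = 1, n_regions = 1L)
  expect_equal(nrow(flagAlleleDropout(adj2, panel, lr_calls = lr)), 0L)
  ## a level far from 0.5 is not a dropout even if extreme
  adj3 <- .uniform_counts(1, 8, 96)
  adj3["A4", "S05"] <- 0.1
  expect_equal(nrow(flagAlleleDropout(adj3, panel)), 0L)
})

test_that("simulated batches recover injected LR events exactly", {
  cfg0 <- SimulationConfig(seed = 51, n_samples = 96, n_genes = 4,
                           regions_per_gene = 5)
  sim <- simulatePanel(cfg0)
  ids <- sprintf("S%02d", 1:96)
  hits <- 0L; total <- 0L; false_pos <- 0L
  for (seed in 51:53) {
    lr <- randomLrSpec(sim$panel, ids, 3, seed = seed)
    cfg <- SimulationConfig(seed = seed, n_samples = 96, n_genes = 4,
                            regions_per_gene = 5, lr_spec = lr,
                            amplicon_count_noise_cv = 0.08)
    cm <- simulateCountMatrix(cfg, sim$panel)
    res <- runLrPipeline(cm$counts, sim$panel)
    calls <- res$lr_calls
    want <- paste(lr$sample_id, lr$gene, lr$region_labels,
                  ifelse(lr$copy_change < 0, "deletion", "duplication"))
    got <- paste(calls$sample_id, calls$gene, calls$region_labels, calls$type)
    hits <- hits + sum(want %in% got)
    total <- total + length(want)
    false_pos <- false_pos + sum(!got %in% want)
  }
  expect_equal(hits, total)
  expect_equal(false_pos, 0L)
})

test_that("dropout events in count matrices are flagged, never promoted to LR calls", {
  cfg0 <- SimulationConfig(seed = 61, n_samples = 96, n_genes = 3,
                           regions_per_gene = 3)
  sim <- simulatePanel(cfg0)
  drp <- data.frame(sample_id = c("S10", "S40"),
                    amplicon_id = c("GENE1_R2_A3", "GENE3_R1_A1"))
  cfg <- SimulationConfig(seed = 61, n_samples = 96, n_genes = 3,
                          regions_per_gene = 3, dropout_spec = drp,
                          amplicon_count_noise_cv = 0.05)
  cm <- simulateCountMatrix(cfg, sim$panel)
  res <- runLrPipeline(cm$counts, sim$panel)
  expect_equal(nrow(res$lr_calls), 0L)
  got <- paste(res$dropout_flags$sample_id, res$dropout_flags$amplicon_id)
  expect_true(all(paste(drp$sample_id, drp$amplicon_id) %in% got))
})
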