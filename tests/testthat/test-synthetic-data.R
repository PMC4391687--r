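test_that("identical seeds reproduce byte-identical panels, reads and matrices", {
  cfg <- SimulationConfig(seed = 13, n_samples = 2, mean_depth = 60,
                          n_genes = 2, regions_per_gene = 2,
                          base_error_rate = 0.002)
  s1 <- simulatePanel(cfg); s2 <- simulatePanel(cfg)
  expect_identical(as.character(refGenes(s1$refs)),
                   as.character(refGenes(s2$refs)))
  expect_identical(as.character(refPseudogenes(s1$refs)),
                   as.character(refPseudogenes(s2$refs)))

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- simulateReads(cfg, s1$panel, s1$refs, out_dir = d1)
  r2 <- simulateReads(cfg, s2$panel, s2$refs, out_dir = d2)
  expect_identical(unname(tools::md5sum(r1$fastq1)),
                   unname(tools::md5sum(r2$fastq1)))
  expect_identical(unname(tools::md5sum(r1$fastq2)),
                   unname(tools::md5sum(r2$fastq2)))
  expect_identical(truthVariants(r1$truth), truthVariants(r2$truth))

  cfg96 <- SimulationConfig(seed = 13, n_samples = 12, n_genes = 2,
                            regions_per_gene = 2)
  m1 <- simulateCountMatrix(cfg96, s1$panel)
  m2 <- simulateCountMatrix(cfg96, s2$panel)
  expect_identical(assay(m1$counts, "counts"), assay(m2$counts, "counts"))
})

test_that("pseudogene divergence tracks the configured identity", {
  cfg <- SimulationConfig(seed = 21, n_genes = 1, regions_per_gene = 1,
                          region_length = 120L, pseudogene_identity = 0.97,
                          pseudogene_fraction = 1)
  sim <- simulatePanel(cfg)
  glen <- nchar(as.character(refGenes(sim$refs)[[1]]))
  n_div <- nrow(sim$divergent)
  mu <- glen * 0.03
  sdv <- sqrt(glen * 0.03 * 0.97)
  expect_gt(n_div, mu - 2 * sdv)
  expect_lt(n_div, mu + 2 * sdv)
  ## recorded positions really differ
  g <- strsplit(as.character(refGenes(sim$refs)[[1]]), "")[[1]]
  p <- strsplit(as.character(refPseudogenes(sim$refs)[[1]]), "")[[1]]
  expect_true(all(g[sim$divergent$position] != p[sim$divergent$position]))
  expect_identical(which(g != p), sort(sim$divergent$position))

  ## identity 1 would make the pseudogene indistinguishable
  expect_error(SimulationConfig(pseudogene_identity = 1),
               "indistinguishable")
  ## no pseudogene -> empty homology map
  none <- simulatePanel(SimulationConfig(seed = 3, n_genes = 1,
                                         pseudogene_fraction = 0))
  expect_equal(nrow(homologyPairs(none$refs)), 0L)
})

test_that("truth sets mirror the injected event specs", {
  sim <- small_sim()
  vs <- randomVariantSpec(sim$panel, sim$refs, c("S01", "S02"), 10, seed = 5)
  expect_equal(nrow(vs), 10L)
  cfg <- SimulationConfig(seed = 5, n_samples = 2, mean_depth = 40,
                          n_genes = 3, regions_per_gene = 3,
                          variant_spec = vs)
  rd <- simulateReads(cfg, sim$panel, sim$refs)
  expect_equal(nrow(truthVariants(rd$truth)), nrow(vs))
  expect_true(all(truthDosages(rd$truth)$copies == 2))

  ## zero-variant config -> no expected calls
  rd0 <- simulateReads(small_sim()$cfg, sim$panel, sim$refs)
  expect_equal(nrow(truthVariants(rd0$truth)), 0L)

  ## variant outside every amplicon insert is rejected
  bad <- data.frame(sample_id = "S01", gene = "GENE1", position = 5L,
                    ref = substr(as.character(refGenes(sim$refs)[["GENE1"]]),
                                 5, 5),
                    alt = "A", zygosity = "heterozygous")
  bad$alt <- ifelse(bad$ref == "A", "C", "A")
  cfg_bad <- SimulationConfig(seed = 5, n_samples = 2, n_genes = 3,
                              regions_per_gene = 3, variant_spec = bad)
  expect_error(simulateReads(cfg_bad, sim$panel, sim$refs),
               "outside every amplicon insert")
})

test_that("count matrices encode copy number, dropout and noise as specified", {
  sim <- small_sim()
  ## noise-free identity: every dosage exactly 2
  cfg0 <- SimulationConfig(seed = 8, n_samples = 12, n_genes = 3,
                           regions_per_gene = 3, amplicon_count_noise_cv = 0)
  cm0 <- simulateCountMatrix(cfg0, sim$panel)
  d0 <- assay(runLrPipeline(cm0$counts, sim$panel)$dosage, "dosage")
  expect_equal(unname(as.vector(d0)), rep(2, length(d0)))

  ## deletion ~1, duplication ~3 by construction
  lr <- data.frame(sample_id = c("S02", "S05"), gene = c("GENE1", "GENE2"),
                   region_labels = c("exon 1", "exon 2,exon 3"),
                   copy_change = c(-1L, 1L))
  cfg <- SimulationConfig(seed = 8, n_samples = 96, n_genes = 3,
                          regions_per_gene = 3, lr_spec = lr,
                          amplicon_count_noise_cv = 0.08)
  cm <- simulateCountMatrix(cfg, sim$panel)
  dos <- runLrPipeline(cm$counts, sim$panel)$dosage
  d <- assay(dos, "dosage")
  disp <- rowData(dos)$dispersion
  del_row <- which(rownames(d) == "GENE1|exon 1")
  expect_lt(abs(d[del_row, "S02"] - 1), 3 * disp[del_row] + 0.15)
  dup_rows <- which(rownames(d) %in% c("GENE2|exon 2", "GENE2|exon 3"))
  expect_true(all(abs(d[dup_rows, "S05"] - 3) < 3 * disp[dup_rows] + 0.25))
  wt <- d[del_row, setdiff(colnames(d), "S02")]
  expect_true(all(abs(wt - 2) < 0.5))

  ## truth dosages match the injected events
  td <- truthDosages(cm$truth)
  expect_equal(td$copies[td$sample_id == "S02" & td$gene == "GENE1" &
                         td$region_label == "exon 1"], 1L)
  expect_equal(sum(td$copies != 2), 3L)

  ## dropout scales exactly one amplicon by half
  drp <- data.frame(sample_id = "S04", amplicon_id = "GENE3_R1_A2")
  cfgd <- SimulationConfig(seed = 9, n_samples = 12, n_genes = 3,
                           regions_per_gene = 3, dropout_spec = drp,
                           amplicon_count_noise_cv = 0)
  cmd <- simulateCountMatrix(cfgd, sim$panel)
  m <- assay(cmd$counts, "counts")
  expect_equal(m["GENE3_R1_A2", "S04"], m["GENE3_R1_A1", "S04"] / 2)
  others <- m[setdiff(rownames(m), "GENE3_R1_A2"), "S04"]
  expect_equal(length(unique(others)), 1L)

  ## batch statistics need >= 8 samples
  expect_error(simulateCountMatrix(
    SimulationConfig(seed = 1, n_samples = 4), sim$panel), "at least 8")
})

test_that("count noise is calibrated: adjusted ratios center on 1 at the configured CV", {
  cfg <- SimulationConfig(seed = 30, n_samples = 96, n_genes = 4,
                          regions_per_gene = 3,
                          amplicon_count_noise_cv = 0.08)
  sim <- simulatePanel(cfg)
  cm <- simulateCountMatrix(cfg, sim$panel, base_count = 500)
  m <- assay(cm$counts, "counts")
  expect_gte(nrow(m), 50)  # >= 50 amplicons exercised
  adj <- normalizeBatchRatios(normalizeSampleCounts(cm$counts))$adjusted
  ## after cancelling sample scale and amplicon efficiency, what remains is
  ## the injected count noise: mean 1 within 3 SE, SD near the configured CV
  se <- 0.08 / sqrt(length(adj))
  expect_lt(abs(mean(adj) - 1), 3 * se + 0.005)
  per_amp_cv <- apply(adj, 1, sd)
  expect_gt(median(per_amp_cv), 0.08 * 0.7)
  expect_lt(median(per_amp_cv), 0.08 * 1.3)
})

test_that("heterozygous variants appear at ~50% allele fraction in reads", {
  cfg0 <- SimulationConfig(seed = 17, n_samples = 1, mean_depth = 1000,
                           n_genes = 1, regions_per_gene = 1,
                           pseudogene_fraction = 0, base_error_rate = 0)
  sim <- simulatePanel(cfg0)
  rg <- panelRegions(sim$panel)
  pos <- start(rg)[1] + 60L
  gs <- as.character(refGenes(sim$refs)[[1]])
  ref <- substr(gs, pos, pos)
  vs <- data.frame(sample_id = "S01", gene = "GENE1", position = pos,
                   ref = ref, alt = ifelse(ref == "A", "G", "A"),
                   zygosity = "heterozygous")
  cfg <- SimulationConfig(seed = 17, n_samples = 1, mean_depth = 1000,
                          n_genes = 1, regions_per_gene = 1,
                          pseudogene_fraction = 0, base_error_rate = 0,
                          variant_spec = vs)
  rd <- simulateReads(cfg, sim$panel, sim$refs)
  res <- runSeqPipeline(rd$fastq1, rd$fastq2, rd$sheet, sim$panel, sim$refs)
  df <- calls_df(res$calls)
  hit <- which(df$pos == pos)
  expect_length(hit, 1L)
  f <- res$calls$non_wt_frequency[hit]
  ## binomial(n~1000, 0.5): P(within [0.40, 0.60]) > 0.99
  expect_gt(f, 0.40)
  expect_lt(f, 0.60)
})

test_that("CGH simulation places probes per design and encodes copy number", {
  sim <- small_sim()
  des <- cghProbeDesign(sim$panel, probes_per_region = 9L, design_seed = 2)
  expect_equal(nrow(des), 9L * length(panelRegions(sim$panel)))
  cfg <- SimulationConfig(seed = 3, n_samples = 2, n_genes = 3,
                          regions_per_gene = 3,
                          lr_spec = data.frame(sample_id = "S02",
                            gene = "GENE2", region_labels = "exon 1",
                            copy_change = -1L))
  arr <- simulateCgh(cfg, sim$panel, design = des, noise_sd = 0)
  pr <- computeLogRatios(arr$probes)
  wt <- pr[pr$sample_id == "S01", ]
  expect_equal(wt$raw_lr, rep(0, nrow(wt)))
  mut <- pr[pr$sample_id == "S02", ]
  del <- mut[mut$gene_name == "GENE2" & mut$region_label == "exon 1", ]
  expect_equal(del$raw_lr, rep(-1, nrow(del)))      # log2(1/2)
  other <- mut[!(mut$gene_name == "GENE2" & mut$region_label == "exon 1"), ]
  expect_equal(other$raw_lr, rep(0, nrow(other)))
  ## duplication level is log2(3/2)
  cfg_dup <- SimulationConfig(seed = 3, n_samples = 1, n_genes = 3,
                              regions_per_gene = 3,
                              lr_spec = data.frame(sample_id = "S01",
                                gene = "GENE1", region_labels = "exon 2",
                                copy_change = 1L))
  dup <- computeLogRatios(simulateCgh(cfg_dup, sim$panel, design = des,
                                      noise_sd = 0)$probes)
  dupp <- dup[dup$gene_name == "GENE1" & dup$region_label == "exon 2", ]
  expect_equal(dupp$raw_lr, rep(log2(3 / 2), nrow(dupp)))
})
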