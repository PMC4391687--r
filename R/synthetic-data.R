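## Synthetic batches with known ground truth: panels, references with
## pseudogene homologs, pooled barcoded paired-end reads, amplicon count
## matrices, and two-channel CGH probe tables. Everything is deterministic
## given the seed, so identical configs reproduce byte-identical outputs.

.PRIMER_LEN <- 18L
.BARCODE_LEN <- 6L

.random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                 collapse = "")

.other_base <- function(b) vapply(b, function(x)
  sample(setdiff(c("A", "C", "G", "T"), x), 1L), "")

## counts around mu (vectorized) with coefficient of variation cv; cv = 0 is
## the exact noise-free mode, cv^2 <= 1/mu degenerates to Poisson
.rcounts <- function(mu, cv) {
  if (cv == 0) return(round(mu))
  out <- numeric(length(mu))
  pois <- cv^2 <= 1 / mu
  out[pois] <- rpois(sum(pois), mu[pois])
  if (any(!pois)) {
    size <- 1 / (cv^2 - 1 / mu[!pois])
    out[!pois] <- rnbinom(sum(!pois), mu = mu[!pois], size = size)
  }
  out
}

#' Simulate a panel and its reference set
#'
#' Builds `n_genes` random gene sequences, each carrying
#' `regions_per_gene` exon-like regions flanked by 20 upstream / 10
#' downstream intronic bases, tiled by `amplicons_per_region` overlapping
#' amplicons (inserts exclude primers; every region base is covered by at
#' least one amplicon and interior bases by several). Amplicons are grouped
#' into multiplexes of five. A configurable subset of genes receives a
#' colinear pseudogene homolog produced by point substitution at rate
#' `1 - pseudogene_identity`; the divergent positions are recorded.
#'
#' @param config a [SimulationConfig-class].
#' @return list with elements `panel` ([PanelDefinition-class]), `refs`
#'   ([ReferenceSet-class]) and `divergent` (data.frame gene, position of
#'   pseudogene-divergent sites).
#' @export
simulatePanel <- function(config) {
  validObject(config)
  set.seed(config@seed)
  L <- config@region_length
  m <- config@amplicons_per_region
  insert_len <- max(60L, config@read_length - .BARCODE_LEN - .PRIMER_LEN - 16L)
  span_pad <- 25L
  buffer <- 60L
  intron <- 100L

  regions <- list(); amplicons <- list(); seqs <- character()
  aid <- 0L
  for (g in seq_len(config@n_genes)) {
    gene <- paste0("GENE", g)
    glen <- buffer + config@regions_per_gene * (L + intron) + buffer
    seqs[[gene]] <- .random_dna(glen)
    for (r in seq_len(config@regions_per_gene)) {
      s <- buffer + (r - 1L) * (L + intron) + 1L
      e <- s + L - 1L
      regions[[length(regions) + 1L]] <- data.frame(contig = gene, start = s,
        end = e, gene_name = gene, region_label = paste("exon", r),
        upstream_flank = 20L, downstream_flank = 10L, tested_by_lr = TRUE)
      span_s <- s - span_pad; span_e <- e + span_pad
      starts <- round(seq(span_s, span_e - insert_len + 1L, length.out = m))
      for (k in seq_len(m)) {
        aid <- aid + 1L
        is <- starts[k]; ie <- is + insert_len - 1L
        amplicons[[length(amplicons) + 1L]] <- data.frame(contig = gene,
          start = is, end = ie,
          amplicon_id = sprintf("%s_R%d_A%d", gene, r, k),
          forward_primer = substr(seqs[[gene]], is - .PRIMER_LEN, is - 1L),
          reverse_primer = as.character(reverseComplement(DNAStringSet(
            substr(seqs[[gene]], ie + 1L, ie + .PRIMER_LEN)))[[1L]]),
          multiplex_group = paste0("mux", (aid - 1L) %/% 5L + 1L))
      }
    }
  }
  rtab <- do.call(rbind, regions)
  atab <- do.call(rbind, amplicons)
  rg <- GRanges(rtab$contig, IRanges(rtab$start, rtab$end))
  mcols(rg) <- DataFrame(rtab[, c("gene_name", "region_label",
    "upstream_flank", "downstream_flank", "tested_by_lr")])
  am <- GRanges(atab$contig, IRanges(atab$start, atab$end))
  mcols(am) <- DataFrame(atab[, c("amplicon_id", "forward_primer",
    "reverse_primer", "multiplex_group")])
  panel <- PanelDefinition(rg, am)

  n_ps <- round(config@pseudogene_fraction * config@n_genes)
  ps <- character(); hp <- data.frame(gene = character(), pseudogene = character())
  div <- data.frame(gene = character(), position = integer())
  if (n_ps > 0) for (g in seq_len(n_ps)) {
    gene <- paste0("GENE", g)
    x <- strsplit(seqs[[gene]], "")[[1L]]
    hit <- which(runif(length(x)) < 1 - config@pseudogene_identity)
    ## the production assay engineered read-level distinguishability into
    ## its pseudogene regions (specific long-range amplification); emulate
    ## that guarantee: no read-length stretch may be divergence-free, or
    ## every read from it would tie with the pseudogene and be discarded,
    ## leaving a coverage hole no assignment rule could fill
    gap_w <- 80L
    repeat {
      bounds <- c(0L, sort(hit), length(x) + 1L)
      gaps <- diff(bounds)
      gi <- which(gaps > gap_w)
      if (!length(gi)) break
      hit <- c(hit, bounds[gi[1L]] + gaps[gi[1L]] %/% 2L)
    }
    hit <- sort(hit)
    if (length(hit)) x[hit] <- .other_base(x[hit])
    psname <- paste0(gene, "_PS")
    ps[[psname]] <- paste(x, collapse = "")
    hp <- rbind(hp, data.frame(gene = gene, pseudogene = psname))
    if (length(hit))
      div <- rbind(div, data.frame(gene = gene, position = hit))
  }
  refs <- ReferenceSet(genes = DNAStringSet(seqs),
                       pseudogenes = DNAStringSet(ps), homologyPairs = hp)
  list(panel = panel, refs = refs, divergent = div)
}

#' Draw a random variant spec over a simulated panel
#'
#' Places SNVs, short deletions and short insertions inside region bodies
#' (where every base is covered by amplicons), at least 10 bases apart within
#' any one (sample, gene), with a configurable heterozygous/homozygous and
#' SNV/indel mix. Positions falling on a pseudogene-divergent site are
#' excluded: an allele that converts the gene to the pseudogene sequence at
#' a divergent site mimics gene conversion, whose carrier reads tie with
#' the pseudogene and are discarded -- a documented blind spot of
#' pseudogene-discard informatics, handled in production by enrichment
#' specificity rather than by calling. Intended for building validation
#' batches.
#'
#' @param panel,refs from [simulatePanel()].
#' @param sample_ids character vector of samples to receive variants.
#' @param n_variants total variants to place.
#' @param seed integer seed.
#' @param indel_fraction fraction of variants that are 1-2 base indels.
#' @param hom_fraction fraction of variants that are homozygous.
#' @return a `variant_spec` data.frame for [SimulationConfig()].
#' @export
randomVariantSpec <- function(panel, refs, sample_ids, n_variants, seed = 1L,
                              indel_fraction = 0.2, hom_fraction = 0.3) {
  set.seed(seed)
  rg <- panelRegions(panel)
  seqs <- refGenes(refs)
  hp <- homologyPairs(refs)
  div_of <- lapply(setNames(nm = names(seqs)), function(g) {
    if (!g %in% hp$gene) return(integer(0))
    ps <- refPseudogenes(refs)[[hp$pseudogene[hp$gene == g][1L]]]
    which(strsplit(as.character(seqs[[g]]), "")[[1L]] !=
          strsplit(as.character(ps), "")[[1L]])
  })
  out <- list()
  taken <- list()
  tries <- 0L
  while (length(out) < n_variants && tries < n_variants * 50L) {
    tries <- tries + 1L
    s <- sample(sample_ids, 1L)
    ri <- sample(length(rg), 1L)
    gene <- mcols(rg)$gene_name[ri]
    # keep 6 bases off each edge so indel ref spans stay inside the region
    pos <- sample(seq(start(rg)[ri] + 6L, end(rg)[ri] - 6L), 1L)
    key <- paste(s, gene)
    if (!is.null(taken[[key]]) && any(abs(taken[[key]] - pos) < 10L)) next
    # keep clear of pseudogene-divergent sites (gene-conversion mimicry)
    if (any(abs(div_of[[gene]] - pos) <= 3L)) next
    gs <- as.character(seqs[[gene]])
    if (runif(1) < indel_fraction) {
      if (runif(1) < 0.5) { # deletion of 2 bases
        ref <- substr(gs, pos, pos + 2L); alt <- substr(gs, pos, pos)
      } else {              # insertion of 2 bases
        ref <- substr(gs, pos, pos); alt <- paste0(ref, .random_dna(2L))
      }
    } else {
      ref <- substr(gs, pos, pos); alt <- .other_base(ref)
    }
    zyg <- if (runif(1) < hom_fraction) "homozygous" else "heterozygous"
    taken[[key]] <- c(taken[[key]], pos)
    out[[length(out) + 1L]] <- data.frame(sample_id = s, gene = gene,
      position = pos, ref = ref, alt = alt, zygosity = zyg)
  }
  do.call(rbind, out)
}

## apply a set of variants (desc position order) to an insert template
.apply_variants <- function(insert, insert_start, vars) {
  if (is.null(vars) || !nrow(vars)) return(insert)
  vars <- vars[order(-vars$position), , drop = FALSE]
  for (i in seq_len(nrow(vars))) {
    off <- vars$position[i] - insert_start + 1L
    rl <- nchar(vars$ref[i])
    if (off < 1L || off + rl - 1L > nchar(insert)) next
    insert <- paste0(substr(insert, 1L, off - 1L), vars$alt[i],
                     substr(insert, off + rl, nchar(insert)))
  }
  insert
}

.make_barcodes <- function(n) {
  bc <- character(0)
  while (length(bc) < n)
    bc <- unique(c(bc, vapply(seq_len(n), function(i) .random_dna(.BARCODE_LEN), "")))
  bc[seq_len(n)]
}

## substitution sequencing errors over a character vector of reads
.add_errors <- function(reads, rate) {
  if (rate <= 0) return(reads)
  nerr <- rbinom(length(reads), nchar(reads), rate)
  hit <- which(nerr > 0L)
  for (i in hit) {
    p <- sample.int(nchar(reads[i]), nerr[i])
    x <- strsplit(reads[i], "")[[1L]]
    x[p] <- .other_base(x[p])
    reads[i] <- paste(x, collapse = "")
  }
  reads
}

## Phred quality strings: baseline Q37; a fraction of reads decay
## geometrically toward the 3' end to sub-Q30 tails
.make_quals <- function(lens, sub_q30_fraction) {
  vapply(seq_along(lens), function(i) {
    L <- lens[i]
    q <- rep(37L, L)
    if (runif(1) < sub_q30_fraction && L > 20L) {
      tail_len <- sample(8:20, 1L)
      decay <- cumsum(rep(4L, tail_len))
      q[(L - tail_len + 1L):L] <- pmax(2L, 37L - decay)
    }
    rawToChar(as.raw(q + 33L))
  }, "")
}

#' Simulate pooled barcoded paired-end reads for a batch
#'
#' Emulates droplet-PCR amplicon sequencing: per-amplicon read-pair counts
#' are drawn around a common mean calibrated to `mean_depth`, each read
#' carries the sample barcode then the amplicon primer at its 5' end,
#' injected variants appear on one (het) or both (hom) haplotypes with
#' per-pair binomial allele sampling, dropout events restrict an amplicon to
#' a single haplotype with halved expected yield, and genes with a
#' pseudogene homolog receive contaminating pseudogene-derived pairs at
#' `contamination_rate`. Substitution errors and decaying 3' quality tails
#' are applied last.
#'
#' @param config a [SimulationConfig-class]; `n_samples` samples are named
#'   `S01 ...` and given distinct random 6-nt barcodes.
#' @param panel,refs from [simulatePanel()].
#' @param out_dir directory for `reads_R1.fastq` / `reads_R2.fastq`
#'   (created); defaults to a fresh tempdir.
#' @param seed read-noise seed, defaulting to `config@seed`; vary it to
#'   produce independent sequencing replicates of the same truth.
#' @return list with `fastq1`, `fastq2` (paths), `sheet`
#'   ([SampleSheet-class]) and `truth` ([TruthSet-class] with
#'   left-normalized expected variants).
#' @export
simulateReads <- function(config, panel, refs, out_dir = tempfile("simreads"),
                          seed = config@seed) {
  validObject(config)
  set.seed(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  am <- panelAmplicons(panel)
  seqs <- refGenes(refs)
  psseqs <- refPseudogenes(refs)
  hp <- homologyPairs(refs)
  n <- config@n_samples
  sample_ids <- sprintf("S%02d", seq_len(n))
  sheet <- SampleSheet(sample_id = sample_ids, barcode = .make_barcodes(n))
  bc <- setNames(sheetEntries(sheet)$barcode, sample_ids)

  vs <- config@variant_spec
  if (nrow(vs)) {
    for (i in seq_len(nrow(vs))) {
      gs <- as.character(seqs[[vs$gene[i]]])
      obs <- substr(gs, vs$position[i], vs$position[i] + nchar(vs$ref[i]) - 1L)
      if (obs != vs$ref[i])
        stop(sprintf("variant_spec ref %s does not match reference %s at %s:%d",
                     vs$ref[i], obs, vs$gene[i], vs$position[i]))
      covered <- any(as.character(seqnames(am)) == vs$gene[i] &
                     start(am) <= vs$position[i] & end(am) >= vs$position[i])
      if (!covered)
        stop(sprintf("variant at %s:%d lies outside every amplicon insert",
                     vs$gene[i], vs$position[i]))
    }
  }

  ## expected pairs per amplicon so that mean region depth ~ mean_depth
  ## (both mates cover the whole insert, so one pair adds depth 2)
  rg <- panelRegions(panel)
  ov <- ampliconOverlaps(panel)
  mult <- vapply(seq_along(rg), function(ri) {
    ai <- queryHits(ov)[subjectHits(ov) == ri]
    if (!length(ai)) return(1)
    pos <- seq(start(rg)[ri], end(rg)[ri])
    mean(vapply(pos, function(p) sum(start(am)[ai] <= p & end(am)[ai] >= p), 0))
  }, 0)
  pairs_per_amp <- config@mean_depth / (2 * mean(mult))

  r1 <- list(); r2 <- list(); ids <- list()
  serial <- 0L
  amp_gene <- as.character(seqnames(am))
  truth_var <- list()
  for (s in sample_ids) {
    sv <- vs[vs$sample_id == s, , drop = FALSE]
    sdrop <- config@dropout_spec[config@dropout_spec$sample_id == s, , drop = FALSE]
    for (ai in seq_along(am)) {
      gene <- amp_gene[ai]
      is <- start(am)[ai]; ie <- end(am)[ai]
      gvars <- sv[sv$gene == gene &
                  sv$position >= is & sv$position <= ie, , drop = FALSE]
      ins_ref <- substr(as.character(seqs[[gene]]), is, ie)
      het <- gvars[gvars$zygosity == "heterozygous", , drop = FALSE]
      hom <- gvars[gvars$zygosity == "homozygous", , drop = FALSE]
      hap1 <- .apply_variants(ins_ref, is, hom)
      hap2 <- .apply_variants(ins_ref, is, rbind(hom, het))
      amp_id <- mcols(am)$amplicon_id[ai]
      dropped <- amp_id %in% sdrop$amplicon_id
      mu <- if (dropped) pairs_per_amp / 2 else pairs_per_amp
      npair <- .rcounts(mu, config@amplicon_count_noise_cv)
      if (dropped) {
        n1 <- npair; n2 <- 0L       # only the reference haplotype amplifies
      } else {
        n2 <- rbinom(1L, npair, 0.5); n1 <- npair - n2
      }
      inserts <- c(rep(hap1, n1), rep(hap2, n2))
      if (gene %in% hp$gene && config@contamination_rate > 0) {
        psname <- hp$pseudogene[hp$gene == gene][1L]
        ncont <- rpois(1L, pairs_per_amp * config@contamination_rate)
        if (ncont > 0)
          inserts <- c(inserts,
                       rep(substr(as.character(psseqs[[psname]]), is, ie), ncont))
      }
      if (!length(inserts)) next
      fwd <- mcols(am)$forward_primer[ai]
      rev_ <- mcols(am)$reverse_primer[ai]
      m1 <- paste0(bc[[s]], fwd, inserts)
      m2 <- paste0(bc[[s]], rev_,
                   as.character(reverseComplement(DNAStringSet(inserts))))
      keep <- config@read_length
      m1 <- substr(m1, 1L, keep); m2 <- substr(m2, 1L, keep)
      ids_new <- sprintf("read%07d", serial + seq_along(m1))
      serial <- serial + length(m1)
      r1[[length(r1) + 1L]] <- m1
      r2[[length(r2) + 1L]] <- m2
      ids[[length(ids) + 1L]] <- ids_new
    }
  }
  r1 <- unlist(r1); r2 <- unlist(r2); ids <- unlist(ids)
  r1 <- .add_errors(r1, config@base_error_rate)
  r2 <- .add_errors(r2, config@base_error_rate)
  q1 <- .make_quals(nchar(r1), config@sub_q30_fraction)
  q2 <- .make_quals(nchar(r2), config@sub_q30_fraction)

  f1 <- file.path(out_dir, "reads_R1.fastq")
  f2 <- file.path(out_dir, "reads_R2.fastq")
  writeLines(paste0("@", ids, "\n", r1, "\n+\n", q1), f1)
  writeLines(paste0("@", ids, "\n", r2, "\n+\n", q2), f2)

  if (nrow(vs)) {
    for (i in seq_len(nrow(vs))) {
      ln <- leftNormalize(as.character(seqs[[vs$gene[i]]]), vs$position[i],
                          vs$ref[i], vs$alt[i])
      truth_var[[i]] <- data.frame(sample_id = vs$sample_id[i],
        contig = vs$gene[i], pos = ln$pos, ref = ln$ref, alt = ln$alt,
        zygosity = vs$zygosity[i])
    }
  }
  tv <- if (length(truth_var)) do.call(rbind, truth_var) else .empty_truth_variants()
  dos <- expand.grid(sample_id = sample_ids,
                     region_label = mcols(rg)$region_label,
                     stringsAsFactors = FALSE)
  dos$gene <- rep(mcols(rg)$gene_name, each = n)
  dos$copies <- 2L
  truth <- TruthSet(variants = tv, dosages = dos,
                    dropouts = config@dropout_spec)
  list(fastq1 = f1, fastq2 = f2, sheet = sheet, truth = truth)
}

#' Draw a random large-rearrangement spec over a simulated panel
#'
#' Each event is a heterozygous deletion (`copy_change = -1`) or duplication
#' (`+1`) over a contiguous run of 1-3 regions of one gene, at most one event
#' per sample.
#'
#' @param panel a [PanelDefinition-class].
#' @param sample_ids candidate samples.
#' @param n_events number of events (must not exceed `length(sample_ids)`).
#' @param seed integer seed.
#' @param max_span maximum regions per event.
#' @return an `lr_spec` data.frame for [SimulationConfig()].
#' @export
randomLrSpec <- function(panel, sample_ids, n_events, seed = 1L, max_span = 3L) {
  stopifnot(n_events <= length(sample_ids))
  set.seed(seed)
  rg <- panelRegions(panel)
  genes <- unique(mcols(rg)$gene_name)
  chosen <- sample(sample_ids, n_events)
  out <- lapply(seq_len(n_events), function(i) {
    gene <- sample(genes, 1L)
    labs <- mcols(rg)$region_label[mcols(rg)$gene_name == gene]
    span <- sample(seq_len(min(max_span, length(labs))), 1L)
    first <- sample(seq_len(length(labs) - span + 1L), 1L)
    data.frame(sample_id = chosen[i], gene = gene,
               region_labels = paste(labs[first:(first + span - 1L)],
                                     collapse = ","),
               copy_change = sample(c(-1L, 1L), 1L))
  })
  do.call(rbind, out)
}

#' Simulate a samples-by-amplicons count matrix with LR/dropout truth
#'
#' Shortcut generator for dosage testing: counts are per-sample scale x
#' per-amplicon efficiency x copy_number/2 x noise. `lr_spec` events scale
#' every amplicon overlapping the spanned regions by 0.5 (heterozygous
#' deletion) or 1.5 (duplication); `dropout_spec` events scale exactly one
#' amplicon by 0.5. With `amplicon_count_noise_cv = 0` the scale and
#' efficiency factors are held at 1 and counts are exact, so the full
#' normalization chain returns dosage 2 exactly on an event-free batch.
#'
#' @param config a [SimulationConfig-class]; requires `n_samples >= 8`.
#' @param panel a [PanelDefinition-class].
#' @param base_count expected count per amplicon at copy number 2.
#' @return list with `counts` ([AmpliconCounts-class]) and `truth`
#'   ([TruthSet-class]).
#' @export
simulateCountMatrix <- function(config, panel, base_count = 500) {
  validObject(config)
  if (config@n_samples < 8L)
    stop("batch statistics need at least 8 samples")
  set.seed(config@seed)
  am <- panelAmplicons(panel)
  rg <- panelRegions(panel)
  ov <- ampliconOverlaps(panel)
  n <- config@n_samples
  sample_ids <- sprintf("S%02d", seq_len(n))
  amp_ids <- mcols(am)$amplicon_id
  cv <- config@amplicon_count_noise_cv
  if (cv == 0) {
    scale_s <- rep(1, n); eff_a <- rep(1, length(am))
  } else {
    scale_s <- exp(rnorm(n, 0, 0.2))
    eff_a <- exp(rnorm(length(am), 0, 0.3))
  }
  copy <- matrix(2, nrow = length(am), ncol = n,
                 dimnames = list(amp_ids, sample_ids))
  dos <- expand.grid(sample_id = sample_ids,
                     region_label = mcols(rg)$region_label,
                     stringsAsFactors = FALSE)
  dos$gene <- rep(mcols(rg)$gene_name, each = n)
  dos$copies <- 2L
  ls <- config@lr_spec
  if (nrow(ls)) for (i in seq_len(nrow(ls))) {
    labs <- strsplit(ls$region_labels[i], ",")[[1L]]
    ri <- which(mcols(rg)$gene_name == ls$gene[i] &
                mcols(rg)$region_label %in% labs)
    if (length(ri) != length(labs))
      stop("lr_spec references unknown region in gene ", ls$gene[i])
    ai <- unique(queryHits(ov)[subjectHits(ov) %in% ri])
    copy[ai, ls$sample_id[i]] <- 2L + ls$copy_change[i]
    sel <- dos$sample_id == ls$sample_id[i] & dos$gene == ls$gene[i] &
           dos$region_label %in% labs
    dos$copies[sel] <- 2L + ls$copy_change[i]
  }
  drop_factor <- matrix(1, nrow = length(am), ncol = n,
                        dimnames = list(amp_ids, sample_ids))
  dsp <- config@dropout_spec
  if (nrow(dsp)) for (i in seq_len(nrow(dsp))) {
    if (!dsp$amplicon_id[i] %in% amp_ids)
      stop("dropout_spec references unknown amplicon ", dsp$amplicon_id[i])
    drop_factor[dsp$amplicon_id[i], dsp$sample_id[i]] <- 0.5
  }
  mu <- base_count * outer(eff_a, scale_s) * (copy / 2) * drop_factor
  cts <- matrix(.rcounts(as.vector(mu), cv), nrow = nrow(mu),
                dimnames = dimnames(mu))
  counts <- AmpliconCounts(cts, rowRanges = am)
  truth <- TruthSet(variants = .empty_truth_variants(), dosages = dos,
                    dropouts = dsp)
  list(counts = counts, truth = truth)
}

#' Deterministic CGH probe design for a panel
#'
#' The chip design -- probe placement across regions, GC fractions, probe
#' affinities and per-probe systematic ratio offsets -- is a property of
#' the array lot, not of any one hybridization, so it is generated once per
#' panel (with its own seed) and shared by every simulated array including
#' the historic reference set.
#'
#' @param panel a [PanelDefinition-class].
#' @param probes_per_region probes per region (default 27).
#' @param probe_offset_sd SD of the per-probe systematic log2 ratio offset
#'   (affinity artifact removed by historic normalization; default 0).
#' @param design_seed seed for the design draws.
#' @return data.frame: probe_id, contig, position, gene_name, region_label,
#'   gc_fraction, affinity, offset.
#' @export
cghProbeDesign <- function(panel, probes_per_region = 27L,
                           probe_offset_sd = 0, design_seed = 1L) {
  if (probes_per_region < 3L) stop("probes_per_region must be >= 3")
  set.seed(design_seed)
  rg <- panelRegions(panel)
  k <- probes_per_region
  probe <- do.call(rbind, lapply(seq_along(rg), function(ri) {
    pos <- round(seq(start(rg)[ri], end(rg)[ri], length.out = k))
    data.frame(probe_id = sprintf("P_%s_%s_%02d", mcols(rg)$gene_name[ri],
                 gsub(" ", "", mcols(rg)$region_label[ri]), seq_len(k)),
               contig = as.character(seqnames(rg))[ri], position = pos,
               gene_name = mcols(rg)$gene_name[ri],
               region_label = mcols(rg)$region_label[ri])
  }))
  np <- nrow(probe)
  probe$gc_fraction <- runif(np, 0.3, 0.7)
  probe$affinity <- exp(rnorm(np, 0, 0.3))
  probe$offset <- if (probe_offset_sd > 0) rnorm(np, 0, probe_offset_sd)
                  else rep(0, np)
  probe
}

#' Simulate two-channel CGH probe intensities for a batch of arrays
#'
#' One array per sample: `probes_per_region` probes are placed across every
#' panel region with random GC fractions and multiplicative probe
#' affinities shared across arrays. The sample (Cy5-role) channel carries
#' the copy-number effect (copy/2) from `lr_spec` plus optional global shift
#' and GC-dependent bias on the log2 scale; the reference (Cy3-role) channel
#' does not. Probe affinity cancels in the ratio only partially: a
#' per-probe systematic ratio offset (`probe_offset_sd`) emulates the
#' affinity artifacts that historic probe normalization removes.
#'
#' @param config a [SimulationConfig-class].
#' @param panel a [PanelDefinition-class].
#' @param design probe design from [cghProbeDesign()]; defaults to a design
#'   with `config@probes_per_region` probes and no systematic offsets. Use
#'   one shared design when simulating historic and test arrays together.
#' @param noise_sd per-channel multiplicative log2 noise SD (0 = noise-free).
#' @param global_shift additive log2 shift applied to every sample channel.
#' @param gc_bias_slope linear log2 bias vs (gc - 0.5).
#' @param seed seed for the array-level draws, defaulting to `config@seed`.
#' @return list with `probes` (long data.frame: sample_id, probe_id, contig,
#'   position, gene_name, region_label, gc_fraction, sample_signal,
#'   reference_signal) and `truth` ([TruthSet-class]).
#' @export
simulateCgh <- function(config, panel,
                        design = cghProbeDesign(panel,
                                                config@probes_per_region),
                        noise_sd = 0.05, global_shift = 0,
                        gc_bias_slope = 0, seed = config@seed) {
  validObject(config)
  set.seed(seed)
  rg <- panelRegions(panel)
  n <- config@n_samples
  sample_ids <- sprintf("S%02d", seq_len(n))

  probe <- design[, c("probe_id", "contig", "position", "gene_name",
                      "region_label", "gc_fraction")]
  np <- nrow(probe)
  affinity <- design$affinity
  offset <- design$offset

  dos <- expand.grid(sample_id = sample_ids,
                     region_label = mcols(rg)$region_label,
                     stringsAsFactors = FALSE)
  dos$gene <- rep(mcols(rg)$gene_name, each = n)
  dos$copies <- 2L
  copy <- matrix(2, nrow = np, ncol = n, dimnames = list(probe$probe_id, sample_ids))
  ls <- config@lr_spec
  if (nrow(ls)) for (i in seq_len(nrow(ls))) {
    labs <- strsplit(ls$region_labels[i], ",")[[1L]]
    pi <- which(probe$gene_name == ls$gene[i] & probe$region_label %in% labs)
    copy[pi, ls$sample_id[i]] <- 2L + ls$copy_change[i]
    sel <- dos$sample_id == ls$sample_id[i] & dos$gene == ls$gene[i] &
           dos$region_label %in% labs
    dos$copies[sel] <- 2L + ls$copy_change[i]
  }

  out <- lapply(seq_len(n), function(si) {
    ref_noise <- if (noise_sd > 0) rnorm(np, 0, noise_sd) else 0
    sam_noise <- if (noise_sd > 0) rnorm(np, 0, noise_sd) else 0
    refsig <- 1000 * affinity * 2^ref_noise
    samsig <- 1000 * affinity * (copy[, si] / 2) *
      2^(global_shift + gc_bias_slope * (probe$gc_fraction - 0.5) +
         offset + sam_noise)
    data.frame(sample_id = sample_ids[si], probe,
               sample_signal = samsig, reference_signal = refsig)
  })
  probes <- do.call(rbind, out)
  rownames(probes) <- NULL
  truth <- TruthSet(variants = .empty_truth_variants(), dosages = dos,
                    dropouts = .empty_dropout_spec())
  list(probes = probes, truth = truth)
}
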