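## Large-rearrangement detection from amplicon read-count dosage across a
## batch, and single-allele (PCR dropout) amplicon flagging. The chain is:
## per-sample normalization -> per-amplicon batch normalization -> region
## summary -> region dosage on the copy-number scale (wild type = 2).

#' Normalize amplicon counts to each sample's mean
#'
#' `ratio(s, a) = count(s, a) / mean_a count(s, .)`, cancelling per-sample
#' sequencing yield. A sample whose counts are all zero cannot be
#' normalized; it is marked failed ("No Result") and excluded downstream.
#'
#' @param counts an [AmpliconCounts-class] or numeric matrix (amplicons x
#'   samples).
#' @return list with `ratios` (matrix, failed samples all-NA) and `failed`
#'   (character vector of failed sample ids).
#' @export
normalizeSampleCounts <- function(counts) {
  m <- if (is(counts, "AmpliconCounts")) assay(counts, "counts") else as.matrix(counts)
  mu <- colMeans(m)
  failed <- colnames(m)[mu == 0]
  ratios <- sweep(m, 2L, mu, "/")
  ratios[, mu == 0] <- NA_real_
  list(ratios = ratios, failed = failed)
}

#' Normalize sample ratios across the batch
#'
#' Divides each amplicon's ratios by that amplicon's median across the
#' batch, so the per-amplicon batch median becomes 1 and amplicon
#' efficiency differences cancel. The median is robust to the occasional
#' mutant sample in the batch. Requires at least 8 non-failed samples.
#' Amplicons with a zero batch median are masked (all-NA) and reported.
#'
#' @param ratios result of [normalizeSampleCounts()] (or its `ratios`
#'   matrix).
#' @return list with `adjusted` (matrix), `masked` (character vector of
#'   masked amplicon ids) and `failed` (carried through).
#' @export
normalizeBatchRatios <- function(ratios) {
  failed <- character()
  if (is.list(ratios) && !is.matrix(ratios)) {
    failed <- ratios$failed; ratios <- ratios$ratios
  }
  ok <- colSums(!is.na(ratios)) > 0
  if (sum(ok) < 8L)
    stop("batch normalization needs at least 8 non-failed samples")
  med <- apply(ratios[, ok, drop = FALSE], 1L, median, na.rm = TRUE)
  masked <- rownames(ratios)[med == 0]
  adjusted <- sweep(ratios, 1L, med, "/")
  adjusted[med == 0, ] <- NA_real_
  list(adjusted = adjusted, masked = masked, failed = failed)
}

#' Combine amplicon ratios into per-region summaries
#'
#' The summary value for a (sample, region) is the mean of the
#' batch-adjusted ratios of all unmasked amplicons overlapping the region.
#' Regions whose amplicons are all masked are untestable for the batch
#' (all-NA row).
#'
#' @param adjusted result of [normalizeBatchRatios()] (or its matrix).
#' @param panel a [PanelDefinition-class].
#' @return matrix regions x samples of summary values, with rownames
#'   `gene|region_label`.
#' @export
summarizeRegionRatios <- function(adjusted, panel) {
  if (is.list(adjusted) && !is.matrix(adjusted)) adjusted <- adjusted$adjusted
  rg <- panelRegions(panel)
  am <- panelAmplicons(panel)
  ov <- ampliconOverlaps(panel)
  amp_ids <- mcols(am)$amplicon_id
  out <- matrix(NA_real_, nrow = length(rg), ncol = ncol(adjusted),
    dimnames = list(paste(mcols(rg)$gene_name, mcols(rg)$region_label,
                          sep = "|"), colnames(adjusted)))
  for (ri in seq_along(rg)) {
    ai <- amp_ids[queryHits(ov)[subjectHits(ov) == ri]]
    ai <- intersect(ai, rownames(adjusted))
    if (!length(ai)) next
    sub <- adjusted[ai, , drop = FALSE]
    sub <- sub[rowSums(!is.na(sub)) > 0, , drop = FALSE]  # drop masked amplicons
    if (!nrow(sub)) next                                  # region untestable
    out[ri, ] <- colMeans(sub)  # stays NA for failed samples
  }
  out
}

#' Convert region summaries to copy-number dosage
#'
#' `dosage(s, r) = 2 * summary(s, r) / median_s summary(., r)`, putting the
#' batch wild type at 2 on the linear copy-number scale. The per-region
#' `dispersion` recorded alongside is the batch standard deviation of the
#' dosage (the scaled summary), the yardstick outlier review uses.
#'
#' @param summaries matrix from [summarizeRegionRatios()].
#' @param panel a [PanelDefinition-class].
#' @return a [RegionDosage-class] (rows = regions with `n_amplicons` and
#'   `dispersion` in rowData, columns = samples).
#' @export
regionDosage <- function(summaries, panel) {
  if (sum(colSums(!is.na(summaries)) > 0) < 8L)
    stop("region dosage needs at least 8 non-failed samples")
  rg <- panelRegions(panel)
  ov <- ampliconOverlaps(panel)
  med <- apply(summaries, 1L, median, na.rm = TRUE)
  dosage <- sweep(summaries, 1L, med, "/") * 2
  disp <- apply(dosage, 1L, sd, na.rm = TRUE)
  n_amp <- vapply(seq_along(rg), function(ri)
    sum(subjectHits(ov) == ri), 0L)
  rd <- rg
  mcols(rd)$n_amplicons <- n_amp
  mcols(rd)$dispersion <- disp
  se <- SummarizedExperiment(assays = list(dosage = dosage), rowRanges = rd)
  rownames(se) <- rownames(summaries)
  new("RegionDosage", se)
}

#' Call large rearrangements from region dosages
#'
#' Per sample and gene, maximal runs of adjacent regions (genomic order)
#' with dosage below `del_threshold` become one deletion call and runs above
#' `dup_threshold` one duplication call; single-region events are allowed.
#' The thresholds sit at the midpoints between integer copy states (1.5
#' between one and two copies, 2.5 between two and three). Regions marked
#' `tested_by_lr = FALSE` in the panel are excluded, as are untestable (NA)
#' dosages.
#'
#' @param dosages a [RegionDosage-class].
#' @param del_threshold,dup_threshold dosage cutoffs (defaults 1.5 / 2.5).
#' @return data.frame: sample_id, gene, region_labels (comma-joined span),
#'   type ("deletion"/"duplication"), mean_dosage, n_regions,
#'   region_dosages (comma-joined).
#' @export
callLargeRearrangements <- function(dosages, del_threshold = 1.5,
                                    dup_threshold = 2.5) {
  d <- assay(dosages, "dosage")
  rr <- SummarizedExperiment::rowRanges(dosages)
  calls <- list()
  for (s in colnames(d)) {
    for (gene in unique(mcols(rr)$gene_name)) {
      ri <- which(mcols(rr)$gene_name == gene & mcols(rr)$tested_by_lr)
      ri <- ri[order(start(rr)[ri])]
      if (!length(ri)) next
      v <- d[ri, s]
      state <- ifelse(is.na(v), "na",
               ifelse(v < del_threshold, "deletion",
               ifelse(v > dup_threshold, "duplication", "wt")))
      r <- rle(state)
      endpos <- cumsum(r$lengths)
      for (k in seq_along(r$values)) {
        if (!r$values[k] %in% c("deletion", "duplication")) next
        span <- ri[(endpos[k] - r$lengths[k] + 1L):endpos[k]]
        calls[[length(calls) + 1L]] <- data.frame(sample_id = s, gene = gene,
          region_labels = paste(mcols(rr)$region_label[span], collapse = ","),
          type = r$values[k], mean_dosage = mean(d[span, s]),
          n_regions = length(span),
          region_dosages = paste(sprintf("%.4f", d[span, s]), collapse = ","))
      }
    }
  }
  if (length(calls)) do.call(rbind, calls)
  else data.frame(sample_id = character(), gene = character(),
                  region_labels = character(), type = character(),
                  mean_dosage = numeric(), n_regions = integer(),
                  region_dosages = character())
}

#' Flag amplicons that appear amplified from a single allele
#'
#' An amplicon is flagged for a sample when its batch-adjusted ratio sits
#' within `tolerance` of the single-allele level (`target`, 0.5 of normal)
#' AND deviates from the amplicon's batch mean by at least `z_threshold`
#' batch standard deviations (SD floored at 1e-6 for noise-free synthetic
#' batches) AND the amplicon's region is not already part of a large
#' rearrangement call for that sample (a whole-region event explains its
#' amplicons; dropout flags target isolated primer-site failures that hide
#' heterozygous variants).
#'
#' @param adjusted result of [normalizeBatchRatios()] (or its matrix).
#' @param panel a [PanelDefinition-class].
#' @param lr_calls data.frame from [callLargeRearrangements()] used for the
#'   precedence rule (optional).
#' @param z_threshold minimum batch z-score (default 4).
#' @param target single-allele dosage level on the adjusted-ratio scale
#'   (default 0.5).
#' @param tolerance half-width of the acceptance window around `target`
#'   (default 0.15).
#' @return data.frame: sample_id, amplicon_id, ratio, z.
#' @export
flagAlleleDropout <- function(adjusted, panel, lr_calls = NULL,
                              z_threshold = 4, target = 0.5,
                              tolerance = 0.15) {
  if (is.list(adjusted) && !is.matrix(adjusted)) adjusted <- adjusted$adjusted
  am <- panelAmplicons(panel)
  rg <- panelRegions(panel)
  ov <- ampliconOverlaps(panel)
  amp_ids <- mcols(am)$amplicon_id
  mu <- rowMeans(adjusted, na.rm = TRUE)
  sdv <- pmax(apply(adjusted, 1L, sd, na.rm = TRUE), 1e-6)
  ## amplicons consumed by an LR call, per sample
  consumed <- new.env(parent = emptyenv())
  if (!is.null(lr_calls) && nrow(lr_calls)) {
    for (i in seq_len(nrow(lr_calls))) {
      labs <- strsplit(lr_calls$region_labels[i], ",")[[1L]]
      ri <- which(mcols(rg)$gene_name == lr_calls$gene[i] &
                  mcols(rg)$region_label %in% labs)
      ai <- amp_ids[queryHits(ov)[subjectHits(ov) %in% ri]]
      key <- lr_calls$sample_id[i]
      assign(key, union(if (exists(key, consumed)) get(key, consumed)
                        else character(), ai), consumed)
    }
  }
  out <- list()
  for (s in colnames(adjusted)) {
    v <- adjusted[, s]
    z <- abs(v - mu) / sdv
    hit <- which(!is.na(v) & abs(v - target) <= tolerance & z >= z_threshold)
    if (!length(hit)) next
    skip <- if (exists(s, consumed)) get(s, consumed) else character()
    for (i in hit) {
      aid <- rownames(adjusted)[i]
      if (aid %in% skip) next
      out[[length(out) + 1L]] <- data.frame(sample_id = s, amplicon_id = aid,
        ratio = v[i], z = z[i])
    }
  }
  if (length(out)) { res <- do.call(rbind, out); rownames(res) <- NULL; res }
  else data.frame(sample_id = character(), amplicon_id = character(),
                  ratio = numeric(), z = numeric())
}

#' Export scatterplot data for dosage review
#'
#' One row per (sample, region) with the region's position index (genes in
#' panel order, regions 5'->3' within gene), mirroring the reviewer
#' scatterplot with wild-type dosage at 2.
#'
#' @param dosages a [RegionDosage-class].
#' @return data.frame: sample_id, gene, region_label, region_index, dosage.
#' @export
dosageScatterData <- function(dosages) {
  d <- assay(dosages, "dosage")
  rr <- SummarizedExperiment::rowRanges(dosages)
  ord <- order(match(mcols(rr)$gene_name, unique(mcols(rr)$gene_name)),
               start(rr))
  idx <- match(seq_along(rr), ord)
  data.frame(sample_id = rep(colnames(d), each = nrow(d)),
             gene = rep(mcols(rr)$gene_name, ncol(d)),
             region_label = rep(mcols(rr)$region_label, ncol(d)),
             region_index = rep(idx, ncol(d)),
             dosage = as.vector(d))
}
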