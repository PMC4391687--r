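## Threshold-based zygosity calling from pileup allele frequencies, plus
## per-region coverage failure flags and a strand-imbalance advisory.

#' Classify a non-wild-type allele frequency into zygosity bands
#'
#' Bands are lower-inclusive half-open intervals with the top band closed:
#' `[0, 0.10)` noise, `[0.10, 0.30)` flagged_low, `[0.30, 0.70)`
#' heterozygous, `[0.70, 0.90)` flagged_high, `[0.90, 1.00]` homozygous.
#' The production thresholds come from the assay definition: below 10
#' percent is attributed to noise, 30-70 percent is called heterozygous,
#' 90-100 percent homozygous, and the intermediate bands are flagged for
#' Sanger follow-up. The band edges themselves (0.10, 0.30, 0.70, 0.90)
#' fall into the higher band by the lower-inclusive convention, so 0.30 is
#' heterozygous and 0.90 homozygous; this is documented rather than
#' configurable because a total deterministic function is required.
#'
#' @param non_wt_frequency numeric vector of frequencies in `[0, 1]`.
#' @return character vector over
#'   `c("noise", "flagged_low", "heterozygous", "flagged_high", "homozygous")`.
#' @examples
#' classifyFrequency(c(0.05, 0.20, 0.50, 0.80, 0.95))
#' @export
classifyFrequency <- function(non_wt_frequency) {
  f <- non_wt_frequency
  if (any(is.na(f)) || any(f < 0) || any(f > 1))
    stop("non_wt_frequency must lie in [0, 1]")
  out <- character(length(f))
  out[f < 0.10] <- "noise"
  out[f >= 0.10 & f < 0.30] <- "flagged_low"
  out[f >= 0.30 & f < 0.70] <- "heterozygous"
  out[f >= 0.70 & f < 0.90] <- "flagged_high"
  out[f >= 0.90] <- "homozygous"
  out
}

.indel_to_alleles <- function(contig_seq, pos, allele) {
  base <- substr(contig_seq, pos, pos)
  if (startsWith(allele, "+"))
    list(ref = base, alt = paste0(base, substr(allele, 2L, nchar(allele))))
  else
    list(ref = paste0(base, substr(allele, 2L, nchar(allele))), alt = base)
}

#' Call variants and coverage failures from a pileup
#'
#' For every pileup position the dominant non-reference allele's frequency
#' (count over position depth) is classified with [classifyFrequency()]:
#' heterozygous/homozygous bands become called variants, the intermediate
#' bands become variants flagged for confirmation, noise produces no
#' output. Indel alleles are converted to VCF-style ref/alt pairs and
#' left-normalized. Independently, every (sample, region) whose minimum base
#' depth over the region body falls below `min_depth` yields a coverage
#' flag (positions with no assigned reads count as depth 0); flagged regions
#' produce no reliance on their calls and are reported for Sanger repeat.
#'
#' @param pileup a [Pileup-class].
#' @param panel a [PanelDefinition-class].
#' @param refs a [ReferenceSet-class] (for reference alleles and indel
#'   normalization).
#' @param min_depth minimum acceptable per-base depth (default 50).
#' @return list with `calls` (a [VariantAnnotation::VRanges] with metadata
#'   columns zygosity, status, non_wt_frequency, forward_depth,
#'   reverse_depth, alt_fwd, alt_rev) and `coverage_flags` (data.frame
#'   sample_id, gene, region_label, contig, start, end, min_depth).
#' @export
callVariants <- function(pileup, panel, refs, min_depth = 50L) {
  pc <- data.table::as.data.table(pileupCalls(pileup))
  seqs <- c(refGenes(refs), refPseudogenes(refs))
  rg <- panelRegions(panel)

  empty <- VariantAnnotation::VRanges()
  samples <- unique(pc$sample_id)

  calls <- empty
  if (nrow(pc)) {
    ## canonicalize indel allele keys first: alignments may anchor the same
    ## event at different positions of a repeat tract, and all of them
    ## left-normalize to one representation whose counts must be pooled
    ind <- grepl("^[+-]", pc$allele)
    if (any(ind)) {
      u <- unique(pc[ind, c("contig", "pos", "allele")])
      canon <- vapply(seq_len(nrow(u)), function(i) {
        cs <- as.character(seqs[[u$contig[i]]])
        al <- .indel_to_alleles(cs, u$pos[i], u$allele[i])
        ln <- leftNormalize(cs, u$pos[i], al$ref, al$alt)
        if (nchar(ln$alt) > nchar(ln$ref))
          paste(ln$pos, paste0("+", substring(ln$alt, 2L)), sep = "\r")
        else
          paste(ln$pos, paste0("-", substring(ln$ref, 2L)), sep = "\r")
      }, "")
      u$canon_pos <- as.integer(sub("\r.*", "", canon))
      u$canon_allele <- sub(".*\r", "", canon)
      pc <- merge(pc, u, by = c("contig", "pos", "allele"), all.x = TRUE)
      sel <- !is.na(pc$canon_pos)
      pc$pos[sel] <- pc$canon_pos[sel]
      pc$allele[sel] <- pc$canon_allele[sel]
      pc <- pc[, list(count = sum(count), fwd = sum(fwd), rev = sum(rev)),
               by = c("sample_id", "contig", "pos", "allele")]
    }
    site <- pc[, list(depth = sum(count), fwd_depth = sum(fwd),
                      rev_depth = sum(rev)),
               by = c("sample_id", "contig", "pos")]
    refbase <- vapply(seq_len(nrow(site)), function(i)
      substr(as.character(seqs[[site$contig[i]]]), site$pos[i], site$pos[i]),
      "")
    site$refbase <- refbase
    alt <- merge(pc, site, by = c("sample_id", "contig", "pos"))
    alt <- alt[alt$allele != alt$refbase]
    if (nrow(alt)) {
      data.table::setorder(alt, sample_id, contig, pos, -count, allele)
      top <- alt[, .SD[1L], by = c("sample_id", "contig", "pos")]
      top$freq <- top$count / top$depth
      ## the assay requires 50X per base: an under-covered position (for
      ## example the interior of a homozygous deletion, where only error
      ## reads remain) is coverage-flag territory and never yields a call
      top <- top[top$depth >= min_depth]
      ## indels: a read whose alignment ends at the anchor cannot inform
      ## the event, and carrier reads contribute no base observation at
      ## anchor+1 (suppressed across the ambiguous tract during event
      ## extraction), so the exact spanning denominator for both insertions
      ## and deletions is carriers + depth(anchor + 1)
      is_indel <- grepl("^[+-]", top$allele)
      if (any(is_indel)) {
        nxt <- data.table::copy(site)
        nxt$pos <- nxt$pos - 1L
        data.table::setnames(nxt, "depth", "depth_next")
        top <- merge(top, nxt[, c("sample_id", "contig", "pos", "depth_next")],
                     by = c("sample_id", "contig", "pos"), all.x = TRUE)
        top$depth_next[is.na(top$depth_next)] <- 0L
        span <- top$count + top$depth_next
        top$freq[is_indel] <- top$count[is_indel] / pmax(span[is_indel], 1L)
        top$depth[is_indel] <- span[is_indel]
        top <- top[top$depth >= min_depth]  # re-gate on the spanning depth
      }
      top$class <- classifyFrequency(pmin(top$freq, 1))
      top <- top[!top$class %in% "noise"]
      if (nrow(top)) {
        recs <- lapply(seq_len(nrow(top)), function(i) {
          ctg <- top$contig[i]; cs <- as.character(seqs[[ctg]])
          if (grepl("^[+-]", top$allele[i])) {
            al <- .indel_to_alleles(cs, top$pos[i], top$allele[i])
            ln <- leftNormalize(cs, top$pos[i], al$ref, al$alt)
          } else {
            ln <- list(pos = top$pos[i], ref = top$refbase[i],
                       alt = top$allele[i])
          }
          data.frame(sample_id = top$sample_id[i], contig = ctg,
            pos = ln$pos, ref = ln$ref, alt = ln$alt,
            depth = top$depth[i], freq = top$freq[i], class = top$class[i],
            fwd_depth = top$fwd_depth[i], rev_depth = top$rev_depth[i],
            alt_fwd = top$fwd[i], alt_rev = top$rev[i])
        })
        tab <- do.call(rbind, recs)
        calls <- VariantAnnotation::VRanges(
          seqnames = tab$contig,
          ranges = IRanges(tab$pos, width = nchar(tab$ref)),
          ref = tab$ref, alt = tab$alt, sampleNames = tab$sample_id,
          totalDepth = as.integer(tab$depth))
        calls$zygosity <- ifelse(tab$class == "homozygous", "homozygous",
                                 "heterozygous")
        calls$status <- ifelse(tab$class %in% c("flagged_low", "flagged_high"),
                               "flagged_for_confirmation", "called")
        calls$non_wt_frequency <- tab$freq
        calls$forward_depth <- as.integer(tab$fwd_depth)
        calls$reverse_depth <- as.integer(tab$rev_depth)
        calls$alt_fwd <- as.integer(tab$alt_fwd)
        calls$alt_rev <- as.integer(tab$alt_rev)
      }
    }
  }

  ## coverage flags: min base depth over each region body, per sample
  flags <- list()
  if (length(samples)) {
    site_depth <- if (nrow(pc))
      pc[, list(depth = sum(count)), by = c("sample_id", "contig", "pos")]
    else data.table::data.table(sample_id = character(), contig = character(),
                                pos = integer(), depth = integer())
    for (s in samples) {
      sd_ <- site_depth[site_depth$sample_id == s]
      for (ri in seq_along(rg)) {
        ctg <- as.character(seqnames(rg))[ri]
        span <- seq(start(rg)[ri], end(rg)[ri])
        d <- sd_$depth[match(paste(ctg, span), paste(sd_$contig, sd_$pos))]
        d[is.na(d)] <- 0L
        if (min(d) < min_depth)
          flags[[length(flags) + 1L]] <- data.frame(sample_id = s,
            gene = mcols(rg)$gene_name[ri],
            region_label = mcols(rg)$region_label[ri], contig = ctg,
            start = start(rg)[ri], end = end(rg)[ri], min_depth = min(d))
      }
    }
  }
  cov <- if (length(flags)) do.call(rbind, flags)
         else data.frame(sample_id = character(), gene = character(),
                         region_label = character(), contig = character(),
                         start = integer(), end = integer(),
                         min_depth = integer())
  list(calls = calls, coverage_flags = cov)
}

#' Flag calls with inadequate per-strand alternate support
#'
#' Advisory annotation mirroring manual review of forward/reverse read
#' support: a call is flagged when its alternate allele is supported by
#' fewer than `min_per_strand` reads on either strand.
#'
#' @param calls the VRanges from [callVariants()].
#' @param min_per_strand minimum alt-supporting reads per strand (default 3).
#' @return logical vector along `calls`.
#' @export
flagStrandImbalance <- function(calls, min_per_strand = 3L) {
  if (!length(calls)) return(logical(0))
  calls$alt_fwd < min_per_strand | calls$alt_rev < min_per_strand
}
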