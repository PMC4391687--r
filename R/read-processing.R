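## Demultiplex -> trim -> assign -> pileup. Reads are assigned to the best
## local alignment across genes AND pseudogenes; any read matching a
## pseudogene as well as or better than a gene is discarded. Assignment uses
## exact k-mer seeding with gapless extension on candidate windows and a
## Smith-Waterman (Biostrings::pairwiseAlignment) fallback when the gapless
## score is depressed (indels) or no seed hits; homologous partner windows
## are always scored so gene/pseudogene ties cannot be missed.

.SEED_K <- 16L
.ALN_MATCH <- 2; .ALN_MISMATCH <- -3; .ALN_GAP_OPEN <- 5; .ALN_GAP_EXT <- 2
.SCORE_FLOOR_FRAC <- 0.6   # of the maximum achievable score (2 per base)
.DP_TRIGGER_FRAC <- 0.85   # gapless score below this fraction -> run DP

#' Read a FASTQ file into a data.frame
#'
#' @param path FASTQ path (Phred+33).
#' @param mate mate label recorded with each read (1 or 2).
#' @return data.frame with read_id, mate, seq, qual.
#' @export
readFastq <- function(path, mate = 1L) {
  x <- readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  if (!length(x))
    return(data.frame(read_id = character(), mate = integer(),
                      seq = character(), qual = character()))
  data.frame(read_id = sub("\\s.*$", "", names(x)), mate = mate,
             seq = as.character(x),
             qual = as.character(mcols(x)$qualities))
}

#' Demultiplex pooled barcoded reads by exact 6-nt barcode match
#'
#' Each read is expected to begin with its sample's 6-nucleotide barcode.
#' Matching is exact (0 mismatches): 6-nt codes leave no safe error margin.
#' Reads whose prefix matches no sheet barcode are counted and set aside.
#' The barcode is stripped from routed reads.
#'
#' @param fastq1 path to the (pooled) first-mate FASTQ.
#' @param fastq2 optional path to the second-mate FASTQ; mates are routed
#'   independently by their own barcode prefix.
#' @param sheet a [SampleSheet-class]; duplicate barcodes within a batch are
#'   rejected at sheet construction.
#' @return list with `reads` (data.frame read_id, mate, sample_id, seq,
#'   qual), `unassigned` (count) and `total` (count).
#' @export
demultiplexReads <- function(fastq1, fastq2 = NULL, sheet) {
  df <- readFastq(fastq1, mate = 1L)
  if (!is.null(fastq2)) df <- rbind(df, readFastq(fastq2, mate = 2L))
  e <- sheetEntries(sheet)
  idx <- match(substr(df$seq, 1L, .BARCODE_LEN), e$barcode)
  routed <- !is.na(idx)
  out <- df[routed, , drop = FALSE]
  out$sample_id <- e$sample_id[idx[routed]]
  out$seq <- substr(out$seq, .BARCODE_LEN + 1L, nchar(out$seq))
  out$qual <- substr(out$qual, .BARCODE_LEN + 1L, nchar(out$qual))
  rownames(out) <- NULL
  list(reads = out[, c("read_id", "mate", "sample_id", "seq", "qual")],
       unassigned = sum(!routed), total = nrow(df))
}

.trim_cut <- function(q, threshold, window) {
  L <- length(q)
  if (!L) return(0L)
  cut <- L
  while (cut >= 1L && q[cut] < threshold) cut <- cut - 1L
  # window guard: keep peeling while the trailing window's mean is still bad
  while (cut >= 1L) {
    lo <- max(1L, cut - window + 1L)
    if (mean(q[lo:cut]) >= threshold) break
    cut <- cut - 1L
  }
  cut
}

#' Trim primers and low-quality 3' tails from reads
#'
#' First the amplicon primer prefix is removed (exact match against the
#' panel's primer set, or near-exact with at most one mismatch), then the
#' 3' tail failing Q30 is removed: the maximal terminal run of sub-threshold
#' bases is cut, and a 5-base sliding-mean guard keeps peeling while the
#' trailing window mean remains below the threshold (so sawtooth tails with
#' isolated good bases are still removed). Interior base order is never
#' altered; a fully trimmed read (length 0) is allowed.
#'
#' @param reads data.frame from [demultiplexReads()] (columns seq, qual), or
#'   a character vector of sequences with `quals` supplied.
#' @param primers character vector of primer sequences (both orientations).
#' @param q_threshold Phred threshold (default 30).
#' @param window sliding-mean guard width (default 5).
#' @param quals qualities when `reads` is a character vector.
#' @return the reads data.frame with trimmed `seq`/`qual` plus
#'   `primer_removed` and `bases_trimmed` columns.
#' @export
trimReads <- function(reads, primers, q_threshold = 30L, window = 5L,
                      quals = NULL) {
  if (is.character(reads)) reads <- data.frame(seq = reads, qual = quals)
  n0 <- nchar(reads$seq)
  plen <- unique(nchar(primers))
  primer_removed <- rep(FALSE, nrow(reads))
  for (pl in sort(plen, decreasing = TRUE)) {
    pre <- substr(reads$seq, 1L, pl)
    hit <- !primer_removed & pre %in% primers & n0 >= pl
    near <- which(!primer_removed & !hit & n0 >= pl)
    if (length(near) && length(primers)) {
      praw <- lapply(primers[nchar(primers) == pl], charToRaw)
      for (i in near) {
        rr <- charToRaw(substr(reads$seq[i], 1L, pl))
        for (p in praw) if (sum(rr != p) <= 1L) { hit[i] <- TRUE; break }
      }
    }
    reads$seq[hit] <- substr(reads$seq[hit], pl + 1L, n0[hit])
    reads$qual[hit] <- substr(reads$qual[hit], pl + 1L, n0[hit])
    primer_removed <- primer_removed | hit
  }
  qi <- lapply(reads$qual, function(s) utf8ToInt(s) - 33L)
  cut <- vapply(qi, .trim_cut, 0L, threshold = q_threshold, window = window)
  reads$seq <- substr(reads$seq, 1L, cut)
  reads$qual <- substr(reads$qual, 1L, cut)
  reads$primer_removed <- primer_removed
  reads$bases_trimmed <- n0 - nchar(reads$seq)
  reads
}

## ---- assignment ----

.build_seed_index <- function(seqs) {
  dt <- data.table::rbindlist(lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    n <- nchar(s)
    if (n < .SEED_K) return(NULL)
    p <- seq_len(n - .SEED_K + 1L)
    data.table::data.table(kmer = substring(s, p, p + .SEED_K - 1L),
                           ref = i, pos = p)
  }))
  data.table::setkey(dt, kmer)
  dt
}

.hamming <- function(a, b) sum(charToRaw(a) != charToRaw(b))

## gapless local score of read against ref window starting at `start`
## (1-based in ref); overhanging read bases are left unaligned (no penalty)
.gapless_score <- function(read, ref, start) {
  L <- nchar(read); rl <- nchar(ref)
  lo <- max(1L, start); hi <- min(rl, start + L - 1L)
  if (hi < lo) return(-Inf)
  rseg <- substr(read, lo - start + 1L, hi - start + 1L)
  wseg <- substr(ref, lo, hi)
  d <- .hamming(rseg, wseg)
  m <- nchar(rseg) - d
  .ALN_MATCH * m + .ALN_MISMATCH * d
}

## TRUE when >= 2 mismatches fall in the first or last 8 aligned bases,
## the signature of an indel sitting near a read end
.terminal_mismatch_cluster <- function(read, ref, start, edge = 8L, k = 2L) {
  L <- nchar(read); rl <- nchar(ref)
  lo <- max(1L, start); hi <- min(rl, start + L - 1L)
  if (hi - lo + 1L < 2L * edge) return(FALSE)
  rseg <- charToRaw(substr(read, lo - start + 1L, hi - start + 1L))
  wseg <- charToRaw(substr(ref, lo, hi))
  mm <- rseg != wseg
  sum(mm[seq_len(edge)]) >= k || sum(mm[(length(mm) - edge + 1L):length(mm)]) >= k
}

.aln_mat <- NULL
.get_aln_mat <- function() {
  m <- Biostrings::nucleotideSubstitutionMatrix(match = .ALN_MATCH,
         mismatch = .ALN_MISMATCH, baseOnly = FALSE)
  m
}

#' Assign reads to genes, discarding pseudogene-matching reads
#'
#' Computes each read's best local-alignment score against the gene
#' references and against the pseudogene references (scoring: match +2,
#' mismatch -3, gap open -5, gap extend -2) and applies the discard rule:
#' a read matching a pseudogene as well as or better than any gene
#' (`pseudogene_score >= gene_score`) is `discarded_pseudogene`; a read whose
#' best score falls below 0.6x the maximum achievable for its length is
#' `unmapped`; otherwise it is `assigned` to the best-scoring gene (ties
#' between genes break to the lexicographically first and are flagged
#' `multi_gene`). Both read orientations are considered.
#'
#' @param reads data.frame from [trimReads()] (columns seq, and optionally
#'   read_id, mate, sample_id), or a plain character vector of sequences.
#' @param refs a [ReferenceSet-class].
#' @return list with `assignments` (one row per input read: status,
#'   best_gene, gene_score, pseudogene_score, ref_start, strand, multi_gene,
#'   uid) and `events` (data.table uid, contig, pos, allele of per-base
#'   observations for assigned unique reads; alleles are observed bases,
#'   `+SEQ` insertions after pos, or `-SEQ` deletions after pos).
#' @export
assignReads <- function(reads, refs) {
  if (is.character(reads)) reads <- data.frame(seq = reads)
  gn <- names(refGenes(refs)); pn <- names(refPseudogenes(refs))
  allseq <- c(as.character(refGenes(refs)), as.character(refPseudogenes(refs)))
  is_ps <- c(rep(FALSE, length(gn)), rep(TRUE, length(pn)))
  hp <- homologyPairs(refs)
  partner <- rep(NA_integer_, length(allseq))
  if (nrow(hp)) {
    gi <- match(hp$gene, names(allseq)); pi <- match(hp$pseudogene, names(allseq))
    partner[gi] <- pi; partner[pi] <- gi
  }
  idx <- .build_seed_index(allseq)
  submat <- .get_aln_mat()

  useq <- unique(reads$seq)
  n_u <- length(useq)
  if (!n_u) {
    empty <- data.frame(status = character(), best_gene = character(),
      gene_score = numeric(), pseudogene_score = numeric(),
      ref_start = integer(), strand = character(), multi_gene = logical(),
      uid = integer())
    return(list(assignments = cbind(
      reads[setdiff(names(reads), c("seq", "qual"))], empty),
      events = data.table::data.table(uid = integer(), contig = character(),
                                      pos = integer(), allele = character())))
  }
  urc <- as.character(reverseComplement(DNAStringSet(useq)))
  L_u <- nchar(useq)

  ## batched seed lookup: three k-mers per orientation for every unique read
  seedable <- which(L_u >= .SEED_K)
  cand_by_uid <- vector("list", n_u)
  if (length(seedable)) {
    seeds <- data.table::rbindlist(lapply(c("+", "-"), function(strand) {
      sv <- if (strand == "+") useq[seedable] else urc[seedable]
      Ls <- L_u[seedable]
      offs <- cbind(1L, (Ls - .SEED_K) %/% 2L + 1L, Ls - .SEED_K + 1L)
      data.table::data.table(
        uid = rep(seedable, 3L), strand = strand,
        off = as.integer(offs),
        kmer = substring(rep(sv, 3L), as.integer(offs),
                         as.integer(offs) + .SEED_K - 1L))
    }))
    hits <- idx[seeds, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
    if (nrow(hits)) {
      hits[, `:=`(start = pos - off + 1L)]
      cand <- unique(hits[, c("uid", "strand", "ref", "start")])
      ## add homologous partner windows (colinear) so ties cannot be missed
      pr <- partner[cand$ref]
      extra <- cand[!is.na(pr)]
      if (nrow(extra)) {
        extra[, `:=`(ref = pr[!is.na(pr)])]
        cand <- unique(rbind(cand, extra))
      }
      data.table::setorder(cand, uid, ref, start)
      cand_by_uid <- split(seq_len(nrow(cand)),
                           factor(cand$uid, levels = seq_len(n_u)))
      c_strand <- cand$strand; c_ref <- cand$ref; c_start <- cand$start
    }
  }

  res <- vector("list", n_u)
  ev <- vector("list", n_u)
  for (u in seq_len(n_u)) {
    rows <- cand_by_uid[[u]]
    L <- L_u[u]
    if (is.null(rows) || !length(rows)) {
      res[[u]] <- list(status = "unmapped", best_gene = NA_character_,
        gene_score = -Inf, ps_score = -Inf, ref_start = NA_integer_,
        strand = "+", multi_gene = FALSE)
      next
    }
    strand_i <- c_strand[rows]; ref_i <- c_ref[rows]; start_i <- c_start[rows]
    nc <- length(rows)
    rd_of <- function(i) if (strand_i[i] == "+") useq[u] else urc[u]
    score <- vapply(seq_len(nc), function(i)
      .gapless_score(rd_of(i), allseq[ref_i[i]], start_i[i]), 0)
    alns <- list()
    ## DP when the gapless score is depressed (internal indel) or the best
    ## candidate shows a terminal mismatch cluster (indel near a read end)
    bi0 <- which.max(score)
    dp_needed <- score[bi0] < .DP_TRIGGER_FRAC * .ALN_MATCH * L ||
      .terminal_mismatch_cluster(rd_of(bi0), allseq[ref_i[bi0]], start_i[bi0])
    if (dp_needed) {
      ## Smith-Waterman on the best candidate window of each reference
      ## class, so gene and pseudogene are compared on equal footing
      for (cls in unique(is_ps[ref_i])) {
        ci <- which(is_ps[ref_i] == cls)
        bi <- ci[which.max(score[ci])]
        w_lo <- max(1L, start_i[bi] - 30L)
        w_hi <- min(nchar(allseq[ref_i[bi]]), start_i[bi] + L + 29L)
        win <- substr(allseq[ref_i[bi]], w_lo, w_hi)
        ## global-local: the whole (primer/quality-trimmed) read must align,
        ## preventing soft-clips that would absorb an indel near a read end
        aln <- Biostrings::pairwiseAlignment(rd_of(bi), win, type = "global-local",
          substitutionMatrix = submat, gapOpening = .ALN_GAP_OPEN,
          gapExtension = .ALN_GAP_EXT)
        score[bi] <- Biostrings::score(aln)
        alns[[as.character(bi)]] <- list(
          pa = as.character(Biostrings::alignedPattern(aln)[[1L]]),
          sa = as.character(Biostrings::alignedSubject(aln)[[1L]]),
          sub_start = w_lo + Biostrings::start(Biostrings::subject(aln)) - 1L)
      }
    }
    gi_ <- which(!is_ps[ref_i]); pi_ <- which(is_ps[ref_i])
    g_best <- if (length(gi_)) max(score[gi_]) else -Inf
    p_best <- if (length(pi_)) max(score[pi_]) else -Inf
    if (max(g_best, p_best) < max(1, .SCORE_FLOOR_FRAC * .ALN_MATCH * L)) {
      res[[u]] <- list(status = "unmapped", best_gene = NA_character_,
        gene_score = g_best, ps_score = p_best, ref_start = NA_integer_,
        strand = "+", multi_gene = FALSE)
      next
    }
    if (p_best >= g_best) {
      g_names0 <- names(allseq)[ref_i[gi_[score[gi_] == g_best]]]
      res[[u]] <- list(status = "discarded_pseudogene",
        best_gene = if (length(g_names0)) sort(g_names0)[1L] else NA_character_,
        gene_score = g_best, ps_score = p_best, ref_start = NA_integer_,
        strand = "+", multi_gene = FALSE)
      next
    }
    g_ties <- gi_[score[gi_] == g_best]
    g_names <- names(allseq)[ref_i[g_ties]]
    bi <- g_ties[order(g_names, start_i[g_ties])][1L]
    gene <- sort(g_names)[1L]
    a <- alns[[as.character(bi)]]
    if (!is.null(a) && (grepl("-", a$pa, fixed = TRUE) ||
                        grepl("-", a$sa, fixed = TRUE))) {
      start <- a$sub_start
      ev[[u]] <- .walk_alignment(a$pa, a$sa, a$sub_start, gene, u,
                                 allseq[[gene]])
    } else {
      ## gapless outcome (with or without a DP pass): give a clustered
      ## mismatch pattern the chance to re-resolve as one short indel
      start <- if (!is.null(a)) a$sub_start else start_i[bi]
      sr <- .split_realign(rd_of(bi), allseq[[gene]], start)
      ev[[u]] <- if (!is.null(sr))
        .walk_alignment(sr$pa, sr$sa, sr$sub_start, gene, u, allseq[[gene]])
      else .gapless_events(rd_of(bi), allseq[[gene]], start, gene, u)
    }
    res[[u]] <- list(status = "assigned", best_gene = gene,
      gene_score = g_best, ps_score = p_best,
      ref_start = start, strand = strand_i[bi],
      multi_gene = length(unique(g_names)) > 1L)
  }
  rtab <- data.table::rbindlist(res)
  data.table::setnames(rtab, "ps_score", "pseudogene_score")
  uid <- match(reads$seq, useq)
  assignments <- cbind(reads[setdiff(names(reads), c("seq", "qual"))],
                       as.data.frame(rtab[uid]), uid = uid)
  events <- data.table::rbindlist(ev)
  list(assignments = assignments, events = events)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Parsimony realignment: a short indel in (semi-)repetitive context can
## align gaplessly with only two mismatches and outscore the gapped truth
## (two mismatches cost 6, a 2-base gap costs 9). When a gapless alignment
## carries >= 2 mismatches, test whether one 1-3 base indel with cleanly
## matching flanks explains the read with at least two fewer edits at a
## bounded score cost; if so, prefer the indel interpretation (independent
## sequencing errors virtually never produce that pattern at error rates
## of ~1e-3). Returns aligned pattern/subject strings, or NULL.
.split_realign <- function(read, ref, start, max_indel = 3L,
                           score_margin = 4) {
  L <- nchar(read); rl <- nchar(ref)
  if (start < 1L || start + L - 1L > rl) return(NULL)   # clipped: skip
  rraw <- charToRaw(read)
  wraw <- charToRaw(substr(ref, start, start + L - 1L))
  mm0 <- sum(rraw != wraw)
  if (mm0 < 2L) return(NULL)
  base_score <- 2 * (L - mm0) - 3 * mm0
  best <- NULL
  ## alignment start of the prefix segment; the seed diagonal may belong to
  ## either the prefix or the suffix segment, so both anchorings are tried
  try_del <- function(s, k) {
    if (s < 1L || s + L + k - 1L > rl) return(NULL)
    wdel <- charToRaw(substr(ref, s, s + L + k - 1L))
    pref <- cumsum(c(0L, rraw != wdel[seq_len(L)]))
    sufmis <- rraw != wdel[(k + 1L):(L + k)]
    suf <- rev(cumsum(c(0L, rev(as.integer(sufmis)))))
    tot <- pref + suf                      # index b+1 for breakpoint b
    bs <- seq.int(2L, L)                   # b in 1..L-1
    b <- bs[which.min(tot[bs])] - 1L
    mm <- tot[b + 1L]
    sc <- 2 * (L - mm) - 3 * mm - (.ALN_GAP_OPEN + .ALN_GAP_EXT * k)
    list(score = sc, mm = mm, type = "del", k = k, b = b, s = s)
  }
  try_ins <- function(s, k) {
    if (L - k < 2L || s < 1L || s + L - k - 1L > rl) return(NULL)
    wref <- charToRaw(substr(ref, s, s + L - k - 1L))
    pref <- cumsum(c(0L, (rraw[seq_len(L - k)] != wref)))
    sufmis <- rraw[(k + 1L):L] != wref     # read j+k vs ref diag j
    suf <- rev(cumsum(c(0L, rev(as.integer(sufmis)))))
    tot <- pref + suf
    bs <- seq.int(2L, L - k)               # b in 1..L-k-1
    b <- bs[which.min(tot[bs])] - 1L
    mm <- tot[b + 1L]
    sc <- 2 * (L - k - mm) - 3 * mm - (.ALN_GAP_OPEN + .ALN_GAP_EXT * k)
    list(score = sc, mm = mm, type = "ins", k = k, b = b, s = s)
  }
  for (k in seq_len(max_indel)) {
    for (cand in list(try_del(start, k), try_del(start - k, k),
                      try_ins(start, k), try_ins(start + k, k))) {
      if (!is.null(cand) && cand$mm <= mm0 - 2L &&
          cand$score >= base_score - score_margin &&
          (is.null(best) || cand$score > best$score))
        best <- cand
    }
  }
  if (is.null(best)) return(NULL)
  b <- best$b; k <- best$k; s <- best$s
  if (best$type == "del") {
    pa <- paste0(substr(read, 1L, b), strrep("-", k),
                 substr(read, b + 1L, L))
    sa <- substr(ref, s, s + L + k - 1L)
  } else {
    pa <- read
    sa <- paste0(substr(ref, s, s + b - 1L), strrep("-", k),
                 substr(ref, s + b, s + L - k - 1L))
  }
  list(pa = pa, sa = sa, sub_start = s)
}

## base observations within this many positions of a read end are masked:
## an indel just beyond the read end is indistinguishable from a terminal
## mismatch under local scoring, so terminal bases are unreliable witnesses
.READ_END_MASK <- 2L

## per-base observation events for a gapless alignment
.gapless_events <- function(read, ref, start, contig, uid) {
  L <- nchar(read); rl <- nchar(ref)
  lo <- max(1L, start); hi <- min(rl, start + L - 1L)
  if (hi < lo) return(NULL)
  bases <- strsplit(substr(read, lo - start + 1L, hi - start + 1L), "")[[1L]]
  dt <- data.table::data.table(uid = uid, contig = contig, pos = lo:hi,
                               allele = bases,
                               readpos = (lo - start + 1L):(hi - start + 1L))
  dt <- dt[dt$readpos > .READ_END_MASK & dt$readpos <= L - .READ_END_MASK]
  dt[, c("uid", "contig", "pos", "allele")]
}

## walk a gapped alignment (pattern = read, subject = reference window);
## sub_start is the global ref position of the first aligned subject base.
## A read carrying an indel contributes the indel allele at its anchor
## instead of a base observation there.
## Walk a gapped alignment, emitting indel alleles in their canonical
## (left-normalized) representation regardless of where the aligner placed
## the gap in a repeat tract. The carrier read's base observations across
## the ambiguous tract -- from the canonical anchor through the base after
## it -- are suppressed, so that the base depth at (anchor + 1) counts only
## non-carrier reads and the indel frequency
## `carriers / (carriers + depth(anchor + 1))` is exact for both insertions
## and deletions, at any zygosity.
.walk_alignment <- function(pa, sa, sub_start, contig, uid, refseq) {
  p <- strsplit(pa, "")[[1L]]
  s <- strsplit(sa, "")[[1L]]
  n <- length(p)
  L <- sum(p != "-")                 # read length
  pos <- integer(0); allele <- character(0); rp <- integer(0)
  refpos <- sub_start
  readpos <- 0L
  i <- 1L
  sup_lo <- integer(0); sup_hi <- integer(0)
  while (i <= n) {
    if (s[i] != "-" && p[i] != "-") {
      readpos <- readpos + 1L
      pos <- c(pos, refpos); allele <- c(allele, p[i]); rp <- c(rp, readpos)
      refpos <- refpos + 1L; i <- i + 1L
    } else if (p[i] == "-") {        # deletion in read
      j <- i
      while (j <= n && p[j] == "-") j <- j + 1L
      delseq <- paste(s[i:(j - 1L)], collapse = "")
      anchor <- refpos - 1L
      ln <- leftNormalize(refseq, anchor,
                          paste0(substr(refseq, anchor, anchor), delseq),
                          substr(refseq, anchor, anchor))
      pos <- c(pos, ln$pos)
      allele <- c(allele, paste0("-", substring(ln$ref, 2L)))
      rp <- c(rp, NA_integer_)       # indel evidence is never masked
      sup_lo <- c(sup_lo, ln$pos)
      sup_hi <- c(sup_hi, max(refpos + (j - i) - 1L, ln$pos + 1L))
      refpos <- refpos + (j - i); i <- j
    } else {                          # insertion in read
      j <- i
      while (j <= n && s[j] == "-") j <- j + 1L
      insseq <- paste(p[i:(j - 1L)], collapse = "")
      anchor <- refpos - 1L
      ln <- leftNormalize(refseq, anchor,
                          substr(refseq, anchor, anchor),
                          paste0(substr(refseq, anchor, anchor), insseq))
      pos <- c(pos, ln$pos)
      allele <- c(allele, paste0("+", substring(ln$alt, 2L)))
      rp <- c(rp, NA_integer_)
      sup_lo <- c(sup_lo, ln$pos)
      sup_hi <- c(sup_hi, max(anchor, ln$pos + 1L))
      readpos <- readpos + (j - i)
      i <- j
    }
  }
  keep <- is.na(rp) | (rp > .READ_END_MASK & rp <= L - .READ_END_MASK)
  dt <- data.table::data.table(uid = uid, contig = contig, pos = pos[keep],
                               allele = allele[keep])
  if (length(sup_lo)) {
    base_row <- !grepl("^[+-]", dt$allele)
    drop <- rep(FALSE, nrow(dt))
    for (k in seq_along(sup_lo))
      drop <- drop | (base_row & dt$pos >= sup_lo[k] & dt$pos <= sup_hi[k])
    dt <- dt[!drop]
  }
  dt
}

#' Build a per-sample allele pileup from assigned reads
#'
#' Accumulates allele counts per (sample, contig, position) from assigned
#' reads, restricted to panel regions extended by their intronic flanks.
#' Read orientation (alignment strand) is tracked so forward/reverse support
#' can be reviewed. Assigned reads falling entirely outside every panel
#' region are ignored and counted.
#'
#' @param assigned result of [assignReads()] run on demultiplexed, trimmed
#'   reads (the `assignments` component must carry `sample_id`).
#' @param panel a [PanelDefinition-class].
#' @return a [Pileup-class].
#' @export
buildPileup <- function(assigned, panel) {
  a <- data.table::as.data.table(assigned$assignments)
  ev <- assigned$events
  counters <- c(reads = nrow(a),
    assigned = sum(a$status == "assigned"),
    discarded_pseudogene = sum(a$status == "discarded_pseudogene"),
    unmapped = sum(a$status == "unmapped"),
    outside_panel = 0L)
  keep <- a[a$status == "assigned",
            list(n = .N), by = c("uid", "sample_id", "strand")]
  if (!nrow(keep) || is.null(ev) || !nrow(ev)) {
    return(new("Pileup", calls = data.frame(sample_id = character(),
      contig = character(), pos = integer(), allele = character(),
      count = integer(), fwd = integer(), rev = integer()),
      counters = setNames(as.integer(counters), names(counters))))
  }
  rg <- panelRegions(panel)
  win <- data.table::data.table(contig = as.character(seqnames(rg)),
    lo = start(rg) - mcols(rg)$upstream_flank,
    hi = end(rg) + mcols(rg)$downstream_flank)
  evk <- ev[win, on = c("contig", "pos>=lo", "pos<=hi"), nomatch = NULL,
            list(uid = x.uid, contig = x.contig, pos = x.pos,
                 allele = x.allele)]
  evk <- unique(evk)
  in_panel_uids <- unique(evk$uid)
  counters["outside_panel"] <- sum(keep$n[!keep$uid %in% in_panel_uids])
  m <- merge(evk, keep, by = "uid", allow.cartesian = TRUE)
  calls <- m[, list(count = sum(n), fwd = sum(n[strand == "+"]),
                    rev = sum(n[strand == "-"])),
             by = c("sample_id", "contig", "pos", "allele")]
  data.table::setorder(calls, sample_id, contig, pos, allele)
  new("Pileup", calls = as.data.frame(calls),
      counters = setNames(as.integer(counters), names(counters)))
}
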