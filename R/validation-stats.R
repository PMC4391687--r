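## Analytical-validation arithmetic: base-complete concordance accounting
## between a test call set and a truth call set, sensitivity/specificity,
## and exact (Clopper-Pearson) one-sided lower confidence bounds.

.calls_to_df <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is(x, "VRanges")) {
    if (!length(x))
      return(data.frame(sample_id = character(), contig = character(),
                        pos = integer(), ref = character(), alt = character(),
                        zygosity = character()))
    return(data.frame(
      sample_id = as.character(VariantAnnotation::sampleNames(x)),
      contig = as.character(seqnames(x)), pos = start(x),
      ref = VariantAnnotation::ref(x), alt = VariantAnnotation::alt(x),
      zygosity = x$zygosity))
  }
  stop("calls must be a data.frame or VRanges")
}

#' Compare a test call set against a truth call set
#'
#' Per (sample, position): a variant present in both sets with the same
#' left-normalized allele and zygosity is a true positive; truth-only sites
#' are false negatives; test-only sites are false positives; a site present
#' in both with a zygosity (or allele) mismatch is counted as one FN plus
#' one FP and itemized. All remaining bases of the
#' `n_samples x bases_per_sample` space are true negatives, so
#' `TP + FN + FP + TN` conserves the total bases compared.
#'
#' @param test,truth call sets: data.frames with sample_id, contig, pos,
#'   ref, alt, zygosity, or VRanges from [callVariants()] (flagged calls are
#'   compared like called ones).
#' @param panel a [PanelDefinition-class]; calls outside every panel region
#'   (+flanks) are an error.
#' @param bases_per_sample bases analyzed per sample; default: total panel
#'   region span including flanks.
#' @param n_samples number of samples compared; default: samples present in
#'   either call set.
#' @return a [ConcordanceTable-class].
#' @export
compareCallsets <- function(test, truth, panel, bases_per_sample = NULL,
                            n_samples = NULL) {
  test <- .calls_to_df(test); truth <- .calls_to_df(truth)
  rg <- panelRegions(panel)
  lo <- start(rg) - mcols(rg)$upstream_flank
  hi <- end(rg) + mcols(rg)$downstream_flank
  ctg <- as.character(seqnames(rg))
  inside <- function(df) {
    if (!nrow(df)) return(TRUE)
    ok <- vapply(seq_len(nrow(df)), function(i)
      any(ctg == df$contig[i] & lo <= df$pos[i] & hi >= df$pos[i]), TRUE)
    if (!all(ok))
      stop("call at ", df$contig[!ok][1], ":", df$pos[!ok][1],
           " lies outside the panel")
    TRUE
  }
  inside(test); inside(truth)
  if (is.null(bases_per_sample))
    bases_per_sample <- sum(hi - lo + 1)
  if (is.null(n_samples))
    n_samples <- length(unique(c(test$sample_id, truth$sample_id)))

  key <- function(df) paste(df$sample_id, df$contig, df$pos)
  full <- function(df) paste(key(df), df$ref, df$alt, df$zygosity)
  tp <- sum(full(test) %in% full(truth))
  test_d <- test[!full(test) %in% full(truth), , drop = FALSE]
  truth_d <- truth[!full(truth) %in% full(test), , drop = FALSE]
  # same site, different allele or zygosity: one FN + one FP, itemized
  mism <- key(truth_d) %in% key(test_d)
  fn <- nrow(truth_d)
  fp <- nrow(test_d)
  tn <- n_samples * bases_per_sample - tp - fn - fp
  disc <- rbind(
    if (nrow(truth_d)) cbind(truth_d,
      kind = ifelse(mism, "zygosity_or_allele_mismatch", "missed_by_test")),
    if (nrow(test_d)) cbind(test_d,
      kind = ifelse(key(test_d) %in% key(truth_d),
                    "zygosity_or_allele_mismatch", "absent_from_truth")))
  ConcordanceTable(tp = tp, fn = fn, fp = fp, tn = tn,
    bases_per_sample = bases_per_sample, n_samples = n_samples,
    discordant = if (is.null(disc)) data.frame() else disc)
}

#' Sensitivity: TP / (TP + FN)
#' @param table a [ConcordanceTable-class].
#' @return proportion.
#' @export
sensitivity <- function(table) {
  if (table@tp + table@fn == 0)
    stop("sensitivity undefined: no positives in truth (TP + FN = 0)")
  table@tp / (table@tp + table@fn)
}

#' Specificity: TN / (TN + FP)
#' @param table a [ConcordanceTable-class].
#' @return proportion.
#' @export
specificity <- function(table) {
  if (table@tn + table@fp == 0)
    stop("specificity undefined: no negatives (TN + FP = 0)")
  table@tn / (table@tn + table@fp)
}

#' Exact one-sided lower confidence bound for a binomial proportion
#'
#' Clopper-Pearson: the lower limit is the p solving
#' `P(X >= successes | trials, p) = 1 - confidence`, i.e. the
#' `1 - confidence` quantile of `Beta(successes, trials - successes + 1)`.
#' When every trial succeeds this reduces to the closed form
#' `(1 - confidence)^(1/trials)`; when no trial succeeds the bound is 0.
#' This is the one-sided "Exact method" bound: reporting its lower limit
#' supports the claim that the true proportion meets or exceeds it with the
#' stated confidence.
#'
#' @param successes,trials non-negative counts, `successes <= trials`,
#'   `trials >= 1`.
#' @param confidence confidence level (default 0.95).
#' @return a [ConfidenceBound-class].
#' @examples
#' lowerBound(exactLowerBound(3923, 3923))    # 0.05^(1/3923)
#' @export
exactLowerBound <- function(successes, trials, confidence = 0.95) {
  if (trials < 1) stop("trials must be >= 1")
  if (successes < 0 || successes > trials)
    stop("successes must lie in [0, trials]")
  alpha <- 1 - confidence
  lower <- if (successes == 0) 0
           else if (successes == trials) alpha^(1 / trials)
           else qbeta(alpha, successes, trials - successes + 1)
  new("ConfidenceBound", point_estimate = successes / trials,
      lower_bound = lower, confidence = confidence,
      method = "exact one-sided")
}

#' Render a concordance summary table
#'
#' Mirrors the validation summary layout: samples, bases analyzed per
#' sample, total positive and negative bases, sensitivity and specificity
#' with their exact lower bounds printed in truncated ">xx.xx%" style.
#'
#' @param table a [ConcordanceTable-class].
#' @param confidence confidence level for the bounds.
#' @return data.frame of labelled values (also printed).
#' @export
concordanceSummary <- function(table, confidence = 0.95) {
  sens <- sensitivity(table)
  spec <- specificity(table)
  sb <- exactLowerBound(table@tp, table@tp + table@fn, confidence)
  pb <- exactLowerBound(table@tn, table@tn + table@fp, confidence)
  data.frame(
    quantity = c("samples", "bases analyzed (per sample)",
                 "total positive bases", "total negative bases",
                 "sensitivity", "sensitivity lower bound",
                 "specificity", "specificity lower bound"),
    value = c(table@n_samples, table@bases_per_sample,
              table@tp + table@fn, table@tn + table@fp,
              sens, lowerBound(sb), spec, lowerBound(pb)),
    printed = c(format(table@n_samples), format(table@bases_per_sample),
                format(table@tp + table@fn), format(table@tn + table@fp),
                sprintf("%.4f%%", sens * 100),
                paste0(">", formatPercentTruncated(lowerBound(sb)), "%"),
                sprintf("%.4f%%", spec * 100),
                paste0(">", formatPercentTruncated(lowerBound(pb)), "%")))
}
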