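## Orthogonal large-rearrangement caller for two-channel microarray CGH:
## per-probe log2 ratios run through a four-stage normalization stack
## (sample dosage, LOWESS vs intensity, historic probe, GC trend), then
## region calling on the log2 scale (wild type = 0).

#' Compute raw per-probe log2 ratios
#'
#' `log2(sample_signal / reference_signal)` per probe; probes with a
#' non-positive signal in either channel are masked (`NA`).
#'
#' @param probes data.frame with columns `sample_signal`,
#'   `reference_signal` (plus identifying columns carried through).
#' @return the data.frame with added columns `raw_lr` (log2 ratio) and
#'   `mean_intensity` (average log2 signal, the x-axis of the LOWESS
#'   stage); masked probes have `raw_lr = NA`.
#' @export
computeLogRatios <- function(probes) {
  ok <- probes$sample_signal > 0 & probes$reference_signal > 0
  probes$raw_lr <- ifelse(ok, log2(probes$sample_signal /
                                   probes$reference_signal), NA_real_)
  probes$mean_intensity <- ifelse(ok,
    0.5 * (log2(pmax(probes$sample_signal, 1e-12)) +
           log2(pmax(probes$reference_signal, 1e-12))), NA_real_)
  probes
}

#' Historic probe statistics from prior wild-type arrays
#'
#' Per-probe median and SD of the raw log2 ratio over a set of reference
#' (wild-type) arrays, used by the historic-probe normalization stage to
#' remove systematic probe affinity artifacts.
#'
#' @param probes long data.frame of prior arrays (must contain `sample_id`,
#'   `probe_id`, and signals or `raw_lr`).
#' @param min_arrays minimum number of arrays required (default 10).
#' @return data.frame: probe_id, median_lr, sd_lr, n_arrays.
#' @export
historicProbeStats <- function(probes, min_arrays = 10L) {
  if (!"raw_lr" %in% names(probes)) probes <- computeLogRatios(probes)
  n_arr <- length(unique(probes$sample_id))
  if (n_arr < min_arrays)
    stop("historic probe statistics need at least ", min_arrays, " arrays")
  dt <- data.table::as.data.table(probes)
  st <- dt[, list(median_lr = median(raw_lr, na.rm = TRUE),
                  sd_lr = sd(raw_lr, na.rm = TRUE),
                  n_arrays = sum(!is.na(raw_lr))), by = "probe_id"]
  as.data.frame(st)
}

.lowess_fit <- function(x, y, f) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 10L || length(unique(x[ok])) < 5L) return(rep(0, length(x)))
  fit <- lowess(x[ok], y[ok], f = f)
  out <- approx(fit$x, fit$y, xout = x, rule = 2)$y
  out[is.na(out)] <- 0
  out
}

#' Normalize CGH log2 ratios through the four-stage stack
#'
#' Stages are applied in order, each recording its adjustment so that
#' `normalized = raw - (adj_sample + adj_lowess + adj_historic + adj_gc)`
#' holds exactly per probe:
#' 1. *sample dosage*: subtract the array-wide median log2 ratio;
#' 2. *LOWESS*: subtract a locally weighted fit of ratio vs mean
#'    log-intensity (MA-style, `f = 0.3`), removing intensity-dependent dye
#'    bias;
#' 3. *historic probe*: subtract each probe's historic median ratio over
#'    prior wild-type arrays (0 and flagged when a probe has no history);
#' 4. *GC*: subtract a LOWESS trend of ratio vs probe GC fraction.
#' Any stage can be disabled. Normalization is per array (sample).
#'
#' @param probes data.frame of one or more arrays (long, with `sample_id`);
#'   columns `gc_fraction` and signals or `raw_lr` required.
#' @param historic optional data.frame from [historicProbeStats()].
#' @param stages character subset of
#'   `c("sample", "lowess", "historic", "gc")`.
#' @param lowess_f LOWESS span (default 0.3).
#' @return the data.frame with `raw_lr`, per-stage adjustment columns
#'   `adj_sample`, `adj_lowess`, `adj_historic`, `adj_gc`, `normalized_lr`
#'   and `historic_missing`.
#' @export
normalizeCgh <- function(probes, historic = NULL,
                         stages = c("sample", "lowess", "historic", "gc"),
                         lowess_f = 0.3) {
  if (!"raw_lr" %in% names(probes)) probes <- computeLogRatios(probes)
  out <- lapply(split(probes, probes$sample_id), function(p) {
    cur <- p$raw_lr
    p$adj_sample <- p$adj_lowess <- p$adj_historic <- p$adj_gc <- 0
    p$historic_missing <- FALSE
    if ("sample" %in% stages) {
      p$adj_sample <- rep(median(cur, na.rm = TRUE), nrow(p))
      cur <- cur - p$adj_sample
    }
    if ("lowess" %in% stages) {
      p$adj_lowess <- .lowess_fit(p$mean_intensity, cur, lowess_f)
      cur <- cur - p$adj_lowess
    }
    if ("historic" %in% stages && !is.null(historic)) {
      hidx <- match(p$probe_id, historic$probe_id)
      adj <- historic$median_lr[hidx]
      p$historic_missing <- is.na(adj)
      adj[is.na(adj)] <- 0
      p$adj_historic <- adj
      cur <- cur - adj
    }
    if ("gc" %in% stages) {
      p$adj_gc <- .lowess_fit(p$gc_fraction, cur, lowess_f)
      cur <- cur - p$adj_gc
    }
    p$normalized_lr <- cur
    p
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call deletions and duplications from normalized CGH ratios
#'
#' A region is called when its mean normalized log2 ratio lies beyond the
#' threshold and at least `min_probes` of its probes individually lie on
#' the same side of the threshold (concordance guard against single-probe
#' artifacts). Thresholds default to -0.5 / +0.4, between wild type (0) and
#' the theoretical heterozygous deletion (-1) and duplication (+0.585)
#' levels. Adjacent called regions of the same type within a gene are
#' merged into one event. Regions with fewer than `min_probes` unmasked
#' probes are untestable.
#'
#' @param normalized data.frame from [normalizeCgh()].
#' @param panel a [PanelDefinition-class].
#' @param del_threshold,dup_threshold log2 cutoffs (defaults -0.5 / +0.4).
#' @param min_probes minimum unmasked and concordant probes (default 3).
#' @return data.frame: sample_id, gene, region_labels, type, mean_lr,
#'   n_regions, plus `untestable` regions as attribute "untestable".
#' @export
callCghRegions <- function(normalized, panel, del_threshold = -0.5,
                           dup_threshold = 0.4, min_probes = 3L) {
  rg <- panelRegions(panel)
  dt <- data.table::as.data.table(normalized)
  reg <- dt[, list(mean_lr = mean(normalized_lr, na.rm = TRUE),
                   n_probes = sum(!is.na(normalized_lr)),
                   n_del = sum(normalized_lr < del_threshold, na.rm = TRUE),
                   n_dup = sum(normalized_lr > dup_threshold, na.rm = TRUE)),
            by = c("sample_id", "gene_name", "region_label")]
  untestable <- as.data.frame(reg[reg$n_probes < min_probes,
                                  c("sample_id", "gene_name", "region_label")])
  calls <- list()
  for (s in unique(reg$sample_id)) {
    for (gene in unique(mcols(rg)$gene_name)) {
      ri <- which(mcols(rg)$gene_name == gene)
      ri <- ri[order(start(rg)[ri])]
      labs <- mcols(rg)$region_label[ri]
      sub <- reg[reg$sample_id == s & reg$gene_name == gene]
      sub <- sub[match(labs, sub$region_label)]
      state <- rep("wt", length(labs))
      testable <- !is.na(sub$n_probes) & sub$n_probes >= min_probes
      state[!testable] <- "na"
      state[testable & sub$mean_lr < del_threshold &
            sub$n_del >= min_probes] <- "deletion"
      state[testable & sub$mean_lr > dup_threshold &
            sub$n_dup >= min_probes] <- "duplication"
      r <- rle(state)
      endpos <- cumsum(r$lengths)
      for (k in seq_along(r$values)) {
        if (!r$values[k] %in% c("deletion", "duplication")) next
        span <- (endpos[k] - r$lengths[k] + 1L):endpos[k]
        calls[[length(calls) + 1L]] <- data.frame(sample_id = s, gene = gene,
          region_labels = paste(labs[span], collapse = ","),
          type = r$values[k], mean_lr = mean(sub$mean_lr[span]),
          n_regions = length(span))
      }
    }
  }
  res <- if (length(calls)) do.call(rbind, calls)
         else data.frame(sample_id = character(), gene = character(),
                         region_labels = character(), type = character(),
                         mean_lr = numeric(), n_regions = integer())
  attr(res, "untestable") <- untestable
  res
}
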