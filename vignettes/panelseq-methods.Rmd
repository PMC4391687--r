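---
title: "Methods: amplicon panel sequencing, dosage and validation in panelseq"
author: "panelseq authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: amplicon panel sequencing, dosage and validation in panelseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`panelseq` implements the dry-lab core of a multiplexed-amplicon germline
panel: reads from up to 96 barcoded samples are pooled per batch, every
exon of every panel gene is tiled by several small PCR amplicons (on
average more than five per exon, multiplexed in groups of five), and each
reported region consists of the coding exon plus up to 20 upstream and 10
downstream intronic bases. Three analytic components sit on top of that
design: threshold-based germline variant calling, dosage-based detection of
exon-level deletions and duplications (large rearrangements, LR), and
analytical-validation statistics with exact confidence bounds. A microarray
CGH caller provides the orthogonal LR route.

Everything operates on generic `PanelDefinition` objects (GRanges of
regions and amplicon inserts); no human genome coordinates are assumed.

# Sequencing pipeline

## Demultiplexing

Each read begins with its sample's 6-nucleotide barcode. Matching is
**exact**: with only six bases there is no mismatch budget that would not
also create cross-sample collisions, so a read whose prefix matches no
barcode goes to a counted unassigned bin. Read-conservation counters
(input = routed + unassigned; routed = assigned + pseudogene-discarded +
unmapped) are carried through the run log.

## Trimming

Primers are stripped by prefix match against the panel's primer set,
tolerating one mismatch. Quality trimming removes the 3' tail that fails
Q30: the maximal terminal run of sub-threshold bases is removed, then a
five-base sliding-mean guard keeps peeling while the trailing window mean
is still below threshold, so sawtooth tails with isolated good bases do
not survive. The rule never reorders interior bases and may trim a read to
length zero. We chose this two-part rule because it removes exactly the
below-Q30 tail on clean inputs (ten trailing Q2 bases lose exactly ten
bases) while still handling degraded tails that a pure terminal-run rule
would keep.

## Pseudogene-aware assignment

Reads are assigned to the reference (genes *and* pseudogene homologs) by
best local alignment score, with scoring match +2, mismatch −3, gap open
−5, gap extension −2 and an assignment floor of 0.6× the maximum
achievable score for the read's length. The discard rule is strict: a read
whose best pseudogene score is **greater than or equal to** its best gene
score is discarded. Ties between genes break to the lexicographically
first gene and are flagged multi-mapping.

Computationally the search is seed-and-extend, the same strategy
production aligners use: exact 16-mers from three read positions (both
orientations) locate candidate reference windows; candidates are scored
gaplessly; and a Smith–Waterman pass (via `Biostrings::pairwiseAlignment`)
re-scores the best candidate window of each reference class whenever the
gapless score is depressed (an internal indel) or a mismatch cluster sits
at a read end (an indel near the boundary). Whenever a candidate falls in
a gene with a pseudogene partner, the colinear partner window is always
scored too, so a gene/pseudogene tie cannot be missed for lack of a seed.
The DP pass uses *global-local* alignment — the whole primer- and
quality-trimmed read must align — because soft-clipping would silently
absorb indels near read ends.

Two numerical decisions matter for allele frequencies:

* **Read-end masking.** The terminal two aligned bases of each read are
  not counted as base observations (gap evidence is kept). A deletion two
  bases past a read end is mathematically indistinguishable from a single
  terminal mismatch under the scoring above (−5 for the mismatch beats −9
  for the gap), so terminal bases are unreliable witnesses; masking them
  removes that artifact class at negligible depth cost.
* **Parsimony (split) realignment.** A short indel flanked by
  semi-repetitive sequence can align gaplessly with only two mismatches
  and outscore the gapped truth (two mismatches cost 6 where a two-base
  gap costs 9), which both hides the indel and plants correlated false
  mismatch observations. Whenever a read's final alignment is gapless
  with at least two mismatches, the assigner tests every single 1–3 base
  insertion/deletion split (both anchorings of the seed diagonal) and
  prefers the indel interpretation when it removes at least two edits at a
  score cost of at most 4. At a per-base error rate of ~10⁻³, two
  independent errors that a consistent split could explain are vastly
  less likely than a real indel, so the parsimony preference is safe; it
  is the same reasoning behind classical indel realignment in variant
  pipelines.
* **Canonical indel events and spanning depth.** Aligners may place a gap
  anywhere in a repeat tract, so indel events are left-normalized at
  extraction time — every carrier of the same event keys the same
  (position, allele) — and a carrier's base observations across the
  ambiguous tract (from the canonical anchor through the following base)
  are suppressed. With that bookkeeping, the indel frequency
  carriers / (carriers + base depth at anchor+1) is exact for insertions
  and deletions at any zygosity: reads ending at the anchor (which cannot
  inform the event) drop out of the denominator, and carriers are never
  double-counted. Without these rules, amplicon-terminal and
  repeat-adjacent indels drifted out of their zygosity bands or split
  their support across two anchors.

## Pileup and calling

Allele counts are accumulated per (sample, contig, position), restricted
to panel regions plus flanks, with forward/reverse orientation tracked.
Indel alleles are keyed by their left-normalized VCF representation
(anchor base plus inserted/deleted sequence).

Calling is purely threshold-based — the assay's definition, not a
likelihood model, and deliberately kept that way. The dominant
non-reference allele's frequency is classified into lower-inclusive
half-open bands: [0, 0.10) noise, [0.10, 0.30) flagged-low, [0.30, 0.70)
heterozygous, [0.70, 0.90) flagged-high, [0.90, 1.00] homozygous. The
band edges themselves fall upward (0.30 is heterozygous, 0.90 homozygous);
the assay text leaves the boundary convention open and a total
deterministic function is required, so this is fixed and documented rather
than configurable. Flagged bands produce calls with
`flagged_for_confirmation` status (Sanger follow-up in production; the
`confirm` filter tag in VCF output). Only the single most frequent
non-reference allele per position is classified.

Two depth rules come straight from the assay: any region containing a
base under 50X yields a per-region coverage flag keyed by its minimum
depth, and **no position under 50X ever yields a call** — inside a
homozygous deletion, for example, only stray error reads remain and would
otherwise produce depth-1 "homozygous" artifacts.

# Large rearrangements from amplicon dosage

The chain is: (1) divide each count by its sample's mean count; (2) divide
by the amplicon's median ratio across the batch (median, not mean, so one
mutant sample in 96 does not shift its own reference); (3) average the
adjusted ratios of the amplicons overlapping each region (mean chosen as
the simplest summary consistent with "combined into a summary value");
(4) scale by 2 / batch-median so wild type sits at copy number 2. Calls
are maximal runs of adjacent regions under 1.5 (deletion) or over 2.5
(duplication) — the midpoints between integer copy states, standing in
for the human reviewer's judgement on the scatterplot. A region-level
dispersion (batch SD of the dosage) is reported for review. At least 8
non-failed samples are required for batch statistics; all-zero samples are
"No Result" and excluded.

Allele dropout: an amplicon is flagged when its adjusted ratio is within
0.15 of the single-allele level 0.5 **and** at least 4 batch SDs from the
amplicon's batch mean (SD floored at 1e-6 for noise-free synthetic
batches), unless its region is already part of an LR call for that sample.
The z-window combination makes the flag specific to isolated single-allele
amplicons — the signature of a variant under a primer binding site hiding
a heterozygous variant.

One known compression: a multi-region event shifts its own sample's mean
count, pulling dosages toward 2 by roughly the fraction of amplicons
involved. On panels of realistic size (hundreds to thousands of amplicons)
the shift is a few percent; on very small synthetic panels it can push a
duplication near the 2.5 threshold, which is why the simulated studies use
panels of 20 regions / ~100 amplicons.

# Microarray CGH

Per-probe log2(sample/reference) ratios run through four stages, applied
in their listing order (the order is not otherwise specified; each stage's
adjustment is recorded and the diagnostics sum exactly to raw −
normalized): array-median subtraction ("sample dosage"); LOWESS of ratio
vs mean log-intensity (MA-style, span 0.3); subtraction of each probe's
historic median ratio over at least 10 prior wild-type arrays (probes
without history get 0 and a flag); and a LOWESS trend of ratio vs GC
fraction as the GC stage — the production "custom GC normalization" is
undisclosed, so a nonparametric trend fit is the defensible generic
choice. Regions are called when the mean normalized ratio passes −0.5
(deletion) or +0.4 (duplication) with at least three probes individually
past the threshold; those cutoffs sit between wild type (0) and the
theoretical heterozygous levels (−1 and +0.585). Adjacent called regions
merge into one event.

# Synthetic data: what it emulates and what it does not

The generator reproduces the assay's structure: 96-sample batches (default),
mean depth 1000 (default; the scaled studies use 200), 2×150 paired reads
carrying barcode then primer, per-amplicon read-pair counts drawn negative
binomial around a mean calibrated to the target depth (CV configurable;
CV = 0 is an exact mode in which the dosage chain returns 2.0 identically),
pseudogene homologs generated as colinear point-substituted copies at
configurable identity (default 0.97, in the 95–98% band typical of the
problematic homologs) with divergent positions recorded — and with the
guarantee that no read-length stretch is divergence-free, mirroring the
production assay's engineered specificity for pseudogene regions
(specific long-range amplification): without at least one divergent site
per read span, every read from such a stretch ties with the pseudogene
and is discarded by the assignment rule, a coverage hole no informatic
method could fill — pseudogene
crosstalk reads at a configurable fraction (default 5%), heterozygous
variants assigned per read pair with probability 0.5, dropout events
restricting one amplicon to a single haplotype at half yield, and a
geometric 3'-quality decay on a configurable fraction of reads. CGH chips
are a fixed per-panel probe design (placement, GC, affinity, systematic
probe offsets) shared by test and historic arrays, as a real array lot
would be.

It does **not** emulate: sequencing indel errors, instrument-specific
error profiles, droplet occupancy statistics of emulsion PCR, GC-dependent
amplification bias in reads, structural variants other than whole-region
deletion/duplication and single-amplicon dropout, or non-colinear
pseudogene architecture. Passing the synthetic studies therefore
demonstrates the correctness of the analytic chain under the assay's
stated statistical model, not robustness to every artifact of real
chemistry.

Variant positions in the random spec generator keep 6 bases off region
edges and 10 bases apart within a (sample, gene), so that indel reference
spans stay inside regions and haplotype construction stays simple.

# Validation statistics

Concordance accounting is base-complete: TP + FN + FP + TN equals samples
× bases analyzed per sample; a zygosity-discordant site counts as one FN
plus one FP (the most conservative reading) and is itemized. Sensitivity
is TP/(TP+FN), specificity TN/(TN+FP). Lower confidence limits use the
one-sided exact (Clopper–Pearson) construction: the limit is the `p`
solving `P(X ≥ x | n, p) = 1 − confidence`, i.e. the `1 − confidence`
quantile of Beta(x, n−x+1), which reduces to `α^(1/n)` when x = n.
Reported percentages are truncated — not rounded — to two decimals,
matching the conservative ">99.92%" reporting style; full precision is
kept internally.

# Problem sizes in the shipped studies

The package's synthetic studies run at desk scale, chosen so the full
suite exercises every stage in minutes on one CPU: the sequencing
validation batch uses 10 samples, a 4-gene / 20-region panel with two
pseudogene homologs, 60 injected variants (SNVs and 1–2 base indels,
heterozygous and homozygous) at mean depth 200 and base error rate 0.002;
the LR study uses ten 96-sample batches of ~100 amplicons with count CV
0.08 and two injected events each; reproducibility uses one sample's
truth run in triplicate within each of three batches at depth 200. The
clinical cohorts behind the assay's published figures (thousands of
patient samples) are not reproducible without those samples; their
arithmetic is exercised exactly, and their study designs via these
synthetic analogs.

Variant positions in the random validation spec also keep clear of
pseudogene-divergent sites: an allele that converts the gene to the
pseudogene sequence at a divergent site mimics gene conversion, and its
carrier reads tie with the pseudogene and are discarded — correctly, by
the assay's rule, but invisibly. Production assays cover that blind spot
with enrichment specificity, not informatics, so the synthetic validation
study mirrors the detectable-variant conditions of the real one.

# Known limitations

* Zygosity of indels adjacent to the terminal bases of *all* covering
  amplicons can still be under-called when the local sequence makes the
  shifted (mismatch) interpretation strictly better-scoring for most
  reads; such sites surface in the flagged bands for confirmation rather
  than as wrong confident calls.
* Mates are aligned independently; no fragment-level rescue is attempted.
* Gene-conversion-like alleles (the pseudogene base appearing in the gene
  at a divergent site) are discarded with the pseudogene crosstalk and
  cannot be called; resolving them requires enrichment-level specificity.
* Batch normalization assumes most samples are wild type at any given
  region — the assay's own assumption; a recurrent event in many samples
  of one batch would shift the median reference.
* The CGH LOWESS stages absorb a fraction of a true event's signal
  (regions at −1 typically normalize to around −0.7/−0.8); the calling
  thresholds are placed to tolerate that.
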