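---
title: "Methods: consensus ChIRP peaks, Hoogsteen triplex search and region-set enrichment"
author: "triplexChIRP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus ChIRP peaks, Hoogsteen triplex search and region-set enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`triplexChIRP` analyses where and how a chromatin-associated long
noncoding RNA (lncRNA) binds the genome, starting from replicate
ChIRP-seq peak calls.  The chain of inference is:

1. **Consensus peaks.** Regions supported by a minimum number of
   replicate experiments (default 2 of 3) are retained.
2. **TSS-relative annotation.** Peaks are classified against gene
   models, with a custom *proximal region* of −1,500 to +500 bp around
   the TSS (strand-aware), split into *region 1* (−1,500/−500) and
   *region 2* (−500/+500).  The proximal excess is tested against random
   fixed-length region lists with a chi-square test and an empirical
   permutation p-value.
3. **Triplex prediction.** A Hoogsteen-rule scanner pairs single-stranded
   RNA stretches (TFOs) with purine-rich duplex tracts (TTS).  RNA bases
   likely buried in secondary structure are masked beforehand.  RNA-side
   hits merge into DNA-binding domains (DBDs); DNA-side hits are the
   DBS.  Enrichment of DBS in target regions is assessed with a
   genomic region test (length-matched random regions) and a promoter
   test (target vs non-target gene promoters).
4. **Region-set enrichment.** Peaks, stratified by predicted triplex
   formation, are tested against feature databases (Alu, histone marks,
   …) within a restricted universe built from the peaks themselves,
   LOLA-style, with odds ratios and one-sided hypergeometric p-values.
   The ratio of odds ratios between triplex-carrying and triplex-less
   peaks isolates features coupled to the binding mechanism.
5. **Co-occurrence.** Distances from each DBS to the nearest Alu element,
   and the percentage of genes carrying both a DBS and an Alu across
   fold-change-ranked gene bins, tested for a monotone trend with the
   Jonckheere–Terpstra (JT) statistic.

# Coordinate conventions

Internally everything is a `GRanges` (1-based, closed), the native
Bioconductor convention.  BED6 and ENCODE narrowPeak files are 0-based
half-open and are converted at the I/O boundary; round-trip identity is
tested.  Chromosome names are compared verbatim — no `chr` prefix
normalisation — so a naming mismatch fails loudly instead of producing an
empty join.  Transcript (RNA) coordinates are 1-based inclusive.

# Consensus peak derivation

Each replicate peak is reduced to a center — its summit when the
narrowPeak summit offset is present, its midpoint otherwise — and
extended ±500 bp.  Connected components of overlapping extended regions,
pooled over replicates, form candidate consensus regions; support counts
*distinct replicates* (two peaks from one replicate count once).  The
consensus interval is the component span, shrunk to the minimal interval
covering the members' narrow regions whenever that fits inside the span.
Chained overlaps (A∩B, B∩C, not A∩C) deliberately resolve to a single
consensus region: connected-component semantics are the simplest
deterministic reading, are order-invariant, and are what the tests pin
down.

# The triplex scanner

## Hit definition

For each motif — pyrimidine parallel (U·A, C·G), purine antiparallel
(A·A, G·G), and the two GT motifs (G·G, U·A) — the RNA is aligned against
the purine strand of either duplex orientation; antiparallel motifs read
the RNA 3'→5'.  A *hit* is a window that

* begins and ends with a matching triplet,
* has length within `[min_length, max_length]` (defaults 15 and 25 nt —
  the biologically expected 15–20 bp range plus margin),
* has mismatch rate ≤ `max_error_rate` (default 0.20, mismatch-only; the
  triplex geometry does not tolerate bulges at this level of modelling),
* is *containment-maximal*: no strictly larger qualifying window on the
  same diagonal contains it, and
* has a TTS (purine-strand) guanine fraction ≥ `min_guanine_rate`
  (default 0.10, Triplexator-style; set 0 to disable).  The guanine
  filter is applied to the DNA side: a pyrimidine-motif TFO contains no
  guanine by construction, so a TFO-side reading would forbid the
  canonical poly-U:poly-A triplex.

Masked bases (`N`, from accessibility masking) never match, so masking
can only remove hits.  A single RNA window may be reported under several
motifs (a poly-U TFO is a legitimate pyrimidine-motif *and* GT-motif
binder); downstream region-level statistics count regions, not hits, and
are unaffected.

## Search strategy and oracle equivalence

Any qualifying window is ≥80% purine on one DNA strand and therefore
contains a 15-mer with at most `floor(max_error_rate * max_length)`
pyrimidines; the scanner therefore restricts the diagonal walk to the
union of such candidate 15-mers (sound, no hits lost) and then runs an
exact per-diagonal maximal-window search in C++.  The implementation is
required by the test suite to equal an independent exhaustive
all-offsets/all-windows enumeration on more than a hundred seeded
instances, including planted dense-hit cases.

## Downstream statistics

DBDs merge TFO intervals within `merge_gap` (10 nt).  The *region test*
compares the number of target regions with ≥1 DBS against length-matched
regions sampled uniformly from the genome (or a supplied background
pool); the empirical p-value is the add-one permutation form
`(1 + #{null ≥ obs}) / (n + 1)`.  This is a simpler, calibration-tested
null than the background-matching scheme of the TDF tool it emulates;
the divergence is intentional and documented here.  The *promoter test*
builds the 2×2 table of genes with/without a promoter DBS for a target
list against all remaining genes and applies the Pearson chi-square.

# Annotation details

Peaks are anchored at their midpoint and classified with priority
Proximal Region > 5'UTR > 3'UTR > Exon > Intron > Downstream > Distal
Intergenic; gene ties break by TSS distance.  The midpoint anchor makes
the classification a partition (each peak one category) and makes the
generator's placement rule exactly recoverable.  UTR and exon categories
engage only when the gene model carries them.  Two empirical p-value
variants are provided: the standard add-one form, and the published
rule — one over the number of random lists whose per-list chi-square
against the observed table stays significant after Benjamini–Hochberg
correction (the correction method is a documented choice; the source
procedure names none).  Note the published rule has granularity `1/N`,
so with 1,000 lists its smallest attainable value is 0.001.

Chi-square tests use no continuity correction: the reconstruction of the
published proximal-enrichment example (518/5,064 vs 401/5,000) then gives
p ≈ 1.2e-4, matching the printed value's order; no reconstruction
reproduces its third digit exactly.

# Enrichment

Universe elements (merged peaks), not base pairs, are the sampling
units, as in LOLA.  Support is ≥1 bp overlap (`min_overlap`
generalises).  The one-sided hypergeometric tail is the default (the
figures read OR > 1 as enrichment); Fisher's two-sided test is available.
The stratified ratio of odds ratios uses the same universe for both
strata; with strata of a few dozen peaks empty cells are common, so a
Haldane–Anscombe-corrected ratio (+0.5 per cell) is available and used by
the pipeline — the uncorrected ratio is reported as undefined in those
cases rather than ±∞.

# Jonckheere–Terpstra

The statistic counts, over ordered group pairs, cross-pairs with
`x < y`, ties as ½.  The normal approximation uses the standard
tie-corrected variance; a seeded permutation p-value is available and
agrees with the approximation to within 0.02 at n = 60 in the tests.
When every value is identical the variance collapses and p = 1 is
reported.  Applied to the co-occurrence table, the values are per-gene
0/1 indicators (has triplex + Alu) within fold-change-ranked bins of
`bin_size` genes (equal-sized bins; ranking by |fold change| with gene-id
tie-break for determinism).

# The synthetic-data generator

The generator is first-class, tested code.  Its defaults are the study
conditions: three replicates, ~775 bp peaks, a 10.23% proximal share
against an ~8% background realised through gene density (40 genes ×
2 kb promoters over 1 Mb), a 2,000-nt lncRNA with pyrimidine
triplex-forming domains at 119–196 (DBD-A, planted as 30-nt target
tiles) and 47–70 (DBD-B, 18-nt tiles, so the domain disappears when the
search minimum rises from 15 to 20 nt), target sites planted in half the
promoters' region 1, Alu-like elements 150 bp from planted sites, and
histone-mark tracks at odds 6 (H3K4me1, H3K36me3) or 1/6 (H3K27me3) for
triplex-carrying versus triplex-less peaks.  Sites are planted as exact
motif complements by default (`tts_errors = 0`): a planted mismatch can
create a match at a window edge that no pre-planting screen of the
transcript can anticipate, blurring the planted domain boundaries, so
mismatch tolerance is exercised by the unit tests and oracle instances
rather than by the bundle defaults.

Three constructions keep the planted ground truth *identifiable*:

* **Genome-wide TTS suppression.** The background genome is rebalanced so
  no 15-bp window carries ≥12 purines on either strand.  Any hit window
  must contain such a window, so the unplanted genome carries no triplex
  target sites at all and every discovered DBS is attributable.
* **Pyrimidine buffers.** Each planted purine tract is flanked by 7
  pyrimidines (on the tract's strand).  A window crossing the buffer
  needs more mismatches than the error budget allows at any length up to
  `max_length`, so hits cannot creep into flanking sequence and the
  recovered DBD endpoints are sharp.
* **Off-target scrub of the lncRNA.** Low-complexity pyrimidine tracts
  match their own purine complements at shifted offsets with high
  probability.  After drafting the lncRNA, the generator repeatedly
  scans it (slightly looser thresholds than the runtime search, so
  per-promoter planted mismatches cannot re-enable anything) against the
  planted tiles' perfect target sequences and the Alu consensus, and
  flips one base of any off-target window until none remains.  Hits
  confined inside a planted domain and no longer than its tiles are
  acceptable — they cannot widen a merged domain nor survive a raised
  length minimum.

The Alu-like element is a fixed synthetic 300-bp sequence (not a RepBase
consensus — element identity is irrelevant to the statistics) built with
balanced purine content so insertions never create target sites.

What the generator does **not** emulate: read-level noise, non-uniform
genomic background (GC isochores, real repeat families), realistic Alu
phylogeny, fuzzy triplex sites, or correlated replicate artefacts.
Passing tests therefore demonstrate algorithmic correctness and
calibration under a controlled null — not performance on real ChIRP-seq
data, where peak callers, mappability and chromatin structure add noise
this package does not model.

# Numerical and design choices

* Peak widths are Normal(775, 80) truncated at 300 bp; true-peak centers
  keep ≥1.2 kb separation so extension ±500 bp cannot chain distinct
  peaks into one consensus component.
* Noise peaks are placed outside proximal windows and the proximal count
  is budgeted over true + noise peaks, so the realised proximal share of
  each replicate file stays within ±1 percentage point of the target.
* Degenerate inputs: empty peak sets give all-zero distributions; a zero
  chi-square margin is an error; a region test with no TFO reports
  observed 0 and p = 1; zero null variance reports z as undefined while
  the empirical p stays valid.
* Floating-point rate thresholds are compared with a 1e-9 slack so that
  `mismatches ≤ rate × length` behaves identically in the scanner and
  the oracles.
* Problem sizes in tests and the acceptance script (e.g. 50-list
  annotation nulls of 1,000 regions instead of the study's 1,000 × 5,000;
  59–99 region-test randomizations; 60-kb calibration genomes) are
  desk-scale choices that keep the full suite reproducible in minutes;
  every statistic's behaviour is size-calibrated by the tests rather
  than by matching the study's genome-scale counts, which depend on the
  deposited raw data and are out of desk-scale reach.

# Known limitations

* The scanner's error model is mismatch-only; no thermodynamic or
  pH-dependent stability scoring.
* The region test's null is genome-uniform length-matched sampling, not
  TDF's covariate-matched background.
* The promoter/annotation gene model is TSS + end + optional UTR lengths
  and exons, not full transcript structure.
* The published empirical p of 0.0001 for 1,000 lists is below the
  granularity of the published rule (1/k ≥ 0.001); both the published
  rule and the standard add-one form are implemented, and the
  discrepancy is left as an observation.
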