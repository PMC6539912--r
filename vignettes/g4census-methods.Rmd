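---
title: "Methods: scoring, localization and cohort statistics in g4census"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, localization and cohort statistics in g4census}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4census)
```

# The problem

G-quadruplexes (G4) are four-stranded nucleic-acid structures built from
stacked guanine tetrads. Whether a stretch of genomic DNA can form one is
predicted here with the G4Hunter score, which rewards G-richness and
G-skewness: in a run of *n* consecutive guanines every base scores
`+min(n, 4)`, in a run of *n* cytosines every base scores `-min(n, 4)`,
and all other bases score 0. The mean of these per-base scores over a
sliding window is the window score; a positive score predicts a
quadruplex on the scanned strand, a negative score on its complement.
`g4census` applies this scan genome-wide across bacterial cohorts, and
adds the two downstream layers such surveys need: where putative
quadruplex sequences (PQS) sit relative to annotated features, and how
PQS density varies between phylogenetic groups.

# Calling model

A window **qualifies** when its mean score `w` satisfies `|w| >= t`
(threshold `t = 1.2`, window `W = 25` bp by default — the standard
G4Hunter settings for genome scans). Overlapping or adjacent qualifying
windows of the same sign merge into one maximal region; regions of
opposite sign never merge. Each merged region is **re-scored as the mean
per-base score over its full extent** and reported once, with strand
`+` for positive and `-` for negative scores. This matches the reporting
convention of the G4Hunter web tooling. Two consequences are worth
stating explicitly:

* Re-scoring can dilute: the union of qualifying windows includes flanking
  low-scoring bases, so a merged region's `|score|` can end up slightly
  below `t` even though every constituent window passed. Such regions are
  kept (they met the window criterion) and censused in the lowest score
  bin. `bin_score()` itself refuses sub-threshold scores, since callers
  binning arbitrary values should be told rather than silently clamped.
* Counts are **merged-region counts**, not window counts. Raw window
  counts would be systematically larger; the convention is fixed here so
  results are comparable across runs.

Score bins are left-closed, right-open (`[1.2,1.4), [1.4,1.6), [1.6,1.8),
[1.8,2.0), [2.0,Inf)`), so a score on a shared endpoint is counted exactly
once, in the upper bin.

Other calling choices: chromosomes are treated as linear (no window spans
a circular origin); non-ACGT symbols score 0 and break G/C runs; `U` is
treated like `T`; lowercase is accepted; a sequence shorter than `W`
contributes zero PQS with a warning rather than an error, so assemblies
with short plasmids aggregate cleanly. Coordinates are 0-based half-open
internally and converted to 1-based inclusive at every file boundary
(NCBI feature tables in, PQS/zone tables out).

# Feature-neighborhood localization

For each annotated feature we build three zones: `inside` (the feature
interval), `before` and `after` (flanks of at most 100 bp by default,
truncated at sequence ends). "Before" is strand-aware — the 5' side of
the feature, i.e. biologically upstream — with features of unknown strand
oriented as plus; a `orientation = "genomic"` switch reverts to plain
left/right for sensitivity analysis, since annotation conventions differ.
Membership is by overlap of at least 1 bp, and a PQS may be assigned to
several cells: once per zone interval it touches, in both zones when it
spans a boundary, and once per feature when same-class features overlap.
This most-inclusive rule is declared rather than inferred; it makes every
count reproducible from the definitions alone. Cell frequencies are
`1000 * count / summed zone length` (PQS per kbp), and cells whose summed
zone length is zero are dropped.

# Cohort statistics

Per genome we report length, GC%, PQS totals and per-bin counts, and the
frequency `f = 1000 * PQS / length`. Group summaries give n, median /
shortest / longest genome length, mean GC (unweighted), total PQS and
mean/min/max `f`. **Mean f is the unweighted mean of per-genome
frequencies**: the min/max columns are clearly per-genome quantities, so
the mean is treated the same; a pooled alternative
(`mean_f_method = "pooled"`, pooled counts over pooled length) is exposed
because the two differ whenever genome sizes vary.

Between-group differences in `f` are tested with the Kruskal–Wallis rank
test (tie-corrected H, chi-square approximation with k−1 df, α = 0.05),
computed via `stats::kruskal.test`; groups with fewer than 10 genomes are
excluded before ranking. When every retained value is identical the tie
correction is undefined (0/0); we define this degenerate case as H = 0,
p = 1 — no evidence of difference — rather than NaN. No multiple-testing
correction is applied: one omnibus test per grouping level.

For GC-versus-frequency outlier screening, per-genome frequencies within
one score bin are divided by the bin maximum and genomes **strictly
above** 0.5 of the maximum are flagged; a value of exactly 0.5 is not
flagged, and an all-zero bin yields no flags.

# The synthetic-data generator

Every stage is testable offline against constructions with known ground
truth. `synth_genome()` draws an i.i.d. background with
`P(G) = P(C) = gc/2`, `P(A) = P(T) = (1−gc)/2` and overwrites planted
motifs at random (spacing-constrained) or explicit positions, so the
stated genome length is exact and the plant ledger is exact. The default
planted tract is `(GGGGTGT)_8` (56 bp): a perfect-repeat quadruplex motif
of the kind observed as `(GGGGTGT)_n` arrays in cyanobacterial genomes,
whose long-tract mean score is 17/7 ≈ 2.43 — firmly in the top census
bin. `synth_cohort()` realizes per-group planted densities as Poisson
counts at the requested per-kbp rate and derives one RNG stream per
genome from (cohort seed, genome index), so cohorts are reproducible
file-by-file and byte-identical across runs. GC spans the bacterial range
(20–75%) and genome lengths 0.3–20 Mbp are supported; tests run at tens
of kb to 1 Mbp, sizes chosen to keep the whole suite under a minute per
file while leaving Poisson/GC concentration bounds comfortably tight.

What the generator does *not* emulate: dinucleotide/codon structure,
skewed chromosome halves, real annotation geometry, or phylogenetic
covariance between genomes. Passing tests therefore demonstrate that the
machinery is correct under known ground truth, not that any biological
conclusion transfers to real genomes.

One empirical property of the generator deserves emphasis: an i.i.d.
background at GC 30% is **not** PQS-free at the default threshold. The
scanner finds roughly 20–30 merged regions per Mbp of plant-free GC-30%
background (about 4/Mbp at GC 25%, about 1/Mbp at GC 20%), which is
consistent with the nonzero densities real low-GC genomes show. Tests
that require *exact* plant recovery with zero background therefore use
zero-score (A/T) spacers, where the construction is deterministic;
low-GC-background tests assert per-plant recovery (each plant covered by
exactly one call) instead of an exact total.

# Numerical choices

* Window means are computed from a cumulative sum (exact for the integer
  base scores; one floating division per window) and agree with naive
  per-window summation to 1e-12 in tests.
* Merging is over sorted window starts: a new region begins when the next
  qualifying start exceeds the previous window's end, which is equivalent
  to interval union of the windows.
* Region ordering is deterministic: (seq_id, start).
* Kruskal–Wallis H is checked against a from-first-principles rank-sum
  recomputation to 1e-9 on random tied data.
* `set.seed`-derived per-genome seeds stay below 2^31 − 1.

# Known limitations

* Quadruplex topology, loop grammars and folding thermodynamics are out
  of scope: a PQS is a score-threshold region, nothing more.
* Circular chromosomes lose at most `W − 1` origin-spanning windows.
* The merged-region convention means totals are not directly comparable
  to window-count surveys; at matching parameters the per-kbp frequencies
  of high-GC genomes are the quantity most sensitive to this choice.
* Group tests treat genomes as exchangeable within groups; no
  phylogenetic correction is attempted.
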