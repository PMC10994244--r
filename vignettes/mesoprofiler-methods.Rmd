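---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models behind `mesoprofiler`, the
parameters that matter, the assumptions the synthetic-data generators make,
and the places where the design was genuinely open and a choice had to be
made.

## Copy number from off-target reads

### Ratio model

A targeted panel's off-target reads cover the genome thinly but uniformly.
Binning the genome (default 30 kb), counting reads whose leftmost aligned
base falls in each bin (primary alignments only, MAPQ strictly greater than
30), and dividing by the mean count gives a ratio track with mean exactly 1.
For a clonal tumour of purity $\rho$ mixed with diploid normal cells, a bin
with tumour copy number $n_T$ has expected ratio

$$ r = \frac{n_T\,\rho + 2(1-\rho)}{\psi}. $$

Because $r$ is normalised to mean 1, the denominator $\psi$ is necessarily
the average copy number of the *sequenced mixture*,
$\psi = \rho\,\bar n_T + 2(1-\rho)$; with any other reading the model would
not average to 1 over the genome. The grid fit therefore estimates the
mixture-average $\psi$, and the tumour's own ploidy is recovered as
$\hat\psi_T = (\hat\psi - 2(1-\hat\rho))/\hat\rho$ — the copy-number
equation evaluated at $r = 1$. `fit_purity_ploidy()` reports both.

### Segmentation

The log2 ratio track is segmented by circular binary segmentation: within
each segment the arc $(i, j]$ maximising
$|\bar x_{arc} - \bar x_{rest}|\sqrt{k(n-k)/n}$ is found (an Rcpp kernel
scans all arcs via prefix sums), its significance is assessed by permuting
the bins within the segment, and the split is kept when the permutation
p-value is below `alpha`. Defaults: `alpha = 0.01`, `n_perm = 1000`,
minimum piece width 2 bins, seeded permutation RNG. Two deliberate
simplifications: the arc statistic uses the segment-wide variance (constant
under permutation, so it cancels from the test) rather than a pooled
two-sample variance, and there is no post-hoc "undo splits" pruning. The
permutation loop stops early once the exceedance count guarantees
rejection of the split, which changes no decision. Segment means are taken
on the *linear* ratio scale, because the copy-number equations are written
in $r$, not $\log r$; the log is used only to stabilise the changepoint
statistic.

### Grid fit and its degeneracies

For every $(\psi, \rho)$ on the grid ($\psi$ 1.5–5, $\rho$ 0.2–1, step
0.01 each) the per-segment $n_T = (\psi\bar r - 2(1-\rho))/\rho$ is scored
by $\sum_s w_s\,|n_T^{(s)} - \mathrm{round}_{\ge 0}(n_T^{(s)})|$ with
$w_s = 1$ by default (`weight_by_length = TRUE` uses bin counts instead;
unweighted sums are fragile when segmentation produces small spurious
segments). Two points deserve emphasis:

* **Distance to non-negative integers.** The copy-number model admits exact
  alternative solutions of the form $n_T \mapsto a\,n_T + b$ with suitably
  adjusted $(\rho, \psi)$. Measuring distance to the nearest *non-negative*
  integer (a segment cannot have negative copies) penalises every
  downward-shifted family as soon as the genome contains a homozygous
  deletion — which mesothelioma genomes, with their frequent CDKN2A
  deletions, typically do. Plain rounding would leave those families
  exactly tied with the truth.
* **Ties and ridges.** Exactly tied minima are resolved deterministically:
  lowest $\psi$, then highest $\rho$ (the most parsimonious genome). When
  grid points essentially tied with the minimum (within $10^{-12}$) spread
  over more than 0.1 in $\psi$ — as happens whenever the profile has a
  single copy state — the fit is flagged `degenerate` and should not be
  trusted.

The doubling family ($a = 2$) survives the non-negativity argument; it is
disfavoured statistically (its slope doubles the noise contribution) and by
the parsimony tie-break, but a profile whose states are all even is
genuinely ambiguous.

### Exon-level copy ratio

On-target copy number per exon is the MAPQ-filtered read depth at the
centre base of each exon target divided by the same count in a
user-supplied diploid reference sample (normalising capture efficiency),
optionally rescaled by 2 to the copy-number scale. Exons where the
reference has zero depth are masked with a warning.

## Expected splicing ratio

The gene model merges all annotated exons of the gene into disjoint
intervals, ordered in transcription direction, and places a 200-nt anchor
pseudo-exon immediately 5′ of the TSS so that promoter-proximal read starts
count as expected for exon 1. Exon $j < k$ belongs to exon $k$'s expected
set iff the exonic length strictly between them is less than
`read_length - 1` (a read whose final base is exon $k$'s first base extends
`read_length - 1` spliced nucleotides upstream); each exon belongs to its
own set. The bound lives in one function (`expected_upstream()`) so the
boundary convention can be revised in one place. Sets are by construction
suffix-contiguous.

For each exon, *informative* reads are those with at least one aligned
(CIGAR M) base in the exon — a read splicing entirely across a skipped
exon contributes nothing to it, which is precisely what depresses the
ratios downstream of a skip. *Expected* reads are the informative reads
whose 5′-most aligned base (strand-aware) lies in the expected set or the
anchor. Cells with fewer than `min_reads = 10` informative reads are
reported `NA` and drawn black in the heatmap. Mate-pair information is not
used for the ratio; the junction screen instead classifies every N gap as
canonical iff both boundaries match an annotated intron exactly.

Two open points were resolved as follows: a read is counted once per exon
it overlaps (not assigned uniquely), and read starts are tested against
genomic exon intervals only, without checking that a spliced read's own
splice path is canonical — the noncanonical-junction fraction covers that
signal separately.

## CDK4 profile and proliferation score

The spot3/spot2 volume ratio maps to A (ratio < 0.025), L
(0.025 ≤ r ≤ 0.5) or H (r > 0.5); the closed-on-both-ends L interval
follows the sharper of the two published statements of the rule. The three
intervals partition $[0, \infty)$; a zero spot 2 volume makes the ratio
undefined and classification is refused with a flag rather than silently
scored. The proliferation score is the per-sample median CP20M expression
over a user-supplied cell-cycle-progression signature list (no list is
hard-coded; absent genes are reported, never imputed), taken on the linear
CP20M scale with a `log2` switch defaulting off. The ratio–score
association uses Spearman's rank correlation with mid-ranks for ties,
restricted by default to the H and L profiles.

## Expression thresholds and survival

CP20M is `count / library_size * 2e7`; with library sizes equal to column
sums every normalised column totals exactly $2\times10^7$. Threshold
conventions, printed by `stratification_schemes()` so they can be audited:
"below x" is $<x$; "from x" and "set at x" are $\ge x$; the CDKN2A
intermediate band 100–1000 is closed on both ends (1000 is intermediate
because "high" is defined as $>1000$). Gene filtering keeps a gene whose
maximum raw count reaches 100; viral genomes are detected at $\ge 20$
counts.

`km_logrank()` computes product-limit curves and the Mantel–Cox test from
observed/expected tallies over pooled event times, with the full
$G \times G$ O−E covariance matrix and a $\chi^2$ on $G-1$ degrees of
freedom. The two-group hazard ratio is $(O_1/E_1)/(O_2/E_2)$ with a
log-scale CI using $\mathrm{SE} = \sqrt{1/E_1 + 1/E_2}$ — the O/E
construction rather than a Cox fit, deliberately. This estimator is known
to attenuate strong effects toward the null (visible in the hazard-ratio
recovery figures the acceptance script reports); its CI coverage remains
near nominal at the effect sizes studied here. Groups with zero events
leave the hazard ratio undefined and flagged. No multiple-testing
correction is applied to survival contrasts. Fisher's exact test for 2×2
tables is two-sided with the conditional MLE odds ratio; a zero margin
returns p = 1 with the odds ratio flagged undefined.

## Synthetic-data generators

All generators are pure functions of their seed.

* **Off-target counts**: negative-binomial bin counts with mean
  $\texttt{mean\_depth} \times r$. `dispersion` is the *excess-variance
  fraction* relative to Poisson (variance $= \mu(1+d)$, Poisson at 0) —
  the realistic magnitude of overdispersion for 30-kb bins of
  shallow-coverage DNA sequencing, where per-bin variance runs a few
  percent above Poisson rather than the many-fold overdispersion typical
  of per-gene RNA-seq counts. The default study profile used by the tests
  and the acceptance script is 500 bins in 10 segments with copy states
  {0,…,4} (including homozygous deletions), purity 0.7, tumour ploidy 2.0,
  mean depth 200, dispersion 0.05.
* **Spliced reads**: isoforms are exon-rank subsets with mixing fractions;
  reads are placed uniformly along each spliced sequence and converted to
  genomic start + M/N CIGAR. The exact per-exon truth is computed by
  exhaustively enumerating every placement on every isoform
  (`splice_truth()`), the oracle the ratio reader is tested against.
* **Spot tables**: true ratios drawn strictly inside each class interval,
  with margins from the boundaries so float noise cannot flip a class.
* **Cohorts**: exponential event times with group-specific hazards
  (rates per month), independent exponential censoring, and an optional
  count matrix whose CP20M group means are exact by construction (columns
  padded to $2\times10^7$ with a background pseudo-gene). The survival
  scenario used in tests takes a poor-prognosis hazard of 0.088/month
  (median ≈ 7.9 months) and a hazard ratio of 0.31 for the favourable
  group, with censoring at 0.02/month.

What the generators do *not* emulate — and hence what passing tests do not
show about real data: GC and mappability bias in bin counts, subclonal
(non-integer) copy number, alignment artefacts and soft-clipping,
positional bias of RNA-seq coverage along transcripts, batch effects in
expression, and non-exponential or informative censoring in survival.

## Problem sizes

The test suite and acceptance script run at desk scale, chosen to make the
statistical checks sharp while staying fast: 500-bin genomes (20 seeds for
parameter recovery, 100 for breakpoint placement), 2000-read splicing
simulations, 1000 null cohorts for log-rank calibration and 200 cohorts of
n = 300 for hazard-ratio coverage. The full 351 × 81 grid fit is vectorised
and takes well under a second.

## Known limitations

* Purity/ploidy estimation needs several segments and at least three
  distinct copy states; with fewer the 2-parameter grid can overfit,
  and the all-even-states doubling ambiguity is unresolvable from ratios
  alone. The degeneracy flag covers the single-state ridge, not every
  weakly-identified profile.
* CBS without undo-splits occasionally emits small boundary slivers at
  low signal-to-noise; the length-weighting flag on the grid fit is the
  intended mitigation.
* The splicing detector assumes the library's read length and a
  single-end view of alignments; paired-end inner-distance information is
  not exploited.
* No GC correction is applied to bin counts, and the diploid reference
  sample for exon-level ratios is a required user input.
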