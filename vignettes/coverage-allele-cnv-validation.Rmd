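---
title: "Coverage- and allele-based validation of single-cell CNVs: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage- and allele-based validation of single-cell CNVs: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the models behind the package, the tunable
parameters and their defaults, the numerical choices made where the
design was genuinely open, what the synthetic-data generator does and
does not emulate, and known limitations. It states no empirical result
that the test suite and `scripts/acceptance.R` do not themselves compute.

## The problem

Single-cell whole-genome sequencing of post-mitotic cells runs at very
low coverage (on the order of 0.1×) after whole-genome amplification
(WGA). At that depth, megabase-scale deletions are visible as read-depth
drops across consecutive bins — but WGA also produces megabase-scale
coverage artifacts. The package's central idea is arbitration: a true
heterozygous deletion removes one parental haplotype, so phased germline
heterozygous SNPs inside it lose one allele in that cell, while a
coverage artifact keeps allelic balance. Read depth proposes; phased
loss of heterozygosity (LOH) disposes.

## Read-depth model

**Binning.** Bins hold a fixed amount of uniquely mappable sequence
(default `target_mappable = 5e5` bp), so bin *widths* vary with local
mappability. Boundaries fall where the cumulative mappable length
reaches multiples of the target; an unmappable gap is assigned to the
bin being accumulated (the left bin) — the choice is arbitrary but must
be fixed, and left-assignment keeps bins contiguous. Trailing
sub-target bins are dropped (the discarded mappable bp are reported).
All coordinates are 0-based half-open, BED-compatible; VCF positions are
converted on ingest.

**Normalization and QC.** Each cell is scaled to mean copy number 2 over
unmasked bins. Two artifact filters follow: (i) bins whose cross-cell
median copy number falls outside Tukey's fences (Q1 − 1.5·IQR,
Q3 + 1.5·IQR) are masked genome-wide — these are systematic
amplification artifacts, not per-cell noise; (ii) cells are dropped when
their per-cell MAD of bin copy numbers exceeds μ + 3σ of a Gaussian fit
to the MAD distribution (fitted on all cells; the alternative of a
trimmed fit changes little and adds a tuning constant), or when more
than 80% of reads map to a single chromosome. A manual exclusion list is
accepted as configuration, not inferred.

**Segmentation.** Circular binary segmentation: within each chromosome,
the arc `(i, j]` maximising
$T = |\bar{x}_{in} - \bar{x}_{out}| / (s\sqrt{1/k + 1/(n-k)})$
is found exhaustively, the split is accepted when its permutation
p value is below `alpha = 0.01` (default `nperm = 1000`, seeded, with
two-sided sequential early stopping: the loop ends as soon as either
significance is impossible or no exceedance has occurred in 200 draws),
and the recursion continues inside the pieces. Segmentation operates on
`log2(cn/2)` (floored at `cn_floor = 0.05` so homozygous losses stay
finite): multiplicative WGA noise is homoscedastic on that scale and a
heterozygous deletion is a unit shift, which is also how the standard
read-depth segmenters work. After recursion, the *undo* step merges the
weakest adjacent pair while the mean difference is at most
`undo_sd = 3` times the bin-to-bin noise SD estimated robustly as
`mad(diff(x))/sqrt(2)`. A pooled within-segment SD would be inflated by
regionally correlated amplification drift (and by the split under
evaluation), making the rule destroy true deletions; the high-pass
estimator measures only the noise the rule is meant to guard against.

**Copy-number cutoffs.** A Gaussian mixture (EM, components initialised
at integer copy numbers, tolerance 1e-6, at most 500 iterations,
deterministic single-pass nearest-mean initialisation, SD floor 1e-4) is
fitted to the pooled segment medians of all cells. The deletion cutoff
is the point between the CN = 1 and CN = 2 component means where the
weighted densities are equal — the closed-form root of a quadratic; the
duplication cutoff likewise between CN = 2 and CN = 3. The phrase "the
two-tailed probability … was calculated" in the method's source is
ambiguous between this equal-density crossing and an equal-tail-mass
point; both are implemented (`method = "density"` is the default,
`"tailmass"` the alternative) — for well-separated components they are
close. When a flank component has weight below 1e-3 the data cannot
estimate that boundary and the configured defaults (1.63 for deletions,
2.43 for duplications — the published operating points) are used with a
warning. Segments below the deletion cutoff (provisionally homozygous
below copy number 0.5 — a gate for candidacy only, final arbitration is
the read-depth-ratio model) or above the duplication cutoff, spanning
more than `min_size = 1e6` bp, become raw calls.

## Allele model

Phase blocks are split into windows of 20–100 phased het-SNPs
(near-equal split targeting 100 per window; blocks under 20 SNPs yield
none). Per cell and window the haplotype-informative reads are summed
and two statistics formed:

* the **strict** ratio `log2(h1/h2)`, defined only when *each* haplotype
  exceeds 3 reads (the conservative reading of "larger than three"; the
  joint reading is available via `min_reads`). It is used where a
  defined, unbiased background is needed: classifier backgrounds and
  duplication assessment.
* the **pseudocount** ratio `log2((h1+0.5)/(h2+0.5))`, always defined,
  used for candidate-region medians — a true deletion drives one count
  to 0, exactly the case the strict form would discard.

Reads supporting neither phased allele do not arise in the bi-allelic
depth format; reads at SNPs outside any window are discarded and
tallied. Label symmetry (swapping hap1/hap2 flips signed ratios, leaves
absolute ones) is a tested invariant.

**Empirical p.** For each deletion call, the carrier's median
pseudocount |log2| over internal windows is ranked against the same
statistic in all cells without an overlapping deletion call; ties count
against the carrier and p = 0 is representable (no pseudocount on the
rank). Candidates pass at p < 0.05; the final rule re-uses the same
backgrounds at p < 0.01.

**Classifier.** The naive-Bayes step estimates one Gaussian per class —
candidates versus 100 size-matched random regions placed uniformly in
the same cells' autosomes outside candidate territory (seeded) — with
class priors from the group sizes, and scores the posterior of the CNV
class; validation requires posterior > 0.99. Estimation is supervised
(the training data are labeled by construction), not EM.

**Sparse-window filter.** A call is dropped when more than 75% of its
internal windows have fewer than 3 informative reads (strict inequality:
exactly 75% passes), or when it has no internal window.

**Homozygous deletions and duplications.** Homozygous candidates have no
allele signal, so they are arbitrated by the read-depth ratio against
bulk, `RDR_{b,i} = (C_{b,i}/B_b)(R_B/R_i)`; a two-component EM mixture
is trained on the mean RDR of LOH-validated heterozygous deletions plus
the homozygous candidates (initialised at 0 and 0.5), and a candidate is
retained at posterior > 0.99 for the low component. A candidate whose
posterior favours the heterozygous class *and* whose LOH profile matches
a heterozygous deletion (empirical p < 0.05) is reclassified rather than
discarded. With fewer than 5 candidates the mixture is not estimable and
a fixed RDR < 0.25 threshold applies, with a warning. Without bulk
counts a pseudo-bulk (column sums over cells) is substituted and
flagged. Duplications are compared against size-matched euploid regions
of the same cell by a one-tailed Welch test (gain of one copy is a 3:2
allele ratio — detectable at high window coverage, invisible at ~10
informative reads per window), and are reported but never enter the
final deletion set.

## Recurrence statistics

**Permutation null.** Each permutation re-places every cell's calls
uniformly at random, preserving call lengths and per-cell counts and
forbidding intra-cell overlap. Placement happens by default in
concatenated mappable coordinates (masked territory removed first, so a
placed call may straddle removed gaps when mapped back — as real calls
do); `mappable_space = FALSE` gives plain whole-genome placement. Note
one diagnostic consequence: under mappable-space placement every bin
holds the same mappable content, so permuted breakpoints per bin are
flat in bin width; the classical "breakpoints scale with bin size"
linearity appears under plain genomic placement, which is what
`breakpoint_clustering_test`'s slope report and its test use.

**Hotspots and cold spots.** Per 5 Mb region (contiguous tiling from
position 0, chromosome tails dropped), p is the fraction of permutations
with at least as many hits as observed (a call counts once per region it
overlaps). Hotspots: p < 0.05; cold spots: p > 0.99. The asymmetric
cold cutoff compensates for the liberal behaviour of discrete counts at
the lower extreme: the attained level of the hot rule sits just *below*
its cutoff, that of the cold rule just *above* — which is why the null
calibration test brackets the rates in bands around the nominal levels
rather than pinning them. Cold spots are merged (union semantics) and
screened against bad-bin/blacklist overlap using 1000 equal-length
random intervals outside cold territory; a spot in the upper 5% tail of
artifact overlap is removed (a flag inverts the direction for users who
read the rule the other way).

**Counts, karyotypes, breakpoints.** Per-cell CNV counts are compared to
`n_cells · Poisson(k; λ = n_calls/n_cells)` by chi-square with
upper-tail pooling to expected ≥ 5 and `df = max(classes − 2, 1)` (one
df for the estimated λ; the floor covers the degenerate two-class
case). Karyotype rows are the fraction of each autosome's bp deleted
(per-cell unions first, so nested homozygous calls are not
double-counted); cells above 5% genome-wide are complex; clustering is
agglomerative with Euclidean distance and average linkage by default,
rows pre-sorted by cell id for deterministic tie-breaking. Breakpoint
bins collect two breakpoints per call (the bins containing the first and
last base; boundaries in masked bins reassign to the nearest unmasked
bin and are flagged); bins with ≥ 2 are CNVBs, compared to permuted
CNVBs after dividing by bin width. CNVRs are calls sharing both boundary
*bins* (breakpoints are bin-resolution objects here); clonality takes,
per bin, max − min of the member cells' median signed pseudocount
ratios and the median over bins: the signed form is essential, since
opposite-haplotype events have opposite signs and separate at a delta of
about twice the single-cell LOH magnitude. The default threshold 5
reflects the observed bimodal separation; the delta distribution is
returned so users can re-derive it. Technical-replicate pairs (per-bin
CN correlation > 0.99 and identical call sets) are flagged so recurrence
statistics can count them once.

## The simulator

`simulate_dataset()` generates the complete input set with known truth.
Defaults encode the study conditions the pipeline targets: 200 cells on
two synthetic chromosomes (120 + 80 Mb), 500 kb-mappable bins, ~450
reads per bin per cell with lognormal per-cell depth factors
(`sdlog = 0.35`), lognormal per-bin amplification noise
(`amp_sigma = 0.12`) plus regionally correlated amplification bias
(`region_sigma = 0.08` over geometric blocks of mean 20 bins — WGA
over- or under-amplifies multi-megabase stretches coherently; without
this term segment medians would be unrealistically tight and read-depth
false positives impossible, which would make the LOH arbitration
pointless), phased het-SNPs at 1/kb in lognormal phase blocks (median a
few hundred kb, mean above 1 Mb), about 5 informative reads per
haplotype per 100-SNP window (`hap_cov = 0.05`), bulk coverage of 5000
reads per bin, and 50 planted heterozygous deletions of 2–20 Mb on
random haplotypes in random cells. These settings produce per-cell copy
number MADs around 0.2–0.3, the range real WGA QC operates in. Planted
events snap to bin boundaries by default (detection is bin-resolution
anyway, and snapping makes planted recurrence exact for CNVR tests).
Deterministic under a fixed seed.

What it does **not** emulate: GC bias (the pipeline hook for GC
correction is deliberately absent, as the calling stage never invokes
it), read-level artifacts (chimeras, barcode collisions beyond the
technical-replicate option), mapping errors that put reads on the wrong
haplotype, non-uniform SNP density, and population structure in phasing
errors. Passing tests therefore demonstrate the statistical machinery is
correct under the declared noise model, not that real-data performance
matches the simulated operating characteristics.

## Problem sizes in the tests

The suite exercises the full pipeline at 200 cells (the default study
condition) once, mid-size datasets of 25–80 cells elsewhere, 1000
permutations for segment tests and hotspot nulls, 10–20 seeds for
calibration experiments, and 200 random instances for the
segmentation-oracle comparison. The oracle comparison runs both routes
under a fixed critical value (`crit = 4.5`) so that two independent
implementations face a deterministic decision problem; the
permutation-acceptance path is tested separately, because two
independent permutation streams necessarily disagree with small
probability on splits whose true p value sits near α.

## Known limitations

* Validated sensitivity starts around 2 Mb at default noise; calls of
  1–2 Mb pass the size filter but few windows fall inside them, so the
  sparse-window filter removes many.
* Duplication validation is out of reach at ~10 informative reads per
  window; the assessment is reported only.
* The empirical p is bounded below by 1/n_background; with few cells the
  final p < 0.01 rule is unattainable (the pipeline warns below 50
  background cells).
* Phase-block extension assumes deletions tile the chromosome with
  overlaps of at least one well-covered block; conflicting votes leave
  blocks unresolved rather than guessing.
* The MAD cell filter assumes a roughly Gaussian noise profile across
  cells; a heavy-tailed population inflates σ and weakens the filter.
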