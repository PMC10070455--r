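---
title: "Methods: comparing 3D genome organization between paired conditions"
author: "rewire3d"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Methods: comparing 3D genome organization between paired conditions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rewire3d)
```

# Scope

`rewire3d` compares chromatin organization between two states of one genome
— a reference ("PR") and a rewired ("CR") condition — across four layers:
contact-map statistics, A/B compartments, loops/TADs, and copy number, with
a final gene-level evidence integration. Everything operates on binned,
intra-chromosomal data; read alignment, matrix generation from reads, and
inter-chromosomal contacts are out of scope. This vignette records the
models, the defaults that matter, and the numerical decisions, so that a
user knows exactly what each number means and what the validation on
synthetic data does and does not establish.

# The synthetic-data generator

## Generative model

One chromosome of `n_bins` bins at `resolution` bp. The expected contact
intensity between bins $i$ and $j$ is

$$
\lambda_{ij} \;=\; (1+|i-j|)^{-\alpha}
\; e^{\,\varepsilon\, s_i s_j}
\; T_{ij} \; L_{ij} \; c_i c_j ,
$$

where $\alpha$ is the power-law decay exponent, $s_i \in \{+1,-1\}$ is a
blockwise compartment sign (alternating blocks of `compartment_block_len`
bins), $T_{ij}$ multiplies within-TAD pixels by a boost factor, $L_{ij}$
multiplies single planted loop pixels, and $c_i$ is the per-bin copy ratio
(1 everywhere in PR). The matrix is scaled so the expected upper-triangle
total equals `depth` and sampled as independent Poisson counts, mirrored to
symmetry. The rewired condition flips the sign of a chosen fraction of
compartment blocks, adds/removes loops, splits TADs, and applies copy
ratios; coverage tracks are Poisson with mean `mean_depth * c_i`, so a copy
ratio of 2 shifts the log2 coverage ratio by +1 while multiplying contacts
by $c_i c_j$. Expression tables couple each gene's log2 fold change to its
bin's compartment sign change and CNV log2 ratio plus Gaussian noise, with
p-values from the exact z-test against that noise SD.

## Default study conditions and why

* `decay_exponent = 1` — the canonical contact-decay slope in the
  0.1–10 Mb range.
* `compartment_block_len = 20` bins at 50 kb = 1 Mb checkerboard blocks,
  the typical compartment domain scale; blockwise-constant signs make
  switch truth unambiguous at block resolution.
* `compartment_effect = 0.4` gives a same-state/cross-state contact ratio
  of $e^{0.8} \approx 2.2$, comparable to saddle-corner enrichments in
  deeply sequenced maps.
* `depth = 10^6` contacts per chromosome — a desk-scale budget at which
  every stage is still identifiable (see the power note below).
* Planted loops: 3× focal boosts, 150–250 kb span, placed *within* a
  compartment block. Loops connect same-state loci; at depth $10^6$ a 3×
  boost on a cross-state background or at spans ≳ 500 kb leaves single-pixel
  Poisson evidence below any genome-wide FDR threshold, so those conditions
  are not a fair test of any caller. This is a property of counting
  statistics, not of the implementation.
* Poisson (not negative-binomial) counts: the simplest noise model
  preserving the mean structure. Real Hi-C is overdispersed; consequences
  are discussed under *Limitations*.

## What the generator does not emulate

Restriction-fragment geometry, read-level artifacts, replicate batch
effects, visibility (mappability/GC) biases of real bins, trans contacts,
and overdispersion. Passing the planted-truth tests therefore demonstrates
correctness of the algorithms under a clean noise model — not performance
on real libraries, where balancing and the local loop filters have more
work to do.

# Contact-map statistics

**Balancing.** VC divides each entry by the product of its bin sums and
rescales to preserve the total; ICE iterates proportional fitting until the
coefficient of variation of unmasked bin sums drops below `tol` (default
$10^{-4}$, 200 iterations max, error on non-convergence). Zero-coverage
bins plus the bottom 2% of positive bin sums are masked first (standard
low-coverage practice; the threshold is strict so a constant matrix masks
nothing). Both methods store per-bin weights such that
`balanced * w_i * w_j` reconstructs the raw counts exactly — downstream
Poisson reasoning depends on this.

**Decay.** `decay_curve()` averages contacts per log-spaced distance
stratum (factor 1.3 by default; factor 1 keeps every distance separate).
The differential curve is `log2((a+pc)/(b+pc))` with the pseudocount
defaulting to the smallest positive stratum mean — published differential
decay plots rarely state their pseudocount, so ours is documented rather
than claimed to match any. Power-law exponents come from least squares of `log10` value on
`log10` distance; at least 5 positive strata are required.

**Reproducibility.** The SCC smooths both matrices with a mean filter
(half-window 1 bin by default), computes per-distance Pearson correlations
up to 5 Mb, and averages them with weights $N_d\sqrt{v_a v_d}$.
Zero-variance strata are skipped with a warning. MDS of `1 − SCC` uses
classical scaling with sign fixed so the first sample's coordinates are
non-negative.

# Compartments

**Calling.** The map is distance-normalized (each diagonal divided by its
mean), converted to a correlation matrix over unmasked bins, and
eigendecomposed. Among the first 3 eigenvectors, the one with the largest
absolute correlation with gene density wins; GC content breaks near-ties
(margin 0.02). The sign is flipped so the gene-density correlation is
positive (A = positive). If no component reaches |r| = 0.1 the orientation
is declared ambiguous and an error is raised — a pipeline must replace
manual inspection with a deterministic rule, and silently guessing would be
worse than failing.

**Saddle and strengths.** Bins are ranked into 50 equal-size percentile
groups (ties broken by position); cell $(g,h)$ is `log2` of the mean O/E
over the group pair. Corner strengths average the top/bottom 20% of groups
and return to the ratio scale; the compartmentalization score is
`log2(AA*BB/AB^2)` — base 2 for consistency with log2 heatmaps; the base is
an argument because the formula is sometimes quoted without one.

**Differential testing.** Scores are quantile-normalized across samples
(reference = mean of sorted vectors, ties averaged). The per-bin squared
Mahalanobis distance of the between-condition mean difference is taken
against the pooled replicate variance (all bins, both conditions), with a
chi-square p-value at 1 degree of freedom — the score difference is scalar;
the exact d.f. used by the method the analysis descends from is unpublished
for two conditions, so our choice is validated by null calibration (type-I
error 0.03–0.07 at nominal 0.05 in the acceptance suite) rather than
claimed identical. Zero replicate variance triggers a documented ridge
($10^{-8}$) with a warning. Significance defaults to FDR < 0.3, the
threshold conventional for this analysis. Switch classes come from
condition sign pairs; fractions are reported over all classified bins and
over significant bins only, and adjacent significant same-class bins are
merged into regions before genes are counted (a gene may count in several
classes; active = AA + BA, inactive = BB + AB).

# Loops and TADs

**Loop calling.** Tested pixels lie in a distance band (defaults 2 bins to
the whole map; analyses here use ≤ 2 Mb, the short-range scale where the
rewiring signal concentrates). Four local backgrounds are estimated around
each pixel — donut ring, 3-wide horizontal and vertical stripes, and the
lower-left quadrant, all with Chebyshev radius 5 and the central 3×3
excluded, restricted to cells at distance ≥ 2 from the diagonal. The
enrichment ratios are estimated on the *raw-count* O/E surface
(reconstructed through the balancing weights): estimating them on balanced
values biases the background near compartment-block boundaries because
weights differ across blocks, and Poisson-testing balanced values is
anti-conservative wherever weights are below 1. The pixel's expectation is
the most demanding of the four backgrounds times the global distance
expectation; the p-value is the Poisson upper tail on raw counts,
Benjamini–Hochberg corrected across all tested pixels, thresholded at FDR
0.05 (and p < 0.1 upstream), and reduced by non-maximum suppression within
the donut radius. This is a documented local-enrichment caller validated on
planted truth — not a re-implementation of any published multi-scale
caller.

**Set algebra.** Loops match when both anchors lie within a one-bin flank
— implemented as *gap strictly smaller than the flank*. The flank could be
read as symmetric expansion of both intervals, but the definitional
examples (a two-bin offset must *not* match at a one-bin flank) pin down
the stricter reading. Matching is greedy one-to-one in input order, so
common counts partition both input totals. Anchors are pooled, reduced
(abutting anchors merge), and a merged region is common exactly when it
captures anchors from loops of both conditions under the same flank rule;
excluded regions (user-supplied BED) are removed before merging.

**APA.** Mean O/E submatrix over loop pixels; strength = center over the
mean of the lower-left corner quadrant (3×3 by default) — the
short-distance side, which is the conservative background. Near-diagonal
windows use the mirrored triangle, which is valid for symmetric matrices.

**Insulation.** Per-bin `log2` of the mean contact in the `w×w` square
straddling the bin over the chromosome mean of such squares (w = 5 bins by
default). Boundaries are local minima with prominence (smaller of the two
flanking maximal rises within the search window) at least
`delta_threshold`, thinned greedily by prominence under a minimum
separation. The insulation window and threshold used by published analyses
are rarely reported; both are exposed as arguments.

**CTCF.** Anchors are classed `multiple`/`single` by motif count;
zero-motif anchors are expanded by one bin and re-tested
(`adjacent-only`/`none`). Loop convergence uses the motif nearest each
anchor midpoint (documented tiebreak when strands conflict): `+`/`−` =
convergent, equal = tandem, `−`/`+` = divergent, one side = one-sided.

**Permutation enrichment.** The null circularly shifts all query regions
by one common offset within the chromosome universe, preserving their
length and spacing structure (unconstrained resampling would not); regions
crossing the origin wrap as two arcs. Empirical p is
`(1 + #{null ≥ obs}) / (1 + n_perm)`; because near-zero offsets reproduce
the observed configuration, the theoretical floor is approached but not
always attained at maximal overlap. An empty reference yields "depleted",
not an error.

# Copy number

**CBS.** Circular binary segmentation maximizes the two-sample t statistic
over all arcs (the scan is `O(n²)` but reduces to one vector pass per arc
length since the statistic is monotone in the drift-corrected cumulative
sum difference), accepts a split when its permutation p-value beats
`alpha`, and recurses. Permutations stop early once the exceedance count
guarantees p > alpha, which makes flat segments cheap. Segment classes use
mean thresholds ±0.3 — unreported in comparable analyses, exposed as
arguments. Length-weighted segment means reconstruct the track mean by
construction.

**Consensus SV.** Calls below 5 supporting read pairs are dropped; the
rest are pooled in genomic order and clustered greedily — a call joins the
first cluster whose *founding* call has the same type and both breakpoints
within the type window (1 kb translocations, 500 bp otherwise). Multi-way
cluster resolution is not defined by pairwise-overlap tooling, so the
first-match tiebreak is our documented choice, checked against a
brute-force matcher. Consensus requires ≥ 2 distinct callers and reports
median coordinates. Condition-specific calls use the same window rules
cross-condition. Gene CNV classes take the maximal-overlap segment;
genome-wide deleted/duplicated totals are summed segment lengths with
percentages of the supplied genome size. Both the segmentation path and the
consensus-SV path can feed the totals — which one a published figure used
is ambiguous, so both are available.

# Integration

Rankings: `sign(log2FC) * −log10(p)` (p = 1 maps to 0), log2 coverage
difference × mean coverage, or CR − PR compartment score at the gene's
maximal-overlap bin. The 1-SD filter removes genes with |change| below one
SD of either distribution before Pearson correlation — note that with two
independent 1-SD filters only ~10% of genes survive, so correlations are
computed on far fewer genes than supplied. Preranked GSEA uses the classic
weighted running sum (weight exponent 1), gene-label permutations for the
sign-matched p and NES, and a permutation-ratio FDR; the installed
independent implementation is used in the test suite only to cross-check
the enrichment score, never as the computation path. The importance score
sums five equally weighted binary flags per gene — upregulated (DE FDR
< 0.1), CNV gain, significant switch to active (AA/BA at compartment FDR
< 0.3), CR-specific loop-anchor overlap, CR-specific TAD-boundary overlap
(loop calls at FDR < 0.05) — with every direction mirrored for the PR
score; genes with ≥ 4 flags are selected. Overlap for every flag is ≥ 1 bp
of the gene body; a promoter-window alternative is deliberately left out
of the default path. Equal weights follow the plain-sum definition; the
split of copy-number evidence into two separate flags is possible by
passing a stricter `cnv` table but is off by default.

# Problem sizes and validation

The test suite and the acceptance script run, by design, at desk scale:
2,000-bin chromosomes (100 Mb at 50 kb) at depth $10^6$ for parameter
recovery; 200-replicate null panels for the four resampling statistics;
50-seed brute-force oracle comparisons for the set algebra. At these sizes
the whole suite completes in a few minutes on one CPU. The recovery results
— ≥ 95% compartment sign agreement, loop recall/precision ≥ 0.9 at FDR
0.05, CBS breakpoints within ±2 bins, decay exponent within ±0.15 —
characterize the implementation under the generator's clean Poisson model
and say nothing quantitative about real libraries.

# Known limitations

* Poisson counts understate real Hi-C dispersion; on real data the loop
  caller's p-values will be anti-conservative and should be read jointly
  with the enrichment column (or refit with an overdispersed null).
* Single-chromosome scope: multi-chromosome analyses are lists of
  independent per-chromosome runs; trans contacts are ignored.
* The differential-compartment covariance is pooled across bins; bin-level
  heteroscedasticity (e.g. copy-number-driven) is not modeled.
* The permutation null preserves query structure only up to circular
  shifts; highly clustered references can make it coarse at small
  `n_perm`.
* No bundled excludable-region list: blocklists are genome-specific inputs.
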