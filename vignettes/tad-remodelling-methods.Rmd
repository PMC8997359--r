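---
title: "Methods: comparing TAD borders, loops and compartments across Hi-C conditions"
author: "tadremodel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing TAD borders, loops and compartments across Hi-C conditions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`tadremodel` compares chromatin architecture between a wild-type Hi-C
experiment and one or more knockdowns of architectural proteins (the
motivating system is *Drosophila* BG3 cells depleted of BEAF-32, Cp190 or
Chromator). Three layers of organisation are analysed — TAD borders,
chromatin loops and A/B compartments — and border reorganisation is linked
to differential gene expression by permutation testing. Because the
package's correctness cannot be judged against deposited sequencing data at
test time, every analysis is exercised on synthetic contact maps with
planted, machine-readable ground truth; the generator is a first-class,
tested part of the package.

# The contact-matrix layer

A matrix is a BED-like bin table plus an upper-triangle pixel list; bins are
0-based half-open, either uniform or restriction-fragment-like
(`digest_genome()` places cut sites at motif hits, absorbs fragments shorter
than 150 bp into the following fragment and splits fragments longer than
1000 bp into equal pieces — both bounds are arguments).

**Balancing.** `balance()` is iterative proportional fitting (ICE): weights
$b_i$ are updated by the ratio of each bin's corrected marginal to the mean
marginal until the coefficient of variation of marginals falls below `tol`
(default $5\times10^{-3}$, reached in well under the default 500
iterations on the simulations used here). Marginals are equalised *within*
each chromosome: with purely intra-chromosomal pixels the chromosomes are
disconnected components and a genome-wide mean would never converge. Only
zero-marginal bins are masked by default. An optional percentile mask
(`mask_percentile`) is available for artefact-laden real libraries, but it
is off by default: strong TAD borders are themselves low-marginal bins, and
on clean simulated maps a 2nd-percentile cut removes almost exactly the
border-adjacent bins — the objects under study.

**Observed/expected.** The expected count at offset $d$ is the mean
corrected count over all intra-chromosomal pairs at that offset (zeros
included, masked bins excluded), so a featureless decay map has O/E $=1$
everywhere and the transform is idempotent in ratio space.

**Per-pixel log2 fold change** between conditions aggregates both matrices
to a common resolution (default 5 kb) and reports
$\log_2\frac{a+1}{s_a}-\log_2\frac{b+1}{s_b}$ with library-size factors
$s$. This is a deliberate simplification of a dispersion-modelling
differential framework; it is used for map display, not inference.

# Insulation and borders

The TAD-separation score of bin $b$ for window $w$ (bins) is the mean
corrected count of the $w\times w$ diamond between the $w$ bins upstream
and the $w$ bins downstream. Per-window tracks are z-scored per chromosome
and averaged over the window set (default 10, 20, 30 kb, converted to bins
by the median bin width with a floor of two bins). Two numerical choices
matter on fine bin tables and are defaults rather than dogma:

* the averaged track is smoothed with a 5-bin running mean
  (`smooth_bins`); single-bin Poisson noise otherwise creates spurious
  local minima that pass any fixed delta threshold, because the z-scored
  scale makes a 0.04 delta small against shot noise;
* a masked neighbour voids only the windows it touches — the score
  averages over the windows that remain defined.

`call_borders()` takes local minima as candidates; `delta` is the mean of
the two flanking local maxima minus the minimum, thresholded at 0.04
(weak) and 0.08 (strong). Significance is a one-sided rank-sum test of the
inter-domain diamond against the two flanking intra-domain triangles,
computed on O/E values — on raw counts the diamond sits at systematically
larger distances than the triangles and distance decay alone makes every
candidate "significant". P-values are BH-adjusted (kept at ≤ 0.01) and
borders closer than 5 kb are resolved by keeping the larger delta. The
reported border position is refined below bin resolution by a least-squares
parabola through the minimum and up to two neighbours per side (clamped to
one bin); cross-condition matching at sub-bin tolerances depends on this.

**Robustness and classification.** A border is robust if a border of the
same strength class lies within 2 kb after 20% binomial down-sampling.
Against a knockdown, each WT strong border is assigned, in order of
precedence: *maintained* (knockdown strong border within `same_tol`),
*weakened* (weak border within `same_tol`), *fuzzy* (any border within
2 kb, shift recorded), else *lost*; knockdown strong borders with no WT
strong border within 2 kb are *new*. Matching is greedy by distance with
leftmost tie-break, and each knockdown border is consumed once. `same_tol`
defaults to 600 bp — positional identity must be stricter than the 2-kb
fuzzy tolerance, and 600 bp corresponds to one fragment-scale bin; the
sub-bin interpolation is what makes this usable on uniform tables coarser
than 600 bp. Statuses partition the WT strong set by construction, an
invariant the tests assert.

# Loops

`call_loops()` is a donut-filter caller at fixed resolution (default
2 kb): for every candidate pixel four local expectations (donut,
horizontal and vertical strips, lower-left quadrant; window 10 bins, peak
half-width 5) are formed as the neighbourhood's observed/expected ratio
mapped back to the pixel's decay level. Significance is a Poisson upper
tail on the raw count with the expectation mapped through the balancing
weights, BH-adjusted per filter at FDR 0.05, with fold-enrichment floors
of 1.75 (donut, lower-left) and 1.5 (strips). Significant pixels within
20 kb (Chebyshev) merge to the most significant pixel; merged clusters
must reach adjusted p ≤ 0.02, and singletons need 2× enrichment over the
donut and lower-left. Candidates are restricted to pixels whose donut fits
above the diagonal (separation > 2 windows). Compared to the original
lambda-chunked implementation of this approach, direct Poisson p-values
are used; this is documented as a deviation and calibrates cleanly on null
simulations. Cross-condition comparison matches anchors within one bin
(2 kb): both anchors → maintained, one → partially maintained, none →
lost. APA averages O/E submatrices (half-width 15 bins) around loop
pixels; the centre score divides the centre by the mean of a lower-left
corner block.

# Compartments

Eigenvectors are computed per chromosome from the Pearson correlation
matrix of the O/E map (masked bins dropped pairwise; chromosomes with
fewer than 20 usable bins, or listed in `exclude` — by default the small
chromosomes 4 and Y — are masked), oriented so the eigenvector correlates
positively with GC content; positive bins are A. The saddle ranks bins by
eigenvector into 30 percentile groups after trimming to the [2.5%, 97.5%]
interval. The grid cell is the mean intra-chromosomal **O/E value** between
groups, and strength is mean(AA, BB corners)/mean(AB, BA corners) on
10×10 corners of the non-normalised grid. Using O/E rather than
correlation values for the grid is a deliberate design choice: a
correlation substrate makes the strength a quotient of near-zero means on
an uncompartmentalised map, where this definition correctly gives
strength ≈ 1. Any cross-condition display normalisation is applied at
render time only, never to the statistic. A small (~3%) downward bias of
the null strength remains because the eigenvector is itself estimated from
the same map — selecting extreme-eigenvector bins selects against their
direct mutual contacts; this is visible in the acceptance output
(`saddle_strength_null` ≈ 0.96–0.98) and is well inside the ±5% band the
tests require.

# Expression association

The genome is split at the union of WT and knockdown border positions and
each segment inherits a class from the displacement of its WT TAD's two
borders (distance to the nearest knockdown border). The published rule set
leaves gaps (a border moved by more than the identity tolerance but within
2 kb, paired with an unmoved border); the package closes them by counting
large moves (> 2 kb): two → `kd_specific`, one → `conserved_one`, zero
with both within `same_tol` → `conserved_two`, else `fuzzy`. Segments
outside any WT TAD are `unassigned` and excluded.

`permutation_overlap_test()` redraws each query region's start uniformly
within its chromosome's universe segments, preserving widths, chromosome
and count (a regioneR-style randomisation; no installed R implementation
was available, so it is authored here with a vectorised single-segment fast
path). The p-value is $(1+\#\{null \ge obs\})/(1+N)$, so it can never be
zero and equals 1 when targets cover the universe. The universe should be
the region genes can occupy — in the shipped analyses, the span between
the first and last WT border; including telomere-like flanks that carry
targets but can never carry genes makes the test anticonservative.
Housekeeping genes are those in the top `percentile`% (default 40, i.e. at
or above each sample's 60th percentile — the stricter of the two possible
readings) in **every** sample.

# Track analysis

Border-centred heat maps extract 50 columns of 100 bp across a 5-kb
window. Winsorisation dialects: *chip* clips at the 5% quantile of
negative and 95% of positive values and scales positives to (0, 1];
*dnase* uses 0 and the 75% positive quantile; *nascent* additionally
scales negatives to [−1, 0). Degenerate inputs (no negatives, constant
tracks) fall back to cut-offs 0 and the maximum. Occupancy clustering
compares the quartiles of the raw per-column signal in each window with a
cut-off equal to the median of positive window sums pooled across all
datasets — always recomputed, never hard-coded, since it is a property of
the input collection. The strict published inequalities leave zeros and
exact-cut-off values unclassified; zeros fall through to `low` and values
at the cut-off go to the lower class. The pausing index is the mean signal
over the promoter (−200..+50 of the TSS) divided by the gene body (−50 to
the gene end), strand-aware; non-positive indices are discarded. PWM sites
are counted on both strands at a relative-score threshold
$s \ge s_{min} + f\,(s_{max}-s_{min})$ (default $f=0.85$); windows with
ambiguous bases are skipped, overlapping sites all count, and the scanner
is checked against a per-window brute force.

# The synthetic generator

Expected intensity is a product of: power-law decay $(1+d)^{-\alpha}$
(default $\alpha = 1$, a typical Hi-C exponent); a TAD term in which a
cross-border contact is attenuated by the **strongest single border**
crossed (fold reduction = that border's depth) — attenuating by every
intervening border would suppress long-range contacts geometrically and
erase the compartment checkerboard, which lives at long range; a
checkerboard factor $f$ for same-compartment pairs; and 2-D Gaussian loop
bumps ($\sigma = 1$ bin). The map is scaled to an expected total `depth`
and counts are Poisson. Counts are drawn by inversion —
`qpois(runif(n), lambda)` — exactly one uniform per pixel, so an edited
condition regenerated under the same seed shares the noise of every
unedited pixel; `rpois` consumes a variable number of draws per pixel and
would decorrelate the pair downstream of the first edit. Condition pairs
also share the WT intensity scale, so edits change only the edited
structure, not the global coverage. The GC covariate is
$0.4 + 0.1\,[A] + \mathcal N(0, 0.02)$, guaranteeing correct eigenvector
orientation in expectation.

Study-condition defaults: border recovery uses a 5-Mb chromosome at 5-kb
bins with $10^6$ contacts and 15 borders of depth 3 (the depth is the
planted cross/within contact ratio, verified directly); classification
uses 500-bp bins (fragment-scale, where a 1.5-kb fuzzy shift spans three
bins) on a 1.5-Mb chromosome at $4\times10^6$ contacts; loops use 2-kb
bins on 1 Mb at $2\times10^6$ contacts with 5× enrichment; compartments
use 10-kb bins on 5 Mb with 100-kb blocks. These sizes keep the full suite
and the acceptance script to a few minutes while leaving every statistic
comfortably identified.

What the generator does **not** emulate: mappability and GC biases beyond a
planted smooth bias (balancing is tested by planting a known bias vector
separately), translocations and copy-number structure, nested TAD
hierarchies, unbalanced chromatin marks, or read-level artefacts
(duplicates, religation). Passing tests therefore demonstrate algorithmic
correctness and calibration on idealised maps, not robustness to every
real-library pathology — the percentile mask and the configurable window
schedule are the knobs a real analysis would revisit.

# Orchestration

`run_pipeline()` drives the full WT-versus-knockdown comparison from a
single YAML/list configuration carrying all seeds (every stochastic stage
requires an explicit seed; unknown keys are rejected) and writes
BED/bedGraph/BEDPE/TSV outputs plus a `summary.json` stamped with the
configuration hash. One knockdown's failure is caught and reported without
aborting the others. The numbered scripts under `analysis/` present the
same computation as a stepwise narrative and write their tables under
`results/`.

# Known limitations

* Fuzzy (≤ 2 kb) displacement detection is only meaningful when bins are
  substantially finer than 2 kb; at 2-kb bins a 1.5-kb shift is sub-bin
  and usually indistinguishable from maintained.
* The null saddle strength carries the small selection bias described
  above.
* The loop caller assumes uniform bins at the calling resolution; fragment
  tables must be aggregated first.
* Compartment-block edges insulate by construction, so on maps that
  combine compartments and TADs the border ledger legitimately contains
  compartment-edge borders alongside planted TAD borders.
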