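# tadremodel

Comparative analysis of chromatin architecture between Hi-C conditions:
what happens to TAD borders, chromatin loops and A/B compartments when
architectural proteins (BEAF-32, Cp190, Chromator in *Drosophila* BG3
cells are the motivating system) are depleted, and whether the genes that
change expression sit in the reorganised TADs.

It is written for computational biologists who have binned Hi-C contact
matrices per condition (plus, optionally, ChIP peak sets, signal tracks,
gene models and DEG tables) and want a tested, reproducible version of the
comparison workflow — and for method developers, who get a synthetic-data
generator that plants TADs, loops, compartments and expression effects
with machine-readable ground truth, so every stage can be validated
against planted truth rather than eyeballed.

## What it computes

* **Insulation / TAD-separation score.** For bin *b* and window *w*, the
  mean corrected count in the *w*×*w* diamond between the *w* bins up- and
  downstream; per-window tracks are z-scored per chromosome and averaged
  (windows 10/20/30 kb by default). Borders are local minima with
  prominence δ = mean(flanking maxima) − minimum, called weak at δ ≥ 0.04
  and strong at δ ≥ 0.08, filtered by a one-sided rank-sum test of the
  inter-domain diamond against the flanking intra-domain triangles on
  observed/expected values (BH ≤ 0.01), with ≥ 5-kb TADs.
* **Border robustness and status.** Robust = recovered after 20% binomial
  down-sampling. Against a knockdown each WT strong border becomes
  maintained / weakened / fuzzy (moved ≤ 2 kb) / lost; unmatched knockdown
  strong borders are new; two knockdowns can be intersected, and borders
  are annotated as "direct" when a ChIP peak lies within the 5-kb window.
* **Loops.** Donut-filter calling at 2-kb bins (FDR 0.05, window 10, peak
  width 5, enrichment floors 1.75/1.5, 20-kb merge), maintained / partial /
  lost anchor comparison, aggregate peak analysis (APA) with a centre
  score, promoter/enhancer/gene/other anchor annotation and DEG fractions
  at maintained versus lost loops (Fisher exact).
* **Compartments.** Leading eigenvector of the per-chromosome O/E
  correlation matrix at 10-kb bins, sign-oriented by GC; A/B switch
  fractions; 30-group saddle grids and compartmentalisation strength
  (homotypic over heterotypic corner means).
* **Expression association.** Genome segments classed by the fate of their
  TAD's borders; a regioneR-style 1000-permutation overlap test of DEG
  positions against reorganised TADs; housekeeping calling (top-40% band
  in every sample); a check that DE genes do not span robust borders.
* **Occupancy.** Border-centred heat maps with assay-specific
  winsorisation dialects, rule-based occupancy clustering, Pol II pausing
  indices, and PWM site counts at a 0.85 relative-score threshold.
* **Synthetic data.** `simulate_matrix()` /`simulate_condition_pair()` /
  `simulate_tracks()` / `simulate_expression()` plant all of the above
  with ground truth; condition pairs share the noise of every unedited
  pixel, so scripted edits (delete / shift / weaken a border, delete a
  loop) are the only differences between conditions.

## Worked example

The shipped demonstration configuration
(`inst/extdata/demo_config.yaml`) simulates a 4-Mb chromosome at 2-kb bins
with 12 planted borders, 4 loops and 200-kb compartments, plus two
scripted knockdowns:

```r
library(tadremodel)
cfg <- system.file("extdata", "demo_config.yaml", package = "tadremodel")
summary <- run_pipeline(cfg, "demo_run")
```

The run finishes in about a minute and `demo_run/summary.json` reports,
among other things:

```
wt: n_robust_borders 29 (strong 29), n_loops 5, saddle_strength 1.72
kd_single: border_status maintained 26 / lost 3 / new 1,
           loop_status maintained 4 / lost 1, switch_fraction 0
kd_double: border_status maintained 27 / lost 2,
           loop_status maintained 4 / lost 1, switch_fraction 0
```

Reading: the two scripted border deletions plus the 10-kb relocation
surface as lost (and one new) borders; the deleted loop in each knockdown
is the lost loop; compartments do not switch (the knockdowns leave them
untouched); and the WT ledger contains the 12 planted TAD borders plus
compartment-block edges, which insulate by construction. The border count
in each status partitions the WT strong set — an invariant the test suite
asserts.

The same computation is presented as a stepwise narrative in
`analysis/01_simulate.R` … `analysis/06_occupancy.R`, which write their
tables under `results/`. Step 5, for example, prints

```
DEGs in reorganised TADs: observed 9, p = 0.02398, z = 2.22
```

— the planted 5:1 DEG odds in reorganised TADs are recovered as a
significant permutation-test enrichment.

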