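---
title: "Methods: the candidate-gene screen and the image quantifications"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the candidate-gene screen and the image quantifications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtocscreen)
```

This vignette explains the models and procedures the package implements,
the parameters that matter, what the synthetic generators do and do not
emulate, and the design decisions taken where the underlying protocol left
the choice open.

## The candidate-gene screen

The screen nominates transcription-factor target genes that may mediate
nuclear-envelope MTOC formation. It is a conjunction of four filters, each
deliberately simple and strict, applied in sequence
(`screen_peaks()` → `rnaseq_upregulated()` → `heart_upregulated()` →
`go_filter()`, orchestrated by `run_cascade()`).

### Promoter binding and persistence

A gene is promoter-bound at a time point if some peak in that time point's
narrowPeak track satisfies both:

* significance: $-\log_{10} p > 5$ (narrowPeak column 8), i.e. $p < 10^{-5}$,
  strict;
* proximity: the peak anchor lies within 1000 bp (inclusive) of the gene's
  TSS.

The **anchor** is the summit (`start + summit_offset`, column 10) when the
peak caller reported one, else the floored interval midpoint. Peak-to-gene
annotation tools differ in this choice (peak start, midpoint, summit); the
summit is the single point best supported by the data, so it is the
default, and it is recorded in the output `params` so a run is
interpretable afterwards. Replicating a historical gene list produced with
a different anchor convention may require matching that convention.

Coordinates are 0-based half-open throughout; the TSS is `start` for `+`
genes and `end - 1` for `-` genes. When a gene table carries several rows
per gene (transcripts), the gene qualifies if *any* of its TSSs does.
Peaks on contigs absent from the gene table are ignored. The inclusive
distance bound means a summit at exactly 1000 bp qualifies; ties in the
significance filter fail (exactly $10^{-5}$ is not below $10^{-5}$).

Persistence is plain set intersection over the required time-point labels
(default 24 h, 60 h, 7 d of differentiation); other tracks, such as
undifferentiated myoblasts, are parsed but do not constrain the
intersection. The rationale is biological: an MTOC-maintenance gene should
stay bound while differentiated cells persist, so early-only binding is
treated as a decoy.

### RNA-seq upregulation

A gene passes when fold change is positive and $p < 0.05$ in both
differentiation contrasts. Only the *sign* of the fold-change column is
used, so log2 and linear fold changes are interchangeable; the p-values are
taken as provided by the upstream DE analysis (no re-testing, no
multiplicity correction — the filter reproduces the screening rule, it does
not improve on it). All comparisons are strict, so $p = 0.05$ fails.

### Developmental time-course upregulation

The third filter asks whether a gene rises across a developmental time
course (e.g. heart development across the window in which cardiomyocytes
assemble a nuclear-envelope MTOC). Two criteria are conjoined:

1. **Differential expression** by an area statistic. With per-timepoint
   mean profile $x_t$ and initial value $x_0$, the statistic is the
   trapezoidal integral of $\lvert x(t) - x_0 \rvert$ over time — the total
   area between the profile and the constant profile pinned at the initial
   level. It is zero iff the mean profile never leaves its initial value,
   invariant under adding a constant to the whole profile, and linear in
   the magnitude of deviations. Significance comes from a within-gene
   permutation null: all replicate values of the gene are pooled and
   reassigned to time-point slots uniformly at random `n_null` times
   (default 1000), and the gene is called differential iff the observed
   statistic strictly exceeds the empirical $1-\alpha$ quantile (type 7) of
   the permuted statistics. The null's exchangeability assumption is
   exactly the "constant profile" hypothesis the statistic is designed
   against. The procedure published for this kind of microarray screen
   states the area comparison but not the null; the permutation null is
   this package's choice because it is assumption-light and fully
   testable — its type-I rate is checked by simulation in the test suite.
   A zero-variance flat profile yields statistic 0 against an all-zero
   null and is (correctly) never called differential, because the
   exceedance is strict.
2. **Upregulation**: $\max_t x_t - x_0 > x_0 - \min_t x_t$, strict, on the
   mean profile. Ties — including flat profiles and profiles that fall as
   much as they rise — fail. This orients the filter: monotone-down genes
   are often strongly "differential" under the area statistic but are not
   candidates.

The permutation test needs replicate data (≥ 2 per time point); with a
single replicate it refuses to run rather than silently degrade.

### GO filter

Gene Ontology matching is by cellular-component **term name**, exact after
case-folding and whitespace trimming, against the search terms
"nuclear membrane" and "nuclear envelope". No ontology-graph descendant
expansion is performed: the rule models a plain search-term match, not a
closure query, so e.g. "nuclear pore" does not match. Genes absent from
the annotation map are dropped. If an analysis needs closure semantics,
pass the expanded term set explicitly via `terms`.

### Scope of the cascade

The time-course filter is evaluated inside the ChIP ∩ RNA-seq
intersection (that is the cascade's meaning, and it avoids thousands of
irrelevant permutation tests); the reported counts therefore satisfy
`go_matched ≤ heart_up ≤ intersection ≤ min(persistent, rnaseq_up)` by
construction, and the test suite asserts the chain on random fixtures.
Reproducing the genome-scale counts of the original public-data screen
requires the full GSE36024/GSE84158 downloads and an Ensembl release 67
TSS table; `inst/scripts/reproduce_geo_cascade.R` documents that run. The
developmental microarray lacks a public accession and GO term membership
moves between releases, so the two final stages of the historical gene
list are not reproducible bit-for-bit from public inputs; the package's
guarantees are instead stated — and tested — on planted synthetic truth.

## The genomic fixture generators

`make_gene_models()` places genes with ≥ 10 kb TSS spacing on a synthetic
chromosome so that 1-kb promoter windows cannot collide and every planted
peak is attributable to exactly one gene. `make_peak_files()` writes valid
BED6+4 narrowPeak files and *always* plants decoy classes alongside the
requested qualifying peaks: distal peaks (summit 1.5–4 kb from a TSS, well
inside the 10-kb spacing so they cannot drift into a neighbour's window),
sub-threshold peaks ($-\log_{10} p \in [3, 4.9]$ at the TSS), and
wrong-time-point binding via the per-timepoint request. This matters for
test honesty: if any filter were dropped, planted-truth recovery would
fail, so passing tests certify each filter is active, not vacuous.
`make_de_table()` splits non-upregulated genes among three decoy classes
that each fail exactly one condition (down in both contrasts, up in one
contrast only, positive but non-significant). `make_time_courses()` plants
monotone-up profiles with a rise of at least $5\sigma$ of the noise (floor
2 expression units), with flat and monotone-down decoys. Defaults are
noise-free so recovery is exact; tests that exercise noise set
`noise_sd > 0` explicitly.

Generated files are byte-identical under a fixed seed, and
`make_screen_fixture()` re-runs the real pipeline at generation time in
noise-free mode and refuses to return a self-inconsistent fixture.

## The imaging procedures

### Segmentation

`segment_nuclei()` is intentionally plain: threshold (explicit value, or
Otsu under `"auto"`), hole filling, connected components, minimum area
20 µm². The reference protocol segmented nuclei manually; automated
watershed splitting is out of scope, so touching nuclei merge into one
component — the documented limitation — and the per-ROI area and
eccentricity are reported so callers can exclude merged objects. On the
package's synthetic scenes (non-overlapping ellipses), segmented centroids
land within a pixel of the planted centers.

### Envelope bands and coverage

A band of width $w$ (default 1 µm) around an outline is the set of pixels
whose center lies within $w/2$ of the outline polygon — exact
point-to-segment distances, not a rasterized approximation, so the band
area of a circular outline of radius $r$ matches the analytic annulus
$\pi\left[(r+w/2)^2 - (r-w/2)^2\right]$ to better than 3 % at 0.1 µm/px.
The band straddles the outline symmetrically by default because the
underlying protocol does not state whether its 1-µm bands sat inside or
outside the DAPI outline; `align = "outer"`/`"inner"` give one-sided bands
(these change absolute coverage but not group contrasts). For a nucleus
smaller than $w/2$ the distance criterion automatically fills the nucleus
— the inner edge clamps at the centroid without special-casing. Coverage
is simply the percentage of band pixels strictly above the threshold;
thresholds are explicit values (or Otsu as `"auto"`) and are always echoed
in the result, since the original measurements used manual thresholds that
cannot be reconstructed.

### Foci and radial profiles

Focus detection combines local-maximum candidates (within a
`min_distance_um` window, default 1 µm) with a prominence gate above the
image median and greedy non-maximum suppression, ordered by intensity.
Focus intensity is the mean over a circular ROI of 1 µm diameter at the
detected center. Radial profiles shrink the outline by `shrink_um`
(default 0.5 µm, i.e. 1 µm of diameter) along inward normals, then cast 72
rays outward along local outward normals, sampling by bilinear
interpolation at pixel-size steps over 3 µm. Ray count and length are not
stated by the reference protocol; 72 rays give 5° angular resolution and
3 µm spans the envelope signal at the default pixel size — both are
configurable. Rays leaving the image contribute only their in-bounds
samples.

### Control-calibrated positivity

`control_threshold()` returns the *maximum* in-band intensity across
control images (undifferentiated cultures), implementing the rule
"subtract the maximal control signal": an experimental nucleus counts as
positive only where it exceeds anything seen in controls.
`classify_positive()` then calls a nucleus positive when its coverage
reaches `min_coverage` (default 10 %) and aggregates to per-replicate
percent-positive values — the replicate-level statistic that group tests
and CIs are applied to.

## The imaging fixture generator

`render_scene()` draws non-overlapping, mildly elliptical nuclei
(semi-axes 3.5–5 µm, ≥ 3 µm clearance), an envelope ring as a band of
radial thickness 0.4 µm centered on each nucleus boundary covering a
contiguous angular arc of the requested fraction (uniformly random start
angle), isotropic Gaussian foci of controlled amplitude and width,
constant background plus Gaussian noise, and optional Gaussian blur. The
default pixel size is 0.1 µm/px so that 1-µm geometric parameters span
10 px and discretization errors in analytic checks stay below a few
percent. The truth record (centers, axes, arcs, focus parameters, all
intensities) is exact.

What it does *not* emulate: 3-D optics and z-stacks, realistic point-spread
functions, myotube morphology, chromatin texture, uneven illumination,
or touching nuclei. Passing tests on these scenes therefore certify the
geometry and arithmetic of the measurements — band construction, distance
computations, coverage fractions, focus integrals — under controlled
conditions, not robustness to the full variability of real micrographs.

One geometric consequence matters for validation: the planted ring is
0.4 µm thick, so a 1-µm measurement band contains envelope signal in only
~40 % of its radial extent, and raw coverage of a full ring reads ~40 %,
not 100 %. When the goal is to recover the planted *angular* fraction, the
validation code measures with a band of half the ring thickness (0.2 µm):
the segmented outline can sit up to one pixel inside the true boundary,
and the narrower band stays radially inside the ring despite that bias,
making coverage a clean readout of arc fraction. With the default 1-µm
band the *contrast between conditions* is unaffected, which is what the
protocol uses the band for on real images.

## The statistics layer

The mapping of tests to data types mirrors common practice for this kind
of experiment and is configuration-driven, not hard-coded: pooled
per-nucleus distributions (violin plots) are compared with the two-sample
Kolmogorov–Smirnov test; per-replicate percentages (n = 3 bar graphs) with
Student's t or one-way ANOVA plus Bonferroni-adjusted selected pairs.

Choices worth stating explicitly:

* **t with F gate.** The protocol pairs the t-test with an F-test for
  equality of variances without stating a threshold; the package uses
  $p_F < 0.05$ to switch from the pooled to the Welch t. Tests are
  two-sided (the sidedness was unstated; two-sided is the conservative
  default).
* **Bonferroni on selected pairs.** Each selected pair's pooled-MSE t
  p-value (on the ANOVA residual degrees of freedom) is multiplied by the
  number of *selected* pairs and capped at 1 — the classical post hoc, with
  the multiplier determined by the comparisons actually made rather than
  all possible pairs.
* **CIs of group differences** use the pooled-variance t interval on
  replicate-level values; with zero pooled variance the interval
  degenerates to the point difference rather than erroring. Coverage is
  verified by simulation.
* **Quantiles** are linear-interpolation (type 7) everywhere; quartile
  conventions differ between tools, so this is pinned and documented.
* Degenerate inputs are handled explicitly: identical constant samples
  give $t = 0, p = 1$; empty groups error.

## Problem sizes and determinism

The test suite and the acceptance script size their simulations to be
decisive yet quick: 200-gene fixtures for the cascade round trip, 20
random fixtures of up to 1000 peaks for brute-force oracle comparisons,
2000 simulated genes (500 permutations each) for type-I calibration, 2000
repeats for CI coverage, and 300–400 px fields with 2–4 nuclei for the
imaging checks. Every stochastic step is seeded; `run_demo()` and the
fixture generators are bit-reproducible under a fixed seed, and each run's
provenance JSON (config echo, seeds, package version) suffices to
reproduce it.

## Known limitations

* Merged (touching) nuclei are not split; they are flagged by area and
  eccentricity for exclusion, not resolved.
* The permutation null for the time-course filter is this package's
  documented stand-in for an un-restated published procedure; absolute
  agreement with historical gene lists is not guaranteed.
* GO matching is name-based; no ontology release management or closure.
* The screen's DE filter consumes upstream p-values as given; it inherits
  whatever multiplicity handling the upstream analysis applied.
* Image measurements are 2-D; out-of-plane signal is not modelled.
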