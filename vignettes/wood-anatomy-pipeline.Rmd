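---
title: "Quantifying tracheid-level wood anatomy: traits, drivers and inter-annual stability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tracheid-level wood anatomy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xylotrait)
```

## The problem

Conifer wood is built from tracheids: the same cell type carries water up the
stem and holds the stem up.  A single tree ring therefore encodes a trade-off —
wide, thin-walled earlywood (EW) tracheids conduct efficiently; narrow,
thick-walled latewood (LW) tracheids resist bending and implosion.  Modern
image analysis delivers tables with one row per tracheid (lumen diameters,
four single-wall thicknesses, lumen and wall areas), and the scientific
questions live at the ring level: how wide is the ring and how much of it is
earlywood, what is its theoretical hydraulic conductivity, how reinforced are
its walls, and — across a stand — how much of the variation in those traits is
explained by tree height, tree age and micro-site, and how stable is each
trait from year to year?

`xylotrait` implements that chain end to end: a canonical per-cell table
format, the full ring-trait catalogue, and the statistical battery (best-curve
fits, year-wise PCA, backward model selection, Mantel and Procrustes
permutation tests, CV-based stability ranking), together with a synthetic
tracheidogram generator that emulates a three-plot Norway spruce stand so the
whole pipeline can be exercised, calibrated and tested without access to
restricted field data.

## Ring traits

All traits are computed from a 1-mm-wide tangential strip of the ring — the
convention under which the per-cell tables are collected — organised into
radial files (sequences of cells from the ring's pith side to its bark side).

**Earlywood/latewood partition.**  The default classifier is Mork's index,
the ratio of four times the single radial wall thickness to the radial lumen
diameter, with the classical cut at 1: a cell is latewood iff the index is
`>= 1`.  (The cut at exactly 1, with LW on the closed side, is the classical
criterion; the index itself is also reported as the trait `rTSR`.)  An
alternative shape rule (`drad/dtan < 1`) is available.  The ring-level
EW–LW boundary is the relative position of the first cell of the terminal
all-LW run of each file, averaged over files.  Rings that lack one class
entirely keep their labels; the boundary is reported as 0 or 1 with a
warning flag, and traits over an empty EW or LW subset are reported as
missing values, never as 0.

**Geometry.**  A cell's radial extent is its lumen diameter plus both radial
single walls.  `TRW` is the mean over files of the summed extents; `EWW` and
`LWW` sum the correspondingly labelled cells, so `TRW = EWW + LWW` and
`EW% + LW% = 100` hold by construction.  `BAI` converts a width series to
ring areas, `pi * (r_i^2 - r_{i-1}^2)`; the stem radius at the inner edge of
the oldest sampled ring is reconstructed as `DBH/2` minus the summed sampled
widths (bark and phloem ignored — a documented approximation that affects
only BAI's absolute level, not its year-to-year contrast).

**Counts.**  `CNO` is the strip total; `NoCells_tang` counts radial files
containing latewood (per mm); `NoCells_rad = CNO / NoCells_tang` is the mean
cells per file.  `EW_Nocells` and `LW_Nocells` are the per-file means of the
two portions, while `CNO_EW`/`CNO_LW` are strip totals — the catalogue keeps
both because the two spellings answer different questions (profile length
vs. cell production).  `CD` divides `CNO` by the analysed area
`TRW × strip width`.

**Mechanics.**  Per cell, single walls are averaged per axis first
(`CWTrad = (cwt_le + cwt_ri)/2`, `CWTtan = (cwt_pi + cwt_ba)/2`,
`CWTall` their mean).  Relative wood density is the wall fraction of the
cell footprint, `RWD = CWA/(CWA + LA)`; we read the "cell area" in that
definition as the lumen area, the reading under which RWD is bounded in
(0, 1) and behaves as a density.  The cell wall reinforcement index
`(t/b)^2` uses the double wall `t = 2 ×` averaged single wall over the lumen
span `b` of the same axis, taking the smaller of the radial and tangential
ratios before squaring (the weaker axis governs implosion safety).  Ring
values are unweighted per-cell means; percentile variants (`_01`, `_25`,
`_50`, `_75`, `_99`, plus the 5th percentile of `(t/b)^2`) use linear
interpolation between order statistics (R's default, type 7) — fixed and
documented because percentile traits depend on the rule.  Low LA percentiles
sample latewood-like cells and high ones earlywood-like cells by
construction, which is how the percentile columns proxy the two portions.

**Hydraulics.**  Lumen-area-equivalent diameters `d_i = 2 sqrt(LA_i/pi)`
give the hydraulic diameter `Dh = sum(d^5)/sum(d^4)`, the moment ratio that
weights conduits by their hydraulic importance (`Dh >=` the arithmetic mean,
with equality only for uniform rings).  Theoretical conductivity treats every
conduit of the strip as a parallel elliptical tube of 1 m length with no pit
resistance: `k = pi a^3 b^3 / (4 eta (a^2+b^2) L)` with semi-axes from the
two measured lumen diameters, which collapses to Hagen–Poiseuille
`pi r^4/(8 eta L)` for circular cells (a closed-form limit the tests check at
1e-12 relative tolerance).  A `conduit_model = "circle"` switch uses
lumen-area-equivalent circles instead, since image-analysis pipelines differ
on this point.  `Ks` divides `Kh` by the analysed xylem area
(`TRW × strip width`), and `HCUE` — the hydraulic return per unit carbon
invested — is reconstructed from its printed units as mass-flow conductivity
(`Kh ×` water density) per unit summed wall area; the source formula is not
reproduced in the literature we follow, so this reconstruction is flagged as
such.  Water properties default to 20 °C (`eta = 1.002e-9` MPa s, density
998.2 kg m⁻³).

The catalogue (`xylo_trait_names()`) expands to 74 columns: 9 directly
measured quantities and 65 derived ones (six trait families carry the five
percentile variants).

## The statistical chain

**Best-of-three curve fits.**  Pairwise trait relationships are summarised by
the best of linear (`y ~ x`), exponential (`log y ~ x`) and logarithmic
(`y ~ log x`) least-squares fits, the winner chosen by R² *computed in each
family's own fitted space*.  That is the convention of the field, and it is
not a likelihood comparison — the caveat is attached to the result.  Families
whose transform is undefined for the data (non-positive x or y) are skipped
rather than contested.  No multiple-testing correction is applied to the
pairwise scan; a Benjamini–Hochberg column is emitted alongside for the
reader but never used for selection.

**Year-wise PCA.**  Each year's individuals × traits matrix is standardized
(n−1 SDs) and decomposed with `prcomp`.  Signs are made deterministic (the
largest-magnitude loading of each component is positive).  At the operation
level a constant trait is an error naming the trait; the pipeline instead
pre-drops incomplete or constant traits with a warning so that every year's
PCA sees the same trait set — both behaviours are exposed
(`on_constant = "error"|"drop"`).

**Backward LRT selection.**  The first three PC scores of the outermost year
(the year with contemporaneous height measurements) are regressed on tree
height, age and plot (a categorical block).  Selection removes, one at a
time, the term whose deletion has the largest likelihood-ratio p-value above
`alpha = 0.05` (the threshold is our choice; the convention "drop when the
simpler model is more parsimonious" names no number), until every remaining
deletion is significant.  A `drop1` F table of the full model is attached —
for this additive design it coincides with Type-II tests, covering the
ambiguity between per-covariate tests and nested LRTs in the original
description.

**Mantel tests.**  Within each plot, the Pearson correlation between
geographic distance (great-circle, from tree coordinates) and Euclidean
distance over the leading PC scores (3 by default; the count is
configurable because the original metric is unstated) is tested by
simultaneous row/column permutation, one-tailed, 999 permutations, with the
add-one convention so p is never 0.

**Procrustes tests.**  For every pair of years, the two score configurations
(first 2 PCs by default, matching how such configurations are displayed and
compared) are centered, scaled to unit sum of squares and optimally rotated
via the SVD of their cross-product; `m² = 1 − (Σ singular values)²`,
`r = sqrt(1 − m²)`, significance again by row permutation.  The statistic is
symmetric in its arguments and invariant to translation, uniform scaling and
rotation/reflection; the tests verify both properties, plus exact agreement
with an established implementation and with a numeric search over rotations.

**Stability ranking.**  Per trait and individual, the CV across years
(`100·sd/mean`, n−1); individual CVs averaged across individuals and their
range recorded; flags at mean CV > 10% and range > 20%, the conventional
thresholds for "unstable" traits.

## The synthetic stand generator

The generator emulates the study design the analysis is built for: 3 plots ×
10 trees along an altitudinal transect, one ring per year 2008–2012, with
per-plot height (10.5–33 m), age (34–155 yr) and DBH ranges matching the
stand table, trees drawn stratified within each range to maximise within-plot
contrast.  Height and age are tied through a shared stratified draw with
mixing weight 0.4, targeting a within-plot Pearson correlation of roughly
0.4–0.7 — the study selected trees to maximise variation in both, but their
realised correlation is unreported, so the target is a modelling choice and
is configurable.

Each ring is a strip of `floor(1000 / (Dtan + 2 CWTtan))` radial files.  A
file is an EW plateau (radial lumen ≈ 32 um, walls ≈ 2 um) followed by a
logistic decline to LW values (lumen ≈ 6 um, walls ≈ 4.5 um).  The logistic
runs in cells-from-ring-end space, centred so that Mork's index crosses 1 at
a roughly constant LW cell count per file (mean 8, truncated normal ≥ 3).
That choice makes ring width earlywood-driven by construction — LW width is
nearly constant, so all the action is in the EW cell count — which is the
structural property the analysis stage is meant to recover (ring width moving
one-to-one with radial cell count, mean EW% above 80%).  For typical EW
counts the decline occupies about the final quarter of the profile.

Covariate effects are linear in the generator: taller trees get larger
tangential (0.32 um/m) and radial (0.11 um/m) earlywood lumina — values
calibrated so that the generator reproduces the reported strength of the
height–diameter relationships (R² ≈ 0.54 tangential, ≈ 0.39 radial) — and
hence fewer files per mm; older trees get thicker walls (0.01 um/yr) and a
higher latewood share (0.03 percentage points/yr, converted internally to an
LW-cell-count slope at the configured mean geometry).  The analysis stage
never assumes this linearity — the best-curve contest is free to prefer
exponential or logarithmic forms.

Random effects are Gaussian on the log scale for the strictly positive
parameters (EW cell count, diameters, wall thickness).  Individual effects
(SD 0.45 on count, 0.06/0.025/0.08 on dtan/drad/cwt) are at least twice the
common per-year effects (0.12/0.02/0.012/0.03), making trees' multivariate
positions stable across years — the precondition for the high inter-annual
Procrustes correlations the study reports.  Within-ring cell noise and a
small per-file count jitter complete the variance budget; the between-ring
CV of the mean earlywood radial diameter stays under the declared 5% cap
(enforced at configuration time), which is what pins the ring-width ↔
cell-count correlation near 0.99.  In the dense high-elevation plot only,
individual effects are spatially correlated through a Gaussian kernel
(range 20 m) on tree coordinates — mirroring the observation that spatial
proximity predicts trait similarity only there; the other plots act as
negative controls at the nominal test level.

Randomness is layered: stand-level draws use the master seed; per-year
effects and per-ring cell noise run in sub-streams keyed by (seed, tree,
year), so any single ring is reproducible without regenerating the stand,
and identical (config, seed) yields byte-identical CSV output.

**What the generator does not emulate.**  No climate forcing (the study
design deliberately minimises it by using five adjacent rings), no
pith-to-bark ontogenetic trend, no intra-annual density fluctuations,
no compression wood, no measurement error model for the image-analysis step.
Passing tests on synthetic stands therefore demonstrate that the trait
formulas and the statistical machinery are correct and that the chain
recovers known structure; they do not validate ecological conclusions on
real wood.

## Numerical choices and degenerate inputs

* Percentiles: type 7 (linear interpolation), everywhere.
* Mork cut: LW iff index ≥ 1 (ties go to latewood).
* Empty EW/LW subsets: `NA`, never 0; a ring with no latewood-bearing file
  has no tangential count (error at the operation level, `NA` with a warning
  through the aggregation path).
* Permutation p-values: add-one convention, one-tailed (greater).
* PCA sign convention: largest-magnitude loading positive.
* LRT drop threshold: 0.05; collinear designs and n ≤ parameters are
  refused.
* Cells are elliptical for lumen area and conductivity, rectangular for
  radial-extent bookkeeping; the cell-table validator admits both
  conventions via a 1e-6 tolerance on `LA ≤ (pi/4)·Drad·Dtan`.

## Problem sizes used in the test suite

The suite's heavier checks run at deliberately chosen sizes: oracle
equivalence of all trait formulas on 100 generator rings at 1e-9 relative
tolerance; permutation-test calibration on 500 null replicates (n = 30, 999
permutations) expecting a 0.05-level rejection rate within [0.03, 0.07];
covariate recovery on 100 single-year replicate stands (the selection stage
only ever uses the outermost year, so multi-year simulation would add
nothing) expecting height retained on the diameter-loading PC and age on the
wall-loading PC in at least 80% of stands; and the three structural claims
(ring-width ↔ cell-count correlation, minimum pairwise Procrustes r,
mean EW%) on one full default stand of 150 rings.

## Known limitations

* The trait-table column dialect is this package's own canonical schema; the
  alias map for raw image-analysis exports is best-effort and unverified.
* `HCUE` is a units-based reconstruction (see above).
* `NoCells_tang` counts latewood-bearing files; the alternative reading
  (latewood cells along one tangential transect) is not implemented.
* BAI's inner radius comes from DBH and ignores bark.
* The backward selection assumes Gaussian responses (PC scores of
  standardized traits make this mild).
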