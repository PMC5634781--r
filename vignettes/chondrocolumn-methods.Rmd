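---
title: "Methods: quantifying clonal columns and sister-cell pivots in growth-plate cartilage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying clonal columns and sister-cell pivots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chondrocolumn)
```

## The biological measurement problem

Long bones elongate because chondrocytes in the growth plate's
proliferative zone arrange into columns stacked along the proximodistal
(PD) axis. Individual labeled clones can look like tight single-cell-wide
columns, wider multi-cell stacks, or loose arbitrary clusters (typical of
the resting zone), and live imaging shows that a column begins with a
mediolateral (ML) division followed by one sister cell pivoting around
the other into a PD-oriented doublet. `chondrocolumn` implements the
quantitative machinery for these observations: orientation statistics
with threshold classification, pivot-angle trajectories, intensity-based
contact and junction measurements, and the supporting statistical tests,
together with a synthetic-tissue generator that provides seeded ground
truth for every estimator.

All analyses are planar: sections and live imaging quantify angles in 2D
projections, so the package fixes PD = +y and ML = +x of the micrometre
tissue frame. Image frames are pixel-indexed with the origin top-left and
y pointing down; `um_to_px()` converts between the two (y negated,
tissue origin at the image centre). Interfaces always speak degrees.

## Clonal architecture (Phi, theta, column orientation)

For each cell the angle Phi between its minor axis and the PD axis is
folded to [0, 90] degrees (axes are undirected). A clone with more than
two cells is classified by the sample SD (n − 1 denominator; clones are
small, so the conventional unbiased estimator is used) of its Phi
values:

* `SD(Phi) <= 12 degrees` — *stacked*;
* otherwise — *arbitrary*.

Values exactly at the threshold count as stacked (and, below, as
single): the field's rule names strict inequalities on both sides
without covering equality, so the package resolves ties toward the
tighter class deterministically.

Within a stacked clone, theta_i is the folded angle between the segment
from the topmost cell (largest PD coordinate; ties broken by smaller ML
coordinate, then by `cell_id`) to cell i and the PD axis. We read
"orientation between the topmost cell and all the other cells" as these
segment angles, because that is what inter-cell connection lines in the
measurement schematic depict; the alternative reading
(orientation-angle differences) would not distinguish lateral from
stacked neighbours at all. `SD(theta) <= 12 degrees` calls a *single*
column, larger values *multi*. A clone of two cells has one theta and no
SD; it is called single by convention and flagged low-confidence.

The column outline is approximated by the convex hull of the cell
centroids expanded by the cell radius (default 5 µm, configurable):
each centroid contributes a sampled circle and the hull of all boundary
points is taken. The manual outline this stands in for may be concave;
the hull is an approximation, not claimed equivalent. Column orientation
is the angle between the polygon's major principal axis — from the
second central moments of the polygon's area, computed with the
shoelace/Green's-theorem formulas — and the PD axis. When the two
principal moments are equal within a relative `1e-6` (a circle), the
orientation is undefined and flagged, returning 0.

Zone-level Phi summaries report both the pooled per-cell mean and the
mean of clone means: with unequal clone sizes the two differ, and the
source material does not say which pooling it used.

## Pivot kinematics (omega)

The pivot angle omega of a sister pair is the two-argument arctangent of
(dy, dx) of the inter-cell vector, folded to [0, 180) with the ML
direction at 0. Folded angles are unwrapped over time — each step is
chosen within ±90 degrees of the previous unwrapped value — so
cumulative pivots beyond 90 degrees (which occur) are preserved; a step
of exactly 90 degrees is directionally ambiguous and is resolved toward
the smaller absolute cumulative value and flagged. The series is
normalized to 0 at the first observed sample (the time origin is the
first observation).

The final pivot is estimated as the mean of the last quartile of samples
(a plateau estimate; source curves were read by eye without a stated
estimator). With fewer than four samples the last value is used and the
series flagged. Classification on |final omega|: *complete* in
[70, 100] degrees (the reported range for pairs that stacked), *partial*
in [30, 70) (anchored to a reported ~50-degree partial pivot; the band
is this package's operationalization and is config-exposed), otherwise
*none*.

## Intensity measurements

`polyline_profile()` samples a frame along a polyline at half-pixel
steps with bilinear interpolation, averaging across a perpendicular band
(default 3 px), and normalizes by the line maximum (F/Fmax). The
contact statistic summarizes the profile between two sister nuclei: over
the central 50% of the path, `dip = 1 − min(F/Fmax)`. A flat profile
(cytoplasmic bridge) has dip near 0; separated cells let the profile
fall to background, pushing the dip toward `1 − background/cell` level.
The default call threshold is dip ≤ 0.5 — the flat-versus-inverted-bell
distinction is qualitative in the source material, so the threshold is
exposed in `run_config()`.

`junctional_fraction()` measures background-subtracted junctional over
total pair intensity; the background is the median outside the pair
region (a choice this package makes; the original background handling is
unstated). `junction_timecourse()` normalizes per-time junctional sums
by the course maximum and also emits the running cumulative sum, because
"cumulative F/Fmax" admits both readings; the per-time series is
primary. `pearson_colocalization()` is the standard product-moment
coefficient over masked pixels, flagged undefined for constant channels.

## Statistical battery

Watson's U² compares two circular samples through the centred squared
discrepancy of empirical cumulative fractions accumulated over the
pooled ordering; the centring makes it origin-invariant. Axial data
(period 180) are doubled to the circle first — the standard treatment,
which the source material leaves implicit. p-values are exact by
exhaustive enumeration whenever `choose(N, n1)` ≤ 5000, otherwise by
seeded random permutation with the add-one estimator; ties use midranks
and are flagged. The Wilcoxon rank-sum and one-sample KS normality
screen delegate to `stats::wilcox.test()` and `stats::ks.test()`; the
KS screen tests against a normal law with estimated parameters and is
therefore conservative (Lilliefors caveat) — this is flagged in the
result rather than corrected, matching its role as a gate that routes
analyses to the nonparametric path.

## The synthetic generator: what it emulates, and what not

The generator is the package's ground-truth instrument, not a microscopy
simulator. Its defaults are the study conditions under which the
estimators are validated:

* **Clone geometry.** Proliferative clones are stacks of
  `cells_per_clone` (default 8–16, i.e. clones after three to four
  division rounds) disk-like cells at 8 µm pitch in `column_width`
  lateral sub-columns, with 0.5 µm positional jitter; clones sit on a
  non-overlapping grid. Resting clones are loose isotropic clusters.
* **Orientation model.** Each proliferative clone draws a stack-axis
  tilt from `N(0, 15 degrees)`; cells draw minor-axis angles about that
  tilt with SD `orientation_spread_deg` (default 3 degrees), folded
  axially. The between-clone tilt SD of 15 degrees was fixed by matching
  the reported zone-level mean Phi of about 12 degrees for wild-type
  proliferative tissue given a 3-degree within-clone spread; with these
  defaults the generator reproduces that mean (~11–12 degrees) without
  further adjustment. Resting-zone orientations are uniform.
* **Folding caveat.** Phi lives on [0, 90]: near the folds (stack axes
  near 0 or 90 degrees) the folded sample SD is compressed relative to
  the generating spread (by ≈ `sqrt(1 − 2/pi)` at the fold). The
  sample-SD-recovers-spread property therefore holds in the fold-free
  regime and is tested there (tilt fixed at 45 degrees); classification
  works on folded values exactly as the measurement rule does. This also
  bounds the achievable folded SD (≈26 degrees for uniform
  orientations), which is why "arbitrary" ground truth is generated by
  spread, not by target SD.
* **Pivot tracks.** The sister axis rotates from `division_angle_deg`
  (NA = uniform misoriented draw) by `final_pivot_deg` along a
  smoothstep ramp completing at 75% of the duration, then plateaus —
  so the last-quartile plateau estimator is unbiased and noise-free
  tracks round-trip exactly. Per-sample angular noise is additive
  Gaussian (the source material gives no quantitative jitter model;
  the default 3–5 degrees is a free parameter, not a claim). If the
  pair separates, the distance grows at 1.5 µm/h after
  `separation_time_h` and the pivot freezes at its value at separation:
  rearrangement requires cell-cell contact, which is exactly the
  behaviour the perturbation phenotypes show.
* **Frames.** Bodies are uniform disks (4 µm radius at 0.5 µm/px in a
  96×96 px field), the cytoplasmic bridge fills the inter-body capsule
  while in contact, and the junctional band (half-width 1 µm) overlays
  the interface midline *after* the bodies — it models a
  membrane-localized signal sitting on the interface, and a band
  narrower than ~2 px rasterizes too unstably under rotation to carry
  ground truth. No point-spread function, z-structure, bleaching, or
  mechanics is simulated: passing tests demonstrate estimator
  correctness on data with the assumed structure, not robustness to
  real-microscopy artefacts.

Four presets encode the qualitative phenotypes: `wild_type` (ML
division, full 85-degree pivot, persistent contact and junction),
`pcp_loss` (misoriented divisions, intact pivot and stacking, stack
tilt SD widened to 40 degrees so stacks point anywhere), `pcp_gain`
(misoriented divisions, separation at 3 h, junction decaying with a 5 h
half-time), and `ncad_block` (ML division but separation at 2 h, hence
no complete pivots). In the pipeline the junction channel is rendered on
the non-separating twin of the pair geometry: junctional protein loss
precedes physical separation, and this keeps the band position defined
over the whole course so the measured F/Fmax tracks the programmed
decay (≈0.5 at 5 h for `pcp_gain`).

## Numerical choices and degenerate inputs

Seeds are mandatory arguments everywhere; generators restore the
caller's RNG state. Zero-length axes, coincident points, all-zero
profiles, empty interiors, constant channels, zero-variance samples and
isotropic polygons all produce explicit errors or flagged-undefined
results rather than silent numbers. Angles are folded with exact
degree arithmetic (`%% 180`), avoiding radian round-trips in the
folding logic. The polygon hull uses 64 boundary samples per cell:
orientation equivariance under joint rotation of data and reference
axis then holds to the discretization level (~1e-3 degrees), while the
moment computation itself is exact.

## Problem sizes

The validation suite runs at deliberately desk-scale sizes: 200 clones
of 8–16 cells for classification recovery, 50 seeded tracks for pivot
recovery, 20-seed ensembles per condition for contact separation, 500
null replicates (199 permutations each) for the U² type-I check, and
10⁵ pixels for the colocalization target. These sizes keep the complete
suite under half a minute while leaving every pass/fail margin
statistically comfortable.

## Known limitations

* The headline quantities from live cartilage imaging are reproducible
  only from the original measured coordinate tables; this package
  reproduces the *machinery* and validates it on synthetic ground
  truth.
* The convex-hull polygon understates concave column outlines, and
  therefore can tilt the major axis slightly for strongly curved
  multi-columns.
* The dip threshold and partial-pivot band are operationalizations of
  qualitative descriptions; both are configuration, not biology.
* Axial folding bounds what orientation SDs can express (see above);
  comparisons of SDs near the folds should use the generator's signed
  spread, not the folded SD, as ground truth.
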