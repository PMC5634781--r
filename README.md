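# chondrocolumn

Quantification of clonal architecture and cell rearrangement in
growth-plate cartilage.

Chondrocytes in the proliferative zone of the growth plate stack into
columns along the bone's proximodistal (PD) axis. Clonal labeling and
live imaging reduce this to a set of planar measurements: the angle
**Φ** between each cell's minor axis and the PD axis (its within-clone
SD separates *stacked* from *arbitrarily arranged* clones at a
12° threshold), the angle **θ** from a stacked clone's topmost cell to
each other cell (its SD separates *single* from *multi* columns, same
threshold), the orientation of the column outline's major principal
axis, and the pivot angle **ω(t)** of a sister-cell pair relative to the
mediolateral axis, tracked after division, normalized to 0° at first
observation, and classified *complete* when it plateaus in 70–100°.
Around these sit intensity measurements (polyline-kymograph F/Fmax
contact detection, junctional/total intensity ratios and junctional
F/Fmax time courses, Pearson colocalization) and the statistical battery
used to compare conditions (two-sample Watson's U² permutation test for
orientations, Wilcoxon rank-sum, and a one-sample Kolmogorov–Smirnov
normality screen that routes to the nonparametric path).

`chondrocolumn` implements all of this as a tested R package for
researchers quantifying oriented cell division and rearrangement in
cartilage (or any planar tissue with a defined growth axis), plus a
seeded synthetic-tissue generator whose presets emulate wild-type,
planar-cell-polarity perturbation, and N-cadherin-blocked phenotypes so
every estimator can be validated against known ground truth.

## Worked example

```r
library(chondrocolumn)

# classify a synthetic clone ensemble
cells <- generate_tissue(tissue_params(n_clones = 3, seed = 1))
summarize_clones(cells)
#>    clone_id n_cells phi_sd_deg arrangement theta_sd_deg width_class
#> 1 clone0001      16   3.026722     stacked     1.159657      single
#> 2 clone0002      11   2.618630     stacked     2.880336      single
#> 3 clone0003      14   3.050918     stacked     1.063404      single
#>   orientation_deg orientation_undefined
#> 1       19.874447                 FALSE
#> 2        6.532311                 FALSE
#> 3        6.211232                 FALSE

# full pipeline on a phenotype preset
rep <- run_pipeline("wild_type", run_config(seed = 1), n_pairs = 8)
rep
#> chondrocolumn report -- preset: wild_type
#>   clones: 50 (stacked 100%, of which single-column 100%)
#>   pairs: 8 (complete pivot 100%, in contact at end 100%)
#>   junction F/Fmax at final hour: 0.99
```

Each clone's `phi_sd_deg` is the within-clone SD of Φ (all well under
the 12° threshold here, hence `stacked`); `theta_sd_deg` likewise calls
every clone a `single` column, and `orientation_deg` gives the column
axis angle to the growth direction. The report line shows the three
analysis tracks: clone classification, pivot outcome fractions, and the
junctional intensity time course (persistent, F/Fmax ≈ 1, in wild
type). Comparing conditions:

```r
loss <- run_pipeline("pcp_loss", run_config(seed = 1), n_pairs = 8)
compare_conditions(rep, loss, seed = 1)$orientation_test
#> watson_u2_permutation
#>   statistic = 0.556424  p = 1e-04
#>   n = 50, 50
```

— misoriented-division clones still stack, but their column orientations
differ sharply from wild type.

A thin command-line wrapper over the same functions ships in
`inst/scripts/chondrocolumn.R`
(`simulate | classify-clones | pivot | compare`, each with `--help`).

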