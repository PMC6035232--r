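# profilecomp

Quantitative mapping of fluorescence markers in morphologically
heterogeneous cell populations.

## The problem

Immunofluorescence images report where a tagged molecule sits — at the
plasma membrane, through the cytoplasm, in a perinuclear organelle — but
cells in a real culture differ wildly in size and shape. Intensity profiles
taken between or across cells are therefore stretched and squeezed
differently in every cell, and averaging them smears the signal until the
localization pattern is unreadable. `profilecomp` removes that geometric
variability: it treats every measured profile as a warped re-sampling of one
latent population-representative "ideal profile" and estimates the template
and the warps jointly, so the aligned profiles can be averaged meaningfully.
It is aimed at cell biologists and image analysts who want per-position
intensity maps (e.g. "how much E-cadherin sits at the cell–cell junction")
rather than whole-cell totals.

## The model

Profiles are extracted along a Delaunay network of nucleus centroids:

* **IN (internuclear) profiles** — `n` quasi-parallel lines spanning the
  axis between two neighbouring nuclei, from one nucleus' perpendicular
  diameter to the other's; they capture cell–cell interface signal.
* **RD (radial) profiles** — `m` equi-angular rays from a nucleus centroid
  out to a periodic spline through the neighbouring centroids; they capture
  the intracellular distribution.

Length-normalized profiles are stacked as columns `y_j` of an `N x M`
matrix `Y`. The ideal profile is a sinc-basis expansion on [0, 1],

    f(x) = sum_k c_k sinc(x/Δ − k),   Δ = 1/(L−1),

and each column is modelled as `y_ij ≈ f(x*_ij)` at unknown monotone
locations `x*_j` (pinned at 0 and 1). Coefficients and locations minimize
the three-term energy

    E(X, c, Y) = E_Y(X, c, Y) + α cᵀψ_L c + β Tr(Xᵀψ_N X),

with `E_Y` a weighted least-squares / Poisson data term, `ψ` the
first-difference penalty (smoothness on `c`, tension on each location
column), by alternating closed-form coefficient updates with fixed-point
location updates. Profiles far from the current template are flagged as
outliers (`ω_j = 0`), excluded from the template fit, but kept moving so
they can be re-admitted. For IN profiles the template is constrained to be
symmetric (`c = P c̃`): the interface reads the same from either cell.

## Worked example

Everything below is synthetic and seeded — no external images required.

```r
library(profilecomp)

cfg <- population_config(n_cells = 12, image_height = 256, image_width = 256,
                         marker_mode = "membrane", seed = 3)
sample <- generate_population(cfg)
report <- run_pipeline(sample$nuclei_channel, sample$marker_channel, kind = "in")
report
#> Profile report
#> Cell network: 12 nuclei, 28 edges, 17 triangles (0 pruned)
#>   IN: 280 profiles, peak 205.96 a.u. at position 50

summary(report$`in`$fit)
#> Profile summary (positions 0-based)
#>   samples per profile: 101 | profiles used: 179
#>   peak: 205.96 a.u. at position 50
```

The synthetic population carries a membrane-localized marker, so after
compensation the 280 internuclear profiles agree: mean intensity peaks at
position 50 of 0–100 — the midpoint of the internuclear axis, i.e. the
shared membrane — at 206 a.u. (the rendered ring peaks at 200 a.u. plus
Poisson noise). Before compensation the per-column peak positions are
scattered by cell-size differences. A third of the columns were flagged as
outliers (lines grazing three-cell corners fit the pairwise template
poorly) and are excluded from the summary but retained, flagged, in the
map. `plot(report[["in"]]$fit)` shows raw vs compensated mean ± SD and the
energy trace; `virtual_cell_pair(report[["in"]]$fit)` renders the
population-typical cell pair.

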