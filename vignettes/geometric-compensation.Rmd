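---
title: "Elastic geometric compensation of fluorescence intensity profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elastic geometric compensation of fluorescence intensity profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(profilecomp)
```

## The model and its assumptions

A fluorescence image of a confluent cell population yields many intensity
profiles — internuclear (IN) lines between neighbouring nuclei, or radial
(RD) rays across single cells. `profilecomp` assumes each length-normalized
profile column $y_j$ is a noisy observation of one latent continuous
template $f:[0,1]\to\mathbb{R}$ read through an unknown *monotone* warp
$g_j$: the observation nominally at position $x_{i,j}=i/(N-1)$ really comes
from $x^*_{i,j}=g_j^{-1}(x_{i,j})$. The template is a finite sinc expansion

$$f(x)=\sum_{k=0}^{L-1}c_k\,\mathrm{sinc}(x/\Delta-k),\qquad
\Delta=(L-1)^{-1},$$

so $f(k\Delta)=c_k$ and $L$ directly caps the template bandwidth. The fit
minimizes

$$E(X,\mathbf{c},Y)=E_Y(X,\mathbf{c},Y)
  +\alpha\,\mathbf{c}^T\psi_L\mathbf{c}
  +\beta\,\mathrm{Tr}(X^T\psi_N X),$$

where $\psi$ is the first-difference quadratic penalty: on $\mathbf{c}$ it
discourages wiggly templates, on each location column it is a tension force
that keeps warped sample spacings near-uniform and prevents the trivial
collapse of all locations onto one point. The endpoints are additionally
pinned, $x_{0,j}=0$, $x_{N-1,j}=1$. Under the additive-Gaussian model the
data term is a weighted sum of squares; under the Poisson model (the
default — fluorescence intensities are photon counts) it is the negative
log-likelihood $\sum_{i,j}\omega_j[f(x_{i,j})-y_{i,j}\log f(x_{i,j})]$, and
the weighted-least-squares steps use the local curvature weights
$\gamma_{i,j}=1/(2f(x_{i,j})+\epsilon)$.

Assumptions worth stating plainly: every profile in a stack measures the
*same* underlying spatial pattern (one marker, one population); the
distortions are monotone re-parameterizations of position, not intensity
changes; and profiles that violate this (debris, mis-segmented pairs) are
rare enough for robust rejection to catch. Intensity is never normalized —
the method aligns positions, not amplitudes.

Per iteration the solver alternates: (1) closed-form regularized weighted
least squares for $\mathbf{c}$ (with the half-size reduced system when the
symmetric IN constraint $\mathbf{c}=P\tilde{\mathbf{c}}$ is active); (2)
re-evaluation of per-column outlier indicators $\omega_j$; (3) one
fixed-point update of the locations, followed by re-pinning the endpoints
and projecting each column onto the monotone cone by a running maximum
clipped to $[0,1]$.

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `N` | 101 | samples per normalized profile, positions 0–100; the internuclear midpoint is then exactly position 50, which keeps map positions interpretable |
| `n` | 10 | lines per IN beam |
| `m` | 36 | rays per RD fan (10° steps; a round trade-off between angular coverage and profile count) |
| `L` | 20 | sinc basis size; resolves features down to ≈ 1/19 of the profile length, adequate for membrane rings a few pixels wide on 40–80 px internuclear distances |
| `alpha` | 1e-3 | template smoothness weight. Must be small relative to the weighted data mass: Poisson curvature weights are $\approx 1/(2f)$, so for intensities of order 100 a.u. the data term in the normal equations has mass of order $NM/200$; an `alpha` of order 1 would visibly flatten sharp peaks (we measured an order-of-magnitude template error when it does), while 1e-3 removes ringing without biasing the peak |
| `beta` | 1e4 | location tension. The fixed-point step moves each location by $\mathcal{O}(z/\beta)$ with $z=\gamma\,(f-y)\dot f$; for 8-bit-like intensities $z$ is of order $10^2$, so `beta` ≈ 1e4 keeps single steps at the sub-grid scale (≈ 1e-2) where the iteration is stable. Much smaller values let single steps exceed the whole domain and the warps collapse into running-max plateaus; much larger values freeze the warps |
| `outlier_factor` | 3 | robust threshold multiplier: a column is rejected when its squared distance to the template exceeds the median by more than 3 × 1.4826 × MAD |
| `outlier_burn_in` | 50 | iterations before rejection starts (see below) |
| `epsilon` | 1e-6 | guards the Poisson weight division and the log |
| `max_iter`, `tol` | 200, 1e-8 | stop on relative energy change; the Poisson energy has large magnitude, so the relative tolerance is kept tight — 1e-6 would stop the loop while the warps are still moving |

Calibration of `alpha`, `beta` and `tol` was done on the package's own
warped-stack simulation (below), by requiring that compensation at least
halve the row-wise SD and that the recovered template beat the naive column
mean; the defaults assume intensities on the native 0–255 a.u. scale.

## Outlier handling: screen, burn-in, re-admission

Rejection is per column: $d_j=\lVert f(x_j)-y_j\rVert^2_2$, threshold
$\tau=\mathrm{median}(d)+3\cdot1.4826\cdot\mathrm{MAD}(d)$. Three
scheduling details matter in practice:

* **Initial screen.** Before the first fit, distances to the initial
  (constant) template identify grossly alien columns, so garbage never
  distorts the early template.
* **Burn-in.** For the first 50 iterations the indicator set is frozen. At
  initialization all locations are uniform, so $d_j$ measures *warp
  magnitude*, not outlierness; applying the threshold immediately
  mass-flags the most-warped valid profiles, and that state is
  self-perpetuating (the template tightens around the remainder). After the
  locations have adapted, $d_j$ discriminates genuine outliers.
* **Re-admission.** Rejected columns keep their locations updated, and
  within each iteration the template fit and the indicators are alternated
  to a joint fixed point, so a column whose distance falls back under the
  threshold re-enters the fit.

A flagged column stays in the compensated map (marked in `omega`) — it is
excluded from the template and the summaries only.

## Numerical choices

* **Sub-pixel sampling** of images uses the Keys bicubic convolution kernel
  ($a=-1/2$), exact on linear fields; sampled intensities are clipped at 0
  because the kernel can undershoot at sharp edges.
* **Length normalization** uses a cubic interpolating spline with the
  output clamped to the native range ± 5 % — resampling may smooth but must
  not invent extremes.
* **Monotonicity** of each location column is enforced by a running maximum
  after every update (the fixed-point step itself does not preserve order);
  ties introduced by the projection are collapsed by averaging when the
  aligned map is resampled (piecewise-linear, hence monotone and bounded by
  the data).
* **Energy descent** is not enforced step-by-step: the plain alternation is
  used, and if the energy rises for 5 consecutive iterations at a stable
  outlier set the location step is halved permanently (`damped` counts
  this). Energy jumps at iterations where the outlier set changes are
  jumps of the objective itself and are recorded in `omega_changes`.
* **Delaunay triangulation** is Bowyer–Watson with an explicit circumcenter
  test (on-circle counts as inside so cocircular configurations
  re-triangulate cleanly), a far-out super-triangle, and the cavity
  restricted to the edge-connected component around the inserted point;
  degenerate (collinear) inputs return zero triangles with a flag. No
  installed package provides a 2-D Delaunay, so it is implemented here and
  tested against a brute-force empty-circumcircle oracle.
* **Triangle pruning** computes the largest internal angle and longest edge
  per triangle and removes those beyond mean + 3 SD (angle) or mean + 5 SD
  (length), statistics taken once per image in a single pass — re-iterating
  could cascade removals. A lone triangle is kept (SD undefined).
* **Ray–spline intersection** for RD profiles takes the first (smallest
  radius) crossing of a densely sampled (1024-vertex) polyline.
* **Peak position ties** resolve to the smallest index.

## The synthetic generator

`generate_population()` emulates what the method needs from a fluorescence
image, not microscopy physics: elliptical nuclei on a jittered grid
(placement retries enforce a minimum separation; failure is an explicit
error), a *confluent* partition of the frame into cell regions via an
elliptical-metric Voronoi rule (every pixel joins the cell with the
smallest scaled-ellipse distance — confluence is required so IN lines cross
true cell–cell interfaces, and the elliptical metric gives curved,
heterogeneous boundaries), and three marker prototypes: a membrane ring
peaking on the region boundary and decaying over `membrane_width` px, a
cytoplasmic field rising from the nucleus toward (but vanishing at) the
boundary, and a perinuclear organelle annulus. Per-pixel Poisson noise is
applied last, per channel. Intensities are 8-bit-like a.u. in [0, 255]; the
frame (512 × 512), cell count (30) and intensity levels (base 20, peak 200)
are configuration defaults, not claims about any instrument.

What the generator does **not** emulate: point-spread blur, uneven
illumination, autofluorescence background, 3-D sectioning, touching or
overlapping nuclei, and mixed sub-populations. Tests passing on these
images therefore demonstrate the geometry and the estimator, no more: on
real data segmentation quality and background handling will dominate
long before the alignment does.

`simulate_warped_stack()` generates profile stacks directly from a known
template through random monotone cubic warps
$g(x)=x+a\,x(1-x)(x-b)$ (amplitude shrunk until $g'>0$), with Poisson or
Gaussian noise — the exact generative model the estimator inverts, used for
the variance-reduction, template-recovery and outlier checks.

## Problem sizes used by the tests

The test-suite runs the full pipeline on 256 × 256 frames with 12 cells
(≈ 280 IN profiles) and warped stacks of 30 × 101; the acceptance script
uses the full default conditions (512 × 512, 30 cells, ≈ 790 profiles,
three seeds). These sizes are the package's reference configurations for
its own checks.

## Known limitations

* The energy is non-convex; the uniform-location initialization is the
  method's anchor, and extreme warps (features displaced by more than the
  tension can recover) end as outliers rather than aligned columns.
* Amplitude variation between profiles is not modelled; a dimmer but
  correctly-shaped profile inflates its distance and may be rejected.
* The sinc basis is global: a local feature mis-fit can produce small
  ripples elsewhere in the template (bounded by `alpha`).
* RD analysis excludes border cells (fewer than three neighbours) by
  design; on sparse fields most cells are border cells.
* The location update cost is dominated by re-evaluating the basis at all
  `N × M` locations per iteration; stacks of a few thousand columns are
  comfortable, orders of magnitude more are not.
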