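---
title: "Modelling microtrichial orientation on insect wings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling microtrichial orientation on insect wings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trichor)
```

## The model and its assumptions

Microtrichia — the small hair-like projections covering the wing
membrane of many flies — act as directional antiwetting devices, and
their local orientation varies across the wing in a structured way.
`trichor` treats the wing as a planar domain (the image plane, after
rotation so the torsional axis is horizontal with positive x pointing
proximally) and models hair direction at any point as the unit vector of

$$
\mathcal{C}(x,y) \;=\; W_1\,\hat{u}(x,y)
  \;+\; W_2\,\frac{\mathbf{D}(x,y)}{\lVert \mathbf{D}(x,y)\rVert^{2}}
  \;+\; \hat{B},
\qquad
\hat\theta = \mathcal{C} / \lVert\mathcal{C}\rVert .
$$

The three terms encode three drop-shedding strategies:

* **Upslope.** $\hat{u}$ points from the query point to the nearest
  point on any ridge-peak polyline. This is a *proxy* for the true
  upslope gradient of the corrugated surface — the package works from
  2-D digitizations, not a 3-D surface reconstruction, so the direction
  to the nearest topographic maximum stands in for the gradient. Within
  0.37 µm of a ridge the point is taken to sit on the peak and
  $\hat{u}$ is the zero vector: on a local maximum there is no upslope.
* **Nearest edge.** $\mathbf{D}$ is the displacement to the nearest
  point on the wing margin. Dividing by $\lVert\mathbf{D}\rVert^2$
  leaves a $1/\lVert\mathbf{D}\rVert$ decay: edge attraction dominates
  within roughly $W_2$ micrometres of the margin and fades in the
  interior. $W_2$ carries micrometres so the term is dimensionless.
* **Distal.** $\hat{B} = (-1, 0)$ is fixed. Its implicit weight of 1
  anchors the scale: $W_1$ and $W_2$ are interpreted *relative to* the
  distal bias.

The model is memoryless and purely geometric: orientation at a point
depends only on the margin, the ridges and the two weights, not on
neighbouring hairs. It is equivariant under joint rotation of geometry
and $\hat{B}$, and invariant under rescaling coordinates and $W_2$
together — both properties are enforced by tests at a $10^{-9}$
tolerance on unit vectors.

## Parameters

| Parameter | Units | Default | Meaning |
|---|---|---|---|
| `w1` | – | 0.544 | upslope weight relative to the distal bias |
| `w2` | µm | 196 | edge-attraction weight; ~distance at which edge term has unit magnitude |
| `distal` | – | (−1, 0) | distal unit vector (x points proximally) |
| `scale` | µm/px | 56/75 | image scale: a 75 px quadrat side is 56 µm |
| `eps` | µm | 0.37 | lower clamp on ‖D‖ and on-ridge radius (half a pixel) |
| `spacing` | µm | 100 | grid spacing for field export |

The defaults for `w1`/`w2` are the calibrated optimum for the reference
specimen; they are starting points, not biology-free constants — other
species should be recalibrated.

## Numerical choices

**The ε-clamp.** The edge term is unbounded as
$\lVert\mathbf{D}\rVert \to 0$: on the margin the model direction is
*exactly* toward the nearest edge. To keep arithmetic finite,
$\lVert\mathbf{D}\rVert$ is clamped below at 0.37 µm (half a pixel of
the reference image). For a point lying exactly on the margin the
clamped displacement uses the outward segment normal, continuing the
limit from inside. The clamp only affects points within half a pixel of
the margin — none of the quadrat centres in practice.

**Degenerate orientations.** With $W_2 = 0$ and $\hat{u}$ exactly
anti-parallel to $\hat{B}$ at $W_1 = 1$, the three terms cancel and no
orientation exists. `model_orientation()` raises an error (or flags the
point, on request) whenever $\lVert\mathcal{C}\rVert \le 10^{-12}$
rather than silently returning any default — a silent 0° would corrupt
the calibration objective. During grid search, degenerate cells become
`NA` and are excluded from the argmin; the synthetic sampler resamples
a quadrat centre that happens to be degenerate under the truth.

**Nearest-feature ties.** A query point equidistant from several
polylines or segments (the centre of a square, say) takes the feature
with the lowest polyline index, then the lowest segment index, then the
smallest parameter along the segment. Deterministic tie-breaking makes
every downstream quantity reproducible bit-for-bit.

**Point-in-polygon.** Quadrat centres are classified by the even–odd
(ray-casting) rule, with points on the margin counted *outside*. The
boundary convention is conservative: a centre on the edge would have
the model predicting hairs half off the wing, so it is excluded, like
any centre outside the margin. Out-of-wing quadrats are retained and
flagged — they still participate in the upslope bias analysis (which
needs no edge geometry), but not in edge-related statistics or in
calibration.

**Mean orientation.** Hair angles are averaged as the arithmetic mean
on the 360° branch centred at the resultant-vector direction. A naive
arithmetic mean fails across the wrap (`c(350, 10)` must average to 0,
not 180), while a pure resultant-vector (circular) mean is *not* the
arithmetic mean of the angles even on wrap-free samples — it weights
clustered angles differently. The branch-centred arithmetic mean is
total (undefined only for exactly cancelling samples, which raise an
error), agrees with the plain arithmetic mean whenever all angles lie
within a 180° arc (true of distally biased quadrats), and satisfies the
wrap examples above. Rotation equivariance is enforced by test.

**Angular residuals and R².** The calibration residual is the unsigned
angle between two directions, wrapped to [0°, 180°]; it needs no branch
choice. The fidelity R², however, correlates two angle *sets*, so both
are unwrapped to the branch centred on 180° (the distal direction,
where observations cluster) before correlating; otherwise a pair like
359°/1° would manufacture 358 degrees of spurious disagreement.

**Bias classification.** A quadrat is upslope-biased iff the dot
product of its mean-orientation unit vector with $\hat{u}$ is strictly
positive (likewise edgeward with $\hat{D}$, and per-hair distal with
$\hat{B}$). Exact perpendicularity counts as *not biased*; because
`sin(pi)` is 1.2e-16 rather than 0 in floating point, dot products
within $10^{-12}$ of zero are snapped to the perpendicular case. A
quadrat centred on a ridge peak has no upslope direction and is
reported as `NA`, separately from either class.

**Exact binomial tails.** The bias question "how often would at least
$k$ of $n$ random quadrats show this bias?" is answered by exact
summation $2^{-n}\sum_{i\ge k}\binom{n}{i}$. All integers involved stay
below $2^{53}$ for the sample sizes here, so the sum is exact in double
precision; tests assert exact identity with the complementary sum and
agreement with `pbinom`. No multiple-testing correction is applied —
the three bias analyses are reported as three separate exact tails.

## Calibration

`grid_search()` reproduces the original brute-force design rather than
substituting a gradient or adaptive optimizer: the objective surface is
cheap, the exhaustive search is transparent, and the full surface is
itself a result (its basin shape is diagnostic). The reference
resolution is 0.001 in $W_1$ over [0, 2] and 0.75 µm in $W_2$ over
[0, 1493] µm — about 4 million SSR evaluations. Because $\hat{u}$ and
$\mathbf{D}$ at the quadrat centres do not depend on the weights, they
are computed once per quadrat and the surface is filled by vectorized
outer sums; the full-resolution search over 23 quadrats takes seconds
on one core, and a test asserts equality with the naive
loop-over-`ssr()` oracle on a coarse grid. The $W_2 = 0$ column (edge
term identically zero) is a legitimate part of the range and is
included. Ties for the minimum are broken toward the smallest
$(W_1, W_2)$ and reported with a warning, since a unique optimum is the
expected outcome.

## The wetting reduction

Rolloff trials tilt the wing in 1° steps to at most 10°; a drop that
never depins is recorded as 11° (right-censoring by protocol).
Direction-level rolloff angles pool per-wing means weighted by the
reciprocal of the per-wing standard error, so precise wings count more.
The dispersion attached to the weighted mean is first-order error
propagation, $\sqrt{\sum w_i^2 s_i^2}/\sum w_i$ with $w_i = 1/s_i$
(which reduces to $\sqrt{n}/\sum 1/s_i$): the published analysis names
a "standard deviation of the weighted mean" without a formula, so the
choice is documented here and isolated in one function
(`weighted_rolloff_mean()`) where an alternative can be swapped in.
Censored trials enter per-wing means at face value (11°), matching the
protocol; `include_censored = FALSE` exists as a sensitivity check.
The force-of-retention ratio $R_{FR} = \sin\beta_p/\sin\beta_d$ is the
entire physical model on this side — no drop-shape or contact-line
mechanics are attempted, and the static contact angle is carried as
metadata only.

## What the synthetic generator does and does not emulate

`generate_wing()` + `sample_quadrats()` exist so that calibration,
statistics and I/O are all testable end-to-end without any specimen
download. The generator emulates the *structure* of the digitized data:

* an elongated, slightly tapered simple margin polygon (4 mm × 1.6 mm
  by default, the scale of a mid-sized bibionid wing);
* several non-crossing, roughly spanwise wavy ridge polylines;
* 24 quadrat centres uniform over the margin's *bounding box* — not the
  interior — so some centres fall off the wing and the exclusion path
  is exercised, as happened in the real sampling;
* 20 hair angles per quadrat, drawn as the ground-truth model
  orientation plus von Mises noise. The concentration is
  $\kappa = 1/\sigma^2$ (radians), the small-angle correspondence with
  a circular standard deviation $\sigma$; the default
  $\sigma = 10°$ is a realistic per-hair scatter giving quadrat-mean
  standard errors near $10°/\sqrt{20} \approx 2.2°$. The sampler is the
  Best–Fisher rejection method, written here because no installed
  package provides circular distributions.

It does **not** emulate: vein networks or the anal-region compliance
(where the real model over-weights the edge term), spatial correlation
of hair angles within a quadrat, digitization error in the polylines,
or any 3-D corrugation height. Consequently, passing recovery tests
show that the *estimation machinery* is unbiased and well-conditioned
under the model's own assumptions — they do not show that the model is
adequate for any particular real wing, which is exactly what the
specimen-level reproduction (when the digitization files are supplied)
is for.

Default generator parameters are fixed at the study conditions —
truth $(W_1, W_2) = (0.544, 196\ \mu m)$, 24 quadrats × 20 hairs,
$\sigma = 10°$ — and the test suite checks that calibration on 50
seeded replicates recovers $W_1$ within ±0.1 and $W_2$ within ±15% in
at least 90% of replicates, on a reduced search grid (0.008 × 4 µm over
[0, 1.2] × [0, 600] µm). Property tests use 100 random polylines
against a dense-sampling nearest-point oracle (10⁵ samples per
polyline, 10⁻³ relative tolerance) and 21-point-per-axis naive-loop SSR
comparisons; these sizes keep the whole suite under a minute while
leaving the assertions sharp.

## A short tour

```{r tour, eval = FALSE}
cfg  <- synthetic_config(seed = 7)
geom <- generate_wing(cfg)
quad <- sample_quadrats(geom, cfg)

fit <- grid_search(quad, geom,
                   w1 = seq(0, 1.2, by = 0.008),
                   w2 = seq(0, 600, by = 4))
glance(fit)          # optimum and RMS residual
autoplot(fit)        # SSR heat map, optimum crossed

fld <- field_on_grid(geom, fit$params, spacing = 100)
autoplot(fld, geom = geom)   # arrows over margin + ridges

st <- direction_stats(quad, geom, params = fit$params)
st$bias              # upslope / edgeward / distal counts + exact tails
st$fidelity          # R^2, residual quartiles
```

## Known limitations

* The upslope proxy ignores the true 3-D gradient; near wide, shallow
  corrugation the direction to the nearest ridge can differ from the
  actual slope.
* Constant $W_1$, $W_2$: the model deliberately does not vary the
  weights spatially (e.g. damping edge attraction near the wing base),
  so it inherits the known artifact of over-weighted edge attraction in
  posterior-proximal regions with sharp margin corners.
* Calibration treats quadrat means as independent observations with
  homogeneous error; no per-quadrat weighting by hair count or mean
  standard error is applied.
* The CSV readers accept a documented superset of the digitization
  dialect (configurable column names, margin/ridge feature column or
  file pair); files in other conventions need a `col_map`.
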