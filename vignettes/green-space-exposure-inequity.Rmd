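---
title: "Methods: street-view green space exposure inequity in a 15-minute city"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: street-view green space exposure inequity in a 15-minute city}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(greenexposure)
```

This vignette documents the models, conventions and design choices behind
the package: what each statistic assumes, which knobs matter, what the
synthetic city does and does not emulate, and the numerical rules applied at
boundaries and degenerate inputs.

## The measurement chain

Eye-level greenery is measured where residents actually walk. Street
networks are sampled at a fixed interval (200 m by default, densifiable to
50 m); each sample point carries up to four views at the cardinal headings.
A semantic segmenter turns each view into a pixel-class raster; the package
ingests such rasters directly (PNG class raster + JSON palette sidecar) and
also provides a rule-based HSV green classifier for RGB input. That
classifier is a deterministic color-threshold rule, adequate for fixtures
and synthetic imagery; on photographs it is no replacement for a trained
segmentation model, and the pipeline is designed so any segmenter's label
output drops in.

**Point GVI** is the ratio of sums over the views — pooled green pixels over
pooled total pixels — not the mean of per-view ratios. For equal-sized views
the two coincide; for unequal sizes the ratio of sums weights views by their
pixel count, which is the defining convention here. GVI is invariant to view
order and always lies in [0, 1].

**Quality control** is an explicit, reproducible exclusion mechanism: a
point is dropped iff its id is on the exclusion list (e.g. views shot in the
non-green season) or it has fewer than `min_views` views (default 4).
Excluded points carry no GVI and never reach later stages, so a judgement
call that was originally visual becomes an auditable input file.

**Community exposure** at walking time *t* minutes is the unweighted mean
GVI of the kept points within a Euclidean buffer of radius *t* × 72 m/min
grown outward from the community polygon. 72 m/min is the conventional
pedestrian speed in 15-minute-city accessibility work; the 5/10/15/30-minute
grid gives 360/720/1080/2160 m. Points exactly on the buffer rim count as
inside (a deterministic tie rule). An empty buffer yields a *missing* value,
never zero, and such communities are excluded listwise from the inequity and
clustering stages with a logged count. Network-distance isochrones are
deliberately out of scope: the buffers are Euclidean radii derived from
walking time.

Membership in a buffered polygon is evaluated with the exact predicate
`dist(point, polygon) <= r`, valid for any simple polygon; the explicit
`buffered_boundary()` constructor (offset edges + vertex arcs) exists for
convex polygons, which covers the rectangular communities the generator
produces, and is used for display and area checks only. Because distances
are computed once and thresholded per radius, point sets are exactly nested
across the four radii.

## Location entropy

With community exposure $G_i$ and rental price $p_i$ (the socioeconomic
proxy),

$$ LQ_i = \frac{G_i / p_i}{\sum_j G_j \,/\, \sum_j p_j}. $$

$LQ_i$ is the green service obtained per unit of price in community $i$
relative to the study-area rate: above 1 is better-than-average green
service for what residents pay. Two algebraic facts are asserted at run
time: the price-weighted mean of LQ is identically 1 (to 1e-12), and LQ is
invariant to rescaling all prices or all exposures by a common factor. The
denominator uses the per-buffer sums of community means, so each buffer has
its own baseline — which is why the seven-level summaries differ by buffer.

The seven levels use half-open, lower-inclusive bins
$[0,0.2), [0.2,0.5), [0.5,1), [1,1.5), [1.5,2), [2,5), [5,\infty)$ — printed
level labels in this literature overlap at the edges, so an explicit
convention is required for reproducibility; lower-inclusive makes LQ = 1
"above average" and LQ = 5 "high". Percentages are rounded half-up to two
decimals, the convention such summary tables use. Tail shares report
LQ < 0.5 (less than half the average green service per unit price) and
LQ ≥ 2 (more than double).

## Bivariate Moran's I and LISA

Prices and exposures are z-scored with the sample (n−1) standard deviation —
the convention consistent with the (N−1) normalizer below, and the one the
naive test oracle uses too. The global cross-correlation between price at a
community and greenness at its neighbors is

$$ I_{P,A} = \frac{N \sum_i \sum_{j \ne i} w_{ij} z_i^P z_j^A}{(N-1) \sum_{i}\sum_{j \ne i} w_{ij}}, $$

and the local form is $I'_i = z_i^P \sum_j w_{ij} z_j^A$. Some presentations
write the local statistic as the bare lag $\sum_j w_{ij} z_j^A$; without the
focal factor the quadrant typology and the exact local-to-global identity
$N \sum_i I'_i / ((N-1) S_0) = I$ are impossible, so the product form is
implemented and the bare lag is still returned per unit. With $A = P$ the
bivariate statistic reduces exactly to univariate Moran's I under this
standardization — a reduction the tests cross-check against an independent
univariate implementation.

**Weights.** Queen contiguity (any shared boundary point, snap tolerance
1e-6 m) over the community polygons, row-standardized, is the default —
the common convention for polygon lattices; k-nearest-neighbor weights are
provided for sensitivity analysis, with distance ties broken by lower index
so duplicate centroids are handled deterministically. Self-weights are
forbidden. Islands are permitted: they keep zero rows after
standardization, get zero lag and local statistic, an NA pseudo p, and are
reported rather than fatal.

**Inference.** Significance is by permutation only (no normal
approximation). Globally, the context variable is permuted across units
`n_perm = 999` times and the two-sided pseudo p is
$(1 + \#\{|I_{perm}| \ge |I_{obs}|\})/(1 + n_{perm})$. Locally, the
conditional scheme holds $z_i^P$ fixed, permutes the remaining context
values, and draws unit $i$'s neighbors from the permuted pool. Quadrants
High-High / High-Low / Low-Low / Low-High come from the signs of
$(z_i^P, \text{lag}_i)$, with zero classified as "High" (a documented tie
rule; ties occur with probability zero for continuous data). No multiplicity
correction is applied to the significance flag by default — the convention
of standard LISA tooling — but Benjamini–Hochberg-adjusted p-values are
returned alongside for an FDR filter. Every permutation routine takes an
explicit seed and is bit-reproducible.

## The synthetic city

The generator plants known ground truth at the magnitudes of a real
single-city study of this kind:

- **Extent and streets:** 12 km × 12 km, street grid every 200 m with
  vertex jitter 0.15 (streets are not perfectly straight; jitter also keeps
  sampling positions from coinciding with every intersection), sampled
  every 200 m → 7560 sample points at the defaults, matching the
  several-thousand-point scale of street-view exposure studies.
- **Greenness field:** a linear west-to-east declining trend (0.35 → 0.15
  by default, emulating a green old core and less green new districts) plus
  kernel-smoothed noise (Gaussian-kernel weighted average of iid
  Normal(0, 0.08) knot values, length scale 1500 m), clipped to [0, 1]. A
  kernel smoother rather than a full Gaussian-random-field model: it is
  sufficient for a smooth center–periphery gradient and keeps the package
  dependency-free.
- **Views:** four 80×60 px label images per point whose pooled green count
  is exactly `round(f × 4 × H × W)` for planted fraction f, so the GVI
  stage recovers the field to within one part in 19200.
- **Communities:** 499 polygons from a seeded recursive binary-space
  partition of the extent into rectangles (split the largest cell at a
  uniform 0.35–0.65 position along its longer side). The cells are convex,
  exactly interior-disjoint and exactly tile the extent, and their queen
  adjacency is well defined without geometry-library dependencies. Real
  community boundaries are of course not rectangles; nothing downstream
  assumes rectangularity.
- **Prices:** $p_i = \alpha + \beta (W \cdot G)_i + \varepsilon_i$,
  $\varepsilon_i \sim N(0, \sigma^2)$, floored at 1 currency-unit/m²
  (location entropy divides by price). Defaults α = 40, β = −30, σ = 5
  currency/m²: β < 0 plants the "wealthier communities in less green
  surroundings" pattern at a strength that leaves the association weak at
  the unit level but clearly detectable at n = 499 — the regime such
  studies report — while β = 0 gives an exact null for calibration. The
  price lag is driven by the 15-minute-buffer exposure by default.

What the generator does **not** emulate: camera optics, occlusion, seasonal
leaf-off, segmentation error (labels are exact by construction), irregular
street topology, multipolygon or hole-bearing community boundaries, and any
correlation between price and non-greenness amenities. Passing tests
therefore demonstrate the correctness of the *computation* under known
ground truth, not the robustness of GVI measurement on real photographs.

## Numerical and degenerate-input rules

- Coordinates are planar meters throughout; no geographic math anywhere.
- Intersection dedup of sample points: exact coordinate equality after
  rounding to 1e-6 m.
- Constant price or exposure vectors are an error for Moran's I (the
  z-score is undefined), named as such.
- Zero or negative prices abort location entropy naming the offending
  community; a zero GVI total likewise.
- Missing values are written as empty CSV fields, never sentinels.
- One master seed; each stage derives its own seed from the master and the
  stage name, all below 2³¹ and logged in the run config/manifest, so a run
  is bit-identical given the config.

## Problem sizes used by the test and replication suites

The shipped suites exercise: oracle equivalence of the sparse Moran
implementation against a naive dense double loop on 100 random instances of
up to 50 units (tolerance 1e-12); permutation calibration with 500 null
replicates on a 10×10 queen lattice at 999 permutations (the type-I error at
α = 0.05 must land in [0.03, 0.07]); and planted-effect recovery with 200
price redraws on the full 499-community city at 999 permutations, requiring
a negative, significant global I in at least 90% of replicates. These sizes
give stable Monte-Carlo estimates while keeping a full run of suite plus
pipeline in the low minutes on one CPU.

## Known limitations

- The HSV classifier is a stand-in; real imagery needs a trained segmenter,
  whose label rasters the pipeline ingests unchanged.
- Euclidean buffers ignore the street network's actual walkable structure;
  a network-isochrone variant would change community exposure where barriers
  (rivers, railways) matter.
- Exposure means are unweighted over sample points, so denser street
  segments contribute more points and hence more weight.
- The LISA significance filter is per-unit at α with no correction by
  default; cluster counts therefore depend on the α convention, and the FDR
  column should be preferred when counts are compared across studies.
- `buffered_boundary()` constructs polygons for convex input only; general
  membership is always available through the distance predicate.
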