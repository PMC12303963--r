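---
title: "Quantifying landscape color structure and its perceptual correlates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying landscape color structure and its perceptual correlates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromascape)
```

## The problem

Traditional Japanese stroll gardens are widely reported to have restorative,
"healing" effects on visitors, and garden designers have long manipulated
the *color structure* of views — which colors appear, how much area each
occupies, how intricately each is arranged, and whether each is gathered
into focal patches or dispersed — to shape that experience. chromascape
implements a quantitative pipeline that links these physical color
properties of landscape photographs to perceptual evaluations: it segments
images into six named color categories, characterizes each color layer
with three spatial metrics, reduces semantic-differential ratings to a
small set of perceptual factors, clusters scenes into landscape types, and
correlates the color metrics with the perceptual factors.

Because garden photograph collections and their rating data are rarely
distributable, the package ships a synthetic-data module that generates
every input with known ground truth — fractal masks with analytic
dimensions, composite images with exactly known compositions, rating
matrices with planted factor structure, and joint datasets with planted
correlations. All validation in the test suite and the acceptance script
runs against this planted truth.

## Color segmentation

Images are 8-bit sRGB. Each of the six categories (red, yellow, brown,
gray, white, green — the chromatic vocabulary of a traditional garden:
maple, gold leaf, timber, stone, sand/sky, foliage) is defined by
inclusive per-channel ranges; a pixel belongs to a category when its R, G
and B values all fall inside that category's ranges
(`default_palette()`).

The ranges overlap — `(150, 150, 150)` satisfies both brown and gray — so
two modes are provided. `non_exclusive` returns the six raw binary masks
(a pixel may appear in several). Wherever a partition is required
(composition proportions, the global diversity index), an `exclusive`
assignment is used: the first matching category in a fixed precedence
order, `white > green > red > yellow > gray > brown`, which orders
categories from the most specific range volume to the widest catch-all.
The precedence is configurable; because synthetic ground-truth images are
painted only with collision-free pixel values (`safe_color_boxes()`),
their recovery does not depend on the precedence choice at all.

Pixels matching no category are *unclassified*. They are excluded from the
proportion denominator rather than treated as a seventh category — the
diversity index below is defined over the six color categories — and the
unclassified fraction is reported per image. Brown's B range (54–194) is
wider than its other channels and subsumes gray's; it is implemented
verbatim as given, since nothing in the range table licenses a correction.

## The three color metrics

For each color layer the package computes a triplet (*D*, *H′*, *C*).

**Fractal dimension D** (spatial complexity). Box counting: overlay grids
of side `eps`, anchored at the top-left corner with partial boxes at the
right/bottom edges included, and count boxes containing at least one mask
pixel. *D* is the OLS slope of `log N(eps)` on `log(1/eps)`. The default
ladder is dyadic, 1, 2, 4, …, 2048 pixels (12 scales), with sizes
exceeding the shorter image side dropped automatically. A single anchored
grid (no offset averaging) keeps the estimator exactly reproducible by an
exhaustive per-box oracle, which the test suite exploits. Trailing scales
where the count has saturated at `N = 1` are trimmed beyond the first,
because a saturated tail only flattens the slope. Filled masks give
*D* ≈ 2, one-pixel-wide lines *D* ≈ 1, and a depth-5 Sierpinski carpet is
recovered within 0.05 of `log 8 / log 3 ≈ 1.8928` (exactly, when the
ladder matches the carpet's base-3 construction).

**Diversity H′** (evenness). Across categories, the Shannon–Wiener index
`H' = -sum(p_i log p_i)` of the six area proportions, between 0 (one
color) and `log 6 ≈ 1.79` (equal sixths). Per color, the package needs a
*spatial* evenness of one layer rather than an across-category entropy;
the convention here partitions the mask into an 8×8 block grid (integer
splitting) and takes the entropy of the color's pixel shares across
blocks, normalized by `log 64` to `[0, 1]`: 0 when the color is confined
to one block, 1 when spread evenly. This block-partition convention is a
package design choice — a per-color entropy is not otherwise well defined —
and both the grid and the normalization are configurable.

**Concentration C** (clustering). Moran's I spatial autocorrelation of the
color's presence. Pixel-level Moran's I on megapixel images is an `O(N^2)`
computation over the weight structure; the package instead coarsens the
mask to a block-mean *presence lattice* (default 100×100, capped at the
mask size), whose cells hold the fraction of color pixels per block, and
computes Moran's I there with rook contiguity and row-standardized
weights (queen and binary-weight variants available). Compact patches give
*C* near +1, checkerboard-like dispersion gives −1 (exactly, on a unit
checkerboard under row-standardized rook weights), spatial randomness
gives values near 0. The generalization of binary per-pixel presence to
block means in `[0, 1]` is documented rather than hidden: it is what makes
the statistic tractable, and the implementation is verified against a
brute-force dense double sum on small lattices to 1e-10.

Colors with empty masks yield explicit `NA` records, never silent zeros,
so downstream correlations use pairwise-complete observations.

## The psychometric arm

**Healing-rating selection.** Candidate views are rated on a 7-point
healing scale by a panel (23 raters by default). Per image the package
reports mean, median (midpoint rule for even panels) and sample standard
deviation (n−1). A view is *selected* when mean ≥ 5.0 and median ≥ 5.0
(inclusive) and sd < 1.2 (strict) — a consensus filter: high central
tendency with low disagreement.

**Factor analysis.** Semantic-differential ratings (24 bipolar items,
5-point scale) are correlated over observations and factored by
principal-axis extraction: the correlation-matrix diagonal is replaced by
communality estimates, initialized at squared multiple correlations and
iterated to 1e-6 (at most 100 iterations; non-convergence is flagged, and
Heywood communalities are clamped at 1 with a warning). The number of
factors follows the Kaiser criterion — eigenvalues of the *unreduced*
correlation matrix strictly greater than 1 — or can be fixed. The
observation unit is configurable: participant×image rows (the default,
n = 58 × 42 = 2436 at study dimensions) or image means.

Rotation is varimax with Kaiser row-normalization, implemented by the
classic pairwise planar-rotation algorithm with the closed-form angle per
factor pair. The pairwise form was chosen deliberately: gradient/SVD
formulations stall on the symmetric plateau where all items load equally
on a pair of factors (a case the test suite covers by rotating perfect
simple structure 45 degrees), while the planar angle formula resolves it;
on generic loadings the implementation attains the same criterion value
as `stats::varimax`, which serves as the independent cross-check in the
tests. Rotation preserves communalities to machine precision; factors are
then ordered by explained variance and sign-fixed so each column's
largest loading is positive.

Each factor's eigenvalue (sum of squared loadings) divided by the number
of items gives its contribution rate; with 24 standardized items, total
variance is 24, so `contribution = 100 * eigenvalue / 24` and the
cumulative contribution is the running sum. Applied to the six published
eigenvalues shipped as `garden_sd_eigenvalues`, this bookkeeping
reproduces the published cumulative 64.313% (half-up rounding at 3
decimals, the convention of published tables; R's own `round()` is
half-to-even and is not used for table output).

Items are screened after rotation: dropped when the largest absolute
loading is below 0.40 or when the gap to the second-largest is below 0.20
(cross-loaders); survivors are assigned to their maximum-loading factor.
Factor scores are Thurstone regression scores on standardized items
(Bartlett scores available); image-level scores are participant means,
z-scored across images.

**Clustering and correlation.** Images are clustered on their factor-score
profiles by Ward's minimum-variance method on squared Euclidean distances
(`hclust(method = "ward.D")` on squared distances), with k fixed (default
8) or chosen to maximize the mean silhouette width over k = 2…10.
Per-cluster mean z-scores form the landscape-type profile table. Finally,
each of the 18 color metrics (6 colors × D/H′/C) is Pearson-correlated
with each factor over images, with two-sided p-values from the
t-distribution (n−2 df) and `*` / `**` flags at 0.05 / 0.01. Raw p-values
are reported by default, matching the reporting convention of the source
literature for this table; a Benjamini–Hochberg column is available
opt-in.

## The synthetic-data generators

The generators exist so that every pipeline stage can be validated against
planted truth; their defaults are the study conditions.

* `gen_mask()` rasterizes deterministic patterns: IFS fractals with
  analytic dimensions (carpet `log8/log3`, triangle `log3/log2`, Cantor
  dust `log4/log3`, Vicsek `log5/log3`), filled blocks, lines,
  checkerboards, and disc clusters (one compact disc versus scattered
  discs, for concentration-ordering checks).
* `gen_landscape_image()` paints planted masks with pixel values drawn
  from collision-free sub-boxes of each category's range, so exclusive
  segmentation recovers the planted masks *exactly*; the sub-boxes are
  re-verified against the palette at every call. Layouts: `blocks` (exact
  pixel-count compositions), `blobs` (compact random patches), and
  `fractal_per_color` (a carpet pattern per color strip).
* `gen_healing_ratings()` plants per-image mean/sd profiles: pass images
  at mean 5.5–6.5, sd 0.4–0.9; fail images at mean 3.0–4.6, sd 0.5–1.0 —
  realistic strong-consensus versus mediocre views with clear margins on
  either side of the 5.0/1.2 thresholds — with a pass fraction of 42/150,
  mirroring a 150-candidate shoot from which 42 views survive. A 23-rater
  panel recovers the planted pass/fail status with ≥ 95% accuracy.
* `gen_sd_ratings()` builds 5-point Likert responses from planted loadings
  (default: six factors, four items each, loading 0.7) via a latent
  normal model `X = F Λ' + E` discretized at cut points
  (−1.5, −0.5, 0.5, 1.5), at the 58 × 24 × 42 study dimensions.
* `gen_joint_dataset()` draws image rows from a multivariate normal with a
  planted metric×factor cross-correlation block (validated positive
  semi-definite).

All randomness flows through explicit seeds (`with_local_seed()` leaves
the caller's RNG untouched), so identical spec + seed gives bit-identical
output.

What the generators do *not* emulate: real photographs' gradients, mixed
pixels at region boundaries, lighting variation, and colors outside the
six ranges; real raters' item-order effects, response styles and missing
data. Passing tests therefore demonstrate the *estimators* are correct
and recover planted structure under the stated noise models — not that
any particular empirical value from field photographs is reproduced.

## Numerical choices and degenerate inputs

* Box-count regression needs ≥ 3 usable scales and non-constant counts;
  otherwise an insufficient-scales error is raised.
* Moran's I on a constant lattice is undefined and errors explicitly
  (degenerate input), as do empty masks for any metric.
* Ward merge ties are resolved by `hclust`'s deterministic ordering, so
  runs are reproducible given input order.
* Singular correlation matrices in factor scoring fall back to a
  1e-8-ridge inverse with a warning.
* Integer block splitting assigns row `r` (1-based) to block
  `floor((r-1) * g / H) + 1`, so uneven divisions spread remainder pixels
  across blocks; block means always use the true block areas.

## Problem sizes used in validation

The test suite and `scripts/acceptance.R` validate at deliberately modest
sizes chosen to exercise every code path with exact oracles: box-count
oracle masks up to 64×64, Moran brute-force lattices up to 12×12, a
243×243 depth-5 carpet for dimension recovery, 200 images × 23 raters for
the selection filter, 500 observations × 20 seeds for factor recovery, 42
images in 6 dimensions for clustering, n = 50000 (and 1000 replicates of
n = 42) for correlation recovery, and an 8-image bundle for the
end-to-end determinism check. These sizes are the package's validation
conditions; all of them can be scaled up through the same interfaces.

## Known limitations

* The raw-RGB range rules are not a perceptual segmentation; shadows,
  highlights and mixed pixels fall outside all ranges by design, and the
  unclassified fraction should be inspected per image.
* The per-color H′ is a block-partition convention, not a universal
  definition; comparisons across studies should state the grid.
* The concentration index depends on the lattice resolution and weight
  scheme; defaults are reported in every manifest.
* Factor-analysis results at small n (few images, image-mean mode) can
  fail to converge or retain noise factors under Kaiser's rule; the
  solution object flags non-convergence rather than hiding it.
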