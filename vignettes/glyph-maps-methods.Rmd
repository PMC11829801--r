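---
title: "Glyph maps for spatial compositional data: model, geometry and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Glyph maps for spatial compositional data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(fig.width = 7, fig.height = 5)
suppressPackageStartupMessages(library(spotglyphs))
```

## The visualization problem

Spatial transcriptomics assays profile gene expression at known positions in
a tissue section, usually at multicellular "spot" resolution. Cell-type
deconvolution (e.g. reference-free approaches applied to Visium arrays)
turns each spot's expression into a vector of cell-type proportions — a
point on the simplex — attached to a planar centroid. Displaying hundreds to
thousands of such compositions *in place* is the problem this package
addresses.

The common solution replaces each spot with a small pie chart ("scatter pie"
plot). Pie charts encode proportions as angles, and perceptual work on chart
reading consistently finds angle comparisons less accurate than length
comparisons, especially for subtle differences; dense fields of small
high-contrast pies also produce moiré-like artifacts. The alternative
implemented here replaces each spot with a stacked bar: proportions become
segment lengths stacked against a shared baseline, so the first and last
categories of the stacking order can be compared across spots against a
common reference edge. The package provides both glyphs so they can be
compared side by side on the same data.

## Data model

The two inputs are a proportion table (rows = locations, columns =
categories, non-negative reals) and a coordinate table (the same locations,
two planar coordinates), matched by row label. `alignSpots()` validates
both, joins them by label in the proportion table's row order, and
row-normalizes the compositions. The result is a `SpotComposition`, an S4
class extending `SummarizedExperiment` with categories as rows, spots as
columns, and `x`/`y` in `colData()` — so subsetting, naming and metadata
behave the Bioconductor way.

Normalization policy: rows whose sum deviates from 1 by more than `1e-6`
are renormalized with a warning rather than rejected, because deconvolution
output is near-1 but float-imperfect; a zero-sum row is a hard error (a
location with no mass cannot be drawn, and silently dropping it would hide a
data problem); missing values are rejected rather than imputed, because 0 is
a meaningful proportion. Whether a tool of this kind should renormalize
imperfect rows or draw them at their literal height is a genuine design
fork; renormalization-with-warning was chosen for drop-in usability and is
stated here rather than left implicit.

## Layout geometry

All geometry is computed by a pure layout engine, independent of any
graphics backend, in plot units with y increasing upward (image-convention
input must be flipped by the caller; `flipAxes()` helps, and one fixed
mathematical convention was preferred over guessing).

**Scale estimation.** If a footprint size is not supplied, each axis is
estimated independently as the coordinate range divided by the square root
of the number of spots:

$$\mathrm{size}_x = \frac{\max(x) - \min(x)}{\sqrt{n}}, \qquad
  \mathrm{size}_y = \frac{\max(y) - \min(y)}{\sqrt{n}}.$$

On an $n \times n$ grid with unit spacing this gives $(n-1)/n < 1$, so
auto-scaled glyphs on a regular grid never collide. An axis with zero range
borrows the other axis's estimate (falling back to 1 when both are zero),
with a warning each time — any positive finite choice works for a degenerate
1-D arrangement, and the warning keeps the substitution visible.

**Bars.** With effective width $w = \mathrm{size}_x - \mathrm{padding}_x$
and height $h = \mathrm{size}_y - \mathrm{padding}_y$, the bar of a spot at
$(x, y)$ spans $[x - w/2,\, x + w/2] \times [y - h/2,\, y + h/2]$. Category
$k$ with proportions $p_1, \dots, p_K$ occupies the vertical slice

$$\Big[\,y - \tfrac{h}{2} + h\sum_{j<k} p_j,\;\;
       y - \tfrac{h}{2} + h\sum_{j\le k} p_j\,\Big],$$

computed from one shared cumulative-sum vector per spot, so adjacent
boundaries are equal *exactly* (not merely within tolerance) and the
segments tile the bar. Glyphs are centered on the centroid on both axes;
bottom-anchoring was rejected because it visually displaces the glyph from
the spot it annotates. Stacking runs bottom-to-top in column order, putting
the first category on the shared baseline; `reorderCategories()` moves
categories of interest to the ends of the order, where the common baseline
makes cross-spot comparison easiest.

**Pies.** The radius is $\min(w, h)/2$; wedges start at 12 o'clock and
proceed clockwise in category order, wedge $k$ subtending $360\,p_k$
degrees. The convention is stated explicitly because nothing forces it;
tests pin it down.

**Padding semantics.** Padding is *subtracted* from the size allotment
(drawable extent = size − padding) rather than added outside it, so `size`
remains the single spacing unit and padding only inserts whitespace between
glyphs. The alternative — padding as an additive outer margin — is
observationally different; the subtractive choice is documented prominently
because other implementations may differ, and the validity rule
`padding < size` follows from it (otherwise the drawable extent would be
non-positive).

**Zero-proportion segments** are kept in the layout with zero height or
angle, so the segment table and the exported JSON have a stable shape;
renderers skip them.

**Overlap diagnostics.** Oversized scale factors make glyphs overlap and
categories indistinguishable; `detectOverlaps()` reports every pair of
spots whose full footprints (boxes for bars, circles for pies) intersect
with positive area. Overlaps are reported, never resolved automatically —
tuning size and padding is deliberately left to the user, and the plot
pipeline only warns.

**Geometry export.** `writeGlyphLayout()`/`readGlyphLayout()` serialize the
layout as JSON at 17 significant digits (round-trip exact for doubles),
validated on write and read against the schema in
`inst/extdata/glyph-layout.schema.json` by a lightweight structural
validator (type/required/properties/items/enum subset of JSON Schema).

## Rendering

`plotGlyphs()` draws the precomputed rectangles or wedge polygons with
ggplot2 and returns the plot object for further customization;
`renderFigure()` writes PNG, SVG or PDF, and `renderComparison()` produces
the two-panel pie-versus-bar figure with a shared palette and a single
collected legend. Choices worth knowing:

* **Equal aspect ratio is always enforced.** Unequal axis scaling would
  distort the tissue geometry the plot exists to preserve.
* **Palette.** The automatic palette is the conventional rainbow: $k$ hues
  evenly spaced from red at full saturation and value, a pure function of
  $k$. With many categories neighboring hues converge; supply a custom
  palette (or a palette file in the CLI) when the automatic one becomes
  indistinguishable — palette optimization is intentionally out of scope.
* **Legend order equals stacking order** (first category at the top), so
  legend and bar baseline read consistently.
* **Segment borders default to off** (edge width 0): black borders around
  very small segments produce moiré-like artifacts; the width is
  user-settable in points.
* **Determinism.** SVG output contains no timestamps; rendering the same
  layout twice is byte-identical, which the tests assert.
* Wedge outlines are polygonal approximations of arcs sampled every 2
  degrees — at most ~0.05% radial error, invisible at plot scale; the
  *layout* wedge angles remain exact.

## Synthetic data generator

Real deconvolution output is not required anywhere; the generator
`simulateSpotComposition()` produces datasets with the statistical features
the visualization cares about, and is itself first-class, tested code.

Spots sit on a square or offset grid (`offset` shifts alternate rows half a
spacing and spaces rows by $\sqrt{3}/2 \cdot$ spacing — a geometric
approximation of hex-packed arrays, with no claim of fidelity to any
platform). Each category $c$ gets Gaussian intensity bumps

$$f_c(x, y) = \sum_{b} \exp\!\Big(-\frac{\lVert (x,y) - \mu_{cb}\rVert^2}{2 w^2}\Big) + 0.01,$$

the floor of 0.01 keeping Dirichlet parameters positive far from all bumps.
The spot's composition is drawn from
$\mathrm{Dirichlet}\big(\alpha \cdot f/\textstyle\sum_c f_c\big)$ with
concentration $\alpha$, and the planted truth label is the argmax of the
mean composition (ties to the lowest category index). This is the simplest
generative model producing smooth compositional fields with distinct
dominant-category regions: adjacent spots differ less than random pairs
(tested), large $\alpha$ pins draws to the mean field (tested via recovery
of planted labels at bump centers), and every draw is exactly on the
simplex. What it does **not** emulate: count noise, platform-specific
spot geometry, segmentation errors, or spatial correlation in the *noise*
(only the mean field is spatially structured) — so passing tests show the
pipeline handles realistically shaped compositions, not that any
deconvolution method works.

`simulateShowcaseDataset()` is a fixed preset for the comparison figure: 12
categories on a 40 × 50 offset grid (2,000 spots, the scale of a typical
section), one bump per category on a fixed 4 × 3 lattice across the section
so every category dominates somewhere, bump width 6 spacings (regions tens
of spots across), concentration 5 — noisy enough to look like deconvolution
output, structured enough that regions are visible.

## Numerical choices and degenerate inputs

* Row sums are accepted as "on the simplex" within `1e-8` at layout time;
  normalization itself reproduces sums to ~1e-16.
* `estimateScaleFactors` on one spot gives zero ranges → fallback rules
  above.
* Overlap detection uses strict inequalities, so footprints that merely
  touch (the auto-scale grid case in the limit) are not flagged; circle
  overlap compares center distance to the diameter.
* Equality of adjacent segment boundaries is exact by construction; tests
  assert identity, not closeness.
* Ties in the truth argmax break to the lowest category index,
  deterministically.

## Problem sizes used in the shipped checks

The test-suite and acceptance checks run at sizes chosen to exercise every
claim while staying quick on one core: grids up to 20 × 20 for the
auto-scale sweep, 1,000 random locations for tiling/closure, 200 random
single-spot instances against the exact-rational oracle, 100 seeded
simulation runs for truth recovery, and the full 2,000-spot showcase for
the end-to-end comparison figure.

## Known limitations

* No automatic overlap resolution (jitter/repulsion) and no hexagonal or
  non-rectangular bar footprints.
* Only 2-D coordinates; 3-D data must be projected upstream.
* The renderer is not a theming system; beyond the exposed style options,
  users customize the returned ggplot object directly.
* The automatic rainbow palette degrades for large category counts; that is
  a property of any fixed hue wheel, and the remedy is a user palette.

## A worked example

```{r example, eval = FALSE}
sim <- simulateSpotComposition(10, 10, nCategories = 4, seed = 7)
ds  <- sim$dataset
estimateScaleFactors(ds)        # auto footprint: range/sqrt(n) per axis
gl  <- layoutBars(ds)           # auto-sized bar layout
nrow(detectOverlaps(gl))        # 0 on a regular grid
renderFigure(gl, outPath = "bars.png")
renderComparison(ds, outPath = "compare.png")   # pies (A) vs bars (B)
```
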