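# spotglyphs

Scatter-bar and scatter-pie glyph maps for spatial compositional data.

Spatial transcriptomics assays measure gene expression at known positions in
a tissue section, typically at multicellular spot resolution; cell-type
deconvolution turns each spot into a vector of cell-type proportions
attached to a planar centroid. **spotglyphs** visualizes such data by
replacing every point of a scatterplot with a glyph encoding the local
composition: a **stacked bar**, where category *k* of composition
*p₁ … p_K* occupies the vertical slice

    [ y − h/2 + h·Σ_{j<k} p_j ,  y − h/2 + h·Σ_{j≤k} p_j ]

of a bar of effective height *h* centered on the spot, or a **pie**, where
wedge *k* subtends 360·*p_k* degrees clockwise from 12 o'clock. Bars encode
proportions as lengths against a shared baseline, which perceptual studies
find easier to compare across locations than pie angles — the package
renders both, including a two-panel side-by-side comparison.

When no footprint size is supplied, each axis is auto-scaled as

    size_x = (max x − min x) / √n ,   size_y = (max y − min y) / √n ,

which stays just below the spacing of a regular grid of *n* spots, so
auto-scaled glyphs never collide; padding (subtracted from the footprint)
adds whitespace between glyphs, and `detectOverlaps()` reports any colliding
footprints when sizes are tuned manually.

The package is written for analysts of spot-level deconvolution output
(Visium and similar multicellular-pixel platforms), but applies to any
table of per-location proportions with planar coordinates.

## What's inside

* `alignSpots()` / `SpotComposition` — validated, label-aligned container
  (S4, extends `SummarizedExperiment`) for proportions + coordinates.
* `layoutBars()`, `layoutPies()`, `estimateScaleFactors()`,
  `detectOverlaps()`, `flipAxes()` — an exact, renderer-independent
  geometry engine, exportable as schema-validated JSON
  (`writeGlyphLayout()`).
* `plotGlyphs()`, `renderFigure()`, `renderComparison()`, `autoPalette()` —
  ggplot2 rendering to PNG/SVG/PDF with a deterministic rainbow palette.
* `simulateSpotComposition()` — seeded generator of smooth synthetic
  compositional fields (Gaussian-bump Dirichlet model) for testing without
  any download.
* `runPlot()` / `runLayout()` / `runSimulate()` and a CLI script at
  `system.file("cli", "spotglyphs.R", package = "spotglyphs")`.

## Worked example

```r
library(spotglyphs)

sim <- simulateSpotComposition(10, 10, nCategories = 4, seed = 7)
ds  <- sim$dataset
ds
#> SpotComposition: 100 spots x 4 categories
#>   x range [0, 9], y range [0, 9]
#>   categories: type01, type02, type03, type04

estimateScaleFactors(ds)
#> size_x size_y
#>    0.9    0.9

gl <- layoutBars(ds)       # auto-sized: (9 - 0)/sqrt(100) per axis
gl
#> GlyphLayout (bar): 100 spots x 4 categories, 400 segments
#>   size (0.9, 0.9) [x auto] [y auto], padding (0, 0)
#>   bbox x [-0.45, 9.45], y [-0.45, 9.45]

head(glyphSegments(gl), 4)
#>   location category x_left x_right   y_bottom      y_top   proportion
#> 1 spot0001   type01  -0.45    0.45 -0.4500000 -0.4500000 1.535928e-08
#> 2 spot0001   type02  -0.45    0.45 -0.4500000  0.4456017 9.951130e-01
#> 3 spot0001   type03  -0.45    0.45  0.4456017  0.4491947 3.992162e-03
#> 4 spot0001   type04  -0.45    0.45  0.4491947  0.4500000 8.948162e-04

nrow(detectOverlaps(gl))   # auto-scale on a regular grid: no collisions
#> [1] 0

autoPalette(4)             # evenly spaced hues from red, pure function of k
#> [1] "#FF0000" "#80FF00" "#00FFFF" "#8000FF"

renderFigure(gl, outPath = "bars.png")
renderComparison(ds, outPath = "compare.png")  # A: pies, B: bars
```

The segment table is the whole story of the plot: each spot's segments share
one cumulative grid, so `y_bottom` of a segment equals `y_top` of its
predecessor exactly, the first segment starts at `y − h/2`, the last ends at
`y + h/2`, and segment height equals proportion × h — here spot0001 is
almost entirely `type02` (p ≈ 0.995), and the zero-height `type01` segment
is kept so the table shape is stable.

From a shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli","spotglyphs.R",package="spotglyphs"))')
Rscript "$CLI" simulate --out-dir demo --seed 7 --rows 10 --cols 10 --categories 4
Rscript "$CLI" plot --proportions demo/proportions.csv \
                    --coords demo/coordinates.csv --out demo/fig.png --glyph compare
```

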