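#' Per-spot category proportions
#'
#' Returns the proportion table in the user-facing orientation: one row per
#' spatial spot, one column per category. (Internally a
#' [SpotComposition-class] stores the transpose, following the
#' SummarizedExperiment features-by-samples convention.)
#'
#' @param x a [SpotComposition-class].
#' @return numeric matrix, spots x categories, rows summing to 1.
#' @export
setGeneric("spotProportions", function(x) standardGeneric("spotProportions"))

#' Planar spot centroids
#'
#' @param x a [SpotComposition-class].
#' @return data.frame with numeric columns `x` and `y`, row names the spot
#'   labels, in spot order.
#' @export
setGeneric("spotCoords", function(x) standardGeneric("spotCoords"))

#' Number of spatial spots
#' @param x a [SpotComposition-class].
#' @return integer count of spots.
#' @export
setGeneric("nSpots", function(x) standardGeneric("nSpots"))

#' Category labels in stacking order
#' @param x a [SpotComposition-class] or [GlyphLayout-class].
#' @return character vector of category labels.
#' @export
setGeneric("categoryNames", function(x) standardGeneric("categoryNames"))

#' Spot labels
#' @param x a [SpotComposition-class].
#' @return character vector of spot labels.
#' @export
setGeneric("spotNames", function(x) standardGeneric("spotNames"))

#' Permute the category (stacking) order
#'
#' Stacking follows column order: the first category sits on the shared
#' baseline at the bottom of every bar, the last at the top. In a stacked-bar
#' map the first and last categories are the easiest to compare across
#' locations because they keep a common baseline, so moving categories of
#' interest to the ends of the order improves readability. `newOrder` must be
#' an exact permutation of the current categories.
#'
#' @param x a proportion matrix (spots x categories) or
#'   [SpotComposition-class].
#' @param newOrder character, a permutation of `categoryNames(x)`.
#' @return object of the same class with columns (categories) permuted;
#'   per-spot values are unchanged as a multiset.
#' @examples
#' pm <- matrix(c(.2, .3, .5, .1, .6, .3), 2, 3, byrow = TRUE,
#'              dimnames = list(c("s1", "s2"), c("a", "b", "c")))
#' reorderCategories(pm, c("c", "a", "b"))
#' @export
setGeneric("reorderCategories", function(x, newOrder) standardGeneric("reorderCategories"))

#' Glyph kind of a layout
#' @param x a [GlyphLayout-class].
#' @return `"bar"` or `"pie"`.
#' @export
setGeneric("glyphKind", function(x) standardGeneric("glyphKind"))

#' Per-segment glyph geometry table
#' @param x a [GlyphLayout-class].
#' @return data.frame of segments (see [GlyphLayout-class] for columns).
#' @export
setGeneric("glyphSegments", function(x) standardGeneric("glyphSegments"))

#' Bounding box of a layout
#' @param x a [GlyphLayout-class].
#' @return named numeric vector `x_min`, `x_max`, `y_min`, `y_max`.
#' @export
setGeneric("boundingBox", function(x) standardGeneric("boundingBox"))

#' Sizing parameters of a layout
#' @param x a [GlyphLayout-class].
#' @return the [GlyphSizing-class] used to compute the layout.
#' @export
setGeneric("layoutSizing", function(x) standardGeneric("layoutSizing"))

#' Swap the two coordinate axes of a layout
#'
#' Maps every spot centroid (x, y) to (y, x) and recomputes the layout from
#' the underlying dataset with the axis roles of the sizing swapped, so bars
#' restack upright along the new vertical axis rather than being rotated as
#' raw rectangles. Applying it twice restores the original layout.
#'
#' @param x a [GlyphLayout-class] that still carries its source dataset.
#' @return a new [GlyphLayout-class] of the same kind.
#' @export
setGeneric("flipAxes", function(x) standardGeneric("flipAxes"))

#' Report pairs of spots whose glyph footprints collide
#'
#' A too-large scale factor makes neighboring glyphs overlap and individual
#' categories impossible to discern; this diagnostic reports every offending
#' pair so the user can shrink `sizeX`/`sizeY` or increase padding. Bar
#' footprints are the full effective boxes (width `sizeX - paddingX`, height
#' `sizeY - paddingY`, centered on the spot); pie footprints are the glyph
#' circles. Only intersections of positive area (or positive overlap depth
#' for circles) count, so glyphs that merely touch are not reported.
#'
#' @param x a [GlyphLayout-class].
#' @return data.frame with character columns `spot1` and `spot2`, one row per
#'   unordered colliding pair; zero rows when no glyphs overlap.
#' @export
setGeneric("detectOverlaps", function(x) standardGeneric("detectOverlaps"))
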