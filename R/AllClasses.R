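#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' SpotComposition: aligned spatial compositional dataset
#'
#' An S4 container for per-spot category proportions together with planar
#' spot centroids, the joined object every layout and rendering step
#' consumes. It extends [SummarizedExperiment::SummarizedExperiment] with
#' categories as rows (features), spatial spots as columns (samples), a
#' single `"proportions"` assay, and numeric `x`/`y` columns in `colData()`.
#' Construct it with [SpotComposition()] or [alignSpots()]; the constructor
#' row-normalizes every spot's composition, so each column of the assay sums
#' to one.
#'
#' Validity requires unique spot and category names, finite non-negative
#' proportions, and finite coordinates.
#'
#' @seealso [spotProportions()], [spotCoords()], [layoutBars()]
#' @export
setClass("SpotComposition", contains = "SummarizedExperiment")

setValidity("SpotComposition", function(object) {
  msg <- character()
  if (!"proportions" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'proportions' is missing")
  else {
    p <- SummarizedExperiment::assay(object, "proportions")
    if (!is.numeric(p)) msg <- c(msg, "'proportions' assay must be numeric")
    else if (any(!is.finite(p))) msg <- c(msg, "proportions contain non-finite values")
    else if (any(p < 0)) msg <- c(msg, "proportions contain negative values")
  }
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("x", "y") %in% colnames(cd)))
    msg <- c(msg, "colData must contain numeric 'x' and 'y' coordinates")
  else if (!all(is.finite(cd$x)) || !all(is.finite(cd$y)))
    msg <- c(msg, "spot coordinates must be finite")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "spot (column) names must be present and unique")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "category (row) names must be present and unique")
  if (length(msg)) msg else TRUE
})

#' GlyphSizing: per-spot footprint allotment and padding
#'
#' Sizing parameters of a glyph layout: `sizeX`/`sizeY` give the footprint
#' allotment of one spot along each axis (plot units), `paddingX`/`paddingY`
#' the whitespace reserved inside that allotment; the drawable glyph extent
#' is `size - padding`, so padding separates neighboring glyphs without
#' changing glyph spacing. `autoX`/`autoY` record whether each size was
#' auto-estimated from the coordinate ranges (see [estimateScaleFactors()]).
#'
#' @slot sizeX,sizeY positive numeric, footprint allotment per spot.
#' @slot paddingX,paddingY non-negative numeric, strictly less than the
#'   corresponding size.
#' @slot autoX,autoY logical flags marking estimated sizes.
#' @seealso [glyphSizing()], [layoutBars()]
#' @export
setClass("GlyphSizing",
  representation(sizeX = "numeric", sizeY = "numeric",
                 paddingX = "numeric", paddingY = "numeric",
                 autoX = "logical", autoY = "logical"),
  prototype(sizeX = 1, sizeY = 1, paddingX = 0, paddingY = 0,
            autoX = FALSE, autoY = FALSE)
)

setValidity("GlyphSizing", function(object) {
  msg <- character()
  for (s in c("sizeX", "sizeY", "paddingX", "paddingY", "autoX", "autoY"))
    if (length(slot(object, s)) != 1L)
      msg <- c(msg, sprintf("slot '%s' must have length 1", s))
  if (length(msg)) return(msg)
  if (!is.finite(object@sizeX) || object@sizeX <= 0)
    msg <- c(msg, "sizeX must be a positive finite number")
  if (!is.finite(object@sizeY) || object@sizeY <= 0)
    msg <- c(msg, "sizeY must be a positive finite number")
  if (!is.finite(object@paddingX) || object@paddingX < 0)
    msg <- c(msg, "paddingX must be a non-negative finite number")
  if (!is.finite(object@paddingY) || object@paddingY < 0)
    msg <- c(msg, "paddingY must be a non-negative finite number")
  if (!length(msg)) {
    if (object@paddingX >= object@sizeX)
      msg <- c(msg, "paddingX must be smaller than sizeX (drawable width would be <= 0)")
    if (object@paddingY >= object@sizeY)
      msg <- c(msg, "paddingY must be smaller than sizeY (drawable height would be <= 0)")
  }
  if (length(msg)) msg else TRUE
})

#' GlyphLayout: exact renderer-independent glyph geometry
#'
#' The computed geometry of a scatter-bar or scatter-pie map. `segments` is a
#' data.frame with one row per (spot, category) piece, contiguous per spot
#' and ordered by the stacking order in `categories`. For bar layouts the
#' geometry columns are `x_left`, `x_right`, `y_bottom`, `y_top`; for pie
#' layouts `center_x`, `center_y`, `radius`, `theta_start`, `theta_end`
#' (degrees, clockwise from 12 o'clock). Zero-proportion pieces are kept
#' (zero height / zero angle) so the table is schema-stable; renderers skip
#' them.
#'
#' @slot glyphKind `"bar"` or `"pie"`.
#' @slot segments data.frame of per-segment geometry (see above).
#' @slot sizing the [GlyphSizing-class] used.
#' @slot categories character, stacking order.
#' @slot boundingBox named numeric: `x_min`, `x_max`, `y_min`, `y_max`,
#'   covering every glyph footprint.
#' @slot data the source [SpotComposition-class], or `NULL` for layouts read
#'   back from JSON (then [flipAxes()] is unavailable).
#' @seealso [layoutBars()], [layoutPies()], [writeGlyphLayout()]
#' @export
setClass("GlyphLayout",
  representation(glyphKind = "character", segments = "data.frame",
                 sizing = "GlyphSizing", categories = "character",
                 boundingBox = "numeric", data = "ANY")
)

setValidity("GlyphLayout", function(object) {
  msg <- character()
  if (!(length(object@glyphKind) == 1L && object@glyphKind %in% c("bar", "pie")))
    msg <- c(msg, "glyphKind must be 'bar' or 'pie'")
  need <- if (identical(object@glyphKind, "bar"))
    c("location", "category", "x_left", "x_right", "y_bottom", "y_top", "proportion")
  else
    c("location", "category", "center_x", "center_y", "radius",
      "theta_start", "theta_end", "proportion")
  miss <- setdiff(need, colnames(object@segments))
  if (length(miss))
    msg <- c(msg, paste("segments table lacks columns:", sgOxford(miss)))
  bb <- object@boundingBox
  if (length(bb) != 4L || !all(c("x_min", "x_max", "y_min", "y_max") %in% names(bb)))
    msg <- c(msg, "boundingBox must be named x_min, x_max, y_min, y_max")
  if (length(msg)) msg else TRUE
})
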