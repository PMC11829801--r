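# Pure geometry engine: proportions + centroids -> exact glyph coordinates.
# All geometry is computed in plot units with y increasing upward; inputs in
# image convention (y down) should be flipped by the caller.

#' Construct glyph sizing parameters
#'
#' Builds a [GlyphSizing-class], auto-estimating any size not supplied from
#' the coordinate ranges via [estimateScaleFactors()] (each axis is estimated
#' independently, so supplying one size still auto-estimates the other).
#' Padding is subtracted from the size allotment: the drawable glyph extent
#' is `size - padding`, which keeps `size` the single spacing unit while
#' padding only inserts whitespace between glyphs.
#'
#' @param sizeX,sizeY positive numeric footprint allotment per spot (plot
#'   units), or `NULL` to auto-estimate (requires `coords`).
#' @param paddingX,paddingY non-negative whitespace inside the allotment
#'   (plot units); must stay below the corresponding size.
#' @param coords a [SpotComposition-class] or coordinate table, needed when
#'   a size is auto-estimated.
#' @return a [GlyphSizing-class].
#' @section Errors: `spotglyphs_sizing_error` when padding is not smaller
#'   than size or a supplied size is not positive.
#' @export
glyphSizing <- function(sizeX = NULL, sizeY = NULL,
                        paddingX = 0, paddingY = 0, coords = NULL) {
  autoX <- is.null(sizeX)
  autoY <- is.null(sizeY)
  if (autoX || autoY) {
    if (is.null(coords))
      sgStop("spotglyphs_sizing_error",
             "coords are required to auto-estimate missing scale factors")
    est <- estimateScaleFactors(coords)
    if (autoX) sizeX <- est[["size_x"]]
    if (autoY) sizeY <- est[["size_y"]]
  }
  bad <- c(
    if (!is.numeric(sizeX) || length(sizeX) != 1L || !is.finite(sizeX) || sizeX <= 0)
      "sizeX must be a positive number",
    if (!is.numeric(sizeY) || length(sizeY) != 1L || !is.finite(sizeY) || sizeY <= 0)
      "sizeY must be a positive number",
    if (!is.numeric(paddingX) || length(paddingX) != 1L || !is.finite(paddingX) || paddingX < 0)
      "paddingX must be non-negative",
    if (!is.numeric(paddingY) || length(paddingY) != 1L || !is.finite(paddingY) || paddingY < 0)
      "paddingY must be non-negative"
  )
  if (is.null(bad) || !length(bad)) {
    if (paddingX >= sizeX)
      bad <- c(bad, sprintf("paddingX (%g) must be smaller than sizeX (%g)", paddingX, sizeX))
    if (paddingY >= sizeY)
      bad <- c(bad, sprintf("paddingY (%g) must be smaller than sizeY (%g)", paddingY, sizeY))
  }
  if (length(bad)) sgStop("spotglyphs_sizing_error", paste(bad, collapse = "; "))
  methods::new("GlyphSizing", sizeX = as.numeric(sizeX), sizeY = as.numeric(sizeY),
               paddingX = as.numeric(paddingX), paddingY = as.numeric(paddingY),
               autoX = autoX, autoY = autoY)
}

#' Automatic per-axis scale-factor estimation
#'
#' Estimates the glyph footprint allotment for each axis as the coordinate
#' range (max minus min) divided by the square root of the number of spatial
#' spots. On a regular grid this yields a footprint slightly below the grid
#' spacing, so auto-scaled glyphs never collide. Degenerate arrangements are
#' handled with a warning (`spotglyphs_degenerate_axis_warning`): an axis of
#' zero range borrows the other axis's estimate, and if both ranges are zero
#' the estimate falls back to 1.
#'
#' @param x a [SpotComposition-class] or a coordinate table accepted by
#'   [validateCoordinates()].
#' @return named numeric vector `c(size_x =, size_y =)`, both positive.
#' @examples
#' xy <- data.frame(x = c(0, 0, 1, 1), y = c(0, 1, 0, 1),
#'                  row.names = paste0("s", 1:4))
#' estimateScaleFactors(xy)  # (1 - 0)/sqrt(4) on both axes
#' @export
estimateScaleFactors <- function(x) {
  coords <- if (methods::is(x, "SpotComposition")) spotCoords(x) else validateCoordinates(x)
  n <- nrow(coords)
  if (n < 1L)
    sgStop("spotglyphs_empty_dataset_error", "no spots: cannot estimate scale factors")
  sx <- (max(coords$x) - min(coords$x)) / sqrt(n)
  sy <- (max(coords$y) - min(coords$y)) / sqrt(n)
  if (sx == 0 && sy == 0) {
    sgWarn("spotglyphs_degenerate_axis_warning",
           "x axis has zero range; falling back to size 1")
    sgWarn("spotglyphs_degenerate_axis_warning",
           "y axis has zero range; falling back to size 1")
    sx <- sy <- 1
  } else if (sx == 0) {
    sgWarn("spotglyphs_degenerate_axis_warning",
           sprintf("x axis has zero range; borrowing y-axis size %g", sy))
    sx <- sy
  } else if (sy == 0) {
    sgWarn("spotglyphs_degenerate_axis_warning",
           sprintf("y axis has zero range; borrowing x-axis size %g", sx))
    sy <- sx
  }
  c(size_x = sx, size_y = sy)
}

resolveSizing <- function(ds, sizing, sizeX, sizeY, paddingX, paddingY) {
  if (!is.null(sizing)) {
    if (!methods::is(sizing, "GlyphSizing"))
      sgStop("spotglyphs_sizing_error", "sizing must be a GlyphSizing object")
    methods::validObject(sizing)
    return(sizing)
  }
  glyphSizing(sizeX, sizeY, paddingX, paddingY, coords = ds)
}

checkUnitRows <- function(pm) {
  dev <- abs(rowSums(pm) - 1)
  if (any(dev > 1e-8))
    sgStop("spotglyphs_input_error",
           "compositions are not on the simplex; normalize with normalizeRows()/alignSpots()")
}

#' Compute a scatter-bar layout
#'
#' For every spot centered at (x, y) with effective width
#' `w = sizeX - paddingX` and height `h = sizeY - paddingY`, the bar spans
#' `[x - w/2, x + w/2]` horizontally and `[y - h/2, y + h/2]` vertically
#' (glyphs are centered on the centroid on both axes so they never displace
#' from the spot). Categories stack bottom-to-top in column order: category k
#' occupies the vertical slice between the cumulative proportions before and
#' through k, so segment height encodes proportion as a length against the
#' shared bottom baseline. Zero-proportion segments are emitted with zero
#' height; adjacent segment boundaries are shared exactly (one cumulative-sum
#' vector per spot), so the segments tile the bar with no gaps or overlaps.
#'
#' @param ds a [SpotComposition-class].
#' @param sizing a [GlyphSizing-class], or `NULL` to build one from the
#'   remaining arguments.
#' @param sizeX,sizeY,paddingX,paddingY see [glyphSizing()]; sizes left
#'   `NULL` are auto-estimated from `ds`.
#' @return a [GlyphLayout-class] with `glyphKind == "bar"`.
#' @examples
#' ds <- alignSpots(
#'   matrix(c(.25, .75), 1, 2, dimnames = list("s1", c("a", "b"))),
#'   data.frame(x = 0, y = 0, row.names = "s1"))
#' glyphSegments(layoutBars(ds, sizeX = 1, sizeY = 1))
#' @export
layoutBars <- function(ds, sizing = NULL, sizeX = NULL, sizeY = NULL,
                       paddingX = 0, paddingY = 0) {
  stopifnot(methods::is(ds, "SpotComposition"))
  sizing <- resolveSizing(ds, sizing, sizeX, sizeY, paddingX, paddingY)
  pm <- spotProportions(ds)
  checkUnitRows(pm)
  xy <- spotCoords(ds)
  n <- nrow(pm); k <- ncol(pm)
  w <- sizing@sizeX - sizing@paddingX
  h <- sizing@sizeY - sizing@paddingY
  # one cumulative vector per spot; boundaries are shared between neighbors
  cum <- t(apply(pm, 1L, cumsum))
  if (k == 1L) cum <- matrix(cum, ncol = 1L)
  lower <- cbind(0, cum[, -k, drop = FALSE])
  y0 <- xy$y - h / 2
  seg <- data.frame(
    location   = rep(rownames(pm), each = k),
    category   = rep(colnames(pm), times = n),
    x_left     = rep(xy$x - w / 2, each = k),
    x_right    = rep(xy$x + w / 2, each = k),
    y_bottom   = as.vector(t(y0 + h * lower)),
    y_top      = as.vector(t(y0 + h * cum)),
    proportion = as.vector(t(pm)),
    stringsAsFactors = FALSE
  )
  bb <- c(x_min = min(xy$x) - sizing@sizeX / 2, x_max = max(xy$x) + sizing@sizeX / 2,
          y_min = min(xy$y) - sizing@sizeY / 2, y_max = max(xy$y) + sizing@sizeY / 2)
  methods::new("GlyphLayout", glyphKind = "bar", segments = seg, sizing = sizing,
               categories = colnames(pm), boundingBox = bb, data = ds)
}

#' Compute a scatter-pie layout
#'
#' Each spot becomes a pie glyph of radius
#' `min(sizeX - paddingX, sizeY - paddingY) / 2` centered on its centroid.
#' Wedges start at 12 o'clock and proceed clockwise in category order;
#' category k subtends `360 * p_k` degrees, so the wedge boundaries are the
#' cumulative proportions scaled to the full circle and the total subtended
#' angle is 360 degrees. Zero-proportion wedges are kept with zero angle.
#'
#' @inheritParams layoutBars
#' @return a [GlyphLayout-class] with `glyphKind == "pie"`.
#' @export
layoutPies <- function(ds, sizing = NULL, sizeX = NULL, sizeY = NULL,
                       paddingX = 0, paddingY = 0) {
  stopifnot(methods::is(ds, "SpotComposition"))
  sizing <- resolveSizing(ds, sizing, sizeX, sizeY, paddingX, paddingY)
  pm <- spotProportions(ds)
  checkUnitRows(pm)
  xy <- spotCoords(ds)
  n <- nrow(pm); k <- ncol(pm)
  r <- min(sizing@sizeX - sizing@paddingX, sizing@sizeY - sizing@paddingY) / 2
  cum <- t(apply(pm, 1L, cumsum))
  if (k == 1L) cum <- matrix(cum, ncol = 1L)
  lower <- cbind(0, cum[, -k, drop = FALSE])
  seg <- data.frame(
    location    = rep(rownames(pm), each = k),
    category    = rep(colnames(pm), times = n),
    center_x    = rep(xy$x, each = k),
    center_y    = rep(xy$y, each = k),
    radius      = r,
    theta_start = as.vector(t(360 * lower)),
    theta_end   = as.vector(t(360 * cum)),
    proportion  = as.vector(t(pm)),
    stringsAsFactors = FALSE
  )
  bb <- c(x_min = min(xy$x) - r, x_max = max(xy$x) + r,
          y_min = min(xy$y) - r, y_max = max(xy$y) + r)
  methods::new("GlyphLayout", glyphKind = "pie", segments = seg, sizing = sizing,
               categories = colnames(pm), boundingBox = bb, data = ds)
}

#' @describeIn detectOverlaps overlap diagnostics for bar and pie layouts
#' @export
setMethod("detectOverlaps", "GlyphLayout", function(x) {
  empty <- data.frame(spot1 = character(), spot2 = character(),
                      stringsAsFactors = FALSE)
  if (!is.null(x@data)) {
    xy <- spotCoords(x@data)
    cx <- xy$x; cy <- xy$y; ids <- rownames(xy)
  } else {
    seg <- x@segments
    first <- !duplicated(seg$location)
    ids <- seg$location[first]
    if (identical(x@glyphKind, "bar")) {
      cx <- (seg$x_left[first] + seg$x_right[first]) / 2
      cy <- numeric(length(ids))
      # vertical centers of the full boxes: mid of per-location extent
      h <- x@sizing@sizeY - x@sizing@paddingY
      ylo <- tapply(seg$y_bottom, seg$location, min)[ids]
      cy <- as.numeric(ylo) + h / 2
    } else {
      cx <- seg$center_x[first]; cy <- seg$center_y[first]
    }
  }
  n <- length(ids)
  if (n < 2L) return(empty)
  if (identical(x@glyphKind, "bar")) {
    w <- x@sizing@sizeX - x@sizing@paddingX
    h <- x@sizing@sizeY - x@sizing@paddingY
    hitx <- abs(outer(cx, cx, "-")) < w
    hity <- abs(outer(cy, cy, "-")) < h
    hit <- hitx & hity
  } else {
    r <- min(x@sizing@sizeX - x@sizing@paddingX,
             x@sizing@sizeY - x@sizing@paddingY) / 2
    d2 <- outer(cx, cx, "-")^2 + outer(cy, cy, "-")^2
    hit <- d2 < (2 * r)^2
  }
  hit[lower.tri(hit, diag = TRUE)] <- FALSE
  ij <- which(hit, arr.ind = TRUE)
  if (!nrow(ij)) return(empty)
  data.frame(spot1 = ids[ij[, 1L]], spot2 = ids[ij[, 2L]],
             stringsAsFactors = FALSE)
})

#' @describeIn flipAxes recompute the layout with axes swapped
#' @export
setMethod("flipAxes", "GlyphLayout", function(x) {
  if (is.null(x@data))
    sgStop("spotglyphs_input_error",
           "this layout no longer carries its source dataset; recompute from data to flip")
  ds <- x@data
  xy <- spotCoords(ds)
  flipped <- alignSpots(spotProportions(ds),
                        data.frame(x = xy$y, y = xy$x, row.names = rownames(xy)))
  sz <- methods::new("GlyphSizing",
                     sizeX = x@sizing@sizeY, sizeY = x@sizing@sizeX,
                     paddingX = x@sizing@paddingY, paddingY = x@sizing@paddingX,
                     autoX = x@sizing@autoY, autoY = x@sizing@autoX)
  if (identical(x@glyphKind, "bar")) layoutBars(flipped, sizing = sz)
  else layoutPies(flipped, sizing = sz)
})

#' @describeIn glyphKind kind of a GlyphLayout
#' @export
setMethod("glyphKind", "GlyphLayout", function(x) x@glyphKind)

#' @describeIn glyphSegments segments of a GlyphLayout
#' @export
setMethod("glyphSegments", "GlyphLayout", function(x) x@segments)

#' @describeIn boundingBox bounding box of a GlyphLayout
#' @export
setMethod("boundingBox", "GlyphLayout", function(x) x@boundingBox)

#' @describeIn layoutSizing sizing of a GlyphLayout
#' @export
setMethod("layoutSizing", "GlyphLayout", function(x) x@sizing)

#' @describeIn categoryNames stacking order of a GlyphLayout
#' @export
setMethod("categoryNames", "GlyphLayout", function(x) x@categories)

#' @rdname GlyphLayout-class
#' @param object a [GlyphLayout-class].
#' @export
setMethod("show", "GlyphLayout", function(object) {
  nloc <- length(unique(object@segments$location))
  cat(sprintf("GlyphLayout (%s): %d spots x %d categories, %d segments\n",
              object@glyphKind, nloc, length(object@categories),
              nrow(object@segments)))
  s <- object@sizing
  cat(sprintf("  size (%.4g, %.4g)%s%s, padding (%.4g, %.4g)\n",
              s@sizeX, s@sizeY,
              if (s@autoX) " [x auto]" else "", if (s@autoY) " [y auto]" else "",
              s@paddingX, s@paddingY))
  bb <- object@boundingBox
  cat(sprintf("  bbox x [%.4g, %.4g], y [%.4g, %.4g]\n",
              bb["x_min"], bb["x_max"], bb["y_min"], bb["y_max"]))
})

#' @rdname GlyphSizing-class
#' @param object a [GlyphSizing-class].
#' @export
setMethod("show", "GlyphSizing", function(object) {
  cat(sprintf("GlyphSizing: size (%g, %g), padding (%g, %g), auto (%s, %s)\n",
              object@sizeX, object@sizeY, object@paddingX, object@paddingY,
              object@autoX, object@autoY))
})
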