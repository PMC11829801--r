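# Rendering: GlyphLayout + palette + style -> ggplot object or PNG/SVG/PDF
# file. Geometry comes ready-made from the layout engine; this layer only
# draws rectangles and wedge polygons with equal axis scaling.

#' Deterministic rainbow palette for categories
#'
#' Generates `k` maximally spread categorical colors: hues evenly spaced over
#' the color wheel starting at red, at full saturation and value (the
#' conventional rainbow palette, via [grDevices::rainbow()]), as hex RGB
#' strings. The palette is a pure function of `k`. With many categories
#' neighboring hues converge; supply a hand-picked palette to the renderer
#' when the automatic one becomes indistinguishable.
#'
#' @param categories either a positive integer (number of categories) or a
#'   character vector of category names; names, when given, name the result.
#' @return character vector of `#RRGGBB` colors, pairwise distinct.
#' @examples
#' autoPalette(3)                 # "#FF0000" "#00FF00" "#0000FF"
#' autoPalette(c("astro", "oligo"))
#' @export
autoPalette <- function(categories) {
  if (is.numeric(categories) && length(categories) == 1L) {
    k <- as.integer(categories)
    nms <- NULL
  } else {
    nms <- as.character(categories)
    k <- length(nms)
  }
  if (k < 1L)
    sgStop("spotglyphs_input_error", "need at least one category for a palette")
  cols <- substr(grDevices::rainbow(k), 1L, 7L)
  if (!is.null(nms)) names(cols) <- nms
  cols
}

#' Styling options for rendered figures
#'
#' Bundles the plot-level options of the renderer with validated defaults.
#'
#' @param title optional plot title.
#' @param showLegend draw the category legend (legend order equals stacking
#'   order, first category at the top).
#' @param legendTitle legend heading.
#' @param background background color.
#' @param segmentEdgeWidth border line width around each segment, in points;
#'   0 (default) draws no borders, avoiding moire-like artifacts at small
#'   glyph sizes.
#' @param figureSize numeric (width, height) in inches.
#' @param dpi raster resolution for PNG output; at least 36.
#' @param axes draw coordinate axes; with `FALSE` the panel is stripped to
#'   the glyphs alone and spans exactly the layout bounding box.
#' @return a validated list of class `glyphStyle`.
#' @export
glyphStyle <- function(title = NULL, showLegend = TRUE, legendTitle = "Category",
                       background = "white", segmentEdgeWidth = 0,
                       figureSize = c(7, 7), dpi = 150, axes = TRUE) {
  if (!is.numeric(dpi) || length(dpi) != 1L || dpi < 36)
    sgStop("spotglyphs_style_error", "dpi must be a number >= 36")
  if (!is.numeric(figureSize) || length(figureSize) != 2L || any(figureSize <= 0))
    sgStop("spotglyphs_style_error", "figureSize must be two positive numbers (inches)")
  if (!is.numeric(segmentEdgeWidth) || segmentEdgeWidth < 0)
    sgStop("spotglyphs_style_error", "segmentEdgeWidth must be non-negative")
  structure(list(title = title, showLegend = isTRUE(showLegend),
                 legendTitle = legendTitle, background = background,
                 segmentEdgeWidth = segmentEdgeWidth,
                 figureSize = as.numeric(figureSize), dpi = as.integer(dpi),
                 axes = isTRUE(axes)),
            class = "glyphStyle")
}

resolvePalette <- function(pal, categories) {
  if (is.null(pal)) pal <- autoPalette(categories)
  if (is.null(names(pal))) {
    if (length(pal) < length(categories))
      sgStop("spotglyphs_missing_color_error",
             sprintf("palette has %d colors for %d categories", length(pal),
                     length(categories)))
    pal <- stats::setNames(pal[seq_along(categories)], categories)
  }
  miss <- setdiff(categories, names(pal))
  if (length(miss))
    sgStop("spotglyphs_missing_color_error",
           paste("palette lacks color(s) for:", sgOxford(miss)),
           categories = miss)
  pal[categories]
}

# wedge outline in plot coordinates; theta clockwise from 12 o'clock
wedgePolygon <- function(cx, cy, r, t0, t1, step = 2) {
  th <- seq(t0, t1, by = step)
  if (th[length(th)] != t1) th <- c(th, t1)
  rad <- th * pi / 180
  full <- (t1 - t0) >= 360 - 1e-9
  x <- cx + r * sin(rad); y <- cy + r * cos(rad)
  if (full) list(x = x, y = y) else list(x = c(cx, x), y = c(cy, y))
}

#' Build a ggplot of a glyph layout
#'
#' Draws the layout's rectangles (bar mode) or wedge polygons (pie mode) with
#' the given palette and style, on an equal-aspect coordinate system so the
#' spatial geometry of the tissue is not distorted. Zero-proportion segments
#' are skipped. The returned ggplot object can be customized further with
#' standard ggplot2 functions before saving.
#'
#' @param gl a [GlyphLayout-class].
#' @param palette optional named (by category) or positional vector of colors;
#'   defaults to [autoPalette()] over the layout's categories.
#' @param style a [glyphStyle()].
#' @return a ggplot object.
#' @export
plotGlyphs <- function(gl, palette = NULL, style = glyphStyle()) {
  stopifnot(methods::is(gl, "GlyphLayout"))
  pal <- resolvePalette(palette, gl@categories)
  seg <- gl@segments[gl@segments$proportion > 0, , drop = FALSE]
  seg$category <- factor(seg$category, levels = gl@categories)
  edge <- if (style$segmentEdgeWidth > 0) "black" else NA
  lwd <- style$segmentEdgeWidth / 2.13  # points -> ggplot linewidth units
  if (identical(gl@glyphKind, "bar")) {
    p <- ggplot2::ggplot(seg) +
      ggplot2::geom_rect(
        ggplot2::aes(xmin = .data$x_left, xmax = .data$x_right,
                     ymin = .data$y_bottom, ymax = .data$y_top,
                     fill = .data$category),
        colour = edge, linewidth = lwd)
  } else {
    polys <- lapply(seq_len(nrow(seg)), function(i) {
      w <- wedgePolygon(seg$center_x[i], seg$center_y[i], seg$radius[i],
                        seg$theta_start[i], seg$theta_end[i])
      data.frame(x = w$x, y = w$y, category = seg$category[i], piece = i)
    })
    polys <- do.call(rbind, polys)
    p <- ggplot2::ggplot(polys) +
      ggplot2::geom_polygon(
        ggplot2::aes(x = .data$x, y = .data$y, group = .data$piece,
                     fill = .data$category),
        colour = edge, linewidth = lwd)
  }
  bb <- gl@boundingBox
  p <- p +
    ggplot2::scale_fill_manual(values = pal, breaks = gl@categories,
                               drop = FALSE, name = style$legendTitle) +
    ggplot2::coord_fixed(xlim = c(bb[["x_min"]], bb[["x_max"]]),
                         ylim = c(bb[["y_min"]], bb[["y_max"]]),
                         expand = style$axes)
  if (style$axes) {
    p <- p + ggplot2::theme_bw() +
      ggplot2::labs(x = "x", y = "y") +
      ggplot2::theme(panel.grid = ggplot2::element_blank())
  } else {
    p <- p + ggplot2::theme_void() +
      ggplot2::theme(plot.margin = ggplot2::margin(0, 0, 0, 0))
  }
  p <- p + ggplot2::theme(
    plot.background = ggplot2::element_rect(fill = style$background, colour = NA),
    panel.background = ggplot2::element_rect(fill = style$background, colour = NA),
    legend.background = ggplot2::element_rect(fill = style$background, colour = NA)
  )
  if (!style$showLegend) p <- p + ggplot2::theme(legend.position = "none")
  if (!is.null(style$title)) p <- p + ggplot2::ggtitle(style$title)
  p
}

openDevice <- function(path, style) {
  ext <- tolower(tools::file_ext(path))
  w <- style$figureSize[1]; h <- style$figureSize[2]
  switch(ext,
    png = grDevices::png(path, width = w, height = h, units = "in",
                         res = style$dpi, type = "cairo",
                         bg = style$background),
    svg = grDevices::svg(path, width = w, height = h, bg = style$background),
    pdf = grDevices::pdf(path, width = w, height = h, bg = style$background,
                         useDingbats = FALSE),
    sgStop("spotglyphs_unsupported_format_error",
           sprintf("unsupported output format '.%s' (use .png, .svg or .pdf)", ext))
  )
}

writeFigure <- function(plot, path, style, bbox) {
  openDevice(path, style)
  on.exit(grDevices::dev.off(), add = TRUE)
  withCallingHandlers(
    print(plot),
    warning = function(w) invokeRestart("muffleWarning")
  )
  list(path = path, bbox = bbox, warnings = character())
}

#' Render a glyph layout to an image file
#'
#' Draws the layout via [plotGlyphs()] and writes it to PNG (raster,
#' dpi-controlled), SVG or PDF (vector). SVG output contains no timestamps
#' and is byte-identical across repeated renders of the same layout.
#'
#' @inheritParams plotGlyphs
#' @param outPath output file; extension selects the format (.png, .svg,
#'   .pdf).
#' @return a render report: list with `path`, `bbox` (the layout bounding
#'   box) and `warnings`.
#' @export
renderFigure <- function(gl, palette = NULL, style = glyphStyle(), outPath) {
  p <- plotGlyphs(gl, palette, style)
  writeFigure(p, outPath, style, gl@boundingBox)
}

#' Render a side-by-side pie-versus-bar comparison
#'
#' Lays out the same dataset as scatter pies (panel A) and scatter bars
#' (panel B) and renders the two panels with a shared palette and a single
#' collected legend, the standard figure for judging which glyph makes the
#' local compositions easier to compare.
#'
#' @param ds a [SpotComposition-class].
#' @param sizing optional [GlyphSizing-class]; auto-estimated when `NULL`.
#' @param palette,style as in [plotGlyphs()].
#' @param outPath output image file (.png, .svg, .pdf).
#' @return a render report (list with `path`, `bbox`, `warnings`).
#' @export
renderComparison <- function(ds, sizing = NULL, palette = NULL,
                             style = glyphStyle(figureSize = c(12, 6)),
                             outPath) {
  if (is.null(sizing)) sizing <- glyphSizing(coords = ds)
  glp <- layoutPies(ds, sizing = sizing)
  glb <- layoutBars(ds, sizing = sizing)
  panelStyle <- style
  panelStyle$showLegend <- TRUE
  pa <- plotGlyphs(glp, palette, panelStyle)
  pb <- plotGlyphs(glb, palette, panelStyle)
  combined <- patchwork::wrap_plots(pa, pb, ncol = 2, guides = "collect") +
    patchwork::plot_annotation(
      title = style$title,
      tag_levels = "A",
      theme = ggplot2::theme(
        plot.background = ggplot2::element_rect(fill = style$background,
                                                colour = NA))
    )
  if (!style$showLegend)
    combined <- combined & ggplot2::theme(legend.position = "none")
  bb <- glb@boundingBox
  writeFigure(combined, outPath, style, bb)
}
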