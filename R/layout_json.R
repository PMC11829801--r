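# Geometry export: a renderer-independent JSON document describing a layout,
# checked on write and read against the schema shipped in inst/extdata.

layoutSchemaPath <- function() {
  system.file("extdata", "glyph-layout.schema.json", package = "spotglyphs",
              mustWork = TRUE)
}

geometryFields <- function(kind) {
  if (identical(kind, "bar")) c("x_left", "x_right", "y_bottom", "y_top")
  else c("center_x", "center_y", "radius", "theta_start", "theta_end")
}

layoutToList <- function(gl) {
  seg <- gl@segments
  segs <- lapply(seq_len(nrow(seg)), function(i) {
    rec <- list(location = seg$location[i], category = seg$category[i])
    for (f in geometryFields(gl@glyphKind)) rec[[f]] <- seg[[f]][i]
    rec$proportion <- seg$proportion[i]
    rec
  })
  s <- gl@sizing
  list(
    glyph_kind = gl@glyphKind,
    sizing = list(size_x = s@sizeX, size_y = s@sizeY,
                  padding_x = s@paddingX, padding_y = s@paddingY,
                  auto_x = s@autoX, auto_y = s@autoY),
    categories = as.list(gl@categories),
    segments = segs,
    bbox = as.list(gl@boundingBox)
  )
}

# Minimal structural JSON-schema checker (type / required / properties /
# items / enum subset) sufficient for the shipped layout schema.
checkAgainstSchema <- function(x, schema, where = "$") {
  fail <- function(msg) sgStop("spotglyphs_schema_error",
                               sprintf("layout JSON invalid at %s: %s", where, msg))
  ty <- schema$type
  if (!is.null(ty)) {
    ok <- switch(ty,
      object  = is.list(x) && (length(x) == 0L || !is.null(names(x))),
      array   = is.list(x) && is.null(names(x)) || (is.list(x) && length(x) == 0L),
      string  = is.character(x) && length(x) == 1L,
      number  = is.numeric(x) && length(x) == 1L,
      boolean = is.logical(x) && length(x) == 1L,
      TRUE)
    if (!isTRUE(ok)) fail(sprintf("expected %s", ty))
  }
  if (!is.null(schema$enum) && !(x %in% unlist(schema$enum)))
    fail(sprintf("value '%s' not in allowed set", as.character(x)))
  if (!is.null(schema$required)) {
    miss <- setdiff(unlist(schema$required), names(x))
    if (length(miss)) fail(paste("missing required field(s):", sgOxford(miss)))
  }
  if (!is.null(schema$properties)) {
    for (nm in intersect(names(schema$properties), names(x)))
      checkAgainstSchema(x[[nm]], schema$properties[[nm]], paste0(where, ".", nm))
  }
  if (!is.null(schema$items) && identical(ty, "array")) {
    for (i in seq_along(x))
      checkAgainstSchema(x[[i]], schema$items, sprintf("%s[%d]", where, i))
  }
  invisible(TRUE)
}

#' Write a layout's geometry to JSON
#'
#' Serializes a [GlyphLayout-class] to a self-contained JSON document (glyph
#' kind, sizing, category order, per-segment geometry, bounding box) with
#' numbers at full double precision (17 significant digits, round-trip
#' exact). The document is validated against the schema shipped with the
#' package before writing. Writing is canonical: writing a layout read back
#' from JSON reproduces the file byte for byte.
#'
#' @param gl a [GlyphLayout-class].
#' @param path output file path (`.json`).
#' @return `path`, invisibly.
#' @seealso [readGlyphLayout()]
#' @export
writeGlyphLayout <- function(gl, path) {
  stopifnot(methods::is(gl, "GlyphLayout"))
  doc <- layoutToList(gl)
  schema <- jsonlite::read_json(layoutSchemaPath())
  checkAgainstSchema(doc, schema)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17), null = "null")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Read a layout's geometry from JSON
#'
#' Parses and schema-validates a geometry document written by
#' [writeGlyphLayout()] and rebuilds the [GlyphLayout-class]. The restored
#' layout carries no source dataset (`data` slot `NULL`), so [flipAxes()]
#' requires recomputing from data, but rendering, overlap diagnostics and
#' re-export work unchanged.
#'
#' @param path path to a layout JSON file.
#' @return a [GlyphLayout-class].
#' @export
readGlyphLayout <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  schema <- jsonlite::read_json(layoutSchemaPath())
  checkAgainstSchema(doc, schema)
  kind <- doc$glyph_kind
  fields <- c("location", "category", geometryFields(kind), "proportion")
  seg <- as.data.frame(
    lapply(stats::setNames(fields, fields), function(f)
      unlist(lapply(doc$segments, `[[`, f))),
    stringsAsFactors = FALSE
  )
  s <- doc$sizing
  sizing <- methods::new("GlyphSizing",
    sizeX = s$size_x, sizeY = s$size_y,
    paddingX = s$padding_x, paddingY = s$padding_y,
    autoX = s$auto_x, autoY = s$auto_y)
  methods::new("GlyphLayout", glyphKind = kind, segments = seg, sizing = sizing,
               categories = unlist(doc$categories),
               boundingBox = unlist(doc$bbox), data = NULL)
}
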