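# Table readers and writers. Delimiter is auto-detected from the extension
# (.csv -> comma; .tsv/.txt -> tab) with an explicit `sep` override; the
# first column holds the location labels; decimal points only.

sniffSep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  switch(tolower(tools::file_ext(path)),
         csv = ",",
         tsv = "\t",
         txt = "\t",
         sgStop("spotglyphs_parse_error",
                sprintf("cannot guess delimiter of '%s'; pass sep explicitly",
                        basename(path))))
}

readLabeledTable <- function(path, sep) {
  if (!file.exists(path))
    sgStop("spotglyphs_parse_error", sprintf("file not found: %s", path))
  out <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                      check.names = FALSE, stringsAsFactors = FALSE,
                      comment.char = ""),
    error = function(e)
      sgStop("spotglyphs_parse_error",
             sprintf("failed to parse '%s': %s", basename(path),
                     conditionMessage(e)))
  )
  out
}

#' Read a proportion table from CSV/TSV
#'
#' First column = location labels, remaining columns = per-category
#' proportions. The table is validated (see [validateProportions()]) but not
#' normalized.
#'
#' @param path file path; `.csv` is read comma-separated, `.tsv`/`.txt`
#'   tab-separated.
#' @param sep optional delimiter override.
#' @return numeric matrix, locations x categories.
#' @export
readProportions <- function(path, sep = NULL) {
  validateProportions(readLabeledTable(path, sniffSep(path, sep)))
}

#' Read a coordinate table from CSV/TSV
#'
#' First column = location labels, then two numeric columns of planar
#' centroid coordinates.
#'
#' @inheritParams readProportions
#' @return data.frame with columns `x`, `y` and location row names.
#' @export
readCoordinates <- function(path, sep = NULL) {
  validateCoordinates(readLabeledTable(path, sniffSep(path, sep)))
}

#' Read a palette file
#'
#' Two-column CSV/TSV mapping category to hex color, no header required to
#' be meaningful beyond the first row being treated as a header when it does
#' not look like a color.
#'
#' @inheritParams readProportions
#' @return named character vector of colors.
#' @export
readPalette <- function(path, sep = NULL) {
  sep <- sniffSep(path, sep)
  raw <- utils::read.table(path, header = FALSE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "")
  if (ncol(raw) < 2L)
    sgStop("spotglyphs_parse_error", "palette file needs two columns: category, color")
  if (nrow(raw) && !grepl("^#|^[a-zA-Z]+[0-9]*$", raw[1, 2]))
    sgStop("spotglyphs_parse_error", "second palette column must hold colors")
  # tolerate a header row
  if (nrow(raw) && identical(tolower(raw[1, 2]), "color")) raw <- raw[-1, , drop = FALSE]
  stats::setNames(as.character(raw[[2]]), as.character(raw[[1]]))
}

writeLabeledTable <- function(x, path, what) {
  df <- as.data.frame(x)
  out <- data.frame(location = rownames(df), df, check.names = FALSE,
                    stringsAsFactors = FALSE)
  # full precision so a write -> read round trip is exact to ~1e-15
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) format(v, digits = 17, trim = TRUE,
                                                  scientific = FALSE))
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a proportion matrix as CSV
#'
#' Emits exactly the dialect [readProportions()] consumes (label column
#' `location`, comma-separated, full double precision).
#'
#' @param pm proportion matrix, locations x categories.
#' @param path output `.csv` path.
#' @return `path`, invisibly.
#' @export
writeProportions <- function(pm, path) writeLabeledTable(pm, path, "proportions")

#' Write a coordinate table as CSV
#' @param coords data.frame/matrix with location row names and x, y columns.
#' @param path output `.csv` path.
#' @return `path`, invisibly.
#' @export
writeCoordinates <- function(coords, path) writeLabeledTable(coords, path, "coordinates")
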