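# Validation, normalization and alignment of the two labeled input tables:
# a proportion matrix (spots x categories, e.g. deconvolved cell-type
# proportions) and a coordinate table (spot centroids in the plane).

coerceLabeledMatrix <- function(raw, what) {
  if (is.data.frame(raw)) {
    bad <- names(raw)[!vapply(raw, is.numeric, logical(1))]
    if (length(bad))
      sgStop("spotglyphs_nonfinite_value_error",
             sprintf("%s: non-numeric column(s): %s", what, sgOxford(bad)))
    m <- as.matrix(raw)
  } else if (is.matrix(raw)) {
    m <- raw
    storage.mode(m) <- "double"
  } else {
    sgStop("spotglyphs_input_error",
           sprintf("%s must be a matrix or data.frame", what))
  }
  if (nrow(m) < 1L || ncol(m) < 1L)
    sgStop("spotglyphs_input_error",
           sprintf("%s must have at least one row and one column", what))
  if (is.null(rownames(m)))
    sgStop("spotglyphs_input_error",
           sprintf("%s must carry row labels (location ids)", what))
  m
}

offenderString <- function(m, idx) {
  ij <- which(idx, arr.ind = TRUE)
  lab <- sprintf("(%s, %s)", rownames(m)[ij[, 1L]], colnames(m)[ij[, 2L]])
  sgOxford(lab)
}

#' Validate a raw proportion table
#'
#' Checks that a spots-by-categories table of proportions is well formed:
#' labeled rows, unique row and column labels, and finite non-negative
#' entries. Values are returned untouched (not yet row-normalized); missing
#' values are rejected as non-finite rather than imputed, since 0 is a
#' meaningful proportion.
#'
#' @param raw matrix or all-numeric data.frame, one row per spatial location,
#'   one column per category, row names carrying the location labels.
#' @return a numeric matrix with the validated values and labels.
#' @section Errors: classed conditions `spotglyphs_duplicate_label_error`,
#'   `spotglyphs_nonfinite_value_error` (naming offending cells) and
#'   `spotglyphs_negative_value_error` (likewise).
#' @examples
#' validateProportions(matrix(c(.5, .5, .2, .8), 2, 2, byrow = TRUE,
#'   dimnames = list(c("s1", "s2"), c("a", "b"))))
#' @export
validateProportions <- function(raw) {
  m <- coerceLabeledMatrix(raw, "proportion table")
  if (is.null(colnames(m)))
    colnames(m) <- paste0("category", seq_len(ncol(m)))
  dupR <- unique(rownames(m)[duplicated(rownames(m))])
  dupC <- unique(colnames(m)[duplicated(colnames(m))])
  if (length(dupR) || length(dupC))
    sgStop("spotglyphs_duplicate_label_error",
           sprintf("duplicated label(s): %s", sgOxford(c(dupR, dupC))),
           duplicates = c(dupR, dupC))
  if (any(!is.finite(m)))
    sgStop("spotglyphs_nonfinite_value_error",
           sprintf("non-finite proportion(s) at %s", offenderString(m, !is.finite(m))))
  if (any(m < 0))
    sgStop("spotglyphs_negative_value_error",
           sprintf("negative proportion(s) at %s", offenderString(m, m < 0)))
  m
}

#' Validate a raw coordinate table
#'
#' Checks a table of planar spot centroids: labeled rows, unique labels, at
#' least two columns, finite values. The first two columns are taken as x
#' and y (3-D coordinates are not supported).
#'
#' @param raw matrix or data.frame with row names carrying location labels
#'   and two numeric columns of planar coordinates.
#' @return data.frame with columns `x` and `y` and the location row names.
#' @export
validateCoordinates <- function(raw) {
  m <- coerceLabeledMatrix(raw, "coordinate table")
  if (ncol(m) < 2L)
    sgStop("spotglyphs_input_error",
           "coordinate table needs two columns of planar coordinates")
  m <- m[, 1:2, drop = FALSE]
  colnames(m) <- c("x", "y")
  dupR <- unique(rownames(m)[duplicated(rownames(m))])
  if (length(dupR))
    sgStop("spotglyphs_duplicate_label_error",
           sprintf("duplicated location label(s): %s", sgOxford(dupR)),
           duplicates = dupR)
  if (any(!is.finite(m)))
    sgStop("spotglyphs_nonfinite_value_error",
           sprintf("non-finite coordinate(s) at %s", offenderString(m, !is.finite(m))))
  data.frame(x = m[, "x"], y = m[, "y"], row.names = rownames(m))
}

#' Row-normalize a proportion matrix onto the simplex
#'
#' Divides each location's row by its sum so every composition sums to one.
#' Deconvolution output is typically near-1 but float-imperfect, so rows
#' whose sum deviates from 1 by more than 1e-6 are renormalized with a
#' warning (class `spotglyphs_renormalized_warning`) rather than rejected.
#' Rows with zero total mass cannot be drawn and raise
#' `spotglyphs_zero_row_error` naming the offending locations.
#'
#' @param pm validated proportion matrix (see [validateProportions()]).
#' @return matrix of the same shape with unit row sums (within 1e-9).
#' @examples
#' normalizeRows(matrix(c(1, 3), 1, 2, dimnames = list("s1", c("a", "b"))))
#' @export
normalizeRows <- function(pm) {
  pm <- validateProportions(pm)
  rs <- rowSums(pm)
  zero <- rownames(pm)[rs <= 0]
  if (length(zero))
    sgStop("spotglyphs_zero_row_error",
           sprintf("location(s) with zero total proportion cannot be drawn: %s",
                   sgOxford(zero)),
           locations = zero)
  off <- abs(rs - 1) > 1e-6
  if (any(off))
    sgWarn("spotglyphs_renormalized_warning",
           sprintf("%d row(s) did not sum to 1 (max deviation %.3g) and were renormalized",
                   sum(off), max(abs(rs - 1))))
  pm / rs
}

#' Join proportions and coordinates into a SpotComposition
#'
#' Matches the two tables by location label, reorders the coordinates to the
#' proportion table's row order (the proportion table defines the analysis
#' object; coordinates are lookup), row-normalizes the compositions, and
#' returns the aligned S4 dataset. Locations present in exactly one input
#' raise `spotglyphs_label_mismatch_error` listing the symmetric difference.
#'
#' @param pm proportion table accepted by [validateProportions()].
#' @param coords coordinate table accepted by [validateCoordinates()].
#' @return a [SpotComposition-class].
#' @examples
#' pm <- matrix(c(.5, .5, .2, .8), 2, 2, byrow = TRUE,
#'              dimnames = list(c("s1", "s2"), c("a", "b")))
#' xy <- data.frame(x = c(0, 1), y = c(0, 0), row.names = c("s2", "s1"))
#' alignSpots(pm, xy)
#' @export
alignSpots <- function(pm, coords) {
  pm <- validateProportions(pm)
  coords <- validateCoordinates(coords)
  only_pm <- setdiff(rownames(pm), rownames(coords))
  only_xy <- setdiff(rownames(coords), rownames(pm))
  if (length(only_pm) || length(only_xy))
    sgStop("spotglyphs_label_mismatch_error",
           sprintf("location labels present in only one input: %s",
                   sgOxford(c(only_pm, only_xy))),
           mismatched = c(only_pm, only_xy))
  pm <- normalizeRows(pm)
  coords <- coords[rownames(pm), , drop = FALSE]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(proportions = t(pm)),
    colData = S4Vectors::DataFrame(x = coords$x, y = coords$y,
                                   row.names = rownames(pm))
  )
  methods::new("SpotComposition", se)
}

#' Construct a SpotComposition from raw tables
#'
#' Convenience constructor equivalent to [alignSpots()].
#'
#' @inheritParams alignSpots
#' @return a [SpotComposition-class].
#' @export
SpotComposition <- function(pm, coords) alignSpots(pm, coords)

#' @describeIn spotProportions spots-by-categories matrix of a SpotComposition
#' @export
setMethod("spotProportions", "SpotComposition", function(x) {
  t(SummarizedExperiment::assay(x, "proportions"))
})

#' @describeIn spotCoords coordinates of a SpotComposition
#' @export
setMethod("spotCoords", "SpotComposition", function(x) {
  cd <- SummarizedExperiment::colData(x)
  data.frame(x = cd$x, y = cd$y, row.names = colnames(x))
})

#' @describeIn nSpots spot count of a SpotComposition
#' @export
setMethod("nSpots", "SpotComposition", function(x) ncol(x))

#' @describeIn categoryNames categories of a SpotComposition, stacking order
#' @export
setMethod("categoryNames", "SpotComposition", function(x) rownames(x))

#' @describeIn spotNames spot labels of a SpotComposition
#' @export
setMethod("spotNames", "SpotComposition", function(x) colnames(x))

checkPermutation <- function(current, newOrder) {
  if (!is.character(newOrder)) newOrder <- as.character(newOrder)
  if (length(newOrder) != length(current) || anyDuplicated(newOrder) ||
      !setequal(newOrder, current))
    sgStop("spotglyphs_invalid_permutation_error",
           sprintf("newOrder is not a permutation of the categories (%s)",
                   sgOxford(current)))
  newOrder
}

#' @describeIn reorderCategories permute the columns of a proportion matrix
#' @export
setMethod("reorderCategories", "matrix", function(x, newOrder) {
  newOrder <- checkPermutation(colnames(x), newOrder)
  x[, newOrder, drop = FALSE]
})

#' @describeIn reorderCategories permute the categories of a SpotComposition
#' @export
setMethod("reorderCategories", "SpotComposition", function(x, newOrder) {
  newOrder <- checkPermutation(rownames(x), newOrder)
  x[newOrder, ]
})

#' @export
#' @describeIn SpotComposition compact display
setMethod("show", "SpotComposition", function(object) {
  cat(sprintf("SpotComposition: %d spots x %d categories\n",
              ncol(object), nrow(object)))
  cd <- SummarizedExperiment::colData(object)
  cat(sprintf("  x range [%g, %g], y range [%g, %g]\n",
              min(cd$x), max(cd$x), min(cd$y), max(cd$y)))
  cat("  categories:", sgOxford(rownames(object), 8L), "\n")
})
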