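# Seeded generator of synthetic spatial compositional fields emulating
# deconvolved cell-type proportions on a spot grid: per-category Gaussian
# intensity bumps define a smooth mean composition, and per-spot compositions
# are Dirichlet draws around it.

withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

gridCentroids <- function(nRows, nCols, gridKind, spacing) {
  row <- rep(seq_len(nRows), each = nCols)
  col <- rep(seq_len(nCols), times = nRows)
  x <- (col - 1) * spacing
  y <- (row - 1) * spacing
  if (identical(gridKind, "offset")) {
    # hex-style packing: every other row shifted half a spacing, rows
    # spacing*sqrt(3)/2 apart
    x <- x + ifelse(row %% 2 == 0, spacing / 2, 0)
    y <- (row - 1) * spacing * sqrt(3) / 2
  }
  data.frame(x = x, y = y,
             row.names = sprintf("spot%04d", seq_along(x)))
}

#' Simulate a spatial compositional dataset
#'
#' Generates spot centroids on a square or offset (hex-packed) grid and a
#' smooth compositional field over them, emulating the output of cell-type
#' deconvolution on a multicellular-pixel spatial transcriptomics array.
#' Each category receives Gaussian intensity bumps
#' \eqn{f_c(x,y) = \sum_b \exp(-\|(x,y)-\mu_{cb}\|^2 / (2 w^2)) + 0.01}
#' (the uniform floor keeps the Dirichlet parameters positive far from all
#' bumps); the per-spot composition is drawn from a Dirichlet distribution
#' with parameter vector `concentration * f / sum(f)`, so large
#' `concentration` gives near-deterministic compositions and the bumps
#' become distinct dominant-category regions. The planted truth label of a
#' spot is the argmax of its mean composition (ties broken by lowest
#' category index). The generator is a pure function of its arguments
#' including `seed`; the caller's RNG state is left untouched.
#'
#' @param nRows,nCols grid dimensions (spots = nRows * nCols).
#' @param nCategories number of categories (>= 2).
#' @param gridKind `"square"` or `"offset"` (alternate rows shifted half a
#'   spacing, rows `spacing * sqrt(3)/2` apart, approximating hex-packed
#'   spot arrays).
#' @param spacing center-to-center spot distance within a row (plot units).
#' @param bumpsPerCategory Gaussian bumps per category.
#' @param bumpWidth bump standard deviation (plot units).
#' @param concentration Dirichlet sharpness; larger is less noisy.
#' @param seed integer seed; same arguments and seed reproduce the dataset
#'   bitwise.
#' @param bumpCenters optional list (one per category) of 2-column matrices
#'   of bump centers, overriding random placement — useful for planting
#'   well-separated regions deterministically.
#' @return a list of class `syntheticSpotData` with elements `dataset` (a
#'   [SpotComposition-class]), `truth` (named character, planted dominant
#'   category per spot), `bumpCenters` (list per category) and `config`
#'   (the generating parameters).
#' @examples
#' sim <- simulateSpotComposition(8, 8, nCategories = 4, seed = 1)
#' sim$dataset
#' table(sim$truth)
#' @export
simulateSpotComposition <- function(nRows, nCols, nCategories,
                                    gridKind = c("square", "offset"),
                                    spacing = 1, bumpsPerCategory = 1,
                                    bumpWidth = max(nRows, nCols) * spacing / 4,
                                    concentration = 10, seed = 1,
                                    bumpCenters = NULL) {
  gridKind <- match.arg(gridKind)
  if (!all(vapply(list(nRows, nCols, nCategories, bumpsPerCategory),
                  function(v) is.numeric(v) && length(v) == 1L && v >= 1 &&
                    v == round(v), logical(1))))
    sgStop("spotglyphs_input_error",
           "nRows, nCols, nCategories and bumpsPerCategory must be positive integers")
  if (nCategories < 2L)
    sgStop("spotglyphs_input_error", "need at least 2 categories")
  if (!(spacing > 0) || !(bumpWidth > 0) || !(concentration > 0))
    sgStop("spotglyphs_input_error",
           "spacing, bumpWidth and concentration must be positive")
  xy <- gridCentroids(nRows, nCols, gridKind, spacing)
  cats <- sprintf("type%02d", seq_len(nCategories))
  withSeed(as.integer(seed), {
    if (is.null(bumpCenters)) {
      bumpCenters <- lapply(seq_len(nCategories), function(i)
        cbind(stats::runif(bumpsPerCategory, min(xy$x), max(xy$x)),
              stats::runif(bumpsPerCategory, min(xy$y), max(xy$y))))
    } else {
      if (length(bumpCenters) != nCategories)
        sgStop("spotglyphs_input_error",
               "bumpCenters must have one element per category")
      bumpCenters <- lapply(bumpCenters, function(m) {
        m <- as.matrix(m)
        if (ncol(m) != 2L)
          sgStop("spotglyphs_input_error", "bump centers must be 2-column")
        m
      })
    }
    names(bumpCenters) <- cats
    f <- vapply(bumpCenters, function(centers) {
      rowSums(vapply(seq_len(nrow(centers)), function(b) {
        d2 <- (xy$x - centers[b, 1])^2 + (xy$y - centers[b, 2])^2
        exp(-d2 / (2 * bumpWidth^2))
      }, numeric(nrow(xy)))) + 0.01
    }, numeric(nrow(xy)))
    mean_comp <- f / rowSums(f)
    alpha <- concentration * mean_comp
    p <- t(vapply(seq_len(nrow(alpha)), function(i) {
      g <- stats::rgamma(ncol(alpha), shape = alpha[i, ])
      g / sum(g)
    }, numeric(ncol(alpha))))
    dimnames(p) <- list(rownames(xy), cats)
    truth <- cats[max.col(mean_comp, ties.method = "first")]
    names(truth) <- rownames(xy)
    structure(list(dataset = alignSpots(p, xy), truth = truth,
                   bumpCenters = bumpCenters,
                   config = list(nRows = nRows, nCols = nCols,
                                 nCategories = nCategories, gridKind = gridKind,
                                 spacing = spacing,
                                 bumpsPerCategory = bumpsPerCategory,
                                 bumpWidth = bumpWidth,
                                 concentration = concentration,
                                 seed = as.integer(seed))),
              class = "syntheticSpotData")
  })
}

#' @export
print.syntheticSpotData <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("syntheticSpotData: %d x %d %s grid, %d categories, seed %d\n",
              cfg$nRows, cfg$nCols, cfg$gridKind, cfg$nCategories, cfg$seed))
  show(x$dataset)
  invisible(x)
}

#' Showcase dataset: 12 categories on a large offset grid
#'
#' Convenience preset emulating a deconvolved Visium-like section: 12
#' categories on a 40 x 50 offset grid (2,000 spots), one bump per category
#' placed on a deterministic spread so dominant-category regions are
#' visually distinct, moderate Dirichlet concentration. Intended for the
#' pie-versus-bar comparison figure and for benchmarks.
#'
#' @param seed integer seed for the Dirichlet noise.
#' @return a `syntheticSpotData` list (see [simulateSpotComposition()]).
#' @export
simulateShowcaseDataset <- function(seed = 1) {
  nRows <- 40L; nCols <- 50L; k <- 12L
  # bump centers on a fixed 4 x 3 lattice across the section, one region
  # per category, jittered deterministically off the lattice by the index
  gx <- rep(seq(0.12, 0.88, length.out = 4), times = 3)
  gy <- rep(seq(0.15, 0.85, length.out = 3), each = 4)
  width <- (nCols - 1)
  height <- (nRows - 1) * sqrt(3) / 2
  centers <- lapply(seq_len(k), function(i)
    cbind(gx[i] * width, gy[i] * height))
  simulateSpotComposition(nRows, nCols, nCategories = k, gridKind = "offset",
                          spacing = 1, bumpsPerCategory = 1,
                          bumpWidth = 6, concentration = 5, seed = seed,
                          bumpCenters = centers)
}
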