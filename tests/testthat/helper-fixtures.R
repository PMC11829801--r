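# Fixture builders and independent oracles, all generated in code.

makeProps <- function(values, spots = NULL, cats = NULL) {
  m <- if (is.matrix(values)) values else matrix(values, nrow = length(spots), byrow = TRUE)
  if (is.null(spots)) spots <- paste0("s", seq_len(nrow(m)))
  if (is.null(cats)) cats <- paste0("c", seq_len(ncol(m)))
  dimnames(m) <- list(spots, cats)
  m
}

makeCoords <- function(x, y, spots = NULL) {
  if (is.null(spots)) spots <- paste0("s", seq_along(x))
  data.frame(x = x, y = y, row.names = spots)
}

gridDataset <- function(n, k = 3, seed = 1) {
  # n x n unit grid with seeded random compositions
  set.seed(seed)
  spots <- paste0("s", seq_len(n * n))
  xy <- makeCoords(rep(0:(n - 1), times = n), rep(0:(n - 1), each = n), spots)
  p <- matrix(rgamma(n * n * k, shape = 1), ncol = k)
  p <- p / rowSums(p)
  alignSpots(makeProps(p, spots), xy)
}

randomDataset <- function(n, k, seed) {
  # n random locations in a box, seeded random compositions
  set.seed(seed)
  spots <- paste0("s", seq_len(n))
  xy <- makeCoords(runif(n, 0, 50), runif(n, 0, 30), spots)
  p <- matrix(rgamma(n * k, shape = 0.7), ncol = k)
  p <- p / rowSums(p)
  alignSpots(makeProps(p, spots), xy)
}

# Independent exact-rational bar-layout oracle: compositions are integer
# weights over a common denominator; cumulative boundaries are computed with
# integer sums and divided once at the end, so every boundary is exact up to
# one final floating division. Returns y_bottom/y_top per category, plus the
# composition the implementation should be fed.
oracleBarColumn <- function(weights, y, sizeY, paddingY) {
  stopifnot(all(weights == round(weights)), sum(weights) > 0)
  D <- sum(weights)
  h <- sizeY - paddingY
  cumInt <- cumsum(c(0, weights))            # exact integer cumulative sums
  bounds <- y - h / 2 + h * (cumInt / D)     # one division per boundary
  list(p = weights / D,
       y_bottom = bounds[-length(bounds)],
       y_top = bounds[-1])
}
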