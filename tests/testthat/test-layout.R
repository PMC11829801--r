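# Geometry engine: scale estimation, bar/pie layouts, overlap diagnostics,
# axis flip, and the layout invariants.

test_that("estimateScaleFactors implements range / sqrt(n) per axis", {
  # unit square corners: (1 - 0)/sqrt(4) = 0.5 on both axes
  xy <- makeCoords(c(0, 0, 1, 1), c(0, 1, 0, 1))
  expect_equal(estimateScaleFactors(xy), c(size_x = 0.5, size_y = 0.5))

  # n x n integer grid: closed form (n-1)/n, strictly below the spacing
  for (n in c(2, 5, 13)) {
    ds <- gridDataset(n)
    est <- estimateScaleFactors(spotCoords(ds))
    expect_identical(unname(est), c((n - 1) / n, (n - 1) / n))
    expect_lt(est[["size_x"]], 1)
  }
})

test_that("degenerate coordinate ranges fall back with warnings", {
  # vertical line: x range zero, borrows y estimate
  line <- makeCoords(rep(2, 4), 0:3)
  w <- testthat::capture_warnings(est <- estimateScaleFactors(line))
  expect_match(w, "zero range", all = TRUE)
  expect_equal(unname(est), rep(3 / sqrt(4), 2))

  # all spots coincident: both axes fall back to 1, two warnings
  same <- makeCoords(rep(1, 3), rep(1, 3))
  w <- testthat::capture_warnings(est <- estimateScaleFactors(same))
  expect_length(w, 2L)
  expect_equal(unname(est), c(1, 1))

  expect_error(estimateScaleFactors(data.frame(x = numeric(), y = numeric())),
               class = "spotglyphs_input_error")
})

test_that("layoutBars stacks cumulative proportions bottom-to-top, centered", {
  ds <- alignSpots(makeProps(c(0.25, 0.75), "s1", c("a", "b")),
                   makeCoords(0, 0, "s1"))
  seg <- glyphSegments(layoutBars(ds, sizeX = 1, sizeY = 1))
  # hand-derived boundaries: cumulative sums 0, 0.25, 1 on [-0.5, 0.5]
  expect_equal(seg$x_left, c(-0.5, -0.5))
  expect_equal(seg$x_right, c(0.5, 0.5))
  expect_equal(seg$y_bottom, c(-0.5, -0.25))
  expect_equal(seg$y_top, c(-0.25, 0.5))
  expect_equal(seg$proportion, c(0.25, 0.75))

  # single category fills the whole w x h box
  one <- alignSpots(makeProps(1, "s1", "a"), makeCoords(2, 3, "s1"))
  s1 <- glyphSegments(layoutBars(one, sizeX = 2, sizeY = 4, paddingX = 1, paddingY = 1))
  expect_equal(s1$x_left, 1.5); expect_equal(s1$x_right, 2.5)
  expect_equal(s1$y_bottom, 1.5); expect_equal(s1$y_top, 4.5)

  # segment height equals proportion * effective height
  expect_equal(seg$y_top - seg$y_bottom, seg$proportion * 1, tolerance = 1e-9)
})

test_that("padding >= size is a sizing error and padding shrinks the glyph", {
  ds <- gridDataset(3)
  expect_error(layoutBars(ds, sizeX = 1, sizeY = 1, paddingX = 1),
               class = "spotglyphs_sizing_error")
  expect_error(glyphSizing(sizeX = 1, sizeY = 0.5, paddingY = 0.7),
               class = "spotglyphs_sizing_error")
  expect_error(glyphSizing(sizeX = -1, sizeY = 1),
               class = "spotglyphs_sizing_error")

  seg <- glyphSegments(layoutBars(ds, sizeX = 1, sizeY = 1,
                                  paddingX = 0.4, paddingY = 0.2))
  expect_equal(unique(round(seg$x_right - seg$x_left, 12)), 0.6)
})

test_that("layoutPies subtends 360 * p degrees clockwise from 12 o'clock", {
  half <- alignSpots(makeProps(c(0.5, 0.5), "s1"), makeCoords(0, 0, "s1"))
  seg <- glyphSegments(layoutPies(half, sizeX = 1, sizeY = 1))
  expect_equal(seg$theta_start, c(0, 180))
  expect_equal(seg$theta_end, c(180, 360))

  quarter <- alignSpots(makeProps(c(0.25, 0.75), "s1"), makeCoords(0, 0, "s1"))
  seg <- glyphSegments(layoutPies(quarter, sizeX = 1, sizeY = 1))
  expect_equal(seg$theta_end, c(90, 360))  # hand-derived: 360 * 0.25 = 90

  full <- alignSpots(makeProps(1, "s1", "a"), makeCoords(0, 0, "s1"))
  seg <- glyphSegments(layoutPies(full, sizeX = 3, sizeY = 2))
  expect_equal(c(seg$theta_start, seg$theta_end), c(0, 360))
  expect_equal(seg$radius, 1)  # min(w, h)/2

  # radius uses the tighter axis after padding
  seg <- glyphSegments(layoutPies(full, sizeX = 3, sizeY = 2, paddingX = 2.5))
  expect_equal(seg$radius, 0.25)
})

test_that("bar segments tile the glyph exactly (partition + conservation)", {
  ds <- randomDataset(60, 7, seed = 11)
  gl <- layoutBars(ds, sizeX = 2, sizeY = 3, paddingX = 0.5, paddingY = 1)
  seg <- glyphSegments(gl)
  h <- 3 - 1
  xy <- spotCoords(ds)
  for (loc in spotNames(ds)) {
    s <- seg[seg$location == loc, ]
    expect_identical(s$category, categoryNames(ds))  # contiguous, in order
    # adjacent boundaries shared exactly, by construction
    expect_identical(s$y_bottom[-1], s$y_top[-nrow(s)])
    expect_equal(s$y_bottom[1], xy[loc, "y"] - h / 2, tolerance = 1e-9)
    expect_equal(s$y_top[nrow(s)], xy[loc, "y"] + h / 2, tolerance = 1e-9)
    # total ink area = w * h
    expect_equal(sum((s$x_right - s$x_left) * (s$y_top - s$y_bottom)),
                 1.5 * h, tolerance = 1e-9)
  }
  # wedge angles of every pie sum to 360
  ps <- glyphSegments(layoutPies(ds, sizeX = 2, sizeY = 3))
  tot <- tapply(ps$theta_end - ps$theta_start, ps$location, sum)
  expect_equal(as.numeric(tot), rep(360, nSpots(ds)), tolerance = 1e-9)
})

test_that("zero-proportion segments are kept with zero extent", {
  ds <- alignSpots(makeProps(c(0.5, 0, 0.5), "s1", c("a", "b", "c")),
                   makeCoords(0, 0, "s1"))
  seg <- glyphSegments(layoutBars(ds, sizeX = 1, sizeY = 1))
  expect_equal(nrow(seg), 3L)
  expect_equal(seg$y_top[2] - seg$y_bottom[2], 0)
  ps <- glyphSegments(layoutPies(ds, sizeX = 1, sizeY = 1))
  expect_equal(ps$theta_end[2] - ps$theta_start[2], 0)
})

test_that("layout matches the exact-rational oracle on random instances", {
  set.seed(7)
  for (rep in 1:40) {
    k <- sample(2:9, 1)
    weights <- sample(0:20, k, replace = TRUE)
    if (sum(weights) == 0) weights[1] <- 1
    y <- runif(1, -50, 50); x <- runif(1, -50, 50)
    sizeY <- runif(1, 0.5, 8); padY <- runif(1, 0, sizeY * 0.8)
    oracle <- oracleBarColumn(weights, y, sizeY, padY)
    ds <- alignSpots(makeProps(oracle$p, "s1"), makeCoords(x, y, "s1"))
    seg <- glyphSegments(layoutBars(ds, sizeX = 1, sizeY = sizeY, paddingY = padY))
    expect_equal(seg$y_bottom, unname(oracle$y_bottom), tolerance = 1e-9)
    expect_equal(seg$y_top, unname(oracle$y_top), tolerance = 1e-9)
  }
})

test_that("category permutation preserves footprint and total ink", {
  ds <- randomDataset(25, 5, seed = 3)
  gl <- layoutBars(ds, sizeX = 1, sizeY = 1)
  perm <- rev(categoryNames(ds))
  gl2 <- layoutBars(reorderCategories(ds, perm), sizeX = 1, sizeY = 1)
  s1 <- glyphSegments(gl); s2 <- glyphSegments(gl2)
  for (loc in spotNames(ds)) {
    a <- s1[s1$location == loc, ]; b <- s2[s2$location == loc, ]
    expect_equal(range(c(a$y_bottom, a$y_top)), range(c(b$y_bottom, b$y_top)))
    expect_equal(sum((a$x_right - a$x_left) * (a$y_top - a$y_bottom)),
                 sum((b$x_right - b$x_left) * (b$y_top - b$y_bottom)))
    # same segments, relabeled
    expect_equal(sort(a$y_top - a$y_bottom), sort(b$y_top - b$y_bottom),
                 tolerance = 1e-12)
  }
})

test_that("detectOverlaps reports exactly the positive-area collisions", {
  two <- function(d) alignSpots(
    makeProps(c(1, 1), paste0("s", 1:2), "a"),
    makeCoords(c(0, d), c(0, 0), paste0("s", 1:2)))
  # 1 unit apart, footprint 0.5 -> disjoint
  gl <- layoutBars(two(1), sizeX = 0.5, sizeY = 0.5)
  expect_equal(nrow(detectOverlaps(gl)), 0L)
  # 0.4 apart, footprint 0.5 -> interval intersection of positive length
  gl <- layoutBars(two(0.4), sizeX = 0.5, sizeY = 0.5)
  ov <- detectOverlaps(gl)
  expect_equal(nrow(ov), 1L)
  expect_setequal(unlist(ov[1, ]), c("s1", "s2"))
  # touching footprints (distance == width) do not count
  gl <- layoutBars(two(0.5), sizeX = 0.5, sizeY = 0.5)
  expect_equal(nrow(detectOverlaps(gl)), 0L)
  # single spot: no pairs exist
  one <- alignSpots(makeProps(1, "s1", "a"), makeCoords(0, 0, "s1"))
  expect_equal(nrow(detectOverlaps(layoutBars(one, sizeX = 1, sizeY = 1))), 0L)
  # pies collide by center distance vs diameter
  gp <- layoutPies(two(0.9), sizeX = 1, sizeY = 1)
  expect_equal(nrow(detectOverlaps(gp)), 1L)
  gp <- layoutPies(two(1.1), sizeX = 1, sizeY = 1)
  expect_equal(nrow(detectOverlaps(gp)), 0L)
})

test_that("auto-scale on regular grids never produces overlaps", {
  for (n in c(2, 6, 12)) {
    ds <- gridDataset(n)
    gl <- layoutBars(ds)  # auto sizing, zero padding
    expect_true(layoutSizing(gl)@autoX && layoutSizing(gl)@autoY)
    expect_equal(nrow(detectOverlaps(gl)), 0L)
  }
})

test_that("flipAxes swaps coordinates, restacks upright, and is an involution", {
  # spots on a horizontal line become a vertical line
  line <- alignSpots(makeProps(matrix(0.5, 5, 2), paste0("s", 1:5)),
                     makeCoords(0:4, rep(0, 5), paste0("s", 1:5)))
  gl <- layoutBars(line, sizeX = 0.8, sizeY = 0.4)
  fl <- flipAxes(gl)
  xy <- spotCoords(fl@data)
  expect_equal(xy$x, rep(0, 5)); expect_equal(xy$y, 0:4)
  # sizing axes swapped so bars stay upright with the same footprint shape
  expect_equal(layoutSizing(fl)@sizeX, 0.4)
  expect_equal(layoutSizing(fl)@sizeY, 0.8)

  # single spot at (2,3) -> bar centered at (3,2)
  one <- alignSpots(makeProps(1, "s1", "a"), makeCoords(2, 3, "s1"))
  fs <- glyphSegments(flipAxes(layoutBars(one, sizeX = 1, sizeY = 1)))
  expect_equal((fs$x_left + fs$x_right) / 2, 3)
  expect_equal((fs$y_bottom + fs$y_top) / 2, 2)

  # flipping twice restores every coordinate
  ds <- randomDataset(20, 4, seed = 5)
  gl <- layoutPies(ds, sizeX = 2, sizeY = 1)
  back <- flipAxes(flipAxes(gl))
  expect_equal(glyphSegments(back)$center_x, glyphSegments(gl)$center_x,
               tolerance = 1e-12)
  expect_equal(glyphSegments(back)$theta_end, glyphSegments(gl)$theta_end,
               tolerance = 1e-12)

  # a layout restored from JSON has no dataset to recompute from
  f <- withr::local_tempfile(fileext = ".json")
  writeGlyphLayout(gl, f)
  expect_error(flipAxes(readGlyphLayout(f)), class = "spotglyphs_input_error")
})

test_that("layout JSON round-trips exactly and is schema-checked", {
  ds <- randomDataset(8, 3, seed = 2)
  for (gl in list(layoutBars(ds, sizeX = 1.3, sizeY = 0.9, paddingY = 0.1),
                  layoutPies(ds, sizeX = 1.3, sizeY = 0.9))) {
    f <- withr::local_tempfile(fileext = ".json")
    writeGlyphLayout(gl, f)
    back <- readGlyphLayout(f)
    expect_identical(glyphKind(back), glyphKind(gl))
    expect_identical(categoryNames(back), categoryNames(gl))
    expect_equal(glyphSegments(back), glyphSegments(gl))  # exact doubles
    expect_equal(boundingBox(back), boundingBox(gl))
    f2 <- withr::local_tempfile(fileext = ".json")
    writeGlyphLayout(back, f2)
    expect_identical(readLines(f), readLines(f2))  # canonical re-serialization
  }
  # corrupted documents are rejected by the structural schema check
  f <- withr::local_tempfile(fileext = ".json")
  writeGlyphLayout(layoutBars(ds, sizeX = 1, sizeY = 1), f)
  doc <- jsonlite::read_json(f)
  doc$glyph_kind <- "hex"
  f3 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, f3, auto_unbox = TRUE)
  expect_error(readGlyphLayout(f3), class = "spotglyphs_schema_error")
  doc$glyph_kind <- NULL
  jsonlite::write_json(doc, f3, auto_unbox = TRUE)
  expect_error(readGlyphLayout(f3), class = "spotglyphs_schema_error")
})
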