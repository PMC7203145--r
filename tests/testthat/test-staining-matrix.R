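test_that("one-hot matrices put all weight on the selected stain plane", {
  m <- oneHotMatrix(1, 2, 2, c("HE", "MT", "JS"))
  w <- stainWeights(m)
  expect_equal(w[, , 1], matrix(1, 2, 2))
  expect_equal(w[, , 2], matrix(0, 2, 2))
  expect_equal(w[, , 3], matrix(0, 2, 2))

  m3 <- oneHotMatrix(3, 1, 1, c("HE", "MT", "JS"))
  expect_equal(as.numeric(stainWeights(m3)[1, 1, ]), c(0, 0, 1))

  expect_equal(nrow(validateStainingMatrix(m)), 0L)
  expect_error(oneHotMatrix(4, 2, 2), "invalid stain")
  expect_error(oneHotMatrix("PAS", 2, 2), "invalid stain")
})

test_that("blend matrices carry the weight vector at every pixel", {
  m <- blendMatrix(c(0.5, 0.5, 0), 4, 4)
  w <- stainWeights(m)
  expect_true(all(w[, , 1] == 0.5) && all(w[, , 2] == 0.5) &&
                all(w[, , 3] == 0))
  expect_identical(stainWeights(blendMatrix(c(1, 0, 0), 5, 7)),
                   stainWeights(oneHotMatrix(1, 5, 7)))
  expect_error(blendMatrix(c(0.3, 0.3, 0.3), 4, 4), "encoding rule")
  expect_error(blendMatrix(c(1.2, -0.2, 0), 4, 4), "nonnegative")
})

test_that("ROI rasterization follows the pixel-center even-odd rule", {
  # rectangle covering x in [1, 2], y in [1, 2]: only the center (1.5, 1.5)
  # of pixel (2, 2) falls inside on a 3 x 3 grid
  rect <- cbind(c(1, 2, 2, 1), c(1, 1, 2, 2))
  spec <- RoiSpec(polygons = list(rect), weights = list(c(0, 1, 0)),
                  defaultWeights = c(1, 0, 0))
  m <- roiMatrix(spec, 3, 3)
  w <- stainWeights(m)

  # independent brute-force even-odd oracle over all 9 pixel centers
  evenOdd <- function(x, y, P) {
    n <- nrow(P); inside <- FALSE
    for (v in seq_len(n)) {
      u <- if (v == 1) n else v - 1
      if ((P[v, 2] > y) != (P[u, 2] > y) &&
          x < (P[u, 1] - P[v, 1]) * (y - P[v, 2]) /
                (P[u, 2] - P[v, 2]) + P[v, 1])
        inside <- !inside
    }
    inside
  }
  expectInside <- outer(1:3, 1:3, Vectorize(function(i, j)
    evenOdd(j - 0.5, i - 0.5, rect)))
  expect_equal(w[, , 2] == 1, expectInside)
  expect_equal(sum(w[, , 2]), 1)  # exactly one pixel differs from default

  # empty polygon list: uniform default
  u <- roiMatrix(RoiSpec(defaultWeights = c(0, 0, 1)), 4, 5)
  expect_true(all(stainWeights(u)[, , 3] == 1))
})

test_that("overlapping ROIs resolve to the last-listed polygon", {
  big <- cbind(c(0, 6, 6, 0), c(0, 0, 6, 6))
  small <- cbind(c(2, 4, 4, 2), c(2, 2, 4, 4))
  spec <- RoiSpec(polygons = list(big, small),
                  weights = list(c(0, 1, 0), c(0, 0, 1)),
                  defaultWeights = c(1, 0, 0))
  w <- stainWeights(roiMatrix(spec, 6, 6))
  expect_equal(w[3, 3, ], c(0, 0, 1))  # inside both: small wins
  expect_equal(w[1, 1, ], c(0, 1, 0))  # inside big only
})

test_that("validation reports per-pixel encoding-rule violations", {
  w <- array(0, c(2, 2, 3)); w[, , 1] <- 1
  w[1, 2, ] <- c(0.6, 0.6, 0)
  v <- validateStainingMatrix(w)
  expect_equal(nrow(v), 1L)
  expect_equal(v$type, "sum")
  expect_equal(c(v$row, v$col), c(1L, 2L))

  w2 <- array(0, c(2, 2, 3)); w2[, , 1] <- 1
  w2[2, 1, ] <- c(1.4, -0.4, 0)
  v2 <- validateStainingMatrix(w2)
  expect_true("range" %in% v2$type)
  expect_error(StainingMatrix(w2), "encoding rule")
})

test_that("every construction path satisfies the encoding rule", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(2:4, 1)
    names <- paste0("S", seq_len(n))
    h <- sample(3:12, 1); wd <- sample(3:12, 1)
    expect_equal(nrow(validateStainingMatrix(
      oneHotMatrix(sample(n, 1), h, wd, names))), 0L)
    raw <- runif(n); raw <- raw / sum(raw)
    expect_equal(nrow(validateStainingMatrix(
      blendMatrix(raw, h, wd, names))), 0L)
    poly <- cbind(runif(3, 0, wd), runif(3, 0, h))
    if (!stainmux:::.polygonIsSimple(poly)) next
    spec <- RoiSpec(polygons = list(poly), weights = list(raw),
                    defaultWeights = as.numeric(seq_len(n) == 1))
    expect_equal(nrow(validateStainingMatrix(
      roiMatrix(spec, h, wd, names))), 0L)
    # idempotence: re-rasterizing the same spec gives the same matrix
    expect_identical(stainWeights(roiMatrix(spec, h, wd, names)),
                     stainWeights(roiMatrix(spec, h, wd, names)))
  }
})

test_that("polygon annotation files map labels to weight vectors", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(shapes = list(
    list(label = "MT", shape_type = "polygon",
         points = list(c(1, 1), c(5, 1), c(5, 5))))),
    auto_unbox = TRUE), path)
  spec <- readPolygonAnnotations(path, labelWeights = list(MT = c(0, 1, 0)),
                                 defaultWeights = c(1, 0, 0))
  expect_length(spec@polygons, 1L)
  expect_equal(spec@roiWeights[[1]], c(0, 1, 0))

  expect_error(readPolygonAnnotations(path, labelWeights = list(),
                                      defaultWeights = c(1, 0, 0)),
               "unknown label")

  writeLines(jsonlite::toJSON(list(shapes = list()), auto_unbox = TRUE), path)
  expect_length(readPolygonAnnotations(path, list(),
                                       c(1, 0, 0))@polygons, 0L)

  writeLines(jsonlite::toJSON(list(shapes = list(
    list(label = "MT", shape_type = "polygon",
         points = list(c(1, 1), c(5, 1))))), auto_unbox = TRUE), path)
  expect_error(readPolygonAnnotations(path, list(MT = c(0, 1, 0)),
                                      c(1, 0, 0)), "fewer than 3")
})

test_that("self-intersecting polygons are rejected", {
  bowtie <- cbind(c(0, 4, 0, 4), c(0, 4, 4, 0))
  expect_error(RoiSpec(polygons = list(bowtie),
                       weights = list(c(1, 0, 0)),
                       defaultWeights = c(1, 0, 0)),
               "self-intersecting")
})

test_that("the bundled example annotation file parses and rasterizes", {
  path <- system.file("extdata", "example_rois.json", package = "stainmux")
  spec <- readPolygonAnnotations(
    path, labelWeights = list(MT = c(0, 1, 0), JS = c(0, 0, 1)),
    defaultWeights = c(1, 0, 0))
  expect_length(spec@polygons, 2L)
  m <- roiMatrix(spec, 176, 176)
  expect_equal(nrow(validateStainingMatrix(m)), 0L)
  expect_gt(sum(stainWeights(m)[, , 2]), 0)
  expect_gt(sum(stainWeights(m)[, , 3]), 0)
})
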