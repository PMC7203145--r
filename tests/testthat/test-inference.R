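# Inference-path tests on an untrained (seeded) model: determinism, output
# contracts, tiling consistency and encoding-rule enforcement. Conditional
# fidelity of trained models is covered by the end-to-end acceptance tests.

untrainedModel <- function() {
  gspec <- tinyGenSpec(); dspec <- tinyDiscSpec(64)
  new("StainGAN", genSpec = gspec, discSpec = dspec,
      generator = initGenerator(gspec, seed = 21),
      discriminator = initDiscriminator(dspec, seed = 22),
      stainNames = defaultStains())
}

test_that("stainPatch is deterministic and emits valid 8-bit RGB", {
  model <- untrainedModel()
  af <- array(rnorm(64 * 64 * 2), c(64, 64, 2))
  dsm <- oneHotMatrix("HE", 64, 64)
  out1 <- stainPatch(model, af, dsm)
  out2 <- stainPatch(model, af, dsm)
  expect_identical(out1, out2)
  expect_equal(dim(out1), c(64, 64, 3))
  expect_true(all(is.finite(out1)))
  expect_true(min(out1) >= 0 && max(out1) <= 255)
  expect_true(all(out1 == round(out1)))

  expect_error(stainPatch(model, af, oneHotMatrix("HE", 32, 32)),
               "spatial shape")
  wrongOrder <- oneHotMatrix(1, 64, 64, c("MT", "HE", "JS"))
  expect_error(stainPatch(model, af, wrongOrder), "ordering")
})

test_that("distinct conditions change the generator response", {
  # continuous outputs: 8-bit rounding would hide the (untrained) model's
  # small but nonzero sensitivity to the conditioning planes
  model <- untrainedModel()
  set.seed(23)
  af <- array(rnorm(64 * 64 * 2), c(64, 64, 2))
  raw <- function(dsm)
    genForward(model@generator, model@genSpec,
               stainmux:::.concat3(af, stainWeights(dsm)))$y
  outs <- lapply(defaultStains(), function(s)
    raw(oneHotMatrix(s, 64, 64)))
  expect_gt(max(abs(outs[[1]] - outs[[2]])), 0)
  expect_gt(max(abs(outs[[1]] - outs[[3]])), 0)
  blend <- raw(blendMatrix(c(0.5, 0.5, 0), 64, 64))
  expect_gt(max(abs(blend - outs[[1]])), 0)
  expect_gt(max(abs(blend - outs[[2]])), 0)
})

test_that("tiled slide inference agrees with a single pass off the seams", {
  model <- untrainedModel()
  af <- array(rnorm(96 * 96 * 2), c(96, 96, 2))
  dsm <- oneHotMatrix("MT", 96, 96)
  single <- stainSlide(model, af, dsm, tile = 96)
  tiled <- stainSlide(model, af, dsm, tile = 64, overlap = 32)
  expect_equal(dim(tiled), c(96, 96, 3))
  # away from tile seams (and their feather bands) the two paths agree
  interior <- abs(tiled[1:24, 1:24, ] - single[1:24, 1:24, ])
  expect_lt(mean(interior), 2)

  # slide of exactly one tile reduces to stainPatch
  af1 <- array(rnorm(64 * 64 * 2), c(64, 64, 2))
  d1 <- oneHotMatrix("HE", 64, 64)
  expect_identical(stainSlide(model, af1, d1, tile = 64),
                   stainPatch(model, af1, d1))
  # tile larger than the slide falls back to a single pass
  expect_identical(stainSlide(model, af1, d1, tile = 256),
                   stainPatch(model, af1, d1))
})

test_that("blend series endpoints equal the pure stains", {
  model <- untrainedModel()
  af <- array(rnorm(64 * 64 * 2), c(64, 64, 2))
  series <- blendSeries(model, af, "HE", "JS", c(1, 0), tile = 64)
  pureA <- stainSlide(model, af, oneHotMatrix("HE", 64, 64), tile = 64)
  pureB <- stainSlide(model, af, oneHotMatrix("JS", 64, 64), tile = 64)
  expect_identical(series[[1]], pureA)
  expect_identical(series[[2]], pureB)
  expect_error(blendSeries(model, af, "HE", "JS", c(0.5, 1.2)),
               "ratios")
})

test_that("micro-structured staining follows the ROI specification", {
  model <- untrainedModel()
  af <- array(rnorm(64 * 64 * 2), c(64, 64, 2))
  empty <- RoiSpec(defaultWeights = c(1, 0, 0))
  uniform <- stainSlide(model, af, oneHotMatrix("HE", 64, 64), tile = 64)
  expect_identical(microStructuredStain(model, af, empty, tile = 64),
                   uniform)

  rect1 <- cbind(c(8, 30, 30, 8), c(8, 8, 30, 30))
  rect2 <- cbind(c(20, 50, 50, 20), c(20, 20, 50, 50))
  ab <- RoiSpec(polygons = list(rect1, rect2),
                weights = list(c(0, 1, 0), c(0, 0, 1)),
                defaultWeights = c(1, 0, 0))
  ba <- RoiSpec(polygons = list(rect2, rect1),
                weights = list(c(0, 0, 1), c(0, 1, 0)),
                defaultWeights = c(1, 0, 0))
  outAB <- microStructuredStain(model, af, ab, tile = 64)
  outBA <- microStructuredStain(model, af, ba, tile = 64)
  # the two orderings differ only through the overlap region's condition
  mAB <- stainWeights(roiMatrix(ab, 64, 64))
  mBA <- stainWeights(roiMatrix(ba, 64, 64))
  overlap <- which(apply(mAB != mBA, c(1, 2), any))
  expect_gt(length(overlap), 0L)
  far <- matrix(TRUE, 64, 64)
  ov <- apply(mAB != mBA, c(1, 2), any)
  # pixels further than the receptive field from any differing pixel agree
  dist <- 24L
  idx <- which(ov, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    r <- pmax(1, idx[k, 1] - dist):pmin(64, idx[k, 1] + dist)
    cc <- pmax(1, idx[k, 2] - dist):pmin(64, idx[k, 2] + dist)
    far[r, cc] <- FALSE
  }
  if (any(far))
    expect_equal(outAB[rep(far, 3)], outBA[rep(far, 3)])
})

test_that("every inference path rejects encoding-rule violations", {
  bad <- array(0, c(64, 64, 3)); bad[, , 1] <- 0.6; bad[, , 2] <- 0.6
  expect_error(StainingMatrix(bad), "encoding rule")
  neg <- array(0, c(64, 64, 3)); neg[, , 1] <- 1.4; neg[, , 2] <- -0.4
  expect_error(StainingMatrix(neg), "encoding rule")
  expect_error(blendMatrix(c(0.7, 0.7, -0.4), 8, 8), "nonnegative")
  expect_error(RoiSpec(polygons = list(cbind(c(0, 4, 4), c(0, 0, 4))),
                       weights = list(c(0.5, 0.4, 0)),
                       defaultWeights = c(1, 0, 0)), "encoding rule")
})
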