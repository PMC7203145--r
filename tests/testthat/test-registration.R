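test_that("block matching recovers known integer shifts to sub-pixel", {
  img <- textureImage(21, 128)
  blk <- img[33:96, 33:96]
  same <- blockShift(blk, blk)
  expect_equal(same$shift, c(0, 0))
  expect_gt(same$confidence, 0.999)

  # wrap-free shifted copy: content moved by (3, -2) within the big image
  mov <- img[(33 + 3):(96 + 3), (33 - 2):(96 - 2)]
  bs <- blockShift(blk, mov)
  # mov(p) = blk(p + (3, -2)), so the aligning field is (3, -2)
  expect_lt(max(abs(bs$shift - c(3, -2))), 0.5)
  expect_false(bs$degenerate)

  flat <- blockShift(matrix(5, 32, 32), matrix(rnorm(1024), 32, 32))
  expect_true(flat$degenerate)
  expect_equal(flat$confidence, 0)
})

test_that("applyDisplacement matches direct index arithmetic", {
  ramp <- matrix(seq_len(25), 5, 5)
  zero <- array(0, c(5, 5, 2))
  expect_equal(applyDisplacement(ramp, zero), ramp)

  # constant field (0, 1): out(i, j) = img(i, j - 1), edge clamped
  f <- zero; f[, , 2] <- 1
  out <- applyDisplacement(ramp, f, "nearest")
  expect_equal(out[, 2:5], ramp[, 1:4])
  expect_equal(out[, 1], ramp[, 1])

  # inverse-warp symmetry on a smooth image
  smooth <- outer(sin(seq(0, 3, length.out = 48)),
                  cos(seq(0, 3, length.out = 48)))
  sw <- syntheticWarp(smooth, seed = 4, amplitude = 2)
  fwd <- applyDisplacement(smooth, -fieldShifts(sw$field))
  back <- applyDisplacement(fwd, fieldShifts(sw$field))
  interior <- back[8:40, 8:40] - smooth[8:40, 8:40]
  expect_lt(mean(abs(interior)), 0.02)

  expect_error(applyDisplacement(ramp, array(0, c(4, 4, 2))), "shape")
})

test_that("elastic registration recovers rigid and smooth warps", {
  # reference against itself: essentially zero field
  ref <- textureImage(31, 200)
  s <- fieldShifts(elasticRegister(ref, ref, minBlock = 30L))
  expect_lt(max(abs(s)), 0.1)

  # rigid shift by (4, 7), wrap-free via cropping a larger phantom
  big <- textureImage(32, 300)
  refc <- big[23:278, 23:278]
  movc <- big[(23 - 4):(278 - 4), (23 - 7):(278 - 7)]
  g <- fieldShifts(elasticRegister(refc, movc))
  epe <- sqrt((g[, , 1] + 4)^2 + (g[, , 2] + 7)^2)
  expect_lt(mean(epe[41:216, 41:216]), 0.5)

  # smooth sinusoidal-scale warp of amplitude 6 px
  base <- textureImage(33, 384)
  sw <- syntheticWarp(base, seed = 9, amplitude = 6)
  fld <- elasticRegister(base, sw$warped, minBlock = 60L)
  g <- fieldShifts(fld); gt <- fieldShifts(sw$field)
  epe <- sqrt((g[, , 1] - gt[, , 1])^2 + (g[, , 2] - gt[, , 2])^2)
  expect_lt(mean(epe[40:344, 40:344]), 1.5)

  # registration raises correlation with the reference
  c0 <- cor(as.vector(base), as.vector(sw$warped))
  c1 <- cor(as.vector(base),
            as.vector(applyDisplacement(sw$warped, fld)))
  expect_gt(c1, c0)

  expect_error(elasticRegister(ref, ref[1:100, 1:100]), "same shape")
})

test_that("a second pyramid level does not degrade the recovered field", {
  base <- textureImage(35, 320)
  sw <- syntheticWarp(base, seed = 13, amplitude = 5)
  gt <- fieldShifts(sw$field)
  epeOf <- function(minBlock) {
    g <- fieldShifts(elasticRegister(base, sw$warped, minBlock = minBlock))
    mean(sqrt((g[, , 1] - gt[, , 1])^2 +
                (g[, , 2] - gt[, , 2])^2)[33:288, 33:288])
  }
  one <- epeOf(64L)   # single level (blocks of 64 halve below the floor)
  two <- epeOf(30L)   # adds a refinement level
  expect_lte(two, one + 0.05)
})

test_that("coarse registration locates the inverted DAPI template", {
  set.seed(7)
  ph <- generatePhantom(seed = 41, height = 96, width = 96)
  dapi <- ph@channels[, , 1]
  canvas <- matrix(runif(256 * 256, 0, 0.2), 256, 256)
  canvas[121:216, 81:176] <- max(dapi) - dapi  # embed at offset (120, 80)
  res <- coarseRegister(canvas, dapi)
  expect_lte(max(abs(res$offset - c(120, 80))), 1)
  expect_equal(dim(res$crop), dim(dapi))

  canvas0 <- matrix(runif(200 * 200, 0, 0.2), 200, 200)
  canvas0[1:96, 1:96] <- max(dapi) - dapi
  expect_equal(coarseRegister(canvas0, dapi)$offset, c(0, 0))

  # two placements with identical correlation: smallest row, then column
  tpl <- matrix(runif(64), 8, 8)
  duo <- matrix(0.5, 40, 40)
  duo[5:12, 3:10] <- max(tpl) - tpl
  duo[21:28, 17:24] <- max(tpl) - tpl
  expect_equal(coarseRegister(duo, tpl)$offset, c(4, 2))

  expect_error(coarseRegister(matrix(1, 50, 50), matrix(1, 20, 20)),
               "degenerate")
})

test_that("rigid mutual-information refinement recovers small rotations", {
  img <- textureImage(51, 160)
  pre <- refineRigid(img, img)
  expect_equal(pre$rotation, 0)
  expect_equal(pre$translation, c(0, 0))

  rot <- stainmux:::.rigidWarp(img, -2, c(0, 0))  # moving rotated by -2 deg
  rec <- refineRigid(img, rot, maxShift = 6)
  expect_lt(abs(rec$rotation - 2), 0.2)

  expect_warning(refineRigid(img, matrix(1, 160, 160)),
                 "failed to improve")
})
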