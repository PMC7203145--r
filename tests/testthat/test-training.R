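test_that("total variation matches direct enumeration", {
  expect_equal(totalVariation(matrix(3, 6, 6)), 0)
  # [[0,1],[0,1]] by rows: vertical diffs 0, horizontal diffs 1 + 1
  z <- matrix(c(0, 0, 1, 1), 2, 2)
  expect_equal(totalVariation(z), 2)
  set.seed(20)
  a <- matrix(rnorm(48), 6, 8)
  expect_gte(totalVariation(a), 0)
  expect_equal(totalVariation(a + 17.3), totalVariation(a))
  # channels sum
  expect_equal(totalVariation(array(c(a, a), c(6, 8, 2))),
               2 * totalVariation(a))
})

test_that("L1 distance is the mean absolute error", {
  a <- array(runif(60), c(5, 4, 3))
  expect_equal(l1Distance(a, a), 0)
  expect_equal(l1Distance(array(1, c(3, 3, 3)), array(0, c(3, 3, 3))), 1)
  expect_equal(l1Distance(matrix(c(0, 1), 1, 2), matrix(c(1, 1), 1, 2)),
               0.5)
  expect_error(l1Distance(a, a[, , 1:2]), "shape")
})

test_that("generator loss reproduces plug-in evaluations", {
  z <- array(0.4, c(8, 8, 3))
  x <- array(0, c(8, 8, 5))
  cond <- c(1, 0, 0)
  Gperfect <- function(x, c) z

  l <- generatorLoss(z, x, cond, Gperfect, function(img, c) 1)
  expect_equal(l$total, 0)

  zt <- array(runif(8 * 8 * 3), c(8, 8, 3))
  l2 <- generatorLoss(zt, x, cond, function(x, c) zt, function(img, c) 1,
                      lambda = 0.02)
  expect_equal(l2$total, 0.02 * totalVariation(zt))

  # D = 0.5, perfect constant output, alpha = 2000: total 2000 * 0.25 = 500
  l3 <- generatorLoss(z, x, cond, Gperfect, function(img, c) 0.5,
                      alpha = 2000)
  expect_equal(l3$total, 500)
  expect_equal(l3$adv, 500)

  # decomposition holds on random stubs
  set.seed(31)
  for (r in 1:5) {
    out <- array(runif(192), c(8, 8, 3))
    d <- runif(1, 0.01, 0.99)
    l <- generatorLoss(zt, x, cond, function(x, c) out,
                       function(img, c) d)
    expect_equal(l$total, l$l1 + l$tv + l$adv, tolerance = 1e-6)
    expect_equal(l$l1, mean(abs(zt - out)))
    expect_equal(l$adv, 2000 * (1 - d)^2)
  }
})

test_that("discriminator loss is the printed squared-error form", {
  z <- array(0.5, c(4, 4, 3)); x <- array(0, c(4, 4, 5))
  G <- function(x, c) z
  mk <- function(pf, pr) {
    force(pf); force(pr); n <- 0
    function(img, c) { n <<- n + 1; if (n %% 2 == 1) pf else pr }
  }
  expect_equal(discriminatorLoss(z, x, c(1, 0, 0), G, mk(0, 1)), 0)
  expect_equal(discriminatorLoss(z, x, c(1, 0, 0), G, mk(0.5, 0.5)), 0.5)
  set.seed(5)
  for (r in 1:10) {
    v <- discriminatorLoss(z, x, c(1, 0, 0), G,
                           mk(runif(1, 0.01, 0.99), runif(1, 0.01, 0.99)))
    expect_gte(v, 0); expect_lte(v, 2)
  }
})

test_that("zero-step training returns the seeded initialization", {
  patches <- smallPatchSet()
  gspec <- tinyGenSpec(); dspec <- tinyDiscSpec(32)
  cfg <- trainingConfig(totalDiscriminatorSteps = 0, seed = 7)
  res <- trainStainGAN(patches, gspec, dspec, cfg)
  expect_equal(res$model@generator, initGenerator(gspec, seed = 7))
  expect_equal(nrow(res$history), 0L)
})

test_that("training is deterministic and decomposes its loss", {
  patches <- smallPatchSet()[1:16]
  gspec <- tinyGenSpec(); dspec <- tinyDiscSpec(32)
  cfg <- trainingConfig(totalDiscriminatorSteps = 2, seed = 11,
                        batchSize = 4)
  r1 <- trainStainGAN(patches, gspec, dspec, cfg)
  r2 <- trainStainGAN(patches, gspec, dspec, cfg)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$model@generator, r2$model@generator)
  h <- r1$history
  expect_true(all(abs(h$total - (h$l1 + h$tv + h$adv)) < 1e-6))
  expect_true(all(is.finite(c(h$l1, h$tv, h$adv))))
  expect_length(attr(h, "discLoss"), 2L)
})

test_that("a short run reduces the generator L1 on the tiny dataset", {
  patches <- smallPatchSet(nSlides = 9, seed = 17)
  gspec <- tinyGenSpec(); dspec <- tinyDiscSpec(32)
  # desk-scale learning rates (calibrated once; 50:1 G:D ratio kept)
  cfg <- trainingConfig(totalDiscriminatorSteps = 25, seed = 1,
                        lrGenerator = 3e-3, lrDiscriminator = 6e-5)
  res <- trainStainGAN(patches, gspec, dspec, cfg)
  h <- res$history
  early <- mean(h$l1[1:5])
  late <- mean(h$l1[(nrow(h) - 4):nrow(h)])
  expect_lt(late, 0.5 * early)
})
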