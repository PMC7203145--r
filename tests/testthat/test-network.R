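test_that("leaky ReLU matches its definition", {
  expect_equal(leakyReLU(2.0), 2.0)
  expect_equal(leakyReLU(-1.0), -0.1)
  expect_equal(leakyReLU(0.0), 0.0)
  x <- c(-3, -0.5, 0, 0.5, 3)
  expect_equal(leakyReLU(x, slope = 0.2), c(-0.6, -0.1, 0, 0.5, 3))
})

test_that("generator halves sizes and doubles channels down the U", {
  spec <- tinyGenSpec()
  gen <- initGenerator(spec, seed = 2)
  x <- array(rnorm(64 * 64 * 5), c(64, 64, 5))
  fw <- genForward(gen, spec, x, keepCache = TRUE)
  expect_equal(dim(fw$y), c(64, 64, 3))

  # down-block l operates at 64 / 2^(l-1) and ends with channels 8 * 2^l
  for (l in 1:2) {
    d <- dim(fw$cache[[sprintf("d%d_3", l)]]$pre)
    expect_equal(d[1:2], rep(64 / 2^(l - 1), 2))
    expect_equal(d[3], 8 * 2^l)
  }
  # up-block l ends with channels 8 * 2^(l-1)
  for (l in 1:2) {
    d <- dim(fw$cache[[sprintf("u%d_3", l)]]$pre)
    expect_equal(d[3], 8 * 2^(l - 1))
  }

  expect_error(genForward(gen, spec, array(0, c(30, 30, 5))),
               "divisible")
  expect_error(genForward(gen, spec, array(0, c(64, 64, 4))), "channels")
})

test_that("output shape contract holds over a sweep of small specs", {
  for (cfg in list(c(1, 4), c(2, 4), c(2, 8), c(3, 4))) {
    spec <- generatorSpec(levels = cfg[1], stemChannels = cfg[2],
                          nStains = 3)
    gen <- initGenerator(spec, seed = 1)
    n <- 8 * 2^cfg[1]
    y <- genForward(gen, spec, array(rnorm(n * n * 5), c(n, n, 5)))$y
    expect_equal(dim(y), c(n, n, 3))
  }
})

test_that("the generator is fully convolutional across input sizes", {
  spec <- tinyGenSpec()
  gen <- initGenerator(spec, seed = 5)
  y32 <- genForward(gen, spec, array(0.5, c(32, 32, 5)))$y
  y64 <- genForward(gen, spec, array(0.5, c(64, 64, 5)))$y
  expect_equal(dim(y32), c(32, 32, 3))
  expect_equal(dim(y64), c(64, 64, 3))
  # identical weights on constant input: central responses agree (border
  # effects decay with the small init weights)
  expect_equal(y32[16, 16, ], y64[32, 32, ], tolerance = 1e-6)
})

test_that("zeroed final layer yields a constant output", {
  spec <- tinyGenSpec()
  gen <- initGenerator(spec, seed = 3)
  gen$final$W[] <- 0
  gen$final$b[] <- c(0.2, 0.5, 0.8)
  y <- genForward(gen, spec, array(rnorm(32 * 32 * 5), c(32, 32, 5)))$y
  for (ch in 1:3)
    expect_equal(max(abs(y[, , ch] - gen$final$b[ch])), 0)
})

test_that("generator gradients match finite differences", {
  set.seed(9)
  spec <- generatorSpec(levels = 2, stemChannels = 4, nStains = 3)
  gen <- initGenerator(spec, seed = 7)
  x <- array(rnorm(16 * 16 * 5), c(16, 16, 5))
  z <- array(rnorm(16 * 16 * 3), c(16, 16, 3))
  lossOf <- function(g) {
    y <- genForward(g, spec, x)$y
    mean(abs(z - y)) + 0.01 * totalVariation(y)
  }
  fw <- genForward(gen, spec, x, keepCache = TRUE)
  gy <- sign(fw$y - z) / length(z) + 0.01 * stainmux:::.tvGrad(fw$y)
  gr <- genBackward(gen, spec, fw$cache, gy)
  eps <- 1e-6
  bump <- function(tree, path, i) {
    if (length(path) == 0) { tree$W[i] <- tree$W[i] + eps; return(tree) }
    tree[[path[[1]]]] <- bump(tree[[path[[1]]]], path[-1], i)
    tree
  }
  pick <- function(tree, path) { for (s in path) tree <- tree[[s]]; tree }
  for (path in list(list("stem"), list("down", 1, 2), list("up", 2, 1),
                    list("final"))) {
    g <- pick(gr, path); p <- pick(gen, path)
    i <- sample(length(p$W), 1)
    num <- (lossOf(bump(gen, path, i)) - lossOf(gen)) / eps
    expect_equal(num, g$W[i], tolerance = 1e-3)
  }
})

test_that("discriminator scores lie in (0,1) and react to the condition", {
  spec <- tinyDiscSpec(patchSize = 32)
  disc <- initDiscriminator(spec, seed = 4)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  c1 <- array(rep(c(1, 0, 0), each = 1024), c(32, 32, 3))
  c2 <- array(rep(c(0, 1, 0), each = 1024), c(32, 32, 3))
  p1 <- discForward(disc, spec, img, c1)$p
  p2 <- discForward(disc, spec, img, c2)$p
  expect_true(p1 > 0 && p1 < 1)
  expect_false(identical(p1, p2))
  expect_error(discForward(disc, spec, img, array(1, c(16, 16, 3))),
               "spatial shape")
  expect_error(discForward(disc, spec, array(0, c(16, 16, 3)),
                           array(1, c(16, 16, 3))), "fixed")
})

test_that("discriminator input gradient matches finite differences", {
  set.seed(12)
  spec <- discriminatorSpec(blocks = 2, stemChannels = 4, nStains = 3,
                            patchSize = 16, fcHidden = 8)
  disc <- initDiscriminator(spec, seed = 3)
  # scale weights up so gradients are far from rounding noise
  disc <- rapply(disc, function(x) x * 8, how = "replace")
  img <- array(rnorm(16 * 16 * 3), c(16, 16, 3))
  cond <- array(1 / 3, c(16, 16, 3))
  fw <- discForward(disc, spec, img, cond, keepCache = TRUE)
  bw <- discBackward(disc, spec, fw$cache, 1)
  bwNoPar <- discBackward(disc, spec, fw$cache, 1, paramGrads = FALSE)
  expect_equal(bwNoPar$gimg, bw$gimg)
  eps <- 1e-5
  for (t in 1:5) {
    i <- sample(length(img), 1)
    up <- img; up[i] <- up[i] + eps
    dn <- img; dn[i] <- dn[i] - eps
    num <- (discForward(disc, spec, up, cond)$p -
              discForward(disc, spec, dn, cond)$p) / (2 * eps)
    expect_equal(num, bw$gimg[i], tolerance = 1e-4)
  }
})

test_that("checkpoints round-trip and enforce the stain ordering", {
  spec <- tinyGenSpec(); dspec <- tinyDiscSpec(32)
  model <- new("StainGAN", genSpec = spec, discSpec = dspec,
               generator = initGenerator(spec, 1),
               discriminator = initDiscriminator(dspec, 2),
               stainNames = c("HE", "MT", "JS"))
  path <- withr::local_tempfile(fileext = ".rds")
  saveCheckpoint(model, path)
  back <- loadCheckpoint(path, expectedStains = c("HE", "MT", "JS"))
  expect_equal(back@generator, model@generator)
  expect_error(loadCheckpoint(path, expectedStains = c("MT", "HE", "JS")),
               "ordering")
})
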