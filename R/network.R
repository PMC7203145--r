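# Conditional generator / discriminator architectures.
#
# Generator: U-net. A stem convolution lifts the (2 + N_stains)-channel input
# (two autofluorescence planes with the staining-matrix planes concatenated)
# to `stemChannels`. Each down-block applies three 3x3 convolutions (Leaky
# ReLU, slope 0.1) that together double the channel count, then 2x2 average
# pooling with stride 2. Each up-block bilinearly upsamples by 2, concatenates
# the matching down-block output (skip connection), and applies three
# convolutions that together reduce the channels by a factor of four. A final
# 3x3 convolution maps to the 3 output colour planes (YCbCr). All
# convolutions are same-padded so sizes follow the halving/doubling exactly.
#
# Discriminator: a stem convolution maps the 6 input planes (3 YCbCr from
# either the generator output or the target, plus the staining-matrix planes)
# to `stemChannels`; each of `blocks` blocks applies a stride-1 convolution
# and then a stride-2 convolution that doubles the channels; the result is
# flattened through two fully connected layers to a single sigmoid score.
#
# Forward passes optionally record caches; backward passes consume them and
# return gradients in the same nested-list shape as the parameters (verified
# against finite differences in the test suite).

#' Leaky rectified linear activation
#'
#' `x` for positive `x`, `slope * x` otherwise.
#'
#' @param x numeric vector or array.
#' @param slope negative-side slope (default 0.1).
#' @return object of the same shape.
#' @export
leakyReLU <- function(x, slope = 0.1) {
  neg <- x < 0
  x - (1 - slope) * (x * neg)
}

.lreluBwd <- function(pre, g, slope = 0.1)
  g - (1 - slope) * (g * (pre < 0))

#' Generator architecture specification
#'
#' @param levels number of down/up block pairs (default 4).
#' @param stemChannels channels after the stem convolution (default 32).
#' @param nStains number of stain classes concatenated to the 2
#'   autofluorescence planes.
#' @param slope Leaky ReLU negative slope.
#' @return list describing the architecture.
#' @export
generatorSpec <- function(levels = 4L, stemChannels = 32L, nStains = 3L,
                          slope = 0.1) {
  stopifnot(levels >= 1L, stemChannels >= 1L, nStains >= 1L)
  list(levels = as.integer(levels), stemChannels = as.integer(stemChannels),
       nStains = as.integer(nStains),
       inChannels = 2L + as.integer(nStains), outChannels = 3L,
       slope = slope)
}

#' Discriminator architecture specification
#'
#' @param blocks number of stride-2 blocks (default 5).
#' @param stemChannels channels after the stem convolution (default 64).
#' @param nStains number of staining-matrix planes (3 image planes are added
#'   to these).
#' @param patchSize the fixed input size the fully connected head operates
#'   on (default 256).
#' @param fcHidden width of the first fully connected layer.
#' @param slope Leaky ReLU negative slope.
#' @return list describing the architecture.
#' @export
discriminatorSpec <- function(blocks = 5L, stemChannels = 64L, nStains = 3L,
                              patchSize = 256L, fcHidden = 64L, slope = 0.1) {
  stopifnot(blocks >= 1L, stemChannels >= 1L)
  list(blocks = as.integer(blocks), stemChannels = as.integer(stemChannels),
       nStains = as.integer(nStains), inChannels = 3L + as.integer(nStains),
       patchSize = as.integer(patchSize), fcHidden = as.integer(fcHidden),
       slope = slope)
}

# Truncated normal init (values beyond 2 sd are redrawn), std 0.02.
.truncNormal <- function(n, sd = 0.02) {
  x <- stats::rnorm(n, sd = sd)
  bad <- abs(x) > 2 * sd
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), sd = sd)
    bad <- abs(x) > 2 * sd
  }
  x
}

.convInit <- function(cin, cout, sd = 0.02) {
  list(W = matrix(.truncNormal(cout * cin * 9L, sd), cout, cin * 9L),
       b = rep(0, cout))
}

.genChannels <- function(spec) {
  S <- spec$stemChannels; L <- spec$levels
  down <- lapply(seq_len(L), function(l) c(S * 2^(l - 1L), S * 2^l))
  up <- lapply(seq_len(L), function(l) c(S * 2^(l + 1L), S * 2^(l - 1L)))
  list(down = down, up = up)
}

#' Initialize generator parameters
#'
#' Weights are drawn from a truncated normal (sd 0.02, seeded); biases are
#' zero.
#'
#' @param spec a [generatorSpec()].
#' @param seed integer seed.
#' @return nested list of parameter arrays.
#' @export
initGenerator <- function(spec, seed = 1L) {
  .withSeed(seed, {
    ch <- .genChannels(spec)
    down <- lapply(ch$down, function(io)
      list(.convInit(io[1], io[2]), .convInit(io[2], io[2]),
           .convInit(io[2], io[2])))
    up <- lapply(ch$up, function(io)
      list(.convInit(io[1], io[2]), .convInit(io[2], io[2]),
           .convInit(io[2], io[2])))
    list(stem = .convInit(spec$inChannels, spec$stemChannels),
         down = down, up = up,
         final = .convInit(spec$stemChannels, spec$outChannels))
  })
}

#' Initialize discriminator parameters
#'
#' @param spec a [discriminatorSpec()].
#' @param seed integer seed.
#' @return nested list of parameter arrays.
#' @export
initDiscriminator <- function(spec, seed = 1L) {
  .withSeed(seed, {
    S <- spec$stemChannels
    blocks <- lapply(seq_len(spec$blocks), function(b) {
      cin <- S * 2^(b - 1L)
      list(conv1 = .convInit(cin, cin), conv2 = .convInit(cin, 2L * cin))
    })
    side <- spec$patchSize %/% (2L^spec$blocks)
    flat <- side * side * S * 2L^spec$blocks
    list(stem = .convInit(spec$inChannels, S), blocks = blocks,
         fc1 = list(W = matrix(.truncNormal(spec$fcHidden * flat, 0.02),
                               spec$fcHidden, flat),
                    b = rep(0, spec$fcHidden)),
         fc2 = list(W = matrix(.truncNormal(spec$fcHidden, 0.02), 1L,
                               spec$fcHidden),
                    b = 0))
  })
}

.convA <- function(x, p, slope, stride = 1L, cache = NULL, name = NULL) {
  y <- sm_conv2d_fwd(x, p$W, p$b, stride)
  a <- leakyReLU(y, slope)
  if (!is.null(cache)) cache[[name]] <- list(x = x, pre = y)
  list(a = a, cache = cache)
}

#' Generator forward pass
#'
#' @param gen generator parameters from [initGenerator()].
#' @param spec the matching [generatorSpec()].
#' @param x numeric `H x W x (2 + nStains)` input stack; `H` and `W` must be
#'   divisible by `2^levels`.
#' @param keepCache record intermediates for [genBackward()].
#' @return list with `y` (the `H x W x 3` YCbCr output) and `cache`.
#' @export
genForward <- function(gen, spec, x, keepCache = FALSE) {
  d <- dim(x)
  if (length(d) != 3L || d[3] != spec$inChannels)
    stop(sprintf("input must have %d channels", spec$inChannels))
  if (d[1] %% 2^spec$levels != 0L || d[2] %% 2^spec$levels != 0L)
    stop(sprintf("spatial size must be divisible by 2^levels = %d",
                 2^spec$levels))
  sl <- spec$slope
  cache <- if (keepCache) list() else NULL
  st <- .convA(x, gen$stem, sl, 1L, cache, "stem"); a <- st$a; cache <- st$cache
  skips <- vector("list", spec$levels)
  for (l in seq_len(spec$levels)) {
    for (k in 1:3) {
      st <- .convA(a, gen$down[[l]][[k]], sl, 1L, cache,
                   sprintf("d%d_%d", l, k))
      a <- st$a; cache <- st$cache
    }
    skips[[l]] <- a
    a <- sm_avgpool2_fwd(a)
  }
  for (l in rev(seq_len(spec$levels))) {
    a <- sm_upsample2_fwd(a)
    nUp <- dim(a)[3]
    a <- .concat3(a, skips[[l]])
    if (keepCache) cache[[sprintf("u%d_split", l)]] <- nUp
    for (k in 1:3) {
      st <- .convA(a, gen$up[[l]][[k]], sl, 1L, cache, sprintf("u%d_%d", l, k))
      a <- st$a; cache <- st$cache
    }
  }
  y <- sm_conv2d_fwd(a, gen$final$W, gen$final$b, 1L)
  if (keepCache) cache$final <- list(x = a)
  list(y = y, cache = cache)
}

.concat3 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3]))
  out[, , seq_len(da[3])] <- a
  out[, , da[3] + seq_len(db[3])] <- b
  out
}

.convBwd <- function(cache, p, g, slope, stride = 1L, paramGrads = TRUE) {
  gpre <- .lreluBwd(cache$pre, g, slope)
  sm_conv2d_bwd(cache$x, p$W, gpre, stride, paramGrads)
}

#' Generator backward pass
#'
#' @param gen generator parameters.
#' @param spec the matching [generatorSpec()].
#' @param cache cache from `genForward(..., keepCache = TRUE)`.
#' @param gy gradient of the loss with respect to the generator output.
#' @return nested list of parameter gradients shaped like `gen`.
#' @export
genBackward <- function(gen, spec, cache, gy) {
  sl <- spec$slope
  grads <- list(down = vector("list", spec$levels),
                up = vector("list", spec$levels))
  bw <- sm_conv2d_bwd(cache$final$x, gen$final$W, gy, 1L)
  grads$final <- list(W = bw$gW, b = bw$gb)
  g <- bw$gx
  gskips <- vector("list", spec$levels)
  for (l in seq_len(spec$levels)) {
    glist <- vector("list", 3L)
    for (k in 3:1) {
      cb <- .convBwd(cache[[sprintf("u%d_%d", l, k)]], gen$up[[l]][[k]], g, sl)
      glist[[k]] <- list(W = cb$gW, b = cb$gb)
      g <- cb$gx
    }
    grads$up[[l]] <- glist
    nUp <- cache[[sprintf("u%d_split", l)]]
    gskips[[l]] <- g[, , (nUp + 1L):dim(g)[3], drop = FALSE]
    g <- sm_upsample2_bwd(g[, , seq_len(nUp), drop = FALSE])
  }
  for (l in rev(seq_len(spec$levels))) {
    g <- sm_avgpool2_bwd(g)
    g <- g + gskips[[l]]
    glist <- vector("list", 3L)
    for (k in 3:1) {
      cb <- .convBwd(cache[[sprintf("d%d_%d", l, k)]], gen$down[[l]][[k]], g,
                     sl)
      glist[[k]] <- list(W = cb$gW, b = cb$gb)
      g <- cb$gx
    }
    grads$down[[l]] <- glist
  }
  cb <- .convBwd(cache$stem, gen$stem, g, sl)
  grads$stem <- list(W = cb$gW, b = cb$gb)
  grads
}

#' Discriminator forward pass
#'
#' @param disc discriminator parameters from [initDiscriminator()].
#' @param spec the matching [discriminatorSpec()].
#' @param img numeric `S x S x 3` YCbCr image (generator output or target),
#'   where `S` is the spec's `patchSize`.
#' @param cond numeric `S x S x nStains` staining-matrix planes.
#' @param keepCache record intermediates for [discBackward()].
#' @return list with `p` (scalar in (0, 1)) and `cache`.
#' @export
discForward <- function(disc, spec, img, cond, keepCache = FALSE) {
  if (!identical(dim(img)[1:2], dim(cond)[1:2]))
    stop("image and staining matrix must share spatial shape")
  if (dim(img)[1] != spec$patchSize || dim(img)[2] != spec$patchSize)
    stop(sprintf("discriminator operates on fixed %d x %d inputs",
                 spec$patchSize, spec$patchSize))
  x <- .concat3(img, cond)
  sl <- spec$slope
  cache <- if (keepCache) list() else NULL
  st <- .convA(x, disc$stem, sl, 1L, cache, "stem"); a <- st$a
  cache <- st$cache
  for (b in seq_len(spec$blocks)) {
    st <- .convA(a, disc$blocks[[b]]$conv1, sl, 1L, cache,
                 sprintf("b%d_1", b))
    a <- st$a; cache <- st$cache
    st <- .convA(a, disc$blocks[[b]]$conv2, sl, 2L, cache,
                 sprintf("b%d_2", b))
    a <- st$a; cache <- st$cache
  }
  flat <- as.vector(a)
  h1pre <- as.vector(disc$fc1$W %*% flat) + disc$fc1$b
  h1 <- leakyReLU(h1pre, sl)
  zpre <- sum(disc$fc2$W * h1) + disc$fc2$b
  p <- 1 / (1 + exp(-zpre))
  if (keepCache) {
    cache$flatDim <- dim(a)
    cache$flat <- flat; cache$h1pre <- h1pre; cache$h1 <- h1; cache$p <- p
  }
  list(p = p, cache = cache)
}

#' Discriminator backward pass
#'
#' @param disc discriminator parameters.
#' @param spec the matching [discriminatorSpec()].
#' @param cache cache from `discForward(..., keepCache = TRUE)`.
#' @param gp gradient of the loss with respect to the sigmoid output.
#' @param paramGrads when `FALSE`, only the input gradient is computed (used
#'   for the generator's adversarial term, where the discriminator's own
#'   parameters are not being updated).
#' @return list with `grads` (shaped like `disc`; `NULL` when
#'   `paramGrads = FALSE`) and `gimg`, the gradient with respect to the 3
#'   image input planes.
#' @export
discBackward <- function(disc, spec, cache, gp, paramGrads = TRUE) {
  sl <- spec$slope
  p <- cache$p
  gz <- gp * p * (1 - p)
  grads <- if (paramGrads)
    list(fc2 = list(W = gz * matrix(cache$h1, 1L), b = gz))
  gh1 <- gz * as.vector(disc$fc2$W)
  gh1pre <- .lreluBwd(cache$h1pre, gh1, sl)
  if (paramGrads)
    grads$fc1 <- list(W = outer(gh1pre, cache$flat), b = gh1pre)
  gflat <- as.vector(crossprod(disc$fc1$W, gh1pre))
  g <- array(gflat, cache$flatDim)
  if (paramGrads) grads$blocks <- vector("list", spec$blocks)
  for (b in rev(seq_len(spec$blocks))) {
    cb2 <- .convBwd(cache[[sprintf("b%d_2", b)]], disc$blocks[[b]]$conv2, g,
                    sl, 2L, paramGrads)
    g <- cb2$gx
    cb1 <- .convBwd(cache[[sprintf("b%d_1", b)]], disc$blocks[[b]]$conv1, g,
                    sl, 1L, paramGrads)
    g <- cb1$gx
    if (paramGrads)
      grads$blocks[[b]] <- list(conv1 = list(W = cb1$gW, b = cb1$gb),
                                conv2 = list(W = cb2$gW, b = cb2$gb))
  }
  cb <- .convBwd(cache$stem, disc$stem, g, sl, 1L, paramGrads)
  if (paramGrads) grads$stem <- list(W = cb$gW, b = cb$gb)
  list(grads = grads, gimg = cb$gx[, , 1:3, drop = FALSE])
}
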