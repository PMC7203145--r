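# Loss operators and the adversarial training loop.
#
# Generator loss = L1{z, G(x, c)} + lambda * TV{G(x, c)}
#                  + alpha * (1 - D(G(x, c), c))^2
# Discriminator loss = D(G(x, c), c)^2 + (1 - D(z, c))^2
#
# with L1 the mean absolute error over pixels and channels and TV the sum of
# absolute forward neighbour differences. Per discriminator update,
# `generatorSteps` generator updates are run on fresh batches; the
# discriminator then sees fakes regenerated with the current generator. Both
# networks use Adam (beta1 0.9, beta2 0.999, eps 1e-8).

#' Total variation of an image
#'
#' Sum over pixels of the absolute forward differences along rows and
#' columns (out-of-range neighbour terms at the last row/column are
#' omitted); channels of a multi-channel array are summed.
#'
#' @param z numeric matrix or `H x W x C` array, at least 2 x 2.
#' @return nonnegative scalar.
#' @export
totalVariation <- function(z) {
  f <- function(m)
    sum(abs(m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE])) +
    sum(abs(m[, -1, drop = FALSE] - m[, -ncol(m), drop = FALSE]))
  if (is.matrix(z)) return(f(z))
  stopifnot(length(dim(z)) == 3L)
  sum(vapply(seq_len(dim(z)[3]), function(c) f(z[, , c]), numeric(1)))
}

.tvGrad <- function(z) {
  g <- array(0, dim(z))
  for (c in seq_len(dim(z)[3])) {
    m <- z[, , c]
    dr <- sign(m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE])
    dc <- sign(m[, -1, drop = FALSE] - m[, -ncol(m), drop = FALSE])
    gm <- matrix(0, nrow(m), ncol(m))
    gm[-1, ] <- gm[-1, , drop = FALSE] + dr
    gm[-nrow(m), ] <- gm[-nrow(m), , drop = FALSE] - dr
    gm[, -1] <- gm[, -1, drop = FALSE] + dc
    gm[, -ncol(m)] <- gm[, -ncol(m), drop = FALSE] - dc
    g[, , c] <- gm
  }
  g
}

#' Mean absolute error between two images
#'
#' @param z,g numeric arrays of equal shape.
#' @return mean over pixels (and channels) of `|z - g|`.
#' @export
l1Distance <- function(z, g) {
  if (!identical(dim(z), dim(g))) stop("shape mismatch")
  mean(abs(z - g))
}

#' Generator loss
#'
#' Evaluates the generator objective for callables `G(x, cond)` and
#' `D(img, cond)`; `cond` is a [StainingMatrix-class] or bare weight array.
#'
#' @param zLabel target image.
#' @param xInput generator input stack.
#' @param cond stain condition passed through to `G` and `D`.
#' @param G generator callable returning an image.
#' @param D discriminator callable returning a scalar in (0, 1).
#' @param lambda total-variation weight (default 0.02).
#' @param alpha adversarial weight (default 2000).
#' @return list with `total` and components `l1`, `tv` (weighted) and
#'   `adv` (weighted); `total = l1 + tv + adv`.
#' @export
generatorLoss <- function(zLabel, xInput, cond, G, D, lambda = 0.02,
                          alpha = 2000) {
  out <- G(xInput, cond)
  l1 <- l1Distance(zLabel, out)
  tv <- lambda * totalVariation(out)
  d <- D(out, cond)
  adv <- alpha * (1 - d)^2
  comp <- c(l1 = l1, tv = tv, adv = adv)
  if (any(!is.finite(comp)))
    stop("training divergence: non-finite generator loss component")
  list(total = l1 + tv + adv, l1 = l1, tv = tv, adv = adv)
}

#' Discriminator loss
#'
#' `D(G(x, c), c)^2 + (1 - D(z, c))^2`: the squared-error adversarial loss.
#'
#' @inheritParams generatorLoss
#' @return scalar in `[0, 2]` for discriminator outputs in (0, 1).
#' @export
discriminatorLoss <- function(zLabel, xInput, cond, G, D) {
  fake <- D(G(xInput, cond), cond)
  real <- D(zLabel, cond)
  v <- fake^2 + (1 - real)^2
  if (!is.finite(v))
    stop("training divergence: non-finite discriminator loss")
  v
}

#' Build a training configuration
#'
#' @param totalDiscriminatorSteps fixed discriminator step budget.
#' @param lambda,alpha,lrGenerator,lrDiscriminator,generatorSteps,batchSize,seed
#'   see [TrainingConfig-class]; defaults are the published operating point.
#' @param checkpointEvery,checkpointDir optional periodic checkpointing.
#' @return a [TrainingConfig-class].
#' @export
trainingConfig <- function(totalDiscriminatorSteps, lambda = 0.02,
                           alpha = 2000, lrGenerator = 1e-4,
                           lrDiscriminator = 2e-6, generatorSteps = 10L,
                           batchSize = 8L, seed = 1L,
                           checkpointEvery = Inf, checkpointDir = "") {
  new("TrainingConfig", lambda = lambda, alpha = alpha,
      lrGenerator = lrGenerator, lrDiscriminator = lrDiscriminator,
      generatorSteps = as.integer(generatorSteps),
      batchSize = as.integer(batchSize),
      totalDiscriminatorSteps = as.integer(totalDiscriminatorSteps),
      seed = as.integer(seed), checkpointEvery = checkpointEvery,
      checkpointDir = checkpointDir)
}

# ---- Adam over nested parameter lists --------------------------------------

.zerosLike <- function(p) {
  if (is.list(p)) return(lapply(p, .zerosLike))
  p * 0
}

.treeOp <- function(f, ...) {
  args <- list(...)
  if (is.list(args[[1]])) {
    nm <- names(args[[1]])
    if (!is.null(nm)) args <- lapply(args, function(a) a[nm])  # align by name
    return(do.call(Map, c(list(function(...) .treeOp(f, ...)), args)))
  }
  do.call(f, args)
}

.adamInit <- function(params) list(m = .zerosLike(params),
                                   v = .zerosLike(params), t = 0L)

.adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- .treeOp(function(m, g) beta1 * m + (1 - beta1) * g, state$m,
                     grads)
  state$v <- .treeOp(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v,
                     grads)
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  params <- .treeOp(function(p, m, v) p - lr * (m / bc1) /
                      (sqrt(v / bc2) + eps),
                    params, state$m, state$v)
  list(params = params, state = state)
}

# ---- training loop ----------------------------------------------------------

.condArray <- function(cond, H, W, n) {
  if (is.array(cond) && length(dim(cond)) == 3L) return(cond)
  array(rep(cond, each = H * W), c(H, W, n))
}

# Per-sample generator gradient; returns grads plus the loss components.
# The TV regularizer is normalized per pixel and channel here so that, at
# lambda = 0.02, it sits near 2% of the L1 term (the published operating
# point); totalVariation() itself stays the raw printed sum.
.genSampleGrad <- function(gen, genSpec, disc, discSpec, patch, lambda,
                          alpha) {
  H <- dim(patch@input)[1]; W <- dim(patch@input)[2]
  condA <- .condArray(patch@condition, H, W, genSpec$nStains)
  x <- .concat3(patch@input, condA)
  fw <- genForward(gen, genSpec, x, keepCache = TRUE)
  z <- rgbToYcbcr(patch@target) / 255
  npx <- length(z)
  l1 <- l1Distance(z, fw$y)
  tv <- lambda * totalVariation(fw$y) / npx
  dfw <- discForward(disc, discSpec, fw$y, condA, keepCache = TRUE)
  adv <- alpha * (1 - dfw$p)^2
  gy <- sign(fw$y - z) / npx + lambda * .tvGrad(fw$y) / npx
  db <- discBackward(disc, discSpec, dfw$cache, -2 * alpha * (1 - dfw$p),
                     paramGrads = FALSE)
  gy <- gy + db$gimg
  grads <- genBackward(gen, genSpec, fw$cache, gy)
  list(grads = grads, l1 = l1, tv = tv, adv = adv, total = l1 + tv + adv)
}

.accumulate <- function(acc, g, w) {
  if (is.null(acc)) return(.treeOp(function(x) x * w, g))
  .treeOp(function(a, x) a + x * w, acc, g)
}

#' Train the conditional staining model
#'
#' Alternating adversarial optimization: per discriminator step,
#' `generatorSteps` generator updates are performed on fresh batches, then
#' one discriminator update on fakes regenerated with the current generator.
#' Both optimizers are Adam at the configured constant rates. Every source
#' of randomness (initialization, batch sampling) derives from the config
#' seed, so two runs with the same inputs are identical.
#'
#' Inside the loop the total-variation regularizer is normalized by pixel
#' and channel count, so that at `lambda = 0.02` it contributes about 2% of
#' the L1 term — the operating point the loss weights were chosen for. The
#' standalone [totalVariation()] operator is the raw (unnormalized) sum.
#'
#' @param patches list of [PatchPair-class] training units.
#' @param genSpec,discSpec architecture specs; the discriminator's
#'   `patchSize` must match the patch size.
#' @param config a [TrainingConfig-class].
#' @param stainNames ordered stain classes recorded in the checkpoint.
#' @param verbose print a progress line per discriminator step.
#' @return list with `model` (a [StainGAN-class]) and `history`, a
#'   data.frame with one row per generator step (columns `step`,
#'   `discStep`, `l1`, `tv`, `adv`, `total`) and the discriminator loss per
#'   discriminator step in `attr(history, "discLoss")`.
#' @export
trainStainGAN <- function(patches, genSpec, discSpec, config,
                          stainNames = defaultStains(), verbose = FALSE) {
  stopifnot(length(patches) > 0L)
  validObject(config)
  set.seed(config@seed)
  gen <- initGenerator(genSpec, seed = config@seed)
  disc <- initDiscriminator(discSpec, seed = config@seed + 1L)
  optG <- .adamInit(gen); optD <- .adamInit(disc)
  n <- length(patches)
  drawBatch <- function() sample.int(n, min(config@batchSize, n))
  hist <- list(); dloss <- numeric(0)
  gstep <- 0L
  for (dstep in seq_len(config@totalDiscriminatorSteps)) {
    for (it in seq_len(config@generatorSteps)) {
      idx <- drawBatch()
      acc <- NULL; comps <- c(l1 = 0, tv = 0, adv = 0, total = 0)
      for (i in idx) {
        sg <- .genSampleGrad(gen, genSpec, disc, discSpec, patches[[i]],
                             config@lambda, config@alpha)
        acc <- .accumulate(acc, sg$grads, 1 / length(idx))
        comps <- comps + c(sg$l1, sg$tv, sg$adv, sg$total) / length(idx)
      }
      if (any(!is.finite(comps)))
        stop("training divergence: non-finite loss at generator step ",
             gstep + 1L)
      up <- .adamStep(gen, acc, optG, config@lrGenerator)
      gen <- up$params; optG <- up$state
      gstep <- gstep + 1L
      hist[[gstep]] <- data.frame(step = gstep, discStep = dstep,
                                  l1 = comps[["l1"]], tv = comps[["tv"]],
                                  adv = comps[["adv"]],
                                  total = comps[["total"]])
    }
    # discriminator update on fakes from the current generator
    idx <- drawBatch()
    accD <- NULL; dl <- 0
    for (i in idx) {
      p <- patches[[i]]
      H <- dim(p@input)[1]; W <- dim(p@input)[2]
      condA <- .condArray(p@condition, H, W, genSpec$nStains)
      fake <- genForward(gen, genSpec, .concat3(p@input, condA))$y
      z <- rgbToYcbcr(p@target) / 255
      dfF <- discForward(disc, discSpec, fake, condA, keepCache = TRUE)
      dbF <- discBackward(disc, discSpec, dfF$cache, 2 * dfF$p)
      dfR <- discForward(disc, discSpec, z, condA, keepCache = TRUE)
      dbR <- discBackward(disc, discSpec, dfR$cache, -2 * (1 - dfR$p))
      accD <- .accumulate(accD, dbF$grads, 1 / length(idx))
      accD <- .accumulate(accD, dbR$grads, 1 / length(idx))
      dl <- dl + (dfF$p^2 + (1 - dfR$p)^2) / length(idx)
    }
    if (!is.finite(dl))
      stop("training divergence: non-finite discriminator loss at step ",
           dstep)
    up <- .adamStep(disc, accD, optD, config@lrDiscriminator)
    disc <- up$params; optD <- up$state
    dloss[dstep] <- dl
    if (verbose)
      message(sprintf(
        "D-step %d/%d: L1 %.4f TV %.4f adv %.2f D %.4f", dstep,
        config@totalDiscriminatorSteps, hist[[gstep]]$l1, hist[[gstep]]$tv,
        hist[[gstep]]$adv, dl))
    if (is.finite(config@checkpointEvery) && nzchar(config@checkpointDir) &&
        dstep %% config@checkpointEvery == 0L) {
      model <- new("StainGAN", genSpec = genSpec, discSpec = discSpec,
                   generator = gen, discriminator = disc,
                   stainNames = stainNames)
      saveCheckpoint(model, file.path(config@checkpointDir,
                                      sprintf("step%06d.rds", dstep)))
    }
  }
  history <- if (length(hist) > 0L) do.call(rbind, hist) else
    data.frame(step = integer(), discStep = integer(), l1 = numeric(),
               tv = numeric(), adv = numeric(), total = numeric())
  attr(history, "discLoss") <- dloss
  model <- new("StainGAN", genSpec = genSpec, discSpec = discSpec,
               generator = gen, discriminator = disc,
               stainNames = stainNames)
  list(model = model, history = history)
}
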