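# Seeded phantom generator with known ground truth: elliptical cells
# (nucleus / membrane ring / cytoplasm) on a dark background, two
# autofluorescence-like channels, deterministic per-stain oracle renderings,
# slide-disjoint dataset manifests, and smooth synthetic warps for the
# registration tests.

#' Generate a synthetic tissue phantom
#'
#' Places elliptical "cells" at seeded random positions: each cell has a
#' cytoplasm interior, a membrane ring along its boundary and an elliptical
#' nucleus at its center. Channel 1 emphasizes nuclei (DAPI-like) and
#' channel 2 membranes and cytoplasm (Texas-Red-like); both carry a smooth
#' multiplicative texture (so block correlation has signal) and additive
#' Gaussian noise. The noise-free channels are kept for the oracle
#' renderings.
#'
#' @param seed integer seed; the phantom is a pure function of its
#'   arguments.
#' @param height,width image size, at least 64.
#' @param density expected cell count per 32 x 32 pixel area (default 0.7);
#'   0 gives a pure background phantom.
#' @param noiseSd additive Gaussian noise sd on the input channels.
#' @return a [Phantom-class].
#' @export
generatePhantom <- function(seed = 1L, height = 256L, width = 256L,
                            density = 0.7, noiseSd = 0.05) {
  if (height < 64L || width < 64L) stop("phantom must be at least 64 x 64")
  .withSeed(seed, {
    lab <- matrix(0L, height, width)
    nCells <- round(density * height * width / 1024)
    rowIdx <- matrix(seq_len(height), height, width)
    colIdx <- matrix(seq_len(width), height, width, byrow = TRUE)
    for (k in seq_len(nCells)) {
      cy <- stats::runif(1, 8, height - 8)
      cx <- stats::runif(1, 8, width - 8)
      ra <- stats::runif(1, 9, 16); rb <- stats::runif(1, 9, 16)
      phi <- stats::runif(1, 0, pi)
      dy <- rowIdx - cy; dx <- colIdx - cx
      u <- cos(phi) * dy + sin(phi) * dx
      v <- -sin(phi) * dy + cos(phi) * dx
      rho <- sqrt((u / ra)^2 + (v / rb)^2)
      lab[lab == 0L & rho <= 0.85] <- 3L                       # cytoplasm
      lab[(lab == 0L | lab == 3L) & rho > 0.85 & rho <= 1] <- 2L  # membrane
      lab[rho <= 0.35] <- 1L                                   # nucleus
    }
    texture <- .smoothNoise(height, width, grid = 6L)
    tex <- 0.8 + 0.4 * texture
    ch1 <- (0.02 + 0.9 * (lab == 1L) + 0.12 * (lab == 3L) +
              0.05 * (lab == 2L)) * tex
    ch2 <- (0.02 + 0.85 * (lab == 2L) + 0.45 * (lab == 3L) +
              0.10 * (lab == 1L)) * tex
    clean <- array(c(ch1, ch2), c(height, width, 2))
    noisy <- clean + array(stats::rnorm(2 * height * width, sd = noiseSd),
                           dim(clean))
    noisy[noisy < 0] <- 0
    new("Phantom", labels = lab, channels = noisy, channelsClean = clean,
        seed = as.integer(seed))
  })
}

# Smooth random field in [0, 1]: bilinear interpolation of a coarse uniform
# grid (values drawn from the active RNG stream).
.smoothNoise <- function(H, W, grid = 6L) {
  g <- matrix(stats::runif(grid * grid), grid, grid)
  .bilinearGrid(g, H, W)
}

# Bilinear interpolation of a g x g grid spanning the image.
.bilinearGrid <- function(g, H, W) {
  gr <- nrow(g); gc <- ncol(g)
  ri <- (seq_len(H) - 0.5) / H * (gr - 1) + 1
  ci <- (seq_len(W) - 0.5) / W * (gc - 1) + 1
  r0 <- pmin(floor(ri), gr - 1); c0 <- pmin(floor(ci), gc - 1)
  wr <- ri - r0; wc <- ci - c0
  out <- matrix(0, H, W)
  for (j in seq_len(W)) {
    a <- g[cbind(r0, rep(c0[j], H))]; b <- g[cbind(r0 + 1, rep(c0[j], H))]
    cc <- g[cbind(r0, rep(c0[j] + 1, H))]
    d <- g[cbind(r0 + 1, rep(c0[j] + 1, H))]
    out[, j] <- (1 - wr) * ((1 - wc[j]) * a + wc[j] * cc) +
      wr * ((1 - wc[j]) * b + wc[j] * d)
  }
  out
}

#' Oracle stain colour tables
#'
#' Deterministic structure-to-colour maps loosely mimicking the real stains
#' (H&E: purple nuclei and pink cytoplasm; Masson's trichrome: blue-green
#' fibrous structures; Jones' silver: dark membranes). The values are fixed
#' constants for interpretability and make the three renderings of any
#' phantom well separated; they make no claim to real stain chemistry.
#'
#' For each stain and structure label the table holds an RGB colour and the
#' channel weights `(a, b)` that modulate stain uptake from the two clean
#' channels.
#'
#' @return named list, one entry per stain, each with a `colors` matrix
#'   (rows bg/nucleus/membrane/cytoplasm) and a `uptake` matrix of channel
#'   weights.
#' @export
oracleStainTable <- function() {
  list(
    HE = list(
      colors = rbind(bg = c(255, 255, 255), nucleus = c(70, 35, 120),
                     membrane = c(235, 140, 160), cytoplasm = c(240, 160, 180)),
      uptake = rbind(bg = c(0, 0), nucleus = c(1.0, 0.3),
                     membrane = c(0.3, 1.0), cytoplasm = c(0.8, 1.6))),
    MT = list(
      colors = rbind(bg = c(255, 255, 255), nucleus = c(60, 40, 110),
                     membrane = c(45, 110, 135), cytoplasm = c(190, 90, 90)),
      uptake = rbind(bg = c(0, 0), nucleus = c(1.0, 0.3),
                     membrane = c(0.2, 1.1), cytoplasm = c(0.6, 1.8))),
    JS = list(
      colors = rbind(bg = c(255, 255, 255), nucleus = c(110, 100, 110),
                     membrane = c(35, 25, 15), cytoplasm = c(225, 215, 170)),
      uptake = rbind(bg = c(0, 0), nucleus = c(0.9, 0.3),
                     membrane = c(0.1, 1.2), cytoplasm = c(0.7, 1.5))))
}

#' Deterministic oracle stain rendering of a phantom
#'
#' Renders the bright-field appearance of a phantom under one stain: each
#' pixel takes the stain's colour for its structure label, modulated toward
#' white by the stain uptake computed from the clean channels (so
#' background stays near white, the bright-field convention). No randomness
#' beyond the phantom itself.
#'
#' @param phantom a [Phantom-class].
#' @param stain stain name or index into `names(table)`.
#' @param table colour table from [oracleStainTable()].
#' @return numeric `H x W x 3` RGB array on the 0..255 scale.
#' @export
oracleStain <- function(phantom, stain, table = oracleStainTable()) {
  idx <- .resolveStain(stain, names(table))
  tab <- table[[idx]]
  lab <- phantom@labels + 1L  # 1..4 indexing into bg/nucleus/membrane/cyto
  if (max(lab) > nrow(tab$colors)) stop("label missing from the stain table")
  ch1 <- phantom@channelsClean[, , 1]; ch2 <- phantom@channelsClean[, , 2]
  m <- tab$uptake[lab, 1] * as.vector(ch1) + tab$uptake[lab, 2] * as.vector(ch2)
  m <- pmin(pmax(m, 0), 1)
  H <- nrow(lab); W <- ncol(lab)
  out <- array(0, c(H, W, 3))
  for (ch in 1:3) {
    colv <- tab$colors[lab, ch]
    out[, , ch] <- matrix(255 - (255 - colv) * m, H, W)
  }
  out
}

#' Blended oracle rendering
#'
#' Defined as the pixel-wise convex combination of the pure oracle
#' renderings; the reference for blend monotonicity checks.
#'
#' @param phantom a [Phantom-class].
#' @param weights stain weight vector (sums to one).
#' @param table colour table from [oracleStainTable()].
#' @return numeric `H x W x 3` RGB array.
#' @export
oracleBlend <- function(phantom, weights, table = oracleStainTable()) {
  msg <- .checkWeightVector(weights, "blend weights")
  if (!is.null(msg)) stop(msg)
  out <- 0
  for (i in seq_along(weights))
    if (weights[i] > 0)
      out <- out + weights[i] * oracleStain(phantom, i, table)
  out
}

#' Build a synthetic paired dataset with slide-disjoint splits
#'
#' Generates `nSlides` phantoms, assigns stains round-robin, renders the
#' oracle target for each slide's stain, and splits the slides (not the
#' patches) into train/val/test so that no slide contributes to two splits,
#' mirroring a patient-disjoint evaluation.
#'
#' @param nSlides number of slides (>= 3).
#' @param stainNames stain classes (must exist in `table`).
#' @param seed integer master seed.
#' @param size slide edge length.
#' @param splits named numeric fractions for train/val/test (sum to 1).
#' @param density,noiseSd phantom parameters, see [generatePhantom()].
#' @param table colour table from [oracleStainTable()].
#' @return list with `slides` (list of [SlidePair-class]), `phantoms`
#'   (list of [Phantom-class]) and `manifest` (data.frame with slide id,
#'   stain, split).
#' @export
makeStainDataset <- function(nSlides, stainNames = defaultStains(),
                             seed = 1L, size = 176L,
                             splits = c(train = 0.7, val = 0.1, test = 0.2),
                             density = 0.7, noiseSd = 0.05,
                             table = oracleStainTable()) {
  stopifnot(nSlides >= 3L, abs(sum(splits) - 1) < 1e-9)
  nStains <- length(stainNames)
  stain <- stainNames[(seq_len(nSlides) - 1L) %% nStains + 1L]
  # slide-disjoint split, stratified by stain via the round-robin ordering
  split <- character(nSlides)
  for (s in stainNames) {
    idx <- which(stain == s); m <- length(idx)
    nTrain <- max(1L, round(splits[["train"]] * m))
    nVal <- round(splits[["val"]] * m)
    nTest <- m - nTrain - nVal
    if (nTest < 1L && m >= 3L) { nTest <- 1L; nTrain <- m - nVal - nTest }
    split[idx] <- rep(c("train", "val", "test"),
                      times = c(nTrain, nVal, max(nTest, 0L)))[seq_len(m)]
  }
  slides <- vector("list", nSlides); phantoms <- vector("list", nSlides)
  for (i in seq_len(nSlides)) {
    ph <- generatePhantom(seed = seed * 1000L + i, height = size,
                          width = size, density = density,
                          noiseSd = noiseSd)
    target <- oracleStain(ph, stain[i], table)
    wts <- as.numeric(seq_len(nStains) == match(stain[i], stainNames))
    slides[[i]] <- new("SlidePair", af = ph@channels, target = target,
                       mask = ph@labels > 0L, stainWeights = wts)
    phantoms[[i]] <- ph
  }
  list(slides = slides, phantoms = phantoms,
       manifest = data.frame(slide = seq_len(nSlides), stain = stain,
                             split = split, stringsAsFactors = FALSE))
}

#' Apply a smooth random warp with known ground truth
#'
#' Draws a band-limited random displacement field (bilinear interpolation of
#' a coarse seeded grid, scaled so the maximum shift magnitude equals
#' `amplitude`), warps the image with bilinear sampling, and returns the
#' ground-truth registration field: the field `G` such that
#' `applyDisplacement(warped, G)` recovers the original image (solved by
#' fixed-point iteration of the warp's inverse, exact for the smooth fields
#' generated here).
#'
#' @param image numeric matrix.
#' @param seed integer seed.
#' @param amplitude maximum shift magnitude in pixels (0 gives the
#'   identity).
#' @param grid coarse grid resolution of the random field (default 4).
#' @return list with `warped` (matrix) and `field`
#'   (a [DisplacementField-class], the registration ground truth).
#' @export
syntheticWarp <- function(image, seed = 1L, amplitude = 4, grid = 4L) {
  stopifnot(is.matrix(image), amplitude >= 0)
  H <- nrow(image); W <- ncol(image)
  if (amplitude == 0) {
    zero <- array(0, c(H, W, 2))
    return(list(warped = image, field = new("DisplacementField",
                                            shifts = zero)))
  }
  Fw <- .withSeed(seed, {
    fy <- .bilinearGrid(matrix(stats::rnorm(grid * grid), grid, grid), H, W)
    fx <- .bilinearGrid(matrix(stats::rnorm(grid * grid), grid, grid), H, W)
    array(c(fy, fx), c(H, W, 2))
  })
  mag <- sqrt(Fw[, , 1]^2 + Fw[, , 2]^2)
  Fw <- Fw * (amplitude / max(mag))
  warped <- sm_warp(array(image, c(H, W, 1)), Fw, TRUE)[, , 1]
  # ground-truth inverse: G(p) = -Fw(q) at the fixed point q = p + Fw(q)
  qI <- matrix(seq_len(H), H, W); qJ <- matrix(seq_len(W), H, W, byrow = TRUE)
  pI <- qI; pJ <- qJ
  for (it in 1:8) {
    sy <- .bilinearSample(Fw[, , 1], qI, qJ)
    sx <- .bilinearSample(Fw[, , 2], qI, qJ)
    qI <- pI + sy; qJ <- pJ + sx
  }
  G <- array(c(-.bilinearSample(Fw[, , 1], qI, qJ),
               -.bilinearSample(Fw[, , 2], qI, qJ)), c(H, W, 2))
  list(warped = warped, field = new("DisplacementField", shifts = G))
}

# Bilinear sampling of matrix m at fractional (1-based) coordinates, edge
# clamped.
.bilinearSample <- function(m, I, J) {
  H <- nrow(m); W <- ncol(m)
  I <- pmin(pmax(I, 1), H); J <- pmin(pmax(J, 1), W)
  i0 <- pmin(floor(I), H - 1); j0 <- pmin(floor(J), W - 1)
  di <- I - i0; dj <- J - j0
  a <- m[cbind(as.vector(i0), as.vector(j0))]
  b <- m[cbind(as.vector(i0 + 1), as.vector(j0))]
  cc <- m[cbind(as.vector(i0), as.vector(j0 + 1))]
  d <- m[cbind(as.vector(i0 + 1), as.vector(j0 + 1))]
  matrix((1 - di) * ((1 - dj) * a + dj * cc) + di * ((1 - dj) * b + dj * d),
         H, W)
}
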