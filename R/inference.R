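# Inference: single patches, tiled whole slides with feathered stitching,
# blend series and ROI micro-structured staining.

.checkModelMatrix <- function(model, dsm) {
  validObject(dsm)
  if (!identical(stainNames(dsm), model@stainNames))
    stop(sprintf(
      "staining matrix stain ordering (%s) differs from the model's (%s)",
      paste(stainNames(dsm), collapse = ","),
      paste(model@stainNames, collapse = ",")))
}

#' Virtually stain one patch
#'
#' Runs the conditional generator on a two-channel autofluorescence patch
#' under the given staining matrix and converts the YCbCr output to 8-bit
#' RGB. Deterministic given the model weights and inputs.
#'
#' @param model a trained [StainGAN-class].
#' @param afPatch numeric `H x W x 2` autofluorescence stack (normalized).
#' @param dsm a [StainingMatrix-class] of the same spatial shape; must
#'   satisfy the encoding rule and match the model's stain ordering.
#' @return numeric `H x W x 3` RGB array with values in 0..255.
#' @export
stainPatch <- function(model, afPatch, dsm) {
  .checkModelMatrix(model, dsm)
  stopifnot(length(dim(afPatch)) == 3L, dim(afPatch)[3] == 2L)
  if (!identical(dim(afPatch)[1:2], dim(dsm)[1:2]))
    stop("staining matrix and patch must share spatial shape")
  x <- .concat3(afPatch, stainWeights(dsm))
  y <- genForward(model@generator, model@genSpec, x)$y
  clampToByte(ycbcrToRgb(y * 255))
}

# Feather weight map for a tile: linear ramp from the tile border over the
# overlap band, per axis, multiplied.
.featherMap <- function(size, overlap) {
  ramp <- pmin(pmin(seq_len(size), rev(seq_len(size))) / (overlap + 1), 1)
  outer(ramp, ramp)
}

#' Virtually stain a whole slide by tiled inference
#'
#' Applies [stainPatch()] over overlapping tiles and blends the overlap
#' bands by linear feathering, accumulating in YCbCr before a single
#' conversion to RGB. A slide no larger than one tile is processed in a
#' single pass.
#'
#' @param model a trained [StainGAN-class].
#' @param afSlide numeric `H x W x 2` autofluorescence stack.
#' @param dsm a [StainingMatrix-class] covering the slide.
#' @param tile tile edge length (default 256); must satisfy the generator's
#'   divisibility constraint.
#' @param overlap overlap band width in pixels (default 32).
#' @return numeric `H x W x 3` RGB array with values in 0..255.
#' @export
stainSlide <- function(model, afSlide, dsm, tile = 256L, overlap = 32L) {
  .checkModelMatrix(model, dsm)
  H <- dim(afSlide)[1]; W <- dim(afSlide)[2]
  if (!identical(dim(afSlide)[1:2], dim(dsm)[1:2]))
    stop("staining matrix and slide must share spatial shape")
  div <- 2^model@genSpec$levels
  if (tile > min(H, W)) tile <- min(H, W)  # single-tile fallback
  tile <- as.integer(tile - tile %% div)
  if (tile < div) stop("slide too small for the generator's divisibility")
  w <- stainWeights(dsm)
  positions <- function(n) {
    if (n <= tile) return(0L)
    step <- tile - overlap
    p <- seq(0L, n - tile, by = step)
    if (p[length(p)] != n - tile) p <- c(p, n - tile)
    as.integer(p)
  }
  accum <- array(0, c(H, W, 3)); wsum <- matrix(0, H, W)
  fm <- .featherMap(tile, overlap)
  for (r0 in positions(H)) for (c0 in positions(W)) {
    ri <- (r0 + 1L):(r0 + tile); ci <- (c0 + 1L):(c0 + tile)
    x <- .concat3(afSlide[ri, ci, , drop = FALSE],
                  w[ri, ci, , drop = FALSE])
    y <- genForward(model@generator, model@genSpec, x)$y
    for (ch in 1:3)
      accum[ri, ci, ch] <- accum[ri, ci, ch] + y[, , ch] * fm
    wsum[ri, ci] <- wsum[ri, ci] + fm
  }
  for (ch in 1:3) accum[, , ch] <- accum[, , ch] / wsum
  clampToByte(ycbcrToRgb(accum * 255))
}

#' Render a blend series between two stains
#'
#' For each ratio `r` the slide is stained under uniform blend weights
#' `r * e_a + (1 - r) * e_b`, sweeping the rendering from pure stain `b`
#' (`r = 0`) to pure stain `a` (`r = 1`).
#'
#' @param model a trained [StainGAN-class].
#' @param afImage numeric `H x W x 2` autofluorescence stack.
#' @param stainA,stainB stain names or indices.
#' @param ratios numeric vector of blend weights for `stainA`, each in
#'   `[0, 1]`.
#' @param tile,overlap tiling parameters passed to [stainSlide()].
#' @return list of RGB arrays, one per ratio.
#' @export
blendSeries <- function(model, afImage, stainA, stainB, ratios,
                        tile = 256L, overlap = 32L) {
  if (any(ratios < 0 | ratios > 1)) stop("ratios must lie in [0, 1]")
  ia <- .resolveStain(stainA, model@stainNames)
  ib <- .resolveStain(stainB, model@stainNames)
  H <- dim(afImage)[1]; W <- dim(afImage)[2]
  lapply(ratios, function(r) {
    wts <- rep(0, length(model@stainNames))
    wts[ia] <- wts[ia] + r
    wts[ib] <- wts[ib] + 1 - r
    stainSlide(model, afImage,
               blendMatrix(wts, H, W, model@stainNames), tile, overlap)
  })
}

#' Micro-structured staining from an ROI specification
#'
#' Rasterizes the ROI specification into a staining matrix and stains the
#' slide with it, so that each region of interest is rendered under its own
#' stain (or blend) and the remaining tissue under the default weights.
#'
#' @param model a trained [StainGAN-class].
#' @param afImage numeric `H x W x 2` autofluorescence stack.
#' @param roiSpec a [RoiSpec-class].
#' @param tile,overlap tiling parameters passed to [stainSlide()].
#' @return numeric `H x W x 3` RGB array with values in 0..255.
#' @export
microStructuredStain <- function(model, afImage, roiSpec, tile = 256L,
                                 overlap = 32L) {
  H <- dim(afImage)[1]; W <- dim(afImage)[2]
  dsm <- roiMatrix(roiSpec, H, W, model@stainNames)
  stainSlide(model, afImage, dsm, tile, overlap)
}
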