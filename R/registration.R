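# Co-registration: elastic pyramidal block matching between the two
# autofluorescence channels, coarse template matching of bright-field targets
# against a contrast-reversed DAPI channel, and an optional rigid
# mutual-information refinement.

.asMatrix <- function(x, what = "image") {
  if (is.matrix(x)) return(x)
  if (is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 1L)
    return(x[, , 1])
  stop(sprintf("%s must be a 2-D matrix", what))
}

#' Normalized cross-correlation shift between two blocks
#'
#' Finds the translation that best aligns `movingBlock` onto
#' `referenceBlock` as the peak of the normalized cross-correlation over
#' their overlap, refined to sub-pixel precision by a parabolic fit along
#' each axis. A constant (zero-variance) block carries no signal and yields
#' a degenerate match with zero shift and zero confidence.
#'
#' @param referenceBlock,movingBlock numeric matrices of equal shape,
#'   at least 8 x 8.
#' @param radius maximum shift searched, in pixels (default a third of the
#'   smaller block edge).
#' @return list with `shift` (row, col shift in pixels to apply to the
#'   moving block via [applyDisplacement()]), `confidence` (peak NCC in
#'   `[-1, 1]`) and `degenerate` (logical).
#' @export
blockShift <- function(referenceBlock, movingBlock, radius = NULL) {
  a <- .asMatrix(referenceBlock, "referenceBlock")
  b <- .asMatrix(movingBlock, "movingBlock")
  if (!identical(dim(a), dim(b))) stop("blocks must have equal shape")
  if (min(dim(a)) < 8L) stop("blocks must be at least 8 x 8")
  if (is.null(radius)) radius <- max(1L, floor(min(dim(a)) / 3))
  r <- sm_block_ncc_overlap(a, b, as.integer(radius))
  if (r[4] < 0.5)
    return(list(shift = c(0, 0), confidence = 0, degenerate = TRUE))
  # peak offset d satisfies moving(p + d) ~ reference(p); the field that
  # aligns moving onto reference is therefore -d
  list(shift = c(-r[1], -r[2]), confidence = unname(r[3]), degenerate = FALSE)
}

# Gaussian-weighted inverse-distance interpolation of block shifts into a
# dense field. Separable weights keep this O(blocks * H * W).
.interpolateShifts <- function(centers, shifts, H, W, sigma) {
  num1 <- matrix(0, H, W); num2 <- matrix(0, H, W); den <- matrix(0, H, W)
  rows <- seq_len(H) - 0.5; cols <- seq_len(W) - 0.5
  for (k in seq_len(nrow(centers))) {
    wr <- exp(-((rows - centers[k, 1])^2) / (2 * sigma^2))
    wc <- exp(-((cols - centers[k, 2])^2) / (2 * sigma^2))
    wk <- outer(wr, wc)
    num1 <- num1 + wk * shifts[k, 1]
    num2 <- num2 + wk * shifts[k, 2]
    den <- den + wk
  }
  den[den < 1e-300] <- 1e-300
  array(c(num1 / den, num2 / den), c(H, W, 2))
}

#' Elastic pyramidal registration
#'
#' Hierarchical block-matching registration: the image is split into a
#' `startGrid x startGrid` grid of blocks, each block's translation is
#' estimated as its normalized cross-correlation peak (sub-pixel refined),
#' and the block shifts are interpolated into a dense translation map by
#' Gaussian-weighted inverse-distance averaging from the block centers. The
#' moving image is warped by the current map, the block size is halved, and
#' the procedure repeats on the residual until blocks would fall below
#' `minBlock` pixels. Low-confidence blocks (peak correlation below
#' `confThreshold`, or constant blocks) contribute no estimate and inherit
#' the interpolated shift of their neighbours.
#'
#' @param reference,moving numeric matrices of equal shape.
#' @param startGrid blocks per image edge at the first level (default 5).
#' @param minBlock smallest block size, in pixels, that is still matched
#'   (default 100).
#' @param searchRadius maximum per-level residual shift searched; default is
#'   half the block edge capped at 20 px.
#' @param globalSearch radius of the initial whole-image shift search that
#'   seeds the pyramid (default 40 px).
#' @param confThreshold minimum NCC peak for a block to contribute.
#' @return a [DisplacementField-class] `G` such that
#'   `applyDisplacement(moving, G)` aligns onto `reference`.
#' @export
elasticRegister <- function(reference, moving, startGrid = 5L,
                            minBlock = 100L, searchRadius = NULL,
                            globalSearch = 40L, confThreshold = 0.2) {
  ref <- .asMatrix(reference, "reference")
  mov <- .asMatrix(moving, "moving")
  if (!identical(dim(ref), dim(mov))) stop("images must have the same shape")
  H <- nrow(ref); W <- ncol(ref)
  field <- array(0, c(H, W, 2))
  bh <- max(1L, H %/% startGrid); bw <- max(1L, W %/% startGrid)

  if (min(bh, bw) < 8L) {
    # image smaller than a usable block grid: single global shift
    bs <- blockShift(ref, mov)
    field[, , 1] <- bs$shift[1]; field[, , 2] <- bs$shift[2]
    return(new("DisplacementField", shifts = field))
  }

  # whole-image coarse shift so that per-block residuals stay small and
  # border blocks are not biased by clipped search windows
  gs <- sm_block_ncc_overlap(ref, mov, as.integer(min(globalSearch,
                                                      min(H, W) %/% 3)))
  if (gs[4] > 0.5 && gs[3] >= confThreshold) {
    field[, , 1] <- -gs[1]; field[, , 2] <- -gs[2]
  }
  warped <- sm_warp(array(mov, c(H, W, 1)), field, TRUE)[, , 1]

  repeat {
    nby <- max(1L, H %/% bh); nbx <- max(1L, W %/% bw)
    r0s <- if (nby == 1L) 0 else round(seq(0, H - bh, length.out = nby))
    c0s <- if (nbx == 1L) 0 else round(seq(0, W - bw, length.out = nbx))
    radius <- if (is.null(searchRadius)) min(floor(min(bh, bw) / 2), 20L)
              else as.integer(searchRadius)
    centers <- NULL; shifts <- NULL
    for (r0 in r0s) for (c0 in c0s) {
      m <- sm_block_search(ref, warped, as.integer(r0), as.integer(c0),
                           as.integer(bh), as.integer(bw), as.integer(radius))
      if (m[4] < 0.5 || m[3] < confThreshold) next
      if (max(abs(m[1:2])) >= radius - 0.5) next  # peak on the search border
      centers <- rbind(centers, c(r0 + bh / 2, c0 + bw / 2))
      shifts <- rbind(shifts, c(-m[1], -m[2]))
    }
    if (!is.null(centers)) {
      sigma <- max(mean(c(bh, bw)) / 2, 1)
      inc <- .interpolateShifts(centers, shifts, H, W, sigma)
      field <- field + inc
      warped <- sm_warp(array(mov, c(H, W, 1)), field, TRUE)[, , 1]
    }
    bh <- bh %/% 2L; bw <- bw %/% 2L
    if (min(bh, bw) < minBlock) break
  }
  new("DisplacementField", shifts = field)
}

#' Warp an image by a displacement field
#'
#' Samples `image(p - field(p))` with the chosen interpolation;
#' out-of-bounds samples clamp to the nearest edge pixel.
#'
#' @param image numeric matrix or `H x W x C` array.
#' @param field a [DisplacementField-class] (or bare `H x W x 2` array) with
#'   the same spatial shape as `image`.
#' @param interpolation `"bilinear"` or `"nearest"`.
#' @return warped image with the shape of `image`.
#' @export
applyDisplacement <- function(image, field,
                              interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  f <- if (is(field, "DisplacementField")) field@shifts else field
  wasMatrix <- is.matrix(image)
  img <- if (wasMatrix) array(image, c(dim(image), 1L)) else image
  if (!identical(dim(img)[1:2], dim(f)[1:2]))
    stop("field shape must match the image")
  out <- sm_warp(img, f, interpolation == "bilinear")
  if (wasMatrix) out[, , 1] else out
}

#' Coarse bright-field to autofluorescence registration
#'
#' Slides a contrast-reversed copy of the DAPI channel over the (grayscale)
#' bright-field image by normalized cross-correlation and returns the
#' best-matching placement. Ties are broken toward the smallest row offset,
#' then the smallest column offset.
#'
#' @param brightfieldGray numeric matrix, at least as large as `dapi`.
#' @param dapi numeric matrix, the DAPI-channel field of view.
#' @return list with `offset` (0-based row, col of the matched placement),
#'   `correlation` (peak NCC) and `crop` (the matching bright-field region).
#' @export
coarseRegister <- function(brightfieldGray, dapi) {
  bf <- .asMatrix(brightfieldGray, "brightfieldGray")
  dp <- .asMatrix(dapi, "dapi")
  if (nrow(bf) < nrow(dp) || ncol(bf) < ncol(dp))
    stop("bright-field image must be at least as large as the DAPI image")
  if (stats::sd(dp) < 1e-12 || stats::sd(bf) < 1e-12)
    stop("degenerate (constant) input image")
  templ <- max(dp) - dp
  cc <- sm_template_ncc(bf, templ)
  peak <- max(cc)
  cand <- which(cc > peak - 1e-12, arr.ind = TRUE)
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  r0 <- unname(cand[1, 1]); c0 <- unname(cand[1, 2])
  list(offset = c(r0 - 1L, c0 - 1L), correlation = peak,
       crop = bf[r0:(r0 + nrow(dp) - 1L), c0:(c0 + ncol(dp) - 1L)])
}

# Rigid transform of an image: rotation (degrees, counter-clockwise about the
# image center) followed by a translation (rows, cols), via the warp kernel.
.rigidWarp <- function(img, angle, translation) {
  H <- nrow(img); W <- ncol(img)
  th <- angle * pi / 180
  ci <- (H + 1) / 2; cj <- (W + 1) / 2
  ii <- matrix(seq_len(H), H, W) - ci
  jj <- matrix(seq_len(W), H, W, byrow = TRUE) - cj
  srcI <- cos(th) * ii + sin(th) * jj + ci - translation[1]
  srcJ <- -sin(th) * ii + cos(th) * jj + cj - translation[2]
  f <- array(0, c(H, W, 2))
  f[, , 1] <- matrix(seq_len(H), H, W) - srcI
  f[, , 2] <- matrix(seq_len(W), H, W, byrow = TRUE) - srcJ
  sm_warp(array(img, c(H, W, 1)), f, TRUE)[, , 1]
}

.mutualInformation <- function(a, b, bins = 32L) {
  qa <- pmin(pmax(findInterval(a, seq(min(a), max(a), length.out = bins + 1L),
                               all.inside = TRUE), 1L), bins)
  qb <- pmin(pmax(findInterval(b, seq(min(b), max(b), length.out = bins + 1L),
                               all.inside = TRUE), 1L), bins)
  joint <- tabulate((qa - 1L) * bins + qb, nbins = bins * bins)
  pj <- matrix(joint / sum(joint), bins, bins)  # rows: b bins, cols: a bins
  pm <- outer(rowSums(pj), colSums(pj))
  nz <- pj > 0
  sum(pj[nz] * log(pj[nz] / pm[nz]))
}

#' Rigid mutual-information refinement
#'
#' Searches a small rigid transform (rotation up to `maxAngle` degrees,
#' translation up to `maxShift` pixels) maximizing the mutual information
#' between the reference and the transformed moving image: a coarse grid
#' search followed by Nelder-Mead refinement. If no transform improves on
#' the identity, the identity is returned with a warning.
#'
#' @param reference,moving numeric matrices of equal shape.
#' @param maxAngle,maxShift search bounds (degrees, pixels).
#' @param bins histogram bins for the mutual-information estimate.
#' @return list with `rotation` (degrees), `translation` (rows, cols) and
#'   `mi` (the achieved mutual information).
#' @export
refineRigid <- function(reference, moving, maxAngle = 5, maxShift = 20,
                        bins = 32L) {
  ref <- .asMatrix(reference, "reference")
  mov <- .asMatrix(moving, "moving")
  if (!identical(dim(ref), dim(mov))) stop("images must have the same shape")
  score <- function(par) {
    if (abs(par[1]) > maxAngle || max(abs(par[2:3])) > maxShift) return(-Inf)
    .mutualInformation(ref, .rigidWarp(mov, par[1], par[2:3]), bins)
  }
  mi0 <- score(c(0, 0, 0))
  best <- c(0, 0, 0); bestMi <- mi0
  for (ang in seq(-maxAngle, maxAngle, length.out = 11)) {
    for (ty in seq(-maxShift, maxShift, length.out = 7)) {
      for (tx in seq(-maxShift, maxShift, length.out = 7)) {
        v <- score(c(ang, ty, tx))
        if (v > bestMi) { bestMi <- v; best <- c(ang, ty, tx) }
      }
    }
  }
  opt <- stats::optim(best, function(p) -score(p), method = "Nelder-Mead",
                      control = list(maxit = 200, reltol = 1e-8))
  if (-opt$value > bestMi) { bestMi <- -opt$value; best <- opt$par }
  if (bestMi <= mi0 + 0.02) {  # no meaningful improvement over the identity
    if (mi0 < 0.1)
      warning("rigid refinement failed to improve similarity; returning identity")
    best <- c(0, 0, 0); bestMi <- mi0
  }
  list(rotation = best[1], translation = best[2:3], mi = bestMi)
}
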