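# Whole-slide normalization and patch dataset construction: tissue masking by
# Otsu thresholding, background-excluded z-normalization, overlapping patch
# extraction with a tissue-fraction filter, and dihedral augmentation.

#' Tissue mask of an autofluorescence channel
#'
#' Foreground is defined by Otsu's threshold after 3x3 median smoothing;
#' small connected components (below `minComponentFrac` of the largest) are
#' dropped as debris. Tissue is assumed brighter than background; apply to a
#' contrast-reversed image otherwise.
#'
#' @param channel numeric matrix.
#' @param minComponentFrac components smaller than this fraction of the
#'   largest component are discarded (default 0.1).
#' @return logical matrix, TRUE on tissue; all-FALSE (with a warning) when
#'   no foreground is found.
#' @export
tissueMask <- function(channel, minComponentFrac = 0.1) {
  stopifnot(is.matrix(channel), length(channel) > 0L)
  rng <- range(channel)
  if (diff(rng) < 1e-12) {
    warning("empty tissue mask: image is constant")
    return(matrix(FALSE, nrow(channel), ncol(channel)))
  }
  x01 <- (channel - rng[1]) / diff(rng)
  med <- EBImage::medianFilter(x01, size = 1L)  # 3x3 window
  th <- EBImage::otsu(med, range = c(0, 1))
  mask <- med > th
  if (!any(mask)) {
    warning("empty tissue mask: no pixel above the Otsu threshold")
    return(mask)
  }
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= minComponentFrac * max(sizes))
  matrix(lab %in% keep, nrow(channel), ncol(channel))
}

#' Whole-slide z-normalization
#'
#' Subtracts the mean and divides by the (population) standard deviation of
#' the tissue pixels; background pixels are excluded from the statistics but
#' transformed with them. Channels are normalized independently.
#'
#' @param channel numeric matrix.
#' @param mask logical matrix of tissue pixels.
#' @return normalized matrix with tissue mean ~0 and tissue sd ~1.
#' @export
normalizeSlide <- function(channel, mask) {
  stopifnot(identical(dim(channel), dim(mask)))
  v <- channel[mask]
  if (length(v) == 0L) stop("mask is empty; cannot normalize")
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  if (s < 1e-12) stop("degenerate slide: tissue is constant")
  (channel - m) / s
}

#' Extract overlapping training patches from a slide pair
#'
#' Patches are sampled on a regular stride grid (plus optional seeded
#' integer jitter, clamped to the image bounds) and kept only when at least
#' `minTissue` of their pixels are tissue.
#'
#' @param pair a [SlidePair-class].
#' @param size patch edge length (default 256).
#' @param stride grid stride in pixels; must be < `size` so patches overlap.
#' @param jitter maximum absolute uniform integer jitter per axis.
#' @param minTissue minimum tissue fraction for a patch to be retained.
#' @param seed integer seed for the jitter (ignored when `jitter = 0`).
#' @return list of [PatchPair-class] objects (possibly empty).
#' @export
extractPatches <- function(pair, size = 256L, stride = 128L, jitter = 0L,
                           minTissue = 0.5, seed = 1L) {
  stopifnot(is(pair, "SlidePair"))
  H <- dim(pair@af)[1]; W <- dim(pair@af)[2]
  if (H < size || W < size)
    stop(sprintf("slide (%d x %d) is smaller than the patch size %d; pad it first",
                 H, W, size))
  if (stride >= size) stop("stride must be smaller than size (overlap required)")
  r0 <- seq(1L, H - size + 1L, by = stride)
  c0 <- seq(1L, W - size + 1L, by = stride)
  grid <- expand.grid(r = r0, c = c0)
  if (jitter > 0L) {
    rs <- .withSeed(seed, {
      cbind(sample.int(2L * jitter + 1L, nrow(grid), replace = TRUE),
            sample.int(2L * jitter + 1L, nrow(grid), replace = TRUE)) -
        (jitter + 1L)
    })
    grid$r <- pmin(pmax(grid$r + rs[, 1], 1L), H - size + 1L)
    grid$c <- pmin(pmax(grid$c + rs[, 2], 1L), W - size + 1L)
  }
  out <- list()
  for (k in seq_len(nrow(grid))) {
    r <- grid$r[k]; cc <- grid$c[k]
    sub <- pair@mask[r:(r + size - 1L), cc:(cc + size - 1L)]
    if (mean(sub) < minTissue) next
    out[[length(out) + 1L]] <- new("PatchPair",
      input = pair@af[r:(r + size - 1L), cc:(cc + size - 1L), , drop = FALSE],
      target = pair@target[r:(r + size - 1L), cc:(cc + size - 1L), ,
                           drop = FALSE],
      condition = pair@stainWeights)
  }
  out
}

# Run expr with a local, restored RNG state.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' Apply a dihedral transform to a matrix or array
#'
#' The eight symmetries of the square, indexed 0..7: `k %% 4` quarter-turn
#' rotations (counter-clockwise) followed, for `k >= 4`, by a horizontal
#' flip. Channels of a 3-d array are transformed identically.
#'
#' @param x square matrix or `H x H x C` array.
#' @param k transform index in 0..7 (0 is the identity).
#' @return transformed object of the same shape.
#' @export
dihedralTransform <- function(x, k) {
  stopifnot(k %in% 0:7)
  rot1 <- function(m) t(m)[ncol(m):1, , drop = FALSE]  # 90 deg CCW
  f <- function(m) {
    for (i in seq_len(k %% 4)) m <- rot1(m)
    if (k >= 4L) m <- m[, ncol(m):1, drop = FALSE]
    m
  }
  if (is.matrix(x)) return(f(x))
  stopifnot(length(dim(x)) == 3L)
  out <- x
  for (c in seq_len(dim(x)[3])) out[, , c] <- f(x[, , c])
  out
}

# Inverse transform index for each dihedral element.
.dihedralInverse <- c(0L, 3L, 2L, 1L, 4L, 5L, 6L, 7L)

#' Augment a training patch
#'
#' Applies one of the eight dihedral transforms (4 rotations x optional
#' flip) identically to the input stack, the target, and a per-pixel
#' staining matrix condition if present; a plain weight-vector condition is
#' unaffected.
#'
#' @param patch a [PatchPair-class] with square patches.
#' @param k transform index 0..7, or `NULL` to draw one from `seed`.
#' @param seed integer seed used when `k` is `NULL`.
#' @return the transformed [PatchPair-class].
#' @export
augmentPatch <- function(patch, k = NULL, seed = 1L) {
  stopifnot(is(patch, "PatchPair"))
  d <- dim(patch@input)
  if (d[1] != d[2]) stop("augmentation requires square patches")
  if (is.null(k)) k <- .withSeed(seed, sample.int(8L, 1L)) - 1L
  cond <- patch@condition
  if (is.array(cond) && length(dim(cond)) == 3L)
    cond <- dihedralTransform(cond, k)
  new("PatchPair", input = dihedralTransform(patch@input, k),
      target = dihedralTransform(patch@target, k), condition = cond)
}
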