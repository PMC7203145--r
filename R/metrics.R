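# Evaluation metrics: whole-patch structural similarity and YCbCr channel
# percentage differences, aggregated over fixed-size evaluation patches.

#' Whole-patch structural similarity index
#'
#' SSIM computed from whole-patch statistics:
#' `(2 mu_a mu_b + C1)(2 sigma_ab + C2) /
#'  ((mu_a^2 + mu_b^2 + C1)(sigma_a^2 + sigma_b^2 + C2))`
#' with means, (population) variances and cross-covariance taken over the
#' entire patch. Channels of multi-channel inputs are scored independently
#' and averaged. The stabilization constants default to `C1 = (0.01 L)^2`,
#' `C2 = (0.03 L)^2` with dynamic range `L = 255`. A sliding-window mean
#' SSIM is available via `window`; the whole-patch form is the default.
#'
#' @param a,b numeric matrices or arrays of equal shape, on the 0..`L` scale.
#' @param C1,C2 stabilization constants (> 0).
#' @param L dynamic range used for the default constants.
#' @param window optional odd window size; when given, SSIM is the mean of
#'   the whole-patch statistic over all complete `window x window`
#'   neighbourhoods.
#' @return scalar in `[-1, 1]`.
#' @export
ssimGlobal <- function(a, b, C1 = (0.01 * L)^2, C2 = (0.03 * L)^2, L = 255,
                       window = NULL) {
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  stopifnot(C1 > 0, C2 > 0)
  one <- function(x, y) {
    mx <- mean(x); my <- mean(y)
    vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
    cxy <- mean((x - mx) * (y - my))
    (2 * mx * my + C1) * (2 * cxy + C2) /
      ((mx^2 + my^2 + C1) * (vx + vy + C2))
  }
  scoreChannel <- function(x, y) {
    if (is.null(window)) return(one(x, y))
    k <- as.integer(window)
    stopifnot(k >= 2L, k <= min(dim(x)))
    vals <- c()
    for (i in seq_len(nrow(x) - k + 1L))
      for (j in seq_len(ncol(x) - k + 1L))
        vals <- c(vals, one(x[i:(i + k - 1L), j:(j + k - 1L)],
                            y[i:(i + k - 1L), j:(j + k - 1L)]))
    mean(vals)
  }
  if (is.matrix(a)) return(scoreChannel(a, b))
  stopifnot(length(dim(a)) == 3L)
  mean(vapply(seq_len(dim(a)[3]),
              function(c) scoreChannel(a[, , c], b[, , c]), numeric(1)))
}

#' YCbCr percentage differences between two RGB images
#'
#' Converts both images to YCbCr (BT.601 full range) and reports, per
#' channel, the mean absolute difference as a percentage of the full 8-bit
#' dynamic range: `100 * mean(|a - b|) / 255`. Normalization by the
#' reference channel mean is available via `normalize = "reference"`.
#'
#' @param a,b numeric `H x W x 3` RGB arrays on the 0..255 scale.
#' @param normalize `"range"` (default; denominator 255) or `"reference"`
#'   (denominator = mean of the reference channel of `b`).
#' @return named numeric vector `c(Y, Cb, Cr)` of percentages.
#' @export
ycbcrPercentDiff <- function(a, b, normalize = c("range", "reference")) {
  normalize <- match.arg(normalize)
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  ya <- rgbToYcbcr(a); yb <- rgbToYcbcr(b)
  out <- numeric(3)
  for (ch in 1:3) {
    den <- if (normalize == "range") 255 else mean(yb[, , ch])
    out[ch] <- 100 * mean(abs(ya[, , ch] - yb[, , ch])) / den
  }
  names(out) <- c("Y", "Cb", "Cr")
  out
}

#' Evaluate virtually stained outputs against references
#'
#' Tiles each co-registered image pair into non-overlapping `patch x patch`
#' blocks (partial edge blocks are discarded), scores each block with
#' [ssimGlobal()] and [ycbcrPercentDiff()], and aggregates the mean and
#' standard deviation per metric.
#'
#' @param outputs,references lists of RGB arrays (0..255) of matching
#'   shapes.
#' @param patch evaluation patch edge length (default 1224).
#' @return a [MetricsReport-class].
#' @export
evaluateStains <- function(outputs, references, patch = 1224L) {
  stopifnot(length(outputs) == length(references), length(outputs) > 0L)
  rows <- list()
  for (k in seq_along(outputs)) {
    a <- outputs[[k]]; b <- references[[k]]
    if (!identical(dim(a), dim(b))) stop("shape mismatch in pair ", k)
    H <- dim(a)[1]; W <- dim(a)[2]
    nr <- H %/% patch; nc <- W %/% patch
    if (nr < 1L || nc < 1L)
      stop(sprintf(
        "pair %d (%d x %d) has no complete %d x %d block; use a smaller patch size",
        k, H, W, patch, patch))
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      ri <- ((i - 1L) * patch + 1L):(i * patch)
      ci <- ((j - 1L) * patch + 1L):(j * patch)
      pa <- a[ri, ci, , drop = FALSE]; pb <- b[ri, ci, , drop = FALSE]
      yd <- ycbcrPercentDiff(pa, pb)
      rows[[length(rows) + 1L]] <- data.frame(
        pair = k, blockRow = i, blockCol = j,
        ssim = ssimGlobal(pa, pb),
        Y = yd[["Y"]], Cb = yd[["Cb"]], Cr = yd[["Cr"]])
    }
  }
  perPatch <- do.call(rbind, rows)
  metrics <- c("ssim", "Y", "Cb", "Cr")
  summary <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(perPatch[[m]]), numeric(1)),
    sd = vapply(metrics, function(m) stats::sd(perPatch[[m]]), numeric(1)),
    n = nrow(perPatch))
  new("MetricsReport", perPatch = perPatch, summary = summary,
      patchSize = as.integer(patch))
}
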