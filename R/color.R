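# RGB <-> YCbCr conversion, ITU-R BT.601 full-range coefficients (the JPEG
# convention). All functions operate on H x W x 3 arrays on the 0..255 scale.

.bt601 <- rbind(Y  = c(0.299, 0.587, 0.114),
                Cb = c(-0.168736, -0.331264, 0.5),
                Cr = c(0.5, -0.418688, -0.081312))

#' Convert RGB to YCbCr (BT.601 full range)
#'
#' @param rgb numeric `H x W x 3` array, values on the 0..255 scale.
#' @return numeric `H x W x 3` array with Y, Cb, Cr planes on 0..255
#'   (Cb and Cr centered at 128).
#' @export
rgbToYcbcr <- function(rgb) {
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3] == 3L)
  d <- dim(rgb)
  m <- matrix(rgb, ncol = 3L) %*% t(.bt601)
  m[, 2:3] <- m[, 2:3] + 128
  array(m, d)
}

#' Convert YCbCr (BT.601 full range) to RGB
#'
#' The inverse of [rgbToYcbcr()]. Output is not clamped; use
#' [clampToByte()] before export.
#'
#' @param ycbcr numeric `H x W x 3` array on the 0..255 scale.
#' @return numeric `H x W x 3` RGB array on the 0..255 scale.
#' @export
ycbcrToRgb <- function(ycbcr) {
  stopifnot(length(dim(ycbcr)) == 3L, dim(ycbcr)[3] == 3L)
  d <- dim(ycbcr)
  m <- matrix(ycbcr, ncol = 3L)
  y <- m[, 1]; cb <- m[, 2] - 128; cr <- m[, 3] - 128
  array(c(y + 1.402 * cr,
          y - 0.344136 * cb - 0.714136 * cr,
          y + 1.772 * cb), d)
}

#' Clamp and round an image to 8-bit range
#'
#' @param x numeric array.
#' @return array with values rounded and clamped to 0..255.
#' @export
clampToByte <- function(x) {
  x <- round(x)
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}
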