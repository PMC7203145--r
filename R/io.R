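# Raster and checkpoint I/O: grayscale / RGB TIFF and PNG images,
# displacement fields as 2-plane 32-bit TIFF, model checkpoints with their
# stain ordering, and patch-set persistence as per-patch TIFF stacks plus a
# manifest TSV.

.imageFormat <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) return("tiff")
  if (ext == "png") return("png")
  stop(sprintf("unsupported image format '.%s' (use TIFF or PNG)", ext))
}

#' Read a grayscale image
#'
#' Reads a TIFF or PNG image as a numeric matrix; multi-channel files are
#' averaged to one plane. TIFF values keep their stored scale; PNG values
#' are in `[0, 1]`.
#'
#' @param path image path.
#' @return numeric matrix.
#' @export
readImageGray <- function(path) {
  img <- switch(.imageFormat(path),
                tiff = tiff::readTIFF(path, as.is = TRUE),
                png = png::readPNG(path))
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  img
}

#' Read an RGB image
#'
#' @param path image path (TIFF or PNG).
#' @return numeric `H x W x 3` array on the 0..255 scale.
#' @export
readImageRGB <- function(path) {
  fmt <- .imageFormat(path)
  img <- switch(fmt, tiff = tiff::readTIFF(path), png = png::readPNG(path))
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  img <- img[, , 1:3, drop = FALSE]
  img * 255
}

#' Write an image
#'
#' Writes a matrix or array as TIFF (32-bit float, values kept as-is) or
#' PNG (values rescaled from 0..255 to 0..1).
#'
#' @param img numeric matrix or array.
#' @param path destination path; the extension selects the format.
#' @export
writeImage <- function(img, path) {
  fmt <- .imageFormat(path)
  if (fmt == "tiff") {
    tiff::writeTIFF(img, path, bits.per.sample = 32L, reduce = FALSE)
  } else {
    png::writePNG(pmin(pmax(img / 255, 0), 1), path)
  }
  invisible(path)
}

#' Persist a displacement field as a 2-plane 32-bit TIFF
#'
#' @param field a [DisplacementField-class].
#' @param path destination TIFF path.
#' @export
writeDisplacementField <- function(field, path) {
  stopifnot(is(field, "DisplacementField"))
  s <- field@shifts
  tiff::writeTIFF(list(s[, , 1], s[, , 2]), path, bits.per.sample = 32L,
                  reduce = FALSE)
  invisible(path)
}

#' Read a displacement field from a 2-plane TIFF
#'
#' @param path TIFF path written by [writeDisplacementField()].
#' @return a [DisplacementField-class].
#' @export
readDisplacementField <- function(path) {
  planes <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  stopifnot(length(planes) == 2L)
  new("DisplacementField",
      shifts = array(c(planes[[1]], planes[[2]]),
                     c(dim(planes[[1]]), 2L)))
}

#' Save a model checkpoint
#'
#' Stores the architecture specs, all weights and the stain-name ordering.
#'
#' @param model a [StainGAN-class].
#' @param path destination path (`.rds`).
#' @export
saveCheckpoint <- function(model, path) {
  stopifnot(is(model, "StainGAN"))
  saveRDS(list(genSpec = model@genSpec, discSpec = model@discSpec,
               generator = model@generator,
               discriminator = model@discriminator,
               stainNames = model@stainNames, format = 1L), path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' Refuses checkpoints whose stain ordering differs from the expected one,
#' since the conditioning planes are positional.
#'
#' @param path checkpoint path from [saveCheckpoint()].
#' @param expectedStains optional stain ordering to enforce.
#' @return a [StainGAN-class].
#' @export
loadCheckpoint <- function(path, expectedStains = NULL) {
  ck <- readRDS(path)
  if (!is.null(expectedStains) &&
      !identical(as.character(expectedStains), ck$stainNames))
    stop(sprintf(
      "checkpoint stain ordering (%s) differs from the run config (%s)",
      paste(ck$stainNames, collapse = ","),
      paste(expectedStains, collapse = ",")))
  new("StainGAN", genSpec = ck$genSpec, discSpec = ck$discSpec,
      generator = ck$generator, discriminator = ck$discriminator,
      stainNames = ck$stainNames)
}

#' Persist a patch set to a directory
#'
#' Writes one 32-bit multi-plane TIFF per patch (2 input planes, then 3
#' target planes rescaled to 0..1) plus a tab-separated manifest with the
#' patch id, source slide, position, stain weights, and split.
#'
#' @param patches list of [PatchPair-class].
#' @param dir output directory (created if missing).
#' @param manifest optional data.frame with one row per patch (columns
#'   `slide`, `row`, `col`, `split`); defaults are filled when absent.
#' @return the manifest path, invisibly.
#' @export
writePatchSet <- function(patches, dir, manifest = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(manifest))
    manifest <- data.frame(slide = NA_integer_, row = NA_integer_,
                           col = NA_integer_, split = "train",
                           stringsAsFactors = FALSE)[rep(1, length(patches)), ]
  manifest$patch <- sprintf("patch%05d.tiff", seq_along(patches))
  manifest$weights <- vapply(patches, function(p) {
    w <- p@condition
    if (is.array(w)) w <- apply(w, 3, mean)
    paste(format(w, digits = 8), collapse = ",")
  }, character(1))
  for (i in seq_along(patches)) {
    p <- patches[[i]]
    planes <- c(lapply(seq_len(dim(p@input)[3]), function(c) p@input[, , c]),
                lapply(1:3, function(c) p@target[, , c] / 255))
    tiff::writeTIFF(planes, file.path(dir, manifest$patch[i]),
                    bits.per.sample = 32L, reduce = FALSE)
  }
  path <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
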