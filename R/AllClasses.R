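#' @useDynLib stainmux, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Digital staining matrix
#'
#' Per-pixel stack of stain-condition weights: an `height x width x N` array
#' whose slice `i` carries the weight of the i-th stain at every pixel. The
#' encoding rule requires every entry to lie in `[0, 1]` and the weights at
#' each pixel to sum to one, so a one-hot matrix selects a single stain,
#' fractional weights blend stains, and spatially varying weights stain
#' different regions differently.
#'
#' @slot weights numeric array, `height x width x nStains`.
#' @slot stainNames ordered character vector naming the stain planes.
#' @seealso [oneHotMatrix()], [blendMatrix()], [roiMatrix()],
#'   [validateStainingMatrix()]
#' @export
setClass("StainingMatrix",
  representation(weights = "array", stainNames = "character"))

setValidity("StainingMatrix", function(object) {
  v <- validateStainingMatrix(object)
  if (length(dim(object@weights)) != 3L)
    return("weights must be a 3-d array (height x width x nStains)")
  if (dim(object@weights)[3] != length(object@stainNames))
    return("number of weight planes must match length(stainNames)")
  if (anyDuplicated(object@stainNames))
    return("stain names must be unique")
  if (nrow(v) > 0L)
    return(sprintf("encoding rule violated at %d pixel(s); first: %s",
                   nrow(v), v$type[1]))
  TRUE
})

#' Region-of-interest staining specification
#'
#' A list of polygons (vertex matrices in `(x, y)` = `(col, row)` pixel
#' coordinates, 0-based continuous) each carrying a stain weight vector, plus
#' a default weight vector for pixels covered by no polygon. Later polygons
#' overwrite earlier ones where they overlap.
#'
#' @slot polygons list of numeric matrices with columns x, y (>= 3 vertices).
#' @slot roiWeights list of numeric weight vectors, one per polygon.
#' @slot defaultWeights numeric weight vector for unassigned pixels.
#' @export
setClass("RoiSpec",
  representation(polygons = "list", roiWeights = "list",
                 defaultWeights = "numeric"))

setValidity("RoiSpec", function(object) {
  if (length(object@polygons) != length(object@roiWeights))
    return("polygons and roiWeights must have the same length")
  n <- length(object@defaultWeights)
  msg <- .checkWeightVector(object@defaultWeights, "defaultWeights")
  if (!is.null(msg)) return(msg)
  for (k in seq_along(object@polygons)) {
    p <- object@polygons[[k]]
    if (!is.matrix(p) || ncol(p) != 2L || nrow(p) < 3L)
      return(sprintf("polygon %d is not a matrix with >= 3 (x, y) vertices", k))
    if (!all(is.finite(p)))
      return(sprintf("polygon %d has non-finite vertices", k))
    if (!.polygonIsSimple(p))
      return(sprintf("polygon %d is self-intersecting", k))
    if (length(object@roiWeights[[k]]) != n)
      return(sprintf("weights of polygon %d have wrong length", k))
    msg <- .checkWeightVector(object@roiWeights[[k]],
                              sprintf("weights of polygon %d", k))
    if (!is.null(msg)) return(msg)
  }
  TRUE
})

#' Dense displacement field
#'
#' Per-pixel translation map: slice 1 holds the row shift and slice 2 the
#' column shift, in pixels. Applying the field with [applyDisplacement()]
#' samples `image(p - field(p))`.
#'
#' @slot shifts numeric array, `height x width x 2`, finite everywhere.
#' @export
setClass("DisplacementField", representation(shifts = "array"))

setValidity("DisplacementField", function(object) {
  d <- dim(object@shifts)
  if (length(d) != 3L || d[3] != 2L)
    return("shifts must be a height x width x 2 array")
  if (!all(is.finite(object@shifts)))
    return("shifts must be finite everywhere")
  TRUE
})

#' Registered slide pair
#'
#' One co-registered training unit at slide scale: the two-channel
#' autofluorescence stack, the stained bright-field RGB target (8-bit scale,
#' values in 0..255), a logical tissue mask, and the stain condition as a
#' weight vector over the stain classes.
#'
#' @slot af numeric array `H x W x 2` (DAPI-like, Texas-Red-like).
#' @slot target numeric array `H x W x 3`, RGB in 0..255.
#' @slot mask logical matrix `H x W`, TRUE on tissue.
#' @slot stainWeights numeric stain weight vector (sums to one).
#' @export
setClass("SlidePair",
  representation(af = "array", target = "array", mask = "matrix",
                 stainWeights = "numeric"))

setValidity("SlidePair", function(object) {
  da <- dim(object@af); dt <- dim(object@target); dm <- dim(object@mask)
  if (length(da) != 3L || da[3] != 2L) return("af must be H x W x 2")
  if (length(dt) != 3L || dt[3] != 3L) return("target must be H x W x 3")
  if (!identical(da[1:2], dt[1:2]) || !identical(da[1:2], dm))
    return("af, target and mask must share spatial shape")
  msg <- .checkWeightVector(object@stainWeights, "stainWeights")
  if (!is.null(msg)) return(msg)
  TRUE
})

#' Aligned training patch
#'
#' A single training unit: 2-channel input patch, RGB target patch (0..255)
#' and the stain condition, either a weight vector (uniform condition) or a
#' full per-pixel staining-matrix array.
#'
#' @slot input numeric array `size x size x 2`.
#' @slot target numeric array `size x size x 3`, RGB 0..255.
#' @slot condition numeric weight vector or `size x size x N` array.
#' @export
setClass("PatchPair",
  representation(input = "array", target = "array", condition = "ANY"))

setValidity("PatchPair", function(object) {
  di <- dim(object@input); dt <- dim(object@target)
  if (length(di) != 3L || di[3] != 2L) return("input must be H x W x 2")
  if (length(dt) != 3L || dt[3] != 3L) return("target must be H x W x 3")
  if (!identical(di[1:2], dt[1:2]))
    return("input and target must share spatial shape")
  cond <- object@condition
  if (is.array(cond) && length(dim(cond)) == 3L) {
    if (!identical(dim(cond)[1:2], di[1:2]))
      return("per-pixel condition must share spatial shape with input")
  } else if (!is.numeric(cond)) {
    return("condition must be a numeric weight vector or a 3-d array")
  }
  TRUE
})

#' Adversarial training configuration
#'
#' Hyper-parameters of the adversarial training loop. Defaults are the
#' published operating point: total-variation weight `lambda = 0.02`,
#' adversarial weight `alpha = 2000`, Adam learning rates `1e-4` (generator)
#' and `2e-6` (discriminator), ten generator updates per discriminator
#' update, and batch size 8.
#'
#' @slot lambda numeric, weight of the total-variation term.
#' @slot alpha numeric, weight of the adversarial term.
#' @slot lrGenerator numeric, generator Adam learning rate.
#' @slot lrDiscriminator numeric, discriminator Adam learning rate.
#' @slot generatorSteps integer, generator updates per discriminator update.
#' @slot batchSize integer.
#' @slot totalDiscriminatorSteps integer, fixed step budget.
#' @slot seed integer, seeds every source of randomness in the run.
#' @slot checkpointEvery numeric, discriminator-step interval for
#'   checkpointing (`Inf` disables).
#' @slot checkpointDir character, directory for checkpoints ("" disables).
#' @export
setClass("TrainingConfig",
  representation(lambda = "numeric", alpha = "numeric",
                 lrGenerator = "numeric", lrDiscriminator = "numeric",
                 generatorSteps = "integer", batchSize = "integer",
                 totalDiscriminatorSteps = "integer", seed = "integer",
                 checkpointEvery = "numeric", checkpointDir = "character"))

setValidity("TrainingConfig", function(object) {
  if (object@lrGenerator <= 0 || object@lrDiscriminator <= 0)
    return("learning rates must be > 0")
  if (object@generatorSteps < 1L)
    return("generatorSteps (generator:discriminator step ratio) must be >= 1")
  if (object@batchSize < 1L) return("batchSize must be >= 1")
  if (object@totalDiscriminatorSteps < 0L)
    return("totalDiscriminatorSteps must be >= 0")
  TRUE
})

#' Trained conditional staining model
#'
#' Container for the conditional generator / discriminator pair together with
#' the architecture specs and the stain-name ordering the model was trained
#' with. The ordering is part of the model contract: a staining matrix whose
#' stain names differ in order is rejected at inference time.
#'
#' @slot genSpec list, generator architecture description.
#' @slot discSpec list, discriminator architecture description.
#' @slot generator list of generator parameter arrays.
#' @slot discriminator list of discriminator parameter arrays.
#' @slot stainNames ordered character vector of stain classes.
#' @export
setClass("StainGAN",
  representation(genSpec = "list", discSpec = "list", generator = "list",
                 discriminator = "list", stainNames = "character"))

#' Evaluation report
#'
#' Per-patch structural similarity and YCbCr channel differences, with
#' per-comparison mean and standard deviation, mirroring a stain-by-stain
#' evaluation table.
#'
#' @slot perPatch data.frame with one row per evaluated patch.
#' @slot summary data.frame of mean / sd / n per metric.
#' @slot patchSize integer edge length of the evaluation patches.
#' @export
setClass("MetricsReport",
  representation(perPatch = "data.frame", summary = "data.frame",
                 patchSize = "integer"))

#' Synthetic tissue phantom
#'
#' Seeded phantom emulating a two-channel autofluorescence capture of tissue:
#' a structure label map (0 background, 1 nucleus, 2 membrane, 3 cytoplasm),
#' noisy input channels (channel 1 emphasizes nuclei, DAPI-like; channel 2
#' membranes and cytoplasm, Texas-Red-like) and the noise-free channels used
#' by the deterministic oracle stain renderings.
#'
#' @slot labels integer matrix of structure labels.
#' @slot channels numeric array `H x W x 2`, noisy input channels.
#' @slot channelsClean numeric array `H x W x 2`, noise-free channels.
#' @slot seed integer seed the phantom was generated from.
#' @export
setClass("Phantom",
  representation(labels = "matrix", channels = "array",
                 channelsClean = "array", seed = "integer"))

# ---- show methods -----------------------------------------------------------

setMethod("show", "StainingMatrix", function(object) {
  d <- dim(object@weights)
  cat(sprintf("StainingMatrix %d x %d, %d stains (%s)\n", d[1], d[2], d[3],
              paste(object@stainNames, collapse = ", ")))
  u <- apply(object@weights, 3, mean)
  cat("  mean plane weights:",
      paste(sprintf("%s=%.3f", object@stainNames, u), collapse = " "), "\n")
})

setMethod("show", "RoiSpec", function(object) {
  cat(sprintf("RoiSpec with %d polygon(s), %d stain classes\n",
              length(object@polygons), length(object@defaultWeights)))
})

setMethod("show", "DisplacementField", function(object) {
  d <- dim(object@shifts)
  m <- sqrt(object@shifts[, , 1]^2 + object@shifts[, , 2]^2)
  cat(sprintf("DisplacementField %d x %d; |shift| mean %.3f px, max %.3f px\n",
              d[1], d[2], mean(m), max(m)))
})

setMethod("show", "StainGAN", function(object) {
  cat(sprintf(
    "StainGAN: %d-level generator (stem %d), %d-block discriminator\n",
    object@genSpec$levels, object@genSpec$stemChannels,
    object@discSpec$blocks))
  cat("  stains:", paste(object@stainNames, collapse = ", "), "\n")
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport over %d patch(es) of %d x %d px\n",
              nrow(object@perPatch), object@patchSize, object@patchSize))
  print(object@summary, row.names = FALSE)
})

setMethod("show", "Phantom", function(object) {
  d <- dim(object@labels)
  fr <- tabulate(object@labels + 1L, nbins = 4L) / length(object@labels)
  cat(sprintf("Phantom %d x %d (seed %d)\n", d[1], d[2], object@seed))
  cat(sprintf("  bg %.2f nucleus %.2f membrane %.2f cytoplasm %.2f\n",
              fr[1], fr[2], fr[3], fr[4]))
})

setMethod("show", "TrainingConfig", function(object) {
  cat(sprintf(paste0(
    "TrainingConfig: lambda=%g alpha=%g lrG=%g lrD=%g ",
    "%d G-steps per D-step, batch %d, %d D-steps, seed %d\n"),
    object@lambda, object@alpha, object@lrGenerator, object@lrDiscriminator,
    object@generatorSteps, object@batchSize,
    object@totalDiscriminatorSteps, object@seed))
})

# ---- small shared accessors -------------------------------------------------

#' Stain names of an object
#' @param x a StainingMatrix or StainGAN.
#' @return character vector of stain class names, in plane order.
#' @export
setGeneric("stainNames", function(x) standardGeneric("stainNames"))

#' @rdname stainNames
#' @export
setMethod("stainNames", "StainingMatrix", function(x) x@stainNames)

#' @rdname stainNames
#' @export
setMethod("stainNames", "StainGAN", function(x) x@stainNames)

#' Weight array of a staining matrix
#' @param x a StainingMatrix.
#' @return the `H x W x N` numeric weight array.
#' @export
setGeneric("stainWeights", function(x) standardGeneric("stainWeights"))

#' @rdname stainWeights
#' @export
setMethod("stainWeights", "StainingMatrix", function(x) x@weights)

#' Shift array of a displacement field
#' @param x a DisplacementField.
#' @return the `H x W x 2` array of (row, col) shifts in pixels.
#' @export
setGeneric("fieldShifts", function(x) standardGeneric("fieldShifts"))

#' @rdname fieldShifts
#' @export
setMethod("fieldShifts", "DisplacementField", function(x) x@shifts)

#' @export
setMethod("dim", "StainingMatrix", function(x) dim(x@weights))

#' @export
setMethod("dim", "DisplacementField", function(x) dim(x@shifts)[1:2])
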