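# Construction and validation of the per-pixel digital staining matrix:
# one-hot single stains, uniform blends, and ROI-structured maps rasterized
# from polygon annotations.

.sumTol <- 1e-6

#' Default stain classes
#'
#' The three stain classes the framework is demonstrated with: H&E ("HE"),
#' Masson's trichrome ("MT") and Jones' silver ("JS").
#' @return character vector of stain names.
#' @export
defaultStains <- function() c("HE", "MT", "JS")

.checkWeightVector <- function(w, what = "weights", tol = .sumTol) {
  if (!is.numeric(w) || length(w) < 1L)
    return(sprintf("%s must be a non-empty numeric vector", what))
  if (any(!is.finite(w)) || any(w < 0))
    return(sprintf("%s must be nonnegative and finite", what))
  if (abs(sum(w) - 1) > tol)
    return(sprintf("%s violate the encoding rule: sum is %.8f, not 1",
                   what, sum(w)))
  NULL
}

# Even-odd simplicity check: no two non-adjacent edges intersect.
.polygonIsSimple <- function(p) {
  n <- nrow(p)
  if (n < 3L) return(FALSE)
  seg <- cbind(p, p[c(2:n, 1L), , drop = FALSE])  # x1 y1 x2 y2
  cross <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (j == i + 1L || (i == 1L && j == n)) next  # adjacent edges share a vertex
      a <- seg[i, ]; b <- seg[j, ]
      d1 <- cross(a[1], a[2], a[3], a[4], b[1], b[2])
      d2 <- cross(a[1], a[2], a[3], a[4], b[3], b[4])
      d3 <- cross(b[1], b[2], b[3], b[4], a[1], a[2])
      d4 <- cross(b[1], b[2], b[3], b[4], a[3], a[4])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
        return(FALSE)
    }
  }
  TRUE
}

#' Create a staining matrix from a weight array
#'
#' @param weights numeric `H x W x N` array of per-pixel stain weights.
#' @param stainNames character vector naming the N planes.
#' @return a validated [StainingMatrix-class] object.
#' @export
StainingMatrix <- function(weights, stainNames = defaultStains()) {
  new("StainingMatrix", weights = weights, stainNames = as.character(stainNames))
}

#' Create an ROI staining specification
#'
#' @param polygons list of numeric matrices with `(x, y)` vertex columns.
#' @param weights list of stain weight vectors, one per polygon.
#' @param defaultWeights weight vector for pixels outside every polygon.
#' @return a validated [RoiSpec-class] object.
#' @export
RoiSpec <- function(polygons = list(), weights = list(), defaultWeights) {
  new("RoiSpec", polygons = polygons, roiWeights = weights,
      defaultWeights = defaultWeights)
}

#' One-hot staining matrix for a single stain
#'
#' The conditioning used during training and single-stain inference: the
#' selected stain's plane is all ones and every other plane all zeros.
#'
#' @param stain stain index (1-based) or stain name.
#' @param height,width spatial size in pixels.
#' @param stainNames ordered stain classes; defines the number of planes.
#' @return a [StainingMatrix-class].
#' @examples
#' m <- oneHotMatrix("HE", 4, 4)
#' apply(stainWeights(m), 3, unique)
#' @export
oneHotMatrix <- function(stain, height, width, stainNames = defaultStains()) {
  idx <- .resolveStain(stain, stainNames)
  if (height < 1L || width < 1L) stop("height and width must be positive")
  w <- array(0, c(height, width, length(stainNames)))
  w[, , idx] <- 1
  StainingMatrix(w, stainNames)
}

.resolveStain <- function(stain, stainNames) {
  if (is.character(stain)) {
    idx <- match(stain, stainNames)
    if (is.na(idx))
      stop(sprintf("invalid stain: '%s' is not one of %s", stain,
                   paste(stainNames, collapse = ", ")))
    return(idx)
  }
  idx <- as.integer(stain)
  if (is.na(idx) || idx < 1L || idx > length(stainNames))
    stop(sprintf("invalid stain: index %s out of range 1..%d",
                 as.character(stain), length(stainNames)))
  idx
}

#' Uniform blend staining matrix
#'
#' Conditions every pixel with the same fractional weight vector, producing a
#' hybrid rendering whose character moves between the pure stains as the
#' weights change.
#'
#' @param weights nonnegative vector summing to one (length = number of stains).
#' @param height,width spatial size in pixels.
#' @param stainNames ordered stain classes.
#' @return a [StainingMatrix-class].
#' @export
blendMatrix <- function(weights, height, width, stainNames = defaultStains()) {
  if (length(weights) != length(stainNames))
    stop("weights must have one entry per stain class")
  msg <- .checkWeightVector(weights, "blend weights")
  if (!is.null(msg)) stop(msg)
  w <- array(rep(weights, each = height * width), c(height, width,
                                                    length(weights)))
  StainingMatrix(w, stainNames)
}

#' Rasterize an ROI specification into a staining matrix
#'
#' Pixels whose center falls inside a polygon (even-odd rule) carry that
#' polygon's weight vector; where polygons overlap the last-listed polygon
#' wins; all remaining pixels carry the default weights. Polygon vertices are
#' `(x, y)` = `(col, row)` in 0-based continuous pixel coordinates, so the
#' center of the top-left pixel is at `(0.5, 0.5)`.
#'
#' @param spec a [RoiSpec-class].
#' @param height,width output size in pixels.
#' @param stainNames ordered stain classes.
#' @return a [StainingMatrix-class].
#' @export
roiMatrix <- function(spec, height, width, stainNames = defaultStains()) {
  validObject(spec)
  n <- length(spec@defaultWeights)
  if (n != length(stainNames))
    stop("RoiSpec weight length must match the number of stain classes")
  w <- array(rep(spec@defaultWeights, each = height * width),
             c(height, width, n))
  if (length(spec@polygons) > 0L) {
    mask <- sm_rasterize(height, width, spec@polygons)
    for (k in seq_along(spec@polygons)) {
      sel <- mask == k
      if (!any(sel)) next
      for (i in seq_len(n)) {
        plane <- w[, , i]
        plane[sel] <- spec@roiWeights[[k]][i]
        w[, , i] <- plane
      }
    }
  }
  StainingMatrix(w, stainNames)
}

#' Check a staining matrix against the encoding rule
#'
#' Reports every pixel violating the encoding rule (per-pixel weights must be
#' in `[0, 1]` and sum to one within `tol`). An empty data frame means the
#' matrix is valid.
#'
#' @param dsm a [StainingMatrix-class] or a bare `H x W x N` array.
#' @param tol numeric tolerance on the per-pixel sum (default `1e-6`).
#' @return data.frame with columns `row`, `col`, `type`
#'   (`"sum"` or `"range"`) and `value`.
#' @export
validateStainingMatrix <- function(dsm, tol = .sumTol) {
  w <- if (is(dsm, "StainingMatrix")) dsm@weights else dsm
  stopifnot(is.array(w), length(dim(w)) == 3L)
  s <- rowSums(w, dims = 2L)
  badSum <- which(abs(s - 1) > tol, arr.ind = TRUE)
  lo <- apply(w, c(1, 2), min)
  hi <- apply(w, c(1, 2), max)
  badRange <- which(lo < 0 | hi > 1, arr.ind = TRUE)
  out <- rbind(
    if (nrow(badSum) > 0L)
      data.frame(row = badSum[, 1], col = badSum[, 2], type = "sum",
                 value = s[badSum]),
    if (nrow(badRange) > 0L)
      data.frame(row = badRange[, 1], col = badRange[, 2], type = "range",
                 value = pmin(lo, 1 - hi)[badRange]))
  if (is.null(out))
    out <- data.frame(row = integer(), col = integer(), type = character(),
                      value = numeric())
  out
}

#' Read polygon annotations into an RoiSpec
#'
#' Reads a polygon-annotation JSON file (a top-level `"shapes"` list of
#' objects with `"label"`, `"points"` and `"shape_type"` fields, as written
#' by common annotation tools) and maps each shape's label to a stain weight
#' vector through a user-supplied table.
#'
#' @param path path to the annotation JSON file.
#' @param labelWeights named list mapping label strings to weight vectors.
#' @param defaultWeights weight vector for unannotated pixels.
#' @return a [RoiSpec-class].
#' @export
readPolygonAnnotations <- function(path, labelWeights, defaultWeights) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  shapes <- doc$shapes
  if (is.null(shapes)) stop("malformed annotation file: no 'shapes' list")
  polys <- list(); wts <- list()
  for (s in shapes) {
    if (!is.null(s$shape_type) && !identical(s$shape_type, "polygon"))
      stop(sprintf("unsupported shape_type '%s'", s$shape_type))
    pts <- do.call(rbind, lapply(s$points, function(p) as.numeric(p)))
    if (is.null(pts) || nrow(pts) < 3L)
      stop(sprintf("annotation error: shape '%s' has fewer than 3 vertices",
                   if (is.null(s$label)) "?" else s$label))
    w <- labelWeights[[s$label]]
    if (is.null(w))
      stop(sprintf("unknown label '%s': no entry in the label-weights table",
                   s$label))
    polys[[length(polys) + 1L]] <- pts
    wts[[length(wts) + 1L]] <- as.numeric(w)
  }
  RoiSpec(polygons = polys, weights = wts, defaultWeights = defaultWeights)
}
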