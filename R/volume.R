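#' Construct a Volume
#'
#' @param values numeric 3D array (HU for CT, counts for SPECT).
#' @param affine 4x4 matrix mapping 0-based voxel indices to world mm.
#'   Alternatively supply \code{spacing} and \code{origin} to build a
#'   diagonal affine.
#' @param modality \code{"ct"}, \code{"spect"} or \code{"other"}.
#' @param spacing,origin length-3 shortcuts used when \code{affine} is NULL.
#' @return a \code{\linkS4class{Volume}}.
#' @examples
#' v <- volume(array(0, c(4, 4, 4)), spacing = c(2, 2, 2), modality = "ct")
#' voxelSpacing(v)
#' @export
volume <- function(values, affine = NULL, modality = "other",
                   spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (is.null(affine)) {
    affine <- diag(4)
    diag(affine)[1:3] <- spacing
    affine[1:3, 4] <- origin
  }
  storage.mode(values) <- "double"
  new("Volume", values = values, affine = affine, modality = modality)
}

#' Construct a BinaryMask on the grid of a companion volume
#'
#' @param values logical 3D array.
#' @param grid a \code{Volume} or \code{BinaryMask} providing the affine, or
#'   a 4x4 affine matrix.
#' @return a \code{\linkS4class{BinaryMask}}.
#' @export
binaryMask <- function(values, grid) {
  aff <- if (is.matrix(grid)) grid else grid@affine
  if (!is.logical(values)) {
    values <- array(values != 0, dim = dim(values))
  }
  new("BinaryMask", values = values, affine = aff)
}

#' Construct a rigid transform
#'
#' @param rotation 3x3 orthonormal matrix, default identity.
#' @param translation length-3 mm, default zero.
#' @export
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = rotation, translation = translation)
}

#' An empty volume describing a target grid
#'
#' Convenience constructor for the target of \code{\link{resampleToGrid}}:
#' an all-zero volume with the given shape, spacing and origin.
#'
#' @param shape length-3 integer voxel counts.
#' @param spacing length-3 voxel size in mm.
#' @param origin world position (mm) of voxel (0,0,0).
#' @param modality modality tag for the grid.
#' @export
gridVolume <- function(shape, spacing, origin = c(0, 0, 0),
                       modality = "other") {
  volume(array(0, dim = as.integer(shape)), spacing = spacing,
         origin = origin, modality = modality)
}

#' Read a grid specification from YAML
#'
#' The file must contain \code{shape}, \code{spacing} and optionally
#' \code{origin} (three numbers each).
#'
#' @param path YAML file path.
#' @return an empty \code{Volume} on that grid (see \code{\link{gridVolume}}).
#' @export
readGridSpec <- function(path) {
  spec <- yaml::read_yaml(path)
  if (is.null(spec$shape) || is.null(spec$spacing))
    stop("grid spec must define 'shape' and 'spacing'")
  gridVolume(spec$shape, spec$spacing,
             origin = if (is.null(spec$origin)) c(0, 0, 0) else spec$origin)
}

#' @describeIn voxelData values of a Volume
#' @export
setMethod("voxelData", "Volume", function(x) x@values)
#' @describeIn voxelData values of a BinaryMask
#' @export
setMethod("voxelData", "BinaryMask", function(x) x@values)

#' @describeIn affine affine of a Volume
#' @export
setMethod("affine", "Volume", function(x) x@affine)
#' @describeIn affine affine of a BinaryMask
#' @export
setMethod("affine", "BinaryMask", function(x) x@affine)

#' @describeIn modality modality of a Volume
#' @export
setMethod("modality", "Volume", function(x) x@modality)

#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "Volume",
          function(x) sqrt(colSums(x@affine[1:3, 1:3]^2)))
#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "BinaryMask",
          function(x) sqrt(colSums(x@affine[1:3, 1:3]^2)))

#' @export
setMethod("dim", "Volume", function(x) dim(x@values))
#' @export
setMethod("dim", "BinaryMask", function(x) dim(x@values))

setMethod("show", "Volume", function(object) {
  d <- dim(object@values)
  sp <- voxelSpacing(object)
  cat(sprintf("Volume [%s] %d x %d x %d, spacing %.3g x %.3g x %.3g mm\n",
              object@modality, d[1], d[2], d[3], sp[1], sp[2], sp[3]))
  cat(sprintf("  value range [%.4g, %.4g]\n",
              min(object@values), max(object@values)))
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@values)
  cat(sprintf("BinaryMask %d x %d x %d, %d foreground voxels (%.2f%%)\n",
              d[1], d[2], d[3], sum(object@values),
              100 * mean(object@values)))
})

setMethod("show", "RigidTransform", function(object) {
  cat("RigidTransform\n  rotation:\n")
  print(round(object@rotation, 6))
  cat("  translation (mm):", format(object@translation), "\n")
})

.asPointMatrix <- function(points) {
  if (is.matrix(points)) points else matrix(points, ncol = 3)
}

#' @rdname worldToVoxel
#' @export
setMethod("worldToVoxel", "Volume", function(v, points) {
  p <- .asPointMatrix(points)
  inv <- solve(v@affine)
  out <- t(inv[1:3, 1:3] %*% t(p) + inv[1:3, 4])
  if (is.matrix(points)) out else drop(out)
})
#' @rdname worldToVoxel
#' @export
setMethod("worldToVoxel", "BinaryMask", function(v, points) {
  worldToVoxel(volume(array(0, c(1, 1, 1)), affine = v@affine), points)
})

#' @rdname voxelToWorld
#' @export
setMethod("voxelToWorld", "Volume", function(v, idx) {
  p <- .asPointMatrix(idx)
  out <- t(v@affine[1:3, 1:3] %*% t(p) + v@affine[1:3, 4])
  if (is.matrix(idx)) out else drop(out)
})
#' @rdname voxelToWorld
#' @export
setMethod("voxelToWorld", "BinaryMask", function(v, idx) {
  voxelToWorld(volume(array(0, c(1, 1, 1)), affine = v@affine), idx)
})

#' Trilinear samples of a volume at world points
#'
#' Out-of-bounds points return 0 (air for CT, no counts for SPECT).
#'
#' @param v a \code{Volume}.
#' @param points length-3 vector or N x 3 matrix of world coordinates (mm).
#' @return numeric vector of interpolated values.
#' @export
sampleVolume <- function(v, points) {
  stopifnot(is(v, "Volume"))
  idx <- .asPointMatrix(worldToVoxel(v, .asPointMatrix(points)))
  .cppSampleTrilinear(as.vector(v@values), dim(v@values), idx)
}

.transformInverse4 <- function(transform) {
  # world_src = R^T (world_tgt - t), as a 4x4
  Ti <- diag(4)
  Ti[1:3, 1:3] <- t(transform@rotation)
  Ti[1:3, 4] <- -t(transform@rotation) %*% transform@translation
  Ti
}

#' Resample a volume onto a target grid
#'
#' Each target voxel centre is mapped through the inverse of the rigid
#' transform into the source volume and sampled with trilinear
#' interpolation; points outside the source grid become 0. The transform
#' maps source world coordinates onto target world coordinates (identity by
#' default, the hybrid-scanner assumption).
#'
#' @param src source \code{Volume}.
#' @param target a \code{Volume}, \code{BinaryMask} or the result of
#'   \code{\link{gridVolume}} defining the output grid.
#' @param transform a \code{\linkS4class{RigidTransform}}.
#' @return a \code{Volume} on the target grid with the source's modality.
#' @examples
#' src <- volume(array(rnorm(8^3), c(8, 8, 8)), spacing = c(2, 2, 2))
#' same <- resampleToGrid(src, src)
#' stopifnot(identical(dim(same), dim(src)))
#' @export
resampleToGrid <- function(src, target, transform = rigidTransform()) {
  stopifnot(is(src, "Volume"))
  tgtAffine <- if (is.matrix(target)) target else target@affine
  tgtDim <- if (is.matrix(target)) stop("target must carry a grid shape") else dim(target)
  M <- solve(src@affine) %*% .transformInverse4(transform) %*% tgtAffine
  vals <- .cppResample(as.vector(src@values), dim(src@values), M,
                       as.integer(tgtDim))
  volume(array(vals, dim = tgtDim), affine = tgtAffine,
         modality = src@modality)
}

#' Dice overlap between two masks
#'
#' @param a,b \code{BinaryMask}s on the same grid.
#' @return 2|A n B| / (|A| + |B|); 1 when both masks are empty.
#' @export
diceCoefficient <- function(a, b) {
  stopifnot(identical(dim(a@values), dim(b@values)))
  sa <- sum(a@values); sb <- sum(b@values)
  if (sa + sb == 0) return(1)
  2 * sum(a@values & b@values) / (sa + sb)
}
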