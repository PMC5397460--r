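#' Voxel values of a volume or mask
#' @param x a \code{Volume} or \code{BinaryMask}.
#' @return the 3D array of voxel values.
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' Voxel-to-world affine of a gridded object
#' @param x a \code{Volume} or \code{BinaryMask}.
#' @return the 4x4 voxel-index-to-world-mm matrix.
#' @export
setGeneric("affine", function(x) standardGeneric("affine"))

#' Modality tag of a volume
#' @param x a \code{Volume}.
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' Voxel spacing in mm along each grid axis
#' @param x a \code{Volume} or \code{BinaryMask}.
#' @return length-3 numeric, column norms of the affine's linear part.
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' Map world coordinates (mm) to continuous 0-based voxel indices
#' @param v a \code{Volume} or \code{BinaryMask} defining the grid.
#' @param points length-3 vector or N x 3 matrix of world points.
#' @return continuous voxel indices, same shape as the input.
#' @export
setGeneric("worldToVoxel", function(v, points) standardGeneric("worldToVoxel"))

#' Map 0-based voxel indices to world coordinates (mm)
#' @param v a \code{Volume} or \code{BinaryMask} defining the grid.
#' @param idx length-3 vector or N x 3 matrix of (possibly fractional)
#'   voxel indices.
#' @export
setGeneric("voxelToWorld", function(v, idx) standardGeneric("voxelToWorld"))
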