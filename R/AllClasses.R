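#' @import methods
NULL

.isAffine <- function(a) {
  is.matrix(a) && all(dim(a) == c(4, 4)) && all(is.finite(a)) &&
    abs(det(a)) > 1e-12 && all(a[4, ] == c(0, 0, 0, 1))
}

#' Scalar volume on a regular 3D grid
#'
#' A \code{Volume} holds one scalar per voxel (Hounsfield units for CT,
#' counts for SPECT) together with a 4x4 affine mapping 0-based voxel
#' indices \code{(i,j,k,1)} to world coordinates in millimetres. All
#' geometry in the package is done in world space, so CT and SPECT volumes
#' with different grids coexist without resampling until explicitly asked.
#'
#' @slot values numeric 3D array of voxel values.
#' @slot affine 4x4 voxel-index-to-world-mm matrix (invertible, last row
#'   \code{0 0 0 1}).
#' @slot modality one of \code{"ct"}, \code{"spect"}, \code{"other"}.
#' @export
setClass("Volume",
  representation(values = "array", affine = "matrix", modality = "character"))

setValidity("Volume", function(object) {
  d <- dim(object@values)
  if (length(d) != 3L || any(d < 1L))
    return("values must be a 3D array with positive extents")
  if (!all(is.finite(object@values)))
    return("voxel values must be finite")
  if (!.isAffine(object@affine))
    return("affine must be an invertible 4x4 matrix with last row 0 0 0 1")
  if (length(object@modality) != 1L ||
      !object@modality %in% c("ct", "spect", "other"))
    return("modality must be one of 'ct', 'spect', 'other'")
  TRUE
})

#' Binary mask aligned to a volume grid
#'
#' Boolean field on the same grid (shape and affine) as a companion
#' \code{\linkS4class{Volume}}: extracted bone, bladder, lesion truths.
#'
#' @slot values logical 3D array.
#' @slot affine 4x4 voxel-index-to-world-mm matrix.
#' @export
setClass("BinaryMask", representation(values = "array", affine = "matrix"))

setValidity("BinaryMask", function(object) {
  d <- dim(object@values)
  if (length(d) != 3L || any(d < 1L))
    return("values must be a 3D array with positive extents")
  if (!is.logical(object@values) || anyNA(object@values))
    return("mask values must be logical without NAs")
  if (!.isAffine(object@affine))
    return("affine must be an invertible 4x4 matrix with last row 0 0 0 1")
  TRUE
})

#' Rigid world-space transform
#'
#' Maps SPECT world coordinates onto CT world coordinates
#' (\code{x' = R x + t}). On hybrid scanners the two volumes are acquired in
#' one session, so the identity is the default everywhere a transform is
#' accepted; estimation of the transform is out of scope.
#'
#' @slot rotation 3x3 orthonormal matrix with determinant +1.
#' @slot translation length-3 numeric, millimetres.
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!is.matrix(R) || !all(dim(R) == c(3, 3)) || !all(is.finite(R)))
    return("rotation must be a finite 3x3 matrix")
  if (max(abs(crossprod(R) - diag(3))) > 1e-8)
    return("rotation must be orthonormal")
  if (abs(det(R) - 1) > 1e-8)
    return("rotation must be proper (det = +1)")
  if (length(object@translation) != 3L || !all(is.finite(object@translation)))
    return("translation must be a finite length-3 vector")
  TRUE
})

#' Orthographic camera
#'
#' Parallel-projection view used by all renderers: rays share one direction
#' and originate on a pixel lattice in the image plane. Orthographic
#' geometry keeps ray-surface intersections analytically checkable.
#'
#' @slot viewDir unit length-3 view direction (world).
#' @slot up unit length-3 up vector, orthogonal to \code{viewDir}.
#' @slot width,height image size in pixels.
#' @slot pixelSpacing pixel pitch in mm.
#' @slot center world point (mm) at the image centre.
#' @export
setClass("Camera",
  representation(viewDir = "numeric", up = "numeric", width = "integer",
                 height = "integer", pixelSpacing = "numeric",
                 center = "numeric"))

setValidity("Camera", function(object) {
  if (length(object@viewDir) != 3L || abs(sqrt(sum(object@viewDir^2)) - 1) > 1e-8)
    return("viewDir must be a unit length-3 vector")
  if (length(object@up) != 3L || abs(sqrt(sum(object@up^2)) - 1) > 1e-8)
    return("up must be a unit length-3 vector")
  if (abs(sum(object@viewDir * object@up)) > 1e-8)
    return("up must be orthogonal to viewDir")
  if (object@width < 1L || object@height < 1L)
    return("image size must be positive")
  if (object@pixelSpacing <= 0)
    return("pixelSpacing must be positive")
  if (length(object@center) != 3L || !all(is.finite(object@center)))
    return("center must be a finite world point")
  TRUE
})

#' Clip plane
#'
#' Half-space editing of the rendered volume: every point with
#' \code{normal . x > offset} is removed, exposing the cut face for
#' cross-sectional reading of internal bone metabolism.
#'
#' @slot normal unit length-3 plane normal.
#' @slot offset plane offset d (mm); the half-space n.x > d is removed.
#' @export
setClass("ClipPlane", representation(normal = "numeric", offset = "numeric"))

setValidity("ClipPlane", function(object) {
  if (length(object@normal) != 3L || abs(sqrt(sum(object@normal^2)) - 1) > 1e-8)
    return("normal must be a unit length-3 vector")
  if (length(object@offset) != 1L || !is.finite(object@offset))
    return("offset must be a finite scalar")
  TRUE
})

#' Colour and opacity transfer functions
#'
#' Piecewise-linear maps from CT value (HU) to colour and opacity, and from
#' window-normalised SPECT value in [0,1] to colour. The SPECT display
#' window (counts) normalises uptake before the colour lookup.
#'
#' @slot ctBreaks strictly increasing HU breakpoints.
#' @slot ctColors matrix (breaks x 3) of RGB in [0,1].
#' @slot ctOpacity opacity in [0,1] at each CT breakpoint.
#' @slot spectBreaks strictly increasing breakpoints in [0,1].
#' @slot spectColors matrix (breaks x 3) of RGB in [0,1].
#' @slot window length-2 (lower, upper) SPECT display window in counts.
#' @export
setClass("TransferFunction",
  representation(ctBreaks = "numeric", ctColors = "matrix",
                 ctOpacity = "numeric", spectBreaks = "numeric",
                 spectColors = "matrix", window = "numeric"))

setValidity("TransferFunction", function(object) {
  if (any(diff(object@ctBreaks) <= 0)) return("ctBreaks must be strictly increasing")
  if (any(diff(object@spectBreaks) <= 0)) return("spectBreaks must be strictly increasing")
  if (nrow(object@ctColors) != length(object@ctBreaks) || ncol(object@ctColors) != 3)
    return("ctColors must be a (breaks x 3) matrix")
  if (nrow(object@spectColors) != length(object@spectBreaks) ||
      ncol(object@spectColors) != 3)
    return("spectColors must be a (breaks x 3) matrix")
  if (length(object@ctOpacity) != length(object@ctBreaks) ||
      any(object@ctOpacity < 0 | object@ctOpacity > 1))
    return("ctOpacity must match ctBreaks and lie in [0,1]")
  if (any(object@ctColors < 0 | object@ctColors > 1) ||
      any(object@spectColors < 0 | object@spectColors > 1))
    return("colours must lie in [0,1]")
  if (length(object@window) != 2L || object@window[2] <= object@window[1])
    return("window must be (lower, upper) with upper > lower")
  TRUE
})

#' Rendering settings
#'
#' @slot blendWeight blend weight beta in [0,1] between shaded CT colour and
#'   the SPECT colour lookup.
#' @slot surfaceMode \code{"opaque"} (first-hit, the routine display mode
#'   with bone opacity at 100\%) or \code{"compositing"}.
#' @slot stepSize ray-march step in mm.
#' @slot ambient,diffuse headlight Lambertian shading coefficients.
#' @slot background background RGB in [0,1].
#' @slot uptakeModulated logical; if TRUE the blend weight is scaled by the
#'   normalised uptake so cold bone renders as plain CT; if FALSE a constant
#'   beta blend is used.
#' @export
setClass("RenderSettings",
  representation(blendWeight = "numeric", surfaceMode = "character",
                 stepSize = "numeric", ambient = "numeric",
                 diffuse = "numeric", background = "numeric",
                 uptakeModulated = "logical"))

setValidity("RenderSettings", function(object) {
  if (object@blendWeight < 0 || object@blendWeight > 1)
    return("blendWeight must lie in [0,1]")
  if (!object@surfaceMode %in% c("opaque", "compositing"))
    return("surfaceMode must be 'opaque' or 'compositing'")
  if (!is.na(object@stepSize) && object@stepSize <= 0)
    return("stepSize must be positive (NA = half the minimum voxel spacing)")
  if (length(object@background) != 3L ||
      any(object@background < 0 | object@background > 1))
    return("background must be RGB in [0,1]")
  TRUE
})

#' Bone segmentation parameters
#'
#' @slot boneThreshold HU threshold for cortical bone; voxels at or above it
#'   are kept. Default 150 HU for diagnostic CT; 100 HU suits noisier
#'   low-dose attenuation-correction CT.
#' @slot minComponentVolume smallest connected component kept, mm^3.
#' @slot closingRadius radius (mm) of the ball used for morphological
#'   closing after thresholding.
#' @slot urinaryPercentile fraction of the SPECT maximum above which an
#'   extraosseous component is treated as urinary pooling.
#' @slot urinaryMargin distance (mm) the bone mask is dilated before testing
#'   whether a hot component lies outside the skeleton.
#' @export
setClass("SegmentationParams",
  representation(boneThreshold = "numeric", minComponentVolume = "numeric",
                 closingRadius = "numeric", urinaryPercentile = "numeric",
                 urinaryMargin = "numeric"))

setValidity("SegmentationParams", function(object) {
  if (!is.finite(object@boneThreshold)) return("boneThreshold must be finite")
  if (object@closingRadius < 0) return("closingRadius must be >= 0")
  if (object@minComponentVolume < 0) return("minComponentVolume must be >= 0")
  if (object@urinaryPercentile <= 0 || object@urinaryPercentile > 1)
    return("urinaryPercentile must lie in (0,1]")
  if (object@urinaryMargin < 0) return("urinaryMargin must be >= 0")
  TRUE
})

#' Ordinal confidence counts for one reader and one display mode
#'
#' Lesion counts per point of the four-point diagnostic confidence scale
#' (1 definitely benign, 2 possibly benign, 3 possibly malignant,
#' 4 definitely malignant), split by lesion truth.
#'
#' @slot malignant integer length-4 counts of metastatic lesions per score.
#' @slot benign integer length-4 counts of benign lesions per score.
#' @export
setClass("OrdinalCounts",
  representation(malignant = "integer", benign = "integer"))

setValidity("OrdinalCounts", function(object) {
  if (length(object@malignant) != 4L || length(object@benign) != 4L)
    return("counts must have length 4 (one per confidence score)")
  if (anyNA(object@malignant) || anyNA(object@benign) ||
      any(object@malignant < 0L) || any(object@benign < 0L))
    return("counts must be nonnegative integers")
  TRUE
})
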