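#' Construct segmentation parameters
#'
#' Defaults suit diagnostic CT; for noisier low-dose
#' attenuation-correction CT a lower threshold (about 100 HU) is
#' appropriate, and in severe osteoporosis the threshold should be set from
#' the patient's own cortical HU (see \code{\link{suggestThreshold}}).
#'
#' @param boneThreshold HU cutoff, voxels >= threshold are bone candidates.
#' @param minComponentVolume smallest 26-connected component kept, mm^3.
#' @param closingRadius morphological closing ball radius, mm.
#' @param urinaryPercentile fraction of the SPECT maximum defining "hot".
#' @param urinaryMargin bone-mask dilation margin, mm.
#' @export
segmentationParams <- function(boneThreshold = 150,
                               minComponentVolume = 200,
                               closingRadius = 2,
                               urinaryPercentile = 0.6,
                               urinaryMargin = 10) {
  new("SegmentationParams", boneThreshold = boneThreshold,
      minComponentVolume = minComponentVolume, closingRadius = closingRadius,
      urinaryPercentile = urinaryPercentile, urinaryMargin = urinaryMargin)
}

# Integer offsets of a discrete ball of the given radius (mm), anisotropic
# in voxel units according to the grid spacing.
.ballOffsets <- function(radius, spacing) {
  r <- pmax(0L, as.integer(ceiling(radius / spacing)))
  g <- expand.grid(di = -r[1]:r[1], dj = -r[2]:r[2], dk = -r[3]:r[3])
  keep <- (g$di * spacing[1])^2 + (g$dj * spacing[2])^2 +
          (g$dk * spacing[3])^2 <= radius^2 + 1e-9
  as.matrix(g[keep, , drop = FALSE])
}

#' Semi-automatic bone extraction from CT
#'
#' Thresholds the CT at \code{boneThreshold} HU (>= convention, so cortex at
#' exactly the threshold is kept), applies a morphological closing with a
#' ball of \code{closingRadius} mm, and removes 26-connected components
#' smaller than \code{minComponentVolume} mm^3. The result is the cortical
#' shell; apply \code{\link{closeHoles}} afterwards to re-fill marrow
#' cavities enclosed by it.
#'
#' @param ct a CT \code{Volume} in HU.
#' @param params a \code{\linkS4class{SegmentationParams}}.
#' @return a \code{\linkS4class{BinaryMask}} on the CT grid.
#' @export
extractBone <- function(ct, params = segmentationParams()) {
  stopifnot(is(ct, "Volume"))
  d <- dim(ct@values)
  sp <- voxelSpacing(ct)
  mask <- ct@values >= params@boneThreshold
  if (params@closingRadius > 0) {
    off <- .ballOffsets(params@closingRadius, sp)
    if (nrow(off) > 1) {
      mask <- .cppDilate(as.vector(mask), d, off)
      mask <- .cppErode(mask, d, off)
    }
  }
  if (params@minComponentVolume > 0 && any(mask)) {
    lab <- .cppLabelComponents(as.vector(mask), d, 26L)
    sizes <- tabulate(lab)
    vox <- prod(sp)
    drop <- which(sizes * vox < params@minComponentVolume)
    if (length(drop)) mask[lab %in% drop] <- FALSE
  }
  if (!any(mask))
    warning("bone extraction produced an empty mask (threshold ",
            params@boneThreshold, " HU)")
  binaryMask(array(mask, d), ct)
}

#' Fill cavities enclosed by a mask ("close holes")
#'
#' Every background component (6-connectivity) that cannot be reached from
#' the volume border is set to foreground, re-filling marrow spaces that
#' the cortical-shell threshold leaves hollow. Foreground is never removed,
#' so the operation is extensive and idempotent.
#'
#' @param mask a \code{BinaryMask}.
#' @return a \code{BinaryMask} with enclosed cavities filled.
#' @export
closeHoles <- function(mask) {
  stopifnot(is(mask, "BinaryMask"))
  d <- dim(mask@values)
  out <- .cppFillHoles(as.vector(mask@values), d)
  binaryMask(array(out, d), mask)
}

#' Suppress urinary-tract and bladder activity in SPECT
#'
#' Tracer pooling in the renal collecting system and bladder dominates the
#' SPECT dynamic range and scatters onto nearby bone. Connected components
#' of high activity (>= \code{urinaryPercentile} x max) whose voxels lie
#' entirely outside the bone mask dilated by \code{urinaryMargin} mm are
#' zeroed; every other voxel is returned unchanged, so skeletal uptake is
#' conserved exactly.
#'
#' @param spect SPECT \code{Volume} on the bone-mask grid (resample first
#'   if needed).
#' @param bone bone \code{BinaryMask}.
#' @param params a \code{\linkS4class{SegmentationParams}}.
#' @return a new SPECT \code{Volume}.
#' @export
removeUrinaryActivity <- function(spect, bone, params = segmentationParams()) {
  stopifnot(is(spect, "Volume"), is(bone, "BinaryMask"))
  d <- dim(spect@values)
  if (!identical(d, dim(bone@values)) ||
      max(abs(spect@affine - bone@affine)) > 1e-6)
    stop("SPECT volume and bone mask must share one grid; resample first")
  mx <- max(spect@values)
  if (mx <= 0) return(spect)
  hot <- spect@values >= params@urinaryPercentile * mx
  if (!any(hot)) return(spect)
  protected <- as.vector(bone@values)
  if (params@urinaryMargin > 0) {
    off <- .ballOffsets(params@urinaryMargin, voxelSpacing(spect))
    protected <- .cppDilate(protected, d, off)
  }
  lab <- .cppLabelComponents(as.vector(hot), d, 26L)
  nlab <- max(lab)
  if (nlab == 0) return(spect)
  touches <- vapply(seq_len(nlab),
                    function(l) any(protected[lab == l]), logical(1))
  vals <- spect@values
  vals[array(lab, d) %in% which(!touches)] <- 0
  volume(vals, affine = spect@affine, modality = spect@modality)
}

#' Advisory bone threshold from cortical probe points
#'
#' Supports the manual step of setting the extraction threshold from the
#' patient's cortical bone density: returns \code{fraction} (default one
#' half) of the median HU sampled at the probe points.
#'
#' @param ct CT \code{Volume} in HU.
#' @param probePoints N x 3 matrix (or length-3 vector) of world points on
#'   the bone cortex.
#' @param fraction fraction of the median cortical HU to propose.
#' @return suggested threshold in HU.
#' @export
suggestThreshold <- function(ct, probePoints, fraction = 0.5) {
  stopifnot(is(ct, "Volume"))
  pts <- .asPointMatrix(probePoints)
  idx <- .asPointMatrix(worldToVoxel(ct, pts))
  d <- dim(ct@values)
  inside <- idx[, 1] > -0.5 & idx[, 1] < d[1] - 0.5 &
            idx[, 2] > -0.5 & idx[, 2] < d[2] - 0.5 &
            idx[, 3] > -0.5 & idx[, 3] < d[3] - 0.5
  if (!all(inside))
    stop("probe point outside the CT volume")
  fraction * stats::median(sampleVolume(ct, pts))
}
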