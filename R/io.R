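#' Read a volume from NIfTI or a DICOM series
#'
#' NIfTI affines are taken from the sform when set, otherwise the qform.
#' For a DICOM series directory, slice geometry comes from
#' ImagePositionPatient / ImageOrientationPatient / PixelSpacing and the
#' rescale slope/intercept is applied so CT values are in HU.
#'
#' @param path a .nii/.nii.gz file or a directory of DICOM slices.
#' @param format \code{"nifti"} or \code{"dicom_series"}; guessed from
#'   \code{path} by default.
#' @param modality modality tag to attach (\code{"ct"}, \code{"spect"},
#'   \code{"other"}).
#' @return a \code{\linkS4class{Volume}}.
#' @export
readVolume <- function(path, format = c("auto", "nifti", "dicom_series"),
                       modality = "other") {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (dir.exists(path)) "dicom_series" else "nifti"
  if (format == "nifti") {
    if (!file.exists(path)) stop("file not found: ", path)
    img <- tryCatch(RNifti::readNifti(path),
                    error = function(e) stop("unreadable NIfTI file: ", path,
                                             " (", conditionMessage(e), ")"))
    vals <- array(as.numeric(img), dim = dim(img))
    if (length(dim(vals)) == 4L && dim(vals)[4] == 1L)
      vals <- array(vals, dim = dim(vals)[1:3])
    if (length(dim(vals)) != 3L)
      stop("expected a 3D NIfTI volume: ", path)
    aff <- structure(RNifti::xform(img, useQuaternionFirst = FALSE),
                     imagedim = NULL, code = NULL)
    aff <- matrix(as.numeric(aff), 4, 4)
    volume(vals, affine = aff, modality = modality)
  } else {
    readDicomSeries(path, modality = modality)
  }
}

#' Write a volume as NIfTI-1
#'
#' The affine is stored in both sform and qform so that values and geometry
#' round-trip through \code{\link{readVolume}} exactly (within float
#' precision of the on-disk representation).
#'
#' @param v a \code{Volume} or \code{BinaryMask} (masks are written 0/1).
#' @param path output .nii or .nii.gz path.
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(v, path) {
  vals <- if (is(v, "BinaryMask")) array(as.numeric(v@values), dim(v@values))
          else v@values
  img <- RNifti::asNifti(vals)
  RNifti::sform(img) <- structure(v@affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a mask as a 0/1 NIfTI volume
#' @param mask a \code{BinaryMask}.
#' @param path output path.
#' @export
writeMask <- function(mask, path) writeVolume(mask, path)

#' Read a mask written by \code{\link{writeMask}}
#' @param path NIfTI path holding 0/1 values.
#' @export
readMask <- function(path) {
  v <- readVolume(path)
  binaryMask(v@values != 0, v)
}
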