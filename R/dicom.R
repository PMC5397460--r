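# Minimal DICOM single-frame reader: little-endian transfer syntaxes
# (explicit "1.2.840.10008.1.2.1" and implicit "1.2.840.10008.1.2"),
# uncompressed 16-bit pixel data. This covers CT series exported by
# SPECT/CT scanners; anything else is rejected with a format error.

.dcmUint16 <- function(raw, pos) {
  readBin(raw[pos:(pos + 1)], "integer", size = 2, signed = FALSE,
          endian = "little")
}

.dcmUint32 <- function(raw, pos) {
  b <- as.integer(raw[pos:(pos + 3)])
  b[1] + b[2] * 256 + b[3] * 65536 + b[4] * 16777216
}

.dcmLongVRs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

.parseDicomFile <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 132 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM marker): ", path)
  pos <- 133L
  implicit <- FALSE
  metaEnd <- NA_integer_
  out <- list(slope = 1, intercept = 0, sliceThickness = NA_real_)
  while (pos + 7 <= length(raw)) {
    group <- .dcmUint16(raw, pos)
    elem <- .dcmUint16(raw, pos + 2L)
    pos <- pos + 4L
    inMeta <- group == 2L
    if (!inMeta && !is.na(metaEnd) && pos <= metaEnd) inMeta <- TRUE
    if (inMeta || !implicit) {
      vr <- rawToChar(raw[pos:(pos + 1L)])
      if (vr %in% .dcmLongVRs) {
        len <- .dcmUint32(raw, pos + 4L)
        pos <- pos + 8L
      } else {
        len <- .dcmUint16(raw, pos + 2L)
        pos <- pos + 4L
      }
    } else {
      vr <- ""
      len <- .dcmUint32(raw, pos)
      pos <- pos + 4L
    }
    if (len == 4294967295)
      stop("undefined-length DICOM elements are not supported: ", path)
    val <- if (len > 0) raw[pos:(pos + len - 1L)] else raw(0)
    pos <- pos + len
    tag <- sprintf("%04x,%04x", group, elem)
    str <- function() trimws(rawToChar(val[val != as.raw(0)]))
    nums <- function() as.numeric(strsplit(str(), "\\\\")[[1]])
    if (tag == "0002,0000") {
      # group length counts the bytes of the remaining meta elements
      metaEnd <- pos + .dcmUint32Val(val)
    } else if (tag == "0002,0010") {
      ts <- str()
      if (ts == "1.2.840.10008.1.2") implicit <- TRUE
      else if (ts != "1.2.840.10008.1.2.1")
        stop("unsupported DICOM transfer syntax ", ts, ": ", path)
    } else if (tag == "0020,0032") out$ipp <- nums()
    else if (tag == "0020,0037") out$iop <- nums()
    else if (tag == "0028,0030") out$pixelSpacing <- nums()
    else if (tag == "0028,0010") out$rows <- .dcmUint16(val, 1L)
    else if (tag == "0028,0011") out$cols <- .dcmUint16(val, 1L)
    else if (tag == "0028,0100") out$bitsAllocated <- .dcmUint16(val, 1L)
    else if (tag == "0028,0103") out$pixelRep <- .dcmUint16(val, 1L)
    else if (tag == "0028,1052") out$intercept <- nums()
    else if (tag == "0028,1053") out$slope <- nums()
    else if (tag == "0018,0050") out$sliceThickness <- nums()
    else if (tag == "7fe0,0010") out$pixelRaw <- val
  }
  for (need in c("ipp", "iop", "pixelSpacing", "rows", "cols", "pixelRaw"))
    if (is.null(out[[need]]))
      stop("DICOM file lacks required element (", need, "): ", path)
  if (!is.null(out$bitsAllocated) && out$bitsAllocated != 16L)
    stop("only 16-bit DICOM pixel data is supported: ", path)
  signed <- !is.null(out$pixelRep) && out$pixelRep == 1L
  out$pixels <- readBin(out$pixelRaw, "integer", n = out$rows * out$cols,
                        size = 2, signed = signed, endian = "little")
  out$pixelRaw <- NULL
  out
}

.dcmUint32Val <- function(val) {
  b <- as.integer(val)
  b[1] + b[2] * 256 + b[3] * 65536 + b[4] * 16777216
}

#' Read a DICOM series directory as a volume
#'
#' Slices are sorted along the slice normal (the cross product of the row
#' and column direction cosines); inconsistent inter-slice spacing is a
#' geometry error. Rescale slope and intercept are applied, so CT series
#' come back in Hounsfield units.
#'
#' @param path directory containing one single-frame DICOM file per slice.
#' @param modality modality tag for the resulting volume.
#' @return a \code{\linkS4class{Volume}}.
#' @export
readDicomSeries <- function(path, modality = "ct") {
  if (!dir.exists(path)) stop("directory not found: ", path)
  files <- list.files(path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0) stop("no files in DICOM directory: ", path)
  slices <- lapply(files, .parseDicomFile)
  ref <- slices[[1]]
  for (s in slices)
    if (s$rows != ref$rows || s$cols != ref$cols ||
        max(abs(s$iop - ref$iop)) > 1e-4)
      stop("DICOM series has inconsistent slice geometry: ", path)
  rowDir <- ref$iop[1:3]  # direction of increasing column index
  colDir <- ref$iop[4:6]  # direction of increasing row index
  normal <- c(rowDir[2] * colDir[3] - rowDir[3] * colDir[2],
              rowDir[3] * colDir[1] - rowDir[1] * colDir[3],
              rowDir[1] * colDir[2] - rowDir[2] * colDir[1])
  zpos <- vapply(slices, function(s) sum(s$ipp * normal), numeric(1))
  ord <- order(zpos)
  slices <- slices[ord]
  zpos <- zpos[ord]
  ns <- length(slices)
  if (ns > 1) {
    dz <- diff(zpos)
    if (any(dz <= 0) || (max(dz) - min(dz)) > 1e-3 * mean(dz))
      stop("inconsistent or duplicate DICOM slice spacing in: ", path)
    sliceSpacing <- mean(dz)
  } else {
    sliceSpacing <- if (is.finite(ref$sliceThickness)) ref$sliceThickness else 1
  }
  vals <- array(0, c(ref$cols, ref$rows, ns))
  for (k in seq_len(ns)) {
    s <- slices[[k]]
    vals[, , k] <- array(s$slope * s$pixels + s$intercept,
                         c(ref$cols, ref$rows))
  }
  aff <- diag(4)
  aff[1:3, 1] <- rowDir * ref$pixelSpacing[2]
  aff[1:3, 2] <- colDir * ref$pixelSpacing[1]
  aff[1:3, 3] <- normal * sliceSpacing
  aff[1:3, 4] <- slices[[1]]$ipp
  volume(vals, affine = aff, modality = modality)
}
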