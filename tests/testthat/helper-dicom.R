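# Tiny explicit-VR little-endian DICOM writer for single-frame CT slices,
# used to build series fixtures at test time.

writeTestDicomSlice <- function(path, pixels, ipp,
                                iop = c(1, 0, 0, 0, 1, 0),
                                pixelSpacing = c(1, 1),
                                slope = 1, intercept = 0,
                                sliceThickness = 1) {
  con <- file(path, "wb")
  on.exit(close(con))

  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  u32raw <- function(x) {
    writeBin(as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
                      (x %/% 16777216) %% 256)), con)
  }
  evenStr <- function(s, nullPad = FALSE) {
    r <- charToRaw(s)
    if (length(r) %% 2 == 1)
      r <- c(r, if (nullPad) as.raw(0) else charToRaw(" "))
    r
  }
  shortEl <- function(group, elem, vr, value) {
    u16(group); u16(elem)
    writeChar(vr, con, eos = NULL)
    u16(length(value))
    writeBin(value, con)
  }
  longEl <- function(group, elem, vr, value) {
    u16(group); u16(elem)
    writeChar(vr, con, eos = NULL)
    u16(0)
    u32raw(length(value))
    writeBin(value, con)
  }
  ds <- function(x) evenStr(paste(format(x, trim = TRUE), collapse = "\\"))

  writeBin(raw(128), con)
  writeChar("DICM", con, eos = NULL)

  # meta group: group length + transfer syntax UID (explicit VR LE)
  ts <- evenStr("1.2.840.10008.1.2.1", nullPad = TRUE)
  metaLen <- 4 + 2 + 2 + length(ts)
  shortEl(0x0002, 0x0000, "UL",
          as.raw(c(metaLen %% 256, (metaLen %/% 256) %% 256, 0, 0)))
  shortEl(0x0002, 0x0010, "UI", ts)

  shortEl(0x0018, 0x0050, "DS", ds(sliceThickness))
  shortEl(0x0020, 0x0032, "DS", ds(ipp))
  shortEl(0x0020, 0x0037, "DS", ds(iop))
  u16el <- function(group, elem, x) {
    u16(group); u16(elem)
    writeChar("US", con, eos = NULL)
    u16(2)
    u16(x)
  }
  u16el(0x0028, 0x0010, nrow(pixels))  # Rows
  u16el(0x0028, 0x0011, ncol(pixels))  # Columns
  shortEl(0x0028, 0x0030, "DS", ds(pixelSpacing))
  u16el(0x0028, 0x0100, 16)            # BitsAllocated
  u16el(0x0028, 0x0103, 1)             # PixelRepresentation (signed)
  shortEl(0x0028, 0x1052, "DS", ds(intercept))
  shortEl(0x0028, 0x1053, "DS", ds(slope))

  # pixel data, row-major int16
  px <- as.integer(t(pixels))
  rawPx <- writeBin(px, raw(), size = 2, endian = "little")
  longEl(0x7fe0, 0x0010, "OW", rawPx)
  invisible(path)
}

# a 3-slice axial CT series in a fresh temp directory
writeTestDicomSeries <- function(dir, nx = 6, ny = 5, nz = 3, dz = 2,
                                 slope = 1, intercept = -1024,
                                 storedBase = 1024) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vol <- array(storedBase + seq_len(nx * ny * nz), c(nx, ny, nz))
  for (k in seq_len(nz)) {
    # pixels as rows x cols; volume index i = column, j = row
    P <- t(vol[, , k])
    writeTestDicomSlice(file.path(dir, sprintf("slice%02d.dcm", k)),
                        P, ipp = c(0, 0, (k - 1) * dz),
                        pixelSpacing = c(1, 1), slope = slope,
                        intercept = intercept, sliceThickness = dz)
  }
  vol
}
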