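#' Construct an orthographic camera
#'
#' @param viewDir world view direction (normalised internally).
#' @param up approximate up vector; re-orthogonalised against
#'   \code{viewDir} and normalised.
#' @param width,height image size in pixels.
#' @param pixelSpacing pixel pitch, mm.
#' @param center world point (mm) the image is centred on.
#' @export
camera <- function(viewDir = c(0, -1, 0), up = c(0, 0, 1),
                   width = 128, height = 128, pixelSpacing = 2,
                   center = c(0, 0, 0)) {
  v <- viewDir / sqrt(sum(viewDir^2))
  u <- up - sum(up * v) * v
  nu <- sqrt(sum(u^2))
  if (nu < 1e-12) stop("up vector is parallel to the view direction")
  new("Camera", viewDir = v, up = u / nu, width = as.integer(width),
      height = as.integer(height), pixelSpacing = pixelSpacing,
      center = center)
}

#' A camera framing a volume along a principal direction
#'
#' @param v volume or mask to frame.
#' @param viewDir,up as in \code{\link{camera}}.
#' @param pixelSpacing pixel pitch in mm; defaults to the smallest voxel
#'   spacing of \code{v}.
#' @param margin extra mm added around the projected bounding box.
#' @export
cameraForVolume <- function(v, viewDir = c(0, -1, 0), up = c(0, 0, 1),
                            pixelSpacing = NULL, margin = 8) {
  d <- dim(v)
  if (is.null(pixelSpacing)) pixelSpacing <- min(voxelSpacing(v))
  corners <- as.matrix(expand.grid(c(-0.5, d[1] - 0.5), c(-0.5, d[2] - 0.5),
                                   c(-0.5, d[3] - 0.5)))
  w <- .asPointMatrix(voxelToWorld(v, corners))
  ctr <- colMeans(w)
  cam0 <- camera(viewDir, up, 2, 2, pixelSpacing, ctr)
  right <- .cameraRight(cam0)
  eu <- w %*% right; ev <- w %*% cam0@up
  camera(viewDir, up,
         width = ceiling((diff(range(eu)) + 2 * margin) / pixelSpacing),
         height = ceiling((diff(range(ev)) + 2 * margin) / pixelSpacing),
         pixelSpacing = pixelSpacing, center = ctr)
}

.cameraRight <- function(cam) {
  v <- cam@viewDir; u <- cam@up
  c(v[2] * u[3] - v[3] * u[2], v[3] * u[1] - v[1] * u[3],
    v[1] * u[2] - v[2] * u[1])
}

# Ray origins for every pixel, ordered with image row fastest so an N-vector
# reshapes directly into an [height, width] array. Origins are backed off
# along -viewDir far enough to start outside any volume framed by the camera.
.cameraOrigins <- function(cam, backoff = 2000) {
  right <- .cameraRight(cam)
  g <- expand.grid(v = seq_len(cam@height), u = seq_len(cam@width))
  du <- (g$u - (cam@width + 1) / 2) * cam@pixelSpacing
  dv <- ((cam@height + 1) / 2 - g$v) * cam@pixelSpacing
  ori <- cbind(cam@center[1] + du * right[1] + dv * cam@up[1],
               cam@center[2] + du * right[2] + dv * cam@up[2],
               cam@center[3] + du * right[3] + dv * cam@up[3])
  ori - matrix(backoff * cam@viewDir, nrow(ori), 3, byrow = TRUE)
}

#' Construct a clip plane
#' @param normal plane normal (normalised internally).
#' @param offset offset d in mm; the half-space \code{normal . x > d} is
#'   removed from the rendering.
#' @export
clipPlane <- function(normal, offset) {
  n <- normal / sqrt(sum(normal^2))
  new("ClipPlane", normal = n, offset = offset)
}

#' Construct render settings
#' @param blendWeight beta in [0,1]; weight of the SPECT colour in the
#'   surface blend.
#' @param surfaceMode \code{"opaque"} (default; bone opacity 100\%) or
#'   \code{"compositing"}.
#' @param stepSize ray step in mm; default half the minimum CT voxel
#'   spacing, set at render time when NULL.
#' @param ambient,diffuse headlight Lambertian coefficients.
#' @param background background RGB.
#' @param uptakeModulated scale the blend weight by normalised uptake so
#'   cold bone shows pure CT colour (default); FALSE gives a constant-beta
#'   blend.
#' @export
renderSettings <- function(blendWeight = 0.5, surfaceMode = "opaque",
                           stepSize = NULL, ambient = 0.3, diffuse = 0.7,
                           background = c(0, 0, 0), uptakeModulated = TRUE) {
  new("RenderSettings", blendWeight = blendWeight, surfaceMode = surfaceMode,
      stepSize = if (is.null(stepSize)) NA_real_ else stepSize,
      ambient = ambient, diffuse = diffuse, background = background,
      uptakeModulated = uptakeModulated)
}

.stepFor <- function(settings, ct) {
  if (is.na(settings@stepSize)) min(voxelSpacing(ct)) / 2 else settings@stepSize
}

#' Construct transfer functions for CT and SPECT colouring
#'
#' Defaults: a bone-tinted CT ramp from air to dense cortex, and a
#' hot-metal SPECT lookup over the window-normalised uptake.
#'
#' @param ctBreaks,ctColors,ctOpacity CT piecewise-linear map (HU).
#' @param spectBreaks,spectColors SPECT colour lookup over [0,1].
#' @param window SPECT display window (lower, upper) in counts.
#' @export
transferFunction <- function(ctBreaks = c(-1000, 0, 300, 800, 2000),
                             ctColors = rbind(c(0, 0, 0),
                                              c(0.30, 0.22, 0.15),
                                              c(0.80, 0.75, 0.65),
                                              c(0.95, 0.92, 0.85),
                                              c(1, 1, 1)),
                             ctOpacity = c(0, 0, 0.15, 0.9, 1),
                             spectBreaks = c(0, 0.25, 0.5, 0.75, 1),
                             spectColors = rbind(c(0, 0, 0),
                                                 c(0.5, 0, 0),
                                                 c(1, 0.2, 0),
                                                 c(1, 0.6, 0),
                                                 c(1, 1, 0.8)),
                             window = c(0, 1)) {
  new("TransferFunction", ctBreaks = ctBreaks, ctColors = ctColors,
      ctOpacity = ctOpacity, spectBreaks = spectBreaks,
      spectColors = spectColors, window = window)
}

#' Default transfer function with an automatic SPECT window
#'
#' The display window is [0, 99.5th percentile of in-mask SPECT values], so
#' a handful of hottest voxels do not compress the colour scale.
#'
#' @param spect SPECT \code{Volume} (optional).
#' @param bone bone \code{BinaryMask} on the SPECT grid (optional); when
#'   given, the percentile is taken over in-mask voxels only.
#' @export
defaultTransferFunction <- function(spect = NULL, bone = NULL) {
  win <- c(0, 1)
  if (!is.null(spect)) {
    vals <- spect@values
    if (!is.null(bone)) vals <- vals[bone@values]
    hi <- stats::quantile(vals, 0.995, names = FALSE)
    if (hi <= 0) hi <- max(vals, 1e-9)
    win <- c(0, hi)
  }
  transferFunction(window = win)
}

# piecewise-linear interpolation of a colour table (clamped at the ends)
.lutColor <- function(breaks, colors, x) {
  sapply(1:3, function(ch)
    stats::approx(breaks, colors[, ch], xout = pmin(pmax(x, breaks[1]),
                                                    breaks[length(breaks)]),
                  rule = 2)$y)
}

.normalizedUptake <- function(s, window) {
  pmin(pmax((s - window[1]) / (window[2] - window[1]), 0), 1)
}

#' First bone-surface intersection of parallel rays
#'
#' Rays march through the mask in steps of \code{step} mm from their entry
#' into the volume bounding box; the first sample inside the (clip-edited)
#' mask is refined by one bisection between the bracketing samples.
#'
#' @param origins N x 3 (or length-3) world ray origins.
#' @param dir shared unit ray direction.
#' @param bone \code{BinaryMask}.
#' @param clip optional \code{\linkS4class{ClipPlane}}.
#' @param step march step in mm (default half the minimum voxel spacing).
#' @return list with logical \code{hit}, hit parameter \code{t} (mm, NA on
#'   a miss) and \code{points} (N x 3 world, NA rows on a miss).
#' @export
firstHit <- function(origins, dir, bone, clip = NULL, step = NULL) {
  stopifnot(is(bone, "BinaryMask"))
  ori <- .asPointMatrix(origins)
  dir <- dir / sqrt(sum(dir^2))
  if (is.null(step)) step <- min(voxelSpacing(bone)) / 2
  res <- .cppFirstHit(as.vector(bone@values), dim(bone@values),
                      solve(bone@affine), ori, dir, step,
                      !is.null(clip),
                      if (is.null(clip)) c(0, 0, 0) else clip@normal,
                      if (is.null(clip)) 0 else clip@offset)
  pts <- ori + outer(res$t, dir)
  list(hit = res$hit, t = res$t, points = pts)
}

# Outward surface normals from central differences of the CT field at world
# points (outward = against the HU gradient). Rows with a vanishing
# gradient fall back to facing the camera.
.surfaceNormals <- function(ct, pts, fallback) {
  h <- min(voxelSpacing(ct)) / 2
  g <- sapply(1:3, function(a) {
    e <- c(0, 0, 0); e[a] <- h
    (sampleVolume(ct, sweep(pts, 2, e, "+")) -
     sampleVolume(ct, sweep(pts, 2, e, "-"))) / (2 * h)
  })
  g <- matrix(g, ncol = 3)
  n <- -g
  len <- sqrt(rowSums(n^2))
  bad <- len < 1e-9
  if (any(bad)) {
    n[bad, ] <- matrix(fallback, sum(bad), 3, byrow = TRUE)
    len[bad] <- 1
  }
  n / len
}

.shadedCtColor <- function(ct, pts, viewDir, tf, settings,
                           normalOverride = NULL) {
  hu <- sampleVolume(ct, pts)
  base <- .lutColor(tf@ctBreaks, tf@ctColors, hu)
  base <- matrix(base, ncol = 3)
  if (is.null(normalOverride)) {
    n <- .surfaceNormals(ct, pts, -viewDir)
  } else {
    n <- matrix(normalOverride, nrow(pts), 3, byrow = TRUE)
  }
  lambert <- pmax(0, -(n %*% viewDir))
  shade <- settings@ambient + settings@diffuse * as.vector(lambert)
  base * shade
}

.imageFromColors <- function(colors, hit, cam, background) {
  img <- array(0, c(cam@height, cam@width, 3))
  for (ch in 1:3) {
    plane <- rep(background[ch], cam@height * cam@width)
    plane[hit] <- colors[hit, ch]
    img[, , ch] <- plane
  }
  img
}

#' Volume-render the CT bone surface
#'
#' In \code{"opaque"} mode (the routine bone display: opacity 100\%) each
#' pixel takes the Lambert-shaded CT transfer-function colour at the first
#' bone-surface hit of its ray. In \code{"compositing"} mode a standard
#' front-to-back accumulation of the CT transfer function (restricted to
#' the bone mask) is used instead.
#'
#' @param ct CT \code{Volume} (HU).
#' @param bone bone \code{BinaryMask} on the CT grid.
#' @param cam a \code{\linkS4class{Camera}}.
#' @param tf a \code{\linkS4class{TransferFunction}}.
#' @param clip optional \code{\linkS4class{ClipPlane}}.
#' @param settings a \code{\linkS4class{RenderSettings}}.
#' @return RGB array [height, width, 3] in [0,1].
#' @export
renderCT <- function(ct, bone, cam, tf = transferFunction(), clip = NULL,
                     settings = renderSettings()) {
  stopifnot(is(ct, "Volume"), is(bone, "BinaryMask"))
  step <- .stepFor(settings, ct)
  ori <- .cameraOrigins(cam)
  if (settings@surfaceMode == "compositing") {
    res <- .cppComposite(as.vector(ct@values), as.vector(bone@values),
                         dim(ct@values), solve(ct@affine), ori, cam@viewDir,
                         step, !is.null(clip),
                         if (is.null(clip)) c(0, 0, 0) else clip@normal,
                         if (is.null(clip)) 0 else clip@offset,
                         tf@ctBreaks, tf@ctColors, tf@ctOpacity)
    img <- array(0, c(cam@height, cam@width, 3))
    for (ch in 1:3)
      img[, , ch] <- res$color[, ch] +
        (1 - res$alpha) * settings@background[ch]
    return(img)
  }
  fh <- firstHit(ori, cam@viewDir, bone, clip, step)
  colors <- matrix(0, nrow(ori), 3)
  if (any(fh$hit))
    colors[fh$hit, ] <- .shadedCtColor(ct, fh$points[fh$hit, , drop = FALSE],
                                       cam@viewDir, tf, settings)
  .imageFromColors(pmin(pmax(colors, 0), 1), fh$hit, cam, settings@background)
}

.fusedSurfaceColors <- function(ct, spect, pts, viewDir, tf, settings,
                                normalOverride = NULL) {
  ctCol <- pmin(pmax(.shadedCtColor(ct, pts, viewDir, tf, settings,
                                    normalOverride), 0), 1)
  s <- sampleVolume(spect, pts)
  w <- .normalizedUptake(s, tf@window)
  lut <- matrix(.lutColor(tf@spectBreaks, tf@spectColors, w), ncol = 3)
  beta <- settings@blendWeight
  wt <- if (settings@uptakeModulated) beta * w else rep(beta, length(w))
  (1 - wt) * ctCol + wt * lut
}

#' Render the 3D SPECT/CT fusion
#'
#' The core display: SPECT uptake is expressed in colour at the first-hit
#' point on the opaque volume-rendered bone surface and blended with the
#' shaded CT colour, so metabolism is visualised only on displayed bone and
#' never on background or soft tissue. With uptake-modulated blending
#' (default) the pixel is
#' \code{(1 - beta w) ct_shaded + beta w LUT(w)} where \code{w} is the
#' window-normalised uptake, so cold bone renders as plain CT.
#'
#' @inheritParams renderCT
#' @param spect SPECT \code{Volume} on the CT grid (resampled and
#'   urinary-cleaned).
#' @return RGB array [height, width, 3].
#' @export
renderFusion3d <- function(ct, bone, spect, cam,
                           tf = defaultTransferFunction(spect, bone),
                           clip = NULL, settings = renderSettings()) {
  stopifnot(is(ct, "Volume"), is(bone, "BinaryMask"), is(spect, "Volume"))
  if (!identical(dim(ct@values), dim(spect@values)) ||
      max(abs(ct@affine - spect@affine)) > 1e-6)
    stop("SPECT must be resampled onto the CT grid before fusion rendering")
  step <- .stepFor(settings, ct)
  ori <- .cameraOrigins(cam)
  fh <- firstHit(ori, cam@viewDir, bone, clip, step)
  colors <- matrix(0, nrow(ori), 3)
  if (any(fh$hit))
    colors[fh$hit, ] <- .fusedSurfaceColors(ct, spect,
                                            fh$points[fh$hit, , drop = FALSE],
                                            cam@viewDir, tf, settings)
  .imageFromColors(pmin(pmax(colors, 0), 1), fh$hit, cam, settings@background)
}

#' Render a clip-plane cross-section of the fusion
#'
#' As \code{\link{renderFusion3d}}, but rays whose first hit lies on the
#' clip plane (the cut face) are coloured by the fused CT/SPECT values of
#' the interior tissue at the cut, using the plane normal for shading. This
#' exposes internal bone metabolism and structure (marrow versus cortex)
#' along the cut.
#'
#' @inheritParams renderFusion3d
#' @param clip the \code{\linkS4class{ClipPlane}} doing the cutting.
#' @export
renderCrossSection <- function(ct, bone, spect, clip, cam,
                               tf = defaultTransferFunction(spect, bone),
                               settings = renderSettings()) {
  stopifnot(is(clip, "ClipPlane"))
  if (sum(cam@viewDir * clip@normal) > -cos(30 * pi / 180))
    warning("camera is not facing the cut (view direction should be ",
            "antiparallel to the clip normal within 30 degrees)")
  step <- .stepFor(settings, ct)
  ori <- .cameraOrigins(cam)
  fh <- firstHit(ori, cam@viewDir, bone, clip, step)
  colors <- matrix(0, nrow(ori), 3)
  if (any(fh$hit)) {
    pts <- fh$points[fh$hit, , drop = FALSE]
    onCut <- abs(pts %*% clip@normal - clip@offset) <= step
    sub <- matrix(0, nrow(pts), 3)
    if (any(!onCut))
      sub[!onCut, ] <- .fusedSurfaceColors(ct, spect,
                                           pts[!onCut, , drop = FALSE],
                                           cam@viewDir, tf, settings)
    if (any(onCut))
      sub[onCut, ] <- .fusedSurfaceColors(ct, spect,
                                          pts[onCut, , drop = FALSE],
                                          cam@viewDir, tf, settings,
                                          normalOverride = clip@normal)
    colors[fh$hit, ] <- sub
  }
  .imageFromColors(pmin(pmax(colors, 0), 1), fh$hit, cam, settings@background)
}

#' Conventional 2D fused slices
#'
#' Window/levelled grayscale CT blended per pixel with the LUT-coloured,
#' window-normalised SPECT at opacity \code{alpha}:
#' \code{(1 - alpha) gray + alpha LUT(w)}.
#'
#' @param ct CT \code{Volume}.
#' @param spect SPECT \code{Volume} on the CT grid.
#' @param axis \code{"axial"}, \code{"coronal"} or \code{"sagittal"}
#'   (slices across the third, second and first grid axis respectively).
#' @param alpha SPECT overlay opacity in [0,1].
#' @param tf \code{TransferFunction} providing the SPECT LUT and window.
#' @param ctWindow CT display window (lower, upper) in HU.
#' @param slices slice indices (default all).
#' @return list of RGB arrays, one per slice.
#' @export
fuse2dSlices <- function(ct, spect, axis = c("axial", "coronal", "sagittal"),
                         alpha = 0.4, tf = defaultTransferFunction(spect),
                         ctWindow = c(-200, 1300), slices = NULL) {
  axis <- match.arg(axis)
  if (!identical(dim(ct@values), dim(spect@values)))
    stop("SPECT must be on the CT grid for 2D fusion")
  ax <- switch(axis, sagittal = 1L, coronal = 2L, axial = 3L)
  d <- dim(ct@values)
  if (is.null(slices)) slices <- seq_len(d[ax])
  lapply(slices, function(s) {
    idx <- list(quote(expr = ), quote(expr = ), quote(expr = ))
    idx[[ax]] <- s
    ctS <- do.call(`[`, c(list(ct@values), idx))
    spS <- do.call(`[`, c(list(spect@values), idx))
    gray <- pmin(pmax((ctS - ctWindow[1]) / diff(ctWindow), 0), 1)
    w <- .normalizedUptake(spS, tf@window)
    lut <- .lutColor(tf@spectBreaks, tf@spectColors, as.vector(w))
    img <- array(0, c(dim(ctS), 3))
    for (ch in 1:3)
      img[, , ch] <- (1 - alpha) * gray +
        alpha * array(lut[, ch], dim(ctS))
    img
  })
}

#' Write an RGB image array as 8-bit PNG
#' @param img array [height, width, 3] in [0,1].
#' @param path output path.
#' @export
writeImagePNG <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}
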