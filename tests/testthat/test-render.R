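# small analytic scenes on a 1 mm grid (world == voxel coordinates)
.slabScene <- function(n = 20, x0 = 9, x1 = 12, hu = 800) {
  vals <- array(-1000, c(n, n, n))
  vals[x0:x1, , ] <- hu
  ct <- volume(vals, spacing = c(1, 1, 1), modality = "ct")
  list(ct = ct, bone = binaryMask(vals >= 150, ct))
}

test_that("rays missing the volume or fully clipped masks report no hit", {
  sc <- .slabScene()
  miss <- firstHit(c(-50, 500, 500), c(1, 0, 0), sc$bone)
  expect_false(miss$hit)
  expect_true(is.na(miss$t))
  # clip plane that removes the whole mask
  gone <- firstHit(c(-50, 10, 10), c(1, 0, 0), sc$bone,
                   clip = clipPlane(c(0, 0, 1), -100))
  expect_false(gone$hit)
})

test_that("an axis-aligned ray hits the slab entry face within step/2", {
  sc <- .slabScene(x0 = 9, x1 = 12)       # slab occupies world x in [7.5, 11.5]
  step <- 0.5
  fh <- firstHit(c(-40, 10, 10), c(1, 0, 0), sc$bone, step = step)
  expect_true(fh$hit)
  expect_lt(abs(fh$points[1, 1] - 7.5), step / 2 + 1e-9)
  expect_equal(fh$points[1, 2:3], c(10, 10))
})

test_that("an empty bone mask renders pure background", {
  sc <- .slabScene()
  empty <- binaryMask(array(FALSE, dim(sc$ct)), sc$ct)
  cam <- camera(c(0, 0, -1), c(0, 1, 0), width = 16, height = 16,
                pixelSpacing = 1, center = c(10, 10, 10))
  st <- renderSettings(background = c(0.1, 0.2, 0.3))
  img <- renderCT(sc$ct, empty, cam, settings = st)
  for (ch in 1:3) expect_true(all(img[, , ch] == st@background[ch]))
})

test_that("a single opaque voxel lights exactly its projected footprint", {
  n <- 21
  vals <- array(-1000, c(n, n, n))
  vals[11, 11, 11] <- 800                # world cube [9.5,10.5]^3
  ct <- volume(vals, spacing = c(1, 1, 1), modality = "ct")
  bone <- binaryMask(vals >= 150, ct)
  cam <- camera(c(0, 0, -1), c(0, 1, 0), width = 33, height = 33,
                pixelSpacing = 0.25, center = c(10, 10, 10))
  img <- renderCT(ct, bone, cam, settings = renderSettings(stepSize = 0.25))
  nonbg <- sum(apply(img, c(1, 2), sum) > 0)
  # footprint area 1 mm^2 over 0.25 mm pixels = 16 pixels
  expect_equal(nonbg, 16)
})

test_that("compositing with zero opacity gives the background image", {
  sc <- .slabScene()
  cam <- camera(c(1, 0, 0), c(0, 0, 1), width = 12, height = 12,
                pixelSpacing = 1.5, center = c(10, 10, 10))
  tf <- transferFunction(ctOpacity = c(0, 0, 0, 0, 0))
  st <- renderSettings(surfaceMode = "compositing", background = c(0, 0.5, 0))
  img <- renderCT(sc$ct, sc$bone, cam, tf, settings = st)
  expect_true(all(img[, , 1] == 0) && all(img[, , 2] == 0.5))
})

test_that("compositing a fully opaque uniform slab equals the first-hit render", {
  sc <- .slabScene(hu = 800)
  sc$ct@values[] <- 800                   # uniform CT so colour is constant
  cam <- camera(c(1, 0, 0), c(0, 0, 1), width = 10, height = 10,
                pixelSpacing = 1, center = c(10, 10, 10))
  tf <- transferFunction(ctOpacity = c(1, 1, 1, 1, 1))
  # headlight off (ambient 1) so the opaque mode is unshaded too
  stO <- renderSettings(surfaceMode = "opaque", ambient = 1, diffuse = 0)
  stC <- renderSettings(surfaceMode = "compositing")
  imgO <- renderCT(sc$ct, sc$bone, cam, tf, settings = stO)
  imgC <- renderCT(sc$ct, sc$bone, cam, tf, settings = stC)
  expect_equal(imgC, imgO, tolerance = 1e-10)
})

test_that("fusion with beta = 0 or zero uptake reproduces the CT render", {
  sc <- .slabScene()
  cam <- camera(c(1, 0, 0), c(0, 0, 1), width = 14, height = 14,
                pixelSpacing = 1.5, center = c(10, 10, 10))
  zero <- volume(array(0, dim(sc$ct)), affine = affine(sc$ct),
                 modality = "spect")
  hot <- volume(array(3, dim(sc$ct)), affine = affine(sc$ct),
                modality = "spect")
  tf <- transferFunction(window = c(0, 3))
  base <- renderCT(sc$ct, sc$bone, cam, tf)
  expect_equal(renderFusion3d(sc$ct, sc$bone, hot, cam, tf,
                              settings = renderSettings(blendWeight = 0)),
               base)
  for (beta in c(0.3, 1))
    expect_equal(renderFusion3d(sc$ct, sc$bone, zero, cam, tf,
                                settings = renderSettings(blendWeight = beta)),
                 base)
})

test_that("window-maximum uptake at beta = 1 yields the top LUT colour", {
  n <- 21
  vals <- array(-1000, c(n, n, n))
  vals[11, 11, 11] <- 800
  ct <- volume(vals, spacing = c(1, 1, 1), modality = "ct")
  bone <- binaryMask(vals >= 150, ct)
  spect <- volume(array(5, c(n, n, n)), affine = affine(ct),
                  modality = "spect")
  tf <- transferFunction(window = c(0, 5))
  cam <- camera(c(0, 0, -1), c(0, 1, 0), width = 9, height = 9,
                pixelSpacing = 0.25, center = c(10, 10, 10))
  img <- renderFusion3d(ct, bone, spect, cam, tf,
                        settings = renderSettings(blendWeight = 1))
  centre <- img[5, 5, ]
  expect_equal(centre, tf@spectColors[5, ], tolerance = 1e-12)
})

test_that("every fused pixel is a convex combination of CT colour and LUT", {
  sc <- .slabScene()
  set.seed(31)
  sp <- volume(array(runif(prod(dim(sc$ct)), 0, 2), dim(sc$ct)),
               affine = affine(sc$ct), modality = "spect")
  tf <- transferFunction(window = c(0, 2))
  cam <- camera(c(1, 0, 0), c(0, 0, 1), width = 16, height = 16,
                pixelSpacing = 1.25, center = c(10, 10, 10))
  img <- renderFusion3d(sc$ct, sc$bone, sp, cam, tf)
  expect_true(all(img >= 0 & img <= 1))
})

test_that("pixels behind the first hit ignore deeper CT values (occlusion)", {
  sc <- .slabScene(x0 = 9, x1 = 14)
  cam <- camera(c(1, 0, 0), c(0, 0, 1), width = 12, height = 12,
                pixelSpacing = 1, center = c(10, 10, 10))
  img1 <- renderCT(sc$ct, sc$bone, cam)
  deep <- sc$ct
  deep@values[13:14, , ] <- 1800          # well behind the x = 7.5 surface
  img2 <- renderCT(deep, sc$bone, cam)
  expect_equal(img2, img1)
})

test_that("cross-sections: no-op clip matches the fusion render, full clip is background", {
  sc <- .slabScene()
  sp <- volume(array(1, dim(sc$ct)), affine = affine(sc$ct),
               modality = "spect")
  tf <- transferFunction(window = c(0, 1))
  cam <- camera(c(0, 0, -1), c(0, 1, 0), width = 14, height = 14,
                pixelSpacing = 1.5, center = c(10, 10, 10))
  noop <- clipPlane(c(0, 0, 1), 1e5)      # removes nothing, faces the camera
  expect_equal(renderCrossSection(sc$ct, sc$bone, sp, noop, cam, tf),
               renderFusion3d(sc$ct, sc$bone, sp, cam, tf))
  all.gone <- clipPlane(c(0, 0, 1), -1e5)
  img <- renderCrossSection(sc$ct, sc$bone, sp, all.gone, cam, tf)
  expect_true(all(img == 0))
})

test_that("the cut face shows marrow surrounded by cortex", {
  # hollow box: cortex 800 HU shell, marrow 100 HU core
  n <- 24
  hu <- array(-1000, c(n, n, n))
  hu[7:18, 7:18, 7:18] <- 800
  hu[10:15, 10:15, 10:15] <- 100
  ct <- volume(hu, spacing = c(1, 1, 1), modality = "ct")
  bone <- closeHoles(binaryMask(hu >= 150, ct))
  sp <- volume(array(0, c(n, n, n)), affine = affine(ct), modality = "spect")
  cam <- camera(c(0, 0, -1), c(0, 1, 0), width = 25, height = 25,
                pixelSpacing = 1, center = c(12, 12, 12))
  clip <- clipPlane(c(0, 0, 1), 12)       # cut through the core
  img <- renderCrossSection(ct, bone, sp, clip, cam,
                            transferFunction(window = c(0, 1)))
  # classify cut pixels by CT colour: marrow (100 HU) vs cortex (800 HU)
  tf <- transferFunction()
  marrowCol <- bonefuse:::.lutColor(tf@ctBreaks, tf@ctColors, 100)
  cortexCol <- bonefuse:::.lutColor(tf@ctBreaks, tf@ctColors, 800)
  mid <- img[13, 13, ]                    # image centre: marrow at the cut
  edge <- img[13, 17, ]                   # within shell ring
  expect_equal(sum(abs(mid / max(mid) - marrowCol / max(marrowCol))), 0,
               tolerance = 0.15)
  expect_equal(sum(abs(edge / max(edge) - cortexCol / max(cortexCol))), 0,
               tolerance = 0.15)
  # marrow pixels darker than the cortex ring around them
  expect_lt(sum(mid), sum(edge))
})

test_that("2D fused slices blend exactly", {
  n <- 8
  ct <- volume(array(500, c(n, n, n)), spacing = c(1, 1, 1), modality = "ct")
  sp <- volume(array(2, c(n, n, n)), affine = affine(ct), modality = "spect")
  tf <- transferFunction(window = c(0, 2))
  ctWindow <- c(-200, 1300)
  gray <- (500 - ctWindow[1]) / diff(ctWindow)
  top <- tf@spectColors[5, ]
  s0 <- fuse2dSlices(ct, sp, "axial", alpha = 0, tf, ctWindow)[[1]]
  expect_true(all(abs(s0 - gray) < 1e-12))
  s1 <- fuse2dSlices(ct, sp, "axial", alpha = 1, tf, ctWindow)[[4]]
  for (ch in 1:3) expect_true(all(abs(s1[, , ch] - top[ch]) < 1e-12))
  s5 <- fuse2dSlices(ct, sp, "coronal", alpha = 0.5, tf, ctWindow)[[2]]
  for (ch in 1:3)
    expect_true(all(abs(s5[, , ch] - (0.5 * gray + 0.5 * top[ch])) < 1e-12))
  expect_length(fuse2dSlices(ct, sp, "sagittal", 0.4, tf), n)
})
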