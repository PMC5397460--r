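# helpers: a hollow cortical box in soft tissue, on a 1 mm grid
.shellPhantom <- function(n = 24, cortexHU = 800, marrowHU = 100) {
  hu <- array(-50, c(n, n, n))
  lo <- 6; hi <- n - 5
  hu[lo:hi, lo:hi, lo:hi] <- cortexHU
  hu[(lo + 2):(hi - 2), (lo + 2):(hi - 2), (lo + 2):(hi - 2)] <- marrowHU
  list(ct = volume(hu, modality = "ct"),
       shell = hu == cortexHU, interior = hu == marrowHU)
}

test_that("an all-air volume yields an empty mask with a warning", {
  ct <- volume(array(-1000, c(8, 8, 8)), modality = "ct")
  expect_warning(m <- extractBone(ct), "empty")
  expect_equal(sum(voxelData(m)), 0)
})

test_that("a voxel exactly at the threshold is included", {
  hu <- array(-1000, c(5, 5, 5))
  hu[3, 3, 3] <- 150
  hu[2, 3, 3] <- 149.999
  ct <- volume(hu, modality = "ct")
  m <- extractBone(ct, segmentationParams(boneThreshold = 150,
                                          closingRadius = 0,
                                          minComponentVolume = 0))
  expect_true(voxelData(m)[3, 3, 3])
  expect_false(voxelData(m)[2, 3, 3])
  expect_equal(sum(voxelData(m)), 1)
})

test_that("thresholding recovers exactly the cortical shell", {
  sp <- .shellPhantom()
  m <- extractBone(sp$ct, segmentationParams(boneThreshold = 150,
                                             closingRadius = 0,
                                             minComponentVolume = 0))
  expect_identical(voxelData(m), sp$shell)
  expect_equal(sum(voxelData(m)), sum(sp$shell))
})

test_that("extraction is monotone in the threshold", {
  set.seed(21)
  ct <- volume(array(rnorm(16^3, mean = 200, sd = 300), c(16, 16, 16)),
               modality = "ct")
  prev <- NULL
  for (thr in c(-100, 50, 150, 400, 700)) {
    m <- voxelData(extractBone(ct, segmentationParams(
      boneThreshold = thr, closingRadius = 0, minComponentVolume = 0)))
    if (!is.null(prev)) expect_true(all(prev | !m))  # m subset of prev
    prev <- m
  }
})

test_that("small components are removed by the volume filter", {
  hu <- array(-1000, c(12, 12, 12))
  hu[2:9, 2:9, 2:9] <- 800      # large block: 512 mm^3 at 1 mm voxels
  hu[11, 11, 11] <- 800         # isolated speck
  ct <- volume(hu, modality = "ct")
  m <- extractBone(ct, segmentationParams(closingRadius = 0,
                                          minComponentVolume = 10))
  expect_false(voxelData(m)[11, 11, 11])
  expect_true(all(voxelData(m)[2:9, 2:9, 2:9]))
})

test_that("closeHoles turns a hollow shell into a solid", {
  sp <- .shellPhantom()
  m <- binaryMask(sp$shell, sp$ct)
  filled <- closeHoles(m)
  expect_identical(voxelData(filled), sp$shell | sp$interior)
})

test_that("closeHoles leaves cavity-free masks unchanged and is idempotent", {
  set.seed(22)
  solid <- array(FALSE, c(10, 10, 10))
  solid[3:7, 3:7, 3:7] <- TRUE
  m <- binaryMask(solid, gridVolume(c(10, 10, 10), c(1, 1, 1)))
  expect_identical(voxelData(closeHoles(m)), solid)
  rnd <- binaryMask(array(runif(12^3) < 0.3, c(12, 12, 12)),
                    gridVolume(c(12, 12, 12), c(1, 1, 1)))
  once <- closeHoles(rnd)
  twice <- closeHoles(once)
  expect_identical(voxelData(once), voxelData(twice))
  expect_true(all(voxelData(once) | !voxelData(rnd)))  # extensive
})

test_that("a cavity connected to the border through a tunnel stays open", {
  shell <- array(FALSE, c(12, 12, 12))
  shell[3:9, 3:9, 3:9] <- TRUE
  shell[4:8, 4:8, 4:8] <- FALSE       # cavity
  shell[6, 6, 1:4] <- FALSE           # tunnel from border into cavity
  m <- binaryMask(shell, gridVolume(c(12, 12, 12), c(1, 1, 1)))
  filled <- closeHoles(m)
  expect_identical(voxelData(filled), shell)
  # oracle agrees
  expect_identical(voxelData(filled), floodFillOracle(shell))
})

test_that("closeHoles matches the border flood-fill oracle on random masks", {
  set.seed(23)
  for (p in c(0.15, 0.3, 0.45)) {
    mask <- array(runif(20^3) < p, c(20, 20, 20))
    m <- binaryMask(mask, gridVolume(c(20, 20, 20), c(1, 1, 1)))
    expect_identical(voxelData(closeHoles(m)), floodFillOracle(mask))
  }
})

test_that("an extraosseous hot blob is zeroed, bone activity conserved", {
  grid <- gridVolume(c(24, 24, 24), c(2, 2, 2))
  bone <- array(FALSE, c(24, 24, 24))
  bone[4:8, 4:8, 4:8] <- TRUE
  boneMask <- binaryMask(bone, grid)
  act <- array(0, c(24, 24, 24))
  act[bone] <- 10
  act[18:21, 18:21, 18:21] <- 100   # blob ~20+ mm from the bone
  spect <- volume(act, affine = affine(grid), modality = "spect")
  out <- removeUrinaryActivity(spect, boneMask,
                               segmentationParams(urinaryPercentile = 0.6,
                                                  urinaryMargin = 10))
  expect_true(all(voxelData(out)[18:21, 18:21, 18:21] == 0))
  expect_equal(voxelData(out)[bone], act[bone])
  # removed activity accounted for exactly
  expect_equal(sum(act) - sum(voxelData(out)), 100 * 4^3)
})

test_that("hot foci inside or near bone are protected", {
  grid <- gridVolume(c(16, 16, 16), c(2, 2, 2))
  bone <- array(FALSE, c(16, 16, 16))
  bone[6:10, 6:10, 6:10] <- TRUE
  act <- array(1, c(16, 16, 16))
  act[8, 8, 8] <- 500               # hot metastasis inside bone
  spect <- volume(act, affine = affine(grid), modality = "spect")
  out <- removeUrinaryActivity(spect, binaryMask(bone, grid))
  expect_identical(voxelData(out), act)
})

test_that("a SPECT with no suprathreshold extraosseous component is unchanged", {
  grid <- gridVolume(c(12, 12, 12), c(2, 2, 2))
  bone <- array(FALSE, c(12, 12, 12)); bone[4:8, 4:8, 4:8] <- TRUE
  act <- array(0.1, c(12, 12, 12)); act[5, 5, 5] <- 10
  spect <- volume(act, affine = affine(grid), modality = "spect")
  out <- removeUrinaryActivity(spect, binaryMask(bone, grid))
  expect_identical(voxelData(out), act)
})

test_that("suggestThreshold halves the median cortical HU", {
  hu <- array(0, c(10, 10, 10))
  ct <- volume(hu, spacing = c(2, 2, 2), modality = "ct")
  pts <- rbind(c(4, 4, 4), c(8, 8, 8), c(12, 12, 12))
  huAt <- function(vals) {
    v <- hu
    for (r in seq_len(nrow(pts))) {
      idx <- round(worldToVoxel(ct, pts[r, ])) + 1
      v[idx[1], idx[2], idx[3]] <- vals[r]
    }
    volume(v, spacing = c(2, 2, 2), modality = "ct")
  }
  expect_equal(suggestThreshold(huAt(c(800, 800, 800)), pts), 400)
  expect_equal(suggestThreshold(huAt(c(700, 800, 900)), pts), 400)
  expect_equal(suggestThreshold(huAt(c(640, 0, 0)), pts[1, , drop = FALSE]),
               320)
  expect_error(suggestThreshold(ct, c(1000, 0, 0)), "outside")
})
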