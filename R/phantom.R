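# Digital skeleton phantom: analytic solids (vertebral bodies with cortical
# shell and marrow, tubular ribs, an ellipsoidal pelvic shell, soft tissue,
# air) plus a bone-turnover activity map with lesion archetypes and a hot
# bladder, blurred to SPECT resolution and Poisson sampled.

#' Default lesion set of the skeleton phantom
#'
#' One lesion per archetype: an osteoblastic vertebral metastasis (+400 HU,
#' high uptake), an osteolytic vertebral metastasis (-400 HU, moderate
#' uptake), a hypermetabolic osteophyte ring at a disc space (degenerative)
#' and a thin low-density fracture band with linear uptake. CT and uptake
#' changes are paired so that activity alone discriminates the classes
#' poorly while CT morphology disambiguates them.
#' @export
defaultLesions <- function() {
  list(
    list(archetype = "osteoblastic_metastasis", center = c(0, 25, 48),
         size = 7, intensity = 8),
    list(archetype = "osteolytic_metastasis", center = c(0, 25, 76),
         size = 7, intensity = 4),
    list(archetype = "degenerative_joint", center = c(0, 25, 90),
         size = 16, intensity = 4),
    list(archetype = "fracture", center = c(0, 25, 20),
         size = 16, intensity = 5)
  )
}

#' Phantom configuration
#'
#' Defaults reproduce the imaging situation the package is tested against:
#' a fine CT grid (2 mm) and a coarse SPECT grid (8 mm, within the 4-10 mm
#' pixel range typical of bone SPECT), Gaussian CT noise, an isotropic
#' Gaussian SPECT point-spread function and a Poisson count budget.
#'
#' @param ctShape,ctSpacing CT grid (voxels, mm).
#' @param spectShape,spectSpacing SPECT grid (voxels, mm); both grids share
#'   one world centre.
#' @param seed RNG seed fixing all randomness of the phantom.
#' @param nVertebrae number of vertebral bodies (1-4 with the default grid).
#' @param ribPairs number of rib pairs (0-2).
#' @param pelvis include the pelvic shell.
#' @param lesions list of lesion specs (archetype, center, size, intensity);
#'   see \code{\link{defaultLesions}}.
#' @param bladderActivity bladder activity relative to the bone baseline of
#'   1; 0 disables the bladder.
#' @param ctNoiseSd Gaussian CT noise, HU.
#' @param psfFwhm SPECT point-spread FWHM, mm.
#' @param countBudget expected total SPECT counts.
#' @export
phantomConfig <- function(ctShape = c(128, 128, 128), ctSpacing = c(2, 2, 2),
                          spectShape = c(32, 32, 32),
                          spectSpacing = c(8, 8, 8),
                          seed = 42L, nVertebrae = 4, ribPairs = 2,
                          pelvis = TRUE, lesions = defaultLesions(),
                          bladderActivity = 20, ctNoiseSd = 20,
                          psfFwhm = 10, countBudget = 5e5) {
  stopifnot(all(ctSpacing > 0), all(spectSpacing > 0), psfFwhm > 0,
            countBudget > 0, ctNoiseSd >= 0, bladderActivity >= 0)
  list(ctShape = as.integer(ctShape), ctSpacing = ctSpacing,
       spectShape = as.integer(spectShape), spectSpacing = spectSpacing,
       seed = as.integer(seed), nVertebrae = nVertebrae, ribPairs = ribPairs,
       pelvis = pelvis, lesions = lesions,
       bladderActivity = bladderActivity, ctNoiseSd = ctNoiseSd,
       psfFwhm = psfFwhm, countBudget = countBudget)
}

# world coordinates of all voxel centres of a centred grid
.centredGrid <- function(shape, spacing) {
  origin <- -(shape - 1) / 2 * spacing
  list(x = origin[1] + (seq_len(shape[1]) - 1) * spacing[1],
       y = origin[2] + (seq_len(shape[2]) - 1) * spacing[2],
       z = origin[3] + (seq_len(shape[3]) - 1) * spacing[3],
       origin = origin)
}

# Separable Gaussian smoothing with edge renormalisation.
.gaussianSmooth <- function(arr, sigmaVox) {
  d <- dim(arr)
  for (axis in 1:3) {
    s <- sigmaVox[axis]
    if (s <= 0) next
    n <- d[axis]
    r <- max(1L, as.integer(ceiling(3 * s)))
    k <- stats::dnorm(-r:r, sd = s)
    K <- matrix(0, n, n)
    for (o in -r:r) {
      i <- seq_len(n); j <- i + o
      ok <- j >= 1 & j <= n
      K[cbind(i[ok], j[ok])] <- k[o + r + 1]
    }
    K <- K / rowSums(K)
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(arr, perm)
    m <- K %*% matrix(ap, n)
    arr <- aperm(array(m, dim(ap)), order(perm))
  }
  arr
}

.lesionMask <- function(les, X, Y, Z, spacing) {
  cx <- les$center[1]; cy <- les$center[2]; cz <- les$center[3]
  switch(les$archetype,
    osteoblastic_metastasis = ,
    osteolytic_metastasis =
      (X - cx)^2 + (Y - cy)^2 + (Z - cz)^2 <= les$size^2,
    degenerative_joint = {
      tube <- 3.5
      (sqrt((X - cx)^2 + (Y - cy)^2) - les$size)^2 + (Z - cz)^2 <= tube^2
    },
    fracture = {
      half <- max(spacing[3] * 0.75, 1)
      abs(Z - cz) <= half & (X - cx)^2 + (Y - cy)^2 <= les$size^2
    },
    bladder_artifact =
      ((X - cx) / les$size)^2 + ((Y - cy) / (0.8 * les$size))^2 +
        ((Z - cz) / (0.6 * les$size))^2 <= 1,
    stop("unknown lesion archetype: ", les$archetype))
}

.lesionIsMalignant <- function(archetype) {
  archetype %in% c("osteolytic_metastasis", "osteoblastic_metastasis")
}

#' Generate the digital CT/SPECT phantom with ground truth
#'
#' Builds the analytic CT, an activity map (bone-turnover baseline 1,
#' faint soft-tissue background, lesion archetype patterns, hot bladder),
#' convolves the activity with the isotropic Gaussian PSF at CT resolution,
#' integrates it onto the coarse SPECT grid and Poisson-samples it under
#' the count budget. Fully reproducible from \code{config$seed}.
#'
#' @param config a \code{\link{phantomConfig}}.
#' @return list with \code{ct} and \code{spect} \code{Volume}s and
#'   \code{truth}: the true skeletal \code{BinaryMask}, per-lesion records
#'   (archetype, malignant flag, world center, mask) and the bladder mask.
#' @examples
#' ph <- generatePhantom(phantomConfig(ctShape = c(48, 48, 48),
#'                                     ctSpacing = c(4, 4, 4),
#'                                     spectShape = c(24, 24, 24),
#'                                     ribPairs = 0, pelvis = FALSE,
#'                                     nVertebrae = 2, lesions = list()))
#' range(voxelData(ph$ct))
#' @export
generatePhantom <- function(config = phantomConfig()) {
  set.seed(config$seed)
  g <- .centredGrid(config$ctShape, config$ctSpacing)
  d <- config$ctShape
  X <- array(rep(g$x, times = d[2] * d[3]), d)
  Y <- array(rep(rep(g$y, each = d[1]), times = d[3]), d)
  Z <- array(rep(g$z, each = d[1] * d[2]), d)

  extent <- d * config$ctSpacing
  body <- (X / (0.36 * extent[1]))^2 + (Y / (0.26 * extent[2]))^2 <= 1
  cortex <- array(FALSE, d)
  marrow <- array(FALSE, d)

  # vertebral bodies: cylinders along z with 3 mm cortical shell + endplates
  vr <- 16; vh <- 11; shell <- 3
  vz <- 20 + (seq_len(config$nVertebrae) - 1) * 28
  for (zc in vz) {
    r2 <- (X - 0)^2 + (Y - 25)^2
    inCyl <- r2 <= vr^2 & abs(Z - zc) <= vh
    inner <- r2 <= (vr - shell)^2 & abs(Z - zc) <= vh - shell
    cortex <- cortex | (inCyl & !inner)
    marrow <- marrow | inner
  }

  # rib pairs: tubes along x with capped ends, 2 mm cortex
  if (config$ribPairs > 0) {
    rr <- 5; rshell <- 2
    ribz <- vz[pmin(length(vz), c(2, 3, 1, 4))][seq_len(config$ribPairs)]
    for (zc in ribz) {
      for (sgn in c(-1, 1)) {
        inTube <- (Y - 10)^2 + (Z - zc)^2 <= rr^2 &
          sgn * X >= 25 & sgn * X <= 85
        innerT <- (Y - 10)^2 + (Z - zc)^2 <= (rr - rshell)^2 &
          sgn * X >= 25 + rshell & sgn * X <= 85 - rshell
        cortex <- cortex | (inTube & !innerT)
        marrow <- marrow | innerT
      }
    }
  }

  # pelvic shell: ellipsoid with 4 mm wall
  if (config$pelvis) {
    pc <- c(0, 10, -35); ax <- c(55, 35, 25)
    rho <- sqrt(((X - pc[1]) / ax[1])^2 + ((Y - pc[2]) / ax[2])^2 +
                ((Z - pc[3]) / ax[3])^2)
    wall <- 4 / mean(ax)
    cortex <- cortex | (rho <= 1 & rho >= 1 - wall)
    marrow <- marrow | (rho < 1 - wall)
  }

  hu <- array(-1000, d)
  hu[body] <- -50
  hu[marrow] <- 100
  hu[cortex] <- 800

  activity <- array(0, d)
  activity[body] <- 0.05
  skeleton <- cortex | marrow
  activity[skeleton] <- 1

  # lesions: paired CT and uptake changes
  lesionRecords <- list()
  for (les in config$lesions) {
    idx <- .lesionMask(les, X, Y, Z, config$ctSpacing)
    if (!any(idx)) stop("lesion lies outside the grid: ", les$archetype)
    deltaHU <- switch(les$archetype,
                      osteoblastic_metastasis = 400,
                      osteolytic_metastasis = -400,
                      degenerative_joint = 300,
                      fracture = -300,
                      bladder_artifact = 0)
    hu[idx] <- hu[idx] + deltaHU
    activity[idx] <- activity[idx] + les$intensity
    if (les$archetype == "degenerative_joint")
      skeleton <- skeleton | idx  # osteophyte is bone
    lesionRecords[[length(lesionRecords) + 1]] <- list(
      archetype = les$archetype,
      malignant = .lesionIsMalignant(les$archetype),
      center = les$center,
      maskIdx = idx)
  }

  # bladder: hot extraosseous pool caudal to the pelvis
  bladder <- array(FALSE, d)
  if (config$bladderActivity > 0) {
    bladder <- ((X - 0) / 22)^2 + ((Y + 30) / 18)^2 + ((Z + 85) / 12)^2 <= 1
    activity[bladder] <- config$bladderActivity
  }

  if (config$ctNoiseSd > 0)
    hu <- hu + array(stats::rnorm(prod(d), sd = config$ctNoiseSd), d)

  ctAffine <- diag(4)
  diag(ctAffine)[1:3] <- config$ctSpacing
  ctAffine[1:3, 4] <- g$origin
  ct <- volume(hu, affine = ctAffine, modality = "ct")

  # PSF in activity space at CT resolution, then integration onto the
  # coarse SPECT grid and Poisson sampling
  sigmaVox <- (config$psfFwhm / 2.3548) / config$ctSpacing
  smoothed <- .gaussianSmooth(activity, sigmaVox)
  smoothedVol <- volume(smoothed, affine = ctAffine, modality = "spect")
  gs <- .centredGrid(config$spectShape, config$spectSpacing)
  spectAffine <- diag(4)
  diag(spectAffine)[1:3] <- config$spectSpacing
  spectAffine[1:3, 4] <- gs$origin
  spectGrid <- gridVolume(config$spectShape, config$spectSpacing,
                          origin = gs$origin, modality = "spect")
  expected <- voxelData(resampleToGrid(smoothedVol, spectGrid))
  tot <- sum(expected)
  if (tot <= 0) stop("phantom activity is empty")
  expected <- expected / tot * config$countBudget
  counts <- array(stats::rpois(length(expected), expected), dim(expected))
  spect <- volume(counts, affine = spectAffine, modality = "spect")

  lesions <- lapply(lesionRecords, function(rec) {
    list(archetype = rec$archetype, malignant = rec$malignant,
         center = rec$center,
         mask = binaryMask(array(rec$maskIdx, d), ct))
  })
  truth <- list(
    skeleton = binaryMask(array(skeleton, d), ct),
    lesions = lesions,
    bladder = binaryMask(array(bladder, d), ct))
  list(ct = ct, spect = spect, truth = truth)
}

#' Simulate ordinal confidence scores for phantom lesions
#'
#' A latent-signal reader model: for each lesion the reader sees
#' \code{discrimination * (+1 malignant / -1 benign)} plus standard normal
#' noise, cut at fixed thresholds (-1, 0, 1) into the four-point scale.
#' Higher discrimination gives higher AUC; 0 gives chance performance.
#'
#' @param truth the \code{truth} element of \code{\link{generatePhantom}},
#'   or any list with a \code{lesions} list carrying \code{malignant}
#'   flags.
#' @param discrimination named numeric vector, one separation parameter
#'   (>= 0) per display modality.
#' @param nReaders number of simulated readers.
#' @param seed RNG seed.
#' @return data.frame with columns lesion_id, truth, reader, modality,
#'   score.
#' @export
simulateReaders <- function(truth,
                            discrimination = c(wb_spect = 0.8,
                                               spectct_2d = 2.2,
                                               spectct_3d = 2.2),
                            nReaders = 2, seed = 1L) {
  stopifnot(all(discrimination >= 0), length(truth$lesions) > 0)
  if (is.null(names(discrimination)))
    names(discrimination) <- paste0("modality", seq_along(discrimination))
  set.seed(seed)
  flags <- vapply(truth$lesions, function(l) isTRUE(l$malignant), logical(1))
  rows <- list()
  for (m in names(discrimination)) {
    for (r in seq_len(nReaders)) {
      latent <- discrimination[[m]] * ifelse(flags, 1, -1) +
        stats::rnorm(length(flags))
      score <- findInterval(latent, c(-1, 0, 1)) + 1L
      rows[[length(rows) + 1]] <- data.frame(
        lesion_id = seq_along(flags),
        truth = ifelse(flags, "malignant", "benign"),
        reader = r, modality = m, score = score,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
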