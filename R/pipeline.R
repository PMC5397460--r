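# Pipeline entry points behind the command-line script (inst/cli/bonefuse.R):
# phantom generation, the segmentation -> urinary cleanup -> resample ->
# render chain, and the reader-statistics summary. Each run writes a JSON
# manifest (parameters, seed, per-stage wall time) so results are
# reproducible from config + seed alone.

.stageTimer <- function() {
  env <- new.env()
  env$times <- list()
  env$mark <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    env$times[[name]] <- round(proc.time()[["elapsed"]] - t0, 3)
    val
  }
  env
}

.writeManifest <- function(path, config, seed, times) {
  manifest <- list(package = "bonefuse",
                   version = as.character(utils::packageVersion("bonefuse")),
                   seed = seed, config = config, stageSeconds = times)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Generate phantom data files
#'
#' Writes ct.nii.gz, spect.nii.gz, the true skeletal and per-lesion masks,
#' and truth.json into \code{outDir}.
#'
#' @param config a \code{\link{phantomConfig}} (or a YAML file path whose
#'   top-level \code{phantom:} keys override the defaults).
#' @param outDir output directory, created if missing.
#' @param seed optional seed overriding \code{config$seed}.
#' @return file paths, invisibly.
#' @export
runPhantom <- function(config = phantomConfig(), outDir = ".", seed = NULL) {
  if (is.character(config)) {
    raw <- yaml::read_yaml(config)
    config <- do.call(phantomConfig,
                      raw$phantom[intersect(names(raw$phantom),
                                            names(formals(phantomConfig)))])
  }
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  ph <- generatePhantom(config)
  paths <- c(ct = file.path(outDir, "ct.nii.gz"),
             spect = file.path(outDir, "spect.nii.gz"),
             skeleton = file.path(outDir, "skeleton_mask.nii.gz"))
  writeVolume(ph$ct, paths[["ct"]])
  writeVolume(ph$spect, paths[["spect"]])
  writeMask(ph$truth$skeleton, paths[["skeleton"]])
  lesionMeta <- list()
  for (i in seq_along(ph$truth$lesions)) {
    les <- ph$truth$lesions[[i]]
    p <- file.path(outDir, sprintf("lesion_%02d_mask.nii.gz", i))
    writeMask(les$mask, p)
    lesionMeta[[i]] <- list(archetype = les$archetype,
                            malignant = les$malignant,
                            center = les$center, mask = basename(p))
  }
  jsonlite::write_json(list(lesions = lesionMeta),
                       file.path(outDir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  .writeManifest(file.path(outDir, "manifest.json"),
                 config[setdiff(names(config), "lesions")],
                 config$seed, list())
  invisible(paths)
}

#' Run the fusion pipeline on a CT/SPECT pair
#'
#' Bone extraction and hole filling, urinary-activity suppression,
#' SPECT-to-CT resampling, then the 3D fusion render (and CT-only render)
#' per camera, optional clip-plane cross-sections, and 2D fused slices.
#'
#' @param ctPath,spectPath input volumes (NIfTI, or a DICOM directory for
#'   CT).
#' @param outDir output directory.
#' @param params \code{\link{segmentationParams}}.
#' @param settings \code{\link{renderSettings}}.
#' @param views named list of \code{\linkS4class{Camera}}s; default
#'   anterior and left-lateral views framing the volume.
#' @param clip optional \code{\linkS4class{ClipPlane}} for an additional
#'   cross-section render.
#' @param axis2d axis for the 2D fused slice stack (NULL to skip).
#' @return paths of the written files, invisibly.
#' @export
runFusion <- function(ctPath, spectPath, outDir = ".",
                      params = segmentationParams(),
                      settings = renderSettings(), views = NULL,
                      clip = NULL, axis2d = "axial") {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  timer <- .stageTimer()
  ct <- timer$mark("read_ct", readVolume(ctPath, modality = "ct"))
  spect <- timer$mark("read_spect", readVolume(spectPath, modality = "spect"))
  bone <- timer$mark("extract_bone", closeHoles(extractBone(ct, params)))
  spectCT <- timer$mark("resample", resampleToGrid(spect, ct))
  spectCT <- timer$mark("urinary",
                        removeUrinaryActivity(spectCT, bone, params))
  tf <- defaultTransferFunction(spectCT, bone)
  if (is.null(views))
    views <- list(anterior = cameraForVolume(ct, c(0, -1, 0), c(0, 0, 1)),
                  lateral = cameraForVolume(ct, c(-1, 0, 0), c(0, 0, 1)))
  paths <- c(bone = file.path(outDir, "bone_mask.nii.gz"))
  writeMask(bone, paths[["bone"]])
  for (nm in names(views)) {
    cam <- views[[nm]]
    imgCT <- timer$mark(paste0("render_ct_", nm),
                        renderCT(ct, bone, cam, tf, settings = settings))
    imgFus <- timer$mark(paste0("render_fusion_", nm),
                         renderFusion3d(ct, bone, spectCT, cam, tf,
                                        settings = settings))
    p1 <- file.path(outDir, sprintf("ct_%s.png", nm))
    p2 <- file.path(outDir, sprintf("fusion3d_%s.png", nm))
    writeImagePNG(imgCT, p1)
    writeImagePNG(imgFus, p2)
    paths <- c(paths, p1, p2)
    if (!is.null(clip)) {
      imgX <- timer$mark(paste0("render_section_", nm),
                         renderCrossSection(ct, bone, spectCT, clip, cam, tf,
                                            settings))
      p3 <- file.path(outDir, sprintf("section_%s.png", nm))
      writeImagePNG(imgX, p3)
      paths <- c(paths, p3)
    }
  }
  if (!is.null(axis2d)) {
    sl <- timer$mark("fuse2d",
                     fuse2dSlices(ct, spectCT, axis = axis2d, tf = tf))
    dir.create(file.path(outDir, "slices"), showWarnings = FALSE)
    for (i in seq_along(sl))
      writeImagePNG(sl[[i]],
                    file.path(outDir, "slices",
                              sprintf("%s_%03d.png", axis2d, i)))
  }
  .writeManifest(file.path(outDir, "manifest.json"),
                 list(ct = ctPath, spect = spectPath,
                      boneThreshold = params@boneThreshold,
                      blendWeight = settings@blendWeight),
                 NA, timer$times)
  invisible(paths)
}

#' Summarise a reader-score table
#'
#' Emits per reader x modality: the four-point counts, confusion metrics at
#' the score >= 3 cutoff, equivocal rate and empirical AUC; plus the
#' between-reader weighted kappa per modality when two readers are present.
#'
#' @param scoresPath per-lesion scores CSV (see \code{\link{readScores}}).
#' @param outDir directory for metrics.json (NULL = don't write).
#' @return the metrics list, invisibly when writing.
#' @export
runStats <- function(scoresPath, outDir = NULL) {
  scores <- readScores(scoresPath)
  out <- list()
  for (m in unique(scores$modality)) {
    for (r in unique(scores$reader)) {
      cnt <- scoresToCounts(scores, reader = r, modality = m)
      cm <- confusionMetrics(cnt)
      eq <- equivocalSummary(cnt)
      auc <- empiricalAuc(cnt)
      out[[sprintf("%s_reader%s", m, r)]] <- list(
        counts = list(malignant = cnt@malignant, benign = cnt@benign),
        percent = as.list(cm$percent), equivocal = eq,
        auc = auc$auc)
    }
    readers <- sort(unique(scores$reader))
    if (length(readers) >= 2) {
      kt <- weightedKappa(readerCrossTab(scores, m, readers[1:2]))
      out[[sprintf("%s_kappa", m)]] <- kt[c("kappa", "weights", "band")]
    }
  }
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(out, file.path(outDir, "metrics.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    return(invisible(out))
  }
  out
}
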