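# Phantoms at the study grid (128^3 CT at 2 mm, 32^3 SPECT at 8 mm) take a
# few seconds to build, so the default and noiseless variants are generated
# once per test session and shared.

.phantomCache <- new.env(parent = emptyenv())

cachedPhantom <- function(noiseless = FALSE) {
  key <- if (noiseless) "clean" else "default"
  if (is.null(.phantomCache[[key]])) {
    cfg <- if (noiseless) phantomConfig(ctNoiseSd = 0) else phantomConfig()
    .phantomCache[[key]] <- generatePhantom(cfg)
  }
  .phantomCache[[key]]
}

cachedBoneMask <- function(noiseless = FALSE) {
  key <- paste0("bone_", if (noiseless) "clean" else "default")
  if (is.null(.phantomCache[[key]])) {
    ph <- cachedPhantom(noiseless)
    .phantomCache[[key]] <- closeHoles(extractBone(ph$ct))
  }
  .phantomCache[[key]]
}

cachedCleanSpect <- function() {
  if (is.null(.phantomCache$spectCT)) {
    ph <- cachedPhantom()
    bone <- cachedBoneMask()
    .phantomCache$spectCT <-
      removeUrinaryActivity(resampleToGrid(ph$spect, ph$ct), bone)
  }
  .phantomCache$spectCT
}
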