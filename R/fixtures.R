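# Canned synthetic experiments ("fixture suites") used by the CLI and the
# test suite: deterministic stacks plus sidecars and a checksum manifest.

#' Default SIM preset triplet
#'
#' Three two-beam presets with fringe orientations 0, 60 and 120 degrees
#' from horizontal. These orientations keep every beam at a distinct
#' horizontal pupil offset, so all three patterns can be phase stepped by
#' the galvo.
#'
#' @param cfg an \linkS4class{OpticalConfig}.
#' @param radius_frac pupil radius fraction (sets the fringe period
#'   \eqn{\lambda/(2\,\mathrm{NA}\cdot\mathrm{radius\_frac})}).
#' @param orientations fringe orientations, rad.
#' @return List of \linkS4class{PatternPreset}.
#' @export
simPresets <- function(cfg, radius_frac = 0.85,
                       orientations = c(0, pi / 3, 2 * pi / 3)) {
  lapply(seq_along(orientations), function(i)
    twoBeamPreset(cfg, orientation = orientations[i],
                  radius_frac = radius_frac,
                  name = sprintf("two-beam-%d", i)))
}

#' Generate a named fixture suite
#'
#' Deterministic synthetic data sets written to \code{dir}:
#' \describe{
#'   \item{sweep15}{two repeated 15-position characterization sweeps
#'     (3 orientations x 5 phases, several frames per position) with
#'     matching schedules, as used for switching-speed and phase
#'     repeatability analysis.}
#'   \item{simcycle11}{two consecutive 11-frame SIM cycles (3 x 3 phases
#'     with orientation dwell frames) of a bead phantom containing
#'     sub-diffraction resolution pairs.}
#'   \item{patterns}{two-beam, hexagonal and linear three-beam intensity
#'     patterns as single-page TIFFs.}
#' }
#' A \code{manifest.json} records every file with a checksum; the same
#' seed always reproduces identical manifests.
#'
#' @param suite suite name.
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @export
makeFixtures <- function(suite = c("sweep15", "simcycle11", "patterns"),
                         seed = 1, dir = ".") {
  suite <- match.arg(suite)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cfg <- opticalConfig()
  camera <- cameraModel(roi = c(128, 128))
  psf <- widefieldPsf(520, 1.42, camera@pixel_size_sample)
  presets <- simPresets(cfg)
  files <- character(0)
  if (suite == "sweep15") {
    phantom <- generateBeadPhantom(40, fov = 8, min_separation = 0.5,
                                   seed = seed)
    sched <- sweepSchedule(frames_per_position = 4)
    for (rep_i in 1:2) {
      st <- runSchedule(phantom, presets, sched, cfg, camera, psf,
                        seed = seed + rep_i)
      f <- file.path(dir, sprintf("sweep15_rep%d.tif", rep_i))
      writeFrameStack(st, f, hash = configHash(list(suite, seed, rep_i)))
      files <- c(files, f, paste0(f, ".json"))
    }
  } else if (suite == "simcycle11") {
    phantom <- generateBeadPhantom(30, fov = 8, min_separation = 0.6,
                                   seed = seed, n_pairs = 2,
                                   pair_separation_nm = 100)
    sched <- simCycleSchedule()
    st <- runSchedule(phantom, presets, sched, cfg, camera, psf,
                      seed = seed, n_cycles = 2)
    f <- file.path(dir, "simcycle11.tif")
    writeFrameStack(st, f, hash = configHash(list(suite, seed)))
    files <- c(files, f, paste0(f, ".json"))
  } else if (suite == "patterns") {
    specs <- list(
      two_beam = twoBeamPreset(cfg),
      hexagonal = hexagonalPreset(cfg),
      linear3 = linearThreeBeamPreset(cfg))
    for (nm in names(specs)) {
      ig <- intensity(synthesizeField(specs[[nm]], cfg, nx = 128, ny = 128,
                                      pixel_size = 0.04))
      f <- file.path(dir, paste0(nm, ".tif"))
      tiff::writeTIFF(ig@values / max(ig@values), f,
                      bits.per.sample = 16)
      files <- c(files, f)
    }
  }
  manifest <- list(suite = suite, seed = seed,
                   files = lapply(files, function(f)
                     list(name = basename(f), checksum = fileHash(f))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
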