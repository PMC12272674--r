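# Configuration files, TIFF stack I/O with structured-text sidecars.

#' Load an optical configuration file
#'
#' YAML key-value file. Recognized keys: \code{wavelength_nm} (or
#' \code{wavelength_um}), \code{refractive_index}, \code{NA},
#' \code{focal_length_main_mm}, \code{galvo_phase_gain},
#' \code{beam_separation_mm}. Lengths are normalized to the package's
#' internal units (nm / mm); unknown keys are rejected by name.
#'
#' @param path file path.
#' @return An \linkS4class{OpticalConfig} with defaults filled in.
#' @export
loadOpticalConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  known <- c("wavelength_nm", "wavelength_um", "refractive_index", "NA",
             "focal_length_main_mm", "galvo_phase_gain",
             "beam_separation_mm")
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(y$wavelength_nm) && !is.null(y$wavelength_um))
    stop("give wavelength_nm or wavelength_um, not both")
  wl <- if (!is.null(y$wavelength_um)) y$wavelength_um * 1000
  else if (!is.null(y$wavelength_nm)) y$wavelength_nm else 473
  opticalConfig(
    wavelength = wl,
    refractive_index = if (is.null(y$refractive_index)) 1.518
      else y$refractive_index,
    focal_length_main = if (is.null(y$focal_length_main_mm)) 200
      else y$focal_length_main_mm,
    effective_NA = if (is.null(y[["NA"]])) 1.5 else y[["NA"]],
    galvo_phase_gain = y$galvo_phase_gain,
    beam_separation_on_galvo = if (is.null(y$beam_separation_mm)) 2
      else y$beam_separation_mm)
}

#' Load a full simulation run configuration
#'
#' YAML file with sections \code{optics} (inline, same keys as
#' [loadOpticalConfig()], or an \code{optics_file} reference),
#' \code{camera}, \code{phantom}, \code{schedule} and top-level
#' \code{seed} / \code{exposure_scale}. Unknown keys anywhere are rejected
#' by name; omitted keys take the package defaults.
#'
#' @param path file path.
#' @return List with elements \code{cfg} (\linkS4class{OpticalConfig}),
#'   \code{camera} (\linkS4class{CameraModel}), \code{phantom_args}
#'   (list), \code{schedule} (\linkS4class{GalvoSchedule}), \code{seed},
#'   \code{exposure_scale} and \code{hash} (config hash stamped into
#'   outputs).
#' @export
loadRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  top_known <- c("optics", "optics_file", "camera", "phantom", "schedule",
                 "seed", "exposure_scale")
  unknown <- setdiff(names(y), top_known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  checkKeys <- function(sec, known, where) {
    unknown <- setdiff(names(sec), known)
    if (length(unknown))
      stop("unknown config key(s) in ", where, ": ",
           paste(unknown, collapse = ", "))
  }
  cfg <- if (!is.null(y$optics_file)) {
    loadOpticalConfig(file.path(dirname(path), y$optics_file))
  } else {
    tmp <- tempfile(fileext = ".yaml")
    on.exit(unlink(tmp), add = TRUE)
    yaml::write_yaml(if (is.null(y$optics)) list() else y$optics, tmp)
    loadOpticalConfig(tmp)
  }
  cam_known <- c("pixel_size_nm", "read_noise", "gain", "offset",
                 "bit_depth", "roi")
  checkKeys(y$camera, cam_known, "camera")
  cam_args <- list()
  if (!is.null(y$camera$pixel_size_nm))
    cam_args$pixel_size_sample <- y$camera$pixel_size_nm
  for (k in c("read_noise", "gain", "offset", "bit_depth", "roi"))
    if (!is.null(y$camera[[k]])) cam_args[[k]] <- unlist(y$camera[[k]])
  camera <- do.call(cameraModel, cam_args)
  ph_known <- c("n_beads", "fov_um", "min_separation_um", "n_pairs",
                "pair_separation_nm", "bead_diameter_nm", "intensity_cv")
  checkKeys(y$phantom, ph_known, "phantom")
  phantom_args <- list(
    n_beads = if (is.null(y$phantom$n_beads)) 50 else y$phantom$n_beads)
  if (!is.null(y$phantom$fov_um))
    phantom_args$fov <- unlist(y$phantom$fov_um)
  if (!is.null(y$phantom$min_separation_um))
    phantom_args$min_separation <- y$phantom$min_separation_um
  for (k in c("n_pairs", "pair_separation_nm", "intensity_cv"))
    if (!is.null(y$phantom[[k]]))
      phantom_args[[sub("_nm$", "_nm", k)]] <- y$phantom[[k]]
  if (!is.null(y$phantom$bead_diameter_nm))
    phantom_args$bead_diameter <- y$phantom$bead_diameter_nm
  sc_known <- c("type", "n_orientations", "n_phases", "phase_step",
                "raw_frame_rate", "frames_per_position",
                "orientation_dwell")
  checkKeys(y$schedule, sc_known, "schedule")
  sc <- y$schedule
  sc_type <- if (is.null(sc$type)) "sim_cycle" else sc$type
  sc_args <- sc[setdiff(names(sc), "type")]
  schedule <- switch(sc_type,
    sim_cycle = do.call(simCycleSchedule, sc_args),
    sweep = do.call(sweepSchedule, sc_args),
    stop("unknown schedule type: ", sc_type))
  out <- list(cfg = cfg, camera = camera, phantom_args = phantom_args,
              schedule = schedule,
              seed = if (is.null(y$seed)) 1L else as.integer(y$seed),
              exposure_scale = if (is.null(y$exposure_scale)) 2000
                else y$exposure_scale)
  out$hash <- configHash(y)
  out
}

#' Write a frame stack as multi-page TIFF plus sidecar metadata
#'
#' Frames are written as a multi-page TIFF (counts scaled to the unit
#' range by the bit-depth maximum); the per-frame metadata, pixel size,
#' seed, bit depth and a config hash go to a JSON sidecar so the pair
#' round-trips exactly.
#'
#' @param stack a \linkS4class{FrameStack}.
#' @param path TIFF output path.
#' @param sidecar sidecar path; default \code{<path>.json}.
#' @param bit_depth bit depth used for scaling (counts assumed within
#'   range).
#' @param hash optional config hash string recorded in the sidecar.
#' @return Invisibly, the sidecar path.
#' @export
writeFrameStack <- function(stack, path, sidecar = paste0(path, ".json"),
                            bit_depth = 16, hash = "") {
  cmax <- 2^bit_depth - 1
  pages <- lapply(seq_len(dim(stack@frames)[3]),
                  function(i) stack@frames[, , i] / cmax)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  meta <- list(pixel_size_um = stack@pixel_size, seed = stack@seed,
               bit_depth = bit_depth, config_hash = hash,
               frames = stack@meta)
  jsonlite::write_json(meta, sidecar, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(sidecar)
}

#' Read a frame stack written by [writeFrameStack()]
#'
#' @param path TIFF path.
#' @param sidecar sidecar path; default \code{<path>.json}.
#' @return A \linkS4class{FrameStack}.
#' @export
readFrameStack <- function(path, sidecar = paste0(path, ".json")) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  cmax <- 2^side$bit_depth - 1
  arr <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]),
                          length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- round(pages[[i]] * cmax)
  meta <- as.data.frame(side$frames)
  new("FrameStack", frames = arr, meta = meta,
      pixel_size = side$pixel_size_um, seed = as.integer(side$seed))
}
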