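#' Read and write volumes as NIfTI
#'
#' Volumes are stored with the full world affine in the NIfTI sform, so
#' spacing, origin and direction survive a round trip. Units are mm.
#'
#' @param path NIfTI file path (.nii or .nii.gz).
#' @return \code{read_volume}: a \code{volume3d}.
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    pwv_error("aortapwv_missing_file", "no such file: %s", path)
  img <- RNifti::readNifti(path)
  S <- unclass(RNifti::xform(img))
  attributes(S) <- list(dim = dim(S))
  spacing <- sqrt(colSums(S[1:3, 1:3]^2))
  if (any(spacing <= 0))
    pwv_error("aortapwv_missing_geometry",
              "degenerate voxel spacing in %s", path)
  direction <- sweep(S[1:3, 1:3], 2, spacing, "/")
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  if (length(dim(arr)) == 2) dim(arr) <- c(dim(arr), 1L)
  volume3d(arr, spacing, S[1:3, 4], direction)
}

#' @rdname read_volume
#' @param vol a \code{volume3d}.
#' @export
write_volume <- function(vol, path) {
  S <- rbind(cbind(vol$direction %*% diag(vol$spacing), vol$origin),
             c(0, 0, 0, 1))
  img <- RNifti::asNifti(vol$data, datatype = "double")
  img <- RNifti::`sform<-`(img, structure(S, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read and write a velocity-encoded cine series
#'
#' A VE series is stored as paired magnitude/phase NIfTI stacks
#' (\code{x, y, time}) plus a JSON sidecar carrying what NIfTI cannot:
#' trigger times (ms), VENC (cm/s), the phase dialect and the slice
#' geometry (origin plus in-plane row/column directions, i.e. a 3-point
#' plane definition).
#'
#' @param prefix file prefix; \code{<prefix>_mag.nii.gz},
#'   \code{<prefix>_phase.nii.gz} and \code{<prefix>.json} are used.
#' @return \code{read_ve}: a \code{ve_series}.
#' @export
read_ve <- function(prefix) {
  side <- paste0(prefix, ".json")
  if (!file.exists(side))
    pwv_error("aortapwv_missing_file", "no sidecar: %s", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  need <- c("trigger_times_ms", "venc_cm_s", "origin", "row_dir", "col_dir",
            "pixel_mm")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    pwv_error("aortapwv_missing_geometry",
              "VE sidecar is missing fields: %s", paste(miss, collapse = ", "))
  mag <- as.array(RNifti::readNifti(paste0(prefix, "_mag.nii.gz")))
  phs <- as.array(RNifti::readNifti(paste0(prefix, "_phase.nii.gz")))
  attributes(mag) <- list(dim = dim(mag))
  attributes(phs) <- list(dim = dim(phs))
  if (!all(dim(mag) == dim(phs)))
    pwv_error("aortapwv_bad_series", "magnitude and phase shapes differ")
  structure(list(magnitude = mag, phase = phs,
                 time_ms = as.numeric(meta$trigger_times_ms),
                 venc_cm_s = meta$venc_cm_s,
                 pixel_mm = as.numeric(meta$pixel_mm),
                 origin = as.numeric(meta$origin),
                 row_dir = as.numeric(meta$row_dir),
                 col_dir = as.numeric(meta$col_dir),
                 dialect = if (is.null(meta$dialect)) "radians" else meta$dialect),
            class = "ve_series")
}

#' @rdname read_ve
#' @param ve a \code{ve_series}.
#' @export
write_ve <- function(ve, prefix) {
  wr <- function(arr, path) {
    img <- RNifti::asNifti(arr, datatype = "double")
    RNifti::writeNifti(img, path)
  }
  wr(ve$magnitude, paste0(prefix, "_mag.nii.gz"))
  wr(ve$phase, paste0(prefix, "_phase.nii.gz"))
  jsonlite::write_json(
    list(trigger_times_ms = ve$time_ms, venc_cm_s = ve$venc_cm_s,
         pixel_mm = ve$pixel_mm, origin = ve$origin, row_dir = ve$row_dir,
         col_dir = ve$col_dir, dialect = ve$dialect),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Write a phantom study to disk
#'
#' Writes the subject volume and label as NIfTI, every atlas pair, the VE
#' series (paired NIfTI + sidecar) and the ground truth as JSON, so the CLI
#' pipeline can run against files exactly as it would on real exports.
#'
#' @param study output of \code{make_phantom_study()}.
#' @param dir output directory (created if needed).
#' @return the manifest path (a JSON listing of every written file).
#' @export
write_phantom_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  at_dir <- file.path(dir, "atlas")
  dir.create(at_dir, showWarnings = FALSE)
  write_volume(study$subject, file.path(dir, "subject.nii.gz"))
  write_volume(study$label, file.path(dir, "subject_label.nii.gz"))
  for (i in seq_along(study$atlases)) {
    write_volume(study$atlases[[i]]$volume,
                 file.path(at_dir, sprintf("atlas%02d.nii.gz", i)))
    write_volume(study$atlases[[i]]$label,
                 file.path(at_dir, sprintf("atlas%02d_label.nii.gz", i)))
  }
  write_ve(study$ve, file.path(dir, "ve"))
  tr <- study$truth
  jsonlite::write_json(
    list(L_true_mm = tr$L_true_mm, dt_ms = tr$dt_ms, pwv_m_s = tr$pwv_m_s,
         t_asc_ms = tr$t_asc_ms, t_desc_ms = tr$t_desc_ms,
         plane_normal = tr$plane$normal, plane_d = tr$plane$d,
         seeds_mm = tr$seeds),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  manifest <- list(
    volume = "subject.nii.gz",
    ve_prefix = "ve",
    atlas_dir = "atlas",
    truth = "truth.json")
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE)
  mpath
}

#' Read the inputs listed in a subject manifest
#'
#' The manifest is an explicit JSON listing (paths relative to its own
#' directory) of the subject volume, the VE prefix and the atlas directory
#' — replacing site-specific scan-folder naming conventions.
#'
#' @param path manifest JSON path.
#' @return list(subject, ve, atlases).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path))
    pwv_error("aortapwv_missing_file", "no such manifest: %s", path)
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  root <- dirname(path)
  subject <- read_volume(file.path(root, m$volume))
  ve <- read_ve(file.path(root, m$ve_prefix))
  at_dir <- file.path(root, m$atlas_dir)
  vols <- sort(list.files(at_dir, pattern = "^atlas[0-9]+\\.nii(\\.gz)?$",
                          full.names = TRUE))
  if (length(vols) == 0)
    pwv_error("aortapwv_missing_file", "no atlas volumes in %s", at_dir)
  atlases <- lapply(vols, function(v) {
    lab <- sub("\\.nii(\\.gz)?$", "_label.nii\\1", v)
    list(volume = read_volume(v), label = read_volume(lab))
  })
  list(subject = subject, ve = ve, atlases = atlases)
}
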