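#' Pipeline configuration
#'
#' All tunable settings of the automatic PWV pipeline in one serialisable
#' list. Defaults follow the published protocol where it states them: 512
#' affine / 2048 B-spline iterations (per resolution level), 15 mm B-spline
#' control grid, reference cardiac phase 30, 19 m/s high-PWV threshold; the
#' remaining values (sampling counts, contour penalties) are this package's
#' documented choices.
#'
#' @param ... named overrides of the defaults.
#' @return a named list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    affine_iterations = 512L,
    bspline_iterations = 2048L,
    grid_spacing_mm = 15,
    n_samples = 2048L,
    bins = 32L,
    n_rays = 64L,
    max_radius_mm = 25,
    radius_step_px = 0.5,
    lambda_s = 1.0,
    lambda_t = 0.5,
    ref_phase = 30L,
    methods = c("foot_to_foot", "half_max", "cross_correlation"),
    max_lag_ms = 100,
    high_pwv_m_s = 19
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  structure(modifyList(cfg, over), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path JSON file to read or write.
#' @export
read_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, vals)
}

#' @rdname pipeline_config
#' @param cfg a \code{pipeline_config}.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

stage_ok <- function(value) list(status = "ok", value = value, error = NULL)
stage_failed <- function(e) list(status = "failed", value = NULL,
                                 error = conditionMessage(e))

#' Run the full automatic PWV pipeline on one subject
#'
#' Chains the three stages with no intermediate interaction: (i) multi-atlas
#' segmentation of the arch and centerline length measurement, (ii) VE
#' contour detection/propagation and flow-curve extraction, (iii) transit
#' time by each configured method and PWV = L / dt. A failing stage is
#' recorded in the report with its reason and all downstream quantities are
#' left absent — never fabricated. Deterministic given the config seed.
#'
#' @param subject \code{volume3d} multi-slice scan of the subject.
#' @param ve \code{ve_series} of the subject.
#' @param atlases list of list(volume, label) atlas pairs.
#' @param config a \code{pipeline_config}.
#' @return a \code{subject_report}: nested list with per-stage status,
#'   \code{length_mm}, per-method \code{ta1_ms}/\code{ta2_ms}/\code{dt_ms}/
#'   \code{pwv_m_s} and flags.
#' @export
run_all <- function(subject, ve, atlases, config = pipeline_config()) {
  report <- list(config = unclass(config), stages = list())

  seg <- tryCatch({
    labels <- lapply(seq_along(atlases), function(i) {
      ch <- register_atlas(subject, atlases[[i]],
                           seed = config$seed + 17L * i,
                           iterations = c(config$affine_iterations,
                                          config$bspline_iterations),
                           grid_spacing_mm = config$grid_spacing_mm,
                           n_samples = config$n_samples)
      transform_label(atlases[[i]]$label, ch, subject)
    })
    stage_ok(fuse_labels(labels))
  }, error = stage_failed)
  report$stages$segmentation <- seg["status"]
  report$stages$segmentation$error <- seg$error

  cl <- if (seg$status == "ok") tryCatch({
    mask <- regularize_mask(seg$value)
    skel <- skeletonize_3d(mask)
    path <- prune_to_path(skel)
    ctr <- label_centroid(mask)
    plane <- ve_plane_from_series(ve, above_point = ctr)
    clipped <- clip_and_measure(path, plane)
    stage_ok(list(clipped = clipped))
  }, error = stage_failed) else
    list(status = "skipped", value = NULL, error = "segmentation failed")
  report$stages$centerline <- cl["status"]
  report$stages$centerline$error <- cl$error
  if (cl$status == "ok")
    report$length_mm <- cl$value$clipped$length_mm

  fl <- if (cl$status == "ok") tryCatch({
    seeds_px <- project_seeds(cl$value$clipped$seeds, ve)
    contours <- propagate_contours(ve, seeds_px,
                                   ref_index = config$ref_phase,
                                   n_rays = config$n_rays,
                                   max_radius_mm = config$max_radius_mm,
                                   radius_step_px = config$radius_step_px,
                                   lambda_s = config$lambda_s,
                                   lambda_t = config$lambda_t)
    stage_ok(flow_curves(ve, contours))
  }, error = stage_failed) else
    list(status = "skipped", value = NULL, error = "centerline failed")
  report$stages$flow <- fl["status"]
  report$stages$flow$error <- fl$error

  if (fl$status == "ok") {
    asc <- preprocess_curve(fl$value[[1]])
    desc <- preprocess_curve(fl$value[[2]])
    report$methods <- list()
    for (m in config$methods) {
      res <- tryCatch({
        tr <- switch(m,
          foot_to_foot = foot_to_foot(asc, desc),
          half_max = half_max(asc, desc),
          cross_correlation = cross_correlation(asc, desc,
                                                config$max_lag_ms),
          stop("unknown method: ", m))
        pw <- compute_pwv(report$length_mm, tr, config$high_pwv_m_s)
        list(status = "ok", ta1_ms = tr$ta1_ms, ta2_ms = tr$ta2_ms,
             dt_ms = tr$dt_ms, pwv_m_s = pw$pwv_m_s,
             high_pwv = pw$high_pwv)
      }, error = function(e) list(status = "failed",
                                  error = conditionMessage(e)))
      report$methods[[m]] <- res
    }
  }

  report$intermediates <- list(
    mask = if (seg$status == "ok") seg$value else NULL,
    centerline = if (cl$status == "ok") cl$value$clipped else NULL,
    curves = if (fl$status == "ok") fl$value else NULL)
  class(report) <- "subject_report"
  report
}

label_centroid <- function(mask) {
  idx <- which(mask$data > 0)
  d <- vol_dim(mask)
  ijk <- cbind((idx - 1) %% d[1],
               ((idx - 1) %/% d[1]) %% d[2],
               (idx - 1) %/% (d[1] * d[2]))
  colMeans(voxel_to_world(mask, ijk))
}

#' @export
print.subject_report <- function(x, ...) {
  cat("<subject_report>\n")
  for (s in names(x$stages))
    cat(sprintf("  %-13s %s%s\n", s, x$stages[[s]]$status,
                if (!is.null(x$stages[[s]]$error))
                  paste0(" (", x$stages[[s]]$error, ")") else ""))
  if (!is.null(x$length_mm))
    cat(sprintf("  length_mm     %.1f\n", x$length_mm))
  for (m in names(x$methods)) {
    r <- x$methods[[m]]
    if (identical(r$status, "ok"))
      cat(sprintf("  %-17s dt_ms %.2f  pwv_m_s %.2f%s\n", m, r$dt_ms,
                  r$pwv_m_s, if (isTRUE(r$high_pwv)) " [high]" else ""))
    else cat(sprintf("  %-17s failed (%s)\n", m, r$error))
  }
  invisible(x)
}

#' Write a subject report as JSON (plus curve CSV)
#'
#' Numeric keys carry their units in the name (\code{length_mm},
#' \code{dt_ms}, \code{pwv_m_s}). Intermediates (mask, centerline, curves)
#' are written alongside when present.
#'
#' @param report a \code{subject_report} from \code{run_all()}.
#' @param dir output directory.
#' @return the report JSON path.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- list(stages = report$stages,
              length_mm = report$length_mm,
              methods = report$methods,
              config = report$config)
  path <- file.path(dir, "report.json")
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = 10,
                       null = "null", pretty = TRUE)
  if (!is.null(report$intermediates$mask))
    write_volume(report$intermediates$mask, file.path(dir, "mask.nii.gz"))
  if (!is.null(report$intermediates$centerline))
    write.csv(setNames(as.data.frame(report$intermediates$centerline$points),
                       c("x_mm", "y_mm", "z_mm")),
              file.path(dir, "centerline.csv"), row.names = FALSE)
  if (!is.null(report$intermediates$curves)) {
    cu <- report$intermediates$curves
    write.csv(data.frame(time_ms = cu[[1]]$time_ms,
                         v_roi1_cm_s = cu[[1]]$v_cm_s,
                         v_roi2_cm_s = cu[[2]]$v_cm_s),
              file.path(dir, "curves.csv"), row.names = FALSE)
  }
  path
}
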