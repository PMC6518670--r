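#' 3D scalar volume with world-coordinate mapping
#'
#' A voxel grid plus the geometry needed to map 0-based voxel indices
#' \code{(i,j,k)} to world coordinates in millimetres:
#' \code{world = origin + direction \%*\% (spacing * c(i,j,k))}.
#' This is the container used for the multi-slice 3D scans, atlas labels and
#' fused segmentations throughout the package.
#'
#' @param data numeric 3D array of voxel values.
#' @param spacing voxel spacing in mm, length 3, all positive.
#' @param origin world position (mm) of voxel (0,0,0), length 3.
#' @param direction 3x3 orthonormal direction-cosine matrix.
#' @return An object of class \code{volume3d}.
#' @export
volume3d <- function(data, spacing, origin = c(0, 0, 0), direction = diag(3)) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive numbers (mm)")
  if (length(origin) != 3L) stop("`origin` must have length 3")
  direction <- as.matrix(direction)
  if (!all(dim(direction) == c(3L, 3L)) ||
      max(abs(crossprod(direction) - diag(3))) > 1e-6)
    stop("`direction` must be a 3x3 orthonormal matrix")
  structure(list(data = data, spacing = spacing, origin = origin,
                 direction = direction),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume3d> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x ")))
  cat(sprintf("  origin (%s) mm, value range [%.4g, %.4g]\n",
              paste(signif(x$origin, 4), collapse = ", "),
              min(x$data), max(x$data)))
  invisible(x)
}

vol_dim <- function(vol) dim(vol$data)

#' Map 0-based voxel indices to world coordinates
#'
#' @param vol a \code{volume3d}.
#' @param ijk numeric matrix (n x 3) of 0-based voxel indices (may be
#'   fractional) or a length-3 vector.
#' @return n x 3 matrix of world coordinates in mm.
#' @export
voxel_to_world <- function(vol, ijk) {
  ijk <- rbind_pts(ijk)
  sweep(ijk %*% diag(vol$spacing) %*% t(vol$direction), 2, vol$origin, "+")
}

#' Map world coordinates to (continuous, 0-based) voxel indices
#'
#' @inheritParams voxel_to_world
#' @param pts n x 3 matrix of world points (mm) or a length-3 vector.
#' @export
world_to_voxel <- function(vol, pts) {
  pts <- rbind_pts(pts)
  q <- sweep(pts, 2, vol$origin, "-") %*% vol$direction  # t(inv) = direction
  sweep(q, 2, vol$spacing, "/")
}

rbind_pts <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3)
  storage.mode(p) <- "double"
  p
}

#' Sample a volume at world points (trilinear interpolation)
#'
#' @param vol a \code{volume3d}.
#' @param pts n x 3 world points (mm).
#' @return numeric vector; \code{NA} where a point falls outside the grid.
#' @export
sample_volume <- function(vol, pts) {
  pts <- rbind_pts(pts)
  cpp_sample_points(as.numeric(vol$data), dim(vol$data), vol$spacing,
                    vol$origin, vol$direction, pts)
}

# Gaussian smoothing (sigma in voxel units per axis)
smooth_volume <- function(vol, sigma_vox) {
  d <- dim(vol$data)
  out <- cpp_smooth3d(as.numeric(vol$data), d, as.numeric(sigma_vox))
  vol$data <- array(out, d)
  vol
}

# Integer-stride downsampling (first voxel kept, origin unchanged)
downsample_volume <- function(vol, factor) {
  d <- dim(vol$data)
  idx <- lapply(1:3, function(a) seq(1L, d[a], by = as.integer(factor[a])))
  vol$data <- vol$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  vol$spacing <- vol$spacing * factor
  vol
}

# smoothing + strided decimation, used by the registration pyramid
pyramid_level <- function(vol, factor) {
  if (all(factor == 1)) return(vol)
  sig <- ifelse(factor > 1, factor / 2, 0)
  downsample_volume(smooth_volume(vol, sig), factor)
}

#' Dice overlap of two binary volumes on a common grid
#'
#' @param a,b binary \code{volume3d} objects (or 3D arrays) on the same grid.
#' @return Dice coefficient in [0, 1].
#' @export
label_dice <- function(a, b) {
  da <- if (inherits(a, "volume3d")) a$data else a
  db <- if (inherits(b, "volume3d")) b$data else b
  stopifnot(all(dim(da) == dim(db)))
  da <- da > 0; db <- db > 0
  denom <- sum(da) + sum(db)
  if (denom == 0) return(1)
  2 * sum(da & db) / denom
}

largest_component <- function(binary_array, connectivity = 26L) {
  d <- dim(binary_array)
  lab <- cpp_label_cc(as.integer(binary_array > 0), d, connectivity)
  if (all(lab == 0L)) return(array(0L, d))
  counts <- tabulate(lab)
  array(as.integer(lab == which.max(counts)), d)
}
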