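#' Skeletonize a binary volume by 3D homotopic thinning
#'
#' Iteratively removes simple points (26-connected foreground, 6-connected
#' background) in six directional sub-iterations until stable, preserving
#' curve endpoints, so a tubular segmentation collapses to a one-voxel-wide
#' centerline with the same topology as the input.
#'
#' Thinning assumes an (approximately) isotropic neighbourhood metric, so
#' anisotropic masks (e.g. 1.76 x 1.76 x 5 mm multi-slice grids) are first
#' resampled to an isotropic grid at the smallest spacing (nearest
#' neighbour); the returned skeleton then lives on that grid. World
#' coordinates are unaffected.
#'
#' @param mask binary \code{volume3d} (non-empty).
#' @param isotropic resample anisotropic masks to isotropic spacing before
#'   thinning (recommended).
#' @return binary \code{volume3d} skeleton (a voxel subset of the mask, on
#'   the possibly resampled grid).
#' @export
skeletonize_3d <- function(mask, isotropic = TRUE) {
  if (!any(mask$data > 0))
    pwv_error("aortapwv_invalid_input", "mask is empty")
  sp <- mask$spacing
  if (isotropic && diff(range(sp)) > 1e-6 * min(sp)) {
    s0 <- min(sp)
    d <- vol_dim(mask)
    nd <- as.integer(pmax(round((d - 1) * sp / s0) + 1, 2))
    target <- volume3d(array(0, nd), rep(s0, 3), mask$origin,
                       mask$direction)
    mask <- resample_volume(mask, identity_chain(), target,
                            interp = "nearest")
    mask$data <- array(as.integer(mask$data > 0), nd)
  }
  out <- mask
  out$data <- array(cpp_thin3d(as.integer(mask$data > 0), vol_dim(mask)),
                    vol_dim(mask))
  out
}

#' Regularise a binary mask before skeletonization
#'
#' Majority-vote segmentations have voxel-bumpy surfaces, and every surface
#' bump seeds a spurious skeleton branch. This resamples the mask to an
#' isotropic grid (smallest spacing), smooths the binary indicator with a
#' Gaussian of \code{sigma_vox} voxels, re-thresholds at 0.5 and keeps the
#' largest 26-connected component, yielding a smooth solid whose skeleton
#' is a clean curve.
#'
#' @param mask binary \code{volume3d}.
#' @param sigma_vox Gaussian SD in (isotropic) voxels.
#' @return binary \code{volume3d} on the isotropic grid.
#' @export
regularize_mask <- function(mask, sigma_vox = 1) {
  sp <- mask$spacing
  if (diff(range(sp)) > 1e-6 * min(sp)) {
    s0 <- min(sp)
    d <- vol_dim(mask)
    nd <- as.integer(pmax(round((d - 1) * sp / s0) + 1, 2))
    target <- volume3d(array(0, nd), rep(s0, 3), mask$origin,
                       mask$direction)
    mask <- resample_volume(mask, identity_chain(), target,
                            interp = "nearest")
  }
  d <- vol_dim(mask)
  sm <- cpp_smooth3d(as.numeric(mask$data > 0), d, rep(sigma_vox, 3))
  mask$data <- largest_component(array(sm >= 0.5, d))
  if (!any(mask$data > 0))
    pwv_error("aortapwv_invalid_input", "mask vanished under regularisation")
  mask
}

#' Prune a skeleton to its longest path
#'
#' Builds the 26-neighbour graph of the skeleton voxels with Euclidean
#' (world-space) edge weights, keeps the largest connected component, and
#' returns the maximum-length shortest path between endpoint pairs (the
#' graph diameter), discarding side branches.
#'
#' A voxel-centre chain zigzags, which inflates polyline length, so the path
#' coordinates are smoothed with a moving average spanning about
#' \code{smooth_mm} of arc (roughly one lumen diameter) before the length is
#' summed; endpoints are kept.
#'
#' @param skeleton binary \code{volume3d} from \code{skeletonize_3d()}.
#' @param smooth_mm physical extent of the staircase-suppression window
#'   (0 disables smoothing).
#' @return ordered world-space point matrix (n x 3 mm) of class
#'   \code{aorta_path}, with the path length in attribute \code{length_mm}.
#' @export
prune_to_path <- function(skeleton, smooth_mm = 18) {
  idx <- which(skeleton$data > 0)
  if (length(idx) == 0)
    pwv_error("aortapwv_invalid_input", "skeleton is empty")
  d <- vol_dim(skeleton)
  ijk <- cbind((idx - 1) %% d[1],
               ((idx - 1) %/% d[1]) %% d[2],
               (idx - 1) %/% (d[1] * d[2]))
  if (length(idx) == 1) {
    pts <- voxel_to_world(skeleton, ijk)
    return(structure(pts, length_mm = 0, class = "aorta_path"))
  }
  key <- idx
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  offs <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & (offs[, 2] > 0 |
           (offs[, 2] == 0 & offs[, 1] > 0))), ]  # half-space: each pair once
  from <- integer(0); to <- integer(0); wt <- numeric(0)
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    nb <- cbind(ijk[, 1] + o[1], ijk[, 2] + o[2], ijk[, 3] + o[3])
    ok <- nb[, 1] >= 0 & nb[, 1] < d[1] & nb[, 2] >= 0 & nb[, 2] < d[2] &
          nb[, 3] >= 0 & nb[, 3] < d[3]
    nkey <- nb[, 1] + 1 + d[1] * (nb[, 2] + d[2] * nb[, 3])
    m <- match(nkey, key)
    hit <- ok & !is.na(m)
    if (!any(hit)) next
    from <- c(from, which(hit))
    to <- c(to, m[hit])
    wt <- c(wt, rep(sqrt(sum((o * skeleton$spacing)^2)), sum(hit)))
  }
  g <- igraph::make_graph(rbind(from, to), n = length(idx), directed = FALSE)
  igraph::E(g)$weight <- wt
  comp <- igraph::components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  sub <- igraph::induced_subgraph(g, keep)
  path_v <- graph_diameter_path(sub)
  sel <- keep[path_v]
  pts <- voxel_to_world(skeleton, ijk[sel, , drop = FALSE])
  pts <- smooth_path(pts, smooth_mm)
  structure(pts, length_mm = polyline_length(pts), class = "aorta_path")
}

# centred moving average over ~smooth_mm of arc; raw endpoints retained
smooth_path <- function(pts, smooth_mm) {
  n <- nrow(pts)
  if (smooth_mm <= 0 || n < 5) return(pts)
  step <- polyline_length(pts) / (n - 1)
  w <- 2L * round(smooth_mm / step / 2) + 1L
  if (w < 3 || n < w) return(pts)
  out <- pts
  for (a in 1:3) out[, a] <- stats::filter(pts[, a], rep(1 / w, w), sides = 2)
  na <- which(is.na(out[, 1]))
  out[na, ] <- pts[na, ]
  out
}

# maximum-length shortest path between endpoint (degree-1) pairs; for
# endpoint-free (cyclic) graphs, a double-sweep farthest-pair fallback
graph_diameter_path <- function(g) {
  deg <- igraph::degree(g)
  ends <- which(deg == 1)
  if (length(ends) >= 2) {
    dm <- igraph::distances(g, v = ends, to = ends)
    dm[!is.finite(dm)] <- -Inf
    best <- arrayInd(which.max(dm), dim(dm))
    from <- ends[best[1]]; to <- ends[best[2]]
  } else {
    d1 <- igraph::distances(g, v = 1)
    from <- which.max(d1)
    d2 <- igraph::distances(g, v = from)
    to <- which.max(d2)
  }
  as.integer(igraph::shortest_paths(g, from, to)$vpath[[1]])
}

#' Cutting plane a x + b y + c z = d
#'
#' @param normal plane normal (will be normalised to unit length).
#' @param d plane offset (mm) for the unit normal.
#' @export
cutting_plane <- function(normal, d) {
  nrm <- sqrt(sum(normal^2))
  if (nrm == 0) stop("`normal` must be non-zero")
  structure(list(normal = normal / nrm, d = d / nrm), class = "cutting_plane")
}

#' @rdname cutting_plane
#' @param p1,p2,p3 three non-collinear points on the plane.
#' @export
plane_from_points <- function(p1, p2, p3) {
  n <- cross3(p2 - p1, p3 - p1)
  if (sqrt(sum(n^2)) < 1e-12) stop("points are collinear")
  n <- normalize3(n)
  cutting_plane(n, sum(n * p1))
}

#' Cutting plane of a VE series
#'
#' The plane of the velocity-encoded slice: normal = through-plane direction,
#' offset = normal dot slice origin. The normal is oriented so that
#' \code{above_point} (typically the arch apex or segmentation centroid)
#' satisfies \code{v . n >= d}, matching the point-retention rule.
#'
#' @param ve a \code{ve_series}.
#' @param above_point optional world point that must lie on the retained side.
#' @return a \code{cutting_plane}.
#' @export
ve_plane_from_series <- function(ve, above_point = NULL) {
  if (is.null(ve$row_dir) || is.null(ve$col_dir) || is.null(ve$origin))
    pwv_error("aortapwv_missing_geometry",
              "VE series has no slice position/orientation")
  n <- normalize3(cross3(ve$row_dir, ve$col_dir))
  d <- sum(n * ve$origin)
  if (!is.null(above_point) && sum(above_point * n) < d) {
    n <- -n; d <- -d
  }
  cutting_plane(n, d)
}

#' Clip a centerline at the VE plane and measure the arch length
#'
#' Retains the path points on the arch side of the plane
#' (\code{v . n >= d}), appends the two exact plane-intersection points on
#' the crossing segments, and returns the arc length between the
#' intersections together with the intersections as seed points for the VE
#' contour detection. A plane below the whole path returns the full path
#' with its endpoints as seeds; any other crossing count than two is a
#' topology error.
#'
#' @param path \code{aorta_path} (or n x 3 point matrix) from
#'   \code{prune_to_path()}.
#' @param plane a \code{cutting_plane}.
#' @return object of class \code{centerline_path}: list(points, length_mm,
#'   seeds) where seeds is a 2 x 3 matrix ordered along the path.
#' @export
clip_and_measure <- function(path, plane) {
  pts <- unclass(path)
  attributes(pts) <- list(dim = dim(pts))
  side <- as.numeric(pts %*% plane$normal) - plane$d
  keep <- side >= 0
  cross <- which(diff(keep) != 0)
  if (length(cross) == 0 && all(keep)) {
    return(structure(list(points = pts, length_mm = polyline_length(pts),
                          seeds = pts[c(1, nrow(pts)), , drop = FALSE]),
                     class = "centerline_path"))
  }
  if (length(cross) != 2)
    pwv_error("aortapwv_topology",
              "centerline crosses the VE plane %d times (need exactly 2)",
              length(cross))
  inter <- t(vapply(cross, function(i) {
    f <- side[i] / (side[i] - side[i + 1])
    pts[i, ] + f * (pts[i + 1, ] - pts[i, ])
  }, numeric(3)))
  mid <- (cross[1] + 1):cross[2]
  if (!all(keep[mid]))
    pwv_error("aortapwv_topology",
              "retained centerline segment is not contiguous")
  chain <- rbind(inter[1, ], pts[mid, , drop = FALSE], inter[2, ])
  structure(list(points = chain, length_mm = polyline_length(chain),
                 seeds = inter),
            class = "centerline_path")
}

#' @export
print.centerline_path <- function(x, ...) {
  cat(sprintf("<centerline_path> %d points, length %.1f mm\n",
              nrow(x$points), x$length_mm))
  invisible(x)
}

#' Project world seed points onto VE pixel coordinates
#'
#' Maps world points lying on the VE plane to continuous 0-based pixel
#' coordinates of the series via its slice geometry.
#'
#' @param seeds n x 3 world points (mm).
#' @param ve a \code{ve_series}.
#' @return n x 2 matrix of (px, py) pixel coordinates.
#' @export
project_seeds <- function(seeds, ve) {
  seeds <- rbind_pts(seeds)
  q <- sweep(seeds, 2, ve$origin, "-")
  px <- as.numeric(q %*% ve$row_dir) / ve$pixel_mm[1]
  py <- as.numeric(q %*% ve$col_dir) / ve$pixel_mm[2]
  d <- dim(ve$magnitude)
  eps <- 1e-6
  if (any(px < -eps | px > d[1] - 1 + eps | py < -eps | py > d[2] - 1 + eps))
    pwv_error("aortapwv_outside_fov",
              "seed point falls outside the VE field of view")
  cbind(px = px, py = py)
}
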