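#' Transform chains
#'
#' Spatial transforms are stored as ordered chains of stages; applying a chain
#' maps a point through every stage in order (stage k initialises stage k+1,
#' mirroring the three-stage registration recipe). A stage is either a world
#' affine (homogeneous 4x4 matrix) or a cubic B-spline free-form deformation
#' (displacement field over a control-point grid, added to the point).
#' Chains map subject (fixed) world coordinates into atlas (moving) world
#' coordinates, so atlas labels can be pulled back onto the subject grid.
#'
#' @param stages list of stages created by \code{affine_stage()} or
#'   \code{bspline_stage()}.
#' @return object of class \code{transform_chain}.
#' @export
transform_chain <- function(stages = list()) {
  for (s in stages)
    if (!inherits(s, c("affine_stage", "bspline_stage")))
      stop("stages must be affine_stage or bspline_stage objects")
  structure(list(stages = stages), class = "transform_chain")
}

#' @rdname transform_chain
#' @export
identity_chain <- function() transform_chain()

#' @rdname transform_chain
#' @param matrix homogeneous 4x4 affine matrix acting on world coordinates.
#' @export
affine_stage <- function(matrix) {
  matrix <- as.matrix(matrix)
  stopifnot(all(dim(matrix) == c(4, 4)))
  structure(list(matrix = matrix), class = "affine_stage")
}

#' @rdname transform_chain
#' @param origin,spacing,dims geometry of the control-point grid (mm / counts).
#' @param coef 4D coefficient array \code{[dims, 3]} of control-point
#'   displacements in mm.
#' @export
bspline_stage <- function(origin, spacing, dims, coef) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3, all(dim(coef) == c(dims, 3L)))
  structure(list(origin = as.numeric(origin), spacing = as.numeric(spacing),
                 dims = dims, coef = coef),
            class = "bspline_stage")
}

#' @export
print.transform_chain <- function(x, ...) {
  kinds <- vapply(x$stages, function(s)
    if (inherits(s, "affine_stage")) "affine" else "bspline", "")
  cat(sprintf("<transform_chain> %d stage(s)%s\n", length(kinds),
              if (length(kinds)) paste0(": ", paste(kinds, collapse = " -> "))
              else " (identity)"))
  invisible(x)
}

#' Apply a transform chain to world points
#'
#' @param chain a \code{transform_chain}.
#' @param pts n x 3 matrix of world points (mm), or length-3 vector.
#' @return n x 3 matrix of mapped points.
#' @export
apply_transform <- function(chain, pts) {
  pts <- rbind_pts(pts)
  for (s in chain$stages) {
    if (inherits(s, "affine_stage")) {
      h <- cbind(pts, 1) %*% t(s$matrix)
      pts <- h[, 1:3, drop = FALSE]
    } else {
      pts <- pts + cpp_bspline_disp(unclass(s), pts)
    }
  }
  pts
}

# Collapse a chain into the (affine 4x4, optional trailing B-spline) form the
# C++ resampler consumes. Chains produced by register_atlas() always fit.
chain_for_cpp <- function(chain) {
  A <- diag(4)
  bs <- NULL
  for (s in chain$stages) {
    if (inherits(s, "affine_stage")) {
      if (!is.null(bs))
        stop("unsupported chain layout: affine stage after a B-spline stage")
      A <- s$matrix %*% A
    } else {
      if (!is.null(bs))
        stop("unsupported chain layout: multiple B-spline stages")
      bs <- unclass(s)
    }
  }
  list(affine = A, bspline = bs)
}

#' Elementary world affines
#'
#' Convenience constructors for homogeneous 4x4 world transforms:
#' a pure translation (mm) and a rigid rotation (degrees) about a world
#' axis through \code{center}. Useful for building known ground-truth
#' poses in simulation studies.
#'
#' @param t translation vector (mm), length 3.
#' @return 4x4 homogeneous matrix for use with \code{affine_stage()}.
#' @export
translation_matrix <- function(t) {
  m <- diag(4); m[1:3, 4] <- t; m
}

#' @rdname translation_matrix
#' @param axis rotation axis, one of \code{"x"}, \code{"y"}, \code{"z"}.
#' @param degrees rotation angle in degrees.
#' @param center world point the axis passes through (mm).
#' @export
rotation_matrix <- function(axis = c("x", "y", "z"), degrees,
                            center = c(0, 0, 0)) {
  axis <- match.arg(axis)
  th <- degrees * pi / 180
  R <- switch(axis,
    x = rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th))),
    y = rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th))),
    z = rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1)))
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- center - R %*% center
  m
}
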