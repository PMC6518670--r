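#' Detect a vessel contour on a magnitude frame
#'
#' Casts \code{n_rays} evenly spaced radial scan lines of fixed length from
#' the seed point, computes the edge response as the negative radial
#' intensity derivative (bright lumen against darker wall), and finds the
#' exact minimum-cost closed contour over the (angle x radius) graph with a
#' smoothness penalty on radius jumps between adjacent rays.
#'
#' @param frame magnitude image (matrix, \code{[x, y]} indexing).
#' @param seed_px seed (px, py) in continuous 0-based pixel coordinates,
#'   inside the frame.
#' @param n_rays number of radial scan lines (>= 16).
#' @param max_radius_mm scan-line length in mm.
#' @param pixel_mm in-plane pixel size (mm).
#' @param radius_step_px radial sampling step in pixels.
#' @param lambda_s smoothness penalty, in units of normalised edge response
#'   per pixel of radius change between adjacent rays.
#' @param extra_cost optional matrix (n_rays x n_radii) added to the cost,
#'   used by the temporal propagation.
#' @return object of class \code{vessel_contour}: closed polygon
#'   (\code{$polygon}, n_rays x 2 pixel coordinates), radii per angle
#'   (\code{$radius_px}) and the ray angles.
#' @export
detect_contour <- function(frame, seed_px, n_rays = 64, max_radius_mm = 25,
                           pixel_mm = 1.25, radius_step_px = 0.5,
                           lambda_s = 1.0, extra_cost = NULL) {
  d <- dim(frame)
  if (n_rays < 16) stop("`n_rays` must be >= 16")
  if (any(seed_px < 0) || seed_px[1] > d[1] - 1 || seed_px[2] > d[2] - 1)
    stop("seed point outside the frame")
  radii <- seq(1, max_radius_mm / pixel_mm, by = radius_step_px)
  angles <- 2 * pi * (seq_len(n_rays) - 1) / n_rays
  gx <- outer(cos(angles), radii) + seed_px[1]
  gy <- outer(sin(angles), radii) + seed_px[2]
  prof <- matrix(bilinear_sample(frame, as.numeric(gx), as.numeric(gy)),
                 n_rays)
  # edge response: negative d(intensity)/d(radius), bright -> dark
  edge <- -t(apply(prof, 1, function(p) c(diff(p) / radius_step_px, 0)))
  dyn <- diff(range(frame))
  if (dyn <= 0 || max(edge) < 1e-3 * dyn)
    pwv_error("aortapwv_no_vessel",
              "no vessel edge found around the seed point")
  cost <- -edge / max(edge)
  if (!is.null(extra_cost)) cost <- cost + extra_cost
  ridx <- cpp_contour_dp(cost, lambda_s * radius_step_px, 2L) + 1L
  r <- radii[ridx]
  structure(list(polygon = cbind(seed_px[1] + r * cos(angles),
                                 seed_px[2] + r * sin(angles)),
                 radius_px = r, angles = angles, seed_px = seed_px,
                 radii_grid = radii),
            class = "vessel_contour")
}

# polygon area centroid (unbiased for a circle sampled from an offset seed,
# unlike the vertex mean, so the propagated seed does not drift)
poly_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-9) return(colMeans(poly))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# bilinear interpolation on a matrix at continuous 0-based (x, y), clamped
bilinear_sample <- function(m, x, y) {
  d <- dim(m)
  x <- pmin(pmax(x, 0), d[1] - 1)
  y <- pmin(pmax(y, 0), d[2] - 1)
  x0 <- pmin(floor(x), d[1] - 2); x0 <- pmax(x0, 0)
  y0 <- pmin(floor(y), d[2] - 2); y0 <- pmax(y0, 0)
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(x0 + 1, y0 + 1); i10 <- cbind(x0 + 2, y0 + 1)
  i01 <- cbind(x0 + 1, y0 + 2); i11 <- cbind(x0 + 2, y0 + 2)
  m[i00] * (1 - fx) * (1 - fy) + m[i10] * fx * (1 - fy) +
    m[i01] * (1 - fx) * fy + m[i11] * fx * fy
}

#' Propagate vessel contours over all cardiac phases
#'
#' Detects the reference contour for each region of interest at the reference
#' phase (default timepoint 30, near peak flow), then solves the contour on
#' every other phase outward in both temporal directions, adding a temporal
#' continuity penalty \code{lambda_t} on the radius difference from the
#' neighbouring phase's contour. The polar origin (seed) is held fixed per
#' ROI across phases, so the (angle x radius) grid — and with it the
#' temporal penalty — is common to the whole series.
#'
#' @param series a \code{ve_series}.
#' @param seeds_px 2 x 2 matrix of seed pixel coordinates (one row per ROI).
#' @param ref_index reference phase (1-based), clamped to the series length.
#' @param lambda_t temporal continuity penalty, normalised edge response per
#'   pixel of radius change between adjacent phases.
#' @inheritParams detect_contour
#' @return list of two elements (ROI 1, ROI 2), each a list of
#'   \code{vessel_contour} objects, one per phase.
#' @export
propagate_contours <- function(series, seeds_px, ref_index = 30,
                               n_rays = 64, max_radius_mm = 25,
                               radius_step_px = 0.5, lambda_s = 1.0,
                               lambda_t = 0.5) {
  nT <- dim(series$magnitude)[3]
  ref <- min(max(1L, as.integer(ref_index)), nT)
  px <- series$pixel_mm[1]
  detect1 <- function(t, seed, prev = NULL) {
    extra <- NULL
    if (!is.null(prev)) {
      # |radius - previous radius| penalty per ray
      extra <- lambda_t * abs(outer(prev$radius_px, prev$radii_grid,
                                    function(a, b) b - a))
    }
    tryCatch(
      detect_contour(series$magnitude[, , t], seed, n_rays = n_rays,
                     max_radius_mm = max_radius_mm, pixel_mm = px,
                     radius_step_px = radius_step_px, lambda_s = lambda_s,
                     extra_cost = extra),
      aortapwv_no_vessel = function(e)
        pwv_error("aortapwv_no_vessel",
                  "phase %d: %s", t, conditionMessage(e)))
  }
  lapply(1:2, function(roi) {
    out <- vector("list", nT)
    out[[ref]] <- detect1(ref, seeds_px[roi, ])
    if (ref < nT) for (t in (ref + 1):nT)
      out[[t]] <- detect1(t, seeds_px[roi, ], out[[t - 1]])
    if (ref > 1) for (t in (ref - 1):1)
      out[[t]] <- detect1(t, seeds_px[roi, ], out[[t + 1]])
    out
  })
}

#' Convert a phase image to a velocity map
#'
#' Linear phase-to-velocity mapping of through-plane velocity encoding:
#' in the \code{"radians"} dialect a phase of pi corresponds to +VENC; in
#' the \code{"scaled"} dialect the stored integer full scale corresponds to
#' +/- VENC.
#'
#' @param phase phase image (matrix or array).
#' @param venc_cm_s velocity-encoding limit in cm/s.
#' @param dialect \code{"radians"} or \code{"scaled"}.
#' @param full_scale full-scale stored value for the scaled dialect.
#' @return velocity map in cm/s, same shape as \code{phase}.
#' @export
velocity_from_phase <- function(phase, venc_cm_s, dialect = "radians",
                                full_scale = 4096) {
  switch(dialect,
    radians = phase / pi * venc_cm_s,
    scaled = phase / full_scale * venc_cm_s,
    pwv_error("aortapwv_bad_dialect", "unknown phase dialect '%s'", dialect))
}

#' Mean-velocity flow curves from propagated contours
#'
#' For every cardiac phase, averages the velocity map over the pixels whose
#' centres fall inside the contour polygon (even-odd rule). ROI 1 is
#' assigned to the curve with a positive systolic peak (ascending aorta),
#' ROI 2 to the other (descending).
#'
#' @param series a \code{ve_series}.
#' @param contours output of \code{propagate_contours()}.
#' @return list of two \code{flow_curve} objects (ROI 1 = ascending).
#' @export
flow_curves <- function(series, contours) {
  nT <- dim(series$phase)[3]
  curves <- lapply(contours, function(ctr) {
    stopifnot(length(ctr) == nT)
    v <- vapply(seq_len(nT), function(t) {
      vm <- velocity_from_phase(series$phase[, , t], series$venc_cm_s,
                                series$dialect)
      inside <- pixels_in_polygon(ctr[[t]]$polygon, dim(vm))
      if (nrow(inside) == 0)
        pwv_error("aortapwv_degenerate_contour",
                  "phase %d: contour encloses no pixel centres", t)
      mean(vm[inside])
    }, numeric(1))
    v
  })
  peak_sign <- vapply(curves, function(v) sign(v[which.max(abs(v))]), 0)
  ord <- if (peak_sign[1] >= 0) 1:2 else 2:1
  list(flow_curve(series$time_ms, curves[[ord[1]]], roi = 1L),
       flow_curve(series$time_ms, curves[[ord[2]]], roi = 2L))
}

# 1-based index matrix of pixels whose centres (0-based integer coords) lie
# inside the polygon, even-odd rule; boundary ties resolve toward lower index
pixels_in_polygon <- function(poly, dims) {
  xr <- floor(range(poly[, 1])); yr <- floor(range(poly[, 2]))
  xs <- max(0, xr[1]):min(dims[1] - 1, xr[2] + 1)
  ys <- max(0, yr[1]):min(dims[2] - 1, yr[2] + 1)
  if (length(xs) == 0 || length(ys) == 0)
    return(matrix(integer(0), 0, 2))
  px <- rep(xs, times = length(ys))
  py <- rep(ys, each = length(xs))
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  cbind(px[inside] + 1L, py[inside] + 1L)
}
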