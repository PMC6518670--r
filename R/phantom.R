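#' Synthetic aortic-arch centerline curve
#'
#' Builds a "candy-cane" aorta: a semicircular arch of radius
#' \code{arch_radius_mm} in the x-y plane joined to two straight limbs
#' (ascending at x = +R, descending at x = -R) running along -y, optionally
#' tilted about the y axis so the arch leaves the in-plane slice direction,
#' and optionally perturbed by a smooth seeded displacement. The unperturbed
#' arc length has the closed form \code{pi * R + limb1 + limb2}; perturbed
#' curves store the arc length of a dense (1e4-point) polyline.
#'
#' @param arch_radius_mm arch radius R in mm (must exceed the tube radius the
#'   curve will be rasterised with).
#' @param limb_mm lengths of the ascending and descending limbs in mm
#'   (length 2, non-negative).
#' @param tilt_deg tilt of the arch plane about the limb (y) axis, degrees.
#' @param tube_radius_mm lumen radius the curve is intended for; only used to
#'   validate \code{arch_radius_mm > tube_radius_mm}.
#' @param perturb_mm amplitude scale (mm) of the smooth random perturbation;
#'   0 disables it.
#' @param seed integer seed making the perturbation reproducible.
#' @param n_points number of sampled points stored on the curve (>= 1000).
#' @return object of class \code{aorta_curve}: ordered world-space points
#'   (n x 3 mm), \code{arc_length_mm}, and the generating parameters.
#' @export
make_aorta_curve <- function(arch_radius_mm = 45, limb_mm = c(50, 50),
                             tilt_deg = 0, tube_radius_mm = 10,
                             perturb_mm = 0, seed = NULL, n_points = 1000) {
  if (!is.finite(arch_radius_mm) || arch_radius_mm <= 0)
    stop("`arch_radius_mm` must be positive")
  if (arch_radius_mm <= tube_radius_mm)
    stop("`arch_radius_mm` must exceed `tube_radius_mm`")
  if (any(limb_mm < 0) || length(limb_mm) != 2)
    stop("`limb_mm` must be two non-negative lengths")
  if (n_points < 1000) stop("`n_points` must be >= 1000")

  R <- arch_radius_mm
  l1 <- limb_mm[1]; l2 <- limb_mm[2]
  L0 <- l1 + pi * R + l2
  tau <- tilt_deg * pi / 180

  pert <- NULL
  if (perturb_mm > 0) {
    if (!is.null(seed)) set.seed(seed)
    pert <- list(ax = runif(3, -1, 1) * perturb_mm,
                 az = runif(3, -1, 1) * perturb_mm,
                 px = runif(3, 0, 2 * pi), pz = runif(3, 0, 2 * pi))
  }

  fun <- function(s) {
    s <- pmin(pmax(s, 0), L0)
    x <- y <- z <- numeric(length(s))
    a <- s <= l1
    x[a] <- R; y[a] <- s[a] - l1
    b <- s > l1 & s <= l1 + pi * R
    th <- (s[b] - l1) / R
    x[b] <- R * cos(th); y[b] <- R * sin(th)
    c3 <- s > l1 + pi * R
    x[c3] <- -R; y[c3] <- -(s[c3] - l1 - pi * R)
    if (!is.null(pert)) {
      for (h in 1:3) {
        x <- x + pert$ax[h] * sin(pi * h * s / L0 + pert$px[h])
        z <- z + pert$az[h] * sin(pi * h * s / L0 + pert$pz[h])
      }
    }
    cbind(x * cos(tau), y, -x * sin(tau)) +
      cbind(z * sin(tau), 0, z * cos(tau))
  }

  arc_length <- if (is.null(pert)) L0 else polyline_length(fun(seq(0, L0, length.out = 1e4)))

  structure(list(points = fun(seq(0, L0, length.out = n_points)),
                 fun = fun, s_max = L0, arc_length_mm = arc_length,
                 params = list(arch_radius_mm = R, limb_mm = limb_mm,
                               tilt_deg = tilt_deg, perturb_mm = perturb_mm,
                               tube_radius_mm = tube_radius_mm, seed = seed)),
            class = "aorta_curve")
}

polyline_length <- function(pts) {
  sum(sqrt(rowSums(diff(pts)^2)))
}

# rigid pose offset applied to a curve (used when building atlas sets)
shift_curve <- function(curve, translation = c(0, 0, 0), rot_z_deg = 0) {
  M <- rotation_matrix("z", rot_z_deg)[1:3, 1:3]
  base <- curve$fun
  curve$fun <- function(s) sweep(base(s) %*% t(M), 2, translation, "+")
  curve$points <- sweep(curve$points %*% t(M), 2, translation, "+")
  curve
}

#' Ground truth for a phantom study
#'
#' Clips an \code{aorta_curve} at a horizontal VE cutting plane (y = d, normal
#' +y so the arch apex lies on the retained side) and derives the true arch
#' length above the plane, the two plane-crossing seed points, the transit
#' time and the pulse wave velocity. Exactly one of \code{dt_ms} or
#' \code{pwv_m_s} must be given; the other follows from
#' \code{PWV = L / dt} (mm/ms = m/s).
#'
#' @param curve an \code{aorta_curve}.
#' @param plane_y_mm height of the VE cutting plane (must cut both limbs).
#' @param dt_ms true transit time in ms.
#' @param pwv_m_s true pulse wave velocity in m/s.
#' @param t_arrival_ms arrival time (half-max of the upslope) of the systolic
#'   wave at the ascending aorta, ms after the R-wave trigger.
#' @return object of class \code{phantom_truth}.
#' @export
phantom_truth <- function(curve, plane_y_mm = -20, dt_ms = NULL,
                          pwv_m_s = NULL, t_arrival_ms = 120) {
  if (is.null(dt_ms) == is.null(pwv_m_s))
    stop("give exactly one of `dt_ms` or `pwv_m_s`")
  s <- seq(0, curve$s_max, length.out = 2e4)
  pts <- curve$fun(s)
  side <- pts[, 2] - plane_y_mm
  keep <- side >= 0
  cross <- which(diff(keep) != 0)
  if (length(cross) != 2)
    stop(sprintf("curve crosses the VE plane %d times (need exactly 2)",
                 length(cross)))
  # exact-to-dense-sampling intersection points by linear interpolation
  seeds <- t(vapply(cross, function(i) {
    f <- side[i] / (side[i] - side[i + 1])
    pts[i, ] + f * (pts[i + 1, ] - pts[i, ])
  }, numeric(3)))
  inner <- pts[keep, , drop = FALSE]
  L_true <- polyline_length(rbind(seeds[1, ], inner, seeds[2, ]))
  if (is.null(dt_ms)) dt_ms <- L_true / pwv_m_s
  if (dt_ms <= 0) stop("`dt_ms` must be positive")
  pwv <- L_true / dt_ms
  structure(list(L_true_mm = L_true, dt_ms = dt_ms, pwv_m_s = pwv,
                 t_asc_ms = t_arrival_ms, t_desc_ms = t_arrival_ms + dt_ms,
                 plane = cutting_plane(c(0, 1, 0), plane_y_mm),
                 seeds = seeds),
            class = "phantom_truth")
}

#' Rasterise a curve into a tube phantom volume
#'
#' Voxels within \code{radius_mm} of the curve receive the lumen intensity,
#' the rest the background intensity (emulating the bright-blood appearance
#' of the multi-slice scan). Noise is Rician-like: Gaussian added to the
#' magnitude and floored at zero. The returned label is the noiseless lumen
#' mask. Default spacing is the acquisition voxel size (1.76 x 1.76 x 5 mm).
#'
#' @param curve an \code{aorta_curve}.
#' @param radius_mm tube (lumen) radius; must be at least twice the largest
#'   in-plane spacing so the tube is resolvable.
#' @param spacing voxel spacing in mm.
#' @param contrast numeric length 2: lumen and background intensity.
#' @param noise_sd Gaussian noise SD in intensity units (0 = noiseless).
#' @param seed integer seed for the noise.
#' @param grid optional list(dim, origin) fixing the voxel grid (shared across
#'   an atlas set); when NULL the grid is fitted around the curve. If the tube
#'   does not fit the given grid an error names the offending axis.
#' @param margin_mm padding around the tube for the auto-fitted grid.
#' @return list(volume, label), both \code{volume3d} on the same grid.
#' @export
rasterize_tube <- function(curve, radius_mm = 10,
                           spacing = c(1.76, 1.76, 5),
                           contrast = c(100, 20), noise_sd = 0, seed = NULL,
                           grid = NULL, margin_mm = 12) {
  spacing <- as.numeric(spacing)
  if (any(spacing <= 0)) stop("`spacing` must be positive")
  if (radius_mm < 2 * max(spacing[1:2]))
    stop("`radius_mm` must be at least twice the in-plane spacing")
  step <- min(spacing) / 2
  s <- seq(0, curve$s_max, by = step)
  pts <- curve$fun(s)

  if (is.null(grid)) {
    lo <- apply(pts, 2, min) - radius_mm - margin_mm
    hi <- apply(pts, 2, max) + radius_mm + margin_mm
    dims <- pmax(as.integer(ceiling((hi - lo) / spacing)) + 1L, 4L)
    origin <- lo
  } else {
    dims <- as.integer(grid$dim)
    origin <- as.numeric(grid$origin)
    lo_fov <- origin - spacing / 2
    hi_fov <- origin + (dims - 1 + 0.5) * spacing
    for (ax in 1:3) {
      if (min(pts[, ax]) - radius_mm < lo_fov[ax] ||
          max(pts[, ax]) + radius_mm > hi_fov[ax])
        stop(sprintf("tube exits the field of view along the %s axis",
                     c("x", "y", "z")[ax]))
    }
  }

  # end-cap planes: the tube ends flat, perpendicular to the curve
  eps <- min(1, curve$s_max / 100)
  t0 <- curve$fun(eps) - curve$fun(0)
  t0 <- t0 / sqrt(sum(t0^2))
  t1 <- curve$fun(curve$s_max) - curve$fun(curve$s_max - eps)
  t1 <- t1 / sqrt(sum(t1^2))
  p0 <- curve$fun(0); p1 <- curve$fun(curve$s_max)

  lab <- array(FALSE, dims)
  r2 <- radius_mm^2
  nb <- ceiling(radius_mm / spacing)
  ax_off <- lapply(1:3, function(a) (-nb[a]):(nb[a]))
  box <- as.matrix(expand.grid(ax_off[[1]], ax_off[[2]], ax_off[[3]]))
  box_world <- box %*% diag(spacing)
  vox <- round(sweep(pts, 2, origin, "-") %*% diag(1 / spacing))
  for (p in seq_len(nrow(pts))) {
    ctr <- vox[p, ]
    cand <- sweep(box, 2, ctr, "+")
    inside <- cand[, 1] >= 0 & cand[, 1] < dims[1] &
              cand[, 2] >= 0 & cand[, 2] < dims[2] &
              cand[, 3] >= 0 & cand[, 3] < dims[3]
    vw <- sweep(box_world, 2, ctr * spacing + origin, "+")
    cw <- sweep(vw, 2, pts[p, ], "-")
    hit <- inside & rowSums(cw^2) <= r2 &
      (sweep(vw, 2, as.numeric(p0), "-") %*% as.numeric(t0)) >= 0 &
      (sweep(vw, 2, as.numeric(p1), "-") %*% as.numeric(t1)) <= 0
    if (any(hit)) {
      ids <- cand[hit, , drop = FALSE]
      lab[ids[, 1] + 1L + dims[1] * (ids[, 2] + dims[2] * ids[, 3])] <- TRUE
    }
  }
  if (!any(lab)) stop("tube rasterised to an empty label; check the grid")

  img <- array(ifelse(lab, contrast[1], contrast[2]), dims)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    img <- pmax(img + array(rnorm(length(img), sd = noise_sd), dims), 0)
  }
  list(volume = volume3d(img, spacing, origin),
       label = volume3d(array(as.integer(lab), dims), spacing, origin))
}

#' Standard phantom voxel grid
#'
#' The default grid used for phantom subjects and atlases: 96 x 96 x 15
#' voxels at the acquisition spacing (1.76, 1.76, 5) mm, centred near the
#' arch so a whole atlas set shares one field of view.
#'
#' @param dims grid size (voxels).
#' @param spacing voxel spacing (mm).
#' @param center world centre of the grid (mm).
#' @export
phantom_grid <- function(dims = c(96, 96, 15), spacing = c(1.76, 1.76, 5),
                         center = c(0, 5, 0)) {
  list(dim = as.integer(dims), spacing = spacing,
       origin = center - (dims - 1) * spacing / 2)
}

#' Generate an atlas set of labelled tube phantoms
#'
#' Produces \code{n} phantoms (default eight, the atlas-set size used for
#' multi-atlas segmentation) with varied arch radius, limb lengths, tilt and
#' random rigid pose offsets, each rasterised on a shared grid with its
#' noiseless lumen label.
#'
#' @param n number of atlases (>= 1).
#' @param base named list of base curve parameters (arch_radius_mm, limb_mm,
#'   tilt_deg, tube_radius_mm).
#' @param seed integer seed controlling the whole set.
#' @param grid shared voxel grid from \code{phantom_grid()}.
#' @param noise_sd intensity noise SD of the atlas scans.
#' @return list of n elements, each list(volume, label, curve).
#' @export
make_atlas_set <- function(n = 8, base = list(), seed = 1,
                           grid = phantom_grid(), noise_sd = 2) {
  if (n < 1) stop("`n` must be >= 1")
  base <- modifyList(list(arch_radius_mm = 45, limb_mm = c(50, 50),
                          tilt_deg = 0, tube_radius_mm = 10), base)
  set.seed(seed)
  draws <- lapply(seq_len(n), function(i)
    list(dR = runif(1, -5, 5), dtilt = runif(1, -8, 8),
         dl = runif(2, -6, 6), shift = runif(3, -4, 4),
         rot = runif(1, -5, 5), pseed = sample.int(1e6, 1)))
  lapply(seq_len(n), function(i) {
    d <- draws[[i]]
    curve <- make_aorta_curve(
      arch_radius_mm = base$arch_radius_mm + d$dR,
      limb_mm = base$limb_mm + d$dl,
      tilt_deg = base$tilt_deg + d$dtilt,
      tube_radius_mm = base$tube_radius_mm,
      perturb_mm = 1.0, seed = d$pseed)
    curve <- shift_curve(curve, d$shift, d$rot)
    ras <- rasterize_tube(curve, radius_mm = base$tube_radius_mm,
                          spacing = grid$spacing, grid = grid,
                          noise_sd = noise_sd, seed = d$pseed + 1L)
    list(volume = ras$volume, label = ras$label, curve = curve)
  })
}

#' Physiological waveform specification for VE phantoms
#'
#' The synthetic systolic waveform: a raised-cosine upslope of duration
#' \code{upslope_ms} from \code{baseline_cm_s} to \code{peak_cm_s}, followed
#' by exponential decay back to baseline with time constant \code{decay_ms}.
#' The descending-aorta copy is delayed, sign-inverted and mildly dispersed
#' (its upslope stretched by \code{dispersion}). The half-max arrival of a
#' curve is \code{onset + stretch * upslope_ms / 2}.
#'
#' @param baseline_cm_s diastolic baseline velocity.
#' @param peak_cm_s systolic peak velocity.
#' @param upslope_ms upslope duration.
#' @param decay_ms exponential decay time constant.
#' @param interval_ms reconstructed phase interval (5 ms, the VE protocol).
#' @param n_phases number of cardiac phases (protocol range 140-250).
#' @param noise_sd_cm_s additive Gaussian velocity noise SD.
#' @param dispersion upslope stretch factor for the descending curve.
#' @param desc_sign sign of the descending flow in the encoding direction
#'   (caudal flow encodes negative).
#' @export
waveform_spec <- function(baseline_cm_s = 0, peak_cm_s = 100, upslope_ms = 80,
                          decay_ms = 150, interval_ms = 5, n_phases = 140,
                          noise_sd_cm_s = 0, dispersion = 1.2,
                          desc_sign = -1) {
  if (interval_ms <= 0) stop("`interval_ms` must be positive")
  if (n_phases < 2) stop("`n_phases` must be >= 2")
  if (upslope_ms <= 0) stop("`upslope_ms` must be positive")
  structure(list(baseline_cm_s = baseline_cm_s, peak_cm_s = peak_cm_s,
                 upslope_ms = upslope_ms, decay_ms = decay_ms,
                 interval_ms = interval_ms, n_phases = n_phases,
                 noise_sd_cm_s = noise_sd_cm_s, dispersion = dispersion,
                 desc_sign = desc_sign),
            class = "waveform_spec")
}

#' @rdname waveform_spec
#' @param spec a \code{waveform_spec}.
#' @param t_ms times (ms) at which to evaluate.
#' @param onset_ms foot (start of upslope) of the waveform.
#' @param stretch upslope stretch factor (1 = nominal, dispersion for the
#'   descending curve).
#' @export
eval_waveform <- function(spec, t_ms, onset_ms, stretch = 1) {
  # dispersion (stretch > 1) broadens the upslope and accelerates the decay
  # by the same factor, front-loading the pulse the way descending-aorta
  # curves are front-loaded relative to ascending ones
  up <- spec$upslope_ms * stretch
  tau <- spec$decay_ms / stretch
  amp <- spec$peak_cm_s - spec$baseline_cm_s
  v <- rep(spec$baseline_cm_s, length(t_ms))
  rise <- t_ms >= onset_ms & t_ms <= onset_ms + up
  v[rise] <- spec$baseline_cm_s +
    amp * 0.5 * (1 - cos(pi * (t_ms[rise] - onset_ms) / up))
  dec <- t_ms > onset_ms + up
  v[dec] <- spec$baseline_cm_s + amp * exp(-(t_ms[dec] - onset_ms - up) / tau)
  v
}

#' @rdname waveform_spec
#' @export
waveform_arrival <- function(spec, onset_ms, stretch = 1) {
  onset_ms + stretch * spec$upslope_ms / 2
}

#' Synthetic flow-curve pair with known transit time
#'
#' Generates an ascending/descending velocity-time curve pair directly from
#' the waveform model (bypassing the imaging chain), with the descending
#' curve delayed, dispersed and sign-inverted so that the half-max arrivals
#' differ by exactly \code{dt_true_ms}. Used for Monte-Carlo evaluation of
#' the transit-time estimators.
#'
#' @param dt_true_ms true transit time (ms).
#' @param spec a \code{waveform_spec} (its \code{noise_sd_cm_s} is applied).
#' @param onset_asc_ms foot of the ascending upslope.
#' @param seed integer noise seed.
#' @return list(asc, desc, dt_true_ms) of \code{flow_curve}s.
#' @export
make_curve_pair <- function(dt_true_ms, spec = waveform_spec(),
                            onset_asc_ms = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- (seq_len(spec$n_phases) - 1) * spec$interval_ms
  onset_desc <- onset_asc_ms + dt_true_ms -
    (spec$dispersion - 1) * spec$upslope_ms / 2
  va <- eval_waveform(spec, t, onset_asc_ms)
  vd <- spec$desc_sign * eval_waveform(spec, t, onset_desc, spec$dispersion)
  if (spec$noise_sd_cm_s > 0) {
    va <- va + rnorm(length(t), sd = spec$noise_sd_cm_s)
    vd <- vd + rnorm(length(t), sd = spec$noise_sd_cm_s)
  }
  list(asc = flow_curve(t, va, roi = 1L),
       desc = flow_curve(t, vd, roi = 2L),
       dt_true_ms = dt_true_ms)
}

#' Synthetic velocity-encoded cine series
#'
#' Emulates the 2D+t through-plane VE acquisition: magnitude frames contain
#' two bright disks at the plane crossings of the phantom aorta (ascending
#' and descending), and phase frames encode the through-plane velocity with
#' the linear mapping phase pi <-> VENC. The ascending disk follows the
#' waveform from the true ascending arrival; the descending disk follows the
#' delayed, dispersed, sign-inverted copy. Static background is zero
#' velocity. Defaults follow the VE protocol: 1.25 mm pixels, 5 ms phase
#' interval, VENC 150 cm/s.
#'
#' @param truth a \code{phantom_truth}.
#' @param waveform a \code{waveform_spec}.
#' @param venc_cm_s velocity-encoding limit; the peak velocity must stay
#'   below it (no aliasing by construction).
#' @param pixel_mm in-plane pixel size (isotropic).
#' @param radii_mm lumen radii of the ascending and descending disks.
#' @param fov_px image matrix (pixels).
#' @param mag_noise_sd magnitude noise SD (floored at zero, Rician-like).
#' @param seed noise seed.
#' @return object of class \code{ve_series}.
#' @export
make_ve_series <- function(truth, waveform = waveform_spec(),
                           venc_cm_s = 150, pixel_mm = 1.25,
                           radii_mm = c(10, 10), fov_px = c(96, 96),
                           mag_noise_sd = 0, seed = NULL) {
  vmax <- max(abs(c(waveform$peak_cm_s, waveform$baseline_cm_s)))
  if (vmax >= venc_cm_s)
    stop("aliasing risk: peak velocity reaches or exceeds VENC")
  n <- truth$plane$normal
  aux <- if (abs(n[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  row_dir <- normalize3(cross3(aux, n))
  col_dir <- cross3(n, row_dir)
  center <- as.numeric(colMeans(truth$seeds))
  origin <- as.numeric(center - (fov_px[1] - 1) / 2 * pixel_mm * row_dir -
                       (fov_px[2] - 1) / 2 * pixel_mm * col_dir)
  seed_px <- t(apply(truth$seeds, 1, function(p)
    c(sum((p - origin) * row_dir), sum((p - origin) * col_dir)) / pixel_mm))
  if (any(seed_px < 2) || any(seed_px[, 1] > fov_px[1] - 3) ||
      any(seed_px[, 2] > fov_px[2] - 3))
    stop("vessel disks do not fit the VE field of view")
  d_px <- sqrt(sum((seed_px[1, ] - seed_px[2, ])^2)) * pixel_mm
  if (d_px < sum(radii_mm))
    stop("vessel disks overlap in the VE field of view")

  t_ms <- (seq_len(waveform$n_phases) - 1) * waveform$interval_ms
  onset_asc <- truth$t_asc_ms - waveform$upslope_ms / 2
  onset_desc <- truth$t_desc_ms - waveform$dispersion * waveform$upslope_ms / 2
  va <- eval_waveform(waveform, t_ms, onset_asc)
  vd <- waveform$desc_sign * eval_waveform(waveform, t_ms, onset_desc,
                                           waveform$dispersion)

  px <- matrix(rep(seq_len(fov_px[1]) - 1, fov_px[2]), fov_px[1])
  py <- matrix(rep(seq_len(fov_px[2]) - 1, each = fov_px[1]), fov_px[1])
  in_disk <- lapply(1:2, function(r)
    (px - seed_px[r, 1])^2 + (py - seed_px[r, 2])^2 <=
      (radii_mm[r] / pixel_mm)^2)

  if (!is.null(seed)) set.seed(seed)
  T <- waveform$n_phases
  mag <- array(20, c(fov_px, T))
  phs <- array(0, c(fov_px, T))
  phase_sd <- if (waveform$noise_sd_cm_s > 0)
    waveform$noise_sd_cm_s / venc_cm_s * pi else 0
  for (tt in seq_len(T)) {
    m <- matrix(20, fov_px[1], fov_px[2])
    m[in_disk[[1]]] <- 100
    m[in_disk[[2]]] <- 100
    p <- matrix(0, fov_px[1], fov_px[2])
    p[in_disk[[1]]] <- va[tt] / venc_cm_s * pi
    p[in_disk[[2]]] <- vd[tt] / venc_cm_s * pi
    if (phase_sd > 0) p <- p + matrix(rnorm(length(p), sd = phase_sd),
                                      nrow(p))
    if (mag_noise_sd > 0) m <- pmax(m + matrix(rnorm(length(m),
                                                     sd = mag_noise_sd),
                                               nrow(m)), 0)
    mag[, , tt] <- m
    phs[, , tt] <- p
  }

  structure(list(magnitude = mag, phase = phs, time_ms = t_ms,
                 venc_cm_s = venc_cm_s, pixel_mm = rep(pixel_mm, 2),
                 origin = origin, row_dir = row_dir, col_dir = col_dir,
                 dialect = "radians",
                 truth_px = list(centres = seed_px,
                                 radii_px = radii_mm / pixel_mm)),
            class = "ve_series")
}

#' @export
print.ve_series <- function(x, ...) {
  d <- dim(x$magnitude)
  cat(sprintf(
    "<ve_series> %d x %d px, %d phases @ %.3g ms, VENC %g cm/s\n",
    d[1], d[2], d[3], diff(x$time_ms[1:2]), x$venc_cm_s))
  invisible(x)
}

cross3 <- function(a, b) c(a[2]*b[3] - a[3]*b[2],
                           a[3]*b[1] - a[1]*b[3],
                           a[1]*b[2] - a[2]*b[1])
normalize3 <- function(v) v / sqrt(sum(v^2))

#' Complete phantom study with known PWV
#'
#' Bundles everything one subject needs for the end-to-end pipeline: a
#' subject tube phantom (volume + noiseless label), an atlas set on the same
#' grid, a VE series cutting both limbs, and the ground truth (arch length
#' above the plane, arrival times, transit time, PWV).
#'
#' @param seed master seed; all randomness derives from it.
#' @param pwv_m_s true pulse wave velocity.
#' @param n_atlas number of atlases.
#' @param arch_radius_mm,limb_mm,tilt_deg subject curve geometry.
#' @param tube_radius_mm lumen radius.
#' @param noise_sd subject image intensity noise SD.
#' @param waveform a \code{waveform_spec}.
#' @param grid shared voxel grid.
#' @return list(subject, label, atlases, ve, truth, curve).
#' @export
make_phantom_study <- function(seed = 1, pwv_m_s = 10, n_atlas = 8,
                               arch_radius_mm = 45, limb_mm = c(50, 50),
                               tilt_deg = 5, tube_radius_mm = 10,
                               noise_sd = 2, waveform = waveform_spec(),
                               grid = phantom_grid()) {
  set.seed(seed)
  pseed <- sample.int(1e6, 3)
  curve <- make_aorta_curve(arch_radius_mm, limb_mm, tilt_deg,
                            tube_radius_mm, perturb_mm = 1.0,
                            seed = pseed[1])
  ras <- rasterize_tube(curve, tube_radius_mm, spacing = grid$spacing,
                        grid = grid, noise_sd = noise_sd, seed = pseed[2])
  truth <- phantom_truth(curve, plane_y_mm = -20, pwv_m_s = pwv_m_s)
  ve <- make_ve_series(truth, waveform, radii_mm = rep(tube_radius_mm, 2),
                       seed = pseed[3])
  atlases <- make_atlas_set(n_atlas,
                            base = list(arch_radius_mm = arch_radius_mm,
                                        limb_mm = limb_mm,
                                        tilt_deg = tilt_deg,
                                        tube_radius_mm = tube_radius_mm),
                            seed = seed + 1000L, grid = grid)
  list(subject = ras$volume, label = ras$label, atlases = atlases,
       ve = ve, truth = truth, curve = curve)
}
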