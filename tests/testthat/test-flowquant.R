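test_that("contour detection finds a disk boundary from centred and offset seeds", {
  fr <- disk_frame(r = 15)
  c0 <- detect_contour(fr, c(31, 33), pixel_mm = 1, max_radius_mm = 22)
  expect_lt(abs(mean(c0$radius_px) - 15), 1)

  # a 3 px off-centre seed finds the same boundary
  c1 <- detect_contour(fr, c(34, 33), pixel_mm = 1, max_radius_mm = 22)
  d <- sqrt((c1$polygon[, 1] - 31)^2 + (c1$polygon[, 2] - 33)^2)
  expect_lt(mean(abs(d - 15)), 1)

  expect_error_class(
    detect_contour(matrix(50, 64, 64), c(31, 33), pixel_mm = 1),
    "aortapwv_no_vessel")
  expect_error(detect_contour(fr, c(31, 33), n_rays = 8), "n_rays")
})

test_that("contour detection is equivariant to integer translation", {
  fr <- disk_frame(n = 80, cx = 30, cy = 30, r = 12)
  sh <- matrix(20, 80, 80)
  sh[6:80, 9:80] <- fr[1:75, 1:72]   # shift by (+5, +8)
  c0 <- detect_contour(fr, c(30, 30), pixel_mm = 1, max_radius_mm = 20)
  c1 <- detect_contour(sh, c(35, 38), pixel_mm = 1, max_radius_mm = 20)
  expect_equal(c1$polygon, c0$polygon + rep(c(5, 8), each = 64),
               tolerance = 1e-9)
})

static_series <- function(n_phases = 50, v = 80) {
  cv <- make_aorta_curve(45, c(50, 50))
  truth <- phantom_truth(cv, dt_ms = 15)
  make_ve_series(truth, waveform_spec(n_phases = n_phases))
}

test_that("propagation keeps contours fixed on a static scene", {
  ve <- static_series()
  seeds <- ve$truth_px$centres
  ctr <- propagate_contours(ve, seeds, ref_index = 30)
  for (roi in 1:2) {
    ref <- ctr[[roi]][[30]]$radius_px
    for (t in c(1, 10, 25, 40, 50))
      expect_lt(max(abs(ctr[[roi]][[t]]$radius_px - ref)), 1)
  }
})

test_that("propagation tracks a smoothly pulsing disk within a pixel", {
  nT <- 40
  r_true <- 10 + 2 * sin(2 * pi * (1:nT) / nT)
  mag <- array(20, c(64, 64, nT))
  for (t in 1:nT) mag[, , t] <- disk_frame(cx = 31, cy = 31, r = r_true[t])
  ve <- structure(list(magnitude = mag, phase = mag * 0,
                       time_ms = (0:(nT - 1)) * 5, venc_cm_s = 150,
                       pixel_mm = c(1, 1), origin = c(0, 0, 0),
                       row_dir = c(1, 0, 0), col_dir = c(0, 1, 0),
                       dialect = "radians"),
                  class = "ve_series")
  ctr <- propagate_contours(ve, rbind(c(31, 31), c(31, 31)),
                            ref_index = 20, max_radius_mm = 20)
  r_est <- vapply(ctr[[1]], function(c3) mean(c3$radius_px), numeric(1))
  expect_lt(max(abs(r_est - r_true)), 1)
  expect_lt(max(abs(diff(r_est))), 2)
})

test_that("temporal penalty limits reduce to the expected behaviours", {
  ve <- static_series(n_phases = 12)
  seeds <- ve$truth_px$centres
  # lambda_t -> infinity: every contour equals the reference
  hard <- propagate_contours(ve, seeds, ref_index = 6, lambda_t = 1e9)
  for (t in 1:12)
    expect_equal(hard[[1]][[t]]$radius_px, hard[[1]][[6]]$radius_px)
  # lambda_t = 0: identical to independent per-phase detection
  free <- propagate_contours(ve, seeds, ref_index = 6, lambda_t = 0)
  indep <- detect_contour(ve$magnitude[, , 3], seeds[1, ])
  expect_equal(free[[1]][[3]]$radius_px, indep$radius_px)
})

test_that("phase images convert linearly to velocity maps", {
  expect_equal(velocity_from_phase(pi / 2, 150), 75)
  expect_equal(velocity_from_phase(0, 150), 0)
  expect_equal(velocity_from_phase(2048, 150, dialect = "scaled"), 75)
  expect_error_class(velocity_from_phase(0, 150, dialect = "foo"),
                     "aortapwv_bad_dialect")
})

test_that("flow curves average velocities inside the contour", {
  # uniform velocity inside the vessel: curve reproduces it exactly
  nT <- 12
  mag <- array(20, c(64, 64, nT)); phs <- array(0, c(64, 64, nT))
  fr <- disk_frame(cx = 31, cy = 31, r = 10)
  for (t in 1:nT) {
    mag[, , t] <- fr
    p <- matrix(0, 64, 64); p[fr > 50] <- 80 / 150 * pi
    phs[, , t] <- p
  }
  ve <- structure(list(magnitude = mag, phase = phs,
                       time_ms = (0:(nT - 1)) * 5, venc_cm_s = 150,
                       pixel_mm = c(1, 1), origin = c(0, 0, 0),
                       row_dir = c(1, 0, 0), col_dir = c(0, 1, 0),
                       dialect = "radians"),
                  class = "ve_series")
  ctr <- propagate_contours(ve, rbind(c(31, 31), c(31, 31)), ref_index = 6,
                            max_radius_mm = 20)
  cu <- flow_curves(ve, ctr)
  expect_equal(cu[[1]]$v_cm_s, rep(80, nT), tolerance = 1e-9)

  # antisymmetric velocity over the full disk averages to zero
  # (disk centre row zeroed so the two halves are exact mirrors)
  p <- matrix(0, 64, 64)
  p[fr > 50] <- pi / 2
  p[1:31, ][fr[1:31, ] > 50] <- -pi / 2
  p[32, ] <- 0
  inside <- aortapwv:::pixels_in_polygon(ctr[[1]][[1]]$polygon, c(64, 64))
  expect_equal(mean(velocity_from_phase(p, 150)[inside]), 0,
               tolerance = 1e-9)

  # a degenerate contour enclosing no pixel centre is an error
  tiny <- lapply(1:nT, function(t)
    list(polygon = cbind(0.4 + 0.01 * cos(seq(0, 2 * pi, length.out = 16)),
                         0.4 + 0.01 * sin(seq(0, 2 * pi, length.out = 16)))))
  expect_error_class(flow_curves(ve, list(tiny, tiny)),
                     "aortapwv_degenerate_contour")
})

test_that("phantom flow curves reproduce the generated waveform", {
  cv <- make_aorta_curve(45, c(50, 50))
  truth <- phantom_truth(cv, dt_ms = 15)
  wf <- waveform_spec(n_phases = 80, noise_sd_cm_s = 5)
  ve <- make_ve_series(truth, wf, seed = 31)
  ctr <- propagate_contours(ve, ve$truth_px$centres, ref_index = 30)
  cu <- flow_curves(ve, ctr)
  v_true <- eval_waveform(wf, ve$time_ms, truth$t_asc_ms - wf$upslope_ms / 2)
  n_pix <- sum((disk_frame(n = 96, cx = ve$truth_px$centres[1, 1],
                           cy = ve$truth_px$centres[1, 2],
                           r = ve$truth_px$radii_px[1])) > 50)
  rms <- sqrt(mean((cu[[1]]$v_cm_s - v_true)^2))
  expect_lt(rms, 2 * wf$noise_sd_cm_s / sqrt(n_pix) + 1)
  # ROI1 is the positive-peak (ascending) curve
  expect_gt(max(cu[[1]]$v_cm_s), 0)
  expect_lt(min(cu[[2]]$v_cm_s), -50)
})
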