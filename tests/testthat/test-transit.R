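ramp_curve <- function(t0 = 40, t1 = 60, peak = 100, tmax = 300) {
  t <- seq(0, tmax, by = 5)
  v <- pmin(pmax((t - t0) / (t1 - t0), 0), 1) * peak
  flow_curve(t, v)
}

test_that("preprocessing normalises sign, filters spikes, checks sampling", {
  t <- (0:19) * 5
  neg <- flow_curve(t, -c(rep(0, 5), seq(0, 100, length.out = 10),
                          rep(60, 5)))
  pos <- preprocess_curve(neg)
  expect_gt(max(pos$v_cm_s), 0)
  expect_identical(preprocess_curve(pos)$v_cm_s, pos$v_cm_s)  # idempotent

  base <- eval_waveform(waveform_spec(upslope_ms = 30, n_phases = 20), t, 25)
  spiky <- flow_curve(t, replace(base, 3, 70))
  sm <- preprocess_curve(spiky, median3 = TRUE)
  expect_lt(sm$v_cm_s[3], 5)                      # spike removed
  # peak time unchanged (3-point median can shift a flat peak <= 1 sample)
  expect_lte(abs(sm$time_ms[which.max(sm$v_cm_s)] -
                   spiky$time_ms[which.max(base)]), 5)

  expect_error(preprocess_curve(flow_curve((0:5) * 5, rep(1, 6))),
               ">= 10")
  irregular <- flow_curve(c(0, 5, 10, 16, 20, 25, 30, 35, 40, 45),
                          (0:9) * 2)
  expect_warning(preprocess_curve(irregular), "non-uniform")
})

test_that("foot-to-foot finds the foot of an ideal ramp exactly", {
  r <- ramp_curve()
  res <- foot_to_foot(r, r, smoothing_ms = 0)
  expect_equal(res$ta1_ms, 40, tolerance = 1e-6)
  expect_equal(res$dt_ms, 0, tolerance = 1e-9)

  # all-flat curve: no upslope window -> foot failure
  flat <- flow_curve((0:20) * 5, rep(1, 21))
  expect_error_class(foot_to_foot(flat, flat), "aortapwv_foot_failed")
})

test_that("half-max crosses an ideal ramp at its midpoint", {
  r <- ramp_curve()
  expect_equal(half_max(r, r, smoothing_ms = 0)$ta1_ms, 50,
               tolerance = 1e-9)
  expect_equal(half_max(r, r)$ta1_ms, 50, tolerance = 1e-6)

  # +10 ms shift moves the arrival by exactly +10 ms
  sh <- flow_curve(r$time_ms, c(rep(0, 2), r$v_cm_s[1:(length(r$v_cm_s) - 2)]))
  res <- half_max(r, sh)
  expect_equal(res$dt_ms, 10, tolerance = 1e-9)
})

test_that("all three estimators return zero for identical curves", {
  spec <- waveform_spec()
  p <- make_curve_pair(0, spec)
  asc <- preprocess_curve(p$asc)
  expect_equal(foot_to_foot(asc, asc)$dt_ms, 0, tolerance = 1e-9)
  expect_equal(half_max(asc, asc)$dt_ms, 0, tolerance = 1e-9)
  expect_equal(cross_correlation(asc, asc)$dt_ms, 0, tolerance = 1e-12)
})

test_that("noiseless phantom pairs recover the true transit time", {
  spec <- waveform_spec(dispersion = 1)
  p <- make_curve_pair(15, spec)
  asc <- preprocess_curve(p$asc); desc <- preprocess_curve(p$desc)
  expect_lt(abs(foot_to_foot(asc, desc)$dt_ms - 15), 0.5)
  expect_lt(abs(half_max(asc, desc)$dt_ms - 15), 0.5)
  expect_lt(abs(cross_correlation(asc, desc)$dt_ms - 15), 0.5)
})

test_that("cross-correlation recovers integer shifts exactly", {
  t <- (0:139) * 5
  v <- eval_waveform(waveform_spec(), t, 100)
  asc <- flow_curve(t, v)
  desc <- flow_curve(t, c(rep(0, 3), v[1:137]))
  expect_identical(cross_correlation(asc, desc)$dt_ms, 15)
  # peak at the search boundary is an error
  expect_error_class(cross_correlation(asc, desc, max_lag_ms = 10),
                     "aortapwv_boundary_peak")
})

test_that("parabolic refinement agrees with a dense lag scan", {
  # oracle: brute-force normalised correlation at 0.1 ms on an
  # analytically shifted smooth pulse
  spec <- waveform_spec()
  t <- (0:139) * 5
  shift <- 12.3
  asc <- flow_curve(t, eval_waveform(spec, t, 100))
  desc <- flow_curve(t, eval_waveform(spec, t, 100 + shift))
  est <- cross_correlation(asc, desc)$dt_ms

  g <- seq(0, 695, by = 0.1)
  a <- eval_waveform(spec, g, 100)
  lag_scan <- vapply(seq(0, 30, by = 0.1), function(l) {
    b <- eval_waveform(spec, g + l, 100 + shift)
    stats::cor(a, b)
  }, numeric(1))
  oracle <- seq(0, 30, by = 0.1)[which.max(lag_scan)]
  expect_equal(oracle, shift, tolerance = 0.05)
  expect_lt(abs(est - oracle), 0.2)
})

test_that("estimators are shift-equivariant and amplitude-invariant", {
  spec <- waveform_spec(dispersion = 1)
  p <- make_curve_pair(10, spec)
  asc <- preprocess_curve(p$asc); desc <- preprocess_curve(p$desc)
  # shift the descending curve by 3 samples (15 ms)
  dsh <- flow_curve(desc$time_ms,
                    c(rep(desc$v_cm_s[1], 3),
                      desc$v_cm_s[1:(length(desc$v_cm_s) - 3)]))
  for (f in list(foot_to_foot, half_max, cross_correlation)) {
    d0 <- f(asc, desc)$dt_ms
    d1 <- f(asc, dsh)$dt_ms
    expect_equal(d1 - d0, 15, tolerance = 0.2)
  }
  # scaling either curve leaves half-max and cross-correlation unchanged
  k <- 3.7
  desc_k <- flow_curve(desc$time_ms, k * desc$v_cm_s)
  expect_equal(half_max(asc, desc_k)$dt_ms, half_max(asc, desc)$dt_ms,
               tolerance = 1e-9)
  expect_equal(cross_correlation(asc, desc_k)$dt_ms,
               cross_correlation(asc, desc)$dt_ms, tolerance = 1e-9)
})

test_that("PWV combines length and transit time with the high-PWV flag", {
  r10 <- compute_pwv(100, transit_result("half_max", 0, 10, 10))
  expect_equal(r10$pwv_m_s, 10)
  expect_false(r10$high_pwv)

  r30 <- compute_pwv(150, transit_result("half_max", 0, 5, 5))
  expect_equal(r30$pwv_m_s, 30)
  expect_true(r30$high_pwv)

  expect_error_class(compute_pwv(100, transit_result("half_max", 5, 2, -3)),
                     "aortapwv_nonphysical_transit")
  expect_error(compute_pwv(-5, transit_result("half_max", 0, 10, 10)),
               "positive")
})

test_that("dispersion orders cross-correlation below half-max", {
  spec <- waveform_spec()     # dispersion 1.2
  p <- make_curve_pair(15, spec)
  asc <- preprocess_curve(p$asc); desc <- preprocess_curve(p$desc)
  expect_lte(cross_correlation(asc, desc)$dt_ms,
             half_max(asc, desc)$dt_ms)
})
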