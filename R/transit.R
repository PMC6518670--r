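#' Velocity-time flow curve
#'
#' @param time_ms trigger times in ms (strictly increasing).
#' @param v_cm_s mean velocity per phase in cm/s.
#' @param roi region id: 1 = ascending aorta, 2 = descending aorta.
#' @export
flow_curve <- function(time_ms, v_cm_s, roi = 1L) {
  if (length(time_ms) != length(v_cm_s))
    stop("`time_ms` and `v_cm_s` must have equal length")
  if (any(diff(time_ms) <= 0)) stop("`time_ms` must be strictly increasing")
  if (any(!is.finite(v_cm_s))) stop("`v_cm_s` must be finite")
  structure(list(time_ms = as.numeric(time_ms), v_cm_s = as.numeric(v_cm_s),
                 roi = as.integer(roi)),
            class = "flow_curve")
}

#' @export
print.flow_curve <- function(x, ...) {
  cat(sprintf("<flow_curve> ROI %d, %d phases, peak %.1f cm/s at %.0f ms\n",
              x$roi, length(x$time_ms), max(abs(x$v_cm_s)),
              x$time_ms[which.max(abs(x$v_cm_s))]))
  invisible(x)
}

#' @export
as.data.frame.flow_curve <- function(x, ...) {
  data.frame(time_ms = x$time_ms, v_cm_s = x$v_cm_s, roi = x$roi)
}

#' Prepare a flow curve for transit-time estimation
#'
#' Sign-normalises the curve so its systolic peak is positive (the
#' descending aorta encodes negative), optionally applies a 3-point median
#' filter, and verifies uniform sampling (non-uniform curves are resampled
#' onto a uniform grid with a warning).
#'
#' @param curve a \code{flow_curve} with at least 10 samples.
#' @param median3 apply a 3-point median filter (off by default).
#' @return the preprocessed \code{flow_curve}.
#' @export
preprocess_curve <- function(curve, median3 = FALSE) {
  if (length(curve$time_ms) < 10) stop("curve must have >= 10 samples")
  dt <- diff(curve$time_ms)
  if (diff(range(dt)) > 0.01 * median(dt)) {
    warning("non-uniform sampling; resampling to a uniform grid")
    tt <- seq(curve$time_ms[1], tail(curve$time_ms, 1),
              by = median(dt))
    curve$v_cm_s <- approx(curve$time_ms, curve$v_cm_s, tt)$y
    curve$time_ms <- tt
  }
  v <- curve$v_cm_s
  if (abs(min(v)) > abs(max(v))) v <- -v
  if (median3) {
    sm <- stats::runmed(v, 3)
    v <- as.numeric(sm)
  }
  curve$v_cm_s <- v
  curve
}

transit_result <- function(method, ta1, ta2, dt, diagnostics = list()) {
  structure(list(method = method, ta1_ms = ta1, ta2_ms = ta2, dt_ms = dt,
                 diagnostics = diagnostics),
            class = "transit_result")
}

#' @export
print.transit_result <- function(x, ...) {
  cat(sprintf("<transit_result> %s: dt = %.2f ms", x$method, x$dt_ms))
  if (!is.null(x$ta1_ms) && !is.na(x$ta1_ms))
    cat(sprintf(" (ta1 = %.2f, ta2 = %.2f ms)", x$ta1_ms, x$ta2_ms))
  cat("\n")
  invisible(x)
}

# zero-phase Gaussian low-pass with edge-value padding; sigma in ms.
# Arrival detection operates on a filtered copy: sample noise at 5 ms
# spacing otherwise dominates the crossing-time jitter (jitter ~ noise/slope).
# The filter is linear, symmetric and time-invariant, so it shifts both
# curves' arrivals identically and leaves the transit time unbiased.
gauss_smooth_ms <- function(v, t, sigma_ms) {
  if (sigma_ms <= 0) return(v)
  dt <- median(diff(t))
  s <- sigma_ms / dt
  r <- ceiling(3 * s)
  if (r < 1) return(v)
  k <- exp(-0.5 * ((-r):r / s)^2)
  k <- k / sum(k)
  n <- length(v)
  vp <- c(rep(v[1], r), v, rep(v[n], r))
  as.numeric(stats::filter(vp, k))[(r + 1):(r + n)]
}

# rising-limb indices up to the global peak
rising_limb <- function(curve) {
  ip <- which.max(curve$v_cm_s)
  list(ip = ip, idx = seq_len(ip))
}

foot_time <- function(curve, smoothing_ms = 15) {
  v <- gauss_smooth_ms(curve$v_cm_s, curve$time_ms, smoothing_ms)
  t <- curve$time_ms
  curve <- list(time_ms = t, v_cm_s = v)
  rl <- rising_limb(curve)
  peak <- v[rl$ip]
  i10 <- which(v[rl$idx] >= 0.1 * peak)[1]
  baseline <- if (!is.na(i10) && i10 > 1) mean(v[seq_len(i10 - 1)]) else 0
  win <- rl$idx[v[rl$idx] >= 0.2 * peak & v[rl$idx] <= 0.8 * peak]
  # keep the contiguous run directly below the peak
  if (length(win) > 1) {
    br <- which(diff(win) > 1)
    if (length(br)) win <- win[(tail(br, 1) + 1):length(win)]
  }
  if (length(win) < 2)
    pwv_error("aortapwv_foot_failed",
              "upslope fit window has %d samples (need >= 2)", length(win))
  fit <- lm(v[win] ~ t[win])
  slope <- coef(fit)[2]
  if (!is.finite(slope) || slope <= 0)
    pwv_error("aortapwv_foot_failed", "non-positive upslope fit")
  foot <- (baseline - coef(fit)[1]) / slope
  if (foot < t[1] || foot > tail(t, 1))
    pwv_error("aortapwv_foot_failed",
              "fitted foot (%.1f ms) outside the sampled range", foot)
  list(foot = as.numeric(foot), baseline = baseline, window = win,
       peak = peak)
}

#' Transit time by the foot-to-foot method
#'
#' For each curve the baseline is the mean of the samples before the
#' 10%-of-peak crossing, a line is fit by least squares to the rising limb
#' between 20% and 80% of peak, and the foot is the intersection of that
#' line with the baseline. The transit time is the difference of the two
#' feet. Fails (with an \code{aortapwv_foot_failed} error) when the fit
#' window is too short or the foot falls outside the sampled range — the
#' known failure mode of this estimator on noisy curves.
#'
#' Detection runs on a lightly low-pass-filtered copy of each curve
#' (zero-phase Gaussian, \code{smoothing_ms}); the filter is identical for
#' both curves, so the transit time stays unbiased while the crossing
#' jitter (noise divided by upslope steepness) is suppressed.
#'
#' @param asc,desc preprocessed ascending and descending \code{flow_curve}s.
#' @param smoothing_ms Gaussian pre-filter SD in ms (0 disables).
#' @return a \code{transit_result}.
#' @export
foot_to_foot <- function(asc, desc, smoothing_ms = 15) {
  fa <- foot_time(asc, smoothing_ms)
  fd <- foot_time(desc, smoothing_ms)
  transit_result("foot_to_foot", fa$foot, fd$foot, fd$foot - fa$foot,
                 list(baseline = c(fa$baseline, fd$baseline),
                      peaks = c(fa$peak, fd$peak)))
}

half_max_time <- function(curve, smoothing_ms = 20) {
  v <- gauss_smooth_ms(curve$v_cm_s, curve$time_ms, smoothing_ms)
  t <- curve$time_ms
  curve <- list(time_ms = t, v_cm_s = v)
  rl <- rising_limb(curve)
  peak <- v[rl$ip]
  half <- 0.5 * peak
  above <- which(v[rl$idx] >= half)
  i <- above[above > 1][1]
  if (is.na(i) || v[i - 1] >= half)
    pwv_error("aortapwv_halfmax_failed",
              "no half-max crossing on the rising limb")
  # linear interpolation between the bracketing samples
  f <- (half - v[i - 1]) / (v[i] - v[i - 1])
  list(ta = t[i - 1] + f * (t[i] - t[i - 1]), peak = peak)
}

#' Transit time by the half-max method
#'
#' The arrival time of each curve is where its rising limb crosses 50% of
#' its peak (first crossing before the global peak, located by linear
#' interpolation between the bracketing samples); the transit time is the
#' difference of the two arrivals. Considers only the systolic upslope, so
#' it is robust to diastolic and reflected-wave differences between the two
#' sites. As for \code{foot_to_foot()}, detection runs on a zero-phase
#' Gaussian-filtered copy (\code{smoothing_ms}) of each curve.
#'
#' @inheritParams foot_to_foot
#' @return a \code{transit_result}.
#' @export
half_max <- function(asc, desc, smoothing_ms = 20) {
  ha <- half_max_time(asc, smoothing_ms)
  hd <- half_max_time(desc, smoothing_ms)
  transit_result("half_max", ha$ta, hd$ta, hd$ta - ha$ta,
                 list(peaks = c(ha$peak, hd$peak)))
}

#' Transit time by cross-correlation
#'
#' The lag maximising the normalised cross-correlation of the two
#' mean-removed curves over a bounded search window, refined to sub-sample
#' precision by parabolic interpolation around the integer-lag peak. Uses
#' the whole curve, not just the upslope, so dispersion between the sites
#' tends to bias it low relative to half-max.
#'
#' The estimator works on a refined common grid: both curves are low-pass
#' filtered (zero-phase Gaussian, \code{smoothing_ms}), trimmed of the
#' filter's edge-affected samples, and linearly resampled to a
#' \code{fine_ms} grid before the lag search; the correlation at each lag
#' is the Pearson coefficient of the overlapping segments, which makes an
#' exact integer-sample shift recover its lag exactly (perfect peak, no
#' refinement applied).
#'
#' @inheritParams foot_to_foot
#' @param max_lag_ms half-width of the lag search window.
#' @param smoothing_ms Gaussian pre-filter SD in ms.
#' @param fine_ms internal lag grid (ms) for the integer search.
#' @return a \code{transit_result} (\code{ta1}/\code{ta2} are \code{NA}: the
#'   method produces only a delay).
#' @export
cross_correlation <- function(asc, desc, max_lag_ms = 100,
                              smoothing_ms = 10, fine_ms = 1) {
  if (length(asc$time_ms) != length(desc$time_ms) ||
      max(abs(asc$time_ms - desc$time_ms)) > 1e-9) {
    grid <- seq(max(asc$time_ms[1], desc$time_ms[1]),
                min(tail(asc$time_ms, 1), tail(desc$time_ms, 1)), by = 5)
    asc <- flow_curve(grid, approx(asc$time_ms, asc$v_cm_s, grid)$y, 1L)
    desc <- flow_curve(grid, approx(desc$time_ms, desc$v_cm_s, grid)$y, 2L)
  }
  t <- asc$time_ms
  a <- gauss_smooth_ms(asc$v_cm_s, t, smoothing_ms)
  b <- gauss_smooth_ms(desc$v_cm_s, t, smoothing_ms)
  if (smoothing_ms > 0) {
    # drop the edge-padding-affected samples so shifts stay exact
    r0 <- ceiling(3 * smoothing_ms / median(diff(t)))
    keep <- (r0 + 1):(length(t) - r0)
    if (length(keep) < 10)
      pwv_error("aortapwv_boundary_peak", "curve too short for lag search")
    t <- t[keep]; a <- a[keep]; b <- b[keep]
  }
  g <- seq(t[1], tail(t, 1), by = fine_ms)
  a <- approx(t, a, g)$y
  b <- approx(t, b, g)$y
  L <- max(1L, as.integer(floor(max_lag_ms / fine_ms)))
  n <- length(a)
  if (n - L < 10)
    pwv_error("aortapwv_boundary_peak", "curve too short for lag search")
  r <- vapply(-L:L, function(l) {
    ia <- seq_len(n - abs(l))
    if (l >= 0) { x <- a[ia]; y <- b[ia + l] } else { x <- a[ia - l]; y <- b[ia] }
    if (sd(x) == 0 || sd(y) == 0) return(0)
    stats::cor(x, y)
  }, numeric(1))
  im <- which.max(r)
  if (im == 1L || im == length(r))
    pwv_error("aortapwv_boundary_peak",
              "correlation peak at the lag search boundary (%g ms)",
              (im - 1L - L) * fine_ms)
  # parabolic sub-sample refinement; a perfect correlation peak means an
  # exact integer-lag alignment, so refinement is skipped there
  y1 <- r[im - 1]; y2 <- r[im]; y3 <- r[im + 1]
  denom <- y1 - 2 * y2 + y3
  delta <- if (1 - y2 < 1e-12 || abs(denom) < 1e-12) 0
           else 0.5 * (y1 - y3) / denom
  lag <- (im - 1L - L + delta) * fine_ms
  transit_result("cross_correlation", NA_real_, NA_real_, lag,
                 list(peak_corr = y2, lag_grid_ms = fine_ms))
}

#' Combine arch length and transit time into PWV
#'
#' \code{PWV = L / dt} with L in mm and dt in ms (mm/ms = m/s). PWV values
#' above the measurability cap of the 5 ms VE temporal resolution (19 m/s)
#' are still reported numerically but flagged as high PWV.
#'
#' @param length_mm aortic arch length (positive).
#' @param transit a \code{transit_result} with positive \code{dt_ms}.
#' @param high_pwv_m_s flag threshold (m/s).
#' @return object of class \code{pwv_result}.
#' @export
compute_pwv <- function(length_mm, transit, high_pwv_m_s = 19) {
  if (length_mm <= 0) stop("`length_mm` must be positive")
  if (!is.finite(transit$dt_ms) || transit$dt_ms <= 0)
    pwv_error("aortapwv_nonphysical_transit",
              "%s transit time is not positive (%.2f ms)",
              transit$method, transit$dt_ms)
  pwv <- length_mm / transit$dt_ms
  structure(list(length_mm = length_mm, dt_ms = transit$dt_ms,
                 pwv_m_s = pwv, high_pwv = pwv > high_pwv_m_s,
                 method = transit$method),
            class = "pwv_result")
}

#' @export
print.pwv_result <- function(x, ...) {
  cat(sprintf("<pwv_result> %s: L = %.1f mm, dt = %.2f ms, PWV = %.2f m/s%s\n",
              x$method, x$length_mm, x$dt_ms, x$pwv_m_s,
              if (x$high_pwv) " [high-PWV flag]" else ""))
  invisible(x)
}
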