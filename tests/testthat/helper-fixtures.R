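# Shared fixtures, all built in code.

# a straight vertical "curve" object compatible with rasterize_tube /
# phantom_truth: runs along -y from y = 0 down to y = -length_mm
straight_curve <- function(length_mm = 100) {
  fun <- function(s) cbind(0, -pmin(pmax(s, 0), length_mm), 0)
  structure(list(points = fun(seq(0, length_mm, length.out = 1000)),
                 fun = fun, s_max = length_mm, arc_length_mm = length_mm,
                 params = list()),
            class = "aorta_curve")
}

# axis-aligned solid cylinder label (axis along x), unit spacing
cylinder_label <- function(nx = 31, ny = 9, nz = 9, r = 3) {
  lab <- array(0L, c(nx, ny, nz))
  cy <- (ny + 1) / 2; cz <- (nz + 1) / 2
  for (j in 1:ny) for (k in 1:nz)
    if ((j - cy)^2 + (k - cz)^2 <= r^2) lab[, j, k] <- 1L
  volume3d(lab, c(1, 1, 1))
}

# small tube phantom pair used across registration tests
small_phantom <- function(seed = 11, tilt = 4) {
  curve <- make_aorta_curve(45, c(50, 50), tilt_deg = tilt,
                            perturb_mm = 1, seed = seed)
  rasterize_tube(curve, 10, grid = phantom_grid(), noise_sd = 2, seed = seed)
}

# synthetic magnitude frame with one bright disk, [x, y] indexing
disk_frame <- function(n = 64, cx = 31, cy = 33, r = 15, lo = 20, hi = 100) {
  fr <- matrix(lo, n, n)
  for (i in 1:n) for (j in 1:n)
    if ((i - 1 - cx)^2 + (j - 1 - cy)^2 <= r^2) fr[i, j] <- hi
  fr
}

expect_error_class <- function(expr, class) {
  testthat::expect_error(expr, class = class)
}
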