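test_that("thinning collapses a straight tube to its axis", {
  tube <- cylinder_label(nx = 31, r = 2)
  sk <- skeletonize_3d(tube)
  idx <- which(sk$data > 0, arr.ind = TRUE)
  # one-voxel-wide chain on the analytic axis
  expect_true(all(idx[, 2] == 5) && all(idx[, 3] == 5))
  expect_true(all(tube$data[sk$data > 0] == 1))   # skeleton subset of mask
  # cap erosion is bounded by the tube radius at each end
  expect_lte(abs(nrow(idx) - 31), 2 * 2)

  # a thin tube keeps the endpoint-to-endpoint count within 2 of its length
  thin <- cylinder_label(nx = 31, r = 1)
  idx2 <- which(skeletonize_3d(thin)$data > 0, arr.ind = TRUE)
  expect_true(all(idx2[, 2] == 5) && all(idx2[, 3] == 5))
  expect_lte(abs(nrow(idx2) - 31), 2)
})

test_that("thinning preserves topology and fixed points", {
  v <- volume3d(array(0L, c(5, 5, 5)), c(1, 1, 1))
  v$data[3, 3, 3] <- 1L
  expect_identical(skeletonize_3d(v)$data, v$data)  # single voxel fixed

  phant <- small_phantom(seed = 14)
  sk <- skeletonize_3d(phant$label)
  n_before <- max(aortapwv:::cpp_label_cc(as.integer(phant$label$data > 0),
                                          dim(phant$label$data), 26L))
  n_after <- max(aortapwv:::cpp_label_cc(as.integer(sk$data > 0),
                                         dim(sk$data), 26L))
  expect_identical(n_before, n_after)
  # skeleton voxels lie inside the mask (compared in world coordinates:
  # anisotropic masks are thinned on an isotropic resampling)
  idx <- which(sk$data > 0)
  d <- dim(sk$data)
  ijk <- cbind((idx - 1) %% d[1], ((idx - 1) %/% d[1]) %% d[2],
               (idx - 1) %/% (d[1] * d[2]))
  mv <- round(world_to_voxel(phant$label, voxel_to_world(sk, ijk)))
  expect_true(all(phant$label$data[mv + 1] == 1))

  expect_error_class(skeletonize_3d(volume3d(array(0L, c(4, 4, 4)),
                                             c(1, 1, 1))),
                     "aortapwv_invalid_input")
})

test_that("pruning keeps the two long arms of a Y and drops the short one", {
  y <- array(0L, c(25, 25, 3))
  y[3:13, 12, 2] <- 1L               # arm A (11 voxels to the junction)
  y[13, 13:22, 2] <- 1L              # arm B (10 voxels)
  for (t in 1:3) y[13 + t, 12 - t, 2] <- 1L  # short diagonal arm C
  vy <- volume3d(y, c(1, 1, 1))
  p <- prune_to_path(skeletonize_3d(vy), smooth_mm = 0)
  # endpoints of the two long arms present, arm C absent
  pts <- round(world_to_voxel(vy, unclass(p)))
  has <- function(i, j) any(pts[, 1] == i & pts[, 2] == j)
  expect_true(has(2, 11))            # 0-based (3,12) end of arm A
  expect_true(has(12, 21))           # end of arm B
  for (t in 1:3) expect_false(has(12 + t, 11 - t))
})

test_that("a simple chain passes through pruning unchanged", {
  ch <- array(0L, c(20, 3, 3))
  ch[2:18, 2, 2] <- 1L
  v <- volume3d(ch, c(1, 1, 1))
  p <- prune_to_path(v, smooth_mm = 0)   # already a skeleton
  expect_equal(nrow(p), 17)
  expect_equal(attr(p, "length_mm"), 16)
})

test_that("pruned path equals the brute-force tree diameter", {
  # oracle: exhaustive DFS over all vertex pairs of a random tree
  dfs_path_len <- function(adj, w, from, to) {
    n <- length(adj)
    seen <- rep(FALSE, n); seen[from] <- TRUE
    rec <- function(v, acc) {
      if (v == to) return(acc)
      for (e in adj[[v]]) {
        if (!seen[e$to]) {
          seen[e$to] <<- TRUE
          r <- rec(e$to, acc + e$w)
          if (!is.na(r)) return(r)
        }
      }
      NA_real_
    }
    rec(from, 0)
  }
  for (s in 1:5) {
    set.seed(s)
    n <- 20
    parent <- c(0, vapply(2:n, function(i) sample.int(i - 1, 1), 0L))
    w <- runif(n - 1, 0.5, 3)
    g <- igraph::make_graph(rbind(2:n, parent[2:n]), n = n,
                            directed = FALSE)
    igraph::E(g)$weight <- w
    adj <- lapply(1:n, function(v) list())
    for (e in seq_len(n - 1)) {
      a <- 2:n; b <- parent[2:n]
      adj[[a[e]]] <- c(adj[[a[e]]], list(list(to = b[e], w = w[e])))
      adj[[b[e]]] <- c(adj[[b[e]]], list(list(to = a[e], w = w[e])))
    }
    best <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      best <- max(best, dfs_path_len(adj, w, i, j))
    path <- aortapwv:::graph_diameter_path(g)
    len <- sum(w[igraph::get_edge_ids(
      g, rbind(path[-length(path)], path[-1]))])
    expect_equal(len, best, tolerance = 1e-12)
  }
})

test_that("cutting planes are constructed and oriented correctly", {
  p <- plane_from_points(c(0, 0, 5), c(1, 0, 5), c(0, 1, 5))
  expect_equal(sqrt(sum(p$normal^2)), 1, tolerance = 1e-12)
  for (pt in list(c(0, 0, 5), c(1, 0, 5), c(0, 1, 5)))
    expect_equal(sum(p$normal * pt), p$d, tolerance = 1e-9)

  # axial slice at z0 with the arch above: n = (0,0,1), d = z0
  ve <- list(origin = c(-10, -10, 7), row_dir = c(1, 0, 0),
             col_dir = c(0, 1, 0), pixel_mm = c(1, 1),
             magnitude = array(0, c(4, 4, 2)))
  class(ve) <- "ve_series"
  pl <- ve_plane_from_series(ve, above_point = c(0, 0, 50))
  expect_equal(pl$normal, c(0, 0, 1))
  expect_equal(pl$d, 7)
  ve$row_dir <- NULL
  expect_error_class(ve_plane_from_series(ve), "aortapwv_missing_geometry")

  # phantom sidecar plane contains both seed points
  truth <- phantom_truth(make_aorta_curve(45, c(50, 50)), dt_ms = 12)
  ve2 <- make_ve_series(truth)
  pl2 <- ve_plane_from_series(ve2, above_point = c(0, 45, 0))
  expect_equal(as.numeric(truth$seeds %*% pl2$normal) - pl2$d, c(0, 0),
               tolerance = 1e-6)
})

test_that("clipping measures the semicircle closed form", {
  th <- seq(0, pi, length.out = 4000)
  semi <- cbind(50 * cos(th), 50 * sin(th), 0)
  # plane below everything: full length, endpoint seeds
  below <- cutting_plane(c(0, 1, 0), -10)
  full <- clip_and_measure(semi, below)
  expect_equal(full$length_mm, pi * 50, tolerance = 0.01)
  expect_equal(full$seeds, semi[c(1, 4000), ])

  # diameter plane through the chord height h: arc = R(pi - 2 asin(h/R))
  ph <- cutting_plane(c(0, 1, 0), 10)
  cl <- clip_and_measure(semi, ph)
  expect_equal(cl$length_mm, 50 * (pi - 2 * asin(10 / 50)), tolerance = 0.01)
  expect_equal(cl$seeds[, 2], c(10, 10), tolerance = 1e-9)

  expect_error_class(clip_and_measure(semi, cutting_plane(c(0, 1, 0), 100)),
                     "aortapwv_topology")
})

test_that("clipped length is rigid-invariant and monotone in plane height", {
  th <- seq(0, pi, length.out = 2000)
  semi <- cbind(50 * cos(th), 50 * sin(th), 0)
  pl <- cutting_plane(c(0, 1, 0), 5)
  L0 <- clip_and_measure(semi, pl)$length_mm

  R <- rotation_matrix("z", 33, center = c(4, -2, 1))
  semi_r <- cbind(semi, 1) %*% t(R)
  n_r <- as.numeric(R[1:3, 1:3] %*% pl$normal)
  d_r <- pl$d + sum(n_r * R[1:3, 4])
  Lr <- clip_and_measure(semi_r[, 1:3], cutting_plane(n_r, d_r))$length_mm
  expect_equal(Lr, L0, tolerance = 1e-6)

  lens <- vapply(seq(-5, 45, by = 5), function(d)
    clip_and_measure(semi, cutting_plane(c(0, 1, 0), d))$length_mm,
    numeric(1))
  expect_true(all(diff(lens) <= 1e-9))
})

test_that("phantom arch length is recovered within one slice thickness", {
  curve <- make_aorta_curve(45, c(50, 50), tilt_deg = 5, perturb_mm = 1,
                            seed = 2)
  ras <- rasterize_tube(curve, 10)
  truth <- phantom_truth(curve, pwv_m_s = 10)
  path <- prune_to_path(skeletonize_3d(ras$label))
  est <- clip_and_measure(path, truth$plane)
  expect_lte(abs(est$length_mm - truth$L_true_mm), 5)
})

test_that("seed projection maps world points to VE pixels", {
  truth <- phantom_truth(make_aorta_curve(45, c(50, 50)), dt_ms = 12)
  ve <- make_ve_series(truth)
  expect_equal(project_seeds(rbind(ve$origin), ve)[1, ],
               c(px = 0, py = 0), tolerance = 1e-9)
  expect_equal(project_seeds(rbind(ve$origin + 10 * ve$pixel_mm[1] *
                                     ve$row_dir), ve)[1, ],
               c(px = 10, py = 0), tolerance = 1e-9)
  # the phantom seed points land on the generated disk centres
  sp <- project_seeds(truth$seeds, ve)
  expect_lt(max(abs(sp - ve$truth_px$centres)), 1)
  expect_error_class(project_seeds(rbind(ve$origin - 50 * ve$row_dir), ve),
                     "aortapwv_outside_fov")
})
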