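phant <- small_phantom(seed = 11)

test_that("mutual information behaves like an information measure", {
  vol <- phant$volume
  # identical images under identity: joint histogram is diagonal, so MI
  # equals the marginal entropy (oracle: direct entropy of the binned data)
  mi <- mutual_information(vol, vol, bins = 32)
  v <- as.numeric(vol$data)
  bin <- pmin(floor((v - min(v)) / diff(range(v)) * 32) + 1, 32)
  p <- tabulate(bin, 32) / length(bin)
  entropy <- -sum(p[p > 0] * log(p[p > 0]))
  expect_equal(mi, entropy, tolerance = 1e-9)

  # independence: MI against a constant image is zero
  con <- vol
  con$data <- array(7, dim(vol$data))
  expect_equal(mutual_information(vol, con), 0)

  # identity pose beats shifted poses for a noiseless self-pair
  for (shift in list(c(20, 0, 0), c(0, 20, 0), c(8, -8, 5))) {
    ch <- transform_chain(list(affine_stage(translation_matrix(shift))))
    expect_gt(mi, mutual_information(vol, vol, chain = ch))
  }

  expect_error(mutual_information(vol, vol, bins = 4), "bins")
})

test_that("affine stage recovers a known translation within one voxel", {
  mov <- phant$volume
  mov$origin <- mov$origin + c(8, 0, 0)   # true map: x -> x + 8
  ch <- register_stage(phant$volume, mov, "affine", seed = 1)
  M <- ch$stages[[1]]$matrix
  expect_lt(max(abs(M[1:3, 4] - c(8, 0, 0))), 1.76)
  expect_lt(max(abs(M[1:3, 1:3] - diag(3))), 0.05)
})

test_that("register_stage validates input and is deterministic", {
  expect_error(register_stage(phant$volume, phant$volume, "affine",
                              iterations = 0), "iterations")
  a <- register_stage(phant$volume, phant$volume, "affine",
                      iterations = 48, n_samples = 256, seed = 5)
  b <- register_stage(phant$volume, phant$volume, "affine",
                      iterations = 48, n_samples = 256, seed = 5)
  expect_identical(a$stages[[1]]$matrix, b$stages[[1]]$matrix)
})

test_that("grossly non-overlapping volumes raise insufficient-overlap", {
  far <- phant$volume
  far$origin <- far$origin + c(1500, 0, 0)
  expect_error_class(
    register_stage(phant$volume, far, "affine", iterations = 8,
                   n_samples = 256, seed = 1),
    "aortapwv_insufficient_overlap")
  expect_error_class(mutual_information(phant$volume, far),
                     "aortapwv_insufficient_overlap")
})

test_that("self-registration reproduces the label almost perfectly", {
  atlas <- list(volume = phant$volume, label = phant$label)
  ch <- register_atlas(phant$volume, atlas, seed = 2,
                       iterations = c(256, 512), n_samples = 1024)
  lab <- transform_label(atlas$label, ch, phant$volume)
  expect_gte(label_dice(lab, atlas$label), 0.99)
})

test_that("a known rigid pose is recovered to high label overlap", {
  atlas <- small_phantom(seed = 12, tilt = 2)
  A <- rotation_matrix("z", 6, center = c(0, 5, 0)) %*%
    translation_matrix(c(5, -4, 2))
  truth_chain <- transform_chain(list(affine_stage(A)))
  subject <- resample_volume(atlas$volume, truth_chain)
  true_label <- resample_volume(atlas$label, truth_chain,
                                interp = "nearest")
  ch <- register_atlas(subject, atlas, seed = 3,
                       iterations = c(256, 512), n_samples = 1024)
  est <- transform_label(atlas$label, ch, subject)
  expect_gte(label_dice(est, true_label), 0.9)
})

test_that("transform_label handles identity, integer shifts and scaling", {
  lab <- phant$label
  expect_identical(transform_label(lab, identity_chain(), lab)$data,
                   as.integer(lab$data > 0) + array(0L, dim(lab$data)))

  # pure integer-voxel translation shifts the voxel set exactly
  sh <- translation_matrix(c(2 * lab$spacing[1], 0, 0))
  out <- transform_label(lab, transform_chain(list(affine_stage(sh))), lab)
  d <- dim(lab$data)
  expect_identical(out$data[1:(d[1] - 2), , ],
                   array(as.integer(lab$data[3:d[1], , ] > 0),
                         c(d[1] - 2, d[2], d[3])))

  # affine scaling changes the label volume by the Jacobian (oracle:
  # analytic volume scaling; chain maps target -> source, so 1/1.1 grows)
  sc <- diag(4) * (1 / 1.1); sc[4, 4] <- 1
  idx <- which(lab$data > 0)
  ijk <- cbind((idx - 1) %% d[1], ((idx - 1) %/% d[1]) %% d[2],
               (idx - 1) %/% (d[1] * d[2]))
  ctr <- colMeans(voxel_to_world(lab, ijk))
  sc[1:3, 4] <- ctr - ctr / 1.1
  out <- transform_label(lab, transform_chain(list(affine_stage(sc))), lab)
  expect_equal(sum(out$data) / sum(lab$data), 1.1^3, tolerance = 0.1)
})

test_that("label fusion is a majority vote with ties to foreground", {
  lab <- phant$label
  fused <- fuse_labels(rep(list(lab), 8))
  expect_gte(label_dice(fused, lab), 0.999)  # unanimity (single component)

  # hand-built 5-of-8 / 4-of-8 / 3-of-8 voxels
  mk <- function(on) {
    l <- volume3d(array(0L, c(3, 3, 3)), c(1, 1, 1))
    if (on) l$data[2, 2, 2] <- 1L
    l
  }
  votes <- function(k) fuse_labels(c(rep(list(mk(TRUE)), k),
                                     rep(list(mk(FALSE)), 8 - k)),
                                   keep_largest = FALSE)$data[2, 2, 2]
  expect_identical(votes(5), 1L)
  expect_identical(votes(4), 1L)  # tie -> foreground
  expect_identical(votes(3), 0L)

  expect_error(fuse_labels(list()), "at least one")
})

test_that("fusion equals a per-voxel counting oracle and is symmetric", {
  set.seed(42)
  labs <- lapply(1:5, function(i)
    volume3d(array(as.integer(runif(125) > 0.5), c(5, 5, 5)), c(1, 1, 1)))
  fused <- fuse_labels(labs, keep_largest = FALSE)
  # oracle: explicit counting loop
  oracle <- array(0L, c(5, 5, 5))
  for (i in 1:5) for (j in 1:5) for (k in 1:5) {
    n_fg <- 0
    for (l in labs) n_fg <- n_fg + (l$data[i, j, k] > 0)
    oracle[i, j, k] <- as.integer(n_fg >= 5 / 2)
  }
  expect_identical(fused$data, oracle)

  # permutation invariance
  perm <- fuse_labels(labs[c(3, 1, 5, 2, 4)], keep_largest = FALSE)
  expect_identical(perm$data, fused$data)
})
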