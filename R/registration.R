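pwv_error <- function(class, msg, ...) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

#' Mutual information between two volumes
#'
#' Similarity measure used by the registration stages: mutual information in
#' nats from a joint histogram of intensity pairs sampled at fixed-image
#' voxel centres, with the second volume read through an optional transform
#' chain. Higher values mean more similar images.
#'
#' @param a fixed \code{volume3d}.
#' @param b moving \code{volume3d}, read at the mapped sample positions.
#' @param chain \code{transform_chain} mapping fixed world to moving world.
#' @param bins number of histogram bins per image (>= 8).
#' @param n_samples number of voxel samples, NULL = all fixed voxels.
#' @param seed seed for the sample draw (only used when subsampling).
#' @return mutual information in nats.
#' @export
mutual_information <- function(a, b, chain = identity_chain(), bins = 32,
                               n_samples = NULL, seed = NULL) {
  if (bins < 8) stop("`bins` must be >= 8")
  d <- vol_dim(a)
  nvox <- prod(d)
  idx <- seq_len(nvox)
  if (!is.null(n_samples) && n_samples < nvox) {
    if (!is.null(seed)) set.seed(seed)
    idx <- sample.int(nvox, n_samples)
  }
  ijk <- cbind((idx - 1) %% d[1],
               ((idx - 1) %/% d[1]) %% d[2],
               (idx - 1) %/% (d[1] * d[2]))
  pts <- apply_transform(chain, voxel_to_world(a, ijk))
  fv <- as.numeric(a$data)[idx]
  mv <- sample_volume(b, pts)
  ok <- !is.na(mv)
  if (sum(ok) < 100)
    pwv_error("aortapwv_insufficient_overlap",
              "only %d valid overlapping samples (need >= 100)", sum(ok))
  mi_nats(fv[ok], mv[ok], bins)
}

mi_nats <- function(fv, mv, bins) {
  bin <- function(v) {
    r <- range(v)
    if (r[2] <= r[1]) return(rep(1L, length(v)))
    pmin(pmax(floor((v - r[1]) / (r[2] - r[1]) * bins) + 1L, 1L), bins)
  }
  joint <- table(factor(bin(fv), levels = 1:bins),
                 factor(bin(mv), levels = 1:bins))
  p <- joint / sum(joint)
  pf <- rowSums(p); pm <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(pf, pm)[nz]))
}

# per-resolution schedule of the coarse-to-fine pyramid: three resolutions,
# in-plane factors 4/2/1 with a milder through-plane schedule (slices are
# already 5 mm thick)
pyramid_schedule <- function() {
  list(factors = rbind(c(4, 4, 2), c(2, 2, 1), c(1, 1, 1)))
}

#' One registration stage (affine or B-spline)
#'
#' Optimises mutual information between the fixed and moving volumes by
#' stochastic gradient ascent (Parzen-window MI with analytic gradient,
#' normalised gradient direction, decaying gain) over a three-level
#' coarse-to-fine pyramid. When a mask is given, samples are drawn only
#' inside it on the fixed grid. The new stage is optimised on top of the
#' (affine-only) \code{init} chain and returned appended to it. Defaults per
#' the protocol: 512 iterations for affine stages, 2048 for B-spline, 15 mm
#' B-spline control grid, 2048 samples per iteration.
#'
#' @param fixed,moving \code{volume3d} images (fixed = subject).
#' @param model \code{"affine"} or \code{"bspline"}.
#' @param mask optional binary \code{volume3d} on the fixed grid restricting
#'   the sampling domain.
#' @param init \code{transform_chain} of affine stages initialising this one.
#' @param iterations gradient iterations per resolution level (>= 1).
#' @param grid_spacing_mm B-spline control-point spacing.
#' @param n_samples stochastic samples per iteration.
#' @param bins histogram bins for the MI estimate.
#' @param seed RNG seed for the stochastic sampling.
#' @param step0_mm initial gain (mm) per level; defaults scale with the
#'   pyramid level.
#' @return the \code{init} chain extended by the optimised stage. If the MI
#'   trend over the final level decreases, a warning is issued; the
#'   best-seen parameters are returned in all cases.
#' @export
register_stage <- function(fixed, moving, model = c("affine", "bspline"),
                           mask = NULL, init = NULL, iterations = NULL,
                           grid_spacing_mm = 15, n_samples = 2048, bins = 32,
                           seed = NULL, step0_mm = NULL) {
  model <- match.arg(model)
  if (is.null(init)) init <- identity_chain()
  if (is.null(iterations)) iterations <- if (model == "affine") 512 else 2048
  if (iterations < 1) stop("`iterations` must be >= 1")
  A0 <- chain_for_cpp(init)
  if (!is.null(A0$bspline))
    stop("`init` must contain affine stages only")
  A0 <- A0$affine
  if (!is.null(seed)) set.seed(seed)

  sched <- pyramid_schedule()
  nlev <- nrow(sched$factors)
  if (is.null(step0_mm))
    step0_mm <- if (model == "affine") c(2, 1, 0.5) else c(1, 0.6, 0.3)
  step0_mm <- rep_len(step0_mm, nlev)

  # B-spline control grid over the moving domain (+ margin)
  bs <- NULL
  if (model == "bspline") {
    ext <- (vol_dim(moving) - 1) * moving$spacing
    gdims <- as.integer(ceiling(ext / grid_spacing_mm)) + 4L
    bs <- list(origin = moving$origin - grid_spacing_mm,
               spacing = rep(grid_spacing_mm, 3), dims = gdims,
               coef = array(0, c(gdims, 3L)))
  }

  S_total <- diag(4)  # affine accumulated over levels
  trace_final <- NULL
  for (lev in seq_len(nlev)) {
    f <- sched$factors[lev, ]
    fl <- pyramid_level(fixed, f)
    ml <- pyramid_level(moving, f)
    cand <- mask_candidates(mask, f, vol_dim(fl))
    # characteristic radius + centre for affine parameter scaling
    sub <- cand[seq(1, length(cand), length.out = min(500, length(cand)))]
    ijk <- cbind((sub - 1) %% dim(fl$data)[1],
                 ((sub - 1) %/% dim(fl$data)[1]) %% dim(fl$data)[2],
                 (sub - 1) %/% (dim(fl$data)[1] * dim(fl$data)[2]))
    w <- voxel_to_world(fl, ijk)
    w <- cbind(w, 1) %*% t(S_total %*% A0)
    ctr <- colMeans(w[, 1:3, drop = FALSE])
    rho <- mean(sqrt(rowSums(sweep(w[, 1:3, drop = FALSE], 2, ctr)^2)))
    rho <- max(rho, 10)

    res <- cpp_register_stage(
      as.numeric(fl$data), dim(fl$data), fl$spacing, fl$origin, fl$direction,
      as.numeric(ml$data), dim(ml$data), ml$spacing, ml$origin, ml$direction,
      as.integer(cand - 1L),
      if (model == "affine") 0L else 1L,
      if (model == "affine") S_total %*% A0 else A0,
      if (model == "bspline") bs else NULL,
      ctr, as.integer(iterations), as.integer(n_samples), as.integer(bins),
      step0_mm[lev], max(iterations / 10, 1), 0.602, rho)
    if (isTRUE(res$insufficient_overlap))
      pwv_error("aortapwv_insufficient_overlap",
                "insufficient overlap between fixed and moving volumes (valid fraction %.2f)",
                res$valid_frac)
    if (model == "affine") {
      p <- res$params
      S <- diag(4)
      S[1:3, 1:3] <- diag(3) + matrix(p[1:9], 3, byrow = TRUE) / rho
      S[1:3, 4] <- p[10:12] - (S[1:3, 1:3] - diag(3)) %*% ctr
      S_total <- S %*% S_total
    } else {
      bs$coef <- array(res$params, c(bs$dims, 3L))
    }
    trace_final <- res$mi_trace
  }

  # divergence check on the final level: the MI trace is stochastic, so a
  # decrease only counts when it exceeds the trace's own noise level
  n <- length(trace_final)
  if (n >= 20) {
    seg <- max(2, n %/% 4)
    a1 <- mean(head(trace_final, seg))
    a2 <- mean(tail(trace_final, seg))
    if (a2 < a1 - sd(trace_final))
      warning("mutual information decreased over the final level; returning best-seen transform")
  }

  stage <- if (model == "affine") affine_stage(S_total)
           else bspline_stage(bs$origin, bs$spacing, bs$dims, bs$coef)
  transform_chain(c(init$stages, list(stage)))
}

mask_candidates <- function(mask, factor, dims_level) {
  if (is.null(mask)) return(seq_len(prod(dims_level)))
  m <- mask
  m$data <- array(as.numeric(m$data > 0), dim(m$data))
  m <- pyramid_level(m, factor)
  cand <- which(m$data > 0.05)
  if (length(cand) == 0) cand <- seq_len(prod(dims_level))
  cand
}

#' Register one atlas to a subject (three-stage recipe)
#'
#' Runs the multi-atlas stage recipe: a global affine registration, an affine
#' registration restricted to an aorta mask, then a B-spline registration
#' with the same mask, each initialised by the previous stage. The mask is
#' the atlas aorta label dilated two voxels in-plane (no through-plane
#' dilation), warped onto the subject grid with the current chain estimate.
#' The subject is the fixed image and the atlas the moving image, so the
#' atlas label can be resampled directly onto the subject grid afterwards.
#'
#' @param subject \code{volume3d} to segment.
#' @param atlas list(volume, label) with the binary aorta label on the atlas
#'   grid.
#' @param seed RNG seed.
#' @param iterations length-2: affine and B-spline iterations per level.
#' @param grid_spacing_mm B-spline control-point spacing.
#' @param n_samples stochastic samples per iteration.
#' @return \code{transform_chain} with three stages.
#' @export
register_atlas <- function(subject, atlas, seed = NULL,
                           iterations = c(512, 2048), grid_spacing_mm = 15,
                           n_samples = 2048) {
  if (!is.null(seed)) set.seed(seed)
  dil <- atlas$label
  dil$data <- dilate_inplane(dil$data > 0, 2L)
  ch1 <- register_stage(subject, atlas$volume, "affine",
                        iterations = iterations[1], n_samples = n_samples)
  m1 <- transform_label(dil, ch1, subject)
  ch2 <- register_stage(subject, atlas$volume, "affine", mask = m1,
                        init = ch1, iterations = iterations[1],
                        n_samples = n_samples)
  m2 <- transform_label(dil, ch2, subject)
  register_stage(subject, atlas$volume, "bspline", mask = m2, init = ch2,
                 iterations = iterations[2],
                 grid_spacing_mm = grid_spacing_mm, n_samples = n_samples)
}

# in-plane (x,y) binary dilation by a disk of `r` voxels
dilate_inplane <- function(mask, r = 2L) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (dx in (-r):r) for (dy in (-r):r) {
    if (dx * dx + dy * dy > r * r) next
    xs <- max(1, 1 + dx):min(d[1], d[1] + dx)
    xt <- max(1, 1 - dx):min(d[1], d[1] - dx)
    ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
    yt <- max(1, 1 - dy):min(d[2], d[2] - dy)
    out[xt, yt, ] <- out[xt, yt, ] | mask[xs, ys, , drop = FALSE]
  }
  array(as.integer(out), d)
}

#' Warp a binary label through a transform chain
#'
#' Nearest-neighbour resampling of a (moving-grid) label onto a target grid:
#' each target voxel is mapped through the chain and the label read at the
#' mapped position. Output is binary.
#'
#' @param label binary \code{volume3d} on the moving (atlas) grid.
#' @param chain \code{transform_chain} from target world to label world.
#' @param target \code{volume3d} providing the output grid.
#' @return binary \code{volume3d} on the target grid.
#' @export
transform_label <- function(label, chain, target) {
  cc <- chain_for_cpp(chain)
  td <- vol_dim(target)
  out <- cpp_resample_volume(
    as.numeric(label$data), dim(label$data), label$spacing, label$origin,
    label$direction, td, target$spacing, target$origin, target$direction,
    cc$affine, cc$bspline, 0L, 0)
  volume3d(array(as.integer(out > 0.5), td), target$spacing, target$origin,
           target$direction)
}

#' Resample a volume through a transform chain
#'
#' Like \code{transform_label()} but for scalar images: each target voxel is
#' mapped through the chain and the source read there with trilinear (or
#' nearest-neighbour) interpolation. Useful for simulating a subject scan as
#' a known rigid/affine deformation of an atlas.
#'
#' @param src source \code{volume3d}.
#' @param chain \code{transform_chain} from target world to source world.
#' @param target \code{volume3d} providing the output grid (defaults to the
#'   source grid).
#' @param interp \code{"linear"} or \code{"nearest"}.
#' @param background value for points mapped outside the source.
#' @return \code{volume3d} on the target grid.
#' @export
resample_volume <- function(src, chain, target = src, interp = "linear",
                            background = 0) {
  cc <- chain_for_cpp(chain)
  td <- vol_dim(target)
  out <- cpp_resample_volume(
    as.numeric(src$data), dim(src$data), src$spacing, src$origin,
    src$direction, td, target$spacing, target$origin, target$direction,
    cc$affine, cc$bspline, if (interp == "nearest") 0L else 1L, background)
  volume3d(array(out, td), target$spacing, target$origin, target$direction)
}

#' Fuse candidate labels by per-voxel majority vote
#'
#' Combines warped atlas labels into one segmentation: a voxel is foreground
#' when at least half of the candidates mark it (ties count as foreground),
#' after which only the largest 26-connected component is retained.
#'
#' @param labels non-empty list of binary \code{volume3d} objects on one grid.
#' @param keep_largest retain only the largest 26-connected component of the
#'   vote result (the default; disable to get the raw majority vote).
#' @return fused binary \code{volume3d}.
#' @export
fuse_labels <- function(labels, keep_largest = TRUE) {
  if (length(labels) == 0) stop("`labels` must contain at least one label")
  d <- vol_dim(labels[[1]])
  for (l in labels)
    if (!all(vol_dim(l) == d)) stop("all labels must share one grid")
  votes <- Reduce(`+`, lapply(labels, function(l) (l$data > 0) * 1L))
  fg <- votes >= length(labels) / 2
  out <- labels[[1]]
  out$data <- if (keep_largest) largest_component(fg)
              else array(as.integer(fg), d)
  out
}
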