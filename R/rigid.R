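#' Rigid (6-DOF) transforms
#'
#' A rigid transform maps a world point `x` (mm) to
#' `R %*% (x - center) + center + translation`, with `R` the rotation
#' composed as `Rz(rz) %*% Ry(ry) %*% Rx(rx)` from the three angles in
#' radians.  Used for positioning initialisation (bone-based alignment of
#' daily anatomy to the planning frame) and for mapping the planning dose
#' onto fraction frames.
#'
#' @param rotation Angles (rx, ry, rz) in radians.
#' @param translation Offsets in mm.
#' @param center Rotation centre in mm.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  stopifnot(length(rotation) == 3, length(translation) == 3,
            length(center) == 3)
  structure(list(rotation = as.numeric(rotation),
                 translation = as.numeric(translation),
                 center = as.numeric(center)),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @export
rigid_identity <- function() rigid_transform()

rotation_matrix <- function(angles) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Apply a rigid transform to points
#' @param transform A [rigid_transform()].
#' @param pts `n x 3` matrix of world positions (mm).
#' @return Transformed `n x 3` matrix.
#' @export
apply_rigid <- function(transform, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  R <- rotation_matrix(transform$rotation)
  shifted <- sweep(pts, 2, transform$center)
  sweep(shifted %*% t(R), 2,
        transform$center + transform$translation, "+")
}

#' Invert a rigid transform
#' @param transform A [rigid_transform()].
#' @return The inverse transform (same rotation centre).
#' @export
invert_rigid <- function(transform) {
  R <- rotation_matrix(transform$rotation)
  # inverse mapping: x -> Rinv (x - c - t) + c; expressed in the same
  # parameterisation via the matrix form below
  rigid_from_matrix(t(R), as.numeric(-t(R) %*% transform$translation),
                    transform$center)
}

# Build a rigid_transform from an explicit rotation matrix (must be a
# rotation composed as Rz Ry Rx; angles are recovered analytically).
rigid_from_matrix <- function(R, translation, center) {
  ry <- asin(-R[3, 1])
  if (abs(cos(ry)) > 1e-9) {
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
  } else {  # gimbal: fold everything into rx
    rx <- atan2(-R[1, 2], R[2, 2])
    rz <- 0
  }
  rigid_transform(c(rx, ry, rz), translation, center)
}

#' Resample a volume through a rigid transform
#'
#' Pull-back resampling: the output at target-grid position `x` samples the
#' source volume at `transform(x)`.  To place a moving volume into the fixed
#' frame using the transform returned by [rigid_register_bone()] (which maps
#' fixed-frame points onto the corresponding moving-frame points), pass that
#' transform unchanged.
#'
#' @param img `image_volume` or `label_volume`.
#' @param transform A [rigid_transform()].
#' @param target A [grid_spec()]; defaults to the grid of `img`.
#' @param method `"trilinear"`, `"nearest"` or `"bspline"`; labels always use
#'   nearest neighbour.
#' @param frame_id Frame label of the output.
#' @return Resampled volume on `target`.
#' @export
resample_rigid <- function(img, transform, target = vol_grid(img),
                           method = c("trilinear", "nearest", "bspline"),
                           frame_id = img$frame_id) {
  method <- match.arg(method)
  is_label <- inherits(img, "label_volume")
  if (is_label) method <- "nearest"
  R <- rotation_matrix(transform$rotation)
  # target voxel index -> world -> transform -> source voxel index
  A <- R %*% diag(target$spacing) / 1   # world scale of target index
  b <- as.numeric(R %*% (target$origin - transform$center)) +
       transform$center + transform$translation
  M <- cbind(A, b)                      # world position of transformed point
  M <- sweep(M, 1, img$spacing, "/")
  M[, 4] <- M[, 4] - img$origin / img$spacing
  data <- img$data
  storage.mode(data) <- "double"
  if (method == "bspline")
    data <- cpp_bspline_prefilter(data, dim(img$data))
  mcode <- switch(method, nearest = 0L, trilinear = 1L, bspline = 2L)
  out <- cpp_resample_matrix(data, dim(img$data), M, target$shape, mcode)
  if (is_label)
    label_volume(out, target$spacing, target$origin, frame_id)
  else
    image_volume(out, target$spacing, target$origin, frame_id)
}

#' Bone-based rigid registration
#'
#' Recovers the 6-DOF transform aligning a moving anatomy onto a fixed one
#' from their bone-range intensities, emulating the bone-based positioning
#' initialisation used clinically before deformable registration.  The
#' similarity feature is the intensity clamped to the bone window
#' `[bone_hu, bone_hu + 600]`, rescaled and Gaussian smoothed — keeping the
#' sub-voxel information a hard bone mask would quantise away — and the
#' mean squared feature difference is minimised by Nelder-Mead over
#' translation first, then all six parameters, starting from the bone
#' centre-of-mass offset.
#'
#' The returned transform maps fixed-frame points onto moving-frame points,
#' i.e. it is directly usable to pull the moving volume onto the fixed grid
#' with [resample_rigid()].
#'
#' @param fixed,moving `image_volume`s containing bone-range voxels.
#' @param bone_hu Bone threshold in HU (lower end of trabecular bone).
#' @param smooth_vox Gaussian sigma (voxels) applied to the bone feature.
#' @param center Rotation centre; defaults to the fixed bone centre of mass.
#' @return A [rigid_transform()].
#' @export
rigid_register_bone <- function(fixed, moving, bone_hu = 200,
                                smooth_vox = 1.5, center = NULL) {
  fm <- fixed$data > bone_hu
  mm <- moving$data > bone_hu
  if (!any(fm) || !any(mm))
    stop("input error: no voxels above the bone threshold (", bone_hu, " HU)")
  com <- function(mask, vol) {
    idx <- which(mask, arr.ind = TRUE) - 1
    colMeans(sweep(idx %*% diag(vol$spacing), 2, vol$origin, "+"))
  }
  com_f <- com(fm, fixed)
  com_m <- com(mm, moving)
  if (is.null(center)) center <- com_f
  feat <- function(v) gauss_smooth(pmin(pmax(v - bone_hu, 0), 600) / 600,
                                   smooth_vox)
  fs <- feat(fixed$data)
  ms_vol <- image_volume(feat(moving$data), moving$spacing, moving$origin,
                         moving$frame_id)
  tgt <- vol_grid(fixed)
  objective <- function(par) {
    tr <- rigid_transform(par[1:3], par[4:6], center)
    w <- resample_rigid(ms_vol, tr, tgt)
    mean((w$data - fs)^2)
  }
  init_t <- com_m - com_f
  # translation-only refinement, then full 6-DOF
  o1 <- stats::optim(init_t, function(t3) objective(c(0, 0, 0, t3)),
                     method = "Nelder-Mead",
                     control = list(maxit = 200, reltol = 1e-10))
  o2 <- stats::optim(c(0, 0, 0, o1$par), objective, method = "Nelder-Mead",
                     control = list(maxit = 600, reltol = 1e-11,
                                    parscale = c(rep(0.02, 3), rep(1, 3))))
  best <- if (o2$value <= o1$value) o2$par else c(0, 0, 0, o1$par)
  rigid_transform(best[1:3], best[4:6], center)
}

# Separable Gaussian smoothing, sigma in voxels (scalar or per-axis).
gauss_smooth <- function(arr, sigma) {
  sigma <- rep_len(sigma, 3)
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-((-r:r)^2) / (2 * s^2)); k <- k / sum(k)
    arr <- filter_axis(arr, k, ax)
  }
  arr
}

# Convolve along one axis with replicate padding using stats::filter on the
# permuted matrix view (filter() operates column-wise).
filter_axis <- function(arr, k, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  n <- dim(a)[1]
  m <- matrix(a, nrow = n)
  r <- (length(k) - 1) / 2
  padded <- rbind(m[rep(1, r), , drop = FALSE], m,
                  m[rep(n, r), , drop = FALSE])
  f <- stats::filter(padded, k, sides = 2)
  res <- f[(r + 1):(r + n), , drop = FALSE]
  out <- array(res, dim(a))
  aperm(out, order(perm))
}
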