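#' Negated normalised mutual information loss
#'
#' Differentiable similarity loss between two intensity-normalised volumes.
#' Intensities are soft-binned with a triangular Parzen window (each voxel
#' splits its unit mass linearly between the two neighbouring bins), the
#' joint histogram is normalised, and the Studholme NMI
#' \eqn{(H(A)+H(B))/H(A,B)} is returned negated, so that lower values mean
#' more similar images.  NMI lies in \[1, 2\], so the loss lies in
#' \[-2, -1\].
#'
#' For a constant image the marginal entropy vanishes and NMI is undefined;
#' the documented fallback returns the independence floor (-1) with zero
#' gradient rather than NaN.
#'
#' @param a,b `image_volume`s (or bare arrays) normalised to `[0, 1]`.
#' @param bins Histogram bin count, at least 8.
#' @return Scalar loss (negated NMI).
#' @export
nmi_loss <- function(a, b, bins = 32) {
  if (bins < 8) stop("parameter error: bins must be >= 8")
  av <- if (inherits(a, "image_volume")) a$data else a
  bv <- if (inherits(b, "image_volume")) b$data else b
  -cpp_nmi_soft(as.numeric(av), as.numeric(bv), as.integer(bins), FALSE)$nmi
}

# One-hot organ channels (codes 1..4); background is implicit.
one_hot_organs <- function(lab_data) {
  d <- dim(lab_data)
  oh <- array(0, c(d, 4))
  for (i in 1:4) oh[, , , i] <- (lab_data == i) * 1.0
  oh
}

#' One-hot L1 label dissimilarity
#'
#' Mean over voxels of the summed absolute differences of the one-hot organ
#' indicator channels (body, rectum, bladder, prostate; background is
#' implicit).  Computing the L1 norm on indicator channels rather than on
#' the integer codes avoids ordinal artifacts — a bladder/rectum confusion
#' costs the same as a rectum/body confusion.  Two completely disjoint
#' single-organ masks each occupying a volume fraction `f` score `2f`; the
#' loss is 0 iff the label volumes are identical.
#'
#' Warped one-hot channels (fractional values from trilinear warping) are
#' accepted directly, which is how the training loop uses it.
#'
#' @param fixed_labels `label_volume` (or a one-hot array).
#' @param warped_labels `label_volume` or one-hot array on the same grid.
#' @return Scalar loss, non-negative.
#' @export
mask_l1_loss <- function(fixed_labels, warped_labels) {
  to_oh <- function(x) {
    if (inherits(x, "label_volume")) one_hot_organs(x$data)
    else if (is.array(x) && length(dim(x)) == 4L) x
    else stop("validation error: expected a label_volume or one-hot array")
  }
  a <- to_oh(fixed_labels); b <- to_oh(warped_labels)
  if (!identical(dim(a), dim(b)))
    stop("validation error: label representations differ in shape")
  sum(abs(a - b)) / prod(dim(a)[1:3])
}

#' Diffusion smoothness regulariser
#'
#' Mean squared forward-difference spatial gradient of the displacement
#' field, summed over the nine component/direction pairs; displacements are
#' taken in voxel units so the value is resolution-invariant.  Zero for any
#' constant field; a linear field `u = c * x` scores `c^2` per affected
#' component/direction pair.
#'
#' @param field A [deformation_field()] (or a voxel-unit displacement
#'   array `(nx, ny, nz, 3)`).
#' @return Scalar penalty, non-negative.
#' @export
smoothness_loss <- function(field) {
  uv <- if (inherits(field, "deformation_field")) field_to_voxels(field)
        else field
  d <- dim(uv)[1:3]
  total <- 0
  for (comp in 1:3) {
    u <- uv[, , , comp]
    if (d[1] > 1) {
      g <- u[-1, , , drop = FALSE] - u[-d[1], , , drop = FALSE]
      total <- total + mean(g^2)
    }
    if (d[2] > 1) {
      g <- u[, -1, , drop = FALSE] - u[, -d[2], , drop = FALSE]
      total <- total + mean(g^2)
    }
    if (d[3] > 1) {
      g <- u[, , -1, drop = FALSE] - u[, , -d[3], drop = FALSE]
      total <- total + mean(g^2)
    }
  }
  total
}

# Gradient of smoothness_loss with respect to the voxel-unit displacements.
smoothness_grad <- function(uvox) {
  d <- dim(uvox)[1:3]
  g <- array(0, dim(uvox))
  for (comp in 1:3) {
    u <- uvox[, , , comp]
    gc <- array(0, d)
    if (d[1] > 1) {
      diff <- u[-1, , , drop = FALSE] - u[-d[1], , , drop = FALSE]
      s <- 2 / length(diff)
      gc[-1, , ] <- gc[-1, , , drop = FALSE] + s * diff
      gc[-d[1], , ] <- gc[-d[1], , , drop = FALSE] - s * diff
    }
    if (d[2] > 1) {
      diff <- u[, -1, , drop = FALSE] - u[, -d[2], , drop = FALSE]
      s <- 2 / length(diff)
      gc[, -1, ] <- gc[, -1, , drop = FALSE] + s * diff
      gc[, -d[2], ] <- gc[, -d[2], , drop = FALSE] - s * diff
    }
    if (d[3] > 1) {
      diff <- u[, , -1, drop = FALSE] - u[, , -d[3], drop = FALSE]
      s <- 2 / length(diff)
      gc[, , -1] <- gc[, , -1, drop = FALSE] + s * diff
      gc[, , -d[3]] <- gc[, , -d[3], drop = FALSE] - s * diff
    }
    g[, , , comp] <- gc
  }
  g
}

#' Total registration loss of a network variant
#'
#' Combines the variant's similarity terms with the diffusion smoothness
#' penalty: `sc` uses NMI + smoothness, `msk` uses one-hot L1 + smoothness,
#' `sc_msk` uses NMI + L1 + smoothness.  Weights default to the variant's
#' configuration.  Returns the scalar total with the individual components
#' as attributes for logging.
#'
#' @param variant `"sc"`, `"msk"` or `"sc_msk"`.
#' @param fixed,moving Normalised scans (`image_volume`), required for
#'   `sc`/`sc_msk`.
#' @param fixed_labels,moving_labels `label_volume`s, required for
#'   `msk`/`sc_msk`.
#' @param field A [deformation_field()] applied to the moving inputs.
#' @param weights Named list/vector with entries `alpha` (similarity),
#'   `beta` (label L1 in `sc_msk`), `lambda` (smoothness); defaults from
#'   [regnet_config()].
#' @param bins NMI bin count.
#' @return Scalar loss with attribute `components`.
#' @export
total_loss <- function(variant = c("sc", "msk", "sc_msk"),
                       fixed = NULL, moving = NULL,
                       fixed_labels = NULL, moving_labels = NULL,
                       field, weights = NULL, bins = 32) {
  variant <- match.arg(variant)
  w <- default_loss_weights(variant)
  if (!is.null(weights)) w[names(weights)] <- unlist(weights)
  # the smoothness component uses the diffusion regulariser in its
  # conventional normalisation (mean over voxels, directions and
  # components), i.e. smoothness_loss / 9, matching the weights
  comps <- c(nmi = 0, l1 = 0, smooth = smoothness_loss(field) / 9)
  if (variant %in% c("sc", "sc_msk")) {
    if (is.null(fixed) || is.null(moving))
      stop("input error: variant '", variant, "' needs fixed and moving scans")
    comps["nmi"] <- nmi_loss(fixed, warp(moving, field), bins = bins)
  }
  if (variant %in% c("msk", "sc_msk")) {
    if (is.null(fixed_labels) || is.null(moving_labels))
      stop("input error: variant '", variant, "' needs label volumes")
    wl <- warp_one_hot(moving_labels, field)
    comps["l1"] <- mask_l1_loss(fixed_labels, wl)
  }
  total <- switch(variant,
    sc = w[["alpha"]] * comps[["nmi"]] + w[["lambda"]] * comps[["smooth"]],
    msk = w[["alpha"]] * comps[["l1"]] + w[["lambda"]] * comps[["smooth"]],
    sc_msk = w[["alpha"]] * comps[["nmi"]] + w[["beta"]] * comps[["l1"]] +
             w[["lambda"]] * comps[["smooth"]])
  attr(total, "components") <- comps
  total
}

default_loss_weights <- function(variant) {
  switch(variant,
    sc = c(alpha = 1, beta = 0, lambda = 4),
    msk = c(alpha = 2, beta = 0, lambda = 4),
    sc_msk = c(alpha = 1, beta = 2, lambda = 4))
}

# Warp the one-hot organ channels of a label volume (fractional output).
warp_one_hot <- function(labels, field) {
  stopifnot_coregistered(labels, field, "labels and field")
  oh <- one_hot_organs(labels$data)
  cpp_warp_linear(oh, dim(labels$data), 4L, field_to_voxels(field))
}
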