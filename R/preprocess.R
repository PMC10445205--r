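#' Clip and normalise intensities
#'
#' Clamps intensities to `[lo, hi]` and maps that range linearly onto
#' `[0, 1]`.  The defaults (-1024 and 1575 HU) bracket the full clinical
#' CT range from air to dense bone; normalised volumes are what the
#' similarity losses and registration networks consume.
#'
#' @param img An `image_volume`.
#' @param lo,hi Clip bounds in HU, `lo < hi`.
#' @return An `image_volume` with values in `[0, 1]`.
#' @export
clip_normalize <- function(img, lo = -1024, hi = 1575) {
  if (!is.numeric(lo) || !is.numeric(hi) || lo >= hi)
    stop("parameter error: need lo < hi")
  out <- img
  out$data <- pmin(pmax(img$data, lo), hi)
  out$data <- (out$data - lo) / (hi - lo)
  out
}

#' Resample a volume onto a target grid
#'
#' Axis-aligned grid-to-grid resampling.  Scalar volumes may use
#' interpolating cubic B-splines (`"bspline"`, with the standard recursive
#' prefilter), trilinear, or nearest-neighbour interpolation; label volumes
#' only ever use nearest neighbour — requesting a smoothing interpolator for
#' labels is an error rather than a silent downgrade.
#'
#' @param img `image_volume` or `label_volume`.
#' @param target A [grid_spec()].
#' @param method `"bspline"`, `"trilinear"` or `"nearest"`.
#' @return Volume of the same kind on `target`.
#' @export
resample_to_grid <- function(img, target,
                             method = c("bspline", "trilinear", "nearest")) {
  method <- match.arg(method)
  is_label <- inherits(img, "label_volume")
  if (is_label && method != "nearest")
    stop("parameter error: label volumes must be resampled with method = \"nearest\"")
  if (grids_equal(vol_grid(img), target)) return(img)
  tr <- rigid_identity()
  resample_rigid(img, tr, target, method = switch(method,
    bspline = "bspline", trilinear = "trilinear", nearest = "nearest"))
}

#' Crop volumes to the common field of view
#'
#' Intersects the world-space bounding boxes of a planning CT and a daily
#' CBCT (typically the CBCT has the smaller axial coverage) and crops every
#' supplied volume to that box.  All inputs must live in a common frame,
#' i.e. after rigid alignment.
#'
#' @param ct,cbct `image_volume`s.
#' @param ... Additional volumes (e.g. `label_volume`s) to crop along.
#' @return A list with elements `ct`, `cbct` and one entry per extra volume.
#' @export
crop_to_fov <- function(ct, cbct, ...) {
  extras <- list(...)
  fov <- function(v) {
    g <- vol_grid(v)
    rbind(g$origin - g$spacing / 2,
          g$origin + (g$shape - 0.5) * g$spacing)
  }
  f1 <- fov(ct); f2 <- fov(cbct)
  lo <- pmax(f1[1, ], f2[1, ])
  hi <- pmin(f1[2, ], f2[2, ])
  if (any(lo >= hi))
    stop("geometry error: the fields of view do not intersect")
  crop1 <- function(v) {
    g <- vol_grid(v)
    idx <- lapply(1:3, function(ax) {
      centers <- g$origin[ax] + (seq_len(g$shape[ax]) - 1) * g$spacing[ax]
      which(centers > lo[ax] - 1e-9 & centers < hi[ax] + 1e-9)
    })
    if (any(lengths(idx) == 0))
      stop("geometry error: empty crop")
    arr <- v$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    org <- g$origin + (vapply(idx, min, 1L) - 1) * g$spacing
    if (inherits(v, "label_volume"))
      label_volume(arr, g$spacing, org, v$frame_id)
    else image_volume(arr, g$spacing, org, v$frame_id)
  }
  out <- c(list(ct = crop1(ct), cbct = crop1(cbct)), lapply(extras, crop1))
  out
}

#' Full preprocessing chain for one planning/daily pair
#'
#' Bone-based rigid alignment of the daily volume onto the planning frame,
#' crop to the common field of view, resampling to a common grid, and
#' intensity normalisation — the standard preparation before deformable
#' registration.
#'
#' @param ct Planning CT (`image_volume`).
#' @param cbct Daily CBCT-like volume (`image_volume`).
#' @param ct_labels,cbct_labels Matching `label_volume`s (optional).
#' @param target_shape Grid to resample the cropped volumes to; the clinical
#'   configuration is `c(256, 256, 128)`, desk-scale runs use much smaller
#'   grids.
#' @param bone_hu Threshold for [rigid_register_bone()].
#' @param normalize Clip/normalise scans to `[0, 1]`.
#' @return List with fields `ct`, `cbct`, `ct_labels`, `cbct_labels`,
#'   `rigid` (the fixed-to-moving transform used).
#' @export
preprocess_pair <- function(ct, cbct, ct_labels = NULL, cbct_labels = NULL,
                            target_shape = dim(ct$data), bone_hu = 200,
                            normalize = TRUE) {
  rigid <- rigid_register_bone(ct, cbct, bone_hu = bone_hu)
  cbct_al <- resample_rigid(cbct, rigid, vol_grid(ct), frame_id = ct$frame_id)
  if (!is.null(cbct_labels))
    cbct_lab_al <- resample_rigid(cbct_labels, rigid, vol_grid(ct),
                                  frame_id = ct$frame_id)
  cropped <- if (is.null(ct_labels)) crop_to_fov(ct, cbct_al)
             else crop_to_fov(ct, cbct_al, ct_labels = ct_labels,
                              cbct_labels = cbct_lab_al)
  g <- vol_grid(cropped$ct)
  extent <- g$shape * g$spacing
  target <- grid_spec(target_shape, extent / target_shape,
                      g$origin + (extent / target_shape - g$spacing) / 2)
  out <- list(
    ct = resample_to_grid(cropped$ct, target, "bspline"),
    cbct = resample_to_grid(cropped$cbct, target, "bspline"),
    rigid = rigid)
  if (!is.null(ct_labels)) {
    out$ct_labels <- resample_to_grid(cropped$ct_labels, target, "nearest")
    out$cbct_labels <- resample_to_grid(cropped$cbct_labels, target, "nearest")
  }
  if (normalize) {
    out$ct <- clip_normalize(out$ct)
    out$cbct <- clip_normalize(out$cbct)
  }
  out
}
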