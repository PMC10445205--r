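#' Grid-aware image volumes
#'
#' `image_volume()` wraps a 3D scalar array (HU for anatomy, Gy for dose,
#' unitless for normalised intensities) together with its sampling grid:
#' per-axis voxel size in mm, the world position of voxel (1,1,1), and a
#' frame label.  Voxel indices are 0-based in world-coordinate arithmetic:
#' the centre of voxel `(i,j,k)` (1-based R index) lies at
#' `origin + (c(i,j,k) - 1) * spacing`.  Axis order is fixed (x, y, z).
#'
#' Two volumes are co-registered iff they agree in shape, spacing, origin
#' and frame.
#'
#' @param data 3D numeric array.
#' @param spacing Voxel size in mm, length 3, all positive.
#' @param origin World position (mm) of the first voxel centre, length 3.
#' @param frame_id Label naming the spatial frame, e.g. `"planning"`.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         frame_id = "unknown") {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("data must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite values")
  structure(list(data = data, spacing = spacing, origin = origin,
                 frame_id = as.character(frame_id)),
            class = "image_volume")
}

#' Organ label volumes
#'
#' Integer-coded segmentation on the same grid model as [image_volume()].
#' The code set is fixed: 0 background, 1 external body, 2 rectum,
#' 3 bladder, 4 prostate.
#'
#' @inheritParams image_volume
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         frame_id = "unknown") {
  vol <- image_volume(data, spacing, origin, frame_id)
  bad <- setdiff(unique(as.vector(vol$data)), 0:4)
  if (length(bad))
    stop("label volume contains values outside {0..4}: ",
         paste(sort(bad), collapse = ", "))
  storage.mode(vol$data) <- "integer"
  vol$label_map <- dosewarp_labels()
  class(vol) <- c("label_volume", "image_volume")
  vol
}

#' The fixed organ label encoding
#'
#' @return Named integer vector mapping structure names to label codes.
#' @export
dosewarp_labels <- function() {
  c(background = 0L, body = 1L, rectum = 2L, bladder = 3L, prostate = 4L)
}

#' @export
print.image_volume <- function(x, ...) {
  kind <- if (inherits(x, "label_volume")) "label_volume" else "image_volume"
  cat(sprintf("<%s> %s  spacing %s mm  origin %s  frame '%s'\n", kind,
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              paste(format(x$origin), collapse = ", "), x$frame_id))
  invisible(x)
}

#' Grid specifications
#'
#' A target grid for resampling: shape (voxels), spacing (mm), origin (mm).
#'
#' @param shape Integer length-3 voxel counts.
#' @param spacing,origin As in [image_volume()].
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(shape, spacing, origin) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) stop("shape must be 3 positive integers")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("spacing must be 3 positive values")
  if (length(origin) != 3L) stop("origin must have length 3")
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %s @ %s mm, origin %s\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

#' Extract the grid of a volume or field
#' @param x An `image_volume`, `label_volume` or `deformation_field`.
#' @return A [grid_spec()].
#' @export
vol_grid <- function(x) {
  d <- if (inherits(x, "deformation_field")) dim(x$u)[1:3] else dim(x$data)
  grid_spec(d, x$spacing, x$origin)
}

grids_equal <- function(a, b, tol = 1e-6) {
  identical(as.integer(a$shape), as.integer(b$shape)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

stopifnot_coregistered <- function(a, b, what = "volumes") {
  if (!grids_equal(vol_grid(a), vol_grid(b)))
    stop("geometry error: ", what, " are not on the same grid")
  invisible(TRUE)
}

#' Read a volume from a NIfTI-1 file
#'
#' Spacing and origin are taken from the stored affine, which must be
#' axis-aligned with positive scales (the convention this package writes).
#' `kind = "label"` validates the organ code set and returns a
#' [label_volume()].
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @param kind `"scalar"` or `"label"`.
#' @param frame_id Frame label to attach (the file format does not carry one).
#' @return An `image_volume` or `label_volume`.
#' @export
read_volume <- function(path, kind = c("scalar", "label"),
                        frame_id = "unknown") {
  kind <- match.arg(kind)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("format error reading '", path,
                                           "': ", conditionMessage(e)))
  arr <- as.array(img)
  d <- dim(arr)
  if (length(d) < 3L) d <- c(d, rep(1L, 3L - length(d)))  # dropped singletons
  if (length(d) != 3L)
    stop("format error: expected a 3D volume, got ",
         length(d), " dimensions")
  arr <- array(as.vector(arr), d)  # strip niftiImage attributes
  aff <- RNifti::xform(img)
  sp <- c(aff[1, 1], aff[2, 2], aff[3, 3])
  off <- abs(aff[1:3, 1:3]) - diag(abs(sp))
  if (max(abs(off)) > 1e-4)
    stop("format error: only axis-aligned NIfTI orientations are supported")
  if (any(sp <= 0)) {
    # fall back to pixdim magnitudes for flipped/absent affines
    sp <- abs(sp)
    sp[sp == 0] <- RNifti::pixdim(img)[sp == 0]
  }
  org <- aff[1:3, 4]
  if (kind == "label") label_volume(arr, sp, org, frame_id)
  else image_volume(arr, sp, org, frame_id)
}

#' Write a volume (or deformation field) to NIfTI-1
#'
#' Deformation fields are written as 4D volumes with the three displacement
#' components (mm, pull-back convention) in the fourth dimension.
#'
#' @param x `image_volume`, `label_volume` or `deformation_field`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  arr <- if (inherits(x, "deformation_field")) x$u else x$data
  storage.mode(arr) <- "double"
  img <- RNifti::asNifti(arr)
  aff <- diag(c(x$spacing, 1))
  aff[1:3, 4] <- x$origin
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a deformation field written by [write_volume()]
#' @inheritParams read_volume
#' @return A [deformation_field()].
#' @export
read_field <- function(path, frame_id = "unknown") {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L || dim(arr)[4] != 3L)
    stop("format error: a deformation field must be 4D with 3 components")
  arr <- array(as.vector(arr), dim(arr))
  aff <- RNifti::xform(img)
  deformation_field(arr, spacing = c(aff[1, 1], aff[2, 2], aff[3, 3]),
                    origin = aff[1:3, 4], frame_id = frame_id)
}

#' World coordinates of every voxel centre
#' @param grid A [grid_spec()].
#' @return An `prod(shape) x 3` matrix of mm positions, voxel index varying
#'   fastest along x.
#' @export
grid_points <- function(grid) {
  idx <- cbind(
    rep.int(seq_len(grid$shape[1]) - 1L, grid$shape[2] * grid$shape[3]),
    rep.int(rep(seq_len(grid$shape[2]) - 1L, each = grid$shape[1]),
            grid$shape[3]),
    rep(seq_len(grid$shape[3]) - 1L, each = grid$shape[1] * grid$shape[2]))
  sweep(sweep(idx, 2, grid$spacing, "*"), 2, grid$origin, "+")
}
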