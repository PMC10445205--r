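#' Dense deformation fields
#'
#' Per-voxel displacements in mm, defined on the fixed grid, in the
#' pull-back convention used throughout the package: the warped volume at
#' fixed-grid position `x` samples the moving volume at `x + u(x)`.
#' Registration outputs, the phantom's ground-truth fields, and the dose
#' accumulation machinery all share this convention.
#'
#' @param u Numeric array `(nx, ny, nz, 3)` of mm displacements.
#' @param spacing,origin,frame_id Grid of the fixed frame, as in
#'   [image_volume()].
#' @return An object of class `deformation_field`.
#' @export
deformation_field <- function(u, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                              frame_id = "unknown") {
  u <- as.array(u)
  if (length(dim(u)) != 4L || dim(u)[4] != 3L)
    stop("u must be an (nx, ny, nz, 3) array")
  if (any(!is.finite(u))) stop("displacements must be finite")
  structure(list(u = u, spacing = as.numeric(spacing),
                 origin = as.numeric(origin),
                 frame_id = as.character(frame_id)),
            class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  cat(sprintf("<deformation_field> %s  spacing %s mm  |u| mean %.2f max %.2f mm\n",
              paste(dim(x$u)[1:3], collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              mean(sqrt(rowSums(matrix(x$u, ncol = 3)^2))),
              max(sqrt(rowSums(matrix(x$u, ncol = 3)^2)))))
  invisible(x)
}

#' Zero field on a grid
#' @param grid A [grid_spec()].
#' @param frame_id Frame label.
#' @return A [deformation_field()] of zeros.
#' @export
zero_field <- function(grid, frame_id = "unknown") {
  deformation_field(array(0, c(grid$shape, 3)), grid$spacing, grid$origin,
                    frame_id)
}

field_to_voxels <- function(field) {
  uv <- field$u
  for (d in 1:3) uv[, , , d] <- uv[, , , d] / field$spacing[d]
  uv
}

#' Warp a volume through a deformation field
#'
#' Pull-back spatial-transformer warping on the fixed grid.  Scalar volumes
#' are sampled trilinearly with border replication.  Label volumes are
#' warped channel-wise on their one-hot indicators and re-assembled by
#' argmax, with ties resolved to the lowest label code — integer codes are
#' never interpolated directly.
#'
#' @param moving `image_volume` or `label_volume`, co-registered with the
#'   field's grid.
#' @param field A [deformation_field()] on the fixed grid.
#' @return Warped volume of the same kind, on the fixed grid.
#' @export
warp <- function(moving, field) {
  stopifnot_coregistered(moving, field, "moving volume and field")
  uv <- field_to_voxels(field)
  d <- dim(moving$data)
  if (inherits(moving, "label_volume")) {
    codes <- 0:4
    oh <- array(0, c(d, length(codes)))
    for (i in seq_along(codes)) oh[, , , i] <- (moving$data == codes[i]) * 1.0
    w <- cpp_warp_linear(oh, d, length(codes), uv)
    # argmax with ties to the lowest code: iterate codes high to low and
    # keep the >= comparison strictness accordingly
    best <- w[, , , 1]
    lab <- array(0L, d)
    for (i in 2:length(codes)) {
      upd <- w[, , , i] > best
      lab[upd] <- codes[i]
      best[upd] <- w[, , , i][upd]
    }
    label_volume(lab, field$spacing, field$origin, field$frame_id)
  } else {
    arr <- moving$data
    storage.mode(arr) <- "double"
    out <- cpp_warp_linear(arr, d, 1L, uv)
    image_volume(out, field$spacing, field$origin, field$frame_id)
  }
}
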