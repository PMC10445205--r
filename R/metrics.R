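#' Dice similarity coefficient
#'
#' `2|A∩B| / (|A| + |B|)` between two binary masks on the same grid.  Two
#' empty masks are defined to agree perfectly (DSC = 1).
#'
#' @param a,b Logical arrays (or coercible) of identical shape.
#' @return DSC in `[0, 1]`.
#' @export
dsc <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  if (length(a) != length(b))
    stop("geometry error: mask shapes differ")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1.0)
  2 * sum(a & b) / (na + nb)
}

mask_from <- function(x, code = NULL) {
  if (inherits(x, "label_volume")) {
    if (is.null(code)) stop("a label code is required for a label_volume")
    x$data == code
  } else if (inherits(x, "image_volume")) x$data != 0
  else as.array(x) != 0
}

#' Directed surface-to-surface distances
#'
#' Surfaces are the border voxels of each mask (mask voxels with at least
#' one face-adjacent outside voxel; array-boundary voxels count).
#' Distances are Euclidean, in mm, between voxel centres.  Both directed
#' multisets are returned: `ab[i]` is the distance from the i-th surface
#' voxel of `a` to the nearest surface voxel of `b`.
#'
#' @param a,b Non-empty binary masks of identical shape.
#' @param spacing Voxel spacing in mm.
#' @return List with numeric vectors `ab` and `ba`.
#' @export
surface_distances <- function(a, b, spacing = c(1, 1, 1)) {
  a <- as.array(a) != 0; b <- as.array(b) != 0
  if (!identical(dim(a), dim(b))) stop("geometry error: mask shapes differ")
  if (!any(a) || !any(b)) stop("input error: surface distances are undefined for empty masks")
  sa <- array(cpp_surface_mask(a, dim(a)), dim(a))
  sb <- array(cpp_surface_mask(b, dim(b)), dim(b))
  ia <- which(sa, arr.ind = TRUE) - 1L
  ib <- which(sb, arr.ind = TRUE) - 1L
  list(ab = as.numeric(cpp_directed_dists(ia, ib, as.numeric(spacing))),
       ba = as.numeric(cpp_directed_dists(ib, ia, as.numeric(spacing))))
}

#' Average surface distance
#'
#' Mean of the directed surface distances from `a` to `b` (`a` is the
#' planning contour in the evaluation protocol).  The directed form is the
#' default; `symmetric = TRUE` averages both directions' means, a common
#' alternative convention.
#'
#' @inheritParams surface_distances
#' @param symmetric Average both directions.
#' @return ASD in mm.
#' @export
asd <- function(a, b, spacing = c(1, 1, 1), symmetric = FALSE) {
  d <- surface_distances(a, b, spacing)
  if (symmetric) (mean(d$ab) + mean(d$ba)) / 2 else mean(d$ab)
}

#' Hausdorff distance
#'
#' Maximum of the two directed maxima of the surface distances.
#'
#' @inheritParams surface_distances
#' @return HD in mm.
#' @export
hd <- function(a, b, spacing = c(1, 1, 1)) {
  d <- surface_distances(a, b, spacing)
  max(max(d$ab), max(d$ba))
}

#' 95th-percentile Hausdorff distance
#'
#' The 95th percentile (linear-interpolation definition) is taken within
#' each directed distance multiset, then the larger of the two is
#' returned; always `<=` [hd()].
#'
#' @inheritParams surface_distances
#' @return HD95 in mm.
#' @export
hd95 <- function(a, b, spacing = c(1, 1, 1)) {
  d <- surface_distances(a, b, spacing)
  max(stats::quantile(d$ab, 0.95, names = FALSE, type = 7),
      stats::quantile(d$ba, 0.95, names = FALSE, type = 7))
}

#' Jacobian determinant map of a deformation field
#'
#' Determinant of `d(x + u)/dx` per voxel, computed with central
#' differences in mm (one-sided at the grid boundary).  The identity field
#' gives 1 everywhere; values `<= 0` indicate folding (local loss of
#' invertibility).
#'
#' @param field A [deformation_field()].
#' @return An `image_volume` of determinants (unitless).
#' @export
jacobian_det <- function(field) {
  det <- cpp_jacobian_det(field$u, dim(field$u)[1:3], field$spacing)
  image_volume(det, field$spacing, field$origin, field$frame_id)
}

#' Folding percentage inside a structure
#'
#' Percentage of voxels within the mask whose Jacobian determinant is zero
#' or negative — the topology statistic reported per organ for each
#' registration method.
#'
#' @param field A [deformation_field()].
#' @param organ_mask Non-empty binary mask on the field's grid.
#' @return Percentage in `[0, 100]`.
#' @export
fold_pct <- function(field, organ_mask) {
  mask <- as.array(organ_mask) != 0
  if (!any(mask)) stop("input error: empty organ mask")
  det <- jacobian_det(field)$data
  100 * sum(det[mask] <= 0) / sum(mask)
}

#' Per-organ geometric and topology metrics
#'
#' DSC, ASD, HD, HD95 between the planning (`fixed_labels`) and warped
#' daily contours for rectum, bladder and prostate, plus the folding
#' percentage of the field inside each planning contour.
#'
#' @param fixed_labels,warped_labels `label_volume`s on the same grid.
#' @param field Optional [deformation_field()] for the folding statistic.
#' @param organs Label codes to evaluate.
#' @return Data frame with one row per organ: `structure`, `dsc`, `asd_mm`,
#'   `hd_mm`, `hd95_mm`, `fold_pct`.
#' @export
structure_metrics <- function(fixed_labels, warped_labels, field = NULL,
                              organs = c(rectum = 2L, bladder = 3L,
                                         prostate = 4L)) {
  stopifnot_coregistered(fixed_labels, warped_labels, "label volumes")
  sp <- fixed_labels$spacing
  rows <- lapply(seq_along(organs), function(i) {
    code <- organs[i]
    a <- fixed_labels$data == code
    b <- warped_labels$data == code
    if (!any(a) || !any(b)) {
      return(data.frame(structure = names(organs)[i], dsc = dsc(a, b),
                        asd_mm = NA_real_, hd_mm = NA_real_,
                        hd95_mm = NA_real_, fold_pct = NA_real_))
    }
    sd <- surface_distances(a, b, sp)
    data.frame(
      structure = names(organs)[i],
      dsc = dsc(a, b),
      asd_mm = mean(sd$ab),
      hd_mm = max(max(sd$ab), max(sd$ba)),
      hd95_mm = max(stats::quantile(sd$ab, 0.95, names = FALSE),
                    stats::quantile(sd$ba, 0.95, names = FALSE)),
      fold_pct = if (is.null(field)) NA_real_ else fold_pct(field, a))
  })
  do.call(rbind, rows)
}
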