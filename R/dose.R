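#' Map the planning dose onto a fraction frame
#'
#' Under the dose deformation-invariance assumption, the daily dose of a
#' fraction is the planning dose rigidly repositioned onto the daily
#' anatomy.  `transform` is the pull-back map for this resampling: the
#' fraction dose at position `x` samples the planning dose at
#' `transform(x)`.  Trilinear interpolation.
#'
#' @param planning_dose Dose `image_volume` (Gy) on the planning frame.
#' @param transform A [rigid_transform()] mapping fraction-frame points to
#'   planning-frame points.
#' @param target Output grid; defaults to the planning grid.
#' @param frame_id Frame label of the output.
#' @return Dose `image_volume` on the fraction frame.
#' @export
fraction_dose <- function(planning_dose, transform,
                          target = vol_grid(planning_dose),
                          frame_id = "fraction") {
  resample_rigid(planning_dose, transform, target, method = "trilinear",
                 frame_id = frame_id)
}

#' Accumulate warped fraction doses on the planning anatomy
#'
#' Warps each fraction dose back onto the planning grid through its
#' deformation field (pull-back, trilinear) and sums:
#' `accumulated = sum_k warp(dose_k, field_k)`.  Linear in every fraction
#' dose and invariant to fraction ordering.
#'
#' @param fraction_doses List of dose `image_volume`s.
#' @param fields List of [deformation_field()]s on the planning grid, one
#'   per fraction.
#' @param n_expected Optional expected fraction count (checked).
#' @return An object of class `accumulated_dose`: `dose` (`image_volume`
#'   on the planning frame) plus a per-fraction provenance list.
#' @export
accumulate_dose <- function(fraction_doses, fields, n_expected = NULL) {
  if (length(fraction_doses) != length(fields))
    stop("input error: ", length(fraction_doses), " fraction doses but ",
         length(fields), " fields")
  if (!is.null(n_expected) && length(fields) != n_expected)
    stop("input error: expected ", n_expected, " fractions, got ",
         length(fields))
  if (!length(fields)) stop("input error: no fractions")
  g <- vol_grid(fields[[1]])
  total <- array(0, g$shape)
  prov <- vector("list", length(fields))
  for (k in seq_along(fields)) {
    if (!grids_equal(vol_grid(fields[[k]]), g))
      stop("geometry error: field ", k, " is not on the planning grid")
    w <- warp(fraction_doses[[k]], fields[[k]])
    total <- total + w$data
    prov[[k]] <- list(fraction = k,
                      frame = fraction_doses[[k]]$frame_id)
  }
  structure(list(
    dose = image_volume(total, g$spacing, g$origin, "planning"),
    fractions = prov), class = "accumulated_dose")
}

#' Cumulative dose-volume histogram of a structure
#'
#' Cumulative DVH over the masked voxels: the percentage of the structure
#' volume receiving at least each bin-edge dose.  The derived indices are
#' computed from the voxel dose distribution directly (not from the binned
#' curve): `Dmean` is the masked mean; `D98` the dose received by at least
#' 98% of the volume (linear-interpolation quantile); `Vx` the percentage
#' of voxels with dose `>= x`.
#'
#' @param dose Dose `image_volume` (Gy).
#' @param mask Non-empty binary mask on the dose grid.
#' @param bin_width Histogram bin width in Gy.
#' @param structure Structure name carried in the result.
#' @return An object of class `dvh_curve` with fields `structure`, `edges`
#'   (Gy), `volume_pct`, `dmean`, `d98`, and the function `vx(x)`.
#' @export
dvh <- function(dose, mask, bin_width = 0.1, structure = "structure") {
  if (bin_width <= 0) stop("parameter error: bin_width must be positive")
  m <- as.array(mask) != 0
  if (!any(m)) stop("input error: empty mask")
  dvals <- dose$data[m]
  edges <- seq(0, max(dvals) + bin_width, by = bin_width)
  vol_pct <- vapply(edges, function(e) 100 * mean(dvals >= e), 0)
  structure(list(
    structure = structure,
    edges = edges,
    volume_pct = vol_pct,
    dmean = mean(dvals),
    d98 = stats::quantile(dvals, 0.02, names = FALSE, type = 7),
    vx = function(x) 100 * mean(dvals >= x)), class = "dvh_curve")
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("<dvh_curve> %s: Dmean %.2f Gy, D98%% %.2f Gy\n",
              x$structure, x$dmean, x$d98))
  invisible(x)
}

#' Organ DVH indices
#'
#' The clinical index set per organ: Dmean for all structures, D98% and
#' V76Gy for the prostate, V70Gy for the bladder, V72Gy for the rectum.
#'
#' @param dose Dose `image_volume` (Gy).
#' @param labels `label_volume` on the dose grid.
#' @return Data frame with columns `structure`, `Dmean_Gy`, `D98_Gy`,
#'   `V70_pct`, `V72_pct`, `V76_pct` (indices outside an organ's set are
#'   `NA`).
#' @export
dvh_indices <- function(dose, labels) {
  stopifnot_coregistered(dose, labels, "dose and labels")
  codes <- c(rectum = 2L, bladder = 3L, prostate = 4L)
  rows <- lapply(names(codes), function(org) {
    curve <- dvh(dose, labels$data == codes[[org]], structure = org)
    data.frame(
      structure = org,
      Dmean_Gy = curve$dmean,
      D98_Gy = if (org == "prostate") curve$d98 else NA_real_,
      V70_pct = if (org == "bladder") curve$vx(70) else NA_real_,
      V72_pct = if (org == "rectum") curve$vx(72) else NA_real_,
      V76_pct = if (org == "prostate") curve$vx(76) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Planning-vs-accumulated DVH comparison
#'
#' Signed differences (accumulated minus planning) of the per-organ DVH
#' indices — the quantity used to judge how much the chosen registration
#' strategy shifts the estimated delivered dose.
#'
#' @param planning,accumulated Index tables from [dvh_indices()].
#' @return Data frame of the same shape with differenced index columns.
#' @export
dose_report <- function(planning, accumulated) {
  if (!identical(planning$structure, accumulated$structure))
    stop("input error: structure sets differ")
  out <- planning
  for (col in c("Dmean_Gy", "D98_Gy", "V70_pct", "V72_pct", "V76_pct"))
    out[[col]] <- accumulated[[col]] - planning[[col]]
  names(out)[-1] <- paste0("d", names(out)[-1])
  out
}

#' Wall structure from a whole-organ mask
#'
#' Clinical constraints for bladder and rectum are defined on organ walls
#' obtained by a negative expansion (7 and 5 mm respectively) of the
#' delineated contour; the wall is the original mask minus its erosion by
#' a sphere of that radius.
#'
#' @param labels `label_volume`.
#' @param organ `"bladder"` or `"rectum"`.
#' @param thickness_mm Erosion radius; defaults to the clinical values.
#' @return Logical wall mask.
#' @export
wall_mask <- function(labels, organ = c("bladder", "rectum"),
                      thickness_mm = NULL) {
  organ <- match.arg(organ)
  if (is.null(thickness_mm))
    thickness_mm <- if (organ == "bladder") 7 else 5
  code <- dosewarp_labels()[[organ]]
  m <- labels$data == code
  if (!any(m)) stop("input error: organ not present in labels")
  # erosion = voxels farther than the radius from the complement
  d_out <- cpp_edt(!m, dim(m), labels$spacing)
  m & d_out <= thickness_mm
}
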