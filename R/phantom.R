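#' Synthetic pelvic phantom specification
#'
#' Parameters of the paired planning/daily pelvic phantom: grid, organ
#' geometry (prostate ellipsoid, bladder sphere, rectum tube, bony
#' hemipelvis arcs inside an elliptical body), per-tissue intensity
#' statistics in HU, the planning-to-daily deformation (bladder filling
#' scale, prostate offset, low-frequency sinusoidal body warp, optional
#' rectal gas pocket), and the CBCT-like degradation applied to the daily
#' scan.  The default grid is 64 x 64 x 32 voxels at 3 mm isotropic — large
#' enough for all organs to be several voxels across, small enough for
#' CPU-minute experiments.
#'
#' Deformation amplitudes default to a moderately deformed daily pelvis:
#' 15% linear bladder filling, a few-mm prostate shift, and a 2.5 mm smooth
#' body warp.  The generator refuses amplitude combinations whose analytic
#' field folds (non-positive Jacobian determinant anywhere on the grid).
#'
#' @param shape,spacing_mm Grid definition; the grid is centred on the
#'   world origin.
#' @param bladder_filling Linear scale factor of the bladder radius between
#'   planning and daily anatomy (volume scales with its cube).
#' @param prostate_shift_mm Rigid offset of the prostate (mm, length 3).
#' @param warp_amplitude_mm Amplitude of the global sinusoidal warp.
#' @param warp_wavelength_mm Wavelength of that warp.
#' @param gas_pocket Insert an air pocket in the daily rectum (intensity
#'   only; the rectum contour still includes it, as delineated contours do).
#' @param cbct_noise_sigma,cbct_bias_hu,cbct_contrast Daily-scan
#'   degradation: added Gaussian noise (HU), global intensity bias (HU), and
#'   soft-tissue contrast compression factor.
#' @param noise_sigma_ct Planning CT noise (HU).
#' @param seed Integer seed; the same seed reproduces the phantom exactly.
#' @param ... Geometry overrides, see the function source for the full set.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 32), spacing_mm = c(3, 3, 3),
                         bladder_filling = 1.15,
                         prostate_shift_mm = c(2, -2, 1),
                         warp_amplitude_mm = 2.5,
                         warp_wavelength_mm = 120,
                         gas_pocket = FALSE,
                         noise_sigma_ct = 12,
                         cbct_noise_sigma = 25, cbct_bias_hu = 15,
                         cbct_contrast = 0.7,
                         seed = 1, ...) {
  geo <- list(
    body_radii = c(85, 75, 95),
    bone_ellipse = c(72, 62), bone_band = c(0.80, 0.95),
    bone_min_x = 30, bone_max_z = 38,
    prostate_center = c(0, 10, -10), prostate_radii = c(20, 17, 15),
    bladder_center = c(0, -25, 15), bladder_radius = 20,
    rectum_center_y = 42, rectum_radius = 11, rectum_halflength = 35,
    hu = c(air = -1000, body = 30, rectum = 20, bladder = 10,
           prostate = 45, bone = 700),
    bladder_decay_mm = 20, prostate_core_mm = 20, prostate_decay_mm = 25)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(geo))
  if (length(unknown)) stop("unknown phantom parameters: ",
                            paste(unknown, collapse = ", "))
  geo[names(dots)] <- dots
  spec <- c(list(shape = as.integer(shape), spacing = as.numeric(spacing_mm),
                 bladder_filling = bladder_filling,
                 prostate_shift = as.numeric(prostate_shift_mm),
                 warp_amplitude = warp_amplitude_mm,
                 warp_wavelength = warp_wavelength_mm,
                 gas_pocket = isTRUE(gas_pocket),
                 noise_sigma_ct = noise_sigma_ct,
                 cbct_noise_sigma = cbct_noise_sigma,
                 cbct_bias = cbct_bias_hu, cbct_contrast = cbct_contrast,
                 seed = as.integer(seed)), geo)
  num <- unlist(spec[setdiff(names(spec), "gas_pocket")])
  if (any(!is.finite(num))) stop("all phantom parameters must be finite")
  structure(spec, class = "phantom_spec")
}

phantom_grid <- function(spec) {
  grid_spec(spec$shape, spec$spacing, -(spec$shape - 1) * spec$spacing / 2)
}

# Evaluate RNG-dependent code under a local, restorable seed.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Analytic tissue label at world positions (planning anatomy).
# Returns integer codes; bone is part of the body label (separate mask).
phantom_label_at <- function(spec, pts) {
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  lab <- integer(nrow(pts))
  body <- (x / spec$body_radii[1])^2 + (y / spec$body_radii[2])^2 +
          (z / spec$body_radii[3])^2 <= 1
  lab[body] <- 1L
  rect <- sqrt(x^2 + (y - spec$rectum_center_y)^2) <= spec$rectum_radius &
          abs(z) <= spec$rectum_halflength
  blad <- sqrt((x - spec$bladder_center[1])^2 + (y - spec$bladder_center[2])^2 +
               (z - spec$bladder_center[3])^2) <= spec$bladder_radius
  pc <- spec$prostate_center; pr <- spec$prostate_radii
  pros <- ((x - pc[1]) / pr[1])^2 + ((y - pc[2]) / pr[2])^2 +
          ((z - pc[3]) / pr[3])^2 <= 1
  if (any((rect & blad) | (rect & pros) | (blad & pros)))
    stop("spec error: organ geometries overlap")
  lab[rect] <- 2L
  lab[blad] <- 3L
  lab[pros] <- 4L
  lab
}

phantom_bone_at <- function(spec, pts) {
  re <- sqrt((pts[, 1] / spec$bone_ellipse[1])^2 +
             (pts[, 2] / spec$bone_ellipse[2])^2)
  re >= spec$bone_band[1] & re <= spec$bone_band[2] &
    abs(pts[, 1]) >= spec$bone_min_x & abs(pts[, 3]) <= spec$bone_max_z
}

# Forward planning-to-daily displacement (mm) at world positions: sum of a
# radial bladder expansion, a localised prostate offset, and a
# low-frequency sinusoidal body warp with seed-determined phases.
phantom_forward_u <- function(spec, pts, phases) {
  u <- matrix(0, nrow(pts), 3)
  # bladder filling: pure radial scaling inside the bladder, Gaussian decay
  db <- sweep(pts, 2, spec$bladder_center)
  r <- sqrt(rowSums(db^2))
  g <- ifelse(r <= spec$bladder_radius, 1,
              exp(-((r - spec$bladder_radius) / spec$bladder_decay_mm)^2))
  u <- u + (spec$bladder_filling - 1) * db * g
  # prostate offset: rigid inside a core radius, Gaussian decay outside
  dp <- sweep(pts, 2, spec$prostate_center)
  rp <- sqrt(rowSums(dp^2))
  h <- ifelse(rp <= spec$prostate_core_mm, 1,
              exp(-((rp - spec$prostate_core_mm) / spec$prostate_decay_mm)^2))
  u <- u + outer(h, spec$prostate_shift)
  # global smooth warp
  L <- spec$warp_wavelength; A <- spec$warp_amplitude
  u[, 1] <- u[, 1] + A * sin(2 * pi * pts[, 2] / L + phases[1]) *
                         sin(2 * pi * pts[, 3] / L + phases[2])
  u[, 2] <- u[, 2] + A * sin(2 * pi * pts[, 3] / L + phases[3]) *
                         sin(2 * pi * pts[, 1] / L + phases[4])
  u[, 3] <- u[, 3] + A * sin(2 * pi * pts[, 1] / L + phases[5]) *
                         sin(2 * pi * pts[, 2] / L + phases[6])
  u
}

phantom_intensity <- function(spec, lab, bone, sigma) {
  hu <- spec$hu
  base <- c(hu["air"], hu["body"], hu["rectum"], hu["bladder"],
            hu["prostate"])[lab + 1L]
  base[bone] <- hu["bone"]
  base + stats::rnorm(length(base), 0, sigma)
}

#' Generate a paired planning/daily phantom with ground truth
#'
#' Builds the planning anatomy analytically, pushes it through the
#' spec's diffeomorphic forward map to obtain the daily anatomy (labels are
#' evaluated at the numerically inverted map, so they stay crisp), degrades
#' the daily scan CBCT-style, and returns the exact planning-to-daily
#' deformation field in the pull-back convention used by [warp()] — so the
#' true field can be fed directly to every downstream stage.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `ground_truth_pair`: lists `planning` and
#'   `daily` (each with `$image` and `$labels`), the true
#'   `field`, and the `spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  grid <- phantom_grid(spec)
  pts <- grid_points(grid)
  phases <- with_seed(spec$seed, stats::runif(6, 0, 2 * pi))
  u <- phantom_forward_u(spec, pts, phases)
  ufield <- array(c(u[, 1], u[, 2], u[, 3]), c(grid$shape, 3))
  detj <- cpp_jacobian_det(ufield, grid$shape, grid$spacing)
  if (min(detj) <= 0)
    stop("spec error: deformation folds (min det J = ",
         format(min(detj)), "); reduce the amplitudes")
  # invert the forward map by fixed-point iteration: x = y - u(x)
  xinv <- pts
  for (it in 1:25) {
    xnew <- pts - phantom_forward_u(spec, xinv, phases)
    delta <- max(abs(xnew - xinv))
    xinv <- xnew
    if (delta < 1e-4) break
  }
  lab_plan <- phantom_label_at(spec, pts)
  bone_plan <- phantom_bone_at(spec, pts)
  lab_daily <- phantom_label_at(spec, xinv)
  bone_daily <- phantom_bone_at(spec, xinv)
  img <- with_seed(spec$seed + 1L, {
    ct <- phantom_intensity(spec, lab_plan, bone_plan, spec$noise_sigma_ct)
    daily <- phantom_intensity(spec, lab_daily, bone_daily,
                               spec$noise_sigma_ct)
    if (spec$gas_pocket) {
      gc <- c(0, spec$rectum_center_y, 10)
      gas <- sqrt((pts[, 1] - gc[1])^2 + (pts[, 2] - gc[2])^2 +
                  (pts[, 3] - gc[3])^2) <= 0.7 * spec$rectum_radius
      daily[gas & lab_daily == 2L] <- spec$hu["air"]
    }
    # CBCT-like degradation: contrast compression, bias, extra noise
    daily <- daily * spec$cbct_contrast + spec$cbct_bias +
      stats::rnorm(length(daily), 0, spec$cbct_noise_sigma)
    list(ct = ct, daily = daily)
  })
  shp <- grid$shape
  structure(list(
    planning = list(
      image = image_volume(array(img$ct, shp), grid$spacing, grid$origin,
                           "planning"),
      labels = label_volume(array(lab_plan, shp), grid$spacing, grid$origin,
                            "planning")),
    daily = list(
      image = image_volume(array(img$daily, shp), grid$spacing, grid$origin,
                           "daily"),
      labels = label_volume(array(lab_daily, shp), grid$spacing, grid$origin,
                            "daily")),
    field = deformation_field(ufield, grid$spacing, grid$origin, "planning"),
    spec = spec), class = "ground_truth_pair")
}

#' Synthetic planning dose for a phantom
#'
#' Prescription dose inside the prostate expanded by a margin, with a
#' Gaussian lateral falloff outside — a deliberately simple stand-in for a
#' planned boost distribution, sufficient for exercising dose warping and
#' DVH reporting.  The maximum equals the prescription.
#'
#' @param pair A `ground_truth_pair` from [make_phantom()].
#' @param prescription Prescription dose in Gy (the clinical boost schema
#'   delivers 80 Gy to the prostate target).
#' @param margin_mm Target margin added around the prostate.
#' @param falloff_sigma_mm Gaussian falloff scale beyond the margin.
#' @return Dose `image_volume` (Gy) on the planning grid.
#' @export
make_planning_dose <- function(pair, prescription = 80, margin_mm = 5,
                               falloff_sigma_mm = 6) {
  if (!is.numeric(prescription) || prescription < 0)
    stop("parameter error: prescription must be non-negative")
  lab <- pair$planning$labels
  mask <- lab$data == dosewarp_labels()[["prostate"]]
  d <- cpp_edt(mask, dim(lab$data), lab$spacing)
  dose <- ifelse(d <= margin_mm, 1,
                 exp(-0.5 * ((d - margin_mm) / falloff_sigma_mm)^2))
  image_volume(array(prescription * dose, dim(lab$data)),
               lab$spacing, lab$origin, "planning")
}

#' Generate a cohort of phantom pairs with varied deformations
#'
#' Draws `n` phantom pairs whose deformation parameters jitter around the
#' base spec — bladder filling in 1.05–1.25, per-axis prostate shifts in
#' ±4 mm, warp amplitudes in 1–3 mm, independent warp phases — emulating
#' the fraction-to-fraction variability of a treatment course.
#'
#' @param n Number of pairs.
#' @param seed Cohort seed (each pair derives its own).
#' @param base_spec Template [phantom_spec()].
#' @return List of `ground_truth_pair`s.
#' @export
phantom_cohort <- function(n, seed = 1, base_spec = phantom_spec()) {
  specs <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      s <- base_spec
      s$bladder_filling <- stats::runif(1, 1.05, 1.25)
      s$prostate_shift <- stats::runif(3, -4, 4)
      s$warp_amplitude <- stats::runif(1, 1, 3)
      s$seed <- as.integer(seed * 1000L + i)
      s
    })
  })
  lapply(specs, make_phantom)
}
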