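test_that("fraction dose mapping: identity, integer shifts, round trips", {
  dose <- fx_dose()
  id <- fraction_dose(dose, rigid_identity())
  expect_equal(id$data, dose$data, tolerance = 1e-12)

  # translation by exactly 2 voxels shifts the grid content exactly
  sp <- dose$spacing
  tr <- rigid_transform(translation = c(2 * sp[1], 0, 0))
  sh <- fraction_dose(dose, tr)
  n <- dim(dose$data)[1]
  expect_equal(sh$data[1:(n - 2), , ], dose$data[3:n, , ],
               tolerance = 1e-12)

  # rigid then inverse-rigid resampling: exact to interpolation order.
  # Trilinear interpolation reproduces affine fields exactly, so a linear
  # dose round-trips to 1e-3 Gy; for the curved falloff dose the error is
  # bounded by the second-order interpolation term h^2/8 * max |f''|.
  rt <- rigid_transform(c(0.02, -0.01, 0.03), c(4.5, -2.5, 3), c(0, 0, 0))
  g <- vol_grid(dose)
  lin <- image_volume(array(0.3 * grid_points(g)[, 1] + 40, g$shape),
                      g$spacing, g$origin, "planning")
  d <- dim(dose$data)
  i <- 6:(d[1] - 5); j <- 6:(d[2] - 5); k <- 4:(d[3] - 3)
  back_lin <- fraction_dose(fraction_dose(lin, rt), invert_rigid(rt))
  expect_lt(max(abs(back_lin$data[i, j, k] - lin$data[i, j, k])), 1e-3)
  back <- fraction_dose(fraction_dose(dose, rt), invert_rigid(rt))
  h2f <- max(dose$spacing)^2 / 8 * (2 * 80 / 6^2)   # falloff sigma = 6 mm
  expect_lt(max(abs(back$data[i, j, k] - dose$data[i, j, k])), 2 * h2f)
})

test_that("accumulation is exact, linear, and order-invariant", {
  dose <- fx_dose()
  g <- vol_grid(dose)
  zf <- zero_field(g, "planning")
  acc <- accumulate_dose(list(dose, dose, dose), list(zf, zf, zf),
                         n_expected = 3)
  expect_equal(acc$dose$data, 3 * dose$data, tolerance = 0)

  # scaling one fraction by 2 adds exactly one extra copy
  dose2 <- dose; dose2$data <- 2 * dose$data
  f <- fx_pair()$field
  a1 <- accumulate_dose(list(dose, dose), list(f, zf))
  a2 <- accumulate_dose(list(dose2, dose), list(f, zf))
  extra <- warp(dose, f)
  expect_equal(a2$dose$data - a1$dose$data, extra$data, tolerance = 1e-12)

  # ordering invariance
  a3 <- accumulate_dose(list(dose, dose2), list(zf, f))
  expect_equal(a2$dose$data, a3$dose$data, tolerance = 1e-12)

  expect_error(accumulate_dose(list(dose), list(zf, zf)), "input error")
  expect_error(accumulate_dose(list(dose, dose), list(zf, zf), 3),
               "expected 3")
})

test_that("phantom dose accumulation through true fields is self-consistent", {
  pair <- fx_pair()
  dose <- fx_dose()
  flds <- replicate(5, pair$field, simplify = FALSE)
  fds <- replicate(5, dose, simplify = FALSE)
  acc <- accumulate_dose(fds, flds, 5)
  prost <- pair$planning$labels$data == 4
  dm_acc <- mean(acc$dose$data[prost]) / 5
  dm_plan <- mean(dose$data[prost])
  expect_lt(abs(dm_acc / dm_plan - 1), 0.03)
})

test_that("DVH: uniform dose, analytic ramp, exact Dmean", {
  d <- c(10, 10, 10)
  mask <- array(TRUE, d)
  uni <- image_volume(array(80, d))
  cv <- dvh(uni, mask)
  expect_equal(cv$dmean, 80)
  expect_equal(cv$d98, 80)
  expect_equal(cv$vx(76), 100)
  expect_equal(cv$vx(81), 0)

  # linear ramp 0..100 Gy
  ramp <- image_volume(array(seq(0, 100, length.out = prod(d)), d))
  cr <- dvh(ramp, mask, bin_width = 0.1)
  expect_equal(cr$vx(50), 50, tolerance = 0.2)
  expect_equal(cr$d98, 2, tolerance = 0.2)
  expect_equal(cr$dmean, mean(ramp$data), tolerance = 1e-9)

  # cumulative curve is monotone non-increasing and starts at 100%
  expect_true(all(diff(cr$volume_pct) <= 0))
  expect_equal(cr$volume_pct[1], 100)

  expect_error(dvh(uni, array(FALSE, d)), "empty")
  expect_error(dvh(uni, mask, bin_width = 0), "positive")
})

test_that("dose_report differences follow the organ-specific index set", {
  pair <- fx_pair()
  dose <- fx_dose()
  lab <- pair$planning$labels
  tab <- dvh_indices(dose, lab)
  expect_equal(tab$structure, c("rectum", "bladder", "prostate"))
  expect_true(is.na(tab$V70_pct[tab$structure == "prostate"]))
  expect_false(is.na(tab$V76_pct[tab$structure == "prostate"]))
  expect_false(is.na(tab$V70_pct[tab$structure == "bladder"]))
  expect_false(is.na(tab$V72_pct[tab$structure == "rectum"]))
  expect_true(all(!is.na(tab$Dmean_Gy)))

  same <- dose_report(tab, tab)
  expect_true(all(same$dDmean_Gy == 0))

  shifted <- dose
  shifted$data <- dose$data + 1
  tab2 <- dvh_indices(shifted, lab)
  rep2 <- dose_report(tab, tab2)
  expect_equal(rep2$dDmean_Gy, rep(1, 3), tolerance = 1e-9)

  bad <- tab; bad$structure <- rev(bad$structure)
  expect_error(dose_report(tab, bad), "structure")
})

test_that("wall masks are hollow shells of the stated thickness", {
  pair <- fx_pair()
  lab <- pair$planning$labels
  wall <- wall_mask(lab, "bladder")
  organ <- lab$data == 3
  expect_true(all(organ[wall]))
  expect_lt(sum(wall), sum(organ))
  # every wall voxel is within 7 mm of the organ boundary
  d_out <- dosewarp:::cpp_edt(!organ, dim(organ), lab$spacing)
  expect_true(all(d_out[wall] <= 7))
  expect_true(all(d_out[organ & !wall] > 7))
})
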