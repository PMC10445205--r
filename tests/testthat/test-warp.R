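test_that("warping with the zero field is the identity operator", {
  pair <- fx_pair()
  z <- zero_field(vol_grid(pair$planning$image), "planning")
  w <- warp(pair$planning$image, z)
  expect_equal(w$data, pair$planning$image$data, tolerance = 1e-6)
  wl <- warp(pair$planning$labels, z)
  expect_identical(wl$data, pair$planning$labels$data)
})

test_that("constant integer-voxel displacements shift the array exactly", {
  set.seed(11)
  d <- c(12, 10, 8)
  v <- image_volume(array(rnorm(prod(d)), d), spacing = c(2, 2, 2))
  k <- 3L
  u <- array(0, c(d, 3))
  u[, , , 1] <- k * 2          # k voxels along x, in mm
  f <- deformation_field(u, v$spacing, v$origin)
  w <- warp(v, f)
  # pull-back: output(x) = input(x + k) so the content shifts by -k
  expect_equal(w$data[1:(d[1] - k), , ], v$data[(k + 1):d[1], , ],
               tolerance = 1e-12)
})

test_that("label warping resolves ties to the lowest label code", {
  d <- c(4, 4, 4)
  lab <- array(0L, d)
  lab[1:2, , ] <- 3L
  lab[3:4, , ] <- 2L
  lv <- label_volume(lab, spacing = c(1, 1, 1))
  u <- array(0, c(d, 3))
  u[, , , 1] <- -0.5          # sample exactly between two voxels
  f <- deformation_field(u, lv$spacing, lv$origin)
  w <- warp(lv, f)
  # at the 3|2 interface both one-hot channels interpolate to 0.5: the tie
  # must go to the lower code (2)
  expect_equal(unique(as.vector(w$data[3, , ])), 2L)
})

test_that("the true phantom field maps daily labels onto planning labels", {
  pair <- fx_pair_fine()
  wl <- warp(pair$daily$labels, pair$field)
  ds <- organ_dsc(pair$planning$labels, wl)
  expect_true(all(ds >= 0.97))
})

test_that("warp rejects a field on a different grid", {
  pair <- fx_pair()
  f <- zero_field(grid_spec(c(8, 8, 8), c(1, 1, 1), c(0, 0, 0)))
  expect_error(warp(pair$planning$image, f), "grid")
})
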