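test_that("NIfTI round-trip preserves data, spacing and origin", {
  set.seed(4)
  v <- image_volume(array(rnorm(8 * 8 * 8), c(8, 8, 8)),
                    spacing = c(1.5, 2, 3), origin = c(-10, 5, 2.5),
                    frame_id = "planning")
  f <- tempfile(fileext = ".nii.gz")
  write_volume(v, f)
  r <- read_volume(f, frame_id = "planning")
  expect_equal(r$data, v$data, tolerance = 1e-12)
  expect_equal(r$spacing, v$spacing)
  expect_equal(r$origin, v$origin)

  lab <- label_volume(array(sample(0:4, 64, TRUE), c(4, 4, 4)),
                      spacing = c(2, 2, 2))
  fl <- tempfile(fileext = ".nii.gz")
  write_volume(lab, fl)
  rl <- read_volume(fl, kind = "label")
  expect_identical(rl$data, lab$data)
})

test_that("label volumes reject out-of-range codes", {
  expect_error(label_volume(array(c(0, 1, 7, 2), c(2, 2, 1))), "7")
  v <- image_volume(array(c(0, 1, 7, 2), c(2, 2, 1)))
  f <- tempfile(fileext = ".nii.gz")
  write_volume(v, f)
  expect_error(read_volume(f, kind = "label"), "outside")
})

test_that("phantom volumes carry the spec's grid through file I/O", {
  pair <- fx_pair()
  f <- tempfile(fileext = ".nii.gz")
  write_volume(pair$planning$image, f)
  r <- read_volume(f)
  expect_equal(r$spacing, pair$spec$spacing)
  expect_equal(dim(r$data), pair$spec$shape)
})

test_that("clip_normalize maps the clip window onto [0,1] affinely", {
  v <- image_volume(array(c(-1024, 1575, (1575 - 1024) / 2, 5000, -3000),
                          c(5, 1, 1)))
  n <- clip_normalize(v)
  expect_equal(as.vector(n$data), c(0, 1, 0.5, 1, 0))
  # idempotent on already-normalised input with lo=0, hi=1
  n2 <- clip_normalize(n, 0, 1)
  expect_equal(n2$data, n$data)
  expect_error(clip_normalize(v, 10, 10), "lo < hi")
})

test_that("resampling: identity grid, constants, and analytic ramps", {
  set.seed(8)
  v <- image_volume(array(rnorm(16 * 12 * 8), c(16, 12, 8)),
                    spacing = c(2, 2, 2), origin = c(0, 0, 0))
  same <- resample_to_grid(v, vol_grid(v), "trilinear")
  expect_identical(same$data, v$data)

  const <- image_volume(array(7, c(16, 16, 8)), spacing = c(1, 1, 1))
  down <- resample_to_grid(const, grid_spec(c(8, 8, 4), c(2, 2, 2),
                                            c(0.5, 0.5, 0.5)), "trilinear")
  expect_equal(as.vector(down$data), rep(7, 256), tolerance = 1e-12)

  # linear ramp, 2x upsampling: trilinear and cubic B-spline must both
  # reproduce the analytic ramp at the new coordinates
  g0 <- grid_spec(c(40, 8, 8), c(2, 2, 2), c(0, 0, 0))
  ramp <- image_volume(array(grid_points(g0)[, 1], g0$shape),
                       g0$spacing, g0$origin)
  g1 <- grid_spec(c(72, 8, 8), c(1, 1, 1), c(1, 1, 1))
  up_lin <- resample_to_grid(ramp, g1, "trilinear")
  expect_equal(as.vector(up_lin$data), grid_points(g1)[, 1],
               tolerance = 1e-6)
  # the cubic B-spline reproduces linear functions away from the border:
  # the prefilter's mirror boundary bends the ramp near the edges, with a
  # perturbation that decays geometrically (pole 2 - sqrt(3)) inwards
  up_bs <- resample_to_grid(ramp, g1, "bspline")
  expect_equal(up_bs$data[25:48, , ],
               array(grid_points(g1)[, 1], g1$shape)[25:48, , ],
               tolerance = 1e-6)

  lab <- label_volume(array(0L, c(4, 4, 4)))
  expect_error(resample_to_grid(lab, g1, "bspline"), "nearest")
})

test_that("crop_to_fov returns the field-of-view intersection", {
  v1 <- image_volume(array(rnorm(1000), c(10, 10, 10)), c(2, 2, 2),
                     c(0, 0, 0))
  same <- crop_to_fov(v1, v1)
  expect_identical(same$ct$data, v1$data)

  inner <- image_volume(array(1, c(4, 4, 4)), c(2, 2, 2), c(6, 6, 6))
  cr <- crop_to_fov(v1, inner)
  expect_equal(dim(cr$ct$data), c(4, 4, 4))
  expect_equal(cr$ct$origin, inner$origin)
  expect_equal(dim(cr$cbct$data), c(4, 4, 4))

  far <- image_volume(array(1, c(4, 4, 4)), c(2, 2, 2), c(100, 0, 0))
  expect_error(crop_to_fov(v1, far), "intersect")
})

test_that("rigid transforms compose with their inverse to identity", {
  tr <- rigid_transform(c(0.2, -0.1, 0.35), c(12, -4, 7), c(5, 5, -10))
  pts <- matrix(stats::rnorm(60, sd = 80), 20)
  back <- apply_rigid(invert_rigid(tr), apply_rigid(tr, pts))
  expect_lt(max(abs(back - pts)), 1e-9)
})

test_that("bone-based rigid registration recovers a known shift", {
  pair <- fx_pair()
  ct <- pair$planning$image
  expect_error(rigid_register_bone(ct, ct, bone_hu = 1e5), "bone threshold")

  t0 <- rigid_register_bone(ct, ct)
  expect_lt(sqrt(sum(t0$translation^2)), 0.1 * min(ct$spacing))

  d <- c(5, -3, 2)
  mov <- resample_rigid(ct, rigid_transform(translation = -d))
  tr <- rigid_register_bone(ct, mov)
  expect_lt(sqrt(sum((tr$translation - d)^2)), 0.5)
  expect_lt(max(abs(tr$rotation)), 0.5 * pi / 180)

  # aligning the degraded daily scan must not degrade bone-mask overlap
  cb <- pair$daily$image
  cb_shift <- resample_rigid(cb, rigid_transform(translation = -c(4, 2, -3)))
  tr2 <- rigid_register_bone(ct, cb_shift)
  aligned <- resample_rigid(cb_shift, tr2, vol_grid(ct))
  bone_f <- ct$data > 200
  before <- dsc(bone_f, cb_shift$data > 200)
  after <- dsc(bone_f, aligned$data > 200)
  expect_gte(after, before)
})
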