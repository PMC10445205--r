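test_that("dsc handles identity, disjoint, empty, and counted overlaps", {
  m <- random_blob(c(10, 10, 10))
  expect_equal(dsc(m, m), 1.0)
  a <- array(FALSE, c(6, 6, 6)); a[1:2, , ] <- TRUE
  b <- array(FALSE, c(6, 6, 6)); b[5:6, , ] <- TRUE
  expect_equal(dsc(a, b), 0.0)
  expect_equal(dsc(array(FALSE, c(4, 4, 4)), array(FALSE, c(4, 4, 4))), 1.0)

  # |A| = 100, |B| = 60, |A∩B| = 40 -> 2*40/160 = 0.5
  a <- array(FALSE, c(10, 10, 10)); a[1:100] <- TRUE
  b <- array(FALSE, c(10, 10, 10)); b[61:120] <- TRUE
  expect_equal(dsc(a, b), 0.5)
})

test_that("two isolated voxels measure their exact separation", {
  a <- array(FALSE, c(10, 10, 10)); a[2, 5, 5] <- TRUE
  b <- array(FALSE, c(10, 10, 10)); b[8, 5, 5] <- TRUE
  sp <- c(2.5, 1, 1)
  d <- surface_distances(a, b, sp)
  expect_equal(d$ab, 6 * 2.5)
  expect_equal(d$ba, 6 * 2.5)
  expect_equal(hd(a, b, sp), 15)
  expect_equal(asd(a, b, sp), 15)
  expect_error(surface_distances(a, array(FALSE, c(10, 10, 10))), "empty")
})

test_that("surface metrics agree exactly with the brute-force oracle", {
  set.seed(21)
  sp <- c(1.5, 2, 1)
  for (rep in 1:12) {
    a <- random_blob(c(12, 11, 10))
    b <- random_blob(c(12, 11, 10))
    if (!any(a) || !any(b)) next
    d <- surface_distances(a, b, sp)
    expect_equal(d$ab, oracle_directed(a, b, sp), tolerance = 1e-12)
    expect_equal(d$ba, oracle_directed(b, a, sp), tolerance = 1e-12)
  }
})

test_that("directed distances are asymmetric; dsc and hd are symmetric", {
  a <- array(FALSE, c(12, 12, 6)); a[3:10, 3:10, 2:5] <- TRUE
  b <- array(FALSE, c(12, 12, 6)); b[5:7, 5:7, 3:4] <- TRUE
  d <- surface_distances(a, b)
  expect_false(isTRUE(all.equal(mean(d$ab), mean(d$ba))))
  expect_equal(dsc(a, b), dsc(b, a))
  expect_equal(hd(a, b), hd(b, a))
})

test_that("hd95 never exceeds hd", {
  set.seed(33)
  for (rep in 1:25) {
    a <- random_blob(c(10, 10, 8))
    b <- random_blob(c(10, 10, 8))
    if (!any(a) || !any(b)) next
    expect_lte(hd95(a, b), hd(a, b))
  }
})

test_that("jacobian determinant: identity, uniform scale, pure shear", {
  g <- grid_spec(c(12, 12, 12), c(2, 2, 2), c(-11, -11, -11))
  expect_equal(jacobian_det(zero_field(g))$data,
               array(1, g$shape), tolerance = 1e-12)

  # u = (s-1) x with s = 1.1: det = s^3 = 1.331 at interior voxels
  pts <- grid_points(g)
  u <- array(0.1 * pts, c(g$shape, 3))
  det <- jacobian_det(deformation_field(u, g$spacing, g$origin))$data
  interior <- det[2:11, 2:11, 2:11]
  expect_equal(as.vector(interior), rep(1.331, length(interior)),
               tolerance = 1e-6)

  # shear: u_x = 0.3 y is volume preserving
  ush <- array(0, c(g$shape, 3))
  ush[, , , 1] <- array(0.3 * pts[, 2], g$shape)
  detsh <- jacobian_det(deformation_field(ush, g$spacing, g$origin))$data
  expect_equal(as.vector(detsh[2:11, 2:11, 2:11]),
               rep(1, 1000), tolerance = 1e-9)
})

test_that("jacobian of composed small fields multiplies to first order", {
  set.seed(5)
  g <- grid_spec(c(12, 12, 12), c(2, 2, 2), c(0, 0, 0))
  smooth_u <- function(seed) {
    set.seed(seed)
    u <- array(rnorm(prod(g$shape) * 3, sd = 1), c(g$shape, 3))
    for (d in 1:3) u[, , , d] <- dosewarp:::gauss_smooth(u[, , , d], 2) * 0.2
    u
  }
  u1 <- smooth_u(1); u2 <- smooth_u(2)
  f1 <- deformation_field(u1, g$spacing, g$origin)
  f2 <- deformation_field(u2, g$spacing, g$origin)
  f12 <- deformation_field(u1 + u2, g$spacing, g$origin)
  d1 <- jacobian_det(f1)$data; d2 <- jacobian_det(f2)$data
  d12 <- jacobian_det(f12)$data
  i <- 3:10
  expect_equal(d12[i, i, i], (d1 * d2)[i, i, i], tolerance = 1e-3)
})

test_that("a constructed sawtooth folds exactly the expected voxels", {
  g <- grid_spec(c(20, 5, 5), c(1, 1, 1), c(0, 0, 0))
  u <- array(0, c(g$shape, 3))
  # displacement decreasing at rate 1.5 voxels/voxel over x in 8..13 makes
  # d(x+u)/dx = -0.5 there; central differences flag the interior range
  ramp <- rep(0, 20)
  ramp[8:13] <- -(seq_len(6) - 1) * 1.5
  ramp[14:20] <- ramp[13]
  u[, , , 1] <- array(rep(ramp, 25), g$shape)
  f <- deformation_field(u, g$spacing, g$origin)
  det <- jacobian_det(f)$data
  mask <- array(TRUE, g$shape)
  m <- sum(det <= 0)
  expect_gt(m, 0)
  expect_equal(fold_pct(f, mask), 100 * m / prod(g$shape))
  # direct count oracle: central differences give slope -1.5 (det -0.5)
  # at the four interior columns of the ramp, -0.75 (det +0.25) at its ends
  expect_equal(m, 4 * 25)
  expect_error(fold_pct(f, array(FALSE, g$shape)), "empty")
})

test_that("structure_metrics summarises the phantom evaluation", {
  pair <- fx_pair()
  wl <- warp(pair$daily$labels, pair$field)
  sm <- structure_metrics(pair$planning$labels, wl, pair$field)
  expect_equal(sm$structure, c("rectum", "bladder", "prostate"))
  expect_true(all(sm$dsc > 0.8 & sm$dsc <= 1))
  expect_true(all(sm$hd95_mm <= sm$hd_mm))
  expect_true(all(sm$fold_pct == 0))
})
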