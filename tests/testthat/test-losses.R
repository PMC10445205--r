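test_that("smoothness loss: constants vanish, linear fields give c^2", {
  g <- grid_spec(c(10, 10, 10), c(2, 2, 2), c(0, 0, 0))
  expect_equal(smoothness_loss(zero_field(g)), 0)
  const <- zero_field(g); const$u[] <- 5.5
  expect_equal(smoothness_loss(const), 0)

  # u_x = c * x (world mm): exactly one component/direction pair is affected
  c0 <- 0.37
  u <- array(0, c(g$shape, 3))
  u[, , , 1] <- array(grid_points(g)[, 1] * c0, g$shape)
  f <- deformation_field(u, g$spacing, g$origin)
  expect_equal(smoothness_loss(f), c0^2, tolerance = 1e-6)
})

test_that("smoothness gradient matches finite differences", {
  set.seed(3)
  uv <- array(rnorm(5 * 4 * 4 * 3, sd = 0.3), c(5, 4, 4, 3))
  g <- dosewarp:::smoothness_grad(uv)
  for (i in sample(length(uv), 5)) {
    e <- 1e-6
    up <- uv; up[i] <- uv[i] + e
    dn <- uv; dn[i] <- uv[i] - e
    num <- (smoothness_loss(up) - smoothness_loss(dn)) / (2 * e)
    expect_equal(g[i], num, tolerance = 1e-5)
  }
})

test_that("one-hot L1: identity, disjoint masks, and monotone alignment", {
  d <- c(10, 10, 10)
  a <- array(0L, d); a[2:3, 2:3, 2:3] <- 4L
  la <- label_volume(a, spacing = c(1, 1, 1))
  expect_equal(mask_l1_loss(la, la), 0)

  # completely disjoint single-organ masks of volume fraction f score 2f
  b <- array(0L, d); b[6:7, 6:7, 6:7] <- 4L
  lb <- label_volume(b, spacing = c(1, 1, 1))
  f <- 8 / prod(d)
  expect_equal(mask_l1_loss(la, lb), 2 * f)

  # loss strictly decreases as a shifted mask moves back into alignment
  wide <- array(0L, d); wide[2:6, 2:6, 2:6] <- 4L
  lw <- label_volume(wide, spacing = c(1, 1, 1))
  losses <- vapply(4:0, function(shift) {
    m <- array(0L, d); m[(2 + shift):(6 + shift), 2:6, 2:6] <- 4L
    mask_l1_loss(lw, label_volume(m, spacing = c(1, 1, 1)))
  }, 0)
  expect_true(all(diff(losses) < 0))
})

test_that("NMI loss: self-similarity, remap invariance, independence", {
  set.seed(7)
  x <- array(runif(16^3), c(16, 16, 16))
  shuffled <- array(sample(x), dim(x))
  expect_lte(nmi_loss(x, x), nmi_loss(x, shuffled))

  # invariance under the bijective intensity remap v -> 1 - v, checked
  # against the hard-histogram oracle as well
  expect_equal(nmi_loss(x, 1 - x), nmi_loss(x, x), tolerance = 0.02)
  expect_equal(oracle_nmi(as.vector(x), as.vector(1 - x), 32),
               oracle_nmi(as.vector(x), as.vector(x), 32), tolerance = 1e-6)

  # independent volumes sit near the oracle's independence value
  y <- array(runif(16^3), c(16, 16, 16))
  soft <- -nmi_loss(x, y)
  hard <- oracle_nmi(as.vector(x), as.vector(y), 32)
  expect_lt(abs(soft - hard), 0.05)
  # and far below the self-similarity value
  expect_gt(-nmi_loss(x, x), soft + 0.2)
})

test_that("NMI is symmetric and safe on constant images", {
  set.seed(9)
  a <- array(runif(1000), c(10, 10, 10))
  b <- array(runif(1000), c(10, 10, 10))
  expect_equal(nmi_loss(a, b), nmi_loss(b, a), tolerance = 1e-6)
  const <- array(0.5, c(10, 10, 10))
  v <- nmi_loss(a, const)
  expect_true(is.finite(v))
  expect_equal(v, -1)  # documented independence-floor fallback
})

test_that("total_loss composes the variant's terms with the stated weights", {
  pair <- fx_pair()
  fx <- clip_normalize(pair$planning$image)
  g <- vol_grid(fx)
  z <- zero_field(g, "planning")

  # moving = fixed, labels equal, zero field: L1 and smoothness exactly 0
  l <- total_loss("sc_msk", fx, fx, pair$planning$labels,
                  pair$planning$labels, field = z)
  comps <- attr(l, "components")
  expect_equal(comps[["l1"]], 0)
  expect_equal(comps[["smooth"]], 0)
  expect_equal(as.numeric(l), comps[["nmi"]])  # alpha = 1

  # default sc_msk weights are (1, 2, 4)
  cfg <- regnet_config("sc_msk")
  expect_equal(unname(cfg$weights[c("alpha", "beta", "lambda")]), c(1, 2, 4))

  # doubling beta doubles the L1 contribution exactly
  mv <- clip_normalize(pair$daily$image)
  l1w <- total_loss("sc_msk", fx, mv, pair$planning$labels,
                    pair$daily$labels, field = z)
  l2w <- total_loss("sc_msk", fx, mv, pair$planning$labels,
                    pair$daily$labels, field = z,
                    weights = list(beta = 4))
  c1 <- attr(l1w, "components")
  expect_equal(as.numeric(l2w) - as.numeric(l1w), 2 * c1[["l1"]])

  expect_error(total_loss("msk", field = z), "label")
})
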