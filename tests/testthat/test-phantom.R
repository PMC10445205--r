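test_that("phantom generation is deterministic and amplitude-faithful", {
  s <- phantom_spec(seed = 42)
  a <- make_phantom(s)
  b <- make_phantom(s)
  expect_identical(a$planning$image$data, b$planning$image$data)
  expect_identical(a$daily$image$data, b$daily$image$data)
  expect_identical(a$field$u, b$field$u)

  # zero amplitudes: daily anatomy is the planning anatomy, field is zero
  s0 <- phantom_spec(bladder_filling = 1, prostate_shift_mm = c(0, 0, 0),
                     warp_amplitude_mm = 0, seed = 42)
  p0 <- make_phantom(s0)
  expect_identical(p0$daily$labels$data, p0$planning$labels$data)
  expect_equal(max(abs(p0$field$u)), 0)
})

test_that("bladder filling scales the daily bladder volume by its cube", {
  s <- phantom_spec(bladder_filling = 1.2, prostate_shift_mm = c(0, 0, 0),
                    warp_amplitude_mm = 0, seed = 5)
  p <- make_phantom(s)
  ratio <- sum(p$daily$labels$data == 3) / sum(p$planning$labels$data == 3)
  expect_lt(abs(ratio / 1.2^3 - 1), 0.05)
})

test_that("the true field never folds and excessive amplitudes are refused", {
  p <- fx_pair()
  det <- jacobian_det(p$field)
  expect_gt(min(det$data), 0)
  expect_equal(fold_pct(p$field, p$planning$labels$data == 4), 0)
  expect_error(make_phantom(phantom_spec(bladder_filling = 3, seed = 1)),
               "fold")
})

test_that("CBCT degradation leaves label geometry untouched", {
  s <- phantom_spec(seed = 13)
  s_clean <- s; s_clean$cbct_noise_sigma <- 0
  s_clean$cbct_bias <- 0; s_clean$cbct_contrast <- 1
  a <- make_phantom(s)
  b <- make_phantom(s_clean)
  expect_identical(a$daily$labels$data, b$daily$labels$data)
  expect_false(identical(a$daily$image$data, b$daily$image$data))
})

test_that("the synthetic planning dose honours its construction bounds", {
  pair <- fx_pair()
  dose <- fx_dose()
  pl <- pair$planning$labels
  expect_gte(mean(dose$data[pl$data == 4]), 78)
  expect_true(all(dose$data >= 0))
  expect_lte(max(dose$data), 1.10 * 80)

  z <- make_planning_dose(pair, prescription = 0)
  expect_equal(max(abs(z$data)), 0)
  expect_error(make_planning_dose(pair, prescription = -5), "non-negative")

  # Gaussian tail: negligible dose beyond margin + 3 sigma
  prost <- pl$data == 4
  d <- dosewarp:::cpp_edt(prost, dim(prost), pl$spacing)
  far <- d >= 5 + 3 * 6
  expect_lt(max(dose$data[far]), 0.05 * 80)
})

test_that("cohort generation varies deformations but keeps geometry", {
  cohort <- phantom_cohort(3, seed = 2)
  fillings <- vapply(cohort, function(p) p$spec$bladder_filling, 0)
  expect_gt(diff(range(fillings)), 0)
  expect_true(all(fillings >= 1.05 & fillings <= 1.25))
  # planning anatomy identical across the cohort (same patient)
  expect_identical(cohort[[1]]$planning$labels$data,
                   cohort[[2]]$planning$labels$data)
})
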