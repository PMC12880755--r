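test_that("exponential concentration profiles", {
  fp <- chemokine_field("point_exp", c0 = 2, decay = 1.5)
  expect_equal(concentration(fp, c(0, 0)), 2)
  expect_equal(concentration(fp, c(1.5, 0)), 2 / exp(1))
  # line source at 8d with decay 1.5d, evaluated 3d below: c0 e^-2
  d <- 3
  fl <- chemokine_field("line_exp", c0 = 1, decay = 1.5 * d, source_y = 8 * d)
  expect_equal(concentration(fl, c(5, 5 * d)), exp(-2))
  expect_error(concentration(chemokine_field("none"), c(0, 0)), "no spatial")
})

test_that("saturating activity response", {
  b0 <- 8; eps <- 0.2
  f <- chemokine_field("point_exp", eps = eps, c0 = 1, C_sat = 0.5, decay = 2)
  # maximal at the source, baseline far away
  expect_equal(beta_at_tip(f, c(0, 0), b0), b0 * (1 + eps))
  expect_equal(beta_at_tip(f, c(0, 100), b0), b0, tolerance = 1e-8)
  # fast saturation (C/c0 = 0.01) keeps most of the enhancement far from the
  # source (c = 0.1 c0) while slow saturation (C/c0 = 1) loses most of it
  resp <- function(Cs, conc) (1 + Cs) * conc / (conc + Cs)  # enhancement/eps
  expect_gt(resp(0.01, 0.1), 0.9)
  expect_lt(resp(1, 0.1), 0.2)
  expect_equal(resp(1, 0.1), 2 * 0.1 / 1.1, tolerance = 1e-12)
  # monotone non-increasing with distance; bounded in [b0, b0(1+eps)]
  ys <- seq(0, 50, by = 0.5)
  bb <- beta_at_tip(f, cbind(0, ys), b0)
  expect_true(all(diff(bb) <= 1e-12))
  expect_true(all(bb >= b0 - 1e-12 & bb <= b0 * (1 + eps) + 1e-12))
})

test_that("junction bias activity", {
  f <- chemokine_field("junction_bias", eps = 0.001, biased_node = 4L)
  expect_equal(junction_bias_beta(f, 4L, 8), 8.008)
  expect_equal(junction_bias_beta(f, 2L, 8), 8)
  f0 <- chemokine_field("junction_bias", eps = 0, biased_node = 4L)
  expect_equal(junction_bias_beta(f0, 4L, 8), junction_bias_beta(f0, 3L, 8))
  expect_error(chemokine_field("junction_bias"), "biased_node")
})

test_that("gradient onset switches the field on at the onset time", {
  f <- chemokine_field("linear", eps = 0.1, source_y = 60, slope_len = 120,
                       onset = 0)
  b0 <- 12
  expect_equal(beta_at_tip(f, c(0, 10), b0, t = -1), b0)
  bt <- beta_at_tip(f, c(0, 10), b0, t = 1)
  expect_gt(bt, b0)
  # linear in y between the clips
  b1 <- beta_at_tip(f, c(0, 0), b0, t = 1)
  b2 <- beta_at_tip(f, c(0, 30), b0, t = 1)
  b3 <- beta_at_tip(f, c(0, 60), b0, t = 1)
  expect_equal(b2 - b1, (b3 - b1) / 2, tolerance = 1e-12)
  expect_equal(b3, b0 * 1.1)
})
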