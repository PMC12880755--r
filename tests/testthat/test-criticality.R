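test_that("spreading length solves the symmetric force balance", {
  p <- model_params()
  for (b in c(4, 6, 9)) {
    L <- spread_length_Lp(b, p)
    # k (L - 1) = beta / (1 + c / L)
    expect_equal(p$k * (L - 1), b / (1 + p$c_amount / L), tolerance = 1e-12)
  }
  # strictly increasing in beta
  bs <- seq(3, 12, by = 0.25)
  expect_true(all(diff(vapply(bs, spread_length_Lp, 0, p = p)) > 0))
})

test_that("polarization length has the expected pole and decay", {
  p <- model_params()
  pole <- 2 * p$D / p$c_amount
  expect_equal(polarization_length_Lc(pole * 0.9, p), Inf)
  expect_true(is.finite(polarization_length_Lc(pole * 1.2, p)))
  # large just above the pole (trapped regime), decreasing beyond
  bs <- seq(pole * 1.05, pole * 3, length.out = 20)
  Ls <- vapply(bs, polarization_length_Lc, 0, p = p)
  expect_true(all(diff(Ls) < 0))
  expect_gt(Ls[1], Ls[10] * 3)
})

test_that("critical activity: closed form equals the L_p = L_c root", {
  p <- model_params()
  bc <- critical_beta_single(p)
  expect_equal(spread_length_Lp(bc, p), polarization_length_Lc(bc, p),
               tolerance = 1e-6)
  # default calibration keeps beta_c in the 5-6 operating window
  expect_gt(bc, 5); expect_lt(bc, 6)
  # also for a different parameter set
  p2 <- update_params(p, k = 1.2, c_amount = 2, D = 3)
  bc2 <- critical_beta_single(p2)
  expect_equal(spread_length_Lp(bc2, p2), polarization_length_Lc(bc2, p2),
               tolerance = 1e-6)
})

test_that("minimal spanning length", {
  expect_equal(min_spanning_length(3, 3), 0)
  expect_equal(min_spanning_length(4, 3), 3)
  expect_equal(min_spanning_length(6, 3.7), 11.1)
})

test_that("multi-junction thresholds", {
  p <- model_params()
  res <- critical_beta_multi(4, d = 3, p)
  # beta_d root satisfies L_p(beta_d) = (N - 3) d when the root is interior
  if (res$beta_d > 2 + 1e-9)
    expect_equal(spread_length_Lp(res$beta_d, p), 3, tolerance = 1e-6)
  expect_true(is.na(res$beta_c_N) || res$beta_c_N >= critical_beta_single(p) - 0.2)
  # N = 3 falls back to the single-junction threshold
  res3 <- critical_beta_multi(3, d = 3, p)
  expect_equal(res3$beta_c_N, critical_beta_single(p))
})

test_that("1D stick-slip threshold: above beta_c, resolution-stable", {
  p <- model_params()
  coarse <- stick_slip_threshold_1d(p, beta_grid = seq(8, 12, by = 1),
                                    t_run = 100)
  expect_gt(coarse$threshold, critical_beta_single(p))
  fine <- stick_slip_threshold_1d(p, beta_grid = seq(coarse$threshold - 1,
                                                     coarse$threshold + 0.5,
                                                     by = 0.5), t_run = 100)
  expect_lte(abs(fine$threshold - coarse$threshold), 1)
})
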