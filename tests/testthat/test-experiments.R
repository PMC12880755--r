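test_that("junction sweep output structure and determinism", {
  sw <- run_junction_sweep(beta0_grid = c(7, 9.5), reps = 5, seed = 3,
                           keep_records = TRUE)
  expect_equal(sw$beta0, c(7, 9.5))
  expect_true(all(c("T_esc_mean", "P_wrong", "P_back", "P_slow") %in% names(sw)))
  rec <- attr(sw, "records")
  expect_equal(nrow(rec), 10)
  expect_true(all(rec$outcome %in% c("correct", "wrong_forward", "back")))
  sw2 <- run_junction_sweep(beta0_grid = c(7, 9.5), reps = 5, seed = 3,
                            keep_records = TRUE)
  expect_identical(attr(sw2, "records"), rec)
})

test_that("network sweep records arrivals and bounded FMI", {
  sw <- run_network_sweep(beta0_grid = 8, reps = 4, t_max = 400, seed = 6,
                          keep_records = TRUE)
  rec <- attr(sw, "records")
  expect_equal(nrow(rec), 4)
  expect_true(all(rec$L_path >= 0))
  expect_true(all(abs(rec$FMI) <= 1))
  expect_true(all(rec$T_arr <= 400))
})

test_that("strong signal beats weak signal in directedness at high activity", {
  s_strong <- run_network_sweep(beta0_grid = 9, C_over_c0 = 0.01, reps = 8,
                                t_max = 600, seed = 9, keep_records = TRUE)
  s_weak <- run_network_sweep(beta0_grid = 9, C_over_c0 = 1, reps = 8,
                              t_max = 600, seed = 9, keep_records = TRUE)
  expect_lte(s_strong$L_path_mean, s_weak$L_path_mean * 1.25)
  expect_gte(s_strong$FMI_mean, s_weak$FMI_mean - 0.1)
})

test_that("drug scenarios preserve the expected orderings", {
  res <- run_drug_scenarios(p = model_params(beta0 = 9, sigma = 0.3),
                            reps = 6, t_max = 40, seed = 2)
  wt <- res[res$scenario == "WT", ]
  ck <- res[res$scenario == "CK666", ]
  bleb <- res[res$scenario == "blebbistatin", ]
  # actin inhibition: slower and shorter than wild type
  expect_lt(ck$speed_mean, wt$speed_mean)
  expect_lt(ck$L_mean, wt$L_mean)
  # myosin inhibition: near-WT length, lower speed
  expect_lt(abs(bleb$L_mean - wt$L_mean) / wt$L_mean, 0.10)
  expect_lt(bleb$speed_mean, wt$speed_mean)
  # identity multiplier reproduces WT at the same seed
  res2 <- run_drug_scenarios(p = model_params(beta0 = 9, sigma = 0.3),
                             scenarios = list(WT = list(beta0_mult = 1,
                                                        k_mult = 1)),
                             reps = 6, t_max = 40, seed = 2)
  expect_equal(res2$speed_mean, wt$speed_mean)
  expect_equal(res2$L_mean, wt$L_mean)
})

test_that("gradient-onset protocol selects retreating cells and reorients them", {
  lw <- run_lw_protocol(p = model_params(), beta0 = 10, sigma = 0.5,
                        angles = c(0, 30), runs_per_angle = 2,
                        t_pre = 10, t_post = 15, seed = 4)
  expect_gte(lw$n_runs, 2)
  expect_true(all(lw$runs$angle %in% c(0, 30)))
  # qualifying runs moved away from the source before onset
  expect_true(all(!is.na(lw$lw_curve$t)))
  # post-onset displacement turns toward +y on average: FMI rises
  expect_gt(lw$fmi_post, lw$fmi_pre)
})

test_that("fixture writer emits the full set as CSV", {
  dir <- tempfile()
  paths <- write_fixtures(dir)
  expect_true(all(file.exists(paths)))
  expect_gte(length(paths), 9)
  one <- utils::read.csv(paths[1])
  expect_true(all(c("time", "com_x", "com_y", "L") %in% names(one)))
  unlink(dir, recursive = TRUE)
})
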