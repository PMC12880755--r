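test_that("junction outcomes from synthetic records", {
  # escape recorded by the engine
  tr <- list(samples = data.frame(time = 0:5, com_x = 0, com_y = 0, L = 5,
                                  N = 2, event = 0L),
             escape_branch = 4L, escape_time = 4.2,
             final = list(kind = "path"))
  class(tr) <- "cell_trajectory"
  rec <- classify_junction_outcome(tr, source_branch = 4L, back_branch = 2L)
  expect_equal(rec$outcome, "correct")
  expect_equal(rec$T_esc, 4.2)
  # timeout: longest-arm rule (arm lengths 0.2, 3.1, 1.0 on branches 2, 3, 4)
  tr2 <- tr
  tr2$escape_branch <- NA_integer_
  tr2$final <- list(kind = "tree", x = c(0.2, 3.1, 1.0), branch = c(2L, 3L, 4L))
  rec2 <- classify_junction_outcome(tr2, t_max = 100)
  expect_equal(rec2$outcome, "wrong_forward")
  expect_true(rec2$timeout)
  expect_equal(rec2$T_esc, 100)
  tr2$final$x <- c(5, 1, 1)
  expect_equal(classify_junction_outcome(tr2)$outcome, "back")
})

test_that("ensemble statistics match hand arithmetic", {
  rec <- data.frame(outcome = c("correct", "correct", "wrong_forward", "back",
                                "correct", "wrong_forward", "correct",
                                "correct", "back", "correct"),
                    T_esc = c(4, 6, 10, 12, 5, 9, 4, 6, 11, 5),
                    slow = c(FALSE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE,
                             FALSE, TRUE, FALSE))
  st <- ensemble_decision_stats(rec)
  expect_equal(st$T_esc_mean, 7.2)
  expect_equal(st$P_wrong, 0.4)
  expect_equal(st$P_back, 0.2)
  expect_equal(st$P_slow, 0.4)
  expect_equal(st$P_wrong_sem, sqrt(0.4 * 0.6 / 10))
  expect_equal(st$T_esc_sem, sd(rec$T_esc) / sqrt(10))
  # all correct: zero error probabilities
  all_ok <- data.frame(outcome = rep("correct", 5), T_esc = 1:5)
  expect_equal(ensemble_decision_stats(all_ok)$P_wrong, 0)
  expect_error(ensemble_decision_stats(rec[1, , drop = FALSE]), "two")
  # decision probabilities partition: P(correct) + P(wrong) = 1 and
  # P(back) <= P(wrong)
  expect_lte(st$P_back, st$P_wrong)
})

test_that("slow-mode detector fires on the constructed fixture only", {
  fx <- fixture_trajectory("slow_mode", t_on = 2, t_off = 5)
  ep <- detect_slow_mode(fx, tau_min = 1, d = 3)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$t_start, 2, tolerance = 0.05)
  expect_equal(ep$t_end, 5, tolerance = 0.05)
  # single-leader migration: no episodes
  fx2 <- fixture_trajectory("single_leader")
  expect_equal(nrow(detect_slow_mode(fx2, tau_min = 1, d = 3)), 0)
  # tau_min longer than the episode suppresses it
  expect_equal(nrow(detect_slow_mode(fx, tau_min = 4, d = 3)), 0)
  expect_error(detect_slow_mode(fx, theta_rear = -1), "positive")
})

test_that("stick-slip detector counts cycles and measures amplitudes", {
  fx <- fixture_trajectory("sawtooth", L_hi = 8, L_lo = 4, period = 2)
  ep <- detect_stick_slip(fx, drop_frac = 0.3, n_cycles = 2)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$ratio, 2, tolerance = 0.02)
  expect_gte(ep$n_cycles, 2)
  # monotone length: nothing
  expect_equal(nrow(detect_stick_slip(fixture_trajectory("monotone_L"))), 0)
  # drops below the threshold fraction are ignored
  fx_small <- fixture_trajectory("sawtooth", L_hi = 8, L_lo = 7.5)
  expect_equal(nrow(detect_stick_slip(fx_small, drop_frac = 0.2)), 0)
  expect_error(detect_stick_slip(fx, drop_frac = 2), "drop_frac")
})

test_that("arrival metrics on geometric fixtures", {
  # straight path toward +y: FMI = 1
  m1 <- arrival_metrics(fixture_trajectory("straight"), t_max = 10)
  expect_equal(m1$FMI, 1, tolerance = 1e-9)
  expect_false(m1$arrived)
  expect_equal(m1$T_arr, 10)
  # closed loop: FMI = 0 (y projection) and near 0 in magnitude
  m2 <- arrival_metrics(fixture_trajectory("loop"), t_max = 10)
  expect_lt(abs(m2$FMI), 1e-6)
  # ideal hexagonal zig-zag: FMI = sqrt(3)/2
  m3 <- arrival_metrics(fixture_trajectory("zigzag"), t_max = 10)
  expect_equal(m3$FMI, sqrt(3) / 2, tolerance = 1e-6)
  # path length always at least the net displacement
  for (k in c("straight", "loop", "zigzag")) {
    m <- arrival_metrics(fixture_trajectory(k), t_max = 10,
                         fmi_axis = "magnitude")
    expect_lte(m$FMI, 1 + 1e-12)
  }
})

test_that("FMI is invariant under time reparameterization", {
  fx <- fixture_trajectory("zigzag", dt = 0.01)
  # warp the clock (strictly increasing, nonlinear); same polyline
  fx2 <- fx
  fx2$samples$time <- fx$samples$time^1.5 + 0.3 * fx$samples$time
  m1 <- arrival_metrics(fx, t_max = 10)
  m2 <- arrival_metrics(fx2, t_max = 10)
  expect_equal(m1$FMI, m2$FMI, tolerance = 1e-12)
  expect_equal(m1$L_path, m2$L_path, tolerance = 1e-12)
})

test_that("beginning-of-movement detector", {
  fx <- fixture_trajectory("switch_vy", t_switch = 3)
  bt <- bm_time(fx, v_thresh = 0.5, window = 0.1)
  expect_equal(bt, 3, tolerance = 0.15)
  # never toward the source: sentinel
  fx_away <- fixture_trajectory("switch_vy", t_switch = 100, t_max = 10)
  expect_true(is.na(bm_time(fx_away, v_thresh = 0.5)))
  # monotone in the threshold
  b_lo <- bm_time(fx, v_thresh = 0.1, window = 0.2)
  b_hi <- bm_time(fx, v_thresh = 0.9, window = 0.2)
  expect_lte(b_lo, b_hi + 1e-9)
})

test_that("event-aligned averaging", {
  t1 <- fixture_trajectory("constant_speed", speed = 1)
  t2 <- fixture_trajectory("constant_speed", speed = 3)
  out <- event_aligned_average(list(t1, t2), c(5, 5), window = 3, bin = 1,
                               speed_dt = 0.5)
  ok <- !is.na(out$mean)
  expect_true(any(ok))
  expect_equal(unique(round(out$mean[ok], 6)), 2)
  expect_equal(unique(round(out$sem[ok], 6)), 1)
  # identical trajectories: zero sem
  out2 <- event_aligned_average(list(t1, t1), c(5, 5), window = 3, bin = 1,
                                speed_dt = 0.5)
  expect_equal(max(out2$sem, na.rm = TRUE), 0)
})

test_that("sem shrinks as 1/sqrt(reps) on a doubled ensemble", {
  set.seed(1)
  mk <- function(n) data.frame(outcome = sample(c("correct", "wrong_forward"),
                                                n, replace = TRUE),
                               T_esc = rexp(n, 0.1))
  # binomial sem formula scales exactly as 1/sqrt(n) at fixed p
  s1 <- ensemble_decision_stats(data.frame(outcome = rep(c("correct", "back"),
                                                         25), T_esc = 1))
  s2 <- ensemble_decision_stats(data.frame(outcome = rep(c("correct", "back"),
                                                         50), T_esc = 1))
  expect_equal(s2$P_wrong_sem / s1$P_wrong_sem, 1 / sqrt(2), tolerance = 1e-9)
})
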