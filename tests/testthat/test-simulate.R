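test_that("identical seed and configuration give bit-identical runs", {
  p <- model_params(sigma = 0.3)
  t1 <- run_line(p, t_max = 5, seed = 42)
  t2 <- run_line(p, t_max = 5, seed = 42)
  expect_identical(t1$samples, t2$samples)
  t3 <- run_line(p, t_max = 5, seed = 43)
  expect_false(identical(t3$samples, t1$samples))
})

test_that("deterministic runs converge under time-step halving", {
  base <- model_params(sigma = 0)
  tA <- run_line(base, t_max = 10)
  tB <- run_line(update_params(base, dt = base$dt / 2), t_max = 10)
  LA <- tA$samples$L[tA$samples$time %in% seq(0, 10, 1)]
  LB <- tB$samples$L[tB$samples$time %in% seq(0, 10, 1)]
  expect_lt(max(abs(LA - LB) / LA), 0.01)
})

test_that("frozen-target flow noise has Ornstein-Uhlenbeck statistics", {
  # iterate the Euler-Maruyama flow step with a frozen target: the sample
  # mean must approach v* and the variance sigma^2 / (2 delta)
  p <- model_params(sigma = 0.25, delta = 2, dt = 1e-3)
  set.seed(11)
  nstep <- 2e5
  v <- numeric(nstep); v[1] <- 3
  z <- rnorm(nstep)
  for (s in 2:nstep) v[s] <- flow_update(v[s - 1], 3, p, z[s])
  v <- v[-(1:5000)]
  n_eff <- length(v) * p$delta * p$dt  # decorrelation time 1/delta
  expect_lt(abs(mean(v) - 3), 3 * sd(v) / sqrt(n_eff))
  v_var <- var(v)
  expect_lt(abs(v_var - p$sigma^2 / (2 * p$delta)),
            3 * v_var * sqrt(2 / n_eff))
})

test_that("below beta_c a symmetric junction cell relaxes to L_p and stays", {
  p <- model_params(beta0 = 5, sigma = 0)
  net <- junction_network()
  tr <- simulate_cell(net, cell_star(net, node = 1, x = 0.3, v = 0.01), p,
                      seed = 1, t_max = 80)
  s <- tail(tr$samples, 200)
  expect_equal(mean(s$L), spread_length_Lp(5, p), tolerance = 1e-3)
  expect_lt(max(abs(diff(s$L))), 1e-6)        # stationary
  expect_lt(max(abs(s$com_x)) + max(abs(s$com_y)), 1e-6)  # at the junction
})

test_that("above beta_c the cell polarizes and migrates along one arm", {
  p <- model_params(beta0 = 7, sigma = 0)
  net <- junction_network()
  tr <- simulate_cell(net, cell_star(net, node = 1, x = 0.3,
                                     v = c(0.1, 0.05, 0.02)),
                      p, seed = 1, t_max = 120, record_arms = TRUE)
  s <- tr$samples
  disp <- sqrt(s$com_x^2 + s$com_y^2)
  expect_gt(max(disp), 2)  # migrated away from the junction
  # flows spontaneously break symmetry (one arm leads)
  spread_by_t <- tapply(tr$arms$v, tr$arms$time,
                        function(v) max(v) - min(v))
  expect_gt(max(spread_by_t), 2)
})

test_that("sigma = 0 simulations bracket the critical activity", {
  p <- model_params(sigma = 0)
  bc <- critical_beta_single(p)
  net <- junction_network()
  run_at <- function(beta) {
    pb <- update_params(p, beta0 = beta)
    tr <- simulate_cell(net, cell_star(net, node = 1, x = 0.3,
                                       v = c(0.05, 0.02, 0.01)),
                        pb, seed = 1, t_max = 400)
    s <- tr$samples
    max(sqrt(s$com_x^2 + s$com_y^2))
  }
  expect_lt(run_at(bc - 0.2), 0.5)   # stationary below
  expect_gt(run_at(bc + 0.2), 1.0)   # migrating above
})

test_that("total length is continuous across topology events", {
  # a migrating cell on a fine lattice undergoes many splits and collapses
  p <- model_params(beta0 = 8, sigma = 0.2)
  net <- hex_lattice(d = 3, nx = 20, ny = 20)
  tr <- simulate_cell(net, cell_star(net, node = nearest_node(net), x = 0.1,
                                     n = 0.8, v = 0),
                      p, seed = 21, t_max = 40)
  expect_gt(nrow(tr$events), 0)
  s <- tr$samples
  # largest jump between consecutive samples bounded by smooth dynamics:
  # compare jumps at event samples with the locally expected rate of change
  dL <- abs(diff(s$L))
  ev_rows <- which(s$event > 0)
  # continuity: no jump anywhere near the grid scale
  expect_lt(max(dL), 0.25 * net$d)
  # events did include splits and collapses
  expect_true(all(c("split", "pin") %in% tr$events$kind))
})

test_that("event-level length continuity is exact at splits", {
  # deterministic single split on the junction network: L at the sample
  # just before and just after the split differs only by the integration
  # step, not by a jump
  p <- model_params(beta0 = 8, sigma = 0, dt = 1e-4)
  net <- junction_network()
  cl <- cell_two_arm(net, node_a = 2L, node_b = 1L,
                     offsets = c(1000 - 8, 1000 - 0.05),
                     n = c(0.5, 0.9), v = c(2, 8))
  tr <- simulate_cell(net, cl, p, seed = 1, t_max = 1, record_every = 1e-4)
  s <- tr$samples
  i_split <- which(s$event == 1)[1]
  expect_false(is.na(i_split))
  dL_at_split <- abs(s$L[i_split] - s$L[i_split - 1])
  dL_typical <- stats::median(abs(diff(s$L)))
  expect_lt(dL_at_split, 10 * dL_typical + 1e-6)
})

test_that("weight identity holds for every arm of every topology generated", {
  # the engine distributes each arm's flow with the 2^-m halving rule and
  # tracks the worst deviation of the distributed weight from 1 across every
  # step of the run (all N and all junction arrangements encountered)
  p <- model_params(beta0 = 8, sigma = 0.3)
  net <- hex_lattice(d = 3, nx = 16, ny = 16)
  tr <- simulate_cell(net, cell_star(net, node = nearest_node(net), x = 0.1),
                      p, seed = 4, t_max = 30)
  expect_gt(max(tr$samples$N), 3)  # multi-junction shapes were visited
  expect_lt(tr$weight_err_max, 1e-9)
})

test_that("centre of mass matches a quadrature oracle", {
  # deterministic short run on the junction network; compare the recorded
  # COM with an arclength quadrature over the final arm geometry
  p <- model_params(beta0 = 7, sigma = 0)
  net <- junction_network()
  tr <- simulate_cell(net, cell_star(net, node = 1, x = c(2, 1, 0.5), v = 0.01),
                      p, seed = 1, t_max = 0.01, record_arms = TRUE,
                      record_every = 0.01)
  a <- tr$arms[tr$arms$time == 0, ]
  # arms lie along straight branches from the origin: mass integral
  ang <- c(270, 150, 30) * pi / 180
  xs <- c(2, 1, 0.5)
  pieces <- do.call(rbind, lapply(1:3, function(i) {
    s <- seq(0, xs[i], length.out = round(1000 * xs[i]))
    cbind(cos(ang[i]) * s, sin(ang[i]) * s)
  }))
  expect_equal(tr$samples$com_x[1], mean(pieces[, 1]), tolerance = 2e-3)
  expect_equal(tr$samples$com_y[1], mean(pieces[, 2]), tolerance = 2e-3)
})
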