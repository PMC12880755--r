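test_that("friction coefficient branches", {
  p <- model_params(kappa = 20)
  expect_equal(friction_coefficient(0.3, p, extending = TRUE), 1)
  expect_equal(friction_coefficient(1, p, extending = FALSE), 20)
  expect_equal(friction_coefficient(0.5, p, extending = FALSE), 10)
  # bare-drag floor for a detached edge
  expect_equal(friction_coefficient(1e-4, p, extending = FALSE), p$gamma_min)
  expect_error(friction_coefficient(0, p, extending = FALSE), "0, 1")
})

test_that("adhesion rate follows the slip-bond law", {
  p <- model_params(r = 1, f_s = 18, k = 0.8, omega_max = 100)
  # attachment term vanishes at n = 1
  r1 <- adhesion_rate(1, v = 2, L = 6, p)
  expect_equal(r1, -exp((0.8 * 5 - 2) / 18))
  # balance point: load zero, r = 1, n = 0.5 -> r(1-n) = n
  L0 <- 1 + 2 / 0.8  # k(L-1) = v
  expect_equal(adhesion_rate(0.5, v = 2, L = L0, p), 0)
  # hand-evaluated generic case
  n <- 0.37; v <- 1.4; L <- 7.2
  expect_equal(adhesion_rate(n, v, L, p),
               1 * (1 - n) - n * exp((0.8 * (L - 1) - v) / (18 * n)))
  # detachment saturates at omega_max
  expect_equal(adhesion_rate(0.01, v = 0, L = 50, p),
               1 * 0.99 - 0.01 * 100)
  expect_error(adhesion_rate(-0.1, 1, 5, p))
})

test_that("length rate and friction branch are sign-consistent", {
  p <- model_params(k = 0.8, kappa = 10)
  L0 <- 1 + 3 / 0.8
  expect_equal(length_rate(0.5, v = 3, L = L0, p), 0)        # force balance
  expect_equal(length_rate(0.5, v = 5, L = L0, p), 2)        # extension
  # retraction divided by the adhesion friction
  expect_equal(length_rate(0.5, v = 1, L = L0, p), -2 / 5)
  # branch consistency on a sweep of states
  for (v in seq(0, 8, by = 0.5)) {
    rate <- length_rate(0.6, v, 6, p)
    expect_equal(sign(rate), sign(v - p$k * 5))
  }
})

test_that("total length bookkeeping follows the spanning rule", {
  expect_equal(total_length(c(1, 1, 1), d = 3), 3)
  expect_equal(total_length(c(1, 1, 1, 1), d = 3), 7)
  expect_equal(total_length(rep(0.5, 5), d = 3), 8.5)
  expect_equal(total_length(c(2, 3), d = 3), 5)  # two-arm: tip-to-tip
  expect_error(total_length(c(1), d = 3))
  expect_error(total_length(c(-1, 2, 2), d = 3))
})

test_that("net arm flows obey the halving rule and the weight identity", {
  star <- list(arm_base = c(1, 1, 1), segments = matrix(numeric(0), ncol = 2))
  m <- junction_distances(star)
  expect_true(all(m[!is.na(m)] == 1))
  expect_equal(net_arm_flow(c(1, 1, 1), m), c(0, 0, 0))
  expect_equal(net_arm_flow(c(2, 1, 1), m)[1], 1)
  # four-arm chain: same-junction weight 1/2, across 1/4; rows sum to 1
  chain <- list(arm_base = c(1, 1, 2, 2), segments = cbind(1, 2))
  m4 <- junction_distances(chain)
  w <- 2^(-m4); diag(w) <- 0
  expect_equal(rowSums(w), rep(1, 4))
  expect_equal(m4[1, 2], 1L)
  expect_equal(m4[1, 3], 2L)
  # all-equal flows give zero net flow in arms and segments
  expect_equal(net_arm_flow(rep(2, 4), m4), rep(0, 4))
  expect_equal(net_segment_flow(rep(2, 4), chain), 0)
})

test_that("segment flows follow the half-sum rule and its generalization", {
  chain <- list(arm_base = c(1, 1, 2, 2), segments = cbind(1, 2))
  expect_equal(net_segment_flow(c(2, 0, 1, 1), chain), 0)
  expect_equal(net_segment_flow(c(3, 1, 1, 1), chain), 1)
  # five arms over three junctions: weights halve at every junction passed
  topo5 <- list(arm_base = c(1, 1, 2, 3, 3), segments = rbind(c(1, 2), c(2, 3)))
  v <- c(4, 2, 1, 3, 5)
  u <- net_segment_flow(v, topo5)
  expect_equal(u[1], (v[1] + v[2]) / 2 - (v[3] / 2 + (v[4] + v[5]) / 4))
  expect_equal(u[2], ((v[1] + v[2]) / 4 + v[3] / 2) - (v[4] + v[5]) / 2)
})

test_that("steady flow targets and the OU step", {
  expect_equal(steady_flow_targets(c(0, 1, 3), 8), c(8, 4, 2))
  expect_error(steady_flow_targets(-0.1, 8))
  p <- model_params(sigma = 0, delta = 2, dt = 1e-3)
  expect_equal(flow_update(3, 3, p), 3)  # fixed point
  # deterministic relaxation follows exp(-delta t)
  v <- 5
  for (s in 1:2000) v <- flow_update(v, 3, p)
  expect_equal(v - 3, 2 * exp(-2 * 2), tolerance = 1e-2)
})

test_that("cue solver matches the finite-volume oracle on generic stars", {
  p <- model_params()
  # uniform when net flows vanish
  ct <- cue_tip_concentrations(c(2, 2, 2), c(0, 0, 0), p = p)
  expect_equal(ct, rep(p$c_amount / 6, 3))
  # mirror-symmetric two-arm cell
  ct2 <- cue_tip_concentrations(c(3, 3), c(1, 1) - 1, p = p)
  expect_equal(ct2[1], ct2[2])
  # generic branched configurations against the independent FD oracle
  cases <- list(list(x = c(2.5, 1.2, 0.8), u = c(1.5, -0.9, -0.6)),
                list(x = c(4, 2, 2), u = c(2.4, -1.0, -1.4)),
                list(x = c(1.5, 1.0), u = c(0.8, -0.8)))
  for (cs in cases) {
    ours <- cue_tip_concentrations(cs$x, cs$u, p = p)
    oracle <- fd_star_cue(cs$x, cs$u, p)
    expect_equal(ours, oracle, tolerance = 0.01)
  }
})

test_that("cue mass is conserved across configurations", {
  p <- model_params()
  total_mass <- function(x, u) {
    # integrate the closed-form profile numerically per arm
    ct <- cue_tip_concentrations(x, u, p = p)
    # node value from tip value: c_tip = c_node exp(-u x / D)
    node <- ct * exp(u * x / p$D)
    expect_lt(max(abs(node - node[1])) / node[1], 1e-8)  # continuity
    sum(vapply(seq_along(x), function(i) {
      s <- seq(0, x[i], length.out = 4000)
      h <- x[i] / 3999
      ci <- node[1] * exp(-u[i] * s / p$D)
      h * (sum(ci) - (ci[1] + ci[length(ci)]) / 2)
    }, 0))
  }
  expect_equal(total_mass(c(2, 2, 2), c(0, 0, 0)), p$c_amount, tolerance = 1e-6)
  expect_equal(total_mass(c(3.2, 1.1, 0.7), c(1.2, -0.5, -0.7)), p$c_amount,
               tolerance = 1e-6)
})
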