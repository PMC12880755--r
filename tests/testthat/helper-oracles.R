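# shared fixtures and independent oracles

p_default <- model_params()

# Fine-grid finite-volume steady state of the cue advection-diffusion
# problem on a star of N arms (lengths x, net inward arm flows u), with a
# conserved total mass c: independent numerical oracle for the package's
# closed-form solver.  Each arm is discretized into m cells; the node is one
# shared cell.  Face fluxes use central diffusion and upwind advection; the
# steady state is the null vector of the conservative rate matrix.
fd_star_cue <- function(x, u, p, m = 300) {
  N <- length(x)
  adv <- -u                      # velocity along arm coordinate (base->tip)
  h <- x / m
  n_unknown <- N * m + 1         # node cell + m cells per arm
  A <- matrix(0, n_unknown, n_unknown)
  idx <- function(i, j) 1 + (i - 1) * m + j   # arm i, cell j (1..m)
  add_flux <- function(from, to, D_over_h, a) {
    # flux from `from` to `to` across a face: D_over_h*(c_from - c_to) +
    # a * (c_from + c_to)/2 (central; cell Peclet numbers are << 1 here)
    A[from, from] <<- A[from, from] - D_over_h - a / 2
    A[from, to] <<- A[from, to] + D_over_h - a / 2
    A[to, from] <<- A[to, from] + D_over_h + a / 2
    A[to, to] <<- A[to, to] - D_over_h + a / 2
  }
  for (i in seq_len(N)) {
    for (j in 0:(m - 1)) {
      from <- if (j == 0) 1L else idx(i, j)
      to <- idx(i, j + 1)
      add_flux(from, to, p$D / h[i], adv[i])
    }
  }
  # per-row scaling by cell widths is a similarity that preserves the null
  # space of the flux-divergence operator in conservative form; solve A c = 0
  # with one concentration pinned
  k <- n_unknown
  cvec <- numeric(n_unknown)
  cvec[k] <- 1
  cvec[-k] <- solve(A[-k, -k, drop = FALSE], -A[-k, k])
  # mass with trapezoid-consistent cell widths (node cell has zero width)
  mass <- 0
  for (i in seq_len(N)) mass <- mass + sum(cvec[idx(i, 1:m)]) * h[i]
  mass <- mass + 0  # node cell carries no length
  cvec <- cvec * p$c_amount / mass
  vapply(seq_len(N), function(i) cvec[idx(i, m)], 0)
}

run_line <- function(p, t_max = 40, seed = 1, ...) {
  net <- line_network()
  simulate_cell(net, cell_two_arm(net), p, seed = seed, t_max = t_max, ...)
}
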