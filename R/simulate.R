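#' Simulate a branched cell on a network
#'
#' Integrates the full stochastic model with the Euler--Maruyama scheme:
#' per-arm length, adhesion and flow dynamics, quasi-static polarity-cue
#' redistribution and flow targets recomputed every step, chemotactic
#' modulation of the tip actin activity by \code{field}, and the discrete
#' topology events (splitting at junctions, tip pinning at branch vertices,
#' element merging when a branch empties).  The total cell length is exactly
#' continuous across every topology event.
#'
#' Reproducibility: all randomness is drawn from per-arm counter-based
#' streams derived from \code{seed} and each arm's birth index, so identical
#' \code{(seed, configuration)} give bit-identical trajectories and arms
#' created by different event histories do not perturb each other's noise.
#'
#' @param net a \code{\link{hex_lattice}}, \code{\link{junction_network}} or
#'   \code{\link{line_network}}.
#' @param cell0 initial cell from \code{\link{cell_two_arm}} or
#'   \code{\link{cell_star}}.
#' @param p a \code{\link{model_params}} object.
#' @param field a \code{\link{chemokine_field}} (default: no field).
#' @param seed integer run seed.
#' @param t_max end time of the run.
#' @param t0 start time (negative for pre-onset episodes of the
#'   gradient-onset protocol).
#' @param record_every sampling interval of the trajectory (0.01 by
#'   default, the protocol sampling used throughout).
#' @param record_arms also record the long per-arm table (time, arm, x, n,
#'   v, beta at tip, tip position, base node)?
#' @param stop_y stop as soon as any tip's y-coordinate reaches this value
#'   (arrival rule of the network chemotaxis protocol).
#' @param stop_escape stop when the cell lies entirely on one branch
#'   (escape rule of the junction protocol).
#' @param escape_node node whose clearing defines escape (the junction
#'   centre).
#' @return a \code{"cell_trajectory"}: list with \code{samples} (data frame:
#'   time, com_x, com_y, L, N, event), optional \code{arms} data frame,
#'   \code{events}, \code{final} state, \code{arrival_time},
#'   \code{escape_branch}, \code{escape_time}, flags, the worst violation
#'   of the flow-splitting weight identity over the whole run
#'   (\code{weight_err_max}), and the run configuration.
#' @examples
#' \donttest{
#' net <- junction_network()
#' cl <- cell_star(net, x = c(2, 0.5, 0.5))
#' tr <- simulate_cell(net, cl, model_params(sigma = 0), seed = 1, t_max = 2)
#' head(tr$samples)
#' }
#' @export
simulate_cell <- function(net, cell0, p, field = chemokine_field("none"),
                          seed = 1, t_max = 100, t0 = 0,
                          record_every = 0.01, record_arms = FALSE,
                          stop_y = Inf, stop_escape = FALSE,
                          escape_node = NULL) {
  stopifnot(inherits(net, "cell_network"), inherits(p, "model_params"),
            inherits(field, "chemokine_field"))
  control <- list(t_max = t_max, t0 = t0, record_every = record_every,
                  record_arms = record_arms, stop_y = stop_y,
                  stop_escape = stop_escape,
                  escape_node = if (is.null(escape_node)) -1L else as.integer(escape_node))
  netl <- list(xy = unname(as.matrix(net$xy)), adj = lapply(net$adj, as.integer))
  res <- .sim_run(netl, cell0, unclass(p), unclass(field), control, as.numeric(seed))
  samples <- data.frame(time = res$time, com_x = res$com_x, com_y = res$com_y,
                        L = res$L, N = res$N, event = res$event)
  out <- list(samples = samples,
              events = data.frame(time = res$events$time,
                                  kind = c("split", "pin", "collapse",
                                           "junction_pass", "regrow")[res$events$kind],
                                  arm = res$events$arm, node = res$events$node),
              final = res$final,
              arrival_time = res$arrival_time,
              escape_branch = res$escape_branch,
              escape_time = res$escape_time,
              finite_ok = res$finite_ok,
              boundary_hit = res$boundary_hit,
              weight_err_max = res$weight_err_max,
              config = list(params = p, field = field, seed = seed,
                            t_max = t_max, t0 = t0,
                            record_every = record_every,
                            net_kind = net$kind, d = net$d, theta = net$theta))
  if (record_arms)
    out$arms <- data.frame(time = res$arms$time, arm_id = res$arms$arm_id,
                           x = res$arms$x, n = res$arms$n, v = res$arms$v,
                           beta_tip = res$arms$beta_tip,
                           tip_x = res$arms$tip_x, tip_y = res$arms$tip_y,
                           base = res$arms$base)
  class(out) <- "cell_trajectory"
  out
}

#' @export
print.cell_trajectory <- function(x, ...) {
  s <- x$samples
  cat(sprintf("cell_trajectory: %d samples over t = [%g, %g], final N = %d\n",
              nrow(s), s$time[1], s$time[nrow(s)], s$N[nrow(s)]))
  if (!is.na(x$arrival_time)) cat(sprintf("  arrived at t = %g\n", x$arrival_time))
  if (!is.na(x$escape_branch)) cat(sprintf("  escaped via node %d at t = %g\n",
                                           x$escape_branch, x$escape_time))
  invisible(x)
}

#' Initial two-arm cell on an edge
#'
#' @param net the network.
#' @param node_a,node_b adjacent nodes; the cell lies on this edge.
#' @param offsets increasing offsets (from \code{node_a}) of the two tips.
#' @param n,v initial adhesion and flow of the two tips.
#' @return an initial-cell description for \code{\link{simulate_cell}}.
#' @export
cell_two_arm <- function(net, node_a = 1L, node_b = 2L,
                         offsets = NULL, n = c(0.8, 0.8), v = c(1, 0.9)) {
  if (is.null(offsets)) {
    el <- sqrt(sum((net$xy[node_b, ] - net$xy[node_a, ])^2))
    offsets <- el / 2 + c(-0.5, 0.5)
  }
  list(kind = "two_arm", node_a = as.integer(node_a), node_b = as.integer(node_b),
       offsets = offsets, n = n, v = v)
}

#' Initial star cell at a junction
#'
#' A cell with one arm along each given branch of a junction node.
#'
#' @param net the network.
#' @param node junction node (defaults to the node nearest the origin).
#' @param toward branch target nodes (default: all neighbours).
#' @param x,n,v per-arm initial length, adhesion, flow (recycled).
#' @return an initial-cell description for \code{\link{simulate_cell}}.
#' @export
cell_star <- function(net, node = NULL, toward = NULL,
                      x = 0.1, n = 0.8, v = 0) {
  if (is.null(node)) node <- nearest_node(net, c(0, 0))
  if (is.null(toward)) toward <- net$adj[[node]]
  N <- length(toward)
  list(kind = "star", node = as.integer(node), toward = as.integer(toward),
       x = rep_len(x, N), n = rep_len(n, N), v = rep_len(v, N))
}

#' Polarized migrating state of a two-arm cell
#'
#' Runs the deterministic (sigma = 0) dynamics of a two-arm cell on a long
#' straight track until it reaches its migrating state, and returns the tip
#' states ordered (front, rear).  Used to initialize the junction protocol
#' with a cell in the polarized incoming state.
#'
#' @param p a \code{\link{model_params}} object.
#' @param t_relax relaxation time.
#' @return list with \code{L}, and front/rear \code{n}, \code{v}.
#' @export
polarized_state_1d <- function(p, t_relax = 30) {
  p0 <- update_params(p, sigma = 0)
  net <- line_network()
  tr <- simulate_cell(net, cell_two_arm(net), p0, seed = 1, t_max = t_relax,
                      record_arms = TRUE)
  a <- tr$arms[tr$arms$time == max(tr$arms$time), ]
  s <- tr$samples[nrow(tr$samples), ]
  front <- which.max(a$v)
  rear <- if (front == 1L) 2L else 1L
  list(L = s$L,
       n_front = a$n[front], v_front = a$v[front],
       n_rear = a$n[rear], v_rear = a$v[rear])
}
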