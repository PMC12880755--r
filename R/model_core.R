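#' Friction coefficient of a cellular arm
#'
#' The leading edge experiences a constant drag (normalized to 1) while the
#' arm extends.  During retraction the drag is carried by the engaged
#' adhesion bonds, \code{Gamma = n * kappa}, bounded below by the bare drag
#' floor \code{gamma_min} of a fully detached edge.  The force dependence of
#' the retraction response is carried by the slip-bond rupture cascade in
#' \code{\link{adhesion_rate}} (see the methods vignette for why the
#' friction itself is taken force-independent).
#'
#' @param n adhesion-bond concentration in (0, 1].
#' @param p a \code{\link{model_params}} object.
#' @param extending logical: is the arm extending (\code{xdot > 0})?
#' @return positive scalar drag coefficient.
#' @examples
#' p <- model_params(kappa = 20)
#' friction_coefficient(n = 1, p, extending = FALSE)   # kappa
#' friction_coefficient(n = 0.3, p, extending = TRUE)  # 1
#' @export
friction_coefficient <- function(n, p, extending) {
  if (any(n <= 0) || any(n > 1)) stop("adhesion n must lie in (0, 1]")
  ifelse(extending, 1, pmax(n * p$kappa, p$gamma_min))
}

#' Slip-bond adhesion dynamics
#'
#' Rate of change of the adhesion-bond concentration at an arm tip:
#' attachment at rate \code{r (1 - n)} and force-accelerated detachment
#' \code{n exp((k (L - 1) - v) / (f_s n))}.  The load per bond is the net
#' contractile force (elastic restoring force minus the protrusive push of
#' the local actin flow) shared among the \code{n} engaged bonds; detachment
#' therefore runs away once the load outgrows \code{f_s}, which is the
#' rupture cascade behind stick-slip migration.  The detachment rate is
#' capped at \code{omega_max} (one bond turnover per \code{1/omega_max} time
#' units) so that a fully detached edge can re-adhere when the load drops.
#'
#' @param n adhesion-bond concentration in (0, 1].
#' @param v local actin flow at the tip.
#' @param L total cell length.
#' @param p a \code{\link{model_params}} object.
#' @return rate \code{dn/dt}.
#' @examples
#' p <- model_params(r = 1, f_s = 18, k = 0.8)
#' adhesion_rate(n = 0.5, v = 2, L = 6, p)
#' @export
adhesion_rate <- function(n, v, L, p) {
  if (any(n <= 0)) stop("adhesion n must be positive")
  load <- (p$k * (L - 1) - v) / (p$f_s * n)
  w_off <- pmin(exp(pmin(load, 50)), p$omega_max)
  p$r * (1 - n) - n * w_off
}

#' Arm elongation rate
#'
#' Force balance at the tip: \code{dx/dt = (v - k (L - 1)) / Gamma}, with
#' the friction branch chosen consistently with the sign of the rate (the
#' extension candidate \code{v - k(L-1)} decides the branch; both branches
#' agree in sign at the switch point).
#'
#' @inheritParams adhesion_rate
#' @return rate \code{dx/dt}.
#' @examples
#' p <- model_params()
#' length_rate(n = 0.8, v = 5, L = 4, p)  # extension: v - k(L-1)
#' @export
length_rate <- function(n, v, L, p) {
  cand <- v - p$k * (L - 1)
  ifelse(cand >= 0, cand, cand / friction_coefficient(n, p, extending = FALSE))
}

#' One Euler--Maruyama step of the actin-flow dynamics
#'
#' \code{v' = v - delta (v - v_star) dt + sigma sqrt(dt) xi} with
#' \code{xi} a standard normal draw.
#'
#' @param v current flow.
#' @param v_star steady-state flow target.
#' @param p a \code{\link{model_params}} object.
#' @param noise_draw standard normal variate(s).
#' @return updated flow.
#' @export
flow_update <- function(v, v_star, p, noise_draw = 0) {
  v - p$delta * (v - v_star) * p$dt + p$sigma * sqrt(p$dt) * noise_draw
}

#' Total cell length
#'
#' For a branched cell with \code{N >= 3} arms spanning \code{N - 2}
#' junctions, \code{L = sum(x) + (N - 3) d}: the arm lengths plus the
#' node-connecting segments fully covered by the cell.  For \code{N = 2} the
#' tip-to-tip arclength is simply \code{sum(x)}.
#'
#' @param x numeric vector of arm lengths.
#' @param d grid size (junction-to-junction distance).
#' @return total length \code{L}.
#' @examples
#' total_length(c(1, 1, 1, 1), d = 3)  # 7
#' @export
total_length <- function(x, d) {
  N <- length(x)
  if (N < 2) stop("a cell has at least two arms")
  if (any(x < 0)) stop("arm lengths must be non-negative")
  if (N == 2) sum(x) else sum(x) + (N - 3) * d
}

#' Net actin flow in each arm
#'
#' \code{u_i = v_i - sum_{j != i} v_j / 2^m_ij}: each arm's treadmilling
#' flow, minus the flows of all other arms halved at every junction they
#' pass on the way.  The weights \code{2^-m_ij} of every row sum to one
#' (checked), so an all-equal flow pattern gives zero net flow everywhere.
#'
#' @param v per-arm flow vector.
#' @param m junction-distance table from \code{\link{junction_distances}}.
#' @return per-arm net flows \code{u}.
#' @examples
#' m <- junction_distances(list(arm_base = c(1, 1, 1),
#'                              segments = matrix(numeric(0), ncol = 2)))
#' net_arm_flow(c(2, 1, 1), m)
#' @export
net_arm_flow <- function(v, m) {
  N <- length(v)
  if (N == 2) return(c(v[1] - v[2], v[2] - v[1]))
  stopifnot(nrow(m) == N)
  w <- 2^(-m)
  diag(w) <- 0
  rs <- rowSums(w)
  if (any(abs(rs - 1) > 1e-9))
    stop("flow-splitting weights do not sum to 1: inconsistent topology")
  as.vector(v - w %*% v)
}

#' Net actin flow in the node-connecting segments
#'
#' For every segment of the cell (a junction-to-junction stretch fully
#' covered by the cell body) the net flow is the difference of the arm flows
#' feeding it from its two sides, each halved at every junction crossed on
#' the way into the segment.  For a single segment QP this reduces to
#' \code{sum(v at Q)/2 - sum(v at P)/2}.
#'
#' @param v per-arm flow vector.
#' @param topo cell topology as in \code{\link{junction_distances}}.
#' @return numeric vector of net flows, one per row of \code{topo$segments},
#'   oriented from the first to the second junction of each row; empty for a
#'   single-junction cell.
#' @examples
#' topo <- list(arm_base = c(1, 1, 2, 2), segments = cbind(1, 2))
#' net_segment_flow(c(2, 0, 1, 1), topo)  # (2+0)/2 - (1+1)/2 = 0
#' @export
net_segment_flow <- function(v, topo) {
  segs <- topo$segments
  if (is.null(dim(segs))) segs <- matrix(segs, ncol = 2)
  if (nrow(segs) == 0) return(numeric(0))
  ab <- topo$arm_base
  juncs <- unique(c(ab, as.vector(segs)))
  # adjacency of the junction graph
  nbrs <- function(j) {
    out <- c(segs[segs[, 1] == j, 2], segs[segs[, 2] == j, 1])
    unique(out)
  }
  u <- numeric(nrow(segs))
  for (i in seq_along(ab)) {
    # distribute arm i's flow: enters at its base, halves at each junction
    front <- list(list(j = ab[i], from = NA, w = v[i]))
    while (length(front)) {
      f <- front[[1]]; front <- front[-1]
      for (s in seq_len(nrow(segs))) {
        a <- segs[s, 1]; b <- segs[s, 2]
        if (!is.na(f$from) && f$from == s) next
        if (a == f$j) {
          u[s] <- u[s] + f$w / 2
          front <- c(front, list(list(j = b, from = s, w = f$w / 2)))
        } else if (b == f$j) {
          u[s] <- u[s] - f$w / 2
          front <- c(front, list(list(j = a, from = s, w = f$w / 2)))
        }
      }
    }
  }
  u
}

#' Steady-state cue concentration at the arm tips
#'
#' Computes the steady-state distribution of a conserved inhibitory cue of
#' total amount \code{c_amount}, advected along the one-dimensional cell
#' body by the net actin flows and diffusing with constant \code{D}, and
#' returns its value at each arm tip.  At steady state on a tree the flux
#' vanishes on every element, so the concentration is piecewise exponential
#' (rate \code{u/D} along each element, decaying toward high-flow tips) with
#' continuity at the junctions; the overall scale is fixed by mass
#' conservation.
#'
#' @param x per-arm lengths.
#' @param u_arm per-arm net flows (positive = toward the cell body).
#' @param topo cell topology (see \code{\link{junction_distances}}); may be
#'   omitted for a single-junction cell.
#' @param u_seg per-segment net flows, oriented as \code{topo$segments}.
#' @param seg_len per-segment lengths.
#' @param p a \code{\link{model_params}} object.
#' @return per-arm normalized tip concentrations \code{c~_i}.
#' @examples
#' p <- model_params()
#' cue_tip_concentrations(c(2, 2, 2), c(0, 0, 0), p = p)  # uniform: c/L
#' @export
cue_tip_concentrations <- function(x, u_arm, topo = NULL, u_seg = numeric(0),
                                   seg_len = numeric(0), p) {
  N <- length(x)
  if (is.null(topo)) topo <- list(arm_base = rep(1, N),
                                  segments = matrix(numeric(0), ncol = 2))
  segs <- topo$segments
  if (is.null(dim(segs))) segs <- matrix(segs, ncol = 2)
  juncs <- unique(c(topo$arm_base, as.vector(segs)))
  logphi <- stats::setNames(rep(NA_real_, length(juncs)), as.character(juncs))
  logphi[1] <- 0
  # propagate log-concentration across segments (c_b = c_a * exp(u l / D))
  repeat {
    progressed <- FALSE
    if (nrow(segs) > 0) for (s in seq_len(nrow(segs))) {
      a <- as.character(segs[s, 1]); b <- as.character(segs[s, 2])
      dphi <- u_seg[s] * seg_len[s] / p$D
      if (!is.na(logphi[a]) && is.na(logphi[b])) { logphi[b] <- logphi[a] + dphi; progressed <- TRUE }
      if (!is.na(logphi[b]) && is.na(logphi[a])) { logphi[a] <- logphi[b] - dphi; progressed <- TRUE }
    }
    if (!progressed) break
  }
  if (anyNA(logphi)) stop("cell topology is disconnected")
  log_h <- function(z) {  # log((e^z - 1)/z), stable
    ifelse(abs(z) < 1e-8, z / 2,
           ifelse(z > 33, z - log(z),
                  ifelse(z < -33, -log(-z), log(expm1(z) / z))))
  }
  lb <- logphi[as.character(topo$arm_base)]
  logm_arm <- ifelse(x > 0, lb + log(pmax(x, 1e-300)) + log_h(-u_arm * x / p$D), -Inf)
  logm_seg <- if (nrow(segs) > 0)
    logphi[as.character(segs[, 1])] + log(seg_len) + log_h(u_seg * seg_len / p$D)
  else numeric(0)
  lm <- c(logm_arm, logm_seg)
  mx <- max(lm)
  logM <- mx + log(sum(exp(lm - mx)))
  logc <- lb - u_arm * x / p$D - logM + log(p$c_amount)
  unname(exp(pmin(logc, 700)))
}

#' Steady-state flow targets
#'
#' \code{v*_i = beta_i / (1 + c~_i)}: the local actin activity at each tip,
#' suppressed by the inhibitory cue concentration there.
#'
#' @param c_tilde per-arm tip cue concentrations (non-negative).
#' @param beta_tips per-arm actin activity (scalar recycled).
#' @return per-arm flow targets.
#' @examples
#' steady_flow_targets(c(0, 1, 3), 8)  # 8, 4, 2
#' @export
steady_flow_targets <- function(c_tilde, beta_tips) {
  if (any(c_tilde < 0)) stop("cue concentrations must be non-negative")
  beta_tips / (1 + c_tilde)
}
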