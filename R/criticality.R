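#' Spreading length of a symmetric cell
#'
#' The stationary length \code{L_p} at which the protrusive force of the
#' actin flow balances the cell elasticity for a symmetrically spread cell
#' with a uniform cue, i.e. the solution of
#' \code{k (L - 1) = beta / (1 + c / L)}:
#' \deqn{L_p = A + \sqrt{A^2 + c}, \quad A = (1 - c + \beta/k)/2.}
#'
#' @param beta actin activity.
#' @param p a \code{\link{model_params}} object.
#' @return the spreading length.
#' @examples
#' spread_length_Lp(6, model_params())
#' @export
spread_length_Lp <- function(beta, p) {
  A <- (1 - p$c_amount + beta / p$k) / 2
  disc <- A^2 + p$c_amount
  if (any(disc < 0)) stop("negative discriminant in L_p")
  A + sqrt(disc)
}

#' Polarization length on a single junction
#'
#' The critical length \code{L_c} above which the uniform-flow state of a
#' symmetric cell on a single junction loses stability and the arms'
#' flows spontaneously deviate (symmetry breaking):
#' \deqn{L_c = c / (\sqrt{c \beta / (2 D)} - 1),}
#' finite and positive for \code{c beta / (2 D) > 1}.  Obtained from the
#' linear stability of the uniform state under the quasi-static cue with
#' the antisymmetric flow perturbations of the three-arm geometry.
#'
#' @inheritParams spread_length_Lp
#' @return the polarization length (\code{Inf} below the pole).
#' @examples
#' polarization_length_Lc(8, model_params())
#' @export
polarization_length_Lc <- function(beta, p) {
  s <- sqrt(p$c_amount * beta / (2 * p$D))
  ifelse(s > 1, p$c_amount / (s - 1), Inf)
}

#' Critical actin activity on a single junction
#'
#' The activity \code{beta_c} above which a cell spreading symmetrically on
#' a single junction polarizes and migrates, obtained by equating the
#' spreading length and the polarization length.  The closed form is
#' \deqn{\beta_c = D/c + c k + c k^2/(4D) +
#'   \frac{2D - ck}{4cD}\sqrt{4D^2 + 4c(1+2c)Dk + c^2k^2}.}
#' It is checked against the numerical root of
#' \code{L_p(beta) = L_c(beta)} (bisection on \code{[1, 20]} to 1e-6 by
#' default); a disagreement signals an inconsistent parameter set.
#'
#' @param p a \code{\link{model_params}} object.
#' @param window search window for the cross-checking root finder.
#' @param tol root-finder tolerance.
#' @return the critical activity.
#' @examples
#' critical_beta_single(model_params())  # about 5.9
#' @export
critical_beta_single <- function(p, window = c(1, 20), tol = 1e-6) {
  cc <- p$c_amount; k <- p$k; D <- p$D
  bc <- D / cc + cc * k + cc * k^2 / (4 * D) +
    (2 * D - cc * k) / (4 * cc * D) *
    sqrt(4 * D^2 + 4 * cc * (1 + 2 * cc) * D * k + cc^2 * k^2)
  f <- function(b) spread_length_Lp(b, p) - polarization_length_Lc(b, p)
  lo <- max(window[1], 2 * p$D / p$c_amount + 1e-9)  # above the L_c pole
  if (f(lo) > 0 || f(window[2]) < 0)
    stop("no polarization threshold in the search window")
  root <- stats::uniroot(f, c(lo, window[2]), tol = tol)$root
  if (abs(root - bc) > 1e-4 * max(1, bc))
    stop("closed form and root of L_p = L_c disagree; inconsistent parameters")
  bc
}

#' Minimal length of a junction-spanning cell
#'
#' A cell with \code{N > 3} arms spans \code{N - 2} junctions and must cover
#' the \code{N - 3} connecting segments: \code{L_min = (N - 3) d}.
#'
#' @param N arm count.
#' @param d grid size.
#' @return the minimal spanning length.
#' @examples
#' min_spanning_length(6, 3.7)  # 11.1
#' @export
min_spanning_length <- function(N, d) {
  stopifnot(N >= 3, d > 0)
  (N - 3) * d
}

#' Critical activities for multi-junction cells
#'
#' \code{beta_d}: the activity at which the symmetric spreading length
#' reaches the minimal spanning length \code{(N-3) d}, i.e. the threshold
#' for a cell to span \code{N - 2} junctions.  \code{beta_c_N}: the
#' activity above which the spanning symmetric state polarizes, obtained by
#' a deterministic simulation scan (bisection on beta): a symmetric cell
#' with \code{N} arms is seeded with a small flow asymmetry and classified
#' as migrating when its centre of mass moves by more than one grid length
#' within the scan horizon.
#'
#' @param N arm count (> 3; for N = 3 the single-junction values apply).
#' @param d grid size.
#' @param p a \code{\link{model_params}} object.
#' @param resolution bisection resolution in beta for \code{beta_c_N}.
#' @param t_scan horizon of each deterministic run.
#' @param window beta search window.
#' @return list with \code{beta_d} and \code{beta_c_N}.
#' @export
critical_beta_multi <- function(N, d, p, resolution = 0.1, t_scan = 60,
                                window = c(2, 20)) {
  stopifnot(N >= 3)
  if (N == 3) {
    bc <- critical_beta_single(p)
    return(list(beta_d = bc, beta_c_N = bc))
  }
  Lmin <- min_spanning_length(N, d)
  f <- function(b) spread_length_Lp(b, p) - Lmin
  if (f(window[1]) > 0) beta_d <- window[1]
  else if (f(window[2]) < 0) stop("no spanning threshold in window")
  else beta_d <- stats::uniroot(f, window, tol = 1e-6)$root
  lo <- max(beta_d, critical_beta_single(p))
  hi <- window[2]
  migr <- function(beta) .spanning_cell_migrates(N, d, update_params(p, beta0 = beta),
                                                 t_scan)
  if (!migr(hi)) return(list(beta_d = beta_d, beta_c_N = NA_real_))
  while (hi - lo > resolution) {
    mid <- (lo + hi) / 2
    if (migr(mid)) hi <- mid else lo <- mid
  }
  list(beta_d = beta_d, beta_c_N = (lo + hi) / 2)
}

# deterministic migration test of an N-arm chain-spanning cell
.spanning_cell_migrates <- function(N, d, p, t_scan) {
  p0 <- update_params(p, sigma = 0)
  net <- hex_lattice(d = d, nx = 2 * N + 6, ny = 2 * N + 6)
  # grow a symmetric cell by spreading a small star from the origin junction:
  # seed with N = 3 star plus a tiny asymmetry in v
  o <- nearest_node(net, c(0, 0))
  cl <- cell_star(net, node = o, x = 0.1, n = 0.8, v = c(0.02, 0.011, 0.01))
  tr <- simulate_cell(net, cl, p0, seed = 1, t_max = t_scan)
  s <- tr$samples
  disp <- sqrt((s$com_x - s$com_x[1])^2 + (s$com_y - s$com_y[1])^2)
  reachedN <- max(s$N) >= N
  reachedN && max(disp) > d
}

#' Onset of stick-slip migration on a one-dimensional line
#'
#' Scans the actin activity over \code{beta_grid} with a two-arm cell on an
#' unbounded straight track and returns the smallest value at which the
#' migrating solution exhibits sustained length oscillations with
#' retraction phases, detected by \code{\link{detect_stick_slip}} on the
#' post-transient trajectory.  Returns \code{Inf} ("above grid") if the
#' detector never fires.
#'
#' @param p a \code{\link{model_params}} object (\code{sigma} is forced
#'   to 0; the onset is a deterministic bifurcation).
#' @param beta_grid activities to scan.
#' @param t_run run length per grid point (the first third is discarded as
#'   transient).
#' @param drop_frac,n_cycles stick-slip detector settings.
#' @return list with \code{threshold} (smallest oscillatory beta),
#'   \code{resolution} (grid step), and the per-beta detector table.
#' @export
stick_slip_threshold_1d <- function(p, beta_grid = seq(6, 13, by = 0.5),
                                    t_run = 120, drop_frac = 0.2,
                                    n_cycles = 2) {
  p0 <- update_params(p, sigma = 0)
  net <- line_network()
  hit <- logical(length(beta_grid))
  for (i in seq_along(beta_grid)) {
    pb <- update_params(p0, beta0 = beta_grid[i])
    tr <- simulate_cell(net, cell_two_arm(net), pb, seed = 1, t_max = t_run)
    s <- tr$samples[tr$samples$time > t_run / 3, ]
    ev <- detect_stick_slip(list(samples = s), drop_frac = drop_frac,
                            n_cycles = n_cycles)
    hit[i] <- nrow(ev) > 0
  }
  th <- if (any(hit)) min(beta_grid[hit]) else Inf
  res <- if (length(beta_grid) > 1) min(diff(sort(beta_grid))) else NA_real_
  list(threshold = th, resolution = res,
       table = data.frame(beta0 = beta_grid, stick_slip = hit))
}

#' Criticality summary
#'
#' Collects the analytic critical lengths and activities, the per-N
#' multi-junction thresholds, and the simulated one-dimensional stick-slip
#' onset into one object (exportable as JSON via \code{jsonlite}).
#'
#' @param p a \code{\link{model_params}} object.
#' @param d grid size for the multi-junction thresholds.
#' @param N_max largest arm count scanned.
#' @param ... passed to \code{\link{stick_slip_threshold_1d}}.
#' @return a list of class \code{"criticality_summary"}.
#' @export
criticality_summary <- function(p, d = 3, N_max = 5, ...) {
  bc <- critical_beta_single(p)
  multi <- lapply(4:max(4, N_max), function(N) critical_beta_multi(N, d, p))
  ss <- stick_slip_threshold_1d(p, ...)
  out <- list(beta_c = bc,
              L_p_at_beta_c = spread_length_Lp(bc, p),
              L_c_at_beta_c = polarization_length_Lc(bc, p),
              beta_d = stats::setNames(vapply(multi, `[[`, 0, "beta_d"),
                                       paste0("N", 4:max(4, N_max))),
              beta_c_N = stats::setNames(vapply(multi, `[[`, 0, "beta_c_N"),
                                         paste0("N", 4:max(4, N_max))),
              L_min = stats::setNames(min_spanning_length(3:max(4, N_max), d),
                                      paste0("N", 3:max(4, N_max))),
              beta_stick_slip_1d = ss$threshold,
              stick_slip_resolution = ss$resolution,
              d = d)
  class(out) <- "criticality_summary"
  out
}

#' @export
print.criticality_summary <- function(x, ...) {
  cat(sprintf("beta_c (single junction): %.4f\n", x$beta_c))
  cat(sprintf("L_p = L_c at beta_c:      %.4f = %.4f\n",
              x$L_p_at_beta_c, x$L_c_at_beta_c))
  cat(sprintf("1D stick-slip onset:      %s (resolution %g)\n",
              format(x$beta_stick_slip_1d), x$stick_slip_resolution))
  cat("beta_d:  ", paste(sprintf("%s=%.3f", names(x$beta_d), x$beta_d),
                         collapse = "  "), "\n")
  cat("beta_c_N:", paste(sprintf("%s=%.3f", names(x$beta_c_N), x$beta_c_N),
                         collapse = "  "), "\n")
  invisible(x)
}
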