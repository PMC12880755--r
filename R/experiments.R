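#' Single-junction decision sweep
#'
#' Reproducible protocol for decision-making statistics at a single
#' junction.  For every \code{beta0} in the grid, \code{reps} stochastic
#' runs are performed: the cell is initialized spanning the junction in the
#' polarized incoming state (rear arm along the incoming branch with the
#' deterministic migrating length and tip states of a one-dimensional cell;
#' two nascent daughter arms on the outgoing branches), the tip of the arm
#' facing the source gets the enhanced activity \code{beta0 (1 + eps)}, and
#' the run ends at escape (cell entirely on one branch) or at \code{t_max}.
#'
#' @param beta0_grid actin activities to sweep.
#' @param p base \code{\link{model_params}} (its \code{beta0}/\code{sigma}
#'   are overridden per point).
#' @param sigma flow-noise amplitude of the protocol.
#' @param eps relative chemotactic enhancement on the source branch.
#' @param reps stochastic runs per grid point.
#' @param t_max maximal simulation time per run.
#' @param seed base seed; run \code{j} of point \code{i} uses
#'   \code{seed + 7919 * (i - 1) + j}.
#' @param slow_args arguments for \code{\link{detect_slow_mode}}.
#' @param ss_args arguments for \code{\link{detect_stick_slip}}.
#' @param init \code{"approach"} (default): the cell starts as a polarized
#'   two-arm cell one grid length below the junction and arrives under the
#'   protocol noise, so the state in which it engages the junction carries
#'   realistic fluctuations; escape times are measured from the splitting
#'   event.  \code{"spanning"}: the cell is placed directly astride the
#'   junction in the deterministic polarized incoming state.
#' @param approach_dist starting distance of the front tip below the
#'   junction (\code{init = "approach"}), in units of the grid size.
#' @param keep_records return per-run records as an attribute?
#' @return data frame with one row per \code{beta0}: decision statistics
#'   with standard errors, plus per-point median within-episode length
#'   ratios; per-run records in \code{attr(, "records")} when requested.
#' @export
run_junction_sweep <- function(beta0_grid = seq(6, 11, by = 0.5),
                               p = model_params(), sigma = 0.1, eps = 0.001,
                               reps = 100, t_max = 100, seed = 1,
                               slow_args = list(), ss_args = list(),
                               init = c("approach", "spanning"),
                               approach_dist = 1, keep_records = FALSE) {
  stopifnot(reps >= 1)
  init <- match.arg(init)
  net <- junction_network()
  blen <- -net$xy[2, 2]  # branch length (branch 1 points toward -y)
  field <- chemokine_field("junction_bias", eps = eps, biased_node = 4L)
  rows <- list(); allrec <- list()
  for (i in seq_along(beta0_grid)) {
    b <- beta0_grid[i]
    pb <- update_params(p, beta0 = b, sigma = sigma)
    inc <- polarized_state_1d(pb)
    if (init == "spanning") {
      x0 <- c(max(inc$L - 2 * p$eps_split, 0.5), p$eps_split, p$eps_split)
      cl <- cell_star(net, node = 1L, toward = c(2L, 3L, 4L), x = x0,
                      n = c(inc$n_rear, inc$n_front, inc$n_front),
                      v = c(inc$v_rear, inc$v_front, inc$v_front))
    } else {
      # polarized two-arm cell on the incoming branch, front tip
      # approach_dist grid lengths below the junction, migrating toward it
      front_off <- blen - approach_dist * net$d
      cl <- cell_two_arm(net, node_a = 2L, node_b = 1L,
                         offsets = c(front_off - inc$L, front_off),
                         n = c(inc$n_rear, inc$n_front),
                         v = c(inc$v_rear, inc$v_front))
    }
    rec <- vector("list", reps)
    for (j in seq_len(reps)) {
      tr <- simulate_cell(net, cl, pb, field,
                          seed = seed + 7919 * (i - 1) + j,
                          t_max = t_max, record_arms = TRUE,
                          stop_escape = TRUE, escape_node = 1L)
      dr <- classify_junction_outcome(tr, source_branch = 4L,
                                      back_branch = 2L, t_max = t_max)
      if (init == "approach") {
        sp <- tr$events$time[tr$events$kind == "split"]
        if (length(sp)) {
          dr$T_esc <- dr$T_esc - sp[1]
        } else {
          # never engaged the junction: moving away along the incoming branch
          dr$outcome <- "back"
        }
      }
      slow_ep <- do.call(detect_slow_mode,
                         c(list(traj = tr, d = net$d), slow_args))
      ss_ep <- do.call(detect_stick_slip, c(list(traj = tr), ss_args))
      dr$slow <- nrow(slow_ep) > 0
      dr$stick_slip <- nrow(ss_ep) > 0
      ratios <- c(ss_ep$ratio, slow_ep$ratio)
      dr$ratio <- if (length(ratios)) stats::median(ratios) else NA_real_
      dr$beta0 <- b
      dr$seed <- seed + 7919 * (i - 1) + j
      rec[[j]] <- dr
    }
    rec <- do.call(rbind, rec)
    st <- ensemble_decision_stats(rec)
    st$beta0 <- b
    st$P_stick_slip <- mean(rec$stick_slip)
    st$ratio_median <- stats::median(rec$ratio, na.rm = TRUE)
    rows[[i]] <- st
    if (keep_records) allrec[[i]] <- rec
  }
  out <- do.call(rbind, rows)
  out <- out[, c("beta0", setdiff(names(out), "beta0"))]
  if (keep_records) attr(out, "records") <- do.call(rbind, allrec)
  out
}

#' Network chemotaxis sweep
#'
#' Branched-cell chemotaxis on a hexagonal network with an exponentially
#' decaying chemokine line source at \code{y_source = 8 d}.  Cells start
#' symmetrically at the origin, spread, polarize and migrate; a run ends
#' when any arm tip reaches \code{y_arr = 6.5 d} or at \code{t_max}
#' (non-arrivals keep \code{T_arr = t_max}).
#'
#' @param beta0_grid actin activities to sweep.
#' @param p base \code{\link{model_params}}.
#' @param C_over_c0 saturation ratio: 0.01 for the strong-signal regime,
#'   1 for the weak-signal regime.
#' @param sigma flow-noise amplitude.
#' @param d grid size.
#' @param eps maximal relative enhancement.
#' @param y0_factor decay length in units of \code{d}.
#' @param reps runs per grid point.
#' @param t_max maximal run time.
#' @param seed base seed.
#' @param nx,ny lattice extent (unit cells).
#' @param keep_records return per-run records as an attribute?
#' @return data frame with one row per \code{beta0}: mean arrival time,
#'   path length, forward speed and FMI with standard errors, and the
#'   non-arrival fraction.
#' @export
run_network_sweep <- function(beta0_grid = seq(6, 10, by = 0.5),
                              p = model_params(), C_over_c0 = 1,
                              sigma = 0.1, d = 3, eps = 0.2,
                              y0_factor = 1.5, reps = 100, t_max = 1000,
                              seed = 1, nx = 90, ny = 90,
                              keep_records = FALSE) {
  net <- hex_lattice(d = d, theta = 0, nx = nx, ny = ny)
  field <- chemokine_field("line_exp", eps = eps, c0 = 1,
                           C_sat = C_over_c0, decay = y0_factor * d,
                           source_y = 8 * d)
  o <- nearest_node(net, c(0, 0))
  rows <- list(); allrec <- list()
  for (i in seq_along(beta0_grid)) {
    b <- beta0_grid[i]
    pb <- update_params(p, beta0 = b, sigma = sigma)
    rec <- vector("list", reps)
    for (j in seq_len(reps)) {
      cl <- cell_star(net, node = o, x = 0.1, n = 0.8, v = 0)
      tr <- simulate_cell(net, cl, pb, field,
                          seed = seed + 104729 * (i - 1) + j,
                          t_max = t_max, stop_y = 6.5 * d)
      am <- arrival_metrics(tr, y_arr = 6.5 * d, t_max = t_max)
      am$beta0 <- b
      am$boundary <- tr$boundary_hit
      rec[[j]] <- am
    }
    rec <- do.call(rbind, rec)
    n <- nrow(rec)
    sem <- function(v) stats::sd(v) / sqrt(n)
    rows[[i]] <- data.frame(
      beta0 = b, n = n,
      T_arr_mean = mean(rec$T_arr), T_arr_sem = sem(rec$T_arr),
      L_path_mean = mean(rec$L_path), L_path_sem = sem(rec$L_path),
      v_y_mean = mean(rec$v_y_mean), v_y_sem = sem(rec$v_y_mean),
      FMI_mean = mean(rec$FMI), FMI_sem = sem(rec$FMI),
      non_arrival = mean(!rec$arrived))
    if (keep_records) allrec[[i]] <- rec
  }
  out <- do.call(rbind, rows)
  if (keep_records) attr(out, "records") <- do.call(rbind, allrec)
  out
}

#' Gradient-onset (laser-wound) reorientation protocol
#'
#' Reproduces the reorientation experiment: cells migrate freely for
#' \code{t_pre} time units, at \code{t = 0} a spatially linear chemokine
#' profile along +y is switched on, and the response is followed for
#' \code{t_post}.  Only runs whose pre-onset mean y-velocity is negative
#' (cells moving away from the future source) are kept, resampling seeds
#' until \code{runs_per_angle} qualify per lattice angle.  Lattices rotated
#' in 10-degree steps average out the orientation of the hexagonal grid
#' relative to the gradient.
#'
#' @param p base \code{\link{model_params}}; the protocol defaults follow
#'   the calibrated comparison point (\code{beta0 = 12}, \code{sigma = 0.5}).
#' @param beta0,sigma,eps,d protocol parameters.
#' @param angles lattice rotation angles (degrees).
#' @param runs_per_angle qualifying runs kept per angle.
#' @param t_pre,t_post pre- and post-onset durations.
#' @param y_source,slope_len linear-profile geometry (in units of d).
#' @param seed base seed.
#' @param max_tries seed resampling cap per angle.
#' @param bm_args arguments for \code{\link{bm_time}}.
#' @return list with the kept trajectories' metrics (\code{runs}),
#'   LW-aligned and BM-aligned ensemble speed curves, pre/post FMI and the
#'   post-onset ensemble mean cell length and speed.
#' @export
run_lw_protocol <- function(p = model_params(), beta0 = 12, sigma = 0.5,
                            eps = 0.1, d = 3, angles = seq(0, 110, by = 10),
                            runs_per_angle = 5, t_pre = 20, t_post = 30,
                            y_source = 20, slope_len = 40, seed = 1,
                            max_tries = 40, bm_args = list()) {
  pb <- update_params(p, beta0 = beta0, sigma = sigma)
  field <- chemokine_field("linear", eps = eps, c0 = 1,
                           source_y = y_source * d, slope_len = slope_len * d,
                           onset = 0)
  trajs <- list(); meta <- list()
  kk <- 0L
  for (ai in seq_along(angles)) {
    net <- hex_lattice(d = d, theta = angles[ai], nx = 60, ny = 60)
    o <- nearest_node(net, c(0, 0))
    got <- 0L; tries <- 0L
    while (got < runs_per_angle && tries < max_tries) {
      tries <- tries + 1L
      sd_run <- seed + 15485863 * (ai - 1) + tries
      cl <- cell_star(net, node = o, x = 0.1, n = 0.8, v = 0)
      tr <- simulate_cell(net, cl, pb, field, seed = sd_run,
                          t0 = -t_pre, t_max = t_post)
      s <- tr$samples
      pre <- s[s$time >= -5 & s$time <= 0, ]
      if (nrow(pre) < 2) next
      vy_pre <- (pre$com_y[nrow(pre)] - pre$com_y[1]) /
                (pre$time[nrow(pre)] - pre$time[1])
      if (vy_pre < 0) {
        got <- got + 1L; kk <- kk + 1L
        trajs[[kk]] <- tr
        meta[[kk]] <- data.frame(angle = angles[ai], seed = sd_run,
                                 vy_pre = vy_pre)
      }
    }
  }
  if (!length(trajs)) stop("no qualifying runs; increase max_tries")
  meta <- do.call(rbind, meta)
  bm <- vapply(trajs, function(tr) do.call(bm_time, c(list(traj = tr), bm_args)),
               0)
  # per-run metrics
  per_run <- do.call(rbind, lapply(seq_along(trajs), function(i) {
    tr <- trajs[[i]]
    s <- tr$samples
    post <- s[s$time >= 0, ]
    pre <- s[s$time < 0, ]
    fmi_of <- function(ss) {
      if (nrow(ss) < 2) return(NA_real_)
      dpl <- sum(sqrt(diff(ss$com_x)^2 + diff(ss$com_y)^2))
      if (dpl <= 0) return(0)
      (ss$com_y[nrow(ss)] - ss$com_y[1]) / dpl
    }
    sp <- com_speed(tr)
    post_sp <- sp$speed[sp$time >= 0]
    data.frame(angle = meta$angle[i], bm_time = bm[i],
               fmi_pre = fmi_of(pre), fmi_post = fmi_of(post),
               L_mean_post = mean(post$L), speed_mean_post = mean(post_sp),
               vx_mean_post = (post$com_x[nrow(post)] - post$com_x[1]) /
                 (post$time[nrow(post)] - post$time[1]))
  }))
  lw_curve <- event_aligned_average(trajs, rep(0, length(trajs)),
                                    window = min(t_pre, t_post) - 1)
  bm_curve <- event_aligned_average(trajs, bm, window = 10)
  list(runs = per_run,
       lw_curve = lw_curve,
       bm_curve = bm_curve,
       fmi_pre = mean(per_run$fmi_pre, na.rm = TRUE),
       fmi_post = mean(per_run$fmi_post, na.rm = TRUE),
       fmi_change = mean(per_run$fmi_post, na.rm = TRUE) -
                    mean(per_run$fmi_pre, na.rm = TRUE),
       mean_length = mean(per_run$L_mean_post),
       mean_speed = mean(per_run$speed_mean_post),
       n_runs = nrow(per_run))
}

#' Cytoskeletal drug scenarios
#'
#' Side-by-side comparison of the wild-type parameter set with the two drug
#' mimics: actin-polymerization inhibition (CK666) as a 17 percent
#' reduction of \code{beta0}, and myosin-II inhibition (blebbistatin) as a
#' joint reduction of the contractile stiffness \code{k} and \code{beta0}
#' chosen to keep the cell length near wild type while lowering the speed.
#'
#' @param p wild-type \code{\link{model_params}} (typically
#'   \code{beta0 = 12}, \code{sigma = 0.5}).
#' @param scenarios named list of multiplier lists (\code{beta0_mult},
#'   \code{k_mult}).
#' @param reps runs per scenario.
#' @param t_max run length.
#' @param d grid size.
#' @param seed base seed.
#' @return data frame with one row per scenario: mean speed, mean cell
#'   length and FMI with standard errors.
#' @export
run_drug_scenarios <- function(p = model_params(beta0 = 12, sigma = 0.5),
                               scenarios = list(
                                 WT = list(beta0_mult = 1, k_mult = 1),
                                 CK666 = list(beta0_mult = 0.83, k_mult = 1),
                                 blebbistatin = list(beta0_mult = 0.83,
                                                     k_mult = 0.83)),
                               reps = 20, t_max = 60, d = 3, seed = 1) {
  net <- hex_lattice(d = d, nx = 70, ny = 70)
  field <- chemokine_field("line_exp", eps = 0.2, C_sat = 0.01,
                           decay = 1.5 * d, source_y = 8 * d)
  o <- nearest_node(net, c(0, 0))
  out <- lapply(names(scenarios), function(nm) {
    sc <- scenarios[[nm]]
    ps <- update_params(p, beta0 = p$beta0 * sc$beta0_mult,
                        k = p$k * sc$k_mult)
    rec <- lapply(seq_len(reps), function(j) {
      cl <- cell_star(net, node = o, x = 0.1, n = 0.8, v = 0)
      tr <- simulate_cell(net, cl, ps, field, seed = seed + j, t_max = t_max)
      sp <- com_speed(tr)
      am <- arrival_metrics(tr, t_max = t_max)
      data.frame(speed = mean(sp$speed), L = mean(tr$samples$L),
                 FMI = am$FMI)
    })
    rec <- do.call(rbind, rec)
    n <- nrow(rec)
    data.frame(scenario = nm,
               beta0 = p$beta0 * sc$beta0_mult, k = p$k * sc$k_mult,
               speed_mean = mean(rec$speed), speed_sem = stats::sd(rec$speed) / sqrt(n),
               L_mean = mean(rec$L), L_sem = stats::sd(rec$L) / sqrt(n),
               FMI_mean = mean(rec$FMI), FMI_sem = stats::sd(rec$FMI) / sqrt(n),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
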