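#' Classify the outcome of a single-junction run
#'
#' Escape is the first time the occupied region lies entirely on one
#' outgoing branch (the rear tip has cleared the junction).  The outcome is
#' \code{"correct"} for the branch facing the source, \code{"wrong_forward"}
#' for the other new branch, and \code{"back"} for the incoming branch.
#' Runs that do not escape by \code{t_max} are assigned the direction of
#' the longest arm at the end of the run and flagged.
#'
#' @param traj a \code{cell_trajectory} from a junction-protocol run.
#' @param source_branch node id of the branch toward the source.
#' @param back_branch node id of the incoming branch.
#' @param t_max maximal simulation time of the protocol.
#' @return a one-row data frame (\code{DecisionRecord}): \code{outcome},
#'   \code{T_esc}, \code{timeout}.
#' @export
classify_junction_outcome <- function(traj, source_branch = 4L,
                                      back_branch = 2L, t_max = 100) {
  if (is.null(traj$samples) || nrow(traj$samples) == 0)
    stop("malformed trajectory: no samples")
  if (!is.na(traj$escape_branch)) {
    out <- if (traj$escape_branch == source_branch) "correct"
           else if (traj$escape_branch == back_branch) "back"
           else "wrong_forward"
    return(data.frame(outcome = out, T_esc = traj$escape_time,
                      timeout = FALSE, stringsAsFactors = FALSE))
  }
  # timeout: longest-arm rule on the final state
  fin <- traj$final
  if (identical(fin$kind, "tree")) {
    br <- fin$branch[which.max(fin$x)]
  } else {
    # two-arm cell still straddling: side with more length; fall back to the
    # larger tip-to-centre branch via the last recorded arm positions
    br <- fin$a_to
    if (!is.null(traj$arms) && nrow(traj$arms) > 0) {
      last <- traj$arms[traj$arms$time == max(traj$arms$time), ]
      br <- fin[[if (last$x[1] >= last$x[2]) "a_to" else "b_to"]]
    }
  }
  out <- if (br == source_branch) "correct"
         else if (br == back_branch) "back" else "wrong_forward"
  data.frame(outcome = out, T_esc = t_max, timeout = TRUE,
             stringsAsFactors = FALSE)
}

#' Ensemble decision statistics
#'
#' Means with standard errors for the junction decision ensemble: mean
#' escape time, error rate \code{P(wrong)} (any exit not toward the
#' source), reflection probability \code{P(back)}, and slow-mode
#' probability \code{P(slow)}, with binomial standard errors for the
#' probabilities.
#'
#' @param records data frame with columns \code{outcome}, \code{T_esc} and
#'   optionally \code{slow} (logical).
#' @return one-row data frame of means and standard errors.
#' @export
ensemble_decision_stats <- function(records) {
  n <- nrow(records)
  if (is.null(n) || n < 2) stop("need at least two decision records")
  bin_sem <- function(p) sqrt(p * (1 - p) / n)
  p_wrong <- mean(records$outcome != "correct")
  p_back <- mean(records$outcome == "back")
  p_slow <- if ("slow" %in% names(records)) mean(records$slow) else NA_real_
  data.frame(n = n,
             T_esc_mean = mean(records$T_esc),
             T_esc_sem = stats::sd(records$T_esc) / sqrt(n),
             P_wrong = p_wrong, P_wrong_sem = bin_sem(p_wrong),
             P_back = p_back, P_back_sem = bin_sem(p_back),
             P_slow = p_slow,
             P_slow_sem = if (is.na(p_slow)) NA_real_ else bin_sem(p_slow))
}

#' Detect slow-mode (tug-of-war) episodes
#'
#' A slow-mode episode is a maximal interval during which (a) at least two
#' arms exceed \code{theta_lead}, (b) the shortest (rear) arm is below
#' \code{theta_rear}, and (c) the rear arm's base node is unchanged,
#' sustained for at least \code{tau_min}.  Requires a trajectory recorded
#' with \code{record_arms = TRUE}.
#'
#' @param traj a \code{cell_trajectory} with an \code{arms} table.
#' @param theta_rear rear-arm length threshold.
#' @param theta_lead leading-arm length threshold (default: two grid
#'   lengths, which places the detected slow-mode onset in the expected
#'   activity window; see the methods vignette).
#' @param tau_min minimal episode duration.
#' @param d grid size used for the default \code{theta_lead}.
#' @return data frame of episodes: \code{t_start}, \code{t_end},
#'   \code{duration}, and the total-length excursion over the episode
#'   (including the resolving retraction, window padded by \code{tau_min}):
#'   \code{L_max}, \code{L_min}, \code{ratio}.
#' @export
detect_slow_mode <- function(traj, theta_rear = 0.2, theta_lead = NULL,
                             tau_min = 5, d = 3) {
  if (theta_rear <= 0 || tau_min <= 0) stop("thresholds must be positive")
  if (is.null(theta_lead)) theta_lead <- 2 * d
  a <- traj$arms
  if (is.null(a)) stop("trajectory was not recorded with record_arms = TRUE")
  tt <- sort(unique(a$time))
  cond <- logical(length(tt))
  rear_node <- rep(NA_integer_, length(tt))
  sp <- split(a, a$time)
  for (i in seq_along(tt)) {
    ai <- sp[[i]]
    if (nrow(ai) < 3) next
    xs <- sort(ai$x, decreasing = TRUE)
    rear <- which.min(ai$x)
    cond[i] <- xs[2] > theta_lead && ai$x[rear] < theta_rear
    rear_node[i] <- ai$base[rear]
  }
  ep <- .intervals_from_condition(tt, cond, rear_node, tau_min)
  if (nrow(ep) && !is.null(traj$samples)) {
    s <- traj$samples
    ep$L_max <- ep$L_min <- NA_real_
    for (r in seq_len(nrow(ep))) {
      w <- s$L[s$time >= ep$t_start[r] & s$time <= ep$t_end[r] + tau_min]
      ep$L_max[r] <- max(w); ep$L_min[r] <- min(w)
    }
    ep$ratio <- ep$L_max / pmax(ep$L_min, 1e-12)
  }
  ep
}

.intervals_from_condition <- function(tt, cond, group, tau_min) {
  out <- data.frame(t_start = numeric(0), t_end = numeric(0),
                    duration = numeric(0))
  i <- 1L
  while (i <= length(tt)) {
    if (isTRUE(cond[i])) {
      j <- i
      while (j < length(tt) && isTRUE(cond[j + 1L]) &&
             (is.na(group[j + 1L]) || is.na(group[i]) ||
              group[j + 1L] == group[i])) j <- j + 1L
      if (tt[j] - tt[i] >= tau_min)
        out <- rbind(out, data.frame(t_start = tt[i], t_end = tt[j],
                                     duration = tt[j] - tt[i]))
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

#' Detect stick-slip episodes
#'
#' Scans the total-length time series for alternations of growth and
#' abrupt contraction: a cycle is a local maximum of \code{L} followed by a
#' trough at least \code{drop_frac} below it.  An episode is an interval
#' containing at least \code{n_cycles} consecutive such cycles; the
#' max/min length ratio within each episode is reported.
#'
#' @param traj a \code{cell_trajectory} (only \code{samples$L} is used).
#' @param drop_frac minimal fractional drop from peak to trough (0-1).
#' @param n_cycles minimal number of growth/contraction alternations.
#' @param smooth_window width (in samples) of the running-median smoothing
#'   applied to L before extremum detection.
#' @param gap_max maximal quiescent time between consecutive cycles grouped
#'   into one episode (covers the regrowth phase between slips).
#' @return data frame of episodes: \code{t_start}, \code{t_end},
#'   \code{n_cycles}, \code{L_max}, \code{L_min}, \code{ratio}.
#' @export
detect_stick_slip <- function(traj, drop_frac = 0.2, n_cycles = 2,
                              smooth_window = 21, gap_max = 6) {
  if (drop_frac <= 0 || drop_frac >= 1) stop("drop_frac must be in (0, 1)")
  s <- traj$samples
  L <- s$L
  tt <- s$time
  if (length(L) > smooth_window)
    L <- stats::runmed(L, k = smooth_window %/% 2 * 2 + 1)
  # alternating extrema by monotone run compression
  dL <- diff(L)
  sgn <- sign(dL)
  sgn[sgn == 0] <- NA
  sgn <- zoo_fill(sgn)
  if (all(is.na(sgn))) return(.empty_ss())
  turns <- which(diff(sgn) != 0) + 1L
  ext_idx <- c(1L, turns, length(L))
  # peak/trough alternation with the drop criterion
  cycles <- data.frame(peak_i = integer(0), trough_i = integer(0))
  i <- 1
  while (i < length(ext_idx)) {
    pk <- ext_idx[i]; tr <- ext_idx[i + 1]
    if (L[pk] > L[tr] && (L[pk] - L[tr]) >= drop_frac * L[pk])
      cycles <- rbind(cycles, data.frame(peak_i = pk, trough_i = tr))
    i <- i + 1
  }
  if (nrow(cycles) < n_cycles) return(.empty_ss())
  # group consecutive cycles into episodes (gap <= one cycle span)
  eps <- list(); cur <- cycles[1, , drop = FALSE]
  if (nrow(cycles) > 1) for (r in 2:nrow(cycles)) {
    gap <- tt[cycles$peak_i[r]] - tt[cur$trough_i[nrow(cur)]]
    if (gap <= gap_max) cur <- rbind(cur, cycles[r, ])
    else { eps <- c(eps, list(cur)); cur <- cycles[r, , drop = FALSE] }
  }
  eps <- c(eps, list(cur))
  out <- do.call(rbind, lapply(eps, function(e) {
    if (nrow(e) < n_cycles) return(NULL)
    i0 <- e$peak_i[1]; i1 <- e$trough_i[nrow(e)]
    seg <- s$L[i0:i1]
    data.frame(t_start = tt[i0], t_end = tt[i1], n_cycles = nrow(e),
               L_max = max(seg), L_min = min(seg),
               ratio = max(seg) / max(min(seg), 1e-12))
  }))
  if (is.null(out)) .empty_ss() else out
}

.empty_ss <- function() {
  data.frame(t_start = numeric(0), t_end = numeric(0), n_cycles = integer(0),
             L_max = numeric(0), L_min = numeric(0), ratio = numeric(0))
}

# last-observation-carried-forward for a sign vector
zoo_fill <- function(x) {
  ok <- !is.na(x)
  if (!any(ok)) return(x)
  idx <- cumsum(ok)
  filled <- c(NA, x[ok])[idx + 1]
  filled
}

#' Arrival and path metrics of a network chemotaxis run
#'
#' \code{T_arr}: first time any arm tip reaches the arrival line
#' \code{y_arr} (\code{t_max} if never, flagged); \code{L_path}: cumulative
#' arc length of the sampled centre-of-mass trajectory; \code{v_y_mean}:
#' mean y-displacement per sampling interval; \code{FMI}: net displacement
#' toward the source divided by \code{L_path}.  By the default convention
#' the net displacement is the y-projection (the gradient points along +y);
#' \code{fmi_axis = "magnitude"} uses the Euclidean displacement instead.
#'
#' @param traj a \code{cell_trajectory}.
#' @param y_arr arrival coordinate (already applied as \code{stop_y} in the
#'   protocol runs; used here for the flag).
#' @param t_max protocol time limit.
#' @param fmi_axis \code{"y"} (default) or \code{"magnitude"}.
#' @return one-row data frame (\code{ChemotaxisRecord}).
#' @export
arrival_metrics <- function(traj, y_arr = Inf, t_max = 1000,
                            fmi_axis = c("y", "magnitude")) {
  fmi_axis <- match.arg(fmi_axis)
  s <- traj$samples
  if (is.null(s) || nrow(s) < 2) stop("trajectory has too few samples")
  arrived <- !is.na(traj$arrival_time)
  T_arr <- if (arrived) traj$arrival_time else t_max
  dx <- diff(s$com_x); dy <- diff(s$com_y)
  L_path <- sum(sqrt(dx^2 + dy^2))
  net <- if (fmi_axis == "y") s$com_y[nrow(s)] - s$com_y[1]
         else sqrt((s$com_x[nrow(s)] - s$com_x[1])^2 +
                   (s$com_y[nrow(s)] - s$com_y[1])^2)
  data.frame(T_arr = T_arr, arrived = arrived,
             L_path = L_path,
             v_y_mean = mean(dy) / mean(diff(s$time)),
             FMI = if (L_path > 0) net / L_path else 0)
}

#' Beginning-of-movement time
#'
#' The earliest time \code{t >= 0} at which the trailing-window mean of the
#' centre-of-mass y-velocity stays above \code{v_thresh}, i.e. the moment
#' the cell first moves toward the source in a sustained way after the
#' gradient onset at \code{t = 0}.  Returns \code{NA} (sentinel) if the
#' cell never does.
#'
#' @param traj a \code{cell_trajectory} covering the gradient onset.
#' @param v_thresh velocity threshold.
#' @param window averaging window (time units).
#' @return the BM time or \code{NA}.
#' @export
bm_time <- function(traj, v_thresh = 0.2, window = 0.5) {
  s <- traj$samples
  dt <- stats::median(diff(s$time))
  vy <- c(NA, diff(s$com_y) / diff(s$time))
  k <- max(1L, round(window / dt))
  cs <- cumsum(ifelse(is.na(vy), 0, vy))
  nvy <- length(vy)
  if (nvy <= k) return(NA_real_)
  wmean <- (cs[(k + 1):nvy] - cs[1:(nvy - k)]) / k
  wt <- s$time[(k + 1):nvy]
  ok <- wt >= 0 & wmean > v_thresh
  if (!any(ok)) return(NA_real_)
  wt[which(ok)[1]] - window  # onset of the qualifying window
}

#' Event-aligned ensemble speed curves
#'
#' Aligns the centre-of-mass speed of each trajectory on a per-trajectory
#' event time, bins the aligned time axis, and returns the per-bin ensemble
#' mean and standard error.  Bins covered by fewer than two trajectories
#' are masked (\code{NA}).
#'
#' @param trajs list of \code{cell_trajectory} objects.
#' @param align_times numeric vector of alignment times (one per
#'   trajectory); trajectories with \code{NA} are dropped.
#' @param window half-width of the aligned window.
#' @param bin bin width.
#' @param speed_dt displacement interval over which speeds are measured
#'   (coarser than the sampling interval to suppress sampling jitter).
#' @return data frame: \code{t} (bin centre), \code{mean}, \code{sem},
#'   \code{n}.
#' @export
event_aligned_average <- function(trajs, align_times, window = 10, bin = 0.5,
                                  speed_dt = 2.5) {
  keep <- !is.na(align_times)
  trajs <- trajs[keep]; align_times <- align_times[keep]
  if (!length(trajs)) stop("no trajectories with valid alignment times")
  breaks <- seq(-window, window, by = bin)
  centres <- breaks[-1] - bin / 2
  acc <- matrix(NA_real_, length(trajs), length(centres))
  for (i in seq_along(trajs)) {
    s <- trajs[[i]]$samples
    sp <- com_speed(trajs[[i]], speed_dt = speed_dt)
    rel <- sp$time - align_times[i]
    bi <- findInterval(rel, breaks, rightmost.closed = TRUE)
    ok <- bi >= 1 & bi <= length(centres)
    if (any(ok))
      acc[i, ] <- vapply(seq_along(centres), function(b) {
        v <- sp$speed[ok & bi == b]
        if (length(v)) mean(v) else NA_real_
      }, 0)
  }
  n <- colSums(!is.na(acc))
  m <- ifelse(n >= 2, colMeans(acc, na.rm = TRUE), NA_real_)
  sem <- ifelse(n >= 2, apply(acc, 2, stats::sd, na.rm = TRUE) / sqrt(n), NA_real_)
  data.frame(t = centres, mean = m, sem = sem, n = n)
}

#' Centre-of-mass speed over a coarse interval
#'
#' Speed computed from displacements over \code{speed_dt} rather than the
#' raw sampling interval, matching how migration speeds are measured from
#' tracked positions at coarse frame intervals.
#'
#' @param traj a \code{cell_trajectory}.
#' @param speed_dt displacement interval.
#' @return data frame with \code{time} (interval midpoints) and
#'   \code{speed}.
#' @export
com_speed <- function(traj, speed_dt = 2.5) {
  s <- traj$samples
  dt <- stats::median(diff(s$time))
  k <- max(1L, round(speed_dt / dt))
  n <- nrow(s)
  if (n <= k) return(data.frame(time = numeric(0), speed = numeric(0)))
  i0 <- 1:(n - k); i1 <- (k + 1):n
  data.frame(time = (s$time[i0] + s$time[i1]) / 2,
             speed = sqrt((s$com_x[i1] - s$com_x[i0])^2 +
                          (s$com_y[i1] - s$com_y[i0])^2) /
                     (s$time[i1] - s$time[i0]))
}
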