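#' Hand-constructed synthetic trajectories for the metrics layer
#'
#' Generates piecewise-defined centre-of-mass / arm-length time series with
#' known properties, independent of the simulator, so the trajectory
#' metrics can be tested against values computable by hand.  Kinds:
#' \describe{
#'   \item{\code{"straight"}}{constant-velocity motion along +y: FMI = 1.}
#'   \item{\code{"loop"}}{a closed circle returning to the start: FMI = 0.}
#'   \item{\code{"zigzag"}}{ideal hexagonal zig-zag toward +y (segments at
#'     30 degrees off axis): FMI = sqrt(3)/2.}
#'   \item{\code{"sawtooth"}}{total length alternating between \code{L_hi}
#'     and \code{L_lo} (stick-slip-like cycles).}
#'   \item{\code{"monotone_L"}}{monotonically growing length (no
#'     stick-slip).}
#'   \item{\code{"slow_mode"}}{three-arm length table with two long leaders
#'     and a rear pinned below threshold during [t_on, t_off].}
#'   \item{\code{"single_leader"}}{three-arm table with one dominant arm
#'     (no slow-mode episode).}
#'   \item{\code{"constant_speed"}}{straight motion at a given speed.}
#'   \item{\code{"switch_vy"}}{y-velocity -1 before \code{t_switch}, +1
#'     after (beginning-of-movement fixture).}
#' }
#'
#' @param kind fixture kind.
#' @param t_max duration.
#' @param dt sampling interval.
#' @param speed,L_hi,L_lo,t_on,t_off,t_switch,period shape parameters.
#' @return a list shaped like a \code{cell_trajectory} (\code{samples} and,
#'   for the arm fixtures, \code{arms}).
#' @examples
#' fx <- fixture_trajectory("zigzag")
#' arrival_metrics(fx, t_max = 10)$FMI  # ~ sqrt(3)/2
#' @export
fixture_trajectory <- function(kind = c("straight", "loop", "zigzag",
                                        "sawtooth", "monotone_L",
                                        "slow_mode", "single_leader",
                                        "constant_speed", "switch_vy"),
                               t_max = 10, dt = 0.01, speed = 1,
                               L_hi = 8, L_lo = 4, t_on = 2, t_off = 5,
                               t_switch = 3, period = 2) {
  kind <- match.arg(kind)
  tt <- seq(0, t_max, by = dt)
  n <- length(tt)
  samples <- data.frame(time = tt, com_x = 0, com_y = 0, L = 5, N = 2,
                        event = 0L)
  arms <- NULL
  if (kind == "straight" || kind == "constant_speed") {
    samples$com_y <- speed * tt
  } else if (kind == "loop") {
    th <- 2 * pi * tt / t_max
    samples$com_x <- cos(th) - 1
    samples$com_y <- sin(th)
  } else if (kind == "zigzag") {
    # unit steps alternating +/- 30 degrees from +y
    seg <- floor(tt / period)
    phase <- (tt %% period) / period
    # arc length advances at unit speed; y gains cos(30deg) per unit arc,
    # x oscillates between 0 and period*sin(30deg)
    samples$com_y <- (seg + phase) * cos(pi / 6) * period
    sx <- sin(pi / 6) * period
    samples$com_x <- ifelse(seg %% 2 == 0, phase * sx, sx - phase * sx)
  } else if (kind == "sawtooth") {
    phase <- (tt %% period) / period
    samples$L <- ifelse(phase < 0.5, L_lo + 2 * phase * (L_hi - L_lo),
                        L_hi - 2 * (phase - 0.5) * (L_hi - L_lo))
  } else if (kind == "monotone_L") {
    samples$L <- L_lo + (L_hi - L_lo) * tt / t_max
  } else if (kind %in% c("slow_mode", "single_leader")) {
    samples$N <- 3
    lead2 <- if (kind == "slow_mode")
      ifelse(tt >= t_on & tt <= t_off, 6.5, 0.5) else 0.5
    rear <- if (kind == "slow_mode")
      ifelse(tt >= t_on & tt <= t_off, 0.05, 2) else 2
    arms <- rbind(
      data.frame(time = tt, arm_id = 0L, x = rear, n = 0.8, v = 1,
                 beta_tip = 8, tip_x = 0, tip_y = -rear, base = 1L),
      data.frame(time = tt, arm_id = 1L, x = 7, n = 0.8, v = 6,
                 beta_tip = 8, tip_x = -1, tip_y = 4, base = 1L),
      data.frame(time = tt, arm_id = 2L, x = lead2, n = 0.8, v = 6,
                 beta_tip = 8, tip_x = 1, tip_y = 4, base = 1L))
    arms <- arms[order(arms$time, arms$arm_id), ]
    samples$L <- rear + 7 + lead2
  } else if (kind == "switch_vy") {
    samples$com_y <- ifelse(tt < t_switch, -tt, tt - 2 * t_switch)
  }
  out <- list(samples = samples, arms = arms,
              arrival_time = NA_real_, escape_branch = NA_integer_,
              escape_time = NA_real_, finite_ok = TRUE, boundary_hit = FALSE,
              config = list(fixture = kind))
  class(out) <- "cell_trajectory"
  out
}

#' Write the metric-test fixture set as CSV
#'
#' Emits every fixture kind as a pair of CSV files (samples and, where
#' defined, per-arm tables) under \code{dir}.
#'
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_fixtures <- function(dir = "fixtures") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  kinds <- c("straight", "loop", "zigzag", "sawtooth", "monotone_L",
             "slow_mode", "single_leader", "constant_speed", "switch_vy")
  paths <- character(0)
  for (k in kinds) {
    fx <- fixture_trajectory(k)
    fp <- file.path(dir, paste0(k, "_samples.csv"))
    utils::write.csv(fx$samples, fp, row.names = FALSE)
    paths <- c(paths, fp)
    if (!is.null(fx$arms)) {
      fa <- file.path(dir, paste0(k, "_arms.csv"))
      utils::write.csv(fx$arms, fa, row.names = FALSE)
      paths <- c(paths, fa)
    }
  }
  invisible(paths)
}
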