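#' Model parameters for the branched-cell simulator
#'
#' Constructs the full dimensionless parameter set of the coarse-grained
#' branched-cell model.  All rates are normalized by the inverse
#' focal-adhesion disassembly timescale and all lengths by the cell rest
#' length, so every entry is dimensionless.
#'
#' The default values are the package calibration: they place the critical
#' actin activity for polarization on a single junction at
#' \code{critical_beta_single()} = 5.9 (inside the 5--6 operating window) and
#' the onset of stick-slip migration on an infinite line near beta0 = 10,
#' above the junction-triggered stick-slip band.  See the methods vignette
#' for the calibration rationale.
#'
#' @param beta0 baseline actin activity (maximal tip polymerization speed).
#' @param k effective cell elasticity (restoring force is \code{k*(L-1)}).
#' @param kappa effective elasticity of the adhesion bonds; scales the
#'   retraction friction \code{Gamma = n*kappa}.
#' @param r effective cell-substrate adhesiveness (bond attachment rate).
#' @param f_s slip-bond force susceptibility: detachment accelerates as
#'   \code{exp((k(L-1)-v)/(f_s n))}.
#' @param delta relaxation rate of the local actin flow toward its
#'   steady-state target.
#' @param sigma amplitude of the Gaussian noise on the actin flows.
#' @param D diffusion constant of the inhibitory polarity cue.
#' @param c_amount total (conserved) amount of polarity cue in the cell.
#' @param dt Euler--Maruyama integration step.
#' @param n_floor lower clamp for the adhesion concentration.
#' @param omega_max cap on the slip-bond detachment rate (one adhesion
#'   turnover per \code{1/omega_max} time units); keeps the fully detached
#'   state dynamically recoverable.
#' @param gamma_min lower bound on the retraction friction (bare drag of a
#'   detached edge); bounds the slip speed.
#' @param eps_split half of the tip overshoot required past a junction before
#'   the arm splits; daughter arms are seeded with half the overshoot each so
#'   the total length is exactly continuous across the event.
#'
#' @return an object of class \code{"model_params"} (a named list).
#' @examples
#' p <- model_params(beta0 = 8)
#' p$beta0
#' @export
model_params <- function(beta0 = 8,
                         k = 0.8,
                         kappa = 10,
                         r = 1,
                         f_s = 18,
                         delta = 2,
                         sigma = 0.1,
                         D = 2.6,
                         c_amount = 1.2,
                         dt = 1e-3,
                         n_floor = 1e-4,
                         omega_max = 100,
                         gamma_min = 0.1,
                         eps_split = 1e-3) {
  p <- list(beta0 = beta0, k = k, kappa = kappa, r = r, f_s = f_s,
            delta = delta, sigma = sigma, D = D, c_amount = c_amount,
            dt = dt, n_floor = n_floor, omega_max = omega_max,
            gamma_min = gamma_min, eps_split = eps_split)
  validate_model_params(p)
  class(p) <- "model_params"
  p
}

validate_model_params <- function(p) {
  pos <- c("beta0", "k", "kappa", "r", "f_s", "delta", "D", "c_amount",
           "dt", "n_floor", "omega_max", "gamma_min", "eps_split")
  for (nm in pos) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("parameter '%s' must be a single positive number", nm))
  }
  if (!is.numeric(p$sigma) || length(p$sigma) != 1L || p$sigma < 0)
    stop("parameter 'sigma' must be a single non-negative number")
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Branched-cell model parameters (dimensionless):\n")
  nm <- names(x)
  for (i in seq_along(x))
    cat(sprintf("  %-10s %g\n", nm[i], x[[i]]))
  invisible(x)
}

#' Modify a parameter set
#'
#' @param p a \code{model_params} object.
#' @param ... named parameters to replace.
#' @return a new \code{model_params} object.
#' @examples
#' p <- update_params(model_params(), beta0 = 12, sigma = 0.5)
#' @export
update_params <- function(p, ...) {
  stopifnot(inherits(p, "model_params"))
  mods <- list(...)
  bad <- setdiff(names(mods), names(unclass(p)))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  out <- unclass(p)
  out[names(mods)] <- mods
  validate_model_params(out)
  class(out) <- "model_params"
  out
}
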