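#' Chemokine concentration fields
#'
#' Describes the external chemokine landscape and how it enhances the actin
#' activity at arm tips.  Available kinds:
#' \describe{
#'   \item{\code{"none"}}{no field; all tips keep \code{beta0}.}
#'   \item{\code{"junction_bias"}}{no spatial profile; the arm growing into
#'     the branch facing the source gets \code{beta0 (1 + eps)}, all others
#'     \code{beta0} (single-junction protocol).}
#'   \item{\code{"point_exp"}}{exponential decay with distance from a point
#'     source, \code{c(r) = c0 exp(-r / decay)}.}
#'   \item{\code{"line_exp"}}{exponential decay with distance from a
#'     horizontal line source, \code{c(y) = c0 exp(-|y - source_y| / decay)}.}
#'   \item{\code{"linear"}}{spatially linear profile along y, saturating at
#'     \code{c0} on the source line: \code{c(y) = c0 max(0, 1 - (source_y -
#'     y)/slope_len)}; the tip activity is \code{beta0 (1 + eps c/c0)}
#'     without further saturation (gradient-onset protocol).}
#' }
#' For the spatial exponential kinds the activity follows the saturating
#' response \code{beta = beta0 [1 + eps (1 + C/c0) c / (c + C)]}: the
#' prefactor normalizes the enhancement to be maximal (\code{beta0(1+eps)})
#' at the source, and the saturation concentration \code{C_sat} sets the
#' range over which guidance is effective (\code{C/c0} small: strong signal
#' far from the source; \code{C/c0 ~ 1}: weak signal, effective only close
#' to it).  Distances are always measured from the arm tips, never from the
#' cell centre.
#'
#' @param kind field kind (see above).
#' @param eps maximal relative enhancement of the actin activity.
#' @param c0 source concentration.
#' @param C_sat saturation concentration of the response.
#' @param decay decay length of the exponential kinds.
#' @param source_x,source_y source position (point) or source line height.
#' @param slope_len length scale of the linear profile.
#' @param onset time at which the field switches on (identically absent for
#'   \code{t < onset}); default: always on.
#' @param biased_node for \code{"junction_bias"}: far node of the favoured
#'   branch.
#' @return an object of class \code{"chemokine_field"}.
#' @examples
#' f <- chemokine_field("line_exp", eps = 0.2, decay = 4.5, source_y = 24,
#'                      C_sat = 1)
#' beta_at_tip(f, tip = c(0, 24), beta0 = 8)  # beta0 * 1.2 at the source
#' @export
chemokine_field <- function(kind = c("none", "junction_bias", "point_exp",
                                     "line_exp", "linear"),
                            eps = 0, c0 = 1, C_sat = 1, decay = 1,
                            source_x = 0, source_y = 0, slope_len = 1,
                            onset = -Inf, biased_node = NA_integer_) {
  kind <- match.arg(kind)
  if (c0 <= 0 || C_sat <= 0 || decay <= 0 || slope_len <= 0)
    stop("c0, C_sat, decay and slope_len must be positive")
  if (eps < 0) stop("eps must be non-negative")
  if (kind == "junction_bias" && is.na(biased_node))
    stop("junction_bias requires `biased_node`")
  structure(list(kind = kind, eps = eps, c0 = c0, C_sat = C_sat,
                 decay = decay, source_x = source_x, source_y = source_y,
                 slope_len = slope_len, onset = onset,
                 biased_node = as.integer(biased_node)),
            class = "chemokine_field")
}

#' @export
print.chemokine_field <- function(x, ...) {
  cat(sprintf("chemokine_field: kind = %s, eps = %g\n", x$kind, x$eps))
  invisible(x)
}

#' Chemokine concentration at a point
#'
#' @param field a \code{\link{chemokine_field}} with a spatial profile.
#' @param point numeric length-2 position (or 2-column matrix).
#' @return concentration value(s).
#' @examples
#' f <- chemokine_field("point_exp", c0 = 2, decay = 1.5)
#' concentration(f, c(0, 0))    # c0 at the source
#' concentration(f, c(1.5, 0))  # c0 / e
#' @export
concentration <- function(field, point) {
  stopifnot(inherits(field, "chemokine_field"))
  if (field$kind %in% c("none", "junction_bias"))
    stop("field kind '", field$kind, "' has no spatial concentration profile")
  pt <- matrix(point, ncol = 2)
  if (field$kind == "point_exp") {
    r <- sqrt((pt[, 1] - field$source_x)^2 + (pt[, 2] - field$source_y)^2)
    field$c0 * exp(-r / field$decay)
  } else if (field$kind == "line_exp") {
    field$c0 * exp(-abs(pt[, 2] - field$source_y) / field$decay)
  } else {
    field$c0 * pmin(1, pmax(0, 1 - (field$source_y - pt[, 2]) / field$slope_len))
  }
}

#' Actin activity at a tip position
#'
#' Applies the saturating chemotactic response to the local concentration;
#' bounded in \code{[beta0, beta0 (1 + eps)]} everywhere and monotone
#' non-increasing with distance from the source.
#'
#' @param field a \code{\link{chemokine_field}}.
#' @param tip numeric length-2 tip position (or 2-column matrix).
#' @param beta0 baseline actin activity.
#' @param t evaluation time (relative to the field onset).
#' @return activity value(s).
#' @export
beta_at_tip <- function(field, tip, beta0, t = 0) {
  stopifnot(inherits(field, "chemokine_field"))
  if (field$kind %in% c("none", "junction_bias") || t < field$onset)
    return(rep_len(beta0, nrow(matrix(tip, ncol = 2))))
  cc <- concentration(field, tip)
  if (field$kind == "linear")
    beta0 * (1 + field$eps * cc / field$c0)
  else
    beta0 * (1 + field$eps * (1 + field$C_sat / field$c0) * cc / (cc + field$C_sat))
}

#' Actin activity under the single-junction bias
#'
#' @param field a \code{"junction_bias"} field.
#' @param arm_branch far node of the branch the arm grows into.
#' @param beta0 baseline activity.
#' @return \code{beta0 (1 + eps)} for the biased branch, \code{beta0}
#'   otherwise.
#' @examples
#' f <- chemokine_field("junction_bias", eps = 0.001, biased_node = 4)
#' junction_bias_beta(f, 4, beta0 = 8)  # 8.008
#' @export
junction_bias_beta <- function(field, arm_branch, beta0) {
  stopifnot(inherits(field, "chemokine_field"))
  if (field$kind != "junction_bias") stop("field kind must be 'junction_bias'")
  if (any(!is.finite(arm_branch)) || any(arm_branch < 1))
    stop("unknown branch id: ", paste(arm_branch, collapse = ", "))
  ifelse(arm_branch == field$biased_node, beta0 * (1 + field$eps), beta0)
}
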