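#' Carreau shear-thinning viscosity parameters
#'
#' Container for the four constants of the Carreau law
#' \deqn{\mu(\dot\gamma) = \mu_\infty + (\mu_0 - \mu_\infty)
#'       \left[1 + (\lambda\dot\gamma)^2\right]^{(n-1)/2}}
#' which interpolates blood viscosity between its zero-shear plateau
#' \eqn{\mu_0} and its infinite-shear plateau \eqn{\mu_\infty}. Defaults are
#' the values commonly fitted to whole blood
#' (\eqn{\lambda} = 3.313 s, \eqn{n} = 0.3568, \eqn{\mu_0} = 0.056 Pa s,
#' \eqn{\mu_\infty} = 0.00345 Pa s).
#'
#' @param relaxation_time Relaxation time \eqn{\lambda} in seconds; > 0.
#' @param power_index Power-law index \eqn{n}, dimensionless, in (0, 1).
#' @param mu_zero Zero-shear viscosity \eqn{\mu_0} in Pa s.
#' @param mu_inf Infinite-shear viscosity \eqn{\mu_\infty} in Pa s;
#'   must satisfy \code{0 < mu_inf <= mu_zero}.
#'
#' @return An object of class \code{carreau_parameters} (a named list).
#' @export
#'
#' @examples
#' p <- carreau_parameters()
#' carreau_viscosity(c(0, 1, 100, 1e6), p)
carreau_parameters <- function(relaxation_time = 3.313,
                               power_index = 0.3568,
                               mu_zero = 0.056,
                               mu_inf = 0.00345) {
  if (!is.numeric(relaxation_time) || relaxation_time <= 0) {
    abort("`relaxation_time` must be a positive number of seconds.")
  }
  if (!is.numeric(power_index) || power_index <= 0 || power_index >= 1) {
    abort("`power_index` must lie strictly between 0 and 1.")
  }
  if (!is.numeric(mu_inf) || mu_inf <= 0) {
    abort("`mu_inf` must be a positive viscosity in Pa s.")
  }
  if (!is.numeric(mu_zero) || mu_zero < mu_inf) {
    abort("`mu_zero` must be at least `mu_inf` (shear-thinning or Newtonian).")
  }
  structure(
    list(
      relaxation_time = as.numeric(relaxation_time),
      power_index = as.numeric(power_index),
      mu_zero = as.numeric(mu_zero),
      mu_inf = as.numeric(mu_inf)
    ),
    class = "carreau_parameters"
  )
}

#' @export
print.carreau_parameters <- function(x, ...) {
  cat("Carreau viscosity parameters\n")
  cat(sprintf("  relaxation time lambda: %g s\n", x$relaxation_time))
  cat(sprintf("  power index n:          %g\n", x$power_index))
  cat(sprintf("  mu_0  (zero shear):     %g Pa s\n", x$mu_zero))
  cat(sprintf("  mu_inf (infinite shear): %g Pa s\n", x$mu_inf))
  invisible(x)
}

#' Carreau viscosity at a given shear rate
#'
#' Evaluates the Carreau law. Vectorised over \code{shear_rate}.
#'
#' @param shear_rate Shear rate \eqn{\dot\gamma} in 1/s; non-negative.
#' @param params A [carreau_parameters()] object.
#'
#' @return Viscosity in Pa s, bounded by \code{[mu_inf, mu_zero]}.
#' @export
carreau_viscosity <- function(shear_rate, params = carreau_parameters()) {
  stopifnot(inherits(params, "carreau_parameters"))
  if (!is.numeric(shear_rate) || any(is.na(shear_rate)) || any(shear_rate < 0)) {
    abort("`shear_rate` must be non-negative and finite (units: 1/s).")
  }
  params$mu_inf + (params$mu_zero - params$mu_inf) *
    (1 + (params$relaxation_time * shear_rate)^2)^((params$power_index - 1) / 2)
}

#' Poiseuille wall shear rate of a tube segment
#'
#' The representative shear rate used to couple the Carreau law to a lumped
#' segment is the fully developed Poiseuille wall shear rate
#' \eqn{\dot\gamma_w = 32 |Q| / (\pi d^3)}.
#'
#' @param flow Volumetric flow in ml/s (sign ignored).
#' @param diameter Lumen diameter in mm; > 0.
#'
#' @return Wall shear rate in 1/s. Vectorised.
#' @export
wall_shear_rate <- function(flow, diameter) {
  if (!is.numeric(diameter) || any(diameter <= 0)) {
    abort("`diameter` must be positive (units: mm).")
  }
  # 32 Q / (pi d^3) with Q in m^3/s, d in m; collapsing the unit factors
  # for ml/s and mm leaves a net 1e3.
  32 * abs(flow) / (pi * diameter^3) * 1e3
}

#' Effective viscosity of a segment at a given flow
#'
#' Couples the Carreau law to a segment's flow through the Poiseuille wall
#' shear rate: \code{carreau_viscosity(wall_shear_rate(flow, diameter))}.
#' At zero flow this is exactly \code{mu_zero}.
#'
#' @inheritParams wall_shear_rate
#' @inheritParams carreau_viscosity
#'
#' @return Viscosity in Pa s. Vectorised.
#' @export
effective_viscosity <- function(flow, diameter, params = carreau_parameters()) {
  carreau_viscosity(wall_shear_rate(flow, diameter), params)
}
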