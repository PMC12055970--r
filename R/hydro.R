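#' Fluid and obstacle parameters for hydrodynamic characterization
#'
#' Bundles the quantities entering the cavitation number
#' \eqn{Ca = (p - p_v) / (\tfrac12 \rho u^2)} and the Reynolds number
#' \eqn{Re = u L \rho / \mu}. Defaults describe water at 20 degrees C
#' (density 998 kg/m3, dynamic viscosity 1 mPa s, vapor pressure 2339 Pa)
#' at atmospheric pressure.
#'
#' @param u flow speed in m/s (needle tip speed relative to the fluid).
#' @param L characteristic obstacle dimension in m; the 14 G needle shaft
#'   outer diameter is 2.109 mm.
#' @param p local static pressure in Pa.
#' @param p_v vapor pressure of the liquid in Pa.
#' @param rho liquid density in kg/m3.
#' @param mu dynamic viscosity in Pa s.
#' @param nu kinematic viscosity in m2/s; defaults to `mu / rho` and must be
#'   consistent with it when supplied (used e.g. for agarose gel, where the
#'   literature quotes nu = 5e-6 m2/s for a 0.9 % w/v gel).
#' @return An object of class `flow_parameters`.
#' @examples
#' fp <- flow_parameters(u = 7, L = 2.109e-3)
#' reynolds_number(fp)
#' cavitation_number(fp)
#' @export
flow_parameters <- function(u, L = 2.109e-3, p = 101325, p_v = 2339,
                            rho = 998, mu = 1e-3, nu = mu / rho) {
  stopifnot(is.numeric(u), length(u) == 1L, u >= 0,
            is.numeric(L), L > 0, rho > 0, mu > 0)
  if (abs(nu - mu / rho) > 1e-9 * max(nu, mu / rho)) {
    stop("inconsistent viscosities: nu must equal mu / rho")
  }
  structure(list(u = u, L = L, p = p, p_v = p_v, rho = rho, mu = mu, nu = nu),
            class = "flow_parameters")
}

#' Cavitation number
#'
#' \eqn{Ca = (p - p_v) / (\tfrac12 \rho u^2)}. Low values indicate a greater
#' probability of cavitation inception; negative values occur when the local
#' pressure is below the vapor pressure. For orientation, cavitation inception
#' in the wake of a wedge-shaped bluff body has been reported at Ca = 4.8
#' (available as `ca_inception_wedge`).
#'
#' @param fp a [flow_parameters()] object.
#' @return Dimensionless cavitation number.
#' @export
cavitation_number <- function(fp) {
  stopifnot(inherits(fp, "flow_parameters"))
  if (fp$u <= 0) stop("cavitation number undefined for u = 0")
  (fp$p - fp$p_v) / (0.5 * fp$rho * fp$u^2)
}

#' Reference cavitation inception number for a wedge bluff body
#'
#' Documented literature comparison constant, not computed by this package.
#' @export
ca_inception_wedge <- 4.8

#' Reynolds number
#'
#' \eqn{Re = u L \rho / \mu}, characterizing the flow regime around an
#' obstacle of dimension L.
#'
#' @inheritParams cavitation_number
#' @return Dimensionless Reynolds number.
#' @export
reynolds_number <- function(fp) {
  stopifnot(inherits(fp, "flow_parameters"))
  if (fp$mu <= 0) stop("Reynolds number undefined for mu = 0")
  fp$u * fp$L * fp$rho / fp$mu
}

#' Classify the wake flow regime from the Reynolds number
#'
#' Below Re = 49 the wake is laminar; between 49 and 190 a transition with
#' Karman vortex shedding develops; above 190 the wake is fully turbulent.
#' Both boundaries are implemented as closed on the transition side.
#'
#' @param Re non-negative Reynolds number (vectorized).
#' @return factor with levels `laminar`, `vortex_transition`, `turbulent`.
#' @export
flow_regime <- function(Re) {
  stopifnot(is.numeric(Re))
  if (any(Re < 0)) stop("negative Reynolds number")
  out <- ifelse(Re < 49, "laminar",
                ifelse(Re <= 190, "vortex_transition", "turbulent"))
  factor(out, levels = c("laminar", "vortex_transition", "turbulent"))
}

#' @export
print.flow_parameters <- function(x, ...) {
  cat("Flow parameters\n")
  cat(sprintf("  u  = %g m/s   L  = %g m\n", x$u, x$L))
  cat(sprintf("  p  = %g Pa    p_v = %g Pa\n", x$p, x$p_v))
  cat(sprintf("  rho = %g kg/m3  mu = %g Pa s  (nu = %g m2/s)\n",
              x$rho, x$mu, x$nu))
  if (x$u > 0) {
    Re <- reynolds_number(x)
    cat(sprintf("  Ca = %.4g   Re = %.5g (%s)\n",
                cavitation_number(x), Re, as.character(flow_regime(Re))))
  }
  invisible(x)
}
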