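#' Reynolds number of a pipe flow
#'
#' \eqn{Re = \rho V D / \mu}. For the aortic reference conditions used
#' throughout this package (density 1060 kg/m3, mean velocity 0.14 m/s,
#' equivalent diameter 35.88 mm, viscosity 0.004 Pa s) this evaluates to
#' about 1331, well inside the laminar regime.
#'
#' @param rho Fluid density, kg/m3.
#' @param V Characteristic (mean) velocity, m/s (`>= 0`).
#' @param D Tube diameter, m (> 0).
#' @param mu Dynamic viscosity, Pa s (> 0).
#' @return Dimensionless Reynolds number.
#' @seealso [is_laminar()], [womersley_number()]
#' @export
#' @examples
#' reynolds_number(1060, 0.14, 0.03588, 0.004)  # ~1331
reynolds_number <- function(rho, V, D, mu) {
  if (mu <= 0 || D <= 0 || rho <= 0)
    stop("'rho', 'D' and 'mu' must be > 0", call. = FALSE)
  if (V < 0) stop("'V' must be >= 0", call. = FALSE)
  rho * V * D / mu
}

#' Laminar-regime check
#'
#' @param re Reynolds number.
#' @param threshold Transition threshold; 2300 is the classical pipe-flow
#'   value.
#' @return Logical.
#' @export
is_laminar <- function(re, threshold = 2300) {
  stopifnot(is.numeric(re), is.numeric(threshold))
  re < threshold
}

#' Womersley number
#'
#' \eqn{\alpha = R\sqrt{\omega\rho/\mu}}, the ratio of transient inertial to
#' viscous effects in oscillatory tube flow. Aortic flow at 1 Hz has
#' \eqn{\alpha \approx 23} at the reference conditions.
#'
#' @param R Tube radius, m (> 0).
#' @param omega Angular frequency, rad/s (`>= 0`).
#' @param rho Density, kg/m3 (> 0).
#' @param mu Dynamic viscosity, Pa s (> 0).
#' @return Dimensionless Womersley number.
#' @export
#' @examples
#' womersley_number(0.01794, 2 * pi, 1060, 0.004)  # ~23.15
womersley_number <- function(R, omega, rho, mu) {
  if (R <= 0 || rho <= 0 || mu <= 0)
    stop("'R', 'rho' and 'mu' must be > 0", call. = FALSE)
  if (omega < 0) stop("'omega' must be >= 0", call. = FALSE)
  R * sqrt(omega * rho / mu)
}
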