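# Complex Bessel J0/J1 by power series. Arguments here stay below |z| ~ 35
# (Womersley number up to ~25 in large arteries), where the series converges
# in < 60 terms and intermediate terms stay ~1e7, so double precision keeps
# ample headroom against the cancellation inherent in the alternating sum.
bessel_j0_complex <- function(z) {
  z <- as.complex(z)
  s <- rep(1 + 0i, length(z))
  term <- rep(1 + 0i, length(z))
  m <- -z^2 / 4
  for (k in 1:200) {
    term <- term * m / k^2
    s <- s + term
    if (max(Mod(term)) < 1e-18 * max(Mod(s), 1)) break
  }
  s
}

bessel_j1_complex <- function(z) {
  z <- as.complex(z)
  term <- z / 2
  s <- term
  m <- -z^2 / 4
  for (k in 1:200) {
    term <- term * m / (k * (k + 1))
    s <- s + term
    if (max(Mod(term)) < 1e-18 * max(Mod(s), 1)) break
  }
  s
}

#' Analytic Womersley solution for oscillatory tube flow
#'
#' Exact velocity field for a Newtonian fluid in a rigid straight tube driven
#' by the oscillatory axial pressure gradient
#' \eqn{-\partial p/\partial x = G\cos(\omega t)}:
#' \deqn{u(r,t) = \Re\left\{\frac{G}{i\rho\omega}\left[1 -
#'   \frac{J_0(\beta r)}{J_0(\beta R)}\right] e^{i\omega t}\right\},
#'   \qquad \beta = i^{3/2}\sqrt{\omega\rho/\mu}.}
#' Serves as the validation oracle for the numerical solver in the Newtonian
#' limit; no-slip at the wall is built in.
#'
#' @param rho Density, kg/m3.
#' @param mu Dynamic viscosity, Pa s.
#' @param R Tube radius, m.
#' @param G_amplitude Pressure-gradient amplitude G, Pa/m (the driving
#'   gradient is `dpdx = -G * cos(omega * t)`).
#' @param omega Angular frequency, rad/s (> 0).
#' @param radii Radial evaluation points, m (a numeric vector or a
#'   [radial_grid()]).
#' @param times Evaluation times, s.
#' @return List with `u` (matrix, time by radius, m/s), `tau_wall`
#'   (magnitude, Pa), `tau_wall_signed` (\eqn{\mu\,\partial u/\partial r} at
#'   the wall, Pa), `radii`, `times`, and the Womersley number `alpha`.
#' @export
#' @examples
#' w <- womersley_flow(1060, 0.004, 0.01794, 100, 2 * pi,
#'                     seq(0, 0.01794, length.out = 41), seq(0, 1, by = 0.05))
#' max(abs(w$u[, 41]))  # no-slip: identically zero at the wall
womersley_flow <- function(rho, mu, R, G_amplitude, omega, radii, times) {
  if (mu <= 0 || rho <= 0 || R <= 0) stop("'rho', 'mu', 'R' must be > 0",
                                          call. = FALSE)
  if (omega <= 0) stop("'omega' must be > 0", call. = FALSE)
  if (inherits(radii, "radial_grid")) radii <- radii$radii
  stopifnot(is.numeric(radii), is.numeric(times))
  beta <- complex(real = 0, imaginary = 1)^1.5 * sqrt(omega * rho / mu)
  j0R <- bessel_j0_complex(beta * R)
  prof <- (G_amplitude / (1i * rho * omega)) *
    (1 - bessel_j0_complex(beta * radii) / j0R)      # complex radial profile
  phase <- exp(1i * omega * times)
  u <- Re(outer(phase, prof))
  # d/dr J0(beta r) = -beta J1(beta r)
  dprof_wall <- (G_amplitude / (1i * rho * omega)) *
    (beta * bessel_j1_complex(beta * R) / j0R)
  tau_signed <- mu * Re(phase * dprof_wall)
  list(u = u, tau_wall = abs(tau_signed), tau_wall_signed = tau_signed,
       radii = radii, times = times,
       alpha = womersley_number(R, omega, rho, mu))
}
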