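#' Carreau rheological parameters for blood
#'
#' Constructs a validated parameter set for the Carreau generalized-Newtonian
#' viscosity law, which interpolates between a zero-shear viscosity
#' \eqn{\mu_0} and an infinite-shear viscosity \eqn{\mu_\infty} with a time
#' constant \eqn{\lambda} and power-law index \eqn{n}:
#' \deqn{\mu(\dot\gamma) = \mu_\infty + (\mu_0 - \mu_\infty)
#'       \left[1 + (\lambda\dot\gamma)^2\right]^{(n-1)/2}.}
#' The defaults are a widely used fit for whole human blood
#' (\eqn{\mu_0 = 0.056} Pa s, \eqn{\mu_\infty = 0.0035} Pa s,
#' \eqn{\lambda = 3.313} s, \eqn{n = 0.568}) with density 1060 kg/m3.
#'
#' @param mu_zero Zero-shear viscosity, Pa s.
#' @param mu_inf Infinite-shear viscosity, Pa s. Must satisfy
#'   `mu_zero >= mu_inf > 0`.
#' @param lambda_s Time constant, s (> 0).
#' @param n_index Power-law index, dimensionless. Shear-thinning requires
#'   `0 < n_index <= 1`; values above 1 (shear-thickening) are rejected
#'   unless `allow_thickening = TRUE`.
#' @param rho Fluid density, kg/m3 (> 0).
#' @param allow_thickening Permit `n_index > 1`. Default `FALSE`.
#'
#' @return An object of class `"carreau_params"`: a named list with fields
#'   `mu_zero`, `mu_inf`, `lambda_s`, `n_index`, `rho`.
#' @seealso [carreau_viscosity()], [apparent_viscosity_range()]
#' @export
#' @examples
#' bp <- carreau_params()
#' carreau_viscosity(bp, c(0, 1, 100, 1e4))
carreau_params <- function(mu_zero = 0.056, mu_inf = 0.0035,
                           lambda_s = 3.313, n_index = 0.568,
                           rho = 1060, allow_thickening = FALSE) {
  for (nm in c("mu_zero", "mu_inf", "lambda_s", "n_index", "rho")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
  }
  if (mu_inf <= 0) stop("'mu_inf' must be > 0", call. = FALSE)
  if (mu_zero < mu_inf) stop("'mu_zero' must be >= 'mu_inf'", call. = FALSE)
  if (lambda_s <= 0) stop("'lambda_s' must be > 0", call. = FALSE)
  if (rho <= 0) stop("'rho' must be > 0", call. = FALSE)
  if (n_index <= 0) stop("'n_index' must be > 0", call. = FALSE)
  if (n_index > 1 && !allow_thickening)
    stop("'n_index' > 1 (shear-thickening) rejected; set allow_thickening = TRUE to override",
         call. = FALSE)
  structure(list(mu_zero = mu_zero, mu_inf = mu_inf, lambda_s = lambda_s,
                 n_index = n_index, rho = rho),
            class = "carreau_params")
}

#' Newtonian parameter set
#'
#' Degenerate Carreau parameters with `mu_zero == mu_inf`, i.e. a constant
#' viscosity fluid. Convenience wrapper used by the solver oracles.
#'
#' @param mu Constant dynamic viscosity, Pa s.
#' @param rho Density, kg/m3.
#' @return A `"carreau_params"` object whose viscosity is `mu` at all shear
#'   rates.
#' @export
newtonian_params <- function(mu = 0.004, rho = 1060) {
  carreau_params(mu_zero = mu, mu_inf = mu, lambda_s = 1, n_index = 1,
                 rho = rho)
}

#' @export
print.carreau_params <- function(x, ...) {
  cat("Carreau viscosity parameters\n")
  cat(sprintf("  mu_zero : %g Pa.s\n", x$mu_zero))
  cat(sprintf("  mu_inf  : %g Pa.s\n", x$mu_inf))
  cat(sprintf("  lambda  : %g s\n", x$lambda_s))
  cat(sprintf("  n       : %g\n", x$n_index))
  cat(sprintf("  rho     : %g kg/m^3\n", x$rho))
  if (x$mu_zero == x$mu_inf) cat("  (Newtonian degenerate case)\n")
  invisible(x)
}

#' Carreau apparent viscosity
#'
#' Evaluates \eqn{\mu(\dot\gamma) = \mu_\infty + (\mu_0 - \mu_\infty)
#' [1 + (\lambda\dot\gamma)^2]^{(n-1)/2}} elementwise. Shear rate is the
#' magnitude of the strain rate; negative inputs are a caller error.
#'
#' @param params A [carreau_params()] object.
#' @param shear_rate Scalar or numeric array of shear-rate magnitudes, 1/s
#'   (all `>= 0`).
#' @return Viscosity in Pa s with the same shape (and dim attributes) as
#'   `shear_rate`, bounded in `[mu_inf, mu_zero]`.
#' @export
carreau_viscosity <- function(params, shear_rate) {
  stopifnot(inherits(params, "carreau_params"))
  if (!is.numeric(shear_rate))
    stop("'shear_rate' must be numeric", call. = FALSE)
  if (anyNA(shear_rate) || any(!is.finite(shear_rate)))
    stop("'shear_rate' contains non-finite values", call. = FALSE)
  if (any(shear_rate < 0))
    stop("'shear_rate' must be >= 0 (pass magnitudes)", call. = FALSE)
  mu <- params$mu_inf + (params$mu_zero - params$mu_inf) *
    (1 + (params$lambda_s * shear_rate)^2)^((params$n_index - 1) / 2)
  # guard round-off at extreme exponents
  mu <- pmin(pmax(mu, params$mu_inf), params$mu_zero)
  dim(mu) <- dim(shear_rate)
  mu
}

#' Attainable apparent-viscosity band
#'
#' The Carreau law is monotone between its asymptotes, so the apparent
#' viscosity over all shear rates spans exactly `[mu_inf, mu_zero]`.
#'
#' @param params A [carreau_params()] object.
#' @return Named numeric vector `c(mu_min = , mu_max = )` in Pa s.
#' @export
apparent_viscosity_range <- function(params) {
  stopifnot(inherits(params, "carreau_params"))
  c(mu_min = params$mu_inf, mu_max = params$mu_zero)
}
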