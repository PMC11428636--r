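#' Stretched radial grid with near-wall inflation layers
#'
#' Builds the node set for the axisymmetric solver: nodes run from the tube
#' axis (r = 0) to the wall (r = R). Near the wall a geometric inflation
#' stack is laid down — the first off-wall gap equals `first_layer` and each
#' successive gap (moving inward) grows by `growth` — mirroring the
#' boundary-layer prisms used in arterial CFD meshes (0.1 mm first layer,
#' 5 layers, 1.2 growth by default). The remaining core is filled with
#' `n_interior` geometrically graded intervals whose spacing matches onto
#' the innermost inflation gap and coarsens smoothly toward the axis.
#'
#' @param R Tube radius, m.
#' @param first_layer First off-wall gap, m. Default `1e-4` (0.1 mm).
#' @param n_layers Number of inflation layers. `0` gives a uniform grid.
#' @param growth Growth ratio of successive inflation gaps. Default 1.2.
#' @param n_interior Number of intervals filling the core region.
#' @return An object of class `"radial_grid"`: list with `radii` (strictly
#'   increasing, `radii[1] == 0`, `radii[n] == R`), `R`, `n_nodes`, and
#'   `layer_spec`.
#' @export
#' @examples
#' g <- radial_grid(R = 0.01794)
#' rev(diff(g$radii))[1:5] * 1000  # inflation gaps in mm: 0.1 0.12 0.144 ...
radial_grid <- function(R, first_layer = 1e-4, n_layers = 5L, growth = 1.2,
                        n_interior = 40L) {
  stopifnot(is.numeric(R), length(R) == 1L, R > 0)
  n_layers <- as.integer(n_layers)
  n_interior <- as.integer(n_interior)
  if (n_interior < 8L) stop("'n_interior' must be >= 8", call. = FALSE)
  if (n_layers < 0L) stop("'n_layers' must be >= 0", call. = FALSE)
  if (n_layers > 0L) {
    if (first_layer <= 0 || growth <= 0)
      stop("'first_layer' and 'growth' must be > 0", call. = FALSE)
    gaps_bl <- first_layer * growth^(seq_len(n_layers) - 1)  # wall-inward
    if (sum(gaps_bl) >= R)
      stop("boundary layers (", signif(sum(gaps_bl), 6),
           " m) are thicker than the radius", call. = FALSE)
    core <- R - sum(gaps_bl)
    # continue the grading into the core: intervals h0*q, h0*q^2, ... summing
    # to the core length, with h0 the innermost inflation gap
    h0 <- gaps_bl[n_layers]
    fsum <- function(q) {
      if (abs(q - 1) < 1e-14) n_interior * h0 * q
      else h0 * q * (q^n_interior - 1) / (q - 1)
    }
    f <- function(q) fsum(q) - core
    q <- stats::uniroot(f, lower = 1e-3, upper = 50, tol = 1e-14)$root
    gaps_core <- h0 * q^seq_len(n_interior)              # wall-inward
    gaps <- c(gaps_bl, gaps_core)                        # wall-inward order
    radii <- R - rev(cumsum(gaps))                       # axis-outward interior
    radii <- c(radii, R)
    radii[1] <- 0                                        # absorb round-off
  } else {
    radii <- seq(0, R, length.out = n_interior + 1L)
  }
  if (any(diff(radii) <= 0)) stop("grid construction failed: non-monotone radii",
                                  call. = FALSE)
  structure(list(radii = radii, R = R, n_nodes = length(radii),
                 layer_spec = list(first_layer = if (n_layers > 0L) first_layer else NA_real_,
                                   n_layers = n_layers,
                                   growth = if (n_layers > 0L) growth else NA_real_)),
            class = "radial_grid")
}

#' @export
print.radial_grid <- function(x, ...) {
  cat(sprintf("Radial grid: %d nodes, R = %g m\n", x$n_nodes, x$R))
  if (x$layer_spec$n_layers > 0L)
    cat(sprintf("  inflation: %d layers, first %g m, growth %g\n",
                x$layer_spec$n_layers, x$layer_spec$first_layer,
                x$layer_spec$growth))
  invisible(x)
}
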