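#' Wall shear stress vector time series on a surface mesh
#'
#' Per-cell 3-vector wall shear stress sampled over exactly one cardiac
#' cycle. The series is treated as periodic: all cycle integrals close the
#' loop from the last sample back to the first.
#'
#' @param mesh A [surface_mesh()].
#' @param times Sample times, s; strictly increasing, starting at 0, not
#'   exceeding `period_T`.
#' @param wss Numeric array `T x C x 3` (time, cell, component), Pa.
#' @param period_T Cardiac period, s.
#' @return Object of class `"wss_series"`.
#' @export
wss_series <- function(mesh, times, wss, period_T) {
  stopifnot(inherits(mesh, "surface_mesh"))
  wss <- as.array(wss)
  if (length(dim(wss)) != 3L || dim(wss)[3] != 3L)
    stop("'wss' must be a T x C x 3 array", call. = FALSE)
  if (dim(wss)[1] != length(times))
    stop("time dimension of 'wss' does not match 'times'", call. = FALSE)
  if (dim(wss)[2] != nrow(mesh$triangles))
    stop("cell dimension of 'wss' does not match the mesh", call. = FALSE)
  if (anyNA(wss) || any(!is.finite(wss)))
    stop("'wss' contains non-finite values", call. = FALSE)
  if (times[1] != 0 || any(diff(times) <= 0) ||
      times[length(times)] > period_T * (1 + 1e-12))
    stop("'times' must be strictly increasing, start at 0 and stay within the period",
         call. = FALSE)
  if (period_T <= 0) stop("'period_T' must be > 0", call. = FALSE)
  structure(list(mesh = mesh, times = as.numeric(times), wss = wss,
                 period_T = period_T),
            class = "wss_series")
}

#' @export
print.wss_series <- function(x, ...) {
  cat(sprintf("WSS series: %d time samples x %d cells over T = %g s, |WSS| <= %.4g Pa\n",
              dim(x$wss)[1], dim(x$wss)[2], x$period_T,
              sqrt(max(apply(x$wss^2, c(1, 2), sum)))))
  invisible(x)
}

# Cyclic trapezoidal weights: integral over one period of a sampled periodic
# signal is sum(w * v), with the wrap segment (last sample -> first + T)
# included. Weights sum to period_T.
periodic_trapezoid_weights <- function(times, period_T) {
  m <- length(times)
  d <- c(diff(times), period_T - times[m] + times[1])
  (d + c(d[m], d[-m])) / 2
}

#' Project a WSS series onto the local tangent planes
#'
#' Removes, per cell and time sample, the component of the stress vector
#' along the cell normal. Wall shear stress is tangential by definition; a
#' normal component in exported data is numerical noise. Magnitudes never
#' increase.
#'
#' @param series A [wss_series()].
#' @return A [wss_series()] with tangential vectors.
#' @export
tangential_project <- function(series) {
  stopifnot(inherits(series, "wss_series"))
  nrml <- series$mesh$cell_normals
  w <- series$wss
  for (k in 1:3) {
    if (k == 1) {
      dotp <- w[, , 1] * rep(nrml[, 1], each = dim(w)[1]) +
        w[, , 2] * rep(nrml[, 2], each = dim(w)[1]) +
        w[, , 3] * rep(nrml[, 3], each = dim(w)[1])
    }
    w[, , k] <- w[, , k] - dotp * rep(nrml[, k], each = dim(w)[1])
  }
  wss_series(series$mesh, series$times, w, series$period_T)
}

wss_magnitudes <- function(series) {
  sqrt(series$wss[, , 1]^2 + series$wss[, , 2]^2 + series$wss[, , 3]^2)
}

#' Time-averaged wall shear stress (TAWSS)
#'
#' Cycle average of the WSS magnitude per cell,
#' \eqn{\mathrm{TAWSS} = \frac1T\int_0^T \lVert \vec{WSS}(t)\rVert\,dt},
#' by cyclic trapezoidal quadrature.
#'
#' @param series A [wss_series()] with at least 3 time samples.
#' @return Numeric vector, Pa, one value per cell.
#' @export
compute_tawss <- function(series) {
  stopifnot(inherits(series, "wss_series"))
  if (length(series$times) < 3L) stop("need at least 3 time samples",
                                      call. = FALSE)
  w <- periodic_trapezoid_weights(series$times, series$period_T)
  mag <- wss_magnitudes(series)
  drop(crossprod(mag, w)) / series$period_T
}

#' Oscillatory shear index (OSI)
#'
#' \deqn{\mathrm{OSI} = \frac12\left(1 -
#'   \frac{\lVert\int_0^T \vec{WSS}\,dt\rVert}{\int_0^T
#'   \lVert\vec{WSS}\rVert\,dt}\right) \in [0, 0.5].}
#' 0 marks unidirectional shear; 0.5 a perfectly oscillatory, zero-mean
#' stress. Cells with identically zero WSS get OSI 0; their count is
#' attached as attribute `"degenerate_cells"`.
#'
#' @param series A [wss_series()].
#' @return Numeric vector per cell, clipped to `[0, 0.5]` against round-off.
#' @export
compute_osi <- function(series) {
  stopifnot(inherits(series, "wss_series"))
  if (length(series$times) < 3L) stop("need at least 3 time samples",
                                      call. = FALSE)
  w <- periodic_trapezoid_weights(series$times, series$period_T)
  vint <- sapply(1:3, function(k) drop(crossprod(series$wss[, , k], w)))
  if (is.null(dim(vint))) vint <- matrix(vint, nrow = 1)
  num <- sqrt(rowSums(vint^2))
  den <- drop(crossprod(wss_magnitudes(series), w))
  degen <- den == 0
  osi <- ifelse(degen, 0, 0.5 * (1 - num / ifelse(degen, 1, den)))
  osi <- pmin(pmax(osi, 0), 0.5)
  attr(osi, "degenerate_cells") <- sum(degen)
  osi
}

#' Relative residence time (RRT)
#'
#' \eqn{\mathrm{RRT} = 1/\big((1 - 2\,\mathrm{OSI})\,\mathrm{TAWSS}\big)},
#' 1/Pa — a proxy for near-wall particle residence. The denominator is
#' genuinely singular at OSI = 0.5 or TAWSS = 0; such cells get a `+Inf`
#' sentinel and are counted in attribute `"sentinel_cells"`.
#'
#' @param tawss Per-cell TAWSS, Pa.
#' @param osi Per-cell OSI.
#' @return Numeric vector, 1/Pa.
#' @export
compute_rrt <- function(tawss, osi) {
  stopifnot(length(tawss) == length(osi))
  den <- (1 - 2 * osi) * tawss
  sing <- den <= .Machine$double.eps * max(tawss, 0)
  out <- ifelse(sing, Inf, 1 / ifelse(sing, 1, den))
  attr(out, "sentinel_cells") <- sum(sing)
  out
}

#' Endothelial cell activation potential (ECAP)
#'
#' \eqn{\mathrm{ECAP} = \mathrm{OSI}/\mathrm{TAWSS}}, 1/Pa. High values mark
#' low-shear, highly oscillatory wall regions prone to endothelial
#' activation and thrombosis. Where TAWSS = 0: `+Inf` sentinel if OSI > 0,
#' else 0.
#'
#' @inheritParams compute_rrt
#' @return Numeric vector, 1/Pa, with attribute `"sentinel_cells"`.
#' @export
compute_ecap <- function(tawss, osi) {
  stopifnot(length(tawss) == length(osi))
  zero <- tawss == 0
  out <- ifelse(zero, ifelse(osi > 0, Inf, 0),
                osi / ifelse(zero, 1, tawss))
  attr(out, "sentinel_cells") <- sum(zero & osi > 0)
  out
}

#' Endothelial wall-index map
#'
#' Runs the full per-cell index pipeline on a WSS series: TAWSS, OSI, RRT
#' and ECAP, with the singular-cell sentinel policy of [compute_rrt()] and
#' [compute_ecap()].
#'
#' @param series A [wss_series()].
#' @param project Remove normal components first via [tangential_project()].
#'   Default `FALSE` (solver-generated fields are already tangential).
#' @return Object of class `"wall_index_map"`: the mesh plus per-cell
#'   `tawss`, `osi`, `rrt`, `ecap` and a `counts` list (degenerate cells,
#'   RRT/ECAP sentinels).
#' @export
#' @examples
#' syn <- synth_wss_series(synth_tube_mesh(0.01, 0.02, 3), synth_config(seed = 1))
#' m <- wall_indices(syn$series)
#' summary(m)
wall_indices <- function(series, project = FALSE) {
  stopifnot(inherits(series, "wss_series"))
  if (project) series <- tangential_project(series)
  tawss <- compute_tawss(series)
  osi <- compute_osi(series)
  rrt <- compute_rrt(tawss, osi)
  ecap <- compute_ecap(tawss, osi)
  structure(list(mesh = series$mesh, tawss = tawss,
                 osi = as.numeric(osi), rrt = as.numeric(rrt),
                 ecap = as.numeric(ecap),
                 counts = list(
                   degenerate_cells = attr(osi, "degenerate_cells"),
                   rrt_sentinels = attr(rrt, "sentinel_cells"),
                   ecap_sentinels = attr(ecap, "sentinel_cells"))),
            class = "wall_index_map")
}

#' @export
print.wall_index_map <- function(x, ...) {
  cat(sprintf("Wall index map: %d cells\n", length(x$tawss)))
  cat(sprintf("  TAWSS [Pa] : %.4g .. %.4g\n", min(x$tawss), max(x$tawss)))
  cat(sprintf("  OSI        : %.4g .. %.4g\n", min(x$osi), max(x$osi)))
  cat(sprintf("  RRT  [1/Pa]: %.4g .. %.4g (%d singular)\n",
              min(x$rrt), max(x$rrt[is.finite(x$rrt)], 0),
              x$counts$rrt_sentinels))
  cat(sprintf("  ECAP [1/Pa]: %.4g .. %.4g (%d singular)\n",
              min(x$ecap), max(x$ecap[is.finite(x$ecap)], 0),
              x$counts$ecap_sentinels))
  invisible(x)
}

#' @export
summary.wall_index_map <- function(object, ...) {
  qs <- function(v) {
    v <- v[is.finite(v)]
    stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1))
  }
  out <- list(n_cells = length(object$tawss),
              total_area = sum(object$mesh$cell_areas),
              tawss = qs(object$tawss), osi = qs(object$osi),
              rrt = qs(object$rrt), ecap = qs(object$ecap),
              counts = object$counts)
  class(out) <- "summary.wall_index_map"
  out
}

#' @export
print.summary.wall_index_map <- function(x, ...) {
  cat(sprintf("Wall index map over %d cells (area %.6g m^2)\n",
              x$n_cells, x$total_area))
  tab <- rbind(TAWSS = x$tawss, OSI = x$osi, RRT = x$rrt, ECAP = x$ecap)
  colnames(tab) <- c("min", "q25", "median", "q75", "max")
  print(signif(tab, 4))
  cat(sprintf("degenerate cells: %d; RRT sentinels: %d; ECAP sentinels: %d\n",
              x$counts$degenerate_cells, x$counts$rrt_sentinels,
              x$counts$ecap_sentinels))
  invisible(x)
}

#' Thresholded surface area of a wall index
#'
#' Area of the wall where an index lies strictly above (or below) a
#' threshold — e.g. TAWSS > 5 Pa as a high-shear demonstration threshold, or
#' TAWSS < 0.4 Pa marking the proatherogenic low-shear phenotype.
#'
#' @param map A [wall_indices()].
#' @param field One of `"tawss"`, `"osi"`, `"rrt"`, `"ecap"`.
#' @param threshold Finite threshold in the field's units.
#' @param direction `"above"` or `"below"` (strict inequality).
#' @return List with `area_m2`, `fraction` (of total wall area) and the
#'   logical `cell_mask`.
#' @export
threshold_area <- function(map, field = c("tawss", "osi", "rrt", "ecap"),
                           threshold, direction = c("above", "below")) {
  stopifnot(inherits(map, "wall_index_map"))
  field <- match.arg(field)
  direction <- match.arg(direction)
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold))
    stop("'threshold' must be a single number", call. = FALSE)
  v <- map[[field]]
  mask <- if (direction == "above") v > threshold else v < threshold
  area <- sum(map$mesh$cell_areas[mask])
  list(area_m2 = area, fraction = area / sum(map$mesh$cell_areas),
       cell_mask = mask)
}
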