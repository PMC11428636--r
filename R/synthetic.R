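## Synthetic-data generators with machine-readable planted ground truth.
## They stand in for patient geometry and CFD exports that are not public:
## clinical-like waveforms, multi-resolution tube surface meshes, WSS vector
## series with exactly recoverable planted indices, and mesh-study tables
## with planted convergence behaviour.

# Run expr with a local RNG stream; global .Random.seed is untouched.
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Configuration for the synthetic-data generators
#'
#' Bundles every knob of the generators with reproducible defaults. The
#' default cardiac period is 1 s (3000 solver steps of 0.001 s spanning
#' three cycles), the inlet velocity peaks at t = 0.15 s with a cycle mean
#' of 0.14 m/s, the tube radius matches an equivalent aortic diameter of
#' 35.88 mm, and the resolution family spans 0.2-1.0 mm element sizes in
#' 0.2 mm steps. Identical configs (including `seed`) yield bitwise
#' identical outputs.
#'
#' @param seed Integer RNG seed.
#' @param period_T Cardiac period, s.
#' @param sbp,dbp Systolic and diastolic pressure, mmHg (`sbp > dbp > 0`);
#'   120/80 are textbook healthy central values.
#' @param t_peak Time of the systolic flow peak, s.
#' @param radius Tube radius, m.
#' @param tube_length Tube length, m.
#' @param element_sizes_mm Element-size family, mm.
#' @param n_samples Samples per cycle for generated waveforms.
#' @param wss_samples Time samples per cycle for generated WSS series.
#' @param mean_velocity Cycle-mean inlet velocity, m/s.
#' @param notch_depth Relative depth of the dicrotic notch dip (0 disables
#'   the notch and the dicrotic secondary wave).
#' @param osi_targets Planted per-region OSI values in `[0, 0.5]`.
#' @param tawss_targets Planted per-region TAWSS values, Pa (same length as
#'   `osi_targets`).
#' @param noise Relative noise level used where a generator supports it.
#' @return Object of class `"synth_config"`.
#' @export
synth_config <- function(seed = 1L, period_T = 1.0, sbp = 120, dbp = 80,
                         t_peak = 0.15, radius = 0.01794, tube_length = 0.1,
                         element_sizes_mm = seq(0.2, 1, by = 0.2),
                         n_samples = 1000L, wss_samples = 200L,
                         mean_velocity = 0.14, notch_depth = 0.12,
                         osi_targets = c(0, 0.1, 0.25, 0.4, 0.5),
                         tawss_targets = c(8, 5.5, 2, 1, 0.3),
                         noise = 0) {
  if (!(sbp > dbp && dbp > 0)) stop("need sbp > dbp > 0", call. = FALSE)
  if (!(t_peak > 0 && t_peak < period_T))
    stop("'t_peak' must lie inside the period", call. = FALSE)
  if (any(element_sizes_mm <= 0)) stop("element sizes must be > 0",
                                       call. = FALSE)
  if (length(osi_targets) != length(tawss_targets))
    stop("'osi_targets' and 'tawss_targets' must have equal length",
         call. = FALSE)
  if (any(osi_targets < 0 | osi_targets > 0.5))
    stop("requested OSI outside [0, 0.5]", call. = FALSE)
  if (any(tawss_targets < 0) || any(tawss_targets > 50))
    stop("planted TAWSS outside the plausible [0, 50] Pa band", call. = FALSE)
  structure(list(seed = as.integer(seed), period_T = period_T, sbp = sbp,
                 dbp = dbp, t_peak = t_peak, radius = radius,
                 tube_length = tube_length,
                 element_sizes_mm = element_sizes_mm,
                 n_samples = as.integer(n_samples),
                 wss_samples = as.integer(wss_samples),
                 mean_velocity = mean_velocity, notch_depth = notch_depth,
                 osi_targets = osi_targets, tawss_targets = tawss_targets,
                 noise = noise),
            class = "synth_config")
}

#' Synthetic central aortic pressure waveform with planted landmarks
#'
#' Builds a smooth periodic waveform showing the seven classical components
#' of the central aortic pulse — initial upstroke, incident rise, systolic
#' peak, late-systolic decline, dicrotic notch, diastolic runoff and
#' end-diastolic pressure — from a Gaussian-bump-plus-runoff construction,
#' then affinely maps it so the sampled maximum equals `sbp` and the
#' minimum equals `dbp` exactly. The exact landmark locations are returned
#' as ground truth. Per-seed jitter varies the bump widths and amplitudes
#' without moving the planted landmarks.
#'
#' @param cfg A [synth_config()].
#' @return List `waveform` (a [pressure_waveform()]) and `truth` (planted
#'   landmark list: `sbp`, `dbp`, `t_peak`, `notch` value/time or `NULL`,
#'   `end_diastolic_pressure`, `seed`).
#' @export
synth_pressure_waveform <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  T_ <- cfg$period_T
  n <- cfg$n_samples
  tt <- seq(0, T_, length.out = n + 1L)[1:n]
  with_local_seed(cfg$seed, {
    w1 <- stats::runif(1, 0.085, 0.095) * T_   # systolic bump width
    a2 <- stats::runif(1, 0.20, 0.30)          # dicrotic wave amplitude
    k_run <- stats::runif(1, 2.5, 3.5)         # runoff rate
    c_run <- stats::runif(1, 0.45, 0.55)       # runoff depth
  })
  t_pk <- tt[which.min(abs(tt - cfg$t_peak))]  # snap peak to the grid
  t_notch <- t_pk + 0.22 * T_
  w_n <- 0.015 * T_
  w2 <- 0.04 * T_
  dip <- cfg$notch_depth
  if (dip == 0) a2 <- 0                        # no notch, no secondary wave
  bump1 <- exp(-0.5 * ((tt - t_pk) / w1)^2)
  bump2 <- a2 * exp(-0.5 * ((tt - t_notch - 1.5 * w_n - w2) / w2)^2)
  notch <- -dip * exp(-0.5 * ((tt - t_notch) / w_n)^2)
  # runoff switches on smoothly just before the notch; flat through systole
  sw <- stats::plogis((tt - t_notch + 2 * w_n) / (0.5 * w_n))
  runoff <- -c_run * sw * (1 - exp(-k_run * (pmax(tt - t_pk, 0)) / T_))
  raw <- bump1 + bump2 + notch + runoff
  ipk <- which.max(raw)
  imin <- which.min(raw)
  if (tt[ipk] != t_pk)
    stop("infeasible landmark constraints: systolic peak moved off t_peak",
         call. = FALSE)
  if (imin != n)
    stop("infeasible landmark constraints: diastolic minimum not at cycle end",
         call. = FALSE)
  p <- cfg$dbp + (cfg$sbp - cfg$dbp) * (raw - raw[imin]) / (raw[ipk] - raw[imin])
  stopifnot(all(p >= 20), all(p <= 250))       # physiological gate
  truth_notch <- NULL
  if (dip > 0) {
    win <- which(tt >= t_notch - 3 * w_n & tt <= t_notch + 3 * w_n)
    i_n <- win[which.min(p[win])]
    truth_notch <- list(value = p[i_n], time = tt[i_n])
  }
  wf <- pressure_waveform(tt, p, T_, location = "ascending aorta")
  list(waveform = wf,
       truth = list(sbp = cfg$sbp, dbp = cfg$dbp, t_peak = t_pk,
                    t_sbp = tt[ipk], t_dbp = tt[imin],
                    notch = truth_notch,
                    end_diastolic_pressure = p[n], seed = cfg$seed))
}

#' Synthetic inlet velocity (or flow-rate) waveform
#'
#' Single-hump systolic pulse peaking at `t_peak` with a small optional
#' diastolic backflow, rescaled so the cyclic trapezoidal time average
#' equals `mean_velocity` exactly. With `as_flow = TRUE` the velocity is
#' multiplied by the tube cross-section to give a volumetric flow waveform.
#'
#' @param cfg A [synth_config()].
#' @param backflow Relative amplitude of the diastolic backflow lobe.
#' @param amplitude Relative systolic amplitude; 0 yields a constant
#'   waveform at `mean_velocity`.
#' @param as_flow Return flow rate (m3/s) instead of velocity (m/s).
#' @return A [waveform_series()].
#' @export
synth_flow_waveform <- function(cfg, backflow = 0.1, amplitude = 1,
                                as_flow = FALSE) {
  stopifnot(inherits(cfg, "synth_config"))
  T_ <- cfg$period_T
  n <- cfg$n_samples
  tt <- seq(0, T_, length.out = n + 1L)[1:n]
  t_pk <- tt[which.min(abs(tt - cfg$t_peak))]
  raw <- 0.02 + amplitude * exp(-0.5 * ((tt - t_pk) / (0.06 * T_))^2) -
    amplitude * backflow * exp(-0.5 * ((tt - t_pk - 0.2 * T_) / (0.04 * T_))^2)
  w <- periodic_trapezoid_weights(tt, T_)
  mean_raw <- sum(w * raw) / T_
  v <- raw * (cfg$mean_velocity / mean_raw)
  if (as_flow) {
    area <- pi * cfg$radius^2
    waveform_series(tt, v * area, T_, units = "m3/s")
  } else {
    waveform_series(tt, v, T_, units = "m/s")
  }
}

#' Synthetic triangulated tube surface mesh
#'
#' Structured triangulation of a straight circular cylinder (or a torus
#' segment when `curved = TRUE`) with mean edge length within 10% of the
#' requested element size, consistent outward normals and total area within
#' 2% of the analytic lateral area.
#'
#' @param R Tube radius, m.
#' @param length Tube length (arc length when curved), m.
#' @param element_size_mm Nominal element size, mm (< `R` in metres when
#'   converted).
#' @param curved Bend the tube onto a torus segment.
#' @return A [surface_mesh()].
#' @export
synth_tube_mesh <- function(R, length, element_size_mm, curved = FALSE) {
  if (R <= 0 || length <= 0) stop("degenerate dimensions", call. = FALSE)
  h <- element_size_mm / 1000
  if (h >= R) stop("'element_size_mm' must be smaller than the radius",
                   call. = FALSE)
  # structured quads split along one diagonal: mean edge = (2 + sqrt(2))/3 h0
  h0 <- h / ((2 + sqrt(2)) / 3)
  n_th <- max(16L, as.integer(round(2 * pi * R / h0)))
  n_z <- max(3L, as.integer(round(length / h0)))
  th <- seq(0, 2 * pi, length.out = n_th + 1L)[1:n_th]
  zz <- seq(0, length, length.out = n_z + 1L)
  if (!curved) {
    verts <- cbind(rep(R * cos(th), n_z + 1L),
                   rep(R * sin(th), n_z + 1L),
                   rep(zz, each = n_th))
  } else {
    Rc <- max(length, 3 * R)              # bend radius of the torus segment
    phi <- zz / Rc
    verts <- do.call(rbind, lapply(seq_along(phi), function(j) {
      cx <- Rc * (1 - cos(phi[j])); cz <- Rc * sin(phi[j])
      ex <- c(cos(phi[j]), 0, sin(phi[j]))   # local outward in bend plane
      ey <- c(0, 1, 0)
      cbind(cx + R * (cos(th) * ex[1]) + R * (sin(th) * ey[1]),
            R * sin(th),
            cz + R * (cos(th) * ex[3]))
    }))
  }
  vid <- function(i, j) (j - 1L) * n_th + ((i - 1L) %% n_th) + 1L
  tris <- vector("list", n_z)
  for (j in seq_len(n_z)) {
    i <- seq_len(n_th)
    a <- vid(i, j); b <- vid(i + 1L, j)
    c_ <- vid(i + 1L, j + 1L); d <- vid(i, j + 1L)
    tris[[j]] <- rbind(cbind(a, b, c_), cbind(a, c_, d))
  }
  mesh <- surface_mesh(verts, do.call(rbind, tris),
                       nominal_element_size = element_size_mm)
  if (!curved) {
    lateral <- 2 * pi * R * length
    stopifnot(abs(sum(mesh$cell_areas) - lateral) < 0.02 * lateral)
  }
  mesh
}

# Axial coordinate used for region banding (z for straight tubes, arc
# parameter for curved ones handled adequately by z ordering).
axial_coordinate <- function(mesh) cell_centroids(mesh)[, 3]

# Tangential unit direction per cell: axial direction projected onto the
# cell tangent plane.
axial_tangent <- function(mesh) {
  nrml <- mesh$cell_normals
  d <- matrix(0, nrow(nrml), 3)
  d[, 1] <- -nrml[, 3] * nrml[, 1]
  d[, 2] <- -nrml[, 3] * nrml[, 2]
  d[, 3] <- 1 - nrml[, 3] * nrml[, 3]
  len <- sqrt(rowSums(d^2))
  if (any(len < 1e-12)) stop("degenerate tangent direction", call. = FALSE)
  d / len
}

#' Synthetic WSS vector series with planted wall indices
#'
#' `mode = "analytic"`: each cell carries a unit square wave along its
#' tangential direction, scaled by a planted magnitude. The duty cycle `f`
#' of the square wave fixes the planted OSI = (1 - |2f - 1|)/2 in closed
#' form and the magnitude fixes TAWSS; RRT and ECAP follow from their
#' definitions. Sign transitions fall halfway between time samples and duty
#' cycles are snapped to the sample grid, so the cyclic trapezoidal
#' quadrature of the index pipeline recovers the planted values exactly
#' (the snapped values are what is reported as truth). Cells are banded
#' axially into one region per `osi_targets` entry; `noise > 0` applies a
#' seeded lognormal per-cell magnitude jitter (recorded in the truth).
#'
#' `mode = "solver"`: the wall-shear magnitude waveform of a
#' [solve_flow_driven()]/[solve_pressure_driven()] solution is laid along
#' the axial tangent with a smooth axial modulation; the planted OSI is 0
#' everywhere (unidirectional shear).
#'
#' @param mesh A [surface_mesh()].
#' @param cfg A [synth_config()] (seed, sample count, region targets).
#' @param mode `"analytic"` or `"solver"`.
#' @param solution A `"flow_solution"`, required for `mode = "solver"`.
#' @return List `series` (a [wss_series()]), `truth` (a
#'   `"wall_index_map"` with the planted per-cell values), `region`
#'   (per-cell region index, analytic mode).
#' @export
synth_wss_series <- function(mesh, cfg, mode = c("analytic", "solver"),
                             solution = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(cfg, "synth_config"))
  mode <- match.arg(mode)
  n <- cfg$wss_samples
  T_ <- cfg$period_T
  tt <- seq(0, T_, length.out = n + 1L)[1:n]
  F_ <- nrow(mesh$triangles)
  dir <- axial_tangent(mesh)
  if (mode == "analytic") {
    nreg <- length(cfg$osi_targets)
    z <- axial_coordinate(mesh)
    band <- cut(z, breaks = stats::quantile(z, probs = seq(0, 1, length.out = nreg + 1L)),
                include.lowest = TRUE, labels = FALSE)
    f_target <- 1 - cfg$osi_targets[band]          # duty cycle per cell
    k <- pmin(pmax(as.integer(round(f_target * n)), 0L), n)
    f_snap <- k / n
    osi_true <- 0.5 * (1 - abs(2 * f_snap - 1))
    mag <- cfg$tawss_targets[band]
    if (cfg$noise > 0) {
      mag <- with_local_seed(cfg$seed,
                             mag * exp(cfg$noise * stats::rnorm(F_)))
    }
    stopifnot(all(mag >= 0), all(mag <= 50))       # plausibility gate
    # sample j is +1 for j <= k (transitions sit between samples)
    sgn <- matrix(-1, nrow = n, ncol = F_)
    jj <- matrix(seq_len(n), nrow = n, ncol = F_)
    sgn[jj <= matrix(k, nrow = n, ncol = F_, byrow = TRUE)] <- 1
    wss <- array(0, dim = c(n, F_, 3))
    for (comp in 1:3)
      wss[, , comp] <- sgn * matrix(mag * dir[, comp], nrow = n, ncol = F_,
                                    byrow = TRUE)
    tawss_true <- mag
    region <- band
  } else {
    if (is.null(solution) || !inherits(solution, "flow_solution"))
      stop("'solution' (a flow_solution) is required for mode = 'solver'",
           call. = FALSE)
    tauf <- waveform_fun(waveform_series(solution$times, solution$tau_wall,
                                         solution$period_T, "Pa"))
    tau <- tauf(tt * solution$period_T / T_)       # map onto our cycle
    z <- axial_coordinate(mesh)
    modz <- 1 + 0.3 * sin(2 * pi * (z - min(z)) / max(diff(range(z)), 1e-12))
    wss <- array(0, dim = c(n, F_, 3))
    for (comp in 1:3)
      wss[, , comp] <- outer(tau, modz * dir[, comp])
    w <- periodic_trapezoid_weights(tt, T_)
    tawss_true <- modz * sum(w * tau) / T_
    osi_true <- rep(0, F_)
    region <- rep(1L, F_)
  }
  series <- wss_series(mesh, tt, wss, T_)
  rrt_true <- ifelse(osi_true >= 0.5 | tawss_true == 0, Inf,
                     1 / ((1 - 2 * osi_true) * tawss_true))
  ecap_true <- ifelse(tawss_true == 0, ifelse(osi_true > 0, Inf, 0),
                      osi_true / tawss_true)
  truth <- structure(list(mesh = mesh, tawss = tawss_true, osi = osi_true,
                          rrt = rrt_true, ecap = ecap_true,
                          counts = list(degenerate_cells = sum(tawss_true == 0),
                                        rrt_sentinels = sum(!is.finite(rrt_true)),
                                        ecap_sentinels = sum(!is.finite(ecap_true) ))),
                     class = "wall_index_map")
  list(series = series, truth = truth, region = region)
}

#' Synthetic mesh-study table with planted convergence behaviour
#'
#' Rows follow `value(h) = true_value + C * h^p` plus seeded Gaussian noise
#' for each element size `h` in the config family; element counts scale as
#' `h^-3`. Both parameters of interest are generated (supply length-2
#' vectors to differentiate them).
#'
#' @param cfg A [synth_config()] (sizes, seed).
#' @param true_value Asymptotic values, length 2 `(v_max, wss_max)` or
#'   scalar.
#' @param p Convergence order (> 0).
#' @param C Error coefficients, length 2 or scalar (sign sets the approach
#'   direction).
#' @param noise Absolute noise standard deviations, length 2 or scalar.
#' @return A [mesh_study_table()] (family label `"synthetic"`).
#' @export
synth_mesh_study <- function(cfg, true_value = c(0.75, 19), p = 2,
                             C = c(-0.15, 6), noise = 0) {
  stopifnot(inherits(cfg, "synth_config"))
  if (p <= 0) stop("'p' must be > 0", call. = FALSE)
  true_value <- rep_len(true_value, 2L)
  C <- rep_len(C, 2L)
  noise <- rep_len(noise, 2L)
  h <- sort(cfg$element_sizes_mm)
  nh <- length(h)
  eps <- with_local_seed(cfg$seed,
                         matrix(stats::rnorm(2L * nh), ncol = 2L))
  v <- true_value[1] + C[1] * h^p + noise[1] * eps[, 1]
  wss <- true_value[2] + C[2] * h^p + noise[2] * eps[, 2]
  counts <- round(400 * (max(h) / h)^3)
  mesh_study_table(h, counts, pmax(v, 0), pmax(wss, 0),
                   mesh_family = "synthetic")
}
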