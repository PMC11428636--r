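test_that("surface mesh areas and normals follow the cross-product formula", {
  mesh <- one_cell_mesh()
  expect_equal(mesh$cell_areas, 0.5)
  expect_equal(as.numeric(mesh$cell_normals), c(0, 0, 1))
  expect_error(surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                            rbind(c(1L, 2L, 3L))), "zero-area")
  expect_error(surface_mesh(diag(3), rbind(c(1L, 2L, 4L))), "out of range")
})

test_that("tangential projection removes exactly the normal component", {
  mesh <- synth_tube_mesh(0.01, 0.02, 3)
  set.seed(21)
  n <- 16; ncell <- nrow(mesh$triangles)
  wss <- array(stats::rnorm(n * ncell * 3), dim = c(n, ncell, 3))
  tt <- seq(0, 1, length.out = n + 1)[1:n]
  ser <- wss_series(mesh, tt, wss, 1)
  proj <- tangential_project(ser)
  # residual normal component vanishes
  for (k in sample(ncell, 5)) {
    dots <- proj$wss[, k, ] %*% mesh$cell_normals[k, ]
    expect_true(all(abs(dots) < 1e-12))
  }
  # magnitudes never increase
  m0 <- sqrt(ser$wss[, , 1]^2 + ser$wss[, , 2]^2 + ser$wss[, , 3]^2)
  m1 <- sqrt(proj$wss[, , 1]^2 + proj$wss[, , 2]^2 + proj$wss[, , 3]^2)
  expect_true(all(m1 <= m0 + 1e-14))
  # already-tangential fields are unchanged; pure-normal fields vanish
  expect_equal(tangential_project(proj)$wss, proj$wss)
  wn <- array(0, dim = c(n, ncell, 3))
  for (k in 1:3) wn[, , k] <- matrix(mesh$cell_normals[, k], n, ncell,
                                     byrow = TRUE)
  pn <- tangential_project(wss_series(mesh, tt, wn, 1))
  expect_lt(max(abs(pn$wss)), 1e-12)
})

test_that("TAWSS: constant and square-wave closed forms, sinusoid oracle", {
  ser <- square_wave_series(f = 0.6, mag = 2.5)
  expect_equal(compute_tawss(ser), 2.5)                 # |WSS| constant
  ser2 <- square_wave_series(f = 1, mag = 0.7)
  expect_equal(compute_tawss(ser2), 0.7)
  # WSS(t) = (a + b sin(2 pi t / T)) x_hat with b > a > 0
  a <- 0.8; b <- 2
  n <- 400
  tt <- seq(0, 1, length.out = n + 1)[1:n]
  wss <- array(0, dim = c(n, 1, 3))
  wss[, 1, 1] <- a + b * sin(2 * pi * tt)
  ser3 <- wss_series(one_cell_mesh(), tt, wss, 1)
  oracle <- oracle_indices(function(tq)
    cbind(abs(a + b * sin(2 * pi * tq)) * sign(a + b * sin(2 * pi * tq)), 0, 0),
    1, n_fine = 1e6)
  expect_equal(compute_tawss(ser3), oracle$tawss, tolerance = 1e-4)
  expect_error(compute_tawss(square_wave_series(0.5, n = 2)), "3 time samples")
})

test_that("OSI: unidirectional zero, square-wave closed form, smooth oracle", {
  # constant-direction, varying magnitude: OSI identically 0
  n <- 64
  tt <- seq(0, 1, length.out = n + 1)[1:n]
  wss <- array(0, dim = c(n, 1, 3))
  wss[, 1, 1] <- 1 + 0.9 * sin(2 * pi * tt)^2
  expect_equal(as.numeric(compute_osi(wss_series(one_cell_mesh(), tt, wss, 1))),
               0)
  # duty-cycle closed form: f = 0.75 -> OSI = 0.25
  expect_equal(as.numeric(compute_osi(square_wave_series(0.75))), 0.25)
  expect_equal(as.numeric(compute_osi(square_wave_series(0.5))), 0.5)
  # random smooth series against an independent fine-quadrature oracle
  set.seed(33)
  sm <- smooth_random_series(n = 2000)
  osi <- compute_osi(sm$series)
  tawss <- compute_tawss(sm$series)
  for (k in sample(length(osi), 6)) {
    co <- sm$coef[k, , ]
    fun <- function(tq) {
      nb <- sm$basis_n
      basis <- cbind(1, sapply(1:nb, function(j) cos(2 * pi * j * tq)),
                     sapply(1:nb, function(j) sin(2 * pi * j * tq)))
      basis %*% t(co)
    }
    orc <- oracle_indices(fun, 1)
    expect_equal(osi[k], orc$osi, tolerance = 1e-6)
    expect_equal(tawss[k], orc$tawss, tolerance = 1e-6)
  }
  # degenerate all-zero cell
  wz <- array(0, dim = c(n, 1, 3))
  oz <- compute_osi(wss_series(one_cell_mesh(), tt, wz, 1))
  expect_equal(as.numeric(oz), 0)
  expect_equal(attr(oz, "degenerate_cells"), 1L)
})

test_that("RRT and ECAP formulas, sentinels, and the consistency triplet", {
  expect_equal(as.numeric(compute_rrt(1, 0.25)), 2)
  expect_identical(as.numeric(compute_rrt(1, 0.5)), Inf)
  expect_equal(as.numeric(compute_ecap(1, 0.25)), 0.25)
  expect_equal(as.numeric(compute_ecap(c(1, 0), c(0, 0))), c(0, 0))
  expect_identical(as.numeric(compute_ecap(0, 0.2)), Inf)
  set.seed(5)
  tawss <- stats::runif(50, 0.1, 10)
  osi <- stats::runif(50, 0, 0.49)
  expect_equal(as.numeric(compute_rrt(tawss, osi)),
               1 / ((1 - 2 * osi) * tawss))
  expect_equal(as.numeric(compute_ecap(tawss, osi)), osi / tawss)
})

test_that("wall_indices satisfies its internal identities and bounds", {
  mesh <- synth_tube_mesh(0.01, 0.03, 2.5)
  syn <- synth_wss_series(mesh, synth_config(seed = 3), mode = "analytic")
  map <- wall_indices(syn$series)
  expect_true(all(map$osi >= 0 & map$osi <= 0.5))
  ok <- map$osi < 0.5 & map$tawss > 0
  expect_equal(map$rrt[ok] * (1 - 2 * map$osi[ok]) * map$tawss[ok],
               rep(1, sum(ok)), tolerance = 1e-9)
  expect_equal(map$ecap[ok] * map$tawss[ok], map$osi[ok], tolerance = 1e-9)
  # consistency triplet: recomputation from (TAWSS, OSI) matches bitwise
  expect_identical(map$rrt, as.numeric(compute_rrt(map$tawss, map$osi)))
  expect_identical(map$ecap, as.numeric(compute_ecap(map$tawss, map$osi)))
})

test_that("scale equivariance: c*WSS scales TAWSS by c, OSI unchanged,
           RRT and ECAP by 1/c", {
  set.seed(44)
  sm <- smooth_random_series(n = 256)
  m1 <- wall_indices(sm$series)
  c_ <- 3.7
  ser2 <- wss_series(sm$series$mesh, sm$series$times, c_ * sm$series$wss, 1)
  m2 <- wall_indices(ser2)
  expect_equal(m2$tawss, c_ * m1$tawss)
  expect_equal(m2$osi, m1$osi, tolerance = 1e-12)
  expect_equal(m2$rrt, m1$rrt / c_, tolerance = 1e-9)
  expect_equal(m2$ecap, m1$ecap / c_, tolerance = 1e-9)
})

test_that("OSI stays within [0, 0.5] on adversarial sign-flipping series", {
  mesh <- one_cell_mesh()
  set.seed(9)
  for (rep in 1:20) {
    n <- sample(c(8, 16, 33, 101), 1)
    tt <- sort(c(0, stats::runif(n - 1, 0, 0.99)))
    wss <- array(stats::rnorm(n * 3) * sample(c(-1, 1), n, TRUE),
                 dim = c(n, 1, 3))
    osi <- compute_osi(wss_series(mesh, tt, wss, 1))
    expect_true(osi >= 0 && osi <= 0.5)
  }
})

test_that("indices are invariant to time-grid refinement/non-uniformity", {
  set.seed(55)
  co <- matrix(stats::rnorm(9), 3)  # 1 harmonic + offset per component
  fun <- function(tq) cbind(2 + co[1, 1] * sin(2 * pi * tq),
                            co[2, 1] + co[2, 2] * cos(2 * pi * tq),
                            co[3, 3] * sin(4 * pi * tq))
  mk <- function(tt) {
    wss <- array(0, dim = c(length(tt), 1, 3))
    wss[, 1, ] <- fun(tt)
    wss_series(one_cell_mesh(), tt, wss, 1)
  }
  t_unif <- seq(0, 1, length.out = 257)[1:256]
  t_rand <- sort(c(0, stats::runif(219, 0, 0.995)))
  mu <- wall_indices(mk(t_unif)); mr <- wall_indices(mk(t_rand))
  expect_equal(mu$tawss, mr$tawss, tolerance = 1e-3)
  expect_equal(mu$osi, mr$osi, tolerance = 1e-3)
})

test_that("threshold areas: uniform fields, infinite threshold, planted ratio", {
  mesh <- synth_tube_mesh(0.01, 0.02, 3)
  nc <- nrow(mesh$triangles)
  map <- structure(list(mesh = mesh, tawss = rep(6, nc), osi = rep(0, nc),
                        rrt = rep(1 / 6, nc), ecap = rep(0, nc),
                        counts = list(degenerate_cells = 0L,
                                      rrt_sentinels = 0L,
                                      ecap_sentinels = 0L)),
                   class = "wall_index_map")
  expect_equal(threshold_area(map, "tawss", 5, "above")$fraction, 1)
  expect_equal(threshold_area(map, "tawss", Inf, "above")$fraction, 0)
  # planted two-region field: fraction equals the constructed area ratio
  z <- cell_centroids(mesh)[, 3]
  hi <- z > stats::median(z)
  map$tawss[hi] <- 10; map$tawss[!hi] <- 1
  fr <- threshold_area(map, "tawss", 5, "above")
  expect_equal(fr$fraction, sum(mesh$cell_areas[hi]) / sum(mesh$cell_areas),
               tolerance = 1e-12)
  expect_error(threshold_area(map, "nope", 1, "above"))
})

test_that("solver-generated unidirectional pulsatile flow has OSI = 0
           everywhere (high TAWSS comes with low OSI)", {
  np <- newtonian_params()
  gr <- radial_grid(0.005, n_interior = 16)
  tt <- seq(0, 0.98, by = 0.02)
  qw <- waveform_series(tt, 2e-6 * (1 + 0.5 * sin(2 * pi * tt)), 1, "m3/s")
  sol <- solve_flow_driven(np, gr, qw, dt = 0.02, n_cycles = 2)
  mesh <- synth_tube_mesh(0.005, 0.02, 1.5)
  syn <- synth_wss_series(mesh, synth_config(seed = 2, radius = 0.005),
                          mode = "solver", solution = sol)
  map <- wall_indices(syn$series)
  expect_true(all(map$osi == 0))
  expect_equal(map$tawss, syn$truth$tawss, tolerance = 1e-9)
})
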