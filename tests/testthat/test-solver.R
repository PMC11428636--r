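test_that("radial grid honours the inflation-layer specification", {
  g <- radial_grid(0.01794)
  gaps_mm <- rev(diff(g$radii))[1:5] * 1000
  expect_equal(gaps_mm, c(0.1, 0.12, 0.144, 0.1728, 0.20736),
               tolerance = 1e-12)
  expect_identical(g$radii[1], 0)
  expect_equal(g$radii[g$n_nodes], 0.01794)
  expect_true(all(diff(g$radii) > 0))
  # constructive recomputation: interior grading continues geometrically
  gaps <- rev(diff(g$radii))
  ratios <- gaps[-1] / gaps[-length(gaps)]
  expect_true(all(ratios > 1))          # monotone coarsening toward axis
  expect_equal(g$n_nodes, 40 + 5 + 1)
})

test_that("degenerate grids: uniform fallback and geometry errors", {
  g0 <- radial_grid(0.01, n_layers = 0, n_interior = 16)
  expect_equal(g0$radii, seq(0, 0.01, length.out = 17))
  expect_error(radial_grid(0.0005, first_layer = 1e-4, n_layers = 5),
               "thicker")
})

test_that("Reynolds and Womersley numbers match direct formulas", {
  expect_equal(round(reynolds_number(1060, 0.14, 0.03588, 0.004)), 1331)
  expect_equal(reynolds_number(1050, 0.2, 0.02, 0.004), 1050)
  expect_equal(reynolds_number(1060, 0, 0.03, 0.004), 0)
  expect_true(is_laminar(1331))
  expect_false(is_laminar(2500))
  expect_equal(womersley_number(0.01794, 2 * pi, 1060, 0.004),
               23.149163902, tolerance = 1e-9)
  expect_equal(womersley_number(0.01, 0, 1060, 0.004), 0)
  a1 <- womersley_number(0.01, 1.7, 1060, 0.004)
  expect_equal(womersley_number(0.01, 4 * 1.7, 1060, 0.004), 2 * a1)
  expect_error(reynolds_number(1060, 0.1, 0, 0.004), "> 0")
  expect_error(womersley_number(-1, 1, 1060, 0.004), "> 0")
})

test_that("analytic Womersley solution: no-slip, quasi-steady limit, and an
           independent special-function cross-check", {
  R <- 0.01794; rho <- 1060; mu <- 0.004; G <- 100
  rr <- seq(0, R, length.out = 41)
  w <- womersley_flow(rho, mu, R, G, 2 * pi, rr, seq(0, 1, by = 0.05))
  expect_true(all(abs(w$u[, 41]) < 1e-14))
  # omega -> 0: quasi-steady Poiseuille at the pressure-gradient peak
  w0 <- womersley_flow(rho, mu, R, G, 1e-6, rr, 0)
  pois <- G * (R^2 - rr^2) / (4 * mu)
  expect_lt(max(abs(w0$u[1, ] - pois)) / max(pois), 1e-4)
  # alpha ~ 23 case against quadrature evaluation of J0(z), z complex, via
  # the integral representation J0(z) = (1/pi) int_0^pi cos(z sin t) dt
  j0q <- function(z) {
    th <- seq(0, pi, length.out = 20001)
    h <- th[2] - th[1]
    sapply(z, function(zi) {
      f <- cos(zi * sin(th))
      h * (sum(f) - (f[1] + f[length(f)]) / 2) / pi
    })
  }
  beta <- complex(real = 0, imaginary = 1)^1.5 * sqrt(2 * pi * rho / mu)
  prof <- (G / (1i * rho * 2 * pi)) * (1 - j0q(beta * rr) / j0q(beta * R))
  u_ref <- Re(prof * exp(1i * 2 * pi * 0.1))
  w1 <- womersley_flow(rho, mu, R, G, 2 * pi, rr, 0.1)
  expect_equal(as.numeric(w1$u[1, ]), u_ref, tolerance = 1e-8)
  # frozen 40-digit spot values for the same case
  ws <- womersley_flow(rho, mu, R, G, 2 * pi, c(0, 0.009, 0.0179), 0.1)
  expect_equal(as.numeric(ws$u[1, ]),
               c(0.00882537559906808, 0.00883115930013029,
                 0.00074033077816531), tolerance = 1e-10)
  expect_equal(ws$tau_wall_signed[1], -0.0755629157770601, tolerance = 1e-9)
})

test_that("steady Newtonian solve reproduces Poiseuille exactly", {
  np <- newtonian_params(0.004)
  gr <- radial_grid(0.01, n_interior = 30)
  wf <- waveform_series(seq(0, 0.9, length.out = 10), rep(-100, 10), 1, "Pa/m")
  sol <- solve_pressure_driven(np, gr, wf, dt = 0.01, n_cycles = 3)
  expect_true(sol$converged)
  expect_equal(sol$tau_wall[1], 0.5, tolerance = 1e-10)  # GR/2
  expect_equal(sol$Q[1], pi * 100 * 0.01^4 / (8 * 0.004), tolerance = 1e-3)
  # no-slip and axis symmetry
  expect_true(all(sol$u[, ncol(sol$u)] == 0))
  r <- gr$radii
  # axis symmetry: second-order (quadratic-fit) derivative at r = 0
  r2 <- r[2]; r3 <- r[3]
  dudr_axis <- sol$u[1, 1] * (-(r2 + r3)) / (r2 * r3) +
    sol$u[1, 2] * r3 / (r2 * (r3 - r2)) +
    sol$u[1, 3] * (-r2) / (r3 * (r3 - r2))
  expect_lt(abs(dudr_axis) * gr$R / max(abs(sol$u)), 1e-8)
  # internal consistency: Q equals the annular quadrature of u
  qq <- 2 * pi * sum(diff(r) * (sol$u[1, -length(r)] * r[-length(r)] +
                                  sol$u[1, -1] * r[-1]) / 2)
  expect_equal(sol$Q[1], qq, tolerance = 1e-12)
})

test_that("oscillatory Newtonian solve matches the Womersley oracle", {
  R <- 0.01794; rho <- 1060; mu <- 0.004; G <- 100; om <- 2 * pi
  np <- newtonian_params(mu, rho)
  gr <- radial_grid(R, n_interior = 60)
  tt <- seq(0, 0.999, by = 0.001)
  wf <- waveform_series(tt, -G * cos(om * tt), 1, "Pa/m")
  wan0 <- womersley_flow(rho, mu, R, G, om, gr, 0)
  sol <- solve_pressure_driven(np, gr, wf, dt = 0.001, n_cycles = 3,
                               u_init = wan0$u[1, ])
  wan <- womersley_flow(rho, mu, R, G, om, gr, sol$times)
  l2 <- sqrt(sum((sol$u - wan$u)^2) / sum(wan$u^2))
  expect_lt(l2, 0.01)
  # periodicity: cycle 3 vs cycle 2 below 1e-3 of peak velocity
  expect_lt(sol$cycle_diffs[length(sol$cycle_diffs)], 1e-3)
})

test_that("Carreau steady profile matches an independent BVP oracle", {
  cp <- paper_carreau()
  G <- 200; R <- 0.01794
  gr <- radial_grid(R, n_interior = 60)
  wf <- waveform_series(seq(0, 0.9, length.out = 10), rep(-G, 10), 1, "Pa/m")
  sol <- solve_pressure_driven(cp, gr, wf, dt = 0.01, n_cycles = 1)
  # oracle: the steady momentum integrates to mu(|u'|) u' = -G r / 2;
  # solve the scalar nonlinear equation for u'(r) and integrate inward
  visc <- function(s) cp$mu_inf + (cp$mu_zero - cp$mu_inf) *
    (1 + (cp$lambda_s * abs(s))^2)^((cp$n_index - 1) / 2)
  sfun <- function(rr) sapply(rr, function(ri) {
    if (ri == 0) return(0)
    stats::uniroot(function(s) visc(s) * s + G * ri / 2, c(-1e7, 0),
                   tol = 1e-14)$root
  })
  u_oracle <- sapply(gr$radii, function(ri)
    -stats::integrate(sfun, ri, R, rel.tol = 1e-10)$value)
  expect_lt(max(abs(sol$u[1, ] - u_oracle)) / max(abs(u_oracle)), 0.005)
  expect_equal(sol$tau_wall[1], G * R / 2, tolerance = 1e-4)
})

test_that("flow-driven solve inverts Poiseuille and round-trips dpdx", {
  np <- newtonian_params(0.004)
  gr <- radial_grid(0.005, n_interior = 24)
  # constant flow: exact Poiseuille inversion
  qc <- 2e-6
  qw <- waveform_series(seq(0, 0.9, length.out = 10), rep(qc, 10), 1, "m3/s")
  s1 <- solve_flow_driven(np, gr, qw, dt = 0.01, n_cycles = 2)
  expect_equal(s1$dpdx[1], -8 * 0.004 * qc / (pi * 0.005^4), tolerance = 2e-3)
  expect_equal(s1$tau_wall[1], 4 * 0.004 * qc / (pi * 0.005^3),
               tolerance = 2e-3)
  # zero flow: identically zero solution
  q0 <- waveform_series(seq(0, 0.9, length.out = 10), rep(0, 10), 1, "m3/s")
  s0 <- solve_flow_driven(np, gr, q0, dt = 0.01, n_cycles = 2)
  expect_true(all(s0$u == 0) && all(s0$tau_wall == 0))
  # pulsatile round trip: recovered dpdx reproduces the imposed flow
  tt <- seq(0, 0.995, by = 0.005)
  qw2 <- waveform_series(tt, qc * (1 + 0.8 * sin(2 * pi * tt)), 1, "m3/s")
  s2 <- solve_flow_driven(np, gr, qw2, dt = 0.005, n_cycles = 2)
  dpdx_wf <- waveform_series(s2$times, s2$dpdx, 1, "Pa/m")
  s3 <- solve_pressure_driven(np, gr, dpdx_wf, dt = 0.005, n_cycles = 1,
                              u_init = s2$u[1, ])
  expect_lt(max(abs(s3$Q - s2$Q)) / max(abs(s2$Q)), 1e-3)
})

test_that("time-step robustness and grid refinement on the oscillatory case", {
  R <- 0.01794; rho <- 1060; mu <- 0.004; G <- 100; om <- 2 * pi
  np <- newtonian_params(mu, rho)
  gr <- radial_grid(R, n_interior = 60)
  wan0 <- womersley_flow(rho, mu, R, G, om, gr, 0)
  mk <- function(dt, grid = gr, init = wan0$u[1, ]) {
    tt <- seq(0, 1 - dt, by = dt)
    wf <- waveform_series(tt, -G * cos(om * tt), 1, "Pa/m")
    solve_pressure_driven(np, grid, wf, dt = dt, n_cycles = 3, u_init = init)
  }
  s5 <- mk(0.005); s1 <- mk(0.001); s05 <- mk(0.0005)
  l2tau <- function(a, b) {
    fb <- stats::approx(c(b$times, 1), c(b$tau_wall, b$tau_wall[1]),
                        xout = a$times)$y
    sqrt(sum((a$tau_wall - fb)^2) / sum(fb^2))
  }
  expect_lt(l2tau(s5, s1), 0.01)
  expect_lt(l2tau(s05, s1), 0.01)
  g2 <- radial_grid(R, n_interior = 120)
  wan2 <- womersley_flow(rho, mu, R, G, om, g2, 0)
  s2 <- mk(0.001, g2, wan2$u[1, ])
  expect_lt(abs(max(s1$tau_wall) - max(s2$tau_wall)) / max(s2$tau_wall),
            0.005)
})

test_that("solver guards: bad time step and NaN inputs", {
  np <- newtonian_params()
  gr <- radial_grid(0.005, n_interior = 10)
  wf <- waveform_series(seq(0, 0.9, length.out = 10), rep(-10, 10), 1, "Pa/m")
  expect_error(solve_pressure_driven(np, gr, wf, dt = 0.15), "divisible")
  expect_error(waveform_series(seq(0, 0.9, length.out = 10),
                               c(rep(1, 9), NaN), 1), "non-finite")
})
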