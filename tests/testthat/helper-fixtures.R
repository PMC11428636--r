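# Printed mesh-independence reference tables (verbatim values, including the
# repeated polyhedral V_max at 0.2 and 1 mm) and small reusable builders.

table_tetra <- function() {
  mesh_study_table(
    element_size_mm = c(0.2, 0.4, 0.6, 0.8, 1),
    element_count = c(7030641, 1148142, 547059, 405490, 369728),
    v_max_mps = c(0.7200, 0.7075, 0.6854, 0.6442, 0.5607),
    wss_max_pa = c(21.8233293, 22.3736838, 23.0381622, 23.6513115, 26.7444558),
    runtime_min = c(222, 50, 35, 31, 30),
    mesh_family = "tetrahedral")
}

table_poly <- function() {
  mesh_study_table(
    element_size_mm = c(0.2, 0.4, 0.6, 0.8, 1),
    element_count = c(9248899, 1753454, 951802, 766309, 732146),
    v_max_mps = c(0.753678, 0.748364, 0.741864, 0.725355, 0.753678),
    wss_max_pa = c(19.67837, 20.14034, 21.35883, 22.67753, 24.66996),
    runtime_min = c(103, 37, 31, 27, 25),
    mesh_family = "polyhedral")
}

# Expected printed percentage columns (fine-to-coarse pairs).
pct_tetra_vmax <- c(2L, 3L, 6L, 13L)
pct_tetra_wss <- c(2L, 3L, 3L, 12L)
pct_poly_vmax <- c(1L, 1L, 2L, 4L)
pct_poly_wss <- c(2L, 6L, 6L, 8L)

paper_carreau <- function() carreau_params(0.056, 0.0035, 3.313, 0.568, 1060)

# Small single-cell mesh for index unit tests (unit normal along +z).
one_cell_mesh <- function() {
  surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
               rbind(c(1L, 2L, 3L)))
}

# Square-wave WSS series along +x on a single cell: duty fraction f of the
# cycle at +mag, the rest at -mag; transitions between samples.
square_wave_series <- function(f, mag = 1, n = 200, T_ = 1) {
  mesh <- one_cell_mesh()
  tt <- seq(0, T_, length.out = n + 1)[1:n]
  k <- round(f * n)
  s <- rep(-1, n); s[seq_len(k)] <- 1
  wss <- array(0, dim = c(n, 1, 3))
  wss[, 1, 1] <- mag * s
  wss_series(mesh, tt, wss, T_)
}

# Smooth random Fourier WSS series (fixed seed handled by caller).
smooth_random_series <- function(n_cells = 4, n = 2000, T_ = 1,
                                 n_harm = 3) {
  mesh <- synth_tube_mesh(0.01, 0.004 * n_cells, 3)
  ncell <- nrow(mesh$triangles)
  tt <- seq(0, T_, length.out = n + 1)[1:n]
  wss <- array(0, dim = c(n, ncell, 3))
  coef <- array(stats::rnorm(ncell * 3 * (2 * n_harm + 1), sd = 0.5),
                dim = c(ncell, 3, 2 * n_harm + 1))
  basis <- cbind(1, sapply(1:n_harm, function(k) cos(2 * pi * k * tt / T_)),
                 sapply(1:n_harm, function(k) sin(2 * pi * k * tt / T_)))
  for (cmp in 1:3) wss[, , cmp] <- basis %*% t(coef[, cmp, ])
  list(series = wss_series(mesh, tt, wss, T_), coef = coef, basis_n = n_harm)
}

# Independent fine-quadrature oracle for TAWSS/OSI of an arbitrary smooth
# vector function of time (midpoint rule at n_fine points; written without
# the package's quadrature helpers).
oracle_indices <- function(fun, T_, n_fine = 2e5) {
  tq <- (seq_len(n_fine) - 0.5) * T_ / n_fine
  v <- fun(tq)                      # n_fine x 3
  mag <- sqrt(rowSums(v^2))
  tawss <- mean(mag)
  vint <- colMeans(v)
  osi <- 0.5 * (1 - sqrt(sum(vint^2)) / mean(mag))
  list(tawss = tawss, osi = osi)
}
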