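test_that("no plasma and zero initial condition stays identically zero", {
  geom <- centred_tumour_1d(nx = 15, diameter_cm = 4)
  p <- baseline_parameters()
  C <- solve_transport(solve_pressure(geom, p), p, plasma_model(a = 0, b = 1e-5),
                       geom, seq(0, 3600 * 10, length.out = 11))
  expect_equal(max(abs(C$values)), 0)
})

test_that("uniform pressure reduces to the scalar ODE closed form", {
  # dC/dt = beta a e^{-bt} - kd C with beta = LpS_V (P_v - P)(1 - sigma):
  # C(t) = beta a (e^{-bt} - e^{-kd t}) / (kd - b)
  p <- baseline_parameters()
  geom <- tumour_geometry(pde_grid(7, 0.1), rep(TRUE, 7))
  pl <- plasma_model(a = 7, half_life_h = 24)
  Pi <- 10
  tg <- seq(0, 200 * 3600, length.out = 4001)
  C <- solve_transport(rep(Pi, 7), p, pl, geom, tg)
  beta <- p$LpS_V_T * (p$P_v - Pi) * (1 - p$sigma_T)
  exact <- beta * pl$a * (exp(-pl$b * tg) - exp(-p$kd_T * tg)) / (p$kd_T - pl$b)
  expect_equal(C$values[4, 4001], exact[4001], tolerance = 1e-6)
  # uniformity is preserved (no spurious fluxes)
  expect_lt(diff(range(C$values[, 4001])), 1e-14 * exact[4001])
})

test_that("Crank-Nicolson converges at second order in the time step", {
  p <- baseline_parameters()
  geom <- tumour_geometry(pde_grid(5, 0.1), rep(TRUE, 5))
  pl <- plasma_model(a = 7, half_life_h = 24)
  tf <- 200 * 3600
  ref <- solve_transport(rep(10, 5), p, pl, geom, seq(0, tf, length.out = 16001))
  err <- sapply(c(101, 201), function(nt) {
    C <- solve_transport(rep(10, 5), p, pl, geom, seq(0, tf, length.out = nt))
    abs(C$values[3, nt] - ref$values[3, 16001])
  })
  expect_equal(err[1] / err[2], 4, tolerance = 0.15)
})

test_that("mass is conserved without elimination or source", {
  set.seed(9)
  geom <- centred_tumour_1d(nx = 40, diameter_cm = 4)
  p <- unclass(baseline_parameters()); p$kd_N <- p$kd_T <- 0
  p <- do.call(tissue_parameters, p)
  P <- solve_pressure(geom, p)
  C0 <- runif(40)
  C <- solve_transport(P, p, plasma_model(a = 0, b = 0), geom,
                       seq(0, 3600 * 100, length.out = 41), C0 = C0)
  drift <- abs(colSums(C$values) - sum(C0)) / sum(C0)
  expect_lt(max(drift), 1e-10)
})

test_that("proportional noise has the contracted statistics", {
  u <- rep(10, 1e4)
  expect_identical(add_noise(u, 0, seed = 1), u)
  n1 <- add_noise(u, 0.05, seed = 42)
  n2 <- add_noise(u, 0.05, seed = 42)
  expect_identical(n1, n2)
  s <- sd(n1 / u - 1)
  expect_lt(abs(s - 0.05) / 0.05, 0.03)
  # negative draws are clipped at zero
  tiny <- add_noise(rep(1, 1000), 5, seed = 1)
  expect_gte(min(tiny), 0)
  expect_error(add_noise(u, -0.1), ">= 0")
})

test_that("snapshot extraction honours times, noise and the mask", {
  case <- baseline_case(noise_level = 0, seed = 1)
  # zero noise reproduces the solver output exactly
  pair <- make_snapshots(case$conc, case$geom, 0, 200 * 3600, noise_level = 0)
  expect_identical(pair$u2, case$conc$values[, 150])
  expect_equal(max(abs(pair$u1)), 0)  # starts from a zero image
  # the accumulated drug concentrates around the tumour: the transvascular
  # source is only active at the tumour rim (the core sits at P_v), and the
  # slower normal-tissue elimination pushes the peak just outside the
  # boundary, so the tumour + 1 cm shell dwarfs the far field
  x <- grid_coords(case$geom$grid)[, 1]
  near <- abs(x - 5) <= 2
  far <- abs(x - 5) > 4
  expect_gt(mean(pair$u2[near]), 10 * mean(pair$u2[far]))
  expect_lt(min(abs(x[which.max(pair$u2)] - x[case$geom$mask])), 1)
  expect_error(make_snapshots(case$conc, case$geom, 3600, 3600), "greater")
  expect_error(make_snapshots(case$conc, case$geom, 0, 12345), "not a sampled")
})
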