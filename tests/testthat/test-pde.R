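test_that("grid validation enforces minimum resolution", {
  expect_error(pde_grid(n1 = 10), "at least 20")
  expect_error(pde_grid(dt = -1), "dt")
  expect_error(pde_grid(t_end = 0), "t_end")
})

test_that("reservoir solution approaches the closed-form steady flux", {
  sol <- solve_pde(metoprolol())
  fs <- flux_series(sol)
  jss <- steady_state_flux(metoprolol())
  expect_equal(fs$flux_ug_cm2_h[nrow(fs)], jss, tolerance = 5e-3)
  # flux starts at zero (drug-free skin) and rises monotonically
  expect_equal(fs$flux_ug_cm2_h[1], 0, tolerance = 1e-10)
  expect_true(all(diff(fs$flux_ug_cm2_h) >= -1e-8 * jss))
  # 98% of steady state at the response time
  f86 <- stats::approx(fs$time_h, fs$flux_ug_cm2_h, 8.60)$y
  expect_equal(f86 / jss, 0.98, tolerance = 5e-3)
})

test_that("matrix solution conserves mass and releases the full dose", {
  sol <- solve_pde(ata())
  # discrete mass balance: released + in layers = initial, exactly
  expect_equal(
    sol$cumulative + sol$mass_in_layers,
    rep(sol$mass_in_layers[1], length(sol$times)),
    tolerance = 1e-10
  )
  # discrete initial mass equals the loaded dose to the quadrature error
  expect_equal(sol$mass_in_layers[1], total_releasable(ata()),
    tolerance = 1e-3
  )
  cs <- cumulative_series(sol)
  expect_true(all(diff(cs$cumulative_ug) >= -1e-8))
  expect_equal(cs$fraction[nrow(cs)], 1, tolerance = 2e-3)
  # matrix flux rises then decays toward zero
  fl <- sol$flux
  pk <- which.max(fl)
  expect_gt(pk, 1)
  expect_lt(fl[length(fl)], 0.05 * fl[pk])
  expect_true(all(fl >= -1e-9 * max(fl)))
})

test_that("fraction at the published release time matches the inversion route", {
  sol <- solve_pde(ata())
  cs <- cumulative_series(sol)
  f461 <- stats::approx(cs$time_h, cs$fraction, 461.4)$y
  expect_equal(f461, 0.98, tolerance = 5e-3)
  lap <- fraction_profile(ata(), times = 461.4)$fraction
  expect_equal(f461, lap, tolerance = 5e-3)
})

test_that("identical-layer flux matches the single-slab analytic series", {
  # km = 1, D1 = D2, la = lb: one slab of thickness L = 2 lb with constant
  # source and perfect sink; j(t)/j_ss = 1 + 2 sum (-1)^n exp(-n^2 pi^2 D t/L^2)
  dev <- tdds_device("reservoir",
    D1 = 1e-6, D2 = 1e-6, la = 0.05, lb = 0.05,
    km = 1, C0 = 1000, time_unit = "s"
  )
  sol <- solve_pde(dev, grid = pde_grid(n1 = 120, n2 = 120, nt = 4000))
  jss <- steady_state_flux(dev)
  uh <- 1 / 3600
  slab_ratio <- function(t_s) {
    th <- 1e-6 * t_s / (0.1)^2
    n <- 1:80
    1 + 2 * sum((-1)^n * exp(-n^2 * pi^2 * th))
  }
  fs <- flux_series(sol)
  for (frac_t in c(0.2, 0.4, 0.7, 1)) {
    t_s <- frac_t * max(sol$times)
    got <- stats::approx(fs$time_h, fs$flux_ug_cm2_h, t_s * uh)$y / jss
    expect_equal(got, slab_ratio(t_s), tolerance = 2e-3)
  }
  # 98% crossing at 4 * (7/15) * lb^2/D2 within 2%
  t98 <- fs$time_h[which(fs$flux_ug_cm2_h / jss >= 0.98)[1]]
  expect_equal(t98, 4 * (7 / 15) * 0.05^2 / 1e-6 / 3600, tolerance = 0.02)
})

test_that("refining the grid changes the solution at second order", {
  dev <- ata()
  coarse <- solve_pde(dev, grid = pde_grid(n1 = 40, n2 = 40, nt = 500,
    t_end = 500))
  fine <- solve_pde(dev, grid = pde_grid(n1 = 80, n2 = 80, nt = 1000,
    t_end = 500))
  t_probe <- 250
  fc <- stats::approx(coarse$times, coarse$cumulative, t_probe)$y
  ff <- stats::approx(fine$times, fine$cumulative, t_probe)$y
  expect_equal(fc, ff, tolerance = 1e-3)
  # halving dx and dt again moves the answer by far less (convergence)
  finest <- solve_pde(dev, grid = pde_grid(n1 = 160, n2 = 160, nt = 2000,
    t_end = 500))
  f3 <- stats::approx(finest$times, finest$cumulative, t_probe)$y
  expect_lt(abs(ff - f3), abs(fc - ff))
})

test_that("reservoir first moment agrees with the effective time constant", {
  sol <- solve_pde(metoprolol(), grid = pde_grid(window = 14))
  expect_equal(
    tdds:::pde_effective_time(sol),
    time_constants(metoprolol())$t_eff_h,
    tolerance = 5e-3
  )
})
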