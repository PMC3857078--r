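test_that("flux profile reproduces the published dynamic values", {
  prof <- flux_profile(metoprolol(), times = c(8.60, 100))
  expect_equal(prof$flux_ug_cm2_h[1], 77.62, tolerance = 0.01)
  expect_equal(prof$flux_ug_cm2_h[2], 79.2, tolerance = 0.005)
  expect_identical(attr(prof, "provenance"), "laplace_inversion")
})

test_that("fraction profile reproduces the published release point", {
  prof <- fraction_profile(ata(), times = c(461.4))
  expect_equal(prof$fraction, 0.98, tolerance = 0.0102)
  expect_equal(prof$cumulative_ug, 0.98 * 28000, tolerance = 0.011)
  # A = 1.786 cm^2 scales the released amount to ~49,000 ug
  dev <- ata()
  dev$A <- 1.786
  expect_equal(fraction_profile(dev, times = 461.4)$cumulative_ug,
    49000,
    tolerance = 0.015
  )
})

test_that("device kinds are routed to the right profile function", {
  expect_error(flux_profile(ata(), 1), "fraction_profile")
  expect_error(fraction_profile(metoprolol(), 1), "flux_profile")
  expect_error(flux_profile(metoprolol(), numeric(0)), "positive")
  expect_error(flux_profile(metoprolol(), c(1, -1)), "positive")
})

test_that("flux is linear in the donor concentration", {
  t <- c(1, 4, 12)
  base <- flux_profile(metoprolol(), t)
  dev2 <- metoprolol()
  dev2$C0 <- 2 * dev2$C0
  doubled <- flux_profile(dev2, t)
  expect_equal(doubled$flux_ug_cm2_h, 2 * base$flux_ug_cm2_h,
    tolerance = 1e-10
  )
})

test_that("profiles vanish at early dimensionless times", {
  early <- fraction_profile(ata(), times = 1e-6)
  expect_equal(early$fraction, 0)
  expect_lt(flux_profile(metoprolol(), times = 0.05)$flux_ug_cm2_h, 1e-6)
})

test_that("laplace and pde profiles agree on both devices", {
  # reservoir flux for t >= 0.05 t_eff, matrix fraction on log-spaced times
  tc1 <- time_constants(metoprolol())$t_eff_h
  t1 <- 10^seq(log10(0.05 * tc1), log10(12 * tc1), length.out = 30)
  lap <- flux_profile(metoprolol(), t1)
  pde <- flux_profile(metoprolol(), t1,
    method = "pde",
    grid = pde_grid(nt = 6000, t_end = 12 * tc1 * 3600)
  )
  jss <- steady_state_flux(metoprolol())
  expect_lt(max(abs(lap$flux_ug_cm2_h - pde$flux_ug_cm2_h)) / jss, 0.01)
  expect_identical(attr(pde, "provenance"), "pde_oracle")

  tc2 <- time_constants(ata())$t_eff_h
  t2 <- 10^seq(log10(0.02 * tc2), log10(10 * tc2), length.out = 30)
  lap2 <- fraction_profile(ata(), t2)
  pde2 <- fraction_profile(ata(), t2,
    method = "pde",
    grid = pde_grid(nt = 6000, t_end = 10 * tc2)
  )
  expect_lt(max(abs(lap2$fraction - pde2$fraction)), 0.01)
})

test_that("flux at the response time sits at the 98% convention", {
  tc <- time_constants(metoprolol())
  ratio <- flux_profile(metoprolol(), tc$response_time_h)$flux_ug_cm2_h /
    tc$steady_flux
  expect_gt(ratio, 0.975)
  expect_lt(ratio, 0.985)
})

test_that("time_to_fraction inverts the release curve", {
  t98 <- time_to_fraction(ata(), 0.98)
  expect_equal(t98, 461.4, tolerance = 0.02)
  # round trip
  expect_equal(fraction_profile(ata(), t98)$fraction, 0.98, tolerance = 1e-3)
  # monotone in the target
  expect_lt(time_to_fraction(ata(), 0.5), time_to_fraction(ata(), 0.9))
  # 63.2% near t_eff under the first-order analogy (loose, not exact)
  t632 <- time_to_fraction(ata(), 0.632)
  expect_equal(t632, time_constants(ata())$t_eff_h, tolerance = 0.15)
  expect_error(time_to_fraction(ata(), 1.2), "between 0 and 1")
  expect_error(time_to_fraction(metoprolol(), 0.5), "matrix")
})

test_that("elasticities satisfy the joint time-scaling sum rule", {
  for (dev in list(metoprolol(), ata())) {
    el <- teff_sensitivity(dev)
    dsum <- sum(el$elasticity[el$parameter %in% c("D1", "D2")])
    expect_equal(dsum, -1, tolerance = 1e-6)
  }
  expect_error(teff_sensitivity(ata(), parameters = "Q"), "unknown parameter")
})

test_that("elasticities reach the skin-controlled limits", {
  # beta -> 0 with moderate km: t_eff ~ lb^2/D2, so D2 -> -1 and lb -> +2
  dev <- device_from_groups(1e-6, 1e3, 1, kind = "reservoir")
  el <- teff_sensitivity(dev)
  expect_equal(el$elasticity[el$parameter == "D2"], -1, tolerance = 5e-3)
  expect_equal(el$elasticity[el$parameter == "lb"], 2, tolerance = 5e-3)
})
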