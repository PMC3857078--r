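test_that("device validation rejects non-positive parameters by name", {
  expect_error(
    tdds_device("reservoir", D1 = 0, D2 = 1, la = 1, lb = 1, km = 1, C0 = 1),
    "'D1'"
  )
  expect_error(
    tdds_device("reservoir", D1 = 1, D2 = 1, la = 1, lb = -2, km = 1, C0 = 1),
    "'lb'"
  )
  expect_error(
    tdds_device("matrix", D1 = 1, D2 = 1, la = 1, lb = 1, km = NA, C0 = 1),
    "'km'"
  )
  # zero concentration is allowed (no driving force), negative is not
  expect_silent(
    tdds_device("reservoir", D1 = 1, D2 = 1, la = 1, lb = 1, km = 1, C0 = 0)
  )
  expect_error(
    tdds_device("reservoir", D1 = 1, D2 = 1, la = 1, lb = 1, km = 1, C0 = -1),
    "'C0'"
  )
})

test_that("bundled fixtures carry the literature parameter values", {
  res <- metoprolol()
  expect_identical(res$kind, "reservoir")
  expect_equal(res$D1, 4.4e-5)
  expect_equal(res$D2, 2.2e-8)
  expect_equal(res$la, 0.12)
  expect_equal(res$lb, 0.038)
  expect_equal(res$km, 1)
  expect_equal(res$C0, 38000) # 0.038 g/cm^3 in ug/cm^3

  mat <- ata()
  expect_identical(mat$kind, "matrix")
  expect_equal(mat$km, 7.81e-3)
  expect_equal(mat$C0, 50000)
  expect_equal(mat$la, 0.56)
  expect_equal(mat$lb, 0.005)
  expect_identical(mat$time_unit, "h")
})

test_that("dimensionless groups satisfy beta*p = lb/la to machine precision", {
  trips <- random_triples(20, seed = 101)
  for (i in seq_len(nrow(trips))) {
    dev <- device_from_groups(trips$beta[i], trips$p[i], trips$km[i])
    g <- dimensionless_groups(dev)
    expect_equal(g$beta * g$p, dev$lb / dev$la, tolerance = 1e-14)
  }
  g <- dimensionless_groups(metoprolol())
  expect_equal(g$beta * g$p, 0.038 / 0.12, tolerance = 1e-14)
})

test_that("identical layers give beta = p = 1", {
  dev <- tdds_device("reservoir",
    D1 = 2, D2 = 2, la = 0.5, lb = 0.5,
    km = 1, C0 = 1
  )
  g <- dimensionless_groups(dev)
  expect_equal(g$beta, 1)
  expect_equal(g$p, 1)
})

test_that("steady flux: closed form, zero-C0 case, and kind guard", {
  expect_equal(steady_state_flux(metoprolol()), 79.0751,
    tolerance = 1e-4
  )
  dev0 <- tdds_device("reservoir",
    D1 = 1, D2 = 1, la = 1, lb = 1,
    km = 1, C0 = 0
  )
  expect_equal(steady_state_flux(dev0), 0)
  expect_error(steady_state_flux(ata()), "matrix")
  expect_error(total_releasable(metoprolol()), "reservoir")
})

test_that("steady flux is invariant under the declared time unit", {
  res_s <- metoprolol()
  res_h <- tdds_device("reservoir",
    D1 = res_s$D1 * 3600, D2 = res_s$D2 * 3600,
    la = res_s$la, lb = res_s$lb, km = res_s$km, C0 = res_s$C0,
    time_unit = "h"
  )
  expect_equal(steady_state_flux(res_h), steady_state_flux(res_s),
    tolerance = 1e-12
  )
  expect_equal(time_constants(res_h)$t_eff_h, time_constants(res_s)$t_eff_h,
    tolerance = 1e-12
  )
})

test_that("steady flux decreases with skin thickness and skin resistance", {
  base <- metoprolol()
  lbs <- seq(0.01, 0.1, length.out = 8)
  flux <- vapply(lbs, function(lb) {
    d <- base
    d$lb <- lb
    steady_state_flux(d)
  }, numeric(1))
  expect_true(all(diff(flux) < 0))
  kms <- c(0.5, 1, 2, 5)
  fk <- vapply(kms, function(km) {
    d <- base
    d$km <- km
    steady_state_flux(d)
  }, numeric(1))
  expect_true(all(diff(fk) < 0))
})

test_that("total releasable mass is A * la * C0", {
  expect_equal(total_releasable(ata()), 0.56 * 50000)
  unit <- tdds_device("matrix", D1 = 1, D2 = 1, la = 1, lb = 1, km = 1, C0 = 1)
  expect_equal(total_releasable(unit), 1)
})
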