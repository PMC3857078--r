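# the closed-form transforms are re-derived independently by solving the
# Laplace-domain two-layer boundary-value problem as a 4x4 linear system at
# each sampled s (tdds:::two_layer_bvp_flux) and compared pointwise

sample_s <- 10^seq(-2, 1.5, length.out = 20)

test_that("reservoir flux transform matches the boundary-value derivation", {
  trips <- random_triples(6, seed = 7)
  for (i in seq_len(nrow(trips))) {
    g <- tdds_groups(trips$beta[i], trips$p[i], trips$km[i])
    tf <- flux_transform(g)
    for (s in sample_s) {
      bvp <- tdds:::two_layer_bvp_flux(g, "reservoir", s)
      expect_equal(Re(eval_tf(tf, s)), Re(bvp$flux), tolerance = 1e-10)
      # interface conditions of the reconstructed solution hold exactly
      expect_lt(max(bvp$residual_interface), 1e-10 * abs(bvp$flux))
    }
  }
})

test_that("matrix fraction transform matches the boundary-value derivation", {
  trips <- random_triples(6, seed = 8)
  for (i in seq_len(nrow(trips))) {
    g <- tdds_groups(trips$beta[i], trips$p[i], trips$km[i])
    tf <- fraction_transform(g)
    for (s in sample_s) {
      bvp <- tdds:::two_layer_bvp_flux(g, "matrix", s)
      # fraction transform = beta p / s * (dimensionless flux transform)
      expect_equal(Re(eval_tf(tf, s)),
        Re(g$beta * g$p * bvp$flux / s),
        tolerance = 1e-10
      )
    }
  }
})

test_that("flux ratio reduces to the single-slab transform for identical layers", {
  g <- tdds_groups(1, 1, 1)
  tf <- flux_ratio_transform(g)
  # one slab of dimensionless thickness 2: 2 / (sqrt(s) sinh(2 sqrt(s)))
  for (s in sample_s) {
    expect_equal(Re(eval_tf(tf, s)),
      Re(2 / (sqrt(s) * sinh(2 * sqrt(s)))),
      tolerance = 1e-12
    )
  }
})

test_that("small-s limits recover the steady states", {
  gm <- dimensionless_groups(metoprolol())
  expect_equal(final_value(flux_ratio_transform(gm)), 1, tolerance = 1e-8)
  expect_equal(final_value(flux_transform(gm)), 1 / (gm$km + gm$beta),
    tolerance = 1e-8
  ) # ~0.99842
  ga <- dimensionless_groups(ata())
  # cumulative scaled by A lb C0 tends to la/lb = 112 for the ATA geometry
  expect_equal(final_value(cumulative_transform(ga)), 0.56 / 0.005,
    tolerance = 1e-7
  )
  expect_equal(final_value(cumulative_transform(tdds_groups(1, 1, 2))), 1,
    tolerance = 1e-8
  ) # equal thicknesses
  g2 <- tdds_groups(0.5, 2, 3)
  expect_equal(final_value(fraction_transform(g2)), 1, tolerance = 1e-8)
})

test_that("mass conservation: fraction transform has unit final value on a sweep", {
  trips <- random_triples(10, seed = 12)
  for (i in seq_len(nrow(trips))) {
    tf <- fraction_transform(tdds_groups(trips$beta[i], trips$p[i], trips$km[i]))
    expect_equal(final_value(tf), 1, tolerance = 1e-7)
  }
})

test_that("series deficit agrees with direct subtraction away from s = 0", {
  trips <- random_triples(8, seed = 5)
  for (i in seq_len(nrow(trips))) {
    g <- tdds_groups(trips$beta[i], trips$p[i], trips$km[i])
    for (tf in list(flux_ratio_transform(g), fraction_transform(g))) {
      for (s in c(0.03, 0.3 + 0.2i, 1.7)) {
        direct <- tf$steady_state / s - eval_tf(tf, s)
        expect_equal(tf$deficit(s), direct, tolerance = 1e-10)
      }
    }
  }
})

test_that("stable exponential scaling survives huge |s| without overflow", {
  gm <- dimensionless_groups(metoprolol())
  big <- eval_tf(flux_ratio_transform(gm), 4e6 + 0i)
  expect_true(is.finite(Mod(big)))
  expect_lt(Mod(big), 1e-300) # transcendentally small, not NaN
  frac <- eval_tf(fraction_transform(dimensionless_groups(ata())), 1e6 + 0i)
  expect_true(is.finite(Mod(frac)))
})
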