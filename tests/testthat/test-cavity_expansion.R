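fric05 <- friction_params(mu = 0.5)

test_that("resistance-force conversion uses the cone base area", {
  p <- steel_probe()
  expect_equal(resistance_from_force(0, p), 0)
  expect_equal(resistance_from_force(15.51, p), 15.51 / (pi * 2.5^2))
  expect_equal(resistance_from_force(15.51, p), 0.79, tolerance = 1e-3)
  expect_equal(force_from_resistance(0.67, p), 0.67 * pi * 2.5^2)
  expect_equal(force_from_resistance(0.67, p), 13.16, tolerance = 1e-3)
})

test_that("stationary radial stress inverts the force balance", {
  p <- steel_probe()
  sig <- radial_stress_stationary(15.51, p, fric05)
  expect_equal(sig, 15.51 / (pi * 2.5^2 * (1 + 0.5 / tan(15 * pi / 180))),
               tolerance = 1e-12)
  expect_equal(sig, 0.276, tolerance = 2e-3)
  # frictionless limit: sigma equals mechanical resistance
  expect_equal(radial_stress_stationary(15.51, p, friction_params(0)),
               resistance_from_force(15.51, p))
  # linearity
  expect_equal(radial_stress_stationary(2 * 15.51, p, fric05), 2 * sig)
})

test_that("stationary decomposition satisfies the exact force identities", {
  p <- steel_probe()
  sig <- radial_stress_stationary(15.51, p, fric05)
  dec <- stationary_decomposition(sig, p, fric05)
  expect_equal(dec$Fc_s, 5.41, tolerance = 1e-2)
  expect_equal(dec$Fr_s, 20.2, tolerance = 1e-2)
  expect_equal(dec$Ff_s, 10.10, tolerance = 1e-2)
  # composing with the inversion recovers the measured force exactly
  expect_equal(dec$Fz, 15.51, tolerance = 1e-12)
  expect_equal(dec$Fz, dec$Fc_s + dec$Ff_s, tolerance = 1e-14)
  # frictionless: no friction force
  dec0 <- stationary_decomposition(sig, p, friction_params(0))
  expect_equal(dec0$Ff_s, 0)
  expect_equal(dec0$Fz, dec0$Fc_s)
})

test_that("orbital radial force scales with deflection and stiffness", {
  expect_equal(orbital_radial_force(0, steel_probe()), 0)
  expect_equal(orbital_radial_force(0.30, brass_probe()), 0.888)
  expect_equal(orbital_radial_force(0.30, steel_probe()), 2.088)
})

test_that("radial force distribution respects the asymmetry constraint", {
  expect_equal(radial_force_distribution(20.2, 0.888, pi / 2), 20.2)
  expect_equal(radial_force_distribution(20.2, 0.888, 0), 20.2 + 0.888)
  expect_equal(radial_force_distribution(20.2, 0.888, pi), 20.2 - 0.888)
  expect_error(radial_force_distribution(1, 2, 0), "asymmetry constraint")
  # circumferential mean equals Fr,s (quadrature)
  for (Fro in c(0, 0.5, 5, 20.2)) {
    m <- integrate(function(g) radial_force_distribution(20.2, Fro, g),
                   0, 2 * pi, rel.tol = 1e-12)$value / (2 * pi)
    expect_equal(m, 20.2, tolerance = 1e-9)
    expect_true(all(radial_force_distribution(
      20.2, Fro, seq(0, 2 * pi, length.out = 181)) >= 0))
  }
})

test_that("moving friction is the residual over the stationary cavity force", {
  expect_equal(moving_friction(15.51, 5.41), 10.10, tolerance = 1e-12)
  expect_equal(moving_friction(13.16, 5.41), 7.75, tolerance = 1e-2)
  expect_equal(moving_friction(5.41, 5.41), 0)
  expect_warning(out <- moving_friction(5, 5.41), "negative friction")
  expect_lt(out, 0)
})

test_that("friction rescaling is exact at the anchor points and affine", {
  p <- steel_probe()
  sig <- radial_stress_stationary(15.51, p, fric05)
  dec <- stationary_decomposition(sig, p, fric05)
  fr <- friction_params(0.5, c(0, 0.1, 0.3, 0.5))
  out <- friction_rescale(15.51, fr, p, dec$Fc_s)
  # identity at mu' = mu, cavity-expansion limit at mu' = 0
  expect_equal(out$Fz_prime[out$mu_prime == 0.5], 15.51, tolerance = 1e-12)
  expect_equal(out$Ff_prime[out$mu_prime == 0.5], dec$Ff_s,
               tolerance = 1e-12)
  expect_equal(out$Fz_prime[out$mu_prime == 0], dec$Fc_s, tolerance = 1e-12)
  expect_equal(out$Fz_prime[out$mu_prime == 0.1], 15.51 *
                 (1 + 0.1 / tan(15 * pi / 180)) /
                 (1 + 0.5 / tan(15 * pi / 180)), tolerance = 1e-12)
  expect_equal(out$Fz_prime[out$mu_prime == 0.1], 7.43, tolerance = 1e-2)
  # strictly increasing and affine in mu'
  d1 <- diff(out$Fz_prime)
  expect_true(all(d1 > 0))
  slopes <- d1 / diff(out$mu_prime)
  expect_equal(max(slopes) - min(slopes), 0, tolerance = 1e-10)
})

test_that("asymmetry and circumnutation-intensity indices stay in range", {
  expect_equal(asymmetry_index(0, 20.2), 0)
  expect_equal(asymmetry_index(20.2, 20.2), 1)
  expect_equal(asymmetry_index(0.888, 20.2), 0.044, tolerance = 1e-2)
  expect_error(asymmetry_index(21, 20.2), "asymmetry constraint")
  expect_equal(circumnutation_intensity(0.044, 0, 10), 0)
  expect_equal(circumnutation_intensity(0.044, 10, 10), 0.044)
  expect_equal(circumnutation_intensity(0.044, 5, 10), 0.022)
  expect_error(circumnutation_intensity(0.044, 11, 10), "exceeds fmax")
})

test_that("treatment-table decomposition pairs moving rows with their material", {
  probes <- list(steel = steel_probe(), brass = brass_probe())
  tr <- data.frame(
    material = c("steel", "steel", "brass", "brass"),
    f = c(0, 10, 0, 10),
    Fz_N = c(15.51, 13.16, 15.51, 13.16),
    delta_c_mm = c(0, 0.30, 0, 0.30))
  out <- decompose_forces(tr, probes, fric05)
  expect_equal(nrow(out), 4)
  # conservation for every row
  expect_equal(out$Fz_N, out$Fc_s_N + out$Ff_N, tolerance = 1e-12)
  # stiffer shaft gives larger Fro hence larger asymmetry
  expect_gt(out$Iasym[out$material == "steel" & out$f == 10],
            out$Iasym[out$material == "brass" & out$f == 10])
  expect_equal(out$CI[out$f == 0], c(0, 0))
  expect_error(decompose_forces(tr[tr$f > 0, ], probes, fric05),
               "no stationary treatment")
})
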