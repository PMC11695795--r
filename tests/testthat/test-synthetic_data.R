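test_that("table-mode traces are exact at zero noise and reproducible", {
  cfg <- generator_config(noise_sd = 0, n_replicates = 2, seed = 4)
  sim <- gen_force_traces(cfg)
  probes <- config_probes(cfg)
  st <- sim$traces[sim$traces$material == "steel" & sim$traces$f == 0, ]
  expect_equal(unique(st$Fz_N), force_from_resistance(0.79, probes$steel))
  f10 <- sim$traces[sim$traces$material == "brass" & sim$traces$f == 10, ]
  expect_equal(unique(f10$Fz_N), force_from_resistance(0.67, probes$brass))
  # depth grid covers the full penetration at 1 Hz / 1 cm/h
  expect_equal(nrow(st), 2 * 3600)
  expect_lt(min(st$depth_mm), 0.01)
  expect_gt(max(st$depth_mm), 9.99)

  cfg2 <- generator_config(seed = 9)
  expect_identical(gen_force_traces(cfg2), gen_force_traces(cfg2))
  expect_false(identical(gen_force_traces(cfg2)$traces$Fz_N,
                         gen_force_traces(cfg2, seed = 10)$traces$Fz_N))
})

test_that("an incomplete treatment table is rejected", {
  tt <- default_treatment_table()
  tt$material[1] <- "titanium"
  expect_error(gen_force_traces(generator_config(treatment_table = tt)))
  expect_error(generator_config(treatment_table = tt[0, ]))
})

test_that("mechanistic stationary traces recover the calibration resistance", {
  cfg <- generator_config(mode = "mechanistic", seed = 21)
  sim <- gen_force_traces(cfg)
  probes <- config_probes(cfg)
  summ <- treatment_summary(sim$traces, probes)
  expect_equal(summ$Q_mean_MPa[summ$f == 0], c(0.79, 0.79),
               tolerance = 0.01)
  # ground truth carries the generating components
  gt <- sim$ground_truth
  expect_equal(length(gt), 8)
  sig <- vapply(gt, `[[`, numeric(1), "sigma_rs")
  expect_equal(unique(round(sig, 10)),
               round(radial_stress_stationary(
                 force_from_resistance(0.79, probes$steel), probes$steel,
                 friction_params(0.5)), 10))
  # friction attenuation makes moving Fz smaller than stationary
  Fz <- vapply(gt, `[[`, numeric(1), "Fz")
  f <- vapply(gt, `[[`, numeric(1), "f")
  expect_true(all(Fz[f > 0] < Fz[f == 0][1] + 1e-9))
})

test_that("deflection series invert the kinematics and round-trip exactly", {
  cfg <- generator_config(angle_noise_sd = 0, seed = 2)
  probes <- config_probes(cfg)
  ser <- gen_deflection_series(cfg, "brass", 10, delta_c_mm = 0.30)
  expect_equal(attr(ser, "delta_alpha_deg"), 0.764, tolerance = 1e-3)
  seg <- segment_oscillations(ser, 10)
  expect_equal(cone_deflection(seg, probes$brass), 0.30, tolerance = 1e-6)
  # flat series at zero deflection
  flat <- gen_deflection_series(cfg, "steel", 0)
  expect_equal(var(flat$angle_deg), 0)
  expect_error(gen_deflection_series(cfg, "steel", 1, delta_c_mm = 50),
               "exceeds shaft length")
  expect_error(gen_deflection_series(cfg, "steel", 2), "no deflection")
})

test_that("phantom porosity, determinism and degenerate cases behave", {
  pc <- small_phantom_config(halo_amplitude = 0)
  ph <- gen_ct_phantom(pc, seed = 31)
  # background porosity by construction, away from the imprint
  dm <- domain_mask(ph$binary)
  far <- array(circumpen:::cpp_edt3d(
    as.integer(ph$ground_truth$imprint_mask), dim(dm)), dim(dm)) > 12
  eps <- sum(ph$binary$values == 1L & dm & far &
               !ph$ground_truth$imprint_mask) / sum(dm & far)
  expect_equal(eps, 0.17, tolerance = 0.01)
  # identical seed, identical volume
  ph2 <- gen_ct_phantom(pc, seed = 31)
  expect_identical(ph$binary$values, ph2$binary$values)
  expect_false(identical(
    ph$binary$values, gen_ct_phantom(pc, seed = 32)$binary$values))
  # sub-voxel spheres are refused
  expect_error(gen_ct_phantom(small_phantom_config(sphere_radius_um = 10),
                              seed = 1),
               "porosity unreachable")
  # reference phantoms carry no imprint
  ref <- gen_ct_phantom(pc, reference = TRUE, seed = 31)
  expect_null(ref$ground_truth$imprint_mask)
  expect_equal(visible_porosity(ref$binary), 0.17, tolerance = 0.01)
})

test_that("grey phantoms segment back to approximately the binary truth", {
  pc <- phantom_config(domain_diameter_mm = 2.4, domain_height_mm = 2.4,
                       voxel_edge_um = 50, halo_amplitude = 0, grey = TRUE)
  ph <- gen_ct_phantom(pc, seed = 41)
  seg <- segment_pores(ph$grey, threshold = 120)
  agree <- mean(seg$values == ph$binary$values)
  expect_gt(agree, 0.9)
})
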