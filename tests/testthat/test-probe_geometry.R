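test_that("oscillation segmentation partitions the series by nominal frequency", {
  ser <- data.frame(time_min = seq_len(600) - 1, angle_deg = 0)
  seg <- segment_oscillations(ser, frequency = 10, depth_cm = 1)
  expect_identical(attr(seg, "R"), 10L)
  expect_equal(unname(table(seg$oscillation)), rep(60L, 10),
               ignore_attr = TRUE)

  seg1 <- segment_oscillations(data.frame(time_min = 0:59, angle_deg = 0),
                               frequency = 1)
  expect_identical(attr(seg1, "R"), 1L)
  expect_true(all(seg1$oscillation == 1L))

  seg0 <- segment_oscillations(data.frame(time_min = 0:59, angle_deg = 0),
                               frequency = 0)
  expect_identical(attr(seg0, "R"), 0L)
  expect_true(all(is.na(seg0$oscillation)))
})

test_that("segmentation rejects series shorter than one oscillation", {
  ser <- data.frame(time_min = 0:9, angle_deg = 0)
  expect_error(segment_oscillations(ser, frequency = 1, depth_cm = 0.1),
               "incomplete oscillation")
  expect_error(segment_oscillations(
    data.frame(time_min = c(0, 0), angle_deg = 0), 1), "increasing")
})

test_that("cone deflection matches hand-evaluated values", {
  p <- steel_probe()
  expect_equal(cone_deflection(0, p), 0)
  # 45 * sin(0.382 deg) for a single oscillation of range 0.764 deg
  da <- 2 * asin(0.30 / 45) * 180 / pi
  expect_equal(cone_deflection(da, p), 0.30, tolerance = 1e-12)
  expect_equal(45 * sin(0.764 / 2 * pi / 180), 0.3000199,
               tolerance = 1e-6)
  # invariance under replication of identical oscillations
  expect_equal(cone_deflection(rep(da, 10), p), cone_deflection(da, p))
  expect_error(cone_deflection(numeric(0), p), "no oscillations")
})

test_that("amplitude is orbit radius minus deflection, within bounds", {
  p <- brass_probe()
  expect_equal(circumnutation_amplitude(0.30, p), 0.70)
  expect_equal(circumnutation_amplitude(0, p), 1.0)
  expect_equal(circumnutation_amplitude(0.19, p), 0.81)
  expect_error(circumnutation_amplitude(1.2, p), "exceeds orbit radius")
})

test_that("axial force correction and relative error follow the geometry", {
  da <- 2 * asin(0.30 / 45) * 180 / pi
  expect_equal(axial_force_correction(15.51, 0), 15.51)
  Fa <- axial_force_correction(15.51, da)
  expect_equal(Fa / 15.51, 1 / cos(asin(0.30 / 45)), tolerance = 1e-12)
  expect_true(Fa >= 15.51)
  # two oscillations [da, 0]: correction between the single-angle cases
  mid <- axial_force_correction(15.51, c(da, 0))
  expect_true(mid > 15.51 && mid < Fa)
  expect_equal(relative_force_error(15.51, 15.51), 0)
  # cancellation in (Fa - Fz)/Fz limits agreement to ~1e-11 relative
  expect_equal(relative_force_error(Fa, 15.51),
               (1 / cos(asin(0.30 / 45)) - 1) * 100, tolerance = 1e-9)
  expect_error(relative_force_error(1, 0), "positive")
})

test_that("erel increases strictly with any oscillation range", {
  base <- c(0.3, 0.5, 0.7)
  e0 <- relative_force_error(axial_force_correction(1, base), 1)
  for (i in seq_along(base)) {
    up <- base
    up[i] <- up[i] + 0.1
    expect_gt(relative_force_error(axial_force_correction(1, up), 1), e0)
  }
  expect_equal(relative_force_error(axial_force_correction(1, c(0, 0)), 1), 0)
})

test_that("noise-free synthetic series round-trips the target deflection", {
  p <- steel_probe()
  for (f in c(1, 5, 10)) {
    for (dc in c(0.1, 0.22, 0.30)) {
      ser <- angle_series_for(dc, f = f)
      seg <- segment_oscillations(ser, frequency = f)
      expect_equal(cone_deflection(seg, p), dc, tolerance = 1e-6)
    }
  }
})

test_that("deflection summary reports stationary treatments as missing amplitude", {
  p <- steel_probe()
  seg0 <- segment_oscillations(data.frame(time_min = 0:59, angle_deg = 0.5),
                               frequency = 0)
  s <- deflection_summary(seg0, p)
  expect_equal(s$delta_c_mm, 0)
  expect_true(is.na(s$amplitude_mm))
  expect_identical(s$R, 0L)

  seg <- segment_oscillations(angle_series_for(0.3, f = 5), frequency = 5)
  s <- deflection_summary(seg, p)
  expect_equal(s$delta_c_mm, 0.3, tolerance = 1e-6)
  expect_equal(s$amplitude_mm, 0.7, tolerance = 1e-6)
  expect_identical(s$R, 5L)
})

test_that("angle series CSV round-trips through the reader", {
  df <- data.frame(time_min = 0:3, angle_deg = c(0, 0.1, 0, -0.1),
                   replicate = 1L, treatment = "steel_f1")
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  expect_equal(read_angle_series(f), df)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df[1:2], f2, row.names = FALSE)
  expect_error(read_angle_series(f2), "columns")
})
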