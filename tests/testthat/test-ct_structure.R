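test_that("connected-component labelling matches the flood-fill oracle", {
  set.seed(42)
  for (conn in c(6, 26)) {
    for (rep_i in 1:10) {
      d <- sample(3:20, 3, replace = TRUE)
      dens <- runif(1, 0.1, 0.7)
      mask <- array(as.integer(runif(prod(d)) < dens), d)
      got <- canonical_labels(label_components(mask, connectivity = conn))
      want <- canonical_labels(flood_fill_oracle(mask, connectivity = conn))
      expect_identical(got, want)
    }
  }
  # 26-connectivity joins diagonals that 6-connectivity separates
  m <- array(0L, c(2, 2, 2)); m[1, 1, 1] <- 1L; m[2, 2, 2] <- 1L
  expect_equal(max(label_components(m, 26)), 1)
  expect_equal(max(label_components(m, 6)), 2)
})

test_that("global-threshold segmentation recovers a constructed binary exactly", {
  set.seed(7)
  d <- c(20, 24, 24)
  truth <- array(as.integer(runif(prod(d)) < 0.2), d)
  grey <- array(ifelse(truth == 1L, 60, 180), d)
  vol <- voxel_volume(grey, 30, binary = FALSE)
  seg <- segment_pores(vol, threshold = 120)
  expect_identical(seg$values, truth)
  expect_warning(segment_pores(vol, threshold = 300), "no matrix")
  expect_warning(segment_pores(vol, threshold = 10), "no pore")
})

test_that("rim exclusion converts mm to voxels and shrinks the domain", {
  v12 <- voxel_volume(array(0L, c(4, 120, 120)), 12)
  expect_equal(v12$radius_vox - exclude_rim(v12, 0.6)$radius_vox, 50)
  v24 <- voxel_volume(array(0L, c(4, 120, 120)), 24)
  expect_equal(v24$radius_vox - exclude_rim(v24, 0.6)$radius_vox, 25)
  expect_identical(exclude_rim(v24, 0)$radius_vox, v24$radius_vox)
  expect_error(exclude_rim(v24, 10), "rim larger")
  # domain voxel count shrinks accordingly
  expect_lt(sum(domain_mask(exclude_rim(v12, 0.6))), sum(domain_mask(v12)))
})

test_that("pore metrics recover porosity and equivalent sphere diameter", {
  d <- c(40, 40, 40)
  region <- array(TRUE, d)
  empty <- array(0L, d)
  m <- pore_metrics(empty, region, voxel_edge_um = 10)
  expect_equal(m$visible_porosity, 0)
  expect_true(is.na(m$mean_pore_diameter_um))

  # single sphere of radius 10 voxels: equivalent diameter 20 voxels +- 5%
  cc <- 20.5
  idx <- which(array(TRUE, d))
  co <- arrayInd(idx, d)
  sph <- array(0L, d)
  sph[idx[(co[, 1] - cc)^2 + (co[, 2] - cc)^2 + (co[, 3] - cc)^2 <= 100]] <- 1L
  m <- pore_metrics(sph, region, voxel_edge_um = 10)
  expect_equal(m$mean_pore_diameter_um, 200, tolerance = 0.05)
  expect_equal(m$visible_porosity, sum(sph) / prod(d))
})

test_that("compactness and structural estimates follow the porosity algebra", {
  expect_equal(compactness(0.17, 0.17), 0)
  expect_equal(compactness(0.45 * 0.17, 0.17), 0.55)
  expect_equal(compactness(0, 0.17), 1)
  expect_error(compactness(0.1, 0), "positive")

  # unchanged visible porosity recovers the initial bulk density exactly
  se <- structural_estimates(0.17, 0.17)
  expect_equal(se$eps_prime, 1 - 1.4 / 2.56)
  expect_equal(se$rho_b_prime, 1.4)
  # losing all total porosity drives bulk density to particle density
  # (reference visible porosity must exceed eps for this limit to exist)
  eps <- 1 - 1.4 / 2.56
  se2 <- structural_estimates(0.5 - eps + 1e-9, 0.5)
  expect_equal(se2$rho_b_prime, 2.56, tolerance = 1e-6)
  expect_error(structural_estimates(0.5 - eps - 0.01, 0.5), "outside")
  # identity rho_b' = (1 - eps') rho_p holds for every bin
  se3 <- structural_estimates(seq(0.05, 0.17, by = 0.01), 0.17)
  expect_equal(se3$rho_b_prime, (1 - se3$eps_prime) * 2.56)
})

test_that("an isolated cone void is returned as the entire pore space", {
  pc <- phantom_config(domain_diameter_mm = 3, domain_height_mm = 3,
                       voxel_edge_um = 50, imprint_volume_mm3 = 0.6,
                       halo_amplitude = 0, eps_vis = 0.05)
  ph <- gen_ct_phantom(pc, seed = 3)
  only_cone <- voxel_volume(
    array(as.integer(ph$ground_truth$imprint_mask), dim(ph$binary$values)),
    50)
  imp <- isolate_imprint(only_cone)
  expect_identical(imp$imprint_mask, ph$ground_truth$imprint_mask)
  expect_equal(sum(imp$residual_pores), 0)
  # empty volume errors
  expect_error(isolate_imprint(voxel_volume(array(0L, c(10, 10, 10)), 50)),
               "empty pore space")
})

test_that("a thin neck between the cone and a large pore is severed", {
  pc <- phantom_config(domain_diameter_mm = 4, domain_height_mm = 4,
                       voxel_edge_um = 50, imprint_volume_mm3 = 1.2,
                       halo_amplitude = 0, eps_vis = 0.05)
  ph <- gen_ct_phantom(pc, seed = 5)
  d <- dim(ph$binary$values)
  cone <- ph$ground_truth$imprint_mask
  vol <- array(as.integer(cone), d)
  # attach a 14-voxel-radius blob to the cone flank through a 2-voxel neck
  ind <- which(cone, arr.ind = TRUE)
  anchor <- ind[which.max(ind[, 2]), ]
  centre <- anchor + c(0, 18, 0)
  co <- arrayInd(seq_len(prod(d)), d)
  blob <- (co[, 1] - centre[1])^2 + (co[, 2] - centre[2])^2 +
    (co[, 3] - centre[3])^2 <= 14^2
  vol[blob] <- 1L
  neck <- abs(co[, 1] - anchor[1]) <= 1 & abs(co[, 3] - anchor[3]) <= 1 &
    co[, 2] >= anchor[2] & co[, 2] <= centre[2]
  vol[neck] <- 1L
  vv <- voxel_volume(array(vol, d), 50)
  imp <- isolate_imprint(vv)
  # the blob ends up in the residual pores, not in the imprint
  blob_arr <- array(blob, d)
  expect_lt(sum(imp$imprint_mask & blob_arr) / sum(blob_arr), 0.1)
  expect_gt(sum(imp$imprint_mask & cone) / sum(cone), 0.9)
  # oracle check: without the neck the two bodies are separate components
  vol2 <- vv$values
  vol2[array(neck, d)] <- 0L
  expect_equal(max(canonical_labels(flood_fill_oracle(
    (vol2 == 1L) & (array(blob, d) | cone), 26))), 2)
})

test_that("region masks hit their target volumes at voxel-layer precision", {
  pc <- small_phantom_config(halo_amplitude = 0)
  ph <- gen_ct_phantom(pc, seed = 11)
  vol <- ph$binary
  gt_imp <- structure(
    list(imprint_mask = ph$ground_truth$imprint_mask,
         imprint_volume_mm3 = ph$ground_truth$imprint_volume_mm3,
         residual_pores = array(vol$values == 1L &
                                  !ph$ground_truth$imprint_mask,
                                dim(vol$values)),
         voxel_edge_um = vol$voxel_edge_um),
    class = "imprint_result")
  rm_ <- region_masks(gt_imp, vol, below_mm3 = 5, around_mm3 = 10)
  layer_mm3 <- sum(domain_mask(vol)[1, , ]) * (0.05)^3
  expect_lt(abs(rm_$below_mm3 - 5), layer_mm3 + 1e-9)
  expect_gte(rm_$around_mm3, 10)
  expect_false(any(rm_$around & gt_imp$imprint_mask))
  expect_false(any(rm_$below_tip & rm_$around))
  # below-tip region sits entirely under the tip
  tip <- max(which(gt_imp$imprint_mask, arr.ind = TRUE)[, 1])
  expect_true(all(which(rm_$below_tip, arr.ind = TRUE)[, 1] > tip))
  expect_error(region_masks(gt_imp, vol, below_mm3 = 1e5), "exceeds domain")
  # an imprint touching the bottom leaves no volume below
  bottom <- gt_imp
  bm <- bottom$imprint_mask
  bm[dim(bm)[1], 1, 1] <- TRUE
  bottom$imprint_mask <- bm
  expect_error(region_masks(bottom, vol), "domain bottom")
})

test_that("radial profiles agree across phantom resolutions", {
  mk <- function(ve) phantom_config(domain_diameter_mm = 4.8,
                                    domain_height_mm = 4.8,
                                    voxel_edge_um = ve,
                                    sphere_radius_um = 160,
                                    halo_lambda_mm = 0.8)
  profiles <- lapply(c(40, 80), function(ve) {
    ph <- gen_ct_phantom(mk(ve), seed = 13)
    vol <- ph$binary
    imp <- structure(
      list(imprint_mask = ph$ground_truth$imprint_mask,
           residual_pores = array(vol$values == 1L &
                                    !ph$ground_truth$imprint_mask,
                                  dim(vol$values)),
           voxel_edge_um = ve,
           imprint_volume_mm3 = ph$ground_truth$imprint_volume_mm3),
      class = "imprint_result")
    radial_porosity_profile(imp, max_distance_mm = 1.6,
                            domain = domain_mask(vol))
  })
  fine <- stats::approx(profiles[[1]]$distance_um, profiles[[1]]$eps_vis,
                        xout = profiles[[2]]$distance_um, rule = 2)$y
  expect_lt(max(abs(fine - profiles[[2]]$eps_vis)), 0.02)
})

test_that("profile shells far from compaction sit at background porosity", {
  pc <- small_phantom_config(halo_amplitude = 0)
  ph <- gen_ct_phantom(pc, seed = 17)
  vol <- ph$binary
  imp <- structure(
    list(imprint_mask = ph$ground_truth$imprint_mask,
         residual_pores = array(vol$values == 1L &
                                  !ph$ground_truth$imprint_mask,
                                dim(vol$values)),
         voxel_edge_um = vol$voxel_edge_um,
         imprint_volume_mm3 = ph$ground_truth$imprint_volume_mm3),
    class = "imprint_result")
  prof <- radial_porosity_profile(imp, max_distance_mm = 1.2,
                                  domain = domain_mask(vol))
  expect_true(all(abs(prof$eps_vis - 0.17) < 0.02))
  # requesting far beyond the domain truncates with a warning
  expect_warning(radial_porosity_profile(imp, max_distance_mm = 50,
                                         domain = domain_mask(vol)),
                 "truncated")
  expect_equal(nrow(radial_porosity_profile(imp, max_distance_mm = 0)), 0)
})

test_that("volumes survive a TIFF + sidecar round trip", {
  set.seed(23)
  d <- c(12, 16, 16)
  bin <- array(as.integer(runif(prod(d)) < 0.3), d)
  vol <- voxel_volume(bin, 24)
  tf <- withr::local_tempfile(fileext = ".tif")
  write_voxel_volume(vol, tf)
  back <- read_voxel_volume(tf)
  expect_identical(array(as.integer(back$values), d), bin)
  expect_equal(back$voxel_edge_um, 24)
  grey <- voxel_volume(array(sample(0:255, prod(d), TRUE), d), 24,
                       binary = FALSE)
  tg <- withr::local_tempfile(fileext = ".tif")
  write_voxel_volume(grey, tg)
  gback <- read_voxel_volume(tg)
  expect_equal(gback$values, grey$values)
})
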