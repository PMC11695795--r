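#' CT phantom configuration
#'
#' Geometry and statistics of the synthetic cylindrical soil volume: a
#' cone-shaped imprint void with a cylindrical penetration channel above
#' it, a Boolean random-sphere background pore field, and a radially
#' decaying compaction halo that thins the pore field near the imprint.
#' The default is a reduced-size phantom (6 mm diameter x 6 mm height at
#' 40 um voxels, about 3.4e6 voxels) whose mm-specified features scale
#' with the domain; finer resolutions are supported through
#' `voxel_edge_um`.
#'
#' @param domain_diameter_mm,domain_height_mm Cylinder dimensions, mm.
#' @param voxel_edge_um Voxel edge length, um.
#' @param eps_vis Background visible porosity (m^3 m^-3, default 0.17).
#' @param sphere_radius_um Radius of the Boolean spheres, um.
#' @param imprint_volume_mm3 Target imprint volume; default scales the
#'   40 mm^3 reference imprint by the domain/reference volume ratio.
#' @param tip_depth_frac Imprint tip depth as a fraction of the domain
#'   height (default 0.7).
#' @param semi_opening_angle Cone semi-opening angle, degrees.
#' @param halo_amplitude Compaction at the imprint surface as a fraction of
#'   the background porosity (0 = no halo). Default 0.85, giving a mean
#'   compactness increase of about 55% over the first half cone radius.
#' @param halo_lambda_mm Exponential decay length of the halo, mm.
#' @param grey Also build an 8-bit grey rendering (two-mode intensities,
#'   box-blurred, with Gaussian noise).
#' @param grey_pore,grey_matrix,grey_noise_sd Grey levels and noise sd.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(domain_diameter_mm = 6, domain_height_mm = 6,
                           voxel_edge_um = 40, eps_vis = 0.17,
                           sphere_radius_um = 80,
                           imprint_volume_mm3 = NULL,
                           tip_depth_frac = 0.7,
                           semi_opening_angle = 15,
                           halo_amplitude = 0.85, halo_lambda_mm = 1.25,
                           grey = FALSE, grey_pore = 60, grey_matrix = 180,
                           grey_noise_sd = 8) {
  stopifnot(domain_diameter_mm > 0, domain_height_mm > 0, voxel_edge_um > 0,
            eps_vis > 0, eps_vis < 1, sphere_radius_um > 0,
            tip_depth_frac > 0, tip_depth_frac < 1,
            halo_amplitude >= 0, halo_amplitude <= 1, halo_lambda_mm > 0)
  if (is.null(imprint_volume_mm3)) {
    vol_dom <- pi * (domain_diameter_mm / 2)^2 * domain_height_mm
    imprint_volume_mm3 <- 40 * vol_dom / (pi * 9^2 * 24)
  }
  structure(
    list(domain_diameter_mm = domain_diameter_mm,
         domain_height_mm = domain_height_mm,
         voxel_edge_um = voxel_edge_um, eps_vis = eps_vis,
         sphere_radius_um = sphere_radius_um,
         imprint_volume_mm3 = imprint_volume_mm3,
         tip_depth_frac = tip_depth_frac,
         semi_opening_angle = semi_opening_angle,
         halo_amplitude = halo_amplitude,
         halo_lambda_mm = halo_lambda_mm,
         grey = grey, grey_pore = grey_pore, grey_matrix = grey_matrix,
         grey_noise_sd = grey_noise_sd),
    class = "phantom_config")
}

# cone + channel imprint mask; returns list(mask, r_mm)
build_imprint_void <- function(d, ve_mm, pc) {
  tip_mm <- pc$tip_depth_frac * d[1] * ve_mm
  tanb <- tan(deg2rad(pc$semi_opening_angle))
  # solve channel/cone radius from the target volume:
  # V(r) = pi r^2 (tip - r/tanb) + pi r^2 (r/tanb) / 3
  vol_fun <- function(r) {
    hc <- r / tanb
    if (hc >= tip_mm) return(Inf)
    pi * r^2 * (tip_mm - hc) + pi * r^2 * hc / 3 - pc$imprint_volume_mm3
  }
  upper <- tip_mm * tanb * 0.999
  if (vol_fun(upper) < 0)
    stop("imprint volume too large for the domain geometry")
  r_mm <- stats::uniroot(vol_fun, c(1e-6, upper))$root
  hc <- r_mm / tanb
  zb <- tip_mm - hc
  cy <- (d[2] + 1) / 2
  cz <- (d[3] + 1) / 2
  r2 <- outer(((seq_len(d[2]) - cy) * ve_mm)^2,
              ((seq_len(d[3]) - cz) * ve_mm)^2, `+`)
  mask <- array(FALSE, d)
  for (i in seq_len(d[1])) {
    z <- (i - 0.5) * ve_mm
    if (z > tip_mm) break
    ri <- if (z <= zb) r_mm else r_mm * (tip_mm - z) / hc
    if (ri <= 0) break
    mask[i, , ] <- r2 <= ri^2
  }
  list(mask = mask, r_mm = r_mm, tip_mm = tip_mm)
}

#' Generate a CT phantom with known ground truth
#'
#' Builds a cylindrical binary pore volume containing (unless `reference`)
#' a cone-shaped imprint void and a Boolean random-sphere pore field whose
#' sphere placement is thinned near the imprint by
#' `halo_amplitude * exp(-d / halo_lambda_mm)` to mimic the compaction
#' halo. With `grey = TRUE` in the configuration an 8-bit grey rendering
#' is returned as well.
#'
#' @param config A [generator_config()] (its `$phantom` is used) or a
#'   [phantom_config()].
#' @param reference Build an unpenetrated reference volume (no imprint, no
#'   halo), as used to estimate the reference visible porosity.
#' @param seed Integer seed.
#' @return List with `binary` (a [voxel_volume()]), `grey` (a
#'   [voxel_volume()] or `NULL`), and `ground_truth` (imprint mask and
#'   volume, background porosity, halo parameters, seed).
#' @export
gen_ct_phantom <- function(config, reference = FALSE, seed = NULL) {
  pc <- if (inherits(config, "generator_config")) config$phantom else config
  stopifnot(inherits(pc, "phantom_config"))
  if (is.null(seed))
    seed <- if (inherits(config, "generator_config")) config$seed else 1L
  set.seed(seed)
  ve_mm <- pc$voxel_edge_um / 1000
  nx <- as.integer(round(pc$domain_diameter_mm / ve_mm))
  nz <- as.integer(round(pc$domain_height_mm / ve_mm))
  d <- c(nz, nx, nx)

  if (!reference) {
    imp <- build_imprint_void(d, ve_mm, pc)
    dist_mm <- array(cpp_edt3d(as.integer(imp$mask), d), d) * ve_mm
  } else {
    imp <- NULL
  }

  rs_vox <- pc$sphere_radius_um / pc$voxel_edge_um
  v_sphere <- 4 / 3 * pi * rs_vox^3
  n_dom_vox <- as.numeric(nz) * nx * nx
  n_spheres <- ceiling(-log(1 - pc$eps_vis) * n_dom_vox / v_sphere)
  if (rs_vox < 1)
    stop("target porosity unreachable: sphere radius below one voxel")

  # uniform centres in the bounding box; halo thinning by distance from
  # the imprint surface
  ci <- stats::runif(n_spheres, 0.5, nz + 0.5)
  cj <- stats::runif(n_spheres, 0.5, nx + 0.5)
  ck <- stats::runif(n_spheres, 0.5, nx + 0.5)
  if (!reference && pc$halo_amplitude > 0) {
    di <- pmin(pmax(round(ci), 1), nz)
    dj <- pmin(pmax(round(cj), 1), nx)
    dk <- pmin(pmax(round(ck), 1), nx)
    dcen <- dist_mm[cbind(di, dj, dk)]
    keep <- stats::runif(n_spheres) >
      pc$halo_amplitude * exp(-dcen / pc$halo_lambda_mm)
    ci <- ci[keep]; cj <- cj[keep]; ck <- ck[keep]
  }

  pores <- array(FALSE, d)
  r_int <- ceiling(rs_vox)
  off <- seq(-r_int, r_int)
  for (s in seq_along(ci)) {
    i0 <- round(ci[s]); j0 <- round(cj[s]); k0 <- round(ck[s])
    ii <- i0 + off; jj <- j0 + off; kk <- k0 + off
    ok_i <- ii >= 1 & ii <= nz; ok_j <- jj >= 1 & jj <= nx
    ok_k <- kk >= 1 & kk <= nx
    if (!any(ok_i) || !any(ok_j) || !any(ok_k)) next
    bi <- ii[ok_i]; bj <- jj[ok_j]; bk <- kk[ok_k]
    sph <- outer(outer((bi - ci[s])^2, (bj - cj[s])^2, `+`),
                 (bk - ck[s])^2, `+`) <= rs_vox^2
    pores[bi, bj, bk] <- pores[bi, bj, bk] | sph
  }
  if (!reference) pores <- pores | imp$mask

  binary <- voxel_volume(array(as.integer(pores), d), pc$voxel_edge_um)
  grey <- NULL
  if (isTRUE(pc$grey)) {
    g <- array(ifelse(pores, pc$grey_pore, pc$grey_matrix), d)
    g <- array(cpp_boxblur3d(g, d, 1L), d)
    g <- g + stats::rnorm(length(g), 0, pc$grey_noise_sd)
    g <- pmin(pmax(round(g), 0), 255)
    grey <- voxel_volume(array(g, d), pc$voxel_edge_um, binary = FALSE)
  }
  list(binary = binary, grey = grey,
       ground_truth = list(
         imprint_mask = if (reference) NULL else imp$mask,
         imprint_volume_mm3 = if (reference) 0 else sum(imp$mask) * ve_mm^3,
         imprint_radius_mm = if (reference) NA_real_ else imp$r_mm,
         tip_depth_mm = if (reference) NA_real_ else imp$tip_mm,
         eps_vis_background = pc$eps_vis,
         halo_amplitude = pc$halo_amplitude,
         halo_lambda_mm = pc$halo_lambda_mm,
         reference = reference, seed = seed))
}
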