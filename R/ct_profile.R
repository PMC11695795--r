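#' Pore metrics of a region
#'
#' Visible porosity (pore voxels / region voxels) and the volume-weighted
#' mean equivalent-sphere diameter of the labelled pore clusters
#' intersecting the region.
#'
#' @param pores Logical/0-1 array of residual pores (imprint removed) or a
#'   binary [voxel_volume()].
#' @param region Logical array delimiting the region.
#' @param voxel_edge_um Voxel edge length in micrometres (taken from the
#'   volume when `pores` is a [voxel_volume()]).
#' @param connectivity Labelling connectivity (default 26).
#' @return List with `visible_porosity`, `mean_pore_diameter_um`,
#'   `n_pores`, and `region_volume_mm3`.
#' @export
pore_metrics <- function(pores, region, voxel_edge_um = NULL,
                         connectivity = 26) {
  if (inherits(pores, "voxel_volume")) {
    if (is.null(voxel_edge_um)) voxel_edge_um <- pores$voxel_edge_um
    pores <- pores$values
  }
  stopifnot(is.array(pores), is.array(region),
            all(dim(pores) == dim(region)), !is.null(voxel_edge_um))
  nreg <- sum(region)
  if (nreg == 0) stop("empty region")
  inreg <- array(as.integer(pores != 0 & region), dim(pores))
  poro <- sum(inreg) / nreg
  if (sum(inreg) == 0)
    return(list(visible_porosity = 0, mean_pore_diameter_um = NA_real_,
                n_pores = 0L,
                region_volume_mm3 = nreg * (voxel_edge_um / 1000)^3))
  lab <- cpp_label3d(inreg, dim(pores), as.integer(connectivity))
  vols_vox <- tabulate(lab[lab > 0L])
  diam <- 2 * (3 * vols_vox / (4 * pi))^(1 / 3) * voxel_edge_um
  list(visible_porosity = poro,
       mean_pore_diameter_um = sum(vols_vox * diam) / sum(vols_vox),
       n_pores = length(vols_vox),
       region_volume_mm3 = nreg * (voxel_edge_um / 1000)^3)
}

#' Radial visible-porosity profile around the cone imprint
#'
#' The imprint is dilated with a spherical (Euclidean) structuring element
#' in steps of `step_voxels` voxels (60 um at 12 um resolution),
#' implemented by thresholding the Euclidean distance transform of the
#' imprint surface; each step's newly reached voxels within the analysis
#' domain form a shell, and the pore fraction of the residual pore system
#' within that shell gives the visible porosity at that distance.
#'
#' @param imprint An `imprint_result` from [isolate_imprint()], or a logical
#'   imprint mask (then `residual`, `domain` and `voxel_edge_um` are
#'   required).
#' @param max_distance_mm Largest distance from the imprint surface to
#'   profile, in mm.
#' @param step_voxels Dilation step in voxels per iteration (default 5).
#' @param residual,domain,voxel_edge_um Overrides when `imprint` is a bare
#'   mask.
#' @return Data frame with `bin`, `distance_um` (outer edge of the shell),
#'   `eps_vis` and `n_voxels`. Truncated with a warning if the domain is
#'   exhausted before `max_distance_mm`.
#' @export
radial_porosity_profile <- function(imprint, max_distance_mm,
                                    step_voxels = 5, residual = NULL,
                                    domain = NULL, voxel_edge_um = NULL) {
  if (inherits(imprint, "imprint_result")) {
    if (is.null(residual)) residual <- imprint$residual_pores
    if (is.null(voxel_edge_um)) voxel_edge_um <- imprint$voxel_edge_um
    mask <- imprint$imprint_mask
  } else mask <- imprint
  stopifnot(is.array(mask), !is.null(residual), !is.null(voxel_edge_um))
  d <- dim(mask)
  if (is.null(domain)) domain <- array(TRUE, d)
  step_um <- step_voxels * voxel_edge_um
  n_bins <- floor(max_distance_mm * 1000 / step_um)
  if (n_bins < 1) return(data.frame(bin = integer(0),
                                    distance_um = numeric(0),
                                    eps_vis = numeric(0),
                                    n_voxels = integer(0)))
  edt <- array(cpp_edt3d(as.integer(mask), d), d)
  rows <- vector("list", n_bins)
  for (j in seq_len(n_bins)) {
    shell <- edt > (j - 1) * step_voxels & edt <= j * step_voxels & domain &
      !mask
    if (sum(shell) == 0) {
      warning("profile truncated: domain exhausted at bin ", j)
      rows <- rows[seq_len(j - 1)]
      break
    }
    rows[[j]] <- data.frame(
      bin = j, distance_um = j * step_um,
      eps_vis = sum(residual[shell]) / sum(shell),
      n_voxels = sum(shell))
  }
  do.call(rbind, rows)
}

#' Relative change in soil compactness
#'
#' Delta_c = 1 - eps_vis' / eps_vis_ref: the relative reduction of visible
#' porosity against the unpenetrated reference (the mean visible porosity
#' of the samples not subjected to penetrometer tests).
#'
#' @param eps_vis_prime Visible porosity after penetration (scalar or per
#'   profile bin).
#' @param eps_vis_ref Reference visible porosity (> 0).
#' @return Delta_c (dimensionless; 0 = unchanged, 1 = all visible pores
#'   lost).
#' @export
compactness <- function(eps_vis_prime, eps_vis_ref) {
  stopifnot(is.numeric(eps_vis_prime), is.numeric(eps_vis_ref))
  if (eps_vis_ref <= 0) stop("reference visible porosity must be positive")
  1 - eps_vis_prime / eps_vis_ref
}

#' Estimated total porosity and bulk density after penetration
#'
#' Changes in visible porosity are carried over to total porosity:
#' eps' = (1 - rho_b / rho_p) - (eps_vis_ref - eps_vis'), and the
#' corresponding bulk density is rho_b' = (1 - eps') rho_p (exact
#' identity). Total porosity before penetration is computed internally as
#' 1 - rho_b / rho_p so that an unchanged visible porosity recovers rho_b
#' exactly. Changes in non-visible porosity are neglected.
#'
#' @param eps_vis_prime Visible porosity after penetration (vectorised).
#' @param eps_vis_ref Reference visible porosity before penetration.
#' @param rho_b Bulk density before penetration in g/cm^3 (default 1.4).
#' @param rho_p Particle density in g/cm^3 (default 2.56).
#' @return Data frame with `eps_vis_prime`, `delta_eps_vis`, `eps_prime`
#'   and `rho_b_prime`; attributes `eps`, `rho_b`, `rho_p`.
#' @export
structural_estimates <- function(eps_vis_prime, eps_vis_ref,
                                 rho_b = 1.4, rho_p = 2.56) {
  stopifnot(is.numeric(eps_vis_prime), all(eps_vis_prime >= 0),
            is.numeric(eps_vis_ref), eps_vis_ref > 0,
            rho_b > 0, rho_p > 0, rho_b < rho_p)
  eps <- 1 - rho_b / rho_p
  delta_eps_vis <- eps_vis_ref - eps_vis_prime
  eps_prime <- eps - delta_eps_vis
  if (any(eps_prime <= 0 | eps_prime >= 1))
    stop("estimated total porosity outside (0, 1)")
  out <- data.frame(eps_vis_prime = eps_vis_prime,
                    delta_eps_vis = delta_eps_vis,
                    eps_prime = eps_prime,
                    rho_b_prime = (1 - eps_prime) * rho_p)
  attr(out, "eps") <- eps
  attr(out, "rho_b") <- rho_b
  attr(out, "rho_p") <- rho_p
  out
}

#' Fit an exponential compaction halo to a porosity profile
#'
#' Estimates the decay length lambda and surface amplitude A of a
#' compaction halo in which the pore *placement intensity* is thinned by
#' A exp(-d / lambda). In a Boolean (random-sphere) medium the visible
#' porosity is a concave function of that intensity,
#' eps(d) = 1 - (1 - eps_ref)^(1 - A exp(-d / lambda)),
#' so the compactness change Delta_c = 1 - eps(d)/eps_ref is slightly
#' steeper than a bare exponential; the fit uses the exact relation, by
#' weighted (shell-size) nonlinear least squares on the untransformed
#' compactness. A log-linear fit over the bins with Delta_c above
#' `min_dc` provides the starting values.
#'
#' @param profile Data frame from [radial_porosity_profile()].
#' @param eps_vis_ref Reference visible porosity.
#' @param min_dc Smallest compactness change used for the starting-value
#'   fit (default 0.05).
#' @param skip_bins Number of innermost shells excluded from the fit
#'   (default 1): pores straddling the imprint surface are truncated when
#'   the imprint is subtracted, which depresses the visible porosity of
#'   the first shell and steepens the apparent decay.
#' @return List with `lambda_um`, `amplitude` (intensity thinning at the
#'   imprint surface) and the fitted `nls` object.
#' @export
fit_halo_decay <- function(profile, eps_vis_ref, min_dc = 0.05,
                           skip_bins = 1) {
  if (skip_bins > 0 && nrow(profile) > skip_bins + 2)
    profile <- profile[-seq_len(skip_bins), ]
  dc <- compactness(profile$eps_vis, eps_vis_ref)
  keep <- dc > min_dc
  if (sum(keep) < 3) stop("too few bins with measurable compaction")
  d_um <- profile$distance_um
  start_fit <- stats::lm(log(dc[keep]) ~ d_um[keep])
  slope <- unname(stats::coef(start_fit)[2])
  if (slope >= 0) stop("compactness does not decay with distance")
  w <- if ("n_voxels" %in% names(profile)) profile$n_voxels
       else rep(1, length(dc))
  fit <- stats::nls(
    dc ~ 1 - (1 - (1 - eps_vis_ref)^(1 - a * exp(-d_um / lambda))) /
      eps_vis_ref,
    start = list(a = min(exp(unname(stats::coef(start_fit)[1])), 1),
                 lambda = -1 / slope),
    weights = w, control = list(maxiter = 500, warnOnly = TRUE))
  est <- stats::coef(fit)
  if (est["lambda"] <= 0) stop("compactness does not decay with distance")
  list(lambda_um = unname(est["lambda"]), amplitude = unname(est["a"]),
       fit = fit)
}
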