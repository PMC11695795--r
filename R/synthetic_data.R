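#' Default treatment table of mean mechanical resistance
#'
#' The eight (shaft material x circumnutation frequency) treatment cells of
#' the reference experiment with their mean mechanical resistance over the
#' 0-10 mm penetration: 0.79 MPa for stationary samples (both materials),
#' a 10% reduction to 0.71 MPa for the stiff steel shaft at 1 and 5
#' oscillations/cm (no reduction for the flexible brass shaft there), and
#' a 15% reduction to 0.67 MPa for both materials at 10 oscillations/cm.
#'
#' @return Data frame with columns `material`, `f`, `Q_MPa`.
#' @export
default_treatment_table <- function() {
  data.frame(
    material = rep(c("steel", "brass"), each = 4),
    f = rep(c(0, 1, 5, 10), 2),
    Q_MPa = c(0.79, 0.71, 0.71, 0.67,
              0.79, 0.79, 0.79, 0.67))
}

#' Default per-treatment horizontal cone deflections
#'
#' Calibration of the generator's deflection targets (mm): the flexible
#' brass shaft deflects 0.30 mm at every frequency (amplitude 0.70 mm);
#' the stiff steel shaft deflects 0.19, 0.22 and 0.30 mm at 1, 5 and 10
#' oscillations/cm (amplitudes 0.81-0.70 mm). Stationary treatments carry
#' zero deflection.
#'
#' @return Data frame with columns `material`, `f`, `delta_c_mm`.
#' @export
default_deflection_table <- function() {
  data.frame(
    material = rep(c("steel", "brass"), each = 4),
    f = rep(c(0, 1, 5, 10), 2),
    delta_c_mm = c(0, 0.19, 0.22, 0.30,
                   0, 0.30, 0.30, 0.30))
}

#' Generator configuration
#'
#' Bundles every knob of the synthetic experiment: the treatment table (or
#' the mechanistic forward-model parameters), probe geometry and stiffness,
#' noise levels, replication, sampling, and the CT phantom geometry.
#'
#' @param mode `"table"` (traces drawn around the treatment-table means) or
#'   `"mechanistic"` (traces built from the cavity-expansion forward model).
#' @param treatment_table Data frame `material, f, Q_MPa` (table mode).
#' @param deflection_table Data frame `material, f, delta_c_mm`.
#' @param stationary_Q_MPa Stationary mean resistance used to calibrate the
#'   mechanistic radial stress (MPa).
#' @param friction_attenuation Dimensionless coefficient a in the
#'   mechanistic friction model Ff,m = Ff,s (1 - a CI).
#' @param mu Metal-soil friction coefficient.
#' @param fmax Maximum circumnutation frequency tested (oscillations/cm).
#' @param noise_sd Gaussian noise sd on resistance samples, MPa.
#' @param ar1_rho AR(1) coefficient for the trace noise (0 = white noise).
#' @param angle_noise_sd Gaussian noise sd on projected angles, degrees.
#' @param n_replicates Replicates per treatment.
#' @param sampling_hz Force sampling rate, Hz.
#' @param speed_cm_h Penetration speed, cm/h.
#' @param depth_mm Penetration depth, mm.
#' @param stiffness Named vector of shaft bending stiffness k, N/mm.
#' @param probe_geometry List with `cone_base_radius`, `semi_opening_angle`,
#'   `shaft_length`, `orbit_radius`.
#' @param phantom A [phantom_config()].
#' @param seed Integer seed; identical configurations give identical
#'   outputs.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(mode = c("table", "mechanistic"),
                             treatment_table = default_treatment_table(),
                             deflection_table = default_deflection_table(),
                             stationary_Q_MPa = 0.79,
                             friction_attenuation = 2,
                             mu = 0.5,
                             fmax = 10,
                             noise_sd = 0.02,
                             ar1_rho = 0,
                             angle_noise_sd = 0.01,
                             n_replicates = 5,
                             sampling_hz = 1,
                             speed_cm_h = 1,
                             depth_mm = 10,
                             stiffness = c(steel = 6.96, brass = 2.96),
                             probe_geometry = list(cone_base_radius = 2.5,
                                                   semi_opening_angle = 15,
                                                   shaft_length = 45,
                                                   orbit_radius = 1),
                             phantom = phantom_config(),
                             seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(treatment_table), nrow(treatment_table) >= 1,
            all(c("material", "f", "Q_MPa") %in% names(treatment_table)),
            all(treatment_table$Q_MPa > 0),
            is.data.frame(deflection_table),
            all(c("material", "f", "delta_c_mm") %in%
                  names(deflection_table)),
            noise_sd >= 0, angle_noise_sd >= 0, n_replicates >= 1,
            sampling_hz > 0, speed_cm_h > 0, depth_mm > 0,
            ar1_rho >= 0, ar1_rho < 1,
            !is.null(names(stiffness)), all(stiffness > 0))
  structure(
    list(mode = mode, treatment_table = treatment_table,
         deflection_table = deflection_table,
         stationary_Q_MPa = stationary_Q_MPa,
         friction_attenuation = friction_attenuation, mu = mu, fmax = fmax,
         noise_sd = noise_sd, ar1_rho = ar1_rho,
         angle_noise_sd = angle_noise_sd, n_replicates = n_replicates,
         sampling_hz = sampling_hz, speed_cm_h = speed_cm_h,
         depth_mm = depth_mm, stiffness = stiffness,
         probe_geometry = probe_geometry, phantom = phantom,
         seed = as.integer(seed)),
    class = "generator_config")
}

#' Probe specifications implied by a generator configuration
#' @param config A [generator_config()].
#' @return Named list of [probe_spec()] objects, one per shaft material.
#' @export
config_probes <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  g <- config$probe_geometry
  stats::setNames(lapply(names(config$stiffness), function(m)
    probe_spec(cone_base_radius = g$cone_base_radius,
               semi_opening_angle = g$semi_opening_angle,
               shaft_length = g$shaft_length,
               bending_stiffness = unname(config$stiffness[m]),
               material = m, orbit_radius = g$orbit_radius)),
    names(config$stiffness))
}

ar1_noise <- function(n, sd, rho) {
  if (sd == 0) return(rep(0, n))
  if (rho == 0) return(stats::rnorm(n, 0, sd))
  e <- stats::rnorm(n, 0, sd * sqrt(1 - rho^2))
  stats::filter(e, rho, method = "recursive", init = stats::rnorm(1, 0, sd))
}

# mechanistic per-treatment mean resistance: Fz = Fc,s + Ff,s (1 - a CI)
mechanistic_targets <- function(config) {
  probes <- config_probes(config)
  fric <- friction_params(mu = config$mu)
  tt <- config$deflection_table
  Q <- numeric(nrow(tt))
  gt <- vector("list", nrow(tt))
  for (r in seq_len(nrow(tt))) {
    probe <- probes[[tt$material[r]]]
    Fz_stat <- force_from_resistance(config$stationary_Q_MPa, probe)
    sigma <- radial_stress_stationary(Fz_stat, probe, fric)
    dec <- stationary_decomposition(sigma, probe, fric)
    Fro <- orbital_radial_force(tt$delta_c_mm[r], probe)
    Ia <- asymmetry_index(Fro, dec$Fr_s)
    CI <- circumnutation_intensity(Ia, tt$f[r], config$fmax)
    Fz <- dec$Fc_s + dec$Ff_s * (1 - config$friction_attenuation * CI)
    Q[r] <- resistance_from_force(Fz, probe)
    gt[[r]] <- list(material = tt$material[r], f = tt$f[r],
                    sigma_rs = sigma, Fc_s = dec$Fc_s, Ff_s = dec$Ff_s,
                    Iasym = Ia, CI = CI, Fz = Fz)
  }
  list(Q = Q, ground_truth = gt)
}

#' Generate synthetic penetration-force traces
#'
#' Simulates the per-second force record of every replicate of every
#' treatment during a constant-speed penetration. In table mode the trace
#' fluctuates around the treatment-table mean resistance; in mechanistic
#' mode the mean is built from the cavity-expansion forward model
#' Fz = Fc,s + Ff,s (1 - a CI), with sigma_r,s calibrated by inverting the
#' stationary force balance at the configured stationary resistance.
#'
#' @param config A [generator_config()].
#' @param seed Seed override (defaults to `config$seed`).
#' @return List with `traces` (data frame `material, f, replicate, time_s,
#'   depth_mm, Fz_N`), `meta` (per-treatment table with the generating
#'   resistance), and `ground_truth` (mechanistic components when
#'   applicable).
#' @export
gen_force_traces <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(seed)
  probes <- config_probes(config)
  tt <- config$treatment_table
  if (config$mode == "mechanistic") {
    mt <- mechanistic_targets(config)
    tt <- config$deflection_table
    tt$Q_MPa <- mt$Q
  } else {
    need <- merge(unique(tt[c("material", "f")]),
                  config$deflection_table, all.x = TRUE)
    if (any(is.na(need$delta_c_mm)))
      stop("treatment table and deflection table are inconsistent")
    mt <- NULL
  }
  n_per_cm <- 3600 * config$sampling_hz / config$speed_cm_h
  n <- as.integer(round(n_per_cm * config$depth_mm / 10))
  depth <- (seq_len(n) - 0.5) / n * config$depth_mm
  time_s <- (seq_len(n) - 0.5) / config$sampling_hz
  rows <- list()
  for (r in seq_len(nrow(tt))) {
    probe <- probes[[tt$material[r]]]
    for (rep_i in seq_len(config$n_replicates)) {
      Q <- tt$Q_MPa[r] + ar1_noise(n, config$noise_sd, config$ar1_rho)
      rows[[length(rows) + 1]] <- data.frame(
        material = tt$material[r], f = tt$f[r], replicate = rep_i,
        time_s = time_s, depth_mm = depth,
        Fz_N = force_from_resistance(pmax(Q, 0), probe))
    }
  }
  list(traces = do.call(rbind, rows),
       meta = tt,
       ground_truth = if (is.null(mt)) NULL else mt$ground_truth)
}

#' Generate a synthetic projected deflection-angle series
#'
#' The probe deflection during one orbital oscillation projects onto the
#' camera plane as (approximately) a sinusoid; the generator inverts the
#' deflection formula to pick the peak-to-peak angle
#' `delta_alpha = 2 asin(delta_c / ls)` that makes the deflection chain
#' return the configured cone deflection. Samples are 1 min apart, starting
#' at t = 0 so every oscillation window contains its extremes exactly
#' (noise-free round trips are exact to machine precision).
#'
#' @param config A [generator_config()].
#' @param material Shaft material (must be in `config$stiffness`).
#' @param f Circumnutation frequency, oscillations/cm (0 = stationary).
#' @param delta_c_mm Target cone deflection; default from the config's
#'   deflection table.
#' @param alpha0_deg Baseline projected angle (degrees, default 0).
#' @param seed Seed override.
#' @return Data frame `time_min, angle_deg` with attributes `delta_c_mm`
#'   (ground truth) and `delta_alpha_deg`.
#' @export
gen_deflection_series <- function(config, material, f, delta_c_mm = NULL,
                                  alpha0_deg = 0, seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(seed)
  ls <- config$probe_geometry$shaft_length
  if (is.null(delta_c_mm)) {
    dt <- config$deflection_table
    hit <- dt$material == material & dt$f == f
    if (!any(hit)) stop("no deflection default for this treatment")
    delta_c_mm <- dt$delta_c_mm[hit][1]
  }
  if (delta_c_mm > ls) stop("deflection exceeds shaft length")
  minutes_per_cm <- 60 / config$speed_cm_h
  depth_cm <- config$depth_mm / 10
  t <- seq(0, minutes_per_cm * depth_cm - 1, by = 1)
  if (f == 0 || delta_c_mm == 0) {
    ang <- rep(alpha0_deg, length(t))
  } else {
    delta_alpha <- 2 * asin(delta_c_mm / ls) * 180 / pi
    period <- minutes_per_cm / f
    ang <- alpha0_deg + delta_alpha / 2 * cos(2 * pi * t / period)
  }
  ang <- ang + stats::rnorm(length(t), 0, config$angle_noise_sd)
  out <- data.frame(time_min = t, angle_deg = ang)
  attr(out, "delta_c_mm") <- delta_c_mm
  attr(out, "delta_alpha_deg") <- if (f == 0 || delta_c_mm == 0) 0 else
    2 * asin(delta_c_mm / ls) * 180 / pi
  out
}
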