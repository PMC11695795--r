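#' Friction parameters
#'
#' @param mu Metal-soil friction coefficient used during the measurement
#'   (dimensionless, in `[0, 1]`; 0.5 for a steel cone in moist silt loam).
#' @param mu_prime Alternative interfacial friction coefficient(s) used to
#'   rescale the measured forces to other interfaces (e.g. root-soil,
#'   0.1-0.5). May be a vector.
#' @return An object of class `friction_params`.
#' @export
friction_params <- function(mu = 0.5, mu_prime = 0.1) {
  stopifnot(is.numeric(mu), length(mu) == 1, mu >= 0, mu <= 1,
            is.numeric(mu_prime), all(mu_prime >= 0), all(mu_prime <= 1))
  structure(list(mu = mu, mu_prime = mu_prime), class = "friction_params")
}

cot_deg <- function(beta_deg) {
  stopifnot(beta_deg > 0, beta_deg < 90)
  1 / tan(deg2rad(beta_deg))
}

#' Mechanical resistance from axial force
#'
#' Q = Fz / (pi rc^2): penetration force divided by the cone base area.
#' With Fz in N and rc in mm the result is in MPa.
#'
#' @param Fz Axial force in N (>= 0).
#' @param probe A [probe_spec()].
#' @return Mechanical resistance Q in MPa.
#' @export
resistance_from_force <- function(Fz, probe) {
  stopifnot(is.numeric(Fz), all(Fz >= 0))
  Fz / cone_base_area(probe)
}

#' Axial force from mechanical resistance (inverse of
#' [resistance_from_force()])
#' @param Q Mechanical resistance in MPa.
#' @param probe A [probe_spec()].
#' @return Axial force in N.
#' @export
force_from_resistance <- function(Q, probe) {
  stopifnot(is.numeric(Q), all(Q >= 0))
  Q * cone_base_area(probe)
}

#' Radial stress on the cone for stationary samples
#'
#' Inverts the stationary force balance: the mean measured axial force is
#' the cavity-expansion force plus Coulomb friction on the cone flank, so
#' sigma_r,s = Fz_mean / (pi rc^2 \[1 + mu cot(beta_c)\]).
#'
#' @param Fz_mean Mean axial force of the stationary replicates in N (> 0).
#' @param probe A [probe_spec()].
#' @param fric A [friction_params()].
#' @return Radial stress sigma_r,s in MPa.
#' @export
radial_stress_stationary <- function(Fz_mean, probe, fric = friction_params()) {
  stopifnot(is.numeric(Fz_mean), all(Fz_mean > 0),
            inherits(fric, "friction_params"))
  Fz_mean / (cone_base_area(probe) *
               (1 + fric$mu * cot_deg(probe$semi_opening_angle)))
}

#' Stationary force decomposition
#'
#' From the radial stress sigma_r,s, the cavity-expansion theory gives
#' * radial force: Fr,s = pi rc^2 cot(beta_c) sigma_r,s
#' * axial cavity-expansion force: Fc,s = Fr,s tan(beta_c) = pi rc^2 sigma_r,s
#' * total axial force: Fz = Fc,s \[1 + mu cot(beta_c)\]
#' * friction force: Ff,s = Fz - Fc,s (exact identity)
#'
#' @param sigma_rs Radial stress sigma_r,s in MPa (> 0).
#' @param probe A [probe_spec()].
#' @param fric A [friction_params()].
#' @return List with `Fr_s`, `Fc_s`, `Ff_s`, `Fz` (all N) and the inputs.
#' @export
stationary_decomposition <- function(sigma_rs, probe,
                                     fric = friction_params()) {
  stopifnot(is.numeric(sigma_rs), sigma_rs > 0,
            inherits(fric, "friction_params"))
  A <- cone_base_area(probe)
  cotb <- cot_deg(probe$semi_opening_angle)
  Fr_s <- A * cotb * sigma_rs
  Fc_s <- A * sigma_rs
  Fz <- Fc_s * (1 + fric$mu * cotb)
  list(sigma_rs = sigma_rs, Fr_s = Fr_s, Fc_s = Fc_s,
       Ff_s = Fz - Fc_s, Fz = Fz)
}

#' Orbital unidirectional radial force
#'
#' The bent shaft pulls the cone toward the orbit centre with a force set by
#' the cantilever stiffness: Fro = delta_c * k.
#'
#' @param delta_c Horizontal cone deflection in mm (>= 0).
#' @param probe A [probe_spec()] supplying k in N/mm.
#' @return Fro in N.
#' @export
orbital_radial_force <- function(delta_c, probe) {
  stopifnot(is.numeric(delta_c), all(delta_c >= 0))
  delta_c * probe$bending_stiffness
}

#' Radial force distribution around the cone
#'
#' F*r(gamma) = Fr,s + cos(gamma) Fro, valid under the constraint
#' Fr,s >= Fro, which keeps F*r non-negative everywhere.
#'
#' @param Fr_s Symmetric radial force in N.
#' @param Fro Orbital unidirectional radial force in N.
#' @param gamma Circumferential angle(s) in radians.
#' @return F*r(gamma) in N.
#' @export
radial_force_distribution <- function(Fr_s, Fro, gamma) {
  stopifnot(is.numeric(Fr_s), is.numeric(Fro), Fro >= 0)
  if (Fro > Fr_s) stop("asymmetry constraint violated: Fro > Fr,s")
  Fr_s + cos(gamma) * Fro
}

#' Friction force for samples subjected to orbital motion
#'
#' Assuming net cavity size and compression patterns match the stationary
#' case (Fc,m = Fc,s), the moving friction force is the residual
#' Ff,m = Fz_moving - Fc,s. A negative residual is returned with a warning
#' rather than clipped, to preserve its diagnostic value.
#'
#' @param Fz_moving Mean axial force of a moving treatment in N.
#' @param Fc_s Axial cavity-expansion force of the matching stationary
#'   decomposition (same shaft material) in N.
#' @return Ff,m in N.
#' @export
moving_friction <- function(Fz_moving, Fc_s) {
  stopifnot(is.numeric(Fz_moving), is.numeric(Fc_s))
  out <- Fz_moving - Fc_s
  if (any(out < 0))
    warning("negative friction force: Fz_moving < Fc,s")
  out
}

#' Rescale total axial force to another friction coefficient
#'
#' Fz'(mu') = Fz \[1 + mu' cot(beta_c)\] / \[1 + mu cot(beta_c)\] and
#' Ff'(mu') = Fz'(mu') - Fc,s. At mu' = 0 the rescaled force equals the
#' pure cavity-expansion force.
#'
#' @param Fz Measured total axial force in N.
#' @param fric A [friction_params()]; `mu` is the measurement value and
#'   `mu_prime` the coefficient(s) to rescale to.
#' @param probe A [probe_spec()].
#' @param Fc_s Axial cavity-expansion force in N.
#' @return Data frame with columns `mu_prime`, `Fz_prime`, `Ff_prime`.
#' @export
friction_rescale <- function(Fz, fric, probe, Fc_s) {
  stopifnot(inherits(fric, "friction_params"), is.numeric(Fz),
            is.numeric(Fc_s))
  cotb <- cot_deg(probe$semi_opening_angle)
  Fz_prime <- Fz * (1 + fric$mu_prime * cotb) / (1 + fric$mu * cotb)
  data.frame(mu_prime = fric$mu_prime, Fz_prime = Fz_prime,
             Ff_prime = Fz_prime - Fc_s)
}

#' Asymmetry index of the radial force distribution
#'
#' Iasym = \[F*r(0) - F*r(pi)\] / (2 Fr,s) = Fro / Fr,s, in `[0, 1]`;
#' larger values mean a more lopsided radial load on the cone.
#'
#' @param Fro Orbital radial force in N (>= 0).
#' @param Fr_s Symmetric radial force in N (>= Fro).
#' @return Iasym, dimensionless.
#' @export
asymmetry_index <- function(Fro, Fr_s) {
  stopifnot(is.numeric(Fro), is.numeric(Fr_s), all(Fro >= 0))
  if (any(Fro > Fr_s)) stop("asymmetry constraint violated: Fro > Fr,s")
  (radial_force_distribution(Fr_s, Fro, 0) -
     radial_force_distribution(Fr_s, Fro, pi)) / (2 * Fr_s)
}

#' Circumnutation intensity index
#'
#' CI = Iasym * f / fmax merges the radial-force asymmetry with the
#' normalised circumnutation frequency into a single predictor of friction
#' reduction.
#'
#' @param Iasym Asymmetry index in `[0, 1]`.
#' @param f Circumnutation frequency in oscillations per cm.
#' @param fmax Maximum frequency tested in the experiment (default 10).
#' @return CI, dimensionless, in `[0, Iasym]`.
#' @export
circumnutation_intensity <- function(Iasym, f, fmax = 10) {
  stopifnot(is.numeric(Iasym), all(Iasym >= 0), all(Iasym <= 1),
            is.numeric(f), all(f >= 0), fmax > 0)
  if (any(f > fmax)) stop("f exceeds fmax")
  Iasym * f / fmax
}

#' Full force decomposition over a treatment table
#'
#' Orchestrates the decomposition for a table of treatment means: the
#' stationary mean force of each shaft material calibrates sigma_r,s and
#' Fc,s for that material; moving treatments inherit Fc,s and yield Ff,m,
#' Fro, Iasym and CI from their mean cone deflection.
#'
#' @param treatments Data frame with columns `material`, `f`
#'   (oscillations/cm, 0 = stationary), `Fz_N` (mean axial force, N) and
#'   `delta_c_mm` (mean horizontal cone deflection, mm; 0 when stationary).
#' @param probes Named list of [probe_spec()] objects, one per material.
#' @param fric A [friction_params()].
#' @param fmax Maximum circumnutation frequency (default 10).
#' @return Data frame with one row per treatment and all force components.
#' @export
decompose_forces <- function(treatments, probes, fric = friction_params(),
                             fmax = 10) {
  need <- c("material", "f", "Fz_N", "delta_c_mm")
  stopifnot(is.data.frame(treatments), all(need %in% names(treatments)))
  out <- lapply(seq_len(nrow(treatments)), function(r) {
    row <- treatments[r, ]
    probe <- probes[[row$material]]
    if (is.null(probe)) stop("no probe spec for material ", row$material)
    stat <- treatments[treatments$material == row$material &
                         treatments$f == 0, ]
    if (nrow(stat) == 0)
      stop("no stationary treatment for material ", row$material)
    Fz_stat <- mean(stat$Fz_N)
    sig <- radial_stress_stationary(Fz_stat, probe, fric)
    dec <- stationary_decomposition(sig, probe, fric)
    Fro <- orbital_radial_force(row$delta_c_mm, probe)
    Ia <- asymmetry_index(Fro, dec$Fr_s)
    data.frame(
      material = row$material, f = row$f, Fz_N = row$Fz_N,
      sigma_rs_MPa = sig, Fr_s_N = dec$Fr_s, Fc_s_N = dec$Fc_s,
      Ff_s_N = dec$Ff_s,
      Ff_N = if (row$f == 0) row$Fz_N - dec$Fc_s
             else moving_friction(row$Fz_N, dec$Fc_s),
      Fro_N = Fro, Iasym = Ia,
      CI = circumnutation_intensity(Ia, row$f, fmax))
  })
  do.call(rbind, out)
}
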